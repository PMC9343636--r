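#' Detect vertically transmitted OTUs across seed generations
#'
#' A seed OTU is called transmitted when it is detected in all three
#' designated seed groups (parent harvest, sowing-stage, progeny harvest);
#' detection is applied to the across-replicate mean abundance of each group.
#' All other OTUs observed in those seed samples are transient.
#'
#' @param t [count_table()].
#' @param meta [sample_meta()].
#' @param generation_groups list of three non-overlapping character vectors of
#'   sample ids, all from compartment `Se`.
#' @param detection `"mean_gt_zero"` (default: mean abundance > 0, i.e. any
#'   read anywhere in the group) or `"min_count"` (group mean count >= `k`).
#' @param k minimum mean count for `detection = "min_count"` (default 5).
#' @return list of class `transmission_result`: `status` (named vector,
#'   transmitted/transient over seed OTUs), `presence` (OTU x group logical),
#'   `summary` (counts and cumulative relative abundance of each status per
#'   seed timepoint).
#' @export
detect_transmitted <- function(t, meta, generation_groups,
                               detection = c("mean_gt_zero", "min_count"),
                               k = 5) {
  detection <- match.arg(detection)
  meta <- check_meta_matches(t, meta)
  if (length(generation_groups) != 3) stop("need exactly three seed groups")
  ids <- unlist(generation_groups)
  if (anyDuplicated(ids)) stop("generation groups overlap")
  if (!all(ids %in% sample_ids(t))) stop("unknown sample id in groups")
  for (g in generation_groups) {
    if (!length(g)) stop("empty generation group")
    comp <- meta$compartment[match(g, meta$sample_id)]
    if (!all(comp == "Se")) stop("generation groups must be seed (Se) samples")
  }
  grp_mean <- vapply(generation_groups, function(g)
    rowMeans(unclass(t)[, g, drop = FALSE]), numeric(nrow(t)))
  detected <- if (detection == "mean_gt_zero") grp_mean > 0 else grp_mean >= k
  seed_otus <- otu_ids(t)[rowSums(unclass(t)[, ids, drop = FALSE]) > 0]
  status <- ifelse(rowSums(detected) == 3, "transmitted", "transient")
  names(status) <- otu_ids(t)
  status <- status[seed_otus]
  rownames(detected) <- otu_ids(t)

  # per-seed-timepoint share of each status
  se_meta <- meta[meta$compartment == "Se", , drop = FALSE]
  ra <- unclass(transform_abundance(t, "relative_abundance"))
  ages <- sort(unique(se_meta$age_days))
  summary <- do.call(rbind, lapply(ages, function(a) {
    s <- se_meta$sample_id[se_meta$age_days == a]
    tm <- names(status)[status == "transmitted"]
    tr <- names(status)[status == "transient"]
    data.frame(age_days = a,
               n_transmitted = length(tm), n_transient = length(tr),
               ra_transmitted = mean(colSums(ra[tm, s, drop = FALSE])),
               ra_transient = mean(colSums(ra[tr, s, drop = FALSE])))
  }))
  structure(list(status = status,
                 presence = detected[seed_otus, , drop = FALSE],
                 summary = summary),
            class = "transmission_result")
}

#' @export
print.transmission_result <- function(x, ...) {
  cat(sprintf("<transmission_result> %d transmitted / %d transient seed OTUs\n",
              sum(x$status == "transmitted"), sum(x$status == "transient")))
  invisible(x)
}

#' Classify OTU successional modes by abundance-age regression
#'
#' Per OTU, ordinary least squares of relative abundance on host age (days
#' after transplanting) across replicates; an OTU is an early successor when
#' the slope t-statistic is negative with p < alpha, a late successor when it
#' is positive with p < alpha, and mid/no-trend otherwise.  Parent seeds
#' (age 0) are excluded from the regression by default.
#'
#' @param t relative-abundance [normalized_table()], [count_table()] (converted
#'   internally), or a plain OTU x sample numeric matrix of per-OTU abundance
#'   trajectories.
#' @param meta [sample_meta()] (may be omitted when `ages` is given).
#' @param ages optional numeric vector of ages per sample, overriding `meta`.
#' @param compartment compartment to restrict to (default `"Se"`; `NULL` keeps
#'   all samples).  Ignored when `ages` is given.
#' @param alpha significance level of the legend rule (default 0.05).
#' @param include_parent keep age-0 samples in the regression (default FALSE).
#' @return data.frame of class `succession_result`: otu_id, slope, t_stat,
#'   p_value, mode (Early/MidNoTrend/Late), degenerate flag.
#' @export
classify_succession <- function(t, meta = NULL, ages = NULL,
                                compartment = "Se", alpha = 0.05,
                                include_parent = FALSE) {
  m <- unclass(as.matrix(t))
  if (inherits(t, "count_table"))
    m <- unclass(transform_abundance(t, "relative_abundance"))
  if (is.null(ages)) {
    if (is.null(meta)) stop("provide meta or ages")
    meta <- check_meta_matches(m, meta)
    keep <- if (is.null(compartment)) rep(TRUE, nrow(meta))
            else meta$compartment == compartment
    if (!include_parent) keep <- keep & meta$age_days > 0
    m <- m[, keep, drop = FALSE]
    ages <- meta$age_days[keep]
  } else {
    if (length(ages) != ncol(m)) stop("ages must match the samples")
    if (!include_parent) { m <- m[, ages > 0, drop = FALSE]; ages <- ages[ages > 0] }
  }
  if (length(unique(ages)) < 3) stop("need at least three distinct timepoints")
  xc <- ages - mean(ages)
  sxx <- sum(xc^2)
  n <- length(ages)
  res <- t(apply(m, 1, function(y) {
    if (all(y == 0) || sd(y) == 0) return(c(0, NA, 1, 1))
    b <- sum(xc * y) / sxx
    yhat <- mean(y) + b * xc
    sse <- sum((y - yhat)^2)
    se <- sqrt(sse / (n - 2) / sxx)
    if (se == 0) return(c(b, sign(b) * Inf, if (b == 0) 1 else 0, 0))
    tt <- b / se
    c(b, tt, 2 * stats::pt(-abs(tt), n - 2), 0)
  }))
  out <- data.frame(otu_id = rownames(m), slope = res[, 1], t_stat = res[, 2],
                    p_value = res[, 3], degenerate = res[, 4] == 1,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$mode <- ifelse(out$p_value < alpha & !is.na(out$t_stat) & out$t_stat < 0,
                     "Early",
              ifelse(out$p_value < alpha & !is.na(out$t_stat) & out$t_stat > 0,
                     "Late", "MidNoTrend"))
  class(out) <- c("succession_result", "data.frame")
  out
}

#' Parent-progeny convergence trajectory
#'
#' All pairwise dissimilarities between parent-seed samples (age 0 by
#' default) and progeny seed samples at each age, optionally restricted to a
#' fixed OTU set (e.g. the transmitted OTUs) with renormalization, plus a
#' Kruskal-Wallis/Dunn comparison of the per-age distance distributions.
#'
#' @param t [count_table()].
#' @param meta [sample_meta()].
#' @param parent_ids sample ids of the parent group; default: `Se` samples at
#'   age 0.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @param restrict_to optional character vector of OTU ids.
#' @return list of class `convergence_trajectory`: `distances` (data.frame
#'   age_days, parent_id, progeny_id, distance), `per_age` (median/mean per
#'   age), `test` ([kruskal_dunn()] output across ages).
#' @export
convergence_trajectory <- function(t, meta, parent_ids = NULL,
                                   metric = c("bray_curtis", "jaccard"),
                                   restrict_to = NULL) {
  metric <- match.arg(metric)
  meta <- check_meta_matches(t, meta)
  if (is.null(parent_ids))
    parent_ids <- meta$sample_id[meta$compartment == "Se" & meta$age_days == 0]
  if (!length(parent_ids)) stop("empty parent group")
  prog <- meta[meta$compartment == "Se" & meta$age_days > 0 &
                 !(meta$sample_id %in% parent_ids), , drop = FALSE]
  m <- unclass(as.matrix(t))
  if (!is.null(restrict_to)) {
    miss <- setdiff(restrict_to, rownames(m))
    if (length(miss)) stop("restrict_to OTUs not in table")
    m <- m[restrict_to, , drop = FALSE]
  }
  ages <- sort(unique(prog$age_days))
  keep_age <- vapply(ages, function(a) sum(prog$age_days == a) >= 2, logical(1))
  if (any(!keep_age))
    warning("progeny age(s) with < 2 samples excluded: ",
            paste(ages[!keep_age], collapse = ", "))
  ages <- ages[keep_age]
  use <- c(parent_ids, prog$sample_id[prog$age_days %in% ages])
  sub <- m[, use, drop = FALSE]
  nonzero <- colSums(sub) > 0
  ra <- sweep(sub[, nonzero, drop = FALSE], 2,
              colSums(sub[, nonzero, drop = FALSE]), "/")
  rownames(ra) <- rownames(sub)
  dm <- dissimilarity(normalized_table(ra, "relative_abundance"), metric)
  rows <- list()
  for (a in ages) {
    pr <- intersect(prog$sample_id[prog$age_days == a], colnames(dm))
    pa <- intersect(parent_ids, colnames(dm))
    rows[[as.character(a)]] <- expand.grid(parent_id = pa, progeny_id = pr,
                                           stringsAsFactors = FALSE)
    rows[[as.character(a)]]$age_days <- a
    rows[[as.character(a)]]$distance <-
      dm[cbind(rows[[as.character(a)]]$parent_id,
               rows[[as.character(a)]]$progeny_id)]
  }
  distances <- do.call(rbind, rows)
  rownames(distances) <- NULL
  per_age <- do.call(rbind, lapply(ages, function(a) {
    d <- distances$distance[distances$age_days == a]
    data.frame(age_days = a, n = length(d), median = median(d), mean = mean(d))
  }))
  test <- kruskal_dunn(distances$distance, distances$age_days)
  structure(list(distances = distances, per_age = per_age, test = test,
                 metric = metric),
            class = "convergence_trajectory")
}

#' Core OTUs by prevalence per compartment
#'
#' @param t [count_table()].
#' @param meta [sample_meta()].
#' @param prevalence minimum fraction of a compartment's samples in which an
#'   OTU must be detected (count > 0); inclusive (default 0.8, the figure
#'   preset; 0.9 is the across-site preset).
#' @param compartments compartments to evaluate (default all present).
#' @return list of class `core_set`: `cores` (compartment -> OTU id vector)
#'   and `prevalence`.
#' @export
core_otus <- function(t, meta, prevalence = 0.8, compartments = NULL) {
  if (prevalence <= 0 || prevalence > 1) stop("prevalence must be in (0, 1]")
  meta <- check_meta_matches(t, meta)
  if (is.null(compartments)) compartments <- unique(meta$compartment)
  m <- unclass(t) > 0
  cores <- list()
  for (cp in compartments) {
    s <- meta$sample_id[meta$compartment == cp]
    if (!length(s)) { warning("no samples for compartment ", cp); next }
    prev <- rowMeans(m[, s, drop = FALSE])
    cores[[cp]] <- otu_ids(t)[prev >= prevalence]
  }
  structure(list(cores = cores, prevalence = prevalence), class = "core_set")
}

#' Venn region counts for transmitted and core OTU sets
#'
#' Counts every exclusive intersection region of the given OTU sets
#' (transmitted OTUs plus per-compartment cores).
#'
#' @param sets named list of character vectors (e.g. `list(transmitted = ...,
#'   Se = ..., S = ..., L = ...)`).
#' @return data.frame with one row per non-empty region membership pattern:
#'   the member flags, `region` label, and exclusive `count`.
#' @export
overlap_summary <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  k <- length(sets)
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, names(sets)))
  pat <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(pat) <- names(sets)
  pat$region <- apply(pat, 1, function(r)
    paste(names(sets)[as.logical(r)], collapse = "&"))
  pat$count <- apply(pat[, seq_len(k), drop = FALSE], 1, function(r)
    sum(apply(memb, 1, function(x) all(x == as.logical(r)))))
  rownames(pat) <- NULL
  pat
}
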