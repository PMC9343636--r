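#' Expectation-maximization source tracking for one sink community
#'
#' Models the sink's taxon distribution as a mixture of the K known source
#' distributions plus one unknown source.  Source taxon distributions are
#' initialized at the empirical source frequencies (with a small pseudocount)
#' and, in the default joint mode, updated together with the mixing
#' proportions by EM on the complete model (source counts are data too), so
#' the full log-likelihood is non-decreasing at every iteration.  The unknown
#' source's distribution is always estimated.  The best of several restarts
#' (jittered initial proportions) by final likelihood is returned.
#'
#' @param sink non-negative integer count vector over OTUs.
#' @param sources K x OTUs count matrix (rownames = source names).
#' @param tol EM stops when the largest change in any mixing proportion falls
#'   below this (default 1e-6).
#' @param max_iter maximum EM iterations (default 1000).  `strict_replication
#'   = TRUE` overrides this to a single iteration, reproducing the
#'   hyperparameter setting reported for the original analysis.
#' @param n_restarts number of restarts with jittered initial alpha
#'   (default 5).
#' @param seed RNG seed for restarts.
#' @param update_gamma update known-source distributions jointly
#'   (FEAST-like, default) or keep them fixed (SourceTracker-like).
#' @param strict_replication run exactly one EM iteration.
#' @return list of class `source_contribution`: `alpha` (named vector over
#'   sources + `"Unknown"`, sums to 1), `log_likelihood` trace of the chosen
#'   restart, `n_iter`, `converged`.
#' @export
fit_source_mixture <- function(sink, sources, tol = 1e-6, max_iter = 1000,
                               n_restarts = 5, seed = 1L,
                               update_gamma = TRUE,
                               strict_replication = FALSE) {
  sources <- as.matrix(sources)
  if (is.null(rownames(sources)))
    rownames(sources) <- paste0("source", seq_len(nrow(sources)))
  if (nrow(sources) < 1) stop("need at least one source")
  if (length(sink) != ncol(sources))
    stop("sink and sources must share the OTU axis")
  y <- as.numeric(sink)
  if (sum(y) == 0) stop("sink has zero depth")
  if (strict_replication) max_iter <- 1L
  K <- nrow(sources)
  J <- K + 1L                      # + unknown
  nms <- c(rownames(sources), "Unknown")
  pc <- 1e-8
  gamma0 <- sweep(sources + pc, 1, rowSums(sources + pc), "/")
  # unknown initialized on the sink mass over OTUs absent from every known
  # source (the unobserved-taxon reading of "unknown"); if the sink has no
  # such mass, fall back to the residual above the source mean
  # the unknown source lives on the OTUs no known source carries (the
  # unobserved-taxon reading); letting it relocate onto source-supported
  # OTUs would make the mixture unidentifiable (any source could be
  # duplicated into the unknown).  When every OTU is source-supported the
  # restriction is vacuous and the unknown is free.
  free <- colSums(sources) == 0
  if (!any(free)) free <- rep(TRUE, length(y))
  resid0 <- ifelse(free, y + pc, 0)
  gamma0 <- rbind(gamma0, Unknown = resid0 / sum(resid0))

  loglik <- function(alpha, gamma) {
    mix <- drop(crossprod(gamma, alpha))
    ll <- sum(y * log(pmax(mix, 1e-300)))
    if (update_gamma)
      ll <- ll + sum(sources * log(pmax(gamma[seq_len(K), , drop = FALSE],
                                        1e-300)))
    ll
  }

  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # known sources start with most of the weight; the unknown must earn
    # its share from sink mass the sources cannot explain
    alpha <- c(rep(0.9 / K, K), 0.1)
    if (r > 1) {                  # Dirichlet jitter around the base init
      g <- rgamma(J, shape = 4, rate = 1)
      alpha <- 0.5 * alpha + 0.5 * g / sum(g)
    }
    gamma <- gamma0
    trace <- loglik(alpha, gamma)
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      # E-step: responsibilities of each source for each OTU's sink reads
      num <- gamma * alpha                  # J x OTU
      den <- pmax(colSums(num), 1e-300)
      resp <- sweep(num, 2, den, "/")
      w <- sweep(resp, 2, y, "*")           # expected reads per source x OTU
      alpha_new <- rowSums(w) / sum(y)
      if (update_gamma) {
        gnew <- w
        gnew[seq_len(K), ] <- gnew[seq_len(K), , drop = FALSE] + sources
        gnew["Unknown", !free] <- 0
        zero <- rowSums(gnew) == 0
        if (any(zero)) {              # keep a degenerate row proper
          gnew[zero, ] <- 1
          gnew["Unknown", !free] <- 0
        }
        gamma <- sweep(gnew, 1, rowSums(gnew), "/")
      } else {
        wU <- w["Unknown", ] * free
        rsU <- sum(wU)
        if (rsU > 0) gamma["Unknown", ] <- wU / rsU
      }
      delta <- max(abs(alpha_new - alpha))
      alpha <- alpha_new
      trace <- c(trace, loglik(alpha, gamma))
      if (delta < tol) { converged <- TRUE; break }
    }
    if (is.null(best) || trace[length(trace)] > best$ll) {
      best <- list(alpha = setNames(alpha, nms), trace = trace,
                   n_iter = it, converged = converged,
                   ll = trace[length(trace)])
    }
  }
  structure(list(alpha = best$alpha, log_likelihood = best$trace,
                 n_iter = best$n_iter, converged = best$converged),
            class = "source_contribution")
}

#' @export
print.source_contribution <- function(x, ...) {
  cat("<source_contribution>\n")
  print(round(x$alpha, 4))
  invisible(x)
}

#' Track sources of harvest-stage seed communities over time
#'
#' Treats each harvest-stage seed biological replicate (technical replicates
#' summed) as a sink, and every earlier (compartment, age) group - including
#' parent seeds - as one candidate source (samples summed).  Harvest-stage
#' non-seed samples are excluded as sources.  Contributions are aggregated by
#' source compartment and by compartment x age, with mean and sd across the
#' sink replicates.
#'
#' @param t [count_table()].
#' @param meta [sample_meta()].
#' @param sink_age age (days) of the sink seeds; default: the maximum seed
#'   age present.
#' @param sink_year restrict sinks to this year (default: max year).
#' @param ... passed to [fit_source_mixture()].
#' @return list of class `source_tracking`: `per_sink` (long data.frame
#'   sink_id, source_compartment, source_age, alpha), `by_compartment` and
#'   `by_compartment_age` aggregations (mean, sd across sinks), `fits`.
#' @export
track_by_timepoint <- function(t, meta, sink_age = NULL, sink_year = NULL,
                               ...) {
  meta <- check_meta_matches(t, meta)
  se <- meta[meta$compartment == "Se", , drop = FALSE]
  if (is.null(sink_year)) sink_year <- max(meta$year)
  if (is.null(sink_age)) sink_age <- max(se$age_days[se$year == sink_year])
  sinks_meta <- se[se$age_days == sink_age & se$year == sink_year, ,
                   drop = FALSE]
  if (!nrow(sinks_meta)) stop("no sink samples at the harvest age")
  m <- unclass(as.matrix(t))
  # sources: all groups strictly before the sink timepoint (same year), plus
  # parent seeds (age 0); harvest-age non-seed groups are excluded
  src_meta <- meta[meta$age_days < sink_age & meta$year == sink_year &
                     !(meta$sample_id %in% sinks_meta$sample_id), ,
                   drop = FALSE]
  if (!nrow(src_meta)) stop("no source samples before the sink timepoint")
  key <- paste(src_meta$compartment, src_meta$age_days, sep = "@")
  groups <- split(src_meta$sample_id, key)
  src <- t(vapply(groups, function(s)
    rowSums(m[, s, drop = FALSE]), numeric(nrow(m))))
  depth0 <- rowSums(src) == 0
  if (any(depth0)) {
    warning("source group(s) with zero depth dropped: ",
            paste(names(groups)[depth0], collapse = ", "))
    src <- src[!depth0, , drop = FALSE]
  }
  sink_groups <- split(sinks_meta$sample_id, sinks_meta$bio_rep)
  fits <- lapply(sink_groups, function(s)
    fit_source_mixture(rowSums(m[, s, drop = FALSE]), src, ...))
  per_sink <- do.call(rbind, lapply(names(fits), function(b) {
    a <- fits[[b]]$alpha
    cp <- sub("@.*", "", names(a)); cp[names(a) == "Unknown"] <- "Unknown"
    ag <- suppressWarnings(as.integer(sub(".*@", "", names(a))))
    data.frame(sink_id = paste0("bio", b), source_compartment = cp,
               source_age = ag, alpha = unname(a), stringsAsFactors = FALSE)
  }))
  agg <- function(keys) {
    key_str <- do.call(paste, c(lapply(per_sink[keys], addNA), sep = "\r"))
    sp <- split(per_sink, key_str, drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(df) {
      tot <- tapply(df$alpha, df$sink_id, sum)
      cbind(df[1, keys, drop = FALSE],
            data.frame(alpha_mean = mean(tot), alpha_sd = sd(tot)))
    }))
    rownames(out) <- NULL
    out
  }
  structure(list(per_sink = per_sink,
                 by_compartment = agg("source_compartment"),
                 by_compartment_age = agg(c("source_compartment",
                                            "source_age")),
                 fits = fits),
            class = "source_tracking")
}
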