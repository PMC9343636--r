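#' Drop OTUs below an overall mean relative abundance
#'
#' @param t [count_table()].
#' @param threshold OTUs whose across-sample mean relative abundance is
#'   strictly below this are removed (default 1e-4); an OTU sitting exactly at
#'   the threshold is retained.
#' @return filtered [count_table()].
#' @export
filter_low_abundance <- function(t, threshold = 1e-4) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  ra <- unclass(transform_abundance(t, "relative_abundance"))
  keep <- rowMeans(ra) >= threshold
  if (!any(keep)) stop("all OTUs fall below the abundance threshold")
  count_table(unclass(t)[keep, , drop = FALSE])
}

#' Classify a niche-responsiveness estimate
#'
#' The legend rule: High when h2 > 0.4, Moderate when 0.2 < h2 <= 0.4, Low
#' when h2 <= 0.2.
#'
#' @param h2 numeric vector of estimates in `[0, 1]`.
#' @return character vector of High/Moderate/Low.
#' @export
classify_h2 <- function(h2) {
  ifelse(h2 > 0.4, "High", ifelse(h2 > 0.2, "Moderate", "Low"))
}

# Mixed-model variance components of y ~ age (fixed) + (1 | replicate):
# raw variance of the fitted fixed effects, replicate variance, residual
# variance.  Falls back to the fixed-effects-only fit (replicate variance 0)
# when the mixed fit fails.
h2_fit_parts <- function(y, age_f, rep_f) {
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(y ~ age_f + (1 | rep_f), REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore",
                                             check.conv.grad = "ignore",
                                             check.conv.hess = "ignore")))),
    error = function(e) NULL)
  if (is.null(fit)) {
    lf <- lm(y ~ age_f)
    return(list(vfix_raw = var(fitted(lf)), v_rep = 0,
                v_res = sum(resid(lf)^2) / stats::df.residual(lf),
                singular = TRUE))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  xb <- drop(lme4::getME(fit, "X") %*% lme4::fixef(fit))
  list(vfix_raw = var(xb), v_rep = vc$vcov[vc$grp == "rep_f"],
       v_res = vc$vcov[vc$grp == "Residual"],
       singular = lme4::isSingular(fit))
}

# Point h2: the raw fixed-effect variance carries a noise floor of
# sigma^2 (k - 1) / (n - 1) (k age means estimated from n points), which is
# subtracted so a null OTU sits near 0 instead of near the floor.
h2_point <- function(parts, k, n, floor_factor = 1) {
  vadj <- parts$vfix_raw - parts$v_res * (k - 1) / (n - 1) * floor_factor
  vadj <- max(0, vadj)
  tot <- vadj + parts$v_rep + parts$v_res
  if (tot > 0) vadj / tot else 0
}

#' Niche responsiveness (heritability analog) per OTU
#'
#' Per OTU a linear mixed-effects model is fitted to the CLR-transformed
#' abundances with host age as a categorical fixed effect and biological
#' replicate (plant) as a random intercept.  The niche-responsiveness h2 is
#' the variance of the fixed-effect fitted values over the total (fixed +
#' replicate + residual) variance.  Uncertainty comes from bootstrapping
#' biological replicates with replacement, preserving each plant's full time
#' series; the reported estimate is the bootstrap mean.
#'
#' @param t_clr CLR [normalized_table()] (or any OTU x sample matrix of
#'   transformed abundances).
#' @param meta [sample_meta()].
#' @param compartment restrict to one compartment (default `"Se"`, `NULL`
#'   keeps all).
#' @param n_boot number of bootstrap resamples (default 100; 0 skips the
#'   bootstrap and reports the point estimate).
#' @param seed RNG seed for the bootstrap.
#' @param include_parent keep age-0 samples (default FALSE).
#' @return data.frame of class `niche_responsiveness`: otu_id, h2_mean,
#'   h2_sd, n_boot, class, singular flag.
#' @export
estimate_niche_responsiveness <- function(t_clr, meta, compartment = "Se",
                                          n_boot = 100, seed = 1L,
                                          include_parent = FALSE) {
  m <- unclass(as.matrix(t_clr))
  meta <- check_meta_matches(m, meta)
  keep <- if (is.null(compartment)) rep(TRUE, nrow(meta))
          else meta$compartment == compartment
  if (!include_parent) keep <- keep & meta$age_days > 0
  m <- m[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  if (length(unique(meta$age_days)) < 3) stop("need at least three ages")
  if (any(tapply(meta$bio_rep, meta$age_days,
                 function(x) length(unique(x))) < 2))
    stop("need at least two biological replicates per age")
  age_f <- factor(meta$age_days)
  rep_id <- as.character(meta$bio_rep)
  reps <- unique(rep_id)
  set.seed(seed)
  draw_plants <- function() {
    # cluster bootstrap; a draw must contain >= 2 distinct plants, else the
    # residual and replicate variances degenerate to zero
    for (i in 1:100) {
      d <- sample(reps, length(reps), replace = TRUE)
      if (length(unique(d)) >= 2) return(d)
    }
    reps
  }
  boot_draws <- if (n_boot > 0)
    replicate(n_boot, draw_plants(), simplify = FALSE) else list()
  k <- length(unique(age_f))
  n <- length(rep_id)
  r <- length(reps)
  res <- lapply(rownames(m), function(o) {
    y <- m[o, ]
    if (sd(y) == 0)
      return(data.frame(otu_id = o, h2_mean = 0, h2_sd = if (n_boot) 0 else
        NA_real_, n_boot = as.integer(n_boot), singular = FALSE))
    point <- h2_fit_parts(y, age_f, rep_id)
    if (n_boot == 0)
      return(data.frame(otu_id = o, h2_mean = h2_point(point, k, n),
                        h2_sd = NA_real_, n_boot = 0L,
                        singular = point$singular))
    # cluster bootstrap over plants; each draw's fixed-effect variance is
    # debiased with a multiplicity-scaled noise floor (a plant drawn c times
    # multiplies the age-mean noise by sum(c^2)/r), and the residual and
    # replicate variances of the full-data fit anchor the denominator so
    # duplicate-induced variance collapse cannot inflate the ratio; draws
    # are signed and only the final mean is clamped to [0, 1]
    h2b <- vapply(boot_draws, function(draw) {
      idx <- unlist(lapply(seq_along(draw),
                           function(b) which(rep_id == draw[b])))
      lab <- rep(seq_along(draw),
                 vapply(draw, function(x) sum(rep_id == x), integer(1)))
      bp <- h2_fit_parts(y[idx], droplevels(age_f[idx]), as.character(lab))
      floor_fac <- sum(table(draw)^2) / r
      vadj <- bp$vfix_raw - point$v_res * (k - 1) / (n - 1) * floor_fac
      vadj / (max(vadj, 0) + point$v_rep + point$v_res)
    }, numeric(1))
    data.frame(otu_id = o, h2_mean = min(1, max(0, mean(h2b))),
               h2_sd = sd(h2b), n_boot = n_boot,
               singular = point$singular)
  })
  out <- do.call(rbind, res)
  out$class <- classify_h2(out$h2_mean)
  rownames(out) <- NULL
  class(out) <- c("niche_responsiveness", "data.frame")
  out
}

# Sloan neutral expectation: probability that an OTU with metacommunity
# relative abundance p is detected in a local community of size N with
# migration rate m.  "exact": P(at least one read) under the beta-binomial
# compound, 1 - B(a, b + N) / B(a, b).  "threshold": the classical continuum
# approximation P(x > d) = 1 - IncompleteBetaCDF(d; a, b) with d = 1/N.
neutral_freq_pred <- function(p, m, N, d = 1 / N,
                              detection_model = c("exact", "threshold")) {
  detection_model <- match.arg(detection_model)
  a <- N * m * p
  b <- N * m * (1 - p)
  f <- if (detection_model == "exact") {
    1 - exp(lbeta(a, b + round(N)) - lbeta(a, b))
  } else {
    1 - pbeta(d, a, b)
  }
  ifelse(p <= 0, 0, ifelse(p >= 1, 1, f))
}

wilson_interval <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  list(lo = pmax(0, ctr - hw), hi = pmin(1, ctr + hw))
}

#' Fit Sloan's neutral community model
#'
#' Relates each OTU's occurrence frequency across local communities to its
#' mean relative abundance in the metacommunity.  The community size N is the
#' mean read depth of the local communities, the detection limit d = 1/N, and
#' the migration rate m is estimated by bounded least squares of observed
#' against predicted occurrence frequencies.  Per-OTU 95% confidence bounds
#' on the prediction use the Wilson score interval with n = number of local
#' communities; OTUs above/below the band are flagged as deviating from
#' neutrality.  Speciation and diversification are excluded from the model.
#'
#' @param t [count_table()].
#' @param local_communities character vector of sample ids forming the local
#'   communities (default: all samples).
#' @param m_bounds search interval for m (default `c(1e-6, 1)`).
#' @param conf confidence level of the prediction band (default 0.95).
#' @param detection_model `"exact"` (default): detection probability of at
#'   least one read under the beta-binomial compound at depth N;
#'   `"threshold"`: the classical continuum approximation, the incomplete
#'   beta CDF at the detection limit d.  The exact form removes the upward
#'   bias of the threshold approximation when local communities are
#'   themselves read-sampled.
#' @return list of class `neutral_fit`: `m`, `N`, `d`, `R2`, `n_communities`,
#'   `at_bound` flag, and `otus` (data.frame otu_id, p, freq_obs, freq_pred,
#'   ci_lo, ci_hi, partition).
#' @export
fit_neutral_model <- function(t, local_communities = NULL,
                              m_bounds = c(1e-6, 1), conf = 0.95,
                              detection_model = c("exact", "threshold")) {
  detection_model <- match.arg(detection_model)
  m0 <- unclass(as.matrix(t))
  if (is.null(local_communities)) local_communities <- colnames(m0)
  if (!all(local_communities %in% colnames(m0)))
    stop("unknown sample id in local_communities")
  x <- m0[, local_communities, drop = FALSE]
  n_comm <- ncol(x)
  if (n_comm < 10) stop("need at least 10 local communities")
  depth <- colSums(x)
  N <- mean(depth)
  d <- 1 / N
  ra <- sweep(x, 2, depth, "/")
  p <- rowMeans(ra)
  freq_obs <- rowMeans(x > 0)
  keep <- p > 0
  p <- p[keep]; freq_obs <- freq_obs[keep]
  sse_of <- function(m)
    sum((freq_obs - neutral_freq_pred(p, m, N, d, detection_model))^2)
  opt <- optimise(sse_of, m_bounds)
  m_hat <- opt$minimum
  sse_hat <- opt$objective
  at_bound <- FALSE
  for (b in m_bounds) if (sse_of(b) <= sse_hat + 1e-12) {
    m_hat <- b; sse_hat <- sse_of(b); at_bound <- TRUE
  }
  opt$objective <- sse_hat
  freq_pred <- neutral_freq_pred(p, m_hat, N, d, detection_model)
  sst <- sum((freq_obs - mean(freq_obs))^2)
  r2 <- 1 - opt$objective / sst
  ci <- wilson_interval(freq_pred, n_comm, conf)
  partition <- ifelse(freq_obs > ci$hi, "above",
                      ifelse(freq_obs < ci$lo, "below", "neutral"))
  otus <- data.frame(otu_id = names(p), p = p, freq_obs = freq_obs,
                     freq_pred = freq_pred, ci_lo = ci$lo, ci_hi = ci$hi,
                     partition = partition, row.names = NULL,
                     stringsAsFactors = FALSE)
  structure(list(m = m_hat, N = N, d = d, R2 = r2, n_communities = n_comm,
                 at_bound = at_bound, otus = otus),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf("<neutral_fit> m = %.4f, N = %.0f, R2 = %.3f, %d OTUs over %d local communities\n",
              x$m, x$N, x$R2, nrow(x$otus), x$n_communities))
  invisible(x)
}

#' Partition OTUs by deviation from the neutral prediction
#'
#' Summarizes the above/neutral/below partition of a [fit_neutral_model()]
#' result and, when a [estimate_niche_responsiveness()] result is supplied,
#' flags the OTUs jointly predicted to be under niche control (class High and
#' outside the neutral band).
#'
#' @param fit [fit_neutral_model()] result.
#' @param niche optional [estimate_niche_responsiveness()] result.
#' @return list of class `neutral_partition`: `otus` (per-OTU partition, and
#'   h2 class plus `niche_consensus` flag when `niche` given), `summary`
#'   (counts per partition).
#' @export
partition_neutral <- function(fit, niche = NULL) {
  stopifnot(inherits(fit, "neutral_fit"))
  otus <- fit$otus
  if (!is.null(niche)) {
    idx <- match(otus$otu_id, niche$otu_id)
    otus$h2_class <- niche$class[idx]
    otus$niche_consensus <- !is.na(otus$h2_class) & otus$h2_class == "High" &
      otus$partition != "neutral"
  }
  counts <- table(factor(otus$partition,
                         levels = c("above", "neutral", "below")))
  structure(list(otus = otus, summary = as.data.frame(counts,
                                                      responseName = "n")),
            class = "neutral_partition")
}
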