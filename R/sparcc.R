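# Basis-variance solve for one variation matrix.  Row a of the linear
# system: (D-1) w_a + sum_{b != a} w_b = sum_b T_ab, with excluded pairs
# removed from both sides.  For D = 3 without exclusions this reproduces the
# closed form w_a = (T_ab + T_ac - T_bc) / 2.
sparcc_basis <- function(T_mat, excluded = NULL) {
  D <- nrow(T_mat)
  keep <- matrix(TRUE, D, D)
  diag(keep) <- FALSE
  if (!is.null(excluded)) keep[excluded] <- keep[t(excluded)] <- FALSE
  M <- matrix(0, D, D)
  M[keep] <- 1
  diag(M) <- rowSums(keep)
  t_vec <- rowSums(T_mat * keep)
  w <- drop(solve(M, t_vec))
  bad <- w <= 0
  if (any(bad)) {
    tp <- T_mat[T_mat > 0]
    w[bad] <- if (length(tp)) min(tp) else 1e-6
  }
  rho <- (outer(w, w, "+") - T_mat) / (2 * sqrt(outer(w, w)))
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  list(omega = w, rho = rho, clamped = any(bad))
}

variation_matrix <- function(frac) {
  L <- log(frac)                       # D x S
  C <- cov(t(L))
  v <- diag(C)
  outer(v, v, "+") - 2 * C
}

sparcc_one <- function(frac, n_exclusion_iter, exclusion_thresh) {
  D <- nrow(frac)
  T_mat <- variation_matrix(frac)
  excluded <- matrix(integer(0), ncol = 2)
  fit <- sparcc_basis(T_mat)
  if (D > 3) {
    for (i in seq_len(n_exclusion_iter)) {
      r <- abs(fit$rho)
      diag(r) <- 0
      if (nrow(excluded)) r[excluded] <- r[excluded[, 2:1, drop = FALSE]] <- 0
      mx <- which(r == max(r), arr.ind = TRUE)[1, , drop = FALSE]
      if (r[mx] <= exclusion_thresh) break
      excluded <- rbind(excluded, mx)
      fit <- sparcc_basis(T_mat, excluded)
    }
  }
  fit$rho
}

#' SparCC compositional correlation inference
#'
#' Estimates basis (absolute-abundance) correlations from compositional count
#' data.  Per resample, component fractions are drawn from a per-sample
#' Dirichlet posterior (counts + 1), the log-ratio variation matrix is formed,
#' basis variances are solved from its linear system, and strongly correlated
#' pairs are iteratively excluded from the system; the final correlation of a
#' pair is the median over resamples.  With `n_resample = 0` the empirical
#' fractions `(counts + 1) / sum` are used once, deterministically.
#'
#' @param t [count_table()] (>= 4 taxa recommended; D = 3 is solved exactly
#'   and skips the exclusion loop).
#' @param n_resample Dirichlet resamples (default 20).
#' @param n_exclusion_iter maximum strongly-correlated pairs to exclude
#'   (default 10).
#' @param exclusion_thresh exclusion threshold on `|rho|` (default 0.1).
#' @param seed RNG seed for the Dirichlet draws.
#' @return correlation matrix (taxa x taxa), values clipped to `[-1, 1]`.
#' @export
sparcc <- function(t, n_resample = 20, n_exclusion_iter = 10,
                   exclusion_thresh = 0.1, seed = 1L) {
  m <- unclass(as.matrix(t))
  D <- nrow(m)
  if (D < 3) stop("need at least 3 taxa")
  if (n_resample == 0) {
    frac <- sweep(m + 1, 2, colSums(m + 1), "/")
    rho <- sparcc_one(frac, n_exclusion_iter, exclusion_thresh)
  } else {
    set.seed(seed)
    rhos <- vapply(seq_len(n_resample), function(i) {
      g <- matrix(rgamma(length(m), shape = m + 1, rate = 1), nrow = D)
      frac <- sweep(g, 2, colSums(g), "/")
      sparcc_one(frac, n_exclusion_iter, exclusion_thresh)
    }, matrix(0, D, D))
    rho <- apply(rhos, c(1, 2), median)
  }
  dimnames(rho) <- list(rownames(m), rownames(m))
  rho
}

#' Permutation p-values for SparCC correlations
#'
#' Each permutation shuffles every taxon's counts across samples
#' independently (destroying all between-taxon structure while keeping
#' marginals), recomputes the SparCC correlations, and the two-sided
#' pseudo-p-value of a pair is `(1 + #{|rho_perm| >= |rho_obs|}) /
#' (1 + n_perm)`.  Benjamini-Hochberg adjustment is applied across all
#' distinct pairs.
#'
#' @param t [count_table()].
#' @param rho_obs observed correlation matrix from [sparcc()] on `t`.
#' @param n_perm number of permutations (default 100; a warning is issued
#'   below 20).
#' @param seed RNG seed.
#' @param ... passed to [sparcc()] (resample counts etc.).
#' @return list with symmetric matrices `p` and `q`.
#' @export
sparcc_pvalues <- function(t, rho_obs, n_perm = 100, seed = 1L, ...) {
  if (n_perm < 20) warning("fewer than 20 permutations: p-values are coarse")
  m <- unclass(as.matrix(t))
  D <- nrow(m)
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max, n_perm)
  exceed <- matrix(0, D, D)
  for (i in seq_len(n_perm)) {
    mp <- t(apply(m, 1, sample))
    rownames(mp) <- rownames(m); colnames(mp) <- colnames(m)
    rp <- sparcc(count_table(mp, allow_zero_samples = TRUE),
                 seed = perm_seeds[i], ...)
    exceed <- exceed + (abs(rp) >= abs(rho_obs) - 1e-12)
  }
  p <- (1 + exceed) / (1 + n_perm)
  diag(p) <- 1
  ut <- upper.tri(p)
  q <- p
  q[ut] <- p.adjust(p[ut], "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  dimnames(p) <- dimnames(q) <- dimnames(rho_obs)
  list(p = p, q = q)
}
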