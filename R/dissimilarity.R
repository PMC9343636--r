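#' Pairwise community dissimilarity
#'
#' Bray-Curtis on (normalized) abundances, or Jaccard distance on
#' presence/absence sets.  A pair of all-zero samples is assigned distance 0
#' with a warning.
#'
#' @param t [count_table()] or [normalized_table()] (OTUs x samples).
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return [dist_matrix()].
#' @export
dissimilarity <- function(t, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  m <- unclass(as.matrix(t))
  if (ncol(m) < 2) stop("need at least two samples")
  x <- t(m)  # vegan: rows are sites
  d <- suppressWarnings(if (metric == "bray_curtis") {
    vegan::vegdist(x, method = "bray")
  } else {
    vegan::vegdist(x, method = "jaccard", binary = TRUE)
  })
  dm <- as.matrix(d)
  if (anyNA(dm)) {
    warning("all-zero sample pair(s); their distance is defined as 0")
    dm[is.na(dm)] <- 0
  }
  dist_matrix(dm, metric)
}

#' Principal coordinates analysis (PCoA)
#'
#' Gower double-centering of the squared dissimilarities followed by
#' eigendecomposition.  Axes are ordered by eigenvalue; negative eigenvalues
#' are reported, never silently dropped.
#'
#' @param d [dist_matrix()].
#' @param k number of axes to return (default `min(n - 1, 2)`).
#' @return list with `coordinates` (samples x k), `eigenvalues` (all n of
#'   them, decreasing), and `prop_explained` (relative to the sum of positive
#'   eigenvalues).
#' @export
pcoa <- function(d, k = min(nrow(d) - 1L, 2L)) {
  stopifnot(inherits(d, "dist_matrix"))
  n <- nrow(d)
  if (k > n - 1L) stop("k must be at most n - 1")
  # Gower centering done explicitly so all eigenvalues are available
  a <- -0.5 * unclass(d)^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  ev <- e$values
  pos <- pmax(ev[seq_len(k)], 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(pos), k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords, eigenvalues = ev,
       prop_explained = ifelse(ev > 0, ev / sum(ev[ev > 0]), 0))
}

ss_within <- function(d2, idx) {
  # sum over groups of (sum of squared within-group distances) / group size
  s <- 0
  for (g in unique(idx)) {
    i <- which(idx == g)
    if (length(i) > 1) s <- s + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }
  s
}

#' Single-factor PERMANOVA
#'
#' Distance-based pseudo-F for one grouping factor with a permutation test.
#' With `exhaustive = TRUE` (small n) every distinct relabeling is evaluated
#' and the p-value is the exact proportion of permutation statistics at or
#' above the observed one (the identity included).
#'
#' @param d [dist_matrix()].
#' @param grouping factor/character vector aligned with the samples of `d`.
#' @param n_perm number of random permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @return list with `statistic` (pseudo-F), `R2`, `p_value`, `df`, `n_perm`.
#' @export
permanova <- function(d, grouping, n_perm = 9999, seed = 1L,
                      exhaustive = FALSE) {
  stopifnot(inherits(d, "dist_matrix"))
  idx <- as.character(grouping)
  n <- nrow(d)
  if (length(idx) != n) stop("grouping length must match the distance matrix")
  a <- length(unique(idx))
  if (a < 2) stop("need at least two groups")
  d2 <- unclass(d)^2
  sst <- sum(d2[upper.tri(d2)]) / n
  f_of <- function(perm) {
    ssw <- ss_within(d2, idx[perm])
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(seq_len(n))
  ssw_obs <- ss_within(d2, idx)
  r2 <- (sst - ssw_obs) / sst
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration is limited to n <= 8")
    perms <- all_permutations(n)
    f_perm <- vapply(perms, f_of, numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- length(perms)
  } else {
    set.seed(seed)
    f_perm <- vapply(seq_len(n_perm), function(i) f_of(sample.int(n)),
                     numeric(1))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  list(statistic = f_obs, R2 = r2, p_value = p,
       df = c(between = a - 1, within = n - a), n_perm = n_used)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (i in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = i - 1L)
  }
  out
}

#' Kruskal-Wallis test with pairwise Dunn's tests and letter display
#'
#' Rank-based Kruskal-Wallis H with tie correction, followed by all pairwise
#' two-sided Dunn z-tests, Benjamini-Hochberg adjustment across the pairs, and
#' a compact letter display grouping levels that are not significantly
#' different.
#'
#' @param values numeric vector of observations.
#' @param groups grouping vector aligned with `values`.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list with `H`, `df`, `p_value` (global test), `pairs` (data.frame
#'   of group_a, group_b, z, p, q), and `letters` (named character vector).
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  lv <- unique(groups)
  if (length(lv) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two values")
  n <- length(values)
  if (length(unique(values)) == 1L) {
    pairs <- as.data.frame(t(combn(lv, 2)), stringsAsFactors = FALSE)
    names(pairs) <- c("group_a", "group_b")
    pairs$z <- 0; pairs$p <- 1; pairs$q <- 1
    return(list(H = 0, df = length(lv) - 1, p_value = 1, pairs = pairs,
                letters = setNames(rep("a", length(lv)), lv)))
  }
  kw <- kruskal.test(values, factor(groups))
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  cmb <- combn(lv, 2)
  z <- p <- numeric(ncol(cmb))
  for (i in seq_len(ncol(cmb))) {
    a <- cmb[1, i]; b <- cmb[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ng[[a]] + 1 / ng[[b]]))
    z[i] <- (rbar[[a]] - rbar[[b]]) / se
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  q <- p.adjust(p, "BH")
  pairs <- data.frame(group_a = cmb[1, ], group_b = cmb[2, ],
                      z = z, p = p, q = q, stringsAsFactors = FALSE)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, pairs = pairs,
       letters = letter_display(lv[order(-unlist(rbar[lv]))], pairs, alpha))
}

# Greedy compact letter display: groups ordered (by mean rank); each group
# joins every existing letter whose members it does not differ from, else
# starts a new letter.
letter_display <- function(ordered_groups, pairs, alpha = 0.05) {
  differs <- function(a, b) {
    i <- (pairs$group_a == a & pairs$group_b == b) |
         (pairs$group_a == b & pairs$group_b == a)
    any(pairs$q[i] < alpha)
  }
  sets <- list()
  for (g in ordered_groups) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      if (!any(vapply(sets[[k]], function(m) differs(g, m), logical(1)))) {
        sets[[k]] <- c(sets[[k]], g); placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  out <- setNames(rep("", length(ordered_groups)), ordered_groups)
  for (k in seq_along(sets))
    for (g in sets[[k]]) out[g] <- paste0(out[g], letters[k])
  out
}
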