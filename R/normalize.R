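#' Cumulative-sum scaling (CSS) normalization
#'
#' Per sample, the scaling factor is the sum of counts at or below the chosen
#' quantile of that sample's nonzero counts; counts are divided by it,
#' rescaled, and (by default) log2-transformed with a pseudocount of 1.  With
#' `q = 1` the factor reduces to the column total (total-sum scaling).
#'
#' @param t [count_table()].
#' @param q quantile of the nonzero counts defining the cumulative sum
#'   (default 0.5, the nonzero median).  Counts equal to the quantile are
#'   included in the sum.
#' @param scale rescaling constant (default 1000).
#' @param log2_plus1 apply `log2(x + 1)` after scaling (default TRUE).
#' @return [normalized_table()] with method `"CSS_log"`.
#' @export
css_normalize <- function(t, q = 0.5, scale = 1000, log2_plus1 = TRUE) {
  stopifnot(inherits(t, "count_table"), q > 0, q <= 1, scale > 0)
  s <- vapply(seq_len(ncol(t)), function(j) {
    x <- t[, j]
    nz <- x[x > 0]
    if (!length(nz)) stop("sample has no nonzero counts: ", colnames(t)[j])
    thr <- unname(quantile(nz, q))
    sum(x[x <= thr])
  }, numeric(1))
  if (any(s == 0))
    stop("zero CSS scaling factor for sample: ",
         paste(colnames(t)[s == 0], collapse = ", "))
  v <- sweep(unclass(t), 2, s, "/") * scale
  if (log2_plus1) v <- log2(v + 1)
  normalized_table(v, "CSS_log")
}

#' Relative-abundance or centered log-ratio transform
#'
#' @param t [count_table()].
#' @param method `"relative_abundance"` (columns divided by their totals) or
#'   `"CLR"` (`log((x + pc) / g)` with `g` the per-sample geometric mean of
#'   `x + pc`).
#' @param pseudocount added before the CLR log (default 0.5); must be > 0.
#' @return [normalized_table()].
#' @export
transform_abundance <- function(t, method = c("relative_abundance", "CLR"),
                                pseudocount = 0.5) {
  method <- match.arg(method)
  m <- unclass(as.matrix(t))
  if (method == "relative_abundance") {
    cs <- colSums(m)
    if (any(cs == 0)) stop("empty sample column")
    normalized_table(sweep(m, 2, cs, "/"), "relative_abundance")
  } else {
    if (pseudocount <= 0) stop("CLR requires a positive pseudocount")
    lx <- log(m + pseudocount)
    normalized_table(sweep(lx, 2, colMeans(lx), "-"), "CLR")
  }
}

#' Aggregate OTUs to a taxonomic rank with an "other" bin
#'
#' Counts are converted to per-sample relative abundances, summed by the
#' label at `rank` (missing labels binned as `"unclassified"`), and groups
#' whose mean relative abundance falls strictly below `min_mean_ra` are pooled
#' into `"other"`.  A group sitting exactly at the threshold is retained.
#'
#' @param t [count_table()].
#' @param tax [taxonomy_table()] covering all OTUs of `t`.
#' @param rank one of phylum, class, order, family, genus.
#' @param min_mean_ra pooling threshold on the across-sample mean relative
#'   abundance (default 0.005, i.e. 0.5%).
#' @return [normalized_table()] at the rank level; columns sum to 1.
#' @export
aggregate_taxa <- function(t, tax, rank, min_mean_ra = 0.005) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  if (!rank %in% ranks) stop("unknown rank: ", rank)
  tax <- tax[match(otu_ids(t), tax$otu_id), , drop = FALSE]
  if (anyNA(tax$otu_id)) stop("taxonomy missing for some OTUs")
  lab <- as.character(tax[[rank]])
  lab[is.na(lab) | lab == ""] <- "unclassified"
  ra <- unclass(transform_abundance(t, "relative_abundance"))
  agg <- rowsum(ra, lab)
  pool <- rowMeans(agg) < min_mean_ra
  if (any(pool)) {
    other <- colSums(agg[pool, , drop = FALSE])
    agg <- agg[!pool, , drop = FALSE]
    agg <- rbind(agg, other = other)
  }
  normalized_table(agg, "relative_abundance")
}
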