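#' @importFrom stats var cov sd median quantile optimise pbeta pnorm phyper
#'   pbinom rbeta rbinom rmultinom rnorm runif rgamma p.adjust kruskal.test
#'   lm coef cmdscale as.dist dist setNames complete.cases rlnorm resid fitted
#' @importFrom utils read.delim write.table head combn packageVersion
NULL

#' Construct an OTU count table
#'
#' The basic observational unit of a longitudinal amplicon study: a matrix of
#' non-negative integer read counts with OTUs as rows and samples as columns.
#'
#' @param counts numeric matrix (OTUs x samples) of non-negative counts.
#' @param otu_ids,sample_ids optional character vectors; default to the
#'   dimnames of `counts`.
#' @param allow_zero_samples keep all-zero sample columns instead of erroring
#'   (used internally by generators before depth is drawn).
#' @return An object of class `count_table`: the integer-valued matrix with
#'   row/column names set.
#' @export
count_table <- function(counts, otu_ids = rownames(counts),
                        sample_ids = colnames(counts),
                        allow_zero_samples = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(otu_ids) || is.null(sample_ids))
    stop("count_table requires OTU and sample identifiers")
  otu_ids <- as.character(otu_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU id(s): ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and non-missing")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  counts <- round(counts)
  dimnames(counts) <- list(otu_ids, sample_ids)
  if (!allow_zero_samples) {
    empty <- colSums(counts) == 0
    if (any(empty))
      stop("empty sample column: ", paste(sample_ids[empty], collapse = ", "))
  }
  structure(counts, class = c("count_table", "matrix", "array"))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d OTUs x %d samples, total reads %s\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

otu_ids <- function(t) rownames(t)
sample_ids <- function(t) colnames(t)

#' Construct a normalized abundance table
#'
#' @param values real-valued matrix, same axes as the count table it came from.
#' @param method one of `"CSS_log"`, `"relative_abundance"`, `"CLR"`.
#' @param validate check the method-specific column invariants
#'   (relative-abundance columns sum to 1, CLR columns sum to 0).
#' @return matrix of class `normalized_table` with a `method` attribute.
#' @export
normalized_table <- function(values,
                             method = c("CSS_log", "relative_abundance", "CLR"),
                             validate = TRUE) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("normalized_table requires dimnames")
  if (validate) {
    cs <- colSums(values)
    if (method == "relative_abundance" && any(abs(cs - 1) > 1e-9))
      stop("relative-abundance columns must sum to 1")
    if (method == "CLR" && any(abs(cs) > 1e-9))
      stop("CLR columns must sum to 0")
    if (method != "CLR" && any(values < 0))
      stop("negative values in a non-CLR normalized table")
  }
  structure(values, method = method,
            class = c("normalized_table", "matrix", "array"))
}

#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("<normalized_table:%s> %d OTUs x %d samples\n",
              attr(x, "method"), nrow(x), ncol(x)))
  invisible(x)
}

#' Sample metadata for a longitudinal multi-compartment design
#'
#' Validates the per-sample annotation table: compartment (bulk soil,
#' rhizosphere, root, stem sections S1-S9, leaf sections L1-L3, flag leaf,
#' seed), days after transplanting (0 = parent seed at sowing), year, site and
#' biological/technical replicate indices.
#'
#' @param df data.frame with columns `sample_id`, `compartment`, `age_days`,
#'   `year`, `site`, `bio_rep`, `tech_rep`.
#' @return validated data.frame of class `sample_meta`.
#' @export
sample_meta <- function(df) {
  req <- c("sample_id", "compartment", "age_days", "year", "site",
           "bio_rep", "tech_rep")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing metadata column(s): ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  df$sample_id <- as.character(df$sample_id)
  df$compartment <- as.character(df$compartment)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(df$compartment), compartment_levels())
  if (length(bad)) stop("unknown compartment(s): ", paste(bad, collapse = ", "))
  if (any(df$age_days < 0)) stop("age_days must be >= 0")
  key <- do.call(paste, c(df[c("compartment", "age_days", "year", "site",
                               "bio_rep", "tech_rep")], sep = "\r"))
  if (anyDuplicated(key))
    stop("(compartment, age, year, site, bio_rep, tech_rep) must be unique")
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Compartment codes used by the study design
#' @return character vector of valid compartment codes.
#' @export
compartment_levels <- function() {
  c("BS", "RS", "R", paste0("S", 1:9), paste0("L", 1:3), "FL", "Se")
}

#' OTU taxonomy table
#'
#' @param df data.frame with columns `otu_id`, `kingdom` and optionally
#'   `phylum`, `class`, `order`, `family`, `genus` (missing ranks allowed,
#'   kingdom always required and restricted to Bacteria/Fungi).
#' @return data.frame of class `taxonomy_table`.
#' @export
taxonomy_table <- function(df) {
  if (!all(c("otu_id", "kingdom") %in% names(df)))
    stop("taxonomy requires otu_id and kingdom columns")
  df <- as.data.frame(df)
  df$otu_id <- as.character(df$otu_id)
  for (r in c("phylum", "class", "order", "family", "genus"))
    if (is.null(df[[r]])) df[[r]] <- NA_character_
  if (anyDuplicated(df$otu_id)) stop("duplicate otu_id in taxonomy")
  if (anyNA(df$kingdom) || !all(df$kingdom %in% c("Bacteria", "Fungi")))
    stop("kingdom must be present and one of Bacteria, Fungi")
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

check_meta_matches <- function(t, meta) {
  if (!setequal(sample_ids(t), meta$sample_id))
    stop("metadata sample ids do not match the count table")
  meta[match(sample_ids(t), meta$sample_id), , drop = FALSE]
}

#' Construct a sample-by-sample dissimilarity matrix
#'
#' @param m symmetric numeric matrix with zero diagonal, values in `[0, 1]`.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return matrix of class `dist_matrix` with a `metric` attribute.
#' @export
dist_matrix <- function(m, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("dist_matrix requires sample ids as dimnames")
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-9)
    stop("dissimilarity matrix must be symmetric")
  if (max(abs(diag(m))) > 1e-9) stop("dissimilarity diagonal must be zero")
  if (min(m) < -1e-9 || max(m) > 1 + 1e-9)
    stop("dissimilarities must lie in [0, 1]")
  m[m < 0] <- 0; m[m > 1] <- 1
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(m, metric = metric, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix:%s> %d samples\n", attr(x, "metric"), nrow(x)))
  invisible(x)
}
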