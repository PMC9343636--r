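#' Read an OTU count table from TSV
#'
#' Rows are OTUs (first column holds the OTU id), columns are samples.  The
#' BIOM-style TSV dialect with a leading `#OTU ID` header (optionally preceded
#' by a `# Constructed from biom file` comment line) is also accepted.
#'
#' @param path file path.
#' @param format `"tsv"` (plain, first column OTU ids) or `"biom_tsv"`
#'   (header line starts with `#OTU ID`).
#' @return [count_table()] with invariants enforced: unique ids, non-negative
#'   integer counts, no empty sample column.
#' @export
read_count_table <- function(path, format = c("tsv", "biom_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom_tsv") {
    lines <- readLines(path)
    lines <- lines[!grepl("^# ", lines)]       # drop comment, keep "#OTU ID"
    lines[1] <- sub("^#OTU ID", "otu_id", lines[1])
    df <- read.delim(text = paste(lines, collapse = "\n"),
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate OTU id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell(s) in count table")
  rownames(m) <- ids
  count_table(m)
}

#' Read the sample metadata TSV
#' @param path TSV with columns sample_id, compartment, age_days, year, site,
#'   bio_rep, tech_rep.
#' @return [sample_meta()] data.frame.
#' @export
read_sample_meta <- function(path) {
  sample_meta(read.delim(path, stringsAsFactors = FALSE))
}

#' Read the taxonomy TSV
#' @param path TSV with columns otu_id, kingdom, phylum, class, order,
#'   family, genus.
#' @return [taxonomy_table()] data.frame.
#' @export
read_taxonomy_table <- function(path) {
  taxonomy_table(read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", "")))
}

#' Write a square dissimilarity matrix as TSV
#' @param d [dist_matrix()].
#' @param path output path.
#' @export
write_dist_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), as.data.frame(unclass(d)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
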