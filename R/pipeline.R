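pipeline_defaults <- function() {
  list(
    input = list(counts = NULL, meta = NULL, taxonomy = NULL),
    out_dir = "seedtrans_out",
    seed = 1L,
    stages = list(simulate = TRUE, normalize = TRUE, transmission = TRUE,
                  succession = TRUE, niche_neutral = TRUE, sources = TRUE,
                  networks = TRUE, meta_network = TRUE),
    simulate = list(n_otus = 300, n_transmitted = 25, n_transient = 40,
                    depth_mean = 10000),
    css_quantile = 0.5,
    abundance_filter = 1e-4,
    prevalence = 0.8,
    r_threshold = 0.3,
    fdr = 0.05,
    h2_low = 0.2,
    h2_high = 0.4,
    alpha = 0.05,
    n_boot = 100,
    n_perm = 100,
    n_resample = 20,
    network_contexts = list(list(compartment = "Se", age = "all")))
}

#' Assemble and validate a pipeline configuration
#'
#' Every analysis threshold is a named, defaulted parameter (CSS quantile,
#' 1e-4 abundance filter, core prevalence, correlation threshold 0.3, FDR
#' 0.05, h2 cut-offs 0.2/0.4, alpha 0.05).  Unknown keys are rejected and
#' thresholds are checked against their documented ranges.
#'
#' @param ... overrides of the defaults (see [run_pipeline()]); may also be a
#'   single named list.
#' @param yaml_file optional YAML file of overrides, applied before `...`.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., yaml_file = NULL) {
  cfg <- pipeline_defaults()
  apply_over <- function(cfg, over, where = "") {
    for (k in names(over)) {
      if (!k %in% names(cfg))
        stop("unknown config key: ", paste0(where, k))
      if (is.list(cfg[[k]]) && is.list(over[[k]]) && k != "network_contexts")
        cfg[[k]] <- apply_over(cfg[[k]], over[[k]], paste0(k, "."))
      else cfg[[k]] <- over[[k]]
    }
    cfg
  }
  if (!is.null(yaml_file)) cfg <- apply_over(cfg, yaml::read_yaml(yaml_file))
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  cfg <- apply_over(cfg, over)
  chk <- function(v, lo, hi, nm, lo_open = FALSE) {
    if (!is.numeric(v) || v < lo || v > hi || (lo_open && v <= lo))
      stop("config value out of range: ", nm)
  }
  chk(cfg$css_quantile, 0, 1, "css_quantile", lo_open = TRUE)
  chk(cfg$abundance_filter, 0, 1, "abundance_filter")
  chk(cfg$prevalence, 0, 1, "prevalence", lo_open = TRUE)
  chk(cfg$r_threshold, 0, 1, "r_threshold")
  chk(cfg$fdr, 0, 1, "fdr")
  chk(cfg$alpha, 0, 1, "alpha")
  chk(cfg$h2_low, 0, 1, "h2_low")
  chk(cfg$h2_high, cfg$h2_low, 1, "h2_high")
  if (!isTRUE(cfg$stages$simulate) &&
      (is.null(cfg$input$counts) || is.null(cfg$input$meta)))
    stop("without the simulate stage, input counts and meta are required")
  if ((isTRUE(cfg$stages$networks) || isTRUE(cfg$stages$meta_network)) &&
      !isTRUE(cfg$stages$normalize))
    stop("networks require the normalize stage")
  if (isTRUE(cfg$stages$meta_network) && !isTRUE(cfg$stages$networks))
    stop("the meta-network requires the networks stage")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the configured analysis pipeline
#'
#' Executes the enabled stages in dependency order on the configured (or
#' simulated) inputs and writes every table/graph artifact plus a manifest
#' (package version, seeds, parameters, input checksums) to the output
#' directory.  Deterministic: the same config and seed reproduce identical
#' numeric outputs.
#'
#' @param cfg [pipeline_config()].
#' @return list of class `pipeline_result` with the in-memory stage results
#'   and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  artifacts <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    write_tsv(df, p)
    artifacts <<- c(artifacts, p)
  }

  if (isTRUE(cfg$stages$simulate)) {
    study <- generate_full_study(
      design = study_design(depth_mean = cfg$simulate$depth_mean),
      n_otus = cfg$simulate$n_otus,
      n_transmitted = cfg$simulate$n_transmitted,
      n_transient = cfg$simulate$n_transient,
      seed = cfg$seed)
    counts <- study$counts; meta <- study$meta; tax <- study$taxonomy
    jsonlite::write_json(study$truth,
                         file.path(cfg$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, file.path(cfg$out_dir, "truth.json"))
    res$study <- study
  } else {
    counts <- read_count_table(cfg$input$counts)
    meta <- read_sample_meta(cfg$input$meta)
    tax <- if (!is.null(cfg$input$taxonomy))
      read_taxonomy_table(cfg$input$taxonomy) else NULL
  }

  if (isTRUE(cfg$stages$normalize)) {
    res$css <- css_normalize(counts, q = cfg$css_quantile)
    res$ra <- transform_abundance(counts, "relative_abundance")
    res$clr <- transform_abundance(counts, "CLR")
    d <- dissimilarity(res$css, "bray_curtis")
    emit(data.frame(sample_id = rownames(d),
                    as.data.frame(unclass(d)), check.names = FALSE),
         "bray_curtis_css.tsv")
  }

  se_groups <- if (isTRUE(cfg$stages$simulate))
    res$study$truth$generation_groups else NULL

  if (isTRUE(cfg$stages$transmission)) {
    if (is.null(se_groups)) {
      se <- meta[meta$compartment == "Se", ]
      yrs <- sort(unique(se$year))
      se_groups <- list(
        se$sample_id[se$year == yrs[1] & se$age_days ==
                       max(se$age_days[se$year == yrs[1]])],
        se$sample_id[se$year == yrs[length(yrs)] & se$age_days == 0],
        se$sample_id[se$year == yrs[length(yrs)] & se$age_days ==
                       max(se$age_days[se$year == yrs[length(yrs)]])])
    }
    res$transmission <- detect_transmitted(counts, meta, se_groups)
    emit(data.frame(otu_id = names(res$transmission$status),
                    status = res$transmission$status),
         "transmission_status.tsv")
    emit(res$transmission$summary, "transmission_summary.tsv")
    res$cores <- core_otus(counts, meta, prevalence = cfg$prevalence)
  }

  if (isTRUE(cfg$stages$succession)) {
    res$succession <- classify_succession(counts, meta, alpha = cfg$alpha)
    emit(as.data.frame(res$succession), "succession_modes.tsv")
  }

  if (isTRUE(cfg$stages$niche_neutral)) {
    filt <- filter_low_abundance(counts, cfg$abundance_filter)
    clr <- transform_abundance(filt, "CLR")
    se_meta <- meta[meta$compartment == "Se" & meta$age_days > 0 &
                      meta$year == max(meta$year), ]
    res$h2 <- estimate_niche_responsiveness(
      clr[, se_meta$sample_id, drop = FALSE],
      sample_meta(se_meta), n_boot = cfg$n_boot, seed = cfg$seed)
    emit(as.data.frame(res$h2), "niche_responsiveness.tsv")
    res$neutral <- fit_neutral_model(filt,
                                     local_communities = se_meta$sample_id)
    emit(res$neutral$otus, "neutral_fit_otus.tsv")
    jsonlite::write_json(res$neutral[c("m", "N", "d", "R2",
                                       "n_communities")],
                         file.path(cfg$out_dir, "neutral_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, file.path(cfg$out_dir, "neutral_fit.json"))
  }

  if (isTRUE(cfg$stages$sources)) {
    res$sources <- track_by_timepoint(counts, meta, seed = cfg$seed)
    emit(res$sources$by_compartment, "source_by_compartment.tsv")
    emit(res$sources$by_compartment_age, "source_by_compartment_age.tsv")
  }

  if (isTRUE(cfg$stages$networks)) {
    res$networks <- list()
    for (ctx in cfg$network_contexts) {
      sel <- meta$compartment == ctx$compartment
      if (!identical(ctx$age, "all")) sel <- sel & meta$age_days == ctx$age
      sub <- unclass(counts)[, meta$sample_id[sel], drop = FALSE]
      sub <- sub[rowSums(sub) > 0, , drop = FALSE]
      ct <- count_table(sub)
      rho <- sparcc(ct, n_resample = cfg$n_resample, seed = cfg$seed)
      pv <- sparcc_pvalues(ct, rho, n_perm = cfg$n_perm, seed = cfg$seed,
                           n_resample = max(2, cfg$n_resample %/% 4))
      nm <- paste0(ctx$compartment, "@", ctx$age)
      net <- build_network(rho, pv$q, tax, r_threshold = cfg$r_threshold,
                           fdr = cfg$fdr, context = ctx)
      res$networks[[nm]] <- net
      emit(net$edges, paste0("network_", gsub("@", "_", nm), ".tsv"))
    }
  }

  if (isTRUE(cfg$stages$meta_network) && length(res$networks) >= 1) {
    nonempty <- Filter(function(n) nrow(n$edges) > 0, res$networks)
    if (length(nonempty)) {
      res$meta_network <- merge_meta(nonempty)
      emit(res$meta_network$edges, "meta_network_edges.tsv")
      if (length(nonempty) >= 2) {
        res$jaccard <- edge_jaccard(nonempty)
        emit(as.data.frame(res$jaccard$J), "network_jaccard.tsv")
      }
    }
  }

  manifest <- list(package = "seedtrans",
                   version = as.character(packageVersion("seedtrans")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = cfg$seed,
                   parameters = unclass(cfg),
                   artifacts = basename(artifacts),
                   checksums = as.list(tools::md5sum(sort(artifacts))))
  names(manifest$checksums) <- basename(sort(artifacts))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res$manifest <- manifest
  class(res) <- c("pipeline_result", "list")
  invisible(res)
}
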