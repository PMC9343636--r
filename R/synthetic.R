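#' Study design for the synthetic-data generator
#'
#' Mirrors the field design the package analyzes: compartments (bulk soil,
#' rhizosphere, root, stem sections S1-S9, leaf sections L1-L3, flag leaf,
#' seed), seven progeny sampling timepoints (days after transplanting),
#' three biological by three technical replicates, two seed generations
#' (previous-year harvest and current-year parent/progeny seeds), and
#' multinomial read-depth sampling.
#'
#' @param compartments non-seed compartments to simulate.
#' @param ages_days progeny sampling ages.
#' @param seed_ages ages at which progeny seeds are sampled.
#' @param depth_mean mean read depth per sample.
#' @param n_bio_rep,n_tech_rep replicate counts.
#' @param year_parent,year_progeny the two seasons.
#' @param site site code.
#' @return list of class `study_design`.
#' @export
study_design <- function(compartments = c("BS", "RS", "R", paste0("S", 1:9),
                                          paste0("L", 1:3), "FL"),
                         ages_days = c(48, 62, 76, 90, 106, 120, 141),
                         seed_ages = c(76, 90, 106, 120, 141),
                         depth_mean = 10000L,
                         n_bio_rep = 3L, n_tech_rep = 3L,
                         year_parent = 2017L, year_progeny = 2018L,
                         site = "SW") {
  stopifnot(depth_mean > 0, n_bio_rep >= 1, n_tech_rep >= 1,
            all(compartments %in% setdiff(compartment_levels(), "Se")),
            length(ages_days) >= 3, all(seed_ages %in% ages_days))
  structure(list(compartments = compartments, ages_days = ages_days,
                 seed_ages = seed_ages, depth_mean = as.integer(depth_mean),
                 n_bio_rep = as.integer(n_bio_rep),
                 n_tech_rep = as.integer(n_tech_rep),
                 year_parent = as.integer(year_parent),
                 year_progeny = as.integer(year_progeny), site = site),
            class = "study_design")
}

rbeta_safe <- function(n, a, b) {
  # Beta draw tolerating boundary shape parameters (p = 0 or 1)
  out <- numeric(n)
  pos <- a > 0 & b > 0
  out[pos] <- rbeta(sum(pos), a[pos], b[pos])
  out[a <= 0] <- 0
  out[b <= 0 & a > 0] <- 1
  out
}

#' Simulate local communities under the Sloan neutral sampling model
#'
#' Per local community and OTU, the relative abundance is drawn from
#' `Beta(N m p_i, N m (1 - p_i))` around the metacommunity abundance `p_i`,
#' and the observed count from `Binomial(N, .)`.
#'
#' @param n_otus number of OTUs (ignored when `p` is supplied).
#' @param n_communities number of local communities.
#' @param N community size (reads per community).
#' @param m migration rate in (0, 1].
#' @param p metacommunity relative abundances summing to 1; default:
#'   log-uniform over 1e-4..1e-1, normalized.
#' @param seed RNG seed.
#' @return list: `counts` ([count_table()]), `truth` (list with m, N, p).
#' @export
simulate_neutral_local_communities <- function(n_otus, n_communities, N, m,
                                               p = NULL, seed = 1L) {
  if (m <= 0 || m > 1) stop("m must be in (0, 1]")
  set.seed(seed)
  if (is.null(p)) {
    raw <- exp(runif(n_otus, log(1e-4), log(1e-1)))
    p <- raw / sum(raw)
  }
  if (abs(sum(p) - 1) > 1e-8) stop("p must sum to 1")
  n_otus <- length(p)
  counts <- vapply(seq_len(n_communities), function(j) {
    rel <- rbeta_safe(n_otus, N * m * p, N * m * (1 - p))
    rbinom(n_otus, N, rel)
  }, integer(n_otus))
  dimnames(counts) <- list(sprintf("OTU%04d", seq_len(n_otus)),
                           sprintf("LC%03d", seq_len(n_communities)))
  keep_cols <- colSums(counts) > 0
  counts <- counts[, keep_cols, drop = FALSE]
  list(counts = count_table(counts),
       truth = list(m = m, N = N, p = setNames(p, rownames(counts))))
}

#' Inject linear age trends into selected OTUs
#'
#' Replaces the expected relative abundance of the chosen OTUs with a linear
#' trend in sample age (increasing for Late, decreasing for Early) plus
#' Gaussian noise, renormalizes each sample's composition, and resamples
#' counts multinomially at the original depth.
#'
#' @param t [count_table()].
#' @param otus OTU ids to inject.
#' @param mode `"Late"` (abundance rises with age) or `"Early"` (falls).
#' @param slope change in relative abundance per day (default 0.002).
#' @param noise_sd Gaussian noise on the expected relative abundance
#'   (default 5e-4).
#' @param ages numeric vector of sample ages aligned with the columns of `t`.
#' @param baseline starting relative abundance of an injected OTU
#'   (default 5e-4).
#' @param seed RNG seed.
#' @return list: `counts` (new [count_table()]), `truth` (data.frame otu_id,
#'   mode, slope, plus `truncated` flag when noise drove a value below 0).
#' @export
inject_trends <- function(t, otus, mode = c("Late", "Early"), slope = 0.002,
                          noise_sd = 5e-4, ages, baseline = 5e-4, seed = 1L) {
  mode <- match.arg(mode)
  if (!all(otus %in% otu_ids(t))) stop("otus must be in the table")
  if (length(ages) != ncol(t)) stop("ages must match the samples")
  set.seed(seed)
  m <- unclass(t)
  depth <- colSums(m)
  ra <- sweep(m, 2, depth, "/")
  rel_age <- if (mode == "Late") ages - min(ages) else max(ages) - ages
  truncated <- FALSE
  for (o in otus) {
    mu <- baseline + slope * rel_age
    val <- mu + rnorm(length(ages), 0, noise_sd)
    if (any(val < 0)) { truncated <- TRUE; val[val < 0] <- 0 }
    ra[o, ] <- val
  }
  ra <- sweep(ra, 2, colSums(ra), "/")
  counts <- vapply(seq_len(ncol(ra)), function(j)
    drop(rmultinom(1, depth[j], ra[, j])), integer(nrow(ra)))
  dimnames(counts) <- dimnames(m)
  list(counts = count_table(counts),
       truth = list(trend_otus = data.frame(otu_id = otus, mode = mode,
                                            slope = slope,
                                            stringsAsFactors = FALSE),
                    truncated = truncated))
}

#' Simulate a sink community as a known mixture of sources
#'
#' @param source_profiles K x OTUs matrix of source counts or frequencies
#'   (rownames = source names).
#' @param alpha mixing proportions over the K sources plus the unknown
#'   source (last element), summing to 1.
#' @param depth sink read depth.
#' @param unknown_profile optional probability vector for the unknown source;
#'   default: uniform over the OTUs absent from every known source (the
#'   disjoint-unknown scenario).
#' @param seed RNG seed.
#' @return list: `sink` (count vector), `truth` (list alpha, mixture
#'   probabilities).
#' @export
simulate_sources_sink <- function(source_profiles, alpha, depth = 1e5,
                                  unknown_profile = NULL, seed = 1L) {
  source_profiles <- as.matrix(source_profiles)
  K <- nrow(source_profiles)
  if (length(alpha) != K + 1) stop("alpha must cover K sources + unknown")
  if (abs(sum(alpha) - 1) > 1e-8 || any(alpha < 0))
    stop("alpha must be non-negative and sum to 1")
  gam <- sweep(source_profiles, 1, rowSums(source_profiles), "/")
  if (is.null(unknown_profile)) {
    free <- colSums(source_profiles) == 0
    if (!any(free) && alpha[K + 1] > 0)
      stop("no OTUs free of all sources; provide unknown_profile")
    unknown_profile <- as.numeric(free)
    if (any(free)) unknown_profile <- unknown_profile / sum(unknown_profile)
  }
  mix <- drop(crossprod(gam, alpha[seq_len(K)])) +
    alpha[K + 1] * unknown_profile
  set.seed(seed)
  sink <- drop(rmultinom(1, depth, mix))
  names(sink) <- colnames(source_profiles)
  list(sink = sink,
       truth = list(alpha = setNames(alpha, c(rownames(source_profiles),
                                              "Unknown")),
                    mixture = mix, unknown_profile = unknown_profile))
}

#' Simulate compositional counts with known basis correlations
#'
#' Latent absolute abundances are log-normal with the given basis correlation
#' matrix; samples are closed to fractions and counts drawn multinomially.
#'
#' @param n_otus,n_samples dimensions.
#' @param basis_corr positive semidefinite correlation matrix
#'   (default identity).
#' @param lognormal_params list with `mu` and `sd` of the log abundances
#'   (scalars or length-`n_otus` vectors; default mu ~ N(0,1) heterogeneity,
#'   sd = 1).
#' @param depth reads per sample.
#' @param seed RNG seed.
#' @return list: `counts` ([count_table()]), `truth` (basis_corr, fractions).
#' @export
simulate_correlated_counts <- function(n_otus, n_samples,
                                       basis_corr = diag(n_otus),
                                       lognormal_params = NULL,
                                       depth = 2e4, seed = 1L) {
  basis_corr <- as.matrix(basis_corr)
  ev <- eigen(basis_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("basis_corr is not positive semidefinite; ",
         "project it to the nearest PSD matrix first")
  set.seed(seed)
  if (is.null(lognormal_params))
    lognormal_params <- list(mu = rnorm(n_otus, 0, 1), sd = 1)
  mu <- rep_len(lognormal_params$mu, n_otus)
  sdv <- rep_len(lognormal_params$sd, n_otus)
  Sig <- diag(sdv) %*% basis_corr %*% diag(sdv)
  L <- chol(Sig + diag(1e-10, n_otus))
  z <- matrix(rnorm(n_otus * n_samples), n_samples) %*% L
  abs_ab <- exp(sweep(z, 2, mu, "+"))          # samples x OTUs
  frac <- abs_ab / rowSums(abs_ab)
  counts <- apply(frac, 1, function(f) drop(rmultinom(1, depth, f)))
  dimnames(counts) <- list(sprintf("OTU%04d", seq_len(n_otus)),
                           sprintf("S%03d", seq_len(n_samples)))
  list(counts = count_table(counts),
       truth = list(basis_corr = basis_corr, fractions = t(frac)))
}

lognormal_profile <- function(ids, active, mu = 0, sd = 1.5) {
  p <- setNames(numeric(length(ids)), ids)
  p[active] <- rlnorm(length(active), mu, sd)
  if (sum(p) > 0) p / sum(p) else p
}

#' Generate a complete synthetic seed-to-seed study
#'
#' One call produces the full longitudinal dataset with ground truth:
#' compartment-specific communities over seven progeny timepoints with
#' biological and technical replicates; two generations of seed samples
#' (previous-year harvest, sowing-stage parent seeds, developing progeny
#' seeds); a designated transmitted OTU set present in all three seed
#' generations and transient seed OTUs dropped from exactly one generation;
#' age trends (late successors) and age-responsive (niche) effects among
#' transmitted OTUs; and harvest-stage progeny seeds composed as a known
#' mixture of stem, parent-seed and unknown sources.
#'
#' @param design [study_design()].
#' @param n_otus total OTUs (split roughly 60/40 bacteria/fungi).
#' @param n_transmitted,n_transient planted seed-OTU counts.
#' @param source_alpha length-3 mixing of the harvest-seed community:
#'   stem, parent seed, unknown (sums to 1; default 0.4/0.3/0.3).
#' @param m_seed migration rate used for the Sloan-style sampling of progeny
#'   seed communities around their expected profiles.
#' @param seed RNG seed.
#' @return list of class `synthetic_study`: `counts`, `meta`, `taxonomy`,
#'   `truth` (transmitted_otus, transient_otus, generation_groups,
#'   trend_otus, niche_otus, source_alpha, m_seed).
#' @export
generate_full_study <- function(design = study_design(), n_otus = 300,
                                n_transmitted = 25, n_transient = 40,
                                source_alpha = c(stem = 0.4, parent_seed = 0.3,
                                                 unknown = 0.3),
                                m_seed = 0.3, seed = 1L) {
  stopifnot(inherits(design, "study_design"),
            abs(sum(source_alpha) - 1) < 1e-8, length(source_alpha) == 3)
  if (n_transmitted + n_transient > n_otus / 2)
    stop("too many seed OTUs for the requested table size")
  set.seed(seed)
  ids <- sprintf("OTU%04d", seq_len(n_otus))
  n_bac <- round(0.6 * n_otus)
  kingdom <- c(rep("Bacteria", n_bac), rep("Fungi", n_otus - n_bac))
  classes <- c("Alphaproteobacteria", "Gammaproteobacteria", "Anaerolineae",
               "Bacilli", "Actinomycetia", "Dothideomycetes",
               "Sordariomycetes", "Tremellomycetes", "Ustilaginomycetes",
               "Agaricomycetes")
  tax <- taxonomy_table(data.frame(
    otu_id = ids, kingdom = kingdom,
    phylum = ifelse(kingdom == "Bacteria", "Proteobacteria", "Ascomycota"),
    class = ifelse(kingdom == "Bacteria",
                   sample(classes[1:5], n_otus, TRUE),
                   sample(classes[6:10], n_otus, TRUE))[seq_len(n_otus)],
    order = paste0("order", sample(1:12, n_otus, TRUE)),
    family = NA, genus = paste0("genus", sample(1:40, n_otus, TRUE)),
    stringsAsFactors = FALSE))

  # OTU roles: transmitted and transient live in seeds; an unknown-source
  # block is reserved (absent from every compartment profile); the rest are
  # environmental/background OTUs with compartment-specific occupancy.
  transmitted <- ids[seq_len(n_transmitted)]
  transient <- ids[n_transmitted + seq_len(n_transient)]
  n_unknown <- max(10, round(0.1 * n_otus))
  unknown_block <- ids[(n_otus - n_unknown + 1):n_otus]
  background <- setdiff(ids, c(transmitted, transient, unknown_block))

  # transient dropout: half absent from the previous-year harvest seeds,
  # half absent from the sowing-stage parent seeds (and hence from the
  # parent-derived share of harvest progeny seeds)
  drop17 <- transient[seq_len(ceiling(n_transient / 2))]
  drop_parent <- setdiff(transient, drop17)

  seed_profile <- function(present) {
    p <- setNames(numeric(n_otus), ids)
    p[present] <- rlnorm(length(present), 0, 1) + 0.5
    p / sum(p)
  }
  prof_se17 <- seed_profile(c(transmitted, drop_parent))
  prof_se0 <- seed_profile(c(transmitted, drop17))

  # compartment profiles: exclusive background block + shared mass; seed
  # OTUs appear in stems/leaves (the transmission route) but transient OTUs
  # stay out of stems so the harvest mixture cannot resurrect them
  comp_prof <- list()
  comp_drift <- list()
  n_comp <- length(design$compartments)
  blocks <- suppressWarnings(split(background,
                                   rep(seq_len(n_comp),
                                       length.out = length(background))))
  for (i in seq_along(design$compartments)) {
    cp <- design$compartments[i]
    active <- blocks[[i]]
    if (grepl("^S", cp) || grepl("^L", cp) || cp == "FL")
      active <- c(active, transmitted)
    comp_prof[[cp]] <- lognormal_profile(ids, active)
    comp_drift[[cp]] <- rnorm(n_otus, 0, 0.004)   # per-OTU drift per day
  }

  # deterministic per-(compartment, age) expected profile; biological
  # variation enters as a mild per-replicate lognormal perturbation
  age_profile <- function(cp, age) {
    w <- comp_prof[[cp]] * exp(comp_drift[[cp]] * (age - 90))
    w / sum(w)
  }
  bio_noise <- function(p) {
    w <- p * exp(rnorm(length(p), 0, 0.15))
    w / sum(w)
  }

  meta_rows <- list()
  count_cols <- list()
  add_sample <- function(id, comp, age, year, bio, tech, prob) {
    meta_rows[[id]] <<- data.frame(sample_id = id, compartment = comp,
                                   age_days = age, year = year,
                                   site = design$site, bio_rep = bio,
                                   tech_rep = tech, stringsAsFactors = FALSE)
    depth <- stats::rpois(1, design$depth_mean)
    count_cols[[id]] <<- drop(rmultinom(1, max(depth, 100), prob))
  }

  # --- non-seed compartments over progeny ages ---
  for (cp in design$compartments) for (age in design$ages_days)
    for (b in seq_len(design$n_bio_rep)) {
      prob_b <- bio_noise(age_profile(cp, age))
      for (tr in seq_len(design$n_tech_rep))
        add_sample(sprintf("%s_a%d_b%d_t%d", cp, age, b, tr),
                   cp, age, design$year_progeny, b, tr, prob_b)
    }

  # --- seed generation groups ---
  sloan_jitter <- function(p) {
    Nm <- design$depth_mean * m_seed
    rel <- rbeta_safe(length(p), Nm * p, Nm * (1 - p))
    if (sum(rel) == 0) p else rel / sum(rel)
  }
  g_2017 <- g_parent <- g_harvest <- character(0)
  for (b in seq_len(design$n_bio_rep)) for (tr in seq_len(design$n_tech_rep)) {
    id <- sprintf("Se17_b%d_t%d", b, tr)
    add_sample(id, "Se", 120, design$year_parent, b, tr,
               sloan_jitter(prof_se17))
    g_2017 <- c(g_2017, id)
    id <- sprintf("Se0_b%d_t%d", b, tr)
    add_sample(id, "Se", 0, design$year_progeny, b, tr,
               sloan_jitter(prof_se0))
    g_parent <- c(g_parent, id)
  }

  # progeny seeds: pre-harvest ages follow the parent-seed profile with age
  # trends; the harvest age is the planted source mixture
  harvest_age <- max(design$seed_ages)
  stem_comps <- grep("^S", design$compartments, value = TRUE)
  stem_source_age <- max(setdiff(design$ages_days, harvest_age))
  prof_stem <- Reduce(`+`, lapply(stem_comps, age_profile,
                                  age = stem_source_age)) /
    length(stem_comps)
  prof_unknown <- setNames(numeric(n_otus), ids)
  prof_unknown[unknown_block] <- rlnorm(n_unknown, 0, 1) + 0.5
  prof_unknown <- prof_unknown / sum(prof_unknown)
  prof_harvest <- source_alpha[1] * prof_stem + source_alpha[2] * prof_se0 +
    source_alpha[3] * prof_unknown

  # niche/trend structure on transmitted OTUs in developing seeds
  trend_otus <- transmitted[seq_len(min(10, n_transmitted))]
  niche_levels <- c(0.5, 1, 2)
  niche_otus <- setNames(rep(niche_levels,
                             length.out = length(trend_otus)), trend_otus)
  pre_ages <- setdiff(design$seed_ages, harvest_age)
  for (age in pre_ages) {
    prof_age <- prof_se0
    gain <- exp(log(1 + niche_otus) * (age - min(pre_ages)) /
                  (harvest_age - min(pre_ages)))
    prof_age[trend_otus] <- prof_age[trend_otus] * gain
    prof_age <- prof_age / sum(prof_age)
    for (b in seq_len(design$n_bio_rep))
      for (tr in seq_len(design$n_tech_rep))
        add_sample(sprintf("Se_a%d_b%d_t%d", age, b, tr),
                   "Se", age, design$year_progeny, b, tr,
                   sloan_jitter(prof_age))
  }
  # harvest sinks are drawn from the planted mixture itself (multinomial
  # noise only), so the recorded source proportions are the realized truth
  for (b in seq_len(design$n_bio_rep)) for (tr in seq_len(design$n_tech_rep)) {
    id <- sprintf("Se_a%d_b%d_t%d", harvest_age, b, tr)
    add_sample(id, "Se", harvest_age, design$year_progeny, b, tr,
               prof_harvest)
    g_harvest <- c(g_harvest, id)
  }

  counts <- do.call(cbind, count_cols)
  rownames(counts) <- ids
  meta <- sample_meta(do.call(rbind, meta_rows))
  # guarantee the planted transmitted OTUs are detected in every generation
  # group (the sampling model makes a missed detection astronomically rare;
  # a single guaranteed read per group mean keeps recovery exact by design)
  for (g in list(g_2017, g_parent, g_harvest)) {
    zero <- rowSums(counts[transmitted, g, drop = FALSE]) == 0
    if (any(zero)) counts[transmitted[zero], g[1]] <- 1L
  }
  structure(list(counts = count_table(counts), meta = meta, taxonomy = tax,
                 truth = list(transmitted_otus = transmitted,
                              transient_otus = transient,
                              generation_groups = list(harvest_2017 = g_2017,
                                                       sowing_2018 = g_parent,
                                                       harvest_2018 = g_harvest),
                              trend_otus = data.frame(otu_id = trend_otus,
                                                      mode = "Late",
                                                      effect = niche_otus,
                                                      stringsAsFactors = FALSE),
                              niche_otus = niche_otus,
                              source_alpha = source_alpha,
                              unknown_block = unknown_block,
                              m_seed = m_seed)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d OTUs x %d samples, %d transmitted / %d transient planted\n",
              nrow(x$counts), ncol(x$counts),
              length(x$truth$transmitted_otus),
              length(x$truth$transient_otus)))
  invisible(x)
}

#' Write a synthetic study to the TSV/JSON dialects the readers accept
#'
#' @param study [generate_full_study()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cpath <- file.path(dir, "counts.tsv")
  df <- data.frame(otu_id = otu_ids(study$counts),
                   as.data.frame(unclass(study$counts)), check.names = FALSE)
  write_tsv(df, cpath)
  mpath <- write_tsv(study$meta, file.path(dir, "meta.tsv"))
  tpath <- write_tsv(study$taxonomy, file.path(dir, "taxonomy.tsv"))
  jpath <- file.path(dir, "truth.json")
  jsonlite::write_json(study$truth, jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(cpath, mpath, tpath, jpath))
}
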