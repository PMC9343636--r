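# seedtrans

Analysis of seed-to-seed (vertical) transmission of plant endophytic
bacterial and fungal communities from longitudinal amplicon surveys.

Seed microbiomes are assembled while the seed develops on the mother
plant, and part of that community is carried into the next generation.
Given OTU count tables sampled across plant compartments (bulk soil,
rhizosphere, root, stem and leaf sections, seeds) and developmental
timepoints over consecutive seasons, `seedtrans` answers, with tested,
reusable code:

- **Which OTUs are transmitted?**  An OTU is vertically transmitted when
  it is detected in all three generation seed groups (previous-season
  harvest, sowing-stage parent seeds, progeny harvest seeds), on the
  across-replicate mean abundance; the rest of the seed community is
  transient.
- **When do they colonize?**  Per-OTU regression of relative abundance on
  host age classifies early successors (slope t < 0, p < 0.05), late
  successors (t > 0, p < 0.05) and mid/no-trend OTUs, with
  parent-progeny convergence traced by Bray-Curtis or Jaccard
  dissimilarity and Kruskal-Wallis/Dunn letters.
- **Niche or neutrality?**  A heritability-analog *niche responsiveness*
  h² = V_age / (V_age + V_plant + V_residual) is estimated per OTU from a
  linear mixed model on CLR abundances (age fixed, plant random; plant
  cluster bootstrap) and classed High (> 0.4) / Moderate (0.2, 0.4] /
  Low (≤ 0.2).  Sloan's neutral community model is fitted to
  occurrence-abundance data - frequency of detection across local
  communities versus metacommunity relative abundance - estimating the
  migration rate m by bounded least squares, with per-OTU Wilson bands
  partitioning OTUs into above / neutral / below.
- **Where do seed microbes come from?**  An expectation-maximization
  mixture model (mixture of multinomials, FEAST-style, implemented here)
  decomposes each harvest-seed sink into contributions from every earlier
  (compartment, age) source plus an unknown source, with a monotone
  log-likelihood guarantee.
- **How are bacteria and fungi associated?**  SparCC compositional
  correlations (Dirichlet resampling, basis-variance linear system,
  exclusion iterations), permutation FDR, |r| > 0.3 edges, per-context
  networks merged into a provenance-tracking meta-network with Louvain
  modules, hubs, ABC/GA/Bertz complexity indices, edge-set Jaccard
  similarity, and hypergeometric / binomial association enrichment.

A first-class synthetic-data module generates complete longitudinal
studies under each stage's own model with recorded ground truth
(transmitted sets, trend OTUs, migration rates, mixing proportions, basis
correlations), so every estimator is validated by parameter recovery.

## Worked example

```r
library(seedtrans)

# a full synthetic study: 16 compartments x 7 ages x 3x3 replicates,
# two seed generations, known ground truth
study <- generate_full_study(seed = 1)
study
#> <synthetic_study> 300 OTUs x 1071 samples, 25 transmitted / 40 transient planted

# transmitted vs transient seed OTUs across the three generations
trans <- detect_transmitted(study$counts, study$meta,
                            study$truth$generation_groups)
trans
#> <transmission_result> 25 transmitted / 186 transient seed OTUs
setequal(names(trans$status)[trans$status == "transmitted"],
         study$truth$transmitted_otus)
#> [1] TRUE

# Sloan neutral model on developing progeny seed communities
se_prog <- subset(study$meta, compartment == "Se" & age_days > 0 & year == 2018)
filt <- filter_low_abundance(study$counts, 1e-4)
fit <- fit_neutral_model(filt,
  local_communities = intersect(se_prog$sample_id, colnames(filt)))
fit
#> <neutral_fit> m = 0.0044, N = 9752, R2 = 0.755, 154 OTUs over 45 local communities
partition_neutral(fit)$summary
#>      Var1   n
#> 1   above 127
#> 2 neutral  18
#> 3   below   9
```

The 25 planted transmitted OTUs are recovered exactly; the 186 transient
calls include both planted transient OTUs and stem/unknown-derived OTUs
that enter progeny seeds only at harvest.  The neutral fit reports the
estimated migration rate m, the community size N (mean read depth), fit
quality R², and the per-OTU partition against the 95% prediction band -
here most OTUs sit above the band because the synthetic seed community is
strongly structured.  On data generated under the neutral sampling model
itself the migration rate is recovered closely:

```r
sim <- simulate_neutral_local_communities(200, 126, N = 1000, m = 0.1, seed = 2)
round(fit_neutral_model(sim$counts)$m, 4)
#> [1] 0.0946
```

The whole analysis can also be driven by a config object:

```r
cfg <- pipeline_config(out_dir = "out", seed = 1)
res <- run_pipeline(cfg)   # writes TSV/JSON artifacts + manifest.json
```

## Package layout

- `R/containers.R`, `R/io.R` - data model (count table, metadata,
  taxonomy, normalized/distance matrices) and TSV readers/writers.
- `R/normalize.R`, `R/dissimilarity.R` - CSS/relative/CLR, Bray-Curtis /
  Jaccard, PCoA, PERMANOVA, Kruskal-Wallis + Dunn.
- `R/transmission.R` - transmitted-OTU detection, succession modes,
  convergence trajectories, core OTUs, Venn regions.
- `R/niche_neutral.R` - niche responsiveness (h²) and the Sloan neutral
  fit with niche/neutral partitioning.
- `R/source_tracking.R` - EM source tracking with unknown source.
- `R/sparcc.R`, `R/networks.R` - SparCC, permutation FDR, networks,
  meta-network, modules, hubs, complexity and enrichment statistics.
- `R/synthetic.R` - generators with ground truth, including
  `generate_full_study()`.
- `R/pipeline.R` - config-driven orchestration with manifest.
- `vignettes/seedtrans-methods.Rmd` - the models, assumptions, parameter
  choices and limitations in detail.
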