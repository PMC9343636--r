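---
title: "Models and methods behind seedtrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seedtrans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

seedtrans analyzes vertical transmission of seed endophytic bacterial and
fungal communities across plant generations: which OTUs persist from parent
seed to progeny seed, when they colonize during host development, whether
host-age niche change or neutral dispersal explains their occurrence, which
plant compartments supply the progeny seed community, and how bacterial-
fungal association networks reorganize over compartments and host age.  This
vignette describes each model, its assumptions, the tunable parameters, and
the design choices made where the literature leaves the procedure open.

## Data model and normalizations

The observational unit is an integer OTU-by-sample count table with sample
annotations (compartment, days after transplanting, year, site, biological
and technical replicate) and a kingdom-to-genus taxonomy.  Compartments
follow a rice field design: bulk soil (BS), rhizosphere (RS), root
endosphere (R), stem sections S1-S9 at 10 cm intervals, leaf sections
L1-L3, flag leaf (FL), and seed (Se); age 0 denotes parent seeds at sowing.

Three normalizations are provided.  Cumulative-sum scaling (CSS) divides
each sample by the sum of its counts at or below the chosen quantile of its
nonzero counts (default `q = 0.5`; counts equal to the quantile are
included), rescales by 1000 and applies `log2(x + 1)`.  The quantile is
fixed rather than chosen adaptively per sample; with `q = 1` CSS reduces to
total-sum scaling, which is a useful identity for testing.  Relative
abundance and the centered log-ratio (CLR, pseudocount 0.5) cover
compositional analyses.  Bray-Curtis and binary Jaccard dissimilarities,
principal coordinates (with negative eigenvalues reported, never dropped),
a single-factor distance-based PERMANOVA with permutation p-values, and
Kruskal-Wallis with pairwise two-sided Dunn tests (Benjamini-Hochberg
adjusted, compact letter display) form the shared statistical layer.  A
distance between two all-zero samples is defined as 0 with a warning.  In
taxa aggregation, groups are pooled into "other" when their mean relative
abundance is strictly below the threshold (default 0.5%), so a group
sitting exactly at the threshold is kept.

## Transmitted OTUs and successional modes

A seed OTU is *vertically transmitted* when it is detected in all three
generation groups - seeds harvested in the first season, the same seed lot
at sowing, and progeny seeds at harvest - and *transient* otherwise.
Detection applies to the across-replicate mean abundance of each group, so
the default rule (`mean_gt_zero`) counts an OTU as present if any replicate
of the group carries a read; a minimum-mean-count alternative is exposed
because robustness to sequencing noise is a judgment call.

Successional modes come from an ordinary least-squares regression of
relative abundance on host age per OTU: early successor when the slope
t-statistic is negative with p < 0.05, late successor when positive with
p < 0.05, mid/no-trend otherwise.  Parent seeds (age 0) are excluded by
default: the trajectory of interest is colonization of the developing
progeny seed.  The regression uses relative abundance (CLR is available as
an option).  The 500-OTU recovery simulations treat each OTU's trajectory
independently at the classifier interface, because several hundred OTUs
each rising by ~0.19 in relative abundance cannot coexist inside one closed
composition; the compositional route (trend injection with renormalization
and multinomial resampling) is exercised separately with a small planted
set.

Core OTUs are those detected in at least a fixed fraction of a
compartment's samples; both the 80% per-compartment preset and the 90%
across-site preset are provided because both appear in practice, and the
choice is left explicit.

## Niche responsiveness (h2)

To ask whether host development acts as a deterministic filter, a
heritability analog is computed per OTU from a linear mixed model on CLR
abundances: host age as a categorical fixed effect, biological replicate
(plant) as a random intercept.  The statistic is the fraction of variance
attributable to age:

h2 = V_age / (V_age + V_plant + V_residual)

with V_age the variance of the fitted fixed effects.  Two numerical choices
matter and are this package's own:

1. **Noise-floor subtraction.**  Estimating k = 7 age means from n = 21
   points inflates the raw V_age by sigma^2 (k-1)/(n-1) even when age has
   no effect (about 0.3 sigma^2 here).  The floor is subtracted, so a null
   OTU sits near h2 = 0 instead of near 0.15.  Without this correction
   roughly a quarter of pure-noise OTUs exceed the Low/Moderate boundary.
2. **Degenerate-resample handling in the bootstrap.**  Uncertainty comes
   from a cluster bootstrap over plants.  With only three plants, naive
   resampling draws all-identical plants with probability 1/9, which
   collapses the residual variance and drives h2 to 1.  Draws are therefore
   required to contain at least two distinct plants, each draw's floor is
   scaled by the plant-multiplicity factor sum(c^2)/r, the residual and
   plant variances of the full-data fit anchor the denominator, and draws
   are signed with only the final mean clamped to [0, 1].

Classification follows the fixed rule High (h2 > 0.4), Moderate
(0.2 < h2 <= 0.4), Low (h2 <= 0.2); the boundaries are closed exactly as
written, so h2 = 0.4 is Moderate and h2 = 0.2 is Low.  Under the null
simulation (no age effect, plant and residual standard deviations 1) at
least 90% of OTUs classify Low, and the mean h2 is monotone in the planted
age-effect size.  Singular mixed fits fall back to a fixed-effects-only fit
with the plant variance set to 0, flagged.

## Sloan's neutral model

The neutral model predicts an OTU's occurrence frequency across local
communities from its mean relative abundance p in the metacommunity, with
one free migration rate m and community size N set to the mean read depth.
Local communities default to the developing progeny seed samples;
speciation and diversification are excluded (the study window is one
season).  m is fitted by bounded least squares on occurrence frequencies
over m in (1e-6, 1), with a flag when the optimum sits at a bound.

The detection probability has two forms.  The classical continuum form
treats an OTU as detected when its latent Beta-distributed frequency
exceeds d = 1/N (an incomplete-beta CDF).  When local communities are
themselves read-sampled - counts drawn at depth N from the latent
frequency, which is exactly how amplicon data arise and how the package's
generator works - the detection event is "at least one read", whose exact
probability under the Beta-Binomial compound is 1 - B(a, b+N)/B(a, b).
The continuum approximation systematically understates detection and
inflates the fitted m by roughly a quarter at N = 1000; the exact form is
therefore the default (`detection_model = "exact"`), with the classical
form available as `"threshold"`.  With the exact form, data generated under
the model at N = 1000, m = 0.1 with 126 local communities return m within a
few percent.

Per-OTU 95% bounds on the predicted frequency use the Wilson score
interval with n = number of local communities (a normal-approximation
option exists); OTUs above the band occur more often than neutral dispersal
predicts (candidate host selection), OTUs below occur less often
(candidate exclusion).  The joint report flags OTUs that are both h2-High
and outside the neutral band as consistently niche-associated.

## Source tracking

Progeny seed communities at harvest are modeled as a mixture of candidate
source communities plus one unknown source: the sink's taxon distribution
is sum_j alpha_j gamma_j.  Sinks are the harvest-stage seed biological
replicates (technical replicates summed); sources are every earlier
(compartment, age) group of the same season plus the parent seeds, with
harvest-stage non-seed groups excluded because systemic senescence makes
them implausible donors.  Estimation is expectation-maximization on the
complete model: source counts are data too, so known-source distributions
are updated jointly with the mixing proportions (a fixed-distribution mode
is available), and the full log-likelihood is non-decreasing at every
iteration - asserted, not assumed.

The unknown source's distribution is restricted to OTUs absent from every
known source.  This is deliberate: if the unknown may place mass on
source-supported OTUs, the mixture is unidentifiable (any known source can
be duplicated into the unknown, and a sink identical to a source splits
arbitrarily between the two).  Under the restriction the unknown captures
exactly the unobserved-taxon mass, which also makes the synthetic
disjoint-unknown scenario exactly identifiable.  The cost is honest: truly
overlapping unknown sources are attributed to the known sources they
resemble, and the unknown is a lower bound in that regime.  Defaults are
tol = 1e-6 on the largest proportion change, 1000 iterations, and 5
restarts with Dirichlet-jittered initial proportions starting known-heavy
(unknown at 0.1).  A strict-replication flag runs exactly one EM iteration,
reproducing a published hyperparameter choice; one iteration cannot
converge and is provided for comparability only.

## Association networks

Compositionality-aware correlations come from the SparCC procedure,
implemented directly: per resample, fractions are drawn from a per-sample
Dirichlet posterior (counts + 1); the log-ratio variation matrix
T_ab = Var log(x_a/x_b) is formed; basis variances solve the linear system
whose row a reads (D-1) w_a + sum_{b != a} w_b = sum_b T_ab; correlations
are (w_a + w_b - T_ab) / 2 sqrt(w_a w_b), clipped to [-1, 1]; up to 10
strongly correlated pairs (|rho| > 0.1) are excluded from the system
iteratively; the final estimate is the median over 20 resamples.  D = 3 is
solved exactly in closed form and skips exclusion.  Non-positive basis
variances are replaced by the smallest positive variation entry and
flagged.  P-values come from column-independent permutations of each
taxon's counts with a two-sided pseudo-p and BH adjustment; edges require
|rho| > 0.3 (strict) and adjusted p < 0.05 (strict).

Node metrics (degree, betweenness, closeness, clustering), hubs (the 10
highest-degree nodes, ties at the cut broken lexicographically), Louvain
modules (seeded, resolution-parameterized) and three degree-based
complexity indices are computed per network: atom-bond connectivity
ABC = sum over edges sqrt((d_u + d_v - 2)/(d_u d_v)), geometric-arithmetic
GA = sum 2 sqrt(d_u d_v)/(d_u + d_v), and a Bertz-style information index
B = 2m log2(2m) - sum_v d_v log2(d_v) over the degree sequence.  The exact
formulas behind published uses of these indices vary; the forms above are
fixed here, documented, and swappable.

Context networks merge into a meta-network by node/edge union, where edge
identity is the unordered OTU pair ignoring sign (a sign-aware mode
exists) and every edge keeps its full context provenance.  Module
composition by compartment and age counts each (edge, context) detection
once.  Network similarity is the Jaccard index on edge sets, with a
similarity graph keeping pairs above 0.02.  Over-representation of label
pairs uses the hypergeometric upper tail on the edge population (draws =
edges touching one label, successes = edges touching the other, observed =
edges joining the two); a node-pair-population variant of this construction
exists in the literature, and the edge-population form used here is checked
against brute-force tail enumeration on every small graph in the test
suite.  Sign bias per label pair uses a two-sided binomial test against the
global positive-edge fraction, p = min(1, 2 min(P(X <= k), P(X >= k))).

## The synthetic-data generator

Every stage is validated against data generated under its own model, with
ground truth recorded: Beta-Binomial local communities for the neutral fit
(Beta(N m p, N m (1-p)) frequencies, Binomial(N) counts); linear age trends
with Gaussian noise, renormalization and multinomial resampling for the
succession classifier; known source mixtures with a disjoint unknown for
the tracker; log-normal latent abundances with a planted basis correlation,
compositional closure and multinomial sampling for SparCC.

`generate_full_study()` composes these into a complete longitudinal study
mirroring the field design: 16 non-seed compartments over 7 ages with 3
biological x 3 technical replicates, two seed generations, Poisson read
depths around 10,000 (amplicon scale, desk-fast).  Transmitted OTUs are
present in all three seed generations; transient OTUs are dropped from
exactly one; compartment profiles drift deterministically with age
(per-compartment drift drawn once) with mild per-replicate lognormal
noise, so that the harvest-seed mixture - 40% stem, 30% parent seed, 30%
unknown by default - is constructed from the same expected profiles that
generate the source samples.  That self-consistency is what makes the
recorded mixing proportions the realized truth rather than an
approximation; harvest sinks are drawn from the mixture with multinomial
noise only, while developing seeds carry Sloan-style Beta jitter
(migration 0.3) so the neutral machinery sees realistic occupancy
variation.  A rare multinomial dropout of a planted transmitted OTU from
an entire generation group would falsify the recorded truth, so the
generator guarantees at least one read per group for planted transmitted
OTUs (astronomically unlikely to trigger at the default scale).

What the generator does not emulate - and what passing tests therefore do
not show about field data: chimeras and sequencing error, taxonomy
misassignment, compositional interactions between compartments,
year-by-site confounding, overdispersion beyond the planted Beta jitter,
and unknown sources that overlap known ones.  Parameter recovery here
demonstrates correctness of the estimators under their assumptions, not
robustness to everything real data contain.

## Pipeline and problem sizes

`run_pipeline(pipeline_config(...))` executes the stages in dependency
order on real or simulated input and writes every artifact plus a manifest
(package version, seeds, parameters, md5 checksums).  All study cut-offs
are named, defaulted parameters: CSS quantile 0.5, abundance filter 1e-4,
core prevalence 0.8 (0.9 preset), correlation threshold 0.3, FDR 0.05, h2
cut-offs 0.2/0.4, alpha 0.05.  Unknown keys are rejected; reruns with the
same config and seed are byte-identical in all numeric outputs.

The shipped simulations are sized for interactive use: 200 OTUs x 126
communities for the neutral round trip, 50 taxa x 200 samples for SparCC
recovery, 500 OTUs for classifier operating characteristics, 200 null OTUs
with 10 bootstrap draws for h2 calibration, 200 datasets at 199
permutations for PERMANOVA calibration, and 101 random contexts for
meta-network bookkeeping.  Each completes in seconds to about a minute;
all scale linearly if larger runs are wanted.

## Known limitations

PERMANOVA is single-factor (no sequential multi-factor partitioning).  The
h2 bootstrap quantifies plant-resampling variability, not model
misspecification.  The neutral fit assumes a single metacommunity for all
local communities.  The unknown-source restriction undercounts overlapping
unknowns.  SparCC assumes a sparse true correlation structure; dense
strong correlations violate the basis approximation.  Network inference
remains correlational; edges are not interactions.
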