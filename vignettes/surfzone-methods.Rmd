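---
title: "Methods: multi-method surf-zone fish biomonitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-method surf-zone fish biomonitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfzone)
```

# The problem

Sandy-beach surf zones are hard to survey: fish are patchy, mobile, and the
habitat is hostile to most gear. Monitoring programs therefore combine beach
seines (counts per haul), baited remote underwater video (BRUV, summarized
as MaxN — the maximum number of individuals of one species visible in a
single frame), and eDNA metabarcoding of filtered seawater. These methods
disagree: each has its own detection probability per species, its own false
positives (misidentification for visual methods; contamination, index
hopping, and DNA transport for eDNA), and its own abundance proxy. This
package implements the analysis chain needed to compare them fairly, plus a
synthetic-data generator with known truth so the whole chain can be
validated end to end.

# eDNA data preparation

**Replicate-consistency decontamination.** The raw observation unit is an
ASV-by-replicate read-count matrix keyed by (site, bottle, PCR, marker).
Contamination from index hopping and sporadic lab events is overwhelmingly a
single-replicate phenomenon, so the mandatory filter keeps an ASV's reads at
a site only if it appears in at least two of that site's technical
replicates. Two interpretation choices are deliberate:

* "Technical replicates in a site" pools all PCR reactions across bottles
  (nine under the default 3 bottles x 3 PCRs). The within-bottle reading is
  available via `min_reps` on a per-bottle subset but the pooled reading is
  the default because replicate counts in this design are naturally quoted
  per site.
* Field blanks and PCR controls are read and can be reported, but are never
  subtracted from samples: blank-based subtraction tends to remove exactly
  the abundant taxa that index hopping plants in blanks.

An optional, stricter stage (`asv_occupancy_filter()`) refits the occupancy
model to each ASV's PCR-level detection pattern and zeroes site records
whose posterior probability of occurrence falls below a threshold (default
0.8). It is off by default: the two-replicate rule is the mandatory filter,
and the model-based stage retains an ASV wherever its sampler fails to
converge rather than risk deleting real signal.

**Aggregation and the eDNA index.** ASVs sharing an assigned taxonomic path
are summed (paths may stop at genus or family — surfperches with identical
12S barcodes stay one family-level taxon). Because amplification efficiency
varies wildly between taxa, read counts are not comparable between species;
the eDNA index normalizes within taxon: first each taxon's proportional
abundance per PCR replicate, then division by that taxon's maximum
proportion across all replicates of all samples (a global, not per-site,
maximum). The result lies in [0, 1] per taxon, with the maximum exactly 1
wherever the taxon has reads. The index supports within-taxon comparisons
across samples only; it deliberately sacrifices between-taxon abundance
information.

**Detection histories.** Downstream occupancy modelling needs, per species,
method, and site, the count N of replicate surveys with a detection out of
K surveys. A seine haul or BRUV deployment detects a species if its count
is at least 1 (the analysis binarizes to presence/absence; no read- or
count-floor beyond that). For eDNA the default replicate unit is the bottle
(a bottle detects a taxon if any of its PCR replicates has reads after
decontamination; K = 3 bottles), with the PCR-level unit available through
`unit = "pcr"` — the bottle unit is the default because bottles are
independent water samples while PCRs of one bottle share an extraction.
Sites that lost a deployment get a reduced K; sites without any deployment
of a method emit no histories for it.

# The occupancy model with false positives

For one species and one method, each of S sites is occupied independently
with probability psi (the species' commonness). Detections at site i follow

* N_i ~ Binomial(K_i, p11) if the site is occupied,
* N_i ~ Binomial(K_i, p10) if it is not,

with p11 the per-replicate true-positive and p10 the false-positive
detection probability. The latent occupancy states are marginalized
analytically, giving the mixture likelihood

    L(psi, p11, p10) = prod_i [ psi B(N_i; K_i, p11) + (1 - psi) B(N_i; K_i, p10) ].

From a fitted model three quantities are derived per posterior draw:

* probability of occurrence at a site with history (K, N):
  psi p11^N (1-p11)^(K-N) / [psi p11^N (1-p11)^(K-N) + (1-psi) p10^N (1-p10)^(K-N)],
  evaluated in log space (`dbinom(..., log = TRUE)` handles the p = 0, 1
  corners exactly);
* sensitivity p11 / (p11 + p10), the proportion of positive replicate
  detections that are true;
* specificity (1 - p10) / ((1 - p10) + (1 - p11)), the proportion of
  negative outcomes that are true negatives. The specificity expression is
  adopted in this ratio form because it is the only reading bounded in
  [0, 1] that matches the verbal definition.

**Priors and identifiability.** The mixture is invariant under swapping
(p11, psi) with (p10, 1 - psi); without a constraint the posterior is
bimodal by symmetry. We impose the standard ordering p10 < p11 and a
Beta(1, 10) prior on p10 (false positives are rare a priori), with flat
Beta(1, 1) priors on psi and p11. Species never detected by a method carry
no information about that method's p11 and are excluded upstream, exactly
as a field analysis would.

**Sampler.** Parameters are sampled on the logit scale by a component-wise
random-walk Metropolis sampler with acceptance-rate adaptation (target
~0.35) during warmup, 4 chains x 2,000 iterations (1,000 warmup) by
default. Detection histories are collapsed to unique (K, N) cells with
multiplicities, so one likelihood evaluation costs O(unique cells) — with
K = 3 at most four cells regardless of the number of sites, which keeps a
200-site fit under a second. Convergence is monitored with split-chain
Rhat (flagged above 1.05, never silently accepted) and an
initial-positive-sequence effective sample size. The test suite
cross-checks posterior means against brute-force 3-D grid quadrature of the
same posterior, and checks calibration (credible-interval coverage) on
simulated species.

**Method comparison.** Per method, the species-level posterior means of
mean probability of occupancy (averaged over that species' sites),
sensitivity, and specificity are compared with a one-way ANOVA (species as
observations — the species-level choice is deliberate; site-level values of
one species are strongly dependent) followed by Tukey HSD.

# Community comparison

Presence/absence (site x method) x taxon matrices are compared with
Jaccard-binary dissimilarities. PERMANOVA uses the sequential
(Type I) model `Detection ~ Method + Site`, Method entered first, through
`vegan::adonis2`; p-values use 999 random permutations by default, except
that designs with at most 7 rows are enumerated completely and the p-value
is exact. Sites missing a method are dropped listwise before PERMANOVA
(mirroring the exclusion of a site whose BRUV survey was lost); coverage
estimates use all available units per method. The companion homogeneity of
multivariate dispersions test (`vegan::betadisper`, group centroids by
default, spatial medians available) guards against conflating location and
dispersion effects. Pairs of all-empty rows have Jaccard distance defined
as 0 and are flagged rather than propagating NaN.

**Coverage and rarefaction.** Per method, incidence frequencies across T
sites feed the coverage estimator

    C_hat = 1 - (Q1 / U) * (T - 1) Q1 / ((T - 1) Q1 + 2 Q2),

with U total incidences and Q1/Q2 the species found in exactly one/two
units. Richness (Hill q = 0) is interpolated by the combinatorial
rarefaction expectation and extrapolated toward the Chao2 asymptote
S_obs + ((T-1)/T) Q1^2 / (2 Q2) (bias-corrected Q1(Q1-1)/(2(Q2+1)) when
Q2 = 0). These estimators are implemented directly from their closed forms
and verified against exhaustive subset enumeration in the tests; the
coverage curve answers design questions like "how many more seine sites
would match eDNA's coverage".

# Abundance concordance

Cross-method abundance comparisons use per-site means (catch per haul,
MaxN per deployment, eDNA index per PCR replicate) for species detected
jointly by both methods — nonzero site means — at three or more sites.
"Nonzero site mean" operationalizes "detected jointly" because the
regressions are computed on the same site means. Each retained species gets
an unweighted OLS regression on untransformed means; since nothing fixes
which variable is the response, both directions are emitted (R-squared is
direction-invariant; slope and p are labelled). Comparing a compositional
index to count data is inherently limited — the index carries no
between-taxon scale and read counts respond nonlinearly to biomass — so
these regressions are a diagnostic of association, not a calibration.

# The synthetic-data generator

The generator draws the full latent state downstream stages are judged
against. One occupancy state z_si and one local abundance lambda_si
(log-normal, meanlog 1.5, sdlog 1) are drawn per site and species and
shared by all methods — the three methods survey the same fish community —
so psi is a species property while p11/p10 are method x species properties.
Defaults describe a plausible surf-zone study:

* 18 sites; 4 seine hauls, 3 BRUV deployments, 3 bottles x 3 PCRs per site;
  20,000 reads per PCR replicate.
* a commonness gradient psi from 0.15 to 0.85 across species (assemblages
  mix rare and ubiquitous fishes);
* eDNA p11 = 0.8 for all species, while only 60% of species are readily
  caught or filmed (seine p11 = 0.55, BRUV 0.6; the cryptic rest 0.06) —
  the structural reason eDNA species lists are longer;
* false positives: 0.02 per haul/deployment (misidentification), 0.01 per
  bottle (contamination or transported DNA);
* read tables: per PCR replicate each species amplifies with its eDNA
  p11/p10; reads are multinomial over amplified species with weights
  (amplification efficiency x lambda), each amplified species receiving at
  least one read so a detection never vanishes by rounding; species reads
  split over 1-3 ASVs with fixed weights; two species share a family-level
  path by default (barcode-sharing surfperches); contaminant ASVs from a
  disjoint taxon pool land in exactly one PCR replicate each, at rate 0.2
  per replicate, making filter efficacy measurable as precision/recall;
* seine counts and BRUV MaxN are Poisson thinnings of lambda with
  catchability constants (default 1, overridable to emulate method biases).

What the generator does **not** emulate: sequence-level artifacts (chimeras,
sequencing error), between-site eDNA transport (no quantitative model
exists to parameterize it, so it is flagged rather than guessed), tidal or
seasonal dynamics, and any abundance dependence of detection probability.
Passing tests therefore demonstrate correctness of the analysis chain under
the stated generative model, not robustness to every failure mode of real
field data.

# Numerical choices and degenerate inputs

* Probability-of-occurrence and the mixture likelihood are evaluated in log
  space; log-space and direct evaluations agree to 1e-12 on non-extreme
  inputs.
* Seeds: every stochastic function takes a seed; sub-streams (truth, reads,
  counts, detections) use distinct fixed offsets of it so shared seeds do
  not couple draws. Same seed + config is byte-identical.
* Degenerate definitions: eDNA index of an all-zero taxon is 0 everywhere,
  and 0 in zero-total replicates; sensitivity is NA at p11 = p10 = 0,
  specificity NA at p11 = p10 = 1 (each with a warning); Jaccard distance
  of two empty units is 0 with a flag; coverage is NA with no incidences;
  a constant regression response has R-squared 0 and an undefined slope p.
* ANOVA of method metrics excludes methods with fewer than two species;
  dispersion tests exclude singleton groups; both warn.
* Problem sizes in the shipped tests and acceptance script (e.g. 40
  species x 200 sites for parameter recovery, 1,000 null datasets with 199
  permutations for PERMANOVA calibration, 18-site studies elsewhere) were
  chosen as the smallest designs that exercise each property cleanly at
  desk scale.

# Known limitations

* The occupancy model is single-season, covariate-free, and fits each
  species x method independently; borrowing strength across species (joint
  hierarchical priors) would stabilize rare-species fits but is out of
  scope.
* The eDNA index inflates rare taxa and cannot be compared between taxa;
  regressions against counts inherit that limitation by design.
* The random-walk sampler is adequate for a 3-parameter posterior but not a
  general-purpose MCMC; severe non-convergence is flagged, and flagged fits
  should be rerun longer rather than trusted.
* Coverage/rarefaction assume exchangeable sampling units (sites); strong
  spatial structure violates that silently.
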