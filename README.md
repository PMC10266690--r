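# surfzone

Comparing beach-seine, BRUV, and eDNA-metabarcoding surveys of surf-zone
fish communities.

Sandy-beach surf zones host distinct fish assemblages that are genuinely
hard to monitor: seines miss fast or cryptic fish, baited cameras (BRUV —
abundance summarized as *MaxN*, the maximum count of a species in one video
frame) favor scavengers and elasmobranchs, and eDNA metabarcoding detects
nearly everything but brings its own contamination and false-positive
problems. `surfzone` implements the full analysis chain for multi-method
comparisons of such surveys:

* **eDNA preparation** — replicate-consistency decontamination (an ASV's
  reads at a site are kept only when seen in ≥ 2 technical PCR replicates
  there), taxonomic aggregation of ASVs with identical paths, and the
  **eDNA index** (per-replicate read proportion of each taxon divided by
  that taxon's maximum proportion across all samples; within-taxon,
  amplification-bias-free relative abundance in [0, 1]).
* **Occupancy modelling with false positives** — for each species × method,
  site detection histories (N detections out of K replicate surveys) are fit
  to the mixture model

  ```
  z_i ~ Bernoulli(ψ),   N_i | z_i ~ Binomial(K_i, z_i ? p11 : p10)
  ```

  by an adaptive MCMC sampler with the identifiability constraint
  p10 < p11. Derived per species: probability of occurrence at each site,
  sensitivity `p11 / (p11 + p10)`, and specificity
  `(1 − p10) / ((1 − p10) + (1 − p11))`; methods are compared by ANOVA +
  Tukey HSD over species.
* **Community comparison** — Jaccard-binary dissimilarities, sequential
  PERMANOVA (`Detection ~ Method + Site`, exact permutation p on small
  designs), homogeneity of multivariate dispersions, Venn overlap of
  species sets, and incidence-based sample coverage with
  rarefaction/extrapolation to the Chao2 asymptote.
* **Abundance concordance** — species-specific OLS regressions between
  per-site mean seine counts, BRUV MaxN, and eDNA index for species
  jointly detected at ≥ 3 sites.
* **Synthetic data with known truth** — a generator for complete
  multi-method studies (latent occupancy and abundance shared across
  methods, multinomial read tables with amplification efficiencies,
  single-replicate contaminant ASVs, Poisson-thinned counts) so every
  stage above is testable end to end.

## Worked example

```r
library(surfzone)

study <- simulate_surfzone_study(n_species = 12,
                                 design = surf_design(n_sites = 10),
                                 contamination_rate = 0.2, seed = 42)
study$reads
#> replicate_read_table: 42 ASVs x 90 replicates (10 sites, 1,800,904 reads)

filt <- replicate_consistency_filter(study$reads, min_reps = 2)
sum(study$reads$counts[study$contaminant_asvs, ])  # contaminant reads before
#> [1] 904
sum(filt$counts[study$contaminant_asvs, ])         # ... and after the filter
#> [1] 0

taxa <- aggregate_by_taxonomy(filt, study$taxonomy)
taxa
#> taxon_read_table: 28 taxa x 90 replicates (1,778,917 reads)

h <- build_detection_history(taxa, unit = "bottle")  # N of K bottles per site
h$species <- path_tip(h$species)
fit <- estimate_occupancy(h[h$species == "Species_07", ], seed = 1)
fit
#> occupancy_fit: Species_07 / edna (4 chains x 1000 draws)
#>    parameter  mean median  q2.5 q97.5  rhat      ess
#>          psi 0.340  0.337 0.110 0.616 1.000  878.751
#>          p11 0.906  0.932 0.688 0.997 1.002 1058.018
#>          p10 0.029  0.020 0.001 0.108 1.003  769.275
#>  sensitivity 0.969  0.979 0.891 0.999    NA       NA
#>  specificity 0.917  0.935 0.754 0.997    NA       NA
```

Species 07 was generated as a common, well-amplifying fish: the model
recovers a high true-positive rate (posterior mean p11 ≈ 0.91), a small
false-positive rate (p10 ≈ 0.03), and an occupancy probability ψ ≈ 0.34
with honest uncertainty from only 10 sites. The same posterior gives each
site's probability of occurrence; a site with 2 of 3 positive bottles under
(ψ = 0.5, p11 = 0.8, p10 = 0.05) would score

```r
probability_of_occurrence(0.5, 0.8, 0.05, K = 3, N = 2)
#> [1] 0.9817833
```

Community-level comparisons start from the same detection histories:

```r
cm <- drop_incomplete_sites(community_matrix(study$detections))
permanova_sequential(jaccard_binary(cm),
                     method = attr(cm, "method"), site = attr(cm, "site"),
                     n_perm = 999, seed = 1)
```

A thin CLI over these functions ships in `inst/cli/surfzone.R`
(subcommands `simulate`, `decontaminate`, `index`, `occupancy`, `compare`,
`regress`; CSV outputs plus JSON run-metadata sidecars).

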