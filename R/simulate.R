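#' Survey design
#'
#' Sampling effort per site for each survey method. Defaults mirror the field
#' study the package emulates: 18 sandy-beach sites, 4 seine hauls and 3 BRUV
#' deployments per site, and 3 replicate water bottles each amplified in 3
#' PCR replicates.
#'
#' @param n_sites number of sites.
#' @param k_seine seine hauls per site.
#' @param k_bruv BRUV deployments per site.
#' @param n_bottles water-sample (bottle) replicates per site.
#' @param n_pcr technical PCR replicates per bottle.
#' @param read_depth sequencing reads per PCR replicate.
#' @param marker marker (primer set) label stamped on replicate keys.
#' @param missing_bruv_sites character vector of sites with no BRUV
#'   deployment (the study lost one site's BRUV survey; listwise exclusion
#'   downstream is exercised through this).
#' @return An object of class `surf_design`.
#' @export
surf_design <- function(n_sites = 18L, k_seine = 4L, k_bruv = 3L,
                        n_bottles = 3L, n_pcr = 3L, read_depth = 20000L,
                        marker = "teleost", missing_bruv_sites = character()) {
  stopifnot(n_sites >= 1L, k_seine >= 1L, k_bruv >= 1L,
            n_bottles >= 1L, n_pcr >= 1L, read_depth >= 1L)
  structure(list(n_sites = as.integer(n_sites), k_seine = as.integer(k_seine),
                 k_bruv = as.integer(k_bruv), n_bottles = as.integer(n_bottles),
                 n_pcr = as.integer(n_pcr), read_depth = as.integer(read_depth),
                 marker = marker,
                 sites = sprintf("Site%02d", seq_len(n_sites)),
                 missing_bruv_sites = missing_bruv_sites),
            class = "surf_design")
}

design_k <- function(design, method) {
  switch(method,
         seine = design$k_seine,
         bruv = design$k_bruv,
         edna = design$n_bottles,
         stop("unknown method: ", method, call. = FALSE))
}

#' Generating truth for a synthetic multi-method survey
#'
#' Draws the latent state every downstream stage is validated against: one
#' occupancy state z_si per site and species (the same fish community is
#' surveyed by all methods, so z and the local abundance lambda_si are shared
#' across methods), per-method true/false-positive detection rates (p11, p10),
#' and per-species amplification efficiencies for the metabarcoding reads.
#'
#' @param n_species number of fish species.
#' @param design a [surf_design()].
#' @param psi occupancy probability per species (length 1 or `n_species`).
#'   The default is a commonness gradient from 0.15 to 0.85: real surf-zone
#'   assemblages mix rare and ubiquitous species.
#' @param p11,p10 per-replicate true-/false-positive detection probabilities;
#'   length 1, or a named list with entries `seine`, `bruv`, `edna`, each of
#'   length 1 or `n_species`. Every (species, method) pair must satisfy
#'   p10 < p11 (identifiability guard). By default eDNA detects every species
#'   well (p11 = 0.8) while only a fraction `visual_frac` of species is
#'   readily caught or filmed (seine p11 = 0.55, BRUV p11 = 0.6); the rest —
#'   think cryptic, fast, or net-avoiding fishes — are nearly invisible to
#'   the visual methods (p11 = 0.06). Default false-positive rates are small
#'   (seine/BRUV 0.02 misidentification, eDNA 0.01 per-bottle contamination
#'   or transport).
#' @param visual_frac fraction of species detectable by seine/BRUV at the
#'   full rates under the default `p11`.
#' @param lambda_meanlog,lambda_sdlog log-normal parameters of the latent
#'   local abundance lambda_si (fish per haul-scale effort).
#' @param efficiency_sdlog log-sd of species amplification efficiencies.
#' @param n_family_collapsed number of species assigned a family-level
#'   taxonomic path shared within one family (emulates surfperches whose 12S
#'   barcode cannot separate species); 0 disables.
#' @param seed RNG seed.
#' @return An object of class `sim_truth`: species/parameter tables plus the
#'   latent `z` and `lambda` matrices (sites x species) and the seed.
#' @export
sim_truth <- function(n_species = 25L, design = surf_design(),
                      psi = NULL, p11 = NULL,
                      p10 = list(seine = 0.02, bruv = 0.02, edna = 0.01),
                      visual_frac = 0.6,
                      lambda_meanlog = 1.5, lambda_sdlog = 1,
                      efficiency_sdlog = 1, n_family_collapsed = 2L,
                      seed = 1L) {
  set.seed(seed)
  methods <- c("seine", "bruv", "edna")
  species <- sprintf("Species_%02d", seq_len(n_species))
  if (is.null(psi)) {
    psi <- if (n_species == 1L) 0.5 else seq(0.15, 0.85, length.out = n_species)
  }
  if (is.null(p11)) {
    visual <- seq_len(n_species) <= ceiling(visual_frac * n_species)
    p11 <- list(seine = ifelse(visual, 0.55, 0.06),
                bruv = ifelse(visual, 0.6, 0.06),
                edna = 0.8)
  }
  psi <- rep_len(psi, n_species)
  expand_rate <- function(x) {
    if (!is.list(x)) x <- stats::setNames(rep(list(x), 3L), methods)
    do.call(cbind, lapply(methods, function(m) rep_len(x[[m]], n_species)))
  }
  p11m <- expand_rate(p11); p10m <- expand_rate(p10)
  colnames(p11m) <- colnames(p10m) <- methods
  if (any(p10m >= p11m)) {
    stop("identifiability requires p10 < p11 for every species x method",
         call. = FALSE)
  }
  if (any(psi < 0 | psi > 1 | p11m < 0 | p11m > 1 | p10m < 0)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  params <- data.frame(
    species = rep(species, times = 3L),
    method = rep(methods, each = n_species),
    psi = rep(psi, times = 3L),
    p11 = as.vector(p11m), p10 = as.vector(p10m),
    stringsAsFactors = FALSE)

  z <- matrix(stats::rbinom(design$n_sites * n_species, 1L, rep(psi, each = design$n_sites)),
              design$n_sites, n_species,
              dimnames = list(design$sites, species))
  lambda <- matrix(stats::rlnorm(design$n_sites * n_species, lambda_meanlog, lambda_sdlog),
                   design$n_sites, n_species,
                   dimnames = list(design$sites, species))
  efficiency <- stats::setNames(stats::rlnorm(n_species, 0, efficiency_sdlog), species)

  taxon <- species
  if (n_family_collapsed > 0L && n_species >= n_family_collapsed) {
    collapsed <- seq_len(n_family_collapsed)
    taxon[collapsed] <- "Embiotocidae_group"  # family-level shared barcode
  }
  species_table <- data.frame(species = species, psi = psi,
                              efficiency = efficiency, taxon = taxon,
                              stringsAsFactors = FALSE)
  structure(list(species = species_table, params = params, z = z,
                 lambda = lambda, design = design, seed = as.integer(seed)),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d species x %d sites (seed %d); mean psi %.2f, occupied fraction %.2f\n",
              nrow(x$species), nrow(x$z), x$seed, mean(x$species$psi), mean(x$z)))
  invisible(x)
}

truth_rates <- function(truth, method) {
  p <- truth$params[truth$params$method == method, ]
  p[match(truth$species$species, p$species), ]
}

#' Simulate detection histories from the occupancy model
#'
#' Inverts the generative model the occupancy module fits: at each occupied
#' site a species is detected in each of K replicates with probability p11,
#' at each unoccupied site with probability p10, so N ~ Binomial(K, p11) or
#' Binomial(K, p10) given z.
#'
#' @param truth a [sim_truth()].
#' @param design a [surf_design()]; defaults to the design in `truth`.
#' @param methods which methods to simulate.
#' @param seed RNG seed.
#' @return data.frame with columns `species, method, site, N, K` (sites in
#'   `design$missing_bruv_sites` emit no BRUV rows).
#' @export
simulate_occupancy_detections <- function(truth, design = truth$design,
                                          methods = c("seine", "bruv", "edna"),
                                          seed = truth$seed) {
  # offset keeps this stream independent of the truth draw under a shared seed
  set.seed(seed + 3L)
  out <- lapply(methods, function(m) {
    rates <- truth_rates(truth, m)
    K <- design_k(design, m)
    sites <- design$sites
    if (m == "bruv") sites <- setdiff(sites, design$missing_bruv_sites)
    grid <- expand.grid(site = sites, species = truth$species$species,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    z <- truth$z[cbind(grid$site, grid$species)]
    p <- ifelse(z == 1L, rates$p11[match(grid$species, rates$species)],
                rates$p10[match(grid$species, rates$species)])
    data.frame(species = grid$species, method = m, site = grid$site,
               N = stats::rbinom(nrow(grid), K, p), K = K,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate an ASV-by-replicate metabarcoding read table
#'
#' Per PCR replicate, each species is "amplifiable" with probability p11
#' (occupied site) or p10 (unoccupied; e.g. transported DNA); reads are then
#' distributed over the amplifiable species proportionally to
#' efficiency_s x lambda_si, each species receiving at least one read so a
#' detection is never lost to rounding. Species reads are split across their
#' ASVs (1-3 per species, fixed weights), ASVs of one species share a
#' taxonomic path, and a configurable set of species carries a family-level
#' path. Contaminant ASVs (index hopping, lab contamination) each land in
#' exactly one PCR replicate.
#'
#' @param truth a [sim_truth()].
#' @param design a [surf_design()].
#' @param contamination_rate probability a PCR replicate receives one
#'   contaminant ASV.
#' @param seed RNG seed.
#' @return list with elements `reads` (a [replicate_read_table()]),
#'   `taxonomy` (data.frame `asv_id`, `path`), `contaminant_asvs`
#'   (character vector of injected ASV ids; truth for filter efficacy) and
#'   `amplified` (species x replicate logical matrix: which species truly
#'   produced reads in each PCR replicate).
#' @export
simulate_read_table <- function(truth, design = truth$design,
                                contamination_rate = 0.2, seed = truth$seed) {
  set.seed(seed + 1L)
  sp <- truth$species
  rates <- truth_rates(truth, "edna")
  n_sp <- nrow(sp)

  # fixed ASV split per species
  n_asv <- sample(1:3, n_sp, replace = TRUE)
  asv_ids <- unlist(lapply(seq_len(n_sp), function(i) {
    sprintf("ASV_%s_%d", sub("Species_", "", sp$species[i]), seq_len(n_asv[i]))
  }))
  asv_species <- rep(sp$species, times = n_asv)
  asv_w <- unlist(lapply(n_asv, function(k) {
    w <- stats::rgamma(k, 2); w / sum(w)
  }))
  fam_path <- function(taxon, species) {
    if (grepl("_group$", taxon)) {
      paste("Actinopteri", "Perciformes", "Embiotocidae", sep = ";")
    } else {
      paste("Actinopteri", "Perciformes", paste0("Family_", species),
            paste0("Genus_", species), species, sep = ";")
    }
  }
  taxonomy <- data.frame(
    asv_id = asv_ids,
    path = vapply(seq_along(asv_ids), function(j) {
      i <- match(asv_species[j], sp$species)
      fam_path(sp$taxon[i], sp$species[i])
    }, ""),
    stringsAsFactors = FALSE)

  labels <- character(0); cols <- list(); amp_cols <- list()
  contaminant_asvs <- character(0)
  n_contam <- 0L
  for (site in design$sites) {
    z <- truth$z[site, ]
    lam <- truth$lambda[site, ]
    for (b in seq_len(design$n_bottles)) {
      for (p in seq_len(design$n_pcr)) {
        amp_p <- ifelse(z == 1L, rates$p11, rates$p10)
        amp <- stats::rbinom(n_sp, 1L, amp_p) == 1L
        reads_sp <- stats::setNames(integer(n_sp), sp$species)
        if (any(amp)) {
          w <- sp$efficiency[amp] * lam[amp]
          k <- sum(amp)
          extra <- stats::rmultinom(1L, max(design$read_depth - k, 0L), w / sum(w))[, 1L]
          reads_sp[amp] <- 1L + extra
        }
        col <- integer(length(asv_ids))
        for (j in which(reads_sp > 0L)) {
          idx <- which(asv_species == sp$species[j])
          if (length(idx) == 1L) {
            col[idx] <- reads_sp[j]
          } else {
            col[idx] <- stats::rmultinom(1L, reads_sp[j], asv_w[idx])[, 1L]
          }
        }
        if (stats::runif(1L) < contamination_rate) {
          n_contam <- n_contam + 1L
          cid <- sprintf("ASV_contam_%03d", n_contam)
          contaminant_asvs <- c(contaminant_asvs, cid)
          asv_ids <- c(asv_ids, cid)
          asv_species <- c(asv_species, NA_character_)
          taxonomy <- rbind(taxonomy, data.frame(
            asv_id = cid,
            path = sprintf("Contaminant;Contaminant_sp_%03d", n_contam),
            stringsAsFactors = FALSE))
          col <- c(col, 1L + stats::rpois(1L, 49))
          cols <- lapply(cols, function(v) c(v, 0L))
        }
        cols[[length(cols) + 1L]] <- col
        amp_cols[[length(amp_cols) + 1L]] <- amp
        labels <- c(labels, paste(site, b, p, design$marker, sep = "__"))
      }
    }
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(asv_ids, labels)
  amplified <- do.call(cbind, amp_cols)
  dimnames(amplified) <- list(sp$species, labels)
  list(reads = replicate_read_table(m, parse_replicate_key(labels)),
       taxonomy = taxonomy, contaminant_asvs = contaminant_asvs,
       amplified = amplified)
}

#' Simulate seine counts and BRUV MaxN
#'
#' Counts are thinned observations of the shared latent abundance: seine
#' catch per haul ~ Poisson(c_seine x lambda_si x z_si) and BRUV MaxN per
#' deployment ~ Poisson(c_bruv x lambda_si x z_si), with method-specific
#' catchability constants.
#'
#' @param truth a [sim_truth()].
#' @param design a [surf_design()].
#' @param c_seine,c_bruv catchability constants (neutral default 1).
#' @param seed RNG seed.
#' @return Long-format data.frame `site, method, replicate, species, value`
#'   including explicit zeros (so K is recoverable from the records).
#' @export
simulate_survey_counts <- function(truth, design = truth$design,
                                   c_seine = 1, c_bruv = 1, seed = truth$seed) {
  set.seed(seed + 2L)
  one <- function(method, catchability) {
    K <- design_k(design, method)
    sites <- design$sites
    if (method == "bruv") sites <- setdiff(sites, design$missing_bruv_sites)
    grid <- expand.grid(site = sites, replicate = seq_len(K),
                        species = truth$species$species,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- catchability * truth$lambda[cbind(grid$site, grid$species)] *
      truth$z[cbind(grid$site, grid$species)]
    data.frame(site = grid$site, method = method, replicate = grid$replicate,
               species = grid$species, value = stats::rpois(nrow(grid), mu),
               stringsAsFactors = FALSE)
  }
  rbind(one("seine", c_seine), one("bruv", c_bruv))
}

#' Simulate a complete multi-method survey study
#'
#' Convenience wrapper drawing truth, detection histories, the metabarcoding
#' read table with taxonomy, and seine/BRUV count records in one call.
#'
#' @param n_species,design,seed see [sim_truth()].
#' @param contamination_rate see [simulate_read_table()].
#' @param ... further arguments passed to [sim_truth()].
#' @return list with elements `truth`, `detections`, `reads`, `taxonomy`,
#'   `contaminant_asvs`, `counts`, `design`, `seed`.
#' @export
simulate_surfzone_study <- function(n_species = 25L, design = surf_design(),
                                    contamination_rate = 0.2, seed = 1L, ...) {
  truth <- sim_truth(n_species = n_species, design = design, seed = seed, ...)
  rt <- simulate_read_table(truth, design, contamination_rate, seed)
  list(truth = truth,
       detections = simulate_occupancy_detections(truth, design, seed = seed),
       reads = rt$reads, taxonomy = rt$taxonomy,
       contaminant_asvs = rt$contaminant_asvs, amplified = rt$amplified,
       counts = simulate_survey_counts(truth, design, seed = seed),
       design = design, seed = as.integer(seed))
}
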