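#' Replicate-consistency decontamination filter
#'
#' An ASV's reads at a site are kept only if the ASV has nonzero reads in at
#' least `min_reps` of that site's technical PCR replicates (pooled across
#' bottles, so 9 replicates per site under the default 3x3 design). The rule
#' is evaluated site by site: an ASV may survive at one site and be removed
#' at another. Single-replicate detections are the signature of index hopping
#' and sporadic contamination, which this filter targets; field blanks are
#' never subtracted.
#'
#' @param reads a [replicate_read_table()].
#' @param min_reps minimum technical replicates per site (default 2;
#'   `min_reps = 1` is the identity).
#' @return A filtered `replicate_read_table` of the same shape.
#' @export
replicate_consistency_filter <- function(reads, min_reps = 2L) {
  stopifnot(inherits(reads, "replicate_read_table"), min_reps >= 1L)
  m <- reads$counts
  for (site in unique(reads$keys$site)) {
    cols <- which(reads$keys$site == site)
    prevalence <- rowSums(m[, cols, drop = FALSE] > 0L)
    m[prevalence < min_reps, cols] <- 0L
  }
  replicate_read_table(m, reads$keys)
}

#' Occupancy-based ASV filter (optional decontamination stage)
#'
#' Fits the site-occupancy model with false positives to each ASV's
#' PCR-replicate detection pattern and zeroes the ASV at sites whose
#' posterior probability of occurrence falls below `threshold`. Off by
#' default in the pipeline: the mandatory decontamination rule is the
#' replicate-consistency filter; this stage is a stricter, model-based
#' alternative. If the sampler fails to converge for an ASV it is retained
#' with a warning (conservative).
#'
#' @param reads a [replicate_read_table()], already replicate-filtered.
#' @param threshold posterior probability-of-occurrence cutoff in `[0, 1]`;
#'   0 is the identity transform.
#' @param seed RNG seed for the sampler.
#' @param ... passed to [estimate_occupancy()] (e.g. `chains`, `iter`).
#' @return A filtered `replicate_read_table`.
#' @export
asv_occupancy_filter <- function(reads, threshold = 0.8, seed = 1L, ...) {
  stopifnot(inherits(reads, "replicate_read_table"),
            threshold >= 0, threshold <= 1)
  if (threshold == 0) return(reads)
  m <- reads$counts
  sites <- unique(reads$keys$site)
  for (i in seq_len(nrow(m))) {
    det <- m[i, ] > 0L
    if (!any(det)) next
    hist <- data.frame(
      species = rownames(m)[i], method = "edna",
      site = sites,
      N = vapply(sites, function(s) sum(det[reads$keys$site == s]), 1L),
      K = vapply(sites, function(s) sum(reads$keys$site == s), 1L),
      stringsAsFactors = FALSE)
    fit <- tryCatch(
      estimate_occupancy(hist, seed = seed + i, ...),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      warning("occupancy sampler did not converge for ", rownames(m)[i],
              "; ASV retained", call. = FALSE)
      next
    }
    drop_sites <- fit$site_occurrence$site[fit$site_occurrence$mean < threshold]
    if (length(drop_sites)) {
      m[i, reads$keys$site %in% drop_sites] <- 0L
    }
  }
  replicate_read_table(m, reads$keys)
}

#' A taxon-by-replicate read table
#' @param counts integer matrix, taxa (full taxonomic paths) x replicates.
#' @param keys replicate key data.frame (see [parse_replicate_key()]).
#' @return An object of class `taxon_read_table`.
#' @export
taxon_read_table <- function(counts, keys) {
  out <- replicate_read_table(counts, keys)
  class(out) <- "taxon_read_table"
  out
}

#' @export
print.taxon_read_table <- function(x, ...) {
  cat(sprintf("taxon_read_table: %d taxa x %d replicates (%s reads)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' Sum ASV reads by assigned taxonomy
#'
#' Reads from multiple ASVs with identical assigned taxonomic paths are
#' summed into one taxon row (e.g. dozens of ASVs from two markers all
#' assigned to one surfperch). Paths that terminate above species level
#' remain family- or genus-level taxa. Per-replicate read totals are
#' conserved exactly.
#'
#' @param reads a [replicate_read_table()].
#' @param taxonomy data.frame with columns `asv_id`, `path`; every ASV in
#'   `reads` must have an assignment.
#' @return A [taxon_read_table()] with rownames = taxonomic paths.
#' @export
aggregate_by_taxonomy <- function(reads, taxonomy) {
  stopifnot(inherits(reads, "replicate_read_table"))
  path <- taxonomy$path[match(rownames(reads$counts), taxonomy$asv_id)]
  if (anyNA(path)) {
    stop("ASVs without taxonomic assignment: ",
         paste(utils::head(rownames(reads$counts)[is.na(path)], 5L),
               collapse = ", "), call. = FALSE)
  }
  agg <- rowsum(reads$counts, group = path, reorder = TRUE)
  storage.mode(agg) <- "integer"
  taxon_read_table(agg, reads$keys)
}

#' Compute the eDNA index
#'
#' A two-step within-taxon normalization of read counts that removes
#' amplification-efficiency bias between taxa: first the proportional
#' relative abundance of each taxon in each PCR replicate
#' (reads / replicate total), then division by that taxon's maximum
#' proportion across all replicates of all samples. Values lie in `[0, 1]`
#' and the per-taxon maximum is exactly 1 whenever the taxon has any reads;
#' the index is comparable across samples within a taxon, never between
#' taxa.
#'
#' @param taxa a [taxon_read_table()] (or `replicate_read_table`).
#' @return Numeric matrix of the same shape with values in `[0, 1]`; taxa
#'   with zero reads everywhere, and replicates with zero total reads, get 0.
#' @export
compute_edna_index <- function(taxa) {
  stopifnot(inherits(taxa, c("taxon_read_table", "replicate_read_table")))
  m <- taxa$counts
  totals <- colSums(m)
  prop <- sweep(m, 2L, ifelse(totals > 0L, totals, 1L), "/")
  prop[, totals == 0L] <- 0
  mx <- apply(prop, 1L, max)
  idx <- sweep(prop, 1L, ifelse(mx > 0, mx, 1), "/")
  idx[mx == 0, ] <- 0
  structure(idx, keys = taxa$keys)
}

#' Tip label of a taxonomic path
#'
#' The finest assigned rank of a semicolon-delimited path — the species
#' binomial when assignment reached species level, otherwise the family or
#' genus the path stops at. Used to align eDNA taxa with the species names
#' of seine/BRUV records.
#'
#' @param path character vector of taxonomic paths.
#' @return character vector of tip labels.
#' @export
path_tip <- function(path) sub(".*;", "", path)

#' Build detection histories
#'
#' Collapses replicate-level observations into the occupancy model's
#' sufficient statistic per (species, method, site): N detections out of K
#' replicate surveys. For seine/BRUV records a replicate detects a species
#' iff its count is at least `threshold`; for eDNA tables, with
#' `unit = "bottle"` a bottle detects a taxon iff any of its PCR replicates
#' has at least `threshold` reads (K = bottles per site), with
#' `unit = "pcr"` every PCR reaction is a replicate. K is reduced at sites
#' with missing deployments; sites with no deployment at all for a method
#' emit no rows.
#'
#' @param x a long-format survey-record data.frame (`site, method,
#'   replicate, species, value`) or a [taxon_read_table()].
#' @param threshold minimum count/reads for a detection (default 1).
#' @param K replicate surveys per site; default inferred as the maximum
#'   replicate index (records) or bottles/PCRs present (eDNA), per site.
#' @param unit eDNA replicate unit, `"bottle"` (default) or `"pcr"`.
#' @param method method label for eDNA tables (default `"edna"`).
#' @return data.frame with columns `species, method, site, N, K`.
#' @export
build_detection_history <- function(x, threshold = 1L, K = NULL,
                                    unit = c("bottle", "pcr"),
                                    method = "edna") {
  stopifnot(threshold >= 1L)
  if (inherits(x, c("taxon_read_table", "replicate_read_table"))) {
    unit <- match.arg(unit)
    detection_history_edna(x, threshold, unit, method)
  } else if (is.data.frame(x)) {
    detection_history_counts(x, threshold, K)
  } else {
    stop("x must be survey records or a taxon read table", call. = FALSE)
  }
}

detection_history_counts <- function(records, threshold, K) {
  out <- list()
  for (m in unique(records$method)) {
    rm_ <- records[records$method == m, ]
    for (site in unique(rm_$site)) {
      rs <- rm_[rm_$site == site, ]
      reps <- sort(unique(rs$replicate))
      k_site <- if (is.null(K)) length(reps) else K
      if (max(reps) > k_site) {
        stop(sprintf("replicate index %d exceeds K = %d at site %s",
                     max(reps), k_site, site), call. = FALSE)
      }
      det <- rs[rs$value >= threshold, ]
      n_by_sp <- tapply(det$replicate, det$species,
                        function(r) length(unique(r)))
      species <- sort(unique(rs$species))
      n <- integer(length(species))
      n[match(names(n_by_sp), species)] <- as.integer(n_by_sp)
      out[[length(out) + 1L]] <- data.frame(
        species = species, method = m, site = site, N = n, K = k_site,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

detection_history_edna <- function(taxa, threshold, unit, method) {
  m <- taxa$counts
  keys <- taxa$keys
  out <- list()
  for (site in unique(keys$site)) {
    cols <- which(keys$site == site)
    if (unit == "bottle") {
      bottles <- unique(keys$bottle[cols])
      det <- sapply(bottles, function(b) {
        bc <- cols[keys$bottle[cols] == b]
        rowSums(m[, bc, drop = FALSE] >= threshold) > 0L
      })
      k_site <- length(bottles)
    } else {
      det <- m[, cols, drop = FALSE] >= threshold
      k_site <- length(cols)
    }
    det <- matrix(det, nrow = nrow(m))
    out[[length(out) + 1L]] <- data.frame(
      species = rownames(m), method = method, site = site,
      N = as.integer(rowSums(det)), K = k_site, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
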