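#' Run configuration
#'
#' Bundles the tunable settings of the pipeline so a whole run is reproducible
#' from (config, seed). Counts follow the field design of the study the
#' package emulates: 4 seine hauls, 3 BRUV deployments, and 3 water bottles
#' x 3 PCR replicates per site.
#'
#' @param seed integer RNG seed recorded in every output.
#' @param min_reps minimum number of technical replicates an ASV must appear
#'   in at a site to survive decontamination (default 2).
#' @param detection_threshold minimum reads (or count) for a replicate-level
#'   detection (default 1).
#' @param chains,iter,warmup occupancy sampler settings.
#' @param n_perm PERMANOVA permutation count.
#' @param min_joint_sites minimum number of jointly-detected sites for a
#'   species to enter cross-method regressions.
#' @return An object of class `surf_config` (a validated list).
#' @export
surf_config <- function(seed = 1L, min_reps = 2L, detection_threshold = 1L,
                        chains = 4L, iter = 2000L, warmup = 1000L,
                        n_perm = 999L, min_joint_sites = 3L) {
  cfg <- list(seed = as.integer(seed), min_reps = as.integer(min_reps),
              detection_threshold = as.integer(detection_threshold),
              chains = as.integer(chains), iter = as.integer(iter),
              warmup = as.integer(warmup), n_perm = as.integer(n_perm),
              min_joint_sites = as.integer(min_joint_sites))
  counts <- cfg[setdiff(names(cfg), "seed")]
  if (any(vapply(counts, function(v) is.na(v) || v < 1L, TRUE))) {
    stop("all config counts must be >= 1", call. = FALSE)
  }
  if (cfg$warmup >= cfg$iter) stop("warmup must be < iter", call. = FALSE)
  structure(cfg, class = "surf_config")
}

#' Write a JSON run-metadata sidecar
#'
#' Every randomly-seeded output gets a sidecar recording the seed, the
#' configuration, and a short content hash of the configuration, so runs can
#' be matched to their settings after the fact.
#'
#' @param path path of the data file the metadata describes; the sidecar is
#'   written next to it as `<path>.meta.json`.
#' @param seed integer seed used.
#' @param config a [surf_config()] (or any list of settings).
#' @param extra optional named list of additional fields.
#' @return The sidecar path, invisibly.
#' @export
write_run_metadata <- function(path, seed, config, extra = list()) {
  meta <- c(list(file = basename(path), seed = as.integer(seed),
                 config = unclass(config), config_hash = config_hash(config),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            extra)
  out <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, out, auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' Content hash of a configuration
#'
#' 32-bit polynomial rolling hash over the deparsed configuration; enough to
#' tell two configurations apart in run metadata.
#'
#' @param config any R object.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
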