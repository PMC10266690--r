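# Small in-code fixtures shared across test files.

# A hand-written 2-site read table: 3 ASVs x 6 PCR replicates (2 sites x 1
# bottle-pair x 3 PCRs is not the field design; it is deliberately tiny).
tiny_read_table <- function() {
  labels <- c("A__1__1__t", "A__1__2__t", "A__1__3__t",
              "B__1__1__t", "B__1__2__t", "B__1__3__t")
  m <- rbind(
    ASV_1 = c(10L, 20L, 0L, 5L, 5L, 5L),   # 2/3 at A, 3/3 at B
    ASV_2 = c(7L, 0L, 0L, 0L, 0L, 0L),     # 1/3 at A only
    ASV_3 = c(0L, 0L, 3L, 0L, 4L, 0L))     # 1/3 at A, 1/3 at B
  colnames(m) <- labels
  replicate_read_table(m, parse_replicate_key(labels))
}

tiny_taxonomy <- function() {
  data.frame(asv_id = c("ASV_1", "ASV_2", "ASV_3"),
             path = c("C;O;F1;G1;Sp one", "C;O;F1;G1;Sp one", "C;O;F2"),
             stringsAsFactors = FALSE)
}

# Full field-scale synthetic study, cached per test run.
study_cache <- new.env(parent = emptyenv())
default_study <- function(seed = 7) {
  key <- paste0("study", seed)
  if (is.null(study_cache[[key]])) {
    study_cache[[key]] <- simulate_surfzone_study(
      n_species = 12L, design = surf_design(n_sites = 8L, read_depth = 5000L),
      contamination_rate = 0.2, seed = seed)
  }
  study_cache[[key]]
}
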