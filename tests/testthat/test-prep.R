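test_that("the two-replicate rule removes single-replicate detections per site", {
  rt <- tiny_read_table()
  filt <- replicate_consistency_filter(rt, min_reps = 2L)
  # ASV_1: 2/3 at A and 3/3 at B -> untouched
  expect_identical(filt$counts["ASV_1", ], rt$counts["ASV_1", ])
  # ASV_2: 1/3 at site A -> zeroed there
  expect_true(all(filt$counts["ASV_2", ] == 0L))
  # ASV_3: one replicate at each site -> removed at both
  expect_true(all(filt$counts["ASV_3", ] == 0L))
})

test_that("the filter is per-site: an ASV can survive at one site only", {
  labels <- c("A__1__1__t", "A__1__2__t", "B__1__1__t", "B__1__2__t")
  m <- rbind(ASV_x = c(5L, 6L, 7L, 0L))
  colnames(m) <- labels
  filt <- replicate_consistency_filter(
    replicate_read_table(m, parse_replicate_key(labels)))
  expect_equal(unname(filt$counts["ASV_x", ]), c(5L, 6L, 0L, 0L))
})

test_that("filter is monotone in min_reps and the identity at min_reps = 1", {
  rt <- default_study()$reads
  expect_identical(replicate_consistency_filter(rt, 1L)$counts, rt$counts)
  prev <- rt$counts
  for (k in 2:4) {
    cur <- replicate_consistency_filter(rt, k)$counts
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("taxonomic aggregation sums identical paths and conserves reads", {
  # two ASVs of one species: 1.5M + 1.4M reads -> one 2.9M-read taxon
  labels <- c("S__1__1__t", "S__1__2__t")
  m <- rbind(ASV_1 = c(1000000L, 500000L), ASV_3 = c(900000L, 500000L))
  colnames(m) <- labels
  rt <- replicate_read_table(m, parse_replicate_key(labels))
  tax <- data.frame(asv_id = c("ASV_1", "ASV_3"),
                    path = rep("C;O;F;G;Atherinops affinis", 2L))
  agg <- aggregate_by_taxonomy(rt, tax)
  expect_equal(nrow(agg$counts), 1L)
  expect_equal(sum(as.numeric(agg$counts)), 2900000)
  expect_equal(unname(colSums(agg$counts)), unname(colSums(rt$counts)))

  # 41 ASVs sharing one path collapse to the 41-row sum
  set.seed(41)
  m41 <- matrix(rpois(41 * 3, 50), 41, 3,
                dimnames = list(sprintf("ASV_%02d", 1:41),
                                c("S__1__1__t", "S__1__2__t", "S__1__3__t")))
  storage.mode(m41) <- "integer"
  rt41 <- replicate_read_table(m41, parse_replicate_key(colnames(m41)))
  tax41 <- data.frame(asv_id = rownames(m41), path = "C;O;Embiotocidae")
  agg41 <- aggregate_by_taxonomy(rt41, tax41)
  expect_equal(unname(agg41$counts[1L, ]), unname(colSums(m41)))

  # single ASV -> identical single-taxon table
  rt1 <- replicate_read_table(m[1L, , drop = FALSE],
                              parse_replicate_key(labels))
  agg1 <- aggregate_by_taxonomy(rt1, tax[1L, ])
  expect_equal(unname(agg1$counts[1L, ]), unname(m[1L, ]))

  # orphan ASVs are listed
  expect_error(aggregate_by_taxonomy(rt, tax[1L, ]), "ASV_3")
})

test_that("aggregation conserves per-replicate totals on synthetic data", {
  study <- default_study()
  agg <- aggregate_by_taxonomy(study$reads, study$taxonomy)
  expect_identical(colSums(agg$counts), colSums(study$reads$counts))
})

test_that("eDNA index follows the two-step definition", {
  # proportions 0.5 and 0.1 in two replicates -> indices 1.0 and 0.2
  labels <- c("S__1__1__t", "S__1__2__t")
  m <- rbind(tax_a = c(50L, 10L), tax_b = c(50L, 90L))
  colnames(m) <- labels
  idx <- compute_edna_index(taxon_read_table(m, parse_replicate_key(labels)))
  expect_equal(unname(idx["tax_a", ]), c(1.0, 0.2))
  expect_equal(unname(idx["tax_b", ]), c(0.5 / 0.9, 1.0))
})

test_that("eDNA index invariants hold: range, per-taxon max, scaling, degenerate cases", {
  study <- default_study()
  taxa <- aggregate_by_taxonomy(replicate_consistency_filter(study$reads),
                                study$taxonomy)
  idx <- compute_edna_index(taxa)
  expect_true(all(idx >= 0 & idx <= 1))
  nonzero <- rowSums(taxa$counts) > 0L
  expect_true(all(abs(apply(idx[nonzero, , drop = FALSE], 1L, max) - 1) < 1e-12))
  expect_true(all(idx[!nonzero, ] == 0))

  # uniform rescaling of one replicate's reads leaves the index unchanged
  m2 <- taxa$counts
  m2[, 3L] <- m2[, 3L] * 7L
  idx2 <- compute_edna_index(taxon_read_table(m2, taxa$keys))
  expect_equal(idx2, idx, tolerance = 1e-12)

  # a replicate with zero total gets index 0 for all taxa
  m3 <- taxa$counts
  m3[, 5L] <- 0L
  idx3 <- compute_edna_index(taxon_read_table(m3, taxa$keys))
  expect_true(all(idx3[, 5L] == 0))

  # one replicate alone: every detected taxon is its own maximum
  one <- taxon_read_table(taxa$counts[, 1L, drop = FALSE], taxa$keys[1L, ])
  idx1 <- compute_edna_index(one)
  expect_true(all(idx1[one$counts[, 1L] > 0L, 1L] == 1))
})

test_that("detection histories apply the threshold rule per method", {
  # hauls (0, 3, 0, 1) -> N = 2 of K = 4
  rec <- data.frame(site = "S", method = "seine", replicate = 1:4,
                    species = "Sp one", value = c(0, 3, 0, 1))
  h <- build_detection_history(rec)
  expect_equal(h$N, 2L)
  expect_equal(h$K, 4L)
  h2 <- build_detection_history(rec, threshold = 3L)
  expect_equal(h2$N, 1L)
})

test_that("eDNA bottle-level histories detect a bottle when any PCR has reads", {
  labels <- as.vector(outer(1:3, 1:3, function(p, b)
    sprintf("S__%d__%d__t", b, p)))
  m <- matrix(0L, 1, 9, dimnames = list("tax_a", labels))
  keys <- parse_replicate_key(labels)
  m[1L, which(keys$bottle == 2L)[1:2]] <- c(5L, 8L)  # bottle 2 only
  h <- build_detection_history(taxon_read_table(m, keys), unit = "bottle")
  expect_equal(h$N, 1L)
  expect_equal(h$K, 3L)
  hp <- build_detection_history(taxon_read_table(m, keys), unit = "pcr")
  expect_equal(hp$N, 2L)
  expect_equal(hp$K, 9L)
})

test_that("sites with missing deployments reduce K and absent methods emit no rows", {
  rec <- rbind(
    data.frame(site = "A", method = "bruv", replicate = rep(1:3, each = 1),
               species = "Sp one", value = c(1, 0, 2)),
    data.frame(site = "B", method = "bruv", replicate = 1:2,
               species = "Sp one", value = c(1, 1)))
  h <- build_detection_history(rec)
  expect_equal(h$K[h$site == "A"], 3L)
  expect_equal(h$K[h$site == "B"], 2L)  # one deployment lost
  expect_false("C" %in% h$site)         # no deployment, no history
  expect_error(build_detection_history(rec, K = 2L), "exceeds K")
})

test_that("generated detections are recoverable from generated read tables", {
  # with no contaminants and threshold 1 the prep pipeline reproduces the
  # amplification truth at PCR level, collapsed to taxon
  des <- surf_design(n_sites = 5L, read_depth = 3000L)
  tr <- sim_truth(n_species = 8L, design = des, seed = 21)
  rt <- simulate_read_table(tr, contamination_rate = 0, seed = 21)
  taxa <- aggregate_by_taxonomy(rt$reads, rt$taxonomy)
  h <- build_detection_history(taxa, threshold = 1L, unit = "pcr")

  path_of <- rt$taxonomy$path[match(
    paste0("ASV_", sub("Species_", "", rownames(rt$amplified)), "_1"),
    rt$taxonomy$asv_id)]
  for (i in seq_len(nrow(h))) {
    cols <- taxa$keys$site == h$site[i]
    sp <- rownames(rt$amplified)[path_of == h$species[i]]
    truth_n <- sum(colSums(rt$amplified[sp, cols, drop = FALSE]) > 0L)
    expect_equal(h$N[i], truth_n)
  }
})

test_that("the occupancy-based ASV filter removes single-shot contaminants and keeps real taxa", {
  labels <- as.vector(outer(1:3, paste0("S", 1:6), function(p, s)
    sprintf("%s__1__%d__t", s, p)))
  keys <- parse_replicate_key(labels)
  contam <- integer(18); contam[5L] <- 30L
  m <- rbind(ASV_real = rep(40L, 18L), ASV_once = contam)
  colnames(m) <- labels
  rt <- replicate_read_table(m, keys)
  filt <- asv_occupancy_filter(rt, threshold = 0.8, seed = 2,
                               chains = 2L, iter = 800L, warmup = 400L)
  expect_true(all(filt$counts["ASV_once", ] == 0L))
  expect_identical(filt$counts["ASV_real", ], rt$counts["ASV_real", ])
  # threshold 0 is the identity
  expect_identical(asv_occupancy_filter(rt, threshold = 0)$counts, rt$counts)
})

test_that("path_tip returns the finest assigned rank", {
  expect_equal(path_tip(c("C;O;F;G;Sp one", "C;O;Embiotocidae", "Solo")),
               c("Sp one", "Embiotocidae", "Solo"))
})
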