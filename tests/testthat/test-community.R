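# Brute-force one-factor PERMANOVA oracle on a distance matrix: SS from
# within-group pairwise distances, exact p by enumerating group labelings.
permanova_oracle <- function(d, groups) {
  dm <- as.matrix(d)^2
  n <- nrow(dm)
  ss_total <- sum(dm[upper.tri(dm)]) / n
  ss_within <- function(g) {
    sum(vapply(unique(g), function(lv) {
      idx <- which(g == lv)
      sum(dm[idx, idx][upper.tri(dm[idx, idx])]) / length(idx)
    }, 1))
  }
  a <- length(unique(groups))
  f_stat <- function(g) {
    ssw <- ss_within(g)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(groups)
  combos <- utils::combn(n, sum(groups == unique(groups)[1L]))
  fs <- apply(combos, 2L, function(idx) {
    g <- rep(unique(groups)[2L], n); g[idx] <- unique(groups)[1L]
    f_stat(g)
  })
  list(F = f_obs, ss_between = ss_total - ss_within(groups),
       ss_total = ss_total, p = mean(fs >= f_obs - 1e-12))
}

test_that("Jaccard-binary distances follow the set-count definition", {
  m <- rbind(u1 = c(1L, 1L, 1L, 0L),   # {a, b, c}
             u2 = c(0L, 1L, 1L, 1L),   # {b, c, d}
             u3 = c(1L, 1L, 1L, 0L),   # identical to u1
             u4 = c(0L, 0L, 0L, 1L))   # disjoint from u1
  colnames(m) <- letters[1:4]
  d <- as.matrix(jaccard_binary(m))
  expect_equal(d["u1", "u2"], 1 - 2 / 4)
  expect_equal(d["u1", "u3"], 0)
  expect_equal(d["u1", "u4"], 1)
})

test_that("Jaccard output is a metric and empty pairs are defined as 0 with a flag", {
  set.seed(17)
  m <- matrix(rbinom(10 * 8, 1, 0.4), 10, 8)
  m[3, ] <- 0L; m[7, ] <- 0L
  rownames(m) <- paste0("r", 1:10)
  d <- jaccard_binary(m)
  dm <- as.matrix(d)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm >= 0 & dm <= 1))
  # triangle inequality, exhaustively
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
  }
  expect_equal(dm["r3", "r7"], 0)
  expect_match(paste(attr(d, "empty_pairs"), collapse = " "), "r3 / r7")
})

test_that("community matrices binarize detection histories by unit", {
  h <- data.frame(species = c("a", "b", "a", "a"),
                  method = c("seine", "seine", "bruv", "seine"),
                  site = c("S1", "S1", "S1", "S2"),
                  N = c(2L, 0L, 1L, 3L), K = 4L)
  cm <- community_matrix(h)
  expect_equal(cm["S1:seine", "a"], 1L)
  expect_equal(cm["S1:seine", "b"], 0L)
  expect_equal(cm["S1:bruv", "a"], 1L)
  expect_true("S2:seine" %in% rownames(cm))
  expect_equal(attr(cm, "empty_rows"), character(0))
})

test_that("sites lacking a required method are dropped listwise", {
  h <- expand.grid(species = "a", method = c("seine", "bruv"),
                   site = c("S1", "S2"), stringsAsFactors = FALSE)
  h$N <- 1L; h$K <- 3L
  h <- h[!(h$site == "S2" & h$method == "bruv"), ]  # S2 lost its BRUV survey
  cm <- community_matrix(h)
  kept <- drop_incomplete_sites(cm)
  expect_equal(sort(unique(attr(kept, "site"))), "S1")
  expect_equal(nrow(kept), 2L)
})

test_that("6-row PERMANOVA matches brute-force SS and exact enumeration", {
  set.seed(18)
  m <- matrix(rbinom(6 * 12, 1, 0.5), 6, 12)
  rownames(m) <- paste0("r", 1:6)
  groups <- rep(c("g1", "g2"), each = 3)
  d <- jaccard_binary(m)
  res <- permanova_sequential(d, method = groups, site = NULL, seed = 1)
  oracle <- permanova_oracle(d, groups)
  tab <- res$table
  expect_true(res$exact)
  expect_equal(tab$F[tab$term == "Method"], oracle$F, tolerance = 1e-10)
  expect_equal(tab$SumOfSqs[tab$term == "Method"], oracle$ss_between,
               tolerance = 1e-10)
  expect_equal(tab$SumOfSqs[tab$term == "Total"], oracle$ss_total,
               tolerance = 1e-10)
  expect_equal(tab$p[tab$term == "Method"], oracle$p, tolerance = 1e-10)
})

test_that("PERMANOVA R-squared values partition the total variance", {
  study <- default_study()
  cm <- community_matrix(study$detections)
  cm <- drop_incomplete_sites(cm)
  d <- jaccard_binary(cm)
  res <- permanova_sequential(d, method = attr(cm, "method"),
                              site = attr(cm, "site"), n_perm = 99, seed = 2)
  tab <- res$table
  expect_equal(sum(tab$R2[tab$term != "Total"]), 1, tolerance = 1e-9)
  expect_equal(tab$SumOfSqs[tab$term == "Total"],
               sum(tab$SumOfSqs[tab$term != "Total"]), tolerance = 1e-9)
  expect_true(all(tab$SumOfSqs > -1e-12))
})

test_that("PERMANOVA guards degenerate inputs", {
  d <- dist(matrix(rnorm(12), 6))
  expect_error(permanova_sequential(d, method = paste0("g", 1:6), site = NULL),
               "confounded")
  expect_error(permanova_sequential(d, method = rep(c("a", "b"), 3),
                                    site = NULL, n_perm = 0), "n_perm")
})

test_that("dispersion homogeneity finds equal spread symmetric groups and unequal ones", {
  # translated copies of one configuration -> equal mean dispersion, p = 1
  base <- matrix(c(0, 0, 1, 0, 0, 1, 1.5, 1.5), 4, 2, byrow = TRUE)
  m <- rbind(base, base + 10)  # same shape, translated
  d <- dist(m)
  grp <- rep(c("a", "b"), each = 4)
  res <- dispersion_homogeneity(d, grp)
  expect_equal(unname(diff(res$group_means)), 0, tolerance = 1e-10)
  expect_gt(res$p, 0.9)

  # one tight group, one spread group -> matches a direct ANOVA on distances
  set.seed(19)
  m2 <- rbind(matrix(rnorm(10, sd = 0.01), 5, 2),
              matrix(rnorm(10, sd = 3), 5, 2))
  d2 <- dist(m2)
  grp2 <- rep(c("tight", "spread"), each = 5)
  res2 <- dispersion_homogeneity(d2, grp2)
  ref <- anova(lm(res2$distances ~ grp2))
  expect_equal(res2$F, ref$`F value`[1])
  expect_equal(res2$p, ref$`Pr(>F)`[1])
  expect_lt(res2$p, 0.05)

  # single usable group: distances only, no test
  expect_warning(res3 <- dispersion_homogeneity(d2, c(rep("a", 9), "b")),
                 "single member")
  expect_true(is.na(res3$F))
  expect_equal(length(res3$distances), 9L)
})

test_that("Venn overlap counts every region of the set partition", {
  v2 <- venn_overlap(list(seine = c("a", "b"), bruv = c("b", "c")))
  expect_equal(v2$regions[["seine"]], 1L)
  expect_equal(v2$regions[["bruv"]], 1L)
  expect_equal(v2$regions[["seine&bruv"]], 1L)
  expect_equal(v2$total, 3L)
  expect_equal(v2$pairwise_shared_fraction[["seine&bruv"]], 1 / 3)

  # identical sets: everything in the centre
  vid <- venn_overlap(list(x = letters[1:5], y = letters[1:5]))
  expect_equal(vid$regions[["x&y"]], 5L)
  expect_equal(vid$regions[["x"]], 0L)

  # three synthetic sets match brute-force set algebra
  set.seed(20)
  pool <- sprintf("sp%03d", 1:120)
  sets <- list(seine = sample(pool, 24), bruv = sample(pool, 30),
               edna = sample(pool, 89))
  v3 <- venn_overlap(sets)
  with_sets <- function(inc) {
    inside <- Reduce(intersect, sets[inc])
    length(setdiff(inside, unlist(sets[!names(sets) %in% inc])))
  }
  expect_equal(v3$regions[["seine"]], with_sets("seine"))
  expect_equal(v3$regions[["seine&edna"]], with_sets(c("seine", "edna")))
  expect_equal(v3$regions[["seine&bruv&edna"]],
               with_sets(c("seine", "bruv", "edna")))
  expect_equal(sum(v3$regions), length(unique(unlist(sets))))
})

test_that("sample coverage matches the incidence estimator by hand", {
  # T = 4, Q1 = 2, Q2 = 1, U = 10 -> 1 - 0.2 * (6 / 8) = 0.85
  # incidence frequencies (3, 3, 2, 1, 1) over 4 units
  inc <- rbind(c(1, 0, 1, 1, 0),
               c(1, 1, 1, 0, 0),
               c(1, 1, 0, 0, 0),
               c(0, 1, 0, 0, 1))
  cov <- sample_coverage(inc)
  expect_equal(cov$Q1, 2L); expect_equal(cov$Q2, 1L); expect_equal(cov$U, 10L)
  expect_equal(cov$coverage, 0.85)

  # no uniques -> coverage exactly 1
  full <- matrix(1L, 3, 6)
  expect_equal(sample_coverage(full)$coverage, 1)
  two <- rbind(c(1, 1), c(1, 1), c(0, 1))
  expect_equal(sample_coverage(two)$Q1, 0L)
  expect_equal(sample_coverage(two)$coverage, 1)

  # no incidences at all -> undefined
  expect_true(is.na(sample_coverage(matrix(0L, 3, 2))$coverage))
})

test_that("rarefaction interpolates exactly and extrapolates to the Chao2 asymptote", {
  # S_obs = 10, Q1 = 4, Q2 = 2, T = 5 -> asymptote 10 + (4/5) * 16/4 = 13.2
  inc <- matrix(0L, 5, 10)
  inc[, 1:4] <- rbind(1, 1, 1, 1, 1)      # 4 species everywhere
  inc[1:2, 5:6] <- 1L                      # 2 duplicates
  inc[1, 7:8] <- 1L; inc[2, 9:10] <- 1L    # 4 uniques
  rc <- rarefy_extrapolate_richness(inc, t_values = 1:10)
  expect_equal(rc$S_obs, 10L)
  expect_equal(rc$chao2, 13.2)
  # rarefying to T returns S_obs
  expect_equal(rc$curve$richness[rc$curve$t == 5], 10)
  # nondecreasing in units, bounded by the asymptote
  expect_true(all(diff(rc$curve$richness) >= -1e-12))
  expect_true(all(rc$curve$richness <= rc$chao2 + 1e-9))
  expect_true(all(diff(rc$curve$coverage) >= -1e-12))

  # interpolated richness matches exhaustive subset enumeration
  set.seed(22)
  inc2 <- matrix(rbinom(5 * 7, 1, 0.45), 5, 7)
  inc2[1, ] <- pmax(inc2[1, ], rbinom(7, 1, 0.5))
  rc2 <- rarefy_extrapolate_richness(inc2, t_values = 1:5)
  for (t in 1:4) {
    subsets <- utils::combn(5, t)
    exp_rich <- mean(apply(subsets, 2L, function(idx) {
      sum(colSums(inc2[idx, , drop = FALSE]) > 0L)
    }))
    expect_equal(rc2$curve$richness[t], exp_rich, tolerance = 1e-10)
  }
})

test_that("coverage and rarefaction are invariant to unit order and zero columns", {
  set.seed(23)
  inc <- matrix(rbinom(6 * 9, 1, 0.4), 6, 9)
  inc[, 9] <- pmax(inc[, 9], c(1, rep(0, 5)))  # ensure a unique exists
  perm <- sample(6)
  aug <- cbind(inc, 0L)                         # all-zero species column
  a <- sample_coverage(inc); b <- sample_coverage(inc[perm, ])
  cc <- sample_coverage(aug)
  expect_equal(a$coverage, b$coverage)
  expect_equal(a$coverage, cc$coverage)
  ra <- rarefy_extrapolate_richness(inc, 1:12)
  rb <- rarefy_extrapolate_richness(inc[perm, ], 1:12)
  rcz <- rarefy_extrapolate_richness(aug, 1:12)
  expect_equal(ra$curve, rb$curve)
  expect_equal(ra$curve, rcz$curve)
  expect_error(rarefy_extrapolate_richness(inc, 0), ">= 1")
})
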