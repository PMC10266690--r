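#' Build a presence/absence community matrix
#'
#' Rows are (site, method) survey units, columns are taxa, cells are 1 when
#' the taxon was detected (N >= 1 in the unit's detection history).
#'
#' @param histories data.frame with columns `species, method, site, N`.
#' @return Binary integer matrix with rownames `site:method`; attributes
#'   `site` and `method` give the row factors. All-zero rows are permitted
#'   but flagged via the `empty_rows` attribute.
#' @export
community_matrix <- function(histories) {
  species <- sort(unique(histories$species))
  units <- unique(histories[c("site", "method")])
  units <- units[order(units$site, units$method), ]
  m <- matrix(0L, nrow(units), length(species),
              dimnames = list(paste(units$site, units$method, sep = ":"),
                              species))
  det <- histories[histories$N >= 1L, ]
  m[cbind(paste(det$site, det$method, sep = ":"), det$species)] <- 1L
  structure(m, site = units$site, method = units$method,
            empty_rows = rownames(m)[rowSums(m) == 0L])
}

#' Jaccard-binary dissimilarity between survey units
#'
#' `d(x, y) = 1 - |shared| / |union|` on presence/absence rows, via
#' [vegan::vegdist()]. A pair of rows with no species at all has an empty
#' union; its distance is defined as 0 and the pairs are listed in the
#' `empty_pairs` attribute.
#'
#' @param mat binary community matrix (rows = units, columns = taxa).
#' @return A `dist` object.
#' @export
jaccard_binary <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L, all(mat %in% c(0L, 1L)))
  # vegdist warns about empty rows; their pairs are defined and flagged below
  d <- suppressWarnings(vegan::vegdist(mat, method = "jaccard", binary = TRUE))
  if (anyNA(d)) {
    pairs <- which(is.na(as.matrix(d)), arr.ind = TRUE)
    pairs <- pairs[pairs[, 1L] < pairs[, 2L], , drop = FALSE]
    attr(d, "empty_pairs") <- apply(pairs, 1L, function(ij) {
      paste(rownames(mat)[ij], collapse = " / ")
    })
    d[is.na(d)] <- 0
  }
  d
}

#' Sequential PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate ANOVA partitioning the distance matrix as
#' `Detection ~ Method + Site` with sequential (Type I) sums of squares,
#' Method entered first, via [vegan::adonis2()]. P-values use `n_perm`
#' random permutations of the rows, except that when the total number of
#' distinct permutations is at most `exact_limit` every permutation is
#' enumerated and the p-value is exact. Units from sites lacking any method
#' should be dropped beforehand (see [drop_incomplete_sites()]) so the
#' design is balanced, mirroring the exclusion of a site that lost its BRUV
#' survey.
#'
#' @param d `dist` object (e.g. from [jaccard_binary()]).
#' @param method,site factors (or vectors) of length `nrow`, the model terms;
#'   `site = NULL` fits the one-factor model `~ Method`.
#' @param n_perm number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param exact_limit enumerate all permutations when `n! <= exact_limit`.
#' @return An object of class `permanova_result`: the per-term table
#'   (`Df, SumOfSqs, R2, F, p`), `n_perm`, `exact`, and `seed`.
#' @export
permanova_sequential <- function(d, method, site, n_perm = 999L, seed = 1L,
                                 exact_limit = 10000L) {
  n <- attr(d, "Size")
  stopifnot(length(method) == n, is.null(site) || length(site) == n)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  method <- factor(method)
  terms <- list(Method = method)
  if (!is.null(site)) terms$Site <- factor(site)
  for (f in terms) {
    if (nlevels(f) == n) {
      stop("a factor with one row per level is confounded with residuals",
           call. = FALSE)
    }
  }
  meta <- as.data.frame(terms)
  fml <- if (is.null(site)) d ~ Method else d ~ Method + Site
  exact <- factorial(n) <= exact_limit
  set.seed(seed)
  if (exact) {
    perms <- all_permutations(n)
    perms <- perms[-1L, , drop = FALSE]  # identity handled by the +1 convention
    res <- vegan::adonis2(fml, data = meta, by = "terms", permutations = perms)
    n_perm_used <- nrow(perms)
  } else {
    res <- vegan::adonis2(fml, data = meta, by = "terms", permutations = n_perm)
    n_perm_used <- n_perm
  }
  tab <- data.frame(term = rownames(res), Df = res$Df, SumOfSqs = res$SumOfSqs,
                    R2 = res$R2, F = res$F, p = res$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n_perm = n_perm_used, exact = exact,
                 seed = as.integer(seed)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, digits = 4L, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %s%d permutations, seed %d)\n",
              if (x$exact) "exact: " else "", x$n_perm, x$seed))
  print(cbind(x$table[1L], round(x$table[-1L], digits)), row.names = FALSE)
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Drop survey units from sites missing a method
#'
#' Listwise exclusion for balanced PERMANOVA designs: a site is kept only if
#' every method in `required` has a row for it.
#'
#' @param mat community matrix from [community_matrix()].
#' @param required methods every retained site must have.
#' @return The row-subset community matrix (attributes updated).
#' @export
drop_incomplete_sites <- function(mat, required = unique(attr(mat, "method"))) {
  site <- attr(mat, "site"); method <- attr(mat, "method")
  keep_sites <- names(which(vapply(
    split(method, site), function(m) all(required %in% m), TRUE)))
  keep <- site %in% keep_sites
  structure(mat[keep, , drop = FALSE], site = site[keep],
            method = method[keep],
            empty_rows = intersect(attr(mat, "empty_rows"),
                                   rownames(mat)[keep]))
}

#' Homogeneity of multivariate group dispersions
#'
#' Embeds the dissimilarity matrix by principal coordinates (with the usual
#' correction for negative eigenvalues), computes each unit's distance to
#' its group centroid via [vegan::betadisper()], and tests for equal mean
#' dispersion with a one-way ANOVA. Groups with a single member are excluded
#' with a warning; with fewer than two usable groups only the distances are
#' returned.
#'
#' @param d `dist` object.
#' @param groups grouping vector (e.g. method).
#' @param type `"centroid"` (default) or `"median"`.
#' @return list with `distances` (per-unit distance to group centroid),
#'   `group_means`, and `F`/`p` (NA when no test was possible).
#' @export
dispersion_homogeneity <- function(d, groups, type = "centroid") {
  groups <- factor(groups)
  sizes <- table(groups)
  singletons <- names(sizes)[sizes < 2L]
  if (length(singletons)) {
    warning("groups with a single member excluded: ",
            paste(singletons, collapse = ", "), call. = FALSE)
    keep <- !(groups %in% singletons)
    d <- stats::as.dist(as.matrix(d)[keep, keep])
    groups <- droplevels(groups[keep])
  }
  bd <- vegan::betadisper(d, groups, type = type)
  distances <- bd$distances
  if (nlevels(groups) < 2L) {
    return(list(distances = distances,
                group_means = tapply(distances, groups, mean),
                F = NA_real_, p = NA_real_))
  }
  an <- stats::anova(bd)
  list(distances = distances,
       group_means = tapply(distances, groups, mean),
       F = an$`F value`[1L], p = an$`Pr(>F)`[1L])
}

#' Venn overlap of species sets between methods
#'
#' Counts every region of the 2- or 3-set partition of species detected by
#' each survey method, plus pairwise shared fractions (shared species over
#' the union of the pair).
#'
#' @param sets named list of 2 or 3 character vectors of species.
#' @return list with `regions` (named counts; names like `"seine&bruv"`),
#'   `total` (size of the union) and `pairwise_shared_fraction`.
#' @export
venn_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2L, 3L),
            !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  all_sp <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_sp %in% s, logical(length(all_sp)))
  membership <- matrix(membership, nrow = length(all_sp),
                       dimnames = list(all_sp, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1L, , drop = FALSE]
  regions <- apply(combos, 1L, function(inc) {
    sum(apply(membership, 1L, function(row) all(row == inc)))
  })
  names(regions) <- apply(combos, 1L, function(inc) {
    paste(names(sets)[as.logical(inc)], collapse = "&")
  })
  pairs <- utils::combn(names(sets), 2L)
  shared <- apply(pairs, 2L, function(pr) {
    a <- sets[[pr[1L]]]; b <- sets[[pr[2L]]]
    u <- length(union(a, b))
    if (u == 0L) NA_real_ else length(intersect(a, b)) / u
  })
  names(shared) <- apply(pairs, 2L, paste, collapse = "&")
  list(regions = regions, total = length(all_sp),
       pairwise_shared_fraction = shared)
}

#' Incidence-based sample coverage
#'
#' Estimated fraction of the community's total incidence probability
#' accounted for by the species detected in T sampling units (sites):
#' \deqn{\hat C = 1 - \frac{Q_1}{U}\,\frac{(T-1)Q_1}{(T-1)Q_1 + 2Q_2}}
#' where U is the total incidence count and Q1/Q2 the numbers of species
#' found in exactly one/two units. Coverage 1 means no undetected species
#' mass remains.
#'
#' @param incidence binary matrix, sampling units (sites) x species, for one
#'   method.
#' @return An object of class `coverage_estimate`: `T`, `S_obs`, `Q1`, `Q2`,
#'   `U`, `coverage` (NA when U = 0).
#' @export
sample_coverage <- function(incidence) {
  stopifnot(is.matrix(incidence), nrow(incidence) >= 2L,
            all(incidence %in% c(0L, 1L)))
  Tn <- nrow(incidence)
  Y <- colSums(incidence)
  U <- sum(Y)
  Q1 <- sum(Y == 1L); Q2 <- sum(Y == 2L)
  cov <- if (U == 0L) {
    NA_real_
  } else if (Q1 == 0L) {
    1
  } else {
    1 - (Q1 / U) * ((Tn - 1) * Q1 / ((Tn - 1) * Q1 + 2 * Q2))
  }
  structure(list(T = Tn, S_obs = sum(Y > 0L), Q1 = Q1, Q2 = Q2, U = U,
                 coverage = cov),
            class = "coverage_estimate")
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf("coverage: %.4f (T = %d units, S_obs = %d, Q1 = %d, Q2 = %d, U = %d)\n",
              x$coverage, x$T, x$S_obs, x$Q1, x$Q2, x$U))
  invisible(x)
}

#' Incidence-based rarefaction and extrapolation of species richness
#'
#' Richness (Hill number q = 0) expected in t sampling units. For t <= T the
#' combinatorial rarefaction expectation
#' \deqn{S(t) = S_{obs} - \sum_i \binom{T - Y_i}{t} / \binom{T}{t}}
#' is used; for t > T richness is extrapolated toward the Chao2 asymptote
#' `S_obs + ((T-1)/T) Q1^2 / (2 Q2)` (bias-corrected
#' `Q1 (Q1 - 1) / (2 (Q2 + 1))` when Q2 = 0). Sample coverage is reported
#' along the same curve, so the number of units needed to reach a target
#' coverage can be read off — e.g. how many more sites a net or camera
#' survey would need to match an eDNA survey's coverage.
#'
#' @param incidence binary units x species matrix for one method.
#' @param t_values sampling-unit counts to evaluate (default 1..2T).
#' @return An object of class `rarefaction_curve`: data.frame `t`,
#'   `richness`, `coverage`, plus `S_obs`, `T` and `chao2` (the asymptote).
#' @export
rarefy_extrapolate_richness <- function(incidence, t_values = NULL) {
  stopifnot(is.matrix(incidence), nrow(incidence) >= 2L,
            all(incidence %in% c(0L, 1L)))
  Tn <- nrow(incidence)
  if (is.null(t_values)) t_values <- seq_len(2L * Tn)
  if (any(t_values < 1L)) stop("target units must be >= 1", call. = FALSE)
  Y <- colSums(incidence); Y <- Y[Y > 0L]
  S_obs <- length(Y)
  U <- sum(Y)
  Q1 <- sum(Y == 1L); Q2 <- sum(Y == 2L)
  chao2 <- if (Q2 > 0L) {
    S_obs + ((Tn - 1) / Tn) * Q1^2 / (2 * Q2)
  } else {
    S_obs + ((Tn - 1) / Tn) * Q1 * (Q1 - 1) / (2 * (Q2 + 1))
  }
  Q0_hat <- chao2 - S_obs
  cov_ref <- sample_coverage(incidence[, colSums(incidence) > 0L, drop = FALSE])$coverage
  # reference-sample deficiency ratio reused by the coverage extrapolation
  defic <- if (Q1 == 0L) 0 else (Tn - 1) * Q1 / ((Tn - 1) * Q1 + 2 * Q2)
  richness <- vapply(t_values, function(t) {
    if (t <= Tn) {
      S_obs - sum(exp(lchoose(Tn - Y, t) - lchoose(Tn, t)))
    } else if (Q0_hat == 0) {
      S_obs
    } else {
      S_obs + Q0_hat * (1 - (1 - Q1 / (Q1 + Tn * Q0_hat))^(t - Tn))
    }
  }, 1)
  coverage <- vapply(t_values, function(t) {
    if (U == 0L) return(NA_real_)
    if (t < Tn) {
      1 - sum(Y / U * exp(lchoose(Tn - Y, t) - lchoose(Tn - 1, t)))
    } else {
      1 - (Q1 / U) * defic^(t - Tn + 1)
    }
  }, 1)
  structure(list(curve = data.frame(t = t_values, richness = richness,
                                    coverage = coverage),
                 S_obs = S_obs, T = Tn, chao2 = chao2),
            class = "rarefaction_curve")
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf("rarefaction_curve: S_obs = %d at T = %d units; Chao2 asymptote %.2f\n",
              x$S_obs, x$T, x$chao2))
  invisible(x)
}
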