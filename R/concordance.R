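#' Per-site mean abundance values
#'
#' Site-level summaries used by the cross-method regressions: the arithmetic
#' mean over a site's replicates — catch per seine haul, MaxN per BRUV
#' deployment, or eDNA index per PCR replicate.
#'
#' @param x long-format survey records (`site, method, replicate, species,
#'   value`) or an eDNA index matrix from [compute_edna_index()].
#' @param method for survey records, which method to summarize.
#' @return data.frame `species, site, mean_value`.
#' @export
site_means <- function(x, method = NULL) {
  if (is.matrix(x)) {
    keys <- attr(x, "keys")
    stopifnot(!is.null(keys))
    out <- do.call(rbind, lapply(unique(keys$site), function(s) {
      cols <- which(keys$site == s)
      data.frame(species = rownames(x), site = s,
                 mean_value = rowMeans(x[, cols, drop = FALSE]),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(is.data.frame(x))
  if (!is.null(method)) x <- x[x$method == method, ]
  agg <- stats::aggregate(value ~ species + site, data = x, FUN = mean)
  names(agg)[names(agg) == "value"] <- "mean_value"
  agg[order(agg$species, agg$site), c("species", "site", "mean_value")]
}

#' Pair site means of two methods for jointly-detected species
#'
#' Retains species detected by both methods (nonzero site mean) at
#' `min_sites` or more common sites; the paired series are aligned on those
#' jointly-nonzero sites. Species failing the rule are reported in the
#' `skipped` attribute.
#'
#' @param x_means,y_means data.frames from [site_means()].
#' @param min_sites minimum number of jointly-nonzero sites (default 3).
#' @return Named list of data.frames `site, x, y`, one per retained species.
#' @export
joint_detection_pairs <- function(x_means, y_means, min_sites = 3L) {
  stopifnot(min_sites >= 2L)
  species <- intersect(unique(x_means$species), unique(y_means$species))
  out <- list(); skipped <- character(0)
  for (sp in species) {
    xs <- x_means[x_means$species == sp, ]
    ys <- y_means[y_means$species == sp, ]
    sites <- intersect(xs$site, ys$site)
    xv <- xs$mean_value[match(sites, xs$site)]
    yv <- ys$mean_value[match(sites, ys$site)]
    joint <- xv > 0 & yv > 0
    if (sum(joint) >= min_sites) {
      out[[sp]] <- data.frame(site = sites[joint], x = xv[joint],
                              y = yv[joint], stringsAsFactors = FALSE)
    } else {
      skipped <- c(skipped, sp)
    }
  }
  structure(out, skipped = skipped)
}

#' Species-specific OLS regression between two methods
#'
#' Ordinary least squares of y on x over the paired sites of one species,
#' with R-squared and the two-sided t-test p-value for the slope. R-squared
#' is direction-invariant; slope and p are labelled with the modelled
#' direction.
#'
#' @param pairs data.frame `site, x, y` (one species), >= 3 rows.
#' @param species species label carried into the result.
#' @param xlab,ylab labels for the predictor and response.
#' @return One-row data.frame `species, response, predictor, n, slope,
#'   intercept, r_squared, p_value`. Zero variance in x yields NA slope/p
#'   with a warning.
#' @export
species_ols_regression <- function(pairs, species = NA_character_,
                                   xlab = "x", ylab = "y") {
  stopifnot(nrow(pairs) >= 3L)
  if (stats::var(pairs$x) == 0) {
    warning("zero variance in predictor; slope undefined", call. = FALSE)
    return(data.frame(species = species, response = ylab, predictor = xlab,
                      n = nrow(pairs), slope = NA_real_, intercept = NA_real_,
                      r_squared = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE))
  }
  fit <- stats::lm(y ~ x, data = pairs)
  s <- summary(fit)
  if (stats::var(pairs$y) == 0) {
    # a constant response has no explainable variance
    s$r.squared <- 0
    p <- NA_real_
  } else {
    p <- s$coefficients["x", "Pr(>|t|)"]
  }
  data.frame(species = species, response = ylab, predictor = xlab,
             n = nrow(pairs), slope = stats::coef(fit)[["x"]],
             intercept = stats::coef(fit)[["(Intercept)"]],
             r_squared = s$r.squared, p_value = p, stringsAsFactors = FALSE)
}

#' Cross-method abundance concordance for all shared species
#'
#' Runs [joint_detection_pairs()] and [species_ols_regression()] in both
#' directions for every species two methods detect jointly at `min_sites`
#' or more sites.
#'
#' @param x_means,y_means data.frames from [site_means()].
#' @param xlab,ylab method labels.
#' @param min_sites minimum jointly-detected sites (default 3).
#' @return data.frame of regression rows (two per species, one per
#'   direction); skipped species in the `skipped` attribute.
#' @export
abundance_concordance <- function(x_means, y_means, xlab, ylab,
                                  min_sites = 3L) {
  pairs <- joint_detection_pairs(x_means, y_means, min_sites)
  rows <- lapply(names(pairs), function(sp) {
    fwd <- species_ols_regression(pairs[[sp]], sp, xlab, ylab)
    rev_ <- species_ols_regression(
      data.frame(site = pairs[[sp]]$site, x = pairs[[sp]]$y,
                 y = pairs[[sp]]$x, stringsAsFactors = FALSE),
      sp, ylab, xlab)
    rbind(fwd, rev_)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), response = character(0),
               predictor = character(0), n = integer(0), slope = numeric(0),
               intercept = numeric(0), r_squared = numeric(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  structure(out, skipped = attr(pairs, "skipped"))
}
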