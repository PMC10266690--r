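#' Posterior probability that a species occupies a site
#'
#' Bayes' rule applied to a site's detection history under the
#' false-positive occupancy model: given occupancy probability psi, a
#' per-replicate true-positive rate p11 and false-positive rate p10, and N
#' detections out of K replicate surveys,
#' \deqn{P(occ) = \frac{\psi\, p_{11}^N (1-p_{11})^{K-N}}
#'   {\psi\, p_{11}^N (1-p_{11})^{K-N} + (1-\psi)\, p_{10}^N (1-p_{10})^{K-N}}}
#' Evaluated in log space for numerical stability; all arguments are
#' vectorized.
#'
#' @param psi occupancy probability (the species' commonness across sites).
#' @param p11 per-replicate detection probability given true presence.
#' @param p10 per-replicate detection probability given true absence.
#' @param K number of replicate surveys at the site.
#' @param N number of surveys with a detection, `0 <= N <= K`.
#' @return Probability of occurrence in `[0, 1]`.
#' @examples
#' probability_of_occurrence(0.5, 0.8, 0.05, K = 3, N = 2)
#' @export
probability_of_occurrence <- function(psi, p11, p10, K, N) {
  n <- max(length(psi), length(p11), length(p10), length(K), length(N))
  psi <- rep_len(psi, n); p11 <- rep_len(p11, n); p10 <- rep_len(p10, n)
  K <- rep_len(K, n); N <- rep_len(N, n)
  if (any(N > K | N < 0)) stop("N must satisfy 0 <= N <= K", call. = FALSE)
  if (any(psi < 0 | psi > 1 | p11 < 0 | p11 > 1 | p10 < 0 | p10 > 1)) {
    stop("psi, p11, p10 must lie in [0, 1]", call. = FALSE)
  }
  # dbinom(log=TRUE) handles the p = 0/1 corners exactly
  la <- log(psi) + stats::dbinom(N, K, p11, log = TRUE)
  lb <- log1p(-psi) + stats::dbinom(N, K, p10, log = TRUE)
  out <- 1 / (1 + exp(lb - la))
  out[psi == 0] <- 0
  out[psi == 1] <- 1
  # a detection is definitive when false positives are impossible
  out[is.infinite(lb) & is.finite(la)] <- 1
  out[is.infinite(la) & is.finite(lb)] <- 0
  out
}

#' Method sensitivity from replicate detection rates
#'
#' The proportion of positive replicate detections that are true positives:
#' `p11 / (p11 + p10)`.
#'
#' @param p11,p10 true-/false-positive per-replicate detection rates.
#' @return Value in `[0, 1]`; `NA` with a warning when `p11 = p10 = 0`.
#' @export
sensitivity <- function(p11, p10) {
  n <- max(length(p11), length(p10))
  p11 <- rep_len(p11, n); p10 <- rep_len(p10, n)
  out <- p11 / (p11 + p10)
  if (any(p11 + p10 == 0)) {
    warning("sensitivity undefined when p11 = p10 = 0", call. = FALSE)
    out[p11 + p10 == 0] <- NA_real_
  }
  out
}

#' Method specificity from replicate detection rates
#'
#' The proportion of negative replicate outcomes that are true negatives:
#' `(1 - p10) / ((1 - p10) + (1 - p11))`.
#'
#' @param p11,p10 true-/false-positive per-replicate detection rates.
#' @return Value in `[0, 1]`; `NA` with a warning when `p11 = p10 = 1`.
#' @export
specificity <- function(p11, p10) {
  n <- max(length(p11), length(p10))
  p11 <- rep_len(p11, n); p10 <- rep_len(p10, n)
  denom <- (1 - p10) + (1 - p11)
  out <- (1 - p10) / denom
  if (any(denom == 0)) {
    warning("specificity undefined when p11 = p10 = 1", call. = FALSE)
    out[denom == 0] <- NA_real_
  }
  out
}

# Log posterior kernel for one species x method. Histories are collapsed to
# unique (K, N) cells with weights, so one evaluation is O(#cells) however
# many sites there are. Priors: psi, p11 ~ Beta(1,1); p10 ~ Beta(1,10),
# truncated to p10 < p11 (resolves the mixture's label switching).
occu_log_post <- function(psi, p11, p10, cells, p10_beta = c(1, 10)) {
  if (p10 >= p11) return(-Inf)
  ll <- sum(cells$w * log_mix_lik(psi, p11, p10, cells$K, cells$N))
  ll + stats::dbeta(p10, p10_beta[1L], p10_beta[2L], log = TRUE)
}

log_mix_lik <- function(psi, p11, p10, K, N) {
  la <- log(psi) + stats::dbinom(N, K, p11, log = TRUE)
  lb <- log1p(-psi) + stats::dbinom(N, K, p10, log = TRUE)
  m <- pmax(la, lb)
  m[is.infinite(m)] <- 0
  m + log(exp(la - m) + exp(lb - m))
}

logit <- function(p) log(p) - log1p(-p)
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Fit the site-occupancy model with false positives
#'
#' Bayesian fit of the three-parameter model for one species and survey
#' method: each site is occupied with probability psi; given occupancy the
#' detection count is N ~ Binomial(K, p11), otherwise N ~ Binomial(K, p10).
#' The latent occupancy states are marginalized analytically (mixture
#' likelihood), and (psi, p11, p10) are sampled on the logit scale by an
#' adaptive component-wise random-walk Metropolis sampler with the ordering
#' constraint p10 < p11. Convergence is monitored with the split-chain
#' potential scale reduction factor and effective sample size.
#'
#' @param histories data.frame with columns `site`, `N`, `K` (one species x
#'   method; extra columns `species`/`method` are carried into the output).
#' @param chains number of MCMC chains (default 4).
#' @param iter iterations per chain including warmup (default 2000).
#' @param warmup adaptation iterations discarded per chain (default 1000).
#' @param p10_beta shape parameters of the Beta prior on p10
#'   (default `c(1, 10)`: false positives are rare a priori).
#' @param seed RNG seed; the same seed reproduces the fit exactly.
#' @return An object of class `occupancy_fit`: posterior draws, a `summary`
#'   data.frame (mean, median, 2.5/97.5 percentiles for psi, p11, p10,
#'   sensitivity, specificity), per-site probability of occurrence
#'   (`site_occurrence`), diagnostics (`rhat`, `ess`, `converged`) and the
#'   seed. Non-convergence (any split-chain Rhat > 1.05) is flagged, never
#'   silently accepted.
#' @export
estimate_occupancy <- function(histories, chains = 4L, iter = 2000L,
                               warmup = 1000L, p10_beta = c(1, 10),
                               seed = 1L) {
  stopifnot(is.data.frame(histories), all(c("N", "K") %in% names(histories)),
            nrow(histories) >= 1L, chains >= 1L, warmup >= 1L, iter > warmup)
  if (any(histories$N > histories$K | histories$K < 1L)) {
    stop("histories must satisfy 0 <= N <= K, K >= 1", call. = FALSE)
  }
  if (all(histories$N == 0L)) {
    stop("species was never detected; undetected species are excluded upstream",
         call. = FALSE)
  }
  cells <- stats::aggregate(w ~ K + N,
                            data = cbind(histories[c("K", "N")], w = 1),
                            FUN = sum)
  set.seed(seed)
  keep <- iter - warmup
  draws <- matrix(NA_real_, chains * keep, 3L,
                  dimnames = list(NULL, c("psi", "p11", "p10")))
  chain_id <- rep(seq_len(chains), each = keep)

  for (ch in seq_len(chains)) {
    # dispersed starts respecting p10 < p11
    p11_0 <- stats::runif(1L, 0.4, 0.95)
    theta <- c(stats::runif(1L, 0.2, 0.8), p11_0, stats::runif(1L, 0.01, p11_0 / 2))
    eta <- logit(theta)
    lp <- occu_log_post(theta[1L], theta[2L], theta[3L], cells, p10_beta) +
      sum(log(theta) + log1p(-theta))  # logit Jacobian
    scales <- rep(1, 3L)
    acc <- rep(0, 3L); tries <- rep(0, 3L)
    for (it in seq_len(iter)) {
      for (j in 1:3) {
        eta_p <- eta
        eta_p[j] <- eta[j] + stats::rnorm(1L, 0, scales[j])
        th <- inv_logit(eta_p)
        lp_p <- occu_log_post(th[1L], th[2L], th[3L], cells, p10_beta) +
          sum(log(th) + log1p(-th))
        tries[j] <- tries[j] + 1
        if (is.finite(lp_p) && log(stats::runif(1L)) < lp_p - lp) {
          eta <- eta_p; lp <- lp_p
          acc[j] <- acc[j] + 1
        }
      }
      if (it <= warmup && it %% 50L == 0L) {
        rate <- acc / pmax(tries, 1)
        scales <- scales * exp((rate - 0.35))  # adapt toward ~35% acceptance
        scales <- pmin(pmax(scales, 0.05), 10)
        acc[] <- 0; tries[] <- 0
      }
      if (it > warmup) draws[(ch - 1L) * keep + (it - warmup), ] <- inv_logit(eta)
    }
  }

  rhat <- apply(draws, 2L, split_rhat, chain_id = chain_id)
  ess <- apply(draws, 2L, ess_basic, chain_id = chain_id)
  sens <- sensitivity(draws[, "p11"], draws[, "p10"])
  spec <- specificity(draws[, "p11"], draws[, "p10"])
  all_draws <- cbind(draws, sensitivity = sens, specificity = spec)
  qs <- function(v) c(mean = mean(v), median = stats::median(v),
                      q2.5 = unname(stats::quantile(v, 0.025)),
                      q97.5 = unname(stats::quantile(v, 0.975)))
  summ <- as.data.frame(t(apply(all_draws, 2L, qs)))
  summ <- cbind(parameter = rownames(summ), summ,
                rhat = c(rhat, NA, NA), ess = c(ess, NA, NA))
  rownames(summ) <- NULL

  occ <- t(vapply(seq_len(nrow(histories)), function(i) {
    po <- probability_of_occurrence(draws[, "psi"], draws[, "p11"],
                                    draws[, "p10"], histories$K[i],
                                    histories$N[i])
    qs(po)
  }, numeric(4L)))
  site_occurrence <- data.frame(
    site = if ("site" %in% names(histories)) histories$site else seq_len(nrow(histories)),
    N = histories$N, K = histories$K, occ, stringsAsFactors = FALSE)

  structure(list(
    species = if ("species" %in% names(histories)) histories$species[1L] else NA_character_,
    method = if ("method" %in% names(histories)) histories$method[1L] else NA_character_,
    draws = all_draws, summary = summ, site_occurrence = site_occurrence,
    rhat = rhat, ess = ess, converged = all(rhat < 1.05),
    chains = chains, iter = iter, warmup = warmup, seed = as.integer(seed)),
    class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, digits = 3L, ...) {
  cat(sprintf("occupancy_fit: %s / %s (%d chains x %d draws)%s\n",
              x$species, x$method, x$chains, nrow(x$draws) / x$chains,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  print(cbind(x$summary[1L], round(x$summary[-1L], digits)), row.names = FALSE)
  invisible(x)
}

# Split-chain potential scale reduction (each chain halved, standard
# between/within variance ratio).
split_rhat <- function(x, chain_id) {
  halves <- lapply(split(x, chain_id), function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[h + seq_len(h)])
  })
  sub <- unlist(halves, recursive = FALSE)
  m <- length(sub); n <- length(sub[[1L]])
  means <- vapply(sub, mean, 1); vars <- vapply(sub, stats::var, 1)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size from pooled-chain autocorrelations (initial positive
# sequence estimator).
ess_basic <- function(x, chain_id) {
  chains <- split(x, chain_id)
  n <- length(chains[[1L]])
  acf_sum <- 0
  max_lag <- min(n - 1L, 200L)
  rho <- rowMeans(vapply(chains, function(v) {
    a <- stats::acf(v, lag.max = max_lag, plot = FALSE)$acf[-1L]
    as.numeric(a)
  }, numeric(max_lag)))
  for (k in seq_along(rho)) {
    if (rho[k] < 0) break
    acf_sum <- acf_sum + rho[k]
  }
  length(x) / (1 + 2 * acf_sum)
}

#' Fit the occupancy model for every species x method
#'
#' Loops [estimate_occupancy()] over all (species, method) pairs present in
#' a detection-history table, skipping species never detected by a method.
#'
#' @param histories data.frame with columns `species, method, site, N, K`.
#' @param seed base seed; each fit uses a distinct seed derived from it.
#' @param ... passed to [estimate_occupancy()].
#' @return An object of class `occupancy_fit_set`: list of fits plus a tidy
#'   `summary` data.frame (one row per species x method with posterior means
#'   and 95% intervals for psi, p11, p10, sensitivity, specificity, the mean
#'   per-site probability of occurrence, and diagnostics).
#' @export
fit_occupancy_all <- function(histories, seed = 1L, ...) {
  pairs <- unique(histories[c("species", "method")])
  fits <- list(); rows <- list()
  for (i in seq_len(nrow(pairs))) {
    h <- histories[histories$species == pairs$species[i] &
                     histories$method == pairs$method[i], ]
    if (all(h$N == 0L)) next
    fit <- estimate_occupancy(h, seed = seed + i, ...)
    fits[[length(fits) + 1L]] <- fit
    s <- fit$summary
    grab <- function(p, col) s[s$parameter == p, col]
    rows[[length(rows) + 1L]] <- data.frame(
      species = pairs$species[i], method = pairs$method[i],
      psi = grab("psi", "mean"), psi_lo = grab("psi", "q2.5"),
      psi_hi = grab("psi", "q97.5"),
      p11 = grab("p11", "mean"), p10 = grab("p10", "mean"),
      sensitivity = grab("sensitivity", "mean"),
      specificity = grab("specificity", "mean"),
      mean_occupancy = mean(fit$site_occurrence$mean),
      max_rhat = max(fit$rhat), min_ess = min(fit$ess),
      converged = fit$converged, stringsAsFactors = FALSE)
  }
  structure(list(fits = fits, summary = do.call(rbind, rows)),
            class = "occupancy_fit_set")
}

#' @export
print.occupancy_fit_set <- function(x, ...) {
  cat(sprintf("occupancy_fit_set: %d fits (%d not converged)\n",
              length(x$fits), sum(!x$summary$converged)))
  invisible(x)
}

#' @export
summary.occupancy_fit_set <- function(object, ...) object$summary

#' Compare occupancy-derived metrics between survey methods
#'
#' Treats each species' posterior-mean metric as one observation and tests
#' for method differences in mean probability of occupancy, sensitivity, and
#' specificity with a one-way ANOVA plus Tukey HSD pairwise comparisons.
#'
#' @param fit_summary the `summary` data.frame of an `occupancy_fit_set`
#'   (or any data.frame with columns `species, method` and the metrics).
#' @param metrics columns to compare.
#' @return An object of class `method_metric_summary`: per metric the
#'   per-method means, ANOVA F and p, and the Tukey pairwise table.
#' @export
compare_method_metrics <- function(fit_summary,
                                   metrics = c("mean_occupancy", "sensitivity",
                                               "specificity")) {
  if (inherits(fit_summary, "occupancy_fit_set")) fit_summary <- fit_summary$summary
  keep <- names(which(table(fit_summary$method) >= 2L))
  dropped <- setdiff(unique(fit_summary$method), keep)
  if (length(dropped)) {
    warning("methods with < 2 species excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 2L) stop("need >= 2 methods with >= 2 species each",
                              call. = FALSE)
  df <- fit_summary[fit_summary$method %in% keep, ]
  df$method <- factor(df$method)
  out <- lapply(metrics, function(metric) {
    vals <- df[[metric]]
    fit <- stats::aov(vals ~ method, data = df)
    tab <- summary(fit)[[1L]]
    tukey <- as.data.frame(stats::TukeyHSD(fit)$method)
    tukey <- cbind(comparison = rownames(tukey), tukey)
    rownames(tukey) <- NULL
    list(metric = metric,
         means = tapply(vals, df$method, mean),
         F = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L],
         df = c(tab[["Df"]][1L], tab[["Df"]][2L]),
         tukey = tukey)
  })
  names(out) <- metrics
  structure(out, class = "method_metric_summary")
}

#' @export
print.method_metric_summary <- function(x, digits = 3L, ...) {
  for (m in x) {
    cat(sprintf("%s: F(%d,%d) = %.3g, p = %.3g\n", m$metric,
                m$df[1L], m$df[2L], m$F, m$p))
    print(round(m$means, digits))
  }
  invisible(x)
}
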