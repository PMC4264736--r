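# XCI ratio estimation. Phased allelic ratios are fitted per parental group
# to a beta distribution by maximum likelihood (the beta's two shape
# parameters absorb the over-dispersion of RNA-seq read counts relative to a
# binomial). Unphased ratios are fitted with a two-component semiparametric
# location-shift mixture via a stochastic EM (see sp_mixture.R). Estimates
# are reported on the percentage scale: maternal mean 82.7% and paternal
# 20.3% read "82.7:20.3" — the two need not sum to 100 because each is the
# mean of its own ratio distribution.

#' Fit a beta distribution to allelic ratios by maximum likelihood
#'
#' Boundary ratios (exactly 0 or 1, common under complete skewing) have zero
#' beta likelihood; each observation is first clamped into
#' `[1/(2 d), 1 - 1/(2 d)]` at its own depth `d`, a depth-aware shrinkage
#' that vanishes as coverage grows. The MLE is found numerically from a
#' method-of-moments start (via [MASS::fitdistr()]); a degenerate sample
#' (all values equal) falls back to the method-of-moments fit with a
#' warning.
#'
#' @param ratios Numeric allelic ratios in \[0, 1\].
#' @param depths Optional per-observation read depths for the boundary
#'   clamp; without them a fixed clamp of `boundary_eps` is used.
#' @param boundary_eps Fallback clamp width when `depths` is absent.
#' @return An object of class `beta_fit`: `alpha`, `beta`, `mean`
#'   (`alpha/(alpha+beta)`), `sd` (the fitted distribution's standard
#'   deviation), `n`, `loglik`, `method` (`"mle"` or `"moments"`).
#' @export
fit_beta <- function(ratios, depths = NULL, boundary_eps = 1e-3) {
  x <- ratios[!is.na(ratios)]
  if (length(x) < 3L) stopf("need at least 3 ratios to fit a beta distribution, got %d", length(x))
  lo <- if (!is.null(depths)) 1 / (2 * depths[!is.na(ratios)]) else rep(boundary_eps, length(x))
  x <- pmin(pmax(x, lo), 1 - lo)

  m <- mean(x); v <- var(x)
  v <- max(v, 1e-8)
  if (v >= m * (1 - m)) v <- 0.99 * m * (1 - m)    # MoM needs v < m(1-m)
  k <- m * (1 - m) / v - 1
  start <- list(shape1 = max(m * k, 1e-3), shape2 = max((1 - m) * k, 1e-3))

  fit <- tryCatch(
    MASS::fitdistr(x, "beta", start = start, lower = c(1e-8, 1e-8)),
    error = function(e) NULL)
  if (is.null(fit) || var(x) < 1e-10) {
    if (var(x) < 1e-10)
      warnf("degenerate ratios (all equal); returning method-of-moments fit")
    a <- start$shape1; b <- start$shape2
    ll <- sum(dbeta(x, a, b, log = TRUE))
    method <- "moments"
  } else {
    a <- unname(fit$estimate["shape1"]); b <- unname(fit$estimate["shape2"])
    ll <- fit$loglik
    method <- "mle"
  }
  structure(list(alpha = a, beta = b, mean = a / (a + b),
                 sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))),
                 n = length(x), loglik = ll, method = method),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf("beta_fit (%s): alpha=%.3f beta=%.3f mean=%.4f sd=%.4f n=%d\n",
              x$method, x$alpha, x$beta, x$mean, x$sd, x$n))
  invisible(x)
}

xci_estimate <- function(maternal_pct, paternal_pct, maternal_sd, paternal_sd,
                         n_maternal, n_paternal, method, seed = NA_integer_,
                         labels = c("maternal", "paternal")) {
  # sampling noise at random XCI can push both means a hair under 50
  major <- min(max(maternal_pct, paternal_pct, 50, na.rm = TRUE), 100)
  structure(list(maternal_pct = maternal_pct, paternal_pct = paternal_pct,
                 maternal_sd = maternal_sd, paternal_sd = paternal_sd,
                 n_maternal = n_maternal, n_paternal = n_paternal,
                 method = method, seed = seed, labels = labels,
                 skew_class = classify_skew(major)),
            class = "xci_estimate")
}

#' @export
print.xci_estimate <- function(x, ...) {
  lab <- if (identical(x$labels, c("maternal", "paternal")))
    "maternal:paternal" else "component1:component2"
  cat(sprintf("XCI estimate (%s): %.1f:%.1f  [%s, %s]\n", x$method,
              x$maternal_pct, x$paternal_pct, lab, x$skew_class))
  invisible(x)
}

#' Estimate the XCI ratio from phased allelic ratios
#'
#' Fits a beta distribution to each parental group's variant-allele ratios
#' and reports 100x the fitted means: e.g. a maternal-group mean of 0.65 and
#' a paternal-group mean of 0.35 is a 65:35 XCI ratio favouring the maternal
#' X. Standard deviations are the fitted beta SDs on the percentage scale;
#' the empirical SDs of the raw ratios are attached as
#' `empirical_maternal_sd`/`empirical_paternal_sd`.
#'
#' @param obs Allelic observations with columns `ratio`, `depth` and `phase`
#'   in `{"maternal", "paternal"}` (e.g. from [simulate_counts()] or
#'   [phase_trio_sites()] joined to counts).
#' @return An `xci_estimate` with `method = "beta_phased"`; one empty phase
#'   group yields a one-sided estimate with a warning.
#' @export
xci_from_phased <- function(obs) {
  m <- obs[obs$phase == "maternal", , drop = FALSE]
  p <- obs[obs$phase == "paternal", , drop = FALSE]
  if (nrow(m) == 0L && nrow(p) == 0L) stopf("no phased observations")
  fit1 <- if (nrow(m) >= 3L) fit_beta(m$ratio, m$depth) else NULL
  fit2 <- if (nrow(p) >= 3L) fit_beta(p$ratio, p$depth) else NULL
  if (is.null(fit1) || is.null(fit2))
    warnf("one phase group is empty or too small; returning a one-sided estimate")
  est <- xci_estimate(
    maternal_pct = if (!is.null(fit1)) 100 * fit1$mean else NA_real_,
    paternal_pct = if (!is.null(fit2)) 100 * fit2$mean else NA_real_,
    maternal_sd = if (!is.null(fit1)) 100 * fit1$sd else NA_real_,
    paternal_sd = if (!is.null(fit2)) 100 * fit2$sd else NA_real_,
    n_maternal = nrow(m), n_paternal = nrow(p), method = "beta_phased")
  est$empirical_maternal_sd <- if (nrow(m) > 1L) 100 * sd(m$ratio) else NA_real_
  est$empirical_paternal_sd <- if (nrow(p) > 1L) 100 * sd(p$ratio) else NA_real_
  est$fits <- list(maternal = fit1, paternal = fit2)
  est
}

#' Estimate the XCI ratio from unphased allelic ratios
#'
#' Fits the two-component semiparametric mixture ([sp_mixture_fit()]) to the
#' pooled, unphased variant-allele ratios and reports 100x the component
#' location estimates, sorted descending. The components are deliberately
#' unlabeled with respect to parental origin — without transmission
#' information the method sees only two expression modes.
#'
#' @param ratios Unphased allelic ratios in \[0, 1\].
#' @param seed RNG seed for the stochastic EM.
#' @param ... Passed to [sp_mixture_fit()].
#' @return An `xci_estimate` with `method = "sp_unphased"` and labels
#'   `component1`/`component2`.
#' @export
xci_from_unphased <- function(ratios, seed = 1L, ...) {
  fit <- sp_mixture_fit(ratios, seed = seed, ...)
  est <- xci_estimate(
    maternal_pct = 100 * fit$component_means[1L],
    paternal_pct = 100 * fit$component_means[2L],
    maternal_sd = NA_real_, paternal_sd = NA_real_,
    n_maternal = length(ratios), n_paternal = length(ratios),
    method = "sp_unphased", seed = seed,
    labels = c("component1", "component2"))
  est$fit <- fit
  est
}

#' Classify the degree of XCI skewing
#'
#' Categories follow the named panel ratios — complete (100:0), extreme
#' (95:5, 90:10), moderate (85:15, 80:20) and random (75:25 and below) —
#' with cutoffs at the midpoints between named ratios: `>= 97.5` complete,
#' `[87.5, 97.5)` extreme, `[77.5, 87.5)` moderate, `< 77.5` random.
#'
#' @param major_pct The larger of the two estimated percentages, in
#'   \[50, 100\].
#' @return One of `"complete"`, `"extreme"`, `"moderate"`, `"random"`.
#' @export
classify_skew <- function(major_pct) {
  if (is.na(major_pct)) return(NA_character_)
  if (major_pct < 50 - 1e-9 || major_pct > 100 + 1e-9)
    stopf("major percentage must lie in [50, 100], got %g", major_pct)
  if (major_pct >= 97.5) "complete"
  else if (major_pct >= 87.5) "extreme"
  else if (major_pct >= 77.5) "moderate"
  else "random"
}

#' Correlate observed and expected XCI ratios across a simulated panel
#'
#' For each minimum-depth threshold, filters every panel dataset, fits the
#' per-phase beta distributions, and computes the Pearson correlation of the
#' observed percentage means against the expected ones — separately for the
#' maternal and paternal series.
#'
#' @param panel Output of [run_ratio_panel()] (or a compatible list with
#'   `datasets` and `expected`).
#' @param min_depths Depth thresholds to evaluate.
#' @return A list with `means` (per dataset x depth: observed maternal and
#'   paternal percentages and SNP counts) and `correlations` (per depth:
#'   `r_maternal`, `r_paternal`).
#' @export
evaluate_concordance <- function(panel, min_depths = c(10, 20, 30, 40, 50)) {
  if (length(panel$datasets) < 3L) stopf("need at least 3 panel datasets")
  rows <- list()
  for (d in min_depths) {
    for (i in seq_along(panel$datasets)) {
      obs <- panel$datasets[[i]]
      obs <- obs[obs$depth >= d, , drop = FALSE]
      est <- suppressWarnings(xci_from_phased(obs))
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = names(panel$datasets)[i],
        expected_maternal = 100 * panel$expected[[i]],
        min_depth = d,
        maternal_pct = est$maternal_pct, paternal_pct = est$paternal_pct,
        n_maternal = est$n_maternal, n_paternal = est$n_paternal,
        stringsAsFactors = FALSE)
    }
  }
  means <- do.call(rbind, rows)
  correlations <- do.call(rbind, lapply(min_depths, function(d) {
    m <- means[means$min_depth == d, , drop = FALSE]
    data.frame(min_depth = d,
               r_maternal = cor(m$maternal_pct, m$expected_maternal),
               r_paternal = cor(m$paternal_pct, 100 - m$expected_maternal))
  }))
  list(means = means, correlations = correlations)
}
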