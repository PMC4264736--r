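# Semiparametric two-component location-shift mixture,
#   g(x) = lambda f(x - mu1) + (1 - lambda) f(x - mu2),
# with f an unknown symmetric density, fitted by a stochastic EM in the
# style of Bordes & Chauveau: the E-step draws a hard component assignment
# for every point from its current posterior, the M-step updates the
# component locations (component-wise means) and the mixing proportion, and
# f is re-estimated by a kernel density on the symmetrized, centered
# residuals. Parameter chains are averaged after burn-in, which tames the
# Monte-Carlo jitter the stochastic E-step injects; multiple random starts
# guard against poor initialization and the start with the best final
# pseudo-log-likelihood is kept.

# Evaluate the current kernel estimate of f at arbitrary points. f is the
# component noise density and is modeled as symmetric about 0 AND unimodal:
# symmetry is enforced by reflecting the residuals, unimodality by a
# decreasing rearrangement of the kernel density estimate over |u|. The
# unimodality constraint is what keeps the model identified when the mixing
# proportion is near 1/2 — an unconstrained f could itself be bimodal and
# absorb the two-component structure, collapsing the location estimates. A
# small-weight broad Gaussian is mixed in so that points far outside both
# components' support still prefer the nearer component instead of getting
# a coin-flip posterior.
kde_fun <- function(residuals, bandwidth, tail_weight = 0.02) {
  rs <- c(residuals, -residuals)              # enforce symmetry of f
  bw <- if (is.character(bandwidth)) stats::bw.nrd0(rs) else bandwidth
  bw <- max(bw, 1e-6)
  hi <- max(abs(rs)) + 4 * bw
  d <- stats::density(rs, bw = bw, n = 512, from = 0, to = hi)
  y <- sort(d$y, decreasing = TRUE)           # unimodal: decreasing in |u|
  y <- y / (sum(y) * diff(d$x[1:2]) * 2)      # renormalize the half-density
  broad_sd <- max(3 * stats::sd(rs), 0.1)
  function(u) {
    v <- approx(d$x, y, xout = abs(u), yleft = y[1L], yright = 0)$y
    (1 - tail_weight) * v + tail_weight * stats::dnorm(u, 0, broad_sd)
  }
}

#' Fit a two-component semiparametric mixture by stochastic EM
#'
#' Estimates the component locations and mixing proportion of
#' `lambda f(x - mu1) + (1 - lambda) f(x - mu2)` with unknown symmetric `f`
#' — no assumption of normality or of any parametric family, which suits
#' over-dispersed allelic-ratio distributions. Deterministic given `seed`.
#'
#' Notes for allelic-ratio data: with near-balanced mixing
#' (`lambda ~ 0.5`) and strongly overlapping components the model is only
#' weakly identified, so location estimates near 50:50 XCI carry more
#' uncertainty than the well-separated skewed cases.
#'
#' @param x Numeric sample (allelic ratios in \[0, 1\] in this package, but
#'   any location-shift mixture works).
#' @param seed RNG seed.
#' @param n_starts Random restarts; the best final pseudo-log-likelihood
#'   wins.
#' @param max_iter Stochastic-EM iterations per start.
#' @param burn_in Iterations discarded before chain averaging.
#' @param bandwidth_rule Kernel bandwidth for the density estimate of `f`:
#'   `"nrd0"` (Silverman) or a numeric bandwidth.
#' @return An object of class `sp_fit`: `component_means` (sorted
#'   descending), `mixing_prop` (weight of the first component),
#'   `n_iterations`, `converged`, `loglik`, `seed`, `bandwidth`.
#' @export
sp_mixture_fit <- function(x, seed = 1L, n_starts = 5L, max_iter = 200L,
                           burn_in = 50L, bandwidth_rule = "nrd0") {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 20L) warnf("semiparametric mixture fit with n = %d (< 20) is fragile", n)
  if (n < 4L) stopf("need at least 4 observations, got %d", n)

  run_start <- function(start_id) {
    # 2-means initialization with a per-start random perturbation of the
    # split point (k-means alone can seed every start identically)
    km <- tryCatch(stats::kmeans(x, centers = 2L, nstart = 3L),
                   error = function(e) NULL)
    pivot <- if (!is.null(km)) mean(km$centers) else median(x)
    pivot <- pivot + runif(1L, -0.25, 0.25) * sd(x)
    z <- as.integer(x >= pivot)
    if (sum(z) < 2L || sum(1L - z) < 2L) z <- as.integer(x >= median(x))
    if (sum(z) < 2L || sum(1L - z) < 2L) z <- rep_len(c(0L, 1L), n)
    mu1 <- mean(x[z == 1L]); mu2 <- mean(x[z == 0L]); lambda <- mean(z)

    chain <- matrix(NA_real_, max_iter, 3L)
    f <- NULL
    for (it in seq_len(max_iter)) {
      resid <- x - ifelse(z == 1L, mu1, mu2)
      f <- kde_fun(resid, bandwidth_rule)
      d1 <- lambda * f(x - mu1)
      d2 <- (1 - lambda) * f(x - mu2)
      post <- d1 / (d1 + d2)
      post[!is.finite(post)] <- 0.5
      z <- as.integer(runif(n) < post)
      # keep both components alive: a dead component would stall the chain
      if (sum(z) < 2L) z[order(post, decreasing = TRUE)[1:2]] <- 1L
      if (sum(1L - z) < 2L) z[order(post)[1:2]] <- 0L
      mu1 <- mean(x[z == 1L]); mu2 <- mean(x[z == 0L]); lambda <- mean(z)
      if (mu1 < mu2) {                       # label convention: mu1 >= mu2
        tmp <- mu1; mu1 <- mu2; mu2 <- tmp
        lambda <- 1 - lambda
        z <- 1L - z
      }
      chain[it, ] <- c(mu1, mu2, lambda)
    }
    keep <- chain[(burn_in + 1L):max_iter, , drop = FALSE]
    est <- colMeans(keep)
    # convergence heuristic: the post-burn-in chain should wander, not drift
    half <- nrow(keep) %/% 2L
    drift <- abs(colMeans(keep[seq_len(half), , drop = FALSE]) -
                 colMeans(keep[(half + 1L):nrow(keep), , drop = FALSE]))
    converged <- all(drift < 0.05)
    # pseudo-log-likelihood at the averaged parameters with the last f
    d1 <- est[3L] * f(x - est[1L]); d2 <- (1 - est[3L]) * f(x - est[2L])
    ll <- sum(log(pmax(d1 + d2, 1e-300)))
    list(mu = est[1:2], lambda = est[3L], loglik = ll, converged = converged)
  }

  best <- withr::with_seed(seed, {
    fits <- lapply(seq_len(n_starts), run_start)
    fits[[which.max(vapply(fits, `[[`, numeric(1L), "loglik"))]]
  })
  structure(list(component_means = best$mu, mixing_prop = best$lambda,
                 n_iterations = max_iter, converged = best$converged,
                 loglik = best$loglik, seed = seed,
                 bandwidth = bandwidth_rule),
            class = "sp_fit")
}

#' @export
print.sp_fit <- function(x, ...) {
  cat(sprintf("sp_fit: means = %.4f / %.4f  lambda = %.3f  (%s, %d iter)\n",
              x$component_means[1L], x$component_means[2L], x$mixing_prop,
              if (x$converged) "converged" else "not converged",
              x$n_iterations))
  invisible(x)
}
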