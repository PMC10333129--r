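#' Posterior mode via kernel density
#'
#' Gaussian KDE with Silverman bandwidth; the mode is the density-maximizing
#' point.
#'
#' @param x numeric draws.
#' @return a single number.
#' @export
posterior_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) == 1L) return(x[1L])
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Highest posterior density interval
#'
#' @param x numeric draws.
#' @param prob coverage probability (default 0.95).
#' @return length-2 numeric (lower, upper).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1L], x[n]))
  w <- x[(m + 1L):n] - x[1:(n - m)]
  i <- which.min(w)
  c(x[i], x[i + m])
}

#' MCMC-based two-sided P value against zero
#'
#' Twice the smaller tail proportion of draws relative to zero, with a
#' finite-sample correction, capped at 1.
#'
#' @param x numeric draws.
#' @return a number in (0, 1].
#' @export
pmcmc <- function(x) {
  n <- length(x)
  min(1, 2 * min(sum(x <= 0) + 1, sum(x >= 0) + 1) / (n + 1))
}

#' Summarize a vector of posterior draws
#' @param x numeric draws.
#' @param prob HPD coverage.
#' @return named numeric: mode, mean, lower, upper, pMCMC.
#' @export
summarize_draws <- function(x, prob = 0.95) {
  ci <- hpd_interval(x, prob)
  c(mode = posterior_mode(x), mean = mean(x), lower = ci[1L], upper = ci[2L],
    pMCMC = pmcmc(x))
}

#' Gelman-Rubin potential scale reduction factor and effective sample size
#'
#' PSRF compares between- and within-chain variance (values well above 1.1
#' indicate poor convergence); ESS uses the initial-positive-sequence
#' autocorrelation estimator. Cross-checked against the `coda`
#' implementations in the test suite.
#'
#' @param chains a list of numeric matrices (iterations x parameters), one
#'   per chain, with matching columns.
#' @return list with `psrf` (per parameter; `NA` with a single chain), `ess`
#'   (per parameter, summed over chains), `converged` (all PSRF <= 1.1), and
#'   `autocorr` (lag-1 autocorrelation per parameter, first chain).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- list(chains)
  chains <- lapply(chains, as.matrix)
  p <- ncol(chains[[1L]])
  nm <- colnames(chains[[1L]])
  ess1 <- function(x) {
    n <- length(x)
    v <- stats::var(x)
    if (v == 0) return(n)
    ac <- stats::acf(x, lag.max = min(n - 2L, 200L), plot = FALSE)$acf[-1L]
    s <- 0
    for (i in seq(1L, length(ac) - 1L, by = 2L)) {
      pair <- ac[i] + ac[i + 1L]
      if (is.na(pair) || pair < 0) break
      s <- s + pair
    }
    max(1, n / (1 + 2 * s))
  }
  ess <- vapply(seq_len(p), function(j)
    sum(vapply(chains, function(ch) ess1(ch[, j]), numeric(1))), numeric(1))
  autoc <- vapply(seq_len(p), function(j) {
    x <- chains[[1L]][, j]
    if (stats::var(x) == 0) 0 else stats::acf(x, lag.max = 1, plot = FALSE)$acf[2L]
  }, numeric(1))
  if (length(chains) < 2L) {
    psrf <- rep(NA_real_, p)
  } else {
    m <- length(chains)
    n <- min(vapply(chains, nrow, integer(1)))
    psrf <- vapply(seq_len(p), function(j) {
      draws <- vapply(chains, function(ch) ch[seq_len(n), j], numeric(n))
      W <- mean(apply(draws, 2L, stats::var))
      B <- n * stats::var(colMeans(draws))
      if (W == 0) return(1)
      sqrt(((n - 1) / n * W + B / n) / W)
    }, numeric(1))
  }
  names(psrf) <- names(ess) <- names(autoc) <- nm
  list(psrf = psrf, ess = ess,
       converged = if (all(is.na(psrf))) NA else all(psrf <= 1.1, na.rm = TRUE),
       autocorr = autoc)
}
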