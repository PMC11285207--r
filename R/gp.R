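# Generalized Poisson distribution (Consul's two-parameter form)
#
# P(X = k) = theta * (theta + k*lambda)^(k-1) * exp(-theta - k*lambda) / k!
#
# theta > 0 is the rate parameter; 0 <= lambda < 1 the dispersion parameter.
# Mean = theta / (1 - lambda); Var = theta / (1 - lambda)^3. lambda = 0 reduces
# to Poisson(theta). This is the null for post-IP read counts at a given input
# read level.

#' Generalized Poisson parameters
#'
#' @param theta rate parameter, > 0.
#' @param lam dispersion parameter in \code{[0, 1)}; 0 gives Poisson.
#' @return An object of class \code{gp_params}.
#' @export
gp_params <- function(theta, lam) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta <= 0)
    stop_param("theta must be a positive finite number")
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) ||
      lam < 0 || lam >= 1)
    stop_param("lam must be in [0, 1)")
  structure(list(theta = theta, lam = lam), class = "gp_params")
}

#' @export
print.gp_params <- function(x, ...) {
  cat(sprintf("generalized Poisson: theta = %.4g, lambda = %.4g (mean %.4g)\n",
              x$theta, x$lam, x$theta / (1 - x$lam)))
  invisible(x)
}

gp_log_pmf <- function(k, theta, lam) {
  # vectorised over k (and theta); guards k = 0 where (k-1)*log(theta) term
  # collapses to log(theta) + ... -> -theta
  log(theta) + (k - 1) * log(theta + k * lam) - theta - k * lam - lgamma(k + 1)
}

#' Generalized Poisson probability mass function
#'
#' @param k non-negative integer count (vectorised).
#' @param params a \code{\link{gp_params}} object.
#' @param log return log-probability.
#' @return numeric vector of probabilities.
#' @export
gp_pmf <- function(k, params, log = FALSE) {
  stopifnot(inherits(params, "gp_params"))
  if (any(k < 0) || any(k != floor(k))) stop_param("k must be >= 0 integer")
  lp <- gp_log_pmf(k, params$theta, params$lam)
  if (log) lp else exp(lp)
}

#' Generalized Poisson upper-tail probability P(X >= k)
#'
#' Computed by direct pmf summation of the complement (or of the tail when the
#' observed count sits far above the mean), floored at the smallest positive
#' double so downstream -log10 transforms stay finite.
#'
#' @inheritParams gp_pmf
#' @return P(X >= k), in (0, 1].
#' @export
gp_upper_tail <- function(k, params) {
  stopifnot(inherits(params, "gp_params"))
  vapply(k, function(ki) {
    if (ki <= 0) return(1)
    p <- 1 - sum(exp(gp_log_pmf(0:(ki - 1), params$theta, params$lam)))
    max(p, .Machine$double.xmin)
  }, numeric(1))
}

#' Draw generalized Poisson variates
#'
#' Uses the branching (Lagrangian Poisson) representation: the total progeny of
#' a Poisson(theta) number of ancestors each reproducing Poisson(lambda) is
#' GP(theta, lambda). Vectorised over \code{theta}.
#'
#' @param n number of draws (must match \code{length(theta)} when theta is a
#'   vector).
#' @param theta rate parameter(s), >= 0 (0 yields all-zero draws).
#' @param lam dispersion in \code{[0, 1)}.
#' @return integer vector of draws.
#' @export
rgenpois <- function(n, theta, lam) {
  if (lam < 0 || lam >= 1) stop_param("lam must be in [0, 1)")
  theta <- rep_len(theta, n)
  total <- alive <- rpois(n, theta)
  while (any(alive > 0L)) {
    idx <- which(alive > 0L)
    born <- rpois(length(idx), lam * alive[idx])
    alive <- integer(n)
    alive[idx] <- born
    total[idx] <- total[idx] + born
  }
  total
}

# moment estimates used to initialise the MLE
gp_moment_estimates <- function(x) {
  m <- mean(x); v <- stats::var(x)
  if (!is.finite(v) || v <= 0 || m <= 0) return(c(theta = max(m, 1e-6), lam = 0))
  lam <- 1 - sqrt(min(m / v, 1))
  lam <- min(max(lam, 0), 0.95)
  c(theta = m * (1 - lam), lam = lam)
}

#' Maximum-likelihood fit of the generalized Poisson
#'
#' Fits (theta, lambda) to an i.i.d. sample of counts by L-BFGS-B on the
#' log-likelihood, initialised at the moment estimates. Degenerate samples
#' (zero variance) are refused rather than silently fitted.
#'
#' @param x integer vector of counts.
#' @return a \code{\link{gp_params}} object with attribute \code{"logLik"}.
#' @export
fit_genpois <- function(x) {
  if (length(x) < 5L) stop_param("need at least 5 observations")
  if (any(x < 0)) stop_param("counts must be non-negative")
  if (stats::var(x) == 0)
    stop("degenerate sample: zero variance; generalized Poisson fit refused",
         call. = FALSE)
  init <- gp_moment_estimates(x)
  nll <- function(par) -sum(gp_log_pmf(x, par[1], par[2]))
  fit <- optim(init, nll, method = "L-BFGS-B",
               lower = c(1e-8, 0), upper = c(Inf, 0.999))
  out <- gp_params(unname(fit$par[1]), unname(min(fit$par[2], 0.999)))
  attr(out, "logLik") <- -fit$value
  out
}
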