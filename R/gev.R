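# Generalized extreme value distribution: density, CDF and maximum-likelihood
# fitting. Windowed score maxima are approximately GEV-distributed, so the
# null distributions of <ICS> and <OS> are modelled with it.

#' GEV density, distribution and quantile functions
#'
#' Parameterization: location mu, scale sigma > 0, shape xi; xi = 0 is the
#' Gumbel limit (taken for |xi| < 1e-8).
#'
#' @param x,q,p Numeric vectors.
#' @param loc,scale,shape GEV parameters.
#' @param log Return log-density?
#' @name gev
#' @export
dgev <- function(x, loc = 0, scale = 1, shape = 0, log = FALSE) {
  stopifnot(scale > 0)
  z <- (x - loc) / scale
  if (abs(shape) < 1e-8) {
    logd <- -z - exp(-z) - log(scale)
  } else {
    t <- 1 + shape * z
    logd <- ifelse(t > 0,
                   -(1 / shape + 1) * log(pmax(t, 1e-300)) -
                     pmax(t, 1e-300)^(-1 / shape) - log(scale),
                   -Inf)
  }
  if (log) logd else exp(logd)
}

#' @rdname gev
#' @export
pgev <- function(q, loc = 0, scale = 1, shape = 0) {
  stopifnot(scale > 0)
  z <- (q - loc) / scale
  if (abs(shape) < 1e-8) return(exp(-exp(-z)))
  t <- 1 + shape * z
  out <- exp(-pmax(t, 0)^(-1 / shape))
  # Outside the support: CDF is 0 below (xi > 0) or 1 above (xi < 0).
  out[t <= 0] <- if (shape > 0) 0 else 1
  out
}

#' @rdname gev
#' @export
qgev <- function(p, loc = 0, scale = 1, shape = 0) {
  stopifnot(scale > 0, all(p > 0 & p < 1))
  if (abs(shape) < 1e-8) return(loc - scale * log(-log(p)))
  loc + scale * ((-log(p))^(-shape) - 1) / shape
}

#' Fit a GEV distribution by maximum likelihood
#'
#' Starts from Gumbel moment estimates; if the full three-parameter
#' optimization fails to converge (or collapses the support onto the data),
#' falls back to a two-parameter Gumbel fit and flags the result.
#'
#' @param x Numeric sample (at least 50 values).
#' @return An object of class `gev_fit`: list with loc, scale, shape,
#'   method ("mle" or "gumbel-fallback"), convergence code and the sample
#'   size.
#' @export
fit_gev <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 50) stop("need at least 50 values to fit a GEV",
                           call. = FALSE)
  scale0 <- stats::sd(x) * sqrt(6) / pi
  loc0 <- mean(x) - 0.5772157 * scale0
  nll <- function(par) {
    if (par[2] <= 0) return(1e10)
    ll <- dgev(x, par[1], par[2], par[3], log = TRUE)
    if (any(!is.finite(ll))) return(1e10)
    -sum(ll)
  }
  fit <- try(stats::optim(c(loc0, scale0, 0.05), nll, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10)),
             silent = TRUE)
  ok <- !inherits(fit, "try-error") && fit$convergence == 0 &&
    is.finite(fit$value) && abs(fit$par[3]) < 5
  if (ok) {
    out <- list(loc = fit$par[1], scale = fit$par[2], shape = fit$par[3],
                method = "mle", convergence = fit$convergence, n = length(x))
  } else {
    nll_g <- function(par) {
      if (par[2] <= 0) return(1e10)
      -sum(dgev(x, par[1], par[2], 0, log = TRUE))
    }
    fg <- stats::optim(c(loc0, scale0), nll_g, method = "Nelder-Mead",
                       control = list(maxit = 2000))
    out <- list(loc = fg$par[1], scale = fg$par[2], shape = 0,
                method = "gumbel-fallback", convergence = fg$convergence,
                n = length(x))
  }
  structure(out, class = "gev_fit")
}

#' @export
print.gev_fit <- function(x, ...) {
  cat(sprintf("<gev_fit> loc=%.4f scale=%.4f shape=%.4f (%s, n=%d)\n",
              x$loc, x$scale, x$shape, x$method, x$n))
  invisible(x)
}

#' Upper-tail probability under a fitted GEV
#'
#' Returns P(X > x): the survival function, strictly decreasing in x. Small
#' values indicate observations far into the upper tail of the null.
#'
#' @param x Numeric vector of observed statistics.
#' @param gev A `gev_fit` (or list with loc, scale, shape).
#' @return Upper-tail probabilities in [0, 1].
#' @export
p_upper <- function(x, gev) {
  1 - pgev(x, gev$loc, gev$scale, gev$shape)
}
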