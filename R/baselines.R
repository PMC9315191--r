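#' Parametric baseline hazard families
#'
#' Constructs a baseline hazard object for use in a mixed-effects general
#' hazard (MEGH) model or in the clustered-data simulator. Four families are
#' supported, chosen so that the baseline can take all of the basic hazard
#' shapes (increasing, decreasing, unimodal, bathtub):
#'
#' \describe{
#'   \item{\code{"pgw"}}{Power Generalised Weibull with scale \eqn{\eta > 0},
#'     power \eqn{\nu > 0} and tilt \eqn{\delta > 0}:
#'     \eqn{H_0(t) = [1 + (t/\eta)^\nu]^{1/\delta} - 1}. With
#'     \eqn{\delta = 1} this degenerates to the Weibull cumulative hazard
#'     \eqn{(t/\eta)^\nu}.}
#'   \item{\code{"loglogistic"}}{log-logistic with log-location \eqn{\mu} and
#'     scale \eqn{\tau > 0}: \eqn{H_0(t) = \log(1 + e^{z})},
#'     \eqn{z = (\log t - \mu)/\tau}.}
#'   \item{\code{"lognormal"}}{log-normal with log-location \eqn{\mu} and
#'     scale \eqn{\tau > 0}: \eqn{H_0(t) = -\log(1 - \Phi(z))}.}
#'   \item{\code{"gamma"}}{gamma with shape and rate, cumulative hazard
#'     \eqn{-\log} of the gamma survival function.}
#' }
#'
#' The standalone Weibull family is deliberately not offered: under a Weibull
#' baseline the general hazard structure is non-identifiable (the time-scale
#' and hazard-scale effects collapse into one another), so requesting
#' \code{"weibull"} is an error. Weibull shapes remain reachable as the
#' \code{pgw} boundary \eqn{\delta = 1}, which is useful as a numerical
#' cross-check but must not be fitted as a family of its own.
#'
#' @param family one of \code{"pgw"}, \code{"loglogistic"}, \code{"lognormal"},
#'   \code{"gamma"}.
#' @param theta numeric vector of family parameters, in the order documented
#'   above (length 3 for \code{pgw}, 2 otherwise). All scale/shape parameters
#'   must be strictly positive; the log-locations \eqn{\mu} are unrestricted.
#' @return an object of class \code{megh_baseline}.
#' @examples
#' b <- baseline_hazard("pgw", c(0.2, 1.5, 3.0))
#' bh_hazard(b, 1)
#' bh_cumhaz_inv(b, bh_cumhaz(b, 2))  # returns 2
#' @export
baseline_hazard <- function(family = c("pgw", "loglogistic", "lognormal", "gamma"),
                            theta) {
  if (identical(tolower(family[1L]), "weibull")) {
    stop("the Weibull family is not available as a standalone baseline: ",
         "the general hazard structure is non-identifiable under it. ",
         "Use family = \"pgw\" (Weibull is its delta = 1 boundary).")
  }
  family <- match.arg(family)
  theta <- as.numeric(theta)
  np <- bh_npar(family)
  if (length(theta) != np) {
    stop(sprintf("family '%s' needs %d parameters, got %d", family, np,
                 length(theta)))
  }
  if (any(!is.finite(theta))) stop("baseline parameters must be finite")
  pos <- bh_pos_mask(family)
  if (any(theta[pos] <= 0)) {
    stop(sprintf("baseline parameters %s must be strictly positive",
                 paste(bh_par_names(family)[pos & (theta <= 0)], collapse = ", ")))
  }
  structure(list(family = family, theta = theta), class = "megh_baseline")
}

bh_npar <- function(family) if (family == "pgw") 3L else 2L

# which components of theta are constrained positive
bh_pos_mask <- function(family) {
  switch(family,
         pgw = c(TRUE, TRUE, TRUE),
         loglogistic = c(FALSE, TRUE),
         lognormal = c(FALSE, TRUE),
         gamma = c(TRUE, TRUE))
}

bh_par_names <- function(family) {
  switch(family,
         pgw = c("eta", "nu", "delta"),
         loglogistic = c("mu", "tau"),
         lognormal = c("mu", "tau"),
         gamma = c("shape", "rate"))
}

#' @export
print.megh_baseline <- function(x, ...) {
  cat("Baseline hazard:", x$family, "\n")
  th <- x$theta
  names(th) <- bh_par_names(x$family)
  print(th)
  invisible(x)
}

# numerically stable log(1 + exp(z))
log1pexp <- function(z) {
  out <- z
  lo <- z <= 33
  out[lo] <- log1p(exp(z[lo]))
  out
}

#' Baseline log-hazard
#'
#' Evaluates \eqn{\log h_0(t \mid \theta)}. Computed directly on the log
#' scale so that extreme time arguments (which arise when large time-scale
#' linear predictors rescale \eqn{t}) do not underflow through
#' \code{log(hazard)}.
#'
#' @param b a \code{megh_baseline} object.
#' @param t vector of strictly positive times.
#' @return vector of log-hazard values.
#' @export
bh_loghaz <- function(b, t) {
  if (any(t <= 0)) stop("hazard is defined for t > 0 only")
  th <- b$theta
  lt <- log(t)
  switch(b$family,
    pgw = {
      # h0(t) = (nu / (delta eta^nu)) t^(nu-1) [1 + (t/eta)^nu]^(1/delta - 1)
      w <- th[2] * (lt - log(th[1]))
      log(th[2]) - log(th[3]) - th[2] * log(th[1]) + (th[2] - 1) * lt +
        (1 / th[3] - 1) * log1pexp(w)
    },
    loglogistic = {
      z <- (lt - th[1]) / th[2]
      z - log(th[2]) - lt - log1pexp(z)
    },
    lognormal = {
      z <- (lt - th[1]) / th[2]
      stats::dnorm(z, log = TRUE) - log(th[2]) - lt -
        stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
    },
    gamma = {
      stats::dgamma(t, shape = th[1], rate = th[2], log = TRUE) -
        stats::pgamma(t, shape = th[1], rate = th[2], lower.tail = FALSE,
                      log.p = TRUE)
    })
}

#' Baseline hazard function
#'
#' @inheritParams bh_loghaz
#' @return vector of hazard values \eqn{h_0(t)}.
#' @export
bh_hazard <- function(b, t) exp(bh_loghaz(b, t))

#' Baseline cumulative hazard
#'
#' Closed-form cumulative hazard \eqn{H_0(t)} with \eqn{H_0(0) = 0}; strictly
#' increasing and unbounded for every supported family.
#'
#' @inheritParams bh_loghaz
#' @param t vector of non-negative times.
#' @return vector of cumulative hazard values.
#' @export
bh_cumhaz <- function(b, t) {
  if (any(t < 0)) stop("cumulative hazard is defined for t >= 0 only")
  th <- b$theta
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- switch(b$family,
    pgw = {
      w <- th[2] * (log(tp) - log(th[1]))
      expm1(log1pexp(w) / th[3])
    },
    loglogistic = log1pexp((log(tp) - th[1]) / th[2]),
    lognormal = -stats::pnorm((log(tp) - th[1]) / th[2], lower.tail = FALSE,
                              log.p = TRUE),
    gamma = -stats::pgamma(tp, shape = th[1], rate = th[2],
                           lower.tail = FALSE, log.p = TRUE))
  out
}

#' Inverse baseline cumulative hazard
#'
#' Returns the time \eqn{t} with \eqn{H_0(t) = s}. Needed to simulate survival
#' times by inversion: if \eqn{E} is a unit exponential draw then
#' \code{bh_cumhaz_inv(b, E)} has baseline survival law. Closed form for the
#' PGW and log-logistic families; via the normal and gamma quantile functions
#' otherwise (evaluated with log-scale tail probabilities so large \eqn{s}
#' does not saturate).
#'
#' @param b a \code{megh_baseline} object.
#' @param s vector of non-negative cumulative-hazard values.
#' @return vector of times with \code{bh_cumhaz(b, t) == s}.
#' @export
bh_cumhaz_inv <- function(b, s) {
  if (any(s < 0)) stop("inverse cumulative hazard is defined for s >= 0 only")
  th <- b$theta
  out <- numeric(length(s))
  pos <- s > 0
  sp <- s[pos]
  out[pos] <- switch(b$family,
    pgw = th[1] * expm1(th[3] * log1p(sp))^(1 / th[2]),
    loglogistic = {
      # e^s - 1 overflows for s > ~700; log(e^s - 1) = s + log(1 - e^-s)
      exp(th[1] + th[2] * (sp + log(-expm1(-sp))))
    },
    lognormal = exp(th[1] + th[2] * stats::qnorm(-sp, lower.tail = FALSE,
                                                 log.p = TRUE)),
    gamma = stats::qgamma(-sp, shape = th[1], rate = th[2],
                          lower.tail = FALSE, log.p = TRUE))
  out
}

# ---- unconstrained reparameterisation (optimisation scale) ----
# positive parameters live on the log scale; log-locations stay as-is.

bh_to_unconstrained <- function(b) {
  pos <- bh_pos_mask(b$family)
  phi <- b$theta
  phi[pos] <- log(phi[pos])
  phi
}

bh_from_unconstrained <- function(family, phi) {
  pos <- bh_pos_mask(family)
  th <- phi
  th[pos] <- exp(phi[pos])
  baseline_hazard(family, th)
}
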