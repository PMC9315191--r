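#' Zero-mean random-effects distributions
#'
#' Constructs the distribution G of the cluster-level random effect in a
#' mixed-effects general hazard model. All families are continuous with
#' support on the whole real line, mean exactly zero and finite variance,
#' as the marginal-likelihood theory requires.
#'
#' \describe{
#'   \item{\code{"normal"}}{N(0, sigma^2).}
#'   \item{\code{"student_t"}}{scaled Student-t with fixed degrees of freedom
#'     \code{df} (> 2, default 4); the scale is set to
#'     \eqn{\sigma\sqrt{(df-2)/df}} so that the variance equals
#'     \eqn{\sigma^2}. Heavier tails than normal, one free parameter.}
#'   \item{\code{"two_piece_normal"}}{two-piece normal with left scale
#'     \code{sigma} and right scale \code{sigma2}, location-shifted so its
#'     mean is exactly zero: the mode sits at
#'     \eqn{m = -\sqrt{2/\pi}(\sigma_2 - \sigma_1)}. Allows skewness in the
#'     cluster effects.}
#' }
#'
#' @param family one of \code{"normal"}, \code{"student_t"},
#'   \code{"two_piece_normal"}.
#' @param sigma standard deviation (normal, Student-t) or left scale
#'   (two-piece normal); must be > 0.
#' @param df degrees of freedom for \code{"student_t"}; fixed, not estimated,
#'   and must exceed 2 so the variance exists.
#' @param sigma2 right scale for \code{"two_piece_normal"}; defaults to
#'   \code{sigma} (the symmetric case, which coincides with the normal).
#' @return an object of class \code{megh_redist}.
#' @examples
#' g <- re_dist("normal", sigma = 0.5)
#' re_density(g, 0)
#' re_sample(g, 5, seed = 1)
#' @export
re_dist <- function(family = c("normal", "student_t", "two_piece_normal"),
                    sigma, df = 4, sigma2 = NULL) {
  family <- match.arg(family)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be a positive number")
  g <- list(family = family, sigma = sigma)
  if (family == "student_t") {
    if (!is.finite(df) || df <= 2) stop("df must exceed 2 for finite variance")
    g$df <- df
  }
  if (family == "two_piece_normal") {
    if (is.null(sigma2)) sigma2 <- sigma
    if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
    g$sigma2 <- sigma2
  }
  class(g) <- "megh_redist"
  g
}

#' @export
print.megh_redist <- function(x, ...) {
  cat("Random-effects distribution:", x$family, "\n")
  cat("  sigma =", x$sigma)
  if (!is.null(x$df)) cat(", df =", x$df)
  if (!is.null(x$sigma2)) cat(", sigma2 =", x$sigma2)
  cat("\n")
  invisible(x)
}

# number of free variance parameters (Student-t df is fixed by design)
re_npar <- function(g) if (g$family == "two_piece_normal") 2L else 1L

# mode shift that centres the two-piece normal at zero mean
tpn_mode <- function(s1, s2) -sqrt(2 / pi) * (s2 - s1)

#' Random-effects density
#'
#' @param g a \code{megh_redist} object.
#' @param u vector of evaluation points.
#' @param log if \code{TRUE} return the log-density.
#' @return vector of (log-)density values.
#' @export
re_density <- function(g, u, log = FALSE) {
  ld <- switch(g$family,
    normal = stats::dnorm(u, 0, g$sigma, log = TRUE),
    student_t = {
      s <- g$sigma * sqrt((g$df - 2) / g$df)
      stats::dt(u / s, df = g$df, log = TRUE) - base::log(s)
    },
    two_piece_normal = {
      s1 <- g$sigma; s2 <- g$sigma2
      m <- tpn_mode(s1, s2)
      s <- ifelse(u < m, s1, s2)
      base::log(2) - base::log(s1 + s2) + stats::dnorm((u - m) / s, log = TRUE)
    })
  if (log) ld else exp(ld)
}

#' Variance of the random-effects distribution
#'
#' @param g a \code{megh_redist} object.
#' @return the variance of G (finite by construction).
#' @export
re_variance <- function(g) {
  switch(g$family,
    normal = g$sigma^2,
    student_t = g$sigma^2,
    two_piece_normal = {
      s1 <- g$sigma; s2 <- g$sigma2
      (1 - 2 / pi) * (s2 - s1)^2 + s1 * s2
    })
}

#' Sample random effects
#'
#' Draws iid cluster effects from G. When \code{seed} is supplied the draw is
#' reproducible and the caller's RNG state is restored afterwards.
#'
#' @param g a \code{megh_redist} object.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of length \code{n}.
#' @export
re_sample <- function(g, n, seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  switch(g$family,
    normal = stats::rnorm(n, 0, g$sigma),
    student_t = {
      s <- g$sigma * sqrt((g$df - 2) / g$df)
      s * stats::rt(n, df = g$df)
    },
    two_piece_normal = {
      s1 <- g$sigma; s2 <- g$sigma2
      m <- tpn_mode(s1, s2)
      side <- stats::runif(n) < s1 / (s1 + s2)
      z <- abs(stats::rnorm(n))
      ifelse(side, m - s1 * z, m + s2 * z)
    })
}

# replace the variance parameters (used by the optimiser);
# xi is on the original (positive) scale
re_with_xi <- function(g, xi) {
  g$sigma <- xi[1]
  if (g$family == "two_piece_normal") g$sigma2 <- xi[2]
  g
}

re_xi <- function(g) {
  if (g$family == "two_piece_normal") c(g$sigma, g$sigma2) else g$sigma
}

re_xi_names <- function(g) {
  if (g$family == "two_piece_normal") c("sigma1", "sigma2") else "sigma_u"
}
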