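#' Gradient-function diagnostic for the random-effects distribution
#'
#' Computes the gradient function
#' \deqn{\Delta(G, u) = \frac{1}{r} \sum_{i=1}^r
#'   \frac{\exp\{\ell_i(\hat\eta, u)\}}{m_i(\hat\eta)}}
#' on a grid of random-effect values, with the fitted parameters plugged in.
#' The gradient function is the directional-derivative diagnostic for the
#' assumed random-effects distribution G: if some other distribution W would
#' raise the marginal likelihood, \eqn{\Delta} exceeds 1 somewhere, so a
#' curve staying at or below 1 supports the assumed G. No alternative W needs
#' to be specified. Because the directional derivative of the marginal
#' log-likelihood at G in the direction of G itself is zero, the identity
#' \eqn{\int \Delta(G, u)\, dG(u) = 1} holds; it is evaluated by quadrature
#' and returned in the \code{integral} element as a numerical self-check.
#'
#' @param data the \code{megh_data} the model was fitted to.
#' @param fit a converged \code{megh_fit} with a mixed structure.
#' @param grid evaluation points; default 101 equally spaced points on
#'   \eqn{\pm 4 \max(\hat\sigma_u, 0.25)}.
#' @return an object of class \code{megh_gradient} with elements \code{grid},
#'   \code{delta}, \code{threshold} (the constant 1), \code{integral}, and
#'   empty band slots (see \code{\link{gradient_bands}}).
#' @seealso \code{\link{gradient_bands}}
#' @export
gradient_function <- function(data, fit, grid = NULL) {
  check_mixed_fit(fit)
  if (is.null(grid)) {
    w <- 4 * max(fit$params$re$sigma, 0.25)
    grid <- seq(-w, w, length.out = 101)
  }
  dl <- gradient_eval(data, fit$params, fit$structure, grid)
  structure(list(grid = grid, delta = dl$delta, threshold = 1,
                 integral = dl$integral, band_lower = NULL, band_upper = NULL,
                 n_boot = 0L),
            class = "megh_gradient")
}

check_mixed_fit <- function(fit) {
  stopifnot(inherits(fit, "megh_fit"))
  if (fit$structure == "gh") {
    stop("the gradient diagnostic needs a mixed structure (megh1 or megh2)")
  }
  if (!isTRUE(fit$converged)) {
    stop("fit did not converge; refusing to compute the gradient diagnostic")
  }
  invisible(fit)
}

# delta on a grid plus the quadrature check of int Delta dG = 1
gradient_eval <- function(data, params, structure, grid) {
  env <- megh_cluster_env(data, params, structure)
  bracket <- megh_bracket(params$re)
  logm <- vapply(seq_len(data$r), function(i) {
    k <- cluster_logK(env, i, bracket)
    k$logK + cluster_log_integral(env, i, k$logK, k$umax)
  }, 0)
  delta_at <- function(u) {
    vapply(u, function(ui) {
      mean(exp(vapply(seq_len(data$r), function(i)
        cluster_ll_u(env, i, ui), 0) - logm))
    }, 0)
  }
  g <- params$re
  s <- g$sigma
  intval <- tryCatch(
    stats::integrate(function(v) delta_at(s * v) * re_density(g, s * v) * s,
                     -Inf, Inf, rel.tol = 1e-6)$value,
    error = function(e) NA_real_)
  list(delta = delta_at(grid), integral = intval)
}

#' Bootstrap confidence bands for the gradient function
#'
#' Pointwise 95\% bands for \eqn{\Delta(G, u)} by cluster-level nonparametric
#' bootstrap: clusters are resampled with replacement, the model is refitted
#' to each resample (unless \code{refit = FALSE}, which keeps the original
#' estimates and only recomputes the gradient curve — much cheaper, at the
#' cost of ignoring estimation uncertainty), and the curve is recomputed.
#' The returned bands are the 2.5\% and 97.5\% pointwise quantiles with the
#' point estimate included, so they always contain the estimated curve.
#'
#' @inheritParams gradient_function
#' @param n_boot number of bootstrap resamples (a warning is raised below 50).
#' @param seed optional seed for reproducible resampling.
#' @param refit refit the model on every resample (default) or reuse the
#'   original estimates.
#' @return a \code{megh_gradient} with \code{band_lower} and
#'   \code{band_upper} filled in.
#' @export
gradient_bands <- function(data, fit, grid = NULL, n_boot = 200, seed = NULL,
                           refit = TRUE) {
  check_mixed_fit(fit)
  if (n_boot < 50) warning("n_boot < 50 gives unstable bands")
  if (!is.null(seed)) set.seed(seed)
  gc0 <- gradient_function(data, fit, grid)
  grid <- gc0$grid
  curves <- matrix(NA_real_, n_boot, length(grid))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    pick <- sample.int(data$r, data$r, replace = TRUE)
    bd <- resample_clusters(data, pick)
    pb <- fit$params
    if (refit) {
      bf <- tryCatch(
        megh_fit(bd, fit$structure, baseline = fit$baseline,
                 re = fit$re_family,
                 df = if (is.na(fit$df)) 4 else fit$df,
                 starts = "gh", hessian = FALSE),
        error = function(e) NULL)
      if (is.null(bf)) { failed <- failed + 1L; next }
      pb <- bf$params
    }
    curves[b, ] <- tryCatch(
      gradient_eval(bd, pb, fit$structure, grid)$delta,
      error = function(e) rep(NA_real_, length(grid)))
  }
  all_curves <- rbind(curves, gc0$delta)
  gc0$band_lower <- apply(all_curves, 2, stats::quantile, probs = 0.025,
                          na.rm = TRUE)
  gc0$band_upper <- apply(all_curves, 2, stats::quantile, probs = 0.975,
                          na.rm = TRUE)
  gc0$n_boot <- n_boot - failed
  gc0
}

#' @export
print.megh_gradient <- function(x, ...) {
  cat(sprintf("Gradient-function diagnostic on %d grid points in [%.3g, %.3g]\n",
              length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  max Delta = %.4f (adequacy threshold 1)\n", max(x$delta)))
  if (is.finite(x$integral)) {
    cat(sprintf("  quadrature check int Delta dG = %.6f (should be 1)\n",
                x$integral))
  }
  if (!is.null(x$band_lower)) {
    cat(sprintf("  95%% bands from %d cluster-bootstrap resamples\n", x$n_boot))
  }
  invisible(x)
}

#' @export
plot.megh_gradient <- function(x, ...) {
  ylim <- range(1, x$delta, x$band_lower, x$band_upper, na.rm = TRUE)
  graphics::plot(x$grid, x$delta, type = "l", lwd = 2, ylim = ylim,
                 xlab = "random effect u", ylab = expression(Delta(G, u)), ...)
  if (!is.null(x$band_lower)) {
    graphics::lines(x$grid, x$band_lower, lty = 2)
    graphics::lines(x$grid, x$band_upper, lty = 2)
  }
  graphics::abline(h = 1, col = "grey50")
  invisible(x)
}

#' Chi-bar-square p-value for variance components on the boundary
#'
#' Null distribution of the likelihood ratio statistic when the tested
#' random-effect variances sit on the boundary of the parameter space.
#' Testing a single variance (\code{"one_variance"}, the relevant case for
#' the implemented mixed structures, where the two scales share one random
#' effect) the null is the equal mixture
#' \eqn{\frac12\chi^2_0 + \frac12\chi^2_1}; testing two variances
#' (\code{"two_variances"}) it is
#' \eqn{\frac14\chi^2_0 + \frac12\chi^2_1 + \frac14\chi^2_2}, with
#' \eqn{\chi^2_0} a point mass at zero. The p-value at \code{r_obs = 0} is 1.
#'
#' @param r_obs observed likelihood ratio statistic, non-negative.
#' @param case \code{"one_variance"} or \code{"two_variances"}.
#' @return the p-value.
#' @examples
#' mixture_pvalue(3.841459, "one_variance")  # 0.025
#' @export
mixture_pvalue <- function(r_obs, case = c("one_variance", "two_variances")) {
  case <- match.arg(case)
  if (!is.finite(r_obs) || r_obs < 0) stop("r_obs must be non-negative")
  if (r_obs == 0) return(1)
  p1 <- stats::pchisq(r_obs, df = 1, lower.tail = FALSE)
  if (case == "one_variance") return(0.5 * p1)
  0.5 * p1 + 0.25 * stats::pchisq(r_obs, df = 2, lower.tail = FALSE)
}

#' Boundary likelihood ratio test for zero random-effect variance
#'
#' Fits the mixed model and its fixed-effects reduction (same covariates and
#' baseline, no random effect), forms
#' \eqn{R_{obs} = \max\{0,\; 2(\log m_{alt} - \log L_{null})\}} (clipped at
#' zero against tiny negative optimiser differences), and computes the
#' chi-bar-square p-value for the single-variance case.
#'
#' @param data a \code{megh_data} object.
#' @param structure the mixed structure under the alternative.
#' @param baseline baseline family for both fits.
#' @param re random-effects family for the alternative.
#' @param df Student-t degrees of freedom, if applicable.
#' @param fit_alt,fit_null optional pre-computed fits (skips refitting).
#' @param ... passed on to \code{\link{megh_fit}}.
#' @return an object of class \code{megh_lrt}: \code{statistic},
#'   \code{p_value} (NA if either fit failed to converge), \code{case}, and
#'   the two fits.
#' @export
lrt_random_effect <- function(data, structure = c("megh1", "megh2"),
                              baseline = "pgw", re = "normal", df = 4,
                              fit_alt = NULL, fit_null = NULL, ...) {
  structure <- match.arg(structure)
  if (is.null(fit_null)) {
    fit_null <- megh_fit(data, "gh", baseline = baseline, hessian = FALSE, ...)
  }
  if (is.null(fit_alt)) {
    fit_alt <- megh_fit(data, structure, baseline = baseline, re = re, df = df,
                        gh_fit = fit_null, hessian = FALSE, ...)
  }
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  ok <- isTRUE(fit_alt$converged) && isTRUE(fit_null$converged)
  if (!ok) warning("one of the fits did not converge; p-value withheld")
  structure(list(statistic = stat,
                 p_value = if (ok) mixture_pvalue(stat, "one_variance")
                           else NA_real_,
                 case = "one_variance", converged = ok,
                 fit_alt = fit_alt, fit_null = fit_null),
            class = "megh_lrt")
}

#' @export
print.megh_lrt <- function(x, ...) {
  cat("Boundary LRT for zero random-effect variance\n")
  cat(sprintf("  R_obs = %.4f, chi-bar-square (%s) p-value = %.5g\n",
              x$statistic, x$case, x$p_value))
  if (!x$converged) cat("  WARNING: a fit did not converge\n")
  invisible(x)
}
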