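#' Clustered survival dataset
#'
#' Bundles right-censored clustered time-to-event data with the two design
#' matrices of a general hazard model: \code{X} carries the hazard-scale
#' covariates (multiplying the hazard) and \code{Xtilde} the time-scale
#' covariates (rescaling time inside the baseline hazard). Typically the
#' time-scale covariates are a subset of the hazard-scale ones.
#'
#' Cluster labels may be arbitrary (factor, character, integer); they are
#' mapped to consecutive integers \code{1..r} in order of first appearance and
#' the original labels are retained in \code{cluster_levels}.
#'
#' The design sub-matrices restricted to uncensored rows must be full column
#' rank for the model to be identifiable; a rank deficiency raises a warning,
#' not an error, so that degenerate bootstrap resamples can still be handled
#' upstream.
#'
#' @param time vector of observed times, strictly positive and finite.
#' @param status event indicators, 1 = event observed, 0 = right-censored.
#' @param cluster cluster labels, one per subject; every cluster non-empty.
#' @param X hazard-scale design matrix (or vector, or NULL for none).
#' @param Xtilde time-scale design matrix (or vector, or NULL for none).
#' @return an object of class \code{megh_data} with elements \code{time},
#'   \code{status}, \code{cluster} (integer codes), \code{cluster_levels},
#'   \code{X}, \code{Xtilde}, \code{n}, \code{r} and \code{idx} (row indices
#'   by cluster).
#' @examples
#' d <- megh_data(time = c(1, 2, 3, 4), status = c(1, 0, 1, 1),
#'                cluster = c("a", "a", "b", "b"),
#'                X = cbind(x = c(0.5, -1, 0, 2)))
#' d$r
#' @export
megh_data <- function(time, status, cluster, X = NULL, Xtilde = NULL) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  n <- length(time)
  if (length(status) != n || length(cluster) != n) {
    stop("time, status and cluster must have equal length")
  }
  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad)) {
    stop("times must be strictly positive and finite; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!all(status %in% c(0, 1))) {
    stop("status must contain only 0 (censored) and 1 (event)")
  }
  as_design <- function(M, what) {
    if (is.null(M)) return(matrix(numeric(0), nrow = n, ncol = 0))
    if (is.data.frame(M)) M <- as.matrix(M)
    if (is.vector(M)) M <- matrix(M, ncol = 1)
    storage.mode(M) <- "double"
    if (nrow(M) != n) stop(what, " must have one row per subject")
    if (any(!is.finite(M))) stop(what, " contains non-finite values")
    if (is.null(colnames(M)) && ncol(M) > 0) {
      colnames(M) <- paste0(if (what == "X") "x" else "xt", seq_len(ncol(M)))
    }
    M
  }
  X <- as_design(X, "X")
  Xtilde <- as_design(Xtilde, "Xtilde")

  cf <- factor(cluster, levels = unique(cluster))
  ci <- as.integer(cf)
  r <- nlevels(cf)

  ev <- status == 1
  if (sum(ev) > 0) {
    if (ncol(X) > 0 && qr(X[ev, , drop = FALSE])$rank < ncol(X)) {
      warning("hazard-scale design matrix is rank-deficient on uncensored rows")
    }
    if (ncol(Xtilde) > 0 && qr(Xtilde[ev, , drop = FALSE])$rank < ncol(Xtilde)) {
      warning("time-scale design matrix is rank-deficient on uncensored rows")
    }
  }
  structure(list(time = time, status = status, cluster = ci,
                 cluster_levels = levels(cf), X = X, Xtilde = Xtilde,
                 n = n, r = r, idx = split(seq_len(n), ci)),
            class = "megh_data")
}

#' @export
print.megh_data <- function(x, ...) {
  cat(sprintf("Clustered survival data: n = %d subjects, r = %d clusters\n",
              x$n, x$r))
  cat(sprintf("  events: %d (%.1f%% censored)\n", sum(x$status),
              100 * mean(x$status == 0)))
  cat(sprintf("  hazard-scale covariates: %s\n",
              if (ncol(x$X)) paste(colnames(x$X), collapse = ", ") else "(none)"))
  cat(sprintf("  time-scale covariates: %s\n",
              if (ncol(x$Xtilde)) paste(colnames(x$Xtilde), collapse = ", ")
              else "(none)"))
  invisible(x)
}

# rebuild a megh_data from a vector of cluster indices (with replacement);
# resampled clusters get fresh labels so repeats stay distinct
resample_clusters <- function(data, which_clusters) {
  rows <- unlist(data$idx[which_clusters], use.names = FALSE)
  sizes <- lengths(data$idx[which_clusters])
  newcl <- rep(seq_along(which_clusters), sizes)
  suppressWarnings(megh_data(data$time[rows], data$status[rows], newcl,
                             data$X[rows, , drop = FALSE],
                             data$Xtilde[rows, , drop = FALSE]))
}
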