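test_that("chi-bar-square p-values match their closed forms", {
  expect_identical(mixture_pvalue(0, "one_variance"), 1)
  expect_identical(mixture_pvalue(0, "two_variances"), 1)
  # half the chi2(1) tail: at the 5% chi2(1) quantile the p-value is 0.025
  expect_equal(mixture_pvalue(3.841459, "one_variance"), 0.025,
               tolerance = 1e-6)
  expect_equal(mixture_pvalue(3.841459, "one_variance"),
               0.5 * pchisq(3.841459, 1, lower.tail = FALSE), tolerance = 1e-12)
  # two-variance mixture at the 5% chi2(2) quantile (exact value computed
  # from the chi-square survival functions)
  expect_equal(mixture_pvalue(5.991465, "two_variances"), 0.0196876265,
               tolerance = 1e-6)
  expect_equal(mixture_pvalue(5.991465, "two_variances"),
               0.5 * pchisq(5.991465, 1, lower.tail = FALSE) +
                 0.25 * pchisq(5.991465, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(mixture_pvalue(-1, "one_variance"), "non-negative")
})

test_that("mixture p-values decrease strictly in the observed statistic", {
  rg <- seq(0.05, 20, length.out = 60)
  for (cs in c("one_variance", "two_variances")) {
    pv <- vapply(rg, mixture_pvalue, 0, case = cs)
    expect_true(all(diff(pv) < 0), label = cs)
    expect_true(all(pv >= 0 & pv <= 1))
  }
})

fit_small <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      d <- small_data(seed = 13)
      f <- megh_fit(d, "megh1", hessian = FALSE)
      memo <<- list(d = d, f = f)
    }
    memo
  }
})

test_that("the gradient function integrates to one against G", {
  fs <- fit_small()
  gc <- gradient_function(fs$d, fs$f)
  expect_true(all(gc$delta >= 0))
  expect_identical(gc$threshold, 1)
  expect_equal(gc$integral, 1, tolerance = 1e-3)

  # single-cluster identity: Delta(u) = exp(l_1(u)) / m_1
  rows <- fs$d$idx[[1]]
  d1 <- megh_data(fs$d$time[rows], fs$d$status[rows], rep(1, length(rows)),
                  fs$d$X[rows, ], fs$d$Xtilde[rows, , drop = FALSE])
  f1 <- megh_fit(d1, "megh1", hessian = FALSE)
  g1 <- gradient_function(d1, f1, grid = c(-0.5, 0, 0.5))
  lm1 <- cluster_marginal_loglik(d1, 1, f1$params, "megh1")
  man <- vapply(c(-0.5, 0, 0.5), function(u)
    exp(cluster_cond_loglik(d1, 1, f1$params, u, 0) - lm1), 0)
  expect_equal(g1$delta, man, tolerance = 1e-8)
  expect_equal(g1$integral, 1, tolerance = 1e-3)
})

test_that("the gradient function is invariant to cluster relabelling", {
  fs <- fit_small()
  set.seed(4)
  perm <- sample(fs$d$r)
  rows <- unlist(fs$d$idx[perm])
  dp <- megh_data(fs$d$time[rows], fs$d$status[rows],
                  rep(seq_len(fs$d$r), lengths(fs$d$idx[perm])),
                  fs$d$X[rows, ], fs$d$Xtilde[rows, , drop = FALSE])
  grid <- seq(-2, 2, length.out = 11)
  g0 <- gradient_function(fs$d, fs$f, grid)
  g1 <- gradient_function(dp, fs$f, grid)
  expect_equal(g0$delta, g1$delta, tolerance = 1e-10)
})

test_that("gradient diagnostics refuse unusable fits", {
  fs <- fit_small()
  gh <- megh_fit(fs$d, "gh", hessian = FALSE)
  expect_error(gradient_function(fs$d, gh), "mixed structure")
  bad <- fs$f
  bad$converged <- FALSE
  expect_error(gradient_function(fs$d, bad), "converge")
})

test_that("bootstrap bands contain the estimate and are reproducible", {
  fs <- fit_small()
  grid <- seq(-1.5, 1.5, length.out = 21)
  expect_warning(gradient_bands(fs$d, fs$f, grid, n_boot = 30, seed = 1,
                                refit = FALSE), "unstable")
  b1 <- gradient_bands(fs$d, fs$f, grid, n_boot = 60, seed = 99, refit = FALSE)
  b2 <- gradient_bands(fs$d, fs$f, grid, n_boot = 60, seed = 99, refit = FALSE)
  expect_identical(b1$band_lower, b2$band_lower)
  expect_identical(b1$band_upper, b2$band_upper)
  expect_true(all(b1$band_lower <= b1$delta + 1e-12))
  expect_true(all(b1$band_upper >= b1$delta - 1e-12))
})

test_that("under a correctly specified normal G the curve stays near the threshold", {
  # small replicates of the correctly specified model: the gradient curve
  # should not exceed 1 by more than its uncertainty band anywhere (the
  # adequacy rule), and the band at u = 0 should usually cover 1
  cover <- 0
  n_ok <- 0
  exceed <- numeric(0)
  for (k in 1:6) {
    d <- small_data(seed = 500 + k, r = 12, size = 15)
    f <- tryCatch(megh_fit(d, "megh1", hessian = FALSE),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) next
    n_ok <- n_ok + 1
    gb <- gradient_bands(d, f, n_boot = 80, seed = k, refit = FALSE)
    exceed <- c(exceed, mean(gb$band_lower > 1))
    at0 <- which.min(abs(gb$grid))
    if (gb$band_lower[at0] <= 1 && gb$band_upper[at0] >= 1) cover <- cover + 1
  }
  expect_identical(as.integer(n_ok), 6L)
  expect_gte(cover, 4)             # coverage of 1 at the centre
  expect_lt(mean(exceed), 0.05)    # the curve rarely clears 1 beyond the band
})

test_that("the boundary LRT respects nesting and clips at zero", {
  fs <- fit_small()
  lr <- lrt_random_effect(fs$d, "megh1", fit_alt = fs$f)
  expect_gte(lr$statistic, 0)
  expect_gte(lr$fit_alt$loglik, lr$fit_null$loglik)
  expect_true(lr$p_value >= 0 && lr$p_value <= 1)
  expect_identical(lr$case, "one_variance")
})
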