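pars_small <- function(sigma = 0.8) {
  des <- small_design(sigma = sigma)
  megh_params(des$beta, des$alpha, des$baseline,
              if (sigma > 0) re_dist("normal", sigma) else NULL)
}

test_that("conditional log-hazard nests the PH and AFT structures", {
  set.seed(1)
  n <- 8
  t <- rexp(n) + 0.1
  X <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  Xt <- X[, 1, drop = FALSE]
  b <- baseline_hazard("pgw", c(0.2, 1.5, 3.0))

  # null covariates and effects recover the baseline
  p0 <- megh_params(c(0, 0), 0, b)
  expect_equal(cond_log_hazard(t, X, Xt, p0), bh_loghaz(b, t))

  # hazard-scale-only structure with alpha = 0 is the mixed PH log-hazard
  p1 <- megh_params(c(0.8, -0.5), 0, b)
  u <- 0.3
  expect_equal(cond_log_hazard(t, X, Xt, p1, u = u, utilde = 0),
               bh_loghaz(b, t) + drop(X %*% c(0.8, -0.5)) + u)

  # shared-effect structure with alpha = beta and xtilde = x is the mixed
  # AFT log-hazard: log h0(t e^{x'b + u}) + x'b + u
  bb <- 0.6
  p2 <- megh_params(bb, bb, b)
  lp <- drop(Xt %*% bb) + u
  expect_equal(cond_log_hazard(t, Xt, Xt, p2, u = u, utilde = u),
               bh_loghaz(b, t * exp(lp)) + lp)
})

test_that("conditional cumulative hazard matches quadrature of the hazard", {
  set.seed(2)
  n <- 5
  t <- runif(n, 0.2, 3)
  X <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  Xt <- X[, 1, drop = FALSE]
  p <- megh_params(c(0.7, -0.3), 0.4, baseline_hazard("pgw", c(0.3, 1.2, 2)),
                   re_dist("normal", 1))
  for (j in seq_len(n)) {
    for (uu in c(-0.5, 0.4)) {
      q <- integrate(function(s)
        exp(cond_log_hazard(rep(s, 1), X[j, , drop = FALSE],
                            Xt[j, , drop = FALSE], p, uu, uu / 2)),
        0, t[j], rel.tol = 1e-9)$value
      expect_equal(cond_cumhaz(t[j], X[j, , drop = FALSE],
                               Xt[j, , drop = FALSE], p, uu, uu / 2),
                   q, tolerance = 1e-5)
    }
  }
  expect_identical(cond_cumhaz(0, X[1, , drop = FALSE],
                               Xt[1, , drop = FALSE], p), 0)
})

test_that("cluster conditional log-likelihood equals a naive per-subject loop", {
  d <- small_data(seed = 77)
  p <- pars_small()
  for (i in c(1, 4)) {
    rows <- d$idx[[i]]
    for (uu in c(-0.8, 0, 0.6)) {
      naive <- 0
      for (j in rows) {
        lh <- cond_log_hazard(d$time[j], d$X[j, , drop = FALSE],
                              d$Xtilde[j, , drop = FALSE], p, uu, 0)
        H <- cond_cumhaz(d$time[j], d$X[j, , drop = FALSE],
                         d$Xtilde[j, , drop = FALSE], p, uu, 0)
        naive <- naive + d$status[j] * lh - H
      }
      expect_equal(cluster_cond_loglik(d, i, p, u = uu, utilde = 0), naive)
    }
  }
  # a fully censored cluster contributes -sum H <= 0
  dc <- suppressWarnings(megh_data(c(1, 2, 3), c(0, 0, 0), c(1, 1, 1),
                                   X = cbind(x = c(0, 1, 0))))
  pc <- megh_params(0.5, numeric(0), baseline_hazard("pgw", c(1, 1, 1)))
  expect_lt(cluster_cond_loglik(dc, 1, pc), 0)
})

test_that("compiled MEGH-II kernel agrees with the R conditional likelihood", {
  d <- small_data(seed = 30)
  for (fam in bh_families) {
    p <- megh_params(c(0.8, -0.5), 0.4, baseline_hazard(fam, theta_for(fam)),
                     re_dist("normal", 0.8))
    env <- meghaz:::megh_cluster_env(d, p, "megh2")
    for (uu in c(-1.2, 0, 0.9)) {
      expect_equal(meghaz:::cluster_ll_u(env, 2, uu),
                   cluster_cond_loglik(d, 2, p, u = uu, utilde = uu),
                   tolerance = 1e-10, label = paste("kernel,", fam))
    }
  }
})

test_that("cluster marginal likelihood matches a Monte Carlo oracle", {
  des <- sim_design(r = 2, cluster_sizes = c(10, 10),
                    re = re_dist("normal", 0.7))
  d <- simulate_dataset(des, seed = 5)
  p <- megh_params(des$beta, des$alpha, des$baseline, des$re)
  for (st in c("megh1", "megh2")) {
    lm1 <- cluster_marginal_loglik(d, 1, p, st)
    env <- meghaz:::megh_cluster_env(d, p, st)
    set.seed(11)
    us <- re_sample(p$re, 2e5)
    vals <- exp(meghaz:::cluster_ll_u(env, 1, us))
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(exp(lm1) - mean(vals)), 3 * se,
              label = paste("MC oracle,", st))
  }
})

test_that("the scaled integrand attains its maximum value 1", {
  d <- small_data(seed = 13)
  p <- pars_small()
  for (st in c("megh1", "megh2")) {
    env <- meghaz:::megh_cluster_env(d, p, st)
    k <- meghaz:::cluster_logK(env, 1, meghaz:::megh_bracket(p$re))
    expect_equal(exp(meghaz:::cluster_ll_u(env, 1, k$umax) - k$logK), 1,
                 tolerance = 1e-6)
    # and never exceeds 1 on a wide grid
    uu <- seq(-6, 6, length.out = 201)
    expect_true(all(exp(meghaz:::cluster_ll_u(env, 1, uu) - k$logK) <= 1 + 1e-8))
  }
})

test_that("vanishing random-effect scale recovers the fixed-effects likelihood", {
  d <- small_data(seed = 5)
  des <- small_design()
  for (st in c("megh1", "megh2")) {
    p0 <- megh_params(des$beta, des$alpha, des$baseline,
                      re_dist("normal", 1e-8))
    expect_equal(marginal_loglik(d, p0, st), marginal_loglik(d, p0, "gh"),
                 tolerance = 1e-4, label = paste("sigma -> 0,", st))
  }
})

test_that("marginal log-likelihood sums cluster terms and ignores cluster order", {
  d <- small_data(seed = 21)
  p <- pars_small()
  by_cluster <- sum(vapply(seq_len(d$r), function(i)
    cluster_marginal_loglik(d, i, p, "megh1"), 0))
  expect_equal(marginal_loglik(d, p, "megh1"), by_cluster)

  # single cluster: identical to the cluster term
  d1 <- megh_data(d$time[d$idx[[1]]], d$status[d$idx[[1]]],
                  rep(1, length(d$idx[[1]])),
                  d$X[d$idx[[1]], ], d$Xtilde[d$idx[[1]], , drop = FALSE])
  expect_equal(marginal_loglik(d1, p, "megh1"),
               cluster_marginal_loglik(d1, 1, p, "megh1"))

  # permuting cluster labels leaves the total unchanged exactly
  set.seed(9)
  perm <- sample(d$r)
  rows <- unlist(d$idx[perm])
  dp <- megh_data(d$time[rows], d$status[rows],
                  rep(seq_len(d$r), lengths(d$idx[perm])),
                  d$X[rows, ], d$Xtilde[rows, , drop = FALSE])
  expect_equal(marginal_loglik(dp, p, "megh1"),
               marginal_loglik(d, p, "megh1"), tolerance = 1e-12)
})

test_that("fitting maximises the marginal likelihood and reports coherent AIC", {
  d <- small_data(seed = 31)
  des <- small_design()
  truth <- megh_params(des$beta, des$alpha, des$baseline, des$re)
  gh <- megh_fit(d, "gh", hessian = FALSE)
  f <- megh_fit(d, "megh1", gh_fit = gh, hessian = FALSE)
  expect_true(f$converged)
  expect_gte(f$loglik, marginal_loglik(d, truth, "megh1"))
  expect_equal(f$aic, 2 * f$k - 2 * f$loglik)
  expect_identical(f$k - gh$k, 1L)   # xi = sigma_u is the only extra parameter
  expect_gte(f$loglik, gh$loglik)    # nested models
})

test_that("standard errors are positive when the Hessian is well-behaved", {
  d <- small_data(seed = 55, r = 12, size = 20)
  f <- megh_fit(d, "megh1")
  expect_true(all(is.finite(f$se)))
  expect_true(all(f$se > 0))
  expect_named(f$se, c("x1", "x2", "t:x1", "eta", "nu", "delta", "sigma_u"))
})

test_that("data generated without random effects drives sigma_hat to the boundary", {
  # under sigma_u = 0 truth the chi-bar-square null puts half its mass at the
  # boundary, so sigma_hat collapses in about half of the datasets; check the
  # ensemble rather than a single draw, plus the nesting tie when it does
  at_boundary <- 0
  for (k in 1:6) {
    d <- small_data(seed = 800 + k, sigma = 0, r = 20, size = 25)
    gh <- megh_fit(d, "gh", hessian = FALSE)
    f <- megh_fit(d, "megh1", gh_fit = gh, hessian = FALSE)
    expect_gte(f$loglik, gh$loglik - 1e-4)  # nesting, up to quadrature error
    if (unname(f$par["sigma_u"]) <= 0.02) {
      at_boundary <- at_boundary + 1
      expect_equal(f$loglik, gh$loglik, tolerance = 0.1)
    }
  }
  expect_gte(at_boundary, 2)
})

test_that("MEGH-I with no time-scale covariates equals an independent mixed-PH fit", {
  d0 <- small_data(seed = 303)
  d <- megh_data(d0$time, d0$status, d0$cluster, d0$X, NULL)
  f <- megh_fit(d, "megh1", hessian = FALSE)

  # independent mixed-PH implementation: naive loops, direct integration of
  # the unscaled integrand (safe at this cluster size)
  meph_nll <- function(par) {
    bl <- baseline_hazard("pgw", exp(par[3:5]))
    sg <- exp(par[6])
    ll <- 0
    for (i in seq_len(d$r)) {
      rows <- d$idx[[i]]
      lp <- drop(d$X[rows, ] %*% par[1:2])
      li <- function(u) {
        vapply(u, function(ui) {
          exp(sum(d$status[rows] * (bh_loghaz(bl, d$time[rows]) + lp + ui)) -
                sum(bh_cumhaz(bl, d$time[rows]) * exp(lp + ui)))
        }, 0)
      }
      mi <- integrate(function(u) li(u) * dnorm(u, 0, sg), -Inf, Inf,
                      rel.tol = 1e-10)$value
      ll <- ll + log(mi)
    }
    -ll
  }
  op <- optim(c(0, 0, meghaz:::megh_theta_init(d, "pgw"), log(0.3)), meph_nll,
              method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  expect_equal(f$loglik, -op$value, tolerance = 1e-4)
})

test_that("MEGH-II at alpha = beta reproduces the mixed-AFT likelihood value", {
  d0 <- small_data(seed = 404)
  # identical covariates on both scales
  d <- megh_data(d0$time, d0$status, d0$cluster, d0$X, d0$X)
  bb <- c(0.6, -0.4)
  bl <- baseline_hazard("pgw", c(0.3, 1.3, 2.2))
  g <- re_dist("normal", 0.7)
  p <- megh_params(bb, bb, bl, g)

  aft_ll <- 0
  for (i in seq_len(d$r)) {
    rows <- d$idx[[i]]
    lp <- drop(d$X[rows, ] %*% bb)
    ev <- d$status[rows] == 1
    li <- function(u) {
      vapply(u, function(ui) {
        tu <- d$time[rows] * exp(lp + ui)
        exp(sum(bh_loghaz(bl, tu[ev]) + lp[ev] + ui) -
              sum(bh_cumhaz(bl, tu)))
      }, 0)
    }
    mi <- integrate(function(u) li(u) * re_density(g, u), -40, 40,
                    rel.tol = 1e-10)$value
    aft_ll <- aft_ll + log(mi)
  }
  expect_equal(marginal_loglik(d, p, "megh2"), aft_ll, tolerance = 1e-4)
})

test_that("estimator bias shrinks as the number of clusters grows", {
  s10 <- run_study(small_design(r = 10, size = 12), fit_structures = "megh1",
                   n_reps = 10, seed = 2024)
  s40 <- run_study(small_design(r = 40, size = 12), fit_structures = "megh1",
                   n_reps = 10, seed = 2024)
  b10 <- mean(abs(s10$bias$megh1))
  b40 <- mean(abs(s40$bias$megh1))
  expect_lt(b40, b10)
})
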