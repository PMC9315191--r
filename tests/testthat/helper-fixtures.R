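# shared fixtures: everything is generated in code, no stored data

# a representative positive parameter vector per baseline family
theta_for <- function(family) {
  switch(family,
         pgw = c(0.2, 1.5, 3.0),
         loglogistic = c(0.1, 0.8),
         lognormal = c(-0.2, 0.9),
         gamma = c(1.4, 0.7))
}

bh_families <- c("pgw", "loglogistic", "lognormal", "gamma")

# small clustered design for fast fitting tests
small_design <- function(sigma = 0.8, r = 10, size = 15,
                         structure = "megh1", baseline = "pgw",
                         censoring = 0.25) {
  sim_design(structure = structure,
             baseline = baseline_hazard(baseline, theta_for(baseline)),
             beta = c(x1 = 0.8, x2 = -0.5), alpha = c(x1 = 0.4),
             re = if (sigma > 0) re_dist("normal", sigma) else NULL,
             cluster_sizes = rep(size, r), censoring = censoring,
             covariates = function(n) {
               X <- cbind(x1 = stats::rnorm(n), x2 = stats::rbinom(n, 1, 0.5))
               list(X = X, Xtilde = X[, "x1", drop = FALSE])
             })
}

small_data <- function(seed = 101, ...) simulate_dataset(small_design(...), seed = seed)
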