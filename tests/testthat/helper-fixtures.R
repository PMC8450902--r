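# Shared fixtures: reference structural parameter sets and small synthetic
# data sets built in code.

# four-contrast synthetic data from the caffeine-loaded reference bilayer
make_caffeine_dataset <- function(seed, noise_rel = 0.02, n_points = 120) {
  generate_nr_dataset(synthetic_nr_spec(
    reference_bilayer("popc_caffeine"),
    noise_rel = noise_rel, n_points = n_points, seed = seed))
}

# the parameters the analysis floats for a guest-loaded bilayer (molecular
# constraints disabled): structural set plus the common roughness and the
# water gap
caf_free_params <- c("t_H", "t_C", "rho_H", "rho_C", "f_H", "f_C",
                     "sigma", "watergap_thickness")

make_caffeine_problem <- function(curves, start = reference_bilayer("popc")) {
  fit_problem(curves, bilayer_param_table(start, free = caf_free_params),
              background = 5e-7)
}

# quadratic objective fixture: weighted linear regression y = a + b x,
# with known analytic covariance; used to validate chi-square profiling
make_linear_fixture <- function(n = 25, a = 1.5, b = -0.7, sigma = 0.3,
                                seed = 42) {
  set.seed(seed)
  x <- seq(-1, 2, length.out = n)
  y <- a + b * x + rnorm(n, 0, sigma)
  X <- cbind(1, x)
  W <- diag(rep(1 / sigma^2, n))
  cov <- solve(t(X) %*% W %*% X)
  beta <- as.numeric(cov %*% t(X) %*% W %*% y)
  fn <- function(values)
    sum((y - values[["a"]] - values[["b"]] * x)^2 / sigma^2)
  table <- data.frame(name = c("a", "b"), value = beta,
                      min = c(-10, -10), max = c(10, 10), fixed = FALSE)
  list(fn = fn, table = table, beta = beta, se = sqrt(diag(cov)))
}
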