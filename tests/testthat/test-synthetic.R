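test_that("noiseless generation equals the forward model and is
           deterministic per seed", {
  truth <- reference_bilayer("popc")
  spec0 <- synthetic_nr_spec(truth, contrasts = c(1, 0.38), n_points = 50,
                             noise_rel = 0, seed = 1)
  curves <- generate_nr_dataset(spec0)
  st <- build_stack(truth, solvent(1))
  expect_equal(curves$D2O$R,
               model_reflectivity(st, curves$D2O$Q, dq_over_q = 0.05,
                                  background = 5e-7),
               tolerance = 1e-14)
  # default Q window matches the instrument configuration
  expect_equal(min(curves$D2O$Q), 0.008)
  expect_equal(max(curves$D2O$Q), 0.28)
  # same seed, same data; different seed, different noise
  s1 <- generate_nr_dataset(synthetic_nr_spec(truth, n_points = 40,
                                              seed = 33))
  s2 <- generate_nr_dataset(synthetic_nr_spec(truth, n_points = 40,
                                              seed = 33))
  s3 <- generate_nr_dataset(synthetic_nr_spec(truth, n_points = 40,
                                              seed = 34))
  expect_identical(s1, s2)
  expect_false(identical(s1$D2O$R, s3$D2O$R))
  # the recorded dR carries the background floor; in the noiseless case
  # it reduces to background / 3 exactly
  expect_equal(unique(curves$D2O$dR), 5e-7 / 3)
  expect_true(all(s1$D2O$dR > 0))
})

test_that("chi-square is zero on noiseless self-generated data and rises
           when a parameter is perturbed", {
  truth <- reference_bilayer("popc_caffeine")
  curves <- generate_nr_dataset(synthetic_nr_spec(
    truth, n_points = 60, noise_rel = 0, seed = 2))
  pr <- fit_problem(curves, bilayer_param_table(truth, free = caf_free_params),
                    background = 5e-7)
  v <- setNames(pr$params$value, pr$params$name)
  expect_equal(chi2(pr, v), 0, tolerance = 1e-16)
  for (pn in c("t_H", "t_C", "rho_C", "sigma")) {
    for (dd in c(-0.05, 0.05)) {
      vv <- v; vv[[pn]] <- vv[[pn]] + dd
      expect_gt(chi2(pr, vv), 0)
    }
  }
})

test_that("reduced chi-square is about one at truth under the generator's
           own noise model", {
  truth <- reference_bilayer("popc_caffeine")
  vals <- vapply(1:5, function(s) {
    curves <- generate_nr_dataset(synthetic_nr_spec(truth, seed = 400 + s))
    pr <- fit_problem(curves, bilayer_param_table(truth,
                                                  free = caf_free_params),
                      background = 5e-7)
    chi2(pr) / 480
  }, numeric(1))
  expect_lt(abs(mean(vals) - 1), 0.1)
})

test_that("fitting the generating model to noiseless data returns the
           truth (round-trip identity)", {
  truth <- reference_bilayer("popc_caffeine")
  curves <- generate_nr_dataset(synthetic_nr_spec(
    truth, n_points = 60, noise_rel = 0, seed = 3))
  # weight with the standard 2% uncertainty model: the weights do not
  # move the chi2 = 0 minimum but keep the objective well scaled
  curves <- lapply(curves, with_synthetic_dr)
  # start away from the truth, at the guest-free parameter set
  pr <- make_caffeine_problem(curves, start = reference_bilayer("popc"))
  res <- fit_reflectivity(pr, seed = 1, max_starts = 1)
  for (pn in c("t_H", "t_C", "rho_H", "rho_C", "f_H", "sigma"))
    expect_equal(res$best_values[[pn]], truth[[pn]], tolerance = 1e-3)
  expect_lt(res$chi2, 1e-4)
})

test_that("zero-noise constant QCM-D schedule gives an exactly constant
           trace; noisy generation is seed-deterministic", {
  stages <- data.frame(time = 0, label = "baseline", level = -24,
                       tau = 1e-6, spread = 0, dissipation = 0.2)
  spec <- synthetic_qcmd_spec(stages, duration = 10, noise_hz = 0,
                              seed = 9)
  tr <- generate_qcmd_trace(spec)
  for (nm in names(tr$df))
    expect_equal(unique(tr$df[[nm]] / as.integer(nm)), -24)
  spec2 <- synthetic_qcmd_spec(qcmd_schedule_slb(), duration = 20, seed = 8)
  expect_identical(generate_qcmd_trace(spec2), generate_qcmd_trace(spec2))
})

test_that("Delta-chi2 = 1 profile intervals have near-nominal coverage on
           a well-conditioned recovery problem", {
  # two contrasts, 60 points, three free structural parameters: a size at
  # which the Gaussian limit of the profile construction holds; in the
  # full 16-parameter problem boundary parameters and the degenerate
  # valley make Delta-chi2 = 1 intervals undercover
  truth <- reference_bilayer("popc_caffeine")
  start <- reference_bilayer("popc")
  hits <- logical(20); widths <- numeric(20)
  for (s in 1:20) {
    curves <- generate_nr_dataset(synthetic_nr_spec(
      truth, contrasts = c(1, 0), n_points = 60, seed = 200 + s))
    st <- truth
    st$t_H <- start$t_H; st$t_C <- start$t_C; st$rho_C <- start$rho_C
    pr <- fit_problem(curves,
                      bilayer_param_table(st,
                                          free = c("t_H", "t_C", "rho_C")),
                      float_scale = FALSE, float_background = FALSE,
                      background = 5e-7)
    f <- fit_reflectivity(pr, seed = s, max_starts = 1)
    iv <- profile_errors(pr, f, parameters = "t_H")
    hits[s] <- iv$low <= truth$t_H && truth$t_H <= iv$high
    widths[s] <- iv$high - iv$low
  }
  coverage <- mean(hits)
  expect_gte(coverage, 0.5)
  expect_lte(coverage, 0.9)
  # interval scale consistent with sub-angstrom headgroup precision:
  # half-widths around 0.1 A, the order of the reference +/- 0.2 A
  expect_gte(mean(widths) / 2, 0.05)
  expect_lte(mean(widths) / 2, 0.4)
})
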