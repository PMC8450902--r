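Qgrid <- exp(seq(log(0.008), log(0.28), length.out = 200))

test_that("no contrast means no reflection", {
  st <- slab_stack(6.35, 6.35)
  expect_equal(parratt_reflectivity(st, Qgrid), rep(0, length(Qgrid)))
})

test_that("total external reflection below the critical edge", {
  st <- slab_stack(2.07, 6.35)
  Qc <- critical_edge(2.07, 6.35)
  expect_equal(Qc, 4 * sqrt(pi * 4.28e-6), tolerance = 1e-12)
  below <- Qgrid[Qgrid < Qc]
  expect_true(all(parratt_reflectivity(st, below) >= 1 - 1e-12))
  above <- Qgrid[Qgrid > 1.05 * Qc]
  expect_true(all(parratt_reflectivity(st, above) < 1))
  # R -> 1 as Q -> 0+ also for a full bilayer stack in D2O
  stb <- build_stack(reference_bilayer("popc"), solvent(1))
  expect_equal(parratt_reflectivity(stb, 1e-4), 1, tolerance = 1e-9)
})

test_that("Parratt agrees with the Abeles transfer-matrix oracle", {
  set.seed(17)
  worst <- 0
  for (i in 1:100) {
    st <- random_stack()
    R1 <- parratt_reflectivity(st, Qgrid)
    R2 <- abeles_reflectivity(st, Qgrid)
    worst <- max(worst, max(abs(R1 - R2) / pmax(R2, 1e-300)))
  }
  expect_lt(worst, 1e-8)
})

test_that("zero-thickness and zero-contrast slabs leave R unchanged", {
  st <- slab_stack(2.07, 6.35, thickness = c(12, 30), sld = c(3.47, -0.29))
  R0 <- parratt_reflectivity(st, Qgrid)
  # zero-thickness slab of arbitrary SLD
  st1 <- slab_stack(2.07, 6.35, thickness = c(12, 0, 30),
                    sld = c(3.47, 5.1, -0.29))
  expect_equal(parratt_reflectivity(st1, Qgrid), R0, tolerance = 1e-12)
  # slab with the SLD of the backing medium only relabels where the
  # semi-infinite backing starts
  st2 <- slab_stack(2.07, 6.35, thickness = c(12, 30, 7),
                    sld = c(3.47, -0.29, 6.35))
  expect_equal(parratt_reflectivity(st2, Qgrid), R0, tolerance = 1e-12)
})

test_that("high-Q reflectivity approaches the kinematic limit", {
  Qc <- critical_edge(2.07, 6.35)
  Qh <- seq(5 * Qc, 8 * Qc, length.out = 30)
  for (s in c(0, 3)) {
    st <- slab_stack(2.07, 6.35, fronting_roughness = s)
    ratio <- parratt_reflectivity(st, Qh) / born_interface(2.07, 6.35, s, Qh)
    expect_true(all(abs(ratio - 1) < 0.05))
  }
})

test_that("Nevot-Croce and microsliced-profile paths agree", {
  # the analytic Nevot-Croce factor is a small-Q*sigma approximation of
  # the exact graded-interface reflectivity, so the cross-check is run
  # where Q*sigma <= about 0.9, and with a looser band across the full
  # instrument range
  for (nm in c("popc", "popc_caffeine")) {
    st <- build_stack(reference_bilayer(nm), solvent(1))
    R1 <- parratt_reflectivity(st, Qgrid)
    R2 <- microslice_reflectivity(st, Qgrid)
    sig <- max(c(st$roughness, st$fronting_roughness))
    core <- Qgrid * sig <= 0.9
    expect_lt(max(abs(R1 - R2)[core] / R2[core]), 0.005)
    expect_lt(max(abs(R1 - R2) / R2), 0.015)
  }
})

test_that("resolution smearing is exact at dq = 0 and damps fringes
           monotonically", {
  st <- slab_stack(2.07, 6.35, thickness = c(20, 30),
                   sld = c(3.47, -0.29))
  R0 <- parratt_reflectivity(st, Qgrid)
  expect_identical(smear_resolution(Qgrid, R0, 0), R0)
  # constant region unchanged by convolution: total-reflection plateau
  plateau <- Qgrid < 0.8 * critical_edge(2.07, 6.35)
  Rs <- smear_resolution(Qgrid, R0, 0.05)
  expect_equal(Rs[plateau], R0[plateau], tolerance = 1e-3)
  # Kiessig fringe amplitude strictly decreases with increasing dq/q
  fringe_amplitude <- function(R) {
    lR <- log10(R[Qgrid > 0.05])
    res <- lR - stats::filter(lR, rep(1 / 15, 15), sides = 2)
    diff(range(res[!is.na(res)]))
  }
  amps <- vapply(c(0.01, 0.03, 0.06, 0.1), function(dq)
    fringe_amplitude(model_reflectivity(st, Qgrid, dq_over_q = dq)),
    numeric(1))
  expect_true(all(diff(amps) < 0))
})

test_that("quadrature smearing matches a brute-force convolution", {
  st <- build_stack(reference_bilayer("popc"), solvent(1))
  Rq <- model_reflectivity(st, Qgrid, dq_over_q = 0.05)
  # brute force with the same +/- 3.5 sigma kernel support as the
  # quadrature (the truncation itself is a documented modelling choice)
  Rb <- smear_brute(function(q) parratt_reflectivity(st, q), Qgrid, 0.05,
                    span = 3.5)
  # agreement away from the critical edge, where the integrand kink
  # limits low-order quadrature
  sel <- Qgrid > 2 * critical_edge(2.07, 6.35)
  expect_lt(max(abs(Rq - Rb)[sel] / Rb[sel]), 0.005)
})

test_that("scale and background act affinely on the observed curve", {
  R <- c(1, 0.5, 1e-4, 1e-7)
  expect_identical(apply_scale_background(R), R)
  expect_equal(min(apply_scale_background(R, 1, 1e-6)), 1e-6 + 1e-7)
  expect_equal(apply_scale_background(R, 0.95, 0)[1], 0.95)
  expect_error(apply_scale_background(R, 0), "scale")
})
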