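test_that("build_stack assembles the six-slab geometry with leaflet symmetry", {
  st <- build_stack(reference_bilayer("popc"), solvent(1.0))
  expect_s3_class(st, "nr_slab_stack")
  expect_equal(st$names,
               c("oxide", "watergap", "inner_heads", "inner_tails",
                 "outer_tails", "outer_heads"))
  expect_equal(st$fronting_sld, 2.07)
  expect_equal(st$backing_sld, 6.35)
  # head slabs: 6.8 A, dry SLD 1.79, hydration 0.18 in both leaflets
  heads <- match(c("inner_heads", "outer_heads"), st$names)
  expect_equal(st$thickness[heads], c(6.8, 6.8))
  expect_equal(st$sld_dry[heads], c(1.79, 1.79))
  expect_equal(st$solvent_fraction[heads], c(0.18, 0.18))
  # tail slabs anhydrous at -0.29
  tails <- match(c("inner_tails", "outer_tails"), st$names)
  expect_equal(st$thickness[tails], c(15, 15))
  expect_equal(st$sld[tails], c(-0.29, -0.29))
  # effective SLD mixes dry SLD with solvent
  expect_equal(st$sld, st$sld_dry * (1 - st$solvent_fraction) +
                 6.35 * st$solvent_fraction)
  # water gap is pure solvent
  expect_equal(st$sld[st$names == "watergap"], 6.35)
  # purity: identical inputs give identical stacks
  expect_identical(st, build_stack(reference_bilayer("popc"), solvent(1.0)))
})

test_that("caffeine-loaded stack carries the raised tail SLD in any solvent", {
  st <- build_stack(reference_bilayer("popc_caffeine"), solvent(0.0))
  expect_equal(unique(st$sld[st$names %in%
                               c("inner_tails", "outer_tails")]), -0.25)
  expect_equal(st$backing_sld, -0.56)
})

test_that("degenerate zero-thickness bilayer reduces to substrate + oxide", {
  p <- bilayer_parameters(t_H = 0, t_C = 0, rho_H = 1.79, rho_C = -0.29,
                          f_H = 0, f_C = 0, sigma = 0,
                          watergap_thickness = 0)
  st <- build_stack(p, solvent(1))
  expect_equal(sum(st$thickness), p$oxide_thickness)
  Q <- seq(0.01, 0.25, length.out = 60)
  bare <- slab_stack(2.07, 6.35, thickness = p$oxide_thickness,
                     sld = st$sld[1], roughness = 0,
                     fronting_roughness = 0)
  expect_equal(parratt_reflectivity(st, Q), parratt_reflectivity(bare, Q),
               tolerance = 1e-12)
})

test_that("molecular constraints link area, thickness and hydration", {
  # reference arithmetic: area = V_tails / t_C, f_H = 1 - V_head/(area t_H)
  mc <- apply_molecular_constraints(t_C = 15.0, V_tails = 923,
                                    V_head = 332, t_H = 6.8)
  expect_equal(mc$area_per_lipid, 923 / 15, tolerance = 1e-12)
  expect_equal(mc$area_per_lipid, 61.5, tolerance = 1e-3)
  expect_equal(mc$f_H, 0.207, tolerance = 1e-2)
  # anhydrous headgroup limit: area * t_H == V_head
  t_H0 <- 332 / (923 / 15)
  expect_equal(apply_molecular_constraints(15, 923, 332, t_H0)$f_H, 0)
  # overfilled headgroup is rejected
  expect_error(apply_molecular_constraints(15, 923, 332, 0.8 * t_H0),
               "constraint")
  # doubling the tail volume doubles the area and raises hydration
  mc2 <- apply_molecular_constraints(15, 2 * 923, 332, 6.8)
  expect_equal(mc2$area_per_lipid, 2 * mc$area_per_lipid)
  expect_gt(mc2$f_H, mc$f_H)
})

test_that("constraint round-trip reproduces the head-slab effective SLD", {
  mc <- apply_molecular_constraints(15.0, 923, 332, 6.8)
  p <- bilayer_parameters(t_H = 6.8, t_C = 15, rho_H = 1.81, rho_C = -0.29,
                          f_H = mc$f_H, f_C = 0, sigma = 4.2)
  st <- build_stack(p, solvent(1))
  eff <- st$sld[st$names == "inner_heads"]
  area <- mc$area_per_lipid
  expect_equal(eff, 332 * 1.81 / (area * 6.8) + mc$f_H * 6.35,
               tolerance = 1e-12)
})

test_that("rendered profile has the right limits, sharp-interface shape and
           conserves total scattering length", {
  p <- reference_bilayer("popc_caffeine")
  st <- build_stack(p, solvent(1))
  pr <- render_profile(st, seq(-60, 140, by = 0.1))
  # far-field limits
  expect_equal(pr$sld[1], 2.07, tolerance = 1e-6)
  expect_equal(pr$sld[length(pr$sld)], 6.35, tolerance = 1e-6)
  # zero roughness reproduces the piecewise-constant slab profile
  p0 <- p; p0$sigma <- 0
  st0 <- build_stack(p0, solvent(1))
  z <- seq(-40, sum(st0$thickness) + 40, by = 0.01)
  pr0 <- render_profile(st0, z)
  pos <- cumsum(c(0, st0$thickness))
  rho <- c(st0$fronting_sld, st0$sld, st0$backing_sld)
  step <- rho[findInterval(z, pos) + 1]
  expect_equal(pr0$sld, step, tolerance = 1e-12)
  # error-function smoothing conserves the integral of (profile - step);
  # the bound reflects the grid-alignment error of the discrete sum
  # (about dz * delta_rho / 2 per interface), far below the sigma *
  # delta_rho scale a genuine conservation violation would produce
  prs <- render_profile(st, z)
  expect_lt(abs(sum(prs$sld - step) * 0.01), 0.05)
  # bilayer extent matches d_B = 2 (t_H + t_C) = 39.4 A
  expect_equal(2 * (p$t_H + p$t_C), 39.4, tolerance = 1e-12)
  expect_error(render_profile(st, c(1, 1, 2)), "increasing")
})
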