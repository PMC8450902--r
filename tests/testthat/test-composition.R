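test_that("SLD mixing inversion recovers the guest volume fraction", {
  # reference numbers: tails at -0.25 vs pure -0.29, caffeine 3.3
  phi <- guest_volume_fraction(-0.25, -0.29, 3.3)
  expect_equal(phi, 0.04 / 3.59, tolerance = 1e-12)
  expect_equal(round(phi, 3), 0.011)
  # endpoints
  expect_equal(guest_volume_fraction(-0.29, -0.29, 3.3), 0)
  expect_equal(guest_volume_fraction(3.3, -0.29, 3.3), 1)
  # round trip with forward mixing for arbitrary phi
  for (p in c(0, 0.013, 0.2, 0.77, 1)) {
    mix <- p * 3.3 + (1 - p) * (-0.29)
    expect_equal(guest_volume_fraction(mix, -0.29, 3.3), p,
                 tolerance = 1e-12)
  }
  # inconsistent hypothesis is flagged
  expect_warning(guest_volume_fraction(-0.35, -0.29, 3.3),
                 class = "nr_inconsistent_composition")
  expect_error(guest_volume_fraction(1, 2, 2), "differ")
})

test_that("mole-percent conversion reproduces the caffeine loading", {
  phi <- guest_volume_fraction(-0.25, -0.29, 3.3)
  mp <- guest_mole_percent(phi, 194, 923)
  expect_equal(round(mp$mol_percent, 1), 5.1)
  expect_gt(mp$lipids_per_guest, 18)
  expect_lt(mp$lipids_per_guest, 19)
  # no guest
  mp0 <- guest_mole_percent(0, 194, 923)
  expect_equal(mp0$mol_percent, 0)
  expect_equal(mp0$lipids_per_guest, Inf)
  # doubling the guest volume halves the mole ratio
  expect_equal(guest_mole_percent(0.0111, 2 * 194, 923)$r,
               guest_mole_percent(0.0111, 194, 923)$r / 2,
               tolerance = 1e-12)
  expect_error(guest_mole_percent(1, 194, 923), "degenerate")
})

test_that("guest share of the total bilayer volume", {
  expect_equal(round(100 * guest_total_volume_fraction(
    r = 0.0536, V_guest = 194, V_lipid = 1256), 1), 0.8)
  expect_equal(guest_total_volume_fraction(r = 0, V_guest = 194,
                                           V_lipid = 1256), 0)
  expect_equal(guest_total_volume_fraction(r = 1, V_guest = 1256,
                                           V_lipid = 1256), 0.5)
})

test_that("bilayer thickness doubles the per-leaflet sums", {
  expect_equal(bilayer_thickness(6.8, 15.0), 43.6)
  expect_equal(bilayer_thickness(5.3, 14.4), 39.4)
  expect_equal(round(bilayer_thickness(5.3, 14.4)), 39)
  expect_equal(bilayer_thickness(0, 0), 0)
})

test_that("composition_report chains the full quantification", {
  rep <- composition_report(reference_bilayer("popc_caffeine"),
                            rho_mix_sd = 0.05)
  expect_equal(round(rep$mol_percent, 1), 5.1)
  expect_equal(round(100 * rep$phi_guest_total, 1), 0.8)
  expect_equal(rep$d_B, 39.4)
  expect_gt(rep$lipids_per_guest, 18)
  expect_lt(rep$lipids_per_guest, 19)
  # first-order error propagation from the SLD uncertainty
  expect_equal(rep$phi_guest_core_sd, 0.05 / 3.59, tolerance = 1e-12)
  expect_gt(rep$mol_percent_sd, 0)
  # whole-lipid host unit is exposed as an option and gives a smaller
  # mole percent for the same volume fraction
  rep2 <- composition_report(reference_bilayer("popc_caffeine"),
                             host_unit = "lipid")
  expect_gt(rep2$mol_percent, rep$mol_percent)
})

test_that("component profiles normalise to one and keep each in [0, 1]", {
  p <- reference_bilayer("popc_caffeine")
  geo <- component_geometry(p, guest = list(rho = 3.3, width = 10,
                                            phi = 0.03))
  z <- seq(-20, 2 * (p$t_H + p$t_C) + 20, by = 0.25)
  pr <- build_component_profiles(geo, z, solvent_sld = 6.35)
  expect_lt(max(abs(rowSums(pr$fractions) - 1)), 1e-12)
  expect_true(all(pr$fractions >= -1e-12 & pr$fractions <= 1 + 1e-12))
  # the guest lives strictly inside the tail support
  guest <- pr$fractions[, "guest"]
  tails <- pr$fractions[, "tails"] + guest
  expect_true(all(guest <= tails + 1e-12))
  # zero-width guest changes nothing
  geo0 <- component_geometry(p, guest = list(rho = 3.3, width = 0,
                                             phi = 0.03))
  pr0 <- build_component_profiles(geo0, z, solvent_sld = 6.35)
  prn <- build_component_profiles(component_geometry(p), z,
                                  solvent_sld = 6.35)
  expect_equal(pr0$sld, prn$sld, tolerance = 1e-12)
  # overlapping components are rejected with a position
  bad <- component_geometry(p)
  bad$amplitude <- c(1, 1.2, 1)
  expect_error(build_component_profiles(bad, z, 6.35), "exceed 1 at z")
})

test_that("tail-volume bookkeeping: integral of the tail profile matches
           two leaflets per unit cell", {
  p <- reference_bilayer("popc")
  mc <- apply_molecular_constraints(p$t_C, 923, 332, p$t_H)
  # an anhydrous tail box of width 2 t_C and amplitude 1
  geo <- component_geometry(p)
  z <- seq(-30, 2 * (p$t_H + p$t_C) + 30, by = 0.01)
  pr <- build_component_profiles(geo, z, solvent_sld = 6.35)
  vol <- sum(pr$fractions[, "tails"]) * 0.01 * mc$area_per_lipid
  expect_equal(vol, 2 * 923, tolerance = 1e-3)
})

test_that("component-profile and slab renderings of one structure agree", {
  p <- reference_bilayer("popc_caffeine")
  d_B <- 2 * (p$t_H + p$t_C)
  z <- seq(-25, d_B + 25, by = 0.25)
  for (fr in c(1.0, 0.0)) {
    sld_s <- mix_solvent(fr)
    comp <- build_component_profiles(component_geometry(p), z, sld_s)
    # equivalent free-floating-bilayer stack: solvent fronting/backing
    st <- slab_stack(sld_s, sld_s,
                     thickness = c(p$t_H, 2 * p$t_C, p$t_H),
                     sld = c(p$rho_H * (1 - p$f_H) + sld_s * p$f_H,
                             p$rho_C * (1 - p$f_C) + sld_s * p$f_C,
                             p$rho_H * (1 - p$f_H) + sld_s * p$f_H),
                     roughness = p$sigma, fronting_roughness = p$sigma)
    slab <- render_profile(st, z)
    scale <- diff(range(slab$sld))
    expect_lt(max(abs(comp$sld - slab$sld)) / scale, 0.005)
  }
})

test_that("preparation stoichiometry gives the nominal loading", {
  mp <- preparation_mole_percent(0.14, 194.19, 10, 760.1)
  expect_equal(round(mp), 5)
  expect_equal(preparation_mole_percent(0, 194.19, 10, 760.1), 0)
})
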