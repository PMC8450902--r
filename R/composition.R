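#' Guest volume fraction from linear SLD mixing
#'
#' Inverts the linear mixing rule for the dry SLD of a host region
#' containing a dissolved guest:
#' `phi = (rho_mix - rho_host) / (rho_guest - rho_host)`.
#'
#' @param rho_mix Fitted SLD of the mixed region (1e-6 A^-2).
#' @param rho_host SLD of the pure host component.
#' @param rho_guest SLD of the pure guest.
#' @return Volume fraction of guest.  A value outside `[0, 1]` is returned
#'   with a warning of class `nr_inconsistent_composition`, signalling a
#'   physically inconsistent host/guest hypothesis.
#' @export
#' @examples
#' guest_volume_fraction(-0.25, -0.29, 3.3)  # approx 0.011
guest_volume_fraction <- function(rho_mix, rho_host, rho_guest) {
  if (rho_guest == rho_host)
    stop("rho_guest must differ from rho_host")
  phi <- (rho_mix - rho_host) / (rho_guest - rho_host)
  if (phi < 0 || phi > 1)
    warning(warningCondition(
      sprintf("guest volume fraction %.4g outside [0, 1]: host/guest hypothesis physically inconsistent", phi),
      class = "nr_inconsistent_composition"))
  phi
}

#' Guest mole percent and lipids per guest
#'
#' Converts a guest volume fraction of the host region into a mole ratio
#' using the molecular volumes: `(phi / V_guest) / ((1 - phi) / V_host)`
#' gives the guest-per-lipid ratio `r`, with one host volume per lipid.
#' Then
#' `mol% = 100 r / (1 + r)` and `lipids_per_guest = 1 / r`.
#'
#' @param phi Guest volume fraction of the host region, in `[0, 1)`.
#' @param V_guest Guest molecular volume (A^3).
#' @param V_host Host volume per lipid in the region considered (A^3);
#'   the tail volume when the guest sits in the anhydrous core.
#' @return List with `mol_percent`, `lipids_per_guest` and the mole ratio
#'   `r` (guest per lipid).
#' @export
#' @examples
#' guest_mole_percent(0.0111, 194, 923)
guest_mole_percent <- function(phi, V_guest, V_host) {
  stopifnot(V_guest > 0, V_host > 0)
  if (phi < 0 || phi >= 1) {
    if (phi == 1) stop("phi = 1 is a degenerate composition (pure guest)")
    stop("phi must lie in [0, 1)")
  }
  r <- (phi / V_guest) / ((1 - phi) / V_host)
  list(mol_percent = 100 * r / (1 + r),
       lipids_per_guest = if (r > 0) 1 / r else Inf,
       r = r)
}

#' Guest share of the total bilayer volume
#'
#' @param mol_percent Guest mole percent (guest / (guest + lipid) * 100),
#'   or alternatively pass the mole ratio `r` directly.
#' @param V_guest Guest molecular volume (A^3).
#' @param V_lipid Whole-lipid molecular volume (A^3).
#' @param r Mole ratio guest per lipid; overrides `mol_percent`.
#' @return Fraction of total bilayer volume occupied by the guest.
#' @export
#' @examples
#' guest_total_volume_fraction(r = 0.0536, V_guest = 194, V_lipid = 1256)
guest_total_volume_fraction <- function(mol_percent = NULL, V_guest, V_lipid,
                                        r = NULL) {
  stopifnot(V_guest > 0, V_lipid > 0)
  if (is.null(r)) {
    stopifnot(mol_percent >= 0, mol_percent < 100)
    r <- mol_percent / (100 - mol_percent)
  }
  stopifnot(r >= 0)
  r * V_guest / (V_lipid + r * V_guest)
}

#' Total bilayer thickness
#'
#' `d_B = 2 (t_H + t_C)` for a symmetric bilayer.
#'
#' @param t_H Headgroup-region thickness per leaflet (A).
#' @param t_C Tail-region thickness per leaflet (A).
#' @return Thickness in A.
#' @export
#' @examples
#' bilayer_thickness(6.8, 15.0)  # 43.6
bilayer_thickness <- function(t_H, t_C) {
  stopifnot(t_H >= 0, t_C >= 0)
  2 * (t_H + t_C)
}

#' Mole percent from preparation masses
#'
#' Stoichiometry of the sample preparation: the guest mole percent
#' obtained by co-dissolving `mass_guest` of guest with `mass_host` of
#' lipid.
#'
#' @param mass_guest,mass_host Masses (same units).
#' @param M_guest,M_host Molar masses (g/mol).
#' @return Guest mole percent.
#' @export
#' @examples
#' preparation_mole_percent(0.14, 194.19, 10, 760.1)  # approx 5
preparation_mole_percent <- function(mass_guest, M_guest, mass_host, M_host) {
  stopifnot(mass_guest >= 0, mass_host > 0, M_guest > 0, M_host > 0)
  n_g <- mass_guest / M_guest
  n_h <- mass_host / M_host
  100 * n_g / (n_g + n_h)
}

#' Full composition report for a guest-loaded bilayer
#'
#' Chains the quantification steps: invert linear SLD mixing on the fitted
#' tail SLD, convert to mole percent and lipids-per-guest with the
#' molecular volumes, derive the guest's share of the total bilayer
#' volume, and the total bilayer thickness.  Optionally propagates a
#' 1-sigma uncertainty on the fitted mixed SLD to the derived quantities
#' (first order).
#'
#' @param params [bilayer_parameters()] of the guest-loaded fit (uses
#'   `rho_C`, `t_H`, `t_C`).
#' @param rho_host SLD of the pure host tails (1e-6 A^-2).
#' @param rho_guest SLD of the guest.
#' @param V_guest,V_tails,V_lipid Molecular volumes (A^3): guest, host
#'   tails (the default host unit, since the guest resides in the
#'   anhydrous core), whole lipid.
#' @param host_unit `"tails"` (default) or `"lipid"`: volume used as the
#'   per-lipid host unit in the mole-ratio conversion.
#' @param rho_mix_sd Optional 1-sigma uncertainty on the fitted `rho_C`.
#' @return Object of class `nr_composition_report`.
#' @export
#' @examples
#' composition_report(reference_bilayer("popc_caffeine"))
composition_report <- function(params, rho_host = -0.29, rho_guest = 3.3,
                               V_guest = 194, V_tails = 923, V_lipid = 1256,
                               host_unit = c("tails", "lipid"),
                               rho_mix_sd = NULL) {
  host_unit <- match.arg(host_unit)
  V_host <- if (host_unit == "tails") V_tails else V_lipid
  rho_mix <- params$rho_C
  phi <- guest_volume_fraction(rho_mix, rho_host, rho_guest)
  mp <- guest_mole_percent(phi, V_guest, V_host)
  total <- guest_total_volume_fraction(r = mp$r, V_guest = V_guest,
                                       V_lipid = V_lipid)
  out <- list(
    phi_guest_core = phi,
    phi_guest_total = total,
    mol_percent = mp$mol_percent,
    lipids_per_guest = mp$lipids_per_guest,
    d_B = bilayer_thickness(params$t_H, params$t_C),
    rho_mix = rho_mix, rho_host = rho_host, rho_guest = rho_guest,
    V_guest = V_guest, V_tails = V_tails, V_lipid = V_lipid,
    host_unit = host_unit
  )
  if (!is.null(rho_mix_sd)) {
    dphi <- rho_mix_sd / abs(rho_guest - rho_host)
    # d(mol%)/dphi = 100 * dr/dphi / (1+r)^2 with r = phi/(1-phi) * Vh/Vg
    drdphi <- (V_host / V_guest) / (1 - phi)^2
    dmol <- 100 * drdphi / (1 + mp$r)^2 * dphi
    out$phi_guest_core_sd <- dphi
    out$mol_percent_sd <- dmol
    out$lipids_per_guest_sd <- if (mp$r > 0) drdphi * dphi / mp$r^2 else NA
  }
  class(out) <- "nr_composition_report"
  out
}

#' @export
print.nr_composition_report <- function(x, ...) {
  cat("<composition report>\n")
  fmt <- function(v, sdv, digits) {
    if (!is.null(sdv)) sprintf("%.*f +/- %.*f", digits, v, digits, sdv)
    else sprintf("%.*f", digits, v)
  }
  sd_pct <- if (is.null(x$phi_guest_core_sd)) NULL else
    100 * x$phi_guest_core_sd
  cat("  guest volume fraction of core : ",
      fmt(100 * x$phi_guest_core, sd_pct, 1), " %\n", sep = "")
  cat(sprintf("  guest fraction of total volume: %.1f %%\n",
              100 * x$phi_guest_total))
  cat("  guest mole percent            : ",
      fmt(x$mol_percent, x$mol_percent_sd, 1), " mol %\n", sep = "")
  cat(sprintf("  lipids per guest molecule     : %.1f\n", x$lipids_per_guest))
  cat(sprintf("  bilayer thickness d_B         : %.1f A\n", x$d_B))
  invisible(x)
}

#' @export
format.nr_composition_report <- function(x, ...) {
  c(sprintf("phi_guest_core      %.4f", x$phi_guest_core),
    sprintf("phi_guest_total     %.4f", x$phi_guest_total),
    sprintf("mol_percent         %.2f", x$mol_percent),
    sprintf("lipids_per_guest    %.2f", x$lipids_per_guest),
    sprintf("d_B                 %.2f", x$d_B))
}

# ---- component-group volume-fraction profiles ----

#' Component-group geometry from bilayer parameters
#'
#' Builds the component-profile geometry equivalent to the slab model: a
#' headgroup box per leaflet of amplitude `1 - f_H`, one tail box of
#' amplitude `1 - f_C` spanning both leaflets, all sharing the fitted
#' roughness.  z = 0 sits at the solvent-side edge of the inner headgroup
#' region.
#'
#' @param params [bilayer_parameters()].
#' @param rho_head_dry,rho_tail_dry Dry SLDs of the components
#'   (1e-6 A^-2); default the fitted `rho_H`, `rho_C`.
#' @param guest Optional list `list(rho, width, phi)` describing a guest
#'   distribution centred on the bilayer midplane: a step of width `width`
#'   (A) and amplitude `phi`, smoothed by the common roughness, carved out
#'   of the tail component.
#' @return `data.frame` geometry for [build_component_profiles()].
#' @export
component_geometry <- function(params, rho_head_dry = params$rho_H,
                               rho_tail_dry = params$rho_C, guest = NULL) {
  p <- params
  g <- data.frame(
    component = c("heads_inner", "tails", "heads_outer"),
    rho = c(rho_head_dry, rho_tail_dry, rho_head_dry),
    center = c(p$t_H / 2, p$t_H + p$t_C, p$t_H + 2 * p$t_C + p$t_H / 2),
    width = c(p$t_H, 2 * p$t_C, p$t_H),
    sigma = p$sigma,
    amplitude = c(1 - p$f_H, 1 - p$f_C, 1 - p$f_H),
    carve_from = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(guest)) {
    g <- rbind(g, data.frame(
      component = "guest", rho = guest$rho,
      center = p$t_H + p$t_C, width = guest$width, sigma = p$sigma,
      amplitude = guest$phi, carve_from = "tails",
      stringsAsFactors = FALSE))
  }
  g
}

# smoothed box profile: two error-function edges
erf_box <- function(z, center, width, sigma, amplitude) {
  lo <- center - width / 2
  hi <- center + width / 2
  if (width <= 0) return(rep(0, length(z)))
  if (sigma > 0)
    amplitude * (pnorm((z - lo) / sigma) - pnorm((z - hi) / sigma))
  else
    amplitude * as.numeric(z >= lo & z < hi)
}

#' Component-group volume-fraction profiles
#'
#' Renders each component as a box smoothed by error-function edges (two
#' symmetric error functions connected by a central step of the given
#' width).  A component with `carve_from` set displaces that much volume
#' from its parent component (a guest dissolved in the tails).  Water
#' fills the complement to 1 everywhere, so the volume fractions sum to
#' one by construction; if the named components alone exceed 1 anywhere,
#' an overlap error reports the z position.
#'
#' @param geometry `data.frame` with columns `component`, `rho`, `center`,
#'   `width`, `sigma`, `amplitude` and optionally `carve_from` (see
#'   [component_geometry()]).
#' @param z Depth grid (A).
#' @param solvent_sld Solvent SLD (1e-6 A^-2) used for the water component
#'   and the synthetic SLD profile.
#' @return List with `z`, `fractions` (matrix, one column per component
#'   plus `water`) and `sld` (the reconstructed SLD profile
#'   `sum(phi_i * rho_i) + phi_w * rho_solvent`).
#' @export
#' @examples
#' geo <- component_geometry(reference_bilayer("popc"))
#' pr <- build_component_profiles(geo, seq(-10, 55, 0.5), solvent_sld = 6.35)
#' range(rowSums(pr$fractions))
build_component_profiles <- function(geometry, z, solvent_sld) {
  stopifnot(all(c("component", "rho", "center", "width", "sigma",
                  "amplitude") %in% names(geometry)))
  if (is.null(geometry$carve_from)) geometry$carve_from <- NA_character_
  n <- nrow(geometry)
  profs <- matrix(0, length(z), n,
                  dimnames = list(NULL, geometry$component))
  for (i in seq_len(n))
    profs[, i] <- erf_box(z, geometry$center[i], geometry$width[i],
                          geometry$sigma[i], geometry$amplitude[i])
  for (i in which(!is.na(geometry$carve_from))) {
    parent <- match(geometry$carve_from[i], geometry$component)
    if (is.na(parent)) stop("carve_from refers to unknown component")
    profs[, parent] <- profs[, parent] - profs[, i]
    if (any(profs[, parent] < -1e-9))
      stop("guest profile exceeds its parent component at z = ",
           signif(z[which.min(profs[, parent])], 4))
    profs[profs[, parent] < 0, parent] <- 0
  }
  total <- rowSums(profs)
  if (any(total > 1 + 1e-9))
    stop("component volume fractions exceed 1 at z = ",
         signif(z[which.max(total)], 4), " (sum = ",
         signif(max(total), 6), ")")
  water <- 1 - total
  fractions <- cbind(profs, water = water)
  sld <- as.numeric(profs %*% geometry$rho) + water * solvent_sld
  list(z = z, fractions = fractions, sld = sld)
}
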