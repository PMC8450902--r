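#' Structural parameters of a supported bilayer
#'
#' Bundles the parameters of the six-slab model of a solid-supported
#' bilayer: native oxide, a water gap, and a symmetric bilayer split into
#' headgroup and hydrophobic (tail) regions.  The two leaflets share
#' (`t_H`, `t_C`, `rho_H`, `rho_C`, `f_H`, `f_C`), i.e. the bilayer is
#' symmetric about the centre of the hydrophobic core, and one roughness
#' `sigma` is common to all interfaces.
#'
#' @param t_H Headgroup-region thickness per leaflet (A).
#' @param t_C Hydrophobic (tail) region thickness per leaflet (A).
#' @param rho_H Dry headgroup SLD (1e-6 A^-2).
#' @param rho_C Dry tail SLD (1e-6 A^-2).
#' @param f_H Water volume fraction of the headgroup region, in `[0, 1]`.
#' @param f_C Water volume fraction of the tail region, in `[0, 1]`.
#' @param sigma Interfacial roughness common to all interfaces (A),
#'   the Gaussian width of the error-function transition.
#' @param oxide_thickness,oxide_sld,oxide_hydration Native SiO2 layer:
#'   thickness (A), dry SLD (1e-6 A^-2), water volume fraction.  These are
#'   normally fixed from a bare-substrate measurement.
#' @param watergap_thickness Thickness of the pure-solvent layer between
#'   oxide and bilayer (A).
#' @return Object of class `nr_bilayer_parameters` (a named list).
#' @seealso [build_stack()], [reference_bilayer()]
#' @export
bilayer_parameters <- function(t_H, t_C, rho_H, rho_C, f_H, f_C, sigma,
                               oxide_thickness = 12, oxide_sld = 3.47,
                               oxide_hydration = 0.12,
                               watergap_thickness = 3) {
  p <- list(t_H = t_H, t_C = t_C, rho_H = rho_H, rho_C = rho_C,
            f_H = f_H, f_C = f_C, sigma = sigma,
            oxide_thickness = oxide_thickness, oxide_sld = oxide_sld,
            oxide_hydration = oxide_hydration,
            watergap_thickness = watergap_thickness)
  validate_bilayer_parameters(p)
  class(p) <- "nr_bilayer_parameters"
  p
}

validate_bilayer_parameters <- function(p) {
  thick <- c("t_H", "t_C", "sigma", "oxide_thickness", "watergap_thickness")
  frac <- c("f_H", "f_C", "oxide_hydration")
  for (nm in thick)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop(nm, " must be nonnegative")
  for (nm in frac)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
      stop(nm, " must lie in [0, 1]")
  invisible(p)
}

#' @export
print.nr_bilayer_parameters <- function(x, ...) {
  cat("<bilayer parameters>\n")
  cat(sprintf("  t_H = %.2f A   t_C = %.2f A   d_B = %.2f A\n",
              x$t_H, x$t_C, 2 * (x$t_H + x$t_C)))
  cat(sprintf("  rho_H = %.3f   rho_C = %.3f (1e-6 A^-2)\n",
              x$rho_H, x$rho_C))
  cat(sprintf("  f_H = %.3f   f_C = %.3f   sigma = %.2f A\n",
              x$f_H, x$f_C, x$sigma))
  cat(sprintf("  oxide: %.1f A, SLD %.2f, hydration %.2f; water gap %.1f A\n",
              x$oxide_thickness, x$oxide_sld, x$oxide_hydration,
              x$watergap_thickness))
  invisible(x)
}

#' Reference bilayer parameter sets
#'
#' Built-in structural parameter sets for a POPC supported bilayer at
#' 28 C, with and without 5 mol% caffeine preloaded in the hydrophobic
#' core.  They serve as worked-example inputs and as ground truth for the
#' synthetic-data generator.
#'
#' @param which `"popc"` (t_H 6.8 A, t_C 15.0 A, rho_C -0.29) or
#'   `"popc_caffeine"` (t_H 5.3 A, t_C 14.4 A, rho_C -0.25, the tail SLD
#'   raised by the dissolved guest).
#' @return An [bilayer_parameters()] object.
#' @export
#' @examples
#' reference_bilayer("popc_caffeine")
reference_bilayer <- function(which = c("popc", "popc_caffeine")) {
  which <- match.arg(which)
  switch(which,
    popc = bilayer_parameters(
      t_H = 6.8, t_C = 15.0, rho_H = 1.79, rho_C = -0.29,
      f_H = 0.18, f_C = 0, sigma = 4.2),
    popc_caffeine = bilayer_parameters(
      t_H = 5.3, t_C = 14.4, rho_H = 1.8, rho_C = -0.25,
      f_H = 0.26, f_C = 0, sigma = 5.7))
}

#' Build a slab stack for a supported bilayer
#'
#' Assembles the fixed-order stack silicon / oxide / water gap / inner
#' heads / inner tails / outer tails / outer heads / solvent.  Each slab
#' carries thickness, dry SLD, solvent fraction and the roughness of its
#' upper (solvent-side) interface; the effective SLD is
#' `sld_dry * (1 - f) + sld_solvent * f`.  Leaflet symmetry is enforced by
#' construction.
#'
#' @param params [bilayer_parameters()] object.
#' @param solv [solvent()] object (or a bare SLD in 1e-6 A^-2).
#' @return Object of class `nr_slab_stack` with fields `fronting_sld`,
#'   `fronting_roughness`, `names`, `thickness`, `sld_dry`,
#'   `solvent_fraction`, `roughness`, `sld` (effective) and `backing_sld`.
#' @export
#' @examples
#' build_stack(reference_bilayer("popc"), solvent(1.0))
build_stack <- function(params, solv) {
  validate_bilayer_parameters(params)
  sld_s <- if (inherits(solv, "nr_solvent")) solv$sld else as.numeric(solv)
  p <- params
  thickness <- c(p$oxide_thickness, p$watergap_thickness,
                 p$t_H, p$t_C, p$t_C, p$t_H)
  sld_dry <- c(p$oxide_sld, sld_s, p$rho_H, p$rho_C, p$rho_C, p$rho_H)
  f <- c(p$oxide_hydration, 1, p$f_H, p$f_C, p$f_C, p$f_H)
  out <- list(
    fronting_sld = .SLD_SI,
    fronting_roughness = p$sigma,
    names = c("oxide", "watergap", "inner_heads", "inner_tails",
              "outer_tails", "outer_heads"),
    thickness = thickness,
    sld_dry = sld_dry,
    solvent_fraction = f,
    roughness = rep(p$sigma, 6L),
    sld = sld_dry * (1 - f) + sld_s * f,
    backing_sld = sld_s
  )
  class(out) <- "nr_slab_stack"
  out
}

#' Construct a slab stack directly
#'
#' Low-level constructor for arbitrary stratified media (used for bare
#' substrates, test fixtures and microsliced profiles).  Slabs are listed
#' from the fronting (incident) medium toward the backing medium; each
#' slab's `roughness` describes its upper (backing-side) interface, and
#' `fronting_roughness` the fronting/first-slab interface.
#'
#' @param fronting_sld,backing_sld Semi-infinite medium SLDs (1e-6 A^-2).
#' @param thickness,sld Numeric vectors of slab thicknesses (A) and
#'   effective SLDs (1e-6 A^-2); may be empty for a bare interface.
#' @param roughness Roughness (A) per slab upper interface; recycled.
#' @param fronting_roughness Roughness of the fronting interface (A).
#' @param names Optional slab labels.
#' @return `nr_slab_stack` object.
#' @export
#' @examples
#' slab_stack(2.07, 6.35)  # bare Si/D2O interface
slab_stack <- function(fronting_sld, backing_sld,
                       thickness = numeric(0), sld = numeric(0),
                       roughness = 0, fronting_roughness = 0,
                       names = NULL) {
  n <- length(thickness)
  stopifnot(length(sld) == n, all(thickness >= 0))
  roughness <- rep_len(roughness, n)
  stopifnot(all(roughness >= 0), fronting_roughness >= 0)
  out <- list(
    fronting_sld = fronting_sld,
    fronting_roughness = fronting_roughness,
    names = if (is.null(names)) paste0("slab", seq_len(n)) else names,
    thickness = as.numeric(thickness),
    sld_dry = as.numeric(sld),
    solvent_fraction = rep(0, n),
    roughness = as.numeric(roughness),
    sld = as.numeric(sld),
    backing_sld = backing_sld
  )
  class(out) <- "nr_slab_stack"
  out
}

#' @export
print.nr_slab_stack <- function(x, ...) {
  cat(sprintf("<slab stack> fronting SLD %.3f (sigma %.2f A)\n",
              x$fronting_sld, x$fronting_roughness))
  if (length(x$thickness)) {
    df <- data.frame(slab = x$names, thickness = x$thickness,
                     sld_dry = x$sld_dry, f_solvent = x$solvent_fraction,
                     sld_eff = x$sld, roughness = x$roughness)
    print(df, row.names = FALSE, digits = 4)
  }
  cat(sprintf("backing SLD %.3f\n", x$backing_sld))
  invisible(x)
}

#' Molecular constraints of the bilayer model
#'
#' Links the tail- and headgroup-region parameters through mass
#' conservation: with one lipid per leaflet unit cell and an anhydrous
#' hydrophobic core, the area per lipid is `A = V_tails / t_C`, and the
#' headgroup hydration follows from volume filling,
#' `f_H = 1 - V_head / (A * t_H)`.
#'
#' @param t_C Tail-region thickness per leaflet (A).
#' @param V_tails Tail moiety volume per lipid (A^3).
#' @param V_head Dry headgroup volume per lipid (A^3).
#' @param t_H Headgroup-region thickness (A).
#' @return List with `area_per_lipid` (A^2) and `f_H`.
#' @export
#' @examples
#' apply_molecular_constraints(t_C = 15.0, V_tails = 923,
#'                             V_head = 332, t_H = 6.8)
apply_molecular_constraints <- function(t_C, V_tails, V_head, t_H) {
  stopifnot(t_C > 0, V_tails > 0, V_head > 0, t_H > 0)
  area <- V_tails / t_C
  fill <- V_head / (area * t_H)
  if (fill > 1 + 1e-12)
    stop("headgroup volume exceeds available slab volume ",
         "(V_head > area * t_H): constraint violated")
  list(area_per_lipid = area, f_H = max(0, 1 - fill))
}

#' Render the SLD depth profile of a stack
#'
#' Builds the continuous scattering length density profile rho(z) by
#' summing error-function transitions at the cumulative interface
#' positions; each interface of Gaussian width sigma contributes
#' `delta_rho * Phi((z - z0)/sigma)` with `Phi` the standard normal CDF
#' (equivalently `0.5 * (1 + erf((z - z0)/(sigma * sqrt(2))))`).
#' z = 0 sits at the fronting/first-slab (silicon/oxide) interface and z
#' increases toward the solvent.
#'
#' @param stack `nr_slab_stack` object.
#' @param z Strictly increasing grid of depths (A).  Defaults to 0.5 A
#'   spacing spanning the stack plus a margin.
#' @return List with `z` and `sld` (1e-6 A^-2).
#' @export
#' @examples
#' pr <- render_profile(build_stack(reference_bilayer("popc"), solvent(1)))
#' range(pr$sld)
render_profile <- function(stack, z = NULL) {
  total <- sum(stack$thickness)
  sig_all <- c(stack$fronting_roughness, stack$roughness)
  margin <- max(10, 4 * max(sig_all, 1))
  if (is.null(z))
    z <- seq(-margin, total + margin, by = 0.5)
  if (any(diff(z) <= 0)) stop("z grid must be strictly increasing")
  pos <- cumsum(c(0, stack$thickness))          # one position per interface
  rho <- c(stack$fronting_sld, stack$sld, stack$backing_sld)
  out <- rep(rho[1], length(z))
  for (i in seq_along(pos)) {
    dr <- rho[i + 1] - rho[i]
    if (dr == 0) next
    s <- sig_all[i]
    step <- if (s > 0) pnorm((z - pos[i]) / s) else as.numeric(z >= pos[i])
    out <- out + dr * step
  }
  list(z = z, sld = out)
}
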