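#' Solvent SLD from isotopic composition
#'
#' The SLD of a D2O/H2O mixture interpolates linearly between the pure-water
#' endpoints, -0.56 and 6.35 (1e-6 A^-2).  This is the contrast-variation
#' dial of the experiment: silicon-matched water (SiMW) is a 38:62 mixture
#' and four-matched water (4MW) a 66:34 mixture by volume.
#'
#' @param fraction_d2o Volume fraction of D2O in `[0, 1]`.
#' @return SLD in 1e-6 A^-2.
#' @export
#' @examples
#' mix_solvent(0.38)  # silicon-matched water, approx 2.07
#' mix_solvent(0.66)  # four-matched water, approx 4.0
mix_solvent <- function(fraction_d2o) {
  if (!is.numeric(fraction_d2o) || any(!is.finite(fraction_d2o)) ||
      any(fraction_d2o < 0) || any(fraction_d2o > 1))
    stop("fraction_d2o must lie in [0, 1]")
  fraction_d2o * .SLD_D2O + (1 - fraction_d2o) * .SLD_H2O
}

#' Invert the solvent mixing rule
#'
#' Returns the D2O volume fraction whose mixture SLD equals `target_sld`.
#' Inverse of [mix_solvent()]; used to design contrasts that match a given
#' component (e.g. crystalline silicon at 2.07).
#'
#' @param target_sld Desired solvent SLD in 1e-6 A^-2; must lie between the
#'   H2O and D2O endpoints.
#' @return D2O volume fraction in `[0, 1]`.
#' @export
#' @examples
#' match_point(2.07)  # approx 0.38
match_point <- function(target_sld) {
  if (!is.numeric(target_sld) || any(!is.finite(target_sld)) ||
      any(target_sld < .SLD_H2O) || any(target_sld > .SLD_D2O))
    stop("target_sld must lie within [", .SLD_H2O, ", ", .SLD_D2O, "]")
  (target_sld - .SLD_H2O) / (.SLD_D2O - .SLD_H2O)
}

#' Define a solvent
#'
#' @param fraction_d2o D2O volume fraction; ignored when `sld` is given
#'   directly.
#' @param sld Optional direct SLD (1e-6 A^-2); the equivalent D2O fraction
#'   is back-computed when it is within the achievable range.
#' @return Object of class `nr_solvent` with fields `fraction_d2o`, `sld`.
#' @export
#' @examples
#' solvent(1.0)   # D2O
#' solvent(0.38)  # SiMW
solvent <- function(fraction_d2o = NULL, sld = NULL) {
  if (is.null(sld)) {
    sld <- mix_solvent(fraction_d2o)
  } else if (is.null(fraction_d2o)) {
    fraction_d2o <- if (sld >= .SLD_H2O && sld <= .SLD_D2O)
      match_point(sld) else NA_real_
  }
  structure(list(fraction_d2o = fraction_d2o, sld = sld),
            class = "nr_solvent")
}

#' @export
print.nr_solvent <- function(x, ...) {
  cat(sprintf("<solvent> %.0f%% D2O, SLD = %.3f e-6 A^-2\n",
              100 * x$fraction_d2o, x$sld))
  invisible(x)
}

# canonical contrast label for a D2O fraction
contrast_label <- function(fraction_d2o) {
  known <- c(D2O = 1.0, `4MW` = 0.66, SiMW = 0.38, H2O = 0.0)
  hit <- which(abs(known - fraction_d2o) < 1e-9)
  if (length(hit)) names(known)[hit[1]] else sprintf("d2o%03.0f",
                                                     100 * fraction_d2o)
}
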