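# run expr with a locally-set RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of a synthetic multi-contrast NR data set
#'
#' Defines the ground truth and measurement conditions emulated by
#' [generate_nr_dataset()].  Defaults reproduce the study conditions: four
#' water contrasts (D2O, 4MW, SiMW, H2O), Q from 0.008 to 0.28 A^-1 on a
#' 120-point logarithmic grid (approximating time-of-flight binning), 2%
#' relative Gaussian noise, a 5e-7 background and 5% dQ/Q resolution.
#'
#' @param truth [bilayer_parameters()] ground truth.
#' @param contrasts D2O volume fractions, one per contrast.
#' @param q_min,q_max,n_points Q grid.
#' @param noise_rel Relative noise level (0 disables noise injection).
#' @param background Constant background added to each curve.
#' @param dq_over_q Fractional resolution width.
#' @param scale Measurement scale factor.
#' @param seed Required integer seed.
#' @return Object of class `nr_synthetic_nr_spec`.
#' @export
synthetic_nr_spec <- function(truth,
                              contrasts = c(1.0, 0.66, 0.38, 0.0),
                              q_min = 0.008, q_max = 0.28, n_points = 120,
                              noise_rel = 0.02, background = 5e-7,
                              dq_over_q = 0.05, scale = 1, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(noise_rel >= 0, q_min > 0, q_max > q_min, n_points >= 2)
  structure(list(truth = truth, contrasts = contrasts, q_min = q_min,
                 q_max = q_max, n_points = n_points, noise_rel = noise_rel,
                 background = background, dq_over_q = dq_over_q,
                 scale = scale, seed = as.integer(seed)),
            class = "nr_synthetic_nr_spec")
}

#' Generate a synthetic multi-contrast NR data set
#'
#' Forward-models each contrast through the slab model and the
#' reflectivity engine (resolution smearing, scale, background), then adds
#' Gaussian noise of width `sigma = noise_rel * R + background / 3`; the
#' `dR` column records the sigma used.  Deterministic for a given seed;
#' with `noise_rel = 0` the curves equal the forward model exactly.
#'
#' @param spec [synthetic_nr_spec()].
#' @return Named list of `nr_reflectivity_curve`, one per contrast.
#' @export
#' @examples
#' spec <- synthetic_nr_spec(reference_bilayer("popc"),
#'                           contrasts = c(1, 0), n_points = 40, seed = 7)
#' curves <- generate_nr_dataset(spec)
#' names(curves)
generate_nr_dataset <- function(spec) {
  stopifnot(inherits(spec, "nr_synthetic_nr_spec"))
  Q <- exp(seq(log(spec$q_min), log(spec$q_max),
               length.out = spec$n_points))
  with_local_seed(spec$seed, {
    curves <- lapply(spec$contrasts, function(fr) {
      st <- build_stack(spec$truth, solvent(fr))
      Rm <- model_reflectivity(st, Q, dq_over_q = spec$dq_over_q,
                               scale = spec$scale,
                               background = spec$background)
      sig <- spec$noise_rel * Rm + spec$background / 3
      Robs <- if (spec$noise_rel > 0)
        pmax(Rm + rnorm(length(Q), 0, sig), 0) else Rm
      reflectivity_curve(Q, Robs, dR = sig, dQ = spec$dq_over_q,
                         contrast = contrast_label(fr), fraction_d2o = fr)
    })
    names(curves) <- vapply(curves, function(cu) cu$contrast, character(1))
    curves
  })
}

#' Specification of a synthetic QCM-D trace
#'
#' A piecewise-exponential stage schedule: at each stage start the
#' normalised frequency shift of every overtone relaxes toward the stage
#' target with the stage time constant.  During soft (vesicle, incubation)
#' stages the overtones split by `spread`; in rigid stages they overlap.
#'
#' @param stages `data.frame` with columns `time` (stage start, min),
#'   `label`, `level` (target dF/n, Hz), `tau` (min), `spread` (full
#'   overtone spread, Hz) and `dissipation` (target, 1e-6 units).
#' @param duration Total record length (min).
#' @param overtones Odd overtone numbers.
#' @param noise_hz Gaussian noise on the raw frequency shifts (Hz).
#' @param sample_period Sampling interval in seconds (2 s by default).
#' @param seed Required integer seed.
#' @return Object of class `nr_synthetic_qcmd_spec`.
#' @export
synthetic_qcmd_spec <- function(stages, duration = NULL,
                                overtones = c(3, 5, 7, 9, 11, 13),
                                noise_hz = 0.05, sample_period = 2, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(is.data.frame(stages), nrow(stages) >= 1,
            all(diff(stages$time) > 0), all(is.finite(stages$level)),
            all(overtones %% 2 == 1))
  if (is.null(duration)) duration <- max(stages$time) + 30
  structure(list(stages = stages, duration = duration,
                 overtones = overtones, noise_hz = noise_hz,
                 sample_period = sample_period, seed = as.integer(seed)),
            class = "nr_synthetic_qcmd_spec")
}

#' Stage schedule emulating successful vesicle fusion
#'
#' Baseline in water, vesicle adsorption after injection (split overtones,
#' high dissipation), rupture to a rigid bilayer at -24 Hz triggered by
#' the osmotic shock at t = 12.5 min, then rinsing with no further change.
#'
#' @return Stage `data.frame` for [synthetic_qcmd_spec()].
#' @export
qcmd_schedule_slb <- function() {
  data.frame(
    time = c(0, 10, 12.5, 62.5),
    label = c("baseline", "vesicle injection", "osmotic shock", "rinse"),
    level = c(0, -30, -24, -24),
    tau = c(0.1, 0.8, 0.4, 0.5),
    spread = c(0, 4, 0, 0),
    dissipation = c(0.1, 3, 0.2, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Stage schedule emulating a reversible incubation
#'
#' Baseline, a split-overtone excursion while a concentrated solution of
#' the guest is incubated in stopped flow, and full return to baseline
#' upon rinsing.
#'
#' @param incubation_min Length of the incubation stage (min).
#' @return Stage `data.frame` for [synthetic_qcmd_spec()].
#' @export
qcmd_schedule_reversible <- function(incubation_min = 100) {
  data.frame(
    time = c(0, 15, 15 + incubation_min),
    label = c("baseline", "guest injection", "rinse"),
    level = c(0, -4, 0),
    tau = c(0.1, 1, 1),
    spread = c(0, 3, 0),
    dissipation = c(0.1, 1.5, 0.1),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic QCM-D trace
#'
#' @param spec [synthetic_qcmd_spec()].
#' @return `nr_qcmd_trace` with events taken from the stage labels.
#' @export
#' @examples
#' spec <- synthetic_qcmd_spec(qcmd_schedule_slb(), duration = 90, seed = 3)
#' tr <- generate_qcmd_trace(spec)
generate_qcmd_trace <- function(spec) {
  stopifnot(inherits(spec, "nr_synthetic_qcmd_spec"))
  t <- seq(0, spec$duration, by = spec$sample_period / 60)
  m <- length(spec$overtones)
  offsets <- if (m > 1) seq(-0.5, 0.5, length.out = m) else 0
  relax <- function(targets) {
    # piecewise exponential relaxation of one scalar signal toward the
    # per-stage targets
    y <- numeric(length(t))
    cur <- targets[1]
    for (s in seq_len(nrow(spec$stages))) {
      t0 <- spec$stages$time[s]
      t1 <- if (s < nrow(spec$stages)) spec$stages$time[s + 1] else Inf
      sel <- t >= t0 & t < t1
      if (!any(sel)) next
      tau <- max(spec$stages$tau[s], 1e-6)
      y[sel] <- targets[s] + (cur - targets[s]) * exp(-(t[sel] - t0) / tau)
      cur <- targets[s] + (cur - targets[s]) *
        exp(-(min(t1, max(t)) - t0) / tau)
    }
    y
  }
  with_local_seed(spec$seed, {
    df <- list(); dd <- list()
    for (i in seq_len(m)) {
      n <- spec$overtones[i]
      targets <- spec$stages$level + spec$stages$spread * offsets[i]
      norm <- relax(targets)
      raw <- norm * n
      if (spec$noise_hz > 0)
        raw <- raw + rnorm(length(t), 0, spec$noise_hz)
      df[[as.character(n)]] <- raw
      dtarget <- relax(spec$stages$dissipation)
      if (spec$noise_hz > 0)
        dtarget <- pmax(dtarget + rnorm(length(t), 0, 0.02), 0)
      dd[[as.character(n)]] <- dtarget
    }
    qcmd_trace(t, df, dd,
               events = data.frame(time = spec$stages$time,
                                   label = spec$stages$label,
                                   stringsAsFactors = FALSE))
  })
}
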