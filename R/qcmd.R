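# Sauerbrey mass sensitivity constant, ng cm^-2 Hz^-1, for a 5 MHz sensor.
.SAUERBREY_C <- 17.7

#' A QCM-D time trace
#'
#' Frequency shifts and dissipation per overtone versus time, with labelled
#' events (injections, rinses).  Dissipation is stored in units of 1e-6
#' (the usual instrument export convention).
#'
#' @param time Time in minutes.
#' @param df Named list of frequency-shift arrays, one per overtone; names
#'   are the odd overtone numbers (`"3"`, `"5"`, ...).  Values are the raw
#'   (not normalised) shifts in Hz.
#' @param dissipation Named list of dissipation arrays (1e-6 units),
#'   matching `df` in names; may be `NULL` entries when not recorded.
#' @param events `data.frame` with columns `time`, `label`.
#' @return Object of class `nr_qcmd_trace`.
#' @export
qcmd_trace <- function(time, df, dissipation = NULL,
                       events = data.frame(time = numeric(0),
                                           label = character(0))) {
  stopifnot(is.numeric(time), length(df) >= 1)
  ns <- suppressWarnings(as.integer(names(df)))
  if (any(is.na(ns)) || any(ns <= 0) || any(ns %% 2 == 0))
    stop("overtone names must be odd positive integers")
  for (nm in names(df))
    if (length(df[[nm]]) != length(time))
      stop("overtone ", nm, " length differs from time axis")
  if (!is.null(dissipation))
    for (nm in names(dissipation))
      if (!is.null(dissipation[[nm]]) &&
          length(dissipation[[nm]]) != length(time))
        stop("dissipation ", nm, " length differs from time axis")
  structure(list(time = time, df = df, dissipation = dissipation,
                 events = events),
            class = "nr_qcmd_trace")
}

#' @export
print.nr_qcmd_trace <- function(x, ...) {
  cat(sprintf("<QCM-D trace> %d points over %.1f min, overtones %s, %d event(s)\n",
              length(x$time), diff(range(x$time)),
              paste(names(x$df), collapse = ","), nrow(x$events)))
  invisible(x)
}

#' Normalised frequency shifts
#'
#' @param trace `nr_qcmd_trace`.
#' @return Matrix of `delta F_n / n`, one column per overtone.
#' @export
normalized_shifts <- function(trace) {
  ns <- as.integer(names(trace$df))
  out <- vapply(seq_along(ns), function(i) trace$df[[i]] / ns[i],
                numeric(length(trace$time)))
  colnames(out) <- names(trace$df)
  out
}

#' Sauerbrey mass of a rigid film
#'
#' `dm = -C_f * dF_n / n` with `C_f = 17.7 ng/(cm^2 Hz)` for a 5 MHz
#' sensor.  Mass uptake (negative frequency shift) is reported positive.
#'
#' @param dF_n Frequency shift of the n-th overtone (Hz).  With the
#'   default `n = 1`, pass the already-normalised shift `dF/n`.
#' @param n Overtone number (odd positive integer).
#' @return Areal mass in ng/cm^2.
#' @export
#' @examples
#' sauerbrey_mass(-25)       # 442.5 ng/cm^2
#' sauerbrey_mass(-120, 5)   # same normalised shift as dF_3 = -72
sauerbrey_mass <- function(dF_n, n = 1) {
  if (!is.numeric(n) || length(n) != 1 || n <= 0 || n != round(n) ||
      n %% 2 == 0)
    stop("overtone n must be an odd positive integer")
  -.SAUERBREY_C * dF_n / n
}

#' Rigid-film validity check
#'
#' The Sauerbrey relation holds for rigid films, recognised by overlapping
#' normalised frequency shifts across overtones together with low
#' dissipation.  The verdict is true iff the spread of the time-averaged
#' `dF_n/n` across overtones within the window is at most `df_tolerance`
#' and the mean dissipation is at most `d_max`.
#'
#' @param trace `nr_qcmd_trace` with at least two overtones.
#' @param window Time interval `c(from, to)` in minutes; default the full
#'   record.
#' @param df_tolerance Maximum allowed overtone spread (Hz).
#' @param d_max Maximum allowed mean dissipation (1e-6 units).
#' @return List with `rigid` (logical), `spread` (Hz),
#'   `mean_dissipation`, and the per-overtone means.
#' @export
rigidity_check <- function(trace, window = range(trace$time),
                           df_tolerance = 1, d_max = 1) {
  if (length(trace$df) < 2)
    stop("rigidity check needs at least two overtones")
  sel <- trace$time >= window[1] & trace$time <= window[2]
  if (!any(sel)) stop("empty time window")
  norm <- normalized_shifts(trace)[sel, , drop = FALSE]
  means <- colMeans(norm)
  spread <- max(means) - min(means)
  mean_d <- if (is.null(trace$dissipation)) NA_real_ else
    mean(vapply(trace$dissipation, function(d)
      if (is.null(d)) NA_real_ else mean(d[sel]), numeric(1)), na.rm = TRUE)
  rigid <- spread <= df_tolerance &&
    (is.na(mean_d) || mean_d <= d_max)
  list(rigid = rigid, spread = spread, mean_dissipation = mean_d,
       overtone_means = means)
}

# local slopes (Hz/min) of y(t) by linear regression in a centred window
rolling_slope <- function(t, y, half_width) {
  n <- length(t)
  vapply(seq_len(n), function(i) {
    sel <- t >= t[i] - half_width & t <= t[i] + half_width
    if (sum(sel) < 2) return(0)
    tt <- t[sel]; yy <- y[sel]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, numeric(1))
}

#' Detect plateaus in a QCM-D trace
#'
#' Finds maximal time segments where the overtone-averaged normalised
#' frequency shift drifts slower than `slope_tol` for at least
#' `min_duration`.  Each plateau is labelled with its mean level and the
#' nearest preceding event.
#'
#' @param trace `nr_qcmd_trace`.
#' @param slope_tol Maximum absolute drift (Hz/min).
#' @param min_duration Minimum plateau length (min).
#' @param slope_window Window (min) over which the local slope is
#'   estimated by linear regression.
#' @return `data.frame` with columns `start`, `end`, `mean_shift`,
#'   `preceding_event` (possibly zero rows).
#' @export
detect_plateau <- function(trace, slope_tol = 0.1, min_duration = 10,
                           slope_window = 2) {
  t <- trace$time
  y <- rowMeans(normalized_shifts(trace))
  flat <- abs(rolling_slope(t, y, slope_window / 2)) <= slope_tol
  runs <- rle(flat)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  out <- lapply(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    if (t[i1] - t[i0] < min_duration) return(NULL)
    prev <- trace$events$label[trace$events$time <= t[i0]]
    data.frame(start = t[i0], end = t[i1],
               mean_shift = mean(y[i0:i1]),
               preceding_event = if (length(prev)) prev[length(prev)]
                                 else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(start = numeric(0), end = numeric(0),
                      mean_shift = numeric(0),
                      preceding_event = character(0))
  out
}

#' Summary classification of a QCM-D experiment
#'
#' Convenience wrapper combining plateau detection, the rigid-film check
#' on the final plateau, and the Sauerbrey mass of its mean level.  Also
#' reports whether the record returned to its initial baseline (a
#' reversible excursion) by comparing the first and last plateau means.
#'
#' @param trace `nr_qcmd_trace`.
#' @param df_tolerance,d_max,slope_tol,min_duration See
#'   [rigidity_check()] and [detect_plateau()].
#' @return List with `plateaus`, `final_rigidity`, `final_mass_ng_cm2`,
#'   `reversible` and `classification` (one of `"SLB formed, rigid"`,
#'   `"reversible, returns to baseline"`, `"adsorbed, not rigid"`,
#'   `"no stable state"`).
#' @export
qcmd_analyze <- function(trace, df_tolerance = 1, d_max = 1,
                         slope_tol = 0.1, min_duration = 10) {
  pl <- detect_plateau(trace, slope_tol = slope_tol,
                       min_duration = min_duration)
  if (nrow(pl) == 0)
    return(list(plateaus = pl, final_rigidity = NULL,
                final_mass_ng_cm2 = NA_real_, reversible = NA,
                classification = "no stable state"))
  last <- pl[nrow(pl), ]
  rig <- rigidity_check(trace, window = c(last$start, last$end),
                        df_tolerance = df_tolerance, d_max = d_max)
  mass <- sauerbrey_mass(last$mean_shift)
  reversible <- abs(last$mean_shift - pl$mean_shift[1]) <= df_tolerance
  classification <-
    if (reversible && abs(last$mean_shift) <= df_tolerance)
      "reversible, returns to baseline"
    else if (rig$rigid) "SLB formed, rigid"
    else "adsorbed, not rigid"
  list(plateaus = pl, final_rigidity = rig, final_mass_ng_cm2 = mass,
       reversible = reversible, classification = classification)
}
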