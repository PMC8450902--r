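#' Default parameter bounds for bilayer fits
#'
#' Box bounds used when a parameter is freed without explicit limits.
#' Units: thicknesses and roughness in A, SLDs in 1e-6 A^-2, fractions
#' dimensionless.
#'
#' @return Named list of `c(min, max)` pairs.
#' @export
default_bounds <- function() {
  list(t_H = c(3, 12), t_C = c(8, 25),
       rho_H = c(0.5, 3), rho_C = c(-0.6, 1.5),
       f_H = c(0, 0.6), f_C = c(0, 0.2), sigma = c(1, 10),
       oxide_thickness = c(5, 25), oxide_sld = c(3.0, 3.8),
       oxide_hydration = c(0, 0.4), watergap_thickness = c(0, 12))
}

#' Parameter table for a bilayer model
#'
#' Expands a [bilayer_parameters()] object into the value/min/max/fixed
#' table consumed by [fit_problem()].  Parameters not listed in `free` are
#' held fixed (the usual treatment of substrate parameters determined from
#' a bare-substrate measurement).
#'
#' @param params Starting [bilayer_parameters()].
#' @param free Character vector of parameters allowed to vary.
#' @param bounds Named list of `c(min, max)` overrides; defaults from
#'   [default_bounds()].
#' @return `data.frame` with columns `name`, `value`, `min`, `max`,
#'   `fixed`.
#' @export
bilayer_param_table <- function(params,
                                free = c("t_H", "t_C", "rho_H", "rho_C",
                                         "f_H", "sigma",
                                         "watergap_thickness"),
                                bounds = NULL) {
  b <- modifyList(default_bounds(), if (is.null(bounds)) list() else bounds)
  nms <- c("t_H", "t_C", "rho_H", "rho_C", "f_H", "f_C", "sigma",
           "oxide_thickness", "oxide_sld", "oxide_hydration",
           "watergap_thickness")
  unknown <- setdiff(free, nms)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  data.frame(
    name = nms,
    value = vapply(nms, function(n) params[[n]], numeric(1)),
    min = vapply(nms, function(n) b[[n]][1], numeric(1)),
    max = vapply(nms, function(n) b[[n]][2], numeric(1)),
    fixed = !(nms %in% free),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Attach synthetic uncertainties to a curve
#'
#' Assigns `dR = noise_rel * R + background / 3`, the uncertainty model of
#' the synthetic-data generator, to a curve measured or simulated without
#' error bars so that chi-square fitting is possible.
#'
#' @param curve `nr_reflectivity_curve`.
#' @param noise_rel Relative noise level.
#' @param background Background level contributing a constant floor.
#' @return The curve with `dR` set.
#' @export
with_synthetic_dr <- function(curve, noise_rel = 0.02, background = 5e-7) {
  curve$dR <- noise_rel * pmax(curve$R, 0) + background / 3
  curve
}

#' Define a multi-contrast co-refinement problem
#'
#' Couples one structural model to several reflectivity curves measured on
#' the same sample in different isotopic contrasts.  Per-contrast scale
#' and background are free nuisance parameters by default; the solvent SLD
#' of each contrast may additionally float within +/- 0.2e-6 A^-2 to
#' absorb imperfect solvent exchange.
#'
#' @param curves List of `nr_reflectivity_curve`, each with `dR` and with
#'   its solvent identified by `fraction_d2o` (or via `solvent_slds`).
#' @param model Parameter table from [bilayer_param_table()].
#' @param solvent_slds Optional numeric vector of solvent SLDs
#'   (1e-6 A^-2), one per curve; defaults to [mix_solvent()] of each
#'   curve's `fraction_d2o`.
#' @param dq_over_q Fractional resolution width used for curves that carry
#'   no per-point `dQ`.
#' @param float_scale,float_background,float_solvent Whether the
#'   per-contrast nuisance parameters vary during the fit.
#' @param scale,background Starting values for the nuisance parameters.
#' @return Object of class `nr_fit_problem`.
#' @export
fit_problem <- function(curves, model, solvent_slds = NULL,
                        dq_over_q = 0.05,
                        float_scale = TRUE, float_background = TRUE,
                        float_solvent = FALSE,
                        scale = 1, background = 1e-6) {
  if (inherits(curves, "nr_reflectivity_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1)
  for (i in seq_along(curves)) {
    if (!inherits(curves[[i]], "nr_reflectivity_curve"))
      stop("curves[[", i, "]] is not a reflectivity curve")
    if (is.null(curves[[i]]$dR))
      stop("curve ", i, " has no dR uncertainties; attach synthetic ",
           "uncertainties with with_synthetic_dr() before fitting")
  }
  if (is.null(solvent_slds)) {
    fr <- vapply(curves, function(cu) cu$fraction_d2o, numeric(1))
    if (any(is.na(fr)))
      stop("curves lack fraction_d2o; supply solvent_slds explicitly")
    solvent_slds <- mix_solvent(fr)
  }
  stopifnot(length(solvent_slds) == length(curves))
  nc <- length(curves)
  scale <- rep_len(scale, nc)
  background <- rep_len(background, nc)
  nuisance <- data.frame(
    name = c(paste0("scale_", seq_len(nc)),
             paste0("background_", seq_len(nc)),
             paste0("dsolv_", seq_len(nc))),
    value = c(scale, background, rep(0, nc)),
    min = c(rep(0.5, nc), rep(0, nc), rep(-0.2, nc)),
    max = c(rep(1.5, nc), rep(1e-5, nc), rep(0.2, nc)),
    fixed = c(rep(!float_scale, nc), rep(!float_background, nc),
              rep(!float_solvent, nc)),
    stringsAsFactors = FALSE
  )
  structure(list(params = rbind(model, nuisance), curves = curves,
                 solvent_slds = solvent_slds, dq_over_q = dq_over_q,
                 n_contrasts = nc),
            class = "nr_fit_problem")
}

#' @export
print.nr_fit_problem <- function(x, ...) {
  cat(sprintf("<fit problem> %d contrast(s), %d points, %d free / %d parameters\n",
              x$n_contrasts, sum(vapply(x$curves, function(cu) length(cu$Q),
                                        integer(1))),
              sum(!x$params$fixed), nrow(x$params)))
  invisible(x)
}

problem_values <- function(problem) {
  setNames(problem$params$value, problem$params$name)
}

# model curves for one parameter vector; returns list of R_model per contrast
problem_model_curves <- function(problem, values) {
  base <- as.list(values[c("t_H", "t_C", "rho_H", "rho_C", "f_H", "f_C",
                           "sigma", "oxide_thickness", "oxide_sld",
                           "oxide_hydration", "watergap_thickness")])
  lapply(seq_len(problem$n_contrasts), function(i) {
    cu <- problem$curves[[i]]
    sld_s <- problem$solvent_slds[i] + values[[paste0("dsolv_", i)]]
    st <- build_stack(base, sld_s)
    dq <- if (!is.null(cu$dQ)) {
      if (length(cu$dQ) == 1) cu$dQ * cu$Q else cu$dQ
    } else problem$dq_over_q * cu$Q
    model_reflectivity(st, cu$Q, dq_over_q = dq,
                       scale = values[[paste0("scale_", i)]],
                       background = values[[paste0("background_", i)]])
  })
}

#' Chi-square of a co-refinement problem
#'
#' Sums `((R_model - R_data) / dR)^2` over all contrasts and points; the
#' model includes resolution smearing, scale and background.
#'
#' @param problem `nr_fit_problem`.
#' @param values Named parameter vector; defaults to the problem's current
#'   values.
#' @return Scalar chi-square.
#' @export
chi2 <- function(problem, values = NULL) {
  if (is.null(values)) values <- problem_values(problem)
  mods <- problem_model_curves(problem, values)
  total <- 0
  for (i in seq_len(problem$n_contrasts)) {
    cu <- problem$curves[[i]]
    total <- total + sum(((mods[[i]] - cu$R) / cu$dR)^2)
  }
  total
}

# weighted residual vector of a co-refinement problem, concatenated over
# contrasts; chi2 = sum(residuals^2)
problem_residuals <- function(problem) {
  function(values) {
    mods <- problem_model_curves(problem, values)
    unlist(lapply(seq_along(mods), function(i)
      (mods[[i]] - problem$curves[[i]]$R) / problem$curves[[i]]$dR),
      use.names = FALSE)
  }
}

# ---- generic bounded multi-start optimiser (works in the unit box) ----

default_opt_control <- function() {
  list(rel.tol = 1e-10, x.tol = 1e-12, eval.max = 20000, iter.max = 500)
}

# bounded Levenberg-Marquardt with restarts until the deviance stops
# improving; used whenever the objective is a sum of squared residuals
polished_lm <- function(par, fres, polish = 4) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                     ptol = 1e-12, maxfev = 20000)
  res <- minpack.lm::nls.lm(par = par, lower = rep(0, length(par)),
                            upper = rep(1, length(par)), fn = fres,
                            control = ctrl)
  for (k in seq_len(polish)) {
    prev <- res$deviance
    res2 <- minpack.lm::nls.lm(par = res$par, lower = rep(0, length(par)),
                               upper = rep(1, length(par)), fn = fres,
                               control = ctrl)
    if (res2$deviance <= res$deviance) res <- res2
    if (prev - res$deviance < 1e-10 * max(1, prev)) break
  }
  list(par = res$par, objective = res$deviance,
       convergence = if (res$info %in% 1:4) 0L else 1L)
}

# nlminb with polish restarts: quasi-Newton runs with finite-difference
# gradients can stall in narrow curved valleys; restarting from the
# incumbent until the objective stops improving recovers full convergence
polished_nlminb <- function(par, fn, control, polish = 6) {
  res <- nlminb(par, fn, lower = 0, upper = 1, control = control)
  for (k in seq_len(polish)) {
    prev <- res$objective
    res2 <- nlminb(res$par, fn, lower = 0, upper = 1, control = control)
    if (res2$objective <= res$objective) res <- res2
    if (prev - res$objective < 1e-10 * max(1, prev)) break
  }
  res
}

optimize_multistart <- function(fn, table, seed = NULL, max_starts = 3,
                                control = default_opt_control(),
                                polish = 6, resid_fn = NULL) {
  free <- !table$fixed
  fixed_vals <- setNames(table$value, table$name)
  lo <- table$min[free]; hi <- table$max[free]
  span <- hi - lo
  to_unit <- function(v) (v - lo) / span
  from_unit <- function(u) lo + u * span
  wrap <- function(u) {
    vals <- fixed_vals
    vals[table$name[free]] <- from_unit(u)
    fn(vals)
  }
  wrap_res <- if (is.null(resid_fn)) NULL else function(u) {
    vals <- fixed_vals
    vals[table$name[free]] <- from_unit(u)
    resid_fn(vals)
  }
  if (!any(free)) {
    return(list(values = fixed_vals, objective = fn(fixed_vals),
                converged = TRUE, n_starts = 0, start_objectives = numeric(0)))
  }
  starts <- list(to_unit(table$value[free]))
  if (max_starts > 1) {
    if (!is.null(seed)) set.seed(seed)
    for (s in seq_len(max_starts - 1))
      starts[[s + 1]] <- runif(sum(free))
  }
  best <- NULL
  objs <- numeric(length(starts))
  for (s in seq_along(starts)) {
    res <- if (is.null(wrap_res))
      polished_nlminb(starts[[s]], wrap, control, polish = polish)
    else polished_lm(starts[[s]], wrap_res, polish = polish)
    objs[s] <- res$objective
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  vals <- fixed_vals
  vals[table$name[free]] <- from_unit(best$par)
  list(values = vals, objective = best$objective,
       converged = best$convergence == 0, n_starts = length(starts),
       start_objectives = objs)
}

#' Fit a co-refinement problem
#'
#' Bounded local optimisation (PORT/`nlminb` in a scaled unit box) from
#' the supplied start point plus `max_starts - 1` additional random starts
#' drawn inside the bounds; the best optimum over all starts is returned.
#' Deterministic for a given `seed`.
#'
#' @param problem `nr_fit_problem`.
#' @param seed Integer seed for the random restarts.
#' @param max_starts Total number of starts (first is the table's values).
#' @param control Control list passed to [nlminb()].
#' @return Object of class `nr_fit_result` with `best_values` (full named
#'   vector), `parameters` (the structural subset as
#'   [bilayer_parameters()]), `chi2`, `reduced_chi2`, `n_points`,
#'   `n_free`, `converged`.
#' @export
fit_reflectivity <- function(problem, seed = 1, max_starts = 3,
                             control = default_opt_control()) {
  stopifnot(inherits(problem, "nr_fit_problem"))
  fn <- function(values) chi2(problem, values)
  opt <- optimize_multistart(fn, problem$params, seed = seed,
                             max_starts = max_starts, control = control,
                             resid_fn = problem_residuals(problem))
  n_points <- sum(vapply(problem$curves, function(cu) length(cu$Q),
                         integer(1)))
  n_free <- sum(!problem$params$fixed)
  pv <- opt$values
  pars <- bilayer_parameters(
    t_H = pv[["t_H"]], t_C = pv[["t_C"]], rho_H = pv[["rho_H"]],
    rho_C = pv[["rho_C"]], f_H = pv[["f_H"]], f_C = pv[["f_C"]],
    sigma = pv[["sigma"]], oxide_thickness = pv[["oxide_thickness"]],
    oxide_sld = pv[["oxide_sld"]], oxide_hydration = pv[["oxide_hydration"]],
    watergap_thickness = pv[["watergap_thickness"]])
  structure(list(best_values = pv, parameters = pars, chi2 = opt$objective,
                 reduced_chi2 = opt$objective / max(1, n_points - n_free),
                 n_points = n_points, n_free = n_free,
                 converged = opt$converged, seed = seed,
                 n_starts = opt$n_starts,
                 start_objectives = opt$start_objectives,
                 problem = problem),
            class = "nr_fit_result")
}

#' @export
print.nr_fit_result <- function(x, ...) {
  cat(sprintf("<fit result> chi2 = %.4g (reduced %.3f), %d points, %d free%s\n",
              x$chi2, x$reduced_chi2, x$n_points, x$n_free,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$parameters)
  invisible(x)
}

# profiled chi2: fix `name` at x, re-optimise all other free parameters
# (warm start), return the minimised chi2 and the warm-start vector
profiled_chi2 <- function(fn, table, name, x, warm_values,
                          resid_fn = NULL) {
  table$value <- warm_values[table$name]
  i <- match(name, table$name)
  table$value[i] <- x
  table$fixed[i] <- TRUE
  # warm-started re-optimisation: one restart suffices near the optimum
  opt <- optimize_multistart(fn, table, max_starts = 1,
                             control = list(rel.tol = 1e-9, x.tol = 1e-10,
                                            eval.max = 2000,
                                            iter.max = 200),
                             polish = 1, resid_fn = resid_fn)
  opt
}

#' Confidence intervals by chi-square profiling
#'
#' For each free parameter, scans away from the optimum while
#' re-optimising all remaining free parameters until the chi-square rises
#' by `delta` (default 1.0, the 68% interval in the Gaussian limit,
#' mirroring MINOS semantics).  A side whose bound is reached before the
#' crossing is reported as open at that bound.
#'
#' @param problem `nr_fit_problem` (or any object with a `params` table
#'   and an objective via `fn`).
#' @param result `nr_fit_result` from [fit_reflectivity()]; profiling
#'   assumes `result` is a local minimum.
#' @param parameters Names of parameters to profile; default all free.
#' @param delta Chi-square increase defining the interval.
#' @param fn Objective override (used for non-reflectivity objectives).
#' @return `data.frame` with columns `parameter`, `best`, `low`, `high`,
#'   `low_open`, `high_open`.
#' @export
profile_errors <- function(problem, result, parameters = NULL, delta = 1,
                           fn = NULL) {
  table <- problem$params
  resid_fn <- NULL
  if (is.null(fn)) {
    fn <- function(values) chi2(problem, values)
    if (inherits(problem, "nr_fit_problem"))
      resid_fn <- problem_residuals(problem)
  }
  best_values <- result$best_values
  chi2_min <- result$chi2
  free_names <- table$name[!table$fixed]
  if (is.null(parameters)) parameters <- free_names
  parameters <- intersect(parameters, free_names)
  rows <- lapply(parameters, function(pn) {
    i <- match(pn, table$name)
    v0 <- best_values[[pn]]
    lims <- c(table$min[i], table$max[i])
    span <- lims[2] - lims[1]
    target <- chi2_min + delta
    one_side <- function(dir) {
      bound <- if (dir > 0) lims[2] else lims[1]
      h <- 0.01 * span
      warm <- best_values
      x_in <- v0; g_in <- 0
      repeat {
        x <- v0 + dir * h
        hit_bound <- (dir > 0 && x >= bound) || (dir < 0 && x <= bound)
        if (hit_bound) x <- bound
        opt <- profiled_chi2(fn, table, pn, x, warm, resid_fn)
        warm <- opt$values
        g <- opt$objective - target
        if (g >= 0) break
        x_in <- x; g_in <- g
        if (hit_bound) return(list(limit = bound, open = TRUE))
        h <- 2 * h
      }
      # bisect between x_in (below target) and x (above target); resolve
      # to 0.5% of the half-width or 1e-6 of the parameter range
      x_out <- x
      for (it in 1:25) {
        tol_x <- max(1e-6 * span, 5e-3 * abs(x_in - v0))
        if (abs(x_out - x_in) < tol_x) break
        xm <- (x_in + x_out) / 2
        opt <- profiled_chi2(fn, table, pn, xm, warm, resid_fn)
        warm <- opt$values
        if (opt$objective - target >= 0) x_out <- xm else x_in <- xm
      }
      list(limit = (x_in + x_out) / 2, open = FALSE)
    }
    up <- one_side(+1)
    dn <- one_side(-1)
    data.frame(parameter = pn, best = v0, low = dn$limit, high = up$limit,
               low_open = dn$open, high_open = up$open,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(parameter = character(0), best = numeric(0),
                      low = numeric(0), high = numeric(0),
                      low_open = logical(0), high_open = logical(0))
  out
}
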