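#' Write a reflectivity curve to an ASCII file
#'
#' Whitespace-separated columns `Q R dR [dQ]` preceded by `#`-comment
#' header lines carrying `key: value` metadata (`contrast`,
#' `fraction_d2o`).  Numbers are written with 17 significant digits so the
#' round trip through [read_reflectivity()] is bit exact.
#'
#' @param curve `nr_reflectivity_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reflectivity <- function(curve, path) {
  stopifnot(inherits(curve, "nr_reflectivity_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# contrast: %s", curve$contrast), con)
  if (!is.na(curve$fraction_d2o))
    writeLines(sprintf("# fraction_d2o: %.17g", curve$fraction_d2o), con)
  has_dq <- !is.null(curve$dQ)
  dq <- if (has_dq) rep_len(curve$dQ, length(curve$Q)) else NULL
  writeLines(paste("# columns: Q R dR", if (has_dq) "dQ" else ""), con)
  dr <- if (is.null(curve$dR)) rep(NA_real_, length(curve$Q)) else curve$dR
  body <- if (has_dq)
    sprintf("%.17g %.17g %.17g %.17g", curve$Q, curve$R, dr, dq)
  else sprintf("%.17g %.17g %.17g", curve$Q, curve$R, dr)
  writeLines(body, con)
  invisible(path)
}

#' Read a reflectivity curve from an ASCII file
#'
#' Accepts whitespace- or comma-separated columns `Q R dR [dQ]` with
#' optional `#`-prefixed header lines; `key: value` headers populate the
#' contrast metadata.  Rows are sorted by Q (with a warning) if needed.
#'
#' @param path Input file.
#' @return `nr_reflectivity_curve`.
#' @export
read_reflectivity <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list(contrast = "", fraction_d2o = NA_real_)
  header <- grepl("^[[:space:]]*#", lines)
  for (ln in lines[header]) {
    m <- regmatches(ln, regexec("^#[[:space:]]*([A-Za-z_0-9]+):[[:space:]]*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      key <- m[2]; val <- trimws(m[3])
      if (key == "contrast") meta$contrast <- val
      if (key == "fraction_d2o") meta$fraction_d2o <- as.numeric(val)
    }
  }
  body_idx <- which(!header & nzchar(trimws(lines)))
  if (!length(body_idx)) stop("no data rows in ", path)
  rows <- lapply(body_idx, function(i) {
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop("non-numeric value on line ", i, " of ", path)
    if (length(vals) < 3)
      stop("fewer than 3 numeric columns on line ", i, " of ", path)
    vals
  })
  ncols <- vapply(rows, length, integer(1))
  if (length(unique(ncols)) != 1)
    stop("inconsistent column count in ", path, " (line ",
         body_idx[which(ncols != ncols[1])[1]], ")")
  mat <- do.call(rbind, rows)
  if (is.unsorted(mat[, 1], strictly = TRUE)) {
    warning("Q not strictly increasing; sorting rows")
    mat <- mat[order(mat[, 1]), , drop = FALSE]
  }
  dr <- mat[, 3]
  if (all(is.na(dr))) dr <- NULL
  dq <- if (ncol(mat) >= 4) mat[, 4] else NULL
  if (!is.null(dq) && length(unique(dq)) == 1) dq <- dq[1]
  reflectivity_curve(mat[, 1], mat[, 2], dR = dr, dQ = dq,
                     contrast = meta$contrast,
                     fraction_d2o = meta$fraction_d2o)
}

#' Write a QCM-D trace to CSV
#'
#' Columns `time_min, F3, D3, F5, D5, ...`; events are stored as
#' `#event: time,label` comment rows before the header.
#'
#' @param trace `nr_qcmd_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qcmd_csv <- function(trace, path) {
  stopifnot(inherits(trace, "nr_qcmd_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(trace$events)))
    writeLines(sprintf("#event: %.17g,%s", trace$events$time[i],
                       trace$events$label[i]), con)
  cols <- list(time_min = trace$time)
  for (nm in names(trace$df)) {
    cols[[paste0("F", nm)]] <- trace$df[[nm]]
    d <- trace$dissipation[[nm]]
    if (!is.null(d)) cols[[paste0("D", nm)]] <- d
  }
  writeLines(paste(names(cols), collapse = ","), con)
  mat <- do.call(cbind, lapply(cols, function(v) sprintf("%.17g", v)))
  writeLines(apply(mat, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a QCM-D trace from CSV
#'
#' Parses the header to discover overtone columns (`F<n>` with optional
#' `D<n>`); missing dissipation columns are tolerated.  `#event:` comment
#' rows populate the event table.
#'
#' @param path Input file.
#' @return `nr_qcmd_trace`.
#' @export
read_qcmd_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ev_idx <- grepl("^#event:", lines)
  events <- if (any(ev_idx)) {
    parts <- strsplit(sub("^#event:[[:space:]]*", "", lines[ev_idx]), ",")
    data.frame(time = vapply(parts, function(p) as.numeric(p[1]),
                             numeric(1)),
               label = vapply(parts, function(p)
                 paste(p[-1], collapse = ","), character(1)),
               stringsAsFactors = FALSE)
  } else data.frame(time = numeric(0), label = character(0))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2) stop("no data rows in ", path)
  header <- strsplit(body[1], ",")[[1]]
  nfield <- vapply(strsplit(body[-1], ","), length, integer(1))
  if (any(nfield != length(header)))
    stop("mismatched column count at data row ",
         which(nfield != length(header))[1], " of ", path)
  df <- read.csv(text = paste(body, collapse = "\n"),
                 check.names = FALSE)
  if (!"time_min" %in% names(df)) stop("missing time_min column in ", path)
  fcols <- grep("^F[0-9]+$", names(df), value = TRUE)
  if (!length(fcols)) stop("no overtone columns (F<n>) found in ", path)
  ns <- sub("^F", "", fcols)
  dflist <- setNames(lapply(fcols, function(cn) df[[cn]]), ns)
  ddlist <- setNames(lapply(ns, function(n) {
    cn <- paste0("D", n)
    if (cn %in% names(df)) df[[cn]] else NULL
  }), ns)
  if (all(vapply(ddlist, is.null, logical(1)))) ddlist <- NULL
  qcmd_trace(df$time_min, dflist, ddlist, events = events)
}

#' Read a fit configuration
#'
#' JSON layout:
#' \preformatted{
#' {
#'   "model": {"t_H": {"value": 6.8, "min": 3, "max": 12, "fixed": false},
#'             ...},
#'   "contrasts": [{"file": "d2o.dat", "fraction_d2o": 1.0,
#'                  "scale": 1.0, "background": 1e-6}, ...],
#'   "options": {"dq_over_q": 0.05, "max_starts": 3, "seed": 1,
#'               "float_scale": true, "float_background": true}
#' }
#' }
#' Parameters omitted from `model` keep the defaults of
#' [reference_bilayer()]'s POPC set and stay fixed.  Curve paths are
#' resolved relative to the configuration file.
#'
#' @param path Configuration file.
#' @return List with `problem` (an [fit_problem()]) and `options`.
#' @export
read_fit_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- reference_bilayer("popc")
  tab <- bilayer_param_table(base, free = character(0))
  for (nm in names(cfg$model)) {
    entry <- cfg$model[[nm]]
    i <- match(nm, tab$name)
    if (is.na(i)) stop("unknown model parameter in config: ", nm)
    if (!is.null(entry$value)) tab$value[i] <- entry$value
    if (!is.null(entry$min)) tab$min[i] <- entry$min
    if (!is.null(entry$max)) tab$max[i] <- entry$max
    if (!is.null(entry$fixed)) tab$fixed[i] <- isTRUE(entry$fixed)
  }
  dir <- dirname(path)
  curves <- list(); slds <- numeric(0)
  scales <- numeric(0); bkgs <- numeric(0)
  for (ct in cfg$contrasts) {
    f <- ct$file
    if (!file.exists(f)) f <- file.path(dir, ct$file)
    cu <- read_reflectivity(f)
    if (!is.null(ct$fraction_d2o)) cu$fraction_d2o <- ct$fraction_d2o
    sld <- if (!is.null(ct$solvent_sld)) ct$solvent_sld
           else mix_solvent(cu$fraction_d2o)
    curves[[length(curves) + 1]] <- cu
    slds <- c(slds, sld)
    scales <- c(scales, if (is.null(ct$scale)) 1 else ct$scale)
    bkgs <- c(bkgs, if (is.null(ct$background)) 1e-6 else ct$background)
  }
  opt <- cfg$options
  getopt <- function(nm, default)
    if (is.null(opt[[nm]])) default else opt[[nm]]
  problem <- fit_problem(
    curves, tab, solvent_slds = slds,
    dq_over_q = getopt("dq_over_q", 0.05),
    float_scale = isTRUE(getopt("float_scale", TRUE)),
    float_background = isTRUE(getopt("float_background", TRUE)),
    float_solvent = isTRUE(getopt("float_solvent", FALSE)),
    scale = scales, background = bkgs)
  list(problem = problem,
       options = list(dq_over_q = getopt("dq_over_q", 0.05),
                      max_starts = getopt("max_starts", 3),
                      seed = getopt("seed", 1)))
}
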