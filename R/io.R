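# ---- reflectivity dataset and file formats --------------------------------

#' A reflectivity dataset tagged with its contrast condition
#'
#' @param q momentum transfer (Angstrom^-1), strictly increasing.
#' @param r reflectivity.
#' @param dr 1-sigma uncertainty on `r` (> 0).
#' @param dq optional FWHM resolution per point (Angstrom^-1).
#' @param contrast the [contrast_condition()] of the measurement.
#' @param label free-text identifier.
#' @return Object of class `nr_dataset`.
#' @export
nr_dataset <- function(q, r, dr, dq = NULL,
                       contrast = contrast_condition(1, "unpolarized"),
                       label = "") {
  n <- length(q)
  if (length(r) != n || length(dr) != n || (!is.null(dq) && length(dq) != n))
    stop("q, r, dr (and dq) must have equal lengths", call. = FALSE)
  if (any(dr <= 0)) stop("dr must be strictly positive", call. = FALSE)
  if (is.unsorted(q, strictly = TRUE)) {
    warning("q not strictly increasing; sorting dataset", call. = FALSE)
    o <- order(q)
    q <- q[o]; r <- r[o]; dr <- dr[o]
    if (!is.null(dq)) dq <- dq[o]
  }
  structure(list(q = q, r = r, dr = dr, dq = dq, contrast = contrast,
                 label = label),
            class = "nr_dataset")
}

#' @export
print.nr_dataset <- function(x, ...) {
  cat(sprintf("<reflectivity dataset '%s'> %d points, Q [%.4g, %.4g] A^-1, %.0f%% D2O, spin %s\n",
              x$label, length(x$q), min(x$q), max(x$q),
              100 * x$contrast$d2o_fraction, x$contrast$spin))
  invisible(x)
}

num17 <- function(x) sprintf("%.17g", x) # exact double round-trip

#' Write a reflectivity dataset as columnar text or ORSO .ort
#'
#' The `"columns"` dialect writes whitespace-separated Q, R, dR (and dQ
#' when present) with `#` comment headers; the `"ort"` dialect writes an
#' ORSO-style header that embeds the contrast condition
#' (`d2o_fraction`, `spin`) so it round-trips through
#' [read_reflectivity()].  Output is byte-stable for identical input.
#'
#' @param dataset an [nr_dataset()].
#' @param path output file path.
#' @param dialect `"ort"` (default) or `"columns"`.
#' @return `path`, invisibly.
#' @export
write_reflectivity <- function(dataset, path, dialect = c("ort", "columns")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dataset, "nr_dataset"))
  has_dq <- !is.null(dataset$dq)
  cols <- if (has_dq)
    cbind(dataset$q, dataset$r, dataset$dr, dataset$dq)
  else cbind(dataset$q, dataset$r, dataset$dr)
  body <- apply(cols, 1, function(row) paste(num17(row), collapse = " "))
  header <- if (dialect == "ort") c(
    "# # ORSO reflectivity data file | 1.0 standard | YAML encoding | https://www.reflectometry.org/",
    "# data_source:",
    "#   experiment:",
    "#     instrument: simulated",
    "#     probe: neutron",
    "#   measurement:",
    "#     instrument_settings:",
    sprintf("#       polarization: %s", dataset$contrast$spin),
    "#     sample:",
    sprintf("#       environment: {d2o_fraction: %s, spin: %s}",
            num17(dataset$contrast$d2o_fraction), dataset$contrast$spin),
    sprintf("# data_set: %s", dataset$label),
    "# columns:",
    "#   - {name: Qz, unit: 1/angstrom}",
    "#   - {name: R}",
    "#   - {name: sR, interpretation: 1-sigma}",
    if (has_dq) "#   - {name: sQz, unit: 1/angstrom, interpretation: FWHM}")
  else c(
    sprintf("# reflectivity dataset: %s", dataset$label),
    sprintf("# d2o_fraction: %s", num17(dataset$contrast$d2o_fraction)),
    sprintf("# spin: %s", dataset$contrast$spin),
    sprintf("# columns: Q R dR%s (Q in 1/angstrom, dR 1-sigma, dQ FWHM)",
            if (has_dq) " dQ" else ""))
  con <- file(path, open = "wb") # binary mode keeps line endings byte-stable
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

parse_contrast_header <- function(lines) {
  d2o <- NA_real_; spin <- NA_character_
  m <- regmatches(lines, regexpr("d2o_fraction: *[0-9eE.+-]+", lines))
  if (length(m))
    d2o <- as.numeric(sub("d2o_fraction: *", "", m[[1]]))
  s <- regmatches(lines, regexpr("spin: *[a-z]+", lines))
  if (length(s))
    spin <- sub("spin: *", "", s[[1]])
  if (is.na(d2o) && is.na(spin)) return(NULL)
  contrast_condition(if (is.na(d2o)) 1 else d2o,
                     if (is.na(spin)) "unpolarized" else spin)
}

#' Read a reflectivity dataset from columnar text or ORSO .ort
#'
#' Parses 3-column (Q, R, dR) or 4-column (Q, R, dR, dQ) whitespace- or
#' comma-separated text; lines beginning `#` are treated as header
#' comments, from which a contrast condition (`d2o_fraction:`,
#' `spin:`) is recovered when present (the ORSO dialect written by
#' [write_reflectivity()] embeds one).  Q is sorted ascending on load
#' (with a warning when the file was unsorted).  dR is interpreted as
#' 1-sigma, dQ as FWHM; `units = "nm"` converts Q and dQ from 1/nm to
#' 1/Angstrom (never auto-detected).
#'
#' @param path input file.
#' @param contrast fallback [contrast_condition()] when the header
#'   carries none.
#' @param units `"A"` (default, 1/Angstrom) or `"nm"` (1/nm in the file).
#' @param label dataset label; defaults to the file name.
#' @return An [nr_dataset()].
#' @export
read_reflectivity <- function(path, contrast = NULL, units = c("A", "nm"),
                              label = basename(path)) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  header <- lines[is_comment]
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (!length(body)) stop("format error: no data rows in ", path,
                          call. = FALSE)
  rows <- strsplit(trimws(body), "[[:space:],]+")
  ncols <- vapply(rows, length, integer(1))
  if (any(ncols < 3))
    stop("format error: need at least 3 columns (Q R dR) in ", path,
         call. = FALSE)
  nc <- min(ncols)
  vals <- matrix(NA_real_, length(rows), nc)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][seq_len(nc)]))
    if (any(is.na(v)))
      stop("non-numeric value at data row ", i, " of ", path,
           call. = FALSE)
    vals[i, ] <- v
  }
  hc <- parse_contrast_header(header)
  if (!is.null(hc)) contrast <- hc
  if (is.null(contrast)) contrast <- contrast_condition(1, "unpolarized")
  fac <- if (units == "nm") 0.1 else 1
  nr_dataset(q = vals[, 1] * fac, r = vals[, 2], dr = vals[, 3],
             dq = if (nc >= 4) vals[, 4] * fac else NULL,
             contrast = contrast, label = label)
}

# ---- fit reports -----------------------------------------------------------

fit_report_list <- function(fit) {
  list(
    parameters = fit$intervals,
    derived = fit$derived,
    asymmetry = asymmetry_metrics(fit$model)[c("outer_ratio",
                                               "inner_ratio")],
    objective = fit$objective, dof = fit$dof,
    chi2_per_dof = fit$objective / max(fit$dof, 1),
    scale = as.list(fit$scale), background = as.list(fit$background),
    seed = fit$seed, n_evaluations = fit$n_evaluations,
    interval_method = fit$interval_method,
    package_version = as.character(utils::packageVersion("fsbnr")))
}

#' Write a fit report in machine- and human-readable form
#'
#' Writes `<stem>.json` (machine-readable: parameter table with 95 %
#' limits, derived metrics, objective, seed) and `<stem>.txt` (the
#' human-readable summary, with parameter values in
#' "value (range low,high)" style and leaflet ratios in "LPS:PC"
#' style).
#'
#' @param fit an [fsb_fit()].
#' @param stem output path without extension.
#' @return Paths of the two files, invisibly.
#' @export
write_fit_report <- function(fit, stem) {
  jsonlite::write_json(fit_report_list(fit), paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output({
    print(fit)
    cat("\n")
    print(summary(fit))
  })
  writeLines(txt, paste0(stem, ".txt"))
  invisible(c(json = paste0(stem, ".json"), txt = paste0(stem, ".txt")))
}
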