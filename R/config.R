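# ---- structured-text model and run configuration --------------------------

# numbers travel as %.17g strings inside YAML so a write -> read cycle
# reproduces every double bit-exactly
num_out <- function(x) if (is.numeric(x)) num17(x) else x
num_in <- function(x) if (is.character(x)) as.numeric(x) else x

model_to_list <- function(model, materials_path = "default") {
  list(
    water_gap = num_out(model$water_gap),
    t_inner_head = num_out(model$t_inner_head),
    t_inner_tail = num_out(model$t_inner_tail),
    t_outer_tail = num_out(model$t_outer_tail),
    t_core = num_out(model$t_core),
    inner = lapply(unclass(model$inner), num_out),
    outer = lapply(unclass(model$outer), num_out),
    coverage = num_out(model$coverage),
    sigma_bilayer = num_out(model$sigma_bilayer),
    protein = if (is.null(model$protein)) NULL else list(
      thickness = num_out(model$protein$thickness),
      fraction = num_out(model$protein$fraction),
      material = model$protein$material),
    substrate = lapply(seq_len(nrow(model$substrate)), function(i) list(
      material = model$substrate$material[i],
      thickness = num_out(model$substrate$thickness[i]),
      roughness = num_out(model$substrate$roughness[i]))),
    materials = materials_path)
}

model_from_list <- function(x) {
  nv <- function(v, default) if (is.null(v)) default else num_in(v)
  mats <- if (is.null(x$materials) || identical(x$materials, "default"))
    load_materials() else load_materials(x$materials)
  substrate <- if (is.null(x$substrate)) default_substrate() else
    data.frame(
      material = vapply(x$substrate, `[[`, character(1), "material"),
      thickness = vapply(x$substrate, function(s) num_in(s$thickness),
                         numeric(1)),
      roughness = vapply(x$substrate, function(s) num_in(s$roughness),
                         numeric(1)),
      stringsAsFactors = FALSE)
  fsb_model(
    water_gap = nv(x$water_gap, 15),
    t_inner_head = nv(x$t_inner_head, 8),
    t_inner_tail = nv(x$t_inner_tail, 16),
    t_outer_tail = nv(x$t_outer_tail, 14),
    t_core = nv(x$t_core, 30),
    inner = if (is.null(x$inner)) leaflet_composition(0.08, 0.82, 0.10)
    else leaflet_composition(num_in(x$inner$f_lps), num_in(x$inner$f_pc),
                             num_in(x$inner$f_solvent)),
    outer = if (is.null(x$outer)) leaflet_composition(0.79, 0.11, 0.10)
    else leaflet_composition(num_in(x$outer$f_lps), num_in(x$outer$f_pc),
                             num_in(x$outer$f_solvent)),
    coverage = nv(x$coverage, 0.93),
    sigma_bilayer = nv(x$sigma_bilayer, 9.31),
    protein = if (is.null(x$protein)) NULL else list(
      thickness = num_in(x$protein$thickness),
      fraction = num_in(x$protein$fraction),
      material = x$protein$material),
    substrate = substrate, materials = mats)
}

#' Serialize an FSB model to a structured text (YAML) file
#'
#' Every model field is written, with numbers encoded so that
#' `read_model_config(write_model_config(m))` reproduces the model
#' bit-exactly.  Optional fit bounds are stored alongside.
#'
#' @param model an [fsb_model()].
#' @param path output file.
#' @param bounds optional bounds data.frame (see [default_bounds()]).
#' @param materials_path reference recorded for the material table
#'   (`"default"` for the packaged table, else a file path).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path, bounds = NULL,
                               materials_path = "default") {
  cfg <- list(model = model_to_list(model, materials_path))
  if (!is.null(bounds))
    cfg$bounds <- lapply(seq_len(nrow(bounds)), function(i)
      list(parameter = bounds$parameter[i],
           lower = num_out(bounds$lower[i]),
           upper = num_out(bounds$upper[i])))
  writeLines(yaml::as.yaml(cfg), path)
  invisible(path)
}

#' Read an FSB model (and optional bounds) from a YAML config
#'
#' @param path file written by [write_model_config()] or hand-authored
#'   in the same layout.
#' @return List with `model` ([fsb_model()]) and `bounds` (data.frame
#'   or NULL).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("config has no 'model' section",
                               call. = FALSE)
  bounds <- NULL
  if (!is.null(cfg$bounds))
    bounds <- data.frame(
      parameter = vapply(cfg$bounds, `[[`, character(1), "parameter"),
      lower = vapply(cfg$bounds, function(b) num_in(b$lower), numeric(1)),
      upper = vapply(cfg$bounds, function(b) num_in(b$upper), numeric(1)),
      stringsAsFactors = FALSE)
  list(model = model_from_list(cfg$model), bounds = bounds)
}

#' Read a full run configuration for the fitting pipeline
#'
#' A run config describes one co-refinement: the model and bounds, the
#' instrument, the datasets (paths plus contrast tags), fit options and
#' the output directory.  Dataset paths are resolved relative to the
#' config file; every referenced path must exist, and every dataset
#' must carry a contrast tag (in the file header or the config).
#'
#' @param path YAML file with sections `model`, optional `bounds`,
#'   `instrument`, `datasets` (list of `path`, `d2o_fraction`, `spin`,
#'   optional `units`), `fit` (`seed`, `resamples`, `method`, optional
#'   `free`), `output`.
#' @return List with `model`, `bounds`, `instrument`, `datasets`,
#'   `fit`, `output`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  mc <- list(model = model_from_list(cfg$model),
             bounds = NULL)
  if (!is.null(cfg$bounds))
    mc$bounds <- data.frame(
      parameter = vapply(cfg$bounds, `[[`, character(1), "parameter"),
      lower = vapply(cfg$bounds, function(b) num_in(b$lower), numeric(1)),
      upper = vapply(cfg$bounds, function(b) num_in(b$upper), numeric(1)),
      stringsAsFactors = FALSE)
  inst <- do.call(nr_instrument, c(
    list(),
    if (!is.null(cfg$instrument$dq_over_q))
      list(dq_over_q = num_in(cfg$instrument$dq_over_q)),
    if (!is.null(cfg$instrument$background))
      list(background = num_in(cfg$instrument$background)),
    if (!is.null(cfg$instrument$scale))
      list(scale = num_in(cfg$instrument$scale))))
  if (is.null(cfg$datasets) || !length(cfg$datasets))
    stop("run config lists no datasets", call. = FALSE)
  datasets <- lapply(cfg$datasets, function(d) {
    p <- d$path
    if (!file.exists(p)) p <- file.path(base_dir, d$path)
    if (!file.exists(p))
      stop("dataset file not found: ", d$path, call. = FALSE)
    ct <- if (!is.null(d$d2o_fraction))
      contrast_condition(num_in(d$d2o_fraction),
                         if (is.null(d$spin)) "unpolarized" else d$spin)
    else NULL
    ds <- read_reflectivity(p, contrast = ct,
                            units = if (is.null(d$units)) "A" else d$units)
    if (is.null(ct) && is.null(parse_contrast_header(readLines(p, n = 50))))
      stop("dataset ", d$path, " has no contrast tag", call. = FALSE)
    ds
  })
  fit <- list(seed = 1L, resamples = 200L, method = "bootstrap",
              free = NULL)
  if (!is.null(cfg$fit)) fit <- utils::modifyList(fit, cfg$fit)
  list(model = mc$model, bounds = mc$bounds, instrument = inst,
       datasets = datasets, fit = fit,
       output = if (is.null(cfg$output)) "." else cfg$output)
}
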