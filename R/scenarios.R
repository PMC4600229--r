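# ---- packaged scenarios and the synthetic-data generator ------------------

#' Default contrast set for synthetic measurements
#'
#' Four polarized contrasts — D2O and H2O buffers, each at spin-up and
#' spin-down — or the two-contrast "paper-minimal" set (D2O/spin-up and
#' H2O/spin-down) actually shown for the measured curves.
#'
#' @param which `"full"` (four contrasts, default) or `"minimal"`.
#' @return List of [contrast_condition()] objects.
#' @export
default_contrasts <- function(which = c("full", "minimal")) {
  which <- match.arg(which)
  if (which == "minimal")
    list(contrast_condition(1, "up"), contrast_condition(0, "down"))
  else
    list(contrast_condition(1, "up"), contrast_condition(1, "down"),
         contrast_condition(0, "up"), contrast_condition(0, "down"))
}

new_scenario <- function(name, truth, contrasts = default_contrasts(),
                         instrument = nr_instrument(), noise_level = 0.03) {
  structure(list(name = name, truth = truth, contrasts = contrasts,
                 instrument = instrument, noise_level = noise_level),
            class = "fsb_scenario")
}

#' @export
print.fsb_scenario <- function(x, ...) {
  cat(sprintf("<scenario %s>  %d contrasts, noise %.3g\n", x$name,
              length(x$contrasts), x$noise_level))
  print(x$truth)
  invisible(x)
}

#' Packaged ground-truth scenarios
#'
#' Six parameter sets encoding the reported structures of the
#' outer-membrane mimic and its perturbations, used as ground truth by
#' the synthetic-data generator:
#' \describe{
#'   \item{baseline_best}{the best bilayer: leaflets 79:11 / 8:82
#'     (LPS:PC), 15 A water gap, 30 A LPS core, 93 % coverage
#'     (satisfying the > 90 % bound), roughness 9.31 A.}
#'   \item{baseline_worst}{the worst bilayer: leaflets 69:28 / 23:75.}
#'   \item{edta}{after calcium sequestration: both dominant leaflet
#'     fractions reduced by 20 percentage points.}
#'   \item{lactoferrin}{a 90 A protein layer above the LPS core,
#'     coverage down 12 points, outer LPS down 30 points.}
#'   \item{lysozyme_before}{identical to baseline_best (measured in
#'     20 uM calcium).}
#'   \item{lysozyme_after}{LPS core thicker by 20 A and roughness
#'     9.31 -> 12.88 A; no coverage loss.}
#' }
#'
#' @param contrasts contrast set used by every scenario (see
#'   [default_contrasts()]).
#' @param noise_level relative counting-noise level of the generator.
#' @return Named list of scenarios.
#' @examples
#' cat <- scenario_catalog()
#' asymmetry_metrics(cat$baseline_best$truth)$outer_ratio # "79:11"
#' @export
scenario_catalog <- function(contrasts = default_contrasts(),
                             noise_level = 0.03) {
  materials <- load_materials()
  base <- fsb_model(materials = materials)
  worst <- fsb_model(outer = leaflet_composition(0.69, 0.28, 0.03),
                     inner = leaflet_composition(0.23, 0.75, 0.02),
                     materials = materials)
  edta <- fsb_model(outer = leaflet_composition(0.59, 0.31, 0.10),
                    inner = leaflet_composition(0.28, 0.62, 0.10),
                    materials = materials)
  lacto <- add_protein_layer(
    fsb_model(outer = leaflet_composition(0.49, 0.41, 0.10),
              coverage = 0.81, materials = materials),
    thickness = 90, f_protein = 0.30, material = "lactoferrin")
  lys_after <- fsb_model(t_core = 50, sigma_bilayer = 12.88,
                         materials = materials)
  sc <- list(
    baseline_best = new_scenario("baseline_best", base, contrasts,
                                 noise_level = noise_level),
    baseline_worst = new_scenario("baseline_worst", worst, contrasts,
                                  noise_level = noise_level),
    edta = new_scenario("edta", edta, contrasts,
                        noise_level = noise_level),
    lactoferrin = new_scenario("lactoferrin", lacto, contrasts,
                               noise_level = noise_level),
    lysozyme_before = new_scenario("lysozyme_before", base, contrasts,
                                   noise_level = noise_level),
    lysozyme_after = new_scenario("lysozyme_after", lys_after, contrasts,
                                  noise_level = noise_level))
  sc
}

get_scenario <- function(name, ...) {
  cat <- scenario_catalog(...)
  if (!name %in% names(cat))
    stop("unknown scenario '", name, "'; valid names: ",
         paste(names(cat), collapse = ", "), call. = FALSE)
  cat[[name]]
}

#' Generate synthetic multi-contrast reflectivity datasets
#'
#' For each contrast of the scenario, computes the noiseless model curve
#' of the ground-truth structure ([measured_curve()]) and perturbs it
#' with Gaussian noise of standard deviation
#' `noise_level * curve` (counting-statistics-like, relative); the dR
#' column is set to that sigma and the dQ column to the instrument's
#' FWHM resolution.  Deterministic given `seed`.
#'
#' @param scenario a scenario from [scenario_catalog()].
#' @param seed integer seed.
#' @param noise_level override the scenario's noise level (>= 0).
#' @param contrasts override the scenario's contrast list.
#' @return List of [nr_dataset()] objects.
#' @export
generate_datasets <- function(scenario, seed = 1L,
                              noise_level = scenario$noise_level,
                              contrasts = scenario$contrasts) {
  stopifnot(inherits(scenario, "fsb_scenario"))
  if (!is.numeric(noise_level) || noise_level < 0)
    stop("noise_level must be >= 0", call. = FALSE)
  inst <- scenario$instrument
  with_seed(seed, {
    lapply(contrasts, function(ct) {
      profile <- build_slabs(scenario$truth, ct)
      curve <- measured_curve(profile, inst, warn_roughness = FALSE)
      sigma <- noise_level * curve
      dr <- pmax(sigma, 1e-6 * curve) # strictly positive dR even at zero noise
      r <- curve + sigma * rnorm(length(curve))
      nr_dataset(q = inst$q_grid, r = r, dr = dr,
                 dq = inst$dq_over_q * inst$q_grid, contrast = ct,
                 label = paste0(scenario$name, "_", contrast_label(ct)))
    })
  })
}
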