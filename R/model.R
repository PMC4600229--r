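#' Leaflet composition of the asymmetric bilayer
#'
#' Volume fractions of LPS, phosphatidylcholine (d-DPPC) and solvent in
#' one leaflet.  The three fractions must sum to 1 within 1e-6.
#'
#' @param f_lps LPS volume fraction.
#' @param f_pc PC (d-DPPC) volume fraction.
#' @param f_solvent solvent volume fraction; defaults to the remainder.
#' @return Object of class `fsb_leaflet`.
#' @examples
#' leaflet_composition(0.79, 0.11)        # best outer leaflet, 10% solvent
#' leaflet_composition(0.08, 0.82, 0.10)  # best inner leaflet
#' @export
leaflet_composition <- function(f_lps, f_pc, f_solvent = 1 - f_lps - f_pc) {
  f <- c(f_lps, f_pc, f_solvent)
  if (any(!is.finite(f)) || any(f < -1e-6) || any(f > 1 + 1e-6))
    stop("leaflet fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-6)
    stop("leaflet fractions must sum to 1 (got ",
         format(sum(f), digits = 10), ")", call. = FALSE)
  structure(list(f_lps = f_lps, f_pc = f_pc, f_solvent = f_solvent),
            class = "fsb_leaflet")
}

#' Default substrate stack below the floating bilayer
#'
#' Fixed layers between the silicon fronting medium and the water gap:
#' native oxide, magnetic permalloy reference, gold film, and the
#' omega-thiolipid self-assembled monolayer split into a chain and a
#' PC head-group sublayer.  Thicknesses and roughnesses are documented
#' defaults, fitted once per experiment and held fixed across
#' perturbation scenarios.
#'
#' @return data.frame with columns `material`, `thickness`, `roughness`.
#' @export
default_substrate <- function() {
  data.frame(
    material = c("sio2", "permalloy", "au", "thiolipid_chains", "pc_head"),
    thickness = c(12, 150, 100, 14, 8),
    roughness = c(3, 4, 4, 4, 4),
    stringsAsFactors = FALSE)
}

#' Parametrize a floating supported bilayer model
#'
#' The structural model of the outer-membrane mimic: a fixed substrate
#' stack (Si / SiO2 / permalloy / Au / SAM), a solvent-filled water gap
#' on which the bilayer floats, a thin inner (PC) head-group layer,
#' inner and outer lipid-tail regions, a thick LPS core-oligosaccharide
#' head-group region, and optionally an adsorbed protein layer on top.
#' A single roughness `sigma_bilayer` applies to every membrane
#' interface, and `coverage` is the fraction of the surface the bilayer
#' occupies (the remainder is solvent in every membrane layer).
#'
#' @param water_gap thickness (Angstrom) of the solvent layer between the
#'   SAM head groups and the bilayer.
#' @param t_inner_head thickness of the inner (d-DPPC) head-group layer.
#' @param t_inner_tail thickness of the inner lipid-tail region.
#' @param t_outer_tail thickness of the outer (lipid A) tail region.
#' @param t_core thickness of the LPS core-oligosaccharide region.
#' @param inner,outer [leaflet_composition()] of the inner and outer
#'   leaflets (LPS / PC / solvent fractions).
#' @param coverage bilayer surface coverage in \[0, 1\].
#' @param sigma_bilayer interfacial roughness (Angstrom) of all membrane
#'   interfaces.
#' @param protein optional protein layer: a list with elements
#'   `thickness` (Angstrom), `fraction` (protein volume fraction) and
#'   `material` (name in the material table); usually added with
#'   [add_protein_layer()].
#' @param substrate fixed substrate stack, as [default_substrate()].
#' @param materials material table, as [load_materials()].
#' @return Object of class `fsb_model`.
#' @examples
#' m <- fsb_model() # the best-bilayer structure
#' asymmetry_metrics(m)$outer_ratio # "79:11"
#' @export
fsb_model <- function(water_gap = 15,
                      t_inner_head = 8,
                      t_inner_tail = 16,
                      t_outer_tail = 14,
                      t_core = 30,
                      inner = leaflet_composition(0.08, 0.82, 0.10),
                      outer = leaflet_composition(0.79, 0.11, 0.10),
                      coverage = 0.93,
                      sigma_bilayer = 9.31,
                      protein = NULL,
                      substrate = default_substrate(),
                      materials = load_materials()) {
  thick <- c(water_gap = water_gap, t_inner_head = t_inner_head,
             t_inner_tail = t_inner_tail, t_outer_tail = t_outer_tail,
             t_core = t_core)
  if (any(!is.finite(thick)) || any(thick < 0))
    stop("all thicknesses must be finite and >= 0", call. = FALSE)
  if (!is.finite(coverage) || coverage < 0 || coverage > 1)
    stop("coverage must lie in [0, 1]", call. = FALSE)
  if (!is.finite(sigma_bilayer) || sigma_bilayer < 0)
    stop("sigma_bilayer must be >= 0", call. = FALSE)
  stopifnot(inherits(inner, "fsb_leaflet"), inherits(outer, "fsb_leaflet"))
  if (!is.null(protein)) {
    if (is.null(protein$material)) protein$material <- "lactoferrin"
    if (!is.finite(protein$thickness) || protein$thickness < 0)
      stop("protein layer thickness must be >= 0", call. = FALSE)
    if (!is.finite(protein$fraction) || protein$fraction < 0 ||
        protein$fraction > 1)
      stop("protein volume fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(water_gap = water_gap, t_inner_head = t_inner_head,
         t_inner_tail = t_inner_tail, t_outer_tail = t_outer_tail,
         t_core = t_core, inner = inner, outer = outer,
         coverage = coverage, sigma_bilayer = sigma_bilayer,
         protein = protein, substrate = substrate, materials = materials),
    class = "fsb_model")
}

#' @export
print.fsb_model <- function(x, ...) {
  am <- asymmetry_metrics(x)
  cat("<floating supported bilayer model>\n")
  cat(sprintf("  water gap      %6.2f A\n", x$water_gap))
  cat(sprintf("  inner head     %6.2f A   inner tails %6.2f A\n",
              x$t_inner_head, x$t_inner_tail))
  cat(sprintf("  outer tails    %6.2f A   LPS core    %6.2f A\n",
              x$t_outer_tail, x$t_core))
  cat(sprintf("  leaflets (LPS:PC)  outer %s   inner %s\n",
              am$outer_ratio, am$inner_ratio))
  cat(sprintf("  coverage       %6.1f %%   roughness   %6.2f A\n",
              100 * x$coverage, x$sigma_bilayer))
  if (!is.null(x$protein))
    cat(sprintf("  protein layer  %6.1f A of %s at %.0f %% volume\n",
                x$protein$thickness, x$protein$material,
                100 * x$protein$fraction))
  invisible(x)
}

#' Construct a slab profile directly
#'
#' Ordered layers from the fronting (silicon, beam-side) medium to the
#' backing (bulk solvent) medium.  Each layer carries the roughness of
#' its interface to the *previous* medium; `backing_roughness` is the
#' final interface to the backing.
#'
#' @param thickness,sld,roughness equal-length numeric vectors
#'   (Angstrom, 1e-6 Angstrom^-2, Angstrom).
#' @param fronting_sld,backing_sld SLDs of the semi-infinite media.
#' @param backing_roughness roughness of the last interface.
#' @param name optional layer labels.
#' @return Object of class `slab_profile`.
#' @export
slab_profile <- function(thickness, sld, roughness,
                         fronting_sld, backing_sld,
                         backing_roughness = 0,
                         name = NULL) {
  n <- length(thickness)
  stopifnot(length(sld) == n, length(roughness) == n)
  if (any(!is.finite(thickness)) || any(thickness < 0))
    stop("slab thicknesses must be >= 0", call. = FALSE)
  if (any(!is.finite(roughness)) || any(roughness < 0) ||
      backing_roughness < 0)
    stop("slab roughnesses must be >= 0", call. = FALSE)
  if (is.null(name))
    name <- if (n) paste0("layer", seq_len(n)) else character(0)
  structure(
    list(layers = data.frame(name = name, thickness = thickness, sld = sld,
                             roughness = roughness,
                             stringsAsFactors = FALSE),
         fronting_sld = fronting_sld, backing_sld = backing_sld,
         backing_roughness = backing_roughness),
    class = "slab_profile")
}

#' @export
print.slab_profile <- function(x, ...) {
  cat("<slab profile> fronting SLD", format(x$fronting_sld, digits = 4),
      "-> backing SLD", format(x$backing_sld, digits = 4), "\n")
  print(x$layers, row.names = FALSE, digits = 4)
  invisible(x)
}

# SLD of one membrane layer: component mixture diluted by coverage,
# remainder solvent.  comp is a named numeric vector of volume fractions
# over materials (solvent excluded); its own solvent fraction fills to 1.
membrane_layer_sld <- function(comp_sld, comp_frac, coverage, rho_solvent) {
  f_solv_internal <- 1 - sum(comp_frac)
  within <- mix_sld(c(comp_sld, rho_solvent), c(comp_frac, f_solv_internal))
  mix_sld(c(within, rho_solvent), c(coverage, 1 - coverage))
}

#' Translate an FSB model into a slab profile for one contrast
#'
#' Applies the co-refinement constraint: all thicknesses, roughnesses,
#' coverage and compositions are contrast-independent; only SLDs change
#' with the solvent isotopic composition (solvent-containing layers) and
#' neutron spin (the permalloy reference layer).  Head-group regions mix
#' the leaflet's LPS component as core-oligosaccharide material and its
#' PC component as PC head-group material; tail regions mix the
#' corresponding tail materials; coverage enters every membrane layer as
#' additional solvent.
#'
#' @param model an [fsb_model()].
#' @param contrast an [contrast_condition()].
#' @return A [slab_profile()] ordered fronting (Si) to backing (solvent).
#' @export
build_slabs <- function(model, contrast) {
  stopifnot(inherits(model, "fsb_model"), inherits(contrast, "fsb_contrast"))
  mats <- model$materials
  rho_solv <- solvent_sld(contrast, mats)
  sub <- model$substrate
  sub_sld <- vapply(sub$material, function(nm)
    spin_sld(get_material(mats, nm), contrast$spin), numeric(1))

  rho <- function(nm) nuclear_sld(get_material(mats, nm))
  cv <- model$coverage
  inner <- model$inner; outer <- model$outer

  mem_name <- c("water_gap", "inner_head", "inner_tail", "outer_tail",
                "lps_core")
  mem_thick <- c(model$water_gap, model$t_inner_head, model$t_inner_tail,
                 model$t_outer_tail, model$t_core)
  mem_sld <- c(
    rho_solv,
    membrane_layer_sld(c(rho("lps_core"), rho("pc_head")),
                       c(inner$f_lps, inner$f_pc), cv, rho_solv),
    membrane_layer_sld(c(rho("lps_tails"), rho("dppc_tails_d")),
                       c(inner$f_lps, inner$f_pc), cv, rho_solv),
    membrane_layer_sld(c(rho("lps_tails"), rho("dppc_tails_d")),
                       c(outer$f_lps, outer$f_pc), cv, rho_solv),
    membrane_layer_sld(c(rho("lps_core"), rho("pc_head")),
                       c(outer$f_lps, outer$f_pc), cv, rho_solv))
  mem_rough <- c(model$sigma_bilayer, rep(model$sigma_bilayer, 4))

  if (!is.null(model$protein) && model$protein$thickness > 0) {
    mem_name <- c(mem_name, "protein")
    mem_thick <- c(mem_thick, model$protein$thickness)
    mem_sld <- c(mem_sld,
                 membrane_layer_sld(rho(model$protein$material),
                                    model$protein$fraction, cv, rho_solv))
    mem_rough <- c(mem_rough, model$sigma_bilayer)
  }

  slab_profile(
    thickness = c(sub$thickness, mem_thick),
    sld = c(sub_sld, mem_sld),
    roughness = c(sub$roughness, mem_rough),
    fronting_sld = spin_sld(get_material(mats, "si"), contrast$spin),
    backing_sld = rho_solv,
    backing_roughness = model$sigma_bilayer,
    name = c(sub$material, mem_name))
}

#' Continuous SLD profile with error-function interfacial broadening
#'
#' Evaluates the laterally averaged SLD along the surface normal,
#' broadening each interface with a Gaussian of that interface's
#' roughness (error-function profile).  z = 0 at the silicon surface,
#' increasing toward the solution; the profile tends to the fronting SLD
#' as z -> -Inf and the backing SLD as z -> +Inf.
#'
#' @param profile a [slab_profile()].
#' @param z numeric vector of heights (Angstrom), monotone.
#' @return Numeric vector of SLDs (1e-6 Angstrom^-2) at `z`.
#' @export
sld_profile <- function(profile, z) {
  stopifnot(inherits(profile, "slab_profile"))
  if (is.unsorted(z)) stop("z grid must be monotone increasing", call. = FALSE)
  lay <- profile$layers
  z_int <- cumsum(c(0, lay$thickness)) # interface positions
  rho_media <- c(profile$fronting_sld, lay$sld, profile$backing_sld)
  sig <- c(lay$roughness, profile$backing_roughness)
  out <- rep(profile$fronting_sld, length(z))
  for (j in seq_along(sig)) {
    step <- if (sig[j] > 0) pnorm((z - z_int[j]) / sig[j]) else
      as.numeric(z >= z_int[j])
    out <- out + (rho_media[j + 1] - rho_media[j]) * step
  }
  out
}

#' Leaflet asymmetry metrics in the field's LPS:PC convention
#'
#' Reports each leaflet's composition as an "LPS:PC" percentage ratio
#' string (fractions times 100, rounded to the nearest integer) together
#' with the raw dominant-species percentages.
#'
#' @param model an [fsb_model()].
#' @return List with `outer_ratio`, `inner_ratio` (character, "LPS:PC"),
#'   `outer_lps_pct`, `inner_pc_pct` (numeric, unrounded).
#' @examples
#' asymmetry_metrics(fsb_model()) # "79:11", "8:82"
#' @export
asymmetry_metrics <- function(model) {
  stopifnot(inherits(model, "fsb_model"))
  ratio <- function(l) sprintf("%d:%d", round(100 * l$f_lps),
                               round(100 * l$f_pc))
  list(outer_ratio = ratio(model$outer),
       inner_ratio = ratio(model$inner),
       outer_lps_pct = 100 * model$outer$f_lps,
       inner_pc_pct = 100 * model$inner$f_pc)
}

#' Change in leaflet asymmetry between two models
#'
#' Per-leaflet change in the dominant-species percentage (outer: LPS,
#' inner: PC), `after - before`.  By default the change is in percentage
#' points; `relative = TRUE` instead reports the change as a percentage
#' of the initial value (both conventions are found in the literature
#' for "asymmetry reduced by X %").
#'
#' @param before,after [fsb_model()] objects.
#' @param relative report relative change instead of percentage points.
#' @return List with `outer_delta_pct` and `inner_delta_pct`.
#' @export
asymmetry_change <- function(before, after, relative = FALSE) {
  b <- asymmetry_metrics(before)
  a <- asymmetry_metrics(after)
  if (relative) {
    list(outer_delta_pct = 100 * (a$outer_lps_pct - b$outer_lps_pct) /
           b$outer_lps_pct,
         inner_delta_pct = 100 * (a$inner_pc_pct - b$inner_pc_pct) /
           b$inner_pc_pct)
  } else {
    list(outer_delta_pct = a$outer_lps_pct - b$outer_lps_pct,
         inner_delta_pct = a$inner_pc_pct - b$inner_pc_pct)
  }
}

#' Add an adsorbed protein layer on top of the LPS core
#'
#' Returns a new model extended with a protein/solvent layer above the
#' core-oligosaccharide region; the original model is unmodified.  A
#' thickness or fraction of zero leaves every computed reflectivity
#' unchanged.
#'
#' @param model an [fsb_model()].
#' @param thickness protein layer thickness (Angstrom, >= 0).
#' @param f_protein protein volume fraction in \[0, 1\].
#' @param material material-table name for the protein (default
#'   `"lactoferrin"`).
#' @return A new [fsb_model()] with the protein layer.
#' @export
add_protein_layer <- function(model, thickness, f_protein,
                              material = "lactoferrin") {
  stopifnot(inherits(model, "fsb_model"))
  if (!is.finite(thickness) || thickness < 0)
    stop("protein layer thickness must be >= 0", call. = FALSE)
  if (!is.finite(f_protein) || f_protein < 0 || f_protein > 1)
    stop("protein volume fraction must lie in [0, 1]", call. = FALSE)
  get_material(model$materials, material) # validate name
  model$protein <- list(thickness = thickness, fraction = f_protein,
                        material = material)
  model
}
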