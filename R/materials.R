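#' Define a material by its coherent scattering length and molecular volume
#'
#' A material is the elementary unit of scattering-length-density (SLD)
#' arithmetic: a formula unit with a summed coherent scattering length
#' (fm), a molecular volume (cubic Angstrom), and, for magnetised metals
#' such as permalloy, a magnetic SLD contribution that adds to (spin-up)
#' or subtracts from (spin-down) the nuclear SLD.
#'
#' @param name character label.
#' @param scattering_length summed coherent scattering length of the
#'   formula unit, in fm.
#' @param molecular_volume volume of the formula unit, in Angstrom^3;
#'   must be positive.
#' @param magnetic_sld magnetic SLD in 1e-6 Angstrom^-2; zero for
#'   non-magnetic materials.
#' @return An object of class `fsb_material`.
#' @examples
#' d2o <- material("d2o", 19.1453, 30)
#' nuclear_sld(d2o) # ~6.38
#' @export
material <- function(name, scattering_length, molecular_volume,
                     magnetic_sld = 0) {
  if (!is.numeric(molecular_volume) || length(molecular_volume) != 1L ||
      !is.finite(molecular_volume) || molecular_volume <= 0)
    stop("invalid material '", name, "': molecular_volume must be positive",
         call. = FALSE)
  if (!is.finite(scattering_length))
    stop("invalid material '", name, "': non-finite scattering length",
         call. = FALSE)
  structure(
    list(name = as.character(name),
         scattering_length = as.numeric(scattering_length),
         molecular_volume = as.numeric(molecular_volume),
         magnetic_sld = as.numeric(magnetic_sld)),
    class = "fsb_material")
}

#' @export
print.fsb_material <- function(x, ...) {
  cat(sprintf("<material %s>  b = %.4g fm, V = %.4g A^3, nSLD = %.4g e-6 A^-2",
              x$name, x$scattering_length, x$molecular_volume,
              nuclear_sld(x)))
  if (x$magnetic_sld != 0)
    cat(sprintf(", magnetic SLD = %.4g e-6 A^-2", x$magnetic_sld))
  cat("\n")
  invisible(x)
}

#' Nuclear scattering length density of a material
#'
#' `rho = b / V`, reported in the conventional 1e-6 Angstrom^-2 units
#' (b in fm = 1e-5 Angstrom, so `rho[1e-6 A^-2] = 10 b[fm] / V[A^3]`).
#'
#' @param material an [material()] object.
#' @return Nuclear SLD in 1e-6 Angstrom^-2.
#' @export
nuclear_sld <- function(material) {
  stopifnot(inherits(material, "fsb_material"))
  if (material$molecular_volume <= 0)
    stop("invalid material: non-positive molecular volume", call. = FALSE)
  10 * material$scattering_length / material$molecular_volume
}

#' Specify one measurement contrast: solvent isotopic composition and spin
#'
#' A contrast condition selects the SLDs one reflectivity curve sees:
#' the D2O volume fraction of the aqueous phase and the neutron spin
#' state relative to the magnetised reference layer.
#'
#' @param d2o_fraction D2O volume fraction of the solvent, in \[0, 1\].
#' @param spin one of `"up"`, `"down"`, `"unpolarized"`.
#' @return An object of class `fsb_contrast`.
#' @examples
#' contrast_condition(1, "up")    # D2O buffer, spin-up neutrons
#' contrast_condition(0, "down")  # H2O buffer, spin-down neutrons
#' @export
contrast_condition <- function(d2o_fraction, spin = "unpolarized") {
  if (!is.numeric(d2o_fraction) || length(d2o_fraction) != 1L ||
      is.na(d2o_fraction) || d2o_fraction < 0 || d2o_fraction > 1)
    stop("d2o_fraction must be a number in [0, 1]", call. = FALSE)
  if (!is.character(spin) || length(spin) != 1L ||
      !spin %in% c("up", "down", "unpolarized"))
    stop("invalid contrast: spin must be 'up', 'down' or 'unpolarized'",
         call. = FALSE)
  structure(list(d2o_fraction = as.numeric(d2o_fraction), spin = spin),
            class = "fsb_contrast")
}

#' @export
print.fsb_contrast <- function(x, ...) {
  cat(sprintf("<contrast %.0f%% D2O, spin %s>\n", 100 * x$d2o_fraction,
              x$spin))
  invisible(x)
}

contrast_label <- function(contrast) {
  solv <- if (contrast$d2o_fraction >= 0.999) "d2o"
  else if (contrast$d2o_fraction <= 0.001) "h2o"
  else sprintf("%.0fpctD2O", 100 * contrast$d2o_fraction)
  paste0(solv, "_", contrast$spin)
}

#' Load a material table
#'
#' Reads the CSV material table (columns `name`, `scattering_length` in
#' fm, `molecular_volume` in Angstrom^3, `magnetic_sld` in 1e-6
#' Angstrom^-2) shipped with the package, or a user-supplied file in the
#' same layout.  The shipped values are documented literature-style
#' defaults and can be overridden by editing a copy of the file.
#'
#' @param path path to a CSV file; `NULL` (default) loads the packaged
#'   table.
#' @return A named list of [material()] objects, classed
#'   `fsb_material_table`.
#' @export
load_materials <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "materials.csv", package = "fsbnr")
  if (!file.exists(path))
    stop("material table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "scattering_length", "molecular_volume", "magnetic_sld")
  if (!all(need %in% names(tab)))
    stop("material table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  mats <- lapply(seq_len(nrow(tab)), function(i)
    material(tab$name[i], tab$scattering_length[i], tab$molecular_volume[i],
             tab$magnetic_sld[i]))
  names(mats) <- tab$name
  structure(mats, class = "fsb_material_table")
}

#' @export
print.fsb_material_table <- function(x, ...) {
  cat("<material table>", length(x), "materials:",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

get_material <- function(materials, name) {
  m <- materials[[name]]
  if (is.null(m))
    stop("unknown material '", name, "'; table has: ",
         paste(names(materials), collapse = ", "), call. = FALSE)
  m
}

#' Solvent SLD at a given isotopic contrast
#'
#' Linear volume-fraction interpolation between the H2O and D2O SLD
#' endpoints of the material table.
#'
#' @param contrast an [contrast_condition()] object.
#' @param materials a material table from [load_materials()].
#' @return Solvent SLD in 1e-6 Angstrom^-2.
#' @examples
#' mats <- load_materials()
#' solvent_sld(contrast_condition(1), mats)   # D2O endpoint, ~6.38
#' solvent_sld(contrast_condition(0.5), mats) # midpoint
#' @export
solvent_sld <- function(contrast, materials = load_materials()) {
  stopifnot(inherits(contrast, "fsb_contrast"))
  h <- nuclear_sld(get_material(materials, "h2o"))
  d <- nuclear_sld(get_material(materials, "d2o"))
  (1 - contrast$d2o_fraction) * h + contrast$d2o_fraction * d
}

#' Spin-dependent SLD of a (possibly magnetic) material
#'
#' A magnetised layer presents `nuclear + magnetic` SLD to spin-up
#' neutrons and `nuclear - magnetic` to spin-down; unpolarized beams see
#' the nuclear SLD.  Non-magnetic materials are unaffected by spin.
#'
#' @param material an [material()] object.
#' @param spin `"up"`, `"down"` or `"unpolarized"`.
#' @return SLD in 1e-6 Angstrom^-2.
#' @export
spin_sld <- function(material, spin) {
  if (!is.character(spin) || length(spin) != 1L ||
      !spin %in% c("up", "down", "unpolarized"))
    stop("invalid contrast: unknown spin label '", paste(spin, collapse = ","),
         "'", call. = FALSE)
  nuc <- nuclear_sld(material)
  switch(spin,
         up = nuc + material$magnetic_sld,
         down = nuc - material$magnetic_sld,
         unpolarized = nuc)
}

#' Volume-fraction mixture of SLDs
#'
#' Ideal (strictly linear) mixing: `sum(f_i * sld_i)` for volume
#' fractions that must sum to 1 within a small tolerance.  Callers are
#' responsible for filling any remainder with solvent before mixing.
#'
#' @param sld numeric vector of component SLDs (1e-6 Angstrom^-2).
#' @param volume_fraction numeric vector of volume fractions in \[0, 1\],
#'   summing to 1 within `tol`.
#' @param tol tolerance on the fraction sum (default 1e-6).
#' @return Mixture SLD in 1e-6 Angstrom^-2.
#' @examples
#' mix_sld(c(7.4, 6.35), c(0.9, 0.1)) # 7.295
#' @export
mix_sld <- function(sld, volume_fraction, tol = 1e-6) {
  if (length(sld) != length(volume_fraction) || length(sld) == 0L)
    stop("sld and volume_fraction must be non-empty and of equal length",
         call. = FALSE)
  if (any(!is.finite(volume_fraction)) ||
      any(volume_fraction < -tol) || any(volume_fraction > 1 + tol))
    stop("composition error: volume fractions must lie in [0, 1]",
         call. = FALSE)
  s <- sum(volume_fraction)
  if (abs(s - 1) > tol)
    stop(sprintf(
      "composition error: volume fractions sum to %.8f, not 1", s),
      call. = FALSE)
  sum(sld * volume_fraction)
}
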