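#' Define the species of a ternary solute/solvent/antisolvent system
#'
#' A `species_set` fixes the ordering convention used throughout the
#' package: species 1 is the solute, species 2 the solvent and species 3
#' the antisolvent (indices 0, 1, 2 in the usual transport literature).
#' It carries two *distinct* sets of volume ratios:
#'
#' * `thermo_volume_ratios` -- the effective molar volumes \eqn{v_i/v_1}
#'   of the free-energy model.  These are fitting parameters of the
#'   activity model, with the solvent as reference (\eqn{v_1/v_1 = 1}).
#' * `physical_volume_ratios` -- the pure-component molar volumes
#'   \eqn{V_i/V_1} that define the volume reference frame of the
#'   diffusion model (the space a molecule actually occupies).
#'
#' The two coincide for the solvent by construction but differ in
#' general: for ethanol the fitted effective ratio is 1.50 while the
#' physical molar-volume ratio at 25 degrees C is 3.23.
#'
#' @param names character vector of three species labels
#'   (solute, solvent, antisolvent).
#' @param molar_masses molar masses in g/mol.
#' @param thermo_volume_ratios effective volumes \eqn{v_i/v_1} used by
#'   the activity model (solvent entry must be 1).
#' @param physical_volume_ratios pure-component molar volumes
#'   \eqn{V_i/V_1} used by the volume reference frame (solvent entry
#'   must be 1).
#' @param solvent_molar_volume absolute molar volume of the solvent in
#'   m^3/mol, used only to put fluxes on an absolute mol/(m^2 s) scale.
#'
#' @return An object of class `species_set`.
#' @seealso [glycine_water_ethanol()] for the default system.
#' @export
species_set <- function(names, molar_masses, thermo_volume_ratios,
                        physical_volume_ratios,
                        solvent_molar_volume = 18.068e-6) {
  stopifnot(length(names) == 3L, length(molar_masses) == 3L,
            length(thermo_volume_ratios) == 3L,
            length(physical_volume_ratios) == 3L)
  if (any(molar_masses <= 0) || any(thermo_volume_ratios <= 0) ||
      any(physical_volume_ratios <= 0))
    stop("molar masses and volume ratios must be strictly positive")
  if (abs(thermo_volume_ratios[2] - 1) > 1e-12 ||
      abs(physical_volume_ratios[2] - 1) > 1e-12)
    stop("volume ratios are referenced to the solvent: entry 2 must equal 1")
  structure(list(
    names = as.character(names),
    molar_masses = as.numeric(molar_masses),
    v = as.numeric(thermo_volume_ratios),
    V = as.numeric(physical_volume_ratios),
    solvent_molar_volume = solvent_molar_volume
  ), class = "species_set")
}

#' Molar volume of a pure liquid from its density
#'
#' @param molar_mass g/mol.
#' @param density g/cm^3 at the temperature of interest.
#' @return molar volume in m^3/mol.
#' @examples
#' # ethanol/water molar-volume ratio at 25 C
#' molar_volume(46.07, 0.78945) / molar_volume(18.015, 0.99705)
#' @export
molar_volume <- function(molar_mass, density) {
  stopifnot(molar_mass > 0, density > 0)
  molar_mass / density * 1e-6
}

#' Default glycine/water/ethanol species set
#'
#' Thermo (effective) volume ratios are the fitted values
#' \eqn{v_0/v_1 = 3.58}, \eqn{v_2/v_1 = 1.50}; physical molar-volume
#' ratios are \eqn{V_0/V_1 = 3.58} and \eqn{V_2/V_1 = 3.23}, the latter
#' following from the 25 degrees C pure-liquid molar volumes of ethanol
#' (46.07 g/mol at 0.78945 g/cm^3) and water (18.015 g/mol at
#' 0.99705 g/cm^3).
#'
#' @return A [species_set()].
#' @export
glycine_water_ethanol <- function() {
  species_set(
    names = c("glycine", "water", "ethanol"),
    molar_masses = c(75.07, 18.015, 46.07),
    thermo_volume_ratios = c(3.58, 1, 1.50),
    physical_volume_ratios = c(3.58, 1, 3.23),
    solvent_molar_volume = molar_volume(18.015, 0.99705)
  )
}

#' @export
print.species_set <- function(x, ...) {
  cat("<species_set>", paste(x$names, collapse = "/"), "\n")
  cat("  molar masses [g/mol]:", format(x$molar_masses), "\n")
  cat("  thermo volumes v_i/v_1:", format(x$v), "\n")
  cat("  physical volumes V_i/V_1:", format(x$V), "\n")
  invisible(x)
}

## ---- composition handling -------------------------------------------------

#' Validate a ternary composition in mole fractions
#'
#' @param x numeric length-3 vector of mole fractions.
#' @param tol tolerance on the simplex constraint.
#' @return `x`, normalized to sum exactly to 1.
#' @export
as_composition <- function(x, tol = 1e-12) {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x)))
    stop("a composition is three finite mole fractions")
  if (any(x < -tol)) stop("mole fractions must be non-negative")
  if (abs(sum(x) - 1) > 1e-8)
    stop("mole fractions must sum to 1 (got ", format(sum(x)), ")")
  x <- pmax(x, 0)
  x / sum(x)
}

#' Convert between composition bases
#'
#' Mole fractions \eqn{x_i}, mass fractions \eqn{w_i}, thermodynamic
#' volume fractions \eqn{\phi_i = x_i v_i / \sum_j x_j v_j} (effective
#' volumes of the activity model) and physical volume fractions
#' \eqn{x_i V_i / \sum_j x_j V_j} (pure-component molar volumes of the
#' volume reference frame).  All conversions are mutually inverse.
#'
#' @param x,w,phi length-3 fraction vector in the source basis.
#' @param s a [species_set()].
#' @param basis for the volume conversions, `"physical"` (default,
#'   reference-frame volumes \eqn{V_i}) or `"thermo"` (effective
#'   volumes \eqn{v_i}).
#' @return length-3 vector in the target basis.
#' @name composition-conversions
NULL

#' @rdname composition-conversions
#' @export
mole_to_mass <- function(x, s) {
  m <- x * s$molar_masses
  m / sum(m)
}

#' @rdname composition-conversions
#' @export
mass_to_mole <- function(w, s) {
  n <- w / s$molar_masses
  n / sum(n)
}

#' @rdname composition-conversions
#' @export
mole_to_volume <- function(x, s, basis = c("physical", "thermo")) {
  vol <- switch(match.arg(basis), physical = s$V, thermo = s$v)
  p <- x * vol
  p / sum(p)
}

#' @rdname composition-conversions
#' @export
volume_to_mole <- function(phi, s, basis = c("physical", "thermo")) {
  vol <- switch(match.arg(basis), physical = s$V, thermo = s$v)
  n <- phi / vol
  n / sum(n)
}

## Vectorized basis conversions on 3 x n matrices (internal hot paths).

## mole fractions (3 x n) -> physical volume fractions (3 x n)
phi_from_x_mat <- function(x, s) {
  p <- x * s$V
  sweep(p, 2L, colSums(p), "/")
}

## physical volume fractions (3 x n) -> mole fractions (3 x n)
x_from_phi_mat <- function(phi, s) {
  n <- phi / s$V
  sweep(n, 2L, colSums(n), "/")
}

## mole fractions (3 x n) -> mass fractions (3 x n)
w_from_x_mat <- function(x, s) {
  m <- x * s$molar_masses
  sweep(m, 2L, colSums(m), "/")
}
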