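#' Thermodynamic parameters of the extended Scatchard-Hildebrand model
#'
#' The free-energy model is a Flory-Huggins entropy of mixing (with
#' effective, size-asymmetric molar volumes \eqn{v_i}) plus a regular
#' solution (Scatchard-Hildebrand) residual with symmetric binary
#' interaction parameters \eqn{\chi_{ij}}.  The dimensionless molar
#' mixing free energy is
#' \deqn{\beta \Delta G = \sum_i x_i \ln\phi_i +
#'   (v/v_{ref}) \sum_{i<j} \chi_{ij}\phi_i\phi_j,}
#' with \eqn{v = \sum_i x_i v_i}, \eqn{v_{ref} = v_1} (solvent) and
#' \eqn{\phi_i = x_i v_i / v}.  The larger \eqn{\chi_{ij}}, the stronger
#' the tendency of the pair to demix.
#'
#' `solubility_constant` is the dimensionless chemical-potential gap
#' \eqn{\beta(\mu_0^s - \mu_0^\circ)} between pure solid and pure liquid
#' solute: on the solubility curve \eqn{\ln(x_0\gamma_0)} equals this
#' constant.
#'
#' @param chi01,chi02,chi12 binary interaction parameters
#'   (solute/solvent, solute/antisolvent, solvent/antisolvent).
#' @param solubility_constant dimensionless solid-liquid chemical
#'   potential difference of the solute.
#' @param temperature fixed temperature label in K; the parameters are
#'   dimensionless at this temperature and carry no T dependence.
#' @return object of class `thermo_params` with the symmetric
#'   zero-diagonal matrix `chi`.
#' @export
thermo_params <- function(chi01 = 0.59, chi02 = 2.075, chi12 = 1.07,
                          solubility_constant = -2.2, temperature = 298) {
  if (temperature <= 0) stop("temperature must be positive")
  chi <- matrix(0, 3, 3)
  chi[1, 2] <- chi[2, 1] <- chi01
  chi[1, 3] <- chi[3, 1] <- chi02
  chi[2, 3] <- chi[3, 2] <- chi12
  structure(list(chi = chi, solubility_constant = solubility_constant,
                 temperature = temperature),
            class = "thermo_params")
}

#' Ideal-solution parameter set
#'
#' All interactions zero and all effective volumes equal, so that every
#' activity coefficient is 1 and the thermodynamic factor is the
#' identity.
#'
#' @param solubility_constant kept so that the ideal model still has a
#'   solubility curve to reference.
#' @return list with elements `params` (a [thermo_params()]) and
#'   `species` (a [species_set()] with all volume ratios 1).
#' @export
ideal_system <- function(solubility_constant = -2.2) {
  list(
    params = thermo_params(0, 0, 0, solubility_constant),
    species = species_set(c("solute", "solvent", "antisolvent"),
                          molar_masses = c(75.07, 18.015, 46.07),
                          thermo_volume_ratios = c(1, 1, 1),
                          physical_volume_ratios = c(1, 1, 1))
  )
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("<thermo_params> chi01 =", x$chi[1, 2], " chi02 =", x$chi[1, 3],
      " chi12 =", x$chi[2, 3], "\n  solubility constant =",
      x$solubility_constant, " T =", x$temperature, "K\n")
  invisible(x)
}

## ---- vectorized core ------------------------------------------------------
## All core routines work elementwise on vectors x0, x1, x2 (which may be
## complex, enabling complex-step differentiation) and return vectors.
## Volumes are in solvent units, so v_ref = 1.

## ln gamma_i = ln(v_i/v) + 1 - v_i/v + v_i [ sum_{j != i} chi_ij phi_j - Q ]
## with Q = sum_{j<k} chi_jk phi_j phi_k.  Note ln(phi_i/x_i) = ln(v_i/v)
## exactly, which keeps the expression finite at x_i = 0.
ln_gamma_core <- function(x0, x1, x2, p, s) {
  v0 <- s$v[1]; v1 <- s$v[2]; v2 <- s$v[3]
  c01 <- p$chi[1, 2]; c02 <- p$chi[1, 3]; c12 <- p$chi[2, 3]
  v <- x0 * v0 + x1 * v1 + x2 * v2
  f0 <- x0 * v0 / v; f1 <- x1 * v1 / v; f2 <- x2 * v2 / v
  Q <- c01 * f0 * f1 + c02 * f0 * f2 + c12 * f1 * f2
  list(
    lg0 = log(v0 / v) + 1 - v0 / v + v0 * (c01 * f1 + c02 * f2 - Q),
    lg1 = log(v1 / v) + 1 - v1 / v + v1 * (c01 * f0 + c12 * f2 - Q),
    lg2 = log(v2 / v) + 1 - v2 / v + v2 * (c02 * f0 + c12 * f1 - Q)
  )
}

## dimensionless molar mixing free energy, vectorized (real input only)
gibbs_core <- function(x0, x1, x2, p, s) {
  v0 <- s$v[1]; v1 <- s$v[2]; v2 <- s$v[3]
  c01 <- p$chi[1, 2]; c02 <- p$chi[1, 3]; c12 <- p$chi[2, 3]
  v <- x0 * v0 + x1 * v1 + x2 * v2
  f0 <- x0 * v0 / v; f1 <- x1 * v1 / v; f2 <- x2 * v2 / v
  xlog <- function(x, f) ifelse(x > 0, x * log(f), 0)  # 0 ln 0 := 0
  xlog(x0, f0) + xlog(x1, f1) + xlog(x2, f2) +
    v * (c01 * f0 * f1 + c02 * f0 * f2 + c12 * f1 * f2)
}

## Thermodynamic factor entries Gamma_ij = delta_ij + x_i dln(gamma_i)/dx_j
## for independent species i, j in {0, 1} (antisolvent x2 = 1 - x0 - x1
## dependent).  Derivatives by complex-step differentiation, which is exact
## to machine precision for this analytic composition dependence.
## Inputs are vectors; returns list g00, g01, g10, g11.
gamma_entries_core <- function(x0, x1, p, s, h = 1e-20) {
  x2 <- 1 - x0 - x1
  d0 <- ln_gamma_core(x0 + 1i * h, x1, x2 - 1i * h, p, s)  # d/dx0
  d1 <- ln_gamma_core(x0, x1 + 1i * h, x2 - 1i * h, p, s)  # d/dx1
  list(
    g00 = 1 + x0 * Im(d0$lg0) / h,
    g01 = x0 * Im(d1$lg0) / h,
    g10 = x1 * Im(d0$lg1) / h,
    g11 = 1 + x1 * Im(d1$lg1) / h
  )
}

## eigenvalues of the 2x2 [[a, b], [c, d]] matrices, vectorized; the
## discriminant is non-negative for these matrices (similar to a symmetric
## matrix); tiny negative round-off is clamped.
eig2_core <- function(a, b, c, d) {
  tr <- a + d
  disc <- sqrt(pmax((a - d)^2 + 4 * b * c, 0))
  list(lo = (tr - disc) / 2, hi = (tr + disc) / 2)
}

## ---- user-facing operations ----------------------------------------------

#' Dimensionless molar Gibbs free energy of mixing
#'
#' \eqn{\beta\Delta G_{mix}} per mole of solution, zero at every pure
#' corner by construction (the pure-component chemical-potential terms
#' cancel in a mixing difference; \eqn{0\ln 0 := 0} by continuity).
#'
#' @param x ternary composition in mole fractions.
#' @param p [thermo_params()].
#' @param s [species_set()].
#' @return scalar dimensionless free energy of mixing.
#' @export
molar_gibbs_energy <- function(x, p, s) {
  x <- as_composition(x)
  gibbs_core(x[1], x[2], x[3], p, s)
}

#' Activity coefficients
#'
#' \eqn{\gamma_i} of each species at a composition, from the analytic
#' derivative of the free-energy model.  At \eqn{x_i = 0} the value is
#' the analytic infinite-dilution limit (\eqn{\phi_i/x_i \to v_i/v}).
#'
#' @inheritParams molar_gibbs_energy
#' @return numeric length-3 vector \eqn{(\gamma_0, \gamma_1, \gamma_2)}.
#' @export
activity_coefficients <- function(x, p, s) {
  x <- as_composition(x)
  lg <- ln_gamma_core(x[1], x[2], x[3], p, s)
  exp(c(lg$lg0, lg$lg1, lg$lg2))
}

#' Chemical potentials relative to the pure liquids
#'
#' \eqn{\beta\Delta\mu_i = \ln(x_i\gamma_i)}.  Species at exactly zero
#' mole fraction have a logarithmically divergent chemical potential and
#' are rejected.
#'
#' @inheritParams molar_gibbs_energy
#' @param species integer indices (1-based) of the species to evaluate;
#'   defaults to all three.
#' @return named numeric vector of \eqn{\beta\Delta\mu_i}.
#' @export
chemical_potentials <- function(x, p, s, species = 1:3) {
  x <- as_composition(x)
  if (any(x[species] <= 0))
    stop("chemical potential is singular at zero mole fraction; ",
         "requested species with x_i = 0")
  g <- activity_coefficients(x, p, s)
  stats::setNames(log(x[species] * g[species]), s$names[species])
}

#' Activity-based (nonideal) supersaturation
#'
#' \eqn{S = x_0\gamma_0 e^{-\beta(\mu_0^s - \mu_0^\circ)}}: the solute
#' activity relative to its (composition-independent) activity at
#' saturation.  \eqn{S < 1} undersaturated, \eqn{S = 1} saturated,
#' \eqn{S > 1} supersaturated.
#'
#' @inheritParams molar_gibbs_energy
#' @return scalar supersaturation ratio.
#' @export
supersaturation_nonideal <- function(x, p, s) {
  x <- as_composition(x)
  g <- ln_gamma_core(x[1], x[2], x[3], p, s)
  x[1] * exp(g$lg0 - p$solubility_constant)
}

## vectorized over a 3 x n mole-fraction matrix (hot path for fields)
supersaturation_nonideal_mat <- function(x, p, s) {
  g <- ln_gamma_core(x[1, ], x[2, ], x[3, ], p, s)
  x[1, ] * exp(g$lg0 - p$solubility_constant)
}

#' Thermodynamic factor matrix
#'
#' \eqn{\Gamma_{ij} = \delta_{ij} + x_i \partial\ln\gamma_i/\partial x_j}
#' over the independent species pair (solute, solvent), with the
#' antisolvent mole fraction dependent (\eqn{x_2 = 1 - x_0 - x_1}).
#' \eqn{\Gamma} converts mole-fraction gradients into activity-based
#' driving forces; it reduces to the identity for an ideal solution and
#' loses positive definiteness on the spinodal.
#'
#' @inheritParams molar_gibbs_energy
#' @return object of class `thermo_factor`: list with `gamma_matrix`
#'   (2x2) and `eigenvalues` (ascending).
#' @export
thermodynamic_factor <- function(x, p, s) {
  x <- as_composition(x)
  g <- gamma_entries_core(x[1], x[2], p, s)
  m <- matrix(c(g$g00, g$g10, g$g01, g$g11), 2, 2)
  ev <- eig2_core(g$g00, g$g01, g$g10, g$g11)
  structure(list(gamma_matrix = m, eigenvalues = c(ev$lo, ev$hi)),
            class = "thermo_factor")
}

#' @export
print.thermo_factor <- function(x, ...) {
  cat("<thermo_factor>\n")
  print(x$gamma_matrix)
  cat("  eigenvalues:", format(x$eigenvalues), "\n")
  invisible(x)
}

#' Local thermodynamic stability
#'
#' A composition is materially unstable (inside the spinodal, will
#' demix spontaneously) when the smallest eigenvalue of the
#' thermodynamic factor matrix is non-positive.  The classification is
#' invariant under the choice of which species is treated as dependent.
#'
#' @inheritParams molar_gibbs_energy
#' @param dependent index (1-based) of the species eliminated by the
#'   simplex constraint; the default 3 matches [thermodynamic_factor()].
#' @return list with `stable` (logical) and `min_eigenvalue`.
#' @export
stability_test <- function(x, p, s, dependent = 3L) {
  x <- as_composition(x)
  perm <- switch(as.integer(dependent),
                 `1` = c(2L, 3L, 1L), `2` = c(1L, 3L, 2L), `3` = 1:3)
  if (is.null(perm)) stop("dependent must be 1, 2 or 3")
  xp <- x[perm]
  sp <- s; sp$v <- s$v[perm]
  pp <- p; pp$chi <- p$chi[perm, perm]
  g <- gamma_entries_core(xp[1], xp[2], pp, sp)
  ev <- eig2_core(g$g00, g$g01, g$g10, g$g11)
  list(stable = ev$lo > 0, min_eigenvalue = ev$lo)
}

## vectorized min eigenvalue of Gamma over a 3 x n composition matrix
min_eigenvalue_mat <- function(x, p, s) {
  g <- gamma_entries_core(x[1, ], x[2, ], p, s)
  eig2_core(g$g00, g$g01, g$g10, g$g11)$lo
}
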