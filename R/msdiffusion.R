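#' Maxwell-Stefan diffusion parameters
#'
#' The three symmetric mutual diffusivities of the ternary pair
#' interactions, assumed composition-independent, and the transport
#' mode: `"nonideal"` drives fluxes with activity gradients (via the
#' thermodynamic factor), `"ideal"` with plain mole-fraction gradients
#' (\eqn{\Gamma = I}, the Fickian/ideal contrast case).
#'
#' @param D01,D02,D12 mutual diffusivities in m^2/s
#'   (solute/solvent, solute/antisolvent, solvent/antisolvent).
#' @param mode `"nonideal"` or `"ideal"`.
#' @return object of class `diffusion_params`.
#' @export
diffusion_params <- function(D01 = 1e-9, D02 = 1e-9, D12 = 1e-9,
                             mode = c("nonideal", "ideal")) {
  if (any(c(D01, D02, D12) <= 0)) stop("diffusivities must be positive")
  structure(list(D01 = D01, D02 = D02, D12 = D12,
                 mode = match.arg(mode)),
            class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat("<diffusion_params>", x$mode, "mode; D01 =", x$D01,
      "D02 =", x$D02, "D12 =", x$D12, "m^2/s\n")
  invisible(x)
}

#' State of the mixture at a cell face
#'
#' Bundles the local composition and the spatial mole-fraction
#' gradients needed to evaluate the diffusive flux at one point.
#'
#' @param x composition in mole fractions.
#' @param grad_x per-species mole-fraction gradient in 1/m (must sum to
#'   zero across species).
#' @param s [species_set()] providing the molar volumes that set the
#'   total concentration \eqn{c_t = 1/\sum_i x_i V_i}.
#' @return object of class `face_state` with `x`, `grad_x`, `phi`
#'   (physical volume fractions) and `c_total` (mol/m^3).
#' @export
face_state <- function(x, grad_x, s) {
  x <- as_composition(x)
  grad_x <- as.numeric(grad_x)
  if (length(grad_x) != 3L || abs(sum(grad_x)) > 1e-9 * max(abs(grad_x), 1))
    stop("mole-fraction gradients must sum to zero across species")
  Vabs <- s$V * s$solvent_molar_volume
  structure(list(x = x, grad_x = grad_x,
                 phi = mole_to_volume(x, s, "physical"),
                 c_total = 1 / sum(x * Vabs)),
            class = "face_state")
}

#' Diffusional driving forces
#'
#' \eqn{d_i = \sum_j \Gamma_{ij} \partial x_j/\partial z} for the
#' independent species (solute, solvent), with
#' \eqn{d_2 = -d_0 - d_1}; equals \eqn{x_i \partial\beta\mu_i/\partial z}
#' in the interior.  Ideal mode uses \eqn{\Gamma = I} so the driving
#' force is the bare mole-fraction gradient.
#'
#' @param f a [face_state()].
#' @param p [thermo_params()].
#' @param s [species_set()].
#' @param mode `"nonideal"` or `"ideal"`.
#' @return numeric length-3 driving-force vector in 1/m (sums to zero).
#' @export
driving_forces <- function(f, p, s, mode = c("nonideal", "ideal")) {
  mode <- match.arg(mode)
  g <- f$grad_x
  if (mode == "ideal") return(g)
  ge <- gamma_entries_core(f$x[1], f$x[2], p, s)
  d0 <- ge$g00 * g[1] + ge$g01 * g[2]
  d1 <- ge$g10 * g[1] + ge$g11 * g[2]
  c(d0, d1, -d0 - d1)
}

## ---- flux solve -----------------------------------------------------------

## Species velocities u_i from the Maxwell-Stefan relations
##   d_i = sum_{j != i} x_i x_j (u_j - u_i) / D_ij   (two independent rows)
## plus the volume-frame closure sum_i phi_i u_i = 0.  Species below the
## mole-fraction floor are pinned to the frame velocity (u_i = 0, J_i = 0).
## Scalar version used by the public API; the simulator uses the
## vectorized coefficient assembly below.
ms_velocities <- function(x, phi, d, dp, floor = 1e-12) {
  pres <- x > floor
  if (sum(pres) < 2L)
    stop("degenerate face: fewer than two species present")
  D <- matrix(c(0, dp$D01, dp$D02,
                dp$D01, 0, dp$D12,
                dp$D02, dp$D12, 0), 3, 3)
  A <- matrix(0, 3, 3); b <- numeric(3)
  ## independent MS rows: two when all species are present, one per
  ## absent species fewer (the relations degenerate without it)
  n_ms <- 2L - (3L - sum(pres))
  rows <- which(pres)[seq_len(n_ms)]
  r <- 1L
  for (i in rows) {
    for (j in setdiff(1:3, i)) {
      cc <- x[i] * x[j] / D[i, j]
      A[r, j] <- A[r, j] + cc
      A[r, i] <- A[r, i] - cc
    }
    b[r] <- d[i]
    r <- r + 1L
  }
  ## absent species pinned to the frame velocity
  for (i in which(!pres)) { A[r, i] <- 1; b[r] <- 0; r <- r + 1L }
  ## volume-frame closure
  A[3, ] <- phi; b[3] <- 0
  solve(A, b)
}

#' Maxwell-Stefan diffusive fluxes in the volume reference frame
#'
#' Solves the two independent Maxwell-Stefan relations together with the
#' volume-frame closure \eqn{\sum_i \phi_i u_i = 0} for the species
#' velocities and returns \eqn{J_i = c_t x_i u_i}.  The resulting fluxes
#' satisfy \eqn{\sum_i V_i J_i = 0} and reduce to independent
#' down-gradient Fickian fluxes \eqn{J_i = -c_t D \partial x_i/\partial z}
#' when all diffusivities, volumes are equal and the mode is ideal.
#'
#' @param f a [face_state()].
#' @param d driving-force vector from [driving_forces()].
#' @param dp [diffusion_params()].
#' @param s [species_set()].
#' @param floor mole fractions at or below this are treated as absent
#'   (their flux is exactly zero).
#' @return numeric length-3 molar flux vector in mol/(m^2 s).
#' @export
ms_flux_solve <- function(f, d, dp, s, floor = 1e-12) {
  u <- ms_velocities(f$x, f$phi, d, dp, floor)
  J <- f$c_total * f$x * u
  J[f$x <= floor] <- 0
  J
}

## Vectorized face transport coefficients for the simulator.
## Inputs: x (3 x n mole fractions at faces), Gamma entries (lists of n),
## diffusion params, species set.  Output: the 2x2 matrices A (per face)
## mapping physical-volume-fraction differences to *volume* fluxes:
##   (V0 J0, V1 J1) = -A %*% (d phi0/dz, d phi1/dz),
## stored as vectors A11, A12, A21, A22 (units m^2/s).
face_coefficients <- function(x, p, s, dp, floor = 1e-12) {
  n <- ncol(x)
  x0 <- x[1, ]; x1 <- x[2, ]; x2 <- x[3, ]
  V <- s$V
  sv <- x0 * V[1] + x1 * V[2] + x2 * V[3]
  f0 <- x0 * V[1] / sv; f1 <- x1 * V[2] / sv; f2 <- x2 * V[3] / sv
  ## Gamma (2x2) or identity
  if (dp$mode == "nonideal") {
    ge <- gamma_entries_core(x0, x1, p, s)
  } else {
    ge <- list(g00 = rep(1, n), g01 = rep(0, n),
               g10 = rep(0, n), g11 = rep(1, n))
  }
  ## T: response of (V0 J0 / ct, V1 J1 / ct) to unit driving d = e_k,
  ## k in {0, 1}; by linearity assemble columns for d = Gamma e_k after.
  ## Solve the 3x3 system per face in closed form (Cramer), vectorized.
  ## Rows: MS(0), MS(1), closure.  For faces where a species is absent,
  ## its row is replaced by u_i = 0 and the MS rows use present species.
  D01 <- dp$D01; D02 <- dp$D02; D12 <- dp$D12
  solve_u <- function(d0, d1, d2) {
    ## coefficient rows for the full 3-species case
    a11 <- -(x0 * x1 / D01 + x0 * x2 / D02); a12 <- x0 * x1 / D01
    a13 <- x0 * x2 / D02
    a21 <- x0 * x1 / D01; a22 <- -(x0 * x1 / D01 + x1 * x2 / D12)
    a23 <- x1 * x2 / D12
    a31 <- f0; a32 <- f1; a33 <- f2
    b1 <- d0; b2 <- d1; b3 <- rep(0, n)
    ## masks for an absent species (at most one per face)
    m0 <- x0 <= floor; m1 <- x1 <= floor; m2 <- x2 <= floor
    ## absent solute: rows MS(1), u0 = 0, closure
    if (any(m0)) {
      a11[m0] <- 1; a12[m0] <- 0; a13[m0] <- 0; b1[m0] <- 0
    }
    ## absent solvent: rows MS(0), u1 = 0, closure
    if (any(m1)) {
      a21[m1] <- 0; a22[m1] <- 1; a23[m1] <- 0; b2[m1] <- 0
    }
    ## absent antisolvent: rows MS(0), u1 row -> u2 = 0? keep MS(0) and
    ## replace MS(1) by u2 = 0 would lose d1; instead replace MS(1),
    ## which is degenerate with MS(0) when x2 = 0, by u2 = 0.
    if (any(m2)) {
      a21[m2] <- 0; a22[m2] <- 0; a23[m2] <- 1; b2[m2] <- 0
    }
    det <- a11 * (a22 * a33 - a23 * a32) -
           a12 * (a21 * a33 - a23 * a31) +
           a13 * (a21 * a32 - a22 * a31)
    u0 <- (b1 * (a22 * a33 - a23 * a32) -
           a12 * (b2 * a33 - a23 * b3) +
           a13 * (b2 * a32 - a22 * b3)) / det
    u1 <- (a11 * (b2 * a33 - a23 * b3) -
           b1 * (a21 * a33 - a23 * a31) +
           a13 * (a21 * b3 - b2 * a31)) / det
    u2 <- (a11 * (a22 * b3 - b2 * a32) -
           a12 * (a21 * b3 - b2 * a31) +
           b1 * (a21 * a32 - a22 * a31)) / det
    u0[m0] <- 0; u1[m1] <- 0; u2[m2] <- 0
    list(u0 = u0, u1 = u1, u2 = u2)
  }
  ## dimensionless total concentration scale: V_i J_i = (V_i x_i u_i)/sv
  ## columns of T from unit mole-fraction gradients e0, e1 mapped through
  ## Gamma: d = (Gamma[, k], -sum)
  Tcol <- function(g0, g1) {
    u <- solve_u(g0, g1, -(g0 + g1))
    list(F0 = V[1] * x0 * u$u0 / sv, F1 = V[2] * x1 * u$u1 / sv)
  }
  c1 <- Tcol(ge$g00, ge$g10)   # response to grad x0 = 1
  c2 <- Tcol(ge$g01, ge$g11)   # response to grad x1 = 1
  ## chain rule x <- phi: dx_j/dphi_l = (delta_jl / Vr_j - x_j q_l)/sphi
  ## with sphi = sum_k phi_k / Vr_k and q_l = 1/Vr_l - 1/Vr_2
  sphi <- f0 / V[1] + f1 / V[2] + f2 / V[3]
  q0 <- 1 / V[1] - 1 / V[3]; q1 <- 1 / V[2] - 1 / V[3]
  c00 <- (1 / V[1] - x0 * q0) / sphi; c01 <- (-x0 * q1) / sphi
  c10 <- (-x1 * q0) / sphi;           c11 <- (1 / V[2] - x1 * q1) / sphi
  ## A = -T %*% C (so that F = -A dphi/dz with F down-gradient positive A)
  list(
    A11 = -(c1$F0 * c00 + c2$F0 * c10),
    A12 = -(c1$F0 * c01 + c2$F0 * c11),
    A21 = -(c1$F1 * c00 + c2$F1 * c10),
    A22 = -(c1$F1 * c01 + c2$F1 * c11)
  )
}

## ---- Fick <-> Maxwell-Stefan conversion -----------------------------------

## binary thermodynamic factor 1 + x dln(gamma)/dx on a named edge;
## pair is the 1-based index pair, x is the mole fraction of pair[1].
binary_thermo_factor <- function(x_frac, pair, p, s, h = 1e-20) {
  xv <- numeric(3); xv[pair[1]] <- x_frac; xv[pair[2]] <- 1 - x_frac
  z <- as.list(xv)
  z[[pair[1]]] <- z[[pair[1]]] + 1i * h
  z[[pair[2]]] <- z[[pair[2]]] - 1i * h
  lg <- ln_gamma_core(z[[1]], z[[2]], z[[3]], p, s)
  lgi <- switch(pair[1], lg$lg0, lg$lg1, lg$lg2)
  1 + x_frac * Im(lgi) / h
}

#' Convert between Fickian and Maxwell-Stefan binary diffusivities
#'
#' On a binary edge the two coefficients are related by
#' \eqn{D_{Fick} = \Dbar\,\Gamma_b} with the binary thermodynamic factor
#' \eqn{\Gamma_b = 1 + x\,\partial\ln\gamma/\partial x}.  This is the
#' standard route for estimating Maxwell-Stefan coefficients from
#' measured binary Fickian diffusivities.  Inside a binary miscibility
#' gap \eqn{\Gamma_b \le 0} and the conversion is undefined.
#'
#' @param x_binary mole fraction of the first species of `pair`.
#' @param D coefficient to convert, m^2/s.
#' @param pair integer pair of 1-based species indices naming the edge
#'   (e.g. `c(2, 3)` for solvent/antisolvent).
#' @param p [thermo_params()].
#' @param s [species_set()].
#' @param direction `"fick_to_ms"` (divide by \eqn{\Gamma_b}) or
#'   `"ms_to_fick"` (multiply).
#' @return converted coefficient in m^2/s, with attribute
#'   `"thermo_factor"` carrying \eqn{\Gamma_b}.
#' @export
fick_ms_convert <- function(x_binary, D, pair, p, s,
                            direction = c("fick_to_ms", "ms_to_fick")) {
  direction <- match.arg(direction)
  if (x_binary < 0 || x_binary > 1) stop("x_binary must be in [0, 1]")
  if (length(pair) != 2L || any(!pair %in% 1:3) || pair[1] == pair[2])
    stop("pair must name two distinct species")
  gb <- binary_thermo_factor(x_binary, as.integer(pair), p, s)
  if (gb <= 0)
    stop("binary thermodynamic factor is non-positive (inside the ",
         "miscibility gap): conversion undefined at x = ", x_binary)
  out <- if (direction == "fick_to_ms") D / gb else D * gb
  attr(out, "thermo_factor") <- gb
  out
}
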