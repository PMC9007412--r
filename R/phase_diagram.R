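## Ternary phase diagram: solubility curve, ideal supersaturation,
## spinodal contour and binodal tie lines.

## Composition on the ray of fixed solvent ratio: w = ethanol mass /
## (water + ethanol mass); given solute mole fraction x0 the remaining
## 1 - x0 is split between water and ethanol at that mass ratio.
solvent_ray <- function(x0, w, s) {
  n1 <- (1 - w) / s$molar_masses[2]
  n2 <- w / s$molar_masses[3]
  r <- n2 / (n1 + n2)
  c(x0, (1 - x0) * (1 - r), (1 - x0) * r)
}

#' Solubility of the solute at a fixed solvent composition
#'
#' Solves the saturation condition \eqn{\ln(x_0\gamma_0) =
#' \beta(\mu_0^s-\mu_0^\circ)} for the solute mole fraction along the
#' ray of fixed water:ethanol ratio, by bracketed root finding.
#'
#' @param ethanol_mass_fraction_in_solvent ethanol mass over total
#'   solvent (water + ethanol) mass, in \eqn{[0, 1]}.
#' @param p [thermo_params()].
#' @param s [species_set()].
#' @return list of class `solubility_point`: the solvent ratio, the
#'   saturated solute mole fraction `x_sat`, the solubility as mass
#'   fraction of solution `mass_fraction_solute`, and the full saturated
#'   `composition` (mole fractions).
#' @export
solubility_mole_fraction <- function(ethanol_mass_fraction_in_solvent, p, s) {
  w <- ethanol_mass_fraction_in_solvent
  if (w < 0 || w > 1) stop("solvent ethanol mass fraction must be in [0, 1]")
  resid <- function(x0) {
    x <- solvent_ray(x0, w, s)
    lg <- ln_gamma_core(x[1], x[2], x[3], p, s)
    log(x0) + lg$lg0 - p$solubility_constant
  }
  lo <- 1e-10; hi <- 0.9
  if (resid(lo) >= 0 || resid(hi) <= 0)
    stop("no saturation root in (1e-10, 0.9): parameter pathology")
  x_sat <- stats::uniroot(resid, c(lo, hi), tol = 1e-15)$root
  ## polish by bisection until the residual is tiny
  a <- x_sat * (1 - 1e-6); b <- min(x_sat * (1 + 1e-6), hi)
  if (resid(a) < 0 && resid(b) > 0) {
    for (i in 1:60) {
      m <- (a + b) / 2
      if (resid(m) < 0) a <- m else b <- m
    }
    x_sat <- (a + b) / 2
  }
  comp <- solvent_ray(x_sat, w, s)
  structure(list(
    solvent_ethanol_mass_fraction = w,
    x_sat = x_sat,
    mass_fraction_solute = mole_to_mass(comp, s)[1],
    composition = comp
  ), class = "solubility_point")
}

#' Sampled solubility curve
#'
#' @inheritParams solubility_mole_fraction
#' @param n number of evenly spaced solvent ratios in \eqn{[0, 1]}.
#' @return data.frame with the solvent ratio, `x_sat`, solute mass
#'   fraction and the three saturated mole fractions.
#' @export
solubility_curve <- function(p, s, n = 51) {
  w <- seq(0, 1, length.out = n)
  rows <- lapply(w, function(wi) {
    sp <- solubility_mole_fraction(wi, p, s)
    c(wi, sp$x_sat, sp$mass_fraction_solute, sp$composition)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("ethanol_mass_fraction_in_solvent", "x_sat",
                  "mass_fraction_solute", "x0", "x1", "x2")
  out
}

## Fast solubility interpolator: monotone spline of ln x_sat over the
## solvent ratio, used for per-cell supersaturation fields.
solubility_interpolator <- function(p, s, n = 201) {
  w <- seq(0, 1, length.out = n)
  lx <- vapply(w, function(wi)
    log(solubility_mole_fraction(wi, p, s)$x_sat), numeric(1))
  f <- stats::splinefun(w, lx, method = "hyman")
  function(wq) exp(f(pmin(pmax(wq, 0), 1)))
}

#' Ideal (concentration-ratio) supersaturation
#'
#' \eqn{S_{ideal} = x_0 / x_{sat}(w)}, the solute mole fraction divided
#' by the model solubility at the *local* solvent composition
#' \eqn{w} = ethanol mass / (water + ethanol mass).  This is the
#' supersaturation measure of a concentration-driven (Fickian/ideal)
#' description; it agrees with [supersaturation_nonideal()] exactly on
#' the solubility curve.
#'
#' @param x composition in mole fractions (requires \eqn{x_1+x_2 > 0}).
#' @inheritParams solubility_mole_fraction
#' @param xsat_fun optional precomputed [solubility_interpolator()]
#'   (used internally for whole-field evaluations); by default the
#'   saturation equation is solved exactly.
#' @return scalar concentration-ratio supersaturation.
#' @export
supersaturation_ideal <- function(x, p, s, xsat_fun = NULL) {
  x <- as_composition(x)
  if (x[2] + x[3] <= 0) stop("needs a solvent: x1 + x2 must be positive")
  mm <- x[2:3] * s$molar_masses[2:3]
  w <- mm[2] / sum(mm)
  xs <- if (is.null(xsat_fun)) solubility_mole_fraction(w, p, s)$x_sat
        else xsat_fun(w)
  x[1] / xs
}

## vectorized over a 3 x n mole-fraction matrix
supersaturation_ideal_mat <- function(x, p, s, xsat_fun) {
  m1 <- x[2, ] * s$molar_masses[2]
  m2 <- x[3, ] * s$molar_masses[3]
  w <- m2 / (m1 + m2)
  x[1, ] / xsat_fun(w)
}

## ---- spinodal -------------------------------------------------------------

#' Spinodal boundary on the ternary simplex
#'
#' Samples the zero contour of the smallest eigenvalue of the
#' thermodynamic factor matrix on a barycentric grid.  Grid edges whose
#' endpoints differ in stability sign are refined by bisection to
#' \eqn{|\lambda_{min}| < 10^{-6}}.
#'
#' @inheritParams solubility_mole_fraction
#' @param resolution number of grid divisions per simplex edge
#'   (at least 50).
#' @return data.frame of contour points: mole fractions `x0,x1,x2`,
#'   mass fractions `w0,w1,w2` and the refined `min_eigenvalue`; zero
#'   rows when the model has no unstable region (e.g. ideal parameters).
#' @export
spinodal_boundary <- function(p, s, resolution = 100) {
  if (resolution < 50) stop("resolution must be at least 50")
  n <- resolution
  ## triangular grid of interior-ish points
  idx <- expand.grid(i = 0:n, j = 0:n)
  idx <- idx[idx$i + idx$j <= n, ]
  x0 <- idx$i / n; x1 <- idx$j / n
  lam <- min_eigenvalue_mat(rbind(x0, x1, 1 - x0 - x1), p, s)
  key <- function(i, j) i * (n + 2L) + j
  tab <- stats::setNames(lam, key(idx$i, idx$j))
  pts <- list()
  ## edges to the east, north and north-east neighbours
  for (d in list(c(1L, 0L), c(0L, 1L), c(-1L, 1L))) {
    i2 <- idx$i + d[1]; j2 <- idx$j + d[2]
    ok <- i2 >= 0 & j2 >= 0 & (i2 + j2) <= n
    la <- lam; lb <- tab[as.character(key(i2, j2))]
    sel <- which(ok & !is.na(lb) & (la * lb < 0))
    for (k in sel) {
      a <- c(idx$i[k], idx$j[k]) / n
      b <- c(i2[k], j2[k]) / n
      fa <- la[k]
      for (it in 1:60) {
        m <- (a + b) / 2
        fm <- min_eigenvalue_mat(rbind(m[1], m[2], 1 - sum(m)), p, s)
        if (abs(fm) < 1e-9) break
        if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
      }
      pts[[length(pts) + 1L]] <- c(m, fm)
    }
  }
  if (!length(pts))
    return(data.frame(x0 = numeric(0), x1 = numeric(0), x2 = numeric(0),
                      w0 = numeric(0), w1 = numeric(0), w2 = numeric(0),
                      min_eigenvalue = numeric(0)))
  m <- do.call(rbind, pts)
  x <- rbind(m[, 1], m[, 2], 1 - m[, 1] - m[, 2])
  w <- w_from_x_mat(x, s)
  data.frame(x0 = x[1, ], x1 = x[2, ], x2 = x[3, ],
             w0 = w[1, ], w1 = w[2, ], w2 = w[3, ],
             min_eigenvalue = m[, 3])
}

## ---- binodal --------------------------------------------------------------

## chemical potentials beta*dmu_i of all species at interior compositions
mu_all <- function(x, p, s) {
  lg <- ln_gamma_core(x[1], x[2], x[3], p, s)
  log(x) + c(lg$lg0, lg$lg1, lg$lg2)
}

## two-phase equilibrium on the solute/antisolvent binary edge (x1 = 0):
## equal beta*dmu_0 and beta*dmu_2 in both phases.  Newton with finite
## difference Jacobian on (x0_a, x0_b).
binary_edge_tieline <- function(p, s, guess = c(0.02, 0.7)) {
  fn <- function(z) {
    a <- c(z[1], 0, 1 - z[1]); b <- c(z[2], 0, 1 - z[2])
    (mu_all(a, p, s) - mu_all(b, p, s))[c(1, 3)]
  }
  z <- guess
  for (it in 1:200) {
    f <- fn(z)
    if (max(abs(f)) < 1e-13) break
    J <- matrix(0, 2, 2)
    for (k in 1:2) {
      h <- 1e-8 * max(abs(z[k]), 1e-3)
      zp <- z; zp[k] <- z[k] + h
      J[, k] <- (fn(zp) - f) / h
    }
    dz <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(dz)) break
    step <- 1
    repeat {
      zn <- z - step * dz
      if (all(zn > 1e-12) && all(zn < 1 - 1e-12) && zn[1] < zn[2]) break
      step <- step / 2
      if (step < 1e-8) return(NULL)
    }
    z <- zn
  }
  if (max(abs(fn(z))) > 1e-10 || abs(z[1] - z[2]) < 1e-4) return(NULL)
  z
}

#' Liquid-liquid binodal tie lines
#'
#' Coexisting liquid phase pairs found by equating the chemical
#' potential of every species in the two phases.  The first tie line is
#' the solute/antisolvent binary pair; subsequent lines are continued
#' into the ternary interior by stepping the solvent content of the
#' solute-lean phase and solving the three equal-chemical-potential
#' equations for the remaining unknowns (damped Newton, finite
#' difference Jacobian), until `n_lines` lines are found or the
#' continuation stalls near the plait point.
#'
#' @inheritParams solubility_mole_fraction
#' @param n_lines maximum number of tie lines.
#' @param step initial continuation step in the solvent mole fraction of
#'   the solute-lean phase (halved on failure).
#' @return object of class `binodal`: list with `status`
#'   (`"ok"`, `"no demixing"` or `"stalled"`) and `tielines`, a list of
#'   `list(phase_a, phase_b)` mole-fraction pairs (phase_a solute-lean).
#' @export
binodal_tielines <- function(p, s, n_lines = 20, step = 0.02) {
  edge <- binary_edge_tieline(p, s)
  if (is.null(edge))
    return(structure(list(status = "no demixing", tielines = list()),
                     class = "binodal"))
  tl <- list(list(phase_a = c(edge[1], 0, 1 - edge[1]),
                  phase_b = c(edge[2], 0, 1 - edge[2])))
  ## unknowns: (x0_a, x0_b, x1_b); parameter: x1_a marched upward
  fn <- function(z, x1a) {
    a <- c(z[1], x1a, 1 - z[1] - x1a)
    b <- c(z[2], z[3], 1 - z[2] - z[3])
    mu_all(a, p, s) - mu_all(b, p, s)
  }
  solve3 <- function(z, x1a) {
    for (it in 1:100) {
      f <- fn(z, x1a)
      if (any(!is.finite(f))) return(NULL)
      if (max(abs(f)) < 1e-12) return(z)
      J <- matrix(0, 3, 3)
      for (k in 1:3) {
        h <- 1e-8 * max(abs(z[k]), 1e-3)
        zp <- z; zp[k] <- z[k] + h
        J[, k] <- (fn(zp, x1a) - f) / h
      }
      dz <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(dz)) return(NULL)
      stp <- 1
      repeat {
        zn <- z - stp * dz
        ok <- all(zn > 1e-12) && zn[1] + x1a < 1 - 1e-12 &&
          zn[2] + zn[3] < 1 - 1e-12
        if (ok) break
        stp <- stp / 2
        if (stp < 1e-8) return(NULL)
      }
      z <- zn
    }
    if (max(abs(fn(z, x1a))) < 1e-10) z else NULL
  }
  z <- c(edge[1], edge[2], 0)
  x1a <- 0; dstep <- step
  status <- "ok"
  while (length(tl) < n_lines) {
    advanced <- FALSE
    while (dstep > 1e-5) {
      zg <- z
      zg[3] <- max(zg[3], (x1a + dstep) * 0.8)  # seed water into phase b
      zn <- solve3(zg, x1a + dstep)
      ## stop when the phases collapse (plait point approached)
      if (!is.null(zn) &&
          max(abs(c(zn[1] - zn[2], x1a + dstep - zn[3]))) > 5e-3) {
        z <- zn; x1a <- x1a + dstep; advanced <- TRUE
        break
      }
      dstep <- dstep / 2
    }
    if (!advanced) { status <- if (length(tl) < n_lines) "stalled" else "ok"
                     break }
    tl[[length(tl) + 1L]] <- list(
      phase_a = c(z[1], x1a, 1 - z[1] - x1a),
      phase_b = c(z[2], z[3], 1 - z[2] - z[3]))
  }
  structure(list(status = status, tielines = tl), class = "binodal")
}

#' @export
print.binodal <- function(x, ...) {
  cat("<binodal>", length(x$tielines), "tie lines, status:", x$status, "\n")
  invisible(x)
}

## ---- regions & classification --------------------------------------------

#' Assemble the phase regions of the ternary diagram
#'
#' @inheritParams solubility_mole_fraction
#' @param resolution spinodal grid resolution.
#' @param n_lines binodal tie lines to march.
#' @param n_solubility points on the solubility curve.
#' @return list of class `phase_regions` with `solubility_curve`
#'   (data.frame), `spinodal_boundary` (data.frame) and `binodal`
#'   (a [binodal_tielines()] result).
#' @export
phase_regions <- function(p, s, resolution = 100, n_lines = 20,
                          n_solubility = 51) {
  structure(list(
    solubility_curve = solubility_curve(p, s, n_solubility),
    spinodal_boundary = spinodal_boundary(p, s, resolution),
    binodal = binodal_tielines(p, s, n_lines)
  ), class = "phase_regions")
}

## point-in-polygon (ray casting) in the (x0, x1) plane
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

## polygon of the two-phase (binodal) region from the marched tie lines
binodal_polygon <- function(bin) {
  if (length(bin$tielines) == 0) return(NULL)
  a <- t(vapply(bin$tielines, function(t) t$phase_a[1:2], numeric(2)))
  b <- t(vapply(bin$tielines, function(t) t$phase_b[1:2], numeric(2)))
  rbind(a, b[rev(seq_len(nrow(b))), , drop = FALSE])
}

#' Classify a composition on the phase diagram
#'
#' Material stability (stable / metastable / unstable) from the
#' thermodynamic factor and the binodal hull, plus the solid-phase
#' status (undersaturated / supersaturated) from the activity-based
#' supersaturation.
#'
#' @param x composition in mole fractions.
#' @param regions a [phase_regions()] object.
#' @inheritParams solubility_mole_fraction
#' @return list with `liquid` (one of `"stable"`, `"metastable"`,
#'   `"unstable"`), `solid` (`"undersaturated"` or `"supersaturated"`),
#'   `min_eigenvalue` and `S`.
#' @export
classify_point <- function(x, regions, p, s) {
  x <- as_composition(x)
  st <- stability_test(x, p, s)
  liquid <- if (!st$stable) "unstable" else {
    poly <- binodal_polygon(regions$binodal)
    inb <- !is.null(poly) &&
      point_in_polygon(x[1], x[2], poly[, 1], poly[, 2])
    if (inb) "metastable" else "stable"
  }
  S <- supersaturation_nonideal(x, p, s)
  list(liquid = liquid,
       solid = if (S > 1) "supersaturated" else "undersaturated",
       min_eigenvalue = st$min_eigenvalue, S = S)
}
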