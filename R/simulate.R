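#' Channel geometry and run control
#'
#' A closed, rigid one-dimensional channel.  Both walls are no-flux
#' (Neumann) boundaries.  The default geometry is a 1 mm channel on
#' 1024 cells advanced with a 0.1 s time step.
#'
#' @param length channel width in m.
#' @param n_cells number of finite-volume cells (>= 16).
#' @param dt integration time step in s.
#' @param dt_output interval at which snapshots (and the spinodal halt
#'   check) are taken, s; must be a multiple of `dt`.
#' @param t_end final time, s.
#' @param snapshot_times optional explicit snapshot times (s); defaults
#'   to every `dt_output` up to `t_end`.
#' @param interface_position initial solution/antisolvent interface as a
#'   fraction of the channel length from the left; `NULL` (default)
#'   derives it from the fill ratio of the initial condition.
#' @param halt_on_spinodal stop the run as soon as any cell becomes
#'   materially unstable (the model cannot follow actual demixing).
#' @param method `"semi_implicit"` (backward-Euler diffusion with
#'   Picard-lagged coefficients) or `"explicit"` (stability-limited
#'   sub-stepping; used as a validation reference).
#' @return object of class `channel_config`.
#' @export
channel_config <- function(length = 1e-3, n_cells = 1024, dt = 0.1,
                           dt_output = NULL, t_end = 100,
                           snapshot_times = NULL,
                           interface_position = NULL,
                           halt_on_spinodal = TRUE,
                           method = c("semi_implicit", "explicit")) {
  if (length <= 0) stop("channel length must be positive")
  if (n_cells < 16) stop("n_cells must be at least 16")
  if (dt <= 0 || t_end <= 0) stop("dt and t_end must be positive")
  if (is.null(dt_output)) dt_output <- dt
  if (abs(dt_output / dt - round(dt_output / dt)) > 1e-9)
    stop("dt_output must be a multiple of dt")
  if (!is.null(snapshot_times) &&
      (any(snapshot_times < 0) || any(snapshot_times > t_end + 1e-9)))
    stop("snapshot times must lie in [0, t_end]")
  if (!is.null(interface_position) &&
      (interface_position <= 0 || interface_position >= 1))
    stop("interface_position must be strictly inside (0, 1)")
  structure(list(length = length, n_cells = as.integer(n_cells), dt = dt,
                 dt_output = dt_output, t_end = t_end,
                 snapshot_times = snapshot_times,
                 interface_position = interface_position,
                 halt_on_spinodal = halt_on_spinodal,
                 method = match.arg(method)),
            class = "channel_config")
}

#' Initial two-sided fill of the channel
#'
#' The left side holds the aqueous solute solution, the right side the
#' antisolvent (or antisolvent/solvent mixture).  `fill_ratio` is the
#' antisolvent:solution volume ratio; the interface sits at
#' \eqn{1/(1 + fill\_ratio)} of the channel length from the left.
#'
#' @param solution_side solution composition in mole fractions (use
#'   [solution_from_ideal_S()] or [solution_from_volume_fraction()]).
#' @param antisolvent_side antisolvent composition in mole fractions
#'   (use [antisolvent_from_mass_percent()] or
#'   [antisolvent_from_volume_percent()]).
#' @param fill_ratio antisolvent:solution volume ratio (e.g. `7/3` for
#'   7:3).  Values far outside the studied 9:1 to 3:7 range are
#'   accepted with a warning.
#' @return object of class `initial_condition`.
#' @export
initial_condition <- function(solution_side, antisolvent_side,
                              fill_ratio = 1) {
  solution_side <- as_composition(solution_side)
  antisolvent_side <- as_composition(antisolvent_side)
  if (fill_ratio <= 0) stop("fill_ratio must be positive")
  if (fill_ratio < 3 / 7 - 1e-9 || fill_ratio > 9 + 1e-9)
    warning("fill_ratio outside the studied 9:1-3:7 range")
  structure(list(solution_side = solution_side,
                 antisolvent_side = antisolvent_side,
                 fill_ratio = fill_ratio),
            class = "initial_condition")
}

#' Convenience constructors for initial compositions
#'
#' `solution_from_ideal_S()` builds the aqueous solute solution whose
#' ideal (concentration-ratio) supersaturation against the model
#' solubility in pure solvent equals `S_ideal`.
#' `solution_from_volume_fraction()` sets the solute physical volume
#' fraction directly.  `antisolvent_from_mass_percent()` /
#' `antisolvent_from_volume_percent()` build solute-free
#' solvent/antisolvent mixtures from an antisolvent weight or volume
#' percent (volumes on the physical molar-volume basis).
#'
#' @param S_ideal target concentration-ratio supersaturation in pure
#'   solvent.
#' @param p [thermo_params()].
#' @param s [species_set()].
#' @return composition in mole fractions.
#' @name initial-compositions
#' @export
solution_from_ideal_S <- function(S_ideal, p, s) {
  if (S_ideal < 0) stop("S_ideal must be non-negative")
  xs <- solubility_mole_fraction(0, p, s)$x_sat
  x0 <- S_ideal * xs
  c(x0, 1 - x0, 0)
}

#' @rdname initial-compositions
#' @param phi0 solute physical volume fraction in the aqueous solution.
#' @export
solution_from_volume_fraction <- function(phi0, s) {
  if (phi0 <= 0 || phi0 >= 1) stop("phi0 must be in (0, 1)")
  volume_to_mole(c(phi0, 1 - phi0, 0), s, "physical")
}

#' @rdname initial-compositions
#' @param wt_percent antisolvent mass percent of the solute-free
#'   mixture (0-100).
#' @export
antisolvent_from_mass_percent <- function(wt_percent, s) {
  if (wt_percent < 0 || wt_percent > 100)
    stop("wt_percent must be between 0 and 100")
  w <- wt_percent / 100
  mass_to_mole(c(0, 1 - w, w), s)
}

#' @rdname initial-compositions
#' @param vol_percent antisolvent volume percent of the solute-free
#'   mixture (0-100), on the pure-component molar-volume basis.
#' @export
antisolvent_from_volume_percent <- function(vol_percent, s) {
  if (vol_percent < 0 || vol_percent > 100)
    stop("vol_percent must be between 0 and 100")
  v <- vol_percent / 100
  volume_to_mole(c(0, 1 - v, v), s, "physical")
}

#' Gridded channel state
#'
#' @param time time stamp in s.
#' @param phi 3 x n_cells matrix of physical volume fractions (columns
#'   sum to 1).
#' @param z cell-center coordinates in m.
#' @return object of class `channel_state`.
#' @export
channel_state <- function(time, phi, z) {
  if (any(phi < -1e-9) || any(phi > 1 + 1e-9))
    stop("volume fractions must lie in [0, 1]")
  csum <- colSums(phi)
  if (any(abs(csum - 1) > 1e-10))
    stop("volume fractions must sum to 1 in every cell")
  structure(list(time = time, phi = phi, z = z), class = "channel_state")
}

#' Build the sharp-step initial state
#'
#' Places the step at the cell boundary nearest the interface position
#' (by default \eqn{1/(1+fill\_ratio)} of the length from the left);
#' left cells carry the solution, right cells the antisolvent, in
#' physical volume fractions.
#'
#' @param ic [initial_condition()].
#' @param cc [channel_config()].
#' @param s [species_set()].
#' @return a [channel_state()] at time 0.
#' @export
build_initial_state <- function(ic, cc, s) {
  n <- cc$n_cells
  pos <- if (is.null(cc$interface_position)) 1 / (1 + ic$fill_ratio)
         else cc$interface_position
  n_left <- round(pos * n)
  n_left <- min(max(n_left, 1L), n - 1L)
  phi_l <- mole_to_volume(ic$solution_side, s, "physical")
  phi_r <- mole_to_volume(ic$antisolvent_side, s, "physical")
  phi <- cbind(matrix(phi_l, 3, n_left),
               matrix(phi_r, 3, n - n_left))
  z <- (seq_len(n) - 0.5) * cc$length / n
  channel_state(0, phi, z)
}

#' Volume-weighted fully mixed state
#'
#' The composition reached at infinite time: the volume-weighted
#' average of the two initial fills (no volume change of mixing), with
#' its activity-based and concentration-ratio supersaturations.
#'
#' @inheritParams build_initial_state
#' @param p [thermo_params()].
#' @return list with `x` (mole fractions), `phi` (physical volume
#'   fractions), `S_nonideal` and `S_ideal`.
#' @export
fully_mixed_state <- function(ic, cc, s, p) {
  fs <- if (is.null(cc$interface_position)) 1 / (1 + ic$fill_ratio)
        else cc$interface_position
  phi <- fs * mole_to_volume(ic$solution_side, s, "physical") +
    (1 - fs) * mole_to_volume(ic$antisolvent_side, s, "physical")
  x <- volume_to_mole(phi, s, "physical")
  list(x = x, phi = phi,
       S_nonideal = supersaturation_nonideal(x, p, s),
       S_ideal = supersaturation_ideal(x, p, s))
}

## ---- stepping -------------------------------------------------------------

## Assemble and solve one backward-Euler step with frozen face
## coefficients A (lists of vectors over the n-1 interior faces).
## Unknown ordering: (phi0_1, phi1_1, phi0_2, phi1_2, ...).
## Returns the 2 x n matrix of updated (phi0, phi1).
be_solve <- function(phi01_old, A, dt, dz, idx) {
  n <- ncol(phi01_old)
  r <- dt / dz^2
  ## triplet values: for face f coupling cells f and f+1 with block A_f,
  ## the residual of cell c gains -r * [A_f (phi_{c+1}-phi_c) - ...]
  vals <- c(
    ## diagonal identity
    rep(1, 2 * n),
    ## face contributions, east cell of face (cell f) and west cell (f+1)
    r * A$A11, r * A$A12, r * A$A21, r * A$A22,      # cell f, -A(f) block on (f+1)... see idx
    -r * A$A11, -r * A$A12, -r * A$A21, -r * A$A22,
    -r * A$A11, -r * A$A12, -r * A$A21, -r * A$A22,
    r * A$A11, r * A$A12, r * A$A21, r * A$A22
  )
  M <- Matrix::sparseMatrix(i = idx$i, j = idx$j, x = vals,
                            dims = c(2 * n, 2 * n))
  b <- as.numeric(phi01_old)  # column-major: (phi0_1, phi1_1, phi0_2, ...)
  sol <- Matrix::solve(M, b)
  matrix(as.numeric(sol), 2, n)
}

## Precompute triplet indices matching be_solve's value layout.
be_indices <- function(n) {
  f <- seq_len(n - 1L)             # interior faces
  c0e <- 2L * f - 1L               # row of phi0 eq in cell f (east of face? left)
  c1e <- 2L * f                    # row of phi1 eq in cell f
  c0w <- 2L * f + 1L               # row of phi0 eq in cell f+1
  c1w <- 2L * f + 2L
  u0l <- 2L * f - 1L               # column of phi0 in cell f
  u1l <- 2L * f
  u0r <- 2L * f + 1L               # column of phi0 in cell f+1
  u1r <- 2L * f + 2L
  i <- c(seq_len(2L * n),
         ## cell f rows: +A on own cell, -A on neighbour
         c0e, c0e, c1e, c1e,
         c0e, c0e, c1e, c1e,
         ## cell f+1 rows: -A on cell f, +A on own cell
         c0w, c0w, c1w, c1w,
         c0w, c0w, c1w, c1w)
  j <- c(seq_len(2L * n),
         u0l, u1l, u0l, u1l,
         u0r, u1r, u0r, u1r,
         u0l, u1l, u0l, u1l,
         u0r, u1r, u0r, u1r)
  list(i = i, j = j)
}

## face coefficient matrices from a cell phi field (3 x n): arithmetic
## mean of adjacent cell volume fractions, converted to mole fractions.
## An optional positivity mask (3 x n-1, entries 0 / +1 / -1) caps the
## marked species' face fraction at twice its donor cell's value
## (+1 = left donor, -1 = right donor): at a sharp front this shuts
## off extraction of a species from a cell that barely contains it.
## The mask is only ever raised by the trial-and-redo logic in
## step_state, so resolved dynamics use the plain arithmetic mean.
face_A <- function(phi, p, s, dp, mask = NULL) {
  n <- ncol(phi)
  phl <- phi[, -n, drop = FALSE]
  phr <- phi[, -1, drop = FALSE]
  phf <- (phl + phr) / 2
  if (!is.null(mask) && any(mask != 0)) {
    donor <- ifelse(mask > 0, phl, phr)
    cap <- 2 * pmax(donor, 0) + 1e-16
    sel <- mask != 0
    phf[sel] <- pmin(phf[sel], cap[sel])
  }
  phf <- pmax(phf, 0)
  phf <- sweep(phf, 2L, colSums(phf), "/")
  xf <- x_from_phi_mat(phf, s)
  face_coefficients(xf, p, s, dp)
}

## volume fluxes (species 0 and 1) at interior faces for a given
## coefficient set and cell field
face_fluxes <- function(A, phi, dz) {
  d1 <- diff(phi[1, ]); d2 <- diff(phi[2, ])
  rbind(-(A$A11 * d1 + A$A12 * d2) / dz,
        -(A$A21 * d1 + A$A22 * d2) / dz)
}

## donor-side mask of faces whose flux extracts a species from a
## near-empty donor cell; F rows are species 0 and 1 (2 by closure)
positivity_mask <- function(phi, F, threshold = 1e-8) {
  n <- ncol(phi)
  phl <- phi[, -n, drop = FALSE]
  phr <- phi[, -1, drop = FALSE]
  Ff <- rbind(F, -F[1, ] - F[2, ])
  donor_side <- ifelse(Ff >= 0, 1, -1)
  donor <- ifelse(Ff >= 0, phl, phr)
  mask <- matrix(0L, 3L, n - 1L)
  sel <- donor < threshold & Ff != 0
  mask[sel] <- donor_side[sel]
  mask
}

#' Advance the channel state by one output interval
#'
#' Conservative finite-volume update of the physical volume fractions:
#' face fluxes are evaluated at arithmetic-mean face compositions with
#' central-difference gradients and zero flux at the walls.  The
#' default scheme is backward Euler with Picard-lagged transport
#' coefficients (tolerance 1e-10, at most 50 sweeps); `"explicit"`
#' sub-steps at the diffusive stability limit and serves as a
#' validation reference.  Because the discrete fluxes satisfy the
#' volume-frame closure, the per-cell volume-fraction sum and the
#' per-species total volume are conserved to solver precision.
#'
#' @param state a [channel_state()].
#' @param dt time-step size, s.
#' @param p [thermo_params()].
#' @param s [species_set()].
#' @param dp [diffusion_params()].
#' @param cc [channel_config()] (supplies the geometry and method).
#' @param n_steps number of consecutive steps to take.
#' @return the advanced [channel_state()].
#' @export
step_state <- function(state, dt, p, s, dp, cc, n_steps = 1L) {
  n <- cc$n_cells
  dz <- cc$length / n
  phi <- state$phi
  t <- state$time
  if (cc$method == "semi_implicit") {
    idx <- be_indices(n)
    solve_once <- function(old01, start, mask) {
      cur <- start
      prev01 <- cur[1:2, , drop = FALSE]
      A <- NULL
      for (sw in 1:50) {
        A <- face_A(cur, p, s, dp, mask)
        new01 <- be_solve(old01, A, dt, dz, idx)
        cur <- rbind(new01, 1 - new01[1, ] - new01[2, ])
        if (max(abs(new01 - prev01)) < 1e-10) break
        prev01 <- new01
      }
      list(phi = cur, A = A)
    }
    for (k in seq_len(n_steps)) {
      old01 <- phi[1:2, , drop = FALSE]
      mask <- NULL
      sol <- solve_once(old01, phi, mask)
      ## trial-and-redo: if the unlimited step drives a fraction
      ## negative, cap extraction from near-empty donor cells (donor
      ## sides frozen from the trial fluxes) and re-solve
      for (attempt in 1:4) {
        if (min(sol$phi) >= -1e-11) break
        F <- face_fluxes(sol$A, sol$phi, dz)
        newmask <- positivity_mask(phi, F)
        if (!is.null(mask)) newmask[mask != 0L] <- mask[mask != 0L]
        if (all(newmask == (if (is.null(mask))
          matrix(0L, 3L, n - 1L) else mask))) break
        mask <- newmask
        sol <- solve_once(old01, phi, mask)
      }
      phi <- sol$phi
      t <- t + dt
    }
  } else {
    for (k in seq_len(n_steps)) {
      remaining <- dt
      while (remaining > 1e-15) {
        A <- face_A(phi, p, s, dp)
        amax <- max(abs(A$A11), abs(A$A22), abs(A$A12), abs(A$A21), 1e-12)
        dts <- min(remaining, 0.2 * dz^2 / amax)
        F <- face_fluxes(A, phi, dz)
        div0 <- (c(F[1, ], 0) - c(0, F[1, ])) / dz
        div1 <- (c(F[2, ], 0) - c(0, F[2, ])) / dz
        phi[1, ] <- phi[1, ] - dts * div0
        phi[2, ] <- phi[2, ] - dts * div1
        phi[3, ] <- 1 - phi[1, ] - phi[2, ]
        remaining <- remaining - dts
      }
      t <- t + dt
    }
  }
  channel_state(t, phi, state$z)
}

## ---- full run -------------------------------------------------------------

#' Run a diffusive-mixing simulation
#'
#' Advances the channel from the sharp-step initial state to `t_end`,
#' storing snapshots every `dt_output` (or at the requested
#' `snapshot_times`), computing per-cell activity-based and
#' concentration-ratio supersaturation fields, and optionally halting
#' as soon as any cell enters the spinodal (recording the first
#' offending cell as an LLPS event).
#'
#' @param ic [initial_condition()].
#' @param cc [channel_config()].
#' @param p [thermo_params()].
#' @param s [species_set()].
#' @param dp [diffusion_params()].
#' @param verbose print progress every 100 output intervals.
#' @return object of class `sim_result`: list with `times`, `snapshots`
#'   (list of 3 x n phi matrices), `z`, `S_nonideal` and `S_ideal`
#'   (n_cells x n_snapshots matrices), `fully_mixed`, `llps_event`
#'   (`NULL` or list with `time`, `cell`, `x`), `halted`, plus the
#'   configuration objects used.
#' @export
run_simulation <- function(ic, cc, p, s, dp, verbose = FALSE) {
  state <- build_initial_state(ic, cc, s)
  fm <- fully_mixed_state(ic, cc, s, p)
  xsat_fun <- solubility_interpolator(p, s)
  out_times <- if (!is.null(cc$snapshot_times))
    sort(unique(c(0, cc$snapshot_times)))
  else seq(0, cc$t_end, by = cc$dt_output)
  steps_per <- round(diff(out_times) / cc$dt)
  if (any(abs(diff(out_times) / cc$dt - steps_per) > 1e-6))
    stop("snapshot times must be multiples of dt")
  snapshots <- vector("list", length(out_times))
  times <- numeric(length(out_times))
  snapshots[[1]] <- state$phi
  times[1] <- 0
  llps <- NULL
  n_out <- 1L
  check_llps <- function(st) {
    if (dp$mode != "nonideal") return(NULL)
    x <- x_from_phi_mat(pmax(st$phi, 0), s)
    lam <- min_eigenvalue_mat(x, p, s)
    bad <- which(lam <= 0)
    if (length(bad))
      list(time = st$time, cell = bad[1],
           x = x[, bad[1]], min_eigenvalue = lam[bad[1]])
    else NULL
  }
  if (cc$halt_on_spinodal) llps <- check_llps(state)
  if (is.null(llps)) {
    for (k in seq_along(steps_per)) {
      state <- step_state(state, cc$dt, p, s, dp, cc,
                          n_steps = steps_per[k])
      n_out <- n_out + 1L
      snapshots[[n_out]] <- state$phi
      times[n_out] <- out_times[k + 1]
      if (cc$halt_on_spinodal) {
        llps <- check_llps(state)
        if (!is.null(llps)) break
      }
      if (verbose && k %% 100 == 0)
        message("t = ", format(times[n_out]), " s")
    }
  }
  snapshots <- snapshots[seq_len(n_out)]
  times <- times[seq_len(n_out)]
  Sn <- matrix(0, cc$n_cells, n_out)
  Si <- matrix(0, cc$n_cells, n_out)
  for (k in seq_len(n_out)) {
    x <- x_from_phi_mat(pmax(snapshots[[k]], 0), s)
    Sn[, k] <- supersaturation_nonideal_mat(x, p, s)
    Si[, k] <- supersaturation_ideal_mat(x, p, s, xsat_fun)
  }
  structure(list(times = times, snapshots = snapshots, z = state$z,
                 S_nonideal = Sn, S_ideal = Si, fully_mixed = fm,
                 llps_event = llps, halted = !is.null(llps),
                 ic = ic, cc = cc, thermo = p, species = s,
                 diffusion = dp),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", length(x$times), "snapshots to t =",
      max(x$times), "s on", x$cc$n_cells, "cells (",
      x$diffusion$mode, "mode )\n")
  if (x$halted)
    cat("  halted: spinodal entered at t =", x$llps_event$time,
        "s, cell", x$llps_event$cell, "\n")
  cat("  fully mixed S_nonideal =", format(x$fully_mixed$S_nonideal),
      ", S_ideal =", format(x$fully_mixed$S_ideal), "\n")
  invisible(x)
}

## total volume per species (relative units), for conservation checks
species_volume_totals <- function(phi_mat, dz) rowSums(phi_mat) * dz

#' Conservation diagnostics of a run
#'
#' @param result a [run_simulation()] result.
#' @return list with `max_volume_drift` (max relative drift of the
#'   per-species volume integral over all snapshots) and
#'   `max_sum_defect` (max deviation of the per-cell fraction sum
#'   from 1).
#' @export
conservation_diagnostics <- function(result) {
  dz <- result$cc$length / result$cc$n_cells
  v0 <- species_volume_totals(result$snapshots[[1]], dz)
  drift <- vapply(result$snapshots, function(ph)
    max(abs(species_volume_totals(ph, dz) - v0) / pmax(v0, 1e-300)),
    numeric(1))
  defect <- vapply(result$snapshots, function(ph)
    max(abs(colSums(ph) - 1)), numeric(1))
  list(max_volume_drift = max(drift), max_sum_defect = max(defect))
}
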