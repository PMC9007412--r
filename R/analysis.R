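## Post-processing of simulation results: peak-supersaturation
## trajectories, overshoot metrics, diffusivity-cube sweeps and LLPS
## reporting.

## supersaturation field of the requested measure, cells x snapshots
pick_S <- function(result, which = c("nonideal", "ideal")) {
  switch(match.arg(which), nonideal = result$S_nonideal,
         ideal = result$S_ideal)
}

#' Compositional trajectory of the supersaturation peak
#'
#' For every sampled time (1 s spacing; coarser snapshot series are
#' interpolated linearly in time, finer ones subsampled) the cell with
#' the largest supersaturation is located (leftmost on ties) and its
#' composition reported in mole and mass fractions.  On a ternary
#' diagram this traces where in composition space nucleation is most
#' likely while mixing proceeds.
#'
#' @param result a [run_simulation()] result.
#' @param which `"nonideal"` (activity-based S) or `"ideal"`
#'   (concentration-ratio S).
#' @param spacing trajectory time spacing in s.
#' @return data.frame of class `peak_trajectory`: `time`, `cell`, `z`,
#'   mole fractions `x0,x1,x2`, mass fractions `w0,w1,w2`, `S`.
#' @export
peak_trajectory <- function(result, which = c("nonideal", "ideal"),
                            spacing = 1) {
  which <- match.arg(which)
  S <- pick_S(result, which)
  tt <- result$times
  if (length(tt) < 2) stop("need at least two snapshots")
  grid <- seq(0, max(tt), by = spacing)
  ## per-cell linear interpolation of the S field and phi onto the grid
  rows <- lapply(grid, function(tq) {
    k2 <- min(which(tt >= tq - 1e-9))
    k1 <- max(k2 - 1L, 1L)
    w <- if (k2 == k1) 0 else (tq - tt[k1]) / (tt[k2] - tt[k1])
    Sq <- (1 - w) * S[, k1] + w * S[, k2]
    phiq <- (1 - w) * result$snapshots[[k1]] + w * result$snapshots[[k2]]
    cell <- which.max(Sq)            # which.max returns leftmost maximum
    x <- volume_to_mole(pmax(phiq[, cell], 0), result$species, "physical")
    wfr <- mole_to_mass(x, result$species)
    c(tq, cell, result$z[cell], x, wfr, Sq[cell])
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("time", "cell", "z", "x0", "x1", "x2",
                  "w0", "w1", "w2", "S")
  class(out) <- c("peak_trajectory", "data.frame")
  out
}

#' Supersaturation overshoot metric
#'
#' Maximum supersaturation anywhere in the channel at any sampled time,
#' divided by the supersaturation of the fully mixed state.  Values
#' above 1 mean mixing transiently exceeds the final driving force for
#' crystallization.
#'
#' @inheritParams peak_trajectory
#' @return dimensionless ratio.
#' @export
overshoot_metric <- function(result, which = c("nonideal", "ideal")) {
  which <- match.arg(which)
  S_mix <- switch(which, nonideal = result$fully_mixed$S_nonideal,
                  ideal = result$fully_mixed$S_ideal)
  if (S_mix <= 0) stop("fully mixed supersaturation must be positive")
  max(pick_S(result, which)) / S_mix
}

#' Relaxation time toward the fully mixed state
#'
#' First snapshot time at which the max-norm distance of the physical
#' volume fractions from the fully mixed values falls below `tol`;
#' `Inf` if never reached within the run.
#'
#' @param result a [run_simulation()] result.
#' @param tol max-norm threshold on the volume fractions.
#' @return time in s.
#' @export
relaxation_time <- function(result, tol = 0.01) {
  target <- result$fully_mixed$phi
  d <- vapply(result$snapshots,
              function(ph) max(abs(ph - target)), numeric(1))
  k <- which(d < tol)
  if (length(k)) result$times[k[1]] else Inf
}

#' Sweep the diffusivity cube
#'
#' Runs the same scenario at the 8 corners of the
#' \eqn{(\Dbar_{01}, \Dbar_{02}, \Dbar_{12})} cube, each coefficient at
#' its low or high value, and summarizes each corner by its overshoot
#' metric, relaxation time, peak trajectory and LLPS flag.  Corners
#' split into two groups by the solvent/antisolvent coefficient
#' \eqn{\Dbar_{12}}: slow solvent/antisolvent interdiffusion keeps local
#' solubility low and produces the larger overshoots.
#'
#' @param ic [initial_condition()].
#' @param cc [channel_config()].
#' @param p [thermo_params()].
#' @param s [species_set()].
#' @param mode `"ideal"` or `"nonideal"`.
#' @param low,high the two diffusivity levels in m^2/s.
#' @return object of class `sweep_result`: `summary` data.frame (one
#'   row per corner: the three diffusivities, `D12_level`, `overshoot`,
#'   `relaxation_time`, `llps`) and `runs`, the list of
#'   [run_simulation()] results named by corner label (e.g. `"LHL"`,
#'   levels ordered D01, D02, D12).
#' @export
sweep_diffusivity_cube <- function(ic, cc, p, s,
                                   mode = c("ideal", "nonideal"),
                                   low = 0.40e-9, high = 1.25e-9) {
  mode <- match.arg(mode)
  if (low >= high) stop("low must be less than high")
  lev <- c(low, high)
  corners <- expand.grid(D01 = 1:2, D02 = 1:2, D12 = 1:2)
  lab <- apply(corners, 1, function(k) paste(c("L", "H")[k], collapse = ""))
  runs <- vector("list", 8L)
  rows <- vector("list", 8L)
  for (k in 1:8) {
    dp <- diffusion_params(lev[corners$D01[k]], lev[corners$D02[k]],
                           lev[corners$D12[k]], mode)
    r <- run_simulation(ic, cc, p, s, dp)
    runs[[k]] <- r
    rows[[k]] <- data.frame(
      corner = lab[k],
      D01 = lev[corners$D01[k]], D02 = lev[corners$D02[k]],
      D12 = lev[corners$D12[k]],
      D12_level = c("low", "high")[corners$D12[k]],
      overshoot = overshoot_metric(r, mode),
      relaxation_time = relaxation_time(r),
      llps = r$halted)
  }
  names(runs) <- lab
  structure(list(summary = do.call(rbind, rows), runs = runs,
                 mode = mode, low = low, high = high),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>", x$mode, "mode, levels", x$low, "/", x$high, "\n")
  print(x$summary[, c("corner", "D12_level", "overshoot",
                      "relaxation_time", "llps")], row.names = FALSE)
  invisible(x)
}

#' Report a liquid-liquid phase separation event
#'
#' Summarizes whether (and when, where, at which composition) the run
#' entered the spinodal, and classifies the fully mixed composition on
#' the phase diagram -- localized demixing can occur even when the
#' final mixture is outside the two-phase region.
#'
#' @param result a [run_simulation()] result.
#' @param regions a [phase_regions()] object for classification.
#' @return list with `occurred`, `time`, `cell`, `composition`
#'   (mole fractions), `event_class` and `fully_mixed_class`
#'   ([classify_point()] results).
#' @export
llps_report <- function(result, regions) {
  p <- result$thermo; s <- result$species
  fmc <- classify_point(result$fully_mixed$x, regions, p, s)
  if (is.null(result$llps_event))
    return(list(occurred = FALSE, time = NA_real_, cell = NA_integer_,
                composition = NULL, event_class = NULL,
                fully_mixed_class = fmc))
  ev <- result$llps_event
  list(occurred = TRUE, time = ev$time, cell = ev$cell,
       composition = ev$x,
       event_class = classify_point(ev$x, regions, p, s),
       fully_mixed_class = fmc)
}
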