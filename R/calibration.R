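## Least-squares calibration of the thermodynamic parameters against
## solubility and binary activity-coefficient tables, plus a seeded
## synthetic-data generator so that fitting is testable without any
## external dataset.

#' Synthetic solubility table
#'
#' Evaluates the model solubility on an even grid of solvent ratios and
#' perturbs it with multiplicative lognormal noise.  Deterministic for
#' a fixed seed; stands in for measured solubility data when exercising
#' the fitting routines.
#'
#' @param true_params generating [thermo_params()].
#' @param s [species_set()].
#' @param n_points number of rows (>= 4).
#' @param noise_rel relative noise scale (lognormal sdlog).
#' @param seed integer RNG seed.
#' @param w_max largest solvent ethanol mass fraction on the grid.
#' @return data.frame of class `solubility_table` with columns
#'   `ethanol_mass_fraction_in_solvent` and `mass_fraction_solute`, and
#'   attribute `provenance = "synthetic"`.
#' @export
synth_solubility_table <- function(true_params, s, n_points = 25,
                                   noise_rel = 0, seed = 1,
                                   w_max = 0.9) {
  if (n_points < 4) stop("need at least 4 points")
  if (noise_rel < 0) stop("noise_rel must be non-negative")
  w <- seq(0, w_max, length.out = n_points)
  m <- vapply(w, function(wi)
    solubility_mole_fraction(wi, true_params, s)$mass_fraction_solute,
    numeric(1))
  if (noise_rel > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    m <- m * exp(stats::rnorm(n_points, 0, noise_rel))
  }
  out <- data.frame(ethanol_mass_fraction_in_solvent = w,
                    mass_fraction_solute = m)
  attr(out, "provenance") <- "synthetic"
  class(out) <- c("solubility_table", "data.frame")
  out
}

## save/restore the global RNG state so generators are self-contained
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Synthetic binary activity-coefficient table
#'
#' Activity coefficient of the second species of `pair` along the named
#' binary edge, with multiplicative lognormal noise.  Mirrors the
#' vapor-liquid-equilibrium-derived activity tables used to calibrate
#' binary interaction parameters.
#'
#' @inheritParams synth_solubility_table
#' @param pair 1-based species index pair naming the edge; the table
#'   holds \eqn{\gamma} of `pair[2]` versus the mole fraction of
#'   `pair[2]`.
#' @param x_range range of the tabulated mole fraction.
#' @return data.frame of class `activity_table` with columns `x` and
#'   `gamma`, attributes `pair` and `provenance = "synthetic"`.
#' @export
synth_activity_table <- function(true_params, s, pair = c(2, 3),
                                 n_points = 25, noise_rel = 0, seed = 1,
                                 x_range = c(0.02, 0.98)) {
  if (n_points < 4) stop("need at least 4 points")
  x <- seq(x_range[1], x_range[2], length.out = n_points)
  g <- vapply(x, function(xi) {
    xv <- numeric(3); xv[pair[2]] <- xi; xv[pair[1]] <- 1 - xi
    activity_coefficients(xv, true_params, s)[pair[2]]
  }, numeric(1))
  if (noise_rel > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    g <- g * exp(stats::rnorm(n_points, 0, noise_rel))
  }
  out <- data.frame(x = x, gamma = g)
  attr(out, "pair") <- as.integer(pair)
  attr(out, "provenance") <- "synthetic"
  class(out) <- c("activity_table", "data.frame")
  out
}

## bounded multi-start minimization shared by both fits
multistart_fit <- function(objective, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    r <- tryCatch(
      stats::optim(st, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(r)) next
    if (is.null(best) || r$value < best$value) best <- r
  }
  if (is.null(best)) stop("all optimization starts failed")
  best
}

#' Fit solubility parameters
#'
#' Recovers the solute/antisolvent interaction parameter and the
#' solubility constant by least squares on the *log* solubility (mass
#' fraction of solution), reflecting that antisolvent-rich solubilities
#' span orders of magnitude.  The remaining parameters are held fixed.
#'
#' @param table a solubility table (columns
#'   `ethanol_mass_fraction_in_solvent`, `mass_fraction_solute`), e.g.
#'   from [synth_solubility_table()] or [read_solubility_table()].
#' @param fixed [thermo_params()] providing the non-fitted parameters
#'   and the starting point.
#' @param s [species_set()].
#' @param starts number of multi-start initial points.
#' @return list of class `fit_result`: `parameters` (named vector with
#'   `chi02` and `solubility_constant`), `residual_norm` (RMS of log
#'   residuals), `converged`.
#' @export
fit_solubility_params <- function(table, fixed, s, starts = 3) {
  w <- table$ethanol_mass_fraction_in_solvent
  m <- table$mass_fraction_solute
  if (length(w) < 4) stop("at least 4 rows are needed for fitting")
  if (diff(range(w)) < 0.3)
    stop("table must span at least 0.3 in solvent ratio for ",
         "identifiability")
  if (any(w < 0 | w > 1 | m <= 0 | m >= 1)) stop("fractions out of range")
  obj <- function(theta) {
    p <- fixed
    p$chi[1, 3] <- p$chi[3, 1] <- theta[1]
    p$solubility_constant <- theta[2]
    pred <- tryCatch(
      vapply(w, function(wi)
        solubility_mole_fraction(wi, p, s)$mass_fraction_solute,
        numeric(1)),
      error = function(e) NULL)
    if (is.null(pred)) return(1e6)
    sum((log(pred) - log(m))^2)
  }
  lower <- c(0, -10); upper <- c(10, 0)
  s0 <- c(fixed$chi[1, 3], fixed$solubility_constant)
  st <- list(pmin(pmax(s0, lower), upper), c(1, -1), c(4, -4))[
    seq_len(max(1, starts))]
  best <- multistart_fit(obj, st, lower, upper)
  structure(list(
    parameters = c(chi02 = best$par[1],
                   solubility_constant = best$par[2]),
    residual_norm = sqrt(best$value / length(w)),
    converged = best$convergence == 0
  ), class = "fit_result")
}

#' Fit binary interaction and volume ratio to an activity table
#'
#' Least squares on \eqn{\ln\gamma} of the tabulated species along a
#' binary edge, with the pair interaction parameter and the non-solvent
#' species' effective volume ratio free.  This is how solvent/
#' antisolvent and solute/solvent parameters are calibrated from
#' activity data.
#'
#' @param table an activity table (columns `x`, `gamma`, attribute
#'   `pair`), e.g. from [synth_activity_table()] or
#'   [read_activity_table()].
#' @param fixed [thermo_params()] for the non-fitted parameters.
#' @param s [species_set()]; the fitted volume ratio is that of the
#'   non-solvent member of the pair.
#' @param starts number of multi-start initial points.
#' @return list of class `fit_result`: `parameters` (named `chi` and
#'   `v_ratio`), `residual_norm`, `converged`.
#' @export
fit_binary_activity <- function(table, fixed, s, starts = 3) {
  pair <- attr(table, "pair")
  if (is.null(pair) || length(pair) != 2L || any(!pair %in% 1:3) ||
      pair[1] == pair[2])
    stop("table must carry a valid species 'pair' attribute")
  if (!(2L %in% pair))
    stop("one member of the pair must be the solvent (species 2)")
  free_sp <- pair[pair != 2L]
  x <- table$x; g <- table$gamma
  if (length(x) < 4) stop("at least 4 rows are needed for fitting")
  if (any(x <= 0 | x >= 1)) stop("mole fractions must be in (0, 1)")
  if (any(g <= 0)) stop("activity coefficients must be positive")
  obj <- function(theta) {
    p <- fixed
    p$chi[pair[1], pair[2]] <- p$chi[pair[2], pair[1]] <- theta[1]
    sv <- s
    sv$v[free_sp] <- theta[2]
    pred <- vapply(x, function(xi) {
      xv <- numeric(3); xv[pair[2]] <- xi; xv[pair[1]] <- 1 - xi
      lg <- ln_gamma_core(xv[1], xv[2], xv[3], p, sv)
      switch(pair[2], lg$lg0, lg$lg1, lg$lg2)
    }, numeric(1))
    sum((pred - log(g))^2)
  }
  lower <- c(0, 0.1); upper <- c(10, 10)
  s0 <- c(fixed$chi[pair[1], pair[2]], s$v[free_sp])
  st <- list(pmin(pmax(s0, lower), upper), c(0.5, 0.5), c(3, 3))[
    seq_len(max(1, starts))]
  best <- multistart_fit(obj, st, lower, upper)
  structure(list(
    parameters = c(chi = best$par[1], v_ratio = best$par[2]),
    residual_norm = sqrt(best$value / length(x)),
    converged = best$convergence == 0
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", if (x$converged) "converged" else "NOT converged",
      "; RMS residual", format(x$residual_norm), "\n")
  print(x$parameters)
  invisible(x)
}

#' Read and write calibration tables as CSV
#'
#' Solubility tables have columns `ethanol_mass_fraction_in_solvent`
#' and `mass_fraction_solute`; activity tables have columns `x` and
#' `gamma` plus a header comment `# pair: i j` naming the edge
#' (1-based species indices).
#'
#' @param path file path.
#' @return the table with the class and attributes expected by the
#'   fitting functions.
#' @name calibration-io
#' @export
read_solubility_table <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("ethanol_mass_fraction_in_solvent", "mass_fraction_solute")
  if (!all(need %in% names(d)))
    stop("expected columns ", paste(need, collapse = ", "))
  class(d) <- c("solubility_table", "data.frame")
  attr(d, "provenance") <- path
  d
}

#' @rdname calibration-io
#' @param table table to write.
#' @export
write_solubility_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname calibration-io
#' @export
read_activity_table <- function(path) {
  first <- readLines(path, n = 1L)
  pair <- if (grepl("^# *pair:", first))
    as.integer(strsplit(sub("^# *pair: *", "", first), "[ ,]+")[[1]])
  else c(2L, 3L)
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("x", "gamma") %in% names(d)))
    stop("expected columns x, gamma")
  attr(d, "pair") <- pair
  attr(d, "provenance") <- path
  class(d) <- c("activity_table", "data.frame")
  d
}

#' @rdname calibration-io
#' @export
write_activity_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# pair:", paste(attr(table, "pair"), collapse = " ")),
             con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}
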