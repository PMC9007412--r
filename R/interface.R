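## Declarative run configuration: YAML parsing with defaults,
## validation, serialization, and output writing.

run_config_defaults <- function() {
  list(
    species = list(
      names = c("glycine", "water", "ethanol"),
      molar_masses = c(75.07, 18.015, 46.07),
      thermo_volume_ratios = c(3.58, 1, 1.50),
      physical_volume_ratios = c(3.58, 1, 3.23)
    ),
    thermo = list(chi01 = 0.59, chi02 = 2.075, chi12 = 1.07,
                  solubility_constant = -2.2, temperature = 298),
    diffusion = list(D01 = 1e-9, D02 = 1e-9, D12 = 1e-9,
                     mode = "nonideal"),
    channel = list(length = 1e-3, n_cells = 1024, dt = 0.1,
                   dt_output = 0.1, t_end = 100,
                   interface_position = NULL,
                   halt_on_spinodal = TRUE, method = "semi_implicit"),
    initial = list(solution = list(basis = "ideal_supersaturation",
                                   value = 0.85),
                   antisolvent = list(basis = "mass", percent = 80),
                   fill_ratio = 1),
    output = list(outdir = "terndiff-out", snapshot_times = NULL,
                  verbose = FALSE)
  )
}

## recursively overlay user values onto defaults, rejecting unknown keys
overlay <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  for (k in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(defaults))
      stop("unknown configuration key: ", key)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]]))
      defaults[[k]] <- overlay(defaults[[k]], user[[k]], key)
    else
      defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Parse a run configuration
#'
#' Reads a YAML document with sections `species`, `thermo`,
#' `diffusion`, `channel`, `initial` and `output`; every omitted key
#' falls back to the default glycine/water/ethanol setup (fitted
#' thermodynamic parameters, nominal diffusivities of 1e-9 m^2/s,
#' 1 mm channel, 1024 cells, 0.1 s step).  Unknown keys and invariant
#' violations raise descriptive errors naming the offending key.
#'
#' The `initial` section supports solution bases
#' `ideal_supersaturation`, `volume_fraction` and `mole` and
#' antisolvent bases `mass` (wt percent), `volume` (vol percent) and
#' `mole`.
#'
#' @param text YAML text, or a file path if `file = TRUE`.
#' @param file interpret `text` as a path.
#' @return object of class `run_config`: the validated configuration
#'   list plus ready-built `species_set`, `thermo_params`,
#'   `diffusion_params`, `channel_config` and `initial_condition`
#'   objects (fields `s`, `p`, `dp`, `cc`, `ic`).
#' @export
parse_config <- function(text = "", file = FALSE) {
  user <- if (file) yaml::read_yaml(text)
          else yaml::yaml.load(text)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("configuration must be a YAML mapping")
  user_chi <- user$thermo$chi         # full-matrix alternative to the
  user$thermo$chi <- NULL             # three pairwise keys
  cfg <- overlay(run_config_defaults(), user)
  if (!is.null(user_chi)) {
    chi <- matrix(unlist(user_chi), 3, 3, byrow = TRUE)
    if (max(abs(chi - t(chi))) > 1e-12)
      stop("thermo.chi must be symmetric")
    if (max(abs(diag(chi))) > 1e-12)
      stop("thermo.chi must have a zero diagonal")
    cfg$thermo$chi01 <- chi[1, 2]; cfg$thermo$chi02 <- chi[1, 3]
    cfg$thermo$chi12 <- chi[2, 3]
  }
  s <- species_set(cfg$species$names, cfg$species$molar_masses,
                   cfg$species$thermo_volume_ratios,
                   cfg$species$physical_volume_ratios)
  p <- thermo_params(cfg$thermo$chi01, cfg$thermo$chi02,
                     cfg$thermo$chi12, cfg$thermo$solubility_constant,
                     cfg$thermo$temperature)
  dp <- diffusion_params(cfg$diffusion$D01, cfg$diffusion$D02,
                         cfg$diffusion$D12, cfg$diffusion$mode)
  ch <- cfg$channel
  cc <- channel_config(ch$length, ch$n_cells, ch$dt, ch$dt_output,
                       ch$t_end, cfg$output$snapshot_times,
                       ch$interface_position, ch$halt_on_spinodal,
                       ch$method)
  ini <- cfg$initial
  sol <- switch(ini$solution$basis,
    ideal_supersaturation = solution_from_ideal_S(ini$solution$value, p, s),
    volume_fraction = solution_from_volume_fraction(ini$solution$value, s),
    mole = as_composition(unlist(ini$solution$value)),
    stop("initial.solution.basis must be one of ",
         "'ideal_supersaturation', 'volume_fraction', 'mole'"))
  anti <- switch(ini$antisolvent$basis,
    mass = antisolvent_from_mass_percent(ini$antisolvent$percent, s),
    volume = antisolvent_from_volume_percent(ini$antisolvent$percent, s),
    mole = as_composition(unlist(ini$antisolvent$value)),
    stop("initial.antisolvent.basis must be one of ",
         "'mass', 'volume', 'mole'"))
  ic <- initial_condition(sol, anti, ini$fill_ratio)
  structure(c(cfg, list(s = s, p = p, dp = dp, cc = cc, ic = ic)),
            class = "run_config")
}

#' Serialize a run configuration back to YAML
#'
#' The serialized form reparses to an identical configuration, so every
#' run is reproducible from its echoed effective config.
#'
#' @param cfg a [parse_config()] result.
#' @return YAML text.
#' @export
serialize_config <- function(cfg) {
  keep <- c("species", "thermo", "diffusion", "channel", "initial",
            "output")
  yaml::as.yaml(cfg[keep])
}

#' Write simulation outputs to disk
#'
#' One CSV per snapshot (cell-center position, the three physical
#' volume fractions, mass and mole fractions, and both supersaturation
#' fields, at full double precision) plus a JSON run summary with the
#' fully mixed state, any LLPS event, and conservation diagnostics.
#'
#' @param result a [run_simulation()] result.
#' @param outdir output directory (created if missing).
#' @param stem file-name stem for the snapshot CSVs.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(result, outdir, stem = "snapshot") {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  s <- result$species
  paths <- character(0)
  for (k in seq_along(result$times)) {
    ph <- result$snapshots[[k]]
    x <- x_from_phi_mat(pmax(ph, 0), s)
    w <- w_from_x_mat(x, s)
    d <- data.frame(
      z = result$z,
      phi0 = ph[1, ], phi1 = ph[2, ], phi2 = ph[3, ],
      w0 = w[1, ], w1 = w[2, ], w2 = w[3, ],
      x0 = x[1, ], x1 = x[2, ], x2 = x[3, ],
      S_ideal = result$S_ideal[, k],
      S_nonideal = result$S_nonideal[, k])
    path <- file.path(outdir, sprintf("%s_t%g.csv", stem,
                                      result$times[k]))
    dput_csv(d, path)
    paths <- c(paths, path)
  }
  cons <- conservation_diagnostics(result)
  fm <- result$fully_mixed
  summ <- list(
    times = result$times,
    n_cells = result$cc$n_cells,
    mode = result$diffusion$mode,
    fully_mixed = list(x = fm$x, phi = fm$phi,
                       S_nonideal = fm$S_nonideal, S_ideal = fm$S_ideal,
                       stable = stability_test(fm$x, result$thermo,
                                               s)$stable),
    llps_event = if (is.null(result$llps_event)) NULL else list(
      time = result$llps_event$time, cell = result$llps_event$cell,
      x = result$llps_event$x),
    conservation = cons)
  jpath <- file.path(outdir, paste0(stem, "_summary.json"))
  jsonlite::write_json(summ, jpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, jpath))
}

## CSV writer preserving full double precision (17 significant digits)
dput_csv <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(col) format(col, digits = 17))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
}

#' Export phase-diagram samples as CSV
#'
#' Writes the solubility curve, spinodal contour and binodal tie-line
#' endpoints of a [phase_regions()] object into one CSV with a region
#' label per row, in both mole- and mass-fraction coordinates.
#'
#' @param regions a [phase_regions()] object.
#' @param s [species_set()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_phase_diagram <- function(regions, s, path) {
  sol <- regions$solubility_curve
  solx <- rbind(sol$x0, sol$x1, sol$x2)
  solw <- w_from_x_mat(solx, s)
  rows <- data.frame(region = "solubility",
                     x0 = solx[1, ], x1 = solx[2, ], x2 = solx[3, ],
                     w0 = solw[1, ], w1 = solw[2, ], w2 = solw[3, ])
  sp <- regions$spinodal_boundary
  if (nrow(sp))
    rows <- rbind(rows, data.frame(region = "spinodal",
                                   x0 = sp$x0, x1 = sp$x1, x2 = sp$x2,
                                   w0 = sp$w0, w1 = sp$w1, w2 = sp$w2))
  for (tl in regions$binodal$tielines) {
    for (ph in list(tl$phase_a, tl$phase_b)) {
      w <- mole_to_mass(ph, s)
      rows <- rbind(rows, data.frame(region = "binodal",
                                     x0 = ph[1], x1 = ph[2], x2 = ph[3],
                                     w0 = w[1], w1 = w[2], w2 = w[3]))
    }
  }
  dput_csv(rows, path)
  invisible(path)
}
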