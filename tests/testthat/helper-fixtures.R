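## Shared fixtures and independent oracles for the suite.

gwe <- glycine_water_ethanol()
tp <- thermo_params()
ideal <- ideal_system()

## random interior compositions, fixed seed
random_compositions <- function(n, seed = 42, margin = 0.02) {
  set.seed(seed)
  t(vapply(seq_len(n), function(i) {
    repeat {
      u <- stats::runif(2)
      x <- c(min(u), diff(sort(u)), 1 - max(u))
      if (all(x > margin)) return(x)
    }
  }, numeric(3)))
}

## finite-difference oracle for ln gamma derivatives w.r.t. x_j
## (species 3 dependent), central differences
fd_dlngamma <- function(x, j, p, s, h = 1e-6) {
  f <- function(xx) log(activity_coefficients(xx, p, s))
  e <- numeric(3); e[j] <- h; e[3] <- e[3] - h
  (f(x + e) - f(x - e)) / (2 * h)
}

## finite-difference thermodynamic factor matrix oracle
fd_gamma_matrix <- function(x, p, s, h = 1e-6) {
  m <- matrix(0, 2, 2)
  for (j in 1:2) {
    d <- fd_dlngamma(x, j, p, s, h)
    m[, j] <- x[1:2] * d[1:2]
  }
  m + diag(2)
}

## brute-force flux oracle: least squares over all three Maxwell-Stefan
## relations plus the volume closure (rows rescaled to comparable size)
brute_force_flux <- function(f, d, dp, s) {
  D <- matrix(c(0, dp$D01, dp$D02,
                dp$D01, 0, dp$D12,
                dp$D02, dp$D12, 0), 3, 3)
  x <- f$x
  A <- matrix(0, 4, 3)
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    A[i, j] <- A[i, j] + x[i] * x[j] / D[i, j]
    A[i, i] <- A[i, i] - x[i] * x[j] / D[i, j]
  }
  A[4, ] <- f$phi
  b <- c(d, 0)
  sc <- max(abs(A[1:3, ]))
  A[1:3, ] <- A[1:3, ] / sc; b[1:3] <- b[1:3] / sc
  u <- unname(stats::lm.fit(A, b)$coefficients)
  f$c_total * x * u
}

## reference mixing scenario: aqueous solution at ideal S = 0.85 against
## 80 wt% ethanol antisolvent, 1:1 fill (interface at 0.5 mm)
refmix_ic <- function(p = tp, s = gwe) {
  initial_condition(solution_from_ideal_S(0.85, p, s),
                    antisolvent_from_mass_percent(80, s),
                    fill_ratio = 1)
}

## cache expensive simulation runs across test files
.run_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .run_cache))
    assign(name, expr, envir = .run_cache)
  get(name, envir = .run_cache)
}

## reduced-scale reference mixing run (256 cells, 1:1 fill), shared by
## the analysis and acceptance suites
refmix_run <- function(mode) {
  cached(paste0("refmix_", mode), {
    ic <- refmix_ic()
    cc <- channel_config(n_cells = 256, dt = 0.5, t_end = 2500,
                         dt_output = 2.5, halt_on_spinodal = FALSE)
    run_simulation(ic, cc, tp, gwe, diffusion_params(mode = mode))
  })
}
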