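test_that("initial-composition constructors reproduce the documented
           conversions", {
  ## solution at ideal S = 0.85 against pure-water solubility
  sol <- solution_from_ideal_S(0.85, tp, gwe)
  expect_equal(sol[1], 0.0655, tolerance = 6e-3)
  expect_equal(sol[3], 0)
  expect_equal(supersaturation_ideal(sol, tp, gwe), 0.85,
               tolerance = 1e-9)
  ## 80 wt% ethanol antisolvent: hand mass-to-mole conversion
  anti <- antisolvent_from_mass_percent(80, gwe)
  n2 <- 0.80 / 46.07; n1 <- 0.20 / 18.015
  expect_equal(anti[3], n2 / (n1 + n2), tolerance = 1e-9)
  expect_equal(anti[3], 0.610, tolerance = 1e-3)
  expect_equal(anti[1], 0)
  ## volume-percent constructor uses the physical molar volumes
  av <- antisolvent_from_volume_percent(50, gwe)
  expect_equal(mole_to_volume(av, gwe, "physical")[3], 0.5,
               tolerance = 1e-12)
  expect_error(antisolvent_from_mass_percent(150, gwe), "between")
  ## solute volume-fraction constructor round-trips
  sv <- solution_from_volume_fraction(0.2, gwe)
  expect_equal(mole_to_volume(sv, gwe, "physical")[1], 0.2,
               tolerance = 1e-12)
})

test_that("the initial state is a sharp step at the fill-ratio
           interface", {
  ic <- initial_condition(solution_from_ideal_S(0.85, tp, gwe),
                          antisolvent_from_mass_percent(80, gwe),
                          fill_ratio = 7 / 3)
  cc <- channel_config(n_cells = 64, t_end = 1)
  st <- build_initial_state(ic, cc, gwe)
  ## 7:3 antisolvent:solution -> solution occupies the left 30%
  n_left <- round(0.3 * 64)
  expect_equal(unname(st$phi[, n_left]),
               mole_to_volume(ic$solution_side, gwe, "physical"))
  expect_equal(unname(st$phi[, n_left + 1]),
               mole_to_volume(ic$antisolvent_side, gwe, "physical"))
  expect_equal(colSums(st$phi), rep(1, 64))
  expect_warning(initial_condition(c(0.05, 0.95, 0), c(0, 0.4, 0.6),
                                   fill_ratio = 30), "range")
})

test_that("a uniform state is a fixed point and single steps conserve
           species volumes to round-off", {
  ic <- initial_condition(c(0.03, 0.67, 0.30), c(0.03, 0.67, 0.30))
  cc <- channel_config(n_cells = 32, dt = 0.1, t_end = 1,
                       halt_on_spinodal = FALSE)
  st <- build_initial_state(ic, cc, gwe)
  st2 <- step_state(st, 0.1, tp, gwe, diffusion_params(), cc)
  expect_equal(st2$phi, st$phi, tolerance = 1e-12)
  ## a sharp-step state: conservation after one step
  ic <- refmix_ic()
  st <- build_initial_state(ic, cc, gwe)
  st2 <- step_state(st, 0.1, tp, gwe, diffusion_params(), cc)
  expect_equal(rowSums(st2$phi), rowSums(st$phi), tolerance = 1e-12)
  expect_equal(colSums(st2$phi), rep(1, 32), tolerance = 1e-12)
})

test_that("the semi-implicit step agrees with sub-stepped explicit
           integration", {
  ic <- refmix_ic()
  cci <- channel_config(n_cells = 256, dt = 0.1, t_end = 5,
                        halt_on_spinodal = FALSE)
  cce <- channel_config(n_cells = 256, dt = 0.1, t_end = 5,
                        halt_on_spinodal = FALSE, method = "explicit")
  dp <- diffusion_params(mode = "nonideal")
  ## compare one 0.1 s step from an evolved state: the first instants
  ## after the sharp step have O(1) front dynamics where a single
  ## backward-Euler step and the exact integral legitimately differ
  st <- step_state(build_initial_state(ic, cci, gwe), 0.1, tp, gwe,
                   dp, cci, n_steps = 50)
  si <- step_state(st, 0.1, tp, gwe, dp, cci)
  se <- step_state(st, 0.1, tp, gwe, dp, cce)
  expect_lt(max(abs(si$phi - se$phi)), 1e-4)
})

test_that("ideal equal-coefficient transport matches the closed-form
           cosine-series solution of the diffusion equation", {
  ## equal diffusivities and equal molar volumes decouple the species
  ic <- initial_condition(c(0.0658, 0.9342, 0), c(0, 0.39, 0.61),
                          fill_ratio = 1)
  cc <- channel_config(n_cells = 256, dt = 0.1, t_end = 10,
                       halt_on_spinodal = FALSE)
  r <- run_simulation(ic, cc, ideal$params, ideal$species,
                      diffusion_params(mode = "ideal"))
  L <- cc$length; D <- 1e-9
  z <- r$z
  phi0 <- r$snapshots[[1]]
  series <- function(phiL, phiR, t, pos = 0.5) {
    val <- rep(pos * phiL + (1 - pos) * phiR, length(z))
    for (k in 1:2000) {
      ak <- 2 * (phiL - phiR) * sin(k * pi * pos) / (k * pi)
      val <- val + ak * cos(k * pi * z / L) * exp(-D * (k * pi / L)^2 * t)
    }
    val
  }
  last <- r$snapshots[[length(r$snapshots)]]
  for (i in 1:3)
    expect_lt(max(abs(last[i, ] - series(phi0[i, 1], phi0[i, 256], 10))),
              1e-3)
})

test_that("identical fills stay constant and the long-time limit is the
           fully mixed state", {
  same <- c(0.02, 0.58, 0.40)
  ic <- initial_condition(same, same)
  cc <- channel_config(n_cells = 32, dt = 0.5, t_end = 5,
                       halt_on_spinodal = FALSE)
  r <- run_simulation(ic, cc, tp, gwe, diffusion_params())
  for (ph in r$snapshots)
    expect_equal(ph, r$snapshots[[1]], tolerance = 1e-10)
  expect_equal(r$fully_mixed$x, same, tolerance = 1e-12)
  ## fill_ratio -> infinity approaches the antisolvent composition
  ic2 <- initial_condition(c(0.05, 0.95, 0), c(0, 0.4, 0.6),
                           fill_ratio = 9)
  fm <- fully_mixed_state(ic2, channel_config(t_end = 1), gwe, tp)
  expect_equal(fm$phi,
               0.1 * mole_to_volume(c(0.05, 0.95, 0), gwe, "physical") +
               0.9 * mole_to_volume(c(0, 0.4, 0.6), gwe, "physical"),
               tolerance = 1e-12)
  ## a short channel mixes to the fully mixed state
  ic3 <- refmix_ic()
  cc3 <- channel_config(length = 1e-4, n_cells = 32, dt = 0.5,
                        t_end = 60, halt_on_spinodal = FALSE)
  r3 <- run_simulation(ic3, cc3, tp, gwe, diffusion_params())
  fm3 <- fully_mixed_state(ic3, cc3, gwe, tp)
  expect_lt(max(abs(r3$snapshots[[length(r3$snapshots)]] - fm3$phi)),
            1e-3)
})

test_that("per-species volumes are conserved and fraction sums stay 1
           across a full nonideal run", {
  ic <- refmix_ic()
  cc <- channel_config(n_cells = 64, dt = 0.5, t_end = 50,
                       halt_on_spinodal = FALSE)
  r <- run_simulation(ic, cc, tp, gwe, diffusion_params())
  d <- conservation_diagnostics(r)
  expect_lt(d$max_volume_drift, 1e-8)
  expect_lt(d$max_sum_defect, 1e-10)
  expect_true(all(vapply(r$snapshots, min, numeric(1)) > -1e-8))
  expect_true(all(vapply(r$snapshots, max, numeric(1)) < 1 + 1e-8))
})

test_that("snapshot fields converge under mesh and time refinement", {
  ic <- refmix_ic()
  cc1 <- channel_config(n_cells = 128, dt = 0.2, t_end = 20,
                        dt_output = 20, halt_on_spinodal = FALSE)
  cc2 <- channel_config(n_cells = 256, dt = 0.1, t_end = 20,
                        dt_output = 20, halt_on_spinodal = FALSE)
  r1 <- run_simulation(ic, cc1, tp, gwe, diffusion_params())
  r2 <- run_simulation(ic, cc2, tp, gwe, diffusion_params())
  coarse <- r1$snapshots[[length(r1$snapshots)]]
  fine <- r2$snapshots[[length(r2$snapshots)]]
  fine_avg <- (fine[, seq(1, 255, by = 2)] + fine[, seq(2, 256, by = 2)]) / 2
  expect_lt(max(abs(coarse - fine_avg)), 1e-3)
})
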