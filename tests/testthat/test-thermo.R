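test_that("mixing free energy vanishes at pure corners and matches the
           ideal entropy and the frozen regression value", {
  expect_equal(molar_gibbs_energy(c(1, 0, 0), tp, gwe), 0)
  expect_equal(molar_gibbs_energy(c(0, 0, 1), tp, gwe), 0)
  x3 <- rep(1, 3) / 3
  expect_equal(molar_gibbs_energy(x3, ideal$params, ideal$species),
               log(1 / 3), tolerance = 1e-12)
  ## frozen from an independent direct evaluation of the formula
  expect_equal(molar_gibbs_energy(c(0.0655, 0.9345, 0), tp, gwe),
               -0.203846611698632, tolerance = 1e-12)
})

test_that("activity coefficients match their stated limits and the
           free-energy derivative oracle", {
  expect_equal(activity_coefficients(c(0.3, 0.3, 0.4), ideal$params,
                                     ideal$species), rep(1, 3))
  expect_equal(activity_coefficients(c(1, 0, 0), tp, gwe)[1], 1)
  ## frozen from numerical differentiation of n * G (step 1e-6)
  g <- activity_coefficients(c(0.0655, 0.9345, 0), tp, gwe)
  expect_equal(g[1], 1.5016404221, tolerance = 1e-7)
  ## analytic infinite-dilution limit of ethanol in water
  expect_equal(activity_coefficients(c(0, 1, 0), tp, gwe)[3],
               4.5288367032, tolerance = 1e-9)
})

test_that("activity coefficients are the partial-molar derivative of the
           mixing free energy at random interior points", {
  xs <- random_compositions(20)
  for (k in seq_len(nrow(xs))) {
    x <- xs[k, ]
    nG <- function(n) sum(n) * molar_gibbs_energy(n / sum(n), tp, gwe)
    h <- 1e-6
    for (i in 1:3) {
      e <- numeric(3); e[i] <- h
      mu_fd <- (nG(x + e) - nG(x - e)) / (2 * h)
      mu <- log(x[i]) + log(activity_coefficients(x, tp, gwe)[i])
      expect_equal(mu, mu_fd, tolerance = 1e-6)
    }
  }
})

test_that("Gibbs-Duhem holds along random directions on the simplex", {
  xs <- random_compositions(100, seed = 7)
  set.seed(11)
  for (k in seq_len(nrow(xs))) {
    x <- xs[k, ]
    d <- stats::rnorm(3); d <- d - mean(d)          # tangent direction
    d <- d / sqrt(sum(d^2)) * 1e-6
    lg <- function(xx) log(activity_coefficients(xx, tp, gwe))
    dlng <- (lg(x + d) - lg(x - d)) / 2
    expect_lt(abs(sum(x * dlng)) / sqrt(sum(dlng^2)), 1e-8)
  }
})

test_that("chemical potentials compose x and gamma and reject absent
           species", {
  expect_equal(unname(chemical_potentials(c(1, 0, 0), tp, gwe, 1)), 0)
  expect_equal(unname(chemical_potentials(c(0.2, 0.5, 0.3),
                                          ideal$params, ideal$species)),
               log(c(0.2, 0.5, 0.3)))
  x <- c(0.0655, 0.9345, 0)
  g <- activity_coefficients(x, tp, gwe)
  expect_equal(unname(chemical_potentials(x, tp, gwe, 1)),
               log(x[1] * g[1]))
  expect_error(chemical_potentials(x, tp, gwe, 3), "singular")
})

test_that("nonideal supersaturation is the activity ratio and is 1 on
           the solubility curve", {
  expect_equal(supersaturation_nonideal(c(0, 0.5, 0.5), tp, gwe), 0)
  for (w in c(0, 0.4, 0.8)) {
    pt <- solubility_mole_fraction(w, tp, gwe)
    expect_equal(supersaturation_nonideal(pt$composition, tp, gwe), 1,
                 tolerance = 1e-9)
  }
})

test_that("thermodynamic factor matches the finite-difference oracle and
           is the identity for the ideal model", {
  tf <- thermodynamic_factor(c(0.3, 0.4, 0.3), ideal$params,
                             ideal$species)
  expect_equal(tf$gamma_matrix, diag(2))
  expect_equal(tf$eigenvalues, c(1, 1))
  for (x in list(c(0.02, 0.93, 0.05), c(0.1, 0.3, 0.6),
                 c(0.25, 0.45, 0.30))) {
    tf <- thermodynamic_factor(x, tp, gwe)
    expect_equal(tf$gamma_matrix, fd_gamma_matrix(x, tp, gwe),
                 tolerance = 1e-6)
  }
  ## finite on the solute-free edge
  tf0 <- thermodynamic_factor(c(0, 0.6, 0.4), tp, gwe)
  expect_true(all(is.finite(tf0$gamma_matrix)))
  expect_equal(tf0$gamma_matrix[1, 1], 1)   # Gamma_00 -> 1 as x0 -> 0
})

test_that("stability classification matches a free-energy Hessian
           oracle and is invariant to the dependent-species choice", {
  ## dilute aqueous corner: stable (Hessian of G positive definite)
  x <- c(0.001, 0.998, 0.001)
  h <- 1e-5
  G <- function(a, b) molar_gibbs_energy(c(a, b, 1 - a - b), tp, gwe)
  H <- matrix(c(
    (G(x[1] + h, x[2]) - 2 * G(x[1], x[2]) + G(x[1] - h, x[2])) / h^2,
    (G(x[1] + h, x[2] + h) - G(x[1] + h, x[2] - h) -
     G(x[1] - h, x[2] + h) + G(x[1] - h, x[2] - h)) / (4 * h^2),
    (G(x[1] + h, x[2] + h) - G(x[1] + h, x[2] - h) -
     G(x[1] - h, x[2] + h) + G(x[1] - h, x[2] - h)) / (4 * h^2),
    (G(x[1], x[2] + h) - 2 * G(x[1], x[2]) + G(x[1], x[2] - h)) / h^2),
    2, 2)
  expect_true(all(eigen(H)$values > 0))
  expect_true(stability_test(x, tp, gwe)$stable)
  expect_gt(min(thermodynamic_factor(x, tp, gwe)$eigenvalues), 0)
  ## ideal mixtures never demix
  expect_true(stability_test(c(0.3, 0.3, 0.4), ideal$params,
                             ideal$species)$stable)
  ## glycine-ethanol tie-line midpoint is unstable
  bin <- cached("binodal", binodal_tielines(tp, gwe, 12))
  mid <- (bin$tielines[[1]]$phase_a + bin$tielines[[1]]$phase_b) / 2
  expect_false(stability_test(mid, tp, gwe)$stable)
  ## dependent-species invariance of the classification
  for (x in list(c(0.02, 0.93, 0.05), mid, c(0.3, 0.2, 0.5)))
    for (dep in 1:2)
      expect_equal(stability_test(x, tp, gwe, dependent = dep)$stable,
                   stability_test(x, tp, gwe)$stable)
})

test_that("outputs are invariant under consistent solvent/antisolvent
           relabeling", {
  perm <- c(1L, 3L, 2L)
  ## the permuted system takes the old antisolvent as its solvent, so
  ## volume ratios are renormalized to it and the interaction
  ## parameters rescale with the new reference volume
  s2 <- species_set(gwe$names[perm], gwe$molar_masses[perm],
                    gwe$v[perm] / gwe$v[3],
                    gwe$V[perm] / gwe$V[3],
                    gwe$solvent_molar_volume * gwe$V[3])
  p2 <- tp; p2$chi <- tp$chi[perm, perm] * gwe$v[3]
  x <- c(0.1, 0.5, 0.4)
  g1 <- activity_coefficients(x, tp, gwe)
  g2 <- activity_coefficients(x[perm], p2, s2)
  expect_equal(g2, g1[perm], tolerance = 1e-12)
  expect_equal(stability_test(x[perm], p2, s2)$stable,
               stability_test(x, tp, gwe)$stable)
})
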