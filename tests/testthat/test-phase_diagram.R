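test_that("solubility solve reproduces the bisection oracle and defines
           saturation", {
  pt <- solubility_mole_fraction(0, tp, gwe)
  ## frozen from an independent bisection on the activity residual,
  ## bracket (1e-8, 0.5)
  expect_equal(pt$x_sat, 0.077443645175, tolerance = 1e-9)
  ## the activity at the point equals the saturation activity
  expect_equal(log(pt$x_sat *
                   activity_coefficients(pt$composition, tp, gwe)[1]),
               tp$solubility_constant, tolerance = 1e-10)
  expect_equal(supersaturation_nonideal(pt$composition, tp, gwe), 1,
               tolerance = 1e-9)
  expect_error(solubility_mole_fraction(1.2, tp, gwe), "\\[0, 1\\]")
})

test_that("solubility decreases strictly with antisolvent content", {
  w <- seq(0, 1, length.out = 21)
  xs <- vapply(w, function(wi)
    solubility_mole_fraction(wi, tp, gwe)$x_sat, numeric(1))
  expect_true(all(diff(xs) < 0))
  ## ethanol-rich solubility is orders of magnitude below aqueous
  expect_lt(xs[21] / xs[1], 0.01)
})

test_that("ideal supersaturation is the concentration ratio against the
           local-solvent solubility", {
  expect_equal(supersaturation_ideal(c(0, 0.6, 0.4), tp, gwe), 0)
  xs <- solubility_mole_fraction(0, tp, gwe)$x_sat
  x0 <- 0.85 * xs
  expect_equal(supersaturation_ideal(c(x0, 1 - x0, 0), tp, gwe), 0.85,
               tolerance = 1e-9)
  for (w in c(0.2, 0.7)) {
    pt <- solubility_mole_fraction(w, tp, gwe)
    expect_equal(supersaturation_ideal(pt$composition, tp, gwe), 1,
                 tolerance = 1e-8)
    ## both measures coincide on the curve
    expect_equal(supersaturation_nonideal(pt$composition, tp, gwe), 1,
                 tolerance = 1e-8)
  }
})

test_that("the two supersaturation measures coincide everywhere for the
           ideal parameter set", {
  xs <- random_compositions(10, seed = 3)
  for (k in seq_len(nrow(xs)))
    expect_equal(
      supersaturation_ideal(xs[k, ], ideal$params, ideal$species),
      supersaturation_nonideal(xs[k, ], ideal$params, ideal$species),
      tolerance = 1e-6)
})

test_that("spinodal contour is empty for ideal parameters, touches the
           solute/antisolvent side otherwise, and sits on the stability
           sign change", {
  expect_equal(nrow(spinodal_boundary(ideal$params, ideal$species, 50)),
               0)
  sp <- cached("spinodal", spinodal_boundary(tp, gwe, 80))
  expect_gt(nrow(sp), 20)
  expect_true(all(abs(sp$min_eigenvalue) < 1e-6))
  ## region lies on the solvent-poor (solute/antisolvent) side
  expect_lt(min(sp$x1), 0.05)
  expect_gt(max(sp$x2), 0.5)
  ## sign change across +-1e-4 normal perturbations (sampled)
  set.seed(5)
  for (k in sample(nrow(sp), 10)) {
    x <- c(sp$x0[k], sp$x1[k], sp$x2[k])
    ## normal direction: gradient of the min eigenvalue
    h <- 1e-6
    g <- vapply(1:2, function(j) {
      e <- numeric(3); e[j] <- h; e[3] <- -h
      (stability_test(x + e, tp, gwe)$min_eigenvalue -
       stability_test(x - e, tp, gwe)$min_eigenvalue) / (2 * h)
    }, numeric(1))
    d <- c(g[1], g[2], -g[1] - g[2])
    d <- d / sqrt(sum(d^2)) * 1e-4
    s_plus <- stability_test(x + d, tp, gwe)$min_eigenvalue
    s_minus <- stability_test(x - d, tp, gwe)$min_eigenvalue
    expect_lt(s_plus * s_minus, 0)
  }
})

test_that("binodal tie lines satisfy equal chemical potentials, start
           from an independent binary solve, and enclose the spinodal", {
  expect_equal(binodal_tielines(ideal$params, ideal$species)$status,
               "no demixing")
  bin <- cached("binodal", binodal_tielines(tp, gwe, 12))
  expect_gte(length(bin$tielines), 5)
  ## independent binary two-phase oracle on the solute/antisolvent edge:
  ## solve the two equal-activity conditions by nested bisection
  mu_bin <- function(x0) {
    g <- activity_coefficients(c(x0, 0, 1 - x0), tp, gwe)
    c(log(x0 * g[1]), log((1 - x0) * g[3]))
  }
  first <- bin$tielines[[1]]
  expect_equal(first$phase_a[2], 0)
  expect_equal(mu_bin(first$phase_a[1]), mu_bin(first$phase_b[1]),
               tolerance = 1e-8)
  ## equal chemical potentials in all tie lines (species present)
  for (tl in bin$tielines) {
    pres <- which(tl$phase_a > 0 & tl$phase_b > 0)
    mua <- chemical_potentials(tl$phase_a, tp, gwe, pres)
    mub <- chemical_potentials(tl$phase_b, tp, gwe, pres)
    expect_equal(mua, mub, tolerance = 1e-8)
    ## endpoints outside the spinodal, midpoint inside
    expect_true(stability_test(tl$phase_a, tp, gwe)$stable)
    expect_true(stability_test(tl$phase_b, tp, gwe)$stable)
    mid <- (tl$phase_a + tl$phase_b) / 2
    expect_false(stability_test(mid, tp, gwe)$stable)
  }
})

test_that("spinodal region lies strictly inside the binodal hull and the
           two-phase region is supersaturated with respect to the solid", {
  sp <- cached("spinodal", spinodal_boundary(tp, gwe, 80))
  bin <- cached("binodal", binodal_tielines(tp, gwe, 12))
  poly <- terndiff:::binodal_polygon(bin)
  inside <- vapply(seq_len(nrow(sp)), function(k)
    terndiff:::point_in_polygon(sp$x0[k], sp$x1[k], poly[, 1], poly[, 2]),
    logical(1))
  ## spinodal samples reachable by the marched tie lines must be inside;
  ## the continuation stops short of the plait point, so restrict to the
  ## solvent range the tie lines cover
  x1max <- max(vapply(bin$tielines, function(t) t$phase_a[2], numeric(1)))
  covered <- sp$x1 <= x1max - 1e-6
  expect_true(all(inside[covered]))
  ## sampled interior points of the two-phase region: S > 1
  for (tl in bin$tielines[seq(1, length(bin$tielines), by = 3)]) {
    mid <- (tl$phase_a + tl$phase_b) / 2
    expect_gt(supersaturation_nonideal(mid, tp, gwe), 1)
  }
})

test_that("classify_point distinguishes the stable, metastable and
           unstable regions and the solid-phase status", {
  regions <- cached("regions", {
    list(solubility_curve = NULL,
         spinodal_boundary = cached("spinodal",
                                    spinodal_boundary(tp, gwe, 80)),
         binodal = cached("binodal", binodal_tielines(tp, gwe, 12)))
  })
  ## pure-water corner neighbourhood
  cl <- classify_point(c(0.001, 0.998, 0.001), regions, tp, gwe)
  expect_equal(cl$liquid, "stable")
  expect_equal(cl$solid, "undersaturated")
  ## the initial aqueous solution of the mixing scenarios
  x0 <- 0.85 * solubility_mole_fraction(0, tp, gwe)$x_sat
  cl <- classify_point(c(x0, 1 - x0, 0), regions, tp, gwe)
  expect_equal(cl$liquid, "stable")
  expect_equal(cl$solid, "undersaturated")
  expect_equal(cl$S, 0.89, tolerance = 0.005)
  ## a tie-line midpoint is unstable and supersaturated
  tl <- regions$binodal$tielines[[3]]
  cl <- classify_point((tl$phase_a + tl$phase_b) / 2, regions, tp, gwe)
  expect_equal(cl$liquid, "unstable")
  expect_equal(cl$solid, "supersaturated")
  ## a point between binodal and spinodal is metastable
  tl1 <- regions$binodal$tielines[[1]]
  near_edge <- 0.97 * tl1$phase_b + 0.03 * tl1$phase_a
  cl <- classify_point(near_edge, regions, tp, gwe)
  expect_equal(cl$liquid, "metastable")
})
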