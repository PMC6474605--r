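# Out-of-plane and constraint energies: closed forms, invariances, and the
# C++ force-kernel consistency with the vectorised R path.

test_that("bending energy approaches the closed-form sphere value and is scale invariant", {
  kappa <- 2.5e-19
  m <- buildIcosphere(140, 3L)
  expect_equal(bendingEnergy(m, kappa), 8 * pi * kappa, tolerance = 0.02)
  m2 <- buildMembrane(m@vertices * 2, m@triangles)
  expect_equal(bendingEnergy(m2, kappa), bendingEnergy(m, kappa),
               tolerance = 1e-9)
  # only non-flat edges contribute
  flat <- subdivideMesh(buildIcosahedron(1), 1L, radius = NA)
  g <- edgeGeometry(flat)
  contrib <- 2 * kappa * (g@edgeCurvature * 1e-6)^2 / (g@edgeArea * 1e-12)
  expect_equal(sum(contrib[abs(g@dihedrals) < 1e-9]), 0, tolerance = 1e-30)
})

test_that("area energy separates global dilation from local redistribution", {
  kA <- 1e-3; ka <- 5e-5
  m <- buildIcosphere(140, 2L)
  g <- edgeGeometry(m)
  con <- selfConstraints(m)
  expect_equal(areaEnergy(m, kA, ka, con), 0, tolerance = 1e-40)
  # uniform 1% dilation: both closed forms
  md <- buildMembrane(m@vertices * sqrt(1.01), m@triangles)
  expected <- 0.5 * kA * 1e-4 * con@A0 * 1e-12 + 0.5 * ka * 1e-4 * con@A0 * 1e-12
  expect_equal(areaEnergy(md, kA, ka, con), expected, tolerance = 1e-9)
  # redistribution at constant total area: global term zero, local positive
  set.seed(9)
  w <- stats::runif(length(con@Ak0), 0.9, 1.1)
  conShift <- referenceConstraints(A0 = con@A0, V0 = con@V0,
    Ak0 = con@Ak0 * w * sum(con@Ak0) / sum(con@Ak0 * w),
    dA0 = con@dA0, C0 = con@C0)
  expect_equal(sum(conShift@Ak0), sum(con@Ak0), tolerance = 1e-9)
  eShift <- areaEnergy(m, kA, ka, conShift)
  eGlobalOnly <- areaEnergy(m, kA, 0, conShift)
  expect_lt(eGlobalOnly, 1e-25)
  expect_gt(eShift, 0)
})

test_that("volume energy follows its closed form including the printed arithmetic check", {
  m <- buildIcosphere(140, 2L)
  con <- selfConstraints(m)
  expect_equal(volumeEnergy(m, 100, con), 0, tolerance = 1e-40)
  con2 <- con; con2@V0 <- enclosedVolume(m) / 1.1
  expect_equal(volumeEnergy(m, 100, con2),
               0.5 * 100 * 0.01 * con2@V0 * 1e-18, tolerance = 1e-9)
  # kv = 100 N/m^2, V0 = 93.48 um^3, V = 0.99 V0 -> 4.674e-16 J
  eArith <- 0.5 * 100 * (0.99 - 1)^2 * 93.48e-18
  expect_equal(eArith, 4.674e-16, tolerance = 1e-4)
  con3 <- con; con3@V0 <- 93.48
  mScaled <- buildMembrane(m@vertices * (0.99 * 93.48 / enclosedVolume(m))^(1 / 3),
                           m@triangles)
  expect_equal(volumeEnergy(mScaled, 100, con3), 4.674e-16, tolerance = 1e-3)
})

test_that("leaflet constraint energies vanish at reference and scale as 1/A", {
  kad <- 7.5e-17; kC <- 2.5e-17; D0 <- 2e-9
  m <- buildIcosphere(140, 2L)
  con <- selfConstraints(m)
  expect_lt(areaDifferenceEnergy(m, kad, D0, con), 1e-30)
  expect_lt(totalCurvatureEnergy(m, kC, D0, con), 1e-30)
  # both parenthesisations of the printed expression coincide
  g <- edgeGeometry(m)
  A <- surfaceArea(m) * 1e-12
  dA <- bilayerAreaDifference(g, D0 * 1e6) * 1e-12
  dev <- dA - 0.9 * dA
  conDev <- con; conDev@dA0 <- 0.9 * con@dA0
  e1 <- pi * kad / (2 * D0^2) * dev^2 / A
  e2 <- pi * kad / (2 * D0^2) * (dev / A)^2 * A
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_equal(areaDifferenceEnergy(m, kad, D0, conDev), e1, tolerance = 1e-9)
  # fixed absolute deviation, doubled area -> energy halves
  m2 <- buildMembrane(m@vertices * sqrt(2), m@triangles)
  g2 <- edgeGeometry(m2)
  dev0 <- 0.05e-12  # 0.05 um^2 in SI
  conA <- con; conA@dA0 <- bilayerAreaDifference(g, D0 * 1e6) - dev0 * 1e12
  conB <- con; conB@dA0 <- bilayerAreaDifference(g2, D0 * 1e6) - dev0 * 1e12
  expect_equal(areaDifferenceEnergy(m2, kad, D0, conB),
               areaDifferenceEnergy(m, kad, D0, conA) / 2, tolerance = 1e-6)
})

test_that("total energy sums its components and every term is rigid-motion invariant", {
  m <- jitteredIcosphere(140, 2L, 0.03, seed = 2L)
  g <- edgeGeometry(m)
  sp <- calibrateSpectrin(4e-6, l0 = g@lengths * 0.98)
  mod <- energyModel()
  con <- selfConstraints(m, dA0Percent = 0.12, C0Percent = 0.45)
  eb <- totalEnergy(m, sp, mod, con)
  comps <- energyComponents(eb)
  expect_equal(unname(comps[["total"]]), sum(comps[1:6]), tolerance = 1e-15)
  expect_true(all(comps >= 0))

  rot <- randomRotation(11L)
  mr <- buildMembrane(m@vertices %*% rot + 7, m@triangles)
  ebr <- totalEnergy(mr, sp, mod, con)
  expect_equal(energyComponents(ebr), comps, tolerance = 1e-9)
})

test_that("the C++ kernel and the vectorised R energies agree to machine precision", {
  for (seed in 1:3) {
    m <- jitteredIcosphere(140, 2L, 0.03, seed = seed)
    g <- edgeGeometry(m)
    sp <- calibrateSpectrin(4e-6, l0 = g@lengths * 0.99)
    mod <- energyModel()
    con <- selfConstraints(m, dA0Percent = 0.10, C0Percent = 0.50)
    eR <- energyComponents(totalEnergy(m, sp, mod, con))
    f <- computeForces(m, sp, mod, con)
    eC <- energyComponents(attr(f, "energy"))
    expect_equal(eC, eR, tolerance = 1e-12)
  }
})

test_that("the energy model constructor enforces the bilayer-coupling regime", {
  mod <- energyModel()
  expect_equal(mod@kad / mod@kappa, 300, tolerance = 1e-12)
  expect_warning(energyModel(kad = 1e-19), "regime")
  expect_silent(energyModel(kad = 0))  # reference-state generation mode
  expect_error(energyModel(kappa = -1), "non-negative")
})
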