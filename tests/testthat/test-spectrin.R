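# Spectrin link calibration and in-plane energetics.

test_that("calibration reproduces the target shear modulus across the sweep range", {
  for (mu0 in c(0.8e-6, 2e-6, 4e-6, 8e-6, 20e-6)) {
    sp <- calibrateSpectrin(mu0, l0 = 0.5)
    expect_lt(abs(shearModulus(sp) - mu0) / mu0, 1e-10)
    expect_equal(sp@lmax, sp@l0 / 0.45, tolerance = 1e-14)
  }
  # doubling mu0 at fixed x0, m, T halves the persistence length
  p1 <- calibrateSpectrin(4e-6, l0 = 0.5)@p
  p2 <- calibrateSpectrin(8e-6, l0 = 0.5)@p
  expect_equal(p1 / p2, 2, tolerance = 1e-12)
  expect_error(calibrateSpectrin(-1e-6, l0 = 0.5), "positive")
  expect_error(calibrateSpectrin(4e-6, l0 = 0.5, x0 = 1.2), "x0")
})

test_that("calibrated parameters agree with an independent dense grid search", {
  # oracle: kp from a numeric force balance (finite differences of the raw
  # energy expressions), mu from the shear relation, best p over a dense grid
  mu0 <- 4e-6; x0 <- 0.45; m <- 2; kBT <- 1.380649e-23 * 296.15
  l0 <- 0.5e-6; lmax <- l0 / x0
  ewlc <- function(l, p) kBT * lmax / (4 * p) *
    (3 * (l / lmax)^2 - 2 * (l / lmax)^3) / (1 - l / lmax)
  epow <- function(l, kp) kp / ((m - 1) * l^(m - 1))
  h <- 1e-13
  kpOf <- function(p) {
    dwlc <- (ewlc(l0 + h, p) - ewlc(l0 - h, p)) / (2 * h)
    # kp / l0^m must equal the WLC pull: d/dl epow = -kp l^-m
    dwlc * l0^m
  }
  muOf <- function(p) {
    kp <- kpOf(p)
    sqrt(3) * kBT / (4 * p * lmax * x0) *
      (x0 / (2 * (1 - x0)^3) - 1 / (4 * (1 - x0)^2) + 1 / 4) +
      sqrt(3) * kp * (m + 1) / (4 * l0^(m + 1))
  }
  grid <- 10^seq(-10, -7, length.out = 20000)
  best <- grid[which.min(abs(vapply(grid, muOf, 0) - mu0))]
  sp <- calibrateSpectrin(mu0, l0 = l0 * 1e6)
  expect_equal(sp@p, best, tolerance = 1e-3)
  expect_equal(sp@kp[1], kpOf(sp@p), tolerance = 1e-4)
})

test_that("each link's energy has its unique minimum at the rest length", {
  sp <- calibrateSpectrin(4e-6, l0 = 0.5)
  l <- seq(0.05, 0.99, by = 0.001) * sp@lmax * 1e6
  e <- vapply(l, function(x) as.numeric(stretchingEnergy(x, sp)), 0)
  i0 <- which.min(e)
  expect_equal(l[i0], sp@l0 * 1e6, tolerance = 2e-3)
  expect_equal(sum(diff(e) < 0 & diff(l) > 0), i0 - 1L)  # monotone down then up
  # positive curvature at the minimum
  expect_gt(e[i0 + 1] + e[i0 - 1] - 2 * e[i0], 0)
})

test_that("stretching energy follows the WLC + power-law limits", {
  sp <- calibrateSpectrin(4e-6, l0 = 0.5)
  # repulsive core: energy diverges as l -> 0
  expect_gt(as.numeric(stretchingEnergy(1e-4, sp)),
            1e3 * as.numeric(stretchingEnergy(0.5, sp)))
  # WLC divergence guard at lmax
  expect_error(stretchingEnergy(sp@lmax * 1.001e6, sp), "maximum length|lmax")
  # m = 1 logarithmic branch evaluates
  sp1 <- calibrateSpectrin(4e-6, l0 = 0.5, m = 1)
  expect_true(is.finite(as.numeric(stretchingEnergy(0.5, sp1))))
})

test_that("stretching forces are equal-opposite, zero at rest, and match quadrature", {
  mesh <- buildIcosphere(140, 2L)
  g <- edgeGeometry(mesh)
  sp <- calibrateSpectrin(4e-6, l0 = g@lengths)
  # at the rest state every link force vanishes identically
  f0 <- stretchingForces(mesh, sp)
  expect_lt(max(abs(f0)), 1e-18)
  # Newton's third law on a deformed state
  mj <- jitteredIcosphere(140, 2L, 0.03, seed = 4L)
  f <- stretchingForces(mj, sp)
  expect_lt(max(abs(colSums(f))), 1e-12 * max(abs(f)))
  # finite differences of the energy reproduce the forces
  h <- 1e-6
  for (idx in list(c(5L, 1L), c(40L, 3L))) {
    vp <- mj@vertices; vp[idx[1], idx[2]] <- vp[idx[1], idx[2]] + h
    vm <- mj@vertices; vm[idx[1], idx[2]] <- vm[idx[1], idx[2]] - h
    up <- buildMembrane(vp, mj@triangles); dn <- buildMembrane(vm, mj@triangles)
    fd <- -(as.numeric(stretchingEnergy(up, sp)) -
            as.numeric(stretchingEnergy(dn, sp))) / (2 * h * 1e-6)
    expect_equal(f[idx[1], idx[2]], fd, tolerance = 1e-6)
  }
  # perturbing one link to 1.05 l0: energy increase equals the integral of
  # the link force over the extension
  spU <- calibrateSpectrin(4e-6, l0 = 0.5)
  l0 <- 0.5e-6
  dE <- as.numeric(stretchingEnergy(0.5 * 1.05, spU)) -
        as.numeric(stretchingEnergy(0.5, spU))
  quad <- stats::integrate(function(l) rbcshape:::.stretchForceScalar(l, spU),
                           l0, 1.05 * l0, rel.tol = 1e-10)$value
  expect_equal(dE, quad, tolerance = 1e-7)
  # uniform compression: every link pushes its endpoints apart (repulsion)
  shrunk <- buildMembrane(mesh@vertices * 0.9, mesh@triangles)
  fs <- stretchingForces(shrunk, sp)
  outward <- rowSums(fs * shrunk@vertices)
  expect_true(all(outward > 0))
})

test_that("calibration report serialises the round-trip residual", {
  sp <- calibrateSpectrin(4e-6, l0 = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  calibrationReport(sp, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_lt(rep$relative_residual, 1e-10)
  expect_equal(rep$mu0_target_N_per_m, 4e-6)
})
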