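# Discrete geometry: edge curvature, areas, volume, vertex curvature,
# extents, assembled metrics and shape comparison.

test_that("edge areas partition the surface exactly and sphere limits hold", {
  R <- sqrt(140 / (4 * pi))
  m <- buildIcosphere(140, 3L)
  g <- edgeGeometry(m)
  expect_equal(sum(g@edgeArea), sum(g@triangleAreas), tolerance = 1e-14)
  expect_equal(sum(g@edgeArea), surfaceArea(m), tolerance = 1e-14)
  # integrated mean curvature of a sphere: sum M_j ~ 4 pi R, all convex
  expect_true(all(g@dihedrals > 0))
  expect_equal(sum(g@edgeCurvature), 4 * pi * R, tolerance = 0.01)
  # the partition identity survives arbitrary jitter
  mj <- jitteredIcosphere(140, 2L, amplitude = 0.05)
  gj <- edgeGeometry(mj)
  expect_equal(sum(gj@edgeArea), surfaceArea(mj), tolerance = 1e-14)
})

test_that("coplanar triangle pairs carry zero dihedral and zero edge curvature", {
  # midpoint subdivision without projection leaves each original face flat:
  # the three interior edges of every face are coplanar pairs
  ico <- buildIcosahedron(1)
  flat <- subdivideMesh(ico, 1L, radius = NA)
  g <- edgeGeometry(flat)
  interior <- abs(g@dihedrals) < 1e-9
  expect_equal(sum(interior), 60L)  # 3 interior edges per original face
  expect_equal(max(abs(g@edgeCurvature[interior])), 0, tolerance = 1e-12)
})

test_that("dihedral sign convention: convex-outward positive, dented region negative", {
  convex <- buildIcosahedron(1)
  expect_true(all(edgeGeometry(convex)@dihedrals > 0))
  dent <- dentedOctahedron()
  g <- edgeGeometry(dent)
  apex <- 6L  # the pulled-in vertex
  atApex <- dent@edges[, 1] == apex | dent@edges[, 2] == apex
  expect_true(all(g@dihedrals[atApex] < 0))
  expect_true(all(g@dihedrals[!atApex] > 0))
  expect_true(all(abs(g@dihedrals) <= pi))
})

test_that("surface area and volume match closed forms; volume is translation invariant", {
  R <- sqrt(140 / (4 * pi))
  m <- buildIcosphere(140, 3L)
  expect_equal(surfaceArea(m), 140, tolerance = 0.01)
  expect_equal(enclosedVolume(m), 4 / 3 * pi * R^3, tolerance = 0.01)
  shifted <- buildMembrane(sweep(m@vertices, 2, c(5, -3, 11), `+`), m@triangles)
  expect_equal(enclosedVolume(shifted), enclosedVolume(m), tolerance = 1e-12)
  e <- buildEllipsoid(c(2, 1, 1), 3L)
  expect_equal(enclosedVolume(e), 8 * pi / 3, tolerance = 0.01)
})

test_that("leaflet area difference and total curvature obey their sphere and ordering laws", {
  R <- sqrt(140 / (4 * pi))
  D0 <- 0.002
  m <- buildIcosphere(140, 3L)
  g <- edgeGeometry(m)
  expect_equal(bilayerAreaDifference(g, D0), 8 * pi * R * D0, tolerance = 0.01)
  # single-signed sphere: C = |dA| to machine precision
  expect_equal(totalMembraneCurvature(g, D0), abs(bilayerAreaDifference(g, D0)),
               tolerance = 1e-14)
  # orientation flip changes the sign of dA
  flipped <- buildMembrane(m@vertices, m@triangles[, c(1, 3, 2)],
                           orientation = "keep")
  gf <- edgeGeometry(flipped)
  expect_equal(bilayerAreaDifference(gf, D0), -bilayerAreaDifference(g, D0),
               tolerance = 1e-10)
  # mixed-sign fixture: C strictly exceeds |dA|
  dimp <- dimpledSphere()
  gd <- edgeGeometry(dimp)
  expect_true(any(gd@dihedrals < 0))
  expect_gt(totalMembraneCurvature(gd, D0),
            abs(bilayerAreaDifference(gd, D0)) * 1.01)
  # C >= |dA| on arbitrary meshes (triangle inequality)
  for (seed in 1:3) {
    gj <- edgeGeometry(jitteredIcosphere(140, 2L, 0.05, seed))
    expect_gte(totalMembraneCurvature(gj, D0), abs(bilayerAreaDifference(gj, D0)))
  }
})

test_that("vertex curvature approximates the mean curvature of a sphere", {
  R <- sqrt(140 / (4 * pi))
  m <- buildIcosphere(140, 4L)
  cv <- vertexCurvature(m)
  expect_equal(median(cv), 1 / R, tolerance = 0.02)
  # valence-6 vertices are accurate to a few percent; the 12 pentagon seed
  # vertices carry a larger (documented) discretisation offset
  val <- tabulate(c(m@edges), nbins = nVertices(m))
  expect_lt(max(abs(cv[val == 6L] - 1 / R)) * R, 0.05)
  expect_lt(max(abs(cv - 1 / R)) * R, 0.20)
  # dented fixture: negative curvature at the pulled-in apex, positive elsewhere
  dent <- dentedOctahedron()
  cvd <- vertexCurvature(dent)
  expect_lt(cvd[6L], 0)
  expect_gt(max(cvd[1:5]), 0)
  # near-flat region: poles of a strongly flattened ellipsoid
  flat <- buildEllipsoid(c(5, 5, 0.8), 3L)
  cvf <- vertexCurvature(flat)
  pole <- which.max(flat@vertices[, 3])
  expect_lt(abs(cvf[pole]), 0.2 / sqrt(surfaceArea(flat) / (4 * pi)))
})

test_that("literal (non-normalised) vertex curvature variant scales with valence", {
  m <- buildIcosphere(140, 2L)
  cvN <- vertexCurvature(m, normalized = TRUE)
  cvL <- vertexCurvature(m, normalized = FALSE)
  val <- tabulate(c(m@edges), nbins = nVertices(m))
  # literal sum is ~valence times larger and carries different units
  expect_equal(median(cvL / cvN), 6, tolerance = 0.1)
  expect_gt(cor(cvL, val), 0.5)
})

test_that("principal extents recover sphere and ellipsoid dimensions and are rigid-motion invariant", {
  R <- sqrt(140 / (4 * pi))
  m <- buildIcosphere(140, 3L)
  H <- principalExtents(m)
  expect_equal(H, rep(2 * R, 3), tolerance = 0.01)
  e <- buildEllipsoid(c(3, 2, 1), 3L)
  expect_equal(principalExtents(e), c(2, 4, 6), tolerance = 0.02)
  rot <- randomRotation()
  er <- buildMembrane(e@vertices %*% rot + 3, e@triangles)
  expect_equal(principalExtents(er), principalExtents(e), tolerance = 1e-9)
})

test_that("shape metrics assemble consistently and are rigid-motion invariant", {
  m <- jitteredIcosphere(140, 2L, 0.03)
  sm <- shapeMetrics(m)
  expect_equal(sm@area, surfaceArea(m), tolerance = 1e-12)
  expect_equal(sm@volume, enclosedVolume(m), tolerance = 1e-12)
  expect_equal(sm@Rstar, sqrt(sm@area / (4 * pi)), tolerance = 1e-12)
  expect_equal(sm@reducedVolume, sm@volume / (4 / 3 * pi * sm@Rstar^3),
               tolerance = 1e-12)
  expect_equal(sm@Hx, sm@extents[3] / sm@Rstar, tolerance = 1e-12)
  expect_equal(sm@Hz, sm@extents[1] / sm@Rstar, tolerance = 1e-12)
  expect_equal(sm@SF, sm@extents[1] / sqrt(sm@extents[2] * sm@extents[3]),
               tolerance = 1e-12)
  expect_lte(sm@reducedVolume, 1 + 1e-6)
  expect_gte(sm@totalCurvature, abs(sm@areaDifference))

  rot <- randomRotation(7L)
  mr <- buildMembrane(m@vertices %*% rot - 2, m@triangles)
  smr <- shapeMetrics(mr)
  for (slot in c("area", "volume", "reducedVolume", "areaDifference",
                 "totalCurvature", "Hx", "Hz", "SF"))
    expect_equal(methods::slot(smr, slot), methods::slot(sm, slot),
                 tolerance = 1e-9)

  sph <- shapeMetrics(buildIcosphere(140, 3L))
  expect_equal(sph@reducedVolume, 1, tolerance = 0.01)
  expect_equal(sph@SF, 1, tolerance = 0.01)
})

test_that("reduced volume strictly decreases along a fixed-area flattening family", {
  nus <- vapply(c(1, 0.85, 0.7, 0.55, 0.4), function(tau) {
    e <- buildEllipsoid(c(1, 1, tau), 2L)
    scale <- sqrt(140 / surfaceArea(e))
    shapeMetrics(buildMembrane(e@vertices * scale, e@triangles))@reducedVolume
  }, 0)
  expect_true(all(diff(nus) < 0))
})

test_that("shape comparison returns percentage errors with the right algebra", {
  m <- buildIcosphere(140, 2L)
  sm <- shapeMetrics(m)
  expect_equal(unname(compareShapes(sm, sm)), c(0, 0, 0))
  stretched <- sm
  stretched@Hz <- 1.2 * sm@Hz
  expect_equal(compareShapes(sm, stretched)[["Hz"]], 20, tolerance = 1e-9)
  # anisotropic scale (1.1, 1, 1): errors follow the hand-computed extents
  ms <- buildMembrane(sweep(m@vertices, 2, c(1.1, 1, 1), `*`), m@triangles)
  sms <- shapeMetrics(ms)
  eps <- compareShapes(sm, sms)
  RsRatio <- sms@Rstar / sm@Rstar
  expect_equal(eps[["Hx"]], 100 * abs(1.1 / RsRatio - 1), tolerance = 0.2)
  expect_equal(eps[["Hz"]], 100 * abs(1 / RsRatio - 1), tolerance = 0.2)
  ext <- compareShapes(sm, sms, extended = TRUE)
  expect_true(all(c("nu", "dA_over_A", "C_over_A") %in% names(ext)))
})

test_that("metrics export as a flat unit-annotated table", {
  df <- metricsTable(shapeMetrics(buildIcosphere(140, 1L)))
  expect_true(all(c("quantity", "value", "unit") %in% names(df)))
  expect_true("SF" %in% df$quantity)
  path <- withr::local_tempfile(fileext = ".csv")
  metricsTable(shapeMetrics(buildIcosphere(140, 1L)), path)
  expect_true(file.exists(path))
})
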