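# Experiment drivers: elastic length scale, sweep plumbing, external
# measurement, protrusion counting.

test_that("elastic length scale reproduces the printed values and sqrt scaling", {
  expect_equal(round(elasticLengthScale(2.5e-19, 4.0e-6), 2), 0.25)
  expect_equal(round(elasticLengthScale(2.5e-19, 0.2 * 4.0e-6), 2), 0.56)
  expect_equal(elasticLengthScale(4 * 2.5e-19, 4.0e-6),
               2 * elasticLengthScale(2.5e-19, 4.0e-6), tolerance = 1e-12)
  # the mu0 multipliers of the length-scale study
  expect_equal(round(elasticLengthScale(2.5e-19, 4.0e-6 * c(5, 2, 1, 0.5, 0.2)), 2),
               c(0.11, 0.18, 0.25, 0.35, 0.56))
  expect_error(elasticLengthScale(-1, 1), "positive")
})

test_that("the default transect spans the sweep ranges", {
  tr <- sdeTransect(9)
  expect_equal(nrow(tr), 9L)
  expect_equal(range(tr$dA0Percent), c(0.05, 0.30))
  expect_equal(range(tr$C0Percent), c(0.30, 0.90))
  expect_true(all(tr$C0Percent >= tr$dA0Percent))
  expect_true(all(tr$nu == 0.6))
})

test_that("protrusion counting finds seeded spikes and nothing on a sphere", {
  m <- buildIcosphere(140, 3L)
  expect_identical(countProtrusions(m), 0L)
  # push four well-separated vertices outward: four distinct spicules
  v <- m@vertices
  seeds <- c(1L, 2L, 3L, 4L)  # icosahedron seed vertices are far apart
  v[seeds, ] <- v[seeds, ] * 1.25
  spiky <- buildMembrane(v, m@triangles)
  expect_identical(countProtrusions(spiky), 4L)
  # the same features are invaginations after mirroring inward
  v2 <- m@vertices
  v2[seeds, ] <- v2[seeds, ] * 0.75
  dented <- buildMembrane(v2, m@triangles)
  expect_gte(countProtrusions(dented, sign = "negative", threshold = 1), 4L)
})

test_that("external measurement matches sphere closed forms and is format independent", {
  m <- buildIcosphere(140, 3L)
  R <- sqrt(140 / (4 * pi))
  off <- withr::local_tempfile(fileext = ".off")
  ply <- withr::local_tempfile(fileext = ".ply")
  writeMesh(m, off); writeMesh(m, ply)
  sm <- measureExternal(off)
  expect_equal(sm@reducedVolume, 1, tolerance = 0.01)
  expect_equal(sm@areaDifference / sm@area, 2 * 0.002 / R, tolerance = 0.01)
  smPly <- measureExternal(ply)
  for (slot in c("area", "volume", "reducedVolume", "areaDifference", "SF"))
    expect_equal(methods::slot(smPly, slot), methods::slot(sm, slot),
                 tolerance = 1e-9)
  # uniform scaling: nu and SF invariant, dA/A scales as 1/s (checked on
  # an ellipsoid - a sphere's principal frame is eigen-degenerate, so its
  # extents are not stable under reordering)
  e <- buildEllipsoid(c(3, 2, 1), 2L)
  offE <- withr::local_tempfile(fileext = ".off")
  offE2 <- withr::local_tempfile(fileext = ".off")
  writeMesh(e, offE)
  writeMesh(buildMembrane(e@vertices * 2, e@triangles), offE2)
  smE <- measureExternal(offE)
  smE2 <- measureExternal(offE2)
  expect_equal(smE2@reducedVolume, smE@reducedVolume, tolerance = 1e-6)
  expect_equal(smE2@SF, smE@SF, tolerance = 1e-6)
  expect_equal(smE2@areaDifference / smE2@area,
               (smE@areaDifference / smE@area) / 2, tolerance = 1e-6)
})

test_that("runPoint resolves the experiment spec and persists a manifest", {
  ref <- cached("refL2", generateReference(0.94, 140, 2L))
  cfg <- dynamicsConfig(maxIterations = 4000L)
  pt <- runPoint(ref, nu = 0.9, dA0Percent = 0.12, C0Percent = 0.35,
                 config = cfg)
  expect_equal(pt$spec$lambdaEl, 0.25, tolerance = 1e-9)
  expect_equal(pt$spec$mu0, 4e-6)
  expect_s4_class(pt$metrics, "ShapeMetrics")
  expect_s4_class(pt$energy, "EnergyBreakdown")
  path <- withr::local_tempfile(fileext = ".json")
  runManifest(pt, path)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(man$spec$nu, 0.9)
  expect_false(is.null(man$metrics$SF))
  expect_warning(runPoint(ref, 0.9, dA0Percent = 0.5, C0Percent = 0.4,
                          config = dynamicsConfig(maxIterations = 10L)),
                 "total curvature")
})

test_that("runSweep returns one flagged row per grid point and tolerates failures", {
  ref <- cached("refL2", generateReference(0.94, 140, 2L))
  grid <- data.frame(nu = c(0.9, 0.95), dA0Percent = c(0.12, 0.12),
                     C0Percent = c(0.35, 0.35))
  sw <- runSweep(ref, grid, config = dynamicsConfig(maxIterations = 2000L))
  expect_equal(nrow(sw), 2L)
  expect_true(all(!sw$failed))
  expect_true(all(is.finite(sw$SF)))
  expect_equal(length(attr(sw, "points")), 2L)
})

test_that("the shape classifier ranks canonical fixtures sensibly", {
  sphere <- buildIcosphere(140, 2L)
  expect_identical(classifyShape(sphere), "sphere-like")
  v <- buildIcosphere(140, 3L)@vertices
  v[c(1L, 2L, 3L, 4L, 5L, 6L), ] <- v[c(1L, 2L, 3L, 4L, 5L, 6L), ] * 1.3
  spiky <- buildMembrane(v, buildIcosphere(140, 3L)@triangles)
  expect_identical(classifyShape(spiky), "echinocyte")
  expect_identical(classifyShape(dimpledSphere(depth = 0.6)), "stomatocyte")
})

test_that("the command-line driver builds and measures meshes", {
  cli <- system.file("cli", "rbcshape.R", package = "rbcshape")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  dir <- withr::local_tempdir()
  mesh <- file.path(dir, "cell.off")
  out <- system2(rscript, c(cli, "build-mesh", "--area", "140",
                            "--levels", "2", "--out", mesh),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(mesh))
  expect_true(any(grepl("162 vertices", out)))
  json <- file.path(dir, "metrics.json")
  out2 <- system2(rscript, c(cli, "measure", "--mesh", mesh, "--json", json),
                  stdout = TRUE, stderr = TRUE)
  expect_true(any(grepl("ShapeMetrics", out2)))
  tab <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_true("SF" %in% tab$quantity)
})
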