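# Mesh construction, subdivision, quality and validity.

test_that("icosahedron has regular-polyhedron combinatorics and geometry", {
  ico <- buildIcosahedron(3.34)
  expect_equal(nVertices(ico), 12L)
  expect_equal(nTriangles(ico), 20L)
  expect_equal(nEdges(ico), 30L)
  expect_true(all(abs(sqrt(rowSums(ico@vertices^2)) - 3.34) < 1e-12))

  q <- meshQuality(ico)
  expect_equal(q@lengthRatio, 0, tolerance = 1e-12)
  expect_identical(names(q@valenceHistogram), "5")

  # closed-form volume of the regular icosahedron with unit circumradius:
  # edge a = 4 / sqrt(10 + 2 sqrt(5)), V = (5/12)(3 + sqrt(5)) a^3
  a <- 4 / sqrt(10 + 2 * sqrt(5))
  vExpected <- 5 / 12 * (3 + sqrt(5)) * a^3
  expect_equal(enclosedVolume(buildIcosahedron(1)), vExpected, tolerance = 1e-9)

  expect_error(buildIcosahedron(0), "positive")
  expect_error(buildIcosahedron(-2), "positive")
})

test_that("subdivision follows V=10*4^L+2, F=20*4^L, E=30*4^L and keeps the surface closed", {
  ico <- buildIcosahedron(1)
  for (L in 0:3) {
    m <- subdivideMesh(ico, L)
    expect_equal(nVertices(m), 10L * 4L^L + 2L)
    expect_equal(nTriangles(m), 20L * 4L^L)
    expect_equal(nEdges(m), 30L * 4L^L)
    # genus 0, outward orientation at every level
    expect_equal(nVertices(m) - nEdges(m) + nTriangles(m), 2L)
    expect_gt(enclosedVolume(m), 0)
  }
  expect_identical(subdivideMesh(ico, 0L), ico)
  m1 <- subdivideMesh(ico, 1L)
  expect_equal(c(nVertices(m1), nTriangles(m1), nEdges(m1)), c(42L, 80L, 120L))
  expect_error(subdivideMesh(ico, -1), "non-negative")
})

test_that("icosphere radius comes from the target area and converges to the sphere", {
  m0 <- buildIcosphere(140, 0L)
  expect_equal(round(m0@metadata$radius, 2), 3.34)
  expect_equal(buildIcosphere(4 * pi, 0L)@metadata$radius, 1)
  expect_error(buildIcosphere(-1), "positive")

  R <- sqrt(140 / (4 * pi))
  errA <- errV <- numeric(4)
  for (L in 1:4) {
    m <- buildIcosphere(140, L)
    errA[L] <- abs(surfaceArea(m) - 140) / 140
    errV[L] <- abs(enclosedVolume(m) - 4 / 3 * pi * R^3) / (4 / 3 * pi * R^3)
  }
  expect_true(all(diff(errA) < 0))
  expect_true(all(diff(errV) < 0))
  expect_lt(errA[4], 0.01)
  expect_lt(errV[4], 0.01)
})

test_that("mesh quality of an icosphere keeps exactly 12 valence-5 seed vertices", {
  m <- buildIcosphere(140, 2L)
  q <- meshQuality(m)
  expect_identical(q@valenceHistogram[["5"]], 12L)
  expect_identical(q@valenceHistogram[["6"]], nVertices(m) - 12L)
  expect_equal(sum(q@valenceFractions), 1)
  expect_gt(q@lengthRatio, 0)
  # population (not sample) standard deviation
  d <- m@vertices[m@edges[, 1], ] - m@vertices[m@edges[, 2], ]
  len <- sqrt(rowSums(d^2))
  expect_equal(q@edgeLengthSD, sqrt(mean((len - mean(len))^2)), tolerance = 1e-12)
})

test_that("ellipsoid meshes scale an icosphere and keep its topology", {
  s <- buildIcosphere(4 * pi, 2L)
  e1 <- buildEllipsoid(c(1, 1, 1), 2L)
  expect_equal(e1@vertices, s@vertices, tolerance = 1e-12)
  expect_identical(e1@triangles, s@triangles)

  e <- buildEllipsoid(c(2, 1, 1), 3L)
  expect_equal(nVertices(e) - nEdges(e) + nTriangles(e), 2L)
  expect_equal(enclosedVolume(e), 4 / 3 * pi * 2, tolerance = 0.01)
  expect_error(buildEllipsoid(c(1, 0, 1), 2L), "positive")
})

test_that("buildMembrane validates closedness, manifoldness and orientation", {
  ico <- buildIcosahedron(1)
  # open surface: drop one triangle
  expect_error(buildMembrane(ico@vertices, ico@triangles[-1, ]),
               "not a closed manifold|not closed")
  # inconsistent winding: flip one triangle
  bad <- ico@triangles
  bad[1, ] <- bad[1, c(1, 3, 2)]
  expect_error(buildMembrane(ico@vertices, bad), "oriented")
  # globally inward winding is flipped back (silently with "fix")
  flipped <- ico@triangles[, c(1, 3, 2)]
  m <- buildMembrane(ico@vertices, flipped)
  expect_gt(enclosedVolume(m), 0)
  expect_warning(buildMembrane(ico@vertices, flipped, orientation = "warn"),
                 "inward")
  expect_error(buildMembrane(ico@vertices, flipped, orientation = "error"),
               "inward")
  # out-of-range index
  oor <- ico@triangles; oor[1, 1] <- 99L
  expect_error(buildMembrane(ico@vertices, oor), "out of range")
})
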