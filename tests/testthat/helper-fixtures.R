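# Shared fixtures and a lazy cache for expensive objects (the cytoskeletal
# reference state and relaxation runs are reused across test files).

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# icosphere with seeded random vertex jitter (keeps closedness, breaks
# all symmetry) - the workhorse fixture for oracle and invariance tests
jitteredIcosphere <- function(area = 140, levels = 2L, amplitude = 0.02,
                              seed = 1L) {
  m <- buildIcosphere(area, levels)
  set.seed(seed)
  v <- m@vertices * (1 + amplitude * matrix(stats::rnorm(3 * nVertices(m)),
                                            ncol = 3L))
  buildMembrane(v, m@triangles, metadata = m@metadata)
}

# octahedron with its lower apex pushed inside (past the equatorial plane):
# the four edges at that vertex form a concave (negative-dihedral)
# neighbourhood on an otherwise convex body
dentedOctahedron <- function(apexZ = 0.3) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, apexZ))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  buildMembrane(v, f)
}

# sphere with both polar caps pushed inward: mixed-sign edge curvature
dimpledSphere <- function(area = 140, levels = 3L, depth = 0.35) {
  m <- buildIcosphere(area, levels)
  v <- m@vertices
  r <- sqrt(area / (4 * pi))
  cap <- abs(v[, 3]) > 0.8 * r
  scale <- 1 - depth * pmax(0, (abs(v[cap, 3]) / r - 0.8) / 0.2)
  v[cap, ] <- v[cap, ] * scale
  buildMembrane(v, m@triangles)
}

# small spectrin/model/constraint bundle for a mesh at its own reference
selfConstraints <- function(mesh, D0 = 0.002, dA0Percent = NULL,
                            C0Percent = NULL) {
  g <- edgeGeometry(mesh)
  dA <- bilayerAreaDifference(g, D0)
  C <- totalMembraneCurvature(g, D0)
  referenceConstraints(
    A0 = sum(g@triangleAreas), V0 = enclosedVolume(mesh),
    Ak0 = g@triangleAreas,
    dA0 = if (is.null(dA0Percent)) dA else dA0Percent / 100 * sum(g@triangleAreas),
    C0 = if (is.null(C0Percent)) C else C0Percent / 100 * sum(g@triangleAreas))
}

# the level-3 nuCyto = 0.94 reference used by relaxation and sweep tests
referenceL3 <- function() {
  cached("referenceL3", generateReference(0.94, 140, 3L))
}

randomRotation <- function(seed = 42L) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(9), 3L)))
}
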