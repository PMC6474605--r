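# Independent naive re-implementation of the six energy components: plain
# R loops over triangles and edges, sharing no code with the package
# internals. Used as the oracle for total-energy equivalence.

oracleCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# all inputs in SI; mesh vertices in micrometres as stored
oracleEnergy <- function(mesh, spectrin, model, constraints) {
  v <- mesh@vertices * 1e-6
  tri <- mesh@triangles
  ed <- mesh@edges
  et <- mesh@edgeTriangles
  nT <- nrow(tri); nE <- nrow(ed)

  areas <- numeric(nT); normals <- matrix(0, nT, 3)
  vol <- 0
  for (t in seq_len(nT)) {
    p1 <- v[tri[t, 1], ]; p2 <- v[tri[t, 2], ]; p3 <- v[tri[t, 3], ]
    n <- oracleCross(p2 - p1, p3 - p1)
    areas[t] <- sqrt(sum(n^2)) / 2
    normals[t, ] <- n / sqrt(sum(n^2))
    vol <- vol + sum(p1 * oracleCross(p2, p3)) / 6
  }
  A <- sum(areas)

  l0 <- rep_len(spectrin@l0, nE)
  lmax <- rep_len(spectrin@lmax, nE)
  kp <- rep_len(spectrin@kp, nE)
  eStretch <- 0; eBend <- 0; sumM <- 0; sumAbsM <- 0
  for (e in seq_len(nE)) {
    pa <- v[ed[e, 1], ]; pb <- v[ed[e, 2], ]
    evec <- pb - pa
    l <- sqrt(sum(evec^2))
    n1 <- normals[et[e, 1], ]; n2 <- normals[et[e, 2], ]
    theta <- atan2(sum(oracleCross(n1, n2) * evec / l), sum(n1 * n2))
    M <- l * theta / 2
    dAe <- (areas[et[e, 1]] + areas[et[e, 2]]) / 3
    x <- l / lmax[e]
    eStretch <- eStretch +
      spectrin@kBT * lmax[e] / (4 * spectrin@p) * (3 * x^2 - 2 * x^3) / (1 - x) +
      (if (spectrin@m == 1) -kp[e] * log(l)
       else kp[e] / ((spectrin@m - 1) * l^(spectrin@m - 1)))
    eBend <- eBend + 2 * model@kappa * M^2 / dAe
    sumM <- sumM + M
    sumAbsM <- sumAbsM + abs(M)
  }
  dA <- 2 * model@D0 * sumM
  C <- 2 * model@D0 * sumAbsM

  A0 <- constraints@A0 * 1e-12
  Ak0 <- constraints@Ak0 * 1e-12
  V0 <- constraints@V0 * 1e-18
  dA0 <- constraints@dA0 * 1e-12
  C0 <- constraints@C0 * 1e-12
  eArea <- 0.5 * model@kA * (A - A0)^2 / A0
  for (t in seq_len(nT))
    eArea <- eArea + 0.5 * model@ka * (areas[t] - Ak0[t])^2 / Ak0[t]
  eVol <- 0.5 * model@kv * (vol - V0)^2 / V0
  eAD <- if (model@kad > 0)
    pi * model@kad / (2 * model@D0^2) * (dA - dA0)^2 / A else 0
  eTC <- if (model@kC > 0)
    pi * model@kC / (2 * model@D0^2) * (C - C0)^2 / A else 0

  c(stretching = eStretch, bending = eBend, surfaceArea = eArea,
    volume = eVol, areaDifference = eAD, totalCurvature = eTC,
    total = eStretch + eBend + eArea + eVol + eAD + eTC)
}
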