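test_that("motif metrics are rigid-invariant and the bands classify", {
  m <- makeMotif(4.0, 60)
  co <- frameCoords(m$trajectory)
  g <- motifGeometry(co, c(1, 4), c(2, 3))
  expect_equal(g$s_s_distance, 4.0, tolerance = 1e-9)
  expect_equal(g$pseudo_torsion, 60, tolerance = 1e-9)
  expect_equal(g$class, "synclinal")
  ## rigid motion and landmark-direction relabelling leave both intact
  rig <- randomRigid(3)
  g2 <- motifGeometry(applyRigidTo(co, rig), c(1, 4), c(2, 3))
  expect_equal(g2$s_s_distance, g$s_s_distance, tolerance = 1e-9)
  expect_equal(g2$pseudo_torsion, g$pseudo_torsion, tolerance = 1e-9)
  g3 <- motifGeometry(co, c(4, 1), c(3, 2))
  expect_equal(g3$pseudo_torsion, g$pseudo_torsion, tolerance = 1e-9)
  ## band boundaries
  expect_equal(motifGeometry(frameCoords(makeMotif(4, 29.9)$trajectory),
                             c(1, 4), c(2, 3))$class, "syn-periplanar")
  expect_equal(motifGeometry(frameCoords(makeMotif(4, 95)$trajectory),
                             c(1, 4), c(2, 3))$class, "anticlinal")
  expect_equal(motifGeometry(frameCoords(makeMotif(4, 175)$trajectory),
                             c(1, 4), c(2, 3))$class, "antiperiplanar")
  expect_error(motifGeometry(co, c(1, 4), c(2, 2)), "distinct")
})

test_that("motif series reproduces per-frame geometry and histograms", {
  a <- frameCoords(makeMotif(4.0, 60)$trajectory)
  b <- frameCoords(makeMotif(4.3, 170)$trajectory)
  arr <- array(NA_real_, c(4, 4, 3))
  arr[1, , ] <- a; arr[2, , ] <- b; arr[3, , ] <- a; arr[4, , ] <- b
  tr <- trajectory(arr, makeMotif(4, 60)$topology)
  ser <- motifSeries(tr, c(1, 4), c(2, 3))
  expect_equal(nrow(ser), 4L)
  expect_equal(as.vector(table(ser$class)),
               c(2L, 2L), ignore_attr = TRUE)
  expect_equal(ser$torsion_deg, c(60, 170, 60, 170), tolerance = 1e-9)
  ## constant trajectory gives a constant table
  cst <- trajectory(array(rep(a, each = 3), c(3, 4, 3)),
                    makeMotif(4, 60)$topology)
  expect_equal(var(motifSeries(cst, c(1, 4), c(2, 3))$d_SS_A), 0)
})

test_that("directional S-H...S fractions count planted geometries", {
  ## topology: S, H on S, S' --- geometry controlled per frame
  topo <- topology(
    atoms = data.frame(name = c("SG", "HG", "SG", "HG"),
                       element = c("S", "H", "S", "H"),
                       resindex = c(1L, 1L, 2L, 2L)),
    residues = data.frame(resname = "CYS", resno = c(37L, 40L),
                          chain = "A"))
  ## thiol 1 points at S', thiol 2 points away: only direction 1 bonds
  inGeom <- rbind(c(0, 0, 0), c(1.34, 0, 0),
                  c(3.3, 0, 0), c(3.3, 1.34, 0))
  outGeom <- inGeom
  outGeom[3, 1] <- 5                     # S...S beyond the cut-off
  outGeom[4, 1] <- 5
  F <- 100
  nIn <- 72
  arr <- array(NA_real_, c(F, 4, 3))
  for (f in seq_len(F)) arr[f, , ] <- if (f <= nIn) inGeom else outGeom
  tr <- trajectory(arr, topo)
  expect_equal(shsHbondFraction(tr, 1, 2, 3), 0.72, tolerance = 1e-12)
  ## swapped donor/acceptor on this asymmetric geometry differs
  expect_equal(shsHbondFraction(tr, 3, 4, 1), 0)
  expect_error(shsHbondFraction(tr, 1, NA, 3), "explicit thiol hydrogen")
})

test_that("tetrahedron edges behave geometrically and flag synchrony", {
  ## unit regular tetrahedron
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    (2 * sqrt(2))
  topo <- syntheticCaTopology(4)
  tr <- trajectory(v, topo)
  e <- tetrahedronEdges(tr, 1:4)
  expect_equal(unlist(e[1, 3:8]), rep(1, 6), ignore_attr = TRUE,
               tolerance = 1e-9)
  ## displacing one vertex changes exactly its three edges
  v2 <- v
  v2[4, ] <- v[4, ] + (v[4, ] - v[1, ])
  arr <- array(NA_real_, c(2, 4, 3))
  arr[1, , ] <- v; arr[2, , ] <- v2
  e2 <- tetrahedronEdges(trajectory(arr, topo), 1:4)
  changed <- abs(unlist(e2[2, 3:8]) - unlist(e2[1, 3:8])) > 1e-9
  expect_equal(sum(changed), 3L)
  expect_true(all(grepl("4", names(changed)[changed])))
  ## synchronous 7 A shift of the three edges at one vertex is localised:
  ## vertex 3 of a large regular tetrahedron moves radially outward
  sep <- v * 12
  sep2 <- sep
  ctr <- colMeans(sep)
  sep2[3, ] <- sep2[3, ] + 7 * (sep[3, ] - ctr) / sqrt(sum((sep[3, ] - ctr)^2))
  arr <- array(NA_real_, c(6, 4, 3))
  for (f in 1:6) arr[f, , ] <- if (f < 4) sep else sep2
  ed <- tetrahedronEdges(trajectory(arr, topo), 1:4)
  sh <- synchronousShift(ed, minDelta = 3)
  expect_equal(sh$frame, 4L)
  expect_equal(sh$vertex, 3L)
  ## triangle inequality on every face, every frame
  dm <- as.matrix(ed[, 3:8])
  for (f in seq_len(nrow(dm))) {
    d <- matrix(0, 4, 4)
    d[lower.tri(d)] <- 0
    pairs <- combn(4, 2)
    for (k in 1:6) {
      d[pairs[1, k], pairs[2, k]] <- dm[f, k]
      d[pairs[2, k], pairs[1, k]] <- dm[f, k]
    }
    for (tri in combn(4, 3, simplify = FALSE))
      expect_lte(d[tri[1], tri[2]],
                 d[tri[1], tri[3]] + d[tri[3], tri[2]] + 1e-12)
  }
})

test_that("helix axes align with construction and transform equivariantly", {
  ## 19 residues: terminal residues sit at the same helical phase, so the
  ## centroid axis is parallel to the true helical axis
  h <- makeIdealHelix(19, "alpha")
  co <- frameCoords(h$trajectory)
  ax <- helixAxis(co, h$topology, 1:19)
  ## check against the least-squares line through all CA atoms
  ca <- co[atomTable(h$topology)$name == "CA", ]
  pc <- prcomp(ca)
  cosang <- abs(sum(ax$direction * pc$rotation[, 1]))
  expect_gt(cosang, cos(2 * pi / 180))
  ## rigid equivariance
  rig <- randomRigid(9)
  ax2 <- helixAxis(applyRigidTo(co, rig), h$topology, 1:19)
  expect_equal(ax2$direction, drop(ax$direction %*% rig$R),
               tolerance = 1e-8)
  ## elongation scales the length symmetrically about the midpoint
  ax15 <- helixAxis(co, h$topology, 1:19, elongation = 1.5)
  expect_equal(ax15$length, 1.5 * ax$length, tolerance = 1e-10)
  expect_equal((ax15$start + ax15$end) / 2, (ax$start + ax$end) / 2,
               tolerance = 1e-10)
  expect_error(helixAxis(co, h$topology, 1:2), "at least 3")
})

test_that("axis drift projects endpoint tracks per plane", {
  h <- makeIdealHelix(8, "alpha")
  co <- frameCoords(h$trajectory)
  arr <- array(rep(co, each = 5), c(5, nrow(co), 3))
  static <- trajectory(arr, h$topology)
  dr <- axisDrift(static, 1:8)
  expect_setequal(unique(dr$plane), c("xz", "yz"))
  for (pl in c("xz", "yz")) for (ep in c("start", "end")) {
    sub <- dr[dr$plane == pl & dr$endpoint == ep, ]
    expect_lt(max(var(sub$u), var(sub$v)), 1e-18)
  }
  ## precessing helix: endpoint track radius matches the cone half-angle
  theta <- 10 * pi / 180
  L <- 20
  nF <- 36
  arr <- array(NA_real_, c(nF, 2, 3))
  for (f in seq_len(nF)) {
    phi <- 2 * pi * (f - 1) / nF
    tip <- L * c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    arr[f, , ] <- rbind(c(0, 0, 0), tip)
  }
  ## analytic check of the construction itself: projected x-radius
  expect_equal(max(arr[, 2, 1]), L * sin(theta), tolerance = 1e-6)
})

test_that("minimal inter-domain S-S distance is found across chains", {
  ## synthetic stand-in for a two-domain redox complex
  topo <- topology(
    atoms = data.frame(name = rep(c("CA", "SG"), 3),
                       element = rep(c("C", "S"), 3),
                       resindex = rep(1:3, each = 2)),
    residues = data.frame(resname = "CYS", resno = c(37L, 43L, 51L),
                          chain = c("A", "B", "B")))
  co <- rbind(c(0, 0, 0), c(2, 0, 0),      # chain A cysteine
              c(2, 16, 0), c(2, 16, 0) + c(0, 0, 2),
              c(30, 30, 0), c(30, 30, 2))
  co[4, ] <- c(2, 16, 0)                   # SG of B/43 at 16 A from A's SG
  d <- minInterDomainSS(co, topo, "chain A", "chain B")
  expect_equal(d, 16, tolerance = 1e-9)
  expect_error(minInterDomainSS(co, topo, "chain A and name CA",
                                "chain B"),
               "no cysteine")
})
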