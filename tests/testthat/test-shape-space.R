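test_that("preshape normalises and is scale/translation invariant", {
  set.seed(51)
  x <- matrix(rnorm(12), 4, 3)
  p <- preshape(x)
  expect_lt(sqrt(sum(colMeans(landmarks(p))^2)), 1e-10)
  expect_equal(sqrt(sum(landmarks(p)^2)), 1, tolerance = 1e-10)
  p2 <- preshape(10 * x + 3)
  expect_equal(landmarks(p), landmarks(p2), tolerance = 1e-10)
  ## shape dimension bookkeeping for k = 4
  expect_equal(3 * nrow(landmarks(p)) - 7, 5)
  expect_error(preshape(matrix(1, 4, 3)), "degenerate")
  expect_error(preshape(matrix(rnorm(6), 2, 3)), "at least 3")
})

test_that("kendall distance is a rigid/scale-invariant metric", {
  set.seed(52)
  x <- matrix(rnorm(15), 5, 3)
  a <- preshape(x)
  expect_equal(kendallDistance(a, a), 0, tolerance = 1e-10)
  rig <- randomRigid(4)
  moved <- preshape(2.7 * applyRigidTo(x, rig))
  expect_lt(kendallDistance(a, moved), 1e-8)
  ## metric axioms on random triples
  set.seed(53)
  shapes <- lapply(1:12, function(i) preshape(matrix(rnorm(15), 5, 3)))
  d <- shapeDistanceMatrix(shapes)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (rep in 1:1000) {
    ijk <- sample(12, 3)
    expect_lte(d[ijk[1], ijk[2]],
               d[ijk[1], ijk[3]] + d[ijk[3], ijk[2]] + 1e-10)
  }
  expect_error(kendallDistance(a, preshape(matrix(rnorm(12), 4, 3))),
               "landmark counts differ")
})

test_that("kendall distance equals the brute-force rotation search", {
  ## equilateral vs collinear: the pole-to-equator distance pi/4
  eq <- landmarks(preshape(equilateralTriangle()))
  col <- landmarks(preshape(collinearTriangle()))
  expect_equal(kendallDistance(preshape(equilateralTriangle()),
                               preshape(collinearTriangle())),
               pi / 4, tolerance = 1e-8)
  expect_equal(bruteForceKendall(eq, col), pi / 4, tolerance = 1e-6)
  set.seed(54)
  for (k in 1:5) {
    A <- landmarks(preshape(matrix(rnorm(12), 4, 3)))
    B <- landmarks(preshape(matrix(rnorm(12), 4, 3)))
    expect_equal(kendallDistance(new("PreShape", landmarks = A),
                                 new("PreShape", landmarks = B)),
                 bruteForceKendall(A, B), tolerance = 1e-6)
  }
})

test_that("mds embeds realizable distances exactly and separates clusters", {
  ## Euclidean-realizable input: near-zero stress, distances recovered
  set.seed(55)
  pts <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(pts))
  e <- mdsEmbed(d, 2, seed = 1)
  expect_lt(e$stress, 1e-6)
  expect_lt(max(abs(as.matrix(dist(e$points)) - d)), 1e-4)
  ## 3-4-5 right triangle embeds exactly in 2-D
  d345 <- matrix(0, 3, 3)
  d345[1, 2] <- d345[2, 1] <- 3
  d345[1, 3] <- d345[3, 1] <- 4
  d345[2, 3] <- d345[3, 2] <- 5
  e3 <- mdsEmbed(d345, 2, seed = 1)
  expect_lt(max(abs(as.matrix(dist(e3$points)) - d345)), 1e-6)
  expect_error(mdsEmbed(matrix(c(0, 1, 2, 0), 2), 2), "symmetric")
  ## two planted shape clusters separate (silhouette > 0.8)
  ctrA <- equilateralTriangle()
  ctrB <- collinearTriangle()
  s <- sampleShapes(list(ctrA, ctrB), noise = 0.02, counts = c(15, 15),
                    seed = 56)
  em <- mdsEmbed(shapeDistanceMatrix(s$shapes), 2, seed = 2)
  dd <- as.matrix(dist(em$points))
  sil <- vapply(seq_len(30), function(i) {
    own <- mean(dd[i, s$labels == s$labels[i]][-1])
    oth <- mean(dd[i, s$labels != s$labels[i]])
    (oth - own) / max(oth, own)
  }, numeric(1))
  expect_gt(mean(sil), 0.8)
  ## stress is non-increasing along the iteration (monitored re-run)
  e2 <- mdsEmbed(shapeDistanceMatrix(s$shapes), 2, seed = 3,
                 maxIter = 1L)
  expect_gte(e2$stress, em$stress - 1e-12)
})

test_that("frechet mean has the flat-limit and midpoint properties", {
  set.seed(57)
  base <- matrix(rnorm(12), 4, 3)
  same <- lapply(1:5, function(i) preshape(base))
  fm <- frechetMean(same)
  ## acos near 1 amplifies round-off to ~1e-8; the shapes are identical
  expect_lt(kendallDistance(fm$mean, preshape(base)), 1e-6)
  ## flat limit: tiny dispersion, compare to the aligned arithmetic mean
  tiny <- lapply(1:20, function(i)
    preshape(base + matrix(rnorm(12, sd = 1e-4), 4, 3)))
  fm2 <- frechetMean(tiny)
  aligned <- lapply(tiny, function(s)
    trajgeom:::procrustesRotate(landmarks(fm2$mean), landmarks(s)))
  euclid <- preshape(Reduce(`+`, aligned) / length(aligned))
  expect_lt(kendallDistance(fm2$mean, euclid), 1e-6)
  ## two shapes: geodesic midpoint
  s1 <- preshape(matrix(rnorm(12), 4, 3))
  s2 <- preshape(matrix(rnorm(12), 4, 3))
  fm3 <- frechetMean(list(s1, s2))
  d1 <- kendallDistance(fm3$mean, s1)
  d2 <- kendallDistance(fm3$mean, s2)
  expect_equal(d1, d2, tolerance = 1e-6)
  expect_equal(d1, kendallDistance(s1, s2) / 2, tolerance = 1e-6)
  ## invariance under relabelling of the set
  fm4 <- frechetMean(list(s2, s1))
  expect_lt(kendallDistance(fm3$mean, fm4$mean), 1e-6)
})

test_that("triangle disk maps shapes between pole and equator", {
  expect_equal(triangleDisk(preshape(equilateralTriangle()))$r, 0,
               tolerance = 1e-8)
  expect_equal(triangleDisk(preshape(collinearTriangle()))$r, 1,
               tolerance = 1e-8)
  ## r equals sin of the colatitude from the spherical construction
  set.seed(58)
  for (k in 1:5) {
    tri <- matrix(rnorm(9), 3, 3)
    rho <- bruteForceKendall(landmarks(preshape(equilateralTriangle())),
                             landmarks(preshape(tri)))
    expect_equal(triangleDisk(preshape(tri))$r, sin(2 * rho),
                 tolerance = 1e-5)
  }
  ## continuous and monotone along the equilateral-to-collinear family
  rs <- vapply(seq(0, 1, length.out = 41), function(t) {
    tri <- rbind(c(0, (1 - t) * sqrt(3) / 2, 0), c(-0.5, 0, 0),
                 c(0.5, 0, 0))
    triangleDisk(preshape(tri))$r
  }, numeric(1))
  expect_true(all(diff(rs) > -1e-9))
  expect_equal(rs[1], 0, tolerance = 1e-9)
  expect_equal(rs[41], 1, tolerance = 1e-9)
  expect_error(triangleDisk(preshape(matrix(rnorm(12), 4, 3))), "k = 3")
})

test_that("shape trajectories keep frame metadata and distinguish torsions", {
  ## rigid-body-only trajectory: all shapes at distance 0 from frame 1
  m <- makeMotif(4, 60)
  co <- frameCoords(m$trajectory)
  arr <- array(NA_real_, c(4, 4, 3))
  for (f in 1:4) arr[f, , ] <- applyRigidTo(co, randomRigid(f))
  tr <- trajectory(arr, m$topology)
  st <- shapeTrajectory(tr, 1:4)
  expect_length(st$shapes, 4L)
  for (s in st$shapes[-1])
    expect_lt(kendallDistance(st$shapes[[1]], s), 1e-8)
  ## metadata column carries the S...S distance
  expect_equal(st$meta$d_landmark_A, rep(4, 4), tolerance = 1e-9)
  ## distinct torsions land on distinct shape points
  tors <- c(20, 60, 100, 140, 170)
  shapes <- lapply(tors, function(t)
    preshape(frameCoords(makeMotif(4, t)$trajectory)))
  d <- shapeDistanceMatrix(shapes)
  expect_gt(min(d[upper.tri(d)]), 1e-3)
})
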