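test_that("reference harvesting meets its separation contract", {
  topo <- syntheticCaTopology(6)
  base <- spreadReference(6)
  cst <- trajectory(array(rep(base, each = 20), c(20, 6, 3)), topo)
  expect_length(harvestReferences(cst, cutoff = 0.5, seed = 1), 1L)
  ms <- twoStateFixture(nframes = 300, seed = 7)
  refs <- harvestReferences(ms$trajectory, cutoff = 2, seed = 5)
  expect_length(refs, 2L)
  ## pairwise reference RMSD exceeds the cut-off
  for (i in seq_along(refs)[-1]) for (j in seq_len(i - 1)) {
    d <- superpose(frameCoords(ms$trajectory, refs[i]),
                   frameCoords(ms$trajectory, refs[j]))$rmsd
    expect_gt(d, 2)
  }
  ## cut-off beyond the trajectory diameter: a single reference
  expect_length(harvestReferences(ms$trajectory, cutoff = 50, seed = 2), 1L)
})

test_that("assignment is the exhaustive nearest-reference map", {
  ms <- twoStateFixture(nframes = 50, seed = 11)
  refs <- c(3L, 17L, 40L)
  cm <- assignClusters(ms$trajectory, refs = refs)
  ## brute-force nearest-reference search with independent RMSD calls
  for (f in seq_len(50)) {
    d <- vapply(refs, function(r)
      bruteForceRmsd(frameCoords(ms$trajectory, f),
                     frameCoords(ms$trajectory, r)), numeric(1))
    expect_equal(clusterAssignment(cm)[f], which.min(d))
  }
  expect_equal(sum(clusterPopulations(cm)), 100, tolerance = 1e-9)
  expect_error(assignClusters(ms$trajectory, refs = integer(0)),
               "no reference")
})

test_that("two-state populations are recovered within sampling error", {
  ms <- twoStateFixture(nframes = 2000, seed = 13)
  cm <- clusterTrajectory(ms$trajectory, cutoff = 2, seed = 13)
  expect_length(referenceFrames(cm), 2L)
  pop <- sort(clusterPopulations(cm), decreasing = TRUE)
  expect_lt(abs(pop[1] - 70), 3)
  expect_lt(abs(pop[2] - 30), 3)
  ## cluster labels agree with the planted states (up to relabelling)
  a <- clusterAssignment(cm)
  agree <- max(mean((a == 1L) == (ms$labels == 1L)),
               mean((a == 1L) == (ms$labels == 2L)))
  expect_gt(agree, 0.99)
})

test_that("cut-off scans cover the default grid and degenerate cases", {
  topo <- syntheticCaTopology(6)
  base <- spreadReference(6)
  one <- trajectory(array(rep(base, each = 30), c(30, 6, 3)) +
                      array(rnorm(30 * 18, sd = 0.05), c(30, 6, 3)), topo)
  sc <- clusterScan(one, seed = 3)
  expect_equal(sc$cutoff_A, seq(1.6, 3.0, by = 0.2))
  expect_equal(nrow(sc), 8L)
  expect_true(all(sc$n_clusters == 1L))
  expect_true(all(sc$dense_population_pct == 100))
  ## three well-separated states at r = 2: always 3 clusters
  ref <- spreadReference(10)
  s2 <- displacedState(ref, 6, seed = 4)
  s3 <- displacedState(ref, 6, seed = 5)
  expect_gt(superpose(s2, s3)$rmsd, 4)
  for (seed in 1:5) {
    ms <- makeMultistateTrajectory(list(ref, s2, s3), 300, seed = seed,
                                   occupancies = c(1, 1, 1) / 3,
                                   jitter = 0.3)
    cm <- clusterTrajectory(ms$trajectory, cutoff = 2, seed = seed)
    expect_length(referenceFrames(cm), 3L)
  }
})

test_that("merged-replica clustering reports source composition", {
  ms <- twoStateFixture(nframes = 200, seed = 17)
  same <- mergeAndCompose(list(ms$trajectory, ms$trajectory), cutoff = 2,
                          seed = 21)
  expect_true(all(abs(same$composition - 50) < 1e-9))
  ## replicas sampling disjoint states give pure-source clusters
  ref <- spreadReference(10)
  s2 <- displacedState(ref, 8)
  r1 <- makeMultistateTrajectory(list(ref), 150, seed = 1, jitter = 0.3)
  r2 <- makeMultistateTrajectory(list(s2), 150, seed = 2, jitter = 0.3)
  mc <- mergeAndCompose(list(r1$trajectory, r2$trajectory), cutoff = 2,
                        seed = 3)
  expect_length(referenceFrames(mc$model), 2L)
  expect_true(all(apply(mc$composition, 1, max) == 100))
  ## overlapping replicas merge into no more clusters than they have apart
  ra <- makeMultistateTrajectory(list(ref, s2), 200, seed = 4,
                                 occupancies = c(0.5, 0.5), jitter = 0.3)
  rb <- makeMultistateTrajectory(list(ref, s2), 200, seed = 5,
                                 occupancies = c(0.5, 0.5), jitter = 0.3)
  ka <- length(harvestReferences(ra$trajectory, cutoff = 2, seed = 6))
  kb <- length(harvestReferences(rb$trajectory, cutoff = 2, seed = 7))
  km <- length(referenceFrames(
    mergeAndCompose(list(ra$trajectory, rb$trajectory), cutoff = 2,
                    seed = 8)$model))
  expect_lte(km, ka + kb)
  expect_error(mergeAndCompose(list(ra$trajectory,
                                    twoStateFixture(10, 1,
                                                    nAtoms = 4)$trajectory),
                               cutoff = 2, seed = 1), "mismatch")
})

test_that("medoid representative equals the all-pairs minimiser", {
  ms <- twoStateFixture(nframes = 60, seed = 19)
  cm <- clusterTrajectory(ms$trajectory, cutoff = 2, seed = 19)
  for (cl in seq_along(referenceFrames(cm))) {
    members <- which(clusterAssignment(cm) == cl)
    meanD <- vapply(members, function(i) {
      mean(vapply(members, function(j)
        bruteForceRmsd(frameCoords(ms$trajectory, j),
                       frameCoords(ms$trajectory, i)), numeric(1)))
    }, numeric(1))
    expect_equal(representativeFrame(ms$trajectory, cm, cl),
                 members[which.min(round(meanD, 9))])
  }
  expect_error(representativeFrame(ms$trajectory, cm, 99), "empty cluster")
})

test_that("timelines track dwell segments and survive striding", {
  ref <- spreadReference(10)
  s2 <- displacedState(ref, 8)
  P <- matrix(c(0.98, 0.02, 0.03, 0.97), 2, byrow = TRUE)
  ms <- makeMultistateTrajectory(list(ref, s2), 1000, seed = 23,
                                 transition = P, jitter = 0.3)
  cm <- clusterTrajectory(ms$trajectory, cutoff = 2, seed = 23)
  tl <- clusterTimeline(cm, timestamps(ms$trajectory))
  expect_equal(tl$time_ps, sort(tl$time_ps))
  ## cluster runs match the ground-truth dwell segments
  relab <- as.integer(names(sort(table(cm@assignment[ms$labels == 1L]),
                                 decreasing = TRUE)))[1]
  agree <- mean((cm@assignment == relab) == (ms$labels == 1L))
  expect_gt(max(agree, 1 - agree), 0.9)
  ## stride re-sampling preserves proportions (on the switching fixture,
  ## whose frames are exchangeable)
  msi <- twoStateFixture(nframes = 2000, seed = 29)
  cmi <- clusterTrajectory(msi$trajectory, cutoff = 2, seed = 29)
  tli <- clusterTimeline(cmi, timestamps(msi$trajectory))
  sub <- tli$cluster[seq(1, 2000, by = 2)]
  expect_lt(abs(100 * mean(tli$cluster == 1L) - 100 * mean(sub == 1L)),
            2 + 1e-9)
})
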