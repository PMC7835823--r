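# Small hand-built frames exercise the geometric criteria exactly.

## one ARG and one ASP with controllable N-O distance
saltPairFixture <- function(dNO) {
  topo <- topology(
    atoms = data.frame(name = c("CA", "NH1", "CA", "OD1"),
                       element = c("C", "N", "C", "O"),
                       resindex = c(1L, 1L, 2L, 2L)),
    residues = data.frame(resname = c("ARG", "ASP"), resno = c(10L, 20L),
                          chain = "A"))
  co <- rbind(c(0, -3.8, 0), c(0, 0, 0), c(0, dNO + 3.8, 0), c(0, dNO, 0))
  list(topo = topo, co = co)
}

## donor N-H ... acceptor O with controllable distance and angle
hbondFixture <- function(dDA, angle) {
  topo <- topology(
    atoms = data.frame(name = c("CA", "ND2", "HD21", "CA", "OG"),
                       element = c("C", "N", "H", "C", "O"),
                       resindex = c(1L, 1L, 1L, 2L, 2L)),
    residues = data.frame(resname = c("ASN", "SER"), resno = c(1L, 2L),
                          chain = "A"))
  D <- c(0, 0, 0)
  A <- c(dDA, 0, 0)
  hAng <- function(beta) {
    H <- D + 1.01 * c(cos(beta), sin(beta), 0)
    v1 <- D - H
    v2 <- A - H
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }
  beta <- if (angle >= 180 - 1e-9) 0 else
    uniroot(function(b) hAng(b) - angle, c(1e-6, pi / 2))$root
  co <- rbind(c(-3.8, 0, 0), D, D + 1.01 * c(cos(beta), sin(beta), 0),
              c(dDA + 3.8, 0, 0), A)
  list(topo = topo, co = co)
}

test_that("hydrogen-bond criteria apply exact distance and angle gates", {
  hx <- hbondFixture(3.5, 150)
  hb <- findHbonds(hx$co, hx$topo)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance_A, 3.5, tolerance = 1e-9)
  expect_equal(hb$angle_deg, 150, tolerance = 1e-4)
  ## distance boundary: 3.7 A fails at the 3.6 A cut-off
  expect_equal(nrow(findHbonds(hbondFixture(3.7, 170)$co, hx$topo)), 0L)
  ## angle boundary
  expect_equal(nrow(findHbonds(hbondFixture(3.0, 115)$co, hx$topo)), 0L)
  ## S-H...S at 3.9 A: absent at defaults, present when the cut is raised
  sx <- topology(
    atoms = data.frame(name = c("SG", "HG", "SG"),
                       element = c("S", "H", "S"),
                       resindex = c(1L, 1L, 2L)),
    residues = data.frame(resname = "CYS", resno = c(37L, 40L),
                          chain = "A"))
  sco <- rbind(c(0, 0, 0), c(1.34, 0, 0), c(3.9, 0, 0))
  expect_equal(nrow(findHbonds(sco, sx)), 0L)
  expect_equal(nrow(findHbonds(sco, sx, dCut = 4.2)), 1L)
  ## H-less structure: explicit error unless idealisation is on
  hless <- makeIdealHelix(6, "alpha")
  noH <- which(atomTable(hless$topology)$name != "H")
  topoNoH <- topology(atoms = atomTable(hless$topology)[noH, ],
                      residues = residueTable(hless$topology))
  coNoH <- frameCoords(hless$trajectory)[noH, ]
  expect_error(findHbonds(coNoH, topoNoH), "no hydrogens")
  expect_gt(nrow(findHbonds(coNoH, topoNoH, idealizeH = TRUE)), 0L)
})

test_that("hydrophobic contacts respect the 4 A side-chain rule", {
  mk <- function(d, rA = "LEU", rB = "LEU") {
    pa <- c(LEU = "CD1", ALA = "CB", GLY = "CA")[rA]
    pb <- c(LEU = "CD1", ALA = "CB", GLY = "CA")[rB]
    atoms <- data.frame(
      name = c(if (rA != "GLY") "CA", pa, if (rB != "GLY") "CA", pb),
      element = "C",
      resindex = c(rep(1L, 1 + (rA != "GLY")), rep(2L, 1 + (rB != "GLY"))))
    topo <- topology(atoms,
                     data.frame(resname = c(rA, rB), resno = c(5L, 50L),
                                chain = "A"))
    co <- NULL
    if (rA != "GLY") co <- rbind(co, c(0, -3.8, 0))
    co <- rbind(co, c(0, 0, 0))
    if (rB != "GLY") co <- rbind(co, c(0, d + 3.8, 0))
    co <- rbind(co, c(0, d, 0))
    list(topo = topo, co = co)
  }
  f <- mk(3.8)
  expect_equal(nrow(findHydrophobic(f$co, f$topo)), 1L)
  f2 <- mk(4.2)
  expect_equal(nrow(findHydrophobic(f2$co, f2$topo)), 0L)
  ## glycine's CA stands in for its side chain
  g <- mk(3.5, "GLY", "ALA")
  hits <- findHydrophobic(g$co, g$topo)
  expect_equal(nrow(hits), 1L)
  expect_setequal(c(hits$resD, hits$resA), c("GLY", "ALA"))
  ## backbone atoms of non-glycine residues never count
  expect_true(all(hits$atomD != "CA" | hits$resD == "GLY"))
})

test_that("salt bridges pair opposite charges and dual-list with H-bonds", {
  s <- saltPairFixture(2.8)
  sb <- findSaltBridges(s$co, s$topo)
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$distance_A, 2.8, tolerance = 1e-9)
  s2 <- saltPairFixture(4.5)
  expect_equal(nrow(findSaltBridges(s2$co, s2$topo)), 0L)
  ## histidine is excluded from salt-bridge donors
  hs <- topology(
    atoms = data.frame(name = c("NE2", "OD1"), element = c("N", "O"),
                       resindex = c(1L, 2L)),
    residues = data.frame(resname = c("HIS", "ASP"), resno = 1:2,
                          chain = "A"))
  expect_equal(nrow(findSaltBridges(rbind(c(0, 0, 0), c(3, 0, 0)), hs)), 0L)
  ## a Lys N-H donating to Glu O is reported both ways
  topo <- topology(
    atoms = data.frame(name = c("NZ", "HZ1", "OE2"),
                       element = c("N", "H", "O"),
                       resindex = c(1L, 1L, 2L)),
    residues = data.frame(resname = c("LYS", "GLU"), resno = 1:2,
                          chain = "A"))
  co <- rbind(c(0, 0, 0), c(1.01, 0, 0), c(3.2, 0, 0))
  expect_equal(nrow(findSaltBridges(co, topo)), 1L)
  expect_equal(nrow(findHbonds(co, topo)), 1L)
})

test_that("detectors equal a brute-force all-pairs oracle and are rigid-invariant", {
  con <- data.frame(
    type = c("salt", "hbond", "hydrophobic", "hydrophobic", "salt"),
    distance = c(2.8, 3.4, 3.8, 3.3, 3.5),
    angle = c(NA, 155, NA, NA, NA))
  pf <- makePlantedInterface(con)
  co <- frameCoords(pf$trajectory)
  pkg <- contactKeys(rbind(findHbonds(co, pf$topology),
                           findSaltBridges(co, pf$topology),
                           findHydrophobic(co, pf$topology)))
  expect_identical(pkg, bruteForceContacts(co, pf$topology))
  ## rigid motion leaves the detected set unchanged
  co2 <- applyRigidTo(co, randomRigid(44))
  pkg2 <- contactKeys(rbind(findHbonds(co2, pf$topology),
                            findSaltBridges(co2, pf$topology),
                            findHydrophobic(co2, pf$topology)))
  expect_identical(pkg2, pkg)
})

test_that("interface analysis is chain-symmetric with no intra-chain leakage", {
  con <- data.frame(type = c("salt", "salt", "hydrophobic", "hydrophobic",
                             "hydrophobic"),
                    distance = c(2.8, 3.2, 3.8, 3.5, 3.6))
  pf <- makePlantedInterface(con)
  co <- frameCoords(pf$trajectory)
  ab <- interfaceContacts(co, pf$topology, "A", "B")
  ba <- interfaceContacts(co, pf$topology, "B", "A")
  expect_equal(ab$summary$residue_pairs, 5L)
  expect_equal(ba$summary$residue_pairs, 5L)
  expect_setequal(
    paste(ab$records$resnoD, ab$records$resnoA),
    paste(ba$records$resnoD, ba$records$resnoA))
  expect_true(all(ab$records$chainD != ab$records$chainA))
  expect_error(interfaceContacts(co, pf$topology, "A", "Z"),
               "unknown chain")
})

test_that("contact maps accumulate occupancy and stay symmetric", {
  s <- saltPairFixture(2.8)
  far <- saltPairFixture(6.0)
  arr <- array(NA_real_, c(2, 4, 3))
  arr[1, , ] <- s$co
  arr[2, , ] <- far$co
  tr <- trajectory(arr, s$topo)
  cmp <- contactMap(tr, detectors = "salt")
  expect_equal(cmp["A:10", "A:20"], 0.5)
  expect_equal(cmp, t(cmp))
  expect_true(all(cmp >= 0 & cmp <= 1))
  one <- contactMap(trajectory(s$co, s$topo), detectors = "salt")
  expect_true(all(one %in% c(0, 1)))
})

test_that("exposed residues are the contact-free ones, labelled by class", {
  s <- saltPairFixture(2.8)
  ## add a lone arginine far from everything
  topo <- topology(
    atoms = rbind(atomTable(s$topo),
                  data.frame(name = "NH1", element = "N", resindex = 3L)),
    residues = rbind(residueTable(s$topo),
                     data.frame(resname = "ARG", resno = 30L,
                                chain = "A")))
  co <- rbind(s$co, c(50, 50, 50))
  ex <- exposedResidues(co, topo)
  expect_equal(ex$resno, 30L)
  expect_equal(ex$class, "positively-charged")
  ## the interacting pair is buried, the singleton is not
  expect_false(any(c(10L, 20L) %in% ex$resno))
})
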