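# Generators of synthetic structures and trajectories with planted ground
# truth. All are deterministic under a fixed seed and return the truth
# (labels, spectra, planted contacts) alongside the data, so downstream
# analyses can be tested without reference MD data.

#' Minimal C-alpha topology for synthetic ensembles
#'
#' @param n number of residues (one CA atom each).
#' @param chain chain identifier.
#' @param resname residue name used throughout (default ALA).
#' @return a \linkS4class{Topology} with one CA per residue.
#' @export
syntheticCaTopology <- function(n, chain = "A", resname = "ALA") {
  topology(
    atoms = data.frame(name = "CA", element = "C", resindex = seq_len(n)),
    residues = data.frame(resname = resname, resno = seq_len(n),
                          chain = chain))
}

## Orthonormal basis of the 6 rigid-body displacement modes (3 trans +
## 3 rot) of a reference configuration, as 3N columns.
rigidBodyBasis <- function(reference) {
  n <- nrow(reference)
  ctr <- sweep(reference, 2, colMeans(reference))
  cols <- matrix(0, 3 * n, 6)
  for (k in 1:3) cols[seq(k, 3 * n, by = 3), k] <- 1
  for (k in 1:3) {
    axis <- c(0, 0, 0)
    axis[k] <- 1
    disp <- t(apply(ctr, 1, function(r) crossProd(axis, r)))
    cols[, 3 + k] <- as.vector(t(disp))
  }
  qr.Q(qr(cols))[, seq_len(qr(cols)$rank), drop = FALSE]
}

#' Orthonormal internal-motion directions for a reference structure
#'
#' Draws random directions in coordinate space and orthogonalises them
#' against the six rigid-body modes (and each other), yielding directions
#' that represent pure internal deformation: superposing frames displaced
#' along them changes nothing, so a planted covariance spectrum survives
#' the fitting step.
#'
#' @param reference N x 3 reference coordinates.
#' @param m number of directions.
#' @param seed RNG seed.
#' @return 3N x m matrix with orthonormal columns.
#' @export
internalModeBasis <- function(reference, m, seed) {
  n3 <- 3 * nrow(reference)
  stopifnot(m <= n3 - 6)
  rig <- rigidBodyBasis(reference)
  rng <- localRng(seed)
  out <- matrix(0, n3, m)
  have <- 0L
  while (have < m) {
    v <- rng$norm(n3)
    v <- v - rig %*% crossprod(rig, v)
    if (have > 0L) {
      B <- out[, seq_len(have), drop = FALSE]
      v <- v - B %*% crossprod(B, v)
    }
    nv <- vnorm(v)
    if (nv > 1e-6) {
      have <- have + 1L
      out[, have] <- v / nv
    }
  }
  out
}

#' Stationary Gaussian ensemble with a planted covariance
#'
#' Frames are drawn i.i.d. around the reference with covariance given
#' either in full or as a planted spectrum (eigenvalues in Angstrom^2
#' along orthonormal directions). As the frame count grows the sample
#' mean converges to the reference and the sample covariance to the
#' specification.
#'
#' @param reference N x 3 reference coordinates (Angstrom).
#' @param nframes number of frames (>= 2).
#' @param seed RNG seed (the same seed reproduces the trajectory
#'   bit-for-bit).
#' @param covariance full 3N x 3N symmetric PSD matrix, or NULL to use
#'   \code{spectrum}/\code{directions}.
#' @param spectrum eigenvalues (Angstrom^2) of the planted covariance.
#' @param directions 3N x m orthonormal matrix of planted directions;
#'   default [internalModeBasis()] directions (internal motions only).
#' @param topology optional \linkS4class{Topology}; default a synthetic
#'   CA topology.
#' @return list with \code{trajectory}, \code{spectrum} and
#'   \code{directions} (the planted truth).
#' @export
makeGaussianEnsemble <- function(reference, nframes, seed,
                                 covariance = NULL, spectrum = NULL,
                                 directions = NULL, topology = NULL) {
  stopifnot(nframes >= 2L)
  n <- nrow(reference)
  n3 <- 3L * n
  if (!is.null(covariance)) {
    if (max(abs(covariance - t(covariance))) > 1e-8)
      stop("covariance specification must be symmetric")
    e <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values), 1))
      stop("covariance specification must be positive semi-definite")
    keep <- e$values > 1e-12
    spectrum <- e$values[keep]
    directions <- e$vectors[, keep, drop = FALSE]
  } else if (is.null(spectrum)) {
    stop("provide either a covariance matrix or a spectrum")
  }
  if (any(spectrum < 0)) stop("spectrum must be non-negative")
  if (is.null(directions))
    directions <- internalModeBasis(reference, length(spectrum), seed + 1L)
  m <- length(spectrum)
  stopifnot(ncol(directions) == m, nrow(directions) == n3)
  rng <- localRng(seed)
  z <- matrix(rng$norm(nframes * m), m, nframes)
  X <- directions %*% (sqrt(spectrum) * z)     # 3N x F displacements
  refv <- as.vector(t(reference))
  coords <- array(NA_real_, dim = c(nframes, n, 3))
  for (f in seq_len(nframes))
    coords[f, , ] <- matrix(refv + X[, f], ncol = 3, byrow = TRUE)
  if (is.null(topology)) topology <- syntheticCaTopology(n)
  list(trajectory = trajectory(coords, topology),
       spectrum = spectrum, directions = directions)
}

#' Multi-state switching trajectory with known occupancies
#'
#' Frames hop between m reference states either i.i.d. according to
#' target occupancies or as a Markov chain with the given transition
#' matrix, with isotropic Gaussian jitter added per atom per coordinate.
#' The ground-truth labels and the pairwise fitted inter-state RMSD
#' matrix are returned alongside.
#'
#' @param states list of N x 3 state reference coordinates.
#' @param nframes number of frames.
#' @param seed RNG seed.
#' @param occupancies target state probabilities (must sum to 1); ignored
#'   when \code{transition} is given.
#' @param transition m x m row-stochastic transition matrix (Markov
#'   sampling starting from \code{start}).
#' @param jitter isotropic per-coordinate jitter sd in Angstrom
#'   (default 0.3).
#' @param start starting state for Markov sampling (default 1).
#' @param topology optional topology; default synthetic CA topology.
#' @return list with \code{trajectory}, \code{labels},
#'   \code{interStateRmsd}.
#' @export
makeMultistateTrajectory <- function(states, nframes, seed,
                                     occupancies = NULL, transition = NULL,
                                     jitter = 0.3, start = 1L,
                                     topology = NULL) {
  m <- length(states)
  n <- nrow(states[[1]])
  stopifnot(m >= 1L, nframes >= 1L)
  rng <- localRng(seed)
  if (is.null(transition)) {
    if (is.null(occupancies)) occupancies <- rep(1 / m, m)
    if (abs(sum(occupancies) - 1) > 1e-9 || any(occupancies < 0))
      stop("occupancies must be non-negative and sum to 1")
    u <- rng$unif(nframes)
    labels <- findInterval(u, cumsum(occupancies), left.open = TRUE) + 1L
  } else {
    stopifnot(nrow(transition) == m, ncol(transition) == m)
    if (max(abs(rowSums(transition) - 1)) > 1e-9)
      stop("transition matrix rows must sum to 1")
    labels <- integer(nframes)
    cur <- as.integer(start)
    u <- rng$unif(nframes)
    for (f in seq_len(nframes)) {
      cur <- findInterval(u[f], cumsum(transition[cur, ]),
                          left.open = TRUE) + 1L
      cur <- min(cur, m)
      labels[f] <- cur
    }
  }
  labels <- pmin(labels, m)
  noise <- array(rng$norm(nframes * n * 3) * jitter, dim = c(nframes, n, 3))
  coords <- array(NA_real_, dim = c(nframes, n, 3))
  for (f in seq_len(nframes))
    coords[f, , ] <- states[[labels[f]]] + matrix(noise[f, , ], ncol = 3)
  inter <- matrix(0, m, m)
  if (m > 1L)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
      inter[i, j] <- inter[j, i] <- fittedRmsd(states[[i]], states[[j]])
  if (is.null(topology)) topology <- syntheticCaTopology(n)
  list(trajectory = trajectory(coords, topology), labels = labels,
       interStateRmsd = inter)
}

## NeRF atom placement: position D bonded to C with |CD| = r, angle
## B-C-D = theta (deg) and dihedral A-B-C-D = chi (deg).
placeAtom <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  bc <- unitize(c - b)
  nrm <- unitize(crossProd(b - a, bc))
  m <- crossProd(nrm, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(ch), -r * sin(th) * sin(ch))
  c + d[1] * bc + d[2] * m + d[3] * nrm
}

## Canonical backbone torsions per helix kind.
.helixTorsions <- list(alpha = c(phi = -57, psi = -47),
                       three_ten = c(phi = -49, psi = -26),
                       extended = c(phi = -180, psi = 180))

#' Build an ideal helix or extended chain
#'
#' Poly-alanine backbone (N, CA, C, O and amide H) built from canonical
#' backbone torsions: alpha (phi, psi) = (-57, -47), 3-10 helix
#' (-49, -26), extended (-180, 180), trans peptide bonds throughout.
#' Amide hydrogens are placed on the bisector of the two N bonds; the
#' first residue has no amide H.
#'
#' @param nResidues chain length (>= 4).
#' @param kind \code{"alpha"}, \code{"three_ten"} or \code{"extended"}.
#' @return list with \code{topology} and single-frame \code{trajectory}.
#' @export
makeIdealHelix <- function(nResidues,
                           kind = c("alpha", "three_ten", "extended")) {
  kind <- match.arg(kind)
  if (nResidues < 4L) stop("need at least 4 residues")
  tor <- .helixTorsions[[kind]]
  phi <- tor["phi"]; psi <- tor["psi"]; omega <- 180
  b <- list(nca = 1.458, cac = 1.525, cn = 1.329, co = 1.231, nh = 1.01)
  ang <- list(cnca = 121.7, ncac = 111.2, cacn = 116.2, caco = 120.8)
  N <- CA <- C <- O <- H <- vector("list", nResidues)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(b$nca, 0, 0)
  th <- ang$ncac * pi / 180
  C[[1]] <- CA[[1]] + b$cac * c(-cos(th), sin(th), 0)
  for (i in 2:nResidues) {
    N[[i]] <- placeAtom(N[[i - 1]], CA[[i - 1]], C[[i - 1]], b$cn,
                        ang$cacn, psi)
    CA[[i]] <- placeAtom(CA[[i - 1]], C[[i - 1]], N[[i]], b$nca,
                         ang$cnca, omega)
    C[[i]] <- placeAtom(C[[i - 1]], N[[i]], CA[[i]], b$cac, ang$ncac, phi)
    H[[i]] <- N[[i]] + b$nh *
      unitize(unitize(N[[i]] - C[[i - 1]]) + unitize(N[[i]] - CA[[i]]))
  }
  for (i in seq_len(nResidues)) {
    ref <- if (i < nResidues) N[[i + 1]] else
      placeAtom(N[[i]], CA[[i]], C[[i]], b$cn, ang$cacn, psi)
    ## O is anti to the next N across the sp2 carbonyl carbon
    O[[i]] <- placeAtom(N[[i]], CA[[i]], C[[i]], b$co, ang$caco,
                        dihedralAngle(N[[i]], CA[[i]], C[[i]], ref) + 180)
  }
  nm <- el <- character(0)
  ridx <- integer(0)
  xyz <- NULL
  for (i in seq_len(nResidues)) {
    atoms <- list(N = N[[i]], CA = CA[[i]], C = C[[i]], O = O[[i]])
    if (i > 1L) atoms$H <- H[[i]]
    for (an in names(atoms)) {
      nm <- c(nm, an)
      el <- c(el, substr(an, 1, 1))
      ridx <- c(ridx, i)
      xyz <- rbind(xyz, atoms[[an]])
    }
  }
  topo <- topology(
    atoms = data.frame(name = nm, element = el, resindex = ridx),
    residues = data.frame(resname = "ALA", resno = seq_len(nResidues),
                          chain = "A"))
  list(topology = topo, trajectory = trajectory(xyz, topo))
}

#' Build a four-landmark CXXC motif with prescribed geometry
#'
#' Places the S-CA-CA'-S' landmarks of a CX1X2C motif so that the S-to-S
#' distance and the absolute pseudo-torsion take the requested values
#' exactly: the two S-CA bond vectors make equal angles with the CA-CA'
#' axis, solved numerically for the requested distance at the requested
#' torsion.
#'
#' @param sSDistance target S...S' distance (Angstrom, > 0).
#' @param pseudoTorsion target absolute pseudo-torsion (degrees, 0-180).
#' @param caDistance CA-CA' separation (Angstrom, default 5.5, typical for
#'   the i, i+3 cysteines of a CXXC motif).
#' @param sCaDistance S-CA distance within a cysteine (default 2.81).
#' @return list with \code{topology} (two CYS residues) and a single-frame
#'   \code{trajectory}; atom order SG, CA, CA', SG'.
#' @export
makeMotif <- function(sSDistance, pseudoTorsion, caDistance = 5.5,
                      sCaDistance = 2.81) {
  stopifnot(sSDistance > 0, pseudoTorsion >= 0, pseudoTorsion <= 180)
  L <- caDistance
  r <- sCaDistance
  ch <- pseudoTorsion * pi / 180
  dd <- function(th)
    (L - 2 * r * cos(th))^2 + 2 * r^2 * sin(th)^2 * (1 - cos(ch))
  g <- function(th) dd(th) - sSDistance^2
  grid <- seq(1e-6, pi - 1e-6, length.out = 512)
  vals <- vapply(grid, g, numeric(1))
  sgn <- which(diff(sign(vals)) != 0)
  if (!length(sgn))
    stop("impossible motif geometry: requested S...S distance of ",
         sSDistance, " A is outside the reachable range")
  th <- stats::uniroot(g, c(grid[sgn[1]], grid[sgn[1] + 1]),
                       tol = 1e-12)$root
  ca1 <- c(0, 0, 0)
  ca2 <- c(L, 0, 0)
  s1 <- c(r * cos(th), r * sin(th), 0)
  s2 <- ca2 + r * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  topo <- topology(
    atoms = data.frame(name = c("SG", "CA", "CA", "SG"),
                       element = c("S", "C", "C", "S"),
                       resindex = c(1L, 1L, 2L, 2L)),
    residues = data.frame(resname = "CYS", resno = c(37L, 40L),
                          chain = "A"))
  list(topology = topo,
       trajectory = trajectory(rbind(s1, ca1, ca2, s2), topo))
}

## Side-chain proxy atom used when planting hydrophobic contacts.
.hydroProxy <- c(LEU = "CD1", ILE = "CD1", VAL = "CG1", ALA = "CB",
                 PHE = "CZ", MET = "CE", PRO = "CG", GLY = "CA")

#' Build a two-chain complex with a planted interface contact list
#'
#' Constructs minimal residues on two chains such that exactly the
#' requested inter-chain contacts (salt bridges, hydrogen bonds,
#' hydrophobic contacts) satisfy the detection criteria and nothing else
#' does: each planted pair sits in its own slot 20 Angstrom from its
#' neighbours, with one far-apart anchor residue per chain.
#'
#' @param contacts data.frame with columns \code{type} (one of
#'   \code{"salt"}, \code{"hbond"}, \code{"hydrophobic"}),
#'   \code{distance} (target heavy-atom distance, Angstrom) and optional
#'   \code{angle} (target D-H...A angle for H-bonds, degrees, default
#'   180) and \code{resnameA}/\code{resnameB}. May have zero rows.
#' @param hbondCut,saltCut,hydroCut detection cut-offs used to validate
#'   the requested geometries (defaults 3.6/4.0/4.0 Angstrom); planted
#'   distances must clear them by at least 0.1 Angstrom and planted
#'   angles the 120-degree threshold by at least 5 degrees.
#' @return list with \code{topology}, single-frame \code{trajectory} and
#'   \code{planted} (the ground-truth contact table with chain/residue
#'   ids).
#' @export
makePlantedInterface <- function(contacts = data.frame(),
                                 hbondCut = 3.6, saltCut = 4.0,
                                 hydroCut = 4.0) {
  if (nrow(contacts) && !all(c("type", "distance") %in% names(contacts)))
    stop("contacts needs columns type and distance")
  nm <- el <- rsn <- ch <- character(0)
  ridx <- integer(0)
  xyz <- NULL
  resno <- integer(0)
  nres <- 0L
  addAtom <- function(name, element, pos) {
    nm <<- c(nm, name); el <<- c(el, element)
    ridx <<- c(ridx, nres); xyz <<- rbind(xyz, pos)
  }
  addResidue <- function(resname, chain) {
    nres <<- nres + 1L
    rsn <<- c(rsn, resname); ch <<- c(ch, chain)
    resno <<- c(resno, nres)
    nres
  }
  ## far-apart anchors guarantee both chains exist (30 A apart)
  addResidue("GLY", "A"); addAtom("CA", "C", c(-30, -15, 0))
  addResidue("GLY", "B"); addAtom("CA", "C", c(-30, 15, 0))
  planted <- NULL
  for (i in seq_len(nrow(contacts))) {
    type <- as.character(contacts$type[i])
    t <- contacts$distance[i]
    x <- 20 * i
    lim <- switch(type, salt = saltCut, hbond = hbondCut,
                  hydrophobic = hydroCut,
                  stop("unknown contact type: ", type))
    if (!(t > 0) || t > lim - 0.1)
      stop("unsatisfiable planted ", type, " contact: distance ", t,
           " A violates the ", lim, " A criterion by less than 0.1 A")
    if (type == "salt") {
      ra <- if ("resnameA" %in% names(contacts) && !is.na(contacts$resnameA[i]))
        contacts$resnameA[i] else "ARG"
      rb <- if ("resnameB" %in% names(contacts) && !is.na(contacts$resnameB[i]))
        contacts$resnameB[i] else "ASP"
      aAtom <- c(ARG = "NH1", LYS = "NZ")[ra]
      bAtom <- c(ASP = "OD1", GLU = "OE1")[rb]
      if (is.na(aAtom) || is.na(bAtom))
        stop("salt contacts need ARG/LYS vs ASP/GLU")
      ia <- addResidue(ra, "A")
      addAtom("CA", "C", c(x, -t / 2 - 3.8, 0))
      addAtom(aAtom, substr(aAtom, 1, 1), c(x, -t / 2, 0))
      ib <- addResidue(rb, "B")
      addAtom("CA", "C", c(x, t / 2 + 3.8, 0))
      addAtom(bAtom, substr(bAtom, 1, 1), c(x, t / 2, 0))
    } else if (type == "hbond") {
      alpha <- if ("angle" %in% names(contacts) && !is.na(contacts$angle[i]))
        contacts$angle[i] else 180
      if (alpha < 125)
        stop("unsatisfiable planted hbond: angle ", alpha,
             " clears the 120-degree criterion by less than 5 degrees")
      ia <- addResidue("SER", "A")
      addAtom("CA", "C", c(x, -t / 2 - 3.8, 0))
      D <- c(x, -t / 2, 0)
      A <- c(x, t / 2, 0)
      addAtom("OG", "O", D)
      ## H on a circle of radius 0.96 about D, opened until angle(D,H,A)
      ## hits the requested value
      hAng <- function(beta) {
        Hp <- D + 0.96 * c(sin(beta), cos(beta), 0)
        vecAngle(D, Hp, A)
      }
      beta <- if (alpha >= 180 - 1e-9) 0 else
        stats::uniroot(function(b) hAng(b) - alpha, c(1e-9, pi / 2),
                       tol = 1e-12)$root
      addAtom("HG", "H", D + 0.96 * c(sin(beta), cos(beta), 0))
      ib <- addResidue("SER", "B")
      addAtom("CA", "C", c(x, t / 2 + 3.8, 0))
      addAtom("OG", "O", A)
    } else {
      ra <- if ("resnameA" %in% names(contacts) && !is.na(contacts$resnameA[i]))
        contacts$resnameA[i] else "LEU"
      rb <- if ("resnameB" %in% names(contacts) && !is.na(contacts$resnameB[i]))
        contacts$resnameB[i] else "LEU"
      pa <- .hydroProxy[ra]; pb <- .hydroProxy[rb]
      if (is.na(pa) || is.na(pb))
        stop("no hydrophobic proxy atom for ", ra, "/", rb)
      ia <- addResidue(ra, "A")
      if (pa != "CA") addAtom("CA", "C", c(x, -t / 2 - 3.8, 0))
      addAtom(pa, substr(pa, 1, 1), c(x, -t / 2, 0))
      ib <- addResidue(rb, "B")
      if (pb != "CA") addAtom("CA", "C", c(x, t / 2 + 3.8, 0))
      addAtom(pb, substr(pb, 1, 1), c(x, t / 2, 0))
    }
    planted <- rbind(planted, data.frame(
      type = ifelse(type == "salt", "salt_bridge", type),
      resnoA = resno[ia], resnoB = resno[ib], distance = t))
  }
  topo <- topology(
    atoms = data.frame(name = nm, element = el, resindex = ridx),
    residues = data.frame(resname = rsn, resno = resno, chain = ch))
  list(topology = topo, trajectory = trajectory(xyz, topo),
       planted = planted)
}

#' Sample labelled landmark shapes around cluster centres
#'
#' Each centre is perturbed with isotropic Gaussian landmark noise and
#' normalised to a pre-shape; labels identifying the generating centre
#' are returned with the shapes.
#'
#' @param centers list of k x 3 landmark configurations (all sharing k).
#' @param noise per-cluster landmark noise sd (recycled).
#' @param counts shapes per cluster.
#' @param seed RNG seed.
#' @return list with \code{shapes} (list of \linkS4class{PreShape}) and
#'   integer \code{labels}.
#' @export
sampleShapes <- function(centers, noise, counts, seed) {
  k <- unique(vapply(centers, nrow, integer(1)))
  if (length(k) != 1L) stop("all centres must share the landmark count k")
  noise <- rep_len(noise, length(centers))
  counts <- rep_len(counts, length(centers))
  rng <- localRng(seed)
  shapes <- list()
  labels <- integer(0)
  for (j in seq_along(centers)) {
    for (i in seq_len(counts[j])) {
      x <- centers[[j]] + matrix(rng$norm(3 * k) * noise[j], k, 3)
      shapes[[length(shapes) + 1L]] <- preshape(x)
      labels <- c(labels, j)
    }
  }
  list(shapes = shapes, labels = labels)
}
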