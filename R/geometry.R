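## Klyne-Prelog bands on the absolute torsion (degrees).
klyneRelogClass <- function(absTorsion) {
  cut(absTorsion, breaks = c(-1e-9, 30, 90, 150, 180 + 1e-9),
      labels = c("syn-periplanar", "synclinal", "anticlinal",
                 "antiperiplanar"), right = FALSE) |> as.character()
}

#' CXXC motif geometry of one frame
#'
#' The two metrics describing a CX1X2C redox motif: the distance between
#' the two sulphur atoms and the absolute pseudo-torsion S-CA-CA'-S',
#' together with its Klyne-Prelog class (syn-periplanar below 30 degrees,
#' synclinal to 90, anticlinal to 150, antiperiplanar above).
#'
#' @param coords N x 3 frame coordinates.
#' @param sPair indices of the two sulphur atoms (S, S').
#' @param caPair indices of the two alpha carbons (CA, CA'), ordered with
#'   their own cysteines.
#' @return list with \code{s_s_distance}, \code{pseudo_torsion} (0-180
#'   degrees) and \code{class}.
#' @examples
#' m <- makeMotif(4.0, 60)
#' motifGeometry(frameCoords(m$trajectory), c(1, 4), c(2, 3))
#' @export
motifGeometry <- function(coords, sPair, caPair) {
  idx <- c(sPair[1], caPair[1], caPair[2], sPair[2])
  if (anyDuplicated(idx)) stop("motif atoms must be four distinct atoms")
  p <- coords[idx, , drop = FALSE]
  if (min(dist(p)) < 1e-6)
    stop("degenerate motif geometry: coincident atoms")
  d <- vnorm(p[1, ] - p[4, ])
  tor <- abs(dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ]))
  list(s_s_distance = d, pseudo_torsion = tor,
       class = klyneRelogClass(tor))
}

#' Per-frame CXXC motif geometry table
#'
#' @param traj a \linkS4class{Trajectory}.
#' @inheritParams motifGeometry
#' @return data.frame with \code{frame}, \code{time_ps}, \code{d_SS_A},
#'   \code{torsion_deg}, \code{class}.
#' @export
motifSeries <- function(traj, sPair, caPair) {
  nF <- nFrames(traj)
  out <- lapply(seq_len(nF), function(f) {
    g <- motifGeometry(frameCoords(traj, f), sPair, caPair)
    data.frame(frame = f, time_ps = traj@timestamps[f],
               d_SS_A = g$s_s_distance, torsion_deg = g$pseudo_torsion,
               class = g$class)
  })
  do.call(rbind, out)
}

#' Fraction of frames forming a directional S-H...S hydrogen bond
#'
#' Evaluates, frame by frame, whether the thiol of the donor cysteine
#' donates a hydrogen bond to the acceptor sulphur: S...S' distance below
#' the cut-off and S-H...S' angle at the hydrogen at or above the angular
#' threshold. The two donation directions of a CXXC motif are separate
#' calls. Thiol hydrogens are never idealised; the hydrogen position is
#' physically meaningful here and must be explicit.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param donorS,donorH,acceptorS atom indices of the donor sulphur, its
#'   thiol hydrogen and the acceptor sulphur.
#' @param dCut S...S distance cut-off (Angstrom, default 3.6).
#' @param angleCut angle-at-H cut-off (degrees, default 120).
#' @return fraction of frames in [0, 1] satisfying both criteria.
#' @export
shsHbondFraction <- function(traj, donorS, donorH, acceptorS,
                             dCut = 3.6, angleCut = 120) {
  if (is.na(donorH) || is.null(donorH))
    stop("explicit thiol hydrogen required; idealised placement is not ",
         "offered for thiols")
  nF <- nFrames(traj)
  hits <- vapply(seq_len(nF), function(f) {
    p <- frameCoords(traj, f)
    d <- vnorm(p[donorS, ] - p[acceptorS, ])
    ang <- vecAngle(p[donorS, ], p[donorH, ], p[acceptorS, ])
    d < dCut && ang >= angleCut
  }, logical(1))
  mean(hits)
}

#' Six edge-distance series of a C-alpha tetrahedron
#'
#' Tracks the six pairwise distances between four anchor residues'
#' C-alpha atoms over the trajectory; synchronous shifts of the three
#' edges meeting at one vertex signal the displacement of that residue's
#' helix relative to the others.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param anchors four distinct atom indices (C-alpha anchors).
#' @return data.frame with \code{frame}, \code{time_ps} and six distance
#'   columns \code{d12}, \code{d13}, \code{d14}, \code{d23}, \code{d24},
#'   \code{d34} (Angstrom).
#' @export
tetrahedronEdges <- function(traj, anchors) {
  if (length(anchors) != 4L || anyDuplicated(anchors))
    stop("need four distinct anchor atoms")
  pairs <- utils::combn(4, 2)
  nF <- nFrames(traj)
  out <- matrix(NA_real_, nF, 6)
  for (f in seq_len(nF)) {
    p <- frameCoords(traj, f)[anchors, , drop = FALSE]
    out[f, ] <- apply(pairs, 2, function(ij) vnorm(p[ij[1], ] - p[ij[2], ]))
  }
  colnames(out) <- apply(pairs, 2, function(ij) paste0("d", ij[1], ij[2]))
  cbind(data.frame(frame = seq_len(nF), time_ps = traj@timestamps),
        as.data.frame(out))
}

#' Largest synchronous edge shift of a tetrahedron series
#'
#' Scans the six edge series for the frame at which the summed absolute
#' step change of the edges meeting at each vertex is largest; a simple
#' change-point indicator for helix displacement events.
#'
#' @param edges result of [tetrahedronEdges()].
#' @param minDelta minimum per-edge step (Angstrom) for an edge to count
#'   as shifted (default 3).
#' @return list with \code{frame} (the step 'frame-1 to frame'),
#'   \code{vertex}, \code{edgesShifted} and \code{delta} (summed shift).
#' @export
synchronousShift <- function(edges, minDelta = 3) {
  vertexEdges <- list(c("d12", "d13", "d14"), c("d12", "d23", "d24"),
                      c("d13", "d23", "d34"), c("d14", "d24", "d34"))
  dmat <- as.matrix(edges[, grep("^d[0-9]", names(edges))])
  steps <- abs(diff(dmat))
  best <- list(frame = NA_integer_, vertex = NA_integer_,
               edgesShifted = 0L, delta = 0)
  for (v in seq_along(vertexEdges)) {
    s <- steps[, vertexEdges[[v]], drop = FALSE]
    score <- rowSums(s * (s >= minDelta))
    nshift <- rowSums(s >= minDelta)
    f <- which.max(score)
    if (length(f) && score[f] > best$delta) {
      best <- list(frame = f + 1L, vertex = v,
                   edgesShifted = as.integer(nshift[f]), delta = score[f])
    }
  }
  best
}

#' Helix axis from terminal-residue main-chain centroids
#'
#' The axis is the line joining the centroids of the main-chain atoms
#' (N, CA, C, O) of the first and last residues of the helix; an
#' elongation factor moves both endpoints symmetrically outward (e.g.
#' 1.5 lengthens the drawn axis by 50 percent).
#'
#' @param coords N x 3 frame coordinates.
#' @param topo the \linkS4class{Topology}.
#' @param resRange residue numbers (author numbering) spanning the helix;
#'   at least 3 residues.
#' @param chain chain of the helix (default first chain).
#' @param elongation axis elongation factor (default 1).
#' @return list with \code{start}, \code{end} (3-vectors), \code{direction}
#'   (unit), \code{length} (Angstrom).
#' @export
helixAxis <- function(coords, topo, resRange, chain = NULL,
                      elongation = 1) {
  if (length(resRange) < 3L) stop("a helix needs at least 3 residues")
  if (is.null(chain)) chain <- topo@residues$chain[1]
  mainChain <- function(resno) {
    sel <- which(topo@residues$resno == resno & topo@residues$chain == chain)
    rows <- which(topo@atoms$resindex %in% sel &
                    toupper(topo@atoms$name) %in% c("N", "CA", "C", "O"))
    if (length(rows) < 4L)
      stop("incomplete main chain for residue ", resno)
    colMeans(coords[rows, , drop = FALSE])
  }
  a <- mainChain(min(resRange))
  b <- mainChain(max(resRange))
  mid <- (a + b) / 2
  a <- mid + (a - mid) * elongation
  b <- mid + (b - mid) * elongation
  len <- vnorm(b - a)
  if (len < 1e-9) stop("degenerate helix axis")
  list(start = a, end = b, direction = (b - a) / len, length = len)
}

#' Helix-axis drift tracks projected on coordinate planes
#'
#' Frames are first fitted to the reference frame on \code{fitMask}; the
#' helix axis endpoints are then projected on the x-z and y-z planes,
#' giving two 2-D tracks per endpoint that visualise the drift of the
#' helix over time.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param resRange,chain helix residue range as in [helixAxis()].
#' @param fitMask atoms for the superposition (default all).
#' @param reference reference frame id (default 1).
#' @return data.frame with \code{frame}, \code{time_ps}, \code{plane}
#'   (\code{"xz"}/\code{"yz"}), \code{endpoint} (\code{"start"}/
#'   \code{"end"}), \code{u}, \code{v} (Angstrom).
#' @export
axisDrift <- function(traj, resRange, chain = NULL, fitMask = NULL,
                      reference = 1L) {
  topo <- traj@topology
  rows <- resolveMask(topo, fitMask)
  ref <- frameCoords(traj, reference)
  nF <- nFrames(traj)
  recs <- vector("list", nF)
  for (f in seq_len(nF)) {
    x <- frameCoords(traj, f)
    x <- applyRigid(x, rigidFit(x, ref, rows))
    ax <- helixAxis(x, topo, resRange, chain)
    recs[[f]] <- data.frame(
      frame = f, time_ps = traj@timestamps[f],
      plane = rep(c("xz", "xz", "yz", "yz")),
      endpoint = rep(c("start", "end"), 2),
      u = c(ax$start[1], ax$end[1], ax$start[2], ax$end[2]),
      v = c(ax$start[3], ax$end[3], ax$start[3], ax$end[3]))
  }
  do.call(rbind, recs)
}

#' Minimal inter-domain cysteine sulphur-sulphur distance
#'
#' The shortest S...S distance between cysteine sulphur atoms of two
#' residue groups (e.g. the thioredoxin-like and VKOR-like domains of a
#' redox complex), the quantity that decides whether a thiol-disulphide
#' exchange geometry is within reach.
#'
#' @param coords N x 3 frame coordinates.
#' @param topo the \linkS4class{Topology}.
#' @param domainA,domainB selection expressions or atom index vectors
#'   delimiting the two domains; only CYS sulphur atoms (name SG) inside
#'   each are used.
#' @return minimal S...S distance in Angstrom.
#' @export
minInterDomainSS <- function(coords, topo, domainA, domainB) {
  sgOf <- function(dom) {
    rows <- resolveMask(topo, dom)
    ctx <- atomContext(topo)
    rows[ctx$resname[rows] == "CYS" & ctx$name[rows] == "SG"]
  }
  a <- sgOf(domainA)
  b <- sgOf(domainB)
  if (!length(a) || !length(b))
    stop("no cysteine SG atoms in one of the domains")
  min(apply(expand.grid(a, b), 1, function(ij)
    vnorm(coords[ij[1], ] - coords[ij[2], ])))
}
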