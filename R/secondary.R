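# Kabsch-Sander style secondary-structure assignment from backbone
# N-H...O=C hydrogen-bond energies.

## Backbone atom coordinates per residue of one chain, with amide H
## idealised when absent.
backboneTable <- function(coords, topo) {
  ctx <- atomContext(topo)
  nRes <- nrow(topo@residues)
  get1 <- function(ri, nm) {
    w <- which(ctx$resindex == ri & ctx$name == nm)
    if (length(w) == 1L) coords[w, ] else NULL
  }
  out <- vector("list", nRes)
  for (ri in seq_len(nRes)) {
    rec <- list(N = get1(ri, "N"), CA = get1(ri, "CA"),
                C = get1(ri, "C"), O = get1(ri, "O"), H = get1(ri, "H"))
    if (is.null(rec$H) && !is.null(rec$N) && !is.null(rec$CA)) {
      prevC <- if (ri > 1L &&
                     topo@residues$chain[ri - 1L] == topo@residues$chain[ri])
        get1(ri - 1L, "C") else NULL
      if (!is.null(prevC))
        rec$H <- rec$N + 1.01 * unitize(unitize(rec$N - prevC) +
                                          unitize(rec$N - rec$CA))
    }
    out[[ri]] <- rec
  }
  out
}

#' Backbone hydrogen-bond energy (Kabsch-Sander electrostatic model)
#'
#' \eqn{E = 0.084 \cdot 332 (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})}
#' kcal/mol between the amide N-H of the donor residue and the carbonyl
#' C=O of the acceptor residue; a hydrogen bond is called when
#' E < -0.5 kcal/mol. The amide hydrogen is idealised (bisector
#' placement) when absent; chain-initial residues have no donor H.
#'
#' @param coords N x 3 frame coordinates.
#' @param topo the \linkS4class{Topology}.
#' @param donor,acceptor residue indices (rows of the residue table).
#' @return energy in kcal/mol (\code{Inf} when backbone atoms are
#'   missing for the pair).
#' @export
backboneHbondEnergy <- function(coords, topo, donor, acceptor) {
  bb <- backboneTable(coords, topo)
  ksEnergy(bb[[donor]], bb[[acceptor]])
}

ksEnergy <- function(don, acc) {
  if (is.null(don$N) || is.null(don$H) || is.null(acc$C) || is.null(acc$O))
    return(Inf)
  q <- 0.084 * 332
  q * (1 / vnorm(acc$O - don$N) + 1 / vnorm(acc$C - don$H) -
         1 / vnorm(acc$O - don$H) - 1 / vnorm(acc$C - don$N))
}

## Residue-pair H-bond matrix: hb[i, j] TRUE when the N-H of residue i
## donates to the C=O of residue j with E < -0.5 kcal/mol.
ksHbondMatrix <- function(coords, topo) {
  bb <- backboneTable(coords, topo)
  n <- length(bb)
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (is.null(bb[[i]]$H)) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2L) next
      ## cheap distance gate before the energy evaluation
      if (!is.null(bb[[j]]$O) &&
            vnorm(bb[[i]]$N - bb[[j]]$O) < 5.2 &&
            ksEnergy(bb[[i]], bb[[j]]) < -0.5)
        hb[i, j] <- TRUE
    }
  }
  hb
}

#' Per-residue secondary-structure labels of one frame
#'
#' DSSP-style assignment from backbone hydrogen bonds: \code{H}
#' (alpha-helix) from two consecutive i+4 turns, \code{G} (3-10 helix)
#' from two consecutive i+3 turns, \code{E} (strand) from parallel or
#' antiparallel bridge patterns, \code{T} for isolated turns, \code{S}
#' (bend) where the C-alpha trace kinks by more than 70 degrees, else
#' \code{C}. Priority on conflicts: H > G > E > T > S > C. The pi-helix
#' pattern is folded into T.
#'
#' @param coords N x 3 frame coordinates.
#' @param topo the \linkS4class{Topology} (protein backbone).
#' @return character vector of labels, one per residue.
#' @export
assignSS <- function(coords, topo) {
  n <- nrow(topo@residues)
  lab <- rep("C", n)
  if (n < 3L) return(lab)
  hb <- ksHbondMatrix(coords, topo)
  turn <- function(k) {
    t <- rep(FALSE, n)
    for (i in seq_len(n - k)) if (hb[i + k, i]) t[i] <- TRUE
    t
  }
  t3 <- turn(3L)
  t4 <- turn(4L)
  ## bends from the C-alpha trace
  ctx <- atomContext(topo)
  caRow <- vapply(seq_len(n), function(ri) {
    w <- which(ctx$resindex == ri & ctx$name == "CA")
    if (length(w) == 1L) w else NA_integer_
  }, integer(1))
  bend <- rep(FALSE, n)
  if (n >= 5L) for (i in 3:(n - 2)) {
    r <- caRow[c(i - 2, i, i + 2)]
    if (!anyNA(r)) {
      ang <- vecAngle(coords[r[1], ], coords[r[2], ], coords[r[3], ])
      if (180 - ang > 70) bend[i] <- TRUE
    }
  }
  ## strands: bridge patterns
  bridge <- rep(FALSE, n)
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    if (abs(i - j) < 3L) next
    par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
    anti <- (hb[i, j] && hb[j, i]) ||
      (hb[j + 1, i - 1] && hb[i + 1, j - 1])
    if (par || anti) {
      bridge[i] <- TRUE
      bridge[j] <- TRUE
    }
  }
  ## turns (lowest priority of the H-bond patterns)
  for (k in c(3L, 4L, 5L)) {
    t <- turn(k)
    for (i in which(t)) {
      span <- (i + 1):(i + k - 1)
      lab[span[span <= n]] <- "T"
    }
  }
  lab[bend & lab == "C"] <- "S"
  lab[bridge] <- "E"
  ## 3-10: two consecutive i+3 turns
  for (i in which(t3[-n] & t3[-1])) lab[(i + 1):(i + 3)] <- "G"
  ## alpha: two consecutive i+4 turns (highest priority)
  for (i in which(t4[-n] & t4[-1])) lab[(i + 1):(i + 4)] <- "H"
  lab
}

#' Secondary-structure timeline over a trajectory
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param stride assign every \code{stride}-th frame (default 1).
#' @return matrix of labels, sampled frames x residues, with frame ids as
#'   rownames.
#' @export
ssTimeline <- function(traj, stride = 1L) {
  frames <- seq(1L, nFrames(traj), by = stride)
  topo <- traj@topology
  out <- t(vapply(frames, function(f) assignSS(frameCoords(traj, f), topo),
                  character(nrow(topo@residues))))
  rownames(out) <- frames
  out
}

#' Fraction of residues in the named secondary-structure classes
#'
#' Mean over frames of the per-frame fraction of residues whose label is
#' in \code{classes} (default: the ordered classes H, G and E).
#'
#' @param assignment label matrix from [ssTimeline()] (or a single
#'   frame's label vector).
#' @param classes label subset (default \code{c("H", "G", "E")}).
#' @return fraction in [0, 1].
#' @export
ssFraction <- function(assignment, classes = c("H", "G", "E")) {
  if (!length(classes)) stop("empty class set")
  if (is.null(dim(assignment)))
    assignment <- matrix(assignment, nrow = 1)
  mean(apply(assignment, 1, function(r) mean(r %in% classes)))
}
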