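# Noncovalent contact detection: hydrogen bonds (N/O/S donors and
# acceptors, distance + angle-at-H criteria), salt bridges (opposite
# charged side-chain N-O pairs) and hydrophobic side-chain contacts.

.backboneNames <- c("N", "CA", "C", "O", "OXT")

## Chain/residue annotation per atom.
atomContext <- function(topo) {
  r <- topo@residues[topo@atoms$resindex, ]
  data.frame(name = toupper(topo@atoms$name),
             element = toupper(topo@atoms$element),
             resindex = topo@atoms$resindex,
             resname = toupper(r$resname), resno = r$resno, chain = r$chain)
}

## Hydrogens attached to each heavy atom: by bond list when present,
## else by a 1.45-Angstrom proximity rule (covers O-H through S-H bonds).
attachedHydrogens <- function(coords, ctx, bonds) {
  hIdx <- which(ctx$element == "H")
  out <- vector("list", nrow(ctx))
  if (!length(hIdx)) return(out)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      if (ctx$element[i] == "H" && ctx$element[j] != "H")
        out[[j]] <- c(out[[j]], i)
      else if (ctx$element[j] == "H" && ctx$element[i] != "H")
        out[[i]] <- c(out[[i]], j)
    }
    return(out)
  }
  heavy <- which(ctx$element != "H")
  for (h in hIdx) {
    d2 <- rowSums(sweep(coords[heavy, , drop = FALSE], 2, coords[h, ])^2)
    nearest <- heavy[which.min(d2)]
    if (min(d2) < 1.45^2) out[[nearest]] <- c(out[[nearest]], h)
  }
  out
}

## Idealised amide hydrogen on the backbone N of residue i: on the
## bisector of the two N bonds (previous C and own CA).
idealAmideH <- function(coords, ctx) {
  res <- split(seq_len(nrow(ctx)), ctx$resindex)
  out <- list()
  for (ri in as.integer(names(res))) {
    rows <- res[[as.character(ri)]]
    nAt <- rows[ctx$name[rows] == "N"]
    caAt <- rows[ctx$name[rows] == "CA"]
    prevRows <- which(ctx$resindex == ri - 1L &
                        ctx$chain == ctx$chain[rows[1]])
    cPrev <- prevRows[ctx$name[prevRows] == "C"]
    if (length(nAt) == 1L && length(caAt) == 1L && length(cPrev) == 1L) {
      h <- coords[nAt, ] + 1.01 *
        unitize(unitize(coords[nAt, ] - coords[cPrev, ]) +
                  unitize(coords[nAt, ] - coords[caAt, ]))
      out[[length(out) + 1L]] <- list(donor = nAt, h = h)
    }
  }
  out
}

#' Hydrogen bonds of one frame
#'
#' A bond is recorded between a donor heavy atom D (N, O or S carrying at
#' least one hydrogen) and an acceptor heavy atom A (N, O or S of a
#' different residue) when the D...A distance is below \code{dCut} and
#' the D-H...A angle at the hydrogen is at least \code{angleCut}.
#' Structures without explicit hydrogens can request idealised backbone
#' amide H placement; side-chain hydrogens are never invented.
#'
#' @param coords N x 3 frame coordinates.
#' @param topo the \linkS4class{Topology}.
#' @param dCut donor-acceptor distance cut-off (Angstrom, default 3.6).
#' @param angleCut angle-at-H cut-off (degrees, default 120).
#' @param idealizeH place idealised backbone amide hydrogens when no
#'   explicit H is present (default FALSE).
#' @return data.frame of contact records: \code{type}, \code{chainD},
#'   \code{resnoD}, \code{resD}, \code{atomD}, \code{chainA},
#'   \code{resnoA}, \code{resA}, \code{atomA}, \code{distance_A},
#'   \code{angle_deg}.
#' @export
findHbonds <- function(coords, topo, dCut = 3.6, angleCut = 120,
                       idealizeH = FALSE) {
  ctx <- atomContext(topo)
  hyd <- attachedHydrogens(coords, ctx, topo@bonds)
  donors <- which(ctx$element %in% c("N", "O", "S") &
                    lengths(hyd) > 0L)
  donorH <- lapply(donors, function(d)
    lapply(hyd[[d]], function(h) coords[h, ]))
  if (idealizeH) {
    extra <- idealAmideH(coords, ctx)
    for (e in extra) {
      if (!length(hyd[[e$donor]])) {
        donors <- c(donors, e$donor)
        donorH <- c(donorH, list(list(e$h)))
      }
    }
  }
  accept <- which(ctx$element %in% c("N", "O", "S"))
  if (!length(donors) && !idealizeH && !any(ctx$element == "H"))
    stop("no hydrogens present: supply explicit H or set idealizeH = TRUE")
  rec <- list()
  for (k in seq_along(donors)) {
    d <- donors[k]
    for (a in accept) {
      if (a == d || ctx$resindex[a] == ctx$resindex[d]) next
      dist <- vnorm(coords[d, ] - coords[a, ])
      if (dist >= dCut) next
      for (hpos in donorH[[k]]) {
        ang <- vecAngle(coords[d, ], hpos, coords[a, ])
        if (ang >= angleCut) {
          rec[[length(rec) + 1L]] <- data.frame(
            type = "hbond", chainD = ctx$chain[d], resnoD = ctx$resno[d],
            resD = ctx$resname[d], atomD = ctx$name[d],
            chainA = ctx$chain[a], resnoA = ctx$resno[a],
            resA = ctx$resname[a], atomA = ctx$name[a],
            distance_A = dist, angle_deg = ang)
          break
        }
      }
    }
  }
  bindContactRecords(rec)
}

bindContactRecords <- function(rec) {
  if (!length(rec))
    return(data.frame(type = character(0), chainD = character(0),
                      resnoD = integer(0), resD = character(0),
                      atomD = character(0), chainA = character(0),
                      resnoA = integer(0), resA = character(0),
                      atomA = character(0), distance_A = numeric(0),
                      angle_deg = numeric(0)))
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}

#' Hydrophobic side-chain contacts of one frame
#'
#' Two hydrophobic residues are in contact when any pair of their
#' side-chain heavy atoms is closer than \code{dCut}; glycine's
#' C-alpha stands in for its (absent) side chain. Sequence-adjacent
#' residues of the same chain are excluded.
#'
#' @inheritParams findHbonds
#' @param dCut side-chain distance cut-off (Angstrom, default 4.0).
#' @return contact-record data.frame (angle is NA); the closest
#'   atom pair of each residue pair is reported.
#' @export
findHydrophobic <- function(coords, topo, dCut = 4.0) {
  ctx <- atomContext(topo)
  isHydro <- classifySafely(ctx$resname) == "hydrophobic"
  side <- which(isHydro & ctx$element != "H" &
                  (!(ctx$name %in% .backboneNames) |
                     (ctx$resname == "GLY" & ctx$name == "CA")))
  rec <- list()
  if (length(side) >= 2L) {
    resOf <- ctx$resindex[side]
    resIds <- unique(resOf)
    for (i in seq_along(resIds)[-length(resIds)]) {
      for (j in (i + 1L):length(resIds)) {
        ri <- resIds[i]; rj <- resIds[j]
        a1 <- side[resOf == ri]; a2 <- side[resOf == rj]
        if (ctx$chain[a1[1]] == ctx$chain[a2[1]] &&
              abs(ctx$resno[a1[1]] - ctx$resno[a2[1]]) <= 1L) next
        best <- c(NA_integer_, NA_integer_, Inf)
        for (p in a1) {
          d <- sqrt(rowSums(sweep(coords[a2, , drop = FALSE], 2,
                                  coords[p, ])^2))
          if (min(d) < best[3]) best <- c(p, a2[which.min(d)], min(d))
        }
        if (best[3] < dCut) {
          p <- best[1]; q <- best[2]
          rec[[length(rec) + 1L]] <- data.frame(
            type = "hydrophobic", chainD = ctx$chain[p],
            resnoD = ctx$resno[p], resD = ctx$resname[p],
            atomD = ctx$name[p], chainA = ctx$chain[q],
            resnoA = ctx$resno[q], resA = ctx$resname[q],
            atomA = ctx$name[q], distance_A = best[3],
            angle_deg = NA_real_)
        }
      }
    }
  }
  bindContactRecords(rec)
}

## classifyResidue that tolerates nonstandard residues (returned as NA).
classifySafely <- function(resname) {
  unname(.residueClassTable[toupper(resname)])
}

.saltDonorAtoms <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
.saltAcceptorAtoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Salt bridges of one frame
#'
#' A salt bridge is recorded when any nitrogen of a positively charged
#' side chain (Arg NE/NH1/NH2, Lys NZ; histidine excluded, treated
#' neutral) lies within \code{dCut} of any carboxylate oxygen of an
#' aspartate or glutamate. The closest N-O pair per residue pair is
#' reported.
#'
#' @inheritParams findHbonds
#' @param dCut N-O distance cut-off (Angstrom, default 4.0).
#' @return contact-record data.frame (angle is NA).
#' @export
findSaltBridges <- function(coords, topo, dCut = 4.0) {
  ctx <- atomContext(topo)
  don <- which(mapply(function(rn, an)
    rn %in% names(.saltDonorAtoms) && an %in% .saltDonorAtoms[[rn]],
    ctx$resname, ctx$name))
  acc <- which(mapply(function(rn, an)
    rn %in% names(.saltAcceptorAtoms) && an %in% .saltAcceptorAtoms[[rn]],
    ctx$resname, ctx$name))
  rec <- list()
  if (length(don) && length(acc)) {
    pairs <- expand.grid(d = unique(ctx$resindex[don]),
                         a = unique(ctx$resindex[acc]))
    for (p in seq_len(nrow(pairs))) {
      a1 <- don[ctx$resindex[don] == pairs$d[p]]
      a2 <- acc[ctx$resindex[acc] == pairs$a[p]]
      best <- c(NA_integer_, NA_integer_, Inf)
      for (q in a1) {
        dd <- sqrt(rowSums(sweep(coords[a2, , drop = FALSE], 2,
                                 coords[q, ])^2))
        if (min(dd) < best[3]) best <- c(q, a2[which.min(dd)], min(dd))
      }
      if (best[3] < dCut) {
        q <- best[1]; r2 <- best[2]
        rec[[length(rec) + 1L]] <- data.frame(
          type = "salt_bridge", chainD = ctx$chain[q],
          resnoD = ctx$resno[q], resD = ctx$resname[q], atomD = ctx$name[q],
          chainA = ctx$chain[r2], resnoA = ctx$resno[r2],
          resA = ctx$resname[r2], atomA = ctx$name[r2],
          distance_A = best[3], angle_deg = NA_real_)
      }
    }
  }
  bindContactRecords(rec)
}

#' Inter-chain interface contacts
#'
#' Runs the three detectors and keeps only contacts crossing the two
#' named chains. A residue pair may legitimately appear both as a salt
#' bridge and as a hydrogen bond; the \code{summary} therefore also
#' reports the deduplicated residue-pair count (the "number of
#' noncovalent contacts").
#'
#' @inheritParams findHbonds
#' @param chainA,chainB the two chain identifiers.
#' @param hbondCut,angleCut,saltCut,hydroCut detection cut-offs.
#' @param idealizeH passed to [findHbonds()]; H-bond detection is skipped
#'   when the frame carries no hydrogens and idealisation is off.
#' @return list with \code{records} (typed contact rows) and
#'   \code{summary} (counts by type plus \code{residue_pairs}).
#' @export
interfaceContacts <- function(coords, topo, chainA, chainB,
                              hbondCut = 3.6, angleCut = 120,
                              saltCut = 4.0, hydroCut = 4.0,
                              idealizeH = FALSE) {
  ctx <- atomContext(topo)
  if (!all(c(chainA, chainB) %in% ctx$chain))
    stop("unknown chain id(s)")
  hb <- if (any(ctx$element == "H") || idealizeH)
    findHbonds(coords, topo, hbondCut, angleCut, idealizeH)
  else bindContactRecords(list())
  recs <- rbind(hb,
                findSaltBridges(coords, topo, saltCut),
                findHydrophobic(coords, topo, hydroCut))
  cross <- (recs$chainD == chainA & recs$chainA == chainB) |
    (recs$chainD == chainB & recs$chainA == chainA)
  recs <- recs[cross, , drop = FALSE]
  key <- apply(recs, 1, function(r)
    paste(sort(c(paste(r["chainD"], r["resnoD"]),
                 paste(r["chainA"], r["resnoA"]))), collapse = "|"))
  list(records = recs,
       summary = c(as.list(table(recs$type)),
                   residue_pairs = length(unique(key))))
}

#' Residue-pair contact occupancy map
#'
#' Fraction of sampled frames in which each residue pair is linked by
#' any of the requested detectors; symmetric with entries in [0, 1].
#'
#' @param traj a \linkS4class{Trajectory} (or a single-frame one).
#' @param detectors subset of \code{c("hbond", "salt", "hydrophobic")}.
#' @param stride sample every \code{stride}-th frame (default 1).
#' @param ... cut-off arguments forwarded to the detectors.
#' @return residue x residue occupancy matrix with \code{chain:resno}
#'   dimnames.
#' @export
contactMap <- function(traj, detectors = c("hbond", "salt", "hydrophobic"),
                       stride = 1L, ...) {
  topo <- traj@topology
  nRes <- nrow(topo@residues)
  lab <- paste0(topo@residues$chain, ":", topo@residues$resno)
  frames <- seq(1L, nFrames(traj), by = stride)
  acc <- matrix(0, nRes, nRes, dimnames = list(lab, lab))
  dots <- list(...)
  hasH <- any(toupper(topo@atoms$element) == "H")
  for (f in frames) {
    co <- frameCoords(traj, f)
    recs <- list()
    if ("hbond" %in% detectors && hasH)
      recs <- c(recs, list(findHbonds(co, topo)))
    if ("salt" %in% detectors)
      recs <- c(recs, list(findSaltBridges(co, topo)))
    if ("hydrophobic" %in% detectors)
      recs <- c(recs, list(findHydrophobic(co, topo)))
    recs <- do.call(rbind, recs)
    hit <- matrix(FALSE, nRes, nRes)
    if (!is.null(recs) && nrow(recs)) {
      ri <- match(paste0(recs$chainD, ":", recs$resnoD), lab)
      rj <- match(paste0(recs$chainA, ":", recs$resnoA), lab)
      for (k in seq_along(ri)) {
        hit[ri[k], rj[k]] <- TRUE
        hit[rj[k], ri[k]] <- TRUE
      }
    }
    acc <- acc + hit
  }
  acc / length(frames)
}

#' Residues with no intra-molecular side-chain contacts
#'
#' A geometric proxy for protrusion: residues whose side chains take part
#' in zero intra-molecular contacts at the configured cut-offs, labelled
#' by physico-chemical class. This is not a solvent-accessible-surface
#' computation.
#'
#' @inheritParams findHbonds
#' @param ... cut-offs forwarded to the detectors.
#' @return data.frame with \code{chain}, \code{resno}, \code{resname},
#'   \code{class}.
#' @export
exposedResidues <- function(coords, topo, ...) {
  hasH <- any(toupper(topo@atoms$element) == "H")
  recs <- rbind(if (hasH) findHbonds(coords, topo, ...) else
                  bindContactRecords(list()),
                findSaltBridges(coords, topo),
                findHydrophobic(coords, topo))
  busy <- unique(c(paste(recs$chainD, recs$resnoD),
                   paste(recs$chainA, recs$resnoA)))
  r <- topo@residues
  free <- !(paste(r$chain, r$resno) %in% busy)
  cls <- classifySafely(r$resname)
  data.frame(chain = r$chain[free], resno = r$resno[free],
             resname = r$resname[free], class = cls[free])
}
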