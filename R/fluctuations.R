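#' Least-squares superposition (Kabsch fit)
#'
#' Optimal proper rotation + translation minimising the RMSD of the mobile
#' coordinates onto the reference over the masked atoms. Reflections are
#' excluded, preserving chirality.
#'
#' @param mobile N x 3 coordinate matrix to move.
#' @param ref N x 3 reference coordinates.
#' @param mask atom indices (or selection string resolved elsewhere) used
#'   for the fit; default all atoms. At least 3 non-collinear atoms.
#' @return list with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length 3, Angstrom) and \code{rmsd} (Angstrom) over the mask. Apply
#'   with \code{coords \%*\% rotation + translation}.
#' @examples
#' ref <- matrix(rnorm(30), 10, 3)
#' superpose(ref + 5, ref)$rmsd  # pure translation: 0
#' @export
superpose <- function(mobile, ref, mask = seq_len(nrow(ref))) {
  rigidFit(mobile, ref, mask)
}

#' Per-frame RMSD series with separate fit and measure masks
#'
#' Each frame is least-squares fitted to the reference frame on
#' \code{fitMask}, then the RMSD is measured on \code{measureMask}. With
#' equal masks this is the standard fitted RMSD; with a fit on one domain
#' and measurement on another the series captures the rigid-body
#' displacement of the measured domain relative to the fitted one.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param reference reference frame index (default 1, the initial model).
#' @param fitMask,measureMask selection strings or index vectors;
#'   \code{measureMask} defaults to \code{fitMask}.
#' @return data.frame with \code{frame}, \code{time_ps}, \code{rmsd_A}.
#' @export
rmsdSeries <- function(traj, reference = 1L, fitMask = NULL,
                       measureMask = NULL) {
  topo <- traj@topology
  fm <- resolveMask(topo, fitMask)
  mm <- if (is.null(measureMask)) fm else resolveMask(topo, measureMask)
  ref <- frameCoords(traj, reference)
  nF <- nFrames(traj)
  out <- numeric(nF)
  for (f in seq_len(nF)) {
    out[f] <- fittedRmsd(frameCoords(traj, f), ref, fm, mm)
  }
  data.frame(frame = seq_len(nF), time_ps = traj@timestamps, rmsd_A = out)
}

## Fit every frame of a coordinate array to reference coordinates on the
## masked atoms; returns the array of aligned coordinates (all atoms).
fitFrames <- function(coordsArr, ref, maskRows) {
  nF <- dim(coordsArr)[1]
  out <- coordsArr
  for (f in seq_len(nF)) {
    x <- matrix(coordsArr[f, , ], ncol = 3)
    out[f, , ] <- applyRigid(x, rigidFit(x, ref, maskRows))
  }
  out
}

#' Root-mean-square fluctuation profile
#'
#' Frames are fitted to the chosen reference conformation on the mask
#' before accumulating per-atom fluctuations
#' \eqn{\sqrt{\langle|\Delta r_i|^2\rangle}}. With
#' \code{reference = "mean"} frames are first fitted to the initial
#' conformation, the time-mean structure is formed and frames are re-fitted
#' to it in a single pass (no fixed-point iteration).
#'
#' @param traj a \linkS4class{Trajectory} with at least 2 frames.
#' @param mask atoms to fit and report on (default all).
#' @param reference \code{"mean"} (default) or \code{"initial"}.
#' @return data.frame with \code{atom}, \code{residue}, \code{resno},
#'   \code{rmsf_A}.
#' @export
rmsfProfile <- function(traj, mask = NULL,
                        reference = c("mean", "initial")) {
  reference <- match.arg(reference)
  if (nFrames(traj) < 2L) stop("RMSF needs at least 2 frames")
  topo <- traj@topology
  rows <- resolveMask(topo, mask)
  sub <- traj@coords[, rows, , drop = FALSE]
  ref0 <- matrix(sub[1, , ], ncol = 3)
  fitted <- fitFrames(sub, ref0, seq_along(rows))
  refc <- ref0
  if (reference == "mean") {
    refc <- apply(fitted, c(2, 3), mean)
    fitted <- fitFrames(fitted, refc, seq_along(rows))
    refc <- apply(fitted, c(2, 3), mean)
  }
  dev <- sweep(fitted, c(2, 3), refc)
  ## dev dims: F x n x 3; per-atom mean over frames of the squared norm
  msf <- sapply(seq_along(rows), function(i)
    mean(rowSums(matrix(dev[, i, ], ncol = 3)^2)))
  res <- topo@residues[topo@atoms$resindex[rows], ]
  data.frame(atom = rows, residue = res$resname, resno = res$resno,
             rmsf_A = sqrt(msf))
}

#' Retain atoms below an RMSF threshold
#'
#' Implements the exclusion of highly fluctuating residues: atoms with an
#' RMSF below the threshold are retained; the number excluded is attached
#' as attribute \code{"excluded"}.
#'
#' @param profile result of [rmsfProfile()].
#' @param threshold exclusion threshold in Angstrom (default 4).
#' @return integer mask of retained atom indices, with attribute
#'   \code{excluded} (count of atoms dropped).
#' @export
highFluctuationMask <- function(profile, threshold = 4.0) {
  keep <- profile$atom[profile$rmsf_A < threshold]
  out <- as.integer(keep)
  attr(out, "excluded") <- nrow(profile) - length(keep)
  out
}
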