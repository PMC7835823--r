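#' Covariance model of fitted coordinates
#'
#' Frames are least-squares fitted to the reference conformation on the
#' mask; the population (1/F) covariance of the fitted coordinates is then
#' accumulated, \eqn{c_{ij} = \langle (x_i - \langle x_i\rangle)(x_j -
#' \langle x_j\rangle) \rangle}, with averages over frames.
#'
#' @param traj a \linkS4class{Trajectory} with F >= 2 frames.
#' @param mask atoms entering the model (default all).
#' @param reference \code{"mean"} (default) or \code{"initial"} fitting
#'   reference; the mean reference is built by one fit-to-initial pass
#'   followed by one fit-to-mean pass.
#' @param fit set \code{FALSE} to skip the superposition (coordinates are
#'   used as recorded).
#' @return a \linkS4class{CovarianceModel} (eigensystem unpopulated; see
#'   [pcaModes()]).
#' @export
covarianceModel <- function(traj, mask = NULL,
                            reference = c("mean", "initial"), fit = TRUE) {
  reference <- match.arg(reference)
  if (nFrames(traj) < 2L) stop("covariance needs at least 2 frames")
  rows <- resolveMask(traj@topology, mask)
  sub <- traj@coords[, rows, , drop = FALSE]
  if (fit) {
    ref0 <- matrix(sub[1, , ], ncol = 3)
    sub <- fitFrames(sub, ref0, seq_along(rows))
    if (reference == "mean") {
      sub <- fitFrames(sub, apply(sub, c(2, 3), mean), seq_along(rows))
    }
  }
  nF <- dim(sub)[1]
  ## X: F x 3n matrix, coordinate order (x1,y1,z1,x2,...)
  X <- matrix(NA_real_, nF, 3 * length(rows))
  for (f in seq_len(nF)) X[f, ] <- as.vector(t(matrix(sub[f, , ], ncol = 3)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nF
  obj <- new("CovarianceModel")
  obj@C <- (C + t(C)) / 2
  obj@mean <- mu
  obj@mask <- as.integer(rows)
  obj@reference <- reference
  validObject(obj)
  obj
}

#' Diagonalise a covariance model
#'
#' Eigendecomposition \eqn{C = V \Lambda V^T} with eigenvalues sorted in
#' decreasing order; the leading eigenvectors are the principal components
#' of the collective motion.
#'
#' @param model a \linkS4class{CovarianceModel}.
#' @return the model with \code{evalues}/\code{evectors} populated.
#' @export
pcaModes <- function(model) {
  stopifnot(is(model, "CovarianceModel"))
  e <- eigen(model@C, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  model@evalues <- pmax(e$values[ord], 0)
  model@evectors <- e$vectors[, ord, drop = FALSE]
  validObject(model)
  model
}

#' Cumulative variance fraction of the first m modes
#'
#' @param model a diagonalised \linkS4class{CovarianceModel}.
#' @param m number of leading modes.
#' @return fraction in [0, 1].
#' @export
cumulativeVariance <- function(model, m) {
  if (m <= 0) stop("m must be positive")
  ev <- eigenvalues(model)
  if (!length(ev)) stop("call pcaModes() first")
  m <- min(m, length(ev))
  sum(ev[seq_len(m)]) / sum(ev)
}

#' Project trajectory frames onto principal components
#'
#' Frames are fitted exactly as in the model construction and projected on
#' the first m eigenvectors: scores \eqn{V^T (x - \langle x\rangle)}.
#'
#' @param traj the trajectory (same topology/mask as the model).
#' @param model a diagonalised \linkS4class{CovarianceModel}.
#' @param m number of components (default 2).
#' @return data.frame with \code{frame}, \code{time_ps} and score columns
#'   \code{PC1}, ..., \code{PCm}; score variance along component i
#'   approximates eigenvalue i.
#' @export
projectFrames <- function(traj, model, m = 2L) {
  rows <- model@mask
  if (any(rows > nAtoms(traj))) stop("mask does not fit this trajectory")
  if (!length(model@evalues)) stop("call pcaModes() first")
  sub <- traj@coords[, rows, , drop = FALSE]
  ref0 <- matrix(sub[1, , ], ncol = 3)
  sub <- fitFrames(sub, ref0, seq_along(rows))
  if (model@reference == "mean")
    sub <- fitFrames(sub, apply(sub, c(2, 3), mean), seq_along(rows))
  nF <- dim(sub)[1]
  m <- min(m, ncol(model@evectors))
  sc <- matrix(NA_real_, nF, m)
  for (f in seq_len(nF)) {
    x <- as.vector(t(matrix(sub[f, , ], ncol = 3)))
    sc[f, ] <- crossprod(model@evectors[, seq_len(m), drop = FALSE],
                         x - model@mean)
  }
  out <- data.frame(frame = seq_len(nF), time_ps = traj@timestamps)
  colnames(sc) <- paste0("PC", seq_len(m))
  cbind(out, as.data.frame(sc))
}

#' Dynamic cross-correlation matrix
#'
#' Normalised covariance of per-atom displacement vectors,
#' \eqn{CC_{ij} = \langle \Delta r_i^T \Delta r_j\rangle /
#' (\langle\Delta r_i^T\Delta r_i\rangle
#'  \langle\Delta r_j^T\Delta r_j\rangle)^{1/2}}, in [-1, 1]. Frames are
#' fitted on \code{fitMask} (default: the measured mask) before the
#' displacements from the mean are formed; fitting on a separate rigid
#' domain mirrors the transmembrane-domain reference convention. Atoms
#' with zero variance get coefficient 0 with a warning.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param mask atoms whose motion is correlated (default all).
#' @param fitMask atoms used for the superposition (default \code{mask}).
#' @return symmetric matrix with unit diagonal (rows/cols named by atom
#'   index).
#' @export
crossCorrelation <- function(traj, mask = NULL, fitMask = NULL) {
  topo <- traj@topology
  rows <- resolveMask(topo, mask)
  frows <- if (is.null(fitMask)) rows else resolveMask(topo, fitMask)
  refAll <- frameCoords(traj, 1L)
  nF <- nFrames(traj)
  n <- length(rows)
  disp <- array(NA_real_, dim = c(nF, n, 3))
  for (f in seq_len(nF)) {
    x <- frameCoords(traj, f)
    ft <- rigidFit(x, refAll, frows)
    disp[f, , ] <- applyRigid(x[rows, , drop = FALSE], ft)
  }
  mu <- apply(disp, c(2, 3), mean)
  disp <- sweep(disp, c(2, 3), mu)
  flat <- matrix(disp, nrow = nF)      # F x (n*3), column blocks per axis
  ## inner products <dri . drj> averaged over frames
  g <- (crossprod(flat[, seq_len(n)]) +
        crossprod(flat[, n + seq_len(n)]) +
        crossprod(flat[, 2 * n + seq_len(n)])) / nF
  v <- diag(g)
  zero <- v <= 1e-24
  if (any(zero)) warning(sum(zero), " zero-variance atom(s): CC set to 0")
  denom <- sqrt(pmax(v, 1e-300))
  cc <- g / tcrossprod(denom)
  cc[zero, ] <- 0
  cc[, zero] <- 0
  diag(cc)[!zero] <- 1
  cc <- pmin(pmax(cc, -1), 1)
  dimnames(cc) <- list(rows, rows)
  cc
}

#' Per-atom displacement arrows of a PCA mode
#'
#' Eigenvector components reshaped to one 3-vector per atom and scaled by
#' the square root of the eigenvalue (an RMS amplitude in Angstrom); atoms
#' moving less than the amplitude threshold are omitted.
#'
#' @param model a diagonalised \linkS4class{CovarianceModel}.
#' @param mode 1-based mode index.
#' @param amplitudeThreshold minimum arrow length kept (Angstrom,
#'   default 2).
#' @return data.frame with \code{atom}, \code{dx}, \code{dy}, \code{dz},
#'   \code{amplitude_A}.
#' @export
modeArrows <- function(model, mode = 1L, amplitudeThreshold = 2.0) {
  ev <- eigenvalues(model)
  if (!length(ev)) stop("call pcaModes() first")
  if (mode < 1L || mode > length(ev)) stop("no such mode: ", mode)
  v <- matrix(model@evectors[, mode], ncol = 3, byrow = TRUE) * sqrt(ev[mode])
  amp <- sqrt(rowSums(v^2))
  keep <- which(amp >= amplitudeThreshold)
  data.frame(atom = model@mask[keep], dx = v[keep, 1], dy = v[keep, 2],
             dz = v[keep, 3], amplitude_A = amp[keep])
}
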