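#' @import methods
NULL

#' Topology: atoms, residues and optional bonds
#'
#' A \code{Topology} carries the chemical identity of a structure: one row
#' per atom (name, element, index of the residue it belongs to) and one row
#' per residue (3-letter name, author residue number, chain identifier).
#' Coordinates live in \linkS4class{Trajectory}.
#'
#' @slot atoms data.frame with columns \code{name}, \code{element},
#'   \code{resindex} (integer row index into \code{residues}).
#' @slot residues data.frame with columns \code{resname}, \code{resno},
#'   \code{chain}.
#' @slot bonds optional two-column integer matrix of atom-index pairs.
#' @seealso [topology()], [selectAtoms()], [readStructure()]
#' @exportClass Topology
setClass("Topology",
  representation(atoms = "data.frame", residues = "data.frame",
                 bonds = "matrix"),
  prototype(bonds = matrix(integer(0), ncol = 2)))

setValidity("Topology", function(object) {
  a <- object@atoms
  r <- object@residues
  msgs <- character(0)
  if (nrow(a) == 0L) msgs <- c(msgs, "topology must contain at least one atom")
  need <- c("name", "element", "resindex")
  if (!all(need %in% names(a)))
    msgs <- c(msgs, "atoms must have columns name, element, resindex")
  needr <- c("resname", "resno", "chain")
  if (!all(needr %in% names(r)))
    msgs <- c(msgs, "residues must have columns resname, resno, chain")
  if (length(msgs) == 0L) {
    if (any(a$resindex < 1L | a$resindex > nrow(r)))
      msgs <- c(msgs, "every atom must reference an existing residue")
    key <- paste(r$chain, r$resno)
    if (anyDuplicated(key))
      msgs <- c(msgs, "residue numbers must be unique within a chain")
  }
  if (length(msgs)) msgs else TRUE
})

#' Trajectory: frames of Cartesian coordinates over a Topology
#'
#' Coordinates are stored as an \code{F x N x 3} array in Angstrom with one
#' timestamp (ps) per frame; \code{N} must equal the topology atom count and
#' timestamps must be strictly increasing.
#'
#' @slot coords numeric array, frames x atoms x 3 (Angstrom).
#' @slot timestamps numeric vector of frame times (ps), strictly increasing.
#' @slot topology the associated \linkS4class{Topology}.
#' @seealso [trajectory()], [frameCoords()], [rmsdSeries()]
#' @exportClass Trajectory
setClass("Trajectory",
  representation(coords = "array", timestamps = "numeric",
                 topology = "Topology"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  msgs <- character(0)
  if (length(d) != 3L || d[3] != 3L)
    msgs <- c(msgs, "coords must be a frames x atoms x 3 array")
  else {
    if (d[1] < 1L) msgs <- c(msgs, "a trajectory needs at least one frame")
    if (d[2] != nrow(object@topology@atoms))
      msgs <- c(msgs, "atom count must match the topology")
    if (length(object@timestamps) != d[1])
      msgs <- c(msgs, "one timestamp per frame required")
    else if (d[1] > 1L && any(diff(object@timestamps) <= 0))
      msgs <- c(msgs, "timestamps must be strictly increasing")
  }
  if (length(msgs)) msgs else TRUE
})

#' Covariance model of fitted coordinate fluctuations
#'
#' Holds the time-average structure, the (population) covariance matrix of
#' the fitted coordinates and, after diagonalisation, its eigenvalues
#' (descending, in squared Angstrom) and orthonormal eigenvectors.
#'
#' @slot C covariance matrix, 3N x 3N (Angstrom^2).
#' @slot mean length-3N vector: mean fitted coordinates.
#' @slot evalues eigenvalues in decreasing order (Angstrom^2); empty until
#'   [pcaModes()] is called.
#' @slot evectors matrix of eigenvector columns matching \code{evalues}.
#' @slot mask integer atom indices the model was built on.
#' @slot reference \code{"mean"} or \code{"initial"} fitting reference.
#' @seealso [covarianceModel()], [pcaModes()], [cumulativeVariance()]
#' @exportClass CovarianceModel
setClass("CovarianceModel",
  representation(C = "matrix", mean = "numeric", evalues = "numeric",
                 evectors = "matrix", mask = "integer",
                 reference = "character"),
  prototype(C = matrix(0, 0, 0), mean = numeric(0), evalues = numeric(0),
            evectors = matrix(0, 0, 0), mask = integer(0),
            reference = NA_character_))

setValidity("CovarianceModel", function(object) {
  if (nrow(object@C) == 0L) return(TRUE)   # unfilled prototype
  msgs <- character(0)
  if (nrow(object@C) != ncol(object@C))
    msgs <- c(msgs, "covariance must be square")
  if (max(abs(object@C - t(object@C))) > 1e-8 * max(1, max(abs(object@C))))
    msgs <- c(msgs, "covariance must be symmetric")
  if (length(object@evalues)) {
    rel <- abs(sum(object@evalues) - sum(diag(object@C))) /
      max(sum(diag(object@C)), .Machine$double.eps)
    if (rel > 1e-8)
      msgs <- c(msgs, "eigenvalues must conserve the covariance trace")
    vtv <- crossprod(object@evectors)
    if (max(abs(vtv - diag(nrow(vtv)))) > 1e-8)
      msgs <- c(msgs, "eigenvectors must be orthonormal")
  }
  if (length(msgs)) msgs else TRUE
})

#' Ensemble-based clustering model
#'
#' Result of random reference harvesting at cut-off \code{r} followed by
#' nearest-reference RMSD assignment: reference frame ids, the per-frame
#' assignment, cluster populations (percent of frames) and, for merged
#' runs, the source trajectory of every frame.
#'
#' @slot cutoff harvesting cut-off r (Angstrom).
#' @slot refFrames integer frame ids of the reference structures.
#' @slot assignment integer cluster id per frame (1-based, ordered as
#'   \code{refFrames}).
#' @slot populations percent of frames per cluster (sums to 100).
#' @slot source integer source-trajectory id per frame (all 1 for a single
#'   trajectory).
#' @slot seed the seed used for reference harvesting.
#' @seealso [harvestReferences()], [assignClusters()], [clusterScan()]
#' @exportClass ClusterModel
setClass("ClusterModel",
  representation(cutoff = "numeric", refFrames = "integer",
                 assignment = "integer", populations = "numeric",
                 source = "integer", seed = "integer"))

setValidity("ClusterModel", function(object) {
  msgs <- character(0)
  k <- length(object@refFrames)
  if (k == 0L) msgs <- c(msgs, "at least one reference required")
  if (any(object@assignment < 1L | object@assignment > k))
    msgs <- c(msgs, "assignments must index the reference set")
  if (abs(sum(object@populations) - 100) > 1e-9)
    msgs <- c(msgs, "populations must sum to 100")
  if (length(object@source) != length(object@assignment))
    msgs <- c(msgs, "one source id per frame required")
  if (length(msgs)) msgs else TRUE
})

#' Pre-shape: a landmark configuration modulo translation and scale
#'
#' k landmarks in 3-D, centred at the origin and scaled to unit centroid
#' size (Frobenius norm 1). Rotation is quotiented out later, by the
#' Procrustes optimisation inside [kendallDistance()]; the shape manifold
#' for k landmarks in 3-D has dimension 3k - 7.
#'
#' @slot landmarks k x 3 matrix, centred, unit Frobenius norm.
#' @seealso [preshape()], [kendallDistance()], [frechetMean()]
#' @exportClass PreShape
setClass("PreShape", representation(landmarks = "matrix"))

setValidity("PreShape", function(object) {
  x <- object@landmarks
  msgs <- character(0)
  if (ncol(x) != 3L) msgs <- c(msgs, "landmarks must be k x 3")
  if (nrow(x) < 3L) msgs <- c(msgs, "need at least 3 landmarks")
  if (vnorm(colMeans(x)) > 1e-8) msgs <- c(msgs, "centroid must be at origin")
  if (abs(sqrt(sum(x^2)) - 1) > 1e-8)
    msgs <- c(msgs, "centroid size must be 1")
  if (length(msgs)) msgs else TRUE
})
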