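#' Normalise a landmark configuration to a pre-shape
#'
#' Centres the k x 3 configuration at the origin and scales it to unit
#' centroid size (Frobenius norm 1), removing translation and scale; the
#' remaining rotation freedom is quotiented out inside
#' [kendallDistance()].
#'
#' @param x k x 3 landmark matrix (k >= 3) or a \linkS4class{PreShape}
#'   (returned unchanged).
#' @return a \linkS4class{PreShape}.
#' @export
preshape <- function(x) {
  if (is(x, "PreShape")) return(x)
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 landmarks")
  x <- sweep(x, 2, colMeans(x))
  s <- sqrt(sum(x^2))
  if (s < 1e-12) stop("degenerate shape: all landmarks coincide")
  new("PreShape", landmarks = x / s)
}

#' Kendall geodesic distance between two shapes
#'
#' The Riemannian distance on the shape manifold: the arc-cosine of the
#' Procrustes alignment score after optimising over proper rotations
#' only (reflections are excluded; molecular handedness is meaningful),
#' in radians on the unit pre-shape sphere.
#'
#' @param a,b \linkS4class{PreShape} objects (or raw k x 3 matrices)
#'   sharing k.
#' @return geodesic distance in radians.
#' @export
kendallDistance <- function(a, b) {
  A <- landmarks(preshape(a))
  B <- landmarks(preshape(b))
  if (nrow(A) != nrow(B)) stop("landmark counts differ")
  ## chordal form 2*asin(||A - BR||/2): equals acos of the alignment
  ## score but keeps full precision for nearly identical shapes
  chord <- sqrt(sum((A - procrustesRotate(A, B))^2))
  2 * asin(max(0, min(1, chord / 2)))
}

## Max over proper rotations R of <A, B R> for unit-norm A, B.
procrustesScore <- function(A, B) {
  m <- crossprod(B, A)                 # 3 x 3
  sv <- svd(m)
  s <- sv$d
  if (det(sv$u %*% t(sv$v)) < 0) s[3] <- -s[3]
  sum(s)
}

## Rotate B optimally onto A (proper rotation), both k x 3.
procrustesRotate <- function(A, B) {
  m <- crossprod(B, A)
  sv <- svd(m)
  d <- sign(det(sv$u %*% t(sv$v)))
  B %*% (sv$u %*% diag(c(1, 1, d)) %*% t(sv$v))
}

#' Pairwise Kendall distance matrix
#'
#' @param shapes list of \linkS4class{PreShape} objects with a common k.
#' @return symmetric zero-diagonal matrix of geodesic distances
#'   (radians).
#' @export
shapeDistanceMatrix <- function(shapes) {
  shapes <- lapply(shapes, preshape)
  k <- unique(vapply(shapes, function(s) nrow(landmarks(s)), integer(1)))
  if (length(k) != 1L) stop("mixed landmark counts")
  n <- length(shapes)
  d <- matrix(0, n, n)
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- kendallDistance(shapes[[i]], shapes[[j]])
  d
}

#' Metric multidimensional scaling by stress majorisation
#'
#' Embeds points in a low-dimensional Euclidean space so that pairwise
#' embedded distances reproduce the given (e.g. Kendall) distances,
#' minimising the raw stress \eqn{\sum_{i\ne j}(d_{ij} - \|x_i -
#' x_j\|)^2} by SMACOF majorisation from a classical-scaling
#' (Torgerson) start; the majorisation guarantees a non-increasing
#' stress sequence.
#'
#' @param d symmetric distance matrix.
#' @param dim embedding dimension (2 or 3 typical).
#' @param seed seed for the tie-breaking random perturbation applied when
#'   the classical start is degenerate.
#' @param maxIter iteration cap (default 500).
#' @param tol relative stress-decrease convergence tolerance
#'   (default 1e-12).
#' @return list with \code{points} (n x dim), \code{stress} (final raw
#'   stress), \code{iterations} and \code{seed}.
#' @export
mdsEmbed <- function(d, dim = 2L, seed = 1L, maxIter = 500L, tol = 1e-12) {
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  n <- nrow(d)
  X <- suppressWarnings(stats::cmdscale(d, k = dim))
  if (ncol(X) < dim) X <- cbind(X, matrix(0, n, dim - ncol(X)))
  if (all(abs(X) < 1e-12)) {
    rng <- localRng(seed)
    X <- matrix(rng$norm(n * dim) * 1e-6, n, dim)
  }
  stress <- function(X) {
    e <- as.matrix(stats::dist(X))
    sum((d - e)^2) / 2
  }
  s0 <- stress(X)
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    e <- as.matrix(stats::dist(X))
    ratio <- ifelse(e > 1e-12, d / e, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n              # Guttman transform
    s1 <- stress(X)
    if (s0 - s1 <= tol * max(s0, 1e-300)) {
      s0 <- s1
      break
    }
    s0 <- s1
  }
  list(points = X, stress = s0, iterations = iter, seed = seed)
}

## Sphere log/exp maps on the unit pre-shape sphere (matrices treated as
## unit vectors under the Frobenius inner product).
sphereLog <- function(mu, x) {
  ip <- max(-1, min(1, sum(mu * x)))
  th <- acos(ip)
  if (th < 1e-12) return(x * 0)
  (x - ip * mu) * th / sin(th)
}

sphereExp <- function(mu, v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-15) return(mu)
  cos(nv) * mu + sin(nv) * v / nv
}

#' Frechet mean of a set of shapes
#'
#' The shape minimising the sum of squared Kendall geodesic distances,
#' computed by iterative tangent-space averaging: each shape is
#' Procrustes-aligned to the current mean, lifted by the sphere log map,
#' the tangent vectors are averaged and the mean is updated by the exp
#' map. In the flat limit (tiny dispersion) this is the ordinary
#' arithmetic mean; for two shapes it is the geodesic midpoint.
#'
#' @param shapes nonempty list of \linkS4class{PreShape} objects.
#' @param tol gradient-norm convergence tolerance (default 1e-8).
#' @param maxIter iteration cap (default 1000).
#' @return list with \code{mean} (\linkS4class{PreShape}),
#'   \code{iterations} and \code{residual} (final gradient norm).
#' @export
frechetMean <- function(shapes, tol = 1e-8, maxIter = 1000L) {
  stopifnot(length(shapes) >= 1L)
  shapes <- lapply(shapes, preshape)
  mu <- landmarks(shapes[[1]])
  iter <- 0L
  repeat {
    iter <- iter + 1L
    tang <- matrix(0, nrow(mu), 3)
    for (s in shapes) {
      b <- procrustesRotate(mu, landmarks(s))
      tang <- tang + sphereLog(mu, b)
    }
    tang <- tang / length(shapes)
    res <- sqrt(sum(tang^2))
    mu <- sphereExp(mu, tang)
    mu <- landmarks(preshape(mu))     # re-project against round-off
    if (res < tol) break
    if (iter >= maxIter)
      stop("Frechet mean did not converge after ", maxIter,
           " iterations (residual ", format(res), ")")
  }
  list(mean = new("PreShape", landmarks = mu), iterations = iter,
       residual = res)
}

## Labelled equilateral triangle pre-shape (the disk centre) and a fixed
## orthonormal tangent basis at it, defining the longitude convention
## (vertex 1 defines the phi = 0 meridian).
.diskPole <- function() {
  eq <- rbind(c(1, 0, 0), c(-1 / 2, sqrt(3) / 2, 0),
              c(-1 / 2, -sqrt(3) / 2, 0))
  landmarks(preshape(eq))
}

.diskTangentBasis <- function(mu) {
  ## two planar deformations of the labelled equilateral triangle
  t1 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 0))      # stretch vertex 1-2
  t2 <- rbind(c(0, 1, 0), c(0, -1, 0), c(0, 0, 0))
  orth <- function(v) {
    v <- v - sum(v * mu) * mu
    v / sqrt(sum(v^2))
  }
  b1 <- orth(t1 / sqrt(sum(t1^2)))
  b2 <- t2 / sqrt(sum(t2^2))
  b2 <- b2 - sum(b2 * mu) * mu - sum(b2 * b1) * b1
  b2 <- b2 / sqrt(sum(b2^2))
  list(b1 = b1, b2 = b2)
}

#' Map a triangle shape to Kendall's disk
#'
#' The shape space of 3-D triangles is a hemisphere of radius 1/2 with
#' the equilateral triangle at the pole and the degenerate (collinear)
#' triangles on the equator. The planar disk representation uses polar
#' coordinates \code{(r = sin(theta), phi)} where \code{theta} is the
#' colatitude (twice the unit-sphere Kendall distance from the
#' equilateral pole) and the longitude convention is fixed by the
#' labelled tangent basis at the pole (vertex 1 defines phi = 0).
#'
#' @param triangle a 3-landmark \linkS4class{PreShape} (or 3 x 3 matrix).
#' @return list with \code{r} in [0, 1] (0 = equilateral, 1 = collinear)
#'   and \code{phi} in (-pi, pi].
#' @export
triangleDisk <- function(triangle) {
  s <- preshape(triangle)
  if (nrow(landmarks(s)) != 3L) stop("triangle disk needs exactly k = 3")
  mu <- .diskPole()
  rho <- kendallDistance(s, new("PreShape", landmarks = mu))
  theta <- 2 * rho                    # colatitude on the radius-1/2 sphere
  b <- procrustesRotate(mu, landmarks(s))
  lg <- sphereLog(mu, b)
  tb <- .diskTangentBasis(mu)
  phi <- atan2(sum(lg * tb$b2), sum(lg * tb$b1))
  list(r = min(1, sin(min(theta, pi / 2))), phi = phi)
}

#' Shape trajectory of selected landmarks
#'
#' Extracts the selected landmark atoms from every frame and normalises
#' them to pre-shapes, attaching per-frame metadata (time and the
#' distance between the first and last landmark in the original
#' coordinates, e.g. the S...S distance of a thiol motif). Degenerate
#' frames are skipped with a warning.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param landmarkIdx atom indices of the k landmarks (k >= 3).
#' @return list with \code{shapes} (list of \linkS4class{PreShape}) and
#'   \code{meta} (data.frame with \code{frame}, \code{time_ps},
#'   \code{d_landmark_A}).
#' @export
shapeTrajectory <- function(traj, landmarkIdx) {
  stopifnot(length(landmarkIdx) >= 3L)
  nF <- nFrames(traj)
  shapes <- list()
  meta <- NULL
  skipped <- 0L
  for (f in seq_len(nF)) {
    p <- frameCoords(traj, f)[landmarkIdx, , drop = FALSE]
    s <- tryCatch(preshape(p), error = function(e) NULL)
    if (is.null(s)) {
      skipped <- skipped + 1L
      next
    }
    shapes[[length(shapes) + 1L]] <- s
    meta <- rbind(meta, data.frame(
      frame = f, time_ps = traj@timestamps[f],
      d_landmark_A = vnorm(p[1, ] - p[nrow(p), ])))
  }
  if (skipped > 0L)
    warning(skipped, " degenerate frame(s) skipped in shape trajectory")
  list(shapes = shapes, meta = meta)
}
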