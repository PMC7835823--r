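# Low-level geometric primitives shared across modules. Coordinates are
# plain N x 3 numeric matrices in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

## Angle at vertex b (in degrees) of the path a-b-c.
vecAngle <- function(a, b, c) {
  u <- a - b
  w <- c - b
  cosang <- sum(u * w) / (vnorm(u) * vnorm(w))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

## Signed dihedral a-b-c-d in degrees, in (-180, 180].
dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- crossProd(b1, b2)
  n2 <- crossProd(b2, b3)
  m1 <- crossProd(n1, unitize(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

crossProd <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## Kabsch optimal proper rotation aligning `mobile` onto `ref` (both n x 3,
## already centred). Reflections are excluded: the smallest singular
## direction is flipped when needed so det(R) = +1 (chirality preserved).
kabschRotation <- function(mobile, ref) {
  h <- crossprod(mobile, ref)           # 3 x 3
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  s <- diag(c(1, 1, d))
  sv$u %*% s %*% t(sv$v)
}

## Rigid-body least-squares fit of mobile onto ref over the given rows.
## Returns rotation R, translation t and the attained RMSD such that the
## aligned coordinates are  x %*% R  + t (row-wise).
rigidFit <- function(mobile, ref, rows = seq_len(nrow(ref))) {
  if (length(rows) < 3L)
    stop("degenerate fit: need at least 3 atoms in the fit mask")
  m <- mobile[rows, , drop = FALSE]
  r <- ref[rows, , drop = FALSE]
  if (qr(sweep(m, 2, colMeans(m)))$rank < 2L)
    stop("degenerate fit: fit-mask atoms are collinear")
  cm <- colMeans(m)
  cr <- colMeans(r)
  rot <- kabschRotation(sweep(m, 2, cm), sweep(r, 2, cr))
  tr <- cr - as.vector(cm %*% rot)
  aligned <- m %*% rot + matrix(tr, nrow(m), 3, byrow = TRUE)
  list(rotation = rot, translation = tr,
       rmsd = sqrt(mean(rowSums((aligned - r)^2))))
}

applyRigid <- function(coords, fit) {
  coords %*% fit$rotation + matrix(fit$translation, nrow(coords), 3,
                                   byrow = TRUE)
}

coordRmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

## Fitted RMSD between two coordinate sets: fit on fitRows, measure on
## measureRows (defaults to the fit rows, the standard fitted RMSD).
fittedRmsd <- function(mobile, ref, fitRows = seq_len(nrow(ref)),
                       measureRows = fitRows) {
  ft <- rigidFit(mobile, ref, fitRows)
  coordRmsd(applyRigid(mobile[measureRows, , drop = FALSE], ft),
            ref[measureRows, , drop = FALSE])
}
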