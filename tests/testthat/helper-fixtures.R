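# Fixture builders shared by several test files.

## Well-spread reference C-alpha cloud (reproducible, non-degenerate).
spreadReference <- function(n, seed = 99) {
  set.seed(seed)
  cbind(seq(0, by = 4, length.out = n), rnorm(n, 0, 3), rnorm(n, 0, 3))
}

## Second state at an exact fitted RMSD from the reference, displaced
## along an internal (fit-invariant) mode.
displacedState <- function(ref, rmsdTarget, seed = 3) {
  v <- internalModeBasis(ref, 1, seed = seed)
  dirM <- matrix(v, nrow(ref), 3, byrow = TRUE)
  f <- function(c) {
    ft <- superpose(ref + c * dirM, ref)
    ft$rmsd - rmsdTarget
  }
  c0 <- uniroot(f, c(0, 100 * rmsdTarget))$root
  ref + c0 * dirM
}

## Two-state switching fixture at the study conditions.
twoStateFixture <- function(nframes = 2000, seed = 1,
                            occupancies = c(0.7, 0.3), sep = 8,
                            jitter = 0.3, nAtoms = 10) {
  ref <- spreadReference(nAtoms)
  st2 <- displacedState(ref, sep)
  makeMultistateTrajectory(list(ref, st2), nframes = nframes, seed = seed,
                           occupancies = occupancies, jitter = jitter)
}

## A small multi-frame trajectory around a helix, with rigid noise-free
## frames (for IO and invariance tests).
helixTrajectory <- function(nres = 6, nframes = 3) {
  h <- makeIdealHelix(nres, "alpha")
  co <- frameCoords(h$trajectory)
  arr <- array(NA_real_, c(nframes, nrow(co), 3))
  for (f in seq_len(nframes)) arr[f, , ] <- co + (f - 1) * 0.25
  trajectory(arr, h$topology)
}

## Equilateral / collinear triangle landmark sets.
equilateralTriangle <- function() {
  rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
}

collinearTriangle <- function() {
  rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0))
}
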