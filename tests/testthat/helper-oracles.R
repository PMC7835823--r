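# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: rotations are searched on a grid of Euler angles and
# refined numerically, contacts are re-derived with naive loops.

eulerRot <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

## Brute-force minimal RMSD over proper rotations + translations.
bruteForceRmsd <- function(mobile, ref) {
  m <- sweep(mobile, 2, colMeans(mobile))
  r <- sweep(ref, 2, colMeans(ref))
  obj <- function(p) {
    R <- eulerRot(p[1], p[2], p[3])
    sqrt(mean(rowSums((m %*% R - r)^2)))
  }
  grid <- as.matrix(expand.grid(a = seq(0, 2 * pi, length.out = 7),
                                b = seq(0, pi, length.out = 5),
                                c = seq(0, 2 * pi, length.out = 7)))
  best <- Inf
  bestp <- NULL
  for (i in seq_len(nrow(grid))) {
    v <- obj(grid[i, ])
    if (v < best) {
      best <- v
      bestp <- grid[i, ]
    }
  }
  for (k in 1:3) {
    o <- optim(bestp, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
    bestp <- o$par
  }
  o$value
}

## Brute-force maximal alignment score between unit pre-shape matrices,
## hence the Kendall geodesic distance.
bruteForceKendall <- function(A, B) {
  obj <- function(p) -sum(A * (B %*% eulerRot(p[1], p[2], p[3])))
  grid <- as.matrix(expand.grid(a = seq(0, 2 * pi, length.out = 9),
                                b = seq(0, pi, length.out = 5),
                                c = seq(0, 2 * pi, length.out = 9)))
  best <- Inf
  bestp <- NULL
  for (i in seq_len(nrow(grid))) {
    v <- obj(grid[i, ])
    if (v < best) {
      best <- v
      bestp <- grid[i, ]
    }
  }
  for (k in 1:3) {
    o <- optim(bestp, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000))
    bestp <- o$par
  }
  acos(max(-1, min(1, -o$value)))
}

## Naive re-derivation of all three contact detectors on one frame.
## Returns sorted "type|resnoD|resnoA" keys.
bruteForceContacts <- function(coords, topo) {
  at <- atomTable(topo)
  rs <- residueTable(topo)[at$resindex, ]
  keys <- character(0)
  n <- nrow(at)
  dmat <- as.matrix(dist(coords))
  ## hydrogen bonds
  for (d in seq_len(n)) {
    if (!toupper(at$element[d]) %in% c("N", "O", "S")) next
    hs <- which(toupper(at$element) == "H" & dmat[, d] < 1.3)
    if (!length(hs)) next
    for (a in seq_len(n)) {
      if (a == d || at$resindex[a] == at$resindex[d]) next
      if (!toupper(at$element[a]) %in% c("N", "O", "S")) next
      if (dmat[d, a] >= 3.6) next
      for (h in hs) {
        v1 <- coords[d, ] - coords[h, ]
        v2 <- coords[a, ] - coords[h, ]
        ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
        if (ang >= 120) {
          keys <- c(keys, paste("hbond", rs$resno[d], rs$resno[a], sep = "|"))
          break
        }
      }
    }
  }
  ## salt bridges
  donA <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
  accA <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  for (d in seq_len(n)) {
    rn <- toupper(rs$resname[d])
    if (!rn %in% names(donA) || !toupper(at$name[d]) %in% donA[[rn]]) next
    for (a in seq_len(n)) {
      rn2 <- toupper(rs$resname[a])
      if (!rn2 %in% names(accA) || !toupper(at$name[a]) %in% accA[[rn2]]) next
      if (dmat[d, a] < 4.0)
        keys <- c(keys, paste("salt_bridge", rs$resno[d], rs$resno[a],
                              sep = "|"))
    }
  }
  ## hydrophobic
  hydroRes <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "GLY")
  backbone <- c("N", "CA", "C", "O", "OXT")
  isSide <- function(i) {
    rn <- toupper(rs$resname[i])
    nm <- toupper(at$name[i])
    rn %in% hydroRes && toupper(at$element[i]) != "H" &&
      (!(nm %in% backbone) || (rn == "GLY" && nm == "CA"))
  }
  side <- Filter(isSide, seq_len(n))
  for (i in side) for (j in side) {
    if (at$resindex[i] >= at$resindex[j]) next
    sameChain <- rs$chain[i] == rs$chain[j]
    if (sameChain && abs(rs$resno[i] - rs$resno[j]) <= 1) next
    if (dmat[i, j] < 4.0)
      keys <- c(keys, paste("hydrophobic", rs$resno[i], rs$resno[j],
                            sep = "|"))
  }
  sort(unique(keys))
}

contactKeys <- function(records) {
  if (!nrow(records)) return(character(0))
  sort(unique(paste(records$type, records$resnoD, records$resnoA,
                    sep = "|")))
}

## Random rigid motion (proper rotation + translation) under a local seed.
randomRigid <- function(seed) {
  set.seed(seed)
  p <- runif(3, 0, 2 * pi)
  list(R = eulerRot(p[1], p[2], p[3]), t = runif(3, -20, 20))
}

applyRigidTo <- function(coords, rig) {
  coords %*% rig$R + matrix(rig$t, nrow(coords), 3, byrow = TRUE)
}

rigidMoveTrajectory <- function(traj, rig) {
  arr <- traj@coords
  for (f in seq_len(dim(arr)[1]))
    arr[f, , ] <- applyRigidTo(matrix(traj@coords[f, , ], ncol = 3), rig)
  trajectory(arr, topologyOf(traj), timestamps(traj))
}
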