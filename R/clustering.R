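## Fitted RMSD of every frame in an array against one reference frame's
## coordinates, on the masked rows. Workhorse of the clustering module.
rmsdToRef <- function(coordsArr, refCoords, rows) {
  nF <- dim(coordsArr)[1]
  ref <- refCoords[rows, , drop = FALSE]
  refC <- sweep(ref, 2, colMeans(ref))
  out <- numeric(nF)
  for (f in seq_len(nF)) {
    m <- matrix(coordsArr[f, rows, ], ncol = 3)
    mC <- sweep(m, 2, colMeans(m))
    rot <- kabschRotation(mC, refC)
    out[f] <- coordRmsd(mC %*% rot, refC)
  }
  out
}

#' Randomly harvest cluster reference structures at cut-off r
#'
#' Implements the reference-harvesting step of ensemble-based clustering:
#' a reference frame is drawn uniformly at random from the remaining
#' ensemble, all frames within fitted RMSD r of it (itself included) are
#' removed, and the step repeats until the ensemble is empty. The
#' resulting references are pairwise more than r apart.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param mask atoms used for the fitted RMSD (default all).
#' @param cutoff harvesting cut-off r in Angstrom (> 0).
#' @param seed integer seed for the random draws (mandatory for
#'   reproducibility).
#' @return integer vector of reference frame ids, in harvesting order.
#' @export
harvestReferences <- function(traj, mask = NULL, cutoff, seed) {
  stopifnot(cutoff > 0)
  if (nFrames(traj) < 1L) stop("empty trajectory")
  rows <- resolveMask(traj@topology, mask)
  remaining <- seq_len(nFrames(traj))
  refs <- integer(0)
  rng <- localRng(seed)
  while (length(remaining)) {
    pick <- remaining[rng$int(length(remaining))]
    refs <- c(refs, pick)
    d <- rmsdToRef(traj@coords[remaining, , , drop = FALSE],
                   frameCoords(traj, pick), rows)
    remaining <- remaining[d > cutoff]
  }
  refs
}

## Small deterministic RNG wrapper: isolates the package's draws from the
## caller's RNG state.
localRng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  draw <- function(fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fun()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(int = function(n) draw(function() sample.int(n, 1L)),
       norm = function(n) draw(function() stats::rnorm(n)),
       unif = function(n) draw(function() stats::runif(n)))
}

#' Assign every frame to its nearest reference structure
#'
#' Grouping step of ensemble-based clustering: each frame joins the
#' cluster of the reference with the smallest fitted RMSD (even when that
#' distance exceeds the harvesting cut-off); ties break to the lowest
#' reference index.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param mask atoms used for the fitted RMSD (default all).
#' @param refs reference frame ids from [harvestReferences()] (or user
#'   supplied).
#' @param cutoff the harvesting cut-off, stored in the model (default NA).
#' @param seed the harvesting seed, stored in the model.
#' @param source optional integer source-trajectory id per frame (for
#'   merged runs).
#' @return a \linkS4class{ClusterModel}.
#' @export
assignClusters <- function(traj, mask = NULL, refs, cutoff = NA_real_,
                           seed = NA_integer_, source = NULL) {
  if (!length(refs)) stop("no reference structures supplied")
  rows <- resolveMask(traj@topology, mask)
  nF <- nFrames(traj)
  d <- matrix(NA_real_, nF, length(refs))
  for (k in seq_along(refs))
    d[, k] <- rmsdToRef(traj@coords, frameCoords(traj, refs[k]), rows)
  assign <- apply(d, 1, which.min)      # which.min takes the first tie
  pop <- 100 * tabulate(assign, nbins = length(refs)) / nF
  if (is.null(source)) source <- rep(1L, nF)
  new("ClusterModel", cutoff = as.numeric(cutoff),
      refFrames = as.integer(refs), assignment = as.integer(assign),
      populations = pop, source = as.integer(source),
      seed = as.integer(seed))
}

#' Cluster the trajectory at one cut-off (harvest + assign)
#'
#' @inheritParams harvestReferences
#' @return a \linkS4class{ClusterModel}.
#' @export
clusterTrajectory <- function(traj, mask = NULL, cutoff, seed) {
  refs <- harvestReferences(traj, mask, cutoff, seed)
  assignClusters(traj, mask, refs, cutoff = cutoff, seed = seed)
}

#' Scan clustering over a grid of RMSD cut-offs
#'
#' Default grid 1.6 to 3.0 Angstrom in steps of 0.2. For each cut-off the
#' trajectory is harvested and assigned with a seed derived
#' deterministically from \code{seed}, and the number of clusters plus the
#' cumulative population of the dense clusters (population above
#' \code{densityFloor}) is reported. The randomised algorithm does not
#' guarantee monotone cluster counts across cut-offs.
#'
#' @inheritParams harvestReferences
#' @param cutoffs cut-off grid in Angstrom.
#' @param densityFloor dense-cluster population floor in percent
#'   (default 4).
#' @return data.frame with \code{cutoff_A}, \code{n_clusters},
#'   \code{dense_population_pct}.
#' @export
clusterScan <- function(traj, mask = NULL,
                        cutoffs = seq(1.6, 3.0, by = 0.2), seed = 1L,
                        densityFloor = 4) {
  stopifnot(length(cutoffs) >= 1L)
  out <- lapply(seq_along(cutoffs), function(i) {
    cm <- clusterTrajectory(traj, mask, cutoffs[i], seed + i - 1L)
    pop <- clusterPopulations(cm)
    data.frame(cutoff_A = cutoffs[i], n_clusters = length(pop),
               dense_population_pct = sum(pop[pop > densityFloor]))
  })
  do.call(rbind, out)
}

#' Cluster a merged set of replica trajectories and report composition
#'
#' Trajectories sharing one topology are concatenated, clustered at the
#' given cut-off, and every cluster is decomposed into the percentage of
#' its frames contributed by each source replica.
#'
#' @param trajs list of \linkS4class{Trajectory} objects with identical
#'   topologies.
#' @inheritParams harvestReferences
#' @return list with \code{model} (the \linkS4class{ClusterModel} on the
#'   merged trajectory, frames carrying their source id) and
#'   \code{composition} (cluster x source percentage matrix).
#' @export
mergeAndCompose <- function(trajs, mask = NULL, cutoff, seed) {
  stopifnot(length(trajs) >= 1L)
  nat <- vapply(trajs, nAtoms, integer(1))
  if (length(unique(nat)) != 1L)
    stop("topology mismatch between trajectories")
  coords <- do.call(abind1, lapply(trajs, function(t) t@coords))
  src <- rep(seq_along(trajs), vapply(trajs, nFrames, integer(1)))
  merged <- trajectory(coords, trajs[[1]]@topology,
                       timestamps = seq_len(dim(coords)[1]) - 1)
  refs <- harvestReferences(merged, mask, cutoff, seed)
  model <- assignClusters(merged, mask, refs, cutoff = cutoff, seed = seed,
                          source = src)
  k <- length(refs)
  comp <- matrix(0, k, length(trajs),
                 dimnames = list(paste0("C", seq_len(k)),
                                 paste0("replica", seq_along(trajs))))
  for (c in seq_len(k)) {
    inC <- model@source[model@assignment == c]
    comp[c, ] <- 100 * tabulate(inC, nbins = length(trajs)) /
      max(length(inC), 1L)
  }
  list(model = model, composition = comp)
}

## rbind for frame arrays (F x N x 3)
abind1 <- function(...) {
  parts <- list(...)
  n <- dim(parts[[1]])[2]
  out <- array(NA_real_, dim = c(sum(vapply(parts, function(p) dim(p)[1],
                                            integer(1))), n, 3))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Medoid representative of a cluster
#'
#' The frame minimising the mean fitted RMSD to all members of its
#' cluster; ties break to the lowest frame id.
#'
#' @param traj the clustered \linkS4class{Trajectory}.
#' @param model a \linkS4class{ClusterModel}.
#' @param cluster 1-based cluster id.
#' @param mask atoms for the fitted RMSD (default all).
#' @return the representative frame id.
#' @export
representativeFrame <- function(traj, model, cluster, mask = NULL) {
  members <- which(clusterAssignment(model) == cluster)
  if (!length(members)) stop("empty cluster: ", cluster)
  rows <- resolveMask(traj@topology, mask)
  sub <- traj@coords[members, , , drop = FALSE]
  meanD <- vapply(seq_along(members), function(i) {
    mean(rmsdToRef(sub, matrix(sub[i, , ], ncol = 3), rows))
  }, numeric(1))
  members[which.min(meanD)]
}

#' Time-ordered cluster membership table
#'
#' @param model a \linkS4class{ClusterModel}.
#' @param times per-frame timestamps in ps.
#' @return data.frame ordered by time with \code{frame}, \code{time_ps},
#'   \code{cluster}, \code{source}.
#' @export
clusterTimeline <- function(model, times) {
  stopifnot(length(times) == length(model@assignment))
  out <- data.frame(frame = seq_along(times), time_ps = times,
                    cluster = model@assignment, source = model@source)
  out[order(out$time_ps), ]
}
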