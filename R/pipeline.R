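#' Label trajectory frames by a stepped restraint schedule
#'
#' Time windows are half-open \code{[start, end)} in ps; a frame exactly
#' on a boundary belongs to the later step. Windows must neither overlap
#' nor leave gaps between the first start and the last end. An empty
#' schedule labels every frame \code{NA}.
#'
#' @param times frame timestamps in ps (or a \linkS4class{Trajectory}).
#' @param schedule data.frame with columns \code{label},
#'   \code{start_ps}, \code{end_ps}; zero rows allowed.
#' @return character vector of per-frame step labels (NA outside the
#'   schedule).
#' @examples
#' sched <- data.frame(label = c("A", "B", "C"),
#'                     start_ps = c(0, 38000, 60000),
#'                     end_ps = c(38000, 60000, 80000))
#' annotateSchedule(c(10000, 38000, 50000, 79999), sched)
#' @export
annotateSchedule <- function(times, schedule) {
  if (is(times, "Trajectory")) times <- timestamps(times)
  if (is.null(schedule) || nrow(schedule) == 0L)
    return(rep(NA_character_, length(times)))
  need <- c("label", "start_ps", "end_ps")
  if (!all(need %in% names(schedule)))
    stop("schedule needs columns label, start_ps, end_ps")
  sc <- schedule[order(schedule$start_ps), ]
  if (any(sc$end_ps <= sc$start_ps))
    stop("schedule config error: empty or inverted window")
  if (nrow(sc) > 1L) {
    gaps <- sc$start_ps[-1] - sc$end_ps[-nrow(sc)]
    if (any(gaps > 0)) stop("schedule config error: gap between windows")
    if (any(gaps < 0)) stop("schedule config error: overlapping windows")
  }
  out <- rep(NA_character_, length(times))
  for (i in seq_len(nrow(sc)))
    out[times >= sc$start_ps[i] & times < sc$end_ps[i]] <-
      as.character(sc$label[i])
  out
}

readAnalysisConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the configured analysis pipeline over one or more trajectories
#'
#' Executes the requested analyses in dependency order (fluctuations,
#' covariance/PCA, cross-correlation, clustering, motif geometry, shape
#' trajectory, contacts, secondary structure) on the input trajectories,
#' writing one CSV per analysis plus a JSON manifest (inputs, config
#' hash, seed, per-stage status and timings) into \code{outDir}.
#' Deterministic outputs are bit-reproducible for a fixed config and
#' seed. A failed stage is recorded in the manifest and marks the bundle
#' partial instead of aborting the remaining stages.
#'
#' @param config a nested list or path to a YAML file: \code{inputs}
#'   (paths, or in-memory trajectories passed via \code{trajectories}),
#'   \code{seed}, \code{trim_ps}, \code{schedule} and an \code{analyses}
#'   block with per-analysis parameter lists (see the vignette).
#' @param outDir output directory (created if absent).
#' @param trajectories optional list of \linkS4class{Trajectory} objects
#'   bypassing file input.
#' @return invisibly, the manifest list (also written to
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config, outDir, trajectories = NULL) {
  config <- readAnalysisConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  if (is.null(trajectories)) {
    if (is.null(config$inputs)) stop("config error: no inputs")
    trajectories <- lapply(config$inputs, function(inp) {
      if (is.character(inp)) inp <- list(path = inp, format = "pdb")
      readStructure(inp$path, inp$format)$trajectory
    })
  }
  trim <- if (!is.null(config$trim_ps)) config$trim_ps else 0
  trajectories <- lapply(trajectories, function(tr) {
    keep <- which(timestamps(tr) >= trim)
    if (!length(keep)) stop("config error: trim removes every frame")
    trajectory(tr@coords[keep, , , drop = FALSE], tr@topology,
               timestamps(tr)[keep])
  })
  traj <- trajectories[[1]]
  analyses <- config$analyses
  if (is.null(analyses)) analyses <- list()
  manifest <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   config_hash = configHash(config), seed = seed,
                   n_inputs = length(trajectories),
                   r_version = as.character(getRversion()),
                   files = character(0), stages = list(), status = "ok")
  emit <- function(name, df) {
    f <- file.path(outDir, paste0(name, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    manifest$files <<- c(manifest$files, basename(f))
  }
  runStage <- function(name, fun) {
    t0 <- proc.time()[3]
    res <- tryCatch({
      fun()
      list(status = "ok")
    }, error = function(e) list(status = "error",
                                message = conditionMessage(e)))
    res$seconds <- round(proc.time()[3] - t0, 3)
    manifest$stages[[name]] <<- res
    if (res$status != "ok") {
      manifest$status <<- "partial"
      message("stage ", name, " failed: ", res$message)
    } else message("stage ", name, " done in ", res$seconds, " s")
  }
  maskOf <- function(p) if (is.null(p$mask)) NULL else p$mask

  if (!is.null(analyses$rmsd)) runStage("rmsd", function() {
    p <- analyses$rmsd
    emit("rmsd", rmsdSeries(traj, reference = p$reference %||% 1L,
                            fitMask = maskOf(p),
                            measureMask = p$measure_mask))
  })
  if (!is.null(analyses$rmsf)) runStage("rmsf", function() {
    p <- analyses$rmsf
    prof <- rmsfProfile(traj, maskOf(p), p$reference %||% "mean")
    emit("rmsf", prof)
    keep <- highFluctuationMask(prof, p$threshold %||% 4.0)
    manifest$stages$rmsf$excluded <<- attr(keep, "excluded")
  })
  if (!is.null(analyses$pca)) runStage("pca", function() {
    p <- analyses$pca
    model <- pcaModes(covarianceModel(traj, maskOf(p),
                                      p$reference %||% "mean"))
    ev <- eigenvalues(model)
    emit("pca_spectrum", data.frame(
      mode = seq_along(ev), eigenvalue_A2 = ev,
      cumulative_fraction = cumsum(ev) / sum(ev)))
    emit("pca_projection",
         projectFrames(traj, model, p$modes %||% 2L))
  })
  if (!is.null(analyses$cross_correlation)) runStage("cross_correlation",
    function() {
      p <- analyses$cross_correlation
      cc <- crossCorrelation(traj, maskOf(p), p$fit_mask)
      emit("cross_correlation", as.data.frame(cc))
    })
  if (!is.null(analyses$clustering)) runStage("clustering", function() {
    p <- analyses$clustering
    cutoff <- p$cutoff %||% 2.0
    if (length(trajectories) > 1L) {
      mc <- mergeAndCompose(trajectories, maskOf(p), cutoff,
                            p$seed %||% seed)
      emit("clusters", clusterTimeline(mc$model,
                                       seq_along(mc$model@assignment) - 1))
      emit("cluster_composition", as.data.frame(mc$composition))
    } else {
      cm <- clusterTrajectory(traj, maskOf(p), cutoff, p$seed %||% seed)
      emit("clusters", clusterTimeline(cm, timestamps(traj)))
    }
  })
  if (!is.null(analyses$cluster_scan)) runStage("cluster_scan", function() {
    p <- analyses$cluster_scan
    grid <- if (!is.null(p$cutoffs)) as.numeric(p$cutoffs)
      else seq(1.6, 3.0, by = 0.2)
    emit("cluster_scan", clusterScan(traj, maskOf(p), grid,
                                     p$seed %||% seed,
                                     p$density_floor %||% 4))
  })
  if (!is.null(analyses$motif)) runStage("motif", function() {
    p <- analyses$motif
    emit("motif", motifSeries(traj, unlist(p$s_pair), unlist(p$ca_pair)))
  })
  if (!is.null(analyses$shapes)) runStage("shapes", function() {
    p <- analyses$shapes
    st <- shapeTrajectory(traj, resolveMask(traj@topology, p$landmarks))
    meta <- st$meta
    if (nrow(landmarks(st$shapes[[1]])) == 3L) {
      disk <- t(vapply(st$shapes, function(s) {
        d <- triangleDisk(s)
        c(d$r, d$phi)
      }, numeric(2)))
      meta$disk_r <- disk[, 1]
      meta$disk_phi <- disk[, 2]
    }
    emit("shape_trajectory", meta)
  })
  if (!is.null(analyses$contacts)) runStage("contacts", function() {
    p <- analyses$contacts
    co <- frameCoords(traj, p$frame %||% 1L)
    if (!is.null(p$chainA)) {
      ic <- interfaceContacts(co, traj@topology, p$chainA, p$chainB)
      emit("interface_contacts", ic$records)
      manifest$stages$contacts$summary <<- ic$summary
    } else {
      emit("contact_map",
           as.data.frame(contactMap(traj, stride = p$stride %||% 1L)))
    }
  })
  if (!is.null(analyses$secondary_structure)) runStage("secondary_structure",
    function() {
      p <- analyses$secondary_structure
      tl <- ssTimeline(traj, p$stride %||% 1L)
      emit("secondary_structure",
           data.frame(frame = rep(as.integer(rownames(tl)), ncol(tl)),
                      residue = rep(seq_len(ncol(tl)), each = nrow(tl)),
                      label = as.vector(tl)))
      manifest$stages$secondary_structure$fraction_folded <<-
        ssFraction(tl)
    })
  if (!is.null(config$schedule)) runStage("schedule", function() {
    sc <- as.data.frame(lapply(config$schedule, unlist))
    emit("schedule", data.frame(frame = seq_len(nFrames(traj)),
                                time_ps = timestamps(traj),
                                step = annotateSchedule(traj, sc)))
  })
  manifest$files <- unique(manifest$files)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
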