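#' Read a structure or multi-model trajectory
#'
#' Supported dialects: multi-model PDB (one frame per \code{MODEL} record;
#' a file without \code{MODEL} records is a single frame) and per-frame
#' XYZ. \code{ATOM} and \code{HETATM} records are accepted; alternate
#' locations other than blank or \code{'A'} are skipped; occupancy is
#' ignored. Coordinates are Angstrom; timestamps default to the frame
#' index in ps.
#'
#' @param path file to read.
#' @param format \code{"pdb"} or \code{"xyz"}.
#' @return list with elements \code{topology} (\linkS4class{Topology}) and
#'   \code{trajectory} (\linkS4class{Trajectory}).
#' @seealso [writeStructure()]
#' @export
readStructure <- function(path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") readPdbFile(path) else readXyzFile(path)
}

readPdbFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  isModel <- substr(lines, 1, 5) == "MODEL"
  altloc <- substr(lines, 17, 17)
  use <- isAtom & (altloc %in% c(" ", "A", ""))
  if (!any(use)) stop("empty structure: no ATOM/HETATM records in ", path)
  ## frame id per atom line: cumulative MODEL count (0 when no MODEL)
  modelId <- cumsum(isModel)
  frameOf <- modelId[use]
  if (max(frameOf) == 0L) frameOf <- frameOf + 1L
  ln <- which(use)
  txt <- lines[use]
  ## locate the first malformed coordinate precisely for the error message
  for (col in list(c(31, 38, "x"), c(39, 46, "y"), c(47, 54, "z"))) {
    raw <- substr(txt, as.integer(col[1]), as.integer(col[2]))
    bad <- which(is.na(suppressWarnings(as.numeric(raw))))
    if (length(bad))
      stop(sprintf("PDB parse error at line %d: malformed %s coordinate",
                   ln[bad[1]], col[3]))
  }
  xyz <- cbind(as.numeric(substr(txt, 31, 38)),
               as.numeric(substr(txt, 39, 46)),
               as.numeric(substr(txt, 47, 54)))
  name <- trimws(substr(txt, 13, 16))
  resname <- trimws(substr(txt, 18, 20))
  chain <- substr(txt, 22, 22)
  chain[chain == " "] <- "A"
  resno <- suppressWarnings(as.integer(trimws(substr(txt, 23, 26))))
  if (anyNA(resno))
    stop(sprintf("PDB parse error at line %d: malformed residue number",
                 ln[which(is.na(resno))[1]]))
  element <- trimws(substr(txt, 77, 78))
  guess <- substr(gsub("[^A-Za-z]", "", name), 1, 1)
  element[element == ""] <- guess[element == ""]

  first <- frameOf == frameOf[1]
  nAt <- sum(first)
  nF <- max(frameOf)
  if (length(txt) != nAt * nF)
    stop("PDB parse error: MODEL blocks have differing atom counts")
  key <- paste(chain[first], resno[first], resname[first])
  resindex <- match(key, unique(key))
  uid <- !duplicated(key)
  topo <- topology(
    atoms = data.frame(name = name[first], element = toupper(element[first]),
                       resindex = resindex),
    residues = data.frame(resname = resname[first][uid],
                          resno = resno[first][uid],
                          chain = chain[first][uid]))
  coords <- array(NA_real_, dim = c(nF, nAt, 3))
  for (f in seq_len(nF)) coords[f, , ] <- xyz[frameOf == f, , drop = FALSE]
  list(topology = topo,
       trajectory = trajectory(coords, topo, timestamps = seq_len(nF) - 1))
}

readXyzFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty structure: no atoms in ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) stop("XYZ parse error at line 1: bad atom count")
  stride <- n + 2L
  nF <- length(lines) %/% stride
  if (nF * stride != length(lines))
    stop("XYZ parse error: truncated frame block")
  coords <- array(NA_real_, dim = c(nF, n, 3))
  nm <- character(n)
  for (f in seq_len(nF)) {
    block <- lines[((f - 1L) * stride + 3L):((f - 1L) * stride + 2L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    for (i in seq_len(n)) {
      p <- parts[[i]]
      if (length(p) < 4L)
        stop(sprintf("XYZ parse error at line %d: expected 'elem x y z'",
                     (f - 1L) * stride + 2L + i))
      if (f == 1L) nm[i] <- p[1]
      v <- suppressWarnings(as.numeric(p[2:4]))
      if (anyNA(v))
        stop(sprintf("XYZ parse error at line %d: malformed coordinate",
                     (f - 1L) * stride + 2L + i))
      coords[f, i, ] <- v
    }
  }
  topo <- topology(
    atoms = data.frame(name = nm, element = toupper(nm), resindex = 1L),
    residues = data.frame(resname = "UNK", resno = 1L, chain = "A"))
  list(topology = topo,
       trajectory = trajectory(coords, topo, timestamps = seq_len(nF) - 1))
}

#' Write a structure or trajectory
#'
#' Multi-frame trajectories are written as multi-model PDB
#' (\code{MODEL}/\code{ENDMDL} pairs); a single frame is written without
#' \code{MODEL} records. Coordinates are written at PDB precision
#' (0.001 Angstrom), so a read/write round trip agrees to 1e-3 Angstrom.
#'
#' @param topo the \linkS4class{Topology}.
#' @param traj the \linkS4class{Trajectory} to write.
#' @param path output file.
#' @param format \code{"pdb"} or \code{"xyz"}.
#' @return \code{path}, invisibly.
#' @seealso [readStructure()]
#' @export
writeStructure <- function(topo, traj, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  stopifnot(is(topo, "Topology"), is(traj, "Trajectory"))
  if (dim(traj@coords)[1] < 1L) stop("refusing to write an empty trajectory")
  a <- topo@atoms
  r <- topo@residues[a$resindex, ]
  nF <- dim(traj@coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    for (f in seq_len(nF)) {
      if (nF > 1L) writeLines(sprintf("MODEL     %4d", f), con)
      xyz <- matrix(traj@coords[f, , ], ncol = 3)
      nm <- ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name)
      writeLines(sprintf(
        "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        seq_len(nrow(a)) %% 100000, nm, " ", r$resname, r$chain, r$resno,
        " ", xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element), con)
      if (nF > 1L) writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (f in seq_len(nF)) {
      writeLines(as.character(nrow(a)), con)
      writeLines(sprintf("frame %d t= %g ps", f, traj@timestamps[f]), con)
      xyz <- matrix(traj@coords[f, , ], ncol = 3)
      writeLines(sprintf("%-3s %12.6f %12.6f %12.6f", a$element,
                         xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  }
  invisible(path)
}
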