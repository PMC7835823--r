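#' Construct a Topology
#'
#' @param atoms data.frame with columns \code{name}, \code{element},
#'   \code{resindex}.
#' @param residues data.frame with columns \code{resname}, \code{resno},
#'   \code{chain}.
#' @param bonds optional two-column integer matrix of bonded atom pairs.
#' @return a validated \linkS4class{Topology}.
#' @examples
#' topo <- topology(
#'   atoms = data.frame(name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
#'                      resindex = 1L),
#'   residues = data.frame(resname = "GLY", resno = 1L, chain = "A"))
#' @export
topology <- function(atoms, residues,
                     bonds = matrix(integer(0), ncol = 2)) {
  atoms$resindex <- as.integer(atoms$resindex)
  residues$resno <- as.integer(residues$resno)
  new("Topology", atoms = as.data.frame(atoms),
      residues = as.data.frame(residues), bonds = bonds)
}

#' Construct a Trajectory
#'
#' @param coords F x N x 3 array, or an N x 3 matrix for a single frame
#'   (Angstrom).
#' @param topology the \linkS4class{Topology} the coordinates live on.
#' @param timestamps frame times in ps; defaults to 0, 1, ... ps.
#' @return a validated \linkS4class{Trajectory}.
#' @export
trajectory <- function(coords, topology, timestamps = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  }
  if (is.null(timestamps)) timestamps <- seq_len(dim(coords)[1]) - 1
  new("Trajectory", coords = coords, timestamps = as.numeric(timestamps),
      topology = topology)
}

## Fixed physico-chemical classification of the 20 standard residues.
## Histidine is kept polar/neutral (epsilon-protonated convention) and
## glycine counts as hydrophobic so that Cα-proxy hydrophobic contacts
## involving glycine are detectable.
.residueClassTable <- c(
  ARG = "positively-charged", LYS = "positively-charged",
  ASP = "negatively-charged", GLU = "negatively-charged",
  SER = "polar", THR = "polar", ASN = "polar", GLN = "polar",
  CYS = "polar", HIS = "polar",
  ALA = "hydrophobic", VAL = "hydrophobic", LEU = "hydrophobic",
  ILE = "hydrophobic", PRO = "hydrophobic", PHE = "hydrophobic",
  MET = "hydrophobic", GLY = "hydrophobic",
  TRP = "amphipathic", TYR = "amphipathic")

#' Classify a standard residue by physico-chemical character
#'
#' Total over the 20 standard residues: positively/negatively charged,
#' polar, hydrophobic or amphipathic. Histidine is treated as neutral
#' (polar); tryptophan and tyrosine are amphipathic; glycine is grouped
#' with the hydrophobics.
#'
#' @param resname 3-letter residue code(s), case-insensitive.
#' @return character vector of classes.
#' @examples
#' classifyResidue(c("ARG", "GLY", "TRP"))
#' @export
classifyResidue <- function(resname) {
  key <- toupper(resname)
  cls <- .residueClassTable[key]
  if (anyNA(cls))
    stop("unknown residue class for: ",
         paste(unique(key[is.na(cls)]), collapse = ", "))
  unname(cls)
}

#' Select atoms with a small mask expression language
#'
#' Grammar: clauses joined by \code{and}; each clause is one of
#' \code{name <atom names>}, \code{resname <codes>}, \code{chain <ids>},
#' \code{resid <numbers or a-b ranges>}, \code{elem <elements>} with
#' space-separated alternatives. The result is a deterministic, sorted,
#' duplicate-free integer mask into the topology.
#'
#' @param topo a \linkS4class{Topology}.
#' @param expression selection string, e.g. \code{"resid 37-40 and name SG"}.
#' @return sorted integer vector of atom indices (possibly empty, with a
#'   warning).
#' @examples
#' topo <- topology(
#'   atoms = data.frame(name = c("CA", "SG"), element = c("C", "S"), resindex = 1L),
#'   residues = data.frame(resname = "CYS", resno = 37L, chain = "A"))
#' selectAtoms(topo, "name SG")
#' @export
selectAtoms <- function(topo, expression) {
  stopifnot(is(topo, "Topology"), is.character(expression))
  a <- topo@atoms
  r <- topo@residues[a$resindex, ]
  keep <- rep(TRUE, nrow(a))
  clauses <- strsplit(trimws(expression), "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    if (length(tok) < 2L)
      stop("selection syntax error near '", cl, "'")
    key <- tok[1]
    vals <- tok[-1]
    keep <- keep & switch(key,
      name = toupper(a$name) %in% toupper(vals),
      elem = toupper(a$element) %in% toupper(vals),
      resname = toupper(r$resname) %in% toupper(vals),
      chain = r$chain %in% vals,
      resid = {
        nums <- unlist(lapply(vals, function(v) {
          if (grepl("^-?[0-9]+--?[0-9]+$", v) || grepl("^[0-9]+-[0-9]+$", v)) {
            ab <- as.integer(strsplit(v, "(?<=[0-9])-", perl = TRUE)[[1]])
            seq(ab[1], ab[2])
          } else if (grepl("^-?[0-9]+$", v)) as.integer(v)
          else stop("selection syntax error: bad resid token '", v, "'")
        }))
        r$resno %in% nums
      },
      stop("selection syntax error: unknown keyword '", key, "'"))
  }
  idx <- which(keep)
  if (length(idx) == 0L) warning("selection '", expression, "' matched no atoms")
  as.integer(idx)
}

## Resolve a mask given either an expression, indices or NULL (all atoms).
resolveMask <- function(topo, mask) {
  if (is.null(mask)) return(seq_len(nrow(topo@atoms)))
  if (is.character(mask)) return(selectAtoms(topo, mask))
  idx <- as.integer(mask)
  if (any(idx < 1L | idx > nrow(topo@atoms)) || anyDuplicated(idx))
    stop("invalid atom mask")
  sort(idx)
}
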