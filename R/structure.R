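#' Parse a PDB structure into a `metox_structure`
#'
#' Reads a PDB file (or literal PDB text) into the atom-table container the
#' descriptor machinery selects against. If the file contains multiple
#' `MODEL` records only the first model's coordinates are kept; use
#' [read_ensemble()] to keep all of them. Alternate locations are resolved
#' to a single conformer per atom: the highest-occupancy altloc wins, ties
#' broken by altloc letter ('A' before 'B'). An orthorhombic `CRYST1` cell,
#' if present and not the 1 Å placeholder, populates the `box` field used
#' for minimum-image distance counting.
#'
#' @param source path to a PDB file, or a character vector of PDB lines
#'   (anything containing a newline or more than one element is treated as
#'   literal text).
#' @param mse_as_met treat selenomethionine (MSE, sulfur replaced by SE) as
#'   methionine. Default `TRUE`.
#' @return an object of class `metox_structure`: a list with
#'   \describe{
#'     \item{atoms}{data.frame with columns `name`, `element`, `resname`,
#'       `chain`, `resnum`, `inscode`, `altloc`, `occupancy`, `het`,
#'       `x`, `y`, `z` (Å), one row per atom in file order.}
#'     \item{box}{numeric length-3 orthorhombic cell edges in Å, or `NULL`.}
#'   }
#' @examples
#' pdb <- c(
#'   "ATOM      1  SD  MET A   1       0.000   0.000   0.000  1.00  0.00           S",
#'   "END")
#' s <- read_structure(pdb)
#' nrow(s$atoms)
#' @seealso [read_ensemble()], [select_methionines()]
#' @export
read_structure <- function(source, mse_as_met = TRUE) {
  parsed <- parse_pdb_source(source, multi = FALSE)
  structure(list(atoms = parsed$atoms, box = parsed$box),
            class = "metox_structure")
}

#' Parse a conformational ensemble
#'
#' Reads a multi-model PDB (or a PDB topology plus a DCD trajectory) into an
#' ensemble over a fixed topology: one `metox_structure` plus a coordinate
#' array with one slab per frame. A single-model PDB yields a valid one-frame
#' ensemble, so static structures degenerate correctly.
#'
#' @param source path to a (multi-model) PDB file or literal PDB text.
#' @param trajectory optional path to a DCD trajectory whose frames replace
#'   the PDB model coordinates (topology still comes from `source`).
#' @param frame_interval optional frame spacing in ps; metadata only.
#' @inheritParams read_structure
#' @return object of class `metox_ensemble`: list with `topology`
#'   (a `metox_structure`), `coords` (array `n_atoms` x 3 x `n_frames`),
#'   and `frame_interval`.
#' @export
read_ensemble <- function(source, trajectory = NULL, frame_interval = NULL,
                          mse_as_met = TRUE) {
  parsed <- parse_pdb_source(source, multi = TRUE)
  topo <- structure(list(atoms = parsed$atoms, box = parsed$box),
                    class = "metox_structure")
  coords <- parsed$coords
  if (!is.null(trajectory)) {
    xyz <- bio3d::read.dcd(trajectory, verbose = FALSE)
    if (ncol(xyz) != 3L * nrow(topo$atoms))
      stop("trajectory frames have ", ncol(xyz) / 3,
           " atoms; topology has ", nrow(topo$atoms),
           " (atom-count congruence violated)")
    coords <- xyz_to_array(xyz)
  }
  as_ensemble(topo, coords, frame_interval = frame_interval)
}

#' Assemble an ensemble from a topology and explicit frame coordinates
#'
#' @param topology a `metox_structure`.
#' @param coords array `n_atoms` x 3 x `n_frames`, a list of `n_atoms` x 3
#'   matrices, or a single matrix (one frame).
#' @param frame_interval optional frame spacing in ps; metadata only.
#' @return a `metox_ensemble`.
#' @export
as_ensemble <- function(topology, coords, frame_interval = NULL) {
  stopifnot(inherits(topology, "metox_structure"))
  n <- nrow(topology$atoms)
  if (is.list(coords)) {
    coords <- array(unlist(lapply(coords, t)), dim = c(3, n, length(coords)))
    coords <- aperm(coords, c(2, 1, 3))
  } else if (is.matrix(coords)) {
    coords <- array(coords, dim = c(nrow(coords), 3, 1))
  }
  if (length(dim(coords)) != 3L || dim(coords)[1] != n || dim(coords)[2] != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array congruent with ",
         "the topology (", n, " atoms)")
  if (dim(coords)[3] < 1L) stop("ensemble must contain at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates in ensemble")
  structure(list(topology = topology, coords = coords,
                 frame_interval = frame_interval),
            class = "metox_ensemble")
}

#' @export
print.metox_structure <- function(x, ...) {
  a <- x$atoms
  cat("metox_structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resnum, a$inscode))), "residues,",
      length(unique(a$chain)), "chain(s)\n")
  if (!is.null(x$box))
    cat("  box:", paste(sprintf("%.2f", x$box), collapse = " x "), "Å\n")
  invisible(x)
}

#' @export
print.metox_ensemble <- function(x, ...) {
  cat("metox_ensemble:", dim(x$coords)[3], "frame(s) over",
      nrow(x$topology$atoms), "atoms\n")
  if (!is.null(x$frame_interval))
    cat("  frame interval:", x$frame_interval, "ps\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x a `metox_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "metox_ensemble"))
  dim(x$coords)[3]
}

#' Coordinates of one frame
#' @param x a `metox_ensemble` or `metox_structure`.
#' @param frame frame index (ignored for a structure).
#' @return numeric `n_atoms` x 3 matrix.
#' @export
frame_coords <- function(x, frame = 1L) {
  if (inherits(x, "metox_structure"))
    return(as.matrix(x$atoms[, c("x", "y", "z")]))
  x$coords[, , frame, drop = TRUE]
}

## ---- internal PDB machinery -------------------------------------------

# Reads `source` (path or literal text) with bio3d after a light syntactic
# validation pass; returns atoms (altloc-resolved), box, and for multi = TRUE
# the full coordinate array.
parse_pdb_source <- function(source, multi) {
  path <- source_to_path(source)
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines)
  box <- parse_cryst1(lines)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE, hex = TRUE))
  atoms <- bio3d_atoms(pdb)
  if (nrow(atoms) == 0L) stop("empty structure: no ATOM/HETATM records")
  nmod <- nrow(pdb$xyz)
  check_model_congruence(lines)
  keep <- resolve_altlocs(atoms)
  atoms <- atoms[keep, , drop = FALSE]
  coords <- xyz_to_array(pdb$xyz)[keep, , , drop = FALSE]
  atoms$x <- coords[, 1, 1]
  atoms$y <- coords[, 2, 1]
  atoms$z <- coords[, 3, 1]
  rownames(atoms) <- NULL
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates after parsing")
  out <- list(atoms = atoms, box = box)
  if (multi) out$coords <- coords
  out
}

source_to_path <- function(source) {
  is_text <- length(source) > 1L || grepl("\n", source[1]) ||
    grepl("^(ATOM|HETATM|MODEL|CRYST1|REMARK|HEADER)", source[1])
  if (!is_text && file.exists(source)) return(source)
  if (!is_text) stop("cannot read PDB source: file not found: ", source)
  path <- tempfile(fileext = ".pdb")
  writeLines(unlist(strsplit(source, "\n", fixed = TRUE)), path)
  path
}

validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("empty structure: no ATOM/HETATM records")
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record at line ", i, ": too short")
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v))
        stop("malformed coordinate field at line ", i, ": '",
             substr(ln, fld[1], fld[2]), "'")
    }
  }
  invisible(TRUE)
}

parse_cryst1 <- function(lines) {
  cl <- lines[startsWith(lines, "CRYST1")]
  if (length(cl) == 0L) return(NULL)
  cl <- cl[1]
  edges <- as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24),
                        substr(cl, 25, 33)))
  angs <- as.numeric(c(substr(cl, 34, 40), substr(cl, 41, 47),
                       substr(cl, 48, 54)))
  if (any(is.na(edges))) stop("malformed CRYST1 record")
  # placeholder cell written by many tools for non-periodic structures
  if (all(edges <= 2)) return(NULL)
  if (any(abs(angs - 90) > 1e-3))
    stop("only orthorhombic boxes are supported; CRYST1 angles are ",
         paste(angs, collapse = ", "))
  edges
}

bio3d_atoms <- function(pdb) {
  a <- pdb$atom
  blank <- function(v) ifelse(is.na(v), "", as.character(v))
  ele <- blank(a$elesy)
  miss <- !nzchar(ele)
  if (any(miss))
    ele[miss] <- vapply(a$elety[miss], guess_element, character(1))
  data.frame(
    name = as.character(a$elety),
    element = toupper(ele),
    resname = as.character(a$resid),
    chain = blank(a$chain),
    resnum = as.integer(a$resno),
    inscode = blank(a$insert),
    altloc = blank(a$alt),
    occupancy = ifelse(is.na(a$o), 1, a$o),
    het = a$type == "HETATM",
    stringsAsFactors = FALSE)
}

guess_element <- function(name) {
  nm <- gsub("[0-9']", "", toupper(name))
  if (!nzchar(nm)) return("")
  two <- substr(nm, 1, 2)
  if (two %in% c("SE", "CL", "BR", "FE", "ZN", "MG", "NA", "MN")) return(two)
  substr(nm, 1, 1)
}

# highest occupancy wins; ties go to the alphabetically first altloc
resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resnum, atoms$inscode, atoms$name,
               sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  first <- !duplicated(key[ord])
  sort(ord[first])
}

# bio3d xyz matrix (frames x 3N) -> array n x 3 x frames
xyz_to_array <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  n <- ncol(xyz) / 3L
  arr <- array(NA_real_, dim = c(n, 3, nf))
  for (f in seq_len(nf)) arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  arr
}

# raw-line scan: every MODEL block must carry the same number of atom records
check_model_congruence <- function(lines) {
  rec <- substr(lines, 1, 6)
  starts <- which(rec == "MODEL ")
  if (length(starts) < 2L) return(invisible(TRUE))
  ends <- which(rec == "ENDMDL")
  if (length(ends) != length(starts))
    stop("unbalanced MODEL/ENDMDL records")
  counts <- mapply(function(s, e) sum(rec[s:e] %in% c("ATOM  ", "HETATM")),
                   starts, ends)
  if (length(unique(counts)) != 1L)
    stop("inconsistent atom count across models: ",
         paste(unique(counts), collapse = ", "),
         " (all models must share the topology)")
  invisible(TRUE)
}

## ---- PDB writing (fixtures, round-trips) ------------------------------

#' Write a structure or ensemble as PDB text
#'
#' Fixed-width writer used by the synthetic-fixture generator and for
#' round-trip tests. Ensembles are written as multi-model PDB. A box, if
#' present, is written as an orthorhombic `CRYST1` record.
#'
#' @param x a `metox_structure` or `metox_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "metox_structure")) {
    topo <- x
    coords <- array(frame_coords(x), dim = c(nrow(x$atoms), 3, 1))
  } else {
    topo <- x$topology
    coords <- x$coords
  }
  a <- topo$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(topo$box))
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      topo$box[1], topo$box[2], topo$box[3], 90, 90, 90), con)
  nf <- dim(coords)[3]
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(format_atom_lines(a, coords[, , f, drop = TRUE]), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

format_atom_lines <- function(a, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  # atom name column convention: 1-3 char names start in column 14
  nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
               sprintf(" %-3s", a$name))
  sprintf("%s%5d %-4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, seq_len(nrow(a)) %% 100000L, nm,
          substr(paste0(a$altloc, " "), 1, 1),
          a$resname, substr(paste0(a$chain, " "), 1, 1), a$resnum %% 10000L,
          substr(paste0(a$inscode, " "), 1, 1),
          xyz[, 1], xyz[, 2], xyz[, 3], a$occupancy, 0,
          substr(paste0(a$element, " "), 1, 2))
}
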