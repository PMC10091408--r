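# Structure and trajectory I/O: fixed-width PDB reading/writing and the shared
# data model every analysis consumes. Coordinates are Angstrom, residue numbers
# 1-based, axes right-handed; no internal unit conversion anywhere.

TWO_LETTER_ELEMENTS <- c("CL", "NA", "MG", "BR", "FE", "ZN", "MN", "RB", "CS", "SR", "LI")
ION_RESNAMES <- c("K+", "NA+", "CL-", "K", "NA", "CL", "MG", "MG2", "RB+", "CS+", "LI+")

#' Construct a structure model
#'
#' The central container: an ordered atom table plus an optional orthorhombic
#' box. Ions are represented as single-atom residues (residue names `K+`,
#' `NA+`, `CL-`), matching common MD PDB output.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `chain`,
#'   `resid` (1-based integer), `resname`, `icode`, `x`, `y`, `z`.
#' @param box optional numeric length-3 orthorhombic box edge lengths (Angstrom).
#' @param metadata free-form list.
#' @return object of class `rna_model`.
#' @export
rna_model <- function(atoms, box = NULL, metadata = list()) {
  required <- c("serial", "name", "element", "chain", "resid", "resname", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty structure: a model needs at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$name))) stop("empty atom names in atom table")
  if (any(atoms$resid < 1)) stop("residue numbers must be 1-based (>= 1)")
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
      stop("box must be three positive lengths (Angstrom)")
  }
  if (is.null(atoms$icode)) atoms$icode <- ""
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, box = box, metadata = metadata),
            class = "rna_model")
}

#' @export
print.rna_model <- function(x, ...) {
  cat(sprintf("<rna_model> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resid")])),
              paste(unique(x$atoms$chain), collapse = " ")))
  if (!is.null(x$box))
    cat(sprintf("  box: %.2f x %.2f x %.2f A\n", x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Number of atoms in a model or trajectory topology
#' @param x an `rna_model` or `rna_traj`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "rna_traj")) nrow(x$topology$atoms) else nrow(x$atoms)
}

#' Coordinates of a model as a matrix
#' @param model an `rna_model`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

set_coords <- function(model, xyz) {
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

as_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}

infer_element <- function(name, resname) {
  up <- gsub("[^A-Z]", "", toupper(name))
  if (resname %in% ION_RESNAMES) {
    ion <- gsub("[^A-Z]", "", toupper(resname))
    if (substr(ion, 1, 2) %in% TWO_LETTER_ELEMENTS) return(substr(ion, 1, 2))
    return(substr(ion, 1, 1))
  }
  if (nchar(up) >= 2 && substr(up, 1, 2) %in% TWO_LETTER_ELEMENTS)
    return(substr(up, 1, 2))
  substr(up, 1, 1)
}

parse_atom_records <- function(lines, linenos) {
  numfield <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v))
    if (length(bad) > 0)
      stop(sprintf("malformed %s field at line %d: '%s'",
                   what, linenos[bad[1]], lines[bad[1]]))
    v
  }
  f <- function(a, b) trimws(substr(lines, a, b))
  serial <- numfield(substr(lines, 7, 11), "serial")
  name <- f(13, 16)
  altloc <- substr(lines, 17, 17)
  resname <- f(18, 20)
  chain <- f(22, 22)
  resid <- numfield(substr(lines, 23, 26), "residue-number")
  icode <- trimws(substr(lines, 27, 27))
  x <- numfield(substr(lines, 31, 38), "coordinate")
  y <- numfield(substr(lines, 39, 46), "coordinate")
  z <- numfield(substr(lines, 47, 54), "coordinate")
  element <- toupper(f(77, 78))
  keep <- altloc %in% c(" ", "", "A")
  atoms <- data.frame(serial = as.integer(serial), name = name,
                      element = element, chain = chain,
                      resid = as.integer(resid), resname = resname,
                      icode = icode, x = x, y = y, z = z,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  blank <- !nzchar(atoms$element)
  if (any(blank))
    atoms$element[blank] <- mapply(infer_element, atoms$name[blank],
                                   atoms$resname[blank])
  # Normalise element case (CL -> Cl style kept upper internally).
  atoms$chain[!nzchar(atoms$chain)] <- "A"
  rownames(atoms) <- NULL
  atoms
}

parse_cryst1 <- function(line) {
  abc <- suppressWarnings(as.numeric(c(substr(line, 7, 15),
                                       substr(line, 16, 24),
                                       substr(line, 25, 33))))
  if (any(is.na(abc)) || any(abc <= 0)) return(NULL)
  if (all(abc == 1)) return(NULL)  # placeholder CRYST1
  abc
}

#' Read a structure from PDB text
#'
#' Parses `ATOM`/`HETATM` records (fixed columns), keeps blank/'A' altlocs and
#' insertion codes, and picks up an orthorhombic box from `CRYST1`. For
#' multi-model files only the first model is read (use [read_trajectory()]).
#'
#' @param text a file path, a single string, or a character vector of lines.
#' @return an [rna_model()].
#' @export
read_structure <- function(text) {
  lines <- as_lines(text)
  first_end <- grep("^ENDMDL", lines)
  if (length(first_end) > 0) lines_model <- lines[seq_len(first_end[1])]
  else lines_model <- lines
  is_atom <- grepl("^(ATOM  |HETATM)", lines_model)
  if (!any(is_atom)) stop("empty structure: no ATOM/HETATM records found")
  atoms <- parse_atom_records(lines_model[is_atom], which(is_atom))
  if (nrow(atoms) == 0) stop("empty structure: all atom records filtered out")
  box <- NULL
  cl <- grep("^CRYST1", lines)
  if (length(cl) > 0) box <- parse_cryst1(lines[cl[1]])
  rna_model(atoms, box = box)
}

format_atom_name <- function(name, element) {
  # Standard PDB alignment: 1-char elements start in column 14.
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(element) == 1 && nchar(name) <= 3)
    return(sprintf("%-4s", paste0(" ", name)))
  sprintf("%-4s", name)
}

format_atom_lines <- function(atoms) {
  names4 <- mapply(format_atom_name, atoms$name, atoms$element)
  sprintf("ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000L, names4, atoms$resname,
          substr(paste0(atoms$chain, " "), 1, 1), atoms$resid,
          substr(paste0(atoms$icode, " "), 1, 1),
          atoms$x, atoms$y, atoms$z, 1, 0, atoms$element)
}

#' Write a structure as PDB text
#'
#' @param model an [rna_model()].
#' @param file optional path; when `NULL` the text is returned invisibly.
#' @return character vector of PDB lines, invisibly.
#' @export
write_structure <- function(model, file = NULL) {
  lines <- character(0)
  if (!is.null(model$box))
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     model$box[1], model$box[2], model$box[3], 90, 90, 90)
  lines <- c(lines, format_atom_lines(model$atoms), "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Construct a trajectory
#'
#' Frames share one topology; each frame is a coordinate matrix congruent with
#' the topology atom count.
#'
#' @param topology an [rna_model()] (reference, frame 1).
#' @param frames list of n_atoms x 3 coordinate matrices.
#' @param box optional per-trajectory box (defaults to the topology box).
#' @return object of class `rna_traj`.
#' @export
trajectory <- function(topology, frames, box = NULL) {
  stopifnot(inherits(topology, "rna_model"))
  if (length(frames) < 1) stop("a trajectory needs at least one frame")
  nt <- nrow(topology$atoms)
  for (k in seq_along(frames)) {
    if (!is.matrix(frames[[k]]) || nrow(frames[[k]]) != nt || ncol(frames[[k]]) != 3)
      stop(sprintf("frame %d is not congruent with the topology (%d atoms expected)",
                   k, nt))
  }
  structure(list(topology = topology, frames = frames,
                 box = box %||% topology$box),
            class = "rna_traj")
}

#' @export
print.rna_traj <- function(x, ...) {
  cat(sprintf("<rna_traj> %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology$atoms)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `rna_traj`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Model for a single trajectory frame
#' @param traj an `rna_traj`.
#' @param k frame index (1-based).
#' @return the topology with frame-`k` coordinates.
#' @export
frame_model <- function(traj, k) {
  stopifnot(k >= 1, k <= length(traj$frames))
  set_coords(traj$topology, traj$frames[[k]])
}

#' Read a multi-model PDB as a trajectory
#'
#' `MODEL`/`ENDMDL` blocks become frames; the topology is taken from model 1.
#' A file without `MODEL` records yields a single-frame trajectory.
#'
#' @inheritParams read_structure
#' @return an `rna_traj`.
#' @export
read_trajectory <- function(text) {
  lines <- as_lines(text)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    m <- read_structure(lines)
    return(trajectory(m, list(coords(m))))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stop("unbalanced MODEL/ENDMDL records")
  box <- NULL
  cl <- grep("^CRYST1", lines)
  if (length(cl) > 0) box <- parse_cryst1(lines[cl[1]])
  topology <- NULL
  frames <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    idx <- (starts[k] + 1):(ends[k] - 1)
    block <- lines[idx]
    is_atom <- grepl("^(ATOM  |HETATM)", block)
    atoms <- parse_atom_records(block[is_atom], idx[is_atom])
    if (k == 1) {
      topology <- rna_model(atoms, box = box)
      frames[[1]] <- as.matrix(atoms[, c("x", "y", "z")])
    } else {
      if (nrow(atoms) != nrow(topology$atoms))
        stop(sprintf("model %d has %d atoms but model 1 has %d: inconsistent trajectory",
                     k, nrow(atoms), nrow(topology$atoms)))
      frames[[k]] <- as.matrix(atoms[, c("x", "y", "z")])
    }
  }
  trajectory(topology, frames, box = box)
}

#' Write a trajectory as multi-model PDB
#'
#' @param traj an `rna_traj`.
#' @param file optional path; when `NULL` lines are returned invisibly.
#' @return character vector of PDB lines, invisibly.
#' @export
write_trajectory <- function(traj, file = NULL) {
  lines <- character(0)
  if (!is.null(traj$box))
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     traj$box[1], traj$box[2], traj$box[3], 90, 90, 90)
  for (k in seq_along(traj$frames)) {
    m <- frame_model(traj, k)
    lines <- c(lines, sprintf("MODEL     %4d", k),
               format_atom_lines(m$atoms), "ENDMDL")
  }
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Append monovalent ions to a model
#'
#' Ions become single-atom residues on chain `X` with the species name as both
#' residue and atom name (`K+`, `NA+`, `CL-`).
#'
#' @param model an [rna_model()].
#' @param positions n x 3 matrix of ion coordinates (Angstrom).
#' @param species residue/atom name, e.g. `"K+"`.
#' @return the model with ions appended.
#' @export
add_ions <- function(model, positions, species = "K+") {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  if (nrow(positions) == 0) return(model)
  elem <- infer_element(species, species)
  start_serial <- max(model$atoms$serial) + 1L
  ions <- data.frame(serial = start_serial + seq_len(nrow(positions)) - 1L,
                     name = species, element = elem, chain = "X",
                     resid = seq_len(nrow(positions)), resname = species,
                     icode = "", x = positions[, 1], y = positions[, 2],
                     z = positions[, 3], stringsAsFactors = FALSE)
  model$atoms <- rbind(model$atoms, ions)
  model
}
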