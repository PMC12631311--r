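#' Protein structure container
#'
#' A minimal all-atom structure: an atom table plus one coordinate set.
#' Residue numbers are author numbers (e.g. 1513-1657 for the alsin
#' VPS9 construct) and are preserved end-to-end; coordinates are in
#' Angstrom.
#'
#' @param atoms data.frame with columns `name`, `element`, `resno`,
#'   `resid`, `chain` (one row per atom).
#' @param xyz numeric matrix (n_atoms x 3), Angstrom.
#' @return An object of class `"structure3d"`.
#' @export
structure3d <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("name", "element", "resno", "resid", "chain")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L || nrow(xyz) != nrow(atoms))
    stop("xyz must be a numeric n_atoms x 3 matrix")
  rownames(xyz) <- NULL
  obj <- list(atoms = atoms, xyz = xyz)
  class(obj) <- "structure3d"
  obj
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, %d residues (%s)\n",
              nrow(x$atoms), length(unique(x$atoms$resno)),
              paste(range(x$atoms$resno), collapse = "-")))
  invisible(x)
}

#' Trajectory container
#'
#' Multi-frame coordinates over a fixed atom table, with per-frame
#' times in nanoseconds (strictly increasing).
#'
#' @param atoms atom table as in [structure3d()].
#' @param coords numeric array (n_atoms x 3 x n_frames), Angstrom.
#' @param time numeric vector of frame times (ns), strictly increasing.
#' @return An object of class `"trajectory3d"`.
#' @export
trajectory3d <- function(atoms, coords, time) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1L] != nrow(atoms))
    stop("coords first dimension must match the atom table")
  nf <- dim(coords)[3L]
  if (length(time) != nf) stop("time must have one entry per frame")
  if (nf > 1L && any(diff(time) <= 0)) stop("frame times must be strictly increasing")
  obj <- list(atoms = atoms, coords = coords, time = as.numeric(time))
  class(obj) <- "trajectory3d"
  obj
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("trajectory3d: %d frames x %d atoms, t = %.4g..%.4g ns\n",
              n_frames(x), nrow(x$atoms), x$time[1L],
              x$time[length(x$time)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory3d()] object.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' Extract one frame of a trajectory as a structure
#' @param traj A [trajectory3d()] object.
#' @param i Frame index (1-based).
#' @return A [structure3d] object.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  structure3d(traj$atoms, traj$coords[, , i, drop = TRUE])
}

#' Assemble frames into a trajectory
#'
#' @param frames list of [structure3d] objects sharing one atom table.
#' @param time frame times in ns; default `0, dt, 2 dt, ...`.
#' @param dt sampling interval (ns) used when `time` is missing.
#' @return A [trajectory3d()] object.
#' @export
frames_to_trajectory <- function(frames, time = NULL, dt = 0.1) {
  stopifnot(length(frames) >= 1L)
  nat <- nrow(frames[[1L]]$atoms)
  if (!all(vapply(frames, function(f) nrow(f$atoms) == nat, logical(1L))))
    stop("all frames must share one atom count")
  coords <- array(NA_real_, c(nat, 3L, length(frames)))
  for (i in seq_along(frames)) coords[, , i] <- frames[[i]]$xyz
  if (is.null(time)) time <- (seq_along(frames) - 1L) * dt
  trajectory3d(frames[[1L]]$atoms, coords, time)
}

#' Select atoms by residue number and/or atom name
#'
#' @param x A [structure3d] or [trajectory3d()] object.
#' @param resno residue numbers to keep (NULL keeps all).
#' @param name atom names to keep (NULL keeps all).
#' @param chain chain ids to keep (NULL keeps all).
#' @return Integer vector of atom indices.
#' @export
atom_select <- function(x, resno = NULL, name = NULL, chain = NULL) {
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  which(keep)
}

# One-/three-letter residue code tables.
.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.aa1to3 <- stats::setNames(names(.aa3to1), unname(.aa3to1))

# Infer the chemical element from a PDB atom name (used when the
# element column is blank in the input file).
infer_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  first <- toupper(substr(nm, 1L, 1L))
  ifelse(first %in% c("C", "N", "O", "S", "H", "P"), first, toupper(nm))
}

#' Read a structure from a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()]; missing element columns are
#' inferred from atom names.
#'
#' @param path PDB file path.
#' @return A [structure3d] object (first model only).
#' @export
read_structure <- function(path) {
  p <- bio3d::read.pdb(path, verbose = FALSE)
  a <- p$atom
  ele <- a$elesy
  bad <- is.na(ele) | trimws(ele) == ""
  ele[bad] <- infer_element(a$elety[bad])
  atoms <- data.frame(name = trimws(a$elety), element = trimws(ele),
                      resno = a$resno, resid = trimws(a$resid),
                      chain = ifelse(is.na(a$chain), "A", a$chain),
                      stringsAsFactors = FALSE)
  structure3d(atoms, cbind(a$x, a$y, a$z))
}

#' Read a multi-model PDB file as a trajectory
#'
#' @param path PDB file path with MODEL/ENDMDL records.
#' @param dt sampling interval in ns (frame i gets time `(i-1) * dt`),
#'   or supply `time` explicitly.
#' @param time optional explicit frame times (ns).
#' @return A [trajectory3d()] object.
#' @export
read_trajectory <- function(path, dt = 0.1, time = NULL) {
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- p$atom
  ele <- a$elesy
  bad <- is.na(ele) | trimws(ele) == ""
  ele[bad] <- infer_element(a$elety[bad])
  atoms <- data.frame(name = trimws(a$elety), element = trimws(ele),
                      resno = a$resno, resid = trimws(a$resid),
                      chain = ifelse(is.na(a$chain), "A", a$chain),
                      stringsAsFactors = FALSE)
  nf <- nrow(p$xyz)
  nat <- nrow(atoms)
  coords <- array(NA_real_, c(nat, 3L, nf))
  for (i in seq_len(nf))
    coords[, , i] <- matrix(p$xyz[i, ], nat, 3L, byrow = TRUE)
  if (is.null(time)) time <- (seq_len(nf) - 1L) * dt
  trajectory3d(atoms, coords, time)
}

#' Write a structure or trajectory to a PDB file
#'
#' Trajectories are written as multi-model PDB (MODEL/ENDMDL).
#'
#' @param x A [structure3d] or [trajectory3d()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "structure3d")) {
    frames <- list(x$xyz)
    atoms <- x$atoms
  } else if (inherits(x, "trajectory3d")) {
    frames <- lapply(seq_len(n_frames(x)), function(i) x$coords[, , i])
    atoms <- x$atoms
  } else stop("x must be a structure3d or trajectory3d")
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (m in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frames[[m]]
    for (i in seq_len(nrow(atoms))) {
      nm <- atoms$name[i]
      nm_fmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      writeLines(sprintf(
        "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        (i - 1L) %% 99999L + 1L, nm_fmt, atoms$resid[i], atoms$chain[i],
        atoms$resno[i], xyz[i, 1L], xyz[i, 2L], xyz[i, 3L], 1, 0,
        atoms$element[i]), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
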