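#' Construct a trajectory object
#'
#' Minimal in-memory trajectory container: an atom table plus a
#' frames x atoms x 3 coordinate array. Atom metadata is assumed constant
#' across frames (the selections resolve once).
#'
#' @param atoms data.frame with columns `name`, `elem`, `resname` (and
#'   optionally `resid`); one row per atom.
#' @param xyz numeric array `[n_frames, n_atoms, 3]`, angstrom.
#' @param time_ps frame times in ps (default `0, dt, ...` with dt = 1).
#' @return object of class `fp_traj`.
#' @export
fp_traj <- function(atoms, xyz, time_ps = NULL) {
  stopifnot(is.data.frame(atoms), length(dim(xyz)) == 3,
            dim(xyz)[2] == nrow(atoms), dim(xyz)[3] == 3)
  if (is.null(time_ps)) time_ps <- seq_len(dim(xyz)[1]) - 1
  stopifnot(length(time_ps) == dim(xyz)[1])
  if (is.unsorted(time_ps, strictly = FALSE)) stop("frames must be time-ordered")
  structure(list(atoms = atoms, xyz = xyz, time_ps = as.numeric(time_ps)),
            class = "fp_traj")
}

#' @export
print.fp_traj <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms\n",
              dim(x$xyz)[1], dim(x$xyz)[2]))
  invisible(x)
}

#' Extract one frame as a coordinate table
#'
#' @param traj an `fp_traj`.
#' @param i frame index.
#' @return data.frame (`fp_frame` layout) with atom metadata plus `x`, `y`,
#'   `z`, suitable for [detect_hbonds()].
#' @export
traj_frame <- function(traj, i = 1L) {
  stopifnot(inherits(traj, "fp_traj"), i >= 1, i <= dim(traj$xyz)[1])
  cbind(traj$atoms,
        data.frame(x = traj$xyz[i, , 1], y = traj$xyz[i, , 2],
                   z = traj$xyz[i, , 3]))
}

#' Read a multi-model PDB file as a trajectory
#'
#' Uses `bio3d::read.pdb(..., multi = TRUE)`; MODEL/ENDMDL blocks become
#' frames. Element symbols are taken from the PDB element column when
#' present, otherwise inferred from the first character of the atom name.
#'
#' @param path PDB file.
#' @param time_ps optional frame times (ps).
#' @return an `fp_traj`.
#' @export
read_pdb_frames <- function(path, time_ps = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  natom <- nrow(pdb$atom)
  xyz_mat <- pdb$xyz
  if (is.null(dim(xyz_mat))) xyz_mat <- matrix(xyz_mat, nrow = 1)
  nf <- nrow(xyz_mat)
  xyz <- array(NA_real_, c(nf, natom, 3))
  for (f in seq_len(nf))
    xyz[f, , ] <- matrix(xyz_mat[f, ], ncol = 3, byrow = TRUE)
  elem <- pdb$atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(gsub("[^A-Za-z].*", "", pdb$atom$elety), 1, 1)
  atoms <- data.frame(name = pdb$atom$elety,
                      elem = toupper(trimws(elem)),
                      resname = pdb$atom$resid,
                      resid = pdb$atom$resno,
                      stringsAsFactors = FALSE)
  fp_traj(atoms, xyz, time_ps)
}

#' Read a concatenated XYZ file as a trajectory
#'
#' Plain multi-frame XYZ: repeated blocks of an atom count line, a comment
#' line and `n` lines of `element x y z`. Atom names are the element
#' symbols, so dihedral selections on XYZ input are usually made by index.
#'
#' @param path XYZ file.
#' @param time_ps optional frame times (ps).
#' @return an `fp_traj`.
#' @export
read_xyz_frames <- function(path, time_ps = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) %% 1 == 0]
  pos <- 1L
  frames <- list()
  elems <- NULL
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", pos)
    block <- lines[(pos + 2L):(pos + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    el <- vapply(toks, `[`, character(1), 1L)
    co <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (is.null(elems)) elems <- el
    else if (!identical(el, elems)) stop("inconsistent atoms across XYZ frames")
    frames[[length(frames) + 1L]] <- co
    pos <- pos + 2L + n
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (length(frames) == 0L) stop("no frames in XYZ file")
  xyz <- array(NA_real_, c(length(frames), length(elems), 3))
  for (f in seq_along(frames)) xyz[f, , ] <- frames[[f]]
  atoms <- data.frame(name = elems, elem = toupper(elems),
                      resname = "XYZ", stringsAsFactors = FALSE)
  fp_traj(atoms, xyz, time_ps)
}

#' Read a per-frame dihedral table
#'
#' CSV with columns `time_ps`, `phi_deg`, `tau_deg`; the planarity
#' deviation `delta_deg` is recomputed (wrapped) on read so the table is
#' self-consistent regardless of how it was produced. This path bypasses
#' coordinate geometry entirely.
#'
#' @param path CSV file.
#' @return data.frame with `time_ps`, `phi_deg`, `tau_deg`, `delta_deg`.
#' @export
read_dihedral_csv <- function(path) {
  d <- read.csv(path)
  need <- c("time_ps", "phi_deg", "tau_deg")
  if (!all(need %in% names(d)))
    stop("dihedral CSV must have columns: ", paste(need, collapse = ", "))
  d$phi_deg <- wrap_angle(d$phi_deg)
  d$tau_deg <- wrap_angle(d$tau_deg)
  d$delta_deg <- wrap_angle(d$phi_deg - d$tau_deg)
  d[, c("time_ps", "phi_deg", "tau_deg", "delta_deg")]
}
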