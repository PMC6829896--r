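#' Wrap angles to the signed interval (-180, 180]
#'
#' @param x angle(s) in degrees.
#' @return wrapped angle(s); -180 maps to +180.
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Signed dihedral angle of four points
#'
#' Standard signed torsion about the p2->p3 axis (right-hand convention,
#' atan2 formulation), returned in degrees in (-180, 180]. A planar cis
#' arrangement gives 0, planar trans gives 180. The value is invariant
#' under rigid rotation/translation and under reversal of the atom path.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (angstrom).
#' @return signed dihedral in degrees.
#' @examples
#' compute_dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))  # 0 (cis)
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b2^2) == 0) stop("degenerate geometry: zero-length central bond")
  n1 <- .cross3(b0, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("degenerate geometry: collinear points")
  e <- b2 / sqrt(sum(b2^2))
  v <- b0 - sum(b0 * e) * e
  w <- b3 - sum(b3 * e) * e
  ang <- atan2(sum(.cross3(e, v) * w), sum(v * w)) * 180 / pi
  wrap_angle(ang)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Atom selection defining the chromophore dihedrals
#'
#' Names the four-atom paths of the two methine-bridge torsions of a
#' GFP-like chromophore: the phenolate flip phi (CD-CG-CB-CA) and the
#' imidazolinone dihedral tau (CG-CB-CA-N). Atoms are matched by name
#' within the chromophore residue of each frame.
#'
#' @param phi_path,tau_path character(4) atom names.
#' @param resname chromophore residue name used to restrict the match
#'   (default "CRO"); set `NULL` to match names over the whole frame.
#' @return an object of class `atom_selection`.
#' @export
atom_selection <- function(phi_path = c("CD", "CG", "CB", "CA"),
                           tau_path = c("CG", "CB", "CA", "N"),
                           resname = "CRO") {
  stopifnot(length(phi_path) == 4, length(tau_path) == 4,
            !anyDuplicated(phi_path), !anyDuplicated(tau_path))
  structure(list(phi_path = phi_path, tau_path = tau_path,
                 resname = resname),
            class = "atom_selection")
}

.resolve_path <- function(atoms, path, resname) {
  pool <- if (is.null(resname)) seq_len(nrow(atoms)) else
    which(atoms$resname == resname)
  idx <- vapply(path, function(nm) {
    hit <- pool[atoms$name[pool] == nm]
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  idx
}

#' Chromophore torsions along a trajectory
#'
#' Computes the phi and tau dihedrals (and the planarity deviation
#' Delta = phi - tau, wrapped) for every frame of a coordinate trajectory.
#' Atom names are resolved once against the atom table and the same indices
#' are used in all frames.
#'
#' @param traj an `fp_traj` object ([read_pdb_frames()], [read_xyz_frames()]
#'   or [fp_traj()]).
#' @param sel an [atom_selection()].
#' @return data.frame with columns `time_ps`, `phi_deg`, `tau_deg`,
#'   `delta_deg` (one row per frame).
#' @export
chromophore_dihedrals <- function(traj, sel = atom_selection()) {
  stopifnot(inherits(traj, "fp_traj"), inherits(sel, "atom_selection"))
  i_phi <- .resolve_path(traj$atoms, sel$phi_path, sel$resname)
  i_tau <- .resolve_path(traj$atoms, sel$tau_path, sel$resname)
  for (k in which(is.na(i_phi)))
    stop("atom '", sel$phi_path[k], "' not found for phi path")
  for (k in which(is.na(i_tau)))
    stop("atom '", sel$tau_path[k], "' not found for tau path")
  nf <- dim(traj$xyz)[1]
  phi <- tau <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- traj$xyz[f, , , drop = TRUE]
    if (anyNA(xyz[c(i_phi, i_tau), ]))
      stop("missing coordinates in frame ", f)
    phi[f] <- compute_dihedral(xyz[i_phi[1], ], xyz[i_phi[2], ],
                               xyz[i_phi[3], ], xyz[i_phi[4], ])
    tau[f] <- compute_dihedral(xyz[i_tau[1], ], xyz[i_tau[2], ],
                               xyz[i_tau[3], ], xyz[i_tau[4], ])
  }
  data.frame(time_ps = traj$time_ps,
             phi_deg = phi, tau_deg = tau,
             delta_deg = wrap_angle(phi - tau))
}

#' Hydrogen-bond detection criteria
#'
#' Geometric criteria for counting hydrogen bonds around the chromophore:
#' donor-acceptor heavy-atom distance cutoff, maximum deviation of the
#' D-H...A angle from linearity, and the radius of the census region around
#' the chromophore. The angle cutoff is interpreted as deviation from
#' linearity (cutoff 20 means D-H...A >= 160 degrees).
#'
#' @param distance_cutoff angstrom, donor-acceptor heavy-atom distance.
#' @param angle_cutoff degrees, deviation from D-H...A linearity (< 90).
#' @param region_radius angstrom around chromophore heavy atoms.
#' @param bond_max angstrom; a hydrogen within this distance of an N/O
#'   heavy atom is considered covalently bonded to it (donor inference).
#' @return an object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(distance_cutoff = 3.2, angle_cutoff = 20,
                           region_radius = 6, bond_max = 1.2) {
  stopifnot(distance_cutoff > 0, angle_cutoff > 0, angle_cutoff < 90,
            region_radius > 0, bond_max > 0)
  structure(list(distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff,
                 region_radius = region_radius,
                 bond_max = bond_max),
            class = "hbond_criteria")
}

#' Detect hydrogen bonds around a chromophore in one frame
#'
#' Donors and acceptors are N and O heavy atoms; a donor must carry a
#' hydrogen (inferred by a D-H distance below `crit$bond_max` when no
#' connectivity is supplied). A triple (D, H, A) is counted when the
#' heavy-atom distance D...A is at most the distance cutoff and the
#' D-H...A angle deviates from linearity by at most the angle cutoff.
#' Two census modes are provided, because "bonds within a radius of the
#' chromophore" can mean either:
#'
#' * `"shell"` (default): any bond with at least one heavy-atom partner
#'   within `region_radius` of any chromophore heavy atom;
#' * `"chromophore"`: only bonds in which the donor or acceptor belongs to
#'   the chromophore itself.
#'
#' @param frame a single-frame `fp_frame` data.frame (columns `name`,
#'   `elem`, `resname`, `x`, `y`, `z`), e.g. one element of
#'   [gen_hbond_frames()] output or [traj_frame()].
#' @param chromophore integer indices of chromophore atoms, or a residue
#'   name (default "CRO") matched against `frame$resname`.
#' @param crit an [hbond_criteria()].
#' @param mode `"shell"` or `"chromophore"`.
#' @return data.frame with one row per bond: `donor`, `hydrogen`,
#'   `acceptor` (row indices into `frame`), `dist_DA`, `deviation_deg`.
#' @export
detect_hbonds <- function(frame, chromophore = "CRO",
                          crit = hbond_criteria(),
                          mode = c("shell", "chromophore")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(frame),
            all(c("name", "elem", "x", "y", "z") %in% names(frame)))
  if (is.character(chromophore)) {
    if (!"resname" %in% names(frame)) stop("frame lacks resname column")
    chrom_idx <- which(frame$resname %in% chromophore)
  } else chrom_idx <- as.integer(chromophore)
  if (length(chrom_idx) == 0L) stop("no chromophore atoms in frame")
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  heavy <- frame$elem != "H"
  chrom_heavy <- intersect(chrom_idx, which(heavy))
  if (length(chrom_heavy) == 0L) stop("no chromophore heavy atoms in frame")
  no_idx <- which(frame$elem %in% c("N", "O"))
  h_idx <- which(frame$elem == "H")
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), dist_DA = numeric(0),
                      deviation_deg = numeric(0))
  if (length(no_idx) < 2L || length(h_idx) == 0L) return(empty)

  # donor-hydrogen covalent pairs
  dh <- expand.grid(D = no_idx, H = h_idx)
  d_dh <- sqrt(rowSums((xyz[dh$D, , drop = FALSE] -
                        xyz[dh$H, , drop = FALSE])^2))
  dh <- dh[d_dh <= crit$bond_max, , drop = FALSE]
  if (nrow(dh) == 0L) return(empty)

  out <- empty
  for (r in seq_len(nrow(dh))) {
    D <- dh$D[r]; H <- dh$H[r]
    acc <- setdiff(no_idx, D)
    if (length(acc) == 0L) next
    dDA <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[D, ])^2))
    keep <- dDA <= crit$distance_cutoff
    acc <- acc[keep]; dDA <- dDA[keep]
    if (length(acc) == 0L) next
    # exclude acceptors covalently bonded to this hydrogen
    dHA <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[H, ])^2))
    keep <- dHA > crit$bond_max
    acc <- acc[keep]; dDA <- dDA[keep]; dHA <- dHA[keep]
    if (length(acc) == 0L) next
    v1 <- xyz[D, ] - xyz[H, ]
    dev <- vapply(seq_along(acc), function(j) {
      v2 <- xyz[acc[j], ] - xyz[H, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    }, numeric(1))
    keep <- dev <= crit$angle_cutoff
    acc <- acc[keep]; dDA <- dDA[keep]; dev <- dev[keep]
    if (length(acc) == 0L) next
    out <- rbind(out, data.frame(donor = D, hydrogen = H, acceptor = acc,
                                 dist_DA = dDA, deviation_deg = dev))
  }
  if (nrow(out) == 0L) return(empty)

  in_region <- switch(mode,
    shell = {
      near <- function(i) min(sqrt(colSums(
        (t(xyz[chrom_heavy, , drop = FALSE]) - xyz[i, ])^2))) <=
        crit$region_radius
      vapply(seq_len(nrow(out)),
             function(r) near(out$donor[r]) || near(out$acceptor[r]),
             logical(1))
    },
    chromophore = out$donor %in% chrom_idx | out$acceptor %in% chrom_idx)
  out <- out[in_region, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Planarity and hydrogen-bond statistics over a trajectory
#'
#' Summarises the chromophore planarity deviation Delta and the per-frame
#' hydrogen-bond counts: means and standard deviations over frames. The
#' population estimator (divide by n) is the default, matching the
#' convention for trajectory statistics where frames are the population of
#' interest; the sample estimator is available via `estimator`.
#'
#' @param delta_deg numeric vector of per-frame Delta values (degrees);
#'   pass `abs(delta)` if the unsigned deviation is wanted.
#' @param hbond_counts optional integer vector of per-frame bond counts
#'   (same length as `delta_deg`).
#' @param estimator `"population"` (default) or `"sample"`.
#' @return list of class `planarity_stats`: `mean_delta`, `std_delta`,
#'   `mean_hbonds`, `std_hbonds`, `n_frames`.
#' @export
planarity_stats <- function(delta_deg, hbond_counts = NULL,
                            estimator = c("population", "sample")) {
  estimator <- match.arg(estimator)
  n <- length(delta_deg)
  if (n < 1L) stop("empty trace")
  if (!is.null(hbond_counts) && length(hbond_counts) != n)
    stop("hbond_counts length must match delta_deg")
  stdev <- function(x) {
    if (estimator == "population") sqrt(mean((x - mean(x))^2))
    else if (length(x) > 1L) sd(x) else 0
  }
  structure(list(
    mean_delta = mean(delta_deg), std_delta = stdev(delta_deg),
    mean_hbonds = if (is.null(hbond_counts)) NA_real_ else mean(hbond_counts),
    std_hbonds = if (is.null(hbond_counts)) NA_real_ else stdev(hbond_counts),
    n_frames = n), class = "planarity_stats")
}

#' @export
print.planarity_stats <- function(x, ...) {
  cat(sprintf("Planarity: mean Delta %.2f deg (std %.2f), %d frames\n",
              x$mean_delta, x$std_delta, x$n_frames))
  if (!is.na(x$mean_hbonds))
    cat(sprintf("H-bonds:   mean %.2f (std %.2f)\n",
                x$mean_hbonds, x$std_hbonds))
  invisible(x)
}
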