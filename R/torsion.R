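#' Cosine-series torsional potential
#'
#' Force-field torsional potential
#' \deqn{V(\theta) = \sum_n K_n [1 + \cos(n\theta - \delta_n)] + offset,}
#' with force constants `K_n` (kcal/mol), distinct integer multiplicities
#' `n` and phases `delta_n` in degrees (conventionally 0 or 180). The
#' optional `offset` absorbs the constant left over when fitting data whose
#' minimum is shifted to zero; it never affects barrier heights.
#'
#' @param K numeric force constants, kcal/mol (nonnegative by convention;
#'   a negative K is folded into a 180-degree phase shift).
#' @param multiplicity positive integers, distinct.
#' @param phase_deg phases in degrees (recycled).
#' @param offset constant energy shift, kcal/mol.
#' @return object of class `torsion_potential`.
#' @examples
#' pot <- torsion_potential(K = 1.795, multiplicity = 2, phase_deg = 180)
#' barrier_height(pot)  # 3.59
#' @export
torsion_potential <- function(K, multiplicity, phase_deg = 0, offset = 0) {
  stopifnot(length(K) == length(multiplicity),
            all(multiplicity == round(multiplicity)), all(multiplicity >= 1),
            !anyDuplicated(multiplicity))
  phase_deg <- rep_len(phase_deg, length(K))
  neg <- K < 0
  K[neg] <- -K[neg]
  phase_deg[neg] <- wrap_angle(phase_deg[neg] + 180)
  structure(list(K = as.numeric(K),
                 multiplicity = as.integer(multiplicity),
                 phase_deg = as.numeric(phase_deg),
                 offset = as.numeric(offset)),
            class = "torsion_potential")
}

#' Evaluate a torsional potential
#'
#' @param pot a [torsion_potential()].
#' @param theta_deg angle(s) in degrees.
#' @return energy in kcal/mol.
#' @export
eval_torsion <- function(pot, theta_deg) {
  stopifnot(inherits(pot, "torsion_potential"))
  th <- theta_deg * pi / 180
  v <- rep(pot$offset, length(th))
  for (j in seq_along(pot$K))
    v <- v + pot$K[j] *
      (1 + cos(pot$multiplicity[j] * th - pot$phase_deg[j] * pi / 180))
  v
}

#' @export
print.torsion_potential <- function(x, ...) {
  cat("Cosine-series torsional potential:\n")
  for (j in seq_along(x$K))
    cat(sprintf("  K = %.4g kcal/mol, n = %d, delta = %g deg\n",
                x$K[j], x$multiplicity[j], x$phase_deg[j]))
  if (x$offset != 0) cat(sprintf("  offset = %.4g kcal/mol\n", x$offset))
  invisible(x)
}

#' Fit a cosine-series torsional potential to a PES scan
#'
#' Linear least-squares fit of relative scan energies to the cosine series.
#' Internally the model is `E = c0 + sum_n A_n cos(n theta)`; fitted
#' amplitudes are converted to the force-field convention `K_n = |A_n|`
#' with phase 0 (A_n > 0) or 180 degrees (A_n < 0), and the residual
#' constant `c0 - sum K_n (1 + cos(delta_n))/1` is stored as `offset` (it is
#' exactly zero for scans generated from the model class). The scan is
#' shifted so its minimum is zero before fitting, matching the convention
#' of relative PES scans.
#'
#' @param scan data.frame with columns `angle_deg`, `energy_kcal` (an
#'   optional `state`/`dihedral` label is carried through untouched).
#' @param multiplicities integer set of multiplicities (default 1:3).
#' @return list of class `torsion_fit`: `potential`
#'   ([torsion_potential()]), `rms_residual`, `residuals`, `fitted`.
#' @examples
#' th <- seq(-180, 170, by = 10)
#' scan <- data.frame(angle_deg = th, energy_kcal = 8 * (1 + cos(2 * th * pi / 180)))
#' fit_torsion_potential(scan, multiplicities = 2)$potential
#' @export
fit_torsion_potential <- function(scan, multiplicities = 1:3) {
  stopifnot(is.data.frame(scan),
            all(c("angle_deg", "energy_kcal") %in% names(scan)))
  multiplicities <- sort(unique(as.integer(multiplicities)))
  if (nrow(scan) < length(multiplicities) + 1L)
    stop("underdetermined: fewer scan points than free coefficients")
  if (any(!is.finite(scan$energy_kcal))) stop("non-finite scan energies")
  th <- scan$angle_deg * pi / 180
  E <- scan$energy_kcal - min(scan$energy_kcal)
  X <- vapply(multiplicities, function(n) cos(n * th),
              numeric(length(th)))
  X <- cbind(`(c0)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("underdetermined multiplicity set: scan grid cannot resolve all terms")
  beta <- qr.coef(qrX, E)
  A <- beta[-1]
  c0 <- beta[1]
  pot <- torsion_potential(K = abs(A), multiplicity = multiplicities,
                           phase_deg = ifelse(A >= 0, 0, 180))
  # the form already carries a constant sum(K); any excess goes to offset
  pot$offset <- unname(c0 - sum(pot$K))
  fitted <- eval_torsion(pot, scan$angle_deg)
  res <- E - fitted
  structure(list(potential = pot,
                 rms_residual = sqrt(mean(res^2)),
                 residuals = res, fitted = fitted),
            class = "torsion_fit")
}

#' Barrier height of a torsional potential
#'
#' Maximum minus minimum of V over one full period, located on a dense
#' grid (0.01 degree by default) and refined by local optimisation, so the
#' result matches brute-force evaluation to high accuracy.
#'
#' @param pot a [torsion_potential()].
#' @param grid_step_deg coarse-location grid step, degrees.
#' @return barrier height in kcal/mol (0 for a constant potential).
#' @export
barrier_height <- function(pot, grid_step_deg = 0.01) {
  stopifnot(inherits(pot, "torsion_potential"))
  if (length(pot$K) == 0L || all(pot$K == 0)) return(0)
  th <- seq(-180, 180, by = grid_step_deg)
  v <- eval_torsion(pot, th)
  i_max <- which.max(v); i_min <- which.min(v)
  refine <- function(i, maximum) {
    lo <- th[max(1L, i - 2L)]; hi <- th[min(length(th), i + 2L)]
    optimize(function(x) eval_torsion(pot, x),
             interval = c(lo, hi), maximum = maximum,
             tol = 1e-10)$objective
  }
  refine(i_max, TRUE) - refine(i_min, FALSE)
}

#' Reconstructed torsional potentials of the GYG model chromophore
#'
#' Single-term cosine potentials whose barriers match ab initio barrier
#' heights for the isolated GYG chromophore: ground state (S0) barriers of
#' 31.61 kcal/mol (phi, phenolate flip) and 34.47 kcal/mol (tau,
#' imidazolinone flip), and excited state (S1) barriers of 3.59 and
#' 4.52 kcal/mol. Only the barrier heights are constrained by the source
#' scans, so these potentials are *reconstructed* (minimum at the planar
#' geometry, multiplicity 2), not scan-exact; they parametrise the
#' Langevin mode of [gen_twist_trajectories()].
#'
#' @return named list of [torsion_potential()] objects: `s0_phi`, `s0_tau`,
#'   `s1_phi`, `s1_tau`.
#' @export
gyg_torsion_potentials <- function() {
  mk <- function(barrier)
    torsion_potential(K = barrier / 2, multiplicity = 2, phase_deg = 180)
  list(s0_phi = mk(31.61), s0_tau = mk(34.47),
       s1_phi = mk(3.59),  s1_tau = mk(4.52))
}
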