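#' Physical constants describing the emitting medium
#'
#' Bundles the constants entering the radiative-lifetime expression: the
#' speed of light in atomic units, the refractive index `n` and dielectric
#' constant `epsilon` of the medium, and the unit conversions used to move
#' between eV, hartree and nanoseconds. The default speed of light is the
#' round value 137 a.u.; pass `c_au = 137.035999` for the CODATA value
#' (changes lifetimes by under 0.1%).
#'
#' @param c_au speed of light in vacuum, atomic units.
#' @param n refractive index of the medium (>= 1). Protein solutions are
#'   commonly taken as ~1.6; water is 1.33.
#' @param epsilon dielectric constant of the medium (>= 1).
#' @param ev_per_hartree energy conversion, eV per hartree.
#' @param atomic_time_s one atomic time unit in seconds.
#' @return an object of class `medium_constants`.
#' @examples
#' medium_constants()            # vacuum
#' medium_constants(n = 1.6)     # protein-solution refractivity
#' @export
medium_constants <- function(c_au = 137, n = 1, epsilon = 1,
                             ev_per_hartree = 27.211386,
                             atomic_time_s = 2.4188843e-17) {
  stopifnot(c_au > 0, n >= 1, epsilon >= 1,
            ev_per_hartree > 0, atomic_time_s > 0)
  structure(list(c_au = c_au, n = n, epsilon = epsilon,
                 ev_per_hartree = ev_per_hartree,
                 atomic_time_s = atomic_time_s),
            class = "medium_constants")
}

#' Intrinsic radiative lifetime from excitation energy and oscillator strength
#'
#' The radiative (fluorescence) lifetime of a transition is inversely
#' proportional to its oscillator strength \eqn{f} and to the square of the
#' excitation energy \eqn{E}: in atomic units
#' \deqn{1/\tau_{fl} = E^2 f / (2\pi (c/n)^3 \epsilon).}
#' The energy is supplied in eV, converted internally to hartree, and the
#' result is returned in nanoseconds. At fixed `epsilon` the lifetime scales
#' as \eqn{n^3} when only the refractive index changes.
#'
#' An alternative medium correction in which the refractive index enters
#' quadratically through the transition rate (Strickler-Berg-like,
#' \eqn{1/\tau \propto n^2 E^2 f}) is available via
#' `correction = "strickler_berg"`; the default `"cubic"` places the full
#' \eqn{(c/n)^3} factor in the rate denominator.
#'
#' @param E_ex_eV vertical excitation energy in eV (> 0). Vectorised.
#' @param f_l dimensionless oscillator strength (>= 0). Vectorised.
#' @param medium a [medium_constants()] object.
#' @param correction `"cubic"` (default) or `"strickler_berg"`.
#' @return radiative lifetime(s) in ns; `Inf` where `f_l` is 0.
#' @examples
#' radiative_lifetime(3.101, 1.02)                         # ~29.50 ns
#' radiative_lifetime(3.081, 0.97, medium_constants(n = 1.6))
#' @export
radiative_lifetime <- function(E_ex_eV, f_l, medium = medium_constants(),
                               correction = c("cubic", "strickler_berg")) {
  correction <- match.arg(correction)
  stopifnot(inherits(medium, "medium_constants"))
  if (any(!is.finite(E_ex_eV)) || any(E_ex_eV <= 0))
    stop("excitation energies must be positive and finite")
  if (any(!is.finite(f_l)) || any(f_l < 0))
    stop("oscillator strengths must be nonnegative and finite")
  E_h <- E_ex_eV / medium$ev_per_hartree
  rate_au <- switch(correction,
    cubic = E_h^2 * f_l / (2 * pi * (medium$c_au / medium$n)^3 * medium$epsilon),
    strickler_berg = medium$n^2 * E_h^2 * f_l /
      (2 * pi * medium$c_au^3 * medium$epsilon))
  tau_ns <- ifelse(f_l == 0, Inf, (1 / rate_au) * medium$atomic_time_s * 1e9)
  tau_ns
}

#' Ensemble radiative lifetime over QM/MM snapshots
#'
#' Averages per-snapshot excitation energies and oscillator strengths (for
#' example, 21 snapshots from a ground-state equilibrium trajectory) into a
#' single radiative lifetime. Two averaging conventions are reported:
#'
#' * `"rate"` (default): rates add over the ensemble, so the lifetime is the
#'   inverse of the mean per-snapshot radiative rate,
#'   \eqn{1/\tau = \langle E^2 f \rangle \cdot const};
#' * `"mean_parameter"`: the lifetime evaluated at the ensemble means,
#'   \eqn{\tau(\langle E \rangle, \langle f \rangle)}.
#'
#' The two differ whenever \eqn{E^2 f} fluctuates (Jensen's inequality:
#' rate-averaging never exceeds the mean-parameter lifetime). Both are
#' returned; `mode` selects which fills `tau_fl_ns`.
#'
#' @param snapshots a data.frame with columns `E_ex_eV` and `f_l` (one row
#'   per snapshot), e.g. from [gen_snapshot_ensemble()].
#' @param medium a [medium_constants()] object.
#' @param mode `"rate"` or `"mean_parameter"`.
#' @return a list with `mean_E_eV`, `mean_f`, `tau_fl_ns`, `tau_rate_ns`,
#'   `tau_mean_parameter_ns`, `n_snapshots`.
#' @export
ensemble_radiative <- function(snapshots, medium = medium_constants(),
                               mode = c("rate", "mean_parameter")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(snapshots),
            all(c("E_ex_eV", "f_l") %in% names(snapshots)))
  if (nrow(snapshots) < 1L) stop("need at least one snapshot")
  tau_i <- radiative_lifetime(snapshots$E_ex_eV, snapshots$f_l, medium)
  tau_rate <- 1 / mean(1 / tau_i)
  tau_mp <- radiative_lifetime(mean(snapshots$E_ex_eV), mean(snapshots$f_l),
                               medium)
  list(mean_E_eV = mean(snapshots$E_ex_eV),
       mean_f = mean(snapshots$f_l),
       tau_fl_ns = if (mode == "rate") tau_rate else tau_mp,
       tau_rate_ns = tau_rate,
       tau_mean_parameter_ns = tau_mp,
       n_snapshots = nrow(snapshots))
}

#' Apparent excited-state lifetime
#'
#' The observable fluorescence lifetime results from the parallel radiative
#' and non-radiative decay channels: \eqn{1/\tau = 1/\tau_{fl} + 1/\tau_{nr}}.
#' An unbounded (`Inf`) non-radiative lifetime returns `tau_fl_ns` itself.
#'
#' @param tau_fl_ns radiative lifetime, ns (> 0). Vectorised.
#' @param tau_nr_ns radiationless lifetime, ns (> 0, may be `Inf`). Vectorised.
#' @return apparent lifetime in ns.
#' @examples
#' apparent_lifetime(7.63, 5.92)  # 3.33 ns
#' @export
apparent_lifetime <- function(tau_fl_ns, tau_nr_ns) {
  .check_lifetimes(tau_fl_ns, tau_nr_ns)
  1 / (1 / tau_fl_ns + 1 / tau_nr_ns)
}

#' Fluorescence quantum yield from the two-channel model
#'
#' The quantum yield is the branching fraction of the radiative channel,
#' \eqn{FQY = k_{fl}/(k_{fl}+k_{nr}) = \tau_{nr}/(\tau_{fl}+\tau_{nr})},
#' identically equal to `apparent_lifetime / tau_fl`.
#'
#' @inheritParams apparent_lifetime
#' @return quantum yield in \[0, 1\].
#' @examples
#' quantum_yield(7.63, 5.92)  # 0.44
#' @export
quantum_yield <- function(tau_fl_ns, tau_nr_ns) {
  .check_lifetimes(tau_fl_ns, tau_nr_ns)
  ifelse(is.infinite(tau_nr_ns), 1, tau_nr_ns / (tau_fl_ns + tau_nr_ns))
}

.check_lifetimes <- function(tau_fl_ns, tau_nr_ns) {
  if (any(is.na(tau_fl_ns)) || any(tau_fl_ns <= 0) || any(is.infinite(tau_fl_ns)))
    stop("tau_fl_ns must be positive and finite")
  if (any(is.na(tau_nr_ns)) || any(tau_nr_ns <= 0))
    stop("tau_nr_ns must be positive (Inf allowed)")
  invisible(TRUE)
}

#' Bleaching yield within first-order photocycle kinetics
#'
#' For a bleaching process with characteristic time `tau_bl_ns` competing
#' with the excited-state decay, the yield of bleached product per
#' excitation is \eqn{Y_{bl} = \tau/\tau_{bl}}: systems with shorter
#' apparent lifetimes bleach less per absorbed photon.
#'
#' @param tau_ns apparent excited-state lifetime, ns. Vectorised.
#' @param tau_bl_ns bleaching lifetime, ns (> 0).
#' @return dimensionless bleaching yield.
#' @export
bleaching_yield <- function(tau_ns, tau_bl_ns) {
  if (any(is.na(tau_bl_ns)) || any(tau_bl_ns <= 0)) stop("tau_bl_ns must be positive")
  if (any(is.na(tau_ns)) || any(tau_ns < 0)) stop("tau_ns must be nonnegative")
  tau_ns / tau_bl_ns
}

#' Relative photostability from relative bleaching yields
#'
#' Photostability is inversely proportional to the bleaching yield, so given
#' bleaching yields relative to a reference protein (under the assumption of
#' a common bleaching rate, relative yields equal relative apparent
#' lifetimes) the relative photostabilities are their inverses.
#'
#' @param y_bl_rel numeric vector of bleaching yields relative to a
#'   reference (the reference itself has value 1).
#' @return vector of relative photostabilities, `1 / y_bl_rel`.
#' @examples
#' relative_photostability(c(1.0, 0.1, 0.4, 1.4))  # 1 10 2.5 0.714...
#' @export
relative_photostability <- function(y_bl_rel) {
  if (any(is.na(y_bl_rel)) || any(y_bl_rel <= 0))
    stop("relative bleaching yields must be positive")
  1 / y_bl_rel
}

#' Assemble a photocycle summary table for a set of proteins
#'
#' Combines per-protein radiative and radiationless lifetimes into the full
#' photocycle summary: apparent lifetime, fluorescence quantum yield,
#' columns relative to a reference protein, relative bleaching yield
#' (assuming a common bleaching rate, so relative yield equals relative
#' apparent lifetime) and relative photostability. All quantities are kept
#' at full precision; `display = TRUE` on [print()] shows the conventional
#' rounded report (lifetimes and FQY to 2 decimals, relative columns to the
#' table precision, photostabilities computed from the rounded relative
#' yields as such tables conventionally print them).
#'
#' @param lifetimes data.frame with columns `protein`, `tau_fl_ns`,
#'   `tau_nr_ns`; protein labels must be unique.
#' @param reference label of the reference protein (must appear in
#'   `lifetimes$protein`).
#' @return a data.frame of class `photocycle_table` with columns `protein`,
#'   `tau_fl_ns`, `tau_nr_ns`, `tau_ns`, `fqy`, `tau_fl_rel`, `tau_nr_rel`,
#'   `tau_rel`, `y_bl_rel`, `photostability_rel`, plus attribute
#'   `reference`.
#' @examples
#' photocycle_table(fp_reference_lifetimes(), reference = "EGFP")
#' @export
photocycle_table <- function(lifetimes, reference) {
  stopifnot(is.data.frame(lifetimes),
            all(c("protein", "tau_fl_ns", "tau_nr_ns") %in% names(lifetimes)))
  if (anyDuplicated(lifetimes$protein))
    stop("duplicate protein labels")
  if (!reference %in% lifetimes$protein)
    stop("reference protein '", reference, "' not among inputs")
  tau <- apparent_lifetime(lifetimes$tau_fl_ns, lifetimes$tau_nr_ns)
  fqy <- quantum_yield(lifetimes$tau_fl_ns, lifetimes$tau_nr_ns)
  i_ref <- match(reference, lifetimes$protein)
  out <- data.frame(
    protein = lifetimes$protein,
    tau_fl_ns = lifetimes$tau_fl_ns,
    tau_nr_ns = lifetimes$tau_nr_ns,
    tau_ns = tau,
    fqy = fqy,
    tau_fl_rel = lifetimes$tau_fl_ns / lifetimes$tau_fl_ns[i_ref],
    tau_nr_rel = lifetimes$tau_nr_ns / lifetimes$tau_nr_ns[i_ref],
    tau_rel = tau / tau[i_ref],
    stringsAsFactors = FALSE)
  # common bleaching rate assumed: relative yield == relative apparent lifetime
  out$y_bl_rel <- out$tau_rel
  out$photostability_rel <- relative_photostability(out$y_bl_rel)
  attr(out, "reference") <- reference
  class(out) <- c("photocycle_table", "data.frame")
  out
}

#' @export
print.photocycle_table <- function(x, display = TRUE, ...) {
  cat("Photocycle summary (reference: ", attr(x, "reference"), ")\n", sep = "")
  if (!display) { print.data.frame(x, ...); return(invisible(x)) }
  # conventional display rounding; photostability printed from the rounded
  # relative yield, matching how such summary tables are reported
  d <- data.frame(
    protein = x$protein,
    tau_fl_ns = sprintf("%.2f (%.2f)", x$tau_fl_ns, x$tau_fl_rel),
    tau_nr_ns = sprintf("%.2f (%.2f)", x$tau_nr_ns, x$tau_nr_rel),
    tau_ns = sprintf("%.2f (%.1f)", x$tau_ns, x$tau_rel),
    fqy = sprintf("%.2f", x$fqy),
    y_bl_rel = sprintf("%.1f", x$y_bl_rel),
    photostab = sprintf("%.2g", 1 / round(x$y_bl_rel, 1)),
    stringsAsFactors = FALSE)
  print.data.frame(d, row.names = FALSE)
  invisible(x)
}

#' Reference computed lifetimes for the EGFP/EYFP variant family
#'
#' Bundled example inputs for [photocycle_table()]: radiative lifetimes
#' (from excitation energies and oscillator strengths of QM/MM snapshot
#' ensembles, evaluated at refractive index 1.6) and radiationless
#' half-lives (from first-order fits of excited-state twisting survival
#' curves) for EGFP, its T65G mutant, EYFP, its G65T mutant and
#' halide-bound EYFP. These are computed estimates for the anionic
#' chromophores, shipped as a worked-example dataset.
#'
#' @return data.frame with columns `protein`, `tau_fl_ns`, `tau_nr_ns`.
#' @export
fp_reference_lifetimes <- function() {
  data.frame(
    protein = c("EGFP", "EGFP-T65G", "EYFP", "EYFP-G65T", "EYFP+Cl"),
    tau_fl_ns = c(7.63, 6.88, 7.02, 7.94, 6.97),
    tau_nr_ns = c(5.92, 0.25, 1.73, 10.8, 0.57),
    stringsAsFactors = FALSE)
}

#' Reference electronic-structure data for the EGFP/EYFP variant family
#'
#' Bundled example excitation energies (eV) and oscillator strengths for the
#' anionic TYG and GYG model chromophores: gas-phase values for the isolated
#' chromophores and ensemble means over 21 QM/MM snapshots from ground-state
#' equilibrium dynamics. Used in worked examples for
#' [radiative_lifetime()] and [ensemble_radiative()].
#'
#' @return data.frame with columns `protein`, `E_gas_eV`, `f_gas`,
#'   `E_qmmm_eV`, `f_qmmm`.
#' @export
fp_reference_electronic <- function() {
  data.frame(
    protein = c("EGFP", "EGFP-T65G", "EYFP", "EYFP-G65T", "EYFP+Cl"),
    E_gas_eV = c(3.101, 3.123, 3.123, 3.101, 3.123),
    f_gas    = c(1.02, 1.05, 1.05, 1.02, 1.05),
    E_qmmm_eV = c(3.081, 3.142, 3.097, 3.015, 3.077),
    f_qmmm    = c(0.97, 1.04, 1.05, 0.98, 1.07),
    stringsAsFactors = FALSE)
}
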