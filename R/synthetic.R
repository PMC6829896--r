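#' Generate excited-state twist trajectories with known ground truth
#'
#' Emulates the excited-state molecular-dynamics protocol used to measure
#' radiationless twisting kinetics: an ensemble of trajectories (default
#' 101) propagated over a fixed window (default 3 ns) with snapshots saved
#' on a regular grid (default 2.5 ps); a trajectory is stopped at the
#' first saved frame where the phenolate-flip dihedral exceeds the twist
#' threshold (irreversible crossing), and trajectories that never cross
#' are censored at the window end.
#'
#' Two generative modes:
#'
#' * `"exponential"` (default): first-passage times are drawn from
#'   Exp(`k_per_ns`), matching the first-order kinetics the survival
#'   analysis assumes. Below its crossing each trace jitters as a
#'   (clamped) Gaussian with standard deviation `sigma_phi_deg` around the
#'   planar geometry; at the crossing sample the trace exceeds the
#'   threshold.
#' * `"langevin"`: overdamped Brownian dynamics on a supplied torsional
#'   potential, integrated by Euler-Maruyama at `internal_dt_fs` and
#'   subsampled to the save grid. Exercises the full geometry pipeline and
#'   the coupling to fitted torsion potentials; crossings emerge from the
#'   barrier height, temperature and diffusion coefficient rather than
#'   from an imposed rate.
#'
#' @param k_per_ns first-order twisting rate (mode `"exponential"`);
#'   `k = 0` means no decay (all trajectories censored).
#' @param mode `"exponential"` or `"langevin"`.
#' @param potential a [torsion_potential()] (mode `"langevin"`), e.g.
#'   `gyg_torsion_potentials()$s1_phi`.
#' @param diffusion_rad2_ns angular diffusion coefficient, rad^2/ns
#'   (mode `"langevin"`).
#' @param temperature_K temperature for the Langevin force balance.
#' @param n_traj number of trajectories (default 101).
#' @param dt_ps save interval, ps (default 2.5).
#' @param t_max_ns observation window, ns (default 3).
#' @param threshold_deg twist threshold, degrees (default 50).
#' @param sigma_phi_deg sub-threshold jitter width, degrees (default 16.7,
#'   a typical planarity-fluctuation width for these chromophores).
#' @param internal_dt_fs Euler-Maruyama step, fs (default 2.5).
#' @param emit_traces materialise per-trajectory phi traces (set FALSE for
#'   large ensembles where only the events are needed).
#' @param seed optional integer seed; fixed seed gives bit-identical output.
#' @return list of class `twist_sim`: `traces` (list of phi vectors, or
#'   NULL), `events` (a `twist_events` data.frame with bookkept grid
#'   crossing times), `truth` (continuous first-passage times where
#'   defined), `params`.
#' @export
gen_twist_trajectories <- function(k_per_ns = log(2) / 5.92,
                                   mode = c("exponential", "langevin"),
                                   potential = NULL,
                                   diffusion_rad2_ns = 100,
                                   temperature_K = 298,
                                   n_traj = 101, dt_ps = 2.5, t_max_ns = 3,
                                   threshold_deg = 50, sigma_phi_deg = 16.7,
                                   internal_dt_fs = 2.5,
                                   emit_traces = TRUE, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_traj >= 1, dt_ps > 0, t_max_ns > 0, threshold_deg > 0)
  if (!is.null(seed)) local_seed(seed)
  n_grid <- round(t_max_ns * 1000 / dt_ps)
  grid_ns <- seq_len(n_grid) * dt_ps / 1000

  if (mode == "exponential") {
    stopifnot(k_per_ns >= 0)
    t_fp <- if (k_per_ns > 0) rexp(n_traj, rate = k_per_ns) else
      rep(Inf, n_traj)
    cross_idx <- ceiling(t_fp * 1000 / dt_ps)
    cross_idx[cross_idx > n_grid] <- NA_integer_
    traces <- NULL
    if (emit_traces) {
      clamp <- threshold_deg - 0.1
      traces <- lapply(seq_len(n_traj), function(i) {
        len <- if (is.na(cross_idx[i])) n_grid else cross_idx[i]
        phi <- rnorm(len, 0, sigma_phi_deg)
        phi <- pmax(pmin(phi, clamp), -clamp)
        if (!is.na(cross_idx[i]))
          phi[len] <- sign(phi[len]) * (threshold_deg + 10)
        phi
      })
    }
  } else {
    stopifnot(inherits(potential, "torsion_potential"),
              diffusion_rad2_ns > 0, temperature_K > 0)
    sim <- .langevin_twist(potential, diffusion_rad2_ns, temperature_K,
                           n_traj, dt_ps, t_max_ns, threshold_deg,
                           internal_dt_fs)
    cross_idx <- sim$cross_idx
    traces <- if (emit_traces) sim$traces else NULL
    t_fp <- ifelse(is.na(cross_idx), Inf, cross_idx * dt_ps / 1000)
  }

  events <- data.frame(
    id = seq_len(n_traj),
    time_ns = ifelse(is.na(cross_idx), NA_real_, cross_idx * dt_ps / 1000),
    censored = is.na(cross_idx))
  attr(events, "t_max_ns") <- t_max_ns
  attr(events, "dt_ps") <- dt_ps
  class(events) <- c("twist_events", "data.frame")

  structure(list(traces = traces, events = events,
                 truth = data.frame(id = seq_len(n_traj),
                                    t_first_passage_ns = t_fp),
                 params = list(mode = mode, k_per_ns = k_per_ns,
                               n_traj = n_traj, dt_ps = dt_ps,
                               t_max_ns = t_max_ns,
                               threshold_deg = threshold_deg,
                               sigma_phi_deg = sigma_phi_deg)),
            class = "twist_sim")
}

# Overdamped Euler-Maruyama on a 1-D periodic torsional potential.
# theta in radians internally; crossings detected on the save grid only,
# mirroring the analysis convention.
.langevin_twist <- function(pot, D_rad2_ns, temp_K, n_traj, dt_ps, t_max_ns,
                            threshold_deg, internal_dt_fs) {
  kT <- 1.987204259e-3 * temp_K            # kcal/mol
  dt_ns <- internal_dt_fs * 1e-6
  n_sub <- round(dt_ps * 1000 / internal_dt_fs)
  n_grid <- round(t_max_ns * 1000 / dt_ps)
  thr <- threshold_deg * pi / 180
  K <- pot$K; mult <- pot$multiplicity; ph <- pot$phase_deg * pi / 180
  drift_fac <- D_rad2_ns / kT * dt_ns
  noise_sd <- sqrt(2 * D_rad2_ns * dt_ns)
  theta <- numeric(n_traj)
  alive <- rep(TRUE, n_traj)
  cross_idx <- rep(NA_integer_, n_traj)
  saved <- matrix(NA_real_, n_grid, n_traj)
  for (g in seq_len(n_grid)) {
    if (!any(alive)) break
    th <- theta[alive]
    na <- length(th)
    for (s in seq_len(n_sub)) {
      grad <- 0
      for (j in seq_along(K))
        grad <- grad - K[j] * mult[j] * sin(mult[j] * th - ph[j])
      th <- th - drift_fac * grad + rnorm(na, 0, noise_sd)
    }
    theta[alive] <- th
    saved[g, alive] <- th * 180 / pi
    hit <- alive & abs(theta) >= thr
    cross_idx[hit] <- g
    alive <- alive & !hit
  }
  traces <- lapply(seq_len(n_traj), function(i) {
    len <- if (is.na(cross_idx[i])) n_grid else cross_idx[i]
    saved[seq_len(len), i]
  })
  list(cross_idx = cross_idx, traces = traces)
}

#' Generate a QM/MM-style snapshot ensemble of electronic properties
#'
#' Emulates per-snapshot excitation energies and oscillator strengths from
#' a ground-state equilibrium ensemble: the twist angle phi fluctuates as
#' Normal(0, `sigma_phi_deg`), the oscillator strength decreases
#' quadratically with twist, `f = f0 - a * phi^2` (clipped at 0), and the
#' excitation energy is `mean_E_eV` plus Gaussian jitter. The default
#' quadratic coefficient makes f drop by a few percent at a one-sigma
#' twist of ~17 degrees, the behaviour computed for GFP-family
#' chromophores (reconstructed magnitude, not a printed constant).
#'
#' @param n_snap number of snapshots (default 21).
#' @param mean_E_eV mean vertical excitation energy, eV.
#' @param sigma_E_eV energy jitter, eV.
#' @param f0 oscillator strength at the planar geometry.
#' @param a_quad quadratic coefficient, per squared degree.
#' @param sigma_phi_deg twist-fluctuation width, degrees.
#' @param seed optional integer seed.
#' @return data.frame with columns `id`, `phi_deg` (ground truth),
#'   `E_ex_eV`, `f_l`; generator parameters attached as attribute `model`.
#' @export
gen_snapshot_ensemble <- function(n_snap = 21, mean_E_eV = 3.101,
                                  sigma_E_eV = 0.03, f0 = 1.02,
                                  a_quad = 1.4e-4, sigma_phi_deg = 16.7,
                                  seed = NULL) {
  stopifnot(n_snap >= 1, mean_E_eV > 0, sigma_E_eV >= 0, f0 >= 0,
            a_quad >= 0, sigma_phi_deg >= 0)
  if (!is.null(seed)) local_seed(seed)
  phi <- rnorm(n_snap, 0, sigma_phi_deg)
  f <- pmax(0, f0 - a_quad * phi^2)
  E <- mean_E_eV + rnorm(n_snap, 0, sigma_E_eV)
  out <- data.frame(id = seq_len(n_snap), phi_deg = phi,
                    E_ex_eV = E, f_l = f)
  attr(out, "model") <- list(mean_E_eV = mean_E_eV, sigma_E_eV = sigma_E_eV,
                             f0 = f0, a_quad = a_quad,
                             sigma_phi_deg = sigma_phi_deg)
  out
}

#' Construct a coordinate frame with a known number of hydrogen bonds
#'
#' Builds a synthetic single-frame structure containing a carbon-chain
#' "chromophore" plus exactly `k` O-H...O triples satisfying the default
#' hydrogen-bond criteria within the census region, together with
#' configurable near-miss decoys: distance decoys at 3.30 A (or 3.21 A
#' when `boundary_decoy = TRUE`, just outside the 3.2 A cutoff) and angle
#' decoys at ~49 degrees deviation from linearity. Clusters are spaced so
#' no accidental cross-cluster bonds arise.
#'
#' @param k number of planted bonds (0..5).
#' @param n_decoys number of decoy clusters (alternating distance/angle).
#' @param boundary_decoy place the first distance decoy at 3.21 A instead
#'   of 3.30 A, probing the boundary semantics of the distance cutoff.
#' @param jitter_A uniform positional jitter applied to cluster anchors
#'   (kept small so the planted criteria still hold), angstrom.
#' @param seed optional integer seed.
#' @return list: `frame` (an `fp_frame` data.frame for [detect_hbonds()]),
#'   `truth` (data.frame of planted donor/hydrogen/acceptor indices),
#'   `chromophore` (indices of chromophore atoms).
#' @export
gen_hbond_frames <- function(k = 3, n_decoys = 2, boundary_decoy = FALSE,
                             jitter_A = 0.05, seed = NULL) {
  stopifnot(k >= 0, k <= 5, n_decoys >= 0)
  if (!is.null(seed)) local_seed(seed)
  n_clusters <- k + n_decoys
  n_carbon <- max(n_clusters, 2L)
  rows <- list()
  add <- function(name, elem, resname, p)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, elem = elem,
                                             resname = resname,
                                             x = p[1], y = p[2], z = p[3])
  for (i in seq_len(n_carbon))
    add(paste0("C", i), "C", "CRO", c(5 * (i - 1), 0, 0))

  place_cluster <- function(i, d_DA, tilt_deg) {
    base <- c(5 * (i - 1), 4.0, 0) + runif(3, -jitter_A, jitter_A)
    axis <- c(0, 0, 1)
    tilt <- tilt_deg * pi / 180
    hdir <- c(0, sin(tilt), cos(tilt))
    iD <- length(rows) + 1L
    add("OD", "O", "ENV", base)
    add("HD", "H", "ENV", base + 0.96 * hdir)
    add("OA", "O", "ENV", base + d_DA * axis)
    c(donor = iD, hydrogen = iD + 1L, acceptor = iD + 2L)
  }

  truth <- NULL
  for (i in seq_len(k)) {
    tr <- place_cluster(i, d_DA = 3.0, tilt_deg = 10)
    truth <- rbind(truth, as.data.frame(as.list(tr)))
  }
  for (j in seq_len(n_decoys)) {
    i <- k + j
    if (j %% 2 == 1L) {
      d <- if (boundary_decoy && j == 1L) 3.21 else 3.30
      place_cluster(i, d_DA = d, tilt_deg = 10)       # distance decoy
    } else {
      place_cluster(i, d_DA = 3.0, tilt_deg = 35)     # angle decoy
    }
  }
  frame <- do.call(rbind, rows)
  rownames(frame) <- NULL
  list(frame = frame,
       truth = if (is.null(truth))
         data.frame(donor = integer(0), hydrogen = integer(0),
                    acceptor = integer(0)) else truth,
       chromophore = seq_len(n_carbon))
}

#' Generate experimental-style fluorescence curves
#'
#' Dispatches to one of three generators, each attaching its ground truth
#' as the attribute `truth`:
#'
#' * `kind = "bleach"`: photobleaching intensity trace
#'   `I(t) = I0 * 2^(-t / half_time_s) + background`, optionally
#'   Poisson-noised.
#' * `kind = "tcspc"`: an integer photon-count decay histogram from a
#'   mono- or multi-exponential intensity model
#'   `I(t) = sum_i a_i exp(-t / tau_i)`; expected bin counts are the
#'   binned intensity normalised to `n_counts` photons, and observed
#'   counts are Poisson draws.
#' * `kind = "redding"`: paired green (bleaching) and red
#'   (photoconversion) traces, the red channel contaminated by a scalar
#'   leak `alpha` of the green signal plus a constant background; the true
#'   red-growth curve is `R_inf * (1 - exp(-t / tau_red_s))`.
#'
#' @param kind `"bleach"`, `"tcspc"` or `"redding"`.
#' @param half_time_s bleaching half-time, s (`"bleach"`, `"redding"`).
#' @param duration_s,dt_s time grid (`"bleach"`, `"redding"`).
#' @param I0 initial intensity, counts.
#' @param background constant background, counts.
#' @param noise `"poisson"` or `"none"`.
#' @param lifetimes_ns,amplitudes,n_counts,t_range_ns,n_bins TCSPC model.
#' @param R_inf,tau_red_s,alpha redding model.
#' @param seed optional integer seed.
#' @return `"bleach"`: data.frame `time_s`, `intensity`; `"tcspc"`:
#'   data.frame `t_ns`, `counts`; `"redding"`: data.frame `time_s`,
#'   `green`, `red`. All carry attribute `truth`.
#' @export
gen_curves <- function(kind = c("bleach", "tcspc", "redding"),
                       half_time_s = 80, duration_s = 6 * half_time_s,
                       dt_s = 2, I0 = 1000, background = 0,
                       noise = c("poisson", "none"),
                       lifetimes_ns = c(3.5, 0.5), amplitudes = c(0.7, 0.3),
                       n_counts = 1e6, t_range_ns = c(0, 25), n_bins = 500,
                       R_inf = 200, tau_red_s = 120, alpha = 0.02,
                       seed = NULL) {
  kind <- match.arg(kind)
  noise <- match.arg(noise)
  if (!is.null(seed)) local_seed(seed)
  switch(kind,
    bleach = {
      stopifnot(half_time_s > 0, I0 > 0)
      t <- seq(0, duration_s, by = dt_s)
      mu <- I0 * 2^(-t / half_time_s) + background
      y <- if (noise == "poisson") rpois(length(mu), mu) else mu
      out <- data.frame(time_s = t, intensity = y)
      attr(out, "truth") <- list(half_time_s = half_time_s,
                                 background = background)
      out
    },
    tcspc = {
      stopifnot(length(lifetimes_ns) == length(amplitudes),
                all(lifetimes_ns > 0), all(amplitudes > 0),
                abs(sum(amplitudes) - 1) < 1e-9, n_counts > 0)
      edges <- seq(t_range_ns[1], t_range_ns[2], length.out = n_bins + 1)
      lo <- edges[-length(edges)]; hi <- edges[-1]
      p <- 0
      for (i in seq_along(lifetimes_ns))
        p <- p + amplitudes[i] * lifetimes_ns[i] *
          (exp(-lo / lifetimes_ns[i]) - exp(-hi / lifetimes_ns[i]))
      mu <- n_counts * p / sum(p)
      counts <- if (noise == "poisson") rpois(length(mu), mu) else round(mu)
      out <- data.frame(t_ns = (lo + hi) / 2, counts = as.integer(counts))
      attr(out, "truth") <- list(lifetimes_ns = lifetimes_ns,
                                 amplitudes = amplitudes,
                                 n_counts = n_counts)
      out
    },
    redding = {
      stopifnot(half_time_s > 0, R_inf >= 0, tau_red_s > 0, alpha >= 0)
      t <- seq(0, duration_s, by = dt_s)
      green_clean <- I0 * 2^(-t / half_time_s)
      red_true <- R_inf * (1 - exp(-t / tau_red_s))
      red_obs <- red_true + alpha * green_clean + background
      if (noise == "poisson") {
        green_obs <- rpois(length(t), green_clean)
        red_obs <- rpois(length(t), red_obs)
      } else green_obs <- green_clean
      out <- data.frame(time_s = t, green = as.numeric(green_obs),
                        red = as.numeric(red_obs))
      attr(out, "truth") <- list(red_true = red_true, alpha = alpha,
                                 background = background,
                                 tau_red_s = tau_red_s, R_inf = R_inf)
      out
    })
}
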