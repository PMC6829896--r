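#' First crossing of the twist threshold per trajectory
#'
#' Scans each excited-state phi trace (sampled on the save grid, `dt_ps`)
#' for the first sample with `|phi| >= threshold_deg`. The boundary counts
#' as twisted. Trajectories that never cross within the observation window
#' are censored at `t_max_ns`. Traces may be "stopped" (shorter than the
#' full grid) only if their last sample crosses the threshold; a short
#' trace without a crossing is an error, since its censoring time would be
#' unknown.
#'
#' @param traces list of numeric vectors (phi in degrees), one per
#'   trajectory, sampled at `dt_ps` starting at `dt_ps`.
#' @param threshold_deg twist threshold in degrees (default 50).
#' @param t_max_ns observation window, ns (default 3).
#' @param dt_ps save interval, ps (default 2.5).
#' @return data.frame of class `twist_events` with columns `id`,
#'   `time_ns` (grid crossing time, `NA` when censored), `censored`;
#'   attributes `t_max_ns`, `dt_ps`.
#' @export
first_crossing_times <- function(traces, threshold_deg = 50,
                                 t_max_ns = 3, dt_ps = 2.5) {
  if (!is.list(traces) || length(traces) == 0L) stop("empty trace set")
  stopifnot(threshold_deg > 0, t_max_ns > 0, dt_ps > 0)
  n_grid <- round(t_max_ns * 1000 / dt_ps)
  ev <- lapply(seq_along(traces), function(i) {
    phi <- traces[[i]]
    hit <- which(abs(phi) >= threshold_deg)
    if (length(hit) > 0L) {
      data.frame(id = i, time_ns = hit[1L] * dt_ps / 1000, censored = FALSE)
    } else {
      if (length(phi) < n_grid)
        stop("trace ", i, " ends before t_max without crossing")
      data.frame(id = i, time_ns = NA_real_, censored = TRUE)
    }
  })
  out <- do.call(rbind, ev)
  attr(out, "t_max_ns") <- t_max_ns
  attr(out, "dt_ps") <- dt_ps
  class(out) <- c("twist_events", "data.frame")
  out
}

#' Planar-population survival curve from twist events
#'
#' The planar population A(t) is the fraction of trajectories with no
#' threshold crossing by time t, evaluated on the save grid (t = 0, dt,
#' 2 dt, ..., t_max). Censored trajectories remain planar throughout, so
#' A(0) = 1 and A is non-increasing. Invariant to trajectory order.
#'
#' @param events a `twist_events` data.frame ([first_crossing_times()] or a
#'   generator's bookkept events) carrying `t_max_ns`/`dt_ps` attributes.
#' @return object of class `survival_curve`: list with `time_ns`, `A`,
#'   `n_total`, `t_max_ns`, `dt_ps`.
#' @export
survival_curve <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("time_ns", "censored") %in% names(events)))
  t_max <- attr(events, "t_max_ns"); dt <- attr(events, "dt_ps")
  if (is.null(t_max) || is.null(dt))
    stop("events must carry t_max_ns and dt_ps attributes (mixed or unknown grids)")
  n <- nrow(events)
  times <- c(0, seq_len(round(t_max * 1000 / dt)) * dt / 1000)
  cross <- sort(events$time_ns[!events$censored])
  # A(t) = fraction with crossing time > t; findInterval counts crossings <= t
  A <- 1 - findInterval(times + 1e-12, cross) / n
  structure(list(time_ns = times, A = A, n_total = n,
                 t_max_ns = t_max, dt_ps = dt),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve: n = %d, A(t_max = %g ns) = %.3f\n",
              x$n_total, x$t_max_ns, x$A[length(x$A)]))
  invisible(x)
}

#' @export
as.data.frame.survival_curve <- function(x, ...) {
  data.frame(time_ns = x$time_ns, A = x$A)
}

#' First-order kinetics fit of a survival curve
#'
#' Fits A(t) = exp(-k t) by least squares on ln A(t) versus t. Because
#' A(0) = 1 by construction, the default regression fixes the intercept at
#' zero (`intercept = FALSE`); the free-intercept variant is also computed
#' and reported in the diagnostics. Grid points with A = 0 carry no
#' information on the log scale and are excluded; the fit window ends at
#' the last positive-A point. The non-radiative half-life is
#' tau_nr = ln(2) / k.
#'
#' @param curve a [survival_curve()].
#' @param intercept fit a free intercept instead of forcing ln A(0) = 0.
#' @return object of class `rate_fit`: `k_per_ns`, `half_life_ns`, `flag`
#'   (`"ok"` or `"no-decay"`), `n_points`, `r_squared`, `residual_sd`,
#'   `k_free_intercept`, `intercept`.
#' @export
fit_first_order <- function(curve, intercept = FALSE) {
  stopifnot(inherits(curve, "survival_curve"))
  use <- curve$A > 0 & curve$time_ns > 0
  t <- curve$time_ns[use]; lnA <- log(curve$A[use])
  if (all(curve$A == 1)) {
    return(structure(list(k_per_ns = 0, half_life_ns = Inf, flag = "no-decay",
                          n_points = length(t), r_squared = NA_real_,
                          residual_sd = NA_real_,
                          k_free_intercept = 0, intercept = 0),
                     class = "rate_fit"))
  }
  if (length(t) < 2L) stop("fewer than 2 usable points for the log-linear fit")
  k0 <- -sum(t * lnA) / sum(t^2)              # through-origin slope
  fit_free <- lm(lnA ~ t)
  k_free <- -unname(coef(fit_free)[2])
  k <- if (intercept) k_free else k0
  resid <- lnA - (-k * t + if (intercept) unname(coef(fit_free)[1]) else 0)
  ss_tot <- sum((lnA - mean(lnA))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  structure(list(k_per_ns = k,
                 half_life_ns = if (k > 0) log(2) / k else Inf,
                 flag = "ok",
                 n_points = length(t),
                 r_squared = r2,
                 residual_sd = sd(resid),
                 k_free_intercept = k_free,
                 intercept = if (intercept) unname(coef(fit_free)[1]) else 0),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("First-order fit: k = %.4g /ns, half-life = %.4g ns [%s]\n",
              x$k_per_ns, x$half_life_ns, x$flag))
  invisible(x)
}

#' Bootstrap confidence interval for the twisting rate
#'
#' Nonparametric bootstrap over trajectories: resamples the event list with
#' replacement, rebuilds the survival curve and refits the first-order
#' rate. Percentile intervals are returned for both the rate and the
#' half-life.
#'
#' @param events a `twist_events` data.frame.
#' @param n_boot number of resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed (local to this call).
#' @param intercept passed to [fit_first_order()].
#' @return list with `k_ci`, `half_life_ci` (length-2 vectors), `k_boot`
#'   (the resampled rates).
#' @export
bootstrap_rate_ci <- function(events, n_boot = 1000, conf = 0.95,
                              seed = NULL, intercept = FALSE) {
  stopifnot(is.data.frame(events), n_boot >= 2, conf > 0, conf < 1)
  if (!is.null(seed)) local_seed(seed)
  n <- nrow(events)
  ks <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    ev <- events[idx, , drop = FALSE]
    attr(ev, "t_max_ns") <- attr(events, "t_max_ns")
    attr(ev, "dt_ps") <- attr(events, "dt_ps")
    fit_first_order(survival_curve(ev), intercept = intercept)$k_per_ns
  }, numeric(1))
  a <- (1 - conf) / 2
  k_ci <- unname(quantile(ks, c(a, 1 - a)))
  list(k_ci = k_ci,
       half_life_ci = rev(log(2) / k_ci),
       k_boot = ks)
}

#' Ratio of twisting rates between two fits
#'
#' Compares the first-order twisting (radiationless) rates of two systems,
#' e.g. halide-bound versus free protein: returns k_a / k_b, equivalently
#' tau_nr(b) / tau_nr(a).
#'
#' @param fit_a,fit_b [fit_first_order()] results.
#' @return dimensionless rate ratio.
#' @export
halide_rate_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "rate_fit"), inherits(fit_b, "rate_fit"))
  if (fit_b$k_per_ns <= 0) stop("zero rate in denominator")
  fit_a$k_per_ns / fit_b$k_per_ns
}

# Set the RNG seed for the duration of the calling function only.
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  expr <- substitute({
    if (!is.null(OLD)) assign(".Random.seed", OLD, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, list(OLD = old))
  do.call(on.exit, list(expr, add = TRUE), envir = env)
  set.seed(seed)
  invisible(NULL)
}
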