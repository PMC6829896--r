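#' Photobleaching half-time of an intensity trace
#'
#' Background-subtracts, normalises to the maximum and returns the first
#' time the normalised signal crosses 0.5 downwards, with linear
#' interpolation between samples. The result is invariant under positive
#' affine rescaling of the raw intensity (detector gain). If the signal
#' never falls to half, the result is censored at the last time point and
#' flagged.
#'
#' @param time_s time points, seconds, strictly increasing.
#' @param intensity raw intensities (same length).
#' @param background constant background level subtracted before
#'   normalisation (default 0).
#' @param smooth for noisy traces: smooth with lowess (span
#'   `smooth_span`) and project onto the nearest non-increasing curve
#'   (isotonic regression) before the crossing search, so shot noise
#'   neither triggers a spurious crossing nor inflates the normalisation
#'   maximum; default FALSE.
#' @param smooth_span lowess span used when `smooth = TRUE`.
#' @return list of class `bleach_halftime`: `half_time_s`, `censored`,
#'   `normalized` (the processed trace).
#' @examples
#' t <- seq(0, 400, by = 2)
#' bleach_halftime(t, exp(-t * log(2) / 80))$half_time_s  # 80
#' @export
bleach_halftime <- function(time_s, intensity, background = 0,
                            smooth = FALSE, smooth_span = 0.08) {
  stopifnot(length(time_s) == length(intensity), length(time_s) >= 3)
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  if (any(!is.finite(intensity))) stop("non-finite intensities")
  y <- intensity - background
  if (max(y) <= 0) stop("initial intensity must exceed background")
  if (smooth) {
    y <- stats::lowess(time_s, y, f = smooth_span)$y
    y <- -stats::isoreg(time_s, -y)$yf
  }
  y <- y / max(y)
  y_search <- y
  below <- which(y_search < 0.5)
  below <- below[below > 1L]
  if (length(below) == 0L) {
    return(structure(list(half_time_s = time_s[length(time_s)],
                          censored = TRUE,
                          normalized = data.frame(time_s = time_s, I = y)),
                     class = "bleach_halftime"))
  }
  i <- below[1L]
  # linear interpolation between samples i-1 and i
  t0 <- time_s[i - 1L]; t1 <- time_s[i]
  y0 <- y_search[i - 1L]; y1 <- y_search[i]
  t_half <- if (y0 == y1) t1 else t0 + (0.5 - y0) * (t1 - t0) / (y1 - y0)
  structure(list(half_time_s = t_half, censored = FALSE,
                 normalized = data.frame(time_s = time_s, I = y)),
            class = "bleach_halftime")
}

#' @export
print.bleach_halftime <- function(x, ...) {
  cat(sprintf("Bleaching half-time: %.4g s%s\n", x$half_time_s,
              if (x$censored) " (censored: never reached 0.5)" else ""))
  invisible(x)
}

#' Fit exponential decays to a TCSPC photon histogram
#'
#' Fits a mono-exponential and (optionally) a bi-exponential decay model to
#' a time-correlated single-photon-counting histogram by weighted least
#' squares (Neyman weights 1/max(counts, 1), the TCSPC convention for
#' Poisson-distributed counts). The model for the expected counts is
#' \deqn{\mu(t) = N \sum_i a_i e^{-t/\tau_i}, \qquad \sum_i a_i = 1,}
#' fitted from `offset_bins` after the peak bin (no instrument-response
#' deconvolution). Model selection between 1 and 2 components uses the
#' reduced chi-square: the richer model is preferred when it improves the
#' reduced chi-square by more than `chisq_improvement` (default 20%); an
#' AIC criterion is available instead.
#'
#' @param t_ns bin centres, ns (constant width).
#' @param counts nonnegative integer photon counts.
#' @param max_components 1 or 2.
#' @param offset_bins bins skipped after the peak before fitting.
#' @param criterion `"chisq"` (default) or `"aic"`.
#' @param chisq_improvement fractional reduced-chi-square improvement
#'   required to accept the second component.
#' @return list of class `decay_fit`: `n_components`, `tau_ns` (sorted
#'   decreasing), `amplitudes` (fractional, matching `tau_ns`),
#'   `chisq_red`, `fits` (per-model details), `preferred`.
#' @export
fit_decay <- function(t_ns, counts, max_components = 2, offset_bins = 0,
                      criterion = c("chisq", "aic"),
                      chisq_improvement = 0.2) {
  criterion <- match.arg(criterion)
  stopifnot(length(t_ns) == length(counts), max_components %in% 1:2)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) == 0) stop("all-zero histogram")
  if (sum(counts > 0) < 3L)
    stop("degenerate histogram: fewer than 3 populated bins")
  if (sum(counts) < 1000)
    warning("fewer than 1000 total counts; fit may be unstable")
  i0 <- which.max(counts) + offset_bins
  if (i0 >= length(t_ns) - 3L) stop("fit window too short after the peak")
  tt <- t_ns[i0:length(t_ns)] - t_ns[i0]
  cc <- counts[i0:length(counts)]
  w <- 1 / pmax(cc, 1)

  fit1 <- .fit_exp1(tt, cc, w)
  fits <- list(fit1)
  best <- 1L
  if (max_components == 2) {
    fit2 <- tryCatch(.fit_exp2(tt, cc, w, fit1), error = function(e) NULL)
    if (!is.null(fit2)) {
      fits[[2]] <- fit2
      better <- if (criterion == "chisq")
        fit2$chisq_red < (1 - chisq_improvement) * fit1$chisq_red
      else fit2$aic < fit1$aic
      if (better) best <- 2L
    }
  }
  sel <- fits[[best]]
  structure(list(n_components = best,
                 tau_ns = sel$tau, amplitudes = sel$amp,
                 chisq_red = sel$chisq_red,
                 fits = fits, preferred = best),
            class = "decay_fit")
}

.gof <- function(obs, mu, w, n_par) {
  chisq <- sum(w * (obs - mu)^2)
  dof <- length(obs) - n_par
  # Gaussian-approximation AIC consistent with the weighted LS objective
  aic <- chisq + 2 * n_par
  list(chisq_red = chisq / dof, aic = aic)
}

.fit_exp1 <- function(t, c, w) {
  pos <- c > 0
  start <- coef(lm(log(c[pos]) ~ t[pos]))
  tau0 <- max(-1 / start[2], diff(range(t)) / 10)
  N0 <- exp(start[1])
  obj <- function(p) {
    mu <- exp(p[1]) * exp(-t / exp(p[2]))
    sum(w * (c - mu)^2)
  }
  op <- optim(c(log(N0), log(tau0)), obj, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-12))
  tau <- exp(op$par[2])
  mu <- exp(op$par[1]) * exp(-t / tau)
  g <- .gof(c, mu, w, 2)
  list(tau = tau, amp = 1, N = exp(op$par[1]),
       chisq_red = g$chisq_red, aic = g$aic)
}

.fit_exp2 <- function(t, c, w, fit1) {
  # start: split the mono-exponential into a slow and a fast component
  start <- c(logN = log(fit1$N), ltau1 = log(fit1$tau * 1.3),
             ltau2 = log(fit1$tau * 0.25), qa = 0.8)
  obj <- function(p) {
    a1 <- 1 / (1 + exp(-p[4]))
    mu <- exp(p[1]) * (a1 * exp(-t / exp(p[2])) +
                       (1 - a1) * exp(-t / exp(p[3])))
    sum(w * (c - mu)^2)
  }
  op <- optim(start, obj, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-12))
  a1 <- 1 / (1 + exp(-op$par[4]))
  tau <- c(exp(op$par[2]), exp(op$par[3]))
  amp <- c(a1, 1 - a1)
  ord <- order(tau, decreasing = TRUE)
  tau <- tau[ord]; amp <- amp[ord]
  if (abs(log(tau[1] / tau[2])) < 0.05)
    stop("components collapsed onto one lifetime")
  mu <- exp(op$par[1]) * (amp[1] * exp(-t / tau[1]) + amp[2] * exp(-t / tau[2]))
  g <- .gof(c, mu, w, 4)
  list(tau = tau, amp = amp, N = exp(op$par[1]),
       chisq_red = g$chisq_red, aic = g$aic)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("TCSPC fit: %d component(s); tau = %s ns; amplitudes = %s; red. chi2 = %.3g\n",
              x$n_components,
              paste(sprintf("%.3g", x$tau_ns), collapse = ", "),
              paste(sprintf("%.2f", x$amplitudes), collapse = ", "),
              x$chisq_red))
  invisible(x)
}

#' Leak-corrected, normalised photoconversion ("redding") curve
#'
#' Corrects a red-channel trace for background and for the red tail of the
#' green/yellow form leaking through the red filter set (modelled as a
#' scalar fraction `alpha` of the simultaneously measured green trace),
#' then normalises:
#' \deqn{red'(t) = red(t) - background - \alpha \cdot green(t).}
#' Two normalisation modes reflect two reporting conventions: `"max"`
#' divides by the maximum of the corrected red signal (curve shape);
#' `"green0"` divides by the initial green intensity (accounts for how much
#' emitting material was present at time zero when comparing proteins).
#'
#' @param time_s shared time grid, seconds.
#' @param red,green intensity traces on that grid.
#' @param background constant red-channel background.
#' @param alpha leak-through coefficient (>= 0).
#' @param norm `"max"` or `"green0"`.
#' @return data.frame with `time_s`, `red_corrected`, `red_norm`.
#' @export
redding_curve <- function(time_s, red, green, background = 0, alpha = 0,
                          norm = c("max", "green0")) {
  norm <- match.arg(norm)
  if (length(red) != length(time_s) || length(green) != length(time_s))
    stop("red, green and time grids must match")
  stopifnot(alpha >= 0)
  corr <- red - background - alpha * green
  denom <- switch(norm,
    max = { m <- max(corr); if (m <= 0) 1 else m },
    green0 = { g0 <- green[1]; if (g0 <= 0) stop("nonpositive initial green intensity"); g0 })
  data.frame(time_s = time_s, red_corrected = corr, red_norm = corr / denom)
}
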