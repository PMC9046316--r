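# Traveling-wave (phase-encoded) retinotopy: Fourier amplitude/phase at the
# stimulus frequency, opposite-direction combination, phase-to-visual-field
# decoding.

#' Fourier phase map at the stimulus frequency
#'
#' For each vertex: linear detrend, then the discrete Fourier component at
#' the stimulus frequency (`n_cycles` over the analyzed window). Phase is
#' reported so that a response `cos(2 pi t / cycle_duration - psi)` yields
#' phase `psi`. Coherence is the amplitude at the stimulus frequency divided
#' by the root-sum-square of amplitudes over all non-DC, non-trend
#' frequencies (bins 0 and 1 cycle/window excluded). Blank periods are
#' excluded from the analysis window by default.
#'
#' @param ts a `vertex_timeseries` (or a vertices x samples matrix).
#' @param spec a [stimulus_spec()]; taken from `ts` when omitted.
#' @param include_blanks keep blank-period samples in the DFT window.
#' @return object of class `phase_map`: `amplitude`, `phase` (rad, in
#'   (-pi, pi]), `coherence` overlays, plus the analysis `spec`.
#' @export
fourier_phase <- function(ts, spec = NULL, include_blanks = FALSE) {
  if (inherits(ts, "vertex_timeseries")) {
    spec <- spec %||% ts$spec
    X <- ts$data; t <- ts$time
  } else {
    if (is.null(spec)) stop("spec required for a bare matrix")
    X <- as.matrix(ts)
    t <- seq(0, by = spec$tr, length.out = ncol(X))
  }
  period <- spec$cycle_duration + spec$blank_duration
  if (!include_blanks && spec$blank_duration > 0) {
    keep <- (t %% period) < spec$cycle_duration
    X <- X[, keep, drop = FALSE]
  }
  N <- ncol(X)
  if (spec$n_cycles < 2L || N < 2L * spec$n_cycles)
    stop("time series shorter than 2 stimulus cycles")
  # Joint least squares on {1, t, cos, sin} at the stimulus frequency:
  # exact phase recovery for a pure harmonic (a plain detrend-then-DFT
  # leaks trend energy into the stimulus bin on the discrete grid).
  tt <- seq_len(N) - 1L
  w <- 2 * pi * spec$n_cycles / N
  B <- cbind(1, tt - mean(tt), cos(w * tt), sin(w * tt))
  coefs <- solve(crossprod(B), crossprod(B, t(X)))   # 4 x vertices
  amp <- sqrt(coefs[3, ]^2 + coefs[4, ]^2)
  phase <- wrap_pi(atan2(coefs[4, ], coefs[3, ]))
  detr <- t(X) - B[, 1:2] %*% coefs[1:2, , drop = FALSE]
  F <- stats::mvfft(detr)            # frequencies x vertices
  k <- spec$n_cycles + 1L            # R index of the stimulus bin
  half <- floor(N / 2) + 1L
  denom_bins <- seq(3L, half)  # exclude DC (bin 1) and 1-cycle trend (bin 2)
  denom <- sqrt(colSums(Mod(F[denom_bins, , drop = FALSE])^2))
  coh <- ifelse(denom > 0, Mod(F[k, ]) / denom, 0)
  structure(list(amplitude = vertex_overlay(amp, units = "unitless"),
                 phase = vertex_overlay(phase, valid = amp > 0,
                                        units = "rad"),
                 coherence = vertex_overlay(pmin(coh, 1), units = "unitless"),
                 spec = spec),
            class = "phase_map")
}

wrap_pi <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w <= -pi] <- pi
  w
}

#' Combine opposite-direction phase maps
#'
#' The per-vertex combined phase is the circular half-difference
#' `(phase_fwd - phase_rev) / 2`, which cancels any hemodynamic delay common
#' to the two directions. The half-difference is defined modulo pi; the
#' ambiguity is resolved by assuming the common delay is below a quarter
#' cycle. Amplitude and coherence are combined by geometric mean.
#'
#' @param map_fwd,map_rev `phase_map`s from runs of opposite direction on
#'   the same mesh and stimulus.
#' @return a `phase_map` with delay-free phase.
#' @export
combine_directions <- function(map_fwd, map_rev) {
  n <- length(map_fwd$phase$values)
  if (length(map_rev$phase$values) != n)
    stop("dimension error: phase maps differ in length")
  pf <- map_fwd$phase$values; pr <- map_rev$phase$values
  h <- wrap_pi((pf - pr) / 2)
  cand <- cbind(h, wrap_pi(h + pi))
  # implied common delay phase for each candidate; keep the candidate whose
  # delay lies in (-pi/2, pi/2] (delay under a quarter cycle)
  delay1 <- wrap_pi(pf - cand[, 1])
  use2 <- abs(delay1) > pi / 2
  phase <- ifelse(use2, cand[, 2], cand[, 1])
  amp <- sqrt(map_fwd$amplitude$values * map_rev$amplitude$values)
  coh <- sqrt(map_fwd$coherence$values * map_rev$coherence$values)
  structure(list(amplitude = vertex_overlay(amp, units = "unitless"),
                 phase = vertex_overlay(phase, valid = map_fwd$phase$valid &
                                          map_rev$phase$valid, units = "rad"),
                 coherence = vertex_overlay(coh, units = "unitless"),
                 spec = map_fwd$spec),
            class = "phase_map")
}

#' Decode a delay-free phase map to visual-field coordinates
#'
#' Maps phase in [0, 2 pi) linearly (or logarithmically, for a log-swept
#' ring) onto the sweep range: polar angle (deg, package convention) for
#' wedge runs, eccentricity (deg) for ring runs.
#'
#' @param map a combined (delay-free) `phase_map`.
#' @param spec a [stimulus_spec()]; taken from `map` when omitted.
#' @param coherence_threshold vertices below it are marked invalid
#'   (default 0.25).
#' @return a `vertex_overlay` in degrees.
#' @export
phase_to_visual <- function(map, spec = NULL, coherence_threshold = 0.25) {
  spec <- spec %||% map$spec
  frac <- (map$phase$values %% (2 * pi)) / (2 * pi)
  r <- spec$sweep_range
  vals <- if (spec$kind == "wedge") {
    wrap180(r[1] + frac * (r[2] - r[1]))
  } else if (spec$sweep_scale == "log") {
    r[1] * exp(frac * log(r[2] / r[1]))
  } else {
    r[1] + frac * (r[2] - r[1])
  }
  valid <- map$phase$valid & (map$coherence$values >= coherence_threshold)
  vertex_overlay(vals, valid = valid, units = "deg")
}
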