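# Synthetic folded-V1 generator: ground-truth retinotopy on a corrugated
# sheet, species presets, measurement noise, and phase-encoded time series.
#
# The sheet is a parameter grid (d, phi): d = cortical distance from the
# foveal edge (mm), phi = polar angle (deg). Folds are raised-cosine
# corrugations expressed through the tangent angle of a unit-speed profile
# curve, so d is exactly arc length along the surface in the d direction and
# the foveal-distance geodesic recovers the generator coordinate up to mesh
# discretization.

#' Species preset for the synthetic V1 generator
#'
#' Ground-truth cortical magnification follows E = a(exp(b d) - 1). Defaults:
#' human a = 1.0 deg, b = 0.063 /mm, stimulated radius 8 deg; macaque
#' a = 0.8 deg, b = 0.12 /mm, radius 10 deg. The retrocalcarine (rCaS) fold
#' sits at eccentricities 2-5 deg (human) or 7-10 deg (macaque); the external
#' calcarine (eCaS) fold at 0-1 deg (human) or 1-4 deg (macaque).
#'
#' @param name `"human"` or `"macaque"`.
#' @param ... overrides for any preset field (`cmf_a`, `cmf_b`,
#'   `stimulus_radius`, `v1_extent_mm`, `lateral_extent_mm`, `rcas_band`,
#'   `ecas_band`, `fold_amplitudes`, `calcarine_width_mm`, `label_tilt_deg`).
#' @return object of class `species_preset`.
#' @export
species_preset <- function(name = c("human", "macaque"), ...) {
  name <- match.arg(name)
  p <- if (name == "human") {
    list(name = "human", cmf_a = 1.0, cmf_b = 0.063, stimulus_radius = 8,
         v1_extent_mm = 34.8, lateral_extent_mm = 28,
         rcas_band = c(2, 5), ecas_band = c(0, 1),
         fold_amplitudes = c(calcarine = 3.5, rcas = 2.5, ecas = 1.5),
         calcarine_width_mm = 12, label_tilt_deg = 15,
         fovea_radius_mm = 2)
  } else {
    list(name = "macaque", cmf_a = 0.8, cmf_b = 0.12, stimulus_radius = 10,
         v1_extent_mm = 21.7, lateral_extent_mm = 20,
         rcas_band = c(7, 10), ecas_band = c(1, 4),
         fold_amplitudes = c(calcarine = 2.5, rcas = 0.7, ecas = 2),
         calcarine_width_mm = 8, label_tilt_deg = 15,
         fovea_radius_mm = 2)
  }
  ov <- list(...)
  p[names(ov)] <- ov
  with(p, {
    if (cmf_a <= 0 || cmf_b <= 0) stop("cmf parameters must be positive")
    for (band in list(rcas_band, ecas_band))
      if (band[1] < 0 || band[2] > stimulus_radius || band[1] >= band[2])
        stop("sulcal bands must be increasing intervals within [0, radius]")
    if (max(rcas_band[1], ecas_band[1]) < min(rcas_band[2], ecas_band[2]))
      stop("rcas_band and ecas_band must be disjoint")
  })
  structure(p, class = "species_preset")
}

#' Invert the magnification function: cortical distance of an eccentricity
#' @param E eccentricity (deg); @param a,b magnification parameters.
#' @return distance d (mm) with `a * (exp(b * d) - 1) = E`.
#' @export
cmf_inverse <- function(E, a, b) log(E / a + 1) / b

# Depth (mm) of a raised-cosine fold of half-angle theta and width w:
# the profile tangent angle is theta * sin(2 pi u / w) over u in [0, w].
fold_depth <- function(theta, w) {
  u <- seq(0, w / 2, length.out = 257)
  sum(diff(u) * (sin(theta * sin(2 * pi * u[-1] / w)) +
                   sin(theta * sin(2 * pi * u[-length(u)] / w))) / 2)
}

fold_theta <- function(depth, w) {
  if (depth <= 0) return(0)
  max_d <- fold_depth(1.25, w)
  if (depth > max_d)
    stop(sprintf("parameter error: fold depth %.2f mm too deep for width %.2f mm (max %.2f)",
                 depth, w, max_d))
  stats::uniroot(function(th) fold_depth(th, w) - depth,
                 c(1e-8, 1.25), tol = 1e-10)$root
}

# Tangent angle (rad) at coordinate t of a set of folds; each fold is
# list(start, width, theta).
fold_angle <- function(t, folds) {
  a <- numeric(length(t))
  for (f in folds) {
    inside <- t >= f$start & t <= f$start + f$width
    a[inside] <- a[inside] -
      f$theta * sin(2 * pi * (t[inside] - f$start) / f$width)
  }
  a
}

# Unit-speed profile curve for grid coordinates tt: returns planar
# coordinates (along, depth) integrated at 16x subresolution.
fold_profile <- function(tt, folds) {
  if (length(tt) < 2) return(list(x = tt, z = numeric(length(tt))))
  fine <- seq(min(tt), max(tt), length.out = 16 * (length(tt) - 1) + 1)
  a <- fold_angle(fine, folds)
  h <- diff(fine)
  cumtrap <- function(y) c(0, cumsum(h * (y[-1] + y[-length(y)]) / 2))
  x <- cumtrap(cos(a)); z <- cumtrap(sin(a))
  list(x = stats::approx(fine, x, xout = tt)$y,
       z = stats::approx(fine, z, xout = tt)$y,
       angle = fold_angle(tt, folds))
}

#' Generate a synthetic folded V1 patch with ground-truth retinotopy
#'
#' Builds a pial/white mesh pair over a (d, phi) grid: a calcarine-like
#' trough running along the d axis, plus transverse rCaS-like and eCaS-like
#' folds at the d intervals whose ground-truth eccentricities are the
#' preset's bands. Sulcal labels are the fold flanks (tangent tilt above
#' `label_tilt_deg`). Truth overlays: polar angle = phi, eccentricity =
#' a(exp(b d) - 1) truncated at the stimulated radius.
#'
#' @param preset a [species_preset()].
#' @param resolution grid vertices per mm (default 2); must yield at least a
#'   40 x 40 grid.
#' @param fold_spec optional list overriding per-fold `depth` / `width`
#'   (names `calcarine`, `rcas`, `ecas`).
#' @param hemisphere stored on the labels.
#' @param subject_id stored on the labels.
#' @param seed recorded in the generator parameters (the geometry itself is
#'   deterministic).
#' @return list with `pial`, `white` (`triangle_mesh`) and `truth`, a
#'   `ground_truth` object carrying `true_map`, `labels`, per-vertex
#'   generator coordinates `d` and `phi`, and `params`.
#' @export
generate_v1_patch <- function(preset, resolution = 2, fold_spec = NULL,
                              hemisphere = "left", subject_id = "synthetic",
                              seed = 1L) {
  stopifnot(inherits(preset, "species_preset"))
  a <- preset$cmf_a; b <- preset$cmf_b
  extent <- preset$v1_extent_mm; width <- preset$lateral_extent_mm
  nd <- round(extent * resolution) + 1L
  nl <- round(width * resolution) + 1L
  if (nd < 40L || nl < 40L)
    stop("parameter error: resolution yields a ", nd, " x ", nl,
         " grid; at least 40 x 40 required")
  dmax_band <- function(band) cmf_inverse(pmin(band, preset$stimulus_radius),
                                          a, b)
  spec_or <- function(nm, default_start, default_width) {
    fs <- fold_spec[[nm]]
    list(start = fs$start %||% default_start,
         width = fs$width %||% default_width,
         depth = fs$depth %||% unname(preset$fold_amplitudes[[nm]]))
  }
  rw <- dmax_band(preset$rcas_band); ew <- dmax_band(preset$ecas_band)
  fr <- spec_or("rcas", rw[1], rw[2] - rw[1])
  fe <- spec_or("ecas", ew[1], ew[2] - ew[1])
  fc <- spec_or("calcarine", -preset$calcarine_width_mm / 2,
                preset$calcarine_width_mm)
  if (fr$start + fr$width > extent + 1e-6)
    fr$width <- extent - fr$start   # clip fold at the peripheral sheet edge
  if (fe$start + fe$width > extent + 1e-6) fe$width <- extent - fe$start
  trans <- list(rcas = c(fr, theta = fold_theta(fr$depth, fr$width)),
                ecas = c(fe, theta = fold_theta(fe$depth, fe$width)))
  cal <- c(fc, theta = fold_theta(fc$depth, fc$width))

  # Annular-wedge embedding: eccentricity runs radially (radial profile has
  # unit speed, so the generator coordinate d is arc length along the
  # surface), polar angle runs angularly, and the foveal confluence is the
  # short inner arc of radius fovea_radius_mm.
  d_grid <- seq(0, extent, length.out = nd)
  phi_grid <- seq(-90, 90, length.out = nl)
  r0 <- preset$fovea_radius_mm
  r_ref <- r0 + extent / 2
  psi_max <- width / (2 * r_ref)
  psi_grid <- phi_grid / 90 * psi_max
  prof_d <- fold_profile(d_grid, trans)
  prof_l <- fold_profile(psi_grid * r_ref, list(cal))
  radius <- r0 + prof_d$x

  vid <- function(i, j) (i - 1L) * nl + j
  # calcarine trough depth scales with radius (conical trough): the short
  # foveal arc stays nearly flat instead of being cut by full-depth walls
  V <- cbind(rep(radius, each = nl) * rep(cos(psi_grid), times = nd),
             rep(radius, each = nl) * rep(sin(psi_grid), times = nd),
             rep(prof_d$z, each = nl) +
               rep(radius / r_ref, each = nl) * rep(prof_l$z, times = nd))
  faces <- NULL
  i <- rep(seq_len(nd - 1L), each = nl - 1L)
  j <- rep(seq_len(nl - 1L), times = nd - 1L)
  faces <- rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
                 cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  pial <- triangle_mesh(V, faces, surface_kind = "synthetic")

  nrm <- vertex_normals(pial)
  white <- triangle_mesh(V - 2 * nrm, faces, surface_kind = "synthetic")

  # generator coordinate = radial arc length along each angular column of
  # the embedded surface (measured, so truth is exactly self-consistent
  # with the geometry the analysis sees)
  Xc <- matrix(V[, 1], nrow = nl); Yc <- matrix(V[, 2], nrow = nl)
  Zc <- matrix(V[, 3], nrow = nl)
  seg <- sqrt((Xc[, -1] - Xc[, -nd])^2 + (Yc[, -1] - Yc[, -nd])^2 +
                (Zc[, -1] - Zc[, -nd])^2)
  s_mat <- cbind(0, t(apply(seg, 1, cumsum)))          # nl x nd
  d_vtx <- as.vector(s_mat)
  phi_vtx <- rep(phi_grid, times = nd)
  ecc <- pmin(a * (exp(b * d_vtx) - 1), preset$stimulus_radius)
  true_map <- retinotopic_map(
    vertex_overlay(phi_vtx, units = "deg"),
    vertex_overlay(ecc, units = "deg"),
    vertex_overlay(rep(1, length(ecc)), units = "unitless"))

  tilt <- preset$label_tilt_deg * pi / 180
  flank <- function(angles, band) {
    ix <- which(rep(abs(angles) > tilt, each = nl))
    ix[ecc[ix] >= band[1] & ecc[ix] <= band[2]]
  }
  labels <- label_set(
    list(V1 = seq_len(nd * nl),
         rCaS = flank(fold_angle(d_grid, trans["rcas"]), preset$rcas_band),
         eCaS = flank(fold_angle(d_grid, trans["ecas"]), preset$ecas_band),
         CaS = which(rep(abs(prof_l$angle) > tilt, times = nd))),
    species = preset$name, hemisphere = hemisphere, subject_id = subject_id)

  truth <- structure(
    list(true_map = true_map, labels = labels, d = d_vtx, phi = phi_vtx,
         grid = c(nd = nd, nl = nl),
         params = list(preset = unclass(preset), resolution = resolution,
                       folds = c(trans, list(calcarine = cal)), seed = seed)),
    class = "ground_truth")
  list(pial = pial, white = white, truth = truth)
}

vertex_normals <- function(mesh) {
  f <- mesh$faces; V <- mesh$vertices
  u <- V[f[, 2], ] - V[f[, 1], ]; v <- V[f[, 3], ] - V[f[, 1], ]
  fn <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nrm <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    acc <- rowsum(fn, f[, k])
    ix <- as.integer(rownames(acc))
    nrm[ix, ] <- nrm[ix, ] + acc
  }
  nrm / pmax(sqrt(rowSums(nrm^2)), 1e-12)
}

wrap180 <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w <= -180] <- 180
  w
}

#' Add measurement noise to a ground-truth map
#'
#' Polar angle receives wrapped Gaussian noise; eccentricity multiplicative
#' log-normal noise; a `dropout_rate` fraction of vertices becomes invalid.
#' The coherence overlay decreases with the injected noise level. With all
#' noise parameters zero the truth is returned unchanged.
#'
#' @param truth a `ground_truth` from [generate_v1_patch()].
#' @param angle_sd wrapped-Gaussian polar-angle sd (deg).
#' @param log_ecc_sd sd of log-normal multiplicative eccentricity noise.
#' @param dropout_rate fraction of vertices dropped, in [0, 1).
#' @param seed RNG seed; identical seeds give identical output.
#' @return a `retinotopic_map`.
#' @export
add_measurement_noise <- function(truth, angle_sd = 8, log_ecc_sd = 0.1,
                                  dropout_rate = 0.05, seed = 1L) {
  stopifnot(angle_sd >= 0, log_ecc_sd >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  tm <- truth$true_map
  if (angle_sd == 0 && log_ecc_sd == 0 && dropout_rate == 0) return(tm)
  n <- tm$n_vertices
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  pa <- wrap180(tm$polar_angle$values + stats::rnorm(n, 0, angle_sd))
  ec <- tm$eccentricity$values * exp(stats::rnorm(n, 0, log_ecc_sd))
  valid <- stats::runif(n) >= dropout_rate
  noise_level <- angle_sd / 45 + log_ecc_sd
  coh <- pmin(1, pmax(0, exp(-noise_level) +
                        stats::rnorm(n, 0, 0.02 * min(1, noise_level))))
  retinotopic_map(
    vertex_overlay(pa, valid = valid, units = "deg"),
    vertex_overlay(ec, valid = valid, units = "deg"),
    vertex_overlay(coh, valid = valid, units = "unitless"))
}

#' Phase-encoded stimulus specification
#'
#' Defaults follow the traveling-wave protocol: wedge runs of 8 cycles of
#' 40 s; ring runs of 7 cycles of 40 s with 10 s blanks between cycles.
#'
#' @param kind `"wedge"` (rotating polar-angle wedge) or `"ring"`
#'   (expanding/contracting eccentricity annulus).
#' @param n_cycles cycles per run (default 8 wedge, 7 ring).
#' @param cycle_duration s per stimulus cycle (default 40).
#' @param blank_duration s of blank after each cycle (default 0 wedge,
#'   10 ring).
#' @param tr sampling interval (s).
#' @param direction +1 or -1 (rotation/expansion direction).
#' @param sweep_range 2-vector: polar-angle span (deg, default c(0, 360))
#'   for wedge, eccentricity span (deg) for ring.
#' @param sweep_scale `"linear"` or `"log"` (ring only; log needs a
#'   positive sweep start).
#' @return object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("wedge", "ring"), n_cycles = NULL,
                          cycle_duration = 40, blank_duration = NULL,
                          tr = 1, direction = 1L, sweep_range = NULL,
                          sweep_scale = c("linear", "log")) {
  kind <- match.arg(kind)
  sweep_scale <- match.arg(sweep_scale)
  n_cycles <- n_cycles %||% if (kind == "wedge") 8L else 7L
  blank_duration <- blank_duration %||% if (kind == "wedge") 0 else 10
  sweep_range <- sweep_range %||% if (kind == "wedge") c(0, 360) else c(0, 8)
  stopifnot(n_cycles >= 1, cycle_duration > 0, blank_duration >= 0,
            tr > 0, direction %in% c(-1L, 1L), length(sweep_range) == 2)
  if (sweep_scale == "log" && sweep_range[1] <= 0)
    stop("log sweep requires a positive sweep start")
  structure(list(kind = kind, n_cycles = as.integer(n_cycles),
                 cycle_duration = cycle_duration,
                 blank_duration = blank_duration, tr = tr,
                 direction = as.integer(direction),
                 sweep_range = sweep_range, sweep_scale = sweep_scale,
                 duration = n_cycles * (cycle_duration + blank_duration)),
            class = "stimulus_spec")
}

# Position of each vertex within the sweep, as a fraction in [0, 1).
sweep_fraction <- function(truth_or_map, spec) {
  if (inherits(truth_or_map, "ground_truth")) {
    pa <- truth_or_map$true_map$polar_angle$values
    ec <- truth_or_map$true_map$eccentricity$values
  } else {
    pa <- truth_or_map$polar_angle$values
    ec <- truth_or_map$eccentricity$values
  }
  r <- spec$sweep_range
  if (spec$kind == "wedge") {
    ((pa - r[1]) %% 360) / (r[2] - r[1])
  } else if (spec$sweep_scale == "log") {
    pmin(pmax(log(ec / r[1]) / log(r[2] / r[1]), 0), 1 - 1e-9)
  } else {
    pmin(pmax((ec - r[1]) / (r[2] - r[1]), 0), 1 - 1e-9)
  }
}

#' Generate phase-encoded traveling-wave time series
#'
#' Each vertex responds with a cosine at the stimulus frequency whose phase
#' encodes the vertex's position within the sweep, shifted by a hemodynamic
#' delay; blank periods contribute baseline (zero) signal.
#'
#' @param truth a `ground_truth`.
#' @param spec a [stimulus_spec()].
#' @param noise_sd additive Gaussian noise sd (signal units; amplitude 1).
#' @param hemodynamic_delay response delay (s).
#' @param seed RNG seed.
#' @return object of class `vertex_timeseries`: `data` (vertices x samples),
#'   `time` (sample onset times, s), `spec`.
#' @export
generate_timeseries <- function(truth, spec, noise_sd = 0,
                                hemodynamic_delay = 0, seed = 1L) {
  frac <- sweep_fraction(truth, spec)
  period <- spec$cycle_duration + spec$blank_duration
  t <- seq(0, spec$duration - spec$tr, by = spec$tr)
  cyc_t <- t %% period
  stim_on <- cyc_t < spec$cycle_duration
  omega <- 2 * pi / spec$cycle_duration
  phase_t <- omega * (cyc_t - hemodynamic_delay)
  X <- outer(spec$direction * 2 * pi * frac, phase_t,
             function(ph, th) cos(th - ph))
  X[, !stim_on] <- 0
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    X <- X + matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X))
  }
  structure(list(data = X, time = t, spec = spec),
            class = "vertex_timeseries")
}
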