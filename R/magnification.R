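# Cortical magnification: eccentricity-vs-cortical-distance samples, the
# exponential fit E = a(exp(b d) - 1), and the 2D histogram with per-sulcus
# isocontours.

#' Collect eccentricity-vs-distance samples over V1
#'
#' One sample per valid V1 vertex: cortical distance from the foveal
#' confluence (`d_hat`, mm), eccentricity (`E`, deg), and sulcus membership
#' flags from the label set.
#'
#' @param map a `retinotopic_map`.
#' @param delineation a `v1_delineation`.
#' @param labels a `label_set` with (at least) `rCaS` / `eCaS` entries;
#'   missing entries simply yield all-FALSE flags.
#' @return data.frame of class `magnification_samples` with columns
#'   `vertex`, `d_hat`, `E`, `rcas`, `ecas`, `tag` (factor: rCaS, eCaS,
#'   V1-other; overlap resolves to the sulcal tags in that order).
#' @export
collect_samples <- function(map, delineation, labels) {
  v1 <- delineation$v1_vertices
  if (length(v1) == 0L) stop("empty V1: no samples to collect")
  dist <- delineation$distance_from_fovea$distance
  check_units(dist, "mm", "distance_from_fovea")
  ok <- map_valid(map)[v1] & dist$valid[v1]
  v <- v1[ok]
  rcas <- v %in% (labels$labels[["rCaS"]] %||% integer(0))
  ecas <- v %in% (labels$labels[["eCaS"]] %||% integer(0))
  out <- data.frame(vertex = v,
                    d_hat = dist$values[v],
                    E = map$eccentricity$values[v],
                    rcas = rcas, ecas = ecas,
                    tag = factor(ifelse(rcas, "rCaS",
                                        ifelse(ecas, "eCaS", "V1-other")),
                                 levels = c("rCaS", "eCaS", "V1-other")))
  class(out) <- c("magnification_samples", "data.frame")
  out
}

#' Fit the exponential cortical magnification function
#'
#' Nonlinear least squares of `E = a (exp(b d) - 1)` to the collected
#' samples (bounded Levenberg-Marquardt), minimizing the sum of squared
#' eccentricity errors. The constant term (-1) forces E(0) = 0, allowing
#' foveal (< 1 deg) measurements to be fit.
#'
#' @param samples a `magnification_samples` data.frame (or any data.frame
#'   with columns `d_hat`, `E`).
#' @param init starting values `c(a, b)` (default `c(1, 0.05)`).
#' @param lower,upper parameter bounds (default a, b in (1e-6, 50] x
#'   (1e-6, 1]).
#' @return object of class `cmf_fit`: `a` (deg), `b` (1/mm), `r_squared`,
#'   `sse`, `n_samples`, `converged`, `init_used`.
#' @export
fit_cmf <- function(samples, init = c(a = 1, b = 0.05),
                    lower = c(1e-6, 1e-6), upper = c(50, 1)) {
  d <- samples$d_hat; E <- samples$E
  keep <- is.finite(d) & is.finite(E)
  d <- d[keep]; E <- E[keep]
  if (length(d) < 10L || diff(range(d)) < 5)
    return(structure(list(a = NA_real_, b = NA_real_, r_squared = NA_real_,
                          sse = NA_real_, n_samples = length(d),
                          converged = FALSE, init_used = init,
                          message = "degenerate samples: need >= 10 samples spanning >= 5 mm"),
                     class = "cmf_fit"))
  sst <- sum((E - mean(E))^2)
  one_fit <- function(ini) {
    tryCatch(
      minpack.lm::nlsLM(E ~ a * (exp(b * d) - 1),
                        data = data.frame(d = d, E = E),
                        start = as.list(stats::setNames(ini, c("a", "b"))),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  # the model has a shallow a*b ridge (a(e^{bd}-1) ~ abd for small bd), so a
  # single start can stall at a near-linear solution; a fixed set of
  # auxiliary starts keeps the fit deterministic while escaping the ridge
  starts <- list(init, c(0.5, 0.1), c(2, 0.02), c(0.25, 0.2))
  best <- NULL; best_sse <- Inf; best_init <- init
  for (ini in starts) {
    fit <- one_fit(ini)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (sse < best_sse) {
      best <- fit; best_sse <- sse; best_init <- ini
    }
  }
  if (is.null(best)) {
    return(structure(list(a = NA_real_, b = NA_real_, r_squared = NA_real_,
                          sse = NA_real_, n_samples = length(d),
                          converged = FALSE, init_used = init,
                          message = "optimizer failed from every start"),
                     class = "cmf_fit"))
  }
  co <- stats::coef(best)
  structure(list(a = unname(co["a"]), b = unname(co["b"]),
                 r_squared = if (sst > 0) 1 - best_sse / sst else NA_real_,
                 sse = best_sse, n_samples = length(d),
                 converged = best$convInfo$isConv, init_used = best_init),
            class = "cmf_fit")
}

#' @export
print.cmf_fit <- function(x, ...) {
  cat(sprintf("<cmf_fit: E = %.4g (exp(%.4g d) - 1), r2 = %.4f, n = %d%s>\n",
              x$a, x$b, x$r_squared, x$n_samples,
              if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}

#' Predicted eccentricity at cortical distance d
#' @param fit a `cmf_fit`; @param d distance(s) from the foveal confluence
#'   (mm, >= 0).
#' @return eccentricity in degrees; exactly 0 at d = 0.
#' @export
predict_eccentricity <- function(fit, d) {
  stopifnot(all(d >= 0))
  fit$a * (exp(fit$b * d) - 1)
}

#' 2D eccentricity-by-distance histogram with per-sulcus isocontours
#'
#' Counts over fixed bins of 0.5 deg eccentricity by 1 mm cortical distance
#' (half-open, anchored at 0). Isocontours are traced per sulcus tag on
#' that tag's own sub-histogram at the given fractions of its maximum bin.
#'
#' @param samples a `magnification_samples` data.frame.
#' @param fractions isocontour levels as fractions of the per-tag maximum
#'   bin (default 0.99, 0.75, 0.50, 0.25).
#' @param ecc_bin,dist_bin bin widths (deg, mm).
#' @return object of class `ecc_dist_histogram`: `counts` (ecc bins x dist
#'   bins), `ecc_edges`, `dist_edges`, and `isocontours`, a per-tag list of
#'   per-fraction lists of polylines (data.frames `d`, `E` in bin-center
#'   coordinates).
#' @export
ecc_distance_histogram <- function(samples, fractions = c(0.99, 0.75, 0.5, 0.25),
                                   ecc_bin = 0.5, dist_bin = 1) {
  stopifnot(nrow(samples) > 0)
  ne <- max(1L, ceiling(max(samples$E) / ecc_bin + 1e-9))
  nd <- max(1L, ceiling(max(samples$d_hat) / dist_bin + 1e-9))
  ecc_edges <- seq(0, ne * ecc_bin, by = ecc_bin)
  dist_edges <- seq(0, nd * dist_bin, by = dist_bin)
  bin2d <- function(df) {
    ie <- pmin(floor(df$E / ecc_bin), ne - 1L) + 1L
    id <- pmin(floor(df$d_hat / dist_bin), nd - 1L) + 1L
    m <- matrix(0L, ne, nd)
    t <- table(factor(ie, levels = 1:ne), factor(id, levels = 1:nd))
    m + as.matrix(t)
  }
  counts <- bin2d(samples)
  iso <- list()
  for (tg in c("rCaS", "eCaS", "V1-other")) {
    sub <- samples[samples$tag == tg, , drop = FALSE]
    if (nrow(sub) == 0) next
    sc <- bin2d(sub)
    iso[[tg]] <- lapply(stats::setNames(fractions, paste0("f", fractions)),
                        function(f) trace_isocontour(sc, f * max(sc),
                                                     ecc_bin, dist_bin))
  }
  structure(list(counts = counts, ecc_edges = ecc_edges,
                 dist_edges = dist_edges, fractions = fractions,
                 isocontours = iso),
            class = "ecc_dist_histogram")
}

# Marching-squares level-set trace on a count matrix (rows = ecc bins,
# cols = dist bins), at absolute level `level`. The grid is padded with a
# zero ring so contours close around boundary cells. Coordinates are in
# data units at bin centers.
trace_isocontour <- function(counts, level, ecc_bin, dist_bin) {
  padded <- matrix(0, nrow(counts) + 2L, ncol(counts) + 2L)
  padded[2:(nrow(counts) + 1L), 2:(ncol(counts) + 1L)] <- counts
  ecc_centers <- (seq_len(nrow(padded)) - 1.5) * ecc_bin
  dist_centers <- (seq_len(ncol(padded)) - 1.5) * dist_bin
  cl <- grDevices::contourLines(x = ecc_centers, y = dist_centers,
                                z = padded, levels = level)
  lapply(cl, function(seg) data.frame(d = seg$y, E = seg$x))
}
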