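# Sample collection, the exponential magnification fit, the 2D histogram
# and per-sulcus isocontours.

macaque_analysis <- function(seed = 1, noise = TRUE) {
  p <- species_preset("macaque")
  patch <- generate_v1_patch(p)
  map <- if (noise) add_measurement_noise(patch$truth, seed = seed)
  else patch$truth$true_map
  delin <- delineate_v1(map, patch$pial,
                        v1_hint = patch$truth$labels$labels$V1,
                        stimulus_radius = p$stimulus_radius)
  list(p = p, patch = patch, map = map, delin = delin,
       samples = collect_samples(map, delin, patch$truth$labels))
}

test_that("sample collection conserves vertices and tags sulci", {
  a <- macaque_analysis(noise = FALSE)
  v1 <- a$patch$truth$labels$labels$V1
  expect_equal(nrow(a$samples), length(v1))     # zero dropout: every vertex
  rcas <- a$patch$truth$labels$labels$rCaS
  expect_setequal(a$samples$vertex[a$samples$rcas], rcas)
  expect_true(all(a$samples$tag[a$samples$rcas] == "rCaS"))
  # with dropout the count equals the valid-mask recount exactly
  noisy <- add_measurement_noise(a$patch$truth, dropout_rate = 0.2, seed = 4)
  delin <- a$delin
  s2 <- collect_samples(noisy, delin, a$patch$truth$labels)
  mask <- noisy$eccentricity$valid & delin$distance_from_fovea$distance$valid
  expect_equal(nrow(s2), sum(mask[v1]))
})

test_that("noiseless samples recover the generating parameters exactly", {
  s <- formula_samples(a = 1.0, b = 0.063)
  fit <- fit_cmf(s)
  expect_true(fit$converged)
  expect_equal(fit$a, 1.0, tolerance = 1e-6)
  expect_equal(fit$b, 0.063, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)
})

test_that("degenerate samples yield a flagged non-fit, not a crash", {
  s <- formula_samples(1, 0.063, dmax = 1, n = 30)   # 1 mm span
  fit <- fit_cmf(s)
  expect_false(fit$converged)
  expect_true(is.na(fit$a))
})

test_that("noisy fits land within 5 percent and match a grid search", {
  set.seed(99)
  n_seeds <- 10
  rel_err <- matrix(NA_real_, n_seeds, 2)
  for (i in seq_len(n_seeds)) {
    d <- runif(5000, 0, 35)
    E <- 1.0 * (exp(0.063 * d) - 1) * exp(rnorm(5000, 0, 0.1))
    fit <- fit_cmf(data.frame(d_hat = d, E = E))
    rel_err[i, ] <- abs(c(fit$a - 1, fit$b - 0.063) / c(1, 0.063))
    if (i <= 2) {
      g <- grid_search_cmf(d, E)
      expect_equal(fit$a, g$a, tolerance = 0.02)
      expect_equal(fit$b, g$b, tolerance = 0.02)
    }
  }
  expect_lt(median(rel_err[, 1]), 0.05)
  expect_lt(median(rel_err[, 2]), 0.05)
})

test_that("a converged fit is a local SSE minimum", {
  a <- macaque_analysis(seed = 2)
  fit <- fit_cmf(a$samples)
  expect_true(fit$converged)
  sse <- function(aa, bb)
    sum((a$samples$E - aa * (exp(bb * a$samples$d_hat) - 1))^2)
  base <- sse(fit$a, fit$b)
  for (da in c(-0.01, 0, 0.01)) for (db in c(-0.01, 0, 0.01)) {
    if (da == 0 && db == 0) next
    expect_gte(sse(fit$a * (1 + da), fit$b * (1 + db)), base)
  }
})

test_that("prediction is exact at zero and inverts analytically", {
  fit <- structure(list(a = 1, b = 0.1), class = "cmf_fit")
  expect_identical(predict_eccentricity(fit, 0), 0)
  expect_equal(predict_eccentricity(fit, 10), exp(1) - 1, tolerance = 1e-12)
  d <- seq(0, 40, by = 0.5)
  expect_equal(cmf_inverse(predict_eccentricity(fit, d), 1, 0.1), d,
               tolerance = 1e-12)
})

test_that("histogram counts are conserved and permutation-invariant", {
  a <- macaque_analysis(seed = 3)
  h <- ecc_distance_histogram(a$samples)
  expect_equal(sum(h$counts), nrow(a$samples))
  expect_equal(diff(h$ecc_edges), rep(0.5, length(h$ecc_edges) - 1))
  expect_equal(diff(h$dist_edges), rep(1, length(h$dist_edges) - 1))
  expect_identical(h$ecc_edges[1], 0); expect_identical(h$dist_edges[1], 0)
  set.seed(5)
  perm <- a$samples[sample(nrow(a$samples)), ]
  h2 <- ecc_distance_histogram(perm)
  expect_identical(h$counts, h2$counts)
})

test_that("single-bin histograms still produce enclosing isocontours", {
  s <- data.frame(vertex = 1:20, d_hat = rep(0.4, 20), E = rep(0.2, 20),
                  rcas = TRUE, ecas = FALSE,
                  tag = factor(rep("rCaS", 20),
                               levels = c("rCaS", "eCaS", "V1-other")))
  h <- ecc_distance_histogram(s)
  expect_equal(sum(h$counts), 20)
  for (f in names(h$isocontours$rCaS)) {
    polys <- h$isocontours$rCaS[[f]]
    expect_gt(length(polys), 0)
    expect_true(point_in_any(0.5, 0.25, polys))   # (d, E) bin center
  }
})

test_that("level sets agree with a flood-fill oracle on a two-peak field", {
  # two clusters: tall peak (100 samples in one bin), short peak (40)
  mk <- function(n, d0, e0) data.frame(
    vertex = seq_len(n), d_hat = rep(d0, n), E = rep(e0, n))
  s <- rbind(mk(100, 2.5, 1.25), mk(40, 7.5, 3.75))
  s$rcas <- TRUE; s$ecas <- FALSE
  s$tag <- factor("rCaS", levels = c("rCaS", "eCaS", "V1-other"))
  class(s) <- c("magnification_samples", "data.frame")
  h <- ecc_distance_histogram(s)
  counts_tag <- matrix(0, nrow(h$counts), ncol(h$counts))
  counts_tag[3, 3] <- 100   # E bin [1,1.5), d bin [2,3)
  counts_tag[8, 8] <- 40
  expect_equal(h$counts[3, 3], 100); expect_equal(h$counts[8, 8], 40)
  centers <- list(tall = c(d = 2.5, E = 1.25), short = c(d = 7.5, E = 3.75))
  for (f in c(0.99, 0.75, 0.5, 0.25)) {
    polys <- h$isocontours$rCaS[[paste0("f", f)]]
    level <- f * 100
    above <- cells_at_level(counts_tag, level)
    for (cell in seq_len(nrow(above))) {
      dc <- (above[cell, 2] - 0.5) * 1
      ec <- (above[cell, 1] - 0.5) * 0.5
      expect_true(point_in_any(dc, ec, polys),
                  label = sprintf("f=%.2f cell (%0.1f,%0.2f) enclosed",
                                  f, dc, ec))
    }
    # the short peak is enclosed exactly when it reaches the level
    expect_identical(point_in_any(centers$short["d"], centers$short["E"],
                                  polys), 40 >= level)
  }
})

test_that("macaque rCaS isocontours sit above eCaS in distance and angle", {
  a <- macaque_analysis(seed = 6)
  h <- ecc_distance_histogram(a$samples)
  mean_iso <- function(tag) {
    pts <- do.call(rbind, h$isocontours[[tag]][["f0.5"]])
    colMeans(pts)
  }
  r <- mean_iso("rCaS"); e <- mean_iso("eCaS")
  expect_gt(r["d"], e["d"])
  expect_gt(r["E"], e["E"])
})
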