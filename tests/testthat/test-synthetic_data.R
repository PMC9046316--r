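# Ground-truth geometry, species presets, noise model, stimulus synthesis.

test_that("ground-truth eccentricity follows the magnification law", {
  p <- species_preset("human")
  patch <- generate_v1_patch(p)
  tr <- patch$truth
  expect_equal(tr$true_map$eccentricity$values,
               pmin(p$cmf_a * (exp(p$cmf_b * tr$d) - 1), p$stimulus_radius),
               tolerance = 1e-9)
  # foveal row is exactly eccentricity 0 for every polar angle
  fov <- which(tr$d == 0)
  expect_true(length(fov) >= 40)
  expect_true(all(tr$true_map$eccentricity$values[fov] == 0))
  # direct scalar evaluation at d = 33 mm: 1.0 * (exp(0.063 * 33) - 1)
  expect_equal(1.0 * (exp(0.063 * 33) - 1), 6.996, tolerance = 1e-3)
  near33 <- which(abs(tr$d - 33) < 0.26)
  expect_true(all(abs(tr$true_map$eccentricity$values[near33] - 7.0) < 0.15))
})

test_that("sulcal labels sit inside their eccentricity bands", {
  for (sp in c("human", "macaque")) {
    p <- species_preset(sp)
    tr <- generate_v1_patch(p)$truth
    ecc <- tr$true_map$eccentricity$values
    r <- tr$labels$labels$rCaS; e <- tr$labels$labels$eCaS
    expect_gt(length(r), 0); expect_gt(length(e), 0)
    expect_true(all(ecc[r] >= p$rcas_band[1] & ecc[r] <= p$rcas_band[2]),
                label = paste(sp, "rCaS band"))
    expect_true(all(ecc[e] >= p$ecas_band[1] & ecc[e] <= p$ecas_band[2]),
                label = paste(sp, "eCaS band"))
  }
})

test_that("preset validation rejects impossible configurations", {
  expect_error(species_preset("human", cmf_a = -1), "positive")
  expect_error(species_preset("human", rcas_band = c(2, 9)), "within")
  expect_error(species_preset("human", rcas_band = c(0.5, 3)), "disjoint")
  expect_error(generate_v1_patch(species_preset("human"), resolution = 0.5),
               "40 x 40")
})

test_that("white surface sits 2 mm under the pial surface", {
  patch <- generate_v1_patch(species_preset("macaque"))
  off <- sqrt(rowSums((patch$pial$vertices - patch$white$vertices)^2))
  expect_equal(max(abs(off - 2)), 0, tolerance = 1e-9)
})

test_that("zero noise is the identity and seeds are reproducible", {
  tr <- generate_v1_patch(species_preset("macaque"))$truth
  clean <- add_measurement_noise(tr, 0, 0, 0, seed = 5)
  expect_identical(clean$polar_angle$values, tr$true_map$polar_angle$values)
  expect_identical(clean$eccentricity$values,
                   tr$true_map$eccentricity$values)
  a <- add_measurement_noise(tr, 8, 0.1, 0.05, seed = 7)
  b <- add_measurement_noise(tr, 8, 0.1, 0.05, seed = 7)
  c_ <- add_measurement_noise(tr, 8, 0.1, 0.05, seed = 8)
  expect_identical(a$polar_angle$values, b$polar_angle$values)
  expect_identical(a$eccentricity$valid, b$eccentricity$valid)
  expect_false(identical(a$polar_angle$values, c_$polar_angle$values))
  # coherence decreases with noise
  expect_lt(mean(a$coherence$values), 1)
})

test_that("dropout count lies in the binomial 99 percent interval", {
  p <- species_preset("human")
  tr <- generate_v1_patch(p, resolution = 3)$truth   # 105 x 85 = 8925 vertices
  n <- tr$true_map$n_vertices
  noisy <- add_measurement_noise(tr, 0, 0, 0.1, seed = 42)
  k <- sum(!noisy$eccentricity$valid)
  lims <- qbinom(c(0.005, 0.995), n, 0.1)
  expect_gte(k, lims[1]); expect_lte(k, lims[2])
})

test_that("noisy polar angle stays wrapped and eccentricity positive", {
  tr <- generate_v1_patch(species_preset("macaque"))$truth
  m <- add_measurement_noise(tr, 45, 0.5, 0, seed = 3)
  pa <- m$polar_angle$values
  expect_true(all(pa > -180 & pa <= 180))
  expect_true(all(m$eccentricity$values >= 0))
})

test_that("stimulus timing invariants hold", {
  w <- stimulus_spec("wedge")
  expect_equal(w$duration, 8 * 40)
  r <- stimulus_spec("ring")
  expect_equal(r$duration, 7 * 50)
  expect_error(stimulus_spec("ring", sweep_scale = "log",
                             sweep_range = c(0, 8)), "positive")
})

test_that("time series phase encodes sweep position, direction and delay", {
  tr <- generate_v1_patch(species_preset("macaque"))$truth
  spec <- stimulus_spec("wedge", sweep_range = c(0, 360))
  v0 <- which(tr$phi == 0 & tr$d == 0)[1]   # polar angle 0 = sweep start
  ts <- generate_timeseries(tr, spec)
  pm <- fourier_phase(ts)
  expect_equal(pm$phase$values[v0], 0, tolerance = 1e-9)
  # reversing direction negates the noiseless phase
  spec_r <- stimulus_spec("wedge", direction = -1L, sweep_range = c(0, 360))
  pm_r <- fourier_phase(generate_timeseries(tr, spec_r))
  ok <- abs(abs(pm$phase$values) - pi) > 1e-6   # away from the wrap point
  expect_equal(pm$phase$values[ok], -pm_r$phase$values[ok],
               tolerance = 1e-9)
  # a 4 s delay on a 40 s cycle shifts phase by 2 pi * 4 / 40
  pm_d <- fourier_phase(generate_timeseries(tr, spec, hemodynamic_delay = 4))
  shift <- wrap_angle(pm_d$phase$values - pm$phase$values)
  expect_equal(shift, rep(2 * pi * 4 / 40, length(shift)),
               tolerance = 1e-9)
  # identical seeds give identical noisy series
  n1 <- generate_timeseries(tr, spec, noise_sd = 1, seed = 9)
  n2 <- generate_timeseries(tr, spec, noise_sd = 1, seed = 9)
  expect_identical(n1$data, n2$data)
})

test_that("ring blanks contribute baseline samples", {
  tr <- generate_v1_patch(species_preset("macaque"))$truth
  spec <- stimulus_spec("ring", sweep_range = c(0, 10))
  ts <- generate_timeseries(tr, spec)
  blank <- (ts$time %% 50) >= 40
  expect_true(sum(blank) == 7 * 10)
  expect_true(all(ts$data[, blank] == 0))
})
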