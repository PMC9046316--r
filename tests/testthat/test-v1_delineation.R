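# Meridian border detection, the foveal confluence line, and the
# distance-from-fovea field.

noiseless_subject <- function(species = "human", resolution = 2) {
  p <- species_preset(species)
  patch <- generate_v1_patch(p, resolution = resolution)
  list(p = p, patch = patch, tr = patch$truth)
}

test_that("noiseless borders coincide with the generator meridian rows", {
  s <- noiseless_subject("macaque")
  borders <- detect_meridian_borders(s$tr$true_map, s$patch$pial)
  expect_true(all(s$tr$phi[borders$dorsal_border] == -90))
  expect_true(all(s$tr$phi[borders$ventral_border] == 90))
  # ordered foveal -> peripheral
  ecc <- s$tr$true_map$eccentricity$values
  expect_true(all(diff(ecc[borders$dorsal_border]) >= 0))
  # symmetry: foveal endpoints are each other's mirror across the d axis
  d1 <- s$tr$d[borders$dorsal_border[1]]
  d2 <- s$tr$d[borders$ventral_border[1]]
  expect_equal(d1, 0); expect_equal(d2, 0)
})

test_that("a flat polar-angle map raises a delineation error", {
  s <- noiseless_subject("macaque")
  flat <- retinotopic_map(
    vertex_overlay(rep(0, s$tr$true_map$n_vertices), units = "deg"),
    s$tr$true_map$eccentricity)
  expect_error(detect_meridian_borders(flat, s$patch$pial),
               "delineation error.*meridian")
})

test_that("noisy borders stay within the band-plus-noise envelope", {
  s <- noiseless_subject("macaque")
  for (seed in 1:5) {
    noisy <- add_measurement_noise(s$tr, angle_sd = 5, log_ecc_sd = 0,
                                   dropout_rate = 0, seed = seed)
    borders <- detect_meridian_borders(noisy, s$patch$pial, tol_deg = 10)
    truth_dev <- abs(s$tr$phi[c(borders$dorsal_border,
                                borders$ventral_border)])
    expect_true(all(truth_dev >= 90 - 25),
                label = sprintf("seed %d", seed))
  }
})

test_that("the confluence line follows the zero-eccentricity edge", {
  s <- noiseless_subject("human")
  borders <- detect_meridian_borders(s$tr$true_map, s$patch$pial)
  line <- foveal_confluence_line(s$tr$true_map, s$patch$pial, borders)
  expect_true(all(s$tr$true_map$eccentricity$values[line] == 0))
  expect_true(all(s$tr$d[line] == 0))
  # endpoints are the borders' foveal endpoints
  expect_identical(line[1], borders$dorsal_border[1])
  expect_identical(line[length(line)], borders$ventral_border[1])
})

test_that("adjacent foveal endpoints give the two-vertex path", {
  g <- make_grid_mesh(5, 5)
  n <- g$nx * g$ny + (g$nx - 1) * (g$ny - 1)
  map <- retinotopic_map(vertex_overlay(rep(0, n), units = "deg"),
                         vertex_overlay(rep(1, n), units = "deg"))
  borders <- list(dorsal_border = g$lattice(1, 1),
                  ventral_border = g$lattice(2, 1))
  line <- suppressWarnings(
    foveal_confluence_line(map, g$mesh, borders))
  expect_equal(line, c(g$lattice(1, 1), g$lattice(2, 1)))
})

test_that("the eccentricity-weighted path matches exhaustive search", {
  # 15x15 lattice patch with a synthetic eccentricity valley
  g <- make_grid_mesh(15, 15)
  mesh <- g$mesh
  n <- nrow(mesh$vertices)
  ecc <- 0.3 * abs(mesh$vertices[, 2] - 7) + 0.05 * mesh$vertices[, 1]
  map <- retinotopic_map(vertex_overlay(rep(0, n), units = "deg"),
                         vertex_overlay(ecc, units = "deg"))
  borders <- list(dorsal_border = g$lattice(1, 8),
                  ventral_border = g$lattice(15, 8))
  line <- suppressWarnings(
    foveal_confluence_line(map, mesh, borders, e_scale = 1))
  adj <- vertex_adjacency(mesh)
  w_oracle <- adj$edges$length *
    (1 + (ecc[adj$edges$from] + ecc[adj$edges$to]) / 2)
  d_oracle <- bellman_ford(n, data.frame(from = adj$edges$from,
                                         to = adj$edges$to,
                                         length = w_oracle),
                           g$lattice(1, 8))
  # path cost equals the brute-force optimum
  cost <- 0
  for (k in seq_len(length(line) - 1)) {
    e <- which((adj$edges$from == line[k] & adj$edges$to == line[k + 1]) |
                 (adj$edges$to == line[k] & adj$edges$from == line[k + 1]))
    cost <- cost + w_oracle[e]
  }
  expect_equal(cost, d_oracle[g$lattice(15, 8)], tolerance = 1e-12)
})

test_that("distance from fovea is zero on the line and tracks the d axis", {
  s <- noiseless_subject("macaque")
  delin <- delineate_v1(s$tr$true_map, s$patch$pial,
                        stimulus_radius = s$p$stimulus_radius)
  dist <- delin$distance_from_fovea$distance$values
  expect_true(all(dist[delin$confluence_line] == 0))
  # the generator coordinate is arc length: agreement within the edge-graph
  # overestimate bound (9 percent) plus discretization
  nonzero <- s$tr$d > 1
  ratio <- dist[nonzero] / s$tr$d[nonzero]
  expect_true(all(ratio > 0.97 & ratio < 1.09))
})

test_that("line-source and midpoint-source distances are near-identical", {
  s <- noiseless_subject("human")
  delin <- delineate_v1(s$tr$true_map, s$patch$pial,
                        stimulus_radius = s$p$stimulus_radius)
  mid <- distance_from_fovea(s$patch$pial, delin$v1_vertices,
                             delin$confluence_line, mode = "midpoint")
  r <- cor(delin$distance_from_fovea$distance$values,
           mid$distance$values)
  expect_gt(r, 0.99)
})

test_that("median eccentricity increases along distance bins", {
  s <- noiseless_subject("macaque")
  noisy <- add_measurement_noise(s$tr, seed = 12)
  delin <- delineate_v1(noisy, s$patch$pial,
                        v1_hint = s$tr$labels$labels$V1,
                        stimulus_radius = s$p$stimulus_radius)
  samples <- collect_samples(noisy, delin, s$tr$labels)
  bins <- floor(samples$d_hat)
  med <- tapply(samples$E, bins, median)
  expect_true(all(diff(med) > -1e-9))
})
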