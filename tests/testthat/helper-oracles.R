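# Independent oracles and geometric fixtures used across the suite. These
# deliberately re-derive quantities by brute force (edge relaxation, direct
# accumulation, grid search, explicit projections) so they share no code
# path with the package implementations they check.

# Unit icosphere: subdivided icosahedron re-projected to radius 1.
make_icosphere <- function(subdiv = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; c_ <- f[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  triangle_mesh(v, f, surface_kind = "sphere")
}

# Flat union-jack grid: nx x ny vertex lattice (unit spacing * `spacing`)
# plus one center vertex per quad, four triangles per quad, so both
# diagonal directions are available to shortest paths.
make_grid_mesh <- function(nx, ny, spacing = 1) {
  gx <- rep(seq_len(nx) - 1L, times = ny)
  gy <- rep(seq_len(ny) - 1L, each = nx)
  cx <- rep(seq_len(nx - 1L) - 0.5, times = ny - 1L)
  cy <- rep(seq_len(ny - 1L) - 0.5, each = nx - 1L)
  v <- cbind(c(gx, cx), c(gy, cy), 0) * spacing
  vid <- function(i, j) (j - 1L) * nx + i
  cid <- function(i, j) nx * ny + (j - 1L) * (nx - 1L) + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  f <- rbind(cbind(vid(i, j), vid(i + 1L, j), cid(i, j)),
             cbind(vid(i + 1L, j), vid(i + 1L, j + 1L), cid(i, j)),
             cbind(vid(i + 1L, j + 1L), vid(i, j + 1L), cid(i, j)),
             cbind(vid(i, j + 1L), vid(i, j), cid(i, j)))
  list(mesh = triangle_mesh(v, f, surface_kind = "synthetic"),
       lattice = function(i, j) vid(i, j), nx = nx, ny = ny)
}

# Brute-force multi-source shortest paths by repeated edge relaxation
# (Bellman-Ford), on the undirected edge list.
bellman_ford <- function(n, edges, sources) {
  d <- rep(Inf, n)
  d[sources] <- 0
  from <- c(edges$from, edges$to)
  to <- c(edges$to, edges$from)
  w <- c(edges$length, edges$length)
  repeat {
    cand <- d[from] + w
    upd <- tapply(cand, to, min)
    dn <- d
    ix <- as.integer(names(upd))
    dn[ix] <- pmin(dn[ix], upd)
    if (identical(dn, d)) break
    d <- dn
  }
  d
}

# Wrap an angle in radians to (-pi, pi].
wrap_angle <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w <= -pi] <- pi
  w
}

# Even-odd ray-casting point-in-polygon.
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py) &&
        px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      inside <- !inside
    j <- i
  }
  inside
}

point_in_any <- function(px, py, polys) {
  for (p in polys) if (point_in_polygon(px, py, p$d, p$E)) return(TRUE)
  FALSE
}

# Cells at or above an absolute level (the level-set the isocontours trace).
cells_at_level <- function(counts, level) which(counts >= level, arr.ind = TRUE)

# Two-stage grid-search minimizer of the exponential magnification SSE,
# independent of the package's nonlinear least squares.
grid_search_cmf <- function(d, E, a_lim = c(0.2, 3), b_lim = c(0.01, 0.3)) {
  sse <- function(a, b) sum((E - a * (exp(b * d) - 1))^2)
  refine <- function(al, bl, n = 41L) {
    as <- seq(al[1], al[2], length.out = n)
    bs <- seq(bl[1], bl[2], length.out = n)
    S <- outer(as, bs, Vectorize(sse))
    ix <- which(S == min(S), arr.ind = TRUE)[1, ]
    list(a = as[ix[1]], b = bs[ix[2]],
         da = diff(al) / (n - 1), db = diff(bl) / (n - 1))
  }
  g <- refine(a_lim, b_lim)
  for (k in 1:3)
    g <- refine(c(g$a - 2 * g$da, g$a + 2 * g$da),
                c(g$b - 2 * g$db, g$b + 2 * g$db))
  list(a = g$a, b = g$b)
}

# Two-way fixed-effects F statistics via explicit normal equations and
# model-comparison (Type II) sums of squares.
oracle_two_way_F <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  rss <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  Xa <- stats::model.matrix(~A); Xb <- stats::model.matrix(~B)
  Xab <- stats::model.matrix(~A + B); Xfull <- stats::model.matrix(~A * B)
  n <- length(y)
  dfe <- n - qr(Xfull)$rank
  mse <- rss(Xfull) / dfe
  ss <- c(species = rss(Xb) - rss(Xab),
          hemisphere = rss(Xa) - rss(Xab),
          interaction = rss(Xab) - rss(Xfull))
  dfn <- c((nlevels(A) - 1), (nlevels(B) - 1),
           (nlevels(A) - 1) * (nlevels(B) - 1))
  list(F = ss / dfn / mse, df_den = dfe)
}

# Small noiseless magnification sample set straight from the formula.
formula_samples <- function(a, b, dmax = 35, n = 400) {
  d <- seq(0, dmax, length.out = n)
  structure(data.frame(vertex = seq_len(n), d_hat = d,
                       E = a * (exp(b * d) - 1),
                       rcas = FALSE, ecas = FALSE,
                       tag = factor(rep("V1-other", n),
                                    levels = c("rCaS", "eCaS", "V1-other"))),
            class = c("magnification_samples", "data.frame"))
}
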