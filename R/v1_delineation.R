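# V1 delineation: vertical-meridian border paths from polar-angle bands, the
# foveal confluence line, and geodesic distance from the fovea.

# One pass of circular (complex-mean) smoothing of polar angle over the
# 1-ring; invalid vertices neither contribute nor change.
smooth_polar_angle <- function(values, valid, neighbors, iters = 1L) {
  th <- values * pi / 180
  for (it in seq_len(iters)) {
    z <- complex(modulus = as.numeric(valid), argument = th)
    znew <- z
    for (v in which(valid)) {
      nb <- neighbors[[v]]
      zs <- z[v] + sum(z[nb])
      if (Mod(zs) > 1e-12) znew[v] <- zs
    }
    th <- Arg(znew)
  }
  out <- values
  out[valid] <- wrap180(th[valid] * 180 / pi)
  out
}

circ_dev <- function(angle_deg, target_deg) abs(wrap180(angle_deg - target_deg))

# Largest connected component (vertex ids) of the subgraph induced by `keep`.
largest_component <- function(g, keep) {
  sub <- igraph::induced_subgraph(g, keep)
  comp <- igraph::components(sub)
  keep[comp$membership == which.max(comp$csize)]
}

#' Detect V1's vertical-meridian borders from a polar-angle map
#'
#' Vertices within `tol_deg` of the lower (-90 deg) and upper (+90 deg)
#' vertical meridians are banded; each band's largest connected component is
#' thinned to an edge-graph path from its most foveal to its most peripheral
#' vertex, preferring vertices closest to the meridian. The polar-angle map
#' is lightly smoothed (circular 1-ring mean) before banding to stabilize
#' the band under measurement noise.
#'
#' @param map a `retinotopic_map`.
#' @param mesh the `triangle_mesh` the map lives on.
#' @param v1_hint optional vertex set restricting the search.
#' @param tol_deg half-width of the meridian band (deg, default 10).
#' @param smooth_iters circular smoothing passes before banding (default 1;
#'   0 disables).
#' @return list with ordered vertex paths `dorsal_border` (lower vertical
#'   meridian, -90) and `ventral_border` (upper, +90), foveal end first.
#' @export
detect_meridian_borders <- function(map, mesh, v1_hint = NULL, tol_deg = 10,
                                    smooth_iters = 1L) {
  adj <- vertex_adjacency(mesh)
  g <- mesh_graph(mesh)
  valid <- map_valid(map)
  pa <- map$polar_angle$values
  if (smooth_iters > 0)
    pa <- smooth_polar_angle(pa, valid, adj$neighbors, smooth_iters)
  ecc <- map$eccentricity$values
  one_border <- function(target, label) {
    dev <- circ_dev(pa, target)
    band <- which(valid & dev < tol_deg)
    if (!is.null(v1_hint)) band <- intersect(band, v1_hint)
    if (length(band) == 0L)
      stop("delineation error: no vertices within ", tol_deg,
           " deg of the ", label, " meridian (", target, " deg)")
    # one-ring dilation bridges cuts from vertex dropout: the component and
    # the path may traverse connector vertices, the endpoints and the band
    # criterion itself stay strict
    dil <- sort(unique(c(band, unlist(adj$neighbors[band]))))
    if (!is.null(v1_hint)) dil <- intersect(dil, sort(unique(c(
      v1_hint, unlist(adj$neighbors[v1_hint])))))
    comp <- largest_component(g, dil)
    bandc <- intersect(band, comp)
    if (length(bandc) == 0L)
      stop("delineation error: ", label, " meridian band is empty after ",
           "component selection")
    pick <- function(extreme) {
      e <- ecc[bandc]
      cand <- bandc[abs(e - extreme(e)) < 1e-12]
      cand[which.min(dev[cand])]
    }
    fov <- pick(min); per <- pick(max)
    if (fov == per) return(fov)
    sub <- igraph::induced_subgraph(g, comp)
    ends <- igraph::ends(sub, igraph::E(sub))
    wdev <- (dev[comp[as.integer(ends[, 1])]] +
               dev[comp[as.integer(ends[, 2])]]) / 2
    w <- igraph::E(sub)$weight * (1 + wdev / tol_deg)
    p <- igraph::shortest_paths(sub, from = match(fov, comp),
                                to = match(per, comp), weights = w)$vpath[[1]]
    comp[as.integer(p)]
  }
  list(dorsal_border = one_border(-90, "lower vertical (dorsal)"),
       ventral_border = one_border(90, "upper vertical (ventral)"))
}

#' Construct the foveal confluence line
#'
#' The line through the most foveal measurements linking the foveal
#' endpoints of the two vertical-meridian borders: an edge-graph shortest
#' path with edge weights `length * (1 + E_mid / e_scale)`, so the path
#' prefers low-eccentricity vertices. A warning is logged if any path vertex
#' exceeds the `foveal_quantile` quantile of V1 eccentricity by more than
#' 0.5 deg.
#'
#' @param map a `retinotopic_map`; @param mesh its mesh.
#' @param borders result of [detect_meridian_borders()].
#' @param foveal_quantile quantile of V1 eccentricity the line should stay
#'   below (default 0.05).
#' @param e_scale eccentricity scale (deg) of the path penalty (default 1).
#' @param v1_vertices vertex set for the quantile check (defaults to all
#'   valid vertices).
#' @return ordered vertex path from the dorsal to the ventral foveal
#'   endpoint.
#' @export
foveal_confluence_line <- function(map, mesh, borders, foveal_quantile = 0.05,
                                   e_scale = 1, v1_vertices = NULL) {
  stopifnot(length(borders$dorsal_border) > 0,
            length(borders$ventral_border) > 0)
  g <- mesh_graph(mesh)
  ecc <- map$eccentricity$values
  ecc_w <- ifelse(is.finite(ecc), ecc, max(ecc[is.finite(ecc)]))
  ends <- igraph::ends(g, igraph::E(g))
  emid <- (ecc_w[as.integer(ends[, 1])] + ecc_w[as.integer(ends[, 2])]) / 2
  w <- igraph::E(g)$weight * (1 + emid / e_scale)
  from <- borders$dorsal_border[1]; to <- borders$ventral_border[1]
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = from, to = to, weights = w)$vpath[[1]])
  if (length(sp) == 0)
    stop("delineation error: border foveal endpoints are disconnected")
  line <- as.integer(sp)
  valid <- map_valid(map)
  pool <- if (is.null(v1_vertices)) which(valid) else
    intersect(v1_vertices, which(valid))
  cap <- stats::quantile(ecc[pool], foveal_quantile, names = FALSE)
  if (any(ecc[line] > cap + 0.5))
    warning(sprintf("confluence line rises to %.2f deg eccentricity (foveal quantile cap %.2f deg)",
                    max(ecc[line]), cap))
  line
}

#' Geodesic distance of every vertex from the foveal confluence
#'
#' @param mesh a `triangle_mesh`.
#' @param v1_vertices vertex set of V1 (kept on the result for bookkeeping).
#' @param confluence_line ordered vertex path from
#'   [foveal_confluence_line()].
#' @param mode `"line"`: multi-source geodesic from every line vertex;
#'   `"midpoint"`: single-source from the line's middle vertex.
#' @return a `geodesic_field` (mm).
#' @export
distance_from_fovea <- function(mesh, v1_vertices, confluence_line,
                                mode = c("line", "midpoint")) {
  mode <- match.arg(mode)
  stopifnot(length(confluence_line) > 0)
  src <- if (mode == "line") confluence_line
  else confluence_line[ceiling(length(confluence_line) / 2)]
  geodesic_distance(mesh, src)
}

#' Full V1 delineation from a retinotopic map
#'
#' Chains border detection, the foveal confluence line, and the
#' distance-from-fovea field. When `v1_hint` is absent, V1 is taken as the
#' connected set of valid vertices whose eccentricity does not exceed
#' `stimulus_radius` (the stimulated extent) containing the confluence
#' line, together with the border paths.
#'
#' @inheritParams detect_meridian_borders
#' @inheritParams foveal_confluence_line
#' @param stimulus_radius eccentricity cap (deg) for the V1 region when
#'   `v1_hint` is absent; defaults to the maximum valid eccentricity.
#' @param mode distance mode, see [distance_from_fovea()].
#' @return object of class `v1_delineation` with `v1_vertices`,
#'   `dorsal_border`, `ventral_border`, `confluence_line`,
#'   `distance_from_fovea`.
#' @export
delineate_v1 <- function(map, mesh, v1_hint = NULL, tol_deg = 10,
                         smooth_iters = 1L, foveal_quantile = 0.05,
                         e_scale = 1, stimulus_radius = NULL,
                         mode = "line") {
  borders <- detect_meridian_borders(map, mesh, v1_hint, tol_deg,
                                     smooth_iters)
  line <- foveal_confluence_line(map, mesh, borders, foveal_quantile,
                                 e_scale, v1_vertices = v1_hint)
  if (is.null(v1_hint)) {
    valid <- map_valid(map)
    ecc <- map$eccentricity$values
    cap <- stimulus_radius %||% max(ecc[valid])
    cand <- which(valid & ecc <= cap + 1e-9)
    g <- mesh_graph(mesh)
    sub <- igraph::induced_subgraph(g, cand)
    comp <- igraph::components(sub)$membership
    seeds <- match(intersect(line, cand), cand)
    seeds <- seeds[!is.na(seeds)]
    keep_comp <- unique(comp[seeds])
    v1 <- sort(unique(c(cand[comp %in% keep_comp], borders$dorsal_border,
                        borders$ventral_border, line)))
  } else v1 <- sort(unique(as.integer(v1_hint)))
  structure(list(v1_vertices = v1,
                 dorsal_border = borders$dorsal_border,
                 ventral_border = borders$ventral_border,
                 confluence_line = line,
                 distance_from_fovea = distance_from_fovea(mesh, v1, line,
                                                           mode)),
            class = "v1_delineation")
}

#' @export
print.v1_delineation <- function(x, ...) {
  cat(sprintf("<v1_delineation: |V1|=%d, borders %d/%d, confluence line %d vertices>\n",
              length(x$v1_vertices), length(x$dorsal_border),
              length(x$ventral_border), length(x$confluence_line)))
  invisible(x)
}
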