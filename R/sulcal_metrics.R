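# Per-sulcus morphometric and retinotopic summaries, visual-field coverage,
# and group overlap maps.

#' Summarize one sulcus against V1
#'
#' Areas are computed on both surfaces by one-third-per-vertex attribution;
#' `pct_of_v1` is the pial area of the sulcus-within-V1 over the pial area
#' of V1. Eccentricity statistics use valid labeled vertices inside V1
#' only: sulcal vertices outside V1 count toward area but not toward
#' eccentricity (a note is logged when the label leaves V1).
#'
#' @param map a `retinotopic_map`.
#' @param pial,white the two `triangle_mesh` surfaces.
#' @param labels a `label_set` containing `sulcus`.
#' @param delineation a `v1_delineation`.
#' @param sulcus label name, e.g. `"rCaS"`.
#' @param weighted if `TRUE`, weight the mean eccentricity by coherence.
#' @return one-row data.frame: `subject_id`, `species`, `hemisphere`,
#'   `sulcus`, `area_pial`, `area_white` (mm^2), `pct_of_v1`, `mean_ecc`,
#'   `ecc_min`, `ecc_max` (deg), `dist_min`, `dist_max` (mm), `n_vertices`.
#' @export
summarize_sulcus <- function(map, pial, white, labels, delineation, sulcus,
                             weighted = FALSE) {
  ix <- labels$labels[[sulcus]]
  if (is.null(ix)) stop("no label named '", sulcus, "'")
  v1 <- delineation$v1_vertices
  in_v1 <- intersect(ix, v1)
  if (length(in_v1) == 0L)
    message("label '", sulcus, "' falls entirely outside V1")
  else if (length(in_v1) < length(ix))
    message("label '", sulcus, "' extends outside V1 (",
            length(ix) - length(in_v1), " of ", length(ix), " vertices)")
  area_pial <- surface_area(pial, ix)
  area_white <- surface_area(white, ix)
  pct <- if (length(in_v1))
    100 * surface_area(pial, in_v1) / surface_area(pial, v1) else 0
  ok <- intersect(in_v1, which(map_valid(map)))
  ecc <- map$eccentricity$values[ok]
  dfield <- delineation$distance_from_fovea$distance
  dd <- dfield$values[intersect(ok, which(dfield$valid))]
  mean_ecc <- if (length(ecc) == 0) NA_real_
  else if (weighted && !is.null(map$coherence)) {
    w <- map$coherence$values[ok]
    sum(w * ecc) / sum(w)
  } else mean(ecc)
  data.frame(subject_id = labels$subject_id, species = labels$species,
             hemisphere = labels$hemisphere, sulcus = sulcus,
             area_pial = area_pial, area_white = area_white,
             pct_of_v1 = pct, mean_ecc = mean_ecc,
             ecc_min = if (length(ecc)) min(ecc) else NA_real_,
             ecc_max = if (length(ecc)) max(ecc) else NA_real_,
             dist_min = if (length(dd)) min(dd) else NA_real_,
             dist_max = if (length(dd)) max(dd) else NA_real_,
             n_vertices = length(ix))
}

#' Visual-field coverage of a labeled region
#'
#' Converts (polar angle, eccentricity) of each valid labeled vertex to
#' Cartesian visual-field coordinates. Under the package convention, 0 deg
#' polar angle is the contralateral horizontal meridian: x is positive in
#' the contralateral hemifield and is mirrored for right-hemisphere data so
#' that left- and right-hemisphere coverages plot into the correct
#' hemifields.
#'
#' @param map a `retinotopic_map`.
#' @param vertices integer vertex set (e.g. one entry of a `label_set`).
#' @param hemisphere `"left"` or `"right"`.
#' @return data.frame `vertex`, `x`, `y` (deg); `sqrt(x^2 + y^2)` equals
#'   the vertex eccentricity.
#' @export
field_coverage <- function(map, vertices, hemisphere = "left") {
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  v <- intersect(as.integer(vertices), which(map_valid(map)))
  th <- map$polar_angle$values[v] * pi / 180
  ec <- map$eccentricity$values[v]
  sgn <- if (hemisphere == "left") 1 else -1
  data.frame(vertex = v, x = sgn * ec * cos(th), y = ec * sin(th))
}

#' Group overlap map of a label across subjects
#'
#' All label sets must be indexed on one shared template mesh (synthetic
#' subjects of one preset share their grid). Returns the per-vertex count
#' of subjects whose label contains the vertex, and the fraction count/n.
#'
#' @param label_sets list of `label_set`s on a common mesh.
#' @param name label name to tally.
#' @param n_vertices vertex count of the shared mesh.
#' @return list with `count` and `fraction` `vertex_overlay`s and
#'   `n_subjects`.
#' @export
group_overlap <- function(label_sets, name, n_vertices) {
  counts <- integer(n_vertices)
  for (ls in label_sets) {
    ix <- ls$labels[[name]]
    if (is.null(ix)) next
    if (length(ix) && max(ix) > n_vertices)
      stop("dimension error: label '", name, "' of subject ",
           ls$subject_id, " exceeds the template mesh")
    counts[ix] <- counts[ix] + 1L
  }
  n <- length(label_sets)
  list(count = vertex_overlay(as.numeric(counts), units = "unitless"),
       fraction = vertex_overlay(counts / n, units = "unitless"),
       n_subjects = n)
}
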