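#' sulcmap: sulcal anatomy and retinotopic cortical magnification in V1
#'
#' Core containers: [triangle_mesh()], [vertex_overlay()], [retinotopic_map()],
#' [label_set()]. Geometry: [surface_area()], [geodesic_distance()].
#' Synthesis: [species_preset()], [generate_v1_patch()]. Analysis:
#' [fourier_phase()], [delineate_v1()], [fit_cmf()], [summarize_sulcus()],
#' [two_way_anova()], [run_pipeline()].
#'
#' Vertex indices are 1-based in R objects; FreeSurfer and GIFTI files store
#' 0-based indices and are converted at the file boundary.
#'
#' @name sulcmap-package
#' @keywords internal
"_PACKAGE"

# ---- core types -------------------------------------------------------------

#' Triangle mesh of one cortical surface
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param surface_kind one of `"pial"`, `"white"`, `"inflated"`, `"sphere"`,
#'   `"synthetic"`.
#' @return object of class `triangle_mesh` with fields `vertices`, `faces`,
#'   `surface_kind`.
#' @export
triangle_mesh <- function(vertices, faces, surface_kind = "pial") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  surface_kind <- match.arg(surface_kind,
                            c("pial", "white", "inflated", "sphere", "synthetic"))
  n <- nrow(vertices)
  if (nrow(faces) > 0L) {
    rng <- range(faces)
    if (rng[1] < 1L || rng[2] > n)
      stop("mesh integrity error: face index ", rng[2],
           " outside vertex range 1..", n)
    ta <- triangle_areas_impl(vertices, faces)
    if (any(ta <= 0))
      stop("mesh integrity error: ", sum(ta <= 0),
           " degenerate (zero-area) face(s)")
  }
  structure(list(vertices = vertices, faces = faces,
                 surface_kind = surface_kind),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces, kind=%s>\n",
              nrow(x$vertices), nrow(x$faces), x$surface_kind))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Per-vertex scalar overlay
#'
#' Values with a validity mask and declared units. Invalid vertices (stored
#' as NaN/NA on disk) are excluded from every downstream statistic.
#'
#' @param values numeric vector, one value per mesh vertex.
#' @param valid logical mask; defaults to `!is.na(values)`.
#' @param units `"deg"`, `"mm"`, `"rad"`, or `"unitless"`.
#' @return object of class `vertex_overlay`.
#' @export
vertex_overlay <- function(values, valid = NULL, units = "unitless") {
  values <- as.numeric(values)
  if (is.null(valid)) valid <- is.finite(values)
  valid <- as.logical(valid) & is.finite(values)
  units <- match.arg(units, c("deg", "mm", "rad", "unitless"))
  structure(list(values = values, valid = valid, units = units),
            class = "vertex_overlay")
}

#' @export
print.vertex_overlay <- function(x, ...) {
  cat(sprintf("<vertex_overlay: %d values (%s), %d invalid>\n",
              length(x$values), x$units, sum(!x$valid)))
  invisible(x)
}

check_units <- function(overlay, expected, what = "overlay") {
  if (!identical(overlay$units, expected))
    stop(sprintf("unit mismatch: %s carries '%s' but '%s' required",
                 what, overlay$units, expected))
  invisible(TRUE)
}

#' Per-vertex retinotopic map
#'
#' Polar angle convention (fixed package-wide): 0 deg = contralateral
#' horizontal meridian, +90 deg = upper vertical meridian, -90 deg = lower
#' vertical meridian; values lie in (-180, 180].
#'
#' @param polar_angle,eccentricity,coherence `vertex_overlay`s (deg, deg,
#'   unitless); `coherence` optional.
#' @return object of class `retinotopic_map`.
#' @export
retinotopic_map <- function(polar_angle, eccentricity, coherence = NULL) {
  stopifnot(inherits(polar_angle, "vertex_overlay"),
            inherits(eccentricity, "vertex_overlay"))
  check_units(polar_angle, "deg", "polar_angle")
  check_units(eccentricity, "deg", "eccentricity")
  n <- length(polar_angle$values)
  if (length(eccentricity$values) != n)
    stop("dimension error: polar_angle and eccentricity differ in length")
  pa <- polar_angle$values[polar_angle$valid]
  if (length(pa) && (any(pa <= -180) || any(pa > 180)))
    stop("polar angle outside (-180, 180]")
  ec <- eccentricity$values[eccentricity$valid]
  if (length(ec) && any(ec < 0)) stop("negative eccentricity")
  if (!is.null(coherence)) {
    stopifnot(inherits(coherence, "vertex_overlay"))
    if (length(coherence$values) != n)
      stop("dimension error: coherence length mismatch")
    co <- coherence$values[coherence$valid]
    if (length(co) && (any(co < 0) || any(co > 1)))
      stop("coherence outside [0, 1]")
  }
  structure(list(polar_angle = polar_angle, eccentricity = eccentricity,
                 coherence = coherence, n_vertices = n),
            class = "retinotopic_map")
}

map_valid <- function(map) {
  v <- map$polar_angle$valid & map$eccentricity$valid
  if (!is.null(map$coherence)) v <- v & map$coherence$valid
  v
}

#' Named vertex subsets (V1, rCaS, eCaS, ...)
#'
#' Labels may overlap: the retrocalcarine sulcus is typically a subset of V1.
#' Duplicate indices within one label are deduplicated with a message.
#'
#' @param labels named list of integer vertex-index vectors (1-based).
#' @param species `"human"` or `"macaque"`.
#' @param hemisphere `"left"` or `"right"`.
#' @param subject_id free-text subject identifier.
#' @return object of class `label_set`.
#' @export
label_set <- function(labels, species = "human", hemisphere = "left",
                      subject_id = "subject") {
  stopifnot(is.list(labels), !is.null(names(labels)))
  species <- match.arg(species, c("human", "macaque"))
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  labels <- lapply(names(labels), function(nm) {
    ix <- as.integer(labels[[nm]])
    if (anyDuplicated(ix)) {
      message("label '", nm, "': duplicate vertex indices deduplicated")
      ix <- unique(ix)
    }
    if (length(ix) && any(ix < 1L)) stop("label '", nm, "': index < 1")
    sort(ix)
  }) |> stats::setNames(names(labels))
  structure(list(labels = labels, species = species, hemisphere = hemisphere,
                 subject_id = subject_id),
            class = "label_set")
}

#' Check a label set against a mesh
#' @param labels a `label_set`; @param mesh a `triangle_mesh`.
#' @return `labels`, invisibly, if all indices are valid on `mesh`.
#' @export
bind_labels <- function(labels, mesh) {
  n <- n_vertices(mesh)
  for (nm in names(labels$labels)) {
    ix <- labels$labels[[nm]]
    if (length(ix) && max(ix) > n)
      stop("label integrity error: '", nm, "' references vertex ", max(ix),
           " beyond mesh size ", n)
  }
  invisible(labels)
}

# ---- FreeSurfer binary formats ---------------------------------------------
# Big-endian throughout. Surface: triangle-file magic 0xFFFFFE; curv: "new
# format" magic 0xFFFFFF (three bytes of 255).

read_int3 <- function(con) {
  b <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  if (length(b) < 3L) stop("format error at byte 0: truncated magic")
  b[1] * 65536L + b[2] * 256L + b[3]
}

write_int3 <- function(con, x) {
  writeBin(as.integer(c(x %/% 65536L, (x %/% 256L) %% 256L, x %% 256L)),
           con, size = 1L)
}

#' Read a cortical surface file
#'
#' @param path file path.
#' @param format `"freesurfer"` (binary triangle file) or `"gifti"`
#'   (`.surf.gii`); guessed from the extension when `NULL`.
#' @param surface_kind stored on the returned mesh.
#' @return a `triangle_mesh`; vertex order preserved exactly as stored.
#' @export
read_surface <- function(path, format = NULL, surface_kind = "pial") {
  format <- format %||% guess_format(path, "surface")
  if (format == "gifti") return(read_gifti_surface(path, surface_kind))
  if (file.size(path) < 3) stop("format error at byte 0: file too short")
  con <- file(path, "rb"); on.exit(close(con))
  magic <- read_int3(con)
  if (magic != 16777214L)  # 0xFFFFFE
    stop("format error at byte 0: bad magic ", magic,
         " (expected FreeSurfer triangle magic 16777214)")
  # created-by line terminated by "\n\n"
  cmt <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) stop("format error: truncated comment")
    cmt <- c(cmt, b)
    lc <- length(cmt)
    if (lc >= 2L && cmt[lc] == as.raw(10L) && cmt[lc - 1L] == as.raw(10L))
      break
  }
  counts <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
  if (length(counts) < 2L) stop("format error: truncated header")
  nv <- counts[1]; nf <- counts[2]
  xyz <- readBin(con, "double", n = 3L * nv, size = 4L, endian = "big")
  fcs <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(xyz) < 3L * nv || length(fcs) < 3L * nf)
    stop("format error: truncated vertex/face data")
  triangle_mesh(matrix(xyz, ncol = 3L, byrow = TRUE),
                matrix(fcs, ncol = 3L, byrow = TRUE) + 1L,
                surface_kind = surface_kind)
}

#' Write a cortical surface file
#' @inheritParams read_surface
#' @param mesh a `triangle_mesh`.
#' @export
write_surface <- function(mesh, path, format = NULL) {
  format <- format %||% guess_format(path, "surface")
  if (format == "gifti") return(write_gifti_surface(mesh, path))
  con <- file(path, "wb"); on.exit(close(con))
  write_int3(con, 16777214L)
  writeBin(charToRaw("created by sulcmap\n\n"), con)
  writeBin(as.integer(c(nrow(mesh$vertices), nrow(mesh$faces))), con,
           size = 4L, endian = "big")
  writeBin(as.vector(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read a per-vertex overlay
#'
#' @param path file path.
#' @param format `"curv"` (FreeSurfer new-format curv), `"gifti"`
#'   (`.func.gii`), or `"csv"` (columns vertex,value); guessed when `NULL`.
#' @param units units to declare on the overlay.
#' @param mesh optional mesh; vertex count is checked when given.
#' @param one_based for CSV only: whether stored vertex indices are 1-based
#'   (default `FALSE`, i.e. 0-based as in the FreeSurfer ecosystem).
#' @return a `vertex_overlay`; NaN values become invalid-mask entries.
#' @export
read_overlay <- function(path, format = NULL, units = "unitless",
                         mesh = NULL, one_based = FALSE) {
  format <- format %||% guess_format(path, "overlay")
  vals <- switch(format,
    curv = {
      con <- file(path, "rb"); on.exit(close(con))
      magic <- read_int3(con)
      if (magic != 16777215L)  # 0xFFFFFF
        stop("format error at byte 0: bad curv magic ", magic,
             " (new-format magic 16777215 required)")
      hdr <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
      v <- readBin(con, "double", n = hdr[1], size = 4L, endian = "big")
      if (length(v) < hdr[1]) stop("format error: truncated curv data")
      v
    },
    gifti = read_gifti_func(path),
    csv = {
      df <- utils::read.csv(path, header = csv_has_header(path))
      names(df)[1:2] <- c("vertex", "value")
      ix <- as.integer(df$vertex) + if (one_based) 0L else 1L
      if (any(ix < 1L))
        stop("vertex index 0 in a CSV declared 1-based; drop one_based")
      v <- rep(NA_real_, max(ix))
      v[ix] <- as.numeric(df$value)
      v
    },
    stop("unknown overlay format: ", format))
  ov <- vertex_overlay(vals, units = units)
  if (!is.null(mesh) && length(ov$values) != n_vertices(mesh))
    stop("dimension error: overlay has ", length(ov$values),
         " values but mesh has ", n_vertices(mesh), " vertices")
  ov
}

#' Write a per-vertex overlay
#' @inheritParams read_overlay
#' @param overlay a `vertex_overlay`; invalid vertices are stored as NaN
#'   (curv/gifti) or skipped (csv).
#' @export
write_overlay <- function(overlay, path, format = NULL, one_based = FALSE) {
  format <- format %||% guess_format(path, "overlay")
  vals <- overlay$values
  vals[!overlay$valid] <- NaN
  switch(format,
    curv = {
      con <- file(path, "wb"); on.exit(close(con))
      write_int3(con, 16777215L)
      writeBin(as.integer(c(length(vals), 0L, 1L)), con, size = 4L,
               endian = "big")
      writeBin(vals, con, size = 4L, endian = "big")
    },
    gifti = write_gifti_func(vals, path),
    csv = {
      ix <- seq_along(vals) - if (one_based) 0L else 1L
      utils::write.csv(data.frame(vertex = ix, value = vals)[overlay$valid, ],
                       path, row.names = FALSE)
    },
    stop("unknown overlay format: ", format))
  invisible(path)
}

csv_has_header <- function(path) {
  first <- readLines(path, n = 1L)
  !grepl("^\\s*[0-9]", first)
}

#' Read / write label sets
#'
#' Supported formats: FreeSurfer ASCII `.label` (one label per file),
#' GIFTI `.label.gii` (one data array per label, preserving overlap), and
#' JSON (whole `label_set` with metadata).
#'
#' @param path file path; for `format = "freesurfer"` with several labels,
#'   one `<name>.label` file per label next to `path`.
#' @param format `"freesurfer"`, `"gifti"`, or `"json"`; guessed when `NULL`.
#' @param name label name for single-label FreeSurfer files.
#' @return a `label_set`.
#' @export
read_labels <- function(path, format = NULL, name = NULL) {
  format <- format %||% guess_format(path, "label")
  switch(format,
    json = {
      j <- jsonlite::read_json(path, simplifyVector = TRUE)
      label_set(lapply(j$labels, as.integer), species = j$species,
                hemisphere = j$hemisphere, subject_id = j$subject_id)
    },
    freesurfer = {
      lines <- readLines(path)
      nv <- as.integer(lines[2])
      dat <- utils::read.table(text = lines[3:(2 + nv)])
      nm <- name %||% sub("\\.label$", "", basename(path))
      ls <- list(as.integer(dat[[1]]) + 1L)
      names(ls) <- nm
      label_set(ls)
    },
    gifti = read_gifti_labels(path),
    stop("unknown label format: ", format))
}

#' @rdname read_labels
#' @param labels a `label_set` to write.
#' @export
write_labels <- function(labels, path, format = NULL) {
  format <- format %||% guess_format(path, "label")
  switch(format,
    json = jsonlite::write_json(
      list(labels = labels$labels, species = labels$species,
           hemisphere = labels$hemisphere, subject_id = labels$subject_id),
      path, auto_unbox = TRUE),
    freesurfer = {
      if (length(labels$labels) != 1L)
        stop("FreeSurfer .label holds one label; write each separately")
      ix <- labels$labels[[1]]
      writeLines(c(sprintf("#!ascii label, from subject %s",
                           labels$subject_id),
                   as.character(length(ix)),
                   sprintf("%d  0.000  0.000  0.000 0.0000000000", ix - 1L)),
                 path)
    },
    gifti = write_gifti_labels(labels, path),
    stop("unknown label format: ", format))
  invisible(path)
}

guess_format <- function(path, kind) {
  p <- tolower(path)
  if (grepl("\\.gii$", p)) return("gifti")
  switch(kind,
    surface = "freesurfer",
    overlay = if (grepl("\\.csv$", p)) "csv" else "curv",
    label   = if (grepl("\\.json$", p)) "json" else "freesurfer")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
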