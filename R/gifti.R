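# Minimal GIFTI (XML) surface/metric/label IO. Covers the subset this
# pipeline emits and consumes: RowMajorOrder data arrays, FLOAT32/INT32,
# Base64Binary or GZipBase64Binary encoding, either endian on read.

gii_decode_data <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  endian <- xml2::xml_attr(node, "Endian")
  endian <- if (identical(endian, "BigEndian")) "big" else "little"
  order <- xml2::xml_attr(node, "ArrayIndexingOrder")
  if (!is.na(order) && order == "ColumnMajorOrder")
    stop("format error: ColumnMajorOrder GIFTI arrays are not supported")
  dims <- as.integer(c(xml2::xml_attr(node, "Dim0"),
                       xml2::xml_attr(node, "Dim1")))
  n <- prod(dims, na.rm = TRUE)
  txt <- gsub("\\s", "",
              xml2::xml_text(xml2::xml_find_first(node, ".//Data")))
  raw <- jsonlite::base64_dec(txt)
  if (identical(enc, "GZipBase64Binary"))
    raw <- memDecompress(raw, type = "gzip")
  else if (!identical(enc, "Base64Binary"))
    stop("format error: unsupported GIFTI encoding '", enc, "'")
  vals <- switch(dtype,
    NIFTI_TYPE_FLOAT32 = readBin(raw, "double", n = n, size = 4L,
                                 endian = endian),
    NIFTI_TYPE_FLOAT64 = readBin(raw, "double", n = n, size = 8L,
                                 endian = endian),
    NIFTI_TYPE_INT32 = readBin(raw, "integer", n = n, size = 4L,
                               endian = endian),
    stop("format error: unsupported GIFTI DataType '", dtype, "'"))
  if (length(vals) < n) stop("format error: truncated GIFTI data array")
  if (!is.na(dims[2]) && dims[2] > 1L)
    matrix(vals, ncol = dims[2], byrow = TRUE)
  else vals
}

gii_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_find_all(doc, "//DataArray")
}

gii_intent <- function(node) xml2::xml_attr(node, "Intent")

gii_meta_name <- function(node) {
  mds <- xml2::xml_find_all(node, "./MetaData/MD")
  for (md in mds) {
    if (identical(xml2::xml_text(xml2::xml_find_first(md, "./Name")), "Name"))
      return(xml2::xml_text(xml2::xml_find_first(md, "./Value")))
  }
  NA_character_
}

read_gifti_surface <- function(path, surface_kind = "pial") {
  arr <- gii_arrays(path)
  pts <- NULL; tri <- NULL
  for (a in arr) {
    it <- gii_intent(a)
    if (identical(it, "NIFTI_INTENT_POINTSET")) pts <- gii_decode_data(a)
    if (identical(it, "NIFTI_INTENT_TRIANGLE")) tri <- gii_decode_data(a)
  }
  if (is.null(pts) || is.null(tri))
    stop("format error: surface GIFTI needs POINTSET and TRIANGLE arrays")
  triangle_mesh(pts, tri + 1L, surface_kind = surface_kind)
}

read_gifti_func <- function(path) {
  arr <- gii_arrays(path)
  if (length(arr) == 0) stop("format error: no data arrays in GIFTI file")
  as.numeric(gii_decode_data(arr[[1]]))
}

read_gifti_labels <- function(path) {
  arr <- gii_arrays(path)
  labs <- list()
  for (a in arr) {
    nm <- gii_meta_name(a)
    if (is.na(nm)) nm <- paste0("label", length(labs) + 1L)
    ind <- gii_decode_data(a)
    labs[[nm]] <- which(ind != 0)
  }
  doc <- xml2::read_xml(path)
  meta <- function(key, default) {
    mds <- xml2::xml_find_all(doc, "/GIFTI/MetaData/MD")
    for (md in mds)
      if (identical(xml2::xml_text(xml2::xml_find_first(md, "./Name")), key))
        return(xml2::xml_text(xml2::xml_find_first(md, "./Value")))
    default
  }
  label_set(labs, species = meta("species", "human"),
            hemisphere = meta("hemisphere", "left"),
            subject_id = meta("subject_id", "subject"))
}

gii_encode <- function(vals, dtype) {
  raw <- switch(dtype,
    NIFTI_TYPE_FLOAT32 = writeBin(as.numeric(vals), raw(), size = 4L,
                                  endian = "little"),
    NIFTI_TYPE_INT32 = writeBin(as.integer(vals), raw(), size = 4L,
                                endian = "little"))
  jsonlite::base64_enc(memCompress(raw, type = "gzip"))
}

gii_data_array <- function(vals, intent, dtype, dims, name = NULL) {
  meta <- if (!is.null(name))
    sprintf("<MetaData><MD><Name>Name</Name><Value>%s</Value></MD></MetaData>",
            name) else ""
  dim_attrs <- paste(sprintf('Dim%d="%d"', seq_along(dims) - 1L, dims),
                     collapse = " ")
  flat <- if (length(dims) > 1L) as.vector(t(vals)) else vals
  sprintf(paste0(
    '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder"',
    ' Dimensionality="%d" %s Encoding="GZipBase64Binary"',
    ' Endian="LittleEndian" ExternalFileName="" ExternalFileOffset="">',
    '%s<Data>%s</Data></DataArray>'),
    intent, dtype, length(dims), dim_attrs, meta, gii_encode(flat, dtype))
}

gii_write_doc <- function(arrays, path, file_meta = NULL) {
  meta <- ""
  if (!is.null(file_meta)) {
    mds <- paste(sprintf("<MD><Name>%s</Name><Value>%s</Value></MD>",
                         names(file_meta), unlist(file_meta)), collapse = "")
    meta <- sprintf("<MetaData>%s</MetaData>", mds)
  }
  xml <- sprintf(
    '<?xml version="1.0" encoding="UTF-8"?>\n<GIFTI Version="1.0" NumberOfDataArrays="%d">%s%s</GIFTI>',
    length(arrays), meta, paste(arrays, collapse = ""))
  writeLines(xml, path)
  invisible(path)
}

write_gifti_surface <- function(mesh, path) {
  gii_write_doc(list(
    gii_data_array(mesh$vertices, "NIFTI_INTENT_POINTSET",
                   "NIFTI_TYPE_FLOAT32", dim(mesh$vertices)),
    gii_data_array(mesh$faces - 1L, "NIFTI_INTENT_TRIANGLE",
                   "NIFTI_TYPE_INT32", dim(mesh$faces))), path)
}

write_gifti_func <- function(vals, path) {
  gii_write_doc(list(
    gii_data_array(vals, "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32",
                   length(vals))), path)
}

write_gifti_labels <- function(labels, path) {
  n <- max(c(1L, unlist(labels$labels)))
  arrays <- lapply(names(labels$labels), function(nm) {
    ind <- integer(n)
    ind[labels$labels[[nm]]] <- 1L
    gii_data_array(ind, "NIFTI_INTENT_LABEL", "NIFTI_TYPE_INT32", n, name = nm)
  })
  gii_write_doc(arrays, path,
                file_meta = list(species = labels$species,
                                 hemisphere = labels$hemisphere,
                                 subject_id = labels$subject_id))
}
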