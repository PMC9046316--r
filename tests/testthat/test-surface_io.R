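# Reading/writing surfaces, overlays and labels, round-trip identity, and
# rejection of malformed files.

tetra_fragment <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                rbind(c(1, 2, 3), c(1, 2, 4)), surface_kind = "synthetic")
}

test_that("surface files round-trip in both formats", {
  mesh <- tetra_fragment()
  for (fmt in c("freesurfer", "gifti")) {
    path <- withr::local_tempfile(fileext = if (fmt == "gifti")
      ".surf.gii" else ".white")
    write_surface(mesh, path, format = fmt)
    back <- read_surface(path, format = fmt, surface_kind = "synthetic")
    expect_equal(back$vertices, mesh$vertices, tolerance = 1e-6)
    expect_identical(back$faces, mesh$faces)
  }
})

test_that("FreeSurfer binary reader agrees with an independent byte layout", {
  # fixture assembled byte-by-byte (big-endian), separate from the writer
  path <- withr::local_tempfile()
  con <- file(path, "wb")
  writeBin(as.raw(c(0xFF, 0xFF, 0xFE)), con)
  writeBin(charToRaw("made elsewhere\n\n"), con)
  writeBin(c(4L, 2L), con, size = 4L, endian = "big")        # counts
  verts <- c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1)
  writeBin(verts, con, size = 4L, endian = "big")
  writeBin(c(0L, 1L, 2L, 0L, 1L, 3L), con, size = 4L, endian = "big")
  close(con)
  mesh <- read_surface(path, format = "freesurfer")
  expect_equal(nrow(mesh$vertices), 4L)
  expect_equal(nrow(mesh$faces), 2L)
  expect_equal(mesh$vertices, matrix(verts, ncol = 3, byrow = TRUE))
  expect_identical(mesh$faces[1, ], c(1L, 2L, 3L))
})

test_that("malformed surface files raise format errors, not crashes", {
  empty <- withr::local_tempfile()
  file.create(empty)
  expect_error(read_surface(empty, format = "freesurfer"), "format error")
  badmagic <- withr::local_tempfile()
  writeBin(as.raw(c(1, 2, 3, 4)), badmagic)
  expect_error(read_surface(badmagic, format = "freesurfer"), "bad magic")
})

test_that("meshes with out-of-range or degenerate faces are rejected", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(triangle_mesh(v, rbind(c(1, 2, 4))), "integrity")
  expect_error(triangle_mesh(rbind(v, c(2, 0, 0)), rbind(c(1, 2, 4))),
               "degenerate")
})

test_that("overlays round-trip with NaN -> validity masking", {
  vals <- c(0.5, -1.25, 2, NaN, 4.75)
  ov <- vertex_overlay(vals, units = "mm")
  expect_identical(which(!ov$valid), 4L)
  for (fmt in c("curv", "gifti")) {
    path <- withr::local_tempfile(fileext = if (fmt == "gifti")
      ".func.gii" else ".curv")
    write_overlay(ov, path, format = fmt)
    back <- read_overlay(path, format = fmt, units = "mm")
    expect_equal(back$values[back$valid], vals[c(1:3, 5)])
    expect_identical(which(!back$valid), 4L)
  }
})

test_that("CSV overlays parse identically with and without a header", {
  vals <- c(1.5, 2.5, 3.5)
  with_h <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("vertex,value", "0,1.5", "1,2.5", "2,3.5"), with_h)
  without_h <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1.5", "1,2.5", "2,3.5"), without_h)
  a <- read_overlay(with_h, format = "csv")
  b <- read_overlay(without_h, format = "csv")
  expect_equal(a$values, vals)
  expect_equal(a$values, b$values)
  # 1-based dialect must be declared explicitly
  based1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("vertex,value", "1,1.5", "2,2.5", "3,3.5"), based1)
  expect_equal(read_overlay(based1, format = "csv",
                            one_based = TRUE)$values, vals)
  shifted <- read_overlay(based1, format = "csv")   # treated as 0-based
  expect_true(is.na(shifted$values[1]))
  expect_equal(shifted$values[2:4], vals)
  expect_error(read_overlay(with_h, format = "csv", one_based = TRUE),
               "0")
})

test_that("overlay vertex count is checked against the mesh", {
  path <- withr::local_tempfile(fileext = ".curv")
  write_overlay(vertex_overlay(1:3), path, format = "curv")
  expect_error(read_overlay(path, format = "curv", mesh = tetra_fragment()),
               "dimension error")
})

test_that("label sets round-trip through json, gifti and freesurfer", {
  ls <- label_set(list(rCaS = c(1L, 2L, 3L), eCaS = c(3L, 4L)),
                  species = "macaque", hemisphere = "right",
                  subject_id = "M1")
  for (fmt in c("json", "gifti")) {
    path <- withr::local_tempfile(fileext = if (fmt == "gifti")
      ".label.gii" else ".json")
    write_labels(ls, path, format = fmt)
    back <- read_labels(path, format = fmt)
    expect_identical(back$labels, ls$labels)   # overlap preserved
    expect_identical(back$species, "macaque")
    expect_identical(back$hemisphere, "right")
  }
  fs <- withr::local_tempfile(fileext = ".label")
  write_labels(label_set(list(rCaS = c(1L, 2L, 3L))), fs,
               format = "freesurfer")
  expect_identical(read_labels(fs, format = "freesurfer",
                               name = "rCaS")$labels$rCaS, c(1L, 2L, 3L))
})

test_that("labels are validated on bind and deduplicated on construction", {
  mesh <- tetra_fragment()
  expect_error(bind_labels(label_set(list(big = c(1L, 9L))), mesh),
               "integrity")
  expect_message(ls <- label_set(list(a = c(2L, 2L, 1L))), "deduplicated")
  expect_identical(ls$labels$a, c(1L, 2L))
  expect_silent(bind_labels(label_set(list(ok = 1:4)), mesh))
})

test_that("unit metadata is enforced at operation boundaries", {
  pa <- vertex_overlay(c(0, 10), units = "deg")
  mm <- vertex_overlay(c(0, 1), units = "mm")
  expect_error(retinotopic_map(pa, mm), "unit mismatch")
})
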