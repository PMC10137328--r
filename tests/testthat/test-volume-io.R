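test_that("write/read round trip preserves labels, spacing and class", {
  arr <- array(0L, c(4, 8, 8))
  arr[2, 3:5, 2:6] <- 7L
  arr[3, 6, 7] <- 65535L
  vol <- label_volume(arr, c(50, 8, 8), organelle_class = "er",
                      provenance = "unit fixture")
  path <- file.path(withr::local_tempdir(), "vol.tif")
  write_label_volume(vol, path)
  back <- read_label_volume(path)
  expect_identical(back$labels, vol$labels)
  expect_equal(back$spacing, vol$spacing)
  expect_identical(back$organelle_class, "er")
  expect_identical(back$provenance, "unit fixture")
})

test_that("spacing resolution: override beats sidecar, neither is an error", {
  path <- file.path(withr::local_tempdir(), "vol.tif")
  vol <- label_volume(array(0L, c(4, 8, 8)), c(50, 8, 8))
  write_label_volume(vol, path)
  over <- read_label_volume(path, spacing_override = c(25, 4, 4))
  expect_equal(over$spacing, c(25, 4, 4))
  file.remove(paste0(tools::file_path_sans_ext(path), ".json"))
  expect_error(read_label_volume(path), "spacing")
  expect_equal(dim(read_label_volume(path, c(50, 8, 8))$labels), c(4, 8, 8))
})

test_that("format guards: label overflow on write, non-integer pixels on read", {
  big <- label_volume(array(c(0L, 70000L), c(1, 2, 1)), c(50, 8, 8))
  expect_error(write_label_volume(big, tempfile(fileext = ".tif")), "65535")

  fpath <- file.path(withr::local_tempdir(), "float.tif")
  tiff::writeTIFF(matrix(c(0.25, 0.5, 0.75, 0.1), 2), fpath,
                  bits.per.sample = 32L)
  expect_error(read_label_volume(fpath, c(50, 8, 8)), "format error")
})

test_that("all-zero volume writes, reads and yields zero objects", {
  path <- file.path(withr::local_tempdir(), "zero.tif")
  vol <- label_volume(array(0L, c(3, 6, 6)), c(50, 8, 8))
  write_label_volume(vol, path)
  expect_length(extract_objects(read_label_volume(path)), 0)
})

test_that("label volumes validate their invariants", {
  expect_error(label_volume(array(-1L, c(2, 2, 2)), c(50, 8, 8)), "non-negative")
  expect_error(label_volume(array(0L, c(2, 2, 2)), c(50, 8, 0)), "positive")
  expect_error(label_volume(matrix(0L, 2, 2), c(50, 8, 8)), "3D")
  a <- label_volume(array(0L, c(2, 3, 4)), c(50, 8, 8))
  b <- label_volume(array(0L, c(2, 3, 4)), c(50, 8, 8), "er")
  expect_true(is_coregistered(a, b))
  expect_false(is_coregistered(a, label_volume(array(0L, c(2, 3, 5)), c(50, 8, 8))))
})

test_that("objects are 26-connected components split per label", {
  arr <- array(0L, c(8, 8, 8))
  arr[3:5, 3:5, 3:5] <- 1L           # interior cube
  arr[7, 7, 7] <- 2L                 # diagonal pair, same label
  arr[6, 6, 6] <- 2L
  arr[2, 2, 2] <- 3L                 # disconnected voxels sharing label 3
  arr[2, 2, 6] <- 3L
  objs <- extract_objects(label_volume(arr, c(50, 8, 8)),
                          exclude_boundary = FALSE)
  expect_length(objs, 4)             # label 3 splits into two objects
  labs <- vapply(objs, `[[`, integer(1), "label")
  expect_equal(sort(labs), c(1L, 2L, 3L, 3L))
  two <- objs[[which(labs == 2L)[1]]]
  expect_equal(nrow(two$voxels), 2L) # corner contact joins under 26-connectivity
  cube <- objs[[which(labs == 1L)]]
  expect_false(cube$touches_boundary)
})

test_that("boundary-touching objects are excluded and the exclusion is logged", {
  arr <- array(0L, c(8, 8, 8))
  arr[1:3, 3:5, 3:5] <- 1L           # touches z = 1 face
  arr[5:6, 5:6, 5:6] <- 2L
  vol <- label_volume(arr, c(50, 8, 8))
  expect_message(objs <- extract_objects(vol, exclude_boundary = TRUE),
                 "1 object")
  expect_length(objs, 1)
  expect_equal(attr(objs, "n_excluded"), 1L)
  all_objs <- extract_objects(vol, exclude_boundary = FALSE)
  expect_length(all_objs, 2)
  expect_true(any(vapply(all_objs, `[[`, logical(1), "touches_boundary")))
})

test_that("voxel counts are conserved between objects and background", {
  vol <- random_blob(180, seed = 11)
  vol$labels[2:3, 2:3, 20:22] <- 2L
  objs <- extract_objects(vol, exclude_boundary = FALSE)
  expect_equal(sum(vapply(objs, function(o) nrow(o$voxels), integer(1))) +
                 sum(vol$labels == 0L),
               length(vol$labels))
})

test_that("extraction is invariant to label renumbering", {
  vol <- random_blob(120, seed = 5)
  vol$labels[20:22, 4:6, 4:6] <- 9L
  relab <- vol
  relab$labels[relab$labels == 1L] <- 5L
  a <- extract_objects(vol, exclude_boundary = FALSE)
  b <- extract_objects(relab, exclude_boundary = FALSE)
  expect_equal(length(a), length(b))
  va <- lapply(a, `[[`, "voxels")
  vb <- lapply(b, `[[`, "voxels")
  key <- function(v) paste(sort(paste(v[, 1], v[, 2], v[, 3])), collapse = "|")
  expect_setequal(vapply(va, key, character(1)), vapply(vb, key, character(1)))
})
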