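test_that("volume is exact in the voxel model", {
  arr <- array(0L, c(3, 3, 3)); arr[2, 2, 2] <- 1L
  o <- extract_objects(label_volume(arr, c(50, 8, 8)),
                       exclude_boundary = FALSE)[[1]]
  expect_equal(measure_volume(o), 3.2e-6)  # 50*8*8 nm^3 in um^3

  # independent recount oracle on an irregular object
  vol <- random_blob(260, seed = 3)
  o2 <- extract_objects(vol, exclude_boundary = FALSE)[[1]]
  recount <- sum(vol$labels == 1L) * prod(vol$spacing) / 1e9
  expect_equal(measure_volume(o2), recount)
})

test_that("surface area matches analytic shapes at documented tolerances", {
  o <- get_sphere_8nm()
  expect_lt(abs(measure_surface_area(o) / (4 * pi * 0.25^2) - 1), 0.05)
  expect_lt(abs(measure_volume(o) / (4 / 3 * pi * 0.25^3) - 1), 0.03)

  arr <- array(0L, c(60, 60, 60))
  arr[6:55, 6:55, 6:55] <- 1L  # 400 nm cube at 8 nm
  co <- extract_objects(label_volume(arr, c(8, 8, 8)),
                        exclude_boundary = FALSE)[[1]]
  expect_lt(abs(measure_surface_area(co) / (6 * 0.4^2) - 1), 0.10)
})

test_that("surface area is stable under grid refinement", {
  sa <- vapply(c(8, 4), function(h) {
    sc <- rasterize_scene(scene_spec(
      spacing = rep(h, 3),
      shapes = list(shape_sphere(500, rep(snapc(300, h), 3)))
    ))
    measure_surface_area(extract_objects(sc$mito, exclude_boundary = FALSE)[[1]])
  }, numeric(1))
  expect_lt(abs(sa[2] / sa[1] - 1), 0.02)
})

test_that("single-voxel objects fall back to the analytic ellipsoid area", {
  arr <- array(0L, c(3, 3, 3)); arr[2, 2, 2] <- 1L
  o <- extract_objects(label_volume(arr, c(50, 8, 8)),
                       exclude_boundary = FALSE)[[1]]
  expect_gt(measure_surface_area(o), 0)
})

test_that("length equals the farthest point pair", {
  arr <- array(0L, c(3, 3, 110))
  arr[2, 2, c(5, 105)] <- 1L  # two voxels 100 apart along x, but same label is
  arr[2, 2, 5:105] <- 1L      # disconnected; fill the line to keep one object
  o <- extract_objects(label_volume(arr, c(50, 8, 8)),
                       exclude_boundary = FALSE)[[1]]
  expect_equal(measure_length(o), 0.8)  # 100 voxels * 8 nm

  expect_lt(abs(measure_length(get_sphere_8nm()) - 0.5),
            sqrt(3 * 8^2) / 1e3)

  # brute-force oracle over all voxel centers of random blobs
  for (seed in 1:3) {
    vol <- random_blob(200, seed = seed)
    o2 <- extract_objects(vol, exclude_boundary = FALSE)[[1]]
    expect_equal(measure_length(o2), brute_length_um(o2), tolerance = 1e-12)
  }
})

test_that("aspect ratio reflects length-to-width and is at least 1", {
  expect_lt(abs(aspect_ratio(get_sphere_8nm()) - 1), 0.02)
  expect_lt(abs(aspect_ratio(get_capsule_8nm()) / 10 - 1), 0.05)
  blob <- extract_objects(random_blob(150, seed = 9),
                          exclude_boundary = FALSE)[[1]]
  expect_gte(as.numeric(aspect_ratio(blob)), 1)
})

test_that("aspect ratio is invariant under lattice rotations", {
  o <- get_capsule_8nm()
  base <- as.numeric(aspect_ratio(o))
  arr <- array(0L, o$dim)
  arr[o$voxels] <- 1L
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2))) {
    ro <- extract_objects(label_volume(aperm(arr, perm), o$spacing[perm]),
                          exclude_boundary = FALSE)[[1]]
    expect_lt(abs(as.numeric(aspect_ratio(ro)) / base - 1), 0.02)
  }
})

test_that("sphericity follows the closed form and flags bad input", {
  r <- 0.25
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1)
  a <- 0.4
  expect_equal(sphericity(a^3, 6 * a^2), (pi / 6)^(1 / 3))
  # capsule closed form as oracle for the measured pipeline
  L <- 2; d <- 0.2; rr <- d / 2
  V <- pi * rr^2 * (L - d) + 4 / 3 * pi * rr^3
  SA <- 2 * pi * rr * (L - d) + 4 * pi * rr^2
  psi_true <- sphericity(V, SA)
  o <- get_capsule_8nm()
  psi_meas <- sphericity(measure_volume(o), measure_surface_area(o))
  expect_lt(abs(psi_meas / psi_true - 1), 0.03)
  expect_error(sphericity(0, 1), "positive")
  expect_error(sphericity(1, -1), "positive")
})

test_that("sphericity never exceeds 1 plus discretization slack; sphere is maximal", {
  cls <- get_panel_classification()
  expect_true(all(cls$records$sphericity <= 1.02))
  expect_equal(which.max(cls$records$sphericity),
               which(cls$calls$type == "I"))
})

test_that("measures are invariant under translation", {
  vol <- random_blob(220, seed = 13)
  o <- extract_objects(vol, exclude_boundary = FALSE)[[1]]
  big <- array(0L, dim(vol$labels) + c(6L, 6L, 6L))
  big[cbind(o$voxels[, 1] + 5L, o$voxels[, 2] + 5L, o$voxels[, 3] + 5L)] <- 1L
  ot <- extract_objects(label_volume(big, vol$spacing),
                        exclude_boundary = FALSE)[[1]]
  expect_equal(measure_volume(ot), measure_volume(o))
  expect_equal(measure_length(ot), measure_length(o), tolerance = 1e-12)
  expect_equal(measure_surface_area(ot), measure_surface_area(o),
               tolerance = 1e-9)
})

test_that("skeleton radius profiles recover tubule and sphere radii", {
  pr <- skeleton_profile(get_capsule_8nm())
  expect_length(pr$paths, 1)
  expect_lt(abs(median(pr$radius_nm) / 100 - 1), 0.15)

  prs <- skeleton_profile(get_sphere_8nm())
  expect_lt(abs(max(prs$radius_nm) / 250 - 1), 0.15)

  # radii are positive and bounded by half the object extent plus a voxel
  expect_true(all(pr$radius_nm > 0))
  expect_true(all(pr$radius_nm <= 100 + sqrt(3) * 8 + 8))
})

test_that("MOAS radius-arclength profile shows 3 wide maxima and thin minima", {
  pr <- get_moas_profile()
  det <- detect_beads_and_necks(pr, classification_thresholds())
  beads <- det$segments[det$segments$kind == "bead", ]
  necks <- det$segments[det$segments$kind == "neck", ]
  expect_equal(nrow(beads), 3)
  expect_equal(nrow(necks), 2)
  expect_true(all(beads$max_radius_nm >= 200))
  expect_true(all(necks$min_radius_nm <= 45))
})
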