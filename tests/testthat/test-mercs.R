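test_that("the 25 nm criterion separates gaps of 10/20/24 from 26/40", {
  detected <- vapply(c(10, 20, 24, 26, 40), function(g) {
    nrow(gap_fixture_contacts(g)) > 0
  }, logical(1))
  expect_equal(detected, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(sum(vapply(c(10, 20, 24, 26, 40),
                          function(g) nrow(gap_fixture_contacts(g)),
                          integer(1))), 3L)
})

test_that("measured face gaps match the generated surface distance", {
  for (g in c(10, 24)) {
    ct <- gap_fixture_contacts(g)
    gf <- attr(ct, "gap_field")
    expect_equal(min(gf$gap_nm), g, tolerance = 0.05)
    expect_true(all(ct$mean_gap_nm >= g - 0.1))
  }
})

test_that("contact length tracks the apposed extent of the ER patch", {
  # analytic oracle from the continuous fixture geometry: the tube is
  # apposed over patch_extent; beyond it the hemispherical tube caps raise
  # the gap quadratically, extending the contact by sqrt(2*Rt*(crit - gap))
  # per side; laterally the patch wraps by a chord set by the combined
  # transverse curvature of tube (Rt) and capsule (Rc)
  crit <- 25; Rt <- 50; Rc <- 75
  for (g in c(10, 20)) {
    ct <- gap_fixture_contacts(g)
    axial <- 200 + 2 * sqrt(2 * Rt * (crit - g))
    lateral <- 2 * sqrt(2 * (1 / (1 / Rt + 1 / Rc)) * (crit - g))
    oracle <- sqrt(axial^2 + lateral^2)
    expect_lt(abs(ct$length_nm / oracle - 1), 0.10)
  }
})

test_that("no ER means infinite gaps and zero contacts", {
  sc <- gap_fixture_2nm(20)
  o <- extract_objects(sc$mito, exclude_boundary = FALSE)[[1]]
  empty_er <- label_volume(array(0L, dim(sc$er$labels)), sc$er$spacing, "er")
  gf <- surface_gap_field(o, empty_er)
  expect_true(all(is.infinite(gf$gap_nm)))
  expect_equal(nrow(detect_contacts(o, empty_er)), 0)
})

test_that("a duplicate of the mitochondrion offered as ER saturates coverage", {
  sc <- rasterize_scene(scene_spec(
    spacing = c(8, 8, 8),
    shapes = list(shape_sphere(300, rep(snapc(250, 8), 3)))
  ))
  o <- extract_objects(sc$mito, exclude_boundary = FALSE)[[1]]
  fake_er <- label_volume(sc$mito$labels, sc$mito$spacing, "er")
  ct <- detect_contacts(o, fake_er)
  expect_equal(nrow(ct), 1)
  rec <- measure_objects(list(o))
  cov <- mercs_coverage(rec, ct)
  expect_gt(cov$coverage_percent, 99)
  expect_lte(cov$coverage_percent, 100 + 1e-6)
})

test_that("a hemispherical ER cap covers half the sphere", {
  h <- 8
  ctr <- snapc(400, h)
  sc <- rasterize_scene(scene_spec(
    spacing = rep(h, 3),
    shapes = list(shape_sphere(400, rep(ctr, 3))),
    dim = c(100, 100, 100)
  ))
  o <- extract_objects(sc$mito, exclude_boundary = FALSE)[[1]]
  # hand-built half-shell at 15 nm gap, 60 nm thick, on the +y side
  d <- dim(sc$mito$labels)
  ax <- (seq_len(d[1]) - 0.5) * h
  r2 <- outer(outer((ax - ctr)^2, (ax - ctr)^2, "+"), (ax - ctr)^2, "+")
  rr <- sqrt(r2)
  Y <- array(rep(rep(ax, each = d[1]), times = d[3]), d)
  shell <- rr >= 215 & rr <= 275 & Y > ctr
  er <- label_volume(array(as.integer(shell), d), rep(h, 3), "er")
  ct <- detect_contacts(o, er)
  rec <- measure_objects(list(o))
  cov <- mercs_coverage(rec, ct)
  expect_lt(abs(cov$coverage_percent - 50), 5)
})

test_that("contact faces and coverage are monotone in the gap threshold", {
  sc <- gap_fixture_2nm(20)
  o <- extract_objects(sc$mito, exclude_boundary = FALSE)[[1]]
  rec <- measure_objects(list(o))
  areas <- vapply(c(21, 25, 32), function(t) {
    ct <- detect_contacts(o, sc$er, contact_params(max_gap_nm = t))
    mercs_coverage(rec, ct)$coverage_percent
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_true(all(areas >= 0 & areas <= 100))
})

test_that("contact metrics are invariant under joint translation", {
  sc <- gap_fixture_2nm(20)
  shift <- c(4L, 3L, 5L)
  grow <- function(vol) {
    arr <- array(0L, dim(vol$labels) + 8L)
    idx <- which(vol$labels != 0L)
    av <- arrayInd(idx, dim(vol$labels))
    arr[cbind(av[, 1] + shift[1], av[, 2] + shift[2], av[, 3] + shift[3])] <-
      vol$labels[idx]
    label_volume(arr, vol$spacing, vol$organelle_class)
  }
  o1 <- extract_objects(sc$mito, exclude_boundary = FALSE)[[1]]
  ct1 <- detect_contacts(o1, sc$er)
  mito2 <- grow(sc$mito)
  er2 <- grow(sc$er)
  o2 <- extract_objects(mito2, exclude_boundary = FALSE)[[1]]
  ct2 <- detect_contacts(o2, er2)
  expect_equal(ct1$area_um2, ct2$area_um2, tolerance = 1e-9)
  expect_equal(ct1$length_nm, ct2$length_nm, tolerance = 1e-9)
  expect_equal(ct1$mean_gap_nm, ct2$mean_gap_nm, tolerance = 1e-9)
})

test_that("patches split by ER object id: two tubes give two contact sites", {
  h <- c(2, 2, 2)
  zc <- snapc(110, 2); yc <- snapc(160, 2)
  sh <- list(shape_capsule(700, 150, c(zc, yc, 360)))
  er <- list(er_placement(1L, 10, patch_extent_nm = 120, along_frac = 0.25),
             er_placement(1L, 10, patch_extent_nm = 120, along_frac = 0.75))
  sc <- rasterize_scene(scene_spec(spacing = h, shapes = sh, er = er, margin = 3L))
  o <- extract_objects(sc$mito, exclude_boundary = FALSE)[[1]]
  ct <- detect_contacts(o, sc$er)
  expect_equal(nrow(ct), 2)
  expect_setequal(ct$er_id, c(1L, 2L))
})

test_that("pooling by type reports I-III and MOAS separately and conserves n", {
  calls <- data.frame(object_id = 1:5,
                      type = c("II", "II", "IV", "I", "IV"))
  covt <- data.frame(mito_id = 1:5, n_contacts = 1,
                     coverage_percent = c(10, 20, 40, 12, 44),
                     mean_contact_length_nm = c(80, 90, 200, 70, 210),
                     total_contact_volume_um3 = c(1, 2, 5, 1, 6) * 1e-4)
  tbl <- mercs_by_type(calls, covt)
  cov_rows <- tbl[tbl$metric == "coverage_percent", ]
  expect_setequal(cov_rows$pool, c("I-III", "MOAS"))
  expect_equal(sum(cov_rows$n), 5)
  expect_gt(cov_rows$mean[cov_rows$pool == "MOAS"],
            cov_rows$mean[cov_rows$pool == "I-III"])

  only_ii <- mercs_by_type(calls[calls$type == "II", ], covt[1:2, ])
  expect_false("MOAS" %in% only_ii$pool)
})
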