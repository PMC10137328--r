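test_that("bead/neck detection follows the radius thresholds on constructed profiles", {
  th <- classification_thresholds()
  # bead - neck - bead: neck run 400 nm at radius 32, beads at 250
  p <- fake_profile(c(rep(250, 5), rep(32, 8), rep(250, 5)), step_nm = 50)
  det <- detect_beads_and_necks(p, th)
  expect_equal(det$n_beads, 2)
  expect_equal(det$n_necks, 1)

  # a 50 nm dip is noise-rejected by the minimum neck run length
  p2 <- fake_profile(c(rep(250, 5), 32, rep(250, 5)), step_nm = 50)
  det2 <- detect_beads_and_necks(p2, th)
  expect_equal(det2$n_beads, 2)
  expect_equal(det2$n_necks, 0)

  # a thin run not flanked by beads on both sides is no neck
  p3 <- fake_profile(c(rep(32, 8), rep(250, 5)), step_nm = 50)
  expect_equal(detect_beads_and_necks(p3, th)$n_necks, 0)

  # uniform tubule radius 100: neither beads nor necks
  p4 <- fake_profile(rep(100, 20), step_nm = 50)
  det4 <- detect_beads_and_necks(p4, th)
  expect_equal(det4$n_beads, 0)
  expect_equal(det4$n_necks, 0)

  # single node
  p5 <- fake_profile(250)
  expect_equal(detect_beads_and_necks(p5, th)$n_beads, 1)
  expect_equal(detect_beads_and_necks(fake_profile(40), th)$n_beads, 0)
})

test_that("threshold presets and invariants", {
  th <- classification_thresholds()
  expect_equal(th$type1_max_length_um, 0.5)
  th2 <- classification_thresholds("results2023")
  expect_equal(th2$type1_max_length_um, 1.0)
  expect_error(classification_thresholds(type1_max_length_um = 6))
  expect_error(classification_thresholds(moas_min_beads = 1))
  expect_error(classification_thresholds(neck_max_radius_nm = 200))
})

test_that("length boundaries assign classes per the stated closed/open bounds", {
  th <- classification_thresholds()
  flat <- fake_profile(rep(100, 10))
  cls_of <- function(len_um, th. = th) {
    rec <- data.frame(object_id = 1L, length_um = len_um)
    classify_mitochondrion(rec, flat, th.)$type
  }
  expect_equal(cls_of(0.4), "I")
  expect_equal(cls_of(0.5), "I")      # closed upper bound for Type I
  expect_equal(cls_of(0.51), "II")
  expect_equal(cls_of(4.99), "II")
  expect_equal(cls_of(5.0), "III")    # "5 um or longer"
  expect_equal(cls_of(6.0), "III")
  expect_equal(cls_of(0.9, classification_thresholds("results2023")), "I")
})

test_that("structural MOAS detection overrides the length rules", {
  th <- classification_thresholds()
  moasy <- fake_profile(c(rep(250, 5), rep(32, 8), rep(250, 5)), step_nm = 50)
  rec <- data.frame(object_id = 1L, length_um = 1.4)
  expect_equal(classify_mitochondrion(rec, moasy, th)$type, "IV")
})

test_that("widening the necks above the bead threshold abolishes MOAS calls", {
  sc <- rasterize_scene(scene_spec(
    spacing = c(8, 8, 8),
    shapes = list(shape_moas(3, 500, 320, 400,
                             c(snapc(300, 8), snapc(300, 8), snapc(1200, 8))))
  ))
  o <- extract_objects(sc$mito, exclude_boundary = FALSE)[[1]]
  det <- detect_beads_and_necks(skeleton_profile(o), classification_thresholds())
  expect_equal(det$n_necks, 0)
})

test_that("the canonical panel classifies into the four types, one each", {
  cls <- get_panel_classification()
  expect_equal(sort(cls$calls$type), c("I", "II", "III", "IV"))
  expect_equal(cls$composition$count, rep(1L, 4))
  expect_equal(sum(cls$composition$fraction), 1)
})

test_that("classification is total, deterministic and monotone in length", {
  cls <- get_panel_classification()
  expect_false(any(is.na(cls$calls$type)))
  expect_equal(nrow(cls$calls), 4)
  again <- classify_population(get_panel()$mito)
  expect_identical(cls$calls, again$calls)

  # lengthening a tubule never demotes its class
  flat <- fake_profile(rep(100, 10))
  th <- classification_thresholds()
  lens <- c(0.3, 0.5, 1, 3, 4.99, 5, 7)
  types <- vapply(lens, function(l) {
    classify_mitochondrion(data.frame(object_id = 1L, length_um = l),
                           flat, th)$type
  }, character(1))
  ranks <- match(types, c("I", "II", "III"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("classification recovers generator truth on a mixed population", {
  pop <- sample_population(c(I = 0.35, II = 0.35, IV = 0.3), n = 25, seed = 42)
  cp <- classify_population(pop$mito)
  truth <- pop$truth$objects
  m <- merge(truth, cp$records[, c("object_id", "label")],
             by.x = "id", by.y = "label")
  m <- merge(m, cp$calls, by = "object_id")
  expect_gte(mean(m$type_true == m$type), 0.95)
  expect_equal(sum(cp$composition$fraction), 1)
})

test_that("an empty volume yields empty calls and an all-zero composition", {
  cp <- classify_population(label_volume(array(0L, c(4, 4, 4)), c(50, 8, 8)))
  expect_equal(nrow(cp$calls), 0)
  expect_equal(cp$composition$count, rep(0L, 4))
})
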