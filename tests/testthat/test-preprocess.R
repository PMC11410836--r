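test_that("standardization pads to square, resizes, and maps endpoints", {
  # 300 wide x 400 tall image: 50 px black added on each side of x, then
  # scaled by 512/400; endpoint (100,100) must land at (192,128)
  img <- matrix(runif(300 * 400), nrow = 300, ncol = 400)
  segs <- list(
    axis_segment("PH1", c(100, 100), c(110, 60)),
    axis_segment("MT1", c(100, 350), c(95, 150)),
    axis_segment("MT2", c(150, 350), c(148, 150)),
    axis_segment("MT3", c(200, 350), c(205, 160)),
    axis_segment("MT4", c(230, 350), c(240, 170)),
    axis_segment("MT5", c(260, 350), c(275, 180)))
  ann <- axis_annotation(segs, image_height = 400, image_width = 300)
  s <- standardize(img, ann)
  expect_equal(dim(s$image), c(512, 512))
  expect_true(all(s$image >= 0 & s$image <= 1))
  expect_equal(s$annotation$segments$PH1$proximal, c(192, 128))
  # similarity transform: all angles preserved
  a0 <- derive_angles(ann)
  a1 <- derive_angles(s$annotation)
  for (b in paste0(bone_labels(), "a")) {
    expect_equal(a1[[b]], a0[[b]], tolerance = 1e-9)
  }
  # already-standardized square input is (geometrically) unchanged
  sq <- matrix(runif(64 * 64), 64, 64)
  ann64 <- toy_annotation(size = 64)
  s2 <- standardize(sq, ann64, size = 64)
  expect_equal(s2$annotation$segments$MT2$proximal,
               ann64$segments$MT2$proximal)
  # constant image maps to zeros by convention
  s3 <- standardize(matrix(5, 40, 40), NULL, size = 64)
  expect_true(all(s3$image == 0))
})

test_that("augmentation transforms image and annotation together", {
  p <- generate_phantom(phantom_spec(image_height = 128, image_width = 128,
                                     noise_sd = 0.02))
  s <- standardize(p$image, p$annotation, size = 128)
  a0 <- derive_angles(s$annotation)
  # pure rotation: every inclination shifts by exactly the drawn angle
  r <- boneaxis:::augment_one(s, flip = FALSE, theta = 10, copy_id = 1)
  a1 <- derive_angles(r$annotation)
  for (b in paste0(bone_labels(), "a")) {
    expect_equal(wrap_angle(a1[[b]] - a0[[b]]), 10, tolerance = 1e-9)
  }
  expect_equal(a1$HVA, a0$HVA, tolerance = 1e-9)
  # pure flip: side toggles and HVA negates
  f <- boneaxis:::augment_one(s, flip = TRUE, theta = 0, copy_id = 1)
  expect_equal(f$annotation$side, "left")
  af <- derive_angles(f$annotation)
  expect_equal(af$HVA, -a0$HVA, tolerance = 1e-9)
  expect_equal(abs(af$IMA), abs(a0$IMA), tolerance = 1e-9)
})

test_that("augmentation is seeded, capped at 6 copies, and bounded to 15 degrees", {
  p <- generate_phantom(phantom_spec(image_height = 128, image_width = 128))
  s <- standardize(p$image, p$annotation, size = 128)
  expect_error(augment(s, n_copies = 7), "at most 6")
  c1 <- augment(s, n_copies = 4, seed = 99)
  c2 <- augment(s, n_copies = 4, seed = 99)
  expect_identical(c1, c2)
  for (cp in c1) {
    tr <- cp$provenance$transforms
    last <- tr[[length(tr)]]
    expect_lte(abs(last$rotation_deg), 15)
    expect_true(is.logical(last$flip))
  }
})

test_that("angles re-derived after random paired transforms match analytic values", {
  ann <- toy_annotation(size = 256)
  a0 <- derive_angles(ann)
  set.seed(123)
  for (i in 1:1000) {
    flip <- runif(1) < 0.5
    theta <- runif(1, -15, 15)
    A <- diag(2); b <- c(0, 0)
    if (flip) { A <- rbind(c(-1, 0), c(0, 1)); b <- c(255, 0) }
    rot <- boneaxis:::rotation_about(theta, center = c(127.5, 127.5))
    ann2 <- boneaxis:::transform_annotation(ann, rot$A %*% A,
                                            as.vector(rot$A %*% b + rot$b),
                                            256, 256)
    a1 <- derive_angles(ann2)
    expected_MT2 <- if (flip) wrap_angle(180 - a0$MT2a + theta) else
      wrap_angle(a0$MT2a + theta)
    expect_equal(wrap_angle(a1$MT2a - expected_MT2), 0, tolerance = 1e-6)
  }
})

test_that("dataset splitting is a seeded largest-remainder partition", {
  x <- as.list(1:10)
  sp <- split_dataset(x, seed = 1)
  expect_equal(lengths(sp), c(train = 7, val = 2, test = 1))
  expect_setequal(unlist(sp), 1:10)
  # largest-remainder at the clinical cohort size
  expect_equal(boneaxis:::largest_remainder(1798, c(0.7, 0.2, 0.1)),
               c(1259L, 359L, 180L))
  # determinism and disjointness
  sp2 <- split_dataset(x, seed = 1)
  expect_identical(sp, sp2)
  expect_length(intersect(unlist(sp$train), unlist(sp$test)), 0)
  expect_error(split_dataset(list()), "empty")
})
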