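test_that("inclination angles follow the CCW-from-horizontal convention", {
  # reference axis, quarter turn, diagonal (pixel y points down)
  expect_equal(inclination_angle(axis_segment("MT1", c(0, 0), c(10, 0))), 0)
  expect_equal(inclination_angle(axis_segment("MT1", c(0, 10), c(0, 0))), 90)
  expect_equal(inclination_angle(axis_segment("MT1", c(0, 5), c(5, 0))), 45)
  expect_equal(inclination_angle(axis_segment("MT1", c(5, 0), c(0, 0))), 180)
  expect_error(axis_segment("MT1", c(3, 3), c(3, 3)), "zero length")
})

test_that("inclination agrees with a two-argument arctangent oracle", {
  set.seed(42)
  for (i in 1:10000) {
    p <- runif(2, 0, 100)
    d <- p + runif(2, -50, 50)
    if (all(d == p)) next
    seg <- axis_segment("MT3", p, d)
    oracle <- atan2(-(d[2] - p[2]), d[1] - p[1]) * 180 / pi
    expect_equal(inclination_angle(seg), oracle, tolerance = 1e-9)
  }
})

test_that("angle wrapping maps to (-180, 180] with ties at +180", {
  expect_equal(wrap_angle(c(190, -190, 540, -180, 180, 360)),
               c(-170, 170, 180, 180, 180, 0))
  expect_equal(wrap_angle(20), 20)
})

test_that("derived HVA/IMA are exact angle differences", {
  ann <- toy_annotation()
  a <- derive_angles(ann)
  expect_equal(a$HVA, wrap_angle(a$PH1a - a$MT1a))
  expect_equal(a$IMA, wrap_angle(a$MT2a - a$MT1a))
  # example values: axes at 60/90/80 give HVA -30, IMA -10
  mk <- function(th) {
    d <- c(cos(th * pi / 180), -sin(th * pi / 180)) * 50
    list(p = c(250, 250), d = c(250, 250) + d)
  }
  segs <- mapply(function(b, th) {
    e <- mk(th)
    axis_segment(b, e$p, e$d)
  }, bone_labels(), c(60, 90, 80, 85, 85, 85), SIMPLIFY = FALSE)
  a2 <- derive_angles(axis_annotation(segs, 512, 512))
  expect_equal(a2$HVA, -30)
  expect_equal(a2$IMA, -10)
})

test_that("angle differences wrap across the +/-180 seam", {
  # brute-force oracle: wrap via trigonometric identity over an angle grid
  wrap_oracle <- function(d) atan2(sin(d * pi / 180), cos(d * pi / 180)) *
    180 / pi
  grid <- expand.grid(a = seq(-175, 180, by = 15), b = seq(-175, 180, 15))
  for (k in seq_len(nrow(grid))) {
    d <- grid$a[k] - grid$b[k]
    w <- wrap_angle(d)
    o <- wrap_oracle(d)
    if (abs(abs(o) - 180) < 1e-9) o <- 180  # tie convention
    expect_equal(w, o, tolerance = 1e-9)
  }
  # wrap across the seam: PH1a -170, MT1a +170 -> HVA +20
  segs <- mapply(function(b, th) {
    d <- c(cos(th * pi / 180), -sin(th * pi / 180)) * 50
    axis_segment(b, c(250, 250), c(250, 250) + d)
  }, bone_labels(), c(-170, 170, 170, 170, 170, 170), SIMPLIFY = FALSE)
  expect_equal(derive_angles(axis_annotation(segs, 512, 512))$HVA, 20)
})

test_that("rigid rotation shifts inclinations and preserves HVA/IMA", {
  ann <- toy_annotation()
  a0 <- derive_angles(ann)
  for (phi in c(-90, -15, 7.3, 45, 160)) {
    rot <- boneaxis:::rotation_about(phi, center = c(255.5, 255.5))
    ann2 <- boneaxis:::transform_annotation(ann, rot$A, rot$b, 512, 512)
    a1 <- derive_angles(ann2)
    for (b in paste0(bone_labels(), "a")) {
      expect_equal(wrap_angle(a1[[b]] - a0[[b]] - phi), 0, tolerance = 1e-9)
    }
    expect_equal(a1$HVA, a0$HVA, tolerance = 1e-9)
    expect_equal(a1$IMA, a0$IMA, tolerance = 1e-9)
  }
})

test_that("side normalization reflects left feet onto the right convention", {
  ann <- toy_annotation()
  a <- derive_angles(ann)
  # right feet unchanged
  expect_identical(normalize_side(a), a)
  # mirrored annotation (a left foot) has negated HVA/IMA ...
  m <- boneaxis:::mirror_sample(structure(
    list(image = matrix(0, 512, 512), annotation = ann,
         provenance = list(id = "t", transforms = list())),
    class = "ba_sample"))
  am <- derive_angles(m$annotation)
  expect_equal(am$HVA, -a$HVA, tolerance = 1e-9)
  expect_equal(am$IMA, -a$IMA, tolerance = 1e-9)
  # ... and normalization recovers the original signed angles
  an <- normalize_side(am)
  expect_equal(an$HVA, a$HVA, tolerance = 1e-9)
  expect_equal(an$IMA, a$IMA, tolerance = 1e-9)
  expect_equal(abs(an$MT2a), abs(a$MT2a), tolerance = 1e-9)
  # 90 degrees is a fixed point of the reflection
  expect_equal(wrap_angle(180 - 90), 90)
})

test_that("annotations validate labels and bounds", {
  segs <- toy_annotation()$segments
  expect_error(axis_annotation(segs[1:5], 512, 512), "missing bone label")
  expect_error(axis_annotation(c(segs, segs[1]), 512, 512), "duplicate")
  bad <- c(segs[-2], list(axis_segment("MT1", c(-5, 10), c(100, 100))))
  expect_error(axis_annotation(bad, 512, 512), "bounds")
})
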