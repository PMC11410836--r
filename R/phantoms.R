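#' Specification of a synthetic foot phantom
#'
#' A phantom is a radiograph-like grayscale image of six capsule-shaped
#' bright "bones" (PH1, MT1-MT5) on a dark noisy background, built so that
#' each capsule's midline is exactly its ground-truth axis segment. The
#' first ray is articulated: PH1 is placed end-to-end with MT1 (a simulated
#' first metatarsophalangeal joint), its axis at `MT1_base_angle +
#' true_HVA`; MT2 runs at `MT1_base_angle + true_IMA`; MT3-MT5 fan
#' laterally. The generated geometry therefore reproduces the requested
#' HVA and IMA exactly (for left feet, after [normalize_side()]).
#'
#' All linear defaults scale with `min(width, height) / 512`, so presets at
#' 128 x 128 keep the same proportions as the full 512 x 512 canvas.
#'
#' @param image_height,image_width Canvas size in pixels.
#' @param side `"right"` or `"left"`; left phantoms are the mirrored right
#'   layout.
#' @param true_HVA Hallux valgus angle in degrees, `|HVA| <= 60`.
#' @param true_IMA First-second intermetatarsal angle in degrees,
#'   `|IMA| <= 30`.
#' @param MT1_base_angle Inclination of the MT1 axis in degrees
#'   (counterclockwise from the right-facing horizontal; toes up is near
#'   90).
#' @param bone_lengths,bone_widths Named numeric vectors (names in
#'   `bone_labels()`), pixels at the 512 reference scale; defaults emulate
#'   dorsoplantar foot proportions.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (intensity units on the `[0, 1]` scale).
#' @param overlap_factor In `[0, 1]`: lateral crowding of the metatarsals
#'   (0 well separated, 1 strongly overlapping shafts).
#' @param seed Integer seed for the noise (and any stochastic decoration).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(image_height = 512, image_width = 512,
                         side = "right", true_HVA = -20, true_IMA = -10,
                         MT1_base_angle = 97,
                         bone_lengths = NULL, bone_widths = NULL,
                         noise_sd = 0.05, overlap_factor = 0.3,
                         seed = 1L) {
  side <- match.arg(side, c("right", "left"))
  default_lengths <- c(PH1 = 95, MT1 = 180, MT2 = 190, MT3 = 180,
                       MT4 = 165, MT5 = 150)
  default_widths <- c(PH1 = 30, MT1 = 34, MT2 = 22, MT3 = 20,
                      MT4 = 20, MT5 = 22)
  bone_lengths <- resolve_per_bone(bone_lengths, default_lengths)
  bone_widths <- resolve_per_bone(bone_widths, default_widths)
  stopifnot(image_height > 0, image_width > 0,
            all(bone_lengths > 0), all(bone_widths > 0),
            abs(true_HVA) <= 60, abs(true_IMA) <= 30, noise_sd >= 0,
            overlap_factor >= 0, overlap_factor <= 1)
  structure(list(image_height = image_height, image_width = image_width,
                 side = side, true_HVA = true_HVA, true_IMA = true_IMA,
                 MT1_base_angle = MT1_base_angle,
                 bone_lengths = bone_lengths, bone_widths = bone_widths,
                 noise_sd = noise_sd, overlap_factor = overlap_factor,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

resolve_per_bone <- function(x, defaults) {
  if (is.null(x)) return(defaults)
  out <- defaults
  stopifnot(!is.null(names(x)), all(names(x) %in% names(defaults)))
  out[names(x)] <- x
  out
}

#' Generate a synthetic foot phantom with known ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: additive capsule
#' densities (overlapping shafts add, as X-ray projections do), a dim
#' background, soft capsule edges, and Gaussian intensity noise. The
#' returned sample carries the ground-truth [axis_annotation()] whose
#' derived angles equal the spec's `true_HVA` / `true_IMA` (after
#' [normalize_side()] for left feet). Same spec (including seed) gives a
#' bit-identical image.
#'
#' @param spec A [phantom_spec()].
#' @return A `ba_sample` with fields `image` (values in `[0,1]`),
#'   `annotation`, `provenance`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  w <- spec$image_width; h <- spec$image_height
  u <- min(w, h) / 512
  geom <- phantom_geometry(spec, u)

  # safety margin: endpoints must survive any rotation augmentation, so
  # keep them inside the inscribed circle of the canvas
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  lim <- min(w, h) / 2 - 3
  for (b in BONE_LABELS) {
    for (pt in geom[[b]]) {
      if (sqrt(sum((pt - ctr)^2)) > lim) {
        stop("layout error: bone ", b, " exceeds the usable canvas; ",
             "reduce bone lengths or angles, or enlarge the image",
             call. = FALSE)
      }
    }
  }

  gx <- rep(seq_len(w) - 1, times = h)
  gy <- rep(seq_len(h) - 1, each = w)
  img <- rep(0.08, w * h)
  intensity <- c(PH1 = 0.75, MT1 = 0.80, MT2 = 0.70, MT3 = 0.65,
                 MT4 = 0.65, MT5 = 0.70)
  edge <- 1.5 * u
  for (b in BONE_LABELS) {
    d <- dist_to_segment(gx, gy, geom[[b]][[1]], geom[[b]][[2]])
    half <- spec$bone_widths[[b]] * u / 2
    # smooth capsule edge: 1 inside, 0 outside, cubic ramp across `edge`
    t <- pmin(pmax((half - d) / edge, 0), 1)
    img <- img + intensity[[b]] * t * t * (3 - 2 * t)
  }
  img <- with_seed(spec$seed, {
    img + stats::rnorm(length(img), sd = spec$noise_sd)
  })
  img <- matrix(pmin(pmax(img, 0), 1), nrow = w, ncol = h)

  segs <- lapply(BONE_LABELS, function(b) {
    axis_segment(b, geom[[b]][[1]], geom[[b]][[2]])
  })
  ann <- axis_annotation(segs, image_height = h, image_width = w,
                         side = "right")
  smp <- structure(list(image = img, annotation = ann,
                        provenance = list(id = sprintf("phantom_seed%d",
                                                       spec$seed),
                                          transforms = list(),
                                          spec = spec)),
                   class = "ba_sample")
  if (spec$side == "left") smp <- mirror_sample(smp)
  smp
}

# Endpoint geometry of the canonical right-foot layout, pixel coordinates.
phantom_geometry <- function(spec, u) {
  w <- spec$image_width; h <- spec$image_height
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  MT1a <- spec$MT1_base_angle
  MT2a <- MT1a + spec$true_IMA
  PH1a <- MT1a + spec$true_HVA
  angles <- c(PH1 = PH1a, MT1 = MT1a, MT2 = MT2a,
              MT3 = MT2a - 5, MT4 = MT2a - 10, MT5 = MT2a - 15)
  spacing <- 55 * u * (1 - 0.6 * spec$overlap_factor)
  base_x <- c(MT1 = 0, MT2 = 1, MT3 = 2, MT4 = 3, MT5 = 4) * spacing - 60 * u
  base_y <- c(MT1 = 0, MT2 = -8, MT3 = -14, MT4 = -18, MT5 = -20) * u + 150 * u
  geom <- list()
  for (b in c("MT1", "MT2", "MT3", "MT4", "MT5")) {
    p0 <- ctr + c(base_x[[b]], base_y[[b]])
    L <- spec$bone_lengths[[b]] * u
    th <- angles[[b]] * pi / 180
    p1 <- p0 + L * c(cos(th), -sin(th))   # pixel y is down
    geom[[b]] <- list(p0, p1)
  }
  # PH1 articulates distally to MT1 across a small joint gap
  th <- PH1a * pi / 180
  dirn <- c(cos(th), -sin(th))
  p0 <- geom$MT1[[2]] + 6 * u * dirn
  geom$PH1 <- list(p0, p0 + spec$bone_lengths[["PH1"]] * u * dirn)
  geom[BONE_LABELS]
}

dist_to_segment <- function(gx, gy, p0, p1) {
  v <- p1 - p0
  len2 <- sum(v^2)
  t <- pmin(pmax(((gx - p0[1]) * v[1] + (gy - p0[2]) * v[2]) / len2, 0), 1)
  sqrt((gx - (p0[1] + t * v[1]))^2 + (gy - (p0[2] + t * v[2]))^2)
}

# Mirror a sample horizontally (exact for the annotation; the image flip is
# an index reversal, no resampling).
mirror_sample <- function(sample) {
  w <- nrow(sample$image)
  img <- sample$image[w:1, , drop = FALSE]
  A <- rbind(c(-1, 0), c(0, 1)); b <- c(w - 1, 0)
  side <- if (sample$annotation$side == "right") "left" else "right"
  ann <- transform_annotation(sample$annotation, A, b,
                              new_w = w, new_h = ncol(sample$image),
                              side = side)
  sample$image <- img
  sample$annotation <- ann
  sample$provenance$transforms <- c(sample$provenance$transforms,
                                    list(list(op = "mirror")))
  sample
}

#' Model of manual raters tracing bone axes
#'
#' Emulates surgeons drawing axis lines: each rater reproduces the true
#' segment with isotropic Gaussian jitter on both endpoints plus a Gaussian
#' rotation of the whole segment about its midpoint. Angle errors are
#' zero-mean by construction.
#'
#' @param angular_noise_sd SD of the per-segment rotation, degrees.
#' @param endpoint_noise_sd SD of the per-endpoint jitter, pixels.
#' @param n_raters Number of raters (>= 1; the validation statistics
#'   expect 3).
#' @param seed Integer seed.
#' @return A `rater_model` object.
#' @export
rater_model <- function(angular_noise_sd = 1.5, endpoint_noise_sd = 2,
                        n_raters = 3, seed = 1L) {
  stopifnot(angular_noise_sd >= 0, endpoint_noise_sd >= 0, n_raters >= 1)
  structure(list(angular_noise_sd = angular_noise_sd,
                 endpoint_noise_sd = endpoint_noise_sd,
                 n_raters = n_raters, seed = as.integer(seed)),
            class = "rater_model")
}

#' Simulate manual axis measurements by several raters
#'
#' @param truth Ground-truth [axis_annotation()].
#' @param model A [rater_model()].
#' @param seed Optional seed overriding `model$seed`.
#' @return List of `n_raters` [axis_annotation()] objects.
#' @export
simulate_raters <- function(truth, model, seed = NULL) {
  stopifnot(inherits(truth, "axis_annotation"), inherits(model, "rater_model"))
  if (is.null(seed)) seed <- model$seed
  w <- truth$image_width; h <- truth$image_height
  with_seed(seed, {
    lapply(seq_len(model$n_raters), function(r) {
      segs <- lapply(truth$segments, function(sg) {
        p <- sg$proximal + stats::rnorm(2, sd = model$endpoint_noise_sd)
        d <- sg$distal + stats::rnorm(2, sd = model$endpoint_noise_sd)
        th <- stats::rnorm(1, sd = model$angular_noise_sd)
        rot <- rotation_about(th, center = (p + d) / 2)
        p <- as.vector(affine_apply(rbind(p), rot$A, rot$b))
        d <- as.vector(affine_apply(rbind(d), rot$A, rot$b))
        clamp <- function(pt) c(min(max(pt[1], 0), w - 1),
                                min(max(pt[2], 0), h - 1))
        axis_segment(sg$bone, clamp(p), clamp(d))
      })
      axis_annotation(segs, image_height = h, image_width = w,
                      side = truth$side)
    })
  })
}
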