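#' Standardize an image and its annotation for the network
#'
#' Pads the shorter dimension with black to a square (split evenly, the odd
#' pixel going to the trailing side), resizes to `size` x `size` preserving
#' the aspect ratio, maps the annotation endpoints through the identical
#' affine transform, and min-max rescales intensities to `[0, 1]` (a
#' constant image maps to all zeros). Padding and uniform scaling are
#' similarity transforms, so all axis angles are unchanged.
#'
#' @param image Matrix indexed `[x + 1, y + 1]`, arbitrary intensity range.
#' @param annotation Matching [axis_annotation()] (dimensions must agree
#'   with the image).
#' @param size Output side length in pixels (default 512, the network
#'   input size).
#' @param id Provenance identifier carried in the sample.
#' @return A `ba_sample`: list with `image` (`size` x `size`, values in
#'   `[0,1]`), `annotation` (transformed), and `provenance` (id plus a log
#'   of applied transforms).
#' @export
standardize <- function(image, annotation, size = 512, id = "sample") {
  stopifnot(is.matrix(image), nrow(image) > 0, ncol(image) > 0)
  w <- nrow(image); h <- ncol(image)
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "axis_annotation"),
              annotation$image_width == w, annotation$image_height == h)
  }
  side <- max(w, h)
  pad_x <- floor((side - w) / 2)
  pad_y <- floor((side - h) / 2)
  s <- size / side
  # forward map: out = s * (in + pad)
  A <- diag(2) * s
  b <- c(pad_x, pad_y) * s
  out <- warp_bilinear(image, A, b, out_w = size, out_h = size)
  rng <- range(image)  # decided on the input: a constant image maps to 0
  out <- if (rng[2] > rng[1]) {
    pmin(pmax((out - rng[1]) / (rng[2] - rng[1]), 0), 1)
  } else {
    out * 0
  }
  ann2 <- if (is.null(annotation)) NULL else
    transform_annotation(annotation, A, b, size, size)
  structure(list(image = out, annotation = ann2,
                 provenance = list(
                   id = id,
                   transforms = list(list(op = "standardize",
                                          pad = c(pad_x, pad_y),
                                          scale = s)))),
            class = "ba_sample")
}

transform_annotation <- function(annotation, A, b, new_w, new_h,
                                 side = annotation$side) {
  segs <- lapply(annotation$segments, function(sg) {
    p <- as.vector(affine_apply(rbind(sg$proximal), A, b))
    d <- as.vector(affine_apply(rbind(sg$distal), A, b))
    axis_segment(sg$bone, p, d)
  })
  axis_annotation(segs, image_height = new_h, image_width = new_w,
                  side = side)
}

#' Augment a standardized sample with random flips and rotations
#'
#' Each copy applies, in order, a horizontal flip with probability 1/2 and
#' a rotation by an angle drawn uniformly from `[-15, 15]` degrees about the
#' image center (bilinear resampling, black fill). The annotation endpoints
#' go through the identical transform; a flip toggles the recorded foot
#' side. Transform parameters are appended to the provenance log.
#'
#' @param sample A `ba_sample` from [standardize()].
#' @param n_copies Number of augmented copies, at most 6.
#' @param max_rotation Rotation range half-width in degrees (default 15).
#' @param seed Integer seed making the draw reproducible.
#' @return List of `n_copies` `ba_sample` objects.
#' @export
augment <- function(sample, n_copies, max_rotation = 15, seed = NULL) {
  stopifnot(inherits(sample, "ba_sample"))
  if (n_copies > 6) {
    stop("configuration error: at most 6 augmented copies per sample",
         call. = FALSE)
  }
  if (n_copies < 1) return(list())
  with_seed(seed, {
    lapply(seq_len(n_copies), function(i) {
      flip <- stats::runif(1) < 0.5
      theta <- stats::runif(1, -max_rotation, max_rotation)
      augment_one(sample, flip, theta, i)
    })
  })
}

augment_one <- function(sample, flip, theta, copy_id) {
  img <- sample$image
  ann <- sample$annotation
  w <- nrow(img); h <- ncol(img)
  side <- ann$side
  A <- diag(2); b <- c(0, 0)
  if (flip) {
    # x -> (w - 1) - x
    A <- rbind(c(-1, 0), c(0, 1))
    b <- c(w - 1, 0)
    side <- if (side == "right") "left" else "right"
  }
  rot <- rotation_about(theta, center = c((w - 1) / 2, (h - 1) / 2))
  A2 <- rot$A %*% A
  b2 <- as.vector(rot$A %*% b + rot$b)
  img2 <- warp_bilinear(img, A2, b2)
  ann2 <- transform_annotation(ann, A2, b2, w, h, side = side)
  prov <- sample$provenance
  prov$id <- paste0(prov$id, "_aug", copy_id)
  prov$transforms <- c(prov$transforms,
                       list(list(op = "augment", flip = flip,
                                 rotation_deg = theta)))
  structure(list(image = img2, annotation = ann2, provenance = prov),
            class = "ba_sample")
}

#' Split samples into train / validation / test partitions
#'
#' Seeded random shuffle followed by a largest-remainder apportionment of
#' the requested ratios, giving a disjoint exhaustive partition whose sizes
#' are the fairest integer rounding of `n * ratios`.
#'
#' @param samples A list (or vector) of cases.
#' @param ratios Length-3 numeric summing to 1 (default `c(0.70, 0.20,
#'   0.10)`).
#' @param seed Integer seed for the shuffle.
#' @return Named list `train`, `val`, `test`.
#' @export
split_dataset <- function(samples, ratios = c(0.70, 0.20, 0.10),
                          seed = NULL) {
  n <- length(samples)
  if (n == 0) stop("empty input: nothing to split", call. = FALSE)
  stopifnot(length(ratios) == 3, all(ratios >= 0),
            abs(sum(ratios) - 1) < 1e-9)
  sizes <- largest_remainder(n, ratios)
  idx <- with_seed(seed, sample.int(n))
  cuts <- cumsum(sizes)
  list(train = samples[idx[seq_len(sizes[1])]],
       val = samples[idx[seq_len(cuts[2] - cuts[1]) + cuts[1]]],
       test = samples[idx[seq_len(cuts[3] - cuts[2]) + cuts[2]]])
}

largest_remainder <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    # round away float noise so exact ties break by position (train first)
    frac <- round(exact - base, 9)
    order_rem <- order(-frac, seq_along(frac))
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Evaluate `code` under a temporarily seeded RNG, restoring the caller's
# RNG state afterwards. seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
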