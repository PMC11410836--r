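# Image convention used throughout the package: a grayscale image or mask is
# a numeric matrix indexed [x + 1, y + 1] -- first dimension along image
# width, second along height, pixel (0,0) at the top-left, y increasing
# downward. This matches EBImage's layout, so filters apply directly.

#' Rasterize an axis segment to a 1-pixel-wide binary mask
#'
#' Draws the discrete 8-connected (Bresenham) line between the segment's
#' endpoints, rounded to the nearest pixel centers. Pixels under the line
#' get value 1, all others 0; both endpoint pixels are always set.
#'
#' @param segment An [axis_segment()].
#' @param height,width Mask dimensions in pixels.
#' @return Binary matrix of dimension `c(width, height)` (see file header
#'   for the indexing convention).
#' @export
rasterize_segment <- function(segment, height, width) {
  p0 <- round(segment$proximal)
  p1 <- round(segment$distal)
  pts <- rbind(p0, p1)
  if (any(pts[, 1] < 0) || any(pts[, 1] > width - 1) ||
      any(pts[, 2] < 0) || any(pts[, 2] > height - 1)) {
    stop("bounds error: segment endpoints outside ", width, " x ", height,
         " mask", call. = FALSE)
  }
  mask <- matrix(0, nrow = width, ncol = height)
  xy <- bresenham_line(segment$proximal[1], segment$proximal[2],
                       segment$distal[1], segment$distal[2])
  mask[cbind(xy[, 1] + 1, xy[, 2] + 1)] <- 1
  mask
}

# Integer 8-connected line between (x0,y0) and (x1,y1) (real-valued
# endpoints), inclusive of both rounded endpoint pixels. Steps one pixel
# per unit along the dominant axis; the minor coordinate is sampled from
# the exact line equation, not from rounded endpoints, so the pixel set
# tracks the true line with zero-mean quantization error.
bresenham_line <- function(x0, y0, x1, y1) {
  if (abs(x1 - x0) >= abs(y1 - y0)) {
    xa <- round(x0); xb <- round(x1)
    if (xa == xb) return(cbind(x = xa, y = round((y0 + y1) / 2)))
    xs <- xa:xb
    ys <- round(y0 + (xs - x0) / (x1 - x0) * (y1 - y0))
    cbind(x = xs, y = ys)
  } else {
    ya <- round(y0); yb <- round(y1)
    ys <- ya:yb
    xs <- round(x0 + (ys - y0) / (y1 - y0) * (x1 - x0))
    cbind(x = xs, y = ys)
  }
}

#' Thicken a binary line mask to a fixed cross-sectional width
#'
#' Morphological dilation with a disc-shaped structuring element whose
#' diameter equals `width_px`, so a 1-pixel line becomes a band `width_px`
#' pixels wide across its direction. The output contains the input.
#'
#' @param mask Binary matrix.
#' @param width_px Target cross-section width in pixels (odd; default 5).
#' @return Binary matrix of the same dimension.
#' @export
thicken <- function(mask, width_px = 5) {
  stopifnot(!any(mask != 0 & mask != 1), width_px >= 1, width_px %% 2 == 1)
  if (width_px == 1 || !any(mask > 0)) return(mask)
  brush <- EBImage::makeBrush(width_px, shape = "disc")
  # line masks are sparse, so dilation as the union of brush-offset
  # translates of the set pixels beats a dense morphological pass
  r <- (width_px - 1) / 2
  off <- which(brush > 0, arr.ind = TRUE) - (r + 1)
  set <- which(mask > 0, arr.ind = TRUE)
  pts <- cbind(rep(set[, 1], nrow(off)) + rep(off[, 1], each = nrow(set)),
               rep(set[, 2], nrow(off)) + rep(off[, 2], each = nrow(set)))
  keep <- pts[, 1] >= 1 & pts[, 1] <= nrow(mask) &
    pts[, 2] >= 1 & pts[, 2] <= ncol(mask)
  out <- matrix(0, nrow(mask), ncol(mask))
  out[pts[keep, , drop = FALSE]] <- 1
  out
}

#' Gaussian standard deviation for a bone's heatmap
#'
#' The blur applied to a thickened axis line scales with the image height
#' `h` and inversely with the segment length `L`: `sigma = h / (2.5 * L)`
#' for the PH1 axis and `sigma = h / L` for the metatarsal axes MT1-MT5.
#' Short bones in tall images thus get proportionally wider probabilistic
#' bands.
#'
#' @param bone_label One of `"PH1"`, `"MT1"` ... `"MT5"`.
#' @param h Image height in pixels (> 0).
#' @param L Segment length in pixels (> 0).
#' @return Standard deviation in pixels.
#' @examples
#' gaussian_sigma("MT2", h = 512, L = 128) # 4
#' gaussian_sigma("PH1", h = 512, L = 204.8) # 1
#' @export
gaussian_sigma <- function(bone_label, h, L) {
  bone_label <- match.arg(bone_label, BONE_LABELS)
  stopifnot(h > 0)
  if (L <= 0) stop("degenerate geometry: segment length must be > 0",
                   call. = FALSE)
  if (bone_label == "PH1") h / (2.5 * L) else h / L
}

# Separable Gaussian blur with zero (black) boundary handling, kernel
# truncated at 4 sigma. Each 1-D pass is a banded Toeplitz matrix product,
# which keeps the boundary semantics exact (outside pixels contribute 0)
# and runs through BLAS.
gaussian_blur_zero <- function(mask, sigma) {
  if (sigma <= 0) return(mask)
  radius <- ceiling(4 * sigma)
  blur_1d <- function(n) {
    d <- outer(seq_len(n), seq_len(n), "-")
    g <- exp(-d^2 / (2 * sigma^2))
    g[abs(d) > radius] <- 0
    g / sum(exp(-(-radius:radius)^2 / (2 * sigma^2)))
  }
  Bx <- blur_1d(nrow(mask))
  By <- if (ncol(mask) == nrow(mask)) Bx else blur_1d(ncol(mask))
  Bx %*% mask %*% By
}

#' Encode an annotation as a 6-channel training heatmap stack
#'
#' Each bone axis is rasterized to a 1-pixel line, thickened to a 5-pixel
#' band, blurred with a Gaussian of bone-specific standard deviation
#' ([gaussian_sigma()]), and renormalized so the channel maximum is 1.
#' Channels are built independently, so overlapping bone regions simply
#' yield overlapping probabilistic bands.
#'
#' @param annotation An [axis_annotation()].
#' @param thicken_px Band width before blurring (default 5).
#' @return Numeric array of dimension `c(width, height, 6)` with values in
#'   `[0, 1]`; `dimnames[[3]]` carries the channel order
#'   (PH1, MT1 ... MT5).
#' @export
make_heatmaps <- function(annotation, thicken_px = 5) {
  stopifnot(inherits(annotation, "axis_annotation"))
  h <- annotation$image_height
  w <- annotation$image_width
  stack <- array(0, dim = c(w, h, 6),
                 dimnames = list(NULL, NULL, BONE_LABELS))
  for (i in seq_along(BONE_LABELS)) {
    seg <- annotation$segments[[BONE_LABELS[i]]]
    mask <- thicken(rasterize_segment(seg, h, w), thicken_px)
    sigma <- gaussian_sigma(seg$bone, h, segment_length(seg))
    ch <- gaussian_blur_zero(mask, sigma)
    m <- max(ch)
    if (m > 0) ch <- ch / m
    stack[, , i] <- pmin(pmax(ch, 0), 1)  # FFT blur can leave ~1e-16 noise
  }
  stack
}

#' Write / read a heatmap stack losslessly
#'
#' Serializes the full-precision array together with its channel-order
#' metadata; the round trip is bit-exact.
#'
#' @param stack Array from [make_heatmaps()] (or a network prediction).
#' @param path File path.
#' @return `read_heatmaps` returns the array; `write_heatmaps` returns
#'   `path` invisibly.
#' @export
write_heatmaps <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3, dim(stack)[3] == 6)
  saveRDS(list(format = "boneaxis_heatmap_stack", channels = BONE_LABELS,
               values = stack), path)
  invisible(path)
}

#' @rdname write_heatmaps
#' @export
read_heatmaps <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "boneaxis_heatmap_stack")) {
    stop("not a heatmap stack file: ", path, call. = FALSE)
  }
  obj$values
}
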