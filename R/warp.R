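# Affine point maps and bilinear image warping.
#
# A transform is forward: out_pt = A %*% in_pt + b on 0-based pixel-center
# coordinates (x right, y down). Images are resampled by the inverse map
# with bilinear interpolation; samples falling outside the source grid read
# as 0 (black). Using one matrix for both the image and the annotation
# endpoints guarantees they receive the identical transform.

affine_apply <- function(pts, A, b) {
  # pts: n x 2 matrix of (x, y)
  sweep(pts %*% t(A), 2, b, "+")
}

affine_invert <- function(A, b) {
  Ai <- solve(A)
  list(A = Ai, b = as.vector(-Ai %*% b))
}

# Rotation by theta degrees CCW on screen (y-down pixel frame) about `center`.
rotation_about <- function(theta_deg, center) {
  th <- theta_deg * pi / 180
  # y-down frame: visual CCW rotation is the clockwise matrix in math coords
  A <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  list(A = A, b = as.vector(center - A %*% center))
}

# Warp `img` (matrix [x+1, y+1]) through forward map (A, b) onto an
# out_w x out_h canvas, bilinear, zero fill.
warp_bilinear <- function(img, A, b, out_w = nrow(img), out_h = ncol(img)) {
  inv <- affine_invert(A, b)
  grid <- cbind(rep(seq_len(out_w) - 1, times = out_h),
                rep(seq_len(out_h) - 1, each = out_w))
  src <- affine_apply(grid, inv$A, inv$b)
  sx <- src[, 1]; sy <- src[, 2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  w <- nrow(img); h <- ncol(img)
  pick <- function(xi, yi) {
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    v <- numeric(length(xi))
    v[ok] <- img[cbind(xi[ok] + 1, yi[ok] + 1)]
    v
  }
  val <- pick(x0, y0) * (1 - fx) * (1 - fy) +
    pick(x0 + 1, y0) * fx * (1 - fy) +
    pick(x0, y0 + 1) * (1 - fx) * fy +
    pick(x0 + 1, y0 + 1) * fx * fy
  matrix(val, nrow = out_w, ncol = out_h)
}
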