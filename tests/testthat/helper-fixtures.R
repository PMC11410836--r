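# Shared fixtures and independent oracles, all built in code.

# A hand-placed six-bone annotation on a canvas of the given size
# (positions scale with the canvas; toes-up layout).
toy_annotation <- function(size = 512, side = "right") {
  u <- size / 512
  seg <- function(bone, p, d) axis_segment(bone, p * u, d * u)
  axis_annotation(list(
    seg("PH1", c(130, 150), c(120, 60)),
    seg("MT1", c(150, 400), c(135, 170)),
    seg("MT2", c(230, 390), c(225, 160)),
    seg("MT3", c(300, 395), c(302, 180)),
    seg("MT4", c(350, 400), c(360, 190)),
    seg("MT5", c(400, 410), c(420, 210))),
    image_height = size, image_width = size, side = side)
}

# Annotation with one probe segment (MT2) of the given inclination and
# length, centered on the canvas; the other bones sit out of the way.
probe_annotation <- function(theta_deg, length_px, size = 512) {
  c0 <- c((size - 1) / 2, (size - 1) / 2)
  d <- c(cos(theta_deg * pi / 180), -sin(theta_deg * pi / 180)) *
    length_px / 2
  u <- size / 512
  seg <- function(bone, p, dd) axis_segment(bone, p * u, dd * u)
  axis_annotation(list(
    seg("PH1", c(60, 100), c(55, 60)),
    seg("MT1", c(60, 400), c(65, 200)),
    axis_segment("MT2", c0 - d, c0 + d),
    seg("MT3", c(450, 400), c(452, 200)),
    seg("MT4", c(480, 400), c(485, 250)),
    seg("MT5", c(470, 420), c(490, 260))),
    image_height = size, image_width = size)
}

# Smallest-angle distance between two undirected axis angles (degrees).
undirected_diff <- function(a, b) {
  abs(((a - b + 90) %% 180) - 90)
}

# Brute-force binary dilation: union of brush-offset translates.
oracle_dilate <- function(mask, brush) {
  r <- (nrow(brush) - 1) / 2
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] == 0) next
      for (di in -r:r) {
        for (dj in -r:r) {
          if (brush[di + r + 1, dj + r + 1] == 0) next
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask))
            out[ii, jj] <- 1
        }
      }
    }
  }
  out
}

# Exhaustive axis-angle search: minimize the value-weighted perpendicular
# scatter of the selected pixels over an angle grid (degrees, undirected).
oracle_axis_angle <- function(channel, tau = 0.5, step = 0.05) {
  mx <- max(channel)
  sel <- which(channel >= tau * mx, arr.ind = TRUE)
  w <- channel[sel]
  w <- w / sum(w)
  x <- sel[, 1] - 1; y <- sel[, 2] - 1
  cx <- sum(w * x); cy <- sum(w * y)
  th <- seq(0, 180 - step, by = step) * pi / 180
  # perpendicular distance of (x,y) to the line through (cx,cy) at angle th
  D <- cbind(x - cx, y - cy) %*% rbind(-sin(th), cos(th))
  scatter <- as.vector(w %*% D^2)
  (which.min(scatter) - 1) * step
}
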