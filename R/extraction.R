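#' Configuration for axis extraction from heatmap channels
#'
#' @param threshold_fraction Fraction of the channel maximum above which
#'   pixels count as the "high-value area" (strictly between 0 and 1;
#'   default 0.5).
#' @param min_support_pixels Minimum number of selected pixels required
#'   for a fit (>= 3; default 20).
#' @param weighting `"heatmap-value"` (default) weights each selected pixel
#'   by its heatmap value; `"binary"` weights all selected pixels equally.
#' @return An `extraction_config` object.
#' @export
extraction_config <- function(threshold_fraction = 0.5,
                              min_support_pixels = 20,
                              weighting = c("heatmap-value", "binary")) {
  weighting <- match.arg(weighting)
  stopifnot(threshold_fraction > 0, threshold_fraction < 1,
            min_support_pixels >= 3)
  structure(list(threshold_fraction = threshold_fraction,
                 min_support_pixels = min_support_pixels,
                 weighting = weighting),
            class = "extraction_config")
}

#' Extract a bone axis from one heatmap channel
#'
#' Selects the high-value area (pixels at or above `threshold_fraction`
#' of the channel maximum) and fits its principal axis: the dominant
#' eigenvector of the (optionally value-weighted) second-moment matrix of
#' the pixel coordinates. This is the total-least-squares line, which is
#' rotation-invariant and has no vertical-line failure mode, unlike
#' y-on-x regression; metatarsal axes are near-vertical in dorsoplantar
#' view.
#'
#' The fitted axis is undirected. The returned direction is oriented with
#' a positive y-up component (toward the toes when toes are at the top of
#' the image); pass `toe_point` to orient toward a known toe-side point
#' instead, as [measure_image()] does using the PH1 channel centroid.
#'
#' @param channel Numeric matrix (one heatmap channel, `[x+1, y+1]`
#'   indexing).
#' @param config An [extraction_config()].
#' @param toe_point Optional `(x, y)` pixel point defining the toe side.
#' @return List with `centroid` (pixel `(x, y)`), `direction` (unit
#'   vector in pixel frame), `angle` (directed inclination, degrees in
#'   (-180, 180]), `support` (number of pixels used).
#' @export
extract_axis <- function(channel, config = extraction_config(),
                         toe_point = NULL) {
  stopifnot(is.matrix(channel))
  mx <- max(channel)
  if (!is.finite(mx) || mx <= 0) {
    stop("insufficient signal: channel maximum is not positive",
         call. = FALSE)
  }
  sel <- which(channel >= config$threshold_fraction * mx, arr.ind = TRUE)
  if (nrow(sel) < config$min_support_pixels) {
    stop("insufficient signal: only ", nrow(sel),
         " pixels above threshold (need ", config$min_support_pixels, ")",
         call. = FALSE)
  }
  x <- sel[, 1] - 1
  y <- sel[, 2] - 1
  wt <- if (config$weighting == "heatmap-value") channel[sel] else
    rep(1, nrow(sel))
  wt <- wt / sum(wt)
  cx <- sum(wt * x); cy <- sum(wt * y)
  dx <- x - cx; dy <- y - cy
  Sxx <- sum(wt * dx * dx)
  Sxy <- sum(wt * dx * dy)
  Syy <- sum(wt * dy * dy)
  e <- eigen(matrix(c(Sxx, Sxy, Sxy, Syy), 2, 2), symmetric = TRUE)
  if (e$values[1] < 1.05 * e$values[2]) {
    stop("degenerate axis: support is isotropic (eigenvalue ratio ",
         sprintf("%.3f", e$values[1] / max(e$values[2], .Machine$double.eps)),
         " < 1.05)", call. = FALSE)
  }
  v <- e$vectors[, 1]        # pixel frame (x right, y down)
  # orient: toward toe_point if given, else y-up (toes at top)
  if (!is.null(toe_point)) {
    ref <- c(toe_point[1] - cx, toe_point[2] - cy)
    if (sum(v * ref) < 0) v <- -v
  } else if (v[2] > 0 || (v[2] == 0 && v[1] < 0)) {
    v <- -v
  }
  list(centroid = c(cx, cy), direction = v,
       angle = wrap_angle(atan2(-v[2], v[1]) * 180 / pi),
       support = nrow(sel))
}

#' Measure all bone-axis angles on one standardized image
#'
#' Runs the network on the image, extracts each channel's axis with
#' [extract_axis()], orients every axis toward the toe side (defined by
#' the PH1 channel centroid relative to the mean metatarsal centroid), and
#' derives HVA and IMA. A channel that fails extraction is flagged and
#' reported as `NA` without aborting the remaining channels.
#'
#' @param network A trained network from [build_model()] / [train_model()],
#'   or `NULL` when `heatmaps` is supplied directly.
#' @param image Standardized image matrix (`input_size` square), or `NULL`
#'   when `heatmaps` is given.
#' @param config An [extraction_config()].
#' @param heatmaps Optional 6-channel array bypassing the network (used
#'   for oracle tests with ground-truth heatmaps).
#' @param side Foot side recorded in the result (default `"right"`).
#' @return List with `angles` (an `angle_set`; failed bones are `NA`) and
#'   `status` (named character vector, `"ok"` or the failure message).
#' @export
measure_image <- function(network, image, config = extraction_config(),
                          heatmaps = NULL, side = "right") {
  if (is.null(heatmaps)) {
    heatmaps <- predict_heatmaps(network, image)
  }
  stopifnot(length(dim(heatmaps)) == 3, dim(heatmaps)[3] == 6)
  fits <- vector("list", 6)
  status <- setNames(rep("ok", 6), BONE_LABELS)
  for (i in 1:6) {
    # single-bracket assignment: a NULL result must not shrink the list
    fits[i] <- list(tryCatch(extract_axis(heatmaps[, , i], config),
                             error = function(e) {
                               status[i] <<- conditionMessage(e)
                               NULL
                             }))
  }
  # toe side: PH1 centroid vs mean metatarsal centroid
  toe_ref <- NULL
  if (!is.null(fits[[1]])) {
    mt_cent <- do.call(rbind, lapply(fits[2:6], function(f)
      if (is.null(f)) NULL else f$centroid))
    if (!is.null(mt_cent) && nrow(mt_cent) > 0) {
      toe_vec <- fits[[1]]$centroid - colMeans(mt_cent)
      if (sum(toe_vec^2) > 0) toe_ref <- toe_vec
    }
  }
  incl <- setNames(rep(NA_real_, 6), paste0(BONE_LABELS, "a"))
  for (i in 1:6) {
    f <- fits[[i]]
    if (is.null(f)) next
    v <- f$direction
    if (!is.null(toe_ref) && sum(v * toe_ref) < 0) v <- -v
    incl[i] <- wrap_angle(atan2(-v[2], v[1]) * 180 / pi)
  }
  list(angles = angle_set(incl, side = side), status = status)
}
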