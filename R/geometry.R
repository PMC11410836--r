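#' @useDynLib boneaxis, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Bone labels in fixed channel order.
BONE_LABELS <- c("PH1", "MT1", "MT2", "MT3", "MT4", "MT5")

#' Bone labels in channel order
#'
#' The six bone axes handled by the package, in the fixed channel order used
#' by heatmap stacks and network outputs: first proximal phalanx (PH1), then
#' metatarsals MT1 to MT5.
#'
#' @return Character vector of length 6.
#' @export
bone_labels <- function() BONE_LABELS

#' Wrap an angle into (-180, 180]
#'
#' Reduces angles in degrees to the unique representative in (-180, 180];
#' ties at +/-180 resolve to +180.
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, each element in (-180, 180].
#' @examples
#' wrap_angle(c(190, -180, 540))
#' @export
wrap_angle <- function(theta) {
  w <- ((theta + 180) %% 360) - 180
  w[which(w == -180)] <- 180
  w
}

#' Construct a labeled bone-axis segment
#'
#' An axis segment is a directed 2-D line segment in 0-based pixel
#' coordinates (x right, y down), running proximal to distal along a bone's
#' longitudinal axis. Endpoints sit at the ends of the bone region.
#'
#' @param bone One of `"PH1"`, `"MT1"` ... `"MT5"`.
#' @param proximal,distal Numeric length-2 vectors, `(x, y)` pixel
#'   coordinates of the proximal and distal endpoints.
#' @return An object of class `axis_segment` with fields `bone`, `proximal`,
#'   `distal`.
#' @examples
#' axis_segment("MT1", c(100, 400), c(120, 100))
#' @export
axis_segment <- function(bone, proximal, distal) {
  bone <- match.arg(bone, BONE_LABELS)
  proximal <- as.numeric(proximal)
  distal <- as.numeric(distal)
  stopifnot(length(proximal) == 2, length(distal) == 2,
            all(is.finite(proximal)), all(is.finite(distal)))
  if (all(proximal == distal)) {
    stop("degenerate geometry: axis segment for ", bone,
         " has zero length", call. = FALSE)
  }
  structure(list(bone = bone, proximal = proximal, distal = distal),
            class = "axis_segment")
}

#' Euclidean length of an axis segment in pixels
#' @param segment An [axis_segment()].
#' @return Numeric scalar, > 0.
#' @export
segment_length <- function(segment) {
  sqrt(sum((segment$distal - segment$proximal)^2))
}

#' Construct a six-bone axis annotation for one image
#'
#' Bundles exactly one [axis_segment()] per bone with the image dimensions
#' and the foot side. All endpoints must lie inside the image bounds
#' (0-based pixel centers, so x in `[0, width - 1]`, y in `[0, height - 1]`).
#'
#' @param segments List of six [axis_segment()] objects, one per bone label
#'   (any order; stored in channel order).
#' @param image_height,image_width Image dimensions in pixels.
#' @param side `"left"` or `"right"`.
#' @return An object of class `axis_annotation`.
#' @export
axis_annotation <- function(segments, image_height, image_width,
                            side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(image_height > 0, image_width > 0)
  labs <- vapply(segments, function(s) s$bone, character(1))
  if (anyDuplicated(labs)) {
    stop("duplicate bone label in annotation: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(BONE_LABELS, labs)
  if (length(missing)) {
    stop("missing bone label in annotation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  segments <- segments[match(BONE_LABELS, labs)]
  names(segments) <- BONE_LABELS
  for (s in segments) {
    pts <- rbind(s$proximal, s$distal)
    if (any(pts[, 1] < 0) || any(pts[, 1] > image_width - 1) ||
        any(pts[, 2] < 0) || any(pts[, 2] > image_height - 1)) {
      stop("bounds error: endpoint of ", s$bone,
           " lies outside the image (", image_width, " x ", image_height,
           ")", call. = FALSE)
    }
  }
  structure(list(segments = segments, image_height = image_height,
                 image_width = image_width, side = side),
            class = "axis_annotation")
}

#' Inclination angle of a directed axis segment
#'
#' Angle of the proximal-to-distal direction vector, measured
#' counterclockwise from the right-facing horizontal in a y-up frame
#' (positive angles are counterclockwise as seen on screen; pixel y, which
#' increases downward, is flipped internally). Result in degrees in
#' (-180, 180].
#'
#' @param segment An [axis_segment()].
#' @return Numeric scalar, degrees in (-180, 180].
#' @examples
#' # toes-up axis in pixel coordinates (distal above proximal): +90 degrees
#' inclination_angle(axis_segment("MT2", c(50, 400), c(50, 100)))
#' @export
inclination_angle <- function(segment) {
  d <- segment$distal - segment$proximal
  if (all(d == 0)) stop("degenerate geometry: zero-length segment",
                        call. = FALSE)
  # flip pixel y (down) to math y (up) so CCW is visually CCW; wrap so a
  # leftward horizontal axis reports +180, not atan2's negative-zero -180
  wrap_angle(atan2(-d[2], d[1]) * 180 / pi)
}

#' Per-bone inclination angles and derived HVA/IMA
#'
#' Computes the six axis inclination angles and derives the hallux valgus
#' angle `HVA = PH1a - MT1a` and the first-second intermetatarsal angle
#' `IMA = MT2a - MT1a`, both wrapped into (-180, 180].
#'
#' @param annotation An [axis_annotation()].
#' @return An object of class `angle_set`: named list with numeric fields
#'   `PH1a`, `MT1a` ... `MT5a`, `HVA`, `IMA` (degrees) and the `side`
#'   carried over from the annotation.
#' @export
derive_angles <- function(annotation) {
  stopifnot(inherits(annotation, "axis_annotation"))
  incl <- vapply(annotation$segments, inclination_angle, numeric(1))
  names(incl) <- paste0(BONE_LABELS, "a")
  angle_set(incl, side = annotation$side)
}

#' Assemble an angle set from six inclination angles
#'
#' @param inclinations Named numeric vector with elements `PH1a`,
#'   `MT1a` ... `MT5a` in degrees (`NA` allowed for failed bones).
#' @param side `"left"` or `"right"`.
#' @return An `angle_set`; `HVA`/`IMA` are wrapped differences of the
#'   inclinations (NA if an operand is NA).
#' @export
angle_set <- function(inclinations, side = "right") {
  need <- paste0(BONE_LABELS, "a")
  stopifnot(all(need %in% names(inclinations)))
  a <- as.list(inclinations[need])
  a$HVA <- wrap_angle(a$PH1a - a$MT1a)
  a$IMA <- wrap_angle(a$MT2a - a$MT1a)
  a$side <- side
  structure(a, class = "angle_set")
}

#' @export
print.angle_set <- function(x, ...) {
  cat("Bone-axis angle set (", x$side, " foot)\n", sep = "")
  for (b in paste0(BONE_LABELS, "a")) {
    cat(sprintf("  %-5s %8.2f deg\n", b, x[[b]]))
  }
  cat(sprintf("  HVA  %8.2f deg\n  IMA  %8.2f deg\n", x$HVA, x$IMA))
  invisible(x)
}

#' Map a left-foot angle set onto the right-foot sign convention
#'
#' Left and right feet are mirror images, so their signed angles live on
#' opposite sign conventions. For a left foot every inclination angle is
#' reflected across the vertical (`theta -> 180 - theta`, wrapped) and the
#' derived angles recomputed; right feet pass through unchanged. `|HVA|`
#' and `|IMA|` are invariant under the transform.
#'
#' @param angles An `angle_set`.
#' @param side Overrides `angles$side` when given.
#' @return An `angle_set` on the right-foot convention (`side` set to
#'   `"right"` after normalization).
#' @export
normalize_side <- function(angles, side = NULL) {
  stopifnot(inherits(angles, "angle_set"))
  side <- if (is.null(side)) angles$side else match.arg(side, c("left", "right"))
  if (side == "right") return(angles)
  incl <- vapply(paste0(BONE_LABELS, "a"),
                 function(b) wrap_angle(180 - angles[[b]]), numeric(1))
  angle_set(incl, side = "right")
}
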