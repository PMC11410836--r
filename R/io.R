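#' Read / write an axis annotation as JSON
#'
#' One JSON document per image: fields `image_height`, `image_width`,
#' `side`, and `axes`, a list of six objects
#' `{bone, proximal: [x, y], distal: [x, y]}` with 0-based pixel-center
#' coordinates. The round trip is lossless; schema violations (missing or
#' duplicate bone, out-of-bounds coordinates, malformed fields) are
#' rejected with a diagnostic naming the offending element.
#'
#' @param path File path.
#' @param annotation An [axis_annotation()].
#' @return `read_annotation` returns an [axis_annotation()];
#'   `write_annotation` returns `path` invisibly.
#' @export
read_annotation <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  for (f in c("image_height", "image_width", "side", "axes")) {
    if (is.null(doc[[f]])) {
      stop("annotation ", path, ": missing field '", f, "'",
           call. = FALSE)
    }
  }
  if (!is.list(doc$axes)) {
    stop("annotation ", path, ": 'axes' must be a list of six objects",
         call. = FALSE)
  }
  segs <- lapply(seq_along(doc$axes), function(i) {
    ax <- doc$axes[[i]]
    if (is.null(ax$bone) || is.null(ax$proximal) || is.null(ax$distal)) {
      stop("annotation ", path, ": axes[", i,
           "] needs fields bone, proximal, distal", call. = FALSE)
    }
    if (!(ax$bone %in% BONE_LABELS)) {
      stop("annotation ", path, ": axes[", i, "] has unknown bone '",
           ax$bone, "'", call. = FALSE)
    }
    if (length(ax$proximal) != 2 || length(ax$distal) != 2) {
      stop("annotation ", path, ": axes[", i,
           "] endpoints must be [x, y] pairs", call. = FALSE)
    }
    axis_segment(ax$bone, as.numeric(ax$proximal), as.numeric(ax$distal))
  })
  axis_annotation(segs, image_height = doc$image_height,
                  image_width = doc$image_width, side = doc$side)
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "axis_annotation"))
  doc <- list(image_height = annotation$image_height,
              image_width = annotation$image_width,
              side = annotation$side,
              axes = lapply(unname(annotation$segments), function(s) {
                list(bone = s$bone, proximal = s$proximal,
                     distal = s$distal)
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a grayscale image as PNG
#'
#' Reads 8- or 16-bit grayscale PNG into the package's `[x+1, y+1]`
#' matrix convention with intensities in `[0, 1]`; color PNGs are
#' averaged to grayscale.
#'
#' @param path File path.
#' @param image Matrix with values in `[0, 1]`.
#' @return `read_image` returns a matrix; `write_image` returns `path`
#'   invisibly.
#' @export
read_image <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) {
    arr <- apply(arr[, , seq_len(min(3, dim(arr)[3])), drop = FALSE],
                 c(1, 2), mean)
  }
  t(arr)  # readPNG is [row = y, col = x]; package convention is [x, y]
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(t(pmin(pmax(image, 0), 1)), path)
  invisible(path)
}

#' Write measured angle sets to CSV
#'
#' One row per case: case id, side, the six inclination angles, HVA, IMA
#' (degrees, 2 decimals), and per-bone status flags.
#'
#' @param measurements Named list of [measure_image()] results (names are
#'   case ids).
#' @param path File path.
#' @return The data frame written, invisibly.
#' @export
write_angles_csv <- function(measurements, path) {
  rows <- lapply(names(measurements), function(id) {
    m <- measurements[[id]]
    a <- m$angles
    df <- data.frame(case_id = id, side = a$side)
    for (p in c(paste0(BONE_LABELS, "a"), "HVA", "IMA")) {
      df[[p]] <- round(a[[p]], 2)
    }
    df$status <- paste(paste0(BONE_LABELS, "=", m$status),
                       collapse = ";")
    df
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
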