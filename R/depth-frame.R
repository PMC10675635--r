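#' Construct a depth frame
#'
#' A depth frame is an integer matrix of range measurements in millimetres,
#' as produced by a time-of-flight sensor; 0 is the no-data sentinel (no
#' return, or a pixel removed by pre-processing). The default sensor raster
#' is 424 rows x 512 columns.
#'
#' @param values Numeric matrix, non-negative integer-valued millimetres.
#' @param camera Camera view token (see [CAMERA_VIEWS]).
#' @param frame_id Opaque identifier string.
#' @return A `depth_frame`: an integer matrix with attributes `camera` and
#'   `frame_id`.
#' @export
#' @examples
#' f <- depth_frame(matrix(1500L, 4, 6), "TOP", "demo")
#' dim(f)
depth_frame <- function(values, camera, frame_id = "") {
  if (!is.matrix(values) || nrow(values) < 1L || ncol(values) < 1L) {
    stop("depth frame values must be a non-empty matrix", call. = FALSE)
  }
  v <- as.vector(values)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
    stop("depth values must be non-negative integers (millimetres)",
         call. = FALSE)
  }
  out <- matrix(as.integer(round(values)), nrow(values), ncol(values))
  structure(out,
            camera = match_camera(camera),
            frame_id = as.character(frame_id),
            class = c("depth_frame", "matrix", "array"))
}

#' @export
print.depth_frame <- function(x, ...) {
  cat(sprintf("<depth_frame %s camera=%s id='%s' range=[%d, %d] mm>\n",
              paste(dim(x), collapse = "x"), attr(x, "camera"),
              attr(x, "frame_id"), min(x), max(x)))
  invisible(x)
}

# Strip class/attrs down to a plain integer matrix.
frame_values <- function(frame) {
  matrix(as.integer(frame), nrow(frame), ncol(frame))
}

#' Write a depth frame to disk
#'
#' Frames are stored as single-channel 16-bit grayscale uncompressed TIFF,
#' pixel value = range in millimetres. The encoding is lossless:
#' [read_depth_frame()] inverts it exactly.
#'
#' @param frame A [depth_frame()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_depth_frame <- function(frame, path) {
  if (!inherits(frame, "depth_frame")) {
    frame <- depth_frame(as.matrix(frame), camera = "TOP")
  }
  if (max(frame) > 65535L) {
    stop("depth value ", max(frame), " exceeds the 16-bit range (65535 mm)",
         call. = FALSE)
  }
  tiff::writeTIFF(frame_values(frame) / 65535, path,
                  bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a depth frame from disk
#'
#' Accepts only single-channel 16-bit grayscale TIFF (the format written by
#' [write_depth_frame()]); anything else is rejected with a format error
#' naming the offence.
#'
#' @param path File path.
#' @param camera Camera view token to attach.
#' @param frame_id Identifier to attach (default: file name sans extension).
#' @return A [depth_frame()] with integer millimetre values.
#' @export
read_depth_frame <- function(path, camera, frame_id = NULL) {
  if (!file.exists(path)) {
    stop("depth frame file not found: ", path, call. = FALSE)
  }
  meta <- tryCatch(tiff::readTIFF(path, payload = FALSE),
                   error = function(e) {
                     stop("not a readable TIFF depth frame: ", path,
                          " (", conditionMessage(e), ")", call. = FALSE)
                   })
  if (!identical(as.integer(meta$bits.per.sample), 16L)) {
    stop("depth frames must be 16-bit grayscale; ", path, " has ",
         meta$bits.per.sample, " bits per sample", call. = FALSE)
  }
  if (!identical(as.integer(meta$samples.per.pixel), 1L)) {
    stop("depth frames must be single-channel; ", path, " has ",
         meta$samples.per.pixel, " channels", call. = FALSE)
  }
  img <- tiff::readTIFF(path)
  values <- matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
  if (is.null(frame_id)) {
    frame_id <- tools::file_path_sans_ext(basename(path))
  }
  depth_frame(values, camera = camera, frame_id = frame_id)
}
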