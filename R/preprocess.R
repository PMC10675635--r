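#' Distance-limit a depth frame
#'
#' Background suppression without background subtraction: every pixel
#' further than `threshold` millimetres is zeroed (set to the no-data
#' sentinel); everything at or below it is kept. The operation is
#' idempotent.
#'
#' @param frame A [depth_frame()].
#' @param threshold Range threshold in millimetres (> 0).
#' @return A [depth_frame()] of the same shape.
#' @export
distance_limit <- function(frame, threshold) {
  stopifnot(inherits(frame, "depth_frame"), threshold > 0)
  v <- frame_values(frame)
  v[v > threshold] <- 0L
  depth_frame(v, attr(frame, "camera"), attr(frame, "frame_id"))
}

#' Crop a depth frame
#'
#' @param frame A [depth_frame()].
#' @param window Integer `c(top, left, height, width)`, 1-based, row-major,
#'   origin at the top-left pixel; must lie fully inside the frame.
#' @return The `height x width` sub-frame.
#' @export
crop_frame <- function(frame, window) {
  stopifnot(inherits(frame, "depth_frame"), length(window) == 4L)
  w <- as.integer(window)
  if (w[3] < 1L || w[4] < 1L || w[1] < 1L || w[2] < 1L ||
      w[1] + w[3] - 1L > nrow(frame) || w[2] + w[4] - 1L > ncol(frame)) {
    stop("crop window (top=", w[1], ", left=", w[2], ", h=", w[3], ", w=",
         w[4], ") out of bounds for a ", nrow(frame), "x", ncol(frame),
         " frame", call. = FALSE)
  }
  v <- frame_values(frame)[w[1]:(w[1] + w[3] - 1L),
                           w[2]:(w[2] + w[4] - 1L), drop = FALSE]
  depth_frame(v, attr(frame, "camera"), attr(frame, "frame_id"))
}

#' Binarize a depth frame into a silhouette plane
#'
#' Pixels strictly closer than `threshold` become 1, pixels at or beyond it
#' become 0. The no-data sentinel 0 mm also maps to 0: it marks removed or
#' unreturned pixels, not something touching the lens.
#'
#' @param frame A [depth_frame()].
#' @param threshold Silhouette threshold in millimetres (> 0).
#' @return A numeric 0/1 matrix of the frame's shape.
#' @export
binarize <- function(frame, threshold) {
  stopifnot(inherits(frame, "depth_frame"), threshold > 0)
  v <- frame_values(frame)
  (v > 0L & v < threshold) * 1
}

#' Left-to-right first-derivative plane
#'
#' Horizontal gradient `g[i, j] = v[i, j] - v[i, j - 1]` (first column
#' padded with 0 to preserve shape), with edge-artifact suppression: any
#' gradient whose magnitude exceeds `gradient_cap` is set to 0. Bone
#' prominence shows up as larger surface gradients on thin cows, which is
#' the signal this channel isolates; object edges produce spuriously large
#' steps and are removed by the cap.
#'
#' @param frame A [depth_frame()] of width >= 2.
#' @param gradient_cap Maximum admissible gradient magnitude, millimetres
#'   per pixel step (> 0).
#' @return A numeric matrix of the frame's shape.
#' @export
depth_derivative <- function(frame, gradient_cap) {
  stopifnot(inherits(frame, "depth_frame"), gradient_cap > 0)
  if (ncol(frame) < 2L) {
    stop("derivative needs frame width >= 2", call. = FALSE)
  }
  v <- frame_values(frame)
  g <- cbind(0, v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE])
  g[abs(g) > gradient_cap] <- 0
  g
}

#' Per-camera pre-processing configuration
#'
#' One block per camera: the distance-limiting threshold, the fixed crop
#' window, the silhouette threshold and the gradient cap. Depth values are
#' normalised by the camera's distance threshold, so the depth plane is in
#' [0, 1]. `default_preprocess_config()` provides values matched to the
#' synthetic scene geometry and the default camera poses, with the crop
#' aspect per view: square for the angled camera, taller than wide for the
#' rear camera, wider than tall for the top camera.
#'
#' @param distance_threshold mm, pixels beyond it are zeroed.
#' @param crop `c(top, left, height, width)` window.
#' @param binarize_threshold mm, silhouette cut.
#' @param gradient_cap mm per pixel step.
#' @return A list of class `camera_preprocess`.
#' @export
camera_preprocess <- function(distance_threshold, crop, binarize_threshold,
                              gradient_cap) {
  stopifnot(distance_threshold > 0, binarize_threshold > 0, gradient_cap > 0,
            length(crop) == 4L, all(crop >= 1))
  structure(list(distance_threshold = distance_threshold,
                 crop = as.integer(crop),
                 binarize_threshold = binarize_threshold,
                 gradient_cap = gradient_cap),
            class = "camera_preprocess")
}

#' @param sensor Sensor shape `c(rows, cols)` the crops are laid out for.
#' @rdname camera_preprocess
#' @export
default_preprocess_config <- function(sensor = c(424L, 512L)) {
  # Scale the full-raster layout to other sensor sizes.
  sy <- sensor[1] / 424; sx <- sensor[2] / 512
  win <- function(top, left, h, w) {
    c(max(1L, round(top * sy)), max(1L, round(left * sx)),
      round(h * sy), round(w * sx))
  }
  list(
    ANGLED = camera_preprocess(3000, win(68, 140, 224, 224), 2700, 100),
    REAR = camera_preprocess(2900, win(79, 185, 224, 144), 2600, 100),
    TOP = camera_preprocess(2600, win(142, 160, 144, 304), 2200, 100)
  )
}

#' Build the three-channel CNN input stack
#'
#' Applies the full per-camera pre-processing chain: distance limiting,
#' cropping, then the three channel transforms -- normalised depth
#' (divided by the distance threshold, hence in [0, 1]), binary silhouette,
#' and capped first derivative (computed on raw millimetres). Planes are
#' stacked in that order.
#'
#' @param frame A [depth_frame()].
#' @param config A [camera_preprocess()] (or a per-camera list keyed by
#'   view, from which the frame's camera entry is taken).
#' @return An `H x W x 3` numeric array of class `channel_stack` with the
#'   camera attached as an attribute.
#' @export
build_channel_stack <- function(frame, config) {
  stopifnot(inherits(frame, "depth_frame"))
  if (!inherits(config, "camera_preprocess")) {
    config <- config[[attr(frame, "camera")]]
  }
  stopifnot(inherits(config, "camera_preprocess"))
  limited <- distance_limit(frame, config$distance_threshold)
  cropped <- crop_frame(limited, config$crop)
  stack <- array(0, c(nrow(cropped), ncol(cropped), 3L))
  stack[, , 1L] <- frame_values(cropped) / config$distance_threshold
  stack[, , 2L] <- binarize(cropped, config$binarize_threshold)
  stack[, , 3L] <- depth_derivative(cropped, config$gradient_cap)
  structure(stack, camera = attr(frame, "camera"),
            frame_id = attr(frame, "frame_id"),
            class = c("channel_stack", "array"))
}
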