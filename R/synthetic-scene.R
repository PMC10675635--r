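#' Map a BCS score to bone prominence
#'
#' The learnable depth signal of body condition is surface angularity:
#' an under-conditioned cow's hook bones, pin bones, tail head and spinous
#' processes protrude, while an over-conditioned cow is rounded. The
#' generator encodes this as a bump amplitude (millimetres of outward
#' displacement at the bone landmarks) that decreases linearly in the score:
#' `amplitude = 70 - 36 * (score - 1.75)` mm, i.e. 70 mm at BCS 1.75 down to
#' 7 mm at BCS 3.50. The map is strictly decreasing, which is the only
#' property downstream stages rely on.
#'
#' @param score BCS score(s) on the grid.
#' @return Bone bump amplitude(s) in millimetres.
#' @export
bone_amplitude_mm <- function(score) {
  70 - 36 * (score - 1.75)
}

#' Cow shape parameters
#'
#' Everything that determines one synthetic cow's back surface: its BCS
#' label (which sets [bone_amplitude_mm()] unless overridden), an overall
#' body scale, and a seed for the cow-specific shape jitter.
#'
#' @param bcs BCS score on the grid.
#' @param body_scale Overall size multiplier (1 = a 1.7 m long adult).
#' @param bone_amplitude Bump amplitude in mm; default derived from `bcs`.
#' @param seed Integer seed making the surface deterministic.
#' @return A list of class `cow_shape_params`.
#' @export
cow_shape_params <- function(bcs, body_scale = 1, bone_amplitude = NULL,
                             seed = 1L) {
  bcs_to_class(bcs)  # validates the label
  if (is.null(bone_amplitude)) bone_amplitude <- bone_amplitude_mm(bcs)
  stopifnot(body_scale > 0, bone_amplitude >= 0)
  structure(list(bcs = bcs, body_scale = body_scale,
                 bone_amplitude = bone_amplitude, seed = as.integer(seed)),
            class = "cow_shape_params")
}

# Evaluate all RNG inside a local stream so callers' RNG state is untouched.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a cow back surface
#'
#' The body is the upper part of an ellipsoid (semi-axes 0.33, 0.85 and
#' 0.38 m at `body_scale = 1`, back line 1.43 m above the floor), sampled as
#' a 3-D point cloud. Bone prominence is added as Gaussian bumps in the
#' surface parameter space at the landmark sites used in manual scoring --
#' two hook bones, two pin bones, the tail head and a row of spinous
#' processes along the spine -- displacing the surface outward along its
#' normal by `bone_amplitude` millimetres (scaled by a small seeded
#' per-landmark jitter). With `bone_amplitude = 0` the surface is exactly
#' the smooth ellipsoid patch.
#'
#' The tail is at world `y = -0.85 * body_scale`, the head end at positive
#' `y`; `x` is lateral and `z` height above the floor.
#'
#' @param params A [cow_shape_params()].
#' @param spacing Approximate sample spacing in metres (controls density).
#' @return A numeric matrix (n x 3) of world coordinates in metres, class
#'   `cow_surface`, with `params` attached as an attribute.
#' @export
generate_cow_surface <- function(params, spacing = 0.012) {
  stopifnot(inherits(params, "cow_shape_params"))
  s <- params$body_scale
  ax <- 0.33 * s; ay <- 0.85 * s; az <- 0.38 * s
  cz <- 1.05 * s
  n_u <- max(40L, ceiling(2.4 * ay / spacing))
  n_phi <- max(30L, ceiling(1.9 * az / spacing))
  u <- seq(-0.98, 0.98, length.out = n_u)          # tail -> head
  phi <- seq(-pi / 5, pi + pi / 5, length.out = n_phi)  # upper body + flanks
  U <- rep(u, times = n_phi)
  PHI <- rep(phi, each = n_u)
  r <- sqrt(pmax(0, 1 - U^2))
  x <- ax * r * cos(PHI)
  y <- ay * U
  z <- cz + az * r * sin(PHI)

  # outward unit normal of the ellipsoid at each sample
  nx <- x / ax^2; ny <- y / ay^2; nz <- (z - cz) / az^2
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  nx <- nx / nn; ny <- ny / nn; nz <- nz / nn

  A <- params$bone_amplitude
  if (A > 0) {
    landmarks <- rbind(
      c(-0.55, pi / 2 + 0.55, 0.09, 0.24, 1.0),   # hook, left
      c(-0.55, pi / 2 - 0.55, 0.09, 0.24, 1.0),   # hook, right
      c(-0.85, pi / 2 + 0.35, 0.07, 0.20, 0.9),   # pin, left
      c(-0.85, pi / 2 - 0.35, 0.07, 0.20, 0.9),   # pin, right
      c(-0.93, pi / 2, 0.06, 0.26, 0.9)           # tail head
    )
    spine_u <- seq(-0.70, 0.55, by = 0.16)        # spinous processes
    landmarks <- rbind(landmarks,
                       cbind(spine_u, pi / 2, 0.05, 0.13, 0.8),
                       # sunken loin: broad depressions either side of the
                       # spine give thin cows their angular cross-section
                       c(-0.35, pi / 2 + 0.30, 0.45, 0.16, -0.7),
                       c(-0.35, pi / 2 - 0.30, 0.45, 0.16, -0.7))
    disp <- with_local_seed(params$seed, {
      gain <- pmax(0.5, 1 + 0.08 * stats::rnorm(nrow(landmarks)))
      d <- numeric(length(U))
      for (k in seq_len(nrow(landmarks))) {
        lm <- landmarks[k, ]
        d <- d + lm[5] * gain[k] *
          exp(-((U - lm[1])^2 / (2 * lm[3]^2) +
                  (PHI - lm[2])^2 / (2 * lm[4]^2)))
      }
      # low-frequency flesh unevenness, also proportional to prominence
      ph <- stats::runif(3, 0, 2 * pi)
      d + 0.08 * (sin(3 * pi * U + ph[1]) * sin(2 * PHI + ph[2]) +
                    0.5 * cos(5 * pi * U + ph[3]))
    })
    off <- (A / 1000) * disp
    x <- x + off * nx; y <- y + off * ny; z <- z + off * nz
  }
  structure(cbind(x = x, y = y, z = z),
            params = params, class = c("cow_surface", "matrix", "array"))
}

#' Camera pose
#'
#' An orthographic camera defined by its world position, unit forward
#' (optical axis) vector and unit image-right vector; image-down is their
#' cross product. Depth is the forward-axis distance in millimetres.
#'
#' @param view Camera view token.
#' @param position Numeric length-3 world position (metres).
#' @param forward,right Numeric length-3 direction vectors (normalised
#'   internally; must be orthogonal).
#' @param near,far Usable range limits in millimetres (default 500-4500).
#' @return A list of class `camera_pose`.
#' @export
camera_pose <- function(view, position, forward, right,
                        near = 500, far = 4500) {
  view <- match_camera(view)
  nrm <- function(v) v / sqrt(sum(v^2))
  forward <- nrm(forward); right <- nrm(right)
  if (abs(sum(forward * right)) > 1e-6) {
    stop("camera forward and right vectors must be orthogonal", call. = FALSE)
  }
  if (!(near >= 500 - 1e-9 && near < far && far <= 4500 + 1e-9)) {
    stop("camera clip range must satisfy 500 <= near < far <= 4500 mm",
         call. = FALSE)
  }
  down <- c(forward[2] * right[3] - forward[3] * right[2],
            forward[3] * right[1] - forward[1] * right[3],
            forward[1] * right[2] - forward[2] * right[1])
  structure(list(view = view, position = as.numeric(position),
                 forward = forward, right = right, down = down,
                 near = near, far = far),
            class = "camera_pose")
}

#' Default camera poses over the crush
#'
#' Plausible placements of the three cameras: top-down from 3 m above the
#' floor, a rear view from 3 m behind the cow mounted high and tilted
#' slightly down at the rump, and a 45 degree angled view of the rear
#' quarter. All are overridable.
#'
#' @return Named list of [camera_pose()] objects (`ANGLED`, `REAR`, `TOP`).
#' @export
default_camera_poses <- function() {
  list(
    ANGLED = camera_pose("ANGLED", position = c(0, -2.5, 2.8),
                         forward = c(0, 1, -1), right = c(1, 0, 0)),
    REAR = camera_pose("REAR", position = c(0, -3.0, 1.6),
                       forward = c(0, 1, -0.15), right = c(1, 0, 0)),
    TOP = camera_pose("TOP", position = c(0, -0.2, 3.0),
                      forward = c(0, 0, -1), right = c(0, 1, 0))
  )
}

#' Scene configuration
#'
#' Sensor raster, pixel pitch, depth noise, background geometry and the
#' dataset-level sampling rules (class mix and frames per cow).
#'
#' The default class probabilities are proportional to the per-class
#' training-sample counts of a commercial Holstein herd
#' (320, 452, 1196, 1468, 2516, 1780, 368, 112 over BCS 1.75-3.50),
#' reproducing the mid-scale concentration at 2.50-3.00 that the
#' cost-sensitive training stage has to correct.
#'
#' @param sensor Integer (rows, cols); default the 424 x 512 raster of a
#'   Kinect-v2-class sensor.
#' @param pixel_pitch Metres per pixel of the orthographic raster; default
#'   scales with sensor width so the ~3.6 m scene always fits.
#' @param noise_sd Depth noise standard deviation in mm (default 5).
#' @param class_probs Length-8 class probability vector (normalised).
#' @param frames_per_cow Integer range `c(min, max)` of frames captured per
#'   cow and camera (default 3-7; capture runs are later capped at 7).
#' @param background Render floor, crush bars and back wall (default TRUE).
#' @param near_clip,far_clip Sensor range limits in mm.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(sensor = c(424L, 512L), pixel_pitch = NULL,
                         noise_sd = 5, class_probs = NULL,
                         frames_per_cow = c(3L, 7L), background = TRUE,
                         near_clip = 500, far_clip = 4500) {
  sensor <- as.integer(sensor)
  stopifnot(length(sensor) == 2L, all(sensor > 0L))
  if (is.null(pixel_pitch)) pixel_pitch <- 3.584 / sensor[2]
  if (is.null(class_probs)) {
    class_probs <- c(320, 452, 1196, 1468, 2516, 1780, 368, 112)
  }
  if (length(class_probs) != length(bcs_grid()) || any(class_probs < 0) ||
      sum(class_probs) <= 0) {
    stop("class_probs must be 8 non-negative values with positive mass",
         call. = FALSE)
  }
  class_probs <- class_probs / sum(class_probs)
  frames_per_cow <- as.integer(frames_per_cow)
  stopifnot(length(frames_per_cow) == 2L, frames_per_cow[1] >= 1L,
            frames_per_cow[1] <= frames_per_cow[2])
  structure(list(sensor = sensor, pixel_pitch = pixel_pitch,
                 noise_sd = noise_sd, class_probs = class_probs,
                 frames_per_cow = frames_per_cow, background = background,
                 near_clip = near_clip, far_clip = far_clip),
            class = "scene_config")
}

# Static background geometry: pen floor, crush bars, and a back wall.
# World-space points, camera-independent, so callers can build it once.
background_points <- function(config) {
  sp <- max(0.008, min(0.03, config$pixel_pitch * 0.75))
  floor_xy <- expand.grid(x = seq(-1.9, 1.9, by = sp),
                          y = seq(-2.9, 2.1, by = sp))
  floor_pts <- cbind(floor_xy$x, floor_xy$y, 0)
  wall_xz <- expand.grid(x = seq(-1.9, 1.9, by = sp * 1.5),
                         z = seq(0, 2.6, by = sp * 1.5))
  wall_pts <- cbind(wall_xz$x, 2.2, wall_xz$z)
  bar <- function(p0, p1, radius = 0.03) {
    len <- sqrt(sum((p1 - p0)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / (sp / 2))))
    ang <- seq(0, 2 * pi, length.out = 9L)[-9L]
    axis <- (p1 - p0) / len
    ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- c(axis[2] * ref[3] - axis[3] * ref[2],
           axis[3] * ref[1] - axis[1] * ref[3],
           axis[1] * ref[2] - axis[2] * ref[1])
    u <- u / sqrt(sum(u^2))
    v <- c(axis[2] * u[3] - axis[3] * u[2],
           axis[3] * u[1] - axis[1] * u[3],
           axis[1] * u[2] - axis[2] * u[1])
    core <- cbind(p0[1] + t * (p1[1] - p0[1]),
                  p0[2] + t * (p1[2] - p0[2]),
                  p0[3] + t * (p1[3] - p0[3]))
    do.call(rbind, lapply(ang, function(a) {
      off <- radius * (cos(a) * u + sin(a) * v)
      sweep(core, 2L, -off)
    }))
  }
  bars <- list()
  for (side in c(-0.55, 0.55)) {
    for (yb in seq(-1.3, 1.1, by = 0.6)) {
      bars[[length(bars) + 1L]] <- bar(c(side, yb, 0), c(side, yb, 1.75))
    }
    for (zb in c(0.95, 1.75)) {
      bars[[length(bars) + 1L]] <- bar(c(side, -1.3, zb), c(side, 1.1, zb))
    }
  }
  rbind(floor_pts, wall_pts, do.call(rbind, bars))
}

#' Render a depth frame
#'
#' Orthographic z-buffer rendering: every scene point is projected onto the
#' sensor raster along the camera's forward axis; each covered pixel keeps
#' the nearest range, integer-quantised millimetres. Pixels with no
#' geometry along the ray are 0 (no-data). Ranges beyond the far clip are
#' kept at their true value (clamped at 65535); removing them is the
#' distance-limiting pre-processing stage's job, as with a real sensor.
#' Gaussian noise of sd `noise_sd` mm is added to covered pixels and
#' re-quantised, truncated at 0.
#'
#' @param surface A `cow_surface` or any n x 3 point matrix (world metres).
#' @param pose A [camera_pose()].
#' @param config A [scene_config()].
#' @param background Optional precomputed [background_points()] matrix; if
#'   `NULL` and `config$background` is TRUE it is built on the fly.
#' @param seed Optional seed for the noise draw (local RNG stream).
#' @param frame_id Identifier for the resulting frame.
#' @return A [depth_frame()] of the configured sensor shape.
#' @export
render_depth <- function(surface, pose, config, background = NULL,
                         seed = NULL, frame_id = "") {
  stopifnot(inherits(pose, "camera_pose"), inherits(config, "scene_config"))
  pts <- unclass(surface)
  stopifnot(is.matrix(pts), ncol(pts) == 3L)
  H <- config$sensor[1]; W <- config$sensor[2]
  pitch <- config$pixel_pitch

  project <- function(p) {
    rel <- cbind(p[, 1] - pose$position[1], p[, 2] - pose$position[2],
                 p[, 3] - pose$position[3])
    list(col = round(rel %*% pose$right / pitch + (W + 1) / 2),
         row = round(rel %*% pose$down / pitch + (H + 1) / 2),
         depth = (rel %*% pose$forward) * 1000)
  }

  pr <- project(pts)
  vis <- pr$row >= 1 & pr$row <= H & pr$col >= 1 & pr$col <= W &
    pr$depth >= pose$near
  if (!any(vis)) {
    stop("surface entirely outside the camera frustum (", pose$view, ")",
         call. = FALSE)
  }
  row <- pr$row[vis]; col <- pr$col[vis]; depth <- pr$depth[vis]
  if (isTRUE(config$background) || !is.null(background)) {
    if (is.null(background)) background <- background_points(config)
    pb <- project(background)
    keep <- pb$row >= 1 & pb$row <= H & pb$col >= 1 & pb$col <= W &
      pb$depth >= pose$near
    row <- c(row, pb$row[keep]); col <- c(col, pb$col[keep])
    depth <- c(depth, pb$depth[keep])
  }
  z <- matrix(0, H, W)
  ord <- order(depth, decreasing = TRUE)  # nearest point wins each pixel
  z[cbind(row[ord], col[ord])] <- depth[ord]
  covered <- z > 0
  if (config$noise_sd > 0) {
    z[covered] <- with_local_seed(seed, {
      z[covered] + stats::rnorm(sum(covered), sd = config$noise_sd)
    })
  }
  z <- round(z)
  z[covered] <- pmin(pmax(z[covered], 0), 65535)
  depth_frame(z, camera = pose$view, frame_id = frame_id)
}

#' Generate a labelled multi-camera synthetic dataset
#'
#' Draws `n_cows` cows (BCS class from `config$class_probs`, body scale
#' ~ N(1, 0.05) truncated to [0.9, 1.1], a per-cow shape seed), renders
#' `frames_per_cow` frames per camera with per-frame pose jitter (lateral
#' and longitudinal shifts, sd 30/50 mm; yaw, sd 3 degrees), writes the
#' frames under `dir/frames/` and the manifest to `dir/manifest.csv`. The
#' whole dataset, manifest bytes included, is a pure function of
#' `(config, seed)`.
#'
#' @param n_cows Number of cows (>= 1).
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param poses Named list of [camera_pose()]s (default
#'   [default_camera_poses()]).
#' @param cameras Camera subset to render (default all three).
#' @return The manifest `data.frame` (also saved to `dir/manifest.csv`),
#'   with attribute `dir`.
#' @export
generate_dataset <- function(n_cows, config = scene_config(), seed = 1L,
                             dir = tempfile("bcs_scene_"),
                             poses = default_camera_poses(),
                             cameras = CAMERA_VIEWS) {
  stopifnot(n_cows >= 1L)
  cameras <- match_camera(cameras)
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  grid <- bcs_grid()
  bg <- if (isTRUE(config$background)) background_points(config) else NULL
  spacing <- max(0.006, min(0.025, config$pixel_pitch * 0.8))
  rot_z <- function(p, ang) {
    c_ <- cos(ang); s_ <- sin(ang)
    cbind(c_ * p[, 1] - s_ * p[, 2], s_ * p[, 1] + c_ * p[, 2], p[, 3])
  }
  recs <- vector("list", n_cows)
  with_local_seed(seed, {
    for (i in seq_len(n_cows)) {
      cow_id <- sprintf("cow%04d", i)
      cls <- sample.int(length(grid), 1L, prob = config$class_probs) - 1L
      score <- grid[cls + 1L]
      scale <- min(1.08, max(0.92, 1 + 0.04 * stats::rnorm(1)))
      cow_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      params <- cow_shape_params(score, body_scale = scale, seed = cow_seed)
      surf <- generate_cow_surface(params, spacing = spacing)
      nf_range <- seq(config$frames_per_cow[1], config$frames_per_cow[2])
      nf <- if (length(nf_range) == 1L) nf_range else sample(nf_range, 1L)
      rows <- vector("list", nf * length(cameras))
      k <- 0L
      for (f in seq_len(nf)) {
        dx <- 0.03 * stats::rnorm(1); dy <- 0.05 * stats::rnorm(1)
        yaw <- 3 * pi / 180 * stats::rnorm(1)
        pts <- rot_z(unclass(surf), yaw)
        pts[, 1] <- pts[, 1] + dx; pts[, 2] <- pts[, 2] + dy
        noise_seeds <- sample.int(.Machine$integer.max - 1L, length(cameras))
        for (ci in seq_along(cameras)) {
          cam <- cameras[ci]
          fid <- sprintf("%s_%s_f%02d", cow_id, cam, f)
          frame <- render_depth(pts, poses[[cam]], config, background = bg,
                                seed = noise_seeds[ci], frame_id = fid)
          ref <- file.path("frames", paste0(fid, ".tif"))
          write_depth_frame(frame, file.path(dir, ref))
          k <- k + 1L
          rows[[k]] <- data.frame(cow_id = cow_id, camera = cam,
                                  frame_ref = ref, bcs = score,
                                  split = "UNASSIGNED",
                                  stringsAsFactors = FALSE)
        }
      }
      recs[[i]] <- do.call(rbind, rows)
    }
  })
  index <- validate_manifest(do.call(rbind, recs))
  save_manifest(index, file.path(dir, "manifest.csv"))
  attr(index, "dir") <- dir
  index
}
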