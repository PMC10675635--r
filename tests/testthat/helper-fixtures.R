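# Shared fixtures: everything is generated in code at test time.

# A deterministic integer ramp frame.
ramp_frame <- function(nr = 4L, nc = 4L, camera = "TOP") {
  depth_frame(matrix(seq_len(nr * nc) - 1L, nr, nc, byrow = TRUE), camera)
}

# A small valid manifest: n_cows cows, frames frames per cow and camera.
toy_manifest <- function(n_cows = 5L, frames = 3L, cameras = CAMERA_VIEWS,
                         bcs = NULL, split = "UNASSIGNED") {
  grid <- bcs_grid()
  if (is.null(bcs)) bcs <- grid[(seq_len(n_cows) - 1L) %% 8L + 1L]
  rows <- expand.grid(frame = seq_len(frames), camera = cameras,
                      cow = seq_len(n_cows), stringsAsFactors = FALSE)
  data.frame(cow_id = sprintf("cow%03d", rows$cow),
             camera = rows$camera,
             frame_ref = sprintf("frames/cow%03d_%s_f%02d.tif",
                                 rows$cow, rows$camera, rows$frame),
             bcs = bcs[rows$cow],
             split = split,
             stringsAsFactors = FALSE)
}

# Tiny scene settings used by rendering and pipeline tests: a 53 x 64
# raster (56 mm pixel pitch) keeps renders to a few milliseconds.
tiny_scene_config <- function(...) {
  scene_config(sensor = c(53L, 64L), frames_per_cow = c(2L, 2L), ...)
}

tiny_run_config <- function(n_cows = 6L, seed = 5L, epochs = 2L,
                            data_dir = tempfile("tiny_data_"),
                            out_dir = tempfile("tiny_out_")) {
  load_run_config(list(
    seed = seed,
    paths = list(data = data_dir, out = out_dir),
    scene = list(n_cows = n_cows, sensor = c(53L, 64L), noise_sd = 5,
                 frames_per_cow = c(2L, 2L)),
    preprocess = list(
      ANGLED = list(distance_threshold = 3000, crop = c(14, 25, 16, 16),
                    binarize_threshold = 2700, gradient_cap = 400),
      REAR = list(distance_threshold = 2900, crop = c(19, 25, 16, 16),
                  binarize_threshold = 2600, gradient_cap = 400),
      TOP = list(distance_threshold = 2600, crop = c(19, 21, 16, 16),
                 binarize_threshold = 2200, gradient_cap = 400)
    ),
    split = list(test_fraction = 0.3, cap = 7, stratify = FALSE),
    model = list(fusion = "LATE", cameras = CAMERA_VIEWS),
    train = list(epochs = epochs, batch_size = 16)
  ))
}

# Linearly separable two-class toy stacks: class 0 bright top-left block,
# class 1 bright bottom-right block, 8x8x3 inputs.
toy_separable_set <- function(n_per_class = 24L, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  x <- array(stats::rnorm(8 * 8 * 3 * n, sd = 0.1), c(8, 8, 3, n))
  y <- rep(0:1, each = n_per_class)
  for (i in seq_len(n)) {
    if (y[i] == 0L) x[1:4, 1:4, 1, i] <- x[1:4, 1:4, 1, i] + 1
    else x[5:8, 5:8, 1, i] <- x[5:8, 5:8, 1, i] + 1
  }
  list(x = list(TOP = x), y = y)
}

# Random probability matrix with rows on the simplex.
random_simplex <- function(n, k = 8L) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}
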