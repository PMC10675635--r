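#' Camera views
#'
#' The three fixed camera placements around the crush: an angled view of the
#' rear quarter, a straight rear view, and the conventional top-down view.
#' Camera identity is carried everywhere as one of these upper-case tokens.
#'
#' @format Character vector of length 3: `"ANGLED"`, `"REAR"`, `"TOP"`.
#' @export
CAMERA_VIEWS <- c("ANGLED", "REAR", "TOP")

#' The body-condition-score class grid
#'
#' Scoring uses the five-point BCS scale in 0.25 increments; in practice a
#' milking herd occupies a narrow band of it, and all classification in this
#' package is over the eight levels 1.75 to 3.50. A custom grid (any
#' equally spaced 0.25-step score vector) may be supplied to the functions
#' that take a `grid` argument.
#'
#' @return Numeric vector of the eight scores 1.75, 2.00, ..., 3.50.
#' @export
#' @examples
#' bcs_grid()
bcs_grid <- function() {
  seq(1.75, 3.50, by = 0.25)
}

#' Convert between BCS scores and class indices
#'
#' Class indices are 0-based: `class_index = round((score - min(grid)) / 0.25)`.
#' The mapping is a bijection on the grid; off-grid scores are an error.
#'
#' @param score Numeric vector of BCS scores on the grid.
#' @param class_index Integer vector of 0-based class indices.
#' @param grid The score grid (default [bcs_grid()]).
#' @return `bcs_to_class()` returns integer indices in `0:(length(grid)-1)`;
#'   `class_to_bcs()` returns scores.
#' @export
#' @examples
#' bcs_to_class(c(1.75, 2.50, 3.50))
#' class_to_bcs(0:7)
bcs_to_class <- function(score, grid = bcs_grid()) {
  idx <- round((score - grid[1]) / 0.25)
  ok <- !is.na(score) & abs(score - (grid[1] + 0.25 * idx)) < 1e-8 &
    idx >= 0 & idx < length(grid)
  if (!all(ok)) {
    stop("BCS value(s) off the ", length(grid), "-level grid [",
         grid[1], ", ", grid[length(grid)], "]: ",
         paste(utils::head(score[!ok], 5L), collapse = ", "),
         call. = FALSE)
  }
  as.integer(idx)
}

#' @rdname bcs_to_class
#' @export
class_to_bcs <- function(class_index, grid = bcs_grid()) {
  ci <- as.integer(class_index)
  if (any(is.na(ci)) || any(ci < 0L | ci >= length(grid))) {
    stop("class_index out of range 0..", length(grid) - 1L, call. = FALSE)
  }
  grid[ci + 1L]
}

match_camera <- function(camera) {
  camera <- toupper(as.character(camera))
  bad <- !(camera %in% CAMERA_VIEWS)
  if (any(bad)) {
    stop("unknown camera view(s): ", paste(unique(camera[bad]), collapse = ", "),
         " (expected one of ", paste(CAMERA_VIEWS, collapse = ", "), ")",
         call. = FALSE)
  }
  camera
}
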