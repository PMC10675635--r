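#' Load or save a dataset manifest
#'
#' The manifest is the dataset index every pipeline stage consumes: one row
#' per captured frame with columns `cow_id`, `camera`, `frame_ref`, `bcs`
#' and `split` (and, after augmentation, `phase`). It is stored as a plain
#' comma-separated file with a fixed header. Validation enforces the data
#' model: BCS labels on the class grid, unique `(cow_id, camera, frame_ref)`
#' keys, and a single label and split per cow (the cow, not the frame, is
#' the unit of labelling and of splitting).
#'
#' @param path Manifest file path.
#' @param grid BCS score grid (default [bcs_grid()]).
#' @return `load_manifest()` returns a validated `data.frame`;
#'   `save_manifest()` returns `path` invisibly.
#' @export
load_manifest <- function(path, grid = bcs_grid()) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("cow_id", "camera", "frame_ref", "bcs", "split")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$bcs <- as.numeric(df$bcs)
  if ("phase" %in% names(df)) df$phase <- as.character(df$phase)
  validate_manifest(df, grid = grid)
}

#' @param index A manifest `data.frame` as returned by [load_manifest()] or
#'   [generate_dataset()].
#' @rdname load_manifest
#' @export
save_manifest <- function(index, path) {
  index <- validate_manifest(index)
  utils::write.csv(index, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a dataset manifest
#'
#' @inheritParams load_manifest
#' @return The manifest with `camera`/`split` normalised to upper case,
#'   ordered columns, or an error describing the first violation.
#' @export
validate_manifest <- function(index, grid = bcs_grid()) {
  stopifnot(is.data.frame(index))
  need <- c("cow_id", "camera", "frame_ref", "bcs", "split")
  miss <- setdiff(need, names(index))
  if (length(miss)) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  index$cow_id <- as.character(index$cow_id)
  index$frame_ref <- as.character(index$frame_ref)
  if (nrow(index) > 0L) {
    index$camera <- match_camera(index$camera)
    index$split <- toupper(as.character(index$split))
    bad_split <- !(index$split %in% c("TRAIN", "TEST", "UNASSIGNED"))
    if (any(bad_split)) {
      stop("invalid split token(s): ",
           paste(unique(index$split[bad_split]), collapse = ", "),
           call. = FALSE)
    }
    bcs_to_class(index$bcs, grid = grid)  # errors on off-grid labels
    key <- paste(index$cow_id, index$camera, index$frame_ref, sep = "\r")
    if ("phase" %in% names(index)) {
      key <- paste(key, index$phase, sep = "\r")
    }
    if (anyDuplicated(key)) {
      stop("duplicate manifest key (cow_id, camera, frame_ref): ",
           sub("\r", "/", key[duplicated(key)][1L]), call. = FALSE)
    }
    per_cow <- function(col) {
      tapply(index[[col]], index$cow_id, function(v) length(unique(v)))
    }
    if (any(per_cow("bcs") > 1L)) {
      stop("a cow carries more than one BCS label", call. = FALSE)
    }
    if (any(per_cow("split") > 1L)) {
      stop("a cow is assigned to more than one split", call. = FALSE)
    }
  } else {
    index$split <- as.character(index$split)
    index$camera <- as.character(index$camera)
  }
  cols <- c(need, intersect("phase", names(index)))
  index[, cols, drop = FALSE]
}
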