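#' Factor-2 phase sub-sampling augmentation
#'
#' Decimates an image by taking every second pixel across and every second
#' pixel down, starting at each of the four (row, column) phase offsets.
#' This yields four half-resolution images carrying slightly different
#' information; for an even-shaped input they interleave back to the
#' original exactly. Works plane-wise on a matrix or a 3-plane
#' [build_channel_stack()] array, so all four phase images of a stack share
#' one label.
#'
#' @param image A matrix or `H x W x C` array with `H >= 2`, `W >= 2`.
#' @return Named list of the four phase images (`p00`, `p01`, `p10`,
#'   `p11`), where `pqr` starts at row offset `q`, column offset `r`.
#' @export
subsample_phases <- function(image) {
  d <- dim(image)
  if (is.null(d) || d[1] < 2L || d[2] < 2L) {
    stop("phase sub-sampling needs at least a 2 x 2 image", call. = FALSE)
  }
  take <- function(p, q) {
    ri <- seq(1L + p, d[1], by = 2L)
    ci <- seq(1L + q, d[2], by = 2L)
    if (length(d) == 2L) image[ri, ci, drop = FALSE]
    else image[ri, ci, , drop = FALSE]
  }
  list(p00 = take(0L, 0L), p01 = take(0L, 1L),
       p10 = take(1L, 0L), p11 = take(1L, 1L))
}

#' Re-interleave four phase images
#'
#' Inverse of [subsample_phases()] for even-shaped originals; used as a
#' self-check of the augmentation.
#'
#' @param phases The list returned by [subsample_phases()].
#' @return The reconstructed image.
#' @export
interleave_phases <- function(phases) {
  d <- dim(phases$p00)
  H <- d[1] * 2L; W <- d[2] * 2L
  out <- if (length(d) == 2L) {
    matrix(0, H, W)
  } else {
    array(0, c(H, W, d[3]))
  }
  put <- function(out, img, p, q) {
    ri <- seq(1L + p, H, by = 2L); ci <- seq(1L + q, W, by = 2L)
    if (length(d) == 2L) out[ri, ci] <- img else out[ri, ci, ] <- img
    out
  }
  out <- put(out, phases$p00, 0L, 0L)
  out <- put(out, phases$p01, 0L, 1L)
  out <- put(out, phases$p10, 1L, 0L)
  put(out, phases$p11, 1L, 1L)
}

#' Cap the number of frames per cow and camera
#'
#' Capture runs yield anywhere from a couple to dozens of frames per cow;
#' to keep per-cow training influence comparable the count is capped
#' (default 7) per cow and camera. Frames are ordered by `frame_ref` (which
#' encodes capture order) and the temporally middle `cap` are retained, so
#' the rule is deterministic.
#'
#' @param index A manifest `data.frame`.
#' @param cap Maximum frames per (cow, camera) (>= 1).
#' @return The filtered manifest.
#' @export
limit_frames_per_cow <- function(index, cap = 7L) {
  index <- validate_manifest(index)
  stopifnot(cap >= 1L)
  if (nrow(index) == 0L) return(index)
  grp <- paste(index$cow_id, index$camera, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(index)), grp), function(rows) {
    rows <- rows[order(index$frame_ref[rows])]
    n <- length(rows)
    if (n <= cap) rows else rows[seq.int(floor((n - cap) / 2) + 1L,
                                         length.out = cap)]
  }), use.names = FALSE)
  index[sort(keep), , drop = FALSE]
}

#' Cow-level train/test split
#'
#' Splitting is performed on cows, never on frames: every frame of a cow
#' lands in the same partition, so no individual can leak across the
#' boundary. `round(test_fraction * n_cows)` cows are assigned to TEST
#' (per class when `stratify = TRUE`), the rest to TRAIN, deterministically
#' for a given seed.
#'
#' @param index A manifest `data.frame`.
#' @param test_fraction Fraction of cows held out (0 < f < 1); default 0.3
#'   for the conventional 70/30 split.
#' @param seed Integer seed.
#' @param stratify Balance the held-out share within each BCS class.
#' @return The manifest with `split` set to TRAIN/TEST.
#' @export
cow_level_split <- function(index, test_fraction = 0.3, seed = 1L,
                            stratify = FALSE) {
  index <- validate_manifest(index)
  stopifnot(test_fraction > 0, test_fraction < 1)
  cows <- unique(index$cow_id)
  if (length(cows) < 2L) {
    stop("cow-level split needs at least 2 cows", call. = FALSE)
  }
  test_cows <- with_local_seed(seed, {
    if (stratify) {
      cow_bcs <- index$bcs[match(cows, index$cow_id)]
      unlist(lapply(split(cows, cow_bcs), function(cc) {
        k <- round(test_fraction * length(cc))
        if (k > 0L) sample(cc, k) else character(0)
      }), use.names = FALSE)
    } else {
      sample(cows, round(test_fraction * length(cows)))
    }
  })
  index$split <- ifelse(index$cow_id %in% test_cows, "TEST", "TRAIN")
  index
}

#' Keep a single test frame per cow and camera
#'
#' During testing each cow contributes exactly one (pre-augmentation) frame
#' per camera, so a slow cow with dozens of near-identical frames cannot be
#' scored many times over. The retained frame is a seeded uniform draw per
#' (cow, camera). A test cow missing a camera entirely is dropped from that
#' camera's test set with a warning.
#'
#' @param index A manifest with splits assigned.
#' @param seed Integer seed.
#' @return The manifest with extra TEST frames removed (TRAIN untouched).
#' @export
select_test_frames <- function(index, seed = 1L) {
  index <- validate_manifest(index)
  test <- index$split == "TEST"
  if (!any(test)) return(index)
  ti <- which(test)
  grp <- paste(index$cow_id[ti], index$camera[ti], sep = "\r")
  keep <- with_local_seed(seed, {
    unlist(lapply(split(ti, grp), function(rows) {
      if (length(rows) == 1L) rows else sample(rows, 1L)
    }), use.names = FALSE)
  })
  test_cows <- unique(index$cow_id[ti])
  cams <- unique(index$camera)
  have <- table(index$cow_id[keep <- sort(keep)], index$camera[keep])
  miss <- length(test_cows) * length(cams) - sum(have > 0)
  if (miss > 0L) {
    warning(miss, " (test cow, camera) pair(s) have no frame; ",
            "those cows are absent from that camera's test set",
            call. = FALSE)
  }
  index[sort(c(which(index$split != "TEST"), keep)), , drop = FALSE]
}

#' Expand a manifest by the four sub-sampling phases
#'
#' Adds a `phase` column and one record per phase image for every frame,
#' multiplying the sample count by exactly 4.
#'
#' @param index A manifest `data.frame`.
#' @return The augmented manifest (4x the rows).
#' @export
augment_index <- function(index) {
  index <- validate_manifest(index)
  phases <- c("p00", "p01", "p10", "p11")
  out <- index[rep(seq_len(nrow(index)), each = length(phases)), ,
               drop = FALSE]
  out$phase <- rep(phases, times = nrow(index))
  rownames(out) <- NULL
  out
}
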