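#' Serpentine fold assignment balanced by MP-pixel count
#'
#' Images are sorted by increasing MP-pixel count (ties broken by id) and
#' dealt one by one over the test set and four cross-validation folds in the
#' repeating boustrophedon order
#' `test, CVF1, CVF2, CVF3, CVF4, CVF4, CVF3, CVF2, CVF1, test`, so that no
#' split accumulates systematically more MP pixels than the others.
#'
#' @param mp_pixel_counts Numeric vector of per-image MP-pixel counts.
#' @param ids Optional image identifiers (default: names or indices).
#' @return A data.frame (id, mp_pixels, split) with split levels
#'   `test, CVF1..CVF4`, in the original input order.
#' @examples
#' table(assign_folds(seq_len(99))$split)
#' @export
assign_folds <- function(mp_pixel_counts, ids = NULL) {
  n <- length(mp_pixel_counts)
  if (n < 1L) stopf("need at least one image")
  if (is.null(ids)) {
    ids <- if (!is.null(names(mp_pixel_counts))) names(mp_pixel_counts)
           else as.character(seq_len(n))
  }
  stopifnot(length(ids) == n, !anyDuplicated(ids))
  ord <- order(mp_pixel_counts, ids)
  cycle <- c("test", "CVF1", "CVF2", "CVF3", "CVF4",
             "CVF4", "CVF3", "CVF2", "CVF1", "test")
  split_sorted <- rep_len(cycle, n)
  split <- character(n)
  split[ord] <- split_sorted
  data.frame(id = ids, mp_pixels = mp_pixel_counts, split = split,
             stringsAsFactors = FALSE)
}

#' Sliding-window patch extraction
#'
#' Tiles an image (or mask) with `size x size` windows at the given stride,
#' zero-padding on the bottom/right so every pixel is covered. Window origins
#' are deterministic given shape, size and stride.
#'
#' @param x Matrix (intensity/mask/probability) or [mp_image()]; 3-channel
#'   arrays are tiled channel-wise.
#' @param size Patch side length in px (default 256).
#' @param stride Step between window origins, `1 <= stride <= size`.
#' @return List with `grid` (a `patch_grid`: patch_size, stride, origins
#'   0-based `(row, col)` matrix, padded_shape, original_shape) and
#'   `patches` (list of `size x size` matrices or `size x size x c` arrays).
#' @export
extract_patches <- function(x, size = 256L, stride = size) {
  if (inherits(x, "mp_image")) x <- x$pixels
  stopifnot(size >= 1, stride >= 1, stride <= size)
  d <- dim(x)
  h <- d[1]; w <- d[2]; nc <- if (length(d) == 3L) d[3] else 1L
  # window origins at every multiple of the stride below the image extent;
  # the canvas is zero-padded so the last windows fit
  starts <- function(extent) {
    as.integer(seq(0L, max(0L, extent - 1L), by = stride))
  }
  r0 <- starts(h); c0 <- starts(w)
  padded <- c(max(r0) + size, max(c0) + size)
  xp <- array(0, c(padded, nc))
  xp[seq_len(h), seq_len(w), ] <- x
  origins <- cbind(row = rep(r0, times = length(c0)),
                   col = rep(c0, each = length(r0)))
  patches <- lapply(seq_len(nrow(origins)), function(k) {
    p <- xp[origins[k, 1] + seq_len(size), origins[k, 2] + seq_len(size), ,
            drop = FALSE]
    if (nc == 1L) p <- p[, , 1L] else p
  })
  grid <- structure(list(patch_size = as.integer(size),
                         stride = as.integer(stride), origins = origins,
                         padded_shape = as.integer(padded),
                         original_shape = c(h, w)),
                    class = "patch_grid")
  list(grid = grid, patches = patches)
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d patches of %d px, stride %d, %d x %d padded to %d x %d\n",
              nrow(x$origins), x$patch_size, x$stride,
              x$original_shape[1], x$original_shape[2],
              x$padded_shape[1], x$padded_shape[2]))
  invisible(x)
}

#' Drop image/mask patch pairs whose mask contains no MP
#'
#' The oversampling strategy for class-imbalanced training: background-only
#' patches are removed so every training patch contains at least one MP
#' pixel.
#'
#' @param image_patches,mask_patches Equal-length lists of paired patches.
#' @return List with filtered `image_patches`, `mask_patches` and the
#'   logical `keep` vector.
#' @export
filter_empty_patches <- function(image_patches, mask_patches) {
  if (length(image_patches) != length(mask_patches)) {
    stopf("image and mask patch lists differ in length (%d vs %d)",
          length(image_patches), length(mask_patches))
  }
  keep <- vapply(mask_patches, function(m) sum(m) > 0, TRUE)
  list(image_patches = image_patches[keep],
       mask_patches = mask_patches[keep], keep = keep)
}

#' Randomly subsample MP-free patch pairs to a target ratio
#'
#' Dataset-balancing alternative to [filter_empty_patches()]: retains all
#' MP-containing pairs and a seeded random subset of MP-free pairs so that
#' empty patches make up at most `ratio` times the MP-containing count.
#'
#' @inheritParams filter_empty_patches
#' @param ratio Maximum empty:non-empty ratio to keep.
#' @param seed Integer seed for the subsampling.
#' @return As [filter_empty_patches()].
#' @export
subsample_empty_patches <- function(image_patches, mask_patches, ratio = 1,
                                    seed = 1L) {
  if (length(image_patches) != length(mask_patches)) {
    stopf("image and mask patch lists differ in length (%d vs %d)",
          length(image_patches), length(mask_patches))
  }
  nonempty <- vapply(mask_patches, function(m) sum(m) > 0, TRUE)
  empties <- which(!nonempty)
  n_keep <- min(length(empties), round(ratio * sum(nonempty)))
  kept_empty <- if (n_keep > 0) {
    with_seed(seed, sort(sample(empties, n_keep)))
  } else integer(0)
  keep <- nonempty
  keep[kept_empty] <- TRUE
  list(image_patches = image_patches[keep],
       mask_patches = mask_patches[keep], keep = keep)
}

#' Merge patch predictions back to full-image size
#'
#' Reassembles per-patch maps onto the padded canvas, averaging overlapping
#' windows pixel-wise, then crops to the original shape. With
#' `stride = size` this is the exact inverse of [extract_patches()].
#'
#' @param grid A `patch_grid` from [extract_patches()].
#' @param patches List of `size x size` numeric matrices (e.g. probability
#'   maps), one per grid origin.
#' @return Numeric matrix of the original image shape.
#' @export
merge_patches <- function(grid, patches) {
  stopifnot(inherits(grid, "patch_grid"))
  if (length(patches) != nrow(grid$origins)) {
    stopf("expected %d patches, got %d", nrow(grid$origins), length(patches))
  }
  size <- grid$patch_size
  acc <- matrix(0, grid$padded_shape[1], grid$padded_shape[2])
  cnt <- matrix(0, grid$padded_shape[1], grid$padded_shape[2])
  for (k in seq_along(patches)) {
    p <- patches[[k]]
    if (!all(dim(p)[1:2] == c(size, size))) {
      stopf("patch %d is not %d x %d", k, size, size)
    }
    ri <- grid$origins[k, 1] + seq_len(size)
    ci <- grid$origins[k, 2] + seq_len(size)
    acc[ri, ci] <- acc[ri, ci] + p
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  (acc / cnt)[seq_len(grid$original_shape[1]), seq_len(grid$original_shape[2]),
              drop = FALSE]
}
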