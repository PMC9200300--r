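#' Fluorescence image objects
#'
#' An `mp_image` holds an 8-bit RGB fluorescence microscopy raster together
#' with an optional physical scale. Pixels are stored as an integer array of
#' dimension `h x w x 3` (row-major semantics: first index is the image row,
#' origin at the top-left), values in `[0, 255]`.
#'
#' @param pixels Numeric or integer array `h x w x 3` (a plain `h x w` matrix
#'   is promoted to three identical channels), values in `[0, 255]`.
#' @param scale Optional micrometres-per-pixel factor (positive scalar).
#' @param id Sample identifier string.
#' @return An object of class `mp_image` with fields `pixels`, `scale`, `id`.
#' @examples
#' img <- mp_image(array(0L, c(4, 4, 3)), id = "blank")
#' dim(img$pixels)
#' @export
mp_image <- function(pixels, scale = NULL, id = "") {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stopf("pixels must be an h x w x 3 array (got dims: %s)",
          paste(dim(pixels), collapse = " x "))
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) stopf("image must be at least 1 x 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stopf("pixel values must lie in [0, 255] with no NAs")
  }
  storage.mode(pixels) <- "integer"
  if (!is.null(scale)) {
    if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
      stopf("scale must be a positive scalar (micrometres per pixel)")
    }
    scale <- as.numeric(scale)
  }
  structure(list(pixels = pixels, scale = scale, id = as.character(id)),
            class = "mp_image")
}

#' @export
print.mp_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<mp_image '%s'> %d x %d x %d, range [%d, %d]%s\n",
              x$id, d[1], d[2], d[3], min(x$pixels), max(x$pixels),
              if (is.null(x$scale)) "" else sprintf(", %.4g um/px", x$scale)))
  invisible(x)
}

#' Binary MP mask constructor
#'
#' Masks use the internal convention foreground (MP) = 1, background = 0,
#' stored as an integer matrix. The 255/0 or black-on-white encodings seen in
#' mask files are serialization polarities handled by [read_mask()] /
#' [write_mask()].
#'
#' @param m Matrix with values in \{0, 1\} (logical matrices accepted).
#' @return Integer matrix of class `mp_mask`.
#' @export
mp_mask <- function(m) {
  if (!is.matrix(m)) stopf("mask must be a matrix")
  if (is.logical(m)) m <- m * 1L
  if (anyNA(m) || !all(m %in% c(0L, 1L))) stopf("mask values must be 0 or 1")
  storage.mode(m) <- "integer"
  class(m) <- c("mp_mask", "matrix", "array")
  m
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "mp_mask")) return(unclass(mask))
  m <- mask
  if (is.logical(m)) m <- m * 1L
  if (!is.matrix(m) || anyNA(m) || !all(m %in% c(0L, 1L))) {
    stopf("expected a binary 0/1 mask matrix")
  }
  storage.mode(m) <- "integer"
  m
}

#' @export
print.mp_mask <- function(x, ...) {
  cat(sprintf("<mp_mask> %d x %d, %d foreground px\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

# ---- raster <-> file helpers --------------------------------------------

# png/tiff/jpeg readers return arrays in [0,1], dim h x w (x c)
decode_raster <- function(path, rescale_16bit = FALSE) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stopf("unsupported image format '%s' for %s", ext, path)
  )
  if (ext %in% c("tif", "tiff")) {
    # readTIFF(as.is = TRUE) yields raw integer sample values
    if (max(raw) > 255) {
      if (!rescale_16bit) {
        stopf("%s has > 8-bit depth; pass rescale_16bit = TRUE to max-normalize", path)
      }
      raw <- raw / max(raw) # max-normalization onto [0, 1]
    } else {
      raw <- raw / 255
    }
  }
  round(raw * 255)
}

#' Read a fluorescence image
#'
#' Reads an 8-bit PNG, TIFF or JPEG image. Grayscale files are promoted to
#' three identical channels; an alpha channel, if present, is dropped.
#' 16-bit TIFFs are accepted only with `rescale_16bit = TRUE`, in which case
#' values are max-normalized onto `[0, 255]`.
#'
#' @param path Image file path.
#' @param scale Optional micrometres-per-pixel factor to attach.
#' @param id Sample identifier; defaults to the file name without extension.
#' @param rescale_16bit Allow reading deeper-than-8-bit TIFFs by rescaling.
#' @return An [mp_image()].
#' @export
read_image <- function(path, scale = NULL, id = NULL,
                       rescale_16bit = FALSE) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  raw <- decode_raster(path, rescale_16bit)
  if (is.matrix(raw)) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  if (dim(raw)[3] == 2L) raw <- array(rep(raw[, , 1L], 3L), c(dim(raw)[1:2], 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  mp_image(raw, scale = scale, id = id)
}

#' Write an 8-bit image or intensity raster to PNG
#'
#' @param image An [mp_image()] or a single-channel integer matrix in
#'   `[0, 255]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "mp_image")) image$pixels else image
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Read / write binary masks with explicit polarity
#'
#' Mask files are single-channel 8-bit PNGs. Two serialization polarities are
#' in common use: `"mp_white"` stores MP (foreground) as 255 on black, while
#' `"mp_black"` stores MP as 0 on white (the display convention of published
#' mask figures). Internally foreground is always 1.
#'
#' @param mask A binary mask (see [mp_mask()]).
#' @param path PNG file path.
#' @param polarity `"mp_white"` or `"mp_black"`.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns an
#'   [mp_mask()].
#' @export
write_mask <- function(mask, path, polarity = c("mp_white", "mp_black")) {
  polarity <- match.arg(polarity)
  m <- as_mask_matrix(mask)
  px <- if (polarity == "mp_white") m * 255L else (1L - m) * 255L
  png::writePNG(px / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, polarity = c("mp_white", "mp_black")) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) stopf("mask file not found: %s", path)
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  m <- (raw > 0.5) * 1L
  if (polarity == "mp_black") m <- 1L - m
  mp_mask(m)
}

# ---- channel reduction ---------------------------------------------------

#' Convert an RGB image to a grayscale intensity image
#'
#' Standard luminance weighting of the R, G, B channels (ITU-R BT.601
#' weights 0.299/0.587/0.114 by default, the convention of the ImageJ-style
#' tooling that classical MP pipelines run on), rounded to 8-bit.
#'
#' @param image An [mp_image()].
#' @param weights Length-3 non-negative luma weights summing to 1.
#' @return Integer `h x w` matrix with values in `[0, 255]`.
#' @export
to_gray <- function(image, weights = c(0.299, 0.587, 0.114)) {
  stopifnot(inherits(image, "mp_image"))
  if (length(weights) != 3L || any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stopf("weights must be 3 non-negative values summing to 1")
  }
  px <- image$pixels
  g <- round(weights[1] * px[, , 1] + weights[2] * px[, , 2] + weights[3] * px[, , 3])
  dim(g) <- dim(px)[1:2]
  storage.mode(g) <- "integer"
  g
}

#' Extract the red channel of an RGB image
#'
#' Nile-red fluorescence carries most of its signal in the red channel;
#' red-channel extraction is the channel-reduction step of the Renyi-entropy
#' thresholding pipeline.
#'
#' @param image An [mp_image()].
#' @return Integer `h x w` matrix (channel 1, copied unchanged).
#' @export
red_channel <- function(image) {
  stopifnot(inherits(image, "mp_image"))
  r <- image$pixels[, , 1L]
  dim(r) <- dim(image$pixels)[1:2]
  storage.mode(r) <- "integer"
  r
}

#' 256-bin intensity histogram
#'
#' @param intensity Integer matrix with values in `[0, 255]`.
#' @return A list of class `mp_histogram` with `counts` (256 integers, bin k
#'   holds the number of pixels with value k-1) and `q` (normalized
#'   frequencies summing to 1).
#' @export
intensity_histogram <- function(intensity) {
  v <- as.vector(intensity)
  if (length(v) == 0L) stopf("cannot histogram an empty raster")
  if (anyNA(v) || min(v) < 0 || max(v) > 255) stopf("intensity values must lie in [0, 255]")
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  structure(list(counts = counts, q = counts / sum(counts)),
            class = "mp_histogram")
}

#' @export
print.mp_histogram <- function(x, ...) {
  occ <- which(x$counts > 0)
  cat(sprintf("<mp_histogram> %d px, %d occupied bins, range [%d, %d]\n",
              sum(x$counts), length(occ), min(occ) - 1L, max(occ) - 1L))
  invisible(x)
}
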