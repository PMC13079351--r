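#' Load a microscopy image as a single-channel integer matrix
#'
#' Reads TIFF, PNG or JPEG into a `[y, x]` integer matrix of raw sample
#' values (0..255 or 0..65535) plus its bit depth. Fluorescence nuclei
#' images are DAPI single-channel; when an RGB image is supplied (e.g. a
#' camera export), one channel is selected by `channel_policy` — the blue
#' channel by default, where the DAPI emission lands.
#'
#' @param path image file; format inferred from the extension.
#' @param channel_policy for RGB inputs: `"blue"`, `"green"`, `"red"` or
#'   `"luminance"` (0.299 R + 0.587 G + 0.114 B, rounded).
#' @return integer matrix with attribute `bit_depth` (8 or 16).
#' @export
load_image <- function(path, channel_policy = c("blue", "green", "red",
                                                "luminance")) {
  channel_policy <- match.arg(channel_policy)
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    depth <- attr(arr, "bits.per.sample") %||% 8L
  } else if (ext == "png") {
    arr <- png::readPNG(path)
    depth <- if (any(abs(arr * 255 - round(arr * 255)) > 1e-9)) 16L else 8L
    arr <- round(arr * (2^depth - 1))
  } else if (ext %in% c("jpg", "jpeg")) {
    arr <- round(jpeg::readJPEG(path) * 255)
    depth <- 8L
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim(arr)) == 3) {
    ch <- switch(channel_policy,
                 red = arr[, , 1], green = arr[, , 2], blue = arr[, , 3],
                 luminance = round(0.299 * arr[, , 1] + 0.587 * arr[, , 2] +
                                     0.114 * arr[, , 3]))
  } else {
    ch <- arr
  }
  m <- matrix(as.integer(ch), nrow(ch), ncol(ch))
  attr(m, "bit_depth") <- as.integer(depth)
  m
}

#' Convert a 16-bit image to 8 bits
#'
#' Full-range linear mapping `v8 = round(v16 / 257)` with half-up rounding,
#' so 0 maps to 0 and 65535 to 255. The mapping is monotone and identical
#' for every image, keeping intensities comparable across a dataset; a
#' per-image min–max stretch is available via `stretch = TRUE` but is not
#' the default precisely because it destroys that comparability.
#'
#' @param image16 integer matrix of 16-bit sample values.
#' @param stretch if `TRUE`, min–max stretch to 0..255 instead of the fixed
#'   linear mapping.
#' @return integer matrix with `bit_depth` 8.
#' @export
convert_16_to_8 <- function(image16, stretch = FALSE) {
  if (any(image16 < 0 | image16 > 65535)) {
    stop("values outside the 16-bit range", call. = FALSE)
  }
  v <- if (stretch) {
    rng <- range(image16)
    if (rng[2] == rng[1]) image16 * 0 else
      floor((image16 - rng[1]) / (rng[2] - rng[1]) * 255 + 0.5)
  } else {
    floor(image16 / 257 + 0.5)
  }
  out <- matrix(as.integer(v), nrow(image16), ncol(image16))
  attr(out, "bit_depth") <- 8L
  out
}

#' Write an 8-bit grayscale image
#'
#' Convenience writer used by the synthetic-scene generator and the
#' pipeline; TIFF or PNG depending on the extension.
#'
#' @param image integer matrix, values 0..255.
#' @param path output path (`.tiff`/`.tif` or `.png`).
#' @export
write_image8 <- function(image, path) {
  x <- pmax(pmin(image, 255L), 0L) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(x, path)
  } else stop("unsupported output format: ", path, call. = FALSE)
  invisible(path)
}
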