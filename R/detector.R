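## Registry of detector backends. A backend is any function
## f(tile_image) -> detections tibble (tile frame) honouring the contract:
## scores in [0, 1], masks inside the tile extent, deterministic for a
## fixed input unless declared otherwise. Trained-network adapters plug in
## here; the package ships a reference thresholding detector.
.backends <- new.env(parent = emptyenv())

#' Detector backend registry
#'
#' `register_backend()` installs a detection function under a name;
#' `get_backend()` retrieves it; `list_backends()` names all registered
#' ones. Each backend pairs with a recommended score threshold
#' (`default_score_threshold`), because a confidence cut-off is an
#' operating point of a specific detector: 0.98 suits a trained instance
#' segmentation network, while the reference thresholding detector is
#' calibrated at 0.5.
#'
#' @param name backend name, e.g. `"toy-threshold"`.
#' @param detect function `(tile image) -> detections tibble` (tile frame).
#' @param version version string of the backend.
#' @param default_score_threshold recommended score cut-off for this
#'   backend.
#' @return `get_backend()` returns a list with `detect`, `name`, `version`,
#'   `default_score_threshold`.
#' @export
register_backend <- function(name, detect, version = "0",
                             default_score_threshold = 0.98) {
  stopifnot(is.function(detect))
  assign(name, list(detect = detect, name = name, version = version,
                    default_score_threshold = default_score_threshold),
         envir = .backends)
  invisible(name)
}

#' @rdname register_backend
#' @export
get_backend <- function(name) {
  if (!exists(name, envir = .backends)) {
    stop("unknown detector backend: '", name, "' (registered: ",
         paste(list_backends(), collapse = ", "), ")", call. = FALSE)
  }
  get(name, envir = .backends)
}

#' @rdname register_backend
#' @export
list_backends <- function() ls(.backends)

#' Reference thresholding detector
#'
#' A deterministic, training-free detector used to exercise the tiling,
#' fusion and analysis stages: Otsu-threshold the tile, label connected
#' components, drop components smaller than `min_area`, and score each
#' component by how far its mean intensity sits above the threshold:
#' `score = min(0.5 + 0.5 * (mean - thr) / (max - thr), 1)`. A uniform tile
#' yields zero detections. Registered at load time as `"toy-threshold"`.
#'
#' @param tile integer/numeric matrix `[y, x]`, a grayscale tile.
#' @param min_area minimum component area in px^2 (default 30).
#' @return detections tibble in the tile frame.
#' @export
toy_detector <- function(tile, min_area = 30) {
  v <- as.numeric(tile)
  if (max(v) == min(v)) return(empty_detections("tile"))
  thr <- otsu_threshold(v)
  fg <- matrix(tile > thr, nrow(tile), ncol(tile))
  if (!any(fg)) return(empty_detections("tile"))
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- matrix(as.integer(lab), nrow(tile), ncol(tile))
  mx <- max(v)
  rows <- list()
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    area <- sum(comp)
    if (area < min_area) next
    mean_int <- mean(tile[comp])
    score <- if (mx > thr) min(0.5 + 0.5 * (mean_int - thr) / (mx - thr), 1) else 0.5
    rows[[length(rows) + 1L]] <- detection_row(
      instance_mask(comp), score = max(score, 0),
      id = length(rows) + 1L, frame = "tile")
  }
  detections(rows)
}

## Otsu's threshold on a 256-bin histogram over the value range.
otsu_threshold <- function(v) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = 257)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), 256)
  p <- counts / sum(counts)
  centers <- (edges[-257] + edges[-1]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[256]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  centers[which.max(between)]
}
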