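#' COCO instance datasets
#'
#' The package stores annotations in the COCO JSON dialect that CVAT
#' imports: polygon segmentations as flat `[x1, y1, x2, y2, ...]` lists,
#' boxes as `[x, y, width, height]`, and a single category `"nucleus"`.
#' In memory a dataset is a list of three tibbles (`images`, `annotations`,
#' `categories`) of class `"coco_dataset"`.
#'
#' @param images tibble with `id`, `file_name`, `width`, `height`.
#' @param annotations tibble with `id`, `image_id`, `segmentation`
#'   (list-column of polygon lists), `bbox` (list-column of `[x, y, w, h]`),
#'   `area`, `category_id`, optionally `score`.
#' @param categories tibble with `id`, `name`; defaults to the single
#'   "nucleus" category.
#' @return a `"coco_dataset"` object.
#' @export
coco_dataset <- function(images = NULL, annotations = NULL,
                         categories = NULL) {
  if (is.null(images) || nrow(images) == 0) {
    images <- tibble::tibble(id = integer(), file_name = character(),
                             width = integer(), height = integer())
  }
  if (is.null(annotations) || nrow(annotations) == 0) {
    annotations <- tibble::tibble(
      id = integer(), image_id = integer(), segmentation = list(),
      bbox = list(), area = numeric(), category_id = integer(),
      iscrowd = integer())
  }
  if (!"iscrowd" %in% names(annotations)) annotations$iscrowd <- 0L
  if (is.null(categories)) {
    categories <- tibble::tibble(id = 1L, name = "nucleus")
  }
  bad <- setdiff(annotations$image_id, images$id)
  if (length(bad) > 0) {
    stop("annotation(s) reference missing image id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(images = images, annotations = annotations,
                 categories = categories),
            class = "coco_dataset")
}

#' @export
print.coco_dataset <- function(x, ...) {
  cat("<coco_dataset> ", nrow(x$images), " image(s), ",
      nrow(x$annotations), " annotation(s), category: ",
      paste(x$categories$name, collapse = ", "), "\n", sep = "")
  invisible(x)
}

## Build one COCO annotation row from a global-frame instance mask.
mask_to_annotation <- function(m, id, image_id, score = NULL) {
  polys <- mask_to_polygons(m)
  out <- tibble::tibble(
    id = as.integer(id), image_id = as.integer(image_id),
    segmentation = list(lapply(polys, function(p) as.numeric(t(p)))),
    bbox = list(c(m$x0, m$y0, ncol(m$px), nrow(m$px))),
    area = as.numeric(sum(m$px)),
    category_id = 1L, iscrowd = 0L)
  if (!is.null(score)) out$score <- score
  out
}

#' Convert between detections tibbles and COCO datasets
#'
#' `detections_to_coco()` exports a global-frame detections tibble for one
#' image as a COCO dataset (masks become polygon segmentations).
#' `coco_to_detections()` rasterizes the annotations of one image back into
#' a detections tibble.
#'
#' @param dets global-frame detections tibble.
#' @param file_name,width,height the image entry the detections belong to.
#' @param image_id image id to use (default 1).
#' @return a `"coco_dataset"` / a detections tibble.
#' @export
detections_to_coco <- function(dets, file_name, width, height, image_id = 1L) {
  imgs <- tibble::tibble(id = as.integer(image_id), file_name = file_name,
                         width = as.integer(width), height = as.integer(height))
  anns <- purrr::map(seq_len(nrow(dets)), function(i) {
    mask_to_annotation(det_mask(dets, i), id = dets$id[i],
                       image_id = image_id, score = dets$score[i])
  })
  coco_dataset(images = imgs, annotations = dplyr::bind_rows(anns))
}

#' @rdname detections_to_coco
#' @param ds a `"coco_dataset"`.
#' @export
coco_to_detections <- function(ds, image_id = NULL) {
  if (is.null(image_id)) {
    if (nrow(ds$images) != 1) stop("specify image_id for multi-image datasets",
                                   call. = FALSE)
    image_id <- ds$images$id[1]
  }
  im <- ds$images[ds$images$id == image_id, ]
  if (nrow(im) == 0) stop("no image with id ", image_id, call. = FALSE)
  anns <- dplyr::filter(ds$annotations, .data$image_id == !!image_id)
  rows <- purrr::map(seq_len(nrow(anns)), function(i) {
    m <- polygons_to_mask(anns$segmentation[[i]], im$width, im$height)
    detection_row(m,
                  score = if ("score" %in% names(anns)) anns$score[i] else 1,
                  id = anns$id[i], frame = "global")
  })
  detections(rows)
}

#' Read / write COCO JSON
#'
#' Lossless round trip of ids, polygon vertices, boxes and areas. Only
#' polygon segmentations are supported; an RLE-encoded annotation raises an
#' error naming its id.
#'
#' @param path JSON file path.
#' @return `read_coco()` returns a `"coco_dataset"`; `write_coco()` its
#'   input, invisibly.
#' @export
read_coco <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  imgs <- dplyr::bind_rows(lapply(raw$images, function(im) {
    tibble::tibble(id = as.integer(im$id), file_name = im$file_name,
                   width = as.integer(im$width), height = as.integer(im$height))
  }))
  anns <- dplyr::bind_rows(lapply(raw$annotations, function(a) {
    seg <- a$segmentation
    if (!is.null(seg$counts) || !is.list(seg)) {
      stop("annotation ", a$id, ": RLE segmentations are not supported",
           call. = FALSE)
    }
    out <- tibble::tibble(
      id = as.integer(a$id), image_id = as.integer(a$image_id),
      segmentation = list(lapply(seg, function(p) as.numeric(unlist(p)))),
      bbox = list(as.numeric(unlist(a$bbox))),
      area = as.numeric(a$area),
      category_id = as.integer(a$category_id),
      iscrowd = as.integer(a$iscrowd %||% 0L))
    if (!is.null(a$score)) out$score <- as.numeric(a$score)
    out
  }))
  cats <- dplyr::bind_rows(lapply(raw$categories, function(ct) {
    tibble::tibble(id = as.integer(ct$id), name = ct$name)
  }))
  if (is.null(cats) || nrow(cats) == 0) cats <- NULL
  coco_dataset(images = imgs, annotations = anns, categories = cats)
}

#' @rdname read_coco
#' @param ds a `"coco_dataset"`.
#' @export
write_coco <- function(ds, path) {
  anns <- lapply(seq_len(nrow(ds$annotations)), function(i) {
    a <- ds$annotations[i, ]
    rec <- list(id = a$id, image_id = a$image_id,
                segmentation = lapply(a$segmentation[[1]], identity),
                bbox = a$bbox[[1]], area = a$area,
                category_id = a$category_id, iscrowd = a$iscrowd)
    if ("score" %in% names(ds$annotations)) rec$score <- a$score
    rec
  })
  imgs <- lapply(seq_len(nrow(ds$images)), function(i) as.list(ds$images[i, ]))
  cats <- lapply(seq_len(nrow(ds$categories)), function(i) as.list(ds$categories[i, ]))
  jsonlite::write_json(list(images = imgs, annotations = anns, categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(ds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
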