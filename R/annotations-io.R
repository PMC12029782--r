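## File formats: YOLO-seg polygon label txt (one object per line,
## `class_id x1 y1 x2 y2 ...`, normalized coordinates, optional confidence
## token after the class id for prediction files) and COCO-segmentation
## JSON. Class ids are fixed: 0 = BAC, 1 = AS.

.default_class_map <- c("0" = "BAC", "1" = "AS")

#' Read YOLO-seg polygon labels
#'
#' Each non-empty line holds an integer class id, optionally a confidence in
#' `[0, 1]` (prediction dialect; a confidence token is identified by an even
#' remaining coordinate count), then `>= 6` normalized coordinates in
#' `x y x y ...` order. Missing confidence reads as 1.
#'
#' @param path label file path.
#' @param class_map named character vector mapping class-id strings to class
#'   labels; defaults to `0 = BAC, 1 = AS`.
#' @return an annotation tibble.
#' @export
read_yolo_seg <- function(path, class_map = .default_class_map) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(annotation_tbl())
  cls <- character(length(lines))
  conf <- numeric(length(lines))
  verts <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (anyNA(vals)) abort(sprintf("line %d: non-numeric token.", i))
    id <- as.character(as.integer(vals[1]))
    if (!id %in% names(class_map)) {
      abort(sprintf("line %d: unknown class id %s.", i, id))
    }
    rest <- vals[-1]
    ## odd count => leading confidence token, even remainder of coordinates
    if (length(rest) %% 2L == 1L) {
      conf[i] <- rest[1]
      rest <- rest[-1]
    } else {
      conf[i] <- 1
    }
    if (length(rest) < 6L) {
      abort(sprintf("line %d: a polygon needs >= 3 vertices.", i))
    }
    if (conf[i] < 0 || conf[i] > 1) {
      abort(sprintf("line %d: confidence outside [0, 1].", i))
    }
    if (any(rest < 0) || any(rest > 1)) {
      abort(sprintf("line %d: coordinates outside [0, 1].", i))
    }
    verts[[i]] <- matrix(rest, ncol = 2, byrow = TRUE,
                         dimnames = list(NULL, c("x", "y")))
    cls[i] <- class_map[[id]]
  }
  annotation_tbl(class = cls, vertices = verts, confidence = conf)
}

#' Write YOLO-seg polygon labels
#'
#' Inverse of [read_yolo_seg()]. Coordinates use fixed 6-decimal formatting
#' for stable diffs; a confidence token is emitted only when `< 1`.
#'
#' @param annotations an annotation tibble.
#' @param path output file path.
#' @param class_map named character vector as in [read_yolo_seg()].
#' @return `path`, invisibly.
#' @export
write_yolo_seg <- function(annotations, path,
                           class_map = .default_class_map) {
  inv <- setNames(names(class_map), class_map)
  lines <- purrr::pmap_chr(annotations, function(class, confidence, vertices) {
    coords <- sprintf("%.6f", as.vector(t(vertices)))
    head_tok <- if (confidence < 1) {
      c(inv[[class]], sprintf("%.6f", confidence))
    } else inv[[class]]
    paste(c(head_tok, coords), collapse = " ")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Write a YOLO-style class map YAML
#'
#' @param path output path for the `data.yaml`-style class map.
#' @param class_map named character vector (id string -> label).
#' @return `path`, invisibly.
#' @export
write_class_map <- function(path, class_map = .default_class_map) {
  yaml::write_yaml(list(names = as.list(setNames(as.character(class_map),
                                                 names(class_map))),
                        nc = length(class_map)), path)
  invisible(path)
}

#' Read COCO-segmentation polygon annotations
#'
#' Supports polygon segmentations only (RLE is rejected). Absolute
#' coordinates are normalized by the referenced image entry's
#' width / height; category names must map onto `BAC` / `AS`.
#'
#' @param path COCO JSON file path.
#' @return an annotation tibble.
#' @export
read_coco_segmentation <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  imgs <- setNames(doc$images, vapply(doc$images, function(x)
    as.character(x$id), character(1)))
  cats <- setNames(vapply(doc$categories, function(x) x$name, character(1)),
                   vapply(doc$categories, function(x) as.character(x$id),
                          character(1)))
  if (!all(cats %in% .classes)) {
    abort(sprintf("COCO categories must be in {%s}; got: %s",
                  paste(.classes, collapse = ", "),
                  paste(setdiff(cats, .classes), collapse = ", ")))
  }
  cls <- character(); conf <- numeric(); verts <- list()
  for (ann in doc$annotations) {
    seg <- ann$segmentation
    if (!is.list(seg) || !length(seg) || !is.numeric(unlist(seg[[1]]))) {
      abort("RLE or non-polygon segmentations are not supported.")
    }
    im <- imgs[[as.character(ann$image_id)]]
    if (is.null(im)) abort(sprintf("annotation references unknown image id %s.",
                                   ann$image_id))
    for (ring in seg) {
      xy <- matrix(unlist(ring), ncol = 2, byrow = TRUE)
      v <- cbind(x = xy[, 1] / im$width, y = xy[, 2] / im$height)
      if (any(v < 0) || any(v > 1)) {
        abort("COCO polygon coordinates fall outside the image extent.")
      }
      verts[[length(verts) + 1L]] <- v
      cls[length(cls) + 1L] <- cats[[as.character(ann$category_id)]]
      conf[length(conf) + 1L] <- if (!is.null(ann$score)) ann$score else 1
    }
  }
  annotation_tbl(class = cls, vertices = verts, confidence = conf)
}

#' Split item identifiers into train and test sets
#'
#' Shuffles with the seed, then takes the first
#' `floor(n * train_fraction)` items for training (the floor rule: 8 items
#' at 0.75 give 6 train / 2 test). Deterministic per seed; changing the seed
#' permutes membership but never the counts.
#'
#' @param item_ids character or integer vector of at least one identifier.
#' @param train_fraction fraction in `(0, 1]`; default 0.75.
#' @param seed integer seed for the shuffle.
#' @return a list with `train` and `test` identifier vectors.
#' @export
split_dataset <- function(item_ids, train_fraction = 0.75, seed = 1L) {
  if (!length(item_ids)) abort("`item_ids` must contain at least one item.")
  check_scalar_number(train_fraction, "train_fraction", min = 0, max = 1,
                      strict_min = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  shuffled <- sample(item_ids)
  n_train <- floor(length(item_ids) * train_fraction)
  list(train = shuffled[seq_len(n_train)],
       test = if (n_train < length(item_ids)) {
         shuffled[(n_train + 1L):length(item_ids)]
       } else item_ids[0])
}
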