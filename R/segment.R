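## Segmentation stage: either import external model predictions
## (read_yolo_seg / read_coco_segmentation) or run the classical reference
## segmenter below; both yield the same annotation-tibble currency, to which
## the confidence filter and polygon -> mask conversion apply.

#' Filter annotations by confidence
#'
#' Keeps annotations with `confidence >= threshold` (inclusive boundary);
#' order is preserved. Idempotent and monotone in the threshold. The default
#' 0.30 balances sensitivity against false detections when importing model
#' predictions.
#'
#' @param annotations an annotation tibble.
#' @param threshold confidence threshold in `[0, 1]`.
#' @return the filtered annotation tibble.
#' @export
filter_by_confidence <- function(annotations, threshold = 0.30) {
  check_scalar_number(threshold, "threshold", min = 0, max = 1)
  dplyr::filter(annotations, .data$confidence >= threshold)
}

#' Rasterize annotations to per-class binary masks
#'
#' Each polygon is rasterized at full image resolution under the
#' pixel-center rule of [rasterize_polygon()]. Degenerate polygons (fewer
#' than 3 distinct vertices) are skipped with a warning.
#'
#' @param annotations an annotation tibble.
#' @param shape integer `(rows, cols)` of the target image.
#' @return a named list with elements `BAC` and `AS`, each a list of
#'   logical masks (possibly empty).
#' @export
polygons_to_masks <- function(annotations, shape) {
  out <- list(BAC = list(), AS = list())
  for (i in seq_len(nrow(annotations))) {
    v <- annotations$vertices[[i]]
    if (nrow(unique(round(v, 12))) < 3L) {
      warn(sprintf("annotation %d: degenerate polygon skipped.", i))
      next
    }
    cls <- annotations$class[i]
    out[[cls]] <- c(out[[cls]], list(rasterize_polygon(v, shape)))
  }
  out
}

#' Classical reference segmentation of a plate image
#'
#' A trained-model-free stand-in segmenter for standardized single-dish
#' plate photographs. Pipeline: (1) locate the dish as the largest bright
#' connected region (Otsu threshold against the frame background, holes
#' filled); (2) inside the dish, classify pixel intensities into three
#' groups (colony-dark, agar, halo-bright) by 1-d k-means seeded at
#' intensity quantiles; (3) morphological opening removes speckle; (4) each
#' connected colony becomes one `BAC` annotation, and the `AS` annotation is
#' the TOTAL region: the surrounding halo component united with the enclosed
#' colony, holes filled. Reference-segmenter confidences are fixed at 1 (the
#' pipeline has no probabilistic head).
#'
#' @param image numeric matrix in `[0, 1]` (`[row, col]`).
#' @param min_object_px smallest object area kept, in pixels.
#' @param brush_size diameter of the disc brush for morphological cleanup.
#' @return a list with `annotations` (annotation tibble), `masks` (per-class
#'   lists of logical masks, `AS` aligned with `BAC` by colony pairing),
#'   `source = "reference"` and `shape`.
#' @export
segment_reference <- function(image, min_object_px = 50, brush_size = 7) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix.")
  }
  shape <- dim(image)
  ## 1. dish: bright vs frame background
  t_dish <- EBImage::otsu(EBImage::Image(t(image)))
  dish <- fill_holes(image > t_dish)
  dish <- largest_component(dish)
  if (sum(dish) < 0.05 * length(image)) {
    abort("no dish found: the bright circular region is too small.")
  }
  inside <- image[dish]

  empty_result <- function() {
    list(annotations = annotation_tbl(),
         masks = list(BAC = list(), AS = list()),
         source = "reference", shape = shape)
  }

  ## 2. three intensity groups within the dish, deterministic k-means
  centers <- matrix(quantile(inside, c(0.02, 0.5, 0.98)), ncol = 1)
  if (length(unique(centers[, 1])) < 3L) return(empty_result())  # flat dish
  km <- kmeans(matrix(inside, ncol = 1), centers = centers, iter.max = 50)
  ord <- order(km$centers[, 1])
  lvl <- match(km$cluster, ord)  # 1 = darkest, 3 = brightest
  colony_px <- halo_px <- matrix(FALSE, shape[1], shape[2])
  colony_px[dish] <- lvl == 1L
  halo_px[dish] <- lvl == 3L

  ## 3. cleanup
  brush <- EBImage::makeBrush(brush_size, shape = "disc")
  open_mask <- function(m) {
    t(EBImage::imageData(EBImage::opening(EBImage::Image(t(m)), brush)) > 0.5)
  }
  colony_px <- open_mask(colony_px)
  halo_px <- open_mask(halo_px)

  ## 4. instance colonies + paired total AS regions
  labm <- label_components(colony_px)
  sizes <- tabulate(labm)
  keep_ids <- which(sizes >= min_object_px)
  if (!length(keep_ids)) return(empty_result())
  halo_lab <- label_components(fill_holes(halo_px | colony_px))

  bac_masks <- as_masks <- list()
  for (id in keep_ids) {
    cm <- labm == id
    idx <- which(cm, arr.ind = TRUE)
    cen <- round(colMeans(idx))
    hid <- halo_lab[cen[1], cen[2]]
    total <- if (hid > 0) fill_holes(halo_lab == hid | cm) else cm
    bac_masks <- c(bac_masks, list(cm))
    as_masks <- c(as_masks, list(total))
  }
  polys <- c(lapply(bac_masks, mask_to_polygon),
             lapply(as_masks, mask_to_polygon))
  cls <- rep(c("BAC", "AS"), c(length(bac_masks), length(as_masks)))
  ok <- !vapply(polys, is.null, logical(1))
  ann <- annotation_tbl(class = cls[ok], vertices = polys[ok], confidence = 1)
  list(annotations = ann,
       masks = list(BAC = bac_masks, AS = as_masks),
       source = "reference", shape = shape)
}
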