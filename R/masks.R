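## Binary masks are plain logical matrices indexed mask[row, col], 0-based
## pixel coordinates in the continuous plane: pixel (r, c) has its center at
## point (x = c, y = r). All geometric membership rules are evaluated at
## pixel centers, consistently across synthesis, rasterization and
## quantification.

#' Rasterize a disk onto a binary mask
#'
#' A pixel is set iff the Euclidean distance from its center to `center` is
#' `<= radius` (inclusive). Coordinates are 0-based `(row, col)`.
#'
#' @param center numeric length-2, `(row, col)` of the disk center.
#' @param radius disk radius in pixels; must be `>= 0`.
#' @param shape integer length-2, `(rows, cols)` of the target raster.
#' @return logical matrix of dimension `shape`.
#' @export
#' @examples
#' sum(rasterize_disk(c(50, 50), 10, c(100, 100)))
rasterize_disk <- function(center, radius, shape) {
  check_scalar_number(radius, "radius", min = 0)
  stopifnot(length(center) == 2L, length(shape) == 2L, all(shape >= 1))
  dr <- (seq_len(shape[1]) - 1) - center[1]
  dc <- (seq_len(shape[2]) - 1) - center[2]
  outer(dr^2, dc^2, `+`) <= radius^2
}

#' Pixel area of a binary mask
#'
#' @param mask logical matrix.
#' @return integer count of set pixels.
#' @export
mask_area <- function(mask) {
  check_mask(mask)
  sum(mask)
}

#' Keep only the largest connected component of a mask
#'
#' Components use 8-connectivity. An empty mask is returned unchanged. Ties
#' are broken by lowest label (scan order), deterministically.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same shape.
#' @export
largest_component <- function(mask) {
  check_mask(mask)
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  counts <- tabulate(lab)
  lab == which.max(counts)
}

## 8-connected component labeling: 4-connected labels from EBImage::bwlabel,
## then labels touching diagonally are united (union-find over label ids)
label_components <- function(mask) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))   # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Intersection over union of two masks
#'
#' Returns `|a AND b| / |a OR b|`. Two empty masks have undefined overlap;
#' by convention 0 is returned with a warning.
#'
#' @param a,b logical matrices of identical shape.
#' @return a number in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  check_mask(a, "a")
  check_mask(b, "b")
  if (!identical(dim(a), dim(b))) abort("`a` and `b` must have the same shape.")
  un <- sum(a | b)
  if (un == 0L) {
    warn("IoU of two empty masks is undefined; returning 0.")
    return(0)
  }
  sum(a & b) / un
}

## fill interior holes (8-connectivity objects), via EBImage
fill_holes <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  t(EBImage::imageData(EBImage::fillHull(lab)) > 0)
}
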