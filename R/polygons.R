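## Polygon annotations are the label/prediction currency. They live in a
## tibble with one row per object:
##   class      "BAC" or "AS"
##   confidence in [0, 1]
##   vertices   list-column of n x 2 matrices, columns (x, y), normalized
##              to [0, 1] by image width / height (YOLO-seg dialect:
##              x = col / width, y = row / height, origin top-left)

#' Build an annotation tibble
#'
#' @param class character vector of class labels (`"BAC"` or `"AS"`).
#' @param vertices list of `n x 2` numeric matrices of normalized `(x, y)`
#'   vertices, one per object; each polygon needs at least 3 vertices with
#'   all coordinates in `[0, 1]`.
#' @param confidence numeric vector in `[0, 1]`, recycled; defaults to 1.
#' @return a tibble with columns `class`, `confidence`, `vertices`.
#' @export
annotation_tbl <- function(class = character(), vertices = list(),
                           confidence = 1) {
  if (length(class) != length(vertices)) {
    abort("`class` and `vertices` must have the same length.")
  }
  if (!all(class %in% .classes)) {
    abort(sprintf("`class` values must be one of: %s.",
                  paste(.classes, collapse = ", ")))
  }
  confidence <- rep_len(confidence, length(class))
  if (length(class) && (any(confidence < 0) || any(confidence > 1))) {
    abort("`confidence` must lie in [0, 1].")
  }
  vertices <- lapply(vertices, function(v) {
    v <- as.matrix(v)
    if (nrow(v) < 3L || ncol(v) != 2L) {
      abort("each polygon needs an n x 2 matrix with n >= 3.")
    }
    if (any(v < 0) || any(v > 1)) {
      abort("polygon coordinates must be normalized to [0, 1].")
    }
    colnames(v) <- c("x", "y")
    v
  })
  tibble(class = as.character(class), confidence = as.numeric(confidence),
         vertices = vertices)
}

#' Signed-area (shoelace) polygon area
#'
#' @param vertices an `n x 2` matrix of `(x, y)` vertices.
#' @return absolute polygon area in the units of the coordinates squared.
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  x <- v[, 1]; y <- v[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Rasterize a normalized polygon to a binary mask
#'
#' Scanline even-odd fill evaluated at pixel centers: pixel `(r, c)` is set
#' iff its center point `(x = c, y = r)` lies inside (or on the boundary of)
#' the polygon scaled to pixel units. Normalized vertex `(x, y)` maps to the
#' pixel-plane point `(x * (cols - 1), y * (rows - 1))`, the inverse of the
#' pixel-center normalization used by [mask_to_polygon()].
#'
#' @param vertices `n x 2` matrix of normalized `(x, y)` vertices.
#' @param shape integer `(rows, cols)` of the target raster.
#' @return logical matrix.
#' @export
rasterize_polygon <- function(vertices, shape) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L) abort("polygon needs at least 3 vertices.")
  rows <- shape[1]; cols <- shape[2]
  px <- v[, 1] * (cols - 1)
  py <- v[, 2] * (rows - 1)
  mask <- matrix(FALSE, rows, cols)
  n <- length(px)
  x1 <- px; y1 <- py
  x2 <- px[c(2:n, 1)]; y2 <- py[c(2:n, 1)]
  eps <- 1e-9
  r0 <- max(0L, floor(min(py)))
  r1 <- min(rows - 1L, ceiling(max(py)))
  if (r1 < r0) return(mask)
  for (r in r0:r1) {
    ## half-open edge rule in y: count edge if y1 <= r < y2 or y2 <= r < y1
    up <- (y1 <= r & y2 > r)
    dn <- (y2 <= r & y1 > r)
    hit <- up | dn
    if (!any(hit)) next
    xc <- x1[hit] + (r - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit])
    xc <- sort(xc)
    k <- length(xc)
    if (k %% 2L != 0L) next  # degenerate; skip row
    for (i in seq(1L, k, by = 2L)) {
      lo <- ceiling(xc[i] - eps)
      hi <- floor(xc[i + 1L] + eps)
      lo <- max(lo, 0L); hi <- min(hi, cols - 1L)
      if (hi >= lo) mask[r + 1L, (lo:hi) + 1L] <- TRUE
    }
  }
  mask
}

#' Trace the outer contour of a mask as a normalized polygon
#'
#' Uses the largest connected component's oriented boundary (pixel centers)
#' and normalizes by `(cols - 1)` / `(rows - 1)` so that
#' [rasterize_polygon()] inverts it. Contours are padded outward by half a
#' pixel along the local normal so re-rasterization keeps boundary pixels.
#'
#' @param mask logical matrix.
#' @return an `n x 2` matrix of normalized `(x, y)` vertices, or `NULL` for
#'   an empty mask.
#' @export
mask_to_polygon <- function(mask) {
  check_mask(mask)
  if (!any(mask)) return(NULL)
  mask <- largest_component(mask)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  counts <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which.max(counts)
  ## ocontour on Image(t(mask)) yields 0-based (x = our col, y = our row)
  ## pixel-center coordinates
  oc <- EBImage::ocontour(lab)[[keep]]
  xs <- oc[, 1]; ys <- oc[, 2]
  ## pad each contour point 0.5 px outward from the component centroid so
  ## boundary pixel centers stay inside the polygon after re-rasterization
  idx <- which(t(EBImage::imageData(lab) == keep), arr.ind = TRUE)
  cy <- mean(idx[, 1]) - 1; cx <- mean(idx[, 2]) - 1
  dx <- xs - cx; dy <- ys - cy
  nrm <- sqrt(dx^2 + dy^2)
  nrm[nrm == 0] <- 1
  xs <- xs + 0.5 * dx / nrm
  ys <- ys + 0.5 * dy / nrm
  rows <- nrow(mask); cols <- ncol(mask)
  v <- cbind(x = pmin(pmax(xs / (cols - 1), 0), 1),
             y = pmin(pmax(ys / (rows - 1), 0), 1))
  if (nrow(v) < 3L) return(NULL)
  v
}
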