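## Synthetic Petri-dish plates with exact ground truth. The generator
## emulates standardized top-down plate photographs: a square frame holding
## an 11 cm dish, dark colony disks each surrounded by a brighter clearing
## halo on mid-grey agar. Ground-truth masks are the noiseless geometry;
## noise and illumination affect the rendered image only.

#' Specify colonies for a synthetic plate
#'
#' @param center_row,center_col colony centers in 0-based pixel coordinates.
#' @param colony_radius_px colony disk radii (px).
#' @param halo_radius_px halo outer radii (px); must be `>=` the colony
#'   radius element-wise.
#' @return a tibble with one row per colony.
#' @export
colony_spec <- function(center_row, center_col, colony_radius_px,
                        halo_radius_px) {
  spec <- tibble(center_row = as.numeric(center_row),
                 center_col = as.numeric(center_col),
                 colony_radius_px = as.numeric(colony_radius_px),
                 halo_radius_px = as.numeric(halo_radius_px))
  if (any(spec$colony_radius_px <= 0)) abort("colony radii must be positive.")
  if (any(spec$halo_radius_px < spec$colony_radius_px)) {
    abort("`halo_radius_px` must be >= `colony_radius_px`.")
  }
  spec
}

#' Configuration for the synthetic plate generator
#'
#' Defaults mirror the standardized imaging setup the toolkit targets:
#' 1746 x 1746 px frames of an 11 cm dish, one colony of radius 65 px with
#' a 90 px halo (a colony area of ~13.3 thousand px, the magnitude typical
#' of the assay). Intensity ordering `colony < agar < halo`: the halo is a
#' clearing in opaque medium, the colony dense growth.
#'
#' @param image_size_px square image side (px), `>= 64`.
#' @param dish_diameter_cm physical dish diameter (cm).
#' @param dish_margin_px gap between dish rim and frame edge (px).
#' @param colonies a tibble from [colony_spec()]; may have zero rows.
#' @param background_level,agar_level,halo_level,colony_level intensities
#'   in `[0, 1]`.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param illumination_gradient multiplicative left-to-right slope in
#'   `[0, 0.3]` (0 = uniform illumination).
#' @param seed integer seed controlling the noise; generation is a pure
#'   function of the full configuration.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(image_size_px = 1746,
                         dish_diameter_cm = 11,
                         dish_margin_px = 40,
                         colonies = colony_spec(image_size_px / 2,
                                                image_size_px / 2, 65, 90),
                         background_level = 0.05,
                         agar_level = 0.45,
                         halo_level = 0.80,
                         colony_level = 0.15,
                         noise_sd = 0.01,
                         illumination_gradient = 0,
                         seed = 1L) {
  check_scalar_number(image_size_px, "image_size_px", min = 64)
  check_scalar_number(dish_diameter_cm, "dish_diameter_cm", min = 0,
                      strict_min = TRUE)
  check_scalar_number(dish_margin_px, "dish_margin_px", min = 0)
  for (nm in c("background_level", "agar_level", "halo_level",
               "colony_level")) {
    check_scalar_number(get(nm), nm, min = 0, max = 1)
  }
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  check_scalar_number(illumination_gradient, "illumination_gradient",
                      min = 0, max = 0.3)
  structure(list(image_size_px = as.integer(image_size_px),
                 dish_diameter_cm = dish_diameter_cm,
                 dish_margin_px = as.integer(dish_margin_px),
                 colonies = colonies,
                 background_level = background_level,
                 agar_level = agar_level,
                 halo_level = halo_level,
                 colony_level = colony_level,
                 noise_sd = noise_sd,
                 illumination_gradient = illumination_gradient,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic plate image with exact ground truth
#'
#' Composites background, dish disk at agar level, then per colony the halo
#' disk followed by the colony disk; applies the multiplicative illumination
#' gradient and additive Gaussian noise, clipping to `[0, 1]`. Ground-truth
#' masks are the noiseless rasterized disks; the `AS` (halo) mask of each
#' colony is the TOTAL halo-plus-colony disk, so the true efficiency
#' `(colony + halo) / colony` is always `>= 2`.
#'
#' @param cfg a [synth_config()].
#' @return a list with elements `image` (numeric matrix in `[0, 1]`),
#'   `truth` (list: `colony_masks`, `halo_masks`, `true_ef`, `dish_mask`)
#'   and `config`.
#' @export
generate_plate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$image_size_px
  ctr <- (n - 1) / 2
  dish_r <- n / 2 - cfg$dish_margin_px
  col_spec <- cfg$colonies
  if (nrow(col_spec)) {
    d <- sqrt((col_spec$center_row - ctr)^2 + (col_spec$center_col - ctr)^2)
    if (any(d + col_spec$halo_radius_px > dish_r)) {
      abort("every colony (including its halo) must lie inside the dish.")
    }
  }
  shape <- c(n, n)
  dish <- rasterize_disk(c(ctr, ctr), dish_r, shape)
  img <- matrix(cfg$background_level, n, n)
  img[dish] <- cfg$agar_level

  colony_masks <- halo_masks <- vector("list", nrow(col_spec))
  for (i in seq_len(nrow(col_spec))) {
    ctr_i <- c(col_spec$center_row[i], col_spec$center_col[i])
    halo <- rasterize_disk(ctr_i, col_spec$halo_radius_px[i], shape)
    colony <- rasterize_disk(ctr_i, col_spec$colony_radius_px[i], shape)
    img[halo] <- cfg$halo_level
    img[colony] <- cfg$colony_level
    colony_masks[[i]] <- colony
    halo_masks[[i]] <- halo   # total region: halo disk contains the colony
  }
  true_ef <- vapply(seq_len(nrow(col_spec)), function(i) {
    a <- sum(colony_masks[[i]]); b <- sum(halo_masks[[i]])
    (a + b) / a
  }, numeric(1))

  if (cfg$illumination_gradient > 0) {
    ramp <- 1 + cfg$illumination_gradient *
      ((seq_len(n) - 1) / (n - 1) - 0.5)
    img <- img * matrix(ramp, n, n, byrow = TRUE)
  }
  if (cfg$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(cfg$seed)
    img <- img + matrix(rnorm(n * n, sd = cfg$noise_sd), n, n)
  }
  img <- pmin(pmax(img, 0), 1)

  list(image = img,
       truth = list(colony_masks = colony_masks,
                    halo_masks = halo_masks,
                    true_ef = true_ef,
                    dish_mask = dish),
       config = cfg)
}

## save/restore global RNG state so generation is side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Convert synthetic ground truth to polygon annotations
#'
#' Traces every ground-truth mask's outer contour into a normalized polygon
#' (class `BAC` for colonies, `AS` for total halo regions), confidence 1.
#' Empty masks are skipped with a warning.
#'
#' @param truth the `truth` element returned by [generate_plate()].
#' @return an annotation tibble (see [annotation_tbl()]).
#' @export
ground_truth_to_annotations <- function(truth) {
  polys <- list(); cls <- character()
  add <- function(masks, label) {
    for (m in masks) {
      v <- mask_to_polygon(m)
      if (is.null(v)) {
        warn(sprintf("empty %s mask skipped during annotation export.", label))
        next
      }
      polys[[length(polys) + 1L]] <<- v
      cls[length(cls) + 1L] <<- label
    }
  }
  add(truth$colony_masks, "BAC")
  add(truth$halo_masks, "AS")
  annotation_tbl(class = cls, vertices = polys, confidence = 1)
}

#' Write a plate image as an 8-bit PNG
#'
#' @param image numeric matrix in `[0, 1]` (rows = image rows).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plate_png <- function(image, path) {
  EBImage::writeImage(EBImage::Image(t(image)), path, type = "png",
                      bits.per.sample = 8L)
  invisible(path)
}

#' Read a plate image from PNG/TIFF/JPEG
#'
#' Color images are converted to grayscale by channel averaging.
#'
#' @param path image file path.
#' @return numeric matrix in `[0, 1]`, indexed `[row, col]`.
#' @export
read_plate_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such image file: %s", path))
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) d <- apply(d, c(1, 2), mean)
  t(d)
}
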