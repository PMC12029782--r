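## Quantification: pixel areas, pixel -> cm calibration, equivalent
## diameters and the solubilization efficiency Ef = (A + B) / A. Two
## conventions coexist deliberately: Ef is defined on colony / halo
## diameters in the assay literature, but is equally computed on areas (the
## ratio is scale invariant, so pixel and cm^2 areas give identical Ef);
## the halo measure B is always the TOTAL halo-plus-colony region.

#' Integer pixels-per-centimeter calibration factor
#'
#' The conversion factor is the image width divided by the known dish
#' diameter, truncated to an integer (1746 px / 11 cm -> 158 px/cm).
#'
#' @param image_width_px image width in pixels.
#' @param dish_diameter_cm dish diameter in centimeters.
#' @return integer pixels per centimeter.
#' @export
#' @examples
#' pixels_per_cm(1746, 11) # 158
pixels_per_cm <- function(image_width_px, dish_diameter_cm) {
  check_scalar_number(image_width_px, "image_width_px", min = 0,
                      strict_min = TRUE)
  check_scalar_number(dish_diameter_cm, "dish_diameter_cm", min = 0,
                      strict_min = TRUE)
  as.integer(image_width_px / dish_diameter_cm)
}

#' Build a calibration record
#'
#' @inheritParams pixels_per_cm
#' @return a tibble row with `image_width_px`, `dish_diameter_cm`,
#'   `pixels_per_cm`.
#' @export
calibration <- function(image_width_px = 1746, dish_diameter_cm = 11) {
  tibble(image_width_px = image_width_px,
         dish_diameter_cm = dish_diameter_cm,
         pixels_per_cm = pixels_per_cm(image_width_px, dish_diameter_cm))
}

#' Equivalent circular diameter in centimeters
#'
#' Diameter of the circle with the same area as the region:
#' `2 * sqrt(area / pi) / pixels_per_cm`.
#'
#' @param area_px region area in pixels, `>= 0`.
#' @param pixels_per_cm integer calibration factor.
#' @return diameter in centimeters.
#' @export
equivalent_diameter_cm <- function(area_px, pixels_per_cm) {
  stopifnot(all(area_px >= 0), pixels_per_cm > 0)
  2 * sqrt(area_px / pi) / pixels_per_cm
}

#' Solubilization efficiency Ef = (A + B) / A
#'
#' `A` is the colony measure and `B` the halo measure in the same units
#' (diameters in cm, or areas in px or cm^2 — the ratio is dimensionless
#' and scale invariant). Reported rounded half-up to two decimals.
#'
#' @param A colony measure, `> 0`.
#' @param B halo measure, `>= 0`, same units as `A`.
#' @return Ef rounded to two decimals.
#' @export
#' @examples
#' solubilization_efficiency(1.6, 2.8)       # 2.75 (manual diameters, cm)
#' solubilization_efficiency(13329, 25571)   # 2.92 (pixel areas)
solubilization_efficiency <- function(A, B) {
  if (any(A <= 0)) abort("`A` (colony measure) must be positive.")
  if (any(B < 0)) abort("`B` (halo measure) must be non-negative.")
  round_half_up((A + B) / A, 2)
}

#' Relative difference in percent
#'
#' `|value - reference| / |reference| * 100`, used to compare automated Ef
#' against a manual reference measurement.
#'
#' @param value measured value.
#' @param reference nonzero reference value.
#' @return percent difference.
#' @export
relative_difference_pct <- function(value, reference) {
  if (any(reference == 0, na.rm = TRUE)) abort("`reference` must be nonzero.")
  abs(value - reference) / abs(reference) * 100
}

#' Measure one colony / halo mask pair
#'
#' Reduces each mask to its largest connected component, measures pixel
#' areas and equivalent diameters, and computes Ef in the requested mode:
#' `"area_px"` (pixel areas; the default), `"area_cm2"` (calibrated areas —
#' Ef is identical to pixel mode by scale invariance) or `"diameter_cm"`
#' (equivalent diameters).
#'
#' @param colony_mask,halo_mask logical matrices of the same shape; the
#'   halo mask is the TOTAL halo-plus-colony region.
#' @param cal a [calibration()] row.
#' @param mode one of `"area_px"`, `"area_cm2"`, `"diameter_cm"`.
#' @return a one-row tibble: measures `A` and `B` in the mode's units, `ef`,
#'   `mode`, pixel areas, equivalent diameters (cm) and the calibration
#'   factor.
#' @export
analyze_plate <- function(colony_mask, halo_mask, cal = calibration(),
                          mode = c("area_px", "area_cm2", "diameter_cm")) {
  mode <- match.arg(mode)
  check_mask(colony_mask, "colony_mask")
  check_mask(halo_mask, "halo_mask")
  if (!identical(dim(colony_mask), dim(halo_mask))) {
    abort("colony and halo masks must have the same shape.")
  }
  colony_mask <- largest_component(colony_mask)
  halo_mask <- largest_component(halo_mask)
  a_px <- mask_area(colony_mask)
  b_px <- mask_area(halo_mask)
  if (a_px == 0L) abort("no colony detected: the colony mask is empty.")
  ppc <- cal$pixels_per_cm
  d_a <- equivalent_diameter_cm(a_px, ppc)
  d_b <- equivalent_diameter_cm(b_px, ppc)
  ab <- switch(mode,
               area_px = c(a_px, b_px),
               area_cm2 = c(a_px, b_px) / ppc^2,
               diameter_cm = c(d_a, d_b))
  tibble(A = ab[1], B = ab[2],
         ef = solubilization_efficiency(ab[1], ab[2]),
         mode = mode,
         colony_area_px = a_px, halo_area_px = b_px,
         colony_equiv_diameter_cm = d_a, halo_equiv_diameter_cm = d_b,
         pixels_per_cm = ppc)
}
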