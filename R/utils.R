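## Reporting conventions: Ef is rounded half-up to 2 decimals; evaluation
## metrics are truncated (floored) to 2 decimals. Both need protection from
## floating-point representation (e.g. 0.56 stored as 0.5599...).

#' Round half-up to a fixed number of decimals
#'
#' Unlike [round()], which rounds half to even, this rounds ties away from
#' zero (for positive input), the convention used when reporting the
#' solubilization efficiency.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
#' @examples
#' round_half_up(2.915, 2) # 2.92
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Truncate to a fixed number of decimals
#'
#' Floors towards zero at `digits` decimals; the reporting convention for
#' precision, recall, F1 and accuracy (0.529... reports as 0.52).
#'
#' @inheritParams round_half_up
#' @return numeric vector.
#' @export
truncate_decimals <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 1e-9) / p
}

## internal argument checks -------------------------------------------------

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %s.", name, format(min)))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be >= %s.", name, format(min)))
  }
  if (x > max) abort(sprintf("`%s` must be <= %s.", name, format(max)))
  invisible(x)
}

check_mask <- function(x, name = "mask") {
  if (!is.matrix(x) || !is.logical(x)) {
    abort(sprintf("`%s` must be a logical matrix (binary mask).", name))
  }
  invisible(x)
}
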