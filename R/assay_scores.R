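# Closed-form laboratory scores: T7E1 indel percentage from cleavage-band
# intensities, immunohistochemistry product score, and ellipsoid xenograft
# tumor volume.

#' T7E1 indel percentage from cleavage-band intensities
#'
#' Estimates editing efficiency from a T7 endonuclease I assay as
#' `100 * (1 - sqrt(1 - (b + c) / (a + b + c)))`, where `a` is the
#' integrated intensity of the undigested PCR product and `b`, `c` the
#' intensities of the two cleavage products. The square root accounts for
#' heteroduplex formation between edited and unedited strands. Vectorized.
#'
#' @param a Intensity of the undigested product (>= 0).
#' @param b,c Intensities of the two cleavage products (>= 0).
#' @return Indel percentage in \[0, 100\].
#' @export
indel_percent <- function(a, b, c) {
  if (any(a < 0 | b < 0 | c < 0)) abort("band intensities must be >= 0.")
  tot <- a + b + c
  if (any(tot == 0)) abort("at least one band intensity must be positive.")
  100 * (1 - sqrt(1 - (b + c) / tot))
}

#' Immunohistochemistry product score
#'
#' Overall staining score: staining intensity on the ordinal scale
#' (none = 1, weak = 2, moderate = 3, strong = 4) multiplied by the fraction
#' of stained cells (percentage / 100). Range \[0, 4\]. Vectorized.
#'
#' @param intensity Staining intensity in `{1, 2, 3, 4}`.
#' @param percentage Staining percentage in \[0, 100\].
#' @return Product score.
#' @export
ihc_product_score <- function(intensity, percentage) {
  if (any(!intensity %in% 1:4)) {
    abort("staining intensity must be one of 1, 2, 3, 4.")
  }
  if (any(percentage < 0 | percentage > 100)) {
    abort("staining percentage must lie in [0, 100].")
  }
  intensity * percentage / 100
}

#' Ellipsoid tumor volume from caliper axes
#'
#' `V = (pi / 6) * a * b * c` for orthogonal axes in mm; volume in mm^3.
#' Vectorized.
#'
#' @param a,b,c Orthogonal caliper measurements (mm, >= 0).
#' @return Volume in mm^3.
#' @export
ellipsoid_volume <- function(a, b, c) {
  if (any(a < 0 | b < 0 | c < 0)) abort("axes must be non-negative.")
  (pi / 6) * a * b * c
}
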