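#' Default ear trait registry
#'
#' Returns the registry of the 15 ear phenotypes measured on every ear:
#' trait name, measurement kind and valid range. Proportion traits are area
#' fractions in \[0, 1\]; ear shape is the tip-third to base-third width
#' ratio; the remaining traits are lengths (mm) or kernel counts.
#'
#' @return A data frame with columns `trait`, `kind` (one of `"length"`,
#'   `"count"`, `"proportion"`, `"ratio"`) and `min`/`max` giving the valid
#'   range.
#' @examples
#' reg <- default_trait_registry()
#' nrow(reg) # 15
#' @export
default_trait_registry <- function() {
  reg <- data.frame(
    trait = c(
      "bald tip length",
      "ear circumference",
      "ear diameter",
      "ear length",
      "ear shape",
      "ear width",
      "kernel thickness",
      "kernel width",
      "normal kernel number",
      "shrunken kernel number",
      "number of kernels per row",
      "number of rows per ear",
      "proportion of bald tip area",
      "proportion of empty area",
      "proportion of normal seed area"
    ),
    kind = c(
      "length", "length", "length", "length", "ratio", "length",
      "length", "length", "count", "count", "count", "count",
      "proportion", "proportion", "proportion"
    ),
    stringsAsFactors = FALSE
  )
  reg$min <- 0
  reg$max <- ifelse(reg$kind == "proportion", 1, Inf)
  reg
}

#' Ear shape ratio
#'
#' Ear shape is the ratio of the ear width measured at one third of the ear
#' length from the tip to the width at one third of the length from the
#' base. A cylindrical ear has shape close to 1; strongly tapered ears have
#' shape well below 1.
#'
#' @param width_tip_third Ear width at one third of the length from the tip
#'   (same length units as `width_base_third`).
#' @param width_base_third Ear width at one third of the length from the
#'   base; must be positive.
#' @return The dimensionless width ratio. Vectorised over both arguments.
#' @examples
#' derive_ear_shape(24, 30) # 0.8
#' @export
derive_ear_shape <- function(width_tip_third, width_base_third) {
  if (any(!is.finite(width_tip_third)) || any(!is.finite(width_base_third))) {
    stop("ear shape requires finite widths", call. = FALSE)
  }
  if (any(width_tip_third <= 0) || any(width_base_third <= 0)) {
    stop("ear shape undefined for non-positive widths", call. = FALSE)
  }
  width_tip_third / width_base_third
}
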