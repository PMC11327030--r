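#' Field counts for viability / apoptosis scoring
#'
#' Per microscope field: `n_reference_cells` cells counted in the reference
#' channel define 100%, and `n_positive_cells` of those score positive for
#' the death/apoptosis marker (propidium iodide or activated caspase).
#'
#' @param n_reference_cells Integer vector, one reference count per field
#'   (typically 100).
#' @param n_positive_cells Integer vector, positives per field
#'   (`0 <= positive <= reference`).
#' @return An object of class `field_counts`.
#' @export
field_counts <- function(n_reference_cells, n_positive_cells) {
  if (length(n_reference_cells) != length(n_positive_cells))
    stop("reference and positive counts must have one value per field",
         call. = FALSE)
  if (length(n_reference_cells) < 1)
    stop("at least one field is required", call. = FALSE)
  if (any(n_reference_cells <= 0))
    stop("reference counts must be > 0", call. = FALSE)
  if (any(n_positive_cells < 0 | n_positive_cells > n_reference_cells))
    stop("positive counts must lie in [0, reference]", call. = FALSE)
  structure(list(n_reference_cells = n_reference_cells,
                 n_positive_cells = n_positive_cells,
                 n_fields = length(n_reference_cells)),
            class = "field_counts")
}

#' Cell viability percentage from field counts
#'
#' Per-field viability is `100 * (1 - positive / reference)`; fields are
#' averaged after the percentage is taken. The same arithmetic serves the
#' apoptosis assay with caspase-positive counts as positives.
#'
#' @param counts A [field_counts()].
#' @return A list with `viability_percent` (mean across fields), `sd`,
#'   `per_field` (vector) and `death_percent` (its complement).
#' @examples
#' viability_percent(field_counts(100, 10))$viability_percent  # 90
#' @export
viability_percent <- function(counts) {
  stopifnot(inherits(counts, "field_counts"))
  per_field <- 100 * (1 - counts$n_positive_cells / counts$n_reference_cells)
  list(viability_percent = mean(per_field),
       sd = if (counts$n_fields > 1) sd(per_field) else NA_real_,
       per_field = per_field,
       death_percent = 100 - mean(per_field))
}

#' Fluorescence readout for collagen degradation
#'
#' Relative fluorescence units from a dye-quenched collagen assay:
#' `background_rfu` from gels without cells, `total_rfu` from complete
#' digestion with bacterial collagenase, and `sample_rfu` from the cells
#' under study.
#'
#' @param sample_rfu,background_rfu,total_rfu Numeric scalars or vectors of
#'   equal length; `total_rfu` must exceed `background_rfu`.
#' @return An object of class `degradation_readout`.
#' @export
degradation_readout <- function(sample_rfu, background_rfu, total_rfu) {
  if (any(total_rfu <= background_rfu))
    stop("`total_rfu` must exceed `background_rfu`", call. = FALSE)
  structure(list(sample_rfu = sample_rfu, background_rfu = background_rfu,
                 total_rfu = total_rfu),
            class = "degradation_readout")
}

#' Collagen degradation percentage
#'
#' `100 * (sample - background) / (total - background)`, the degradation of
#' type-I collagen relative to total enzymatic degradation. Values outside
#' \[0, 100\] (noise pushing the sample below background or above total)
#' are clipped with a warning; the statistic is invariant under affine
#' rescaling (gain/offset) of all three readouts.
#'
#' @param readout A [degradation_readout()].
#' @return Percentage(s) in \[0, 100\].
#' @examples
#' degradation_percent(degradation_readout(55, 5, 105))  # 50
#' @export
degradation_percent <- function(readout) {
  stopifnot(inherits(readout, "degradation_readout"))
  pct <- 100 * (readout$sample_rfu - readout$background_rfu) /
    (readout$total_rfu - readout$background_rfu)
  if (any(pct < 0 | pct > 100)) {
    warning("degradation percentage outside [0, 100] clipped", call. = FALSE)
    pct <- pmin(100, pmax(0, pct))
  }
  pct
}
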