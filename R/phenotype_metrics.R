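#' Soluble-sugar reduction over storage
#'
#' Difference between the 0 h and 72 h soluble-sugar contents
#' (mg g^-1); negative values mean the content increased. Reported at 2
#' decimal places.
#'
#' @param c0,c72 Sugar contents at 0 h and 72 h, mg g^-1.
#' @return Reduction in mg g^-1, 2 dp.
#' @export
sugar_reduction <- function(c0, c72) {
  round(c0 - c72, 2)
}

#' Percent decrease in soluble sugar over storage
#'
#' `100 * (c0 - c72) / c0`, defined only for a positive 0 h content.
#'
#' @param c0,c72 Sugar contents at 0 h and 72 h, mg g^-1.
#' @return Percent decrease, 2 dp.
#' @export
percent_decrease <- function(c0, c72) {
  if (any(c0 <= 0))
    stop("percent decrease requires sugar_0h > 0", call. = FALSE)
  round(100 * (c0 - c72) / c0, 2)
}

#' Derive per-line degradation metrics from a phenotype table
#'
#' @param records Tibble with `line_id`, `sugar_0h`, `sugar_72h` (and
#'   optionally `sugar_8h`), mg g^-1.
#' @return The input with `reduction_0_72` and `percent_decrease_0_72`
#'   added.
#' @export
phenotype_metrics <- function(records) {
  records$reduction_0_72 <- sugar_reduction(records$sugar_0h,
                                            records$sugar_72h)
  records$percent_decrease_0_72 <- percent_decrease(records$sugar_0h,
                                                    records$sugar_72h)
  records
}

#' Population-level phenotype summary
#'
#' @param records Tibble with `sugar_0h` and `sugar_72h` per line.
#' @return List with `n`, `mean_sugar_0h`, `mean_reduction`,
#'   `min_reduction`, `max_reduction` (mg g^-1, 2 dp).
#' @export
population_summary <- function(records) {
  if (nrow(records) == 0L)
    stop("population_summary needs at least one record", call. = FALSE)
  red <- records$sugar_0h - records$sugar_72h
  list(
    n = nrow(records),
    mean_sugar_0h = round(mean(records$sugar_0h), 2),
    mean_reduction = round(mean(red), 2),
    min_reduction = round(min(red), 2),
    max_reduction = round(max(red), 2))
}

#' Relative qRT-PCR expression by the 2^-dCT method
#'
#' `2^-(ct_target - ct_reference)`; equal cycle thresholds give 1.
#'
#' @param ct_target Target-gene cycle threshold(s).
#' @param ct_reference Reference-gene (e.g. actin) cycle threshold(s).
#' @return Relative expression level(s).
#' @export
relative_expression <- function(ct_target, ct_reference) {
  2^(-(ct_target - ct_reference))
}
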