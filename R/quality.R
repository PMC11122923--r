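# Default whole-blood red-cell concentration (cells/uL) at ~48% hematocrit.
.DEFAULT_BLOOD_CONC <- 5e6

# round() halves-to-even; reported percentages use conventional half-up.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Pooled cell concentration from hemocytometer samples
#'
#' Pools counting-chamber samples (five-point sampling across replicates in
#' the reference protocol) into a single concentration estimate:
#' total cells / total sampled volume.
#'
#' @param counts A data frame with columns `cells` (counts, >= 0) and
#'   `volume_uL` (sampled volume per point, > 0). Extra columns (e.g.
#'   `replicate`, `sample_point`) are ignored.
#'
#' @return Concentration in cells/uL (scalar).
#' @examples
#' concentration(data.frame(cells = c(2, 3, 1, 4, 2), volume_uL = rep(0.02, 5)))
#' @export
concentration <- function(counts) {
  if (!all(c("cells", "volume_uL") %in% names(counts))) {
    abort("`counts` must have `cells` and `volume_uL` columns.")
  }
  if (nrow(counts) < 1) abort("`counts` must have at least one sample.")
  if (any(counts$cells < 0)) abort("Cell counts must be >= 0.")
  if (any(counts$volume_uL <= 0)) abort("Sampled volumes must be > 0.")
  sum(counts$cells) / sum(counts$volume_uL)
}

#' Red-blood-cell residue rate of separated plasma
#'
#' Residual cell concentration in the plasma expressed as a percentage of the
#' input whole-blood cell concentration.
#'
#' @param plasma_conc Cell concentration in the separated plasma (cells/uL).
#' @param blood_conc Cell concentration of the input whole blood (cells/uL);
#'   default 5e6, typical of ~48% hematocrit blood.
#'
#' @return Residue rate in percent.
#' @examples
#' residue_rate(1e4, 5e6) # 0.2
#' @export
residue_rate <- function(plasma_conc, blood_conc = .DEFAULT_BLOOD_CONC) {
  if (any(plasma_conc < 0)) abort("`plasma_conc` must be >= 0.")
  if (blood_conc <= 0) abort("`blood_conc` must be > 0.")
  100 * plasma_conc / blood_conc
}

#' Capture efficiency from replicate residue rates
#'
#' Averages replicate residue rates and reports the red-blood-cell capture
#' efficiency as the complement to 100%. Both figures are rounded half-up to
#' `decimals` places, so the pair is always consistent
#' (efficiency = 100 - mean residue at the reported precision).
#'
#' @param replicate_rates Residue rates in percent, each in \[0, 100\].
#' @param decimals Decimal places for reporting. Default 1.
#'
#' @return A one-row tibble: `n_replicates`, `mean_residue_pct`,
#'   `capture_efficiency_pct`, with the unrounded replicate rates as the
#'   `"replicate_rates"` attribute.
#' @examples
#' capture_efficiency(c(0.202, 0.266, 0.248)) # 0.2% residue, 99.8% efficiency
#' @export
capture_efficiency <- function(replicate_rates, decimals = 1) {
  if (length(replicate_rates) < 1) abort("Need at least one replicate rate.")
  if (any(replicate_rates < 0 | replicate_rates > 100)) {
    abort("Residue rates must lie in [0, 100] percent.")
  }
  mean_res <- round_half_up(mean(replicate_rates), decimals)
  out <- tibble::tibble(
    n_replicates = length(replicate_rates),
    mean_residue_pct = mean_res,
    capture_efficiency_pct = round_half_up(100 - mean_res, decimals)
  )
  attr(out, "replicate_rates") <- replicate_rates
  out
}

#' Quality report from a raw count table
#'
#' Per-replicate pooled concentrations, residue rates against the whole-blood
#' concentration, and the overall capture efficiency.
#'
#' @param counts Data frame with columns `replicate`, `cells`, `volume_uL`
#'   (and optionally `sample_point`).
#' @param blood_conc Whole-blood cell concentration (cells/uL); default 5e6.
#' @param decimals Reporting precision for the summary. Default 1.
#'
#' @return A list with `replicates` (tibble: `replicate`, `plasma_conc`,
#'   `residue_pct`) and `summary` (the [capture_efficiency()] tibble).
#' @export
quality_report <- function(counts, blood_conc = .DEFAULT_BLOOD_CONC, decimals = 1) {
  if (!all(c("replicate", "cells", "volume_uL") %in% names(counts))) {
    abort("`counts` must have `replicate`, `cells` and `volume_uL` columns.")
  }
  reps <- counts |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(
      plasma_conc = sum(.data$cells) / sum(.data$volume_uL),
      .groups = "drop"
    ) |>
    dplyr::mutate(residue_pct = residue_rate(.data$plasma_conc, blood_conc))
  list(
    replicates = reps,
    summary = capture_efficiency(reps$residue_pct, decimals = decimals)
  )
}
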