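#' Assay constants of the spectrophotometric carotene determination
#'
#' Frozen named constants: the chlorophyll-correction divisor applied to the
#' 665 nm absorbance, the HPLC-derived calibration factor, and the dodecane
#' extraction volume in mL. Not configurable, so the concentration formula
#' stays bit-exact.
#' @format Named numeric vector.
#' @export
ASSAY_CONSTANTS <- c(chlorophyll_divisor = 3.91, hplc_calibration = 3.657,
                     extraction_volume_ml = 3)

#' Interval specific growth rates from a dry-weight series
#'
#' Per-interval log-difference quotient
#' `mu_i = (ln DW_i - ln DW_{i-1}) / (t_i - t_{i-1})`. The rates telescope:
#' `sum(mu_i * dt_i) = ln(DW_n / DW_1)`, and they are invariant to rescaling
#' the series by any positive constant.
#'
#' @param times Sampling times, h, strictly increasing, length >= 2.
#' @param DW Dry weights, g/L, strictly positive.
#' @return Numeric vector of length `length(times) - 1`, 1/h.
#' @export
growth_rate_series <- function(times, DW) {
  if (length(times) != length(DW) || length(times) < 2L)
    stop("growth_rate_series: need matched times and DW with >= 2 points")
  if (any(diff(times) <= 0))
    stop("growth_rate_series: times must be strictly increasing")
  if (any(DW <= 0))
    stop("growth_rate_series: DW must be strictly positive")
  diff(log(DW)) / diff(times)
}

#' Beta-carotene concentration from absorbance readings
#'
#' `C (mg/L) = (A453 - A665 / 3.91) * 3.657 * 3 * dilution`: the 453 nm
#' absorbance corrected for chlorophyll via the 665 nm reading, scaled by the
#' HPLC calibration factor, the 3 mL extraction volume and the dilution
#' factor. Noisy assays can over-correct the chlorophyll term; a negative
#' result is returned with a warning rather than raised.
#'
#' @param A453,A665 Absorbances at 453 and 665 nm (>= 0). Vectorized.
#' @param dilution Dilution factor (>= 1).
#' @return Concentration in mg/L.
#' @export
carotene_concentration <- function(A453, A665, dilution = 1) {
  if (any(A453 < 0) || any(A665 < 0))
    stop("carotene_concentration: absorbances must be >= 0")
  if (any(dilution < 1))
    stop("carotene_concentration: dilution factor must be >= 1")
  k <- ASSAY_CONSTANTS
  out <- (A453 - A665 / k[["chlorophyll_divisor"]]) *
    k[["hplc_calibration"]] * k[["extraction_volume_ml"]] * dilution
  if (any(out < 0))
    warning("carotene_concentration: negative value(s); chlorophyll correction ",
            "exceeds the 453 nm signal")
  out
}

#' Carotene content as percent of dry weight
#'
#' `pct = C * 10 / DW` with the concentration in mg/L and the dry weight in
#' mg/L. With content expressed as a mass fraction W, this is consistent with
#' `pct = 100 W` when `C = W * DW`.
#'
#' @param C_bcar Carotene concentration, mg/L.
#' @param DW_mg Dry weight, mg/L (> 0). Vectorized.
#' @return Content in percent of DW.
#' @export
carotene_content_percent <- function(C_bcar, DW_mg) {
  if (any(DW_mg <= 0))
    stop("carotene_content_percent: DW must be > 0")
  C_bcar * 10 / DW_mg
}

#' Carotene concentration implied by a content percentage
#'
#' Algebraic inverse of [carotene_content_percent()]:
#' `C = pct * DW / 10`.
#'
#' @param pct Content, percent of DW.
#' @param DW_mg Dry weight, mg/L (> 0).
#' @return Concentration in mg/L.
#' @export
content_to_concentration <- function(pct, DW_mg) {
  if (any(DW_mg <= 0))
    stop("content_to_concentration: DW must be > 0")
  pct * DW_mg / 10
}

#' Process an assay table
#'
#' Adds `bcar_mg_per_l` and `bcar_pct` columns to a data frame of absorbance
#' readings (`A453`, `A665`, `dilution`, `dw_mg_per_l`).
#'
#' @param df Assay data frame.
#' @return The data frame with derived columns appended.
#' @export
process_assay_table <- function(df) {
  require_columns(df, c("A453", "A665", "dilution", "dw_mg_per_l"), "assay table")
  df$bcar_mg_per_l <- carotene_concentration(df$A453, df$A665, df$dilution)
  df$bcar_pct <- carotene_content_percent(df$bcar_mg_per_l, df$dw_mg_per_l)
  df
}
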