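#' Percent methylated molecules from dual-probe qMSP
#'
#' With simultaneous methylated and unmethylated detection probes, the
#' fraction of methylated molecules follows from the two threshold cycles
#' and the amplification efficiency E:
#' `percent = 100 * E^-CtM / (E^-CtM + E^-CtU)`.
#' An undetected channel (`Ct = Inf`) yields exactly 0 or 100.
#'
#' @param ct_m,ct_u Threshold cycles of the methylated / unmethylated
#'   probes (vectors recycled; `Inf` = undetected).
#' @param efficiency Amplification factor per cycle (> 1; 2 = perfect
#'   doubling).
#' @return Percent methylated molecules in \[0, 100\].
#' @examples
#' methylation_percent(30, 30) # 50
#' @export
methylation_percent <- function(ct_m, ct_u, efficiency = 2.0) {
  if (efficiency <= 1) abort("`efficiency` must exceed 1")
  args <- vctrs_recycle(ct_m, ct_u)
  ct_m <- args[[1]]; ct_u <- args[[2]]
  if (any(is.na(ct_m) | is.na(ct_u))) abort("Ct values must not be NA")
  if (any(is.infinite(ct_m) & is.infinite(ct_u))) {
    abort("no signal in either channel")
  }
  # work on the Ct difference so one undetected channel is exact
  x <- ct_u - ct_m # positive when methylated molecules dominate
  ifelse(is.infinite(x) & x > 0, 100,
    ifelse(is.infinite(x) & x < 0, 0,
      100 * efficiency^x / (efficiency^x + 1)
    )
  )
}

#' Classify MSP positivity from percent methylation
#'
#' A sample is called methylated when its percent methylation is strictly
#' above the threshold (default 29.74%, the lowest quantitative value
#' observed to coincide with a positive qualitative MSP call).
#'
#' @param percent Percent methylated molecules in \[0, 100\].
#' @param threshold Positivity cutoff (strictly above).
#' @return Logical vector.
#' @examples
#' classify_msp(c(29.74, 60)) # FALSE TRUE
#' @export
classify_msp <- function(percent, threshold = 29.74) {
  if (any(percent < 0 | percent > 100, na.rm = TRUE)) {
    abort("`percent` must lie in [0, 100]")
  }
  percent > threshold
}

#' Fold change between two percent-methylation values
#'
#' @param percent_a Numerator (e.g. resistant).
#' @param percent_b Denominator (e.g. sensitive); must be positive.
#' @return `percent_a / percent_b`.
#' @examples
#' fold_change(60, 10) # 6
#' @export
fold_change <- function(percent_a, percent_b) {
  if (any(percent_b <= 0)) {
    abort("fold change not estimable: zero or negative denominator")
  }
  percent_a / percent_b
}

#' Absolute demethylation after reactivation treatment
#'
#' Drop in percent methylated molecules between the resistant and the
#' reactivation-treated phenotype, in percentage points.
#'
#' @param percent_r,percent_rt Percent methylation in R and RT, in
#'   \[0, 100\].
#' @return `percent_r - percent_rt` (percentage points).
#' @examples
#' demethylation_after_rt(60, 45) # 15
#' @export
demethylation_after_rt <- function(percent_r, percent_rt) {
  ok <- function(x) all(x >= 0 & x <= 100)
  if (!ok(percent_r) || !ok(percent_rt)) {
    abort("percentages must lie in [0, 100]")
  }
  percent_r - percent_rt
}
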