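#' Normalize raw viability signal to the untreated control
#'
#' Expresses each well as a percentage of the untreated (dose 0) control
#' signal, the 100%-survival anchor of a dose-response assay.
#'
#' @param dr Tibble `dose, signal` (one row per replicate well; dose in
#'   ug/mL, ascending doses not required).
#' @param control_dose Dose identifying the untreated control rows.
#' @return A `dose_response` tibble `dose, viability` (percent), one row
#'   per input well, plus a `mean_curve` attribute (tibble `dose,
#'   viability, sd`).
#' @examples
#' dr <- tibble::tibble(dose = c(0, 0, 1, 1), signal = c(100, 102, 55, 50))
#' normalize_viability(dr)
#' @export
normalize_viability <- function(dr, control_dose = 0) {
  assert_columns(dr, c("dose", "signal"), "`dr`")
  ctrl <- dr$signal[dr$dose == control_dose]
  if (length(ctrl) == 0 || mean(ctrl) <= 0) {
    abort("untreated control signal must be present and positive")
  }
  out <- dr |>
    mutate(viability = 100 * .data$signal / mean(ctrl)) |>
    select("dose", "viability")
  mean_curve <- out |>
    group_by(.data$dose) |>
    summarise(sd = ifelse(dplyr::n() > 1, stats::sd(.data$viability), 0),
              viability = mean(.data$viability), .groups = "drop") |>
    select("dose", "viability", "sd") |>
    arrange(.data$dose)
  structure(out, mean_curve = mean_curve,
            class = c("dose_response", class(out)))
}

#' Interpolate the half-maximal inhibitory concentration
#'
#' Finds the first (lowest-dose) crossing of the mean viability curve
#' through 50% and linearly interpolates the dose at the crossing.
#'
#' @param dr A `dose_response` (from [normalize_viability()]) or a tibble
#'   `dose, viability` of per-dose means.
#' @return IC50 dose (same units as `dose`).
#' @examples
#' ic50(tibble::tibble(dose = c(1, 2), viability = c(80, 40))) # 1.75
#' @export
ic50 <- function(dr) {
  curve <- attr(dr, "mean_curve") %||% dr
  assert_columns(curve, c("dose", "viability"), "`dr`")
  curve <- curve |>
    group_by(.data$dose) |>
    summarise(viability = mean(.data$viability), .groups = "drop") |>
    arrange(.data$dose)
  v <- curve$viability
  d <- curve$dose
  cross <- which((v[-length(v)] - 50) * (v[-1] - 50) <= 0 &
                   v[-length(v)] != v[-1])
  exact <- which(v == 50)
  if (length(exact) > 0 && (length(cross) == 0 || exact[1] <= cross[1])) {
    return(d[exact[1]])
  }
  if (length(cross) == 0) {
    abort("viability curve does not cross 50%: IC50 undefined")
  }
  i <- cross[1]
  d[i] + (v[i] - 50) / (v[i] - v[i + 1]) * (d[i + 1] - d[i])
}

#' Resistance index
#'
#' Ratio of the resistant to the sensitive IC50. The raw ratio is returned;
#' `printed` carries the 2-decimal reporting convention.
#'
#' @param ic50_resistant,ic50_sensitive Positive IC50 values.
#' @return A tibble `ri, printed`.
#' @examples
#' resistance_index(2.0, 1.3)
#' @export
resistance_index <- function(ic50_resistant, ic50_sensitive) {
  assert_positive(ic50_resistant, "ic50_resistant")
  assert_positive(ic50_sensitive, "ic50_sensitive")
  ri <- ic50_resistant / ic50_sensitive
  tibble(ri = ri, printed = round(ri, 2))
}
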