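#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival step function S(t) from right-censored times
#' (deaths processed before censorings at tied times, the standard
#' convention). Backed by [survival::survfit()].
#'
#' @param samples Tibble `time, event` (days; `event` logical or 0/1),
#'   optionally `group` for stratified curves.
#' @return A `km_fit` tibble `group (if any), time, n_risk, n_event,
#'   n_censor, survival`, anchored at S(0) = 1.
#' @examples
#' km_estimate(tibble::tibble(time = 1:3, event = TRUE))
#' @export
km_estimate <- function(samples) {
  assert_columns(samples, c("time", "event"), "`samples`")
  if (any(samples$time < 0)) abort("survival times must be non-negative")
  has_group <- "group" %in% names(samples)
  fit <- if (has_group) {
    survival::survfit(survival::Surv(time, event) ~ group, data = samples)
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = samples)
  }
  sm <- summary(fit, censored = TRUE)
  out <- tibble(
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    n_censor = sm$n.censor, survival = sm$surv
  )
  if (has_group) {
    grp <- as.character(sm$strata)
    out <- mutate(out, group = sub("^group=", "", grp), .before = 1)
    anchor <- distinct(out, .data$group) |>
      mutate(time = 0, n_risk = NA_integer_, n_event = 0L, n_censor = 0L,
             survival = 1)
    out <- bind_rows(anchor, out) |> arrange(.data$group, .data$time)
  } else {
    out <- bind_rows(
      tibble(time = 0, n_risk = fit$n, n_event = 0L, n_censor = 0L,
             survival = 1),
      out
    )
  }
  structure(out, class = c("km_fit", class(out)))
}

#' Two-group log-rank test
#'
#' Observed-minus-expected chi-square statistic over shared event times,
#' with a 1-df chi-square p-value. Backed by [survival::survdiff()].
#'
#' @param samples Tibble `time, event, group` with exactly two groups.
#' @return A `logrank_test` list: `statistic, p_value, n, n_events` (per
#'   group).
#' @examples
#' s <- tibble::tibble(time = c(1, 2, 3, 4), event = TRUE,
#'                     group = c("a", "a", "b", "b"))
#' logrank_test(s)$p_value
#' @export
logrank_test <- function(samples) {
  assert_columns(samples, c("time", "event", "group"), "`samples`")
  groups <- unique(samples$group)
  if (length(groups) != 2) {
    abort("log-rank comparison requires exactly 2 groups")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = samples)
  stat <- unname(sd$chisq)
  structure(
    list(
      statistic = stat,
      p_value = pchisq(stat, df = 1, lower.tail = FALSE),
      n = as.integer(table(samples$group)[as.character(groups)]),
      n_events = unname(sd$obs)
    ),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g, p = %.4g (n = %s)\n",
              x$statistic, x$p_value, paste(x$n, collapse = " vs ")))
  invisible(x)
}

#' Stratify patients into methylated / unmethylated survival groups
#'
#' Assigns each patient a methylation group from a qualitative MSP call
#' when available, otherwise from the quantitative qMSP percentage via
#' [classify_msp()] (qualitative call takes precedence when both are
#' present). Patients with neither measure are excluded with a message.
#'
#' @param clinical Tibble with `patient`, a time column and an event
#'   column (see `endpoint`), optionally `msp_call` (logical) and
#'   `qmsp_percent`.
#' @param endpoint `"os"` or `"pfs"`: selects `os_days`/`os_event` or
#'   `pfs_days`/`pfs_event`.
#' @param threshold qMSP positivity cutoff (percent, strictly above).
#' @return Tibble `patient, time, event, group` with group
#'   `"methylated"`/`"unmethylated"`.
#' @export
stratify_by_methylation <- function(clinical, endpoint = c("os", "pfs"),
                                    threshold = 29.74) {
  endpoint <- match.arg(endpoint)
  time_col <- paste0(endpoint, "_days")
  event_col <- paste0(endpoint, "_event")
  assert_columns(clinical, c("patient", time_col, event_col), "`clinical`")

  call <- rep(NA, nrow(clinical))
  if ("qmsp_percent" %in% names(clinical)) {
    has_pct <- !is.na(clinical$qmsp_percent)
    call[has_pct] <- classify_msp(clinical$qmsp_percent[has_pct], threshold)
  }
  if ("msp_call" %in% names(clinical)) {
    has_msp <- !is.na(clinical$msp_call)
    call[has_msp] <- clinical$msp_call[has_msp]
  }
  if (all(is.na(call))) abort("no methylation measure for any patient")
  n_drop <- sum(is.na(call))
  if (n_drop > 0) {
    message(sprintf("%d patient(s) without a methylation measure excluded",
                    n_drop))
  }
  tibble(
    patient = clinical$patient,
    time = clinical[[time_col]],
    event = clinical[[event_col]],
    group = if_else(call, "methylated", "unmethylated")
  ) |>
    filter(!is.na(.data$group))
}
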