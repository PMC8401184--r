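#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns one row per tested unit,
#' `glance()` a one-row summary.
#'
#' @param x A `dm_result`, `de_result`, `logrank_test`, `km_fit` or
#'   `epiresist_pipeline` object.
#' @param ... Unused.
#' @return A tibble.
#' @name epiresist-tidiers
NULL

#' @rdname epiresist-tidiers
#' @method tidy dm_result
#' @export
tidy.dm_result <- function(x, ...) as_tibble(x)

#' @rdname epiresist-tidiers
#' @method glance dm_result
#' @export
glance.dm_result <- function(x, ...) {
  sch <- attr(x, "scheme")
  tibble(
    n_called = nrow(x), n_tested = attr(x, "n_tested"),
    n_hyper = sum(x$direction == "hyper"),
    n_hypo = sum(x$direction == "hypo"),
    scheme = sch$name, fdr = sch$fdr
  )
}

#' @rdname epiresist-tidiers
#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) as_tibble(x)

#' @rdname epiresist-tidiers
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  groups <- attr(x, "groups")
  tibble(
    n_genes = nrow(x), n_de = sum(x$de),
    n_up = sum(x$de & x$direction == "up"),
    n_down = sum(x$de & x$direction == "down"),
    group_a = groups[1], group_b = groups[2], alpha = attr(x, "alpha")
  )
}

#' @rdname epiresist-tidiers
#' @method tidy logrank_test
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, df = 1L)
}

#' @rdname epiresist-tidiers
#' @method glance logrank_test
#' @export
glance.logrank_test <- function(x, ...) tidy.logrank_test(x)

#' @rdname epiresist-tidiers
#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) as_tibble(x)

#' @rdname epiresist-tidiers
#' @method glance epiresist_pipeline
#' @export
glance.epiresist_pipeline <- function(x, ...) {
  bind_cols(
    tibble(
      seed = x$config$seed,
      n_genes = x$config$n_genes,
      n_planted = x$config$n_planted,
      n_dm_cpgs = nrow(x$dm),
      n_islands = nrow(x$islands),
      n_selected_patients = length(x$selected),
      logrank_p = if (!is.null(x$logrank)) x$logrank$p_value else NA_real_
    ),
    recovery_stats(x)
  )
}
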