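# Internal helpers shared across modules.

# Single place for the 1-based (CpG report) <-> 0-based half-open (BED)
# conversion so off-by-one bugs cannot diverge between readers and writers.
pos1_to_bed0 <- function(pos) pos - 1L
bed0_to_pos1 <- function(start0) start0 + 1L

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a fraction in [0, 1]", name))
  }
  invisible(x)
}

assert_positive <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(!is.finite(x) | x <= 0) else any(!is.finite(x) | x < 0)
  if (!is.numeric(x) || bad) {
    abort(sprintf(
      "`%s` must be %s", name, if (strict) "positive" else "non-negative"
    ))
  }
  invisible(x)
}

# Deterministic header stamped onto every text output of the pipeline.
output_header <- function(seed = NULL, config_hash = NULL) {
  parts <- c(
    sprintf("# epiresist %s", as.character(packageVersion("epiresist"))),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
    if (!is.null(config_hash)) sprintf("# config: %s", config_hash)
  )
  paste(parts, collapse = "\n")
}

# Stable short hash of a configuration list (polynomial rolling hash over
# its deparsed form); avoids a digest dependency for a provenance stamp.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
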