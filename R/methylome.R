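#' Compute beta values with a coverage filter
#'
#' Removes CpG rows whose coverage is not strictly greater than
#' `min_coverage` (the filter is "greater than", so coverage equal to the
#' cutoff is dropped) and populates `beta = meth / coverage` on the
#' survivors.
#'
#' @param profiles Tibble with `meth` and `unmeth` count columns (plus any
#'   coordinate columns, carried through).
#' @param min_coverage Coverage cutoff; rows with `meth + unmeth >
#'   min_coverage` are kept.
#' @return Filtered tibble with `coverage` and `beta` columns added.
#' @examples
#' compute_beta(tibble::tibble(meth = c(5, 3), unmeth = c(5, 2)),
#'              min_coverage = 5)
#' @export
compute_beta <- function(profiles, min_coverage = 5) {
  assert_columns(profiles, c("meth", "unmeth"), "`profiles`")
  if (any(profiles$meth < 0 | profiles$unmeth < 0)) {
    abort("methylation counts must be non-negative")
  }
  profiles |>
    mutate(coverage = .data$meth + .data$unmeth) |>
    filter(.data$coverage > min_coverage) |>
    mutate(beta = .data$meth / .data$coverage)
}

#' Two-sided Fisher's exact test for one CpG
#'
#' Exact hypergeometric test on the 2x2 table of methylated/unmethylated
#' counts in two phenotypes, the per-CpG significance stand-in used by
#' [call_dm()]. Two-sided p sums all tables with probability not exceeding
#' that of the observed one (with a small relative tolerance, matching
#' [stats::fisher.test()]).
#'
#' @param meth_s,unmeth_s,meth_r,unmeth_r Non-negative counts; vectors are
#'   recycled to common length.
#' @return Numeric vector of p-values in (0, 1]. An empty margin (one
#'   phenotype with zero total counts) is untestable and returns 1 with a
#'   warning.
#' @examples
#' test_cpg(9, 1, 1, 9) # ~1.09e-3
#' @export
test_cpg <- function(meth_s, unmeth_s, meth_r, unmeth_r) {
  args <- vctrs_recycle(meth_s, unmeth_s, meth_r, unmeth_r)
  if (any(unlist(args) < 0)) abort("counts must be non-negative")
  empty <- (args[[1]] + args[[2]] == 0) | (args[[3]] + args[[4]] == 0)
  if (any(empty)) {
    warn("CpG(s) with an empty phenotype margin: p set to 1")
  }
  p <- fisher_p2(args[[1]], args[[2]], args[[3]], args[[4]])
  p[empty] <- 1
  p
}

vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}

# Vectorized two-sided Fisher p via hypergeometric enumeration. For the
# table (a, b; c, d) with fixed margins, sums dhyper mass over all tables
# at most as probable as the observed (relative tolerance 1e-7, as in
# stats::fisher.test).
fisher_p2 <- function(a, b, c, d) {
  vapply(seq_along(a), function(i) {
    m <- a[i] + b[i]        # row 1 total
    n2 <- c[i] + d[i]       # row 2 total
    k <- a[i] + c[i]        # column 1 total
    if (k == 0 || k == m + n2) return(1)
    support <- max(0, k - n2):min(k, m)
    dens <- dhyper(support, m, n2, k)
    obs <- dhyper(a[i], m, n2, k)
    min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, a thin wrapper over
#' [stats::p.adjust()] kept as the package's single FDR entry point.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Differential-methylation threshold schemes
#'
#' Named presets for calling differentially methylated CpGs between
#' resistant (R) and sensitive (S) phenotypes:
#' * `initial` — beta_R > 0.7 and beta_S < 0.3, coverage > 5;
#' * `readjusted` — beta_S < 0.2 and delta (beta_R - beta_S) > 0.4,
#'   coverage > 5;
#' * `matrix_a` — beta_R > 0.4 and beta_S < 0.23, coverage > 10;
#' * `matrix_b` — beta_S < 0.16 and delta >= 0.14, coverage > 10.
#' All apply a BH false-discovery cutoff `fdr` (default 0.05) on the
#' per-CpG exact test.
#'
#' @param name Preset name, or `"custom"` with explicit bounds.
#' @param min_beta_r Optional lower bound on beta_R (strict).
#' @param max_beta_s Upper bound on beta_S (strict).
#' @param min_delta Optional bound on beta_R - beta_S.
#' @param delta_strict Whether the delta bound is strict (`>`) or not
#'   (`>=`).
#' @param min_coverage Coverage cutoff (strict, both phenotypes).
#' @param fdr BH false-discovery cutoff.
#' @return A `dm_scheme` list.
#' @examples
#' dm_scheme("readjusted")
#' @export
dm_scheme <- function(name = c("initial", "readjusted", "matrix_a",
                               "matrix_b", "custom"),
                      min_beta_r = NULL, max_beta_s = NULL, min_delta = NULL,
                      delta_strict = TRUE, min_coverage = 5, fdr = 0.05) {
  name <- match.arg(name)
  preset <- switch(name,
    initial = list(min_beta_r = 0.7, max_beta_s = 0.3, min_delta = NULL,
                   delta_strict = TRUE, min_coverage = 5),
    readjusted = list(min_beta_r = NULL, max_beta_s = 0.2, min_delta = 0.4,
                      delta_strict = TRUE, min_coverage = 5),
    matrix_a = list(min_beta_r = 0.4, max_beta_s = 0.23, min_delta = NULL,
                    delta_strict = TRUE, min_coverage = 10),
    matrix_b = list(min_beta_r = NULL, max_beta_s = 0.16, min_delta = 0.14,
                    delta_strict = FALSE, min_coverage = 10),
    custom = list(min_beta_r = min_beta_r, max_beta_s = max_beta_s,
                  min_delta = min_delta, delta_strict = delta_strict,
                  min_coverage = min_coverage)
  )
  structure(c(list(name = name), preset, list(fdr = fdr)),
            class = "dm_scheme")
}

#' Call differentially methylated CpGs between two phenotypes
#'
#' Pools replicate count tables within each phenotype by count summation,
#' inner-joins the phenotypes on (chrom, pos), applies the scheme's coverage
#' filter to both, computes beta values, delta and a per-CpG two-sided
#' Fisher's exact p with BH adjustment across all tested CpGs, and reports
#' exactly the CpGs satisfying every scheme inequality with q below the
#' scheme's FDR.
#'
#' @param profiles_s,profiles_r A count tibble (`chrom, pos, meth, unmeth`)
#'   or a list of replicate tibbles to pool.
#' @param scheme A [dm_scheme()] (or preset name).
#' @return A `dm_result` tibble: `chrom, pos, beta_s, beta_r, delta, p, q,
#'   direction` (`hyper` = more methylated in R). Attribute `n_tested`
#'   records the number of coverage-passing CpGs tested.
#' @examples
#' s <- tibble::tibble(chrom = "chr1", pos = 1:2, meth = c(1, 1),
#'                     unmeth = c(19, 19))
#' r <- tibble::tibble(chrom = "chr1", pos = 1:2, meth = c(18, 1),
#'                     unmeth = c(2, 19))
#' call_dm(s, r, dm_scheme("readjusted"))
#' @export
call_dm <- function(profiles_s, profiles_r, scheme = dm_scheme("readjusted")) {
  if (is.character(scheme)) scheme <- dm_scheme(scheme)
  stopifnot(inherits(scheme, "dm_scheme"))
  s <- pool_replicates(profiles_s)
  r <- pool_replicates(profiles_r)

  s <- compute_beta(s, scheme$min_coverage)
  r <- compute_beta(r, scheme$min_coverage)
  joined <- inner_join(
    rename(s, meth_s = "meth", unmeth_s = "unmeth",
           cov_s = "coverage", beta_s = "beta"),
    rename(r, meth_r = "meth", unmeth_r = "unmeth",
           cov_r = "coverage", beta_r = "beta"),
    by = c("chrom", "pos")
  )
  if (nrow(joined) == 0) {
    warn("no CpG coordinates shared between phenotypes after filtering")
    out <- tibble(chrom = character(), pos = integer(), beta_s = numeric(),
                  beta_r = numeric(), delta = numeric(), p = numeric(),
                  q = numeric(), direction = character())
    return(structure(out, n_tested = 0L, scheme = scheme,
                     class = c("dm_result", class(out))))
  }

  joined <- joined |>
    mutate(
      delta = .data$beta_r - .data$beta_s,
      p = test_cpg(.data$meth_s, .data$unmeth_s,
                   .data$meth_r, .data$unmeth_r),
      q = p.adjust(.data$p, method = "BH"),
      direction = if_else(.data$delta >= 0, "hyper", "hypo")
    )

  keep <- joined$q < scheme$fdr & joined$beta_s < scheme$max_beta_s
  if (!is.null(scheme$min_beta_r)) {
    keep <- keep & joined$beta_r > scheme$min_beta_r
  }
  if (!is.null(scheme$min_delta)) {
    keep <- keep & if (scheme$delta_strict) {
      joined$delta > scheme$min_delta
    } else {
      joined$delta >= scheme$min_delta
    }
  }

  out <- joined[keep, ] |>
    select("chrom", "pos", "beta_s", "beta_r", "delta", "p", "q",
           "direction") |>
    arrange(.data$chrom, .data$pos)
  structure(out, n_tested = nrow(joined), scheme = scheme,
            class = c("dm_result", class(out)))
}

pool_replicates <- function(x) {
  if (is.data.frame(x)) x <- list(x)
  purrr::map(x, ~ assert_columns(.x, c("chrom", "pos", "meth", "unmeth"),
                                 "count table")) |>
    bind_rows() |>
    group_by(.data$chrom, .data$pos) |>
    summarise(meth = sum(.data$meth), unmeth = sum(.data$unmeth),
              .groups = "drop")
}

#' Roll differentially methylated CpGs up to genes
#'
#' Annotates each DM CpG with its genomic zone (via
#' [classify_positions()]) and tallies, per gene, the number of DM CpGs,
#' the set of zones hit and the maximum absolute delta. Genes with no DM
#' CpG are absent.
#'
#' @param dm A [call_dm()] result (or any tibble with `chrom, pos, delta`).
#' @param genes,islands Gene models and islands as in
#'   [classify_positions()].
#' @param promoter_up,promoter_down Promoter window (bp).
#' @return Tibble `gene, n_dm_cpgs, regions, max_abs_delta`, with `regions`
#'   a comma-separated label set.
#' @export
dm_genes <- function(dm, genes, islands = NULL, promoter_up = 2000,
                     promoter_down = 500) {
  assert_columns(dm, c("chrom", "pos", "delta"), "`dm`")
  if (nrow(dm) == 0) {
    return(tibble(gene = character(), n_dm_cpgs = integer(),
                  regions = character(), max_abs_delta = numeric()))
  }
  ann <- classify_positions(dm, genes, islands, promoter_up, promoter_down)
  ann |>
    filter(!is.na(.data$gene)) |>
    group_by(.data$gene) |>
    summarise(
      n_dm_cpgs = dplyr::n(),
      regions = paste(sort(unique(.data$zone)), collapse = ","),
      max_abs_delta = max(abs(.data$delta)),
      .groups = "drop"
    )
}
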