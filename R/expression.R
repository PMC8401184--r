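#' Collapse duplicate probes to one row per gene
#'
#' Expression tables must carry unique gene ids; when a gene appears more
#' than once (duplicate hybridizing probes), the probe with the highest
#' variance across samples is kept and a warning reports the number
#' eliminated.
#'
#' @param values Tibble with a `gene` column and one numeric column per
#'   sample.
#' @return Tibble with unique `gene` values.
#' @export
collapse_duplicates <- function(values) {
  assert_columns(values, "gene", "`values`")
  if (!anyDuplicated(values$gene)) return(values)
  n_dup <- sum(duplicated(values$gene))
  warn(sprintf("%d duplicate probe(s) eliminated (kept max-variance probe)",
               n_dup))
  mat <- as.matrix(values[setdiff(names(values), "gene")])
  values |>
    mutate(.var = apply(mat, 1, var)) |>
    group_by(.data$gene) |>
    arrange(desc(.data$.var), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select(-".var") |>
    arrange(match(.data$gene, unique(values$gene)))
}

#' Per-gene differential expression by unpaired (Welch) t-test with BH FDR
#'
#' Tests every gene between two sample groups on log2 values with Welch's
#' two-sample t-test, adjusts p-values by Benjamini-Hochberg across all
#' tested genes, and flags genes differentially expressed at `q <= alpha`.
#' Genes with zero variance in both groups and equal means are ties
#' (p = 1).
#'
#' @param values Expression tibble: `gene` column plus one numeric column
#'   per sample (log2 scale).
#' @param design Tibble `sample, group`.
#' @param group_a,group_b Group labels to compare; `logFC` is B minus A.
#' @param alpha FDR cutoff for the `de` flag.
#' @return A `de_result` tibble: `gene, mean_a, mean_b, logFC, p, q,
#'   direction, de`.
#' @examples
#' vals <- tibble::tibble(gene = "g1", s1 = 1, s2 = 1.1, r1 = 3, r2 = 3.2)
#' des <- tibble::tibble(sample = c("s1", "s2", "r1", "r2"),
#'                       group = c("S", "S", "R", "R"))
#' differential_expression(vals, des, "S", "R")
#' @export
differential_expression <- function(values, design, group_a, group_b,
                                    alpha = 0.05) {
  assert_columns(values, "gene", "`values`")
  assert_columns(design, c("sample", "group"), "`design`")
  values <- collapse_duplicates(values)
  a_samp <- design$sample[design$group == group_a]
  b_samp <- design$sample[design$group == group_b]
  if (length(a_samp) < 2 || length(b_samp) < 2) {
    abort(paste0(
      "each group needs >= 2 samples for variance estimation; ",
      "use a paired fixture or add replicates"
    ))
  }
  a <- as.matrix(values[a_samp])
  b <- as.matrix(values[b_samp])
  wt <- welch_t_rows(a, b)
  out <- tibble(
    gene = values$gene,
    mean_a = wt$mean_a, mean_b = wt$mean_b,
    logFC = wt$mean_b - wt$mean_a,
    p = wt$p,
    q = p.adjust(wt$p, method = "BH")
  ) |>
    mutate(
      direction = if_else(.data$logFC >= 0, "up", "down"),
      de = .data$q <= alpha
    )
  structure(out, groups = c(group_a, group_b), alpha = alpha,
            class = c("de_result", class(out)))
}

# Row-wise Welch t with the zero-variance tie rule: se == 0 and equal means
# gives p = 1; se == 0 with distinct means is an exact separation (p = 0).
welch_t_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  se2 <- va / na + vb / nb
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  tt <- (mb - ma) / sqrt(se2)
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  zero <- se2 == 0
  p[zero & (ma == mb)] <- 1
  p[zero & (ma != mb)] <- 0
  list(mean_a = ma, mean_b = mb, p = p)
}

#' Filter low-abundance genes by counts per million
#'
#' Keeps a gene when its CPM is at least `min_cpm` in at least
#' `min_samples` samples (genes with fewer than 1 read per million in fewer
#' than 6 samples are discarded under the defaults).
#'
#' @param counts Tibble: `gene` column plus integer count columns.
#' @param min_cpm CPM threshold.
#' @param min_samples Minimum number of samples at or above `min_cpm`.
#' @return Filtered count tibble.
#' @export
cpm_filter <- function(counts, min_cpm = 1, min_samples = 6) {
  assert_columns(counts, "gene", "`counts`")
  mat <- as.matrix(counts[setdiff(names(counts), "gene")])
  if (any(mat < 0)) abort("counts must be non-negative")
  cpm <- t(t(mat) / colSums(mat)) * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  counts[keep, ]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample against a reference column
#' (the one whose upper-quartile CPM is closest to the mean upper quartile),
#' gene-wise log2 ratios (M) and average log2 abundances (A) are computed on
#' genes expressed in both; the most extreme 30% of M and 5% of A are
#' trimmed symmetrically and the factor is the precision-weighted mean of
#' the remaining M values. Factors are normalized to geometric mean 1.
#'
#' @param counts Tibble: `gene` column plus integer count columns.
#' @param ref Reference sample name, or `NULL` for automatic selection.
#' @param trim_m,trim_a Two-sided trim fractions for M and A.
#' @return Named numeric vector of normalization factors.
#' @export
tmm_factors <- function(counts, ref = NULL, trim_m = 0.3, trim_a = 0.05) {
  assert_columns(counts, "gene", "`counts`")
  mat <- as.matrix(counts[setdiff(names(counts), "gene")])
  if (ncol(mat) < 2) abort("need at least 2 samples")
  lib <- colSums(mat)
  if (any(lib == 0)) abort("sample(s) with all-zero counts")

  if (is.null(ref)) {
    uq <- apply(t(t(mat) / lib), 2, quantile, probs = 0.75)
    ref <- colnames(mat)[which.min(abs(uq - mean(uq)))]
  }
  r <- mat[, ref]
  nr <- lib[ref]

  f <- vapply(colnames(mat), function(s) {
    tmm_one(mat[, s], lib[s], r, nr, trim_m, trim_a)
  }, numeric(1))
  f / exp(mean(log(f)))
}

# One sample vs reference, the standard TMM recipe (two-sided rank trim on
# M and A, inverse-asymptotic-variance weights).
tmm_one <- function(x, nx, r, nr, trim_m, trim_a) {
  keep <- x > 0 & r > 0
  x <- x[keep]; r <- r[keep]
  if (length(x) == 0) return(1)
  m <- log2((x / nx) / (r / nr))
  a <- 0.5 * log2((x / nx) * (r / nr))
  w <- (nx - x) / (nx * x) + (nr - r) / (nr * r)

  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)

  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Detect genes re-expressed after epigenetic reactivation
#'
#' Compares the reactivation-treated (RT) phenotype against resistant (R):
#' genes with `logFC(RT - R) >= log2(min_fc)` and BH `q <= alpha` are
#' re-expressed.
#'
#' @inheritParams differential_expression
#' @param group_r,group_rt Group labels for resistant and
#'   reactivation-treated samples.
#' @param min_fc Minimum fold change (linear scale).
#' @return A `de_result` tibble restricted to re-expressed genes.
#' @export
detect_reexpression <- function(values, design, group_r = "R",
                                group_rt = "RT", min_fc = 2, alpha = 0.05) {
  if (!group_rt %in% design$group) {
    abort(sprintf("no `%s` (reactivation-treated) samples in design",
                  group_rt))
  }
  de <- differential_expression(values, design, group_r, group_rt,
                                alpha = alpha)
  filter(de, .data$logFC >= log2(min_fc), .data$q <= alpha)
}

#' Relative expression by the comparative threshold-cycle method
#'
#' `2^-ddCt` with the target gene normalized to an endogenous reference and
#' a calibrator sample:
#' `ddCt = (ct_target_sample - ct_ref_sample) - (ct_target_cal - ct_ref_cal)`.
#'
#' @param ct_target_sample,ct_ref_sample Target/reference Ct in the sample.
#' @param ct_target_cal,ct_ref_cal Target/reference Ct in the calibrator.
#' @return Relative expression (1 at the calibrator).
#' @examples
#' ddct(25, 20, 22, 20) # ddCt = 3 -> 0.125
#' @export
ddct <- function(ct_target_sample, ct_ref_sample, ct_target_cal,
                 ct_ref_cal) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_cal, ct_ref_cal)
  if (any(!is.finite(cts))) abort("Ct values must be finite")
  2^-((ct_target_sample - ct_ref_sample) - (ct_target_cal - ct_ref_cal))
}
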