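test_that("welch test and BH match the reference implementations", {
  set.seed(7)
  vals <- tibble::tibble(gene = sprintf("g%02d", 1:30))
  for (s in c(paste0("a", 1:4), paste0("b", 1:4))) {
    vals[[s]] <- rnorm(30, mean = 8)
  }
  design <- tibble::tibble(sample = setdiff(names(vals), "gene"),
                           group = rep(c("A", "B"), each = 4))
  de <- differential_expression(vals, design, "A", "B")

  for (i in c(1, 13, 30)) {
    ref <- stats::t.test(as.numeric(vals[i, 2:5]),
                         as.numeric(vals[i, 6:9]))
    expect_equal(de$p[i], ref$p.value)
    expect_equal(de$logFC[i],
                 unname(ref$estimate[2] - ref$estimate[1]))
  }
  expect_equal(de$q, stats::p.adjust(de$p, "BH"))
})

test_that("zero-variance ties give p = 1 and group minima are enforced", {
  vals <- tibble::tibble(gene = "g1", a1 = 10, a2 = 10, b1 = 10, b2 = 10)
  design <- tibble::tibble(sample = c("a1", "a2", "b1", "b2"),
                           group = c("A", "A", "B", "B"))
  de <- differential_expression(vals, design, "A", "B")
  expect_equal(de$logFC, 0)
  expect_equal(de$p, 1)

  expect_error(
    differential_expression(vals, design[-1, ], "A", "B"),
    ">= 2 samples"
  )
})

test_that("planted two-fold genes are recovered with high sensitivity", {
  set.seed(11)
  n_gene <- 100; n_de <- 10
  vals <- tibble::tibble(gene = sprintf("g%03d", 1:n_gene))
  shift <- c(rep(1, n_de), rep(0, n_gene - n_de))
  for (s in paste0("a", 1:5)) vals[[s]] <- rnorm(n_gene, 8, 0.25)
  for (s in paste0("b", 1:5)) vals[[s]] <- rnorm(n_gene, 8, 0.25) - shift
  design <- tibble::tibble(sample = setdiff(names(vals), "gene"),
                           group = rep(c("A", "B"), each = 5))
  de <- differential_expression(vals, design, "A", "B")
  expect_gte(mean(de$de[1:n_de]), 0.9)
  # null genes essentially uncalled
  expect_lte(mean(de$de[-(1:n_de)]), 0.05)
})

test_that("duplicate probes collapse to the max-variance probe", {
  vals <- tibble::tibble(
    gene = c("g1", "g1", "g2"),
    s1 = c(1, 5, 3), s2 = c(1.1, 9, 3), s3 = c(0.9, 1, 3)
  )
  expect_warning(out <- collapse_duplicates(vals), "duplicate")
  expect_equal(nrow(out), 2)
  expect_equal(as.numeric(out[out$gene == "g1", -1]), c(5, 9, 1))
})

test_that("cpm_filter implements the 1-CPM-in-6-samples rule", {
  counts <- tibble::tibble(gene = c("hi6", "hi5", "zero"))
  lib <- 1e6
  for (j in 1:8) {
    # gene 1: 2 CPM in 6 samples; gene 2: 2 CPM in 5 samples; gene 3: zero
    counts[[paste0("s", j)]] <- c(ifelse(j <= 6, 2, 0),
                                  ifelse(j <= 5, 2, 0), 0)
    counts[[paste0("s", j)]] <- counts[[paste0("s", j)]] +
      c(0, 0, 0) # keep integers
  }
  # add a filler gene so library sizes are ~1e6 and CPM ~ counts
  filler <- tibble::tibble(gene = "filler")
  for (j in 1:8) filler[[paste0("s", j)]] <- lib
  tbl <- dplyr::bind_rows(counts, filler)
  kept <- cpm_filter(tbl, min_cpm = 1, min_samples = 6)
  expect_true("hi6" %in% kept$gene)
  expect_false("hi5" %in% kept$gene)
  expect_false("zero" %in% kept$gene)

  # monotonicity: raising either threshold never keeps a discarded gene
  k1 <- cpm_filter(tbl, 1, 6)$gene
  expect_true(all(cpm_filter(tbl, 2, 6)$gene %in% k1))
  expect_true(all(cpm_filter(tbl, 1, 7)$gene %in% k1))
  expect_error(cpm_filter(dplyr::mutate(tbl, s1 = -1)), "non-negative")
})

test_that("TMM factors are 1 for identical or depth-scaled libraries", {
  set.seed(5)
  base <- rpois(200, 50)
  counts <- tibble::tibble(gene = sprintf("g%03d", 1:200),
                           a = base, b = base, c = base)
  f <- tmm_factors(counts)
  expect_equal(unname(f), rep(1, 3))
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)

  # pure depth change: M-values all 0 => factors 1
  counts2 <- tibble::tibble(gene = counts$gene, a = base, b = 2L * base)
  expect_equal(unname(tmm_factors(counts2)), c(1, 1))
  expect_error(tmm_factors(tibble::tibble(gene = "g", a = 0L, b = 5L)),
               "all-zero")
})

test_that("TMM matches edgeR on a fixture with a DE block", {
  skip_if_not_installed("edgeR")
  set.seed(8)
  n <- 500
  mat <- cbind(
    a = rpois(n, 40),
    b = rpois(n, c(rep(400, 50), rep(40, n - 50))), # top block DE up in b
    c = rpois(n, 60)
  )
  counts <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%03d", 1:n)),
                             tibble::as_tibble(mat))
  ours <- tmm_factors(counts)
  ref <- edgeR::calcNormFactors(mat, method = "TMM")
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
  expect_equal(exp(mean(log(ours))), 1, tolerance = 1e-12)
})

test_that("re-expression screening keys on RT-vs-R fold and FDR", {
  cfg <- small_cfg(seed = 9, reexpr_effect = 3)
  sim <- generate_genome(cfg)
  ex <- generate_expression(cfg, sim, "cell-line")
  re <- detect_reexpression(ex$values, ex$design)
  expect_setequal(re$gene, sim$truth$gene)

  # degenerate thresholds return every positive-logFC gene
  all_pos <- detect_reexpression(ex$values, ex$design, min_fc = 1, alpha = 1)
  de_rt <- differential_expression(ex$values, ex$design, "R", "RT")
  expect_setequal(all_pos$gene, de_rt$gene[de_rt$logFC >= 0])

  bad_design <- dplyr::filter(ex$design, group != "RT")
  expect_error(detect_reexpression(ex$values, ex$design[
    ex$design$group != "RT", ]), "RT")
})

test_that("ddct implements the comparative-Ct closed form", {
  expect_equal(ddct(25, 20, 25, 20), 1)
  expect_equal(ddct(24, 20, 25, 20), 2)
  expect_equal(ddct(25.2, 20, 22, 20), 2^-3.2)
  expect_error(ddct(Inf, 20, 25, 20), "finite")
})
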