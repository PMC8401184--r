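test_that("compute_beta applies a strict coverage filter", {
  prof <- tibble::tibble(chrom = "chr1", pos = 1:3,
                         meth = c(5, 3, 0), unmeth = c(5, 2, 8))
  out <- compute_beta(prof, min_coverage = 5)
  # 10 > 5 kept, 5 is not > 5 dropped, 8 > 5 kept
  expect_equal(out$pos, c(1L, 3L))
  expect_equal(out$beta, c(0.5, 0))
  expect_error(compute_beta(tibble::tibble(meth = -1, unmeth = 2)),
               "non-negative")
})

test_that("the per-CpG exact test matches fisher.test", {
  # frozen enumeration value for the 2x2 table (9,1 | 1,9)
  expect_equal(test_cpg(9, 1, 1, 9), 0.001093334, tolerance = 1e-6)
  expect_equal(test_cpg(5, 5, 5, 5), 1)
  expect_equal(test_cpg(1, 0, 0, 1), 1)
  expect_warning(p <- test_cpg(0, 0, 3, 4), "empty")
  expect_equal(p, 1)

  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 8), 2)
    if (any(rowSums(tab) == 0)) next
    ours <- test_cpg(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("bh_adjust reproduces the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(bh_adjust(numeric(0)), numeric(0))

  # independent step-up oracle
  set.seed(1)
  p <- runif(50)
  n <- length(p)
  o <- order(p)
  q_o <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q <- numeric(n); q[o] <- pmin(q_o, 1)
  expect_equal(bh_adjust(p), q)
})

test_that("scheme inequalities decide calls as specified", {
  big <- function(beta) {
    tibble::tibble(chrom = "chr1", pos = 1L,
                   meth = round(1000 * beta), unmeth = 1000 - round(1000 * beta))
  }
  # beta_s 0.1, beta_r 0.8: called under readjusted (0.1 < 0.2, delta 0.7 > 0.4)
  out <- call_dm(big(0.1), big(0.8), dm_scheme("readjusted"))
  expect_equal(nrow(out), 1)
  expect_equal(out$direction, "hyper")
  # beta_s 0.25 fails the S bound even with a huge delta
  out2 <- call_dm(big(0.25), big(0.9), dm_scheme("readjusted"))
  expect_equal(nrow(out2), 0)
})

test_that("call_dm equals a row-wise brute-force filter on a random fixture", {
  set.seed(99)
  n <- 500
  prof <- function() tibble::tibble(
    chrom = "chr1", pos = seq_len(n),
    meth = rbinom(n, 30, runif(n)), unmeth = 30 - rbinom(n, 30, 0.5)
  )
  s <- prof(); r <- prof()
  scheme <- dm_scheme("readjusted")
  got <- call_dm(s, r, scheme)

  # independent row-by-row oracle with fisher.test and the step-up formula
  cov_s <- s$meth + s$unmeth; cov_r <- r$meth + r$unmeth
  keep <- cov_s > scheme$min_coverage & cov_r > scheme$min_coverage
  bs <- s$meth[keep] / cov_s[keep]; br <- r$meth[keep] / cov_r[keep]
  p <- mapply(function(a, b, c, d) {
    stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  }, s$meth[keep], s$unmeth[keep], r$meth[keep], r$unmeth[keep])
  q <- stats::p.adjust(p, "BH")
  want <- which(bs < 0.2 & (br - bs) > 0.4 & q < 0.05)
  expect_equal(got$pos, s$pos[keep][want])
  expect_equal(got$q, unname(q[want]))
})

test_that("tightening any scheme bound never adds calls", {
  cfg <- tiny_cfg(seed = 12)
  sim <- generate_genome(cfg)
  s <- generate_wgbs(cfg, sim, "S")
  r <- generate_wgbs(cfg, sim, "R")
  base <- call_dm(s, r, dm_scheme("readjusted"))
  key <- function(x) paste(x$chrom, x$pos)

  tighter <- list(
    dm_scheme("custom", max_beta_s = 0.1, min_delta = 0.4, min_coverage = 5),
    dm_scheme("custom", max_beta_s = 0.2, min_delta = 0.6, min_coverage = 5),
    dm_scheme("custom", max_beta_s = 0.2, min_delta = 0.4, min_coverage = 10),
    dm_scheme("custom", max_beta_s = 0.2, min_delta = 0.4, min_coverage = 5,
              fdr = 0.01)
  )
  for (sch in tighter) {
    expect_true(all(key(call_dm(s, r, sch)) %in% key(base)))
  }
})

test_that("replicates are pooled by count summation", {
  a <- tibble::tibble(chrom = "chr1", pos = 1L, meth = 3, unmeth = 7)
  b <- tibble::tibble(chrom = "chr1", pos = 1L, meth = 4, unmeth = 6)
  r <- tibble::tibble(chrom = "chr1", pos = 1L, meth = 18, unmeth = 2)
  out <- call_dm(list(a, b), r, dm_scheme("readjusted"))
  # pooled S = 7/20 = 0.35 -> fails beta_s < 0.2
  expect_equal(nrow(out), 0)
  pooled <- call_dm(list(a, b), r, dm_scheme("custom", max_beta_s = 0.5,
                                             min_delta = 0.3))
  expect_equal(pooled$beta_s, 0.35)
})

test_that("disjoint coordinate sets yield an empty result with a warning", {
  s <- tibble::tibble(chrom = "chr1", pos = 1:5, meth = 10, unmeth = 10)
  r <- tibble::tibble(chrom = "chr1", pos = 6:10, meth = 10, unmeth = 10)
  expect_warning(out <- call_dm(s, r), "shared")
  expect_equal(nrow(out), 0)
})

test_that("dm_genes tallies per-gene DM CpGs like an independent groupby", {
  cfg <- tiny_cfg(seed = 12)
  sim <- generate_genome(cfg)
  dm <- call_dm(generate_wgbs(cfg, sim, "S"), generate_wgbs(cfg, sim, "R"))
  tbl <- dm_genes(dm, sim$genes, sim$true_cgis)

  ann <- classify_positions(dm, sim$genes, sim$true_cgis)
  ref <- table(ann$gene[!is.na(ann$gene)])
  expect_setequal(tbl$gene, names(ref))
  expect_equal(tbl$n_dm_cpgs[match(names(ref), tbl$gene)],
               unname(as.integer(ref)))
  # planted genes dominate the calls and hit the promoter zone
  expect_true(all(sim$truth$gene %in% tbl$gene))
  expect_true(all(grepl("alpha", tbl$regions[tbl$gene %in% sim$truth$gene])))
})
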