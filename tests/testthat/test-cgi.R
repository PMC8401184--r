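test_that("observed/expected CpG ratio follows the closed form", {
  expect_equal(obs_exp_cpg(cg_island(500)), 2.0)
  expect_equal(obs_exp_cpg(at_fill(500)), 0)
  expect_equal(gc_percent("ACGT"), 50)
  expect_error(obs_exp_cpg("ACGT!!"), "IUPAC")

  set.seed(21)
  seqc <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  cs <- count_seq(seqc)
  expect_equal(obs_exp_cpg(seqc), cs$cpg * cs$n / (cs$c * cs$g))
  expect_equal(gc_percent(seqc), 100 * (cs$c + cs$g) / cs$n)
})

test_that("an engineered island is found and masked islands are skipped", {
  seqc <- paste0(at_fill(2000), cg_island(600), at_fill(2000))
  isl <- find_cgis(c(chr1 = seqc))
  expect_equal(nrow(isl), 1)
  expect_gte(isl$length, 500)
  # detected span sits on the engineered island
  expect_gte(isl$start, 1800)
  expect_lte(isl$end, 2800)

  masked <- paste0(at_fill(2000), tolower(cg_island(600)), at_fill(2000))
  expect_equal(nrow(find_cgis(c(chr1 = masked))), 0)
})

test_that("islands match an exhaustive brute-force scan on short sequences", {
  brute_cgis <- function(seqc, min_gc = 55, min_oe = 0.65, min_len = 500,
                         window = 200) {
    n <- nchar(seqc)
    stat <- function(s, e) {
      cs <- count_seq(substr(seqc, s, e))
      masked <- grepl("[a-z]", substr(seqc, s, e))
      oe <- if (cs$c * cs$g > 0) cs$cpg * cs$n / (cs$c * cs$g) else 0
      list(gc = 100 * (cs$c + cs$g) / cs$n, oe = oe, masked = masked)
    }
    ok_span <- function(s, e) {
      st <- stat(s, e)
      !st$masked && st$gc >= min_gc && st$oe >= min_oe
    }
    covered <- logical(n)
    for (s in seq_len(n - window + 1)) {
      if (ok_span(s, s + window - 1)) covered[s:(s + window - 1)] <- TRUE
    }
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    out <- list()
    for (i in which(runs$values)) {
      if (runs$lengths[i] < min_len) next
      found <- NULL
      # all sub-intervals, longest first, leftmost tie-break
      for (L in seq(runs$lengths[i], min_len)) {
        for (s in starts[i]:(ends[i] - L + 1)) {
          if (ok_span(s, s + L - 1)) { found <- c(s, s + L - 1); break }
        }
        if (!is.null(found)) break
      }
      if (!is.null(found)) out[[length(out) + 1]] <- found
    }
    out
  }

  set.seed(33)
  for (rep in 1:3) {
    seqc <- paste0(
      at_fill(600), cg_island(480 + 60 * rep), at_fill(400),
      paste(sample(c("A", "C", "G", "T"), 800, TRUE,
                   prob = c(.2, .3, .3, .2)), collapse = ""),
      at_fill(500)
    )
    got <- find_cgis(c(chr1 = seqc))
    want <- brute_cgis(seqc)
    expect_equal(nrow(got), length(want))
    for (k in seq_along(want)) {
      expect_equal(c(got$start[k], got$end[k]), want[[k]])
    }
  }
})

test_that("rescanning a reported island returns the same span", {
  seqc <- paste0(at_fill(1500), cg_island(700), at_fill(1500))
  isl <- find_cgis(c(chr1 = seqc))
  expect_equal(nrow(isl), 1)
  again <- find_cgis(c(chr1 = substr(seqc, isl$start, isl$end)))
  expect_equal(nrow(again), 1)
  expect_equal(again$length, isl$length)
})

test_that("positions are classified with alpha > beta > gamma precedence", {
  genes <- tibble::tibble(
    gene = c("Gp", "Gm"), chrom = "chr1", strand = c("+", "-"),
    tss = c(10000L, 40000L), start = c(10000L, 37000L),
    end = c(13000L, 40000L)
  )
  islands <- tibble::tibble(island = "CGI_1", chrom = "chr1",
                            start = 20000L, end = 20800L)
  zone_of <- function(pos) {
    classify_positions(tibble::tibble(chrom = "chr1", pos = pos),
                       genes, islands)$zone
  }
  # TSS itself is promoter on either strand
  expect_equal(zone_of(10000L), "alpha")
  expect_equal(zone_of(40000L), "alpha")
  # promoter window follows gene orientation
  expect_equal(zone_of(10000L - 2000L), "alpha")
  expect_equal(zone_of(10000L + 500L), "alpha")
  expect_equal(zone_of(40000L + 2000L), "alpha")
  # shore at 1 kb, shelf at 3 kb upstream of the island start
  expect_equal(zone_of(20000L - 1000L), "beta_shore")
  expect_equal(zone_of(20000L - 3000L), "beta_shelf")
  # mid-gene-body, far from TSS and islands
  expect_equal(zone_of(12800L), "gamma")
  expect_equal(zone_of(5000L), "none")
  expect_error(zone_of_bad <- classify_positions(
    tibble::tibble(chrom = "chrX", pos = 1L), genes, islands
  ), "undeclared")
})

test_that("each position receives exactly one zone and alpha wins overlaps", {
  # promoter of gene B inside the body of gene A
  genes <- tibble::tibble(
    gene = c("A", "B"), chrom = "chr1", strand = "+",
    tss = c(1000L, 6000L), start = c(1000L, 6000L), end = c(9000L, 8000L)
  )
  ann <- classify_positions(tibble::tibble(chrom = "chr1", pos = 5500L),
                            genes, NULL)
  expect_equal(ann$zone, "alpha")
  expect_equal(ann$gene, "B")
})

test_that("promoter CGI flags equal an interval-overlap oracle", {
  cfg <- tiny_cfg(seed = 14)
  sim <- generate_genome(cfg)
  islands <- find_cgis(sim$genome)
  got <- promoter_has_cgi(sim$genes, islands)

  for (i in seq_len(nrow(sim$genes))) {
    g <- sim$genes[i, ]
    win <- if (g$strand == "+") c(g$tss - 2000, g$tss + 500) else
      c(g$tss - 500, g$tss + 2000)
    want <- any(islands$chrom == g$chrom &
                  pmax(islands$start, win[1]) <= pmin(islands$end, win[2]))
    expect_equal(got$promoter_cgi[i], want)
  }
  # a gene with no nearby island is not flagged
  far <- tibble::tibble(gene = "far", chrom = "chr1", strand = "+",
                        tss = 99L, start = 99L, end = 200L)
  lone <- tibble::tibble(island = "CGI_1", chrom = "chr1",
                         start = 10099L, end = 10700L)
  expect_false(promoter_has_cgi(far, lone)$promoter_cgi)
  # island spanning the TSS is flagged
  expect_true(promoter_has_cgi(
    far, tibble::tibble(island = "CGI_1", chrom = "chr1",
                        start = 50L, end = 600L)
  )$promoter_cgi)
})
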