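test_that("patient selection applies every active criterion", {
  cl <- tibble::tibble(
    patient = c("ok", "late_death", "no_plat", "no_expr", "alive"),
    platinum = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    os_days = c(900, 1200, 900, 900, 900),
    os_event = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    relapse_days = c(100, 100, 100, 100, 100),
    has_expression = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    has_methylation = TRUE
  )
  expect_equal(select_patients(cl, "approach1"), "ok")
  # approach2 keys on relapse and both data layers, not on death
  expect_setequal(select_patients(cl, "approach2"),
                  c("ok", "late_death", "alive"))
  expect_error(select_patients(cl[, -2], "approach1"), "platinum")
  expect_error(cohort_criteria("custom", require_platinum = FALSE),
               "at least one")
})

test_that("selection equals a row-wise predicate oracle on a synthetic cohort", {
  cfg <- tiny_cfg(seed = 21)
  sim <- generate_genome(cfg)
  cl <- generate_cohort(cfg, sim)$clinical
  got <- select_patients(cl, "approach1")
  want <- cl$patient[cl$platinum & cl$os_event & cl$os_days <= 1100 &
                       cl$has_expression]
  expect_identical(got, want)

  got2 <- select_patients(cl, "approach2")
  want2 <- cl$patient[cl$platinum & cl$relapse_days <= 183 &
                        cl$has_expression & cl$has_methylation]
  expect_identical(got2, want2)
})

test_that("the funnel intersects stages in order and reports percentages", {
  # stage sizes engineered as 100 -> 80 -> 70 -> 66 -> 29
  g <- sprintf("g%03d", 1:100)
  fun <- run_funnel(
    de_genes = g,
    cohort_genes = g[1:80],
    reexpressed_genes = g[1:70],
    promoter_cgi_genes = g[1:66],
    dm_gene_table = tibble::tibble(gene = g[1:29], n_dm_cpgs = 5L,
                                   regions = "alpha", max_abs_delta = 0.5)
  )
  expect_equal(fun$stages$n, c(100, 80, 70, 66, 29))
  # 29 of 66 prints as 44% at nearest-integer rounding
  expect_equal(fun$stages$pct_prev[5], 44)
  expect_true(all(diff(fun$stages$n) <= 0))
  expect_equal(nrow(fun$candidates), 29)

  empty <- run_funnel(g[1:5], g[6:10], g, g, tibble::tibble(
    gene = g, n_dm_cpgs = 1L, regions = "alpha", max_abs_delta = 0.1
  ))
  expect_equal(empty$stages$n[2], 0)
  expect_equal(nrow(empty$candidates), 0)
})

test_that("funnel survivors cover planted genes passing all layers", {
  res <- run_pipeline(small_cfg(seed = 2))
  truth <- res$truth$gene
  passing <- Reduce(intersect, list(
    res$de$gene[res$de$de], res$cohort_de$gene, res$reexpressed$gene,
    res$promoter_cgi$gene[res$promoter_cgi$promoter_cgi],
    res$dm_gene_table$gene
  ))
  expect_setequal(res$funnel$candidates$gene, passing)
  expect_true(all(intersect(truth, passing) %in%
                    res$funnel$candidates$gene))
})

test_that("contrast evaluation equals brute-force set algebra", {
  expect_equal(
    evaluate_contrasts(
      list(list(name = "ab", layers = list(A = NULL, B = NULL))),
      list(A = c("g1", "g2"), B = c("g2", "g3"))
    ),
    list(ab = "g2")
  )

  # a direction filter removes genes before intersection
  layers <- list(
    meth = tibble::tibble(gene = c("g1", "g2"),
                          direction = c("hyper", "hypo")),
    expr = tibble::tibble(gene = c("g1", "g2"),
                          direction = c("down", "down"))
  )
  spec <- list(list(name = "hi", layers = list(meth = "hyper",
                                               expr = "down")))
  expect_equal(evaluate_contrasts(spec, layers), list(hi = "g1"))

  expect_error(
    evaluate_contrasts(list(list(name = "x", layers = list(nope = NULL))),
                       layers),
    "unknown layer"
  )

  # random sets vs independent set algebra
  set.seed(17)
  pool <- sprintf("g%03d", 1:60)
  for (i in 1:20) {
    a <- sample(pool, 30); b <- sample(pool, 30); c <- sample(pool, 30)
    got <- evaluate_contrasts(
      list(list(name = "abc", layers = list(A = NULL, B = NULL, C = NULL))),
      list(A = a, B = b, C = c)
    )$abc
    want <- sort(pool[pool %in% a & pool %in% b & pool %in% c])
    expect_setequal(got, want)
  }
})

test_that("the shipped catalogue parses into 24 grouped contrasts", {
  specs <- default_contrasts()
  expect_length(specs, 24)
  expect_setequal(unique(purrr::map_chr(specs, "group")),
                  c("group1", "group2", "group3"))
  expect_length(default_contrasts(group = "group2"), 8)
  # direction filters survive parsing; "any" becomes NULL
  g1 <- specs[[1]]
  expect_equal(g1$layers$wgbs_dm, "hyper")
  any_spec <- purrr::detect(specs, ~ .x$name == "g1_dm_any_inhibited")
  expect_null(any_spec$layers$wgbs_dm)
})

test_that("the position filter keeps only counts strictly above the cutoff", {
  cand <- tibble::tibble(gene = c("a", "b", "c"),
                         n_dm_cpgs = c(10L, 11L, 3L))
  expect_equal(filter_min_positions(cand)$gene, "b")
  expect_equal(nrow(filter_min_positions(cand[0, ])), 0)
  # predicate oracle
  set.seed(3)
  cand2 <- tibble::tibble(gene = sprintf("g%02d", 1:40),
                          n_dm_cpgs = rpois(40, 10))
  expect_identical(filter_min_positions(cand2, 8)$gene,
                   cand2$gene[cand2$n_dm_cpgs > 8])
})

test_that("candidates rank by recurrence with deterministic tie-breaks", {
  sets <- list(c1 = c("a", "b"), c2 = c("a", "b"), c3 = c("a", "c"),
               c4 = "a", c5 = "a")
  dm_tbl <- tibble::tibble(
    gene = c("a", "b", "c"), n_dm_cpgs = c(5L, 12L, 12L),
    regions = "alpha", max_abs_delta = c(0.5, 0.6, 0.6)
  )
  rk <- rank_candidates(sets, dm_tbl)
  expect_equal(rk$gene[1], "a") # in 5 contrasts vs 2 and 1
  expect_equal(rk$recurrence, c(5L, 2L, 1L))

  # full tie on all keys except id falls back to lexicographic order
  tie <- rank_candidates(list(c1 = c("z", "y")), tibble::tibble(
    gene = c("z", "y"), n_dm_cpgs = 4L, regions = "alpha",
    max_abs_delta = 0.3
  ))
  expect_equal(tie$gene, c("y", "z"))

  # independent stable multi-key sort oracle
  set.seed(31)
  genes <- sprintf("g%02d", 1:25)
  sets2 <- purrr::map(1:6, ~ sample(genes, 12))
  names(sets2) <- paste0("c", 1:6)
  dm2 <- tibble::tibble(gene = genes, n_dm_cpgs = rpois(25, 6),
                        regions = "alpha",
                        max_abs_delta = round(runif(25), 2))
  rk2 <- rank_candidates(sets2, dm2)
  tally <- table(unlist(lapply(sets2, unique)))
  df <- data.frame(gene = names(tally), rec = as.integer(tally))
  df <- merge(df, as.data.frame(dm2), by = "gene")
  ord <- df[order(-df$rec, -df$n_dm_cpgs, -df$max_abs_delta, df$gene), ]
  expect_equal(rk2$gene, ord$gene)
})
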