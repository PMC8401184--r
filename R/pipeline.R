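#' Patient 450K-style differential methylation
#'
#' Per-gene Welch t-test of array beta values between methylated and
#' unmethylated patients with BH adjustment; genes pass at `q <= alpha`
#' and mean beta difference at least `min_delta` in magnitude.
#'
#' @param beta Tibble `gene` + one column per patient (beta values).
#' @param groups Tibble `patient, methylated` (logical).
#' @param min_delta Minimum |mean beta difference|.
#' @param alpha FDR cutoff.
#' @return Tibble `gene, delta, q, direction` (`hyper` = higher beta in
#'   methylated patients).
#' @export
dm_450k <- function(beta, groups, min_delta = 0.2, alpha = 0.05) {
  assert_columns(beta, "gene", "`beta`")
  assert_columns(groups, c("patient", "methylated"), "`groups`")
  design <- tibble(sample = groups$patient,
                   group = if_else(groups$methylated, "meth", "unmeth"))
  de <- differential_expression(beta, design, "unmeth", "meth",
                                alpha = alpha)
  de |>
    mutate(delta = .data$logFC,
           direction = if_else(.data$delta >= 0, "hyper", "hypo")) |>
    filter(.data$q <= alpha, abs(.data$delta) >= min_delta) |>
    select("gene", "delta", "q", "direction")
}

#' Run the full discovery pipeline on a synthetic study
#'
#' Simulates the study defined by `cfg` and runs every stage end to end:
#' WGBS differential methylation (S vs R) under `scheme`, CpG-island
#' detection and promoter/shore/shelf/gene-body annotation, cell-line
#' differential expression and re-expression after reactivation, cohort
#' selection and cohort-level differential expression, the candidate
#' funnel, the cross-study contrast catalogue with recurrence ranking, and
#' Kaplan-Meier survival stratified by methylation. With `out_dir` set,
#' all artifacts are written as headered text files (FASTA, BED, TSV,
#' JSON); reruns with the same config are byte-identical.
#'
#' @param cfg A [sim_config()].
#' @param scheme A [dm_scheme()] or preset name.
#' @param criteria A [cohort_criteria()] or preset name.
#' @param contrasts Contrast specs (default: the shipped catalogue).
#' @param min_fc Re-expression fold-change cutoff.
#' @param promoter_up,promoter_down Promoter window (bp around TSS).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param quiet Suppress stage messages.
#' @return An `epiresist_pipeline` list: simulation inputs (`sim`,
#'   `truth`), per-stage results (`dm`, `islands`, `dm_gene_table`,
#'   `de`, `reexpressed`, `cohort`, `selected`, `cohort_de`, `funnel`,
#'   `contrast_sets`, `ranking`, `km`, `logrank`) and the effective
#'   configuration.
#' @examples
#' \donttest{
#' res <- run_pipeline(sim_config(seed = 1, n_genes = 40, n_planted = 3,
#'                                chrom_len = 4e5))
#' res$funnel
#' }
#' @export
run_pipeline <- function(cfg = sim_config(),
                         scheme = dm_scheme("readjusted"),
                         criteria = cohort_criteria("approach1"),
                         contrasts = NULL,
                         min_fc = 2,
                         promoter_up = 2000, promoter_down = 500,
                         out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.character(scheme)) scheme <- dm_scheme(scheme)
  if (is.character(criteria)) criteria <- cohort_criteria(criteria)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("simulating genome (%d genes, %d planted)", cfg$n_genes, cfg$n_planted)
  sim <- generate_genome(cfg)
  wgbs <- purrr::map(setNames(c("S", "R", "RT"), c("S", "R", "RT")),
                     ~ generate_wgbs(cfg, sim, .x))

  say("calling differential methylation (scheme %s)", scheme$name)
  dm <- call_dm(wgbs$S, wgbs$R, scheme)

  say("scanning CpG islands")
  islands <- find_cgis(sim$genome)
  islands_assigned <- assign_islands(islands, sim$genes)
  dm_gene_table <- dm_genes(dm, sim$genes, islands_assigned,
                            promoter_up, promoter_down)
  prom <- promoter_has_cgi(sim$genes, islands, promoter_up, promoter_down)

  say("expression screening")
  expr_cell <- generate_expression(cfg, sim, "cell-line")
  de <- differential_expression(expr_cell$values, expr_cell$design, "S", "R")
  reexpr <- detect_reexpression(expr_cell$values, expr_cell$design,
                                min_fc = min_fc)

  say("cohort selection and expression")
  cohort <- generate_cohort(cfg, sim)
  expr_cohort <- generate_expression(cfg, sim, "cohort", cohort = cohort)
  selected <- select_patients(cohort$clinical, criteria)
  cohort_de <- cohort_de_genes(expr_cohort, selected)

  say("candidate funnel")
  funnel <- run_funnel(
    de_genes = de$gene[de$de],
    cohort_genes = cohort_de$gene,
    reexpressed_genes = reexpr$gene,
    promoter_cgi_genes = prom$gene[prom$promoter_cgi],
    dm_gene_table = dm_gene_table
  )

  say("contrast matrix and ranking")
  layers <- build_layers(dm, dm_gene_table, de, cohort_de, cohort,
                         expr_cohort, sim)
  contrasts <- contrasts %||% default_contrasts()
  contrast_sets <- evaluate_contrasts(contrasts, layers)
  ranking <- rank_candidates(contrast_sets, dm_gene_table)

  say("survival analysis")
  strata <- stratify_by_methylation(cohort$clinical, "os")
  km <- km_estimate(strata)
  lr <- if (length(unique(strata$group)) == 2) logrank_test(strata) else NULL

  res <- structure(list(
    config = cfg, scheme = scheme, criteria = criteria,
    sim = sim, truth = sim$truth, wgbs = wgbs, dm = dm,
    islands = islands, dm_gene_table = dm_gene_table,
    promoter_cgi = prom, de = de, reexpressed = reexpr,
    cohort = cohort, selected = selected, cohort_de = cohort_de,
    funnel = funnel, contrast_sets = contrast_sets, ranking = ranking,
    km = km, logrank = lr
  ), class = "epiresist_pipeline")

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Assign each detected island to the gene whose promoter or body it
# overlaps (first match), for strand-aware shore/shelf orientation.
assign_islands <- function(islands, genes) {
  if (nrow(islands) == 0) return(mutate(islands, gene = character(0)))
  gene_of <- vapply(seq_len(nrow(islands)), function(i) {
    hit <- which(genes$chrom == islands$chrom[i] &
                   genes$start - 2000 <= islands$end[i] &
                   genes$end + 2000 >= islands$start[i])
    if (length(hit) > 0) genes$gene[hit[1]] else NA_character_
  }, character(1))
  mutate(islands, gene = gene_of)
}

build_layers <- function(dm, dm_gene_table, de, cohort_de, cohort,
                         expr_cohort, sim) {
  # WGBS gene-level direction: a gene is hyper when any of its DM CpGs is
  wgbs_dir <- if (nrow(dm) == 0) {
    tibble(gene = character(), direction = character())
  } else {
    classify_positions(dm, sim$genes, NULL) |>
      filter(!is.na(.data$gene)) |>
      group_by(.data$gene) |>
      summarise(direction = if_else(any(.data$delta > 0), "hyper", "hypo"),
                .groups = "drop")
  }

  k450 <- dm_450k(cohort$beta, rename(cohort$clinical,
                                      methylated = "msp_call") |>
                    select("patient", "methylated"))

  # cohort RNA-seq DE, resistant vs sensitive tumors (log2 CPM)
  vals <- expr_cohort$values
  mat <- as.matrix(vals[setdiff(names(vals), "gene")])
  logcpm <- log2(t(t(mat + 0.5) / (colSums(mat) + 1)) * 1e6)
  tumor <- intersect(colnames(mat), cohort$clinical$patient)
  rs_design <- tibble(
    sample = tumor,
    group = if_else(
      cohort$clinical$resistant[match(tumor, cohort$clinical$patient)],
      "resistant", "sensitive"
    )
  )
  rnaseq_de <- differential_expression(
    bind_cols(tibble(gene = vals$gene),
              as_tibble(logcpm[, tumor, drop = FALSE])),
    rs_design, "sensitive", "resistant"
  ) |>
    filter(.data$de) |>
    mutate(direction = if_else(.data$logFC >= 0, "up", "down"))

  list(
    wgbs_dm = wgbs_dir,
    array_de = filter(de, .data$de) |> select("gene", "direction"),
    cohort_de = select(cohort_de, "gene", "direction"),
    k450_dm = select(k450, "gene", "direction"),
    rnaseq_de = select(rnaseq_de, "gene", "direction")
  )
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  hdr <- output_header(cfg$seed, config_hash(unclass(cfg)))
  fp <- function(name) file.path(out_dir, name)

  write_fasta(res$sim$genome, fp("genome.fa"))
  write_gene_models(res$sim$genes, fp("genes.bed"), header = hdr)
  purrr::iwalk(res$wgbs, function(tbl, ph) {
    write_cpg_report(tbl, fp(sprintf("wgbs_%s.tsv", ph)), header = hdr)
  })
  write_bed(
    res$islands |> mutate(name = .data$island),
    fp("islands.bed"), header = hdr
  )
  if (nrow(res$dm) > 0) {
    write_bed(
      tibble(chrom = res$dm$chrom, start = res$dm$pos, end = res$dm$pos,
             name = sprintf("dm_%d", seq_len(nrow(res$dm))),
             score = round(1000 * res$dm$delta)),
      fp("dm_cpgs.bed"), header = hdr
    )
  }
  write_matrix(res$dm_gene_table, fp("dm_genes.tsv"), header = hdr)
  write_matrix(res$de, fp("de.tsv"), header = hdr)
  write_matrix(res$cohort$clinical, fp("clinical.tsv"), header = hdr)
  write_matrix(res$ranking, fp("candidates.tsv"), header = hdr)
  write_matrix(res$km, fp("km.tsv"), header = hdr)
  jsonlite::write_json(
    list(
      version = as.character(packageVersion("epiresist")),
      seed = cfg$seed, config = config_hash(unclass(cfg)),
      stages = res$funnel$stages,
      candidates = res$funnel$candidates$gene,
      logrank_p = if (!is.null(res$logrank)) res$logrank$p_value else NA
    ),
    fp("funnel.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.epiresist_pipeline <- function(x, ...) {
  cat(sprintf(
    "epiresist pipeline (seed %d: %d genes, %d planted, %d patients)\n",
    x$config$seed, x$config$n_genes, x$config$n_planted,
    x$config$n_patients
  ))
  print(x$funnel)
  cat(sprintf("Top candidate: %s\n",
              if (nrow(x$ranking) > 0) x$ranking$gene[1] else "<none>"))
  if (!is.null(x$logrank)) {
    cat(sprintf("Log-rank (methylated vs unmethylated OS): p = %.3g\n",
                x$logrank$p_value))
  }
  invisible(x)
}

#' Recovery of planted genes by the pipeline
#'
#' Compares the funnel's surviving candidates with the planted ground
#' truth: sensitivity = recovered / planted, precision = recovered /
#' reported, plus whether the top-ranked contrast candidate is planted.
#'
#' @param res An `epiresist_pipeline` result.
#' @return Tibble `sensitivity, precision, n_candidates, top_is_planted`.
#' @export
recovery_stats <- function(res) {
  stopifnot(inherits(res, "epiresist_pipeline"))
  planted <- res$truth$gene
  found <- res$funnel$candidates$gene
  tp <- length(intersect(found, planted))
  tibble(
    sensitivity = if (length(planted) > 0) tp / length(planted) else NA_real_,
    precision = if (length(found) > 0) tp / length(found) else NA_real_,
    n_candidates = length(found),
    top_is_planted = nrow(res$ranking) > 0 &&
      res$ranking$gene[1] %in% planted
  )
}
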