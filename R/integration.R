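#' Cohort selection criteria
#'
#' Presets for selecting analyzable patients:
#' * `approach1` — platinum-treated, death within 1100 days, expression
#'   data available;
#' * `approach2` — platinum-treated, expression (RNA-seq) and methylation
#'   (450K) data available, relapse within 6 months (183 days).
#'
#' @param preset `"approach1"`, `"approach2"` or `"custom"`.
#' @param require_platinum Require platinum treatment.
#' @param max_death_days Require death (event) within this many days, or
#'   `NULL`.
#' @param max_relapse_days Require relapse within this many days, or
#'   `NULL`.
#' @param require_expression,require_methylation Require the data layer.
#' @return A `cohort_criteria` list.
#' @examples
#' cohort_criteria("approach1")
#' @export
cohort_criteria <- function(preset = c("approach1", "approach2", "custom"),
                            require_platinum = TRUE,
                            max_death_days = NULL,
                            max_relapse_days = NULL,
                            require_expression = FALSE,
                            require_methylation = FALSE) {
  preset <- match.arg(preset)
  out <- switch(preset,
    approach1 = list(require_platinum = TRUE, max_death_days = 1100,
                     max_relapse_days = NULL, require_expression = TRUE,
                     require_methylation = FALSE),
    approach2 = list(require_platinum = TRUE, max_death_days = NULL,
                     max_relapse_days = 183, require_expression = TRUE,
                     require_methylation = TRUE),
    custom = list(require_platinum = require_platinum,
                  max_death_days = max_death_days,
                  max_relapse_days = max_relapse_days,
                  require_expression = require_expression,
                  require_methylation = require_methylation)
  )
  active <- out$require_platinum || !is.null(out$max_death_days) ||
    !is.null(out$max_relapse_days) || out$require_expression ||
    out$require_methylation
  if (!active) abort("at least one selection requirement must be set")
  structure(c(list(preset = preset), out), class = "cohort_criteria")
}

#' Select patients meeting cohort criteria
#'
#' Applies every active requirement of a [cohort_criteria()] as a row-wise
#' predicate: platinum treatment, death (event) within the death window,
#' relapse within the relapse window, availability of expression /
#' methylation data.
#'
#' @param clinical Clinical tibble (see [generate_cohort()] for the
#'   schema).
#' @param criteria A [cohort_criteria()] or preset name.
#' @return Character vector of selected patient ids.
#' @export
select_patients <- function(clinical, criteria = cohort_criteria("approach1")) {
  if (is.character(criteria)) criteria <- cohort_criteria(criteria)
  stopifnot(inherits(criteria, "cohort_criteria"))
  need <- c("patient",
            if (criteria$require_platinum) "platinum",
            if (!is.null(criteria$max_death_days)) c("os_days", "os_event"),
            if (!is.null(criteria$max_relapse_days)) "relapse_days",
            if (criteria$require_expression) "has_expression",
            if (criteria$require_methylation) "has_methylation")
  assert_columns(clinical, need, "`clinical`")

  keep <- rep(TRUE, nrow(clinical))
  if (criteria$require_platinum) keep <- keep & clinical$platinum
  if (!is.null(criteria$max_death_days)) {
    keep <- keep & clinical$os_event &
      clinical$os_days <= criteria$max_death_days
  }
  if (!is.null(criteria$max_relapse_days)) {
    keep <- keep & clinical$relapse_days <= criteria$max_relapse_days
  }
  if (criteria$require_expression) keep <- keep & clinical$has_expression
  if (criteria$require_methylation) keep <- keep & clinical$has_methylation
  clinical$patient[keep]
}

#' Cohort-level differential genes present in every selected patient
#'
#' Emulates the "present in all selected patients" funnel stage: a gene
#' qualifies when it is differentially expressed between tumors and
#' controls at the cohort level (Welch t + BH, `q <= alpha`) and its
#' per-patient direction (sign of the patient's log2 CPM deviation from
#' the mean control profile) is consistent in at least
#' `direction_fraction` of the selected patients.
#'
#' @param expr Cohort expression list (`values`, `design`) with
#'   tumor/control groups (counts).
#' @param selected Character vector of selected patient ids (tumor
#'   samples).
#' @param direction_fraction Required fraction of selected patients
#'   sharing the cohort-level direction (default 1 = all).
#' @param alpha FDR cutoff.
#' @return Tibble `gene, logFC, q, direction, frac_consistent`.
#' @export
cohort_de_genes <- function(expr, selected, direction_fraction = 1,
                            alpha = 0.05) {
  values <- expr$values
  design <- expr$design
  selected <- intersect(selected, design$sample[design$group == "tumor"])
  if (length(selected) == 0) {
    return(tibble(gene = character(), logFC = numeric(), q = numeric(),
                  direction = character(), frac_consistent = numeric()))
  }
  # cohort-level test on log2 CPM
  mat <- as.matrix(values[setdiff(names(values), "gene")])
  logcpm <- log2(t(t(mat + 0.5) / (colSums(mat) + 1)) * 1e6)
  log_values <- bind_cols(tibble(gene = values$gene), as_tibble(logcpm))
  de <- differential_expression(log_values, design, "control", "tumor",
                                alpha = alpha)

  ctrl <- design$sample[design$group == "control"]
  ctrl_mean <- rowMeans(logcpm[, ctrl, drop = FALSE])
  dev <- logcpm[, selected, drop = FALSE] - ctrl_mean
  frac_down <- rowMeans(dev < 0)
  frac_up <- rowMeans(dev > 0)
  frac <- if_else(de$direction == "down", frac_down, frac_up)

  de |>
    mutate(frac_consistent = frac) |>
    filter(.data$de, .data$frac_consistent >= direction_fraction) |>
    select("gene", "logFC", "q", "direction", "frac_consistent")
}

#' Run the candidate-gene funnel
#'
#' Sequential intersection of the in-vitro differential-expression genes
#' with (1) the cohort differential set, (2) the re-expressed-after-
#' reactivation set, (3) the genes with a CpG island in the promoter and
#' (4) the differentially methylated genes. Reports each stage's size and
#' its nearest-integer percentage of the previous stage.
#'
#' @param de_genes Genes differentially expressed R vs S (character).
#' @param cohort_genes Cohort-supported genes (character).
#' @param reexpressed_genes Re-expressed genes (character).
#' @param promoter_cgi_genes Genes with a promoter CpG island (character).
#' @param dm_gene_table Output of [dm_genes()] (or a character vector).
#' @return A `funnel_result` list: `stages` (tibble `stage, n, pct_prev`)
#'   and `candidates` (tibble `gene, n_dm_cpgs, regions, max_abs_delta`
#'   for the survivors).
#' @export
run_funnel <- function(de_genes, cohort_genes, reexpressed_genes,
                       promoter_cgi_genes, dm_gene_table) {
  dm_tbl <- if (is.character(dm_gene_table)) {
    tibble(gene = dm_gene_table, n_dm_cpgs = NA_integer_,
           regions = NA_character_, max_abs_delta = NA_real_)
  } else {
    dm_gene_table
  }
  sets <- list(
    differential = unique(de_genes),
    cohort = intersect(unique(de_genes), cohort_genes),
    reexpressed = character(), promoter_cgi = character(),
    dm = character()
  )
  sets$reexpressed <- intersect(sets$cohort, reexpressed_genes)
  sets$promoter_cgi <- intersect(sets$reexpressed, promoter_cgi_genes)
  sets$dm <- intersect(sets$promoter_cgi, dm_tbl$gene)

  n <- vapply(sets, length, integer(1))
  pct_prev <- c(NA, round(100 * n[-1] / pmax(n[-length(n)], 1)))
  pct_prev[is.nan(pct_prev)] <- NA
  stages <- tibble(stage = names(sets), n = unname(n),
                   pct_prev = unname(pct_prev))

  candidates <- dm_tbl |>
    filter(.data$gene %in% sets$dm) |>
    arrange(.data$gene)
  structure(list(stages = stages, candidates = candidates),
            class = "funnel_result")
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("Candidate funnel:\n")
  for (i in seq_len(nrow(x$stages))) {
    pct <- if (is.na(x$stages$pct_prev[i])) "" else {
      sprintf(" (%d%% of previous)", x$stages$pct_prev[i])
    }
    cat(sprintf("  %-13s %5d%s\n", x$stages$stage[i], x$stages$n[i], pct))
  }
  invisible(x)
}

#' Evaluate named multi-omics contrasts
#'
#' Each contrast intersects a set of data layers, optionally filtering a
#' layer to one direction (`hyper`/`hypo`, `up`/`down`) before the
#' intersection. Layers are tibbles with a `gene` column and (optionally)
#' a `direction` column, or plain character vectors.
#'
#' @param specs A list of contrast specifications, each a list with
#'   `name` and `layers` (named list mapping layer name to `NULL` for no
#'   direction filter or a direction string), e.g. as returned by
#'   [default_contrasts()].
#' @param layers Named list of available layers.
#' @return Named list of character gene-id vectors, one per contrast.
#' @export
evaluate_contrasts <- function(specs, layers) {
  purrr::map(setNames(specs, purrr::map_chr(specs, "name")),
             function(spec) {
    sets <- purrr::imap(spec$layers, function(dir, layer_name) {
      if (!layer_name %in% names(layers)) {
        abort(sprintf("contrast `%s` references unknown layer `%s`",
                      spec$name, layer_name))
      }
      layer <- layers[[layer_name]]
      if (is.character(layer)) {
        if (!is.null(dir)) {
          abort(sprintf("layer `%s` has no direction information",
                        layer_name))
        }
        return(unique(layer))
      }
      assert_columns(layer, "gene", sprintf("layer `%s`", layer_name))
      if (!is.null(dir)) {
        layer <- filter(layer, .data$direction == dir)
      }
      unique(layer$gene)
    })
    Reduce(intersect, sets)
  })
}

#' Load the shipped contrast catalogue
#'
#' Reads the package's built-in YAML catalogue of 24 named cross-study
#' contrasts, organised in three groups by the data layers they combine
#' (group 1: WGBS + expression array + cohort; group 2: 450K + RNA-seq +
#' cohort; group 3: all four layers), with direction filters such as
#' hypermethylated + inhibited or hypomethylated + overexpressed.
#'
#' @param path Optional path to a user YAML catalogue with the same
#'   structure.
#' @param group Optional filter: `"group1"`, `"group2"` or `"group3"`.
#' @return List of contrast specifications for [evaluate_contrasts()].
#' @export
default_contrasts <- function(path = NULL, group = NULL) {
  path <- path %||% system.file("extdata", "contrasts.yaml",
                                package = "epiresist")
  raw <- yaml::read_yaml(path)
  specs <- purrr::map(raw$contrasts, function(x) {
    layers <- purrr::map(x$layers, function(d) {
      if (identical(d, "any")) NULL else d
    })
    list(name = x$name, group = x$group, layers = layers)
  })
  if (!is.null(group)) {
    specs <- purrr::keep(specs, ~ identical(.x$group, group))
  }
  specs
}

#' Filter candidates by minimum methylated-position count
#'
#' Keeps candidates with strictly more than `min_positions`
#' differentially methylated CpG positions.
#'
#' @param candidates Tibble with an `n_dm_cpgs` column.
#' @param min_positions Count that must be exceeded (default 10).
#' @return Filtered tibble.
#' @export
filter_min_positions <- function(candidates, min_positions = 10) {
  assert_columns(candidates, "n_dm_cpgs", "`candidates`")
  filter(candidates, .data$n_dm_cpgs > min_positions)
}

#' Rank candidate genes by cross-study recurrence
#'
#' Orders candidates by the number of contrasts containing them
#' (descending), breaking ties by DM-CpG count (descending), maximum
#' absolute delta-beta (descending) and finally gene id (ascending) — a
#' deterministic total order.
#'
#' @param contrast_sets Named list of gene-id vectors (from
#'   [evaluate_contrasts()]).
#' @param dm_gene_table Output of [dm_genes()].
#' @return Tibble `gene, recurrence, n_dm_cpgs, regions, max_abs_delta,
#'   contrasts, rank`.
#' @export
rank_candidates <- function(contrast_sets, dm_gene_table) {
  if (length(contrast_sets) == 0) abort("no contrasts evaluated")
  membership <- purrr::imap(contrast_sets,
                            ~ tibble(gene = .x, contrast = .y)) |>
    bind_rows()
  if (nrow(membership) == 0) {
    return(tibble(gene = character(), recurrence = integer(),
                  n_dm_cpgs = integer(), regions = character(),
                  max_abs_delta = numeric(), contrasts = character(),
                  rank = integer()))
  }
  membership |>
    group_by(.data$gene) |>
    summarise(recurrence = dplyr::n(),
              contrasts = paste(sort(.data$contrast), collapse = ","),
              .groups = "drop") |>
    left_join(dm_gene_table, by = "gene") |>
    mutate(
      n_dm_cpgs = dplyr::coalesce(.data$n_dm_cpgs, 0L),
      max_abs_delta = dplyr::coalesce(.data$max_abs_delta, 0)
    ) |>
    arrange(desc(.data$recurrence), desc(.data$n_dm_cpgs),
            desc(.data$max_abs_delta), .data$gene) |>
    mutate(rank = row_number()) |>
    select("gene", "recurrence", "n_dm_cpgs", dplyr::any_of("regions"),
           "max_abs_delta", "contrasts", "rank")
}
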