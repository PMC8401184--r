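#' Simulate an expression matrix for the cell-line or cohort design
#'
#' Cell-line design: log2 intensities for `n_rep` replicates of the S, R and
#' RT phenotypes; planted genes are down by `expr_effect` log2 units in R vs S
#' and up by `reexpr_effect` in RT vs R, with Gaussian noise `expr_sd`.
#'
#' Cohort design: integer counts (for the CPM/TMM path) for one tumor sample
#' per patient plus `n_controls` normal controls; planted genes are silenced
#' by `expr_effect` log2 units in every tumor (epigenetic silencing is
#' tumor-intrinsic), with lognormal library-size variation.
#'
#' @param cfg A [sim_config()].
#' @param sim Output of [generate_genome()].
#' @param design `"cell-line"` or `"cohort"`.
#' @param cohort For `design = "cohort"`, the output of [generate_cohort()];
#'   only used for patient ids (optional — defaults to `P0001..`).
#' @return A list: `values` (tibble, `gene` column then one column per
#'   sample) and `design` (tibble `sample, group`). Cell-line groups are
#'   S/R/RT; cohort groups are tumor/control.
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 20, n_planted = 3)
#' sim <- generate_genome(cfg)
#' ex <- generate_expression(cfg, sim, design = "cell-line")
#' ex$design
#' @export
generate_expression <- function(cfg, sim, design = c("cell-line", "cohort"),
                                cohort = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  design <- match.arg(design)
  genes <- sim$genes$gene
  planted <- genes %in% sim$truth$gene

  if (design == "cell-line") {
    with_seed(derive_seed(cfg$seed, "expr_cell"), {
      groups <- rep(c("S", "R", "RT"), each = cfg$n_rep)
      samples <- paste0(groups, "_", rep(seq_len(cfg$n_rep), times = 3))
      baseline <- rnorm(length(genes), mean = 8, sd = 1.5)
      shift <- cbind(
        S = rep(0, length(genes)),
        R = ifelse(planted, -cfg$expr_effect, 0),
        RT = ifelse(planted, -cfg$expr_effect + cfg$reexpr_effect, 0)
      )
      mat <- vapply(seq_along(samples), function(j) {
        baseline + shift[, groups[j]] +
          rnorm(length(genes), sd = cfg$expr_sd)
      }, numeric(length(genes)))
      colnames(mat) <- samples
      list(
        values = bind_cols(tibble(gene = genes), as_tibble(mat)),
        design = tibble(sample = samples, group = groups)
      )
    })
  } else {
    patient_ids <- if (!is.null(cohort)) {
      cohort$clinical$patient
    } else {
      sprintf("P%04d", seq_len(cfg$n_patients))
    }
    with_seed(derive_seed(cfg$seed, "expr_cohort"), {
      samples <- c(patient_ids, sprintf("N%03d", seq_len(cfg$n_controls)))
      groups <- c(rep("tumor", length(patient_ids)),
                  rep("control", cfg$n_controls))
      base_mu <- 2^rnorm(length(genes), mean = 8, sd = 1.5)
      lib_factor <- exp(rnorm(length(samples), sd = 0.2))
      fold <- ifelse(planted, 2^(-cfg$expr_effect), 1)
      mat <- vapply(seq_along(samples), function(j) {
        mu <- base_mu * lib_factor[j] *
          (if (groups[j] == "tumor") fold else 1)
        rpois(length(genes), mu)
      }, numeric(length(genes)))
      colnames(mat) <- samples
      list(
        values = bind_cols(tibble(gene = genes), as_tibble(mat)),
        design = tibble(sample = samples, group = groups)
      )
    })
  }
}
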