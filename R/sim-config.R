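#' Simulation configuration for the synthetic study
#'
#' Bundles every knob of the synthetic-data generator: a miniature soft-masked
#' genome with CpG islands planted at gene promoters, bisulfite count tables
#' for the sensitive (S), resistant (R) and reactivation-treated (RT)
#' phenotypes, expression matrices for the cell-line and patient-cohort
#' designs, and a platinum-treated cohort with survival endpoints. A subset of
#' `n_planted` genes is epigenetically silenced in R: hypermethylated at the
#' promoter island (`beta_r_planted`), transcriptionally down by `expr_effect`
#' log2 units, partially demethylated and re-expressed in RT.
#'
#' @param seed Integer seed; one seed fully reproduces every artifact.
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param n_genes Total number of gene models.
#' @param n_planted Number of epigenetically silenced (planted) genes.
#' @param depth_mean Mean sequencing depth per CpG (Poisson).
#' @param beta_s Background methylation fraction (all phenotypes outside
#'   planted regions, and everywhere in S).
#' @param beta_r_planted Methylation fraction over planted regions in R.
#' @param beta_rt_planted Methylation fraction over planted regions in RT;
#'   defaults to `0.65 * beta_r_planted`, reflecting partial demethylation
#'   after 5-Aza-dC/TSA reactivation.
#' @param expr_effect Log2 fold silencing of planted genes in R vs S (and in
#'   cohort tumors vs normal controls).
#' @param reexpr_effect Log2 fold re-expression of planted genes in RT vs R.
#' @param expr_sd Gaussian noise sd on log2 expression values.
#' @param n_rep Replicates per phenotype in the cell-line expression design.
#' @param n_patients Cohort size.
#' @param frac_resistant Fraction of platinum-resistant patients.
#' @param hazard_ratio_meth Multiplicative hazard for methylated patients.
#' @param os_median_days Baseline (unmethylated) median overall survival;
#'   `Inf` yields an event-free cohort censored administratively.
#' @param pfs_median_days Baseline median progression-free survival.
#' @param censor_days Administrative censoring horizon in days.
#' @param gene_len Gene-body length in bp.
#' @param island_len Planted CpG-island length in bp.
#' @param frac_extra_cgi Fraction of non-planted genes that also receive a
#'   promoter island (so the promoter-CGI funnel stage is a real filter).
#' @param n_controls Normal-control samples in the cohort expression design.
#'
#' @return A `sim_config` list, validated.
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 20, n_planted = 3)
#' cfg$n_planted
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 1L,
                       chrom_len = 2e6,
                       n_genes = 200L,
                       n_planted = 10L,
                       depth_mean = 30,
                       beta_s = 0.1,
                       beta_r_planted = 0.8,
                       beta_rt_planted = 0.65 * beta_r_planted,
                       expr_effect = 2,
                       reexpr_effect = 3,
                       expr_sd = 0.25,
                       n_rep = 5L,
                       n_patients = 60L,
                       frac_resistant = 0.5,
                       hazard_ratio_meth = 3,
                       os_median_days = 900,
                       pfs_median_days = 300,
                       censor_days = 1825,
                       gene_len = 2400L,
                       island_len = 800L,
                       frac_extra_cgi = 0.5,
                       n_controls = 10L) {
  cfg <- list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_len = as.integer(chrom_len), n_genes = as.integer(n_genes),
    n_planted = as.integer(n_planted), depth_mean = depth_mean,
    beta_s = beta_s, beta_r_planted = beta_r_planted,
    beta_rt_planted = beta_rt_planted, expr_effect = expr_effect,
    reexpr_effect = reexpr_effect, expr_sd = expr_sd,
    n_rep = as.integer(n_rep), n_patients = as.integer(n_patients),
    frac_resistant = frac_resistant, hazard_ratio_meth = hazard_ratio_meth,
    os_median_days = os_median_days, pfs_median_days = pfs_median_days,
    censor_days = censor_days, gene_len = as.integer(gene_len),
    island_len = as.integer(island_len), frac_extra_cgi = frac_extra_cgi,
    n_controls = as.integer(n_controls)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  assert_fraction(cfg$beta_s, "beta_s")
  assert_fraction(cfg$beta_r_planted, "beta_r_planted")
  assert_fraction(cfg$beta_rt_planted, "beta_rt_planted")
  assert_fraction(cfg$frac_resistant, "frac_resistant")
  assert_fraction(cfg$frac_extra_cgi, "frac_extra_cgi")
  assert_positive(cfg$depth_mean, "depth_mean")
  assert_positive(cfg$hazard_ratio_meth, "hazard_ratio_meth")
  if (cfg$n_planted > cfg$n_genes) {
    abort("`n_planted` must not exceed `n_genes`")
  }
  if (cfg$n_chrom < 1 || cfg$n_genes < 1) {
    abort("`n_chrom` and `n_genes` must be at least 1")
  }
  cfg
}

# Deterministic sub-seed per artifact so generators can be called in any
# order (or individually) and still reproduce byte-identically.
derive_seed <- function(seed, tag) {
  # double arithmetic below 2^53, reduced into the 32-bit seed range
  as.integer((as.numeric(seed) * 7919 + sum(utf8ToInt(tag)) * 131) %%
               2147483562)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
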