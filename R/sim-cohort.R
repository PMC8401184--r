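#' Simulate a platinum-treated patient cohort with survival endpoints
#'
#' Generates a clinical table, a 450K-style per-patient beta matrix and
#' per-patient qMSP read-outs. Survival times are exponential; methylated
#' patients (ground truth) have their hazard multiplied by
#' `cfg$hazard_ratio_meth` for both OS and PFS, then administratively
#' censored at `cfg$censor_days`. Resistant patients carry the planted
#' methylation with high probability (0.85 vs 0.10 for sensitive ones), and
#' planted genes are hypermethylated in the beta matrix of methylated
#' patients.
#'
#' @param cfg A [sim_config()].
#' @param sim Output of [generate_genome()] (gene ids and planted truth).
#' @return A list:
#'   * `clinical`: tibble `patient, platinum, resistant, os_days, os_event,
#'     pfs_days, pfs_event, relapse_days, vital_status, msp_call,
#'     qmsp_percent, has_expression, has_methylation`,
#'   * `beta`: tibble `gene` + one column per patient (450K-style betas),
#'   * `truth`: tibble `patient, methylated` (ground-truth state).
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 20, n_planted = 3, n_patients = 10)
#' coh <- generate_cohort(cfg, generate_genome(cfg))
#' head(coh$clinical)
#' @export
generate_cohort <- function(cfg, sim) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_patients < 2) abort("`n_patients` must be at least 2")
  assert_fraction(cfg$frac_resistant, "frac_resistant")

  with_seed(derive_seed(cfg$seed, "cohort"), {
    n <- cfg$n_patients
    patient <- sprintf("P%04d", seq_len(n))
    resistant <- runif(n) < cfg$frac_resistant
    methylated <- runif(n) < ifelse(resistant, 0.85, 0.10)

    os <- survival_times(n, cfg$os_median_days, methylated,
                         cfg$hazard_ratio_meth, cfg$censor_days)
    pfs <- survival_times(n, cfg$pfs_median_days, methylated,
                          cfg$hazard_ratio_meth, cfg$censor_days)

    qmsp_percent <- ifelse(methylated, runif(n, 40, 95), runif(n, 0, 25))

    clinical <- tibble(
      patient = patient,
      platinum = runif(n) < 0.95,
      resistant = resistant,
      os_days = os$time, os_event = os$event,
      pfs_days = pfs$time, pfs_event = pfs$event,
      relapse_days = pfs$time,
      vital_status = ifelse(os$event, "dead", "alive"),
      msp_call = qmsp_percent > 29.74,
      qmsp_percent = qmsp_percent,
      has_expression = runif(n) < 0.9,
      has_methylation = runif(n) < 0.9
    )

    genes <- sim$genes$gene
    planted <- genes %in% sim$truth$gene
    beta_mat <- vapply(seq_len(n), function(j) {
      mu <- ifelse(planted & methylated[j], 0.75, 0.10)
      pmin(pmax(rnorm(length(genes), mu, 0.06), 0), 1)
    }, numeric(length(genes)))
    colnames(beta_mat) <- patient

    list(
      clinical = clinical,
      beta = bind_cols(tibble(gene = genes), as_tibble(beta_mat)),
      truth = tibble(patient = patient, methylated = methylated)
    )
  })
}

# Exponential survival with administrative censoring; a zero hazard
# (median = Inf) yields an event-free cohort at the censoring horizon.
survival_times <- function(n, median_days, methylated, hazard_ratio,
                           censor_days) {
  rate <- log(2) / median_days * ifelse(methylated, hazard_ratio, 1)
  raw <- ifelse(rate > 0, rexp(n, pmax(rate, 1e-300)), Inf)
  event <- raw <= censor_days
  list(time = pmin(raw, censor_days), event = event)
}
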