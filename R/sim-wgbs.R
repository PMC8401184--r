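#' Simulate a bisulfite CpG count table for one phenotype
#'
#' Emits a Bismark-cytosine-report-style table over every CpG dinucleotide of
#' the genome (destranded: both strands pooled at the forward-strand C).
#' Coverage is Poisson with mean `cfg$depth_mean`; methylated counts are
#' Binomial with success probability `cfg$beta_s` everywhere except the
#' planted regions, which are hypermethylated in R (`cfg$beta_r_planted`) and
#' partially demethylated in RT (`cfg$beta_rt_planted`).
#'
#' @param cfg A [sim_config()].
#' @param sim Output of [generate_genome()] (uses `genome` and `truth`).
#' @param phenotype One of `"S"`, `"R"`, `"RT"`.
#' @return Tibble `chrom, pos, strand, meth, unmeth` (1-based positions,
#'   strand `"+"` after destranding); `meth + unmeth` is the coverage.
#' @examples
#' sim <- generate_genome(sim_config(seed = 7, n_genes = 20, n_planted = 3))
#' wg <- generate_wgbs(sim_config(seed = 7, n_genes = 20, n_planted = 3), sim, "R")
#' head(wg)
#' @export
generate_wgbs <- function(cfg, sim, phenotype = c("S", "R", "RT")) {
  stopifnot(inherits(cfg, "sim_config"))
  phenotype <- match.arg(phenotype)
  assert_positive(cfg$depth_mean, "depth_mean")

  sites <- cpg_sites(sim$genome)
  p <- rep(cfg$beta_s, nrow(sites))
  if (phenotype != "S" && nrow(sim$truth) > 0) {
    planted_p <- switch(phenotype,
      R = cfg$beta_r_planted,
      RT = cfg$beta_rt_planted
    )
    in_planted <- positions_in_intervals(sites$chrom, sites$pos, sim$truth)
    p[in_planted] <- planted_p
  }

  with_seed(derive_seed(cfg$seed, paste0("wgbs_", phenotype)), {
    coverage <- rpois(nrow(sites), cfg$depth_mean)
    meth <- rbinom(nrow(sites), coverage, p)
    sites |>
      mutate(strand = "+", meth = meth, unmeth = coverage - meth)
  })
}

# All CpG dinucleotide positions (1-based position of the C), case-blind:
# masked repeats are still sequenced by WGBS.
cpg_sites <- function(genome) {
  purrr::imap(genome, function(seqc, chrom) {
    hits <- gregexpr("CG", toupper(seqc), fixed = TRUE)[[1]]
    pos <- as.integer(hits[hits > 0])
    tibble(chrom = chrom, pos = pos)
  }) |>
    bind_rows() |>
    arrange(.data$chrom, .data$pos)
}

# Logical index of (chrom, pos) pairs falling inside any 1-based closed
# interval of `intervals` (columns chrom, start, end).
positions_in_intervals <- function(chrom, pos, intervals) {
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals))) {
    out <- out | (chrom == intervals$chrom[i] &
                    pos >= intervals$start[i] & pos <= intervals$end[i])
  }
  out
}
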