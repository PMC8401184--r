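#' Generate a miniature soft-masked genome with planted CpG islands
#'
#' Builds `n_chrom` chromosomes of CpG-depleted background sequence (~40% GC,
#' CpG dinucleotides suppressed well below island criteria), places
#' non-overlapping gene models on alternating strands, and plants a CpG island
#' across the promoter of every silenced (planted) gene plus a configurable
#' fraction of the remaining genes. Each planted island is guaranteed to
#' re-satisfy the Takai-Jones criteria (GC >= 55%, observed/expected CpG
#' >= 0.65, length >= 500 bp) on its own sequence. Two lowercase (soft-masked)
#' island-like decoys per chromosome emulate repeat-masked ALU background that
#' an island scanner must skip.
#'
#' @param cfg A [sim_config()].
#' @return A list with
#'   * `genome`: named character vector of sequences (lowercase = masked),
#'   * `genes`: tibble `gene, chrom, strand, tss, start, end` (1-based,
#'     closed intervals),
#'   * `true_cgis`: tibble `island, chrom, start, end, gene` of planted
#'     islands (1-based, closed),
#'   * `truth`: tibble `gene, region, chrom, start, end` for the planted
#'     (epi-silenced) genes; `region` is the genomic zone carrying the
#'     planted methylation (`"alpha"`: promoter).
#' @examples
#' sim <- generate_genome(sim_config(seed = 7, n_genes = 20, n_planted = 3))
#' nrow(sim$genes)
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "genome"), {
    genes_per_chrom <- distribute_genes(cfg$n_genes, cfg$n_chrom)
    spacing_needed <- cfg$gene_len + 6000L
    if (any(genes_per_chrom * spacing_needed > cfg$chrom_len)) {
      abort(sprintf(
        "chrom_len = %d too small for %d genes per chromosome (need >= %d bp)",
        cfg$chrom_len, max(genes_per_chrom),
        max(genes_per_chrom) * spacing_needed
      ))
    }

    planted_ids <- sort(sample.int(cfg$n_genes, cfg$n_planted))
    remaining <- setdiff(seq_len(cfg$n_genes), planted_ids)
    n_extra <- round(cfg$frac_extra_cgi * length(remaining))
    extra_cgi_ids <- sort(sample(remaining, n_extra))

    genome <- character(cfg$n_chrom)
    names(genome) <- paste0("chr", seq_len(cfg$n_chrom))
    genes_list <- vector("list", cfg$n_chrom)
    cgi_list <- vector("list", cfg$n_chrom)
    gene_idx <- 0L

    for (ch in seq_len(cfg$n_chrom)) {
      n_g <- genes_per_chrom[ch]
      chrom <- names(genome)[ch]
      base <- random_background(cfg$chrom_len)

      spacing <- cfg$chrom_len %/% n_g
      starts <- (seq_len(n_g) - 1L) * spacing + 3000L
      strands <- rep(c("+", "-"), length.out = n_g)
      ends <- starts + cfg$gene_len - 1L
      tss <- ifelse(strands == "+", starts, ends)
      ids <- gene_idx + seq_len(n_g)
      gene_idx <- gene_idx + n_g

      genes_list[[ch]] <- tibble(
        gene = sprintf("G%04d", ids), chrom = chrom, strand = strands,
        tss = as.integer(tss), start = as.integer(starts),
        end = as.integer(ends)
      )

      cgi_genes <- ids %in% c(planted_ids, extra_cgi_ids)
      half <- cfg$island_len %/% 2L
      isl_start <- as.integer(tss - half)
      isl_end <- as.integer(isl_start + cfg$island_len - 1L)
      keep <- which(cgi_genes)
      for (k in keep) {
        isl_seq <- random_island(cfg$island_len)
        substr(base, isl_start[k], isl_end[k]) <- isl_seq
      }
      cgi_list[[ch]] <- tibble(
        chrom = chrom, start = isl_start[keep], end = isl_end[keep],
        gene = sprintf("G%04d", ids[keep])
      )

      # soft-masked island-like decoys in intergenic space
      for (d in 1:2) {
        dec_start <- spacing * (n_g - d) + spacing - 2500L
        dec_seq <- tolower(random_island(600L))
        substr(base, dec_start, dec_start + 599L) <- dec_seq
      }
      genome[ch] <- base
    }

    genes <- bind_rows(genes_list)
    true_cgis <- bind_rows(cgi_list) |>
      arrange(.data$chrom, .data$start) |>
      mutate(island = sprintf("CGI_%d", row_number()), .before = 1)

    planted_names <- sprintf("G%04d", planted_ids)
    truth <- true_cgis |>
      filter(.data$gene %in% planted_names) |>
      mutate(region = "alpha") |>
      select("gene", "region", "chrom", "start", "end")

    list(genome = genome, genes = genes, true_cgis = true_cgis, truth = truth)
  })
}

distribute_genes <- function(n_genes, n_chrom) {
  base <- n_genes %/% n_chrom
  extra <- n_genes %% n_chrom
  base + c(rep(1L, extra), rep(0L, n_chrom - extra))
}

# CpG-depleted background: ~40% GC, then 85% of CpG dinucleotides broken by
# a C->T transition (mimics germline CpG decay outside islands).
random_background <- function(len) {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
  is_cpg <- which(bases[-len] == "C" & bases[-1] == "G")
  if (length(is_cpg) > 0) {
    hit <- is_cpg[runif(length(is_cpg)) < 0.85]
    bases[hit] <- "T"
  }
  paste(bases, collapse = "")
}

# Island-grade sequence: CpG dinucleotides emitted at high rate within a
# GC-rich background; re-drawn (deterministically, same RNG stream) in the
# rare case a draw misses the Takai-Jones thresholds.
random_island <- function(len) {
  for (attempt in 1:20) {
    out <- character(0)
    n <- 0L
    while (n < len) {
      if (runif(1) < 0.15) {
        out <- c(out, "CG")
        n <- n + 2L
      } else {
        out <- c(out, sample(c("A", "C", "G", "T"), 1,
                             prob = c(0.2, 0.3, 0.3, 0.2)))
        n <- n + 1L
      }
    }
    seqc <- substr(paste(out, collapse = ""), 1, len)
    if (island_criteria_met(seqc)) return(seqc)
  }
  abort("failed to draw an island-grade sequence (internal)")
}

island_criteria_met <- function(seqc, min_gc = 55, min_oe = 0.65,
                                min_len = 500) {
  nchar(seqc) >= min_len &&
    gc_percent(seqc) >= min_gc &&
    obs_exp_cpg(seqc) >= min_oe
}
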