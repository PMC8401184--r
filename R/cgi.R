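#' CpG observed/expected ratio and GC content
#'
#' `obs_exp_cpg()` computes the Takai-Jones observed/expected CpG ratio
#' `N_CpG * L / (N_C * N_G)`; it is 0 when the sequence contains no C or no
#' G. `gc_percent()` returns the GC content as a percentage. Both are
#' case-insensitive (soft-masking does not change composition).
#'
#' @param seqc A single character string of IUPAC DNA.
#' @return A numeric scalar.
#' @examples
#' obs_exp_cpg(strrep("CG", 250)) # 2.0
#' gc_percent("ACGT") # 50
#' @export
obs_exp_cpg <- function(seqc) {
  check_dna(seqc)
  s <- toupper(seqc)
  L <- nchar(s)
  n_c <- stringr::str_count(s, stringr::fixed("C"))
  n_g <- stringr::str_count(s, stringr::fixed("G"))
  n_cpg <- stringr::str_count(s, stringr::fixed("CG"))
  if (n_c == 0 || n_g == 0) return(0)
  n_cpg * L / (n_c * n_g)
}

#' @rdname obs_exp_cpg
#' @export
gc_percent <- function(seqc) {
  check_dna(seqc)
  s <- toupper(seqc)
  100 * stringr::str_count(s, "[CG]") / nchar(s)
}

check_dna <- function(seqc) {
  if (!is.character(seqc) || length(seqc) != 1 || nchar(seqc) == 0) {
    abort("`seqc` must be a single non-empty string")
  }
  if (grepl("[^ACGTURYSWKMBDHVNacgturyswkmbdhvn]", seqc)) {
    abort("sequence contains non-IUPAC characters")
  }
  invisible(seqc)
}

#' Detect CpG islands with Takai-Jones criteria
#'
#' Scans each sequence with a 200-bp window at 1-bp step; windows qualify
#' when GC >= `min_gc`, observed/expected CpG >= `min_oe` and no soft-masked
#' (lowercase) base is included — masked repeats break candidates, standing
#' in for RepeatMasker removal of ALU-like background. Qualifying windows are
#' unioned into runs and each run is trimmed to its longest (leftmost on
#' ties) sub-interval whose full span still satisfies all three criteria,
#' including length >= `min_len`.
#'
#' @param genome Named character vector of sequences (lowercase = masked),
#'   or a single string.
#' @param min_gc Minimum GC percentage of the island span.
#' @param min_oe Minimum observed/expected CpG ratio of the span.
#' @param min_len Minimum island length in bp.
#' @param window Scan window width in bp.
#' @return Tibble `island, chrom, start, end, length, gc_percent, obs_exp`
#'   with 1-based closed coordinates, sorted, non-overlapping.
#' @examples
#' isl <- find_cgis(c(chr1 = paste0(
#'   strrep("AT", 1000), strrep("CG", 300), strrep("AT", 1000)
#' )))
#' isl$length
#' @export
find_cgis <- function(genome, min_gc = 55, min_oe = 0.65, min_len = 500,
                      window = 200) {
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  out <- purrr::imap(genome, function(seqc, chrom) {
    iv <- find_cgis_one(seqc, min_gc, min_oe, min_len, window)
    if (nrow(iv) == 0) return(NULL)
    mutate(iv, chrom = chrom, .before = 1)
  }) |>
    purrr::compact() |>
    bind_rows()
  if (nrow(out) == 0) {
    return(tibble(island = character(), chrom = character(),
                  start = integer(), end = integer(), length = integer(),
                  gc_percent = numeric(), obs_exp = numeric()))
  }
  out |>
    arrange(.data$chrom, .data$start) |>
    mutate(island = sprintf("CGI_%d", row_number()), .before = 1)
}

find_cgis_one <- function(seqc, min_gc, min_oe, min_len, window) {
  n <- nchar(seqc)
  empty <- tibble(start = integer(), end = integer(), length = integer(),
                  gc_percent = numeric(), obs_exp = numeric())
  if (window > n) return(empty)
  chars <- strsplit(seqc, "", fixed = TRUE)[[1]]
  masked <- chars %in% letters
  up <- toupper(chars)
  is_c <- up == "C"
  is_g <- up == "G"
  is_cpg <- c(is_c[-n] & is_g[-1], FALSE)

  cum <- function(x) c(0, cumsum(x))
  cc <- cum(is_c); cg <- cum(is_g); ccpg <- cum(is_cpg); cm <- cum(masked)

  # window statistics over all start positions (1-based window start)
  starts <- seq_len(n - window + 1L)
  ends <- starts + window - 1L
  w_c <- cc[ends + 1L] - cc[starts]
  w_g <- cg[ends + 1L] - cg[starts]
  # CpG fully inside the window: exclude a CpG starting at the last base
  w_cpg <- ccpg[ends] - ccpg[starts]
  w_mask <- cm[ends + 1L] - cm[starts]
  w_gc <- 100 * (w_c + w_g) / window
  w_oe <- ifelse(w_c * w_g > 0, w_cpg * window / (w_c * w_g), 0)
  ok <- w_mask == 0 & w_gc >= min_gc & w_oe >= min_oe

  if (!any(ok)) return(empty)

  # union of qualifying windows -> covered positions -> runs
  covered <- logical(n)
  r <- rle(ok)
  pos <- cumsum(c(1L, r$lengths))
  for (i in seq_along(r$values)) {
    if (r$values[i]) {
      covered[pos[i]:(pos[i + 1L] - 1L + window - 1L)] <- TRUE
    }
  }
  runs <- rle(covered)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L

  span_stats <- function(s, e) {
    len <- e - s + 1L
    nc <- cc[e + 1L] - cc[s]
    ng <- cg[e + 1L] - cg[s]
    ncpg <- ccpg[e] - ccpg[s]
    gc <- 100 * (nc + ng) / len
    oe <- if (nc * ng > 0) ncpg * len / (nc * ng) else 0
    c(gc = gc, oe = oe)
  }

  res <- list()
  for (i in which(runs$values)) {
    s0 <- run_start[i]; e0 <- run_end[i]
    m <- e0 - s0 + 1L
    if (m < min_len) next
    found <- NULL
    for (L in seq(m, min_len)) {
      cand_s <- s0:(e0 - L + 1L)
      cand_e <- cand_s + L - 1L
      nc <- cc[cand_e + 1L] - cc[cand_s]
      ng <- cg[cand_e + 1L] - cg[cand_s]
      ncpg <- ccpg[cand_e] - ccpg[cand_s]
      nm <- cm[cand_e + 1L] - cm[cand_s]
      gc <- 100 * (nc + ng) / L
      oe <- ifelse(nc * ng > 0, ncpg * L / (nc * ng), 0)
      hit <- which(nm == 0 & gc >= min_gc & oe >= min_oe)
      if (length(hit) > 0) {
        j <- hit[1]
        found <- tibble(
          start = cand_s[j], end = cand_e[j], length = L,
          gc_percent = gc[j], obs_exp = oe[j]
        )
        break
      }
    }
    if (!is.null(found)) res[[length(res) + 1]] <- found
  }
  if (length(res) == 0) empty else bind_rows(res)
}

#' Classify genomic positions into promoter/shore/shelf/gene-body zones
#'
#' Assigns each position exactly one zone with precedence
#' alpha > beta_shore > beta_shelf > gamma > none:
#' * `alpha` — promoter: within `promoter_up` bp upstream to `promoter_down`
#'   bp downstream of a TSS, in gene orientation;
#' * `beta_shore` — within (0, 2 kb] upstream (5') of a CpG-island start;
#' * `beta_shelf` — within (2 kb, 4 kb] upstream of a CpG-island start;
#' * `gamma` — within a gene body;
#' * `none` — elsewhere.
#' Shore/shelf are measured upstream of the island's 5' start on the strand
#' of the island's assigned gene (genomic left for `+` or unassigned
#' islands, genomic right for `-`).
#'
#' @param positions Tibble with `chrom, pos` (1-based).
#' @param genes Gene-model tibble `gene, chrom, strand, tss, start, end`.
#' @param islands Island tibble `island, chrom, start, end` (optionally a
#'   `gene` column assigning each island to a gene for strand orientation).
#' @param promoter_up,promoter_down Promoter window, bp up/downstream of TSS.
#' @return `positions` with `zone`, `gene`, `island` columns added.
#' @examples
#' genes <- tibble::tibble(gene = "G1", chrom = "chr1", strand = "+",
#'                         tss = 5000L, start = 5000L, end = 8000L)
#' classify_positions(tibble::tibble(chrom = "chr1", pos = 5000L), genes,
#'                    islands = NULL)
#' @export
classify_positions <- function(positions, genes, islands = NULL,
                               promoter_up = 2000, promoter_down = 500) {
  assert_columns(positions, c("chrom", "pos"), "`positions`")
  assert_columns(genes, c("gene", "chrom", "strand", "tss", "start", "end"),
                 "`genes`")
  unknown <- setdiff(unique(positions$chrom), unique(genes$chrom))
  if (length(unknown) > 0) {
    abort(sprintf("position(s) on undeclared chromosome(s): %s",
                  paste(unknown, collapse = ", ")))
  }

  n <- nrow(positions)
  zone <- rep("none", n)
  gene_hit <- rep(NA_character_, n)
  island_hit <- rep(NA_character_, n)

  # gamma first (lowest precedence), overwritten by beta then alpha
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    in_body <- positions$chrom == g$chrom &
      positions$pos >= g$start & positions$pos <= g$end
    zone[in_body] <- "gamma"
    gene_hit[in_body] <- g$gene
  }

  if (!is.null(islands) && nrow(islands) > 0) {
    isl <- islands
    if (!"gene" %in% names(isl)) isl$gene <- NA_character_
    isl <- left_join(isl, select(genes, "gene", isl_strand = "strand"),
                     by = "gene")
    isl$isl_strand[is.na(isl$isl_strand)] <- "+"
    for (i in seq_len(nrow(isl))) {
      on_chrom <- positions$chrom == isl$chrom[i]
      # distance upstream of the island 5' start, in gene orientation
      d <- if (isl$isl_strand[i] == "+") {
        isl$start[i] - positions$pos
      } else {
        positions$pos - isl$end[i]
      }
      shelf <- on_chrom & d > 2000 & d <= 4000
      shore <- on_chrom & d > 0 & d <= 2000
      zone[shelf] <- "beta_shelf"
      island_hit[shelf] <- isl$island[i]
      zone[shore] <- "beta_shore"
      island_hit[shore] <- isl$island[i]
      if (!is.na(isl$gene[i])) {
        gene_hit[shelf | shore] <- isl$gene[i]
      }
    }
  }

  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    off <- if (g$strand == "+") positions$pos - g$tss else g$tss - positions$pos
    in_prom <- positions$chrom == g$chrom &
      off >= -promoter_up & off <= promoter_down
    zone[in_prom] <- "alpha"
    gene_hit[in_prom] <- g$gene
  }

  positions |>
    mutate(zone = zone, gene = gene_hit, island = island_hit)
}

#' Flag genes whose promoter overlaps a CpG island
#'
#' A gene passes when any island overlaps its promoter window
#' (`promoter_up` bp upstream to `promoter_down` bp downstream of the TSS,
#' in gene orientation) by at least one base.
#'
#' @inheritParams classify_positions
#' @return `genes` with a logical `promoter_cgi` column added.
#' @examples
#' genes <- tibble::tibble(gene = "G1", chrom = "chr1", strand = "+",
#'                         tss = 5000L, start = 5000L, end = 8000L)
#' islands <- tibble::tibble(island = "CGI_1", chrom = "chr1",
#'                           start = 4800L, end = 5400L)
#' promoter_has_cgi(genes, islands)$promoter_cgi
#' @export
promoter_has_cgi <- function(genes, islands, promoter_up = 2000,
                             promoter_down = 500) {
  assert_columns(genes, c("gene", "chrom", "strand", "tss"), "`genes`")
  prom_start <- ifelse(genes$strand == "+",
                       genes$tss - promoter_up, genes$tss - promoter_down)
  prom_end <- ifelse(genes$strand == "+",
                     genes$tss + promoter_down, genes$tss + promoter_up)
  flag <- vapply(seq_len(nrow(genes)), function(i) {
    any(islands$chrom == genes$chrom[i] &
          islands$start <= prom_end[i] & islands$end >= prom_start[i])
  }, logical(1))
  mutate(genes, promoter_cgi = flag)
}
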