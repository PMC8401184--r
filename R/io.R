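#' Read and write CpG count reports
#'
#' A CpG report is a header-less TSV in the Bismark cytosine-report dialect:
#' `chrom, pos (1-based), strand, meth, unmeth`; the strand column is
#' optional (counts are treated as destranded either way). Comment lines
#' starting with `#` are skipped. Malformed rows raise an error naming the
#' offending line.
#'
#' @param path File path (plain or gzip TSV).
#' @return Tibble `chrom, pos, strand, meth, unmeth`, coordinate-sorted.
#' @export
read_cpg_report <- function(path) {
  lines <- readr::read_lines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body) == 0) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  meth = integer(), unmeth = integer()))
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 4 & nf != 5)
  if (length(bad) > 0) {
    abort(sprintf("malformed CpG report row at line %d of %s",
                  body[bad[1]], path))
  }
  has_strand <- nf == 5
  get <- function(i) vapply(fields, `[`, character(1), i)
  pos <- suppressWarnings(as.integer(get(2)))
  meth <- suppressWarnings(as.integer(ifelse(has_strand, get(4), get(3))))
  unmeth <- suppressWarnings(as.integer(ifelse(has_strand, get(5), get(4))))
  bad <- which(is.na(pos) | pos < 1 | is.na(meth) | meth < 0 |
                 is.na(unmeth) | unmeth < 0)
  if (length(bad) > 0) {
    abort(sprintf("invalid position or counts at line %d of %s",
                  body[bad[1]], path))
  }
  tibble(
    chrom = get(1), pos = pos,
    strand = ifelse(has_strand, get(3), "+"),
    meth = meth, unmeth = unmeth
  ) |>
    arrange(.data$chrom, .data$pos)
}

#' @rdname read_cpg_report
#' @param profiles Tibble `chrom, pos, strand, meth, unmeth`.
#' @param header Optional header comment (written as `#`-prefixed lines).
#' @export
write_cpg_report <- function(profiles, path, header = NULL) {
  assert_columns(profiles, c("chrom", "pos", "meth", "unmeth"),
                 "`profiles`")
  if (!"strand" %in% names(profiles)) profiles$strand <- "+"
  profiles <- arrange(profiles, .data$chrom, .data$pos) |>
    select("chrom", "pos", "strand", "meth", "unmeth")
  write_tsv_headed(profiles, path, header, col_names = FALSE)
}

#' Read and write FASTA with soft-masking preserved
#'
#' Backed by [Biostrings::readBStringSet()] / `writeXStringSet()`, which
#' keep lowercase (soft-masked) letters intact.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param genome Named character vector of sequences.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(genome), path,
                              width = 70L)
  invisible(path)
}

#' Read and write BED interval files
#'
#' BED uses 0-based half-open coordinates; the package's tables are 1-based
#' closed, and the conversion lives here only. `write_bed()` accepts any
#' tibble with `chrom, start, end` (1-based closed) and an optional name
#' column; scores, when given, are written in BED column 5.
#'
#' @param intervals Tibble `chrom, start, end` (1-based closed), optional
#'   `name` and `score`.
#' @param path File path.
#' @param header Optional `#`-prefixed header lines.
#' @return `read_bed()`: tibble `chrom, start, end, name, score` (1-based
#'   closed).
#' @export
write_bed <- function(intervals, path, header = NULL) {
  assert_columns(intervals, c("chrom", "start", "end"), "`intervals`")
  bed <- tibble(
    chrom = intervals$chrom,
    start = pos1_to_bed0(intervals$start),
    end = intervals$end,
    name = intervals[["name"]] %||%
      sprintf("region_%d", seq_len(nrow(intervals)))
  )
  if (!is.null(intervals[["score"]])) bed$score <- intervals[["score"]]
  write_tsv_headed(bed, path, header, col_names = FALSE)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE)
  out <- tibble(
    chrom = as.character(raw[[1]]),
    start = bed0_to_pos1(as.integer(raw[[2]])),
    end = as.integer(raw[[3]]),
    name = if (ncol(raw) >= 4) as.character(raw[[4]]) else NA_character_,
    score = if (ncol(raw) >= 5) as.numeric(raw[[5]]) else NA_real_
  )
  out
}

#' Read and write gene/sample matrices and clinical tables
#'
#' Matrices are TSV with a header row of sample ids and a leading `gene`
#' column; clinical tables are TSV with a header. `#`-prefixed lines are
#' treated as comments.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_matrix <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' @rdname read_matrix
#' @param x Tibble to write.
#' @param header Optional `#`-prefixed header lines.
#' @export
write_matrix <- function(x, path, header = NULL) {
  write_tsv_headed(x, path, header, col_names = TRUE)
}

#' @rdname read_matrix
#' @export
read_clinical <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  assert_columns(out, "patient", "clinical table")
  out
}

#' Write gene models as BED6+2
#'
#' Columns: chrom, start, end, name, score (0), strand, TSS, gene id —
#' coordinates 0-based half-open.
#'
#' @param genes Gene-model tibble (`gene, chrom, strand, tss, start, end`,
#'   1-based closed).
#' @param path File path.
#' @param header Optional `#`-prefixed header lines.
#' @export
write_gene_models <- function(genes, path, header = NULL) {
  assert_columns(genes, c("gene", "chrom", "strand", "tss", "start", "end"),
                 "`genes`")
  bed <- tibble(
    chrom = genes$chrom, start = pos1_to_bed0(genes$start),
    end = genes$end, name = genes$gene, score = 0L,
    strand = genes$strand, tss = pos1_to_bed0(genes$tss), gene = genes$gene
  )
  write_tsv_headed(bed, path, header, col_names = FALSE)
}

# header lines then body; readr appends without re-writing column names
write_tsv_headed <- function(x, path, header = NULL, col_names = TRUE) {
  if (is.null(header)) {
    readr::write_tsv(x, path, col_names = col_names)
  } else {
    readr::write_lines(header, path)
    readr::write_tsv(x, path, append = TRUE, col_names = col_names)
  }
  invisible(path)
}
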