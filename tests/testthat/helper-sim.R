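# Shared fixtures: tiny simulation configs and engineered sequences.

tiny_cfg <- function(seed = 7, ...) {
  sim_config(seed = seed, n_genes = 10L, n_planted = 3L, chrom_len = 1.5e5,
             n_patients = 20L, ...)
}

small_cfg <- function(seed = 7, ...) {
  sim_config(seed = seed, n_genes = 40L, n_planted = 4L, chrom_len = 4e5,
             n_patients = 30L, ...)
}

# AT-rich filler that cannot satisfy island criteria.
at_fill <- function(n) strrep("AT", ceiling(n / 2)) |> substr(1, n)

# Dense, deterministic island-grade sequence (alternating CGCG / GC-rich).
cg_island <- function(n) strrep("CG", ceiling(n / 2)) |> substr(1, n)

# Independent composition counter used as an oracle against the package's
# sequence statistics (direct character tabulation, no shared code).
count_seq <- function(seqc) {
  ch <- strsplit(toupper(seqc), "")[[1]]
  n <- length(ch)
  list(
    n = n,
    c = sum(ch == "C"),
    g = sum(ch == "G"),
    cpg = sum(ch[-n] == "C" & ch[-1] == "G")
  )
}
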