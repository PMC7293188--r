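# shared fixture builders: everything is generated in code at test time

BASES <- c("A", "C", "G", "T")

write_reads <- function(reads, ext = ".fa") {
  f <- tempfile(fileext = ext)
  writeLines(as.vector(rbind(paste0(">r", seq_along(reads)), reads)), f)
  f
}

rnd_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

other_base <- function(b, pick = 1L) setdiff(BASES, b)[[pick]]

# plant substitutions at 0-based positions; alt base deterministic unless given
plant_snps <- function(seq, positions, alts = NULL) {
  for (i in seq_along(positions)) {
    p <- positions[[i]] + 1L
    alt <- if (is.null(alts)) other_base(substr(seq, p, p)) else alts[[i]]
    substr(seq, p, p) <- alt
  }
  seq
}

# 0-based mismatch positions between two equal-length strings (brute force)
mismatch_positions <- function(a, b) {
  which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) - 1L
}

# brute-force canonical k-mer set of sequences (independent of the C++ path)
brute_canonical_kmers <- function(seqs, k) {
  rc_map <- c(A = "T", C = "G", G = "C", T = "A")
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      rc <- paste(rev(rc_map[strsplit(w, "")[[1]]]), collapse = "")
      out <- c(out, min(w, rc))
    }
  }
  sort(unique(out))
}

# graph from in-memory reads, one sample unless a list of samples is given
graph_from_reads <- function(reads, k, min_abundance = 1L) {
  if (!is.list(reads)) reads <- list(reads)
  files <- vapply(reads, write_reads, character(1))
  kmer_graph(files, k = k, min_abundance = min_abundance)
}

# bubbles (with contexts) from two haplotypes sequenced error-free
bubbles_from_haplotypes <- function(..., k, min_abundance = 1L) {
  g <- graph_from_reads(c(...), k = k)
  extend_contexts(g, detect_bubbles(g))
}

# a tiny deterministic two-population dataset for integration tests
small_sim <- function(seed, genome_length = 6e4, n_ind = 4L, error_rate = 0.01,
                      coverage = 20L) {
  cfg <- sim_config(n_populations = 2L, individuals_per_population = n_ind,
                    error_rate = error_rate, coverage = coverage, seed = seed)
  simulate_rad_dataset(cfg, dir = tempfile("sim_"), genome_length = genome_length)
}
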