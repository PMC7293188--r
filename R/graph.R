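#' Build a de Bruijn graph (canonical k-mer count table) from read sets
#'
#' Counts canonical k-mers (the lexicographic minimum of a k-mer and its
#' reverse complement) over any number of read sets and keeps those reaching
#' `min_abundance` within at least one sample; for a single sample this is
#' simply an abundance threshold on the total count. Windows containing a
#' non-ACGT character are skipped, so `N`s break k-mer windows rather than
#' aborting the run.
#'
#' @param samples Character vector (or list) with one element per sample. Each
#'   element is a FASTA/FASTQ file path, plain or gzipped (format detected
#'   from content), or several comma-separated paths forming one sample.
#'   Sample order defines sample indices everywhere downstream.
#' @param k Odd k-mer size between 5 and 63. 31 is a usual value for
#'   Illumina-length reads.
#' @param min_abundance Minimum within-sample k-mer count for a k-mer to enter
#'   the graph; filters most sequencing-error k-mers.
#' @return An object of class `kmer_graph`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACTGACTGAC"), fa)
#' g <- kmer_graph(fa, k = 5, min_abundance = 1)
#' g
#' @export
kmer_graph <- function(samples, k = 31L, min_abundance = 3L) {
  k <- as.integer(k)
  if (is.na(k) || k < 5L || k > 63L || k %% 2L == 0L) {
    stop("`k` must be an odd integer between 5 and 63", call. = FALSE)
  }
  min_abundance <- as.integer(min_abundance)
  if (is.na(min_abundance) || min_abundance < 1L) {
    stop("`min_abundance` must be a positive integer", call. = FALSE)
  }
  samples <- unlist(samples, use.names = TRUE)
  if (length(samples) == 0L) stop("at least one sample is required", call. = FALSE)
  sample_names <- names(samples) %||% default_sample_names(samples)

  ptr <- cpp_graph_new(k)
  for (i in seq_along(samples)) {
    for (f in split_file_group(samples[[i]])) {
      cpp_graph_add_reads(ptr, read_sequence_file(f), i)
    }
  }
  cpp_graph_finalize(ptr, min_abundance)

  structure(
    list(
      ptr = ptr, k = k, min_abundance = min_abundance,
      samples = unname(samples), sample_names = sample_names,
      n_kmers = cpp_graph_size(ptr),
      total_occurrences = cpp_graph_total_occurrences(ptr)
    ),
    class = "kmer_graph"
  )
}

default_sample_names <- function(files) {
  base <- vapply(
    strsplit(unname(files), ",", fixed = TRUE),
    function(x) sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "", basename(x[[1]])),
    character(1)
  )
  make.unique(base, sep = "_")
}

split_file_group <- function(x) trimws(strsplit(x, ",", fixed = TRUE)[[1]])

#' Read a FASTA or FASTQ file (plain or gzipped) as a character vector
#'
#' The format is auto-detected from the first record character.
#'
#' @param path File path.
#' @return Character vector of read sequences.
#' @export
read_sequence_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read input file '%s'", path), call. = FALSE)
  }
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- ""
  while (TRUE) {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) return(character(0))  # empty file: no reads
    line <- trimws(line)
    if (nzchar(line)) { first <- substr(line, 1L, 1L); break }
  }
  fmt <- if (first == "@") "fastq" else if (first == ">") "fasta" else
    stop(sprintf("file '%s' is neither FASTA nor FASTQ", path), call. = FALSE)
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat(sprintf(
    "de Bruijn graph: k = %d, %s solid canonical k-mers (min within-sample abundance %d)\n",
    x$k, format(x$n_kmers, big.mark = ","), x$min_abundance
  ))
  cat(sprintf(
    "built from %d sample(s), %s k-mer occurrences scanned\n",
    length(x$samples), format(x$total_occurrences, big.mark = ",")
  ))
  invisible(x)
}

check_graph <- function(g) {
  if (!inherits(g, "kmer_graph")) stop("`graph` must be a kmer_graph object", call. = FALSE)
  g
}

check_kmer <- function(g, kmer) {
  if (!is.character(kmer) || length(kmer) != 1L || nchar(kmer) != g$k) {
    stop(sprintf("query k-mer must be a single string of length k = %d", g$k), call. = FALSE)
  }
  kmer
}

#' Query k-mer membership and counts
#'
#' Membership and counts are strand-agnostic: a k-mer and its reverse
#' complement give identical answers.
#'
#' @param graph A [kmer_graph()].
#' @param kmers Character vector of k-mers (each of length `k`).
#' @return `graph_contains()`: logical vector; `kmer_count()`: integer vector
#'   of total occurrence counts (0 for absent k-mers).
#' @export
graph_contains <- function(graph, kmers) {
  check_graph(graph)
  kmer_count(graph, kmers) > 0L
}

#' @rdname graph_contains
#' @export
kmer_count <- function(graph, kmers) {
  check_graph(graph)
  if (any(nchar(kmers) != graph$k)) {
    stop(sprintf("query k-mers must have length k = %d", graph$k), call. = FALSE)
  }
  cpp_graph_count(graph$ptr, toupper(kmers))
}

#' All stored canonical k-mers
#'
#' @param graph A [kmer_graph()].
#' @param counts Also return total counts?
#' @return A tibble with columns `kmer` and (optionally) `count`, sorted
#'   lexicographically.
#' @export
graph_kmers <- function(graph, counts = TRUE) {
  check_graph(graph)
  km <- cpp_graph_kmers(graph$ptr)
  if (counts) {
    tibble(kmer = km, count = cpp_graph_kmer_totals(graph$ptr))
  } else {
    tibble(kmer = km)
  }
}

#' Oriented successors and predecessors of a k-mer
#'
#' `successors()` returns, for each base `a`, the oriented k-mer
#' `substr(kmer, 2, k) + a` present in the graph (membership tested on the
#' canonical form). `predecessors()` is the symmetric query, implemented by
#' applying `successors()` to the reverse complement.
#'
#' @param graph A [kmer_graph()].
#' @param kmer A single k-mer string of length `k`.
#' @return A tibble with columns `base` (the extension nucleotide) and `kmer`
#'   (the oriented neighbour), 0-4 rows.
#' @export
successors <- function(graph, kmer) {
  check_graph(graph)
  kmer <- toupper(check_kmer(graph, kmer))
  base <- cpp_successors(graph$ptr, kmer)
  tibble(base = base, kmer = paste0(substr(kmer, 2L, graph$k), base))
}

#' @rdname successors
#' @export
predecessors <- function(graph, kmer) {
  check_graph(graph)
  kmer <- toupper(check_kmer(graph, kmer))
  rc <- cpp_revcomp(kmer)
  base_rc <- cpp_successors(graph$ptr, rc)
  base <- revcomp(base_rc)
  tibble(base = base, kmer = paste0(base, substr(kmer, 1L, graph$k - 1L)))
}

#' Is a node branching?
#'
#' A node is branching when it has two or more oriented successors and/or two
#' or more oriented predecessors.
#'
#' @inheritParams successors
#' @return A logical scalar.
#' @export
is_branching <- function(graph, kmer) {
  check_graph(graph)
  kmer <- toupper(check_kmer(graph, kmer))
  cpp_is_branching(graph$ptr, kmer)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of ACGT strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) cpp_revcomp(toupper(x))
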