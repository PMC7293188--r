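#' Detect variant bubbles in a de Bruijn graph
#'
#' Enumerates variant-induced bubbles by extending, from every branching node
#' and every unordered pair of its successors, two paths one nucleotide at a
#' time in lockstep. Extension stops when the two current k-mers become equal
#' (a complete bubble), when both k-mers are successor-free at equal path
#' length with identical last 3-mer (a symmetrically truncated bubble, the
#' RAD-specific motif caused by a variant within k bp of a locus extremity),
#' or when extension is impossible (abandoned). Left-truncated bubbles are
#' found by the same procedure on the reverse-complement orientation. At a
#' crossroad where more than one extension combination is possible, all
#' combinations are explored recursively, up to `max_sbc` such traversals per
#' bubble. Additional mismatches closer than k apart accumulate into a single
#' close-SNP bubble; indels are sought by holding one branch while the other
#' consumes up to `max_indel` extra nucleotides before lockstep resumes.
#'
#' Each biological bubble is reported exactly once: bubbles are deduplicated
#' across the two strands and the two path orderings, `path_a` being the
#' lexicographically smaller path in the retained orientation.
#'
#' @param graph A [kmer_graph()].
#' @param max_snps Maximum number of mismatches (close SNPs) per bubble;
#'   bubbles that would exceed it are abandoned.
#' @param max_sbc Maximum number of symmetrically branching crossroads
#'   traversed per bubble.
#' @param max_indel Maximum indel length sought; 0 disables indel search.
#' @param high_precision If `TRUE`, bubbles containing one or more crossroads
#'   are not detected at all.
#' @return A tibble with one row per bubble: `bubble_id`, `kind` (`"SNP"`,
#'   `"CLOSE_SNPS"` or `"INDEL"`), `closure` (`"COMPLETE"`,
#'   `"LEFT_TRUNCATED"` or `"RIGHT_TRUNCATED"`), `path_a`, `path_b`,
#'   `variant_offsets` (list column: 0-based mismatch offsets for SNP kinds;
#'   `c(offset, length)` of the inserted/deleted segment, on the longer path
#'   and leftmost-aligned, for indels) and `sbc_crossed`. The k-mer size and
#'   number of samples are carried in attributes `k` and `n_samples`.
#' @export
detect_bubbles <- function(graph, max_snps = 5L, max_sbc = 5L, max_indel = 10L,
                           high_precision = FALSE) {
  check_graph(graph)
  stopifnot(max_snps >= 1L, max_sbc >= 0L, max_indel >= 0L)
  if (graph$n_kmers == 0) {
    res <- tibble(
      bubble_id = integer(), kind = character(), closure = character(),
      path_a = character(), path_b = character(),
      variant_offsets = list(), sbc_crossed = integer()
    )
    return(bubble_attrs(res, graph))
  }
  raw <- cpp_detect_bubbles(graph$ptr, as.integer(max_snps), as.integer(max_sbc),
                            as.integer(max_indel), isTRUE(high_precision))
  res <- tibble(
    bubble_id = seq_along(raw$path_a),
    kind = c("SNP", "CLOSE_SNPS", "INDEL")[raw$kind + 1L],
    closure = c("COMPLETE", "LEFT_TRUNCATED", "RIGHT_TRUNCATED")[raw$closure + 1L],
    path_a = raw$path_a,
    path_b = raw$path_b,
    variant_offsets = raw$offsets,
    sbc_crossed = raw$sbc_crossed
  )
  bubble_attrs(res, graph)
}

bubble_attrs <- function(x, graph) {
  attr(x, "k") <- graph$k
  attr(x, "n_samples") <- length(graph$samples)
  x
}

#' Extend bubbles with their left and right graph contexts
#'
#' Walks left from a bubble's opening node and right from its closing node,
#' appending one nucleotide at a time while the walk is unambiguous (exactly
#' one successor in the walking direction, and the node walked into has
#' exactly one predecessor); the walk ends at the first ambiguity. A truncated
#' side gets an empty context.
#'
#' @param graph The [kmer_graph()] the bubbles were detected on.
#' @param bubbles A tibble from [detect_bubbles()].
#' @return `bubbles` with added columns `left_context`, `right_context`,
#'   `extended_a` and `extended_b` (context + path + context).
#' @export
extend_contexts <- function(graph, bubbles) {
  check_graph(graph)
  cl <- match(bubbles$closure, c("COMPLETE", "LEFT_TRUNCATED", "RIGHT_TRUNCATED")) - 1L
  ctx <- cpp_extend_contexts(graph$ptr, bubbles$path_a, bubbles$path_b, cl)
  out <- mutate(
    bubbles,
    left_context = ctx$left_context,
    right_context = ctx$right_context,
    extended_a = paste0(.data$left_context, .data$path_a, .data$right_context),
    extended_b = paste0(.data$left_context, .data$path_b, .data$right_context)
  )
  bubble_attrs(out, graph)
}

#' Write extended bubbles to FASTA
#'
#' Two records per bubble, header
#' `>bubble_<id>_path_<a|b>|type=<...>|closure=<...>|offsets=<comma list>`;
#' the bubble path is written uppercase and the contexts lowercase.
#'
#' @param bubbles A tibble from [extend_contexts()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bubble_fasta <- function(bubbles, path) {
  stopifnot(all(c("left_context", "right_context") %in% names(bubbles)))
  off <- vapply(bubbles$variant_offsets, paste, character(1), collapse = ",")
  k <- attr(bubbles, "k")
  lines <- character(0)
  if (nrow(bubbles) > 0) {
    hdr <- sprintf("bubble_%d_path_%%s|type=%s|closure=%s|offsets=%s",
                   bubbles$bubble_id, bubbles$kind, bubbles$closure, off)
    if (!is.null(k)) hdr <- sprintf("%s|k=%d", hdr, k)
    seq_a <- paste0(tolower(bubbles$left_context), bubbles$path_a,
                    tolower(bubbles$right_context))
    seq_b <- paste0(tolower(bubbles$left_context), bubbles$path_b,
                    tolower(bubbles$right_context))
    lines <- as.vector(rbind(
      paste0(">", sprintf(hdr, "a")), seq_a,
      paste0(">", sprintf(hdr, "b")), seq_b
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bubble FASTA back into a bubbles tibble
#'
#' Inverse of [write_bubble_fasta()]: paths, contexts (lowercase in the file)
#' and variant offsets are recovered, as is the k-mer size when present in the
#' headers.
#'
#' @param path A FASTA written by [write_bubble_fasta()].
#' @return A bubbles tibble as produced by [extend_contexts()].
#' @export
read_bubble_fasta <- function(path) {
  lines <- readLines(path)
  hd <- grepl("^>", lines)
  headers <- sub("^>", "", lines[hd])
  seqs <- lines[!hd]
  stopifnot(length(headers) == length(seqs), length(headers) %% 2L == 0L)
  a <- seq(1L, length(headers), by = 2L)
  meta <- strsplit(headers[a], "|", fixed = TRUE)
  bid <- as.integer(sub("^bubble_(\\d+)_path_a$", "\\1",
                        vapply(meta, `[`, character(1), 1L)))
  field <- function(nm) {
    vapply(meta, function(m) {
      hit <- grep(paste0("^", nm, "="), m, value = TRUE)
      if (length(hit)) sub(paste0("^", nm, "="), "", hit[[1]]) else NA_character_
    }, character(1))
  }
  offsets <- lapply(strsplit(field("offsets"), ",", fixed = TRUE), as.integer)
  seq_a <- seqs[a]
  seq_b <- seqs[a + 1L]
  left <- sub("^([a-z]*).*$", "\\1", seq_a)
  right <- sub("^.*?[A-Z]([a-z]*)$", "\\1", seq_a)
  path_a <- substr(seq_a, nchar(left) + 1L, nchar(seq_a) - nchar(right))
  path_b <- substr(seq_b, nchar(left) + 1L, nchar(seq_b) - nchar(right))
  out <- tibble(
    bubble_id = bid, kind = field("type"), closure = field("closure"),
    path_a = path_a, path_b = path_b, variant_offsets = offsets,
    sbc_crossed = NA_integer_,
    left_context = toupper(left), right_context = toupper(right),
    extended_a = toupper(seq_a), extended_b = toupper(seq_b)
  )
  kf <- suppressWarnings(as.integer(field("k")))
  if (!all(is.na(kf))) attr(out, "k") <- kf[[1]]
  out
}
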