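#' Map reads back onto extended bubble sequences: per-sample allele coverage
#'
#' Each read (either strand) is placed on extended bubble sequences by exact
#' k-mer seeding followed by ungapped verification: a placement is accepted if
#' the read lies fully inside the extended sequence (or overhangs with an
#' overlap of at least k), carries at most `max_subst` substitutions over the
#' overlap, and matches exactly at every variant position it covers. A read
#' supports the single allele whose variant-position bases it matches; reads
#' covering no variant position, or consistent with both alleles, contribute
#' nothing. A read that matches several distinct bubbles is counted for each.
#' For indel bubbles a read must span the whole inserted/deleted segment
#' (plus one anchor base on each side) to support an allele.
#'
#' @param bubbles A tibble from [extend_contexts()].
#' @param samples Sample read files, in the order used to build the graph (one
#'   path or comma-separated group per sample).
#' @param max_subst Maximum substitutions allowed over the read/bubble overlap
#'   (never at variant positions).
#' @param k k-mer size used for seeding; defaults to the graph k carried by
#'   `bubbles`.
#' @return A tibble with one row per bubble and sample: `bubble_id`, `sample`,
#'   `sample_idx`, `count_a`, `count_b`.
#' @export
map_allele_coverage <- function(bubbles, samples, max_subst = 10L,
                                k = attr(bubbles, "k")) {
  stopifnot(all(c("extended_a", "extended_b") %in% names(bubbles)))
  if (is.null(k)) stop("`k` is required (not carried by `bubbles`)", call. = FALSE)
  samples <- unlist(samples, use.names = TRUE)
  n_graph <- attr(bubbles, "n_samples")
  if (!is.null(n_graph) && length(samples) != n_graph) {
    stop(sprintf(
      "%d sample(s) supplied but the graph was built from %d; reads must match graph construction",
      length(samples), n_graph
    ), call. = FALSE)
  }
  sample_names <- names(samples) %||% default_sample_names(samples)

  req <- required_positions(bubbles)
  if (nrow(bubbles) == 0L) {
    return(tibble(bubble_id = integer(), sample = character(),
                  sample_idx = integer(), count_a = integer(), count_b = integer()))
  }
  idx <- cpp_bubble_index(bubbles$extended_a, bubbles$extended_b,
                          req$a, req$b, bubbles$kind == "INDEL", as.integer(k))
  out <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    reads <- unlist(lapply(split_file_group(samples[[i]]), read_sequence_file))
    counts <- cpp_map_sample(idx, reads, as.integer(max_subst))
    out[[i]] <- tibble(
      bubble_id = bubbles$bubble_id, sample = sample_names[[i]], sample_idx = i,
      count_a = counts[, 1L], count_b = counts[, 2L]
    )
  }
  bind_rows(out)
}

# variant positions that must match exactly, in extended-sequence coordinates,
# for each allele (0-based)
required_positions <- function(bubbles) {
  lc <- if ("left_context" %in% names(bubbles)) nchar(bubbles$left_context) else
    rep(0L, nrow(bubbles))
  a <- vector("list", nrow(bubbles))
  b <- a
  for (i in seq_len(nrow(bubbles))) {
    off <- bubbles$variant_offsets[[i]]
    if (bubbles$kind[[i]] == "INDEL") {
      o <- off[[1]] + lc[[i]]
      len <- off[[2]]
      long_is_a <- nchar(bubbles$path_a[[i]]) > nchar(bubbles$path_b[[i]])
      long <- seq.int(max(0L, o - 1L), o + len)       # anchor + segment + next base
      short <- seq.int(max(0L, o - 1L), o)            # junction anchors
      if (long_is_a) { a[[i]] <- long; b[[i]] <- short } else {
        a[[i]] <- short; b[[i]] <- long
      }
    } else {
      a[[i]] <- off + lc[[i]]
      b[[i]] <- off + lc[[i]]
    }
  }
  list(a = a, b = b)
}

#' Call a genotype from allele counts by binomial maximum likelihood
#'
#' With `n = count_a + count_b` reads, the likelihoods of genotypes 0/0, 0/1
#' and 1/1 are binomial with success probability `err`, 0.5 and `1 - err`
#' respectively for the alternate-allele count. When `n < min_depth` the
#' genotype is missing (`"./."`); otherwise the maximum-likelihood genotype is
#' called, ties breaking toward the heterozygote.
#'
#' @param count_a,count_b Non-negative integer vectors of reads supporting
#'   each allele.
#' @param min_depth Minimum total depth to call a genotype.
#' @param err Sequencing error rate, in (0, 0.5).
#' @return A tibble with columns `gt`, `depth`, `ll_0_0`, `ll_0_1`, `ll_1_1`
#'   (log-likelihoods).
#' @examples
#' genotype_call(c(2, 10, 5), c(0, 0, 5))
#' @export
genotype_call <- function(count_a, count_b, min_depth = 3L, err = 0.01) {
  if (any(count_a < 0) || any(count_b < 0)) {
    stop("allele counts must be non-negative", call. = FALSE)
  }
  if (err <= 0 || err >= 0.5) stop("`err` must be in (0, 0.5)", call. = FALSE)
  n <- count_a + count_b
  ll00 <- dbinom(count_b, n, err, log = TRUE)
  ll01 <- dbinom(count_b, n, 0.5, log = TRUE)
  ll11 <- dbinom(count_b, n, 1 - err, log = TRUE)
  gt <- ifelse(
    n < min_depth, "./.",
    ifelse(ll01 >= ll00 & ll01 >= ll11, "0/1", ifelse(ll00 >= ll11, "0/0", "1/1"))
  )
  tibble(gt = gt, depth = as.integer(n), ll_0_0 = ll00, ll_0_1 = ll01, ll_1_1 = ll11)
}

#' Genotype an allele-coverage table
#'
#' @param coverage A tibble from [map_allele_coverage()].
#' @inheritParams genotype_call
#' @return `coverage` with added columns `gt` and `depth`.
#' @export
call_genotypes <- function(coverage, min_depth = 3L, err = 0.01) {
  gc <- genotype_call(coverage$count_a, coverage$count_b, min_depth, err)
  mutate(coverage, gt = gc$gt, depth = gc$depth)
}

#' Phi coefficient of a 2x2 contingency table
#'
#' Returns `sqrt(chi2 / n)` where `chi2` is Pearson's statistic without
#' continuity correction and `n` the table total; equivalently
#' `|ad - bc| / sqrt((a+b)(c+d)(a+c)(b+d))`. Defined as 0 when any row or
#' column total is 0 (no association measurable).
#'
#' @param table A 2x2 numeric matrix (or anything coercible) of non-negative
#'   counts.
#' @return A number in `[0, 1]`.
#' @examples
#' phi_coefficient(matrix(c(8, 2, 2, 8), 2, byrow = TRUE))
#' @export
phi_coefficient <- function(table) {
  m <- matrix(as.numeric(table), 2L, 2L)
  if (any(m < 0)) stop("table cells must be non-negative", call. = FALSE)
  pair_phi(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
}

pair_phi <- function(a, b, c, d) {
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  ifelse(denom > 0, abs(a * d - b * c) / sqrt(denom), 0)
}

#' Rank score of one variant from its per-sample allele counts
#'
#' The rank is the maximum Phi coefficient over all unordered sample pairs,
#' the pair table being `rbind(c(count_a[i], count_b[i]), c(count_a[j],
#' count_b[j]))`. Paralog-induced variants, whose allele balance is similar in
#' every sample, get low ranks; discriminant variants get ranks near 1.
#'
#' @param count_a,count_b Per-sample allele counts of a single variant.
#' @return A number in `[0, 1]`.
#' @export
variant_rank <- function(count_a, count_b) {
  ns <- length(count_a)
  stopifnot(length(count_b) == ns)
  if (ns < 2L) {
    warning("rank requires at least two samples; returning 0", call. = FALSE)
    return(0)
  }
  best <- 0
  for (i in seq_len(ns - 1L)) {
    j <- seq.int(i + 1L, ns)
    best <- max(best, pair_phi(count_a[i], count_b[i], count_a[j], count_b[j]))
  }
  best
}

#' Rank scores for every variant in a coverage table
#'
#' @param coverage A tibble from [map_allele_coverage()].
#' @return A tibble with columns `bubble_id` and `rank`.
#' @export
rank_variants <- function(coverage) {
  ids <- sort(unique(coverage$bubble_id))
  ss <- sort(unique(coverage$sample_idx))
  ns <- length(ss)
  if (length(ids) == 0L) return(tibble(bubble_id = integer(), rank = numeric()))
  if (ns < 2L) {
    warning("rank requires at least two samples; returning 0", call. = FALSE)
    return(tibble(bubble_id = ids, rank = 0))
  }
  A <- matrix(0, length(ids), ns)
  B <- matrix(0, length(ids), ns)
  ri <- match(coverage$bubble_id, ids)
  ci <- match(coverage$sample_idx, ss)
  A[cbind(ri, ci)] <- coverage$count_a
  B[cbind(ri, ci)] <- coverage$count_b
  best <- rep(0, length(ids))
  for (i in seq_len(ns - 1L)) {
    for (j in seq.int(i + 1L, ns)) {
      best <- pmax(best, pair_phi(A[, i], B[, i], A[, j], B[, j]))
    }
  }
  tibble(bubble_id = ids, rank = best)
}

#' Rank and missingness filters
#'
#' `filter_rank()` keeps variants whose rank is at least `min_rank` (strictly
#' below is discarded). `filter_missing()` discards variants whose fraction of
#' missing (`"./."`) genotypes exceeds `max_missing_frac`.
#'
#' @param variants A tibble with a `rank` (resp. `missing_frac`) column.
#' @param min_rank Minimum rank kept.
#' @param max_missing_frac Highest tolerated missing-genotype fraction.
#' @return The filtered tibble.
#' @export
filter_rank <- function(variants, min_rank = 0.4) {
  filter(variants, .data$rank >= min_rank)
}

#' @rdname filter_rank
#' @export
filter_missing <- function(variants, max_missing_frac = 0.95) {
  filter(variants, .data$missing_frac <= max_missing_frac)
}
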