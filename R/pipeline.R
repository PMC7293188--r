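#' Run the full reference-free RAD variant-calling pipeline
#'
#' Builds the de Bruijn graph from all samples, detects and context-extends
#' bubbles, maps reads back for per-sample allele coverage, calls genotypes
#' and rank scores, applies the rank and missingness filters, clusters
#' surviving variants into RAD loci by shared (k-1)-mers (discarding oversized
#' clusters) and optionally writes a VCF.
#'
#' @param samples One FASTA/FASTQ path (or comma-separated group) per sample;
#'   input order defines sample/column order everywhere downstream.
#' @param k,min_abundance Graph construction parameters (see [kmer_graph()]).
#' @param max_snps,max_sbc,max_indel,high_precision Bubble detection
#'   parameters (see [detect_bubbles()]).
#' @param max_subst Maximum substitutions when mapping reads on bubbles.
#' @param min_depth,err Genotyping parameters (see [genotype_call()]).
#' @param min_rank Variants with rank strictly below this are discarded.
#' @param max_missing_frac Variants with a larger missing-genotype fraction
#'   are discarded.
#' @param max_cluster_size Clusters with more variants are discarded whole.
#' @param out_vcf Optional VCF output path.
#' @param sample_names Optional sample names (defaults to file basenames).
#' @param quiet Suppress progress messages (stderr)?
#' @return A `rad_call` object: `variants` (surviving bubble-level tibble with
#'   `rank`, `missing_frac`, `cluster_id`, `cluster_size`), `records`
#'   (VCF-level rows), `genotypes` and `coverage` (long tibbles over all
#'   detected bubbles), `sample_names`, `stats` (stage counts) and `config`.
#' @export
rad_call <- function(samples, k = 31L, min_abundance = 3L, max_snps = 5L,
                     max_sbc = 5L, max_indel = 10L, high_precision = FALSE,
                     max_subst = 10L, min_depth = 3L, err = 0.01,
                     min_rank = 0.4, max_missing_frac = 0.95,
                     max_cluster_size = 150L, out_vcf = NULL,
                     sample_names = NULL, quiet = FALSE) {
  say <- function(fmt, ...) if (!isTRUE(quiet)) message(sprintf(fmt, ...))
  samples <- unlist(samples, use.names = TRUE)
  if (!is.null(sample_names)) names(samples) <- sample_names
  config <- list(
    k = as.integer(k), min_abundance = as.integer(min_abundance),
    max_snps = as.integer(max_snps), max_sbc = as.integer(max_sbc),
    max_indel = as.integer(max_indel), high_precision = isTRUE(high_precision),
    max_subst = as.integer(max_subst), min_depth = as.integer(min_depth),
    err = err, min_rank = min_rank, max_missing_frac = max_missing_frac,
    max_cluster_size = as.integer(max_cluster_size),
    samples = unname(samples)
  )

  say("building de Bruijn graph (k = %d) from %d sample(s) ...", config$k, length(samples))
  graph <- kmer_graph(samples, k = config$k, min_abundance = config$min_abundance)
  say("  %s solid canonical k-mers", format(graph$n_kmers, big.mark = ","))

  say("detecting bubbles ...")
  bubbles <- detect_bubbles(graph, max_snps = config$max_snps,
                            max_sbc = config$max_sbc, max_indel = config$max_indel,
                            high_precision = config$high_precision)
  bubbles <- extend_contexts(graph, bubbles)
  say("  %d bubble(s) found", nrow(bubbles))

  say("mapping reads back on bubble sequences ...")
  coverage <- map_allele_coverage(bubbles, samples, max_subst = config$max_subst,
                                  k = config$k)
  genotypes <- call_genotypes(coverage, min_depth = config$min_depth,
                              err = config$err)
  ranks <- if (nrow(bubbles) > 0L) rank_variants(coverage) else
    tibble(bubble_id = integer(), rank = numeric())
  miss <- summarise(group_by(genotypes, .data$bubble_id),
                    missing_frac = mean(.data$gt == "./."), .groups = "drop")

  variants <- left_join(bubbles, ranks, by = "bubble_id")
  variants <- left_join(variants, miss, by = "bubble_id")
  variants <- mutate(variants,
                     rank = ifelse(is.na(.data$rank), 0, .data$rank),
                     missing_frac = ifelse(is.na(.data$missing_frac), 1,
                                           .data$missing_frac))

  n_bubbles <- nrow(variants)
  variants <- filter_rank(variants, min_rank = config$min_rank)
  n_rank_dropped <- n_bubbles - nrow(variants)
  say("  %d variant(s) after rank filter (rank >= %.2f; %d dropped)",
      nrow(variants), config$min_rank, n_rank_dropped)
  n_before <- nrow(variants)
  variants <- filter_missing(variants, max_missing_frac = config$max_missing_frac)
  n_missing_dropped <- n_before - nrow(variants)
  say("  %d variant(s) after missingness filter (%d dropped)",
      nrow(variants), n_missing_dropped)

  say("clustering variants per locus (shared %d-mers) ...", config$k - 1L)
  clusters <- if (nrow(variants) > 0L) cluster_variants(variants, k = config$k) else
    tibble(bubble_id = integer(), cluster_id = integer(), cluster_size = integer())
  fl <- filter_large_clusters(clusters, max_cluster_size = config$max_cluster_size)
  n_cluster_dropped <- length(fl$dropped)
  variants <- filter(variants, !(.data$bubble_id %in% fl$dropped))
  variants <- left_join(variants, fl$clusters, by = "bubble_id")
  say("  %d cluster(s) formed, %d oversized cluster variant(s) dropped",
      length(unique(fl$clusters$cluster_id)), n_cluster_dropped)

  records <- variant_records(variants, fl$clusters, ranks)
  kept_genotypes <- filter(genotypes, .data$bubble_id %in% variants$bubble_id)

  stats <- tibble(
    n_samples = length(samples), n_kmers = graph$n_kmers,
    n_bubbles = n_bubbles, n_rank_dropped = n_rank_dropped,
    n_missing_dropped = n_missing_dropped, n_cluster_dropped = n_cluster_dropped,
    n_clusters = length(unique(fl$clusters$cluster_id)),
    n_variants = nrow(variants), n_records = nrow(records)
  )

  res <- structure(
    list(variants = bubble_attrs(variants, graph), records = records,
         genotypes = kept_genotypes, coverage = coverage,
         sample_names = graph$sample_names, stats = stats, config = config),
    class = "rad_call"
  )
  if (!is.null(out_vcf)) {
    write_variant_vcf(records, kept_genotypes, graph$sample_names, out_vcf)
    say("wrote %d record(s) to %s", nrow(records), out_vcf)
  }
  res
}

#' @export
print.rad_call <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    paste0("radbubbles call: %d sample(s), %d bubble(s) -> %d variant(s) in %d",
           " cluster(s) (%d VCF record(s))\n"),
    s$n_samples, s$n_bubbles, s$n_variants, s$n_clusters, s$n_records
  ))
  cat(sprintf("filters dropped: rank %d, missingness %d, oversized clusters %d\n",
              s$n_rank_dropped, s$n_missing_dropped, s$n_cluster_dropped))
  invisible(x)
}
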