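#' Shared (k-1)-mer graph over bubbles
#'
#' Two bubbles are connected when any of their two context-extended sequences
#' share at least one canonical (k-1)-mer; connected components of this graph
#' group the variants of one RAD locus.
#'
#' @param bubbles A tibble from [extend_contexts()].
#' @param k The graph k-mer size (edges use (k-1)-mers); defaults to the value
#'   carried by `bubbles`.
#' @return A tibble of undirected edges with columns `from` and `to`
#'   (bubble ids, `from < to`).
#' @export
build_share_graph <- function(bubbles, k = attr(bubbles, "k")) {
  stopifnot(all(c("extended_a", "extended_b") %in% names(bubbles)))
  if (is.null(k)) stop("`k` is required (not carried by `bubbles`)", call. = FALSE)
  m <- as.integer(k) - 1L
  if (nrow(bubbles) < 2L) return(tibble(from = integer(), to = integer()))
  kms <- cpp_canonical_kmers(c(bubbles$extended_a, bubbles$extended_b), m)
  id <- rep(bubbles$bubble_id, 2L)
  tab <- tibble(
    bubble = rep(id, lengths(kms)),
    kmer = unlist(kms, use.names = FALSE)
  )
  tab <- distinct(tab)
  pairs <- inner_join(tab, tab, by = "kmer", relationship = "many-to-many")
  pairs <- filter(pairs, .data$bubble.x < .data$bubble.y)
  pairs <- distinct(select(pairs, from = "bubble.x", to = "bubble.y"))
  arrange(pairs, .data$from, .data$to)
}

#' Connected components with deterministic cluster ids
#'
#' Cluster ids are consecutive integers assigned in order of each component's
#' smallest member id, so the labelling does not depend on input order.
#'
#' @param edges A tibble with columns `from` and `to` (node ids).
#' @param ids All node ids (isolated nodes become singleton clusters).
#' @return A tibble with columns `bubble_id`, `cluster_id` and `cluster_size`.
#' @export
connected_components <- function(edges, ids) {
  ids <- sort(unique(as.integer(ids)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE, vertices = data.frame(name = as.character(ids))
  )
  comp <- igraph::components(g)$membership
  member <- comp[as.character(ids)]
  smallest <- tapply(ids, member, min)
  relabel <- rank(smallest)  # order components by smallest member id
  cl <- as.integer(relabel[as.character(member)])
  sizes <- table(cl)
  tibble(bubble_id = ids, cluster_id = cl,
         cluster_size = as.integer(sizes[as.character(cl)]))
}

#' Cluster variants into RAD loci
#'
#' Convenience wrapper: [build_share_graph()] then [connected_components()].
#'
#' @inheritParams build_share_graph
#' @return A tibble with columns `bubble_id`, `cluster_id`, `cluster_size`.
#' @export
cluster_variants <- function(bubbles, k = attr(bubbles, "k")) {
  connected_components(build_share_graph(bubbles, k), bubbles$bubble_id)
}

#' Discard oversized clusters
#'
#' Clusters with more than `max_cluster_size` variants are likely to aggregate
#' paralogous variants from repetitive regions and are removed together with
#' all their variants. Dropped variant ids are returned rather than silently
#' deleted.
#'
#' @param clusters A tibble from [connected_components()].
#' @param max_cluster_size Largest cluster size kept.
#' @return A list with `clusters` (surviving rows) and `dropped` (variant ids
#'   of removed clusters).
#' @export
filter_large_clusters <- function(clusters, max_cluster_size = 150L) {
  drop <- clusters$cluster_size > max_cluster_size
  list(
    clusters = clusters[!drop, , drop = FALSE],
    dropped = clusters$bubble_id[drop]
  )
}
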