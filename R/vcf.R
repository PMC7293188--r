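#' Expand bubbles into VCF-style variant records
#'
#' SNP-kind bubbles yield one record per variant offset (single-base ref/alt
#' taken from `path_a`/`path_b`); indel bubbles yield one left-anchored record
#' (anchor base included, VCF convention). Since there is no reference genome,
#' `CHROM` is the pseudo-chromosome `cluster_<cluster_id>` (or `bubble_<id>`
#' when unclustered) and `POS` the 1-based offset of the variant within the
#' bubble's extended `path_a`.
#'
#' @param bubbles A tibble from [extend_contexts()].
#' @param clusters A tibble from [connected_components()], or `NULL`.
#' @param ranks A tibble from [rank_variants()], or `NULL`.
#' @return A tibble with one row per VCF record.
#' @export
variant_records <- function(bubbles, clusters = NULL, ranks = NULL) {
  cols <- list(
    record_id = character(), bubble_id = integer(), chrom = character(),
    pos = integer(), ref = character(), alt = character(), type = character(),
    rank = numeric(), cluster_id = integer(), cluster_size = integer()
  )
  if (nrow(bubbles) == 0L) return(as_tibble(cols))
  lc <- if ("left_context" %in% names(bubbles)) nchar(bubbles$left_context) else
    rep(0L, nrow(bubbles))
  rows <- vector("list", nrow(bubbles))
  for (i in seq_len(nrow(bubbles))) {
    off <- bubbles$variant_offsets[[i]]
    pa <- bubbles$path_a[[i]]
    pb <- bubbles$path_b[[i]]
    bid <- bubbles$bubble_id[[i]]
    if (bubbles$kind[[i]] == "INDEL") {
      o <- off[[1]]
      len <- off[[2]]
      a_long <- nchar(pa) > nchar(pb)
      long <- if (a_long) pa else pb
      short <- if (a_long) pb else pa
      if (o > 0L) {
        seg_long <- substr(long, o, o + len)    # anchor + segment
        seg_short <- substr(short, o, o)        # anchor
        pos <- lc[[i]] + o
      } else {
        seg_long <- substr(long, 1L, len + 1L)  # segment + following anchor
        seg_short <- substr(short, 1L, 1L)
        pos <- lc[[i]] + 1L
      }
      rows[[i]] <- tibble(
        record_id = sprintf("bubble_%d", bid), bubble_id = bid,
        pos = as.integer(pos),
        ref = if (a_long) seg_long else seg_short,
        alt = if (a_long) seg_short else seg_long,
        type = if (a_long) "DEL" else "INS"
      )
    } else {
      n_off <- length(off)
      rows[[i]] <- tibble(
        record_id = if (n_off == 1L) sprintf("bubble_%d", bid) else
          sprintf("bubble_%d_%d", bid, seq_len(n_off)),
        bubble_id = bid,
        pos = as.integer(lc[[i]] + off + 1L),
        ref = substring(pa, off + 1L, off + 1L),
        alt = substring(pb, off + 1L, off + 1L),
        type = "SNP"
      )
    }
  }
  rec <- bind_rows(rows)
  rk <- if (is.null(ranks)) tibble(bubble_id = integer(), rank = numeric()) else ranks
  cl <- if (is.null(clusters)) {
    tibble(bubble_id = integer(), cluster_id = integer(), cluster_size = integer())
  } else {
    clusters
  }
  rec <- left_join(rec, rk, by = "bubble_id")
  rec <- left_join(rec, select(cl, "bubble_id", "cluster_id", "cluster_size"),
                   by = "bubble_id")
  rec <- mutate(
    rec,
    rank = ifelse(is.na(.data$rank), 0, .data$rank),
    chrom = ifelse(is.na(.data$cluster_id),
                   sprintf("bubble_%d", .data$bubble_id),
                   sprintf("cluster_%d", .data$cluster_id))
  )
  arrange(
    select(rec, "record_id", "bubble_id", "chrom", "pos", "ref", "alt",
           "type", "rank", "cluster_id", "cluster_size"),
    !is.na(.data$cluster_id), .data$cluster_id, .data$bubble_id, .data$pos
  )
}

#' Write variant records and genotypes to a VCF 4.2 file
#'
#' `INFO` carries `Ty` (SNP/INS/DEL), `Rk` (rank, 3 decimals), `Cluster` and
#' `ClSize`; `FORMAT` is `GT:DP:AD`. Missing genotypes are rendered `./.`.
#'
#' @param records A tibble from [variant_records()].
#' @param genotypes A tibble with columns `bubble_id`, `sample_idx`, `gt`,
#'   `depth`, `count_a`, `count_b` (one row per bubble and sample), as
#'   produced by the calling pipeline.
#' @param sample_names Sample names, in input order (defines column order).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(records, genotypes, sample_names, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##fileDate=", format(Sys.Date(), "%Y%m%d")),
    sprintf("##source=radbubbles %s", as.character(utils::packageVersion("radbubbles"))),
    "##INFO=<ID=Ty,Number=1,Type=String,Description=\"Variant type (SNP, INS or DEL)\">",
    "##INFO=<ID=Rk,Number=1,Type=Float,Description=\"Rank: max pairwise Phi coefficient of allele counts\">",
    "##INFO=<ID=Cluster,Number=1,Type=Integer,Description=\"Locus cluster id (shared (k-1)-mer connected component)\">",
    "##INFO=<ID=ClSize,Number=1,Type=Integer,Description=\"Number of variants in the locus cluster\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth over both alleles (variant-informative reads)\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            sample_names), collapse = "\t")
  )
  writeLines(header, con)
  if (nrow(records) == 0L) return(invisible(path))

  gt_str <- sprintf("%s:%d:%d,%d", genotypes$gt, genotypes$depth,
                    genotypes$count_a, genotypes$count_b)
  gm <- matrix("", nrow = length(unique(genotypes$bubble_id)), ncol = length(sample_names))
  bids <- sort(unique(genotypes$bubble_id))
  gm[cbind(match(genotypes$bubble_id, bids), genotypes$sample_idx)] <- gt_str
  gcol <- apply(gm, 1L, paste, collapse = "\t")
  info <- sprintf("Ty=%s;Rk=%.3f", records$type, records$rank)
  has_cl <- !is.na(records$cluster_id)
  info[has_cl] <- sprintf("%s;Cluster=%d;ClSize=%d", info[has_cl],
                          records$cluster_id[has_cl], records$cluster_size[has_cl])
  body <- paste(records$chrom, records$pos, records$record_id, records$ref,
                records$alt, ".", ".", info, "GT:DP:AD",
                gcol[match(records$bubble_id, bids)],
                sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Parse a VCF written by [write_variant_vcf()]
#'
#' @param path VCF file path.
#' @return A list with `records` (tibble), `genotypes` (long tibble),
#'   `sample_names` and `header` (the meta lines).
#' @export
read_variant_vcf <- function(path) {
  lines <- readLines(path)
  meta <- grepl("^##", lines)
  hline <- which(grepl("^#CHROM", lines))
  if (length(hline) != 1L) stop("malformed VCF: missing #CHROM header line", call. = FALSE)
  cols <- strsplit(lines[hline], "\t", fixed = TRUE)[[1]]
  sample_names <- cols[-(1:9)]
  body_idx <- which(!meta & !grepl("^#", lines) & nzchar(lines))
  recs <- vector("list", length(body_idx))
  gts <- vector("list", length(body_idx))
  for (i in seq_along(body_idx)) {
    ln <- body_idx[[i]]
    f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L + length(sample_names)) {
      stop(sprintf("malformed VCF record at line %d: %d fields, expected %d",
                   ln, length(f), 9L + length(sample_names)), call. = FALSE)
    }
    info <- parse_info(f[[8]], ln)
    bid <- as.integer(sub("^bubble_(\\d+).*$", "\\1", f[[3]]))
    recs[[i]] <- tibble(
      record_id = f[[3]], bubble_id = bid, chrom = f[[1]],
      pos = as.integer(f[[2]]), ref = f[[4]], alt = f[[5]],
      type = info[["Ty"]], rank = as.numeric(info[["Rk"]]),
      cluster_id = if (is.na(info[["Cluster"]])) NA_integer_ else as.integer(info[["Cluster"]]),
      cluster_size = if (is.na(info[["ClSize"]])) NA_integer_ else as.integer(info[["ClSize"]])
    )
    sf <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    ad <- strsplit(vapply(sf, `[`, character(1), 3L), ",", fixed = TRUE)
    gts[[i]] <- tibble(
      record_id = f[[3]], bubble_id = bid,
      sample = sample_names, sample_idx = seq_along(sample_names),
      gt = vapply(sf, `[`, character(1), 1L),
      depth = as.integer(vapply(sf, `[`, character(1), 2L)),
      count_a = as.integer(vapply(ad, `[`, character(1), 1L)),
      count_b = as.integer(vapply(ad, `[`, character(1), 2L))
    )
  }
  list(
    records = if (length(recs)) bind_rows(recs) else NULL,
    genotypes = if (length(gts)) bind_rows(gts) else NULL,
    sample_names = sample_names,
    header = lines[meta]
  )
}

parse_info <- function(x, line) {
  kv <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop(sprintf("malformed INFO field at line %d", line), call. = FALSE)
  vals <- setNames(vapply(kv, `[`, character(1), 2L), vapply(kv, `[`, character(1), 1L))
  out <- c(Ty = NA_character_, Rk = NA_character_, Cluster = NA_character_,
           ClSize = NA_character_)
  out[names(vals)] <- vals
  out
}

#' Post-filters for a called VCF
#'
#' Applies, in this fixed order (the order is part of the contract, as
#' reordering changes results): (1) genotypes with `DP < min_gt_depth` are set
#' missing; (2) variants with minor allele frequency below `maf` (computed
#' over non-missing genotypes, two alleles per diploid call) are removed;
#' (3) variants genotyped in fewer than `min_genotyped_frac` of the samples
#' are removed; (4) optionally, exactly one surviving variant per locus
#' cluster is retained, chosen uniformly at random under `seed`.
#'
#' @param input,output VCF file paths (as produced by [write_variant_vcf()]).
#' @param min_gt_depth Minimum genotype depth.
#' @param maf Minimal minor allele frequency kept.
#' @param min_genotyped_frac Minimal fraction of genotyped (non-missing)
#'   samples kept.
#' @param one_per_locus Keep a single random variant per cluster?
#' @param seed Seed for the one-per-locus draw (reproducibility).
#' @return `output`, invisibly.
#' @export
apply_post_filters <- function(input, output, min_gt_depth = 6L, maf = 0.01,
                               min_genotyped_frac = 0.6, one_per_locus = FALSE,
                               seed = 17L) {
  vcf <- read_variant_vcf(input)
  records <- vcf$records
  genotypes <- vcf$genotypes
  ns <- length(vcf$sample_names)
  if (!is.null(records) && nrow(records) > 0L) {
    genotypes <- mutate(genotypes,
                        gt = ifelse(.data$depth < min_gt_depth, "./.", .data$gt))
    stats <- summarise(
      group_by(genotypes, .data$record_id),
      n_called = sum(.data$gt != "./."),
      n_alt = sum((.data$gt == "0/1") + 2L * (.data$gt == "1/1")),
      .groups = "drop"
    )
    stats <- mutate(
      stats,
      f_alt = ifelse(.data$n_called > 0, .data$n_alt / (2 * .data$n_called), 0),
      maf_value = pmin(.data$f_alt, 1 - .data$f_alt),
      genotyped_frac = .data$n_called / ns
    )
    keep <- filter(stats, .data$maf_value >= maf, .data$genotyped_frac >= min_genotyped_frac)
    records <- filter(records, .data$record_id %in% keep$record_id)
    if (isTRUE(one_per_locus) && nrow(records) > 0L) {
      set.seed(seed)
      locus <- ifelse(is.na(records$cluster_id),
                      paste0("u", records$record_id),
                      paste0("c", records$cluster_id))
      chosen <- unlist(lapply(
        split(records$record_id, locus)[unique(locus[order(locus)])],
        function(ids) ids[sample.int(length(ids), 1L)]
      ))
      records <- filter(records, .data$record_id %in% chosen)
    }
    genotypes <- filter(genotypes, .data$record_id %in% records$record_id)
  }
  write_filtered_vcf(records, genotypes, vcf$sample_names, vcf$header, output)
  invisible(output)
}

# rewrite a parsed-and-filtered VCF (per-record genotypes, possibly masked)
write_filtered_vcf <- function(records, genotypes, sample_names, header, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_names), collapse = "\t"), con)
  if (is.null(records) || nrow(records) == 0L) return(invisible(path))
  info <- sprintf("Ty=%s;Rk=%.3f", records$type, records$rank)
  has_cl <- !is.na(records$cluster_id)
  info[has_cl] <- sprintf("%s;Cluster=%d;ClSize=%d", info[has_cl],
                          records$cluster_id[has_cl], records$cluster_size[has_cl])
  genotypes <- arrange(genotypes, match(.data$record_id, records$record_id),
                       .data$sample_idx)
  gt_str <- sprintf("%s:%d:%d,%d", genotypes$gt, genotypes$depth,
                    genotypes$count_a, genotypes$count_b)
  gcol <- vapply(split(gt_str, rep(seq_len(nrow(records)), each = length(sample_names))),
                 paste, character(1), collapse = "\t")
  body <- paste(records$chrom, records$pos, records$record_id, records$ref,
                records$alt, ".", ".", info, "GT:DP:AD", gcol, sep = "\t")
  writeLines(body, con)
  invisible(path)
}
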