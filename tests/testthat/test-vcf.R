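# VCF serialization and post-filters

# a small synthetic call set: 3 SNP records in 2 clusters + 1 unclustered indel
make_callset <- function() {
  bubbles <- tibble::tibble(
    bubble_id = 1:4,
    kind = c("SNP", "SNP", "SNP", "INDEL"),
    closure = "COMPLETE",
    path_a = c("ACGTACGTAAC", "TTGCAGCCGTA", "CCATGGCATCA", "AACCGGTTACGT"),
    path_b = c("ACGTATGTAAC", "TTGCACCCGTA", "CCATGACATCA", "AACCTTACGT"),
    variant_offsets = list(5L, 5L, 5L, c(4L, 2L)),
    sbc_crossed = 0L,
    left_context = c("TT", "", "A", ""),
    right_context = c("", "GG", "", "C")
  )
  bubbles$extended_a <- paste0(bubbles$left_context, bubbles$path_a, bubbles$right_context)
  bubbles$extended_b <- paste0(bubbles$left_context, bubbles$path_b, bubbles$right_context)
  clusters <- tibble::tibble(bubble_id = 1:3, cluster_id = c(1L, 1L, 2L),
                             cluster_size = c(2L, 2L, 1L))
  ranks <- tibble::tibble(bubble_id = 1:4, rank = c(0.6, 1, 0.45, 0.8))
  samples <- c("s1", "s2")
  genotypes <- tibble::tibble(
    bubble_id = rep(1:4, each = 2),
    sample = rep(samples, 4), sample_idx = rep(1:2, 4),
    gt = c("0/0", "0/1", "0/0", "1/1", "./.", "0/1", "0/0", "0/0"),
    depth = c(20L, 18L, 10L, 12L, 2L, 9L, 15L, 5L),
    count_a = c(20L, 9L, 10L, 0L, 2L, 5L, 15L, 5L),
    count_b = c(0L, 9L, 0L, 12L, 0L, 4L, 0L, 0L)
  )
  list(bubbles = bubbles, clusters = clusters, ranks = ranks,
       genotypes = genotypes, samples = samples)
}

test_that("variant records carry pseudo-coordinates, types and INFO fields", {
  cs <- make_callset()
  rec <- variant_records(cs$bubbles, cs$clusters, cs$ranks)
  expect_equal(nrow(rec), 4L)
  r1 <- rec[rec$bubble_id == 1, ]
  expect_equal(r1$chrom, "cluster_1")
  expect_equal(r1$pos, 2L + 5L + 1L)  # left context + 0-based offset + 1
  expect_equal(c(r1$ref, r1$alt), c("C", "T"))
  expect_equal(r1$type, "SNP")
  # unclustered indel: bubble chromosome, left-anchored alleles
  r4 <- rec[rec$bubble_id == 4, ]
  expect_equal(r4$chrom, "bubble_4")
  expect_equal(r4$type, "DEL")
  expect_equal(c(r4$ref, r4$alt), c("CGG", "C"))
  expect_equal(r4$pos, 4L)
})

test_that("VCF writing produces valid records that round-trip bit-identically", {
  cs <- make_callset()
  rec <- variant_records(cs$bubbles, cs$clusters, cs$ranks)
  f1 <- tempfile(fileext = ".vcf")
  write_variant_vcf(rec, cs$genotypes, cs$samples, f1)
  lines <- readLines(f1)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  expect_equal(sum(!grepl("^#", lines)), 4L)
  expect_match(grep("bubble_1\t", lines, value = TRUE, fixed = TRUE), "Rk=0.600",
               fixed = TRUE)
  expect_match(grep("bubble_1\t", lines, value = TRUE, fixed = TRUE),
               "0/0:20:20,0\t0/1:18:9,9", fixed = TRUE)
  # header lists both samples in input order
  expect_match(lines[grepl("^#CHROM", lines)], "FORMAT\ts1\ts2$")

  vcf <- read_variant_vcf(f1)
  expect_equal(vcf$sample_names, cs$samples)
  expect_equal(nrow(vcf$records), 4L)
  expect_equal(vcf$records$pos, rec$pos)
  expect_equal(vcf$records$rank, round(rec$rank, 3))
  expect_equal(vcf$records$cluster_id, rec$cluster_id)
  gt_in <- dplyr::arrange(cs$genotypes, bubble_id, sample_idx)
  gt_out <- dplyr::arrange(vcf$genotypes, bubble_id, sample_idx)
  expect_equal(gt_out$gt, gt_in$gt)
  expect_equal(gt_out$count_a, gt_in$count_a)

  # parse -> rewrite is byte-identical
  f2 <- tempfile(fileext = ".vcf")
  radbubbles:::write_filtered_vcf(vcf$records, vcf$genotypes, vcf$sample_names,
                                  vcf$header, f2)
  expect_identical(readLines(f2), lines)
})

test_that("written VCF is readable by an independent parser (vcfR)", {
  skip_if_not_installed("vcfR")
  cs <- make_callset()
  rec <- variant_records(cs$bubbles, cs$clusters, cs$ranks)
  f <- tempfile(fileext = ".vcf")
  write_variant_vcf(rec, cs$genotypes, cs$samples, f)
  v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
  expect_equal(nrow(v@fix), 4L)
  expect_equal(unname(v@fix[1, "POS"]), as.character(rec$pos[1]))
  gt <- vcfR::extract.gt(v)
  expect_equal(unname(gt[, "s1"])[1], "0/0")
})

test_that("malformed VCF lines are reported with their line number", {
  cs <- make_callset()
  rec <- variant_records(cs$bubbles, cs$clusters, cs$ranks)
  f <- tempfile(fileext = ".vcf")
  write_variant_vcf(rec, cs$genotypes, cs$samples, f)
  lines <- readLines(f)
  bad <- which(!grepl("^#", lines))[1]
  lines[bad] <- sub("\t[^\t]*$", "", lines[bad])
  writeLines(lines, f)
  expect_error(read_variant_vcf(f), sprintf("line %d", bad))
})

test_that("post-filters mask depth, then apply MAF and missingness", {
  cs <- make_callset()
  rec <- variant_records(cs$bubbles, cs$clusters, cs$ranks)
  f1 <- tempfile(fileext = ".vcf")
  write_variant_vcf(rec, cs$genotypes, cs$samples, f1)
  f2 <- tempfile(fileext = ".vcf")
  # bubble 3 has s1 at DP 2 (masked, 50% genotyped); bubble 4 has s2 at DP 5
  # (masked) and s1 0/0 -> MAF 0 -> removed; bubble 2 is 0/0+1/1 (MAF 0.5)
  apply_post_filters(f1, f2, min_gt_depth = 6, maf = 0.01,
                     min_genotyped_frac = 0.6)
  out <- read_variant_vcf(f2)
  expect_equal(sort(out$records$bubble_id), c(1L, 2L))
  # the depth mask is visible in the surviving genotypes? (none masked here)
  expect_true(all(out$genotypes$gt[out$genotypes$depth < 6] == "./."))

  # genotyped-fraction boundary: exactly 60% is kept, 59% is not
  expect_equal(nrow(read_variant_vcf(f2)$records), 2L)
})

test_that("MAF and genotyped-fraction boundaries are inclusive", {
  # 50 samples. bubble 1: one het among 50 -> MAF 1/100 = 0.01, kept at the
  # 0.01 threshold. bubble 2: all 0/0 -> MAF 0, removed. bubble 3: genotyped
  # in exactly 60% of samples, kept. bubble 4: 58% genotyped, removed.
  ns <- 50L
  paths_a <- c("ACGTACGTAAC", "TTGCAGCCGTA", "CCATGGCATCA", "GGATCACGATC")
  paths_b <- c("ACGTATGTAAC", "TTGCACCCGTA", "CCATGACATCA", "GGATCTCGATC")
  bubbles <- tibble::tibble(
    bubble_id = 1:4, kind = "SNP", closure = "COMPLETE",
    path_a = paths_a, path_b = paths_b,
    variant_offsets = list(5L, 5L, 5L, 5L), sbc_crossed = 0L,
    left_context = "", right_context = "",
    extended_a = paths_a, extended_b = paths_b
  )
  gts <- c(
    c("0/1", rep("0/0", ns - 1)),
    rep("0/0", ns),
    c(rep("0/1", 15), rep("0/0", 15), rep("./.", 20)),
    c(rep("0/1", 15), rep("0/0", 14), rep("./.", 21))
  )
  gt <- tibble::tibble(
    bubble_id = rep(1:4, each = ns),
    sample = rep(sprintf("s%02d", 1:ns), 4),
    sample_idx = rep(1:ns, 4),
    gt = gts,
    depth = ifelse(gts == "./.", 0L, 20L), count_a = 10L, count_b = 10L
  )
  rec <- variant_records(bubbles, NULL, tibble::tibble(bubble_id = 1:4, rank = 1))
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_variant_vcf(rec, gt, sprintf("s%02d", 1:ns), f1)
  apply_post_filters(f1, f2, min_gt_depth = 6, maf = 0.01, min_genotyped_frac = 0.6)
  expect_equal(sort(read_variant_vcf(f2)$records$bubble_id), c(1L, 3L))
})

test_that("one-per-locus thinning is seeded, reproducible and idempotent", {
  cs <- make_callset()
  rec <- variant_records(cs$bubbles, cs$clusters, cs$ranks)
  f1 <- tempfile(fileext = ".vcf")
  write_variant_vcf(rec, cs$genotypes, cs$samples, f1)
  outs <- replicate(2, {
    f <- tempfile(fileext = ".vcf")
    apply_post_filters(f1, f, min_gt_depth = 1, maf = 0, min_genotyped_frac = 0,
                       one_per_locus = TRUE, seed = 99)
    read_variant_vcf(f)$records$record_id
  }, simplify = FALSE)
  expect_identical(outs[[1]], outs[[2]])
  # exactly one record per cluster (cluster 1 had two), unclustered kept
  out <- outs[[1]]
  expect_equal(length(out), 3L)
  expect_equal(sum(out %in% c("bubble_1", "bubble_2")), 1L)

  # idempotence: filtering an already filtered VCF changes nothing
  fa <- tempfile(fileext = ".vcf"); fb <- tempfile(fileext = ".vcf")
  apply_post_filters(f1, fa, min_gt_depth = 6, maf = 0.01,
                     min_genotyped_frac = 0.6, one_per_locus = TRUE, seed = 5)
  apply_post_filters(fa, fb, min_gt_depth = 6, maf = 0.01,
                     min_genotyped_frac = 0.6, one_per_locus = TRUE, seed = 5)
  expect_identical(readLines(fa), readLines(fb))
})
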