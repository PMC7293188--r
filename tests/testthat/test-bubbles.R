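# bubble detection: complete, truncated, close SNPs, indels, contexts

# expected normalized representation of a two-path bubble: both orientations,
# paths sorted within each, smaller tuple wins (independent oracle for the
# dedup/normalization convention)
normalize_pair <- function(p1, p2) {
  fwd <- c(min(p1, p2), max(p1, p2))
  q1 <- revcomp(p1); q2 <- revcomp(p2)
  rev <- c(min(q1, q2), max(q1, q2))
  if (fwd[1] < rev[1] || (fwd[1] == rev[1] && fwd[2] <= rev[2])) fwd else rev
}

test_that("an isolated SNP yields one complete bubble of length 2k+1 centred on it", {
  set.seed(10)
  k <- 15; L <- 60; p <- 30
  h1 <- rnd_seq(L)
  h2 <- plant_snps(h1, p)
  b <- bubbles_from_haplotypes(h1, h2, k = k)
  expect_equal(nrow(b), 1L)
  expect_equal(b$kind, "SNP")
  expect_equal(b$closure, "COMPLETE")
  expect_equal(nchar(b$path_a), 2 * k + 1)
  expect_equal(b$variant_offsets[[1]], k)
  # paths are the +/- (k) windows around the SNP, up to strand normalization
  w1 <- substr(h1, p + 1 - k, p + 1 + k)
  w2 <- substr(h2, p + 1 - k, p + 1 + k)
  expect_equal(c(b$path_a, b$path_b), normalize_pair(w1, w2))
  # paths differ exactly at the variant offsets and nowhere else
  expect_equal(mismatch_positions(b$path_a, b$path_b), b$variant_offsets[[1]])
})

test_that("a SNP within k of the locus end yields a symmetrically truncated bubble", {
  set.seed(11)
  k <- 15; L <- 50; p <- L - 5  # 4 bp from the end
  h1 <- rnd_seq(L)
  h2 <- plant_snps(h1, p)
  g <- graph_from_reads(c(h1, h2), k = k)
  b <- detect_bubbles(g)
  expect_equal(nrow(b), 1L)
  expect_equal(b$kind, "SNP")
  expect_true(b$closure %in% c("LEFT_TRUNCATED", "RIGHT_TRUNCATED"))
  expect_equal(nchar(b$path_a), nchar(b$path_b))
  # identical last 3-mer on the truncated side
  side_right <- b$closure == "RIGHT_TRUNCATED"
  last3 <- function(x) substr(x, nchar(x) - 2, nchar(x))
  first3 <- function(x) substr(x, 1, 3)
  if (side_right) expect_equal(last3(b$path_a), last3(b$path_b))
  else expect_equal(first3(b$path_a), first3(b$path_b))
  # terminal k-mers on the truncated side have no successors in the graph
  term <- function(x) if (side_right) substr(x, nchar(x) - k + 1, nchar(x)) else
    revcomp(substr(x, 1, k))
  expect_equal(nrow(successors(g, term(b$path_a))), 0L)
  expect_equal(nrow(successors(g, term(b$path_b))), 0L)
})

test_that("truncation requires an identical last 3-mer", {
  set.seed(12)
  k <- 15; L <- 50
  h1 <- rnd_seq(L)
  # a difference 4 bp from the end plus one in the final 3-mer: ambiguous event
  h2 <- plant_snps(h1, c(L - 5, L - 1))
  b <- detect_bubbles(graph_from_reads(c(h1, h2), k = k))
  expect_equal(nrow(b), 0L)
})

test_that("a single haplotype produces no bubbles", {
  set.seed(13)
  b <- detect_bubbles(graph_from_reads(rnd_seq(80), k = 15))
  expect_equal(nrow(b), 0L)
  # and an empty graph is tolerated
  g <- graph_from_reads("ACTGAC", k = 5, min_abundance = 5)
  expect_equal(nrow(detect_bubbles(g)), 0L)
})

test_that("position sweep: complete iff k <= p <= L-k-1, nothing within 3 bp of ends", {
  set.seed(14)
  k <- 15; L <- 60
  h1 <- rnd_seq(L)
  closure <- character(L)
  for (p in 0:(L - 1)) {
    h2 <- plant_snps(h1, p)
    b <- detect_bubbles(graph_from_reads(c(h1, h2), k = k))
    closure[p + 1] <- if (nrow(b) == 0) "none" else b$closure
  }
  pos <- 0:(L - 1)
  expect_equal(which(closure == "COMPLETE") - 1, pos[pos >= k & pos <= L - k - 1])
  expect_equal(which(closure == "none") - 1, c(0:2, (L - 3):(L - 1)))
  expect_true(all(closure[c(4:k, (L - k + 1):(L - 3))] %in%
                    c("LEFT_TRUNCATED", "RIGHT_TRUNCATED")))
})

test_that("bubble detection is strand-invariant up to representation", {
  set.seed(15)
  k <- 15; L <- 70
  h1 <- rnd_seq(L)
  h2 <- plant_snps(h1, c(20, 24, 66))
  b1 <- detect_bubbles(graph_from_reads(c(h1, h2), k = k))
  b2 <- detect_bubbles(graph_from_reads(revcomp(c(h1, h2)), k = k))
  cols <- c("kind", "closure", "path_a", "path_b", "variant_offsets")
  o1 <- b1[do.call(order, b1[c("path_a", "path_b")]), cols]
  o2 <- b2[do.call(order, b2[c("path_a", "path_b")]), cols]
  expect_equal(as.list(o1), as.list(o2), ignore_attr = TRUE)
})

test_that("close SNPs within k collapse into one bubble, bounded by max_snps", {
  set.seed(16)
  k <- 15; L <- 70
  h1 <- rnd_seq(L)
  h2 <- plant_snps(h1, c(30, 35))
  b <- bubbles_from_haplotypes(h1, h2, k = k)
  expect_equal(nrow(b), 1L)
  expect_equal(b$kind, "CLOSE_SNPS")
  expect_equal(diff(b$variant_offsets[[1]]), 5)
  expect_equal(mismatch_positions(b$path_a, b$path_b), b$variant_offsets[[1]])
  # with max_snps = 1 the bubble is abandoned
  g <- graph_from_reads(c(h1, h2), k = k)
  expect_equal(nrow(detect_bubbles(g, max_snps = 1)), 0L)
})

test_that("small indels are detected with leftmost placement; capped by max_indel", {
  set.seed(17)
  k <- 15; L <- 70; at <- 35
  h1 <- rnd_seq(L)
  ins <- "GT"
  h2 <- paste0(substr(h1, 1, at), ins, substr(h1, at + 1, L))
  g <- graph_from_reads(c(h1, h2), k = k)
  b <- detect_bubbles(g)
  b <- b[b$kind == "INDEL", ]
  expect_equal(nrow(b), 1L)
  expect_equal(abs(nchar(b$path_a) - nchar(b$path_b)), 2L)
  o <- b$variant_offsets[[1]]
  long <- if (nchar(b$path_a) > nchar(b$path_b)) b$path_a else b$path_b
  short <- if (nchar(b$path_a) > nchar(b$path_b)) b$path_b else b$path_a
  # removing the reported segment from the long path restores the short path
  expect_equal(paste0(substr(long, 1, o[1]), substr(long, o[1] + o[2] + 1, nchar(long))),
               short)
  # leftmost: the segment cannot slide one position left
  if (o[1] > 0) {
    expect_false(substr(long, o[1], o[1]) == substr(long, o[1] + o[2], o[1] + o[2]))
  }
  expect_equal(nrow(detect_bubbles(g, max_indel = 1)), 0L)
  # deletions are the same motif discovered from the other haplotype order
  b2 <- detect_bubbles(graph_from_reads(c(h2, h1), k = k))
  expect_equal(b2$path_a[b2$kind == "INDEL"], b$path_a)
})

test_that("crossroad traversal is capped, monotone, and disabled by high_precision", {
  set.seed(18)
  k <- 15; L <- 70
  ref <- rnd_seq(L)
  hA <- plant_snps(ref, 30)   # three extra haplotypes with close SNPs create
  hB <- plant_snps(ref, 36)   # entangled bubbles and crossroads
  hAB <- plant_snps(ref, c(30, 36))
  reads <- c(ref, hA, hB, hAB)
  g <- graph_from_reads(reads, k = k)
  sets <- lapply(0:3, function(s) {
    b <- detect_bubbles(g, max_sbc = s)
    paste(b$path_a, b$path_b)
  })
  for (s in 1:3) expect_true(all(sets[[s]] %in% sets[[s + 1]]))
  expect_true(any(detect_bubbles(g)$sbc_crossed > 0))
  hp <- detect_bubbles(g, high_precision = TRUE)
  expect_true(all(hp$sbc_crossed == 0))
  expect_true(all(paste(hp$path_a, hp$path_b) %in% sets[[4]]))
})

test_that("contexts extend to the first ambiguity and serialize as lowercase", {
  set.seed(19)
  k <- 15; L <- 120
  h1 <- rnd_seq(L)
  h2 <- plant_snps(h1, c(40, 80))  # two far-apart SNPs: two complete bubbles
  g <- graph_from_reads(c(h1, h2), k = k)
  b <- extend_contexts(g, detect_bubbles(g))
  expect_equal(nrow(b), 2L)
  # each extended sequence is a substring of one haplotype (either strand)
  for (i in 1:2) {
    hits <- c(grepl(b$extended_a[i], h1, fixed = TRUE),
              grepl(b$extended_a[i], h2, fixed = TRUE),
              grepl(revcomp(b$extended_a[i]), h1, fixed = TRUE),
              grepl(revcomp(b$extended_a[i]), h2, fixed = TRUE))
    expect_true(any(hits))
  }
  # the two extended bubbles overlap between the SNPs: they share (k-1)-mers
  edges <- build_share_graph(b, k = k)
  expect_equal(nrow(edges), 1L)

  # FASTA serialization round trip, contexts lowercased
  fa <- tempfile(fileext = ".fa")
  write_bubble_fasta(b, fa)
  lines <- readLines(fa)
  expect_equal(length(lines), 8L)
  seq1 <- lines[[2]]
  expect_match(seq1, "^[acgt]*[ACGT]+[acgt]*$")
  rt <- read_bubble_fasta(fa)
  expect_equal(rt$path_a, b$path_a)
  expect_equal(rt$extended_a, b$extended_a)
  expect_equal(rt$variant_offsets, b$variant_offsets)
  expect_equal(attr(rt, "k"), k)
})

test_that("detector agrees with a brute-force two-haplotype oracle", {
  set.seed(20)
  n_cases <- 30
  for (case in seq_len(n_cases)) {
    k <- sample(c(15L, 21L), 1)
    L <- sample(80:200, 1)
    n_snp <- sample(1:3, 1)
    h1 <- rnd_seq(L)
    pos <- sort(sample(3:(L - 4), n_snp))
    h2 <- plant_snps(h1, pos)
    b <- bubbles_from_haplotypes(h1, h2, k = k)
    sites <- localize_predictions(b, c(locus = h1), k = k)
    found <- sort(unique(sites$offset[sites$status == "localized"]))
    expect_equal(found, pos, info = sprintf("case %d (k=%d L=%d)", case, k, L))
  }
})
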