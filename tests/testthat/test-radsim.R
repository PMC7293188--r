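# RAD population simulator

test_that("restriction digest yields two flanking loci per usable site", {
  set.seed(50)
  pad <- function(n) rnd_seq(n)
  site <- "CTGCAG"
  contig <- paste0(pad(30), site, pad(50), site, pad(30))
  loci <- digest_genome(c(chrA = contig), site = site, flank = 20)
  expect_equal(nrow(loci), 4L)  # 2 internal sites x 2 sides
  expect_true(all(nchar(loci$seq) == 20))
  # loci flank the site exactly
  up <- loci[loci$side == "up", ]
  down <- loci[loci$side == "down", ]
  for (i in seq_len(nrow(up))) {
    expect_equal(substr(contig, up$site_pos[i] - 20, up$site_pos[i] - 1), up$seq[i])
  }
  for (i in seq_len(nrow(down))) {
    expect_equal(substr(contig, down$site_pos[i] + 6, down$site_pos[i] + 25), down$seq[i])
  }

  # a site too close to the contig edge loses that side's locus
  contig2 <- paste0(pad(10), site, pad(40))
  loci2 <- digest_genome(c(chrB = contig2), site = site, flank = 20)
  expect_equal(loci2$side, "down")
  # no site, no loci; empty genome errors
  expect_equal(nrow(digest_genome(c(chrC = pad(60)), site = site, flank = 20)), 0L)
  expect_error(digest_genome(character(0)), "empty genome")
})

test_that("variant injection respects shared/private structure and het fraction", {
  set.seed(51)
  loci <- tibble::tibble(locus_id = sprintf("locus_%d", 1:40),
                         seq = replicate(40, rnd_seq(150)))
  # no private picks, no heterozygosity: every individual carries exactly the
  # shared set, all genotypes homozygous alternate
  cfg <- sim_config(n_populations = 1, individuals_per_population = 3,
                    private_pick_fraction = 0, het_fraction = 0, seed = NULL)
  sim <- simulate_variants(loci, cfg)
  expect_true(all(sim$genotypes == "1/1"))
  # size is ~ shared_fraction * snp_rate * positions (binomial, loose bounds)
  expect_gt(nrow(sim$truth), 0.7 * 0.01 * 6000 * 0.5)
  expect_lt(nrow(sim$truth), 0.7 * 0.01 * 6000 * 1.6)

  # het_fraction 1: every carried genotype is heterozygous
  set.seed(52)
  cfg2 <- sim_config(n_populations = 1, individuals_per_population = 2,
                     private_pick_fraction = 0, het_fraction = 1, seed = NULL)
  sim2 <- simulate_variants(loci, cfg2)
  expect_true(all(sim2$genotypes == "0/1"))

  # shared + private: shared variants are carried by everyone in the
  # population, private ones by a strict subset
  set.seed(53)
  cfg3 <- sim_config(n_populations = 2, individuals_per_population = 5, seed = NULL)
  sim3 <- simulate_variants(loci, cfg3)
  pop <- rep(1:2, each = 5)
  carriers <- rowSums(sim3$genotypes != "0/0")
  carriers_p1 <- rowSums(sim3$genotypes[, pop == 1, drop = FALSE] != "0/0")
  carriers_p2 <- rowSums(sim3$genotypes[, pop == 2, drop = FALSE] != "0/0")
  expect_true(all(carriers > 0))  # uncarried candidates are dropped
  # a shared-in-pop1 variant has all 5 pop-1 individuals as carriers
  expect_true(any(carriers_p1 == 5))
  expect_true(any(carriers_p1 %in% 1:4))  # private picks exist too
  # heterozygous fraction among carried genotypes is near het_fraction
  carried <- sim3$genotypes[sim3$genotypes != "0/0"]
  p_het <- mean(carried == "0/1")
  se <- sqrt(0.1 * 0.9 / length(carried))
  expect_lt(abs(p_het - 0.1), 4 * se + 0.02)
})

test_that("haplotypes are exactly the references with truth genotypes applied", {
  set.seed(54)
  ds <- small_sim(seed = 54, genome_length = 3e4, n_ind = 3)
  ref <- setNames(ds$loci$seq, ds$loci$locus_id)
  for (ind in sample(colnames(ds$genotypes), 3)) {
    h <- ds$haplotypes[[ind]]
    for (v in seq_len(nrow(ds$truth))) {
      lid <- ds$truth$locus_id[v]
      p <- ds$truth$offset[v] + 1
      gt <- ds$genotypes[v, ind]
      n_alt <- (substr(h$h1[[lid]], p, p) == ds$truth$alt[v]) +
        (substr(h$h2[[lid]], p, p) == ds$truth$alt[v])
      expected <- c("0/0" = 0, "0/1" = 1, "1/1" = 2)[[gt]]
      expect_equal(n_alt, expected)
    }
    # positions without variants match the reference everywhere
    clean <- ds$truth$locus_id[1]
    off <- ds$truth$offset[ds$truth$locus_id == clean]
    keep <- setdiff(seq_len(nchar(ref[[clean]])) - 1, off)
    split1 <- strsplit(h$h1[[clean]], "")[[1]]
    expect_equal(split1[keep + 1], strsplit(ref[[clean]], "")[[1]][keep + 1])
  }
})

test_that("reads start at the locus start, split evenly across homologs", {
  set.seed(55)
  ds <- small_sim(seed = 55, genome_length = 2e4, n_ind = 2, error_rate = 0,
                  coverage = 20)
  fq <- ds$samples[[1]]
  lines <- readLines(gzfile(fq))
  reads <- lines[seq(2, length(lines), by = 4)]
  ids <- lines[seq(1, length(lines), by = 4)]
  expect_equal(length(reads), 20 * nrow(ds$loci))
  expect_true(all(nchar(reads) == 150))
  # error-free reads equal a homolog prefix for their locus
  ind <- names(ds$samples)[1]
  locus_of <- sub(sprintf("^@%s_(locus_\\d+)_.*$", ind), "\\1", ids)
  h <- ds$haplotypes[[ind]]
  ok <- reads == substr(h$h1[locus_of], 1, 150) |
    reads == substr(h$h2[locus_of], 1, 150)
  expect_true(all(ok))
  # even coverage split: 10 reads per homolog
  hom_of <- sub("^.*_(h[12])_r\\d+$", "\\1", ids)
  counts <- table(locus_of, hom_of)
  expect_true(all(counts == 10))
})

test_that("the empirical substitution rate matches error_rate", {
  set.seed(56)
  n <- 1500
  tmpl <- replicate(n, rnd_seq(100))
  mut <- radbubbles:::cpp_mutate_reads(tmpl, 0.01)
  mism <- sum(mapply(function(a, b) length(mismatch_positions(a, b)), tmpl, mut))
  total <- 100 * n
  se <- sqrt(0.01 * 0.99 * total)
  expect_lt(abs(mism - 0.01 * total), 4 * se)
  # error_rate 0: reads are untouched
  expect_identical(radbubbles:::cpp_mutate_reads(tmpl[1:10], 0), tmpl[1:10])
})

test_that("the simulator is fully deterministic under (config, seed)", {
  cfg <- sim_config(n_populations = 1, individuals_per_population = 2, seed = 57)
  d1 <- simulate_rad_dataset(cfg, dir = tempfile(), genome_length = 2e4)
  d2 <- simulate_rad_dataset(cfg, dir = tempfile(), genome_length = 2e4)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(readLines(gzfile(d1$samples[[1]])),
                   readLines(gzfile(d2$samples[[1]])))
  # written artifacts round-trip
  tr <- read_truth(file.path(d1$dir, "truth.tsv"))
  expect_equal(tr$truth, d1$truth)
  expect_equal(tr$genotypes, d1$genotypes, ignore_attr = TRUE)
  cfg_json <- jsonlite::read_json(file.path(d1$dir, "simconfig.json"),
                                  simplifyVector = TRUE)
  expect_equal(cfg_json$seed, 57)
})
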