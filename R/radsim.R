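#' Configuration for the RAD population simulator
#'
#' Defaults reproduce the simulation protocol used throughout the package's
#' benchmarks: PstI digest with 150 bp loci on both sides of each site,
#' populations of 20 diploid individuals, SNPs at 1% per locus position of
#' which 70% are shared by the whole population and the rest distributed by
#' random 10% picks per individual, 10% heterozygous carriers, forward 150 bp
#' reads at 20x per individual with 1% substitution errors.
#'
#' @param enzyme_site Restriction site (fixed ACGT word; default PstI).
#' @param flank Locus length taken on each side of a site, bp.
#' @param n_populations,individuals_per_population Population layout.
#' @param snp_rate Per-position probability of a candidate SNP, per population.
#' @param shared_fraction Fraction of candidates given to every individual of
#'   the population.
#' @param private_pick_fraction Fraction of the remaining pool drawn
#'   independently (without replacement) by each individual.
#' @param het_fraction Probability that a carried SNP sits on a single
#'   homologous chromosome.
#' @param read_length Read length, bp (reads are clipped to the locus length).
#' @param coverage Reads per locus per individual.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed; all simulator randomness is derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(enzyme_site = "CTGCAG", flank = 150L, n_populations = 2L,
                       individuals_per_population = 20L, snp_rate = 0.01,
                       shared_fraction = 0.7, private_pick_fraction = 0.1,
                       het_fraction = 0.1, read_length = 150L, coverage = 20L,
                       error_rate = 0.01, seed = 1L) {
  cfg <- list(
    enzyme_site = toupper(enzyme_site), flank = as.integer(flank),
    n_populations = as.integer(n_populations),
    individuals_per_population = as.integer(individuals_per_population),
    snp_rate = snp_rate, shared_fraction = shared_fraction,
    private_pick_fraction = private_pick_fraction, het_fraction = het_fraction,
    read_length = as.integer(read_length), coverage = as.integer(coverage),
    error_rate = error_rate, seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  fr <- c("snp_rate", "shared_fraction", "private_pick_fraction", "het_fraction",
          "error_rate")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(sprintf("`%s` must be in [0, 1]", f), call. = FALSE)
  }
  if (!grepl("^[ACGT]+$", cfg$enzyme_site)) {
    stop("`enzyme_site` must be a fixed ACGT word", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Random genome as a single-contig DNA string
#'
#' Uniform base composition; uses the current RNG stream.
#'
#' @param length Genome length in bp.
#' @return A named character vector of length 1 (contig `chr1`).
#' @export
random_genome <- function(length) {
  c(chr1 = paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
}

#' Digest a genome into RAD loci
#'
#' For every occurrence of the restriction site on the forward strand of each
#' contig, two loci are produced: the `flank` bp immediately upstream and the
#' `flank` bp immediately downstream of the site. Occurrences closer than
#' `flank` to a contig edge lose that side's locus.
#'
#' @param genome A FASTA file path, a `Biostrings::DNAStringSet`, or a (named)
#'   character vector of contig sequences.
#' @param site Restriction site (fixed ACGT word).
#' @param flank Locus length, bp.
#' @return A tibble with columns `locus_id`, `contig`, `site_pos` (1-based
#'   start of the site occurrence), `side` (`"up"`/`"down"`), `start` (0-based
#'   genome offset of the locus) and `seq`.
#' @export
digest_genome <- function(genome, site = "CTGCAG", flank = 150L) {
  seqs <- load_contigs(genome)
  if (length(seqs) == 0L || all(nchar(seqs) == 0L)) {
    stop("empty genome: nothing to digest", call. = FALSE)
  }
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site)) stop("`site` must be a fixed ACGT word", call. = FALSE)
  flank <- as.integer(flank)
  out <- vector("list", length(seqs))
  for (ci in seq_along(seqs)) {
    s <- seqs[[ci]]
    n <- nchar(s)
    hits <- as.integer(
      Biostrings::start(Biostrings::matchPattern(site, Biostrings::DNAString(s)))
    )
    if (length(hits) == 0L) next
    up_ok <- hits - flank >= 1L
    down_ok <- hits + nchar(site) + flank - 1L <= n
    rows <- list()
    if (any(up_ok)) {
      h <- hits[up_ok]
      rows$up <- tibble(contig = names(seqs)[[ci]], site_pos = h, side = "up",
                        start = h - flank - 1L,
                        seq = substring(s, h - flank, h - 1L))
    }
    if (any(down_ok)) {
      h <- hits[down_ok]
      rows$down <- tibble(contig = names(seqs)[[ci]], site_pos = h, side = "down",
                          start = h + nchar(site) - 1L,
                          seq = substring(s, h + nchar(site), h + nchar(site) + flank - 1L))
    }
    out[[ci]] <- bind_rows(rows)
  }
  loci <- bind_rows(out)
  if (nrow(loci) == 0L) {
    return(tibble(locus_id = character(), contig = character(),
                  site_pos = integer(), side = character(), start = integer(),
                  seq = character()))
  }
  loci <- arrange(loci, .data$contig, .data$site_pos, .data$side)
  mutate(loci, locus_id = sprintf("locus_%d", row_number()),
         .before = "contig")
}

load_contigs <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    return(setNames(as.character(genome), names(genome)))
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    x <- Biostrings::readDNAStringSet(genome)
    nm <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
    return(setNames(as.character(x), nm))
  }
  if (is.character(genome)) {
    nm <- names(genome) %||% sprintf("contig_%d", seq_along(genome))
    return(setNames(toupper(genome), nm))
  }
  stop("`genome` must be a FASTA path, DNAStringSet or character vector", call. = FALSE)
}

#' Simulate population SNPs over RAD loci
#'
#' Per population, candidate SNP positions are drawn uniformly over all locus
#' positions at rate `snp_rate`, each with a random alternate base. A
#' `shared_fraction` subset is given to every individual of the population;
#' from the remaining pool each individual independently draws a
#' `private_pick_fraction` sample without replacement. Each carried SNP is
#' heterozygous (a single random homolog) with probability `het_fraction`,
#' otherwise homozygous. Candidates carried by no individual are dropped: they
#' exist in no genome and no read.
#'
#' @param loci A tibble from [digest_genome()].
#' @param cfg A [sim_config()]. The caller controls the RNG (seed or stream).
#' @return A list with `truth` (tibble: `locus_id`, `offset` 0-based, `ref`,
#'   `alt`), `genotypes` (character matrix, variants x individuals, values
#'   `"0/0"`, `"0/1"`, `"1/1"`), `phase` (integer matrix: 0 none, 1/2 single
#'   homolog, 3 both) and `individuals` (names, `pop<P>_ind<I>`).
#' @export
simulate_variants <- function(loci, cfg) {
  stopifnot(nrow(loci) > 0L)
  n_ind <- cfg$n_populations * cfg$individuals_per_population
  individuals <- sprintf(
    "pop%d_ind%02d",
    rep(seq_len(cfg$n_populations), each = cfg$individuals_per_population),
    rep(seq_len(cfg$individuals_per_population), cfg$n_populations)
  )
  pos_tab <- tibble(
    locus_id = rep(loci$locus_id, nchar(loci$seq)),
    offset = unlist(lapply(nchar(loci$seq), function(n) seq_len(n) - 1L)),
    ref = unlist(strsplit(loci$seq, "", fixed = TRUE))
  )
  bases <- c("A", "C", "G", "T")
  vars <- list()
  for (p in seq_len(cfg$n_populations)) {
    cand_idx <- which(runif(nrow(pos_tab)) < cfg$snp_rate)
    ncand <- length(cand_idx)
    if (ncand == 0L) next
    ref <- pos_tab$ref[cand_idx]
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    n_shared <- round(cfg$shared_fraction * ncand)
    shared <- sort(sample.int(ncand, n_shared))
    pool <- setdiff(seq_len(ncand), shared)
    phase <- matrix(0L, ncand, n_ind)
    ind_range <- (p - 1L) * cfg$individuals_per_population +
      seq_len(cfg$individuals_per_population)
    n_pick <- round(cfg$private_pick_fraction * length(pool))
    for (i in ind_range) {
      private <- if (length(pool) > 0L && n_pick > 0L) {
        pool[sample.int(length(pool), n_pick)]
      } else integer(0)
      assigned <- c(shared, private)
      het <- runif(length(assigned)) < cfg$het_fraction
      ph <- ifelse(het, sample(c(1L, 2L), length(assigned), replace = TRUE), 3L)
      phase[assigned, i] <- ph
    }
    vars[[p]] <- list(
      truth = tibble(locus_id = pos_tab$locus_id[cand_idx],
                     offset = pos_tab$offset[cand_idx], ref = ref, alt = unname(alt)),
      phase = phase
    )
  }
  truth <- bind_rows(lapply(vars, `[[`, "truth"))
  phase <- do.call(rbind, lapply(vars, `[[`, "phase"))
  if (is.null(phase)) phase <- matrix(0L, 0L, n_ind)

  # merge identical (locus, offset, alt) drawn in several populations; keep
  # distinct alts at one position as distinct (tri-allelic) truth variants
  key <- paste(truth$locus_id, truth$offset, truth$alt, sep = "\r")
  grp <- match(key, unique(key))
  merged_phase <- matrix(0L, length(unique(key)), n_ind)
  for (r in seq_along(grp)) {
    tgt <- grp[[r]]
    merged_phase[tgt, ] <- pmax(merged_phase[tgt, ], phase[r, ])
  }
  truth <- truth[!duplicated(key), , drop = FALSE]

  carried <- rowSums(merged_phase > 0L) > 0L
  truth <- truth[carried, , drop = FALSE]
  merged_phase <- merged_phase[carried, , drop = FALSE]
  ord <- order(match(truth$locus_id, loci$locus_id), truth$offset, truth$alt)
  truth <- truth[ord, , drop = FALSE]
  merged_phase <- merged_phase[ord, , drop = FALSE]

  gt <- matrix("0/0", nrow(truth), n_ind, dimnames = list(NULL, individuals))
  gt[merged_phase == 1L | merged_phase == 2L] <- "0/1"
  gt[merged_phase == 3L] <- "1/1"
  colnames(merged_phase) <- individuals
  list(truth = as_tibble(truth), genotypes = gt, phase = merged_phase,
       individuals = individuals)
}

#' Build per-individual diploid haplotypes from simulated variants
#'
#' @param loci A tibble from [digest_genome()].
#' @param sim The list returned by [simulate_variants()].
#' @return A list, one element per individual, each a list of two named
#'   character vectors (`h1`, `h2`) of locus sequences.
#' @export
build_haplotypes <- function(loci, sim) {
  ref <- setNames(loci$seq, loci$locus_id)
  lapply(setNames(seq_along(sim$individuals), sim$individuals), function(i) {
    h1 <- ref
    h2 <- ref
    ph <- sim$phase[, i]
    on1 <- which(ph == 1L | ph == 3L)
    on2 <- which(ph == 2L | ph == 3L)
    for (v in on1) {
      lid <- sim$truth$locus_id[[v]]
      substr(h1[[lid]], sim$truth$offset[[v]] + 1L, sim$truth$offset[[v]] + 1L) <-
        sim$truth$alt[[v]]
    }
    for (v in on2) {
      lid <- sim$truth$locus_id[[v]]
      substr(h2[[lid]], sim$truth$offset[[v]] + 1L, sim$truth$offset[[v]] + 1L) <-
        sim$truth$alt[[v]]
    }
    list(h1 = h1, h2 = h2)
  })
}

#' Simulate error-prone RAD reads from haplotypes
#'
#' Per individual and locus, `coverage` forward reads of `read_length` bp start
#' at the locus start (RAD reads share their start), split evenly between the
#' two homologs (an odd remainder goes to a randomly drawn homolog). Each base
#' is substituted to a uniformly chosen different base with probability
#' `error_rate`; qualities are constant `I`.
#'
#' @param haplotypes From [build_haplotypes()].
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed); one
#'   `<individual>.fastq.gz` per individual.
#' @return A named character vector of FASTQ paths (one per individual).
#' @export
simulate_reads <- function(haplotypes, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_h1 <- cfg$coverage %/% 2L
  odd <- cfg$coverage %% 2L == 1L
  paths <- character(0)
  for (ind in names(haplotypes)) {
    h <- haplotypes[[ind]]
    n_loci <- length(h$h1)
    extra1 <- if (odd) runif(n_loci) < 0.5 else rep(FALSE, n_loci)
    k1 <- n_h1 + extra1
    k2 <- cfg$coverage - k1
    tmpl <- c(rep(substr(h$h1, 1L, cfg$read_length), k1),
              rep(substr(h$h2, 1L, cfg$read_length), k2))
    locus_of <- c(rep(names(h$h1), k1), rep(names(h$h2), k2))
    hom_of <- rep(c(1L, 2L), c(sum(k1), sum(k2)))
    reads <- cpp_mutate_reads(tmpl, cfg$error_rate)
    qual <- strrep("I", nchar(reads))
    ids <- sprintf("@%s_%s_h%d_r%d", ind, locus_of, hom_of,
                   as.integer(stats::ave(seq_along(reads), locus_of, hom_of,
                                         FUN = seq_along)))
    path <- file.path(dir, paste0(ind, ".fastq.gz"))
    con <- gzfile(path, "wt")
    writeLines(as.vector(rbind(ids, reads, "+", qual)), con)
    close(con)
    paths[[ind]] <- path
  }
  paths
}

#' Simulate a complete RAD-Seq dataset with its truth table
#'
#' Runs digest, variant injection and read simulation under a single seed and
#' writes `loci.fasta`, `truth.tsv`, `simconfig.json` and one FASTQ per
#' individual into `dir`.
#'
#' @param cfg A [sim_config()]; `cfg$seed` drives all randomness.
#' @param dir Output directory.
#' @param genome Optional genome (FASTA path, DNAStringSet or character); when
#'   `NULL` a random genome of `genome_length` bp is generated.
#' @param genome_length Length of the random genome when `genome` is `NULL`.
#' @return A list: `loci`, `truth`, `genotypes`, `phase`, `haplotypes`,
#'   `samples` (named FASTQ paths), `config`, `dir`.
#' @export
simulate_rad_dataset <- function(cfg = sim_config(), dir = tempfile("radsim_"),
                                 genome = NULL, genome_length = 1.3e6) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(genome)) genome <- random_genome(genome_length)
  loci <- digest_genome(genome, cfg$enzyme_site, cfg$flank)
  if (nrow(loci) == 0L) stop("the genome contains no usable restriction site", call. = FALSE)
  sim <- simulate_variants(loci, cfg)
  haps <- build_haplotypes(loci, sim)
  samples <- simulate_reads(haps, cfg, dir)

  writeLines(as.vector(rbind(paste0(">", loci$locus_id), loci$seq)),
             file.path(dir, "loci.fasta"))
  genome_seqs <- load_contigs(genome)
  writeLines(as.vector(rbind(paste0(">", names(genome_seqs)), unname(genome_seqs))),
             file.path(dir, "genome.fasta"))
  write_truth(sim, file.path(dir, "truth.tsv"))
  jsonlite::write_json(unclass(cfg), file.path(dir, "simconfig.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(loci = loci, truth = sim$truth, genotypes = sim$genotypes,
       phase = sim$phase, haplotypes = haps, samples = samples,
       genome = genome_seqs, config = cfg, dir = dir)
}

#' Read and write the simulation truth table
#'
#' Tab-separated: `locus`, `offset` (0-based), `ref`, `alt`, then one diploid
#' genotype column per individual.
#'
#' @param sim The list from [simulate_variants()] (or a `simulate_rad_dataset()`
#'   result).
#' @param path TSV path.
#' @return `write_truth()`: `path`, invisibly. `read_truth()`: a list with
#'   `truth` and `genotypes` as in [simulate_variants()].
#' @export
write_truth <- function(sim, path) {
  df <- data.frame(
    locus = sim$truth$locus_id, offset = sim$truth$offset,
    ref = sim$truth$ref, alt = sim$truth$alt,
    sim$genotypes, check.names = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  gt <- as.matrix(df[, -(1:4), drop = FALSE])
  list(
    truth = tibble(locus_id = df$locus, offset = as.integer(df$offset),
                   ref = df$ref, alt = df$alt),
    genotypes = gt
  )
}
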