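---
title: "Reference-free RAD-Seq variant calling with radbubbles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free RAD-Seq variant calling with radbubbles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radbubbles)
```

## The problem

RAD-Seq reduces a genome to short loci flanking restriction-enzyme cut sites
and sequences them across many individuals. Because every read from a locus
starts at the cut site, classical de novo RAD tools cluster reads into loci by
all-vs-all alignment and call variants inside clusters; the clustering
threshold then becomes a critical, dataset-dependent parameter. `radbubbles`
takes the opposite route: all samples' reads are pooled into a single de
Bruijn graph (dBG) and small variants are read off the graph's topology, so no
read clustering and no similarity threshold is ever involved.

## The de Bruijn graph

Nodes are the canonical k-mers (the lexicographic minimum of a k-mer and its
reverse complement) occurring in the reads; two nodes are linked when they
overlap on $k-1$ bases. `k` must be odd (no k-mer is then its own reverse
complement) and defaults to 31, a usual value for Illumina-length reads.

Sequencing errors create low-abundance k-mers. A k-mer enters the graph only
if its count reaches `min_abundance` (default 3) **within at least one
sample**. The within-sample rule matters at cohort scale: with dozens of
individuals at 20x each, a locus position is covered by hundreds of pooled
reads and a 1% error rate re-creates the same error k-mer several times
across samples, so a pooled threshold of 3 would keep roughly one spurious
branch per locus position and the graph would become untraversable. Within one
sample, by contrast, an error must recur at 20x — rare enough that almost all
error k-mers are dropped while true alleles (carried at 10–20x by any
carrier) always survive. For a single input sample the rule reduces to a plain
threshold on the total count.

## Bubbles: the graph signature of a variant

A SNP between two haplotypes produces two paths that diverge at a branching
k-mer and re-merge k bases after the variant — a *bubble*. The detector walks,
from every branching node and every pair of its successors, two paths in
lockstep, one base per step, and stops when:

1. the two current k-mers become equal — a **complete** bubble; its paths run
   from the opening branching k-mer through the first re-merged k-mer, so an
   isolated SNP gives paths of length $2k+1$ with the variant at offset $k$;
2. both k-mers have no successor at equal path length **and** the last 3 bases
   of the two paths are identical — a **symmetrically truncated** bubble;
3. extension is impossible — the exploration is abandoned.

Truncated bubbles are the RAD-specific motif: loci are only as long as the
reads, and a variant lying within $k$ bp of a locus end produces paths that
dead-end before re-merging (all reads of a locus stop at the same position).
Left-truncated bubbles are found by running the same procedure on the
reverse-complement orientation. A complete bubble for a SNP at 0-based locus
position $p$ on an $L$ bp locus needs $k \le p \le L-k-1$; every other
position relies on the truncated model. At $L = 100$ and $k = 31$ that is 62%
of positions — the motivation for supporting truncation at all.

The last-3-mer condition trades a little recall for typing confidence: when
two locus copies differ over their final few bases, an indel, successive
substitutions, or a mix are equally parsimonious explanations, and reporting a
wrong type is worse than reporting nothing. The rule forgoes variants within
3 bp of a locus extremity (6% of positions at $L=100$) and admits a chance
match with probability $4^{-3} \approx 1.56\%$.

Two further generalisations:

* **Close SNPs.** When the lockstep extensions differ again within $k$ bases,
  the mismatch joins the same bubble, up to `max_snps` (default 5) mismatches;
  exceeding the budget abandons the exploration.
* **Indels.** One branch is held at the opening node while the other consumes
  up to `max_indel` (default 10) extra bases; lockstep then resumes with
  identical bases and k-mer equality within $k$ steps certifies the motif.
  The inserted/deleted segment is reported leftmost-aligned. Only unambiguous
  extensions are followed during these two phases, which bounds the search;
  truncated indel bubbles are not emitted because paths of unequal length
  cannot pass the symmetric-truncation test.

**Crossroads.** With many samples, several haplotypes co-exist and bubbles
entangle. Whenever more than one extension combination is possible at a step
(on either path — error branches are usually one-sided), all combinations are
explored recursively and the step counts as one *symmetrically branching
crossroad* (SBC) traversal; a bubble may cross at most `max_sbc` (default 5)
of them. `high_precision = TRUE` sets the budget to zero: any bubble touching
a crossroad is dropped, trading recall for near-perfect precision. The bubble
set found at a given budget is always a subset of the set at a larger budget.

Each biological bubble is reported once: every discovery is rendered on both
strands, path `a` is the lexicographically smaller path, and the orientation
with the smaller `(path_a, path_b)` tuple is the representative. This makes
output deterministic and strand-stable.

## Allele coverage, genotypes, and the rank score

Reads are mapped back on bubble sequences extended with their graph contexts
(see below) by exact k-mer seeding plus ungapped verification. A placement is
accepted when the read lies inside the extended sequence (or overhangs with at
least $k$ overlap) with at most `max_subst` (default 10) substitutions — but
**zero** at variant positions. The generous substitution budget keeps
divergent reads countable while the variant positions stay authoritative; a
read consistent with both alleles, or covering no variant position, counts for
nothing, so depth is the number of allele-informative reads. For indel alleles
a read must span the whole segment plus one anchor base on each side.

Genotypes are called per sample by binomial maximum likelihood: with $n$
informative reads of which $b$ support the alternate allele, the likelihoods
of 0/0, 0/1 and 1/1 are $\mathrm{Bin}(b; n, \epsilon)$,
$\mathrm{Bin}(b; n, 1/2)$ and $\mathrm{Bin}(b; n, 1-\epsilon)$ with
$\epsilon$ = `err` (default 0.01). Below `min_depth` (default 3) the genotype
is missing (`./.`); ties break toward the heterozygote. Variants missing in
more than `max_missing_frac` (default 95%) of samples are discarded.

Paralogous regions collapse distinct loci onto one bubble; their hallmark is
an allele balance that does not discriminate samples. The *rank* of a variant
is the maximum over sample pairs of the Phi coefficient
$\sqrt{\chi^2 / n} = |ad - bc| / \sqrt{(a{+}b)(c{+}d)(a{+}c)(b{+}d)}$ of the
pair's 2x2 allele-count table (defined as 0 on degenerate tables). Real
variants separate at least one pair of samples (rank near 1); paralog-induced
ones stay flat. Variants with rank below `min_rank` (default 0.4) are
discarded. The known cost: a real variant heterozygous in strictly every
sample also ranks low; such variants are rare in large cohorts and matter
little for structure or phylogeny, though heterozygosity estimates can be
slightly deflated.

## Clustering variants per locus

Bubbles are extended left and right with their graph contexts: a walk that
appends one base while the step is unambiguous (exactly one successor in the
walking direction, and the node walked into has exactly one predecessor),
ending at the first ambiguity; truncated sides get empty contexts. Two bubbles
from one locus then necessarily share at least one $(k-1)$-mer between their
extended sequences, so the undirected graph with an edge for every sharing
pair decomposes into connected components that act as RAD loci. Component ids
are assigned in order of each component's smallest member, making the
labelling input-order-invariant. Clusters with more than `max_cluster_size`
(default 150) variants are discarded whole — they aggregate paralogous
variants from repetitive regions — and the dropped ids are reported, not
silently deleted.

## VCF output and post-filters

Without a reference there is no natural coordinate system, so records use
pseudo-chromosomes `cluster_<id>` (or `bubble_<id>` when unclustered) with
`POS` the 1-based variant offset within the extended `path_a`; `INFO` carries
the type, rank, cluster id and cluster size, and `FORMAT` is `GT:DP:AD`.
Optional post-filters apply in a fixed, documented order — genotypes below
`min_gt_depth` (default 6) are masked, variants below a minor allele frequency
of `maf` (default 0.01, computed over non-missing diploid genotypes, not raw
read counts) are removed, variants genotyped in fewer than
`min_genotyped_frac` (default 60%) of samples are removed, and optionally one
variant per cluster is kept, drawn uniformly under a caller-supplied seed. The
order is part of the contract: reordering changes results.

## The simulator

`simulate_rad_dataset()` emulates the benchmark protocol: digest a genome at a
restriction site (default PstI, `CTGCAG`), taking `flank` = 150 bp on each
side of every occurrence (sites closer than the flank to a contig edge lose
that side); per population, draw candidate SNP positions at `snp_rate` = 1%
per locus position, give a `shared_fraction` = 70% subset to every individual
and let each individual independently draw `private_pick_fraction` = 10% of
the remaining pool; make each carried SNP heterozygous (one random homolog)
with probability `het_fraction` = 10%, else homozygous; generate `coverage` =
20 forward reads of `read_length` = 150 bp per locus and individual, all
starting at the locus start, split evenly between homologs, with per-base
substitution errors at `error_rate` = 1% and constant qualities. Candidates
carried by no individual are dropped from the truth table — they exist in no
genome and no read. Everything is deterministic under `(config, seed)`.

The default benchmark uses 2 populations of 20 diploid individuals over a
uniform random genome of 1.3 Mb. That length is chosen so the expected locus
count ($2 \times$ sites, about 630) safely exceeds 500 loci; a 1.0 Mb uniform
random sequence would be expected to yield slightly fewer than 500. On one CPU
the full cycle — simulate, call, evaluate — takes under five minutes at this
size.

What the generator deliberately does **not** emulate: genomic repeats and
paralogs (a uniform random genome is repeat-free at $k=31$), allele dropout
from restriction-site polymorphism (reads are generated per locus, not
re-digested), indels, PCR duplicates, read-2/random-shear layouts, and
quality-score structure. Passing the clean-data tests therefore demonstrates
the machinery is exact on its own assumptions, not that real-data recall will
match: on a real genome the rank filter, the oversized-cluster discard and
ambiguous localization all remove additional true variants, so recall measured
on this repeat-free benchmark is an upper bound on what the same pipeline
achieves on repeat-rich genomes. The residual false positives on the benchmark
are error-chain close-SNP bubbles paired with true variant haplotypes, plus
rare same-position collisions of different alternate alleles drawn in the two
populations.

## Evaluation

Predictions are localized by placing each allele's extended sequence (either
strand, at most `max_subst` substitutions, unique best placement) onto the
locus references — or onto the source genome when it is available
(`evaluate_calls(..., genome = )`). Genome coordinates are preferred for
scoring because loci from nearby restriction sites overlap on the genome and a
context-extended bubble may legitimately span past a single locus boundary.
A predicted site is a true positive when a truth variant matches its locus,
offset and unordered allele pair; sites predicted through several bubbles are
counted once; unlocalized predictions count as false positives. Recall is
$TP/(TP+FN)$ and precision $TP/(TP+FP)$, reported as undefined (not 0) when a
denominator is 0.

## Numerical and degeneracy choices

* Non-ACGT read characters break k-mer windows; they never abort a run.
* An empty read set yields an empty (header-only) VCF and a clean exit: an
  empty result is a result.
* Phi on tables with an empty row or column is 0 (no discriminant signal).
* Genotype likelihood ties break toward 0/1 — conservative and deterministic.
* Bubble traversal is bounded by `max_snps`, `max_sbc` and a fixed per-start
  work cap; context walks are capped in length so graph cycles terminate.
  All iteration orders are fixed (k-mers sorted, extensions in A<C<G<T
  order), so byte-identical inputs give byte-identical VCFs apart from the
  file-date header.
* The one-per-locus thinning draw uses an explicit seed; replaying a manifest
  reproduces the run.

## Known limitations

Indel support is conservative: entangled indels (branching during the held
phase) are abandoned, and the evaluator matches indels only by locus, leftmost
offset and segment, which the SNP-only simulator never exercises end to end.
Genotype likelihoods ignore base qualities. The rank filter removes variants
heterozygous in all samples. Memory holds the full k-mer count table of the
pooled samples; the implementation targets desk-scale datasets (hundreds of
samples at RAD-locus genome reduction), not whole-genome shotgun cohorts.
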