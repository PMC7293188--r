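#' Localize predicted variants onto simulated locus references
#'
#' Each allele's extended sequence is placed on the locus references (either
#' strand, full containment, at most `max_subst` substitutions) by exact k-mer
#' seeding plus ungapped verification; the unique best placement localizes the
#' bubble, and each variant offset is translated into locus coordinates. At a
#' localized SNP site the reference allele is the one whose base equals the
#' locus base. Predictions placing nowhere, or ambiguously (ties, or the two
#' alleles landing on different loci), are retained as unlocalized: they can
#' only count as false positives downstream.
#'
#' @param bubbles A tibble from [extend_contexts()] (e.g. the `variants` field
#'   of a [rad_call()] result).
#' @param loci Locus references: a tibble from [digest_genome()], a FASTA path,
#'   or a named character vector.
#' @param max_subst Maximum substitutions tolerated when placing an allele.
#' @param k Seeding k-mer size; defaults to the graph k carried by `bubbles`.
#' @return A site-level tibble: `record_id`, `bubble_id`, `type`, `status`
#'   (`"localized"`, `"unlocalized"` or `"ambiguous"`), `locus_id`, `offset`
#'   (0-based locus coordinate), `ref`, `alt` (locus-oriented; `ref` is the
#'   locus base when one allele matches it), `allele_a`, `allele_b` and
#'   `segment` (indels).
#' @export
localize_predictions <- function(bubbles, loci, max_subst = 10L,
                                 k = attr(bubbles, "k")) {
  stopifnot(all(c("extended_a", "extended_b") %in% names(bubbles)))
  if (is.null(k)) stop("`k` is required (not carried by `bubbles`)", call. = FALSE)
  loci <- load_loci(loci)
  empty <- tibble(
    record_id = character(), bubble_id = integer(), type = character(),
    status = character(), locus_id = character(), offset = integer(),
    ref = character(), alt = character(), allele_a = character(),
    allele_b = character(), segment = character()
  )
  if (nrow(bubbles) == 0L) return(empty)
  loc <- cpp_localize(bubbles$extended_a, bubbles$extended_b, loci$seq,
                      as.integer(k), as.integer(max_subst))
  lc <- nchar(bubbles$left_context)
  rows <- vector("list", nrow(bubbles))
  for (i in seq_len(nrow(bubbles))) {
    off <- bubbles$variant_offsets[[i]]
    bid <- bubbles$bubble_id[[i]]
    is_indel <- bubbles$kind[[i]] == "INDEL"
    n_rec <- if (is_indel) 1L else length(off)
    rid <- if (n_rec == 1L) sprintf("bubble_%d", bid) else
      sprintf("bubble_%d_%d", bid, seq_len(n_rec))
    type <- if (is_indel) {
      if (nchar(bubbles$path_a[[i]]) > nchar(bubbles$path_b[[i]])) "DEL" else "INS"
    } else "SNP"
    if (loc$status[[i]] != 0L) {
      rows[[i]] <- tibble(
        record_id = rid, bubble_id = bid, type = type,
        status = if (loc$status[[i]] == 2L) "ambiguous" else "unlocalized",
        locus_id = NA_character_, offset = NA_integer_,
        ref = NA_character_, alt = NA_character_,
        allele_a = NA_character_, allele_b = NA_character_,
        segment = NA_character_
      )
      next
    }
    placed <- if (loc$allele[[i]] == 1L) bubbles$extended_a[[i]] else bubbles$extended_b[[i]]
    Lp <- nchar(placed)
    q <- loc$start[[i]]
    fwd <- loc$strand[[i]] == 1L
    lseq <- loci$seq[[loc$locus[[i]]]]
    lid <- loci$locus_id[[loc$locus[[i]]]]
    if (is_indel) {
      o <- off[[1]]
      len <- off[[2]]
      a_long <- nchar(bubbles$path_a[[i]]) > nchar(bubbles$path_b[[i]])
      long <- if (a_long) bubbles$path_a[[i]] else bubbles$path_b[[i]]
      seg <- substr(long, o + 1L, o + len)
      # translate through an anchor inside the shared path prefix
      e_anchor <- max(0L, lc[[i]] + o - 1L)
      la <- if (fwd) q + e_anchor else q + (Lp - 1L - e_anchor)
      loff <- max(0L, if (fwd) la + 1L else la - len)
      if (!fwd) seg <- revcomp(seg)
      # leftmost placement in locus coordinates
      while (loff > 0L &&
             substr(lseq, loff, loff) == substr(seg, len, len)) {
        seg <- paste0(substr(lseq, loff, loff), substr(seg, 1L, len - 1L))
        loff <- loff - 1L
      }
      rows[[i]] <- tibble(
        record_id = rid, bubble_id = bid, type = type, status = "localized",
        locus_id = lid, offset = as.integer(loff),
        ref = NA_character_, alt = NA_character_,
        allele_a = NA_character_, allele_b = NA_character_, segment = seg
      )
    } else {
      e <- lc[[i]] + off
      loff <- if (fwd) q + e else q + (Lp - 1L - e)
      ca <- substring(bubbles$extended_a[[i]], e + 1L, e + 1L)
      cb <- substring(bubbles$extended_b[[i]], e + 1L, e + 1L)
      if (!fwd) {
        ca <- revcomp(ca)
        cb <- revcomp(cb)
      }
      lbase <- substring(lseq, loff + 1L, loff + 1L)
      ref <- ifelse(ca == lbase, ca, ifelse(cb == lbase, cb, NA_character_))
      alt <- ifelse(ca == lbase, cb, ifelse(cb == lbase, ca, NA_character_))
      rows[[i]] <- tibble(
        record_id = rid, bubble_id = bid, type = type, status = "localized",
        locus_id = lid, offset = as.integer(loff),
        ref = ref, alt = alt, allele_a = ca, allele_b = cb,
        segment = NA_character_
      )
    }
  }
  bind_rows(rows)
}

load_loci <- function(loci) {
  if (is.data.frame(loci)) {
    stopifnot(all(c("locus_id", "seq") %in% names(loci)))
    return(loci)
  }
  if (is.character(loci) && length(loci) == 1L && file.exists(loci)) {
    x <- Biostrings::readDNAStringSet(loci)
    nm <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
    return(tibble(locus_id = nm, seq = as.character(x)))
  }
  if (is.character(loci)) {
    nm <- names(loci) %||% sprintf("locus_%d", seq_along(loci))
    return(tibble(locus_id = nm, seq = unname(toupper(loci))))
  }
  stop("`loci` must be a tibble, FASTA path or named character vector", call. = FALSE)
}

#' Score predictions against a simulation truth table
#'
#' A predicted SNP site is a true positive when a truth variant exists with the
#' same locus, offset and unordered allele pair; each truth variant matches at
#' most one prediction (site-level predictions are first deduplicated on
#' locus, offset and allele pair, so the same site discovered through several
#' bubbles counts once). False positives are unmatched predictions, including
#' all unlocalized ones; false negatives are unmatched truth variants. Recall
#' is `TP / (TP + FN)` and precision `TP / (TP + FP)`, each `NA` (undefined)
#' when its denominator is 0.
#'
#' @param predictions A tibble from [localize_predictions()].
#' @param truth A truth tibble (`locus_id`, `offset`, `ref`, `alt`), e.g. from
#'   [simulate_variants()] or [read_truth()].
#' @return A `rad_eval` object: `tp`, `fp`, `fn`, `recall`, `precision`,
#'   `n_predictions`, `n_truth` and an `audit` tibble with a `status` column
#'   in `TP`, `FP`, `FN`, `UNLOCALIZED`.
#' @export
score_predictions <- function(predictions, truth) {
  pair_key <- function(x, y) {
    ifelse(is.na(x) | is.na(y), NA_character_,
           ifelse(x <= y, paste(x, y, sep = "/"), paste(y, x, sep = "/")))
  }
  truth <- mutate(truth,
                  key = paste(.data$locus_id, .data$offset,
                              pair_key(.data$ref, .data$alt)))
  pred <- mutate(
    predictions,
    key = ifelse(.data$status == "localized" & .data$type == "SNP",
                 paste(.data$locus_id, .data$offset,
                       pair_key(.data$allele_a, .data$allele_b)),
                 NA_character_)
  )
  # site-level deduplication: several bubbles may predict the same site
  dup <- !is.na(pred$key) & duplicated(pred$key)
  pred <- pred[!dup, , drop = FALSE]
  pred <- mutate(
    pred,
    eval_status = as.character(ifelse(.data$status != "localized", "UNLOCALIZED",
                                      ifelse(.data$key %in% truth$key, "TP", "FP")))
  )
  fn_rows <- filter(truth, !(.data$key %in% pred$key))
  tp <- sum(pred$eval_status == "TP")
  fp <- sum(pred$eval_status %in% c("FP", "UNLOCALIZED"))
  fn <- nrow(fn_rows)
  audit <- bind_rows(
    select(pred, "record_id", "bubble_id", "type", "locus_id", "offset",
           "ref", "alt", status = "eval_status"),
    tibble(record_id = NA_character_, bubble_id = NA_integer_,
           type = "SNP", locus_id = fn_rows$locus_id, offset = fn_rows$offset,
           ref = fn_rows$ref, alt = fn_rows$alt, status = "FN")
  )
  structure(
    list(
      tp = tp, fp = fp, fn = fn,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      n_predictions = nrow(pred), n_truth = nrow(truth), audit = audit
    ),
    class = "rad_eval"
  )
}

#' @export
print.rad_eval <- function(x, ...) {
  cat(sprintf(
    "variant-site evaluation: TP = %d, FP = %d, FN = %d\nrecall = %s, precision = %s\n",
    x$tp, x$fp, x$fn,
    if (is.na(x$recall)) "undefined" else sprintf("%.4f", x$recall),
    if (is.na(x$precision)) "undefined" else sprintf("%.4f", x$precision)
  ))
  invisible(x)
}

#' Evaluate a calling result against a simulated dataset
#'
#' Localizes the surviving variants of a [rad_call()] result on the simulated
#' locus references and scores them against the truth table.
#'
#' @param result A [rad_call()] result (or any tibble of extended bubbles).
#' @param truth Truth tibble or `truth.tsv` path.
#' @param loci Locus references (tibble, FASTA path or named character).
#' @param max_subst Substitutions tolerated during localization.
#' @param genome Optional genome the loci were digested from (named character,
#'   `DNAStringSet` or FASTA path). When given — and `loci` is a
#'   [digest_genome()] tibble carrying genome coordinates — predictions are
#'   localized on the genome and the truth is translated to genome
#'   coordinates. This mirrors reference-based evaluation protocols and
#'   handles loci that overlap on the genome (their context-extended bubbles
#'   can span past an individual locus boundary).
#' @return A `rad_eval` object (see [score_predictions()]).
#' @export
evaluate_calls <- function(result, truth, loci, max_subst = 10L, genome = NULL) {
  bubbles <- if (inherits(result, "rad_call")) result$variants else result
  if (is.character(truth) && length(truth) == 1L && file.exists(truth)) {
    truth <- read_truth(truth)$truth
  } else if (is.list(truth) && !is.data.frame(truth) && !is.null(truth$truth)) {
    truth <- truth$truth
  }
  k <- attr(bubbles, "k")
  if (is.null(k) && inherits(result, "rad_call")) k <- result$config$k
  reference <- loci
  if (!is.null(genome)) {
    if (!is.data.frame(loci) || !all(c("contig", "start") %in% names(loci))) {
      stop("genome-coordinate evaluation needs a digest_genome() loci tibble",
           call. = FALSE)
    }
    truth <- truth_to_genome(truth, loci)
    reference <- load_contigs(genome)
  }
  preds <- localize_predictions(bubbles, reference, max_subst = max_subst, k = k)
  score_predictions(preds, truth)
}

#' Translate a per-locus truth table into genome coordinates
#'
#' Offsets become 0-based positions on the contig each locus was cut from;
#' variants duplicated by overlapping loci collapse to one genomic site.
#'
#' @param truth A truth tibble (`locus_id`, `offset`, `ref`, `alt`).
#' @param loci A [digest_genome()] tibble (columns `locus_id`, `contig`,
#'   `start`).
#' @return A truth tibble whose `locus_id` is the contig name and `offset` the
#'   genomic offset.
#' @export
truth_to_genome <- function(truth, loci) {
  m <- match(truth$locus_id, loci$locus_id)
  if (anyNA(m)) stop("truth refers to loci absent from `loci`", call. = FALSE)
  out <- tibble(
    locus_id = loci$contig[m],
    offset = as.integer(loci$start[m] + truth$offset),
    ref = truth$ref, alt = truth$alt
  )
  distinct(out)
}

#' Write an evaluation report
#'
#' A one-line TSV with counts and rates, plus a per-variant audit TSV
#' (`status` in `TP`, `FP`, `FN`, `UNLOCALIZED`).
#'
#' @param x A `rad_eval` object.
#' @param report_path Path of the one-line summary TSV.
#' @param audit_path Path of the audit TSV (default: `report_path` +
#'   `.audit.tsv`).
#' @return `report_path`, invisibly.
#' @export
write_eval_report <- function(x, report_path,
                              audit_path = paste0(report_path, ".audit.tsv")) {
  df <- data.frame(TP = x$tp, FP = x$fp, FN = x$fn,
                   recall = x$recall, precision = x$precision)
  write.table(df, report_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(x$audit), audit_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(report_path)
}
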