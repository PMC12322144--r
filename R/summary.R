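# Library-level summaries: SSB frequency per aligned nucleotide,
# reference-set filtering, amplicon per-position error profiles and
# unique-sequence fractions.

#' SSB frequency per million aligned base pairs
#'
#' @param n_unique Number of detected unique SSBs.
#' @param aligned_nt Usable aligned nucleotides (bp).
#' @return List of class `ssb_frequency`: `n_unique_ssbs`,
#'   `aligned_nucleotides`, `ssb_per_million_bp` (exact division; text
#'   output rounds to one decimal).
#' @examples
#' ssb_frequency(40097, 6.7e9)   # 6.0 per million bp
#' @export
ssb_frequency <- function(n_unique, aligned_nt) {
  if (aligned_nt <= 0) stop("aligned_nt must be positive")
  structure(list(n_unique_ssbs = n_unique,
                 aligned_nucleotides = aligned_nt,
                 ssb_per_million_bp = n_unique / (aligned_nt / 1e6)),
            class = "ssb_frequency")
}

#' @export
print.ssb_frequency <- function(x, ...) {
  cat(sprintf("%d unique SSBs / %.3g aligned nt = %.1f per million bp\n",
              x$n_unique_ssbs, x$aligned_nucleotides,
              x$ssb_per_million_bp))
  invisible(x)
}

#' Remove calls present in a reference (untreated) call set
#'
#' Drops every call whose `(chrom, start, end, strand)` also occurs in the
#' reference set, e.g. to subtract background breaks seen in untreated
#' control libraries.
#'
#' @param calls,reference_calls Call data frames (or BED paths).
#' @return Filtered call data frame.
#' @export
filter_by_reference_set <- function(calls, reference_calls) {
  if (is.character(calls)) calls <- read_calls_bed(calls)
  if (is.character(reference_calls)) {
    reference_calls <- read_calls_bed(reference_calls)
  }
  key <- paste(calls$chrom, calls$start, calls$end, calls$strand)
  ref_key <- paste(reference_calls$chrom, reference_calls$start,
                   reference_calls$end, reference_calls$strand)
  out <- calls[!key %in% ref_key, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep calls on canonical chromosomes
#'
#' @param calls Call data frame.
#' @param pattern Regular expression of chromosome names to keep
#'   (default the canonical human set `chr1`-`chr22`, `chrX`, `chrY`,
#'   `chrM`).
#' @return Filtered call data frame.
#' @export
filter_canonical_chroms <- function(calls,
                                    pattern = "^chr([0-9]{1,2}|X|Y|M)$") {
  out <- calls[grepl(pattern, calls$chrom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Reconstruct, for one read, the observed base at every reference position
# of a window: "A"/"C"/"G"/"T"/"N" for aligned bases, "-" for deletions,
# NA where the read does not align. Insertions are returned separately,
# attributed to the following reference position.
window_bases <- function(record, w0, w1) {
  ops <- parse_cigar(record$cigar)
  seq_raw <- charToRaw(record$seq)
  n <- w1 - w0
  base <- rep(NA_character_, n)
  ins <- integer(0)
  r <- as.integer(record$start); q <- 0L
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      lo <- max(r, w0); hi <- min(r + len, w1)
      if (hi > lo) {
        off <- (lo - r)
        base[(lo - w0 + 1L):(hi - w0)] <-
          strsplit(rawToChar(seq_raw[(q + off + 1L):(q + off + hi - lo)]),
                   "", fixed = TRUE)[[1]]
      }
      r <- r + len; q <- q + len
    } else if (op == "I") {
      if (r >= w0 && r < w1) ins <- c(ins, r)
      q <- q + len
    } else if (op == "D") {
      lo <- max(r, w0); hi <- min(r + len, w1)
      if (hi > lo) base[(lo - w0 + 1L):(hi - w0)] <- "-"
      r <- r + len
    } else if (op == "N") {
      r <- r + len
    } else if (op == "S") {
      q <- q + len
    }
  }
  list(base = base, ins = ins)
}

#' Per-position nucleotide composition over a window
#'
#' For every reference position of the window, tabulates the percentage of
#' reads (among those aligned across the position) observing each
#' nucleotide or a deletion; the base and deletion percentages sum to 100.
#' Insertions are attributed to the reference position that follows them
#' and reported as a percentage of the coverage at that position (an
#' inserted read also contributes a base there, so the insertion share is
#' reported alongside rather than inside the composition).
#'
#' @param aln Alignment data frame or SAM/BAM path.
#' @param ref Reference genome.
#' @param chrom,start,end Window (0-based half-open).
#' @param max_error_rate Per-read usability bound (default 0.10).
#' @return Data frame: `pos`, `ref_base`, `coverage`, `pct_A`, `pct_C`,
#'   `pct_G`, `pct_T`, `pct_N`, `pct_del`, `pct_ins`. Zero-coverage rows
#'   have `NA` percentages.
#' @export
per_position_profile <- function(aln, ref, chrom, start, end,
                                 max_error_rate = 0.10) {
  if (is.character(aln)) aln <- read_alignments(aln)
  usable <- filter_usable_alignments(aln, ref, max_error_rate)
  usable <- usable[usable$chrom == chrom, , drop = FALSE]
  n <- end - start
  counts <- matrix(0L, nrow = n, ncol = 6,
                   dimnames = list(NULL, c("A", "C", "G", "T", "N", "-")))
  n_ins <- integer(n)
  for (i in seq_len(nrow(usable))) {
    wb <- window_bases(usable[i, ], start, end)
    got <- !is.na(wb$base)
    if (any(got)) {
      idx <- cbind(which(got), match(wb$base[got], colnames(counts)))
      counts[idx] <- counts[idx] + 1L
    }
    if (length(wb$ins)) {
      tab <- table(wb$ins - start + 1L)
      n_ins[as.integer(names(tab))] <- n_ins[as.integer(names(tab))] +
        as.integer(tab)
    }
  }
  cov <- rowSums(counts)
  pct <- counts / ifelse(cov > 0, cov, NA) * 100
  refchars <- strsplit(substr(as.character(ref[[chrom]]), start + 1L, end),
                       "", fixed = TRUE)[[1]]
  data.frame(
    pos = start:(end - 1L), ref_base = refchars, coverage = cov,
    pct_A = pct[, "A"], pct_C = pct[, "C"], pct_G = pct[, "G"],
    pct_T = pct[, "T"], pct_N = pct[, "N"], pct_del = pct[, "-"],
    pct_ins = n_ins / ifelse(cov > 0, cov, NA) * 100,
    stringsAsFactors = FALSE
  )
}

#' Unique-sequence fraction over a window
#'
#' Collapses the reads that fully span the window on their observed
#' sequence across it (deletions and insertions included), and reports how
#' many distinct sequences remain -- the readout used to show that the
#' polymerase stamps each molecule with a unique signature.
#'
#' @param aln Alignment data frame or SAM/BAM path.
#' @param ref Reference genome (used only for read filtering).
#' @param chrom,start,end Window (0-based half-open).
#' @param max_error_rate Per-read usability bound.
#' @return List: `n_mapped`, `n_unique`, `percent` (integer-rounded).
#' @export
unique_fraction <- function(aln, ref, chrom, start, end,
                            max_error_rate = 0.10) {
  if (is.character(aln)) aln <- read_alignments(aln)
  usable <- filter_usable_alignments(aln, ref, max_error_rate)
  usable <- usable[usable$chrom == chrom, , drop = FALSE]
  seqs <- character(0)
  for (i in seq_len(nrow(usable))) {
    wb <- window_bases(usable[i, ], start, end)
    if (anyNA(wb$base)) next   # does not span the full window
    tag <- paste0(paste(wb$base, collapse = ""), "|",
                  paste(wb$ins, collapse = ","))
    seqs <- c(seqs, tag)
  }
  unique_fraction_stats(length(unique(seqs)), length(seqs))
}

#' Unique-fraction arithmetic from counts
#'
#' @param n_unique Number of distinct sequences.
#' @param n_mapped Number of mapped reads considered.
#' @return List: `n_mapped`, `n_unique`, `percent`
#'   (`round(100 * n_unique / n_mapped)`; `NA` when `n_mapped` is 0).
#' @examples
#' unique_fraction_stats(98097, 124452)$percent   # 79
#' @export
unique_fraction_stats <- function(n_unique, n_mapped) {
  list(n_mapped = n_mapped, n_unique = n_unique,
       percent = if (n_mapped > 0) round(100 * n_unique / n_mapped)
                 else NA_real_)
}
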