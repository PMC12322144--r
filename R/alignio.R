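#' Load a reference genome from FASTA
#'
#' Reads a (possibly line-wrapped, multi-record) FASTA file and returns the
#' sequences uppercased, so that soft-masked (lowercase) bases are treated
#' like their uppercase counterparts.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' ref <- load_reference(fa)
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  ref <- Biostrings::readDNAStringSet(path)
  if (length(ref) == 0L) stop("reference FASTA contains no sequences: ", path)
  # Drop description after first whitespace, as aligners do.
  names(ref) <- sub("\\s.*$", "", names(ref))
  if (anyDuplicated(names(ref))) {
    stop("duplicate sequence names in FASTA: ",
         paste(unique(names(ref)[duplicated(names(ref))]), collapse = ", "))
  }
  Biostrings::DNAStringSet(toupper(ref))
}

#' Write a reference genome to FASTA
#'
#' @param ref A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_reference <- function(ref, path) {
  Biostrings::writeXStringSet(ref, path)
  invisible(path)
}

#' Read alignments from SAM or BAM into a data frame
#'
#' SAM input is converted on the fly through [Rsamtools::asBam()]. One row
#' per record; `start` is the 0-based leftmost reference coordinate.
#' Unmapped, secondary and supplementary records are retained here and
#' excluded later by [filter_usable_alignments()].
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A data frame with columns `qname`, `flag`, `chrom`, `start`,
#'   `mapq`, `cigar`, `seq`, `qual`, `is_unmapped`, `is_secondary`,
#'   `is_supplementary`, `strand`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
    )
  )[[1]]
  flag <- res$flag
  data.frame(
    qname = res$qname,
    flag = flag,
    chrom = as.character(res$rname),
    start = ifelse(is.na(res$pos), NA_integer_, res$pos - 1L),
    mapq = res$mapq,
    cigar = res$cigar,
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    is_unmapped = bitwAnd(flag, 4L) != 0L,
    is_secondary = bitwAnd(flag, 256L) != 0L,
    is_supplementary = bitwAnd(flag, 2048L) != 0L,
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    stringsAsFactors = FALSE
  )
}

# Walk one alignment against the reference, collecting per-position mutation
# observations and read-level error accounting in a single pass.
#
# Returns list(observations = data.frame(ref_pos, ref_base, kind, obs_base,
# qual), stats = list(ref_span, n_sub, n_ins_bases, n_del_bases, error_rate,
# aligned_read_bases)). Positions are 0-based; observations are sorted by
# ref_pos. Insertions are anchored at the reference position that follows
# them. Reference N positions never yield substitution observations.
cigar_walk <- function(chrom_raw, start0, cigar, seq, qual = NULL) {
  ops <- parse_cigar(cigar)
  seq_raw <- charToRaw(seq)
  phred <- qual_to_phred(qual)
  read_consumes <- ops$op %in% c("M", "=", "X", "I", "S")
  if (sum(ops$len[read_consumes]) != length(seq_raw)) {
    stop("CIGAR/sequence length mismatch: CIGAR ", cigar,
         " consumes ", sum(ops$len[read_consumes]),
         " read bases but sequence has ", length(seq_raw))
  }
  ref_end <- start0 + sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
  if (ref_end > length(chrom_raw)) {
    stop("alignment extends past end of reference sequence")
  }

  r <- start0   # next reference position (0-based)
  q <- 0L       # read bases consumed
  acc_pos <- list(); acc_kind <- list(); acc_refb <- list()
  acc_obsb <- list(); acc_qual <- list()
  k <- 0L
  n_sub <- 0L; n_ins <- 0L; n_del <- 0L
  ref_span <- 0L; aligned_read <- 0L

  push <- function(pos, kind, refb, obsb, qv) {
    k <<- k + 1L
    acc_pos[[k]] <<- pos; acc_kind[[k]] <<- kind; acc_refb[[k]] <<- refb
    acc_obsb[[k]] <<- obsb; acc_qual[[k]] <<- qv
  }

  for (i in seq_along(ops$op)) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      rb <- chrom_raw[(r + 1L):(r + len)]
      qb <- seq_raw[(q + 1L):(q + len)]
      mism <- which(rb != qb & rb != RAW_N)
      if (length(mism)) {
        n_sub <- n_sub + length(mism)
        push(r + mism - 1L, rep("substitution", length(mism)),
             strsplit(rawToChar(rb[mism]), "", fixed = TRUE)[[1]],
             strsplit(rawToChar(qb[mism]), "", fixed = TRUE)[[1]],
             if (is.null(phred)) rep(NA_integer_, length(mism))
             else phred[q + mism])
      }
      r <- r + len; q <- q + len
      ref_span <- ref_span + len; aligned_read <- aligned_read + len
    } else if (op == "I") {
      push(r, "insertion", NA_character_,
           rawToChar(seq_raw[(q + 1L):(q + len)]), NA_integer_)
      n_ins <- n_ins + len
      q <- q + len
    } else if (op == "D") {
      del_pos <- r:(r + len - 1L)
      push(del_pos, rep("deletion", len),
           strsplit(rawToChar(chrom_raw[del_pos + 1L]), "", fixed = TRUE)[[1]],
           rep(NA_character_, len), rep(NA_integer_, len))
      n_del <- n_del + len
      r <- r + len; ref_span <- ref_span + len
    } else if (op == "N") {
      r <- r + len
    } else if (op == "S") {
      q <- q + len
    } # H, P consume nothing we track
  }

  obs <- data.frame(
    ref_pos = as.integer(unlist(acc_pos) %||% integer(0)),
    ref_base = as.character(unlist(acc_refb) %||% character(0)),
    kind = as.character(unlist(acc_kind) %||% character(0)),
    obs_base = as.character(unlist(acc_obsb) %||% character(0)),
    qual = as.integer(unlist(acc_qual) %||% integer(0)),
    stringsAsFactors = FALSE
  )
  if (nrow(obs)) obs <- obs[order(obs$ref_pos), , drop = FALSE]
  rownames(obs) <- NULL

  stats <- list(
    ref_span = ref_span,
    n_sub = n_sub,
    n_ins_bases = n_ins,
    n_del_bases = n_del,
    error_rate = if (ref_span > 0L) (n_sub + n_ins + n_del) / ref_span
                 else NaN,
    aligned_read_bases = aligned_read
  )
  list(observations = obs, stats = stats)
}

#' Extract per-position mutation observations from one alignment
#'
#' Compares an aligned record to the reference base by base: each substituted
#' reference position, each deleted reference position, and each insertion
#' run yields one observation. Soft/hard-clipped bases are ignored;
#' reference `N` positions are never called substitutions. Read-level error
#' accounting uses the reference span consumed by `M/=/X/D` operations as
#' denominator and counts every substituted, inserted and deleted base.
#'
#' @param record A single-row data frame (or list) with at least `chrom`,
#'   `start` (0-based), `cigar`, `seq` and optionally `qual` ("*" means
#'   qualities unavailable).
#' @param ref Reference genome ([Biostrings::DNAStringSet]).
#' @return A list with `observations` (data frame: `ref_pos`, `ref_base`,
#'   `kind`, `obs_base`, `qual`) and `stats` (`ref_span`, `n_sub`,
#'   `n_ins_bases`, `n_del_bases`, `error_rate`, `aligned_read_bases`).
#' @export
extract_mutations <- function(record, ref) {
  record <- as.list(record)
  chrom <- as.character(record$chrom)
  if (!chrom %in% names(ref)) {
    stop("alignment references chromosome absent from reference: ", chrom)
  }
  cigar_walk(charToRaw(as.character(ref[[chrom]])),
             as.integer(record$start), record$cigar, record$seq,
             record$qual %||% NA_character_)
}

# Append error-accounting columns to an alignment data frame. `refraw` may
# be passed to avoid recomputing raw reference vectors.
alignment_error_stats <- function(aln, ref, refraw = NULL) {
  refraw <- refraw %||% ref_as_raw(ref)
  n <- nrow(aln)
  ref_span <- integer(n); n_sub <- integer(n); n_ins <- integer(n)
  n_del <- integer(n); rate <- rep(NaN, n); aligned <- integer(n)
  for (i in seq_len(n)) {
    if (aln$is_unmapped[i] || is.na(aln$cigar[i])) next
    chrom <- aln$chrom[i]
    if (!chrom %in% names(refraw)) {
      stop("alignment references chromosome absent from reference: ", chrom)
    }
    st <- cigar_walk(refraw[[chrom]], aln$start[i], aln$cigar[i],
                     aln$seq[i], aln$qual[i])$stats
    ref_span[i] <- st$ref_span; n_sub[i] <- st$n_sub
    n_ins[i] <- st$n_ins_bases; n_del[i] <- st$n_del_bases
    rate[i] <- st$error_rate; aligned[i] <- st$aligned_read_bases
  }
  aln$ref_span <- ref_span; aln$n_sub <- n_sub
  aln$n_ins_bases <- n_ins; aln$n_del_bases <- n_del
  aln$error_rate <- rate; aln$aligned_read_bases <- aligned
  aln
}

#' Keep only usable alignments
#'
#' An alignment is usable if it is mapped, primary (neither secondary nor
#' supplementary) and its overall mutation rate -- substitutions, insertions
#' and deletions over the reference span -- is at most `max_error_rate`
#' (inclusive bound).
#'
#' @param aln Alignment data frame from [read_alignments()].
#' @param ref Reference genome.
#' @param max_error_rate Maximum tolerated per-read error rate (default 0.10).
#' @return The usable subset of `aln` with error-statistics columns appended.
#' @export
filter_usable_alignments <- function(aln, ref, max_error_rate = 0.10) {
  keep <- !aln$is_unmapped & !aln$is_secondary & !aln$is_supplementary &
    !is.na(aln$cigar)
  aln <- aln[keep, , drop = FALSE]
  aln <- alignment_error_stats(aln, ref)
  ok <- is.finite(aln$error_rate) & aln$error_rate <= max_error_rate
  out <- aln[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count usable aligned nucleotides
#'
#' Sums, over usable alignments (see [filter_usable_alignments()]), the read
#' bases in `M/=/X` CIGAR operations. Inserted and clipped bases do not
#' count; this is the denominator used for SSB-per-million-bp frequencies.
#'
#' @param aln Alignment data frame or path to SAM/BAM.
#' @param ref Reference genome.
#' @param max_error_rate Per-read error-rate bound (default 0.10).
#' @return Total aligned nucleotides (numeric scalar).
#' @export
count_aligned_nucleotides <- function(aln, ref, max_error_rate = 0.10) {
  if (is.character(aln)) aln <- read_alignments(aln)
  usable <- filter_usable_alignments(aln, ref, max_error_rate)
  sum(as.numeric(usable$aligned_read_bases))
}
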