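# Shared fixtures: hand-built alignment records, an independent brute-force
# event oracle, and a small random-alignment generator. Everything is built
# in code; coordinates are 0-based half-open throughout.

toy_ref <- function(seqs) {
  Biostrings::DNAStringSet(seqs)
}

# Test-side reverse complement, independent of the package internals.
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# One alignment record in the package's data-frame convention.
make_record <- function(cigar, seq, chrom = "chr1", start = 0L,
                        qual = NULL, qname = "r1", mapq = 60L, flag = 0L) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))   # phred 40
  data.frame(
    qname = qname, flag = flag, chrom = chrom, start = as.integer(start),
    mapq = mapq, cigar = cigar, seq = seq, qual = qual,
    is_unmapped = bitwAnd(flag, 4L) != 0L,
    is_secondary = bitwAnd(flag, 256L) != 0L,
    is_supplementary = bitwAnd(flag, 2048L) != 0L,
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    stringsAsFactors = FALSE
  )
}

# Substitute bases of `seq` at 0-based offsets.
sub_at <- function(seq, offsets, bases) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[offsets + 1L] <- bases
  paste(chars, collapse = "")
}

# Independent per-position replay of an alignment: observed base per
# reference position ("-" = deleted, NA = not aligned), via a deliberately
# simple per-base loop.
replay_alignment <- function(record, refseq) {
  record <- as.list(record)
  n <- nchar(refseq)
  obs <- rep(NA_character_, n)
  toks <- regmatches(record$cigar,
                     gregexpr("\\d+[MIDNSHP=X]", record$cigar))[[1]]
  ops <- substring(toks, nchar(toks), nchar(toks))
  lens <- as.integer(substring(toks, 1, nchar(toks) - 1))
  r <- as.integer(record$start); q <- 0L
  rd <- strsplit(record$seq, "", fixed = TRUE)[[1]]
  for (i in seq_along(ops)) {
    for (k in seq_len(lens[i])) {
      if (ops[i] %in% c("M", "=", "X")) {
        obs[r + 1L] <- rd[q + 1L]; r <- r + 1L; q <- q + 1L
      } else if (ops[i] == "D") {
        obs[r + 1L] <- "-"; r <- r + 1L
      } else if (ops[i] == "N") {
        r <- r + 1L
      } else if (ops[i] %in% c("I", "S")) {
        q <- q + 1L
      }
    }
  }
  obs
}

# Brute-force oracle for scan_events: tests every contiguous subinterval of
# target-base positions for "all mutated, flanked by an intact target base
# on the anchor side, maximal". Returns a data frame sorted by first_mut.
oracle_scan <- function(record, ref, target_base) {
  record <- as.list(record)
  refseq <- as.character(ref[[record$chrom]])
  obs <- replay_alignment(record, refseq)
  refchars <- strsplit(refseq, "", fixed = TRUE)[[1]]
  aligned <- which(!is.na(obs))
  tpos <- aligned[refchars[aligned] == target_base]
  k <- length(tpos)
  if (k == 0L) return(NULL)
  mutated <- obs[tpos] != refchars[tpos]   # substitution or "-"
  upstream <- target_base %in% c("A", "C")
  out <- NULL
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (!all(mutated[i:j])) next
      if (i > 1L && mutated[i - 1L]) next        # not maximal left
      if (j < k && mutated[j + 1L]) next         # not maximal right
      if (upstream && i == 1L) next              # unanchored
      if (!upstream && j == k) next
      run <- tpos[i:j]
      anchor <- if (upstream) tpos[i - 1L] else tpos[j + 1L]
      n_del <- sum(obs[run] == "-")
      out <- rbind(out, data.frame(
        anchor_pos = anchor - 1L, first_mut_pos = run[1] - 1L,
        last_mut_pos = run[length(run)] - 1L, n_mut_targets = j - i + 1L,
        n_sub = (j - i + 1L) - n_del, n_del = n_del))
    }
  }
  if (!is.null(out)) out <- out[order(out$first_mut_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random toy alignment over a fresh random reference; edits injected with
# an independent per-base construction (CIGAR built by simple looping).
random_toy_record <- function(seed, ref_len = 200L, p_sub = 0.12,
                              p_del = 0.05, p_ins = 0.03) {
  set.seed(seed)
  refseq <- paste(sample(c("A", "C", "G", "T"), ref_len, replace = TRUE),
                  collapse = "")
  ref <- toy_ref(c(chr1 = refseq))
  s <- sample.int(ref_len - 60L, 1L) - 1L
  e <- s + sample(40:min(60L, ref_len - s), 1L)
  refchars <- strsplit(refseq, "", fixed = TRUE)[[1]]
  seq_chars <- character(0); ops <- character(0)
  for (p in (s + 1L):e) {
    u <- runif(1)
    if (u < p_del) {
      ops <- c(ops, "D")
    } else if (u < p_del + p_sub) {
      seq_chars <- c(seq_chars,
                     sample(setdiff(c("A", "C", "G", "T"), refchars[p]), 1L))
      ops <- c(ops, "M")
    } else {
      seq_chars <- c(seq_chars, refchars[p])
      ops <- c(ops, "M")
    }
    if (p < e && runif(1) < p_ins) {
      seq_chars <- c(seq_chars, sample(c("A", "C", "G", "T"), 1L))
      ops <- c(ops, "I")
    }
  }
  rl <- rle(ops)
  cigar <- paste0(rl$lengths, rl$values, collapse = "")
  list(ref = ref,
       record = make_record(cigar, paste(seq_chars, collapse = ""),
                            start = s, qname = paste0("toy", seed)))
}

# Hand-built event row for filter tests.
make_event <- function(n_mut = 5L, n_sub = 4L, mean_qual = 30,
                       target_base = "A", anchor = 3L, first = 6L,
                       last = 6L + n_mut - 1L, mapq = 60L,
                       read_name = "r1") {
  data.frame(
    read_name = read_name, chrom = "chr1", target_base = target_base,
    strand = if (target_base %in% c("A", "C")) "+" else "-",
    anchor_pos = anchor, first_mut_pos = first, last_mut_pos = last,
    n_mut_targets = as.integer(n_mut), n_sub = as.integer(n_sub),
    n_del = as.integer(n_mut - n_sub),
    mean_sub_quality = if (n_sub > 0) mean_qual else NA_real_,
    mapq = mapq, mut_pos = I(list(seq(first, last))),
    stringsAsFactors = FALSE
  )
}

# Write a SAM file for records aligned to `ref` (header included).
write_sam <- function(records, ref, path) {
  lens <- Biostrings::width(ref)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(ref), "\tLN:", lens))
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    paste(r$qname, r$flag, r$chrom, r$start + 1L, r$mapq, r$cigar, "*", 0L,
          0L, r$seq, r$qual, sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}
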