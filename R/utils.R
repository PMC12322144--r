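# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open; conversion to the 1-based closed convention
# used by Bioconductor containers happens only at the boundary.

RAW_A <- charToRaw("A")
RAW_C <- charToRaw("C")
RAW_G <- charToRaw("G")
RAW_T <- charToRaw("T")
RAW_N <- charToRaw("N")

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @importFrom methods is
ref_lengths <- function(ref) {
  stats::setNames(Biostrings::width(ref), names(ref))
}

# Reference chromosomes as raw vectors for fast per-position work.
ref_as_raw <- function(ref) {
  out <- lapply(seq_along(ref), function(i) charToRaw(as.character(ref[[i]])))
  names(out) <- names(ref)
  out
}

parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(list(op = character(0), len = integer(0)))
  }
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar)
  }
  list(
    op = substring(toks, nchar(toks), nchar(toks)),
    len = as.integer(substring(toks, 1L, nchar(toks) - 1L))
  )
}

qual_to_phred <- function(qual) {
  if (is.null(qual) || is.na(qual) || qual == "*") return(NULL)
  utf8ToInt(qual) - 33L
}

phred_to_qual <- function(phred) {
  intToUtf8(phred + 33L)
}

# 0-based half-open intervals -> GRanges (1-based closed).
intervals_to_granges <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
}

# Deterministic child seeds below 2^31 derived from a user seed.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
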