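# Synthetic-data generator: seeded references, nick placement, error-prone
# nick-translation tracts, technology-specific sequencing error layers, and
# emission of pre-aligned SAM records with exact CIGAR/MD edit scripts plus
# ground truth. Every downstream stage of the pipeline is testable against
# the truth these functions record.

#' Generate a random reference genome
#'
#' Draws i.i.d. bases at the requested GC content and optionally embeds
#' copies of a nickase recognition motif (in random orientation, at
#' positions kept at least `motif_spacing` bp apart and away from the
#' chromosome ends). Embedded motif positions are recorded in
#' `S4Vectors::metadata(ref)$motif_sites`.
#'
#' @param length Total genome length in bp (split evenly over chromosomes).
#' @param gc GC fraction in (0, 1).
#' @param n_chroms Number of chromosomes.
#' @param seed Random seed.
#' @param motif Optional motif to embed (e.g. `"GTCTC"`).
#' @param motif_count Number of embedded copies.
#' @param motif_spacing Minimum distance between embedded copies (bp).
#' @return A [Biostrings::DNAStringSet]; embedded sites (0-based `start`,
#'   `strand`) in its metadata.
#' @export
make_reference <- function(length, gc = 0.5, n_chroms = 1L, seed = NULL,
                           motif = NULL, motif_count = 0L,
                           motif_spacing = 100L) {
  if (length < 1) stop("length must be >= 1")
  if (gc <= 0 || gc >= 1) stop("gc must be strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  per <- rep(floor(length / n_chroms), n_chroms)
  per[n_chroms] <- length - sum(per[-n_chroms])
  seqs <- vapply(per, function(n) {
    paste(sample(BASES, n, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(n_chroms))

  sites <- data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (!is.null(motif) && motif_count > 0L) {
    ml <- nchar(motif)
    margin <- 200L
    alloc <- table(factor(
      sample(names(seqs), motif_count, replace = TRUE, prob = per),
      levels = names(seqs)))
    for (ch in names(seqs)) {
      k <- as.integer(alloc[[ch]])
      if (k == 0L) next
      len <- nchar(seqs[[ch]])
      lo <- margin; hi <- len - margin - ml
      if (hi <= lo) stop("chromosome too short to embed motifs")
      pos <- NULL
      for (try in 1:1000) {
        cand <- sort(sample(lo:hi, k))
        if (k == 1L || min(diff(cand)) >= motif_spacing) { pos <- cand; break }
      }
      if (is.null(pos)) stop("could not place motifs at requested spacing")
      strand <- sample(c("+", "-"), k, replace = TRUE)
      for (j in seq_len(k)) {
        ins <- if (strand[j] == "+") motif else revcomp(motif)
        substr(seqs[[ch]], pos[j] + 1L, pos[j] + ml) <- ins
      }
      sites <- rbind(sites, data.frame(chrom = ch, start = pos,
                                       strand = strand,
                                       stringsAsFactors = FALSE))
    }
  }
  ref <- Biostrings::DNAStringSet(seqs)
  S4Vectors::metadata(ref)$motif_sites <- sites
  S4Vectors::metadata(ref)$motif <- motif
  ref
}

#' Nick positions implied by embedded motif copies
#'
#' Converts the embedded-motif record of [make_reference()] into nick
#' positions using the nicking-enzyme geometry (forward motif at `m` nicks
#' at `m + nick_offset`; a reverse-orientation copy nicks the minus strand
#' at `m - (nick_offset - motif_length) - 1`).
#'
#' @param ref Reference from [make_reference()] with embedded motifs.
#' @param nick_offset Offset of the nick from the motif start (default 6,
#'   i.e. one spacer base after a 5-bp recognition site).
#' @return Data frame `chrom`, `nick_pos` (0-based), `strand`.
#' @export
embedded_nick_sites <- function(ref, nick_offset = 6L) {
  sites <- S4Vectors::metadata(ref)$motif_sites
  if (is.null(sites) || nrow(sites) == 0L) {
    stop("reference has no embedded motif sites")
  }
  ml <- nchar(S4Vectors::metadata(ref)$motif)
  nick <- ifelse(sites$strand == "+",
                 sites$start + nick_offset,
                 sites$start - (nick_offset - ml) - 1L)
  data.frame(chrom = sites$chrom, nick_pos = as.integer(nick),
             strand = sites$strand, stringsAsFactors = FALSE)
}

#' Plan nick positions
#'
#' Three placement modes: at every motif occurrence in the reference
#' (`motif`), at a seeded Poisson-random rate per bp (`rate`), or at
#' explicitly supplied positions (`sites` data frame or `bed` file).
#'
#' @param ref Reference genome.
#' @param motif Nickase recognition motif (IUPAC) for motif mode.
#' @param nick_offset Nick offset from motif start (motif mode).
#' @param rate Expected nicks per bp (random mode; both strands combined).
#' @param sites Data frame with `chrom`, `nick_pos` (or `start`), `strand`.
#' @param bed BED path of 1-bp nick intervals.
#' @param seed Seed for random mode.
#' @return Data frame `chrom`, `nick_pos` (0-based), `strand`, `origin`.
#' @export
place_nicks <- function(ref, motif = NULL, nick_offset = 6L, rate = NULL,
                        sites = NULL, bed = NULL, seed = NULL) {
  modes <- c(!is.null(motif), !is.null(rate), !is.null(sites), !is.null(bed))
  if (sum(modes) != 1L) {
    stop("specify exactly one of motif=, rate=, sites=, bed=")
  }
  lens <- ref_lengths(ref)
  if (!is.null(motif)) {
    tr <- find_motif_sites(ref, motif, nick_offset)
    out <- data.frame(chrom = tr$chrom, nick_pos = tr$start,
                      strand = tr$strand,
                      origin = rep("motif", nrow(tr)),
                      stringsAsFactors = FALSE)
  } else if (!is.null(rate)) {
    if (!is.null(seed)) set.seed(seed)
    out <- do.call(rbind, lapply(names(lens), function(ch) {
      n <- stats::rpois(1, rate * lens[[ch]])
      if (n == 0L) return(NULL)
      data.frame(chrom = ch,
                 nick_pos = sort(sample.int(lens[[ch]], n, replace = TRUE) - 1L),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 origin = "random", stringsAsFactors = FALSE)
    }))
    if (is.null(out)) {
      out <- data.frame(chrom = character(0), nick_pos = integer(0),
                        strand = character(0), origin = character(0),
                        stringsAsFactors = FALSE)
    }
  } else if (!is.null(sites)) {
    pos <- sites$nick_pos %||% sites$start
    out <- data.frame(chrom = as.character(sites$chrom),
                      nick_pos = as.integer(pos),
                      strand = as.character(sites$strand),
                      origin = rep("explicit", length(pos)),
                      stringsAsFactors = FALSE)
  } else {
    b <- read_calls_bed(bed)
    out <- data.frame(chrom = b$chrom, nick_pos = b$start,
                      strand = ifelse(b$strand %in% c("+", "-"), b$strand, "+"),
                      origin = rep("explicit", nrow(b)),
                      stringsAsFactors = FALSE)
  }
  bad <- !(out$chrom %in% names(lens)) | out$nick_pos < 0L |
    out$nick_pos >= lens[out$chrom]
  if (any(bad)) {
    if (any(out$origin != "motif")) {
      stop("nick position outside reference bounds")
    }
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Substitution/deletion spectrum of the error-prone polymerase
#'
#' Describes what happens at each occurrence of the omitted nucleotide
#' inside a newly synthesized tract: substitution probabilities for the
#' three available bases, deletion probability, and a small per-position
#' insertion probability. Replacement and deletion probabilities must sum
#' to one (the correct base is unavailable inside the tract). Defaults
#' follow the observed bias of the polymerase: with dATP omitted, A is most
#' often replaced by G, and deletions are common.
#'
#' @param target_base The omitted base as read on the synthesized strand
#'   (`"A"` for the -dATP reaction, `"C"` for -dCTP).
#' @param p_replace Named numeric: replacement probabilities for the three
#'   other bases.
#' @param p_del Deletion probability at target positions.
#' @param p_ins Per-position insertion probability inside the tract.
#' @param tract_mean Mean tract length in bp.
#' @param tract_model `"geometric"` or `"fixed"`.
#' @return A list of class `sloppy_spectrum`.
#' @export
sloppy_spectrum <- function(target_base = "A",
                            p_replace = NULL,
                            p_del = 0.25, p_ins = 0.01,
                            tract_mean = 50, tract_model = c("geometric",
                                                             "fixed")) {
  tract_model <- match.arg(tract_model)
  if (is.null(p_replace)) {
    p_replace <- switch(target_base,
      A = c(G = 0.55, T = 0.10, C = 0.10),
      C = c(T = 0.55, G = 0.10, A = 0.10),
      stop("no default spectrum for target base ", target_base))
  }
  if (target_base %in% names(p_replace)) {
    stop("replacement probabilities must not include the omitted base")
  }
  tot <- sum(p_replace) + p_del
  if (abs(tot - 1) > 1e-8) {
    stop("replacement + deletion probabilities must sum to 1 (got ", tot, ")")
  }
  structure(list(target_base = target_base, p_replace = p_replace,
                 p_del = p_del, p_ins = p_ins, tract_mean = tract_mean,
                 tract_model = tract_model),
            class = "sloppy_spectrum")
}

#' Per-technology sequencing error model
#'
#' Simple i.i.d. per-base substitution/insertion/deletion layer with a
#' constant base quality, parameterised per platform. Defaults:
#' illumina 1e-3 substitutions and 1e-4 indels at Q35; pacbio-hifi 2e-3 and
#' 1e-3 at Q30; nanopore 2e-2 and 2e-2 at Q15. All rates are configurable
#' and sit well below the 10% per-read usability bound.
#'
#' @param technology `"illumina"`, `"pacbio-hifi"`, `"nanopore"` or
#'   `"error-free"`.
#' @param p_sub,p_ins,p_del Override per-base rates.
#' @param qual Override the constant phred quality.
#' @return A list of class `seq_error_model`.
#' @export
seq_error_model <- function(technology = c("illumina", "pacbio-hifi",
                                           "nanopore", "error-free"),
                            p_sub = NULL, p_ins = NULL, p_del = NULL,
                            qual = NULL) {
  technology <- match.arg(technology)
  d <- switch(technology,
    "illumina"    = list(p_sub = 1e-3, p_ins = 1e-4, p_del = 1e-4, qual = 35L),
    "pacbio-hifi" = list(p_sub = 2e-3, p_ins = 1e-3, p_del = 1e-3, qual = 30L),
    "nanopore"    = list(p_sub = 2e-2, p_ins = 2e-2, p_del = 2e-2, qual = 15L),
    "error-free"  = list(p_sub = 0, p_ins = 0, p_del = 0, qual = 40L))
  structure(list(technology = technology,
                 p_sub = p_sub %||% d$p_sub, p_ins = p_ins %||% d$p_ins,
                 p_del = p_del %||% d$p_del, qual = as.integer(qual %||%
                                                                 d$qual)),
            class = "seq_error_model")
}

# Sample a tract length according to the spectrum.
sample_tract_len <- function(spectrum) {
  if (spectrum$tract_model == "fixed") {
    as.integer(round(spectrum$tract_mean))
  } else {
    stats::rgeom(1, 1 / spectrum$tract_mean) + 1L
  }
}

# Edit script for one nick-translation tract, in forward coordinates.
# For a + nick the tract covers [nick_pos, nick_pos + L); every forward
# occurrence of the omitted base is substituted or deleted. For a - nick
# synthesis runs right-to-left, the tract covers (nick_pos - L, nick_pos],
# and the omitted base appears in forward coordinates as its complement.
# Inserted bases never equal the omitted base on the synthesized strand.
# Returns list(edits = data.frame(pos, kind, alt), tract = c(start, end)).
tract_edits <- function(chrom_raw, nick_pos, strand, spectrum,
                        tract_len = NULL) {
  L <- tract_len %||% sample_tract_len(spectrum)
  chrlen <- length(chrom_raw)
  if (strand == "+") {
    t0 <- nick_pos; t1 <- min(nick_pos + L, chrlen)
    fwd_target <- spectrum$target_base
    map_alt <- identity
  } else {
    t0 <- max(nick_pos - L + 1L, 0L); t1 <- nick_pos + 1L
    fwd_target <- COMPLEMENT[[spectrum$target_base]]
    map_alt <- function(b) unname(COMPLEMENT[b])
  }
  if (t1 <= t0) {
    return(list(edits = data.frame(pos = integer(0), kind = character(0),
                                   alt = character(0),
                                   stringsAsFactors = FALSE),
                tract = c(t0, t1)))
  }
  span <- chrom_raw[(t0 + 1L):t1]
  tpos <- t0 + which(span == charToRaw(fwd_target)) - 1L

  pos <- integer(0); kind <- character(0); alt <- character(0)
  if (length(tpos)) {
    choices <- c(names(spectrum$p_replace), "-")
    probs <- c(spectrum$p_replace, spectrum$p_del)
    draw <- sample(choices, length(tpos), replace = TRUE, prob = probs)
    is_del <- draw == "-"
    pos <- c(pos, tpos)
    kind <- c(kind, ifelse(is_del, "deletion", "substitution"))
    alt <- c(alt, ifelse(is_del, NA_character_, map_alt(draw)))
  }
  if (spectrum$p_ins > 0) {
    n_ins <- stats::rbinom(1, t1 - t0, spectrum$p_ins)
    if (n_ins > 0L) {
      ipos <- t0 + sample.int(t1 - t0, n_ins)   # anchored at following base
      allowed <- setdiff(BASES, map_alt(spectrum$target_base))
      ibase <- sample(allowed, n_ins, replace = TRUE)
      pos <- c(pos, ipos)
      kind <- c(kind, rep("insertion", n_ins))
      alt <- c(alt, ibase)
    }
  }
  ord <- order(pos)
  list(edits = data.frame(pos = as.integer(pos[ord]), kind = kind[ord],
                          alt = alt[ord], stringsAsFactors = FALSE),
       tract = c(t0, t1))
}

#' Apply the polymerase signature downstream of one nick
#'
#' Simulates nick translation by the error-prone polymerase on the nicked
#' strand of a duplex: the strand downstream of the nick is resynthesized
#' over a tract whose every occurrence of the omitted base is substituted
#' or deleted according to the spectrum. The opposite strand is untouched.
#'
#' @param ref Reference genome.
#' @param nick One-row data frame (or list) with `chrom`, `nick_pos`,
#'   `strand`.
#' @param spectrum A [sloppy_spectrum()].
#' @param tract_len Fixed tract length; default samples from the spectrum's
#'   tract model.
#' @param seed Optional seed.
#' @return List: `edits` (data frame `pos`, `kind`, `alt`; forward
#'   coordinates, insertions anchored at the following reference position),
#'   `tract` (0-based half-open interval), `modified` (the forward-sense
#'   sequence of the modified strand across the tract).
#' @export
sloppy_modify <- function(ref, nick, spectrum = sloppy_spectrum(),
                          tract_len = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nick <- as.list(nick)
  chrom <- as.character(nick$chrom)
  if (!chrom %in% names(ref)) stop("nick chromosome absent from reference")
  chrom_raw <- charToRaw(as.character(ref[[chrom]]))
  res <- tract_edits(chrom_raw, as.integer(nick$nick_pos),
                     as.character(nick$strand), spectrum, tract_len)
  t0 <- res$tract[1]; t1 <- res$tract[2]
  modified <- ""
  if (t1 > t0) {
    chars <- strsplit(rawToChar(chrom_raw[(t0 + 1L):t1]), "",
                      fixed = TRUE)[[1]]
    keep <- rep(TRUE, length(chars))
    ins_before <- rep("", length(chars) + 1L)
    for (i in seq_len(nrow(res$edits))) {
      e <- res$edits[i, ]
      off <- e$pos - t0 + 1L
      if (e$kind == "substitution") chars[off] <- e$alt
      else if (e$kind == "deletion") keep[off] <- FALSE
      else ins_before[off] <- paste0(ins_before[off], e$alt)
    }
    pieces <- character(0)
    for (i in seq_along(chars)) {
      pieces <- c(pieces, ins_before[i], if (keep[i]) chars[i] else "")
    }
    modified <- paste0(paste(pieces, collapse = ""), ins_before[length(chars) + 1L])
  }
  list(edits = res$edits, tract = c(start = t0, end = t1),
       modified = modified)
}

# --- read construction -----------------------------------------------------

# Build CIGAR, MD, SEQ and truth edits from the per-position span state of
# one read. `alt` raw vector of current bases, `del` logical, `ins`
# character vector length n+1 (ins[i] inserted before span offset i).
# Returns NULL when nothing aligns.
build_read <- function(span_start, span_ref, alt, del, ins) {
  n <- length(span_ref)
  keep_idx <- which(!del)
  if (!length(keep_idx)) return(NULL)
  a <- keep_idx[1]; b <- keep_idx[length(keep_idx)]
  # trim leading/trailing deletions and edge insertions
  idx <- a:b
  alt <- alt[idx]; del <- del[idx]; ref <- span_ref[idx]
  ins <- ins[(a + 1L):b]              # ins[j] now before local offset j+1
  n <- length(idx)
  pos0 <- span_start + a - 1L

  mism <- alt != ref & !del
  code <- ifelse(del, "D", ifelse(mism, "S", "M"))

  # CIGAR: M/D runs split by insertion anchors
  anchors <- which(nchar(ins) > 0L)   # before local offset j+1
  ops <- character(0); lens <- integer(0)
  add <- function(op, len) {
    if (len == 0L) return()
    k <- length(ops)
    if (k && ops[k] == op) lens[k] <<- lens[k] + len
    else { ops[k + 1L] <<- op; lens[k + 1L] <<- len }
  }
  seg_start <- 1L
  for (jj in c(anchors, NA)) {
    seg_end <- if (is.na(jj)) n else jj
    if (seg_end >= seg_start) {
      rr <- rle(ifelse(del[seg_start:seg_end], "D", "M"))
      for (t in seq_along(rr$values)) add(rr$values[t], rr$lengths[t])
    }
    if (!is.na(jj)) add("I", nchar(ins[jj]))
    seg_start <- seg_end + 1L
  }
  cigar <- paste0(lens, ops, collapse = "")

  # SEQ: non-deleted bases with insertions spliced in
  base_str <- rawToChar(alt[!del])
  if (length(anchors)) {
    read_off <- cumsum(!del)          # read bases up to local offset
    parts <- character(0); prev <- 0L
    for (jj in anchors) {
      parts <- c(parts, substr(base_str, prev + 1L, read_off[jj]), ins[jj])
      prev <- read_off[jj]
    }
    seq <- paste0(paste(parts, collapse = ""),
                  substr(base_str, prev + 1L, nchar(base_str)))
  } else {
    seq <- base_str
  }

  # MD over aligned (non-insertion) positions
  rr <- rle(code)
  md <- character(0); pending <- 0L
  pos_cursor <- 0L
  refchars <- strsplit(rawToChar(ref), "", fixed = TRUE)[[1]]
  for (t in seq_along(rr$values)) {
    len <- rr$lengths[t]; v <- rr$values[t]
    if (v == "M") {
      pending <- pending + len
    } else if (v == "S") {
      for (u in seq_len(len)) {
        md <- c(md, as.character(pending), refchars[pos_cursor + u])
        pending <- 0L
      }
    } else {
      md <- c(md, as.character(pending),
              paste0("^", paste(refchars[pos_cursor + seq_len(len)],
                                collapse = "")))
      pending <- 0L
    }
    pos_cursor <- pos_cursor + len
  }
  md <- paste0(paste(md, collapse = ""), pending)

  nm <- sum(mism) + sum(del) + sum(nchar(ins))

  # truth edit script in the package's observation convention
  tp <- integer(0); tk <- character(0); ta <- character(0)
  if (any(mism)) {
    w <- which(mism)
    tp <- c(tp, pos0 + w - 1L); tk <- c(tk, rep("substitution", length(w)))
    ta <- c(ta, strsplit(rawToChar(alt[w]), "", fixed = TRUE)[[1]])
  }
  if (any(del)) {
    w <- which(del)
    tp <- c(tp, pos0 + w - 1L); tk <- c(tk, rep("deletion", length(w)))
    ta <- c(ta, rep(NA_character_, length(w)))
  }
  if (length(anchors)) {
    tp <- c(tp, pos0 + anchors)       # anchored at following reference pos
    tk <- c(tk, rep("insertion", length(anchors)))
    ta <- c(ta, ins[anchors])
  }
  ord <- order(tp)
  list(pos = pos0, cigar = cigar, seq = seq, md = md, nm = nm,
       edits = data.frame(ref_pos = tp[ord], kind = tk[ord], alt = ta[ord],
                          stringsAsFactors = FALSE))
}

#' Simulate a sequencing library over nicked molecules
#'
#' Each simulated read corresponds to one molecule: it is drawn uniformly
#' from the genome, assigned a strand of origin, and -- when a nick on that
#' strand has a tract overlapping the read -- carries the polymerase
#' signature (tract length resampled per molecule). A per-technology
#' sequencing error layer is added on top, and each read is emitted as a
#' pre-aligned SAM record whose CIGAR/MD/NM replay exactly to its sequence
#' against the reference. Reads from the unmodified strand of a nicked
#' duplex show no signature, as in a real library.
#'
#' @param ref Reference genome.
#' @param nicks Nick plan from [place_nicks()] (may have zero rows).
#' @param spectrum A [sloppy_spectrum()].
#' @param err A [seq_error_model()].
#' @param coverage Mean fold coverage.
#' @param read_length Mean read length (bp).
#' @param read_length_sd Read-length standard deviation (default 10% of the
#'   mean; 0 gives fixed-length reads).
#' @param seed Random seed.
#' @param out_prefix If non-NULL, write `<prefix>.sam`, `<prefix>.fastq`,
#'   `<prefix>.truth.bed` and `<prefix>.manifest.json`.
#' @return List of class `steel_sim`: `reads` (data frame with SAM fields),
#'   `truth_edits` (per-read edit script), `nicks`, `paths`.
#' @export
simulate_reads <- function(ref, nicks, spectrum = sloppy_spectrum(),
                           err = seq_error_model("pacbio-hifi"),
                           coverage = 30, read_length = 3000,
                           read_length_sd = NULL, seed = NULL,
                           out_prefix = NULL) {
  if (coverage <= 0) stop("coverage must be positive")
  if (!is.null(seed)) set.seed(seed)
  read_length_sd <- read_length_sd %||% (0.1 * read_length)
  lens <- ref_lengths(ref)
  refraw <- ref_as_raw(ref)
  tract_cap <- as.integer(ceiling(spectrum$tract_mean * 40))

  sam <- list(); truth <- list(); reads <- list()
  fastq_seq <- list(); fastq_name <- list()
  ridx <- 0L
  for (ch in names(lens)) {
    chrlen <- lens[[ch]]
    chrom_raw <- refraw[[ch]]
    ch_nicks <- nicks[nicks$chrom == ch, , drop = FALSE]
    n_reads <- as.integer(ceiling(coverage * chrlen / read_length))
    rl <- round(stats::rnorm(n_reads, read_length, read_length_sd))
    rl <- pmax(50L, pmin(as.integer(rl), chrlen))
    st <- vapply(rl, function(l) sample.int(chrlen - l + 1L, 1L) - 1L,
                 integer(1))
    dstrand <- sample(c("+", "-"), n_reads, replace = TRUE)

    for (i in seq_len(n_reads)) {
      s <- st[i]; e <- s + rl[i]; n <- rl[i]
      span_ref <- chrom_raw[(s + 1L):e]
      alt <- span_ref
      del <- rep(FALSE, n)
      ins <- rep("", n + 1L)

      # polymerase tracts from nicks on this molecule's strand
      if (nrow(ch_nicks)) {
        cand <- ch_nicks[ch_nicks$strand == dstrand[i] &
                           ((ch_nicks$strand == "+" &
                               ch_nicks$nick_pos < e &
                               ch_nicks$nick_pos > s - tract_cap) |
                              (ch_nicks$strand == "-" &
                                 ch_nicks$nick_pos >= s &
                                 ch_nicks$nick_pos < e + tract_cap)), ,
                         drop = FALSE]
        for (j in seq_len(nrow(cand))) {
          te <- tract_edits(chrom_raw, cand$nick_pos[j], cand$strand[j],
                            spectrum)
          ed <- te$edits
          ed <- ed[ed$pos >= s & ed$pos < e, , drop = FALSE]
          for (kk in seq_len(nrow(ed))) {
            off <- ed$pos[kk] - s + 1L
            if (ed$kind[kk] == "substitution") {
              alt[off] <- charToRaw(ed$alt[kk])
            } else if (ed$kind[kk] == "deletion") {
              del[off] <- TRUE
            } else if (ed$pos[kk] > s) {
              ins[off] <- paste0(ins[off], ed$alt[kk])
            }
          }
        }
      }

      # sequencing error layer
      if (err$p_sub > 0) {
        k <- stats::rbinom(1, n, err$p_sub)
        if (k > 0L) {
          w <- sample.int(n, k)
          w <- w[!del[w]]
          for (off in w) {
            cur <- rawToChar(alt[off])
            alt[off] <- charToRaw(sample(setdiff(BASES, cur), 1L))
          }
        }
      }
      if (err$p_del > 0) {
        k <- stats::rbinom(1, n, err$p_del)
        if (k > 0L) del[sample.int(n, k)] <- TRUE
      }
      if (err$p_ins > 0) {
        k <- stats::rbinom(1, n, err$p_ins)
        if (k > 0L) {
          w <- sample.int(n - 1L, min(k, n - 1L)) + 1L
          for (off in w) {
            ins[off] <- paste0(ins[off], sample(BASES, 1L))
          }
        }
      }

      br <- build_read(s, span_ref, alt, del, ins)
      if (is.null(br)) next
      ridx <- ridx + 1L
      qname <- sprintf("read%06d", ridx)
      flag <- if (dstrand[i] == "+") 0L else 16L
      qual <- phred_to_qual(rep(err$qual, nchar(br$seq)))
      sam[[ridx]] <- paste(qname, flag, ch, br$pos + 1L, 60L, br$cigar,
                           "*", 0L, 0L, br$seq, qual,
                           paste0("NM:i:", br$nm), paste0("MD:Z:", br$md),
                           sep = "\t")
      if (nrow(br$edits)) {
        br$edits$qname <- qname
        truth[[ridx]] <- br$edits
      }
      cig <- parse_cigar(br$cigar)
      reads[[ridx]] <- data.frame(
        qname = qname, chrom = ch, start = br$pos,
        end = br$pos + sum(cig$len[cig$op %in% c("M", "D", "N")]),
        strand = dstrand[i], flag = flag, stringsAsFactors = FALSE)
      fastq_name[[ridx]] <- qname
      fastq_seq[[ridx]] <- if (flag == 16L) revcomp(br$seq) else br$seq
    }
  }

  reads <- if (ridx) do.call(rbind, reads) else
    data.frame(qname = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               flag = integer(0), stringsAsFactors = FALSE)
  truth_edits <- if (length(truth)) do.call(rbind, truth) else
    data.frame(ref_pos = integer(0), kind = character(0),
               alt = character(0), qname = character(0),
               stringsAsFactors = FALSE)
  rownames(reads) <- rownames(truth_edits) <- NULL

  paths <- NULL
  if (!is.null(out_prefix)) {
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                paste0("@SQ\tSN:", names(lens), "\tLN:", unname(lens)),
                "@PG\tID:steelseq-sim\tPN:steelseq-sim")
    ord <- order(reads$chrom, reads$start)
    sam_path <- paste0(out_prefix, ".sam")
    writeLines(c(header, unlist(sam)[ord]), sam_path)
    fq_path <- paste0(out_prefix, ".fastq")
    fq <- character(4L * ridx)
    if (ridx) {
      sq <- unlist(fastq_seq)
      fq[seq(1, by = 4, length.out = ridx)] <- paste0("@", unlist(fastq_name))
      fq[seq(2, by = 4, length.out = ridx)] <- sq
      fq[seq(3, by = 4, length.out = ridx)] <- "+"
      fq[seq(4, by = 4, length.out = ridx)] <-
        vapply(nchar(sq), function(nn) phred_to_qual(rep(err$qual, nn)), "")
    }
    writeLines(fq, fq_path)
    bed_path <- paste0(out_prefix, ".truth.bed")
    if (nrow(nicks)) {
      writeLines(paste(nicks$chrom, nicks$nick_pos, nicks$nick_pos + 1L,
                       paste0("nick", seq_len(nrow(nicks))), 0L,
                       nicks$strand, sep = "\t"), bed_path)
    } else writeLines(character(0), bed_path)
    manifest_path <- paste0(out_prefix, ".manifest.json")
    jsonlite::write_json(
      list(tool = "steelseq", version = as.character(
             utils::packageVersion("steelseq")),
           seed = seed, coverage = coverage, read_length = read_length,
           technology = err$technology, n_reads = ridx,
           n_nicks = nrow(nicks),
           spectrum = list(target_base = spectrum$target_base,
                           p_replace = as.list(spectrum$p_replace),
                           p_del = spectrum$p_del, p_ins = spectrum$p_ins,
                           tract_mean = spectrum$tract_mean,
                           tract_model = spectrum$tract_model)),
      manifest_path, auto_unbox = TRUE, digits = NA, null = "null")
    paths <- list(sam = sam_path, fastq = fq_path, truth_bed = bed_path,
                  manifest = manifest_path)
  }

  structure(list(reads = reads, truth_edits = truth_edits, nicks = nicks,
                 paths = paths, n_reads = ridx),
            class = "steel_sim")
}
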