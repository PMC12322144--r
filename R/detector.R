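# Break detection: locate runs of mutated target bases (events), filter them
# per sequencing technology, and translate each passing event into the
# interval that must contain the single-strand break.

#' Technology-specific filter profiles
#'
#' Bundles the per-platform thresholds used when filtering candidate events:
#' the minimum number of mutated target bases in an event, the minimum
#' number of those mutations that must be substitutions, the per-read error
#' cap, and the minimum mean base quality of substituted bases. Named
#' profiles: `pacbio-hifi` and `nanopore` require five mutated targets
#' (nanopore additionally three substitutions), `illumina-tk6` three and
#' `illumina-hacat` four; all use a 10% read error cap and mean substituted
#' base quality of at least 10. Only the Illumina profiles deduplicate
#' calls by position, since short-read libraries contain PCR duplicates.
#'
#' @param name One of `"pacbio-hifi"`, `"nanopore"`, `"illumina-tk6"`,
#'   `"illumina-hacat"`, `"custom"`.
#' @param min_mutated_targets,min_substitutions,max_read_error_rate,min_mean_sub_quality,require_quality,dedup
#'   Override individual thresholds (required for `"custom"`).
#' @return A list of class `technology_profile`.
#' @examples
#' technology_profile("nanopore")
#' technology_profile("custom", min_mutated_targets = 6, min_substitutions = 2)
#' @export
technology_profile <- function(name = c("pacbio-hifi", "nanopore",
                                        "illumina-tk6", "illumina-hacat",
                                        "custom"),
                               min_mutated_targets = NULL,
                               min_substitutions = NULL,
                               max_read_error_rate = NULL,
                               min_mean_sub_quality = NULL,
                               require_quality = NULL,
                               dedup = NULL) {
  name <- match.arg(name)
  defaults <- list(
    "pacbio-hifi"    = list(min_mutated_targets = 5L, min_substitutions = 1L,
                            dedup = FALSE),
    "nanopore"       = list(min_mutated_targets = 5L, min_substitutions = 3L,
                            dedup = FALSE),
    "illumina-tk6"   = list(min_mutated_targets = 3L, min_substitutions = 1L,
                            dedup = TRUE),
    "illumina-hacat" = list(min_mutated_targets = 4L, min_substitutions = 1L,
                            dedup = TRUE),
    "custom"         = list(min_mutated_targets = 1L, min_substitutions = 1L,
                            dedup = FALSE)
  )[[name]]
  p <- list(
    name = name,
    min_mutated_targets = as.integer(min_mutated_targets %||%
                                       defaults$min_mutated_targets),
    min_substitutions = as.integer(min_substitutions %||%
                                     defaults$min_substitutions),
    max_read_error_rate = max_read_error_rate %||% 0.10,
    min_mean_sub_quality = min_mean_sub_quality %||% 10,
    require_quality = require_quality %||% TRUE,
    dedup = dedup %||% defaults$dedup
  )
  if (p$min_mutated_targets < 1L) {
    stop("min_mutated_targets must be at least 1")
  }
  if (p$min_substitutions > p$min_mutated_targets) {
    stop("min_substitutions cannot exceed min_mutated_targets")
  }
  structure(p, class = "technology_profile")
}

#' @export
print.technology_profile <- function(x, ...) {
  cat("Technology profile:", x$name, "\n")
  cat("  min mutated target bases per event:", x$min_mutated_targets, "\n")
  cat("  min substitutions per event:      ", x$min_substitutions, "\n")
  cat("  max per-read error rate:          ", x$max_read_error_rate, "\n")
  cat("  min mean substituted-base quality:", x$min_mean_sub_quality, "\n")
  cat("  deduplicate calls by position:    ", x$dedup, "\n")
  invisible(x)
}

# Which side carries the anchor (the flanking intact target base) for a
# given target base. Synthesis that replaced forward-strand A (or C in
# -dCTP mode) started upstream; signatures on the sequenced reverse strand
# appear as mutated T (or G) with the anchor downstream.
anchor_side <- function(target_base) {
  switch(target_base,
         A = "upstream", C = "upstream",
         T = "downstream", G = "downstream",
         stop("unsupported target base: ", target_base))
}

event_strand <- function(target_base) {
  if (anchor_side(target_base) == "upstream") "+" else "-"
}

empty_events <- function() {
  data.frame(
    read_name = character(0), chrom = character(0),
    target_base = character(0), strand = character(0),
    anchor_pos = integer(0), first_mut_pos = integer(0),
    last_mut_pos = integer(0), n_mut_targets = integer(0),
    n_sub = integer(0), n_del = integer(0),
    mean_sub_quality = numeric(0), mapq = integer(0),
    mut_pos = I(list()), stringsAsFactors = FALSE
  )
}

#' Scan one read for runs of mutated target bases
#'
#' Enumerates every reference occurrence of `target_base` within the aligned
#' span of the read (positions consumed by `M/=/X/D`; `N` gaps are not part
#' of the alignment), marks each as mutated (substituted or deleted) or
#' intact, and returns every maximal run of consecutive mutated target
#' positions that is anchored by an intact target base immediately flanking
#' the run on the anchor side: the 5' flank for `A`/`C` signatures, the 3'
#' flank for `T`/`G`. Runs touching the alignment edge on the anchor side
#' are discarded because the flanking intact base cannot be verified.
#'
#' @param observations Mutation observations for this read, from
#'   [extract_mutations()].
#' @param record The alignment record (single-row data frame or list).
#' @param ref Reference genome.
#' @param target_base `"A"`, `"T"`, `"C"` or `"G"`.
#' @return Event data frame; `mut_pos` is a list column of the mutated
#'   target positions (0-based).
#' @export
scan_events <- function(observations, record, ref, target_base = "A") {
  record <- as.list(record)
  chrom <- as.character(record$chrom)
  if (!chrom %in% names(ref)) {
    stop("alignment references chromosome absent from reference: ", chrom)
  }
  scan_events_raw(observations, record, charToRaw(as.character(ref[[chrom]])),
                  target_base)
}

# Core scanner against a raw reference chromosome (shared with detect()).
scan_events_raw <- function(observations, record, chrom_raw, target_base) {
  target_raw <- charToRaw(target_base)
  side <- anchor_side(target_base)

  ops <- parse_cigar(record$cigar)
  r <- as.integer(record$start)
  target_pos <- integer(0)
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X", "D")) {
      hits <- which(chrom_raw[(r + 1L):(r + len)] == target_raw)
      if (length(hits)) target_pos <- c(target_pos, r + hits - 1L)
      r <- r + len
    } else if (op == "N") {
      r <- r + len
    }
  }
  k <- length(target_pos)
  if (k == 0L) return(empty_events())

  mut_obs <- observations[observations$kind %in% c("substitution", "deletion"), ,
                          drop = FALSE]
  idx <- match(target_pos, mut_obs$ref_pos)
  mutated <- !is.na(idx)
  if (!any(mutated)) return(empty_events())

  runs <- rle(mutated)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  out <- list(); m <- 0L
  for (j in seq_along(runs$values)) {
    if (!runs$values[j]) next
    i0 <- starts[j]; i1 <- ends[j]
    if (side == "upstream") {
      if (i0 == 1L) next                    # run touches alignment edge
      anchor <- target_pos[i0 - 1L]
    } else {
      if (i1 == k) next
      anchor <- target_pos[i1 + 1L]
    }
    run_idx <- idx[i0:i1]
    kinds <- mut_obs$kind[run_idx]
    quals <- mut_obs$qual[run_idx][kinds == "substitution"]
    n_sub <- sum(kinds == "substitution")
    m <- m + 1L
    out[[m]] <- list(
      anchor = anchor, first = target_pos[i0], last = target_pos[i1],
      n = i1 - i0 + 1L, n_sub = n_sub, n_del = sum(kinds == "deletion"),
      mq = if (n_sub > 0L && !all(is.na(quals))) mean(quals) else NA_real_,
      pos = target_pos[i0:i1]
    )
  }
  if (m == 0L) return(empty_events())

  data.frame(
    read_name = rep(as.character(record$qname %||% record$read_name %||% NA),
                    m),
    chrom = rep(as.character(record$chrom), m),
    target_base = rep(target_base, m),
    strand = rep(event_strand(target_base), m),
    anchor_pos = vapply(out, `[[`, integer(1), "anchor"),
    first_mut_pos = vapply(out, `[[`, integer(1), "first"),
    last_mut_pos = vapply(out, `[[`, integer(1), "last"),
    n_mut_targets = vapply(out, `[[`, integer(1), "n"),
    n_sub = vapply(out, `[[`, integer(1), "n_sub"),
    n_del = vapply(out, `[[`, integer(1), "n_del"),
    mean_sub_quality = vapply(out, `[[`, numeric(1), "mq"),
    mapq = rep(as.integer(record$mapq %||% NA), m),
    mut_pos = I(lapply(out, `[[`, "pos")),
    stringsAsFactors = FALSE
  )
}

#' Apply technology filters to candidate events
#'
#' Checks, in order: enough mutated target bases; mean quality of
#' substituted bases at least the profile threshold (skipped when the event
#' contains no substitutions, and failing closed when qualities are
#' unavailable and the profile requires them); enough substitutions among
#' the mutations. The read-level error-rate filter is applied upstream by
#' [filter_usable_alignments()].
#'
#' @param events Event data frame from [scan_events()].
#' @param profile A [technology_profile()].
#' @return `events` with logical `pass` and character `fail_reason`
#'   (`NA` when passing; otherwise the first failing filter:
#'   `"min_mutated_targets"`, `"mean_sub_quality"` or
#'   `"min_substitutions"`).
#' @export
apply_filters <- function(events, profile) {
  stopifnot(inherits(profile, "technology_profile"))
  n <- nrow(events)
  reason <- rep(NA_character_, n)

  too_few <- events$n_mut_targets < profile$min_mutated_targets
  reason[too_few] <- "min_mutated_targets"

  has_sub <- events$n_sub > 0L
  qual_known <- !is.na(events$mean_sub_quality)
  bad_qual <- has_sub &
    ((qual_known & events$mean_sub_quality < profile$min_mean_sub_quality) |
       (!qual_known & profile$require_quality))
  sel <- is.na(reason) & bad_qual
  reason[sel] <- "mean_sub_quality"

  sel <- is.na(reason) & events$n_sub < profile$min_substitutions
  reason[sel] <- "min_substitutions"

  events$pass <- is.na(reason)
  events$fail_reason <- reason
  events
}

#' Convert passing events into SSB call intervals
#'
#' For an `A`/`C` signature the break lies between the last intact target
#' base upstream of the run and the first mutated target base, i.e. the
#' 0-based half-open interval `[anchor_pos + 1, first_mut_pos + 1)` on the
#' `+` strand. For a `T`/`G` signature the break lies between the last
#' mutated target base and the first intact target base downstream:
#' `[last_mut_pos, anchor_pos)` on the `-` strand.
#'
#' @param events Event data frame (typically the passing subset).
#' @return Call data frame: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `read_name`, `mapq`, `n_mut_targets`, `n_sub`, `n_del`,
#'   `mean_sub_quality`, `target_base`.
#' @export
call_ssb <- function(events) {
  upstream <- vapply(events$target_base, function(b) anchor_side(b), "") ==
    "upstream"
  start <- ifelse(upstream, events$anchor_pos + 1L, events$last_mut_pos)
  end <- ifelse(upstream, events$first_mut_pos + 1L, events$anchor_pos)
  data.frame(
    chrom = events$chrom,
    start = as.integer(start),
    end = as.integer(end),
    strand = events$strand,
    read_name = events$read_name,
    mapq = events$mapq,
    n_mut_targets = events$n_mut_targets,
    n_sub = events$n_sub,
    n_del = events$n_del,
    mean_sub_quality = events$mean_sub_quality,
    target_base = events$target_base,
    stringsAsFactors = FALSE
  )
}

#' Deduplicate SSB calls by position
#'
#' Keeps one call per `(chrom, start, end, strand)`, retaining the call with
#' the highest mapping quality (ties broken by lexicographically smallest
#' read name, for determinism). Output is sorted by chromosome, start, end.
#'
#' @param calls Call data frame from [call_ssb()].
#' @return Deduplicated, sorted call data frame.
#' @export
dedupe_calls <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  ord <- order(calls$chrom, calls$start, calls$end, calls$strand,
               -ifelse(is.na(calls$mapq), -1L, calls$mapq), calls$read_name)
  calls <- calls[ord, , drop = FALSE]
  key <- paste(calls$chrom, calls$start, calls$end, calls$strand)
  out <- calls[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sort_calls <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  out <- calls[order(calls$chrom, calls$start, calls$end, calls$strand,
                     calls$read_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write SSB calls as BED6+
#'
#' Columns: chrom, start, end, name (read name / event index), score (mapq),
#' strand, then `n_mut_targets`, `n_sub`, `n_del`, `mean_sub_quality`.
#' Sorted; duplicate lines removed.
#'
#' @param calls Call data frame.
#' @param path Output path.
#' @export
write_calls_bed <- function(calls, path) {
  calls <- sort_calls(calls)
  lines <- character(0)
  if (nrow(calls)) {
    name <- paste0(calls$read_name, "/", seq_len(nrow(calls)))
    lines <- paste(calls$chrom, calls$start, calls$end, name,
                   ifelse(is.na(calls$mapq), 0L, calls$mapq), calls$strand,
                   calls$n_mut_targets, calls$n_sub, calls$n_del,
                   ifelse(is.na(calls$mean_sub_quality), ".",
                          format(round(calls$mean_sub_quality, 2),
                                 trim = TRUE)),
                   sep = "\t")
    lines <- unique(lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of SSB calls
#'
#' Accepts BED3/BED6/BED6+ as written by [write_calls_bed()] or external
#' tools; missing columns are filled with defaults.
#'
#' @param path BED path.
#' @return Call data frame with at least `chrom`, `start`, `end`, `strand`.
#' @export
read_calls_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      read_name = character(0), mapq = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (ncol(raw) < 3L || !is.numeric(raw[[2]]) || !is.numeric(raw[[3]])) {
    stop("malformed BED file: ", path)
  }
  data.frame(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    strand = if (ncol(raw) >= 6L) as.character(raw[[6]]) else "*",
    read_name = if (ncol(raw) >= 4L) sub("/[0-9]+$", "", as.character(raw[[4]]))
                else NA_character_,
    mapq = if (ncol(raw) >= 5L) suppressWarnings(as.integer(raw[[5]]))
           else NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Detect single-strand breaks in aligned reads
#'
#' Orchestrates the full pipeline: usable-alignment filtering, per-read
#' mutation extraction, signature-run scanning on both strands (`A` and `T`
#' target bases when dATP was omitted; `C` and `G` when dCTP was), event
#' filtering, break-interval calling, and optional position deduplication.
#'
#' @param alignments Alignment data frame from [read_alignments()] or a
#'   SAM/BAM path.
#' @param ref Reference genome ([Biostrings::DNAStringSet]) or FASTA path.
#' @param profile A [technology_profile()] (or profile name).
#' @param mode `"-dATP"` (default) or `"-dCTP"`: which nucleotide was
#'   omitted from the labelling reaction.
#' @param dedup Override the profile's deduplication setting.
#' @param out_bed Optional path: write calls as BED6+ (sorted, unique).
#' @param out_bam Optional path: write the subset of input records on which
#'   passing events were detected (requires `alignments` to be a file path).
#' @return A list of class `ssb_detection`: `calls` (data frame), `events`
#'   (all candidate events with filter outcomes), `log` (named counts at
#'   each stage), `aligned_nucleotides`.
#' @export
detect_breaks <- function(alignments, ref, profile = technology_profile(),
                          mode = c("-dATP", "-dCTP"), dedup = NULL,
                          out_bed = NULL, out_bam = NULL) {
  mode <- match.arg(mode)
  if (is.character(profile)) profile <- technology_profile(profile)
  if (is.character(ref)) ref <- load_reference(ref)
  src_path <- NULL
  if (is.character(alignments)) {
    src_path <- alignments
    alignments <- read_alignments(alignments)
  }
  target_bases <- if (mode == "-dATP") c("A", "T") else c("C", "G")
  dedup <- dedup %||% profile$dedup

  refraw <- ref_as_raw(ref)
  n_records <- nrow(alignments)
  mapped <- alignments[!alignments$is_unmapped & !alignments$is_secondary &
                         !alignments$is_supplementary &
                         !is.na(alignments$cigar), , drop = FALSE]
  n_primary <- nrow(mapped)

  events_list <- list(); ei <- 0L
  n_usable <- 0L; aligned_nt <- 0
  for (i in seq_len(n_primary)) {
    rec <- list(qname = mapped$qname[i], chrom = mapped$chrom[i],
                start = mapped$start[i], cigar = mapped$cigar[i],
                seq = mapped$seq[i], qual = mapped$qual[i],
                mapq = mapped$mapq[i])
    if (!rec$chrom %in% names(refraw)) {
      stop("alignment references chromosome absent from reference: ",
           rec$chrom)
    }
    walked <- cigar_walk(refraw[[rec$chrom]], rec$start, rec$cigar, rec$seq,
                         rec$qual)
    er <- walked$stats$error_rate
    if (!is.finite(er) || er > profile$max_read_error_rate) next
    n_usable <- n_usable + 1L
    aligned_nt <- aligned_nt + walked$stats$aligned_read_bases
    for (tb in target_bases) {
      ev <- scan_events_raw(walked$observations, rec, refraw[[rec$chrom]], tb)
      if (nrow(ev)) {
        ei <- ei + 1L
        events_list[[ei]] <- ev
      }
    }
  }
  events <- if (ei) do.call(rbind, events_list) else empty_events()
  events <- apply_filters(events, profile)

  calls <- call_ssb(events[events$pass, , drop = FALSE])
  n_calls_raw <- nrow(calls)
  if (dedup) calls <- dedupe_calls(calls)
  calls <- sort_calls(calls)

  fail_counts <- table(factor(events$fail_reason,
                              levels = c("min_mutated_targets",
                                         "mean_sub_quality",
                                         "min_substitutions")))
  log <- c(n_records = n_records, n_primary_mapped = n_primary,
           n_usable = n_usable, n_events = nrow(events),
           n_events_pass = sum(events$pass),
           n_fail_min_mutated_targets = unname(fail_counts[1]),
           n_fail_mean_sub_quality = unname(fail_counts[2]),
           n_fail_min_substitutions = unname(fail_counts[3]),
           n_calls = n_calls_raw, n_calls_final = nrow(calls))

  if (!is.null(out_bed)) write_calls_bed(calls, out_bed)
  if (!is.null(out_bam)) {
    if (is.null(src_path)) {
      stop("out_bam requires 'alignments' to be given as a file path")
    }
    write_subset_bam(src_path, unique(calls$read_name), out_bam)
  }

  structure(list(calls = calls, events = events, log = log,
                 aligned_nucleotides = aligned_nt,
                 profile = profile, mode = mode),
            class = "ssb_detection")
}

#' @export
print.ssb_detection <- function(x, ...) {
  cat("SSB detection (", x$mode, ", profile ", x$profile$name, ")\n",
      sep = "")
  for (nm in names(x$log)) cat(" ", nm, "=", x$log[[nm]], "\n")
  invisible(x)
}

# Subset the input SAM/BAM to the reads named in `keep`.
write_subset_bam <- function(path, keep, out_bam) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
  } else if (!file.exists(paste0(bam, ".bai"))) {
    sorted <- Rsamtools::sortBam(bam, tempfile())
    Rsamtools::indexBam(sorted)
    bam <- sorted
  }
  rules <- S4Vectors::FilterRules(list(function(df) df$qname %in% keep))
  Rsamtools::filterBam(bam, out_bam, filter = rules,
                       param = Rsamtools::ScanBamParam(what = "qname"),
                       indexDestination = FALSE)
  invisible(out_bam)
}
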