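# Nickase site tracks and call/site coincidence with bedtools-window
# overlap semantics.

empty_site_track <- function(origin = character(0)) {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), origin = origin,
             stringsAsFactors = FALSE)
}

#' Locate nicking-endonuclease sites in a reference
#'
#' Scans both strands for an IUPAC motif and records each site as the 1-bp
#' nick-point interval. A forward match starting at 0-based position `m`
#' nicks the forward strand at `m + nick_offset`; a match of the
#' reverse-complement motif at `m` nicks the reverse strand at
#' `m - (nick_offset - motif_length) - 1`. Sites whose nick point falls
#' outside the chromosome are dropped.
#'
#' @param ref Reference genome.
#' @param motif IUPAC motif string (default `"GTCTC"`).
#' @param nick_offset Nick offset from the motif start (default 6).
#' @return Site-track data frame: `chrom`, `start`, `end` (0-based
#'   half-open 1-bp interval), `strand`, `origin = "motif"`.
#' @export
find_motif_sites <- function(ref, motif = "GTCTC", nick_offset = 6L) {
  if (nchar(motif) < 1L) stop("motif must be non-empty")
  pat <- tryCatch(Biostrings::DNAString(motif),
                  error = function(e) stop("invalid IUPAC motif: ", motif))
  ml <- nchar(motif)
  out <- list(); k <- 0L
  for (ch in names(ref)) {
    chrlen <- Biostrings::width(ref)[match(ch, names(ref))]
    fwd <- Biostrings::matchPattern(pat, ref[[ch]], fixed = "subject")
    if (length(fwd)) {
      nick <- BiocGenerics::start(fwd) - 1L + nick_offset
      nick <- nick[nick >= 0L & nick < chrlen]
      if (length(nick)) {
        k <- k + 1L
        out[[k]] <- data.frame(chrom = ch, start = nick, end = nick + 1L,
                               strand = "+", origin = "motif",
                               stringsAsFactors = FALSE)
      }
    }
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                    ref[[ch]], fixed = "subject")
    if (length(rev)) {
      m <- BiocGenerics::start(rev) - 1L
      nick <- m - (nick_offset - ml) - 1L
      nick <- nick[nick >= 0L & nick < chrlen]
      if (length(nick)) {
        k <- k + 1L
        out[[k]] <- data.frame(chrom = ch, start = nick, end = nick + 1L,
                               strand = "-", origin = "motif",
                               stringsAsFactors = FALSE)
      }
    }
  }
  if (!k) return(empty_site_track())
  track <- do.call(rbind, out)
  track <- track[order(track$chrom, track$start, track$strand), ,
                 drop = FALSE]
  rownames(track) <- NULL
  track
}

#' Random control site track
#'
#' Draws `n` 1-bp sites uniformly over the concatenated chromosome lengths
#' (so expected counts are length-proportional), with random strands. Used
#' as the chance-overlap control for coincidence analysis.
#'
#' @param ref Reference genome.
#' @param n Number of sites.
#' @param seed Random seed.
#' @return Site-track data frame with `origin = "random"`.
#' @export
random_site_track <- function(ref, n, seed = NULL) {
  if (n < 0) stop("n must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(empty_site_track())
  lens <- ref_lengths(ref)
  offsets <- cumsum(c(0, as.numeric(lens)))
  u <- sort(sample.int(sum(lens), n, replace = TRUE)) - 1
  chrom_idx <- findInterval(u, offsets[-length(offsets)],
                            rightmost.closed = FALSE)
  pos <- as.integer(u - offsets[chrom_idx])
  data.frame(chrom = names(lens)[chrom_idx], start = pos, end = pos + 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             origin = "random", stringsAsFactors = FALSE)
}

#' Coincidence of calls with a site track under window extension
#'
#' A call coincides with a site if the call interval, extended by `w` bp on
#' both sides, overlaps the site interval (half-open overlap, i.e. the
#' `bedtools window -w` rule). The fraction is computed over unique calls
#' (one per `chrom`/`start`/`end`/`strand`); strand is ignored in the
#' overlap test.
#'
#' @param calls Call data frame (columns `chrom`, `start`, `end`, `strand`)
#'   or BED path.
#' @param sites Site-track data frame or BED path.
#' @param w Window extension in bp (default 10).
#' @return List: `fraction` (coinciding fraction over unique calls; `NA`
#'   when there are none), `flags` (per-unique-call logical), `calls`
#'   (the unique calls), `n_sites`.
#' @export
window_coincidence <- function(calls, sites, w = 10L) {
  if (is.character(calls)) calls <- read_calls_bed(calls)
  if (is.character(sites)) sites <- read_calls_bed(sites)
  if (!"strand" %in% names(calls)) calls$strand <- "*"
  key <- paste(calls$chrom, calls$start, calls$end, calls$strand)
  uniq <- calls[!duplicated(key), , drop = FALSE]
  uniq <- uniq[order(uniq$chrom, uniq$start, uniq$end, uniq$strand), ,
               drop = FALSE]
  rownames(uniq) <- NULL
  if (nrow(uniq) == 0L) {
    return(list(fraction = NA_real_, flags = logical(0), calls = uniq,
                n_sites = nrow(sites)))
  }
  if (nrow(sites) == 0L) {
    return(list(fraction = 0, flags = rep(FALSE, nrow(uniq)), calls = uniq,
                n_sites = 0L))
  }
  ext <- intervals_to_granges(uniq$chrom, pmax(uniq$start - w, 0L),
                              uniq$end + w)
  sg <- intervals_to_granges(sites$chrom, sites$start, sites$end)
  hits <- GenomicRanges::countOverlaps(ext, sg, ignore.strand = TRUE) > 0L
  list(fraction = mean(hits), flags = unname(hits), calls = uniq,
       n_sites = nrow(sites))
}

# Distance between a half-open call interval [s, e) and a 1-bp site at t:
# 0 when t is inside, otherwise the gap to the nearest contained position.
call_point_distance <- function(s, e, t) {
  pmax(0L, pmax(s - t, t - (e - 1L)))
}

#' Score detected calls against simulator truth
#'
#' Recall is the fraction of true nicks with at least one call within
#' `tol` bp (distance 0 when the nick point lies inside the call interval);
#' precision is the fraction of calls -- scored as given, so deduplicate
#' first if desired -- within `tol` of some true nick. A greedy 1-to-1
#' matching by increasing distance (ties broken by coordinate) provides
#' the per-nick hit table.
#'
#' @param calls Call data frame or BED path.
#' @param truth Truth track: data frame with `chrom`, `nick_pos` (or
#'   `start`), `strand`, or a BED path.
#' @param tol Matching tolerance in bp (default 10).
#' @return List: `recall`, `precision` (`NA` when there are no calls),
#'   `hits` (per-nick data frame with matched call index and distance),
#'   `n_calls`, `n_truth`.
#' @export
score_against_truth <- function(calls, truth, tol = 10L) {
  if (is.character(calls)) calls <- read_calls_bed(calls)
  if (is.character(truth)) truth <- read_calls_bed(truth)
  tpos <- truth$nick_pos %||% truth$start
  tchrom <- as.character(truth$chrom)
  n_truth <- length(tpos)

  uniq <- calls
  rownames(uniq) <- NULL
  n_calls <- nrow(uniq)

  hits <- data.frame(chrom = tchrom, nick_pos = as.integer(tpos),
                     call = NA_integer_, distance = NA_integer_,
                     stringsAsFactors = FALSE)
  if (n_calls == 0L) {
    return(list(recall = if (n_truth) 0 else NA_real_,
                precision = NA_real_, hits = hits,
                n_calls = 0L, n_truth = n_truth))
  }

  # all pairs within tol
  pairs <- list(); np <- 0L
  for (ti in seq_len(n_truth)) {
    same <- which(uniq$chrom == tchrom[ti])
    if (!length(same)) next
    d <- call_point_distance(uniq$start[same], uniq$end[same], tpos[ti])
    ok <- which(d <= tol)
    if (length(ok)) {
      np <- np + 1L
      pairs[[np]] <- data.frame(truth = ti, call = same[ok],
                                distance = d[ok])
    }
  }
  call_hit <- rep(FALSE, n_calls)
  if (np) {
    pairs <- do.call(rbind, pairs)
    call_hit[unique(pairs$call)] <- TRUE
    # greedy 1-to-1 matching for the hit table
    pairs <- pairs[order(pairs$distance, pairs$truth, pairs$call), ,
                   drop = FALSE]
    used_t <- logical(n_truth); used_c <- logical(n_calls)
    for (r in seq_len(nrow(pairs))) {
      ti <- pairs$truth[r]; ci <- pairs$call[r]
      if (used_t[ti] || used_c[ci]) next
      used_t[ti] <- TRUE; used_c[ci] <- TRUE
      hits$call[ti] <- ci; hits$distance[ti] <- pairs$distance[r]
    }
  }
  truth_hit <- vapply(seq_len(n_truth), function(ti) {
    if (np) any(pairs$truth == ti) else FALSE
  }, logical(1))

  list(recall = if (n_truth) mean(truth_hit) else NA_real_,
       precision = mean(call_hit), hits = hits,
       n_calls = n_calls, n_truth = n_truth)
}
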