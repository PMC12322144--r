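# Genomic-region model: a priority partition of the genome into promoter
# bins, UTRs, exons, introns, downstream and distal intergenic space, plus
# assignment of SSB calls to regions with gene-relative strandedness.

REGION_CATEGORIES <- c("promoter_0_1kb", "promoter_1_2kb", "promoter_2_3kb",
                       "five_prime_utr", "three_prime_utr", "exon",
                       "first_intron", "other_intron", "downstream_3kb",
                       "distal_intergenic")

#' Build a genomic-region model from a gene annotation
#'
#' Imports a GTF/GFF3 annotation, keeps one representative (longest)
#' transcript per gene, and materialises region categories with the
#' priority order promoter (0-1, 1-2, 2-3 kb upstream of the TSS) >
#' 5' UTR > 3' UTR > exon > first intron > other introns > downstream
#' (up to 3 kb past the gene end) > distal intergenic. The categories,
#' masked by priority, partition the genome.
#'
#' @param annotation Path to a GTF/GFF3 file or a
#'   [GenomicRanges::GRanges] as returned by [rtracklayer::import()].
#' @param ref Reference genome or named vector of chromosome lengths.
#' @return A list of class `region_model`: `regions` (GRanges with
#'   `category`, `priority`, `gene_id`, `gene_strand`), `category_bp`
#'   (named partition sizes, bp), `genome_bp`, `ref_lengths`.
#' @export
build_region_model <- function(annotation, ref) {
  lens <- if (is.numeric(ref)) ref else ref_lengths(ref)
  anno <- if (is.character(annotation)) {
    rtracklayer::import(annotation)
  } else annotation
  if (!length(anno)) stop("annotation contains no records")
  type <- as.character(anno$type)
  if (!any(type %in% c("transcript", "mRNA", "exon"))) {
    stop("annotation has no transcript or exon records")
  }
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(anno))),
                 names(lens))
  if (length(bad)) {
    stop("annotation chromosomes absent from reference: ",
         paste(bad, collapse = ", "))
  }

  tx <- anno[type %in% c("transcript", "mRNA")]
  if (!length(tx)) {   # derive transcript spans from exons
    ex_all <- anno[type == "exon"]
    spl <- split(ex_all, as.character(ex_all$transcript_id))
    tx <- unlist(GenomicRanges::reduce(
      methods::as(range(spl), "GRangesList")))
    tx$transcript_id <- names(tx)
    gid <- vapply(spl, function(g) as.character(g$gene_id[1]), "")
    tx$gene_id <- gid[tx$transcript_id]
  }
  tx_gene <- as.character(tx$gene_id %||% tx$transcript_id)
  tx_gene[is.na(tx_gene)] <- as.character(tx$transcript_id)[is.na(tx_gene)]
  # longest transcript per gene (ties: first in file order)
  ord <- order(tx_gene, -GenomicRanges::width(tx))
  keep <- !duplicated(tx_gene[ord])
  tx <- tx[ord][keep]
  tx_gene <- tx_gene[ord][keep]
  tx_id <- as.character(tx$transcript_id)

  exons <- anno[type == "exon"]
  utr5 <- anno[type %in% c("five_prime_utr", "five_prime_UTR", "5UTR")]
  utr3 <- anno[type %in% c("three_prime_utr", "three_prime_UTR", "3UTR")]

  pieces <- list(); pk <- 0L
  add_piece <- function(gr, category, gene_id, gene_strand) {
    gr <- GenomicRanges::trim(gr)
    gr <- gr[GenomicRanges::width(gr) > 0L]
    if (!length(gr)) return()
    pk <<- pk + 1L
    pieces[[pk]] <<- GenomicRanges::GRanges(
      GenomicRanges::seqnames(gr), GenomicRanges::ranges(gr), "*",
      category = category,
      priority = match(category, REGION_CATEGORIES),
      gene_id = gene_id, gene_strand = gene_strand)
  }

  for (i in seq_along(tx)) {
    t1 <- tx[i]
    gid <- tx_gene[i]
    str <- as.character(GenomicRanges::strand(t1))
    if (!str %in% c("+", "-")) str <- "+"
    chrlen <- lens[[as.character(GenomicRanges::seqnames(t1))]]
    tss <- if (str == "+") GenomicRanges::start(t1) else
      GenomicRanges::end(t1)
    gend <- if (str == "+") GenomicRanges::end(t1) else
      GenomicRanges::start(t1)

    clamp <- function(lo, hi) {
      lo <- max(lo, 1L); hi <- min(hi, chrlen)
      if (hi < lo) return(NULL)
      GenomicRanges::GRanges(GenomicRanges::seqnames(t1),
                             IRanges::IRanges(lo, hi))
    }
    for (b in 1:3) {
      pr <- if (str == "+") clamp(tss - 1000L * b, tss - 1000L * (b - 1L) - 1L)
            else clamp(tss + 1000L * (b - 1L) + 1L, tss + 1000L * b)
      if (!is.null(pr)) {
        add_piece(pr, REGION_CATEGORIES[b], gid, str)
      }
    }
    tx_utr5 <- utr5[as.character(utr5$transcript_id) == tx_id[i]]
    tx_utr3 <- utr3[as.character(utr3$transcript_id) == tx_id[i]]
    if (length(tx_utr5)) add_piece(tx_utr5, "five_prime_utr", gid, str)
    if (length(tx_utr3)) add_piece(tx_utr3, "three_prime_utr", gid, str)

    tx_ex <- exons[as.character(exons$transcript_id) == tx_id[i]]
    if (!length(tx_ex)) tx_ex <- t1
    add_piece(tx_ex, "exon", gid, str)

    introns <- GenomicRanges::setdiff(
      GenomicRanges::GRanges(GenomicRanges::seqnames(t1),
                             GenomicRanges::ranges(t1)),
      GenomicRanges::GRanges(GenomicRanges::seqnames(tx_ex),
                             GenomicRanges::ranges(tx_ex)))
    if (length(introns)) {
      introns <- GenomicRanges::sort(introns)
      first_idx <- if (str == "+") 1L else length(introns)
      add_piece(introns[first_idx], "first_intron", gid, str)
      if (length(introns) > 1L) {
        add_piece(introns[-first_idx], "other_intron", gid, str)
      }
    }
    dn <- if (str == "+") clamp(gend + 1L, gend + 3000L)
          else clamp(gend - 3000L, gend - 1L)
    if (!is.null(dn)) add_piece(dn, "downstream_3kb", gid, str)
  }
  regions <- if (pk) suppressWarnings(do.call(c, pieces)) else
    GenomicRanges::GRanges()

  genome_bp <- sum(as.numeric(lens))
  category_bp <- stats::setNames(numeric(length(REGION_CATEGORIES)),
                                 REGION_CATEGORIES)
  covered <- GenomicRanges::GRanges()
  for (cat in setdiff(REGION_CATEGORIES, "distal_intergenic")) {
    cr <- GenomicRanges::reduce(regions[regions$category == cat])
    masked <- GenomicRanges::setdiff(cr, covered)
    category_bp[[cat]] <- sum(as.numeric(GenomicRanges::width(masked)))
    covered <- GenomicRanges::reduce(c(covered, masked))
  }
  category_bp[["distal_intergenic"]] <-
    genome_bp - sum(as.numeric(GenomicRanges::width(covered)))

  structure(list(regions = regions, category_bp = category_bp,
                 genome_bp = genome_bp, ref_lengths = lens),
            class = "region_model")
}

#' @export
print.region_model <- function(x, ...) {
  cat("Region model over", format(x$genome_bp, big.mark = ","), "bp\n")
  print(round(x$category_bp))
  invisible(x)
}

#' Assign SSB calls to genomic regions
#'
#' Each unique call is assigned the category of its interval midpoint
#' (highest-priority overlapping region). The call's strand is re-expressed
#' relative to the assigned gene: forward when it matches the gene strand;
#' distal intergenic calls keep their absolute strand. Frequencies are
#' calls per million bp of each category's partition size; when
#' `aligned_nt` is supplied the denominators are additionally scaled by
#' the mean genome coverage `aligned_nt / genome_bp`.
#'
#' @param calls Call data frame or BED path.
#' @param model A [build_region_model()] result.
#' @param aligned_nt Optional usable aligned nucleotides, for
#'   coverage-weighted frequencies.
#' @return List of class `region_annotation`: `assignments` (per-call
#'   category, gene and relative strand), `table` (category x relative
#'   strand counts and frequencies).
#' @export
annotate_calls <- function(calls, model, aligned_nt = NULL) {
  stopifnot(inherits(model, "region_model"))
  if (is.character(calls)) calls <- read_calls_bed(calls)
  key <- paste(calls$chrom, calls$start, calls$end, calls$strand)
  calls <- calls[!duplicated(key), , drop = FALSE]
  rownames(calls) <- NULL
  n <- nrow(calls)

  category <- rep("distal_intergenic", n)
  gene_id <- rep(NA_character_, n)
  gene_strand <- rep(NA_character_, n)
  if (n > 0L && length(model$regions)) {
    mid <- (calls$start + calls$end) %/% 2L
    pts <- intervals_to_granges(calls$chrom, mid, mid + 1L)
    ov <- GenomicRanges::findOverlaps(pts, model$regions,
                                      ignore.strand = TRUE)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      prio <- model$regions$priority[sh]
      ord <- order(qh, prio, sh)
      qh <- qh[ord]; sh <- sh[ord]
      first <- !duplicated(qh)
      category[qh[first]] <- model$regions$category[sh[first]]
      gene_id[qh[first]] <- model$regions$gene_id[sh[first]]
      gene_strand[qh[first]] <- model$regions$gene_strand[sh[first]]
    }
  }
  relative_strand <- ifelse(
    is.na(gene_strand) | category == "distal_intergenic",
    ifelse(calls$strand == "-", "reverse", "forward"),
    ifelse(calls$strand == gene_strand, "forward", "reverse"))

  assignments <- data.frame(
    chrom = calls$chrom, start = calls$start, end = calls$end,
    strand = calls$strand, category = category, gene_id = gene_id,
    gene_strand = gene_strand, relative_strand = relative_strand,
    stringsAsFactors = FALSE)

  denom_scale <- if (is.null(aligned_nt)) 1 else aligned_nt / model$genome_bp
  tab <- expand.grid(category = REGION_CATEGORIES,
                     relative_strand = c("forward", "reverse"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$n_ssbs <- mapply(function(cat, rs) {
    sum(category == cat & relative_strand == rs)
  }, tab$category, tab$relative_strand)
  tab$region_bp <- model$category_bp[tab$category] * denom_scale
  tab$ssb_per_million_bp <- ifelse(tab$region_bp > 0,
                                   tab$n_ssbs / tab$region_bp * 1e6, NA)
  structure(list(assignments = assignments, table = tab),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat("Region annotation of", nrow(x$assignments), "unique calls\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
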