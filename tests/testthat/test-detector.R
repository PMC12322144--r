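# The worked example used throughout: positions 0-14 of the reference are
# GACATGACAGTACAT (A at 1, 3, 6, 8, 11, 13).
worked_ref <- toy_ref(c(chr1 = "GACATGACAGTACAT"))

test_that("scan_events finds the unique maximal anchored A-run", {
  # A at 6, 8, 11, 13 all substituted by G; A at 1, 3 intact
  rec <- make_record("15M", "GACATGGCGGTGCGT")
  obs <- extract_mutations(rec, worked_ref)$observations
  ev <- scan_events(obs, rec, worked_ref, "A")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$mut_pos[[1]], c(6L, 8L, 11L, 13L))
  expect_equal(ev$n_sub, 4L)
  expect_equal(ev$n_del, 0L)
  expect_equal(ev$anchor_pos, 3L)
  expect_equal(ev$strand, "+")
  # agrees with the brute-force oracle
  orc <- oracle_scan(rec, worked_ref, "A")
  expect_equal(ev[, c("anchor_pos", "first_mut_pos", "last_mut_pos",
                      "n_mut_targets", "n_sub", "n_del")],
               orc, ignore_attr = TRUE)
})

test_that("an intact target base splits the run and moves the anchor", {
  # A at 6 intact: longest anchored run is {8, 11, 13} with anchor 6
  rec <- make_record("15M", "GACATGACGGTGCGT")
  obs <- extract_mutations(rec, worked_ref)$observations
  ev <- scan_events(obs, rec, worked_ref, "A")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$mut_pos[[1]], c(8L, 11L, 13L))
  expect_equal(ev$anchor_pos, 6L)
  orc <- oracle_scan(rec, worked_ref, "A")
  expect_equal(nrow(orc), 1L)
  expect_equal(orc$anchor_pos, 6L)
})

test_that("identical reads produce no events", {
  rec <- make_record("15M", "GACATGACAGTACAT")
  obs <- extract_mutations(rec, worked_ref)$observations
  expect_equal(nrow(scan_events(obs, rec, worked_ref, "A")), 0L)
  expect_equal(nrow(scan_events(obs, rec, worked_ref, "T")), 0L)
})

test_that("runs touching the alignment edge on the anchor side are dropped", {
  # read starts at the first mutated A: no upstream intact A in alignment
  ref <- toy_ref(c(chr1 = "AAGAGAGACA"))
  rec <- make_record("8M", "GGGGGGGA", start = 2L)  # A at 2,4,6 mutated? build
  # ref[2..9] = GAGAGACA; A at ref pos 3,5,8 within span; mutate 3 and 5
  rec <- make_record("8M", "GGGGGACA", start = 2L)
  obs <- extract_mutations(rec, ref)$observations
  ev <- scan_events(obs, rec, ref, "A")
  # run {3,5} starts at the first target position in the span -> unanchored
  expect_equal(nrow(ev), 0L)
  expect_null(oracle_scan(rec, ref, "A"))
})

test_that("deleted target bases count as mutated", {
  # delete A at 6 and substitute A at 8: one run {6,8} anchored at 3
  rec <- make_record("6M1D8M", "GACATGCGGTACAT")
  obs <- extract_mutations(rec, worked_ref)$observations
  ev <- scan_events(obs, rec, worked_ref, "A")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$mut_pos[[1]], c(6L, 8L))
  expect_equal(ev$n_sub, 1L)
  expect_equal(ev$n_del, 1L)
  orc <- oracle_scan(rec, worked_ref, "A")
  expect_equal(orc$n_del, 1L)
})

test_that("scan_events equals the brute-force oracle on random alignments", {
  for (seed in 1:60) {
    toy <- random_toy_record(seed)
    obs <- extract_mutations(toy$record, toy$ref)$observations
    for (tb in c("A", "T", "C", "G")) {
      ev <- scan_events(obs, toy$record, toy$ref, tb)
      orc <- oracle_scan(toy$record, toy$ref, tb)
      if (is.null(orc)) {
        expect_equal(nrow(ev), 0L)
      } else {
        expect_equal(nrow(ev), nrow(orc),
                     info = paste("seed", seed, "base", tb))
        expect_equal(
          ev[order(ev$first_mut_pos),
             c("anchor_pos", "first_mut_pos", "last_mut_pos",
               "n_mut_targets", "n_sub", "n_del")],
          orc, ignore_attr = TRUE)
      }
    }
  }
})

test_that("filters pass and fail at the documented thresholds", {
  nano <- technology_profile("nanopore")
  pacbio <- technology_profile("pacbio-hifi")

  # 5 mutated A (4 sub, 1 del), mean qual 30 -> passes nanopore
  ok <- apply_filters(make_event(n_mut = 5, n_sub = 4, mean_qual = 30), nano)
  expect_true(ok$pass)
  expect_true(is.na(ok$fail_reason))

  # 4 mutated A fails the PacBio minimum of five
  few <- apply_filters(make_event(n_mut = 4, n_sub = 4), pacbio)
  expect_false(few$pass)
  expect_equal(few$fail_reason, "min_mutated_targets")

  # all-deletion event fails the nanopore substitution minimum
  alldel <- apply_filters(make_event(n_mut = 5, n_sub = 0), nano)
  expect_false(alldel$pass)
  expect_equal(alldel$fail_reason, "min_substitutions")

  # quality boundary: mean 10 passes, just below fails
  q10 <- apply_filters(make_event(n_mut = 5, n_sub = 3, mean_qual = 10), nano)
  expect_true(q10$pass)
  q9 <- apply_filters(make_event(n_mut = 5, n_sub = 3, mean_qual = 9.9), nano)
  expect_false(q9$pass)
  expect_equal(q9$fail_reason, "mean_sub_quality")

  # nanopore substitution boundary: 3 of 5 passes, 2 of 5 fails
  s3 <- apply_filters(make_event(n_mut = 5, n_sub = 3, mean_qual = 30), nano)
  expect_true(s3$pass)
  s2 <- apply_filters(make_event(n_mut = 5, n_sub = 2, mean_qual = 30), nano)
  expect_false(s2$pass)
  expect_equal(s2$fail_reason, "min_substitutions")

  # per-platform event-size minima: 3 for illumina-tk6, 4 for illumina-hacat
  tk6 <- technology_profile("illumina-tk6")
  hacat <- technology_profile("illumina-hacat")
  expect_true(apply_filters(make_event(n_mut = 3, n_sub = 3), tk6)$pass)
  expect_false(apply_filters(make_event(n_mut = 2, n_sub = 2), tk6)$pass)
  expect_true(apply_filters(make_event(n_mut = 4, n_sub = 4), hacat)$pass)
  expect_false(apply_filters(make_event(n_mut = 3, n_sub = 3), hacat)$pass)
})

test_that("unavailable qualities fail closed unless the profile opts out", {
  ev <- make_event(n_mut = 5, n_sub = 4)
  ev$mean_sub_quality <- NA_real_
  strict <- apply_filters(ev, technology_profile("pacbio-hifi"))
  expect_false(strict$pass)
  expect_equal(strict$fail_reason, "mean_sub_quality")
  lax <- apply_filters(ev, technology_profile("custom",
                                              min_mutated_targets = 5,
                                              require_quality = FALSE))
  expect_true(lax$pass)
})

test_that("call intervals follow the anchor/first-mutated rule", {
  # A-event: anchor 3, first mutated 6 -> [4, 7) on +
  a <- call_ssb(make_event(anchor = 3, first = 6, last = 13, n_mut = 4,
                           n_sub = 4))
  expect_equal(a$start, 4L)
  expect_equal(a$end, 7L)
  expect_equal(a$strand, "+")

  # T-event: last mutated 120, downstream intact T at 125 -> [120, 125) on -
  t <- call_ssb(make_event(target_base = "T", anchor = 125, first = 110,
                           last = 120, n_mut = 3, n_sub = 3))
  expect_equal(t$start, 120L)
  expect_equal(t$end, 125L)
  expect_equal(t$strand, "-")

  # adjacent anchor: anchor 10, first 11 -> single-base localization [11, 12)
  tight <- call_ssb(make_event(anchor = 10, first = 11, last = 15,
                               n_mut = 3, n_sub = 3))
  expect_equal(tight$start, 11L)
  expect_equal(tight$end, 12L)
})

test_that("deduplication keeps one call per position and is idempotent", {
  base <- call_ssb(make_event())
  c1 <- base; c1$read_name <- "b"; c1$mapq <- 50L
  c2 <- base; c2$read_name <- "a"; c2$mapq <- 60L
  c3 <- base; c3$read_name <- "c"; c3$mapq <- 60L
  calls <- rbind(c1, c2, c3)
  dd <- dedupe_calls(calls)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$read_name, "a")   # highest mapq, then smallest name
  expect_equal(dedupe_calls(dd), dd)

  # strand is part of the key
  c4 <- base; c4$strand <- "-"
  expect_equal(nrow(dedupe_calls(rbind(base, c4))), 2L)
})

test_that("detect_breaks is deterministic and clean reads yield no calls", {
  set.seed(21)
  ref <- make_reference(20000, seed = 21)
  sim <- simulate_reads(ref, place_nicks(ref, sites = data.frame(
    chrom = character(0), nick_pos = integer(0), strand = character(0))),
    err = seq_error_model("error-free"), coverage = 5,
    read_length = 500, seed = 9,
    out_prefix = withr::local_tempfile())
  res <- detect_breaks(sim$paths$sam, ref,
                       technology_profile("custom",
                                          min_mutated_targets = 1))
  expect_equal(nrow(res$calls), 0L)

  # determinism: nicked library detected twice gives byte-identical BED
  nicks <- place_nicks(ref, rate = 5e-4, seed = 4)
  sim2 <- simulate_reads(ref, nicks, err = seq_error_model("pacbio-hifi"),
                         coverage = 10, read_length = 800, seed = 10,
                         out_prefix = withr::local_tempfile())
  bed1 <- withr::local_tempfile(fileext = ".bed")
  bed2 <- withr::local_tempfile(fileext = ".bed")
  detect_breaks(sim2$paths$sam, ref, "pacbio-hifi", out_bed = bed1)
  detect_breaks(sim2$paths$sam, ref, "pacbio-hifi", out_bed = bed2)
  expect_identical(readLines(bed1), readLines(bed2))
  expect_gt(length(readLines(bed1)), 0L)
})

test_that("raising the event-size threshold never increases calls", {
  set.seed(31)
  ref <- make_reference(30000, seed = 31)
  nicks <- place_nicks(ref, rate = 1e-3, seed = 5)
  sim <- simulate_reads(ref, nicks, err = seq_error_model("nanopore"),
                        coverage = 8, read_length = 600, seed = 11,
                        out_prefix = withr::local_tempfile())
  aln <- read_alignments(sim$paths$sam)
  n_calls <- vapply(1:8, function(m) {
    nrow(detect_breaks(aln, ref,
                       technology_profile("custom", min_mutated_targets = m,
                                          min_substitutions = 1))$calls)
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))

  # lowering the error-rate cap never increases usable reads
  n_usable <- vapply(c(0.10, 0.05, 0.02, 0.01), function(e) {
    nrow(filter_usable_alignments(aln, ref, e))
  }, numeric(1))
  expect_true(all(diff(n_usable) <= 0))
})

test_that("strand symmetry: A-calls mirror to T-calls on the reverse genome", {
  for (seed in 101:112) {
    toy <- random_toy_record(seed, p_sub = 0.3, p_del = 0.08, p_ins = 0)
    L <- 200L
    refseq <- as.character(toy$ref[[1]])
    rc_ref <- toy_ref(c(chr1 = revcomp(refseq)))
    rec <- as.list(toy$record)
    # mirror the record: reverse-complement read, flip coordinates and CIGAR
    ops <- regmatches(rec$cigar, gregexpr("\\d+[MIDNSHP=X]", rec$cigar))[[1]]
    span <- sum(as.integer(sub("[MIDNSHP=X]", "", ops))[
      grepl("[MDN=X]", ops)])
    mirror <- make_record(paste(rev(ops), collapse = ""),
                          revcomp(rec$seq), start = L - rec$start - span,
                          qname = rec$qname)
    obs_f <- extract_mutations(toy$record, toy$ref)$observations
    obs_r <- extract_mutations(mirror, rc_ref)$observations
    ev_a <- scan_events(obs_f, toy$record, toy$ref, "A")
    ev_t <- scan_events(obs_r, mirror, rc_ref, "T")
    calls_a <- call_ssb(ev_a)
    calls_t <- call_ssb(ev_t)
    expect_equal(nrow(calls_a), nrow(calls_t), info = paste("seed", seed))
    if (nrow(calls_a)) {
      mirrored <- data.frame(start = L - calls_t$end,
                             end = L - calls_t$start)
      expect_setequal(paste(calls_a$start, calls_a$end),
                      paste(mirrored$start, mirrored$end))
    }
  }
})

test_that("detected events are sound against the raw alignment", {
  set.seed(77)
  ref <- make_reference(40000, seed = 77)
  nicks <- place_nicks(ref, rate = 8e-4, seed = 6)
  sim <- simulate_reads(ref, nicks, err = seq_error_model("pacbio-hifi"),
                        coverage = 8, read_length = 900, seed = 12,
                        out_prefix = withr::local_tempfile())
  res <- detect_breaks(sim$paths$sam, ref, "pacbio-hifi")
  ev <- res$events[res$events$pass, ]
  aln <- read_alignments(sim$paths$sam)
  refseq <- as.character(ref[[1]])
  refchars <- strsplit(refseq, "", fixed = TRUE)[[1]]
  for (i in seq_len(min(nrow(ev), 40))) {
    rec <- aln[aln$qname == ev$read_name[i], ][1, ]
    obs <- replay_alignment(rec, refseq)
    run <- ev$mut_pos[[i]]
    # every target base inside the run is substituted or deleted
    expect_true(all(obs[run + 1L] != refchars[run + 1L]))
    # the anchor base is intact
    expect_equal(obs[ev$anchor_pos[i] + 1L], refchars[ev$anchor_pos[i] + 1L])
  }
})

test_that("-dCTP mode scans C and G signatures", {
  ref <- toy_ref(c(chr1 = "GTCATGCCAGTCCAG"))  # C at 2,6,7,11,12
  rec <- make_record("15M", "GTCATGTTAGTTTAG")  # C at 6,7,11,12 -> T
  obs <- extract_mutations(rec, ref)$observations
  ev <- scan_events(obs, rec, ref, "C")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$anchor_pos, 2L)
  expect_equal(ev$strand, "+")
  res_calls <- call_ssb(ev)
  expect_equal(res_calls$start, 3L)
  expect_equal(res_calls$end, 7L)
})

test_that("detect_breaks writes a subset BAM of event-bearing reads", {
  set.seed(88)
  ref <- make_reference(30000, seed = 88)
  nicks <- place_nicks(ref, rate = 1e-3, seed = 7)
  sim <- simulate_reads(ref, nicks, err = seq_error_model("pacbio-hifi"),
                        coverage = 6, read_length = 800, seed = 13,
                        out_prefix = withr::local_tempfile())
  fa <- withr::local_tempfile(fileext = ".fa")
  write_reference(ref, fa)
  out_bam <- withr::local_tempfile(fileext = ".bam")
  res <- detect_breaks(sim$paths$sam, ref, "pacbio-hifi",
                       out_bam = out_bam)
  expect_true(file.exists(out_bam))
  back <- read_alignments(out_bam)
  expect_setequal(unique(back$qname), unique(res$calls$read_name))
})
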