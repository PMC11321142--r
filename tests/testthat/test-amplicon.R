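# amplicon caller: loading, boundary filtering, pattern extraction, reporting

test_that("pairs load grouped by locus with orphan and unknown-ref counters", {
  refA <- make_reference(400, 0.5, seed = 1, id = "locA")
  refB <- make_reference(400, 0.5, seed = 2, id = "locB")
  locA <- locus_spec("locA", refA, c(85, 115))
  locB <- locus_spec("locB", refB, c(85, 115))
  recs <- c(
    unlist(lapply(1:10, function(i) c(
      sam_rec(paste0("a", i), 99, "locA", 1, "150M", 251),
      sam_rec(paste0("a", i), 147, "locA", 251, "150M", 1)))),
    unlist(lapply(1:4, function(i) c(
      sam_rec(paste0("b", i), 99, "locB", 1, "150M", 251),
      sam_rec(paste0("b", i), 147, "locB", 251, "150M", 1)))),
    sam_rec("orphan1", 99, "locA", 1, "150M", 251),
    sam_rec("u1", 99, "locC", 1, "150M", 251)
  )
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               "@SQ\tSN:locA\tLN:400", "@SQ\tSN:locB\tLN:400",
               "@SQ\tSN:locC\tLN:400", recs), sam)
  got <- load_alignments(sam, list(locA, locB))
  expect_equal(nrow(got$locA), 10L)
  expect_equal(nrow(got$locB), 4L)
  cnt <- attr(got, "counters")
  expect_equal(unname(cnt["orphan"]), 1L)
  expect_equal(unname(cnt["unknown_ref"]), 1L)
})

test_that("modal starts: majority, tie toward the smaller coordinate, n = 1", {
  mk <- function(s1, s2, k) data.frame(
    pair_id = paste0("p", seq_len(k)), start1 = rep(s1, k),
    start2 = rep(s2, k), cigar1 = "150M", cigar2 = "150M")
  expect_equal(modal_starts(rbind(mk(100, 250, 10), mk(101, 250, 2))),
               c(100L, 250L))
  expect_equal(modal_starts(rbind(mk(100, 250, 5), mk(99, 250, 5))),
               c(99L, 250L))
  expect_equal(modal_starts(mk(7, 300, 1)), c(7L, 300L))
  expect_error(modal_starts(mk(1, 2, 1)[0, ]), "no read pairs")
})

test_that("boundary filtering is exact and orientation-agnostic", {
  pairs <- data.frame(
    pair_id = paste0("p", 1:12),
    start1 = c(rep(0L, 10), 3L, 0L),
    start2 = c(rep(250L, 10), 250L, 247L),
    cigar1 = "150M", cigar2 = "150M", stringsAsFactors = FALSE)
  expect_equal(nrow(filter_usable(pairs, c(0L, 250L))), 10L)
  # flipped boundary order is accepted
  expect_equal(nrow(filter_usable(pairs, c(250L, 0L))), 10L)
  # identity when everything already sits on the boundaries
  expect_equal(nrow(filter_usable(pairs[1:10, ], c(0L, 250L))), 10L)
  # a deletion upstream of a mate's start shifts it and excludes the pair
  shifted <- data.frame(pair_id = "s", start1 = 0L, start2 = 253L,
                        cigar1 = "150M", cigar2 = "150M")
  expect_equal(nrow(filter_usable(shifted, c(0L, 250L))), 0L)
})

test_that("pattern extraction walks CIGARs to reference coordinates", {
  ref <- make_reference(400, 0.5, seed = 3, id = "L")
  loc <- locus_spec("L", ref, c(60, 90))
  pair <- function(c1, s1 = 0L) data.frame(
    pair_id = "p", start1 = s1, start2 = 250L, cigar1 = c1, cigar2 = "150M")
  expect_identical(extract_pattern(pair("150M"), loc)$key, "")
  # 72M7D78M starting at 0: deletion at reference 72 (1-based 73)
  expect_identical(extract_pattern(pair("72M7D78M"), loc)$key, "D:73:7")
  expect_identical(extract_pattern(pair("75M3I75M"), loc)$key, "I:76:3")
  # an indel outside the window is an alignment artifact, not a mutation
  expect_identical(extract_pattern(pair("10M2D140M"), loc)$key, "")
  # deletions-only mode ignores insertions
  expect_identical(extract_pattern(pair("75M3I75M"), loc,
                                   deletions_only = TRUE)$key, "")
  expect_error(extract_pattern(pair("XYZ"), loc), "malformed CIGAR")
})

test_that("discordant overlapping mates are unioned and flagged", {
  ref <- make_reference(260, 0.5, seed = 4, id = "L")
  loc <- locus_spec("L", ref, c(120, 140))
  # both mates cover the window: mate1 reports a deletion, mate2 does not
  pr <- data.frame(pair_id = "p", start1 = 0L, start2 = 110L,
                   cigar1 = "125M5D25M", cigar2 = "150M")
  pat <- extract_pattern(pr, loc)
  expect_true(pat$discordant)
  expect_identical(pat$key, "D:126:5")
  # agreeing mates are not discordant
  pr2 <- data.frame(pair_id = "p", start1 = 0L, start2 = 110L,
                    cigar1 = "125M5D25M", cigar2 = "15M5D135M")
  pat2 <- extract_pattern(pr2, loc)
  expect_false(pat2$discordant)
  expect_identical(pat2$key, "D:126:5")
})

test_that("pattern extraction matches a GenomicAlignments-based oracle", {
  ref <- make_reference(400, 0.5, seed = 5, id = "L")
  loc <- locus_spec("L", ref, c(0, 400))  # whole-reference window
  set.seed(606)
  oracle_events <- function(start0, cigar) {
    d <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigar, ops = "D", pos = start0 + 1L)[[1]]
    i <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigar, ops = "I", pos = start0 + 1L)[[1]]
    iq <- GenomicAlignments::cigarRangesAlongQuerySpace(cigar, ops = "I")[[1]]
    ev <- rbind(
      if (length(d)) data.frame(op = "D", ref_pos = BiocGenerics::start(d) - 1L,
                                len = BiocGenerics::width(d)),
      if (length(i)) data.frame(op = "I", ref_pos = BiocGenerics::start(i) - 1L,
                                len = BiocGenerics::width(iq))
    )
    if (is.null(ev)) return(ev)
    ev[order(ev$ref_pos, ev$op), , drop = FALSE]
  }
  for (rep in 1:300) {
    n_ev <- sample(0:2, 1)
    lens <- sample(1:8, n_ev, replace = TRUE)
    ops <- sample(c("D", "I"), n_ev, replace = TRUE)
    pos <- sort(sample(20:120, n_ev))
    if (n_ev == 2 && pos[2] - pos[1] < lens[1] + 2) next
    # build the CIGAR by hand
    cig <- ""
    cur <- 0L
    read_used <- 0L
    for (j in seq_len(n_ev)) {
      m <- pos[j] - cur
      cig <- paste0(cig, m, "M")
      read_used <- read_used + m
      cig <- paste0(cig, lens[j], ops[j])
      if (ops[j] == "D") cur <- pos[j] + lens[j]
      else { cur <- pos[j]; read_used <- read_used + lens[j] }
    }
    cig <- paste0(cig, 150L - read_used, "M")
    pr <- data.frame(pair_id = "p", start1 = 0L, start2 = 250L,
                     cigar1 = cig, cigar2 = "150M")
    got <- extract_pattern(pr, loc)$events
    want <- oracle_events(0L, cig)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$op, want$op)
      expect_equal(got$ref_pos, want$ref_pos)
      expect_equal(got$len, want$len)
    }
  }
})

test_that("locus calling recovers simulated ground truth", {
  ref <- make_reference(400, 0.45, seed = 11, id = "locusA")
  loc <- locus_spec("locusA", ref, c(85, 115))
  del7 <- indel_pattern("D", 97, 7)
  sam <- tempfile(fileext = ".sam")

  sim <- simulate_edited_reads(loc, list(del7), 0.7, wt_frequency = 0.3,
                               n_pairs = 200, seed = 5, sam_path = sam)
  cl <- call_locus("s1", load_alignments(sam, loc)$locusA, loc)
  expect_equal(cl$usable_pairs, 200L)
  expect_equal(cl$pct_mutant, 70)
  expect_equal(unname(cl$pattern_counts["D:98:7"]), 140L)

  # all wild type
  simulate_edited_reads(loc, wt_frequency = 1, n_pairs = 50, seed = 6,
                        sam_path = sam)
  cl2 <- call_locus("s2", load_alignments(sam, loc)$locusA, loc)
  expect_equal(cl2$pct_wt, 100)

  # three patterns at 20/30/50 with no wild type
  pats <- list(indel_pattern("D", 95, 4), indel_pattern("D", 100, 12),
               indel_pattern("I", 103, 1))
  simulate_edited_reads(loc, pats, c(0.2, 0.3, 0.5), wt_frequency = 0,
                        n_pairs = 100, seed = 7, sam_path = sam)
  cl3 <- call_locus("s3", load_alignments(sam, loc)$locusA, loc)
  expect_equal(cl3$pct_mutant, 100)
  expect_setequal(unname(cl3$pattern_counts), c(20L, 30L, 50L))
})

test_that("report accounting identities always hold", {
  ref <- make_reference(400, 0.45, seed = 21, id = "locusA")
  loc <- locus_spec("locusA", ref, c(85, 115))
  sam <- tempfile(fileext = ".sam")
  for (f in c(0, 0.4, 1)) {
    simulate_edited_reads(loc, list(indel_pattern("D", 97, 5)), f,
                          wt_frequency = 1 - f, n_pairs = 60,
                          off_boundary_fraction = 0.1, seed = 30 + 10 * f,
                          sam_path = sam)
    cl <- call_locus("s", load_alignments(sam, loc)$locusA, loc)
    expect_lte(cl$usable_pairs, cl$total_pairs)
    expect_lte(cl$wt_pairs, cl$usable_pairs)
    expect_equal(sum(cl$pattern_counts) + cl$wt_pairs, cl$usable_pairs)
    expect_equal(cl$pct_wt + cl$pct_mutant, 100)
  }
})

test_that("substitution errors never register as mutations", {
  ref <- make_reference(400, 0.45, seed = 31, id = "locusA")
  loc <- locus_spec("locusA", ref, c(85, 115))
  sam <- tempfile(fileext = ".sam")
  simulate_edited_reads(loc, wt_frequency = 1, n_pairs = 200,
                        substitution_error_rate = 0.005, seed = 8,
                        sam_path = sam)
  cl <- call_locus("s", load_alignments(sam, loc)$locusA, loc)
  expect_identical(cl$pct_mutant, 0)
})

test_that("zero usable pairs yields a flagged report, not an error", {
  ref <- make_reference(400, 0.45, seed = 41, id = "locusA")
  loc <- locus_spec("locusA", ref, c(85, 115), expected_starts = c(5L, 255L))
  pairs <- data.frame(pair_id = "p1", start1 = 0L, start2 = 250L,
                      cigar1 = "150M", cigar2 = "150M")
  cl <- call_locus("s", pairs, loc)
  expect_true(cl$zero_usable)
  expect_true(is.na(cl$pct_wt))
  expect_true(is.na(cl$pct_mutant))
})

test_that("reports tabulate and write", {
  ref <- make_reference(400, 0.45, seed = 51, id = "locusA")
  loc <- locus_spec("locusA", ref, c(85, 115))
  sam <- tempfile(fileext = ".sam")
  simulate_edited_reads(loc, list(indel_pattern("D", 97, 7)), 0.5,
                        wt_frequency = 0.5, n_pairs = 40, seed = 9,
                        sam_path = sam)
  cl <- call_locus("s", load_alignments(sam, loc)$locusA, loc)
  rep <- call_report(cl)
  expect_equal(rep$pct_mutant, 50)
  spec <- pattern_spectrum(cl)
  expect_equal(spec$count, 20L)
  out <- tempfile(fileext = ".tsv")
  write_call_reports(list(cl), out, json_path = tempfile(fileext = ".json"))
  expect_true(file.exists(out))
})

test_that("Sanger classification flags window gaps but not substitutions", {
  ref <- make_reference(300, 0.5, seed = 61, id = "L")
  loc <- locus_spec("L", ref, c(140, 170))
  expect_false(sanger_classify(ref, loc)$mutated)
  # 5-bp deletion at the cut site
  q <- paste0(substr(ref, 1, 150), substr(ref, 156, 300))
  r <- sanger_classify(q, loc)
  expect_true(r$mutated)
  expect_identical(r$pattern$key, "D:151:5")
  # a single substitution does not flag mutation
  qs <- ref
  substr(qs, 155, 155) <- if (substr(ref, 155, 155) == "A") "G" else "A"
  expect_false(sanger_classify(qs, loc)$mutated)
  # insertion in the window flags
  qi <- paste0(substr(ref, 1, 150), "ACGTA", substr(ref, 151, 300))
  expect_true(sanger_classify(qi, loc)$mutated)
  # gaps far outside the window do not flag
  qo <- paste0(substr(ref, 1, 20), substr(ref, 27, 300))
  expect_false(sanger_classify(qo, loc)$mutated)
  expect_error(sanger_classify(strrep("A", 30), loc), "at least 50")
})
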