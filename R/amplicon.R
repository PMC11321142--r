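# amplicon-sequencing mutation calling
#
# Re-implements the deposited amplicon pipeline's logic: read pairs per locus,
# boundary filtering on the modal mate start positions, CIGAR walking to
# collect indel events inside a window around the cut site, and per-sample
# percent-wild-type reporting. Coordinates are 0-based half-open internally;
# SAM's 1-based starts are converted on input and report positions are
# emitted 1-based.

#' Define a target locus for amplicon calling
#'
#' @param locus_id Reference name as used in the SAM header.
#' @param reference A/C/G/T reference sequence of the amplicon/locus.
#' @param cut_window 0-based half-open `(start, end)` interval in which indel
#'   events count as mutations; typically cut site +/- 15 nt (see
#'   [cut_window_from_site()]). Alignment artefacts outside the window are
#'   ignored.
#' @param expected_starts `"auto"` (infer boundaries from the modal mate
#'   starts) or an integer pair of 0-based expected mate start positions.
#' @return Object of class `locus_spec`.
#' @export
locus_spec <- function(locus_id, reference, cut_window,
                       expected_starts = "auto") {
  reference <- toupper(reference)
  .assert_acgt(reference, "reference")
  cut_window <- as.integer(cut_window)
  if (length(cut_window) != 2L || cut_window[1] >= cut_window[2] ||
      cut_window[1] < 0L || cut_window[2] > nchar(reference)) {
    stop("cut_window must be a non-empty 0-based half-open interval within ",
         "the reference", call. = FALSE)
  }
  if (!identical(expected_starts, "auto")) {
    expected_starts <- as.integer(expected_starts)
    stopifnot(length(expected_starts) == 2L)
  }
  structure(list(locus_id = locus_id, reference = reference,
                 cut_window = cut_window, expected_starts = expected_starts),
            class = "locus_spec")
}

#' Default cut window around a scanned target site
#'
#' @param site One row from [scan_targets()].
#' @param spec The matching [nuclease_spec()].
#' @param flank Half-width of the window (default 15 nt).
#' @return Integer 0-based half-open interval `c(start, end)`.
#' @export
cut_window_from_site <- function(site, spec, flank = 15L) {
  cp <- cut_position(site, spec)
  c(max(0L, cp - as.integer(flank)), cp + as.integer(flank))
}

#' Load aligned read pairs per locus from a SAM file
#'
#' Reads a SAM file (via Rsamtools), drops unmapped, secondary and
#' supplementary records, assembles mates by query name and assigns each pair
#' to the locus whose id matches its reference name. Orphan reads (one usable
#' mate) and records on unknown references are dropped and counted.
#'
#' @param sam_path Path to a SAM file with a header.
#' @param loci List of [locus_spec()]s.
#' @return Named list (by locus id) of data frames `pair_id`, `start1`,
#'   `start2` (0-based leftmost positions), `cigar1`, `cigar2`; with a
#'   `counters` attribute (`orphan`, `unknown_ref`, `excluded_records`).
#' @export
load_alignments <- function(sam_path, loci) {
  if (inherits(loci, "locus_spec")) loci <- list(loci)
  ids <- vapply(loci, `[[`, character(1), "locus_id")
  bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "cigar"))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- r$flag
  keep <- !bitwAnd(flag, 0x4) & !bitwAnd(flag, 0x100) & !bitwAnd(flag, 0x800)
  excluded <- sum(!keep)
  df <- data.frame(qname = r$qname[keep], rname = as.character(r$rname)[keep],
                   pos = r$pos[keep], cigar = r$cigar[keep],
                   stringsAsFactors = FALSE)
  known <- df$rname %in% ids
  unknown_ref <- sum(!known)
  df <- df[known, , drop = FALSE]
  cnt <- table(df$qname)
  orphan <- sum(cnt != 2L)
  df <- df[df$qname %in% names(cnt)[cnt == 2L], , drop = FALSE]
  out <- setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    d <- df[df$rname == id, , drop = FALSE]
    if (nrow(d)) {
      d <- d[order(d$qname, d$pos), ]
      i1 <- seq(1L, nrow(d), by = 2L)
      # both mates must sit on the same reference
      same <- d$qname[i1] == d$qname[i1 + 1L]
      i1 <- i1[same]
      pairs <- data.frame(pair_id = d$qname[i1],
                          start1 = d$pos[i1] - 1L, start2 = d$pos[i1 + 1L] - 1L,
                          cigar1 = d$cigar[i1], cigar2 = d$cigar[i1 + 1L],
                          stringsAsFactors = FALSE)
    } else {
      pairs <- data.frame(pair_id = character(0), start1 = integer(0),
                          start2 = integer(0), cigar1 = character(0),
                          cigar2 = character(0), stringsAsFactors = FALSE)
    }
    rownames(pairs) <- NULL
    out[[id]] <- pairs
  }
  attr(out, "counters") <- c(orphan = orphan, unknown_ref = unknown_ref,
                             excluded_records = excluded)
  out
}

#' Modal mate start positions of a locus
#'
#' The amplicon boundaries are inferred as the modes of the lower and upper
#' mate start positions over all pairs; ties are broken toward the smaller
#' coordinate.
#'
#' @param pairs Pair data frame for one locus (see [load_alignments()]).
#' @return Integer pair `(boundary1, boundary2)`, 0-based.
#' @export
modal_starts <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("no read pairs: cannot infer modal starts", call. = FALSE)
  }
  lo <- pmin(pairs$start1, pairs$start2)
  hi <- pmax(pairs$start1, pairs$start2)
  pick <- function(x) {
    tab <- table(x)
    cand <- as.integer(names(tab)[tab == max(tab)])
    min(cand)
  }
  c(pick(lo), pick(hi))
}

#' Filter pairs to those starting exactly at the amplicon boundaries
#'
#' Keeps the pairs whose two mate start positions equal the two boundary
#' positions (orientation-agnostic). A deletion upstream of a mate's start
#' shifts that start and excludes the pair: this is a documented consequence
#' of boundary filtering, not a defect.
#'
#' @param pairs Pair data frame.
#' @param boundaries Integer pair from [modal_starts()] or
#'   `locus_spec$expected_starts`.
#' @return The usable subset of `pairs`.
#' @export
filter_usable <- function(pairs, boundaries) {
  b <- sort(as.integer(boundaries))
  keep <- pmin(pairs$start1, pairs$start2) == b[1] &
    pmax(pairs$start1, pairs$start2) == b[2]
  pairs[keep, , drop = FALSE]
}

.parse_cigar <- function(cigar) {
  if (is.na(cigar) || !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)) {
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  }
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  data.frame(op = substring(toks, nchar(toks)),
             len = as.integer(substring(toks, 1L, nchar(toks) - 1L)),
             stringsAsFactors = FALSE)
}

# indel events of one mate: walk the CIGAR accumulating reference coordinates
.mate_events <- function(start0, cigar) {
  ops <- .parse_cigar(cigar)
  if (any(ops$len <= 0L)) stop("malformed CIGAR: ", cigar, call. = FALSE)
  ev <- list()
  ref <- start0
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]
    len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      ref <- ref + len
    } else if (op %in% c("D", "N")) {
      if (op == "D") ev[[length(ev) + 1L]] <- c(ref, len, 1L)
      ref <- ref + len
    } else if (op == "I") {
      ev[[length(ev) + 1L]] <- c(ref, len, 2L)
    }
    # S/H/P consume no reference
  }
  events <- if (length(ev)) {
    m <- do.call(rbind, ev)
    data.frame(op = c("D", "I")[m[, 3]], ref_pos = m[, 1], len = m[, 2],
               stringsAsFactors = FALSE)
  } else {
    data.frame(op = character(0), ref_pos = integer(0), len = integer(0),
               stringsAsFactors = FALSE)
  }
  list(events = events, ref_end = ref)
}

.window_events <- function(events, window) {
  if (!nrow(events)) return(events)
  span_end <- events$ref_pos + ifelse(events$op == "D", events$len, 0L)
  keep <- ifelse(events$op == "D",
                 events$ref_pos < window[2] & span_end > window[1],
                 events$ref_pos >= window[1] & events$ref_pos < window[2])
  out <- events[keep, , drop = FALSE]
  out <- out[order(out$ref_pos, out$op), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the indel pattern of one usable read pair
#'
#' Walks both mates' CIGARs accumulating reference coordinates and collects
#' insertion and deletion operations intersecting the locus cut window (for
#' insertions, the insertion point must fall inside it). The pattern is taken
#' from the mate overlapping the cut window; if both mates overlap and
#' disagree the pair is flagged discordant and the union of events is
#' returned (counted as mutant downstream).
#'
#' @param pair One row of a pair data frame.
#' @param locus The [locus_spec()].
#' @param deletions_only If `TRUE`, only deletion operations are collected,
#'   matching the strictly deletion-based original behaviour.
#' @return An [indel_pattern()] with an additional `discordant` element.
#' @export
extract_pattern <- function(pair, locus, deletions_only = FALSE) {
  w <- locus$cut_window
  m1 <- .mate_events(pair$start1, pair$cigar1)
  m2 <- .mate_events(pair$start2, pair$cigar2)
  e1 <- .window_events(m1$events, w)
  e2 <- .window_events(m2$events, w)
  if (deletions_only) {
    e1 <- e1[e1$op == "D", , drop = FALSE]
    e2 <- e2[e2$op == "D", , drop = FALSE]
  }
  o1 <- pair$start1 < w[2] && m1$ref_end > w[1]
  o2 <- pair$start2 < w[2] && m2$ref_end > w[1]
  discordant <- FALSE
  if (o1 && o2) {
    if (!identical(.pattern_key(e1), .pattern_key(e2))) {
      discordant <- TRUE
      ev <- unique(rbind(e1, e2))
      ev <- ev[order(ev$ref_pos, ev$op), , drop = FALSE]
    } else {
      ev <- e1
    }
  } else if (o1) {
    ev <- e1
  } else if (o2) {
    ev <- e2
  } else {
    ev <- e1[0, , drop = FALSE]
  }
  rownames(ev) <- NULL
  out <- indel_pattern(ev$op, ev$ref_pos, ev$len)
  out$discordant <- discordant
  out
}

#' Call editing outcomes at one locus
#'
#' Applies the full pipeline to one sample x locus: boundary inference
#' ([modal_starts()], unless the locus fixes `expected_starts`), boundary
#' filtering ([filter_usable()]), per-pair pattern extraction
#' ([extract_pattern()]) and accounting. The headline output is the
#' percentage of usable pairs supporting a wild-type allele
#' (`pct_wt = 100 * wt / usable`) and its complement `pct_mutant`.
#'
#' @param sample_id Sample label for the report.
#' @param pairs Pair data frame for this locus.
#' @param locus The [locus_spec()].
#' @param deletions_only Passed to [extract_pattern()].
#' @return Object of class `locus_call`: `sample_id`, `locus_id`,
#'   `total_pairs`, `usable_pairs`, `wt_pairs`, `pct_wt`, `pct_mutant`
#'   (both `NA` with `zero_usable = TRUE` when no pair passes the filter),
#'   `pattern_counts` (named integer vector keyed by pattern),
#'   `discordant_pairs` and `boundaries`.
#' @export
call_locus <- function(sample_id, pairs, locus, deletions_only = FALSE) {
  stopifnot(inherits(locus, "locus_spec"))
  total <- nrow(pairs)
  boundaries <- if (identical(locus$expected_starts, "auto")) {
    if (total == 0L) c(NA_integer_, NA_integer_) else modal_starts(pairs)
  } else {
    locus$expected_starts
  }
  usable <- if (total == 0L) pairs else filter_usable(pairs, boundaries)
  nu <- nrow(usable)
  keys <- character(nu)
  discordant <- 0L
  if (nu > 0L) {
    for (i in seq_len(nu)) {
      pat <- extract_pattern(usable[i, ], locus, deletions_only)
      keys[i] <- pat$key
      if (isTRUE(pat$discordant)) discordant <- discordant + 1L
    }
  }
  wt <- sum(keys == "")
  mut_keys <- keys[keys != ""]
  pattern_counts <- if (length(mut_keys)) {
    tab <- table(mut_keys)
    setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }
  structure(
    list(sample_id = sample_id, locus_id = locus$locus_id,
         total_pairs = total, usable_pairs = nu, wt_pairs = wt,
         pct_wt = if (nu > 0L) 100 * wt / nu else NA_real_,
         pct_mutant = if (nu > 0L) 100 * (nu - wt) / nu else NA_real_,
         pattern_counts = pattern_counts,
         discordant_pairs = discordant,
         boundaries = boundaries,
         zero_usable = nu == 0L),
    class = "locus_call"
  )
}

#' @export
print.locus_call <- function(x, ...) {
  cat(sprintf("<locus_call> %s @ %s: %d pairs, %d usable, %d WT",
              x$sample_id, x$locus_id, x$total_pairs, x$usable_pairs,
              x$wt_pairs))
  if (!x$zero_usable) {
    cat(sprintf(" (%.1f%% WT / %.1f%% mutant)\n", x$pct_wt, x$pct_mutant))
  } else {
    cat(" (no usable pairs)\n")
  }
  if (length(x$pattern_counts)) {
    for (k in names(x$pattern_counts)) {
      cat(sprintf("  %-24s %d\n", k, x$pattern_counts[[k]]))
    }
  }
  invisible(x)
}

#' Tabulate locus calls
#'
#' @param calls A `locus_call` or list of them.
#' @return Data frame with one row per call: `sample`, `locus`, `total`,
#'   `usable`, `wt`, `pct_wt`, `pct_mutant`.
#' @export
call_report <- function(calls) {
  if (inherits(calls, "locus_call")) calls <- list(calls)
  do.call(rbind, lapply(calls, function(x) {
    data.frame(sample = x$sample_id, locus = x$locus_id,
               total = x$total_pairs, usable = x$usable_pairs,
               wt = x$wt_pairs, pct_wt = x$pct_wt, pct_mutant = x$pct_mutant,
               stringsAsFactors = FALSE)
  }))
}

#' Tabulate the indel-pattern spectrum of locus calls
#'
#' @param calls A `locus_call` or list of them.
#' @return Data frame `sample`, `locus`, `pattern`, `count` (positions in the
#'   pattern keys are 1-based).
#' @export
pattern_spectrum <- function(calls) {
  if (inherits(calls, "locus_call")) calls <- list(calls)
  out <- lapply(calls, function(x) {
    if (!length(x$pattern_counts)) return(NULL)
    data.frame(sample = x$sample_id, locus = x$locus_id,
               pattern = names(x$pattern_counts),
               count = as.integer(x$pattern_counts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(sample = character(0), locus = character(0),
                      pattern = character(0), count = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Write call reports as TSV + JSON
#'
#' @param calls List of `locus_call`s.
#' @param report_path TSV path for the per-locus summary.
#' @param spectrum_path Optional TSV path for the pattern spectrum.
#' @param json_path Optional path for a machine-readable JSON mirror.
#' @export
write_call_reports <- function(calls, report_path, spectrum_path = NULL,
                               json_path = NULL) {
  rep <- call_report(calls)
  write_tsv(rep, report_path)
  if (!is.null(spectrum_path)) write_tsv(pattern_spectrum(calls), spectrum_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(report = rep, spectrum = pattern_spectrum(calls)),
                         json_path, auto_unbox = TRUE, pretty = TRUE,
                         na = "null")
  }
  invisible(report_path)
}
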