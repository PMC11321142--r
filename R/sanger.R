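# Sanger-style mutation classification by global pairwise alignment

#' Classify a Sanger read against a wild-type reference
#'
#' Globally aligns the query to the locus reference (affine gap penalties,
#' Biostrings) and scores the read as mutated when any alignment gap
#' (insertion or deletion) intersects the locus cut window. Substitutions
#' alone never flag a mutation, mirroring indel-based scoring of capillary
#' traces against a wild-type reference.
#'
#' @param query Base-called A/C/G/T sequence (>= 50 nt, spanning the window).
#' @param locus A [locus_spec()].
#' @param match,mismatch Alignment match/mismatch scores (defaults +2/-1).
#' @param gap_open,gap_ext Affine gap penalties (defaults 6 and 1, applied as
#'   costs).
#' @return List with `mutated` (logical) and `pattern` (an [indel_pattern()]
#'   of the gaps inside the cut window, reference coordinates).
#' @examples
#' ref <- strrep("ACGTT", 40)
#' loc <- locus_spec("l", ref, c(90, 110))
#' sanger_classify(ref, loc)$mutated
#' @export
sanger_classify <- function(query, locus, match = 2, mismatch = -1,
                            gap_open = 6, gap_ext = 1) {
  stopifnot(inherits(locus, "locus_spec"))
  query <- toupper(query)
  .assert_acgt(query, "query")
  if (nchar(query) < 50L) {
    stop("query must be at least 50 nt", call. = FALSE)
  }
  if (nchar(query) < locus$cut_window[2] - locus$cut_window[1]) {
    stop("query shorter than the cut window context", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(locus$reference),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext
  )
  qa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ev <- list()
  ref <- 0L  # 0-based reference cursor
  i <- 1L
  n <- length(qa)
  while (i <= n) {
    if (sa[i] == "-") {            # gap in reference = insertion
      j <- i
      while (j <= n && sa[j] == "-") j <- j + 1L
      ev[[length(ev) + 1L]] <- c(ref, j - i, 2L)
      i <- j
    } else if (qa[i] == "-") {     # gap in query = deletion from reference
      j <- i
      while (j <= n && qa[j] == "-") j <- j + 1L
      ev[[length(ev) + 1L]] <- c(ref, j - i, 1L)
      ref <- ref + (j - i)
      i <- j
    } else {
      ref <- ref + 1L
      i <- i + 1L
    }
  }
  events <- if (length(ev)) {
    m <- do.call(rbind, ev)
    data.frame(op = c("D", "I")[m[, 3]], ref_pos = m[, 1], len = m[, 2],
               stringsAsFactors = FALSE)
  } else {
    data.frame(op = character(0), ref_pos = integer(0), len = integer(0),
               stringsAsFactors = FALSE)
  }
  win_ev <- .window_events(events, locus$cut_window)
  pat <- indel_pattern(win_ev$op, win_ev$ref_pos, win_ev$len)
  list(mutated = nrow(win_ev) > 0L, pattern = pat)
}
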