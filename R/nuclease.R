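#' Nuclease specification
#'
#' Describes the target-site geometry of a programmable nuclease: the PAM
#' pattern (IUPAC), which side of the protospacer the PAM sits on, the
#' protospacer length, and approximate cut offsets. Cas9 recognises an NGG PAM
#' 3' of a 20-nt protospacer and cuts bluntly 3 bp 5' of the PAM; Cas12a
#' recognises a TTTV PAM 5' of the protospacer (23 nt default here) and makes
#' a staggered, PAM-distal cut.
#'
#' @param nuclease `"Cas9"` or `"Cas12a"`.
#' @param protospacer_length Positive integer (>= 15). Defaults: 20 for Cas9,
#'   23 for Cas12a.
#' @param pam_pattern IUPAC string overriding the default PAM (`"NGG"` for
#'   Cas9, `"TTTV"` for Cas12a).
#' @param cut_offsets Integer pair: cut positions of the two strands counted
#'   in bases from the PAM-proximal protospacer end. Defaults: `c(3, 3)` for
#'   Cas9 (blunt, 3 bp 5' of the PAM), `c(18, 23)` for Cas12a (staggered,
#'   PAM-distal). Used only to derive default cut windows for outcome calling.
#'
#' @return An object of class `nuclease_spec`.
#' @examples
#' nuclease_spec("Cas9")
#' nuclease_spec("Cas12a", protospacer_length = 21)
#' @export
nuclease_spec <- function(nuclease = c("Cas9", "Cas12a"),
                          protospacer_length = NULL,
                          pam_pattern = NULL,
                          cut_offsets = NULL) {
  nuclease <- match.arg(nuclease)
  defaults <- switch(nuclease,
    Cas9   = list(pam = "NGG",  side = "three_prime", len = 20L, cut = c(3L, 3L)),
    Cas12a = list(pam = "TTTV", side = "five_prime",  len = 23L, cut = c(18L, 23L))
  )
  pam_pattern <- toupper(if (is.null(pam_pattern)) defaults$pam else pam_pattern)
  if (!.is_iupac(pam_pattern)) stop("pam_pattern must be an IUPAC string", call. = FALSE)
  protospacer_length <- as.integer(if (is.null(protospacer_length)) defaults$len
                                   else protospacer_length)
  if (is.na(protospacer_length) || protospacer_length < 15L) {
    stop("protospacer_length must be an integer >= 15", call. = FALSE)
  }
  cut_offsets <- as.integer(if (is.null(cut_offsets)) defaults$cut else cut_offsets)
  if (length(cut_offsets) != 2L) stop("cut_offsets must be a pair of integers", call. = FALSE)
  structure(
    list(name = nuclease, pam_pattern = pam_pattern, pam_side = defaults$side,
         protospacer_length = protospacer_length, cut_offsets = cut_offsets),
    class = "nuclease_spec"
  )
}

#' @export
print.nuclease_spec <- function(x, ...) {
  cat(sprintf("<nuclease_spec> %s: PAM %s (%s), protospacer %d nt, cut offsets %d/%d\n",
              x$name, x$pam_pattern,
              if (x$pam_side == "three_prime") "3'" else "5'",
              x$protospacer_length, x$cut_offsets[1], x$cut_offsets[2]))
  invisible(x)
}

# protospacer starts (1-based) on one strand given its character vector
.scan_strand <- function(chars, spec) {
  n <- length(chars)
  L <- spec$protospacer_length
  pam <- strsplit(spec$pam_pattern, "")[[1]]
  P <- length(pam)
  if (n < L + P) return(integer(0))
  fp <- seq_len(n - L - P + 1L)                  # footprint starts
  if (spec$pam_side == "three_prime") {
    proto_start <- fp
    pam_start <- fp + L
  } else {
    pam_start <- fp
    proto_start <- fp + P
  }
  ok <- rep(TRUE, length(fp))
  for (j in seq_len(P)) {
    ok <- ok & .iupac_hits(pam[j], chars[pam_start + j - 1L])
  }
  # protospacer window must be pure ACGT (N never matches)
  bad <- cumsum(!(chars %in% .BASES))
  before <- c(0L, bad)[proto_start]
  ok <- ok & (bad[proto_start + L - 1L] - before) == 0L
  proto_start[ok]
}

#' Scan sequences for nuclease target sites
#'
#' Finds every position on both strands where the PAM pattern lies adjacent
#' (3' for Cas9, 5' for Cas12a) to a full-length protospacer window. `N` bases
#' never match, either inside the protospacer or the PAM; windows running past
#' a sequence end are silently skipped.
#'
#' @param sequences Named character vector of A/C/G/T/N sequences, or a
#'   `Biostrings::DNAStringSet` (e.g. from `readDNAStringSet()`).
#' @param spec A [nuclease_spec()].
#' @return A data frame with one row per site: `seq_id`, `start` (0-based
#'   offset of the leftmost protospacer base on the forward strand), `strand`
#'   (`"+"`/`"-"`), `protospacer` and `pam`, both reported in the site's own
#'   reading orientation. For a minus-strand site, reverse-complementing the
#'   forward-strand window `[start, start + length)` reproduces the
#'   protospacer. Rows are sorted by `(seq_id, start, strand)`.
#' @examples
#' scan_targets(c(amp = "TACGTGGACTAGTCAGTTAGTGG"), nuclease_spec("Cas9"))
#' @export
scan_targets <- function(sequences, spec) {
  stopifnot(inherits(spec, "nuclease_spec"))
  if (methods_is_dss(sequences)) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  if (length(sequences) == 0L) stop("no sequences supplied", call. = FALSE)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    names(sequences) <- if (is.null(names(sequences))) {
      paste0("seq", seq_along(sequences))
    } else {
      ifelse(nzchar(names(sequences)), names(sequences),
             paste0("seq", seq_along(sequences)))
    }
  }
  out <- lapply(names(sequences), function(id) {
    s <- .as_seq_chr(sequences[[id]])
    if (!nzchar(s)) stop("empty sequence: ", id, call. = FALSE)
    if (!grepl("^[ACGTN]+$", s)) {
      stop("sequence ", id, " contains characters outside A/C/G/T/N", call. = FALSE)
    }
    .scan_one(id, s, spec)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.scan_one <- function(id, s, spec) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  L <- spec$protospacer_length
  P <- nchar(spec$pam_pattern)
  res <- list()

  plus <- .scan_strand(ch, spec)
  if (length(plus)) {
    pam_at <- if (spec$pam_side == "three_prime") plus + L else plus - P
    res[[1]] <- data.frame(
      seq_id = id, start = plus - 1L, strand = "+",
      protospacer = substring(s, plus, plus + L - 1L),
      pam = substring(s, pam_at, pam_at + P - 1L),
      stringsAsFactors = FALSE
    )
  }
  rc <- .revcomp(s)
  minus <- .scan_strand(strsplit(rc, "")[[1]], spec)
  if (length(minus)) {
    pam_at <- if (spec$pam_side == "three_prime") minus + L else minus - P
    res[[2]] <- data.frame(
      seq_id = id, start = n - minus - L + 1L, strand = "-",
      protospacer = substring(rc, minus, minus + L - 1L),
      pam = substring(rc, pam_at, pam_at + P - 1L),
      stringsAsFactors = FALSE
    )
  }
  if (!length(res)) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      strand = character(0), protospacer = character(0),
                      pam = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Approximate cut position of a target site
#'
#' Returns the 0-based forward-strand reference coordinate of the (top-strand)
#' cut for a scanned site: 3 bp 5' of the PAM for Cas9, after protospacer
#' position 18 (PAM-distal) for Cas12a by default. Used to centre default cut
#' windows for amplicon calling.
#'
#' @param site One row of the data frame returned by [scan_targets()] (or a
#'   list with `start` and `strand`).
#' @param spec The [nuclease_spec()] used for scanning.
#' @return Integer 0-based coordinate of the cut on the forward strand.
#' @export
cut_position <- function(site, spec) {
  stopifnot(inherits(spec, "nuclease_spec"))
  L <- spec$protospacer_length
  off <- spec$cut_offsets[1]
  start <- as.integer(site$start)
  if (spec$pam_side == "three_prime") {
    # PAM-proximal end is the 3' protospacer end
    if (site$strand == "+") start + L - off else start + off
  } else {
    # PAM-proximal end is the 5' protospacer start
    if (site$strand == "+") start + off else start + L - off
  }
}

# Biostrings objects are optional inputs; avoid a hard class dependency
methods_is_dss <- function(x) {
  inherits(x, "XStringSet") || inherits(x, "XString")
}
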