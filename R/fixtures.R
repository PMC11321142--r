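# seed-deterministic simulators: references, edited amplicon read pairs, T0 cohorts

#' Generate a random reference sequence
#'
#' Deterministic given the seed. GC content is exact by construction (quota
#' placement of G/C bases), so the realised GC fraction equals
#' `round(gc_fraction * length) / length`.
#'
#' @param length Sequence length (>= 100).
#' @param gc_fraction Target GC fraction in `[0, 1]`.
#' @param seed Integer seed (mandatory).
#' @param id Sequence name.
#' @return Named character vector of length 1 (name = `id`).
#' @export
make_reference <- function(length, gc_fraction = 0.45, seed, id = "ref") {
  if (length < 100L) stop("reference length must be >= 100", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(gc_fraction >= 0, gc_fraction <= 1)
  .with_seed(seed, {
    n_gc <- round(gc_fraction * length)
    base <- character(length)
    gc_pos <- sample.int(length, n_gc)
    base[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
    base[-gc_pos] <- sample(c("A", "T"), length - n_gc, replace = TRUE)
    if (n_gc == 0L) base <- sample(c("A", "T"), length, replace = TRUE)
    setNames(paste(base, collapse = ""), id)
  })
}

#' Generate random GoldenGate-compatible protospacers
#'
#' Uniform random A/C/G/T protospacers free of BsaI/BpiI recognition motifs
#' (guides carrying such motifs would leave residual type-IIS sites after
#' cloning and are screened out in practice).
#'
#' @param n Number of protospacers.
#' @param length Protospacer length (20 for Cas9, 23 for Cas12a).
#' @param seed Integer seed (mandatory).
#' @return Character vector of protospacers.
#' @export
random_protospacers <- function(n, length = 20L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  .with_seed(seed, vapply(seq_len(n), function(i) .filler(length), character(1)))
}

#' Define an indel pattern
#'
#' @param ops Character vector of `"D"`/`"I"` operations.
#' @param positions 0-based reference positions (for insertions, the
#'   insertion point).
#' @param lengths Positive event lengths.
#' @return Object of class `indel_pattern` (data frame of events, sorted by
#'   position, plus its canonical key).
#' @export
indel_pattern <- function(ops = character(0), positions = integer(0),
                          lengths = integer(0)) {
  stopifnot(length(ops) == length(positions), length(ops) == length(lengths),
            all(ops %in% c("D", "I")), all(lengths >= 1))
  ev <- data.frame(op = as.character(ops), ref_pos = as.integer(positions),
                   len = as.integer(lengths), stringsAsFactors = FALSE)
  ev <- ev[order(ev$ref_pos, ev$op), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(events = ev, key = .pattern_key(ev)),
            class = "indel_pattern")
}

# canonical key; positions reported 1-based to match emitted reports
.pattern_key <- function(events) {
  if (!nrow(events)) return("")
  paste(sprintf("%s:%d:%d", events$op, events$ref_pos + 1L, events$len),
        collapse = ";")
}

#' @export
print.indel_pattern <- function(x, ...) {
  cat(sprintf("<indel_pattern> %s\n", if (nzchar(x$key)) x$key else "WT"))
  invisible(x)
}

# CIGAR for a mate-1 read of fixed length starting at ref b1 carrying events
.cigar_for_events <- function(events, read_len, read_start) {
  if (!nrow(events)) return(sprintf("%dM", read_len))
  cig <- character(0)
  remaining <- read_len
  ref_cur <- read_start
  for (i in seq_len(nrow(events))) {
    m <- events$ref_pos[i] - ref_cur
    if (m <= 0L || m >= remaining) {
      stop("pattern event does not fall strictly inside the read", call. = FALSE)
    }
    cig <- c(cig, sprintf("%dM", m))
    remaining <- remaining - m
    if (events$op[i] == "D") {
      cig <- c(cig, sprintf("%dD", events$len[i]))
      ref_cur <- events$ref_pos[i] + events$len[i]
    } else {
      if (events$len[i] >= remaining) {
        stop("insertion exhausts the read", call. = FALSE)
      }
      cig <- c(cig, sprintf("%dI", events$len[i]))
      remaining <- remaining - events$len[i]
      ref_cur <- events$ref_pos[i]
    }
  }
  cig <- c(cig, sprintf("%dM", remaining))
  paste(cig, collapse = "")
}

# read sequence implied by a CIGAR over a reference (for SAM SEQ fields)
.read_seq <- function(ref, start0, cigar, sub_rate = 0) {
  ops <- .parse_cigar(cigar)
  out <- character(0)
  ref_cur <- start0
  for (i in seq_len(nrow(ops))) {
    len <- ops$len[i]
    if (ops$op[i] %in% c("M", "=", "X")) {
      out <- c(out, substring(ref, ref_cur + 1L, ref_cur + len))
      ref_cur <- ref_cur + len
    } else if (ops$op[i] == "D") {
      ref_cur <- ref_cur + len
    } else if (ops$op[i] == "I") {
      out <- c(out, paste(sample(.BASES, len, replace = TRUE), collapse = ""))
    }
  }
  s <- paste(out, collapse = "")
  if (sub_rate > 0) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < sub_rate)
    for (j in hit) ch[j] <- sample(setdiff(.BASES, ch[j]), 1L)
    s <- paste(ch, collapse = "")
  }
  s
}

#' Simulate aligned amplicon read pairs with defined indel patterns
#'
#' Emits proper read pairs over a locus as SAM records, with mate-1 carrying
#' the requested indel pattern (CIGAR and SEQ consistent) and mate-2 a pure
#' match at the right amplicon boundary. Pattern frequencies are realised by
#' exact quota (largest-remainder) allocation, so the simulated mutant
#' fraction among usable pairs is exact by construction, not Bernoulli.
#' A configurable fraction of pairs start off-boundary (shifted mate-1 start)
#' and are therefore rejected by the caller's boundary filter. Substitution
#' errors change SEQ only, never the CIGAR, mirroring how substitutions do
#' not register as indel events.
#'
#' @param locus A [locus_spec()]; patterns must fall inside the mate-1 span
#'   and outside the mate-2 span.
#' @param patterns List of [indel_pattern()]s (may be empty for all-WT).
#' @param frequencies Numeric vector, same length as `patterns`; together
#'   with `wt_frequency` must sum to 1.
#' @param wt_frequency Frequency of wild-type pairs.
#' @param n_pairs Number of read pairs (>= 1).
#' @param read_length Read length (default 150).
#' @param substitution_error_rate Per-base substitution rate in SEQ.
#' @param off_boundary_fraction Fraction of additional pairs whose mate-1
#'   start is shifted by 1-3 bp (quota-allocated from `n_pairs`).
#' @param seed Integer seed (mandatory).
#' @param sam_path Optional path; when given the SAM text is written there.
#' @return List with `sam` (character vector of SAM lines), `truth` (data
#'   frame `pair_id`, `label`; label is the pattern key, `""` for WT, or
#'   `"off_boundary"`), and `boundaries` (the 0-based mate start pair).
#' @export
simulate_edited_reads <- function(locus, patterns = list(), frequencies = numeric(0),
                                  wt_frequency = 1, n_pairs, read_length = 150L,
                                  substitution_error_rate = 0,
                                  off_boundary_fraction = 0,
                                  seed, sam_path = NULL) {
  stopifnot(inherits(locus, "locus_spec"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
  freqs <- c(wt_frequency, frequencies)
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1", call. = FALSE)
  ref <- locus$reference
  rl <- as.integer(read_length)
  n <- nchar(ref)
  if (n < 2L * rl) stop("reference shorter than two read lengths", call. = FALSE)
  b1 <- 0L
  b2 <- n - rl
  for (p in patterns) {
    ev <- p$events
    span_end <- max(ev$ref_pos + ifelse(ev$op == "D", ev$len, 0L))
    if (any(ev$ref_pos <= b1) || span_end >= b2) {
      stop("pattern must lie strictly inside the mate-1 span and before the ",
           "mate-2 start", call. = FALSE)
    }
  }
  .with_seed(seed, {
    n_off <- round(off_boundary_fraction * n_pairs)
    n_use <- n_pairs - n_off
    counts <- .quota_counts(n_use, freqs)
    labels <- c(rep("", counts[1]),
                unlist(mapply(function(p, k) rep(p$key, k), patterns,
                              counts[-1], SIMPLIFY = FALSE), use.names = FALSE),
                rep("off_boundary", n_off))
    labels <- sample(labels)  # permute pair order
    key2pat <- setNames(patterns, vapply(patterns, `[[`, character(1), "key"))
    recs <- character(0)
    truth <- data.frame(pair_id = sprintf("pair%04d", seq_along(labels)),
                        label = labels, stringsAsFactors = FALSE)
    for (i in seq_along(labels)) {
      lab <- labels[i]
      qn <- truth$pair_id[i]
      if (lab == "off_boundary") {
        s1 <- b1 + sample(1:3, 1L)
        cig1 <- sprintf("%dM", rl)
        seq1 <- .read_seq(ref, s1, cig1, substitution_error_rate)
      } else {
        s1 <- b1
        ev <- if (nzchar(lab)) key2pat[[lab]]$events
              else data.frame(op = character(0), ref_pos = integer(0),
                              len = integer(0))
        cig1 <- .cigar_for_events(ev, rl, b1)
        seq1 <- .read_seq(ref, s1, cig1, substitution_error_rate)
      }
      cig2 <- sprintf("%dM", rl)
      seq2 <- .read_seq(ref, b2, cig2, substitution_error_rate)
      qual <- strrep("I", rl)
      tlen <- b2 + rl - s1
      recs <- c(recs,
        paste(qn, 99L, locus$locus_id, s1 + 1L, 60L, cig1, "=", b2 + 1L,
              tlen, seq1, qual, sep = "\t"),
        paste(qn, 147L, locus$locus_id, b2 + 1L, 60L, cig2, "=", s1 + 1L,
              -tlen, seq2, qual, sep = "\t"))
    }
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", locus$locus_id, n))
    sam <- c(header, recs)
    if (!is.null(sam_path)) writeLines(sam, sam_path)
    list(sam = sam, truth = truth, boundaries = c(b1, b2))
  })
}

#' Simulate a T0 editing cohort
#'
#' Two outcome models over a multi-gene construct. `"nested_activity"` draws
#' one latent per-plant activity `a ~ Uniform(0, 1)` and scores gene `g`
#' mutated iff `a < e_g`: outcomes are perfectly nested, so the all-targets
#' rate equals the lowest per-gene efficiency, reproducing the empirically
#' observed structure where the least-edited gene limits the fraction of
#' plants edited everywhere. `"independent"` draws per-gene Bernoulli
#' outcomes, under which the all-targets rate tends to the product of the
#' efficiencies.
#'
#' @param genes Named numeric vector of per-gene true efficiencies in `[0,1]`.
#' @param n_plants Number of T0 plants.
#' @param model `"nested_activity"` or `"independent"`.
#' @param construct Construct label recorded in the output.
#' @param seed Integer seed (mandatory).
#' @return Data frame `plant_id`, `construct`, `gene`, `mutated` (logical),
#'   one row per plant x gene.
#' @export
simulate_t0_cohort <- function(genes, n_plants,
                               model = c("nested_activity", "independent"),
                               construct = "construct1", seed) {
  model <- match.arg(model)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(all(genes >= 0), all(genes <= 1), n_plants >= 1)
  if (is.null(names(genes))) names(genes) <- paste0("gene", seq_along(genes))
  .with_seed(seed, {
    plants <- sprintf("plant%03d", seq_len(n_plants))
    if (model == "nested_activity") {
      a <- runif(n_plants)
      out <- do.call(rbind, lapply(names(genes), function(g) {
        data.frame(plant_id = plants, construct = construct, gene = g,
                   mutated = a < genes[[g]], stringsAsFactors = FALSE)
      }))
    } else {
      out <- do.call(rbind, lapply(names(genes), function(g) {
        data.frame(plant_id = plants, construct = construct, gene = g,
                   mutated = runif(n_plants) < genes[[g]],
                   stringsAsFactors = FALSE)
      }))
    }
    rownames(out) <- NULL
    out[order(out$plant_id, out$gene), ]
  })
}
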