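# shared fixture builders (all generated in code; nothing is read from disk)

# n random Cas9 guide requests with GoldenGate-compatible protospacers
make_guides <- function(n, seed = 1, nuclease = "Cas9") {
  len <- if (nuclease == "Cas9") 20L else 23L
  data.frame(
    label = paste0("g", seq_len(n)),
    protospacer = random_protospacers(n, len, seed),
    nuclease = nuclease,
    stringsAsFactors = FALSE
  )
}

# deterministic, perfectly nested T0 outcomes realising given per-gene rates:
# plant i is mutated in gene g iff i <= round(rate_g * n)
nested_outcomes <- function(rates, n, construct = "c1") {
  do.call(rbind, lapply(names(rates), function(g) {
    k <- round(rates[[g]] * n)
    data.frame(plant_id = sprintf("p%03d", seq_len(n)), construct = construct,
               gene = g, mutated = seq_len(n) <= k, stringsAsFactors = FALSE)
  }))
}

# small explicit linear toy part with one BsaI site, for hand-traced digests:
# AAAA GGTCTC A TTTT CCAACCAACCAACCAACCAACCAAC  (40 nt)
toy_bsai_linear <- function() {
  gg_part("toy", paste0("AAAA", "GGTCTC", "A", "TTTT",
                        "CCAACCAACCAACCAACCAACCAAC"))
}

# minimal hand-built circular accepter whose only sites are two inward BsaI
# cuts around a dropout, leaving backbone overhangs CTTG (three) / GTTT (five)
toy_l1_accepter <- function() {
  prom <- "ATTACCAATTCCAATTACCA"
  lacz <- "CCATTACCATTACCATTACCATTACCATTA"
  scaf <- "TTCCAATTACCAATTCCAAT"
  bb <- "ATACCATTACCAATACCATTACCA"
  seq <- paste0(bb, prom, "CTTG", "A", "GAGACC", lacz,
                "GGTCTC", "A", "GTTT", scaf)
  lacz_start <- nchar(bb) + nchar(prom) + 4L + 1L + 6L + 1L
  ann <- data.frame(label = c("backbone", "dropout"),
                    start = c(1L, lacz_start),
                    end = c(nchar(bb), lacz_start + nchar(lacz) - 1L))
  gg_part("toyL1", seq, circular = TRUE, role = "accepter", annotations = ann)
}

# write SAM lines for hand-constructed records over one reference
sam_lines <- function(locus_id, ref_len, recs) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", locus_id, ref_len),
    recs)
}

sam_rec <- function(qname, flag, rname, pos1, cigar, mpos1) {
  # SEQ consistent with CIGAR: count M/I/S/=/X lengths
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  ops <- substring(toks, nchar(toks))
  lens <- as.integer(substring(toks, 1, nchar(toks) - 1))
  qlen <- sum(lens[ops %in% c("M", "I", "S", "=", "X")])
  paste(qname, flag, rname, pos1, 60L, cigar, "=", mpos1, 0L,
        strrep("A", qlen), strrep("I", qlen), sep = "\t")
}
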