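# shared internal helpers

.BASES <- c("A", "C", "G", "T")

# IUPAC code -> logical over A,C,G,T
.IUPAC <- local({
  sets <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  m <- matrix(FALSE, length(sets), 4, dimnames = list(names(sets), .BASES))
  for (cd in names(sets)) m[cd, sets[[cd]]] <- TRUE
  m
})

.is_iupac <- function(x) {
  all(strsplit(x, "")[[1]] %in% rownames(.IUPAC))
}

# does IUPAC code match each observed base? non-ACGT observations never match
.iupac_hits <- function(code, bases) {
  idx <- match(bases, .BASES)
  out <- rep(FALSE, length(bases))
  ok <- !is.na(idx)
  out[ok] <- .IUPAC[code, idx[ok]]
  out
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTRYSWKMBDHVNacgt", "TGCAYRSWMKVHDBNtgca", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.assert_acgt <- function(x, what = "sequence") {
  if (!grepl("^[ACGT]+$", x)) {
    stop(sprintf("%s must contain only A/C/G/T characters", what), call. = FALSE)
  }
  invisible(x)
}

# evaluate code with a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# largest-remainder apportionment of n among weights (exact quota counts)
.quota_counts <- function(n, weights) {
  if (n == 0) return(integer(length(weights)))
  w <- weights / sum(weights)
  raw <- w * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

# uppercase single character sequence, accepting DNAString-likes
.as_seq_chr <- function(x) {
  toupper(as.character(x))
}
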