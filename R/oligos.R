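# level-1 cloning oligo design

.ARCHS <- data.frame(
  architecture = c("CAS9_A_TaU6", "CAS9_A_TaU3", "CAS9_A_HvU3",
                   "CAS12A_V2", "CAS12A_V3"),
  nuclease     = c("Cas9", "Cas9", "Cas9", "Cas12a", "Cas12a"),
  promoter     = c("TaU6", "TaU3", "HvU3", NA, NA),
  fwd_overhang = c("CTTG", "AGCA", "AGCA", "AGAT", "AGAT"),
  rev_overhang = c("AAAC", "AAAC", "AAAC", "GGCC", "ATTA"),
  stringsAsFactors = FALSE
)

#' Guide cloning architectures
#'
#' The level-1 oligo architectures supported by the toolkit and their 4-nt
#' cloning overhangs. Cas9 architecture A uses one pol III promoter per guide
#' (TaU6, TaU3 or HvU3; the two U3 accepters share overhangs); Cas12a V2
#' (ribozyme-separated) and V3 (tRNA-separated) arrays each have their own
#' reverse overhang.
#'
#' @return Data frame with columns `architecture`, `nuclease`, `promoter`,
#'   `fwd_overhang`, `rev_overhang`.
#' @export
guide_architectures <- function() .ARCHS

.arch_row <- function(architecture) {
  i <- match(architecture, .ARCHS$architecture)
  if (is.na(i)) {
    stop("unknown architecture: ", architecture, " (see guide_architectures())",
         call. = FALSE)
  }
  .ARCHS[i, ]
}

# default architecture for a (nuclease, promoter/array) pair used by planner
.arch_for <- function(nuclease, promoter = NULL, family = NULL) {
  if (nuclease == "Cas9") {
    if (is.null(promoter) || is.na(promoter)) promoter <- "TaU6"
    .ARCHS$architecture[.ARCHS$nuclease == "Cas9" & .ARCHS$promoter == promoter]
  } else {
    if (is.null(family) || is.na(family)) family <- "V2"
    paste0("CAS12A_", family)
  }
}

#' Design a cloning oligo pair for one protospacer
#'
#' Builds the forward/reverse level-1 cloning oligos for a protospacer:
#' `forward = fwd_overhang + protospacer`,
#' `reverse = rev_overhang + reverse_complement(protospacer)`. The protospacer
#' excludes the PAM. Expected lengths are 20 nt for Cas9 architectures and
#' 23 nt for Cas12a unless `length_override` is given. A Cas12a protospacer
#' beginning `TTT` (the PAM probably included by mistake) triggers a warning.
#'
#' @param protospacer A/C/G/T string, PAM excluded.
#' @param architecture One of the names in [guide_architectures()].
#' @param length_override Optional integer protospacer length to accept
#'   instead of the architecture default.
#' @return Object of class `oligo_pair` with elements `forward`, `reverse`,
#'   `architecture`, `protospacer`.
#' @examples
#' design_oligo_pair("TACGTGGACTAGTCAGTTAG", "CAS9_A_TaU6")
#' @export
design_oligo_pair <- function(protospacer, architecture,
                              length_override = NULL) {
  arch <- .arch_row(architecture)
  protospacer <- toupper(protospacer)
  if (!grepl("^[ACGT]+$", protospacer)) {
    stop("protospacer contains characters outside A/C/G/T", call. = FALSE)
  }
  expected <- if (!is.null(length_override)) as.integer(length_override)
              else if (arch$nuclease == "Cas9") 20L else 23L
  if (nchar(protospacer) != expected) {
    stop(sprintf("protospacer for %s must be %d nt (got %d)",
                 architecture, expected, nchar(protospacer)), call. = FALSE)
  }
  if (arch$nuclease == "Cas12a" && startsWith(protospacer, "TTT")) {
    warning("Cas12a protospacer begins 'TTT': the TTTV PAM may have been ",
            "included by mistake (the protospacer should exclude it)",
            call. = FALSE)
  }
  if (.has_site(protospacer)) {
    warning("protospacer contains a BsaI/BpiI recognition motif and will ",
            "leave a residual type-IIS site after GoldenGate cloning; ",
            "choose a different guide", call. = FALSE)
  }
  structure(
    list(
      forward = paste0(arch$fwd_overhang, protospacer),
      reverse = paste0(arch$rev_overhang, .revcomp(protospacer)),
      architecture = arch$architecture,
      protospacer = protospacer
    ),
    class = "oligo_pair"
  )
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat(sprintf("<oligo_pair> %s\n  forward 5'-%s-3'\n  reverse 5'-%s-3'\n",
              x$architecture, x$forward, x$reverse))
  invisible(x)
}

#' Batch oligo design
#'
#' @param guides Data frame with columns `name`, `protospacer`,
#'   `architecture` (e.g. read with [read_guides_tsv()]).
#' @return Data frame `name`, `architecture`, `forward`, `reverse`.
#' @export
design_oligos <- function(guides) {
  stopifnot(all(c("name", "protospacer", "architecture") %in% names(guides)))
  rows <- lapply(seq_len(nrow(guides)), function(i) {
    p <- design_oligo_pair(guides$protospacer[i], guides$architecture[i])
    data.frame(name = guides$name[i], architecture = p$architecture,
               forward = p$forward, reverse = p$reverse,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annealed oligo duplex as an assembly part
#'
#' Models the annealed forward/reverse oligo duplex as a linear double-stranded
#' part with 4-nt 5' single-stranded ends, ready to drop into a level-1
#' GoldenGate reaction via [simulate_reaction()]. Overhangs are stored in
#' top-strand space: the right-hand (bottom strand) 5' overhang is recorded as
#' the reverse complement of the reverse oligo's overhang.
#'
#' @param pair An [design_oligo_pair()] result.
#' @param id Part identifier.
#' @return A `gg_part` (see [gg_part()]).
#' @export
anneal_oligos <- function(pair, id = "oligo_duplex") {
  stopifnot(inherits(pair, "oligo_pair"))
  arch <- .arch_row(pair$architecture)
  five <- arch$fwd_overhang
  three <- .revcomp(arch$rev_overhang)
  gg_part(
    id = id,
    sequence = paste0(five, pair$protospacer, three),
    circular = FALSE,
    role = "insert",
    five_overhang = five,
    three_overhang = three
  )
}

#' Read a guides table
#'
#' Tab-separated file with columns `name`, `protospacer` and either
#' `architecture` (for [design_oligos()]) or `nuclease` (+ optional
#' `architecture_family`, `promoter`) for [plan_assembly()].
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_guides_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' 96-well ordering layout for oligo pairs
#'
#' Assigns each oligo of each pair to consecutive wells, column-major
#' (A1, B1, ... H1, A2, ...), forward before reverse, for ordering synthesis
#' in plate format.
#'
#' @param oligos Data frame from [design_oligos()]; at most 48 pairs.
#' @return Data frame `well`, `name`, `oligo`, `sequence`.
#' @export
plate_layout <- function(oligos) {
  n <- nrow(oligos)
  if (n > 48L) stop("a 96-well plate holds at most 48 oligo pairs", call. = FALSE)
  wells <- paste0(rep(LETTERS[1:8], times = 12), rep(1:12, each = 8))
  idx <- seq_len(2L * n)
  data.frame(
    well = wells[idx],
    name = rep(oligos$name, each = 2L),
    oligo = rep(c("forward", "reverse"), times = n),
    sequence = as.vector(rbind(oligos$forward, oligos$reverse)),
    stringsAsFactors = FALSE
  )
}
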