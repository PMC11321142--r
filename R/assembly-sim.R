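# in silico type-IIS digestion-ligation
#
# Double-stranded parts and fragments are represented by their top strand.
# 4-nt 5' protruding overhangs are stored in top-strand space: a fragment's
# right-hand (bottom strand) 5' overhang is recorded as the corresponding
# top-strand text, so two fragments ligate when one's `three_overhang` equals
# the next one's `five_overhang`. Fragment sequences include both overhang
# regions; at a join the shared 4 nt are therefore counted twice across the
# two fragments and dropped once on ligation.

#' Type-IIS enzymes used by the toolkit
#'
#' BsaI (GGTCTC, cutting 1 nt downstream) and BpiI (GAAGAC, 2 nt downstream),
#' both leaving 4-nt 5' overhangs. Offsets follow the standard enzyme
#' definitions.
#'
#' @param name `"BsaI"`, `"BpiI"`, or a vector of both.
#' @return A list of enzyme definitions (`name`, `recognition`, `spacer`,
#'   `overhang_length`).
#' @export
typeIIS_enzymes <- function(name = c("BsaI", "BpiI")) {
  defs <- list(
    BsaI = list(name = "BsaI", recognition = "GGTCTC", spacer = 1L,
                overhang_length = 4L),
    BpiI = list(name = "BpiI", recognition = "GAAGAC", spacer = 2L,
                overhang_length = 4L)
  )
  bad <- setdiff(name, names(defs))
  if (length(bad)) stop("unknown enzyme: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  defs[name]
}

#' Construct a DNA part
#'
#' @param id Part identifier.
#' @param sequence Top-strand A/C/G/T sequence.
#' @param circular Is the part circular (plasmid)?
#' @param role One of `"accepter"`, `"insert"`, `"end_linker"`, `"product"`.
#' @param annotations Data frame with columns `label`, `start`, `end`
#'   (1-based, inclusive, top strand). The labels `"backbone"` and
#'   `"dropout"` steer fragment selection in [simulate_reaction()].
#' @param five_overhang,three_overhang For linear parts only: pre-existing
#'   4-nt 5' single-stranded ends (top-strand space), e.g. an annealed oligo
#'   duplex. Empty string means blunt.
#' @return Object of class `gg_part`.
#' @export
gg_part <- function(id, sequence, circular = FALSE,
                    role = c("insert", "accepter", "end_linker", "product"),
                    annotations = NULL,
                    five_overhang = "", three_overhang = "") {
  role <- match.arg(role)
  sequence <- toupper(sequence)
  .assert_acgt(sequence, paste0("part ", id))
  if (is.null(annotations)) {
    annotations <- data.frame(label = character(0), start = integer(0),
                              end = integer(0), stringsAsFactors = FALSE)
  }
  if (circular && (nzchar(five_overhang) || nzchar(three_overhang))) {
    stop("circular parts cannot carry terminal overhangs", call. = FALSE)
  }
  structure(
    list(id = id, sequence = sequence, circular = isTRUE(circular),
         role = role, annotations = annotations,
         five_overhang = five_overhang, three_overhang = three_overhang),
    class = "gg_part"
  )
}

#' @export
print.gg_part <- function(x, ...) {
  cat(sprintf("<gg_part> %s: %d bp, %s, role=%s, %d annotation(s)\n",
              x$id, nchar(x$sequence),
              if (x$circular) "circular" else "linear", x$role,
              nrow(x$annotations)))
  invisible(x)
}

.gg_fragment <- function(sequence, five, three, origin, annotations = NULL) {
  if (is.null(annotations)) {
    annotations <- data.frame(label = character(0), start = integer(0),
                              end = integer(0), stringsAsFactors = FALSE)
  }
  structure(
    list(sequence = sequence, five_overhang = five, three_overhang = three,
         origin_part = origin, annotations = annotations),
    class = "gg_fragment"
  )
}

#' @export
print.gg_fragment <- function(x, ...) {
  cat(sprintf("<gg_fragment> %d bp from %s [%s ... %s]\n", nchar(x$sequence),
              x$origin_part,
              if (nzchar(x$five_overhang)) x$five_overhang else "blunt",
              if (nzchar(x$three_overhang)) x$three_overhang else "blunt"))
  invisible(x)
}

# 0-based match starts of a fixed pattern; circular search crosses the origin
.find_motif <- function(seq, motif, circular) {
  n <- nchar(seq)
  subject <- if (circular) paste0(seq, substr(seq, 1, nchar(motif) - 1)) else seq
  m <- gregexpr(motif, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  p <- as.integer(m) - 1L
  p[p < n]
}

# all (c_top, c_bot) cut pairs, 0-based between-coordinates; c_bot = c_top + 4
.cut_pairs <- function(part, enzymes) {
  n <- nchar(part$sequence)
  out <- list()
  for (e in enzymes) {
    rl <- nchar(e$recognition)
    plus <- .find_motif(part$sequence, e$recognition, part$circular)
    minus <- .find_motif(part$sequence, .revcomp(e$recognition), part$circular)
    ct <- c(plus + rl + e$spacer, minus - e$spacer - e$overhang_length)
    if (length(ct)) {
      if (part$circular) {
        ct <- ct %% n
      } else {
        ct <- ct[ct >= 0L & ct + e$overhang_length <= n]  # end-truncated sites skipped
      }
      if (length(ct)) out[[length(out) + 1L]] <- ct
    }
  }
  sort(unique(unlist(out)))
}

.keep_annotations <- function(ann, from, to, shift) {
  # annotations fully inside [from, to] (1-based), rebased by shift
  if (!nrow(ann)) return(ann)
  keep <- ann$start >= from & ann$end <= to
  out <- ann[keep, , drop = FALSE]
  out$start <- out$start - shift
  out$end <- out$end - shift
  rownames(out) <- NULL
  out
}

#' Digest a part with type-IIS enzymes
#'
#' Locates every recognition site on both strands, applies the cut-offset
#' arithmetic (recognition + spacer, 4-nt 5' overhang) and returns the
#' resulting fragments. Circular parts are linearised at their cut points;
#' parts with no sites are returned intact (a single fragment preserving any
#' terminal overhangs).
#'
#' @param part A [gg_part()].
#' @param enzymes Result of [typeIIS_enzymes()].
#' @return List of `gg_fragment` objects.
#' @export
digest_part <- function(part, enzymes) {
  stopifnot(inherits(part, "gg_part"))
  if (!length(enzymes)) stop("no enzymes supplied", call. = FALSE)
  s <- part$sequence
  n <- nchar(s)
  cuts <- .cut_pairs(part, enzymes)
  if (!length(cuts)) {
    return(list(.gg_fragment(s, part$five_overhang, part$three_overhang,
                             part$id, part$annotations)))
  }
  oh <- 4L
  if (part$circular) {
    r <- cuts[1]
    rot <- paste0(substring(s, r + 1L), substring(s, 1L, r))
    cuts <- sort((cuts - r) %% n)
    ann <- part$annotations
    if (nrow(ann)) {
      ns <- ((ann$start - 1L - r) %% n) + 1L
      ann$end <- ns + (ann$end - ann$start)
      ann$start <- ns
      ann <- ann[ann$end <= n, , drop = FALSE]  # origin-spanning annotations dropped
    }
    k <- length(cuts)
    if (any(diff(c(cuts, n + cuts[1])) < oh)) {
      stop("overlapping cut sites produce negative-length fragments",
           call. = FALSE)
    }
    frags <- vector("list", k)
    for (i in seq_len(k)) {
      a <- cuts[i]
      if (i < k) {
        b <- cuts[i + 1L]
        seq_i <- substring(rot, a + 1L, b + oh)
        ann_i <- .keep_annotations(ann, a + 1L, b + oh, a)
        three <- substring(rot, b + 1L, b + oh)
      } else {
        seq_i <- paste0(substring(rot, a + 1L, n), substring(rot, 1L, oh))
        ann_i <- .keep_annotations(ann, a + 1L, n, a)
        three <- substring(rot, 1L, oh)
      }
      frags[[i]] <- .gg_fragment(seq_i, substring(rot, a + 1L, a + oh),
                                 three, part$id, ann_i)
    }
    return(frags)
  }
  # linear
  if (any(diff(cuts) < oh)) {
    stop("overlapping cut sites produce negative-length fragments",
         call. = FALSE)
  }
  bounds_top <- c(0L, cuts)
  bounds_bot <- c(cuts + oh, n)
  k <- length(cuts)
  frags <- vector("list", k + 1L)
  for (i in seq_len(k + 1L)) {
    a <- bounds_top[i]
    b <- bounds_bot[i]
    five <- if (i == 1L) part$five_overhang else substring(s, a + 1L, a + oh)
    three <- if (i == k + 1L) part$three_overhang
             else substring(s, bounds_top[i + 1L] + 1L, b)
    frags[[i]] <- .gg_fragment(substring(s, a + 1L, b), five, three, part$id,
                               .keep_annotations(part$annotations, a + 1L, b, a))
  }
  frags
}

#' Ligate fragments into a circular product
#'
#' Builds the overhang-matching graph over the supplied fragments and
#' succeeds only if a unique closed chain (Hamiltonian cycle) uses every
#' fragment exactly once. Any overhang occurring more than once among the
#' available 5' ends is ambiguous: no product is formed and a diagnostic is
#' recorded. Failures are always encoded as diagnostics, never errors.
#'
#' @param fragments List of `gg_fragment` objects (>= 1).
#' @return Object of class `assembly_result`: `product` (a circular
#'   [gg_part()] or `NULL`), `joins` (data frame of fragment order and the
#'   overhang used at each join) and `diagnostics` (character vector).
#' @export
ligate_fragments <- function(fragments) {
  stopifnot(length(fragments) >= 1L)
  diags <- character(0)
  fives <- vapply(fragments, function(f) f$five_overhang, character(1))
  threes <- vapply(fragments, function(f) f$three_overhang, character(1))
  blunt <- !nzchar(fives) | !nzchar(threes)
  if (any(blunt)) {
    diags <- c(diags, sprintf("blunt-ended fragment from %s cannot circularise",
                              paste(unique(vapply(fragments[blunt], `[[`,
                                                  character(1), "origin_part")),
                                    collapse = ", ")))
  }
  dup5 <- unique(fives[duplicated(fives) & nzchar(fives)])
  dup3 <- unique(threes[duplicated(threes) & nzchar(threes)])
  for (d in unique(c(dup5, dup3))) {
    diags <- c(diags, sprintf("ambiguous overhang %s present on multiple fragments", d))
  }
  if (length(diags)) {
    return(structure(list(product = NULL, joins = NULL, diagnostics = diags),
                     class = "assembly_result"))
  }
  nxt <- match(threes, fives)
  if (anyNA(nxt)) {
    diags <- c(diags, sprintf("unmatched overhang %s has no ligation partner",
                              paste(threes[is.na(nxt)], collapse = ", ")))
    return(structure(list(product = NULL, joins = NULL, diagnostics = diags),
                     class = "assembly_result"))
  }
  n <- length(fragments)
  ord <- integer(n)
  cur <- 1L
  for (i in seq_len(n)) {
    ord[i] <- cur
    cur <- nxt[cur]
  }
  if (anyDuplicated(ord) || cur != 1L) {
    diags <- c(diags, "fragments do not form a single closed assembly")
    return(structure(list(product = NULL, joins = NULL, diagnostics = diags),
                     class = "assembly_result"))
  }
  oh <- 4L
  pieces <- character(n)
  ann_all <- list()
  offset <- 0L
  for (i in seq_len(n)) {
    f <- fragments[[ord[i]]]
    core_len <- nchar(f$sequence) - oh
    pieces[i] <- substring(f$sequence, 1L, core_len)
    a <- f$annotations
    if (nrow(a)) {
      a <- a[a$end <= core_len, , drop = FALSE]
      if (nrow(a)) {
        a$start <- a$start + offset
        a$end <- a$end + offset
        ann_all[[length(ann_all) + 1L]] <- a
      }
    }
    offset <- offset + core_len
  }
  joins <- data.frame(
    fragment = vapply(fragments[ord], `[[`, character(1), "origin_part"),
    via_overhang = threes[ord],
    stringsAsFactors = FALSE
  )
  ann <- if (length(ann_all)) do.call(rbind, ann_all) else NULL
  product <- gg_part("ligation_product", paste(pieces, collapse = ""),
                     circular = TRUE, role = "product", annotations = ann)
  structure(list(product = product, joins = joins, diagnostics = character(0)),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  if (is.null(x$product)) {
    cat("<assembly_result> FAILED\n")
  } else {
    cat(sprintf("<assembly_result> circular product %s, %d bp, %d join(s)\n",
                x$product$id, nchar(x$product$sequence), nrow(x$joins)))
  }
  for (d in x$diagnostics) cat("  ! ", d, "\n", sep = "")
  invisible(x)
}

#' Simulate a one-pot GoldenGate reaction
#'
#' Digests the accepter and every insert with the reaction enzymes, selects
#' the accepter backbone (the accepter fragment lacking a `"dropout"`
#' annotation) and the cargo fragments of the inserts (fragments lacking a
#' `"backbone"` annotation), ligates them, and checks GoldenGate
#' irreversibility: the final circular product must contain no intact
#' recognition site of the reaction enzymes (a residual site yields a warning
#' diagnostic).
#'
#' @param accepter A circular accepter [gg_part()].
#' @param inserts List of insert [gg_part()]s (donor plasmids, annealed
#'   duplexes, end linkers).
#' @param enzymes Result of [typeIIS_enzymes()] matching the plan step.
#' @param product_id Identifier given to the product part.
#' @return An `assembly_result` (see [ligate_fragments()]).
#' @export
simulate_reaction <- function(accepter, inserts, enzymes,
                              product_id = "assembled") {
  stopifnot(inherits(accepter, "gg_part"))
  diags <- character(0)
  acc_frags <- digest_part(accepter, enzymes)
  if (length(acc_frags) == 1L && acc_frags[[1]]$sequence == accepter$sequence) {
    diags <- c(diags, sprintf("accepter %s has no sites for the reaction enzymes",
                              accepter$id))
  }
  is_backbone <- vapply(acc_frags, function(f) {
    !("dropout" %in% f$annotations$label)
  }, logical(1))
  if (sum(is_backbone) != 1L) {
    diags <- c(diags,
               sprintf("could not identify a unique backbone in %s (%d candidates)",
                       accepter$id, sum(is_backbone)))
    return(structure(list(product = NULL, joins = NULL, diagnostics = diags),
                     class = "assembly_result"))
  }
  selected <- acc_frags[is_backbone]
  for (p in inserts) {
    frags <- digest_part(p, enzymes)
    cargo <- Filter(function(f) !("backbone" %in% f$annotations$label), frags)
    if (!length(cargo)) {
      diags <- c(diags, sprintf("insert %s yields no cargo fragment", p$id))
      next
    }
    selected <- c(selected, cargo)
  }
  res <- ligate_fragments(selected)
  res$diagnostics <- c(diags, res$diagnostics)
  if (!is.null(res$product)) {
    res$product$id <- product_id
    for (e in enzymes) {
      hit <- length(.find_motif(res$product$sequence, e$recognition, TRUE)) +
        length(.find_motif(res$product$sequence, .revcomp(e$recognition), TRUE))
      if (hit > 0L) {
        res$diagnostics <- c(res$diagnostics,
                             sprintf("residual %s site in product %s",
                                     e$name, product_id))
      }
    }
    if (length(res$diagnostics)) {
      # a product was formed but the reaction is suspect; keep both
      names(res$diagnostics) <- NULL
    }
  }
  res
}
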