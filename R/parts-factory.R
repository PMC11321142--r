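# synthetic part factory
#
# Builds minimal, self-consistent accepters, end linkers and oligo duplexes
# for any assembly plan, so plans can be verified in silico without any
# physical plasmid sequences. Position fusion overhangs are invented (the
# physical toolkit's inter-position overhangs are not public) but are fixed,
# distinct 4-mers, so products are deterministic given a seed. Parts built
# here are synthetic stand-ins, not reconstructions of the AddGene plasmids.

.POS_OH <- c("AATG", "AGGT", "TTCG", "GCTT", "ACGA", "CAGT", "TGTC", "CCAG")
.END_OH <- "CGAA"

.SITE_MOTIFS <- c("GGTCTC", "GAGACC", "GAAGAC", "GTCTTC")

.has_site <- function(s, circular = FALSE) {
  subject <- if (circular) paste0(s, substr(s, 1, 5)) else s
  any(vapply(.SITE_MOTIFS, function(m) grepl(m, subject, fixed = TRUE),
             logical(1)))
}

# random filler free of recognition motifs (draws from the current RNG stream)
.filler <- function(n) {
  repeat {
    s <- paste(sample(.BASES, n, replace = TRUE), collapse = "")
    if (!.has_site(s)) return(s)
  }
}

.annot <- function(label, start, len) {
  data.frame(label = label, start = start, end = start + len - 1L,
             stringsAsFactors = FALSE)
}

# circular level-1 guide accepter for one architecture at one GoldenGate
# position: BsaI sites flank a lacZ dropout (recognitions leave with the
# dropout), outer BpiI sites later release the loaded cassette with the
# position fusion overhangs (recognitions stay in the backbone).
.make_l1_accepter <- function(architecture, position, id) {
  arch <- .arch_row(architecture)
  fwd <- arch$fwd_overhang
  three <- .revcomp(arch$rev_overhang)
  bb1 <- .filler(30); sp2a <- .filler(2); prom <- .filler(25)
  sp1a <- .filler(1); lacz <- .filler(30); sp1b <- .filler(1)
  scaf <- .filler(25); sp2b <- .filler(2); bb2 <- .filler(20)
  segs <- c(bb1, "GAAGAC", sp2a, .POS_OH[position], prom,
            fwd, sp1a, "GAGACC", lacz, "GGTCTC", sp1b, three,
            scaf, .POS_OH[position + 1L], sp2b, "GTCTTC", bb2)
  seq <- paste(segs, collapse = "")
  lacz_start <- nchar(bb1) + 6L + 2L + 4L + nchar(prom) + 4L + 1L + 6L + 1L
  ann <- rbind(.annot("backbone", 1L, nchar(bb1)),
               .annot("dropout", lacz_start, nchar(lacz)))
  gg_part(id, seq, circular = TRUE, role = "accepter", annotations = ann)
}

# circular level-M accepter for level-2 position j: BpiI dropout (recognitions
# inside) accepts level-1 cassettes; outer BsaI sites release the stacked
# module with overhangs (pos j, pos j+1).
.make_lm_accepter <- function(position, id) {
  bb1 <- .filler(30); f1 <- .filler(1); link1 <- .filler(10)
  f2 <- .filler(2); lacz <- .filler(30); f3 <- .filler(2)
  link2 <- .filler(10); f5 <- .filler(1); bb2 <- .filler(20)
  segs <- c(bb1, "GGTCTC", f1, .POS_OH[position], link1,
            .POS_OH[1L], f2, "GTCTTC", lacz, "GAAGAC", f3, .END_OH,
            link2, .POS_OH[position + 1L], f5, "GAGACC", bb2)
  seq <- paste(segs, collapse = "")
  lacz_start <- nchar(bb1) + 6L + 1L + 4L + nchar(link1) + 4L + 2L + 6L + 1L
  ann <- rbind(.annot("backbone", 1L, nchar(bb1)),
               .annot("dropout", lacz_start, nchar(lacz)))
  gg_part(id, seq, circular = TRUE, role = "accepter", annotations = ann)
}

# circular level-2 binary vector: RFP dropout flanked by BsaI sites
# (recognitions leave with the dropout); backbone carries the plant selection
# and nuclease cassettes (represented here only as annotated filler).
.make_l2_accepter <- function(id) {
  bb1 <- .filler(40); sp1 <- .filler(1); rfp <- .filler(30)
  sp2 <- .filler(1); bb2 <- .filler(30)
  segs <- c(bb1, .POS_OH[1L], sp1, "GAGACC", rfp, "GGTCTC", sp2, .END_OH, bb2)
  seq <- paste(segs, collapse = "")
  rfp_start <- nchar(bb1) + 4L + 1L + 6L + 1L
  ann <- rbind(.annot("backbone", 1L, nchar(bb1)),
               .annot("dropout", rfp_start, nchar(rfp)))
  gg_part(id, seq, circular = TRUE, role = "accepter", annotations = ann)
}

# circular end-linker donor: BpiI releases a short linker bridging the last
# cassette overhang (pos m+1) to the accepter's end overhang.
.make_end_linker <- function(m_plus_one, id) {
  bb1 <- .filler(25); f1 <- .filler(2); core <- .filler(12)
  f2 <- .filler(2); bb2 <- .filler(15)
  segs <- c(bb1, "GAAGAC", f1, .POS_OH[m_plus_one], core,
            .END_OH, f2, "GTCTTC", bb2)
  seq <- paste(segs, collapse = "")
  gg_part(id, seq, circular = TRUE, role = "end_linker",
          annotations = .annot("backbone", 1L, nchar(bb1)))
}

#' Generate synthetic parts for an assembly plan
#'
#' Builds every accepter, annealed oligo duplex and end linker a plan needs,
#' with deterministic (seeded) filler sequences that avoid BsaI/BpiI
#' recognition motifs. The inter-position fusion overhangs are fixed synthetic
#' 4-mers.
#'
#' @param plan An [plan_assembly()] result.
#' @param seed Integer seed controlling the filler sequences.
#' @return Named list of [gg_part()] objects keyed by the part ids used in
#'   `plan$steps`, plus the end-linker parts (`LMlink_<j>`, `L2link`).
#' @export
plan_parts <- function(plan, seed = 1L) {
  stopifnot(inherits(plan, "assembly_plan"))
  .with_seed(seed, {
    parts <- list()
    g <- plan$guides
    for (i in seq_len(nrow(g))) {
      acc_id <- sprintf("L1acc_%s_pos%d", g$architecture[i], g$position[i])
      if (is.null(parts[[acc_id]])) {
        parts[[acc_id]] <- .make_l1_accepter(g$architecture[i], g$position[i],
                                             acc_id)
      }
      oligo_id <- paste0("oligos_", g$label[i])
      parts[[oligo_id]] <- anneal_oligos(
        design_oligo_pair(g$protospacer[i], g$architecture[i]), oligo_id
      )
    }
    lm_steps <- plan$steps[plan$steps$level == "LM", , drop = FALSE]
    for (j in seq_len(nrow(lm_steps))) {
      pos <- lm_steps$position_index[j]
      parts[[lm_steps$accepter_id[j]]] <-
        .make_lm_accepter(pos, lm_steps$accepter_id[j])
      m <- length(strsplit(lm_steps$insert_ids[j], ";")[[1]])
      lid <- sprintf("LMlink_%d", pos)
      parts[[lid]] <- .make_end_linker(m + 1L, lid)
    }
    l2 <- plan$steps[plan$steps$level == "L2", , drop = FALSE]
    parts[[plan$binary_vector]] <- .make_l2_accepter(plan$binary_vector)
    k <- length(strsplit(l2$insert_ids[1], ";")[[1]])
    parts[["L2link"]] <- .make_end_linker(k + 1L, "L2link")
    parts
  })
}

#' Simulate every step of an assembly plan
#'
#' Runs each plan step through [simulate_reaction()] in order, feeding loaded
#' level-1 and level-M products forward, and returns the final level-2
#' product. When `parts` is omitted they are generated with [plan_parts()];
#' if a seed's random fillers happen to recreate a recognition motif across a
#' junction the parts are regenerated from a derived seed until the full plan
#' simulates cleanly (bounded retries), keeping the result deterministic.
#'
#' @param plan An [plan_assembly()] result.
#' @param parts Optional named part list (see [plan_parts()]).
#' @param seed Seed used when generating parts.
#' @param max_tries Maximum part-generation attempts.
#' @return List with `final` (the level-2 `assembly_result`), `products`
#'   (named list of intermediate product parts), `step_results` and
#'   `diagnostics` (character vector pooled over steps).
#' @export
simulate_plan <- function(plan, parts = NULL, seed = 1L, max_tries = 25L) {
  stopifnot(inherits(plan, "assembly_plan"))
  if (!is.null(parts)) return(.run_plan(plan, parts))
  res <- NULL
  for (try in seq_len(max_tries)) {
    parts_try <- plan_parts(plan, seed + (try - 1L) * 1000L)
    # a spurious recognition motif across a random-filler junction can make a
    # step fail or even produce clashing cut sites; both trigger a retry
    res <- tryCatch(.run_plan(plan, parts_try), error = function(e) {
      list(final = NULL, products = list(), step_results = list(),
           diagnostics = conditionMessage(e))
    })
    if (!length(res$diagnostics)) return(res)
  }
  res
}

.run_plan <- function(plan, parts) {
  products <- list()
  step_results <- list()
  diags <- character(0)
  s <- plan$steps
  for (i in seq_len(nrow(s))) {
    enz <- typeIIS_enzymes(strsplit(s$enzymes[i], ";")[[1]])
    ins_ids <- strsplit(s$insert_ids[i], ";")[[1]]
    inserts <- lapply(ins_ids, function(id) {
      if (!is.null(products[[id]])) products[[id]]
      else if (!is.null(parts[[id]])) parts[[id]]
      else stop("no part or product with id ", id, call. = FALSE)
    })
    if (s$level[i] == "LM") {
      inserts <- c(inserts, parts[sprintf("LMlink_%d", s$position_index[i])])
    } else if (s$level[i] == "L2") {
      inserts <- c(inserts, parts["L2link"])
    }
    acc <- if (!is.null(products[[s$accepter_id[i]]])) products[[s$accepter_id[i]]]
           else parts[[s$accepter_id[i]]]
    if (is.null(acc)) stop("no accepter part with id ", s$accepter_id[i],
                           call. = FALSE)
    res <- simulate_reaction(acc, inserts, enz, product_id = s$product_id[i])
    step_results[[s$product_id[i]]] <- res
    diags <- c(diags, res$diagnostics)
    if (is.null(res$product)) {
      return(list(final = res, products = products,
                  step_results = step_results, diagnostics = diags))
    }
    products[[s$product_id[i]]] <- res$product
  }
  list(final = step_results[[s$product_id[nrow(s)]]], products = products,
       step_results = step_results, diagnostics = diags)
}

#' Write parts or a product to FASTA with a JSON annotation sidecar
#'
#' @param parts List of [gg_part()]s (or a single part).
#' @param fasta_path Output FASTA path.
#' @param json_path Optional path for annotations/topology metadata.
#' @export
write_parts <- function(parts, fasta_path, json_path = NULL) {
  if (inherits(parts, "gg_part")) parts <- list(parts)
  seqs <- Biostrings::DNAStringSet(vapply(parts, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(parts, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(json_path)) {
    meta <- lapply(parts, function(p) {
      list(id = p$id, circular = p$circular, role = p$role,
           annotations = p$annotations)
    })
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(fasta_path)
}
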