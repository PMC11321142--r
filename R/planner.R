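# GoldenGate cloning plan construction (level 1 -> optional level M -> level 2)

.CAPACITY <- 26L  # toolkit limit on guides per final level-2 vector

.U6_CLASS <- "TaU6"
.U3_CLASS <- c("TaU3", "HvU3")

.promoter_class <- function(p) ifelse(p %in% .U6_CLASS, "U6", "U3")

#' Assign pol III promoters along a tandem guide array
#'
#' Honors explicit preferences and otherwise alternates U6-class (TaU6) and
#' U3-class (TaU3/HvU3) promoters along the final tandem order, so that no two
#' adjacent cassettes share a promoter class. Alternation avoids the bacterial
#' recombination problems caused by repetitive tandem arrays during cloning.
#' If preferences force two adjacent cassettes into the same class a warning
#' is emitted (the assignment is still returned).
#'
#' @param preferences Character vector along the tandem order; entries are
#'   `"TaU6"`, `"TaU3"`, `"HvU3"` or `NA` (unconstrained).
#' @return Character vector of promoters, same length as `preferences`.
#' @examples
#' assign_promoters(rep(NA, 4))
#' @export
assign_promoters <- function(preferences) {
  n <- length(preferences)
  if (n == 0L) stop("no guides supplied", call. = FALSE)
  bad <- !is.na(preferences) & !(preferences %in% c(.U6_CLASS, .U3_CLASS))
  if (any(bad)) {
    stop("unknown promoter preference: ",
         paste(unique(preferences[bad]), collapse = ", "), call. = FALSE)
  }
  out <- character(n)
  prev_class <- ""
  for (i in seq_len(n)) {
    if (!is.na(preferences[i])) {
      out[i] <- preferences[i]
    } else {
      out[i] <- if (prev_class == "U6") "TaU3" else "TaU6"
    }
    prev_class <- .promoter_class(out[i])
  }
  if (n > 1L) {
    cls <- .promoter_class(out)
    same <- which(cls[-1] == cls[-n])
    if (length(same)) {
      warning("promoter preferences force adjacent same-class promoters at ",
              "position(s) ", paste(same, collapse = ", "), call. = FALSE)
    }
  }
  out
}

.validate_guides <- function(guides, config) {
  if (is.null(guides) || nrow(guides) == 0L) {
    stop("at least one guide is required", call. = FALSE)
  }
  req <- c("label", "protospacer", "nuclease")
  miss <- setdiff(req, names(guides))
  if (length(miss)) stop("guides table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(guides) > .CAPACITY) {
    stop(sprintf("toolkit capacity is %d guides per level-2 vector (got %d)",
                 .CAPACITY, nrow(guides)), call. = FALSE)
  }
  if (!all(guides$nuclease %in% c("Cas9", "Cas12a"))) {
    stop("guide nuclease must be 'Cas9' or 'Cas12a'", call. = FALSE)
  }
  if (anyDuplicated(guides$label)) stop("guide labels must be unique", call. = FALSE)
  if (!"architecture_family" %in% names(guides)) guides$architecture_family <- NA
  if (!"promoter" %in% names(guides)) guides$promoter <- NA
  bad9 <- guides$nuclease == "Cas9" &
    !is.na(guides$architecture_family) & guides$architecture_family != "A"
  bad12 <- guides$nuclease == "Cas12a" &
    !is.na(guides$architecture_family) &
    !(guides$architecture_family %in% c("V2", "V3"))
  if (any(bad9) || any(bad12)) {
    stop("architecture family A is Cas9-only; V2/V3 are Cas12a-only",
         call. = FALSE)
  }
  if (any(guides$nuclease == "Cas9") && !config$use_cas9) {
    stop("guides include Cas9 but config does not request a Cas9 vector",
         call. = FALSE)
  }
  if (any(guides$nuclease == "Cas12a") && !config$use_cas12a) {
    stop("guides include Cas12a but config does not request a Cas12a vector",
         call. = FALSE)
  }
  guides
}

# greedy fill-to-k packing of indices, preserving order
.pack <- function(idx, k) {
  if (!length(idx)) return(list())
  split(idx, ceiling(seq_along(idx) / k))
}

#' Build a GoldenGate assembly plan
#'
#' Produces the ordered cloning plan implementing the toolkit routing rules:
#' one level-1 oligo-insertion step per guide (BsaI); with up to 4 guides the
#' loaded level-1 cassettes go straight into the level-2 binary vector
#' (BsaI + BpiI); with more than 4, cassettes are first greedily packed in
#' groups of up to `max_inserts_per_step` into intermediate level-M vectors
#' (BpiI), which are then combined in the level-2 step (BsaI + BpiI). With
#' both nucleases requested, Cas9 and Cas12a guides form two consecutive
#' sub-arrays, each packed independently. Promoters are assigned with
#' [assign_promoters()] along the final tandem order.
#'
#' @param guides Data frame with columns `label`, `protospacer`, `nuclease`
#'   and optionally `architecture_family` (`"A"`, `"V2"`, `"V3"`) and
#'   `promoter` preference.
#' @param config A [planner_config()].
#' @return Object of class `assembly_plan`: a list with `steps` (data frame:
#'   `level`, `accepter_id`, `insert_ids` (";"-joined), `enzymes`
#'   (";"-joined), `position_index`), `binary_vector`, `guides` (augmented
#'   with `architecture`, `promoter`, destination and position), and `config`.
#' @examples
#' g <- data.frame(label = paste0("g", 1:3),
#'                 protospacer = c("TACGTGGACTAGTCAGTTAG",
#'                                 "ACGTACGTACGTACGTACGT",
#'                                 "GGACTAGTCAGTTAGTACGT"),
#'                 nuclease = "Cas9")
#' plan_assembly(g, planner_config("barley", use_cas9 = TRUE))
#' @export
plan_assembly <- function(guides, config) {
  stopifnot(inherits(config, "planner_config"))
  guides <- .validate_guides(as.data.frame(guides), config)
  binary_vector <- choose_binary_vector(config)

  # final tandem order: Cas9 sub-array then Cas12a sub-array
  ord <- order(match(guides$nuclease, c("Cas9", "Cas12a")))
  guides <- guides[ord, , drop = FALSE]
  n <- nrow(guides)
  k <- config$max_inserts_per_step

  guides$promoter <- assign_promoters(
    ifelse(is.na(guides$promoter), NA, as.character(guides$promoter))
  )
  guides$architecture <- vapply(seq_len(n), function(i) {
    .arch_for(guides$nuclease[i], guides$promoter[i],
              guides$architecture_family[i])
  }, character(1))
  guides$module_id <- paste0("L1_", guides$label)

  direct <- n <= k
  if (direct) {
    groups <- list(seq_len(n))
    guides$destination <- binary_vector
    guides$position <- seq_len(n)
  } else {
    g9 <- which(guides$nuclease == "Cas9")
    g12 <- which(guides$nuclease == "Cas12a")
    groups <- c(.pack(g9, k), .pack(g12, k))
    names(groups) <- NULL
    guides$destination <- NA_character_
    guides$position <- NA_integer_
    for (j in seq_along(groups)) {
      guides$destination[groups[[j]]] <- sprintf("LM_%d", j)
      guides$position[groups[[j]]] <- seq_along(groups[[j]])
    }
  }

  steps <- list()
  for (i in seq_len(n)) {
    steps[[length(steps) + 1L]] <- data.frame(
      level = "L1",
      accepter_id = sprintf("L1acc_%s_pos%d", guides$architecture[i],
                            guides$position[i]),
      insert_ids = paste0("oligos_", guides$label[i]),
      enzymes = "BsaI",
      position_index = guides$position[i],
      product_id = guides$module_id[i],
      stringsAsFactors = FALSE
    )
  }
  if (!direct) {
    for (j in seq_along(groups)) {
      steps[[length(steps) + 1L]] <- data.frame(
        level = "LM",
        accepter_id = sprintf("LMacc_pos%d", j),
        insert_ids = paste(guides$module_id[groups[[j]]], collapse = ";"),
        enzymes = "BpiI",
        position_index = j,
        product_id = sprintf("LM_%d", j),
        stringsAsFactors = FALSE
      )
    }
    l2_inserts <- sprintf("LM_%d", seq_along(groups))
  } else {
    l2_inserts <- guides$module_id
  }
  steps[[length(steps) + 1L]] <- data.frame(
    level = "L2",
    accepter_id = binary_vector,
    insert_ids = paste(l2_inserts, collapse = ";"),
    enzymes = "BsaI;BpiI",
    position_index = 1L,
    product_id = paste0(binary_vector, "_loaded"),
    stringsAsFactors = FALSE
  )
  steps <- do.call(rbind, steps)
  rownames(steps) <- NULL

  structure(
    list(steps = steps, binary_vector = binary_vector, guides = guides,
         config = config,
         lm_groups = if (direct) NULL else groups),
    class = "assembly_plan"
  )
}

#' @export
print.assembly_plan <- function(x, ...) {
  n <- nrow(x$guides)
  nlm <- sum(x$steps$level == "LM")
  cat(sprintf("<assembly_plan> %d guide(s) -> %s (%s)\n", n, x$binary_vector,
              x$config$species))
  cat(sprintf("  route: %d x L1 (BsaI)%s -> L2 (BsaI+BpiI)\n",
              n, if (nlm) sprintf(" -> %d x LM (BpiI)", nlm) else ""))
  cat("  promoters:", paste(x$guides$promoter, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a plan to JSON
#'
#' @param plan An [plan_assembly()] result.
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @export
plan_to_json <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "assembly_plan"))
  obj <- list(
    binary_vector = plan$binary_vector,
    species = plan$config$species,
    guides = plan$guides[, c("label", "protospacer", "nuclease",
                             "architecture", "promoter", "destination",
                             "position")],
    steps = plan$steps
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
  }
}

#' Render a bench protocol for a plan
#'
#' Markdown protocol listing the oligos to order (via [design_oligo_pair()])
#' and the ordered digestion-ligation steps with their accepters and enzymes.
#'
#' @param plan An [plan_assembly()] result.
#' @param path Optional file to write; if `NULL` the text is returned.
#' @export
plan_protocol <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "assembly_plan"))
  g <- plan$guides
  lines <- c(
    sprintf("# Cloning protocol: %d guide(s) into %s", nrow(g),
            plan$binary_vector),
    "",
    "## Oligos to order",
    "",
    "| guide | architecture | forward (5'->3') | reverse (5'->3') |",
    "|---|---|---|---|"
  )
  for (i in seq_len(nrow(g))) {
    p <- design_oligo_pair(g$protospacer[i], g$architecture[i])
    lines <- c(lines, sprintf("| %s | %s | %s | %s |", g$label[i],
                              g$architecture[i], p$forward, p$reverse))
  }
  lines <- c(lines, "", "## GoldenGate steps", "")
  s <- plan$steps
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "%d. [%s] %s + {%s} with %s (position %d) -> %s",
      i, s$level[i], s$accepter_id[i],
      gsub(";", ", ", s$insert_ids[i]),
      gsub(";", " + ", s$enzymes[i]), s$position_index[i], s$product_id[i]
    ))
  }
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) txt else { writeLines(txt, path); invisible(path) }
}
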