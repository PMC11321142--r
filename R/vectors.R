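# level-2 binary vector catalogue and selection

.VECTORS <- data.frame(
  vector  = c("EC64420", "EC67842", "EC64434",
              "EC67844", "EC70364", "EC67907",
              "EC67843", "EC67841", "EC67908"),
  species = c("barley", "barley", "barley",
              "wheat", "wheat", "wheat",
              "wheat", "wheat", "wheat"),
  cas9    = c(TRUE,  FALSE, TRUE,  TRUE,  TRUE,  TRUE,  FALSE, FALSE, FALSE),
  cas12a  = c(FALSE, TRUE,  TRUE,  FALSE, FALSE, FALSE, TRUE,  TRUE,  TRUE),
  grf_option = c("none", "none", "none",
                 "none", "GRF_GIF", "GR_GRF_GIF",
                 "none", "GRF_GIF", "GR_GRF_GIF"),
  stringsAsFactors = FALSE
)

#' Binary vector catalogue
#'
#' The level-2 binary (T-DNA) vectors available in the toolkit, one row per
#' vector with the species it targets, which nuclease cassettes it carries
#' (Cas9 with 13 introns, Cas12a with 8 introns, or both), and whether a
#' GRF-GIF or dexamethasone-inducible GR-GRF-GIF transformation-boosting
#' cassette is included (wheat only).
#'
#' @return Data frame with columns `vector`, `species`, `cas9`, `cas12a`,
#'   `grf_option`.
#' @export
binary_vectors <- function() .VECTORS

#' Planner configuration
#'
#' @param species `"barley"` or `"wheat"`.
#' @param use_cas9,use_cas12a Which nuclease cassette(s) the final vector must
#'   carry; at least one must be `TRUE`.
#' @param grf_option `"none"`, `"GRF_GIF"` or `"GR_GRF_GIF"`.
#' @param max_inserts_per_step Maximum fragments ligated per level-M/level-2
#'   step (default 4, the toolkit's packing bound).
#' @return Object of class `planner_config`.
#' @export
planner_config <- function(species = c("barley", "wheat"),
                           use_cas9 = FALSE, use_cas12a = FALSE,
                           grf_option = c("none", "GRF_GIF", "GR_GRF_GIF"),
                           max_inserts_per_step = 4L) {
  species <- match.arg(species)
  grf_option <- match.arg(grf_option)
  if (!use_cas9 && !use_cas12a) {
    stop("at least one of use_cas9/use_cas12a must be TRUE", call. = FALSE)
  }
  max_inserts_per_step <- as.integer(max_inserts_per_step)
  if (max_inserts_per_step < 1L) stop("max_inserts_per_step must be >= 1", call. = FALSE)
  structure(
    list(species = species, use_cas9 = isTRUE(use_cas9),
         use_cas12a = isTRUE(use_cas12a), grf_option = grf_option,
         max_inserts_per_step = max_inserts_per_step),
    class = "planner_config"
  )
}

#' Choose the level-2 binary vector for a configuration
#'
#' Looks the requested `(species, Cas9, Cas12a, GRF option)` combination up in
#' the catalogue ([binary_vectors()]). Exactly nine combinations are
#' supported; anything else (e.g. wheat + both nucleases, or barley + any GRF
#' option) raises an error listing the nearest supported configurations.
#'
#' @param config A [planner_config()].
#' @return The vector identifier (e.g. `"EC64420"`).
#' @examples
#' choose_binary_vector(planner_config("barley", use_cas9 = TRUE))
#' @export
choose_binary_vector <- function(config) {
  stopifnot(inherits(config, "planner_config"))
  hit <- .VECTORS$species == config$species &
    .VECTORS$cas9 == config$use_cas9 &
    .VECTORS$cas12a == config$use_cas12a &
    .VECTORS$grf_option == config$grf_option
  if (sum(hit) == 1L) return(.VECTORS$vector[hit])
  # no vector: rank catalogue rows by number of matching fields
  score <- (.VECTORS$species == config$species) +
    (.VECTORS$cas9 == config$use_cas9) +
    (.VECTORS$cas12a == config$use_cas12a) +
    (.VECTORS$grf_option == config$grf_option)
  near <- .VECTORS[score == max(score), ]
  stop(sprintf(
    paste0("no binary vector supports species=%s cas9=%s cas12a=%s grf=%s; ",
           "nearest supported: %s"),
    config$species, config$use_cas9, config$use_cas12a, config$grf_option,
    paste(sprintf("%s (%s%s%s, grf=%s)", near$vector, near$species,
                  ifelse(near$cas9, " +Cas9", ""),
                  ifelse(near$cas12a, " +Cas12a", ""), near$grf_option),
          collapse = "; ")
  ), call. = FALSE)
}
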