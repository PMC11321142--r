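# efficiency statistics: binomial GLM + LRT, crossed ANOVA, summaries, synergy

.check_outcomes <- function(outcomes) {
  req <- c("plant_id", "construct", "gene")
  miss <- setdiff(req, names(outcomes))
  if (length(miss)) stop("outcomes lack column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  has_bin <- "mutated" %in% names(outcomes)
  has_pct <- "pct_mutant_alleles" %in% names(outcomes)
  if (!has_bin && !has_pct) {
    stop("outcomes need a 'mutated' flag (Sanger mode) or ",
         "'pct_mutant_alleles' (Illumina mode)", call. = FALSE)
  }
  if (has_pct) {
    p <- outcomes$pct_mutant_alleles
    if (any(!is.na(p) & (p < 0 | p > 100))) {
      stop("pct_mutant_alleles must lie in [0, 100]", call. = FALSE)
    }
  }
  outcomes
}

# binary 'mutated' column, thresholding Illumina percentages if needed
.binary_outcomes <- function(outcomes, threshold = 10) {
  outcomes <- .check_outcomes(outcomes)
  if (!"mutated" %in% names(outcomes)) {
    outcomes$mutated <- outcomes$pct_mutant_alleles > threshold
  }
  outcomes
}

#' Aggregate outcomes into a (construct, gene) proportion table
#'
#' @param outcomes Data frame with `plant_id`, `construct`, `gene` and either
#'   a logical `mutated` or a numeric `pct_mutant_alleles` column.
#' @param threshold When only `pct_mutant_alleles` is present, plants are
#'   scored mutated when it exceeds this percentage (default 10, above the
#'   few-percent artefact floor seen in wild-type controls).
#' @return Data frame `construct`, `gene`, `k` (mutated plants), `n` (plants).
#' @export
proportion_table <- function(outcomes, threshold = 10) {
  outcomes <- .binary_outcomes(outcomes, threshold)
  agg <- aggregate(cbind(k = mutated, n = 1) ~ construct + gene,
                   data = transform(outcomes, mutated = as.integer(mutated)),
                   FUN = sum)
  agg <- agg[order(agg$construct, agg$gene), ]
  rownames(agg) <- NULL
  agg
}

#' Fit a binomial GLM to a proportion table
#'
#' Logit-link binomial GLM of mutated/total counts on the supplied factors,
#' fitted by iteratively reweighted least squares. Complete separation is
#' tolerated (finite-iteration fit with a warning); non-convergence is an
#' error.
#'
#' @param table A [proportion_table()].
#' @param terms Character vector of model terms in fitting order, e.g.
#'   `c("gene", "construct")`.
#' @return A fitted `glm` object (with the term list in `attr(, "gk_terms")`).
#' @export
fit_mutagenesis_glm <- function(table, terms) {
  stopifnot(all(c("k", "n") %in% names(table)))
  bad <- setdiff(terms, names(table))
  if (length(bad)) stop("unknown model term(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (t in terms) {
    table[[t]] <- factor(table[[t]])
    if (nlevels(table[[t]]) < 2L) {
      stop("factor '", t, "' needs >= 2 levels", call. = FALSE)
    }
  }
  fml <- as.formula(paste("cbind(k, n - k) ~",
                          if (length(terms)) paste(terms, collapse = " + ")
                          else "1"))
  fit <- glm(fml, family = binomial(link = "logit"), data = table)
  if (!fit$converged) stop("IRLS did not converge", call. = FALSE)
  if (any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)) {
    warning("fitted proportions at 0/1: complete separation; ",
            "deviance-based tests remain valid but coefficients are unstable",
            call. = FALSE)
  }
  attr(fit, "gk_terms") <- terms
  fit
}

#' Likelihood-ratio test between nested binomial GLMs
#'
#' `chi2 = deviance(null) - deviance(full)` with degrees of freedom equal to
#' the parameter difference; p-value from the upper chi-squared tail.
#' Identical models give `chi2 = 0`, `p = 1`.
#'
#' @param null,full Nested fits from [fit_mutagenesis_glm()] (the null model's
#'   terms must be a subset of the full model's).
#' @return Object of class `lrt_result`: `term`, `chi2`, `df`, `p`.
#' @export
lrt <- function(null, full) {
  t0 <- attr(null, "gk_terms")
  t1 <- attr(full, "gk_terms")
  if (is.null(t0) || is.null(t1) || !all(t0 %in% t1)) {
    stop("models are not nested (null terms must be a subset of full terms)",
         call. = FALSE)
  }
  df <- df.residual(null) - df.residual(full)
  if (df < 0L) stop("models are not nested (null has more parameters)",
                    call. = FALSE)
  chi2 <- max(0, deviance(null) - deviance(full))
  p <- if (df == 0L) 1 else pchisq(chi2, df, lower.tail = FALSE)
  structure(
    list(term = paste(setdiff(t1, t0), collapse = "+"),
         chi2 = chi2, df = df, p = p),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt> %s: Chi2 = %.3g, %d df, p = %.3g\n",
              if (nzchar(x$term)) x$term else "(identical models)",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Crossed two-factor ANOVA of mutant-allele percentages
#'
#' Sequential (type-I) analysis of variance of per-plant mutant-allele
#' percentages under the crossed model `A * B` (main effects plus
#' interaction), F-tested against the residual. Factors are coded with
#' treatment contrasts in the supplied order.
#'
#' @param outcomes Illumina-mode outcomes (must carry `pct_mutant_alleles`).
#' @param factors Character pair naming the two crossing factors among the
#'   outcome columns (default `c("gene", "construct")`).
#' @return Data frame `term`, `df`, `sum_sq`, `mean_sq`, `F`, `p` including
#'   the residual row.
#' @export
anova_crossed <- function(outcomes, factors = c("gene", "construct")) {
  outcomes <- .check_outcomes(outcomes)
  if (!"pct_mutant_alleles" %in% names(outcomes)) {
    stop("crossed ANOVA needs Illumina-mode outcomes (pct_mutant_alleles)",
         call. = FALSE)
  }
  stopifnot(length(factors) == 2L)
  a <- factor(outcomes[[factors[1]]])
  b <- factor(outcomes[[factors[2]]])
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stop("each factor needs >= 2 levels", call. = FALSE)
  }
  cells <- table(a, b)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s", factors[1],
                 rownames(cells)[empty[1]], factors[2],
                 colnames(cells)[empty[2]]), call. = FALSE)
  }
  d <- data.frame(y = outcomes$pct_mutant_alleles, A = a, B = b)
  fit <- lm(y ~ A * B, data = d)
  tab <- anova(fit)
  data.frame(
    term = c(factors, paste(factors, collapse = ":"), "Residuals"),
    df = tab$Df, sum_sq = tab$`Sum Sq`, mean_sq = tab$`Mean Sq`,
    F = tab$`F value`, p = tab$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
}

#' Summarise editing efficiency per construct
#'
#' Per-gene efficiency is `100 * k / n`; the construct mean is the unweighted
#' arithmetic mean of its per-gene percentages and its standard error is the
#' standard deviation of the gene-level percentages divided by the square
#' root of the number of genes. The all-targets rate is the percentage of
#' plants mutated in every gene targeted by the construct; plants missing a
#' record for any gene are excluded from it with a warning.
#'
#' @param outcomes Outcome data frame (Sanger or Illumina mode).
#' @param threshold Illumina-to-binary threshold (see [proportion_table()]).
#' @return Object of class `efficiency_summary`: `per_gene` (data frame
#'   `construct`, `gene`, `k`, `n`, `pct`), `per_construct` (data frame
#'   `construct`, `mean_over_genes`, `se_over_genes`, `all_targets`,
#'   `n_genes`, `n_plants`).
#' @export
summarize_efficiency <- function(outcomes, threshold = 10) {
  outcomes <- .binary_outcomes(outcomes, threshold)
  tab <- proportion_table(outcomes, threshold)
  tab$pct <- 100 * tab$k / tab$n
  constructs <- unique(tab$construct)
  rows <- lapply(constructs, function(cc) {
    sub <- tab[tab$construct == cc, ]
    oc <- outcomes[outcomes$construct == cc, ]
    genes <- unique(sub$gene)
    per_plant <- table(oc$plant_id)
    complete <- names(per_plant)[per_plant == length(genes)]
    if (length(complete) < length(per_plant)) {
      warning(sprintf("construct %s: %d plant(s) missing gene records, ",
                      cc, length(per_plant) - length(complete)),
              "excluded from the all-targets rate", call. = FALSE)
    }
    occ <- oc[oc$plant_id %in% complete, ]
    all_hit <- aggregate(mutated ~ plant_id, data = occ, FUN = all)
    data.frame(
      construct = cc,
      mean_over_genes = mean(sub$pct),
      se_over_genes = if (nrow(sub) > 1L) sd(sub$pct) / sqrt(nrow(sub))
                      else NA_real_,
      all_targets = if (length(complete)) 100 * mean(all_hit$mutated)
                    else NA_real_,
      n_genes = length(genes),
      n_plants = length(per_plant),
      stringsAsFactors = FALSE
    )
  })
  structure(
    list(per_gene = tab, per_construct = do.call(rbind, rows)),
    class = "efficiency_summary"
  )
}

#' @export
print.efficiency_summary <- function(x, ...) {
  cat("<efficiency_summary>\n per gene (% mutated plants):\n")
  pg <- x$per_gene
  for (i in seq_len(nrow(pg))) {
    cat(sprintf("  %-12s %-14s %3d/%-3d = %3.0f%%\n", pg$construct[i],
                pg$gene[i], pg$k[i], pg$n[i], pg$pct[i]))
  }
  cat(" per construct:\n")
  pc <- x$per_construct
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-12s mean %3.0f%% (SE %.1f), all targets %3.0f%%\n",
                pc$construct[i], pc$mean_over_genes[i], pc$se_over_genes[i],
                pc$all_targets[i]))
  }
  invisible(x)
}

#' Additive decomposition of two enhancing features
#'
#' Given baseline efficiency and the efficiencies with feature A alone,
#' feature B alone and both combined, computes the single-feature gains
#' (`delta_a`, `delta_b`), the additive expectation
#' (`base + delta_a + delta_b`) and the synergy
#' (`combined - expected_additive`). When the additive expectation exceeds
#' 100% the decomposition is flagged saturated: the synergy cannot be
#' determined because the single effects already exceed the scale.
#'
#' @param base,with_a,with_b,combined Percentages in `[0, 100]`.
#' @return Object of class `synergy_decomposition` with fields `base`,
#'   `delta_a`, `delta_b`, `combined`, `expected_additive`, `synergy`,
#'   `saturated`.
#' @examples
#' synergy_decomposition(10, 20, 20, 30)  # purely additive: synergy 0
#' @export
synergy_decomposition <- function(base, with_a, with_b, combined) {
  vals <- c(base, with_a, with_b, combined)
  if (any(vals < 0 | vals > 100)) stop("inputs must be percentages in [0, 100]",
                                       call. = FALSE)
  delta_a <- with_a - base
  delta_b <- with_b - base
  expected <- base + delta_a + delta_b
  structure(
    list(base = base, delta_a = delta_a, delta_b = delta_b,
         combined = combined, expected_additive = expected,
         synergy = combined - expected, saturated = expected > 100),
    class = "synergy_decomposition"
  )
}

#' @export
print.synergy_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<synergy> base %.3g%% + delta_a %.3g%% + delta_b %.3g%%",
                     " = %.3g%% expected; combined %.3g%% -> synergy %.3g%%%s\n"),
              x$base, x$delta_a, x$delta_b, x$expected_additive, x$combined,
              x$synergy, if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Round percentages for display the way reports print them
#'
#' @param x Numeric percentages.
#' @return Nearest-integer percentages (raw values should be kept in
#'   machine-readable output).
#' @export
report_pct <- function(x) round(x)
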