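# efficiency statistics: GLM/LRT, crossed ANOVA, summaries, synergy

# independent ML oracle: direct maximisation of the binomial log-likelihood
# over the model's design matrix with optim (analytic gradient)
optim_glm_oracle <- function(tab, terms) {
  for (t in terms) tab[[t]] <- factor(tab[[t]])
  X <- stats::model.matrix(
    stats::as.formula(paste("~", if (length(terms)) paste(terms, collapse = "+")
                            else "1")), tab)
  k <- tab$k
  n <- tab$n
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(k * eta - n * log1p(exp(eta)))
  }
  grad <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    -drop(t(X) %*% (k - n * p))
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  p <- stats::plogis(drop(X %*% fit$par))
  # deviance vs the saturated model
  ll <- sum(stats::dbinom(k, n, p, log = TRUE))
  ll_sat <- sum(stats::dbinom(k, n, ifelse(n > 0, k / n, 0), log = TRUE))
  list(coef = fit$par, deviance = 2 * (ll_sat - ll))
}

test_that("the two-construct LRT matches a direct likelihood oracle", {
  tab <- data.frame(construct = c("c1", "c2"), gene = "g",
                    k = c(2L, 18L), n = c(20L, 20L))
  null <- fit_mutagenesis_glm(tab, character(0))
  full <- suppressWarnings(fit_mutagenesis_glm(tab, "construct"))
  got <- lrt(null, full)
  # closed-form ML: cell proportions for the full model, pooled for the null
  ll <- function(k, n, p) sum(dbinom(k, n, p, log = TRUE))
  chi2_oracle <- 2 * (ll(c(2, 18), c(20, 20), c(0.1, 0.9)) -
                      ll(c(2, 18), c(20, 20), c(0.5, 0.5)))
  expect_equal(got$chi2, chi2_oracle, tolerance = 1e-6)
  expect_equal(got$df, 1L)
  expect_lt(got$p, 1e-6)
})

test_that("GLM deviances and coefficients match the optim oracle", {
  set.seed(2024)
  for (rep in 1:20) {
    tab <- expand.grid(construct = paste0("c", 1:3), gene = paste0("g", 1:2),
                       stringsAsFactors = FALSE)
    tab$n <- sample(10:30, nrow(tab), replace = TRUE)
    tab$k <- rbinom(nrow(tab), tab$n, runif(nrow(tab), 0.15, 0.85))
    fit <- fit_mutagenesis_glm(tab, c("gene", "construct"))
    oracle <- optim_glm_oracle(tab, c("gene", "construct"))
    expect_equal(deviance(fit), oracle$deviance, tolerance = 1e-6)
    expect_equal(unname(coef(fit)), unname(oracle$coef), tolerance = 1e-4)
  }
})

test_that("LRT edge cases: identical models, non-nested, null case", {
  tab <- data.frame(construct = rep(c("c1", "c2"), each = 2),
                    gene = rep(c("g1", "g2"), 2),
                    k = c(5L, 6L, 5L, 6L), n = 20L)
  m <- fit_mutagenesis_glm(tab, "gene")
  same <- lrt(m, m)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  full <- fit_mutagenesis_glm(tab, c("gene", "construct"))
  expect_error(lrt(full, m), "not nested")
  # identical proportions across constructs: deviance change ~ 0, p ~ 1
  nullish <- lrt(m, full)
  expect_lt(nullish$chi2, 1e-8)
  expect_gt(nullish$p, 0.999)
})

test_that("LRT type-I error is calibrated under a seeded null", {
  set.seed(314159)
  reps <- 1000
  cells <- expand.grid(gene = paste0("g", 1:3), construct = c("c1", "c2"),
                       stringsAsFactors = FALSE)
  pvals <- vapply(seq_len(reps), function(r) {
    cells$n <- 20L
    cells$k <- rbinom(nrow(cells), cells$n, 0.3)
    null <- fit_mutagenesis_glm(cells, "gene")
    full <- fit_mutagenesis_glm(cells, c("gene", "construct"))
    lrt(null, full)$p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("a true construct effect is detected with high power", {
  set.seed(271828)
  reps <- 500
  cells <- expand.grid(gene = paste0("g", 1:3), construct = c("c1", "c2"),
                       stringsAsFactors = FALSE)
  p_true <- ifelse(cells$construct == "c1", plogis(-1), plogis(1))
  rejected <- vapply(seq_len(reps), function(r) {
    cells$n <- 20L
    cells$k <- rbinom(nrow(cells), cells$n, p_true)
    null <- fit_mutagenesis_glm(cells, "gene")
    full <- suppressWarnings(fit_mutagenesis_glm(cells, c("gene", "construct")))
    lrt(null, full)$p < 0.001
  }, logical(1))
  expect_gt(mean(rejected), 0.8)
})

test_that("crossed ANOVA matches a projection-matrix oracle", {
  set.seed(7)
  d <- expand.grid(gene = paste0("g", 1:3), construct = paste0("v", 1:4),
                   rep = 1:5, stringsAsFactors = FALSE)
  d$plant_id <- sprintf("p%03d", seq_len(nrow(d)))
  d$pct_mutant_alleles <- pmin(100, pmax(0, 50 + 10 * (d$gene == "g2") +
    8 * as.integer(factor(d$construct)) + rnorm(nrow(d), 0, 6)))
  got <- anova_crossed(d, c("gene", "construct"))

  # oracle: sequential SS from projections onto nested design matrices
  y <- d$pct_mutant_alleles
  A <- factor(d$gene)
  B <- factor(d$construct)
  fits <- lapply(list(y ~ 1, y ~ A, y ~ A + B, y ~ A + B + A:B), function(f) {
    qr.fitted(qr(stats::model.matrix(f)), y)
  })
  ss <- vapply(2:4, function(i) sum((fits[[i]] - fits[[i - 1]])^2), numeric(1))
  ss_res <- sum((y - fits[[4]])^2)
  expect_equal(got$sum_sq[1:3], ss, tolerance = 1e-8)
  expect_equal(got$sum_sq[4], ss_res, tolerance = 1e-8)
  # decomposition sums to the total SS
  expect_equal(sum(got$sum_sq), sum((y - mean(y))^2), tolerance = 1e-8)
  # df bookkeeping: (a-1), (b-1), (a-1)(b-1), n - ab
  expect_equal(got$df, c(2L, 3L, 6L, nrow(d) - 12L))
})

test_that("noise-free ANOVA: huge main effects, null interaction", {
  d <- expand.grid(gene = c("g1", "g2"), construct = c("v1", "v2"),
                   rep = 1:6, stringsAsFactors = FALSE)
  d$plant_id <- as.character(seq_len(nrow(d)))
  # perfectly additive cell means plus a tiny jitter for a nonzero residual
  set.seed(1)
  d$pct_mutant_alleles <- 40 + 20 * (d$gene == "g2") +
    10 * (d$construct == "v2") + rnorm(nrow(d), 0, 1e-3)
  got <- anova_crossed(d, c("gene", "construct"))
  expect_gt(got$F[1], 1e6)
  expect_gt(got$F[2], 1e6)
  expect_lt(got$p[3], Inf)
  expect_gt(got$p[3], 0.01)  # no interaction signal
  # empty cell errors with the cell named
  expect_error(anova_crossed(d[!(d$gene == "g2" & d$construct == "v2"), ],
                             c("gene", "construct")), "empty design cell")
})

test_that("per-construct summaries reproduce the worked arithmetic", {
  # three genes at 100/100/90 percent over 20 plants
  oc <- nested_outcomes(c(gA = 1, gB = 1, gC = 0.9), 20, "archB")
  s <- summarize_efficiency(oc)
  expect_equal(s$per_gene$pct, c(100, 100, 90))
  expect_equal(s$per_construct$mean_over_genes, 96.6667, tolerance = 1e-4)
  expect_equal(report_pct(s$per_construct$mean_over_genes), 97)
  expect_equal(s$per_construct$se_over_genes, sd(c(100, 100, 90)) / sqrt(3))

  # wheat-style 98/94/92 over 50 plants: mean 94.7 -> 95
  s2 <- summarize_efficiency(nested_outcomes(c(A = 0.98, B = 0.94, D = 0.92),
                                             50, "wheat"))
  expect_equal(s2$per_gene$pct, c(98, 94, 92))
  expect_equal(report_pct(s2$per_construct$mean_over_genes), 95)

  # perfectly nested outcomes: all-targets equals the lowest per-gene rate
  s3 <- summarize_efficiency(nested_outcomes(
    c(g1 = 0.68, g2 = 0.90, g3 = 0.95, g4 = 0.90), 100, "construct4"))
  expect_equal(s3$per_construct$all_targets, 68)
  expect_equal(min(s3$per_gene$pct), 68)
})

test_that("all-targets never exceeds the per-gene minimum", {
  # independent outcomes: all-targets below the minimum with high probability
  oc <- simulate_t0_cohort(c(a = 0.68, b = 0.9, c = 0.95, d = 0.9), 400,
                           "independent", seed = 12)
  s <- summarize_efficiency(oc)
  expect_lte(s$per_construct$all_targets, min(s$per_gene$pct))
  expect_lt(s$per_construct$all_targets, 60)  # near the 52% product
  # nested outcomes: equality with the minimum
  oc2 <- simulate_t0_cohort(c(a = 0.68, b = 0.9, c = 0.95, d = 0.9), 400,
                            "nested_activity", seed = 12)
  s2 <- summarize_efficiency(oc2)
  expect_equal(s2$per_construct$all_targets, min(s2$per_gene$pct))
})

test_that("plants missing gene records are excluded with a warning", {
  oc <- nested_outcomes(c(g1 = 0.5, g2 = 0.8), 10)
  oc <- oc[!(oc$plant_id == "p001" & oc$gene == "g2"), ]
  expect_warning(s <- summarize_efficiency(oc), "missing gene records")
  expect_equal(s$per_construct$n_plants, 10L)
})

test_that("Illumina percentages are thresholded into binary outcomes", {
  oc <- data.frame(plant_id = paste0("p", 1:6), construct = "c", gene = "g",
                   pct_mutant_alleles = c(0, 3.5, 9, 11, 60, 100))
  tab <- proportion_table(oc)  # default threshold 10%
  expect_equal(tab$k, 3L)
  expect_equal(tab$n, 6L)
  tab2 <- proportion_table(oc, threshold = 5)
  expect_equal(tab2$k, 4L)
  expect_error(proportion_table(transform(oc, pct_mutant_alleles = 120)),
               "0, 100")
})

test_that("synergy decomposition arithmetic and saturation flag", {
  s0 <- synergy_decomposition(10, 20, 20, 30)
  expect_equal(s0$synergy, 0)
  expect_false(s0$saturated)

  # recalcitrant-locus decomposition from per-locus efficiencies:
  # base 5, D156R alone 17, introns alone 13 (single-feature gains sum to 20),
  # combined 68 -> formula synergy 43
  s1 <- synergy_decomposition(5, 17, 13, 68)
  expect_equal(s1$delta_a + s1$delta_b, 20)
  expect_equal(s1$expected_additive, 25)
  expect_equal(s1$synergy, 43)
  expect_false(s1$saturated)

  # overall means: base 26, singles 53 and 55, combined 87
  s2 <- synergy_decomposition(26, 53, 55, 87)
  expect_equal(s2$expected_additive, 82)
  expect_false(s2$saturated)
  expect_equal(s2$synergy, 5)

  # high-baseline variant saturates the additive expectation
  s3 <- synergy_decomposition(60, 87, 89, 95)
  expect_true(s3$saturated)
  expect_equal(s3$expected_additive, 116)

  expect_error(synergy_decomposition(-1, 10, 10, 10), "percentages")
})

test_that("simulated cohorts round-trip through the GLM within 3 SE", {
  e <- c(g1 = 0.3, g2 = 0.7)
  oc <- simulate_t0_cohort(e, 200, "independent", seed = 77)
  tab <- proportion_table(oc)
  for (i in seq_len(nrow(tab))) {
    p_hat <- tab$k[i] / tab$n[i]
    se <- sqrt(e[[tab$gene[i]]] * (1 - e[[tab$gene[i]]]) / tab$n[i])
    expect_lt(abs(p_hat - e[[tab$gene[i]]]), 3 * se)
  }
})
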