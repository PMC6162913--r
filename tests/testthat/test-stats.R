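# Statistical battery: transformation, group tests, correlations, AUC,
# mixed and offset models, temporal variability.

test_that("log transform fixes 0 and preserves order", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(exp(1) - 1), 1)
  x <- c(0, 0.1, 2, 50)
  expect_true(all(diff(log_transform(x)) > 0))
  expect_error(log_transform(-1), ">= 0")
})

test_that("Welch test flags degenerate arms and separates clear shifts", {
  same <- welch_t_test(c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  sep <- welch_t_test(log_transform(c(0, 0, 0, 10, 10, 10)),
                      rep(c("a", "b"), each = 3))
  expect_lt(sep$p, 0.01)
  expect_equal(sep$tier, "*")
  # agrees with the standard Welch implementation
  set.seed(41)
  x <- rnorm(12); g <- rep(c("a", "b"), 6)
  mine <- welch_t_test(x, g)
  ref <- t.test(x[g == "b"], x[g == "a"], var.equal = FALSE)
  expect_equal(mine$p, ref$p.value)
})

test_that("exact Mann-Whitney p equals enumeration and the base oracle", {
  # {1,2,3} vs {4,5,6}: one-sided 1/20, two-sided 0.1 (20 rank splits)
  r <- mwu_fdr(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$p, 0.1)
  # identical arms -> p = 1
  r2 <- mwu_fdr(c(5, 5, 5, 5), rep(c("a", "b"), 2))
  expect_equal(r2$p, 1)
  # exact path agrees with wilcox.test's exact p on tie-free data
  set.seed(42)
  for (i in 1:10) {
    x <- sample(100, 7); y <- sample(200, 6) + 0.5
    mine <- mwu_fdr(c(x, y), rep(c("a", "b"), c(7, 6)))
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p, ref$p.value)
  }
})

test_that("BH q-values are monotone, bounded by p, and fix equal p", {
  set.seed(43)
  p <- runif(30)
  q <- stats::p.adjust(p, "BH")
  r <- mwu_fdr(rep(c(1, 2, 3, 9, 9, 10), 5),
               rep(rep(c("a", "b"), each = 3), 5),
               family = rep(letters[1:5], each = 6))
  expect_true(all(r$q >= r$p))
  # equal p across the family is a BH fixed point
  expect_equal(unique(r$q), unique(r$p))
  # monotone in p within a family
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
})

test_that("Spearman rho endpoints, ties and permutation agreement", {
  expect_equal(spearman_test(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_test(1:10, rev(1:10))$rho, -1)
  expect_true(is.na(spearman_test(1:5, rep(2, 5))$rho))
  # frozen n = 8 cases: t-approximation within 10% of the exhaustive
  # permutation p-value (computed once over all 40320 permutations)
  s1 <- spearman_test(1:8, c(4, 2, 1, 8, 7, 6, 3, 5))
  expect_equal(s1$rho, 0.3095238, tolerance = 1e-6)
  expect_equal(s1$p, 0.4618, tolerance = 0.10)
  s2 <- spearman_test(1:8, c(6, 7, 3, 4, 5, 8, 1, 2))
  expect_equal(s2$rho, -0.5)
  expect_equal(s2$p, 0.2162, tolerance = 0.10)
})

test_that("rank AUC equals brute-force pair counting and flips under swap", {
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  set.seed(44)
  for (i in 1:10) {
    sc <- sample(20, 15, replace = TRUE)  # ties included
    lab <- sample(c(0, 1), 15, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(auc(sc, lab), auc_oracle(sc, lab))
    expect_equal(auc(sc, lab), 1 - auc(sc, 1 - lab))
  }
  expect_error(auc(1:5, rep(1, 5)), "both classes")
})

test_that("GLMM recovers the fixed effect and degenerates gracefully", {
  d <- simulate_association(12, 200, beta = 1, sd_dataset = 0.5, seed = 7)
  fit <- glmm_disease(d$abundance, d$disease, d$dataset)
  expect_true(fit$converged)
  expect_equal(fit$beta, 1, tolerance = 0.25)
  expect_gt(fit$intercept_var, 0)
  # zero dataset effect: intercept variance collapses toward 0
  d0 <- simulate_association(12, 150, beta = 1, sd_dataset = 0, seed = 9)
  fit0 <- glmm_disease(d0$abundance, d0$disease, d0$dataset)
  expect_lt(fit0$intercept_var, 0.05)
  # single dataset: plain logistic fallback
  d1 <- simulate_association(1, 150, beta = 1, seed = 10)
  fit1 <- glmm_disease(d1$abundance, d1$disease, d1$dataset)
  expect_true(is.na(fit1$intercept_var))
  expect_true(fit1$converged)
})

test_that("null association yields chance-level AUC", {
  d <- simulate_association(12, 200, beta = 0, sd_dataset = 0, seed = 8)
  fit <- glmm_disease(d$abundance, d$disease, d$dataset)
  expect_equal(fit$auc, 0.5, tolerance = 0.05)
  expect_lt(abs(fit$beta), 0.25)
})

test_that("depth-offset GLM adjusts level comparisons", {
  set.seed(45)
  n <- 200
  # equal detection, equal depth: no level effect
  pres <- rep(c(TRUE, FALSE), n / 2)
  lev <- rep(c("MTG", "MTX"), each = n / 2)
  depth <- rep(4e6, n)
  r0 <- glm_mtg_vs_mtx(pres, lev, depth)
  expect_lt(abs(r0$level_effect), 0.5)
  expect_gt(r0$p, 0.05)
  # MTX depth halved but detection equal: effect favors MTX after offset
  depth2 <- ifelse(lev == "MTX", 2e6, 4e6)
  r1 <- glm_mtg_vs_mtx(pres, lev, depth2)
  expect_equal(r1$favors, "MTX")
  expect_gt(r1$level_effect, 0)
  # all-present: no information
  r2 <- glm_mtg_vs_mtx(rep(TRUE, n), lev, depth)
  expect_true(r2$degenerate)
})

test_that("taxa-function correlation separates lineage structure", {
  set.seed(46)
  datasets <- paste0("D", 1:4)
  rows <- list(); tots <- list()
  for (d in datasets) {
    n <- 30
    sid <- paste0(d, "_s", seq_len(n))
    genus_ab <- rlnorm(n, 0, 1)
    # whole-genus carrier: pathway signal proportional to the genus
    rows[[paste0(d, "a")]] <- data.frame(
      sample_id = sid, pathway = "dsrAB", genus = "Desulfovibrio",
      abundance = genus_ab * 0.8, stringsAsFactors = FALSE)
    # rare sub-lineage: pathway signal independent of the genus
    rows[[paste0(d, "b")]] <- data.frame(
      sample_id = sid, pathway = "cutCD", genus = "Clostridium",
      abundance = rlnorm(n, -2, 1), stringsAsFactors = FALSE)
    tots[[paste0(d, "a")]] <- data.frame(
      sample_id = sid, genus = "Desulfovibrio", abundance_pct = genus_ab,
      stringsAsFactors = FALSE)
    tots[[paste0(d, "b")]] <- data.frame(
      sample_id = sid, genus = "Clostridium",
      abundance_pct = rlnorm(n, 0, 1), stringsAsFactors = FALSE)
  }
  gp <- do.call(rbind, rows); gt <- do.call(rbind, tots)
  ds <- setNames(sub("_s.*", "", gp$sample_id), gp$sample_id)
  res <- taxa_function_correlation(gp, gt, ds)
  sum_tab <- res$summary
  whole <- sum_tab[sum_tab$genus == "Desulfovibrio", ]
  subl <- sum_tab[sum_tab$genus == "Clostridium", ]
  expect_equal(whole$n_supporting, 4L)
  expect_gt(whole$mean_rho, 0.9)
  expect_lt(subl$n_supporting, 2L)
})

test_that("temporal variability formula, symmetry and scale invariance", {
  expect_equal(temporal_variability(5, 5), 0)
  expect_equal(temporal_variability(5, 0), 100)
  expect_equal(temporal_variability(4, 2), 50)
  expect_true(is.na(temporal_variability(0, 0)))
  set.seed(47)
  v1 <- runif(1000, 0, 10); v2 <- runif(1000, 0, 10); k <- runif(1000, 0.1, 9)
  expect_equal(temporal_variability(v1, v2), temporal_variability(v2, v1))
  expect_equal(temporal_variability(k * v1, k * v2),
               temporal_variability(v1, v2))
  expect_true(all(temporal_variability(v1, v2) >= 0 &
                  temporal_variability(v1, v2) <= 100))
  expect_error(temporal_variability(-1, 2), ">= 0")
})
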