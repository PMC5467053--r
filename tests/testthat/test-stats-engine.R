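# Closed-form balanced two-way ANOVA, textbook cell-mean decomposition.
twoway_oracle <- function(d) {
  a <- factor(d$genotype); b <- factor(d$drug); y <- d$value
  n <- table(a, b)[1, 1]  # balanced
  ybar <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  ss_a <- n * nlevels(b) * sum((ma - ybar)^2)
  ss_b <- n * nlevels(a) * sum((mb - ybar)^2)
  ss_ab <- n * sum((outer(ma - ybar, mb - ybar, `+`) + ybar - mab)^2)
  ss_e <- sum((y - mab[cbind(a, b)])^2)
  df_e <- length(y) - nlevels(a) * nlevels(b)
  list(
    F_a = (ss_a / (nlevels(a) - 1)) / (ss_e / df_e),
    F_b = (ss_b / (nlevels(b) - 1)) / (ss_e / df_e),
    F_ab = (ss_ab / ((nlevels(a) - 1) * (nlevels(b) - 1))) / (ss_e / df_e)
  )
}

test_that("factorial ANOVA matches the closed-form balanced decomposition", {
  # fixed tiny fixture, n = 2 per cell
  d <- data.frame(
    genotype = rep(c("WT", "WT", "KO", "KO"), 2),
    drug = rep(c("SAL", "Acamp"), each = 4),
    value = c(3.1, 2.7, 5.2, 4.8, 2.9, 3.3, 6.4, 6.0)
  )
  res <- factorial_anova(d, "value")
  orc <- twoway_oracle(d)
  expect_equal(res$statistic[res$effect == "genotype"], orc$F_a,
               tolerance = 1e-10)
  expect_equal(res$statistic[res$effect == "drug"], orc$F_b,
               tolerance = 1e-10)
  expect_equal(res$statistic[res$effect == "genotype:drug"], orc$F_ab,
               tolerance = 1e-10)

  # gene-only injected effect, larger balanced design
  set.seed(8)
  d2 <- balanced_cohort(8, cell_means = c("WT:SAL" = 0, "WT:Acamp" = 0,
                                          "KO:SAL" = 2, "KO:Acamp" = 2))
  r2 <- factorial_anova(d2, "value")
  o2 <- twoway_oracle(d2)
  expect_equal(r2$statistic[r2$effect == "genotype"], o2$F_a,
               tolerance = 1e-10)

  # degenerate and malformed designs
  dconst <- d; dconst$value <- 1
  expect_error(factorial_anova(dconst, "value"), "residual variance")
  dmiss <- d[d$genotype != "KO" | d$drug != "SAL", ]
  expect_error(factorial_anova(dmiss, "value"), "empty design cell")
})

test_that("mixed ANOVA handles within factors, degeneracy and pairing", {
  # collapsing a 2-level within factor to differences reproduces the
  # paired-contrast tests
  set.seed(9)
  n <- 12
  d <- data.frame(
    animal = rep(sprintf("a%02d", 1:n), each = 2),
    genotype = rep(rep(c("WT", "KO"), each = 2), n / 2),
    within_level = rep(c("L1", "L2"), n)
  )
  d$value <- rnorm(2 * n) + (d$within_level == "L2") * 0.9 +
    rep(rnorm(n, 0, 0.8), each = 2)
  ma <- mixed_anova(d, between = "genotype")
  diffs <- tapply(d$value, d$animal, function(v) v[2] - v[1])
  g <- factor(tapply(as.character(d$genotype), d$animal, `[`, 1))
  fit <- lm(diffs ~ g, contrasts = list(g = "contr.sum"))
  tt <- summary(fit)$coefficients
  expect_equal(ma$statistic[ma$effect == "within_level"], tt[1, 3]^2,
               tolerance = 1e-5)
  expect_equal(ma$statistic[ma$effect == "genotype:within_level"],
               tt[2, 3]^2, tolerance = 1e-5)
  expect_identical(attr(ma, "covariance"), "compound symmetry")

  # within factor with identical values across levels: within F = 0
  dflat <- d
  dflat$value <- ave(dflat$value, dflat$animal, FUN = function(v) v[1])
  mflat <- mixed_anova(dflat, between = "genotype")
  expect_identical(mflat$statistic[mflat$effect == "within_level"], 0)
  expect_identical(mflat$p_raw[mflat$effect == "within_level"], 1)

  # incomplete within-subject data is refused (no imputation)
  expect_error(mixed_anova(d[-1, ], between = "genotype"), "incomplete")
})

test_that("mixed ANOVA detects within trends at calibrated between rates", {
  set.seed(10)
  n_rep <- 60
  p_within <- p_between <- numeric(n_rep)
  for (r in 1:n_rep) {
    cfg <- cohort_sim_config(
      n_per_group = c("WT:SAL" = 6, "KO:SAL" = 6),
      measures = list(m = list(
        type = "continuous", baseline = 10, sd = 1,
        within = list(levels = paste0("seg", 1:4),
                      offsets = c(0, 2, 4, 2), subject_sd = 0.5))),
      seed = 1000 + r
    )
    mt <- measure_table(simulate_cohort(cfg)$cohort, "m")
    res <- mixed_anova(mt, between = "genotype")
    p_within[r] <- res$p_raw[res$effect == "within_level"]
    p_between[r] <- res$p_raw[res$effect == "genotype"]
  }
  expect_true(all(p_within < 0.01))            # strong within trend
  expect_lt(mean(p_between < 0.05), 0.15)      # between stays near nominal
})

test_that("exact Wilcoxon equals enumeration on the worked examples", {
  expect_equal(exact_wilcoxon(c(1, 2), c(3, 4))$p.value, 2 / 6)
  expect_equal(exact_wilcoxon(c(1, 2, 3), c(4, 5, 6))$p.value, 2 / 20)
  # identical multisets: every outcome at least as extreme
  expect_equal(exact_wilcoxon(c(1, 2, 2), c(2, 1, 2))$p.value, 1)
  w <- exact_wilcoxon(c(1, 2), c(3, 4))
  expect_true(w$exact)
  expect_identical(w$support, choose(4, 2))
  expect_equal(w$statistic, 3)  # ranks 1 + 2
})

test_that("exact Wilcoxon matches the brute-force oracle under ties", {
  set.seed(11)
  for (i in 1:60) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- sample(0:4, nx, replace = TRUE)  # heavily tied ordinals
    y <- sample(0:4, ny, replace = TRUE)
    for (tails in c("two", "less", "greater")) {
      expect_equal(exact_wilcoxon(x, y, tails = tails)$p.value,
                   wilcoxon_reference(x, y, tails = tails),
                   tolerance = 1e-12)
    }
  }
})

test_that("the Monte-Carlo fallback above the cap is flagged and close", {
  x <- rnorm(8); y <- rnorm(8) + 1
  w <- exact_wilcoxon(x, y, cap = 10, n_mc = 40000, mc_seed = 4)
  expect_false(w$exact)
  expect_match(w$method, "Monte-Carlo")
  exact <- exact_wilcoxon(x, y)$p.value  # n = 16 <= default cap
  expect_lt(abs(w$p.value - exact), 0.02)
})

test_that("BH adjustment matches the hand step-up and its invariants", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03))$p_adj, rep(0.03, 3))
  expect_equal(fdr_adjust(0.2)$p_adj, 0.2)
  expect_equal(fdr_adjust(rep(1, 4))$p_adj, rep(1, 4))
  expect_identical(fdr_adjust(numeric())$p_adj, numeric())

  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))^2
    adj <- fdr_adjust(p)$p_adj
    expect_equal(adj, bh_by_hand(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # monotone in the sorted raw order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    # invariant under reordering
    perm <- sample(length(p))
    expect_equal(fdr_adjust(p[perm])$p_adj[order(perm)], adj,
                 tolerance = 1e-15)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "p_raw")
})

test_that("preplanned one-tailed contrasts follow the halving convention", {
  set.seed(13)
  x <- rnorm(10, 1); y <- rnorm(10)
  p2 <- t.test(x, y, var.equal = TRUE)$p.value
  hit <- preplanned_contrast(x, y, direction = "greater")
  miss <- preplanned_contrast(x, y, direction = "less")
  expect_equal(hit$p_raw, p2 / 2)
  expect_equal(miss$p_raw, 1 - p2 / 2)
  expect_identical(hit$tails, "one")
  # zero observed difference -> 0.5
  z <- preplanned_contrast(c(1, 2, 3), c(3, 1, 2), direction = "greater")
  expect_equal(z$p_raw, 0.5)
  expect_error(preplanned_contrast(x, y), "direction")
})

test_that("control pooling combines null arms and withholds under real differences", {
  # identical SAL and CaCl2 arms: pooled at close to the two-test rate
  pooled <- logical(150)
  for (r in seq_along(pooled)) {
    cfg <- cohort_sim_config(
      n_per_group = c("WT:SAL" = 10, "WT:CaCl2" = 10,
                      "KO:SAL" = 10, "KO:CaCl2" = 10),
      measures = list(m = list(type = "continuous", baseline = 20, sd = 5)),
      seed = 3000 + r
    )
    pl <- pool_controls(simulate_cohort(cfg)$cohort)
    pooled[r] <- pl$log$pooled[1]
  }
  # two alpha = 0.05 decision tests -> expect ~0.90 pooling rate
  expect_gt(mean(pooled), 0.82)
  expect_lt(mean(pooled), 0.98)

  # a large injected CaCl2 effect blocks pooling for that measure
  cfg2 <- cohort_sim_config(
    n_per_group = c("WT:SAL" = 10, "WT:CaCl2" = 10,
                    "KO:SAL" = 10, "KO:CaCl2" = 10),
    measures = list(m = list(type = "continuous", baseline = 20, sd = 2,
                             drug_effect = c(CaCl2 = 8))),
    seed = 5
  )
  pl2 <- pool_controls(simulate_cohort(cfg2)$cohort)
  expect_false(pl2$log$pooled[1])
  expect_match(pl2$log$note[1], "withheld")

  # missing CaCl2 arm: warning and no-op
  cfg3 <- cohort_sim_config(n_per_group = c("WT:SAL" = 8, "KO:SAL" = 8),
                            measures = list(m = list(type = "continuous",
                                                     baseline = 1, sd = 1)),
                            seed = 6)
  sim3 <- simulate_cohort(cfg3)
  expect_warning(pl3 <- pool_controls(sim3$cohort), "absent")
  expect_identical(pl3$cohort$drug, sim3$cohort$drug)
})

test_that("a one-SD effects-coded interaction is detected with high power", {
  set.seed(14)
  n_rep <- 120
  hits <- logical(n_rep)
  for (r in 1:n_rep) {
    d <- balanced_cohort(11, cell_means = c("WT:SAL" = 1, "WT:Acamp" = -1,
                                            "KO:SAL" = -1, "KO:Acamp" = 1))
    res <- factorial_anova(d, "value")
    hits[r] <- res$p_raw[res$effect == "genotype:drug"] < 0.05
  }
  expect_gte(mean(hits), 0.8)
})

test_that("LS means reproduce group means on balanced one-way data", {
  set.seed(15)
  d <- balanced_cohort(6)
  lm_tab <- ls_means(d)
  emp <- tapply(d$value, d$group, mean)
  expect_equal(lm_tab$lsmean[match(names(emp), lm_tab$group)],
               as.vector(emp), tolerance = 1e-10)
})
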