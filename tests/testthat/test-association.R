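# builds a minimal scored-cohort data.frame directly (no simulation) so the
# regression layer can be tested against closed-form oracles
make_scored <- function(n, outcome, mvs = rnorm(n), icm = "B", te = "B",
                        expansion = "BL4", day = 5L, err2 = FALSE,
                        err4 = FALSE, cutoff = 0.3) {
  d <- data.frame(
    embryo_id = sprintf("S%04d", seq_len(n)),
    expansion_grade = rep_len(expansion, n),
    icm_grade = rep_len(icm, n),
    te_grade = rep_len(te, n),
    nuclear_error_2cell = rep_len(err2, n),
    nuclear_error_4cell = rep_len(err4, n),
    day_of_blastulation = rep_len(day, n),
    outcome = rep_len(outcome, n),
    mvs = mvs,
    stringsAsFactors = FALSE
  )
  d$mvs_category <- classify_mvs(d$mvs, cutoff = cutoff)
  d
}

test_that("logistic OR from a 2x2 design equals the contingency cross-product", {
  # exposed: 100 events / 50 non-events; unexposed: 50 / 50 -> OR = 2
  d <- make_scored(250, outcome = c(rep("live_birth", 100),
                                    rep("no_pregnancy", 50),
                                    rep("live_birth", 50),
                                    rep("pregnancy_loss", 50)))
  d$nuclear_error_2cell <- rep(c(TRUE, FALSE), c(150, 100))
  fit <- fit_univariable(d, "nuclear_error_2cell")
  expect_equal(fit$terms$odds_ratio, (100 / 50) / (50 / 50), tolerance = 1e-6)
  expect_true(fit$converged)
  # a second table with a different cross-product
  d2 <- make_scored(200, outcome = c(rep("live_birth", 30),
                                     rep("no_pregnancy", 70),
                                     rep("live_birth", 60),
                                     rep("no_pregnancy", 40)))
  d2$nuclear_error_4cell <- rep(c(TRUE, FALSE), each = 100)
  fit2 <- fit_univariable(d2, "nuclear_error_4cell")
  expect_equal(fit2$terms$odds_ratio, (30 / 70) / (60 / 40), tolerance = 1e-6)
})

test_that("degenerate designs are rejected or flagged", {
  d <- make_scored(40, outcome = rep(c("live_birth", "no_pregnancy"), 20))
  expect_error(fit_univariable(d, "icm_grade"), "single observed level")
  expect_error(fit_univariable(d, "height"), "unknown model term")
  # perfectly separating covariate -> flagged, not silently estimated
  d$mvs <- ifelse(d$outcome == "live_birth", -2, 2) + rnorm(40, sd = 1e-3)
  fit <- fit_univariable(d, "mvs")
  expect_true(fit$separation)
})

test_that("multivariable fit recovers generating ORs and flags rank deficiency", {
  cohort <- generate_cohort(sim_config(5000, seed = 61))
  scored <- score_cohort(cohort, ref_chart)
  fit <- fit_multivariable(scored)
  gen <- c("icm_gradeB" = log(0.51), "icm_gradeC" = log(0.21),
           "mvs" = log(0.62))
  for (nm in names(gen)) {
    row <- fit$terms[fit$terms$term == nm, ]
    est <- log(row$odds_ratio)
    se <- (log(row$ci_high) - log(row$ci_low)) / (2 * qnorm(0.975))
    expect_lt(abs(est - gen[[nm]]), 2 * se)
  }
  # generating model with MVS effect only: morphology ORs ~ 1 after adjustment
  co <- default_outcome_coefficients()
  co[setdiff(names(co), c("intercept", "mvs_per_sd"))] <- 0
  cohort0 <- generate_cohort(sim_config(5000, seed = 62,
                                        outcome_coefficients = co))
  fit0 <- fit_multivariable(score_cohort(cohort0, ref_chart))
  morph <- fit0$terms[fit0$terms$term %in% c("icm_gradeB", "te_gradeB"), ]
  for (i in seq_len(nrow(morph))) {
    se <- (log(morph$ci_high[i]) - log(morph$ci_low[i])) / (2 * qnorm(0.975))
    expect_lt(abs(log(morph$odds_ratio[i])), 2 * se)
  }
  # duplicated covariate column -> aliased coefficients flagged
  dup <- scored
  dup$nuclear_error_2cell <- dup$nuclear_error_4cell
  fitd <- suppressWarnings(fit_multivariable(dup))
  expect_true(fitd$rank_deficient)
})

test_that("three-group MVS comparison: power, and boundary p for identical samples", {
  set.seed(63)
  d <- make_scored(300, outcome = rep(OUTCOME_LEVELS, each = 100),
                   mvs = c(rnorm(100, -1), rnorm(100), rnorm(100)))
  res <- compare_mvs_by_outcome(d)
  lb_pl <- res$pairwise[res$pairwise$group1 == "live_birth" &
                          res$pairwise$group2 == "pregnancy_loss", ]
  expect_lt(lb_pl$p_value, 0.001)
  expect_equal(res$summary$n, c(100L, 100L, 100L))
  expect_lt(res$summary$median[res$summary$group == "live_birth"],
            res$summary$median[res$summary$group == "pregnancy_loss"])
  # two identical samples: the rank test cannot reject
  same <- rep(seq(-1, 1, length.out = 20), 3)
  d2 <- make_scored(60, outcome = rep(OUTCOME_LEVELS, each = 20), mvs = same)
  res2 <- compare_mvs_by_outcome(d2)
  expect_equal(res2$pairwise$p_value[1], 1, tolerance = 1e-9)
  d3 <- make_scored(3, outcome = c("live_birth", "live_birth", "no_pregnancy"))
  expect_error(compare_mvs_by_outcome(d3), "2 embryos per outcome group")
})

test_that("AUC equals brute-force concordant-pair counting (ties half credit)", {
  # documented tie pattern: scores 1,2,2,3 / outcomes 0,0,1,1
  y <- c(0, 0, 1, 1)
  s <- c(1, 2, 2, 3)
  expect_equal(fast_auc(s, y), brute_auc(s, y))
  expect_equal(fast_auc(s, y), 0.875)
  expect_equal(fast_auc(c(1, 2, 3, 4), y), 1)
  set.seed(64)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(seq_len(8), n, replace = TRUE)  # many ties
    expect_equal(fast_auc(s, y), brute_auc(s, y), tolerance = 1e-12)
  }
  expect_error(fast_auc(rep(1, 10), rep(c(0, 1), 5)), "constant predictor")
  expect_error(fast_auc(1:10, rep(1, 10)), "one outcome class")
})

test_that("apparent ROC comparison behaves on separable and random scores", {
  set.seed(65)
  n <- 400
  d <- make_scored(n, outcome = ifelse(runif(n) < 0.5, "live_birth",
                                       "no_pregnancy"),
                   mvs = rnorm(n),
                   icm = sample(c("A", "B", "C"), n, replace = TRUE),
                   te = sample(c("A", "B", "C"), n, replace = TRUE))
  # random covariates: both AUCs near 0.5
  rc <- roc_compare(d)
  expect_lt(abs(rc$auc_base - 0.5), 0.07)
  expect_lt(abs(rc$auc_augmented - 0.5), 0.07)
  expect_gt(rc$p_value, 0.001)
  # perfectly separating MVS -> augmented AUC = 1
  d$mvs <- ifelse(d$outcome == "live_birth", -2, 2) + rnorm(n, sd = 0.01)
  rc2 <- roc_compare(d)
  expect_equal(rc2$auc_augmented, 1, tolerance = 1e-6)
})

test_that("cross-validated AUC is seeded-deterministic and row-order invariant", {
  cohort <- generate_cohort(sim_config(200, seed = 66))
  scored <- score_cohort(cohort, ref_chart)
  a <- cross_validate_auc(scored, k = 5, repeats = 10, seed = 9)
  b <- cross_validate_auc(scored, k = 5, repeats = 10, seed = 9)
  expect_identical(a$cv_auc_base, b$cv_auc_base)
  expect_identical(a$cv_auc_augmented, b$cv_auc_augmented)
  perm <- sample(nrow(scored))
  c2 <- cross_validate_auc(scored[perm, ], k = 5, repeats = 10, seed = 9)
  expect_equal(c2$mean_augmented, a$mean_augmented, tolerance = 0.05)
  different <- cross_validate_auc(scored, k = 5, repeats = 10, seed = 10)
  expect_false(identical(a$cv_auc_base, different$cv_auc_base))
})

test_that("cross-validation is pessimistic relative to the apparent AUC", {
  deltas <- vapply(1:10, function(s) {
    cohort <- generate_cohort(sim_config(150, seed = 200 + s))
    scored <- score_cohort(cohort, ref_chart)
    cv <- cross_validate_auc(scored, k = 5, repeats = 5, seed = s)
    cv$optimism_augmented
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("with a true MVS effect the augmented model usually wins in CV (n = 340)", {
  wins <- vapply(1:10, function(s) {
    cohort <- generate_cohort(sim_config(340, seed = 300 + s))
    scored <- score_cohort(cohort, ref_chart)
    cv <- cross_validate_auc(scored, k = 5, repeats = 20, seed = s)
    cv$mean_augmented > cv$mean_base
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("NPV cutoff sweep matches exhaustive enumeration on a small fixture", {
  # 10 embryos, hand-checkable: outcomes by decreasing MVS
  mvs <- c(2.0, 1.5, 1.0, 0.8, 0.5, 0.2, 0.0, -0.3, -0.8, -1.2)
  out <- c("no_pregnancy", "pregnancy_loss", "no_pregnancy", "live_birth",
           "no_pregnancy", "live_birth", "live_birth", "no_pregnancy",
           "live_birth", "live_birth")
  d <- make_scored(10, outcome = out, mvs = mvs)
  sel <- select_cutoff(d)
  lb <- as.integer(out == "live_birth")
  # brute-force oracle over every candidate cutoff
  cands <- sort(unique(mvs))
  cands <- cands[-length(cands)]
  npv <- vapply(cands, function(cc) mean(lb[mvs > cc] == 0), numeric(1))
  expect_equal(sel$sweep$npv, npv, tolerance = 1e-12)
  best <- max(npv)
  expect_equal(sel$npv, best, tolerance = 1e-12)
  expect_equal(sel$cutoff, min(cands[npv == best]))
  # perfectly separated MVS: NPV 1 between the groups
  d2 <- make_scored(10, outcome = rep(c("live_birth", "no_pregnancy"),
                                      each = 5),
                    mvs = c(rnorm(5, -3), rnorm(5, 3)))
  sel2 <- select_cutoff(d2)
  expect_equal(sel2$npv, 1)
  d3 <- make_scored(6, outcome = rep("live_birth", 6))
  expect_error(select_cutoff(d3), "both")
})

test_that("trend test reduces to the closed form for two strata and is powered", {
  # 2x2 closed form: chi-squared without continuity correction
  d <- make_scored(80, outcome = rep(c("live_birth", "no_pregnancy"),
                                     c(35, 45)))
  d$icm_grade <- "A"
  d$mvs_category <- rep(c("low", "high"), 40)
  lb <- as.integer(d$outcome == "live_birth")
  tab <- table(d$mvs_category, lb)
  suppressWarnings({
    tr <- trend_test(d)
    oracle <- prop.trend.test(
      c(sum(lb[d$mvs_category == "low"]), sum(lb[d$mvs_category == "high"])),
      c(sum(d$mvs_category == "low"), sum(d$mvs_category == "high")))
    chisq <- chisq.test(tab, correct = FALSE)
  })
  expect_equal(tr$statistic, unname(oracle$statistic), tolerance = 1e-9)
  expect_equal(tr$statistic, unname(chisq$statistic), tolerance = 1e-9)
  # powered replication at the published stratum rates
  rates <- c(0.85, 0.76, 0.67, 0.65, 0.48, 0.21)
  set.seed(67)
  rejections <- vapply(1:200, function(i) {
    ns <- rep(50, 6)
    events <- rbinom(6, ns, rates)
    suppressWarnings(prop.trend.test(events, ns)$p.value) < 0.001
  }, logical(1))
  expect_gte(mean(rejections), 0.99)
})

test_that("trend and rank tests hold their nominal size (type-I in [3.5%, 6.5%])", {
  set.seed(68)
  trend_p <- vapply(1:1000, function(i) {
    events <- rbinom(6, 50, 0.5)
    suppressWarnings(prop.trend.test(events, rep(50, 6))$p.value)
  }, numeric(1))
  expect_gte(mean(trend_p < 0.05), 0.035)
  expect_lte(mean(trend_p < 0.05), 0.065)

  wilcox_p <- vapply(1:1000, function(i) {
    suppressWarnings(wilcox.test(rnorm(50), rnorm(50))$p.value)
  }, numeric(1))
  expect_gte(mean(wilcox_p < 0.05), 0.035)
  expect_lte(mean(wilcox_p < 0.05), 0.065)
})

test_that("empty strata are dropped with a warning, preserving the ordering", {
  d <- make_scored(90, outcome = rep(c("live_birth", "no_pregnancy", "live_birth"), 30),
                   icm = rep(c("A", "B"), c(45, 45)))
  d$mvs_category <- rep(c("low", "high"), 45)
  expect_warning(tr <- trend_test(d), "C-low")
  expect_equal(nrow(tr$strata), 6L)
  expect_equal(sum(tr$strata$n > 0), 4L)
})

test_that("baseline table reports group percentages and test p-values", {
  cohort <- generate_cohort(sim_config(340, seed = 69))
  cohort$age <- round(rnorm(340, 34, 4), 1)
  tab <- baseline_table(cohort)
  expect_true("age" %in% tab$variable)
  icm_rows <- tab[tab$variable == "icm_grade", ]
  expect_equal(nrow(icm_rows), 3L)
  expect_equal(icm_rows$test[1], "chi-squared")
  # percentage arithmetic oracle on the live-birth column
  n_lb <- sum(cohort$outcome == "live_birth")
  n_a <- sum(cohort$icm_grade == "A" & cohort$outcome == "live_birth")
  expect_match(icm_rows$live_birth[1],
               sprintf("%d \\(%.1f\\)", n_a, 100 * n_a / n_lb))
  # chi-squared p matches the direct call
  p_direct <- suppressWarnings(
    chisq.test(table(cohort$icm_grade, cohort$outcome))$p.value)
  expect_equal(icm_rows$p_value[1], p_direct, tolerance = 1e-12)
})
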