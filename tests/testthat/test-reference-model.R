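# Fitting tests generate with monotone = "none": the rejection/clip step that
# keeps simulated annotations ordered conditions the closely spaced cleavage
# milestones (t3/t4) and would bias their marginal means by ~0.5 h, which is
# a property of the ordering constraint, not of the estimator under test.

test_that("mean and SD curves recover the generating parameters (n = 500)", {
  cohort <- generate_cohort(sim_config(500, seed = 1))
  chart <- fit_reference_chart(cohort)
  mu_err <- chart$mu - setNames(ref_params$mu, ref_params$milestone)
  expect_lt(max(abs(mu_err)), 0.5)
  sig_rel <- (chart$sigma - ref_params$sigma) / ref_params$sigma
  expect_lt(max(abs(sig_rel)), 0.15)
  # endpoint behaviour: sigma grows from sub-hour at tPB2 to ~6 h at tB
  expect_lt(abs(chart$sigma[["tPB2"]] - ref_params$sigma[1]) /
              ref_params$sigma[1], 0.15)
  expect_lt(abs(chart$sigma[["tB"]] - ref_params$sigma[15]) /
              ref_params$sigma[15], 0.15)
  expect_true(all(diff(chart$mu) > 0))
})

test_that("a homoskedastic cohort yields a flat fitted SD curve", {
  cohort <- generate_cohort(sim_config(500, seed = 2,
                                       reference_params = flat_sigma_params(5)))
  mean_fit <- fit_mean_curve(cohort)
  sigma <- fit_sd_curve(cohort, mean_fit)
  expect_true(all(abs(sigma - 5) < 0.5),
              label = paste("flat sigma within 0.5 (range",
                            paste(round(range(sigma), 2), collapse = "-"), ")"))
})

test_that("the zero-noise limit reproduces the generating mean exactly", {
  p <- ref_params
  p$sigma <- rep(1e-6, 15)
  cohort <- generate_cohort(sim_config(100, seed = 3, rho = 0,
                                       reference_params = p))
  mean_fit <- fit_mean_curve(cohort, random = "intercept_only")
  expect_equal(unname(mean_fit$mu), p$mu, tolerance = 1e-3)
  sigma <- fit_sd_curve(cohort, mean_fit)
  expect_true(all(sigma < 0.05))
})

test_that("a constant +10 h offset embryo is absorbed by its random intercept", {
  cohort <- generate_cohort(sim_config(120, seed = 4))
  shifted <- "E0007"
  for (m in MILESTONE_CODES) {
    cohort[[m]][cohort$embryo_id == shifted] <-
      cohort[[m]][cohort$embryo_id == shifted] + 10
  }
  mean_fit <- fit_mean_curve(cohort, random = "intercept_only")
  re <- lme4::ranef(mean_fit$fit)$embryo_id
  expect_equal(re[shifted, "(Intercept)"], 10, tolerance = 1.5)
  # brute-force check: the embryo's mean marginal residual is ~ +10 h
  long <- cohort_long(cohort)
  r <- long$time - mean_fit$mu[long$milestone]
  expect_equal(mean(r[long$embryo_id == shifted]), 10, tolerance = 1.5)
})

test_that("the data floor and all-missing milestones are enforced", {
  cohort <- generate_cohort(sim_config(20, seed = 5))
  expect_error(fit_mean_curve(cohort), "at least 30 embryos")
  cohort2 <- generate_cohort(sim_config(60, seed = 6))
  cohort2$tSC <- NA_real_
  expect_error(fit_mean_curve(cohort2, min_embryos = 10L), "tSC")
})

test_that("likelihood-ratio comparison behaves at the boundary and detects curvature", {
  cohort <- generate_cohort(sim_config(150, seed = 7))
  f_lin <- fit_mean_curve(cohort, basis = "linear")
  f_spl <- fit_mean_curve(cohort, basis = "spline")
  # identical models: statistic 0, p = 1
  same <- compare_models(f_lin, f_lin)
  expect_equal(same$statistic, 0, tolerance = 1e-6)
  expect_equal(same$p_value, 1)
  # the reference trajectory is curved in stage: spline wins decisively
  lrt <- compare_models(f_lin, f_spl)
  expect_gt(lrt$statistic, 0)
  expect_equal(lrt$df, 13L)
  expect_lt(lrt$p_value, 0.01)
  expect_error(compare_models(f_spl, f_lin), "nested")
  other <- generate_cohort(sim_config(150, seed = 8))
  expect_error(compare_models(fit_mean_curve(other, basis = "linear"), f_spl),
               "same data")
})

test_that("under a linear truth the spline rarely improves fit (null calibration)", {
  p <- ref_params
  p$mu <- seq(12, 110, length.out = 15)  # linear in stage
  p$sigma <- rep(2, 15)
  rejections <- vapply(1:20, function(s) {
    cohort <- generate_cohort(sim_config(60, seed = 100 + s, rho = 0,
                                         reference_params = p))
    f_lin <- fit_mean_curve(cohort, basis = "linear",
                            random = "intercept_only")
    f_spl <- fit_mean_curve(cohort, basis = "spline",
                            random = "intercept_only")
    suppressWarnings(compare_models(f_lin, f_spl)$p_value) < 0.05
  }, logical(1))
  expect_gte(mean(!rejections), 0.9)
})

test_that("LRT statistic is invariant to relabeling embryo ids", {
  cohort <- generate_cohort(sim_config(80, seed = 9))
  relabeled <- cohort
  relabeled$embryo_id <- sample(sprintf("X%03d", 1:80))
  a <- compare_models(fit_mean_curve(cohort, basis = "linear"),
                      fit_mean_curve(cohort, basis = "spline"))
  b <- compare_models(fit_mean_curve(relabeled, basis = "linear"),
                      fit_mean_curve(relabeled, basis = "spline"))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-6)
})

test_that("diagnostics report calibrated Z, planted outliers, and misspecification", {
  cohort <- generate_cohort(sim_config(500, seed = 10))
  chart <- fit_reference_chart(cohort)
  d <- diagnose_fit(cohort, chart)
  expect_lt(abs(d$pooled$mean), 0.05)
  expect_gt(d$pooled$sd, 0.93)
  expect_lt(d$pooled$sd, 1.07)
  # with rho = 0.5 half the Z variance is the shared embryo factor, so
  # consecutive within-embryo Z-scores correlate near rho
  expect_equal(d$lag1_autocorrelation, 0.5, tolerance = 0.1)

  planted <- cohort
  for (i in 1:3) {
    m <- c("t5", "tM", "tB")[i]
    planted[[m]][i] <- chart$mu[[m]] + 6 * chart$sigma[[m]]
  }
  d2 <- diagnose_fit(planted, chart, outlier_z_threshold = 4)
  expect_equal(nrow(d2$outliers), 3L)
  expect_setequal(d2$outliers$milestone, c("t5", "tM", "tB"))
  expect_true(all(abs(d2$outliers$z) > 4))

  # misspecified chart (+5 h everywhere): pooled Z mean far from 0
  wrong <- chart
  wrong$mu <- chart$mu + 5
  d3 <- diagnose_fit(cohort, wrong)
  z_se <- d3$pooled$sd / sqrt(d3$pooled$n)
  expect_gt(abs(d3$pooled$mean), 4 * z_se)
})

test_that("charts serialize and reload exactly", {
  cohort <- generate_cohort(sim_config(60, seed = 11))
  chart <- fit_reference_chart(cohort)
  path <- tempfile(fileext = ".txt")
  write_chart(chart, path)
  back <- read_chart(path)
  expect_identical(back$milestones, chart$milestones)
  expect_equal(back$mu, chart$mu, tolerance = 0)
  expect_equal(back$sigma, chart$sigma, tolerance = 0)
  expect_equal(back$centiles, chart$centiles)
  expect_equal(back$fit_meta$n_embryos, chart$fit_meta$n_embryos)
})
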