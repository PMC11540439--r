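#' @keywords internal
live_birth_indicator <- function(cohort) {
  if (!"outcome" %in% names(cohort)) stop("no outcome column", call. = FALSE)
  bad <- !(cohort$outcome %in% OUTCOME_LEVELS)
  if (any(bad)) {
    stop("unknown outcome value(s): ",
         paste(unique(cohort$outcome[bad]), collapse = ", "), call. = FALSE)
  }
  as.integer(cohort$outcome == "live_birth")
}

# model terms exposed to the regression layer; reference levels first
MODEL_TERMS <- c("expansion_grade", "te_grade", "icm_grade",
                 "day_of_blastulation", "nuclear_error_2cell",
                 "nuclear_error_4cell", "mvs")

#' @keywords internal
prepare_model_frame <- function(scored, terms) {
  unknown <- setdiff(terms, MODEL_TERMS)
  if (length(unknown)) {
    stop("unknown model term(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(MODEL_TERMS, collapse = ", "), call. = FALSE)
  }
  d <- data.frame(y = live_birth_indicator(scored))
  for (t in terms) {
    d[[t]] <- switch(
      t,
      expansion_grade = factor(scored$expansion_grade, levels = EXPANSION_LEVELS),
      te_grade = factor(scored$te_grade, levels = GRADE_LEVELS),
      icm_grade = factor(scored$icm_grade, levels = GRADE_LEVELS),
      day_of_blastulation = factor(scored$day_of_blastulation, levels = DAY_LEVELS),
      nuclear_error_2cell = as.logical(scored$nuclear_error_2cell),
      nuclear_error_4cell = as.logical(scored$nuclear_error_4cell),
      mvs = {
        if (!"mvs" %in% names(scored)) {
          stop("cohort is not scored (no mvs column); run score_cohort() first",
               call. = FALSE)
        }
        s <- stats::sd(scored$mvs)
        if (!is.finite(s) || s == 0) stop("MVS has zero spread", call. = FALSE)
        # per-SD units: odds ratios are per one SD of the scoring cohort's MVS
        (scored$mvs - mean(scored$mvs)) / s
      }
    )
  }
  d <- d[stats::complete.cases(d), , drop = FALSE]
  for (t in terms) {
    if (is.factor(d[[t]])) {
      d[[t]] <- droplevels(d[[t]])
      if (nlevels(d[[t]]) < 2L) {
        stop("term '", t, "' has a single observed level; no contrast to fit",
             call. = FALSE)
      }
    }
  }
  d
}

#' @keywords internal
glm_or_table <- function(fit, kind, n_used) {
  sm <- summary(fit)$coefficients
  est <- sm[, 1]; se <- sm[, 2]; p <- sm[, 4]
  keep <- rownames(sm) != "(Intercept)"
  zcrit <- stats::qnorm(0.975)
  aliased <- is.na(stats::coef(fit))
  separation <- any(abs(est[keep]) > 15) || any(se[keep] > 15)
  terms <- data.frame(
    term = rownames(sm)[keep],
    odds_ratio = exp(est[keep]),
    ci_low = exp(est[keep] - zcrit * se[keep]),
    ci_high = exp(est[keep] + zcrit * se[keep]),
    p_value = p[keep],
    stringsAsFactors = FALSE
  )
  rownames(terms) <- NULL
  structure(list(
    model_kind = kind,
    terms = terms,
    n_used = n_used,
    converged = fit$converged && !any(aliased),
    rank_deficient = any(aliased),
    separation = separation,
    fit = fit
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(x$model_kind, "logistic regression for live birth (n =", x$n_used, ")\n")
  if (x$rank_deficient) cat("  ** rank-deficient design (aliased terms) **\n")
  if (x$separation) cat("  ** possible separation; estimates unreliable **\n")
  tab <- x$terms
  tab$odds_ratio <- round(tab$odds_ratio, 2)
  tab$ci_low <- round(tab$ci_low, 2)
  tab$ci_high <- round(tab$ci_high, 2)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Univariable logistic regression of live birth on one embryo characteristic
#'
#' The endpoint is live birth vs not (pregnancy loss and no pregnancy pooled).
#' Categorical terms use the conventional reference levels (expansion BL3,
#' TE A, ICM A, Day 5, no nuclear error); `"mvs"` enters in per-SD units
#' (standardized by the scoring cohort's MVS SD). Odds ratios are reported
#' with Wald 95% CIs.
#'
#' @param scored a scored cohort ([score_cohort()]).
#' @param term one of `expansion_grade`, `te_grade`, `icm_grade`,
#'   `day_of_blastulation`, `nuclear_error_2cell`, `nuclear_error_4cell`, `mvs`.
#' @return An `association_result` (term table with OR, 95% CI, p; flags for
#'   separation / rank deficiency).
#' @export
fit_univariable <- function(scored, term) {
  stopifnot(length(term) == 1L)
  d <- prepare_model_frame(scored, term)
  fit <- suppressWarnings(
    stats::glm(stats::reformulate(term, "y"), data = d, family = stats::binomial()))
  glm_or_table(fit, "univariable", nrow(d))
}

#' Multivariable logistic regression of live birth
#'
#' Adjusted model including expansion grade, TE grade, ICM grade, day of
#' blastulation, nuclear errors at the 2- and 4-cell stage, and MVS (per SD),
#' simultaneously.
#'
#' @param scored a scored cohort.
#' @param terms model terms (default: the full adjusted set).
#' @return An `association_result`.
#' @export
fit_multivariable <- function(scored, terms = MODEL_TERMS) {
  d <- prepare_model_frame(scored, terms)
  fit <- suppressWarnings(
    stats::glm(stats::reformulate(terms, "y"), data = d, family = stats::binomial()))
  glm_or_table(fit, "multivariable", nrow(d))
}

#' Compare MVS distributions across the three transfer outcomes
#'
#' Medians and IQRs per outcome group plus pairwise two-sided Wilcoxon
#' rank-sum comparisons (live birth vs pregnancy loss, live birth vs no
#' pregnancy, pregnancy loss vs no pregnancy).
#'
#' @param scored a scored cohort with the three-way `outcome`.
#' @return list with `summary` (per-group n, median, IQR) and `pairwise`
#'   (group pair, W statistic, p-value).
#' @export
compare_mvs_by_outcome <- function(scored) {
  stopifnot("mvs" %in% names(scored))
  groups <- split(scored$mvs, factor(scored$outcome, levels = OUTCOME_LEVELS))
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("need at least 2 embryos per outcome group; counts: ",
         paste(names(groups), vapply(groups, length, integer(1)),
               sep = "=", collapse = ", "), call. = FALSE)
  }
  q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    qq <- q(groups[[g]])
    data.frame(group = g, n = length(groups[[g]]),
               median = qq[2], iqr_low = qq[1], iqr_high = qq[3],
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(OUTCOME_LEVELS, 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    w <- suppressWarnings(stats::wilcox.test(groups[[pr[1]]], groups[[pr[2]]]))
    data.frame(group1 = pr[1], group2 = pr[2],
               statistic = unname(w$statistic), p_value = w$p.value,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, pairwise = pairwise)
}

#' Fast rank-based AUC (Wilcoxon form; ties get half credit)
#' @keywords internal
fast_auc <- function(score, y) {
  y <- as.logical(y)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: only one outcome class present", call. = FALSE)
  }
  if (length(unique(score)) == 1L) {
    stop("AUC undefined: constant predictor", call. = FALSE)
  }
  r <- rank(score)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Apparent (in-sample) AUC comparison of nested live-birth models
#'
#' Fits the base and the augmented logistic model on the same rows, computes
#' in-sample AUCs from the predicted probabilities, and compares the two
#' correlated ROC curves with DeLong's paired test.
#'
#' @param scored a scored cohort.
#' @param base_terms terms of the base model (default ICM + TE grade).
#' @param added_terms terms added in the augmented model (default `"mvs"`).
#' @return list of class `"roc_comparison"` with `auc_base`, `auc_augmented`,
#'   `p_value` (DeLong), `n` and the two fitted models.
#' @export
roc_compare <- function(scored,
                        base_terms = c("icm_grade", "te_grade"),
                        added_terms = "mvs") {
  d <- prepare_model_frame(scored, unique(c(base_terms, added_terms)))
  f_base <- suppressWarnings(
    stats::glm(stats::reformulate(base_terms, "y"), data = d,
               family = stats::binomial()))
  f_aug <- suppressWarnings(
    stats::glm(stats::reformulate(unique(c(base_terms, added_terms)), "y"),
               data = d, family = stats::binomial()))
  p_base <- stats::fitted(f_base)
  p_aug <- stats::fitted(f_aug)
  if (length(unique(p_base)) == 1L || length(unique(p_aug)) == 1L) {
    stop("AUC undefined: constant predictor in one of the models", call. = FALSE)
  }
  roc_base <- pROC::roc(d$y, p_base, quiet = TRUE, direction = "<")
  roc_aug <- pROC::roc(d$y, p_aug, quiet = TRUE, direction = "<")
  cmp <- pROC::roc.test(roc_base, roc_aug, paired = TRUE, method = "delong")
  structure(list(
    auc_base = as.numeric(pROC::auc(roc_base)),
    auc_augmented = as.numeric(pROC::auc(roc_aug)),
    p_value = cmp$p.value,
    n = nrow(d),
    base_terms = base_terms,
    added_terms = added_terms,
    fit_base = f_base,
    fit_augmented = f_aug
  ), class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat("Apparent AUC: base ", round(x$auc_base, 3), " vs augmented ",
      round(x$auc_augmented, 3), " (DeLong p = ", signif(x$p_value, 3),
      ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @keywords internal
stratified_folds <- function(y, k, max_resample = 20L) {
  for (attempt in seq_len(max_resample)) {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(y[fold != f])) == 2L && sum(fold == f) > 0L
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build ", k, "-fold split with both classes in every ",
       "training set", call. = FALSE)
}

#' Repeated stratified k-fold cross-validated AUC comparison
#'
#' For each repeat, rows are shuffled (seeded) into k outcome-stratified folds;
#' base and augmented logistic models are fitted on k-1 folds and the held-out
#' fold is scored. Held-out predictions are pooled within a repeat, giving one
#' cross-validated AUC per model per repeat. Reported are mean +/- SD across
#' repeats, a paired t-test across repeat-level AUC differences, and the
#' optimism (apparent minus cross-validated mean) per model.
#'
#' @inheritParams roc_compare
#' @param k number of folds (default 5).
#' @param repeats number of repeats (default 100).
#' @param seed integer seed making the whole CV schedule reproducible.
#' @return list of class `"cv_auc"`: per-repeat AUC vectors, means, SDs,
#'   paired p-value, apparent AUCs and optimism.
#' @export
cross_validate_auc <- function(scored,
                               base_terms = c("icm_grade", "te_grade"),
                               added_terms = "mvs",
                               k = 5L, repeats = 100L, seed = 1L) {
  all_terms <- unique(c(base_terms, added_terms))
  d <- prepare_model_frame(scored, all_terms)
  if (min(table(d$y)) < k) {
    stop("too few embryos in the rarer outcome class for ", k, " folds",
         call. = FALSE)
  }
  fb <- stats::reformulate(base_terms, "y")
  fa <- stats::reformulate(all_terms, "y")
  apparent <- roc_compare(scored, base_terms, added_terms)

  set.seed(seed)
  auc_base <- auc_aug <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(d$y, k)
    pb <- pa <- numeric(nrow(d))
    for (f in seq_len(k)) {
      train <- d[fold != f, , drop = FALSE]
      test <- d[fold == f, , drop = FALSE]
      mb <- suppressWarnings(stats::glm(fb, data = train, family = stats::binomial()))
      ma <- suppressWarnings(stats::glm(fa, data = train, family = stats::binomial()))
      pb[fold == f] <- stats::predict(mb, newdata = test, type = "response")
      pa[fold == f] <- stats::predict(ma, newdata = test, type = "response")
    }
    auc_base[r] <- fast_auc(pb, d$y)
    auc_aug[r] <- fast_auc(pa, d$y)
  }
  p_paired <- if (repeats > 1L) {
    if (stats::sd(auc_aug - auc_base) < 1e-12) {
      if (mean(auc_aug - auc_base) == 0) 1 else 0
    } else stats::t.test(auc_aug, auc_base, paired = TRUE)$p.value
  } else NA_real_
  structure(list(
    cv_auc_base = auc_base,
    cv_auc_augmented = auc_aug,
    mean_base = mean(auc_base), sd_base = stats::sd(auc_base),
    mean_augmented = mean(auc_aug), sd_augmented = stats::sd(auc_aug),
    p_value = p_paired,
    apparent_base = apparent$auc_base,
    apparent_augmented = apparent$auc_augmented,
    optimism_base = apparent$auc_base - mean(auc_base),
    optimism_augmented = apparent$auc_augmented - mean(auc_aug),
    k = k, repeats = repeats, seed = seed, n = nrow(d)
  ), class = "cv_auc")
}

#' @export
print.cv_auc <- function(x, ...) {
  cat("Cross-validated AUC (", x$k, "-fold x ", x$repeats, " repeats, n = ",
      x$n, ")\n", sep = "")
  cat(sprintf("  base:      %.3f +/- %.3f (apparent %.3f, optimism %.3f)\n",
              x$mean_base, x$sd_base, x$apparent_base, x$optimism_base))
  cat(sprintf("  augmented: %.3f +/- %.3f (apparent %.3f, optimism %.3f)\n",
              x$mean_augmented, x$sd_augmented, x$apparent_augmented,
              x$optimism_augmented))
  cat("  paired p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

#' @keywords internal
operating_characteristics <- function(mvs, lb, cutoff) {
  low <- mvs <= cutoff      # predicts live birth
  high <- !low              # predicts no live birth
  data.frame(
    cutoff = cutoff,
    n_low = sum(low), n_high = sum(high),
    sensitivity = if (sum(lb) > 0) mean(low[lb == 1]) else NA_real_,
    specificity = if (sum(!lb) > 0) mean(high[lb == 0]) else NA_real_,
    ppv = if (sum(low) > 0) mean(lb[low] == 1) else NA_real_,
    npv = if (sum(high) > 0) mean(lb[high] == 0) else NA_real_
  )
}

#' Select the NPV-maximizing MVS cutoff
#'
#' Sweeps every observed MVS value as a candidate cutoff (low MVS <= cutoff
#' predicts live birth, high MVS predicts no live birth) and returns the
#' cutoff maximizing the negative predictive value — the probability of no
#' live birth among high-MVS embryos — with ties broken toward the smallest
#' cutoff. Operating characteristics are reported at the selected cutoff and
#' at the conventional 0.3.
#'
#' @param scored a scored cohort.
#' @param reference_cutoff additional cutoff at which to report operating
#'   characteristics (default 0.3).
#' @return list: `cutoff`, `npv`, `at_selected` and `at_reference` (one-row
#'   data.frames of sensitivity/specificity/PPV/NPV), and the full `sweep`.
#' @export
select_cutoff <- function(scored, reference_cutoff = 0.3) {
  lb <- live_birth_indicator(scored)
  mvs <- scored$mvs
  if (length(unique(lb)) < 2L) {
    stop("cutoff selection needs both live-birth and failure outcomes",
         call. = FALSE)
  }
  cands <- sort(unique(mvs))
  cands <- cands[-length(cands)]  # keep the high group non-empty
  if (!length(cands)) stop("not enough distinct MVS values", call. = FALSE)
  sweep_tab <- do.call(rbind, lapply(cands, function(cc) {
    operating_characteristics(mvs, lb, cc)
  }))
  best <- which(sweep_tab$npv == max(sweep_tab$npv))[1]  # smallest among ties
  list(
    cutoff = sweep_tab$cutoff[best],
    npv = sweep_tab$npv[best],
    at_selected = sweep_tab[best, , drop = FALSE],
    at_reference = operating_characteristics(mvs, lb, reference_cutoff),
    sweep = sweep_tab
  )
}

#' Cochran-Armitage trend test across ICM-by-MVS strata
#'
#' Embryos are stratified by ICM grade and MVS category, ordered from the
#' most favourable (ICM A, low MVS) to the least (ICM C, high MVS):
#' A-low, B-low, C-low, A-high, B-high, C-high. Live-birth proportions per
#' stratum are tested for trend over that ordering with the Cochran-Armitage
#' test (via `stats::prop.trend.test`, equidistant scores). Empty strata are
#' dropped with a warning, preserving the ordering.
#'
#' @param scored a scored cohort with `icm_grade` and `mvs_category`.
#' @return list of class `"trend_result"`: `strata` (stratum, n, live_births,
#'   rate), `statistic`, `df`, `p_value`.
#' @export
trend_test <- function(scored) {
  stopifnot(all(c("icm_grade", "mvs_category") %in% names(scored)))
  lb <- live_birth_indicator(scored)
  order_def <- expand.grid(icm = GRADE_LEVELS, mvs = c("low", "high"),
                           stringsAsFactors = FALSE)
  strata <- do.call(rbind, lapply(seq_len(nrow(order_def)), function(i) {
    sel <- scored$icm_grade == order_def$icm[i] &
      scored$mvs_category == order_def$mvs[i]
    data.frame(
      icm_grade = order_def$icm[i], mvs_category = order_def$mvs[i],
      n = sum(sel), live_births = sum(lb[sel]),
      rate = if (sum(sel) > 0) mean(lb[sel]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  keep <- strata$n > 0
  if (any(!keep)) {
    warning("dropping empty stratum(a): ",
            paste(paste(strata$icm_grade[!keep], strata$mvs_category[!keep],
                        sep = "-"), collapse = ", "), call. = FALSE)
  }
  used <- strata[keep, , drop = FALSE]
  if (nrow(used) < 2L) stop("need at least two non-empty strata", call. = FALSE)
  tt <- suppressWarnings(
    stats::prop.trend.test(used$live_births, used$n, score = seq_len(nrow(used))))
  structure(list(
    strata = strata,
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  ), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat("Cochran-Armitage trend in live-birth rate across ICM x MVS strata\n")
  tab <- x$strata
  tab$rate <- round(100 * tab$rate, 1)
  print(tab, row.names = FALSE)
  cat("  chi-squared =", round(x$statistic, 3), "df =", x$df,
      "p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

#' Baseline descriptive table by transfer outcome
#'
#' Continuous covariates are summarised as median (IQR) per outcome group and
#' compared with the Kruskal-Wallis test; categorical covariates as n (%) per
#' group, compared with the chi-squared test.
#'
#' @param cohort a cohort data.frame.
#' @param continuous names of continuous covariate columns present.
#' @param categorical names of categorical covariate columns present.
#' @return data.frame with one row per variable level: per-group summaries and
#'   the comparison p-value (on each variable's first row).
#' @export
baseline_table <- function(cohort,
                           continuous = intersect(c("age", "bmi"), names(cohort)),
                           categorical = intersect(
                             c("cycle_type", "icm_grade", "te_grade",
                               "expansion_grade", "nuclear_error_2cell",
                               "nuclear_error_4cell", "day_of_blastulation"),
                             names(cohort))) {
  grp <- factor(cohort$outcome, levels = OUTCOME_LEVELS)
  if (any(table(grp) == 0L)) stop("empty outcome group", call. = FALSE)
  rows <- list()
  fmt_cont <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    sprintf("%.1f (%.1f to %.1f)", q[2], q[1], q[3])
  }
  for (v in continuous) {
    x <- as.numeric(cohort[[v]])
    p <- stats::kruskal.test(x, grp)$p.value
    cells <- stats::setNames(vapply(split(x, grp), fmt_cont, character(1)),
                             OUTCOME_LEVELS)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = "", t(cells), p_value = p, test = "kruskal-wallis",
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  for (v in categorical) {
    x <- factor(cohort[[v]])
    tab <- table(x, grp)
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    for (i in seq_len(nrow(tab))) {
      cells <- stats::setNames(
        sprintf("%d (%.1f)", tab[i, ], 100 * prop.table(tab, 2)[i, ]),
        OUTCOME_LEVELS)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = rownames(tab)[i], t(cells),
        p_value = if (i == 1L) p else NA_real_,
        test = if (i == 1L) "chi-squared" else "",
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:5] <- OUTCOME_LEVELS
  rownames(out) <- NULL
  out
}
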