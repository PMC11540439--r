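#' Fit the population mean curve of milestone times
#'
#' Models annotation time (hpi) as a smooth function of developmental stage
#' (the 1..15 milestone index) with a linear mixed-effect regression: a natural
#' cubic spline fixed-effect basis (by default with a knot at every milestone,
#' i.e. interior knots at stages 2..14) and embryo-level random effects, either
#' a random intercept plus a random slope over stage (default) or a random
#' intercept only. With knots at every milestone the mean curve is flexible
#' enough to track each stage's population mean.
#'
#' @param cohort cohort data.frame (wide, one row per embryo).
#' @param basis `"spline"` (natural cubic splines over stage) or `"linear"`.
#' @param knots interior knot stages for the spline basis; `"every"` places one
#'   at each interior milestone (2..14).
#' @param random `"intercept_and_slope"` or `"intercept_only"`.
#' @param REML fit by REML (default) or ML.
#' @param min_embryos,min_milestones data floor: at least `min_embryos` embryos
#'   each observed at `min_milestones`+ milestones.
#' @return An object of class `"mean_curve_fit"`: the `lme4` fit, the predicted
#'   population mean `mu` at every stage, and bookkeeping used by
#'   [fit_sd_curve()] and [compare_models()].
#' @export
fit_mean_curve <- function(cohort,
                           basis = c("spline", "linear"),
                           knots = "every",
                           random = c("intercept_and_slope", "intercept_only"),
                           REML = TRUE,
                           min_embryos = 30L,
                           min_milestones = 8L) {
  basis <- match.arg(basis)
  random <- match.arg(random)
  long <- cohort_long(cohort)
  if (any(long$time <= 0)) stop("milestone times must be positive", call. = FALSE)

  n_per <- table(long$embryo_id)
  if (sum(n_per >= min_milestones) < min_embryos) {
    stop("need at least ", min_embryos, " embryos with >= ", min_milestones,
         " observed milestones (have ", sum(n_per >= min_milestones), ")",
         call. = FALSE)
  }
  all_missing <- setdiff(MILESTONE_CODES, unique(long$milestone))
  if (length(all_missing)) {
    stop("milestone(s) with no observations: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  }

  if (identical(knots, "every")) knots <- 2:14
  fixed <- if (basis == "spline") {
    sprintf("splines::ns(stage, knots = c(%s), Boundary.knots = c(1, 15))",
            paste(knots, collapse = ", "))
  } else "stage"
  ranef_term <- if (random == "intercept_and_slope") {
    "(stage | embryo_id)"
  } else "(1 | embryo_id)"
  form <- stats::as.formula(paste("time ~", fixed, "+", ranef_term))

  fit <- withCallingHandlers(
    lme4::lmer(form, data = long, REML = REML,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage")
  )
  opt <- fit@optinfo
  if (!is.null(opt$conv$opt) && opt$conv$opt != 0) {
    stop("mean-curve model failed to converge (optimizer code ",
         opt$conv$opt, "): ",
         paste(unlist(opt$conv$lme4$messages), collapse = "; "),
         call. = FALSE)
  }
  converged <- length(opt$conv$lme4$messages) == 0L

  newd <- data.frame(stage = 1:15)
  mu <- stats::predict(fit, newdata = newd, re.form = NA)
  mu <- stats::setNames(as.numeric(mu), MILESTONE_CODES)

  structure(list(
    fit = fit,
    formula = form,
    basis = basis,
    knots = if (basis == "spline") knots else integer(0),
    random = random,
    REML = REML,
    mu = mu,
    logLik = as.numeric(stats::logLik(fit)),
    n_embryos = length(n_per),
    n_obs = nrow(long),
    converged = converged,
    data = long
  ), class = "mean_curve_fit")
}

#' @export
print.mean_curve_fit <- function(x, ...) {
  cat("Mean curve fit (", x$basis, " basis, random = ", x$random, ")\n",
      "  ", x$n_obs, " observations on ", x$n_embryos, " embryos; logLik = ",
      round(x$logLik, 2), if (!x$converged) "  [convergence warnings]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Fit the standard-deviation curve from scaled absolute residuals
#'
#' The SD curve is estimated separately from the mean curve: population-level
#' residuals (observation minus mean-curve prediction, random effects
#' excluded, so sigma measures the full between-embryo spread needed to
#' Z-score new embryos) are transformed to scaled absolute residuals
#' `|r| * sqrt(pi / 2)` — whose expectation under normality equals the local
#' SD — and regressed on the same stage spline basis. Fitted values at stages
#' 1..15 are the sigma curve.
#'
#' @param cohort cohort data.frame (same data the mean model was fitted on).
#' @param mean_fit a [fit_mean_curve()] result.
#' @param knots interior knots for the SD-curve spline (default as mean curve).
#' @return Named numeric vector `sigma` over the 15 milestones, with the
#'   underlying `lm` fit as attribute `"fit"`.
#' @export
fit_sd_curve <- function(cohort, mean_fit, knots = "every") {
  stopifnot(inherits(mean_fit, "mean_curve_fit"))
  long <- cohort_long(cohort)
  r <- long$time - mean_fit$mu[long$milestone]
  if (identical(knots, "every")) knots <- 2:14
  asr <- abs(r) * sqrt(pi / 2)
  d <- data.frame(asr = asr, stage = long$stage)
  fit <- stats::lm(
    asr ~ splines::ns(stage, knots = knots, Boundary.knots = c(1, 15)),
    data = d)
  sigma <- stats::predict(fit, newdata = data.frame(stage = 1:15))
  sigma <- stats::setNames(as.numeric(sigma), MILESTONE_CODES)
  if (any(sigma <= 0)) {
    # an essentially noise-free cohort can give numerically negative fitted
    # values; clamp those at a tiny positive floor rather than fail
    if (max(sigma) < 1e-3) {
      sigma <- pmax(sigma, 1e-9)
    } else {
      stop("fitted SD curve non-positive at milestone(s): ",
           paste(MILESTONE_CODES[sigma <= 0], collapse = ", "),
           "; reduce the spline flexibility (fewer knots)", call. = FALSE)
    }
  }
  attr(sigma, "fit") <- fit
  sigma
}

#' Fit a full reference chart (mean curve + SD curve + centile grid)
#'
#' Convenience wrapper running [fit_mean_curve()] and [fit_sd_curve()] and
#' assembling a `reference_chart`.
#'
#' @inheritParams fit_mean_curve
#' @param centiles percentiles retained on the chart.
#' @return A `reference_chart` whose `fit_meta` records sample sizes, knots,
#'   log-likelihood and convergence; the mean fit is attached as attribute
#'   `"mean_fit"` for diagnostics and model comparison.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(simulation_config(n_embryos = 60, seed = 1))
#' chart <- fit_reference_chart(cohort)
#' export_centile_grid(chart)
#' }
#' @export
fit_reference_chart <- function(cohort,
                                basis = "spline",
                                knots = "every",
                                random = c("intercept_and_slope", "intercept_only"),
                                centiles = DEFAULT_CENTILES,
                                min_embryos = 30L,
                                min_milestones = 8L) {
  random <- match.arg(random)
  mean_fit <- fit_mean_curve(cohort, basis = basis, knots = knots,
                             random = random, min_embryos = min_embryos,
                             min_milestones = min_milestones)
  sigma <- fit_sd_curve(cohort, mean_fit, knots = knots)
  if (any(diff(mean_fit$mu) <= 0)) {
    stop("fitted mean curve is not strictly increasing across stages",
         call. = FALSE)
  }
  chart <- new_reference_chart(
    milestones = MILESTONE_CODES,
    mu = mean_fit$mu,
    sigma = stats::setNames(as.numeric(sigma), MILESTONE_CODES),
    centiles = centiles,
    fit_meta = list(
      source = "fitted",
      n_embryos = mean_fit$n_embryos,
      n_observations = mean_fit$n_obs,
      basis = mean_fit$basis,
      knots = mean_fit$knots,
      random = mean_fit$random,
      logLik = mean_fit$logLik,
      converged = mean_fit$converged
    )
  )
  attr(chart, "mean_fit") <- mean_fit
  chart
}

#' Likelihood-ratio comparison of nested mean-curve models
#'
#' Both fits are refit by maximum likelihood if needed; the statistic is
#' `2 * (logLik_B - logLik_A)` on `df =` the difference in parameter counts,
#' referred to a chi-squared distribution.
#'
#' @param fitA the simpler (nested) [fit_mean_curve()] model.
#' @param fitB the richer model, fitted on the same data.
#' @return list with `statistic`, `df`, `p_value`, and the two ML log-likelihoods.
#' @export
compare_models <- function(fitA, fitB) {
  stopifnot(inherits(fitA, "mean_curve_fit"), inherits(fitB, "mean_curve_fit"))
  if (fitA$n_obs != fitB$n_obs ||
      !isTRUE(all.equal(fitA$data$time, fitB$data$time))) {
    stop("models were not fitted on the same data", call. = FALSE)
  }
  mlA <- if (fitA$REML) lme4::refitML(fitA$fit) else fitA$fit
  mlB <- if (fitB$REML) lme4::refitML(fitB$fit) else fitB$fit
  dfA <- attr(stats::logLik(mlA), "df")
  dfB <- attr(stats::logLik(mlB), "df")
  if (dfA > dfB) {
    stop("fitA must be nested in fitB (fitA has more parameters)", call. = FALSE)
  }
  llA <- as.numeric(stats::logLik(mlA))
  llB <- as.numeric(stats::logLik(mlB))
  stat <- max(0, 2 * (llB - llA))
  df <- dfB - dfA
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p, logLik_A = llA, logLik_B = llB)
}

#' Fit diagnostics for a reference chart
#'
#' Z-scores every observation against the chart and reports what a reference-
#' range fit should satisfy: per-milestone and pooled normality (Shapiro-Wilk),
#' pooled Z mean near 0 and SD near 1, the lag-1 autocorrelation of
#' within-embryo Z sequences, and a list of observations beyond the outlier
#' threshold. Embryos contributing 3+ outlying observations are flagged as
#' influential.
#'
#' @param cohort cohort the chart was fitted on.
#' @param chart a `reference_chart`.
#' @param outlier_z_threshold |Z| beyond which an observation is listed
#'   (default 4).
#' @return An object of class `"fit_diagnostics"`.
#' @export
diagnose_fit <- function(cohort, chart, outlier_z_threshold = 4) {
  stopifnot(inherits(chart, "reference_chart"), outlier_z_threshold > 0)
  long <- cohort_long(cohort)
  long$z <- (long$time - chart$mu[long$milestone]) / chart$sigma[long$milestone]

  shapiro_safe <- function(z) {
    if (length(z) < 3L) return(c(NA_real_, NA_real_))
    if (length(z) > 5000L) z <- z[seq(1L, length(z), length.out = 5000L)]
    if (stats::sd(z) < 1e-12) return(c(NA_real_, NA_real_))
    s <- stats::shapiro.test(z)
    c(unname(s$statistic), s$p.value)
  }
  per <- do.call(rbind, lapply(MILESTONE_CODES, function(m) {
    z <- long$z[long$milestone == m]
    s <- shapiro_safe(z)
    data.frame(milestone = m, n = length(z),
               z_mean = mean(z), z_sd = stats::sd(z),
               shapiro_W = s[1], shapiro_p = s[2],
               stringsAsFactors = FALSE)
  }))
  pooled_s <- shapiro_safe(long$z)

  # lag-1 autocorrelation across consecutive stages within the same embryo
  ord <- order(long$embryo_id, long$stage)
  lz <- long[ord, ]
  same <- lz$embryo_id[-1] == lz$embryo_id[-nrow(lz)] &
    diff(lz$stage) == 1L
  lag1 <- if (sum(same) >= 3L) {
    stats::cor(lz$z[-nrow(lz)][same], lz$z[-1][same])
  } else NA_real_

  out_idx <- which(abs(long$z) > outlier_z_threshold)
  outliers <- long[out_idx, c("embryo_id", "milestone", "z")]
  rownames(outliers) <- NULL
  tab <- table(outliers$embryo_id)
  influential <- names(tab)[tab >= 3L]

  structure(list(
    per_milestone = per,
    pooled = list(n = nrow(long), mean = mean(long$z), sd = stats::sd(long$z),
                  shapiro_W = pooled_s[1], shapiro_p = pooled_s[2]),
    lag1_autocorrelation = lag1,
    outliers = outliers,
    influential_embryos = influential,
    threshold = outlier_z_threshold
  ), class = "fit_diagnostics")
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat("Reference fit diagnostics (", x$pooled$n, " observations)\n",
      "  pooled Z: mean = ", signif(x$pooled$mean, 3),
      ", sd = ", signif(x$pooled$sd, 4),
      ", Shapiro p = ", signif(x$pooled$shapiro_p, 3), "\n",
      "  lag-1 autocorrelation of within-embryo Z: ",
      signif(x$lag1_autocorrelation, 3), "\n",
      "  outliers (|Z| > ", x$threshold, "): ", nrow(x$outliers),
      "; influential embryos: ", length(x$influential_embryos), "\n", sep = "")
  invisible(x)
}

#' Export the centile grid of a chart
#'
#' Grid cells are `mu_s + qnorm(p/100) * sigma_s`. By default cells are
#' rounded to 2 decimals (the printed-table convention); `digits = NULL`
#' keeps full precision, under which the grid round-trips exactly through
#' [derive_gaussian_params()].
#'
#' @param chart a `reference_chart`.
#' @param centiles percentiles (each in (0, 100)); default the chart's set.
#' @param digits decimals for the exported cells, or `NULL` for full precision.
#' @return Grid data.frame: `milestone` plus `p<percentile>` columns.
#' @export
export_centile_grid <- function(chart, centiles = NULL, digits = 2) {
  stopifnot(inherits(chart, "reference_chart"))
  if (is.null(centiles)) centiles <- chart$centiles
  if (any(centiles <= 0 | centiles >= 100)) {
    stop("percentiles must lie strictly inside (0, 100)", call. = FALSE)
  }
  centiles <- sort(centiles)
  grid <- data.frame(milestone = chart$milestones, stringsAsFactors = FALSE)
  for (p in centiles) {
    cells <- unname(chart$mu + stats::qnorm(p / 100) * chart$sigma)
    grid[[paste0("p", p)]] <- if (is.null(digits)) cells else round(cells, digits)
  }
  grid
}

#' Save / load a reference chart as a self-describing text file
#'
#' The format is a commented key-value header (metadata) followed by a CSV
#' block of `milestone, mu, sigma` at full precision; [read_chart()] restores
#' the chart exactly.
#'
#' @param chart a `reference_chart`.
#' @param path file path.
#' @return `path` invisibly ([write_chart()]); a `reference_chart`
#'   ([read_chart()]).
#' @export
write_chart <- function(chart, path) {
  stopifnot(inherits(chart, "reference_chart"))
  meta <- chart$fit_meta
  hdr <- c(
    "# mvsref reference chart v1",
    paste0("# centiles: ", paste(chart$centiles, collapse = ",")),
    paste0("# source: ", meta$source %||% "unknown"),
    paste0("# n_embryos: ", meta$n_embryos %||% "NA"),
    paste0("# n_observations: ", meta$n_observations %||% "NA"),
    paste0("# logLik: ", meta$logLik %||% "NA"),
    paste0("# converged: ", meta$converged %||% "NA"),
    "milestone,mu,sigma"
  )
  rows <- sprintf("%s,%.17g,%.17g", chart$milestones,
                  unname(chart$mu), unname(chart$sigma))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_chart
#' @export
read_chart <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# mvsref reference chart", lines[1])) {
    stop("not an mvsref chart file: ", path, call. = FALSE)
  }
  kv <- function(key, cast = identity) {
    ln <- grep(paste0("^# ", key, ": "), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    v <- sub(paste0("^# ", key, ": "), "", ln[1])
    if (v %in% c("NA", "unknown")) return(NULL)
    cast(v)
  }
  centiles <- as.numeric(strsplit(kv("centiles"), ",")[[1]])
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         stringsAsFactors = FALSE)
  params <- validate_gaussian_params(tab)
  new_reference_chart(
    milestones = params$milestone,
    mu = stats::setNames(params$mu, params$milestone),
    sigma = stats::setNames(params$sigma, params$milestone),
    centiles = centiles,
    fit_meta = list(
      source = kv("source"),
      n_embryos = kv("n_embryos", as.integer),
      n_observations = kv("n_observations", as.integer),
      logLik = kv("logLik", as.numeric),
      converged = kv("converged", as.logical)
    )
  )
}
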