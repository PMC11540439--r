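#' Z-score of a milestone time against a reference chart
#'
#' `Z = (time - mu_s) / sigma_s` for milestone `s`; dimensionless.
#'
#' @param time annotation time in hours post-insemination (> 0).
#' @param milestone milestone code (one of `milestone_schema()$code`).
#' @param chart a `reference_chart`.
#' @return Numeric Z-score (vectorised over `time`/`milestone`).
#' @examples
#' chart <- chart_from_params(derive_gaussian_params(
#'   load_reference_grid(mvsref_example_grid())))
#' z_score(109.92, "tB", chart)
#' @export
z_score <- function(time, milestone, chart) {
  stopifnot(inherits(chart, "reference_chart"), all(time > 0))
  match_milestone(milestone)
  unname((time - chart$mu[milestone]) / chart$sigma[milestone])
}

#' Percentile of a time, and quantile of a percentile, on the reference
#'
#' `percentile_of()` maps an annotation time to its reference percentile,
#' `100 * pnorm(Z)`; `quantile_of()` maps a percentile `p` in (0, 100) to the
#' reference time `mu_s + qnorm(p/100) * sigma_s`. The two are mutual inverses.
#'
#' @param time annotation time (hpi).
#' @param p percentile in (0, 100).
#' @param milestone milestone code.
#' @param chart a `reference_chart`.
#' @return Percentile in (0, 100), or time in hours.
#' @examples
#' chart <- chart_from_params(derive_gaussian_params(
#'   load_reference_grid(mvsref_example_grid())))
#' quantile_of(50, "tB", chart)
#' percentile_of(109.92, "tB", chart)
#' @export
percentile_of <- function(time, milestone, chart) {
  100 * stats::pnorm(z_score(time, milestone, chart))
}

#' @rdname percentile_of
#' @export
quantile_of <- function(p, milestone, chart) {
  stopifnot(inherits(chart, "reference_chart"))
  if (any(p <= 0 | p >= 100)) {
    stop("percentile must lie strictly inside (0, 100)", call. = FALSE)
  }
  match_milestone(milestone)
  unname(chart$mu[milestone] + stats::qnorm(p / 100) * chart$sigma[milestone])
}

# variance floor below which an MVS is flagged degenerate, and its log floor
MVS_VARIANCE_FLOOR <- 1e-12

#' Score one embryo against a reference chart
#'
#' Computes a Z-score for every observed milestone, the variance of those
#' Z-scores, and the morphokinetic variance score MVS = ln(variance). Low
#' variance means steady progression along one centile track; high variance
#' means erratic kinetics. A variance below `1e-12` (e.g. an embryo exactly on
#' the median everywhere) is degenerate: the MVS is floored at `ln(1e-12)` and
#' flagged, and such embryos classify as low-MVS.
#'
#' @param record one-row data.frame (or list) with `embryo_id` and milestone
#'   time columns; missing milestones are skipped.
#' @param chart a `reference_chart`.
#' @param min_milestones minimum observed milestones required (default 3).
#' @param cutoff MVS classification cutoff (default 0.3; see [classify_mvs()]).
#' @param variance `"sample"` (n-1 denominator, default: keeps the large-n
#'   expectation at 1 for standard-normal Z) or `"population"` (n).
#' @return A list of class `"zprofile"`: `embryo_id`, `z` (named vector over
#'   observed milestones), `n_observed`, `z_variance`, `mvs`, `degenerate`,
#'   `mvs_category`.
#' @export
score_embryo <- function(record, chart, min_milestones = 3L, cutoff = 0.3,
                         variance = c("sample", "population")) {
  variance <- match.arg(variance)
  rec <- as.list(record)
  present <- intersect(MILESTONE_CODES, names(rec))
  times <- vapply(rec[present], function(x) as.numeric(x)[1], numeric(1))
  obs <- present[!is.na(times)]
  if (length(obs) < min_milestones) {
    stop("embryo ", rec$embryo_id %||% "<unnamed>", " has only ", length(obs),
         " observed milestone(s); need >= ", min_milestones, call. = FALSE)
  }
  z <- stats::setNames(z_score(times[obs], obs, chart), obs)
  zv <- stats::var(z)
  if (variance == "population") zv <- zv * (length(z) - 1) / length(z)
  degenerate <- zv < MVS_VARIANCE_FLOOR
  mvs <- log(max(zv, MVS_VARIANCE_FLOOR))
  structure(list(
    embryo_id = rec$embryo_id %||% NA_character_,
    z = z,
    n_observed = length(obs),
    z_variance = zv,
    mvs = mvs,
    degenerate = degenerate,
    mvs_category = classify_mvs(mvs, cutoff = cutoff, degenerate = degenerate)
  ), class = "zprofile")
}

#' @export
print.zprofile <- function(x, ...) {
  cat("Z-profile for embryo ", x$embryo_id, ": ", x$n_observed,
      " milestones, variance = ", signif(x$z_variance, 4),
      ", MVS = ", round(x$mvs, 3),
      if (x$degenerate) " (degenerate)" else "",
      ", category = ", x$mvs_category, "\n", sep = "")
  invisible(x)
}

#' Classify an MVS as low or high
#'
#' Low if `mvs <= cutoff` (boundary inclusive); the default cutoff 0.3 is the
#' published NPV-maximizing point. Degenerate-variance embryos (the steadiest
#' possible) are low.
#'
#' @param mvs MVS value(s).
#' @param cutoff classification cutoff.
#' @param degenerate logical flag(s) for degenerate variance.
#' @return `"low"` or `"high"` (character, vectorised).
#' @export
classify_mvs <- function(mvs, cutoff = 0.3, degenerate = FALSE) {
  ifelse(degenerate | mvs <= cutoff, "low", "high")
}

#' Score a whole cohort against a reference chart
#'
#' Applies [score_embryo()] row-wise and appends `z_<milestone>` columns plus
#' `n_observed`, `z_variance`, `mvs`, `mvs_degenerate` and `mvs_category` to
#' the cohort.
#'
#' @inheritParams score_embryo
#' @param cohort cohort data.frame.
#' @return The cohort with scoring columns appended (class
#'   `c("mvsref_scored", ...)`).
#' @examples
#' cohort <- generate_cohort(simulation_config(n_embryos = 40, seed = 2))
#' chart <- chart_from_params(derive_gaussian_params(
#'   load_reference_grid(mvsref_example_grid())))
#' scored <- score_cohort(cohort, chart)
#' summary(scored$mvs)
#' @export
score_cohort <- function(cohort, chart, min_milestones = 3L, cutoff = 0.3,
                         variance = c("sample", "population")) {
  variance <- match.arg(variance)
  present <- intersect(MILESTONE_CODES, names(cohort))
  zmat <- matrix(NA_real_, nrow(cohort), length(present),
                 dimnames = list(NULL, paste0("z_", present)))
  for (j in seq_along(present)) {
    m <- present[j]
    zmat[, j] <- (as.numeric(cohort[[m]]) - chart$mu[m]) / chart$sigma[m]
  }
  n_obs <- rowSums(!is.na(zmat))
  if (any(n_obs < min_milestones)) {
    stop("embryo(s) with fewer than ", min_milestones,
         " observed milestones: ",
         paste(cohort$embryo_id[n_obs < min_milestones], collapse = ", "),
         call. = FALSE)
  }
  zv <- apply(zmat, 1L, stats::var, na.rm = TRUE)
  if (variance == "population") zv <- zv * (n_obs - 1) / n_obs
  degenerate <- zv < MVS_VARIANCE_FLOOR
  mvs <- log(pmax(zv, MVS_VARIANCE_FLOOR))

  out <- cbind(as.data.frame(cohort), as.data.frame(zmat))
  out$n_observed <- as.integer(n_obs)
  out$z_variance <- zv
  out$mvs <- mvs
  out$mvs_degenerate <- degenerate
  out$mvs_category <- classify_mvs(mvs, cutoff = cutoff, degenerate = degenerate)
  class(out) <- c("mvsref_scored", "data.frame")
  attr(out, "cutoff") <- cutoff
  out
}
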