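#' Configuration for the synthetic cohort generator
#'
#' Assembles and validates all knobs of [generate_cohort()]. Defaults emulate
#' the single-euploid-frozen-transfer cohort the analysis pipeline targets:
#' milestone means/SDs derived from the packaged euploid reference grid,
#' within-embryo correlation through a single latent factor (`rho`), morphology
#' and nuclear-error frequencies matching the published cohort's marginals, a
#' live-birth rate of about 55.6%, failures split into pregnancy loss vs no
#' pregnancy in the published 48:103 proportion, and outcome log-odds taken
#' from the published adjusted odds ratios (MVS 0.62 per SD; ICM B 0.51,
#' C 0.21; the remaining morphology terms near 1).
#'
#' @param n_embryos number of embryos (rows) to simulate.
#' @param reference_params `gaussian_params` data.frame of per-milestone
#'   (mu, sigma); default: derived from the packaged reference grid.
#' @param rho latent within-embryo correlation of milestone Z-scores, in
#'   `[0, 1)`. Every pair of milestones of the same embryo has correlation
#'   `rho` on the Z scale.
#' @param embryo_dispersion_sd SD of the log embryo-level variance factor
#'   (default 0 = none). Positive values make some embryos systematically
#'   steadier/more erratic, widening the MVS distribution (about 0.81 gives
#'   an MVS SD near 0.9) at the cost of heavier-than-Gaussian milestone
#'   marginals.
#' @param outcome_coefficients named list of log-odds for the live-birth model:
#'   `intercept` (`NA` = calibrate to `live_birth_rate`), `mvs_per_sd`,
#'   `expansion_BL4`, `expansion_BL5`, `te_B`, `te_C`, `icm_B`, `icm_C`,
#'   `day_6`, `day_7`, `nuclear_error_2cell`, `nuclear_error_4cell`.
#' @param live_birth_rate target overall live-birth rate used to calibrate the
#'   intercept when `outcome_coefficients$intercept` is `NA`.
#' @param pregnancy_loss_fraction_of_failures fraction of non-live-birth
#'   transfers labelled `pregnancy_loss` (rest `no_pregnancy`).
#' @param missingness_rate per-milestone probability that an annotation is
#'   missing; scalar or named vector over milestone codes. Default 0.
#' @param nuclear_error_rates length-2 probabilities of a nuclear error at the
#'   2- and 4-cell stage.
#' @param morphology_grade_probabilities list with elements `expansion`
#'   (BL3/BL4/BL5), `icm` (A/B/C), `te` (A/B/C), `day` (5/6/7); each a
#'   probability vector.
#' @param monotone how to enforce non-decreasing milestone times within an
#'   embryo: `"redraw"` (redraw the embryo's Z vector up to `max_retries`
#'   times, then clip to ordering), `"clip"` (running-maximum clip only) or
#'   `"none"` (leave raw Gaussian draws; violations possible).
#' @param max_retries retry budget per embryo under `monotone = "redraw"`.
#' @param seed integer seed; every random draw in [generate_cohort()] flows
#'   from it.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_embryos = 340,
                              reference_params = NULL,
                              rho = 0.5,
                              embryo_dispersion_sd = 0,
                              outcome_coefficients = default_outcome_coefficients(),
                              live_birth_rate = 189 / 340,
                              pregnancy_loss_fraction_of_failures = 48 / 151,
                              missingness_rate = 0,
                              nuclear_error_rates = c(196 / 340, 38 / 340),
                              morphology_grade_probabilities = default_grade_probabilities(),
                              monotone = c("redraw", "clip", "none"),
                              max_retries = 100L,
                              seed = 1L) {
  if (is.null(reference_params)) {
    reference_params <- derive_gaussian_params(
      load_reference_grid(mvsref_example_grid()))
  }
  reference_params <- validate_gaussian_params(reference_params)
  monotone <- match.arg(monotone)
  stopifnot(
    n_embryos >= 1, rho >= 0, rho < 1, embryo_dispersion_sd >= 0,
    live_birth_rate > 0, live_birth_rate < 1,
    pregnancy_loss_fraction_of_failures >= 0,
    pregnancy_loss_fraction_of_failures <= 1,
    all(missingness_rate >= 0), all(missingness_rate < 1),
    length(nuclear_error_rates) == 2L,
    all(nuclear_error_rates >= 0), all(nuclear_error_rates <= 1),
    max_retries >= 1
  )
  co <- utils::modifyList(default_outcome_coefficients(),
                          as.list(outcome_coefficients))
  gp <- utils::modifyList(default_grade_probabilities(),
                          as.list(morphology_grade_probabilities))
  for (nm in names(gp)) {
    if (any(gp[[nm]] < 0) || abs(sum(gp[[nm]]) - 1) > 1e-8) {
      stop("morphology_grade_probabilities$", nm,
           " must be non-negative and sum to 1", call. = FALSE)
    }
  }
  miss <- missingness_rate
  if (length(miss) == 1L) {
    miss <- stats::setNames(rep(miss, length(MILESTONE_CODES)), MILESTONE_CODES)
  } else {
    stopifnot(!is.null(names(miss)), all(names(miss) %in% MILESTONE_CODES))
    full <- stats::setNames(rep(0, length(MILESTONE_CODES)), MILESTONE_CODES)
    full[names(miss)] <- miss
    miss <- full
  }
  structure(list(
    n_embryos = as.integer(n_embryos),
    reference_params = reference_params,
    rho = rho,
    embryo_dispersion_sd = embryo_dispersion_sd,
    outcome_coefficients = co,
    live_birth_rate = live_birth_rate,
    pregnancy_loss_fraction_of_failures = pregnancy_loss_fraction_of_failures,
    missingness_rate = miss,
    nuclear_error_rates = nuclear_error_rates,
    morphology_grade_probabilities = gp,
    monotone = monotone,
    max_retries = as.integer(max_retries),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Default outcome log-odds (published adjusted odds ratios)
#' @keywords internal
default_outcome_coefficients <- function() {
  list(
    intercept = NA_real_,     # NA = calibrate to live_birth_rate
    mvs_per_sd = log(0.62),
    expansion_BL4 = log(1.06),
    expansion_BL5 = log(1.03),
    te_B = log(1.25),
    te_C = log(1.30),
    icm_B = log(0.51),
    icm_C = log(0.21),
    day_6 = log(1.66),
    day_7 = log(1.86),
    nuclear_error_2cell = log(1.19),
    nuclear_error_4cell = log(0.48)
  )
}

#' Default morphology-grade frequencies
#'
#' ICM/TE and nuclear-error frequencies follow the published cohort marginals;
#' expansion and day-of-blastulation frequencies are not published and use
#' plausible clinic values (most biopsied blastocysts expanded, Day 7 rare).
#' @keywords internal
default_grade_probabilities <- function() {
  list(
    expansion = stats::setNames(c(0.15, 0.45, 0.40), EXPANSION_LEVELS),
    icm = stats::setNames(c(63, 241, 36) / 340, GRADE_LEVELS),
    te = stats::setNames(c(71, 214, 55) / 340, GRADE_LEVELS),
    day = stats::setNames(c(0.70, 0.28, 0.02), as.character(DAY_LEVELS))
  )
}

#' Generate a synthetic single-euploid-transfer cohort
#'
#' Draws, for each embryo, a latent factor `u ~ N(0,1)` and per-milestone
#' Z-scores `z = sqrt(rho) * u + sqrt(1 - rho) * eps` (`eps` standard normal,
#' optionally scaled by an embryo-level dispersion factor), converts them to
#' annotation times `mu_s + sigma_s * z_s`, enforces within-embryo monotonicity
#' per the config, draws morphology grades and nuclear errors, computes the
#' true MVS from the Z-scores, and draws the transfer outcome from a logistic
#' model on standardized MVS and the categorical covariates. Fully reproducible
#' from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A data.frame of class `c("mvsref_cohort", "data.frame")`, one row
#'   per embryo, with columns `embryo_id`, the 15 milestone times (hpi),
#'   `expansion_grade`, `icm_grade`, `te_grade`, `nuclear_error_2cell`,
#'   `nuclear_error_4cell`, `day_of_blastulation`, `outcome`, and attribute
#'   `true_mvs` (the generator-side MVS before any missingness).
#' @examples
#' cohort <- generate_cohort(simulation_config(n_embryos = 50, seed = 7))
#' table(cohort$outcome)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_embryos
  p <- config$reference_params
  S <- nrow(p)
  rho <- config$rho

  u <- stats::rnorm(n)
  lam <- if (config$embryo_dispersion_sd > 0) {
    # lognormal embryo variance factor with unit mean on the variance scale
    s2 <- config$embryo_dispersion_sd
    exp(stats::rnorm(n, mean = -s2^2 / 4, sd = s2 / 2))
  } else rep(1, n)
  z <- sqrt(rho) * u + sqrt(1 - rho) * lam *
    matrix(stats::rnorm(n * S), n, S)

  times <- sweep(sweep(z, 2L, p$sigma, `*`), 2L, p$mu, `+`)

  clipped <- 0L
  if (config$monotone != "none") {
    viol <- function(tt) any(diff(tt) < 0)
    bad <- which(apply(times, 1L, viol))
    if (config$monotone == "redraw") {
      for (i in bad) {
        ok <- FALSE
        for (r in seq_len(config$max_retries)) {
          zi <- sqrt(rho) * u[i] + sqrt(1 - rho) * lam[i] * stats::rnorm(S)
          ti <- p$mu + p$sigma * zi
          if (!viol(ti)) {
            z[i, ] <- zi; times[i, ] <- ti; ok <- TRUE; break
          }
        }
        if (!ok) {
          times[i, ] <- cummax(times[i, ])
          clipped <- clipped + 1L
        }
      }
      if (clipped > 0.05 * n) {
        stop("monotonicity retry budget exhausted for ", clipped, " of ", n,
             " embryos (> 5%); lower the milestone sigmas or increase rho",
             call. = FALSE)
      }
    } else { # clip
      for (i in bad) times[i, ] <- cummax(times[i, ])
      clipped <- length(bad)
    }
  }

  gp <- config$morphology_grade_probabilities
  expansion <- sample(EXPANSION_LEVELS, n, replace = TRUE, prob = gp$expansion)
  icm <- sample(GRADE_LEVELS, n, replace = TRUE, prob = gp$icm)
  te <- sample(GRADE_LEVELS, n, replace = TRUE, prob = gp$te)
  day <- as.integer(sample(as.character(DAY_LEVELS), n, replace = TRUE,
                           prob = gp$day))
  err2 <- stats::runif(n) < config$nuclear_error_rates[1]
  err4 <- stats::runif(n) < config$nuclear_error_rates[2]

  # true MVS from the generator-side Z-scores (all milestones, n-1 variance)
  zv <- apply(z, 1L, stats::var)
  mvs <- log(pmax(zv, 1e-12))
  mvs_sd <- stats::sd(mvs)
  mvs_std <- (mvs - mean(mvs)) / if (mvs_sd > 0) mvs_sd else 1

  co <- config$outcome_coefficients
  lp <- co$mvs_per_sd * mvs_std +
    co$expansion_BL4 * (expansion == "BL4") +
    co$expansion_BL5 * (expansion == "BL5") +
    co$te_B * (te == "B") + co$te_C * (te == "C") +
    co$icm_B * (icm == "B") + co$icm_C * (icm == "C") +
    co$day_6 * (day == 6L) + co$day_7 * (day == 7L) +
    co$nuclear_error_2cell * err2 + co$nuclear_error_4cell * err4
  b0 <- co$intercept
  if (is.na(b0)) b0 <- calibrate_intercept(lp, config$live_birth_rate)
  live <- stats::runif(n) < stats::plogis(b0 + lp)
  loss <- !live & (stats::runif(n) < config$pregnancy_loss_fraction_of_failures)
  outcome <- ifelse(live, "live_birth",
                    ifelse(loss, "pregnancy_loss", "no_pregnancy"))

  # missingness last, so the outcome model saw the full profile
  for (s in seq_len(S)) {
    r <- config$missingness_rate[[p$milestone[s]]]
    if (r > 0) times[stats::runif(n) < r, s] <- NA_real_
  }

  cohort <- data.frame(
    embryo_id = sprintf("E%04d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  for (s in seq_len(S)) cohort[[p$milestone[s]]] <- round(times[, s], 3)
  cohort$expansion_grade <- expansion
  cohort$icm_grade <- icm
  cohort$te_grade <- te
  cohort$nuclear_error_2cell <- err2
  cohort$nuclear_error_4cell <- err4
  cohort$day_of_blastulation <- day
  cohort$outcome <- outcome
  attr(cohort, "true_mvs") <- mvs
  attr(cohort, "intercept") <- b0
  attr(cohort, "n_clipped") <- clipped
  class(cohort) <- c("mvsref_cohort", "data.frame")
  cohort
}

#' Solve for the logistic intercept hitting a target mean event rate
#' @keywords internal
calibrate_intercept <- function(lp, target) {
  f <- function(b0) mean(stats::plogis(b0 + lp)) - target
  stats::uniroot(f, interval = c(-20, 20), tol = 1e-10)$root
}
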