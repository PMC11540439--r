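#' Derive per-milestone Gaussian parameters from a centile grid
#'
#' A reference centile grid in which each milestone's row is Gaussian-consistent
#' (cell = mu + z_p * sigma) determines mu and sigma exactly from any symmetric
#' pair of centiles. This inverts a printed grid back to the (mu, sigma) pair
#' per milestone using the symmetric centile pair farthest apart (typically the
#' 3rd/97th): mu is the midpoint, sigma = (c_hi - c_lo) / (2 * qnorm(1 - p/100)).
#'
#' @param grid a centile grid as returned by [load_reference_grid()] or
#'   [export_centile_grid()]: column `milestone` plus numeric centile columns
#'   named `p<percentile>` (e.g. `p3`, `p50`, `p97`).
#' @return A data.frame of class `"gaussian_params"` with columns `milestone`,
#'   `mu` and `sigma` (hours), rows in developmental order.
#' @examples
#' grid <- load_reference_grid(mvsref_example_grid())
#' derive_gaussian_params(grid)
#' @export
derive_gaussian_params <- function(grid) {
  grid <- validate_grid(grid)
  pcts <- grid_percentiles(grid)
  # farthest symmetric pair available for the whole grid
  lo <- pcts[pcts < 50]
  partners <- 100 - lo
  lo <- lo[partners %in% pcts]
  if (length(lo) == 0L) {
    stop("grid needs at least one symmetric centile pair (p, 100 - p)",
         call. = FALSE)
  }
  p <- min(lo)
  zp <- stats::qnorm(1 - p / 100)
  c_lo <- grid[[paste0("p", p)]]
  c_hi <- grid[[paste0("p", 100 - p)]]
  sigma <- (c_hi - c_lo) / (2 * zp)
  if (any(sigma <= 0)) {
    stop("degenerate grid row(s) for milestone(s): ",
         paste(grid$milestone[sigma <= 0], collapse = ", "),
         " (derived sigma would be <= 0)", call. = FALSE)
  }
  out <- data.frame(
    milestone = grid$milestone,
    mu = (c_lo + c_hi) / 2,
    sigma = sigma,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gaussian_params", "data.frame")
  out
}

#' Validate Gaussian milestone parameters
#' @keywords internal
validate_gaussian_params <- function(params) {
  stopifnot(is.data.frame(params),
            all(c("milestone", "mu", "sigma") %in% names(params)))
  match_milestone(params$milestone)
  if (anyDuplicated(params$milestone)) {
    stop("duplicated milestone rows in parameters", call. = FALSE)
  }
  if (any(!is.finite(params$mu)) || any(!is.finite(params$sigma))) {
    stop("non-finite mu/sigma", call. = FALSE)
  }
  if (any(params$sigma <= 0)) stop("sigma must be > 0 for every milestone", call. = FALSE)
  ord <- order(match_milestone(params$milestone))
  params <- params[ord, , drop = FALSE]
  if (any(diff(params$mu) <= 0)) {
    stop("mu must be strictly increasing along the developmental order",
         call. = FALSE)
  }
  rownames(params) <- NULL
  params
}

#' Build a reference chart directly from Gaussian milestone parameters
#'
#' Wraps per-milestone (mu, sigma) pairs — e.g. derived from a published grid
#' via [derive_gaussian_params()] — into a chart object usable by the scoring
#' functions and by [export_centile_grid()].
#'
#' @param params a `gaussian_params` data.frame (`milestone`, `mu`, `sigma`).
#' @param centiles percentiles retained on the chart's grid.
#' @return An object of class `"reference_chart"`.
#' @examples
#' chart <- chart_from_params(derive_gaussian_params(
#'   load_reference_grid(mvsref_example_grid())))
#' quantile_of(50, "tB", chart)
#' @export
chart_from_params <- function(params, centiles = DEFAULT_CENTILES) {
  params <- validate_gaussian_params(params)
  new_reference_chart(
    milestones = params$milestone,
    mu = stats::setNames(params$mu, params$milestone),
    sigma = stats::setNames(params$sigma, params$milestone),
    centiles = centiles,
    fit_meta = list(source = "gaussian_params")
  )
}

DEFAULT_CENTILES <- c(3, 5, 10, 25, 50, 75, 90, 95, 97)

#' @keywords internal
new_reference_chart <- function(milestones, mu, sigma, centiles, fit_meta) {
  stopifnot(length(mu) == length(milestones), length(sigma) == length(milestones))
  structure(
    list(milestones = milestones, mu = mu, sigma = sigma,
         centiles = sort(centiles), fit_meta = fit_meta),
    class = "reference_chart"
  )
}

#' @export
print.reference_chart <- function(x, ...) {
  cat("Morphokinetic reference chart (", length(x$milestones),
      " milestones)\n", sep = "")
  src <- x$fit_meta$source %||% "fitted"
  cat("  source: ", src, "\n", sep = "")
  if (!is.null(x$fit_meta$n_embryos)) {
    cat("  fitted on ", x$fit_meta$n_embryos, " embryos / ",
        x$fit_meta$n_observations, " observations\n", sep = "")
  }
  tab <- data.frame(milestone = x$milestones,
                    mu = round(unname(x$mu), 2),
                    sigma = round(unname(x$sigma), 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
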