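#' Load a reference centile grid from CSV
#'
#' Reads a milestone-by-percentile reference table: first column the milestone
#' code, then one column per percentile. Percentile headers may be written as
#' `3`, `p3`, `3rd`, `97th`, `50` or `Median` (alias for the 50th); they are
#' normalised to `p<percentile>`. Rows are validated (known milestone codes,
#' no duplicates, strictly increasing cells across percentiles) and returned
#' in developmental order.
#'
#' @param path path to the CSV file.
#' @return A validated grid data.frame: `milestone` plus `p<percentile>` columns.
#' @examples
#' grid <- load_reference_grid(mvsref_example_grid())
#' dim(grid)
#' @export
load_reference_grid <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("grid needs a milestone column and >= 2 centile columns", call. = FALSE)
  names(raw)[1] <- "milestone"
  pct <- vapply(names(raw)[-1], parse_percentile_header, numeric(1))
  names(raw)[-1] <- paste0("p", pct)
  validate_grid(raw)
}

#' @keywords internal
parse_percentile_header <- function(h) {
  h0 <- trimws(h)
  if (tolower(h0) == "median") return(50)
  num <- sub("^p", "", sub("(st|nd|rd|th)$", "", tolower(h0)))
  p <- suppressWarnings(as.numeric(num))
  if (is.na(p) || p <= 0 || p >= 100) {
    stop("cannot parse centile column header '", h, "'", call. = FALSE)
  }
  p
}

#' Percentiles present on a grid
#' @keywords internal
grid_percentiles <- function(grid) {
  cols <- grep("^p[0-9.]+$", names(grid), value = TRUE)
  sort(as.numeric(sub("^p", "", cols)))
}

#' Validate a centile grid
#'
#' Checks milestone codes, ordering, and strict monotonicity of every row
#' across increasing percentiles; errors name the offending milestone/cell.
#' @keywords internal
validate_grid <- function(grid) {
  stopifnot(is.data.frame(grid), "milestone" %in% names(grid))
  idx <- match_milestone(grid$milestone)
  if (anyDuplicated(grid$milestone)) {
    stop("duplicated milestone row(s): ",
         paste(grid$milestone[duplicated(grid$milestone)], collapse = ", "),
         call. = FALSE)
  }
  pcts <- grid_percentiles(grid)
  if (length(pcts) < 2L) stop("grid needs at least two centile columns", call. = FALSE)
  cols <- paste0("p", pcts)
  mat <- as.matrix(grid[, cols, drop = FALSE])
  if (any(!is.finite(mat))) stop("grid contains missing or non-numeric cells", call. = FALSE)
  bad <- which(apply(mat, 1L, function(r) any(diff(r) <= 0)))
  if (length(bad)) {
    r <- mat[bad[1], ]
    j <- which(diff(r) <= 0)[1]
    stop("non-monotone grid row for milestone ", grid$milestone[bad[1]],
         ": p", pcts[j], " = ", r[j], " >= p", pcts[j + 1], " = ", r[j + 1],
         call. = FALSE)
  }
  grid <- grid[order(idx), c("milestone", cols), drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Write a centile grid to CSV
#'
#' Cells are written to 2 decimals, the layout used by published reference
#' tables (milestone code first, then one column per percentile).
#'
#' @param grid a centile grid data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_centile_grid <- function(grid, path) {
  grid <- validate_grid(grid)
  num <- names(grid) != "milestone"
  grid[num] <- lapply(grid[num], function(x) sprintf("%.2f", x))
  utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Path to the packaged euploid reference grid
#'
#' The package ships the published centile grid (3rd-97th percentiles, hours
#' post-insemination) for the 15 morphokinetic milestones of euploid embryos,
#' so that the percentile calculator and scoring work out of the box without
#' refitting a chart.
#'
#' @return Path to the installed CSV file.
#' @examples
#' load_reference_grid(mvsref_example_grid())
#' @export
mvsref_example_grid <- function() {
  system.file("extdata", "euploid_reference_grid.csv",
              package = "mvsref", mustWork = TRUE)
}
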