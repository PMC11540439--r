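#' The morphokinetic milestone axis
#'
#' All fitting and scoring in mvsref happens on a fixed, ordered axis of 15
#' morphokinetic milestones annotated during time-lapse monitoring, from
#' extrusion of the second polar body to the full blastocyst. Times are in
#' hours post-insemination (hpi), clocked from ICSI injection. The integer
#' position of a milestone on this axis (1..15) is the "developmental stage"
#' coordinate used as the pseudo-time covariate of the reference model.
#'
#' @return A data.frame with columns `code`, `stage` (1..15) and
#'   `description`, one row per milestone in developmental order.
#' @examples
#' milestone_schema()
#' @export
milestone_schema <- function() {
  data.frame(
    code = MILESTONE_CODES,
    stage = seq_along(MILESTONE_CODES),
    description = c(
      "second polar body extrusion",
      "appearance of both pronuclei",
      "pronuclear fading",
      "two cells", "three cells", "four cells", "five cells",
      "six cells", "seven cells", "eight cells", "nine cells",
      "start of compaction",
      "morula (end of compaction)",
      "start of blastulation",
      "full blastocyst"
    ),
    stringsAsFactors = FALSE
  )
}

#' Ordered milestone codes, tPB2 first, tB last.
#' @keywords internal
MILESTONE_CODES <- c(
  "tPB2", "tPNa", "tPNf",
  "t2", "t3", "t4", "t5", "t6", "t7", "t8", "t9",
  "tSC", "tM", "tSB", "tB"
)

# Grade / outcome level sets used across the package. Reference levels for
# the regression models come first.
EXPANSION_LEVELS <- c("BL3", "BL4", "BL5")
GRADE_LEVELS <- c("A", "B", "C")
DAY_LEVELS <- c(5L, 6L, 7L)
OUTCOME_LEVELS <- c("live_birth", "pregnancy_loss", "no_pregnancy")

#' Match milestone codes, with informative failure
#' @keywords internal
match_milestone <- function(code) {
  idx <- match(code, MILESTONE_CODES)
  if (anyNA(idx)) {
    stop("unknown milestone code(s): ",
         paste(unique(code[is.na(idx)]), collapse = ", "),
         "; allowed codes are: ", paste(MILESTONE_CODES, collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Stack a cohort into long (one row per observed milestone) format
#'
#' @param cohort a cohort data.frame as produced by [generate_cohort()] or
#'   [read_cohort()].
#' @return data.frame with columns `embryo_id`, `milestone`, `stage`, `time`;
#'   missing annotations are dropped.
#' @export
cohort_long <- function(cohort) {
  stopifnot(is.data.frame(cohort), "embryo_id" %in% names(cohort))
  present <- intersect(MILESTONE_CODES, names(cohort))
  if (length(present) == 0L) stop("cohort has no milestone columns", call. = FALSE)
  out <- do.call(rbind, lapply(present, function(m) {
    data.frame(
      embryo_id = cohort$embryo_id,
      milestone = m,
      stage = match(m, MILESTONE_CODES),
      time = as.numeric(cohort[[m]]),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[!is.na(out$time), , drop = FALSE]
  out[order(out$embryo_id, out$stage), , drop = FALSE]
}
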