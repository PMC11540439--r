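#' Write a cohort table to CSV
#'
#' One row per embryo; columns `embryo_id`, the milestone times in hours
#' (decimal point, empty cell or `NA` for missing), `expansion_grade`,
#' `icm_grade`, `te_grade`, `nuclear_error_2cell`, `nuclear_error_4cell`,
#' `day_of_blastulation`, `outcome`, plus any optional covariates present
#' (e.g. `age`, `bmi`, `cycle_type`). UTF-8, header required.
#'
#' @param cohort a cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

# documented synonym table for outcome labels (lower-cased, separators removed)
OUTCOME_SYNONYMS <- c(
  livebirth = "live_birth", lb = "live_birth", birth = "live_birth",
  pregnancyloss = "pregnancy_loss", miscarriage = "pregnancy_loss",
  loss = "pregnancy_loss",
  nopregnancy = "no_pregnancy", notpregnant = "no_pregnancy",
  nopreg = "no_pregnancy", none = "no_pregnancy"
)

#' @keywords internal
normalize_outcome <- function(x) {
  key <- gsub("[ _\\-]", "", tolower(trimws(x)))
  out <- OUTCOME_SYNONYMS[key]
  unname(out)
}

#' Read a cohort table from CSV
#'
#' Inverse of [write_cohort()]. Missing milestone annotations may be empty
#' cells or `NA`. Outcome labels are normalised through a documented synonym
#' table (e.g. `"LiveBirth"`, `"live birth"` -> `live_birth`). Validation
#' problems (unknown milestone-like columns, unparsable grades or outcomes,
#' non-positive or out-of-range times) are collected and reported with the
#' offending line numbers. Non-monotone milestone times within an embryo
#' produce a warning by default, an error under `strict = TRUE`.
#'
#' @param path path to the CSV file.
#' @param strict error (rather than warn) on non-decreasing-order violations.
#' @return A data.frame of class `c("mvsref_cohort", "data.frame")`.
#' @export
read_cohort <- function(path, strict = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  required <- c("embryo_id", "expansion_grade", "icm_grade", "te_grade",
                "nuclear_error_2cell", "nuclear_error_4cell",
                "day_of_blastulation", "outcome")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("cohort CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  # columns that look like milestone annotations but are not on the axis
  known_other <- c(required, "age", "bmi", "cycle_type")
  extra <- setdiff(names(raw), c(required, MILESTONE_CODES, known_other))
  milestone_like <- grep("^t([A-Z]|[0-9])", extra, value = TRUE)
  if (length(milestone_like)) {
    stop("unknown milestone column(s): ", paste(milestone_like, collapse = ", "),
         "; allowed codes are: ", paste(MILESTONE_CODES, collapse = ", "),
         call. = FALSE)
  }

  problems <- character(0)
  note <- function(lines, msg) {
    problems <<- c(problems, paste0("line ", lines + 1L, ": ", msg))
  }

  for (m in intersect(MILESTONE_CODES, names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[m]]))
    bad_parse <- which(!is.na(raw[[m]]) & is.na(v))
    if (length(bad_parse)) note(bad_parse, paste0("unparsable time in ", m))
    bad_range <- which(!is.na(v) & (v <= 0 | v >= 200))
    if (length(bad_range)) {
      note(bad_range, paste0(m, " outside (0, 200) hours"))
    }
    raw[[m]] <- v
  }
  chk_levels <- function(col, levels) {
    bad <- which(!is.na(raw[[col]]) & !(as.character(raw[[col]]) %in% levels))
    if (length(bad)) {
      note(bad, paste0("unparsable ", col, " (allowed: ",
                       paste(levels, collapse = ", "), ")"))
    }
  }
  chk_levels("expansion_grade", EXPANSION_LEVELS)
  chk_levels("icm_grade", GRADE_LEVELS)
  chk_levels("te_grade", GRADE_LEVELS)
  chk_levels("day_of_blastulation", as.character(DAY_LEVELS))
  for (col in c("nuclear_error_2cell", "nuclear_error_4cell")) {
    v <- tolower(as.character(raw[[col]]))
    parsed <- ifelse(v %in% c("true", "t", "1", "yes"), TRUE,
                     ifelse(v %in% c("false", "f", "0", "no"), FALSE, NA))
    bad <- which(!is.na(raw[[col]]) & is.na(parsed))
    if (length(bad)) note(bad, paste0("unparsable boolean in ", col))
    raw[[col]] <- as.logical(parsed)
  }
  out_norm <- normalize_outcome(raw$outcome)
  bad_outcome <- which(!is.na(raw$outcome) & is.na(out_norm))
  if (length(bad_outcome)) {
    note(bad_outcome, paste0("unparsable outcome '",
                             raw$outcome[bad_outcome], "'"))
  }
  raw$outcome <- out_norm

  if (length(problems)) {
    stop("invalid cohort CSV:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }

  present <- intersect(MILESTONE_CODES, names(raw))
  if (length(present) >= 2L) {
    tm <- as.matrix(raw[, present])
    nonmono <- which(apply(tm, 1L, function(r) {
      r <- r[!is.na(r)]
      length(r) >= 2L && any(diff(r) < 0)
    }))
    if (length(nonmono)) {
      msg <- paste0("non-decreasing milestone order violated for embryo(s): ",
                    paste(raw$embryo_id[utils::head(nonmono, 10L)], collapse = ", "),
                    if (length(nonmono) > 10L) " ..." else "")
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  raw$day_of_blastulation <- as.integer(raw$day_of_blastulation)
  class(raw) <- c("mvsref_cohort", "data.frame")
  raw
}
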