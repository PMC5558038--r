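# Trial-table readers/writers and the exclusion rules.

TRIAL_COLUMNS <- c("subject_id", "task", "trial_index", "coh_signed",
                   "duration", "delay", "choice", "correct", "t_sd", "rt",
                   "left_home_early", "over_clock", "no_decision",
                   "forgot_clock", "practice")

FLAG_COLUMNS <- c("left_home_early", "over_clock", "no_decision",
                  "forgot_clock", "practice")

#' Read / write a trial table as CSV
#'
#' The CSV carries exactly the standard trial columns (extra columns are
#' preserved with a warning; missing required columns are an error);
#' missing values are written as empty fields, and a write/read round trip
#' is the identity.
#'
#' @param path CSV file path.
#' @return `read_trial_table` returns the table; `write_trial_table`
#'   returns `path` invisibly.
#' @export
read_trial_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(tab))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(tab), TRIAL_COLUMNS)
  if (length(extra)) {
    warning("unknown columns preserved: ", paste(extra, collapse = ", "))
  }
  for (cc in c("coh_signed", "duration", "delay", "t_sd", "rt")) {
    if (!is.numeric(tab[[cc]])) {
      bad <- which(!is.na(tab[[cc]]) & is.na(suppressWarnings(
        as.numeric(tab[[cc]]))) & tab[[cc]] != "")
      if (length(bad)) {
        stop(sprintf("malformed numeric value in column `%s`, row %d", cc,
                     bad[1]))
      }
      tab[[cc]] <- suppressWarnings(as.numeric(tab[[cc]]))
    }
  }
  for (cc in FLAG_COLUMNS) tab[[cc]] <- as.logical(tab[[cc]])
  tab$trial_index <- as.integer(tab$trial_index)
  tab$choice <- as.integer(tab$choice)
  tab$correct <- as.integer(tab$correct)
  tab
}

#' @rdname read_trial_table
#' @param trials trial table.
#' @export
write_trial_table <- function(trials, path) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the trial-exclusion rules
#'
#' Removes flagged trials in priority order — left the home position early,
#' response after one clock revolution (2.7 s), no decision reported,
#' forgot the clock position, practice (first 200 per task) — counting each
#' excluded trial once, under the highest-priority rule that applies.
#'
#' @param trials trial table.
#' @return list with `trials` (retained rows) and `report` (counts per
#'   rule, `n_in`, `n_out`).
#' @export
apply_exclusions <- function(trials) {
  n_in <- nrow(trials)
  counts <- setNames(integer(length(FLAG_COLUMNS)), FLAG_COLUMNS)
  excluded <- rep(FALSE, n_in)
  for (rule in FLAG_COLUMNS) {
    hit <- !excluded & trials[[rule]] %in% TRUE
    counts[rule] <- sum(hit)
    excluded <- excluded | hit
  }
  list(trials = trials[!excluded, , drop = FALSE],
       report = c(as.list(counts), list(n_in = n_in,
                                        n_out = n_in - sum(counts))))
}
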