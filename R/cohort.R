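# Cohort data model: subjects table + daily feed log, with validation and
# CSV readers/writers. All times are integer days since delivery (day 0).

FEED_TYPES <- c("breast", "formula", "fortifier", "unknown")
SEX_LEVELS <- c("male", "female")
ARM_LEVELS <- c("early", "late")

#' Construct a validated cohort
#'
#' A cohort bundles a subjects table with a long-format daily feed log.
#' Follow-up starts at day 0 (day of delivery) for every subject and ends at
#' `exit_day`, the first of the outcome event, death, or the last log record.
#' A subject whose event falls on its exit day is treated as exiting because
#' of the event.
#'
#' @param subjects data frame with columns `id` (unique character), `sex`
#'   (`"male"`/`"female"`), `gestational_age` (weeks, > 0), `birth_weight`
#'   (grams, > 0), `trial_arm` (`"early"`/`"late"`, or `NA` for non-trial
#'   cohorts), `exit_day` (non-negative integer), `event` (logical),
#'   `event_day` (integer, present iff `event`). Extra columns are preserved.
#' @param feed_log data frame with columns `id`, `day` (non-negative integer,
#'   at most `exit_day` for that subject), `feed_type` (one of `"breast"`,
#'   `"formula"`, `"fortifier"`, `"unknown"`); at most one record per
#'   subject-day. May be empty.
#' @return An object of class `ncc_cohort`: a list with elements `subjects`
#'   and `feed_log`.
#' @examples
#' subj <- data.frame(id = "A", sex = "male", gestational_age = 29,
#'                    birth_weight = 850, trial_arm = "early",
#'                    exit_day = 20L, event = FALSE, event_day = NA_integer_)
#' cohort(subj)
#' @export
cohort <- function(subjects, feed_log = empty_feed_log()) {
  obj <- structure(list(subjects = as.data.frame(subjects),
                        feed_log = as.data.frame(feed_log)),
                   class = "ncc_cohort")
  validate_cohort(obj)
  obj
}

#' @rdname cohort
#' @export
empty_feed_log <- function() {
  data.frame(id = character(0), day = integer(0), feed_type = character(0),
             stringsAsFactors = FALSE)
}

#' Validate a cohort object
#'
#' Checks every structural invariant of the data model and stops with an
#' informative error naming the offending subject or row on the first
#' violation found.
#'
#' @param x an `ncc_cohort` object.
#' @return `x`, invisibly, if valid.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "ncc_cohort"))
  s <- x$subjects
  fl <- x$feed_log

  req <- c("id", "sex", "gestational_age", "birth_weight", "trial_arm",
           "exit_day", "event", "event_day")
  miss <- setdiff(req, names(s))
  if (length(miss))
    stop("subjects table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(s$id) || any(!nzchar(s$id)))
    stop("subjects table contains a missing or empty id")
  dup <- s$id[duplicated(s$id)]
  if (length(dup))
    stop("duplicate subject id(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!(s$sex %in% SEX_LEVELS))
  if (length(bad))
    stop("subject ", s$id[bad[1]], ": sex must be one of ",
         paste(SEX_LEVELS, collapse = "/"))
  bad <- which(!is.na(s$trial_arm) & !(s$trial_arm %in% ARM_LEVELS))
  if (length(bad))
    stop("subject ", s$id[bad[1]], ": trial_arm must be early/late or NA")
  bad <- which(is.na(s$gestational_age) | s$gestational_age <= 0)
  if (length(bad))
    stop("subject ", s$id[bad[1]], ": gestational_age must be > 0")
  bad <- which(is.na(s$birth_weight) | s$birth_weight <= 0)
  if (length(bad))
    stop("subject ", s$id[bad[1]], ": birth_weight must be > 0")
  bad <- which(is.na(s$exit_day) | s$exit_day < 0 | s$exit_day != round(s$exit_day))
  if (length(bad))
    stop("subject ", s$id[bad[1]], ": exit_day must be a non-negative integer")
  if (!is.logical(s$event) || anyNA(s$event))
    stop("subjects column 'event' must be logical with no missing values")
  bad <- which(s$event & is.na(s$event_day))
  if (length(bad))
    stop("subject ", s$id[bad[1]], ": event recorded without an event_day")
  bad <- which(!s$event & !is.na(s$event_day))
  if (length(bad))
    stop("subject ", s$id[bad[1]], ": event_day present but event is 0")
  bad <- which(s$event & (s$event_day < 0 | s$event_day > s$exit_day))
  if (length(bad))
    stop("subject ", s$id[bad[1]],
         ": event_day must lie in [0, exit_day] (the event defines exit)")

  reqf <- c("id", "day", "feed_type")
  miss <- setdiff(reqf, names(fl))
  if (length(miss))
    stop("feed log is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(fl)) {
    orphan <- setdiff(unique(fl$id), s$id)
    if (length(orphan))
      stop("feed log refers to unknown subject id(s): ",
           paste(orphan, collapse = ", "))
    bad <- which(is.na(fl$day) | fl$day < 0 | fl$day != round(fl$day))
    if (length(bad))
      stop("feed log row ", bad[1], " (subject ", fl$id[bad[1]],
           "): day must be a non-negative integer")
    bad <- which(!(fl$feed_type %in% FEED_TYPES))
    if (length(bad))
      stop("feed log row ", bad[1], " (subject ", fl$id[bad[1]],
           "): feed_type must be one of ", paste(FEED_TYPES, collapse = "/"))
    key <- paste(fl$id, fl$day)
    dup <- which(duplicated(key))
    if (length(dup))
      stop("feed log has more than one record for subject ", fl$id[dup[1]],
           " on day ", fl$day[dup[1]])
    exit <- s$exit_day[match(fl$id, s$id)]
    bad <- which(fl$day > exit)
    if (length(bad))
      stop("feed log row ", bad[1], " (subject ", fl$id[bad[1]],
           "): day ", fl$day[bad[1]], " is beyond the subject's exit_day ",
           exit[bad[1]])
  }
  invisible(x)
}

#' @export
print.ncc_cohort <- function(x, ...) {
  s <- x$subjects
  cat("<ncc_cohort> ", nrow(s), " subjects (", sum(s$event), " cases), ",
      nrow(x$feed_log), " feed-log records\n", sep = "")
  invisible(x)
}

# column name mapping between on-disk CSV schema and the internal table
.subject_csv_map <- c(id = "id", sex = "sex",
                      gestational_age_weeks = "gestational_age",
                      birth_weight_g = "birth_weight",
                      trial_arm = "trial_arm", exit_day = "exit_day",
                      event = "event", event_day = "event_day")

#' Read a cohort from CSV files
#'
#' The subjects file must have columns `id, sex, gestational_age_weeks,
#' birth_weight_g, trial_arm, exit_day, event, event_day` (booleans coded
#' 0/1, `event_day` empty when no event; extra columns are kept). The feed
#' log file has columns `id, day, feed_type`.
#'
#' @param subjects_path,feedlog_path paths to the two CSV files.
#' @return A validated [cohort()].
#' @export
read_cohort <- function(subjects_path, feedlog_path) {
  if (!file.exists(subjects_path))
    stop("subjects file not found: ", subjects_path)
  if (!file.exists(feedlog_path))
    stop("feed log file not found: ", feedlog_path)
  s <- utils::read.csv(subjects_path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character"))
  miss <- setdiff(names(.subject_csv_map), names(s))
  if (length(miss))
    stop("subjects CSV is missing column(s): ", paste(miss, collapse = ", "))
  idx <- match(names(.subject_csv_map), names(s))
  names(s)[idx] <- unname(.subject_csv_map)
  if (!is.logical(s$event)) {
    if (!all(s$event %in% c(0L, 1L)))
      stop("subjects CSV column 'event' must be coded 0/1")
    s$event <- s$event == 1L
  }
  s$exit_day <- as.integer(s$exit_day)
  s$event_day <- suppressWarnings(as.integer(s$event_day))
  s$trial_arm <- as.character(s$trial_arm)
  s$trial_arm[!is.na(s$trial_arm) & s$trial_arm == ""] <- NA_character_
  fl <- utils::read.csv(feedlog_path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  if (!nrow(fl)) fl <- empty_feed_log()
  else fl$day <- as.integer(fl$day)
  cohort(s, fl)
}

# full-precision numeric formatting so that write -> read round-trips exactly
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  # prefer the shortest representation that still parses back exactly
  short <- vapply(x, function(v) if (is.na(v)) "" else format(v, digits = 15),
                  character(1))
  ok <- !is.na(x) & as.numeric(ifelse(short == "", NA, short)) == x
  out[which(ok)] <- short[which(ok)]
  out
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_cohort()]: numeric fields are written with enough digits
#' that reading the files back reproduces the cohort exactly.
#'
#' @param x an `ncc_cohort`.
#' @param subjects_path,feedlog_path output paths.
#' @return The two paths, invisibly.
#' @export
write_cohort <- function(x, subjects_path, feedlog_path) {
  stopifnot(inherits(x, "ncc_cohort"))
  s <- x$subjects
  out <- s
  out$gestational_age <- .fmt_num(s$gestational_age)
  out$birth_weight <- .fmt_num(s$birth_weight)
  out$event <- as.integer(s$event)
  out$event_day <- ifelse(is.na(s$event_day), "", as.character(s$event_day))
  out$trial_arm <- ifelse(is.na(s$trial_arm), "", s$trial_arm)
  idx <- match(unname(.subject_csv_map), names(out))
  names(out)[idx] <- names(.subject_csv_map)
  utils::write.csv(out, subjects_path, row.names = FALSE, quote = FALSE,
                   na = "")
  utils::write.csv(x$feed_log, feedlog_path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(c(subjects_path, feedlog_path))
}

#' Apply exclusion rules to a cohort
#'
#' Removes subjects that fail data-quality rules before analysis and returns
#' an itemised report. A subject failing several rules is excluded once but
#' listed under every rule it fails.
#'
#' Built-in rules:
#' \describe{
#'   \item{`require_feed_log`}{exclude subjects with no feed-log records.}
#'   \item{`drop_withdrawn`}{exclude subjects flagged in an optional 0/1
#'     subjects column `withdrawn` (consent withdrawn).}
#'   \item{`require_outcome_known`}{exclude subjects flagged in an optional
#'     0/1 subjects column `outcome_missing` (outcome severity unknown).}
#' }
#' If a rule's flag column is absent the rule excludes nobody, with a warning.
#'
#' @param x an `ncc_cohort`.
#' @param rules character vector of rule names; `character(0)` leaves the
#'   cohort unchanged.
#' @return list with elements `cohort` (the filtered cohort) and `exclusions`
#'   (data frame `id`, `reason`, one row per subject-rule failure).
#' @export
exclude_invalid <- function(x, rules = character(0)) {
  stopifnot(inherits(x, "ncc_cohort"))
  known <- c("require_feed_log", "drop_withdrawn", "require_outcome_known")
  bad <- setdiff(rules, known)
  if (length(bad))
    stop("unknown exclusion rule(s): ", paste(bad, collapse = ", "))
  s <- x$subjects
  hits <- list()
  flag_rule <- function(col, reason) {
    if (!col %in% names(s)) {
      warning("exclusion rule '", reason, "' skipped: subjects column '",
              col, "' is absent")
      return(character(0))
    }
    s$id[!is.na(s[[col]]) & s[[col]] == 1]
  }
  for (r in rules) {
    ids <- switch(r,
      require_feed_log = setdiff(s$id, unique(x$feed_log$id)),
      drop_withdrawn = flag_rule("withdrawn", "drop_withdrawn"),
      require_outcome_known = flag_rule("outcome_missing",
                                        "require_outcome_known"))
    if (length(ids))
      hits[[r]] <- data.frame(id = ids, reason = r, stringsAsFactors = FALSE)
  }
  report <- if (length(hits)) do.call(rbind, c(hits, make.row.names = FALSE))
            else data.frame(id = character(0), reason = character(0))
  drop_ids <- unique(report$id)
  keep <- !(s$id %in% drop_ids)
  if (!any(keep))
    warning("all subjects excluded; returning an empty cohort")
  out <- x
  out$subjects <- s[keep, , drop = FALSE]
  rownames(out$subjects) <- NULL
  out$feed_log <- x$feed_log[!(x$feed_log$id %in% drop_ids), , drop = FALSE]
  rownames(out$feed_log) <- NULL
  list(cohort = out, exclusions = report)
}
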