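# Exposure classification from daily feed logs.
#
# Feed logs are gap-filled conservatively, then each subject's exposure is
# evaluated at an index day (the matched set's event day) using only records
# strictly before that day, so no post-outcome feeding can leak into the
# classification.

EXPOSURE_KINDS <- c("first_k_days", "any_prior", "change_within_k")

#' Define an exposure window
#'
#' Three kinds of time-truncated exposure are supported, all evaluated
#' strictly before an index day:
#' \describe{
#'   \item{`first_k_days`}{any exposed feed type on days `0 .. min(k, index) - 1`.}
#'   \item{`any_prior`}{any exposed feed type on any day before the index day.}
#'   \item{`change_within_k`}{a change between two consecutive days of known
#'     feed type within the k days before the index day. Unknown days break
#'     the comparison chain and never count as a change.}
#' }
#'
#' @param name label used for the exposure column.
#' @param kind one of `"first_k_days"`, `"any_prior"`, `"change_within_k"`.
#' @param k window length in days (required except for `any_prior`).
#' @param exposed_types feed types counting as exposure (ignored for
#'   `change_within_k`, which compares all known types).
#' @return An object of class `ncc_exposure_def`.
#' @export
exposure_definition <- function(name, kind, k = NULL,
                                exposed_types = c("formula", "fortifier")) {
  if (!kind %in% EXPOSURE_KINDS)
    stop("unsupported exposure kind: ", kind)
  if (kind != "any_prior") {
    if (is.null(k) || length(k) != 1L || k < 1L)
      stop("exposure '", name, "' (", kind, ") needs a positive window k")
    k <- as.integer(k)
  } else if (!is.null(k)) {
    stop("exposure '", name, "': k is not meaningful for any_prior")
  }
  bad <- setdiff(exposed_types, FEED_TYPES)
  if (length(bad)) stop("unknown feed type(s): ", paste(bad, collapse = ", "))
  structure(list(name = name, kind = kind, k = k,
                 exposed_types = exposed_types),
            class = "ncc_exposure_def")
}

#' The four predefined exposures
#'
#' Non-breast-milk feeding (formula or fortifier) in the first 14 days of
#' life, in the first 28 days, at any prior time, and any change of feed type
#' within the previous 7 days.
#'
#' @return Named list of [exposure_definition()]s.
#' @export
default_exposures <- function() {
  list(
    first_14 = exposure_definition("first_14", "first_k_days", 14L),
    first_28 = exposure_definition("first_28", "first_k_days", 28L),
    any_prior = exposure_definition("any_prior", "any_prior"),
    change_within_7 = exposure_definition("change_within_7",
                                          "change_within_k", 7L,
                                          exposed_types = FEED_TYPES)
  )
}

#' Fill small gaps in one subject's daily feed log
#'
#' Returns a complete daily grid from day 0 to the last recorded day. An
#' interior run of at most `max_gap` missing days flanked on both sides by
#' the same recorded feed type is filled with that type; every other missing
#' day (longer runs, runs between different types, days before the first
#' record) becomes `"unknown"`. Recorded values are never altered.
#'
#' @param log data frame with columns `day` and `feed_type` for one subject
#'   (an `id` column, if present, must be constant).
#' @param max_gap largest fillable run length in days (default 2).
#' @return Data frame `day`, `feed_type` covering days `0:max(log$day)`;
#'   zero rows if the input has none.
#' @export
fill_feed_gaps <- function(log, max_gap = 2L) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  if ("id" %in% names(log) && length(unique(log$id)) > 1L)
    stop("fill_feed_gaps expects the log of a single subject")
  if (!nrow(log))
    return(data.frame(day = integer(0), feed_type = character(0),
                      stringsAsFactors = FALSE))
  if (anyDuplicated(log$day))
    stop("duplicate day in feed log")
  n <- max(log$day) + 1L
  types <- rep(NA_character_, n)
  types[log$day + 1L] <- log$feed_type
  r <- rle(is.na(types))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    a <- starts[j]; b <- ends[j]
    fill <- "unknown"
    if (a > 1L && b < n && r$lengths[j] <= max_gap) {
      left <- types[a - 1L]; right <- types[b + 1L]
      if (identical(left, right) && left != "unknown") fill <- left
    }
    types[a:b] <- fill
  }
  data.frame(day = 0:(n - 1L), feed_type = types, stringsAsFactors = FALSE)
}

#' Classify one exposure at an index day
#'
#' Evaluates an [exposure_definition()] on a gap-filled log, using only days
#' strictly before `index_day`. Days missing from the grid (beyond the last
#' record) are treated as unknown; unknown days never count as exposure nor
#' as a feed change.
#'
#' @param filled output of [fill_feed_gaps()].
#' @param definition an `ncc_exposure_def`.
#' @param index_day non-negative integer day.
#' @return `TRUE`/`FALSE`.
#' @export
classify_exposure <- function(filled, definition, index_day) {
  stopifnot(inherits(definition, "ncc_exposure_def"), index_day >= 0)
  n <- nrow(filled)
  type_at <- function(d) {
    ifelse(d >= 0L & d < n, filled$feed_type[pmax(d, 0L) + 1L], "unknown")
  }
  kind <- definition$kind
  if (kind %in% c("first_k_days", "any_prior")) {
    hi <- if (kind == "any_prior") index_day
          else min(definition$k, index_day)
    if (hi <= 0L || n == 0L) return(FALSE)
    days <- 0:(min(hi, n) - 1L)
    return(any(filled$feed_type[days + 1L] %in% definition$exposed_types))
  }
  if (kind == "change_within_k") {
    lo <- max(index_day - definition$k, 1L)
    if (index_day - 1L < lo) return(FALSE)
    ds <- lo:(index_day - 1L)
    prev <- type_at(ds - 1L)
    cur <- type_at(ds)
    return(any(prev != "unknown" & cur != "unknown" & prev != cur))
  }
  stop("unsupported exposure kind: ", kind)
}

#' Build the matched-set analysis table
#'
#' One row per matched-set member, with every member of a set classified at
#' the set's event day (the case's). Each member's log is first truncated to
#' days strictly before the index day and only then gap-filled, so a record
#' on or after the index day can never influence any flag (not even through
#' a fill). A subject appearing in several sets gets one row per appearance,
#' with exposure re-evaluated at each index day.
#'
#' @param matched_sets an `ncc_matched_sets` from [sample_all()].
#' @param x the `ncc_cohort`.
#' @param definitions named list of [exposure_definition()]s (default
#'   [default_exposures()]).
#' @param max_gap gap-filling parameter, see [fill_feed_gaps()].
#' @return Data frame with columns `set_id`, `subject_id`, `is_case`,
#'   `index_day`, `trial_arm`, and one logical column per exposure.
#' @export
build_analysis_table <- function(matched_sets, x,
                                 definitions = default_exposures(),
                                 max_gap = 2L) {
  stopifnot(inherits(matched_sets, "ncc_matched_sets"),
            inherits(x, "ncc_cohort"))
  if (is.null(names(definitions)))
    names(definitions) <- vapply(definitions, `[[`, character(1), "name")
  long <- as.data.frame(matched_sets)
  missing_ids <- setdiff(long$subject_id, x$subjects$id)
  if (length(missing_ids))
    stop("matched-set member(s) absent from cohort: ",
         paste(missing_ids, collapse = ", "))
  ids <- unique(long$subject_id)
  fl <- x$feed_log[x$feed_log$id %in% ids, , drop = FALSE]
  fl <- fl[order(fl$id, fl$day), , drop = FALSE]
  logs <- split(fl[, c("day", "feed_type")], factor(fl$id, levels = ids))
  # fill once per distinct (subject, index day): truncate, then fill
  key <- paste0(long$subject_id, "@", long$event_day)
  ukey <- !duplicated(key)
  filled <- stats::setNames(lapply(which(ukey), function(i) {
    lg <- logs[[long$subject_id[i]]]
    fill_feed_gaps(lg[lg$day < long$event_day[i], , drop = FALSE],
                   max_gap = max_gap)
  }), key[ukey])
  arm <- x$subjects$trial_arm[match(long$subject_id, x$subjects$id)]
  out <- data.frame(set_id = long$set_id,
                    subject_id = long$subject_id,
                    is_case = long$role == "case",
                    index_day = long$event_day,
                    trial_arm = arm,
                    stringsAsFactors = FALSE)
  for (nm in names(definitions)) {
    def <- definitions[[nm]]
    out[[nm]] <- vapply(seq_len(nrow(long)), function(i) {
      classify_exposure(filled[[key[i]]], def, long$event_day[i])
    }, logical(1))
  }
  out
}
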