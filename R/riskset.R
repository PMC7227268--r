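# Incidence-density risk sets and matched-control selection.
#
# At each case's event day the risk set contains every subject still under
# follow-up with no event on or before that day. Controls are drawn from the
# risk set without replacement, matched exactly on categorical factors (sex by
# default) and by minimal Mahalanobis distance on continuous factors
# (gestational age and birth weight by default). Prior cases are never
# eligible again; future cases are.

#' Matching specification
#'
#' @param exact_factors categorical subject columns a control must equal the
#'   case on (default `"sex"`).
#' @param distance_factors continuous subject columns entering the
#'   Mahalanobis distance (default gestational age and birth weight).
#' @param controls_per_case number of controls m per case (default 4).
#' @param covariance optional k x k positive-definite matrix for the distance;
#'   when `NULL` it is estimated once from the full cohort with
#'   [estimate_covariance()].
#' @param ridge_epsilon ridge added to a numerically singular covariance.
#' @return An object of class `ncc_matching_spec`.
#' @export
matching_spec <- function(exact_factors = "sex",
                          distance_factors = c("gestational_age",
                                               "birth_weight"),
                          controls_per_case = 4L,
                          covariance = NULL,
                          ridge_epsilon = 1e-8) {
  m <- as.integer(controls_per_case)
  if (is.na(m) || m < 1L) stop("controls_per_case must be a positive integer")
  if (!is.null(covariance)) .check_pd(covariance, length(distance_factors))
  structure(list(exact_factors = exact_factors,
                 distance_factors = distance_factors,
                 controls_per_case = m,
                 covariance = covariance,
                 ridge_epsilon = ridge_epsilon),
            class = "ncc_matching_spec")
}

.check_pd <- function(v, k) {
  if (!is.matrix(v) || nrow(v) != k || ncol(v) != k)
    stop("covariance must be a ", k, "x", k, " matrix")
  if (max(abs(v - t(v))) > 1e-8 * max(1, max(abs(v))))
    stop("covariance must be symmetric")
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance must be positive definite")
  invisible(v)
}

#' Estimate the matching covariance from the cohort
#'
#' Sample covariance of the continuous matching factors over the whole
#' cohort, so the distance metric is the same in every risk set. If the
#' sample covariance is numerically singular a small ridge is added, with a
#' warning.
#'
#' @param x an `ncc_cohort`.
#' @param factors continuous subject columns.
#' @param ridge_epsilon ridge used for the singular fallback.
#' @return A symmetric positive-definite matrix.
#' @export
estimate_covariance <- function(x, factors = c("gestational_age",
                                               "birth_weight"),
                                ridge_epsilon = 1e-8) {
  stopifnot(inherits(x, "ncc_cohort"))
  miss <- setdiff(factors, names(x$subjects))
  if (length(miss))
    stop("unknown matching factor(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(x$subjects[, factors, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  k <- length(factors)
  if (nrow(X) < k + 1L)
    stop("need at least ", k + 1L, " subjects with complete ",
         paste(factors, collapse = ", "), " values")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance matching factor: ", factors[which(sds == 0)[1]])
  S <- stats::cov(X)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * mean(diag(S))) {
    warning("matching covariance numerically singular; adding ridge ",
            ridge_epsilon)
    S <- S + diag(ridge_epsilon, k)
  }
  S
}

#' Mahalanobis distance between two covariate vectors
#'
#' `sqrt((x - y)' V^{-1} (x - y))` for a positive-definite `V`.
#'
#' @param x,y numeric vectors of equal length.
#' @param cov positive-definite covariance matrix.
#' @return Non-negative scalar; zero iff `x == y`.
#' @export
mahalanobis_distance <- function(x, y, cov) {
  if (length(x) != length(y) || length(x) != nrow(cov))
    stop("dimension mismatch between vectors and covariance")
  d <- x - y
  q <- tryCatch(sum(d * solve(cov, d)),
                error = function(e) stop("singular covariance matrix"))
  sqrt(max(q, 0))
}

#' Build the risk set at a case's event time
#'
#' Eligible controls are subjects still under follow-up at `event_day`
#' (`exit_day >= event_day`; exiting without an event on the day itself still
#' counts as at risk), with no event on or before `event_day`, not previously
#' a case, and not the case itself. Subjects whose own event comes later are
#' eligible.
#'
#' @param x an `ncc_cohort`.
#' @param case_id id of the case.
#' @param event_day the case's event day.
#' @param prior_case_ids ids of cases with earlier events (never eligible
#'   again).
#' @return An object of class `ncc_risk_set`: list with `case_id`,
#'   `event_day`, `eligible_ids`.
#' @export
build_risk_set <- function(x, case_id, event_day,
                           prior_case_ids = character(0)) {
  stopifnot(inherits(x, "ncc_cohort"))
  s <- x$subjects
  row <- match(case_id, s$id)
  if (is.na(row)) stop("unknown case id: ", case_id)
  if (!s$event[row] || s$event_day[row] != event_day)
    stop("subject ", case_id, " has no event on day ", event_day)
  had_event_by_now <- s$event & !is.na(s$event_day) & s$event_day <= event_day
  elig <- s$exit_day >= event_day & !had_event_by_now &
    !(s$id %in% prior_case_ids) & s$id != case_id
  ids <- s$id[elig]
  if (!length(ids))
    warning("empty risk set for case ", case_id, " at day ", event_day)
  structure(list(case_id = case_id, event_day = as.integer(event_day),
                 eligible_ids = ids),
            class = "ncc_risk_set")
}

#' Select matched controls from a risk set
#'
#' Keeps the eligible subjects equal to the case on every exact factor, then
#' takes the `m` with smallest Mahalanobis distance to the case on the
#' continuous factors. Ties at the selection boundary are broken uniformly at
#' random using the current RNG state (seed via [sample_all()] or
#' `set.seed()`). If fewer than `m` matching subjects exist, all are taken
#' and the set is flagged short.
#'
#' @param risk_set an `ncc_risk_set`.
#' @param x the `ncc_cohort` the risk set was built from.
#' @param spec an [matching_spec()]; `spec$covariance` must be set (use
#'   [estimate_covariance()]) unless there are no distance factors.
#' @return An object of class `ncc_matched_set`: list with `case_id`,
#'   `event_day`, `control_ids`, `distances` (same order), `short` flag.
#' @export
select_controls <- function(risk_set, x, spec = matching_spec()) {
  stopifnot(inherits(risk_set, "ncc_risk_set"), inherits(x, "ncc_cohort"))
  s <- x$subjects
  m <- spec$controls_per_case
  case_row <- s[match(risk_set$case_id, s$id), , drop = FALSE]
  cand <- s[s$id %in% risk_set$eligible_ids, , drop = FALSE]
  for (f in spec$exact_factors) {
    cand <- cand[!is.na(cand[[f]]) & cand[[f]] == case_row[[f]], ,
                 drop = FALSE]
  }
  if (!nrow(cand)) {
    warning("no eligible controls match case ", risk_set$case_id,
            " on ", paste(spec$exact_factors, collapse = ", "))
    return(structure(list(case_id = risk_set$case_id,
                          event_day = risk_set$event_day,
                          control_ids = character(0),
                          distances = numeric(0), short = TRUE),
                     class = "ncc_matched_set"))
  }
  V <- spec$covariance
  if (is.null(V) && length(spec$distance_factors))
    V <- estimate_covariance(x, spec$distance_factors, spec$ridge_epsilon)
  if (length(spec$distance_factors)) {
    Xc <- as.matrix(cand[, spec$distance_factors, drop = FALSE])
    xc <- as.numeric(case_row[, spec$distance_factors])
    D <- sweep(Xc, 2L, xc)
    d <- sqrt(pmax(rowSums((D %*% solve(V)) * D), 0))
  } else {
    d <- numeric(nrow(cand))
  }
  if (nrow(cand) <= m) {
    ord <- order(d)
    sel <- seq_len(nrow(cand))[ord]
  } else {
    thr <- sort(d)[m]
    sure <- which(d < thr)
    border <- which(d == thr)
    need <- m - length(sure)
    pick <- border[sample.int(length(border), need)]
    sel <- c(sure, pick)
    sel <- sel[order(d[sel])]
  }
  structure(list(case_id = risk_set$case_id,
                 event_day = risk_set$event_day,
                 control_ids = cand$id[sel],
                 distances = d[sel],
                 short = length(sel) < m),
            class = "ncc_matched_set")
}

#' Sample matched controls for every case in the cohort
#'
#' Processes cases in increasing event-day order (same-day cases in a
#' seeded random order, since each is excluded from the other's risk set),
#' accumulating prior cases so no case is ever reused as a control for a
#' later event. A subject may serve as a control in several sets (sampling
#' is with replacement across sets, without replacement within a set).
#'
#' @param x an `ncc_cohort` with at least one case.
#' @param spec a [matching_spec()].
#' @param seed integer seed; the whole output is reproducible from
#'   (cohort, spec, seed).
#' @return An object of class `ncc_matched_sets`: list of `ncc_matched_set`
#'   in processing order, with the covariance actually used in
#'   `attr(, "covariance")`.
#' @export
sample_all <- function(x, spec = matching_spec(), seed) {
  stopifnot(inherits(x, "ncc_cohort"))
  if (missing(seed)) stop("a seed is required for control sampling")
  s <- x$subjects
  cases <- s[s$event, , drop = FALSE]
  if (!nrow(cases)) stop("cohort contains no cases")
  set.seed(as.integer(seed))
  if (is.null(spec$covariance) && length(spec$distance_factors))
    spec$covariance <- estimate_covariance(x, spec$distance_factors,
                                           spec$ridge_epsilon)
  ord <- order(cases$event_day, stats::runif(nrow(cases)))
  cases <- cases[ord, , drop = FALSE]
  prior <- character(0)
  out <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    rs <- suppressWarnings(
      build_risk_set(x, cases$id[i], cases$event_day[i], prior))
    out[[i]] <- select_controls(rs, x, spec)
    prior <- c(prior, cases$id[i])
  }
  structure(out, class = "ncc_matched_sets",
            covariance = spec$covariance, spec = spec, seed = as.integer(seed))
}

#' @export
print.ncc_matched_sets <- function(x, ...) {
  slots <- sum(vapply(x, function(ms) length(ms$control_ids), integer(1)))
  short <- sum(vapply(x, function(ms) ms$short, logical(1)))
  cat("<ncc_matched_sets> ", length(x), " matched sets, ", slots,
      " control slots", if (short) paste0(" (", short, " short)"), "\n",
      sep = "")
  invisible(x)
}

#' Flatten matched sets to a long data frame
#'
#' One row per member (case first, then controls) per set, in the export
#' schema `set_id, role, subject_id, event_day, distance, short_flag`
#' (distance is `NA` for the case row).
#'
#' @param x an `ncc_matched_sets`.
#' @param ... unused.
#' @return A data frame.
#' @export
as.data.frame.ncc_matched_sets <- function(x, ...) {
  rows <- lapply(seq_along(x), function(i) {
    ms <- x[[i]]
    data.frame(set_id = i,
               role = c("case", rep("control", length(ms$control_ids))),
               subject_id = c(ms$case_id, ms$control_ids),
               event_day = ms$event_day,
               distance = c(NA_real_, ms$distances),
               short_flag = ms$short,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write matched sets to CSV
#' @param x an `ncc_matched_sets`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matched_sets <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
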