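# Builders for tiny in-code fixtures and independent oracles used across
# the suite. The oracles deliberately re-derive quantities with naive code
# (explicit inverses, double loops) so they share nothing with the package
# implementation they check.

make_subjects <- function(id, sex = "male", ga = 30, bw = 900,
                          arm = "early", exit_day = 56L, event = FALSE,
                          event_day = NA_integer_) {
  n <- length(id)
  data.frame(id = id,
             sex = rep_len(sex, n),
             gestational_age = rep_len(ga, n),
             birth_weight = rep_len(bw, n),
             trial_arm = rep_len(arm, n),
             exit_day = as.integer(rep_len(exit_day, n)),
             event = rep_len(event, n),
             event_day = as.integer(rep_len(event_day, n)),
             stringsAsFactors = FALSE)
}

make_feed <- function(id, day, feed_type) {
  data.frame(id = id, day = as.integer(day), feed_type = feed_type,
             stringsAsFactors = FALSE)
}

# constant daily breast log so subjects pass feed-log-based rules
breast_log <- function(ids, days = 0:5) {
  do.call(rbind, lapply(ids, function(i) make_feed(i, days, "breast")))
}

# explicit 2x2 inverse, independent of solve()
inv2 <- function(V) {
  det <- V[1, 1] * V[2, 2] - V[1, 2] * V[2, 1]
  matrix(c(V[2, 2], -V[2, 1], -V[1, 2], V[1, 1]), 2, 2) / det
}

ref_mahalanobis <- function(x, y, V) {
  d <- x - y
  sqrt(as.numeric(t(d) %*% inv2(V) %*% d))
}

# naive conditional log likelihood: double loop, no shared code
ref_clogit_ll <- function(beta, X, case, set_id) {
  total <- 0
  for (s in unique(set_id)) {
    rows <- which(set_id == s)
    denom <- 0
    num <- NA_real_
    for (r in rows) {
      e <- exp(sum(X[r, ] * beta))
      denom <- denom + e
      if (case[r]) num <- e
    }
    total <- total + log(num / denom)
  }
  total
}

# random 1:m matched-set analysis rows for fitter tests
random_clogit_rows <- function(n_sets, m, p = 1L, beta = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(beta)) beta <- rep(0.5, p)
  rows <- lapply(seq_len(n_sets), function(j) {
    X <- matrix(rnorm((m + 1) * p), m + 1, p)
    eta <- as.numeric(X %*% beta)
    pr <- exp(eta) / sum(exp(eta))
    case_row <- sample.int(m + 1, 1, prob = pr)
    df <- data.frame(set_id = j, is_case = seq_len(m + 1) == case_row)
    for (k in seq_len(p)) df[[paste0("x", k)]] <- X[, k]
    df
  })
  do.call(rbind, rows)
}

# random single-subject feed log on days 0..horizon (each day present with
# probability p_obs), used for exposure property tests
random_feed_log <- function(horizon = 30L, p_obs = 0.8) {
  days <- which(runif(horizon + 1L) < p_obs) - 1L
  make_feed(id = rep("X", length(days)), day = days,
            feed_type = sample(c("breast", "formula", "fortifier",
                                 "unknown"),
                               length(days), replace = TRUE,
                               prob = c(0.55, 0.2, 0.15, 0.1)))
}

all_exposure_flags <- function(log, index_day, max_gap = 2L) {
  filled <- fill_feed_gaps(log[log$day < index_day, , drop = FALSE],
                           max_gap = max_gap)
  vapply(default_exposures(), classify_exposure, logical(1),
         filled = filled, index_day = index_day)
}

# independent re-derivation of risk-set eligibility from the design rules
ref_eligible <- function(subjects, case_id, event_day, prior_ids) {
  ok <- logical(nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    ok[i] <- s$id != case_id &&
      !(s$id %in% prior_ids) &&
      s$exit_day >= event_day &&
      !(s$event && s$event_day <= event_day)
  }
  subjects$id[ok]
}
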