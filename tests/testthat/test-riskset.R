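test_that("estimate_covariance matches the textbook formula and guards", {
  ga <- c(27.1, 29.4, 30.2, 31.8, 33.5)
  bw <- c(610, 840, 905, 1120, 1380)
  ch <- cohort(make_subjects(sprintf("C%d", 1:5), ga = ga, bw = bw))
  S <- estimate_covariance(ch)
  # hand formula: sum of centred cross-products over n - 1
  cc <- function(a, b) sum((a - mean(a)) * (b - mean(b))) / 4
  expect_equal(S[1, 1], cc(ga, ga))
  expect_equal(S[2, 2], cc(bw, bw))
  expect_equal(S[1, 2], cc(ga, bw))
  expect_equal(S[1, 2], S[2, 1])

  # zero-variance factor is named
  flat <- cohort(make_subjects(sprintf("C%d", 1:5), ga = 30, bw = bw))
  expect_error(estimate_covariance(flat), "gestational_age")
  # fewer subjects than factors + 1
  tiny <- cohort(make_subjects(c("A", "B"), ga = c(29, 30),
                               bw = c(800, 900)))
  expect_error(estimate_covariance(tiny), "at least 3")
  # perfectly collinear factors fall back to a ridge, with a warning
  lin <- cohort(make_subjects(sprintf("C%d", 1:5), ga = ga, bw = ga * 10))
  expect_warning(S2 <- estimate_covariance(lin), "ridge")
  expect_gt(min(eigen(S2, symmetric = TRUE)$values), 0)
})

test_that("estimated covariance of standardized independent factors is near identity", {
  set.seed(101)
  n <- 10000
  # unit-variance independent factors (shifted to stay positive)
  ch <- cohort(make_subjects(sprintf("S%05d", 1:n), ga = 100 + rnorm(n),
                             bw = 100 + rnorm(n)))
  S <- estimate_covariance(ch)
  expect_lt(max(abs(S - diag(2))), 0.05)
})

test_that("mahalanobis_distance agrees with an explicit-inverse oracle", {
  expect_equal(mahalanobis_distance(c(30, 900), c(30, 900), diag(2)), 0)
  expect_equal(mahalanobis_distance(c(3, 4), c(0, 0), diag(2)), 5)
  V <- matrix(c(4, 2, 2, 3), 2, 2)
  expect_equal(mahalanobis_distance(c(1, 1), c(0, 0), V),
               ref_mahalanobis(c(1, 1), c(0, 0), V))
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(2); y <- rnorm(2)
    A <- matrix(rnorm(4), 2)
    V <- crossprod(A) + diag(0.5, 2)
    expect_equal(mahalanobis_distance(x, y, V), ref_mahalanobis(x, y, V))
    expect_equal(mahalanobis_distance(x, y, V),
                 mahalanobis_distance(y, x, V))
  }
  expect_error(mahalanobis_distance(c(1, 1), c(0, 0),
                                    matrix(c(1, 1, 1, 1), 2)), "singular")
  expect_error(mahalanobis_distance(c(1, 1, 1), c(0, 0), diag(2)),
               "dimension")
})

test_that("risk set holds everyone still at risk, excluding the case and prior cases", {
  # 12 subjects, one develops the outcome at day 3: 11 remain at risk
  subj <- make_subjects(sprintf("I%02d", 1:12), ga = 25 + (1:12) / 2,
                        bw = 600 + 40 * (1:12))
  subj$event[1] <- TRUE
  subj$event_day[1] <- 3L
  subj$exit_day[1] <- 3L
  ch <- cohort(subj)
  rs <- build_risk_set(ch, "I01", 3L)
  expect_equal(length(rs$eligible_ids), 11L)
  expect_false("I01" %in% rs$eligible_ids)

  # a day-2 case never re-enters a day-5 risk set, whatever its exit day
  subj$event[2] <- TRUE; subj$event_day[2] <- 2L
  subj$event[3] <- TRUE; subj$event_day[3] <- 5L
  subj$event[1] <- FALSE; subj$event_day[1] <- NA_integer_
  subj$exit_day[1] <- 56L; subj$exit_day[2] <- 56L
  ch <- cohort(subj)
  rs5 <- build_risk_set(ch, "I03", 5L, prior_case_ids = "I02")
  expect_false("I02" %in% rs5$eligible_ids)
  # ... and the exclusion holds even without the explicit prior list
  rs5b <- build_risk_set(ch, "I03", 5L)
  expect_false("I02" %in% rs5b$eligible_ids)

  # exiting without an event on the event day still counts as at risk;
  # a same-day event does not
  subj$exit_day[4] <- 5L
  subj$event[5] <- TRUE; subj$event_day[5] <- 5L; subj$exit_day[5] <- 5L
  ch <- cohort(subj)
  rs5c <- build_risk_set(ch, "I03", 5L, prior_case_ids = "I02")
  expect_true("I04" %in% rs5c$eligible_ids)
  expect_false("I05" %in% rs5c$eligible_ids)

  # exhausted cohort -> empty risk set with a warning
  lone <- make_subjects(c("A", "B"), exit_day = c(10L, 2L))
  lone$event[1] <- TRUE; lone$event_day[1] <- 9L; lone$exit_day[1] <- 9L
  ch <- cohort(lone)
  expect_warning(rs0 <- build_risk_set(ch, "A", 9L), "empty risk set")
  expect_equal(length(rs0$eligible_ids), 0L)
})

test_that("control selection is exact on sex and minimal in Mahalanobis distance", {
  spec <- matching_spec(covariance = diag(2))
  subj <- make_subjects(c("CASE", sprintf("M%d", 1:6), "F1"),
                        sex = c(rep("male", 7), "female"),
                        ga = 30, bw = c(900, 901, 905, 903, 930, 902, 904,
                                        900))
  subj$event[1] <- TRUE; subj$event_day[1] <- 5L
  ch <- cohort(subj)
  rs <- build_risk_set(ch, "CASE", 5L)
  set.seed(1)
  ms <- select_controls(rs, ch, spec)
  # 6 male candidates with distinct distances: the 4 closest by brute force
  d_all <- abs(c(901, 905, 903, 930, 902, 904) - 900)
  want <- sprintf("M%d", order(d_all)[1:4])
  expect_setequal(ms$control_ids, want)
  expect_false(ms$short)
  expect_false("F1" %in% ms$control_ids)
  expect_equal(sort(unname(ms$distances)), sort(d_all)[1:4])

  # exactly m same-sex candidates: all taken regardless of distance
  subj4 <- subj[1:5, ]
  ch4 <- cohort(subj4)
  rs4 <- build_risk_set(ch4, "CASE", 5L)
  ms4 <- select_controls(rs4, ch4, spec)
  expect_setequal(ms4$control_ids, sprintf("M%d", 1:4))
  expect_false(ms4$short)

  # fewer than m: short flag
  subj2 <- subj[1:3, ]
  ch2 <- cohort(subj2)
  ms2 <- select_controls(build_risk_set(ch2, "CASE", 5L), ch2, spec)
  expect_true(ms2$short)
  expect_equal(length(ms2$control_ids), 2L)

  # no same-stratum candidate at all: empty, flagged, with a warning
  solo <- make_subjects(c("CASE", "F1"), sex = c("male", "female"))
  solo$event[1] <- TRUE; solo$event_day[1] <- 5L
  chs <- cohort(solo)
  expect_warning(ms0 <- select_controls(build_risk_set(chs, "CASE", 5L),
                                        chs, spec), "no eligible")
  expect_true(ms0$short)
  expect_equal(length(ms0$control_ids), 0L)
})

test_that("boundary ties are broken uniformly at random", {
  spec <- matching_spec(covariance = diag(2))
  subj <- make_subjects(c("CASE", "A", "B", "C", "T1", "T2"),
                        ga = 30,
                        bw = c(900, 901, 902, 903, 904, 904))
  subj$event[1] <- TRUE; subj$event_day[1] <- 5L
  ch <- cohort(subj)
  rs <- build_risk_set(ch, "CASE", 5L)
  set.seed(2024)
  picks <- replicate(1000, {
    ms <- select_controls(rs, ch, spec)
    "T1" %in% ms$control_ids
  })
  p_hat <- mean(picks)
  expect_gt(p_hat, 0.44)
  expect_lt(p_hat, 0.56)
  # interior members are always selected
  set.seed(2025)
  ms <- select_controls(rs, ch, spec)
  expect_true(all(c("A", "B", "C") %in% ms$control_ids))
})

test_that("sample_all processes cases in event order, deterministically", {
  set.seed(31)
  subj <- make_subjects(sprintf("S%02d", 1:20),
                        sex = rep(c("male", "female"), 10),
                        ga = rnorm(20, 30, 2), bw = rnorm(20, 900, 150))
  subj$event[c(2, 5, 9)] <- TRUE
  subj$event_day[c(2, 5, 9)] <- c(18L, 3L, 3L)
  subj$exit_day[c(2, 5, 9)] <- c(18L, 3L, 3L)
  ch <- cohort(subj)
  spec <- matching_spec(controls_per_case = 2L)
  ms1 <- sample_all(ch, spec, seed = 99)
  ms2 <- sample_all(ch, spec, seed = 99)
  expect_identical(as.data.frame(ms1), as.data.frame(ms2))
  # event days are processed in increasing order
  days <- vapply(ms1, `[[`, integer(1), "event_day")
  expect_true(all(diff(days) >= 0))
  # the day-18 case was eligible as a control in the day-3 sets
  early_controls <- unlist(lapply(ms1[days == 3], `[[`, "control_ids"))
  cases <- vapply(ms1, `[[`, character(1), "case_id")
  expect_true("S02" %in% cases)
  # no set contains its own case, a prior case, or a same-day case
  for (i in seq_along(ms1)) {
    s <- ms1[[i]]
    expect_false(s$case_id %in% s$control_ids)
    expect_false(anyDuplicated(s$control_ids) > 0)
    prior <- cases[seq_len(i - 1)]
    expect_false(any(s$control_ids %in%
                       cases[days <= s$event_day & cases != s$case_id]))
  }

  # single case -> single matched set
  one <- subj[1:8, ]
  one$event <- FALSE; one$event_day <- NA_integer_
  one$event[3] <- TRUE; one$event_day[3] <- 4L; one$exit_day[3] <- 4L
  ch1 <- cohort(one)
  msx <- sample_all(ch1, spec, seed = 5)
  expect_length(msx, 1L)
})

test_that("control reuse across sets is allowed and accounted", {
  # two well-separated cases share the same small pool of male controls
  subj <- make_subjects(c("C1", "C2", "X", "Y", "Z"),
                        ga = c(28, 28.1, 28.05, 28.2, 33),
                        bw = c(700, 710, 705, 715, 1400))
  subj$event[1:2] <- TRUE
  subj$event_day[1:2] <- c(4L, 9L)
  subj$exit_day[1:2] <- c(4L, 9L)
  ch <- cohort(subj)
  ms <- sample_all(ch, matching_spec(controls_per_case = 3L,
                                     covariance = diag(2)), seed = 1)
  long <- as.data.frame(ms)
  ctrl <- long$subject_id[long$role == "control"]
  # X, Y, Z serve both cases; C2 additionally serves C1's set
  expect_equal(sum(ctrl == "X"), 2L)
  total_slots <- length(ctrl)
  expect_lte(length(unique(ctrl)), total_slots)
  expect_equal(total_slots, 3L + 3L)  # m slots per case, none short
})
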