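test_that("gap filling fills short same-type runs and nothing else", {
  # no gaps: identity
  log <- make_feed(rep("X", 4), 0:3, c("breast", "breast", "formula",
                                       "formula"))
  expect_identical(fill_feed_gaps(log)$feed_type, log$feed_type)

  # one missing day flanked by the same type is filled with it
  log <- make_feed(rep("X", 2), c(4, 6), c("breast", "breast"))
  filled <- fill_feed_gaps(log, max_gap = 2)
  expect_equal(filled$feed_type[filled$day == 5], "breast")
  # ... leading days before the first record stay unknown
  expect_true(all(filled$feed_type[filled$day < 4] == "unknown"))

  # conflicting flanks stay unknown
  log <- make_feed(rep("X", 2), c(4, 6), c("breast", "formula"))
  expect_equal(fill_feed_gaps(log, 2)$feed_type[6], "unknown")

  # runs longer than max_gap stay unknown even with matching flanks
  log <- make_feed(rep("X", 2), c(0, 4), c("formula", "formula"))
  filled <- fill_feed_gaps(log, max_gap = 2)
  expect_true(all(filled$feed_type[2:4] == "unknown"))
  filled3 <- fill_feed_gaps(log, max_gap = 3)
  expect_true(all(filled3$feed_type[2:4] == "formula"))

  # recorded values are never altered
  log <- make_feed(rep("X", 3), c(0, 2, 4), c("breast", "unknown",
                                              "breast"))
  filled <- fill_feed_gaps(log, 5)
  expect_equal(filled$feed_type[c(1, 3, 5)], c("breast", "unknown",
                                               "breast"))
  # unknown flanks never propagate a type
  expect_equal(filled$feed_type[2], "unknown")

  expect_equal(nrow(fill_feed_gaps(make_feed(character(0), integer(0),
                                             character(0)))), 0L)
})

test_that("exposure windows honour their boundaries and the index day", {
  defs <- default_exposures()
  flags <- function(log, index) all_exposure_flags(log, index, max_gap = 2)

  # formula on day 10 -> exposed under all cumulative definitions at day 20
  log <- make_feed(rep("X", 21), 0:20, c(rep("breast", 10), "formula",
                                         rep("breast", 10)))
  f <- flags(log, 20)
  expect_true(f[["first_14"]])
  expect_true(f[["first_28"]])
  expect_true(f[["any_prior"]])

  # exclusive breast feeding -> nothing fires
  log <- make_feed(rep("X", 30), 0:29, "breast")
  expect_false(any(flags(log, 25)))

  # first formula on day 16: outside the 14-day window, inside the 28-day one
  log <- make_feed(rep("X", 20), 0:19, c(rep("breast", 16),
                                         rep("formula", 4)))
  f <- flags(log, 20)
  expect_false(f[["first_14"]])
  expect_true(f[["first_28"]])

  # a switch on day 15 is outside the 7-day lookback from day 25...
  log <- make_feed(rep("X", 26), 0:25, c(rep("breast", 15),
                                         rep("fortifier", 11)))
  expect_false(flags(log, 25)[["change_within_7"]])
  # ...but inside it from day 20
  expect_true(flags(log, 20)[["change_within_7"]])

  # unknown days break the change chain
  log <- make_feed(rep("X", 3), 14:16, c("breast", "unknown", "formula"))
  filled <- fill_feed_gaps(log, 2)
  expect_false(classify_exposure(filled, defs$change_within_7, 20))

  # the index day itself never counts: exposure on the event day is ignored
  log <- make_feed(rep("X", 6), 0:5, c(rep("breast", 5), "formula"))
  expect_false(flags(log, 5)[["any_prior"]])
  expect_true(flags(log, 6)[["any_prior"]])
})

test_that("analysis table classifies every member at the case's event day", {
  subj <- make_subjects(c("CASE", "K1", "K2", "K3", "K4"),
                        ga = c(29, 29.1, 29.2, 28.9, 28.8),
                        bw = c(800, 810, 820, 790, 780))
  subj$event[1] <- TRUE; subj$event_day[1] <- 10L; subj$exit_day[1] <- 10L
  fl <- rbind(breast_log(c("CASE", "K1", "K2", "K3"), days = 0:9),
              make_feed(rep("K4", 10), 0:9,
                        c(rep("breast", 5), rep("formula", 5))))
  ch <- cohort(subj, fl)
  ms <- sample_all(ch, matching_spec(covariance = diag(2)), seed = 1)
  defs <- default_exposures()[c("first_14", "any_prior")]
  tab <- build_analysis_table(ms, ch, defs)
  expect_equal(nrow(tab), 5L)
  expect_equal(sum(tab$is_case), 1L)
  expect_true(all(tab$index_day == 10L))
  expect_setequal(names(tab)[6:7], c("first_14", "any_prior"))
  expect_true(tab$any_prior[tab$subject_id == "K4"])
  expect_false(any(tab$any_prior[tab$subject_id != "K4"]))

  # a member missing from the cohort is an error
  ms_bad <- ms
  ms_bad[[1]]$control_ids[1] <- "GHOST"
  expect_error(build_analysis_table(ms_bad, ch, defs), "GHOST")
})

test_that("a reused control is re-classified at each set's index day", {
  # S switches to formula on day 5; controls a day-3 case and a day-10 case
  subj <- make_subjects(c("C1", "C2", "S", "T", "U"),
                        ga = c(29, 29, 29.1, 29.2, 29.3),
                        bw = c(800, 805, 810, 815, 820))
  subj$event[1:2] <- TRUE
  subj$event_day[1:2] <- c(3L, 10L)
  subj$exit_day[1:2] <- c(3L, 10L)
  fl <- rbind(breast_log(c("C1", "T", "U"), 0:2),
              breast_log("C2", 0:9),
              make_feed(rep("S", 15), 0:14, c(rep("breast", 5),
                                              rep("formula", 10))))
  ch <- cohort(subj, fl)
  ms <- sample_all(ch, matching_spec(controls_per_case = 3L,
                                     covariance = diag(2)), seed = 3)
  tab <- build_analysis_table(ms, ch,
                              default_exposures()["any_prior"])
  s_rows <- tab[tab$subject_id == "S", ]
  expect_equal(nrow(s_rows), 2L)
  expect_false(s_rows$any_prior[s_rows$index_day == 3])
  expect_true(s_rows$any_prior[s_rows$index_day == 10])
})

test_that("cumulative exposures are monotone in the index day and nested", {
  set.seed(77)
  defs <- default_exposures()
  for (rep in 1:40) {
    log <- random_feed_log()
    flags_by_day <- t(vapply(0:32, function(d) all_exposure_flags(log, d),
                             logical(4)))
    colnames(flags_by_day) <- names(defs)
    for (nm in c("first_14", "first_28", "any_prior"))
      expect_true(all(diff(flags_by_day[, nm]) >= 0), label = nm)
    # nested windows: first_14 => first_28 => any_prior
    expect_true(all(!flags_by_day[, "first_14"] |
                      flags_by_day[, "first_28"]))
    expect_true(all(!flags_by_day[, "first_28"] |
                      flags_by_day[, "any_prior"]))
  }
})

test_that("records on or after the index day can never alter any flag", {
  set.seed(88)
  for (rep in 1:60) {
    log <- random_feed_log()
    index_day <- sample(0:25, 1)
    before <- all_exposure_flags(log, index_day)
    # mutate the log arbitrarily at days >= index_day
    mutated <- log[log$day < index_day, , drop = FALSE]
    extra_days <- index_day + sample(0:5, sample(1:4, 1))
    mutated <- rbind(mutated,
                     make_feed(rep("X", length(extra_days)),
                               unique(extra_days),
                               sample(c("formula", "breast", "fortifier"),
                                      length(unique(extra_days)),
                                      replace = TRUE)))
    after <- all_exposure_flags(mutated, index_day)
    expect_identical(before, after)
  }
})
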