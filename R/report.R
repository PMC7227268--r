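# Descriptive reporting and the end-to-end pipeline.

#' Baseline characteristics of cases, matched controls and non-cases
#'
#' Three-column descriptive table in the conventional layout: cases, matched
#' controls, non-cases. The matched-control column counts control *slots* --
#' a subject sampled in three sets contributes three times -- with the
#' unique-control, sampled-more-than-once and future-case counts reported as
#' footnotes. Categorical rows show n (%), continuous rows median (IQR).
#'
#' @param x the `ncc_cohort`.
#' @param matched_sets an `ncc_matched_sets` from [sample_all()].
#' @return An object of class `ncc_baseline_table`: a data frame (columns
#'   `variable`, `cases`, `matched_controls`, `non_cases`) with an
#'   `accounting` attribute (named list of the footnote counts).
#' @export
baseline_table <- function(x, matched_sets) {
  stopifnot(inherits(x, "ncc_cohort"), inherits(matched_sets,
                                                "ncc_matched_sets"))
  if (!length(matched_sets)) stop("matched_sets is empty")
  s <- x$subjects
  long <- as.data.frame(matched_sets)
  ctrl_ids <- long$subject_id[long$role == "control"]
  case_ids <- unique(long$subject_id[long$role == "case"])
  g_case <- s[match(case_ids, s$id), , drop = FALSE]
  g_ctrl <- s[match(ctrl_ids, s$id), , drop = FALSE]   # one row per slot
  g_non <- s[!s$event, , drop = FALSE]

  np <- function(k, n) sprintf("%d (%.1f)", k, if (n) 100 * k / n else 0)
  miqr <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
    sprintf("%s (%s to %s)", format(q[2], digits = 3),
            format(q[1], digits = 3), format(q[3], digits = 3))
  }
  one_group <- function(g) {
    n <- nrow(g)
    c("Allocated to early arm, n (%)" = np(sum(!is.na(g$trial_arm) &
                                                 g$trial_arm == "early"), n),
      "Male sex, n (%)" = np(sum(g$sex == "male"), n),
      "Gestational age (weeks), median (IQR)" = miqr(g$gestational_age),
      "  < 29 weeks, n (%)" = np(sum(g$gestational_age < 29), n),
      "  >= 29 weeks, n (%)" = np(sum(g$gestational_age >= 29), n),
      "Birth weight (g), median (IQR)" = miqr(g$birth_weight),
      "  < 750 g, n (%)" = np(sum(g$birth_weight < 750), n),
      "  >= 750 g, n (%)" = np(sum(g$birth_weight >= 750), n))
  }
  ca <- one_group(g_case)
  co <- one_group(g_ctrl)
  no <- one_group(g_non)
  out <- data.frame(variable = names(ca), cases = unname(ca),
                    matched_controls = unname(co), non_cases = unname(no),
                    stringsAsFactors = FALSE)
  tab <- table(ctrl_ids)
  future_ids <- unique(ctrl_ids[s$event[match(ctrl_ids, s$id)]])
  attr(out, "accounting") <- list(
    n_cases = nrow(g_case),
    n_control_slots = length(ctrl_ids),
    n_unique_controls = length(tab),
    n_sampled_more_than_once = sum(tab > 1),
    n_future_cases_as_controls = length(future_ids),
    n_non_cases = nrow(g_non))
  class(out) <- c("ncc_baseline_table", "data.frame")
  out
}

#' @export
print.ncc_baseline_table <- function(x, ...) {
  a <- attr(x, "accounting")
  hdr <- sprintf("%-40s %-22s %-22s %-22s", "",
                 sprintf("Cases (n=%d)", a$n_cases),
                 sprintf("Matched controls (n=%d)", a$n_control_slots),
                 sprintf("Non-cases (n=%d)", a$n_non_cases))
  cat(hdr, "\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-40s %-22s %-22s %-22s\n", x$variable[i], x$cases[i],
                x$matched_controls[i], x$non_cases[i]))
  }
  cat(sprintf("Unique controls: %d; sampled more than once: %d; ",
              a$n_unique_controls, a$n_sampled_more_than_once),
      sprintf("future cases used as controls: %d\n",
              a$n_future_cases_as_controls), sep = "")
  invisible(x)
}

#' Read a run configuration file
#'
#' YAML (or JSON, which YAML subsumes) with keys `paths` (`subjects`,
#' `feed_log`, `output_dir`), `seed` (mandatory), and optionally `max_gap`,
#' `exclusion_rules`, `adjust_for`, `matching` (`exact_factors`,
#' `distance_factors`, `controls_per_case`, `ridge_epsilon`), `exposures`
#' (list of `name`/`kind`/`k`/`exposed_types`) and `simulation` (arguments
#' of [simulation_config()], used by the simulate command).
#'
#' @param path config file path.
#' @return A named list of class `ncc_run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a plain named list with the same schema.
#' @export
as_run_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("run config must set a seed")
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$max_gap)) cfg$max_gap <- 2L
  if (is.null(cfg$exclusion_rules)) cfg$exclusion_rules <- character(0)
  if (is.null(cfg$adjust_for)) cfg$adjust_for <- "trial_arm"
  mt <- cfg$matching
  cfg$matching <- matching_spec(
    exact_factors = mt$exact_factors %||% "sex",
    distance_factors = mt$distance_factors %||% c("gestational_age",
                                                  "birth_weight"),
    controls_per_case = mt$controls_per_case %||% 4L,
    ridge_epsilon = mt$ridge_epsilon %||% 1e-8)
  if (!is.null(cfg$exposures)) {
    defs <- lapply(cfg$exposures, function(e) {
      # [[ with exact names: $ would partially match 'k' to 'kind'
      exposure_definition(e[["name"]], e[["kind"]], e[["k"]],
                          e[["exposed_types"]] %||% c("formula",
                                                      "fortifier"))
    })
    names(defs) <- vapply(defs, `[[`, character(1), "name")
    cfg$exposures <- defs
  } else {
    cfg$exposures <- default_exposures()
  }
  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    sim_args$seed <- sim_args$seed %||% cfg$seed
    cfg$simulation <- do.call(simulation_config, sim_args)
  }
  class(cfg) <- "ncc_run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small multiplicative fingerprint of the config for stamping artifacts
config_fingerprint <- function(cfg) {
  cfg <- unclass(cfg)
  s <- paste(deparse(cfg[sort(names(cfg))]), collapse = "\n")
  b <- utf8ToInt(s)
  mulmod32 <- function(a, m) {
    lo <- a %% 65536
    hi <- a %/% 65536
    (((hi * m) %% 65536) * 65536 + lo * m) %% 4294967296
  }
  h <- 2166136261
  for (v in b) h <- mulmod32((h + v) %% 4294967296, 16777619)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Simulate a cohort and write it in the standard CSV schema
#'
#' For a run config the files go to its `paths$subjects` / `paths$feed_log`
#' (so a subsequent [run_pipeline()] reads what was simulated); for a bare
#' simulation config they go to `output_dir` as `subjects.csv` and
#' `feed_log.csv`.
#'
#' @param config an `ncc_run_config` with a `simulation` entry, or an
#'   `ncc_sim_config`.
#' @param output_dir directory used when `config` is a bare simulation
#'   config.
#' @return Paths of the two files, invisibly.
#' @export
simulate_to_files <- function(config, output_dir = NULL) {
  if (inherits(config, "ncc_run_config")) {
    if (is.null(config$simulation))
      stop("run config has no 'simulation' section")
    sim <- config$simulation
    sp <- config$paths$subjects
    fp <- config$paths$feed_log
    if (is.null(sp) || is.null(fp))
      stop("run config must set paths$subjects and paths$feed_log")
  } else {
    sim <- config
    if (is.null(output_dir)) stop("output_dir is required")
    sp <- file.path(output_dir, "subjects.csv")
    fp <- file.path(output_dir, "feed_log.csv")
  }
  for (p in unique(dirname(c(sp, fp))))
    dir.create(p, recursive = TRUE, showWarnings = FALSE)
  ch <- simulate_cohort(sim)
  write_cohort(ch, sp, fp)
}

#' Run the full matched nested case-control pipeline
#'
#' Executes read, exclude, sample, classify, fit and report stages, writing
#' five artifacts into the configured output directory: `matched_sets.csv`,
#' `analysis_table.csv`, `or_report.csv`, `baseline_table.txt` and
#' `run.log`. Every artifact carries the config fingerprint and seed; rerun
#' with identical inputs and config, the CSV artifacts are byte-identical.
#' Any stage failure aborts with an error message naming the stage.
#'
#' @param config an `ncc_run_config` (see [read_run_config()]) or a path to
#'   a config file.
#' @return Invisibly, a list with the in-memory results and artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "ncc_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  fp <- config_fingerprint(config)
  stamp <- sprintf("# nestedcc run %s seed %d", fp, config$seed)
  out_dir <- stage("config", {
    if (is.null(config$paths$output_dir)) stop("paths$output_dir is not set")
    dir.create(config$paths$output_dir, recursive = TRUE,
               showWarnings = FALSE)
    config$paths$output_dir
  })
  note("run ", fp, " seed ", config$seed)

  ch <- stage("read", {
    if (is.null(config$paths$subjects) || is.null(config$paths$feed_log))
      stop("paths$subjects and paths$feed_log are required")
    read_cohort(config$paths$subjects, config$paths$feed_log)
  })
  note("read ", nrow(ch$subjects), " subjects, ", nrow(ch$feed_log),
       " feed-log records")

  excl <- stage("exclude", exclude_invalid(ch, config$exclusion_rules))
  ch <- excl$cohort
  note("excluded ", length(unique(excl$exclusions$id)), " subjects (",
       nrow(excl$exclusions), " rule hits); ", nrow(ch$subjects), " remain")

  sets <- stage("sample", sample_all(ch, config$matching, config$seed))
  note("sampled ", length(sets), " matched sets")

  rows <- stage("classify",
                build_analysis_table(sets, ch, config$exposures,
                                     config$max_gap))
  note("classified ", nrow(rows), " member rows for ",
       length(config$exposures), " exposures")

  fits <- stage("fit", fit_exposure_models(rows, names(config$exposures),
                                           config$adjust_for))
  report <- stage("report", odds_ratio_report(fits))
  base_tab <- stage("report", baseline_table(ch, sets))

  write_stamped_csv <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(stamp, con)
    utils::write.csv(df, con, row.names = FALSE, na = "")
    path
  }
  paths <- list(
    matched_sets = write_stamped_csv(as.data.frame(sets),
                                     file.path(out_dir, "matched_sets.csv")),
    analysis_table = write_stamped_csv(rows,
                                       file.path(out_dir,
                                                 "analysis_table.csv")),
    or_report = write_stamped_csv(as.data.frame(report),
                                  file.path(out_dir, "or_report.csv")),
    baseline_table = {
      p <- file.path(out_dir, "baseline_table.txt")
      txt <- c(stamp, utils::capture.output(print(base_tab)))
      writeLines(txt, p)
      p
    })
  note("wrote ", length(paths), " artifacts to ", out_dir)
  log_path <- file.path(out_dir, "run.log")
  writeLines(c(stamp, log_lines), log_path)
  paths$log <- log_path
  invisible(list(cohort = ch, exclusions = excl$exclusions,
                 matched_sets = sets, analysis_table = rows, fits = fits,
                 or_report = report, baseline_table = base_tab,
                 artifact_paths = paths, fingerprint = fp))
}
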