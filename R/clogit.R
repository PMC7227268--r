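# Conditional logistic regression for 1:m matched sets.
#
# Each matched set is a stratum with exactly one case. The conditional
# likelihood for set j with members k is
#
#   L_j(beta) = exp(x_case' beta) / sum_k exp(x_k' beta)
#
# which eliminates the set-specific intercept. The fitter maximises the sum
# of log L_j by Newton-Raphson with analytic gradient and Hessian,
# step-halving, and a separation diagnosis when the MLE diverges.

.logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# group rows into sets and validate the one-case-per-set contract
.clogit_sets <- function(x, case, set_id) {
  idx <- split(seq_along(case), set_id)
  for (j in seq_along(idx)) {
    nc <- sum(case[idx[[j]]])
    if (nc != 1L)
      stop("matched set ", names(idx)[j], " has ", nc,
           " cases; exactly one is required")
    if (length(idx[[j]]) < 2L)
      stop("matched set ", names(idx)[j], " has no controls")
  }
  idx
}

#' Conditional log likelihood for matched sets
#'
#' Sum over sets of the case's linear predictor minus the log-sum-exp of all
#' members' linear predictors. A set whose members share identical covariate
#' vectors contributes the constant `-log(set size)` regardless of `beta`
#' (it is non-informative).
#'
#' @param beta coefficient vector (length = `ncol(x)`).
#' @param x numeric covariate matrix, one row per set member.
#' @param case logical vector, `TRUE` for the case row of each set.
#' @param set_id set identifier per row; each set must contain exactly one
#'   case and at least one control.
#' @return The conditional log likelihood (a non-positive number at the MLE
#'   scale of interest).
#' @export
conditional_loglik <- function(beta, x, case, set_id) {
  x <- as.matrix(x)
  idx <- .clogit_sets(x, case, set_id)
  eta <- as.numeric(x %*% beta)
  ll <- 0
  for (rows in idx) {
    ll <- ll + eta[rows][case[rows]] - .logsumexp(eta[rows])
  }
  ll
}

# log likelihood, gradient and Hessian in one pass
.clogit_derivs <- function(beta, x, case, idx) {
  p <- length(beta)
  eta <- as.numeric(x %*% beta)
  ll <- 0
  g <- numeric(p)
  H <- matrix(0, p, p)
  for (rows in idx) {
    e <- eta[rows]
    m <- max(e)
    w <- exp(e - m)
    w <- w / sum(w)
    xs <- x[rows, , drop = FALSE]
    mu <- as.numeric(crossprod(w, xs))
    ll <- ll + e[case[rows]] - (m + log(sum(exp(e - m))))
    g <- g + xs[case[rows], ] - mu
    H <- H - (crossprod(xs * w, xs) - tcrossprod(mu))
  }
  list(ll = ll, grad = g, hess = H)
}

#' Fit conditional logistic regression on an analysis table
#'
#' Maximises the matched-set conditional likelihood by Newton-Raphson with
#' analytic gradient and Hessian, starting at `beta = 0`, halving any step
#' that decreases the log likelihood. Standard errors come from the inverse
#' observed information; 95% confidence intervals are Wald
#' (`exp(beta +/- 1.96 se)`). Sets with no within-set covariate variation
#' are retained (they contribute a constant) and counted as non-informative.
#' If the exposure perfectly predicts case status across informative sets
#' the MLE diverges; the fit is then returned flagged as separated and
#' non-converged, with the direction of divergence.
#'
#' @param rows analysis table from [build_analysis_table()] (needs columns
#'   `set_id`, `is_case`, the exposure, and any adjustment covariates).
#' @param exposure name of the logical/numeric exposure column.
#' @param adjust_for character vector of covariate columns to adjust for
#'   (factors/character columns are expanded to treatment-coded dummies).
#' @param grad_tol,ll_tol,max_iter convergence controls: stop when the
#'   gradient max-norm falls below `grad_tol` (1e-8) or the relative log
#'   likelihood change falls below `ll_tol` (1e-10).
#' @return An object of class `ncc_fit` with coefficients, standard errors,
#'   odds ratios with CI bounds, log likelihood, set counts, and convergence
#'   information.
#' @export
fit_clogit <- function(rows, exposure, adjust_for = character(0),
                       grad_tol = 1e-8, ll_tol = 1e-10, max_iter = 50L) {
  size <- stats::ave(seq_len(nrow(rows)), rows$set_id, FUN = length)
  if (any(size < 2L)) {
    warning("dropping ", length(unique(rows$set_id[size < 2L])),
            " matched set(s) with no controls")
    rows <- rows[size >= 2L, , drop = FALSE]
  }
  X <- .build_design(rows, exposure, adjust_for)
  case <- rows$is_case
  set_id <- rows$set_id
  idx <- .clogit_sets(X, case, set_id)

  informative <- vapply(idx, function(rws) {
    xs <- X[rws, , drop = FALSE]
    any(apply(xs, 2L, function(col) any(col != col[1])))
  }, logical(1))
  n_inf <- sum(informative)
  if (n_inf == 0L)
    stop("no discordant sets: every matched set is concordant on ",
         paste(colnames(X), collapse = ", "))
  for (j in seq_len(ncol(X))) {
    varies <- any(vapply(idx, function(rws) {
      col <- X[rws, j]
      any(col != col[1])
    }, logical(1)))
    if (!varies)
      stop("covariate '", colnames(X)[j],
           "' is constant within every matched set and cannot be estimated")
  }

  p <- ncol(X)
  beta <- numeric(p)
  d <- .clogit_derivs(beta, X, case, idx)
  converged <- FALSE
  separated <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(-d$hess, d$grad), error = function(e) NULL)
    if (is.null(step)) { separated <- TRUE; break }
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      dc <- .clogit_derivs(cand, X, case, idx)
      if (dc$ll >= d$ll || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    rel_change <- abs(dc$ll - d$ll) / (abs(d$ll) + 1e-300)
    beta <- cand
    d <- dc
    if (max(abs(d$grad)) < grad_tol || rel_change < ll_tol) {
      converged <- max(abs(d$grad)) < grad_tol || rel_change < ll_tol
      break
    }
    if (max(abs(beta)) > 30) { separated <- TRUE; break }
  }
  # a conditional log-odds ratio beyond +-10 (OR > 22000) signals that the
  # likelihood has no interior maximum (separation), not a real estimate
  if (max(abs(beta)) > 10) separated <- TRUE
  if (separated) converged <- FALSE

  se <- tryCatch(sqrt(diag(solve(-d$hess))), error = function(e)
    rep(NA_real_, p))
  if (converged && any(!is.finite(se))) converged <- FALSE
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  or <- data.frame(term = colnames(X),
                   odds_ratio = exp(beta),
                   ci_low = exp(beta - 1.96 * se),
                   ci_high = exp(beta + 1.96 * se),
                   stringsAsFactors = FALSE)
  structure(list(coefficients = beta,
                 standard_errors = se,
                 odds_ratios = or,
                 log_likelihood = d$ll,
                 n_sets = length(idx),
                 n_informative_sets = n_inf,
                 converged = converged,
                 separated = separated,
                 separation_direction = if (separated) sign(beta) else NULL,
                 iterations = iter,
                 n_cases = sum(case),
                 n_controls = sum(!case),
                 exposure = exposure,
                 adjust_for = adjust_for),
            class = "ncc_fit")
}

.build_design <- function(rows, exposure, adjust_for) {
  if (!exposure %in% names(rows))
    stop("exposure column '", exposure, "' not found")
  cols <- list()
  cols[[exposure]] <- as.numeric(rows[[exposure]])
  for (a in adjust_for) {
    if (!a %in% names(rows))
      stop("adjustment covariate '", a, "' not found")
    v <- rows[[a]]
    if (anyNA(v))
      stop("adjustment covariate '", a, "' has missing values (is this a ",
           "non-trial cohort without trial_arm?)")
    if (is.numeric(v) || is.logical(v)) {
      cols[[a]] <- as.numeric(v)
    } else {
      f <- factor(v)
      for (l in levels(f)[-1]) cols[[paste0(a, l)]] <- as.numeric(f == l)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' @export
print.ncc_fit <- function(x, ...) {
  cat("Conditional logistic regression (", x$n_sets, " matched sets, ",
      x$n_informative_sets, " informative)\n", sep = "")
  if (x$separated)
    cat("WARNING: separation detected; estimates diverge (direction: ",
        paste(sprintf("%s%+d", names(x$coefficients),
                      as.integer(x$separation_direction)), collapse = ", "),
        ")\n", sep = "")
  tab <- data.frame(coef = x$coefficients, se = x$standard_errors,
                    OR = x$odds_ratios$odds_ratio,
                    ci_low = x$odds_ratios$ci_low,
                    ci_high = x$odds_ratios$ci_high)
  print(round(tab, 4))
  cat("log-likelihood:", format(x$log_likelihood), " converged:",
      x$converged, " iterations:", x$iterations, "\n")
  invisible(x)
}

#' Fit every exposure, unadjusted and adjusted
#'
#' Convenience wrapper running [fit_clogit()] for each exposure column with
#' and without the adjustment covariates. Fits that fail (e.g. no discordant
#' sets) are recorded as `NULL` with the error message attached.
#'
#' @param rows analysis table.
#' @param exposures character vector of exposure column names.
#' @param adjust_for covariates for the adjusted fits (default `trial_arm`).
#' @return Nested named list `fits[[exposure]][[adjustment]]` with
#'   adjustment in `c("unadjusted", "adjusted")`.
#' @export
fit_exposure_models <- function(rows, exposures,
                                adjust_for = "trial_arm") {
  out <- list()
  for (e in exposures) {
    out[[e]] <- list()
    for (adj in c("unadjusted", "adjusted")) {
      av <- if (adj == "adjusted") adjust_for else character(0)
      out[[e]][[adj]] <- tryCatch(fit_clogit(rows, e, av),
                                  error = function(err) {
                                    structure(list(error =
                                                     conditionMessage(err)),
                                              class = "ncc_fit_failure")
                                  })
    }
  }
  out
}

#' Tabulate odds ratios across fits
#'
#' One row per exposure and adjustment: odds ratio for the exposure term
#' with its 95% CI, set counts and convergence flag. Failed or non-converged
#' fits keep their row with the odds ratio left blank.
#'
#' @param fits nested list from [fit_exposure_models()] (or any list of
#'   lists of `ncc_fit` objects keyed exposure then adjustment).
#' @return Data frame of class `ncc_or_report` with columns `exposure`,
#'   `adjustment`, `n_cases`, `n_controls`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `converged`, `n_informative_sets`.
#' @export
odds_ratio_report <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  rows <- list()
  for (e in names(fits)) {
    for (adj in names(fits[[e]])) {
      f <- fits[[e]][[adj]]
      if (inherits(f, "ncc_fit_failure") ||
          (inherits(f, "ncc_fit") && !f$converged)) {
        conv <- FALSE
        nc <- if (inherits(f, "ncc_fit")) f$n_cases else NA_integer_
        nk <- if (inherits(f, "ncc_fit")) f$n_controls else NA_integer_
        ni <- if (inherits(f, "ncc_fit")) f$n_informative_sets else
          NA_integer_
        or <- lo <- hi <- NA_real_
      } else {
        conv <- TRUE
        i <- match(f$exposure, f$odds_ratios$term)
        or <- f$odds_ratios$odds_ratio[i]
        lo <- f$odds_ratios$ci_low[i]
        hi <- f$odds_ratios$ci_high[i]
        nc <- f$n_cases
        nk <- f$n_controls
        ni <- f$n_informative_sets
      }
      rows[[paste(e, adj)]] <- data.frame(
        exposure = e, adjustment = adj, n_cases = nc, n_controls = nk,
        odds_ratio = or, ci_low = lo, ci_high = hi, converged = conv,
        n_informative_sets = ni, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("ncc_or_report", "data.frame")
  out
}

#' @export
print.ncc_or_report <- function(x, ...) {
  cat("Exposure odds ratios (conditional logistic regression)\n")
  df <- as.data.frame(x)
  df$odds_ratio <- ifelse(is.na(df$odds_ratio), "-",
                          sprintf("%.2f", df$odds_ratio))
  df$ci <- ifelse(is.na(df$ci_low), "-",
                  sprintf("(%.2f, %.2f)", df$ci_low, df$ci_high))
  print(df[, c("exposure", "adjustment", "n_cases", "n_controls",
               "odds_ratio", "ci", "converged")], row.names = FALSE)
  invisible(x)
}
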