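## Cox proportional-hazards fitting by Newton-Raphson on the partial
## likelihood. The engine works on a plain design matrix; fit_cox() adds the
## clinical factor coding used throughout the staging analyses.

# Per-risk-set sufficient statistics at the distinct event times:
# S0(t) = sum_{j: T_j >= t} w_j, S1(t) = sum w_j x_j, S2(t) = sum w_j x_j x_j'
# with w_j = exp(x_j' beta). Computed via cumulative sums over subjects
# sorted by decreasing follow-up time, so equal times (including censoring
# ties) all remain in the risk set at their own time.
cox_loglik_deriv <- function(X, time, event, beta, ties = "breslow") {
  n <- nrow(X); p <- ncol(X)
  lp <- drop(X %*% beta)
  lp <- lp - max(lp)            # stabilize exp(); cancels in all ratios
  w <- exp(lp)

  ord <- order(time, decreasing = TRUE)
  t_s <- time[ord]; e_s <- event[ord]; w_s <- w[ord]
  X_s <- X[ord, , drop = FALSE]; lp_s <- lp[ord]

  ev_times <- unique(t_s[e_s == 1])            # decreasing order
  # last index (in the sorted order) belonging to each risk set
  risk_end <- findInterval(-ev_times, sort(-t_s))

  cs0 <- cumsum(w_s)
  wX <- X_s * w_s
  cs1 <- apply(wX, 2L, cumsum)
  if (p == 1L) cs1 <- matrix(cs1, ncol = 1L)
  # upper triangle of the weighted cross-product, cumulated
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  cross <- wX[, pairs[, 1L], drop = FALSE] * X_s[, pairs[, 2L], drop = FALSE]
  cs2 <- apply(cross, 2L, cumsum)
  if (nrow(pairs) == 1L) cs2 <- matrix(cs2, ncol = 1L)

  unpack <- function(v) {
    M <- matrix(0, p, p)
    M[cbind(pairs[, 1L], pairs[, 2L])] <- v
    M[cbind(pairs[, 2L], pairs[, 1L])] <- v
    M
  }

  # death counts per distinct event time (decreasing order, matching
  # ev_times) and the total contribution of the deaths themselves
  d_t <- as.numeric(table(factor(t_s[e_s == 1],
                                 levels = ev_times)))
  ll <- sum(lp_s[e_s == 1])
  U <- colSums(X_s[e_s == 1, , drop = FALSE])

  S0v <- cs0[risk_end]
  S1m <- cs1[risk_end, , drop = FALSE]
  S2m <- cs2[risk_end, , drop = FALSE]

  if (ties == "breslow") {
    plain <- seq_along(ev_times)
  } else {
    plain <- which(d_t == 1)
  }
  if (length(plain) > 0L) {
    dd <- d_t[plain]
    ll <- ll - sum(dd * log(S0v[plain]))
    r1 <- S1m[plain, , drop = FALSE] / S0v[plain]
    U <- U - colSums(dd * r1)
    I <- unpack(colSums(dd * S2m[plain, , drop = FALSE] / S0v[plain])) -
      crossprod(r1, dd * r1)
  } else {
    I <- matrix(0, p, p)
  }

  if (ties == "efron") {
    # Efron: average out the within-tie ordering of the d deaths
    for (i in which(d_t > 1)) {
      at_t <- which(t_s == ev_times[i] & e_s == 1)
      d <- length(at_t)
      S0 <- S0v[i]; S1 <- S1m[i, ]; S2 <- unpack(S2m[i, ])
      wd <- w_s[at_t]
      S0d <- sum(wd)
      Xd <- X_s[at_t, , drop = FALSE]
      S1d <- colSums(Xd * wd)
      S2d <- crossprod(Xd * sqrt(wd))
      for (j in seq_len(d) - 1L) {
        f <- j / d
        S0j <- S0 - f * S0d
        S1j <- S1 - f * S1d
        ll <- ll - log(S0j)
        r1 <- S1j / S0j
        U <- U - r1
        I <- I + (S2 - f * S2d) / S0j - tcrossprod(r1)
      }
    }
  }
  list(loglik = ll, U = U, I = I)
}

#' Low-level Cox partial-likelihood fitter
#'
#' Newton-Raphson maximization of the Cox partial likelihood on a plain
#' design matrix, with Breslow or Efron handling of tied event times and
#' step-halving on non-increase. Most users want [fit_cox()], which adds
#' the clinical factor coding; this routine is exported for programmatic
#' use on arbitrary designs.
#'
#' @param X Numeric design matrix (one column per coefficient, no
#'   intercept).
#' @param time,event Follow-up times and 0/1 event flags.
#' @param ties `"breslow"` or `"efron"`.
#' @param tol Convergence tolerance on the log partial likelihood change.
#' @param max_iter Iteration cap; non-convergence and diverging
#'   coefficients (complete separation) raise errors with diagnostics.
#' @return List with `coefficients`, `var` (inverse observed information),
#'   `loglik` (named: `null` at beta = 0 and `final`), `iter` and `ties`.
#' @export
cox_engine <- function(X, time, event, ties = c("breslow", "efron"),
                       tol = 1e-9, max_iter = 30L) {
  ties <- match.arg(ties)
  stopifnot(is.matrix(X), nrow(X) == length(time),
            length(time) == length(event))
  p <- ncol(X)
  null_ll <- cox_loglik_deriv(X, time, event, rep(0, p), ties)$loglik
  beta <- rep(0, p)
  ll <- null_ll
  for (iter in seq_len(max_iter)) {
    der <- cox_loglik_deriv(X, time, event, beta, ties)
    step <- tryCatch(solve(der$I, der$U), error = function(e)
      stop("Cox fit failed: singular information matrix (complete ",
           "separation or redundant term) at iteration ", iter, call. = FALSE))
    new_beta <- beta + step
    new_ll <- cox_loglik_deriv(X, time, event, new_beta, ties)$loglik
    halvings <- 0L
    while ((!is.finite(new_ll) || new_ll < ll - 1e-12) && halvings < 20L) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- cox_loglik_deriv(X, time, event, new_beta, ties)$loglik
      halvings <- halvings + 1L
    }
    done <- abs(new_ll - ll) < tol && iter > 1L
    beta <- new_beta
    ll <- new_ll
    if (any(abs(beta) > 15)) {
      stop("Cox fit diverged (|coefficient| > 15); likely complete ",
           "separation. iterations = ", iter, call. = FALSE)
    }
    if (done) break
  }
  if (!done) {
    stop("Cox fit did not converge in ", max_iter,
         " iterations (last loglik change ", signif(abs(new_ll - ll), 3),
         ")", call. = FALSE)
  }
  final <- cox_loglik_deriv(X, time, event, beta, ties)
  var <- solve(final$I)
  list(coefficients = beta, var = var, loglik = c(null = null_ll, final = ll),
       iter = iter, ties = ties)
}

## Clinical factor coding (reference level first). Columns of the design
## matrix are named "<factor>:<level>".
COX_FACTORS <- list(
  age_group       = c("<65", ">=65"),
  sex             = c("male", "female"),
  ethnicity       = c("white", "asian", "black", "hispanic",
                      "native_american", "other"),
  histology_grade = c("G1_G2", "G3_G4", "other"),
  size_group      = c("<=60mm", ">60mm"),
  pt_category     = c("T1", "T2", "T3", "T4a", "T4b"),
  surgery         = c("partial_gastrectomy", "total_gastrectomy"),
  eighth_n3       = c("N3a", "N3b"),
  modified_n3     = c("mN3a", "mN3b")
)

factor_values <- function(cohort, factor_name, modified_cutoff = 13L) {
  switch(factor_name,
    age_group   = age_group(cohort),
    size_group  = size_group(cohort),
    eighth_n3   = assign_n(cohort$mln_count, system = "eighth"),
    modified_n3 = assign_n(cohort$mln_count, system = "modified",
                           cutoff = modified_cutoff),
    {
      if (!factor_name %in% names(cohort))
        stop("unknown factor: ", factor_name, call. = FALSE)
      cohort[[factor_name]]
    })
}

cox_design <- function(cohort, terms, modified_cutoff = 13L) {
  cols <- list()
  for (tm in terms) {
    if (!tm %in% names(COX_FACTORS))
      stop("unknown Cox term: ", tm, call. = FALSE)
    lv <- COX_FACTORS[[tm]]
    vals <- factor_values(cohort, tm, modified_cutoff)
    if (any(is.na(vals)))
      stop("missing values in factor '", tm, "'; screen the cohort first",
           call. = FALSE)
    present <- lv[lv %in% unique(vals)]
    if (length(present) < 2L)
      stop("factor '", tm, "' has fewer than 2 populated levels", call. = FALSE)
    # reference = the declared reference level, or the first populated one
    for (level in present[-1L]) {
      cols[[paste0(tm, ":", level)]] <- as.numeric(vals == level)
    }
  }
  if (length(cols) == 0L) stop("empty design matrix", call. = FALSE)
  do.call(cbind, cols)
}

#' Fit a Cox proportional-hazards model on a cohort
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson with Breslow
#' (default) or Efron handling of tied event times. Categorical factors are
#' dummy-coded against fixed clinical reference levels: age < 65, male,
#' White, G1/G2, tumor size <= 60 mm, T1, partial (proximal/distal)
#' gastrectomy, N3a and mN3a. Confidence intervals and p-values are Wald.
#'
#' @param cohort A screened [cohort][as_cohort] (no missing covariates).
#' @param terms Character vector of factor names among `age_group`, `sex`,
#'   `ethnicity`, `histology_grade`, `size_group`, `pt_category`, `surgery`,
#'   `eighth_n3`, `modified_n3`.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param modified_cutoff MLN boundary used for the `modified_n3` term
#'   (mN3a: 7..cutoff, mN3b above it).
#' @return A `cox_fit` with `terms`, `coefficients`, `hazard_ratios`,
#'   `ci95` (matrix with columns low/high), `p_values`,
#'   `log_partial_likelihood` (final), `loglik_null`, `n_params`,
#'   `n_subjects`, `n_events`, `ties` and `iterations`.
#' @export
fit_cox <- function(cohort, terms, ties = c("breslow", "efron"),
                    modified_cutoff = 13L) {
  ties <- match.arg(ties)
  stopifnot(inherits(cohort, "cohort"))
  X <- cox_design(cohort, terms, modified_cutoff)
  fit <- cox_engine(X, cohort$followup_months, cohort$event, ties)
  se <- sqrt(diag(fit$var))
  z <- fit$coefficients / se
  ci <- cbind(low  = exp(fit$coefficients - stats::qnorm(0.975) * se),
              high = exp(fit$coefficients + stats::qnorm(0.975) * se))
  structure(list(
    terms = colnames(X),
    coefficients = stats::setNames(fit$coefficients, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    hazard_ratios = stats::setNames(exp(fit$coefficients), colnames(X)),
    ci95 = ci,
    p_values = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
    log_partial_likelihood = unname(fit$loglik["final"]),
    loglik_null = unname(fit$loglik["null"]),
    n_params = ncol(X),
    n_subjects = nrow(cohort),
    n_events = sum(cohort$event),
    ties = ties,
    iterations = fit$iter), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (%s ties): %d subjects, %d events, %d parameter(s)\n",
              x$ties, x$n_subjects, x$n_events, x$n_params))
  tab <- data.frame(term = x$terms,
                    coef = round(x$coefficients, 4),
                    HR = round(x$hazard_ratios, 3),
                    ci_low = round(x$ci95[, "low"], 3),
                    ci_high = round(x$ci95[, "high"], 3),
                    p = signif(x$p_values, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("log partial likelihood: %.4f (null %.4f)\n",
              x$log_partial_likelihood, x$loglik_null))
  invisible(x)
}

#' Univariate prognostic screening by log-rank test
#'
#' For each factor, compares survival across its levels with a k-group
#' log-rank test and reports per-level five-year overall survival. A factor
#' is flagged significant at `alpha` (default 0.05).
#'
#' @inheritParams fit_cox
#' @param factors Factor names, as in [fit_cox()].
#' @param alpha Significance level.
#' @return A data frame with one row per factor: `factor`, `chi2`, `df`,
#'   `p_value`, `significant`; per-level detail (levels, n, 5-year OS) in
#'   the `levels` attribute.
#' @export
univariate_screen <- function(cohort, factors = names(COX_FACTORS),
                              alpha = 0.05, modified_cutoff = 13L) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- list(); level_detail <- list()
  for (f in factors) {
    vals <- factor_values(cohort, f, modified_cutoff)
    lv <- COX_FACTORS[[f]]
    lv <- lv[lv %in% unique(vals)]
    if (length(lv) < 2L) {
      stop("factor '", f, "' has fewer than 2 populated levels", call. = FALSE)
    }
    lr <- logrank(times = cohort$followup_months, events = cohort$event,
                  group = factor(vals, levels = lv))
    os5 <- vapply(lv, function(l) {
      sel <- vals == l
      os5_percent(cohort$followup_months[sel], cohort$event[sel])
    }, numeric(1L))
    rows[[f]] <- data.frame(factor = f, chi2 = lr$chi2, df = lr$df,
                            p_value = lr$p_value,
                            significant = lr$p_value < alpha)
    level_detail[[f]] <- data.frame(factor = f, level = lv,
                                    n = as.integer(table(factor(vals, lv))),
                                    os5_pct = os5)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "levels") <- do.call(rbind, c(level_detail,
                                          list(make.row.names = FALSE)))
  out
}

#' Two-step multivariate validation of the modified N3 boundary
#'
#' Step 1 fits a multivariate Cox model on the factors that were significant
#' in univariate screening, together with the eighth-edition N3 subdivision
#' but *excluding* the modified one. Step 2 adds the modified N3 term to the
#' step-1 model, so the two N definitions compete directly; the verdict
#' reports which of them retains significance.
#'
#' @inheritParams fit_cox
#' @param alpha Significance level used both for univariate entry and for
#'   the step-2 verdict.
#' @return A `two_step_result` with `univariate` (screening table),
#'   `step1_fit`, `step2_fit`, and `verdict`: a data frame with the step-2
#'   hazard ratio and p-value for the eighth and modified N3b terms and a
#'   `retained` flag at `alpha`.
#' @export
two_step <- function(cohort, ties = c("breslow", "efron"), alpha = 0.05,
                     modified_cutoff = 13L) {
  ties <- match.arg(ties)
  uni <- univariate_screen(cohort, modified_cutoff = modified_cutoff,
                           alpha = alpha)
  sig <- uni$factor[uni$significant]
  step1_terms <- union(setdiff(sig, c("modified_n3", "eighth_n3")),
                       "eighth_n3")
  # keep the clinical ordering of terms
  step1_terms <- names(COX_FACTORS)[names(COX_FACTORS) %in% step1_terms]
  step2_terms <- c(step1_terms, "modified_n3")
  step1 <- fit_cox(cohort, step1_terms, ties, modified_cutoff)
  step2 <- fit_cox(cohort, step2_terms, ties, modified_cutoff)
  pick <- function(fit, term) {
    i <- grep(paste0("^", term, ":"), fit$terms)
    data.frame(term = fit$terms[i], hr = fit$hazard_ratios[i],
               ci_low = fit$ci95[i, "low"], ci_high = fit$ci95[i, "high"],
               p_value = fit$p_values[i],
               retained = fit$p_values[i] < alpha)
  }
  verdict <- rbind(pick(step2, "eighth_n3"), pick(step2, "modified_n3"))
  rownames(verdict) <- NULL
  structure(list(univariate = uni, step1_fit = step1, step2_fit = step2,
                 verdict = verdict, alpha = alpha,
                 modified_cutoff = modified_cutoff),
            class = "two_step_result")
}

#' @export
print.two_step_result <- function(x, ...) {
  cat("Two-step multivariate Cox validation (modified cutoff =",
      x$modified_cutoff, ")\n\nUnivariate screening:\n")
  print(x$univariate, row.names = FALSE, digits = 4)
  cat("\nStep 2 verdict (both N definitions in the model):\n")
  print(x$verdict, row.names = FALSE, digits = 4)
  invisible(x)
}
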