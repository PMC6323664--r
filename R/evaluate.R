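## Staging-system performance: homogeneity (likelihood-ratio chi-squared of
## the categorical-stage Cox model), discrimination / gradient monotonicity
## (linear-trend chi-squared with stages as an ordinal score), and AIC.

#' Evaluate a staging system's prognostic performance
#'
#' Fits two Cox models to the staged cohort: one with stage as a categorical
#' factor (reference = first non-empty stage) and one with stage as a single
#' consecutive-integer score in the declared order. The likelihood-ratio
#' chi-squared 2 (logPL_stage - logPL_null) on (non-empty stages - 1) df
#' measures within-system homogeneity; the 1-df trend chi-squared from the
#' scored model measures discriminatory ability and gradient monotonicity
#' (a score-test variant is available via `trend_method = "score"`); AIC is
#' -2 logPL + 2 k from the categorical model.
#'
#' @param restaged A `restaged_cohort` from [restage_cohort()], or a data
#'   frame with columns `followup_months`, `event` and `stage`.
#' @param stage_order Stage labels in prognostic order; defaults to the
#'   system's declared order.
#' @param ties Tie handling passed to the Cox fits.
#' @param trend_method `"lr"` (likelihood-ratio, default) or `"score"`
#'   (the score test at beta = 0 of the scored model).
#' @return A `system_evaluation` with `system_name`, `lr_chi2`, `lr_df`,
#'   `lr_p`, `trend_chi2`, `trend_p`, `aic`, `n_subjects`, `n_events`.
#' @export
evaluate_system <- function(restaged, stage_order = NULL,
                            ties = c("breslow", "efron"),
                            trend_method = c("lr", "score")) {
  ties <- match.arg(ties)
  trend_method <- match.arg(trend_method)
  if (inherits(restaged, "restaged_cohort")) {
    df <- restaged$cohort
    if (is.null(stage_order)) stage_order <- restaged$system$stage_order
    system_name <- restaged$system$name
  } else {
    df <- restaged
    if (is.null(stage_order)) stage_order <- sort(unique(as.character(df$stage)))
    system_name <- "custom"
  }
  stage <- factor(as.character(df$stage), levels = stage_order)
  if (any(is.na(stage))) stop("records with stage outside stage_order",
                              call. = FALSE)
  present <- stage_order[table(stage) > 0]
  if (length(present) < 2L) {
    stop("evaluate_system: need at least 2 non-empty stages", call. = FALSE)
  }
  time <- df$followup_months
  event <- df$event

  # categorical-stage model (dummies against the first non-empty stage)
  Xcat <- sapply(present[-1L], function(s) as.numeric(stage == s))
  Xcat <- matrix(Xcat, nrow = length(time),
                 dimnames = list(NULL, paste0("stage:", present[-1L])))
  fit_cat <- cox_engine(Xcat, time, event, ties)
  lr_chi2 <- 2 * (fit_cat$loglik["final"] - fit_cat$loglik["null"])
  lr_df <- length(present) - 1L
  aic <- -2 * fit_cat$loglik["final"] + 2 * lr_df

  # ordinal score model: consecutive integers in declared order
  score <- as.numeric(factor(as.character(stage), levels = present))
  Xs <- matrix(score, ncol = 1L, dimnames = list(NULL, "stage_score"))
  if (trend_method == "lr") {
    fit_s <- cox_engine(Xs, time, event, ties)
    trend_chi2 <- 2 * (fit_s$loglik["final"] - fit_s$loglik["null"])
  } else {
    der <- cox_loglik_deriv(Xs, time, event, 0, ties)
    trend_chi2 <- drop(der$U^2 / der$I)
  }

  structure(list(system_name = system_name,
                 lr_chi2 = unname(lr_chi2), lr_df = lr_df,
                 lr_p = stats::pchisq(unname(lr_chi2), lr_df,
                                      lower.tail = FALSE),
                 trend_chi2 = unname(trend_chi2),
                 trend_p = stats::pchisq(unname(trend_chi2), 1L,
                                         lower.tail = FALSE),
                 aic = unname(aic),
                 n_subjects = length(time), n_events = sum(event),
                 trend_method = trend_method, ties = ties),
            class = "system_evaluation")
}

#' @export
print.system_evaluation <- function(x, ...) {
  cat(sprintf(
    "System '%s': trend chi2 = %.3f (p = %.3g), LR chi2 = %.3f on %d df (p = %.3g), AIC = %.2f\n",
    x$system_name, x$trend_chi2, x$trend_p, x$lr_chi2, x$lr_df, x$lr_p,
    x$aic))
  invisible(x)
}

#' Compare two staging-system evaluations
#'
#' Higher likelihood-ratio and trend chi-squared values and a lower AIC
#' indicate the better system. Both evaluations must come from the same
#' cohort (same subject and event counts).
#'
#' @param eval_a,eval_b [system_evaluation][evaluate_system] objects.
#' @return A `system_comparison`: data frame with one row per metric
#'   (`lr_chi2`, `trend_chi2`, `aic`), the two values, the margin
#'   (`a - b`), and the winner's system name (`"tie"` on a zero margin).
#' @export
compare_systems <- function(eval_a, eval_b) {
  stopifnot(inherits(eval_a, "system_evaluation"),
            inherits(eval_b, "system_evaluation"))
  if (eval_a$n_subjects != eval_b$n_subjects ||
      eval_a$n_events != eval_b$n_events) {
    stop("compare_systems: evaluations come from different cohorts",
         call. = FALSE)
  }
  metric <- c("lr_chi2", "trend_chi2", "aic")
  a <- c(eval_a$lr_chi2, eval_a$trend_chi2, eval_a$aic)
  b <- c(eval_b$lr_chi2, eval_b$trend_chi2, eval_b$aic)
  higher_wins <- c(TRUE, TRUE, FALSE)
  winner <- ifelse(a == b, "tie",
                   ifelse((a > b) == higher_wins,
                          eval_a$system_name, eval_b$system_name))
  out <- data.frame(metric = metric, a = a, b = b, margin = a - b,
                    winner = winner)
  names(out)[2:3] <- c(eval_a$system_name, eval_b$system_name)
  structure(out, class = c("system_comparison", "data.frame"))
}
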