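#' Kaplan-Meier product-limit estimate
#'
#' Computes the survival function S(t) = prod over event times t_i <= t of
#' (1 - d_i / n_i), where d_i is the number of deaths at t_i and n_i the
#' number at risk. A subject censored exactly at an event time is counted as
#' at risk for that time (the standard convention): the risk set at t is
#' everyone with follow-up >= t.
#'
#' @param times Follow-up times in months (>= 0).
#' @param events Event indicators, 1 = death, 0 = censored.
#' @return A `km_curve` with `event_times` (distinct times with at least one
#'   death, increasing), `n_at_risk`, `n_events`, `survival` (the step
#'   estimate just after each event time) and `n_total`.
#' @export
km_fit <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (length(times) == 0L) stop("km_fit: empty input", call. = FALSE)
  if (any(is.na(times)) || any(is.na(events)))
    stop("km_fit: missing times or events", call. = FALSE)
  if (any(times < 0)) stop("km_fit: negative times", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("km_fit: events must be 0/1", call. = FALSE)
  ev_times <- sort(unique(times[events == 1]))
  if (length(ev_times) == 0L) {
    return(structure(list(event_times = numeric(0), n_at_risk = integer(0),
                          n_events = integer(0), survival = numeric(0),
                          n_total = length(times)),
                     class = "km_curve"))
  }
  st <- sort(times)
  # n at risk at t = #{follow-up >= t}; times below t counted via findInterval
  n_risk <- length(times) - findInterval(ev_times, st, left.open = TRUE)
  d <- as.integer(table(factor(times[events == 1], levels = ev_times)))
  surv <- cumprod(1 - d / n_risk)
  structure(list(event_times = ev_times, n_at_risk = as.integer(n_risk),
                 n_events = d, survival = surv, n_total = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n_total, ",",
      sum(x$n_events), "events at", length(x$event_times),
      "distinct times\n")
  if (length(x$event_times)) {
    cat("S(t) at last event time", max(x$event_times), "=",
        signif(x$survival[length(x$survival)], 4), "\n")
  }
  invisible(x)
}

#' Survival probability at a given time
#'
#' Evaluates the right-continuous Kaplan-Meier step function: the estimate at
#' the largest event time less than or equal to `t`, and 1 if no event has
#' occurred by `t`. For `t` beyond the last follow-up the last estimate is
#' carried forward.
#'
#' @param curve A [km_curve][km_fit].
#' @param t Time in months (>= 0).
#' @return The estimated survival probability in \[0, 1\].
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  idx <- findInterval(t, curve$event_times)
  if (idx == 0L) 1 else curve$survival[idx]
}

#' Five-year overall survival as a percentage
#'
#' Convenience wrapper: S(60 months) * 100.
#'
#' @param times,events As in [km_fit()].
#' @return Percentage in \[0, 100\].
#' @export
os5_percent <- function(times, events) {
  100 * survival_at(km_fit(times, events), 60)
}

#' Export a Kaplan-Meier curve as TSV
#'
#' @param curve A [km_curve][km_fit].
#' @param path Output path; columns `time`, `n_at_risk`, `n_events`,
#'   `survival`.
#' @return `path`, invisibly.
#' @export
write_km_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  utils::write.table(
    data.frame(time = curve$event_times, n_at_risk = curve$n_at_risk,
               n_events = curve$n_events, survival = curve$survival),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' k-group log-rank test
#'
#' Pools the distinct event times across groups; at each event time t_i with
#' d_i deaths out of n_i at risk, the expected deaths in group g are
#' E_gi = n_gi d_i / n_i. For two groups the statistic is
#' (sum(O_1i - E_1i))^2 / sum(V_i) with the hypergeometric variance
#' V_i = n_1i n_2i d_i (n_i - d_i) / (n_i^2 (n_i - 1)), taking V_i = 0 when
#' n_i = 1. For k > 2 groups the vector of O - E over the first k - 1 groups
#' is combined with its estimated covariance matrix, giving a chi-squared
#' statistic on k - 1 degrees of freedom. No continuity correction is
#' applied. With zero events in total the degenerate result chi2 = 0, p = 1
#' is returned.
#'
#' @param groups A list with one element per group, each a list or data frame
#'   with components `times` and `events`; alternatively supply `times`,
#'   `events` and `group` vectors directly.
#' @param times,events,group Vector interface (used when `groups` is NULL):
#'   follow-up times, 0/1 event flags, and a group label per subject.
#' @return A `logrank_test` with `chi2`, `df`, `p_value`, `group_sizes`,
#'   `observed` and `expected` per group.
#' @export
logrank <- function(groups = NULL, times = NULL, events = NULL, group = NULL) {
  if (!is.null(groups)) {
    stopifnot(is.list(groups), length(groups) >= 2L)
    times <- unlist(lapply(groups, function(g) g$times), use.names = FALSE)
    events <- unlist(lapply(groups, function(g) g$events), use.names = FALSE)
    labels <- if (!is.null(names(groups)) && all(nzchar(names(groups))))
      names(groups) else as.character(seq_along(groups))
    group <- rep(labels,
                 vapply(groups, function(g) length(g$times), integer(1L)))
    group <- factor(group, levels = labels)
  } else {
    if (!is.factor(group)) group <- factor(group)
  }
  stopifnot(length(times) == length(events), length(times) == length(group))
  if (nlevels(group) < 2L) stop("logrank needs at least 2 groups", call. = FALSE)
  sizes <- table(group)
  if (any(sizes == 0L)) {
    stop("logrank: group with zero subjects: ",
         paste(names(sizes)[sizes == 0], collapse = ", "), call. = FALSE)
  }
  if (any(is.na(times)) || any(is.na(events)))
    stop("logrank: missing times or events", call. = FALSE)

  k <- nlevels(group)
  ev_times <- sort(unique(times[events == 1]))
  observed <- as.numeric(tapply(events, group, sum))
  observed[is.na(observed)] <- 0
  if (length(ev_times) == 0L) {
    res <- list(chi2 = 0, df = k - 1L, p_value = 1,
                group_sizes = as.integer(sizes),
                observed = observed, expected = rep(0, k),
                groups = levels(group))
    return(structure(res, class = "logrank_test"))
  }

  m <- length(ev_times)
  st_all <- sort(times)
  n_i <- length(times) - findInterval(ev_times, st_all, left.open = TRUE)
  d_i <- as.numeric(table(factor(times[events == 1], levels = ev_times)))

  # per-group at-risk and death counts at each pooled event time
  n_gi <- matrix(0, nrow = m, ncol = k)
  d_gi <- matrix(0, nrow = m, ncol = k)
  for (g in seq_len(k)) {
    tg <- times[group == levels(group)[g]]
    eg <- events[group == levels(group)[g]]
    n_gi[, g] <- length(tg) - findInterval(ev_times, sort(tg), left.open = TRUE)
    d_gi[, g] <- as.numeric(table(factor(tg[eg == 1], levels = ev_times)))
  }
  E_gi <- n_gi * (d_i / n_i)
  expected <- colSums(E_gi)

  if (k == 2L) {
    denom <- n_i^2 * pmax(n_i - 1, 1)
    V_i <- ifelse(n_i > 1,
                  n_gi[, 1] * n_gi[, 2] * d_i * (n_i - d_i) / denom, 0)
    V <- sum(V_i)
    OE <- sum(d_gi[, 1] - E_gi[, 1])
    chi2 <- if (V > 0) OE^2 / V else 0
  } else {
    # covariance of the (k-1)-vector of observed-minus-expected deaths
    z <- colSums(d_gi - E_gi)[-k]
    V <- matrix(0, k - 1L, k - 1L)
    mult <- ifelse(n_i > 1, d_i * (n_i - d_i) / (n_i - 1), 0)
    p_gi <- n_gi / n_i
    for (g in seq_len(k - 1L)) {
      for (h in g:(k - 1L)) {
        vgh <- sum(mult * p_gi[, g] * ((g == h) - p_gi[, h]))
        V[g, h] <- vgh
        V[h, g] <- vgh
      }
    }
    chi2 <- tryCatch(drop(t(z) %*% solve(V, z)),
                     error = function(e) {
                       vi <- pseudo_inverse(V)
                       drop(t(z) %*% vi %*% z)
                     })
    chi2 <- max(chi2, 0)
  }
  df <- k - 1L
  structure(list(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 group_sizes = as.integer(sizes),
                 observed = observed, expected = expected,
                 groups = levels(group)),
            class = "logrank_test")
}

# Moore-Penrose pseudoinverse via SVD; used only when the O-E covariance is
# singular (e.g. a group with no events overlapping the others).
pseudo_inverse <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1L], 0)
  if (!any(pos)) return(array(0, dim(X)[2:1]))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4g on %d df, p = %.3g\n",
              x$chi2, x$df, x$p_value))
  tab <- data.frame(group = x$groups, n = x$group_sizes,
                    observed = x$observed, expected = round(x$expected, 2))
  print(tab, row.names = FALSE)
  invisible(x)
}
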