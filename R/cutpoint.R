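#' Maximal log-rank chi-squared scan over candidate MLN cutoffs
#'
#' Evaluates every candidate cutoff c in `cutoff_range` by splitting the
#' cohort into mln_count <= c versus > c and computing the two-group
#' log-rank chi-squared; the selected cutoff is the (smallest) maximizer.
#' Because the maximum is taken over many correlated tests, the selected
#' cutoff's p-value is anti-conservative relative to a single pre-specified
#' split; no multiplicity correction is applied.
#'
#' @param cohort A screened N3 [cohort][as_cohort] (all `mln_count >= 7`).
#' @param cutoff_range Integer candidates, default `7:20`.
#' @param min_group Minimum subjects required on each side of a cutoff for
#'   it to be admissible (guards against degenerate chi-squared values in
#'   tiny groups); default 20.
#' @return A `cutpoint_scan` with `rows` (data frame: `cutoff`, `n_low`,
#'   `n_high`, `os5_low`, `os5_high` in percent, `chi2`, `p_value`),
#'   `selected_cutoff` and `selection_chi2`.
#' @export
scan_cutpoints <- function(cohort, cutoff_range = 7:20, min_group = 20L) {
  stopifnot(inherits(cohort, "cohort"))
  if (any(is.na(cohort$mln_count)) || any(cohort$mln_count < 7)) {
    stop("scan_cutpoints: all records must have mln_count >= 7 ",
         "(screen the cohort first)", call. = FALSE)
  }
  rows <- list()
  for (cp in sort(unique(as.integer(cutoff_range)))) {
    low <- cohort$mln_count <= cp
    n_low <- sum(low); n_high <- sum(!low)
    if (n_low < min_group || n_high < min_group) next
    lr <- logrank(times = cohort$followup_months, events = cohort$event,
                  group = factor(ifelse(low, "low", "high"),
                                 levels = c("low", "high")))
    rows[[length(rows) + 1L]] <- data.frame(
      cutoff = cp, n_low = n_low, n_high = n_high,
      os5_low = os5_percent(cohort$followup_months[low], cohort$event[low]),
      os5_high = os5_percent(cohort$followup_months[!low], cohort$event[!low]),
      chi2 = lr$chi2, p_value = lr$p_value)
  }
  if (length(rows) == 0L) {
    stop("scan_cutpoints: no admissible cutoff in ",
         min(cutoff_range), "..", max(cutoff_range),
         " with at least ", min_group, " subjects per side", call. = FALSE)
  }
  rows <- do.call(rbind, rows)
  best <- which(rows$chi2 == max(rows$chi2))[1L]  # ties: smallest cutoff
  structure(list(rows = rows,
                 selected_cutoff = rows$cutoff[best],
                 selection_chi2 = rows$chi2[best],
                 min_group = min_group),
            class = "cutpoint_scan")
}

#' @export
print.cutpoint_scan <- function(x, ...) {
  cat(sprintf("Cut-point scan: %d admissible cutoffs; selected %d (chi2 = %.3f)\n",
              nrow(x$rows), x$selected_cutoff, x$selection_chi2))
  tab <- x$rows
  tab$os5_low <- round_half_up(tab$os5_low, 1)
  tab$os5_high <- round_half_up(tab$os5_high, 1)
  tab$chi2 <- round(tab$chi2, 3)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a cut-point scan as TSV
#'
#' @param scan A [cutpoint_scan][scan_cutpoints].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "cutpoint_scan"))
  utils::write.table(scan$rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Three-band survival analysis around a candidate boundary
#'
#' Partitions the MLN range into a low band, a middle band (the patients a
#' boundary change would re-assign) and a high band (everything above the
#' middle band), and compares the bands pairwise by two-group log-rank
#' tests with unadjusted p-values. With the default bands this asks whether
#' patients with 14-15 MLNs resemble the 7-13 group or the >15 group.
#'
#' @param cohort A screened N3 [cohort][as_cohort].
#' @param low_band Integer `c(lo, hi)` for the low band, default `c(7, 13)`.
#' @param mid_band Integer `c(lo, hi)` for the middle band, default
#'   `c(14, 15)`; the high band is everything above `mid_band[2]`.
#' @return A `three_band_report`: list with `bands` (data frame: band label,
#'   n, os5_pct), `curves` (per-band [km_curve][km_fit]) and `pairwise`
#'   (data frame of the three unadjusted log-rank comparisons).
#' @export
three_band_analysis <- function(cohort, low_band = c(7L, 13L),
                                mid_band = c(14L, 15L)) {
  stopifnot(inherits(cohort, "cohort"))
  if (low_band[2L] + 1L != mid_band[1L]) {
    stop("low and mid bands must be adjacent", call. = FALSE)
  }
  mln <- cohort$mln_count
  band <- ifelse(mln <= low_band[2L], "low",
                 ifelse(mln <= mid_band[2L], "mid", "high"))
  labels <- c(low = sprintf("%d-%d", low_band[1L], low_band[2L]),
              mid = sprintf("%d-%d", mid_band[1L], mid_band[2L]),
              high = sprintf(">%d", mid_band[2L]))
  for (b in c("low", "mid", "high")) {
    if (!any(band == b)) stop("empty band: ", labels[b], call. = FALSE)
  }
  curves <- list(); ns <- integer(3L); os5 <- numeric(3L)
  for (i in seq_along(c("low", "mid", "high"))) {
    b <- c("low", "mid", "high")[i]
    sel <- band == b
    ns[i] <- sum(sel)
    curves[[labels[b]]] <- km_fit(cohort$followup_months[sel],
                                  cohort$event[sel])
    os5[i] <- 100 * survival_at(curves[[labels[b]]], 60)
  }
  pairs <- list(c("low", "mid"), c("mid", "high"), c("low", "high"))
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    sel <- band %in% pr
    lr <- logrank(times = cohort$followup_months[sel],
                  events = cohort$event[sel],
                  group = factor(band[sel], levels = pr))
    data.frame(comparison = paste(labels[pr[1L]], "vs", labels[pr[2L]]),
               chi2 = lr$chi2, p_value = lr$p_value)
  }))
  structure(list(bands = data.frame(band = unname(labels), n = ns,
                                    os5_pct = os5),
                 curves = curves, pairwise = pw),
            class = "three_band_report")
}

#' @export
print.three_band_report <- function(x, ...) {
  cat("Three-band MLN survival analysis:\n")
  print(x$bands, row.names = FALSE, digits = 3)
  cat("\nPairwise log-rank tests (unadjusted):\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
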