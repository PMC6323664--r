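#' @keywords internal
"_PACKAGE"

## Column schema shared by read/write/screen/simulate. Booleans stored 0/1,
## missing values as empty strings on disk and NA in memory.
COHORT_COLUMNS <- c(
  "id", "source", "age_years", "sex", "ethnicity", "histology_grade",
  "tumor_size_mm", "pt_category", "m_category", "lns_examined", "mln_count",
  "surgery", "followup_months", "event", "primary_site_stomach",
  "adenocarcinoma", "multiple_primaries", "remnant_gastric"
)

COHORT_LEVELS <- list(
  source          = c("SEER", "FMUUH", "SYNTH"),
  sex             = c("male", "female"),
  ethnicity       = c("white", "asian", "black", "hispanic",
                      "native_american", "other"),
  histology_grade = c("G1_G2", "G3_G4", "other"),
  pt_category     = c("T1", "T2", "T3", "T4a", "T4b", "other"),
  m_category      = c("M0", "M1", "unknown"),
  surgery         = c("partial_gastrectomy", "total_gastrectomy",
                      "none", "other")
)

NUMERIC_COLUMNS <- c("age_years", "tumor_size_mm", "lns_examined",
                     "mln_count", "followup_months", "event")
FLAG_COLUMNS <- c("primary_site_stomach", "adenocarcinoma",
                  "multiple_primaries", "remnant_gastric")

#' Construct a patient cohort
#'
#' A cohort is a data frame with one row per patient following the fixed
#' column schema (see [read_cohort()] for the column list). `as_cohort()`
#' validates column presence, enum levels, id uniqueness and the structural
#' invariants `mln_count <= lns_examined`, `followup_months >= 0` and
#' `event` in \{0, 1\} (rows with missing values are tolerated; eligibility
#' is the business of [screen_cohort()], not of the container).
#'
#' @param x A data frame holding the schema columns.
#' @param provenance Free-text label describing where the records came from.
#' @return An object of class `cohort` (a data frame).
#' @export
as_cohort <- function(x, provenance = "unspecified") {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(COHORT_COLUMNS, names(x))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)[COHORT_COLUMNS]
  x$id <- as.character(x$id)
  if (anyDuplicated(x$id)) {
    stop("cohort ids must be unique", call. = FALSE)
  }
  for (col in names(COHORT_LEVELS)) {
    vals <- as.character(x[[col]])
    bad <- !is.na(vals) & !(vals %in% COHORT_LEVELS[[col]])
    if (any(bad)) {
      stop(sprintf("invalid value(s) in '%s': %s", col,
                   paste(unique(vals[bad]), collapse = ", ")), call. = FALSE)
    }
    x[[col]] <- vals
  }
  for (col in c(NUMERIC_COLUMNS, FLAG_COLUMNS)) x[[col]] <- as.numeric(x[[col]])
  bad_mln <- !is.na(x$mln_count) & !is.na(x$lns_examined) &
    x$mln_count > x$lns_examined
  if (any(bad_mln)) {
    stop("mln_count exceeds lns_examined for row(s): ",
         paste(utils::head(which(bad_mln), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(x$followup_months) & x$followup_months < 0)) {
    stop("followup_months must be >= 0", call. = FALSE)
  }
  if (any(!is.na(x$event) & !(x$event %in% c(0, 1)))) {
    stop("event must be 0 (censored) or 1 (death)", call. = FALSE)
  }
  rownames(x) <- NULL
  structure(x, provenance = provenance,
            class = c("cohort", "data.frame"))
}

#' Read a patient cohort from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row holding exactly the
#' schema columns: `id, source, age_years, sex, ethnicity, histology_grade,
#' tumor_size_mm, pt_category, m_category, lns_examined, mln_count, surgery,
#' followup_months, event, primary_site_stomach, adenocarcinoma,
#' multiple_primaries, remnant_gastric`. Boolean flags are coded 0/1 and
#' missing values are empty strings.
#'
#' @param path Path to the CSV file.
#' @param provenance Label stored on the cohort; defaults to the file name.
#' @return A [cohort][as_cohort] object.
#' @seealso [write_cohort()] for the inverse operation.
#' @export
read_cohort <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = "", check.names = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c(NUMERIC_COLUMNS, FLAG_COLUMNS)) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                   col, bad[1L], raw[[col]][bad[1L]]), call. = FALSE)
    }
    raw[[col]] <- vals
  }
  as_cohort(raw, provenance = provenance)
}

#' Write a patient cohort to CSV
#'
#' Writes the schema columns with missing values as empty strings, so that
#' `read_cohort(write_cohort(x, f))` reproduces `x` field for field.
#'
#' @param cohort A [cohort][as_cohort] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(as.data.frame(cohort)[COHORT_COLUMNS], path,
                   row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

## Eligibility criteria in the fixed attribution order. Each predicate
## returns TRUE only on a *definite* violation; records with missing fields
## fall through to the final incomplete-record criterion.
SCREEN_CRITERIA <- list(
  non_gastric_primary  = function(x) !is.na(x$primary_site_stomach) & x$primary_site_stomach == 0,
  age_under_18         = function(x) !is.na(x$age_years) & x$age_years < 18,
  not_adenocarcinoma   = function(x) !is.na(x$adenocarcinoma) & x$adenocarcinoma == 0,
  no_gastrectomy       = function(x) !is.na(x$surgery) &
    !(x$surgery %in% c("partial_gastrectomy", "total_gastrectomy")),
  lns_examined_le_15   = function(x) !is.na(x$lns_examined) & x$lns_examined <= 15,
  mln_count_lt_7       = function(x) !is.na(x$mln_count) & x$mln_count < 7,
  pt_category_ineligible = function(x) !is.na(x$pt_category) &
    !(x$pt_category %in% c("T1", "T2", "T3", "T4a", "T4b")),
  not_m0               = function(x) !is.na(x$m_category) & x$m_category != "M0",
  survival_lt_1_month  = function(x) !is.na(x$followup_months) & x$followup_months < 1,
  multiple_primaries   = function(x) !is.na(x$multiple_primaries) & x$multiple_primaries == 1,
  remnant_gastric      = function(x) !is.na(x$remnant_gastric) & x$remnant_gastric == 1,
  incomplete_record    = function(x) {
    apply(is.na(as.data.frame(x)[COHORT_COLUMNS]), 1L, any)
  }
)

#' Screen a cohort for analysis eligibility
#'
#' Applies the eligibility filter for the N3 gastric-cancer analysis: gastric
#' primary site, age >= 18, adenocarcinoma histology, partial or total
#' gastrectomy, more than 15 lymph nodes examined, at least 7 metastatic
#' nodes (pN3), pT1-T4b, M0, at least 1 month of follow-up, no multiple
#' primaries, no remnant gastric cancer, and no missing fields. Each excluded
#' record is charged to the *first* failing criterion in that order, which
#' makes the exclusion tally deterministic.
#'
#' @param cohort A [cohort][as_cohort] object.
#' @return A list with elements `cohort` (the eligible subset) and `report`,
#'   a `screening_report` with `n_input`, `n_eligible` and the named
#'   per-criterion exclusion counts (`n_input = n_eligible + sum(exclusions)`
#'   always holds).
#' @export
screen_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  n <- nrow(cohort)
  reason <- rep(NA_character_, n)
  for (crit in names(SCREEN_CRITERIA)) {
    fails <- SCREEN_CRITERIA[[crit]](cohort)
    reason[is.na(reason) & fails] <- crit
  }
  keep <- is.na(reason)
  exclusions <- vapply(names(SCREEN_CRITERIA),
                       function(cr) sum(reason == cr, na.rm = TRUE),
                       integer(1L))
  eligible <- as_cohort(as.data.frame(cohort)[keep, , drop = FALSE],
                        provenance = paste0(attr(cohort, "provenance"),
                                            " [screened]"))
  report <- structure(
    list(n_input = n, n_eligible = sum(keep), exclusions = exclusions,
         reason = reason),
    class = "screening_report")
  list(cohort = eligible, report = report)
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Eligibility screening:", x$n_input, "records in,",
      x$n_eligible, "eligible\n")
  shown <- x$exclusions[x$exclusions > 0]
  if (length(shown)) {
    for (nm in names(shown)) cat(sprintf("  excluded (%s): %d\n", nm, shown[nm]))
  }
  invisible(x)
}

## Round half away from zero, as survival tables are conventionally printed
## (base round() uses round-half-even).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derived dichotomies used in the staged analyses
#'
#' Age is split at 65 years (the WHO "elderly" boundary) and tumor size at
#' 60 mm. Both are computed on demand rather than stored.
#'
#' @param cohort A [cohort][as_cohort] object.
#' @return A character vector of group labels (`NA` where the source field
#'   is missing).
#' @export
age_group <- function(cohort) {
  ifelse(is.na(cohort$age_years), NA_character_,
         ifelse(cohort$age_years >= 65, ">=65", "<65"))
}

#' @rdname age_group
#' @export
size_group <- function(cohort) {
  ifelse(is.na(cohort$tumor_size_mm), NA_character_,
         ifelse(cohort$tumor_size_mm > 60, ">60mm", "<=60mm"))
}

summary_categoricals <- function(cohort) {
  list(
    sex             = cohort$sex,
    ethnicity       = cohort$ethnicity,
    histology_grade = cohort$histology_grade,
    pt_category     = cohort$pt_category,
    surgery         = cohort$surgery,
    age_group       = age_group(cohort),
    size_group      = size_group(cohort)
  )
}

summary_continuous <- function(cohort) {
  list(
    age_years       = cohort$age_years,
    tumor_size_mm   = cohort$tumor_size_mm,
    lns_examined    = cohort$lns_examined,
    mln_count       = cohort$mln_count
  )
}

#' Summarize a cohort's demographics
#'
#' Produces a demographics table in the conventional registry-comparison
#' layout: per-level counts with percentages (one decimal, half-up rounding)
#' for each categorical variable, mean and SD for age, and median (range) for
#' the continuous variables. When `by_source = TRUE` and at least two data
#' sources are present, each categorical level is compared between sources
#' with a two-sided chi-squared test (level vs. rest, no continuity
#' correction) and each continuous variable with a two-sided Mann-Whitney
#' U test.
#'
#' @param cohort A non-empty [cohort][as_cohort] object.
#' @param by_source Stratify by the `source` column and add between-source
#'   tests?
#' @return A `cohort_summary`: a list with data frames `categorical`
#'   (variable, level, per-stratum `n`/`pct`, overall, p-value) and
#'   `continuous` (per-stratum mean/sd/median/min/max, p-value).
#' @export
summarize_cohort <- function(cohort, by_source = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(cohort) == 0L) stop("cannot summarize an empty cohort", call. = FALSE)
  sources <- if (by_source) sort(unique(cohort$source)) else character(0)
  if (by_source) {
    for (s in sources) {
      if (sum(cohort$source == s) == 0L)
        stop("source stratum with zero records: ", s, call. = FALSE)
    }
  }
  strata <- c(sources, "overall")
  in_stratum <- function(s) if (s == "overall") rep(TRUE, nrow(cohort)) else cohort$source == s

  cat_vars <- summary_categoricals(cohort)
  cat_rows <- list()
  for (v in names(cat_vars)) {
    vals <- cat_vars[[v]]
    levels_v <- sort(unique(vals[!is.na(vals)]))
    for (lv in levels_v) {
      row <- list(variable = v, level = lv)
      for (s in strata) {
        sv <- vals[in_stratum(s)]
        n_lv <- sum(sv == lv, na.rm = TRUE)
        denom <- sum(!is.na(sv))
        row[[paste0("n_", s)]] <- n_lv
        row[[paste0("pct_", s)]] <- if (denom > 0)
          round_half_up(100 * n_lv / denom, 1L) else NA_real_
      }
      row$p_value <- NA_real_
      if (by_source && length(sources) >= 2L) {
        tab <- table(factor(vals == lv, levels = c(TRUE, FALSE)),
                     factor(cohort$source, levels = sources))
        if (all(colSums(tab) > 0)) {
          row$p_value <- suppressWarnings(
            stats::chisq.test(tab, correct = FALSE)$p.value)
        }
      }
      cat_rows[[length(cat_rows) + 1L]] <- as.data.frame(row)
    }
  }
  categorical <- do.call(rbind, cat_rows)

  cont_vars <- summary_continuous(cohort)
  cont_rows <- list()
  for (v in names(cont_vars)) {
    vals <- cont_vars[[v]]
    row <- list(variable = v)
    for (s in strata) {
      sv <- vals[in_stratum(s)]
      row[[paste0("mean_", s)]] <- mean(sv, na.rm = TRUE)
      row[[paste0("sd_", s)]] <- stats::sd(sv, na.rm = TRUE)
      row[[paste0("median_", s)]] <- stats::median(sv, na.rm = TRUE)
      row[[paste0("min_", s)]] <- suppressWarnings(min(sv, na.rm = TRUE))
      row[[paste0("max_", s)]] <- suppressWarnings(max(sv, na.rm = TRUE))
    }
    row$p_value <- NA_real_
    if (by_source && length(sources) == 2L) {
      a <- vals[cohort$source == sources[1L]]
      b <- vals[cohort$source == sources[2L]]
      if (sum(!is.na(a)) > 0 && sum(!is.na(b)) > 0) {
        row$p_value <- suppressWarnings(
          stats::wilcox.test(a, b, exact = FALSE)$p.value)
      }
    }
    cont_rows[[length(cont_rows) + 1L]] <- as.data.frame(row)
  }
  continuous <- do.call(rbind, cont_rows)

  structure(list(categorical = categorical, continuous = continuous,
                 strata = strata, n = nrow(cohort)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (n =", x$n, ")\n\nCategorical variables:\n")
  print(x$categorical, row.names = FALSE, digits = 4)
  cat("\nContinuous variables:\n")
  print(x$continuous, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a summary table to TSV
#'
#' @param summary A `cohort_summary` from [summarize_cohort()].
#' @param path Output file path; the categorical and continuous blocks are
#'   written one after the other, separated by a blank line.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  stopifnot(inherits(summary, "cohort_summary"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(summary$categorical, con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines("", con)
  utils::write.table(summary$continuous, con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
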