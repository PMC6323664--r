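# Fixture builders shared across the suite. Everything is generated in code;
# nothing is read from disk except files the tests themselves write.

# A minimal eligible record; override any field through ...
make_record <- function(id = "p1", ...) {
  rec <- list(
    id = id, source = "SYNTH", age_years = 60, sex = "male",
    ethnicity = "white", histology_grade = "G3_G4", tumor_size_mm = 50,
    pt_category = "T3", m_category = "M0", lns_examined = 30,
    mln_count = 12, surgery = "total_gastrectomy", followup_months = 24,
    event = 1, primary_site_stomach = 1, adenocarcinoma = 1,
    multiple_primaries = 0, remnant_gastric = 0)
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

make_cohort <- function(records) {
  as_cohort(do.call(rbind, records), provenance = "test fixture")
}

# Cohort from bare survival data, mln defaults chosen to stay eligible
survival_cohort <- function(times, events, mln = NULL, pt = "T3") {
  n <- length(times)
  if (is.null(mln)) mln <- rep(12, n)
  make_cohort(lapply(seq_len(n), function(i) {
    make_record(id = paste0("p", i), followup_months = times[i],
                event = events[i], mln_count = mln[i],
                lns_examined = max(30, mln[i] + 5),
                pt_category = if (length(pt) == 1L) pt else pt[i])
  }))
}

# Independent brute-force k-group log-rank oracle: literal O/E/V sums over
# the pooled event times, no shared code with logrank().
brute_logrank_2g <- function(t1, e1, t2, e2) {
  ev <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  OE <- 0; V <- 0
  for (t in ev) {
    n1 <- sum(t1 >= t); n2 <- sum(t2 >= t); n <- n1 + n2
    d1 <- sum(t1 == t & e1 == 1); d2 <- sum(t2 == t & e2 == 1); d <- d1 + d2
    OE <- OE + d1 - n1 * d / n
    if (n > 1) V <- V + n1 * n2 * d * (n - d) / (n^2 * (n - 1))
  }
  if (V == 0) return(0)
  OE^2 / V
}

# Independent hand Kaplan-Meier oracle (loop over event times)
brute_km <- function(times, events, at) {
  ev <- sort(unique(times[events == 1]))
  s <- 1
  for (t in ev[ev <= at]) {
    n <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n)
  }
  s
}
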