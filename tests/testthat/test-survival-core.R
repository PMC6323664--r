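test_that("km_fit matches closed forms on degenerate inputs", {
  # no events: S(t) = 1 everywhere
  cv <- km_fit(c(5, 10), c(0, 0))
  expect_equal(survival_at(cv, 60), 1)
  expect_length(cv$event_times, 0)

  # two deaths, no censoring: S = 0.5 on [1,2), 0 from 2
  cv2 <- km_fit(c(1, 2), c(1, 1))
  expect_equal(cv2$survival, c(0.5, 0))
  expect_equal(survival_at(cv2, 1.5), 0.5)
  expect_equal(survival_at(cv2, 0.5), 1)
  expect_equal(survival_at(cv2, 2), 0)

  expect_error(km_fit(numeric(0), numeric(0)), "empty")
})

test_that("km_fit reproduces the hand-computed six-subject curve", {
  # deaths at 1, 2, 3, 5; censored at 2 and 4
  times <- c(1, 2, 2, 3, 4, 5)
  events <- c(1, 1, 0, 1, 0, 1)
  cv <- km_fit(times, events)
  expect_equal(cv$event_times, c(1, 2, 3, 5))
  expect_equal(cv$n_at_risk, c(6L, 5L, 3L, 1L))
  # censoring at an event time stays in the risk set for that time
  expect_equal(cv$survival,
               cumprod(c(5 / 6, 4 / 5, 2 / 3, 0)))
  expect_equal(survival_at(cv, 60), 0)
  # independent loop oracle at several times
  for (t in c(0.5, 1, 2.5, 4.9, 60)) {
    expect_equal(survival_at(cv, t), brute_km(times, events, t))
  }
})

test_that("all-event curves hit exactly zero after the last death", {
  set.seed(31)
  tm <- sample(1:50, 25, replace = TRUE)
  cv <- km_fit(tm, rep(1, 25))
  expect_equal(cv$survival[length(cv$survival)], 0)
})

test_that("km_fit agrees with an independent implementation", {
  skip_if_not_installed("survival")
  set.seed(17)
  for (i in 1:20) {
    tm <- ceiling(rexp(60, 0.05))
    ev <- rbinom(60, 1, 0.6)
    if (sum(ev) == 0) next
    cv <- km_fit(tm, ev)
    sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
    at_ev <- summary(sf, times = cv$event_times)
    expect_equal(cv$survival, at_ev$surv, tolerance = 1e-9)
  }
})

test_that("logrank degenerate and symmetry contracts hold", {
  # identical groups: chi2 = 0, p = 1
  g <- list(times = c(1, 3, 7), events = c(1, 0, 1))
  lr <- logrank(list(a = g, b = g))
  expect_equal(lr$chi2, 0)
  expect_equal(lr$p_value, 1)

  # zero events anywhere is the documented degenerate result, not an error
  lr0 <- logrank(times = c(2, 3, 4, 5), events = rep(0, 4),
                 group = c(1, 1, 2, 2))
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$p_value, 1)

  # empty group is an error
  expect_error(logrank(times = c(1, 2), events = c(1, 1),
                       group = factor(c("a", "a"), levels = c("a", "b"))),
               "zero subjects")

  # observed and expected totals balance
  set.seed(4)
  tm <- rexp(80, 0.1); ev <- rbinom(80, 1, 0.7); gr <- rep(1:2, 40)
  lr2 <- logrank(times = tm, events = ev, group = gr)
  expect_equal(sum(lr2$observed), sum(lr2$expected), tolerance = 1e-9)

  # label symmetry
  lr3 <- logrank(times = tm, events = ev, group = 3 - gr)
  expect_equal(lr2$chi2, lr3$chi2, tolerance = 1e-12)
})

test_that("logrank matches the brute-force O/E/V oracle on small fixtures", {
  lr <- logrank(list(A = list(times = c(1, 3), events = c(1, 1)),
                     B = list(times = c(2, 4), events = c(1, 1))))
  expect_equal(lr$chi2, brute_logrank_2g(c(1, 3), c(1, 1),
                                         c(2, 4), c(1, 1)),
               tolerance = 1e-12)
  expect_equal(lr$df, 1L)

  set.seed(8)
  for (i in 1:25) {
    n1 <- sample(5:25, 1); n2 <- sample(5:25, 1)
    t1 <- ceiling(rexp(n1, 0.1)); e1 <- rbinom(n1, 1, 0.7)
    t2 <- ceiling(rexp(n2, 0.15)); e2 <- rbinom(n2, 1, 0.7)
    lr <- logrank(list(a = list(times = t1, events = e1),
                       b = list(times = t2, events = e2)))
    expect_equal(lr$chi2, brute_logrank_2g(t1, e1, t2, e2),
                 tolerance = 1e-9)
  }
})

test_that("two-group logrank agrees with an established implementation", {
  skip_if_not_installed("survival")
  set.seed(12)
  for (i in 1:100) {
    n <- sample(30:120, 1)
    tm <- ceiling(rexp(n, 0.08))
    ev <- rbinom(n, 1, 0.65)
    gr <- rbinom(n, 1, 0.5)
    if (length(unique(gr)) < 2 || sum(ev) == 0) next
    lr <- logrank(times = tm, events = ev, group = gr)
    sd <- survival::survdiff(survival::Surv(tm, ev) ~ gr)
    expect_equal(lr$chi2, sd$chisq, tolerance = 1e-6)
  }
})

test_that("k-group logrank has the right df and matches survdiff", {
  skip_if_not_installed("survival")
  set.seed(13)
  for (i in 1:25) {
    n <- 90
    gr <- sample(1:3, n, replace = TRUE)
    tm <- ceiling(rexp(n, 0.05 * gr))  # one group with far shorter survival
    ev <- rbinom(n, 1, 0.8)
    lr <- logrank(times = tm, events = ev, group = gr)
    expect_equal(lr$df, 2L)
    sd <- survival::survdiff(survival::Surv(tm, ev) ~ gr)
    expect_equal(lr$chi2, sd$chisq, tolerance = 1e-6)
    expect_equal(lr$p_value,
                 pchisq(lr$chi2, 2, lower.tail = FALSE))
  }
})

test_that("reported p-values are the upper chi-squared tail of the statistic", {
  set.seed(23)
  res <- lapply(1:8, function(i) {
    tm <- rexp(50, 0.05 * sample(1:2, 50, replace = TRUE))
    logrank(times = tm, events = rbinom(50, 1, 0.8),
            group = rbinom(50, 1, 0.5))
  })
  for (lr in res) {
    expect_equal(lr$p_value, pchisq(lr$chi2, lr$df, lower.tail = FALSE))
  }
  # hence p is monotone decreasing in chi2 at fixed df
  o <- order(vapply(res, `[[`, numeric(1), "chi2"))
  ps <- vapply(res, `[[`, numeric(1), "p_value")[o]
  expect_true(all(diff(ps) <= 0))
})
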