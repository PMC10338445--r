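# frequencies -> counts helper for one pregnancy, focal taxon in asvA (L. iners)
dominance_counts <- function(focal_freqs) {
  other <- (1 - focal_freqs) / 3
  m <- cbind(asvA = focal_freqs, asvB = other, asvC = other, asvD = other)
  counts <- round(m * 1e5)
  storage.mode(counts) <- "integer"
  rownames(counts) <- sprintf("s%02d", seq_along(focal_freqs))
  counts
}

test_that("dominance records follow the at-risk / event / censor rules", {
  tax <- toy_taxonomy()
  # dominated at entry: not at risk
  r1 <- extract_dominance_record(dominance_counts(c(0.8, 0.1)), c(40, 70),
                                 tax, "L. iners")
  expect_false(r1$at_risk)
  expect_equal(r1$reason, "dominated_at_entry")
  # event at the first day exceeding 0.7
  r2 <- extract_dominance_record(dominance_counts(c(0.1, 0.2, 0.75)),
                                 c(40, 70, 100), tax, "L. iners")
  expect_true(r2$at_risk)
  expect_true(r2$event)
  expect_equal(r2$time_days, 100)
  # censored at the last sampled day
  r3 <- extract_dominance_record(dominance_counts(c(0.1, 0.3)), c(40, 200),
                                 tax, "L. iners")
  expect_false(r3$event)
  expect_equal(r3$time_days, 200)
  # no follow-up
  r4 <- extract_dominance_record(dominance_counts(c(0.1)), c(40), tax, "L. iners")
  expect_false(r4$at_risk)
  expect_equal(r4$reason, "no_follow_up")
  # gestational samples are ignored: only day > 0 counts
  r5 <- extract_dominance_record(dominance_counts(c(0.9, 0.1, 0.2)),
                                 c(-20, 40, 100), tax, "L. iners")
  expect_true(r5$at_risk)
  expect_false(r5$event)
})

test_that("taxon frequency sums member ASVs before thresholding", {
  tax <- toy_taxonomy()
  # asvA (L. iners) + asvB (L. crispatus) both Lactobacillus: 0.4 + 0.4 > 0.7
  m <- cbind(asvA = c(0.1, 0.4), asvB = c(0.1, 0.4),
             asvC = c(0.4, 0.1), asvD = c(0.4, 0.1))
  counts <- round(m * 1e5); storage.mode(counts) <- "integer"
  rownames(counts) <- c("s1", "s2")
  r <- extract_dominance_record(counts, c(30, 60), tax, "Lactobacillus")
  expect_true(r$event)
  expect_equal(r$time_days, 60)
  # at species level neither ASV exceeds 0.7
  r2 <- extract_dominance_record(counts, c(30, 60), tax, "L. iners")
  expect_false(r2$event)
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  rec <- data.frame(pregnancy_id = c("a", "b", "c"),
                    time_days = c(100, 200, 300),
                    event = c(FALSE, TRUE, TRUE))
  km <- km_fit(rec)
  oracle <- km_oracle(rec$time_days, rec$event)
  expect_equal(km$survival[km$time == 200], 0.5)
  expect_equal(km$survival[km$time == 300], 0)
  expect_equal(km$survival[km$time %in% oracle$time], oracle$surv)
  # cumulative incidence at 365 is 1; before any event it is 0
  expect_equal(cumulative_incidence_at(km, 365)$probability, 1)
  expect_equal(cumulative_incidence_at(km, 50)$probability, 0)
  expect_equal(cumulative_incidence_at(km, 50)$ci_upper, 0)
})

test_that("KM reduces to 1 - ECDF without censoring and stays flat when all censored", {
  set.seed(60)
  times <- sample(30:360, 25, replace = TRUE)
  rec <- data.frame(pregnancy_id = seq_along(times), time_days = times,
                    event = TRUE)
  km <- km_fit(rec)
  for (t in c(45, 120, 250, 360)) {
    expect_equal(1 - cumulative_incidence_at(km, t)$probability,
                 1 - stats::ecdf(times)(t))
  }
  allc <- km_fit(data.frame(pregnancy_id = 1:5, time_days = times[1:5],
                            event = FALSE))
  expect_true(all(allc$survival == 1))
  expect_equal(sum(allc$n_event), 0)
  # survival is a non-increasing step function
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$ci_lower <= km$survival + 1e-12 &
                    km$survival <= km$ci_upper + 1e-12))
})

test_that("landmarking excludes early endpoints and groups by onset before landmark", {
  rec <- data.frame(pregnancy_id = c("a", "b", "c", "d"),
                    time_days = c(60, 200, 200, 90),
                    event = c(FALSE, TRUE, TRUE, TRUE))
  onsets <- c(b = 30, c = 150)
  lm <- landmark_split(rec, onsets, landmark_day = 90)
  # a censored at 60 and d with endpoint exactly at the landmark are excluded
  expect_equal(sort(lm$pregnancy_id), c("b", "c"))
  expect_equal(lm$exposed[lm$pregnancy_id == "b"], TRUE)   # onset 30 <= 90
  expect_equal(lm$exposed[lm$pregnancy_id == "c"], FALSE)  # onset 150 > 90
  expect_equal(lm$time_days, c(110, 110))
  expect_error(landmark_split(rec[1, ], onsets), "no cases survive")
})

test_that("counting-process intervals split at onset with the event on the last interval", {
  rec <- data.frame(pregnancy_id = c("a", "b"),
                    time_days = c(200, 300), event = c(TRUE, FALSE))
  iv <- counting_process_intervals(rec, c(a = 120))
  expect_equal(nrow(iv), 3)
  a_iv <- iv[iv$pregnancy_id == "a", ]
  expect_equal(a_iv$start_day, c(0, 120))
  expect_equal(a_iv$stop_day, c(120, 200))
  expect_equal(a_iv$event_at_stop, c(FALSE, TRUE))
  expect_equal(a_iv$covariate, c(0L, 1L))
  b_iv <- iv[iv$pregnancy_id == "b", ]
  expect_equal(nrow(b_iv), 1)
  expect_equal(b_iv$covariate, 0L)
  # onset after the record end gives a single unexposed interval
  iv2 <- counting_process_intervals(rec, c(a = 250))
  expect_equal(nrow(iv2[iv2$pregnancy_id == "a", ]), 1)
  # 25 cases, 10 with interior onsets -> 35 intervals
  rec25 <- data.frame(pregnancy_id = sprintf("c%02d", 1:25),
                      time_days = rep(300, 25),
                      event = rep(c(TRUE, FALSE), length.out = 25))
  on10 <- stats::setNames(rep(100, 10), sprintf("c%02d", 1:10))
  expect_equal(nrow(counting_process_intervals(rec25, on10)), 35)
})

test_that("Cox fit maximizes the partial likelihood (grid oracle, n = 3)", {
  iv <- data.frame(pregnancy_id = c("a", "b", "c"),
                   start_day = c(0, 0, 0), stop_day = c(50, 80, 120),
                   event_at_stop = c(TRUE, TRUE, FALSE),
                   covariate = c(1L, 0L, 1L))
  fit <- cox_fit(iv)
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, function(b) cox_loglik_oracle(iv, b), numeric(1))
  expect_equal(fit$log_hr, grid[which.max(ll)], tolerance = 1e-3)
  expect_gt(fit$hr, 0)
  expect_true(fit$hr_ci_95[1] <= fit$hr && fit$hr <= fit$hr_ci_95[2])
})

test_that("Cox with a time-fixed covariate equals the classic single-interval fit", {
  set.seed(71)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  t <- round(rexp(n, 0.01 * exp(0.7 * x))) + 1
  ev <- t < 150
  t <- pmin(t, 150) + seq_len(n) * 1e-3  # break ties
  iv <- data.frame(pregnancy_id = seq_len(n), start_day = 0, stop_day = t,
                   event_at_stop = ev, covariate = x)
  classic <- survival::coxph(survival::Surv(t, ev) ~ x, ties = "efron")
  expect_equal(cox_fit(iv)$log_hr, unname(coef(classic)), tolerance = 1e-8)
})

test_that("Cox is null-calibrated under permuted covariates and flags separation", {
  set.seed(72)
  n <- 100
  t <- round(rexp(n, 0.01)) + 1
  ev <- rbinom(n, 1, 0.7) == 1
  iv <- data.frame(pregnancy_id = seq_len(n), start_day = 0,
                   stop_day = t + runif(n) * 1e-2,
                   event_at_stop = ev, covariate = sample(rep(0:1, n / 2)))
  fit <- cox_fit(iv)
  se <- (log(fit$hr_ci_95[2]) - fit$log_hr) / 1.96
  expect_lt(abs(fit$log_hr), 3 * se)
  # complete separation: all events in one group, none in the other
  sep <- data.frame(pregnancy_id = 1:20, start_day = 0,
                    stop_day = c(seq(10, 100, by = 10), seq(110, 200, by = 10)),
                    event_at_stop = rep(c(TRUE, FALSE), each = 10),
                    covariate = rep(c(1L, 0L), each = 10))
  expect_true(suppressWarnings(cox_fit(sep))$separation)
  expect_error(cox_fit(iv[!iv$event_at_stop, ]), "no events")
})
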