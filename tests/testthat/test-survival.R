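test_that("km_estimate reproduces hand-computed product-limit curves", {
  # all censored: survival stays at 1
  c0 <- km_estimate(c(5, 10, 15), c(FALSE, FALSE, FALSE))
  expect_equal(c0$n_events, 0)
  expect_equal(survival_at(c0, 100), 1)

  # all events: S = {2/3, 1/3, 0}
  c1 <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(c1$survival, c(2 / 3, 1 / 3, 0))

  # censoring at 2: S(1) = 2/3, then the last subject's event empties the
  # risk set, so S(3) = 0
  c2 <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(c2$times, c(1, 3))
  expect_equal(c2$survival, c(2 / 3, 0))

  expect_error(km_estimate(numeric(0), logical(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(TRUE, TRUE)), "negative")
})

test_that("km_estimate matches a brute-force product-limit oracle on random data", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    times <- round(rexp(n, 0.05), 1) # rounding induces ties
    events <- runif(n) < 0.7
    if (!any(events)) events[1] <- TRUE
    fit <- km_estimate(times, events)
    ora <- oracle_km(times, events)
    expect_equal(fit$times, ora$times)
    expect_equal(fit$survival, ora$survival, tolerance = 1e-12)
  }
})

test_that("survival_at is a right-continuous non-increasing step function", {
  curve <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(survival_at(curve, 0), 1)
  expect_equal(survival_at(curve, 2.5), survival_at(curve, 1)) # step holds
  expect_equal(survival_at(curve, 99), curve$survival[length(curve$survival)])
  expect_error(survival_at(curve, -1), "negative")

  set.seed(5)
  times <- rexp(50, 0.03)
  curve <- km_estimate(times, runif(50) < 0.6)
  grid <- seq(0, 150, by = 1.7)
  vals <- survival_at(curve, grid)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("logrank_test matches the O-E oracle and behaves at the extremes", {
  # two identical groups interleaved: no evidence of difference
  t0 <- rep(c(1, 2, 3, 4), 2)
  e0 <- rep(TRUE, 8)
  g0 <- rep(c("a", "b"), each = 4)
  lr0 <- logrank_test(t0, e0, g0)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  # completely separated event times at large n
  n <- 60
  lr1 <- logrank_test(c(1:n, 100 + 1:n), rep(TRUE, 2 * n),
                      rep(c("a", "b"), each = n))
  expect_lt(lr1$p_value, 0.001)

  # hand-checkable 2-group mix against the brute-force O-E computation
  set.seed(31)
  for (i in 1:20) {
    times <- round(rexp(24, 0.1), 1)
    events <- runif(24) < 0.8
    group <- rep(c("a", "b"), 12)
    if (!any(events)) events[1] <- TRUE
    lr <- logrank_test(times, events, group)
    expect_equal(lr$statistic, unname(oracle_logrank(times, events, group)),
                 tolerance = 1e-8)
  }

  expect_error(logrank_test(1:3, c(TRUE, TRUE, TRUE), rep("a", 3)),
               "2 non-empty groups")
})

test_that("reverse KM follow-up inverts the event indicator", {
  # all censored at 60: median potential follow-up is 60
  expect_equal(reverse_km_followup(rep(60, 10), rep(FALSE, 10)), 60)
  # no censoring at all: the reversed curve never drops, median not reached
  expect_true(is.na(reverse_km_followup(c(5, 10, 20), rep(TRUE, 3))))
  # half censored at 24, half events at 100: reversed curve hits 0.5 at 24
  times <- c(rep(24, 5), rep(100, 5))
  events <- c(rep(FALSE, 5), rep(TRUE, 5))
  expect_equal(reverse_km_followup(times, events), 24)
})

sim_survival_frame <- function(n, hr, seed) {
  set.seed(seed)
  ind <- runif(n) < 0.5
  lambda0 <- -log(0.3) / 60
  times <- rexp(n, lambda0 * ifelse(ind, hr, 1))
  cens <- runif(n, 0, 240)
  data.frame(patient_id = sprintf("P%d", 1:n),
             dss_time = pmin(times, cens), dss_event = times <= cens,
             dfs_time = pmin(times, cens), dfs_event = times <= cens,
             pT = sample(c("pT2", "pT3"), n, TRUE),
             pN = sample(c("pN0", "pN+"), n, TRUE),
             L = sample(c("L0", "L1"), n, TRUE),
             age = rnorm(n, 70, 8),
             gender = sample(c("male", "female"), n, TRUE),
             margin = sample(c("R0", "R1"), n, TRUE),
             adj_chemo = runif(n) < 0.25,
             grade = sample(c("G2", "G3"), n, TRUE),
             indicator = ind, stringsAsFactors = FALSE)
}

test_that("cox_multivariable recovers a null indicator and the output schema", {
  d <- sim_survival_frame(600, hr = 1, seed = 41)
  est <- cox_multivariable(d[-ncol(d)],
                           d[c("patient_id", "indicator")], "dss")
  ind <- est[startsWith(est$variable, "indicator"), ]
  expect_equal(nrow(ind), 1)
  expect_true(ind$ci_low <= ind$hr && ind$hr <= ind$ci_high)
  expect_true(ind$ci_low < 1 && ind$ci_high > 1) # HR ~ 1 inside the CI
  expect_true(all(c("variable", "hr", "ci_low", "ci_high", "p_value")
                  %in% names(est)))
})

test_that("cox_multivariable drops incomplete rows with a message", {
  d <- sim_survival_frame(120, hr = 1, seed = 43)
  d$age[1:5] <- NA
  expect_message(
    cox_multivariable(d[-ncol(d)], d[c("patient_id", "indicator")], "dss"),
    "excluding 5")
})

test_that("the Cox fit maximizes the partial likelihood (grid-checked toy)", {
  set.seed(19)
  n <- 30
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  beta_true <- c(0.8, -0.5)
  times <- rexp(n, 0.05 * exp(as.vector(X %*% beta_true)))
  events <- rep(TRUE, n) # no ties, no censoring: partial likelihood exact
  d <- data.frame(patient_id = sprintf("P%d", 1:n),
                  dss_time = times, dss_event = events,
                  dfs_time = times, dfs_event = events,
                  x1 = X[, 1], indicator = X[, 2])
  est <- cox_multivariable(d[setdiff(names(d), "indicator")],
                           d[c("patient_id", "indicator")],
                           "dss", covariates = "x1")
  fit_beta <- c(log(est$hr[est$variable == "indicator"]),
                log(est$hr[est$variable == "x1"]))
  Xo <- cbind(X[, 2], X[, 1])
  opt <- optim(c(0, 0), function(b) -oracle_cox_loglik(b, Xo, times, events),
               method = "BFGS")
  expect_equal(fit_beta, opt$par, tolerance = 1e-3)
})

test_that("five_year_rates reads the KM curve at 60 months per group", {
  times <- c(10, 70, 80, 90, 5, 20)
  events <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  group <- rep(c("good", "bad"), each = 3)
  r <- five_year_rates(times, events, group)
  expect_equal(r$five_year_rate[r$group == "good"], 2 / 3)
  expect_equal(r$five_year_rate[r$group == "bad"], 1 / 3)
})
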