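# Cox engine: agreement with survival::coxph, the grid-search oracle,
# invariances, reference-level handling and failure modes.

test_that("fit_cox agrees with survival::coxph on random tied data", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 40 + rep * 10
    d <- data.frame(
      x1 = rnorm(n),
      x2 = factor(sample(c("a", "b", "c"), n, replace = TRUE,
                         prob = c(.5, .3, .2))),
      x3 = rbinom(n, 1, 0.4)
    )
    d$time <- round(rexp(n, 0.2 * exp(0.6 * d$x1 - 0.4 * d$x3)), 1) + 0.1
    d$event <- rbinom(n, 1, 0.75)
    if (sum(d$event) < 3) next

    for (ties in c("efron", "breslow")) {
      ref <- survival::coxph(
        survival::Surv(time, event) ~ x1 + stats::relevel(x2, "a") + x3,
        data = d, ties = ties)
      fit <- fit_cox(d, "time", "event", c("x1", "x2", "x3"), ties = ties)
      td <- tidy(fit)
      expect_equal(sort(unname(td$estimate)), sort(unname(coef(ref))),
                   tolerance = 1e-6)
      expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
      expect_equal(fit$aic, stats::AIC(ref), tolerance = 1e-6)
      expect_equal(sort(td$std.error), sort(unname(sqrt(diag(vcov(ref))))),
                   tolerance = 1e-6)
    }
  }
})

test_that("the 8-subject toy fit matches grid maximization of the partial likelihood", {
  # group 1 tends to fail earlier (interleaved so the maximizer is finite)
  d <- data.frame(time = 1:8, event = 1,
                  x = c(1, 1, 0, 1, 0, 1, 0, 0))
  fit <- fit_cox(d, "time", "event", "x")
  beta_grid <- grid_max_oracle(d$time, d$event, d$x)
  expect_lt(abs(tidy(fit)$estimate - beta_grid), 1e-4)
  # direction agreement at alpha = 0.05 with the oracle's curvature
  ll_at <- function(b) efron_loglik_oracle(b, d$time, d$event, d$x)
  lr_stat <- 2 * (ll_at(beta_grid) - ll_at(0))
  expect_equal(significance(fit, "x"),
               lr_stat > stats::qchisq(0.95, 1))
})

test_that("a two-group exponential simulation recovers the true HR", {
  set.seed(202)
  n <- 2000
  g <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1 * exp(log(3) * g))
  event <- rep(1L, n)
  d <- data.frame(time = time, event = event, g = g)
  fit <- fit_cox(d, "time", "event", "g")
  oracle <- (sum(event[g == 1]) / sum(time[g == 1])) /
    (sum(event[g == 0]) / sum(time[g == 0]))
  expect_lt(abs(tidy(fit)$hr / oracle - 1), 0.1)
})

test_that("categorical reference is the most frequent level", {
  set.seed(9)
  d <- data.frame(time = rexp(50) + 0.1, event = rbinom(50, 1, 0.8),
                  grp = sample(c("rare", "common"), 50, replace = TRUE,
                               prob = c(0.25, 0.75)))
  fit <- fit_cox(d, "time", "event", "grp")
  td <- tidy(fit)
  expect_equal(td$reference, "common")
  expect_equal(td$term, "grprare")
})

test_that("degenerate designs fail loudly", {
  d <- data.frame(time = rexp(30) + 0.1, event = rbinom(30, 1, 0.8),
                  x = 1, g = "same")
  expect_error(fit_cox(d, "time", "event", "x"), "constant")
  expect_error(fit_cox(d, "time", "event", "g"), "levels")
  d2 <- data.frame(time = rexp(30) + 0.1, event = 0, x = rnorm(30))
  expect_error(fit_cox(d2, "time", "event", "x"), "no events")
  # complete separation is flagged, not silently returned
  d3 <- data.frame(time = c(1:10, 101:110), event = 1,
                   x = rep(c(1, 0), each = 10))
  expect_warning(fit3 <- fit_cox(d3, "time", "event", "x"), "converge")
  expect_false(fit3$converged)
  expect_false(significance(suppressWarnings(
    fit_cox(d3, "time", "event", "x")), "x"))
})

test_that("missing rows are dropped as complete cases and counted", {
  set.seed(30)
  d <- data.frame(time = rexp(60) + 0.1, event = rbinom(60, 1, 0.8),
                  x = rnorm(60))
  d$x[c(3, 10)] <- NA
  expect_message(fit <- fit_cox(d, "time", "event", "x"), "2 row")
  expect_equal(fit$n, 58)
  expect_equal(fit$n_dropped, 2)
})

test_that("estimates are invariant to time origin and equivariant to covariate scale", {
  set.seed(17)
  d <- data.frame(time = rexp(80, 0.3) + 0.1, event = rbinom(80, 1, 0.7),
                  x = rnorm(80))
  b1 <- tidy(fit_cox(d, "time", "event", "x"))$estimate
  d2 <- d; d2$time <- d2$time + 5
  expect_equal(tidy(fit_cox(d2, "time", "event", "x"))$estimate, b1,
               tolerance = 1e-10)
  d3 <- d; d3$x <- d3$x * 10
  expect_equal(tidy(fit_cox(d3, "time", "event", "x"))$estimate, b1 / 10,
               tolerance = 1e-7)
})

test_that("partial log-likelihood never decreases along accepted Newton steps", {
  # convergence from a null start implies loglik >= loglik_null; check on
  # a batch of random instances
  set.seed(55)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    d <- data.frame(time = rexp(n, 0.2) + 0.05,
                    event = rbinom(n, 1, 0.7), x = rnorm(n))
    if (sum(d$event) < 3 || length(unique(d$time[d$event == 1])) < 2) next
    fit <- tryCatch(suppressWarnings(fit_cox(d, "time", "event", "x")),
                    error = function(e) NULL)
    if (is.null(fit)) next
    expect_gte(fit$loglik, fit$loglik_null - 1e-10)
  }
})

test_that("significance applies a strict 0.05 threshold", {
  set.seed(71)
  d <- data.frame(time = rexp(100, 0.2 * exp(0.8 * rep(0:1, 50))) + 0.01,
                  event = 1, g = rep(0:1, 50))
  fit <- fit_cox(d, "time", "event", "g")
  p <- tidy(fit)$p.value
  expect_identical(significance(fit, "g"), p < 0.05)
  expect_identical(significance(fit, "g", alpha = p), FALSE) # p == alpha
  expect_identical(significance(fit, "g", alpha = p + 1e-12), TRUE)
  expect_error(significance(fit, "nope"), "nope")
})

test_that("tidy/glance expose a broom-shaped summary", {
  d <- toy_step_cohort(n = 100, seed = 12)
  fit <- fit_cox(d, "time_LRC", "event_LRC", c("marker", "sex"))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value", "hr",
                    "conf.low", "conf.high") %in% names(td)))
  expect_true(all(td$hr > 0))
  expect_true(all(td$conf.low <= td$hr & td$hr <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$AIC, -2 * fit$loglik + 2 * nrow(td))
  expect_true(gl$converged)
  expect_lt(gl$score_max, 1e-7)
})
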