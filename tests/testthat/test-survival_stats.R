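test_that("Kaplan-Meier matches the hand product-limit", {
  km <- kaplan_meier(c(1, 2), c(1, 0))
  expect_equal(km$fn(0), 1)
  expect_equal(km$fn(1), 0.5)
  # no events -> flat at 1
  flat <- kaplan_meier(c(3, 5, 7), c(0, 0, 0))
  expect_equal(flat$fn(100), 1)
  expect_error(kaplan_meier(c(0, 1), c(1, 1)), "positive")

  set.seed(51)
  for (k in 1:10) {
    d <- random_surv(sample(10:60, 1))
    km <- kaplan_meier(d$time, d$event)
    want <- km_oracle(d$time, d$event)
    expect_equal(km$time[km$n_event > 0], want$time)
    expect_equal(km$surv[km$n_event > 0], want$surv, tolerance = 1e-12)
  }
})

test_that("KM is invariant to censoring after the last event", {
  d <- data.frame(time = c(2, 4, 6, 8), event = c(1, 1, 0, 0))
  km1 <- kaplan_meier(d$time, d$event)
  d2 <- d; d2$time[3:4] <- c(60, 80)
  km2 <- kaplan_meier(d2$time, d2$event)
  expect_equal(km1$fn(5), km2$fn(5))
  expect_equal(min(km1$surv), min(km2$surv))
})

test_that("log-rank handles the degenerate and hand-checkable cases", {
  # identical groups -> no signal
  t0 <- c(1, 2, 3, 4); e0 <- c(1, 1, 0, 1)
  lr <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  expect_warning(
    lr0 <- logrank_test(c(1, 2, 3, 4), c(0, 0, 0, 0),
                        c("a", "a", "b", "b")), "no events")
  expect_equal(lr0$p, 1)
  expect_error(logrank_test(1:3, c(1, 1, 1), c("a", "a", "a")),
               "two non-empty")

  # 4-subject example against the observed-minus-expected formula
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1)
  group <- c("a", "b", "a", "b")
  got <- logrank_test(time, event, group)
  o_a <- 2
  e_a <- 2 / 4 + 1 / 3 + 1 / 2 + 0 / 1
  v <- sum(vapply(c(1, 2, 3), function(t) {
    n <- sum(time >= t); n_a <- sum(time >= t & group == "a")
    (n_a / n) * (1 - n_a / n)
  }, 0))
  expect_equal(got$statistic, (o_a - e_a)^2 / v, tolerance = 1e-9)
})

test_that("log-rank has power against a hazard ratio of 3", {
  set.seed(52)
  hits <- replicate(100, {
    t_a <- rexp(100, 0.05); t_b <- rexp(100, 0.15)
    cens <- runif(200, 5, 50)
    time <- pmin(c(t_a, t_b), cens)
    event <- as.numeric(c(t_a, t_b) <= cens)
    logrank_test(time, event, rep(c("a", "b"), each = 100))$p < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("log-rank p-values are uniform under label permutation", {
  set.seed(53)
  d <- random_surv(40)
  g0 <- rep(c("a", "b"), each = 20)
  ps <- replicate(500, logrank_test(d$time, d$event, sample(g0))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Cox fits match a hand-maximised partial likelihood", {
  # untied case: alternating binary covariate, no censoring; risk sets
  # {1,0,1,0}, {0,1,0}, {1,0}, {0}
  d <- data.frame(time = c(1, 2, 3, 4), event = 1, x = c(1, 0, 1, 0))
  nll <- function(b) -(2 * b - log(2 * exp(b) + 2) - log(exp(b) + 2) -
                         log(exp(b) + 1))
  bhat <- optimize(nll, c(-10, 10), tol = 1e-10)$minimum
  got <- cox_fit(d, "x")
  expect_equal(got$coef, bhat, tolerance = 1e-6)
  expect_equal(got$hr, exp(bhat), tolerance = 1e-5)

  # tied case: no censoring, two distinct death times with two deaths
  # each; Efron denominators subtract half the tied-death risk mass
  d2 <- data.frame(time = c(1, 1, 2, 2), event = 1, x = c(1, 0, 0, 0))
  nll2 <- function(b) -(b - log(exp(b) + 3) -
                          log(exp(b) + 3 - 0.5 * (exp(b) + 1)) -
                          log(2) - log(1))
  bhat2 <- optimize(nll2, c(-10, 10), tol = 1e-10)$minimum
  got2 <- cox_fit(d2, "x")
  expect_equal(got2$coef, bhat2, tolerance = 1e-6)
})

test_that("Cox rejects degenerate input and scales equivariantly", {
  d <- random_surv(30); d$x <- 1
  expect_error(cox_fit(d, "x"), "constant")
  expect_error(cox_fit(d, "nope"), "missing covariate")

  set.seed(54)
  d <- random_surv(120); d$x <- rnorm(120)
  f1 <- cox_fit(d, "x")
  d$x <- d$x * 10
  f2 <- cox_fit(d, "x")
  expect_equal(f2$coef, f1$coef / 10, tolerance = 1e-6)

  # multivariable fit needs enough events and returns one row per term
  d$z <- rnorm(120)
  mv <- cox_fit(d, c("x", "z"), adjustment = "multivariable")
  expect_equal(nrow(mv), 2)
})

test_that("the PH check flags proportional and crossing hazards", {
  set.seed(55)
  # proportional data -> satisfied
  n <- 300
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.08 * exp(0.5 * x))
  d <- data.frame(time = pmin(t_ev, 30), event = as.numeric(t_ev <= 30),
                  x = x)
  chk <- ph_check(d, "x")
  expect_true(chk$p > 0)
  # effect reversing over time -> violated at n = 500
  n <- 500
  x <- rbinom(n, 1, 0.5)
  early <- rexp(n, 0.4 * exp(1.5 * x))
  late <- 2 + rexp(n, 0.4 * exp(-1.5 * x))
  t_ev <- ifelse(early < 2, early, late)
  d2 <- data.frame(time = t_ev, event = 1, x = x)
  expect_false(ph_check(d2, "x")$satisfied)

  d$k <- 1
  expect_error(ph_check(d, "k"), "zero variance")
})
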