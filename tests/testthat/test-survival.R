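# Survival machinery: Kaplan-Meier, log-rank, Cox partial likelihood,
# Harrell's c, bootstrap CIs, sparse-group merging, median imputation.
# The survival CRAN package serves as the independent cross-check oracle.

library(survival)

test_that("Kaplan-Meier matches closed forms and a hand calculation", {
  # all censored: S identically 1 (no event-time rows, flat curve)
  km0 <- km_estimate(c(3, 5, 8), c(FALSE, FALSE, FALSE))
  expect_equal(nrow(km0), 0)

  # no censoring: product-limit equals the empirical survival function
  km1 <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km1$survival, c(2 / 3, 1 / 3, 0))

  # hand-computed mixed example: events at 2, 5, 7; censored at 4, 9
  # S(2) = 4/5; S(5) = 4/5 * 2/3 = 8/15; S(7) = 8/15 * 1/2 = 4/15
  km2 <- km_estimate(c(2, 4, 5, 7, 9), c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(km2$time, c(2, 5, 7))
  expect_equal(km2$survival, c(4 / 5, 8 / 15, 4 / 15))
  expect_equal(km2$n_risk, c(5L, 3L, 2L))

  # property: without censoring S(t) = P(T > t) exactly, risk set
  # non-increasing, survival non-increasing from 1
  set.seed(21)
  t <- round(rexp(40, 0.2) + 0.1, 1)
  km <- km_estimate(t, rep(TRUE, 40))
  expect_equal(km$survival, vapply(km$time, function(u) mean(t > u), 0))
  expect_true(all(diff(km$n_risk) <= 0))
  expect_true(all(diff(km$survival) <= 0))
  expect_error(km_estimate(numeric(), logical()), "empty")
  expect_error(km_estimate(c(0, 1), c(TRUE, TRUE)), "positive")
})

test_that("log-rank test behaves under the null, separation, and agrees
           with the survdiff oracle", {
  # two identical groups: exchangeable, statistic ~ 0
  t <- c(1, 2, 3, 4, 6, 8); e <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  lr0 <- logrank_test(c(t, t), c(e, e), rep(1:2, each = 6))
  expect_lt(lr0$chisq, 1e-10)
  expect_equal(lr0$df, 1)

  # wholly separated event times: strong evidence
  lr1 <- logrank_test(c(1:10, 101:110), rep(TRUE, 20), rep(1:2, each = 10))
  expect_gt(lr1$chisq, 0)
  expect_lt(lr1$p_value, 0.05)

  # cross-library oracle on random censored data, 2 and 5 groups
  set.seed(31)
  for (k in c(2, 5)) {
    n <- 40 * k
    g <- sample(seq_len(k), n, replace = TRUE)
    tt <- rexp(n, 0.1 * g)
    ev <- runif(n) < 0.7
    mine <- logrank_test(tt, ev, g)
    ref <- survival::survdiff(Surv(tt, ev) ~ g)
    expect_equal(mine$chisq, ref$chisq, tolerance = 1e-8)
    expect_equal(mine$df, k - 1)
  }

  expect_error(logrank_test(1:4, rep(TRUE, 4), rep(1, 4)), "two groups")
  expect_error(logrank_test(1:4, rep(FALSE, 4), rep(1:2, 2)), "no events")
})

test_that("Cox fit agrees with the survival package to high precision", {
  set.seed(41)
  n <- 120
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  tt <- rexp(n, exp(0.5 * x[, 1] - 0.7 * x[, 2])) + runif(n, 0, 1e-9)
  ev <- runif(n) < 0.8
  fit <- cox_fit(tt, ev, x)
  ref <- survival::coxph(Surv(tt, ev) ~ x, ties = "efron")
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-7)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
  expect_equal(fit$hr, exp(fit$coef), ignore_attr = TRUE)
  expect_true(all(fit$ci_low < fit$hr & fit$hr < fit$ci_high))

  # heavily tied times exercise the Efron correction
  t2 <- ceiling(tt * 3)
  fit2 <- cox_fit(t2, ev, x)
  ref2 <- survival::coxph(Surv(t2, ev) ~ x, ties = "efron")
  expect_equal(unname(fit2$coef), unname(coef(ref2)), tolerance = 1e-7)
  fit3 <- cox_fit(t2, ev, x, ties = "breslow")
  ref3 <- survival::coxph(Surv(t2, ev) ~ x, ties = "breslow")
  expect_equal(unname(fit3$coef), unname(coef(ref3)), tolerance = 1e-7)
})

test_that("Cox score test reproduces the log-rank statistic on untied data", {
  set.seed(43)
  n <- 80
  g <- rbinom(n, 1, 0.5)
  tt <- rexp(n, exp(0.6 * g)) + runif(n, 0, 1e-9)
  ev <- runif(n) < 0.75
  fit <- cox_fit(tt, ev, g)
  lr <- logrank_test(tt, ev, g)
  expect_equal(fit$score_chisq, lr$chisq, tolerance = 1e-6)
})

test_that("Cox fit rejects degenerate designs", {
  tt <- 1:10; ev <- rep(TRUE, 10)
  expect_error(cox_fit(tt, ev, rep(0, 10)), "constant covariate")
  expect_error(cox_fit(tt, rep(FALSE, 10), rnorm(10)), "zero events")
  # perfectly separated risk ordering -> monotone partial likelihood
  expect_error(cox_fit(10:1 + 0.5, ev, 1:10),
               "separation|converge|singular")
})

test_that("Harrell's c matches the brute-force pair enumeration exactly", {
  set.seed(51)
  for (r in 1:50) {
    n <- 30
    tt <- round(rexp(n, 0.1), 1) + 0.1     # some tied times
    ev <- runif(n) < 0.6
    if (!any(ev)) ev[1] <- TRUE
    sc <- sample(1:5, n, replace = TRUE)   # some tied scores
    mine <- harrell_c(tt, ev, sc)
    ora <- oracle_harrell(tt, ev, sc)
    expect_identical(mine$c, ora$c)
    expect_identical(mine$n_comparable_pairs, ora$n_comparable_pairs)
  }
})

test_that("Harrell's c limiting values, antisymmetry and rank invariance", {
  set.seed(52)
  n <- 60
  tt <- rexp(n) + 0.01
  ev <- runif(n) < 0.7
  if (!any(ev)) ev[1] <- TRUE
  expect_equal(harrell_c(tt, ev, rep(1, n))$c, 0.5)        # all ties
  expect_equal(harrell_c(tt, ev, -tt)$c, 1)                # perfect ranking
  sc <- rnorm(n)                                           # untied scores
  expect_equal(harrell_c(tt, ev, sc)$c + harrell_c(tt, ev, -sc)$c, 1)
  expect_equal(harrell_c(tt, ev, sc)$c,
               harrell_c(tt, ev, exp(3 * sc) + 7)$c)       # monotone invariant
  # cross-library check (concordance counts risk pairs the same way)
  ref <- survival::concordance(Surv(tt, ev) ~ sc, reverse = TRUE)
  expect_equal(harrell_c(tt, ev, sc)$c, unname(ref$concordance))
  expect_error(harrell_c(5, TRUE, 1), "no comparable pairs")
})

test_that("bootstrap c-index is reproducible and degenerates correctly", {
  set.seed(53)
  d <- data.frame(time = rexp(80) + 0.01, event = runif(80) < 0.6,
                  score = rnorm(80))
  scorer <- function(x) x$score
  b1 <- bootstrap_c(d, scorer, n_boot = 25, seed = 99)
  b2 <- bootstrap_c(d, scorer, n_boot = 25, seed = 99)
  expect_identical(b1$replicates, b2$replicates)
  expect_true(b1$ci_low <= b1$estimate || b1$estimate <= b1$ci_high)
  expect_equal(b1$estimate, harrell_c(d$time, d$event, d$score)$c)

  # a perfectly discriminating score has c = 1 on every resample
  d$score <- -d$time
  bp <- bootstrap_c(d, scorer, n_boot = 20, seed = 1)
  expect_equal(bp$estimate, 1)
  expect_equal(c(bp$ci_low, bp$ci_high), c(1, 1))
  expect_error(bootstrap_c(d, scorer, n_boot = 1, seed = 1), "n_boot")

  # a training-free scorer is unbiased: its optimism is only bootstrap
  # noise, and the corrected estimate honours the arithmetic contract
  d$score <- rnorm(80)
  bo <- bootstrap_c(d, scorer, n_boot = 40, seed = 4,
                    train_scorer = function(train) function(new) new$score)
  expect_lt(abs(bo$optimism), 0.05)
  expect_equal(bo$estimate_corrected, bo$estimate - bo$optimism)
  # a Cox-trained scorer is optimistic on its own training resample
  bt <- bootstrap_c(d, scorer, n_boot = 25, seed = 5,
                    train_scorer = function(train) {
                      f <- cox_fit(train$time, train$event,
                                   cbind(s = train$score))
                      function(new) drop(cbind(new$score) %*% f$coef)
                    })
  expect_true(is.finite(bt$estimate_corrected))
})

test_that("sparse-group merging follows the lowest-group rule", {
  # no events in group 1 -> merged '1 & 2' reference
  lab <- c(1, 1, 2, 2, 3, 4, 5)
  ev <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  m <- merge_sparse_groups(lab, ev)
  expect_equal(m$group_names, c("1 & 2", "3", "4", "5"))
  expect_equal(m$labels, c(1, 1, 1, 1, 2, 3, 4))

  # all groups populated with events: identity relabeling
  m2 <- merge_sparse_groups(1:5, rep(TRUE, 5))
  expect_equal(m2$labels, 1:5)
  expect_equal(m2$group_names, as.character(1:5))

  # events only in group 5: cascade merge of 1-4 into the reference
  m3 <- merge_sparse_groups(c(1:5, 5), c(rep(FALSE, 4), TRUE, TRUE))
  expect_equal(m3$group_names, c("1 & 2 & 3 & 4", "5"))
  expect_equal(m3$labels, c(1, 1, 1, 1, 2, 2))

  expect_error(merge_sparse_groups(c(1, 2), c(FALSE, FALSE)),
               "min_events")
})

test_that("median imputation replaces only missing entries", {
  expect_equal(median_impute(c(1, NA, 3)), c(1, 2, 3))
  expect_equal(median_impute(c(4, 2, 9)), c(4, 2, 9))
  set.seed(61)
  psa <- rlnorm(1064, log(8.3), 0.6)
  miss <- sample(1064, 27)
  psa_na <- replace(psa, miss, NA)
  imp <- median_impute(psa_na)
  expect_equal(unique(imp[miss]), median(psa[-miss]))
  expect_equal(imp[-miss], psa[-miss])
  expect_error(median_impute(c(NA_real_, NA_real_)), "all values missing")
})
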