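test_that("the contingency Bayes factor matches dense numerical integration", {
  set.seed(21)
  for (rep in 1:8) {
    y <- matrix(rpois(4, 8), 2, 2)
    if (any(rowSums(y) == 0)) next
    got <- contingency_bf(y)$bf10
    want <- oracle_contingency_bf(y)
    expect_equal(got, want, tolerance = 1e-6)
  }
  # a different prior concentration still matches the oracle
  y <- rbind(c(3, 9), c(7, 2))
  expect_equal(contingency_bf(y, a = 2)$bf10, oracle_contingency_bf(y, a = 2),
               tolerance = 1e-6)
})

test_that("null-consistent tables give evidence for independence", {
  expect_lt(contingency_bf(rbind(c(10, 10), c(10, 10)))$bf10, 1)
})

test_that("the contingency Bayes factor is invariant to swapping rows and columns", {
  y <- rbind(c(1, 27), c(0, 17))
  b <- contingency_bf(y)$bf10
  expect_equal(contingency_bf(y[2:1, ])$bf10, b)
  expect_equal(contingency_bf(y[, 2:1])$bf10, b)
  expect_error(contingency_bf(rbind(c(0, 0), c(1, 2))), "empty")
  expect_error(contingency_bf(rbind(c(0.5, 1), c(1, 2))), "integer")
})

test_that("JZS Bayes factor favours the null for null-like data", {
  set.seed(3)
  x <- rnorm(20); y <- x + 0  # identical groups, t = 0
  expect_lt(jzs_ttest_bf(x, y)$bf10, 1)
  y2 <- rnorm(20)
  t0 <- t.test(x, y2, var.equal = TRUE)$statistic
  if (abs(t0) < 0.5) expect_lt(jzs_ttest_bf(x, y2)$bf10, 1)
  expect_error(jzs_ttest_bf(rep(1, 5), rep(1, 5)), "variance")
  expect_error(jzs_ttest_bf(1, c(1, 2)), "n >= 2")
})

test_that("JZS quadrature agrees with seeded Monte-Carlo prior integration", {
  set.seed(17)
  n1 <- 29; n2 <- 17
  x <- rnorm(n1, 0.83, 1); y <- rnorm(n2, 0, 1)
  got <- jzs_ttest_bf(x, y)$bf10
  # oracle: average the noncentral-t likelihood over draws from the prior
  v <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(v * (1 / n1 + 1 / n2))
  ne <- n1 * n2 / (n1 + n2)
  delta <- rcauchy(1e6, 0, sqrt(2) / 2)
  lik <- suppressWarnings(dt(tstat, n1 + n2 - 2, ncp = delta * sqrt(ne)))
  want <- mean(lik) / dt(tstat, n1 + n2 - 2)
  expect_equal(got, want, tolerance = 0.01)
})

test_that("the directional JZS variant rewards correctly-signed effects", {
  set.seed(5)
  x <- rnorm(25, 1, 1); y <- rnorm(25, 0, 1)
  two <- jzs_ttest_bf(x, y)$bf10
  one <- jzs_ttest_bf(x, y, directional = TRUE)$bf10
  expect_gt(one, two)
  expect_equal(one, 2 * two - jzs_ttest_bf(y, x, directional = TRUE)$bf10,
               tolerance = 1e-6)
})

test_that("the replication Bayes factor equals the conjugate closed form", {
  set.seed(9)
  for (rep in 1:10) {
    eff <- rnorm(1); se <- runif(1, 0.05, 1); pm <- rnorm(1, 0, 2)
    if (abs(pm) < 0.1) next
    got <- dienes_bf(eff, se, pm)
    closed <- dnorm(eff, pm, sqrt(se^2 + (abs(pm) / 2)^2)) / dnorm(eff, 0, se)
    expect_equal(got$bf10, closed, tolerance = 1e-8)
    expect_lt(got$error, 1e-8 * max(1, closed))
  }
  # a null replication of a large claimed effect argues against it
  expect_lt(dienes_bf(0, 0.05, 1)$bf10, 1)
  # reproducing the claimed effect precisely supports it strongly
  expect_gt(dienes_bf(1, 0.01, 1)$bf10, 100)
})

test_that("the replication Bayes factor is scale-invariant", {
  b1 <- dienes_bf(0.08, 0.03, 0.10)$bf10
  b2 <- dienes_bf(8, 3, 10)$bf10
  expect_equal(b1, b2, tolerance = 1e-8)
})

test_that("power functions reduce to alpha under the null and match simulation", {
  expect_equal(power_chisq(0, 100, 1), 0.05)
  expect_equal(power_ttest(0, 25), 0.05, tolerance = 1e-10)

  # noncentral chi-square rejection rate from first principles (df = 1:
  # squared shifted normal)
  set.seed(41)
  nrep <- 1e5
  w <- 0.4; N <- 46
  stat <- (rnorm(nrep) + sqrt(N * w^2))^2
  sim <- mean(stat > qchisq(0.95, 1))
  se <- sqrt(sim * (1 - sim) / nrep)
  expect_lt(abs(power_chisq(w, N, 1) - sim), 2 * se)

  # t-test rejection rate from simulated normal groups
  d <- 0.83; n1 <- 25; n2 <- 25
  g1 <- matrix(rnorm(nrep / 10 * n1, d), n1)
  g2 <- matrix(rnorm(nrep / 10 * n2, 0), n2)
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v <- ((n1 - 1) * apply(g1, 2, var) + (n2 - 1) * apply(g2, 2, var)) /
    (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(v * (1 / n1 + 1 / n2))
  sim_t <- mean(abs(tt) > qt(0.975, n1 + n2 - 2))
  se_t <- sqrt(sim_t * (1 - sim_t) / (nrep / 10))
  expect_lt(abs(power_ttest(d, n1, n2) - sim_t), 2.5 * se_t)
})

test_that("the block-trend regression has 20 residual df and sane nulls", {
  # pure-noise data: the interaction should rarely look significant
  set.seed(6)
  hits <- 0
  for (rep in 1:20) {
    traj <- expand.grid(condition_ms = c(100, 2000), block = 1:12)
    traj$prop_ud <- runif(24, 0, 0.3)
    fit <- block_trend_ols(traj)
    expect_identical(fit$df_residual, 20L)
    if (abs(fit$coefficients["block:long", "t value"]) < 2) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("a perfectly planar trend is reported with essentially zero p", {
  traj <- expand.grid(condition_ms = c(100, 2000), block = 1:12)
  traj$prop_ud <- 0.2 - 0.01 * traj$block -
    0.1 * (traj$condition_ms == 2000) + rnorm(24, 0, 1e-9)
  fit <- block_trend_ols(traj)
  expect_lt(fit$coefficients["block", "Pr(>|t|)"], 1e-10)
  expect_lt(fit$coefficients["long", "Pr(>|t|)"], 1e-10)
})
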