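test_that("zscore standardizes to mean 0, sd 1 with the n-1 denominator", {
  expect_equal(unname(zscore(c(1, 2, 3))), c(-1, 0, 1))
  set.seed(2)
  v <- rnorm(40, 10, 3)
  z <- zscore(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(zscore(rep(4, 10)), "constant")
  # standardized balanced binary vector: values +/- 1, mean 0
  b <- zscore(rep(c(0, 1), each = 29))
  expect_equal(mean(b), 0, tolerance = 1e-12)
  p <- 0.5
  expect_equal(sort(unique(round(b, 10))),
               round(c(-p, 1 - p) / sqrt(p * (1 - p) * 58 / 57), 10))
})

test_that("the OLS identity c = c_prime + a*b holds on any dataset", {
  for (seed in c(1, 7, 19, 101)) {
    s <- simulate_triad_series(seed)
    p <- fit_paths(s$x, s$m, s$y, s$cov)
    expect_equal(p$c, p$c_prime + p$ab, tolerance = 1e-10)
    expect_equal(p$ab, p$a * p$b, tolerance = 1e-12)
  }
  # also on unstructured noise
  set.seed(55)
  cov <- make_covariates(45)
  x <- named_over(rbinom(45, 1, 0.3), cov)
  m <- named_over(rnorm(45), cov)
  y <- named_over(rnorm(45), cov)
  p <- fit_paths(x, m, y, cov)
  expect_equal(p$c, p$c_prime + p$ab, tolerance = 1e-10)
})

test_that("a mediator unrelated to X and Y contributes no indirect effect", {
  set.seed(77)
  n <- 4000
  cov <- make_covariates(n)
  x <- named_over(rbinom(n, 1, 0.5), cov)
  y <- named_over(0.3 * x + rnorm(n), cov)
  m <- named_over(rnorm(n), cov)
  p <- fit_paths(x, m, y, cov)
  expect_lt(abs(p$a), 0.05)
  expect_lt(abs(p$ab), 0.02)
  expect_equal(p$c, p$c_prime, tolerance = 0.02)
})

test_that("bootstrap distributions are seeded and centered", {
  s <- simulate_triad_series(5)
  b1 <- bootstrap_paths(s$x, s$m, s$y, s$cov, n_resamples = 400, seed = 99)
  b2 <- bootstrap_paths(s$x, s$m, s$y, s$cov, n_resamples = 400, seed = 99)
  expect_identical(b1, b2)                       # bit-identical under a seed
  b3 <- bootstrap_paths(s$x, s$m, s$y, s$cov, n_resamples = 400, seed = 100)
  expect_false(identical(b1$draws, b3$draws))
  est <- fit_paths(s$x, s$m, s$y, s$cov)
  for (pp in c("a", "b", "c", "c_prime", "ab")) {
    se <- sd(b1$draws[, pp])
    expect_lt(abs(mean(b1$draws[, pp]) - est[[pp]]), 4 * se / sqrt(400) + 0.05)
  }
  expect_error(bootstrap_paths(s$x, s$m, s$y, s$cov, n_resamples = 100),
               "seed")
})

test_that("bootstrap spread matches the analytic OLS standard error", {
  set.seed(31)
  n <- 400
  cov <- make_covariates(n)
  x <- named_over(rbinom(n, 1, 0.4), cov)
  m <- named_over(-0.4 * x + rnorm(n), cov)
  y <- named_over(0.2 * x - 0.3 * m + rnorm(n), cov)
  b <- bootstrap_paths(x, m, y, cov, n_resamples = 800, seed = 17)
  d <- data.frame(x = zscore(x), m = zscore(m), y = zscore(y),
                  age = cov$age, gender = as.numeric(factor(cov$gender)) - 1)
  se_a <- summary(lm(m ~ gender + age + x, d))$coefficients["x", "Std. Error"]
  expect_lt(abs(sd(b$draws[, "a"]) / se_a - 1), 0.2)
})

test_that("BCa reduces to the percentile interval when z0 = accel = 0", {
  # symmetric bootstrap distribution with the estimate at the median and
  # perfectly symmetric jackknife values: z0 = 0 and accel = 0 exactly
  boot <- c(seq(-1, -0.01, length.out = 500), seq(0.01, 1, length.out = 500)) + 5
  jack <- c(seq(-1, 1, length.out = 20)) + 5
  res <- bca_interval(boot, point_estimate = 5, jackknife_estimates = jack,
                      alpha = 0.05)
  expect_equal(res$z0, 0)
  expect_equal(res$accel, 0)
  expect_equal(c(res$lower, res$upper),
               unname(quantile(boot, c(0.025, 0.975), type = 6)))
})

test_that("an all-positive indirect-effect distribution reports a p bound", {
  set.seed(4)
  boot <- rlnorm(1000, 0, 0.3)         # strictly positive
  jack <- rlnorm(30, 0, 0.1)
  est <- median(boot)
  res <- bca_interval(boot, est, jack)
  expect_true(res$p_bound)
  expect_equal(res$p, 2 / 1000)
  # degenerate: all resamples below the estimate is an error
  expect_error(bca_interval(boot, max(boot) + 1, jack), "one side")
})

test_that("mediation results are byte-identical under a fixed seed", {
  s <- simulate_triad_series(9)
  r1 <- mediate(s$x, s$m, s$y, s$cov, n_resamples = 1000, seed = 42)
  r2 <- mediate(s$x, s$m, s$y, s$cov, n_resamples = 1000, seed = 42)
  expect_identical(r1, r2)
  expect_error(mediate(s$x, s$m, s$y, s$cov, n_resamples = 500, seed = 1),
               "1000")
})

test_that("prerequisite gating reproduces the n.e. pattern", {
  # MA2-like data: strong genotype-to-mediator path, null mediator-to-
  # outcome path -> ab and c_prime are not evaluated
  set.seed(12)
  n <- 58
  cov <- make_covariates(n)
  x <- named_over(rbinom(n, 1, 0.5), cov)
  m <- named_over(-0.8 * x + 0.3 * rnorm(n), cov)
  y <- named_over(0.9 * x + 0.05 * rnorm(n), cov)  # strong c, b null given x
  r <- mediate(x, m, y, cov, n_resamples = 1000, seed = 8)
  pa <- r$paths
  expect_true(all(pa$evaluated[pa$parameter %in% c("a", "b", "c")]))
  expect_false(any(pa$evaluated[pa$parameter %in% c("ab", "c_prime")]))
  expect_true(all(is.na(pa$p[!pa$evaluated])))
  expect_true(is.na(r$proportion_mediated))
  # printing shows the n.e. markers
  out <- capture.output(print(r))
  expect_true(any(grepl("n.e.", out, fixed = TRUE)))
})

test_that("a well-powered mediation reports the proportion mediated", {
  # strong planted paths so prerequisites pass in a single draw
  found <- FALSE
  for (seed in c(3, 4, 5, 6, 8, 10)) {
    s <- simulate_triad_series(seed, a = -0.6, b = -0.45, c_prime = 0.25)
    r <- mediate(s$x, s$m, s$y, s$cov, n_resamples = 1000, seed = 21)
    pa <- r$paths
    if (!all(pa$evaluated)) next
    found <- TRUE
    est <- pa$estimate
    names(est) <- pa$parameter
    expect_equal(r$proportion_mediated,
                 100 * est[["ab"]] / est[["c"]], tolerance = 1e-10)
    expect_match(r$classification, "mediation")
    break
  }
  expect_true(found)
})

test_that("sign-inconsistent mediation suppresses the proportion", {
  # force ab and c of opposite sign with strong paths: a*b > 0, c' < 0
  set.seed(60)
  n <- 300
  cov <- make_covariates(n)
  x <- named_over(rbinom(n, 1, 0.5), cov)
  m <- named_over(0.7 * x + 0.5 * rnorm(n), cov)
  y <- named_over(-0.9 * x + 0.45 * m + 0.4 * rnorm(n), cov)
  r <- mediate(x, m, y, cov, n_resamples = 1000, seed = 3)
  if (all(r$paths$evaluated)) {
    expect_true(is.na(r$proportion_mediated))
    expect_match(r$proportion_note, "inconsistent")
  }
})

test_that("permutation p has the exact lower bound under perfect association", {
  set.seed(14)
  n <- 58
  cov <- make_covariates(n)
  x <- named_over(rnorm(n), cov)
  m <- named_over(x + 1e-8 * rnorm(n), cov)   # near-copy, below collinearity
  y <- named_over(rnorm(n), cov)
  expect_error(permutation_p(x, m, y, cov, path = "a", n_perm = 50, seed = 1),
               "100")
  # a perfect association is never beaten by a permutation
  m2 <- named_over(0.95 * x + 0.05 * rnorm(n), cov)
  p <- permutation_p(x, m2, y, cov, path = "a", n_perm = 199, seed = 2)
  expect_equal(p, 1 / 200)
})

test_that("permutation p-values are uniform under the null", {
  n_data <- 150
  pvals <- numeric(n_data)
  for (i in seq_len(n_data)) {
    set.seed(7000 + i)
    n <- 58
    cov <- make_covariates(n, seed = 7000 + i)
    x <- named_over(rbinom(n, 1, 0.4), cov)
    m <- named_over(rnorm(n), cov)
    y <- named_over(rnorm(n), cov)
    pvals[i] <- permutation_p(x, m, y, cov, path = "a", n_perm = 150,
                              seed = i)
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation and bootstrap BCa agree on moderately powered data", {
  n_data <- 30
  agree <- 0L
  for (i in seq_len(n_data)) {
    s <- simulate_triad_series(4000 + i, a = -0.5, b = -0.4, c_prime = 0.2)
    r <- mediate(s$x, s$m, s$y, s$cov, n_resamples = 1000, seed = 5)
    pb <- r$paths$p[r$paths$parameter == "a"]
    pp <- permutation_p(s$x, s$m, s$y, s$cov, path = "a", n_perm = 400,
                        seed = 5)
    if ((pb < 0.05) == (pp < 0.05)) agree <- agree + 1L
  }
  expect_gte(agree / n_data, 0.9)
})
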