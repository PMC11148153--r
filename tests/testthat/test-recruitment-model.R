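test_that("log-scale expected recruitment is the linear predictor", {
  expect_equal(log_expected_recruitment(1, 0, 0.5, 2), 0)
  expect_equal(log_expected_recruitment(2.3, 0.4, 0, 5), 2.7)
  expect_equal(log_expected_recruitment(3, -0.2, 1.1, 1.425), 1.2325)
  expect_error(log_expected_recruitment(1, 0, 1, -2), "non-negative")
})

test_that("negative-binomial log-pmf is a proper mean-dispersion NB", {
  # normalization over the (truncated) support
  y <- 0:10000
  expect_equal(sum(exp(negbin_logpmf(y, mu = 3, theta = 1.5))), 1,
               tolerance = 1e-9)
  # Poisson limit as theta -> Inf
  y <- 0:50
  expect_equal(negbin_logpmf(y, mu = 5, theta = 1e8),
               dpois(y, 5, log = TRUE), tolerance = 1e-4)
  # agreement with the reference density in its size/mu parameterization
  expect_equal(negbin_logpmf(0:40, mu = 7.3, theta = 0.42),
               dnbinom(0:40, size = 0.42, mu = 7.3, log = TRUE),
               tolerance = 1e-12)
  expect_error(negbin_logpmf(2.5, 3, 1), "non-negative integers")
  expect_error(negbin_logpmf(2, -3, 1), "positive")
})

test_that("simulated NB variance matches mu + mu^2/theta", {
  set.seed(77)
  draws <- rnbinom(1e6, size = 0.5, mu = 4)
  expect_equal(var(draws), 4 + 16 / 0.5, tolerance = 0.03)
})

test_that("log_posterior agrees with a straight-line dual implementation", {
  d <- tiny_recruitment_data()
  p <- tiny_params()
  pr <- prior_config()

  # independent brute-force evaluation, term by term, sharing no code with
  # the package implementation beyond base R densities
  brute <- 0
  for (s in c("A", "B")) {
    brute <- brute + dnorm(p$a[[s]], 0, 10, log = TRUE) +
      log(2) + dnorm(p$q[[s]], 0, 1.5, log = TRUE)
  }
  brute <- brute + log(2) + dnorm(p$sigma_a, 0, 2, log = TRUE) +
    log(2) + dnorm(p$theta, 0, 5, log = TRUE)
  for (g in names(p$a_dev)) {
    brute <- brute + dnorm(p$a_dev[[g]], 0, p$sigma_a, log = TRUE)
  }
  for (i in seq_len(nrow(d$obs))) {
    row <- d$obs[i, ]
    mu <- exp(p$a[[row$stream]] + p$a_dev[[row$group]] -
                p$q[[row$stream]] * row$effort)
    brute <- brute + dnbinom(row$index, size = p$theta, mu = mu, log = TRUE)
  }
  expect_equal(log_posterior(p, d, pr), brute, tolerance = 1e-10)
})

test_that("log_posterior is additive in observations and proper outside support", {
  d <- tiny_recruitment_data()
  p <- tiny_params()
  pr <- prior_config()
  lp <- log_posterior(p, d, pr)

  # duplicating one observation adds exactly its own log-pmf
  d2 <- d
  row <- d$obs[5, ]
  d2$obs <- rbind(d$obs, row)
  mu <- exp(p$a[[row$stream]] + p$a_dev[[row$group]] -
              p$q[[row$stream]] * row$effort)
  expect_equal(log_posterior(p, d2, pr), lp + negbin_logpmf(row$index, mu, p$theta),
               tolerance = 1e-10)

  # with no observations only priors and deviation densities remain
  d0 <- d
  d0$obs <- d$obs[0, ]
  expected <- sum(dnorm(p$a, 0, 10, log = TRUE)) +
    log(2) + dnorm(p$sigma_a, 0, 2, log = TRUE) +
    sum(log(2) + dnorm(p$q, 0, 1.5, log = TRUE)) +
    log(2) + dnorm(p$theta, 0, 5, log = TRUE) +
    sum(dnorm(p$a_dev, 0, p$sigma_a, log = TRUE))
  expect_equal(log_posterior(p, d0, pr), expected, tolerance = 1e-10)

  # out of support
  p2 <- p; p2$sigma_a <- -1
  expect_identical(log_posterior(p2, d, pr), -Inf)
  p3 <- p; p3$q["A"] <- -0.2
  expect_identical(log_posterior(p3, d, pr), -Inf)
  expect_gt(log_posterior(p3, d, prior_config(q = list("normal", mean = 0, sd = 1.5),
                                              q_signed = TRUE)), -Inf)
})

test_that("percent_reduction transforms mortality correctly", {
  expect_equal(percent_reduction(0, 1), 0)
  expect_equal(percent_reduction(log(2), 1), 50)
  expect_equal(percent_reduction(1.1087, 1), 67, tolerance = 0.05 / 67)
  # monotone in q and E; effort composes multiplicatively on survival
  set.seed(11)
  q <- sort(runif(30, 0, 3)); E <- sort(runif(30, 0, 3))
  expect_true(all(diff(percent_reduction(q, 1)) >= 0))
  expect_true(all(diff(percent_reduction(1, E)) >= 0))
  E1 <- runif(30, 0, 2); E2 <- runif(30, 0, 2)
  surv <- (1 - percent_reduction(q, E1) / 100) * (1 - percent_reduction(q, E2) / 100)
  expect_equal(percent_reduction(q, E1 + E2), 100 * (1 - surv), tolerance = 1e-12)
  expect_error(percent_reduction(-1, 1), "non-negative")
})

test_that("prior configuration validates families and supports", {
  pr <- prior_config()
  expect_s3_class(pr, "smr_priors")
  expect_error(prior_config(q = list("normal", mean = 0, sd = 1)), "q_signed")
  expect_error(prior_config(sigma_a = list("lognormal", sd = 1)), "family")
  expect_error(prior_config(theta = list("gamma", shape = 2)), "rate")

  tf <- tempfile(fileext = ".yaml")
  writeLines(c("q: {family: half-normal, sd: 0.7}",
               "theta: {family: gamma, shape: 2, rate: 0.5}"), tf)
  pry <- priors_from_yaml(tf)
  expect_equal(pry$q$sd, 0.7)
  expect_equal(pry$theta[[1]], "gamma")
  expect_equal(pry$a, pr$a)   # unspecified entries keep defaults
  unlink(tf)
})
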