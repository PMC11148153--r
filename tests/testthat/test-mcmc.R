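# half-normal CDF, used when comparing a posterior to its prior
phalfnorm <- function(x, sd) pmax(0, 2 * pnorm(x, 0, sd) - 1)

test_that("split_rhat matches a direct evaluation of the split-chain formula", {
  set.seed(31)
  m <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(m), 1.02)
  # construction lower bound: var_hat >= (n-1)/n * W
  expect_gte(split_rhat(m), sqrt(499 / 500))

  # direct formula evaluation on deliberately separated chains
  m2 <- cbind(rnorm(500, 0, 1), rnorm(500, 10, 1))
  halves <- cbind(m2[1:250, 1], m2[251:500, 1], m2[1:250, 2], m2[251:500, 2])
  n <- 250
  W <- mean(apply(halves, 2, var))
  B <- n * var(colMeans(halves))
  direct <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(split_rhat(m2), direct, tolerance = 1e-12)
  expect_gt(split_rhat(m2), 2)

  # splitting one stationary chain in half agrees with treating the halves
  # as separate chains
  x <- rnorm(1000)
  expect_equal(split_rhat(matrix(x, ncol = 1)),
               split_rhat(cbind(x[1:500], x[501:1000])), tolerance = 0.02)

  expect_true(is.na(split_rhat(matrix(1, 100, 4))))
  expect_error(split_rhat(matrix(1, 2, 2)), "4 draws")

  # independent reference on stationary chains: coda's PSRF on the pre-split
  # half-chains (coda adds a sampling-variability term and a df correction
  # that only matter far from stationarity, hence stationary data here)
  halves8 <- do.call(cbind, lapply(1:4, function(j) {
    cbind(m[1:500, j], m[501:1000, j])
  }))
  ref <- coda::gelman.diag(coda::mcmc.list(apply(halves8, 2, coda::mcmc,
                                                 simplify = FALSE)),
                           autoburnin = FALSE)$psrf[1]
  expect_equal(split_rhat(m), ref, tolerance = 0.02)
})

test_that("identical seeds give identical chains; different seeds differ", {
  d <- tiny_recruitment_data()
  f1 <- fit_mcmc(d, chains = 2, iter = 300, warmup = 150, seed = 5)
  f2 <- fit_mcmc(d, chains = 2, iter = 300, warmup = 150, seed = 5)
  f3 <- fit_mcmc(d, chains = 2, iter = 300, warmup = 150, seed = 6)
  expect_identical(f1$draws, f2$draws)
  expect_false(identical(f1$draws, f3$draws))
  expect_identical(f1$metadata$seed, 5L)
})

test_that("draw containers respect parameter constraints and shapes", {
  d <- tiny_recruitment_data()
  f <- fit_mcmc(d, chains = 2, iter = 400, warmup = 200, seed = 9)
  m <- as.matrix(f)
  expect_equal(nrow(m), 2 * 200)
  expect_true(all(m[, "sigma_a"] > 0))
  expect_true(all(m[, "theta"] > 0))
  expect_true(all(m[, grep("^q\\[", colnames(m))] >= 0))
  expect_equal(length(f$rhat), dim(f$draws)[3])
  # effect summary endpoints are the percentiles of the transformed draws
  eff <- summarize_effect(f, E = 1)
  qa <- percent_reduction(posterior_draws(f, "q[A]"), 1)
  expect_equal(unlist(eff[eff$stream == "A", c("lower95", "median", "upper95")],
                      use.names = FALSE),
               unname(quantile(qa, c(0.025, 0.5, 0.975))))
  expect_error(posterior_draws(f, "nope"), "unknown parameter")
})

test_that("posterior mean of q matches a grid-integration oracle on the sub-model", {
  # single stream, year deviations off, sigma/theta pinned: the posterior is
  # a 2-parameter density p(a, q | y) that a fine quadrature grid integrates
  set.seed(204)
  theta0 <- 1.2
  E <- c(0, 0, 1, 1.4, 0, 1)
  years <- 2015:2020
  mu_true <- exp(4 - 0.8 * E)
  surveys <- do.call(rbind, lapply(seq_along(E), function(i) {
    data.frame(stream = "S1", year = years[i] + 1, month = 6,
               site = paste0("s", 1:10),
               density_per_m2 = rnbinom(10, size = theta0, mu = mu_true[i]) / 1000)
  }))
  releases <- data.frame(stream = "S1", spawning_year = years,
                         sterile_released = E * 1000)
  d <- recruitment_data(surveys, releases)

  pr <- prior_config()
  loglik_aq <- function(a, q) {
    ll <- 0
    for (g in seq_along(E)) {
      y <- d$obs$index[d$obs$year == years[g] + 1]
      ll <- ll + sum(dnbinom(y, size = theta0, mu = exp(a - q * E[g]),
                             log = TRUE))
    }
    ll + dnorm(a, 0, 10, log = TRUE) + log(2) + dnorm(q, 0, 1.5, log = TRUE)
  }
  a_grid <- seq(3.0, 5.0, length.out = 220)
  q_grid <- seq(1e-5, 4, length.out = 260)
  lg <- outer(a_grid, q_grid, Vectorize(loglik_aq))
  w <- exp(lg - max(lg))
  q_mean_grid <- sum(w %*% diag(q_grid)) / sum(w)

  f <- fit_mcmc(d, pr, chains = 4, iter = 3000, warmup = 1000, seed = 42,
                fix = list(sigma_a = 1, theta = theta0, a_dev_zero = TRUE))
  qd <- posterior_draws(f, "q[S1]")
  # Monte-Carlo standard error by batch means within chains
  per_chain <- matrix(qd, ncol = 4)
  bm <- apply(per_chain, 2, function(ch) {
    colMeans(matrix(ch, nrow = 100))  # 20 batches of 100
  })
  mcse <- sd(as.vector(bm)) / sqrt(length(bm))
  expect_lt(abs(mean(qd) - q_mean_grid), 3 * mcse + 1e-9)
  # pinned parameters stay pinned
  expect_true(all(posterior_draws(f, "theta") == theta0))
  expect_true(all(posterior_draws(f, "a_dev[S1 2016]") == 0))
})

test_that("q is not spuriously identified from a single year per stream", {
  # one stream-year each: effort and mean recruitment are confounded, so the
  # marginal posterior of q must collapse to its prior
  set.seed(88)
  surveys <- do.call(rbind, lapply(c("A", "B"), function(s) {
    data.frame(stream = s, year = 2019, month = 6, site = paste0("s", 1:12),
               density_per_m2 = rnbinom(12, size = 0.8, mu = 150) / 1000)
  }))
  releases <- data.frame(stream = c("A", "B"), spawning_year = 2018,
                         sterile_released = c(1000, 800))
  d <- recruitment_data(surveys, releases)
  f <- fit_mcmc(d, chains = 4, iter = 2000, warmup = 1000, seed = 13)
  qd <- posterior_draws(f, "q[A]")
  ks <- max(abs(ecdf(qd)(sort(qd)) - phalfnorm(sort(qd), 1.5)))
  expect_lt(ks, 0.1)
})

test_that("initialization failure surfaces as an error, not a hang", {
  d <- tiny_recruitment_data()
  # an impossible prior support: uniform far from any feasible a
  pr <- prior_config(a = list("uniform", min = 500, max = 501))
  expect_error(fit_mcmc(d, pr, chains = 1, iter = 100, warmup = 50, seed = 1,
                        init_retries = 3),
               "initialization error")
})
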