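test_that("simulate_trapping is exact at full capture and seed-stable", {
  ts <- simulate_trapping(100, 1000, capture_prob = 1, seed = 3)
  expect_equal(ts$sterile_recaptured, 1000)
  expect_equal(ts$wild_captured, 100)
  expect_identical(simulate_trapping(50, 500, 0.3, seed = 12),
                   simulate_trapping(50, 500, 0.3, seed = 12))
})

test_that("simulate_eggs reproduces the accounting arithmetic in expectation", {
  set.seed(61)
  reps <- replicate(1e4, simulate_eggs(10, 6)$eggs_before)
  expect_equal(mean(reps), 10 * 0.5 * 51000, tolerance = 0.02)

  set.seed(62)
  frac <- replicate(1e4, {
    e <- simulate_eggs(10, 6)
    if (e$eggs_before > 0) e$eggs_after / e$eggs_before else NA
  })
  expect_equal(mean(frac, na.rm = TRUE), 1 / 6, tolerance = 0.02)

  # limits: no sterile males / infinitely many
  e0 <- simulate_eggs(10, 0, seed = 63)
  expect_equal(e0$eggs_after, e0$eggs_before)
  expect_equal(simulate_eggs(10, Inf, seed = 63)$eggs_after, 0)

  # fecundity draws respect the published range
  set.seed(64)
  e <- simulate_eggs(1000, 0)
  expect_true(e$eggs_before / 500 > 3100 && e$eggs_before / 500 < 72000)
})

test_that("simulate_recruitment realizes the process model", {
  # survival factor: mean index under E=1 vs E=0 is e^(-q)
  cfg <- simulation_config(
    streams = "S", years = 2000:2001, a_s = 5, sigma_a = 1e-8, q_s = 1.1,
    theta = 50, surveys_per_stream_year = 10000,
    release_schedule = data.frame(stream = "S", spawning_year = 2000:2001,
                                  sterile_released = c(0, 1000)),
    seed = 90)
  set.seed(90)
  sv <- simulate_recruitment(cfg)
  idx <- round_half_away(sv$density_per_m2 * 1000)
  m0 <- mean(idx[sv$year == 2001]); m1 <- mean(idx[sv$year == 2002])
  expect_equal(m1 / m0, exp(-1.1), tolerance = 0.03)

  # overdispersion: sample variance matches mu + mu^2/theta
  cfg2 <- simulation_config(
    streams = "S", years = 2000, a_s = log(50), sigma_a = 1e-8, q_s = 0,
    theta = 0.5, surveys_per_stream_year = 1e5,
    release_schedule = data.frame(stream = "S", spawning_year = 2000,
                                  sterile_released = 0),
    seed = 91)
  set.seed(91)
  idx2 <- round_half_away(simulate_recruitment(cfg2)$density_per_m2 * 1000)
  expect_equal(var(idx2), 50 + 2500 / 0.5, tolerance = 0.05)

  # null model: with q = 0 release years are indistinguishable
  cfg3 <- simulation_config(
    streams = "S", years = 2000:2001, a_s = 5, sigma_a = 1e-8, q_s = 0,
    theta = 1, surveys_per_stream_year = 2000,
    release_schedule = data.frame(stream = "S", spawning_year = 2000:2001,
                                  sterile_released = c(0, 1000)),
    seed = 92)
  set.seed(92)
  sv3 <- simulate_recruitment(cfg3)
  ks <- suppressWarnings(ks.test(sv3$density_per_m2[sv3$year == 2001],
                                 sv3$density_per_m2[sv3$year == 2002]))
  expect_gt(ks$p.value, 0.01)
})

test_that("bundles are deterministic per seed and internally consistent", {
  cfg <- simulation_config(seed = 123, surveys_per_stream_year = 5)
  d1 <- file.path(tempdir(), "b1"); d2 <- file.path(tempdir(), "b2")
  b1 <- generate_bundle(cfg, d1)
  b2 <- generate_bundle(cfg, d2)
  for (f in c("trap_seasons.csv", "larval_surveys.csv", "releases.csv",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  b3 <- generate_bundle(simulation_config(seed = 124,
                                          surveys_per_stream_year = 5))
  expect_false(identical(b1$larval_surveys$density_per_m2,
                         b3$larval_surveys$density_per_m2))

  # all generated counts are non-negative integers; CSVs re-read losslessly
  ts <- read_trap_seasons(file.path(d1, "trap_seasons.csv"))
  expect_true(all(ts$sterile_recaptured <= ts$sterile_released))
  expect_equal(as.data.frame(ts)[names(b1$trap_seasons)],
               as.data.frame(b1$trap_seasons))
  rel <- read_releases(file.path(d1, "releases.csv"))
  expect_equal(rel, b1$releases)

  # generated files feed both pipeline stages without modification
  a <- assess_table(ts)
  expect_s3_class(a, "smr_assessment")
  d <- recruitment_data(read_larval_surveys(file.path(d1, "larval_surveys.csv")),
                        rel)
  expect_equal(nrow(d$obs), nrow(b1$larval_surveys))

  # truth.json round-trips to the identical generating config
  cfg2 <- config_from_truth(file.path(d1, "truth.json"))
  expect_equal(unclass(cfg2), unclass(cfg))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("assessment of simulated seasons recovers the generating reduction", {
  # equal catchability cancels out of the ratio, so the generating
  # sterile:wild-male ratio is M / (N * (1 - p_female)) = 1000 / 20 = 50 and
  # the mean assessed egg reduction should match 100 * (1 - 1/50) = 98
  set.seed(55)
  red <- replicate(300, {
    ts <- simulate_trapping(40, 1000, 0.25)
    assess_table(ts)$egg_reduction_pct
  })
  expect_equal(mean(red, na.rm = TRUE), 98, tolerance = 0.01)
})

test_that("simulation_config validates its invariants", {
  expect_error(simulation_config(), "seed is mandatory")
  expect_error(simulation_config(seed = 1, capture_prob = 0), "capture_prob")
  expect_error(simulation_config(seed = 1, sigma_a = -1), "positive")
  expect_error(simulation_config(seed = 1, q_s = -0.1), "non-negative")
})
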