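test_that("propensity follows mass-action combinatorics", {
  # toggle-switch cross-binding: c = 0.2, A = 10, ProB = 1, *ProA = 1
  r <- reaction(data.frame(species = c("A", "ProB", "ProA"), stoich = 1L,
                           consumed = c(TRUE, TRUE, FALSE)),
                data.frame(species = "ProB.A", stoich = 1L), 0.2)
  expect_equal(propensity(r, c(A = 10, ProB = 1, ProA = 1)), 2.0)
  expect_equal(propensity(r, c(A = 10, ProB = 0, ProA = 1)), 0)

  dimer <- reaction(data.frame(species = "X", stoich = 2L, consumed = TRUE),
                    data.frame(species = "Y", stoich = 1L), 0.3)
  for (n in c(0, 1, 2, 7))
    expect_equal(propensity(dimer, c(X = n, Y = 0)), 0.3 * n * (n - 1) / 2)
})

test_that("sample_delay honours each delay law", {
  expect_equal(sample_delay(delay_spec("constant", value = 5), 10), rep(5, 10))
  expect_equal(sample_delay(delay_spec("none"), 3), rep(0, 3))

  set.seed(1)
  d <- sample_delay(delay_spec("gamma", shape = 4, scale = 2), 1e5)
  se <- sqrt(4 * 2^2 / 1e5)          # gamma sd / sqrt(n)
  expect_lt(abs(mean(d) - 8), 3 * se)

  set.seed(2)
  g <- sample_delay(delay_spec("gaussian", mean = -1, sd = 0.1), 500)
  expect_true(all(g >= 0))            # truncation contract

  expect_error(delay_spec("gamma", shape = -1, scale = 1), "> 0")
  expect_error(delay_spec("constant"), "requires")
})

test_that("forced wait-list release advances time when propensity is zero", {
  sys <- reaction_system(
    data.frame(name = "X", count = 0L),
    waitlist = data.frame(species = "X", count = 1L, release_time = 7))
  cfg <- sim_config(stop_time = 10, readout_interval = 1, seed = 1)
  res <- suppressMessages(simulate_system(sys, cfg))
  expect_equal(unname(res$counts["X", ]),
               c(rep(0L, 7), rep(1L, 4)))  # 1 from the t = 7 snapshot on
})

test_that("inter-event gaps of a pure birth process are exponential", {
  k <- 5
  sys <- parse_reactions(c("species X = 0", sprintf(" --[%g]--> X", k)))
  cfg <- sim_config(stop_time = 2500, readout_interval = 2500, seed = 3)
  res <- simulate_system(sys, cfg, log_events = TRUE)
  gaps <- diff(res$events$time)
  n <- length(gaps)
  expect_gt(n, 1e4)
  expect_lt(abs(mean(gaps) - 1 / k), 3 * (1 / k) / sqrt(n))
})

test_that("releases come off the wait list in non-decreasing time order", {
  sys <- birth_death_system(10, 1, "(gamma:2,1)")
  cfg <- sim_config(stop_time = 40, readout_interval = 40, seed = 4)
  res <- simulate_system(sys, cfg, log_events = TRUE)
  rel <- res$events[res$events$kind == "release", ]
  expect_gt(nrow(rel), 100)
  expect_true(all(diff(rel$time) >= 0))
  # every release happens after its producing reaction fired
  expect_true(all(rel$time <= cfg$stop_time))
})

test_that("nothing appears before a constant production delay", {
  d <- 20
  sys <- birth_death_system(10, 0, sprintf("(%d)", d))
  sys$reactions <- sys$reactions[1L]      # drop the zero-rate decay
  cfg <- sim_config(stop_time = 30, readout_interval = 2, seed = 5)
  res <- simulate_system(sys, cfg)
  expect_true(all(res$counts["X", res$times < d] == 0L))
  expect_gt(res$counts["X", length(res$times)], 0L)
})

test_that("deadlock fast-forwards to stop_time with a notice", {
  sys <- reaction_system(data.frame(name = "X", count = 2L))
  cfg <- sim_config(stop_time = 5, readout_interval = 1, seed = 1)
  expect_message(res <- simulate_system(sys, cfg), "deadlock")
  expect_true(res$deadlock)
  expect_equal(unname(res$counts["X", ]), rep(2L, 6))
})

test_that("a fixed seed gives bit-identical trajectories", {
  sys <- compile_network(worked_example_network(),
                         rates = rate_params(transcription = 0.5,
                                             binding = 0.01))
  cfg <- sim_config(stop_time = 200, readout_interval = 10, seed = 42)
  a <- simulate_system(sys, cfg, log_events = TRUE)
  b <- simulate_system(sys, cfg, log_events = TRUE)
  expect_identical(a$counts, b$counts)
  expect_identical(a$events, b$events)
})

test_that("gamma-delayed production leaves the stationary mean in place", {
  # small-n sanity check; the full-size version lives in test-acceptance.R
  cfg <- sim_config(stop_time = 50, readout_interval = 25, seed = 6,
                    sample = 150)
  m <- suppressMessages(run_ensemble(birth_death_system(10, 1, "(gamma:2,1)"),
                                     cfg))
  expect_lt(abs(mean(m) - 10), 3 * sqrt(10 / 150))
})

test_that("counts never go negative along an audited trajectory", {
  sys <- parse_reactions(c("species X = 3", "2 X --[0.4]--> X",
                           "X --[0.3]--> ", " --[2]--> X"))
  cfg <- sim_config(stop_time = 100, readout_interval = 1, seed = 7)
  res <- simulate_system(sys, cfg)
  expect_true(all(res$counts >= 0L))
})
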