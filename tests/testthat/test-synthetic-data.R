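test_that("dwell sampler matches the closed-form discretized law", {
  # b = 1: memoryless case, analytic mean of ceil(min_dwell + Exp(tau))
  d <- sample_stretched_exp_durations(1, 5, 1e4, seed = 1)
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - discretized_exponential_mean(5)), 3 * se)

  # b = 0.5: KS distance at the integer support against the incomplete-gamma
  # oracle CDF
  d <- sample_stretched_exp_durations(0.5, 5, 1e4, seed = 11)
  ks <- sort(unique(d))
  expect_lt(max(abs(stats::ecdf(d)(ks) - stretched_cdf_truncated(ks, 0.5, 5))),
            0.02)

  # determinism and domain
  expect_identical(sample_stretched_exp_durations(0.3, 4, 50, seed = 3),
                   sample_stretched_exp_durations(0.3, 4, 50, seed = 3))
  expect_true(all(sample_stretched_exp_durations(0.3, 4, 100, seed = 2) >= 1))
  expect_error(sample_stretched_exp_durations(0, 4, 10), "b must be")
  expect_error(sample_stretched_exp_durations(1.2, 4, 10), "b must be")
  expect_error(sample_stretched_exp_durations(0.5, -1, 10), "tau")
  expect_error(sample_stretched_exp_durations(0.5, Inf, 10), "tau")
})

test_that("smaller stretching exponents give heavier dwell tails", {
  ratios <- vapply(1:10, function(s) {
    d03 <- sample_stretched_exp_durations(0.3, 5, 1e4, seed = s)
    d10 <- sample_stretched_exp_durations(1, 5, 1e4, seed = s + 100)
    r03 <- unname(stats::quantile(d03, 0.99) / stats::median(d03))
    r10 <- unname(stats::quantile(d10, 0.99) / stats::median(d10))
    r03 / r10
  }, 0)
  expect_true(all(ratios > 1))
})

test_that("behavior series satisfy the construction invariants", {
  for (s in 1:5) {
    p <- behavior_gen_params(session_length = 50)
    x <- generate_behavior_series(p, seed = s)
    expect_length(x, 50)
    expect_true(all(x %in% 1:3))
    r <- rle(x)
    if (length(r$values) > 1)
      expect_true(all(diff(r$values) != 0))
  }
  p <- behavior_gen_params(dwell_form = "markov", timescale_tau = 4)
  expect_identical(generate_behavior_series(p, seed = 9),
                   generate_behavior_series(p, seed = 9))
  # biased transition weights: from any state, next state follows the weights
  p <- behavior_gen_params(transition_weights = c(1, 0), session_length = 300)
  x <- generate_behavior_series(p, seed = 4)
  r <- rle(x)$values
  # with weight 0 on the higher-numbered alternative: 1 -> 2, 2 -> 1, 3 -> 1
  for (i in seq_len(length(r) - 1))
    expect_equal(r[i + 1], c(2, 1, 1)[r[i]])
})

test_that("markov dwell times follow the discretized exponential", {
  tau <- 4
  p <- behavior_gen_params(dwell_form = "markov", timescale_tau = tau,
                           session_length = 1200)
  dwells <- unlist(lapply(1:200, function(s) {
    r <- rle(generate_behavior_series(p, seed = s))
    r$lengths[-length(r$lengths)]     # drop the boundary-truncated final run
  }))
  kmax <- 30
  expect_true(all(dwells >= 2))       # ceil of support [1, Inf) has no mass at 1
  obs <- tabulate(pmin(dwells, kmax + 1), nbins = kmax + 1)[-1]
  pr <- stretched_ceil_pmf(2:kmax, 1, tau)
  pr <- c(pr, 1 - sum(pr))            # tail bin
  gof <- suppressWarnings(stats::chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("stretched dwell times are heavy-tailed in sessions", {
  tau <- 4
  p <- behavior_gen_params(exponent_b = 0.3, timescale_tau = tau,
                           session_length = 1200)
  longest <- max(unlist(lapply(1:100, function(s)
    rle(generate_behavior_series(p, seed = s))$lengths)))
  expect_gte(longest, 5 * tau)
})

test_that("emotion generator is deterministic, bounded, and centered", {
  p <- emotion_gen_params(increment_sd = 5, start_value = 561,
                          session_length = 1200)
  expect_identical(generate_emotion_series(p, seed = 2),
                   generate_emotion_series(p, seed = 2))
  for (s in 1:5) {
    x <- generate_emotion_series(p, seed = s)
    expect_true(all(x >= 0 & x <= 1123))
    expect_true(is.integer(x))
  }
  # forced saturation still respects bounds
  ps <- emotion_gen_params(increment_sd = 400, start_value = 100,
                           bounds = c(0, 200), session_length = 300)
  x <- generate_emotion_series(ps, seed = 1)
  expect_true(all(x >= 0 & x <= 200))
  expect_true(any(x %in% c(0, 200)))  # the walk actually hits the edges
  # pre-clipping increments: mean within 3 SE of 0, over 20 seeds
  inc <- unlist(lapply(1:20, function(s) conflictdyn:::emotion_increments(p, s)))
  expect_lt(abs(mean(inc)), 3 * stats::sd(inc) / sqrt(length(inc)))
  # lag-1 autocorrelation of Brownian increments near 0
  ac <- mean(vapply(1:20, function(s) {
    z <- conflictdyn:::emotion_increments(p, s)
    stats::cor(z[-1], z[-length(z)])
  }, 0))
  expect_lt(abs(ac), 3 / sqrt(20 * 1199))
})

test_that("fGn generator reproduces the target autocovariance", {
  for (H in c(0.3, 0.8)) {
    rho1 <- mean(vapply(1:20, function(s) {
      z <- fgn_sim(4096, H, seed = s)
      stats::cor(z[-1], z[-length(z)])
    }, 0))
    expect_lt(abs(rho1 - (2^(2 * H - 1) - 1)), 0.03)
  }
  z <- fgn_sim(1024, 0.7, seed = 4)
  expect_identical(z, fgn_sim(1024, 0.7, seed = 4))
  expect_lt(abs(stats::sd(z) - 1), 0.15)
  expect_error(fgn_sim(1024, 1.2), "H must be")
})

test_that("study generation respects counts, missingness, and seeds", {
  cfg <- study_gen_config(missing_person_rate = 0, master_seed = 3)
  study <- generate_study(cfg)
  expect_length(study$records, 46)     # 11 + 12 dyads x 2 persons
  groups <- vapply(study$records, function(r) r$group, "")
  expect_equal(sum(groups == "intractable"), 22)
  expect_equal(sum(groups == "tractable"), 24)

  none <- generate_study(study_gen_config(missing_person_rate = 1))
  expect_length(none$records, 0)

  some <- generate_study(study_gen_config(master_seed = 3))
  expect_lte(length(some$records), 46)

  expect_identical(generate_study(cfg)$records, study$records)
  # appending dyads must not perturb existing persons
  bigger <- generate_study(study_gen_config(n_tractable_dyads = 13,
                                            missing_person_rate = 0,
                                            master_seed = 3))
  expect_identical(bigger$records[[1]], study$records[[1]])
  expect_identical(bigger$records[[46]], study$records[[46]])
})
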