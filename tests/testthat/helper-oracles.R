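# Closed-form oracles, independent of the package's numerically tabulated
# CDFs: everything here goes through the upper incomplete gamma function.

# int_t^Inf exp(-(u/tau)^b) du = (tau/b) * Gamma(1/b, (t/tau)^b)
stretched_tail_integral <- function(t, b, tau) {
  (tau / b) * gamma(1 / b) * stats::pgamma((t / tau)^b, 1 / b, lower.tail = FALSE)
}

# CDF of the continuous law truncated to [min_dwell, Inf)
stretched_cdf_truncated <- function(t, b, tau, min_dwell = 1) {
  1 - stretched_tail_integral(t, b, tau) /
    stretched_tail_integral(min_dwell, b, tau)
}

# pmf of ceil(T), T ~ truncated stretched exponential: mass of (k-1, k]
stretched_ceil_pmf <- function(k, b, tau, min_dwell = 1) {
  lo <- pmax(k - 1, min_dwell)
  (stretched_tail_integral(lo, b, tau) - stretched_tail_integral(k, b, tau)) /
    stretched_tail_integral(min_dwell, b, tau)
}

# mean of ceil(1 + Exp(rate = 1/tau)): 1 + 1 / (1 - exp(-1/tau))
discretized_exponential_mean <- function(tau, min_dwell = 1) {
  min_dwell + 1 / (1 - exp(-1 / tau))
}

# small synthetic study used by io/pipeline tests
make_tiny_study <- function(seed = 5, n_dyads = 2, session_length = 400,
                            missing_rate = 0) {
  cfg <- study_gen_config(
    n_intractable_dyads = n_dyads, n_tractable_dyads = n_dyads,
    behavior_params = behavior_gen_params(session_length = session_length),
    emotion_params = emotion_gen_params(session_length = session_length),
    missing_person_rate = missing_rate, master_seed = seed)
  generate_study(cfg)
}
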