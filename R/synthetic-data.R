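#' Parameters for the semi-Markov behavior generator
#'
#' Describes how a synthetic per-second behavior stream (state codes 1 =
#' proself, 2 = neutral, 3 = prosocial) is generated: a semi-Markov chain
#' whose dwell times in each state are drawn from either a discretized
#' single exponential (`dwell_form = "markov"`, the memoryless null) or a
#' discretized stretched exponential with survival
#' \eqn{\exp(-(t/\tau)^b)} (`dwell_form = "stretched"`, switching rate
#' falling with time already spent in the state).
#'
#' @param dwell_form `"stretched"` or `"markov"` (the latter is the b = 1
#'   special case).
#' @param exponent_b Stretching exponent in (0, 1]; smaller values mean a
#'   heavier tail and longer behavioral "memory". Default 0.3, the pooled
#'   estimate scale typical of conflict-conversation dwell times.
#' @param timescale_tau Dwell time scale in seconds (> 0); the reciprocal
#'   rate in the form A exp(-(a t)^b), a = 1/tau. With b well below 1 the
#'   mean dwell is much longer than tau; the default 0.2 yields a mean
#'   dwell of about 9 s at b = 0.3, i.e. roughly 135 state switches in a
#'   twenty-minute session.
#' @param transition_weights Non-negative weights, length 2, giving the
#'   relative probability of switching to each of the other two states (in
#'   ascending state order). Default uniform.
#' @param session_length Session length in seconds (default 1200, a
#'   twenty-minute conversation).
#' @param min_dwell Lower support bound of the dwell-time density, seconds.
#' @return An object of class `behavior_gen_params`.
#' @seealso [generate_behavior_series()], [sample_stretched_exp_durations()]
#' @export
behavior_gen_params <- function(dwell_form = c("stretched", "markov"),
                                exponent_b = 0.3,
                                timescale_tau = 0.2,
                                transition_weights = c(1, 1),
                                session_length = 1200,
                                min_dwell = 1) {
  dwell_form <- match.arg(dwell_form)
  if (!is_scalar_num(exponent_b) || exponent_b <= 0 || exponent_b > 1)
    stop("exponent_b must be a finite number in (0, 1]")
  if (!is_scalar_num(timescale_tau) || timescale_tau <= 0)
    stop("timescale_tau must be a finite positive number")
  if (!is.numeric(transition_weights) || length(transition_weights) != 2L ||
      any(!is.finite(transition_weights)) || any(transition_weights < 0) ||
      sum(transition_weights) == 0)
    stop("transition_weights must be two nonnegative weights, not all zero")
  if (!is_count(session_length) || session_length < 1)
    stop("session_length must be an integer >= 1")
  if (!is_scalar_num(min_dwell) || min_dwell <= 0)
    stop("min_dwell must be a finite positive number")
  structure(list(dwell_form = dwell_form,
                 exponent_b = exponent_b,
                 timescale_tau = timescale_tau,
                 transition_weights = as.numeric(transition_weights),
                 session_length = as.integer(session_length),
                 min_dwell = min_dwell),
            class = "behavior_gen_params")
}

#' Parameters for the bounded random-walk emotion generator
#'
#' Describes a synthetic emotional-valence trace in the "mouse paradigm"
#' convention: integer pixel positions on a horizontal screen axis from 0
#' (maximally negative) to 1123 (maximally positive), recorded once per
#' second. With `hurst_target = 0.5` the trace is a saturating bounded
#' random walk (iid Gaussian increments); other targets use fractional
#' Gaussian noise increments with that Hurst index.
#'
#' @param increment_sd Standard deviation of the per-second increment, in
#'   pixels (> 0).
#' @param start_value Starting pixel, within `bounds`. Default 561
#'   (mid-scale, emotionally neutral).
#' @param bounds Inclusive pixel range; default `c(0, 1123)`.
#' @param hurst_target Hurst index of the increment process in (0, 1);
#'   0.5 gives uncorrelated (ordinary Brownian) increments.
#' @param session_length Trace length in seconds.
#' @return An object of class `emotion_gen_params`.
#' @seealso [generate_emotion_series()]
#' @export
emotion_gen_params <- function(increment_sd = 10,
                               start_value = 561,
                               bounds = c(0, 1123),
                               hurst_target = 0.5,
                               session_length = 1200) {
  if (!is_scalar_num(increment_sd) || increment_sd <= 0)
    stop("increment_sd must be a finite positive number")
  if (!is.numeric(bounds) || length(bounds) != 2L || any(!is.finite(bounds)) ||
      bounds[1] >= bounds[2])
    stop("bounds must be two finite increasing numbers")
  if (!is_scalar_num(start_value) || start_value < bounds[1] || start_value > bounds[2])
    stop("start_value must lie within bounds")
  if (!is_scalar_num(hurst_target) || hurst_target <= 0 || hurst_target >= 1)
    stop("hurst_target must be in (0, 1)")
  if (!is_count(session_length) || session_length < 1)
    stop("session_length must be an integer >= 1")
  structure(list(increment_sd = increment_sd,
                 start_value = start_value,
                 bounds = as.numeric(bounds),
                 hurst_target = hurst_target,
                 session_length = as.integer(session_length)),
            class = "emotion_gen_params")
}

#' Configuration for a whole synthetic study
#'
#' Assembles the study shape: a number of intractable and tractable dyads of
#' two persons each, per-group behavior and emotion generator parameters,
#' and an occasional missing person (a person-record dropped entirely, as
#' happens with technical recording failures).
#'
#' @param n_intractable_dyads,n_tractable_dyads Dyad counts (defaults 11
#'   and 12, the two extreme outcome groups of the emulated study design).
#' @param behavior_params Either one [behavior_gen_params()] used for both
#'   groups or a list with elements `intractable` and `tractable`.
#' @param emotion_params As `behavior_params`, for [emotion_gen_params()].
#' @param missing_person_rate Probability that a person-record is absent.
#'   Default 0.04 (about 2 in 46).
#' @param master_seed Integer master seed; per-person seeds are derived
#'   deterministically from it so adding dyads never perturbs existing ones.
#' @return An object of class `study_gen_config`.
#' @seealso [generate_study()]
#' @export
study_gen_config <- function(n_intractable_dyads = 11,
                             n_tractable_dyads = 12,
                             behavior_params = behavior_gen_params(),
                             emotion_params = emotion_gen_params(),
                             missing_person_rate = 0.04,
                             master_seed = 1L) {
  if (!is_count(n_intractable_dyads) || !is_count(n_tractable_dyads))
    stop("dyad counts must be nonnegative integers")
  if (!is_scalar_num(missing_person_rate) ||
      missing_person_rate < 0 || missing_person_rate > 1)
    stop("missing_person_rate must be in [0, 1]")
  as_group_list <- function(p, cls) {
    if (inherits(p, cls)) p <- list(intractable = p, tractable = p)
    if (!is.list(p) || !all(c("intractable", "tractable") %in% names(p)) ||
        !inherits(p$intractable, cls) || !inherits(p$tractable, cls))
      stop("group parameters must be a ", cls,
           " or a list with elements 'intractable' and 'tractable'")
    p
  }
  structure(list(n_intractable_dyads = as.integer(n_intractable_dyads),
                 n_tractable_dyads = as.integer(n_tractable_dyads),
                 behavior_params = as_group_list(behavior_params, "behavior_gen_params"),
                 emotion_params = as_group_list(emotion_params, "emotion_gen_params"),
                 missing_person_rate = missing_person_rate,
                 master_seed = as.integer(master_seed)),
            class = "study_gen_config")
}

#' Sample integer dwell times from a (stretched) exponential density
#'
#' Draws dwell durations whose continuous density is proportional to
#' \eqn{\exp(-(t/\tau)^b)} on `t >= min_dwell`, by inverse transform on a
#' numerically tabulated CDF, then rounded up to whole seconds (matching the
#' 1 Hz coding resolution of the behavior streams). `b = 1` reduces to the
#' memoryless single exponential; `b < 1` produces the heavy-tailed dwell
#' times characteristic of state-switching with memory.
#'
#' @param b Stretching exponent in (0, 1].
#' @param tau Time scale in seconds (> 0).
#' @param n Number of durations to draw.
#' @param min_dwell Lower support bound (seconds, > 0; default 1).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Integer vector of `n` durations (seconds).
#' @examples
#' d <- sample_stretched_exp_durations(0.5, 5, 100, seed = 1)
#' range(d)
#' @export
sample_stretched_exp_durations <- function(b, tau, n, min_dwell = 1, seed = NULL) {
  if (!is_scalar_num(b) || b <= 0 || b > 1) stop("b must be in (0, 1]")
  if (!is_scalar_num(tau) || tau <= 0) stop("tau must be a finite positive number")
  if (!is_count(n) || n < 1) stop("n must be an integer >= 1")
  if (!is_scalar_num(min_dwell) || min_dwell <= 0) stop("min_dwell must be positive")
  inv <- stretched_quantile_table(b, tau, min_dwell)
  u <- with_seed(seed, stats::runif(n))
  t_cont <- stats::approx(inv$p, inv$t, xout = u, rule = 2)$y
  as.integer(ceiling(t_cont))
}

# Tabulate the truncated stretched-exponential CDF on a fine log-spaced grid
# and return it in quantile orientation (p -> t). Trapezoidal integration;
# the grid reaches the point where the survival is ~exp(-45).
stretched_quantile_table <- function(b, tau, min_dwell, n_grid = 32768L) {
  t_max <- tau * 45^(1 / b)
  tt <- exp(seq(log(min_dwell), log(t_max), length.out = n_grid))
  dens <- exp(-(tt / tau)^b)
  cdf <- c(0, cumsum(diff(tt) * (dens[-1] + dens[-n_grid]) / 2))
  cdf <- cdf / cdf[n_grid]
  keep <- c(TRUE, diff(cdf) > 0)  # drop flat tail so approx() sees a function
  list(p = cdf[keep], t = tt[keep])
}

#' Generate a per-second behavior state series
#'
#' Simulates a semi-Markov chain over states \{1, 2, 3\}: dwell times are
#' drawn from the configured family ([sample_stretched_exp_durations()]),
#' and at each switch the next state is drawn among the other two states
#' with the configured weights, so no two adjacent runs share a state. The
#' final run is truncated at the session boundary.
#'
#' @param params A [behavior_gen_params()] object.
#' @param seed Optional integer seed (same seed, same output).
#' @return Integer vector of length `params$session_length` with values in
#'   \{1, 2, 3\}.
#' @export
generate_behavior_series <- function(params, seed = NULL) {
  stopifnot(inherits(params, "behavior_gen_params"))
  b <- if (params$dwell_form == "markov") 1 else params$exponent_b
  with_seed(seed, {
    n_sec <- params$session_length
    states <- integer(0)
    dwells <- integer(0)
    state <- sample.int(3L, 1L)
    total <- 0L
    while (total < n_sec) {
      mean_dwell <- if (length(dwells)) mean(dwells) else 2 * params$timescale_tau + 2
      k <- min(4096L, max(16L, ceiling((n_sec - total) / mean_dwell)))
      d <- sample_stretched_exp_durations(b, params$timescale_tau,
                                          n = k, min_dwell = params$min_dwell)
      for (di in d) {
        states <- c(states, state)
        dwells <- c(dwells, di)
        total <- total + di
        others <- setdiff(1:3, state)
        state <- others[sample.int(2L, 1L, prob = params$transition_weights)]
        if (total >= n_sec) break
      }
    }
    rep(states, dwells)[seq_len(n_sec)]
  })
}

# Pre-clipping increments of the emotion generator: iid Gaussian for
# hurst_target = 0.5, exact-covariance fractional Gaussian noise otherwise.
emotion_increments <- function(params, seed = NULL) {
  stopifnot(inherits(params, "emotion_gen_params"))
  n <- params$session_length - 1L
  if (n < 1L) return(numeric(0))
  with_seed(seed, {
    if (params$hurst_target == 0.5) stats::rnorm(n, sd = params$increment_sd)
    else params$increment_sd * fgn_sim(n, params$hurst_target)
  })
}

#' Generate a bounded integer emotional-valence series
#'
#' Builds a per-second pixel trace by accumulating Gaussian (or fractional
#' Gaussian) increments from `start_value`, with saturating clipping at the
#' screen bounds: the walk sticks at a bound and resumes from it, as a mouse
#' pinned at a screen edge would. Values are rounded to integers.
#'
#' @param params An [emotion_gen_params()] object.
#' @param seed Optional integer seed (same seed, same output).
#' @return Integer vector of length `params$session_length` within
#'   `params$bounds`.
#' @export
generate_emotion_series <- function(params, seed = NULL) {
  stopifnot(inherits(params, "emotion_gen_params"))
  inc <- emotion_increments(params, seed)
  lo <- params$bounds[1]; hi <- params$bounds[2]
  x <- numeric(params$session_length)
  x[1] <- params$start_value
  if (length(inc)) {
    cur <- params$start_value
    for (i in seq_along(inc)) {
      cur <- min(max(cur + inc[i], lo), hi)
      x[i + 1L] <- cur
    }
  }
  as.integer(pmin(pmax(round(x), lo), hi))
}

#' Exact-covariance fractional Gaussian noise
#'
#' Generates a zero-mean, unit-variance fractional Gaussian noise sample of
#' length `n` with Hurst index `H` by Davies-Harte circulant embedding of
#' the exact autocovariance \eqn{\gamma(k) = (|k+1|^{2H} - 2|k|^{2H} +
#' |k-1|^{2H})/2}. Used as a controlled fixture for the Hurst and spectral
#' estimators.
#'
#' @param n Length (>= 2).
#' @param H Hurst index in (0, 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
fgn_sim <- function(n, H, seed = NULL) {
  if (!is_count(n) || n < 2) stop("n must be an integer >= 2")
  if (!is_scalar_num(H) || H <= 0 || H >= 1) stop("H must be in (0, 1)")
  with_seed(seed, {
    if (H == 0.5) return(stats::rnorm(n))
    g <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
    m <- 2L * n
    lam <- Re(stats::fft(c(g(0:n), g((n - 1):1))))
    lam <- pmax(lam, 0)  # guard tiny negative round-off
    zr <- stats::rnorm(n + 1L)
    zi <- stats::rnorm(n - 1L)
    y <- complex(length.out = m)
    y[1] <- sqrt(lam[1]) * zr[1]
    y[n + 1L] <- sqrt(lam[n + 1L]) * zr[n + 1L]
    k <- 2:n
    y[k] <- sqrt(lam[k] / 2) * complex(real = zr[k], imaginary = zi[k - 1L])
    y[m - k + 2L] <- Conj(y[k])
    Re(stats::fft(y))[seq_len(n)] / sqrt(m)
  })
}

#' Generate a complete synthetic study
#'
#' Produces one session record per person per dyad (two persons per dyad),
#' with intractable dyads first, then tractable. Each person's behavior
#' stream, emotion stream, and missingness indicator use seeds derived
#' deterministically from the master seed by a fixed counter scheme, so the
#' output is reproducible and stable under adding dyads.
#'
#' @param config A [study_gen_config()] object.
#' @param seed Optional override of `config$master_seed`.
#' @return A [study_table()] of session records.
#' @examples
#' cfg <- study_gen_config(n_intractable_dyads = 1, n_tractable_dyads = 1,
#'                         missing_person_rate = 0, master_seed = 7)
#' study <- generate_study(cfg)
#' length(study$records)
#' @export
generate_study <- function(config, seed = NULL) {
  stopifnot(inherits(config, "study_gen_config"))
  master <- if (is.null(seed)) config$master_seed else as.integer(seed)
  groups <- c(rep("intractable", config$n_intractable_dyads),
              rep("tractable", config$n_tractable_dyads))
  dyad_ids <- c(sprintf("I%02d", seq_len(config$n_intractable_dyads)),
                sprintf("T%02d", seq_len(config$n_tractable_dyads)))
  records <- list()
  for (i in seq_along(dyad_ids)) {
    for (person in 1:2) {
      counter <- (i - 1L) * 2L + (person - 1L)
      miss_seed <- derive_seed(master, 3L * counter)
      beh_seed <- derive_seed(master, 3L * counter + 1L)
      emo_seed <- derive_seed(master, 3L * counter + 2L)
      missing <- with_seed(miss_seed, stats::runif(1)) < config$missing_person_rate
      if (missing) next
      g <- groups[i]
      records[[length(records) + 1L]] <- session_record(
        dyad_id = dyad_ids[i], person = person, group = g,
        behavior = generate_behavior_series(config$behavior_params[[g]], beh_seed),
        emotion = generate_emotion_series(config$emotion_params[[g]], emo_seed))
    }
  }
  study_table(records, provenance = sprintf("synthetic (master_seed=%d)", master))
}
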