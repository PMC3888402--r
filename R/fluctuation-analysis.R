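#' Hurst exponent by rescaled-range (R/S) analysis
#'
#' For each segment size n, the series is partitioned into non-overlapping
#' segments (the remainder is dropped). Within a segment, the rescaled
#' range is the range of the running sum of the values minus the segment
#' mean, divided by the segment (population) standard deviation. The Hurst
#' exponent H is the least-squares slope of log mean R/S versus log n.
#' H = 0.5 indicates uncorrelated values, H > 0.5 persistence, H < 0.5
#' anti-persistence; on bounded or strongly alternating data R/S saturates
#' and the slope collapses toward 0.
#'
#' @param values Numeric series, not constant, length >= 2 x max segment
#'   size.
#' @param segment_sizes Strictly increasing integers, each >= 8; default
#'   powers of two from 8 to N/4.
#' @return An object of class `hurst_result`: `hurst_H`, `r_squared` of the
#'   log-log line, `segment_sizes`, and `log_points` (natural-log pairs).
#' @examples
#' h <- rescaled_range_hurst(cumsum(rnorm(512)))
#' h$hurst_H
#' @export
rescaled_range_hurst <- function(values, segment_sizes = NULL) {
  values <- as.numeric(values)
  n_obs <- length(values)
  if (is.null(segment_sizes)) {
    if (n_obs < 32) stop("series too short for default segment sizes (need >= 32)")
    segment_sizes <- 2^(3:floor(log2(n_obs / 4)))
  }
  segment_sizes <- as.integer(segment_sizes)
  if (any(segment_sizes < 8) || is.unsorted(segment_sizes, strictly = TRUE))
    stop("segment_sizes must be strictly increasing integers, each >= 8")
  if (length(segment_sizes) < 2) stop("need at least two segment sizes")
  if (n_obs < 2 * max(segment_sizes))
    stop("series length ", n_obs, " < 2 x max segment size ", max(segment_sizes))
  if (stats::sd(values) == 0) stop("degenerate input: series is constant")

  mean_rs <- vapply(segment_sizes, function(n) {
    k <- n_obs %/% n
    m <- matrix(values[seq_len(k * n)], nrow = n)
    mu <- colMeans(m)
    dev <- sweep(m, 2, mu)
    cs <- apply(dev, 2, cumsum)
    r <- apply(cs, 2, function(z) max(z) - min(z))
    s <- sqrt(colMeans(dev^2))             # population sd
    ok <- s > 0
    if (!any(ok)) return(NA_real_)
    mean(r[ok] / s[ok])
  }, 0)
  ok <- is.finite(mean_rs) & mean_rs > 0
  if (sum(ok) < 2) stop("degenerate input: rescaled range undefined at all sizes")
  lx <- log(segment_sizes[ok]); ly <- log(mean_rs[ok])
  fit <- stats::lm(ly ~ lx)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(hurst_H = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 segment_sizes = segment_sizes[ok],
                 log_points = data.frame(log_n = lx, log_rs = ly)),
            class = "hurst_result")
}

#' @export
print.hurst_result <- function(x, ...) {
  cat(sprintf("Hurst R/S: H = %.4f (line R^2 = %.4f, %d segment sizes %d..%d)\n",
              x$hurst_H, x$r_squared, length(x$segment_sizes),
              min(x$segment_sizes), max(x$segment_sizes)))
  invisible(x)
}

#' Shuffle-surrogate check for the R/S estimate
#'
#' Recomputes the Hurst estimate on uniform random permutations of the
#' series. Shuffling preserves the value distribution but destroys temporal
#' order, so surrogate H should fall near 0.5 whatever the original
#' correlation structure; it also removes any curvature of the log-log
#' R/S plot that reflects higher-order temporal structure.
#'
#' @param values Numeric series (as [rescaled_range_hurst()]).
#' @param n_shuffles Number of surrogates (>= 1).
#' @param seed Optional integer seed.
#' @param segment_sizes Passed to [rescaled_range_hurst()].
#' @return An object of class `surrogate_comparison`: `original`
#'   (hurst_result), `shuffled_mean_H`, `shuffled_mean_r_squared`,
#'   `n_shuffles`, `surrogate_H` (per-surrogate estimates), and
#'   `first_surrogate` (one permuted series, for auditing).
#' @export
shuffle_surrogate_hurst <- function(values, n_shuffles, seed = NULL,
                                    segment_sizes = NULL) {
  if (!is_count(n_shuffles) || n_shuffles < 1) stop("n_shuffles must be >= 1")
  original <- rescaled_range_hurst(values, segment_sizes)
  res <- with_seed(seed, {
    hs <- numeric(n_shuffles); r2s <- numeric(n_shuffles); first <- NULL
    for (i in seq_len(n_shuffles)) {
      perm <- sample(values)
      if (i == 1L) first <- perm
      h <- rescaled_range_hurst(perm, segment_sizes)
      hs[i] <- h$hurst_H; r2s[i] <- h$r_squared
    }
    list(hs = hs, r2s = r2s, first = first)
  })
  structure(list(original = original,
                 shuffled_mean_H = mean(res$hs),
                 shuffled_mean_r_squared = mean(res$r2s),
                 n_shuffles = as.integer(n_shuffles),
                 surrogate_H = res$hs,
                 first_surrogate = res$first),
            class = "surrogate_comparison")
}

#' One-sided power spectral density at 1 Hz sampling
#'
#' Computes the PSD of a per-second series by one of four estimators:
#' `"fft"` (squared modulus of the discrete Fourier transform),
#' `"periodogram"` (rectangular window, no zero-padding), `"welch"`
#' (averaged modified periodograms: 8 segments, 50\% overlap, rectangular
#' window), or `"multitaper"` (Thomson's method with DPSS tapers,
#' time-bandwidth 4, 7 tapers). The zero frequency is excluded;
#' frequencies run over (0, 0.5] cycles/s. The tail slope of log power vs
#' log frequency is fitted over `tail_range` ([fit_tail_slope()]): it is
#' about -2 for a Brownian path and 0 for white noise.
#'
#' @param values Numeric series, length >= 64.
#' @param method One of `"fft"`, `"periodogram"`, `"welch"`, `"multitaper"`.
#' @param tail_range Frequency interval (Hz) for the tail fit.
#' @return An object of class `psd_result`: `method`, `frequencies`,
#'   `power`, `tail_slope`, `tail_r_squared`, `tail_range`.
#' @export
power_spectrum <- function(values, method = c("periodogram", "fft", "welch",
                                              "multitaper"),
                           tail_range = c(0.01, 0.5)) {
  method <- match.arg(method)
  x <- as.numeric(values)
  n <- length(x)
  if (n < 64) stop("series too short for spectral estimation (need >= 64)")
  if (method == "fft") {
    x <- x - mean(x)
    p <- Mod(stats::fft(x))^2 / n
    k <- seq_len(n %/% 2)
    freq <- k / n
    pow <- p[k + 1L]
  } else if (method == "periodogram") {
    sp <- stats::spec.pgram(x, taper = 0, fast = FALSE, detrend = FALSE,
                            demean = TRUE, plot = FALSE)
    freq <- sp$freq
    pow <- sp$spec
  } else if (method == "welch") {
    L <- max(64L, floor(2 * n / 9))        # ~8 segments at 50% overlap
    step <- max(1L, L %/% 2L)
    starts <- seq(1L, n - L + 1L, by = step)
    k <- seq_len(L %/% 2)
    acc <- numeric(length(k))
    for (s0 in starts) {
      seg <- x[s0:(s0 + L - 1L)]
      seg <- seg - mean(seg)
      acc <- acc + (Mod(stats::fft(seg))[k + 1L])^2 / L
    }
    freq <- k / L
    pow <- acc / length(starts)
  } else {
    tap <- dpss_tapers(n, nw = 4, k = 7)
    x <- x - mean(x)
    kk <- seq_len(n %/% 2)
    acc <- numeric(length(kk))
    for (j in seq_len(ncol(tap)))
      acc <- acc + (Mod(stats::fft(x * tap[, j]))[kk + 1L])^2
    freq <- kk / n
    pow <- acc / ncol(tap)
  }
  res <- structure(list(method = method, frequencies = freq, power = pow,
                        tail_slope = NA_real_, tail_r_squared = NA_real_,
                        tail_range = tail_range),
                   class = "psd_result")
  tail <- fit_tail_slope(res, tail_range)
  res$tail_slope <- tail$slope
  res$tail_r_squared <- tail$r_squared
  res
}

# Discrete prolate spheroidal (Slepian) tapers via the symmetric
# tridiagonal eigenproblem; columns are unit-norm tapers, best-concentrated
# first.
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  w <- nw / n
  i <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * ((n - 1):1) / 2
  m <- matrix(0, n, n)
  m[cbind(1:n, 1:n)] <- diag_main
  m[cbind(1:(n - 1), 2:n)] <- off
  m[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(m, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  sweep(tap, 2, sqrt(colSums(tap^2)), "/")
}

#' Fit the tail slope of a power spectrum
#'
#' Least-squares line on (log frequency, log power) restricted to
#' `f_range`. Non-positive power values inside the range are dropped.
#'
#' @param psd A `psd_result` from [power_spectrum()].
#' @param f_range Frequency interval (Hz); default \[0.01, 0.5\].
#' @return List with `slope` and `r_squared`.
#' @export
fit_tail_slope <- function(psd, f_range = c(0.01, 0.5)) {
  stopifnot(inherits(psd, "psd_result"))
  if (!is.numeric(f_range) || length(f_range) != 2L || f_range[1] >= f_range[2])
    stop("f_range must be an increasing frequency interval")
  sel <- psd$frequencies >= f_range[1] & psd$frequencies <= f_range[2] &
    psd$power > 0
  if (sum(sel) < 8) stop("fewer than 8 positive spectral points in f_range")
  lf <- log(psd$frequencies[sel]); lp <- log(psd$power[sel])
  fit <- stats::lm(lp ~ lf)
  sst <- sum((lp - mean(lp))^2)
  list(slope = unname(stats::coef(fit)[2]),
       r_squared = if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst)
}

#' Convert a PSD tail slope to a Hurst exponent
#'
#' Uses the standard fractional-Brownian-motion / fractional-Gaussian-noise
#' identities. In `"data_slope"` mode the slope comes from the series
#' itself and H describes its increments: H = (|slope| - 1) / 2 (so a
#' Brownian slope of -2 gives H = 0.5). In `"increment_slope"` mode both
#' the slope and H refer to the increments: H = (|slope| + 1) / 2. Results
#' outside \[0, 1\] are clamped with a warning.
#'
#' @param slope Finite tail slope.
#' @param mode `"data_slope"` or `"increment_slope"`.
#' @return Hurst exponent in \[0, 1\].
#' @examples
#' slope_to_hurst(-2, "data_slope")    # 0.5
#' slope_to_hurst(0, "increment_slope") # 0.5
#' @export
slope_to_hurst <- function(slope, mode = c("data_slope", "increment_slope")) {
  mode <- match.arg(mode)
  if (!is_scalar_num(slope)) stop("slope must be a finite number")
  h <- if (mode == "data_slope") (abs(slope) - 1) / 2 else (abs(slope) + 1) / 2
  if (h < 0 || h > 1) {
    warning("implied Hurst exponent ", signif(h, 4), " outside [0, 1]; clamped")
    h <- min(max(h, 0), 1)
  }
  h
}

#' Dichotomize an emotion series and extract crossing intervals
#'
#' Splits the series at its session mean into below/above states (values
#' exactly equal to the mean count as "above") and returns the run lengths
#' of the binary sequence — the durations between crossings of the mean
#' level. For an uncorrelated random walk these intervals follow the
#' first-return-time power law, density ~ t^(-3/2), at short times.
#'
#' @param emotion Nonempty, non-constant numeric series.
#' @return A [duration_set()] with label `"dichotomized"`.
#' @examples
#' dichotomize_and_intervals(c(0, 0, 10, 10))$durations
#' @export
dichotomize_and_intervals <- function(emotion) {
  x <- as.numeric(emotion)
  if (length(x) == 0) stop("emotion series must be nonempty")
  if (anyNA(x)) stop("emotion series must not contain missing values")
  if (min(x) == max(x)) stop("degenerate input: series is constant")
  above <- x >= mean(x)
  duration_set("dichotomized", rle(above)$lengths)
}
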