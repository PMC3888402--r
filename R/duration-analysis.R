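#' Durations of consecutive seconds spent in one state
#'
#' @param state_label State label: `"1"`, `"2"`, `"3"`, `"123"` (all states
#'   pooled), or `"dichotomized"` for mean-split emotion intervals.
#' @param durations Integer vector of dwell durations (seconds, >= 1).
#' @return An object of class `duration_set` with fields `state_label`,
#'   `durations`, `n_total`.
#' @export
duration_set <- function(state_label, durations) {
  stopifnot(is.character(state_label), length(state_label) == 1L)
  durations <- as.integer(durations)
  if (anyNA(durations) || any(durations < 1))
    stop("durations must be integers >= 1")
  structure(list(state_label = state_label, durations = durations,
                 n_total = length(durations)),
            class = "duration_set")
}

#' Extract dwell durations from a behavior series
#'
#' Run-length encodes a per-second state series: every second belongs to
#' exactly one run, and boundary (first and last) runs are included as
#' complete durations.
#'
#' @param behavior Integer vector of codes in \{1, 2, 3\}.
#' @return Named list mapping each state present (`"1"`, `"2"`, `"3"`) to a
#'   [duration_set()].
#' @examples
#' extract_durations(c(1, 1, 1, 2, 2, 3))
#' @export
extract_durations <- function(behavior) {
  if (length(behavior) == 0) stop("behavior series must be nonempty")
  if (anyNA(behavior) || !all(behavior %in% 1:3))
    stop("behavior codes must be in {1, 2, 3}")
  r <- rle(as.integer(behavior))
  out <- list()
  for (s in sort(unique(r$values)))
    out[[as.character(s)]] <- duration_set(as.character(s),
                                           r$lengths[r$values == s])
  out
}

#' Pool duration sets across persons and/or states
#'
#' Concatenates durations from several sets. Pooling all three states gives
#' label `"123"`; pooling a single state requires all inputs to carry that
#' state's label.
#'
#' @param sets List of [duration_set()] objects (or of named lists of them,
#'   as returned by [extract_durations()], which are flattened).
#' @param states States to pool: a subset of `1:3`.
#' @return A [duration_set()].
#' @export
pool_durations <- function(sets, states = 1:3) {
  if (length(sets) == 0) stop("sets must be a nonempty list")
  flat <- list()
  for (s in sets) {
    if (inherits(s, "duration_set")) flat[[length(flat) + 1L]] <- s
    else if (is.list(s)) for (x in s) {
      stopifnot(inherits(x, "duration_set"))
      flat[[length(flat) + 1L]] <- x
    } else stop("sets must contain duration_set objects")
  }
  states <- sort(unique(as.integer(states)))
  if (!all(states %in% 1:3)) stop("states must be a subset of 1:3")
  label <- if (length(states) == 3L) "123" else if (length(states) == 1L)
    as.character(states) else paste(states, collapse = "")
  keep <- flat[vapply(flat, function(x) x$state_label %in% as.character(states), TRUE)]
  if (length(keep) == 0)
    stop("incompatible state labels: no input set carries state ",
         paste(states, collapse = "/"))
  duration_set(label, unlist(lapply(keep, function(x) x$durations), use.names = FALSE))
}

#' Multi-bin-size probability density estimate of dwell durations
#'
#' Estimates the dwell-time PDF from histograms of several bin sizes at
#' once: for each width \eqn{\Delta t}, the density at bin start t is
#' \eqn{N(t, \Delta t) / (N_{total}\,\Delta t)}; only bins holding at least
#' `min_count` observations are retained, and when two widths yield a point
#' at the same t the smaller width wins. Combining widths improves
#' resolution at small durations (narrow bins) and in the sparse tail (wide
#' bins) relative to any single histogram.
#'
#' @param durations A [duration_set()] or plain integer vector.
#' @param bin_widths Strictly increasing widths (seconds, each >= 1);
#'   default powers of two from 1 up to the maximum duration.
#' @param min_count Minimum bin occupancy to retain a density point.
#' @return An object of class `pdf_estimate`: `points` (data.frame with
#'   `t`, `density`, `bin_width`, `count`), `n_total`, and `cumulative`
#'   (survival fraction of durations >= t at each observed t).
#' @examples
#' estimate_pdf_multibin(c(1, 1, 2, 4), bin_widths = 1, min_count = 1)$points
#' @export
estimate_pdf_multibin <- function(durations, bin_widths = NULL, min_count = 5) {
  d <- if (inherits(durations, "duration_set")) durations$durations
       else as.integer(durations)
  if (!is_count(min_count) || min_count < 1) stop("min_count must be >= 1")
  n_total <- length(d)
  if (n_total < min_count)
    stop("insufficient data: ", n_total, " durations, need at least ", min_count)
  if (is.null(bin_widths))
    bin_widths <- 2^(0:max(0, floor(log2(max(d)))))
  bin_widths <- as.numeric(bin_widths)
  if (any(bin_widths < 1) || is.unsorted(bin_widths, strictly = TRUE))
    stop("bin_widths must be strictly increasing and each >= 1")
  anchor <- min(d)
  pts <- list()
  for (dt in bin_widths) {
    edges <- seq(anchor, max(d) + dt, by = dt)
    idx <- findInterval(d, edges)          # bins [t, t + dt)
    counts <- tabulate(idx, nbins = length(edges) - 1L)
    keep <- which(counts >= min_count)
    if (length(keep))
      pts[[length(pts) + 1L]] <- data.frame(
        t = edges[keep], density = counts[keep] / (n_total * dt),
        bin_width = dt, count = counts[keep])
  }
  if (length(pts) == 0) stop("no bin reached min_count = ", min_count)
  pts <- do.call(rbind, pts)
  pts <- pts[order(pts$t, pts$bin_width), , drop = FALSE]
  pts <- pts[!duplicated(pts$t), , drop = FALSE]   # smaller width wins at a tie
  rownames(pts) <- NULL
  ts <- sort(unique(d))
  structure(list(points = pts, n_total = n_total,
                 cumulative = data.frame(
                   t = ts,
                   p = vapply(ts, function(x) mean(d >= x), 0))),
            class = "pdf_estimate")
}

#' Fit one functional form to a PDF estimate
#'
#' Least-squares fit in log-density space (matching assessment of the fits
#' on log-log axes): parameters minimize \eqn{\sum (\log \hat f(t) - \log
#' f(t))^2}. Forms: single exponential \eqn{A e^{-a t}}, power law
#' \eqn{A t^{-\alpha}}, and stretched exponential \eqn{A e^{-(a t)^b}}. The
#' stretched fit profiles over b (coarse grid including b = 1, then local
#' refinement); for fixed b the problem is linear in \eqn{\log A} and
#' \eqn{a^b}, so each start is solved exactly — this also guarantees the
#' stretched optimum is never worse than the single-exponential one.
#'
#' @param pdf A `pdf_estimate` from [estimate_pdf_multibin()].
#' @param form `"single_exponential"`, `"power_law"`, or
#'   `"stretched_exponential"`.
#' @return An object of class `model_fit` with the form's parameters
#'   (`amplitude_A` and `rate_a`; `exponent_b` for stretched;
#'   `exponent_alpha` for power law) and `r_squared` computed on the log
#'   densities (1 - SSE/SST about the mean log density).
#' @export
fit_pdf_model <- function(pdf, form = c("stretched_exponential",
                                        "single_exponential", "power_law")) {
  stopifnot(inherits(pdf, "pdf_estimate"))
  form <- match.arg(form)
  t <- pdf$points$t
  ld <- log(pdf$points$density)
  min_pts <- if (form == "power_law") 2L else 4L
  if (length(t) < min_pts)
    stop("need at least ", min_pts, " PDF points for a ", form, " fit")
  sst <- sum((ld - mean(ld))^2)
  r2 <- function(fitted) if (sst == 0) 1 else 1 - sum((ld - fitted)^2) / sst

  if (form == "single_exponential") {
    co <- stats::coef(stats::lm(ld ~ t))
    fit <- list(form = form, amplitude_A = exp(unname(co[1])),
                rate_a = -unname(co[2]), exponent_b = NA_real_,
                exponent_alpha = NA_real_,
                r_squared = r2(co[1] + co[2] * t))
  } else if (form == "power_law") {
    lt <- log(t)
    co <- stats::coef(stats::lm(ld ~ lt))
    fit <- list(form = form, amplitude_A = exp(unname(co[1])),
                rate_a = NA_real_, exponent_b = NA_real_,
                exponent_alpha = -unname(co[2]),
                r_squared = r2(co[1] + co[2] * lt))
  } else {
    prof <- function(b) {                  # SSE of the best fit at this b
      tb <- t^b
      co <- stats::coef(stats::lm(ld ~ tb))
      if (!all(is.finite(co)) || co[2] >= 0) return(Inf)
      sum((ld - (co[1] + co[2] * tb))^2)
    }
    grid <- sort(unique(c(seq(0.05, 1.6, by = 0.05), 1)))
    sse_grid <- vapply(grid, prof, 0)
    if (all(!is.finite(sse_grid)))
      stop("stretched-exponential fit failed from every start ",
           "(no decreasing log-density trend in the points)")
    i <- which.min(sse_grid)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(prof, lower = lo, upper = hi, tol = 1e-8)
    b <- if (opt$objective <= sse_grid[i]) opt$minimum else grid[i]
    tb <- t^b
    co <- stats::coef(stats::lm(ld ~ tb))
    fit <- list(form = form, amplitude_A = exp(unname(co[1])),
                rate_a = (-unname(co[2]))^(1 / b), exponent_b = b,
                exponent_alpha = NA_real_,
                r_squared = r2(co[1] + co[2] * tb))
  }
  fit$n_points <- length(t)
  class(fit) <- "model_fit"
  fit
}

#' @export
print.model_fit <- function(x, digits = 4, ...) {
  pars <- switch(x$form,
    single_exponential = sprintf("A = %.*g, a = %.*g /s", digits,
                                 x$amplitude_A, digits, x$rate_a),
    power_law = sprintf("A = %.*g, alpha = %.*g", digits, x$amplitude_A,
                        digits, x$exponent_alpha),
    stretched_exponential = sprintf("A = %.*g, a = %.*g /s, b = %.*g", digits,
                                    x$amplitude_A, digits, x$rate_a,
                                    digits, x$exponent_b))
  cat(sprintf("%s fit: %s; R^2 = %.*f (%d points)\n", x$form, pars,
              digits, x$r_squared, x$n_points))
  invisible(x)
}

#' Fit and rank all three dwell-time models
#'
#' Fits the single-exponential, power-law, and stretched-exponential forms
#' to the same PDF estimate and ranks them by descending R-squared (ties
#' broken in favor of fewer parameters). A form whose fit fails is dropped
#' with a warning; at least two must succeed.
#'
#' @param pdf A `pdf_estimate`.
#' @return List of [fit_pdf_model()] results, best first.
#' @export
compare_fits <- function(pdf) {
  forms <- c("stretched_exponential", "single_exponential", "power_law")
  n_par <- c(stretched_exponential = 3, single_exponential = 2, power_law = 2)
  fits <- list()
  for (f in forms) {
    res <- tryCatch(fit_pdf_model(pdf, f), error = function(e) e)
    if (inherits(res, "error")) warning(f, " fit failed: ", conditionMessage(res))
    else fits[[f]] <- res
  }
  if (length(fits) < 2) stop("fewer than two model forms could be fitted")
  ord <- order(-vapply(fits, function(x) x$r_squared, 0),
               n_par[names(fits)])
  unname(fits[ord])
}

#' Effective kinetic rate constant of a fitted dwell-time model
#'
#' The instantaneous probability per second of leaving the current state
#' after already spending t seconds in it: \eqn{k(t) = f(t) / S(t)} with
#' survival \eqn{S(t) = \int_t^\infty f(u)\,du}, evaluated by adaptive
#' numerical integration of the fitted density. For the memoryless single
#' exponential k(t) is the constant rate a; for a stretched exponential
#' with b < 1, k(t) decreases with the time already spent in the state —
#' the "memory" signature.
#'
#' @param fit A `model_fit` of form `single_exponential` or
#'   `stretched_exponential`.
#' @param grid Strictly increasing positive times (seconds).
#' @return An object of class `rate_curve`: data.frame with columns `t`
#'   and `rate_k` (1/seconds).
#' @export
effective_rate_constant <- function(fit, grid) {
  stopifnot(inherits(fit, "model_fit"))
  if (!fit$form %in% c("single_exponential", "stretched_exponential"))
    stop("effective rate is defined for exponential-family fits only")
  grid <- as.numeric(grid)
  if (any(!is.finite(grid)) || any(grid <= 0) ||
      is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing positive times")
  a <- fit$rate_a
  b <- if (fit$form == "single_exponential") 1 else fit$exponent_b
  if (!is.finite(a) || a <= 0) stop("fit has no positive rate parameter")
  dens <- function(u) exp(-(a * u)^b)      # amplitude cancels in f/S
  k <- vapply(grid, function(t0) {
    s <- stats::integrate(dens, t0, Inf, rel.tol = 1e-10)$value
    dens(t0) / s
  }, 0)
  structure(data.frame(t = grid, rate_k = k), class = c("rate_curve", "data.frame"))
}
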