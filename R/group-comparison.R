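#' Mann-Whitney U test (exact or tie-corrected normal approximation)
#'
#' Rank-sum test for a location shift between two independent samples. The
#' statistic U counts pairs where an `x` value exceeds a `y` value (ties
#' count one half). For tie-free samples with n + m <= 16 the null
#' distribution of U is enumerated exactly over all C(n+m, n) rank
#' assignments; otherwise the normal approximation with tie correction and
#' continuity correction is used. The one-sided direction must be stated
#' explicitly by the caller; no default is assumed.
#'
#' @param x,y Nonempty numeric samples.
#' @param alternative `"less"` (x shifted low relative to y), `"greater"`,
#'   or `"two.sided"`. Required.
#' @return An object of class `u_test_result`: `u_statistic`,
#'   `p_one_sided` (in the stated direction; `NA` for `"two.sided"`),
#'   `p_two_sided`, `method` (`"exact"` or `"normal_approximation"`),
#'   `alternative`, `n_x`, `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4), alternative = "less")
#' @export
mann_whitney_u <- function(x, y, alternative) {
  if (missing(alternative))
    stop("state the alternative explicitly: 'less', 'greater' or 'two.sided'")
  alternative <- match.arg(alternative, c("less", "greater", "two.sided"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain missing values")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2   # pairs with x > y (+0.5/tie)
  has_ties <- anyDuplicated(pooled) > 0

  if (!has_ties && n + m <= 16) {
    method <- "exact"
    combos <- utils::combn(n + m, n)   # which pooled ranks go to x
    all_u <- colSums(combos) - n * (n + 1) / 2
    p_le <- mean(all_u <= u)
    p_ge <- mean(all_u >= u)
  } else {
    method <- "normal_approximation"
    nm <- as.double(n) * m
    big_n <- n + m
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (big_n * (big_n - 1))
    sigma <- sqrt(nm / 12 * ((big_n + 1) - tie_term))
    mu <- nm / 2
    p_le <- stats::pnorm((u - mu + 0.5) / sigma)
    p_ge <- stats::pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE)
  }
  p_one <- switch(alternative, less = p_le, greater = p_ge,
                  two.sided = NA_real_)
  p_two <- min(1, 2 * min(p_le, p_ge))
  structure(list(u_statistic = u, p_one_sided = p_one, p_two_sided = p_two,
                 method = method, alternative = alternative,
                 n_x = n, n_y = m),
            class = "u_test_result")
}

#' @export
print.u_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, m = %d, %s)\n", x$u_statistic,
              x$n_x, x$n_y, x$method))
  if (!is.na(x$p_one_sided))
    cat(sprintf("  one-sided p (%s) = %.5g\n", x$alternative, x$p_one_sided))
  cat(sprintf("  two-sided p = %.5g\n", x$p_two_sided))
  invisible(x)
}

#' Per-person metric table with per-group AVERAGES rows
#'
#' Sorts a per-person metric table by dyad then person and appends one
#' `AVERAGES` row per group holding the arithmetic mean of each metric over
#' the group's non-missing rows. Rows whose metrics are all missing are
#' kept in the table (blank), excluded from the averages, and listed in the
#' `footnotes` attribute.
#'
#' @param metrics data.frame with columns `dyad`, `person`, `group`, and
#'   one or more numeric metric columns. Groups must be `"intractable"`,
#'   `"tractable"`, or `"unknown"`.
#' @return A data.frame (class `group_summary`) with the AVERAGES rows
#'   appended per group; attribute `footnotes` lists excluded persons.
#' @export
summarize_groups <- function(metrics) {
  stopifnot(is.data.frame(metrics),
            all(c("dyad", "person", "group") %in% names(metrics)))
  known <- c("intractable", "tractable", "unknown")
  if (!all(metrics$group %in% known))
    stop("unknown group label(s): ",
         paste(setdiff(unique(metrics$group), known), collapse = ", "))
  metric_cols <- setdiff(names(metrics), c("dyad", "person", "group"))
  if (length(metric_cols) == 0) stop("no metric columns to summarize")
  metrics <- metrics[order(metrics$dyad, metrics$person), , drop = FALSE]
  rownames(metrics) <- NULL
  all_missing <- apply(metrics[metric_cols], 1,
                       function(r) all(is.na(r)))
  footnotes <- sprintf("dyad %s person %d excluded from averages (missing)",
                       metrics$dyad[all_missing], metrics$person[all_missing])
  out <- metrics
  for (g in unique(metrics$group)) {
    rows <- metrics[metrics$group == g & !all_missing, , drop = FALSE]
    avg <- data.frame(dyad = "AVERAGES", person = NA_integer_, group = g)
    for (mc in metric_cols)
      avg[[mc]] <- if (nrow(rows)) mean(rows[[mc]], na.rm = TRUE) else NA_real_
    out <- rbind(out, avg)
  }
  rownames(out) <- NULL
  attr(out, "footnotes") <- footnotes
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Bootstrap confidence interval for a difference in stretching exponents
#'
#' Exploratory extension beyond the core pooled-fit analysis: the pooled
#' stretched-exponential fit yields a single exponent per group with no
#' between-person variance estimate, so this routine bootstraps the
#' durations (resampling with replacement, refitting the multi-bin PDF and
#' stretched model on each resample) to attach a confidence interval to the
#' difference b_a - b_b. The interval is the basic (reverse-percentile)
#' bootstrap interval: the multi-bin estimator's bin-retention rule makes
#' refits on resampled data systematically biased, and the basic interval
#' cancels that first-order bias where the plain percentile interval would
#' not.
#'
#' @param durations_a,durations_b [duration_set()]s with >= 50 durations
#'   each.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional integer seed.
#' @param conf Confidence level (default 0.95).
#' @param bin_widths,min_count Passed to [estimate_pdf_multibin()].
#' @return List (class `exponent_difference_ci`): `estimate` (point
#'   difference), `ci` (percentile interval), `conf`, `boot_diffs`,
#'   `n_failed`, `extension = TRUE` (this is an add-on beyond the core
#'   pooled analysis).
#' @export
bootstrap_exponent_difference <- function(durations_a, durations_b,
                                          n_boot = 200, seed = NULL,
                                          conf = 0.95,
                                          bin_widths = NULL, min_count = 5) {
  stopifnot(inherits(durations_a, "duration_set"),
            inherits(durations_b, "duration_set"))
  if (durations_a$n_total < 50 || durations_b$n_total < 50)
    stop("need at least 50 durations in each set")
  if (!is_count(n_boot) || n_boot < 10) stop("n_boot must be an integer >= 10")
  fit_b <- function(d) {
    pdf <- estimate_pdf_multibin(d, bin_widths, min_count)
    fit_pdf_model(pdf, "stretched_exponential")$exponent_b
  }
  est <- fit_b(durations_a$durations) - fit_b(durations_b$durations)
  boot <- with_seed(seed, {
    diffs <- rep(NA_real_, n_boot)
    for (i in seq_len(n_boot)) {
      ra <- sample(durations_a$durations, durations_a$n_total, replace = TRUE)
      rb <- sample(durations_b$durations, durations_b$n_total, replace = TRUE)
      diffs[i] <- tryCatch(fit_b(ra) - fit_b(rb), error = function(e) NA_real_)
    }
    diffs
  })
  n_failed <- sum(is.na(boot))
  if (n_failed > 0.2 * n_boot)
    stop("unstable estimate: ", n_failed, "/", n_boot, " resamples failed to fit")
  alpha <- (1 - conf) / 2
  q <- unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
  ci <- c(2 * est - q[2], 2 * est - q[1])
  structure(list(estimate = est, ci = ci, conf = conf,
                 boot_diffs = boot, n_failed = n_failed, extension = TRUE),
            class = "exponent_difference_ci")
}

#' @export
print.exponent_difference_ci <- function(x, ...) {
  cat(sprintf(paste0("Bootstrap exponent difference (exploratory extension):",
                     " %.4f, %g%% CI [%.4f, %.4f] (%d resamples, %d failed)\n"),
              x$estimate, 100 * x$conf, x$ci[1], x$ci[2],
              length(x$boot_diffs), x$n_failed))
  invisible(x)
}
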