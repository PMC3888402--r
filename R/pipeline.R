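#' Pipeline configuration
#'
#' Exactly one of `data_path`/`metadata_path` (read an existing study) or
#' `gen_config` (simulate one) must be supplied.
#'
#' @param data_path,metadata_path CSV paths of an existing study, or `NULL`.
#' @param gen_config A [study_gen_config()], or `NULL`.
#' @param bin_widths,min_count Dwell-time PDF settings
#'   ([estimate_pdf_multibin()]).
#' @param segment_sizes R/S segment sizes ([rescaled_range_hurst()]);
#'   `NULL` for the power-of-two default.
#' @param tail_range PSD tail-fit frequency interval (Hz).
#' @param psd_method Spectral estimator used for the per-person metrics.
#' @param test_direction Alternative for the group tests, stated
#'   explicitly: `"two.sided"` (default), `"less"` or `"greater"` (direction
#'   of the intractable group relative to the tractable group).
#' @param master_seed Seed echoed into the run manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(data_path = NULL, metadata_path = NULL,
                            gen_config = NULL,
                            bin_widths = NULL, min_count = 5,
                            segment_sizes = NULL,
                            tail_range = c(0.01, 0.5),
                            psd_method = "periodogram",
                            test_direction = "two.sided",
                            master_seed = 1L) {
  has_paths <- !is.null(data_path) || !is.null(metadata_path)
  if (has_paths && !is.null(gen_config))
    stop("config error: supply input paths or a generator config, not both")
  if (!has_paths && is.null(gen_config))
    stop("config error: supply input paths or a generator config")
  if (has_paths && (is.null(data_path) || is.null(metadata_path)))
    stop("config error: both data_path and metadata_path are required")
  if (!is.null(gen_config)) stopifnot(inherits(gen_config, "study_gen_config"))
  test_direction <- match.arg(test_direction, c("two.sided", "less", "greater"))
  structure(list(data_path = data_path, metadata_path = metadata_path,
                 gen_config = gen_config, bin_widths = bin_widths,
                 min_count = min_count, segment_sizes = segment_sizes,
                 tail_range = tail_range, psd_method = psd_method,
                 test_direction = test_direction,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Behavior-stage analysis: pooled dwell-time model comparison
#'
#' For each group, pools dwell durations across all persons for each state
#' (1, 2, 3) and for all states combined ("123"), estimates the multi-bin
#' PDF, and fits and ranks the three candidate models.
#'
#' @param study A [study_table()].
#' @param bin_widths,min_count Passed to [estimate_pdf_multibin()].
#' @return data.frame with one row per group x state x form: fitted
#'   parameters, `r_squared`, `rank` (1 = best), `n_durations`.
#' @export
analyze_behavior <- function(study, bin_widths = NULL, min_count = 5) {
  stopifnot(inherits(study, "study_table"))
  rows <- list()
  for (g in intersect(c("intractable", "tractable", "unknown"),
                      unique(vapply(study$records, function(r) r$group, "")))) {
    recs <- Filter(function(r) r$group == g && !is.null(r$behavior),
                   study$records)
    if (length(recs) == 0) next
    per_person <- lapply(recs, function(r) extract_durations(r$behavior))
    for (state_set in list(1L, 2L, 3L, 1:3)) {
      pooled <- pool_durations(per_person, states = state_set)
      pdf <- estimate_pdf_multibin(pooled, bin_widths, min_count)
      fits <- compare_fits(pdf)
      for (i in seq_along(fits)) {
        f <- fits[[i]]
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, state = pooled$state_label, form = f$form,
          amplitude_A = f$amplitude_A, rate_a = f$rate_a,
          exponent_b = f$exponent_b, exponent_alpha = f$exponent_alpha,
          r_squared = f$r_squared, rank = i, n_durations = pooled$n_total)
      }
    }
  }
  if (length(rows) == 0) stop("behavior stage: no behavior streams present")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Emotion-stage analysis: per-person fluctuation metrics
#'
#' For each person with an emotion stream: PSD tail slope from the raw
#' pixel series and Hurst exponent from the rescaled-range analysis of its
#' first differences — the combination under which slope -2 and H = 0.5
#' both indicate uncorrelated increments. Also records the
#' mean-split dichotomization interval count as a diagnostic.
#'
#' @param study A [study_table()].
#' @param segment_sizes,tail_range,psd_method See [pipeline_config()].
#' @return data.frame with columns `dyad`, `person`, `group`,
#'   `tail_slope`, `psd_tail_r_squared`, `hurst_H`, `rs_r_squared`,
#'   `n_crossing_intervals`, `n_seconds`.
#' @export
analyze_emotion <- function(study, segment_sizes = NULL,
                            tail_range = c(0.01, 0.5),
                            psd_method = "periodogram") {
  stopifnot(inherits(study, "study_table"))
  rows <- list()
  for (r in study$records) {
    if (is.null(r$emotion)) next
    e <- as.numeric(r$emotion)
    psd <- power_spectrum(e, method = psd_method, tail_range = tail_range)
    h <- rescaled_range_hurst(diff(e), segment_sizes)
    di <- tryCatch(dichotomize_and_intervals(e), error = function(e2) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      dyad = r$dyad_id, person = r$person, group = r$group,
      tail_slope = psd$tail_slope, psd_tail_r_squared = psd$tail_r_squared,
      hurst_H = h$hurst_H, rs_r_squared = h$r_squared,
      n_crossing_intervals = if (is.null(di)) NA_integer_ else di$n_total,
      n_seconds = length(e))
  }
  if (length(rows) == 0) stop("emotion stage: no emotion streams present")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-comparison stage: Mann-Whitney tests on per-person metrics
#'
#' Tests the intractable against the tractable group on the Hurst exponent
#' and on the R/S line-fit R-squared (the latter probes a difference in the
#' nonlinearity of the time correlations).
#'
#' @param metrics Output of [analyze_emotion()].
#' @param direction Alternative for the intractable sample relative to the
#'   tractable sample (`"two.sided"`, `"less"`, `"greater"`).
#' @return data.frame with one row per tested metric: `metric`, group
#'   sizes, `u_statistic`, `p_one_sided`, `p_two_sided`, `method`.
#' @export
compare_groups <- function(metrics, direction = "two.sided") {
  stopifnot(is.data.frame(metrics))
  xi <- metrics[metrics$group == "intractable", , drop = FALSE]
  xt <- metrics[metrics$group == "tractable", , drop = FALSE]
  if (nrow(xi) == 0 || nrow(xt) == 0)
    stop("group comparison needs both intractable and tractable persons")
  rows <- lapply(c("hurst_H", "rs_r_squared"), function(mc) {
    a <- xi[[mc]][!is.na(xi[[mc]])]
    b <- xt[[mc]][!is.na(xt[[mc]])]
    res <- mann_whitney_u(a, b, alternative = direction)
    data.frame(metric = mc, n_intractable = length(a), n_tractable = length(b),
               u_statistic = res$u_statistic, p_one_sided = res$p_one_sided,
               p_two_sided = res$p_two_sided, method = res$method)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Sequences simulate/read -> validate -> behavior analysis -> emotion
#' analysis -> group comparison, and optionally writes the report tables
#' (`fits.csv`, `metrics.csv`, `tests.csv`) plus a run manifest
#' (`manifest.json`) that echoes the configuration and seeds so the run can
#' be reproduced bit-for-bit. On a stage error, partially written outputs
#' are removed and the error names the failing stage.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return An object of class `report_bundle`: `fits`, `metrics` (with
#'   AVERAGES rows), `tests`, `diagnostics`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "acquire"
  written <- character(0)
  on_fail <- function(e) {
    for (f in written) if (file.exists(f)) unlink(f)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    study <- if (!is.null(config$gen_config))
      generate_study(config$gen_config, seed = config$master_seed)
    else read_study(config$data_path, config$metadata_path)

    stage <- "validate"
    violations <- lapply(study$records, validate_session)
    n_viol <- sum(vapply(violations, nrow, 0L))
    if (n_viol > 0) stop(n_viol, " coding-domain violations in the input")

    stage <- "behavior"
    fits <- analyze_behavior(study, config$bin_widths, config$min_count)

    stage <- "emotion"
    metrics_raw <- analyze_emotion(study, config$segment_sizes,
                                   config$tail_range, config$psd_method)
    metrics <- summarize_groups(metrics_raw)

    stage <- "compare"
    tests <- compare_groups(metrics_raw, config$test_direction)

    stage <- "report"
    diagnostics <- list(
      warnings = study$warnings,
      n_person_records = length(study$records),
      mean_crossing_intervals = mean(metrics_raw$n_crossing_intervals,
                                     na.rm = TRUE))
    manifest <- list(
      package_version = as.character(utils::packageVersion("conflictdyn")),
      master_seed = config$master_seed,
      config = config_echo(config),
      provenance = study$provenance,
      warnings = study$warnings,
      footnotes = attr(metrics, "footnotes"))
    bundle <- structure(list(fits = fits, metrics = metrics, tests = tests,
                             diagnostics = diagnostics, manifest = manifest),
                        class = "report_bundle")
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- file.path(out_dir, c("fits.csv", "metrics.csv", "tests.csv",
                                    "manifest.json"))
      written <- paths
      utils::write.csv(fits, paths[1], row.names = FALSE, quote = FALSE,
                       eol = "\n")
      utils::write.csv(as.data.frame(metrics), paths[2], row.names = FALSE,
                       quote = FALSE, eol = "\n")
      utils::write.csv(tests, paths[3], row.names = FALSE, quote = FALSE,
                       eol = "\n")
      jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
    }
    bundle
  }, error = on_fail)
}

# Serializable echo of a pipeline_config (functions/objects flattened).
config_echo <- function(config) {
  gc <- config$gen_config
  list(data_path = config$data_path, metadata_path = config$metadata_path,
       gen_config = if (!is.null(gc)) list(
         n_intractable_dyads = gc$n_intractable_dyads,
         n_tractable_dyads = gc$n_tractable_dyads,
         missing_person_rate = gc$missing_person_rate,
         master_seed = gc$master_seed,
         behavior_params = lapply(gc$behavior_params, unclass),
         emotion_params = lapply(gc$emotion_params, unclass)),
       bin_widths = config$bin_widths, min_count = config$min_count,
       segment_sizes = config$segment_sizes, tail_range = config$tail_range,
       psd_method = config$psd_method,
       test_direction = config$test_direction,
       master_seed = config$master_seed)
}

#' Read a generator configuration from a YAML file
#'
#' The file mirrors [study_gen_config()] field names; `behavior_params`
#' and `emotion_params` may be given once (applied to both groups) or as
#' `intractable:` / `tractable:` sub-maps.
#'
#' @param path YAML file path.
#' @return A [study_gen_config()].
#' @export
read_gen_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(spec, ctor) {
    if (is.null(spec)) return(ctor())
    if (all(c("intractable", "tractable") %in% names(spec)))
      list(intractable = do.call(ctor, spec$intractable),
           tractable = do.call(ctor, spec$tractable))
    else do.call(ctor, spec)
  }
  study_gen_config(
    n_intractable_dyads = y$n_intractable_dyads %||% 11,
    n_tractable_dyads = y$n_tractable_dyads %||% 12,
    behavior_params = build(y$behavior_params, behavior_gen_params),
    emotion_params = build(y$emotion_params, emotion_gen_params),
    missing_person_rate = y$missing_person_rate %||% 0.04,
    master_seed = y$master_seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
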