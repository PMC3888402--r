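#' A single person-session record
#'
#' Holds one person's per-second streams for one dyad session: the behavior
#' state codes (1 = proself, 2 = neutral, 3 = prosocial) and/or the
#' emotional-valence pixels (integers in \[0, 1123\]). Either stream may be
#' absent (`NULL`); absence is distinct from zero.
#'
#' @param dyad_id Dyad identifier (string).
#' @param person Person within the dyad, 1 or 2.
#' @param group `"intractable"`, `"tractable"`, or `"unknown"`.
#' @param behavior Integer vector of codes in \{1, 2, 3\}, or `NULL`.
#' @param emotion Integer vector in \[0, 1123\], or `NULL`.
#' @return An object of class `session_record`.
#' @export
session_record <- function(dyad_id, person, group = "unknown",
                           behavior = NULL, emotion = NULL) {
  stopifnot(is.character(dyad_id), length(dyad_id) == 1L, nzchar(dyad_id))
  if (!is_count(person) || !(person %in% 1:2)) stop("person must be 1 or 2")
  group <- match.arg(group, c("intractable", "tractable", "unknown"))
  structure(list(dyad_id = dyad_id, person = as.integer(person), group = group,
                 behavior = if (!is.null(behavior)) as.integer(behavior),
                 emotion = if (!is.null(emotion)) as.integer(emotion)),
            class = "session_record")
}

#' A validated collection of session records
#'
#' @param records List of [session_record()] objects; `(dyad_id, person)`
#'   pairs must be unique.
#' @param provenance Free-text provenance note.
#' @param warnings Character vector of non-fatal observations (e.g. a dyad
#'   with only one person present).
#' @return An object of class `study_table`.
#' @export
study_table <- function(records, provenance = "", warnings = character(0)) {
  stopifnot(is.list(records))
  for (r in records) if (!inherits(r, "session_record"))
    stop("all records must be session_record objects")
  keys <- vapply(records, function(r) paste(r$dyad_id, r$person), "")
  if (anyDuplicated(keys)) stop("duplicate (dyad_id, person) pair: ",
                                keys[duplicated(keys)][1])
  structure(list(records = records, provenance = provenance,
                 warnings = warnings),
            class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  cat("study_table:", length(x$records), "person-records")
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Validate a session record
#'
#' Checks the coding-domain invariants: behavior codes in \{1, 2, 3\},
#' emotion pixels integer in \[0, 1123\], no missing values inside a present
#' stream. Violations are returned as data, not raised.
#'
#' @param record A [session_record()].
#' @return A data.frame with columns `field`, `index` (0-based second),
#'   `value`, `message`; zero rows when the record is valid.
#' @export
validate_session <- function(record) {
  out <- list()
  add <- function(field, index, value, message)
    out[[length(out) + 1L]] <<- data.frame(field = field, index = index,
                                           value = value, message = message)
  if (!is.null(record$behavior)) {
    bad <- which(is.na(record$behavior) | !(record$behavior %in% 1:3))
    for (i in bad) add("behavior", i - 1L, record$behavior[i],
                       "behavior code must be 1, 2 or 3")
  }
  if (!is.null(record$emotion)) {
    e <- record$emotion
    bad <- which(is.na(e) | e < 0 | e > 1123)
    for (i in bad) add("emotion", i - 1L, e[i],
                       "emotion pixel must be an integer in [0, 1123]")
  }
  if (is.null(record$behavior) && is.null(record$emotion))
    add("record", NA_integer_, NA_integer_, "record has neither stream")
  if (length(out) == 0)
    data.frame(field = character(0), index = integer(0),
               value = integer(0), message = character(0))
  else do.call(rbind, out)
}

#' Write a study to the long CSV dialect
#'
#' Data CSV columns: `dyad,person,second,behavior_code,emotion_pixel` — one
#' row per person-second, seconds 0-based, absent stream values left empty
#' (never zero-filled). Metadata CSV columns: `dyad,group`. Rows are ordered
#' by dyad, person, second, so two writes of the same table are
#' byte-identical.
#'
#' @param study A [study_table()].
#' @param data_path,metadata_path Output file paths.
#' @return Invisibly, `NULL`.
#' @export
write_study <- function(study, data_path, metadata_path) {
  stopifnot(inherits(study, "study_table"))
  rows <- lapply(study$records, function(r) {
    n <- max(length(r$behavior), length(r$emotion))
    if (n == 0) return(NULL)
    pad <- function(v) if (is.null(v)) rep(NA_integer_, n)
      else c(v, rep(NA_integer_, n - length(v)))
    data.frame(dyad = r$dyad_id, person = r$person, second = 0:(n - 1),
               behavior_code = pad(r$behavior), emotion_pixel = pad(r$emotion))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  df <- if (length(rows)) do.call(rbind, rows)
    else data.frame(dyad = character(0), person = integer(0), second = integer(0),
                    behavior_code = integer(0), emotion_pixel = integer(0))
  df <- df[order(df$dyad, df$person, df$second), , drop = FALSE]
  utils::write.csv(df, data_path, row.names = FALSE, na = "", quote = FALSE,
                   eol = "\n")
  meta <- unique(data.frame(
    dyad = vapply(study$records, function(r) r$dyad_id, ""),
    group = vapply(study$records, function(r) r$group, "")))
  meta <- meta[order(meta$dyad), , drop = FALSE]
  utils::write.csv(meta, metadata_path, row.names = FALSE, na = "",
                   quote = FALSE, eol = "\n")
  invisible(NULL)
}

#' Read a study from the long CSV dialect
#'
#' Reads and validates the format written by [write_study()]. Seconds must
#' be contiguous from 0 per person; behavior codes and emotion pixels must
#' lie in their coding domains. A stream that is entirely empty for a person
#' is recorded as absent. Dyads with a single person present are accepted
#' and noted in the returned table's `warnings`.
#'
#' @param data_path,metadata_path Input file paths.
#' @return A [study_table()].
#' @export
read_study <- function(data_path, metadata_path) {
  if (!file.exists(data_path)) stop("data file not found: ", data_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  df <- utils::read.csv(data_path, stringsAsFactors = FALSE,
                        colClasses = c(dyad = "character"))
  need <- c("dyad", "person", "second", "behavior_code", "emotion_pixel")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("data file missing column(s): ", paste(missing_cols, collapse = ", "))
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                          colClasses = c(dyad = "character"))
  if (!all(c("dyad", "group") %in% names(meta)))
    stop("metadata file missing column(s): dyad, group")
  group_of <- stats::setNames(meta$group, meta$dyad)

  records <- list()
  warnings <- character(0)
  if (nrow(df)) {
    df <- df[order(df$dyad, df$person, df$second), , drop = FALSE]
    for (key in unique(paste(df$dyad, df$person, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      sub <- df[df$dyad == parts[1] & df$person == as.integer(parts[2]), ]
      if (!identical(as.integer(sub$second), 0:(nrow(sub) - 1L)))
        stop("non-contiguous seconds for dyad ", parts[1], " person ", parts[2])
      beh <- sub$behavior_code
      emo <- sub$emotion_pixel
      if (all(is.na(beh))) beh <- NULL
      if (all(is.na(emo))) emo <- NULL
      g <- group_of[parts[1]]
      if (is.na(g)) g <- "unknown"
      if (!g %in% c("intractable", "tractable", "unknown"))
        stop("unknown group label '", g, "' for dyad ", parts[1])
      rec <- session_record(parts[1], as.integer(parts[2]), g,
                            behavior = beh, emotion = emo)
      v <- validate_session(rec)
      if (!is.null(beh) && anyNA(beh))
        stop("behavior stream for dyad ", parts[1], " person ", parts[2],
             " has interior gaps")
      if (nrow(v))
        stop("invalid data for dyad ", parts[1], " person ", parts[2], ": ",
             v$message[1], " (second ", v$index[1], ", value ", v$value[1], ")")
      records[[length(records) + 1L]] <- rec
    }
  }
  dyads <- vapply(records, function(r) r$dyad_id, "")
  for (d in unique(dyads)) if (sum(dyads == d) == 1L)
    warnings <- c(warnings, sprintf(
      "dyad %s has only person %d present", d,
      records[[which(dyads == d)]]$person))
  study_table(records, provenance = paste("read from", data_path),
              warnings = warnings)
}
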