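#' Write a recording to CSV
#'
#' Plain-text interchange format: one header row naming the time column and
#' the six channels, '.' decimal separator, full double precision. Optional
#' metadata (seed, configuration hash) is embedded as '#' comment lines above
#' the header.
#'
#' @param recording Recording tibble (`t`, `ch1_dc`, ..., `ch6_emg`).
#' @param path Output file path.
#' @param meta Optional named character/numeric vector written as
#'   `# key=value` comment lines.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, meta = NULL) {
  assert_recording(recording)
  fs <- recording_fs(recording)
  header <- c(
    sprintf("# sampling_rate=%.10g", fs),
    if (length(meta)) sprintf("# %s=%s", names(meta), as.character(meta))
  )
  writeLines(header, path)
  readr::write_csv(recording[c("t", recording_channels)], path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Inverse of [write_recording()]: restores all samples at stored precision
#' and the `sampling_rate` attribute. Malformed files (missing channel
#' columns, ragged rows) raise a parse error naming the offending
#' line/column.
#'
#' @param path CSV file path.
#' @return Recording tibble with `sampling_rate` attribute.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) {
    abort_oculoemg(sprintf("Recording file not found: %s", path), "parse_error")
  }
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0) {
    abort_oculoemg(sprintf("%s: no header row found.", path), "parse_error")
  }
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  missing_cols <- setdiff(c("t", recording_channels), header)
  if (length(missing_cols) > 0) {
    abort_oculoemg(sprintf(
      "%s: header (line %d) is missing column(s): %s",
      path, which(!grepl("^#", lines))[1], paste(missing_cols, collapse = ", ")
    ), "parse_error")
  }
  n_fields <- lengths(strsplit(body, ",", fixed = TRUE))
  bad <- which(n_fields != length(header))
  if (length(bad) > 0) {
    abort_oculoemg(sprintf(
      "%s: ragged row at line %d (%d fields, expected %d).",
      path, bad[1] + length(comments), n_fields[bad[1]], length(header)
    ), "parse_error")
  }
  rec <- readr::read_csv(I(paste(body, collapse = "\n")),
                         col_types = readr::cols(.default = readr::col_double()),
                         progress = FALSE)
  prob <- readr::problems(rec)
  if (nrow(prob) > 0) {
    abort_oculoemg(sprintf(
      "%s: could not parse value at line %d, column %d.",
      path, prob$row[1] + length(comments) + 1L, prob$col[1]
    ), "parse_error")
  }
  rec <- rec[c("t", recording_channels)]
  fs_line <- grep("^# sampling_rate=", comments, value = TRUE)
  attr(rec, "sampling_rate") <- if (length(fs_line)) {
    as.numeric(sub("^# sampling_rate=", "", fs_line[1]))
  } else if (nrow(rec) >= 2) 1 / median(diff(rec$t)) else NA_real_
  rec
}

#' Write events as JSON Lines
#'
#' One event object per line (`label`, `onset`, `duration`, plus any further
#' columns present), suitable for ground-truth schedules and classified event
#' streams.
#'
#' @param events Event tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE, digits = NA,
                     na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read events from JSON Lines
#'
#' @param path JSONL file path (one JSON object per line).
#' @return Event tibble.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    abort_oculoemg(sprintf("Event file not found: %s", path), "parse_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(label = character(0), onset = numeric(0), duration = numeric(0)))
  }
  rows <- lapply(seq_along(lines), function(i) {
    parsed <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(parsed)) {
      abort_oculoemg(sprintf("%s: invalid JSON at line %d.", path, i), "parse_error")
    }
    parsed[vapply(parsed, is.null, logical(1))] <- NA
    as_tibble(parsed)
  })
  bind_rows(rows)
}
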