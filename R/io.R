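# Session-log and feature-matrix input/output.
#
# Session log: JSON Lines. The first line is a header object declaring the
# schema version, device model, screen footprint in mm, and the nominal
# sensor sample rate; every following line is one session set with nested
# arrays for the touch and sensor streams. Ground-truth grip is recomputed
# at read time from the two stored readings.

SCHEMA_VERSION <- 1L

exec_to_list <- function(ex) {
  out <- list(task = ex$task,
              elapsed = ex$elapsed,
              sub_events = as.list(ex$sub_events),
              touch = as.list(ex$touch),
              sensor = as.list(ex$sensor))
  sp <- attr(ex, "spiral")
  if (!is.null(sp)) out$spiral <- unclass(sp)
  out
}

exec_from_list <- function(l) {
  spiral <- NULL
  if (!is.null(l$spiral))
    spiral <- structure(l$spiral, class = "spiral_spec")
  sub <- as.data.frame(l$sub_events, stringsAsFactors = FALSE)
  task_execution(l$task,
                 sub_events = sub,
                 touch = as.data.frame(l$touch, stringsAsFactors = FALSE),
                 sensor = as.data.frame(l$sensor, stringsAsFactors = FALSE),
                 elapsed = l$elapsed, spiral = spiral)
}

#' Write session sets to a JSON Lines log
#'
#' @param sets list of [session_set()] objects.
#' @param path output file.
#' @param screen a [screen_spec()] recorded in the header.
#' @param device device model string for the header.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sets, path, screen = screen_spec(),
                           device = "synthetic") {
  header <- list(schema = "gripsense-session-log",
                 version = SCHEMA_VERSION, device = device,
                 screen_mm = c(screen$width_mm, screen$height_mm),
                 sample_rate_hz = 60)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  for (s in sets) {
    rec <- list(participant_id = s$participant_id, day = s$day,
                set_index = s$set_index,
                grip = list(reading_1 = s$grip$reading_1,
                            reading_2 = s$grip$reading_2),
                hand = s$hand, handedness = s$handedness,
                executions = lapply(s$executions, exec_to_list))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns"), con)
  }
  invisible(path)
}

#' Read session sets from a JSON Lines log
#'
#' Parses and validates every record against the data-model invariants
#' (stream ordering, screen bounds, sub-event counts); ground-truth grip is
#' derived from the two stored readings. Schema or invariant violations name
#' the offending participant/day/set.
#'
#' @param path session-log file written by [write_sessions()].
#' @return List of [session_set()] objects ordered by
#'   (participant_id, day, set_index).
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stopf("no such session log: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1) stopf("empty session log: %s", path)
  header <- jsonlite::fromJSON(lines[[1]])
  if (!identical(header$schema, "gripsense-session-log"))
    stopf("not a gripsense session log (schema header missing): %s", path)
  screen <- screen_spec(header$screen_mm[1], header$screen_mm[2])
  sets <- lapply(lines[-1], function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    need <- c("participant_id", "day", "set_index", "grip", "executions")
    miss <- setdiff(need, names(rec))
    if (length(miss))
      stopf("schema error: record missing field(s) %s",
            paste(miss, collapse = ", "))
    grip <- grip_measurement(rec$grip$reading_1, rec$grip$reading_2)
    execs <- lapply(rec$executions, exec_from_list)
    s <- session_set(rec$participant_id, rec$day, rec$set_index, grip, execs,
                     hand = rec$hand %||% "right",
                     handedness = rec$handedness %||% "dominant")
    validate_session_set(s, screen)
    s
  })
  ord <- order(vapply(sets, `[[`, "", "participant_id"),
               vapply(sets, `[[`, 0L, "day"),
               vapply(sets, `[[`, 0L, "set_index"))
  sets[ord]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a feature matrix to CSV
#'
#' RFC-4180 CSV with a header row: the key columns `participant_id`, `day`,
#' `set_index`, then the snake_case feature columns, with `grip_kg` last.
#' Values are written at full double precision so a round trip is lossless
#' to better than 1e-9 relative tolerance. The feature schema hash is kept
#' as a `#` comment on the first line.
#'
#' @param features a feature data frame from [extract_features()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  stopifnot(is.data.frame(features))
  keys <- c("participant_id", "day", "set_index")
  if (!all(keys %in% names(features)) || !"grip_kg" %in% names(features))
    stopf("feature matrix must carry key columns and grip_kg")
  feat <- setdiff(names(features), c(keys, "grip_kg"))
  df <- features[, c(keys, feat, "grip_kg"), drop = FALSE]
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# gripsense-features v%d scope=%s schema=%s",
                     SCHEMA_VERSION,
                     attr(features, "task_scope") %||% "unknown",
                     feature_schema_hash(c(feat, "grip_kg"))), con)
  writeLines(paste(names(df), collapse = ","), con)
  num <- vapply(names(df), function(nm) is.numeric(df[[nm]]), logical(1))
  cols <- lapply(seq_along(df), function(j) {
    if (num[j]) format(df[[j]], digits = 17, trim = TRUE, scientific = FALSE)
    else as.character(df[[j]])
  })
  if (nrow(df) > 0)
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV file.
#' @return Feature data frame with `task_scope` and `schema_hash` attributes.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stopf("no such feature matrix: %s", path)
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1 else 0
  df <- utils::read.csv(path, skip = skip, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (skip == 1) {
    m <- regmatches(first, regexec("scope=(\\S+) schema=(\\S+)", first))[[1]]
    if (length(m) == 3) {
      attr(df, "task_scope") <- m[2]
      attr(df, "schema_hash") <- m[3]
    }
  }
  df
}

# Stable fingerprint of an ordered feature-name list.
feature_schema_hash <- function(names) fnv1a(names)
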