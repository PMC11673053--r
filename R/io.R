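# Delimited-text session formats. All files open with `# key=value` comment
# headers carrying session metadata, followed by a normal header line.

meta_header <- function(meta, extra = character(0)) {
  c(sprintf("# mouse=%s", meta$mouse),
    sprintf("# phase=%s", meta$phase),
    sprintf("# day=%d", meta$day),
    sprintf("# test=%d", meta$test),
    extra)
}

parse_meta <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  parts <- strsplit(kv, "=", fixed = TRUE)
  vals <- lapply(parts, function(p) paste(p[-1], collapse = "="))
  names(vals) <- vapply(parts, `[[`, "", 1L)
  vals
}

read_commented <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  head_meta <- lines[cumprod(is_meta) == 1]
  body <- lines[cumprod(is_meta) != 1]
  list(meta = parse_meta(head_meta), body = body)
}

#' Write a behavioral event log as TSV
#'
#' @param log An `event_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events
  val <- ifelse(is.na(ev$value), "", formatC(ev$value, format = "g"))
  lines <- c(meta_header(log$meta),
             "time_s\tevent\tvalue",
             sprintf("%.4f\t%s\t%s", ev$time_s, ev$event, val))
  writeLines(lines, path)
  invisible(path)
}

#' Read a behavioral event log
#'
#' Parses the TSV event-log dialect written by [write_event_log()]:
#' `# key=value` metadata comments, then columns `time_s`, `event`,
#' `value`. Validates that the metadata names the mouse, phase, day and
#' test, that timestamps are non-decreasing, and that tone on/off markers
#' alternate; an unmatched `tone_on` at end of file is auto-closed at the
#' session end with a warning.
#'
#' @param path Path to the TSV file.
#' @return An `event_log`.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parsed <- read_commented(path)
  meta <- parsed$meta
  need <- c("mouse", "phase", "day", "test")
  if (!all(need %in% names(meta)))
    stop("event log metadata header must declare mouse, phase, day, test",
         call. = FALSE)
  body <- parsed$body
  if (!length(body) || !grepl("^time_s\t", body[1]))
    stop("missing 'time_s\\tevent\\tvalue' header line", call. = FALSE)
  body <- body[-1]
  body <- body[nzchar(body)]
  if (length(body)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    ok <- lengths(fields) %in% 2:3
    if (any(!ok))
      warning(sum(!ok), " malformed event line(s) dropped", call. = FALSE)
    fields <- fields[ok]
    ev <- data.frame(
      time_s = as.numeric(vapply(fields, `[[`, "", 1L)),
      event = vapply(fields, `[[`, "", 2L),
      value = as.numeric(vapply(fields, function(f)
        if (length(f) >= 3L && nzchar(f[3])) f[3] else NA_character_, "")),
      stringsAsFactors = FALSE)
  } else {
    ev <- data.frame(time_s = numeric(0), event = character(0),
                     value = numeric(0), stringsAsFactors = FALSE)
  }
  if (any(is.na(ev$time_s)))
    stop("non-numeric timestamps in event log", call. = FALSE)
  if (any(diff(ev$time_s) < -1e-6))
    stop("event timestamps decrease beyond tolerance", call. = FALSE)
  tones <- ev$event[ev$event %in% c("tone_on", "tone_off")]
  if (length(tones)) {
    expect <- rep(c("tone_on", "tone_off"), length.out = length(tones))
    if (!all(tones == expect))
      stop("tone_on/tone_off markers do not alternate", call. = FALSE)
    if (tones[length(tones)] == "tone_on") {
      warning("unmatched tone_on at end of file; auto-closing at session end",
              call. = FALSE)
      ev <- rbind(ev, data.frame(time_s = max(ev$time_s), event = "tone_off",
                                 value = NA_real_, stringsAsFactors = FALSE))
    }
  }
  new_event_log(ev, meta$mouse, meta$phase,
                as.integer(meta$day), as.integer(meta$test))
}

#' Write a photometry recording as CSV
#'
#' @param rec A `photometry_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_photometry <- function(rec, path) {
  stopifnot(inherits(rec, "photometry_recording"))
  extra <- c(sprintf("# sample_rate_hz=%g", rec$sample_rate_hz),
             sprintf("# sync_offset_s=%g", rec$sync_offset_s))
  lines <- c(meta_header(rec$meta, extra),
             "time_s,F405,F465",
             sprintf("%.4f,%.6f,%.6f", rec$time_s, rec$F405, rec$F465))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-channel photometry recording
#'
#' Expects the CSV dialect written by [write_photometry()] (metadata
#' comments, then `time_s,F405,F465`). The sampling grid must be uniform;
#' timestamp jitter below 1% of the sampling interval is accepted with a
#' warning, larger jitter is an error. The sync offset from the metadata is
#' applied to the time axis so behavior and photometry share a timebase.
#'
#' @param path Path to the CSV file.
#' @return A `photometry_recording`.
#' @export
read_photometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parsed <- read_commented(path)
  meta <- parsed$meta
  body <- parsed$body
  if (!length(body)) stop("empty photometry file", call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  need <- c("time_s", "F405", "F465")
  if (!all(need %in% names(df)))
    stop("photometry file must have columns time_s, F405, F465",
         call. = FALSE)
  if (nrow(df) < 2)
    stop("photometry recording too short to analyze (need >= 2 samples)",
         call. = FALSE)
  dts <- diff(df$time_s)
  dt_med <- stats::median(dts)
  if (dt_med <= 0) stop("non-increasing photometry timestamps", call. = FALSE)
  jit <- max(abs(dts - dt_med)) / dt_med
  if (jit > 0.01)
    stop("photometry sampling jitter exceeds 1% of the sampling interval",
         call. = FALSE)
  if (jit > 1e-4)
    warning("photometry timestamps jittered within tolerance; using median rate",
            call. = FALSE)
  rate <- if (!is.null(meta$sample_rate_hz))
    as.numeric(meta$sample_rate_hz) else 1 / dt_med
  offset <- if (!is.null(meta$sync_offset_s))
    as.numeric(meta$sync_offset_s) else 0
  structure(list(time_s = df$time_s + offset, F405 = df$F405,
                 F465 = df$F465, sample_rate_hz = rate,
                 sync_offset_s = offset,
                 meta = list(mouse = meta$mouse %||% NA_character_,
                             phase = meta$phase %||% NA_character_,
                             day = as.integer(meta$day %||% NA),
                             test = as.integer(meta$test %||% NA)),
                 provenance = list(file = path)),
            class = "photometry_recording")
}

#' Write a pose track in the two-header tracking-export layout
#'
#' First header row names the body part for each column triplet, the second
#' the coordinate (`x`, `y`, `likelihood`), matching common pose-estimation
#' exports. A `# frame_rate_hz=` comment precedes the headers.
#'
#' @param pose A `pose_track`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pose <- function(pose, path) {
  stopifnot(inherits(pose, "pose_track"))
  parts <- pose$parts
  wide <- lapply(parts, function(p) {
    d <- pose$data[pose$data$part == p, c("x", "y", "likelihood")]
    rownames(d) <- NULL
    d
  })
  frames <- sort(unique(pose$data$frame))
  h1 <- paste(c("bodypart", rep(parts, each = 3)), collapse = ",")
  h2 <- paste(c("coord", rep(c("x", "y", "likelihood"), length(parts))),
              collapse = ",")
  mat <- do.call(cbind, wide)
  rows <- apply(cbind(frames, round(mat, 3)), 1L,
                function(r) paste(r, collapse = ","))
  lines <- c(meta_header(pose$meta,
                         sprintf("# frame_rate_hz=%g", pose$frame_rate_hz)),
             h1, h2, rows)
  writeLines(lines, path)
  invisible(path)
}

#' Write a full simulated session to disk
#'
#' Emits `events.tsv`, `photometry.csv`, `pose.csv` (if given), and the
#' ground-truth sidecars `truth_transients.csv` and `truth_trials.csv` into
#' `out_dir`. These round-trip losslessly (within print precision) through
#' [read_event_log()], [read_photometry()] and [read_pose()].
#'
#' @param log An `event_log`.
#' @param recording A `photometry_recording`, or `NULL` to skip.
#' @param pose A `pose_track`, or `NULL` to skip.
#' @param truth A `sim_truth`, or `NULL` to skip the sidecars.
#' @param out_dir Output directory; created if needed.
#' @return Character vector of paths written, invisibly.
#' @export
write_session <- function(log, recording = NULL, pose = NULL, truth = NULL,
                          out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- character(0)
  p <- file.path(out_dir, "events.tsv")
  write_event_log(log, p); paths <- c(paths, p)
  if (!is.null(recording)) {
    p <- file.path(out_dir, "photometry.csv")
    write_photometry(recording, p); paths <- c(paths, p)
  }
  if (!is.null(pose)) {
    p <- file.path(out_dir, "pose.csv")
    write_pose(pose, p); paths <- c(paths, p)
  }
  if (!is.null(truth)) {
    tr <- truth$transients
    p <- file.path(out_dir, "truth_transients.csv")
    utils::write.csv(tr[, intersect(c("time_s", "amplitude",
                                      "linked_behavior", "trial_idx"),
                                    names(tr))],
                     p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
    p <- file.path(out_dir, "truth_trials.csv")
    utils::write.csv(truth$trials, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
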