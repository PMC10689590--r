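#' Frame schedule for a dynamic PET acquisition
#'
#' A frame schedule holds the start and end times (minutes post-injection) of
#' each reconstruction frame of a dynamic PET recording, together with the
#' arithmetic mid-time of every frame, which is the abscissa used by all
#' regression steps. Frames must be strictly increasing, non-overlapping, and
#' are truncated at 67 minutes post-injection: a frame whose end exceeds
#' 67 min is clipped to end at 67 min (its value is kept unchanged), and
#' frames starting at or after 67 min are dropped.
#'
#' @param start numeric vector of frame start times, minutes post-injection.
#' @param end numeric vector of frame end times, minutes; same length as
#'   `start`.
#' @param truncate_at upper limit of the recording in minutes (default 67);
#'   set to `Inf` to disable truncation.
#' @return An object of class `frame_schedule`: a list with elements `start`,
#'   `end` and `mid` (arithmetic frame midpoints, minutes).
#' @examples
#' sched <- frame_schedule(0:2, 1:3)
#' sched$mid  # 0.5 1.5 2.5
#' @export
frame_schedule <- function(start, end, truncate_at = 67) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != length(end)) {
    stop("'start' and 'end' must have the same length", call. = FALSE)
  }
  if (length(start) < 1L) stop("schedule needs at least one frame", call. = FALSE)
  if (anyNA(start) || anyNA(end) || any(!is.finite(start)) || any(!is.finite(end))) {
    stop("frame times must be finite", call. = FALSE)
  }
  keep <- start < truncate_at
  start <- start[keep]
  end <- end[keep]
  if (length(start) < 1L) stop("no frames remain below the truncation limit", call. = FALSE)
  end <- pmin(end, truncate_at)
  if (any(diff(start) <= 0)) {
    stop("frame_start must be strictly increasing", call. = FALSE)
  }
  if (any(end <= start)) {
    bad <- which(end <= start)[1L]
    stop(sprintf("frame_end must exceed frame_start (frame %d)", bad), call. = FALSE)
  }
  n <- length(start)
  if (n > 1L && any(end[-n] > start[-1L] + 1e-9)) {
    bad <- which(end[-n] > start[-1L] + 1e-9)[1L]
    stop(sprintf("frames overlap (frame %d ends after frame %d starts)", bad, bad + 1L),
         call. = FALSE)
  }
  structure(list(start = start, end = end, mid = (start + end) / 2),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("frame_schedule: %d frames, %.3g-%.3g min\n",
              length(x$start), x$start[1L], x$end[length(x$end)]))
  invisible(x)
}

#' @export
length.frame_schedule <- function(x) length(x$start)

#' Framed time-activity curve
#'
#' The universal data object of the package: a decay-corrected radioactivity
#' concentration per frame on a [frame_schedule()]. Units are carried as an
#' opaque string and never converted; all computations require internally
#' consistent units across blood and tissue curves.
#'
#' @param schedule a [frame_schedule()].
#' @param value numeric vector of concentrations, one per frame; finite and
#'   non-negative (pre-appearance frames may be exactly zero).
#' @param label curve label, one of `"blood"`, `"GM"`, `"WM"`, `"other"`.
#' @param subject_id opaque subject identifier string.
#' @param units free-text units string (e.g. `"kBq/mL"`).
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, value, label = c("other", "blood", "GM", "WM"),
                subject_id = "", units = "arbitrary") {
  if (!inherits(schedule, "frame_schedule")) {
    stop("'schedule' must be a frame_schedule", call. = FALSE)
  }
  label <- match.arg(label)
  value <- as.numeric(value)
  if (length(value) != length(schedule$start)) {
    stop(sprintf("value length (%d) must equal frame count (%d)",
                 length(value), length(schedule$start)), call. = FALSE)
  }
  if (anyNA(value) || any(!is.finite(value))) {
    stop("all TAC values must be finite", call. = FALSE)
  }
  if (any(value < 0)) {
    bad <- which(value < 0)[1L]
    stop(sprintf("negative concentration in frame %d", bad), call. = FALSE)
  }
  structure(list(schedule = schedule, value = value, label = label,
                 subject_id = as.character(subject_id),
                 units = as.character(units)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("tac [%s]%s: %d frames, %.3g-%.3g min, peak %.4g %s\n",
              x$label,
              if (nzchar(x$subject_id)) paste0(" ", x$subject_id) else "",
              length(x$value), x$schedule$start[1L],
              x$schedule$end[length(x$value)], max(x$value), x$units))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(frame_start_min = x$schedule$start,
             frame_end_min = x$schedule$end,
             mid_time_min = x$schedule$mid,
             value = x$value)
}

# indices of frames whose mid-time lies in the closed window [lo, hi]
frames_in_window <- function(x, lo, hi) {
  which(x$schedule$mid >= lo & x$schedule$mid <= hi)
}

#' Read a time-activity curve from CSV
#'
#' Expects a comma-separated file with header columns `frame_start_min`,
#' `frame_end_min`, `value` (dot decimal, UTF-8). Comment lines starting with
#' `#` may carry `key: value` metadata (`subject_id`, `label`, `units`). Any
#' frame extending past 67 min post-injection is truncated: its end time is
#' clipped to 67 and its value kept as-is.
#'
#' @param path path to the CSV file.
#' @param label curve label override; if `NULL`, taken from file metadata,
#'   defaulting to `"other"`.
#' @return A [tac()] object.
#' @seealso [write_tac()]
#' @export
read_tac <- function(path, label = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ml))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("TAC file has no data rows", call. = FALSE)
  dat <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  required <- c("frame_start_min", "frame_end_min", "value")
  if (!all(required %in% names(dat))) {
    stop(sprintf("malformed TAC header: need columns %s",
                 paste(required, collapse = ", ")), call. = FALSE)
  }
  if (nrow(dat) < 3L) stop("TAC needs at least 3 frames", call. = FALSE)
  if (any(dat$value < 0, na.rm = TRUE)) {
    bad <- which(dat$value < 0)[1L]
    stop(sprintf("negative value in row %d of %s", bad, path), call. = FALSE)
  }
  sched <- frame_schedule(dat$frame_start_min, dat$frame_end_min)
  if (is.null(label)) label <- meta$label %||% "other"
  tac(sched, dat$value[seq_along(sched$start)], label = label,
      subject_id = meta$subject_id %||% "",
      units = meta$units %||% "arbitrary")
}

#' Write a time-activity curve to CSV
#'
#' Writes the dialect read by [read_tac()], with full float precision and
#' metadata comment lines for subject id, label and units.
#'
#' @param x a [tac()] object.
#' @param path destination file path.
#' @return Invisibly, `path`.
#' @export
write_tac <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop(sprintf("cannot write to %s: %s", path, conditionMessage(e)), call. = FALSE)
  })
  on.exit(close(con))
  writeLines(c(sprintf("# subject_id: %s", x$subject_id),
               sprintf("# label: %s", x$label),
               sprintf("# units: %s", x$units),
               "frame_start_min,frame_end_min,value"), con)
  writeLines(sprintf("%s,%s,%s",
                     format(x$schedule$start, digits = 17, trim = TRUE, scientific = FALSE),
                     format(x$schedule$end, digits = 17, trim = TRUE, scientific = FALSE),
                     format(x$value, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' Read a subject manifest
#'
#' A manifest is a CSV with columns `subject_id`, `age_years`, `site`,
#' `idif_path`, `gm_path`, `wm_path`; TAC paths are resolved relative to the
#' manifest's directory unless absolute.
#'
#' @param path manifest CSV path.
#' @return A data.frame, one row per subject.
#' @export
read_manifest <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "age_years", "site", "idif_path", "gm_path", "wm_path")
  if (!all(required %in% names(dat))) {
    stop(sprintf("malformed manifest: need columns %s",
                 paste(required, collapse = ", ")), call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  for (col in c("idif_path", "gm_path", "wm_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", dat[[col]])
    dat[[col]][rel] <- file.path(base, dat[[col]][rel])
  }
  dat
}

#' Assemble a subject record from a manifest row
#'
#' @param row one-row data.frame as returned by [read_manifest()].
#' @return A `subject_record`: list with `subject_id`, `age`, `site`, and the
#'   three TACs `idif`, `gm`, `wm` sharing one schedule.
#' @export
read_subject <- function(row) {
  idif <- read_tac(row$idif_path, label = "blood")
  gm <- read_tac(row$gm_path, label = "GM")
  wm <- read_tac(row$wm_path, label = "WM")
  subject_record(row$subject_id, row$age_years, row$site, idif, gm, wm)
}

#' Construct a subject record
#'
#' @param subject_id opaque identifier.
#' @param age age in years (> 0).
#' @param site acquisition site name.
#' @param idif blood [tac()].
#' @param gm,wm tissue [tac()]s; all three must share one frame schedule.
#' @return A list of class `subject_record`.
#' @export
subject_record <- function(subject_id, age, site, idif, gm, wm) {
  if (!is.numeric(age) || age <= 0) stop("age must be positive", call. = FALSE)
  same <- function(a, b) {
    length(a$schedule$mid) == length(b$schedule$mid) &&
      max(abs(a$schedule$mid - b$schedule$mid)) < 1e-9
  }
  if (!same(idif, gm) || !same(idif, wm)) {
    stop("idif, gm and wm must share one frame schedule", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), age = as.numeric(age),
                 site = as.character(site), idif = idif, gm = gm, wm = wm),
            class = "subject_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
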