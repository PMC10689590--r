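#' Site frame-schedule templates
#'
#' Frame schedules emulating the two acquisition protocols supported out of
#' the box, both truncated at 67 min post-injection.
#'
#' * `"aarhus"`: 0.1-min frames for the first minute, 0.5-min frames to
#'   6 min, 2-min frames to 22 min, then 5-min frames to 67 min (37 frames).
#' * `"bern"`: 0.05-min frames to 1.5 min, 0.25-min frames to 5 min, 1-min
#'   frames to 17 min, then 5-min frames to 67 min (66 frames).
#'
#' Both templates end with three 5-min frames spanning 52-67 min, the window
#' over which the terminal arterial concentration is averaged.
#'
#' @param site `"aarhus"` or `"bern"` (case-insensitive).
#' @return A [frame_schedule()].
#' @export
site_schedule <- function(site = c("aarhus", "bern")) {
  site <- match.arg(tolower(site), c("aarhus", "bern"))
  if (site == "aarhus") {
    start <- c(seq(0, 0.9, by = 0.1),
               seq(1, 5.5, by = 0.5),
               seq(6, 20, by = 2),
               seq(22, 62, by = 5))
    width <- c(rep(0.1, 10), rep(0.5, 10), rep(2, 8), rep(5, 9))
  } else {
    start <- c(seq(0, 1.45, by = 0.05),
               seq(1.5, 4.75, by = 0.25),
               seq(5, 16, by = 1),
               seq(17, 62, by = 5))
    width <- c(rep(0.05, 30), rep(0.25, 14), rep(1, 12), rep(5, 10))
  }
  frame_schedule(start, start + width)
}
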