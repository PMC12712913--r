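# Behavioral scoring from pre-scored event tables: Y-maze spontaneous
# alternation, forced-swim immobility and open-field/EPM zone summaries.

#' Y-maze spontaneous alternation percentage
#'
#' An alternation is a window of three consecutive arm entries visiting
#' three distinct arms; the score is
#' `100 * alternations / (total entries - 2)`.
#'
#' @param entries character (or factor) vector of arm labels in entry order;
#'   at least 3 entries.
#' @return alternation percentage in `[0, 100]`.
#' @export
alternation_percentage <- function(entries) {
  entries <- as.character(entries)
  n <- length(entries)
  if (n < 3L) stopf("need at least 3 arm entries, got %d", n)
  wins <- vapply(seq_len(n - 2L), function(i)
    length(unique(entries[i:(i + 2L)])) == 3L, logical(1L))
  100 * sum(wins) / (n - 2L)
}

# intersect bouts with a window, dropping empties
clip_bouts <- function(start, stop, window) {
  s <- pmax(start, window[1])
  e <- pmin(stop, window[2])
  keep <- e > s
  data.frame(start = s[keep], stop = e[keep])
}

# union of intervals -> merged non-overlapping bouts
merge_bouts <- function(start, stop) {
  if (!length(start)) return(data.frame(start = numeric(), stop = numeric()))
  o <- order(start, stop)
  start <- start[o]; stop <- stop[o]
  ms <- start[1L]; me <- stop[1L]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) me <- max(me, stop[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[i]; me <- stop[i] }
  }
  data.frame(start = c(out_s, ms), stop = c(out_e, me))
}

#' Forced-swim immobility summary
#'
#' Clips immobility bouts to the scoring window (by default the last four
#' minutes of a six-minute test, 120-360 s) and reports bout count and total
#' immobile time.
#'
#' @param events an [event_table()] containing bouts labeled `label`.
#' @param window scoring window `c(start, end)` in seconds.
#' @param label event label to score (default `"immobile"`).
#' @return list with `count` (bouts intersecting the window) and
#'   `duration` (summed clipped time, s).
#' @export
immobility_summary <- function(events, window = c(120, 360),
                               label = "immobile") {
  stopifnot(inherits(events, "event_table"))
  d <- events[events$label == label, , drop = FALSE]
  cl <- clip_bouts(d$start, d$stop, window)
  list(count = nrow(cl), duration = sum(cl$stop - cl$start))
}

#' Zone occupancy summary
#'
#' Counts entries into a zone (overlapping bouts are merged first, so
#' double-scored overlaps are one entry) and the total time in the zone.
#' Mean speed is reported when the event table carries a `speed` column
#' (bout-duration-weighted mean).
#'
#' @param events an [event_table()].
#' @param zone zone label (e.g. `"center"`, `"open_arm"`).
#' @return list with `entries`, `time` (s) and `mean_speed` (or `NA`).
#' @export
zone_summary <- function(events, zone) {
  stopifnot(inherits(events, "event_table"))
  d <- events[events$label == zone, , drop = FALSE]
  m <- merge_bouts(d$start, d$stop)
  speed <- if (!is.null(events$speed) && nrow(d)) {
    dur <- d$stop - d$start
    if (sum(dur) > 0) sum(d$speed * dur) / sum(dur) else mean(d$speed)
  } else NA_real_
  list(entries = nrow(m), time = sum(m$stop - m$start), mean_speed = speed)
}
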