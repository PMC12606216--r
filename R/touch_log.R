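#' Validate a touch-event table
#'
#' Touch-event logs carry one record per screen contact sample: `t_ms`
#' (milliseconds since session start, non-decreasing), `x`, `y` (normalised
#' coordinates in \[0, 1\]), `phase` (`"down"`, `"move"` or `"up"`) and an
#' optional hardware `touch_id` (integer, `NA` when the device did not track
#' contacts).
#'
#' @param events data.frame of touch events.
#' @return The validated data.frame (with a `touch_id` column added, all-`NA`,
#'   if absent), invisibly usable downstream.
#' @export
validate_touch_events <- function(events) {
  events <- as.data.frame(events)
  req <- c("t_ms", "x", "y", "phase")
  if (!all(req %in% names(events)))
    stop("touch events need columns: ", paste(req, collapse = ", "))
  if (!"touch_id" %in% names(events))
    events$touch_id <- rep(NA_integer_, nrow(events))
  if (!nrow(events)) return(events)
  if (any(!is.finite(events$t_ms)) || any(events$t_ms < 0))
    stop("t_ms must be finite and >= 0")
  if (is.unsorted(events$t_ms))
    stop("touch events must be non-decreasing in t_ms")
  if (any(!is.finite(events$x)) || any(!is.finite(events$y)) ||
      any(events$x < 0 | events$x > 1) || any(events$y < 0 | events$y > 1))
    stop("x and y must lie in [0, 1] (normalise device points first)")
  bad <- setdiff(unique(events$phase), c("down", "move", "up"))
  if (length(bad)) stop("unknown phase value(s): ", paste(bad, collapse = ", "))
  events
}

#' Read or write a touch-event log
#'
#' The canonical log dialect is CSV with header `t_ms,x,y,phase,touch_id`;
#' `touch_id` may be blank. Coordinates are normalised; logs recorded in
#' device points can be converted by dividing by the zone map's
#' `screen_size` before assembly.
#'
#' @param path file path.
#' @return `read_touch_log()` returns a validated data.frame;
#'   `write_touch_log()` returns `path` invisibly.
#' @export
read_touch_log <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(t_ms = "numeric", x = "numeric",
                                       y = "numeric", phase = "character",
                                       touch_id = "integer"))
  validate_touch_events(ev)
}

#' @rdname read_touch_log
#' @param events validated touch-event data.frame.
#' @export
write_touch_log <- function(events, path) {
  events <- validate_touch_events(events)
  utils::write.csv(events[c("t_ms", "x", "y", "phase", "touch_id")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}
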