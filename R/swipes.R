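#' Predict the next contact location of a swipe in progress
#'
#' Used while assembling multi-touch logs without hardware contact tracking:
#' each unassigned contact is matched to the active swipe whose predicted next
#' location is closest. With four or more previous contacts the prediction is
#' the unique interpolating cubic through the last four contacts,
#' parameterised by timestamp and extrapolated to the incoming event's time
#' (for contacts lying on a polynomial trajectory of degree <= 3 this
#' reproduces the trajectory exactly). When a cubic cannot be constructed
#' (fewer than four contacts, or coincident timestamps) linear extrapolation
#' from the last two contacts is used; a single contact predicts its own
#' position.
#'
#' @param recent_contacts data.frame with columns `t_ms`, `x`, `y`, time
#'   ordered, at least one row.
#' @param t_new timestamp (ms) at which to predict.
#' @return Numeric `c(x, y)`.
#' @export
predict_next_location <- function(recent_contacts, t_new) {
  n <- nrow(recent_contacts)
  if (is.null(n) || n < 1) stop("need at least one previous contact")
  ts <- recent_contacts$t_ms
  xs <- recent_contacts$x
  ys <- recent_contacts$y
  if (n == 1) return(c(xs, ys))

  linear <- function() {
    dt <- ts[n] - ts[n - 1]
    if (dt <= 0) return(c(xs[n], ys[n]))
    h <- (t_new - ts[n]) / dt
    c(xs[n] + h * (xs[n] - xs[n - 1]), ys[n] + h * (ys[n] - ys[n - 1]))
  }
  if (n < 4) return(linear())

  i <- (n - 3):n
  tau <- (ts[i] - ts[n]) / 1000   # centred, in seconds, for conditioning
  if (anyDuplicated(tau)) return(linear())
  V <- outer(tau, 0:3, `^`)
  coef <- tryCatch(solve(V, cbind(xs[i], ys[i])), error = function(e) NULL)
  if (is.null(coef)) return(linear())
  tn <- (t_new - ts[n]) / 1000
  as.numeric(tn^(0:3) %*% coef)
}

#' Assemble raw touch contacts into swipes
#'
#' A swipe is a continuous screen contact: it begins at a touch-down event and
#' ends at the first subsequent touch-up assigned to it. When the log carries
#' hardware `touch_id`s these are trusted directly. Otherwise each `move`/`up`
#' event is assigned to the active swipe whose predicted next location (see
#' [predict_next_location()]) is nearest in Euclidean distance. A `down` event
#' always opens a new swipe. A `move` event farther than `max_assign_dist`
#' from every prediction starts a recovery swipe (guarding against dropped
#' up-events chaining distant contacts); an `up` event with no active swipe is
#' dropped with a warning.
#'
#' @param events touch-event data.frame (see [validate_touch_events()]).
#' @param use_touch_id `"auto"` (use ids when fully present), `"always"`, or
#'   `"never"` (force predictive assignment).
#' @param max_assign_dist maximum normalised distance for predictive
#'   assignment of `move` events (default 0.25).
#' @return An object of class `swipes`: a list with `events` (the input rows,
#'   time ordered, plus a `swipe_id` column), `n_swipes`, and `dropped` (count
#'   of discarded events). Swipe ids are numbered 1..n by swipe start time.
#' @export
assemble_swipes <- function(events, use_touch_id = c("auto", "always", "never"),
                            max_assign_dist = 0.25) {
  use_touch_id <- match.arg(use_touch_id)
  events <- validate_touch_events(events)
  if (!nrow(events)) {
    return(structure(list(events = cbind(events, swipe_id = integer(0)),
                          n_swipes = 0L, dropped = 0L), class = "swipes"))
  }
  ids_ok <- !any(is.na(events$touch_id))
  if (use_touch_id == "always" && !ids_ok)
    stop("use_touch_id = 'always' but touch_id has missing values")
  use_ids <- switch(use_touch_id, auto = ids_ok, always = TRUE, never = FALSE)

  if (use_ids) res <- .assemble_by_id(events) else
    res <- .assemble_by_prediction(events, max_assign_dist)
  ev <- res$events

  # renumber swipes 1..n by start time
  starts <- tapply(ev$t_ms, ev$swipe_id, min)
  # ties in start time keep original opening order
  ord <- names(starts)[order(as.numeric(starts), as.numeric(names(starts)))]
  remap <- stats::setNames(seq_along(ord), ord)
  ev$swipe_id <- as.integer(remap[as.character(ev$swipe_id)])
  structure(list(events = ev, n_swipes = length(ord), dropped = res$dropped),
            class = "swipes")
}

.assemble_by_id <- function(events) {
  events$.row <- seq_len(nrow(events))
  dropped <- 0L
  pieces <- lapply(split(events, events$touch_id), function(g) {
    # a down opens a new swipe; a segment may also start with a move
    # (recovery) if the log lost the down event
    opens <- g$phase == "down" |
      c(TRUE, g$phase[-length(g$phase)] == "up")
    g$.seg <- cumsum(opens)
    g
  })
  ev <- do.call(rbind, pieces)
  ev <- ev[order(ev$.row), , drop = FALSE]
  key <- paste(ev$touch_id, ev$.seg, sep = "/")
  # drop segments that are a bare 'up' with no opening contact
  seg_first_phase <- tapply(ev$phase, key, function(p) p[1])
  seg_len <- tapply(key, key, length)
  bare_up <- names(seg_first_phase)[seg_first_phase == "up" & seg_len == 1]
  if (length(bare_up)) {
    warning(length(bare_up), " up event(s) with no active swipe dropped")
    dropped <- sum(key %in% bare_up)
    ev <- ev[!key %in% bare_up, , drop = FALSE]
    key <- key[!key %in% bare_up]
  }
  ev$swipe_id <- as.integer(factor(key, levels = unique(key)))
  ev$.row <- NULL; ev$.seg <- NULL
  rownames(ev) <- NULL
  list(events = ev, dropped = dropped)
}

.assemble_by_prediction <- function(events, max_assign_dist) {
  n <- nrow(events)
  swipe_id <- integer(n)
  dropped <- 0L
  next_id <- 0L
  # active swipes: parallel lists of id and recent-contact matrices (t, x, y)
  act_id <- integer(0)
  act_recent <- list()

  open_swipe <- function(i) {
    next_id <<- next_id + 1L
    act_id <<- c(act_id, next_id)
    act_recent[[length(act_id)]] <<-
      matrix(c(events$t_ms[i], events$x[i], events$y[i]), 1)
    swipe_id[i] <<- next_id
  }

  for (i in seq_len(n)) {
    ph <- events$phase[i]
    if (ph == "down") {
      open_swipe(i)
      next
    }
    if (!length(act_id)) {
      if (ph == "move") open_swipe(i) else {
        warning("up event at t=", events$t_ms[i],
                " with no active swipe dropped")
        swipe_id[i] <- NA_integer_
        dropped <- dropped + 1L
      }
      next
    }
    d <- vapply(act_recent, function(m) {
      p <- predict_next_location(
        data.frame(t_ms = m[, 1], x = m[, 2], y = m[, 3]), events$t_ms[i])
      sqrt((p[1] - events$x[i])^2 + (p[2] - events$y[i])^2)
    }, numeric(1))
    k <- which.min(d)
    if (ph == "move" && d[k] > max_assign_dist) {
      open_swipe(i)   # recovery swipe: nothing plausibly continues here
      next
    }
    swipe_id[i] <- act_id[k]
    m <- rbind(act_recent[[k]],
               c(events$t_ms[i], events$x[i], events$y[i]))
    if (nrow(m) > 4) m <- m[(nrow(m) - 3):nrow(m), , drop = FALSE]
    act_recent[[k]] <- m
    if (ph == "up") {   # contact removed: swipe complete
      act_id <- act_id[-k]
      act_recent[[k]] <- NULL
    }
  }
  ev <- events
  ev$swipe_id <- swipe_id
  keep <- !is.na(swipe_id)
  list(events = ev[keep, , drop = FALSE], dropped = dropped)
}

#' @export
print.swipes <- function(x, ...) {
  cat("<swipes>", x$n_swipes, "swipes,", nrow(x$events), "contacts",
      if (x$dropped) paste0("(", x$dropped, " dropped)"), "\n")
  invisible(x)
}

#' Per-swipe summary of an assembled session
#'
#' @param sw a `swipes` object from [assemble_swipes()].
#' @return data.frame with one row per swipe: `swipe_id`, `start_t`, `end_t`,
#'   `n_contacts`, and first/last contact coordinates `x_first`, `y_first`,
#'   `x_last`, `y_last`.
#' @export
swipe_summary <- function(sw) {
  ev <- sw$events
  if (!nrow(ev))
    return(data.frame(swipe_id = integer(0), start_t = numeric(0),
                      end_t = numeric(0), n_contacts = integer(0),
                      x_first = numeric(0), y_first = numeric(0),
                      x_last = numeric(0), y_last = numeric(0)))
  o <- order(ev$swipe_id, ev$t_ms, seq_len(nrow(ev)))
  ev <- ev[o, , drop = FALSE]
  first <- !duplicated(ev$swipe_id)
  last <- !duplicated(ev$swipe_id, fromLast = TRUE)
  data.frame(
    swipe_id = ev$swipe_id[first],
    start_t = ev$t_ms[first], end_t = ev$t_ms[last],
    n_contacts = as.integer(table(ev$swipe_id)[as.character(ev$swipe_id[first])]),
    x_first = ev$x[first], y_first = ev$y[first],
    x_last = ev$x[last], y_last = ev$y[last])
}
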