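#' Strategy profile for a simulated gameplay session
#'
#' Describes one participant's 5-minute session as a mix of gameplay
#' behaviours. Each food cycle places an item on the serving table which
#' splits into four pieces; a cycle is played either directly (each piece
#' dragged from the food zone to a distinct character) or by stacking (all
#' four pieces dragged to one plate, then three inter-plate redistribution
#' swipes even the food out). Off-task swipes, taps and within-zone swipes
#' model play unrelated to food delivery.
#'
#' @param n_cycles food cycles per session (default 12, roughly a 5-minute
#'   session at the game's pace).
#' @param p_direct in a direct cycle, the probability a piece is dropped on
#'   the plate itself rather than elsewhere in the character's snap-to-plate
#'   region (both are food deliveries; default 0.9).
#' @param p_stack probability a cycle is played stack-then-redistribute
#'   (default 0.15).
#' @param offtask_rate expected off-task between-zone swipes per cycle
#'   (Poisson; default 1.5).
#' @param tap_rate expected taps per cycle (default 1).
#' @param within_zone_rate expected within-zone swipes per cycle
#'   (default 0.5).
#' @param multitouch_prob probability a swipe overlaps the previous one in
#'   time, producing simultaneous contacts (default 0.05); overlap is only
#'   kept when the two trajectories stay at least `min_separation` apart.
#' @param min_separation minimum distance between concurrent trajectories in
#'   normalised units (default 0.15).
#' @param contact_hz sampling rate of move events (default 60, typical of
#'   tablet touch digitisers).
#' @param noise_sd positional jitter s.d. in normalised units (default
#'   0.004, sub-fingertip sensor noise).
#' @param seed integer seed; every session is fully reproducible from it.
#' @return A `strategy_profile` list.
#' @export
strategy_profile <- function(n_cycles = 12L, p_direct = 0.9, p_stack = 0.15,
                             offtask_rate = 1.5, tap_rate = 1,
                             within_zone_rate = 0.5, multitouch_prob = 0.05,
                             min_separation = 0.15, contact_hz = 60,
                             noise_sd = 0.004, seed = NULL) {
  p <- list(n_cycles = as.integer(n_cycles), p_direct = p_direct,
            p_stack = p_stack, offtask_rate = offtask_rate,
            tap_rate = tap_rate, within_zone_rate = within_zone_rate,
            multitouch_prob = multitouch_prob,
            min_separation = min_separation, contact_hz = contact_hz,
            noise_sd = noise_sd, seed = seed)
  for (nm in c("p_direct", "p_stack", "multitouch_prob"))
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must be in [0, 1]")
  for (nm in c("offtask_rate", "tap_rate", "within_zone_rate", "noise_sd"))
    if (p[[nm]] < 0) stop(nm, " must be >= 0")
  if (p$n_cycles < 0) stop("n_cycles must be >= 0")
  if (p$contact_hz <= 0) stop("contact_hz must be positive")
  structure(p, class = "strategy_profile")
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

# uniform point inside a zone rectangle, shrunk by a relative margin
.point_in_zone <- function(zm, vertex, margin = 0.15) {
  z <- zm$zones[zm$zones$vertex == vertex, ]
  mx <- (z$x1 - z$x0) * margin
  my <- (z$y1 - z$y0) * margin
  c(stats::runif(1, z$x0 + mx, z$x1 - mx),
    stats::runif(1, z$y0 + my, z$y1 - my))
}

# point inside a snap-to-plate zone but outside its nested plate rectangle
.point_in_snap_ring <- function(zm, snap_vertex) {
  z <- zm$zones[zm$zones$vertex == snap_vertex, ]
  plate_v <- plate_of(snap_vertex, zm)
  p <- zm$zones[zm$zones$vertex == plate_v, ]
  for (i in 1:50) {
    pt <- .point_in_zone(zm, snap_vertex, margin = 0.05)
    if (!(pt[1] >= p$x0 && pt[1] <= p$x1 && pt[2] >= p$y0 && pt[2] <= p$y1))
      return(pt)
  }
  # fall back to the band above the plate, always inside the snap zone
  c(stats::runif(1, z$x0 + 0.01, z$x1 - 0.01),
    stats::runif(1, z$y0 + 0.005, p$y0 - 0.005))
}

# smooth eased quadratic-Bezier trajectory between two points
.trajectory <- function(p0, p1, t0, duration, hz, noise_sd) {
  nmove <- max(2L, floor(duration * hz / 1000))
  tt <- seq(0, duration, length.out = nmove + 2)
  s <- tt / duration
  s <- 3 * s^2 - 2 * s^3                     # ease in/out
  mid <- (p0 + p1) / 2
  d <- p1 - p0
  perp <- c(-d[2], d[1])
  ctrl <- mid + perp * stats::rnorm(1, 0, 0.08)
  bez <- function(s, a, c, b) (1 - s)^2 * a + 2 * s * (1 - s) * c + s^2 * b
  x <- bez(s, p0[1], ctrl[1], p1[1])
  y <- bez(s, p0[2], ctrl[2], p1[2])
  npt <- length(s)
  if (noise_sd > 0) {
    x <- x + stats::rnorm(npt, 0, noise_sd)
    y <- y + stats::rnorm(npt, 0, noise_sd)
    x[c(1, npt)] <- c(p0[1], p1[1]) + stats::rnorm(2, 0, noise_sd)
    y[c(1, npt)] <- c(p0[2], p1[2]) + stats::rnorm(2, 0, noise_sd)
  }
  data.frame(t_ms = t0 + tt,
             x = pmin(1, pmax(0, x)), y = pmin(1, pmax(0, y)),
             phase = c("down", rep("move", npt - 2), "up"))
}

#' Simulate one gameplay session
#'
#' Generates a touch-event log with the structure the analysis assumes: game
#' cycles of four food pieces delivered directly or stacked-then-
#' redistributed, plus off-task swipes (between zones unrelated to food),
#' taps and within-zone swipes, sampled as smooth jittered trajectories at
#' the device contact rate. Occasional swipes overlap in time (multi-touch);
#' concurrent trajectories are kept spatially separated so hardware ids are
#' recoverable. Every swipe carries a ground-truth label.
#'
#' @param profile a [strategy_profile()].
#' @param zm a [zone_map()].
#' @return List with `events` (touch-event data.frame with `touch_id`) and
#'   `truth` (data.frame: `swipe_id` in start-time order, `label` in
#'   `{direct_delivery, stack_delivery, inter_plate, offtask, tap,
#'   within_zone}`, `origin_vertex`, `dest_vertex`, `start_t`).
#' @export
simulate_session <- function(profile = strategy_profile(),
                             zm = default_zone_map()) {
  stopifnot(inherits(profile, "strategy_profile"))
  .with_seed(profile$seed, .simulate_session_impl(profile, zm))
}

.simulate_session_impl <- function(pr, zm) {
  force(pr)
  psi <- plate_vertices(zm)
  f <- food_vertex(zm)
  others <- zm$zones$vertex[zm$zones$role == "other"]
  swipes <- list()   # each: list(kind, origin, dest, p0, p1, duration)

  add <- function(kind, origin, dest, p0, p1,
                  duration = stats::runif(1, 350, 700)) {
    swipes[[length(swipes) + 1L]] <<-
      list(kind = kind, origin = origin, dest = dest,
           p0 = p0, p1 = p1, duration = duration)
  }

  for (cyc in seq_len(pr$n_cycles)) {
    stacked <- stats::runif(1) < pr$p_stack
    if (stacked) {
      k <- sample(psi, 1)
      for (piece in 1:4)
        add("stack_delivery", f, k,
            .point_in_zone(zm, f), .point_in_zone(zm, k))
      for (j in sample(setdiff(psi, k)))
        add("inter_plate", k, j,
            .point_in_zone(zm, k), .point_in_zone(zm, j))
    } else {
      for (k in sample(psi)) {
        if (stats::runif(1) < pr$p_direct) {
          add("direct_delivery", f, k,
              .point_in_zone(zm, f), .point_in_zone(zm, k))
        } else {
          sk <- parent_snap_of(k, zm)
          add("direct_delivery", f, sk,
              .point_in_zone(zm, f), .point_in_snap_ring(zm, sk))
        }
      }
    }
    for (i in seq_len(stats::rpois(1, pr$offtask_rate))) {
      vv <- sample(others, 2)
      add("offtask", vv[1], vv[2],
          .point_in_zone(zm, vv[1]), .point_in_zone(zm, vv[2]))
    }
    for (i in seq_len(stats::rpois(1, pr$tap_rate))) {
      v <- sample(c(others, f), 1)
      p <- .point_in_zone(zm, v)
      add("tap", v, v, p, p, duration = stats::runif(1, 40, 90))
    }
    for (i in seq_len(stats::rpois(1, pr$within_zone_rate))) {
      v <- sample(c(others, f), 1)
      p0 <- .point_in_zone(zm, v, margin = 0.2)
      z <- zm$zones[zm$zones$vertex == v, ]
      span <- 0.15 * c(z$x1 - z$x0, z$y1 - z$y0)
      p1 <- pmin(c(z$x1, z$y1) - 0.01,
                 pmax(c(z$x0, z$y0) + 0.01,
                      p0 + stats::runif(2, -1, 1) * span))
      add("within_zone", v, v, p0, p1)
    }
  }

  if (!length(swipes)) {
    empty <- validate_touch_events(
      data.frame(t_ms = numeric(0), x = numeric(0), y = numeric(0),
                 phase = character(0)))
    return(list(events = empty,
                truth = data.frame(swipe_id = integer(0),
                                   label = character(0),
                                   origin_vertex = integer(0),
                                   dest_vertex = integer(0),
                                   start_t = numeric(0))))
  }

  # schedule: sequential with gaps; occasional overlap with the previous
  # swipe when the trajectories stay separated
  cursor <- stats::runif(1, 200, 800)
  traj <- vector("list", length(swipes))
  prev <- NULL
  for (i in seq_along(swipes)) {
    s <- swipes[[i]]
    start <- cursor + stats::runif(1, 120, 600)
    tr <- .trajectory(s$p0, s$p1, start, s$duration, pr$contact_hz,
                      pr$noise_sd)
    if (!is.null(prev) && s$kind != "tap" &&
        stats::runif(1) < pr$multitouch_prob) {
      ov_start <- prev$t_ms[1] + 0.3 * (max(prev$t_ms) - prev$t_ms[1])
      cand <- .trajectory(s$p0, s$p1, ov_start, s$duration, pr$contact_hz,
                          pr$noise_sd)
      # keep the overlap only if the candidate stays clear of every swipe
      # it would be concurrent with (overlaps can chain across >2 swipes)
      sep <- min(vapply(traj[seq_len(i - 1)], .min_concurrent_dist,
                        numeric(1), b = cand))
      if (sep >= pr$min_separation) tr <- cand
    }
    traj[[i]] <- tr
    cursor <- max(cursor, max(tr$t_ms))
    prev <- tr
  }

  truth <- data.frame(
    swipe_id = seq_along(swipes),
    label = vapply(swipes, `[[`, "", "kind"),
    origin_vertex = vapply(swipes, `[[`, 0L, "origin"),
    dest_vertex = vapply(swipes, `[[`, 0L, "dest"),
    start_t = vapply(traj, function(tr) tr$t_ms[1], 0))
  o <- order(truth$start_t, truth$swipe_id)
  truth <- truth[o, , drop = FALSE]
  truth$swipe_id <- seq_len(nrow(truth))
  rownames(truth) <- NULL

  ids <- .assign_touch_ids(traj)
  ev <- do.call(rbind, Map(function(tr, id) cbind(tr, touch_id = id),
                           traj, ids))
  ev <- ev[order(ev$t_ms, seq_len(nrow(ev))), , drop = FALSE]
  rownames(ev) <- NULL
  list(events = validate_touch_events(ev), truth = truth)
}

.min_concurrent_dist <- function(a, b) {
  t0 <- max(a$t_ms[1], b$t_ms[1])
  t1 <- min(max(a$t_ms), max(b$t_ms))
  if (t1 < t0) return(Inf)
  tt <- seq(t0, t1, length.out = 25)
  ax <- stats::approx(a$t_ms, a$x, tt)$y; ay <- stats::approx(a$t_ms, a$y, tt)$y
  bx <- stats::approx(b$t_ms, b$x, tt)$y; by <- stats::approx(b$t_ms, b$y, tt)$y
  min(sqrt((ax - bx)^2 + (ay - by)^2))
}

# hardware-style ids: smallest id not in use among concurrent swipes
.assign_touch_ids <- function(traj) {
  starts <- vapply(traj, function(tr) tr$t_ms[1], 0)
  ends <- vapply(traj, function(tr) max(tr$t_ms), 0)
  ids <- rep(NA_integer_, length(traj))
  for (i in order(starts)) {
    busy <- ids[!is.na(ids) & ends >= starts[i]]
    cand <- 0L
    while (cand %in% busy) cand <- cand + 1L
    ids[i] <- cand
  }
  ids
}

#' Cohort specification for the synthetic simulator
#'
#' @param groups list of group definitions, each a list with `label`, `n`,
#'   `age_range` (months, within 30-72), and `profile_fn`, a function of age
#'   in months returning a named list of [strategy_profile()] parameter
#'   overrides (the age-response of the group's strategy mix).
#' @param seed integer seed for the whole cohort.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(groups, seed = NULL) {
  for (g in groups) {
    if (is.null(g$label) || is.null(g$n) || is.null(g$profile_fn))
      stop("each group needs label, n and profile_fn")
    if (g$n < 1) stop("group '", g$label, "' must have n >= 1")
    ar <- if (is.null(g$age_range)) c(30, 72) else g$age_range
    if (ar[1] < 30 || ar[2] > 72 || ar[1] > ar[2])
      stop("age_range must lie within [30, 72] months")
  }
  structure(list(groups = groups, seed = seed), class = "cohort_spec")
}

#' Simulate a cohort of gameplay sessions
#'
#' Ages are drawn uniformly within each group's range, sexes are balanced
#' Bernoulli draws, optional severity levels are sampled from the group's
#' `severity_probs`, and each participant's session is generated from the
#' group's age-response profile with a participant seed derived from the
#' cohort seed — the whole cohort is reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param zm a [zone_map()].
#' @param outdir optional directory; when given, writes `manifest.csv` and
#'   one event CSV per participant.
#' @return List with `manifest` (participant table) and `sessions` (named
#'   list of `simulate_session()` results).
#' @export
simulate_cohort <- function(spec, zm = default_zone_map(), outdir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(spec$seed, {
    rows <- list(); sessions <- list()
    for (g in spec$groups) {
      ar <- if (is.null(g$age_range)) c(30, 72) else g$age_range
      for (i in seq_len(g$n)) {
        pid <- sprintf("%s_%03d", g$label, i)
        age <- stats::runif(1, ar[1], ar[2])
        sex <- sample(c("F", "M"), 1)
        severity <- if (!is.null(g$severity_probs))
          sample(seq_along(g$severity_probs), 1, prob = g$severity_probs)
        else NA_integer_
        pseed <- sample.int(.Machine$integer.max - 1L, 1)
        prof <- do.call(strategy_profile,
                        c(g$profile_fn(age), list(seed = pseed)))
        sessions[[pid]] <- simulate_session(prof, zm)
        rows[[pid]] <- data.frame(
          participant_id = pid, group = g$label, age_months = age,
          sex = sex, severity = severity, seed = pseed)
      }
    }
    manifest <- do.call(rbind, rows)
    rownames(manifest) <- NULL
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                       row.names = FALSE)
      for (pid in names(sessions))
        write_touch_log(sessions[[pid]]$events,
                        file.path(outdir, paste0(pid, ".csv")))
    }
    list(manifest = manifest, sessions = sessions)
  })
}

#' Preset cohort specifications for the recovery experiments
#'
#' `recovery_cohort_spec()` defines the two-strategy contrast cohort: a
#' "direct" group that never stacks (every delivery goes straight from the
#' food zone to a distinct plate, so its direct and indirect networks are
#' identical) and a "stacker" group that plays most cycles by stacking four
#' pieces on one plate and redistributing. `age_trend_cohort_spec()` defines
#' a single group whose stacking probability either rises linearly over the
#' 30-72 month age range (`trend = TRUE`) or stays flat at the range
#' midpoint value (`trend = FALSE`), for testing age-correlation recovery
#' against a null.
#'
#' @param n_per_group,n participants per group.
#' @param seed cohort seed.
#' @param trend logical; rising or flat stacking probability.
#' @return A [cohort_spec()].
#' @export
recovery_cohort_spec <- function(n_per_group = 100L, seed = NULL) {
  cohort_spec(list(
    list(label = "direct", n = n_per_group,
         profile_fn = function(age) list(p_stack = 0)),
    list(label = "stacker", n = n_per_group,
         profile_fn = function(age) list(p_stack = 0.7))),
    seed = seed)
}

#' Read a cohort specification from YAML
#'
#' File schema: top-level `seed` and `groups`; each group has `label`,
#' `n_participants`, optional `age_range` (months) and `severity_probs`, and
#' a `profile`
#' mapping of [strategy_profile()] parameters. Each profile entry is either
#' a scalar (constant over age) or a mapping `{base, per_month, ref_age}`
#' encoding the linear age response `base + per_month * (age - ref_age)`
#' (default `ref_age` 30); probability parameters are clipped to \[0, 1\].
#' See `system.file("extdata", "example_cohort.yaml", package = "playnet")`
#' for a commented example.
#'
#' @param path YAML file path.
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  probs <- c("p_direct", "p_stack", "multitouch_prob")
  make_fn <- function(profile) {
    force(profile)
    function(age) {
      out <- lapply(names(profile), function(nm) {
        v <- profile[[nm]]
        val <- if (is.list(v)) {
          ref <- if (is.null(v$ref_age)) 30 else v$ref_age
          v$base + v$per_month * (age - ref)
        } else v
        if (nm %in% probs) val <- min(1, max(0, val))
        if (nm == "n_cycles") val <- max(0L, as.integer(round(val)))
        val
      })
      stats::setNames(out, names(profile))
    }
  }
  groups <- lapply(cfg$groups, function(g) {
    n <- if (!is.null(g$n_participants)) g$n_participants else g$n
    list(label = g$label, n = n,
         age_range = if (is.null(g$age_range)) c(30, 72) else
           as.numeric(unlist(g$age_range)),
         severity_probs = if (is.null(g$severity_probs)) NULL else
           as.numeric(unlist(g$severity_probs)),
         profile_fn = make_fn(if (is.null(g$profile)) list() else g$profile))
  })
  cohort_spec(groups, seed = cfg$seed)
}

#' @rdname recovery_cohort_spec
#' @export
age_trend_cohort_spec <- function(n = 100L, trend = TRUE, seed = NULL) {
  fn <- if (trend)
    function(age) list(p_stack = 0.1 + 0.5 * (age - 30) / 42)
  else
    function(age) list(p_stack = 0.35)
  cohort_spec(list(list(label = if (trend) "trend" else "flat", n = n,
                        profile_fn = fn)),
              seed = seed)
}
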