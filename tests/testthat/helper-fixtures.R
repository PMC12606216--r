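# Shared fixtures and independent oracles used across the suite.

# A straight single-finger drag sampled at fixed intervals.
drag_events <- function(from, to, n = 10, t0 = 0, dt = 30,
                        touch_id = NA_integer_) {
  s <- seq(0, 1, length.out = n)
  data.frame(
    t_ms = t0 + s * (n - 1) * dt,
    x = from[1] + s * (to[1] - from[1]),
    y = from[2] + s * (to[2] - from[2]),
    phase = c("down", rep("move", n - 2), "up"),
    touch_id = touch_id)
}

interleave_events <- function(...) {
  ev <- do.call(rbind, list(...))
  ev[order(ev$t_ms, seq_len(nrow(ev))), , drop = FALSE]
}

# Build a transition network directly from endpoint vertex pairs.
net_from_pairs <- function(origin, dest, zm) {
  ep <- data.frame(swipe_id = seq_along(origin), origin = origin, dest = dest)
  ep$within <- ep$origin == ep$dest
  build_raw_network(ep, zm)
}

# Independent oracle: leading left eigenvector by plain power iteration on
# the shifted transpose.
power_left_eigenvector <- function(M, tol = 1e-15, maxit = 200000) {
  shift <- max(0, -min(diag(M)))
  Mt <- t(M + diag(shift, nrow(M)))
  v <- rep(1 / sqrt(nrow(M)), nrow(M))
  for (i in seq_len(maxit)) {
    w <- as.numeric(Mt %*% v)
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) break
    v <- w
  }
  if (w[which.max(abs(w))] < 0) w <- -w
  w
}

# Independent oracle: exact two-sided Wilcoxon rank-sum p-value by exhaustive
# enumeration of all rank assignments (no ties).
wilcoxon_exact_enumeration <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  stat <- function(xi) {
    xs <- pooled[xi]; ys <- pooled[-xi]
    sum(outer(xs, ys, `>`))
  }
  obs <- stat(seq_len(nx))
  all_u <- apply(utils::combn(length(pooled), nx), 2, stat)
  mu <- nx * (length(pooled) - nx) / 2
  mean(abs(all_u - mu) >= abs(obs - mu))
}

default_session <- function(seed, ...) {
  simulate_session(strategy_profile(seed = seed, ...), default_zone_map())
}

session_adjacencies <- function(events, zm) {
  sw <- assemble_swipes(events)
  raw <- build_raw_network(sw, zm)
  list(direct = normalise_with_baseline(apply_direct_rules(raw)),
       indirect = normalise_with_baseline(apply_indirect_rules(raw)),
       raw = raw)
}
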