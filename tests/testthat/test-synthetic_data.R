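zm <- default_zone_map()

test_that("profile validation rejects out-of-range parameters", {
  expect_error(strategy_profile(p_stack = 1.2), "p_stack")
  expect_error(strategy_profile(offtask_rate = -1), "offtask_rate")
  expect_s3_class(strategy_profile(), "strategy_profile")
})

test_that("session composition follows the strategy profile by construction", {
  s <- simulate_session(strategy_profile(
    n_cycles = 10, p_stack = 0, p_direct = 1, offtask_rate = 0,
    tap_rate = 0, within_zone_rate = 0, noise_sd = 0, seed = 71), zm)
  expect_equal(nrow(s$truth), 40)
  expect_true(all(s$truth$label == "direct_delivery"))
  expect_equal(as.integer(table(s$truth$dest_vertex)), rep(10L, 4))

  s2 <- simulate_session(strategy_profile(
    n_cycles = 10, p_stack = 1, offtask_rate = 0, tap_rate = 0,
    within_zone_rate = 0, noise_sd = 0, seed = 72), zm)
  expect_equal(sum(s2$truth$label == "stack_delivery"), 40)
  expect_equal(sum(s2$truth$label == "inter_plate"), 30)
})

test_that("sessions are reproducible from the seed", {
  a <- simulate_session(strategy_profile(seed = 99), zm)
  b <- simulate_session(strategy_profile(seed = 99), zm)
  expect_identical(a, b)
  c <- simulate_session(strategy_profile(seed = 100), zm)
  expect_false(identical(a$events, c$events))
})

test_that("noise-free pipeline recovers the generator's truth labels", {
  for (seed in c(81, 82, 83)) {
    s <- simulate_session(strategy_profile(
      n_cycles = 8, p_stack = 0.5, p_direct = 0.8, noise_sd = 0,
      seed = seed), zm)
    sw <- assemble_swipes(s$events)
    ep <- swipe_endpoints(sw, zm)
    expect_equal(count_food_delivery_swipes(ep, zm),
                 sum(s$truth$label %in% c("direct_delivery",
                                          "stack_delivery")))
    expect_equal(count_inter_plate_swipes(ep, zm),
                 sum(s$truth$label == "inter_plate"))
    # assembled endpoints match the truth table swipe by swipe
    expect_equal(ep$origin, s$truth$origin_vertex)
  }
})

test_that("cohort manifests have the requested structure and determinism", {
  spec <- cohort_spec(list(
    list(label = "A", n = 5, profile_fn = function(age) list(p_stack = 0.2),
         severity_probs = c(0.5, 0.3, 0.2)),
    list(label = "B", n = 5, age_range = c(40, 60),
         profile_fn = function(age) list(p_stack = 0))), seed = 7)
  co <- simulate_cohort(spec, zm)
  expect_equal(nrow(co$manifest), 10)
  expect_setequal(unique(co$manifest$group), c("A", "B"))
  expect_true(all(co$manifest$age_months >= 30 &
                    co$manifest$age_months <= 72))
  bages <- co$manifest$age_months[co$manifest$group == "B"]
  expect_true(all(bages >= 40 & bages <= 60))
  expect_true(all(co$manifest$severity[co$manifest$group == "A"] %in% 1:3))
  expect_true(all(is.na(co$manifest$severity[co$manifest$group == "B"])))
  co2 <- simulate_cohort(spec, zm)
  expect_identical(co, co2)
})

test_that("expected inter-plate count tracks 3 * n_cycles * p_stack", {
  # analytic expectation for the stacked-cycle mechanism
  n_cycles <- 12; p_stack <- 0.6; nrep <- 40
  counts <- vapply(seq_len(nrep), function(i) {
    s <- simulate_session(strategy_profile(
      n_cycles = n_cycles, p_stack = p_stack, offtask_rate = 0,
      tap_rate = 0, within_zone_rate = 0, seed = 7000 + i), zm)
    sum(s$truth$label == "inter_plate")
  }, numeric(1))
  expected <- 3 * n_cycles * p_stack
  se <- sqrt(9 * n_cycles * p_stack * (1 - p_stack) / nrep)
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("YAML cohort specs build age-responsive profiles", {
  path <- system.file("extdata", "example_cohort.yaml", package = "playnet")
  spec <- read_cohort_spec(path)
  expect_s3_class(spec, "cohort_spec")
  expect_equal(vapply(spec$groups, `[[`, "", "label"),
               c("single_step", "two_step"))
  p30 <- spec$groups[[2]]$profile_fn(30)
  p70 <- spec$groups[[2]]$profile_fn(70)
  expect_equal(p30$p_stack, 0.3)
  expect_equal(p70$p_stack, 0.3 + 0.008 * 40)
  # probabilities are clipped to [0, 1]
  pf <- read_cohort_spec(path)$groups[[1]]$profile_fn
  expect_gte(pf(72)$offtask_rate, 0)
})

test_that("simulated multi-touch keeps concurrent trajectories separated", {
  s <- simulate_session(strategy_profile(
    n_cycles = 5, multitouch_prob = 0.8, seed = 91), zm)
  ev <- s$events
  expect_gt(length(unique(ev$touch_id)), 1)
  # concurrent samples from different swipes are never close: interpolate
  # each pair of swipes over their joint time support
  swd <- assemble_swipes(ev, use_touch_id = "always")
  ss <- swipe_summary(swd)
  for (i in seq_len(nrow(ss))) for (j in seq_len(i - 1)) {
    t0 <- max(ss$start_t[i], ss$start_t[j])
    t1 <- min(ss$end_t[i], ss$end_t[j])
    if (t1 <= t0) next
    a <- swd$events[swd$events$swipe_id == ss$swipe_id[i], ]
    b <- swd$events[swd$events$swipe_id == ss$swipe_id[j], ]
    tt <- seq(t0, t1, length.out = 20)
    dx <- approx(a$t_ms, a$x, tt)$y - approx(b$t_ms, b$x, tt)$y
    dy <- approx(a$t_ms, a$y, tt)$y - approx(b$t_ms, b$y, tt)$y
    expect_gt(min(sqrt(dx^2 + dy^2)), 0.1)
  }
})
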