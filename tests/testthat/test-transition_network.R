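zm <- default_zone_map()
f <- food_vertex(zm)        # 8
psi <- plate_vertices(zm)   # 4:7
sv <- snap_vertices(zm)     # 0:3

test_that("swipe endpoints define transitions; taps and loops are within-zone", {
  sw <- swipe_to_transition(
    data.frame(t_ms = c(0, 50, 100), x = c(0.5, 0.45, 0.375),
               y = c(0.9, 0.7, 0.545)), zm)
  expect_equal(sw$origin, f)
  expect_equal(sw$destination, 5)   # plate_2 centre
  expect_false(sw$within_zone)
  tap <- swipe_to_transition(data.frame(t_ms = 0, x = 0.5, y = 0.9), zm)
  expect_true(tap$within_zone)
  loop <- swipe_to_transition(
    data.frame(t_ms = c(0, 40), x = c(0.3, 0.6), y = c(0.9, 0.9)), zm)
  expect_true(loop$within_zone)
})

test_that("raw network counts between-zone swipes with a zero diagonal", {
  net <- net_from_pairs(c(f, f, 4), c(4, 4, 5), zm)
  expect_equal(net$counts[f + 1, 5], 2)
  expect_equal(net$counts[5, 6], 1)
  expect_equal(sum(net$counts), 3)
  expect_true(all(diag(net$counts) == 0))
  empty <- net_from_pairs(integer(0), integer(0), zm)
  expect_equal(sum(empty$counts), 0)
  rep100 <- net_from_pairs(rep(f, 100), rep(6, 100), zm)
  expect_equal(rep100$counts[f + 1, 7], 100)
})

test_that("direct rules unify deliveries to plates and reconnect the rest", {
  # f -> snap_3 (vertex 2) counts as delivery to plate_3 (vertex 6)
  net <- apply_direct_rules(net_from_pairs(f, 2, zm))
  expect_equal(net$counts[f + 1, 7], 1)
  expect_equal(sum(net$counts), 1)
  # plate_1 -> plate_3 is reconnected to plate_1 -> snap_3
  net2 <- apply_direct_rules(net_from_pairs(4, 6, zm))
  expect_equal(net2$counts[5, 3], 1)  # origin 4, dest snap 2
  expect_false(any(net2$endpoints$delivery))
  # unrelated transitions pass through
  net3 <- apply_direct_rules(net_from_pairs(9, 10, zm))
  expect_equal(net3$counts[10, 11], 1)
})

test_that("indirect rules admit inter-plate deliveries but not own-parent returns", {
  # plate_1 -> plate_3 is a delivery and keeps its plate destination
  net <- apply_indirect_rules(net_from_pairs(4, 6, zm))
  expect_equal(net$counts[5, 7], 1)
  expect_true(all(net$endpoints$delivery))
  # plate_1 -> own surrounding snap_1 is recorded but is not a delivery
  net2 <- apply_indirect_rules(net_from_pairs(4, 0, zm))
  expect_equal(net2$counts[5, 1], 1)
  expect_false(any(net2$endpoints$delivery))
  # plate_1 -> snap_3 (a different character) is a delivery to plate_3
  net3 <- apply_indirect_rules(net_from_pairs(4, 2, zm))
  expect_equal(net3$counts[5, 7], 1)
  # f -> plate_2 unchanged
  net4 <- apply_indirect_rules(net_from_pairs(f, 5, zm))
  expect_equal(net4$counts[f + 1, 6], 1)
})

test_that("delivery-vertex structure of the rewired variants holds", {
  s <- default_session(31, p_stack = 0.5)
  sw <- assemble_swipes(s$events)
  raw <- build_raw_network(sw, zm)
  dnet <- apply_direct_rules(raw)
  inet <- apply_indirect_rules(raw)
  # conservation of between-zone swipes under rewiring
  expect_equal(sum(dnet$counts), sum(raw$counts))
  expect_equal(sum(inet$counts), sum(raw$counts))
  # direct: no entries into plates except from the food vertex
  into_plates_d <- dnet$counts[, psi + 1, drop = FALSE]
  expect_true(all(into_plates_d[-(f + 1), ] == 0))
  # indirect: no entries into plates except from food or plates
  into_plates_i <- inet$counts[, psi + 1, drop = FALSE]
  expect_true(all(into_plates_i[-c(f + 1, psi + 1), ] == 0))
})

test_that("normalisation adds the baseline and is scale invariant", {
  net <- apply_direct_rules(net_from_pairs(c(f, f, 4), c(5, 5, 2), zm))
  A <- normalise_with_baseline(net)
  expect_equal(A$A[f + 1, 6], 2 / 3 + 0.01)
  expect_equal(A$A[5, 3], 1 / 3 + 0.01)
  expect_equal(A$A[1, 1], 0.01)
  expect_equal(sum(A$A - 0.01), 1)
  # k * T gives the identical adjacency
  for (k in c(2, 5, 10)) {
    netk <- net
    netk$counts <- netk$counts * k
    expect_equal(normalise_with_baseline(netk)$A, A$A)
  }
  # empty network: bare baseline, flagged degenerate
  e <- normalise_with_baseline(apply_direct_rules(
    net_from_pairs(integer(0), integer(0), zm)))
  expect_true(e$degenerate)
  expect_equal(unique(as.numeric(e$A)), 0.01)
  expect_error(normalise_with_baseline(net, baseline = -0.1), "non-negative")
})

test_that("swipe metric counts follow their endpoint definitions", {
  ep <- data.frame(
    swipe_id = 1:8,
    origin = c(f, f, f, 4, 4, 4, 9, 0),
    dest   = c(4, 0, 9, 6, 0, 2, 10, 9))
  ep$within <- ep$origin == ep$dest
  # f->plate, f->snap are deliveries; f->character is not
  expect_equal(count_food_delivery_swipes(ep, zm), 2)
  # plate->plate and plate->other snap count; plate->own parent snap does not
  expect_equal(count_inter_plate_swipes(ep, zm), 2)
  expect_equal(count_food_delivery_swipes(ep[0, ], zm), 0)
})

test_that("edge-list export round-trips integer networks bit-exactly", {
  s <- default_session(33)
  raw <- build_raw_network(assemble_swipes(s$events), zm)
  dnet <- apply_direct_rules(raw)
  tmp <- tempfile(fileext = ".csv")
  write_network(dnet, tmp)
  back <- read_network(tmp, zm)
  expect_identical(back$counts, dnet$counts)
  expect_equal(back$variant, "direct")
})
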