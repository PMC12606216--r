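#' Origin and destination vertices of a single swipe
#'
#' A swipe's transition is defined by the zone containing its first contact
#' (origin) and the zone containing its last contact (destination). Swipes
#' that begin and end in the same zone — including taps, which have a single
#' contact point — are within-zone and are excluded from the transition
#' matrix (its diagonal is identically zero).
#'
#' @param swipe data.frame of one swipe's contacts (`t_ms`, `x`, `y`), time
#'   ordered.
#' @param zm a [zone_map()].
#' @return List with `origin`, `destination` (vertex indices) and
#'   `within_zone` (logical sentinel, `TRUE` when origin equals destination).
#' @export
swipe_to_transition <- function(swipe, zm) {
  n <- nrow(swipe)
  if (is.null(n) || n < 1) stop("swipe must contain at least one contact")
  o <- classify_point(swipe$x[1], swipe$y[1], zm)
  d <- classify_point(swipe$x[n], swipe$y[n], zm)
  list(origin = o, destination = d, within_zone = o == d)
}

#' Endpoint table of an assembled session
#'
#' @param sw a `swipes` object (or its [swipe_summary()]).
#' @param zm a [zone_map()].
#' @return data.frame with one row per swipe: `swipe_id`, `origin`, `dest`
#'   (vertex indices of first/last contact zones) and `within` (logical).
#' @export
swipe_endpoints <- function(sw, zm) {
  ss <- if (inherits(sw, "swipes")) swipe_summary(sw) else as.data.frame(sw)
  ep <- data.frame(
    swipe_id = ss$swipe_id,
    origin = classify_point(ss$x_first, ss$y_first, zm),
    dest = classify_point(ss$x_last, ss$y_last, zm))
  ep$within <- ep$origin == ep$dest
  ep
}

.count_matrix <- function(origin, dest, n = 16L) {
  T <- matrix(0L, n, n)
  if (length(origin)) {
    tab <- table(factor(origin, 0:(n - 1)), factor(dest, 0:(n - 1)))
    T <- matrix(as.integer(tab), n, n)
  }
  dimnames(T) <- list(origin = as.character(0:(n - 1)),
                      dest = as.character(0:(n - 1)))
  T
}

.new_network <- function(counts, variant, endpoints, zm) {
  structure(list(counts = counts, variant = variant,
                 endpoints = endpoints, zone_map = zm),
            class = "transition_network")
}

#' @export
print.transition_network <- function(x, ...) {
  cat("<transition_network>", x$variant, "variant,",
      sum(x$counts), "between-zone swipes\n")
  invisible(x)
}

#' Build the raw zone-transition network of a session
#'
#' Every between-zone swipe contributes one count to the entry indexed by its
#' origin and destination vertices; taps and within-zone swipes are excluded,
#' so the diagonal is zero. The per-swipe endpoint list is retained on the
#' object because the delivery rewiring rules need each swipe's true origin.
#'
#' @param sw a `swipes` object or endpoint table from [swipe_endpoints()].
#' @param zm a [zone_map()].
#' @return A `transition_network` (variant `"raw"`) with a 16x16 integer
#'   `counts` matrix (rows = origin vertex 0..15, columns = destination).
#' @export
build_raw_network <- function(sw, zm) {
  ep <- if (is.data.frame(sw) && "origin" %in% names(sw)) sw else
    swipe_endpoints(sw, zm)
  bz <- ep[!ep$within, , drop = FALSE]
  .new_network(.count_matrix(bz$origin, bz$dest), "raw", ep, zm)
}

#' Apply the direct food-delivery rewiring rules
#'
#' For the direct sharing analysis, food-delivery swipes must originate in the
#' food zone and end in a snap-to-plate or plate zone; their destination is
#' unified to the corresponding plate vertex. Swipes ending in a plate zone
#' without originating in the food zone are not moving food, and are
#' reconnected so the enclosing snap-to-plate zone is taken as the
#' destination. All other transitions pass through unchanged. (A
#' snap-to-plate to own-nested-plate swipe would reconnect onto the diagonal
#' and is then excluded, consistent with the zero-diagonal convention.)
#'
#' @param net a raw `transition_network` from [build_raw_network()].
#' @return A `transition_network` with variant `"direct"`; its endpoint table
#'   gains the rewired `dest` and a logical `delivery` column.
#' @export
apply_direct_rules <- function(net) {
  stopifnot(inherits(net, "transition_network"))
  if (net$variant != "raw") stop("expected a raw-variant network")
  zm <- net$zone_map
  ep <- net$endpoints[!net$endpoints$within, , drop = FALSE]
  f <- food_vertex(zm)
  sp <- c(snap_vertices(zm), plate_vertices(zm))
  psi <- plate_vertices(zm)

  dest <- ep$dest
  delivery <- ep$origin == f & ep$dest %in% sp
  dest[delivery] <- plate_of(ep$dest[delivery], zm)
  reconnect <- !delivery & ep$dest %in% psi
  dest[reconnect] <- parent_snap_of(ep$dest[reconnect], zm)
  ep$dest <- dest
  ep$delivery <- delivery
  ep <- ep[ep$origin != ep$dest, , drop = FALSE]
  .new_network(.count_matrix(ep$origin, ep$dest), "direct", ep, zm)
}

#' Apply the indirect food-delivery rewiring rules
#'
#' The indirect analysis additionally counts stack-then-redistribute sharing:
#' delivery swipes may originate from the food zone or from any plate zone,
#' with destinations unified to the plate vertex, except that a swipe from a
#' plate to its own surrounding snap-to-plate zone keeps the snap-to-plate
#' destination — the food simply returns to the plate it came from, so the
#' movement contributes nothing to sharing. Swipes ending in a plate zone from
#' any other origin are reconnected to the enclosing snap-to-plate vertex as
#' in [apply_direct_rules()].
#'
#' @inheritParams apply_direct_rules
#' @return A `transition_network` with variant `"indirect"`.
#' @export
apply_indirect_rules <- function(net) {
  stopifnot(inherits(net, "transition_network"))
  if (net$variant != "raw") stop("expected a raw-variant network")
  zm <- net$zone_map
  ep <- net$endpoints[!net$endpoints$within, , drop = FALSE]
  f <- food_vertex(zm)
  sp <- c(snap_vertices(zm), plate_vertices(zm))
  psi <- plate_vertices(zm)

  dest <- ep$dest
  to_plate_area <- ep$dest %in% sp
  own_parent <- ep$origin %in% psi & to_plate_area &
    plate_of(ep$dest, zm) == ep$origin
  delivery <- to_plate_area & !own_parent &
    (ep$origin == f | ep$origin %in% psi)
  dest[delivery] <- plate_of(ep$dest[delivery], zm)
  reconnect <- !delivery & !own_parent & ep$dest %in% psi
  dest[reconnect] <- parent_snap_of(ep$dest[reconnect], zm)
  ep$dest <- dest
  ep$delivery <- delivery
  ep <- ep[ep$origin != ep$dest, , drop = FALSE]
  .new_network(.count_matrix(ep$origin, ep$dest), "indirect", ep, zm)
}

#' Normalise a transition network and add the complete-graph baseline
#'
#' The counts are scaled to proportions of all between-zone swipes, then a
#' complete baseline graph with uniform weight (default 0.01 on every entry,
#' diagonal included) is added, giving every participant's network the same
#' strictly positive support so eigenvector entries are comparable across
#' participants. A session with no between-zone swipes yields the bare
#' baseline and is flagged degenerate.
#'
#' @param net a `transition_network` of variant `"direct"` or `"indirect"`.
#' @param baseline uniform baseline weight (default 0.01).
#' @return An object of class `adjacency_matrix`: list with `A` (16x16
#'   numeric), `variant`, `baseline`, `total` (sum of counts) and
#'   `degenerate`.
#' @export
normalise_with_baseline <- function(net, baseline = 0.01) {
  stopifnot(inherits(net, "transition_network"))
  if (!net$variant %in% c("direct", "indirect"))
    stop("normalisation applies to the direct or indirect variants")
  if (!is.numeric(baseline) || length(baseline) != 1 || baseline < 0)
    stop("baseline weight must be a single non-negative number")
  total <- sum(net$counts)
  A <- matrix(baseline, nrow(net$counts), ncol(net$counts),
              dimnames = dimnames(net$counts))
  if (total > 0) A <- A + net$counts / total
  structure(list(A = A, variant = net$variant, baseline = baseline,
                 total = total, degenerate = total == 0),
            class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat("<adjacency_matrix>", x$variant, "variant, baseline", x$baseline,
      if (x$degenerate) "(degenerate)", "\n")
  invisible(x)
}

#' Count food-delivery swipes
#'
#' The number of swipes transitioning from the food zone to a snap-to-plate
#' zone (including the plate zones nested inside them): the direct deliveries
#' of food pieces to the characters.
#'
#' @param sw a `swipes` object or endpoint table.
#' @param zm a [zone_map()].
#' @return Integer count.
#' @export
count_food_delivery_swipes <- function(sw, zm) {
  ep <- if (is.data.frame(sw) && "origin" %in% names(sw)) sw else
    swipe_endpoints(sw, zm)
  sp <- c(snap_vertices(zm), plate_vertices(zm))
  sum(ep$origin == food_vertex(zm) & ep$dest %in% sp)
}

#' Count inter-plate swipes
#'
#' The number of swipes beginning in a plate zone and ending in a different
#' snap-to-plate zone (or its nested plate): redistribution of stacked food.
#' A swipe from a plate to its own surrounding snap-to-plate zone is not
#' counted — the food lands back on the plate it started from.
#'
#' @inheritParams count_food_delivery_swipes
#' @return Integer count.
#' @export
count_inter_plate_swipes <- function(sw, zm) {
  ep <- if (is.data.frame(sw) && "origin" %in% names(sw)) sw else
    swipe_endpoints(sw, zm)
  psi <- plate_vertices(zm)
  sp <- c(snap_vertices(zm), psi)
  from_plate <- ep$origin %in% psi & ep$dest %in% sp
  sum(from_plate & plate_of(ep$dest, zm) != ep$origin)
}

#' Export / import a transition network as a weighted edge list
#'
#' Writes a CSV `origin,destination,weight` of the non-zero entries plus a
#' JSON sidecar (`<path>.json`) recording the variant, total between-zone
#' swipe count and baseline convention. Import reverses the export
#' bit-exactly for integer count matrices (the endpoint list is not
#' round-tripped).
#'
#' @param net a `transition_network`.
#' @param path CSV output path.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a `transition_network` (without endpoints).
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "transition_network"))
  nz <- which(net$counts != 0, arr.ind = TRUE)
  el <- data.frame(origin = nz[, 1] - 1L, destination = nz[, 2] - 1L,
                   weight = net$counts[nz])
  el <- el[order(el$origin, el$destination), , drop = FALSE]
  utils::write.csv(el, path, row.names = FALSE)
  jsonlite::write_json(
    list(variant = net$variant, total = sum(net$counts), n_vertices = 16L),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @param zm a [zone_map()] to attach on import.
#' @export
read_network <- function(path, zm = default_zone_map()) {
  el <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  T <- matrix(0L, 16, 16, dimnames = list(origin = as.character(0:15),
                                          dest = as.character(0:15)))
  T[cbind(el$origin + 1L, el$destination + 1L)] <- as.integer(el$weight)
  .new_network(T, side$variant, endpoints = NULL, zm)
}
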