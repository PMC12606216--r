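#' Screen zone map for the food-sharing game
#'
#' A `zone_map` describes the 16 named screen regions of the sharing game in
#' normalised screen units (origin top-left, x rightwards, y downwards, both in
#' \[0, 1\]). Each zone is a vertex of the swipe transition network. The layout
#' always contains exactly one food zone (the foreground serving area), four
#' snap-to-plate zones (the regions around the game characters within which a
#' released food item snaps onto that character's plate), four plate zones
#' (smaller rectangles nested inside the snap-to-plate zones, centred on the
#' plates and extended upwards to cover stacked food), and seven other zones.
#'
#' @param zones data.frame with columns `vertex` (integer 0-15), `name`,
#'   `role` (one of `"food"`, `"snap_to_plate"`, `"plate"`, `"other"`), and
#'   rectangle corners `x0`, `y0`, `x1`, `y1` in normalised units.
#' @param plate_parent named integer vector mapping each plate vertex (name)
#'   to its enclosing snap-to-plate vertex (value).
#' @param screen_size numeric length-2, device width and height in points;
#'   used to convert raw pixel logs to normalised units on ingestion.
#' @param background vertex index (role `"other"`) that collects points lying
#'   in no configured rectangle; defaults to the last `"other"` zone.
#'
#' @return An object of class `zone_map`.
#' @seealso [default_zone_map()], [load_zone_map()], [classify_point()]
#' @export
zone_map <- function(zones, plate_parent, screen_size = c(1024, 768),
                     background = NULL) {
  zones <- as.data.frame(zones)
  req <- c("vertex", "name", "role", "x0", "y0", "x1", "y1")
  if (!all(req %in% names(zones)))
    stop("zone table must have columns: ", paste(req, collapse = ", "))
  zones$vertex <- as.integer(zones$vertex)
  zones <- zones[order(zones$vertex), , drop = FALSE]
  rownames(zones) <- NULL

  if (nrow(zones) != 16L)
    stop("expected 16 zones, got ", nrow(zones))
  if (!identical(zones$vertex, 0:15))
    stop("zone vertex indices must be exactly 0..15")
  bad_role <- setdiff(unique(zones$role),
                      c("food", "snap_to_plate", "plate", "other"))
  if (length(bad_role))
    stop("unknown zone role(s): ", paste(bad_role, collapse = ", "))
  counts <- table(factor(zones$role,
                         c("food", "snap_to_plate", "plate", "other")))
  want <- c(food = 1L, snap_to_plate = 4L, plate = 4L, other = 7L)
  for (r in names(want))
    if (counts[[r]] != want[[r]])
      stop(sprintf("expected %d zone(s) with role '%s', got %d",
                   want[[r]], r, counts[[r]]))
  if (any(zones$x0 >= zones$x1) || any(zones$y0 >= zones$y1))
    stop("every zone rectangle must satisfy x0 < x1 and y0 < y1")
  if (any(zones$x0 < 0) || any(zones$y0 < 0) ||
      any(zones$x1 > 1) || any(zones$y1 > 1))
    stop("zone rectangles must lie within the unit square")

  plate_v <- zones$vertex[zones$role == "plate"]
  snap_v <- zones$vertex[zones$role == "snap_to_plate"]
  pp <- as.integer(plate_parent)
  names(pp) <- names(plate_parent)
  if (is.null(names(pp)) || !setequal(as.integer(names(pp)), plate_v))
    stop("plate_parent must be named by the four plate vertices")
  if (!setequal(pp, snap_v) || anyDuplicated(pp))
    stop("plate_parent must be a bijection onto the four snap-to-plate vertices")

  rect <- function(v) unlist(zones[zones$vertex == v, c("x0", "y0", "x1", "y1")])
  for (v in plate_v) {
    pr <- rect(v); sr <- rect(pp[[as.character(v)]])
    if (!(pr[1] > sr[1] && pr[2] > sr[2] && pr[3] < sr[3] && pr[4] < sr[4]))
      stop(sprintf(
        "plate zone %d must be strictly contained in its snap-to-plate zone %d",
        v, pp[[as.character(v)]]))
  }

  # same-role rectangles must have disjoint interiors (shared edges allowed)
  for (r in c("food", "snap_to_plate", "plate", "other")) {
    zz <- zones[zones$role == r, , drop = FALSE]
    if (nrow(zz) < 2) next
    for (i in seq_len(nrow(zz) - 1)) for (j in (i + 1):nrow(zz)) {
      if (zz$x0[i] < zz$x1[j] && zz$x1[i] > zz$x0[j] &&
          zz$y0[i] < zz$y1[j] && zz$y1[i] > zz$y0[j])
        stop(sprintf("zones '%s' and '%s' (role %s) overlap",
                     zz$name[i], zz$name[j], r))
    }
  }

  other_v <- zones$vertex[zones$role == "other"]
  if (is.null(background)) background <- other_v[length(other_v)]
  background <- as.integer(background)
  if (!background %in% other_v)
    stop("background vertex must have role 'other'")

  if (length(screen_size) != 2L || any(screen_size <= 0))
    stop("screen_size must be two positive numbers (width, height)")

  structure(
    list(zones = zones, plate_parent = pp,
         screen_size = as.numeric(screen_size), background = background),
    class = "zone_map")
}

#' @export
print.zone_map <- function(x, ...) {
  cat("<zone_map> 16 zones; plates", paste(plate_vertices(x), collapse = ","),
      "nested in snaps", paste(unname(x$plate_parent), collapse = ","),
      "; food vertex", food_vertex(x), "\n")
  invisible(x)
}

#' Zone vertex accessors
#'
#' Convenience accessors returning the vertex indices (0-based) of the food
#' zone `f`, the snap-to-plate set `s`, and the plate set `psi`.
#'
#' @param zm a [zone_map()].
#' @return Integer vertex indices.
#' @export
plate_vertices <- function(zm) zm$zones$vertex[zm$zones$role == "plate"]

#' @rdname plate_vertices
#' @export
snap_vertices <- function(zm) zm$zones$vertex[zm$zones$role == "snap_to_plate"]

#' @rdname plate_vertices
#' @export
food_vertex <- function(zm) zm$zones$vertex[zm$zones$role == "food"]

#' Map the plate nested inside a snap-to-plate zone (and back)
#'
#' `plate_of()` returns, for each vertex in the snap-to-plate or plate sets,
#' the corresponding plate vertex (a plate maps to itself); `parent_snap_of()`
#' returns the enclosing snap-to-plate vertex of each plate.
#'
#' @param v integer vertex indices.
#' @param zm a [zone_map()].
#' @return Integer vertex indices (NA where `v` is not in the relevant set).
#' @export
plate_of <- function(v, zm) {
  snap_to_plate <- structure(as.integer(names(zm$plate_parent)),
                             names = as.character(zm$plate_parent))
  out <- ifelse(v %in% plate_vertices(zm), v,
                unname(snap_to_plate[as.character(v)]))
  as.integer(out)
}

#' @rdname plate_of
#' @export
parent_snap_of <- function(v, zm) {
  unname(zm$plate_parent[as.character(v)])
}

#' Default 16-zone layout
#'
#' The published description of the game gives zone roles but no coordinates,
#' so the package ships a synthetic default layout that is mutually consistent
#' between the simulator and the scorer: four character zones across the top,
#' a row of four snap-to-plate zones spanning mid-screen (each with a nested,
#' upward-extended plate rectangle), the food serving band along the
#' bottom-centre, table corners either side of it, and a thin background strip
#' that also collects unclassified points. Plate zones are vertices 4-7.
#'
#' @return A [zone_map()].
#' @export
default_zone_map <- function() {
  cols <- function(y0, y1, names, roles, v0) {
    data.frame(vertex = v0 + 0:3, name = names, role = roles,
               x0 = c(0, .25, .5, .75), y0 = y0,
               x1 = c(.25, .5, .75, 1), y1 = y1)
  }
  snaps <- cols(.35, .75, paste0("snap_", 1:4), "snap_to_plate", 0L)
  plates <- data.frame(
    vertex = 4:7, name = paste0("plate_", 1:4), role = "plate",
    x0 = c(0, .25, .5, .75) + .055, y0 = .38,
    x1 = c(0, .25, .5, .75) + .195, y1 = .71)
  food <- data.frame(vertex = 8L, name = "food", role = "food",
                     x0 = .15, y0 = .78, x1 = .85, y1 = 1)
  chars <- cols(0, .35, paste0("other_", 0:3), "other", 9L)
  rest <- data.frame(
    vertex = 13:15, name = paste0("other_", 4:6), role = "other",
    x0 = c(0, .85, 0), y0 = c(.78, .78, .75),
    x1 = c(.15, 1, 1), y1 = c(1, 1, .78))
  zone_map(rbind(snaps, plates, food, chars, rest),
           plate_parent = c(`4` = 0L, `5` = 1L, `6` = 2L, `7` = 3L),
           screen_size = c(1024, 768), background = 15L)
}

#' Load a zone map from a YAML or JSON configuration file
#'
#' The configuration mirrors the [zone_map()] fields: a `zones` list (each
#' entry with `vertex`, `name`, `role`, `rect` as `[x0, y0, x1, y1]`), a
#' `plate_parent` mapping, `screen_size`, and an optional `background` vertex.
#' All `zone_map` invariants are validated; violations raise errors naming the
#' broken invariant.
#'
#' @param config_path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [zone_map()].
#' @export
load_zone_map <- function(config_path) {
  if (!file.exists(config_path))
    stop("zone-map config not found: ", config_path)
  cfg <- if (grepl("\\.json$", config_path, ignore.case = TRUE))
    jsonlite::read_json(config_path, simplifyVector = FALSE)
  else
    yaml::read_yaml(config_path)
  if (is.null(cfg$zones)) stop("config has no 'zones' entry")
  zones <- do.call(rbind, lapply(cfg$zones, function(z) {
    if (is.null(z$rect) || length(z$rect) != 4)
      stop("each zone needs a rect of four numbers [x0, y0, x1, y1]")
    data.frame(vertex = as.integer(z$vertex), name = as.character(z$name),
               role = as.character(z$role),
               x0 = as.numeric(z$rect[[1]]), y0 = as.numeric(z$rect[[2]]),
               x1 = as.numeric(z$rect[[3]]), y1 = as.numeric(z$rect[[4]]))
  }))
  pp <- unlist(cfg$plate_parent)
  screen <- if (is.null(cfg$screen_size)) c(1024, 768) else
    as.numeric(unlist(cfg$screen_size))
  zone_map(zones, plate_parent = pp, screen_size = screen,
           background = cfg$background)
}

#' Classify screen points into zone vertices
#'
#' Maps normalised screen coordinates to the vertex of the most specific zone
#' containing them. Precedence is plate > snap-to-plate > food > other, so a
#' point inside a plate rectangle classifies as the plate even though it also
#' lies in the enclosing snap-to-plate rectangle. Rectangles are closed; a
#' point on a shared edge resolves to the higher-precedence role, then to the
#' lower vertex index. Points contained in no configured rectangle map to the
#' designated background vertex, making classification total on the unit
#' square.
#'
#' @param x,y numeric vectors of normalised coordinates in \[0, 1\].
#' @param zm a [zone_map()].
#' @return Integer vector of vertex indices (0-based), one per point.
#' @export
classify_point <- function(x, y, zm) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!length(x)) return(integer(0))
  if (any(!is.finite(x)) || any(!is.finite(y)) ||
      any(x < 0) || any(x > 1) || any(y < 0) || any(y > 1))
    stop("coordinates must be finite and within [0, 1]")
  zz <- zm$zones
  rank <- c(plate = 1L, snap_to_plate = 2L, food = 3L, other = 4L)
  # priority = role rank then vertex index; pick the minimum among containing
  best <- rep.int(.Machine$integer.max, length(x))
  pick <- rep.int(zm$background, length(x))
  for (k in seq_len(nrow(zz))) {
    inside <- x >= zz$x0[k] & x <= zz$x1[k] & y >= zz$y0[k] & y <= zz$y1[k]
    pr <- rank[[zz$role[k]]] * 100L + zz$vertex[k]
    upd <- inside & pr < best
    best[upd] <- pr
    pick[upd] <- zz$vertex[k]
  }
  as.integer(pick)
}

#' Write a zone map to a YAML configuration file
#'
#' Inverse of [load_zone_map()] for the shipped dialect.
#'
#' @param zm a [zone_map()].
#' @param path output file path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_zone_map <- function(zm, path) {
  cfg <- list(
    zones = lapply(seq_len(nrow(zm$zones)), function(i) {
      z <- zm$zones[i, ]
      list(vertex = z$vertex, name = z$name, role = z$role,
           rect = c(z$x0, z$y0, z$x1, z$y1))
    }),
    plate_parent = as.list(zm$plate_parent),
    screen_size = zm$screen_size,
    background = zm$background)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
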