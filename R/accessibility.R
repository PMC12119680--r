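#' Travel-speed table
#'
#' Maps every road and land-cover class to a travel speed and mode, or
#' flags it impassable. Friction (seconds per metre) is `3.6 / speed`
#' for speeds in km/h.
#'
#' @param df data frame with columns `class`, `speed_kmh`, `mode`
#'   (walk / motorcycle / vehicle) and logical `impassable`.
#' @return The validated table, classed `speed_table`.
#' @export
speed_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("class", "speed_kmh", "mode", "impassable") %in% names(df)))
  if (anyDuplicated(df$class)) stop("duplicate class in speed table")
  bad <- !df$impassable & (is.na(df$speed_kmh) | df$speed_kmh <= 0)
  if (any(bad))
    stop("non-positive speed for passable class: ",
         paste(df$class[bad], collapse = ", "))
  structure(df, class = c("speed_table", "data.frame"))
}

#' Default hybrid-mode speed table
#'
#' Literature-style speeds for a rural African setting: vehicle travel
#' on tarmac (80 km/h) and gravel (40 km/h) roads, motorcycle on earth
#' roads (20 km/h), walking across land cover (2-5 km/h), with water
#' impassable. The mode is attached to the surface class, so a journey
#' implicitly switches mode when the path reaches a road.
#'
#' @return A [speed_table()].
#' @export
default_speed_table <- function() {
  speed_table(data.frame(
    class = c("tarmac", "gravel", "earth",
              "farmland", "bushland", "grassland", "wetland", "water"),
    speed_kmh = c(80, 40, 20, 4, 4, 5, 2, NA),
    mode = c("vehicle", "vehicle", "motorcycle",
             "walk", "walk", "walk", "walk", NA),
    impassable = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  ))
}

#' Merge landscape layers into a friction surface
#'
#' Assigns each pixel the traversal cost (seconds per metre) of its
#' surface class: the road class where a road is present (roads
#' override land cover), the land-cover class otherwise. Barrier pixels
#' (water bodies, protected areas) and classes flagged impassable in
#' the speed table get no finite friction.
#'
#' @param layers the `layers` element of a [generate_landscape()]
#'   result, or any named list of aligned [raster_grid()]s with
#'   `road_class`, `land_cover`, `barrier_mask`.
#' @param speeds a [speed_table()].
#' @return A list of class `friction_surface`: `grid` ([raster_grid()]
#'   of s/m, `NA` where impassable) and logical matrix `impassable`.
#' @export
build_friction_surface <- function(layers, speeds = default_speed_table()) {
  road <- layers$road_class; land <- layers$land_cover
  barrier <- layers$barrier_mask
  if (!rasters_aligned(road, land) || !rasters_aligned(road, barrier))
    stop("landscape rasters are not aligned")
  cls <- land$values
  has_road <- road$values != "none"
  cls[has_road] <- road$values[has_road]
  present <- unique(as.vector(cls))
  unmapped <- setdiff(present, speeds$class)
  if (length(unmapped))
    stop("no speed-table entry for class: ", paste(unmapped, collapse = ", "))
  idx <- match(cls, speeds$class)
  fr <- 3.6 / speeds$speed_kmh[idx]
  fr[speeds$impassable[idx]] <- NA
  fr <- matrix(fr, nrow(cls))
  fr[barrier$values] <- NA
  structure(list(grid = raster_grid(fr, road$pixel_size, road$origin),
                 impassable = is.na(fr)),
            class = "friction_surface")
}

# 8-neighbour edge list of the passable pixel graph, weighted by
# d(a, b) * (friction(a) + friction(b)) / 2 in seconds.
friction_edges <- function(friction) {
  f <- friction$grid$values
  nr <- nrow(f); nc <- ncol(f)
  px <- friction$grid$pixel_size
  id <- matrix(seq_len(nr * nc), nr, nc)
  pass <- !friction$impassable
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  from <- to <- integer(0); w <- numeric(0)
  for (o in offs) {
    r1 <- max(1L, 1L - o[1]):min(nr, nr - o[1])
    c1 <- max(1L, 1L - o[2]):min(nc, nc - o[2])
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + o[1], c1 + o[2], drop = FALSE]
    keep <- pass[a] & pass[b]
    d <- px * if (o[1] != 0L && o[2] != 0L) sqrt(2) else 1
    from <- c(from, a[keep]); to <- c(to, b[keep])
    w <- c(w, d * (f[a[keep]] + f[b[keep]]) / 2)
  }
  list(from = from, to = to, weight = w, n = nr * nc)
}

#' Least-cost-path travel time to the hospital
#'
#' Single-source shortest paths on the 8-connected pixel graph with
#' edge cost `d(a, b) * (friction(a) + friction(b)) / 2`, where `d` is
#' the pixel size for rook moves and pixel size times sqrt(2) for
#' diagonal moves. Costs are deterministic, so priority-queue
#' tie-breaking cannot affect the values.
#'
#' @param friction a [build_friction_surface()] result.
#' @param origin hospital location: a column-major pixel index, a
#'   `c(row, col)` pair, or the `hospital` element of a landscape.
#' @return A list of class `travel_time_raster`: `grid`
#'   ([raster_grid()] of minutes, `NA` where unreachable or
#'   impassable), logical matrix `unreachable` (passable pixels with no
#'   route), and `origin` (pixel index).
#' @export
least_cost_travel_time <- function(friction, origin) {
  f <- friction$grid$values
  nr <- nrow(f)
  if (is.list(origin)) origin <- origin$pixel
  if (length(origin) == 2L) origin <- (origin[2] - 1L) * nr + origin[1]
  origin <- as.integer(origin)
  if (origin < 1L || origin > length(f)) stop("origin outside the grid")
  if (friction$impassable[origin]) stop("origin pixel is impassable")
  ed <- friction_edges(friction)
  g <- igraph::make_graph(rbind(ed$from, ed$to), n = ed$n, directed = FALSE)
  secs <- as.vector(igraph::distances(g, v = origin, weights = ed$weight,
                                      algorithm = "dijkstra"))
  mins <- secs / 60
  unreachable <- is.infinite(mins) & !friction$impassable
  mins[is.infinite(mins)] <- NA
  mins[friction$impassable] <- NA
  structure(list(grid = raster_grid(matrix(mins, nr),
                                    friction$grid$pixel_size,
                                    friction$grid$origin),
                 unreachable = matrix(unreachable, nr),
                 origin = origin),
            class = "travel_time_raster")
}

#' Mean travel time per enumeration area
#'
#' Arithmetic mean of the travel-time raster over the passable,
#' reachable pixels belonging to each EA. Membership uses the EA's
#' pixel assignment when available, otherwise pixel-centre-in-polygon.
#' EAs with no reachable pixel are flagged (`NA` mean) with a warning
#' and are meant to be excluded downstream.
#'
#' @param tt a [least_cost_travel_time()] result.
#' @param eas an [ea_set()].
#' @return Data frame: `ea_id`, `mean_travel_min`, `n_pixels`
#'   (reachable pixels contributing), `tt_class` (30-min scheme),
#'   `band15` (15-min scheme).
#' @export
zonal_mean_travel_time <- function(tt, eas) {
  stopifnot(inherits(eas, "ea_set"))
  mins <- tt$grid$values
  pix_list <- eas$pixels
  if (is.null(pix_list)) {
    if (is.null(eas$polygons)) stop("ea_set has neither pixels nor polygons")
    ctr <- pixel_centres(tt$grid)
    pix_list <- lapply(eas$polygons, function(ring)
      which(mgcv::in.out(ring, ctr)))
    names(pix_list) <- eas$table$ea_id
  }
  out <- data.frame(ea_id = eas$table$ea_id, stringsAsFactors = FALSE)
  res <- lapply(out$ea_id, function(id) {
    v <- mins[pix_list[[id]]]
    v <- v[!is.na(v)]
    c(mean = if (length(v)) mean(v) else NA_real_, n = length(v))
  })
  out$mean_travel_min <- vapply(res, `[[`, 0, "mean")
  out$n_pixels <- as.integer(vapply(res, `[[`, 0, "n"))
  if (anyNA(out$mean_travel_min))
    warning("EA(s) with no reachable pixel excluded from analysis: ",
            paste(out$ea_id[is.na(out$mean_travel_min)], collapse = ", "))
  ok <- !is.na(out$mean_travel_min)
  out$tt_class <- NA_character_
  out$band15 <- NA_character_
  out$tt_class[ok] <- bin_travel_time(out$mean_travel_min[ok], "30min")
  out$band15[ok] <- bin_travel_time(out$mean_travel_min[ok], "15min")
  out
}

#' Attach zonal travel times to an EA set
#'
#' @param eas an [ea_set()].
#' @param zonal result of [zonal_mean_travel_time()].
#' @return The `ea_set` with `mean_travel_min` and `tt_class` filled in.
#' @export
attach_travel_time <- function(eas, zonal) {
  stopifnot(inherits(eas, "ea_set"))
  i <- match(eas$table$ea_id, zonal$ea_id)
  eas$table$mean_travel_min <- zonal$mean_travel_min[i]
  eas$table$tt_class <- zonal$tt_class[i]
  eas
}

#' Bin travel time into half-open classes
#'
#' The 30-minute scheme uses [0, 30), [30, 60), [60, 90), [90, Inf)
#' labelled `<30`, `30-59`, `60-89`, `>=90`; the 15-minute scheme is
#' analogous with a final open band at 120 minutes.
#'
#' @param minutes non-negative travel times.
#' @param scheme `"30min"` or `"15min"`.
#' @return Character vector of class labels.
#' @export
bin_travel_time <- function(minutes, scheme = c("30min", "15min")) {
  scheme <- match.arg(scheme)
  if (any(is.na(minutes)) || any(minutes < 0))
    stop("travel time must be non-negative and non-missing")
  if (scheme == "30min") {
    breaks <- c(0, 30, 60, 90, Inf)
    labels <- TT_LEVELS
  } else {
    breaks <- c(seq(0, 120, by = 15), Inf)
    labels <- c("<15", paste(seq(15, 105, 15), seq(29, 119, 15), sep = "-"),
                ">=120")
  }
  as.character(cut(minutes, breaks = breaks, labels = labels, right = FALSE))
}
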