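#' Configuration for the synthetic study region
#'
#' Defaults emulate a rural county served by one referral hospital:
#' a pixel grid carrying road class, land cover, water/protected
#' barriers and altitude, partitioned into enumeration areas (EAs) of
#' roughly village size. Pixel size defaults to 12.5 m, the resolution
#' at which travel time is modelled; coarser pixels (with a larger
#' region) are appropriate for fast end-to-end experiments.
#'
#' @param nx,ny grid size in pixels (each at least 50).
#' @param pixel_size pixel edge length in metres.
#' @param n_eas number of enumeration areas (at least 2).
#' @param n_roads number of roads radiating from the hospital.
#' @param barrier_frac fraction of the region covered by impassable
#'   water/protected cells.
#' @param pop_meanlog,pop_sdlog log-normal parameters for the under-5
#'   population of an EA (default median 100).
#' @param ntl_radius_frac radius, as a fraction of the region diagonal,
#'   within which EAs receive positive night-time light (urban).
#' @param altitude_base,altitude_relief base altitude and relief
#'   amplitude in metres (default 1,140-1,260 m, a western-Kenya
#'   plateau).
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(nx = 100, ny = 100, pixel_size = 12.5,
                             n_eas = 25, n_roads = 6, barrier_frac = 0.05,
                             pop_meanlog = log(100), pop_sdlog = 0.5,
                             ntl_radius_frac = 0.15,
                             altitude_base = 1140, altitude_relief = 120,
                             seed = 1) {
  cfg <- list(nx = nx, ny = ny, pixel_size = pixel_size, n_eas = n_eas,
              n_roads = n_roads, barrier_frac = barrier_frac,
              pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
              ntl_radius_frac = ntl_radius_frac,
              altitude_base = altitude_base,
              altitude_relief = altitude_relief, seed = seed)
  class(cfg) <- "landscape_config"
  cfg
}

# Smooth random field on an nr x nc grid: a sum of Gaussian bumps,
# rescaled to [0, 1]. Cheap stand-in for a geostatistical surface.
blob_field <- function(nr, nc, n_blobs = 15, bandwidth = NULL) {
  if (is.null(bandwidth)) bandwidth <- max(nr, nc) / 6
  ctr <- cbind(stats::runif(n_blobs, 1, nr), stats::runif(n_blobs, 1, nc))
  amp <- stats::runif(n_blobs, 0.3, 1)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  f <- matrix(0, nr, nc)
  for (b in seq_len(n_blobs)) {
    d2 <- (rows - ctr[b, 1])^2 + (cols - ctr[b, 2])^2
    f <- f + amp[b] * exp(-d2 / (2 * bandwidth^2))
  }
  rng <- range(f)
  if (diff(rng) < .Machine$double.eps) return(matrix(0.5, nr, nc))
  (f - rng[1]) / diff(rng)
}

# Trace one road from the start pixel towards a boundary target as a
# jittered 8-neighbour walk; returns a matrix of (row, col) steps.
trace_road <- function(start, target, nr, nc, jitter = 0.25) {
  pos <- start
  path <- matrix(0L, nrow = 2L * (nr + nc), ncol = 2)
  path[1, ] <- pos
  k <- 1L
  moves <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  moves <- moves[!(moves[, 1] == 0 & moves[, 2] == 0), ]
  while (k < nrow(path)) {
    if (all(pos == target)) break
    cand <- sweep(moves, 2, pos, "+")
    ok <- cand[, 1] >= 1 & cand[, 1] <= nr & cand[, 2] >= 1 & cand[, 2] <= nc
    cand <- cand[ok, , drop = FALSE]
    d <- sqrt((cand[, 1] - target[1])^2 + (cand[, 2] - target[2])^2)
    step <- if (stats::runif(1) < jitter) {
      cand[sample.int(nrow(cand), 1L), ]
    } else {
      cand[which.min(d), ]
    }
    pos <- as.integer(step)
    k <- k + 1L
    path[k, ] <- pos
    if (pos[1] %in% c(1L, nr) || pos[2] %in% c(1L, nc)) break
  }
  path[seq_len(k), , drop = FALSE]
}

#' Enumeration-area set
#'
#' Container pairing the per-EA attribute table with each EA's pixel
#' membership (column-major indices into the region grid) and a convex
#' outline polygon used for interchange.
#'
#' @param table data frame with columns `ea_id`, `cx`, `cy`, `pop_u5`,
#'   `ntl`, `pfpr`, `altitude_m` and (once accessibility has run)
#'   `mean_travel_min`.
#' @param polygons named list of two-column (x, y) matrices, one closed
#'   ring per EA.
#' @param pixels named list of integer vectors of pixel indices.
#' @param grid_meta list with `nx`, `ny`, `pixel_size`, `origin`.
#' @return An object of class `ea_set`.
#' @export
ea_set <- function(table, polygons = NULL, pixels = NULL, grid_meta = NULL) {
  stopifnot(is.data.frame(table),
            all(c("ea_id", "pop_u5", "ntl", "pfpr") %in% names(table)))
  if (anyDuplicated(table$ea_id)) stop("duplicate ea_id")
  structure(list(table = table, polygons = polygons, pixels = pixels,
                 grid_meta = grid_meta),
            class = "ea_set")
}

#' @export
print.ea_set <- function(x, ...) {
  cat(sprintf("ea_set: %d enumeration areas, total under-5 population %d\n",
              nrow(x$table), as.integer(round(sum(x$table$pop_u5)))))
  invisible(x)
}

# Accept an ea_set or a bare attribute data frame.
ea_table <- function(eas) {
  if (inherits(eas, "ea_set")) return(eas$table)
  if (is.data.frame(eas)) return(eas)
  stop("`eas` must be an ea_set or a data frame of EA attributes")
}

#' Generate a synthetic landscape and enumeration areas
#'
#' Builds the raster layer stack the accessibility analysis consumes —
#' road class, land cover, barrier mask and altitude — together with a
#' Voronoi partition of the region into enumeration areas carrying
#' under-5 population, night-time light (positive only near the
#' hospital by default) and malaria endemicity (PfPR, a smooth spatial
#' field). Roads radiate from the hospital, so the road network is
#' connected and touches the hospital pixel by construction.
#'
#' @param config a [landscape_config()].
#' @return A list of class `landscape` with elements `layers` (named
#'   list of [raster_grid()]: `road_class`, `land_cover`,
#'   `barrier_mask`, `altitude`), `hospital` (list: `xy` planar
#'   coordinates, `rc` row/col, `pixel` column-major index) and `eas`
#'   (an [ea_set()]).
#' @export
generate_landscape <- function(config = landscape_config()) {
  nx <- config$nx; ny <- config$ny
  if (nx < 50 || ny < 50) stop("region must be at least 50x50 pixels")
  if (config$n_eas < 2) stop("at least 2 enumeration areas are required")
  if (config$barrier_frac >= 1) stop("barrier fraction must be < 1")
  set.seed(config$seed)
  nr <- ny; nc <- nx
  px <- config$pixel_size

  # hospital near the region centre
  hosp_rc <- c(round(nr / 2), round(nc / 2))

  road <- matrix("none", nr, nc)
  road_classes <- c("tarmac", rep(c("gravel", "earth"),
                                  length.out = max(config$n_roads - 1, 0)))
  for (r in seq_len(config$n_roads)) {
    side <- sample.int(4L, 1L)
    target <- switch(side,
      c(1L, sample.int(nc, 1L)), c(nr, sample.int(nc, 1L)),
      c(sample.int(nr, 1L), 1L), c(sample.int(nr, 1L), nc))
    path <- trace_road(hosp_rc, target, nr, nc)
    road[path] <- road_classes[r]
  }

  lc_field <- blob_field(nr, nc, n_blobs = 18)
  qs <- stats::quantile(lc_field, c(0.45, 0.75, 0.95))
  land <- matrix("farmland", nr, nc)
  land[lc_field > qs[1]] <- "bushland"
  land[lc_field > qs[2]] <- "grassland"
  land[lc_field > qs[3]] <- "wetland"

  barrier <- matrix(FALSE, nr, nc)
  if (config$barrier_frac > 0) {
    bf <- blob_field(nr, nc, n_blobs = 8, bandwidth = max(nr, nc) / 10)
    barrier <- bf > stats::quantile(bf, 1 - config$barrier_frac)
  }
  barrier[road != "none"] <- FALSE      # roads bridge water
  barrier[hosp_rc[1], hosp_rc[2]] <- FALSE
  if (mean(barrier) > 0.95) stop("degenerate config: region is nearly all barrier")

  alt <- config$altitude_base +
    config$altitude_relief * blob_field(nr, nc, n_blobs = 10)

  origin <- c(0, 0)
  layers <- list(
    road_class   = raster_grid(road, px, origin),
    land_cover   = raster_grid(land, px, origin),
    barrier_mask = raster_grid(barrier, px, origin),
    altitude     = raster_grid(alt, px, origin)
  )

  # Voronoi partition of pixels into EAs around random seed points
  seeds <- cbind(stats::runif(config$n_eas, 0.5, nr + 0.5),
                 stats::runif(config$n_eas, 0.5, nc + 0.5))
  rows <- rep(seq_len(nr), times = nc)   # column-major pixel order
  cols <- rep(seq_len(nc), each = nr)
  d2min <- rep(Inf, nr * nc)
  assign <- integer(nr * nc)
  for (k in seq_len(config$n_eas)) {
    d2 <- (rows - seeds[k, 1])^2 + (cols - seeds[k, 2])^2
    hit <- d2 < d2min
    assign[hit] <- k
    d2min[hit] <- d2[hit]
  }

  centres <- pixel_centres(layers$altitude)
  hosp_pixel <- (hosp_rc[2] - 1L) * nr + hosp_rc[1]
  hosp_xy <- centres[hosp_pixel, ]
  diag_len <- sqrt((nc * px)^2 + (nr * px)^2)
  pfpr_field <- blob_field(nr, nc, n_blobs = 12)

  pix <- split(seq_len(nr * nc), assign)
  names(pix) <- paste0("EA", sprintf("%03d", as.integer(names(pix))))
  tab <- data.frame(ea_id = names(pix), stringsAsFactors = FALSE)
  tab$cx <- vapply(pix, function(i) mean(centres[i, 1]), 0)
  tab$cy <- vapply(pix, function(i) mean(centres[i, 2]), 0)
  tab$pop_u5 <- pmax(1, round(stats::rlnorm(nrow(tab), config$pop_meanlog,
                                            config$pop_sdlog)))
  d_hosp <- sqrt((tab$cx - hosp_xy[1])^2 + (tab$cy - hosp_xy[2])^2)
  urban <- d_hosp < config$ntl_radius_frac * diag_len
  tab$ntl <- ifelse(urban, round(stats::runif(nrow(tab), 5, 60) *
                                   pmax(0.1, 1 - d_hosp / diag_len), 1), 0)
  tab$pfpr <- round(0.15 + 0.40 *
                      vapply(pix, function(i) mean(pfpr_field[i]), 0), 4)
  tab$altitude_m <- vapply(pix, function(i) mean(alt[i]), 0)
  tab$mean_travel_min <- NA_real_

  polys <- lapply(pix, function(i) {
    xy <- centres[i, , drop = FALSE]
    hull <- grDevices::chull(xy)
    ring <- xy[c(hull, hull[1]), , drop = FALSE]
    colnames(ring) <- c("x", "y")
    ring
  })

  eas <- ea_set(tab, polygons = polys, pixels = pix,
                grid_meta = list(nx = nc, ny = nr, pixel_size = px,
                                 origin = origin))
  structure(list(layers = layers,
                 hospital = list(xy = hosp_xy, rc = hosp_rc,
                                 pixel = hosp_pixel),
                 eas = eas, config = config),
            class = "landscape")
}

#' Simulate a Matern Gaussian random field at EA centroids
#'
#' Draws one realisation of a zero-mean multivariate normal whose
#' covariance between two EAs is the Matern function of the Euclidean
#' distance between their centroids (see [matern_covariance()]). Used
#' as the spatial random effect \eqn{\omega(s_k)} on the generative side.
#'
#' @param centroids two-column matrix of planar EA centroids (metres).
#' @param matern a [matern_params()] object.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return Numeric vector, one value per centroid.
#' @export
simulate_matern_field <- function(centroids, matern, seed = NULL) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 1L) stop("at least one centroid is required")
  validate_matern(matern)
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(centroids)
  if (matern$sigma2 == 0) return(rep(0, m))
  K <- matern_covariance_matrix(centroids, matern)
  L <- chol_with_jitter(K, max_jitter = 1e-8 * matern$sigma2)
  drop(t(L) %*% stats::rnorm(m))
}

# Upper-triangular Cholesky with escalating diagonal jitter up to
# max_jitter; fails loudly if the matrix is not PD even then.
chol_with_jitter <- function(K, max_jitter) {
  jit <- 0
  repeat {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- if (jit == 0) max_jitter / 100 else jit * 10
    if (jit > max_jitter)
      stop("covariance matrix not positive definite after jitter")
  }
}

#' Generative truth for the synthetic cohort
#'
#' Bundles the parameters of the severity model used to simulate
#' admissions: a Bernoulli-logit for severe (vs mild/moderate) anaemia
#' with travel-time class effects, covariate effects, a Matern spatial
#' random effect over EA centroids and an optional iid observation
#' term. Default travel-time log-odds-ratios are (log 2.44, log 3.55,
#' log 3.41) for the 30-59, 60-89 and >=90 minute classes, i.e. a
#' strong, monotone-then-plateauing distance effect of the size seen in
#' referral-hospital admission data.
#'
#' @param beta0 log-odds intercept (reference child, <30 min class).
#' @param beta_tt length-3 numeric: log-ORs for classes 30-59, 60-89,
#'   >=90 relative to <30 min.
#' @param beta_cov named numeric vector of covariate log-ORs, names
#'   matching [build_design_matrix()] columns; unnamed effects are 0.
#' @param matern a [matern_params()] for the spatial field.
#' @param iid_sd standard deviation of the optional per-admission
#'   Gaussian term (default 0: weakly identified under a Bernoulli
#'   likelihood, so off unless explicitly requested).
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(beta0 = -6.2,
                            beta_tt = log(c(2.44, 3.55, 3.41)),
                            beta_cov = default_covariate_effects(),
                            matern = matern_params(sigma2 = 0.5,
                                                   kappa = 2e-4, nu = 1),
                            iid_sd = 0) {
  stopifnot(length(beta_tt) == 3L, iid_sd >= 0)
  validate_matern(matern)
  structure(list(beta0 = beta0, beta_tt = beta_tt, beta_cov = beta_cov,
                 matern = matern, iid_sd = iid_sd),
            class = "synthetic_truth")
}

#' Default generative covariate effects
#'
#' Log-odds-ratios for the candidate covariates, chosen so that the
#' eight covariates that matter in practice (age, nutrition,
#' vaccination, malaria diagnosis, sickle-cell disease, weekday
#' admission, community PfPR and rural residence) carry detectable
#' effects at a cohort of around two thousand admissions, while sex and
#' season are null or negligible.
#'
#' @return Named numeric vector of log-ORs.
#' @export
default_covariate_effects <- function() {
  c(age_1 = 0.25, age_2 = 0.8, age_3 = 0.85, age_4 = 1.0,
    female = 0,
    nutrition_mild = 0.25, nutrition_moderate = 0.4, nutrition_severe = 0.45,
    nutrition_missing = 0,
    vaccinated = 0.8, malaria_dx = 0.8, scd = 1.0,
    weekday = 0.35, wet_season = -0.05, pfpr = 4.0, rural = 1.2)
}

# Pools of surveillance-window dates, cross-classified by weekday and
# wet season (wet: Apr-Jun and Oct-Dec).
date_pools <- function(from = "2020-01-01", to = "2023-06-30") {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  wd <- !(format(dates, "%u") %in% c("6", "7"))
  wet <- as.integer(format(dates, "%m")) %in% c(4:6, 10:12)
  list(dates = dates, weekday = wd, wet = wet)
}

#' Simulate an admission cohort from known truth
#'
#' Generates per-admission records with the statistical structure the
#' downstream analysis assumes. Admissions are allocated to EAs with
#' probability proportional to under-5 population, optionally damped by
#' an exponential distance-decay attendance weight
#' `exp(-travel_time / decay_tau)` reflecting lower utilisation from
#' distal villages. Severity is severe with probability
#' `plogis(beta0 + beta_tt[class] + x'beta_cov + omega + eps)`; other
#' admissions split mild vs moderate by a fixed auxiliary probability.
#' Raw haemoglobin is back-constructed so that altitude adjustment at
#' the EA's mean altitude reproduces the generated class. Fractions of
#' records are flagged with cause-based exclusions, missing Hb, or
#' non-anaemic Hb so the exclusion cascade is exercised end to end.
#'
#' @param eas an [ea_set()] or EA attribute data frame (columns
#'   `ea_id`, `pop_u5`, `ntl`, `pfpr`; optional `altitude_m`, `cx`,
#'   `cy`, `mean_travel_min`).
#' @param tt_class character vector of travel-time classes (levels
#'   `<30`, `30-59`, `60-89`, `>=90`), one per EA row, or a named
#'   vector keyed by `ea_id`.
#' @param truth a [synthetic_truth()].
#' @param n_admissions number of admission records to generate.
#' @param seed integer seed.
#' @param marginals covariate marginals, see [covariate_marginals()].
#' @param decay_tau attendance distance-decay scale in minutes
#'   (`NULL` disables decay). Requires `mean_travel_min` on the EAs.
#' @param p_mild_given_nonsevere probability a non-severe anaemic
#'   admission is mild rather than moderate (default 1151/1553).
#' @param p_not_anaemic probability of a non-anaemic (Hb >= 10) record.
#' @param p_excluded_cause probability of a cause-based exclusion flag.
#' @param p_missing_hb probability the Hb result is missing.
#' @return A list of class `synthetic_cohort`: `admissions` (data
#'   frame), `truth`, `omega` (named per-EA spatial effects), `seed`.
#' @export
simulate_admissions <- function(eas, tt_class, truth = synthetic_truth(),
                                n_admissions, seed = 1,
                                marginals = covariate_marginals(),
                                decay_tau = NULL,
                                p_mild_given_nonsevere = 1151 / 1553,
                                p_not_anaemic = 0,
                                p_excluded_cause = 0,
                                p_missing_hb = 0) {
  tab <- ea_table(eas)
  if (n_admissions < 1) stop("n_admissions must be at least 1")
  if (!is.null(names(tt_class)) && all(nzchar(names(tt_class)))) {
    if (!all(tab$ea_id %in% names(tt_class)))
      stop("travel-time class missing for some EAs")
    tt_class <- tt_class[tab$ea_id]
  }
  if (length(tt_class) != nrow(tab))
    stop("`tt_class` must provide one class per EA")
  if (any(is.na(tt_class)) || !all(tt_class %in% TT_LEVELS))
    stop("invalid travel-time class; expected one of: ",
         paste(TT_LEVELS, collapse = ", "))
  set.seed(seed)

  # spatial random effect at EA centroids
  omega <- if (truth$matern$sigma2 > 0) {
    if (!all(c("cx", "cy") %in% names(tab)))
      stop("EA centroids (cx, cy) required when matern sigma2 > 0")
    simulate_matern_field(cbind(tab$cx, tab$cy), truth$matern)
  } else rep(0, nrow(tab))
  names(omega) <- tab$ea_id

  w <- tab$pop_u5
  if (!is.null(decay_tau)) {
    if (!"mean_travel_min" %in% names(tab) || anyNA(tab$mean_travel_min))
      stop("distance decay requires mean_travel_min on the EAs")
    w <- w * exp(-tab$mean_travel_min / decay_tau)
  }
  ea_idx <- sample.int(nrow(tab), n_admissions, replace = TRUE, prob = w)

  n <- n_admissions
  age_cat <- sample(names(marginals$age), n, TRUE,
                    prob = marginals$age / sum(marginals$age))
  age_lo <- c("<1" = 1, "1" = 12, "2" = 24, "3" = 36, "4" = 48)[age_cat]
  age_months <- as.integer(age_lo + floor(stats::runif(n, 0, 12)))
  age_months <- pmin(age_months, 59L)
  sex <- ifelse(stats::runif(n) < marginals$p_female, "female", "male")
  nut <- sample(names(marginals$nutrition), n, TRUE,
                prob = marginals$nutrition / sum(marginals$nutrition))
  muac_z <- numeric(n)
  muac_z[nut == "well"] <- stats::runif(sum(nut == "well"), -1, 1.5)
  muac_z[nut == "mild"] <- stats::runif(sum(nut == "mild"), -2, -1)
  muac_z[nut == "moderate"] <- stats::runif(sum(nut == "moderate"), -3, -2)
  muac_z[nut == "severe"] <- stats::runif(sum(nut == "severe"), -4, -3)
  muac_z[stats::runif(n) < marginals$p_muac_missing] <- NA
  vaccinated <- stats::runif(n) < marginals$p_vaccinated
  malaria_dx <- stats::runif(n) < marginals$p_malaria
  scd <- stats::runif(n) < marginals$p_scd
  weekday <- stats::runif(n) < marginals$p_weekday
  wet <- stats::runif(n) < marginals$p_wet
  pools <- date_pools()
  date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  for (w_flag in c(TRUE, FALSE)) for (s_flag in c(TRUE, FALSE)) {
    sel <- weekday == w_flag & wet == s_flag
    pool <- pools$dates[pools$weekday == w_flag & pools$wet == s_flag]
    if (any(sel)) date[sel] <- sample(pool, sum(sel), replace = TRUE)
  }

  cohort <- data.frame(
    admission_id = sprintf("A%05d", seq_len(n)),
    ea_id = tab$ea_id[ea_idx],
    date = date,
    age_months = age_months,
    age_cat = age_cat,
    sex = sex,
    muac_z = muac_z,
    nutrition = nutrition_class(muac_z),
    vaccinated = vaccinated,
    malaria_dx = malaria_dx,
    scd = scd,
    weekday = weekday,
    wet_season = wet,
    pfpr = tab$pfpr[ea_idx],
    ntl = tab$ntl[ea_idx],
    rural = tab$ntl[ea_idx] == 0,
    tt_class = tt_class[ea_idx],
    resident = TRUE,
    stringsAsFactors = FALSE
  )
  if ("mean_travel_min" %in% names(tab))
    cohort$mean_travel_min <- tab$mean_travel_min[ea_idx]

  X <- build_design_matrix(cohort, blocks = candidate_covariates(),
                           intercept = FALSE)
  beta <- numeric(ncol(X))
  names(beta) <- colnames(X)
  beta[c("tt_30_59", "tt_60_89", "tt_90_plus")] <- truth$beta_tt
  common <- intersect(names(truth$beta_cov), names(beta))
  beta[common] <- truth$beta_cov[common]
  eps <- if (truth$iid_sd > 0) stats::rnorm(n, 0, truth$iid_sd) else 0
  eta <- truth$beta0 + drop(X %*% beta) + omega[cohort$ea_id] + eps
  severe <- stats::runif(n) < stats::plogis(eta)
  severity <- ifelse(severe, "severe",
                     ifelse(stats::runif(n) < p_mild_given_nonsevere,
                            "mild", "moderate"))
  severity[stats::runif(n) < p_not_anaemic] <- "not_anaemic"

  hb_adj <- numeric(n)
  hb_adj[severity == "severe"] <- stats::runif(sum(severity == "severe"), 2.5, 5)
  hb_adj[severity == "moderate"] <- stats::runif(sum(severity == "moderate"), 5, 7)
  hb_adj[severity == "mild"] <- stats::runif(sum(severity == "mild"), 7, 10)
  hb_adj[severity == "not_anaemic"] <-
    stats::runif(sum(severity == "not_anaemic"), 10, 13)
  altitude <- if ("altitude_m" %in% names(tab)) tab$altitude_m[ea_idx] else 0
  cohort$hb_raw <- hb_adj + who_altitude_increment(altitude)
  cohort$severity_true <- severity

  causes <- c("bite", "burn", "malignancy", "poisoning", "surgery", "trauma")
  cohort$exclusion_cause <- ifelse(stats::runif(n) < p_excluded_cause,
                                   sample(causes, n, TRUE), "none")
  cohort$hb_raw[stats::runif(n) < p_missing_hb] <- NA

  structure(list(admissions = cohort, truth = truth, omega = omega,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d admissions over %d EAs (seed %d)\n",
              nrow(x$admissions), length(unique(x$admissions$ea_id)),
              x$seed))
  invisible(x)
}
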