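small_cfg <- function(seed = 1, ...) {
  landscape_config(nx = 50, ny = 50, pixel_size = 100, n_eas = 12,
                   seed = seed, ...)
}

test_that("landscape generation is a pure function of (config, seed)", {
  a <- generate_landscape(small_cfg(seed = 4))
  b <- generate_landscape(small_cfg(seed = 4))
  expect_identical(a$layers, b$layers)
  expect_identical(a$eas$table, b$eas$table)
  c <- generate_landscape(small_cfg(seed = 5))
  expect_false(identical(a$layers$land_cover$values,
                         c$layers$land_cover$values))
})

test_that("landscape respects configured structure", {
  land <- generate_landscape(small_cfg(seed = 2, barrier_frac = 0))
  expect_false(any(land$layers$barrier_mask$values))
  # hospital pixel is passable and touched by a road
  rc <- land$hospital$rc
  expect_false(land$layers$barrier_mask$values[rc[1], rc[2]])
  expect_true(land$layers$road_class$values[rc[1], rc[2]] != "none")
  # every pixel belongs to exactly one EA
  all_pix <- sort(unname(unlist(land$eas$pixels)))
  expect_identical(all_pix, seq_len(50 * 50))
  # degenerate configs fail fast
  expect_error(generate_landscape(landscape_config(nx = 10, ny = 10)),
               "50x50")
  expect_error(
    generate_landscape(landscape_config(nx = 50, ny = 50, n_eas = 1)),
    "2 enumeration")
})

test_that("Matern field simulation has the right marginal moments", {
  p1 <- matern_params(sigma2 = 1, kappa = 1e-3, nu = 1)
  set.seed(11)
  draws <- replicate(10000, simulate_matern_field(cbind(0, 0), p1))
  expect_lt(abs(mean(draws)), 0.05)
  expect_lt(abs(var(draws) - 1), 0.05)

  p0 <- matern_params(sigma2 = 0, kappa = 1e-3, nu = 1)
  expect_identical(simulate_matern_field(cbind(c(0, 10), c(0, 0)), p0,
                                         seed = 1),
                   c(0, 0))
})

test_that("exponential-limit correlation matches exp(-kappa*h) at nu = 1/2", {
  h <- 800
  kap <- 1 / 1000
  p <- matern_params(sigma2 = 1, kappa = kap, nu = 0.5)
  coords <- cbind(c(0, h), c(0, 0))
  set.seed(22)
  draws <- replicate(20000, simulate_matern_field(coords, p))
  expect_lt(abs(cor(draws[1, ], draws[2, ]) - exp(-kap * h)), 0.02)
})

test_that("simulated variogram of the spatial field rises to the sill", {
  # correlation is negligible beyond ~ sqrt(8)/kappa; with kappa chosen
  # large relative to the domain the far bins estimate the sill sigma2
  m <- 40
  set.seed(31)
  coords <- cbind(runif(m, 0, 10000), runif(m, 0, 10000))
  p <- matern_params(sigma2 = 0.8, kappa = 2e-3, nu = 1)
  reps <- 400
  far <- numeric(reps)
  for (r in seq_len(reps)) {
    f <- simulate_matern_field(coords, p)
    v <- empirical_variogram(f, coords, n_bins = 6)
    far[r] <- mean(v$semivariance[5:6], na.rm = TRUE)
  }
  expect_lt(abs(mean(far) - p$sigma2) / p$sigma2, 0.15)
})

test_that("admission generator reproduces the intercept-only severe rate", {
  eaf <- make_ea_frame(20, seed = 3)
  truth <- synthetic_truth(beta0 = qlogis(0.3), beta_tt = c(0, 0, 0),
                           beta_cov = c(none = 0),
                           matern = matern_params(0, 1e-3, 1), iid_sd = 0)
  sim <- simulate_admissions(eaf, setNames(eaf$tt_class, eaf$ea_id),
                             truth = truth, n_admissions = 10000, seed = 9)
  sev <- mean(sim$admissions$severity_true == "severe")
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(sev - 0.3), 3 * se)
})

test_that("class-specific odds ratios converge to the generative truth", {
  eaf <- make_ea_frame(60, seed = 5)
  truth <- synthetic_truth(beta0 = qlogis(0.25),
                           beta_tt = c(log(2.44), 0, 0),
                           beta_cov = c(none = 0),
                           matern = matern_params(0, 1e-3, 1))
  sim <- simulate_admissions(eaf, setNames(eaf$tt_class, eaf$ea_id),
                             truth = truth, n_admissions = 1e5, seed = 13)
  d <- sim$admissions
  sev <- d$severity_true == "severe"
  a <- sum(sev & d$tt_class == "30-59")
  b <- sum(!sev & d$tt_class == "30-59")
  c0 <- sum(sev & d$tt_class == "<30")
  d0 <- sum(!sev & d$tt_class == "<30")
  expect_lt(abs(log((a / b) / (c0 / d0)) - log(2.44)), 0.05)
})

test_that("generator is deterministic and calibrated to its marginals", {
  eaf <- make_ea_frame(20, seed = 3)
  tt <- setNames(eaf$tt_class, eaf$ea_id)
  s1 <- simulate_admissions(eaf, tt, n_admissions = 500, seed = 42)
  s2 <- simulate_admissions(eaf, tt, n_admissions = 500, seed = 42)
  expect_identical(s1$admissions, s2$admissions)

  big <- simulate_admissions(eaf, tt, n_admissions = 10000, seed = 7)$admissions
  marg <- covariate_marginals()
  tol <- 3 * sqrt(0.5 * 0.5 / 10000) + 0.005
  expect_lt(abs(mean(big$sex == "female") - marg$p_female), tol)
  expect_lt(abs(mean(big$malaria_dx) - marg$p_malaria), tol)
  expect_lt(abs(mean(big$weekday) - marg$p_weekday), tol)
  expect_lt(abs(mean(big$age_cat == "<1") -
                  marg$age[["<1"]] / sum(marg$age)), tol)
  # derived flags agree with the calendar date
  wd <- !(format(big$date, "%u") %in% c("6", "7"))
  expect_identical(unname(wd), big$weekday)
  wet <- as.integer(format(big$date, "%m")) %in% c(4:6, 10:12)
  expect_identical(unname(wet), big$wet_season)
})

test_that("generator validates its inputs", {
  eaf <- make_ea_frame(5, seed = 1)
  expect_error(simulate_admissions(eaf, c("<30", "30-59"),
                                   n_admissions = 10),
               "one class per EA")
  bad_tt <- setNames(rep("<30", 4), eaf$ea_id[1:4])
  expect_error(simulate_admissions(eaf, bad_tt, n_admissions = 10),
               "missing for some EAs")
  expect_error(simulate_admissions(eaf, setNames(rep("soon", 5), eaf$ea_id),
                                   n_admissions = 10),
               "invalid travel-time class")
})

test_that("EA GeoJSON round-trips attributes and polygons", {
  land <- generate_landscape(small_cfg(seed = 6))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_ea_geojson(land$eas, f)
  back <- read_ea_geojson(f)
  expect_equal(back$table$ea_id, land$eas$table$ea_id)
  expect_equal(back$table$pop_u5, land$eas$table$pop_u5)
  expect_equal(back$table$pfpr, land$eas$table$pfpr)
  id <- land$eas$table$ea_id[1]
  expect_equal(back$polygons[[id]], land$eas$polygons[[id]],
               ignore_attr = TRUE)
})
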