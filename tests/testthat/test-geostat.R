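test_that("Matern covariance matches its closed forms", {
  # nu = 1/2: exponential
  p <- matern_params(sigma2 = 1, kappa = 1, nu = 0.5)
  expect_equal(matern_covariance(1, p), exp(-1), tolerance = 1e-10)
  expect_equal(matern_covariance(2.5, p), exp(-2.5), tolerance = 1e-10)
  # nu = 3/2: (1 + kh) exp(-kh)
  p32 <- matern_params(sigma2 = 1, kappa = 1, nu = 1.5)
  expect_equal(matern_covariance(2, p32), 3 * exp(-2), tolerance = 1e-10)
  # h = 0 limit is the marginal variance
  p2 <- matern_params(sigma2 = 2.7, kappa = 1e-3, nu = 1)
  expect_equal(matern_covariance(0, p2), 2.7)
  # scaling in sigma2
  expect_equal(matern_covariance(700, p2),
               2.7 * matern_covariance(700, matern_params(1, 1e-3, 1)))
  expect_error(matern_params(-1, 1, 1), "sigma2")
  expect_error(matern_params(1, 0, 1), "kappa")
  expect_error(matern_covariance(-1, p), ">= 0")
})

test_that("Matern matrices are positive definite after tiny jitter", {
  set.seed(5)
  for (nu in c(0.5, 1, 1.5)) {
    coords <- cbind(runif(80, 0, 20000), runif(80, 0, 20000))
    K <- ecaccess:::matern_covariance_matrix(coords,
                                             matern_params(1.3, 3e-4, nu))
    expect_equal(K, t(K))
    L <- ecaccess:::chol_with_jitter(K, max_jitter = 1e-8 * 1.3)
    expect_true(all(diag(L) > 0))
  }
})

test_that("screening keeps true effects and is calibrated on null ones", {
  eaf <- make_ea_frame(120, seed = 14)
  # a covariate identical to the outcome is always retained
  sim <- simulate_admissions(eaf, setNames(eaf$tt_class, eaf$ea_id),
                             n_admissions = 800, seed = 5)
  res <- apply_exclusions(sim$admissions, altitude_m = 1200)
  cohort <- res$cohort
  cohort$malaria_dx <- cohort$severity == "severe"   # proxy = outcome
  sc <- suppressWarnings(univariate_screen(cohort,
                                           candidates = "malaria_dx"))
  expect_true(sc$selected)

  # null covariate retained about 20% of the time at alpha = 0.2
  set.seed(31)
  hits <- replicate(300, {
    cohort$wet_season <- runif(nrow(cohort)) < 0.5
    univariate_screen(cohort, candidates = "wet_season")$selected
  })
  expect_lt(abs(mean(hits) - 0.2), 0.07)   # 3 binomial SEs at 300 reps
})

test_that("the screen separates true effects from null covariates", {
  effect_blocks <- c("age_cat", "nutrition", "vaccinated", "malaria_dx",
                     "scd", "weekday", "pfpr", "rural")
  null_blocks <- c("sex", "wet_season")
  seeds <- 1:20
  sel <- matrix(NA, length(seeds), 10,
                dimnames = list(NULL, candidate_covariates()))
  for (s in seeds) {
    eaf <- make_ea_frame(300, seed = s)
    sim <- simulate_admissions(eaf, setNames(eaf$tt_class, eaf$ea_id),
                               n_admissions = 2187, seed = s + 500,
                               decay_tau = 25)
    res <- apply_exclusions(sim$admissions, altitude_m = 1200)
    sc <- univariate_screen(res$cohort)
    sel[s, ] <- sc$selected[match(colnames(sel), sc$block)]
  }
  rate <- colMeans(sel)
  # unambiguous effects are picked up essentially always
  expect_true(all(rate[c("age_cat", "malaria_dx", "scd", "rural")] >= 0.95))
  # borderline effects (of the size seen in admission data) mostly so
  expect_true(all(rate[effect_blocks] >= 0.75))
  # null covariates stay near the 20% false-retention rate
  expect_true(all(rate[null_blocks] <= 0.4))
})

test_that("variograms are flat for iid residuals and recover structure", {
  # trivial: identical residuals give zero semivariance
  v0 <- empirical_variogram(c(1, 1, 1),
                            rbind(c(0, 0), c(10, 0), c(1000, 0)),
                            n_bins = 2)
  expect_true(any(v0$n_pairs > 0))
  expect_true(all(v0$semivariance[v0$n_pairs > 0] == 0))

  # iid field: no positive trend of semivariance with lag
  set.seed(46)
  coords <- cbind(runif(200, 0, 30000), runif(200, 0, 30000))
  slopes <- replicate(50, {
    v <- empirical_variogram(rnorm(200), coords, n_bins = 10)
    ok <- v$n_pairs > 0
    coef(lm(v$semivariance[ok] ~ v$lag_mid[ok]))[2]
  })
  expect_lt(abs(mean(slopes)) / sd(slopes) * sqrt(50), 3)

  # exponential field: sill and range recovered within 25%
  p <- matern_params(sigma2 = 1, kappa = 4e-4, nu = 0.5)
  set.seed(47)
  coords2 <- cbind(runif(500, 0, 30000), runif(500, 0, 30000))
  f <- simulate_matern_field(coords2, p)
  v <- empirical_variogram(f, coords2, n_bins = 12)
  fit <- stats::nls(semivariance ~ s * (1 - exp(-lag_mid * k)),
                    data = v[v$n_pairs > 0, ],
                    start = list(s = 0.5, k = 1e-4))
  est <- coef(fit)
  expect_lt(abs(est[["s"]] - 1), 0.25)
  expect_lt(abs(est[["k"]] - 4e-4) / 4e-4, 0.25)
})

test_that("with sigma2 = 0 the Laplace fit matches the logistic MLE", {
  # intercept-only: posterior mean near logit(0.3)
  set.seed(61)
  y <- runif(2000) < 0.3
  cohort <- data.frame(severity = ifelse(y, "severe", "mild"),
                       tt_class = "<30", ea_id = "EA1",
                       stringsAsFactors = FALSE)
  # degenerate design: intercept only (single tt class drops out)
  fit <- fit_spatial_logit(cohort,
                           model_spec(blocks = character(), sigma2 = 0))
  b0 <- fit$coefficients$mean[fit$coefficients$term == "(Intercept)"]
  expect_lt(abs(b0 - qlogis(mean(y))), 0.01 + 0)
  expect_lt(abs(b0 - qlogis(0.3)), 0.1)

  # with covariates, coefficients agree with glm within 0.01
  eaf <- make_ea_frame(80, seed = 9)
  truth <- synthetic_truth(matern = matern_params(0, 1e-3, 1))
  sim <- simulate_admissions(eaf, setNames(eaf$tt_class, eaf$ea_id),
                             truth = truth, n_admissions = 2500, seed = 10)
  res <- apply_exclusions(sim$admissions, altitude_m = 1200)
  spec <- model_spec(blocks = c("malaria_dx", "scd", "rural"), sigma2 = 0)
  fit2 <- fit_spatial_logit(res$cohort, spec)
  X <- build_design_matrix(res$cohort, spec$blocks, intercept = FALSE)
  glm_fit <- glm(I(severity == "severe") ~ X, family = binomial,
                 data = res$cohort)
  expect_equal(fit2$coefficients$mean, unname(coef(glm_fit)),
               tolerance = 0.011)
})

test_that("spatial fit recovers effects and reduces to sane AOR tables", {
  eaf <- make_ea_frame(150, seed = 17)
  truth <- synthetic_truth()
  sim <- simulate_admissions(eaf, setNames(eaf$tt_class, eaf$ea_id),
                             truth = truth, n_admissions = 2187, seed = 18,
                             decay_tau = 25)
  res <- apply_exclusions(sim$admissions, altitude_m = 1200)
  fit <- fit_spatial_logit(res$cohort, model_spec(), eaf)
  cf <- fit$coefficients
  i <- match(c("tt_30_59", "tt_60_89", "tt_90_plus"), cf$term)
  # credible intervals are ordered and positive on the OR scale
  expect_true(all(cf$aor_lo[i] < cf$aor[i] & cf$aor[i] < cf$aor_hi[i]))
  expect_true(all(cf$aor_lo[i] > 0))
  # point estimates land in a plausible neighbourhood of the truth
  expect_true(all(abs(log(cf$aor[i]) - truth$beta_tt) < 1.5))

  tab <- adjusted_or_table(fit, res$cohort)
  expect_equal(tab$tt_class, c("<30", "30-59", "60-89", ">=90"))
  expect_true(all(is.na(tab[1, c("crude_or", "aor")])))
  expect_equal(sum(tab$n), nrow(res$cohort))
  expect_equal(sum(tab$pct), 100, tolerance = 1e-8)
  # the crude column equals the descriptive module's calculation
  sev <- res$cohort$severity == "severe"
  a <- sum(sev & res$cohort$tt_class == "30-59")
  b <- sum(!sev & res$cohort$tt_class == "30-59")
  c0 <- sum(sev & res$cohort$tt_class == "<30")
  d0 <- sum(!sev & res$cohort$tt_class == "<30")
  expect_equal(tab$crude_or[2], crude_or(a, b, c0, d0)$or)
})

test_that("fit validates its inputs", {
  cohort <- data.frame(severity = c("severe", "mild"), tt_class = "<30",
                       ea_id = "EAX", stringsAsFactors = FALSE)
  expect_error(fit_spatial_logit(cohort, model_spec(blocks = character())),
               "eas")
  expect_error(fit_spatial_logit(cohort,
                                 model_spec(blocks = character(),
                                            include_iid = TRUE),
                                 eas = make_ea_frame(5)),
               "iid")
  expect_error(fit_spatial_logit(cohort, model_spec(blocks = character()),
                                 eas = make_ea_frame(5)),
               "unknown EA")
})
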