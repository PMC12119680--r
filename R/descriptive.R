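#' Admission rate per 1,000 children
#'
#' Rate over the whole surveillance window (not annualised):
#' `1000 * count / pop_u5`.
#'
#' @param count admissions in the unit (EA or travel-time band).
#' @param pop_u5 under-5 population denominator (> 0).
#' @return Numeric rate per 1,000 children.
#' @export
admission_rate <- function(count, pop_u5) {
  if (any(is.na(pop_u5)) || any(pop_u5 <= 0))
    stop("population denominator must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  1000 * count / pop_u5
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes number of successes (0 <= successes <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)` on the proportion scale.
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  if (n < 1) stop("n must be at least 1")
  if (successes < 0 || successes > n)
    stop("successes must lie in [0, n]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  # boundary counts have exact limits (avoids 1e-17 round-off residue)
  lower <- if (successes == 0) 0 else max(0, centre - half)
  upper <- if (successes == n) 1 else min(1, centre + half)
  c(lower = lower, upper = upper)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1
#' degrees of freedom. When every observation is tied the tie
#' correction degenerates; by convention H = 0 and p = 1.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return List with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("at least two groups are required")
  if (any(vapply(groups, length, 0L) == 0L)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) stop("at least 3 observations are required")
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (length(unique(x)) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1))
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Fisher's exact test for an r x c contingency table
#'
#' 2x2 tables use the exact two-sided point-probability rule. Larger
#' tables are tested exactly when the total is at most `exact_max`,
#' otherwise by Monte-Carlo simulation with a fixed seed; the
#' Monte-Carlo p-value is returned with its binomial standard error.
#'
#' @param table matrix of non-negative integer counts with positive
#'   margins.
#' @param exact_max largest table total for which the exact network
#'   algorithm is attempted (default 200).
#' @param B Monte-Carlo replicates (default 1e5).
#' @param seed seed for the Monte-Carlo path.
#' @return List with `p_value`, `method` ("exact" or "monte-carlo") and
#'   `mc_se` (`NA` for exact).
#' @export
fisher_exact <- function(table, exact_max = 200, B = 1e5, seed = 1) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("empty margin in contingency table")
  two_by_two <- all(dim(table) == c(2L, 2L))
  if (two_by_two || sum(table) <= exact_max) {
    p <- stats::fisher.test(table)$p.value
    return(list(p_value = min(p, 1), method = "exact", mc_se = NA_real_))
  }
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  p <- stats::fisher.test(table, simulate.p.value = TRUE, B = B)$p.value
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(p_value = p, method = "monte-carlo", mc_se = sqrt(p * (1 - p) / B))
}

#' Crude odds ratio with Woolf confidence interval
#'
#' For a 2x2 table with `a` severe-exposed, `b` other-exposed, `c`
#' severe-reference, `d` other-reference: OR = (a/b) / (c/d), CI from
#' log-OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d). Zero cells trigger the
#' Haldane-Anscombe +0.5 correction to every cell, flagged in the
#' output.
#'
#' @param a,b,c,d cell counts (exposed severe/other, reference
#'   severe/other).
#' @param level confidence level.
#' @return List: `or`, `lower`, `upper`, `corrected` (logical).
#' @export
crude_or <- function(a, b, c, d, level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) stop("cell counts must be >= 0")
  if ((a == 0 && b == 0) || (c == 0 && d == 0))
    stop("all-zero row in 2x2 table")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a / b) / (c / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se),
       corrected = corrected)
}

# Severity column order used in summary tables.
SEVERITY_LEVELS <- c("mild", "moderate", "severe")

#' Severity-stratified characteristics table
#'
#' Cross-tabulates each covariate block against anaemia severity with
#' counts, column percentages within severity class, Wilson 95%
#' intervals, medians/IQRs for continuous variables, and a test
#' p-value per block: Fisher's exact test for categorical blocks
#' (Monte-Carlo above `exact_max` unless `fisher_mode = "exact"`),
#' Kruskal-Wallis for continuous ones.
#'
#' @param cohort analysis cohort with `severity` plus the covariate
#'   columns (`tt_class`, `age_cat`, `sex`, `nutrition`, `vaccinated`,
#'   `malaria_dx`, `scd`, `weekday`, `wet_season`, `rural`,
#'   `mean_travel_min`, `pfpr`). Missing columns are skipped.
#' @param fisher_mode `"auto"` (exact up to `exact_max` total, else
#'   Monte-Carlo) or `"exact"`.
#' @param exact_max,B,seed passed to [fisher_exact()].
#' @return Data frame with one row per characteristic level: columns
#'   `block`, `level`, then `n`, `pct`, `ci_lo`, `ci_hi` for overall
#'   and each severity class, and the block p-value on its first row.
#' @export
summarize_table1 <- function(cohort, fisher_mode = c("auto", "exact"),
                             exact_max = 200, B = 1e5, seed = 1) {
  fisher_mode <- match.arg(fisher_mode)
  if (!"severity" %in% names(cohort)) stop("cohort lacks `severity`")
  if (any(is.na(cohort$severity))) stop("missing severity in cohort")
  sev <- factor(cohort$severity, levels = SEVERITY_LEVELS)

  cat_blocks <- list(
    tt_class = list(col = "tt_class", levels = TT_LEVELS),
    age_cat = list(col = "age_cat", levels = AGE_LEVELS),
    sex = list(col = "sex", levels = c("male", "female")),
    nutrition = list(col = "nutrition", levels = NUTRITION_LEVELS),
    vaccinated = list(col = "vaccinated", levels = c(FALSE, TRUE)),
    malaria_dx = list(col = "malaria_dx", levels = c(FALSE, TRUE)),
    scd = list(col = "scd", levels = c(FALSE, TRUE)),
    weekday = list(col = "weekday", levels = c(FALSE, TRUE)),
    wet_season = list(col = "wet_season", levels = c(FALSE, TRUE)),
    rural = list(col = "rural", levels = c(FALSE, TRUE))
  )
  num_blocks <- c(mean_travel_min = "mean_travel_min", pfpr = "pfpr")

  rows <- list()
  add_cat <- function(name, spec) {
    x <- factor(cohort[[spec$col]], levels = spec$levels)
    tab <- table(x, sev)
    mode_exact <- fisher_mode == "exact"
    p <- fisher_exact(tab, exact_max = if (mode_exact) Inf else exact_max,
                      B = B, seed = seed)$p_value
    for (i in seq_along(spec$levels)) {
      row <- data.frame(block = name, level = as.character(spec$levels[i]),
                        stringsAsFactors = FALSE)
      cnt <- sum(tab[i, ]); tot <- sum(tab)
      ci <- wilson_ci(cnt, tot)
      row$n_overall <- cnt; row$pct_overall <- 100 * cnt / tot
      row$ci_lo_overall <- 100 * ci[1]; row$ci_hi_overall <- 100 * ci[2]
      for (s in SEVERITY_LEVELS) {
        cnt_s <- tab[i, s]; tot_s <- sum(tab[, s])
        ci_s <- wilson_ci(cnt_s, tot_s)
        row[[paste0("n_", s)]] <- cnt_s
        row[[paste0("pct_", s)]] <- 100 * cnt_s / tot_s
        row[[paste0("ci_lo_", s)]] <- 100 * ci_s[1]
        row[[paste0("ci_hi_", s)]] <- 100 * ci_s[2]
      }
      row$p_value <- if (i == 1L) p else NA_real_
      rows[[length(rows) + 1L]] <<- row
    }
  }
  add_num <- function(name, col) {
    groups <- split(cohort[[col]], sev)
    groups <- lapply(groups, function(v) v[!is.na(v)])
    p <- kruskal_wallis(groups)$p_value
    row <- data.frame(block = name, level = "median (IQR)",
                      stringsAsFactors = FALSE)
    q <- stats::quantile(cohort[[col]], c(0.25, 0.5, 0.75), na.rm = TRUE)
    row$n_overall <- sum(!is.na(cohort[[col]]))
    row$pct_overall <- NA; row$ci_lo_overall <- q[1]; row$ci_hi_overall <- q[3]
    for (s in SEVERITY_LEVELS) {
      qs <- stats::quantile(groups[[s]], c(0.25, 0.5, 0.75))
      row[[paste0("n_", s)]] <- length(groups[[s]])
      row[[paste0("pct_", s)]] <- qs[2]
      row[[paste0("ci_lo_", s)]] <- qs[1]
      row[[paste0("ci_hi_", s)]] <- qs[3]
    }
    row$p_value <- p
    rows[[length(rows) + 1L]] <<- row
  }
  for (name in names(cat_blocks)) {
    if (cat_blocks[[name]]$col %in% names(cohort)) {
      add_cat(name, cat_blocks[[name]])
    }
  }
  for (name in names(num_blocks)) {
    if (num_blocks[[name]] %in% names(cohort)) add_num(name, num_blocks[[name]])
  }
  do.call(rbind, rows)
}

#' Admission rates by travel-time band and severity
#'
#' Admissions per 1,000 under-5 children over the surveillance window,
#' within 15-minute travel-time bands, split by severity. The
#' denominator of a band is the summed under-5 population of the EAs
#' whose mean travel time falls in the band. Used to visualise
#' distance decay in care-seeking.
#'
#' @param cohort analysis cohort with `ea_id` and `severity`.
#' @param eas an [ea_set()] (or EA data frame) with `mean_travel_min`
#'   and `pop_u5`.
#' @return Data frame: `band15`, `severity`, `n_admissions`, `pop_u5`,
#'   `rate_per_1000`.
#' @export
band_admission_rates <- function(cohort, eas) {
  tab <- ea_table(eas)
  if (!"mean_travel_min" %in% names(tab) || anyNA(tab$mean_travel_min))
    warning("EAs without travel time are dropped from band rates")
  tab <- tab[!is.na(tab$mean_travel_min), , drop = FALSE]
  tab$band15 <- bin_travel_time(tab$mean_travel_min, "15min")
  band_levels <- c("<15", paste(seq(15, 105, 15), seq(29, 119, 15), sep = "-"),
                   ">=120")
  pop <- tapply(tab$pop_u5, factor(tab$band15, band_levels), sum)
  pop[is.na(pop)] <- 0
  cohort <- cohort[cohort$ea_id %in% tab$ea_id, , drop = FALSE]
  band_of <- tab$band15[match(cohort$ea_id, tab$ea_id)]
  out <- expand.grid(band15 = band_levels, severity = SEVERITY_LEVELS,
                     stringsAsFactors = FALSE)
  cnt <- table(factor(band_of, band_levels),
               factor(cohort$severity, SEVERITY_LEVELS))
  out$n_admissions <- as.vector(cnt)
  out$pop_u5 <- as.vector(pop)[match(out$band15, band_levels)]
  out$rate_per_1000 <- NA_real_
  ok <- out$pop_u5 > 0
  out$rate_per_1000[ok] <- admission_rate(out$n_admissions[ok],
                                          out$pop_u5[ok])
  out
}

#' Plot distance-decay band rates
#'
#' Base-graphics bar panels of admission rates per 1,000 children by
#' 15-minute travel-time band, one panel per severity class.
#'
#' @param rates result of [band_admission_rates()].
#' @param file optional PNG path; `NULL` draws on the current device.
#' @export
plot_band_rates <- function(rates, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 420)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, 3), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (s in SEVERITY_LEVELS) {
    d <- rates[rates$severity == s, ]
    graphics::barplot(d$rate_per_1000, names.arg = d$band15, las = 2,
                      main = paste0(s, " anaemia"),
                      ylab = "admissions / 1,000 children")
  }
  invisible(rates)
}
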