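# Shared fixtures built in code.

# Printed severity-by-travel-class counts of the reference admission
# table (mild, moderate, severe by 30-min class).
table1_counts <- function() {
  data.frame(
    tt_class = c("<30", "30-59", "60-89", ">=90"),
    mild = c(826, 265, 37, 23),
    moderate = c(224, 138, 36, 4),
    severe = c(221, 302, 87, 24),
    stringsAsFactors = FALSE
  )
}

# Expand the counts into a per-admission cohort data frame.
table1_cohort <- function() {
  counts <- table1_counts()
  rows <- list()
  for (i in seq_len(nrow(counts))) for (s in c("mild", "moderate", "severe"))
    if (counts[[s]][i] > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        tt_class = counts$tt_class[i], severity = s,
        n = counts[[s]][i], stringsAsFactors = FALSE)
  long <- do.call(rbind, rows)
  data.frame(tt_class = rep(long$tt_class, long$n),
             severity = rep(long$severity, long$n),
             stringsAsFactors = FALSE)
}

# Minimal EA attribute frame with centroids on a square region,
# travel time roughly proportional to distance from the central
# hospital (so travel-time class is spatially structured, as in a
# one-referral-hospital county).
make_ea_frame <- function(m, seed = 1, extent = 40000,
                          speed_min_per_km = 4.5) {
  set.seed(seed)
  cx <- stats::runif(m, 0, extent)
  cy <- stats::runif(m, 0, extent)
  d_km <- sqrt((cx - extent / 2)^2 + (cy - extent / 2)^2) / 1000
  tt <- d_km * speed_min_per_km * stats::runif(m, 0.8, 1.3)
  data.frame(
    ea_id = sprintf("EA%04d", seq_len(m)),
    cx = cx, cy = cy,
    pop_u5 = pmax(1, round(stats::rlnorm(m, log(100), 0.5))),
    ntl = ifelse(d_km < 0.12 * extent / 1000, 10, 0),
    pfpr = round(stats::runif(m, 0.2, 0.55), 3),
    altitude_m = 1200,
    mean_travel_min = tt,
    tt_class = bin_travel_time(tt),
    stringsAsFactors = FALSE
  )
}

# Admissions table realising the printed exclusion-cascade step counts:
# 4,361 extracted; 665 cause-based; 264 missing Hb; 1,245 non-anaemic.
cascade_fixture <- function() {
  n <- 4361
  df <- data.frame(
    admission_id = seq_len(n),
    resident = TRUE,
    age_months = 24L,
    exclusion_cause = "none",
    hb_raw = 8,
    stringsAsFactors = FALSE
  )
  df$exclusion_cause[1:665] <- rep(c("bite", "burn", "malignancy",
                                     "poisoning", "surgery", "trauma"),
                                   length.out = 665)
  df$hb_raw[666:929] <- NA          # 264 missing Hb
  df$hb_raw[930:2174] <- 11         # 1,245 not anaemic
  df
}
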