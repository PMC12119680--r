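#' WHO altitude adjustment steps for haemoglobin
#'
#' The guideline step table: the amount (g/dl) subtracted from measured
#' haemoglobin for residence altitude, as a step function of altitude
#' with no interpolation.
#'
#' @return Data frame with columns `altitude_from` (metres, inclusive
#'   lower bound) and `decrement` (g/dl).
#' @export
who_altitude_steps <- function() {
  data.frame(
    altitude_from = c(0, 1000, 1500, 2000, 2500, 3000, 3500, 4000, 4500),
    decrement     = c(0, 0.2, 0.5, 0.8, 1.3, 1.9, 2.7, 3.5, 4.5)
  )
}

# Decrement (g/dl) for a vector of altitudes, per the step table.
who_altitude_increment <- function(altitude_m, steps = who_altitude_steps()) {
  idx <- findInterval(altitude_m, steps$altitude_from)
  steps$decrement[pmax(idx, 1L)]
}

#' Adjust haemoglobin for residence altitude
#'
#' Subtracts the WHO step-table decrement for the given altitude from
#' the measured haemoglobin. Altitudes below 1,000 m carry no
#' adjustment.
#'
#' @param hb_raw measured haemoglobin, g/dl (> 0).
#' @param altitude_m residence altitude in metres (>= 0).
#' @param steps adjustment table, see [who_altitude_steps()].
#' @return Adjusted haemoglobin, g/dl.
#' @export
adjust_hb_for_altitude <- function(hb_raw, altitude_m,
                                   steps = who_altitude_steps()) {
  if (any(is.na(hb_raw)) || any(hb_raw <= 0))
    stop("hb_raw must be positive and non-missing")
  if (any(is.na(altitude_m)) || any(altitude_m < 0))
    stop("altitude_m must be non-negative and non-missing")
  adj <- hb_raw - who_altitude_increment(altitude_m, steps)
  if (any(adj <= 0))
    stop("altitude adjustment drove haemoglobin to or below 0 g/dl; ",
         "implausible record")
  adj
}

#' Classify anaemia severity from adjusted haemoglobin
#'
#' Severe: Hb < 5; moderate: 5 <= Hb < 7; mild: 7 <= Hb < 10;
#' not anaemic: Hb >= 10 g/dl (excluded from analysis downstream).
#'
#' @param hb_adj altitude-adjusted haemoglobin, g/dl (> 0).
#' @return Character vector: `severe`, `moderate`, `mild`,
#'   `not_anaemic`.
#' @export
classify_anaemia <- function(hb_adj) {
  if (any(is.na(hb_adj)) || any(hb_adj <= 0))
    stop("hb_adj must be positive and non-missing")
  ifelse(hb_adj < 5, "severe",
  ifelse(hb_adj < 7, "moderate",
  ifelse(hb_adj < 10, "mild", "not_anaemic")))
}

#' Apply the inclusion/exclusion cascade
#'
#' Sequential cascade producing the analysis cohort and a flow ledger:
#' (1) restrict to residents aged 1-59 months (the "extracted" set);
#' (2) drop admissions with cause-based exclusions (bites, burns,
#' malignancy/congenital abnormality, poisoning, surgery,
#' trauma/accidents) — conditions unlikely to relate to place of
#' residence; (3) drop admissions with no haemoglobin result;
#' (4) drop non-anaemic admissions (adjusted Hb >= 10 g/dl). A record
#' qualifying for several steps is removed once, at the first matching
#' step. Haemoglobin is altitude-adjusted before classification using
#' the altitude supplied per record (scalar recycled).
#'
#' @param admissions data frame with columns `exclusion_cause`
#'   (`"none"` or a cause), `resident` (logical), `age_months`,
#'   `hb_raw` (NA when missing), plus any covariates carried through.
#' @param altitude_m per-record residence altitude in metres (scalar or
#'   vector); if the admissions table has an `altitude_m` column it is
#'   used when this argument is `NULL`.
#' @return List of class `cohort_result`: `cohort` (analysis rows with
#'   added `hb_adj` and `severity`) and `ledger` (a `flow_ledger`).
#' @export
apply_exclusions <- function(admissions, altitude_m = NULL) {
  need <- c("exclusion_cause", "resident", "age_months", "hb_raw")
  miss <- setdiff(need, names(admissions))
  if (length(miss)) stop("admissions lack column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(altitude_m)) {
    altitude_m <- if ("altitude_m" %in% names(admissions))
      admissions$altitude_m else 0
  }
  altitude_m <- rep_len(altitude_m, nrow(admissions))

  extracted_mask <- admissions$resident &
    !is.na(admissions$age_months) &
    admissions$age_months >= 1 & admissions$age_months <= 59
  d <- admissions[extracted_mask, , drop = FALSE]
  alt <- altitude_m[extracted_mask]
  n_extracted <- nrow(d)

  cause <- !is.na(d$exclusion_cause) & d$exclusion_cause != "none"
  n_cause <- sum(cause)
  d <- d[!cause, , drop = FALSE]; alt <- alt[!cause]

  no_hb <- is.na(d$hb_raw)
  n_no_hb <- sum(no_hb)
  d <- d[!no_hb, , drop = FALSE]; alt <- alt[!no_hb]

  d$hb_adj <- adjust_hb_for_altitude(d$hb_raw, alt)
  d$severity <- classify_anaemia(d$hb_adj)
  not_anaemic <- d$severity == "not_anaemic"
  n_not_anaemic <- sum(not_anaemic)
  d <- d[!not_anaemic, , drop = FALSE]

  ledger <- flow_ledger(extracted = n_extracted,
                        excluded_cause = n_cause,
                        excluded_no_hb = n_no_hb,
                        excluded_not_anaemic = n_not_anaemic,
                        analysed = nrow(d))
  structure(list(cohort = d, ledger = ledger), class = "cohort_result")
}

#' Exclusion-cascade flow ledger
#'
#' @param extracted,excluded_cause,excluded_no_hb,excluded_not_anaemic,analysed
#'   counts at each cascade step.
#' @return A list of class `flow_ledger`. Construction fails unless
#'   `analysed = extracted - excluded_cause - excluded_no_hb -
#'   excluded_not_anaemic` and all counts are non-negative.
#' @export
flow_ledger <- function(extracted, excluded_cause, excluded_no_hb,
                        excluded_not_anaemic, analysed) {
  counts <- c(extracted = extracted, excluded_cause = excluded_cause,
              excluded_no_hb = excluded_no_hb,
              excluded_not_anaemic = excluded_not_anaemic,
              analysed = analysed)
  if (any(counts < 0)) stop("flow ledger counts must be non-negative")
  if (analysed !=
      extracted - excluded_cause - excluded_no_hb - excluded_not_anaemic)
    stop("flow ledger does not balance")
  structure(as.list(counts), class = "flow_ledger")
}

#' @export
print.flow_ledger <- function(x, ...) {
  cat("Exclusion cascade:\n")
  cat(sprintf("  extracted (residents aged 1-59 m) %6d\n", x$extracted))
  cat(sprintf("  - cause-based exclusions          %6d\n", x$excluded_cause))
  cat(sprintf("  - missing haemoglobin             %6d\n", x$excluded_no_hb))
  cat(sprintf("  - not anaemic (Hb >= 10 g/dl)     %6d\n",
              x$excluded_not_anaemic))
  cat(sprintf("  analysed                          %6d\n", x$analysed))
  invisible(x)
}
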