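#' Travel-time class labels
#'
#' Half-open 30-minute classes used for the exposure of interest; the
#' reference class is `<30`.
#' @keywords internal
TT_LEVELS <- c("<30", "30-59", "60-89", ">=90")

AGE_LEVELS <- c("<1", "1", "2", "3", "4")
NUTRITION_LEVELS <- c("well", "mild", "moderate", "severe", "missing")

#' Default covariate marginal frequencies for the admission generator
#'
#' Marginal prevalences of the patient- and community-level covariates
#' used when simulating admission cohorts. Defaults reflect the
#' characteristics of paediatric anaemia admissions at a western-Kenya
#' county referral hospital: about 41% female, 94% fully vaccinated
#' (BCG + Penta 1 + Penta 3), 40% with a malaria discharge diagnosis,
#' 16% with sickle-cell disease, 78.5% admitted on weekdays and roughly
#' half during the wet season. Nutrition-status frequencies refer to
#' MUAC z-score classes among children with a recorded MUAC; a separate
#' missingness probability controls how often MUAC is absent.
#'
#' @return A named list of marginal probabilities; probability vectors
#'   are normalised to sum to one.
#' @export
covariate_marginals <- function() {
  list(
    age = c("<1" = 0.285, "1" = 0.299, "2" = 0.166, "3" = 0.128, "4" = 0.123),
    p_female = 0.412,
    nutrition = c(well = 0.416, mild = 0.351, moderate = 0.143, severe = 0.090),
    p_muac_missing = 0.084,
    p_vaccinated = 0.940,
    p_malaria = 0.400,
    p_scd = 0.160,
    p_weekday = 0.785,
    p_wet = 0.516
  )
}

#' Names of the model's candidate covariates
#'
#' @return Character vector of covariate block names as used by
#'   [univariate_screen()] and [fit_spatial_logit()].
#' @export
candidate_covariates <- function() {
  c("age_cat", "sex", "nutrition", "vaccinated", "malaria_dx",
    "scd", "weekday", "wet_season", "pfpr", "rural")
}

# Column names in a cohort data frame required to build the design matrix
# for a given covariate block.
covariate_column <- function(block) {
  switch(block,
    tt_class = "tt_class", age_cat = "age_cat", sex = "sex",
    nutrition = "nutrition", vaccinated = "vaccinated",
    malaria_dx = "malaria_dx", scd = "scd", weekday = "weekday",
    wet_season = "wet_season", pfpr = "pfpr", rural = "rural",
    stop("unknown covariate block: ", block)
  )
}

# Dummy-encode one covariate block. Categorical blocks drop the first
# (reference) level; logical blocks give a single 0/1 column; pfpr stays
# continuous (a fraction in [0, 1]).
encode_block <- function(cohort, block) {
  col <- covariate_column(block)
  if (!col %in% names(cohort)) stop("cohort lacks column `", col, "`")
  x <- cohort[[col]]
  if (block == "tt_class") {
    f <- factor(x, levels = TT_LEVELS)
    m <- outer(f, TT_LEVELS[-1], "==") * 1
    colnames(m) <- c("tt_30_59", "tt_60_89", "tt_90_plus")
    return(m)
  }
  if (block == "age_cat") {
    f <- factor(x, levels = AGE_LEVELS)
    m <- outer(f, AGE_LEVELS[-1], "==") * 1
    colnames(m) <- paste0("age_", c("1", "2", "3", "4"))
    return(m)
  }
  if (block == "nutrition") {
    f <- factor(x, levels = NUTRITION_LEVELS)
    m <- outer(f, NUTRITION_LEVELS[-1], "==") * 1
    colnames(m) <- paste0("nutrition_", NUTRITION_LEVELS[-1])
    return(m)
  }
  if (block == "sex") {
    m <- matrix((x == "female") * 1, ncol = 1)
    colnames(m) <- "female"
    return(m)
  }
  if (block == "pfpr") {
    m <- matrix(as.numeric(x), ncol = 1)
    colnames(m) <- "pfpr"
    return(m)
  }
  m <- matrix(as.numeric(as.logical(x)), ncol = 1)
  colnames(m) <- block
  m
}

#' Build the fixed-effects design matrix
#'
#' Dummy-encodes the travel-time exposure plus the requested covariate
#' blocks against their reference levels. All covariates are categorical
#' except malaria endemicity (`pfpr`), which enters as a continuous
#' fraction.
#'
#' @param cohort a cohort data frame (see [simulate_admissions()] for
#'   the column contract).
#' @param blocks character vector of covariate block names
#'   (subset of [candidate_covariates()]); the travel-time exposure is
#'   always included first.
#' @param intercept logical; prepend an intercept column.
#' @return Numeric matrix with one row per admission.
#' @export
build_design_matrix <- function(cohort, blocks = character(),
                                intercept = TRUE) {
  parts <- lapply(c("tt_class", setdiff(blocks, "tt_class")),
                  function(b) encode_block(cohort, b))
  X <- do.call(cbind, parts)
  if (any(is.na(X))) stop("design matrix contains missing values")
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

# Nutrition class from a MUAC z-score; NA maps to the explicit
# "missing" category so no admission is dropped for absent MUAC.
nutrition_class <- function(muac_z) {
  out <- rep("missing", length(muac_z))
  ok <- !is.na(muac_z)
  z <- muac_z[ok]
  out[ok] <- ifelse(z > -1, "well",
             ifelse(z > -2, "mild",
             ifelse(z > -3, "moderate", "severe")))
  out
}
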