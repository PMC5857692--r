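# Synthetic cohort generator. Emulates the fields of an HSE-style
# population dataset that the risk engines and adherence model consume:
# demographics, risk factors, deprivation, comorbidity, prior CVD events and
# current medication. Continuous risk factors are drawn through a Gaussian
# copula so marginals stay exactly as specified while age-SBP and age-BMI
# correlations are preserved.

#' Specification of a synthetic population
#'
#' Defines the marginal distributions, correlation structure and prevalences
#' for [generate_population()]. Defaults describe a middle-aged-to-elderly
#' English adult population enriched for cardiovascular risk, the pool from
#' which a high-risk trial-like cohort is selected by [apply_inclusion()].
#'
#' @param n number of individuals (>= 1).
#' @param seed integer seed; identical specs reproduce identical cohorts.
#' @param age_mean,age_sd,age_range mean, SD and truncation range of age (years).
#' @param sbp_mean,sbp_sd systolic blood pressure (mmHg).
#' @param chol_mean,chol_sd total/HDL cholesterol ratio.
#' @param bmi_mean,bmi_sd body-mass index (kg/m^2).
#' @param deprivation_sd SD of the Townsend-style deprivation score (mean 0).
#' @param cor_age_sbp,cor_age_bmi copula correlations.
#' @param p_male probability of male sex.
#' @param p_ethnicity named probabilities over
#'   `white`, `south_asian`, `black`, `other`.
#' @param p_smoking named probabilities over `non`, `ex`, `current`.
#' @param p_diabetes,p_family_history,p_treated_htn prevalences.
#' @param p_cvd prevalence of established CVD (a non-empty event history).
#' @param p_statin,p_aspirin,p_acei baseline medication prevalences.
#' @param aht_rate mean of the Poisson count of antihypertensive agents.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n = 1000L,
                            seed = 1L,
                            age_mean = 62, age_sd = 10, age_range = c(35, 90),
                            sbp_mean = 138, sbp_sd = 16,
                            chol_mean = 4.3, chol_sd = 1.0,
                            bmi_mean = 28, bmi_sd = 4.5,
                            deprivation_sd = 3,
                            cor_age_sbp = 0.35, cor_age_bmi = 0.12,
                            p_male = 0.52,
                            p_ethnicity = c(white = 0.85, south_asian = 0.07,
                                            black = 0.04, other = 0.04),
                            p_smoking = c(non = 0.50, ex = 0.30, current = 0.20),
                            p_diabetes = 0.12,
                            p_family_history = 0.15,
                            p_treated_htn = 0.35,
                            p_cvd = 0.25,
                            p_statin = 0.40, p_aspirin = 0.30, p_acei = 0.25,
                            aht_rate = 0.8) {
  spec <- list(
    n = as.integer(n), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    sbp_mean = sbp_mean, sbp_sd = sbp_sd,
    chol_mean = chol_mean, chol_sd = chol_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    deprivation_sd = deprivation_sd,
    cor_age_sbp = cor_age_sbp, cor_age_bmi = cor_age_bmi,
    p_male = p_male, p_ethnicity = p_ethnicity, p_smoking = p_smoking,
    p_diabetes = p_diabetes, p_family_history = p_family_history,
    p_treated_htn = p_treated_htn, p_cvd = p_cvd,
    p_statin = p_statin, p_aspirin = p_aspirin, p_acei = p_acei,
    aht_rate = aht_rate
  )
  v <- validator()
  v$check(spec$n >= 1L, "n: must be >= 1")
  for (f in c("p_male", "p_diabetes", "p_family_history", "p_treated_htn",
              "p_cvd", "p_statin", "p_aspirin", "p_acei")) {
    v$check(is_prob(spec[[f]]) && length(spec[[f]]) == 1L,
            sprintf("%s: must be a probability in [0, 1]", f))
  }
  v$check(is_prob(spec$p_ethnicity) && abs(sum(spec$p_ethnicity) - 1) < 1e-9,
          "p_ethnicity: probabilities must be in [0, 1] and sum to 1")
  v$check(is_prob(spec$p_smoking) && abs(sum(spec$p_smoking) - 1) < 1e-9,
          "p_smoking: probabilities must be in [0, 1] and sum to 1")
  for (f in c("age_sd", "sbp_sd", "chol_sd", "bmi_sd", "deprivation_sd")) {
    v$check(is_pos(spec[[f]]), sprintf("%s: must be > 0", f))
  }
  v$check(is_nonneg(spec$aht_rate), "aht_rate: must be >= 0")
  v$check(abs(spec$cor_age_sbp) < 1 && abs(spec$cor_age_bmi) < 1,
          "copula correlations must lie in (-1, 1)")
  v$fail_if_any("invalid population spec")
  structure(spec, class = "population_spec")
}

# Truncated-normal quantile via the probability-integral transform.
qtruncnorm <- function(u, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

CVD_EVENT_TYPES <- c("TIA", "stroke", "MI", "angina")

#' Generate a synthetic population
#'
#' Draws `spec$n` individuals with the joint structure defined by the spec:
#' continuous risk factors through a Gaussian copula (exact marginals,
#' specified age-SBP / age-BMI correlation), categorical fields from their
#' marginal prevalences, and for the `p_cvd` fraction a prior-event history
#' of one or two acute CVD events at times up to 10 years before entry.
#'
#' @param spec a [population_spec()].
#' @return A data frame with one row per individual, class
#'   `c("population", "data.frame")`; `cvd_history` is serialised as
#'   semicolon-separated `type:years_before_entry` tokens (empty string for
#'   no history).
#' @export
generate_population <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n
  with_seed(mix_seed(spec$seed, STREAM_POPULATION), {
    # Gaussian copula over (age, sbp, bmi, chol_ratio, deprivation)
    R <- diag(5)
    R[1, 2] <- R[2, 1] <- spec$cor_age_sbp
    R[1, 3] <- R[3, 1] <- spec$cor_age_bmi
    L <- chol(R)
    z <- matrix(rnorm(n * 5), n, 5) %*% L
    u <- pnorm(z)

    age <- qtruncnorm(u[, 1], spec$age_mean, spec$age_sd,
                      spec$age_range[1], spec$age_range[2])
    sbp <- qtruncnorm(u[, 2], spec$sbp_mean, spec$sbp_sd, 80, 240)
    bmi <- qtruncnorm(u[, 3], spec$bmi_mean, spec$bmi_sd, 15, 60)
    chol <- qtruncnorm(u[, 4], spec$chol_mean, spec$chol_sd, 1.5, 12)
    depr <- qnorm(u[, 5], 0, spec$deprivation_sd)

    sex <- ifelse(runif(n) < spec$p_male, "male", "female")
    ethnicity <- sample(names(spec$p_ethnicity), n, TRUE, spec$p_ethnicity)
    smoking <- sample(names(spec$p_smoking), n, TRUE, spec$p_smoking)
    diabetes <- runif(n) < spec$p_diabetes
    fam <- runif(n) < spec$p_family_history
    thtn <- runif(n) < spec$p_treated_htn
    has_cvd <- runif(n) < spec$p_cvd

    cvd_history <- character(n)
    idx <- which(has_cvd)
    if (length(idx)) {
      k <- 1L + rbinom(length(idx), 1L, 0.35) # one or two prior events
      cvd_history[idx] <- vapply(seq_along(idx), function(j) {
        types <- sample(CVD_EVENT_TYPES, k[j], TRUE, c(0.2, 0.3, 0.35, 0.15))
        times <- round(sort(runif(k[j], 0, 10), decreasing = TRUE), 2)
        paste(sprintf("%s:%.2f", types, times), collapse = ";")
      }, character(1))
    }

    statin <- runif(n) < spec$p_statin
    aspirin <- runif(n) < spec$p_aspirin
    acei <- runif(n) < spec$p_acei
    n_aht <- rpois(n, spec$aht_rate)

    pop <- data.frame(
      id = seq_len(n),
      age = age, sex = sex, ethnicity = ethnicity, smoking = smoking,
      sbp = sbp, chol_ratio = chol, bmi = bmi, deprivation = depr,
      diabetes = diabetes, family_history_chd = fam,
      treated_hypertension = thtn,
      cvd_history = cvd_history,
      statin = statin, n_antihypertensives = n_aht,
      acei = acei, aspirin = aspirin,
      stringsAsFactors = FALSE
    )
    class(pop) <- c("population", "data.frame")
    pop
  })
}

#' Filter a population to the trial-eligible high-risk subset
#'
#' Retains adults (age >= 18) who either have established CVD or whose
#' 5-year first-event CVD risk is at or above the threshold. When the
#' inclusion engine predicts over a different horizon its risk is rescaled
#' to 5 years under a constant-hazard assumption.
#'
#' @param pop a population data frame from [generate_population()] or
#'   [read_population()].
#' @param inclusion_engine a [risk_coefficients()] object used to score
#'   non-CVD individuals (default: the packaged primary CVD engine).
#' @param threshold 5-year risk threshold (default 0.15); inclusion is
#'   `risk >= threshold`.
#' @return The retained rows, original order preserved, with an
#'   `inclusion_risk5` column (NA for established-CVD entrants).
#' @export
apply_inclusion <- function(pop,
                            inclusion_engine = default_primary_engine(),
                            threshold = 0.15) {
  stopifnot(is.data.frame(pop), threshold >= 0)
  has_cvd <- nzchar(pop$cvd_history)
  risk5 <- rep(NA_real_, nrow(pop))
  idx <- which(!has_cvd)
  if (length(idx)) {
    p <- predict_risk(inclusion_engine, pop[idx, , drop = FALSE])
    risk5[idx] <- rescale_risk_horizon(p, inclusion_engine$horizon, 5)
  }
  keep <- pop$age >= 18 & (has_cvd | (!is.na(risk5) & risk5 >= threshold))
  out <- pop[keep, , drop = FALSE]
  out$inclusion_risk5 <- risk5[keep]
  class(out) <- c("population", "data.frame")
  out
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf(
    "Synthetic population: %d individuals (age %.0f-%.0f, %.0f%% male, %.0f%% established CVD)\n",
    nrow(x), min(x$age), max(x$age), 100 * mean(x$sex == "male"),
    100 * mean(nzchar(x$cvd_history))
  ))
  print(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Write a population to CSV
#'
#' One individual per row, one header row; `cvd_history` stays in its
#' semicolon-separated `type:time` serialisation.
#' @param pop population data frame.
#' @param path file path.
#' @export
write_population <- function(pop, path) {
  write.csv(as.data.frame(pop), path, row.names = FALSE)
  invisible(path)
}

#' Read a population CSV written by [write_population()]
#' @param path file path.
#' @export
read_population <- function(path) {
  pop <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "sex", "ethnicity", "smoking", "sbp", "chol_ratio",
            "bmi", "deprivation", "diabetes", "family_history_chd",
            "treated_hypertension", "cvd_history", "statin",
            "n_antihypertensives", "acei", "aspirin")
  missing <- setdiff(need, names(pop))
  if (length(missing)) {
    stop(sprintf("population CSV missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  pop$cvd_history[is.na(pop$cvd_history)] <- ""
  class(pop) <- c("population", "data.frame")
  pop
}

#' Parse a serialised CVD history
#'
#' @param history semicolon-separated `type:years_before_entry` string.
#' @return Data frame with columns `type` and `years_before_entry`.
#' @export
parse_cvd_history <- function(history) {
  if (length(history) != 1L) stop("one history string at a time", call. = FALSE)
  if (is.na(history) || !nzchar(history)) {
    return(data.frame(type = character(0), years_before_entry = numeric(0)))
  }
  tok <- strsplit(strsplit(history, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(
    type = vapply(tok, `[`, character(1), 1L),
    years_before_entry = as.numeric(vapply(tok, `[`, character(1), 2L)),
    stringsAsFactors = FALSE
  )
}
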