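# Shared fixtures, all built in code at test time.

# Treatment effects with every relative risk at 1 and no cough: the two
# arms then differ in nothing but the adherence draw (which the common
# random numbers make identical when the adherence RR is 1 too).
null_effects <- function(p_cough = 0) {
  treatment_effects(
    rr_cvd_statin = 1, rr_cvd_aht = 1, rr_cvd_aspirin = 1,
    rr_diabetes_tx = 1, rr_gi_bleed_aspirin = 1,
    p_cough_acei = p_cough, rr_hf_aht = 1
  )
}

# Parameter set under which the null scenario is exactly arm-identical.
null_params <- function() {
  default_parameters(
    treatment_effects = null_effects(),
    adherence_rr = adherence_rr(1)
  )
}

# A risk engine with no covariate terms: constant horizon risk 1 - s0.
flat_engine <- function(name, s0, horizon = 10) {
  risk_coefficients(name, horizon, s0,
                    data.frame(term = character(0), transform = character(0),
                               weight = numeric(0)))
}

# Life table with the same annual probability of death at every age.
flat_life_table <- function(q, max_age = 109) {
  age <- 0:max_age
  rbind(
    data.frame(age = age, sex = "male", qx = c(rep(q, max_age), 1)),
    data.frame(age = age, sex = "female", qx = c(rep(q, max_age), 1))
  )
}

# Parameters in which only other-cause mortality can fire: zero-risk
# engines, zero heart-failure/GI hazards, no cessation, no cough.
mortality_only_params <- function(life_table = default_life_table()) {
  default_parameters(
    primary_engine = flat_engine("primary_cvd", 1),
    secondary_engine = flat_engine("secondary_cvd", 1),
    diabetes_engine = flat_engine("diabetes", 1),
    hf_table = data.frame(age = c(0, 110), rate = c(0, 0)),
    treatment_effects = null_effects(),
    adherence_model = adherence_model(0.62, cessation_hazard = 0),
    adherence_rr = adherence_rr(1),
    life_table = life_table,
    baseline_gi_hazard = 0
  )
}

# One fully specified individual for single-trajectory tests.
test_individual <- function(age = 60, sex = "male", cvd_history = "",
                            diabetes = FALSE, id = 1L) {
  list(
    id = id, age = age, sex = sex, ethnicity = "white", smoking = "non",
    sbp = 138, chol_ratio = 4.3, bmi = 28, deprivation = 0,
    diabetes = diabetes, family_history_chd = FALSE,
    treated_hypertension = FALSE, cvd_history = cvd_history,
    statin = FALSE, n_antihypertensives = 0L, acei = FALSE, aspirin = FALSE
  )
}

as_pop <- function(inds) {
  pop <- do.call(rbind, lapply(inds, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
  class(pop) <- c("population", "data.frame")
  pop
}

# Minimal hand-built trajectory for economics tests.
stub_trajectory <- function(events = data.frame(time = numeric(0),
                                                type = character(0),
                                                fatal = logical(0),
                                                age = numeric(0)),
                            exposure = data.frame(start = numeric(0),
                                                  end = numeric(0),
                                                  on_treatment = logical(0),
                                                  adherent = logical(0)),
                            exit = "death", exit_time = 10,
                            entry_age = 60, sex = "male", arm = "usual") {
  structure(list(id = 1L, arm = arm, entry_age = entry_age, sex = sex,
                 events = events, exposure = exposure, exit = exit,
                 exit_time = exit_time, first_period_adherent = NA),
            class = "trajectory")
}

# Utility table with unit baseline utility and no decrements.
unit_utilities <- function() {
  utility_table(
    baseline = data.frame(age = 0, male = 1, female = 1),
    decrements = c(stroke = 0, TIA = 0, MI = 0, angina = 0, diabetes = 0,
                   heart_failure = 0),
    transient = list(gi_bleed = c(decrement = 0, duration = 0),
                     cough_onset = c(decrement = 0, duration = 0))
  )
}
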