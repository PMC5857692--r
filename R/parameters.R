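# The full model parameter schema: risk engines, heart-failure incidence,
# relative incidence of CVD types, treatment effects, adherence model and
# relative risk, case fatality, life table, costs, utilities, and the
# structural constants (discount rate, age cap, risk-update interval,
# inclusion threshold).

#' Construct a complete model parameter set
#'
#' All arguments default to the packaged illustrative inputs; any component
#' can be replaced (e.g. a published coefficient table via
#' [read_risk_coefficients()], a national life table via [read_life_table()]).
#'
#' @param primary_engine,secondary_engine,diabetes_engine
#'   [risk_coefficients()] objects.
#' @param hf_table heart-failure baseline incidence, data frame
#'   `age`, `rate`.
#' @param rel_incidence named probabilities over `TIA`, `stroke`, `MI`,
#'   `angina` summing to 1.
#' @param treatment_effects a [treatment_effects()] object.
#' @param adherence_model an [adherence_model()].
#' @param adherence_rr an [adherence_rr()].
#' @param case_fatality a [case_fatality()].
#' @param life_table data frame `age`, `sex`, `qx`.
#' @param costs a [cost_table()].
#' @param utilities a [utility_table()].
#' @param baseline_gi_hazard per-year untreated GI-bleed hazard (>= 0).
#' @param discount_rate annual discount rate (default 0.035).
#' @param age_cap maximum simulated age (default 100).
#' @param update_interval years between scheduled risk updates (default 10,
#'   the engines' prediction horizon).
#' @param inclusion_threshold 5-year risk threshold for trial eligibility
#'   (default 0.15).
#' @return Object of class `parameter_set`.
#' @export
default_parameters <- function(primary_engine = default_primary_engine(),
                               secondary_engine = default_secondary_engine(),
                               diabetes_engine = default_diabetes_engine(),
                               hf_table = default_hf_table(),
                               rel_incidence = default_rel_incidence(),
                               treatment_effects = polypillCEA::treatment_effects(),
                               adherence_model = default_adherence_model(),
                               adherence_rr = default_adherence_rr(),
                               case_fatality = polypillCEA::case_fatality(),
                               life_table = default_life_table(),
                               costs = cost_table(),
                               utilities = utility_table(),
                               baseline_gi_hazard = 0.001,
                               discount_rate = 0.035,
                               age_cap = 100,
                               update_interval = 10,
                               inclusion_threshold = 0.15) {
  params <- structure(list(
    primary_engine = primary_engine,
    secondary_engine = secondary_engine,
    diabetes_engine = diabetes_engine,
    hf_table = hf_table,
    rel_incidence = rel_incidence,
    treatment_effects = treatment_effects,
    adherence_model = adherence_model,
    adherence_rr = adherence_rr,
    case_fatality = case_fatality,
    life_table = life_table,
    costs = costs,
    utilities = utilities,
    baseline_gi_hazard = baseline_gi_hazard,
    discount_rate = discount_rate,
    age_cap = age_cap,
    update_interval = update_interval,
    inclusion_threshold = inclusion_threshold,
    regimen = regimen_classes()
  ), class = "parameter_set")
  validate_parameters(params)
  params
}

#' Validate a parameter set
#'
#' Checks every component's types and ranges and that all required tables
#' are present, reporting every violation (not just the first) with the
#' offending field's path.
#'
#' @param params a `parameter_set`.
#' @return Invisibly `TRUE`; throws an aggregated error otherwise.
#' @export
validate_parameters <- function(params) {
  v <- validator()
  for (f in c("primary_engine", "secondary_engine", "diabetes_engine")) {
    v$check(inherits(params[[f]], "risk_coefficients"),
            sprintf("%s: must be a risk_coefficients object", f))
  }
  v$check(is.data.frame(params$hf_table) &&
            all(c("age", "rate") %in% names(params$hf_table)) &&
            is_nonneg(params$hf_table$rate),
          "hf_table: needs columns age, rate with rate >= 0")
  ri <- params$rel_incidence
  v$check(is.numeric(ri) && all(CVD_EVENT_TYPES %in% names(ri)) &&
            all(ri >= 0) && abs(sum(ri[CVD_EVENT_TYPES]) - 1) < 1e-9,
          "rel_incidence: named probabilities over TIA/stroke/MI/angina summing to 1")
  v$check(inherits(params$treatment_effects, "treatment_effects"),
          "treatment_effects: wrong class")
  v$check(inherits(params$adherence_model, "adherence_model"),
          "adherence_model: wrong class")
  v$check(inherits(params$adherence_rr, "adherence_rr"),
          "adherence_rr: wrong class")
  v$check(inherits(params$case_fatality, "case_fatality"),
          "case_fatality: wrong class")
  v$check(is.data.frame(params$life_table) &&
            all(c("age", "sex", "qx") %in% names(params$life_table)),
          "life_table: needs columns age, sex, qx")
  if (is.data.frame(params$life_table) && "qx" %in% names(params$life_table)) {
    v$check(is_prob(params$life_table$qx), "life_table$qx: probabilities in [0, 1]")
    v$check(max(params$life_table$age) >= 100, "life_table: must cover ages up to 100")
  }
  v$check(inherits(params$costs, "cost_table"), "costs: wrong class")
  v$check(inherits(params$utilities, "utility_table"), "utilities: wrong class")
  v$check(is_nonneg(params$baseline_gi_hazard), "baseline_gi_hazard: must be >= 0")
  v$check(is_nonneg(params$discount_rate), "discount_rate: must be >= 0")
  v$check(is_pos(params$age_cap), "age_cap: must be > 0")
  v$check(is_pos(params$update_interval), "update_interval: must be > 0")
  v$check(is_prob(params$inclusion_threshold), "inclusion_threshold: must be in [0, 1]")
  v$fail_if_any("invalid parameter set")
  invisible(TRUE)
}

# Attach precomputed structures (per-sex life-table hazards) once per run.
prepare_parameters <- function(params) {
  if (!is.null(params$.life_table)) {
    return(params)
  }
  validate_parameters(params)
  params$.life_table <- prepare_life_table(params$life_table)
  params
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Model parameter set\n")
  cat(sprintf("  engines: %s / %s / %s (horizons %g / %g / %g y)\n",
              x$primary_engine$engine_name, x$secondary_engine$engine_name,
              x$diabetes_engine$engine_name, x$primary_engine$horizon,
              x$secondary_engine$horizon, x$diabetes_engine$horizon))
  cat(sprintf("  discount rate %.3f/yr, age cap %g, risk update every %g y, inclusion threshold %.2f (5-y risk)\n",
              x$discount_rate, x$age_cap, x$update_interval,
              x$inclusion_threshold))
  cat(sprintf("  adherence RR %.3f; cessation hazard %.3f/yr\n",
              x$adherence_rr$rr, x$adherence_model$cessation_hazard))
  invisible(x)
}

#' Construct a scenario configuration
#'
#' @param arm `"usual"` or `"polypill"`.
#' @param polypill_version composition metadata only: version 1 combines
#'   aspirin 75 mg, simvastatin 40 mg, lisinopril 10 mg and atenolol 50 mg;
#'   version 2 substitutes hydrochlorothiazide 12.5 mg for atenolol.
#' @param master_seed integer master seed fixed before any sampling.
#' @param n number of individuals to simulate (used by [run_cea()] when it
#'   generates its own population).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(arm = c("usual", "polypill"),
                            polypill_version = c("v1", "v2"),
                            master_seed = 1L,
                            n = 1000L) {
  arm <- match.arg(arm)
  polypill_version <- match.arg(polypill_version)
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  structure(list(arm = arm, polypill_version = polypill_version,
                 master_seed = as.integer(master_seed), n = as.integer(n)),
            class = "scenario_config")
}

#' Write a life table to CSV (`age`, `sex`, `qx` layout)
#' @param life_table data frame.
#' @param path file path.
#' @export
write_life_table <- function(life_table, path) {
  write.csv(life_table, path, row.names = FALSE)
  invisible(path)
}

#' Read a life table CSV (`age`, `sex`, `qx` layout)
#' @param path file path.
#' @export
read_life_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "sex", "qx") %in% names(d))) {
    stop("life table CSV needs columns age, sex, qx", call. = FALSE)
  }
  prepare_life_table(d) # validates coverage and ranges
  d
}
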