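# Proportional-hazards risk engines in the QRISK2 functional form:
#   P(event by horizon) = 1 - S0 ^ exp(lp),
# where S0 is the baseline survival at the horizon for a zero linear
# predictor and lp is a weighted sum of (possibly transformed) covariates.
# Coefficient tables are data-driven: each term is an R expression in the
# individual's fields, so age transforms and interactions live in the table,
# not in code. The packaged coefficient sets are illustrative defaults in
# this functional form; published coefficient sets are a drop-in.

#' Construct a risk-engine coefficient set
#'
#' @param engine_name identifier, e.g. `"primary_cvd"`.
#' @param horizon prediction horizon in years (> 0).
#' @param baseline_survival survival at `horizon` for a zero linear
#'   predictor, in (0, 1].
#' @param terms data frame with columns `term` (label), `transform` (an R
#'   expression in covariate names, evaluated in the individual's fields) and
#'   `weight` (numeric log-hazard-ratio scale weight).
#' @return An object of class `risk_coefficients`.
#' @examples
#' rc <- risk_coefficients("toy", 10, 0.95,
#'   data.frame(term = "age", transform = "(age - 50)/10", weight = 0.5))
#' @export
risk_coefficients <- function(engine_name, horizon, baseline_survival, terms) {
  v <- validator()
  v$check(is.character(engine_name) && length(engine_name) == 1L, "engine_name: single string")
  v$check(is.numeric(horizon) && length(horizon) == 1L && horizon > 0,
          sprintf("%s: horizon must be > 0", engine_name))
  v$check(is.numeric(baseline_survival) && length(baseline_survival) == 1L &&
            baseline_survival > 0 && baseline_survival <= 1,
          sprintf("%s: baseline_survival must be in (0, 1]", engine_name))
  v$check(is.data.frame(terms) && all(c("term", "transform", "weight") %in% names(terms)),
          sprintf("%s: terms needs columns term, transform, weight", engine_name))
  v$fail_if_any("invalid risk coefficients")
  if (nrow(terms) && !is.numeric(terms$weight)) {
    stop(sprintf("%s: term weights must be numeric", engine_name), call. = FALSE)
  }

  # Compile the linear predictor once: lp(x) = sum_j w_j * transform_j(x).
  lp_expr <- if (nrow(terms) == 0L) {
    quote(0)
  } else {
    pieces <- sprintf("(%.17g) * (%s)", terms$weight, terms$transform)
    str2lang(paste(pieces, collapse = " + "))
  }
  covars <- if (nrow(terms)) unique(unlist(lapply(
    terms$transform, function(tr) all.vars(str2lang(tr))
  ))) else character(0)

  structure(
    list(
      engine_name = engine_name,
      horizon = horizon,
      baseline_survival = baseline_survival,
      terms = terms,
      lp_expr = lp_expr,
      covariates = covars
    ),
    class = "risk_coefficients"
  )
}

#' @export
print.risk_coefficients <- function(x, ...) {
  cat(sprintf(
    "Risk engine '%s': %g-year horizon, baseline survival %.4f, %d term(s)\n",
    x$engine_name, x$horizon, x$baseline_survival, nrow(x$terms)
  ))
  if (nrow(x$terms)) print(x$terms[, c("term", "transform", "weight")], row.names = FALSE)
  invisible(x)
}

# Evaluate the linear predictor for a named list or data frame of covariates.
# Vectorised over data-frame rows. Missing covariates are a data error.
linear_predictor <- function(coeffs, data) {
  missing <- setdiff(coeffs$covariates, names(data))
  if (length(missing)) {
    id <- if (!is.null(data$id)) paste0(" (id ", paste(unique(data$id), collapse = ","), ")") else ""
    stop(sprintf(
      "risk engine '%s': missing covariate(s) %s%s",
      coeffs$engine_name, paste(missing, collapse = ", "), id
    ), call. = FALSE)
  }
  lp <- eval(coeffs$lp_expr, envir = data, enclos = baseenv())
  n <- if (is.data.frame(data)) nrow(data) else 1L
  if (length(lp) == 1L && n > 1L) lp <- rep(lp, n)
  lp
}

# Core of every engine; exported wrappers add preconditions.
predict_risk <- function(coeffs, data) {
  lp <- linear_predictor(coeffs, data)
  p <- 1 - coeffs$baseline_survival^exp(lp)
  pmin(pmax(p, 0), 1)
}

risk_estimate <- function(probability, horizon) {
  stopifnot(all(probability >= 0), all(probability <= 1), horizon > 0)
  structure(list(probability = probability, horizon = horizon),
            class = "risk_estimate")
}

has_established_cvd <- function(ind) {
  h <- ind$cvd_history
  if (is.null(h)) return(FALSE)
  if (is.list(h)) h <- h[[1]]
  length(h) > 0 && any(nzchar(h))
}

#' Ten-year primary cardiovascular risk
#'
#' First-event CVD risk (TIA, stroke, MI or angina) for an individual with no
#' established cardiovascular disease, in the QRISK2 functional form
#' `1 - S0^exp(lp)`.
#'
#' @param ind an individual: one-row data frame or named list with the
#'   covariates the engine requires.
#' @param coeffs a [risk_coefficients()] object (default: packaged primary
#'   engine, 10-year horizon).
#' @return A `risk_estimate`: list with `probability` and `horizon`.
#' @export
primary_cvd_risk <- function(ind, coeffs = default_primary_engine()) {
  if (has_established_cvd(ind)) {
    stop("primary_cvd_risk: individual has established CVD; use secondary_cvd_risk",
         call. = FALSE)
  }
  risk_estimate(predict_risk(coeffs, ind), coeffs$horizon)
}

#' Ten-year risk of incident type 2 diabetes
#'
#' QDiabetes-style risk of acquiring type 2 diabetes, for a currently
#' non-diabetic individual.
#'
#' @inheritParams primary_cvd_risk
#' @export
diabetes_risk <- function(ind, coeffs = default_diabetes_engine()) {
  d <- ind$diabetes
  if (is.null(d)) stop("diabetes_risk: missing 'diabetes' field", call. = FALSE)
  if (any(as.logical(d))) {
    stop("diabetes_risk: individual already diabetic", call. = FALSE)
  }
  risk_estimate(predict_risk(coeffs, ind), coeffs$horizon)
}

#' Recurrent cardiovascular risk for established disease
#'
#' REACH-style composite risk of a next cardiovascular event (cardiovascular
#' death, non-fatal MI, non-fatal stroke or cardiovascular hospitalisation)
#' for an individual with established CVD. The composite is mapped onto the
#' four modelled acute event types by the relative-incidence split.
#'
#' @inheritParams primary_cvd_risk
#' @export
secondary_cvd_risk <- function(ind, coeffs = default_secondary_engine()) {
  if (!has_established_cvd(ind)) {
    stop("secondary_cvd_risk: individual has no established CVD; use primary_cvd_risk",
         call. = FALSE)
  }
  if (!"n_prior_events" %in% names(ind)) {
    ind <- c(as.list(ind), list(n_prior_events = n_cvd_events(ind$cvd_history)))
  }
  risk_estimate(predict_risk(coeffs, ind), coeffs$horizon)
}

n_cvd_events <- function(history) {
  if (is.list(history)) history <- history[[1]]
  if (length(history) == 0 || !nzchar(history[1])) return(0L)
  length(strsplit(history[1], ";", fixed = TRUE)[[1]])
}

#' Convert a horizon risk to a constant yearly hazard
#'
#' Under a constant hazard, a cumulative probability `p` over `h` years
#' corresponds to rate `-log(1 - p) / h`. This is the bridge between the risk
#' engines (which return horizon probabilities) and the event simulation
#' (which runs on rates between risk-recalculation points).
#'
#' @param est a `risk_estimate`, or a probability (then `horizon` must be given).
#' @param horizon horizon in years when `est` is a bare probability.
#' @return Hazard rate per year.
#' @export
risk_to_hazard <- function(est, horizon = NULL) {
  if (inherits(est, "risk_estimate")) {
    p <- est$probability
    horizon <- est$horizon
  } else {
    p <- est
    if (is.null(horizon)) stop("risk_to_hazard: horizon required", call. = FALSE)
  }
  stopifnot(all(p >= 0))
  if (any(p >= 1)) {
    stop("risk_to_hazard: probability 1 implies an infinite hazard", call. = FALSE)
  }
  -log1p(-p) / horizon
}

#' Inverse of [risk_to_hazard()]
#' @param hazard per-year rate (>= 0).
#' @param horizon years.
#' @return Cumulative event probability over the horizon.
#' @export
hazard_to_risk <- function(hazard, horizon) {
  stopifnot(all(hazard >= 0), horizon > 0)
  -expm1(-hazard * horizon)
}

#' Sample a time to event from a constant hazard
#'
#' Exponential draw with the given rate; a zero hazard returns `Inf` (the
#' event never fires). Draws come from the current R random-number stream so
#' that substream seeding controls reproducibility.
#'
#' @param hazard per-year rate (>= 0).
#' @param n number of draws.
#' @return Times in years.
#' @export
sample_time_to_event <- function(hazard, n = 1L) {
  if (any(hazard < 0)) stop("sample_time_to_event: negative hazard", call. = FALSE)
  if (length(hazard) == 1L && hazard == 0) {
    return(rep(Inf, n))
  }
  if (length(hazard) == 1L) {
    return(rexp(n, rate = hazard))
  }
  out <- rep(Inf, length(hazard))
  pos <- hazard > 0
  # rexp consumes one uniform per draw either way; keep stream use stable
  out[pos] <- rexp(sum(pos), rate = hazard[pos])
  out
}

#' Convert a risk to a shorter horizon under a constant hazard
#'
#' Used to derive the 5-year inclusion risk from a 10-year engine:
#' `S(h2) = S(h1)^(h2/h1)` for a constant hazard.
#'
#' @param p cumulative probability over `from` years.
#' @param from,to horizons in years.
#' @export
rescale_risk_horizon <- function(p, from, to) {
  stopifnot(all(p >= 0), all(p <= 1), from > 0, to > 0)
  -expm1(log1p(-p) * to / from)
}

# ---- packaged illustrative coefficient sets -------------------------------

#' Packaged primary CVD engine (illustrative coefficients)
#'
#' QRISK2-style 10-year first-CVD-event engine. Weights are illustrative
#' values in the published functional form, centred on a 50-year-old white
#' non-smoking reference profile; a published coefficient table can be loaded
#' with [read_risk_coefficients()] instead.
#' @export
default_primary_engine <- function() {
  risk_coefficients(
    engine_name = "primary_cvd",
    horizon = 10,
    baseline_survival = 0.962,
    terms = data.frame(
      term = c("age", "male", "sbp", "chol_ratio", "bmi", "smoker_current",
               "smoker_ex", "diabetes", "family_history", "deprivation",
               "treated_htn", "south_asian"),
      transform = c(
        "(age - 50)/10", "sex == 'male'", "(sbp - 130)/20",
        "(chol_ratio - 4)/1.5", "(bmi - 27)/5", "smoking == 'current'",
        "smoking == 'ex'", "diabetes", "family_history_chd",
        "deprivation/3", "treated_hypertension", "ethnicity == 'south_asian'"
      ),
      weight = c(0.52, 0.32, 0.18, 0.16, 0.08, 0.56, 0.19, 0.58, 0.28,
                 0.10, 0.14, 0.27),
      stringsAsFactors = FALSE
    )
  )
}

#' Packaged incident-diabetes engine (illustrative coefficients)
#' @export
default_diabetes_engine <- function() {
  risk_coefficients(
    engine_name = "diabetes",
    horizon = 10,
    baseline_survival = 0.945,
    terms = data.frame(
      term = c("age", "bmi", "male", "sbp", "deprivation", "south_asian",
               "smoker_current"),
      transform = c("(age - 50)/10", "(bmi - 27)/5", "sex == 'male'",
                    "(sbp - 130)/20", "deprivation/3",
                    "ethnicity == 'south_asian'", "smoking == 'current'"),
      weight = c(0.32, 0.66, 0.12, 0.06, 0.10, 0.52, 0.14),
      stringsAsFactors = FALSE
    )
  )
}

#' Packaged secondary (recurrent) CVD engine (illustrative coefficients)
#'
#' REACH-style next-event engine for established CVD. The `n_prior_events`
#' covariate is the number of prior acute CVD events; it is maintained by the
#' simulation as history accrues.
#' @export
default_secondary_engine <- function() {
  risk_coefficients(
    engine_name = "secondary_cvd",
    horizon = 10,
    baseline_survival = 0.80,
    terms = data.frame(
      term = c("age", "male", "diabetes", "prior_events", "smoker_current"),
      transform = c("(age - 65)/10", "sex == 'male'", "diabetes",
                    "pmax(n_prior_events - 1, 0)", "smoking == 'current'"),
      weight = c(0.36, 0.18, 0.40, 0.24, 0.30),
      stringsAsFactors = FALSE
    )
  )
}

# ---- coefficient-table CSV interface --------------------------------------

#' Write a coefficient set to CSV
#'
#' Layout: columns `engine`, `term`, `transform`, `weight`, with one metadata
#' row (`term == ".meta"`) carrying the horizon (in `transform`) and baseline
#' survival (in `weight`).
#' @param coeffs a `risk_coefficients` object.
#' @param path file path.
#' @export
write_risk_coefficients <- function(coeffs, path) {
  meta <- data.frame(
    engine = coeffs$engine_name, term = ".meta",
    transform = as.character(coeffs$horizon),
    weight = coeffs$baseline_survival, stringsAsFactors = FALSE
  )
  body <- data.frame(
    engine = coeffs$engine_name, term = coeffs$terms$term,
    transform = coeffs$terms$transform, weight = coeffs$terms$weight,
    stringsAsFactors = FALSE
  )
  write.csv(rbind(meta, body), path, row.names = FALSE)
  invisible(path)
}

#' Read a coefficient set from CSV (see [write_risk_coefficients()])
#' @param path file path.
#' @export
read_risk_coefficients <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("engine", "term", "transform", "weight")
  if (!all(need %in% names(d))) {
    stop("coefficient CSV needs columns engine, term, transform, weight", call. = FALSE)
  }
  meta <- d[d$term == ".meta", , drop = FALSE]
  if (nrow(meta) != 1L) stop("coefficient CSV needs exactly one '.meta' row", call. = FALSE)
  body <- d[d$term != ".meta", , drop = FALSE]
  risk_coefficients(
    engine_name = meta$engine[1],
    horizon = as.numeric(meta$transform[1]),
    baseline_survival = as.numeric(meta$weight[1]),
    terms = data.frame(term = body$term, transform = body$transform,
                       weight = body$weight, stringsAsFactors = FALSE)
  )
}
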