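# Adherence under usual care and its modification by the polypill.
# Usual-care adherence is a logistic regression on individual
# characteristics (emulating a survey-derived fit); the polypill multiplies
# the usual-care probability by a relative risk estimated from a two-arm
# trial-like dataset with a log-link binomial regression, capped at 1.

#' Trial adherence endpoint: adherent to the full regimen?
#'
#' An individual is adherent when, in the preceding week, they used a statin
#' on at least 4 days, an antiplatelet on at least 4 days, and at least two
#' distinct antihypertensive agents each on at least 4 days.
#'
#' @param statin_days days of statin use in the last 7 (0-7).
#' @param antiplatelet_days days of antiplatelet use in the last 7 (0-7).
#' @param aht_days integer vector, days of use per antihypertensive agent.
#' @param min_days threshold in days (default 4).
#' @return `TRUE` or `FALSE`.
#' @export
classify_adherent <- function(statin_days, antiplatelet_days, aht_days,
                              min_days = 4L) {
  counts <- c(statin_days, antiplatelet_days, aht_days)
  if (!is.numeric(counts) || any(is.na(counts)) || any(counts < 0) || any(counts > 7)) {
    stop("classify_adherent: day counts must be in 0..7", call. = FALSE)
  }
  statin_days >= min_days &&
    antiplatelet_days >= min_days &&
    sum(aht_days >= min_days) >= 2L
}

#' Construct an adherence model
#'
#' A logistic model for the probability of being adherent under usual care,
#' plus a constant yearly hazard of permanently ceasing medication.
#'
#' @param intercept logit-scale intercept.
#' @param terms data frame with columns `term`, `transform` (expression in
#'   individual fields) and `weight`, as in [risk_coefficients()]; may have
#'   zero rows for an intercept-only model.
#' @param cessation_hazard per-year rate of stopping medication (>= 0).
#' @param vcov optional coefficient covariance matrix (kept by
#'   [fit_adherence_model()]).
#' @return Object of class `adherence_model`.
#' @export
adherence_model <- function(intercept,
                            terms = data.frame(term = character(0),
                                               transform = character(0),
                                               weight = numeric(0)),
                            cessation_hazard = 0.05,
                            vcov = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  if (!is_nonneg(cessation_hazard)) {
    stop("adherence_model: cessation_hazard must be >= 0", call. = FALSE)
  }
  lp_expr <- if (nrow(terms) == 0L) {
    quote(0)
  } else {
    str2lang(paste(sprintf("(%.17g) * (%s)", terms$weight, terms$transform),
                   collapse = " + "))
  }
  structure(
    list(intercept = intercept, terms = terms, link = "logit",
         cessation_hazard = cessation_hazard, lp_expr = lp_expr, vcov = vcov),
    class = "adherence_model"
  )
}

#' Packaged illustrative usual-care adherence model
#'
#' Adherence around 65% at the reference profile, rising with age and
#' falling with deprivation; cessation hazard 0.05 per year.
#' @export
default_adherence_model <- function() {
  adherence_model(
    intercept = 0.62,
    terms = data.frame(
      term = c("age", "female", "deprivation"),
      transform = c("(age - 60)/10", "sex == 'female'", "deprivation/3"),
      weight = c(0.25, -0.10, -0.15),
      stringsAsFactors = FALSE
    ),
    cessation_hazard = 0.05
  )
}

#' @export
print.adherence_model <- function(x, ...) {
  cat(sprintf(
    "Adherence model (logit link): intercept %.4f, %d covariate term(s), cessation hazard %.3f/yr\n",
    x$intercept, nrow(x$terms), x$cessation_hazard
  ))
  if (nrow(x$terms)) print(x$terms[, c("term", "transform", "weight")], row.names = FALSE)
  invisible(x)
}

adherence_lp <- function(model, ind) {
  model$intercept + eval(model$lp_expr, envir = ind, enclos = baseenv())
}

#' Polypill-versus-usual-care adherence relative risk
#'
#' @param rr relative risk (> 0).
#' @param ci_low,ci_high confidence bounds, `ci_low <= rr <= ci_high`.
#' @param se_log optional standard error of log(rr).
#' @return Object of class `adherence_rr`.
#' @export
adherence_rr <- function(rr, ci_low = rr, ci_high = rr, se_log = NA_real_) {
  if (!is_pos(c(rr, ci_low, ci_high))) {
    stop("adherence_rr: rr and CI bounds must be > 0", call. = FALSE)
  }
  if (!(ci_low <= rr && rr <= ci_high)) {
    stop("adherence_rr: require ci_low <= rr <= ci_high", call. = FALSE)
  }
  structure(list(rr = rr, ci_low = ci_low, ci_high = ci_high, se_log = se_log),
            class = "adherence_rr")
}

#' @export
print.adherence_rr <- function(x, ...) {
  cat(sprintf("Adherence RR (polypill vs usual care): %.3f (95%% CI %.3f-%.3f)\n",
              x$rr, x$ci_low, x$ci_high))
  invisible(x)
}

#' Fit the usual-care adherence model from observed records
#'
#' Maximum-likelihood logistic regression of an observed adherence indicator
#' on individual characteristics (via [stats::glm()]).
#'
#' @param records data frame containing `adherent` (0/1 or logical) and the
#'   covariates named in `formula`.
#' @param formula model formula; default
#'   `adherent ~ I((age - 60)/10) + I(sex == "female") + I(deprivation/3)`
#'   mirrors the packaged model's terms.
#' @param cessation_hazard carried into the returned model (not estimated
#'   from the cross-sectional records).
#' @return An `adherence_model` with fitted weights, plus `fit` details
#'   (coefficients, standard errors, covariance).
#' @export
fit_adherence_model <- function(records,
                                formula = adherent ~ I((age - 60)/10) +
                                  I(sex == "female") + I(deprivation/3),
                                cessation_hazard = 0.05) {
  stopifnot(is.data.frame(records), "adherent" %in% names(records))
  y <- as.integer(records$adherent)
  if (length(unique(y)) < 2L) {
    stop("fit_adherence_model: need both adherent and non-adherent records",
         call. = FALSE)
  }
  fit <- glm(formula, data = records, family = binomial("logit"))
  if (!fit$converged) {
    stop(sprintf(
      "fit_adherence_model: IRLS did not converge (deviance %.3f after %d iterations)",
      fit$deviance, fit$iter
    ), call. = FALSE)
  }
  fitted_p <- fitted(fit)
  if (any(fitted_p > 1 - 1e-10) || any(fitted_p < 1e-10)) {
    warning("fit_adherence_model: fitted probabilities at the boundary suggest separation")
  }
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  term_labels <- names(cf)[-1L]
  # glm term labels like I((age - 60)/10) -> expression "(age - 60)/10";
  # logical terms I(sex == "female")TRUE -> "(sex == \"female\")"
  transforms <- vapply(term_labels, function(lb) {
    lb <- sub("TRUE$", "", lb)
    if (startsWith(lb, "I(")) lb <- substr(lb, 3L, nchar(lb) - 1L)
    lb
  }, character(1))
  model <- adherence_model(
    intercept = unname(cf[1L]),
    terms = data.frame(term = term_labels, transform = unname(transforms),
                       weight = unname(cf[-1L]), stringsAsFactors = FALSE),
    cessation_hazard = cessation_hazard,
    vcov = vcov(fit)
  )
  model$fit <- list(coefficients = cf, se = se, deviance = fit$deviance,
                    n = nrow(records))
  model
}

#' Probability of adherence for one individual
#'
#' Usual-care arm: inverse-logit of the model's linear predictor. Polypill
#' arm: the usual-care probability multiplied by the adherence relative risk
#' and capped at 1.
#'
#' @param ind individual (named list or one-row data frame).
#' @param model an `adherence_model`.
#' @param arm `"usual"` or `"polypill"`.
#' @param rr an [adherence_rr()]; ignored in the usual-care arm.
#' @return Probability in `[0, 1]`.
#' @export
prob_adherent <- function(ind, model = default_adherence_model(),
                          arm = c("usual", "polypill"),
                          rr = default_adherence_rr()) {
  arm <- match.arg(arm)
  p <- plogis(adherence_lp(model, ind))
  if (arm == "polypill") p <- pmin(1, p * rr$rr)
  p
}

#' Packaged illustrative adherence relative risk
#'
#' Default polypill-vs-usual-care adherence RR of 1.3 (95% CI 1.18-1.43),
#' the kind of improvement a fixed-dose combination trial reports.
#' @export
default_adherence_rr <- function() {
  adherence_rr(1.3, 1.18, 1.43, se_log = (log(1.43) - log(1.18)) / (2 * 1.96))
}

#' Estimate the adherence relative risk from a two-arm trial dataset
#'
#' Log-link binomial regression of the adherence indicator on arm; the
#' exponentiated arm coefficient is the relative risk, with a Wald interval.
#'
#' @param trial data frame with columns `arm` (`"usual"`/`"polypill"`) and
#'   `adherent` (0/1 or logical).
#' @param conf_level confidence level (default 0.95).
#' @return An [adherence_rr()].
#' @export
estimate_polypill_rr <- function(trial, conf_level = 0.95) {
  stopifnot(is.data.frame(trial), all(c("arm", "adherent") %in% names(trial)))
  arms <- unique(trial$arm)
  if (!all(c("usual", "polypill") %in% arms)) {
    stop("estimate_polypill_rr: both arms must be present", call. = FALSE)
  }
  tab <- tapply(as.integer(trial$adherent), trial$arm, sum)
  if (any(tab == 0)) {
    stop("estimate_polypill_rr: an arm has zero adherent participants; RR not estimable",
         call. = FALSE)
  }
  trial$.arm <- as.integer(trial$arm == "polypill")
  p0 <- mean(as.integer(trial$adherent)[trial$.arm == 0])
  fit <- glm(adherent ~ .arm, data = trial, family = binomial(link = "log"),
             start = c(log(p0), 0))
  if (!fit$converged) {
    stop("estimate_polypill_rr: log-binomial fit did not converge", call. = FALSE)
  }
  b <- coef(fit)[".arm"]
  se <- sqrt(vcov(fit)[".arm", ".arm"])
  z <- qnorm(1 - (1 - conf_level) / 2)
  adherence_rr(
    rr = unname(exp(b)),
    ci_low = unname(exp(b - z * se)),
    ci_high = unname(exp(b + z * se)),
    se_log = unname(se)
  )
}

#' Sample a time until medication cessation
#'
#' Exponential draw at the model's cessation hazard; zero hazard means the
#' individual never stops (`Inf`). In the simulation, cessation removes all
#' treatment effects for the remainder of the trajectory and triggers a
#' one-off stopping cost.
#'
#' @param model an `adherence_model`.
#' @param n number of draws.
#' @export
sample_cessation_time <- function(model, n = 1L) {
  sample_time_to_event(model$cessation_hazard, n)
}

#' Simulate a two-arm adherence trial dataset
#'
#' Synthetic stand-in for a polypill trial's adherence endpoint: equal-size
#' arms, usual-care adherence probability from the adherence model evaluated
#' on generated covariates, polypill-arm probability multiplied by `true_rr`
#' (capped at 1).
#'
#' @param n_per_arm participants per arm.
#' @param model usual-care [adherence_model()].
#' @param true_rr true adherence relative risk.
#' @param seed integer seed.
#' @return Data frame with `id`, `arm`, `adherent`, `age`, `sex`,
#'   `deprivation`.
#' @export
simulate_adherence_trial <- function(n_per_arm = 1000L,
                                     model = default_adherence_model(),
                                     true_rr = 1.3,
                                     seed = 1L) {
  stopifnot(n_per_arm >= 1, true_rr > 0)
  with_seed(mix_seed(seed, STREAM_TRIAL), {
    n <- 2L * n_per_arm
    d <- data.frame(
      id = seq_len(n),
      arm = rep(c("usual", "polypill"), each = n_per_arm),
      age = qtruncnorm(runif(n), 62, 10, 35, 90),
      sex = ifelse(runif(n) < 0.52, "male", "female"),
      deprivation = rnorm(n, 0, 3),
      stringsAsFactors = FALSE
    )
    p <- plogis(model$intercept + eval(model$lp_expr, d, baseenv()))
    p <- ifelse(d$arm == "polypill", pmin(1, p * true_rr), p)
    d$adherent <- as.integer(runif(n) < p)
    d
  })
}
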