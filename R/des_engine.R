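# Discrete-event simulation core. Each individual moves through lifetime
# history under competing exponential clocks with piecewise-constant
# hazards: a composite CVD clock (primary engine before the first event,
# secondary engine afterwards), incident diabetes, heart failure, GI bleed,
# medication cessation, and other-cause mortality from a national-style
# life table. Risks are refreshed after every event and at a deterministic
# update every 10 years (the engines' prediction horizon); firing any clock
# resamples the rest, which is statistically exact for exponential clocks.

#' Event types recognised by the simulation
#'
#' Acute CVD events are exactly `TIA`, `stroke`, `MI` and `angina`.
#' @export
EVENT_TYPES <- c("TIA", "stroke", "MI", "angina", "diabetes_onset",
                 "gi_bleed", "cough_onset", "heart_failure", "cessation",
                 "risk_update", "other_cause_death", "cvd_death")

#' Case-fatality probabilities for acute stroke and MI
#'
#' Sixty-day stroke fatality by age band (`<75`, `>=75`) and thirty-day MI
#' fatality by age band (`30-54`, `55-64`, `65-74`, `75-84`, `85+`). Age
#' bands are closed on the left: a stroke at age 75.0 uses the `>=75` band.
#' Defaults are illustrative values with the steep age gradient record
#' linkage studies report.
#'
#' @param stroke length-2 probability vector `c("<75", ">=75")`.
#' @param mi length-5 probability vector
#'   `c("30-54", "55-64", "65-74", "75-84", "85+")`.
#' @return Object of class `case_fatality`.
#' @export
case_fatality <- function(stroke = c("<75" = 0.15, ">=75" = 0.30),
                          mi = c("30-54" = 0.03, "55-64" = 0.05,
                                 "65-74" = 0.10, "75-84" = 0.20,
                                 "85+" = 0.35)) {
  if (!is_prob(stroke) || length(stroke) != 2L) {
    stop("case_fatality: stroke needs 2 probabilities (<75, >=75)", call. = FALSE)
  }
  if (!is_prob(mi) || length(mi) != 5L) {
    stop("case_fatality: mi needs 5 probabilities (30-54 ... 85+)", call. = FALSE)
  }
  structure(list(stroke = stroke, mi = mi), class = "case_fatality")
}

case_fatality_prob <- function(event, age, cf) {
  if (event == "stroke") {
    if (age < 75) cf$stroke[[1L]] else cf$stroke[[2L]]
  } else if (event == "MI") {
    if (age < 55) cf$mi[[1L]]
    else if (age < 65) cf$mi[[2L]]
    else if (age < 75) cf$mi[[3L]]
    else if (age < 85) cf$mi[[4L]]
    else cf$mi[[5L]]
  } else {
    stop("apply_case_fatality: only stroke and MI carry case fatality", call. = FALSE)
  }
}

#' Draw whether an acute stroke or MI is fatal
#'
#' Bernoulli draw at the age-band case-fatality probability. A fatal event
#' terminates the trajectory with cardiovascular death at the event time
#' plus the case-fatality window (60 days for stroke, 30 for MI).
#'
#' @param event `"stroke"` or `"MI"`.
#' @param age age at the event (years).
#' @param cf a [case_fatality()] object.
#' @return Logical fatal flag.
#' @export
apply_case_fatality <- function(event, age, cf = case_fatality()) {
  p <- case_fatality_prob(event, age, cf)
  runif(1) < p
}

#' Resolve a composite CVD event into one of the four acute types
#'
#' Categorical draw over `TIA`, `stroke`, `MI`, `angina` with the supplied
#' relative-incidence probabilities (an OXVASC-style split).
#'
#' @param rel_incidence named non-negative probabilities over the four CVD
#'   types, summing to 1 (tolerance 1e-9).
#' @return One of `"TIA"`, `"stroke"`, `"MI"`, `"angina"`.
#' @export
split_cvd_event <- function(rel_incidence = default_rel_incidence()) {
  p <- rel_incidence[CVD_EVENT_TYPES]
  if (any(is.na(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("split_cvd_event: rel_incidence must be named probabilities over TIA, stroke, MI, angina summing to 1",
         call. = FALSE)
  }
  CVD_EVENT_TYPES[findInterval(runif(1), cumsum(p), left.open = TRUE) + 1L]
}

#' Packaged relative incidence of acute CVD event types
#'
#' Illustrative split in the proportions population-based vascular cohorts
#' report for first presentations.
#' @export
default_rel_incidence <- function() {
  c(TIA = 0.20, stroke = 0.30, MI = 0.33, angina = 0.17)
}

#' Packaged illustrative national-style life table
#'
#' Annual probabilities of death by single year of age and sex, ages 0-109,
#' Gompertz-shaped with a female advantage; `qx = 1` at the final age. A
#' published national life table in the same layout (`age`, `sex`, `qx`)
#' is a drop-in replacement.
#' @export
default_life_table <- function() {
  age <- 0:109
  qm <- pmin(1, 3.3e-5 * exp(0.093 * age) + 8e-4)
  qf <- pmin(1, 2.1e-5 * exp(0.094 * age) + 6e-4)
  qm[age >= 109] <- 1
  qf[age >= 109] <- 1
  rbind(
    data.frame(age = age, sex = "male", qx = qm),
    data.frame(age = age, sex = "female", qx = qf)
  )
}

# Precompute per-sex yearly hazards for fast repeated sampling.
prepare_life_table <- function(life_table) {
  stopifnot(all(c("age", "sex", "qx") %in% names(life_table)))
  out <- list()
  for (s in c("male", "female")) {
    d <- life_table[life_table$sex == s, , drop = FALSE]
    d <- d[order(d$age), , drop = FALSE]
    if (nrow(d) == 0L) {
      stop(sprintf("life table: no rows for sex '%s'", s), call. = FALSE)
    }
    if (!all(diff(d$age) == 1L)) {
      stop(sprintf("life table: ages for sex '%s' must be consecutive integers", s),
           call. = FALSE)
    }
    if (max(d$age) < 100) {
      stop("life table must cover ages up to at least 100", call. = FALSE)
    }
    if (!is_prob(d$qx)) stop("life table: qx must be probabilities", call. = FALSE)
    out[[s]] <- list(min_age = d$age[1L], hazard = -log1p(-d$qx))
  }
  out
}

# Piecewise-exponential draw of years until other-cause death for someone
# alive at `age`, using precomputed yearly hazards. Consumes one uniform.
sample_ocd_time <- function(age, lt_sex) {
  target <- rexp(1)
  h <- lt_sex$hazard
  i <- floor(age) - lt_sex$min_age + 1L
  n <- length(h)
  if (i < 1L) i <- 1L
  frac <- age - floor(age)
  width <- 1 - frac
  t <- 0
  cum <- 0
  while (i <= n) {
    hi <- h[i]
    step <- hi * width
    if (!is.finite(step) || cum + step >= target) {
      return(t + if (is.finite(hi) && hi > 0) (target - cum) / hi else 0)
    }
    cum <- cum + step
    t <- t + width
    width <- 1
    i <- i + 1L
  }
  # beyond the table: continue at the final hazard
  hl <- h[n]
  if (is.finite(hl) && hl > 0) t + (target - cum) / hl else Inf
}

#' Sample years until death from non-cardiovascular causes
#'
#' Draws from the piecewise-exponential survival distribution implied by a
#' national-style life table's annual probabilities of death, conditional on
#' being alive at the given age.
#'
#' @param age current age (years, may be fractional).
#' @param sex `"male"` or `"female"`.
#' @param life_table data frame with columns `age`, `sex`, `qx` covering
#'   ages up to at least 100.
#' @return Years until other-cause death.
#' @export
other_cause_death_time <- function(age, sex, life_table = default_life_table()) {
  lt <- prepare_life_table(life_table)
  if (!sex %in% names(lt)) stop("sex must be 'male' or 'female'", call. = FALSE)
  sample_ocd_time(age, lt[[sex]])
}

# case-fatality windows, in years
STROKE_FATAL_WINDOW <- 60 / 365.25
MI_FATAL_WINDOW <- 30 / 365.25

#' Simulate one individual's lifetime trajectory
#'
#' Runs the discrete-event loop for a single included individual under one
#' scenario arm: at each state point the competing hazards are computed
#' (composite CVD from the primary or secondary engine according to event
#' history, incident diabetes while non-diabetic, heart failure, GI bleed,
#' cessation while on treatment, other-cause mortality from the life
#' table), one exponential clock is sampled per cause, and the earliest
#' clock fires, subject to a deterministic risk update every
#' `params$update_interval` years and an age cap. Adherence is redrawn at
#' every state point; the same random stream is used for both arms when the
#' seed derives only from the master seed and the individual id, giving
#' common random numbers across scenarios.
#'
#' @param ind one individual: one-row data frame or named list.
#' @param scenario a [scenario_config()]; `scenario$arm` selects usual care
#'   or polypill.
#' @param params a [default_parameters()] parameter set.
#' @param seed optional integer seed for this individual's stream; default
#'   derives from `scenario$master_seed` and `ind$id` (arm-independent).
#' @return Object of class `trajectory`: event records, exposure intervals,
#'   exit type (`death` or `age_cap`) and exit time.
#' @export
simulate_individual <- function(ind, scenario, params, seed = NULL) {
  params <- prepare_parameters(params)
  if (is.null(seed)) {
    seed <- mix_seed(scenario$master_seed, STREAM_DES, as.integer(ind$id))
  }
  set.seed(seed)
  simulate_individual_impl(as.list(ind), scenario$arm, params)
}

# Internal: assumes RNG already seeded and params prepared.
simulate_individual_impl <- function(ind, arm, params) {
  age0 <- ind$age
  sex <- ind$sex
  age_cap <- params$age_cap
  upd <- params$update_interval

  ev_time <- numeric(32L); ev_type <- character(32L)
  ev_fatal <- logical(32L); ev_age <- numeric(32L); n_ev <- 0L
  add_event <- function(time, type, fatal) {
    n_ev <<- n_ev + 1L
    if (n_ev > length(ev_time)) {
      ev_time <<- c(ev_time, numeric(length(ev_time)))
      ev_type <<- c(ev_type, character(length(ev_type)))
      ev_fatal <<- c(ev_fatal, logical(length(ev_fatal)))
      ev_age <<- c(ev_age, numeric(length(ev_age)))
    }
    ev_time[n_ev] <<- time; ev_type[n_ev] <<- type
    ev_fatal[n_ev] <<- fatal; ev_age[n_ev] <<- age0 + time
  }

  ex_start <- numeric(16L); ex_end <- numeric(16L)
  ex_on <- logical(16L); ex_adh <- logical(16L); n_ex <- 0L
  add_exposure <- function(t0, t1, on, adh) {
    if (t1 <= t0) return(invisible())
    n_ex <<- n_ex + 1L
    if (n_ex > length(ex_start)) {
      ex_start <<- c(ex_start, numeric(length(ex_start)))
      ex_end <<- c(ex_end, numeric(length(ex_end)))
      ex_on <<- c(ex_on, logical(length(ex_on)))
      ex_adh <<- c(ex_adh, logical(length(ex_adh)))
    }
    ex_start[n_ex] <<- t0; ex_end[n_ex] <<- t1
    ex_on[n_ex] <<- on; ex_adh[n_ex] <<- adh
  }

  finish <- function(exit, exit_time, first_adherent) {
    structure(list(
      id = ind$id, arm = arm, entry_age = age0, sex = sex,
      events = data.frame(
        time = ev_time[seq_len(n_ev)], type = ev_type[seq_len(n_ev)],
        fatal = ev_fatal[seq_len(n_ev)], age = ev_age[seq_len(n_ev)],
        stringsAsFactors = FALSE
      ),
      exposure = data.frame(
        start = ex_start[seq_len(n_ex)], end = ex_end[seq_len(n_ex)],
        on_treatment = ex_on[seq_len(n_ex)], adherent = ex_adh[seq_len(n_ex)],
        stringsAsFactors = FALSE
      ),
      exit = exit, exit_time = exit_time,
      first_period_adherent = first_adherent
    ), class = "trajectory")
  }

  if (age0 >= age_cap) {
    return(finish("age_cap", 0, NA))
  }

  # mutable covariate state seen by the risk engines and adherence model
  state <- ind
  state$n_prior_events <- n_cvd_events(ind$cvd_history)
  n_cvd <- state$n_prior_events
  diabetic <- isTRUE(as.logical(ind$diabetes))
  state$diabetes <- diabetic
  on_treatment <- TRUE
  meds <- params$regimen
  fx <- params$treatment_effects
  lt_sex <- params$.life_table[[sex]]
  pending_cough <- Inf
  first_adherent <- NA
  t <- 0

  repeat {
    cur_age <- age0 + t
    state$age <- cur_age

    # adherence for this risk period
    if (on_treatment) {
      p_adh <- prob_adherent(state, params$adherence_model, arm,
                             params$adherence_rr)
      adherent <- runif(1) < p_adh
    } else {
      adherent <- FALSE
    }
    if (is.na(first_adherent)) first_adherent <- adherent

    # one-shot cough at treatment initiation under an ACE inhibitor
    if (t == 0 && adherent && isTRUE(meds$acei) && fx$p_cough_acei > 0) {
      if (runif(1) < fx$p_cough_acei) pending_cough <- runif(1)
    }

    # competing hazards for this period
    if (n_cvd == 0L) {
      p_cvd <- predict_risk(params$primary_engine, state)
      hz <- params$primary_engine$horizon
    } else {
      p_cvd <- predict_risk(params$secondary_engine, state)
      hz <- params$secondary_engine$horizon
    }
    h_cvd <- -log1p(-min(p_cvd, 1 - 1e-12)) / hz
    h_cvd <- adjusted_cvd_hazard(h_cvd, meds, adherent, fx)

    h_dia_base <- if (!diabetic) {
      p_d <- predict_risk(params$diabetes_engine, state)
      -log1p(-min(p_d, 1 - 1e-12)) / params$diabetes_engine$horizon
    } else 0
    adv <- adverse_event_hazards(meds, adherent, h_dia_base,
                                 params$baseline_gi_hazard, fx)
    h_dia <- if (diabetic) 0 else adv$diabetes
    h_gi <- adv$gi_bleed
    h_hf <- hf_hazard_at(cur_age, params$hf_table)
    if (adherent && isTRUE(meds$aht)) h_hf <- h_hf * fx$rr_hf_aht^fx$itt_adjustment
    h_cess <- if (on_treatment) params$adherence_model$cessation_hazard else 0

    # one clock per cause, fixed draw order (stable across arms)
    t_cvd <- if (h_cvd > 0) rexp(1, h_cvd) else Inf
    t_dia <- if (h_dia > 0) rexp(1, h_dia) else Inf
    t_hf <- if (h_hf > 0) rexp(1, h_hf) else Inf
    t_gi <- if (h_gi > 0) rexp(1, h_gi) else Inf
    t_cess <- if (h_cess > 0) rexp(1, h_cess) else Inf
    t_ocd <- sample_ocd_time(cur_age, lt_sex)

    dt_cap <- age_cap - cur_age
    cand <- c(cap = dt_cap, ocd = t_ocd, cvd = t_cvd, diabetes = t_dia,
              hf = t_hf, gi = t_gi, cessation = t_cess, update = upd)
    k <- which.min(cand)
    dt <- cand[[k]]
    cause <- names(cand)[k]
    t_next <- t + dt

    # a pending cough falling inside this step is recorded as it is passed
    if (pending_cough <= t_next) {
      add_event(pending_cough, "cough_onset", FALSE)
      pending_cough <- Inf
    }
    add_exposure(t, t_next, on_treatment, adherent)

    if (cause == "cap") {
      return(finish("age_cap", t_next, first_adherent))
    } else if (cause == "ocd") {
      add_event(t_next, "other_cause_death", TRUE)
      return(finish("death", t_next, first_adherent))
    } else if (cause == "update") {
      add_event(t_next, "risk_update", FALSE)
    } else if (cause == "cessation") {
      add_event(t_next, "cessation", FALSE)
      on_treatment <- FALSE
    } else if (cause == "diabetes") {
      add_event(t_next, "diabetes_onset", FALSE)
      diabetic <- TRUE
      state$diabetes <- TRUE
    } else if (cause == "hf") {
      add_event(t_next, "heart_failure", FALSE)
    } else if (cause == "gi") {
      add_event(t_next, "gi_bleed", FALSE)
    } else { # cvd
      type <- split_cvd_event(params$rel_incidence)
      age_at <- cur_age + dt
      fatal <- if (type %in% c("stroke", "MI")) {
        apply_case_fatality(type, age_at, params$case_fatality)
      } else FALSE
      add_event(t_next, type, fatal)
      n_cvd <- n_cvd + 1L
      state$n_prior_events <- n_cvd
      if (!nzchar(state$cvd_history)) {
        state$cvd_history <- sprintf("%s:0", type)
      }
      if (fatal) {
        window <- if (type == "stroke") STROKE_FATAL_WINDOW else MI_FATAL_WINDOW
        t_death <- min(t_next + window, age_cap - age0)
        add_event(t_death, "cvd_death", TRUE)
        return(finish("death", t_death, first_adherent))
      }
    }
    t <- t_next
  }
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory (id %s, %s arm): entry age %.1f, exit '%s' at %.2f y (age %.1f)\n",
    x$id, x$arm, x$entry_age, x$exit, x$exit_time, x$entry_age + x$exit_time
  ))
  shown <- x$events[x$events$type != "risk_update", , drop = FALSE]
  if (nrow(shown)) {
    print(shown, row.names = FALSE)
  } else {
    cat("  no events (risk updates only)\n")
  }
  invisible(x)
}
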