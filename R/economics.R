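# Cost and QALY accrual over a trajectory, with continuous-time discounting
# at exact event times: point costs are discounted by (1+r)^(-t) and annual
# flows (medication, monitoring, post-event state costs, utility) are
# integrated as \int c (1+r)^(-t) dt over their intervals, the natural
# continuous analogue of an annual 3.5% rate in a model with no cycles.

#' Construct a cost table (GBP, NHS/PSS perspective)
#'
#' Defaults are illustrative values of the magnitude NHS costing sources
#' report, in a fixed price year recorded in `currency_year`.
#'
#' @param acute named per-event acute costs by event type.
#' @param state_annual named annual post-event state costs; each applies for
#'   life from the first event of that type.
#' @param med_annual named annual medication costs per class
#'   (`statin`, `aht`, `aspirin`, `acei`).
#' @param polypill_annual annual polypill cost; `NULL` means the aggregate
#'   of the component drug costs (see [polypill_annual_cost()]).
#' @param monitoring_annual annual monitoring cost while on treatment.
#' @param stopping one-off cost applied at medication cessation (e.g. two
#'   GP visits plus tests).
#' @param currency_year metadata only.
#' @return Object of class `cost_table`.
#' @export
cost_table <- function(acute = c(TIA = 1000, stroke = 4500, MI = 3500,
                                 angina = 2000, gi_bleed = 1500,
                                 heart_failure = 2500, diabetes_onset = 500,
                                 cough_onset = 50, cvd_death = 0,
                                 other_cause_death = 0),
                       state_annual = c(stroke = 1500, MI = 500,
                                        angina = 400, diabetes = 800,
                                        heart_failure = 1200),
                       med_annual = c(statin = 15, aht = 40, aspirin = 5,
                                      acei = 20),
                       polypill_annual = NULL,
                       monitoring_annual = 30,
                       stopping = 70,
                       currency_year = 2015) {
  v <- validator()
  v$check(is_nonneg(acute), "acute: costs must be >= 0")
  v$check(is_nonneg(state_annual), "state_annual: costs must be >= 0")
  v$check(is_nonneg(med_annual), "med_annual: costs must be >= 0")
  v$check(is.null(polypill_annual) || is_nonneg(polypill_annual),
          "polypill_annual: must be >= 0 or NULL")
  v$check(is_nonneg(monitoring_annual), "monitoring_annual: must be >= 0")
  v$check(is_nonneg(stopping), "stopping: must be >= 0")
  v$fail_if_any("invalid cost table")
  structure(list(
    acute = acute, state_annual = state_annual, med_annual = med_annual,
    polypill_annual = polypill_annual, monitoring_annual = monitoring_annual,
    stopping = stopping, currency_year = currency_year
  ), class = "cost_table")
}

#' Annual polypill cost
#'
#' The polypill is costed as the aggregate of its component drugs' annual
#' costs unless a sensitivity price override is supplied, in which case the
#' override is returned and the components are ignored.
#'
#' @param component_costs numeric vector of annual component drug costs.
#' @param override optional sensitivity price (>= 0).
#' @return Annual cost in GBP.
#' @export
polypill_annual_cost <- function(component_costs, override = NULL) {
  if (!is.null(override)) {
    stopifnot(is_nonneg(override), length(override) == 1L)
    return(override)
  }
  stopifnot(is_nonneg(component_costs))
  sum(component_costs)
}

#' Construct a utility table (EQ-5D scale)
#'
#' Baseline utility by age band and sex, permanent per-state decrements
#' applied additively from the first event of each type (floored at zero),
#' and transient decrements with durations for GI bleed and cough.
#'
#' @param baseline data frame with columns `age` (band lower edge), `male`,
#'   `female`; bands are closed on the left.
#' @param decrements named per-state utility decrements (>= 0).
#' @param transient named list with `gi_bleed` and `cough_onset`, each
#'   `c(decrement, duration_years)`.
#' @return Object of class `utility_table`.
#' @export
utility_table <- function(baseline = data.frame(
                            age = c(18, 45, 55, 65, 75, 85),
                            male = c(0.93, 0.91, 0.87, 0.83, 0.77, 0.70),
                            female = c(0.92, 0.90, 0.85, 0.81, 0.74, 0.67)
                          ),
                          decrements = c(stroke = 0.15, TIA = 0.05,
                                         MI = 0.08, angina = 0.09,
                                         diabetes = 0.06,
                                         heart_failure = 0.15),
                          transient = list(
                            gi_bleed = c(decrement = 0.10, duration = 0.1),
                            cough_onset = c(decrement = 0.05, duration = 0.5)
                          )) {
  v <- validator()
  v$check(is.data.frame(baseline) &&
            all(c("age", "male", "female") %in% names(baseline)),
          "baseline: needs columns age, male, female")
  v$check(is_prob(baseline$male) && is_prob(baseline$female),
          "baseline: utilities must be in [0, 1]")
  v$check(is_nonneg(decrements), "decrements: must be >= 0")
  for (nm in names(transient)) {
    v$check(is_nonneg(transient[[nm]]) && length(transient[[nm]]) == 2L,
            sprintf("transient$%s: needs c(decrement, duration) >= 0", nm))
  }
  v$fail_if_any("invalid utility table")
  structure(list(baseline = baseline, decrements = decrements,
                 transient = transient), class = "utility_table")
}

baseline_utility_at <- function(age, sex, utable) {
  b <- utable$baseline
  i <- findInterval(age, b$age)
  if (any(i < 1L)) i[i < 1L] <- 1L
  b[[sex]][i]
}

# annual medication + monitoring flow while adherent, by arm
treatment_flow <- function(arm, costs) {
  med <- if (arm == "polypill") {
    polypill_annual_cost(costs$med_annual, costs$polypill_annual)
  } else {
    sum(costs$med_annual)
  }
  med + costs$monitoring_annual
}

# map acute event types to the chronic state they start
STATE_OF_EVENT <- c(stroke = "stroke", MI = "MI", angina = "angina",
                    diabetes_onset = "diabetes",
                    heart_failure = "heart_failure")

#' Discounted lifetime cost of a trajectory
#'
#' Acute event costs are discounted at their exact event times; annual
#' flows (medication and monitoring while adherent, post-event state costs
#' for life from the first event of each chronic type) are integrated with
#' continuous discounting; the stopping cost applies once at cessation.
#' Repeat events of a type re-trigger the acute cost only.
#'
#' @param traj a [simulate_individual()] trajectory.
#' @param costs a [cost_table()].
#' @param rate annual discount rate (>= 0).
#' @return List with `cost` (discounted) and `cost_undiscounted`.
#' @export
accrue_costs <- function(traj, costs = cost_table(), rate = 0.035) {
  stopifnot(rate >= 0)
  ev <- traj$events
  if (any(ev$time < 0)) stop("accrue_costs: negative event times", call. = FALSE)
  exit_t <- traj$exit_time
  pv <- 0; undisc <- 0

  # acute event costs at exact event times
  if (nrow(ev)) {
    ac <- costs$acute[ev$type]
    ac[is.na(ac)] <- 0
    pv <- pv + sum(ac * (1 + rate)^(-ev$time))
    undisc <- undisc + sum(ac)
    # stopping cost at cessation
    ces <- ev$time[ev$type == "cessation"]
    if (length(ces)) {
      pv <- pv + costs$stopping * (1 + rate)^(-ces[1L])
      undisc <- undisc + costs$stopping
    }
    # chronic state costs: for life from the first event of each type
    for (et in names(STATE_OF_EVENT)) {
      times <- ev$time[ev$type == et & !ev$fatal]
      if (length(times)) {
        t0 <- min(times)
        flow <- costs$state_annual[[STATE_OF_EVENT[[et]]]]
        if (!is.null(flow) && flow > 0 && exit_t > t0) {
          pv <- pv + discount_flow(flow, t0, exit_t, rate)
          undisc <- undisc + flow * (exit_t - t0)
        }
      }
    }
  }

  # medication + monitoring while adherent
  exb <- traj$exposure
  keep <- exb$adherent
  if (any(keep)) {
    flow <- treatment_flow(traj$arm, costs)
    if (flow > 0) {
      pv <- pv + sum(discount_flow(flow, exb$start[keep], exb$end[keep], rate))
      undisc <- undisc + flow * sum(exb$end[keep] - exb$start[keep])
    }
  }
  list(cost = pv, cost_undiscounted = undisc)
}

#' Discounted quality-adjusted life years of a trajectory
#'
#' The utility path is the age- and sex-specific baseline minus the sum of
#' active decrements (permanent from the first event of each chronic type;
#' transient for GI bleed and cough), floored at zero, integrated with
#' continuous discounting up to exit.
#'
#' @param traj a [simulate_individual()] trajectory.
#' @param utils a [utility_table()].
#' @param rate annual discount rate (>= 0).
#' @return List with `qalys` (discounted) and `qalys_undiscounted`.
#' @export
accrue_qalys <- function(traj, utils = utility_table(), rate = 0.035) {
  stopifnot(rate >= 0)
  exit_t <- traj$exit_time
  if (exit_t <= 0) {
    return(list(qalys = 0, qalys_undiscounted = 0))
  }
  ev <- traj$events
  age0 <- traj$entry_age

  # decrement onsets: permanent states and transient windows
  dec_start <- numeric(0); dec_end <- numeric(0); dec_val <- numeric(0)
  for (et in names(STATE_OF_EVENT)) {
    times <- ev$time[ev$type == et]
    if (length(times)) {
      state <- if (et == "diabetes_onset") "diabetes" else et
      d <- utils$decrements[[state]]
      if (!is.null(d) && d > 0) {
        dec_start <- c(dec_start, min(times))
        dec_end <- c(dec_end, Inf)
        dec_val <- c(dec_val, d)
      }
    }
  }
  tia_times <- ev$time[ev$type == "TIA"]
  if (length(tia_times) && !is.null(utils$decrements[["TIA"]]) &&
      utils$decrements[["TIA"]] > 0) {
    dec_start <- c(dec_start, min(tia_times))
    dec_end <- c(dec_end, Inf)
    dec_val <- c(dec_val, utils$decrements[["TIA"]])
  }
  for (tt in names(utils$transient)) {
    times <- ev$time[ev$type == tt]
    spec <- utils$transient[[tt]]
    if (length(times) && spec[[1L]] > 0 && spec[[2L]] > 0) {
      dec_start <- c(dec_start, times)
      dec_end <- c(dec_end, times + spec[[2L]])
      dec_val <- c(dec_val, rep(spec[[1L]], length(times)))
    }
  }

  # breakpoints: decrement edges plus age-band boundaries
  band_edges <- utils$baseline$age
  band_breaks <- band_edges[band_edges > age0 & band_edges < age0 + exit_t] - age0
  brk <- sort(unique(c(0, exit_t,
                       dec_start[dec_start < exit_t],
                       pmin(dec_end[is.finite(dec_end)], exit_t),
                       band_breaks)))
  brk <- brk[brk >= 0 & brk <= exit_t]

  qaly <- 0; qaly_un <- 0
  for (j in seq_len(length(brk) - 1L)) {
    t0 <- brk[j]; t1 <- brk[j + 1L]
    mid <- (t0 + t1) / 2
    u <- baseline_utility_at(age0 + mid, traj$sex, utils)
    if (length(dec_val)) {
      active <- dec_start <= mid & mid < dec_end
      u <- u - sum(dec_val[active])
    }
    u <- max(u, 0)
    qaly <- qaly + discount_flow(u, t0, t1, rate)
    qaly_un <- qaly_un + u * (t1 - t0)
  }
  list(qalys = qaly, qalys_undiscounted = qaly_un)
}

#' Discounted outcome (cost and QALYs) for one trajectory
#'
#' Convenience wrapper combining [accrue_costs()] and [accrue_qalys()].
#'
#' @inheritParams accrue_costs
#' @param utils a [utility_table()].
#' @return List with `cost`, `qalys` and their undiscounted variants.
#' @export
discounted_outcome <- function(traj, costs = cost_table(),
                               utils = utility_table(), rate = 0.035) {
  c(accrue_costs(traj, costs, rate), accrue_qalys(traj, utils, rate))
}
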