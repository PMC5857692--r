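# Probabilistic sensitivity analysis: per iteration, draw one parameter set
# from the PSA distributions (lognormal for relative risks, beta for
# probabilities, gamma for costs by default), draw one bootstrap resample of
# the population with replacement (same size), run both arms under common
# random numbers, and record the increments. The cost-effectiveness
# acceptability curve is the fraction of iterations with positive net
# benefit at each willingness-to-pay value.

#' Specify a probabilistic sensitivity analysis
#'
#' @param n_iterations number of PSA iterations (>= 1).
#' @param distributions list of parameter-distribution entries as produced
#'   by [default_psa_distributions()]; each entry has `path` (character
#'   vector into the parameter set), `dist`
#'   (`"lognormal"`, `"beta"`, `"gamma"` or `"fixed"`) and its spread
#'   (`cv` for lognormal/gamma, `ess` for beta). A zero spread or
#'   `"fixed"` makes the entry degenerate at the point value.
#' @param bootstrap draw a population bootstrap resample each iteration?
#' @param master_seed integer master seed for the PSA streams.
#' @return Object of class `psa_spec`.
#' @export
psa_spec <- function(n_iterations = 200L,
                     distributions = default_psa_distributions(),
                     bootstrap = TRUE,
                     master_seed = 1L) {
  stopifnot(n_iterations >= 1L)
  for (e in distributions) {
    if (!all(c("path", "dist") %in% names(e))) {
      stop("psa_spec: each distribution entry needs 'path' and 'dist'", call. = FALSE)
    }
    if (!e$dist %in% c("lognormal", "beta", "gamma", "fixed")) {
      stop(sprintf("psa_spec: unknown distribution '%s' for %s",
                   e$dist, paste(e$path, collapse = "$")), call. = FALSE)
    }
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 distributions = distributions,
                 bootstrap = isTRUE(bootstrap),
                 master_seed = as.integer(master_seed)),
            class = "psa_spec")
}

#' Default PSA distributions for the packaged parameter set
#'
#' Standard health-economics families: lognormal on relative risks, beta on
#' probabilities (cough, case fatality), gamma on costs. Every entry can be
#' overridden or removed; `cv = 0` (or `ess = Inf`) makes an entry
#' degenerate.
#'
#' @param rr_cv coefficient of variation (log scale SD) for relative risks.
#' @param cost_cv coefficient of variation for costs.
#' @param prob_ess effective sample size for beta-distributed probabilities.
#' @export
default_psa_distributions <- function(rr_cv = 0.08, cost_cv = 0.2,
                                      prob_ess = 200) {
  rr_paths <- list(
    c("treatment_effects", "rr_cvd_statin"),
    c("treatment_effects", "rr_cvd_aht"),
    c("treatment_effects", "rr_cvd_aspirin"),
    c("treatment_effects", "rr_diabetes_tx"),
    c("treatment_effects", "rr_gi_bleed_aspirin"),
    c("treatment_effects", "rr_hf_aht"),
    c("adherence_rr", "rr")
  )
  out <- lapply(rr_paths, function(p) list(path = p, dist = "lognormal", cv = rr_cv))
  out <- c(out, list(
    list(path = c("treatment_effects", "p_cough_acei"), dist = "beta", ess = prob_ess),
    list(path = c("case_fatality", "stroke"), dist = "beta", ess = prob_ess),
    list(path = c("case_fatality", "mi"), dist = "beta", ess = prob_ess),
    list(path = c("costs", "acute"), dist = "gamma", cv = cost_cv),
    list(path = c("costs", "state_annual"), dist = "gamma", cv = cost_cv),
    list(path = c("costs", "stopping"), dist = "gamma", cv = cost_cv)
  ))
  out
}

# Draw a replacement value for one entry; elementwise over vectors.
# Lognormal is median-preserving at the point value; beta and gamma are
# mean-preserving.
draw_psa_value <- function(value, entry) {
  if (entry$dist == "fixed") {
    return(value)
  }
  if (entry$dist == "lognormal") {
    cv <- entry$cv %||% 0
    if (cv <= 0) return(value)
    return(value * exp(rnorm(length(value), 0, cv)))
  }
  if (entry$dist == "gamma") {
    cv <- entry$cv %||% 0
    if (cv <= 0) return(value)
    shape <- 1 / cv^2
    out <- value
    pos <- value > 0
    out[pos] <- rgamma(sum(pos), shape = shape, rate = shape / value[pos])
    return(out)
  }
  # beta
  ess <- entry$ess %||% Inf
  if (!is.finite(ess) || ess <= 0) return(value)
  out <- value
  inner <- value > 0 & value < 1
  out[inner] <- rbeta(sum(inner), value[inner] * ess, (1 - value[inner]) * ess)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One parameter-set draw; preserves classes of the nested components.
draw_psa_parameters <- function(params, distributions) {
  for (e in distributions) {
    node <- params
    for (k in e$path[-length(e$path)]) node <- node[[k]]
    leaf <- e$path[length(e$path)]
    cur <- node[[leaf]]
    if (is.null(cur)) {
      stop(sprintf("PSA distribution points at missing parameter %s",
                   paste(e$path, collapse = "$")), call. = FALSE)
    }
    new <- draw_psa_value(cur, e)
    # write back along the path
    expr <- "params"
    for (k in e$path) expr <- sprintf("%s[['%s']]", expr, k)
    eval(str2lang(sprintf("%s <- new", expr)))
  }
  params$.life_table <- NULL # force re-preparation against drawn tables
  params
}

#' Run the probabilistic sensitivity analysis
#'
#' @param pop an included population data frame (the bootstrap resamples
#'   it with replacement at its own size each iteration when
#'   `psa$bootstrap` is `TRUE`).
#' @param psa a [psa_spec()].
#' @param params base-case [default_parameters()].
#' @param wtp willingness-to-pay grid for the acceptability curve.
#' @return Object of class `psa_result`: `cloud` (per-iteration
#'   `delta_cost`, `delta_qalys`), `ceac` (probability cost-effective per
#'   willingness-to-pay value), convergence diagnostics, and the base-case
#'   increments.
#' @export
run_psa <- function(pop, psa = psa_spec(), params = default_parameters(),
                    wtp = seq(0, 50000, by = 5000)) {
  stopifnot(is.data.frame(pop), nrow(pop) >= 1L)
  n <- nrow(pop)
  d_cost <- numeric(psa$n_iterations)
  d_qalys <- numeric(psa$n_iterations)
  boot_n <- integer(psa$n_iterations)

  for (it in seq_len(psa$n_iterations)) {
    set.seed(mix_seed(psa$master_seed, STREAM_PSA, it))
    params_it <- draw_psa_parameters(params, psa$distributions)
    boot <- if (psa$bootstrap) {
      idx <- sample.int(n, n, replace = TRUE)
      b <- pop[idx, , drop = FALSE]
      b$id <- seq_len(n) # fresh ids keep per-individual streams distinct
      b
    } else {
      pop
    }
    boot_n[it] <- nrow(boot)
    # common random numbers across iterations: the DES stream depends on the
    # PSA master seed only, so iteration-to-iteration variation reflects the
    # parameter draws and bootstrap resample, not fresh simulation noise
    oc <- run_scenarios(boot, params_it,
                        master_seed = mix_seed(psa$master_seed, STREAM_PSA, 7L))
    res <- icer_and_nmb(oc, wtp = 20000)
    d_cost[it] <- res$delta_cost
    d_qalys[it] <- res$delta_qalys
  }

  cloud <- data.frame(iteration = seq_len(psa$n_iterations),
                      delta_cost = d_cost, delta_qalys = d_qalys,
                      boot_n = boot_n)
  ceac <- data.frame(
    wtp = wtp,
    p_cost_effective = vapply(wtp, function(l) mean(l * d_qalys - d_cost > 0),
                              numeric(1))
  )
  conv <- convergence_check(cloud[, c("delta_cost", "delta_qalys")])
  structure(list(cloud = cloud, ceac = ceac, convergence = conv,
                 n_iterations = psa$n_iterations, n = n,
                 bootstrap = psa$bootstrap),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "PSA: %d iterations over %d individuals%s\n", x$n_iterations, x$n,
    if (x$bootstrap) " (population bootstrap on)" else ""
  ))
  cat(sprintf("  mean ΔC = £%.2f, mean ΔE = %.5f QALYs\n",
              mean(x$cloud$delta_cost), mean(x$cloud$delta_qalys)))
  cat(sprintf("  convergence: %s (recommended iterations: %s)\n",
              if (x$convergence$stable) "stable" else "unstable",
              format(x$convergence$recommended_n)))
  invisible(x)
}

#' Cost-effectiveness plane and acceptability curve
#'
#' @param x a `psa_result`.
#' @param which `"plane"` or `"ceac"`.
#' @param ... passed to the base plotting call.
#' @export
plot.psa_result <- function(x, which = c("plane", "ceac"), ...) {
  which <- match.arg(which)
  if (which == "plane") {
    plot(x$cloud$delta_qalys, x$cloud$delta_cost,
         xlab = "Incremental QALYs", ylab = "Incremental cost (GBP)",
         main = "Cost-effectiveness plane", pch = 16,
         col = "#00000055", ...)
    abline(h = 0, v = 0, lty = 3)
  } else {
    plot(x$ceac$wtp, x$ceac$p_cost_effective, type = "b",
         xlab = "Willingness to pay (GBP/QALY)",
         ylab = "Probability cost-effective", ylim = c(0, 1),
         main = "Cost-effectiveness acceptability curve", ...)
  }
  invisible(x)
}

#' Check stability of running PSA means
#'
#' The analysis is judged stable when the 95% confidence half-width of the
#' mean of each column falls below `rel_tol` times the absolute mean. A
#' non-positive tolerance is flagged as never satisfiable rather than
#' looping.
#'
#' @param values data frame or matrix of per-iteration quantities (e.g.
#'   `delta_cost`, `delta_qalys`), at least 2 rows.
#' @param rel_tol relative tolerance (default 0.01).
#' @param min_iterations minimum iterations before stability can be
#'   declared.
#' @return List with `stable`, `recommended_n`, and per-column diagnostics.
#' @export
convergence_check <- function(values, rel_tol = 0.01, min_iterations = 10L) {
  values <- as.data.frame(values)
  n <- nrow(values)
  if (n < 2L) stop("convergence_check: need at least 2 iterations", call. = FALSE)
  z <- qnorm(0.975)
  diag <- lapply(values, function(v) {
    m <- mean(v); s <- sd(v)
    hw <- z * s / sqrt(n)
    # target half-width is relative to the mean magnitude; a zero-variance
    # stream is immediately stable
    ok <- if (s == 0) TRUE else if (rel_tol <= 0) FALSE else hw <= rel_tol * abs(m)
    n_req <- if (s == 0) min_iterations else if (rel_tol <= 0 || m == 0) {
      Inf
    } else {
      ceiling((z * s / (rel_tol * abs(m)))^2)
    }
    list(mean = m, sd = s, half_width = hw, stable = ok, n_required = n_req)
  })
  stable <- all(vapply(diag, `[[`, logical(1), "stable")) && n >= min_iterations
  recommended <- max(vapply(diag, `[[`, numeric(1), "n_required"), min_iterations)
  list(stable = stable && rel_tol > 0,
       recommended_n = recommended,
       rel_tol = rel_tol,
       n = n,
       flag = if (rel_tol <= 0) "tolerance <= 0 can never be satisfied" else NULL,
       columns = diag)
}
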