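test_that("the CVD split draws only the four acute types with the given weights", {
  set.seed(51)
  expect_identical(split_cvd_event(c(TIA = 0, stroke = 1, MI = 0, angina = 0)),
                   "stroke")
  draws <- replicate(20000, split_cvd_event(c(TIA = 0.25, stroke = 0.25,
                                              MI = 0.25, angina = 0.25)))
  expect_true(all(draws %in% c("TIA", "stroke", "MI", "angina")))
  freq <- table(factor(draws, levels = c("TIA", "stroke", "MI", "angina"))) / 20000
  se <- sqrt(0.25 * 0.75 / 20000)
  expect_true(all(abs(freq - 0.25) < 3 * se))
  expect_error(split_cvd_event(c(TIA = 0.5, stroke = 0.5, MI = 0.5, angina = 0.5)),
               "summing to 1")
})

test_that("case fatality uses left-closed age bands", {
  cf <- case_fatality(stroke = c("<75" = 0, ">=75" = 1),
                      mi = c("30-54" = 0, "55-64" = 0, "65-74" = 0,
                             "75-84" = 0, "85+" = 1))
  set.seed(1)
  expect_false(apply_case_fatality("stroke", 74.9, cf))
  expect_true(apply_case_fatality("stroke", 75.0, cf))
  expect_true(apply_case_fatality("MI", 86, cf))   # 85+ band
  expect_false(apply_case_fatality("MI", 84.99, cf))
  # zero-probability band is never fatal
  cf0 <- case_fatality(stroke = c("<75" = 0, ">=75" = 0))
  expect_false(any(replicate(200, apply_case_fatality("stroke", 80, cf0))))
  expect_error(apply_case_fatality("angina", 60, cf), "stroke and MI")
})

test_that("other-cause death sampling honours the life table", {
  # certain death in the entry year
  lt1 <- flat_life_table(1)
  set.seed(61)
  t1 <- replicate(200, other_cause_death_time(60, "male", lt1))
  expect_true(all(t1 <= 1))
  # flat annual probability q is a constant hazard -log(1-q)
  q <- 0.05
  ltq <- flat_life_table(q)
  set.seed(62)
  lam <- -log(1 - q)
  draws <- replicate(20000, other_cause_death_time(40, "female", ltq))
  capped <- draws[draws < 69] # piecewise part before the table forces death
  ks <- suppressWarnings(ks.test(
    capped, function(x) pexp(x, lam) / pexp(69, lam)))
  expect_gt(ks$p.value, 0.01)
})

test_that("an individual entering at the age cap exits immediately with no events", {
  traj <- simulate_individual(test_individual(age = 100),
                              scenario_config("usual", master_seed = 1),
                              default_parameters())
  expect_identical(traj$exit, "age_cap")
  expect_equal(traj$exit_time, 0)
  expect_equal(nrow(traj$events), 0L)
})

test_that("a degenerate life table forces death within the entry year", {
  params <- mortality_only_params(flat_life_table(1))
  for (seed in 1:20) {
    traj <- simulate_individual(test_individual(age = 60),
                                scenario_config("usual", master_seed = seed),
                                params)
    expect_identical(traj$exit, "death")
    expect_lte(traj$exit_time, 1)
    expect_identical(traj$events$type, "other_cause_death")
  }
})

test_that("event-free trajectories get risk updates exactly ten years apart", {
  # no events, negligible mortality until the cap
  params <- mortality_only_params(flat_life_table(1e-12))
  traj <- simulate_individual(test_individual(age = 55),
                              scenario_config("usual", master_seed = 2),
                              params)
  expect_identical(traj$exit, "age_cap")
  expect_equal(traj$exit_time, 45, tolerance = 1e-9)
  upd <- traj$events$time[traj$events$type == "risk_update"]
  expect_equal(upd, c(10, 20, 30, 40), tolerance = 1e-9)
  expect_true(all(abs(diff(upd) - 10) < 1e-9))
})

test_that("trajectories satisfy ordering, exit and age-cap invariants", {
  pop <- apply_inclusion(generate_population(population_spec(n = 600, seed = 23)))
  params <- polypillCEA:::prepare_parameters(default_parameters())
  exits <- character(nrow(pop))
  for (i in seq_len(nrow(pop))) {
    traj <- simulate_individual(as.list(pop[i, ]),
                                scenario_config("polypill", master_seed = 7),
                                params)
    expect_true(all(diff(traj$events$time) >= 0))
    expect_true(all(traj$events$time <= traj$exit_time + 1e-12))
    expect_lte(traj$entry_age + traj$exit_time, 100 + 1e-9)
    expect_true(traj$exit %in% c("death", "age_cap"))
    exits[i] <- traj$exit
    # exposure intervals tile [0, exit] without overlap
    ex <- traj$exposure
    if (nrow(ex) > 1) {
      expect_true(all(abs(ex$start[-1] - ex$end[-nrow(ex)]) < 1e-9))
    }
  }
  # conservation: every individual is in exactly one exit category
  expect_equal(sum(exits == "death") + sum(exits == "age_cap"), nrow(pop))
})

test_that("zero composite CVD hazard yields no acute CVD events", {
  params <- mortality_only_params()
  for (seed in 1:10) {
    traj <- simulate_individual(test_individual(age = 70, cvd_history = "MI:1.00"),
                                scenario_config("usual", master_seed = seed),
                                params)
    expect_false(any(traj$events$type %in% c("TIA", "stroke", "MI", "angina")))
  }
})

test_that("after a first CVD event subsequent risks come from the secondary engine", {
  # primary engine gives zero risk; secondary gives a high risk. Seed a
  # prior-CVD individual: events can only arise through the secondary engine.
  params <- default_parameters(
    primary_engine = flat_engine("primary_cvd", 1),
    secondary_engine = flat_engine("secondary_cvd", 0.2), # ~2.2%/yr hazard
    diabetes_engine = flat_engine("diabetes", 1),
    hf_table = data.frame(age = c(0, 110), rate = c(0, 0)),
    treatment_effects = null_effects(),
    adherence_model = adherence_model(0.62, cessation_hazard = 0),
    adherence_rr = adherence_rr(1),
    life_table = flat_life_table(1e-12),
    baseline_gi_hazard = 0,
    case_fatality = case_fatality(stroke = c("<75" = 0, ">=75" = 0),
                                  mi = setNames(rep(0, 5), c("30-54", "55-64", "65-74", "75-84", "85+")))
  )
  n_events_noncvd <- 0L
  n_events_cvd <- 0L
  for (seed in 1:30) {
    t_non <- simulate_individual(test_individual(age = 60),
                                 scenario_config("usual", master_seed = seed), params)
    t_cvd <- simulate_individual(test_individual(age = 60, cvd_history = "MI:1.00"),
                                 scenario_config("usual", master_seed = seed), params)
    acute <- c("TIA", "stroke", "MI", "angina")
    non_first <- t_non$events$type[t_non$events$type %in% acute]
    n_events_cvd <- n_events_cvd + sum(t_cvd$events$type %in% acute)
    # a non-CVD individual can only get an acute event after a first one,
    # which the zero-risk primary engine never produces
    expect_length(non_first, 0)
  }
  expect_gt(n_events_cvd, 0)
})

test_that("common random numbers give identical arms in the null scenario", {
  pop <- apply_inclusion(generate_population(population_spec(n = 400, seed = 29)))
  oc <- run_scenarios(pop, null_params(), master_seed = 9)
  expect_identical(oc$outcomes$usual, oc$outcomes$polypill)
})
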