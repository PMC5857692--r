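test_that("the polypill price is the component aggregate unless overridden", {
  expect_equal(polypill_annual_cost(c(10, 20, 5, 5)), 40)
  expect_equal(polypill_annual_cost(c(17)), 17)
  expect_equal(polypill_annual_cost(c(10, 20, 5, 5), override = 25), 25)
  expect_error(polypill_annual_cost(c(-1, 5)))
})

test_that("point and flow discounting match closed forms and a numeric oracle", {
  expect_equal(discount_point(1000, 1, 0.035), 1000 / 1.035, tolerance = 1e-12)
  expect_equal(round(discount_point(1000, 1, 0.035), 2), 966.18)
  # flow of 100/yr for 10 years: closed form equals numerical integration
  oracle <- integrate(function(t) 100 * 1.035^(-t), 0, 10)$value
  expect_equal(discount_flow(100, 0, 10, 0.035), oracle, tolerance = 1e-8)
  expect_equal(discount_flow(100, 0, 10, 0.035),
               100 * (1 - 1.035^(-10)) / log(1.035), tolerance = 1e-12)
  # zero rate: plain duration product
  expect_equal(discount_flow(100, 0, 10, 0), 1000)
  # additivity over any split point
  for (s in c(0.1, 1, 5, 9.9)) {
    expect_equal(discount_flow(100, 0, 10, 0.035),
                 discount_flow(100, 0, s, 0.035) + discount_flow(100, s, 10, 0.035),
                 tolerance = 1e-9)
  }
})

test_that("zero-rate accrual equals the undiscounted sums exactly", {
  ev <- data.frame(time = c(1, 4), type = c("MI", "cessation"),
                   fatal = c(FALSE, FALSE), age = c(61, 64))
  ex <- data.frame(start = c(0, 4), end = c(4, 10),
                   on_treatment = c(TRUE, FALSE), adherent = c(TRUE, FALSE))
  traj <- stub_trajectory(ev, ex, exit = "death", exit_time = 10)
  costs <- cost_table()
  out <- accrue_costs(traj, costs, rate = 0)
  manual <- costs$acute[["MI"]] + costs$stopping +
    costs$state_annual[["MI"]] * 9 + # MI state cost from year 1 to exit
    (sum(costs$med_annual) + costs$monitoring_annual) * 4
  expect_equal(out$cost, unname(manual), tolerance = 1e-9)
  expect_equal(out$cost, out$cost_undiscounted, tolerance = 1e-9)
})

test_that("a single cost of 1000 at one year discounts to 966.18", {
  ev <- data.frame(time = 1, type = "MI", fatal = FALSE, age = 61)
  traj <- stub_trajectory(ev, exit_time = 1.0001)
  costs <- cost_table(acute = c(MI = 1000),
                      state_annual = c(MI = 0),
                      med_annual = c(statin = 0, aht = 0, aspirin = 0, acei = 0),
                      monitoring_annual = 0, stopping = 0)
  out <- accrue_costs(traj, costs, rate = 0.035)
  expect_equal(round(out$cost, 2), 966.18)
})

test_that("unit utility over a year at zero rate is exactly one QALY", {
  traj <- stub_trajectory(exit_time = 1, entry_age = 60)
  out <- accrue_qalys(traj, unit_utilities(), rate = 0)
  expect_equal(out$qalys, 1, tolerance = 1e-12)
})

test_that("ten years of unit utility at 3.5% equals the closed-form annuity", {
  traj <- stub_trajectory(exit_time = 10, entry_age = 60)
  out <- accrue_qalys(traj, unit_utilities(), rate = 0.035)
  expect_equal(out$qalys, (1 - 1.035^(-10)) / log(1.035), tolerance = 1e-9)
  expect_equal(out$qalys_undiscounted, 10, tolerance = 1e-12)
})

test_that("utility decrements add and floor at zero", {
  ev <- data.frame(time = c(1, 1), type = c("stroke", "heart_failure"),
                   fatal = c(FALSE, FALSE), age = c(61, 61))
  utils <- utility_table(
    baseline = data.frame(age = 0, male = 0.8, female = 0.8),
    decrements = c(stroke = 0.5, TIA = 0, MI = 0, angina = 0,
                   diabetes = 0, heart_failure = 0.4),
    transient = list(gi_bleed = c(decrement = 0, duration = 0),
                     cough_onset = c(decrement = 0, duration = 0))
  )
  traj <- stub_trajectory(ev, exit_time = 2, entry_age = 60)
  out <- accrue_qalys(traj, utils, rate = 0)
  # 0.8 for the first year, floored at 0 (0.8 - 0.9) afterwards
  expect_equal(out$qalys, 0.8, tolerance = 1e-9)
})

test_that("transient decrements last their configured duration", {
  ev <- data.frame(time = 1, type = "gi_bleed", fatal = FALSE, age = 61)
  utils <- utility_table(
    baseline = data.frame(age = 0, male = 1, female = 1),
    decrements = c(stroke = 0, TIA = 0, MI = 0, angina = 0, diabetes = 0,
                   heart_failure = 0),
    transient = list(gi_bleed = c(decrement = 0.5, duration = 0.5),
                     cough_onset = c(decrement = 0, duration = 0))
  )
  traj <- stub_trajectory(ev, exit_time = 3, entry_age = 60)
  out <- accrue_qalys(traj, utils, rate = 0)
  expect_equal(out$qalys, 3 - 0.5 * 0.5, tolerance = 1e-9)
})

test_that("discounting never increases totals and QALYs never exceed life years", {
  pop <- apply_inclusion(generate_population(population_spec(n = 200, seed = 31)))
  params <- polypillCEA:::prepare_parameters(default_parameters())
  for (i in seq_len(min(50, nrow(pop)))) {
    traj <- simulate_individual(as.list(pop[i, ]),
                                scenario_config("polypill", master_seed = 4),
                                params)
    o <- discounted_outcome(traj, params$costs, params$utilities, 0.035)
    expect_lte(o$cost, o$cost_undiscounted + 1e-9)
    expect_lte(o$qalys, o$qalys_undiscounted + 1e-9)
    expect_lte(o$qalys_undiscounted, traj$exit_time + 1e-9)
    expect_gte(o$qalys, 0)
  }
})

test_that("accrual is splice-invariant over trajectory partitions", {
  # accrual computed on a trajectory equals the sum over its two halves,
  # holding state (events before the cut stay active after it)
  ev <- data.frame(time = c(0.5, 2), type = c("MI", "gi_bleed"),
                   fatal = c(FALSE, FALSE), age = c(60.5, 62))
  ex <- data.frame(start = 0, end = 6, on_treatment = TRUE, adherent = TRUE)
  full <- stub_trajectory(ev, ex, exit_time = 6, entry_age = 60)
  costs <- cost_table(); utils <- utility_table(); rate <- 0.035
  o_full <- discounted_outcome(full, costs, utils, rate)
  cut <- 3
  # first half: truncate exposure and exit at the cut, drop the state flow after
  first <- stub_trajectory(ev, data.frame(start = 0, end = cut,
                                          on_treatment = TRUE, adherent = TRUE),
                           exit_time = cut, entry_age = 60)
  # second half: shift times so the cut is the new origin; re-declare the MI
  # state as active from time 0 with no fresh acute cost
  second_ev <- data.frame(time = 0, type = "MI", fatal = FALSE, age = 63)
  second <- stub_trajectory(second_ev,
                            data.frame(start = 0, end = 6 - cut,
                                       on_treatment = TRUE, adherent = TRUE),
                            exit_time = 6 - cut, entry_age = 63)
  costs_nofresh <- costs; costs_nofresh$acute[["MI"]] <- 0
  c1 <- accrue_costs(first, costs, rate)$cost
  c2 <- accrue_costs(second, costs_nofresh, rate)$cost
  disc <- (1 + rate)^(-cut)
  expect_equal(o_full$cost, c1 + disc * c2, tolerance = 1e-9)
  q1 <- accrue_qalys(first, utils, rate)$qalys
  q2 <- accrue_qalys(second, utils, rate)$qalys
  expect_equal(o_full$qalys, q1 + disc * q2, tolerance = 1e-9)
})

test_that("raising the polypill price raises polypill-arm cost and leaves QALYs unchanged", {
  pop <- apply_inclusion(generate_population(population_spec(n = 500, seed = 37)))
  base <- default_parameters()
  dear <- default_parameters(costs = cost_table(polypill_annual = 200))
  oc_base <- run_scenarios(pop, base, master_seed = 6)
  oc_dear <- run_scenarios(pop, dear, master_seed = 6)
  expect_gt(mean(oc_dear$outcomes$polypill$cost),
            mean(oc_base$outcomes$polypill$cost))
  expect_identical(oc_dear$outcomes$polypill$qalys,
                   oc_base$outcomes$polypill$qalys)
  # the usual-care arm never pays the polypill price
  expect_identical(oc_dear$outcomes$usual$cost, oc_base$outcomes$usual$cost)
})

test_that("negative event times are data errors", {
  ev <- data.frame(time = -1, type = "MI", fatal = FALSE, age = 59)
  expect_error(accrue_costs(stub_trajectory(ev), cost_table()), "negative")
})
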