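mk_outcomes <- function(usual_cost, usual_q, poly_cost, poly_q) {
  list(usual = data.frame(cost = usual_cost, qalys = usual_q),
       polypill = data.frame(cost = poly_cost, qalys = poly_q))
}

test_that("ICER, dominance labels and NMB follow the sign conventions", {
  r <- icer_and_nmb(mk_outcomes(0, 0, 1000, 0.1), wtp = 20000)
  expect_equal(r$icer, 10000)
  expect_equal(unname(r$nmb[[1]]), 20000 * 0.1 - 1000)
  expect_equal(unname(r$nmb[[1]]), 1000)

  dom <- icer_and_nmb(mk_outcomes(50, 0, 0, 0.2))
  expect_identical(dom$dominance, "dominant")
  expect_true(is.na(dom$icer)) # no ratio reported

  ddom <- icer_and_nmb(mk_outcomes(0, 0.2, 100, 0))
  expect_identical(ddom$dominance, "dominated")

  zero <- icer_and_nmb(mk_outcomes(10, 1, 10, 1))
  expect_true(is.na(zero$icer))
  expect_equal(unname(zero$nmb), c(0, 0)) # NMB still reported

  expect_error(icer_and_nmb(list(usual = data.frame(cost = 1, qalys = 1))),
               "both arms")
})

test_that("NMB is zero exactly at the ICER willingness-to-pay", {
  r <- icer_and_nmb(mk_outcomes(0, 0, 750, 0.05), wtp = 750 / 0.05)
  expect_equal(unname(r$nmb[[1]]), 0, tolerance = 1e-9)
})

test_that("scenario runs are reproducible bit-for-bit from the master seed", {
  pop <- apply_inclusion(generate_population(population_spec(n = 300, seed = 41)))
  oc1 <- run_scenarios(pop, default_parameters(), master_seed = 12)
  oc2 <- run_scenarios(pop, default_parameters(), master_seed = 12)
  expect_identical(oc1, oc2)
  oc3 <- run_scenarios(pop, default_parameters(), master_seed = 13)
  expect_false(identical(oc1$outcomes$usual$cost, oc3$outcomes$usual$cost))
})

test_that("degenerate PSA distributions without bootstrap reproduce the base case", {
  pop <- apply_inclusion(generate_population(population_spec(n = 300, seed = 43)))
  params <- default_parameters()
  fixed <- lapply(default_psa_distributions(),
                  function(e) { e$dist <- "fixed"; e })
  psa <- run_psa(pop, psa_spec(n_iterations = 4, distributions = fixed,
                               bootstrap = FALSE, master_seed = 3),
                 params)
  # every iteration identical (parameters fixed, same population) ...
  expect_equal(var(psa$cloud$delta_cost), 0)
  expect_equal(var(psa$cloud$delta_qalys), 0)
  # ... and equal to the base case run with the shared simulation stream
  base <- icer_and_nmb(run_scenarios(pop, params,
                                     master_seed = mix_seed(3, 4L, 7L)))
  expect_equal(psa$cloud$delta_cost[1], base$delta_cost, tolerance = 1e-9)
  expect_equal(psa$cloud$delta_qalys[1], base$delta_qalys, tolerance = 1e-9)
})

test_that("each bootstrap resample has the original population size", {
  pop <- apply_inclusion(generate_population(population_spec(n = 250, seed = 47)))
  psa <- run_psa(pop, psa_spec(n_iterations = 3, bootstrap = TRUE,
                               master_seed = 5), default_parameters())
  expect_true(all(psa$cloud$boot_n == nrow(pop)))
})

test_that("the acceptability curve is coherent with the cloud", {
  pop <- apply_inclusion(generate_population(population_spec(n = 200, seed = 53)))
  psa <- run_psa(pop, psa_spec(n_iterations = 12, master_seed = 11),
                 default_parameters(), wtp = seq(0, 40000, by = 10000))
  expect_true(all(psa$ceac$p_cost_effective >= 0 & psa$ceac$p_cost_effective <= 1))
  # CEAC is non-decreasing in willingness to pay when every iteration gains QALYs
  if (all(psa$cloud$delta_qalys > 0)) {
    expect_true(all(diff(psa$ceac$p_cost_effective) >= 0))
  }
  # the curve equals the positive-NMB fraction recomputed from the cloud
  manual <- vapply(psa$ceac$wtp, function(l)
    mean(l * psa$cloud$delta_qalys - psa$cloud$delta_cost > 0), numeric(1))
  expect_equal(psa$ceac$p_cost_effective, manual)
})

test_that("widening a parameter's uncertainty never shrinks the increment spread", {
  pop <- apply_inclusion(generate_population(population_spec(n = 150, seed = 59)))
  narrow <- list(list(path = c("costs", "acute"), dist = "gamma", cv = 0.1))
  wide <- list(list(path = c("costs", "acute"), dist = "gamma", cv = 0.2))
  p1 <- run_psa(pop, psa_spec(n_iterations = 40, distributions = narrow,
                              bootstrap = FALSE, master_seed = 8),
                default_parameters())
  p2 <- run_psa(pop, psa_spec(n_iterations = 40, distributions = wide,
                              bootstrap = FALSE, master_seed = 8),
                default_parameters())
  expect_gte(IQR(p2$cloud$delta_cost), IQR(p1$cloud$delta_cost))
})

test_that("convergence diagnostics follow the 1/sqrt(n) law and edge cases", {
  # constant stream: stable once the minimum iteration count is reached
  const <- data.frame(delta_cost = rep(5, 20), delta_qalys = rep(0.1, 20))
  chk <- convergence_check(const)
  expect_true(chk$stable)
  # iid stream: half-width shrinks like 1/sqrt(n)
  set.seed(71)
  x <- rnorm(6400, mean = 100, sd = 10)
  hw_n <- convergence_check(data.frame(v = x[1:400]))$columns$v$half_width
  hw_4n <- convergence_check(data.frame(v = x[1:1600]))$columns$v$half_width
  hw_16n <- convergence_check(data.frame(v = x))$columns$v$half_width
  expect_equal(hw_n / hw_4n, 2, tolerance = 0.25)
  expect_equal(hw_4n / hw_16n, 2, tolerance = 0.25)
  # zero tolerance can never be satisfied; flagged, not an infinite loop
  chk0 <- convergence_check(data.frame(v = x[1:100]), rel_tol = 0)
  expect_false(chk0$stable)
  expect_match(chk0$flag, "never")
  expect_error(convergence_check(data.frame(v = 1)), "at least 2")
})

test_that("run_cea wires population, scenarios and summary together", {
  res <- run_cea(n = 600, master_seed = 21)
  expect_s3_class(res, "cea_result")
  expect_true(res$delta_qalys > 0) # higher adherence with protective effects
  expect_identical(nrow(res$outcomes$outcomes$usual), nrow(res$population))
  expect_output(print(res), "increments")
  expect_named(summary(res), c("arm", "mean_cost", "mean_qalys"))
})
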