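test_that("generation is seed-deterministic and returns exactly n individuals", {
  spec <- population_spec(n = 100, seed = 42)
  p1 <- generate_population(spec)
  p2 <- generate_population(spec)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 100L)
  expect_false(anyNA(p1))
  # every covariate the risk engines need is present
  eng <- default_primary_engine()
  expect_true(all(eng$covariates %in% names(p1)))
  # a different seed changes the draw
  expect_false(identical(p1, generate_population(population_spec(n = 100, seed = 43))))
})

test_that("degenerate prevalences are honoured exactly", {
  p <- generate_population(population_spec(n = 500, seed = 1, p_cvd = 0))
  expect_true(all(p$cvd_history == ""))
  p2 <- generate_population(population_spec(n = 500, seed = 1, p_cvd = 1))
  expect_true(all(nzchar(p2$cvd_history)))
})

test_that("marginal moments recover the spec within Monte Carlo error", {
  spec <- population_spec(n = 10000, seed = 7)
  p <- generate_population(spec)
  # age is truncated to [35, 90]; compare against the truncated-normal mean
  # computed by numerical integration (independent oracle)
  a <- spec$age_range[1]; b <- spec$age_range[2]
  Z <- pnorm(b, spec$age_mean, spec$age_sd) - pnorm(a, spec$age_mean, spec$age_sd)
  true_mean <- integrate(function(x) x * dnorm(x, spec$age_mean, spec$age_sd) / Z,
                         a, b)$value
  se <- sd(p$age) / sqrt(nrow(p))
  expect_lt(abs(mean(p$age) - true_mean), 3 * se)
  # binary prevalences within 3 SE
  for (f in c("diabetes", "family_history_chd")) {
    ph <- mean(p[[f]])
    p0 <- spec[[if (f == "diabetes") "p_diabetes" else "p_family_history"]]
    expect_lt(abs(ph - p0), 3 * sqrt(p0 * (1 - p0) / nrow(p)))
  }
  # copula correlation approximately reproduced
  expect_lt(abs(cor(p$age, p$sbp) - spec$cor_age_sbp), 0.05)
})

test_that("invalid spec values are rejected naming the field", {
  expect_error(population_spec(n = 0), "n")
  expect_error(population_spec(p_cvd = 1.2), "p_cvd")
  expect_error(population_spec(age_sd = -1), "age_sd")
  expect_error(population_spec(p_smoking = c(non = 0.5, ex = 0.5, current = 0.5)),
               "p_smoking")
})

test_that("inclusion keeps adults at or above the risk threshold and all prior-CVD adults", {
  # engine with a 5-year horizon and no terms: everyone's 5-year risk is
  # exactly 1 - s0, so the threshold boundary is exact
  at_threshold <- flat_engine("incl", 0.85, horizon = 5) # risk = 0.15
  below <- flat_engine("incl", 0.8501, horizon = 5)      # risk = 0.1499
  inds <- as_pop(list(
    test_individual(age = 17, id = 1L),                       # minor
    test_individual(age = 60, id = 2L),                       # non-CVD
    test_individual(age = 60, cvd_history = "MI:3.00", id = 3L) # prior MI
  ))
  kept <- apply_inclusion(inds, at_threshold, threshold = 0.15)
  expect_identical(kept$id, c(2L, 3L)) # 17-year-old excluded regardless of risk
  kept2 <- apply_inclusion(inds, below, threshold = 0.15)
  expect_identical(kept2$id, 3L) # 0.1499 < 0.15 excluded; prior MI stays
})

test_that("a prior-CVD individual is included however low the engine risk", {
  never <- flat_engine("incl", 1, horizon = 5) # risk 0 for everyone
  inds <- as_pop(list(test_individual(age = 40, cvd_history = "MI:1.00", id = 1L)))
  expect_equal(nrow(apply_inclusion(inds, never)), 1L)
})

test_that("inclusion is idempotent, order-preserving and risk-bounded", {
  pop <- generate_population(population_spec(n = 2000, seed = 5))
  inc <- apply_inclusion(pop)
  inc2 <- apply_inclusion(inc)
  expect_equal(inc2$id, inc$id)
  expect_identical(inc$id, sort(inc$id)) # generation order preserved
  non_cvd <- inc[!nzchar(inc$cvd_history), ]
  expect_true(all(non_cvd$inclusion_risk5 >= 0.15))
  # complement check: no excluded non-CVD adult reaches the threshold
  out <- pop[!pop$id %in% inc$id & !nzchar(pop$cvd_history) & pop$age >= 18, ]
  if (nrow(out)) {
    r <- rescale_risk_horizon(
      1 - default_primary_engine()$baseline_survival ^
        exp(vapply(seq_len(nrow(out)), function(i) {
          polypillCEA:::linear_predictor(default_primary_engine(), out[i, ])
        }, numeric(1))), 10, 5)
    expect_true(all(r < 0.15))
  }
})

test_that("population CSV round-trips including serialised CVD histories", {
  pop <- generate_population(population_spec(n = 50, seed = 9, p_cvd = 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(as.data.frame(back), as.data.frame(pop), tolerance = 1e-12)
  h <- parse_cvd_history(pop$cvd_history[which(nzchar(pop$cvd_history))[1]])
  expect_true(all(h$type %in% c("TIA", "stroke", "MI", "angina")))
  expect_true(all(h$years_before_entry >= 0))
})

test_that("missing covariates surface as data errors naming the individual", {
  ind <- test_individual(id = 99L)
  ind$sbp <- NULL
  expect_error(primary_cvd_risk(ind), "sbp")
})
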