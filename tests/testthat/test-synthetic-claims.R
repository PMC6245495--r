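test_that("code group maps are surjective, total and deterministic", {
  maps <- build_code_group_maps(3000, 2000, 9000, seed = 1)
  expect_length(unique(maps$dx_map), 283L)
  expect_length(unique(maps$proc_map), 231L)
  expect_length(unique(maps$drug_map), 893L)
  # totality: every raw code carries exactly one group id
  expect_length(maps$dx_map, 3000L)
  expect_true(all(maps$dx_map >= 1 & maps$dx_map <= 283))
  expect_false(anyNA(maps$drug_map))
  # determinism
  maps2 <- build_code_group_maps(3000, 2000, 9000, seed = 1)
  expect_identical(maps, maps2)
  maps3 <- build_code_group_maps(3000, 2000, 9000, seed = 2)
  expect_false(identical(maps$dx_map, maps3$dx_map))
})

test_that("too few raw codes for the group vocabulary is an error", {
  expect_error(build_code_group_maps(282, 2000, 9000), "cannot cover")
  expect_error(build_code_group_maps(3000, 2000, 892), "cannot cover")
})

test_that("an empty population produces empty outputs", {
  panel <- simulate_population(generator_config(0, 12, seed = 1))
  expect_identical(nrow(panel$claims), 0L)
  expect_identical(nrow(panel$enrollment), 0L)
  expect_identical(nrow(panel$demographics), 0L)
})

test_that("identical configurations reproduce the panel exactly", {
  cfg <- generator_config(150, 8, seed = 99, rho = 0.6,
                          cohort_prevalences = c(asthma = 0.1))
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$claims, p2$claims)
  expect_identical(p1$enrollment, p2$enrollment)
  expect_identical(p1$demographics, p2$demographics)
  expect_identical(p1$ground_truth$latent_states,
                   p2$ground_truth$latent_states)
})

test_that("latent severity has the configured autocorrelation and variance", {
  cfg <- generator_config(2000, 24, seed = 3, rho = 0.9, sigma = 1,
                          mu_sd = 0)
  panel <- simulate_population(cfg)
  h <- panel$ground_truth$latent_states
  # pooled lag-1 sample autocorrelation of the emitted states
  acf1 <- cor(as.numeric(h[, -24]), as.numeric(h[, -1]))
  expect_lt(abs(acf1 - 0.9), 0.05)
  # stationary marginal variance within 10% of sigma^2
  expect_lt(abs(var(as.numeric(h)) - 1), 0.1)
})

test_that("zero inflation matches the configured rate", {
  cfg <- generator_config(5000, 4, seed = 4, zero_prob = 0.5)
  panel <- simulate_population(cfg)
  enr <- panel$ground_truth$enrolled == 1
  zero_frac <- mean(panel$ground_truth$monthly_cost[enr] == 0)
  expect_lt(abs(zero_frac - 0.5), 0.02)
})

test_that("claim paid amounts conserve the monthly expenditures exactly", {
  panel <- small_panel()
  expect_equal(sum(panel$claims$paid_amount),
               sum(panel$ground_truth$monthly_cost), tolerance = 1e-10)
  # and per patient-month
  by_pm <- tapply(panel$claims$paid_amount,
                  list(panel$claims$patient_id, panel$claims$month_index),
                  sum, default = 0)
  ids <- rownames(by_pm)
  truth <- panel$ground_truth$monthly_cost[
    match(ids, sprintf("P%06d", seq_len(panel$config$n_patients))), ]
  mismatch <- abs(by_pm - truth[, as.integer(colnames(by_pm)) + 1L])
  expect_lt(max(mismatch), 1e-8)
})

test_that("cohort prevalence is within binomial bounds and flags recoverable", {
  panel <- small_panel()
  flags <- panel$ground_truth$cohort_flags
  n <- nrow(flags)
  prev <- 0.12
  se <- sqrt(prev * (1 - prev) / n)
  expect_lt(abs(mean(flags$diabetes) - prev), 3 * se)
  # members emit reserved marker groups, so claims recover the flags
  pd <- small_period_data()
  enrolled_any <- unique(
    panel$enrollment$patient_id[panel$enrollment$enrolled == 1]
  )
  expect_setequal(
    select_cohort(pd, default_cohorts()$diabetes),
    intersect(flags$patient_id[flags$diabetes], enrolled_any)
  )
  expect_setequal(
    select_cohort(pd, default_cohorts()$copd),
    intersect(flags$patient_id[flags$copd], enrolled_any)
  )
})

test_that("planted linear regime yields an exactly recoverable signal", {
  beta <- planted_coefficients(n_active = 8, seed = 2)
  # n must exceed the number of occupied count columns for the noiseless
  # design to be identifiable
  cfg <- generator_config(
    2000, 8, seed = 6, regime = "planted_linear",
    planted_coefficients = beta, planted_noise_ratio = 0.02,
    enroll_gap_prob = 0, rho = 0, event_rate = 0.5
  )
  panel <- simulate_population(cfg)
  pt <- panel$ground_truth$planted
  expect_identical(pt$period_months, 4L)
  # OLS on the true design at near-zero noise recovers the actives
  X <- as.matrix(claimscast:::grouped_count_matrix(
    panel$claims, panel$maps, months = 0:3,
    patient_ids = sprintf("P%06d", 1:2000)
  ))
  keep <- which(colSums(X) > 0)
  fit <- fit_ols(X[, keep], pt$intercept + pt$signal + pt$noise)
  active <- intersect(which(beta != 0), keep)
  est <- fit$theta[match(active, keep)]
  expect_lt(max(abs(est - beta[active])), 0.05 * max(abs(beta)))
})

test_that("panel round-trips through the delimited text schema", {
  panel <- simulate_population(generator_config(40, 6, seed = 12))
  dir <- withr::local_tempdir()
  write_claims_panel(panel, dir)
  back <- read_claims_panel(dir)
  expect_equal(sum(back$claims$paid_amount), sum(panel$claims$paid_amount),
               tolerance = 1e-8)
  expect_identical(nrow(back$enrollment), nrow(panel$enrollment))
  expect_identical(sort(names(back$maps)), sort(names(panel$maps)))
  expect_identical(unname(back$maps$dx_map[names(panel$maps$dx_map)[1:5]]),
                   unname(panel$maps$dx_map[1:5]))
})
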