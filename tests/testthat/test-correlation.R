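test_that("pearson_on_percentiles handles exact and degenerate cases", {
  p <- (1:10) / 10
  expect_equal(pearson_on_percentiles(p, p), 1.0)
  expect_equal(pearson_on_percentiles(p, rev(p)), -1.0)
  expect_error(pearson_on_percentiles(c(0.1, 0.2), c(0.1, 0.2)),
               "at least 3")
  expect_error(pearson_on_percentiles(rep(0.5, 5), p[1:5]), "zero variance")
})

test_that("rank-percentile correlation matches the bivariate-normal form", {
  # Pearson on ranks of a Gaussian copula converges to (6/pi) asin(rho/2)
  rho <- 0.6
  n <- 8000
  z <- with_seed_test(123, {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    cbind(z1, z2)
  })
  r <- pearson_on_percentiles(
    claimscast:::rank_percentile(z[, 1]),
    claimscast:::rank_percentile(z[, 2])
  )
  expect_lt(abs(r - (6 / pi) * asin(rho / 2)), 0.03)
})

test_that("percentile correlation is invariant to monotone transforms", {
  x <- with_seed_test(5, rexp(500))
  y <- with_seed_test(6, 0.5 * x + rexp(500))
  r1 <- pearson_on_percentiles(claimscast:::rank_percentile(x),
                               claimscast:::rank_percentile(y))
  r2 <- pearson_on_percentiles(claimscast:::rank_percentile(log1p(x)),
                               claimscast:::rank_percentile(exp(y / 5)))
  expect_equal(r1, r2)
})

test_that("independent periods give near-zero correlation", {
  panel <- simulate_population(generator_config(
    3000, 6, seed = 8, rho = 0, mu_sd = 0, enroll_gap_prob = 0
  ))
  pd <- compute_objectives(aggregate_period(
    panel$claims, panel$enrollment, panel$demographics,
    period_grid(6, 3), panel$maps
  ))
  tab <- lagged_correlation_table(pd, 1)
  expect_lt(abs(tab$pearson_r), 0.03)
})

test_that("persistent severity gives correlations that decay with lag", {
  panel <- simulate_population(generator_config(
    3000, 15, seed = 9, rho = 0.9, enroll_gap_prob = 0
  ))
  pd <- compute_objectives(aggregate_period(
    panel$claims, panel$enrollment, panel$demographics,
    period_grid(15, 3), panel$maps
  ))
  tab <- lagged_correlation_table(pd, 1:3)
  expect_identical(nrow(tab), 3L)
  expect_gt(tab$pearson_r[1], 0.2)
  expect_gt(tab$pearson_r[1], tab$pearson_r[2] - 0.02)
  expect_gt(tab$pearson_r[2], tab$pearson_r[3] - 0.02)
  expect_gt(tab$pearson_r[1], tab$pearson_r[3])
})

test_that("unavailable lags are omitted with a warning", {
  pd <- small_period_data()  # 4 quarterly periods
  expect_warning(tab <- lagged_correlation_table(pd, c(1, 5)), "lag 5")
  expect_identical(tab$lag, 1L)
})

test_that("identical periods give r = 1 and full retention", {
  # the whole top decile is tied, so its follow-up percentile has zero sd
  spend <- c(seq(10, 170, by = 10), 200, 200, 200)
  fx_claims <- data.table::data.table(
    patient_id = rep(sprintf("Q%02d", 1:20), 2),
    month_index = rep(c(0L, 1L), each = 20),
    code_system = "dx",
    raw_code = names(build_code_group_maps(300, 250, 900, 1)$dx_map)[1],
    paid_amount = rep(spend, 2)
  )
  enrollment <- data.table::CJ(patient_id = sprintf("Q%02d", 1:20),
                               month_index = 0:1)
  enrollment$enrolled <- 1L
  demo <- data.table::data.table(
    patient_id = sprintf("Q%02d", 1:20), age = 30L, sex = "F",
    race = "White", disabled = 0L
  )
  maps <- build_code_group_maps(300, 250, 900, 1)
  pd <- compute_objectives(
    aggregate_period(fx_claims, enrollment, demo, period_grid(2, 1), maps)
  )
  tab <- lagged_correlation_table(pd, 1)
  expect_equal(tab$pearson_r, 1.0)
  pers <- top_decile_persistence(pd, 1, 2)
  expect_equal(pers$retention_pct, 100)
  expect_equal(pers$sd_followup_pctl, 0)
})

test_that("exchangeable periods retain about a tenth of the top decile", {
  panel <- simulate_population(generator_config(
    20000, 2, seed = 10, rho = 0, mu_sd = 0, enroll_gap_prob = 0,
    event_rate = 0.1
  ))
  pd <- compute_objectives(aggregate_period(
    panel$claims, panel$enrollment, panel$demographics,
    period_grid(2, 1), panel$maps
  ))
  pers <- top_decile_persistence(pd, 1, 2)
  expect_lt(abs(pers$retention_pct - 10), 1.5)
})

test_that("autocorrelated severity lifts retention above the null", {
  panel <- simulate_population(generator_config(
    5000, 6, seed = 11, rho = 0.9, enroll_gap_prob = 0
  ))
  pd <- compute_objectives(aggregate_period(
    panel$claims, panel$enrollment, panel$demographics,
    period_grid(6, 3), panel$maps
  ))
  pers <- top_decile_persistence(pd, 1, 2)
  # null retention is 10% with binomial sd ~ sqrt(.1*.9/500)*100 = 1.34
  expect_gt(pers$retention_pct, 10 + 3 * 1.35)
})
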