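means_df <- function(level, years, values) {
  structure(data.frame(adoption_level = level, followup_year = years,
                       mean = values, se = 0.1, scale = "arithmetic",
                       stringsAsFactors = FALSE),
            class = c("herd_trend_means", "data.frame"))
}

test_that("annual change is the OLS slope of marginal means on year", {
  m <- means_df("MEDIUM", 1:5, 10 + 2 * (1:5))
  expect_equal(annual_change_from_means(m), 2)
  expect_equal(annual_change_from_means(means_df("MEDIUM", 1:5,
                                                 rep(7, 5))), 0)
  set.seed(12)
  for (i in 1:10) {
    y <- rnorm(5)
    x <- 1:5
    slope_closed <- sum((x - mean(x)) * (y - mean(y))) /
      sum((x - mean(x))^2)
    expect_equal(annual_change_from_means(means_df("MEDIUM", x, y)),
                 slope_closed, tolerance = 1e-12)
  }
  expect_error(annual_change_from_means(means_df("MEDIUM", 1, 5)),
               "at least 2")
  expect_error(budget_inputs(horizon_years = 0), "positive")
})

test_that("cost lines reproduce the base-scenario arithmetic", {
  costs <- compute_costs(budget_inputs())
  expect_equal(unname(costs$lines["hardware"]), 140)
  expect_equal(unname(costs$lines["software"]), 140)
  expect_equal(unname(costs$lines["collection"]), 7.6 * 24.7)
  expect_equal(unname(costs$lines["entry"]), 15.2 * 24.7)
  expect_equal(costs$delta_cost, 5 * (280 + 7.6 * 24.7 + 15.2 * 24.7))

  ## labor scales with herd size, fixed investments do not
  c90 <- compute_costs(budget_inputs(herd_cows = 90))
  expect_equal(c90$delta_cost,
               5 * (140 + 140 + 0.9 * (187.72 + 375.44)),
               tolerance = 1e-9)
  c1 <- compute_costs(budget_inputs(horizon_years = 1))
  expect_equal(c1$delta_cost, costs$delta_cost / 5)
})

test_that("income accrues non-cumulatively per trait", {
  inc <- compute_income(budget_inputs())
  expect_equal(unname(inc$by_trait["DMY"]), 0.31 * 64.6 * 100 * 5)
  expect_equal(unname(inc$by_trait["DO"]), (-1.02) * (-2.15) * 100 * 5)
  expect_equal(inc$delta_income, sum(inc$by_trait))
  z <- budget_inputs(traits = data.frame(trait = "DMY", annual_change = 0,
                                         economic_value = 64.6))
  expect_equal(compute_income(z)$delta_income, 0)
})

test_that("budget identities hold for arbitrary inputs", {
  ev <- budget_evaluate(budget_inputs())
  expect_equal(ev$gross_margin, ev$delta_income - ev$delta_cost)
  expect_equal(ev$marginal_return_rate,
               100 * ev$gross_margin / ev$delta_cost)

  ## all changes zero: GM = -dC, MRR = -100%
  z <- budget_inputs(traits = data.frame(
    trait = c("DO", "DMY"), annual_change = c(0, 0),
    economic_value = c(-2.15, 64.6)))
  evz <- budget_evaluate(z)
  expect_equal(evz$gross_margin, -evz$delta_cost)
  expect_equal(evz$marginal_return_rate, -100)

  set.seed(5)
  for (i in 1:1000) {
    inp <- budget_inputs(
      horizon_years = sample(1:10, 1), herd_cows = runif(1, 5, 500),
      hardware_cost = runif(1, 0, 2000), software_cost = runif(1, 0, 2000),
      collection_days = runif(1, 0, 30), entry_days = runif(1, 0, 30),
      day_wage = runif(1, 5, 60),
      traits = data.frame(trait = c("DO", "DMY"),
                          annual_change = runif(2, -2, 2),
                          economic_value = runif(2, -100, 100)))
    ev <- budget_evaluate(inp)
    expect_equal(ev$gross_margin + ev$delta_cost - ev$delta_income, 0,
                 tolerance = 1e-9)
  }
})

test_that("gross margin is affine in herd size with the expected slope
           and intercept", {
  inp <- budget_inputs()
  gm_at <- function(h) {
    i <- inp; i$herd_cows <- h
    budget_evaluate(i)$gross_margin
  }
  tr <- inp$traits
  per_cow <- sum(tr$annual_change * tr$economic_value) -
    (7.6 * 24.7 + 15.2 * 24.7) / 100
  slope <- (gm_at(200) - gm_at(100)) / 100
  expect_equal(slope, per_cow * 5, tolerance = 1e-9)
  expect_equal(gm_at(100) - 100 * per_cow * 5, -5 * 280, tolerance = 1e-9)

  ## scaling wage up and days down leaves costs unchanged
  a <- compute_costs(budget_inputs(day_wage = 24.7 * 2,
                                   collection_days = 7.6 / 2,
                                   entry_days = 15.2 / 2))$delta_cost
  expect_equal(a, compute_costs(inp)$delta_cost)
})

test_that("break-even herd size matches a brute-force sweep", {
  inp <- budget_inputs()
  be <- break_even_herd_size(inp)
  sweep <- vapply(1:500, function(h) {
    i <- inp; i$herd_cows <- h
    budget_evaluate(i)$gross_margin
  }, numeric(1))
  expect_equal(be, which(sweep >= 0)[1])

  ## no fixed costs: every herd size at least breaks even
  free <- budget_inputs(hardware_cost = 0, software_cost = 0)
  expect_equal(break_even_herd_size(free), 1L)

  ## per-cow margin below labor cost: never breaks even
  never <- budget_inputs(traits = data.frame(
    trait = "DMY", annual_change = 0.01, economic_value = 10))
  expect_identical(break_even_herd_size(never), Inf)

  set.seed(99)
  for (i in 1:5) {
    inp2 <- budget_inputs(hardware_cost = runif(1, 100, 2000),
                          software_cost = runif(1, 100, 2000),
                          day_wage = runif(1, 10, 40))
    be2 <- break_even_herd_size(inp2)
    sweep2 <- vapply(1:2000, function(h) {
      j <- inp2; j$herd_cows <- h
      budget_evaluate(j)$gross_margin
    }, numeric(1))
    expect_equal(be2, which(sweep2 >= 0)[1])
  }
})
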