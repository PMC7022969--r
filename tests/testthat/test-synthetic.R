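test_that("degenerate config (no noise, no trend) reproduces baselines
           plus offsets exactly", {
  bl <- default_trait_baselines()
  bl$sd <- 0
  cfg <- sim_config(n_herds_per_level = c(2, 2, 2), followup_years = 5,
                    herd_size_sd = 0, trait_baselines = bl,
                    trends = flat_trends(),
                    level_offsets = flat_level_offsets(),
                    fixed_effects = zero_offsets(), seed = 4)
  st <- simulate_traits(cfg)
  for (tr in TRAITS) {
    vals <- st$traits$value[st$traits$trait == tr]
    expect_equal(vals, rep(bl$mean[bl$trait == tr], length(vals)),
                 tolerance = 1e-12)
  }
  ## with a level offset the shift is additive on the model scale
  lo <- flat_level_offsets()
  lo$DO <- c(LOW = -4, MEDIUM = 0, HIGH = 0)
  cfg2 <- sim_config(n_herds_per_level = c(2, 2, 2), followup_years = 5,
                     herd_size_sd = 0, trait_baselines = bl,
                     trends = flat_trends(), level_offsets = lo,
                     fixed_effects = zero_offsets(), seed = 4)
  st2 <- simulate_traits(cfg2)
  low_do <- st2$traits$value[st2$traits$trait == "DO" &
                               st2$traits$herd_id %in%
                               st2$herds$herd_id[st2$herds$level == "LOW"]]
  expect_equal(unique(low_do), 100.6 - 4, tolerance = 1e-12)
})

test_that("within-herd deviations carry the configured AR(1) correlation", {
  cfg <- sim_config(n_herds_per_level = c(450, 450, 450),
                    followup_years = 8, rho_within = 0.8, seed = 14)
  st <- simulate_traits(cfg)
  e <- st$truth$expectations
  e <- e[e$trait == "AFC", ]
  e <- e[order(e$herd_id, e$followup_year), ]
  wide <- matrix(e$ar1, ncol = 8, byrow = TRUE)
  lag1 <- cor(as.vector(wide[, 1:7]), as.vector(wide[, 2:8]))
  expect_lt(abs(lag1 - 0.8), 0.03)
})

test_that("default-config population mean of daily milk yield matches the
           emulated population", {
  cfg <- sim_config(n_herds_per_level = c(167, 167, 166), seed = 9)
  st <- simulate_traits(cfg)
  dmy <- st$traits[st$traits$trait == "DMY", ]
  herd_means <- tapply(dmy$value, dmy$herd_id, mean)
  se <- sd(herd_means) / sqrt(length(herd_means))
  expect_lt(abs(mean(herd_means) - 16.7), 2 * se + 1e-9)
  ## and the default configuration passes its own invariants
  expect_s3_class(default_config(), "sim_config")
  expect_equal(default_config()$trait_baselines$mean[1], 31.3)
  expect_equal(default_config()$trait_baselines$mean[2], 100.6)
})

test_that("same seed reproduces byte-identical output, different seeds differ", {
  cfg <- sim_config(n_herds_per_level = c(3, 3, 3), followup_years = 5,
                    herd_size_mean = 12, herd_size_sd = 3, seed = 5)
  a <- simulate_events(cfg)
  b <- simulate_events(cfg)
  expect_identical(a$events, b$events)
  expect_identical(simulate_traits(cfg)$traits, simulate_traits(cfg)$traits)
  cfg2 <- sim_config(n_herds_per_level = c(3, 3, 3), followup_years = 5,
                     herd_size_mean = 12, herd_size_sd = 3, seed = 6)
  c_ <- simulate_events(cfg2)
  expect_false(identical(a$events$event_date, c_$events$event_date))
})

test_that("record availability follows the adoption-level pattern", {
  cfg <- sim_config(n_herds_per_level = c(4, 4, 4), followup_years = 5,
                    herd_size_mean = 15, herd_size_sd = 4, seed = 2)
  st <- simulate_traits(cfg)
  herds <- st$herds
  lv <- function(l) herds$herd_id[herds$level == l]
  tt <- st$traits
  expect_true(all(tt$trait[tt$herd_id %in% lv("LOW")] %in% c("AFC", "DO")))
  expect_true(all(tt$trait[tt$herd_id %in% lv("MEDIUM")] %in%
                    c("AFC", "DO", "DMY", "PL")))
  expect_setequal(unique(tt$trait[tt$herd_id %in% lv("HIGH")]), TRAITS)

  sim <- simulate_events(cfg)
  ev <- sim$events
  expect_false(any(ev$event_type[ev$herd_id %in% lv("LOW")] %in%
                     c("MILK_WEIGH", "CULL", "MASTITIS", "LAMENESS")))
  expect_false(any(ev$event_type[ev$herd_id %in% lv("MEDIUM")] %in%
                     c("MASTITIS", "LAMENESS")))

  ## positivity: multiplicative traits strictly positive, others
  ## truncated at zero
  expect_true(all(tt$value[tt$trait %in% c("MAST", "LAM")] > 0))
  expect_true(all(tt$value >= 0))
})

test_that("zero configured incidence suppresses health events entirely", {
  cfg <- sim_config(n_herds_per_level = c(0, 0, 4), followup_years = 5,
                    herd_size_mean = 20, herd_size_sd = 0,
                    mast_incidence = 0, seed = 8)
  sim <- simulate_events(cfg)
  expect_false(any(sim$events$event_type == "MASTITIS"))
  expect_true(any(sim$events$event_type == "LAMENESS"))
})
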