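make_sim <- function(n = c(20, 20, 20), years = 6, rho = 0.6, seed = 77,
                     ...) {
  cfg <- sim_config(n_herds_per_level = n, followup_years = years,
                    rho_within = rho, fixed_effects = zero_offsets(),
                    seed = seed, ...)
  simulate_traits(cfg)
}

test_that("design coding: interaction columns, log transform, full rank", {
  st <- make_sim(n = c(10, 10, 10), years = 10, seed = 1)
  des <- build_design(st$traits, st$truth$herds, "DO",
                      factors = character(0), interaction = TRUE)
  ## (3-1) x (10-1) interaction columns
  expect_equal(sum(des$assign == 3L), 18L)
  expect_equal(ncol(des$X), 1 + 2 + 9 + 18)
  expect_equal(qr(des$X)$rank, ncol(des$X))

  ## default synthetic population with every nuisance factor: still full
  ## column rank after coding
  cfg <- sim_config(n_herds_per_level = c(25, 25, 25), followup_years = 8,
                    seed = 31)
  st2 <- simulate_traits(cfg)
  des2 <- build_design(st2$traits, st2$truth$herds, "AFC")
  expect_equal(length(des2$dropped), 0L)
  expect_equal(qr(des2$X)$rank, ncol(des2$X))

  ## lognormal response with a zero: offset applied before the log
  d0 <- st$traits[st$traits$trait == "DO", ]
  tt <- d0[d0$herd_id %in% unique(d0$herd_id)[c(1:6, 11:16)] &
             d0$followup_year <= 3, ]           # spans two adoption levels
  tt$trait <- "MAST"
  tt$value <- c(0, rep(5, nrow(tt) - 1L))
  des3 <- build_design(tt, st$truth$herds, "MAST", factors = character(0),
                       log_offset = 0.5)
  expect_equal(sort(unique(des3$y))[1], log(0.5))

  ## a single-level factor is an error naming the factor
  one_lv <- st$traits
  one_lv$herd_size_class <- 2L
  expect_error(build_design(one_lv, st$truth$herds, "DO",
                            factors = "herd_size"),
               "herd_size.*single observed level")
})

test_that("null variance components are recovered near zero", {
  cfg <- sim_config(n_herds_per_level = c(25, 25, 25), followup_years = 6,
                    between_frac = 0, rho_within = 0,
                    fixed_effects = zero_offsets(), seed = 19)
  st <- simulate_traits(cfg)
  fit <- herd_trend(st$traits, st$truth$herds, "DMY",
                    factors = character(0))
  se_b <- fit$wald_random$se[1]
  se_r <- fit$wald_random$se[3]
  tot <- fit$sigma2_between + fit$sigma2_within
  expect_lt(fit$sigma2_between,
            if (is.finite(se_b)) 2 * se_b + 1e-8 else 0.05 * tot)
  expect_lt(abs(fit$rho),
            if (is.finite(se_r)) 2 * se_r + 0.02 else 0.1)
})

test_that("without AR(1), follow-up estimates equal OLS on herd-demeaned
           data (balanced design)", {
  st <- make_sim(rho = 0, seed = 77)
  fit <- herd_trend(st$traits, st$truth$herds, "DO",
                    factors = character(0), interaction = FALSE,
                    ar1 = FALSE)
  dd <- st$traits[st$traits$trait == "DO", ]
  dd$ydem <- dd$value - ave(dd$value, dd$herd_id)
  dd$followup <- factor(dd$followup_year)
  ols <- lm(ydem ~ followup, dd)
  fy <- grep("^followup", names(coef(fit)), value = TRUE)
  expect_equal(unname(coef(fit)[fy]), unname(coef(ols)[fy]),
               tolerance = 1e-8)
})

test_that("REML estimates agree with the independent nlme oracle", {
  skip_if_not_installed("nlme")
  st <- make_sim(n = c(25, 25, 25), years = 8, seed = 11)
  herds <- st$truth$herds
  fit <- herd_trend(st$traits, herds, "DO", factors = "herd_size")
  d <- st$traits[st$traits$trait == "DO", ]
  idx <- match(d$herd_id, herds$herd_id)
  d$adoption <- factor(herds$level[idx], c("LOW", "MEDIUM", "HIGH"))
  d$followup <- factor(d$followup_year)
  d$herd_size <- factor(d$herd_size_class, sort(unique(d$herd_size_class)))
  lf <- nlme::lme(value ~ herd_size + adoption * followup,
                  random = ~ 1 | herd_id,
                  correlation = nlme::corAR1(form = ~ followup_year |
                                               herd_id),
                  data = d, method = "REML")
  vc <- suppressWarnings(as.numeric(nlme::VarCorr(lf)[, 1]))
  rho_nlme <- as.numeric(stats::coef(lf$modelStruct$corStruct,
                                     unconstrained = FALSE))
  ## no degradation: our optimum is at least as good as the oracle's
  expect_gte(fit$loglik, as.numeric(stats::logLik(lf)) - 1e-4)
  expect_equal(fit$sigma2_between, vc[1], tolerance = 0.01)
  expect_equal(fit$sigma2_within, vc[2], tolerance = 0.01)
  expect_equal(fit$rho, rho_nlme, tolerance = 0.01)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-4)
  b_nlme <- nlme::fixef(lf)[names(coef(fit))]
  expect_equal(unname(coef(fit)), unname(b_nlme), tolerance = 1e-3)
  se_nlme <- sqrt(diag(stats::vcov(lf)))[names(coef(fit))]
  expect_equal(unname(sqrt(diag(fit$vcov))), unname(se_nlme),
               tolerance = 0.02)
})

test_that("marginal means: saturated cells, invariances and geometric
           back-transform", {
  st <- make_sim(seed = 77)
  herds <- st$truth$herds
  d <- st$traits
  ## saturated adoption x followup model, balanced: cells = sample means
  fit <- herd_trend(d, herds, "DO", factors = character(0))
  mm <- marginal_means(fit)
  dd <- d[d$trait == "DO", ]
  dd$lv <- herds$level[match(dd$herd_id, herds$herd_id)]
  cm <- aggregate(value ~ lv + followup_year, dd, mean)
  key <- paste(cm$lv, cm$followup_year)
  expect_equal(mm$mean,
               cm$value[match(paste(mm$adoption_level, mm$followup_year),
                              key)], tolerance = 1e-8)
  expect_true(all(mm$se >= 0))

  ## invariant to input row order
  fit_shuf <- herd_trend(d[rev(seq_len(nrow(d))), ], herds, "DO",
                         factors = character(0))
  expect_equal(marginal_means(fit_shuf)$mean, mm$mean, tolerance = 1e-8)

  ## near-zero noise: marginal means equal the generating cell expectations
  bl <- default_trait_baselines()
  bl$sd <- 0.05
  cfg0 <- sim_config(n_herds_per_level = c(3, 3, 3), followup_years = 5,
                     herd_size_sd = 0, trait_baselines = bl,
                     level_offsets = flat_level_offsets(),
                     fixed_effects = zero_offsets(), seed = 6)
  st0 <- simulate_traits(cfg0)
  f0 <- herd_trend(st0$traits, st0$truth$herds, "DO",
                   factors = character(0))
  mm0 <- marginal_means(f0)
  exp0 <- st0$truth$expectations
  exp0 <- exp0[exp0$trait == "DO", ]
  truth_cell <- aggregate(mu_fixed ~ level + followup_year, exp0, mean)
  k0 <- paste(truth_cell$level, truth_cell$followup_year)
  expect_equal(mm0$mean,
               truth_cell$mu_fixed[match(paste(mm0$adoption_level,
                                               mm0$followup_year), k0)],
               tolerance = 0.01)

  ## lognormal: geometric cell means never exceed arithmetic raw means
  cfgH <- sim_config(n_herds_per_level = c(0, 0, 30), followup_years = 6,
                     seed = 5)
  stH <- simulate_traits(cfgH)
  fH <- herd_trend(stH$traits, stH$truth$herds, "MAST",
                   factors = character(0), drop_single = TRUE)
  mmH <- marginal_means(fH)
  expect_true(all(mmH$scale == "geometric"))
  dH <- stH$traits[stH$traits$trait == "MAST", ]
  am <- aggregate(value ~ followup_year, dH, mean)
  expect_true(all(mmH$mean <= am$value[match(mmH$followup_year,
                                             am$followup_year)] + 1e-9))
})

test_that("effect table flags injected adoption effects and covers all
           model effects", {
  lo <- flat_level_offsets()
  lo$AFC <- c(LOW = 0, MEDIUM = 3, HIGH = 3)   # strong AFC level effect
  cfg <- sim_config(n_herds_per_level = c(25, 25, 25), followup_years = 6,
                    trends = flat_trends(), level_offsets = lo,
                    fixed_effects = zero_offsets(), seed = 23)
  st <- simulate_traits(cfg)
  fits <- list(
    AFC = herd_trend(st$traits, st$truth$herds, "AFC",
                     factors = character(0), interaction = FALSE),
    DMY = herd_trend(st$traits, st$truth$herds, "DMY",
                     factors = character(0), interaction = FALSE)
  )
  tab <- effect_table(fits)
  p_afc <- tab$AFC[tab$effect == "adoption"]
  p_dmy <- tab$DMY[tab$effect == "adoption"]
  expect_lt(p_afc, 0.01)
  expect_gt(p_dmy, 0.01)
  expect_true(all(c("adoption", "followup", "between_herd_variance",
                    "within_herd_variance") %in% tab$effect))
  expect_true(all(tab$AFC >= 0 & tab$AFC <= 1))
})

test_that("fitted-model methods are coherent", {
  st <- make_sim(n = c(8, 8, 8), years = 5, seed = 3)
  fit <- herd_trend(st$traits, st$truth$herds, "DMY",
                    factors = character(0))
  expect_equal(length(fitted(fit)), fit$n)
  expect_equal(fitted(fit) + residuals(fit), fit$design$y)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(unname(predict(fit)[1]), fitted(fit)[1])
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n, 3L))
  ## simulated values center on the fitted mean
  expect_lt(abs(mean(as.matrix(sims)) - mean(fitted(fit))),
            3 * sqrt(fit$sigma2_between + fit$sigma2_within) /
              sqrt(fit$n * 3) * 5)
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("Random components", out)))
})
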