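fmap_for <- function(herd, years) {
  data.frame(herd_id = herd, calendar_year = years,
             followup_year = seq_along(years), stringsAsFactors = FALSE)
}

test_that("single-animal trait arithmetic matches hand calculation", {
  ev <- event_table(
    rep("h1", 2), rep("c1", 2),
    as.Date(c("2000-01-01", "2002-06-01")), c("BIRTH", "CALVING"),
    parity = c(NA, 1L))
  tr <- derive_traits(ev, fmap_for("h1", 2000:2005))
  afc <- tr[tr$trait == "AFC", ]
  expect_equal(afc$calendar_year, 2002)
  expect_equal(afc$value, 882 / 30.4375, tolerance = 1e-12)
  expect_equal(afc$n_units, 1L)

  ## birth-to-first-calving of 940 days, the generator's anchoring
  ev2 <- event_table(
    rep("h1", 2), rep("c2", 2),
    as.Date("2001-03-15") + c(0, 940), c("BIRTH", "CALVING"),
    parity = c(NA, 1L))
  tr2 <- derive_traits(ev2, fmap_for("h1", 2001:2006))
  expect_equal(tr2$value[tr2$trait == "AFC"], 940 / 30.4375,
               tolerance = 1e-12)

  ## days open from calving to confirmed conception, indexed by the
  ## conception year
  ev3 <- event_table(
    rep("h1", 2), rep("c3", 2),
    as.Date(c("2003-11-20", "2004-02-10")), c("CALVING", "CONCEPTION"),
    parity = c(2L, NA))
  tr3 <- derive_traits(ev3, fmap_for("h1", 2003:2008))
  do_row <- tr3[tr3$trait == "DO", ]
  expect_equal(do_row$calendar_year, 2004)
  expect_equal(do_row$value, 82)

  ## productive life from first calving to cull
  ev4 <- event_table(
    rep("h1", 2), rep("c4", 2),
    as.Date(c("2001-05-01", "2005-05-01")), c("CALVING", "CULL"),
    parity = c(1L, NA))
  tr4 <- derive_traits(ev4, fmap_for("h1", 2001:2006))
  expect_equal(tr4$value[tr4$trait == "PL"], 1461 / 365.25)
})

test_that("incidence traits are lactation percentages, invariant to
           duplicating every lactation", {
  mk <- function(dup) {
    rows <- list()
    for (d in seq_len(dup)) {
      for (i in 1:4) {
        id <- sprintf("cow%d_%d", i, d)
        rows[[length(rows) + 1L]] <- data.frame(
          herd_id = "h1", animal_id = id,
          event_date = as.Date("2005-03-01") + i, event_type = "CALVING",
          value = NA_real_, parity = 1L)
        if (i == 1) {
          rows[[length(rows) + 1L]] <- data.frame(
            herd_id = "h1", animal_id = id,
            event_date = as.Date("2005-06-01"), event_type = "MASTITIS",
            value = NA_real_, parity = NA_integer_)
        }
      }
    }
    tab <- do.call(rbind, rows)
    event_table(tab$herd_id, tab$animal_id, tab$event_date,
                tab$event_type, tab$value, tab$parity)
  }
  t1 <- derive_traits(mk(1), fmap_for("h1", 2005:2009))
  expect_equal(t1$value[t1$trait == "MAST"], 25)
  expect_equal(t1$n_units[t1$trait == "MAST"], 4L)
  t2 <- derive_traits(mk(3), fmap_for("h1", 2005:2009))
  expect_equal(t2$value[t2$trait == "MAST"], 25)
})

test_that("herd-size classes and calendar periods bin correctly", {
  expect_equal(herd_size_class(c(34, 120, 55, 5, 19, 20, 69, 70, 99, 100)),
               c(2L, 5L, 3L, 1L, 1L, 2L, 3L, 4L, 4L, 5L))
  expect_equal(calendar_period(c(1985, 1990, 1991, 1995, 1996, 2000, 2001,
                                 2005, 2006, 2010, 2011, 2020)),
               c("<=1990", "<=1990", "1991-1995", "1991-1995", "1996-2000",
                 "1996-2000", "2001-2005", "2001-2005", "2006-2010",
                 "2006-2010", ">=2010", ">=2010"))
})

test_that("cut-offs remove and log exactly the rows outside the limits", {
  tab <- data.frame(herd_id = "h1", calendar_year = 2001L,
                    followup_year = 1L,
                    trait = c("AFC", "AFC", "DO"), value = c(80, 30, 95),
                    n_units = 3L, herd_size_class = 2L,
                    calendar_period = "2001-2005",
                    stringsAsFactors = FALSE)
  lim <- data.frame(trait = "AFC", min = 18, max = 60)
  res <- apply_cutoffs(tab, lim)
  expect_equal(nrow(res$table), 2L)
  expect_equal(res$removed$value, 80)
  expect_equal(res$removed$reason, "above_max")
  ## empty limits: identity
  res0 <- apply_cutoffs(tab, NULL)
  expect_identical(res0$table, tab)
  expect_error(apply_cutoffs(tab, data.frame(trait = "AFC", min = 5,
                                             max = 5)), "malformed")

  ## normal-tail oracle: mean +/- 4 SD trims the expected tiny fraction
  set.seed(8)
  big <- tab[rep(1, 10000), ]
  big$trait <- "DMY"
  big$value <- rnorm(10000, 16.7, 4.5)
  lim4 <- default_cutoffs()[default_cutoffs()$trait == "DMY", ]
  res4 <- apply_cutoffs(big, lim4)
  outside <- sum(big$value < lim4$min | big$value > lim4$max)
  expect_equal(nrow(res4$removed), outside)
  expect_lt(nrow(res4$removed) / 10000, 0.002)
})

test_that("derived traits from simulated events track the simulated truth", {
  cfg <- sim_config(n_herds_per_level = c(4, 4, 4), followup_years = 5,
                    herd_size_mean = 60, herd_size_sd = 0, seed = 3)
  sim <- simulate_events(cfg)
  herds <- sim$truth$herds
  fmap <- do.call(rbind, lapply(seq_len(nrow(herds)), function(i) {
    fmap_for(herds$herd_id[i],
             herds$first_followup_year[i] + 0:(cfg$followup_years - 1))
  }))
  der <- derive_traits(sim$events, fmap)
  truth <- sim$truth$expectations
  m <- merge(der, truth[, c("herd_id", "calendar_year", "trait", "value")],
             by = c("herd_id", "calendar_year", "trait"),
             suffixes = c("_derived", "_truth"))
  expect_gte(nrow(m), 240)   # 12 herds x 5 years x level-dependent traits
  for (tr in c("AFC", "DO", "DMY", "PL")) {
    sub <- m[m$trait == tr, ]
    expect_gt(cor(sub$value_derived, sub$value_truth), 0.9)
  }

  ## DO bookkeeping: n_units sums to the conception events inside windows
  conc <- sim$events[sim$events$event_type == "CONCEPTION", ]
  conc_year <- as.integer(format(conc$event_date, "%Y"))
  inside <- paste(conc$herd_id, conc_year) %in%
    paste(fmap$herd_id, fmap$calendar_year)
  expect_equal(sum(der$n_units[der$trait == "DO"]), sum(inside))

  ## each animal's first calving contributes to AFC exactly once
  expect_equal(sum(der$n_units[der$trait == "AFC"]),
               length(unique(sim$events$animal_id[
                 sim$events$event_type == "BIRTH"])))
})
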