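## Synthetic herd-event generator.
##
## Emulates the statistical structure of a national dairy recording
## database: herd-year trait means/SDs, adoption-level-dependent record
## availability, linear follow-up-year trends per adoption level,
## between-herd heterogeneity, and within-herd AR(1) serial correlation.
## Incidence traits (MAST, LAM) are generated multiplicatively so their
## logs follow the same additive structure as the normal traits.

#' Default trait baselines
#'
#' Herd-year means and standard deviations of the six performance traits in
#' the emulated population: age at first calving (months), days open (days),
#' daily milk yield (kg), productive life (years), and clinical mastitis and
#' lameness incidence (percent of lactations).
#'
#' @return A `data.frame` with columns `trait`, `mean`, `sd`.
#' @export
default_trait_baselines <- function() {
  data.frame(
    trait = TRAITS,
    mean = c(31.3, 100.6, 16.7, 4.02, 10.9, 17.9),
    sd = c(4.8, 16.1, 4.5, 1.45, 10.7, 17.4),
    stringsAsFactors = FALSE
  )
}

## Per-level linear trend ramps: total change in trait units (log units for
## MAST/LAM) accrued linearly from follow-up year 1 to `span`, flat after.
default_trends <- function() {
  trend <- function(low, medium, high, span_low = 10, span_medium = 10,
                    span_high = 10) {
    data.frame(level = c("LOW", "MEDIUM", "HIGH"),
               total = c(low, medium, high),
               span = c(span_low, span_medium, span_high),
               stringsAsFactors = FALSE)
  }
  list(
    ## AFC: medium/high drop 2 and 1 months over the first 4 years; low
    ## herds end higher (~33.4 months after 10 years).
    AFC = trend(2.1, -2, -1, 10, 4, 4),
    ## DO: drops of ~5 d (medium/high) and ~7 d (low) over the period.
    DO = trend(-7, -5, -5),
    ## DMY: rises of ~1 kg (low/medium) and ~2 kg (high).
    DMY = trend(1, 1, 2),
    ## PL: rises ~1 year, mainly over years 1-8.
    PL = trend(1, 1, 1, 8, 8, 8),
    ## MAST fluctuates without a systematic trend (log scale).
    MAST = trend(0, 0, 0),
    ## LAM: low/medium decline from ~10% to ~4% (log scale); high flat.
    LAM = trend(log(0.4), log(0.4), 0)
  )
}

## Adoption-level offsets on the model scale (log scale for MAST/LAM).
## Reference is the level whose records actually carry the trait baseline.
default_level_offsets <- function() {
  list(
    AFC = c(LOW = 0, MEDIUM = 0, HIGH = 0),
    ## Low-adoption herds run shorter days open throughout.
    DO = c(LOW = -4, MEDIUM = 0, HIGH = 0),
    DMY = c(LOW = 0, MEDIUM = 0, HIGH = 0),
    PL = c(LOW = 0, MEDIUM = 0, HIGH = 0),
    ## Health incidence is higher in high-adoption herds (better detection);
    ## only high-adoption herds record it, so HIGH is the reference.
    MAST = c(LOW = -0.6, MEDIUM = -0.6, HIGH = 0),
    LAM = c(LOW = -0.5, MEDIUM = -0.5, HIGH = 0)
  )
}

## Traits recorded at each adoption level.
LEVEL_TRAITS <- list(
  LOW = c("AFC", "DO"),
  MEDIUM = c("AFC", "DO", "DMY", "PL"),
  HIGH = TRAITS
)

LOGNORMAL_TRAITS <- c("MAST", "LAM")

#' Build a synthetic-herd simulation configuration
#'
#' All arguments have defaults describing the emulated study population:
#' herd counts by adoption level, 34-cow average herds, trait baselines of
#' [default_trait_baselines()], per-level linear trend ramps, an equal split
#' of each trait's total SD into between-herd and within-herd components,
#' and within-herd AR(1) correlation 0.6.
#'
#' @param n_herds_per_level integer vector `(low, medium, high)`.
#' @param followup_years follow-up span per herd, 5-10 years.
#' @param herd_size_mean,herd_size_sd lognormal herd-size parameters (cows);
#'   sizes are truncated at a minimum of 5 cows.
#' @param trait_baselines data frame `trait, mean, sd` on the natural scale.
#' @param trends per-trait data frames `level, total, span`: the trait drifts
#'   linearly by `total` units (log units for MAST/LAM) from follow-up year
#'   1 to year `span`, then stays flat.
#' @param level_offsets per-trait named vectors of adoption-level offsets on
#'   the model scale.
#' @param between_frac fraction of each trait's total variance assigned to
#'   the between-herd component (the rest is the within-herd AR(1) process).
#' @param rho_within AR(1) correlation of successive herd-year deviations,
#'   in (-1, 1).
#' @param sigma_residual per-trait iid residual SD on the model scale added
#'   on top of the AR(1) process; default 0 for all traits (the within-herd
#'   noise is the serial process itself).
#' @param fixed_effects list with named numeric vectors `zone` and `breed`:
#'   offsets in units of the trait's total SD applied on the model scale.
#' @param zone_probs,breed_probs sampling probabilities for herd zone and
#'   predominant breed.
#' @param first_year_range calendar-year range from which each herd's first
#'   follow-up year is drawn.
#' @param cow_level list of animal-level event parameters used by
#'   [simulate_events()]: `weighings_per_cow_year`, `conception_frac`,
#'   `first_calver_frac`, `cull_frac`, and individual-animal SDs
#'   `sd_afc` (months), `sd_do` (days), `sd_dmy` (kg), `sd_pl` (years).
#' @param mast_incidence,lam_incidence optional overrides for the health
#'   baselines (percent); `0` suppresses the corresponding events entirely.
#' @param seed integer RNG seed; simulation output is a pure function of the
#'   configuration.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_herds_per_level = c(low = 389, medium = 343,
                                             high = 180),
                       followup_years = 10,
                       herd_size_mean = 34, herd_size_sd = 25,
                       trait_baselines = default_trait_baselines(),
                       trends = default_trends(),
                       level_offsets = default_level_offsets(),
                       between_frac = 0.5,
                       rho_within = 0.6,
                       sigma_residual = c(AFC = 0, DO = 0, DMY = 0, PL = 0,
                                          MAST = 0, LAM = 0),
                       fixed_effects = list(
                         zone = c(HF_TROPICAL = 0, HF_LOW_MONTANE = 0.1,
                                  HF_PREMONTANE = -0.1, VHF_TROPICAL = 0.05,
                                  VHF_LOW_MONTANE = 0.15,
                                  VHF_PREMONTANE = -0.05,
                                  RF_PREMONTANE = 0.2),
                         breed = c(HOLSTEIN = 0, JERSEY = -0.2,
                                   HOLSTEIN_X_JERSEY = -0.1,
                                   DAIRY_CROSS = 0.05,
                                   DAIRY_X_BOS_INDICUS = 0.15, OTHER = 0.1)),
                       zone_probs = c(0.25, 0.2, 0.15, 0.15, 0.1, 0.1, 0.05),
                       breed_probs = c(0.35, 0.2, 0.2, 0.1, 0.1, 0.05),
                       first_year_range = c(1988, 2008),
                       cow_level = list(weighings_per_cow_year = 8,
                                        conception_frac = 0.85,
                                        first_calver_frac = 0.25,
                                        cull_frac = 0.15,
                                        sd_afc = 2.5, sd_do = 8,
                                        sd_dmy = 2.5, sd_pl = 0.8),
                       mast_incidence = NULL, lam_incidence = NULL,
                       seed = 1L) {
  if (length(n_herds_per_level) != 3L || any(n_herds_per_level < 0)) {
    stop("n_herds_per_level must be three non-negative counts (low, medium, high)")
  }
  names(n_herds_per_level) <- c("low", "medium", "high")
  if (followup_years < 5 || followup_years > 10) {
    stop("followup_years must be in [5, 10]")
  }
  if (herd_size_mean <= 0 || herd_size_sd < 0) {
    stop("herd_size_mean must be positive and herd_size_sd non-negative")
  }
  stopifnot(all(TRAITS %in% trait_baselines$trait))
  if (any(trait_baselines$sd < 0) || any(trait_baselines$mean <= 0)) {
    stop("trait baselines must have positive means and non-negative SDs")
  }
  if (abs(rho_within) >= 1) stop("rho_within must lie in (-1, 1)")
  if (between_frac < 0 || between_frac > 1) {
    stop("between_frac must lie in [0, 1]")
  }
  if (!is.null(mast_incidence)) {
    trait_baselines$mean[trait_baselines$trait == "MAST"] <-
      max(mast_incidence, 1e-8)
    if (mast_incidence == 0) trait_baselines$sd[trait_baselines$trait == "MAST"] <- 0
  }
  if (!is.null(lam_incidence)) {
    trait_baselines$mean[trait_baselines$trait == "LAM"] <-
      max(lam_incidence, 1e-8)
    if (lam_incidence == 0) trait_baselines$sd[trait_baselines$trait == "LAM"] <- 0
  }
  structure(list(
    n_herds_per_level = n_herds_per_level,
    followup_years = as.integer(followup_years),
    herd_size_mean = herd_size_mean, herd_size_sd = herd_size_sd,
    trait_baselines = trait_baselines, trends = trends,
    level_offsets = level_offsets, between_frac = between_frac,
    rho_within = rho_within, sigma_residual = sigma_residual,
    fixed_effects = fixed_effects, zone_probs = zone_probs,
    breed_probs = breed_probs, first_year_range = first_year_range,
    cow_level = cow_level,
    mast_zero = !is.null(mast_incidence) && mast_incidence == 0,
    lam_zero = !is.null(lam_incidence) && lam_incidence == 0,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_config <- function(seed = 1L) sim_config(seed = seed)

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic herd simulation configuration\n")
  cat(sprintf("  herds (low/medium/high): %d/%d/%d, %d follow-up years\n",
              x$n_herds_per_level[1], x$n_herds_per_level[2],
              x$n_herds_per_level[3], x$followup_years))
  cat(sprintf("  herd size ~ lognormal(mean %.0f, sd %.0f), min 5 cows\n",
              x$herd_size_mean, x$herd_size_sd))
  cat(sprintf("  between-herd variance fraction %.2f, AR(1) rho %.2f, seed %d\n",
              x$between_frac, x$rho_within, x$seed))
  invisible(x)
}

## Evaluate an expression with a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Model-scale parameters per trait: intercept, SD components. For the
## multiplicative traits the intercept is the log-scale mean that makes the
## arithmetic mean of the lognormal equal the configured baseline given the
## configured total log-scale SD.
trait_scale_params <- function(config) {
  bl <- config$trait_baselines
  out <- data.frame(trait = bl$trait, baseline = bl$mean, sd_total = bl$sd,
                    stringsAsFactors = FALSE)
  out$model_intercept <- out$baseline
  out$model_sd <- out$sd_total
  for (i in seq_len(nrow(out))) {
    if (out$trait[i] %in% LOGNORMAL_TRAITS) {
      m <- out$baseline[i]; s <- out$sd_total[i]
      sdlog2 <- log(1 + (s / m)^2)
      out$model_sd[i] <- sqrt(sdlog2)
      out$model_intercept[i] <- log(m) - sdlog2 / 2
    }
  }
  out$sd_between <- sqrt(config$between_frac) * out$model_sd
  out$sd_within <- sqrt(1 - config$between_frac) * out$model_sd
  rownames(out) <- out$trait
  out
}

trend_at <- function(trend_row, fy) {
  span <- max(trend_row$span, 2)
  trend_row$total * pmin(fy - 1, span - 1) / (span - 1)
}

## Draw the herd population and all herd-year model-scale expectations.
## Consumes RNG; callers wrap in with_seed().
sim_population <- function(config) {
  n <- config$n_herds_per_level
  H <- sum(n)
  if (H == 0L) stop("no herds configured")
  level <- rep(c("LOW", "MEDIUM", "HIGH"), times = n)
  herd_id <- sprintf("H%04d", seq_len(H))
  sizes <- draw_herd_sizes(H, config$herd_size_mean, config$herd_size_sd)
  zone <- sample(ZONES, H, replace = TRUE, prob = config$zone_probs)
  breed <- sample(BREED_GROUPS, H, replace = TRUE, prob = config$breed_probs)
  first_year <- sample(seq(config$first_year_range[1],
                           config$first_year_range[2]), H, replace = TRUE)
  herds <- data.frame(herd_id = herd_id, level = level, n_cows = sizes,
                      zone = zone, breed_group = breed,
                      first_followup_year = first_year,
                      stringsAsFactors = FALSE)

  sp <- trait_scale_params(config)
  Tn <- config$followup_years
  rho <- config$rho_within

  exp_list <- vector("list", length(TRAITS))
  eff_list <- vector("list", length(TRAITS))
  for (k in seq_along(TRAITS)) {
    tr <- TRAITS[k]
    b <- stats::rnorm(H, 0, sp[tr, "sd_between"])
    ## AR(1) path per herd, stationary marginal SD = sd_within
    sw <- sp[tr, "sd_within"]
    e <- matrix(0, H, Tn)
    e[, 1] <- stats::rnorm(H, 0, sw)
    if (Tn > 1) {
      innov_sd <- sw * sqrt(1 - rho^2)
      for (t in 2:Tn) e[, t] <- rho * e[, t - 1] + stats::rnorm(H, 0, innov_sd)
    }
    resid_sd <- config$sigma_residual[[tr]]
    if (is.null(resid_sd) || is.na(resid_sd)) resid_sd <- 0
    r <- if (resid_sd > 0) matrix(stats::rnorm(H * Tn, 0, resid_sd), H, Tn)
         else matrix(0, H, Tn)

    zoff <- config$fixed_effects$zone[herds$zone] * sp[tr, "model_sd"]
    boff <- config$fixed_effects$breed[herds$breed_group] * sp[tr, "model_sd"]
    loff <- config$level_offsets[[tr]][herds$level]
    trrows <- config$trends[[tr]]
    fy <- seq_len(Tn)
    mu_fixed <- matrix(0, H, Tn)
    for (lv in c("LOW", "MEDIUM", "HIGH")) {
      idx <- herds$level == lv
      if (!any(idx)) next
      tl <- trrows[trrows$level == lv, , drop = FALSE]
      ## centered ramp: the configured baseline is the mean over the whole
      ## follow-up span, the trend redistributes it across years
      ramp <- trend_at(tl, fy)
      ramp <- ramp - mean(ramp)
      mu_fixed[idx, ] <- matrix(rep(ramp, each = sum(idx)), sum(idx), Tn)
    }
    mu_fixed <- mu_fixed + sp[tr, "model_intercept"] + zoff + boff + loff

    value_model <- mu_fixed + b + e + r
    df <- data.frame(
      herd_id = rep(herds$herd_id, Tn),
      level = rep(herds$level, Tn),
      followup_year = rep(fy, each = H),
      calendar_year = rep(herds$first_followup_year, Tn) +
        rep(fy, each = H) - 1L,
      trait = tr,
      mu_fixed = as.vector(mu_fixed),
      herd_effect = rep(b, Tn),
      ar1 = as.vector(e),
      value_model = as.vector(value_model),
      stringsAsFactors = FALSE
    )
    df$value <- if (tr %in% LOGNORMAL_TRAITS) {
      pmin(exp(df$value_model), 100)
    } else {
      pmax(df$value_model, 0)
    }
    exp_list[[k]] <- df
    eff_list[[k]] <- data.frame(herd_id = herds$herd_id, trait = tr,
                                herd_effect = b, stringsAsFactors = FALSE)
  }
  expectations <- do.call(rbind, exp_list)
  expectations <- expectations[order(expectations$herd_id,
                                     expectations$trait,
                                     expectations$followup_year), ]
  rownames(expectations) <- NULL
  list(herds = herds, expectations = expectations,
       herd_effects = do.call(rbind, eff_list))
}

draw_herd_sizes <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(5L, round(mean)), n))
  sdlog2 <- log(1 + (sd / mean)^2)
  sizes <- round(stats::rlnorm(n, log(mean) - sdlog2 / 2, sqrt(sdlog2)))
  pmax(sizes, 5L)
}

#' Simulate herd-year trait values directly
#'
#' Draws, for every configured herd and follow-up year, the model-scale
#' trait expectation (baseline + zone/breed offsets + adoption-level offset
#' + linear trend ramp + herd random effect + AR(1) within-herd deviation),
#' back-transforms MAST/LAM by exponentiation, and emits rows only for the
#' trait domains the herd's adoption level records.
#'
#' @param config a [sim_config()] object.
#' @return A list with components `traits` (herd-year trait table with
#'   columns `herd_id, calendar_year, followup_year, trait, value, n_units,
#'   herd_size_class, calendar_period`), `truth` (realized herd effects and
#'   herd-year expectations plus the generating config), and `herds` (herd
#'   metadata including adoption level and size).
#' @export
simulate_traits <- function(config) {
  pop <- with_seed(config$seed, sim_population(config))
  herds <- pop$herds
  exps <- pop$expectations
  keep <- mapply(function(tr, lv) tr %in% LEVEL_TRAITS[[lv]],
                 exps$trait, exps$level)
  tab <- exps[keep, c("herd_id", "calendar_year", "followup_year",
                      "trait", "value")]
  ncows <- herds$n_cows[match(tab$herd_id, herds$herd_id)]
  cl <- config$cow_level
  units <- ifelse(tab$trait == "AFC",
                  pmax(1, round(cl$first_calver_frac * ncows)),
           ifelse(tab$trait == "DO",
                  pmax(1, round(cl$conception_frac * ncows)),
           ifelse(tab$trait == "DMY", cl$weighings_per_cow_year * ncows,
           ifelse(tab$trait == "PL",
                  pmax(1, round(cl$cull_frac * ncows)), ncows))))
  tab$n_units <- as.integer(units)
  tab$herd_size_class <- herd_size_class(ncows)
  tab$calendar_period <- calendar_period(tab$calendar_year)
  rownames(tab) <- NULL
  truth <- list(herds = herds, herd_effects = pop$herd_effects,
                expectations = exps, config = config)
  list(traits = tab, truth = truth, herds = herds)
}

#' Simulate animal-level event streams
#'
#' Emits per-animal event histories consistent with the herd-year trait
#' expectations of [simulate_traits()]: first calvings anchored to births
#' give AFC, calving-to-conception intervals give DO, daily weighings
#' average to DMY, cull dates back-anchor first calvings for PL, and
#' mastitis/lameness flags are drawn per lactation at the herd-year target
#' incidence. Events are present only for the record domains the herd's
#' adoption level keeps (reproductive; + productive; + health).
#'
#' @param config a [sim_config()] object.
#' @return A list with `events` (event table), `herds` (herd metadata in
#'   [herd_meta()] layout), `truth` (as in [simulate_traits()]).
#' @export
simulate_events <- function(config) {
  with_seed(config$seed, {
    pop <- sim_population(config)
    herds <- pop$herds
    exps <- pop$expectations
    cl <- config$cow_level
    ## quick lookup: expectations by herd/trait -> vector over followup years
    Tn <- config$followup_years
    target <- function(h, tr) {
      v <- exps$value[exps$herd_id == h & exps$trait == tr]
      v[order(exps$followup_year[exps$herd_id == h & exps$trait == tr])]
    }
    pieces <- vector("list", nrow(herds) * Tn * 4L)
    np <- 0L
    add <- function(df) {
      np <<- np + 1L
      pieces[[np]] <<- df
    }
    rdate <- function(year, n) {
      as.Date(sprintf("%d-01-01", year)) + floor(stats::runif(n) * 365)
    }
    for (i in seq_len(nrow(herds))) {
      h <- herds$herd_id[i]
      lv <- herds$level[i]
      n <- herds$n_cows[i]
      y0 <- herds$first_followup_year[i]
      tg <- sapply(TRAITS, function(tr) target(h, tr))  # Tn x 6
      has_prod <- lv %in% c("MEDIUM", "HIGH")
      has_health <- lv == "HIGH"
      prod_ids <- sprintf("%s-C%03d", h, seq_len(n))
      health_roll <- function(calv_df) {
        ## Bernoulli health flags per lactation at the calving-year target
        if (!has_health || nrow(calv_df) == 0L) return(NULL)
        yrs <- as.integer(format(calv_df$event_date, "%Y"))
        fy <- yrs - y0 + 1L
        inside <- fy >= 1L & fy <= Tn
        out <- list()
        for (tr in c("MAST", "LAM")) {
          if ((tr == "MAST" && isTRUE(config$mast_zero)) ||
              (tr == "LAM" && isTRUE(config$lam_zero))) next
          p <- rep(0, nrow(calv_df))
          p[inside] <- pmin(tg[fy[inside], tr] / 100, 1)
          hit <- stats::runif(nrow(calv_df)) < p
          if (any(hit)) {
            out[[tr]] <- data.frame(
              herd_id = h, animal_id = calv_df$animal_id[hit],
              event_date = calv_df$event_date[hit] +
                5 + floor(stats::runif(sum(hit)) * 180),
              event_type = if (tr == "MAST") "MASTITIS" else "LAMENESS",
              value = NA_real_, parity = NA_integer_,
              stringsAsFactors = FALSE)
          }
        }
        if (length(out)) do.call(rbind, out) else NULL
      }
      for (fy in seq_len(Tn)) {
        y <- y0 + fy - 1L
        ## -- production cohort: one calving per cow per year
        calv <- data.frame(
          herd_id = h, animal_id = prod_ids, event_date = rdate(y, n),
          event_type = "CALVING", value = NA_real_, parity = fy,
          stringsAsFactors = FALSE)
        add(calv)
        ## conceptions: days open drawn around the herd-year target
        k_do <- max(1L, round(cl$conception_frac * n))
        who <- sample.int(n, k_do)
        do_i <- pmax(21, stats::rnorm(k_do, tg[fy, "DO"], cl$sd_do))
        add(data.frame(
          herd_id = h, animal_id = prod_ids[who],
          event_date = calv$event_date[who] + round(do_i),
          event_type = "CONCEPTION", value = NA_real_,
          parity = NA_integer_, stringsAsFactors = FALSE))
        ## -- first calvers: birth anchored at calving - AFC
        k_afc <- max(1L, round(cl$first_calver_frac * n))
        afc_ids <- sprintf("%s-A%d-%02d", h, y, seq_len(k_afc))
        afc_i <- pmax(18, stats::rnorm(k_afc, tg[fy, "AFC"], cl$sd_afc))
        afc_calv_date <- rdate(y, k_afc)
        afc_calv <- data.frame(
          herd_id = h, animal_id = afc_ids, event_date = afc_calv_date,
          event_type = "CALVING", value = NA_real_, parity = 1L,
          stringsAsFactors = FALSE)
        add(data.frame(
          herd_id = h, animal_id = afc_ids,
          event_date = afc_calv_date - round(afc_i * DAYS_PER_MONTH),
          event_type = "BIRTH", value = NA_real_, parity = NA_integer_,
          stringsAsFactors = FALSE))
        add(afc_calv)
        hr <- health_roll(rbind(calv, afc_calv))
        if (!is.null(hr)) add(hr)
        if (has_prod) {
          ## -- daily weighings
          w <- cl$weighings_per_cow_year
          add(data.frame(
            herd_id = h, animal_id = rep(prod_ids, each = w),
            event_date = rdate(y, n * w),
            event_type = "MILK_WEIGH",
            value = pmax(0.5, stats::rnorm(n * w, tg[fy, "DMY"], cl$sd_dmy)),
            parity = NA_integer_, stringsAsFactors = FALSE))
          ## -- culls: first calving back-anchored at cull - PL
          k_pl <- max(1L, round(cl$cull_frac * n))
          pl_ids <- sprintf("%s-P%d-%02d", h, y, seq_len(k_pl))
          pl_i <- pmax(0.5, stats::rnorm(k_pl, tg[fy, "PL"], cl$sd_pl))
          cull_date <- rdate(y, k_pl)
          pl_calv <- data.frame(
            herd_id = h, animal_id = pl_ids,
            event_date = cull_date - round(pl_i * DAYS_PER_YEAR),
            event_type = "CALVING", value = NA_real_, parity = 1L,
            stringsAsFactors = FALSE)
          add(pl_calv)
          add(data.frame(
            herd_id = h, animal_id = pl_ids, event_date = cull_date,
            event_type = "CULL", value = NA_real_, parity = NA_integer_,
            stringsAsFactors = FALSE))
          hr <- health_roll(pl_calv)
          if (!is.null(hr)) add(hr)
        }
      }
    }
    events <- do.call(rbind, pieces[seq_len(np)])
    events <- events[order(events$herd_id, events$animal_id,
                           events$event_date), ]
    rownames(events) <- NULL
    meta <- herd_meta(herds$herd_id, herds$zone, herds$breed_group,
                      herds$first_followup_year)
    truth <- list(herds = herds, herd_effects = pop$herd_effects,
                  expectations = exps, config = config)
    list(events = events, herds = meta, truth = truth)
  })
}
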