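## Derivation of the six herd-year performance traits from event records.
##
## All traits are herd-year averages over the animals/lactations/weighings
## observed that calendar year:
##   AFC  months from birth to first calving, over first calvings that year
##   DO   days from calving to confirmed conception, over conceptions that
##        year (indexed by the conception year)
##   DMY  mean kg over all daily individual weighings that year
##   PL   years from first calving to culling, over culls that year
##   MAST/LAM  percent of lactations started that year with >=1 event;
##        a health event belongs to the most recent preceding calving

#' Herd-size class
#'
#' Classifies the number of cows in production: 1 = 5-19, 2 = 20-39,
#' 3 = 40-69, 4 = 70-99, 5 = 100 or more. Herds below 5 cows fall in
#' class 1 (the population of interest starts at 5 cows).
#'
#' @param n_cows positive integer vector.
#' @return Integer classes 1-5.
#' @export
herd_size_class <- function(n_cows) {
  stopifnot(all(n_cows >= 1))
  as.integer(cut(n_cows, breaks = c(-Inf, 20, 40, 70, 100, Inf),
                 labels = FALSE, right = FALSE))
}

CALENDAR_PERIODS <- c("<=1990", "1991-1995", "1996-2000", "2001-2005",
                      "2006-2010", ">=2010")

#' Calendar-period bin
#'
#' Five-year calendar periods used as a fixed effect: `<=1990`,
#' `1991-1995`, `1996-2000`, `2001-2005`, `2006-2010` and `>=2010`
#' (which, following the source labelling, holds the years from 2011 on;
#' 2010 itself belongs to `2006-2010`).
#'
#' @param year integer calendar years.
#' @return Character vector of period labels.
#' @export
calendar_period <- function(year) {
  CALENDAR_PERIODS[findInterval(year, c(-Inf, 1991, 1996, 2001, 2006, 2011))]
}

## Last-observation-carried-forward anchor: rows must be sorted by
## (animal, date); anchor rows are those of `anchor_type`. Returns, for each
## row, the row index of the most recent anchor of the same animal at or
## before it (NA if none).
locf_anchor <- function(animal, is_anchor) {
  idx <- seq_along(animal)
  pos <- ifelse(is_anchor, idx, 0L)
  filled <- cummax(pos)
  out <- ifelse(filled > 0L, filled, NA_integer_)
  bad <- !is.na(out) & animal[out] != animal
  out[bad] <- NA_integer_
  out
}

group_mean <- function(key, value) {
  s <- rowsum(value, key)
  n <- rowsum(rep(1, length(key)), key)
  data.frame(key = rownames(s), value = s[, 1] / n[, 1],
             n_units = as.integer(n[, 1]), stringsAsFactors = FALSE)
}

#' Derive herd-year performance traits from events
#'
#' Computes the six performance traits for every herd-year inside the
#' follow-up map, with one output row per herd x calendar year x derivable
#' trait. When adoption profiles are supplied, traits are restricted to the
#' record domains the herd's level keeps (low: AFC/DO; medium: + DMY/PL;
#' high: + MAST/LAM); otherwise every trait with observed source events is
#' emitted.
#'
#' @param events an event table (see [event_table()]).
#' @param followup_map output of [select_followup()].
#' @param profiles optional output of [classify_adoption()].
#' @return A herd-year trait table: `herd_id, calendar_year, followup_year,
#'   trait, value, n_units, herd_size_class, calendar_period`.
#' @export
derive_traits <- function(events, followup_map, profiles = NULL) {
  ev <- events[order(events$herd_id, events$animal_id, events$event_date), ]
  yr <- as.integer(format(ev$event_date, "%Y"))
  akey <- paste(ev$herd_id, ev$animal_id, sep = "\r")
  dnum <- as.numeric(ev$event_date)
  in_map <- function(h, y) paste(h, y, sep = "\r") %in%
    paste(followup_map$herd_id, followup_map$calendar_year, sep = "\r")

  res <- list()
  emit <- function(trait, herd, year, value, n_units) {
    keep <- in_map(herd, year)
    if (!any(keep)) return()
    res[[length(res) + 1L]] <<- data.frame(
      herd_id = herd[keep], calendar_year = year[keep], trait = trait,
      value = value[keep], n_units = n_units[keep],
      stringsAsFactors = FALSE)
  }
  split_key <- function(key) {
    parts <- strsplit(key, "\r", fixed = TRUE)
    list(herd = vapply(parts, `[[`, "", 1L),
         year = as.integer(vapply(parts, `[[`, "", 2L)))
  }

  ## --- AFC: animals with both a BIRTH and a first CALVING
  is_birth <- ev$event_type == "BIRTH"
  is_calv <- ev$event_type == "CALVING"
  if (any(is_birth) && any(is_calv)) {
    birth <- tapply(dnum[is_birth], akey[is_birth], min)
    fcalv <- tapply(dnum[is_calv], akey[is_calv], min)
    common <- intersect(names(birth), names(fcalv))
    if (length(common) > 0L) {
      afc <- (fcalv[common] - birth[common]) / DAYS_PER_MONTH
      herd <- ev$herd_id[match(common, akey)]
      year <- as.integer(format(as.Date(fcalv[common],
                                        origin = "1970-01-01"), "%Y"))
      g <- group_mean(paste(herd, year, sep = "\r"), afc)
      sk <- split_key(g$key)
      emit("AFC", sk$herd, sk$year, g$value, g$n_units)
    }
  }

  ## --- DO: conception minus most recent preceding calving
  if (any(ev$event_type == "CONCEPTION") && any(is_calv)) {
    sub <- which(is_calv | ev$event_type == "CONCEPTION")
    anchor <- locf_anchor(akey[sub], is_calv[sub])
    conc <- which(ev$event_type[sub] == "CONCEPTION" & !is.na(anchor))
    if (length(conc) > 0L) {
      i <- sub[conc]
      do_days <- dnum[i] - dnum[sub[anchor[conc]]]
      ok <- do_days >= 0
      i <- i[ok]; do_days <- do_days[ok]
      g <- group_mean(paste(ev$herd_id[i], yr[i], sep = "\r"), do_days)
      sk <- split_key(g$key)
      emit("DO", sk$herd, sk$year, g$value, g$n_units)
    }
  }

  ## --- DMY: mean over all weighings
  mw <- which(ev$event_type == "MILK_WEIGH" & !is.na(ev$value))
  if (length(mw) > 0L) {
    g <- group_mean(paste(ev$herd_id[mw], yr[mw], sep = "\r"), ev$value[mw])
    sk <- split_key(g$key)
    emit("DMY", sk$herd, sk$year, g$value, g$n_units)
  }

  ## --- PL: cull minus the animal's first calving
  cull <- which(ev$event_type == "CULL")
  if (length(cull) > 0L && any(is_calv)) {
    fcalv <- tapply(dnum[is_calv], akey[is_calv], min)
    fc <- fcalv[akey[cull]]
    ok <- !is.na(fc) & dnum[cull] >= fc
    if (any(ok)) {
      i <- cull[ok]
      pl <- (dnum[i] - fc[ok]) / DAYS_PER_YEAR
      g <- group_mean(paste(ev$herd_id[i], yr[i], sep = "\r"), pl)
      sk <- split_key(g$key)
      emit("PL", sk$herd, sk$year, g$value, g$n_units)
    }
  }

  ## --- MAST / LAM: lactation-level flags
  for (tr in c("MAST", "LAM")) {
    etype <- if (tr == "MAST") "MASTITIS" else "LAMENESS"
    if (!any(is_calv)) next
    has_events <- tapply(ev$event_type == etype, ev$herd_id, any)
    herds_tr <- names(has_events)[has_events]
    if (is.null(profiles) && length(herds_tr) == 0L) next
    sub <- which(is_calv | ev$event_type == etype)
    anchor <- locf_anchor(akey[sub], is_calv[sub])
    hit_anchor <- anchor[ev$event_type[sub] == etype]
    hit_anchor <- unique(hit_anchor[!is.na(hit_anchor)])
    flagged <- rep(FALSE, length(sub))
    flagged[hit_anchor] <- TRUE
    calv_rows <- which(is_calv[sub])
    i <- sub[calv_rows]
    g <- group_mean(paste(ev$herd_id[i], yr[i], sep = "\r"),
                    100 * as.numeric(flagged[calv_rows]))
    sk <- split_key(g$key)
    if (is.null(profiles)) {
      keep <- sk$herd %in% herds_tr
      emit(tr, sk$herd[keep], sk$year[keep], g$value[keep], g$n_units[keep])
    } else {
      emit(tr, sk$herd, sk$year, g$value, g$n_units)
    }
  }

  if (length(res) == 0L) {
    out <- data.frame(herd_id = character(), calendar_year = integer(),
                      trait = character(), value = numeric(),
                      n_units = integer(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, res)
  }

  ## restrict traits to the herd's adoption-level domains
  if (!is.null(profiles) && nrow(out) > 0L) {
    lv <- profiles$level[match(out$herd_id, profiles$herd_id)]
    lv[is.na(lv)] <- "EXCLUDED"
    allowed <- mapply(function(tr, l) {
      !is.na(l) && l %in% names(LEVEL_TRAITS) && tr %in% LEVEL_TRAITS[[l]]
    }, out$trait, lv)
    out <- out[allowed, , drop = FALSE]
  }

  ## herd size in production per herd-year: distinct cows with >=1
  ## CALVING, CONCEPTION or MILK_WEIGH event that year
  prod_ev <- which(ev$event_type %in% c("CALVING", "CONCEPTION",
                                        "MILK_WEIGH"))
  sizes <- tapply(akey[prod_ev],
                  paste(ev$herd_id[prod_ev], yr[prod_ev], sep = "\r"),
                  function(a) length(unique(a)))
  out$followup_year <- followup_map$followup_year[
    match(paste(out$herd_id, out$calendar_year, sep = "\r"),
          paste(followup_map$herd_id, followup_map$calendar_year, sep = "\r"))]
  n_prod <- sizes[paste(out$herd_id, out$calendar_year, sep = "\r")]
  n_prod[is.na(n_prod)] <- 1
  out$herd_size_class <- herd_size_class(pmax(1, as.integer(n_prod)))
  out$calendar_period <- calendar_period(out$calendar_year)
  out <- out[order(out$herd_id, out$trait, out$calendar_year),
             c("herd_id", "calendar_year", "followup_year", "trait",
               "value", "n_units", "herd_size_class", "calendar_period")]
  rownames(out) <- NULL
  out
}

#' Default trait cut-off limits
#'
#' The analysis trims extreme herd-year values before modelling. The study
#' limits are not published; the package default is mean +/- `k` SD of the
#' population baselines, a conservative trim that preserves the population
#' moments.
#'
#' @param baselines data frame `trait, mean, sd`.
#' @param k half-width in SD units (default 4).
#' @return A `data.frame` with columns `trait, min, max`.
#' @export
default_cutoffs <- function(baselines = default_trait_baselines(), k = 4) {
  data.frame(trait = baselines$trait,
             min = baselines$mean - k * baselines$sd,
             max = baselines$mean + k * baselines$sd,
             stringsAsFactors = FALSE)
}

#' Apply min/max cut-offs to a trait table
#'
#' Removes (never mutates) herd-year rows outside the configured per-trait
#' limits and logs each removal.
#'
#' @param table a herd-year trait table.
#' @param limits data frame `trait, min, max`; traits absent from `limits`
#'   are kept untouched.
#' @return A list with `table` (filtered) and `removed` (the removal log
#'   with a `reason` column).
#' @export
apply_cutoffs <- function(table, limits = default_cutoffs()) {
  if (is.null(limits) || nrow(limits) == 0L) {
    return(list(table = table, removed = table[0, , drop = FALSE]))
  }
  if (any(limits$min >= limits$max)) {
    stop("malformed limits: min must be below max for every trait")
  }
  lo <- limits$min[match(table$trait, limits$trait)]
  hi <- limits$max[match(table$trait, limits$trait)]
  out_low <- !is.na(lo) & table$value < lo
  out_high <- !is.na(hi) & table$value > hi
  drop <- out_low | out_high
  removed <- table[drop, , drop = FALSE]
  if (nrow(removed) > 0L) {
    removed$reason <- ifelse(out_low[drop], "below_min", "above_max")
    rownames(removed) <- NULL
  } else {
    removed$reason <- character(0)
  }
  kept <- table[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(table = kept, removed = removed)
}
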