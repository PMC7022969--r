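# Shared fixtures built in code: neutral fixed effects, flattened trends
# and offsets for configurations where the generating parameters must be
# known exactly, plus a random-but-valid event table builder.

zero_offsets <- function() {
  list(zone = stats::setNames(rep(0, length(ZONES)), ZONES),
       breed = stats::setNames(rep(0, length(BREED_GROUPS)), BREED_GROUPS))
}

flat_level_offsets <- function() {
  lapply(default_level_offsets(), function(x) x * 0)
}

flat_trends <- function() {
  lapply(default_trends(), function(d) {
    d$total <- 0
    d
  })
}

# A valid random event table: per animal a BIRTH, then calvings,
# conceptions after calvings, weighings and possibly a cull.
random_event_table <- function(n_animals = 40, seed = 99) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_animals)) {
    herd <- sprintf("h%02d", sample(1:5, 1))
    animal <- sprintf("%s-a%03d", herd, i)
    birth <- as.Date("1998-01-01") + sample(0:2000, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      herd_id = herd, animal_id = animal, event_date = birth,
      event_type = "BIRTH", value = NA_real_, parity = NA_integer_)
    calv <- birth + 900 + sample(0:120, 1)
    for (p in 1:sample(1:3, 1)) {
      rows[[length(rows) + 1L]] <- data.frame(
        herd_id = herd, animal_id = animal, event_date = calv,
        event_type = "CALVING", value = NA_real_, parity = p)
      if (runif(1) < 0.8) {
        rows[[length(rows) + 1L]] <- data.frame(
          herd_id = herd, animal_id = animal,
          event_date = calv + sample(60:150, 1),
          event_type = "CONCEPTION", value = NA_real_,
          parity = NA_integer_)
      }
      if (runif(1) < 0.6) {
        rows[[length(rows) + 1L]] <- data.frame(
          herd_id = herd, animal_id = animal,
          event_date = calv + sample(10:200, 1),
          event_type = "MILK_WEIGH", value = round(runif(1, 5, 30), 1),
          parity = NA_integer_)
      }
      calv <- calv + 380 + sample(0:60, 1)
    }
    if (runif(1) < 0.3) {
      rows[[length(rows) + 1L]] <- data.frame(
        herd_id = herd, animal_id = animal, event_date = calv + 100,
        event_type = "CULL", value = NA_real_, parity = NA_integer_)
    }
  }
  tab <- do.call(rbind, rows)
  event_table(tab$herd_id, tab$animal_id, tab$event_date, tab$event_type,
              tab$value, tab$parity)
}

# Compact builder for cohort tests: one CALVING-like event per year per
# requested type.
yearly_events <- function(herd, years_by_type) {
  rows <- list()
  for (tp in names(years_by_type)) {
    for (y in years_by_type[[tp]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        herd_id = herd, animal_id = paste0(herd, "-", y),
        event_date = as.Date(sprintf("%d-06-01", y)), event_type = tp,
        value = if (tp == "MILK_WEIGH") 15 else NA_real_,
        parity = NA_integer_)
    }
  }
  tab <- do.call(rbind, rows)
  event_table(tab$herd_id, tab$animal_id, tab$event_date, tab$event_type,
              tab$value, tab$parity)
}
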