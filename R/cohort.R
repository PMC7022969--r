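## Herd-selection and MIS adoption-level classification.
##
## A herd qualifies through runs of consecutive calendar years with
## recorded information. Levels: LOW = >=5 consecutive years of
## reproductive records only; MEDIUM = reproductive and productive;
## HIGH = reproductive, productive and health. For MEDIUM/HIGH the
## categories' runs must share at least 5 common consecutive years, so
## the same herd-years are analyzable across domains.

## Consecutive runs (>= min_len) within a sorted integer vector; returns a
## data.frame of run starts/ends, earliest first.
year_runs <- function(years, min_len = 1L) {
  years <- sort(unique(years))
  if (length(years) == 0L) {
    return(data.frame(start = integer(), end = integer(), len = integer()))
  }
  brk <- c(0L, which(diff(years) > 1L), length(years))
  runs <- data.frame(
    start = years[brk[-length(brk)] + 1L],
    end = years[brk[-1L]]
  )
  runs$len <- runs$end - runs$start + 1L
  runs[runs$len >= min_len, , drop = FALSE]
}

longest_run <- function(years) {
  r <- year_runs(years)
  if (nrow(r) == 0L) 0L else max(r$len)
}

#' Classify herds by MIS adoption level
#'
#' Scores each herd's record availability by category (reproductive =
#' BIRTH/CALVING/CONCEPTION, productive = MILK_WEIGH/CULL, health =
#' MASTITIS/LAMENESS) and assigns an adoption level: `HIGH` when all three
#' categories share at least `min_years` common consecutive calendar years
#' of records, `MEDIUM` when reproductive and productive (but not health)
#' do, `LOW` when only the reproductive category has such a run, and
#' `EXCLUDED` otherwise. The qualifying window is the earliest consecutive
#' run of common years.
#'
#' @param events an event table.
#' @param min_years minimum consecutive years required (default 5).
#' @param min_records minimum records per category-year for the year to
#'   count as covered (default 1).
#' @return A `data.frame` with one row per herd: `herd_id`, `level`,
#'   `window_first`, `window_last` (NA when excluded), per-category longest
#'   run lengths `run_reproductive`, `run_productive`, `run_health`, and
#'   the per-category available years as comma-separated strings.
#' @export
classify_adoption <- function(events, min_years = 5L, min_records = 1L) {
  if (nrow(events) == 0L) stop("no events to classify")
  yr <- as.integer(format(events$event_date, "%Y"))
  herds <- sort(unique(events$herd_id))
  cat_lookup <- c(BIRTH = "reproductive", CALVING = "reproductive",
                  CONCEPTION = "reproductive", MILK_WEIGH = "productive",
                  CULL = "productive", MASTITIS = "health",
                  LAMENESS = "health")
  category <- unname(cat_lookup[events$event_type])
  counts <- as.data.frame(table(herd_id = events$herd_id, year = yr,
                                category = category),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq >= min_records, ]
  counts$year <- as.integer(counts$year)

  one <- function(h) {
    ys <- function(cat) counts$year[counts$herd_id == h &
                                      counts$category == cat]
    rep_y <- ys("reproductive"); prod_y <- ys("productive")
    heal_y <- ys("health")
    pick <- function(years) {
      r <- year_runs(years, min_years)
      if (nrow(r) == 0L) NULL else r[1L, ]
    }
    high <- pick(intersect(intersect(rep_y, prod_y), heal_y))
    med <- pick(intersect(rep_y, prod_y))
    low <- pick(rep_y)
    if (!is.null(high)) {
      level <- "HIGH"; win <- high
    } else if (!is.null(med)) {
      level <- "MEDIUM"; win <- med
    } else if (!is.null(low)) {
      level <- "LOW"; win <- low
    } else {
      level <- "EXCLUDED"; win <- data.frame(start = NA_integer_,
                                             end = NA_integer_)
    }
    data.frame(
      herd_id = h, level = level,
      window_first = win$start, window_last = win$end,
      run_reproductive = longest_run(rep_y),
      run_productive = longest_run(prod_y),
      run_health = longest_run(heal_y),
      years_reproductive = paste(sort(unique(rep_y)), collapse = ","),
      years_productive = paste(sort(unique(prod_y)), collapse = ","),
      years_health = paste(sort(unique(heal_y)), collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(herds, one))
  rownames(out) <- NULL
  out
}

#' Map calendar years to follow-up years
#'
#' Follow-up year 1 is the first calendar year of a herd's qualifying
#' window; years beyond `max_years` are dropped, and excluded herds are
#' absent from the map.
#'
#' @param profiles output of [classify_adoption()].
#' @param max_years maximum follow-up span retained (default 10; must be at
#'   least 5).
#' @return A `data.frame` with columns `herd_id, calendar_year,
#'   followup_year`.
#' @export
select_followup <- function(profiles, max_years = 10L) {
  if (max_years < 5L) stop("max_years must be at least 5")
  keep <- profiles[profiles$level != "EXCLUDED", , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(data.frame(herd_id = character(), calendar_year = integer(),
                      followup_year = integer(), stringsAsFactors = FALSE))
  }
  maps <- lapply(seq_len(nrow(keep)), function(i) {
    first <- keep$window_first[i]
    last <- min(keep$window_last[i], first + max_years - 1L)
    yrs <- first:last
    data.frame(herd_id = keep$herd_id[i], calendar_year = yrs,
               followup_year = seq_along(yrs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  out
}
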