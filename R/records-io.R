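#' @keywords internal
"_PACKAGE"

## Closed enumerations shared across the package ------------------------------

#' Event, trait, zone and breed vocabularies
#'
#' The package works with a closed set of animal event types, the six
#' herd-year performance traits derived from them, the Holdridge life-zone
#' labels used for the agroecological-zone fixed effect, and the predominant
#' breed groups.
#'
#' @format Character vectors of the legal tokens.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
EVENT_TYPES <- c("BIRTH", "CALVING", "CONCEPTION", "MILK_WEIGH",
                 "MASTITIS", "LAMENESS", "CULL")

#' @rdname vocabularies
#' @export
TRAITS <- c("AFC", "DO", "DMY", "PL", "MAST", "LAM")

#' @rdname vocabularies
#' @export
ZONES <- c("HF_TROPICAL", "HF_LOW_MONTANE", "HF_PREMONTANE",
           "VHF_TROPICAL", "VHF_LOW_MONTANE", "VHF_PREMONTANE",
           "RF_PREMONTANE")

#' @rdname vocabularies
#' @export
BREED_GROUPS <- c("HOLSTEIN", "JERSEY", "HOLSTEIN_X_JERSEY", "DAIRY_CROSS",
                  "DAIRY_X_BOS_INDICUS", "OTHER")

## Record categories used for adoption-level classification: productive
## life is scored under the productive domain, so CULL sits with MILK_WEIGH.
EVENT_CATEGORIES <- list(
  reproductive = c("BIRTH", "CALVING", "CONCEPTION"),
  productive   = c("MILK_WEIGH", "CULL"),
  health       = c("MASTITIS", "LAMENESS")
)

EVENT_COLUMNS <- c("herd_id", "animal_id", "event_date", "event_type",
                   "value", "parity")
HERD_COLUMNS <- c("herd_id", "zone", "breed_group", "first_followup_year")

## Days per month (Julian year / 12) and per year, used for every
## date-difference-to-months/years conversion in the package.
DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

#' Construct an event table
#'
#' Builds a validated data frame of animal event records. IDs are opaque
#' strings (never coerced to numeric), dates are `Date`, `value` carries the
#' milk weight in kg for `MILK_WEIGH` events and is `NA` otherwise, and
#' `parity` is the lactation number for `CALVING` events.
#'
#' @param herd_id,animal_id character vectors.
#' @param event_date `Date` vector (or ISO-8601 strings).
#' @param event_type character vector of tokens in [EVENT_TYPES].
#' @param value numeric, kg for `MILK_WEIGH` rows, `NA` otherwise.
#' @param parity integer lactation number for `CALVING` rows, `NA` otherwise.
#' @return A `data.frame` with columns
#'   `herd_id, animal_id, event_date, event_type, value, parity`.
#' @export
event_table <- function(herd_id = character(), animal_id = character(),
                        event_date = as.Date(character()),
                        event_type = character(),
                        value = rep(NA_real_, length(herd_id)),
                        parity = rep(NA_integer_, length(herd_id))) {
  tab <- data.frame(
    herd_id = as.character(herd_id),
    animal_id = as.character(animal_id),
    event_date = as.Date(event_date),
    event_type = as.character(event_type),
    value = as.numeric(value),
    parity = as.integer(parity),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(unique(tab$event_type), EVENT_TYPES)
  if (length(bad) > 0L) {
    stop("unknown event_type token(s): ", paste(bad, collapse = ", "))
  }
  tab
}

#' Read an event table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header naming the columns
#' `herd_id, animal_id, event_date, event_type, value, parity` and ISO-8601
#' dates. Empty cells (never 0) encode missing `value`/`parity`. Row order
#' is preserved.
#'
#' @param path path to the CSV file.
#' @return An event table (see [event_table()]).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(EVENT_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[, EVENT_COLUMNS]
  bad_type <- which(!(raw$event_type %in% EVENT_TYPES))
  if (length(bad_type) > 0L) {
    stop(sprintf("unknown event_type %s at row %d of %s",
                 dQuote(raw$event_type[bad_type[1]]), bad_type[1], path))
  }
  dates <- as.Date(raw$event_date, format = "%Y-%m-%d")
  bad_date <- which(is.na(dates) & nzchar(raw$event_date))
  bad_date <- union(bad_date, which(!nzchar(raw$event_date)))
  if (length(bad_date) > 0L) {
    stop(sprintf("unparseable event_date %s at row %d, column 'event_date' of %s",
                 dQuote(raw$event_date[bad_date[1]]), bad_date[1], path))
  }
  value <- suppressWarnings(as.numeric(raw$value))
  bad_value <- which(is.na(value) & nzchar(raw$value))
  if (length(bad_value) > 0L) {
    stop(sprintf("unparseable value %s at row %d, column 'value' of %s",
                 dQuote(raw$value[bad_value[1]]), bad_value[1], path))
  }
  parity <- suppressWarnings(as.integer(raw$parity))
  bad_par <- which(is.na(parity) & nzchar(raw$parity))
  if (length(bad_par) > 0L) {
    stop(sprintf("unparseable parity %s at row %d, column 'parity' of %s",
                 dQuote(raw$parity[bad_par[1]]), bad_par[1], path))
  }
  event_table(raw$herd_id, raw$animal_id, dates, raw$event_type,
              value, parity)
}

#' Write an event table to CSV
#'
#' Writes the fixed six-column header, ISO-8601 dates, and empty strings for
#' missing `value`/`parity` cells so that [read_events()] round-trips the
#' table field-for-field.
#'
#' @param table an event table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path) {
  out <- data.frame(
    herd_id = table$herd_id,
    animal_id = table$animal_id,
    event_date = format(table$event_date, "%Y-%m-%d"),
    event_type = table$event_type,
    value = ifelse(is.na(table$value), "",
                   format(table$value, trim = TRUE, scientific = FALSE,
                          digits = 15)),
    parity = ifelse(is.na(table$parity), "",
                    as.character(table$parity)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct a herd metadata table
#'
#' One row per herd: agroecological zone (Holdridge life-zone label, see
#' [ZONES]), predominant breed group, and the calendar year of first MIS use.
#'
#' @param herd_id character vector, unique.
#' @param zone character vector of tokens in [ZONES].
#' @param breed_group character vector of tokens in [BREED_GROUPS].
#' @param first_followup_year integer calendar years.
#' @return A `data.frame` with one row per herd.
#' @export
herd_meta <- function(herd_id = character(), zone = character(),
                      breed_group = character(),
                      first_followup_year = integer()) {
  if (anyDuplicated(herd_id)) stop("duplicated herd_id in herd metadata")
  bad_zone <- setdiff(unique(zone), ZONES)
  if (length(bad_zone) > 0L) {
    stop("unknown zone token(s): ", paste(bad_zone, collapse = ", "))
  }
  bad_breed <- setdiff(unique(breed_group), BREED_GROUPS)
  if (length(bad_breed) > 0L) {
    stop("unknown breed_group token(s): ", paste(bad_breed, collapse = ", "))
  }
  data.frame(herd_id = as.character(herd_id), zone = as.character(zone),
             breed_group = as.character(breed_group),
             first_followup_year = as.integer(first_followup_year),
             stringsAsFactors = FALSE)
}

#' @rdname herd_meta
#' @param path path to a herds CSV (columns
#'   `herd_id, zone, breed_group, first_followup_year`).
#' @export
read_herds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(HERD_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  herd_meta(raw$herd_id, raw$zone, raw$breed_group,
            as.integer(raw$first_followup_year))
}

#' @rdname herd_meta
#' @param meta a herd metadata table.
#' @export
write_herds <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate an event table
#'
#' Checks the event-record invariants and returns every violation as a row
#' of a report (never an error): milk weights present exactly on
#' `MILK_WEIGH` rows and strictly positive; an animal's `BIRTH` (when
#' recorded) precedes all its other events; a `CONCEPTION` is preceded by a
#' `CALVING` or `BIRTH` of the same animal; and, when herd metadata are
#' given, every `herd_id` is known.
#'
#' @param table an event table.
#' @param meta optional herd metadata table; enables the orphan-herd check.
#' @return A `data.frame` with columns `row, herd_id, animal_id, rule,
#'   message`; zero rows for a clean table.
#' @export
validate_events <- function(table, meta = NULL) {
  reports <- list()
  note <- function(rows, rule, msg) {
    if (length(rows) == 0L) return()
    reports[[length(reports) + 1L]] <<- data.frame(
      row = rows, herd_id = table$herd_id[rows],
      animal_id = table$animal_id[rows], rule = rule, message = msg,
      stringsAsFactors = FALSE)
  }

  is_mw <- table$event_type == "MILK_WEIGH"
  note(which(is_mw & is.na(table$value)), "value_missing",
       "MILK_WEIGH record without a milk weight")
  note(which(is_mw & !is.na(table$value) & table$value <= 0),
       "value_nonpositive", "milk weight must be > 0")
  note(which(!is_mw & !is.na(table$value)), "value_unexpected",
       "value present on a non-MILK_WEIGH record")

  if (!is.null(meta)) {
    note(which(!(table$herd_id %in% meta$herd_id)), "orphan_herd",
         "herd_id absent from herd metadata")
  }

  if (nrow(table) > 0L) {
    key <- paste(table$herd_id, table$animal_id, sep = "\r")
    ## BIRTH precedes all other events of the animal
    birth_rows <- which(table$event_type == "BIRTH")
    if (length(birth_rows) > 0L) {
      birth_date <- tapply(table$event_date[birth_rows], key[birth_rows], min)
      bd <- birth_date[key]
      offending <- which(!is.na(bd) & table$event_type != "BIRTH" &
                           as.numeric(table$event_date) < as.numeric(bd))
      note(offending, "event_before_birth",
           "event dated before the animal's BIRTH")
    }
    ## CONCEPTION preceded by a CALVING or BIRTH of the same animal
    conc_rows <- which(table$event_type == "CONCEPTION")
    if (length(conc_rows) > 0L) {
      start_rows <- which(table$event_type %in% c("CALVING", "BIRTH"))
      first_start <- if (length(start_rows) > 0L) {
        tapply(table$event_date[start_rows], key[start_rows], min)
      } else {
        numeric(0)
      }
      fs <- first_start[key[conc_rows]]
      offending <- conc_rows[is.na(fs) |
                               as.numeric(table$event_date[conc_rows]) <
                                 as.numeric(fs)]
      note(offending, "conception_unanchored",
           "CONCEPTION with no earlier CALVING or BIRTH for the animal")
    }
  }

  if (length(reports) == 0L) {
    return(data.frame(row = integer(), herd_id = character(),
                      animal_id = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, reports)
  out <- out[order(out$row), , drop = FALSE]
  rownames(out) <- NULL
  out
}
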