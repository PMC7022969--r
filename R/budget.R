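## Partial-budget appraisal of MIS implementation.
##
## Only the cost and income changes caused by the intervention are
## counted. Costs: straight-line amortization of hardware and software
## plus additional labor for data collection and data entry/analysis,
## labor scaling linearly with herd size (expressed per 100 cows). Income:
## per-trait annual improvement x economic value x cows, accrued once per
## year of the horizon (non-cumulative: the Table-style $ per 5 years per
## 100 cows convention). All internal arithmetic is unrounded; rounding
## happens only in print methods.

#' Partial-budget inputs
#'
#' Base scenario defaults: a 100-cow herd over a 5-year horizon, $700
#' hardware and $700 software amortized over 5 years, 7.6 data-collection
#' and 15.2 data-entry/analysis additional labor days per year per 100
#' cows at a $24.7 daily wage, and two income traits: days open improving
#' by -1.02 d/cow/year at an economic value of -$2.15/d/cow/year, and
#' daily milk yield improving by 0.31 kg/cow/year at $64.6/kg/cow/year.
#'
#' @param horizon_years time horizon (years).
#' @param herd_cows cows in production.
#' @param hardware_cost,hardware_life purchase cost and straight-line
#'   amortization life of the hardware.
#' @param software_cost,software_life same for the software license
#'   (renewed every `software_life` years).
#' @param collection_days,entry_days additional labor days per year per
#'   100 cows for data collection and for data entry/analysis.
#' @param day_wage daily wage applied to both labor lines unless a
#'   line-specific wage is given.
#' @param collection_day_wage,entry_day_wage per-line daily wages
#'   (default `day_wage`).
#' @param traits data frame `trait, annual_change, economic_value` with
#'   annual trait change (units/cow/year) and economic value
#'   (currency/unit/cow/year).
#' @return An object of class `"budget_inputs"`.
#' @export
budget_inputs <- function(horizon_years = 5, herd_cows = 100,
                          hardware_cost = 700, hardware_life = 5,
                          software_cost = 700, software_life = 5,
                          collection_days = 7.6, entry_days = 15.2,
                          day_wage = 24.7,
                          collection_day_wage = day_wage,
                          entry_day_wage = day_wage,
                          traits = data.frame(
                            trait = c("DO", "DMY"),
                            annual_change = c(-1.02, 0.31),
                            economic_value = c(-2.15, 64.6),
                            stringsAsFactors = FALSE)) {
  if (horizon_years <= 0) stop("horizon_years must be positive")
  if (herd_cows <= 0) stop("herd_cows must be positive")
  if (hardware_life <= 0 || software_life <= 0) {
    stop("amortization life must be positive")
  }
  if (day_wage <= 0 || collection_day_wage <= 0 || entry_day_wage <= 0) {
    stop("wages must be positive")
  }
  if (hardware_cost < 0 || software_cost < 0 ||
      collection_days < 0 || entry_days < 0) {
    stop("costs and labor days must be non-negative")
  }
  stopifnot(all(c("trait", "annual_change", "economic_value") %in%
                  names(traits)))
  structure(list(
    horizon_years = horizon_years, herd_cows = herd_cows,
    hardware_cost = hardware_cost, hardware_life = hardware_life,
    software_cost = software_cost, software_life = software_life,
    collection_days = collection_days, entry_days = entry_days,
    collection_day_wage = collection_day_wage,
    entry_day_wage = entry_day_wage,
    traits = traits
  ), class = "budget_inputs")
}

#' Annual trait change from marginal means
#'
#' Ordinary least-squares slope of the marginal mean on follow-up year for
#' one adoption level, over a year range (by default the first 5 follow-up
#' years): the expected annual change of the trait attributable to MIS
#' use.
#'
#' @param means a [marginal_means()] table.
#' @param level adoption level whose trajectory is regressed
#'   (default `"MEDIUM"`, the base-scenario herd profile).
#' @param years follow-up years used (default 1:5).
#' @return The slope, in trait units per cow per year.
#' @export
annual_change_from_means <- function(means, level = "MEDIUM",
                                     years = 1:5) {
  fy <- as.integer(as.character(means$followup_year))
  sel <- means$adoption_level == level & fy %in% years
  if (sum(sel) < 2L) stop("need at least 2 marginal means in the year range")
  x <- fy[sel]
  y <- means$mean[sel]
  unname(stats::coef(stats::lm(y ~ x))[2])
}

#' Expected increase in costs
#'
#' Per-year cost lines (hardware and software amortization, data
#' collection, data entry/analysis; labor scales linearly with
#' `herd_cows`/100) and their total over the horizon.
#'
#' @param inputs a [budget_inputs()] object.
#' @return List with `lines` (per-year cost lines), `per_year` and
#'   `delta_cost` (total over the horizon).
#' @export
compute_costs <- function(inputs) {
  scale <- inputs$herd_cows / 100
  lines <- c(
    hardware = inputs$hardware_cost / inputs$hardware_life,
    software = inputs$software_cost / inputs$software_life,
    collection = inputs$collection_days * inputs$collection_day_wage * scale,
    entry = inputs$entry_days * inputs$entry_day_wage * scale
  )
  per_year <- sum(lines)
  list(lines = lines, per_year = per_year,
       delta_cost = inputs$horizon_years * per_year)
}

#' Expected increase in income
#'
#' Per trait: annual change x economic value x cows, credited once per
#' year of the horizon (non-cumulative accrual).
#'
#' @param inputs a [budget_inputs()] object.
#' @return List with `by_trait` (named, total over horizon) and
#'   `delta_income`.
#' @export
compute_income <- function(inputs) {
  tr <- inputs$traits
  by_trait <- tr$annual_change * tr$economic_value * inputs$herd_cows *
    inputs$horizon_years
  names(by_trait) <- tr$trait
  list(by_trait = by_trait, delta_income = sum(by_trait))
}

#' Evaluate the partial budget
#'
#' Assembles the expected cost increase, the expected income increase, the
#' gross margin GM = dI - dC and the marginal return rate
#' MRR = 100 x GM / dC of MIS implementation.
#'
#' @param inputs a [budget_inputs()] object.
#' @return An object of class `"mis_budget"`: `delta_cost`, `cost_lines`
#'   (per year), `income_by_trait`, `delta_income`, `gross_margin`,
#'   `marginal_return_rate` (percent; `NA` when `delta_cost` is 0).
#' @export
budget_evaluate <- function(inputs) {
  costs <- compute_costs(inputs)
  income <- compute_income(inputs)
  gm <- income$delta_income - costs$delta_cost
  mrr <- if (costs$delta_cost == 0) NA_real_ else 100 * gm / costs$delta_cost
  structure(list(
    inputs = inputs,
    cost_lines = costs$lines, delta_cost = costs$delta_cost,
    income_by_trait = income$by_trait, delta_income = income$delta_income,
    gross_margin = gm, marginal_return_rate = mrr
  ), class = "mis_budget")
}

#' @export
print.mis_budget <- function(x, ...) {
  inp <- x$inputs
  cat(sprintf("Partial budget: %g cows, %g-year horizon\n",
              inp$herd_cows, inp$horizon_years))
  cat("  Expected increase in costs (per year):\n")
  for (nm in names(x$cost_lines)) {
    cat(sprintf("    %-12s $%8.0f\n", nm, x$cost_lines[nm]))
  }
  cat(sprintf("  Total increase of costs (dC):   $%8.0f\n", x$delta_cost))
  cat("  Expected increase in income (over horizon):\n")
  for (nm in names(x$income_by_trait)) {
    cat(sprintf("    %-12s $%8.0f\n", nm, x$income_by_trait[nm]))
  }
  cat(sprintf("  Total increase of income (dI):  $%8.0f\n", x$delta_income))
  cat(sprintf("  Gross margin (GM = dI - dC):    $%8.0f\n", x$gross_margin))
  if (is.na(x$marginal_return_rate)) {
    cat("  Marginal return rate: undefined (dC = 0)\n")
  } else {
    cat(sprintf("  Marginal return rate (MRR):     %8.1f%%\n",
                x$marginal_return_rate))
  }
  invisible(x)
}

#' Break-even herd size
#'
#' Smallest integer herd size at which the gross margin of MIS
#' implementation is non-negative, holding every other input fixed:
#' income and labor scale linearly with herd size, hardware/software are
#' fixed costs. Computed in closed form from the per-cow margin and
#' verified against the definition.
#'
#' @param inputs a [budget_inputs()] object.
#' @param max_size largest herd size considered before reporting that the
#'   margin never turns positive.
#' @return The break-even herd size (integer), or `Inf` when the per-cow
#'   margin cannot cover the fixed costs within `max_size`.
#' @export
break_even_herd_size <- function(inputs, max_size = 10000) {
  tr <- inputs$traits
  income_per_cow_year <- sum(tr$annual_change * tr$economic_value)
  labor_per_cow_year <- (inputs$collection_days * inputs$collection_day_wage +
                           inputs$entry_days * inputs$entry_day_wage) / 100
  fixed_per_year <- inputs$hardware_cost / inputs$hardware_life +
    inputs$software_cost / inputs$software_life
  margin <- income_per_cow_year - labor_per_cow_year
  if (margin <= 0) {
    return(if (fixed_per_year == 0 && margin == 0) 1L else Inf)
  }
  be <- as.integer(max(1L, ceiling(fixed_per_year / margin)))
  ## guard against floating-point edge at the boundary
  gm_at <- function(h) {
    i2 <- inputs; i2$herd_cows <- h
    budget_evaluate(i2)$gross_margin
  }
  while (be > 1L && gm_at(be - 1L) >= 0) be <- be - 1L
  while (gm_at(be) < 0) {
    be <- be + 1L
    if (be > max_size) return(Inf)
  }
  be
}
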