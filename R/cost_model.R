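#' Full-time-equivalent multiplier at a given age
#'
#' Retirement trajectory of the human-capital model: individuals work at the
#' full FTE level (0.9 by default) from the labour-entry age through age 71,
#' taper linearly to 0.5 by age 75, and are fully retired (0 FTE) from age
#' 76 onward. Ages below the entry age carry 0 FTE.
#'
#' @param age Integer age(s) in years; must be >= 0.
#' @param params A [cost_parameters()] object.
#' @return FTE fraction(s) in \[0, 1\]; monotone non-increasing in age from
#'   the entry age onward.
#' @export
#' @examples
#' p <- cost_parameters()
#' fte_multiplier(c(65, 73, 76), p)  # 0.9, 0.7, 0.0
fte_multiplier <- function(age, params = cost_parameters()) {
  stopifnot_msg(all(age >= 0), "input error: age must be >= 0")
  taper_ages <- as.integer(names(params$fte_taper))
  out <- numeric(length(age))
  out[age >= params$fte_entry_age & age <= 71] <- params$fte_full
  in_taper <- age %in% taper_ages
  out[in_taper] <- unname(params$fte_taper[as.character(age[in_taper])])
  out[age >= 76] <- 0
  out
}

#' Present value of lost future earnings
#'
#' Discounted sum, over the whole remaining years of life, of
#' occupation-matched annual earnings scaled by the age-specific FTE
#' multiplier: for a death at age \eqn{a}, the sum over
#' \eqn{t = 1, \dots, \lceil e(a) \rceil} of
#' \eqn{w \cdot \mathrm{FTE}(a + t) \cdot (1 + r)^{-t}}, where \eqn{e(a)} is
#' remaining life expectancy and \eqn{w} the annual wage. The horizon is the
#' rounded-up expectancy; the fractional final year is ignored.
#'
#' @param case A one-row fatality record (list or data.frame row) with
#'   `age`, `sex` and optionally `occupation_code`.
#' @param lt Life table (see [default_life_table()]).
#' @param es Earnings schedule (see [default_earnings_schedule()]).
#' @param params A [cost_parameters()] object.
#' @return Present value in AUD (nominal, year-of-death dollars).
#' @export
pv_future_earnings <- function(case, lt = default_life_table(),
                               es = default_earnings_schedule(),
                               params = cost_parameters()) {
  w <- annual_earnings(case$occupation_code %||% NA, es)
  horizon <- ceiling(life_expectancy(case$age, case$sex, lt))
  if (horizon < 1) return(0)
  t <- seq_len(horizon)
  wage_t <- w * (1 + params$wage_growth)^(t - 1)
  sum(wage_t * fte_multiplier(case$age + t, params) /
        (1 + params$discount_rate)^t)
}

#' Present value of lost household production
#'
#' A fixed annual value of unpaid household contributions accrues from the
#' start age (16) through a sex-specific end age: 76 for men, 82 for women,
#' both inclusive. A death at age \eqn{a} forgoes the years
#' \eqn{\max(a + 1, 16), \dots, \mathrm{end}}, each discounted back to the
#' year of death.
#'
#' @inheritParams pv_future_earnings
#' @return Present value in AUD; 0 for ages at or above the end age.
#' @export
pv_household_production <- function(case, params = cost_parameters()) {
  stopifnot_msg(case$sex %in% c("male", "female"),
                "sex must be 'male' or 'female'")
  end_age <- if (case$sex == "male") params$hp_end_age_male
             else params$hp_end_age_female
  first <- max(case$age + 1, params$hp_start_age)
  if (first > end_age) return(0)
  t <- (first:end_age) - case$age
  sum(params$hp_annual_value / (1 + params$discount_rate)^t)
}

#' Friction-period cost
#'
#' Employer disruption and replacement costs in the year of death, valued
#' as a fixed fraction (25% by default) of the decedent's annual salary.
#'
#' @param annual_salary Annual gross salary in AUD; must be >= 0.
#' @param params A [cost_parameters()] object.
#' @return AUD.
#' @export
friction_cost <- function(annual_salary, params = cost_parameters()) {
  stopifnot_msg(all(annual_salary >= 0),
                "input error: annual_salary must be >= 0")
  annual_salary * params$friction_fraction
}

#' Index a monetary amount to the base year
#'
#' Rescales by the ratio of CPI index values: `amount * cpi[base] / cpi[year]`.
#' Identity when `year` equals the base year.
#'
#' @param amount AUD amount(s) in `year` dollars.
#' @param year Calendar year the amount is denominated in.
#' @param cpi Named CPI series (see [default_cpi()]).
#' @param base_year Target year; defaults to 2023.
#' @return AUD in base-year dollars.
#' @export
index_to_base_year <- function(amount, year, cpi = default_cpi(),
                               base_year = 2023) {
  for (y in unique(c(year, base_year))) {
    if (!as.character(y) %in% names(cpi))
      stop(sprintf("configuration error: CPI series has no entry for year %s", y),
           call. = FALSE)
  }
  amount * unname(cpi[as.character(base_year)] / cpi[as.character(year)])
}

#' Value one fatality with the human-capital model
#'
#' Assembles the per-case cost breakdown: present value of future earnings,
#' household production, the friction cost, fixed direct costs (funeral,
#' coronial, investigation, emergency response) and -- only when the death
#' is work-related -- a compensation payout. Each component is computed in
#' year-of-death dollars and indexed to the base year; the total is the
#' component sum.
#'
#' @param case One fatality record with `age`, `sex`, `year`, `work_related`
#'   and optionally `occupation_code`.
#' @param lt,es,params See [pv_future_earnings()].
#' @param cpi Named CPI series covering the case year and base year.
#' @return An object of class `cost_breakdown`: list with `components`
#'   (named AUD vector: `future_earnings`, `household_production`,
#'   `friction`, `fixed_direct`, `compensation`), `total` and `base_year`.
#' @export
#' @examples
#' kase <- list(age = 40, sex = "male", year = 2023, work_related = "work",
#'              occupation_code = "1211")
#' case_cost(kase)
case_cost <- function(case, lt = default_life_table(),
                      es = default_earnings_schedule(),
                      cpi = default_cpi(),
                      params = cost_parameters()) {
  salary <- annual_earnings(case$occupation_code %||% NA, es)
  nominal <- c(
    future_earnings = pv_future_earnings(case, lt, es, params),
    household_production = pv_household_production(case, params),
    friction = friction_cost(salary, params),
    fixed_direct = sum(params$fixed_costs),
    compensation = if (identical(case$work_related, "work"))
      params$compensation_payout else 0
  )
  components <- index_to_base_year(nominal, case$year, cpi, params$base_year)
  structure(list(components = components,
                 total = sum(components),
                 base_year = params$base_year),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("Fatality cost breakdown (%d AUD)\n", x$base_year))
  for (nm in names(x$components))
    cat(sprintf("  %-22s %14s\n", nm,
                format(round(x$components[[nm]]), big.mark = ",")))
  cat(sprintf("  %-22s %14s\n", "total",
              format(round(x$total), big.mark = ",")))
  invisible(x)
}

#' Cost a whole cohort of fatality cases
#'
#' @param cases Data.frame of fatality records (see [generate_fatality_cases()]).
#' @inheritParams case_cost
#' @return Data.frame with one row per case: `case_id`, the five components
#'   and `total`, in base-year dollars.
#' @export
cost_cases <- function(cases, lt = default_life_table(),
                       es = default_earnings_schedule(),
                       cpi = default_cpi(),
                       params = cost_parameters()) {
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    b <- case_cost(as.list(cases[i, ]), lt, es, cpi, params)
    c(as.list(b$components), total = b$total)
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  cbind(case_id = cases$case_id, out)
}

#' Annualise a period total
#'
#' @param total AUD over the whole period.
#' @param n_years Number of years in the period; must be > 0.
#' @param multiple Optional rounding multiple applied to the annual figure
#'   (e.g. 1e6 for nearest million); `NULL` leaves it unrounded.
#' @return AUD per year.
#' @export
#' @examples
#' annualise(1.8e9, 11, multiple = 1e6)  # 164,000,000
annualise <- function(total, n_years, multiple = NULL) {
  stopifnot_msg(n_years > 0, "input error: n_years must be > 0")
  out <- total / n_years
  if (!is.null(multiple)) out <- round_to_multiple(out, multiple)
  out
}

#' Scale an annual claims cost for workers' compensation under-coverage
#'
#' Workers' compensation covers only part of the farm workforce
#' (owner-operators outside family trusts are excluded), so claims-based
#' costs under-represent the sector's injury burden. Two conventions are
#' offered: the default multiplies by `1 + under_coverage_factor` (1.4 with
#' the default 0.4, taking about $190M/yr to about $265M/yr); the
#' alternative divides by the coverage fraction (0.58), a larger uplift.
#'
#' @param annual_amount AUD per year; must be >= 0.
#' @param params A [cost_parameters()] object.
#' @param convention `"multiplicative"` (default) or `"coverage"`.
#' @param multiple Optional rounding multiple for the result.
#' @return Adjusted AUD per year.
#' @export
adjust_for_coverage <- function(annual_amount, params = cost_parameters(),
                                convention = c("multiplicative", "coverage"),
                                multiple = NULL) {
  stopifnot_msg(all(annual_amount >= 0),
                "input error: annual_amount must be >= 0")
  convention <- match.arg(convention)
  out <- switch(convention,
                multiplicative = annual_amount * (1 + params$under_coverage_factor),
                coverage = annual_amount / params$coverage_fraction)
  if (!is.null(multiple)) out <- round_to_multiple(out, multiple)
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
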