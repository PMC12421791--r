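#' Cost-model parameters
#'
#' Bundle every constant of the human-capital fatality costing model into a
#' validated parameter object. All monetary magnitudes are configurable;
#' the shipped fixed-cost and compensation defaults are round placeholder
#' values in 2023 AUD and should be replaced with jurisdiction-specific
#' figures for substantive use.
#'
#' @param friction_fraction Proportion of one annual salary charged as a
#'   friction (replacement/disruption) cost in the year of death. Default 0.25.
#' @param discount_rate Annual discount rate applied to future earnings and
#'   household production. Default 0.03; 0 is allowed.
#' @param fte_entry_age Age (years) from which market work is assumed; ages
#'   below earn 0 FTE but still accrue future earnings from this age onward.
#' @param fte_full Full-time-equivalent fraction worked from `fte_entry_age`
#'   through age 71. Default 0.9.
#' @param fte_taper Named numeric vector of FTE values for ages 72--75; the
#'   default is the linear taper 0.8, 0.7, 0.6, 0.5. From age 76 FTE is 0.
#' @param hp_start_age,hp_end_age_male,hp_end_age_female Household-production
#'   accrual window: value accrues for ages `max(age + 1, hp_start_age)`
#'   through the sex-specific end age (inclusive).
#' @param hp_annual_value AUD value of one year of household production.
#' @param fixed_costs Named numeric vector of per-case fixed direct costs
#'   (funeral, coronial services, WHS/police investigation, emergency
#'   response).
#' @param compensation_payout AUD payout applied only when the death is
#'   work-related.
#' @param coverage_fraction Proportion of the farm workforce covered by
#'   workers' compensation (0.58 by default).
#' @param under_coverage_factor Multiplicative uplift used by
#'   [adjust_for_coverage()] under the default convention; 0.4 scales an
#'   annual claims cost by 1.4.
#' @param base_year Calendar year in whose dollars results are expressed.
#' @param wage_growth Optional real annual wage growth rate; default 0 (flat
#'   real earnings).
#'
#' @return An object of class `cost_parameters` (a validated list).
#' @seealso [case_cost()], [fte_multiplier()], [default_life_table()],
#'   [default_earnings_schedule()], [default_cpi()]
#' @export
#' @examples
#' p <- cost_parameters(discount_rate = 0)
#' fte_multiplier(73, p)
cost_parameters <- function(friction_fraction = 0.25,
                            discount_rate = 0.03,
                            fte_entry_age = 16,
                            fte_full = 0.9,
                            fte_taper = c(`72` = 0.8, `73` = 0.7,
                                          `74` = 0.6, `75` = 0.5),
                            hp_start_age = 16,
                            hp_end_age_male = 76,
                            hp_end_age_female = 82,
                            hp_annual_value = 25000,
                            fixed_costs = c(funeral = 15000,
                                            coronial = 9000,
                                            investigation_whs_police = 35000,
                                            emergency_response = 12000),
                            compensation_payout = 580000,
                            coverage_fraction = 0.58,
                            under_coverage_factor = 0.4,
                            base_year = 2023,
                            wage_growth = 0) {
  p <- list(friction_fraction = friction_fraction,
            discount_rate = discount_rate,
            fte_entry_age = fte_entry_age,
            fte_full = fte_full,
            fte_taper = fte_taper,
            hp_start_age = hp_start_age,
            hp_end_age_male = hp_end_age_male,
            hp_end_age_female = hp_end_age_female,
            hp_annual_value = hp_annual_value,
            fixed_costs = fixed_costs,
            compensation_payout = compensation_payout,
            coverage_fraction = coverage_fraction,
            under_coverage_factor = under_coverage_factor,
            base_year = base_year,
            wage_growth = wage_growth)
  validate_cost_parameters(p)
  structure(p, class = "cost_parameters")
}

validate_cost_parameters <- function(p) {
  stopifnot_msg(p$friction_fraction >= 0 && p$friction_fraction <= 1,
                "friction_fraction must lie in [0, 1]")
  stopifnot_msg(p$discount_rate >= 0, "discount_rate must be >= 0")
  stopifnot_msg(all(p$fte_taper >= 0 & p$fte_taper <= 1) &&
                  p$fte_full >= 0 && p$fte_full <= 1,
                "FTE values must lie in [0, 1]")
  stopifnot_msg(all(p$fixed_costs >= 0) && p$compensation_payout >= 0 &&
                  p$hp_annual_value >= 0,
                "monetary parameters must be non-negative")
  stopifnot_msg(p$coverage_fraction > 0 && p$coverage_fraction <= 1,
                "coverage_fraction must lie in (0, 1]")
  stopifnot_msg(p$under_coverage_factor >= 0,
                "configuration error: under_coverage_factor must be >= 0")
  invisible(p)
}

#' @export
print.cost_parameters <- function(x, ...) {
  cat("Human-capital fatality cost parameters\n")
  cat(sprintf("  base year         : %d\n", x$base_year))
  cat(sprintf("  discount rate     : %.1f%%\n", 100 * x$discount_rate))
  cat(sprintf("  friction fraction : %.2f of annual salary\n",
              x$friction_fraction))
  cat(sprintf("  FTE               : %.2f from age %d to 71, taper %s, 0 from 76\n",
              x$fte_full, x$fte_entry_age,
              paste(x$fte_taper, collapse = "/")))
  cat(sprintf("  household prod.   : $%s/yr, ages %d-%d (m) / %d (f)\n",
              format(x$hp_annual_value, big.mark = ","),
              x$hp_start_age, x$hp_end_age_male, x$hp_end_age_female))
  cat(sprintf("  fixed direct      : $%s\n",
              format(sum(x$fixed_costs), big.mark = ",")))
  cat(sprintf("  compensation      : $%s (work-related only)\n",
              format(x$compensation_payout, big.mark = ",")))
  invisible(x)
}

# small internal helper: stop with a plain message (no call)
stopifnot_msg <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Synthetic default life table
#'
#' Remaining life expectancy by integer age and sex. The values are a
#' synthetic approximation built from a Gompertz mortality law calibrated so
#' that life expectancy at birth is 78.1 years for males and 83.0 for
#' females (the level of the official Australian 2002--2004 life tables,
#' which are not redistributable here). Expectancy is strictly positive and
#' non-increasing in age for each sex.
#'
#' @param max_age Oldest age tabulated (default 110).
#' @return A data.frame with columns `age`, `male`, `female` (remaining
#'   expectancy in years).
#' @export
default_life_table <- function(max_age = 110) {
  gompertz_expectancy <- function(e0_target, b) {
    expectancy <- function(a) {
      ages <- 0:(max_age + 60)
      # cumulative hazard of Gompertz h(x) = a * exp(b x)
      H <- a / b * (exp(b * ages) - 1)
      l <- exp(-H)
      e <- numeric(max_age + 1)
      for (x in 0:max_age) {
        lx <- l[(x + 1):length(l)]
        e[x + 1] <- sum((lx[-1] + lx[-length(lx)]) / 2) / lx[1]
      }
      e
    }
    a <- stats::uniroot(function(a) expectancy(a)[1] - e0_target,
                        c(1e-6, 1e-2), tol = 1e-10)$root
    expectancy(a)
  }
  data.frame(age = 0:max_age,
             male = gompertz_expectancy(78.1, 0.095),
             female = gompertz_expectancy(83.0, 0.100))
}

#' Look up remaining life expectancy
#'
#' @param age Integer age in years.
#' @param sex `"male"` or `"female"`.
#' @param lt Life table data.frame as returned by [default_life_table()].
#' @return Remaining life expectancy in years.
#' @export
life_expectancy <- function(age, sex, lt = default_life_table()) {
  stopifnot_msg(all(sex %in% c("male", "female")),
                "sex must be 'male' or 'female'")
  stopifnot_msg(all(age >= 0), "input error: age must be >= 0")
  i <- match(pmin(age, max(lt$age)), lt$age)
  stopifnot_msg(!anyNA(i), "life table does not cover the requested age")
  ifelse(sex == "male", lt$male[i], lt$female[i])
}

#' Default annual earnings schedule
#'
#' Gross annual earnings (AUD) by occupation classifier code, ANZSCO-style
#' major/unit groups relevant to agriculture, with a fallback for unmatched
#' or absent codes. Placeholder magnitudes; replace with survey-based
#' figures for substantive use.
#'
#' @return A list with elements `by_code` (named numeric vector) and
#'   `default_earnings` (scalar).
#' @export
default_earnings_schedule <- function() {
  list(by_code = c(`1211` = 78000,  # livestock farmers
                   `1212` = 76000,  # crop farmers
                   `1213` = 77000,  # mixed crop and livestock farmers
                   `7331` = 65000,  # truck drivers
                   `721`  = 62000,  # mobile plant operators
                   `8411` = 56000,  # agricultural and forestry labourers
                   `3622` = 60000), # gardeners/horticultural trades
       default_earnings = 65000)
}

#' Annual earnings for a case
#'
#' @param occupation_code Occupation classifier code or `NA`.
#' @param es Earnings schedule (see [default_earnings_schedule()]).
#' @return Annual gross earnings in AUD.
#' @export
annual_earnings <- function(occupation_code, es = default_earnings_schedule()) {
  stopifnot_msg(all(es$by_code > 0),
                "configuration error: earnings must be positive")
  out <- unname(es$by_code[as.character(occupation_code)])
  if (anyNA(out)) {
    if (is.null(es$default_earnings))
      stop("configuration error: occupation code unmatched and no default_earnings set",
           call. = FALSE)
    out[is.na(out)] <- es$default_earnings
  }
  out
}

#' Synthetic default consumer price index series
#'
#' Annual all-groups CPI index values for calendar years 2013--2023
#' (reference base 2011--12 = 100). These approximate the published
#' Australian national series and are intended for indexation of costs to
#' 2023 dollars; supply the official series for substantive work.
#'
#' @return Named numeric vector, names are calendar years.
#' @export
default_cpi <- function() {
  c(`2013` = 102.8, `2014` = 105.4, `2015` = 106.6, `2016` = 108.0,
    `2017` = 110.1, `2018` = 112.1, `2019` = 113.9, `2020` = 114.8,
    `2021` = 117.9, `2022` = 124.3, `2023` = 131.3)
}
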