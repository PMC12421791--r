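# Published national farm injury-burden figures (2013-2023 fatalities from
# the coronial registry; 2013-14 to 2021-22 workers' compensation claims).
# These printed summary values serve three roles: default calibration targets
# for the synthetic registry generator, fixtures for tabulation tests, and
# inputs to verify_published_figures(), which replays the arithmetic that
# connects them. Masked cells of the source tables are NA here; line totals
# are always visible.

#' Published agent-by-work-status fatality counts
#'
#' Per-agent fatality counts (2013--2023) by work status. Cells suppressed
#' in the source ("np" for fewer than five cases, "+" for a complementary
#' mask) are `NA`; the `total` column is fully visible and reconciles to
#' the published group totals and the grand total of 747 classified cases
#' plus one case of unknown agent and work status (748 overall).
#'
#' @return Data.frame with columns `group`, `agent`, `non_work`, `work`,
#'   `total`.
#' @export
published_agent_counts <- function() {
  rows <- list(
    # group, agent, non_work, work, total
    c("farm_vehicles", "quad", 32, 85, 117),
    c("farm_vehicles", "utility", 33, 19, 52),
    c("farm_vehicles", "ssv", 28, 16, 44),
    c("farm_vehicles", "motorbike", 16, 13, 29),
    c("farm_vehicles", "car", NA, NA, 16),
    c("farm_vehicles", "helicopter", 0, 15, 15),
    c("farm_vehicles", "truck", NA, NA, 15),
    c("farm_vehicles", "fixed_wing_aircraft", NA, NA, 12),
    c("farm_vehicles", "trailer", NA, NA, 11),
    c("farm_vehicles", "gyrocopter", 0, 6, 6),
    c("farm_vehicles", "other", NA, NA, 10),
    c("mobile_machinery", "tractor", 6, 112, 118),
    c("mobile_machinery", "forklift", NA, NA, 12),
    c("mobile_machinery", "bobcat", NA, NA, 8),
    c("mobile_machinery", "bulldozer", NA, NA, 8),
    c("mobile_machinery", "harvesting_machine", 0, 8, 8),
    c("mobile_machinery", "slasher_mower_conditioner", 0, 6, 6),
    c("mobile_machinery", "telehandler", 0, 6, 6),
    c("mobile_machinery", "other", NA, NA, 40),
    c("farm_structures", "dam_creek_river", NA, NA, 19),
    c("farm_structures", "powerlines", NA, NA, 8),
    c("farm_structures", "water_tank", NA, NA, 7),
    c("farm_structures", "other_shed", NA, NA, 5),
    c("farm_structures", "other", NA, NA, 17),
    c("working_environment", "trees_felling", 6, 12, 18),
    c("working_environment", "trees_not_felling", NA, NA, 14),
    c("working_environment", "fire_smoke_flame", 0, 11, 11),
    c("working_environment", "other", NA, NA, 13),
    c("animal", "horse", 16, 13, 29),
    c("animal", "cattle", 0, 14, 14),
    c("animal", "other", NA, NA, 12),
    c("other_classified", "firearms", NA, NA, 6),
    c("other_classified", "other", 6, 35, 41)
  )
  df <- data.frame(group = vapply(rows, `[[`, character(1), 1),
                   agent = vapply(rows, `[[`, character(1), 2),
                   non_work = as.numeric(vapply(rows, `[[`, character(1), 3)),
                   work = as.numeric(vapply(rows, `[[`, character(1), 4)),
                   total = as.numeric(vapply(rows, `[[`, character(1), 5)))
  df
}

#' Published fatality headline counts and narrative figures
#'
#' @return Named list of the headline published quantities: fatality counts
#'   by work status and sex, the six leading agents, cohort cost totals,
#'   claims-cost narrative figures and the coverage-adjusted annual figure.
#' @export
published_headlines <- function() {
  list(n_total = 748, n_work = 544, n_nonwork = 203, n_unknown = 1,
       n_male_work = 513,
       top6_agents = c("tractor", "quad", "utility", "ssv", "horse",
                       "motorbike"),
       fatal_total_cost = 1.8e9,       # narrative, all fatalities
       fatal_work_cost = 1.24e9,       # narrative, work-related
       fatal_years = 11,
       claims_total_cost = 1.505e9,    # eight years of claims costs
       claims_cost_years = 8,
       claims_annual_cost_m = 190,
       coverage_adjusted_annual_m = 265,
       combined_annual_m = 355)
}

#' Published age-band fatality cost summary
#'
#' Case counts, rounded cost totals and rounded average cost per fatality
#' by age band, 2023 dollars, plus the overall row.
#'
#' @return Data.frame with columns `band`, `n`, `total`, `average`; the
#'   last row is the overall summary.
#' @export
published_age_band_costs <- function() {
  data.frame(
    band = c("<15", "15-24", "25-34", "35-44", "45-54", "55-64", ">=65",
             "total"),
    n = c(87, 61, 68, 72, 99, 125, 236, 748),
    total = c(172540000, 196070000, 328350000, 281800000, 348470000,
              257455000, 194995000, 1.78e9),
    average = c(1985000, 3215000, 4830000, 3915000, 3520000, 2060000,
                825000, 2380000))
}

#' Published claim counts by severity and period
#'
#' @return Data.frame: `period` (1 or 2), `n_years`, `severity`, `total`
#'   and the printed `annual_mean` (rounded to 5 in the source).
#' @export
published_claim_counts <- function() {
  data.frame(
    period = c(1, 1, 1, 2, 2, 2),
    n_years = c(4, 4, 4, 5, 5, 5),
    severity = c("minor", "serious", "all", "minor", "serious", "all"),
    total = c(9280, 10900, 20185, 10220, 14385, 24605),
    annual_mean = c(2320, 2725, 5045, 2045, 2875, 4920))
}

#' Published claim counts by agency group and period
#'
#' Period totals, integer percentage shares and rounded annual means for
#' the nine agency-of-injury major groups. The source's
#' `non_powered_handtools` first-period total (3,799) is internally
#' inconsistent with its printed annual mean (925); it is carried verbatim
#' and excluded from arithmetic checks.
#'
#' @return Data.frame with columns `agency_group`, `p1_total`, `p1_pct`,
#'   `p1_mean`, `p2_total`, `p2_pct`, `p2_mean`.
#' @export
published_agency_counts <- function() {
  data.frame(
    agency_group = c("animal_human_biological", "chemicals",
                     "environmental", "machinery_fixed_plant",
                     "materials_substances", "mobile_plant_transport",
                     "non_powered_handtools", "other_unspecified",
                     "powered_equipment"),
    p1_total = c(4430, 335, 3055, 1185, 2575, 2620, 3799, 1695, 590),
    p1_pct = c(22, 2, 15, 6, 13, 13, 19, 8, 3),
    p1_mean = c(1110, 85, 765, 295, 645, 655, 925, 425, 145),
    p2_total = c(5260, 370, 4155, 1490, 3185, 3055, 4265, 2060, 765),
    p2_pct = c(21, 2, 17, 6, 13, 12, 17, 8, 3),
    p2_mean = c(1050, 75, 830, 300, 635, 610, 855, 410, 155))
}

#' Published annual claim weeks and costs
#'
#' Total weeks of work lost and total compensation paid per financial year
#' for the eight years with finalised cost data, with the printed integer
#' percentage shares of the grand totals.
#'
#' @return Data.frame with columns `fin_year`, `weeks`, `weeks_pct`,
#'   `cost`, `cost_pct`.
#' @export
published_time_cost <- function() {
  data.frame(
    fin_year = c("2013-14", "2014-15", "2015-16", "2016-17",
                 "2017-18", "2018-19", "2019-20", "2020-21"),
    weeks = c(55460, 54575, 63895, 66250, 72140, 65730, 66060, 58540),
    weeks_pct = c(11, 11, 13, 13, 14, 13, 13, 12),
    cost = c(167965000, 160655000, 222090000, 215060000,
             226480000, 198585000, 171384000, 144145000),
    cost_pct = c(11, 11, 15, 14, 15, 13, 11, 10))
}

#' Published serious-claim medians
#'
#' Median weeks of work lost and median compensation cost for serious
#' claims (five or more days lost), by financial year, plus the pooled
#' all-years row.
#'
#' @return Data.frame with columns `fin_year`, `median_weeks`,
#'   `median_cost`; last row is the pooled total.
#' @export
published_serious_medians <- function() {
  data.frame(
    fin_year = c("2013-14", "2014-15", "2015-16", "2016-17",
                 "2017-18", "2018-19", "2019-20", "2020-21", "total"),
    median_weeks = c(5.4, 5.2, 6, 6.5, 6.9, 6.4, 6.6, 6.8, 6.3),
    median_cost = c(9310, 8950, 11320, 12250, 13230, 12830, 12660, 12430,
                    11750))
}
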