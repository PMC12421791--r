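# Synthetic stand-ins for the two restricted data sources: case-level farm
# fatality records (coronial registry) and claim-level workers' compensation
# records. Generators are seeded and calibrated so that the aggregate
# structure of the published tables (agent mix, age bands, severity split,
# agency shares, weeks/cost medians) re-emerges from the synthetic streams.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Marginal distribution specification for one registry axis
#'
#' @param axis Axis name (e.g. `"work_status"`).
#' @param probs Named numeric vector of category probabilities; must be
#'   non-negative and sum to 1 within 1e-9.
#' @return An object of class `marginal_spec`.
#' @export
marginal_spec <- function(axis, probs) {
  stopifnot_msg(is.numeric(probs) && !is.null(names(probs)) &&
                  all(probs >= 0),
                "configuration error: probs must be a named non-negative vector")
  stopifnot_msg(abs(sum(probs) - 1) < 1e-9,
                sprintf("configuration error: probabilities on axis '%s' sum to %.12f, not 1",
                        axis, sum(probs)))
  structure(list(axis = axis, probs = probs), class = "marginal_spec")
}

sample_axis <- function(n, spec) {
  sample(names(spec$probs), n, replace = TRUE, prob = spec$probs)
}

#' Catalogue of fatality agent categories
#'
#' The packaged (agent group, agent) mapping, taken from the published
#' agent cross-tabulation, plus the unknown/unknown pair. Used both to
#' parameterise the generator and to validate records.
#'
#' @return Data.frame with columns `group`, `agent`, `total` (published
#'   per-agent case counts over 2013--2023).
#' @export
agent_catalogue <- function() {
  pub <- published_agent_counts()[, c("group", "agent", "total")]
  rbind(pub, data.frame(group = "unknown", agent = "unknown", total = 1))
}

#' Default fatality age bands
#'
#' @return Data.frame with `label`, `lower`, `upper` (inclusive integer
#'   bounds; the open-ended oldest band is truncated at 95 for sampling).
#' @export
age_bands <- function() {
  data.frame(label = c("<15", "15-24", "25-34", "35-44", "45-54", "55-64",
                       ">=65"),
             lower = c(0, 15, 25, 35, 45, 55, 65),
             upper = c(14, 24, 34, 44, 54, 64, 95))
}

#' Default marginal specification for the fatality generator
#'
#' Marginals mirror the published cohort: work status 544/203/1 of 748,
#' agents in proportion to the published per-agent totals (as consistent
#' group:agent pairs), ages in proportion to the published band counts, and
#' a sex mix conditional on work status (94% male among work-related; the
#' non-work male share is a documented configurable default, 75%, as the
#' source is silent).
#'
#' @param male_share Named numeric: probability a case is male, by work
#'   status.
#' @return List of `marginal_spec` objects plus `sex_by_work`, `year_range`
#'   and an occupation mix.
#' @export
default_fatality_spec <- function(male_share = c(work = 0.94,
                                                 non_work = 0.75,
                                                 unknown = 0.5)) {
  cat <- agent_catalogue()
  agent_probs <- stats::setNames(cat$total / sum(cat$total),
                                 paste(cat$group, cat$agent, sep = ":"))
  band <- age_bands()
  band_n <- c(87, 61, 68, 72, 99, 125, 236)
  list(work_status = marginal_spec("work_status",
                                   c(work = 544, non_work = 203,
                                     unknown = 1) / 748),
       agent = marginal_spec("agent", agent_probs),
       age_band = marginal_spec("age_band",
                                stats::setNames(band_n / sum(band_n),
                                                band$label)),
       sex_by_work = male_share,
       occupation = marginal_spec("occupation",
                                  c(`1211` = 0.35, `1212` = 0.08,
                                    `1213` = 0.08, `7331` = 0.05,
                                    `721` = 0.06, `8411` = 0.30,
                                    `3622` = 0.08)),
       year_range = c(2013, 2023))
}

#' Generate synthetic fatality cases
#'
#' Draws `n` case records with work status, agent (consistent with its
#' agent group), age band (uniform integer age within the band), sex and
#' calendar year sampled from the configured marginals. Occupation codes
#' are assigned to work-related cases aged 16 or over.
#'
#' @param n Number of cases; must be > 0.
#' @param seed Integer seed; the draw is fully reproducible given it.
#' @param spec Specification list as from [default_fatality_spec()].
#' @return Data.frame of fatality records: `case_id`, `year`, `age`, `sex`,
#'   `work_related`, `agent_group`, `agent`, `occupation_code`.
#' @export
#' @examples
#' cases <- generate_fatality_cases(100, seed = 1)
#' table(cases$work_related)
generate_fatality_cases <- function(n, seed = NULL,
                                    spec = default_fatality_spec()) {
  stopifnot_msg(is.numeric(n) && length(n) == 1 && n > 0,
                "input error: n must be a positive count")
  known_pairs <- paste(agent_catalogue()$group, agent_catalogue()$agent,
                       sep = ":")
  bad <- setdiff(names(spec$agent$probs), known_pairs)
  if (length(bad))
    stop(sprintf("configuration error: unknown agent categories in spec: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  bad_ws <- setdiff(names(spec$work_status$probs),
                    c("work", "non_work", "unknown"))
  if (length(bad_ws))
    stop(sprintf("configuration error: unknown work-status categories: %s",
                 paste(bad_ws, collapse = ", ")), call. = FALSE)
  with_seed(seed, {
    work <- sample_axis(n, spec$work_status)
    pair <- sample_axis(n, spec$agent)
    grp <- sub(":.*$", "", pair)
    agent <- sub("^[^:]*:", "", pair)
    band_lab <- sample_axis(n, spec$age_band)
    band <- age_bands()
    i <- match(band_lab, band$label)
    lo <- band$lower[i]; hi <- band$upper[i]
    age <- lo + floor(stats::runif(n) * (hi - lo + 1))
    p_male <- spec$sex_by_work[work]
    sex <- ifelse(stats::runif(n) < p_male, "male", "female")
    year <- sample(spec$year_range[1]:spec$year_range[2], n, replace = TRUE)
    occ <- rep(NA_character_, n)
    eligible <- work == "work" & age >= 16
    occ[eligible] <- sample_axis(sum(eligible), spec$occupation)
    data.frame(case_id = sprintf("F%05d", seq_len(n)),
               year = year, age = as.integer(age), sex = sex,
               work_related = work, agent_group = grp, agent = agent,
               occupation_code = occ, stringsAsFactors = FALSE)
  })
}

#' Financial-year labels and reporting periods
#'
#' The claims window spans nine financial years, split into two reporting
#' periods: 2013-14 to 2016-17 (four years) and 2017-18 to 2021-22 (five
#' years, the last provisional). Labels are opaque ordered categories.
#'
#' @return Character vector of the nine financial-year labels.
#' @export
fin_years <- function() {
  c("2013-14", "2014-15", "2015-16", "2016-17",
    "2017-18", "2018-19", "2019-20", "2020-21", "2021-22")
}

#' @rdname fin_years
#' @return `period_definitions()`: list of two periods, each with `label`,
#'   `fin_years` and `n_years`.
#' @export
period_definitions <- function() {
  fy <- fin_years()
  list(list(label = "2013-14 to 2016-17", fin_years = fy[1:4], n_years = 4L),
       list(label = "2017-18 to 2021-22", fin_years = fy[5:9], n_years = 5L))
}

#' Default annual claim volumes
#'
#' Published period totals divided over their member years: about 5,046
#' claims per year in the first period and 4,921 in the second (roughly
#' 5,000 per year throughout).
#'
#' @return Named integer vector over [fin_years()].
#' @export
default_claims_per_year <- function() {
  stats::setNames(c(rep(5046L, 4), rep(4921L, 5)), fin_years())
}

#' Default claim-generation specification
#'
#' Severity mix and agency shares are period-specific, taken from the
#' published period totals. Category axes without published cell values
#' (nature, mechanism, bodily location) use defaults constrained by the
#' published narrative shares (top three natures ~75% of claims, top three
#' mechanisms ~75%, upper limbs just under 40% and the top four body
#' locations over 90%). Weeks lost: minor claims uniform on \[0, 5/7)
#' weeks; serious claims lognormal with per-year target medians and a
#' heavy tail (`sdlog` 1.58) chosen so annual total weeks land near the
#' published ~63,000. Costs: serious claims follow
#' `base * weeks^elasticity * lognormal noise` with `base` solved per year
#' from the published median cost and median weeks; minor claims draw a
#' separate lognormal (median $2,500) so serious claims carry ~95% of all
#' cost.
#'
#' @return A list of generator settings; every element may be overridden.
#' @export
claim_spec <- function() {
  agency <- published_agency_counts()
  med <- published_serious_medians()
  med <- med[med$fin_year != "total", ]
  # provisional final year: carry the last published medians forward
  wk <- stats::setNames(c(med$median_weeks, 6.8), fin_years())
  ct <- stats::setNames(c(med$median_cost, 12430), fin_years())
  list(
    p_serious_by_period = c(10900 / 20185, 14385 / 24605),
    agency_by_period = list(
      marginal_spec("agency", stats::setNames(
        agency$p1_total / sum(agency$p1_total), agency$agency_group)),
      marginal_spec("agency", stats::setNames(
        agency$p2_total / sum(agency$p2_total), agency$agency_group))),
    nature = marginal_spec("nature", c(
      traumatic_joint_ligament_muscle = 0.33, wounds_lacerations = 0.25,
      fractures = 0.17, musculoskeletal_disease = 0.10, other = 0.15)),
    mechanism = marginal_spec("mechanism", c(
      hit_by_moving_object = 0.33, body_stressing = 0.25,
      falls_trips_slips = 0.17, hit_stationary_object = 0.08,
      vehicle_incident = 0.07, other = 0.10)),
    bodily_location = marginal_spec("bodily_location", c(
      upper_limbs = 0.38, lower_limbs = 0.24, trunk = 0.18, head = 0.12,
      multiple = 0.04, other = 0.04)),
    minor_weeks_max = 5 / 7,
    serious_weeks_median = wk,
    serious_weeks_sdlog = 1.58,
    cost_elasticity = 1,
    serious_cost_median = ct,
    cost_noise_sdlog = 0.94,
    minor_cost_median = 2500,
    minor_cost_sdlog = 1)
}

#' Generate synthetic workers' compensation claims
#'
#' Draws claim records year by year: severity and agency from the
#' period-specific mixes, category axes from their marginals, then weeks
#' lost and cost from the severity-specific models described in
#' [claim_spec()]. A claim is serious exactly when its weeks-lost
#' equivalent is at least 5/7 of a week (five working days).
#'
#' @param per_year Named vector of claim counts per financial year; names
#'   must be drawn from [fin_years()]. Must be non-negative.
#' @param seed Integer seed.
#' @param spec Settings list from [claim_spec()].
#' @return Data.frame of claims: `claim_id`, `fin_year`, `severity`,
#'   `agency_group`, `nature`, `mechanism`, `bodily_location`,
#'   `weeks_lost`, `cost`.
#' @export
generate_claims <- function(per_year = default_claims_per_year(),
                            seed = NULL, spec = claim_spec()) {
  stopifnot_msg(length(per_year) > 0 && !is.null(names(per_year)),
                "input error: per_year must be a named count vector")
  stopifnot_msg(all(per_year >= 0), "input error: negative claim rate")
  stopifnot_msg(all(names(per_year) %in% fin_years()),
                "configuration error: unknown financial-year label in per_year")
  periods <- period_definitions()
  with_seed(seed, {
    out <- lapply(names(per_year), function(fy) {
      n <- per_year[[fy]]
      if (n == 0) return(NULL)
      p_idx <- if (fy %in% periods[[1]]$fin_years) 1 else 2
      serious <- stats::runif(n) < spec$p_serious_by_period[p_idx]
      weeks <- numeric(n)
      weeks[!serious] <- stats::runif(sum(!serious), 0, spec$minor_weeks_max)
      weeks[serious] <- pmax(spec$minor_weeks_max,
                             stats::rlnorm(sum(serious),
                                           log(spec$serious_weeks_median[[fy]]),
                                           spec$serious_weeks_sdlog))
      cost <- numeric(n)
      base <- spec$serious_cost_median[[fy]] /
        spec$serious_weeks_median[[fy]]^spec$cost_elasticity
      cost[serious] <- base * weeks[serious]^spec$cost_elasticity *
        stats::rlnorm(sum(serious), 0, spec$cost_noise_sdlog)
      cost[!serious] <- stats::rlnorm(sum(!serious),
                                      log(spec$minor_cost_median),
                                      spec$minor_cost_sdlog)
      data.frame(fin_year = fy,
                 severity = ifelse(serious, "serious", "minor"),
                 agency_group = sample_axis(n, spec$agency_by_period[[p_idx]]),
                 nature = sample_axis(n, spec$nature),
                 mechanism = sample_axis(n, spec$mechanism),
                 bodily_location = sample_axis(n, spec$bodily_location),
                 weeks_lost = weeks, cost = cost,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    cbind(claim_id = sprintf("C%06d", seq_len(nrow(out))), out)
  })
}

registry_columns <- list(
  fatality = c("case_id", "year", "age", "sex", "work_related",
               "agent_group", "agent", "occupation_code"),
  claim = c("claim_id", "fin_year", "severity", "agency_group", "nature",
            "mechanism", "bodily_location", "weeks_lost", "cost"))

#' Write a registry to delimited text
#'
#' CSV, UTF-8, header row, fixed column order. Real-valued columns are
#' written with 17 significant digits so that a read/write round trip is
#' an exact identity, and output is byte-identical across runs for the
#' same records.
#'
#' @param records Data.frame of fatality or claim records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(records, path) {
  type <- registry_type(records)
  records <- records[, registry_columns[[type]]]
  for (col in names(records)) {
    if (is.double(records[[col]]))
      records[[col]] <- sprintf("%.17g", records[[col]])
  }
  utils::write.table(records, path, sep = ",", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

registry_type <- function(records) {
  for (type in names(registry_columns)) {
    if (all(registry_columns[[type]] %in% names(records))) return(type)
  }
  stop("input error: records match neither registry schema", call. = FALSE)
}

#' Read a registry written by [write_registry()]
#'
#' Every row is validated against the type invariants; a malformed row
#' raises a parse error naming the offending line (line 1 is the header)
#' and value.
#'
#' @param path CSV path.
#' @param type `"fatality"` or `"claim"`.
#' @param year_range Allowed calendar-year window for fatality records.
#' @return Validated data.frame of records.
#' @export
read_registry <- function(path, type = c("fatality", "claim"),
                          year_range = c(2013, 2023)) {
  type <- match.arg(type)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(registry_columns[[type]], names(df))
  if (length(missing_cols))
    stop(sprintf("parse error: missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  fail <- function(rows, what, values) {
    stop(sprintf("parse error at line %s: %s (got %s)",
                 paste(line[rows], collapse = ", "), what,
                 paste(unique(values), collapse = ", ")), call. = FALSE)
  }
  if (type == "fatality") {
    df$occupation_code <- as.character(df$occupation_code)
    bad <- which(is.na(df$age) | df$age < 0)
    if (length(bad)) fail(bad, "age must be a non-negative integer",
                          df$age[bad])
    bad <- which(df$year < year_range[1] | df$year > year_range[2])
    if (length(bad)) fail(bad, "year outside configured window",
                          df$year[bad])
    bad <- which(!df$sex %in% c("male", "female"))
    if (length(bad)) fail(bad, "unknown sex", df$sex[bad])
    bad <- which(!df$work_related %in% c("work", "non_work", "unknown"))
    if (length(bad)) fail(bad, "unknown work_related value",
                          df$work_related[bad])
    cat <- agent_catalogue()
    pair <- paste(df$agent_group, df$agent, sep = ":")
    bad <- which(!pair %in% paste(cat$group, cat$agent, sep = ":"))
    if (length(bad)) fail(bad, "agent inconsistent with agent_group",
                          pair[bad])
  } else {
    bad <- which(!df$fin_year %in% fin_years())
    if (length(bad)) fail(bad, "unknown financial year", df$fin_year[bad])
    bad <- which(!df$severity %in% c("minor", "serious"))
    if (length(bad)) fail(bad, "unknown severity", df$severity[bad])
    known <- published_agency_counts()$agency_group
    bad <- which(!df$agency_group %in% known)
    if (length(bad)) fail(bad, "unknown agency_group", df$agency_group[bad])
    bad <- which(is.na(df$weeks_lost) | df$weeks_lost < 0)
    if (length(bad)) fail(bad, "weeks_lost must be >= 0", df$weeks_lost[bad])
    bad <- which(is.na(df$cost) | df$cost < 0)
    if (length(bad)) fail(bad, "cost must be >= 0", df$cost[bad])
    thresh <- 5 / 7
    bad <- which((df$severity == "minor") != (df$weeks_lost < thresh))
    if (length(bad)) fail(bad, "severity inconsistent with weeks_lost",
                          df$severity[bad])
  }
  df
}
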