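#' Demo pipeline configuration
#'
#' A complete run configuration at the scale of the published study: 748
#' fatality cases over 2013--2023 and roughly 5,000 compensation claims
#' per year over nine financial years.
#'
#' @param seed Integer seed driving every random draw.
#' @param out_dir Output directory for the report set.
#' @return A named list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1, out_dir = tempfile("farmburden_run_")) {
  list(seed = seed,
       n_fatalities = 748,
       claims_per_year = default_claims_per_year(),
       fatality_spec = default_fatality_spec(),
       claim_spec = claim_spec(),
       params = cost_parameters(),
       life_table = default_life_table(),
       earnings = default_earnings_schedule(),
       cpi = default_cpi(),
       periods = period_definitions(),
       suppression_threshold = 5,
       count_multiple = 5,
       money_multiple = 5000,
       out_dir = out_dir)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config),
                                    c("out_dir", "life_table"))]), f)
  unname(tools::md5sum(f))
}

#' Run the full burden-analysis pipeline
#'
#' Simulate registries, cost every fatality, build all summary tables,
#' apply disclosure masking to the agent cross-tabulation, and write the
#' report set: six table analogues, the per-case cost CSV and a run log,
#' plus the two input registries and a JSON manifest. Reruns with the same
#' configuration are byte-identical.
#'
#' @param config Configuration list (see [demo_config()]).
#' @return The manifest (named list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config = demo_config()) {
  stopifnot_msg(!is.null(config$seed),
                "configuration error: seed is mandatory for simulation")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("config_hash: %s", config_hash(config)),
                 sprintf("package: farmburden %s",
                         as.character(utils::packageVersion("farmburden"))))

  # simulate
  cases <- generate_fatality_cases(config$n_fatalities, config$seed,
                                   config$fatality_spec)
  claims <- generate_claims(config$claims_per_year, config$seed + 1,
                            config$claim_spec)
  write_registry(cases, out("fatality_registry.csv"))
  write_registry(claims, out("claims_registry.csv"))
  log_lines <- c(log_lines,
                 sprintf("fatalities: %d", nrow(cases)),
                 sprintf("claims: %d", nrow(claims)))

  # cost
  for (y in unique(cases$year)) {
    if (!as.character(y) %in% names(config$cpi))
      stop(sprintf("configuration error: CPI series has no entry for year %s", y),
           call. = FALSE)
  }
  breakdowns <- cost_cases(cases, config$life_table, config$earnings,
                           config$cpi, config$params)
  utils::write.csv(round(breakdowns[, -1], 2), row.names = FALSE,
                   file = out("case_costs.csv"))

  # tabulate + mask
  xt <- apply_masking(crosstab_fatalities(cases),
                      config$suppression_threshold)
  writeLines(render_table(xt, "csv"), out("table_agents_by_workstatus.csv"))
  utils::write.csv(age_band_cost_summary(cases, breakdowns,
                                         money_multiple = config$money_multiple),
                   out("table_age_band_costs.csv"), row.names = FALSE)
  utils::write.csv(claims_period_summary(claims, config$periods,
                                         count_multiple = config$count_multiple),
                   out("table_claims_by_severity.csv"), row.names = FALSE)
  utils::write.csv(claims_agency_summary(claims, config$periods,
                                         count_multiple = config$count_multiple),
                   out("table_claims_by_agency.csv"), row.names = FALSE)
  tc <- claims_time_cost_by_year(claims, config$periods)
  tc$weeks <- round_to_multiple(tc$weeks, config$count_multiple)
  tc$cost <- round_to_multiple(tc$cost, config$money_multiple)
  utils::write.csv(tc, out("table_time_cost_by_year.csv"), row.names = FALSE)
  med <- serious_claim_medians(claims)
  med$median_weeks <- round(med$median_weeks, 1)
  med$median_cost <- round_to_multiple(med$median_cost, 10)
  utils::write.csv(med, out("table_serious_medians.csv"), row.names = FALSE)

  writeLines(log_lines, out("run.log"))
  artifacts <- c("table_agents_by_workstatus.csv",
                 "table_age_band_costs.csv",
                 "table_claims_by_severity.csv",
                 "table_claims_by_agency.csv",
                 "table_time_cost_by_year.csv",
                 "table_serious_medians.csv",
                 "case_costs.csv", "run.log")
  manifest <- list(seed = config$seed,
                   config_hash = config_hash(config),
                   inputs = c("fatality_registry.csv",
                              "claims_registry.csv"),
                   artifacts = artifacts,
                   artifact_md5 = as.list(tools::md5sum(
                     vapply(artifacts, out, character(1)))))
  names(manifest$artifact_md5) <- artifacts
  jsonlite::write_json(manifest, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Replay the arithmetic connecting the published figures
#'
#' Recomputes, from the packaged published table values, every piece of
#' arithmetic that links them -- proportions, divide-and-round averages,
#' annual means under nearest-multiple rounding, additive totals, and the
#' coverage-scaled annual figure -- and compares each against the printed
#' value. Twelve checks in total; all pass with the publication rounding
#' conventions (counts to 5, monetary summaries to 5,000, narrative grand
#' totals to 5,000,000).
#'
#' @param count_multiple Rounding multiple for counts and annual means
#'   (publication convention 5).
#' @param money_multiple Rounding multiple for monetary averages and
#'   totals (publication convention 5,000).
#' @param quiet Suppress the printed report.
#' @return Data.frame with columns `check`, `expected`, `computed`,
#'   `pass`, invisibly when `quiet = FALSE`.
#' @export
verify_published_figures <- function(count_multiple = 5,
                                     money_multiple = 5000,
                                     quiet = FALSE) {
  hl <- published_headlines()
  agents <- published_agent_counts()
  age <- published_age_band_costs()
  cc <- published_claim_counts()
  ag <- published_agency_counts()
  tc <- published_time_cost()

  checks <- list()
  add <- function(check, expected, computed) {
    checks[[length(checks) + 1]] <<- data.frame(
      check = check, expected = expected, computed = computed,
      pass = isTRUE(all.equal(expected, computed)))
  }

  add("work-related share of fatalities (%)", 73,
      percent_share(hl$n_work, hl$n_work + hl$n_nonwork + hl$n_unknown))
  add("male share of work-related fatalities (%)", 94,
      percent_share(hl$n_male_work, hl$n_work))
  add("share of six leading agents (%)", 52,
      percent_share(sum(agents$total[agents$agent %in% hl$top6_agents]),
                    hl$n_total))
  add("agent totals reconcile to group and grand totals", 748,
      sum(agents$total) + hl$n_unknown)
  band <- age[age$band != "total", ]
  add("all seven age-band averages reproduce under divide-and-round", 7,
      sum(round_to_multiple(band$total / band$n, money_multiple) ==
            band$average))
  add("overall average fatality cost ($)", 2380000,
      round_to_multiple(1.78e9 / hl$n_total, money_multiple))
  add("severity-by-period annual means reproduce under nearest-5 rounding", 4,
      {sev <- cc[cc$severity != "all", ]
       sum(round_to_multiple(sev$total / sev$n_years, count_multiple) ==
             sev$annual_mean)})
  # the source's own footnote: totals may not align exactly as all figures
  # are rounded -- additivity holds within one rounding multiple per period
  add("severity totals additive within the rounding convention", 2,
      {per <- split(cc, cc$period)
       sum(vapply(per, function(p)
         abs(sum(p$total[p$severity != "all"]) -
               p$total[p$severity == "all"]) <= count_multiple,
         logical(1)))})
  add("agency percentages: environmental row and column sums", 3,
      {p1 <- percent_share(ag$p1_total[ag$agency_group == "environmental"],
                           20185)
       m1 <- round_to_multiple(
         ag$p1_total[ag$agency_group == "environmental"] / 4, count_multiple)
       colsum_ok <- abs(sum(ag$p1_pct) - 100) <= 1 &&
         abs(sum(ag$p2_pct) - 100) <= 1
       sum(p1 == 15, m1 == 765, colsum_ok)})
  add("annual weeks sum to the printed grand total", 502650, sum(tc$weeks))
  add("annual costs sum to the printed sub- and grand totals", 3,
      {p1 <- sum(tc$cost[1:4]); p2 <- sum(tc$cost[5:8])
       grand <- round_to_multiple(p1 + p2, 5e6)
       sum(p1 == 765770000,
           round_to_multiple(p2, money_multiple) == 740595000,
           grand == 1.505e9)})
  add("narrative annual figures (fatal, coverage-adjusted, combined)", 3,
      {fatal_m <- annualise(hl$fatal_total_cost, hl$fatal_years, 1e6) / 1e6
       claims_m <- round_to_multiple(
         hl$claims_total_cost / hl$claims_cost_years / 1e6, count_multiple)
       adj_m <- adjust_for_coverage(claims_m, cost_parameters(),
                                    multiple = count_multiple)
       comb_m <- round_to_multiple(fatal_m + claims_m, count_multiple)
       sum(fatal_m == 164, adj_m == hl$coverage_adjusted_annual_m,
           comb_m == hl$combined_annual_m)})

  out <- do.call(rbind, checks)
  if (!quiet) {
    cat(sprintf("%-62s %10s %10s %s\n", "check", "expected", "computed",
                "pass"))
    for (i in seq_len(nrow(out)))
      cat(sprintf("%-62s %10s %10s %s\n", out$check[i],
                  format(out$expected[i]), format(out$computed[i]),
                  if (out$pass[i]) "ok" else "FAIL"))
    cat(sprintf("%d/%d checks pass\n", sum(out$pass), nrow(out)))
  }
  invisible(out)
}
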