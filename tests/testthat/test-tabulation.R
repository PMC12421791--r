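test_that("integer percentage shares use half-up rounding", {
  expect_equal(percent_share(544, 748), 73)
  expect_equal(percent_share(513, 544), 94)
  expect_equal(percent_share(0, 748), 0)
  expect_equal(percent_share(1, 200), 1)   # 0.5% rounds up
  expect_error(percent_share(1, 0), "whole")
  expect_error(percent_share(5, 3), "part")
})

test_that("the agent cross-tab reconciles with the published structure", {
  # cohort rebuilt from the published per-agent totals (all visible), with
  # one unknown case carried in the grand total only
  pub <- published_agent_counts()
  cases <- data.frame(
    case_id = sprintf("P%03d", seq_len(sum(pub$total) + 1)),
    agent_group = c(rep(pub$group, pub$total), "unknown"),
    agent = c(rep(pub$agent, pub$total), "unknown"),
    work_related = c(rep("work", sum(pub$total)), "unknown"))
  xt <- crosstab_fatalities(cases)
  expect_equal(xt$grand_total, 748)
  expect_equal(sum(xt$true), 747)
  group_tot <- tapply(rowSums(xt$true), xt$row_groups, sum)
  expect_equal(group_tot[["farm_vehicles"]], 327)
  expect_equal(group_tot[["mobile_machinery"]], 206)
  expect_equal(group_tot[["animal"]], 55)

  empty <- crosstab_fatalities(cases[0, ])
  expect_true(all(empty$true == 0))
  expect_equal(empty$grand_total, 0)
})

test_that("the six leading agents carry about half of synthetic fatalities", {
  cases <- generate_fatality_cases(20000, seed = 7)
  top6 <- published_headlines()$top6_agents
  share <- 100 * mean(cases$agent %in% top6 &
                        cases$agent_group %in%
                          c("farm_vehicles", "mobile_machinery", "animal"))
  expect_lt(abs(share - 52), 2)
})

test_that("age-band cost summaries sum, average and round correctly", {
  cases <- data.frame(case_id = c("a", "b", "c"),
                      age = c(10, 12, 40))
  bd <- data.frame(case_id = c("a", "b", "c"),
                   total = c(1e6, 2e6, 3e6))
  s <- age_band_cost_summary(cases, bd)
  expect_equal(s$n[s$band == "<15"], 2)
  expect_equal(s$total[s$band == "<15"], 3e6)
  expect_equal(s$average[s$band == "<15"], 1.5e6)
  expect_equal(s$average[s$band == "35-44"], 3e6)  # single case: total = avg
  expect_true(is.na(s$average[s$band == "55-64"])) # empty band: absent
  expect_equal(s$total[s$band == "total"], 6e6)
  # publication rounding reproduces the printed <15 average from (n, total)
  r <- age_band_cost_summary(
    data.frame(case_id = as.character(1:87), age = rep(5, 87)),
    data.frame(case_id = as.character(1:87),
               total = c(rep(172540000 / 87, 87))),
    money_multiple = 5000)
  expect_equal(r$average[r$band == "<15"], 1985000)
})

test_that("claims period summaries match a naive full-scan recomputation", {
  claims <- generate_claims(stats::setNames(rep(120L, 9), fin_years()),
                            seed = 4)
  periods <- period_definitions()
  ps <- claims_period_summary(claims, periods)
  ag <- claims_agency_summary(claims, periods)
  for (k in 1:2) {
    in_p <- claims$fin_year %in% periods[[k]]$fin_years
    for (sev in c("minor", "serious")) {
      naive <- sum(in_p & claims$severity == sev)
      expect_equal(ps$total[ps$period == periods[[k]]$label &
                              ps$severity == sev], naive)
      expect_equal(ps$annual_mean[ps$period == periods[[k]]$label &
                                    ps$severity == sev],
                   naive / periods[[k]]$n_years)
    }
    for (g in unique(claims$agency_group)) {
      naive <- sum(in_p & claims$agency_group == g)
      expect_equal(ag$total[ag$period == periods[[k]]$label &
                              ag$agency_group == g], naive)
    }
    pct <- ag$percent[ag$period == periods[[k]]$label]
    expect_lte(abs(sum(pct) - 100), 1)
  }
  # a single agency group takes 100% of its period
  mono <- claims
  mono$agency_group <- "chemicals"
  agm <- claims_agency_summary(mono, periods)
  expect_equal(agm$percent[agm$agency_group == "chemicals"], c(100, 100))
})

test_that("annual means round to the publication multiple at render", {
  one <- generate_claims(c(`2013-14` = 1), seed = 6)
  ps <- claims_period_summary(one, count_multiple = 5)
  expect_equal(ps$total[ps$severity == "all" &
                          ps$period == "2013-14 to 2016-17"], 1)
  # one claim over a four-year period: mean 0.25 rounds to 0
  expect_equal(ps$annual_mean[ps$severity == "all" &
                                ps$period == "2013-14 to 2016-17"], 0)
})

test_that("time/cost by year is additive with subtotals and percentages", {
  claims <- generate_claims(stats::setNames(rep(150L, 9), fin_years()),
                            seed = 8)
  tc <- claims_time_cost_by_year(claims)
  years <- tc[!grepl("subtotal|total", tc$row), ]
  subs <- tc[grepl("^subtotal", tc$row), ]
  grand <- tc[tc$row == "total", ]
  expect_equal(sum(years$weeks), grand$weeks)
  expect_equal(sum(subs$weeks), grand$weeks)
  expect_equal(sum(subs$cost), grand$cost)
  expect_equal(grand$weeks_pct, 100)
  expect_equal(grand$cost_pct, 100)
  # naive oracle per year
  for (fy in unique(claims$fin_year)) {
    expect_equal(years$weeks[years$row == fy],
                 sum(claims$weeks_lost[claims$fin_year == fy]))
  }
  # all claims in one year: that year carries 100% of both columns
  one_year <- claims[claims$fin_year == "2013-14", ]
  tc1 <- claims_time_cost_by_year(one_year)
  expect_equal(tc1$weeks_pct[tc1$row == "2013-14"], 100)
  expect_equal(tc1$cost_pct[tc1$row == "2013-14"], 100)
})

test_that("serious-claim medians use the midpoint convention and pool claims", {
  claims <- data.frame(
    claim_id = sprintf("c%d", 1:5),
    fin_year = c("2013-14", "2013-14", "2013-14", "2014-15", "2014-15"),
    severity = c("serious", "serious", "serious", "serious", "minor"),
    agency_group = "chemicals", nature = "other", mechanism = "other",
    bodily_location = "other",
    weeks_lost = c(4, 6, 9, 2, 0.1),
    cost = c(100, 200, 300, 400, 5))
  med <- serious_claim_medians(claims)
  expect_equal(med$median_weeks[med$fin_year == "2013-14"], 6)
  expect_equal(med$median_cost[med$fin_year == "2014-15"], 400)  # single claim
  # pooled row is the median of pooled values, not the mean of medians
  expect_equal(med$median_weeks[med$fin_year == "total"],
               stats::median(c(4, 6, 9, 2)))
  expect_equal(med$median_cost[med$fin_year == "total"], (200 + 300) / 2)
})
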