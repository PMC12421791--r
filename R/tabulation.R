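#' Integer percentage share
#'
#' `100 * part / whole` rounded half-up to the nearest integer, the
#' convention used throughout the published tables.
#'
#' @param part,whole Non-negative counts, `part <= whole`, `whole > 0`.
#' @return Integer percentage.
#' @export
#' @examples
#' percent_share(544, 748)  # 73
percent_share <- function(part, whole) {
  stopifnot_msg(all(whole > 0), "input error: whole must be > 0")
  stopifnot_msg(all(part <= whole) && all(part >= 0),
                "input error: part must lie in [0, whole]")
  floor(100 * part / whole + 0.5)
}

#' Cross-tabulate fatalities by agent and work status
#'
#' Counts cases by (agent, work status), with agents ordered and grouped
#' by the packaged agent catalogue so group subtotals can be rendered.
#' Cases of unknown work status are carried in the grand total only.
#' Masking is not applied here; pass the result through [apply_masking()].
#'
#' @param cases Data.frame of fatality records.
#' @return A [masked_table()] (all cells visible) with row groups.
#' @export
crosstab_fatalities <- function(cases) {
  cat <- agent_catalogue()
  cat <- cat[cat$group != "unknown", ]
  rows <- paste(cat$group, cat$agent, sep = ":")
  statuses <- c("non_work", "work")
  m <- matrix(0L, nrow(cat), length(statuses),
              dimnames = list(cat$agent, statuses))
  known <- cases[cases$work_related %in% statuses &
                   cases$agent_group != "unknown", ]
  if (nrow(known)) {
    tab <- table(paste(known$agent_group, known$agent, sep = ":"),
                 known$work_related)
    idx <- match(rownames(tab), rows)
    for (j in intersect(colnames(tab), statuses))
      m[idx[!is.na(idx)], j] <- tab[!is.na(idx), j]
  }
  extra <- nrow(cases) - sum(m)
  masked_table(m, row_groups = cat$group, extra_total = extra)
}

#' Age-band cost summary for a fatality cohort
#'
#' Joins per-case cost breakdowns to their cases and summarises by age
#' band: case count, summed total cost and the average cost per fatality
#' (total divided by count). Values are unrounded; rounding to the
#' publication multiple happens only at render via `money_multiple`.
#'
#' @param cases Data.frame of fatality records.
#' @param breakdowns Data.frame from [cost_cases()] with `case_id` and
#'   `total`.
#' @param bands Age-band definition (see [age_bands()]).
#' @param money_multiple If non-`NULL`, round `total` and `average` to this
#'   multiple (publication default 5,000).
#' @return Data.frame `band`, `n`, `total`, `average` plus an overall row;
#'   empty bands report `NA` averages.
#' @export
age_band_cost_summary <- function(cases, breakdowns, bands = age_bands(),
                                  money_multiple = NULL) {
  stopifnot_msg(all(cases$case_id %in% breakdowns$case_id),
                "every case needs a cost breakdown")
  cost <- breakdowns$total[match(cases$case_id, breakdowns$case_id)]
  band_of <- cut(cases$age, breaks = c(bands$lower, Inf), right = FALSE,
                 labels = bands$label)
  n <- as.vector(table(band_of))
  tot <- as.vector(tapply(cost, band_of, sum, default = 0))
  out <- data.frame(band = c(bands$label, "total"),
                    n = c(n, length(cost)),
                    total = c(tot, sum(cost)),
                    average = NA_real_)
  out$average <- ifelse(out$n > 0, out$total / out$n, NA_real_)
  if (!is.null(money_multiple)) {
    out$total <- round_to_multiple(out$total, money_multiple)
    out$average <- ifelse(is.na(out$average), NA,
                          round_to_multiple(out$average, money_multiple))
  }
  out
}

claim_period_index <- function(claims, periods) {
  idx <- rep(NA_integer_, nrow(claims))
  for (k in seq_along(periods))
    idx[claims$fin_year %in% periods[[k]]$fin_years] <- k
  if (anyNA(idx))
    message(sum(is.na(idx)), " claims fall outside all periods and were excluded")
  idx
}

#' Claim counts by severity and period
#'
#' Totals and annual means (total / years in period) by severity within
#' each reporting period, plus all-severity rows. Annual means are
#' computed from unrounded totals; `count_multiple` rounds them at render
#' (publication default 5).
#'
#' @param claims Data.frame of claim records.
#' @param periods Period definitions (see [period_definitions()]).
#' @param count_multiple Rounding multiple for the annual mean, or `NULL`.
#' @return Data.frame `period`, `severity`, `total`, `annual_mean`.
#' @export
claims_period_summary <- function(claims, periods = period_definitions(),
                                  count_multiple = NULL) {
  idx <- claim_period_index(claims, periods)
  keep <- !is.na(idx)
  claims <- claims[keep, ]; idx <- idx[keep]
  rows <- list()
  for (k in seq_along(periods)) {
    in_p <- idx == k
    for (sev in c("minor", "serious", "all")) {
      n <- if (sev == "all") sum(in_p)
           else sum(in_p & claims$severity == sev)
      rows[[length(rows) + 1]] <-
        data.frame(period = periods[[k]]$label, severity = sev,
                   total = n, annual_mean = n / periods[[k]]$n_years)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(count_multiple))
    out$annual_mean <- round_to_multiple(out$annual_mean, count_multiple)
  out
}

#' Claim counts by agency group and period
#'
#' Per-period totals, integer percentage shares of the period total and
#' annual means for the nine agency-of-injury major groups.
#'
#' @inheritParams claims_period_summary
#' @return Data.frame `period`, `agency_group`, `total`, `percent`,
#'   `annual_mean`.
#' @export
claims_agency_summary <- function(claims, periods = period_definitions(),
                                  count_multiple = NULL) {
  known <- published_agency_counts()$agency_group
  bad <- setdiff(unique(claims$agency_group), known)
  if (length(bad))
    stop(sprintf("unknown agency group(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  idx <- claim_period_index(claims, periods)
  keep <- !is.na(idx)
  claims <- claims[keep, ]; idx <- idx[keep]
  rows <- list()
  for (k in seq_along(periods)) {
    in_p <- idx == k
    period_total <- sum(in_p)
    for (g in known) {
      n <- sum(in_p & claims$agency_group == g)
      rows[[length(rows) + 1]] <-
        data.frame(period = periods[[k]]$label, agency_group = g,
                   total = n,
                   percent = if (period_total > 0)
                     percent_share(n, period_total) else NA,
                   annual_mean = n / periods[[k]]$n_years)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(count_multiple))
    out$annual_mean <- round_to_multiple(out$annual_mean, count_multiple)
  out
}

#' Annual weeks-lost and cost totals with sub-period subtotals
#'
#' Sums weeks lost and compensation cost per financial year, appends a
#' subtotal row per reporting period and a grand-total row, and expresses
#' each year as an integer percentage of the grand totals (weeks and cost
#' percentaged separately).
#'
#' @inheritParams claims_period_summary
#' @return Data.frame `row` (fin year, `subtotal:<label>` or `total`),
#'   `weeks`, `weeks_pct`, `cost`, `cost_pct`.
#' @export
claims_time_cost_by_year <- function(claims, periods = period_definitions()) {
  idx <- claim_period_index(claims, periods)
  keep <- !is.na(idx)
  claims <- claims[keep, ]; idx <- idx[keep]
  grand_w <- sum(claims$weeks_lost); grand_c <- sum(claims$cost)
  rows <- list()
  for (k in seq_along(periods)) {
    sub_w <- 0; sub_c <- 0
    for (fy in periods[[k]]$fin_years) {
      in_y <- claims$fin_year == fy
      if (!any(in_y)) next
      w <- sum(claims$weeks_lost[in_y]); cst <- sum(claims$cost[in_y])
      sub_w <- sub_w + w; sub_c <- sub_c + cst
      rows[[length(rows) + 1]] <- data.frame(
        row = fy, weeks = w,
        weeks_pct = percent_share_safe(w, grand_w),
        cost = cst, cost_pct = percent_share_safe(cst, grand_c))
    }
    rows[[length(rows) + 1]] <- data.frame(
      row = paste0("subtotal:", periods[[k]]$label), weeks = sub_w,
      weeks_pct = percent_share_safe(sub_w, grand_w),
      cost = sub_c, cost_pct = percent_share_safe(sub_c, grand_c))
  }
  rows[[length(rows) + 1]] <- data.frame(
    row = "total", weeks = grand_w, weeks_pct = 100,
    cost = grand_c, cost_pct = 100)
  do.call(rbind, rows)
}

percent_share_safe <- function(part, whole) {
  if (whole <= 0) return(NA_real_)
  floor(100 * part / whole + 0.5)
}

#' Median weeks and cost of serious claims by year
#'
#' Medians (midpoint convention for even counts, via [stats::median()])
#' of weeks lost and cost over serious claims only, per financial year,
#' plus a pooled all-years row computed over the pooled claim-level
#' values. Years without serious claims are absent.
#'
#' @param claims Data.frame of claim records.
#' @return Data.frame `fin_year`, `n`, `median_weeks`, `median_cost`;
#'   last row `"total"` is the pooled median.
#' @export
serious_claim_medians <- function(claims) {
  s <- claims[claims$severity == "serious", ]
  years <- intersect(fin_years(), unique(s$fin_year))
  rows <- lapply(years, function(fy) {
    x <- s[s$fin_year == fy, ]
    data.frame(fin_year = fy, n = nrow(x),
               median_weeks = stats::median(x$weeks_lost),
               median_cost = stats::median(x$cost))
  })
  rows[[length(rows) + 1]] <- data.frame(
    fin_year = "total", n = nrow(s),
    median_weeks = stats::median(s$weeks_lost),
    median_cost = stats::median(s$cost))
  do.call(rbind, rows)
}
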