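# Independent oracles used across the suite: a straight-loop recomputation
# of the per-case valuation, and a brute-force enumeration of masked-table
# completions for the disclosure-safety checks. Both are written against
# the declared rules, not against the package internals they check.

oracle_case_cost <- function(case, lt, es, cpi, params) {
  code <- case$occupation_code
  wage <- if (!is.null(code) && !is.na(code) &&
              as.character(code) %in% names(es$by_code))
    es$by_code[[as.character(code)]] else es$default_earnings
  fte_at <- function(a) {
    if (a < params$fte_entry_age) 0
    else if (a <= 71) params$fte_full
    else if (a >= 76) 0
    else params$fte_taper[[as.character(a)]]
  }
  e <- if (case$sex == "male") lt$male[lt$age == min(case$age, max(lt$age))]
       else lt$female[lt$age == min(case$age, max(lt$age))]
  pe <- 0
  for (t in seq_len(ceiling(e))) {
    pe <- pe + wage * (1 + params$wage_growth)^(t - 1) *
      fte_at(case$age + t) / (1 + params$discount_rate)^t
  }
  end_age <- if (case$sex == "male") params$hp_end_age_male
             else params$hp_end_age_female
  hp <- 0
  y <- max(case$age + 1, params$hp_start_age)
  while (y <= end_age) {
    hp <- hp + params$hp_annual_value /
      (1 + params$discount_rate)^(y - case$age)
    y <- y + 1
  }
  fr <- wage * params$friction_fraction
  fx <- sum(params$fixed_costs)
  cp <- if (identical(case$work_related, "work")) params$compensation_payout
        else 0
  ratio <- cpi[[as.character(params$base_year)]] /
    cpi[[as.character(case$year)]]
  (pe + hp + fr + fx + cp) * ratio
}

random_cases <- function(n, seed) {
  set.seed(seed)
  data.frame(
    case_id = sprintf("R%04d", seq_len(n)),
    year = sample(2013:2023, n, replace = TRUE),
    age = sample(0:95, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    work_related = sample(c("work", "non_work"), n, replace = TRUE),
    agent_group = "animal", agent = "horse",
    occupation_code = sample(c("1211", "8411", NA), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# All non-negative integer completions of a masked table's hidden cells
# consistent with the visible cells and the true row/column totals, under
# attacker knowledge: an np cell held 1..threshold-1 and a plus cell held
# a value that was never suppressed (0 or >= threshold). Returns, per np
# cell, the set of values it takes across feasible completions.
np_feasible_values <- function(mt, threshold = 5) {
  masked <- which(mt$mask != "visible", arr.ind = TRUE)
  if (nrow(masked) == 0) return(list())
  vis <- mt$true
  vis[mt$mask != "visible"] <- 0
  row_res <- mt$row_totals - rowSums(vis)
  col_res <- mt$col_totals - colSums(vis)
  np_idx <- which(mt$mask[masked] == "np")
  found <- vector("list", length(np_idx))
  recurse <- function(k, row_res, col_res, assigned) {
    if (k > nrow(masked)) {
      if (all(row_res == 0) && all(col_res == 0)) {
        for (j in seq_along(np_idx)) {
          found[[j]] <<- union(found[[j]], assigned[np_idx[j]])
        }
      }
      return(invisible())
    }
    i <- masked[k, 1]; j <- masked[k, 2]
    upper <- min(row_res[i], col_res[j])
    if (upper < 0) return(invisible())
    vals <- 0:upper
    # the last unassigned cell of a line is forced to the line residual
    if (k < nrow(masked)) {
      later <- masked[(k + 1):nrow(masked), , drop = FALSE]
      if (!any(later[, 1] == i)) vals <- vals[vals == row_res[i]]
      if (!any(later[, 2] == j)) vals <- vals[vals == col_res[j]]
    } else {
      vals <- vals[vals == row_res[i] & vals == col_res[j]]
    }
    if (mt$mask[masked[k, 1], masked[k, 2]] == "np") {
      vals <- vals[vals >= 1 & vals <= threshold - 1]
    } else {
      vals <- vals[vals == 0 | vals >= threshold]
    }
    for (v in vals) {
      row_res[i] <- row_res[i] - v
      col_res[j] <- col_res[j] - v
      assigned[k] <- v
      recurse(k + 1, row_res, col_res, assigned)
      row_res[i] <- row_res[i] + v
      col_res[j] <- col_res[j] + v
    }
  }
  recurse(1, row_res, col_res, integer(nrow(masked)))
  found
}

expect_no_np_recoverable <- function(mt, threshold = 5) {
  vals <- np_feasible_values(mt, threshold)
  for (v in vals) {
    expect_gt(length(v), 1)
  }
  invisible(vals)
}
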