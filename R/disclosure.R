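#' Round to the nearest multiple
#'
#' Nearest-multiple rounding as used in published surveillance tables
#' (counts and annual means to 5, monetary summaries to 5,000, narrative
#' grand totals to 5,000,000). Ties round away from zero. Idempotent on
#' exact multiples.
#'
#' @param x Numeric value(s).
#' @param m Positive rounding multiple.
#' @return Integer-valued numeric: the nearest multiple of `m`.
#' @export
#' @examples
#' round_to_multiple(14385 / 5, 5)   # 2875
#' round_to_multiple(7, 5)           # 5
round_to_multiple <- function(x, m) {
  stopifnot_msg(is.numeric(m) && length(m) == 1 && m > 0,
                "input error: rounding multiple must be > 0")
  sign(x) * m * floor(abs(x) / m + 0.5)
}

#' Construct a masked cross-tabulation
#'
#' A `masked_table` holds the true (pre-mask) cell counts together with a
#' parallel mask matrix whose entries are `"visible"`, `"np"` (suppressed
#' small cell) or `"plus"` (complementary mask). Row, column and grand
#' totals are always computed from the true values and retained internally,
#' so published totals remain exact regardless of masking.
#'
#' @param true Non-negative integer matrix of counts with dimnames.
#' @param rounding_multiple Multiple applied to displayed values at render
#'   time (1 = no rounding).
#' @param row_groups Optional character vector, one entry per row, naming a
#'   higher-level grouping used for subtotal rows at render.
#' @param extra_total Count added to the grand total only (e.g. cases whose
#'   classifying variable is unknown and which appear in no cell).
#' @return An object of class `masked_table`.
#' @export
masked_table <- function(true, rounding_multiple = 1, row_groups = NULL,
                         extra_total = 0) {
  stopifnot_msg(is.matrix(true) && all(true >= 0),
                "input error: counts must form a non-negative matrix")
  structure(list(true = true,
                 mask = matrix("visible", nrow(true), ncol(true),
                               dimnames = dimnames(true)),
                 row_totals = rowSums(true),
                 col_totals = colSums(true),
                 grand_total = sum(true) + extra_total,
                 extra_total = extra_total,
                 row_groups = row_groups,
                 rounding_multiple = rounding_multiple),
            class = "masked_table")
}

#' Suppress small cells
#'
#' Primary disclosure control: any cell whose true count is strictly
#' between 0 and the threshold is replaced by the marker `np` ("not
#' published"). Zero cells stay visible -- a zero discloses nothing about
#' individuals -- and suppressed cases still contribute to all totals.
#'
#' @param x A `masked_table` or a count matrix (coerced via [masked_table()]).
#' @param threshold Counts below this (and above 0) are suppressed;
#'   default 5.
#' @return A `masked_table` with `np` markers applied.
#' @export
suppress_small_cells <- function(x, threshold = 5) {
  if (!inherits(x, "masked_table")) x <- masked_table(x)
  stopifnot_msg(all(x$true >= 0), "input error: negative counts")
  x$mask[x$true > 0 & x$true < threshold] <- "np"
  x$threshold <- threshold
  x
}

#' Complementary suppression
#'
#' Secondary disclosure control: in any row or column where exactly one
#' cell is masked, its value can be recovered by subtracting the visible
#' cells from the (always visible) line total -- and once any masked cell
#' unravels, suppressed `np` cells elsewhere can follow. The smallest
#' remaining positive visible cell in such a line is therefore masked with
#' `+` (ties broken by first category order), and the rule is applied to
#' rows and columns repeatedly until no line changes, so that every line
#' containing a masked cell contains at least two. Zero cells are never
#' masked (they are printed, and a `+` marker denotes withheld data above
#' the threshold); a line whose only nonzero entry is the suppressed cell
#' therefore cannot be protected by in-table masking -- its printed total
#' discloses it.
#'
#' @param x A `masked_table`, normally after [suppress_small_cells()].
#' @return The table with `plus` markers added.
#' @export
complementary_suppress <- function(x) {
  stopifnot_msg(inherits(x, "masked_table"),
                "complementary_suppress needs a masked_table")
  repeat {
    changed <- FALSE
    for (dim_i in 1:2) {
      n_lines <- dim(x$true)[dim_i]
      for (k in seq_len(n_lines)) {
        line_mask <- if (dim_i == 1) x$mask[k, ] else x$mask[, k]
        masked <- which(line_mask != "visible")
        if (length(masked) == 1) {
          line_true <- if (dim_i == 1) x$true[k, ] else x$true[, k]
          vis <- which(line_mask == "visible" & line_true > 0)
          if (length(vis) == 0) next
          pick <- vis[which.min(line_true[vis])]
          if (dim_i == 1) x$mask[k, pick] <- "plus"
          else x$mask[pick, k] <- "plus"
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  x
}

#' Apply the full masking pipeline
#'
#' [suppress_small_cells()] followed by [complementary_suppress()];
#' idempotent.
#'
#' @inheritParams suppress_small_cells
#' @return A fully masked `masked_table`.
#' @export
apply_masking <- function(x, threshold = 5) {
  complementary_suppress(suppress_small_cells(x, threshold))
}

display_cell <- function(value, mask, multiple) {
  if (mask == "np") "np"
  else if (mask == "plus") "+"
  else format(round_to_multiple(value, multiple), scientific = FALSE)
}

#' Render a masked table as text
#'
#' Deterministic layout with the markers rendered exactly as `np` and `+`.
#' Row and column totals are the true totals, rounded (only) here by the
#' table's `rounding_multiple`. With row groups, a subtotal line is emitted
#' after each group.
#'
#' @param x A `masked_table`.
#' @param format `"csv"` or `"markdown"`.
#' @return A character vector of lines.
#' @export
render_table <- function(x, format = c("csv", "markdown")) {
  format <- match.arg(format)
  m <- x$rounding_multiple
  header <- c("category", colnames(x$true), "total")
  if (nrow(x$true) == 0) {
    return(if (format == "csv") paste(header, collapse = ",")
           else paste0("| ", paste(header, collapse = " | "), " |"))
  }
  emit_group_subtotal <- function(g) {
    rows <- which(x$row_groups == g)
    tot <- sum(x$true[rows, ])
    c(paste0("[", g, "]"), rep("", ncol(x$true)),
      format(round_to_multiple(tot, m), scientific = FALSE))
  }
  rows_list <- list()
  prev_group <- NULL
  for (i in seq_len(nrow(x$true))) {
    g <- if (!is.null(x$row_groups)) x$row_groups[i] else NULL
    if (!is.null(g) && !identical(g, prev_group)) {
      rows_list[[length(rows_list) + 1]] <- emit_group_subtotal(g)
      prev_group <- g
    }
    cells <- vapply(seq_len(ncol(x$true)), function(j)
      display_cell(x$true[i, j], x$mask[i, j], m), character(1))
    rows_list[[length(rows_list) + 1]] <-
      c(rownames(x$true)[i], cells,
        format(round_to_multiple(x$row_totals[i], m), scientific = FALSE))
  }
  total_row <- c("total",
                 vapply(x$col_totals, function(v)
                   format(round_to_multiple(v, m), scientific = FALSE),
                   character(1)),
                 format(round_to_multiple(x$grand_total, m),
                        scientific = FALSE))
  rows_list[[length(rows_list) + 1]] <- total_row
  if (format == "csv") {
    c(paste(header, collapse = ","),
      vapply(rows_list, paste, character(1), collapse = ","))
  } else {
    c(paste0("| ", paste(header, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(header)), collapse = "|"), "|"),
      vapply(rows_list, function(r)
        paste0("| ", paste(r, collapse = " | "), " |"), character(1)))
  }
}

#' Parse a rendered CSV table back into display cells
#'
#' Recovers the grid of displayed values (including marker positions) from
#' the output of [render_table()] in CSV format. Used to verify the
#' render/parse round trip; subtotal and total lines are skipped.
#'
#' @param lines Character vector as returned by `render_table(x, "csv")`.
#' @return Character matrix of displayed cell values (`"np"`, `"+"` or a
#'   number), with the category column as rownames.
#' @export
parse_rendered_table <- function(lines) {
  parts <- strsplit(lines, ",", fixed = TRUE)
  header <- parts[[1]]
  body <- parts[-1]
  keep <- vapply(body, function(r)
    !grepl("^\\[", r[1]) && r[1] != "total", logical(1))
  body <- body[keep]
  cells <- t(vapply(body, function(r) r[2:(length(header) - 1)],
                    character(length(header) - 2)))
  rownames(cells) <- vapply(body, `[[`, character(1), 1)
  colnames(cells) <- header[2:(length(header) - 1)]
  cells
}

#' @export
print.masked_table <- function(x, ...) {
  writeLines(render_table(x, "markdown"))
  invisible(x)
}
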