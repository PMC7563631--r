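#' Two-arm summary table of a scored cohort
#'
#' Builds a study-style performance table: categorical (0/1 deviation)
#' variables are shown as `count (percent)` per arm and compared with
#' Fisher's exact test when any expected cell is below 5 (chi-squared
#' otherwise); continuous variables are shown as `median (Q1-Q3)` using
#' Tukey hinges and compared with the Mann-Whitney test (exact
#' enumeration up to a combined n of 20, normal approximation above).
#' Percentages are rounded half-up to integers. With a single arm the
#' summaries are still produced but p-values are omitted with a warning.
#'
#' @param scores Data frame from [score_cohort()] (or any table with an
#'   `arm` column).
#' @param categorical_vars Names of 0/1 columns; default: every
#'   checklist-item column found.
#' @param continuous_vars Names of numeric columns; defaults to the
#'   deviation total, performance total and time to epinephrine.
#' @return Data frame of class `cohort_summary`: one row per variable
#'   with formatted per-arm cells, the test used and its p-value.
#' @export
summarize_cohort <- function(scores,
                             categorical_vars = NULL,
                             continuous_vars = intersect(
                               c("cdevplus_total", "cpt_total",
                                 "time_to_epi_s"), names(scores))) {
  stopifnot("arm" %in% names(scores))
  arms <- intersect(c("control", "intervention"), unique(scores$arm))
  two_arms <- length(arms) == 2
  if (!two_arms)
    warning("single-arm input: p-values omitted", call. = FALSE)
  if (is.null(categorical_vars)) {
    skip <- c("team_id", "arm", continuous_vars)
    categorical_vars <- names(scores)[vapply(names(scores), function(v)
      !(v %in% skip) && all(scores[[v]] %in% c(0, 1)), TRUE)]
  }
  n_arm <- vapply(arms, function(a) sum(scores$arm == a), 0L)
  rows <- list()
  for (v in categorical_vars) {
    counts <- vapply(arms, function(a)
      sum(scores[[v]][scores$arm == a] == 1), 0)
    pct <- round_half_up(100 * counts / n_arm)
    cells <- sprintf("%d (%d)", as.integer(counts), as.integer(pct))
    test <- NA_character_; p <- NA_real_
    if (two_arms) {
      tab <- rbind(c(counts[1], n_arm[1] - counts[1]),
                   c(counts[2], n_arm[2] - counts[2]))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        test <- "fisher"
        p <- fisher_exact_2x2(tab)
      } else {
        test <- "chi_squared"
        p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "categorical",
      control_summary = if ("control" %in% arms) cells[arms == "control"]
        else NA_character_,
      intervention_summary = if ("intervention" %in% arms)
        cells[arms == "intervention"] else NA_character_,
      control_pct = if ("control" %in% arms) pct[arms == "control"]
        else NA_real_,
      intervention_pct = if ("intervention" %in% arms)
        pct[arms == "intervention"] else NA_real_,
      test = test, p_value = p, stringsAsFactors = FALSE)
  }
  for (v in continuous_vars) {
    vals <- lapply(arms, function(a) {
      x <- scores[[v]][scores$arm == a]
      x[!is.na(x)]
    })
    cells <- vapply(vals, function(x) {
      if (!length(x)) return("-")
      f <- stats::fivenum(x)
      sprintf("%s (%s-%s)", format_num(f[3]), format_num(f[2]),
              format_num(f[4]))
    }, "")
    test <- NA_character_; p <- NA_real_
    if (two_arms && all(lengths(vals) > 0)) {
      test <- "mann_whitney"
      mode <- if (sum(lengths(vals)) <= 20) "exact" else "approximate"
      p <- mann_whitney(vals[[1]], vals[[2]], mode = mode)$p_two_sided
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "continuous",
      control_summary = if ("control" %in% arms) cells[arms == "control"]
        else NA_character_,
      intervention_summary = if ("intervention" %in% arms)
        cells[arms == "intervention"] else NA_character_,
      control_pct = NA_real_, intervention_pct = NA_real_,
      test = test, p_value = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  attr(res, "n_control") <- if ("control" %in% arms)
    n_arm[arms == "control"] else 0L
  attr(res, "n_intervention") <- if ("intervention" %in% arms)
    n_arm[arms == "intervention"] else 0L
  class(res) <- c("cohort_summary", class(res))
  res
}

format_num <- function(x) {
  if (abs(x - round(x)) < 1e-9) format(round(x)) else format(round(x, 1))
}

#' Format a p-value in report style
#'
#' Two to three decimals with no leading zero, `<.001` below that.
#'
#' @param p Numeric p-value.
#' @return Character scalar.
#' @export
format_p <- function(p) {
  if (is.na(p)) return("-")
  if (p < 0.001) return("<.001")
  s <- if (p < 0.1) sprintf("%.3f", p) else sprintf("%.2f", p)
  sub("^0", "", s)
}

#' Write a cohort summary as a Markdown report
#'
#' @param summary A [summarize_cohort()] table.
#' @param path Output file; omit to return the lines invisibly.
#' @param title Report heading.
#' @return Character vector of Markdown lines, invisibly.
#' @export
report_markdown <- function(summary, path = NULL,
                            title = "Resuscitation performance of the teams") {
  nc <- attr(summary, "n_control") %||% NA
  ni <- attr(summary, "n_intervention") %||% NA
  lines <- c(paste("#", title), "",
             sprintf("| Performance | Control group (N=%s) | Intervention group (N=%s) | Test | P-value |",
                     nc, ni),
             "|---|---|---|---|---|")
  for (i in seq_len(nrow(summary))) {
    r <- summary[i, ]
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s |",
                              r$variable,
                              if (is.na(r$control_summary)) "-"
                                else r$control_summary,
                              if (is.na(r$intervention_summary)) "-"
                                else r$intervention_summary,
                              if (is.na(r$test)) "-" else r$test,
                              format_p(r$p_value)))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}
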