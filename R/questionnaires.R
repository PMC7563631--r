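#' Load the UEQ scale map
#'
#' Six scales (attractiveness, perspicuity, efficiency, dependability,
#' stimulation, novelty) whose item indices partition 1..26, plus a
#' per-item polarity flag (+1/-1) applied before averaging.
#'
#' @param path YAML scale map; defaults to the bundled standard map.
#' @return List of class `ueq_scale_map` with `scales` and `polarity`.
#' @export
load_ueq_scales <- function(path = resusim_extdata("ueq_scales.yaml")) {
  raw <- yaml::read_yaml(path)
  idx <- sort(unlist(raw$scales, use.names = FALSE))
  if (!identical(as.integer(idx), 1:26))
    stop("UEQ scale map must partition item indices 1..26", call. = FALSE)
  if (length(raw$polarity) != 26 || !all(raw$polarity %in% c(-1, 1)))
    stop("UEQ polarity must be 26 values of +1/-1", call. = FALSE)
  structure(list(scales = raw$scales, polarity = as.numeric(raw$polarity)),
            class = "ueq_scale_map")
}

#' Normal-approximation 95% confidence interval for a mean
#'
#' `mean +/- 1.96 * sd / sqrt(n)`, the interval convention used for the
#' questionnaire scale summaries. With `sd = 0` the interval collapses
#' to the mean.
#'
#' @param mean,sd,n Sample mean, sample (n-1) standard deviation, size.
#' @return Numeric `c(low, high)`.
#' @export
scale_ci <- function(mean, sd, n) {
  half <- 1.96 * sd / sqrt(n)
  c(low = mean - half, high = mean + half)
}

#' Cronbach's coefficient alpha
#'
#' `k/(k-1) * (1 - sum(item variances) / var(total))` on an
#' items-by-respondents matrix. Undefined (returned as `NA`) when the
#' total score has zero variance or there are fewer than two items or
#' respondents.
#'
#' @param items Numeric matrix, respondents in rows, items in columns.
#' @return Alpha, or `NA_real_` when undefined.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2 || nrow(items) < 2) return(NA_real_)
  total_var <- stats::var(rowSums(items))
  if (!is.finite(total_var) || total_var <= 0) return(NA_real_)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}

#' Score UEQ responses into per-scale summaries
#'
#' Each respondent's scale score is the mean of the polarity-adjusted
#' items of that scale (range -3..+3); the cohort summary per scale is
#' the mean, sample (n-1) SD, the normal 95% CI ([scale_ci()]) and
#' Cronbach's alpha over the scale's item matrix.
#'
#' @param responses Data frame with columns `item_1` .. `item_26` (one
#'   row per respondent; integers in -3..3) and optionally
#'   `respondent_id`.
#' @param scale_map A [load_ueq_scales()] map.
#' @return Data frame of class `ueq_summary`, one row per scale:
#'   `scale, n, mean, sd, ci_low, ci_high, alpha, evaluation`.
#' @export
score_ueq <- function(responses, scale_map = load_ueq_scales()) {
  stopifnot(inherits(scale_map, "ueq_scale_map"))
  item_cols <- paste0("item_", 1:26)
  missing <- setdiff(item_cols, names(responses))
  if (length(missing))
    stop("responses lack item column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  n <- nrow(responses)
  if (n < 2)
    stop("at least 2 respondents are required for SD and alpha",
         call. = FALSE)
  items <- as.matrix(responses[, item_cols])
  ids <- responses$respondent_id %||% sprintf("r%02d", seq_len(n))
  for (i in seq_len(n)) {
    bad <- which(!(items[i, ] %in% -3:3))
    if (length(bad))
      stop("respondent '", ids[i], "': item value out of range [-3, 3]",
           call. = FALSE)
  }
  adjusted <- sweep(items, 2, scale_map$polarity, `*`)
  out <- lapply(names(scale_map$scales), function(sc) {
    ix <- scale_map$scales[[sc]]
    mat <- adjusted[, ix, drop = FALSE]
    per_resp <- rowMeans(mat)
    m <- mean(per_resp)
    s <- stats::sd(per_resp)
    ci <- scale_ci(m, s, n)
    data.frame(scale = sc, n = n, mean = m, sd = s,
               ci_low = ci[["low"]], ci_high = ci[["high"]],
               alpha = cronbach_alpha(mat),
               evaluation = interpret_ueq(m),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("ueq_summary", class(res))
  res
}

#' Interpret a UEQ scale score
#'
#' Scores above 0.8 are a positive evaluation, below -0.8 negative, and
#' the band between them (inclusive) neutral.
#'
#' @param score Scale score in \[-3, 3\].
#' @return `"positive"`, `"neutral"` or `"negative"`.
#' @export
interpret_ueq <- function(score) {
  if (!is_scalar_number(score) || score < -3 || score > 3)
    stop("score must lie in [-3, 3]", call. = FALSE)
  if (score > 0.8) "positive" else if (score < -0.8) "negative"
  else "neutral"
}

#' Score a NASA raw task-load response
#'
#' The overall raw TLX is the plain average of the six subscales (each
#' 0-100 in steps of 5); workload bands are low (<40), moderate (40-60,
#' inclusive at both ends) and high (>60).
#'
#' @param response Named numeric vector or one-row data frame / list with
#'   subscales `mental, physical, temporal, performance, effort,
#'   frustration`.
#' @return List with `overall` and `band`.
#' @examples
#' score_rtlx(c(mental = 70, physical = 70, temporal = 70,
#'              performance = 70, effort = 70, frustration = 70))
#' @export
score_rtlx <- function(response) {
  subs <- c("mental", "physical", "temporal", "performance", "effort",
            "frustration")
  if (is.data.frame(response)) response <- as.list(response[1, ])
  response <- unlist(response[subs])
  if (length(response) != 6 || anyNA(response))
    stop("response must provide all six subscales", call. = FALSE)
  if (any(response < 0 | response > 100 | response %% 5 != 0))
    stop("subscale values must be multiples of 5 within 0-100",
         call. = FALSE)
  overall <- mean(response)
  band <- if (overall < 40) "low" else if (overall > 60) "high"
  else "moderate"
  list(overall = overall, band = band)
}

#' Score a table of RTLX respondents
#'
#' @param responses Data frame with the six subscale columns.
#' @return Data frame: `respondent_id`, `overall`, `band`.
#' @export
score_rtlx_cohort <- function(responses) {
  ids <- responses$respondent_id %||% sprintf("r%02d",
                                              seq_len(nrow(responses)))
  res <- lapply(seq_len(nrow(responses)), function(i)
    score_rtlx(responses[i, ]))
  data.frame(respondent_id = ids,
             overall = vapply(res, function(x) x$overall, 0),
             band = vapply(res, function(x) x$band, ""),
             stringsAsFactors = FALSE)
}
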