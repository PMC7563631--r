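#' Patient profile
#'
#' @param weight_kg Body weight in kilograms; must be positive and not
#'   exceed `max_weight_kg` (all weight-based dosing reads this value).
#' @param age_label Free-text age description, documentation only.
#' @param max_weight_kg Upper bound on accepted weight (default 100 kg).
#' @return An object of class `patient_profile`.
#' @examples
#' patient_profile(10, "about 1 year")
#' @export
patient_profile <- function(weight_kg, age_label = "", max_weight_kg = 100) {
  if (!is_scalar_number(weight_kg) || weight_kg <= 0)
    stop("weight_kg must be a positive number", call. = FALSE)
  if (weight_kg > max_weight_kg)
    stop("weight_kg exceeds the configured maximum (", max_weight_kg, " kg)",
         call. = FALSE)
  structure(list(weight_kg = weight_kg, age_label = age_label),
            class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("<patient_profile> ", x$weight_kg, " kg",
      if (nzchar(x$age_label)) paste0(" (", x$age_label, ")"), "\n", sep = "")
  invisible(x)
}

#' Load the engine configuration
#'
#' Reads timers, drug-dose specifications, defibrillation energy schedule,
#' metronome bounds and special-button identifiers from YAML. All clinical
#' constants live in this file; the engine never hard-codes them.
#'
#' @param path Path to a YAML configuration; defaults to the bundled one.
#' @return A validated list of class `engine_config`.
#' @export
load_engine_config <- function(path = resusim_extdata("engine_config.yaml")) {
  cfg <- yaml::read_yaml(path)
  validate_engine_config(cfg)
}

validate_engine_config <- function(cfg) {
  for (nm in c("timers", "doses", "energy", "metronome", "limits", "buttons"))
    if (is.null(cfg[[nm]])) stop("engine config missing section: ", nm,
                                 call. = FALSE)
  tm <- cfg$timers
  if (is.null(tm$rhythm_check) || is.null(tm$medication))
    stop("engine config must define rhythm_check and medication timers",
         call. = FALSE)
  for (nm in names(tm)) {
    t <- tm[[nm]]
    if (!is_scalar_number(t$period_s) || t$period_s <= 0 ||
        t$period_s != round(t$period_s))
      stop("timer '", nm, "': period_s must be a positive integer",
           call. = FALSE)
    if (!is_scalar_number(t$priority_rank))
      stop("timer '", nm, "': priority_rank required", call. = FALSE)
  }
  if (tm$rhythm_check$period_s != 120)
    stop("rhythm_check timer period must be 120 s", call. = FALSE)
  if (tm$medication$period_s < 180 || tm$medication$period_s > 300)
    stop("medication timer period must lie in 180-300 s", call. = FALSE)
  ms <- tm$medication$start %||% "first_epi"
  if (!ms %in% c("first_epi", "case_start"))
    stop("medication timer start must be 'first_epi' or 'case_start'",
         call. = FALSE)
  for (drug in names(cfg$doses)) {
    d <- cfg$doses[[drug]]
    if (!is_scalar_number(d$per_kg) || d$per_kg <= 0 ||
        !is_scalar_number(d$max_total) || d$max_total <= 0 ||
        !is_scalar_number(d$concentration) || d$concentration <= 0)
      stop("dose spec '", drug, "': per_kg, max_total and concentration ",
           "must be positive", call. = FALSE)
  }
  en <- cfg$energy
  js <- c(en$first_j_per_kg, en$second_j_per_kg, en$subsequent_j_per_kg,
          en$cap_j_per_kg)
  if (any(!vapply(js, is_scalar_number, TRUE)) || any(diff(js) < 0))
    stop("energy schedule must satisfy first <= second <= subsequent <= cap",
         call. = FALSE)
  if (!is_scalar_number(en$absolute_cap_j) || en$absolute_cap_j <= 0)
    stop("absolute_cap_j must be positive", call. = FALSE)
  if (cfg$metronome$min_bpm > cfg$metronome$max_bpm)
    stop("metronome bounds inverted", call. = FALSE)
  structure(cfg, class = "engine_config")
}

# Timer spec accessor: returns list(name, period_s, priority_rank, repeating)
timer_spec <- function(config, name) {
  t <- config$timers[[name]]
  if (is.null(t)) stop("unknown timer: ", name, call. = FALSE)
  list(name = name, period_s = t$period_s, priority_rank = t$priority_rank,
       repeating = isTRUE(t$repeating))
}

dose_spec <- function(config, drug) {
  d <- config$doses[[drug]]
  if (is.null(d)) stop("unknown drug in config: ", drug, call. = FALSE)
  d$drug <- drug
  d
}
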