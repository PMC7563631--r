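#' Weight-based drug dose
#'
#' Mass is `weight_kg * per_kg`, capped at the specification's
#' `max_total`; volume follows from the concentration. Display rounding
#' (`round_to`) applies to the returned values.
#'
#' @param profile A [patient_profile()] (or a bare weight in kg).
#' @param spec Dose specification: list with `per_kg` (mg/kg),
#'   `max_total` (mg), `concentration` (mg/mL) and optional `round_to`.
#' @return List with `mass_mg` and `volume_ml`.
#' @examples
#' compute_dose(patient_profile(10),
#'              list(per_kg = 0.01, max_total = 1, concentration = 0.1))
#' @export
compute_dose <- function(profile, spec) {
  if (!inherits(profile, "patient_profile")) profile <- patient_profile(profile)
  stopifnot(is_scalar_number(spec$per_kg), spec$per_kg > 0,
            is_scalar_number(spec$max_total), spec$max_total > 0,
            is_scalar_number(spec$concentration), spec$concentration > 0)
  digits <- spec$round_to %||% 3
  mass <- min(profile$weight_kg * spec$per_kg, spec$max_total)
  list(mass_mg = round(mass, digits),
       volume_ml = round(mass / spec$concentration, digits))
}

#' Defibrillation energy for the n-th shock
#'
#' First shock at `first_j_per_kg`, second at `second_j_per_kg`,
#' subsequent shocks at `subsequent_j_per_kg`, always clamped to
#' `min(cap_j_per_kg * weight, absolute_cap_j)`.
#'
#' @param shock_number Positive integer (1 = first shock).
#' @param profile A [patient_profile()] (or bare weight in kg).
#' @param schedule List with `first_j_per_kg`, `second_j_per_kg`,
#'   `subsequent_j_per_kg`, `cap_j_per_kg`, `absolute_cap_j`.
#' @return Energy in joules.
#' @examples
#' sched <- list(first_j_per_kg = 2, second_j_per_kg = 4,
#'               subsequent_j_per_kg = 4, cap_j_per_kg = 10,
#'               absolute_cap_j = 360)
#' defib_energy(1, patient_profile(10), sched) # 20 J
#' @export
defib_energy <- function(shock_number, profile, schedule) {
  if (!is_scalar_number(shock_number) || shock_number < 1 ||
      shock_number != round(shock_number))
    stop("shock_number must be a positive integer", call. = FALSE)
  if (!inherits(profile, "patient_profile")) profile <- patient_profile(profile)
  w <- profile$weight_kg
  per_kg <- if (shock_number == 1) schedule$first_j_per_kg
            else if (shock_number == 2) schedule$second_j_per_kg
            else schedule$subsequent_j_per_kg
  min(per_kg * w, schedule$cap_j_per_kg * w, schedule$absolute_cap_j)
}

#' Metronome beat times
#'
#' Evenly spaced compression-guide beats including t = 0;
#' `floor(duration_s * rate_bpm / 60) + 1` beats in total. The accepted
#' rate window (default 100-120/min) comes from the engine config.
#'
#' @param rate_bpm Beats per minute, within `bounds`.
#' @param duration_s Nonnegative duration in seconds.
#' @param bounds Length-2 numeric `c(min_bpm, max_bpm)`.
#' @return Numeric vector of beat times in seconds.
#' @examples
#' metronome_beats(120, 1) # 0.0 0.5 1.0
#' @export
metronome_beats <- function(rate_bpm, duration_s, bounds = c(100, 120)) {
  if (!is_scalar_number(rate_bpm) || rate_bpm < bounds[1] ||
      rate_bpm > bounds[2])
    stop("rate_bpm must lie within [", bounds[1], ", ", bounds[2], "]",
         call. = FALSE)
  stopifnot(is_scalar_number(duration_s), duration_s >= 0)
  n <- floor(duration_s * rate_bpm / 60 + 1e-9)
  (0:n) * 60 / rate_bpm
}
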