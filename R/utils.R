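`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero to integer
#'
#' Percentages in report tables are rounded half-up (e.g. 18.18 -> 18,
#' 20.5 -> 21), matching the usual clinical-report convention rather than
#' banker's rounding.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @examples
#' round_half_up(100 * 2 / 11) # 18
#' round_half_up(100 * 1 / 5)  # 20
#' @export
round_half_up <- function(x) {
  stopifnot(is.numeric(x))
  floor(x + 0.5)
}

#' Derive a child seed from a master seed
#'
#' Deterministic Lehmer-style integer hash used to give each simulated
#' team (or questionnaire batch) its own RNG stream from one master seed.
#' All arithmetic stays below 2^53 so it is exact in doubles; results lie
#' in 1..(2^31 - 2).
#'
#' @param seed Master seed (nonnegative integer scalar).
#' @param index Stream index (nonnegative integer scalar).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(seed) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + (as.numeric(index) + 1) * 9973) %% m
  s <- (s * 48271) %% m
  as.integer(if (s == 0) 1 else s)
}

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Locate a bundled extdata file, working both from the installed package
# and from a source checkout (devtools loads).
resusim_extdata <- function(file) {
  p <- system.file("extdata", file, package = "resusim")
  if (!nzchar(p)) stop("bundled data file not found: ", file, call. = FALSE)
  p
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
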