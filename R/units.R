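# Physical constants and small numeric helpers shared across modules.
# Internal bookkeeping: time in hours, activity in kBq, energy in MeV;
# uCi and cGy appear only at presentation boundaries.

MEV_TO_J <- 1.602176634e-13
BQ_PER_UCI <- 3.7e4
KBQ_PER_UCI <- 37
SECONDS_PER_HOUR <- 3600

# Gy·g per (uCi·h) contributed by 1 MeV released per disintegration:
# E[J/decay] * 3.7e4 decay/(s·uCi) * 3600 s/h / 1e-3 kg/g
GYG_PER_UCIH_PER_MEV <- MEV_TO_J * BQ_PER_UCI * SECONDS_PER_HOUR / 1e-3

HOURS_PER_UNIT <- c(s = 1 / 3600, min = 1 / 60, h = 1, d = 24)

#' Convert a duration to hours
#'
#' @param x numeric duration.
#' @param unit one of `"s"`, `"min"`, `"h"`, `"d"`.
#' @return duration in hours.
#' @keywords internal
to_hours <- function(x, unit) {
  unit <- as.character(unit)
  if (!all(unit %in% names(HOURS_PER_UNIT))) {
    stop("unknown time unit: ", paste(setdiff(unit, names(HOURS_PER_UNIT)), collapse = ", "))
  }
  x * unname(HOURS_PER_UNIT[unit])
}

#' Round half-integers downward
#'
#' Rounding rule used when reporting prescriptions to integer MBq/kBq:
#' exact halves round down (17.5 -> 17), everything else rounds to nearest.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_down <- function(x) ceiling(x - 0.5)

# Derive a reproducible 31-bit sub-seed for a named random stream so the
# generator stages can be re-run independently under one global seed.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% (.Machine$integer.max - 1)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
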