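#' Generate a hyperbaric oxygen therapy session profile
#'
#' Builds the phase table of a therapy session. The only scheme currently
#' recognized is `"TS240-90"`: compression on air to 2.4 atmospheres
#' absolute (ATA), then an isopressure block of three 30 min pure-oxygen
#' periods separated by two 10 min ambient-air breaks, and decompression
#' back to 1 ATA with continued oxygen breathing. Total isopressure oxygen
#' time is 90 min. Compression and decompression durations are configurable
#' (default 15 min each).
#'
#' @param scheme Scheme identifier; only `"TS240-90"` is known.
#' @param compression_min,decompression_min Ramp durations, minutes.
#' @return A `session_profile`: a tibble with columns `phase`, `label`,
#'   `start_min`, `end_min`, `pressure_ata`, `gas`. Phases are contiguous
#'   and non-overlapping; `pressure_ata` is the plateau (isopressure)
#'   pressure of the phase, with ramps carrying their target pressure.
#' @examples
#' prof <- generate_session_profile()
#' oxygen_duty_fraction(prof)   # fraction of a 24 h day at elevated O2 tension
#' @export
generate_session_profile <- function(scheme = "TS240-90",
                                     compression_min = 15,
                                     decompression_min = 15) {
  if (!identical(scheme, "TS240-90")) {
    stop_param(sprintf("Unknown therapy scheme '%s' (known: TS240-90).", scheme))
  }
  check_scalar_num(compression_min, "compression_min", lower = 0, strict_lower = TRUE)
  check_scalar_num(decompression_min, "decompression_min", lower = 0, strict_lower = TRUE)

  durations <- c(compression_min, 30, 10, 30, 10, 30, decompression_min)
  labels <- c("compression", "oxygen", "air_break", "oxygen", "air_break",
              "oxygen", "decompression")
  gas <- c("air", "oxygen", "air", "oxygen", "air", "oxygen", "oxygen")
  pressure <- c(2.4, 2.4, 2.4, 2.4, 2.4, 2.4, 1.0)
  ends <- cumsum(durations)

  out <- tibble::tibble(
    phase = seq_along(labels),
    label = labels,
    start_min = c(0, ends[-length(ends)]),
    end_min = ends,
    pressure_ata = pressure,
    gas = gas
  )
  structure(out, scheme = scheme,
            class = c("session_profile", class(out)))
}

#' Fraction of a day spent at elevated oxygen tension
#'
#' The isopressure pure-oxygen periods of the profile summed over one day.
#' For the standard TS 240-90 scheme this is 90 min over 1440 min = 6.25%
#' — the small duty cycle of the presumed effective agent in daily
#' hyperbaric oxygen therapy.
#'
#' @param profile A [generate_session_profile()] result.
#' @param day_min Reference period, minutes (default one day, 1440).
#' @param percent If `TRUE` (default) return percent, else a fraction.
#' @return Scalar duty fraction.
#' @export
oxygen_duty_fraction <- function(profile, day_min = 1440, percent = TRUE) {
  if (!inherits(profile, "session_profile")) {
    stop_param("`profile` must be a session_profile.")
  }
  check_scalar_num(day_min, "day_min", lower = 0, strict_lower = TRUE)
  o2 <- sum((profile$end_min - profile$start_min)[profile$label == "oxygen"])
  frac <- o2 / day_min
  if (percent) 100 * frac else frac
}

#' Phase timeline of the nicotine validation trial
#'
#' The normoxic functional test used to provoke a measurable
#' vasoconstrictive response: 5 min rest, about 5 min of smoking three
#' cigarettes in quick succession, then 10 min rest. Times in seconds.
#'
#' @return Tibble with columns `label`, `start_s`, `end_s`.
#' @examples
#' nicotine_trial_timeline()
#' @export
nicotine_trial_timeline <- function() {
  tibble::tibble(
    label = c("rest", "intake", "rest"),
    start_s = c(0, 300, 600),
    end_s = c(300, 600, 1200)
  )
}
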