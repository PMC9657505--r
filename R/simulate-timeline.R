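#' Generate ground-truth beat times
#'
#' Builds the cardiac timeline that anchors every simulated signal: beat
#' times from a mean heart rate, i.i.d. Gaussian R-to-R jitter, and optional
#' event-driven RR modulation (e.g. the heart-rate response to nicotine,
#' expressed as a [vaso_event()] acting on the RR interval). Successive RR
#' intervals are clipped at a 0.3 s physiological refractory floor.
#'
#' The first beat falls half a nominal interval after the recording start
#' (so boundary complexes are never truncated) and beats are emitted while
#' they fall strictly inside `[0, duration)`; at an exact nominal rate the
#' beat count is exactly `duration * mean_hr / 60`. RR jitter is independent
#' between beats — a deliberate simplification with no autocorrelated
#' heart-rate-variability structure.
#'
#' @param duration Recording length, seconds (> 0).
#' @param mean_hr Mean heart rate, beats per minute, in `[30, 220]`.
#' @param rr_jitter_sd Standard deviation of the Gaussian RR jitter, seconds.
#' @param rr_events Optional [vaso_event()] (or list) modulating the RR
#'   interval, `delta` in seconds of RR change.
#' @param seed Integer seed; the timeline is deterministic given it.
#'
#' @return A `cardiac_timeline`: a tibble with columns `beat`, `beat_time_s`
#'   and `rr_s` (interval to the next beat, `NA` for the last), carrying the
#'   generation parameters as attributes.
#' @examples
#' tl <- generate_beat_times(60, mean_hr = 60, rr_jitter_sd = 0)
#' nrow(tl)          # 60 beats, exactly 1 s apart
#' @export
generate_beat_times <- function(duration, mean_hr, rr_jitter_sd = 0,
                                rr_events = NULL, seed = 1L) {
  check_scalar_num(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar_num(mean_hr, "mean_hr", lower = 30, upper = 220)
  check_scalar_num(rr_jitter_sd, "rr_jitter_sd", lower = 0)
  rr_events <- as_event_list(rr_events)

  rr_base <- 60 / mean_hr
  # generous upper bound on beat count for pre-drawn jitter
  n_max <- ceiling(duration / 0.3) + 2L
  jit <- if (rr_jitter_sd > 0) {
    with_seed(derive_seed(seed, 1L), rnorm(n_max, sd = rr_jitter_sd))
  } else {
    numeric(n_max)
  }

  times <- numeric(n_max)
  t <- rr_base / 2
  i <- 0L
  # strict "< duration" with a tolerance so accumulated floating error
  # cannot admit a beat at exactly t = duration
  while (t < duration - 1e-9) {
    i <- i + 1L
    times[i] <- t
    rr <- rr_base + jit[i] + sum(vaso_response(t, rr_events))
    rr <- max(rr, 0.3)
    t <- t + rr
  }
  times <- times[seq_len(i)]

  out <- tibble::tibble(
    beat = seq_along(times),
    beat_time_s = times,
    rr_s = c(diff(times), NA_real_)
  )
  structure(
    out,
    mean_hr = mean_hr,
    rr_jitter_sd = rr_jitter_sd,
    duration = duration,
    class = c("cardiac_timeline", class(out))
  )
}
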