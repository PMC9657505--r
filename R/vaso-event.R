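#' Describe a vasoconstriction (or vasodilation) event
#'
#' A vaso event models the response of a beat-level quantity (per-beat PTT,
#' or R-to-R interval) to an intervention such as nicotine intake or oxygen
#' onset: a saturating-exponential change while the stimulus is applied,
#' followed by an exponential relaxation back to baseline after it stops.
#' Vasoconstriction shortens the PTT, so a constrictive event has a negative
#' `delta`.
#'
#' The response at time `t` (seconds from recording start) is
#' \deqn{r(t) = \Delta\,(1 - e^{-(t - t_{on})/\tau_{on}})}{r(t) = delta * (1 - exp(-(t - t_on)/tau_on))}
#' for \eqn{t_{on} \le t \le t_{off}}, zero before the onset, and
#' \eqn{r(t_{off})\, e^{-(t - t_{off})/\tau_{rec}}} afterwards.
#'
#' @param t_on,t_off Event start and end, seconds; `t_on < t_off`.
#' @param delta Asymptotic change, in the units of the modulated quantity
#'   (seconds for PTT or RR). Negative for a drop.
#' @param tau_on Onset time constant, seconds (> 0).
#' @param tau_recovery Recovery time constant, seconds (> 0).
#'
#' @return An object of class `vaso_event`.
#' @examples
#' ev <- vaso_event(t_on = 300, t_off = 600, delta = -0.03,
#'                  tau_on = 40, tau_recovery = 60)
#' vaso_response(c(0, 300, 330, 600, 700), ev)
#' @export
vaso_event <- function(t_on, t_off, delta, tau_on, tau_recovery) {
  check_scalar_num(t_on, "t_on")
  check_scalar_num(t_off, "t_off")
  check_scalar_num(delta, "delta")
  check_scalar_num(tau_on, "tau_on", lower = 0, strict_lower = TRUE)
  check_scalar_num(tau_recovery, "tau_recovery", lower = 0, strict_lower = TRUE)
  if (t_on >= t_off) stop_param("`t_on` must be earlier than `t_off`.")
  structure(
    list(t_on = t_on, t_off = t_off, delta = delta,
         tau_on = tau_on, tau_recovery = tau_recovery),
    class = "vaso_event"
  )
}

#' @export
print.vaso_event <- function(x, ...) {
  cat(sprintf(
    "<vaso_event> %g..%g s, delta = %+g, tau_on = %g s, tau_recovery = %g s\n",
    x$t_on, x$t_off, x$delta, x$tau_on, x$tau_recovery
  ))
  invisible(x)
}

#' Evaluate the response of one or more vaso events
#'
#' Events are linear: the total response is the sum of the individual
#' responses.
#'
#' @param t Numeric vector of times, seconds.
#' @param events A single [vaso_event()] or a list of them (possibly empty).
#' @return Numeric vector of responses, same length as `t`, in the units of
#'   `delta`.
#' @export
vaso_response <- function(t, events) {
  events <- as_event_list(events)
  resp <- numeric(length(t))
  for (ev in events) {
    r <- numeric(length(t))
    during <- t >= ev$t_on & t <= ev$t_off
    after <- t > ev$t_off
    r[during] <- ev$delta * (1 - exp(-(t[during] - ev$t_on) / ev$tau_on))
    r_off <- ev$delta * (1 - exp(-(ev$t_off - ev$t_on) / ev$tau_on))
    r[after] <- r_off * exp(-(t[after] - ev$t_off) / ev$tau_recovery)
    resp <- resp + r
  }
  resp
}

as_event_list <- function(events) {
  if (is.null(events)) return(list())
  if (inherits(events, "vaso_event")) return(list(events))
  if (is.list(events) && all(vapply(events, inherits, logical(1), "vaso_event"))) {
    return(events)
  }
  stop_param("`events` must be a vaso_event or a list of vaso_event objects.")
}
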