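new_ptt_series <- function(beat_time_s, ptt_s, quality = TRUE) {
  out <- tibble::tibble(beat_time_s = beat_time_s, ptt_s = ptt_s,
                        quality = rep_len(quality, length(ptt_s)))
  structure(out, class = c("ptt_series", class(out)))
}

#' Pair ECG R-peaks with PPG inflection points into a PTT series
#'
#' For each R-peak, the pulse transit time is the delay to the earliest PPG
#' upstroke inflection falling inside the physiologic window
#' `(r + window[1], r + window[2]]`. Each inflection is consumed at most
#' once and pairing is order-preserving; R-peaks with no candidate (dropped
#' or unresolved pulses) are omitted rather than mis-paired with a later
#' pulse.
#'
#' @param r_times Strictly increasing R-peak times, seconds.
#' @param inflections Strictly increasing PPG inflection times, seconds
#'   (e.g. the `inflection_s` column of [detect_ppg_fiducials()]).
#' @param window Physiologic PTT window `c(min_s, max_s)`; default
#'   `c(0.1, 0.6)`.
#' @return A `ptt_series`: tibble with `beat_time_s` (the R-peak time),
#'   `ptt_s`, and a logical `quality` column (all `TRUE` here; see
#'   [clean_ptt_series()]).
#' @examples
#' pair_beats(c(1, 2), c(1.25, 2.24))
#' @export
pair_beats <- function(r_times, inflections, window = c(0.1, 0.6)) {
  check_increasing(r_times, "r_times")
  check_increasing(inflections, "inflections")
  if (length(window) != 2 || window[1] >= window[2]) {
    stop_param("`window` must be c(min_s, max_s) with min < max.")
  }
  bt <- numeric(0)
  ptt <- numeric(0)
  j <- 1L
  m <- length(inflections)
  for (r in r_times) {
    while (j <= m && inflections[j] <= r + window[1]) j <- j + 1L
    if (j > m) break
    if (inflections[j] <= r + window[2]) {
      bt <- c(bt, r)
      ptt <- c(ptt, inflections[j] - r)
      j <- j + 1L
    }
  }
  new_ptt_series(bt, ptt)
}

#' Flag PTT outliers against a running median
#'
#' Beats whose PTT deviates from the running median (window of `win_beats`
#' beats) by more than `mad_k` local median-absolute-deviations are marked
#' `quality = FALSE`. Values are never altered or removed — only flagged —
#' so downstream consumers decide what to exclude.
#'
#' @param series A `ptt_series`.
#' @param mad_k Deviation threshold in local MAD units.
#' @param win_beats Running window length in beats (forced odd).
#' @return The series with an updated `quality` column.
#' @export
clean_ptt_series <- function(series, mad_k = 5, win_beats = 31) {
  if (nrow(series) == 0) stop_param("`series` must be non-empty.")
  check_scalar_num(mad_k, "mad_k", lower = 0, strict_lower = TRUE)
  x <- series$ptt_s
  n <- length(x)
  k <- min(2L * floor(win_beats / 2) + 1L, if (n %% 2L == 1L) n else n - 1L)
  if (k < 3L) {
    med <- rep(median(x), n)
    madev <- rep(mad(x, constant = 1.4826), n)
  } else {
    med <- stats::runmed(x, k, endrule = "median")
    madev <- 1.4826 * stats::runmed(abs(x - med), k, endrule = "median")
  }
  flag <- abs(x - med) > mad_k * madev
  series$quality <- series$quality & !flag
  series
}

#' Fit a vasoconstriction response to a PTT series
#'
#' Nonlinear least squares of the intervention model: constant baseline,
#' saturating-exponential change
#' `delta * (1 - exp(-(t - t_on)/tau_on))` while the stimulus is applied
#' (`t_on <= t <= t_off`, both fixed at the supplied hints), and
#' exponential relaxation back to baseline with time constant
#' `tau_recovery` afterwards. Beats flagged `quality = FALSE` are excluded.
#' Five deterministic starts spanning the physiological tau range guard
#' against local minima; the best-RSS convergent fit is returned, and
#' non-convergence of all starts raises an error carrying the per-start
#' diagnostics.
#'
#' @param series A `ptt_series` spanning beyond both hints, with at least
#'   30 usable beats.
#' @param t_on_hint,t_off_hint Stimulus start/end, seconds.
#' @return An `intervention_fit` object; see [tidy.intervention_fit()] and
#'   [glance.intervention_fit()]. Units: baseline and delta in seconds of
#'   PTT, taus in seconds of elapsed time.
#' @export
fit_intervention <- function(series, t_on_hint, t_off_hint) {
  check_scalar_num(t_on_hint, "t_on_hint")
  check_scalar_num(t_off_hint, "t_off_hint")
  if (t_on_hint >= t_off_hint) stop_param("`t_on_hint` must precede `t_off_hint`.")
  use <- series$quality
  t <- series$beat_time_s[use]
  y <- series$ptt_s[use]
  if (length(t) < 30) {
    stop_analysis("At least 30 usable beats are required for an intervention fit.")
  }
  if (min(t) > t_on_hint || max(t) < t_off_hint) {
    stop_param("The series must span beyond both hints.")
  }

  model_fun <- function(t, baseline, delta, tau_on, tau_recovery) {
    baseline + vaso_response(
      t, vaso_event(t_on_hint, t_off_hint, delta, tau_on, tau_recovery))
  }

  pre <- y[t < t_on_hint]
  baseline0 <- if (length(pre) >= 5) mean(pre) else mean(y)
  during <- y[t >= t_on_hint & t <= t_off_hint]
  delta0 <- if (length(during) >= 5) mean(during) - baseline0 else 0
  # a delta start of exactly zero zeroes the tau gradient columns
  if (abs(delta0) < 1e-9) delta0 <- -1e-4

  tau_starts <- c(5, 15, 40, 80, 150)
  fits <- list()
  diags <- character(0)
  for (tau0 in tau_starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        y ~ model_fun(t, baseline, delta, tau_on, tau_recovery),
        start = list(baseline = baseline0, delta = delta0,
                     tau_on = tau0, tau_recovery = tau0),
        lower = c(-Inf, -Inf, 0.1, 0.1),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
    if (inherits(f, "error")) {
      diags <- c(diags, sprintf("start tau=%g: %s", tau0, conditionMessage(f)))
    } else {
      fits[[length(fits) + 1L]] <- f
    }
  }
  if (length(fits) == 0) {
    stop_analysis(paste0("Intervention fit failed to converge from any start:\n",
                         paste(diags, collapse = "\n")))
  }
  rss <- vapply(fits, function(f) sum(residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- coef(best)

  structure(
    list(baseline_ptt = unname(cf["baseline"]),
         delta = unname(cf["delta"]),
         t_on = t_on_hint, t_off = t_off_hint,
         tau_on = unname(cf["tau_on"]),
         tau_recovery = unname(cf["tau_recovery"]),
         rss = min(rss), n_beats = length(t),
         fit = best, data = tibble::tibble(beat_time_s = t, ptt_s = y)),
    class = "intervention_fit"
  )
}

#' @export
print.intervention_fit <- function(x, ...) {
  cat("<intervention_fit>\n")
  cat(sprintf("  baseline PTT : %.1f ms\n", 1000 * x$baseline_ptt))
  cat(sprintf("  delta        : %+.1f ms\n", 1000 * x$delta))
  cat(sprintf("  stimulus     : %g..%g s\n", x$t_on, x$t_off))
  cat(sprintf("  tau (onset)  : %.1f s\n", x$tau_on))
  cat(sprintf("  tau (recovery): %.1f s\n", x$tau_recovery))
  cat(sprintf("  RSS %.3g s^2 over %d beats\n", x$rss, x$n_beats))
  invisible(x)
}

#' Tidy an intervention fit
#'
#' @param x An `intervention_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @method tidy intervention_fit
#' @export
tidy.intervention_fit <- function(x, ...) {
  sm <- tryCatch(summary(x$fit)$coefficients, error = function(e) NULL)
  terms <- c("baseline", "delta", "tau_on", "tau_recovery")
  est <- c(x$baseline_ptt, x$delta, x$tau_on, x$tau_recovery)
  se <- if (!is.null(sm)) sm[terms, "Std. Error"] else rep(NA_real_, 4)
  tibble::tibble(term = terms, estimate = est, std.error = unname(se))
}

#' One-row summary of an intervention fit
#'
#' @param x An `intervention_fit`.
#' @param ... Unused.
#' @return One-row tibble: parameter estimates, RSS and beat count.
#' @method glance intervention_fit
#' @export
glance.intervention_fit <- function(x, ...) {
  tibble::tibble(baseline_ptt_s = x$baseline_ptt, delta_s = x$delta,
                 tau_on_s = x$tau_on, tau_recovery_s = x$tau_recovery,
                 rss = x$rss, n_beats = x$n_beats)
}

#' Arterial vessel parameters
#'
#' Geometry and material parameters of the arterial segment for the
#' Moens-Korteweg relation: Young's modulus `E` (Pa), wall thickness `h`
#' (m), inner diameter `D` (m), and blood density `rho` (kg/m^3, default
#' 1060). All must be strictly positive.
#'
#' @param E,h,D,rho See description.
#' @return A list of class `vessel_params`.
#' @export
vessel_params <- function(E, h, D, rho = 1060) {
  check_scalar_num(E, "E", lower = 0, strict_lower = TRUE)
  check_scalar_num(h, "h", lower = 0, strict_lower = TRUE)
  check_scalar_num(D, "D", lower = 0, strict_lower = TRUE)
  check_scalar_num(rho, "rho", lower = 0, strict_lower = TRUE)
  structure(list(E = E, h = h, D = D, rho = rho), class = "vessel_params")
}

#' Moens-Korteweg pulse wave velocity
#'
#' The classical relation between pulse wave velocity and vessel
#' properties, `PWV = sqrt(E h / (rho D))`: a stiffer (larger `E`) or
#' narrower (smaller `D`) artery propagates the pressure pulse faster —
#' which is why vasoconstriction shortens the pulse transit time.
#'
#' @param params A [vessel_params()].
#' @return Pulse wave velocity, m/s.
#' @examples
#' moens_korteweg_pwv(vessel_params(E = 4e5, h = 1e-3, D = 8e-3))
#' @export
moens_korteweg_pwv <- function(params) {
  if (!inherits(params, "vessel_params")) {
    stop_param("`params` must be a vessel_params object.")
  }
  sqrt(params$E * params$h / (params$rho * params$D))
}

#' Pulse wave velocity from a transit time and path length
#'
#' @param ptt Pulse transit time, seconds (> 0).
#' @param path_length Arterial path length between the two sites, m (> 0).
#' @return Velocity, m/s.
#' @export
pwv_from_ptt <- function(ptt, path_length) {
  check_scalar_num(ptt, "ptt", lower = 0, strict_lower = TRUE)
  check_scalar_num(path_length, "path_length", lower = 0, strict_lower = TRUE)
  path_length / ptt
}

#' Summarize a PTT series per session phase
#'
#' Assigns each usable beat to the unique therapy-session phase containing
#' its beat time (series and profile must share the time origin) and
#' reports per-phase mean and SD of the PTT in milliseconds. Phases with no
#' beats are reported with `n_beats = 0`.
#'
#' @param series A `ptt_series` (seconds).
#' @param profile A [generate_session_profile()] result (minutes).
#' @return Tibble: `phase`, `label`, `start_min`, `end_min`, `n_beats`,
#'   `mean_ptt_ms`, `sd_ptt_ms`.
#' @export
phase_summary <- function(series, profile) {
  if (!inherits(profile, "session_profile")) {
    stop_param("`profile` must be a session_profile.")
  }
  use <- series[series$quality, ]
  t_min <- use$beat_time_s / 60
  rows <- lapply(seq_len(nrow(profile)), function(i) {
    lo <- profile$start_min[i]
    hi <- profile$end_min[i]
    sel <- if (i == nrow(profile)) t_min >= lo & t_min <= hi else
      t_min >= lo & t_min < hi
    p <- use$ptt_s[sel]
    tibble::tibble(
      phase = profile$phase[i], label = profile$label[i],
      start_min = lo, end_min = hi, n_beats = length(p),
      mean_ptt_ms = if (length(p)) 1000 * mean(p) else NA_real_,
      sd_ptt_ms = if (length(p) > 1) 1000 * sd(p) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}
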