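local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

new_beat_annotation <- function(r_times) {
  out <- tibble::tibble(
    beat = seq_along(r_times),
    r_time_s = r_times,
    rr_s = if (length(r_times) > 1) c(diff(r_times), NA_real_) else
      rep(NA_real_, length(r_times))
  )
  structure(out, class = c("beat_annotation", class(out)))
}

#' Detect ECG R-peaks
#'
#' A Pan-Tompkins-style QRS detector: band-pass emphasis of the QRS band
#' (5-15 Hz, zero-phase), differentiation, squaring, 150 ms moving-window
#' integration, then an adaptive dual-threshold (running signal- and
#' noise-level estimates) with a refractory period. Every accepted
#' detection is refined to the local maximum of the conditioned ECG within
#' +/-50 ms, and beats implying an R-to-R interval under the 0.3 s
#' physiologic floor are gated out (the smaller peak is dropped).
#'
#' All decision thresholds are relative, so detection times are invariant
#' to positive rescaling of the input.
#'
#' @param ecg Conditioned (detrended) ECG sample vector.
#' @param fs Sampling rate, Hz (>= 250).
#' @param refractory_s Minimum separation enforced during detection, s.
#' @return A `beat_annotation`: tibble with `beat`, `r_time_s` (strictly
#'   increasing) and `rr_s` (interval to next beat; `NA` on the last row).
#'   A flat signal yields zero beats.
#' @examples
#' tl <- generate_beat_times(30, 60, 0)
#' ecg <- synthesize_ecg(tl, fs = 500)
#' detect_r_peaks(ecg, fs = 500)
#' @export
detect_r_peaks <- function(ecg, fs, refractory_s = 0.2) {
  check_scalar_num(fs, "fs", lower = 250)
  check_scalar_num(refractory_s, "refractory_s", lower = 0, strict_lower = TRUE)
  n <- length(ecg)
  if (n < fs) {
    stop_analysis("ECG shorter than one second; cannot detect beats.")
  }
  if (sd(ecg) == 0) return(new_beat_annotation(numeric(0)))

  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  y <- filtfilt_padded(bf$b, bf$a, ecg, ceiling(fs / 2))
  d <- c(0, diff(y))
  sq <- d^2
  wl <- max(3L, round(0.150 * fs))
  m <- as.numeric(stats::filter(sq, rep(1 / wl, wl), sides = 2))
  m[is.na(m)] <- 0

  cand <- local_maxima(m)
  cand <- cand[m[cand] > 0]
  if (length(cand) == 0) return(new_beat_annotation(numeric(0)))

  init <- m[seq_len(min(n, round(2 * fs)))]
  spki <- max(init)
  npki <- median(init)
  refr <- round(refractory_s * fs)
  half_win <- as.integer(round(0.050 * fs))

  peaks <- integer(0)
  for (p in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (m[p] > thr) {
      if (length(peaks) && p - peaks[length(peaks)] < refr) {
        # within refractory: keep whichever candidate is larger
        if (m[p] > m[peaks[length(peaks)]]) peaks[length(peaks)] <- p
        next
      }
      peaks <- c(peaks, p)
      spki <- 0.125 * m[p] + 0.875 * spki
    } else {
      npki <- 0.125 * m[p] + 0.875 * npki
    }
  }
  if (length(peaks) == 0) return(new_beat_annotation(numeric(0)))

  # refine each detection to the conditioned-ECG local maximum (+/- 50 ms)
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, p - half_win)
    hi <- min(n, p + half_win)
    lo + which.max(ecg[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))

  # physiologic gating: drop the smaller of any pair closer than 0.3 s
  min_rr <- round(0.3 * fs)
  repeat {
    if (length(refined) < 2) break
    gaps <- diff(refined)
    bad <- which(gaps < min_rr)
    if (length(bad) == 0) break
    i <- bad[1]
    drop <- if (ecg[refined[i]] < ecg[refined[i + 1]]) i else i + 1L
    refined <- refined[-drop]
  }

  new_beat_annotation((refined - 1) / fs)
}

#' R-to-R intervals of a beat annotation
#'
#' @param annotation A `beat_annotation` from [detect_r_peaks()].
#' @return Numeric vector of RR intervals, seconds (length = beats - 1).
#' @export
rr_intervals <- function(annotation) {
  rr <- annotation$rr_s
  rr[!is.na(rr)]
}

#' Heart-rate progression as a once-per-second series
#'
#' Sliding-window mean heart rate, emitted once per second — the cadence at
#' which the wearable reports a live heart rate to its control unit. Each
#' emitted value averages 60/RR over the beats whose interval ends inside
#' the trailing window.
#'
#' @param annotation A `beat_annotation` with at least 2 beats.
#' @param window_s Trailing window length, seconds.
#' @return Tibble with `time_s` and `hr_bpm`.
#' @export
heart_rate_series <- function(annotation, window_s = 10) {
  check_scalar_num(window_s, "window_s", lower = 0, strict_lower = TRUE)
  r <- annotation$r_time_s
  if (length(r) < 2) {
    stop_analysis("At least two beats are required for a heart-rate series.")
  }
  rr_end <- r[-1]
  rr <- diff(r)
  ts <- seq(ceiling(rr_end[1]), floor(max(rr_end)))
  if (length(ts) == 0) ts <- max(rr_end)
  hr <- vapply(ts, function(t) {
    sel <- rr_end > t - window_s & rr_end <= t
    if (!any(sel)) return(NA_real_)
    mean(60 / rr[sel])
  }, numeric(1))
  out <- tibble::tibble(time_s = as.numeric(ts), hr_bpm = hr)
  out[!is.na(out$hr_bpm), ]
}

#' Heart-rate variability summary
#'
#' Time-domain HRV over the full annotation: SDNN (standard deviation of
#' RR intervals) and RMSSD (root mean square of successive RR differences),
#' both in milliseconds, plus the mean heart rate.
#'
#' @param annotation A `beat_annotation` with at least 3 beats.
#' @return One-row tibble: `n_beats`, `mean_hr_bpm`, `sdnn_ms`, `rmssd_ms`.
#' @examples
#' ann <- detect_r_peaks(synthesize_ecg(generate_beat_times(60, 70, 0.02, seed = 2),
#'                                      fs = 500), fs = 500)
#' hrv_metrics(ann)
#' @export
hrv_metrics <- function(annotation) {
  r <- annotation$r_time_s
  if (length(r) < 3) {
    stop_analysis("At least three beats are required for HRV metrics.")
  }
  rr <- diff(r)
  tibble::tibble(
    n_beats = length(r),
    mean_hr_bpm = 60 / mean(rr),
    sdnn_ms = sd(rr) * 1000,
    rmssd_ms = sqrt(mean(diff(rr)^2)) * 1000
  )
}

#' Detect PPG pulse fiducial points
#'
#' Per pulse: the systolic peak (local-maximum search with an adaptive
#' amplitude threshold, or guided by ECG R-peak times), the pulse onset
#' (foot: the preceding local minimum, refined to the 1%-of-amplitude
#' upcrossing), the upstroke inflection point (maximum of the first
#' derivative between onset and peak, refined to sub-sample precision by
#' parabolic interpolation — the PTT fiducial), and, best-effort, the
#' dicrotic wave (highest local maximum within 0.5 s after the systolic
#' peak, absent when no candidate exists). Unresolvable pulses are skipped,
#' never fabricated. Peak-candidate ties break toward the earlier sample.
#'
#' @param ppg Conditioned PPG sample vector.
#' @param fs Sampling rate, Hz (>= 100).
#' @param search_guides Optional ECG R-peak times (s); when given, one pulse
#'   is sought after each R-peak instead of free-running peak detection.
#' @param min_separation_s Minimum separation between systolic peaks, s.
#' @return Tibble with one row per resolved pulse: `pulse`, `onset_s`,
#'   `inflection_s`, `peak_s`, `dicrotic_s` (`NA` when absent), satisfying
#'   `onset < inflection < peak < dicrotic`.
#' @export
detect_ppg_fiducials <- function(ppg, fs, search_guides = NULL,
                                 min_separation_s = 0.3) {
  check_scalar_num(fs, "fs", lower = 100)
  n <- length(ppg)
  empty <- tibble::tibble(pulse = integer(), onset_s = numeric(),
                          inflection_s = numeric(), peak_s = numeric(),
                          dicrotic_s = numeric())
  if (n < 3 || sd(ppg) == 0) return(empty)

  if (is.null(search_guides)) {
    cand <- local_maxima(ppg)
    med <- median(ppg)
    thr <- med + 0.4 * (max(ppg) - med)
    cand <- cand[ppg[cand] > thr]
    # enforce minimum separation, keeping the taller peak (earlier on ties)
    min_sep <- round(min_separation_s * fs)
    peaks <- integer(0)
    for (p in cand[order(-ppg[cand], cand)]) {
      if (all(abs(peaks - p) >= min_sep)) peaks <- c(peaks, p)
    }
    peaks <- sort(peaks)
  } else {
    check_increasing(search_guides, "search_guides")
    peaks <- integer(0)
    for (g in search_guides) {
      lo <- round(g * fs) + 1L
      hi <- min(n, lo + round(1.0 * fs))
      if (lo >= hi || lo < 1) next
      seg_max <- local_maxima(ppg[lo:hi])
      if (length(seg_max) == 0) next
      best <- seg_max[which.max(ppg[lo:hi][seg_max])]
      peaks <- c(peaks, lo + best - 1L)
    }
    peaks <- sort(unique(peaks))
  }
  if (length(peaks) == 0) return(empty)

  rows <- vector("list", length(peaks))
  for (i in seq_along(peaks)) {
    p <- peaks[i]
    prev_bound <- if (i > 1) peaks[i - 1] + 1L else 1L
    lo <- max(prev_bound, p - round(0.5 * fs))
    if (lo >= p) next
    seg <- ppg[lo:p]
    foot <- lo + which.min(seg) - 1L
    if (foot >= p) next
    amp <- ppg[p] - ppg[foot]
    if (amp <= 0) next

    # onset: first upcrossing of foot + 1% amplitude, linearly interpolated
    thr <- ppg[foot] + 0.01 * amp
    above <- which(ppg[foot:p] > thr)
    if (length(above) == 0) next
    k <- foot + above[1] - 1L
    onset_idx <- k
    onset_s <- if (k > foot && ppg[k] > ppg[k - 1]) {
      (k - 2 + (thr - ppg[k - 1]) / (ppg[k] - ppg[k - 1])) / fs
    } else {
      (k - 1) / fs
    }

    # inflection: maximum first derivative on the upstroke, parabolic refine
    lo_d <- max(onset_idx, 2L)
    hi_d <- min(p, n - 1L)
    if (hi_d <= lo_d) next
    idx_d <- lo_d:hi_d
    d <- (ppg[idx_d + 1L] - ppg[idx_d - 1L]) / 2
    j <- which.max(d)
    jj <- idx_d[j]
    delta <- 0
    if (j > 1 && j < length(d)) {
      denom <- d[j - 1] - 2 * d[j] + d[j + 1]
      if (denom < 0) delta <- 0.5 * (d[j - 1] - d[j + 1]) / denom
      if (!is.finite(delta) || abs(delta) > 1) delta <- 0
    }
    inflection_s <- (jj - 1 + delta) / fs

    # dicrotic wave: highest local maximum in (peak, peak + 0.5 s],
    # bounded by the next pulse
    hi_w <- min(n, p + round(0.5 * fs))
    if (i < length(peaks)) hi_w <- min(hi_w, peaks[i + 1] - 1L)
    dicrotic_s <- NA_real_
    if (hi_w - p >= 2) {
      wseg <- ppg[p:hi_w]
      wmax <- local_maxima(wseg)
      wmax <- wmax[wmax > 1]
      if (length(wmax) > 0) {
        best <- wmax[which.max(wseg[wmax])]
        dicrotic_s <- (p + best - 2) / fs
      }
    }

    peak_s <- (p - 1) / fs
    if (!(onset_s < inflection_s && inflection_s < peak_s)) next
    rows[[i]] <- tibble::tibble(onset_s = onset_s, inflection_s = inflection_s,
                                peak_s = peak_s, dicrotic_s = dicrotic_s)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  out <- dplyr::mutate(out, pulse = dplyr::row_number(), .before = 1)
  out
}
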