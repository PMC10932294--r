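#' Single-channel EEG trace container
#'
#' @param values Numeric signal samples.
#' @param fs Sampling rate in Hz (at least a few tens of Hz for the
#'   screening criteria to be meaningful).
#' @param start_s Time of the first sample in seconds.
#' @return An `eeg_trace` object.
#' @export
eeg_trace <- function(values, fs, start_s = 0) {
  if (!is.numeric(values) || length(values) < 1L) {
    abort("`values` must be a non-empty numeric vector.")
  }
  assert_scalar_number(fs, "fs", lower = 0, strict_lower = TRUE)
  structure(list(values = as.numeric(values), fs = fs, start_s = start_s),
            class = "eeg_trace")
}

#' @export
print.eeg_trace <- function(x, ...) {
  cat(sprintf("<eeg_trace> %d samples @ %g Hz (%.1f s)\n",
              length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

#' Simulate an EEG trace with planted high-amplitude evolving bursts
#'
#' Background is stationary Gaussian noise of standard deviation
#' `noise_sd`. Each planted event is an additive oscillatory burst whose
#' instantaneous frequency sweeps monotonically from `freq_start` to
#' `freq_end` and whose amplitude envelope ramps monotonically from 0.8x to
#' 1.2x the nominal level, so both the amplitude and the frequency of the
#' event evolve. The nominal level is chosen so the burst's RMS envelope is
#' `ratio` times the background RMS.
#'
#' @param duration_s Trace duration in seconds.
#' @param fs Sampling rate in Hz (>= 100).
#' @param events Optional tibble with columns `start`, `duration` (s),
#'   `ratio` (amplitude ratio vs background RMS) and optionally
#'   `freq_start`, `freq_end` (Hz). Events must lie within the trace and
#'   must not overlap.
#' @param noise_sd Background noise standard deviation (signal units).
#' @param seed Integer seed.
#' @return List with `trace` (an [eeg_trace()]) and `truth` (tibble of the
#'   planted events).
#' @examples
#' sim <- simulate_eeg(60, fs = 200, events = tibble::tibble(
#'   start = 20, duration = 10, ratio = 5
#' ), seed = 1)
#' sim$trace
#' @export
simulate_eeg <- function(duration_s, fs = 200, events = NULL, noise_sd = 1,
                         seed = 1L) {
  assert_scalar_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  assert_scalar_number(fs, "fs", lower = 100)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  n <- round(duration_s * fs)
  events <- normalize_events(events, duration_s)

  with_seed(seed, {
    x <- rnorm(n, 0, noise_sd)
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      idx <- seq(floor(ev$start * fs) + 1, min(n, floor((ev$start + ev$duration) * fs)))
      t_loc <- (seq_along(idx) - 1) / fs
      d <- ev$duration
      f0 <- ev$freq_start
      f1 <- ev$freq_end
      phase <- 2 * pi * (f0 * t_loc + (f1 - f0) * t_loc^2 / (2 * d))
      amp <- ev$ratio * noise_sd * sqrt(2) * (0.8 + 0.4 * t_loc / d)
      x[idx] <- x[idx] + amp * sin(phase)
    }
    list(trace = eeg_trace(x, fs), truth = events)
  })
}

#' @noRd
normalize_events <- function(events, duration_s) {
  if (is.null(events) || nrow(tibble::as_tibble(events)) == 0) {
    return(tibble::tibble(start = numeric(), duration = numeric(),
                          ratio = numeric(), freq_start = numeric(),
                          freq_end = numeric()))
  }
  events <- tibble::as_tibble(events)
  if (!all(c("start", "duration", "ratio") %in% names(events))) {
    abort("`events` needs columns `start`, `duration`, `ratio`.")
  }
  if (!"freq_start" %in% names(events)) events$freq_start <- 6
  if (!"freq_end" %in% names(events)) events$freq_end <- 12
  if (any(events$start < 0) ||
      any(events$start + events$duration > duration_s)) {
    abort("Events must lie within [0, duration_s].")
  }
  events <- dplyr::arrange(events, .data$start)
  if (nrow(events) > 1) {
    ends <- events$start + events$duration
    if (any(events$start[-1] < ends[-nrow(events)])) {
      abort("Planted events must not overlap.")
    }
  }
  events[c("start", "duration", "ratio", "freq_start", "freq_end")]
}

#' Robust background amplitude of an EEG trace
#'
#' Estimates the background signal level as the median of per-window RMS
#' amplitudes over non-overlapping windows. The median makes the estimate
#' robust to high-amplitude bursts as long as they occupy fewer than half
#' of the windows.
#'
#' @param trace An [eeg_trace()].
#' @param window_s Window length in seconds (default 10).
#' @return Background RMS estimate (signal units).
#' @export
background_amplitude <- function(trace, window_s = 10) {
  stopifnot(inherits(trace, "eeg_trace"))
  w <- round(window_s * trace$fs)
  if (length(trace$values) < w) {
    abort("Trace shorter than one background window.")
  }
  n_win <- floor(length(trace$values) / w)
  idx <- seq_len(n_win * w)
  rms <- sqrt(colMeans(matrix(trace$values[idx]^2, nrow = w)))
  median(rms)
}

#' Screen an EEG trace for electrographic seizure candidates
#'
#' Implements a three-criterion screen for electrographic seizures:
#' candidate regions are contiguous stretches where the 1-s sliding-window
#' RMS reaches `amplitude_ratio` times the robust background amplitude
#' (regions separated by gaps shorter than 1 s are merged); candidates are
#' kept iff they last at least `min_duration_s` and - when
#' `require_evolution` - show a significant monotone trend (Spearman rank
#' correlation, p < `evolution_p`) in either the windowed RMS or the
#' dominant spectral frequency across the event. Rejected candidates are
#' retained with the failed criterion. This is a screening tool whose
#' candidates are meant for expert review, not a validated seizure
#' detector.
#'
#' @param trace An [eeg_trace()].
#' @param min_duration_s Minimum event duration in seconds (default 5).
#' @param amplitude_ratio Amplitude criterion relative to background
#'   (default 3).
#' @param require_evolution Require the amplitude/frequency evolution
#'   criterion (default `TRUE`).
#' @param background_window_s Window for [background_amplitude()].
#' @param merge_gap_s Merge candidate regions separated by less than this
#'   (default 1 s).
#' @param evolution_p Significance level for the trend test (default 0.05).
#' @return An `eeg_screen` object; `tidy()` returns accepted events
#'   (`start`, `end`, `duration`, `peak_ratio`, `evolution`,
#'   `trend_statistic`), and `$rejected` holds rejected candidates with
#'   `reject_reason`.
#' @examples
#' sim <- simulate_eeg(120, fs = 200, events = tibble::tibble(
#'   start = 50, duration = 10, ratio = 5
#' ), seed = 2)
#' detect_seizure_events(sim$trace)
#' @export
detect_seizure_events <- function(trace, min_duration_s = 5,
                                  amplitude_ratio = 3,
                                  require_evolution = TRUE,
                                  background_window_s = 10,
                                  merge_gap_s = 1,
                                  evolution_p = 0.05) {
  stopifnot(inherits(trace, "eeg_trace"))
  assert_scalar_number(min_duration_s, "min_duration_s", lower = 0)
  assert_scalar_number(amplitude_ratio, "amplitude_ratio", lower = 1)
  fs <- trace$fs
  x <- trace$values
  bg <- background_amplitude(trace, background_window_s)

  empty <- tibble::tibble(start = numeric(), end = numeric(),
                          duration = numeric(), peak_ratio = numeric(),
                          evolution = logical(), trend_statistic = numeric())
  if (bg == 0) {
    return(new_eeg_screen(empty, cbind(empty, reject_reason = character()),
                          bg, trace))
  }

  w <- round(fs)  # 1-s sliding window
  r <- sqrt(stats::filter(x^2, rep(1 / w, w), sides = 2))
  r[is.na(r)] <- 0
  above <- r >= amplitude_ratio * bg

  runs <- rle(as.vector(above))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- data.frame(start = starts[runs$values], end = ends[runs$values])
  # Merge candidates separated by sub-second gaps.
  if (nrow(cand) > 1) {
    merged <- cand[1, ]
    for (i in 2:nrow(cand)) {
      if (cand$start[i] - merged$end[nrow(merged)] < merge_gap_s * fs) {
        merged$end[nrow(merged)] <- cand$end[i]
      } else {
        merged <- rbind(merged, cand[i, ])
      }
    }
    cand <- merged
  }

  accepted <- list()
  rejected <- list()
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    dur <- (e - s + 1) / fs
    peak <- max(r[s:e]) / bg
    ev <- tibble::tibble(
      start = (s - 1) / fs + trace$start_s,
      end = e / fs + trace$start_s,
      duration = dur,
      peak_ratio = peak,
      evolution = NA,
      trend_statistic = NA_real_
    )
    if (dur < min_duration_s) {
      rejected[[length(rejected) + 1L]] <- cbind(ev, reject_reason = "duration")
      next
    }
    trend <- event_evolution(x[s:e], fs, evolution_p)
    ev$evolution <- trend$significant
    ev$trend_statistic <- trend$statistic
    if (require_evolution && !trend$significant) {
      rejected[[length(rejected) + 1L]] <- cbind(ev, reject_reason = "evolution")
      next
    }
    accepted[[length(accepted) + 1L]] <- ev
  }

  new_eeg_screen(
    if (length(accepted)) dplyr::bind_rows(accepted) else empty,
    if (length(rejected)) dplyr::bind_rows(rejected) else {
      cbind(empty, reject_reason = character())
    },
    bg, trace
  )
}

# Monotone-trend statistic across an event: Spearman rank correlation of
# per-second windowed RMS and of dominant FFT frequency against time.
#' @noRd
event_evolution <- function(x, fs, alpha) {
  w <- round(fs)
  k <- floor(length(x) / w)
  if (k < 4) return(list(significant = FALSE, statistic = NA_real_))
  win <- matrix(x[seq_len(k * w)], nrow = w)
  rms <- sqrt(colMeans(win^2))
  domfreq <- apply(win, 2, function(seg) {
    spec <- Mod(fft(seg - mean(seg)))[2:floor(w / 2)]
    (which.max(spec)) * fs / w
  })
  test <- function(y) {
    ct <- suppressWarnings(cor.test(seq_len(k), y, method = "spearman"))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }
  t_rms <- test(rms)
  t_frq <- test(domfreq)
  sig <- (t_rms["p"] < alpha) || (t_frq["p"] < alpha)
  best <- if (t_rms["p"] <= t_frq["p"]) t_rms else t_frq
  list(significant = isTRUE(unname(sig)), statistic = unname(best["rho"]))
}

#' @noRd
new_eeg_screen <- function(events, rejected, background, trace) {
  structure(
    list(events = tibble::as_tibble(events),
         rejected = tibble::as_tibble(rejected),
         background = background,
         fs = trace$fs,
         duration_s = length(trace$values) / trace$fs),
    class = "eeg_screen"
  )
}

#' @export
print.eeg_screen <- function(x, ...) {
  cat(sprintf(
    "<eeg_screen> %.0f s @ %g Hz; background RMS %.3g; %d event(s), %d rejected candidate(s)\n",
    x$duration_s, x$fs, x$background, nrow(x$events), nrow(x$rejected)
  ))
  invisible(x)
}

#' Seizure incidence summary
#'
#' @param n_positive Number of animals with detected seizures.
#' @param n_total Number of animals monitored.
#' @return One-row tibble with `n_positive`, `n_total`, `proportion`,
#'   `percent` and `percent_int` (rounded integer percent).
#' @examples
#' seizure_incidence(11, 53)  # 21%
#' @export
seizure_incidence <- function(n_positive, n_total) {
  n_positive <- assert_count(n_positive, "n_positive", min = 0L)
  n_total <- assert_count(n_total, "n_total", min = 1L)
  if (n_positive > n_total) abort("`n_positive` cannot exceed `n_total`.")
  pct <- 100 * n_positive / n_total
  tibble::tibble(
    n_positive = n_positive, n_total = n_total,
    proportion = n_positive / n_total,
    percent = pct, percent_int = as.integer(round(pct))
  )
}
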