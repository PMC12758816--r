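#' Centered moving-average smoothing
#'
#' Smooths a uniformly sampled signal with a centered moving average of the
#' given window length (in seconds); at the ends the window shrinks
#' symmetrically so no samples are lost.
#'
#' @param signal Numeric vector.
#' @param rate Sampling rate (Hz).
#' @param window Window length (s); default 1 s.
#' @return Smoothed vector of the same length.
#' @export
smooth_signal <- function(signal, rate, window = 1) {
  n <- length(signal)
  w <- as.integer(round(window * rate))
  if (w %% 2L == 0L) w <- w + 1L
  if (w < 3L) stop("smoothing window shorter than 3 samples")
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, signal))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  # shrink symmetrically at the ends (centered window throughout)
  shrink <- pmin(i - lo, hi - i)
  lo <- i - shrink
  hi <- i + shrink
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Topographic prominence of local minima of a signal (standard peak
# prominence of the inverted signal); compiled for speed on long noisy
# recordings. Returns 1-based indices and prominences of troughs whose
# prominence reaches `min_prominence`.
local_minima_prominence <- function(signal, min_prominence = 0) {
  minima_prominence(as.numeric(signal), min_prominence)
}

#' Detect seizure offsets
#'
#' Seizure offsets are the deep troughs of the (smoothed) signal that
#' terminate each seizure: local minima whose topographic prominence is at
#' least half the signal span over the analyzed segment, kept greedily in
#' order of decreasing prominence subject to a pairwise separation of at
#' least `min_separation` seconds (ties broken toward the earlier
#' minimum).
#'
#' @param signal Smoothed, uniformly sampled signal.
#' @param rate Sampling rate (Hz).
#' @param min_separation Minimum time between retained offsets (s).
#' @param t0 Time of the first sample (s).
#' @return Numeric vector of offset times (s), in chronological order.
#' @export
detect_offsets <- function(signal, rate, min_separation = 20, t0 = 0) {
  span <- diff(range(signal))
  if (!is.finite(span) || span == 0) return(numeric(0))
  cand <- local_minima_prominence(signal, min_prominence = span / 2)
  cand <- cand[cand$prominence >= span / 2, , drop = FALSE]
  if (!nrow(cand)) return(numeric(0))
  # greedy by decreasing prominence, ties -> earlier index
  cand <- cand[order(-cand$prominence, cand$index), , drop = FALSE]
  min_gap <- min_separation * rate
  kept <- integer(0)
  for (i in cand$index) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  t0 + (sort(kept) - 1L) / rate
}

#' Locate a seizure onset before a detected offset
#'
#' Finds the changepoint of the smoothed signal in a lookback window of up
#' to `lookback` seconds before the given offset, as the split minimizing
#' the total residual sum of squares of a two-piece linear least-squares
#' fit (the "linear" changepoint statistic). The onset marks the steep
#' depolarization that starts the seizure.
#'
#' @param signal Smoothed, uniformly sampled signal.
#' @param rate Sampling rate (Hz).
#' @param offset_time Offset time (s) within the signal support.
#' @param lookback Window length (s) before the offset; default 30 s.
#' @param window_start Optional earliest time (s) the window may reach
#'   back to (e.g. the previous offset).
#' @param t0 Time of the first sample (s).
#' @return Onset time (s), with attribute `low_confidence` set to `TRUE`
#'   when the two-piece fit improves on a single line by less than 1%.
#' @export
detect_onset_before <- function(signal, rate, offset_time, lookback = 30,
                                window_start = -Inf, t0 = 0) {
  n <- length(signal)
  i_off <- as.integer(round((offset_time - t0) * rate)) + 1L
  if (i_off < 1L || i_off > n) stop("offset_time outside the signal support")
  i_lo <- max(1L, i_off - as.integer(round(lookback * rate)),
              if (is.finite(window_start))
                as.integer(ceiling((window_start - t0) * rate)) + 1L
              else 1L)
  y <- signal[i_lo:i_off]
  m <- length(y)
  if (m < 4L) stop("changepoint window shorter than 4 samples")
  x <- as.numeric(seq_len(m))

  # O(n) two-piece OLS via prefix sums
  cx <- cumsum(x); cy <- cumsum(y); cxx <- cumsum(x * x)
  cxy <- cumsum(x * y); cyy <- cumsum(y * y)
  seg_sse <- function(a, b) {     # vectors of segment starts/ends
    k <- b - a + 1
    sx <- cx[b] - ifelse(a > 1, cx[a - 1], 0)
    sy <- cy[b] - ifelse(a > 1, cy[a - 1], 0)
    sxx <- cxx[b] - ifelse(a > 1, cxx[a - 1], 0)
    sxy <- cxy[b] - ifelse(a > 1, cxy[a - 1], 0)
    syy <- cyy[b] - ifelse(a > 1, cyy[a - 1], 0)
    vxx <- sxx - sx * sx / k
    vxy <- sxy - sx * sy / k
    vyy <- syy - sy * sy / k
    sse <- vyy - ifelse(vxx > 0, vxy * vxy / vxx, 0)
    pmax(sse, 0)
  }
  splits <- 2:(m - 2)               # >= 2 samples in each piece
  total <- seg_sse(rep(1L, length(splits)), splits) +
    seg_sse(splits + 1L, rep(m, length(splits)))
  best <- splits[which.min(total)]
  sse1 <- seg_sse(1L, m)
  # a split is low-confidence when it barely improves on a single line
  # (including the degenerate exactly-linear case)
  low_conf <- !is.finite(sse1) || sse1 <= m * .Machine$double.eps *
    max(1, max(abs(y))^2) || (sse1 - min(total)) < 0.01 * sse1
  onset <- t0 + (i_lo - 1L + best - 1L) / rate
  attr(onset, "low_confidence") <- low_conf
  onset
}

#' Detect seizure events in a recording or simulated trajectory
#'
#' Applies the full detection pipeline: 1 s moving-average smoothing,
#' prominence-based offset (trough) detection, and changepoint onset
#' location in a window of up to `lookback` seconds before each offset
#' (clipped at the previous offset). The model's membrane potential `V`
#' serves as the LFP proxy.
#'
#' @param x An `epi_trajectory`, a `synthetic_recording`, or a numeric
#'   signal (then `rate` is required).
#' @param rate Sampling rate (Hz) when `x` is a plain numeric vector.
#' @param window Smoothing window (s).
#' @param min_separation Minimum offset separation (s).
#' @param lookback Onset search window (s).
#' @param min_duration Events shorter than this (s) are discarded as
#'   detection artifacts; seizure-like events last tens of seconds.
#' @return An object of class `epi_events`: a data frame with columns
#'   `onset`, `offset`, `duration` (s), one row per seizure, plus a
#'   `regime` attribute (`"periodic"`, `"silent"` or
#'   `"persistent-depolarized"`).
#' @export
detect_events <- function(x, rate = NULL, window = 1, min_separation = 20,
                          lookback = 30, min_duration = 2) {
  if (inherits(x, "epi_trajectory")) {
    signal <- x$V; rate <- 1 / x$record_dt; t0 <- x$time[1]
    params <- x$params
  } else if (inherits(x, "synthetic_recording")) {
    signal <- x$trace; rate <- x$rate; t0 <- x$time[1]
    params <- x$params
  } else {
    stopifnot(is.numeric(x), !is.null(rate))
    signal <- x; t0 <- 0; params <- NULL
  }
  s <- smooth_signal(signal, rate, window)
  offs <- detect_offsets(s, rate, min_separation, t0 = t0)
  ons <- numeric(length(offs))
  low <- logical(length(offs))
  for (k in seq_along(offs)) {
    prev <- if (k > 1) offs[k - 1] else -Inf
    o <- detect_onset_before(s, rate, offs[k], lookback,
                             window_start = prev, t0 = t0)
    ons[k] <- o
    low[k] <- isTRUE(attr(o, "low_confidence"))
  }
  ev <- data.frame(onset = ons, offset = offs, duration = offs - ons)
  keep <- ev$duration >= min_duration
  ev <- ev[keep, , drop = FALSE]
  low <- low[keep]
  rownames(ev) <- NULL
  regime <- classify_regime(signal, rate, ev, params)
  structure(ev, class = c("epi_events", "data.frame"),
            regime = regime, low_confidence = low)
}

# Heuristic regime label for a segment: "periodic" when full events are
# detected; otherwise "persistent-depolarized" when the firing rate stays
# high over the last quarter of the segment, else "silent".
classify_regime <- function(signal, rate, events, params = NULL) {
  if (nrow(events) >= 1) return("periodic")
  tail_seg <- signal[seq.int(max(1L, floor(length(signal) * 0.75)),
                             length(signal))]
  if (!is.null(params)) {
    nu <- mean(firing_rate(tail_seg, params))
    if (nu > params$nu_max / 4) return("persistent-depolarized")
  } else if (mean(tail_seg) > mean(signal) + 0.25 * diff(range(signal))) {
    return("persistent-depolarized")
  }
  "silent"
}

#' @export
print.epi_events <- function(x, ...) {
  cat(sprintf("epi_events: %d seizure(s), regime '%s'\n", nrow(x),
              attr(x, "regime")))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' Inter-seizure intervals of an event table
#'
#' The ISI is the time from the end (offset) of one seizure to the
#' beginning (onset) of the next.
#'
#' @param events An `epi_events` object (or data frame with `onset` and
#'   `offset` columns).
#' @return Numeric vector of ISIs (s); empty when fewer than 2 events.
#' @export
extract_isis <- function(events) {
  if (nrow(events) < 2) return(numeric(0))
  events$onset[-1] - events$offset[-nrow(events)]
}

#' Write an event table as CSV
#'
#' Columns: `onset, offset, duration, next_isi`.
#'
#' @param events An `epi_events` object.
#' @param path Output file path.
#' @export
write_events_csv <- function(events, path) {
  isis <- extract_isis(events)
  df <- as.data.frame(events)
  df$next_isi <- c(isis, NA)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
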