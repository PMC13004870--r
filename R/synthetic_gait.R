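#' Simulate one subject's instrumented-sock sensor stream
#'
#' Emulates the five key signals per foot (three pressure points plus
#' accelerometer and gyroscope magnitudes) at a nominal sampling rate.
#' Inside walking bouts every channel carries a sinusoid at the subject's
#' cadence plus two harmonics and white noise; outside bouts the channels
#' carry noise plus a slow drift emulating long-term pressure-sensor decay.
#' The two feet share the cadence with a half-period phase offset.
#'
#' @param cadence_hz Gait frequency in the 0.6-2 Hz band.
#' @param amplitude Overall signal amplitude multiplier.
#' @param noise_sd White-noise standard deviation.
#' @param bouts Tibble with columns `start`, `end` (seconds) and `walking`
#'   (logical); non-walking time needs no row. Bouts must not overlap.
#' @param duration Total stream length in seconds.
#' @param rate Sampling rate in Hz (default 70).
#' @param subject_id Identifier attached to the stream.
#' @param seed Seed; the stream is deterministic given it.
#' @return An object of class `sensor_stream`: a list with tibbles `left`
#'   and `right` (columns `time`, `p1`, `p2`, `p3`, `acc`, `gyro`), the
#'   `rate`, `subject_id`, and the ground-truth `bouts`.
#' @export
simulate_subject <- function(cadence_hz, amplitude = 1, noise_sd = 0.25,
                             bouts = tibble::tibble(start = numeric(0),
                                                    end = numeric(0),
                                                    walking = logical(0)),
                             duration = 60, rate = 70, subject_id = "S1",
                             seed = 1) {
  if (cadence_hz < 0.6 || cadence_hz > 2) {
    stop("cadence must lie in the 0.6-2 Hz gait band", call. = FALSE)
  }
  if (nrow(bouts) > 1) {
    b <- bouts[order(bouts$start), ]
    if (any(b$start[-1] < b$end[-nrow(b)])) {
      stop("bouts must not overlap", call. = FALSE)
    }
  }
  tt <- seq(0, duration, by = 1 / rate)
  walking <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(bouts))) {
    if (isTRUE(bouts$walking[i])) {
      walking <- walking | (tt >= bouts$start[i] & tt < bouts$end[i])
    }
  }
  channels <- c("p1", "p2", "p3", "acc", "gyro")
  chan_amp <- c(p1 = 1, p2 = 0.9, p3 = 0.8, acc = 0.8, gyro = 0.6)
  make_foot <- function(phase, foot_seed) {
    with_local_seed(foot_seed, {
      out <- tibble::tibble(time = tt)
      for (ch in channels) {
        ph <- phase + stats::runif(1, -0.3, 0.3)
        gait <- amplitude * chan_amp[[ch]] *
          (sin(2 * pi * cadence_hz * tt + ph) +
             0.4 * sin(2 * pi * 2 * cadence_hz * tt + 2 * ph) +
             0.2 * sin(2 * pi * 3 * cadence_hz * tt + 3 * ph))
        drift <- 0.3 * amplitude * sin(2 * pi * 0.03 * tt + stats::runif(1, 0, 2 * pi))
        sig <- ifelse(walking, gait, drift) +
          stats::rnorm(length(tt), sd = noise_sd)
        out[[ch]] <- sig
      }
      out
    })
  }
  structure(
    list(
      left = make_foot(0, derive_seed(seed, paste0(subject_id, "L"))),
      right = make_foot(pi, derive_seed(seed, paste0(subject_id, "R"))),
      rate = rate, subject_id = subject_id, bouts = bouts
    ),
    class = "sensor_stream"
  )
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat("<sensor_stream>", x$subject_id, ":", nrow(x$left), "samples at",
      x$rate, "Hz,", nrow(x$bouts), "declared bouts\n")
  invisible(x)
}

#' Synchronize and resample two per-foot streams onto a common grid
#'
#' Finds the overlapping time window of both feet and linearly interpolates
#' every channel onto a uniform grid at the target rate over that overlap.
#'
#' @param left,right Tibbles with a `time` column and channel columns.
#' @param target_hz Target sampling rate.
#' @return A list with resampled `left` and `right` tibbles sharing an
#'   identical `time` grid, and `rate = target_hz`.
#' @export
resample_sync <- function(left, right, target_hz = 70) {
  t0 <- max(min(left$time), min(right$time))
  t1 <- min(max(left$time), max(right$time))
  if (t1 <= t0) stop("streams do not overlap in time", call. = FALSE)
  grid <- seq(t0, t1, by = 1 / target_hz)
  interp <- function(df) {
    out <- tibble::tibble(time = grid)
    for (ch in setdiff(names(df), "time")) {
      out[[ch]] <- stats::approx(df$time, df[[ch]], xout = grid)$y
    }
    out
  }
  list(left = interp(left), right = interp(right), rate = target_hz)
}

#' Power-spectral-density spectrogram of one channel
#'
#' Short-time periodogram (Hann window) on a sliding window, converted to
#' decibels with a floor at -120 dB. Optionally the frequency rows are
#' aggregated into `n_freq_bins` fixed bands; with 4 bins the boundaries are
#' gait-aware: 0-0.6, 0.6-2, 2-5 Hz and 5 Hz-Nyquist.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param window_len STFT window length in samples (default 112: 1.6 s
#'   at 70 Hz, so a 560-sample 8 s window yields 12 frames).
#' @param hop Hop size in samples (default 40).
#' @param n_freq_bins Optional number of aggregated frequency rows.
#' @return A list with `db` (frequency rows x time frames), `freq`
#'   (row centers or band edges), and `time` (frame centers in seconds).
#' @export
psd_spectrogram <- function(x, fs, window_len = 112, hop = 40,
                            n_freq_bins = NULL) {
  sg <- signal::specgram(x, n = window_len, Fs = fs,
                         window = signal::hanning(window_len),
                         overlap = window_len - hop)
  psd <- abs(sg$S)^2 / (fs * window_len)
  db <- pmax(10 * log10(pmax(psd, 1e-300)), -120)
  freq <- as.numeric(sg$f)
  if (!is.null(n_freq_bins)) {
    edges <- if (n_freq_bins == 4) {
      c(0, 0.6, 2, 5, fs / 2 + 1e-9)
    } else {
      seq(0, fs / 2 + 1e-9, length.out = n_freq_bins + 1)
    }
    db <- t(vapply(seq_len(n_freq_bins), function(b) {
      rows <- which(freq >= edges[b] & freq < edges[b + 1])
      if (length(rows) == 0) rep(-120, ncol(db)) else
        colMeans(db[rows, , drop = FALSE])
    }, numeric(ncol(db))))
    freq <- edges
  }
  list(db = db, freq = freq, time = as.numeric(sg$t))
}

#' Quantize and stack per-signal spectrograms into a labeled-window grid
#'
#' Each per-signal dB grid is min-max normalized to `[0, 1]` (a zero-range
#' grid maps to all zeros) and rounded to 8-bit integers 0-255; the ten
#' grids (five per foot, left foot first, 4 frequency rows each) are stacked
#' vertically into the 40 x 12 window representation.
#'
#' @param grids A list of 10 numeric matrices with identical dimensions
#'   (4 x 12 in the standard layout), ordered as [stack_row_map()].
#' @return An integer matrix (40 x 12 in the standard layout).
#' @export
quantize_stack <- function(grids) {
  stopifnot(is.list(grids), length(grids) >= 1)
  q <- lapply(grids, function(g) {
    rng <- range(g)
    scaled <- if (diff(rng) == 0) matrix(0, nrow(g), ncol(g)) else
      (g - rng[1]) / diff(rng)
    matrix(as.integer(round(scaled * 255)), nrow(g), ncol(g))
  })
  do.call(rbind, q)
}

#' Row layout of the stacked window
#'
#' Documents (and inverts) the stacking order: row
#' `(signal - 1) * 4 + band`, signals ordered left foot `p1, p2, p3, acc,
#' gyro` then right foot likewise, bands ordered low to high frequency.
#'
#' @param n_bands Frequency rows per signal (default 4).
#' @return A tibble with columns `row`, `foot`, `signal`, `band`.
#' @export
stack_row_map <- function(n_bands = 4) {
  sig <- c("p1", "p2", "p3", "acc", "gyro")
  tidyr::crossing(
    foot = factor(c("left", "right"), levels = c("left", "right")),
    signal = factor(sig, levels = sig),
    band = seq_len(n_bands)
  ) |>
    dplyr::arrange(.data$foot, .data$signal, .data$band) |>
    dplyr::mutate(row = dplyr::row_number(), .before = 1)
}

#' Automatic walking-bout labeling from band energy
#'
#' Short-time Fourier frames are scored by the fraction of (drift-excluded)
#' spectral power lying in the gait band; frames above the threshold that
#' form sustained runs of at least `min_duration` seconds are labeled
#' walking, shorter runs are rejected as incidental movement. The default
#' threshold is three times the band-occupancy ratio a flat (white-noise)
#' spectrum would produce.
#'
#' @param synced A list as returned by [resample_sync()] (or a
#'   `sensor_stream`, which is synchronized first).
#' @param band Gait band in Hz (default `c(0.6, 2)`).
#' @param min_duration Minimum sustained duration in seconds (default 5).
#' @param threshold Band-energy ratio threshold; `NULL` uses the 3x
#'   noise-floor default.
#' @param frame_len,frame_hop STFT frame length and hop in seconds.
#' @return A list with `frames` (tibble `time`, `ratio`, `walking`) and
#'   `bouts` (tibble `start`, `end`, `walking = TRUE` runs after the
#'   sustain rule).
#' @export
auto_label <- function(synced, band = c(0.6, 2), min_duration = 5,
                       threshold = NULL, frame_len = 2, frame_hop = 0.5) {
  if (inherits(synced, "sensor_stream")) {
    synced <- resample_sync(synced$left, synced$right, synced$rate)
  }
  fs <- synced$rate
  drift_hz <- 0.2
  if (is.null(threshold)) {
    threshold <- 3 * diff(band) / (fs / 2 - drift_hz)
  }
  n <- round(frame_len * fs)
  hop <- round(frame_hop * fs)
  chans <- setdiff(names(synced$left), "time")
  total_psd <- NULL
  for (foot in c("left", "right")) {
    for (ch in chans) {
      sp <- psd_spectrogram(synced[[foot]][[ch]], fs, window_len = n,
                            hop = hop)
      psd <- 10^(sp$db / 10)
      total_psd <- if (is.null(total_psd)) psd else total_psd + psd
      freq <- sp$freq
      times <- sp$time + min(synced$left$time)
    }
  }
  in_band <- freq >= band[1] & freq <= band[2]
  usable <- freq >= drift_hz
  ratio <- colSums(total_psd[in_band, , drop = FALSE]) /
    pmax(colSums(total_psd[usable, , drop = FALSE]), 1e-300)
  above <- ratio > threshold
  # sustain rule: drop runs of above-threshold frames shorter than
  # min_duration seconds
  r <- rle(above)
  keep <- r
  # run duration measured as the span of above-threshold frame centers; this
  # avoids counting the smearing of the analysis window into the bout length
  run_secs <- (r$lengths - 1) * frame_hop
  keep$values <- r$values & run_secs >= min_duration
  walking <- inverse.rle(keep)
  frames <- tibble::tibble(time = times, ratio = ratio, walking = walking)
  rw <- rle(walking)
  ends <- cumsum(rw$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  bouts <- tibble::tibble(
    start = times[starts] - frame_len / 2,
    end = times[ends] + frame_len / 2,
    walking = rw$values
  ) |> dplyr::filter(.data$walking)
  list(frames = frames, bouts = bouts, threshold = threshold)
}

# Label non-overlapping windows of length window_s from frame labels:
# a window is walking when the majority of frame centers inside it are.
label_windows_from_frames <- function(frames, window_s, n_windows, t0 = 0) {
  vapply(seq_len(n_windows), function(w) {
    lo <- t0 + (w - 1) * window_s
    hi <- lo + window_s
    inside <- frames$walking[frames$time >= lo & frames$time < hi]
    as.integer(length(inside) > 0 && mean(inside) > 0.5)
  }, integer(1))
}

#' Generate a labeled synthetic gait-window dataset
#'
#' End-to-end generation of the study representation with no external data:
#' per subject, a bout plan aligned to 8 s windows (positives at the
#' requested rate) drives [simulate_subject()]; both feet are synchronized
#' and resampled, each window's ten channel spectrograms are band-reduced,
#' quantized and stacked into a 40 x 12 grid, and the automatic labeler is
#' run on the full stream. Deterministic given `seed`.
#'
#' @param n_subjects Number of subjects (default 9, supporting 3 grouped
#'   folds of three subjects with a held-out validation subject).
#' @param windows_per_subject Windows per subject (default 76; with 9
#'   subjects this yields 684 windows, matching the scale of three folds of
#'   roughly 227 windows each).
#' @param positive_fraction Target walking fraction (default 0.29, echoing
#'   the imbalance of the study folds).
#' @param noise_sd Sensor noise standard deviation (default 0.25).
#' @param rate Sampling rate (default 70 Hz).
#' @param window_s Window length in seconds (default 8: 560 samples, 12
#'   STFT frames).
#' @param seed Root seed.
#' @return A tibble with one row per window: `window_id`, `subject_id`,
#'   `label` (automatic label, as in the deployed pipeline), `label_true`
#'   (generator ground truth), and the `grid` list-column of 40 x 12
#'   integer matrices.
#' @export
build_gait_dataset <- function(n_subjects = 9, windows_per_subject = 76,
                               positive_fraction = 0.29, noise_sd = 0.25,
                               rate = 70, window_s = 8, seed = 1) {
  if (n_subjects < 1) stop("need at least one subject", call. = FALSE)
  n_pos <- round(positive_fraction * windows_per_subject)
  purrr::map_dfr(seq_len(n_subjects), function(si) {
    sid <- sprintf("S%02d", si)
    sseed <- derive_seed(seed, sid)
    plan <- with_local_seed(sseed, {
      walk_windows <- sort(sample.int(windows_per_subject, n_pos))
      cadence <- stats::runif(1, 0.9, 1.8)
      amp <- stats::runif(1, 0.8, 1.2)
      list(walk = walk_windows, cadence = cadence, amp = amp)
    })
    truth <- as.integer(seq_len(windows_per_subject) %in% plan$walk)
    runs <- rle(truth == 1L)
    ends <- cumsum(runs$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    bouts <- tibble::tibble(
      start = (starts - 1) * window_s, end = ends * window_s,
      walking = runs$values
    ) |> dplyr::filter(.data$walking)
    duration <- windows_per_subject * window_s
    stream <- simulate_subject(plan$cadence, amplitude = plan$amp,
                               noise_sd = noise_sd, bouts = bouts,
                               duration = duration, rate = rate,
                               subject_id = sid, seed = sseed)
    synced <- resample_sync(stream$left, stream$right, rate)
    lab <- auto_label(synced)
    auto <- label_windows_from_frames(lab$frames, window_s,
                                      windows_per_subject)
    nwin_samp <- round(window_s * rate)
    grids <- lapply(seq_len(windows_per_subject), function(w) {
      idx <- ((w - 1) * nwin_samp + 1):min(w * nwin_samp, nrow(synced$left))
      g <- vector("list", 10)
      k <- 1
      for (foot in c("left", "right")) {
        for (ch in c("p1", "p2", "p3", "acc", "gyro")) {
          g[[k]] <- psd_spectrogram(synced[[foot]][[ch]][idx], rate,
                                    n_freq_bins = 4)$db
          k <- k + 1
        }
      }
      quantize_stack(g)
    })
    tibble::tibble(
      window_id = sprintf("%s_w%03d", sid, seq_len(windows_per_subject)),
      subject_id = sid,
      label = auto,
      label_true = truth,
      grid = grids
    )
  })
}

#' Plot one labeled spectrogram window
#'
#' @param grid A 40 x 12 integer matrix.
#' @param title Optional plot title.
#' @return A ggplot heat map with the stacked-signal row layout.
#' @export
plot_window <- function(grid, title = NULL) {
  df <- tidyr::expand_grid(row = seq_len(nrow(grid)),
                           frame = seq_len(ncol(grid)))
  df$value <- grid[cbind(df$row, df$frame)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::labs(x = "time frame", y = "stacked row", fill = "intensity",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Write a dataset as a portable text archive
#'
#' The grids go to one long-format CSV (window_id, row, col, value) next to
#' an index CSV (window_id, subject_id, label, label_true) — a text-only
#' alternative to per-window image files.
#'
#' @param data Dataset tibble from [build_gait_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gait_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- dplyr::select(data, -"grid")
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  long <- purrr::map2_dfr(data$window_id, data$grid, function(id, g) {
    tibble::tibble(
      window_id = id,
      row = rep(seq_len(nrow(g)), each = ncol(g)),
      col = rep(seq_len(ncol(g)), times = nrow(g)),
      value = as.integer(t(g))
    )
  })
  utils::write.csv(long, file.path(dir, "grids.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_gait_dataset()]
#' @param dir Directory containing `index.csv` and `grids.csv`.
#' @return A dataset tibble with the `grid` list-column restored.
#' @export
read_gait_dataset <- function(dir) {
  idx <- tibble::as_tibble(utils::read.csv(file.path(dir, "index.csv")))
  long <- utils::read.csv(file.path(dir, "grids.csv"))
  grids <- lapply(split(long, long$window_id), function(d) {
    m <- matrix(0L, max(d$row), max(d$col))
    m[cbind(d$row, d$col)] <- as.integer(d$value)
    m
  })
  idx$grid <- grids[idx$window_id]
  idx
}
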