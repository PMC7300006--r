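#' Short-time magnitude spectrogram
#'
#' Computes a magnitude short-time Fourier spectrogram with the analysis
#' conventions used for the call spectrograms: 512-point FFT, Hamming
#' window, 95% overlap. Frames are half-open `[start, start + fft_len)`;
#' a trailing partial frame is dropped.
#'
#' @param w a [waveform()].
#' @param fft_len FFT length in samples.
#' @param window window name; `"hamming"` or `"hann"`.
#' @param overlap fractional overlap between consecutive frames in \[0, 1).
#' @return an object of class `"spectrogram"`: list with `magnitudes`
#'   (frame x frequency-bin matrix of linear amplitudes), `frame_times` (s,
#'   frame starts), `bin_freqs` (Hz, spanning 0..rate/2), `fft_len`,
#'   `overlap`, `window`, `rate`.
#' @export
spectrogram <- function(w, fft_len = 512, window = "hamming", overlap = 0.95) {
  stopifnot(inherits(w, "waveform"))
  n <- length(w$samples)
  if (n < fft_len)
    stop(sprintf(paste("signal (%d samples) is shorter than one frame (%d);",
                       "zero-pad the signal or reduce `fft_len`"), n, fft_len),
         call. = FALSE)
  win <- switch(window,
                hamming = as.numeric(signal::hamming(fft_len)),
                hann = as.numeric(signal::hanning(fft_len)),
                stop(sprintf("unknown window '%s'", window), call. = FALSE))
  step <- max(1L, as.integer(round(fft_len * (1 - overlap))))
  starts <- seq.int(1L, n - fft_len + 1L, by = step)
  nb <- fft_len %/% 2L + 1L
  frames <- matrix(w$samples[outer(0:(fft_len - 1L), starts, "+")],
                   nrow = fft_len)
  spec <- stats::mvfft(frames * win)
  mag <- t(Mod(spec[seq_len(nb), , drop = FALSE]))
  structure(list(magnitudes = mag,
                 frame_times = (starts - 1L) / w$rate,
                 bin_freqs = (0:(nb - 1L)) * w$rate / fft_len,
                 fft_len = as.integer(fft_len), overlap = overlap,
                 window = window, rate = w$rate),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d frames x %d bins, fft %d, %s window, %.0f%% overlap>\n",
              nrow(x$magnitudes), ncol(x$magnitudes), x$fft_len, x$window,
              100 * x$overlap))
  invisible(x)
}

#' Acoustic analysis configuration
#'
#' @param fft_len FFT length (samples).
#' @param window analysis window name.
#' @param overlap fractional frame overlap.
#' @param band_threshold_db threshold below the mean-spectrum peak (dB,
#'   positive) defining "dominant" bins for the frequency-range and
#'   dominant-frequency-band measures.
#' @param lowcut_hz stimulus high-pass cut-off frequency (Hz).
#' @param lowcut_order Butterworth order of the high-pass (applied
#'   forwards and backwards, so the effective order is doubled).
#' @return a list of settings.
#' @export
acoustic_config <- function(fft_len = 512, window = "hamming", overlap = 0.95,
                            band_threshold_db = 20, lowcut_hz = 1000,
                            lowcut_order = 4) {
  stopifnot(fft_len >= 16, overlap >= 0, overlap < 1, band_threshold_db > 0,
            lowcut_hz > 0, lowcut_order >= 1)
  list(fft_len = as.integer(fft_len), window = window, overlap = overlap,
       band_threshold_db = band_threshold_db, lowcut_hz = lowcut_hz,
       lowcut_order = as.integer(lowcut_order))
}

#' Extract the five call-unit acoustic parameters
#'
#' From one call unit's waveform computes, via the mean magnitude spectrum
#' over spectrogram frames:
#' * `PF` — overall peak frequency: bin of the global maximum of the mean
#'   spectrum (Hz);
#' * `FR` — frequency range: high edge minus low edge of the bins whose
#'   mean-spectrum amplitude exceeds the peak minus `band_threshold_db` dB;
#' * `DFB1` — first dominant frequency band: centre frequency of the
#'   lowest-frequency contiguous run of bins above that threshold;
#' * `DFA2` — mean over frames of the frequency at which the cumulative
#'   within-frame energy first reaches 50%;
#' * `duration` — signal length in ms.
#'
#' All frequency measures are amplitude-scale invariant.
#'
#' @param w a [waveform()] containing a single call unit.
#' @param cfg an [acoustic_config()].
#' @return named numeric vector `DFB1, DFA2, PF, FR, duration` (Hz except
#'   duration in ms).
#' @export
extract_features <- function(w, cfg = acoustic_config()) {
  stopifnot(inherits(w, "waveform"))
  if (all(w$samples == 0))
    stop("degenerate all-zero signal: acoustic features are undefined",
         call. = FALSE)
  sp <- spectrogram(w, fft_len = cfg$fft_len, window = cfg$window,
                    overlap = cfg$overlap)
  mean_spec <- colMeans(sp$magnitudes)
  freqs <- sp$bin_freqs
  pf <- freqs[which.max(mean_spec)]

  thr <- max(mean_spec) * 10 ^ (-cfg$band_threshold_db / 20)
  dom <- mean_spec >= thr
  fr <- freqs[max(which(dom))] - freqs[min(which(dom))]
  runs <- rle(dom)
  ends <- cumsum(runs$lengths)
  first_run <- which(runs$values)[1L]
  lo <- ends[first_run] - runs$lengths[first_run] + 1L
  hi <- ends[first_run]
  dfb1 <- (freqs[lo] + freqs[hi]) / 2

  energy <- sp$magnitudes ^ 2
  csum <- t(apply(energy, 1L, cumsum))
  tot <- csum[, ncol(csum)]
  med_bin <- apply(csum >= 0.5 * tot, 1L, function(z) which(z)[1L])
  dfa2 <- mean(freqs[med_bin])

  c(DFB1 = dfb1, DFA2 = dfa2, PF = pf, FR = fr,
    duration = duration_ms(w))
}

#' Extract features for every WAV in a metadata table
#'
#' Convenience wrapper running [extract_features()] over the files listed in
#' a metadata table (as produced by [gen_call_waveforms()]).
#'
#' @param meta data.frame with columns `unit_id, bout_id, caller_id, file`.
#' @param dir directory containing the WAV files.
#' @param cfg an [acoustic_config()].
#' @return a feature table `unit_id, bout_id, caller_id, DFB1, DFA2, PF,
#'   FR, duration`.
#' @export
extract_feature_table <- function(meta, dir, cfg = acoustic_config()) {
  feats <- t(vapply(meta$file, function(f)
    extract_features(load_wav(file.path(dir, f)), cfg), numeric(5L)))
  out <- cbind(meta[, c("unit_id", "bout_id", "caller_id")],
               as.data.frame(feats))
  rownames(out) <- NULL
  out
}

.skewness <- function(x) e1071::skewness(x, type = 2)

#' Normalise a call-unit feature table
#'
#' Optionally natural-log transforms each feature column and then z-scores
#' it (mean 0, sd 1). With `log_rule = "auto"`, a column is log-transformed
#' when a Shapiro-Wilk test rejects normality at 0.05 and the transform
#' reduces absolute skewness (requires all-positive values). Explicit rules
#' are given as a named logical vector over the feature columns.
#'
#' @param tab a feature table with the five feature columns.
#' @param log_rule `"auto"`, `"none"`, or a named logical vector.
#' @return the table with transformed, standardised feature columns and a
#'   `transform_flags` attribute (`"raw"` or `"log"` per feature).
#' @export
normalize_features <- function(tab, log_rule = "auto") {
  feats <- intersect(feature_names, colnames(tab))
  if (length(feats) == 0L) stop("no feature columns found", call. = FALSE)
  if (nrow(tab) < 2L) stop("need at least 2 rows to standardise", call. = FALSE)
  flags <- stats::setNames(rep("raw", length(feats)), feats)
  for (f in feats) {
    x <- tab[[f]]
    if (stats::sd(x) == 0)
      stop(sprintf("feature '%s' has zero variance", f), call. = FALSE)
    take_log <- FALSE
    if (identical(log_rule, "auto")) {
      if (all(x > 0) && nrow(tab) >= 3L && nrow(tab) <= 5000L) {
        sw <- stats::shapiro.test(x)
        if (sw$p.value < 0.05 &&
            abs(.skewness(log(x))) < abs(.skewness(x)))
          take_log <- TRUE
      }
    } else if (is.logical(log_rule)) {
      take_log <- isTRUE(log_rule[[f]])
    } else if (!identical(log_rule, "none")) {
      stop("`log_rule` must be 'auto', 'none', or a named logical vector",
           call. = FALSE)
    }
    if (take_log) {
      if (any(x <= 0))
        stop(sprintf("feature '%s' has non-positive values; cannot log", f),
             call. = FALSE)
      x <- log(x)
      flags[f] <- "log"
    }
    tab[[f]] <- as.numeric(scale(x))
  }
  attr(tab, "transform_flags") <- flags
  tab
}

#' Assemble a two-caller conflict stimulus
#'
#' Overlays the calls of two individuals with synchronous onsets, applies a
#' zero-phase Butterworth high-pass with a 1 kHz cut-off (removing energy
#' below the call band), standardises the result to exactly 4 s at the
#' input rate (zero-padded; longer inputs are truncated with a warning) and
#' peak-normalises to avoid clipping.
#'
#' @param a,b [waveform()]s at the same sampling rate.
#' @param cfg an [acoustic_config()] (uses `lowcut_hz` and `lowcut_order`).
#' @param target_s output duration in seconds.
#' @return a [waveform()] of exactly `target_s` seconds.
#' @export
build_stimulus <- function(a, b, cfg = acoustic_config(), target_s = 4) {
  stopifnot(inherits(a, "waveform"), inherits(b, "waveform"))
  if (a$rate != b$rate)
    stop(sprintf("sampling rates differ (%g vs %g Hz)", a$rate, b$rate),
         call. = FALSE)
  n_out <- round(target_s * a$rate)
  pad <- function(x) {
    if (length(x) > n_out) {
      warning(sprintf("input longer than %g s; truncated", target_s),
              call. = FALSE)
      x[seq_len(n_out)]
    } else c(x, rep(0, n_out - length(x)))
  }
  mix <- pad(a$samples) + pad(b$samples)
  if (any(mix != 0)) {
    bf <- signal::butter(cfg$lowcut_order, cfg$lowcut_hz / (a$rate / 2),
                         type = "high")
    mix <- signal::filtfilt(bf, mix)
    peak <- max(abs(mix))
    if (peak > 0.891) mix <- mix * 0.891 / peak  # -1 dBFS headroom
  }
  waveform(mix[seq_len(n_out)], a$rate)
}

#' Band energy of a waveform
#'
#' Mean squared-magnitude spectral energy of the bins inside a frequency
#' band; used to verify stop-band attenuation of assembled stimuli.
#'
#' @param w a [waveform()].
#' @param band `c(lo, hi)` in Hz.
#' @param cfg an [acoustic_config()].
#' @return scalar energy (linear).
#' @export
band_energy <- function(w, band, cfg = acoustic_config()) {
  sp <- spectrogram(w, fft_len = cfg$fft_len, window = cfg$window,
                    overlap = cfg$overlap)
  sel <- sp$bin_freqs >= band[1] & sp$bin_freqs <= band[2]
  mean(sp$magnitudes[, sel, drop = FALSE] ^ 2)
}
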