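#' @name metrics
#' @title Segment-based denoising metrics
#' @description
#' In field recordings the clean signal is unobservable, so denoising
#' quality is measured from manually labelled intervals: "noise"
#' intervals covering silence before/after the call (pure background
#' noise) and "song" intervals covering the call itself (signal plus
#' noise). Three metrics are computed: the signal-plus-noise to noise
#' ratio SnNR \eqn{= 10\log_{10}((S+N)/N)}, the success ratio
#' \eqn{\log_{10}(\mathrm{var}(N_b)/\mathrm{var}(N_a))} of the noise-only
#' region before/after denoising (positive means the noise floor
#' dropped), and a modified peak signal-to-noise ratio
#' \eqn{20\log_{10}(\max|x_{ref}| / \sqrt{\mathrm{MSE}})} between the
#' noisy reference and the denoised signal.
NULL

#' Labelled intervals of a recording
#'
#' @param start_s,end_s Interval boundaries in seconds, `0 <= start < end`.
#' @param kind `"noise"` (background only) or `"song"` (call present).
#' @return A `segment_label` object (a one-row data frame).
#' @export
segment_label <- function(start_s, end_s, kind = c("noise", "song")) {
  kind <- match.arg(kind)
  if (!is.numeric(start_s) || !is.numeric(end_s) ||
      start_s < 0 || end_s <= start_s) {
    stop("invalid interval: need 0 <= start_s < end_s")
  }
  structure(data.frame(start_s = start_s, end_s = end_s, kind = kind,
                       stringsAsFactors = FALSE),
            class = c("segment_label", "data.frame"))
}

# Validate and normalize a label set: a data frame with columns
# start_s, end_s, kind. Checks ordering, bounds, and same-kind overlap.
validate_labels <- function(labels, duration_s = NULL) {
  if (inherits(labels, "segment_label")) labels <- as.data.frame(labels)
  if (is.list(labels) && !is.data.frame(labels)) {
    labels <- do.call(rbind, lapply(labels, as.data.frame))
  }
  need <- c("start_s", "end_s", "kind")
  if (!is.data.frame(labels) || !all(need %in% names(labels))) {
    stop("labels must have columns start_s, end_s, kind")
  }
  if (nrow(labels) == 0L) stop("no labelled intervals")
  if (!all(labels$kind %in% c("noise", "song"))) {
    stop("unknown label kind: ", paste(setdiff(labels$kind, c("noise", "song")),
                                       collapse = ", "))
  }
  if (any(labels$end_s <= labels$start_s) || any(labels$start_s < 0)) {
    stop("invalid interval: need 0 <= start_s < end_s")
  }
  if (!is.null(duration_s) && any(labels$end_s > duration_s + 1e-9)) {
    stop("labelled interval extends beyond the recording (",
         format(duration_s, digits = 6), " s)")
  }
  labels <- labels[order(labels$start_s), , drop = FALSE]
  for (k in unique(labels$kind)) {
    sub <- labels[labels$kind == k, , drop = FALSE]
    if (nrow(sub) > 1L &&
        any(sub$start_s[-1L] < sub$end_s[-nrow(sub)] - 1e-12)) {
      stop("overlapping '", k, "' intervals")
    }
  }
  rownames(labels) <- NULL
  labels
}

#' A recording with noise/song interval labels
#'
#' Pairs a waveform with the labelled intervals needed by the
#' segment-based metrics. At least one noise and one song interval are
#' required.
#'
#' @param audio An [audio_signal()].
#' @param labels A data frame with columns `start_s`, `end_s`, `kind`
#'   (values `"noise"`/`"song"`), e.g. from [read_labels()] or built from
#'   [segment_label()] rows.
#' @return An object of class `annotated_recording`.
#' @export
annotated_recording <- function(audio, labels) {
  stopifnot(inherits(audio, "audio_signal"))
  labels <- validate_labels(labels, duration(audio))
  if (!any(labels$kind == "noise") || !any(labels$kind == "song")) {
    stop("need at least one 'noise' and one 'song' interval")
  }
  structure(list(audio = audio, labels = labels),
            class = "annotated_recording")
}

#' @export
print.annotated_recording <- function(x, ...) {
  cat(sprintf("<annotated_recording> %.3f s, %d noise / %d song intervals\n",
              duration(x$audio), sum(x$labels$kind == "noise"),
              sum(x$labels$kind == "song")))
  invisible(x)
}

# sample indices covered by the union of intervals of one kind
label_indices <- function(audio, labels, kind = NULL) {
  if (!is.null(kind)) labels <- labels[labels$kind == kind, , drop = FALSE]
  fs <- audio$sample_rate
  n <- length(audio$samples)
  idx <- integer(0)
  for (r in seq_len(nrow(labels))) {
    from <- max(1L, floor(labels$start_s[r] * fs) + 1L)
    to <- min(n, ceiling(labels$end_s[r] * fs))
    if (to >= from) idx <- c(idx, from:to)
  }
  unique(idx)
}

#' Mean power over labelled intervals
#'
#' Power is the mean squared amplitude over all samples in the union of
#' the given intervals, so intervals of unequal total duration compare
#' fairly.
#'
#' @param audio An [audio_signal()].
#' @param labels Data frame of intervals (columns `start_s`, `end_s`,
#'   optionally `kind`); all rows are used.
#' @return Mean squared amplitude.
#' @export
segment_power <- function(audio, labels) {
  stopifnot(inherits(audio, "audio_signal"))
  if (!"kind" %in% names(labels)) labels$kind <- "song"
  labels <- validate_labels(labels, duration(audio))
  idx <- label_indices(audio, labels)
  if (length(idx) == 0L) stop("labelled intervals cover no samples")
  mean(audio$samples[idx]^2)
}

#' Signal-to-noise ratio in decibels
#'
#' @param signal_power Power of the signal (>= 0).
#' @param noise_power Power of the noise (> 0).
#' @return \eqn{10 \log_{10}(S/N)} in dB.
#' @examples
#' snr(100, 1)  # 20 dB
#' @export
snr <- function(signal_power, noise_power) {
  if (!is.numeric(noise_power) || noise_power <= 0) {
    stop("degenerate metric: noise power must be > 0")
  }
  if (signal_power < 0) stop("signal power must be >= 0")
  10 * log10(signal_power / noise_power)
}

#' Signal-plus-noise to noise ratio (SnNR)
#'
#' The field-recording surrogate for SNR: since the pure signal is not
#' observable, the power over the song intervals (signal + noise) is
#' compared against the power over the noise-only intervals. With known
#' true SNR it satisfies \eqn{\mathrm{SnNR} = 10\log_{10}(1 +
#' 10^{\mathrm{SNR}/10})}.
#'
#' @param rec An [annotated_recording()].
#' @return SnNR in dB.
#' @export
snnr <- function(rec) {
  stopifnot(inherits(rec, "annotated_recording"))
  p_song <- segment_power(rec$audio,
                          rec$labels[rec$labels$kind == "song", , drop = FALSE])
  p_noise <- segment_power(rec$audio,
                           rec$labels[rec$labels$kind == "noise", , drop = FALSE])
  snr(p_song, p_noise)
}

#' Success ratio of a denoising run
#'
#' \eqn{\log_{10}(\mathrm{var}(N_b)/\mathrm{var}(N_a))} where \eqn{N_b}
#' and \eqn{N_a} are the samples of the noise-only intervals before and
#' after denoising (population variance). Values above 0 mean the noise
#' floor was reduced; each unit is a tenfold variance reduction.
#'
#' @param noise_before,noise_after Numeric sample vectors from the same
#'   noise-labelled intervals before/after denoising.
#' @return The success ratio (dimensionless).
#' @export
success_ratio <- function(noise_before, noise_after) {
  noise_before <- as_samples(noise_before)
  noise_after <- as_samples(noise_after)
  if (length(noise_before) == 0L || length(noise_after) == 0L) {
    stop("noise segments must be non-empty")
  }
  pv <- function(x) mean((x - mean(x))^2)
  va <- pv(noise_after)
  if (va == 0) {
    stop("degenerate metric: denoised noise segment is perfectly silent")
  }
  log10(pv(noise_before) / va)
}

#' Modified peak signal-to-noise ratio
#'
#' \eqn{20\log_{10}(\max|x_{ref}| / \sqrt{\mathrm{MSE}})} with the noisy
#' recording as the reference and its denoised version as the test. The
#' peak of the reference does not change with denoising, so PSNR mostly
#' tracks how much the waveform moved.
#'
#' @param reference,test [audio_signal()]s or numeric vectors of equal
#'   length.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test) {
  r <- as_samples(reference)
  t <- as_samples(test)
  if (length(r) != length(t)) stop("signals must have equal length")
  mse <- mean((r - t)^2)
  if (mse == 0) stop("degenerate metric: signals are identical (MSE = 0)")
  20 * log10(max(abs(r)) / sqrt(mse))
}

#' Full metrics report for a denoising run
#'
#' Computes SnNR before and after, the success ratio over the
#' noise-labelled intervals, and PSNR of denoised against noisy, in the
#' layout used to compare the original (O), filtered (F), denoised (D)
#' and denoised-plus-filtered (DF) variants.
#'
#' @param rec An [annotated_recording()] of the original noisy recording.
#' @param denoised The denoised [audio_signal()] (same length).
#' @return A one-row data frame with columns `snnr_before_db`,
#'   `snnr_after_db`, `success_ratio`, `psnr_db`, `song_power`,
#'   `noise_power`.
#' @export
metrics_report <- function(rec, denoised) {
  stopifnot(inherits(rec, "annotated_recording"))
  den <- audio_signal(as_samples(denoised), rec$audio$sample_rate)
  if (length(den$samples) != length(rec$audio$samples)) {
    stop("denoised signal must have the same length as the recording")
  }
  noise_idx <- label_indices(rec$audio, rec$labels, "noise")
  rec_after <- annotated_recording(den, rec$labels)
  data.frame(
    snnr_before_db = snnr(rec),
    snnr_after_db = snnr(rec_after),
    success_ratio = success_ratio(rec$audio$samples[noise_idx],
                                  den$samples[noise_idx]),
    psnr_db = psnr(rec$audio, den),
    song_power = segment_power(rec$audio,
                               rec$labels[rec$labels$kind == "song", , drop = FALSE]),
    noise_power = segment_power(rec$audio,
                                rec$labels[rec$labels$kind == "noise", , drop = FALSE])
  )
}
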