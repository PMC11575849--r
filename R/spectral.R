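#' Welch power spectral density estimate
#'
#' Averaged modified periodogram of a force-magnitude series: Hann-windowed
#' segments (default 256 samples, 50% overlap), per-segment mean removal,
#' one-sided density normalised by `fs * sum(w^2)` so that
#' `sum(power) * resolution` approximates the signal variance (Parseval).
#' The default 256-sample window gives the 1000/256 = 3.90625 Hz grid on
#' which the study's printed peak frequencies (3.91, 66.41, 85.94 Hz) lie
#' exactly.
#'
#' @param x numeric series (e.g. instantaneous 3D force magnitude).
#' @param fs sampling rate, Hz.
#' @param window segment length in samples (default 256).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return A `data.frame` of class `psd_curve` with columns `freq` (0 to
#'   Nyquist) and `power`, and attribute `resolution` = `fs / window`.
#' @export
power_spectrum <- function(x, fs, window = 256L, overlap = 0.5) {
  n <- length(x)
  window <- as.integer(window)
  if (window > n) stop_domain("window longer than the series")
  if (fs <= 0) stop_domain("fs must be positive")
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  starts <- seq(1L, n - window + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(window - 1)) / window)  # periodic Hann
  scale <- fs * sum(w^2)
  nb <- window %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + window - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nb)])^2 / scale
    acc <- acc + sp
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC and (for even windows) Nyquist
  dbl <- rep(2, nb); dbl[1] <- 1; if (window %% 2L == 0L) dbl[nb] <- 1
  p <- p * dbl
  structure(data.frame(freq = (seq_len(nb) - 1) * fs / window, power = p),
            resolution = fs / window, class = c("psd_curve", "data.frame"))
}

#' Per-frequency median of PSD curves
#'
#' The treatment-level spectral summary: the median across fish of the
#' per-fish PSD curves, bin by bin. All curves must share one grid.
#'
#' @param curves list of `psd_curve` objects on a common frequency grid.
#' @return A `psd_curve` with the per-bin median power.
#' @export
median_psd <- function(curves) {
  if (length(curves) == 0L) stop_domain("no curves supplied")
  f0 <- curves[[1]]$freq
  same <- vapply(curves, function(cv)
    length(cv$freq) == length(f0) && all(cv$freq == f0), TRUE)
  if (!all(same)) stop_domain("PSD curves are on mismatched frequency grids")
  pw <- vapply(curves, function(cv) cv$power, numeric(length(f0)))
  structure(data.frame(freq = f0, power = apply(pw, 1, stats::median)),
            resolution = attr(curves[[1]], "resolution"),
            class = c("psd_curve", "data.frame"))
}

#' Dominant spectral peaks of a PSD curve
#'
#' Frequencies of the `k` local maxima with greatest power, in decreasing
#' power order. A local maximum strictly exceeds both neighbours; peaks are
#' reported on the grid without interpolation. If fewer than `k` local
#' maxima exist, all found are returned with attribute `incomplete = TRUE`.
#'
#' @param curve a `psd_curve`.
#' @param k number of peaks (default 5).
#' @return Numeric vector of peak frequencies (Hz), attribute `power` with
#'   the corresponding powers.
#' @export
top_peaks <- function(curve, k = 5L) {
  p <- curve$power
  nb <- length(p)
  if (nb < 2L * k) stop_domain("curve has too few bins for ", k, " peaks")
  i <- 2:(nb - 1L)
  is_peak <- p[i] > p[i - 1L] & p[i] > p[i + 1L]
  idx <- i[is_peak]
  idx <- idx[order(p[idx], decreasing = TRUE)]
  incomplete <- length(idx) < k
  if (incomplete)
    warning("fewer than ", k, " local maxima found", call. = FALSE)
  idx <- utils::head(idx, k)
  structure(curve$freq[idx], power = p[idx], incomplete = incomplete)
}

#' Median PSD and peak table per treatment
#'
#' Computes each preserved-fish run's PSD of the instantaneous 3D force
#' magnitude, takes the per-treatment median curve, and extracts the top-k
#' peak frequencies for comparison across treatments.
#'
#' @param bundle an `experiment_bundle`.
#' @param window,overlap Welch parameters (see [power_spectrum()]).
#' @param k peaks per treatment.
#' @param r lever length, m.
#' @return list with `curves` (named list of median `psd_curve`s) and
#'   `peaks` (`data.frame` treatment/rank/freq/power).
#' @export
psd_by_treatment <- function(bundle, window = 256L, overlap = 0.5, k = 5L,
                             r = 0.10) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  keep <- vapply(bundle$runs, function(x) x$object_class == "preserved", TRUE)
  runs <- bundle$runs[keep]
  trs <- vapply(runs, `[[`, "", "treatment")
  curves <- lapply(TREATMENTS, function(tr) {
    per_fish <- lapply(runs[trs == tr], function(run)
      power_spectrum(force_magnitude(run, r), run$fs, window, overlap))
    median_psd(per_fish)
  })
  names(curves) <- TREATMENTS
  peaks <- do.call(rbind, lapply(TREATMENTS, function(tr) {
    pk <- top_peaks(curves[[tr]], k)
    data.frame(treatment = tr, rank = seq_along(pk), freq = as.numeric(pk),
               power = attr(pk, "power"), stringsAsFactors = FALSE)
  }))
  list(curves = curves, peaks = peaks)
}
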