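#' Cohort configuration for the synthetic fish population
#'
#' Describes the morphometric distribution of the study population: 112 round
#' gobies (60 males, 37 females, 15 juveniles) with total length
#' 9.71 cm (s.d. 1.54), wet weight 12.95 g (s.d. 6.11), head width
#' 1.93 cm (s.d. 0.36) and body depth 1.83 cm (s.d. 0.30). Morphometric draws
#' are truncated at zero (physical positivity). Pectoral fin-spread and
#' body-arch angle distributions are not summarised numerically in the study
#' population table; the defaults (fin angles ~ N(25, 12) degrees, arch
#' ~ N(8, 5) degrees, truncated at zero) are chosen as realistic for slightly
#' spread fins and mostly straight preserved bodies.
#'
#' @param n_fish total number of fish.
#' @param n_male,n_female,n_juvenile sex counts; must sum to `n_fish`.
#'   Juveniles carry the sex label `"undefined"`.
#' @param TL_mean,TL_sd total length, cm.
#' @param WW_mean,WW_sd wet weight, g.
#' @param HW_mean,HW_sd maximum head width, cm.
#' @param BD_mean,BD_sd maximum body depth, cm.
#' @param fin_angle_mean,fin_angle_sd per-side pectoral fin-spread angle,
#'   degrees.
#' @param arch_mean,arch_sd body-arch angle, degrees.
#' @param seed integer seed for cohort generation.
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_fish = 112L,
                          n_male = 60L, n_female = 37L, n_juvenile = 15L,
                          TL_mean = 9.71, TL_sd = 1.54,
                          WW_mean = 12.95, WW_sd = 6.11,
                          HW_mean = 1.93, HW_sd = 0.36,
                          BD_mean = 1.83, BD_sd = 0.30,
                          fin_angle_mean = 25, fin_angle_sd = 12,
                          arch_mean = 8, arch_sd = 5,
                          seed = 1L) {
  cfg <- list(n_fish = as.integer(n_fish), n_male = as.integer(n_male),
              n_female = as.integer(n_female), n_juvenile = as.integer(n_juvenile),
              TL_mean = TL_mean, TL_sd = TL_sd, WW_mean = WW_mean, WW_sd = WW_sd,
              HW_mean = HW_mean, HW_sd = HW_sd, BD_mean = BD_mean, BD_sd = BD_sd,
              fin_angle_mean = fin_angle_mean, fin_angle_sd = fin_angle_sd,
              arch_mean = arch_mean, arch_sd = arch_sd,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  counts <- c(cfg$n_fish, cfg$n_male, cfg$n_female, cfg$n_juvenile)
  if (any(counts < 0L))
    stop_domain("cohort counts must be non-negative")
  if (cfg$n_male + cfg$n_female + cfg$n_juvenile != cfg$n_fish)
    stop_domain("n_male + n_female + n_juvenile must equal n_fish")
  scales <- c(cfg$TL_mean, cfg$TL_sd, cfg$WW_mean, cfg$WW_sd, cfg$HW_mean,
              cfg$HW_sd, cfg$BD_mean, cfg$BD_sd, cfg$fin_angle_sd, cfg$arch_sd)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop_domain("all morphometric scale parameters must be positive")
  structure(cfg, class = "cohort_config")
}

#' Treatment labels used throughout the package
#'
#' Column Smooth, Column Rough (10 cm above the bottom), Bottom Rough and
#' Bottom Smooth (5 mm above the bottom). The integer class labels used by
#' the classifier are CS = 0, CR = 1, BR = 2, BS = 3.
#' @export
TREATMENTS <- c("CS", "CR", "BR", "BS")

#' Integer class labels for the four treatments (CS 0, CR 1, BR 2, BS 3)
#' @export
TREATMENT_LABELS <- c(CS = 0L, CR = 1L, BR = 2L, BS = 3L)

#' Signal configuration for the synthetic force recordings
#'
#' Defines the study conditions the generator emulates: 60 s records at
#' 1000 Hz; per-treatment mean 3D hydraulic force targets for preserved fish
#' (CR 0.077, BR 0.070, BS 0.070, CS 0.068 N), 3D-printed fish, the rubber
#' ball, and the empty fixation stick ("reference": BS 0.034, CS 0.035,
#' BR 0.038, CR 0.041 N); per-treatment signal-to-noise targets
#' (CR 12.10, CS 13.69, BR 13.30, BS 13.13); and per-treatment spectral peak
#' sets on the 1000/256 = 3.90625 Hz grid, with the BS-specific peaks at
#' 66.41 and 85.94 Hz and a shared dominance of peaks below 66.41 Hz.
#'
#' The generated signal for one run is a constant mean force vector (whose
#' Euclidean norm is the planted run mean) plus three fluctuation components
#' whose total variance is `(mean / SNR)^2`: planted sinusoids at the
#' treatment's peak frequencies, Gaussian white noise, and a band-limited
#' 1/f ("pink") low-frequency component. `noise_scale = 0` switches all
#' fluctuations off, giving an exactly constant record.
#'
#' @param fs sampling rate, Hz.
#' @param duration record length, s; `fs * duration` must be an integer.
#' @param target_f3d named numeric, per-treatment mean F_3D targets (N) for
#'   preserved fish.
#' @param target_snr named numeric, per-treatment SNR targets
#'   (mean / s.d. of the instantaneous 3D force magnitude).
#' @param reference_f3d,printed_f3d,ball_f3d per-treatment mean F_3D targets
#'   (N) for the other object classes.
#' @param peaks named list of per-treatment peak frequency vectors, Hz; all
#'   must lie below `fs / 2`.
#' @param peak_weights named list of relative peak amplitudes (same lengths
#'   as `peaks`).
#' @param share_sine,share_white,share_pink fluctuation variance shares;
#'   must sum to 1.
#' @param pink_band frequency band of the 1/f component, Hz.
#' @param direction unit-normalised mean force direction (X drag-dominant).
#' @param sigma_fish log-s.d. of the per-fish multiplicative (log-normal)
#'   force effect, shared by all four runs of one fish.
#' @param sigma_run log-s.d. of the per-run multiplicative effect.
#' @param sigma_run_reference per-run log-s.d. for reference runs.
#' @param beta_fin planted log-scale coefficients for fin-spread classes
#'   1 to 4 (class 1 is the reference level).
#' @param beta_arch planted log-scale coefficient per degree of body arch.
#' @param beta_ww planted log-scale coefficient per gram of wet weight.
#' @param arch_ref,arch_sd_ref,ww_ref,ww_sd_ref centring values used to keep
#'   the planted morphometric effects mean-neutral; defaults match
#'   [cohort_config()].
#' @param lever_r lever length of the fixation stick, m.
#' @param noise_scale overall fluctuation amplitude multiplier.
#' @param seed integer seed for signal generation.
#' @return A list of class `signal_config`.
#' @seealso [generate_force_series()], [generate_experiment()]
#' @export
signal_config <- function(fs = 1000, duration = 60,
                          target_f3d = c(CS = 0.068, CR = 0.077, BR = 0.070, BS = 0.070),
                          target_snr = c(CS = 13.69, CR = 12.10, BR = 13.30, BS = 13.13),
                          reference_f3d = c(CS = 0.035, CR = 0.041, BR = 0.038, BS = 0.034),
                          printed_f3d = c(CS = 0.092, CR = 0.100, BR = 0.112, BS = 0.105),
                          ball_f3d = c(CS = 0.143, CR = 0.154, BR = 0.194, BS = 0.178),
                          peaks = NULL, peak_weights = NULL,
                          share_sine = 0.5, share_white = 0.4, share_pink = 0.1,
                          pink_band = c(5, 100),
                          direction = c(0.88, 0.33, 0.34),
                          sigma_fish = 0.08, sigma_run = 0.27,
                          sigma_run_reference = 0.18,
                          beta_fin = c(0, 0.10, 0.18, 0.28),
                          beta_arch = 0.010, beta_ww = 0.008,
                          arch_ref = 8, arch_sd_ref = 5,
                          ww_ref = 12.95, ww_sd_ref = 6.11,
                          lever_r = 0.10, noise_scale = 1,
                          seed = 1L) {
  grid <- 1000 / 256  # 3.90625 Hz, the PSD bin width implied by the peak grid
  if (is.null(peaks)) {
    # Peak bins are spaced >= 2 apart so each planted frequency survives as
    # a distinct local maximum under the Hann main-lobe leakage (+-1 bin).
    peaks <- list(
      CS = grid * c(1, 4, 7, 10, 13),
      CR = grid * c(1, 3, 6, 9, 12),
      BR = grid * c(1, 5, 8, 11, 14),
      # BS: no 3.91 Hz peak, extra peaks at 66.41 (17 * grid) and 85.94 Hz
      # (22 * grid); four stronger peaks stay below 66.41 Hz.
      BS = grid * c(2, 4, 6, 9, 17, 22))
  }
  if (is.null(peak_weights)) {
    peak_weights <- lapply(peaks, function(p) {
      w <- seq(1, 0.5, length.out = length(p))
      w
    })
  }
  cfg <- list(fs = fs, duration = duration,
              target_f3d = target_f3d, target_snr = target_snr,
              reference_f3d = reference_f3d, printed_f3d = printed_f3d,
              ball_f3d = ball_f3d,
              peaks = peaks, peak_weights = peak_weights,
              share_sine = share_sine, share_white = share_white,
              share_pink = share_pink, pink_band = pink_band,
              direction = direction / sqrt(sum(direction^2)),
              sigma_fish = sigma_fish, sigma_run = sigma_run,
              sigma_run_reference = sigma_run_reference,
              beta_fin = beta_fin, beta_arch = beta_arch, beta_ww = beta_ww,
              arch_ref = arch_ref, arch_sd_ref = arch_sd_ref,
              ww_ref = ww_ref, ww_sd_ref = ww_sd_ref,
              lever_r = lever_r, noise_scale = noise_scale,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  n <- cfg$fs * cfg$duration
  if (abs(n - round(n)) > 1e-9)
    stop_domain("fs * duration must be an integer sample count")
  for (tbl in list(cfg$target_f3d, cfg$target_snr, cfg$reference_f3d)) {
    if (!all(TREATMENTS %in% names(tbl)) || any(tbl[TREATMENTS] <= 0))
      stop_domain("per-treatment targets must be positive and named CS/CR/BR/BS")
  }
  if (!all(TREATMENTS %in% names(cfg$peaks)))
    stop_domain("peaks must be a named list covering CS/CR/BR/BS")
  if (any(unlist(cfg$peaks) >= cfg$fs / 2))
    stop_domain("peak frequencies must lie below the Nyquist frequency")
  shares <- share_sine + share_white + share_pink
  if (abs(shares - 1) > 1e-8)
    stop_domain("fluctuation variance shares must sum to 1")
  if (noise_scale < 0) stop_domain("noise_scale must be non-negative")
  structure(cfg, class = "signal_config")
}
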