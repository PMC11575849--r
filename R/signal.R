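# Synthetic force-signal generation: each run is a constant mean force
# vector (norm = planted run mean) plus calibrated fluctuations: planted
# sinusoids at the treatment's spectral peaks, white noise, and a
# band-limited 1/f component. Torque channels are force * lever so that the
# moment-arm conversion downstream recovers the planted forces.

# Planted morphometric multiplier exp(beta * x), centred so its expectation
# over the cohort distribution is ~1: quartile classes are uniform on 1..4
# by construction, and the continuous effects use the log-normal moment
# E[exp(b (X - mu))] = exp(b^2 sd^2 / 2).
planted_multiplier <- function(fish, config) {
  need <- c("FinSpreadClass", "Arch_deg", "WW_g")
  if (!all(need %in% names(fish))) return(1)
  eta <- config$beta_fin[fish$FinSpreadClass] +
    config$beta_arch * (fish$Arch_deg - config$arch_ref) +
    config$beta_ww * (fish$WW_g - config$ww_ref)
  norm <- mean(exp(config$beta_fin)) *
    exp((config$beta_arch * config$arch_sd_ref)^2 / 2) *
    exp((config$beta_ww * config$ww_sd_ref)^2 / 2)
  exp(eta) / norm
}

target_for <- function(object_class, treatment, config) {
  tbl <- switch(object_class,
                preserved = config$target_f3d,
                printed   = config$printed_f3d,
                ball      = config$ball_f3d,
                reference = config$reference_f3d,
                stop_domain("unknown object class: ", object_class))
  unname(tbl[[treatment]])
}

# Band-limited 1/f noise via frequency-domain shaping of white noise,
# rescaled to an exact sample s.d.
pink_noise <- function(n, fs, band, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  shape <- ifelse(f >= band[1] & f <= band[2], 1 / sqrt(pmax(f, band[1])), 0)
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y * (sd_target / s)
}

# Deterministic planted run mean: treatment target x morphometric multiplier
# x fish-level effect x run-level effect (both log-normal, mean 1).
draw_run_mean <- function(fish, treatment, object_class, config,
                          fish_effect = NULL, multiplier = NULL) {
  m0 <- target_for(object_class, treatment, config)
  if (object_class == "reference") {
    sr <- config$sigma_run_reference
    return(m0 * stats::rlnorm(1, -sr^2 / 2, sr))
  }
  mult <- multiplier %||% planted_multiplier(fish, config)
  if (is.null(fish_effect)) {
    sf <- config$sigma_fish
    fish_effect <- stats::rlnorm(1, -sf^2 / 2, sf)
  }
  sr <- config$sigma_run
  m0 * mult * fish_effect * stats::rlnorm(1, -sr^2 / 2, sr)
}

#' Generate one synthetic 3-channel sensor record
#'
#' Produces a 60 s, 1000 Hz record of torque X/Y (N m) and force Z (N) for
#' one fish under one treatment. The Euclidean norm of the planted mean
#' force vector equals the treatment target scaled by the fish's planted
#' morphometric effects and the fish- and run-level random effects; total
#' fluctuation variance is calibrated so the expected signal-to-noise ratio
#' (mean / s.d. of the instantaneous 3D force magnitude) matches the
#' treatment target; sinusoids are planted at the treatment's configured
#' peak frequencies.
#'
#' @param fish one-row `data.frame` (a fish record); may carry the derived
#'   columns `FinSpreadClass`, `Arch_deg`, `WW_g` for planted effects.
#' @param treatment one of `"CS"`, `"CR"`, `"BR"`, `"BS"`.
#' @param object_class `"preserved"`, `"printed"`, `"ball"` or `"reference"`.
#' @param config a [signal_config()]. Its seed is *not* applied here; seed
#'   externally (or via [generate_experiment()]) for reproducibility.
#' @param fish_effect optional pre-drawn fish-level multiplicative effect
#'   (shared across that fish's runs).
#' @param multiplier optional pre-computed morphometric multiplier;
#'   [generate_experiment()] passes cohort-normalised multipliers (mean
#'   exactly one over the cohort) so treatment means are unbiased, while a
#'   standalone call uses the analytic centring of `planted_multiplier`.
#' @return A list of class `force_series` with elements `fish_id`,
#'   `treatment`, `object_class`, `fs`, `Mx_Nm`, `My_Nm`, `Fz_N` and the
#'   planted run mean as attribute `planted_mean`.
#' @export
generate_force_series <- function(fish, treatment,
                                  object_class = "preserved",
                                  config = signal_config(),
                                  fish_effect = NULL, multiplier = NULL) {
  stopifnot(inherits(config, "signal_config"))
  if (!treatment %in% TREATMENTS)
    stop_domain("unknown treatment label: ", treatment)
  n <- as.integer(round(config$fs * config$duration))
  m_run <- draw_run_mean(fish, treatment, object_class, config, fish_effect,
                         multiplier)
  mu <- m_run * config$direction

  v <- (m_run / config$target_snr[[treatment]])^2 * config$noise_scale^2
  freqs <- config$peaks[[treatment]]
  w <- config$peak_weights[[treatment]]
  amps <- if (v > 0) w * sqrt(2 * config$share_sine * v / sum(w^2)) else numeric(length(w))
  tt <- (seq_len(n) - 1) / config$fs
  sd_white <- sqrt(config$share_white * v)
  sd_pink <- sqrt(config$share_pink * v)

  chan <- lapply(1:3, function(c_i) {
    x <- rep(mu[c_i], n)
    if (v > 0) {
      for (k in seq_along(freqs)) {
        phi <- stats::runif(1, 0, 2 * pi)
        x <- x + amps[k] * cos(2 * pi * freqs[k] * tt + phi)
      }
      if (sd_white > 0) x <- x + stats::rnorm(n, 0, sd_white)
      if (sd_pink > 0) x <- x + pink_noise(n, config$fs, config$pink_band, sd_pink)
    }
    x
  })

  structure(list(fish_id = if ("ID" %in% names(fish)) fish$ID else NA_character_,
                 treatment = treatment, object_class = object_class,
                 fs = config$fs,
                 Mx_Nm = chan[[1]] * config$lever_r,
                 My_Nm = chan[[2]] * config$lever_r,
                 Fz_N = chan[[3]]),
            planted_mean = m_run, class = "force_series")
}

#' @export
print.force_series <- function(x, ...) {
  cat(sprintf("<force_series> %s / %s (%s), %d samples at %g Hz\n",
              x$fish_id, x$treatment, x$object_class, length(x$Fz_N), x$fs))
  invisible(x)
}

#' Generate a full synthetic flume experiment
#'
#' One record per fish x four treatments, plus four reference runs (empty
#' fixation stick) per treatment with lower force targets. The cohort is
#' generated and its derived morphometrics computed first; fish-level random
#' effects are drawn once per fish and shared across that fish's runs. Fully
#' reproducible from the two config seeds.
#'
#' @param cohort_cfg a [cohort_config()].
#' @param signal_cfg a [signal_config()].
#' @param n_reference_per_treatment reference runs per treatment (default 4).
#' @return A list of class `experiment_bundle` with elements `cohort` (the
#'   derived cohort table), `runs` (list of [generate_force_series()]
#'   outputs), and both configs.
#' @export
generate_experiment <- function(cohort_cfg = cohort_config(),
                                signal_cfg = signal_config(),
                                n_reference_per_treatment = 4L) {
  cohort <- derive_morphometrics(generate_cohort(cohort_cfg))
  runs <- with_seed(signal_cfg$seed, {
    sf <- signal_cfg$sigma_fish
    effects <- stats::rlnorm(nrow(cohort), -sf^2 / 2, sf)
    mult <- vapply(seq_len(nrow(cohort)), function(f)
      planted_multiplier(cohort[f, , drop = FALSE], signal_cfg), 0)
    mult <- mult / mean(mult)  # cohort-exact centring
    out <- vector("list", nrow(cohort) * 4L +
                    4L * n_reference_per_treatment)
    i <- 0L
    for (f in seq_len(nrow(cohort))) {
      for (tr in TREATMENTS) {
        i <- i + 1L
        out[[i]] <- generate_force_series(cohort[f, , drop = FALSE], tr,
                                          "preserved", signal_cfg,
                                          fish_effect = effects[f],
                                          multiplier = mult[f])
      }
    }
    ref_i <- 0L
    for (tr in TREATMENTS) {
      for (r in seq_len(n_reference_per_treatment)) {
        i <- i + 1L; ref_i <- ref_i + 1L
        s <- generate_force_series(data.frame(ID = sprintf("REF%02d", ref_i)),
                                   tr, "reference", signal_cfg)
        out[[i]] <- s
      }
    }
    out
  })
  structure(list(cohort = cohort, runs = runs,
                 cohort_config = cohort_cfg, signal_config = signal_cfg),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  oc <- vapply(x$runs, `[[`, "", "object_class")
  cat(sprintf("<experiment_bundle> %d fish, %d runs (%s)\n",
              nrow(x$cohort), length(x$runs),
              paste(sprintf("%s: %d", names(table(oc)), table(oc)),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate run-level force summaries without full time series
#'
#' Draws per-run mean 3D forces directly from the same planted model used by
#' [generate_force_series()] (treatment target x morphometric multiplier x
#' fish effect x run effect), skipping the 60 000-sample signal synthesis.
#' Intended for statistics-scale Monte Carlo (GLM parameter recovery, test
#' calibration) where hundreds of replicate experiments are needed; the
#' full-series route is tied to this one by round-trip tests.
#'
#' @inheritParams generate_experiment
#' @param seed optional seed overriding `signal_cfg$seed`.
#' @return A `data.frame` with one row per fish x treatment: identity,
#'   morphometrics, `treatment` and the planted run mean `F3D_N`.
#' @export
simulate_run_table <- function(cohort_cfg = cohort_config(),
                               signal_cfg = signal_config(),
                               seed = NULL) {
  cohort <- derive_morphometrics(generate_cohort(cohort_cfg))
  with_seed(seed %||% signal_cfg$seed, {
    sf <- signal_cfg$sigma_fish
    sr <- signal_cfg$sigma_run
    effects <- stats::rlnorm(nrow(cohort), -sf^2 / 2, sf)
    mult <- vapply(seq_len(nrow(cohort)), function(f)
      planted_multiplier(cohort[f, , drop = FALSE], signal_cfg), 0)
    mult <- mult / mean(mult)  # cohort-exact centring
    rows <- expand.grid(f = seq_len(nrow(cohort)), treatment = TREATMENTS,
                        stringsAsFactors = FALSE)
    m0 <- signal_cfg$target_f3d[rows$treatment]
    f3d <- m0 * mult[rows$f] * effects[rows$f] *
      stats::rlnorm(nrow(rows), -sr^2 / 2, sr)
    out <- cbind(cohort[rows$f, , drop = FALSE],
                 data.frame(treatment = rows$treatment,
                            object_class = "preserved",
                            F3D_N = unname(f3d)))
    rownames(out) <- NULL
    out
  })
}

#' Write an experiment bundle to plain-text files
#'
#' Writes `cohort.csv`, a `manifest.csv`, per-run sensor CSVs
#' (`runs/<fishID>_<treatment>.csv` with columns `t_s, Mx_Nm, My_Nm, Fz_N`)
#' and the configs as JSON. Numeric values are written with 17 significant
#' digits so a read-back reproduces the doubles bit-for-bit.
#'
#' @param bundle an [generate_experiment()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  num <- function(x) sprintf("%.17g", x)
  co <- bundle$cohort
  co_out <- data.frame(lapply(co, function(col)
    if (is.double(col)) num(col) else col), stringsAsFactors = FALSE)
  data.table::fwrite(co_out, file.path(dir, "cohort.csv"), quote = FALSE)
  man <- data.frame(
    fish_id = vapply(bundle$runs, `[[`, "", "fish_id"),
    treatment = vapply(bundle$runs, `[[`, "", "treatment"),
    object_class = vapply(bundle$runs, `[[`, "", "object_class"),
    fs = vapply(bundle$runs, function(r) r$fs, 0),
    file = vapply(bundle$runs, function(r)
      file.path("runs", sprintf("%s_%s.csv", r$fish_id, r$treatment)), ""),
    stringsAsFactors = FALSE)
  data.table::fwrite(man, file.path(dir, "manifest.csv"), quote = FALSE)
  for (r in bundle$runs) {
    n <- length(r$Fz_N)
    dt <- data.table::data.table(
      t_s = num((seq_len(n) - 1) / r$fs),
      Mx_Nm = num(r$Mx_Nm), My_Nm = num(r$My_Nm), Fz_N = num(r$Fz_N))
    data.table::fwrite(dt, file.path(dir, sprintf("runs/%s_%s.csv",
                                                  r$fish_id, r$treatment)),
                       quote = FALSE)
  }
  jsonlite::write_json(list(cohort_config = unclass(bundle$cohort_config),
                            signal_config = unclass(bundle$signal_config)),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an experiment bundle written by [write_bundle()]
#'
#' @param dir directory containing `cohort.csv`, `manifest.csv` and `runs/`.
#' @return An `experiment_bundle`.
#' @export
read_bundle <- function(dir) {
  co <- as.data.frame(data.table::fread(file.path(dir, "cohort.csv")))
  man <- as.data.frame(data.table::fread(file.path(dir, "manifest.csv")))
  cls_int <- c("FinSpreadClass", "ArchClass")
  for (cl in intersect(cls_int, names(co))) co[[cl]] <- as.integer(co[[cl]])
  runs <- lapply(seq_len(nrow(man)), function(i) {
    dt <- data.table::fread(file.path(dir, man$file[i]))
    structure(list(fish_id = man$fish_id[i], treatment = man$treatment[i],
                   object_class = man$object_class[i], fs = man$fs[i],
                   Mx_Nm = dt$Mx_Nm, My_Nm = dt$My_Nm, Fz_N = dt$Fz_N),
              class = "force_series")
  })
  cfg <- NULL
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path)) cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  structure(list(cohort = co, runs = runs,
                 cohort_config = cfg$cohort_config,
                 signal_config = cfg$signal_config),
            class = "experiment_bundle")
}
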