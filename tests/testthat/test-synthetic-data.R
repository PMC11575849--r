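test_that("cohort generation honours counts, seeds and configured moments", {
  co <- generate_cohort(cohort_config(seed = 1))
  expect_equal(nrow(co), 112L)
  expect_equal(sum(co$Sex == "male"), 60L)
  expect_equal(sum(co$Sex == "female"), 37L)
  expect_equal(sum(co$Sex == "undefined"), 15L)
  expect_true(all(co$TL_cm > 0 & co$WW_g > 0 & co$HW_cm > 0 & co$BD_cm > 0))
  # determinism
  expect_identical(co, generate_cohort(cohort_config(seed = 1)))
  expect_false(identical(co, generate_cohort(cohort_config(seed = 2))))
  # Monte-Carlo: configured moments recovered (TL truncation is negligible
  # at 6+ s.d. from zero)
  big <- generate_cohort(cohort_config(n_fish = 10000L, n_male = 4000L,
                                       n_female = 4000L, n_juvenile = 2000L,
                                       seed = 7))
  expect_lt(abs(mean(big$TL_cm) - 9.71), 3 * 1.54 / sqrt(10000))
  expect_lt(abs(sd(big$TL_cm) - 1.54), 0.05)
})

test_that("cohort configuration is validated", {
  expect_error(cohort_config(n_fish = 10, n_male = 5, n_female = 4,
                             n_juvenile = 3), "equal n_fish")
  expect_error(cohort_config(TL_sd = 0), "positive")
  expect_error(signal_config(target_f3d = c(CS = -1, CR = 1, BR = 1, BS = 1)),
               "positive")
  expect_error(signal_config(share_sine = 0.9), "sum to 1")
  expect_error(signal_config(fs = 1000, duration = 0.0005), "integer sample")
})

test_that("noise-free generation is exact and unknown treatments error", {
  cfg <- short_signal_config(noise_scale = 0)
  s <- generate_force_series(data.frame(ID = "X"), "CS", "reference", cfg)
  rs <- suppressWarnings(mean_force_3d(s))
  expect_equal(rs$F_3D, attr(s, "planted_mean"))
  expect_warning(snr <- signal_to_noise(s), "infinite")
  expect_identical(snr, Inf)
  expect_error(generate_force_series(data.frame(ID = "X"), "XX", "reference",
                                     cfg), "unknown treatment")
})

test_that("planted BS peaks dominate the spectrum of a noise-free record", {
  cfg <- signal_config(duration = 10, seed = 3,
                       peaks = list(CS = 10, CR = 10, BR = 10,
                                    BS = c(66.40625, 85.9375)),
                       peak_weights = list(CS = 1, CR = 1, BR = 1,
                                           BS = c(1, 0.8)),
                       share_sine = 1, share_white = 0, share_pink = 0)
  set.seed(4)
  s <- generate_force_series(data.frame(ID = "X"), "BS", "reference", cfg)
  ps <- power_spectrum(force_magnitude(s), cfg$fs, 256L)
  pk <- sort(top_peaks(ps, 2L))
  expect_equal(as.numeric(pk), c(66.40625, 85.9375))
})

test_that("Monte-Carlo run means converge to the treatment target", {
  cfg <- short_signal_config(duration = 2, seed = NULL)
  set.seed(5)
  co <- derive_morphometrics(generate_cohort(tiny_cohort_config(seed = 6)))
  f3d <- replicate(200, {
    i <- sample(nrow(co), 1)
    s <- generate_force_series(co[i, , drop = FALSE], "CR", "preserved", cfg)
    mean_force_3d(s)$F_3D
  })
  rel_sd <- sqrt(cfg$sigma_fish^2 + cfg$sigma_run^2)
  expect_lt(abs(mean(f3d) - 0.077), 3 * 0.077 * rel_sd / sqrt(200))
})

test_that("reference run means converge to the printed stick-only targets", {
  cfg <- short_signal_config(duration = 2, seed = NULL)
  set.seed(8)
  targets <- c(BS = 0.034, CS = 0.035, BR = 0.038, CR = 0.041)
  for (tr in names(targets)) {
    m <- mean(replicate(120, attr(generate_force_series(
      data.frame(ID = "R"), tr, "reference", cfg), "planted_mean")))
    expect_lt(abs(m - targets[[tr]]),
              3 * targets[[tr]] * cfg$sigma_run_reference / sqrt(120))
  }
})

test_that("experiment bundles have the configured run structure and are
           deterministic", {
  cc <- tiny_cohort_config(seed = 1)
  sc <- short_signal_config(duration = 1, seed = 2)
  b <- generate_experiment(cc, sc)
  oc <- vapply(b$runs, `[[`, "", "object_class")
  expect_equal(sum(oc == "preserved"), 6L * 4L)
  expect_equal(sum(oc == "reference"), 16L)
  trt <- vapply(b$runs, `[[`, "", "treatment")
  expect_equal(as.integer(table(trt[oc == "preserved"])[TREATMENTS]),
               rep(6L, 4L))
  b2 <- generate_experiment(cc, sc)
  expect_identical(b$cohort, b2$cohort)
  expect_identical(b$runs, b2$runs)
})

test_that("full-series runs reproduce their planted run means", {
  # ties the series route to the run-table model: channel means recover the
  # planted mean almost exactly (fluctuations average out over the record)
  b <- generate_experiment(tiny_cohort_config(seed = 3),
                           short_signal_config(duration = 5, seed = 4))
  for (run in b$runs[1:10]) {
    f3d <- mean_force_3d(run)$F_3D
    expect_lt(abs(f3d - attr(run, "planted_mean")) / attr(run, "planted_mean"),
              0.02)
  }
})

test_that("simulate_run_table plants the same model at run level", {
  tab <- simulate_run_table(cohort_config(seed = 5), signal_config(seed = 6))
  expect_equal(nrow(tab), 112L * 4L)
  expect_true(all(tab$F3D_N > 0))
  expect_identical(tab, simulate_run_table(cohort_config(seed = 5),
                                           signal_config(seed = 6)))
  # treatment ordering of planted targets survives in the sample means
  m <- tapply(tab$F3D_N, tab$treatment, mean)
  expect_gt(m[["CR"]], m[["CS"]])
})

test_that("bundle serialization round-trips bit-identically", {
  b <- generate_experiment(
    cohort_config(n_fish = 4L, n_male = 2L, n_female = 1L, n_juvenile = 1L,
                  seed = 9),
    short_signal_config(duration = 1, seed = 10),
    n_reference_per_treatment = 1L)
  d1 <- file.path(tempdir(), "bundle_rt1")
  unlink(d1, recursive = TRUE)
  write_bundle(b, d1)
  b2 <- read_bundle(d1)
  for (i in seq_along(b$runs)) {
    expect_identical(b$runs[[i]]$Mx_Nm, b2$runs[[i]]$Mx_Nm)
    expect_identical(b$runs[[i]]$My_Nm, b2$runs[[i]]$My_Nm)
    expect_identical(b$runs[[i]]$Fz_N, b2$runs[[i]]$Fz_N)
  }
  expect_equal(b$cohort$TL_cm, b2$cohort$TL_cm)
  # writing the re-read bundle reproduces identical bytes
  d2 <- file.path(tempdir(), "bundle_rt2")
  unlink(d2, recursive = TRUE)
  b2$cohort_config <- b$cohort_config
  b2$signal_config <- b$signal_config
  class(b2$cohort_config) <- "cohort_config"
  class(b2$signal_config) <- "signal_config"
  write_bundle(b2, d2)
  for (f in c("cohort.csv", "manifest.csv",
              file.path("runs", "F001_CS.csv"))) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})
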