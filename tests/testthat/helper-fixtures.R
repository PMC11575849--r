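# Shared fixtures: everything is generated in code at test time.

# Small cohort: 6 fish keeps full-series bundles cheap.
tiny_cohort_config <- function(seed = 1L)
  cohort_config(n_fish = 6L, n_male = 3L, n_female = 2L, n_juvenile = 1L,
                seed = seed)

# Short-duration signal config for tests that only need run-level behaviour.
short_signal_config <- function(duration = 5, seed = 2L, ...)
  signal_config(duration = duration, seed = seed, ...)

# Strongly separable planted spectra: disjoint, well-spaced low-frequency
# peak pairs per treatment (all below 43 Hz so every smoothing kernel
# passes them), a dominant sinusoid share and a low SNR target so the
# class-specific oscillations carry most of the fluctuation power. Used for
# the classification-recovery construction.
separable_signal_config <- function(seed = 11L) {
  g <- 1000 / 256
  signal_config(seed = seed,
                peaks = list(CS = g * c(1, 2), CR = g * c(4, 5),
                             BR = g * c(7, 8), BS = g * c(10, 11)),
                peak_weights = list(CS = c(1, 0.8), CR = c(1, 0.8),
                                    BR = c(1, 0.8), BS = c(1, 0.8)),
                target_snr = c(CS = 6, CR = 6, BR = 6, BS = 6),
                share_sine = 0.9, share_white = 0.1, share_pink = 0)
}

# Reduced-scale CNN configuration used throughout the tests: same
# architecture family as the default (four residual blocks, increasing
# filters, pooling, GAP head) but sized for single-CPU training.
reduced_cnn_spec <- function(...)
  cnn_spec(filters = c(8L, 16L, 24L, 32L), kernel = 5L, dropout = 0.3,
           batch_size = 64L, lr = 2e-3, ...)

# One full-length (60 s) 6-fish bundle, generated once and reused by the
# preparation/classifier tests.
.fixture_cache <- new.env(parent = emptyenv())
tiny_bundle_cached <- function() {
  if (is.null(.fixture_cache$bundle))
    .fixture_cache$bundle <- generate_experiment(tiny_cohort_config(seed = 31),
                                                 signal_config(seed = 32))
  .fixture_cache$bundle
}

# Hand-made constant-channel force series (forces in N; torques = force * r).
const_series <- function(fx, fy, fz, n = 100L, r = 0.10,
                         treatment = "CS", object_class = "preserved")
  structure(list(fish_id = "T1", treatment = treatment,
                 object_class = object_class, fs = 1000,
                 Mx_Nm = rep(fx * r, n), My_Nm = rep(fy * r, n),
                 Fz_N = rep(fz, n)),
            class = "force_series")

random_series <- function(n = 1000L, seed = 1L, r = 0.10) {
  set.seed(seed)
  structure(list(fish_id = "T1", treatment = "CS",
                 object_class = "preserved", fs = 1000,
                 Mx_Nm = rnorm(n, 0.006, 0.002), My_Nm = rnorm(n, 0.002, 0.001),
                 Fz_N = rnorm(n, 0.02, 0.005)),
            class = "force_series")
}

# Independent rank-formula oracle for the Kruskal-Wallis H with ties.
kw_oracle_H <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  rk <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, g, sum)^2 / tapply(rk, g, length)) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Independent brute-force oracle for Dunn z statistics.
dunn_oracle_z <- function(ga, gb, groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  rk <- rank(x)
  ties <- table(x)
  sigma2 <- (N * (N + 1) / 12) - sum(ties^3 - ties) / (12 * (N - 1))
  (mean(rk[g == ga]) - mean(rk[g == gb])) /
    sqrt(sigma2 * (1 / sum(g == ga) + 1 / sum(g == gb)))
}
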