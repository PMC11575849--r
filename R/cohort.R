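#' Generate a synthetic fish cohort
#'
#' Draws one fish record per individual: sex labels in the configured counts
#' (juveniles are labelled `"undefined"`), and morphometrics from
#' positive-truncated normal distributions with the configured moments.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A `data.frame` with columns `ID, Sex, TL_cm, WW_g, HW_cm, BD_cm,
#'   LPFSA_deg, RPFSA_deg, Arch_deg`, one row per fish.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' table(cohort$Sex)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_fish
  with_seed(config$seed, {
    sex <- sample(rep(c("male", "female", "undefined"),
                      times = c(config$n_male, config$n_female, config$n_juvenile)))
    data.frame(
      ID = sprintf("F%03d", seq_len(n)),
      Sex = sex,
      TL_cm = rtruncnorm_pos(n, config$TL_mean, config$TL_sd),
      WW_g = rtruncnorm_pos(n, config$WW_mean, config$WW_sd),
      HW_cm = rtruncnorm_pos(n, config$HW_mean, config$HW_sd),
      BD_cm = rtruncnorm_pos(n, config$BD_mean, config$BD_sd),
      LPFSA_deg = rtruncnorm_pos(n, config$fin_angle_mean, config$fin_angle_sd),
      RPFSA_deg = rtruncnorm_pos(n, config$fin_angle_mean, config$fin_angle_sd),
      Arch_deg = rtruncnorm_pos(n, config$arch_mean, config$arch_sd),
      stringsAsFactors = FALSE)
  })
}
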