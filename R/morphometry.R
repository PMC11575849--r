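#' Fineness ratio of a fish body
#'
#' Length-to-effective-diameter ratio of an elliptical body of revolution:
#' total length divided by the geometric mean of maximum head width and
#' maximum body depth, `TL / sqrt(HW * BD)`. A sphere (all three equal) has
#' fineness ratio 1; the study population averages about 5.2. The ratio is
#' scale-invariant: multiplying all three lengths by a constant leaves it
#' unchanged.
#'
#' @param TL total length, cm.
#' @param HW maximum head width, cm.
#' @param BD maximum body depth, cm.
#' @return Dimensionless fineness ratio (vectorised).
#' @examples
#' fineness_ratio(3, 3, 3)           # sphere: 1
#' fineness_ratio(9.71, 1.93, 1.83)  # study population means: ~5.17
#' @export
fineness_ratio <- function(TL, HW, BD) {
  if (any(!is.finite(TL)) || any(!is.finite(HW)) || any(!is.finite(BD)) ||
      any(TL <= 0) || any(HW <= 0) || any(BD <= 0))
    stop_domain("TL, HW and BD must all be positive")
  TL / sqrt(HW * BD)
}

#' Fluid context for Reynolds-number computation
#'
#' @param U water velocity, m/s (study value 0.95).
#' @param L characteristic length of the body, m (e.g. 0.097 for the mean
#'   preserved fish, 0.03 for the rubber ball).
#' @param rho water density, kg/m^3 (study value 998.2).
#' @param mu dynamic viscosity, Pa s (study value 0.001308).
#' @return A list of class `fluid_context`.
#' @export
fluid_context <- function(U = 0.95, L, rho = 998.2, mu = 0.001308) {
  vals <- c(U = U, L = L, rho = rho, mu = mu)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_domain("all fluid-context parameters must be strictly positive")
  structure(list(U = U, L = L, rho = rho, mu = mu), class = "fluid_context")
}

#' Reynolds number
#'
#' `Re = rho * U * L / mu`, the dimensionless flow-regime indicator for each
#' tested body.
#'
#' @param ctx a [fluid_context()].
#' @return The Reynolds number (dimensionless).
#' @seealso [re_mantissa()] for the (coefficient, exponent) form.
#' @export
reynolds_number <- function(ctx) {
  stopifnot(inherits(ctx, "fluid_context"))
  ctx$rho * ctx$U * ctx$L / ctx$mu
}

#' Scientific-notation decomposition of a Reynolds number
#'
#' Reports `Re` as a coefficient in `[0.1, 1)` times a power of ten, the
#' convention in which the study bodies read 0.70 (preserved fish) and 0.22
#' (rubber ball) at exponent magnitude 5.
#'
#' @param Re positive Reynolds number.
#' @return list with `coefficient` (in `[0.1, 1)`) and `exponent` (integer).
#' @examples
#' re_mantissa(reynolds_number(fluid_context(L = 0.097)))
#' @export
re_mantissa <- function(Re) {
  if (!is.finite(Re) || Re <= 0) stop_domain("Re must be positive")
  ex <- ceiling(log10(Re))
  co <- Re / 10^ex
  if (co >= 1) { co <- co / 10; ex <- ex + 1L }  # guard exact powers of ten
  list(coefficient = co, exponent = as.integer(ex))
}

#' Ordinal categorisation of angle measurements
#'
#' Bins per-fish angles (fin-spread or body-arch) into `n_classes` ordinal
#' classes by sample quantiles, class 1 = smallest angles ("non-spread" /
#' "straight"). Ties at a boundary fall into the lower class, so identical
#' values always share a class and an all-equal input collapses to class 1.
#' The class boundaries are returned so alternative binnings can be compared.
#'
#' @param values numeric angles, degrees.
#' @param n_classes number of ordinal classes (default 4).
#' @return list with `class` (integer vector, 1..n_classes) and `breaks`
#'   (the `n_classes - 1` quantile boundaries).
#' @export
categorize_angles <- function(values, n_classes = 4L) {
  if (length(values) < n_classes)
    stop_domain("need at least as many values as classes")
  if (any(!is.finite(values))) stop_domain("values must be finite")
  probs <- seq_len(n_classes - 1L) / n_classes
  breaks <- stats::quantile(values, probs, names = FALSE)
  cls <- 1L + rowSums(outer(values, breaks, ">"))
  list(class = as.integer(cls), breaks = breaks)
}

#' Male-to-female sex ratio
#'
#' @param n_male,n_female counts; juveniles with undetermined sex are
#'   excluded before calling this.
#' @return `n_male / n_female`.
#' @examples
#' sex_ratio(60, 37)  # 1.62 to two decimals
#' @export
sex_ratio <- function(n_male, n_female) {
  if (n_female <= 0) stop_domain("sex ratio undefined: no females")
  if (n_male < 0) stop_domain("n_male must be non-negative")
  n_male / n_female
}

#' Derive shape indices and classes for a cohort
#'
#' Adds to a cohort table: the mean pectoral fin-spread angle
#' `MPFSA = (LPFSA + RPFSA) / 2`, quartile-based ordinal fin-spread and
#' body-arch classes (1 to 4), and the fineness ratio.
#'
#' @param cohort a cohort `data.frame` as from [generate_cohort()].
#' @return The cohort with columns `MPFSA_deg, FinSpreadClass, ArchClass, FR`
#'   appended. The class boundaries are attached as attributes
#'   `fin_breaks` and `arch_breaks`.
#' @export
derive_morphometrics <- function(cohort) {
  need <- c("TL_cm", "HW_cm", "BD_cm", "LPFSA_deg", "RPFSA_deg", "Arch_deg")
  if (!all(need %in% names(cohort)))
    stop_domain("cohort is missing columns: ",
                paste(setdiff(need, names(cohort)), collapse = ", "))
  cohort$MPFSA_deg <- (cohort$LPFSA_deg + cohort$RPFSA_deg) / 2
  fin <- categorize_angles(cohort$MPFSA_deg)
  arch <- categorize_angles(cohort$Arch_deg)
  cohort$FinSpreadClass <- fin$class
  cohort$ArchClass <- arch$class
  cohort$FR <- fineness_ratio(cohort$TL_cm, cohort$HW_cm, cohort$BD_cm)
  attr(cohort, "fin_breaks") <- fin$breaks
  attr(cohort, "arch_breaks") <- arch$breaks
  cohort
}
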