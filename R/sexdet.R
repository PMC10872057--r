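# The switchlike ESD reaction norm. Sex is male at cool and female at warm
# developmental temperatures (type 1a). With expressed phenotypes tpiv,
# slope (<= 0 for ESD) and shift, the probability of developing male at
# nest temperature td in a year with mean climate t_ann is
#
#   r = 1 / (1 + exp(-(td - (tpiv + shift * (t_ann - t_base))) * slope))
#
# The slope multiplies the exponent, so steepness grows with |slope| and
# slope = 0 is a flat norm (sex independent of temperature); this is the
# convention recorded in run metadata.

#' Effective (plastically shifted) pivotal temperature
#'
#' The shift locus moves the expressed pivotal temperature in proportion to
#' the deviation of the annual climate from the baseline climate:
#' `tpiv + shift * (t_ann - t_base)`.
#'
#' @param tpiv Genetic pivotal temperature (expressed phenotype, degC).
#' @param shift Shift-plasticity phenotype (degC per degC of deviation).
#' @param t_ann Annual mean temperature (degC).
#' @param t_base Baseline climate (degC, default 28).
#' @return Effective pivotal temperature (degC); vectorised.
#' @export
effective_pivotal_temperature <- function(tpiv, shift, t_ann, t_base = 28) {
  tpiv + shift * (t_ann - t_base)
}

#' Probability of developing male
#'
#' Evaluates the logistic reaction norm at developmental temperature `td`.
#' With `slope < 0` the probability decreases from 1 at cold temperatures
#' to 0 at warm ones, crossing 0.5 exactly at the effective pivotal
#' temperature; `slope = 0` gives 0.5 everywhere. Saturates smoothly to 0
#' or 1 for extreme arguments.
#'
#' @param td Developmental (nest) temperature (degC).
#' @param tpiv,slope,shift Expressed phenotypes at the three loci.
#' @param t_ann Annual mean temperature (degC, default `t_base`).
#' @param t_base Baseline climate (degC, default 28).
#' @return Probability in \[0, 1\]; vectorised over all arguments.
#' @examples
#' male_probability(30, tpiv = 28, slope = -5)   # ~4.54e-05
#' male_probability(30, tpiv = 28, slope = -0.5) # ~0.269
#' @export
male_probability <- function(td, tpiv, slope, shift = 0, t_ann = t_base,
                             t_base = 28) {
  tpiv_eff <- effective_pivotal_temperature(tpiv, shift, t_ann, t_base)
  stats::plogis((td - tpiv_eff) * slope)
}

#' Stochastic sex assignment
#'
#' An individual with male probability `r` is male iff an independent
#' Uniform(0, 1) draw falls below `r`.
#'
#' @param r Male probabilities in \[0, 1\].
#' @return Logical vector: `TRUE` for male, `FALSE` for female.
#' @export
assign_sex <- function(r) {
  if (any(!is.finite(r) | r < 0 | r > 1))
    stop("male probabilities must lie in [0, 1]", call. = FALSE)
  stats::runif(length(r)) < r
}

#' Expected cohort male fraction (analytic oracle)
#'
#' Integrates [male_probability()] against the Normal(`t_ann`, `sd_wi`)
#' nest-temperature density. For a cohort of one genotype this is the exact
#' expected male fraction, so it serves as an independent check on
#' simulated cohort sex ratios.
#'
#' @param tpiv,slope,shift Expressed phenotypes (scalars).
#' @param t_ann Annual mean temperature (degC).
#' @param climate A [climate_params()] object (supplies `sd_wi`, `t_base`).
#' @param rel_tol Relative accuracy requested from the quadrature.
#' @return Expected male fraction in \[0, 1\].
#' @export
expected_cohort_male_fraction <- function(tpiv, slope, shift = 0, t_ann,
                                          climate = climate_params(),
                                          rel_tol = 1e-9) {
  stopifnot(inherits(climate, "climate_params"))
  if (climate$sd_wi == 0) {
    return(male_probability(t_ann, tpiv, slope, shift, t_ann,
                            climate$t_base))
  }
  f <- function(td) {
    male_probability(td, tpiv, slope, shift, t_ann, climate$t_base) *
      stats::dnorm(td, t_ann, climate$sd_wi)
  }
  lim <- 10 * climate$sd_wi
  stats::integrate(f, t_ann - lim, t_ann + lim, rel.tol = rel_tol,
                   abs.tol = 0)$value
}

#' Classify a reaction norm as ESD or GSD
#'
#' A mean reaction-norm slope more positive than the threshold (-0.1 by
#' default, i.e. nearly flat) is classified as a switch to genotypic sex
#' determination; the boundary itself still counts as ESD.
#'
#' @param mean_slope Mean expressed slope (e.g. over the final window of a
#'   replicate); vectorised.
#' @param threshold Classification boundary (default -0.1).
#' @return Character vector of `"ESD"` or `"GSD"`.
#' @export
classify_sd_system <- function(mean_slope, threshold = -0.1) {
  stopifnot(all(is.finite(mean_slope)))
  ifelse(mean_slope > threshold, "GSD", "ESD")
}
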