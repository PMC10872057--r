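# Fertility with male limitation, fixed adult mortality, and
# density-dependent first-year (juvenile) mortality.

#' Demographic parameters
#'
#' @param f_scale Fecundity scaler (default 0.02).
#' @param phi Exponent linking maternal developmental temperature to clutch
#'   size (default 2); with the defaults, clutch size spans roughly 10-25
#'   over 22-35 degC, creating the warm-female fecundity advantage that
#'   maintains ESD.
#' @param m_lim Male-limitation constant (default 0.01): fertility is
#'   multiplied by `osr / (osr + m_lim)`, which only bites when fewer than
#'   about 10% of adults are male.
#' @param ad_mort Annual adult mortality probability (default 0.1),
#'   applied after breeding.
#' @param dd_const Density constant of first-year survival (default 0.01):
#'   juvenile mortality is `1 - exp(-dd_const * n_adults)`.
#' @return A validated list of class `demography_params`.
#' @export
demography_params <- function(f_scale = 0.02, phi = 2, m_lim = 0.01,
                              ad_mort = 0.1, dd_const = 0.01) {
  stopifnot(f_scale >= 0, phi >= 0, m_lim >= 0, dd_const >= 0,
            ad_mort >= 0, ad_mort <= 1)
  structure(list(f_scale = f_scale, phi = phi, m_lim = m_lim,
                 ad_mort = ad_mort, dd_const = dd_const),
            class = "demography_params")
}

#' Operational sex ratio
#'
#' Proportion of adult males among all adults.
#'
#' @param n_males,n_females Non-negative adult counts; at least one adult.
#' @return Proportion in \[0, 1\].
#' @export
operational_sex_ratio <- function(n_males, n_females) {
  stopifnot(n_males >= 0, n_females >= 0)
  if (any(n_males + n_females == 0))
    stop("operational sex ratio is undefined for an empty population",
         call. = FALSE)
  n_males / (n_males + n_females)
}

#' Clutch size
#'
#' Clutch size grows exponentially with the mother's own developmental
#' temperature and is discounted by male limitation:
#' `CS = f_scale * td^phi * osr / (osr + m_lim)`, rounded to an integer
#' offspring count. `rounding = "nearest"` rounds to the nearest integer;
#' `"stochastic"` rounds up with probability equal to the fractional part,
#' which is unbiased clutch by clutch.
#'
#' @param td_mother Maternal developmental temperature(s) (degC, > 0).
#' @param osr Operational sex ratio at breeding time.
#' @param params A [demography_params()] object.
#' @param rounding `"nearest"` (default) or `"stochastic"`.
#' @return Non-negative integer vector of offspring counts.
#' @export
clutch_size <- function(td_mother, osr, params = demography_params(),
                        rounding = c("nearest", "stochastic")) {
  stopifnot(inherits(params, "demography_params"),
            all(td_mother > 0), osr >= 0, osr <= 1)
  rounding <- match.arg(rounding)
  cs <- params$f_scale * td_mother^params$phi * osr / (osr + params$m_lim)
  if (rounding == "nearest") {
    as.integer(round(cs))
  } else {
    fl <- floor(cs)
    as.integer(fl + (stats::runif(length(cs)) < cs - fl))
  }
}

#' Density-dependent juvenile mortality probability
#'
#' First-year mortality increases with the number of adults already in the
#' population: `1 - exp(-dd_const * n_adults)`, in \[0, 1).
#'
#' @param n_adults Adult count(s) at recruitment time.
#' @param params A [demography_params()] object.
#' @return Mortality probability, vectorised over `n_adults`.
#' @export
juvenile_mortality_probability <- function(n_adults,
                                           params = demography_params()) {
  stopifnot(inherits(params, "demography_params"), all(n_adults >= 0))
  1 - exp(-params$dd_const * n_adults)
}

#' Apply adult mortality
#'
#' Removes each adult independently with probability `rate` (a Bernoulli
#' draw per individual, so realised mortality fluctuates around the rate).
#'
#' @param adults A matrix or data frame with one row per adult.
#' @param rate Mortality probability in \[0, 1\].
#' @return The surviving rows.
#' @export
apply_adult_mortality <- function(adults, rate) {
  stopifnot(rate >= 0, rate <= 1)
  n <- nrow(adults)
  if (n == 0L || rate == 0) return(adults)
  adults[stats::runif(n) >= rate, , drop = FALSE]
}
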