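# Two-level Gaussian climate: annual means around a global mean, nest
# (developmental) temperatures around each annual mean. Temperatures are
# never truncated; the logistic reaction norm tolerates extremes.

#' Climate parameters
#'
#' @param t_glob Global mean temperature of the scenario (degC); the study
#'   design uses 28 (base), 30 (moderate warming) and 32 (extreme warming).
#' @param sd_bw Between-year SD of annual mean temperatures (degC); 0.75
#'   (low variability) or 1.5 (high variability) in the study design.
#' @param sd_wi Within-year SD of nest temperatures around the annual mean
#'   (degC, default 1.2, reflecting among-nest variation in wild reptile
#'   nests).
#' @param t_base Baseline climate the founders are adapted to (degC,
#'   fixed at 28 across scenarios).
#' @return A validated list of class `climate_params`.
#' @export
climate_params <- function(t_glob = 28, sd_bw = 0.75, sd_wi = 1.2,
                           t_base = 28) {
  stopifnot(is.finite(t_glob), sd_bw >= 0, sd_wi >= 0, is.finite(t_base))
  structure(list(t_glob = t_glob, sd_bw = sd_bw, sd_wi = sd_wi,
                 t_base = t_base),
            class = "climate_params")
}

#' Draw annual mean temperatures
#'
#' Each simulated year's mean temperature is Normal(`t_glob`, `sd_bw`).
#'
#' @param climate A [climate_params()] object.
#' @param n Number of years to draw.
#' @return Numeric vector of annual mean temperatures (degC).
#' @export
draw_annual_temperature <- function(climate, n = 1L) {
  stopifnot(inherits(climate, "climate_params"))
  stats::rnorm(n, climate$t_glob, climate$sd_bw)
}

#' Draw nest temperatures
#'
#' One nest temperature is drawn per clutch, Normal(`t_ann`, `sd_wi`);
#' it becomes the developmental temperature of every offspring in the nest
#' (siblings share it).
#'
#' @param t_ann Annual mean temperature of the year (degC); recycled
#'   against `n`.
#' @param climate A [climate_params()] object.
#' @param n Number of nests.
#' @return Numeric vector of nest temperatures (degC).
#' @export
draw_nest_temperature <- function(t_ann, climate, n = length(t_ann)) {
  stopifnot(inherits(climate, "climate_params"))
  stats::rnorm(n, t_ann, climate$sd_wi)
}
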