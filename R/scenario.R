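# Scenario configuration: which plasticity trait can evolve, at what
# starting level, under which climate. Every simulation parameter is an
# explicit, overridable knob so sensitivity analyses (mutation range,
# adult mortality, ...) need no code changes.

.SLOPE_LEVELS <- c(low = -0.5, medium = -1.5, high = -5)
.SHIFT_LEVELS <- c(low = 0, medium = 0.38, high = 0.6666)

#' Build a simulation scenario
#'
#' A scenario fixes the plasticity design and all model parameters. In
#' `"slope"` scenarios the pivotal temperature and the reaction-norm slope
#' can evolve while shift is held at its low level (0, no mutation); in
#' `"shift"` scenarios the pivotal temperature and shift can evolve while
#' the slope is held at its high level (-5, no mutation). The fixed trait
#' sits at the level that least balances sex ratios, maximising the
#' potential for sex-ratio bias under warming.
#'
#' @param plasticity `"slope"` or `"shift"`: which plasticity trait varies
#'   across levels and can evolve (together with the pivotal temperature).
#' @param level Starting plasticity level: `"low"`, `"medium"` or `"high"`.
#' @param t_glob Global mean temperature (degC): 28, 30 or 32 in the study
#'   design, any value allowed.
#' @param sd_bw Between-year climate SD (degC): 0.75 or 1.5 in the design.
#' @param sd_wi Within-year SD of nest temperatures (degC, default 1.2).
#' @param t_base Baseline climate founders are adapted to (degC, 28).
#' @param ni Founding population size (default 500).
#' @param t_max Maximum number of simulated years (default 50000).
#' @param f_scale,phi,m_lim,ad_mort,dd_const Demography; see
#'   [demography_params()].
#' @param mutation_rate Probability an offspring is a mutant (default 0.02).
#' @param mutvar_tpiv,mutvar_shift,mutvar_slope Mutation SDs per locus
#'   (defaults 0.08, 0.1, 0.02).
#' @param mean_tpiv,sd_tpiv Founder pivotal-temperature allele mean and SD
#'   (defaults 28, 0.5; the SD places extreme genotypes near the moderate
#'   warming climate).
#' @param sd_slope,sd_shift Founder allele SDs for slope and shift
#'   (defaults 0.05, 0.01); means come from the plasticity design.
#' @param slope_levels,shift_levels Named vectors mapping levels to
#'   starting values (defaults `c(low = -0.5, medium = -1.5, high = -5)`
#'   and `c(low = 0, medium = 0.38, high = 0.6666)`).
#' @param evolvable Loci free to mutate; `NULL` (default) applies the
#'   scenario rule (`tpiv` plus the focal plasticity trait). Override for
#'   single-trait validation runs, e.g. `"tpiv"`.
#' @param cs_rounding Clutch-size rounding, `"nearest"` or `"stochastic"`.
#' @param id Scenario identifier; auto-generated when `NULL`.
#' @return A list of class `esd_scenario` with components `id`,
#'   `plasticity`, `level`, `climate`, `demography`, `mutation`, `founder`,
#'   `ni`, `t_max`, `cs_rounding`.
#' @examples
#' sc <- esd_scenario("slope", "high", t_glob = 30, sd_bw = 0.75)
#' sc$founder$mean  # tpiv 28, slope -5, shift 0
#' @export
esd_scenario <- function(plasticity = c("slope", "shift"),
                         level = c("low", "medium", "high"),
                         t_glob = 28, sd_bw = 0.75, sd_wi = 1.2,
                         t_base = 28, ni = 500L, t_max = 50000L,
                         f_scale = 0.02, phi = 2, m_lim = 0.01,
                         ad_mort = 0.1, dd_const = 0.01,
                         mutation_rate = 0.02, mutvar_tpiv = 0.08,
                         mutvar_shift = 0.1, mutvar_slope = 0.02,
                         mean_tpiv = 28, sd_tpiv = 0.5,
                         sd_slope = 0.05, sd_shift = 0.01,
                         slope_levels = .SLOPE_LEVELS,
                         shift_levels = .SHIFT_LEVELS,
                         evolvable = NULL,
                         cs_rounding = c("nearest", "stochastic"),
                         id = NULL) {
  plasticity <- match.arg(plasticity)
  level <- match.arg(level)
  cs_rounding <- match.arg(cs_rounding)
  stopifnot(ni > 0, t_max > 0)
  if (!all(c("low", "medium", "high") %in% names(slope_levels)) ||
      !all(c("low", "medium", "high") %in% names(shift_levels)))
    stop("'slope_levels' and 'shift_levels' need low/medium/high entries",
         call. = FALSE)
  if (plasticity == "slope") {
    mean_slope <- slope_levels[[level]]
    mean_shift <- shift_levels[["low"]]
    default_evolve <- c("tpiv", "slope")
  } else {
    mean_slope <- slope_levels[["high"]]
    mean_shift <- shift_levels[[level]]
    default_evolve <- c("tpiv", "shift")
  }
  if (is.null(evolvable)) evolvable <- default_evolve
  if (is.null(id)) {
    id <- sprintf("%s-%s-t%g-sd%g", plasticity, level, t_glob, sd_bw)
  }
  structure(list(
    id = id,
    plasticity = plasticity,
    level = level,
    climate = climate_params(t_glob = t_glob, sd_bw = sd_bw,
                             sd_wi = sd_wi, t_base = t_base),
    demography = demography_params(f_scale = f_scale, phi = phi,
                                   m_lim = m_lim, ad_mort = ad_mort,
                                   dd_const = dd_const),
    mutation = mutation_params(rate = mutation_rate, sd_tpiv = mutvar_tpiv,
                               sd_shift = mutvar_shift,
                               sd_slope = mutvar_slope,
                               evolvable = evolvable),
    founder = founder_params(mean_tpiv = mean_tpiv, sd_tpiv = sd_tpiv,
                             mean_slope = mean_slope, sd_slope = sd_slope,
                             mean_shift = mean_shift, sd_shift = sd_shift),
    ni = as.integer(ni),
    t_max = as.integer(t_max),
    cs_rounding = cs_rounding
  ), class = "esd_scenario")
}

#' @export
print.esd_scenario <- function(x, ...) {
  cat("<esd_scenario> ", x$id, "\n", sep = "")
  cat("  plasticity: ", x$plasticity, " (", x$level, "); evolvable: ",
      paste(x$mutation$evolvable, collapse = ", "), "\n", sep = "")
  cat(sprintf("  climate: t_glob %g, sd_bw %g, sd_wi %g, t_base %g\n",
              x$climate$t_glob, x$climate$sd_bw, x$climate$sd_wi,
              x$climate$t_base))
  cat(sprintf("  founders: tpiv %g, slope %g, shift %g (n = %d)\n",
              x$founder$mean[["tpiv"]], x$founder$mean[["slope"]],
              x$founder$mean[["shift"]], x$ni))
  cat(sprintf("  max years: %d\n", x$t_max))
  invisible(x)
}

#' Build the factorial scenario grid
#'
#' Crosses plasticity type, plasticity level, global climate and climate
#' variability; the full study design is 2 x 3 x 3 x 2 = 36 scenarios.
#' Pass subsets of the factor values to filter, and any other
#' [esd_scenario()] parameter through `...` to override it in every cell.
#'
#' @param plasticity,level,t_glob,sd_bw Factor values to cross.
#' @param ... Further parameters forwarded to [esd_scenario()].
#' @return A list of `esd_scenario` objects.
#' @examples
#' length(scenario_grid())  # 36
#' scenario_grid(plasticity = "slope", t_glob = 30, sd_bw = 0.75)  # 3
#' @export
scenario_grid <- function(plasticity = c("slope", "shift"),
                          level = c("low", "medium", "high"),
                          t_glob = c(28, 30, 32),
                          sd_bw = c(0.75, 1.5), ...) {
  plasticity <- match.arg(plasticity, several.ok = TRUE)
  level <- match.arg(level, several.ok = TRUE)
  if (anyDuplicated(t_glob) || anyDuplicated(sd_bw) ||
      anyDuplicated(plasticity) || anyDuplicated(level))
    stop("grid factor values must be distinct", call. = FALSE)
  if (...length() > 0L) {
    extras <- names(list(...))
    clash <- intersect(extras, c("plasticity", "level", "t_glob", "sd_bw",
                                 "id"))
    if (length(clash) || is.null(extras) || any(extras == ""))
      stop("contradictory or unnamed overrides: ",
           paste(clash, collapse = ", "), call. = FALSE)
  }
  cells <- expand.grid(sd_bw = sd_bw, t_glob = t_glob, level = level,
                       plasticity = plasticity,
                       stringsAsFactors = FALSE)
  lapply(seq_len(nrow(cells)), function(i) {
    esd_scenario(plasticity = cells$plasticity[i], level = cells$level[i],
                 t_glob = cells$t_glob[i], sd_bw = cells$sd_bw[i], ...)
  })
}
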