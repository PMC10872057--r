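# Population state and the annual cycle. Adults live in a numeric matrix
# (one row per individual): six allele columns, developmental temperature
# (fixed at birth) and sex (1 male, 0 female). Everything in the yearly
# step is vectorised over the cohort.

.IND_COLS <- c("tpiv1", "tpiv2", "slope1", "slope2", "shift1", "shift2",
               "td", "sex")
.TD <- 7L
.SEX <- 8L

.RECORD_COLS <- c("year", "t_ann", "n_adults", "adult_male_fraction",
                  "cohort_male_fraction", "mean_tpiv", "mean_slope",
                  "mean_shift")

.year_record <- function(year, t_ann, adults, cohort_male_fraction) {
  n <- nrow(adults)
  ph <- if (n > 0L) colMeans(.express_all(adults[, 1:6, drop = FALSE]))
        else c(tpiv = NA_real_, slope = NA_real_, shift = NA_real_)
  c(year = year, t_ann = t_ann, n_adults = n,
    adult_male_fraction = if (n > 0L) mean(adults[, .SEX]) else NA_real_,
    cohort_male_fraction = cohort_male_fraction,
    mean_tpiv = ph[["tpiv"]], mean_slope = ph[["slope"]],
    mean_shift = ph[["shift"]])
}

#' Seed a founding population
#'
#' Founders get genotypes from [founder_genotypes()], developmental
#' temperatures Normal(`t_base`, `sd_wi`) regardless of the climate
#' scenario (an established population that subsequently experiences
#' warming), and sexes from the reaction norm evaluated at
#' `t_ann = t_base`, so the shift term is zero at seeding.
#'
#' @param scenario An [esd_scenario()] object.
#' @return An `esd_population`: list with the adult matrix and `year = 0`.
#' @export
seed_population <- function(scenario) {
  stopifnot(inherits(scenario, "esd_scenario"))
  cl <- scenario$climate
  g <- founder_genotypes(scenario$ni, scenario$founder)
  td <- stats::rnorm(scenario$ni, cl$t_base, cl$sd_wi)
  ph <- .express_all(g)
  r <- male_probability(td, ph[, "tpiv"], ph[, "slope"], ph[, "shift"],
                        t_ann = cl$t_base, t_base = cl$t_base)
  adults <- cbind(g, td = td, sex = as.numeric(assign_sex(r)))
  colnames(adults) <- .IND_COLS
  structure(list(adults = adults, year = 0L), class = "esd_population")
}

#' @export
print.esd_population <- function(x, ...) {
  n <- nrow(x$adults)
  cat("<esd_population> year ", x$year, ": ", n, " adults", sep = "")
  if (n > 0L) {
    cat(sprintf(" (%.1f%% male); mean tpiv %.2f, slope %.2f, shift %.3f",
                100 * mean(x$adults[, .SEX]),
                mean(express_phenotype(x$adults, "tpiv")),
                mean(express_phenotype(x$adults, "slope")),
                mean(express_phenotype(x$adults, "shift"))))
  }
  cat("\n")
  invisible(x)
}

# One breeding season: returns the offspring matrix (possibly 0 rows).
# OSR is evaluated at breeding time, before that year's adult mortality.
.breed <- function(adults, t_ann, scenario) {
  sex <- adults[, .SEX]
  females <- which(sex == 0)
  males <- which(sex == 1)
  empty <- matrix(numeric(0), 0L, 8L, dimnames = list(NULL, .IND_COLS))
  if (!length(females) || !length(males)) return(empty)
  osr <- operational_sex_ratio(length(males), length(females))
  cl <- scenario$climate
  # one mate and one nest per breeding female
  mates <- males[sample.int(length(males), length(females), replace = TRUE)]
  nest_td <- draw_nest_temperature(rep(t_ann, length(females)), cl)
  cs <- clutch_size(adults[females, .TD], osr, scenario$demography,
                    rounding = scenario$cs_rounding)
  keep <- cs > 0L
  if (!any(keep)) return(empty)
  mom <- rep(females[keep], cs[keep])
  dad <- rep(mates[keep], cs[keep])
  td <- rep(nest_td[keep], cs[keep])
  g <- inherit_genotypes(adults[mom, 1:6, drop = FALSE],
                         adults[dad, 1:6, drop = FALSE])
  g <- mutate_genotypes(g, scenario$mutation)
  ph <- .express_all(g)
  r <- male_probability(td, ph[, "tpiv"], ph[, "slope"], ph[, "shift"],
                        t_ann = t_ann, t_base = cl$t_base)
  off <- cbind(g, td = td, sex = as.numeric(assign_sex(r)))
  colnames(off) <- .IND_COLS
  off
}

# Advance the adult matrix by one year; returns list(adults, record).
.step <- function(adults, year, scenario) {
  t_ann <- draw_annual_temperature(scenario$climate)
  offspring <- .breed(adults, t_ann, scenario)
  cohort_mf <- if (nrow(offspring) > 0L) mean(offspring[, .SEX])
               else NA_real_
  survivors <- apply_adult_mortality(adults, scenario$demography$ad_mort)
  if (nrow(offspring) > 0L) {
    mort <- juvenile_mortality_probability(nrow(survivors),
                                           scenario$demography)
    recruits <- offspring[stats::runif(nrow(offspring)) >= mort, ,
                          drop = FALSE]
    survivors <- rbind(survivors, recruits)
  }
  list(adults = survivors,
       record = .year_record(year, t_ann, survivors, cohort_mf))
}

#' Advance a population by one year
#'
#' Runs one full annual cycle: draw the annual temperature; breed (each
#' adult female takes a male mate uniformly at random with replacement,
#' lays one clutch at a fresh nest temperature; offspring genotypes pass
#' through inheritance and mutation and get sexes from the reaction norm);
#' apply adult mortality; apply density-dependent juvenile mortality using
#' the post-mortality adult count; recruit the surviving juveniles.
#'
#' @param population An `esd_population` with at least one adult.
#' @param scenario An [esd_scenario()] object.
#' @return List with the advanced `population` and a one-row data frame
#'   `record` of that year's observables (post-recruitment adult state
#'   plus the at-birth cohort male fraction, `NA` in years with no
#'   births).
#' @export
step_year <- function(population, scenario) {
  stopifnot(inherits(population, "esd_population"),
            inherits(scenario, "esd_scenario"))
  if (nrow(population$adults) == 0L)
    stop("cannot step an extinct population", call. = FALSE)
  year <- population$year + 1L
  st <- .step(population$adults, year, scenario)
  list(population = structure(list(adults = st$adults, year = year),
                              class = "esd_population"),
       record = as.data.frame(as.list(st$record)))
}

#' Run one replicate simulation
#'
#' Seeds a population and iterates the annual cycle for up to
#' `scenario$t_max` years, stopping early when the adult population goes
#' extinct — empty or single-sex (under warming this is in practice 100%
#' female). The full per-year time series is retained; the founding state
#' is recorded as year 0. The stream of records is a pure function of
#' `(scenario, seed)`.
#'
#' @param scenario An [esd_scenario()] object.
#' @param seed Integer seed for the replicate's random number generator.
#' @return An `esd_replicate`: list with `scenario_id`, `seed`, `years`
#'   (data frame, one row per recorded year), `outcome` (`"extinct"`,
#'   `"GSD"` or `"ESD"`), `extinction_year` (`NA` for survivors) and
#'   `final` (named means of the trait columns over the last up-to-1000
#'   recorded years, `NA` for extinct replicates).
#' @export
run_replicate <- function(scenario, seed) {
  stopifnot(inherits(scenario, "esd_scenario"))
  set.seed(as.integer(seed))
  pop <- seed_population(scenario)
  records <- matrix(NA_real_, scenario$t_max + 1L, length(.RECORD_COLS),
                    dimnames = list(NULL, .RECORD_COLS))
  records[1L, ] <- .year_record(0, scenario$climate$t_base, pop$adults,
                                NA_real_)
  adults <- pop$adults
  extinction_year <- NA_integer_
  for (year in seq_len(scenario$t_max)) {
    st <- .step(adults, year, scenario)
    adults <- st$adults
    records[year + 1L, ] <- st$record
    n <- nrow(adults)
    if (n == 0L || sum(adults[, .SEX]) %in% c(0, n)) {
      extinction_year <- year
      break
    }
  }
  years <- as.data.frame(records[!is.na(records[, "year"]), ,
                                 drop = FALSE])
  res <- structure(list(scenario_id = scenario$id, seed = as.integer(seed),
                        years = years,
                        outcome = NA_character_,
                        extinction_year = extinction_year,
                        final = NULL),
                   class = "esd_replicate")
  res$final <- if (is.na(extinction_year)) summarize_final_window(years)
               else c(mean_tpiv = NA_real_, mean_slope = NA_real_,
                      mean_shift = NA_real_)
  res$outcome <- classify_outcome(res)
  res
}

#' @export
print.esd_replicate <- function(x, ...) {
  cat("<esd_replicate> ", x$scenario_id, " (seed ", x$seed, ")\n",
      sep = "")
  cat("  outcome: ", x$outcome, sep = "")
  if (!is.na(x$extinction_year))
    cat(" (year ", x$extinction_year, ")", sep = "")
  cat("; years recorded: ", nrow(x$years), "\n", sep = "")
  if (is.na(x$extinction_year))
    cat(sprintf(
      "  final window: tpiv %.2f, slope %.2f, shift %.3f\n",
      x$final[["mean_tpiv"]], x$final[["mean_slope"]],
      x$final[["mean_shift"]]))
  invisible(x)
}
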