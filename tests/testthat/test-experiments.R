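test_that("the factorial grid crosses 2 types x 3 levels x 3 climates x 2 SDs", {
  grid <- scenario_grid()
  expect_length(grid, 36)
  expect_length(unique(vapply(grid, `[[`, character(1), "id")), 36)
  # slope scenarios: shift held at its low level and not evolvable
  for (sc in grid) {
    if (sc$plasticity == "slope") {
      expect_equal(sc$founder$mean[["shift"]], 0)
      expect_setequal(sc$mutation$evolvable, c("tpiv", "slope"))
    } else {
      expect_equal(sc$founder$mean[["slope"]], -5)
      expect_setequal(sc$mutation$evolvable, c("tpiv", "shift"))
    }
  }
  sub <- scenario_grid(plasticity = "slope", t_glob = 30, sd_bw = 0.75)
  expect_length(sub, 3)
  expect_error(scenario_grid(t_glob = c(30, 30)), "distinct")
  expect_error(scenario_grid(plasticity = "slope", level = "low",
                             t_glob = 30, sd_bw = 0.75, 99), "overrides")
})

test_that("scenario levels map onto the design's starting values", {
  expect_equal(esd_scenario("slope", "low")$founder$mean[["slope"]], -0.5)
  expect_equal(esd_scenario("slope", "medium")$founder$mean[["slope"]],
               -1.5)
  expect_equal(esd_scenario("shift", "medium")$founder$mean[["shift"]],
               0.38)
  expect_equal(esd_scenario("shift", "high")$founder$mean[["shift"]],
               0.6666)
  # every simulation parameter is an overridable knob
  sc <- esd_scenario("slope", "high", mutation_rate = 0.05, ad_mort = 0.2,
                     mutvar_tpiv = 0.16, evolvable = "tpiv")
  expect_equal(sc$mutation$rate, 0.05)
  expect_equal(sc$demography$ad_mort, 0.2)
  expect_equal(sc$mutation$sd[["tpiv"]], 0.16)
  expect_equal(sc$mutation$evolvable, "tpiv")
})

test_that("batches are reproducible with distinct per-replicate seeds", {
  grid <- scenario_grid(plasticity = "slope", level = c("low", "high"),
                        t_glob = 28, sd_bw = 0.75, t_max = 25L)
  b1 <- run_batch(grid, n_replicates = 2, base_seed = 50)
  b2 <- run_batch(grid, n_replicates = 2, base_seed = 50)
  expect_length(b1, 4)
  seeds <- vapply(b1, `[[`, integer(1), "seed")
  expect_equal(seeds, 50:53)
  expect_identical(replicate_summary(b1), replicate_summary(b2))
  expect_identical(batch_timeseries(b1), batch_timeseries(b2))
})

test_that("outcome classification distinguishes extinct, GSD and ESD", {
  fake <- function(ext_year, slope) {
    yrs <- data.frame(year = 0:10, t_ann = 28, n_adults = 100,
                      adult_male_fraction = 0.5,
                      cohort_male_fraction = 0.5, mean_tpiv = 28,
                      mean_slope = slope, mean_shift = 0)
    structure(list(scenario_id = "x", seed = 1L, years = yrs,
                   outcome = NA_character_, extinction_year = ext_year,
                   final = NULL), class = "esd_replicate")
  }
  expect_equal(classify_outcome(fake(8000L, -5)), "extinct")
  expect_equal(classify_outcome(fake(NA_integer_, -0.04)), "GSD")
  expect_equal(classify_outcome(fake(NA_integer_, -4.8)), "ESD")
})

test_that("final-window summaries average the last 1000 recorded years", {
  mk <- function(v) data.frame(mean_tpiv = v, mean_slope = v,
                               mean_shift = v)
  expect_equal(summarize_final_window(mk(rep(3, 5000)))[["mean_tpiv"]], 3)
  # series shorter than the window: mean over everything
  expect_equal(summarize_final_window(mk(1:10))[["mean_slope"]], 5.5)
  # linear series: mean over the last 1000 values is their midpoint
  expect_equal(summarize_final_window(mk(1:5000))[["mean_tpiv"]],
               mean(4001:5000))
})

test_that("written outputs round-trip and carry full metadata", {
  grid <- scenario_grid(plasticity = "shift", level = "high", t_glob = 30,
                        sd_bw = 1.5, t_max = 15L)
  b <- run_batch(grid, n_replicates = 2, base_seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_outputs(b, dir)
  expect_true(all(file.exists(paths)))

  summ <- read.csv(paths[["replicates"]])
  expect_equal(nrow(summ), 2)
  ref <- replicate_summary(b)
  expect_equal(summ$final_mean_tpiv, ref$final_mean_tpiv,
               tolerance = 1e-12)
  expect_equal(summ$outcome, ref$outcome)

  ts <- read.csv(paths[["timeseries"]])
  expect_equal(nrow(ts), sum(vapply(b, function(r) nrow(r$years),
                                    integer(1))))

  meta <- jsonlite::read_json(paths[["metadata"]])
  expect_equal(meta$package, "esdsim")
  expect_length(meta$scenarios, 1)
  expect_equal(meta$scenarios[[1]]$t_glob, 30)
  expect_equal(unlist(meta$seeds), c(9, 10))
  expect_match(meta$reaction_norm_convention, "slope multiplies")
})
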