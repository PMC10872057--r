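# Small scenario factories shared across tests.

# A scenario with all stochastic inputs switched off except where a test
# turns them back on: no climate noise, no founder variation, no mutation.
quiet_scenario <- function(...) {
  defaults <- list(plasticity = "slope", level = "high", t_glob = 28,
                   sd_bw = 0, sd_wi = 0, sd_tpiv = 0, sd_slope = 0,
                   sd_shift = 0, mutation_rate = 0, t_max = 100L)
  args <- utils::modifyList(defaults, list(...))
  do.call(esd_scenario, args)
}

# Uniform-genotype population of known size and sex split.
uniform_population <- function(n_males, n_females, tpiv = 28, slope = -5,
                               shift = 0, td = 28) {
  n <- n_males + n_females
  g <- genotypes(tpiv = matrix(tpiv, n, 2), slope = matrix(slope, n, 2),
                 shift = matrix(shift, n, 2))
  adults <- cbind(g, td = rep(td, n),
                  sex = rep(c(1, 0), c(n_males, n_females)))
  structure(list(adults = adults, year = 0L), class = "esd_population")
}
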