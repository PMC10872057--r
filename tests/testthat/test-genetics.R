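test_that("phenotypes are the mean of the two alleles at a locus", {
  g <- genotypes(tpiv = c(28, 28), slope = c(-5, -1.5), shift = c(0, 0.1))
  expect_equal(express_phenotype(g, "tpiv"), 28)
  expect_equal(express_phenotype(g, "slope"), -3.25)
  expect_equal(express_phenotype(g, "shift"), 0.05)
  g2 <- genotypes(tpiv = c(27.5, 28.5), slope = c(-5, -5), shift = c(0, 0))
  expect_equal(express_phenotype(g2, "tpiv"), 28)
  expect_error(express_phenotype(g, "dominance"), "unknown locus")
  expect_error(genotypes(tpiv = c(28, NA), slope = c(-5, -5),
                         shift = c(0, 0)), "finite")
})

test_that("inheritance passes one allele from each parent per locus", {
  mother <- genotypes(tpiv = c(27, 27), slope = c(-5, -5), shift = c(0, 0))
  father <- genotypes(tpiv = c(29, 29), slope = c(-1, -1), shift = c(1, 1))
  off <- inherit_genotypes(mother[rep(1, 50), ], father[rep(1, 50), ])
  # homozygous parents make offspring genotypes certain at every locus
  expect_true(all(off[, "tpiv1"] == 27 & off[, "tpiv2"] == 29))
  expect_true(all(off[, "slope1"] == -5 & off[, "slope2"] == -1))
  expect_true(all(off[, "shift1"] == 0 & off[, "shift2"] == 1))
})

test_that("maternal allele choice is a fair coin", {
  set.seed(101)
  n <- 10000
  mother <- genotypes(tpiv = c(0, 1), slope = c(-5, -5), shift = c(0, 0))
  father <- genotypes(tpiv = c(0, 0), slope = c(-5, -5), shift = c(0, 0))
  off <- inherit_genotypes(mother[rep(1, n), ], father[rep(1, n), ])
  frac_one <- mean(off[, "tpiv1"] == 1)
  expect_lt(abs(frac_one - 0.5), 4 * sqrt(0.25 / n))
})

test_that("inheritance without mutation conserves the allele pool", {
  set.seed(102)
  for (i in 1:20) {
    mothers <- founder_genotypes(30, founder_params())
    fathers <- founder_genotypes(30, founder_params())
    off <- inherit_genotypes(mothers, fathers)
    for (locus in ESD_LOCI) {
      cols <- paste0(locus, 1:2)
      pool <- c(mothers[, cols], fathers[, cols])
      expect_true(all(off[, cols] %in% pool))
    }
  }
})

test_that("mutation respects the rate, the evolvable set and the SDs", {
  set.seed(103)
  g <- founder_genotypes(200, founder_params())
  none <- mutation_params(rate = 0)
  expect_identical(mutate_genotypes(g, none), g)

  # only tpiv evolvable: slope and shift alleles never change
  tpiv_only <- mutation_params(rate = 1, evolvable = "tpiv")
  m <- mutate_genotypes(g, tpiv_only)
  expect_identical(m[, c("slope1", "slope2", "shift1", "shift2")],
                   g[, c("slope1", "slope2", "shift1", "shift2")])
  expect_false(any(m[, "tpiv1"] == g[, "tpiv1"]))

  # forced mutation of a tpiv allele at 28: deviations are N(0, 0.08)
  n <- 100000
  base <- genotypes(tpiv = matrix(28, n, 2), slope = matrix(-5, n, 2),
                    shift = matrix(0, n, 2))
  mut <- mutate_genotypes(base, mutation_params(rate = 1,
                                                evolvable = "tpiv"))
  dev <- mut[, "tpiv1"] - 28
  expect_lt(abs(sd(dev) - 0.08), 0.002)
  # mutation is unbiased: mean within 4 standard errors of zero
  expect_lt(abs(mean(dev)), 4 * 0.08 / sqrt(n))
})

test_that("mutation rate controls the mutant fraction", {
  set.seed(104)
  n <- 50000
  g <- genotypes(tpiv = matrix(28, n, 2), slope = matrix(-5, n, 2),
                 shift = matrix(0, n, 2))
  m <- mutate_genotypes(g, mutation_params(rate = 0.02,
                                           evolvable = "tpiv"))
  frac <- mean(m[, "tpiv1"] != 28)
  expect_lt(abs(frac - 0.02), 4 * sqrt(0.02 * 0.98 / n))
})

test_that("founder genotypes follow the per-allele normal model", {
  set.seed(105)
  expect_equal(nrow(founder_genotypes(500, founder_params())), 500)
  expect_error(founder_genotypes(0, founder_params()), "positive")
  expect_error(founder_genotypes(-3, founder_params()), "positive")

  degenerate <- founder_params(sd_tpiv = 0, sd_slope = 0, sd_shift = 0,
                               mean_tpiv = 28, mean_slope = -5,
                               mean_shift = 0.38)
  g0 <- founder_genotypes(10, degenerate)
  expect_true(all(g0[, c("tpiv1", "tpiv2")] == 28))
  expect_true(all(g0[, c("slope1", "slope2")] == -5))
  expect_true(all(g0[, c("shift1", "shift2")] == 0.38))

  g <- founder_genotypes(10000, founder_params(mean_tpiv = 28,
                                               sd_tpiv = 0.5))
  expect_lt(abs(mean(express_phenotype(g, "tpiv")) - 28), 0.02)
  # phenotypic SD is the allelic SD / sqrt(2) under i.i.d. alleles
  expect_lt(abs(sd(express_phenotype(g, "tpiv")) - 0.5 / sqrt(2)), 0.02)
})
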