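# Diploid three-locus genetic system: pivotal temperature (tpiv, degC),
# reaction-norm slope (dimensionless) and shift (degC per degC of annual
# climate deviation). Genotypes are rows of a 6-column numeric matrix so
# that inheritance and mutation vectorise over whole cohorts.

#' Loci of the sex-determination genotype
#'
#' The three diploid loci of the model, in the column order used by
#' genotype matrices.
#'
#' @format Character vector `c("tpiv", "slope", "shift")`.
#' @export
ESD_LOCI <- c("tpiv", "slope", "shift")

.GENO_COLS <- c("tpiv1", "tpiv2", "slope1", "slope2", "shift1", "shift2")

.locus_cols <- function(locus) {
  i <- match(locus, ESD_LOCI)
  if (is.na(i)) {
    stop("unknown locus '", locus, "'; must be one of ",
         paste(ESD_LOCI, collapse = ", "), call. = FALSE)
  }
  c(2L * i - 1L, 2L * i)
}

#' Build a genotype matrix from allele pairs
#'
#' A genotype carries two real-valued alleles at each of the three loci;
#' the expressed phenotype at a locus is the arithmetic mean of its two
#' alleles. Alleles at a locus are unordered.
#'
#' @param tpiv,slope,shift Two-column numeric matrices (or length-2 vectors
#'   for a single genotype) of allele values at each locus.
#' @return A numeric matrix with one row per genotype and columns
#'   `tpiv1, tpiv2, slope1, slope2, shift1, shift2`.
#' @examples
#' g <- genotypes(tpiv = c(27.5, 28.5), slope = c(-5, -5), shift = c(0, 0))
#' express_phenotype(g, "tpiv")  # 28
#' @export
genotypes <- function(tpiv, slope, shift) {
  as_pair <- function(x, nm) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    if (ncol(x) != 2L) stop("'", nm, "' must supply two alleles per genotype",
                            call. = FALSE)
    x
  }
  g <- cbind(as_pair(tpiv, "tpiv"), as_pair(slope, "slope"),
             as_pair(shift, "shift"))
  if (!all(is.finite(g))) stop("allele values must be finite", call. = FALSE)
  colnames(g) <- .GENO_COLS
  g
}

#' Expressed phenotype at one locus
#'
#' Phenotypes are codominant: the expressed value at a locus is the mean of
#' its two alleles.
#'
#' @param geno Genotype matrix (see [genotypes()]).
#' @param locus One of `"tpiv"`, `"slope"`, `"shift"`.
#' @return Numeric vector of expressed phenotypes, one per genotype row.
#' @export
express_phenotype <- function(geno, locus) {
  cols <- .locus_cols(locus)
  unname((geno[, cols[1L]] + geno[, cols[2L]]) / 2)
}

# All three expressed phenotypes at once; n x 3 matrix (tpiv, slope, shift).
.express_all <- function(geno) {
  cbind(tpiv  = (geno[, 1L] + geno[, 2L]) / 2,
        slope = (geno[, 3L] + geno[, 4L]) / 2,
        shift = (geno[, 5L] + geno[, 6L]) / 2)
}

#' Mutation parameters
#'
#' Each hatchling becomes a mutant with probability `rate` (a single
#' Bernoulli draw per offspring). A mutant perturbs *both* alleles at every
#' evolvable locus by independent Gaussian deviates centred on the original
#' allelic value; non-evolvable loci are never touched.
#'
#' @param rate Probability that an offspring is a mutant (default 0.02).
#' @param sd_tpiv,sd_shift,sd_slope Mutation standard deviations per locus
#'   (defaults 0.08 degC, 0.1, 0.02).
#' @param evolvable Character vector naming the loci free to mutate.
#' @return A validated list of class `mutation_params`.
#' @export
mutation_params <- function(rate = 0.02, sd_tpiv = 0.08, sd_shift = 0.1,
                            sd_slope = 0.02,
                            evolvable = c("tpiv", "slope")) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0, rate <= 1,
            sd_tpiv >= 0, sd_shift >= 0, sd_slope >= 0)
  bad <- setdiff(evolvable, ESD_LOCI)
  if (length(bad)) stop("unknown loci in 'evolvable': ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(rate = rate,
                 sd = c(tpiv = sd_tpiv, slope = sd_slope, shift = sd_shift),
                 evolvable = unique(evolvable)),
            class = "mutation_params")
}

#' Founder-genotype distribution parameters
#'
#' Founder alleles at each locus are drawn i.i.d. from a Normal with the
#' scenario's locus mean and a small standard deviation representing
#' standing variation (about 1% of the evolutionary range of the trait).
#'
#' @param mean_tpiv,mean_slope,mean_shift Locus means (pivotal temperature
#'   in degC; slope and shift at the scenario's plasticity level).
#' @param sd_tpiv,sd_slope,sd_shift Allelic standard deviations
#'   (defaults 0.5, 0.05, 0.01).
#' @return A validated list of class `founder_params`.
#' @export
founder_params <- function(mean_tpiv = 28, sd_tpiv = 0.5,
                           mean_slope = -5, sd_slope = 0.05,
                           mean_shift = 0, sd_shift = 0.01) {
  stopifnot(sd_tpiv >= 0, sd_slope >= 0, sd_shift >= 0)
  structure(list(mean = c(tpiv = mean_tpiv, slope = mean_slope,
                          shift = mean_shift),
                 sd = c(tpiv = sd_tpiv, slope = sd_slope, shift = sd_shift)),
            class = "founder_params")
}

#' Mendelian inheritance at three unlinked loci
#'
#' Each offspring receives one allele from its mother and one from its
#' father at every locus, each drawn uniformly from that parent's allele
#' pair, independently across loci. Rows are matched: offspring `i` has
#' mother `mothers[i, ]` and father `fathers[i, ]`.
#'
#' @param mothers,fathers Genotype matrices with equal row counts.
#' @return Genotype matrix of offspring, one row per cross.
#' @export
inherit_genotypes <- function(mothers, fathers) {
  if (is.null(dim(mothers))) mothers <- matrix(mothers, nrow = 1L)
  if (is.null(dim(fathers))) fathers <- matrix(fathers, nrow = 1L)
  n <- nrow(mothers)
  stopifnot(nrow(fathers) == n, ncol(mothers) == 6L, ncol(fathers) == 6L)
  off <- matrix(0, n, 6L, dimnames = list(NULL, .GENO_COLS))
  # one fair coin per parent per locus; linear indexing picks allele 1 or 2
  pick <- stats::runif(6L * n) < 0.5
  rows <- seq_len(n)
  for (i in seq_len(3L)) {
    c1 <- 2L * i - 1L
    off[, c1] <- mothers[rows + (c1 - 1L + pick[(2L * i - 2L) * n + rows]) * n]
    off[, c1 + 1L] <- fathers[rows + (c1 - 1L + pick[(2L * i - 1L) * n + rows]) * n]
  }
  off
}

#' Gaussian mutation of hatchling genotypes
#'
#' Applies the mutation model of [mutation_params()]: each row is a mutant
#' with probability `params$rate`; mutants have both alleles at every
#' evolvable locus replaced by Normal(original value, locus SD) draws.
#' Allele values are unbounded: slope alleles may drift across zero, which
#' downstream classification treats as loss of environmental sex
#' determination rather than clamping away.
#'
#' @param geno Genotype matrix.
#' @param params A [mutation_params()] object.
#' @return Genotype matrix of the same shape.
#' @export
mutate_genotypes <- function(geno, params) {
  stopifnot(inherits(params, "mutation_params"))
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1L,
                                         dimnames = list(NULL, .GENO_COLS))
  n <- nrow(geno)
  if (params$rate == 0 || n == 0L) return(geno)
  mut <- which(stats::runif(n) < params$rate)
  if (!length(mut)) return(geno)
  k <- length(mut)
  for (locus in params$evolvable) {
    sd <- params$sd[[locus]]
    if (sd == 0) next
    cols <- .locus_cols(locus)
    for (cc in cols) {
      geno[mut, cc] <- stats::rnorm(k, mean = geno[mut, cc], sd = sd)
    }
  }
  geno
}

#' Draw founder genotypes
#'
#' Every allele is drawn independently from its locus's founder Normal,
#' so the expressed-phenotype SD is the allelic SD divided by sqrt(2).
#'
#' @param n Number of genotypes (positive integer).
#' @param params A [founder_params()] object.
#' @return Genotype matrix with `n` rows.
#' @export
founder_genotypes <- function(n, params) {
  stopifnot(inherits(params, "founder_params"))
  if (length(n) != 1L || !is.finite(n) || n <= 0)
    stop("'n' must be a positive count", call. = FALSE)
  n <- as.integer(n)
  g <- matrix(0, n, 6L, dimnames = list(NULL, .GENO_COLS))
  for (i in seq_len(3L)) {
    locus <- ESD_LOCI[i]
    cols <- c(2L * i - 1L, 2L * i)
    g[, cols[1L]] <- stats::rnorm(n, params$mean[[locus]], params$sd[[locus]])
    g[, cols[2L]] <- stats::rnorm(n, params$mean[[locus]], params$sd[[locus]])
  }
  g
}
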