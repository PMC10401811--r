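# Probability models for cohort experiments on an outbred stock:
# the genotype-configuration bias probability (closed form plus an
# exhaustive enumeration oracle), expected biased-region counts, the
# binomial allele-detection power, and the asymptotic variant-discovery
# saturation curve with its nonlinear least-squares fit.

#' Parameters of the genotype-bias model
#'
#' A biallelic locus with allele "a" at frequency `alleleFreq`; each of the
#' `nTreatment + nControl` diploid individuals draws two alleles
#' independently (Hardy-Weinberg, no relatedness).
#'
#' @param nTreatment,nControl group sizes (>= 1).
#' @param alleleFreq frequency of allele "a", in (0, 1).
#' @return named list of validated parameters.
#' @export
biasModelParams <- function(nTreatment = 5L, nControl = 5L,
                            alleleFreq = 0.5) {
  nTreatment <- as.integer(nTreatment)
  nControl <- as.integer(nControl)
  if (nTreatment < 1L || nControl < 1L) stop("group sizes must be >= 1")
  if (!is.finite(alleleFreq) || alleleFreq <= 0 || alleleFreq >= 1)
    stop("alleleFreq must lie strictly inside (0, 1)")
  list(nTreatment = nTreatment, nControl = nControl,
       alleleFreq = alleleFreq)
}

#' Probability of a biased genotype configuration (closed form)
#'
#' The probability that every treatment individual shares a homozygous
#' genotype carried by no control individual, or vice versa. With
#' `f = alleleFreq`, inclusion-exclusion over the four one-sided events
#' (treatment all aa with no control aa, treatment all bb with no control
#' bb, and the two control-sided mirrors) minus the two cross
#' configurations counted twice (treatment all aa and control all bb, and
#' its mirror) gives
#' \deqn{P = f^{2n_t}(1-f^2)^{n_c} + (1-f)^{2n_t}(1-(1-f)^2)^{n_c} +
#'       f^{2n_c}(1-f^2)^{n_t} + (1-f)^{2n_c}(1-(1-f)^2)^{n_t} -
#'       f^{2n_t}(1-f)^{2n_c} - (1-f)^{2n_t}f^{2n_c}.}
#' At (5, 5, 0.5) this reduces to 970/4^10 = 0.0009250641. A group that is
#' uniformly heterozygous does not count as biased: the shared genotype
#' must be homozygous.
#'
#' @param params as from [biasModelParams()].
#' @return the probability.
#' @export
biasedConfigProbability <- function(params = biasModelParams()) {
  f <- params$alleleFreq
  nt <- params$nTreatment
  nc <- params$nControl
  g <- 1 - f
  p_aa <- f^2; p_bb <- g^2
  p_no_aa <- 1 - p_aa; p_no_bb <- 1 - p_bb
  p_aa^nt * p_no_aa^nc + p_bb^nt * p_no_bb^nc +
    p_aa^nc * p_no_aa^nt + p_bb^nc * p_no_bb^nt -
    p_aa^nt * p_bb^nc - p_bb^nt * p_aa^nc
}

#' Probability of a biased configuration by exhaustive enumeration
#'
#' Enumerates all `4^(nTreatment + nControl)` ordered two-allele draws and
#' sums the probability of the biased event. The independent oracle for
#' [biasedConfigProbability()]; desk-scale only.
#'
#' @param params as from [biasModelParams()].
#' @return the probability.
#' @export
biasedConfigProbBruteforce <- function(params = biasModelParams()) {
  n <- params$nTreatment + params$nControl
  if (n > 12L)
    stop("enumeration over 4^", n, " configurations is too large; ",
         "use biasedConfigProbability()")
  f <- params$alleleFreq
  # genotype codes per mouse: 1 = aa, 2 = ab, 3 = ba, 4 = bb
  codes <- as.matrix(expand.grid(rep(list(1:4), n)))
  a_per_code <- c(2L, 1L, 1L, 0L)
  n_a <- rowSums(matrix(a_per_code[codes], nrow = nrow(codes)))
  p_config <- f^n_a * (1 - f)^(2L * n - n_a)
  tr <- codes[, seq_len(params$nTreatment), drop = FALSE]
  ct <- codes[, params$nTreatment + seq_len(params$nControl), drop = FALSE]
  all_aa <- function(m) rowSums(m == 1L) == ncol(m)
  all_bb <- function(m) rowSums(m == 4L) == ncol(m)
  none_aa <- function(m) rowSums(m == 1L) == 0L
  none_bb <- function(m) rowSums(m == 4L) == 0L
  event <- (all_aa(tr) & none_aa(ct)) | (all_bb(tr) & none_bb(ct)) |
    (all_aa(ct) & none_aa(tr)) | (all_bb(ct) & none_bb(tr))
  sum(p_config[event])
}

#' Expected number of biased regions
#'
#' `round(nVariants * biasedConfigProbability(params))`: the expected count
#' of balanced segregating variants at which a treatment/control genotype
#' split arises by chance.
#'
#' @param nVariants number of applicable variants (>= 0).
#' @param params as from [biasModelParams()].
#' @return integer expected count.
#' @export
expectedBiasedRegions <- function(nVariants, params = biasModelParams()) {
  stopifnot(nVariants >= 0)
  as.integer(round(nVariants * biasedConfigProbability(params)))
}

#' Expected biased regions near genes
#'
#' Sums per-class expected biased-region counts and scales by the fraction
#' of variants near genes, truncating to an integer.
#'
#' @param counts numeric vector of expected biased-region counts.
#' @param nearGeneFraction fraction in `[0, 1]`.
#' @return integer estimate.
#' @export
nearGeneBiasedEstimate <- function(counts, nearGeneFraction) {
  stopifnot(nearGeneFraction >= 0, nearGeneFraction <= 1)
  as.integer(floor(sum(counts) * nearGeneFraction))
}

#' Probability of missing a segregating allele entirely
#'
#' The chance that none of `2 * nMice` independently drawn alleles carries
#' a variant of population frequency `popFreq`: `(1 - popFreq)^(2 nMice)`.
#'
#' @param nMice cohort size (>= 1).
#' @param popFreq per-allele population frequency in `[0, 1]`.
#' @return the miss probability.
#' @export
detectionMissProbability <- function(nMice, popFreq) {
  stopifnot(nMice >= 1, popFreq >= 0, popFreq <= 1)
  (1 - popFreq)^(2 * nMice)
}

#' Evaluate the saturation curve
#'
#' `N(x) = a - (a - c) * exp(-b * (x - x0))`.
#'
#' @param model a [SaturationModel-class].
#' @param x cohort size(s).
#' @return predicted variant count(s).
#' @export
evalSaturation <- function(model, x) {
  model@a - (model@a - model@c) * exp(-model@b * (x - model@x0))
}

#' Fit the saturation curve by nonlinear least squares
#'
#' Uses `stats::nls()` with the port algorithm and `maxiter = 5000`. Start
#' values: `c0` is the count at the smallest x, `b0 = 1`, and `a0` solves
#' the model at the largest x given `b0` and `c0`. With exactly 3 distinct
#' x values the fit interpolates all three points.
#'
#' @param xs cohort sizes (>= 3 distinct values).
#' @param counts observed variant counts.
#' @param x0 anchor cohort size (defaults to the smallest x).
#' @return A [SaturationModel-class].
#' @export
fitSaturation <- function(xs, counts, x0 = min(xs)) {
  if (length(unique(xs)) < 3L)
    stop("fitSaturation needs at least 3 distinct x values")
  o <- order(xs)
  xs <- xs[o]; counts <- counts[o]
  c0 <- mean(counts[xs == min(xs)])
  b0 <- 1
  x_max <- max(xs)
  N_max <- mean(counts[xs == x_max])
  # solve a from N_max = a - (a - c0) exp(-b0 (x_max - x0))
  e <- exp(-b0 * (x_max - x0))
  a0 <- (N_max - c0 * e) / (1 - e)
  dat <- data.frame(x = xs, N = counts)
  fit <- tryCatch(
    stats::nls(N ~ a - (a - c) * exp(-b * (x - x0)), data = dat,
               start = list(a = a0, b = b0, c = c0),
               algorithm = "port", control = list(maxiter = 5000)),
    error = function(e)
      stop("saturation fit did not converge (start a=", signif(a0, 6),
           ", b=", b0, ", c=", signif(c0, 6), "): ", conditionMessage(e)))
  est <- stats::coef(fit)
  SaturationModel(a = est[["a"]], b = est[["b"]], c = est[["c"]], x0 = x0)
}
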