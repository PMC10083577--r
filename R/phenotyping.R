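#' Calibrate the phenotypic error variance from founder heritability
#'
#' The error variance is anchored once, at the start of a program, so that
#' the trait shows heritability `h2` in the founder population:
#' `Ve = Vg * (1 - h2) / h2` with `Vg` the variance of founder true breeding
#' values. The same `Ve` is reused in every later generation, so realized
#' heritability erodes as genetic variance is consumed by selection.
#'
#' The default `h2 = 0.7` corresponds to a multitrial evaluation with a
#' single replicate in 4 environments and a single-trial repeatability of
#' 0.37: `0.37 / (0.37 + 0.63/4) ~= 0.70`.
#'
#' @param founder_tbvs numeric vector of founder true breeding values
#'   (length >= 2, non-zero variance).
#' @param h2 target founder heritability in (0, 1].
#' @return scalar error variance.
#' @export
calibrate_error_variance <- function(founder_tbvs, h2 = 0.7) {
  if (!(h2 > 0 && h2 <= 1)) stop("h2 must be in (0, 1]")
  stopifnot(length(founder_tbvs) >= 2)
  vg <- stats::var(founder_tbvs)
  if (vg <= 0) stop("founder TBV variance must be positive")
  vg * (1 - h2) / h2
}

#' Simulate phenotypes for a population
#'
#' One routine record per line: `phenotype = TBV + N(0, error_variance)`,
#' i.i.d. across lines (the multi-environment trial mean is collapsed into a
#' single Gaussian deviate whose variance is the trial-mean error variance).
#'
#' @param pop a `gsb_pop`.
#' @param arch a `gsb_arch`.
#' @param error_variance non-negative error variance from
#'   [calibrate_error_variance()].
#' @return numeric vector of phenotypes, named by individual id.
#' @export
phenotype_population <- function(pop, arch, error_variance) {
  stopifnot(error_variance >= 0)
  tbv <- true_breeding_value(pop, arch)
  y <- tbv + stats::rnorm(n_ind(pop), 0, sqrt(error_variance))
  names(y) <- pop$id
  y
}

#' Shrink donor phenotypes toward the scale of genomic predictions
#'
#' Donor-panel lines are phenotyped only once (same error variance as the
#' routine trials). To make those records comparable with GEBVs, they are
#' centred and shrunk by the observed heritability:
#' `value_i = observed_h2 * (phenotype_i - mean(phenotypes))`.
#'
#' @param phenotypes numeric vector of single-trial donor phenotypes
#'   (length >= 2).
#' @param observed_h2 heritability observed in the donor trial, in (0, 1].
#'   See [observed_heritability()].
#' @return centred, shrunk values (mean zero; ranking preserved).
#' @export
shrink_donor_phenotypes <- function(phenotypes, observed_h2) {
  stopifnot(length(phenotypes) >= 2)
  if (!(observed_h2 > 0 && observed_h2 <= 1)) {
    stop("observed_h2 must be in (0, 1]")
  }
  observed_h2 * (phenotypes - mean(phenotypes))
}

#' Plug-in observed heritability of a simulated trial
#'
#' In simulation the "observed" heritability of a single-trial evaluation is
#' available as the plug-in ratio `Vg / (Vg + Ve)` with `Vg` the variance of
#' the trialed lines' true breeding values.
#'
#' @param tbvs true breeding values of the trialed lines.
#' @param error_variance trial error variance.
#' @return scalar in (0, 1].
#' @export
observed_heritability <- function(tbvs, error_variance) {
  vg <- stats::var(tbvs)
  vg / (vg + error_variance)
}
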