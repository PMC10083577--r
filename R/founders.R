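#' Specification of a synthetic founder panel
#'
#' Describes a structured panel of inbred lines emulating a dent maize
#' diversity panel: three subpopulations (57, 82 and 199 lines by default)
#' genotyped at biallelic SNPs spread over 10 chromosomes. Group
#' differentiation follows a Balding-Nichols model with dispersion
#' `divergence`, and within-group linkage disequilibrium decays with map
#' distance through a Gaussian-copula autoregression (correlation
#' `exp(-d / ld_scale)` at distance d cM).
#'
#' @param group_sizes integer vector of subpopulation sizes.
#' @param n_chromosomes,chrom_length,n_markers map parameters, see
#'   [generate_genetic_map()].
#' @param divergence Balding-Nichols Fst-like dispersion, in (0, 1).
#' @param maf_floor minimum panel-wide minor allele frequency in [0, 0.5);
#'   violating sites are resampled after generation.
#' @param ld_scale LD decay scale in cM (copula correlation `exp(-d/ld_scale)`).
#' @param seed integer seed making the panel reproducible.
#' @return an object of class `gsb_founder_spec`.
#' @export
founder_panel_spec <- function(group_sizes = c(57, 82, 199),
                               n_chromosomes = 10,
                               chrom_length = 160,
                               n_markers = 41495,
                               divergence = 0.15,
                               maf_floor = 0.05,
                               ld_scale = 5,
                               seed = 1L) {
  group_sizes <- as.integer(group_sizes)
  stopifnot(length(group_sizes) >= 1, all(group_sizes >= 1),
            divergence > 0, divergence < 1,
            maf_floor >= 0, maf_floor < 0.5,
            ld_scale > 0)
  spec <- list(
    n_groups = length(group_sizes), group_sizes = group_sizes,
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length, n_markers = as.integer(n_markers),
    divergence = divergence, maf_floor = maf_floor,
    ld_scale = ld_scale, seed = as.integer(seed)
  )
  class(spec) <- "gsb_founder_spec"
  spec
}

#' Generate a structured panel of inbred founder lines
#'
#' Ancestral allele frequencies are drawn Uniform(0.1, 0.9) per marker; each
#' subpopulation's frequencies are dispersed around them with a
#' Balding-Nichols Beta distribution controlled by `spec$divergence`.
#' Within a group, each line's haplotype is drawn marker-by-marker along a
#' chromosome from a first-order Gaussian copula so that marginal frequencies
#' are respected exactly while correlation (hence r-squared LD) decays with
#' map distance. Sites whose realized panel-wide minor allele frequency
#' falls below `spec$maf_floor` are resampled.
#'
#' All lines are fully homozygous; the returned population stores one
#' haplotype per line.
#'
#' @param spec a [founder_panel_spec()].
#' @param map a `gsb_map` with `spec$n_markers` markers (generated from the
#'   spec when omitted).
#' @param seed overrides `spec$seed` when given.
#' @return a `gsb_pop` of `sum(spec$group_sizes)` lines, with a `group`
#'   attribute (integer group index per line) and component tag `"founder"`.
#' @export
generate_founder_panel <- function(spec, map = NULL, seed = NULL) {
  stopifnot(inherits(spec, "gsb_founder_spec"))
  if (is.null(map)) {
    map <- generate_genetic_map(spec$n_chromosomes, spec$chrom_length,
                                spec$n_markers)
  }
  if (n_markers(map) != spec$n_markers) {
    stop("map marker count does not match spec")
  }
  set.seed(if (is.null(seed)) spec$seed else seed)

  m <- spec$n_markers
  n <- sum(spec$group_sizes)
  F <- spec$divergence
  p_anc <- stats::runif(m, 0.1, 0.9)
  # Balding-Nichols per-group frequencies
  p_grp <- vapply(seq_len(spec$n_groups), function(g) {
    stats::rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  }, numeric(m))
  # guard against Beta draws collapsing to exactly 0/1
  p_grp <- pmin(pmax(p_grp, 1e-6), 1 - 1e-6)

  haplo <- matrix(0L, n, m)
  chrom_idx <- map_chrom_index(map)
  row0 <- 0L
  for (g in seq_len(spec$n_groups)) {
    ng <- spec$group_sizes[g]
    rows <- row0 + seq_len(ng)
    for (idx in chrom_idx) {
      a <- exp(-diff(map$pos[idx]) / spec$ld_scale)  # copula autocorrelation
      z <- stats::rnorm(ng)
      thr <- stats::qnorm(p_grp[idx, g])
      haplo[rows, idx[1]] <- as.integer(z < thr[1])
      for (j in seq_along(a)) {
        z <- a[j] * z + sqrt(1 - a[j]^2) * stats::rnorm(ng)
        haplo[rows, idx[j + 1L]] <- as.integer(z < thr[j + 1L])
      }
    }
    row0 <- row0 + ng
  }

  # enforce the panel-wide MAF floor by resampling offending sites
  if (spec$maf_floor > 0) {
    for (iter in 1:100) {
      freq <- colMeans(haplo)
      bad <- which(pmin(freq, 1 - freq) < spec$maf_floor)
      if (!length(bad)) break
      for (j in bad) {
        haplo[, j] <- as.integer(stats::runif(n) < stats::runif(1, 0.3, 0.7))
      }
    }
    freq <- colMeans(haplo)
    bad <- which(pmin(freq, 1 - freq) < spec$maf_floor)
    for (j in bad) {  # deterministic fallback for pathological sizes
      haplo[, j] <- 0L
      haplo[sample.int(n, max(1L, ceiling(n / 2))), j] <- 1L
    }
  }

  pop <- new_population(seq_len(n), haplo, component = "founder", generation = 0L)
  attr(pop, "group") <- rep(seq_len(spec$n_groups), spec$group_sizes)
  pop
}

#' Mean r-squared LD by map-distance bin
#'
#' Diagnostic used to check that simulated linkage disequilibrium decays
#' with distance. Pairs are sampled within chromosomes.
#'
#' @param pop a `gsb_pop`.
#' @param map the matching `gsb_map`.
#' @param breaks distance bin edges in cM.
#' @param max_pairs pairs sampled per bin.
#' @param seed RNG seed for pair sampling.
#' @return data.frame with bin labels and mean r-squared per bin.
#' @export
ld_decay <- function(pop, map, breaks = c(0, 1, 5, 20), max_pairs = 2000,
                     seed = 1L) {
  set.seed(seed)
  n_bin <- length(breaks) - 1
  acc <- vector("list", n_bin)
  chrom_idx <- map_chrom_index(map)
  freq <- allele_freq(pop)
  poly <- pmin(freq, 1 - freq) > 0
  for (b in seq_len(n_bin)) {
    lo <- breaks[b]; hi <- breaks[b + 1]
    r2 <- numeric(0)
    tries <- 0L
    while (length(r2) < max_pairs && tries < 50L * max_pairs) {
      tries <- tries + 1L
      idx <- chrom_idx[[sample.int(length(chrom_idx), 1)]]
      i <- idx[sample.int(length(idx), 1)]
      cand <- idx[abs(map$pos[idx] - map$pos[i]) > lo &
                    abs(map$pos[idx] - map$pos[i]) <= hi & idx != i]
      cand <- cand[poly[cand]]
      if (!poly[i] || !length(cand)) next
      j <- cand[sample.int(length(cand), 1)]
      r2 <- c(r2, stats::cor(pop$haplo[, i], pop$haplo[, j])^2)
    }
    acc[[b]] <- r2
  }
  data.frame(
    bin = sprintf("(%g,%g] cM", breaks[-length(breaks)], breaks[-1]),
    mean_r2 = vapply(acc, function(x) if (length(x)) mean(x) else NA_real_, 1),
    n_pairs = vapply(acc, length, 1L)
  )
}
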