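#' Sample a simulated trait architecture
#'
#' Draws `n_qtl` biallelic QTLs among the markers subject to a minimal map
#' distance between consecutive QTLs, with additive allele-substitution
#' effects sampled i.i.d. from a centred Gaussian, plus a disjoint set of
#' neutral markers used for diversity monitoring and as the genomic
#' selection genotyping panel. QTL positions are never visible to selection.
#'
#' Sampling strategy for the spacing constraint: full QTL sets are rejection
#' sampled (up to `max_retries` draws); if no draw satisfies the constraint a
#' greedy left-to-right thinning of a random candidate ordering is used.
#'
#' @param map a `gsb_map`.
#' @param n_qtl number of QTLs (default 1000).
#' @param min_dist_cM minimal distance between consecutive QTLs in map order
#'   (default 0.2 cM).
#' @param effect_var variance of the Gaussian effect distribution
#'   (default 0.05).
#' @param n_neutral number of neutral markers (default 2000), sampled
#'   uniformly among non-QTL markers.
#' @param seed optional RNG seed.
#' @param max_retries rejection-sampling budget for the QTL set.
#' @return an object of class `gsb_arch` with fields `qtl_indices`,
#'   `qtl_effects`, `neutral_indices`, `effect_variance`.
#' @export
sample_trait_architecture <- function(map, n_qtl = 1000, min_dist_cM = 0.2,
                                      effect_var = 0.05, n_neutral = 2000,
                                      seed = NULL, max_retries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  m <- n_markers(map)
  if (n_qtl + n_neutral > m) stop("not enough markers for QTL + neutral sets")

  qtl <- NULL
  for (try in seq_len(max_retries)) {
    cand <- sort(sample.int(m, n_qtl))
    if (qtl_spacing_ok(cand, map, min_dist_cM)) { qtl <- cand; break }
  }
  if (is.null(qtl)) {
    # greedy fallback: scan markers in map order, keep while spacing holds
    perm <- sample.int(m)               # random priority
    keep <- logical(m)
    ord <- order(map$chrom, map$pos, perm)
    last_pos <- rep(-Inf, max(map$chrom))
    taken <- 0L
    for (i in ord) {
      if (taken == n_qtl) break
      c_ <- map$chrom[i]
      if (map$pos[i] - last_pos[c_] >= min_dist_cM) {
        keep[i] <- TRUE; last_pos[c_] <- map$pos[i]; taken <- taken + 1L
      }
    }
    if (taken < n_qtl) {
      stop("cannot place ", n_qtl, " QTLs at spacing ", min_dist_cM,
           " cM on this map")
    }
    qtl <- which(keep)
  }
  pool <- setdiff(seq_len(m), qtl)
  if (length(pool) < n_neutral) stop("not enough non-QTL markers for neutral set")
  neutral <- sort(sample(pool, n_neutral))
  arch <- list(
    qtl_indices = qtl,
    qtl_effects = stats::rnorm(n_qtl, 0, sqrt(effect_var)),
    neutral_indices = neutral,
    effect_variance = effect_var,
    min_dist_cM = min_dist_cM
  )
  class(arch) <- "gsb_arch"
  arch
}

# spacing check: consecutive QTLs on the same chromosome >= min_dist apart
qtl_spacing_ok <- function(qtl_sorted, map, min_dist_cM) {
  same <- diff(map$chrom[qtl_sorted]) == 0L
  d <- diff(map$pos[qtl_sorted])
  all(d[same] >= min_dist_cM)
}

#' @export
print.gsb_arch <- function(x, ...) {
  cat(sprintf(
    "<gsb_arch> %d QTLs (effect var %.3g), %d neutral markers\n",
    length(x$qtl_indices), x$effect_variance, length(x$neutral_indices)))
  invisible(x)
}

#' True breeding values
#'
#' TBV of a line is the dosage-weighted sum of QTL effects,
#' `sum(effect_q * dosage_q)` with dosages in {0, 2}. Known in simulation,
#' hidden from selection.
#'
#' @param pop a `gsb_pop`.
#' @param arch a `gsb_arch`.
#' @return numeric vector, one TBV per line.
#' @export
true_breeding_value <- function(pop, arch) {
  as.vector(dosages(pop, arch$qtl_indices) %*% arch$qtl_effects)
}

#' Weighted QTL fixation classes
#'
#' Classifies every QTL in a population as fixed for the favorable allele
#' (the fixed allele is the one whose substitution increases breeding value),
#' fixed for the unfavorable allele, or still segregating. Each class is
#' reported as a weighted rate: the sum of absolute effects of its QTLs
#' divided by the sum of absolute effects of all QTLs, so the three rates
#' sum to one.
#'
#' @param pop a `gsb_pop` (typically the elite component of a generation).
#' @param arch a `gsb_arch`.
#' @return named numeric vector `c(fixed_plus, fixed_minus, segregating)`.
#' @export
classify_qtl_fixation <- function(pop, arch) {
  stopifnot(n_ind(pop) > 0)
  p <- allele_freq(pop, arch$qtl_indices)   # frequency of the 1-allele
  eff <- arch$qtl_effects
  w <- abs(eff)
  # zero-effect QTLs carry zero weight; class them by frequency only
  fixed_hi <- p == 1     # 1-allele fixed
  fixed_lo <- p == 0     # 0-allele fixed
  plus  <- (fixed_hi & eff >= 0) | (fixed_lo & eff < 0)
  minus <- (fixed_hi & eff < 0)  | (fixed_lo & eff >= 0)
  seg   <- !(fixed_hi | fixed_lo)
  tot <- sum(w)
  c(fixed_plus = sum(w[plus]) / tot,
    fixed_minus = sum(w[minus]) / tot,
    segregating = sum(w[seg]) / tot)
}

#' Serialize / read a trait architecture as CSV
#'
#' One row per QTL or neutral marker: `marker_id, role, effect` (effects are
#' empty for neutral markers).
#'
#' @param arch a `gsb_arch`.
#' @param map the `gsb_map` supplying marker ids.
#' @param file CSV path.
#' @return `file` invisibly; `read_trait_architecture` returns a `gsb_arch`.
#' @export
write_trait_architecture <- function(arch, map, file) {
  df <- rbind(
    data.frame(marker_id = map$marker_id[arch$qtl_indices], role = "qtl",
               effect = arch$qtl_effects, stringsAsFactors = FALSE),
    data.frame(marker_id = map$marker_id[arch$neutral_indices],
               role = "neutral", effect = NA_real_, stringsAsFactors = FALSE)
  )
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_trait_architecture
#' @export
read_trait_architecture <- function(file, map) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  idx <- match(df$marker_id, map$marker_id)
  if (anyNA(idx)) stop("architecture refers to markers absent from the map")
  qtl <- df$role == "qtl"
  ord <- order(idx[qtl])
  arch <- list(
    qtl_indices = idx[qtl][ord],
    qtl_effects = df$effect[qtl][ord],
    neutral_indices = sort(idx[!qtl]),
    effect_variance = stats::var(df$effect[qtl]),
    min_dist_cM = NA_real_
  )
  class(arch) <- "gsb_arch"
  arch
}
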