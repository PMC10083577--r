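#' Restrict a genetic map to a marker subset
#'
#' Used to carry the GS genotyping panel's coordinates (chromosome, cM)
#' alongside its effect estimates.
#'
#' @param map a `gsb_map`.
#' @param indices marker indices to keep (map order preserved).
#' @return a `gsb_map` over the subset.
#' @export
subset_map <- function(map, indices) {
  new_genetic_map(map$chrom[indices], map$pos[indices], map$marker_id[indices])
}

#' Predicted standard deviation of DH progeny of a biparental cross
#'
#' For two fully homozygous parents with dosages `a` in {0, 2} at the GS
#' marker panel, let `s_m = (a_jm - a_km) / 2` in {-1, 0, +1}. The genetic
#' variance among DH progeny predicted from estimated marker effects `beta`
#' and map-based linkage disequilibrium is
#' `sigma2 = sum_l sum_m beta_l beta_m s_l s_m (1 - 2 r_lm)`,
#' with `r_lm` the Haldane recombination fraction from the cM distance within
#' a chromosome and `r = 0.5` across chromosomes. Because Haldane's
#' `1 - 2r(d) = exp(-2d)` (d in Morgans) is multiplicative along a
#' chromosome, the double sum is evaluated in O(m) with cumulative products.
#'
#' @param hap_j,hap_k parental haplotypes (0/1) over the GS marker panel.
#' @param effects estimated marker effects over the same panel.
#' @param panel_map `gsb_map` of the panel markers (see [subset_map()]).
#' @return `sigma_jk >= 0`, the predicted progeny standard deviation.
#' @export
progeny_sd_dh <- function(hap_j, hap_k, effects, panel_map) {
  if (!all(hap_j %in% c(0L, 1L)) || !all(hap_k %in% c(0L, 1L))) {
    stop("parents must be homozygous lines coded by 0/1 haplotypes")
  }
  d_all <- effects * (hap_j - hap_k)    # beta * s, s in {-1,0,1}
  sigma2 <- 0
  for (idx in map_chrom_index(panel_map)) {
    d <- d_all[idx]
    if (!any(d != 0)) next
    rho <- exp(-2 * diff(panel_map$pos[idx]) / 100)  # 1 - 2r, Haldane
    C <- cumprod(c(1, rho))
    a <- d * C
    b <- d / C
    cross_terms <- sum(a * (cumsum(b) - b))
    sigma2 <- sigma2 + sum(d^2) + 2 * cross_terms
  }
  sqrt(max(sigma2, 0))
}

#' Usefulness criterion of a cross
#'
#' Expected mean of the selected fraction of a cross's DH progeny:
#' `UC = (gebv_j + gebv_k) / 2 + i * h * sigma_jk`, with selection intensity
#' `i` (default 2.06, the intensity of truncating the top 5% of a standard
#' normal) and evaluation accuracy `h` (default 1).
#'
#' @param gebv_j,gebv_k parental predicted values.
#' @param sigma_jk predicted progeny standard deviation, `>= 0`.
#' @param i selection intensity.
#' @param h evaluation accuracy.
#' @return the UC value (same units as the GEBVs).
#' @export
usefulness_criterion <- function(gebv_j, gebv_k, sigma_jk, i = 2.06, h = 1) {
  stopifnot(all(sigma_jk >= 0))
  (gebv_j + gebv_k) / 2 + i * h * sigma_jk
}

#' Selection intensity of truncating the top fraction of a standard normal
#'
#' `i(alpha) = dnorm(qnorm(1 - alpha)) / alpha`; for `alpha = 0.05` this is
#' 2.06 to two decimals.
#'
#' @param alpha selected fraction in (0, 1).
#' @return the standardized selection differential.
#' @export
selection_intensity <- function(alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  stats::dnorm(stats::qnorm(1 - alpha)) / alpha
}

#' Nei expected heterozygosity over a marker set
#'
#' `He = mean_m 2 p_m (1 - p_m)` with `p_m` the allele frequency in the
#' population at neutral marker m.
#'
#' @param pop a `gsb_pop`.
#' @param neutral_indices marker column indices of the neutral panel.
#' @return scalar He in `[0, 0.5]`.
#' @export
nei_he <- function(pop, neutral_indices) {
  stopifnot(n_ind(pop) > 0)
  p <- allele_freq(pop, neutral_indices)
  mean(2 * p * (1 - p))
}

# He from a frequency vector
he_from_freq <- function(p) mean(2 * p * (1 - p))

#' Expected neutral diversity after executing a cross plan
#'
#' The expected next-generation allele frequency at each neutral marker is
#' the progeny-weighted mean of the crosses' midparent frequencies (each DH
#' inherits either parental allele with probability 1/2); He is computed from
#' those expected frequencies. An optional per-cross frequency shift
#' accommodates within-cross selection (see [ucpc_select()]).
#'
#' @param plan a [cross_plan()].
#' @param candidate_pool `gsb_pop` containing the plan's parents.
#' @param neutral_indices neutral marker column indices.
#' @param shift optional matrix (crosses x neutral markers) added to the
#'   midparent frequencies before averaging.
#' @return expected He after the plan.
#' @export
expected_he_after_plan <- function(plan, candidate_pool, neutral_indices,
                                   shift = NULL) {
  stopifnot(nrow(plan) >= 1)
  ra <- match(plan$parent_a, candidate_pool$id)
  rb <- match(plan$parent_b, candidate_pool$id)
  if (anyNA(ra) || anyNA(rb)) stop("plan parent absent from candidate pool")
  ha <- candidate_pool$haplo[ra, neutral_indices, drop = FALSE]
  hb <- candidate_pool$haplo[rb, neutral_indices, drop = FALSE]
  pf <- (ha + hb) / 2
  if (!is.null(shift)) pf <- pmin(pmax(pf + shift, 0), 1)
  w <- plan$n_progeny / sum(plan$n_progeny)
  he_from_freq(colSums(pf * w))
}

#' Optimizer settings for cross-plan selection
#'
#' Simulated annealing over cross lists: a move swaps one cross of the plan
#' for a random candidate cross; once a feasible plan (expected He at or
#' above target) has been visited, moves that violate the constraint are
#' rejected, before that the violation is penalized. Geometric cooling.
#'
#' @param iterations annealing steps (default 20000).
#' @param t0_frac initial temperature as a fraction of the candidate score
#'   range.
#' @param cooling per-step geometric cooling factor (computed from
#'   `iterations` when `NULL`).
#' @param penalty He-violation penalty per unit of shortfall (scaled by the
#'   score range when `NULL`).
#' @return a list of class `gsb_optim_cfg`.
#' @export
optimizer_config <- function(iterations = 20000, t0_frac = 0.2,
                             cooling = NULL, penalty = NULL) {
  structure(list(iterations = iterations, t0_frac = t0_frac,
                 cooling = cooling, penalty = penalty),
            class = "gsb_optim_cfg")
}

# Core simulated-annealing search over cross lists.
#
# pairs:    data.frame(a_row, b_row, score) of candidate crosses (row indices
#           into `freq_parent`), plus optional shift rows in `shift`.
# freq_parent: matrix (parents x neutral markers) of parental haplotypes.
# fixed:    optional list(sum = weighted freq sum vector, weight = total
#           progeny weight) of crosses fixed outside the search.
# Returns indices into `pairs` of the selected plan with attributes.
anneal_cross_plan <- function(pairs, freq_parent, n_crosses, He_target,
                              cross_weight, fixed = NULL, shift = NULL,
                              cfg = optimizer_config(), seed = NULL) {
  if (n_crosses < 1) stop("n_crosses must be >= 1")
  np <- nrow(pairs)
  if (np < n_crosses) stop("fewer candidate crosses than requested")
  if (!is.null(seed)) set.seed(seed)

  cross_freq <- function(k) {
    f <- (freq_parent[pairs$a_row[k], ] + freq_parent[pairs$b_row[k], ]) / 2
    if (!is.null(shift)) f <- pmin(pmax(f + shift[k, ], 0), 1)
    f
  }
  fixed_sum <- if (is.null(fixed)) 0 else fixed$sum
  fixed_w <- if (is.null(fixed)) 0 else fixed$weight
  he_of <- function(sum_sel) {
    he_from_freq((fixed_sum + sum_sel) / (fixed_w + n_crosses * cross_weight))
  }

  ord <- order(pairs$score, decreasing = TRUE)
  cur <- ord[seq_len(n_crosses)]
  freq_rows <- t(vapply(cur, cross_freq, numeric(ncol(freq_parent))))
  sum_sel <- colSums(freq_rows) * cross_weight
  cur_he <- he_of(sum_sel)
  cur_score <- mean(pairs$score[cur])

  score_range <- diff(range(pairs$score))
  if (!is.finite(score_range) || score_range == 0) score_range <- 1
  penalty <- if (is.null(cfg$penalty)) 200 * score_range else cfg$penalty
  merit <- function(score, he) {
    score - penalty * max(0, He_target - he)
  }
  cur_merit <- merit(cur_score, cur_he)

  best_feas <- NULL; best_feas_score <- -Inf; best_feas_he <- NA_real_
  best_he_plan <- cur; best_he <- cur_he
  feasible_seen <- cur_he >= He_target
  if (feasible_seen) {
    best_feas <- cur; best_feas_score <- cur_score; best_feas_he <- cur_he
  }

  iters <- cfg$iterations
  temp <- cfg$t0_frac * score_range
  cool <- if (is.null(cfg$cooling)) exp(log(1e-4) / max(1, iters)) else cfg$cooling
  in_plan <- logical(np); in_plan[cur] <- TRUE

  for (it in seq_len(iters)) {
    pos <- sample.int(n_crosses, 1)
    cand <- sample.int(np, 1)
    if (in_plan[cand]) next
    new_freq <- cross_freq(cand)
    new_sum <- sum_sel + (new_freq - freq_rows[pos, ]) * cross_weight
    new_he <- he_of(new_sum)
    new_score <- cur_score + (pairs$score[cand] - pairs$score[cur[pos]]) / n_crosses
    if (feasible_seen && new_he < He_target) { temp <- temp * cool; next }
    new_merit <- merit(new_score, new_he)
    d <- new_merit - cur_merit
    if (d >= 0 || stats::runif(1) < exp(d / max(temp, 1e-12))) {
      in_plan[cur[pos]] <- FALSE; in_plan[cand] <- TRUE
      cur[pos] <- cand
      freq_rows[pos, ] <- new_freq
      sum_sel <- new_sum; cur_he <- new_he
      cur_score <- new_score; cur_merit <- new_merit
      if (cur_he >= He_target) {
        feasible_seen <- TRUE
        if (cur_score > best_feas_score) {
          best_feas <- cur; best_feas_score <- cur_score; best_feas_he <- cur_he
        }
      }
      if (cur_he > best_he) { best_he <- cur_he; best_he_plan <- cur }
    }
    temp <- temp * cool
  }

  if (!is.null(best_feas)) {
    structure(best_feas, he = best_feas_he, score = best_feas_score,
              feasible = TRUE)
  } else {
    structure(best_he_plan, he = best_he, score = mean(pairs$score[best_he_plan]),
              feasible = FALSE)
  }
}

# All unordered candidate pairs among pool rows (a specific pair at most once
# per plan; a parent may appear in several crosses).
all_pairs <- function(n) {
  if (n < 2) stop("need at least 2 candidates")
  idx <- utils::combn(n, 2)
  data.frame(a_row = idx[1, ], b_row = idx[2, ])
}

#' Optimal cross selection under a Nei-diversity constraint
#'
#' Selects `n_crosses` biparental crosses among all unordered candidate
#' pairs, maximizing the plan's mean midparent score subject to the expected
#' next-generation neutral He staying at or above `He_target`. When no
#' feasible plan is found, the plan with maximal expected He is returned and
#' flagged (`attr(plan, "feasible") == FALSE`). With `He_target = 0` the
#' result reduces to the top crosses by score.
#'
#' @param candidates a `gsb_pop` of candidate parents.
#' @param scores_mean per-candidate values (named by id or in pool order);
#'   a cross is scored by the mean of its two parents' values.
#' @param neutral_indices neutral marker column indices.
#' @param He_target diversity floor for the expected He after the plan.
#' @param n_crosses number of crosses to select.
#' @param n_progeny DH per cross (recorded in the plan).
#' @param component component tag of the plan's crosses.
#' @param cfg an [optimizer_config()].
#' @param seed optional RNG seed for the annealer.
#' @param generation generation index stamped on the plan.
#' @return a [cross_plan()] with attributes `expected_he`, `feasible`,
#'   `mean_score`.
#' @export
ocs_select <- function(candidates, scores_mean, neutral_indices, He_target,
                       n_crosses, n_progeny = 80, component = "elite",
                       cfg = optimizer_config(), seed = NULL,
                       generation = NA_integer_) {
  n <- n_ind(candidates)
  scores_mean <- resolve_scores(scores_mean, candidates)
  pairs <- all_pairs(n)
  pairs$score <- (scores_mean[pairs$a_row] + scores_mean[pairs$b_row]) / 2
  freq_parent <- candidates$haplo[, neutral_indices, drop = FALSE]
  sel <- anneal_cross_plan(pairs, freq_parent, n_crosses, He_target,
                           cross_weight = n_progeny, cfg = cfg, seed = seed)
  finalize_plan(sel, pairs, candidates, n_progeny, component, generation)
}

#' UCPC-based optimal cross selection
#'
#' Like [ocs_select()] but each cross is scored by its usefulness criterion
#' (midparent GEBV plus `i * h` times the predicted DH progeny standard
#' deviation), and the diversity constraint accounts for within-cross
#' selection: the expected frequency contribution of cross (j, k) at neutral
#' marker m is shifted from the midparent frequency by
#' `i * h * cov(dosage_m, GEBV) / (2 * sigma_jk)`, the first-order
#' truncation-selection regression of marker frequency on the selection
#' criterion among the cross's DH (falling back to the midparent frequency
#' when `sigma_jk = 0`). The GS marker panel and the neutral panel coincide,
#' so the shift is available at every neutral marker.
#'
#' @param candidates a `gsb_pop` of candidate parents.
#' @param gebv per-candidate GEBVs (named by id or in pool order).
#' @param effects backsolved marker effects over the GS/neutral panel.
#' @param panel_map `gsb_map` of the panel markers.
#' @param neutral_indices column indices of the panel in the population's
#'   marker matrix.
#' @param He_target,n_crosses,n_progeny,component,cfg,seed,generation as in
#'   [ocs_select()].
#' @param i,h selection intensity and accuracy of the UC.
#' @return a [cross_plan()] with attributes `expected_he`, `feasible`,
#'   `mean_score`.
#' @export
ucpc_select <- function(candidates, gebv, effects, panel_map, neutral_indices,
                        He_target, n_crosses, n_progeny = 80,
                        component = "elite", i = 2.06, h = 1,
                        cfg = optimizer_config(), seed = NULL,
                        generation = NA_integer_) {
  n <- n_ind(candidates)
  gebv <- resolve_scores(gebv, candidates)
  pairs <- all_pairs(n)
  hap_panel <- candidates$haplo[, neutral_indices, drop = FALSE]
  k <- nrow(pairs)
  sigma <- numeric(k)
  shift <- matrix(0, k, length(neutral_indices))
  for (q in seq_len(k)) {
    hj <- hap_panel[pairs$a_row[q], ]
    hk <- hap_panel[pairs$b_row[q], ]
    sigma[q] <- progeny_sd_dh(hj, hk, effects, panel_map)
    if (sigma[q] > 0) {
      cov_m <- dosage_gebv_cov(hj, hk, effects, panel_map)
      shift[q, ] <- i * h * cov_m / (2 * sigma[q])
    }
  }
  pairs$score <- usefulness_criterion(gebv[pairs$a_row], gebv[pairs$b_row],
                                      sigma, i = i, h = h)
  sel <- anneal_cross_plan(pairs, hap_panel, n_crosses, He_target,
                           cross_weight = n_progeny, shift = shift,
                           cfg = cfg, seed = seed)
  plan <- finalize_plan(sel, pairs, candidates, n_progeny, component, generation)
  attr(plan, "sigma") <- sigma[as.integer(sel)]
  plan
}

# cov(dosage_m, GEBV) among DH of a cross, for every panel marker:
# cov_m = s_m * v_m with v_m = sum_l beta_l s_l (1 - 2 r_lm); O(m) per
# chromosome via cumulative products (same algebra as progeny_sd_dh).
dosage_gebv_cov <- function(hap_j, hap_k, effects, panel_map) {
  s <- hap_j - hap_k
  d_all <- effects * s
  v <- numeric(length(s))
  for (idx in map_chrom_index(panel_map)) {
    d <- d_all[idx]
    if (!any(d != 0)) next
    rho <- exp(-2 * diff(panel_map$pos[idx]) / 100)
    C <- cumprod(c(1, rho))
    left <- C * cumsum(d / C)                       # sum_{l<=m} d_l R_lm
    right <- (rev(cumsum(rev(d * C))) - d * C) / C  # sum_{l>m}  d_l R_lm
    v[idx] <- left + right
  }
  s * v
}

resolve_scores <- function(scores, pop) {
  if (!is.null(names(scores))) {
    out <- scores[as.character(pop$id)]
    if (anyNA(out)) stop("scores missing for some candidate ids")
    unname(out)
  } else {
    stopifnot(length(scores) == n_ind(pop))
    scores
  }
}

finalize_plan <- function(sel, pairs, candidates, n_progeny, component,
                          generation) {
  rows <- as.integer(sel)
  plan <- cross_plan(candidates$id[pairs$a_row[rows]],
                     candidates$id[pairs$b_row[rows]],
                     n_progeny, component, generation)
  attr(plan, "expected_he") <- attr(sel, "he")
  attr(plan, "feasible") <- attr(sel, "feasible")
  attr(plan, "mean_score") <- attr(sel, "score")
  attr(plan, "pair_score") <- pairs$score[rows]
  plan
}

#' Bridging cross selection conditional on the elite cross list
#'
#' Selects donor x elite (and, in multiple-stage mode, DE x elite) crosses
#' after the elite plan of the same generation is fixed, so that the
#' bridging component complements it: the diversity constraint is evaluated
#' on the union of the fixed elite crosses and the bridging crosses, and the
#' objective is the mean cross score of the bridging crosses.
#'
#' Scoring: with GS-based donor evaluation (`criterion = "uc"`) each
#' candidate cross is scored by its usefulness criterion with the
#' within-cross frequency shift of [ucpc_select()]; with phenotype-based
#' donor evaluation (`criterion = "midparent"`) the score is the plain mean
#' of the donor's centred, shrunk phenotype and the elite parent's GEBV, and
#' selection is a classical OCS (no shift).
#'
#' @param donor_pool `gsb_pop` of donor-side candidates (gene-bank donors
#'   and/or DE progeny in multiple-stage mode).
#' @param donor_scores per-donor values: GEBVs (`"uc"`) or centred shrunk
#'   phenotypes (`"midparent"`), named by id or in pool order.
#' @param elite_presel `gsb_pop` of preselected elite candidates.
#' @param elite_gebv per-elite GEBVs.
#' @param elite_plan the fixed elite [cross_plan()] of the generation.
#' @param elite_pool `gsb_pop` containing the elite plan's parents.
#' @param n_crosses,n_progeny bridging crosses and DH per cross.
#' @param He_target diversity floor on the union plan.
#' @param neutral_indices neutral marker column indices.
#' @param criterion `"uc"` or `"midparent"`.
#' @param effects,panel_map marker effects and panel map (required for
#'   `"uc"`).
#' @param i,h UC constants.
#' @param cfg,seed,generation as in [ocs_select()].
#' @return a [cross_plan()] of bridging crosses with attributes
#'   `expected_he` (union-plan He) and `feasible`.
#' @export
conditional_bridging_select <- function(donor_pool, donor_scores,
                                        elite_presel, elite_gebv,
                                        elite_plan, elite_pool,
                                        n_crosses, n_progeny,
                                        He_target, neutral_indices,
                                        criterion = c("uc", "midparent"),
                                        effects = NULL, panel_map = NULL,
                                        i = 2.06, h = 1,
                                        cfg = optimizer_config(), seed = NULL,
                                        generation = NA_integer_) {
  criterion <- match.arg(criterion)
  if (n_ind(donor_pool) == 0) stop("empty donor pool")
  donor_scores <- resolve_scores(donor_scores, donor_pool)
  elite_gebv <- resolve_scores(elite_gebv, elite_presel)

  # fixed contribution of the elite plan to next-generation frequencies
  ra <- match(elite_plan$parent_a, elite_pool$id)
  rb <- match(elite_plan$parent_b, elite_pool$id)
  if (anyNA(ra) || anyNA(rb)) stop("elite plan parent absent from elite pool")
  pf <- (elite_pool$haplo[ra, neutral_indices, drop = FALSE] +
           elite_pool$haplo[rb, neutral_indices, drop = FALSE]) / 2
  fixed <- list(sum = colSums(pf * elite_plan$n_progeny),
                weight = sum(elite_plan$n_progeny))

  nd <- n_ind(donor_pool); ne <- n_ind(elite_presel)
  pairs <- data.frame(a_row = rep(seq_len(nd), each = ne),
                      b_row = nd + rep(seq_len(ne), times = nd))
  pool <- pop_bind(
    new_population(seq_len(nd), donor_pool$haplo,
                   component = donor_pool$component,
                   generation = donor_pool$generation),
    new_population(nd + seq_len(ne), elite_presel$haplo,
                   component = "elite", generation = elite_presel$generation)
  )
  hap_panel <- pool$haplo[, neutral_indices, drop = FALSE]

  shift <- NULL
  if (criterion == "uc") {
    if (is.null(effects) || is.null(panel_map)) {
      stop("criterion 'uc' needs marker effects and the panel map")
    }
    k <- nrow(pairs)
    sigma <- numeric(k)
    shift <- matrix(0, k, length(neutral_indices))
    for (q in seq_len(k)) {
      hj <- hap_panel[pairs$a_row[q], ]
      hk <- hap_panel[pairs$b_row[q], ]
      sigma[q] <- progeny_sd_dh(hj, hk, effects, panel_map)
      if (sigma[q] > 0) {
        shift[q, ] <- i * h *
          dosage_gebv_cov(hj, hk, effects, panel_map) / (2 * sigma[q])
      }
    }
    pairs$score <- usefulness_criterion(donor_scores[pairs$a_row],
                                        elite_gebv[pairs$b_row - nd],
                                        sigma, i = i, h = h)
  } else {
    pairs$score <- (donor_scores[pairs$a_row] +
                      elite_gebv[pairs$b_row - nd]) / 2
  }

  sel <- anneal_cross_plan(pairs, hap_panel, n_crosses, He_target,
                           cross_weight = n_progeny, fixed = fixed,
                           shift = shift, cfg = cfg, seed = seed)
  rows <- as.integer(sel)
  plan <- cross_plan(donor_pool$id[pairs$a_row[rows]],
                     elite_presel$id[pairs$b_row[rows] - nd],
                     n_progeny, "bridging", generation)
  attr(plan, "expected_he") <- attr(sel, "he")
  attr(plan, "feasible") <- attr(sel, "feasible")
  attr(plan, "mean_score") <- attr(sel, "score")
  plan
}

#' H criterion: windowed haplotype complementation score of a donor
#'
#' The genome is tiled into candidate windows (default 20 cM long, on a
#' 10 cM step grid); a haplotype's window value is the sum of `effects x
#' dosage` over the window's markers. A non-overlapping cover is assembled
#' greedily left to right (first admissible window on the grid), and
#' `H = sum over the cover of max(donor window value, best elite window
#' value)`: the score of the best DH line conceivably assembled from the
#' donor and the elite pool after several generations of intercrossing and
#' selection. H is therefore never below the best elite segment sum.
#'
#' @param donors `gsb_pop` (or 0/1 haplotype matrix) of candidate donors,
#'   columns = GS panel markers.
#' @param elites `gsb_pop` (or haplotype matrix) of elite reference lines
#'   over the same panel.
#' @param effects marker effects over the panel.
#' @param panel_map `gsb_map` of the panel markers.
#' @param window_length window length in cM (clipped at chromosome ends).
#' @param step grid step in cM.
#' @return numeric vector, one H value per donor.
#' @export
h_criterion <- function(donors, elites, effects, panel_map,
                        window_length = 20, step = 10) {
  dh <- if (inherits(donors, "gsb_pop")) donors$haplo else as.matrix(donors)
  eh <- if (inherits(elites, "gsb_pop")) elites$haplo else as.matrix(elites)
  stopifnot(ncol(dh) == length(effects), ncol(eh) == length(effects),
            window_length > 0, step > 0)
  wins <- h_windows(panel_map, window_length, step)
  H <- numeric(nrow(dh))
  for (w in wins) {
    ev <- 2 * (eh[, w, drop = FALSE] %*% effects[w])   # dosage scale
    best_elite <- max(ev)
    dv <- as.vector(2 * (dh[, w, drop = FALSE] %*% effects[w]))
    H <- H + pmax(dv, best_elite)
  }
  H
}

# Non-overlapping greedy cover of the genome by windows on a (step, length)
# grid; returns a list of marker-index vectors. Windows longer than a
# chromosome are clipped to it.
h_windows <- function(panel_map, window_length, step) {
  out <- list()
  for (idx in map_chrom_index(panel_map)) {
    pos <- panel_map$pos[idx]
    L <- max(pos)
    starts <- seq(0, max(0, L - step), by = step)
    cur_end <- -Inf
    for (s in starts) {
      if (s < cur_end) next
      e <- min(s + window_length, L + 1e-9)
      w <- idx[pos >= s & pos < e]
      if (!length(w)) next
      out[[length(out) + 1L]] <- w
      cur_end <- e
    }
  }
  out
}

#' Write a scored cross plan to CSV
#'
#' One row per cross: generation, parents, component, per-cross score and
#' the plan-level expected He.
#'
#' @param plan a [cross_plan()].
#' @param file CSV path.
#' @return `file` invisibly.
#' @export
write_cross_plan <- function(plan, file) {
  df <- as.data.frame(plan)
  df$generation <- attr(plan, "generation")
  sc <- attr(plan, "pair_score")
  df$score <- if (is.null(sc)) NA_real_ else sc
  df$expected_he <- attr(plan, "expected_he") %||% NA_real_
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
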