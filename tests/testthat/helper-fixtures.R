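# Shared fixtures: everything is generated in code at test time.

tiny_map <- function(n_chrom = 2, len = 100, m = 200) {
  generate_genetic_map(n_chrom, len, m)
}

tiny_panel <- function(group_sizes = c(20, 20, 40), m = 200, n_chrom = 2,
                       len = 100, seed = 42, divergence = 0.15) {
  spec <- founder_panel_spec(group_sizes = group_sizes, n_chromosomes = n_chrom,
                             chrom_length = len, n_markers = m,
                             divergence = divergence, seed = seed)
  map <- generate_genetic_map(n_chrom, len, m)
  list(spec = spec, map = map, panel = generate_founder_panel(spec, map))
}

tiny_arch <- function(map, n_qtl = 40, n_neutral = 80, seed = 7) {
  sample_trait_architecture(map, n_qtl = n_qtl, n_neutral = n_neutral,
                            seed = seed)
}

# quarter-scale scheme configuration used across engine tests
scaled_cfg <- function(strategy = "GEBV", n_generations = 4, ...) {
  scheme_config(strategy = strategy, scale = 4, n_generations = n_generations,
                optimizer = optimizer_config(iterations = 1500),
                n_qtl = 150, n_neutral = 300, ...)
}

# one cached scaled world (panel/map/arch) shared by engine and metric tests
.world_cache <- new.env(parent = emptyenv())
scaled_world <- function() {
  if (is.null(.world_cache$world)) {
    spec <- founder_panel_spec(group_sizes = c(30, 30, 60), n_markers = 600,
                               n_chromosomes = 5, chrom_length = 120,
                               seed = 3)
    map <- generate_genetic_map(5, 120, 600)
    panel <- generate_founder_panel(spec, map)
    arch <- sample_trait_architecture(map, n_qtl = 150, n_neutral = 300,
                                      seed = 4)
    .world_cache$world <- list(spec = spec, map = map, panel = panel,
                               arch = arch)
  }
  .world_cache$world
}

# cached burn-in + short closed GEBV run reused by scheme/metrics tests
scaled_closed_history <- function() {
  if (is.null(.world_cache$closed)) {
    w <- scaled_world()
    cfg <- scaled_cfg("GEBV", n_generations = 4)
    h <- run_burn_in(w$panel, w$map, w$arch, cfg, seed = 11)
    .world_cache$closed <- run_closed_strategy(h, cfg, seed = 12)
  }
  .world_cache$closed
}

# cached short bridging run (one-stage, GS donors, joint TS)
scaled_bridging_history <- function() {
  if (is.null(.world_cache$bridging)) {
    w <- scaled_world()
    cfg <- scheme_config(strategy = "bridging", allocation = "15CE+5CB",
                         donor_selection = "gs", training = "joint",
                         trajectory = "constant", scale = 4,
                         n_generations = 6,
                         optimizer = optimizer_config(iterations = 1200),
                         n_qtl = 150, n_neutral = 300)
    h <- run_burn_in(w$panel, w$map, w$arch, cfg, seed = 11)
    .world_cache$bridging <- run_bridging_strategy(h, cfg = cfg, seed = 13)
  }
  .world_cache$bridging
}

# ---- independent oracles ---------------------------------------------------

# Exact DH-progeny distribution of a cross by exhaustive enumeration of
# parental-origin patterns (Markov chain over adjacent recombination
# fractions). Returns classes (origin patterns), probabilities and the
# genetic value of each class under `effects` (dosage scale).
enumerate_dh <- function(hap_j, hap_k, effects, panel_map) {
  chrom_idx <- map_chrom_index(panel_map)
  # enumerate per chromosome, then combine independently
  per_chrom <- lapply(chrom_idx, function(idx) {
    k <- length(idx)
    pats <- as.matrix(expand.grid(rep(list(0:1), k)))
    r <- 0.5 * (1 - exp(-2 * diff(panel_map$pos[idx]) / 100))  # Haldane
    prob <- apply(pats, 1, function(g) {
      p <- 0.5
      if (k > 1) {
        sw <- abs(diff(g))
        p <- p * prod(ifelse(sw == 1, r, 1 - r))
      }
      p
    })
    val <- apply(pats, 1, function(g) {
      a <- 2 * (g * hap_j[idx] + (1 - g) * hap_k[idx])
      sum(effects[idx] * a)
    })
    freq1 <- apply(pats, 1, function(g) g * hap_j[idx] + (1 - g) * hap_k[idx])
    list(prob = prob, val = val,
         freq = if (is.matrix(freq1)) t(freq1) else matrix(freq1, ncol = k))
  })
  # cross-chromosome combination (independent assortment)
  prob <- Reduce(function(p1, p2) as.vector(outer(p1, p2)),
                 lapply(per_chrom, `[[`, "prob"))
  val <- Reduce(function(v1, v2) as.vector(outer(v1, v2, `+`)),
                lapply(per_chrom, `[[`, "val"))
  list(prob = prob, val = val, per_chrom = per_chrom)
}

# exact DH-progeny variance of the genetic value
enumerate_dh_variance <- function(hap_j, hap_k, effects, panel_map) {
  e <- enumerate_dh(hap_j, hap_k, effects, panel_map)
  mu <- sum(e$prob * e$val)
  sum(e$prob * (e$val - mu)^2)
}

# brute-force optimal cross plan: all size-n sets of distinct pairs
brute_force_plan <- function(pool, pair_score, He_target, n_crosses,
                             neutral_indices, n_progeny = 10,
                             shift = NULL, fixed = NULL) {
  pairs <- gsbridge:::all_pairs(n_ind(pool))
  combos <- utils::combn(nrow(pairs), n_crosses)
  hap <- pool$haplo[, neutral_indices, drop = FALSE]
  pf <- (hap[pairs$a_row, , drop = FALSE] + hap[pairs$b_row, , drop = FALSE]) / 2
  if (!is.null(shift)) pf <- pmin(pmax(pf + shift, 0), 1)
  fixed_sum <- if (is.null(fixed)) 0 else fixed$sum
  fixed_w <- if (is.null(fixed)) 0 else fixed$weight
  best_score <- -Inf; best <- NULL; best_he <- -Inf; any_feasible <- FALSE
  max_he <- -Inf
  for (ci in seq_len(ncol(combos))) {
    rows <- combos[, ci]
    p <- (fixed_sum + colSums(pf[rows, , drop = FALSE]) * n_progeny) /
      (fixed_w + n_crosses * n_progeny)
    he <- mean(2 * p * (1 - p))
    sc <- mean(pair_score[rows])
    max_he <- max(max_he, he)
    if (he >= He_target) {
      any_feasible <- TRUE
      if (sc > best_score) { best_score <- sc; best <- rows; best_he <- he }
    }
  }
  list(score = best_score, rows = best, he = best_he,
       any_feasible = any_feasible, max_he = max_he)
}
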