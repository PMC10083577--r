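test_that("progeny SD closed form handles degenerate and two-marker cases exactly", {
  pm <- new_genetic_map(c(1, 1), c(0, 0))
  b <- c(0.4, -0.25)

  # identical parents: nothing segregates
  expect_equal(progeny_sd_dh(c(1L, 0L), c(1L, 0L), b, pm), 0)

  # one segregating marker with effect b: sigma = |b|
  pm1 <- new_genetic_map(1, 0)
  expect_equal(progeny_sd_dh(1L, 0L, 0.4, pm1), 0.4)
  expect_equal(progeny_sd_dh(0L, 1L, -0.4, pm1), 0.4)

  # fully linked (0 cM) pair: coupling |b1 + b2|, repulsion |b1 - b2|
  expect_equal(progeny_sd_dh(c(1L, 1L), c(0L, 0L), c(0.4, 0.25), pm),
               0.65, tolerance = 1e-12)
  expect_equal(progeny_sd_dh(c(1L, 0L), c(0L, 1L), c(0.4, 0.25), pm),
               0.15, tolerance = 1e-12)

  expect_error(progeny_sd_dh(c(2L, 0L), c(0L, 1L), b, pm), "homozygous")
})

test_that("progeny SD equals the exhaustive DH enumeration for up to 12 segregating markers", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(2:12, 1)
    n_chrom <- sample(1:2, 1)
    chrom <- sort(sample(seq_len(n_chrom), k, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(k), chrom), function(ix) {
      sort(runif(length(ix), 0, 80))
    }))
    pm <- new_genetic_map(chrom, pos)
    hj <- rbinom(k, 1, 0.5)
    hk <- rbinom(k, 1, 0.5)
    beta <- rnorm(k, 0, 0.3)
    sigma <- progeny_sd_dh(hj, hk, beta, pm)
    exact <- enumerate_dh_variance(hj, hk, beta, pm)
    expect_equal(sigma^2, exact, tolerance = 1e-10)
  }
})

test_that("progeny SD matches the Monte-Carlo variance of simulated DH", {
  set.seed(22)
  k <- 10
  pm <- new_genetic_map(rep(1, k), sort(runif(k, 0, 100)))
  hj <- rbinom(k, 1, 0.5); hk <- 1L - hj
  beta <- rnorm(k, 0, 0.3)
  sigma2 <- progeny_sd_dh(hj, hk, beta, pm)^2
  dh <- make_dh(hj, hk, 50000, pm)
  vals <- as.vector(2 * (dh %*% beta))
  mc_var <- var(vals)
  se <- mc_var * sqrt(2 / 49999)
  expect_lt(abs(mc_var - sigma2), 3 * se + 1e-8)
})

test_that("the within-cross frequency shift matches exhaustive truncation algebra", {
  # cov(dosage_m, value) under the exact DH distribution must equal the
  # closed-form s_m * sum_l beta_l s_l (1 - 2 r_lm)
  set.seed(23)
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    pm <- new_genetic_map(rep(1, k), sort(runif(k, 0, 60)))
    hj <- rbinom(k, 1, 0.5); hk <- rbinom(k, 1, 0.5)
    beta <- rnorm(k, 0, 0.3)
    e <- enumerate_dh(hj, hk, beta, pm)
    pats <- e$per_chrom[[1]]
    cov_exact <- vapply(seq_len(k), function(m) {
      a_m <- 2 * pats$freq[, m]
      mu_a <- sum(pats$prob * a_m)
      mu_v <- sum(pats$prob * pats$val)
      sum(pats$prob * (a_m - mu_a) * (pats$val - mu_v))
    }, 0)
    cov_closed <- gsbridge:::dosage_gebv_cov(hj, hk, beta, pm)
    expect_equal(cov_closed, cov_exact, tolerance = 1e-10)
  }
})

test_that("usefulness criterion arithmetic and symmetry", {
  expect_equal(usefulness_criterion(10, 12, 0), 11)
  expect_equal(usefulness_criterion(10, 12, 1, i = 2.06, h = 1), 13.06)
  expect_equal(usefulness_criterion(3, 7, 0.5), usefulness_criterion(7, 3, 0.5))
  expect_error(usefulness_criterion(1, 2, -0.1), "sigma")
  # UC never falls below the midparent mean
  set.seed(24)
  g1 <- rnorm(20); g2 <- rnorm(20); s <- abs(rnorm(20))
  expect_true(all(usefulness_criterion(g1, g2, s) >= (g1 + g2) / 2))
})

test_that("the selection intensity of the top 5% is 2.06", {
  expect_equal(round(selection_intensity(0.05), 2), 2.06)
})

test_that("Nei diversity covers fixed, balanced and mixed frequency cases", {
  m <- 4
  fixed <- new_population(1:4, matrix(1L, 4, m))
  expect_equal(nei_he(fixed, 1:m), 0)

  half <- new_population(1:4, rbind(matrix(0L, 2, m), matrix(1L, 2, m)))
  expect_equal(nei_he(half, 1:m), 0.5)

  # p = 0.1 and p = 0.5: He = (0.18 + 0.5) / 2 = 0.34
  h <- matrix(0L, 10, 2)
  h[1, 1] <- 1L
  h[1:5, 2] <- 1L
  expect_equal(nei_he(new_population(1:10, h), 1:2), 0.34)
})

test_that("expected post-plan diversity matches hand cases and realized progeny", {
  m <- 6
  map <- new_genetic_map(rep(1, m), seq(0, 100, length.out = m))
  hapA <- rep(1L, m); hapB <- rep(0L, m)
  pool <- new_population(1:3, rbind(hapA, hapB, hapA))

  # one cross of opposite homozygotes: expected p = 0.5 everywhere, He = 0.5
  plan <- cross_plan(1, 2, 10, generation = 1)
  expect_equal(expected_he_after_plan(plan, pool, 1:m), 0.5)

  # two identical-genotype parents: He of that genotype's frequencies (0)
  plan2 <- cross_plan(1, 3, 10, generation = 1)
  expect_equal(expected_he_after_plan(plan2, pool, 1:m), 0)

  # agreement with realized progeny of a real pool
  fx <- tiny_panel(group_sizes = c(10, 10), m = 40, seed = 31)
  plan3 <- cross_plan(c(1, 3, 11), c(2, 14, 20), 10000, generation = 1)
  exp_he <- expected_he_after_plan(plan3, fx$panel, 1:40)
  set.seed(32)
  prog <- execute_cross_plan(plan3, fx$panel, fx$map, 100L)
  expect_lt(abs(nei_he(prog, 1:40) - exp_he), 0.005)
})

test_that("OCS reduces to top crosses when unconstrained and matches brute force", {
  fx <- tiny_panel(group_sizes = 6, m = 60, seed = 33)
  pool <- pop_subset(fx$panel, 1:6)
  set.seed(34)
  vals <- rnorm(6)

  # unconstrained: the best plan is the top pairs by midparent score
  plan <- ocs_select(pool, vals, 1:60, He_target = 0, n_crosses = 2,
                     n_progeny = 10, seed = 35,
                     cfg = optimizer_config(iterations = 3000))
  pairs <- gsbridge:::all_pairs(6)
  sc <- (vals[pairs$a_row] + vals[pairs$b_row]) / 2
  oracle <- brute_force_plan(pool, sc, 0, 2, 1:60)
  expect_equal(attr(plan, "mean_score"), oracle$score, tolerance = 1e-12)
  expect_true(attr(plan, "feasible"))

  # constrained instances match exhaustive search over all plans
  for (seed in 1:8) {
    set.seed(seed)
    vals <- rnorm(6)
    sc <- (vals[pairs$a_row] + vals[pairs$b_row]) / 2
    he_lo <- expected_he_after_plan(
      cross_plan(pool$id[pairs$a_row[which.max(sc)]],
                 pool$id[pairs$b_row[which.max(sc)]], 10, generation = 1),
      pool, 1:60)
    target <- he_lo + 0.02
    oracle <- brute_force_plan(pool, sc, target, 2, 1:60)
    plan <- ocs_select(pool, vals, 1:60, target, 2, n_progeny = 10,
                       seed = 100 + seed,
                       cfg = optimizer_config(iterations = 4000))
    if (oracle$any_feasible) {
      expect_true(attr(plan, "feasible"))
      expect_equal(attr(plan, "mean_score"), oracle$score, tolerance = 1e-9)
      expect_gte(attr(plan, "expected_he"), target)
    } else {
      expect_false(attr(plan, "feasible"))
    }
  }
})

test_that("tightening the diversity target never improves the achieved score", {
  fx <- tiny_panel(group_sizes = 6, m = 60, seed = 36)
  pool <- pop_subset(fx$panel, 1:6)
  pairs <- gsbridge:::all_pairs(6)
  set.seed(37)
  for (inst in 1:20) {
    vals <- rnorm(6)
    sc <- (vals[pairs$a_row] + vals[pairs$b_row]) / 2
    targets <- seq(0, 0.5, length.out = 5)
    scores <- vapply(targets, function(tg) {
      o <- brute_force_plan(pool, sc, tg, 2, 1:60)
      if (o$any_feasible) o$score else NA_real_
    }, 0)
    ok <- !is.na(scores)
    expect_true(all(diff(scores[ok]) <= 1e-12))
  }
})

test_that("UCPC selection collapses to OCS when nothing segregates and matches brute force", {
  m <- 30
  pm <- new_genetic_map(rep(1, m), seq(0, 80, length.out = m))
  set.seed(38)
  base <- rbinom(m, 1, 0.5)
  pool_fixed <- new_population(1:4, matrix(rep(base, each = 4), 4))
  gebv <- c(3, 1, 2, 0.5)
  beta <- rnorm(m, 0, 0.2)
  # all sigma are zero: UC = midparent, same optimum as plain OCS
  p_ucpc <- ucpc_select(pool_fixed, gebv, beta, pm, 1:m, He_target = 0,
                        n_crosses = 2, n_progeny = 10, seed = 39,
                        cfg = optimizer_config(iterations = 2000))
  p_ocs <- ocs_select(pool_fixed, gebv, 1:m, He_target = 0, n_crosses = 2,
                      n_progeny = 10, seed = 40,
                      cfg = optimizer_config(iterations = 2000))
  key <- function(p) paste(sort(paste(pmin(p$parent_a, p$parent_b),
                                      pmax(p$parent_a, p$parent_b))),
                           collapse = ";")
  expect_identical(key(p_ucpc), key(p_ocs))

  # segregating instance vs exhaustive oracle on the same objective/constraint
  fx <- tiny_panel(group_sizes = 5, m = m, seed = 41)
  pool <- pop_subset(fx$panel, 1:5)
  pm2 <- subset_map(fx$map, 1:m)
  pairs <- gsbridge:::all_pairs(5)
  for (seed in 1:5) {
    set.seed(seed)
    gebv <- rnorm(5)
    beta <- rnorm(m, 0, 0.15)
    k <- nrow(pairs)
    sigma <- numeric(k); shift <- matrix(0, k, m)
    for (q in seq_len(k)) {
      hj <- pool$haplo[pairs$a_row[q], ]; hk <- pool$haplo[pairs$b_row[q], ]
      sigma[q] <- progeny_sd_dh(hj, hk, beta, pm2)
      if (sigma[q] > 0) {
        shift[q, ] <- 2.06 * gsbridge:::dosage_gebv_cov(hj, hk, beta, pm2) /
          (2 * sigma[q])
      }
    }
    uc <- usefulness_criterion(gebv[pairs$a_row], gebv[pairs$b_row], sigma)
    target <- 0.3
    oracle <- brute_force_plan(pool, uc, target, 2, 1:m, n_progeny = 10,
                               shift = shift)
    plan <- ucpc_select(pool, gebv, beta, pm2, 1:m, target, 2,
                        n_progeny = 10, seed = 200 + seed,
                        cfg = optimizer_config(iterations = 4000))
    if (oracle$any_feasible) {
      expect_true(attr(plan, "feasible"))
      expect_equal(attr(plan, "mean_score"), oracle$score, tolerance = 1e-9)
      expect_gte(attr(plan, "expected_he"), target)
    } else {
      expect_false(attr(plan, "feasible"))
    }
  }
})

test_that("conditional bridging complements the fixed elite plan", {
  m <- 40
  fx <- tiny_panel(group_sizes = c(8, 8), m = m, seed = 43)
  pm <- subset_map(fx$map, 1:m)
  elite <- pop_subset(fx$panel, 9:14)
  elite_gebv <- seq(3, 0.5, length.out = 6)
  elite_plan <- cross_plan(elite$id[1], elite$id[2], 10, "elite", 5)

  # donor 1 duplicates an elite genotype; donor 2 is frequency-divergent.
  # at equal score the divergent donor must win under a binding constraint.
  dup <- elite$haplo[3, ]
  divg <- 1L - dup
  donors <- new_population(101:102, rbind(dup, divg), component = "donor")
  union_he_for <- function(which_donor) {
    pool <- gsbridge:::dedup_bind(donors, elite)
    plan <- cross_plan(100 + which_donor, elite$id[3], 10, "bridging", 5)
    both <- rbind(as.data.frame(elite_plan), as.data.frame(plan))
    class(both) <- c("gsb_plan", "data.frame")
    expected_he_after_plan(both, pool, 1:m)
  }
  target <- (union_he_for(1) + union_he_for(2)) / 2  # separates the two
  plan <- conditional_bridging_select(
    donors, donor_scores = c(1, 1), elite, elite_gebv,
    elite_plan, elite, n_crosses = 1, n_progeny = 10,
    He_target = target, neutral_indices = 1:m, criterion = "midparent",
    seed = 44, cfg = optimizer_config(iterations = 1500)
  )
  expect_equal(plan$parent_a, 102L)
  expect_true(attr(plan, "feasible"))
  expect_gte(attr(plan, "expected_he"), target)

  expect_error(conditional_bridging_select(
    new_population(integer(0), matrix(0L, 0, m)), numeric(0), elite,
    elite_gebv, elite_plan, elite, 1, 10, 0, 1:m, "midparent"),
    "empty donor pool")
})

test_that("H criterion equals hand-built window sums and dominates the elite score", {
  # two disjoint 20 cM windows on one chromosome
  pm <- new_genetic_map(rep(1, 4), c(0, 10, 20, 30))
  beta <- c(0.5, 0.2, 0.3, 0.1)
  elite <- matrix(c(1L, 0L, 1L, 0L), 1)
  elite_sum <- 2 * (0.5 + 0.3)  # windows [0,20) and [20,40)

  # donor identical to the single elite: H equals the elite's segment sum
  expect_equal(h_criterion(elite, elite, beta, pm), elite_sum)

  # donor superior by delta in exactly the second window
  donor <- matrix(c(1L, 0L, 1L, 1L), 1)
  expect_equal(h_criterion(donor, elite, beta, pm), elite_sum + 2 * 0.1)

  # H is never below the best elite segment sum (pointwise max)
  set.seed(45)
  elites <- matrix(rbinom(5 * 4, 1, 0.5), 5)
  donors <- matrix(rbinom(20 * 4, 1, 0.5), 20)
  elite_sums <- vapply(seq_len(5), function(i) {
    h_criterion(elites[i, , drop = FALSE], elites, beta, pm)
  }, 0)
  H <- h_criterion(donors, elites, beta, pm)
  expect_true(all(H >= max(elite_sums) - 1e-12))

  # windows longer than the chromosome are clipped, not an error
  pm_short <- new_genetic_map(c(1, 1), c(0, 5))
  expect_equal(h_criterion(matrix(c(1L, 1L), 1), matrix(c(1L, 1L), 1),
                           c(0.2, 0.3), pm_short, window_length = 50),
               1)
})
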