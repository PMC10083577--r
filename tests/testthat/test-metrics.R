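# hand-built minimal history for arithmetic checks
fake_history <- function() {
  m <- 6
  arch <- list(qtl_indices = 1:2, qtl_effects = c(1, 1),
               neutral_indices = 3:6, effect_variance = 0.05)
  class(arch) <- "gsb_arch"
  # burn-in cohort: mean TBV = 10 (dosage 2 at both QTLs gives TBV 4)
  h20 <- matrix(0L, 4, m)
  h20[, 1] <- 1L                 # QTL 1 fixed: TBV = 2 per line
  h20[1:2, 3:6] <- 1L            # neutral markers at p = 0.5: He_ref = 0.5
  pop20 <- new_population(1:4, h20, component = "elite", generation = 20L)
  # current cohort with mean TBV = 14/5 of reference set by construction
  structure(list(
    pops = list("20" = pop20), phenos = list(),
    arch = arch, burnin_end = 20L,
    he_ref = nei_he(pop20, arch$neutral_indices),
    tbv_ref = mean(true_breeding_value(pop20, arch)),
    donors = NULL, cfg = NULL, error_variance = 1
  ), class = "gsb_history")
}

test_that("gain metrics normalize by the burn-in mean as stated", {
  h <- fake_history()
  # at the end of burn-in the deviation is zero by definition
  g <- gain_metrics(h, 20)
  expect_equal(g[["mu"]], 0)

  # burn-in mean 10, current mean 14 -> mu = 40
  m <- 6
  h$tbv_ref <- 10
  cur <- matrix(0L, 4, m)
  cur[, 1:2] <- 1L                    # TBV = 4 per line
  h$pops[["25"]] <- new_population(11:14, cur, component = "elite",
                                   generation = 25L)
  tbv <- true_breeding_value(h$pops[["25"]], h$arch)
  h$tbv_ref <- mean(tbv) / 1.4        # makes the ratio exactly 1.4
  g <- gain_metrics(h, 25)
  expect_equal(g[["mu"]], 40, tolerance = 1e-12)

  # absolute mode reports trait units
  ga <- gain_metrics(h, 25, absolute = TRUE)
  expect_equal(ga[["mu"]], mean(tbv) - h$tbv_ref)

  # mu10 is an order statistic: never below mu
  hist_real <- scaled_closed_history()
  for (t in hist_real$burnin_end + 0:4) {
    g <- gain_metrics(hist_real, t)
    expect_gte(g[["mu10"]], g[["mu"]])
  }

  h$tbv_ref <- 0
  expect_error(gain_metrics(h, 25), "absolute")
})

test_that("He percentage anchors at 100 and hits 0 under full fixation", {
  h <- fake_history()
  expect_equal(he_percent(h, 20), 100)
  m <- 6
  fixedpop <- new_population(21:24, matrix(1L, 4, m), component = "elite",
                             generation = 26L)
  h$pops[["26"]] <- fixedpop
  expect_equal(he_percent(h, 26), 0)

  h$he_ref <- 0
  expect_error(he_percent(h, 26), "zero")
})

test_that("He declines in trend over a closed GEBV program", {
  h <- scaled_closed_history()
  hp <- vapply(h$burnin_end + 0:4, function(t) he_percent(h, t), 0)
  # non-increasing in trend, allowing small sampling upticks
  expect_true(all(diff(hp) <= 2))
  expect_lt(stats::coef(stats::lm(hp ~ seq_along(hp)))[2], 0)
})

test_that("pedigree contributions follow the halving recursion and conserve mass", {
  # donor x elite -> 0.5; (DE x elite) -> 0.25
  ped <- data.frame(
    id = c(1L, 2L, 3L, 10L, 11L),
    parent1 = c(NA, NA, NA, 1L, 10L),
    parent2 = c(NA, NA, NA, 2L, 3L)
  )
  dc <- donor_contribution(ped, target_ids = 10L, donor_ids = 1L)
  expect_equal(unname(dc$per_donor), 50)
  dc2 <- donor_contribution(ped, target_ids = 11L, donor_ids = 1L)
  expect_equal(unname(dc2$per_donor), 25)
  expect_equal(dc2$nid, 1)

  expect_error(donor_contribution(data.frame(id = 5L, parent1 = 4L,
                                             parent2 = 3L), 5L, 1L),
               "missing")

  # all pedigree roots sum to 1 for every individual in a real run
  h <- scaled_bridging_history()
  all_pop <- do.call(pop_bind, c(list(h$panel), unname(h$pops)))
  ped_full <- pedigree_table(all_pop)
  last <- h$pops[[as.character(h$burnin_end + h$cfg$n_generations)]]
  roots <- h$panel$id
  M <- gsbridge:::contribution_matrix(ped_full, last$id[1:10], roots)
  expect_equal(unname(rowSums(M)), rep(1, 10), tolerance = 1e-9)
})

test_that("quintile attribution partitions the total donor contribution", {
  set.seed(51)
  per_donor <- runif(40, 0, 2)
  names(per_donor) <- 1:40
  tbv <- rnorm(40)
  q <- donor_quintile_contributions(per_donor, tbv)
  expect_equal(sum(q), sum(per_donor), tolerance = 1e-9)
  expect_length(q, 5)
})

test_that("He and weighted QTL rates agree between batch and streaming computations", {
  h <- scaled_bridging_history()
  t <- h$burnin_end + 3
  pop <- h$pops[[as.character(t)]]
  elite <- pop_subset(pop, which(pop$component == "elite"))

  # streaming He: accumulate counts marker by marker
  he_stream <- 0
  for (j in h$arch$neutral_indices) {
    p <- sum(elite$haplo[, j]) / n_ind(elite)
    he_stream <- he_stream + 2 * p * (1 - p)
  }
  he_stream <- he_stream / length(h$arch$neutral_indices)
  expect_equal(nei_he(elite, h$arch$neutral_indices), he_stream,
               tolerance = 1e-12)

  # streaming fixation classes: per-QTL loop with explicit branching
  w_plus <- w_minus <- w_seg <- 0
  for (k in seq_along(h$arch$qtl_indices)) {
    j <- h$arch$qtl_indices[k]
    eff <- h$arch$qtl_effects[k]
    p <- mean(elite$haplo[, j])
    w <- abs(eff)
    if (p == 1) {
      if (eff >= 0) w_plus <- w_plus + w else w_minus <- w_minus + w
    } else if (p == 0) {
      if (eff >= 0) w_minus <- w_minus + w else w_plus <- w_plus + w
    } else {
      w_seg <- w_seg + w
    }
  }
  tot <- w_plus + w_minus + w_seg
  got <- classify_qtl_fixation(elite, h$arch)
  expect_equal(got[["fixed_plus"]], w_plus / tot, tolerance = 1e-12)
  expect_equal(got[["fixed_minus"]], w_minus / tot, tolerance = 1e-12)
  expect_equal(got[["segregating"]], w_seg / tot, tolerance = 1e-12)
})

test_that("metrics tables and reports have the stated shape and are idempotent", {
  h <- scaled_bridging_history()
  mt <- metrics_table(h)
  expect_equal(nrow(mt), h$cfg$n_generations + 1)
  expect_equal(mt$he_percent[1], 100)
  expect_equal(mt$mu[1], 0)
  expect_true(all(abs(mt$qtl_fixed_plus + mt$qtl_fixed_minus +
                        mt$qtl_segregating - 1) < 1e-12))
  # cumulative NID never decreases
  expect_true(all(diff(mt$nid) >= 0))

  # 2 scenarios x 3 replicates x 10 generations -> 60 tidy rows
  fake <- expand.grid(replicate = 1:3, generation = 1:10)
  fake$mu <- rnorm(30); fake$mu10 <- fake$mu + 1
  dir <- withr::local_tempdir()
  paths <- write_report(list(A = fake, B = fake), dir)
  tidy <- utils::read.csv(paths[1])
  expect_equal(nrow(tidy), 60)

  # summary means equal hand-computed means of the tidy file
  summ <- utils::read.csv(paths[2])
  hand <- mean(fake$mu[fake$generation == 4])
  expect_equal(summ$mu[summ$scenario == "A" & summ$generation == 4], hand)

  # idempotent re-run
  before <- readLines(paths[1])
  write_report(list(A = fake, B = fake), dir)
  expect_identical(readLines(paths[1]), before)
})
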