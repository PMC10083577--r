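test_that("burn-in produces the configured cohort layout and parent lag", {
  h <- scaled_closed_history()
  s <- h$cfg$sizes
  # random phase then selection phase cohort sizes
  for (t in 1:3) {
    expect_equal(n_ind(h$pops[[as.character(t)]]),
                 s$burnin_random_families * s$burnin_family_size)
  }
  for (t in 4:20) {
    expect_equal(n_ind(h$pops[[as.character(t)]]),
                 s$burnin_crosses * s$burnin_family_size)
  }
  # overlapping generations: parents of generation 10 born in 5..7
  pop10 <- h$pops[["10"]]
  parent_gen <- function(h, ids) {
    vapply(ids, function(id) {
      for (g in names(h$pops)) {
        if (id %in% h$pops[[g]]$id) return(as.integer(g))
      }
      0L  # panel line
    }, 0L)
  }
  expect_true(all(parent_gen(h, pop10$parent1) %in% 5:7))
  expect_true(all(parent_gen(h, pop10$parent2) %in% 5:7))

  # T-3..T-5 lag (or panel founders) holds for every cohort
  for (t in names(h$pops)) {
    tt <- as.integer(t)
    pg <- parent_gen(h, h$pops[[t]]$parent1)
    ok <- pg == 0 | (pg >= tt - 5 & pg <= tt - 3)
    expect_true(all(ok))
  }
})

test_that("burn-in selection produces genetic gain over the founders", {
  w <- scaled_world()
  cfg <- scaled_cfg("GEBV", n_generations = 1)
  gains <- vapply(1:3, function(r) {
    h <- run_burn_in(w$panel, w$map, w$arch, cfg, seed = 100 + r)
    founders <- pop_subset(w$panel, which(attr(w$panel, "group") == 1))
    mean(true_breeding_value(h$pops[["20"]], w$arch)) -
      mean(true_breeding_value(founders, w$arch))
  }, 0)
  expect_gte(sum(gains > 0), 2)
})

test_that("burn-in rejects a founder group that is too small", {
  w <- scaled_world()
  cfg <- scheme_config(strategy = "GEBV", scale = 1, n_qtl = 150,
                       n_neutral = 300)
  small <- pop_subset(w$panel, 1:10)
  attr(small, "group") <- rep(1L, 10)
  expect_error(run_burn_in(small, w$map, w$arch, cfg), "fewer than")
})

test_that("closed strategies keep the candidate pool and resources at the configured sizes", {
  h <- scaled_closed_history()
  s <- h$cfg$sizes
  log <- do.call(rbind, h$log)
  presel <- gsbridge:::presel_k(h$cfg$presel_frac, s$closed_family_size)
  expect_true(all(log$n_candidates == 3 * s$closed_crosses * presel))
  expect_true(all(log$n_training == 3 * s$closed_crosses *
                    s$closed_family_size))
  # resource conservation in every post-burn-in generation
  for (t in (h$burnin_end + 1):(h$burnin_end + h$cfg$n_generations)) {
    expect_equal(n_ind(h$pops[[as.character(t)]]),
                 s$closed_crosses * s$closed_family_size)
  }
})

test_that("phenotypic selection with zero error variance ranks on TBV", {
  w <- scaled_world()
  cfg <- scaled_cfg("PHENO", n_generations = 2, h2 = 1)
  h <- run_burn_in(w$panel, w$map, w$arch, cfg, seed = 21)
  expect_equal(h$error_variance, 0)
  h <- run_closed_strategy(h, cfg, seed = 22)
  for (t in names(h$pops)) {
    pop <- h$pops[[t]]
    expect_equal(unname(h$phenos[[t]]), true_breeding_value(pop, h$arch))
  }
})

test_that("bridging programs follow the allocation layout with a static donor collection", {
  h <- scaled_bridging_history()
  s <- h$cfg$sizes
  for (t in (h$burnin_end + 1):(h$burnin_end + h$cfg$n_generations)) {
    pop <- h$pops[[as.character(t)]]
    expect_equal(sum(pop$component == "elite"), s$ce_crosses * s$ce_size)
    expect_equal(sum(pop$component == "bridging"), s$cb_crosses * s$cb_size)
    # bridging parents: donor or DE on one side, elite candidates other side
    bridge <- pop_subset(pop, which(pop$component == "bridging"))
    expect_true(all(bridge$parent1 %in% c(h$donors$id,
                                          unlist(lapply(h$pops, `[[`, "id")))))
  }
  # the donor collection is static: ids and genotypes never change
  expect_identical(h$donors$haplo,
                   pop_subset(h$panel,
                              which(attr(h$panel, "group") != 1))$haplo)
  # joint model taken up once three DE cohorts exist
  log <- do.call(rbind, h$log)
  expect_equal(log$model_used[1:3], rep("elite-specific", 3))
  expect_true(any(log$model_used == "joint"))
})

test_that("the H-criterion screen passes the configured number of donors to OCS", {
  w <- scaled_world()
  cfg <- scheme_config(strategy = "bridging", allocation = "15CE+5CB",
                       donor_selection = "h_then_phenotype",
                       training = "specific", trajectory = "constant",
                       scale = 4, n_generations = 1, n_donor_screen = 7,
                       optimizer = optimizer_config(iterations = 600),
                       n_qtl = 150, n_neutral = 300)
  h <- run_burn_in(w$panel, w$map, w$arch, cfg, seed = 31)
  h <- run_bridging_strategy(h, cfg = cfg, seed = 32)
  t <- h$burnin_end + 1
  bridge <- pop_subset(h$pops[[as.character(t)]],
                       which(h$pops[[as.character(t)]]$component == "bridging"))
  # all bridging donors must come from a screened subset of <= 7 donors
  expect_lte(length(unique(bridge$parent1)), 7)
  expect_true(all(bridge$parent1 %in% h$donors$id))
})

test_that("replicated runs are deterministic, independent and correctly stacked", {
  w <- scaled_world()
  cfg <- scheme_config(strategy = "GEBV", scale = 4, n_generations = 2,
                       n_replicates = 2, base_seed = 7,
                       optimizer = optimizer_config(iterations = 500),
                       n_qtl = 100, n_neutral = 200)
  r1 <- run_replicates(cfg, panel = w$panel, map = w$map)
  r2 <- run_replicates(cfg, panel = w$panel, map = w$map)
  expect_identical(r1[names(r1) != "replicate"], r2[names(r2) != "replicate"])
  expect_equal(sort(unique(r1$replicate)), 1:2)
  expect_equal(nrow(r1), 2 * (cfg$n_generations + 1))
  # architectures are resampled per replicate
  hists <- attr(r1, "histories")
  expect_false(identical(hists[[1]]$arch$qtl_indices,
                         hists[[2]]$arch$qtl_indices))
})

test_that("scenario configuration round-trips through YAML and rejects junk", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "strategy: bridging",
    "allocation: 15CE+10CB",
    "donor_selection: phenotype",
    "training: joint",
    "trajectory: constant",
    "n_generations: 12",
    "scale: 4"
  ), f)
  cfg <- read_scheme_config(f)
  expect_equal(cfg$strategy, "bridging")
  expect_equal(cfg$sizes$cb_crosses, 2L)  # 10 / 4, rounded half to even
  expect_equal(cfg$sizes$cb_size, 10L)    # 40 / 4
  writeLines(c("strategy: GEBV", "bogus_field: 1"), f)
  expect_error(read_scheme_config(f), "bogus_field")
})

test_that("full-scale allocations conserve 1,600 DH per generation", {
  for (al in c("15CE+5CB", "15CE+10CB", "10CE+10CB")) {
    cfg <- scheme_config(strategy = "bridging", allocation = al, scale = 1)
    s <- cfg$sizes
    expect_equal(s$ce_crosses * s$ce_size + s$cb_crosses * s$cb_size, 1600)
  }
  cfg <- scheme_config(strategy = "GEBV", scale = 1)
  expect_equal(cfg$sizes$closed_crosses * cfg$sizes$closed_family_size, 1600)
})
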