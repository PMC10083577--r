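#' Configure a breeding-program scenario
#'
#' Collects every knob of a simulated program: the burn-in layout, the
#' post-burn-in strategy, resource allocation between elite and bridging
#' components, GS model calibration, donor selection, the diversity
#' trajectory and replicate management. All counts refer to full scale
#' (1,600 DH per generation); `scale` divides both family counts and family
#' sizes (so `scale = 4` runs quarter-scale programs, e.g. 5 elite crosses of
#' 20 DH) while keeping every selection rule intact.
#'
#' Allocations (full scale): closed programs use 20 elite crosses x 80 DH;
#' `"15CE+5CB"` = 15 elite x 80 + 5 bridging x 80; `"15CE+10CB"` = 15 x 80 +
#' 10 x 40; `"10CE+10CB"` = 10 x 80 + 10 x 80. Every allocation totals
#' 1,600 DH per generation.
#'
#' @param strategy `"PHENO"`, `"GEBV"`, `"UC"`, `"OCS"`, `"UCPC"` (closed
#'   programs) or `"bridging"`.
#' @param allocation `"15CE+5CB"`, `"15CE+10CB"` or `"10CE+10CB"`
#'   (bridging only).
#' @param bridging_stage `"one_stage"`, `"multiple_stage"` or
#'   `"multiple_stage_presel_DE"`.
#' @param donor_selection `"gs"`, `"phenotype"` or `"h_then_phenotype"`.
#' @param training `"specific"` or `"joint"` GS calibration.
#' @param trajectory `"constant"` or `"linear_loss"` elite-He target.
#' @param linear_loss_rate per-generation fractional He decline of the
#'   linear-loss trajectory (default 0.005 of the burn-in He).
#' @param n_generations post-burn-in generations (default 60).
#' @param n_replicates replicates (default 10).
#' @param base_seed replicate r uses seed `base_seed + r`.
#' @param h2 founder heritability anchoring the error variance.
#' @param h2_model fixed model heritability of the direct GBLUP fit.
#' @param i,h_acc usefulness-criterion selection intensity and accuracy.
#' @param presel_frac within-family preselected fraction (default 0.05).
#' @param n_donor_screen donors retained by the H-criterion screen.
#' @param donor_pool `"non_founder"` (panel minus the founder group) or
#'   `"all"` panel lines.
#' @param scale scale-down divisor applied to family counts and sizes.
#' @param optimizer an [optimizer_config()] for OCS/UCPC searches.
#' @param founder_spec a [founder_panel_spec()] used by [run_replicates()].
#' @param n_qtl,n_neutral,qtl_min_dist,effect_var trait-architecture
#'   parameters resampled per replicate (defaults: 1000 QTLs at least 0.2 cM
#'   apart, effect variance 0.05, 2000 neutral markers).
#' @return a list of class `gsb_scheme_cfg` with a `sizes` element holding
#'   the scaled per-generation layout.
#' @export
scheme_config <- function(strategy = c("UCPC", "PHENO", "GEBV", "UC", "OCS",
                                       "bridging"),
                          allocation = c("15CE+5CB", "15CE+10CB", "10CE+10CB"),
                          bridging_stage = c("one_stage", "multiple_stage",
                                             "multiple_stage_presel_DE"),
                          donor_selection = c("gs", "phenotype",
                                              "h_then_phenotype"),
                          training = c("joint", "specific"),
                          trajectory = c("linear_loss", "constant"),
                          linear_loss_rate = 0.005,
                          n_generations = 60, n_replicates = 10,
                          base_seed = 1L, h2 = 0.7, h2_model = 0.7,
                          i = 2.06, h_acc = 1, presel_frac = 0.05,
                          n_donor_screen = 20,
                          donor_pool = c("non_founder", "all"),
                          scale = 1, optimizer = optimizer_config(),
                          founder_spec = NULL,
                          n_qtl = 1000, n_neutral = 2000,
                          qtl_min_dist = 0.2, effect_var = 0.05) {
  strategy <- match.arg(strategy)
  allocation <- match.arg(allocation)
  bridging_stage <- match.arg(bridging_stage)
  donor_selection <- match.arg(donor_selection)
  training <- match.arg(training)
  trajectory <- match.arg(trajectory)
  donor_pool <- match.arg(donor_pool)
  stopifnot(scale >= 1)

  sc <- function(x) max(1L, as.integer(round(x / scale)))
  alloc <- switch(allocation,
                  "15CE+5CB"  = c(ce = 15, ce_size = 80, cb = 5,  cb_size = 80),
                  "15CE+10CB" = c(ce = 15, ce_size = 80, cb = 10, cb_size = 40),
                  "10CE+10CB" = c(ce = 10, ce_size = 80, cb = 10, cb_size = 80))
  sizes <- list(
    burnin_random_gens = 3L,
    burnin_gens = 20L,
    burnin_founder_parents = sc(20),
    burnin_random_families = sc(10),
    burnin_family_size = sc(80),
    burnin_parents_selected = sc(50),
    burnin_crosses = sc(20),
    closed_crosses = sc(20),
    closed_family_size = sc(80),
    ce_crosses = sc(alloc[["ce"]]), ce_size = sc(alloc[["ce_size"]]),
    cb_crosses = sc(alloc[["cb"]]), cb_size = sc(alloc[["cb_size"]])
  )
  cfg <- list(
    strategy = strategy, allocation = allocation,
    bridging_stage = bridging_stage, donor_selection = donor_selection,
    training = training, trajectory = trajectory,
    linear_loss_rate = linear_loss_rate,
    n_generations = as.integer(n_generations),
    n_replicates = as.integer(n_replicates),
    base_seed = as.integer(base_seed),
    h2 = h2, h2_model = h2_model, i = i, h_acc = h_acc,
    presel_frac = presel_frac, n_donor_screen = as.integer(n_donor_screen),
    donor_pool = donor_pool, scale = scale, optimizer = optimizer,
    founder_spec = founder_spec, sizes = sizes,
    n_qtl = as.integer(n_qtl), n_neutral = as.integer(n_neutral),
    qtl_min_dist = qtl_min_dist, effect_var = effect_var
  )
  class(cfg) <- "gsb_scheme_cfg"
  cfg
}

#' Read a scenario configuration from YAML
#'
#' The YAML fields mirror the arguments of [scheme_config()]; unknown fields
#' are rejected. A `founder_spec` block, when present, is passed to
#' [founder_panel_spec()].
#'
#' @param file YAML path.
#' @return a `gsb_scheme_cfg`.
#' @export
read_scheme_config <- function(file) {
  y <- yaml::read_yaml(file)
  if (!is.null(y$founder_spec)) {
    y$founder_spec <- do.call(founder_panel_spec, y$founder_spec)
  }
  known <- names(formals(scheme_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(scheme_config, y)
}

# per-family preselected count for a family of the given size
presel_k <- function(frac, fam_size) max(1L, as.integer(round(frac * fam_size)))

# generations contributing parents for generation t (overlapping generations,
# T-3..T-5; clipped at 1 during the first burn-in selections)
parent_window <- function(t) {
  w <- (t - 5):(t - 3)
  w[w >= 1]
}

new_history <- function(panel, map, arch, cfg, error_variance) {
  structure(list(
    pops = list(), phenos = list(),
    panel = panel, map = map, arch = arch, cfg = cfg,
    error_variance = error_variance,
    burnin_end = cfg$sizes$burnin_gens,
    he_ref = NA_real_, tbv_ref = NA_real_,
    donors = NULL, donor_shrunk = NULL,
    next_id = max(panel$id) + 1L,
    log = list()
  ), class = "gsb_history")
}

#' @export
print.gsb_history <- function(x, ...) {
  cat(sprintf("<gsb_history> %d generations (burn-in %d) | strategy %s\n",
              length(x$pops), x$burnin_end, x$cfg$strategy))
  invisible(x)
}

# register a new cohort (population + phenotypes) in the history
add_cohort <- function(history, pop, t) {
  y <- phenotype_population(pop, history$arch, history$error_variance)
  history$pops[[as.character(t)]] <- pop
  history$phenos[[as.character(t)]] <- y
  history$next_id <- history$next_id + n_ind(pop)
  history
}

# progeny of a component over the parent window of generation t
window_progeny <- function(history, t, component) {
  keys <- as.character(parent_window(t))
  keys <- keys[keys %in% names(history$pops)]
  pieces <- list(); vals <- numeric(0)
  for (k in keys) {
    pop <- history$pops[[k]]
    keep <- which(pop$component %in% component)
    if (!length(keep)) next
    pieces[[length(pieces) + 1L]] <- pop_subset(pop, keep)
    vals <- c(vals, history$phenos[[k]][keep])
  }
  if (!length(pieces)) return(NULL)
  pop <- do.call(pop_bind, pieces)
  list(pop = pop, pheno = unname(vals))
}

# indices of the top-k rows per family (parent pair), ranked by `values`
# descending, ties broken by id ascending
preselect_per_family <- function(pop, values, frac) {
  fam <- paste(pop$parent1, pop$parent2, sep = "x")
  out <- integer(0)
  for (rows in split(seq_len(n_ind(pop)), fam)) {
    k <- presel_k(frac, length(rows))
    r <- rows[order(-values[rows], pop$id[rows])]
    out <- c(out, r[seq_len(min(k, length(r)))])
  }
  sort(out)
}

# best n distinct unordered pairs by pair score (mean of parental values),
# deterministic tie-break by parent ids
top_pairs_plan <- function(candidates, values, n_crosses, n_progeny,
                           component, generation, pair_score = NULL) {
  pairs <- all_pairs(n_ind(candidates))
  score <- if (is.null(pair_score)) {
    (values[pairs$a_row] + values[pairs$b_row]) / 2
  } else pair_score
  ord <- order(-score, candidates$id[pairs$a_row], candidates$id[pairs$b_row])
  take <- ord[seq_len(n_crosses)]
  plan <- cross_plan(candidates$id[pairs$a_row[take]],
                     candidates$id[pairs$b_row[take]],
                     n_progeny, component, generation)
  attr(plan, "pair_score") <- score[take]
  attr(plan, "mean_score") <- mean(score[take])
  plan
}

# elite-He target of the configured trajectory at post-burn-in step t_post
he_target_at <- function(history, t) {
  t_post <- t - history$burnin_end
  switch(history$cfg$trajectory,
         constant = history$he_ref,
         linear_loss = history$he_ref *
           max(0, 1 - history$cfg$linear_loss_rate * t_post))
}

log_generation <- function(history, t, ...) {
  row <- data.frame(generation = t, ..., stringsAsFactors = FALSE)
  history$log[[length(history$log) + 1L]] <- row
  history
}

#' Run the burn-in phase of an elite program
#'
#' Twenty generations founding an elite program: the error variance is
#' calibrated on the founders for heritability `cfg$h2`; during the first 3
#' generations a fixed set of random founders is intermated at random; during
#' the next 17 the best progeny by phenotype from generations T-3..T-5 are
#' selected and randomly intermated. Progeny are DH lines, phenotyped at
#' creation. At the end the burn-in reference points (mean elite TBV, elite
#' neutral He) are recorded.
#'
#' @param panel founder `gsb_pop` (a `group` attribute restricts the founder
#'   pool to group 1, mirroring a subpopulation-founded program; otherwise
#'   all lines are eligible founders).
#' @param map a `gsb_map`.
#' @param arch a `gsb_arch`.
#' @param cfg a [scheme_config()].
#' @param seed optional RNG seed.
#' @return a `gsb_history` holding the burn-in cohorts.
#' @export
run_burn_in <- function(panel, map, arch, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- cfg$sizes
  grp <- attr(panel, "group")
  founder_rows <- if (is.null(grp)) seq_len(n_ind(panel)) else which(grp == 1)
  if (length(founder_rows) < s$burnin_founder_parents) {
    stop("founder group has fewer than ", s$burnin_founder_parents, " lines")
  }
  founders <- pop_subset(panel, founder_rows)
  ev <- calibrate_error_variance(true_breeding_value(founders, arch), cfg$h2)
  history <- new_history(panel, map, arch, cfg, ev)

  base_parents <- pop_subset(founders,
                             sample.int(n_ind(founders),
                                        s$burnin_founder_parents))
  for (t in seq_len(s$burnin_random_gens)) {
    plan <- random_intermating_plan(base_parents$id, s$burnin_random_families,
                                    s$burnin_family_size, t)
    prog <- execute_cross_plan(plan, base_parents, map, history$next_id, t)
    history <- add_cohort(history, prog, t)
  }
  for (t in (s$burnin_random_gens + 1):s$burnin_gens) {
    win <- window_progeny(history, t, "elite")
    ord <- order(-win$pheno, win$pop$id)
    parents <- pop_subset(win$pop,
                          ord[seq_len(min(s$burnin_parents_selected,
                                          length(ord)))])
    plan <- random_intermating_plan(parents$id, s$burnin_crosses,
                                    s$burnin_family_size, t)
    prog <- execute_cross_plan(plan, parents, map, history$next_id, t)
    history <- add_cohort(history, prog, t)
  }
  final <- history$pops[[as.character(s$burnin_gens)]]
  history$he_ref <- nei_he(final, arch$neutral_indices)
  history$tbv_ref <- mean(true_breeding_value(final, arch))
  history
}

# n distinct random pairs among parent ids (parents may repeat across pairs)
random_intermating_plan <- function(ids, n_crosses, fam_size, generation) {
  pairs <- utils::combn(sort(ids), 2)
  if (ncol(pairs) < n_crosses) stop("not enough distinct parent pairs")
  take <- sample.int(ncol(pairs), n_crosses)
  cross_plan(pairs[1, take], pairs[2, take], fam_size, "elite", generation)
}

#' Run a closed elite strategy after burn-in
#'
#' Per generation: the top within-family fraction of E progeny from
#' generations T-3..T-5 is preselected (ranked by phenotype for `"PHENO"`,
#' by GEBV from a freshly fitted elite GBLUP model otherwise); crosses are
#' then chosen by the configured rule — best midparent phenotype
#' (`"PHENO"`), best midparent GEBV (`"GEBV"`), best usefulness criterion
#' (`"UC"`), classical OCS (`"OCS"`) or UCPC-based OCS (`"UCPC"`) under the
#' configured He trajectory — and executed as DH families.
#'
#' @param history a `gsb_history` from [run_burn_in()].
#' @param cfg a [scheme_config()] (defaults to the history's).
#' @param seed optional RNG seed.
#' @return the extended `gsb_history` (with a per-generation `log`).
#' @export
run_closed_strategy <- function(history, cfg = history$cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- cfg$sizes
  arch <- history$arch
  panel_map <- subset_map(history$map, arch$neutral_indices)
  gens <- history$burnin_end + seq_len(cfg$n_generations)

  for (t in gens) {
    win <- window_progeny(history, t, "elite")
    model <- NULL
    if (cfg$strategy != "PHENO") {
      ts <- assemble_training_set(history, "elite-specific", t)
      model <- fit_gblup_direct(ts$genotypes, ts$phenotypes, cfg$h2_model,
                                ids = ts$ids)
      rank_val <- predict_gebv(model, win$pop, arch$neutral_indices)
    } else {
      rank_val <- win$pheno
    }
    keep <- preselect_per_family(win$pop, rank_val, cfg$presel_frac)
    cand <- pop_subset(win$pop, keep)
    cand_val <- rank_val[keep]
    he_target <- he_target_at(history, t)

    plan <- switch(
      cfg$strategy,
      PHENO = ,
      GEBV = top_pairs_plan(cand, cand_val, s$closed_crosses,
                            s$closed_family_size, "elite", t),
      UC = {
        pairs <- all_pairs(n_ind(cand))
        happ <- cand$haplo[, arch$neutral_indices, drop = FALSE]
        sig <- vapply(seq_len(nrow(pairs)), function(q) {
          progeny_sd_dh(happ[pairs$a_row[q], ], happ[pairs$b_row[q], ],
                        model$beta, panel_map)
        }, 0)
        uc <- usefulness_criterion(cand_val[pairs$a_row], cand_val[pairs$b_row],
                                   sig, cfg$i, cfg$h_acc)
        top_pairs_plan(cand, cand_val, s$closed_crosses, s$closed_family_size,
                       "elite", t, pair_score = uc)
      },
      OCS = ocs_select(cand, cand_val, arch$neutral_indices, he_target,
                       s$closed_crosses, s$closed_family_size,
                       cfg = cfg$optimizer, generation = t),
      UCPC = ucpc_select(cand, cand_val, model$beta, panel_map,
                         arch$neutral_indices, he_target, s$closed_crosses,
                         s$closed_family_size, i = cfg$i, h = cfg$h_acc,
                         cfg = cfg$optimizer, generation = t)
    )
    prog <- execute_cross_plan(plan, cand, history$map, history$next_id, t)
    history <- add_cohort(history, prog, t)
    history <- log_generation(
      history, t, strategy = cfg$strategy,
      n_candidates = n_ind(cand),
      n_training = if (is.null(model)) NA_integer_ else model$n_training,
      he_target = he_target,
      he_expected = attr(plan, "expected_he") %||% NA_real_,
      feasible = attr(plan, "feasible") %||% NA
    )
  }
  history
}

#' Run an open strategy with donor introductions through bridging
#'
#' Per generation after burn-in: elite and DE (bridging) progeny from
#' generations T-3..T-5 are preselected within family by GEBV; the elite
#' cross list (among preselected E and DE lines, which is how DE progeny are
#' introduced into the elite component) is chosen by UCPC-based OCS under the
#' configured He trajectory; the bridging cross list (donor x elite, plus
#' DE x elite in multiple-stage modes) is chosen conditionally on the fixed
#' elite list so that it complements it. Bridging-specific or joint GS
#' models require three post-burn-in DE cohorts to exist and are used from
#' then on; earlier generations fall back to the elite-specific model.
#' Donors form a static collection: their genotypes never change and, in
#' phenotype-based modes, each donor is phenotyped exactly once.
#'
#' @param history a `gsb_history` from [run_burn_in()].
#' @param donor_panel `gsb_pop` of donor lines (defaults to the history's
#'   panel minus the founder group, per `cfg$donor_pool`).
#' @param cfg a [scheme_config()] with `strategy = "bridging"`.
#' @param seed optional RNG seed.
#' @return the extended `gsb_history`.
#' @export
run_bridging_strategy <- function(history, donor_panel = NULL,
                                  cfg = history$cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- cfg$sizes
  arch <- history$arch
  panel_map <- subset_map(history$map, arch$neutral_indices)

  if (is.null(donor_panel)) {
    grp <- attr(history$panel, "group")
    rows <- if (cfg$donor_pool == "all" || is.null(grp)) {
      seq_len(n_ind(history$panel))
    } else which(grp != 1)
    donor_panel <- pop_subset(history$panel, rows)
  }
  donor_panel$component <- rep("donor", n_ind(donor_panel))
  history$donors <- donor_panel

  gens <- history$burnin_end + seq_len(cfg$n_generations)
  for (t in gens) {
    # --- GS models -------------------------------------------------------
    elite_model <- {
      ts <- assemble_training_set(history, "elite-specific", t)
      fit_gblup_direct(ts$genotypes, ts$phenotypes, cfg$h2_model, ids = ts$ids)
    }
    adv_mode <- if (cfg$training == "joint") "joint" else "bridging-specific"
    adv_model <- tryCatch({
      ts <- assemble_training_set(history, adv_mode, t)
      fit_gblup_direct(ts$genotypes, ts$phenotypes, cfg$h2_model,
                       ids = ts$ids, mode = adv_mode)
    }, error = function(e) NULL)
    elite_rank_model <- if (cfg$training == "joint" && !is.null(adv_model)) {
      adv_model
    } else elite_model
    bridge_model <- if (is.null(adv_model)) elite_model else adv_model

    # --- preselection ----------------------------------------------------
    ewin <- window_progeny(history, t, "elite")
    e_gebv <- predict_gebv(elite_rank_model, ewin$pop, arch$neutral_indices)
    e_keep <- preselect_per_family(ewin$pop, e_gebv, cfg$presel_frac)
    e_presel <- pop_subset(ewin$pop, e_keep)
    e_presel_gebv <- e_gebv[e_keep]

    bwin <- window_progeny(history, t, "bridging")
    de_presel <- NULL; de_presel_gebv <- numeric(0)
    de_all <- NULL; de_all_gebv <- numeric(0)
    if (!is.null(bwin)) {
      de_gebv <- predict_gebv(elite_rank_model, bwin$pop, arch$neutral_indices)
      de_keep <- preselect_per_family(bwin$pop, de_gebv, cfg$presel_frac)
      de_presel <- pop_subset(bwin$pop, de_keep)
      de_presel_gebv <- de_gebv[de_keep]
      de_all <- bwin$pop; de_all_gebv <- de_gebv
    }

    # --- elite cross list (UCPC-based OCS over E u DE candidates) --------
    elite_cand <- if (is.null(de_presel)) e_presel else {
      pop_bind(e_presel, de_presel)
    }
    elite_cand_gebv <- c(e_presel_gebv, de_presel_gebv)
    he_target <- he_target_at(history, t)
    elite_plan <- ucpc_select(elite_cand, elite_cand_gebv,
                              elite_rank_model$beta, panel_map,
                              arch$neutral_indices, he_target, s$ce_crosses,
                              s$ce_size, i = cfg$i, h = cfg$h_acc,
                              cfg = cfg$optimizer, generation = t)

    # --- bridging cross list, conditional on the elite list --------------
    donor_side <- donor_panel
    if (cfg$donor_selection == "gs") {
      donor_scores <- predict_gebv(bridge_model, donor_panel,
                                   arch$neutral_indices)
      criterion <- "uc"
    } else {
      if (is.null(history$donor_shrunk)) {
        history$donor_shrunk <- donor_shrunk_phenotypes(history, donor_panel)
      }
      donor_scores <- history$donor_shrunk
      criterion <- "midparent"
      if (cfg$donor_selection == "h_then_phenotype") {
        Hv <- h_criterion(
          donor_panel$haplo[, arch$neutral_indices, drop = FALSE],
          e_presel$haplo[, arch$neutral_indices, drop = FALSE],
          bridge_model$beta, panel_map
        )
        top <- order(-Hv, donor_panel$id)[
          seq_len(min(cfg$n_donor_screen, n_ind(donor_panel)))]
        donor_side <- pop_subset(donor_panel, top)
        donor_scores <- donor_scores[top]
      }
    }
    names(donor_scores) <- donor_side$id
    if (cfg$bridging_stage != "one_stage" && !is.null(de_all)) {
      de_side <- if (cfg$bridging_stage == "multiple_stage_presel_DE") {
        list(pop = de_presel, val = de_presel_gebv)
      } else {
        list(pop = de_all, val = de_all_gebv)
      }
      donor_side <- pop_bind(donor_side, de_side$pop)
      donor_scores <- c(donor_scores,
                        stats::setNames(de_side$val, de_side$pop$id))
    }
    bridge_plan <- conditional_bridging_select(
      donor_side, donor_scores, e_presel, e_presel_gebv,
      elite_plan, elite_cand, s$cb_crosses, s$cb_size,
      he_target, arch$neutral_indices, criterion = criterion,
      effects = bridge_model$beta, panel_map = panel_map,
      i = cfg$i, h = cfg$h_acc, cfg = cfg$optimizer, generation = t
    )

    # --- reproduction ----------------------------------------------------
    parent_pool <- dedup_bind(elite_cand, donor_side, e_presel)
    e_prog <- execute_cross_plan(elite_plan, parent_pool, history$map,
                                 history$next_id, t)
    b_prog <- execute_cross_plan(bridge_plan, parent_pool, history$map,
                                 history$next_id + n_ind(e_prog), t)
    history <- add_cohort(history, pop_bind(e_prog, b_prog), t)
    history <- log_generation(
      history, t, strategy = "bridging",
      n_candidates = n_ind(elite_cand),
      n_training = elite_rank_model$n_training,
      model_used = elite_rank_model$mode,
      he_target = he_target,
      he_expected = attr(elite_plan, "expected_he") %||% NA_real_,
      feasible = (attr(elite_plan, "feasible") %||% NA) &
        (attr(bridge_plan, "feasible") %||% NA)
    )
  }
  history
}

# bind populations, keeping the first occurrence of each id
dedup_bind <- function(...) {
  pops <- list(...)
  ids <- unlist(lapply(pops, `[[`, "id"))
  keep <- !duplicated(ids)
  out <- new_population(
    id = ids[keep],
    haplo = do.call(rbind, lapply(pops, `[[`, "haplo"))[keep, , drop = FALSE],
    parent1 = unlist(lapply(pops, `[[`, "parent1"))[keep],
    parent2 = unlist(lapply(pops, `[[`, "parent2"))[keep],
    component = unlist(lapply(pops, `[[`, "component"))[keep],
    generation = unlist(lapply(pops, `[[`, "generation"))[keep]
  )
  out
}

# single-trial donor phenotypes, centred and shrunk by observed heritability
donor_shrunk_phenotypes <- function(history, donor_panel) {
  tbv <- true_breeding_value(donor_panel, history$arch)
  y <- tbv + stats::rnorm(n_ind(donor_panel), 0,
                          sqrt(history$error_variance))
  h2_obs <- observed_heritability(tbv, history$error_variance)
  v <- shrink_donor_phenotypes(y, min(h2_obs, 1))
  names(v) <- donor_panel$id
  v
}

#' Run replicated scenario simulations
#'
#' Replicate r reseeds the RNG with `base_seed + r`, resamples the trait
#' architecture, reruns burn-in and the configured strategy, and returns the
#' stacked per-generation metrics (see [metrics_table()]). The founder panel
#' is generated once from `cfg$founder_spec` (a static panel, as for a real
#' genotyped collection) unless `panel`/`map` are supplied.
#'
#' @param cfg a [scheme_config()] with a `founder_spec` (or explicit
#'   `panel` + `map`).
#' @param panel,map optional pre-generated founder panel and map.
#' @return a data.frame of metrics with a `replicate` column; the individual
#'   histories are attached as attribute `"histories"`.
#' @export
run_replicates <- function(cfg, panel = NULL, map = NULL) {
  if (is.null(panel)) {
    if (is.null(cfg$founder_spec)) stop("cfg$founder_spec or panel required")
    map <- generate_genetic_map(cfg$founder_spec$n_chromosomes,
                                cfg$founder_spec$chrom_length,
                                cfg$founder_spec$n_markers)
    panel <- generate_founder_panel(cfg$founder_spec, map,
                                    seed = cfg$base_seed)
  }
  out <- vector("list", cfg$n_replicates)
  hists <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    set.seed(cfg$base_seed + r)
    arch <- sample_trait_architecture(map, n_qtl = cfg$n_qtl,
                                      min_dist_cM = cfg$qtl_min_dist,
                                      effect_var = cfg$effect_var,
                                      n_neutral = cfg$n_neutral)
    history <- run_burn_in(panel, map, arch, cfg)
    history <- if (cfg$strategy == "bridging") {
      run_bridging_strategy(history, cfg = cfg)
    } else {
      run_closed_strategy(history, cfg)
    }
    mt <- metrics_table(history)
    mt$replicate <- r
    out[[r]] <- mt
    hists[[r]] <- history
  }
  res <- do.call(rbind, out)
  attr(res, "histories") <- hists
  res
}
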