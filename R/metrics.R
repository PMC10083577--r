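#' Genetic-gain metrics relative to the end of burn-in
#'
#' `mu` is the mean true breeding value of the generation's elite progeny
#' and `mu10` the mean of its 10 best lines by TBV ("most performing" is
#' defined on genetic values), both reported as percentage deviations from
#' the mean elite TBV at the end of the burn-in phase:
#' `mu_t = 100 * (mean_t - mean_burnin) / |mean_burnin|`.
#'
#' @param history a `gsb_history`.
#' @param generation generation index (`>=` the burn-in end).
#' @param n_top lines entering `mu10` (default 10).
#' @param absolute return absolute gains in trait units instead of the
#'   percentage normalization (required when the burn-in mean is ~0).
#' @return named vector `c(mu, mu10)`.
#' @export
gain_metrics <- function(history, generation, n_top = 10, absolute = FALSE) {
  stopifnot(generation >= history$burnin_end)
  pop <- history$pops[[as.character(generation)]]
  elite <- pop_subset(pop, which(pop$component == "elite"))
  tbv <- true_breeding_value(elite, history$arch)
  top <- sort(tbv, decreasing = TRUE)[seq_len(min(n_top, length(tbv)))]
  ref <- history$tbv_ref
  if (absolute) {
    return(c(mu = mean(tbv) - ref, mu10 = mean(top) - ref))
  }
  if (abs(ref) < 1e-8) {
    stop("burn-in mean TBV is ~0; use absolute = TRUE")
  }
  c(mu = 100 * (mean(tbv) - ref) / abs(ref),
    mu10 = 100 * (mean(top) - ref) / abs(ref))
}

#' Elite neutral diversity as a percentage of the burn-in level
#'
#' `100 * He_t / He_burnin`, computed over the neutral marker panel on the
#' elite component only; equals 100 at the end of burn-in by construction.
#'
#' @param history a `gsb_history`.
#' @param generation generation index.
#' @return scalar percentage.
#' @export
he_percent <- function(history, generation) {
  stopifnot(generation >= history$burnin_end)
  if (!(history$he_ref > 0)) stop("burn-in He is zero")
  pop <- history$pops[[as.character(generation)]]
  elite <- pop_subset(pop, which(pop$component == "elite"))
  100 * nei_he(elite, history$arch$neutral_indices) / history$he_ref
}

#' Expected donor genome contributions from pedigree
#'
#' The expected contribution of an ancestor to an individual follows the
#' pedigree recursion: 1 for the ancestor itself, otherwise the mean of the
#' two parents' contributions (DH doubling involves a single meiosis, so the
#' expectation is unchanged). Contributions of all pedigree roots
#' (founders + donors) to any individual sum to 1.
#'
#' @param pedigree data.frame with columns `id, parent1, parent2` covering
#'   the full ancestor closure (see [pedigree_table()]); roots have `NA`
#'   parents.
#' @param target_ids individuals to evaluate (e.g. the elite lines of a
#'   generation).
#' @param donor_ids ids of the donor lines.
#' @return list with `per_donor` (named mean percentage contribution of each
#'   donor over the targets), `total` (their sum) and `nid` (donors with a
#'   positive contribution among the targets).
#' @export
donor_contribution <- function(pedigree, target_ids, donor_ids) {
  donor_ids <- as.integer(donor_ids)
  contrib <- contribution_matrix(pedigree, target_ids, donor_ids)
  per_donor <- 100 * colMeans(contrib)
  list(per_donor = per_donor, total = sum(per_donor),
       nid = sum(per_donor > 0))
}

# matrix (targets x sources) of expected pedigree contributions
contribution_matrix <- function(pedigree, target_ids, source_ids) {
  lut_p1 <- stats::setNames(pedigree$parent1, pedigree$id)
  lut_p2 <- stats::setNames(pedigree$parent2, pedigree$id)
  # ancestor closure of the targets
  needed <- unique(as.integer(target_ids))
  frontier <- needed
  while (length(frontier)) {
    miss <- setdiff(frontier, pedigree$id)
    if (length(miss)) {
      stop("pedigree is missing individual(s): ", paste(miss, collapse = ", "))
    }
    par <- c(lut_p1[as.character(frontier)], lut_p2[as.character(frontier)])
    par <- unique(as.integer(par[!is.na(par)]))
    frontier <- setdiff(par, needed)
    needed <- c(needed, frontier)
  }
  needed <- sort(needed)               # ids increase with generation
  M <- matrix(0, length(needed), length(source_ids),
              dimnames = list(needed, source_ids))
  src_row <- match(source_ids, needed)
  M[cbind(src_row[!is.na(src_row)], which(!is.na(src_row)))] <- 1
  pa <- lut_p1[as.character(needed)]
  pb <- lut_p2[as.character(needed)]
  is_source <- needed %in% source_ids
  for (r in seq_along(needed)) {
    if (is.na(pa[r]) || is_source[r]) next   # roots and sources stay as set
    ra <- match(pa[r], needed); rb <- match(pb[r], needed)
    if (is.na(ra) || is.na(rb)) stop("dangling parent id for ", needed[r])
    M[r, ] <- (M[ra, ] + M[rb, ]) / 2
  }
  M[match(as.integer(target_ids), needed), , drop = FALSE]
}

#' Donor contributions summed by true-breeding-value quintile
#'
#' Donors are binned into TBV quintiles within the donor panel (quintile 1 =
#' highest TBV); per-donor contributions are summed per bin, so the bins add
#' up to the total donor contribution.
#'
#' @param per_donor named per-donor percentage contributions
#'   (from [donor_contribution()]).
#' @param donor_tbv TBVs of the same donors (same order).
#' @return numeric vector of length 5 (quintile 1 first).
#' @export
donor_quintile_contributions <- function(per_donor, donor_tbv) {
  stopifnot(length(per_donor) == length(donor_tbv))
  q <- stats::quantile(donor_tbv, probs = seq(0, 1, 0.2))
  bin <- cut(donor_tbv, breaks = q, include.lowest = TRUE, labels = FALSE)
  bin <- 6L - bin                     # 1 = top quintile
  out <- vapply(1:5, function(b) sum(per_donor[bin == b]), 0)
  names(out) <- paste0("Q", 1:5)
  out
}

#' Per-generation metrics table of a run
#'
#' One row per post-burn-in generation (including the burn-in end as the
#' reference row): genetic gains `mu` and `mu10` (% of burn-in mean), elite
#' neutral He as % of burn-in He, the three weighted QTL fixation rates and,
#' for open programs, the number of incorporated donors (NID, donors with a
#' positive pedigree contribution to the generation's elite lines;
#' `cumulative = TRUE` counts donors that contributed at any generation up
#' to t) and the mean donor genome proportion.
#'
#' @param history a `gsb_history`.
#' @param cumulative report NID as a running count of donors ever
#'   incorporated (default) rather than a per-generation snapshot.
#' @return a data.frame, one row per generation.
#' @export
metrics_table <- function(history, cumulative = TRUE) {
  gens <- history$burnin_end:max(as.integer(names(history$pops)))
  has_donors <- !is.null(history$donors)
  ped <- NULL
  if (has_donors) {
    all_pop <- do.call(pop_bind, c(list(history$panel), unname(history$pops)))
    ped <- pedigree_table(all_pop)
  }
  ever <- character(0)
  rows <- lapply(gens, function(t) {
    g <- gain_metrics(history, t)
    qtl <- {
      pop <- history$pops[[as.character(t)]]
      elite <- pop_subset(pop, which(pop$component == "elite"))
      classify_qtl_fixation(elite, history$arch)
    }
    out <- data.frame(
      generation = t, t_post = t - history$burnin_end,
      mu = g[["mu"]], mu10 = g[["mu10"]],
      he_percent = he_percent(history, t),
      qtl_fixed_plus = qtl[["fixed_plus"]],
      qtl_fixed_minus = qtl[["fixed_minus"]],
      qtl_segregating = qtl[["segregating"]],
      nid = NA_integer_, donor_prop = NA_real_
    )
    if (has_donors) {
      pop <- history$pops[[as.character(t)]]
      elite_ids <- pop$id[pop$component == "elite"]
      dc <- donor_contribution(ped, elite_ids, history$donors$id)
      ever <<- union(ever, names(dc$per_donor)[dc$per_donor > 0])
      out$nid <- if (cumulative) length(ever) else dc$nid
      out$donor_prop <- dc$total
    }
    out
  })
  do.call(rbind, rows)
}

#' Write tidy and summary reports for a set of replicated runs
#'
#' Writes `metrics_tidy.csv` (one row per scenario x replicate x generation)
#' and `metrics_summary.csv` (mean and sd across replicates per scenario and
#' generation); optionally draws gain, diversity and QTL-fixation
#' trajectories to `plots.pdf`. Re-running on the same inputs overwrites the
#' same files with identical content.
#'
#' @param metrics_tables named list of metrics data.frames (one per
#'   scenario; each with a `replicate` column) or a single data.frame with a
#'   `scenario` column.
#' @param out_dir output directory (created if needed).
#' @param plots also draw summary figures (default FALSE).
#' @return invisible character vector of the written paths.
#' @export
write_report <- function(metrics_tables, out_dir, plots = FALSE) {
  if (is.data.frame(metrics_tables)) {
    tidy <- metrics_tables
    if (is.null(tidy$scenario)) tidy$scenario <- "scenario"
  } else {
    tidy <- do.call(rbind, lapply(names(metrics_tables), function(nm) {
      df <- metrics_tables[[nm]]
      df$scenario <- nm
      df
    }))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tidy_path <- file.path(out_dir, "metrics_tidy.csv")
  utils::write.csv(tidy, tidy_path, row.names = FALSE)

  num_cols <- c("mu", "mu10", "he_percent", "qtl_fixed_plus",
                "qtl_fixed_minus", "qtl_segregating", "nid", "donor_prop")
  num_cols <- intersect(num_cols, names(tidy))
  agg_mean <- stats::aggregate(tidy[num_cols],
                               by = tidy[c("scenario", "generation")],
                               FUN = mean)
  agg_sd <- stats::aggregate(tidy[num_cols],
                             by = tidy[c("scenario", "generation")],
                             FUN = stats::sd)
  names(agg_sd)[-(1:2)] <- paste0(names(agg_sd)[-(1:2)], "_sd")
  summary <- merge(agg_mean, agg_sd, by = c("scenario", "generation"))
  summary <- summary[order(summary$scenario, summary$generation), ]
  summary_path <- file.path(out_dir, "metrics_summary.csv")
  utils::write.csv(summary, summary_path, row.names = FALSE)

  paths <- c(tidy_path, summary_path)
  if (plots) {
    pdf_path <- file.path(out_dir, "plots.pdf")
    grDevices::pdf(pdf_path, width = 8, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    for (metric in intersect(c("mu", "mu10", "he_percent",
                               "qtl_segregating"), names(summary))) {
      scen <- unique(summary$scenario)
      cols <- grDevices::hcl.colors(max(3, length(scen)), "Dark 3")
      rng <- range(summary[[metric]], na.rm = TRUE)
      graphics::plot(NULL, xlim = range(summary$generation), ylim = rng,
                     xlab = "generation", ylab = metric, main = metric)
      for (k in seq_along(scen)) {
        d <- summary[summary$scenario == scen[k], ]
        graphics::lines(d$generation, d[[metric]], col = cols[k], lwd = 2)
      }
      graphics::legend("topleft", legend = scen, col = cols[seq_along(scen)],
                       lwd = 2, bty = "n", cex = 0.8)
    }
    paths <- c(paths, pdf_path)
  }
  invisible(paths)
}
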