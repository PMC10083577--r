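#' Cross plans
#'
#' An ordered list of biparental crosses to execute in one generation.
#'
#' @param parent_a,parent_b integer vectors of parent ids (`parent_a[i] !=
#'   parent_b[i]`).
#' @param n_progeny integer vector (or scalar) of DH per cross.
#' @param component `"elite"` or `"bridging"` per cross.
#' @param generation generation index the progeny will be born into.
#' @return an object of class `gsb_plan` (a data.frame).
#' @export
cross_plan <- function(parent_a, parent_b, n_progeny, component = "elite",
                       generation = NA_integer_) {
  k <- length(parent_a)
  stopifnot(length(parent_b) == k)
  plan <- data.frame(
    parent_a = as.integer(parent_a), parent_b = as.integer(parent_b),
    n_progeny = rep_len(as.integer(n_progeny), k),
    component = rep_len(as.character(component), k),
    stringsAsFactors = FALSE
  )
  if (k > 0 && any(plan$parent_a == plan$parent_b)) {
    stop("a cross needs two distinct parents")
  }
  if (k > 0 && any(plan$n_progeny < 1)) stop("n_progeny must be >= 1")
  attr(plan, "generation") <- as.integer(generation)
  class(plan) <- c("gsb_plan", "data.frame")
  plan
}

#' Simulate one meiotic gamete of a virtual F1
#'
#' The F1 of a cross between two fully homozygous lines carries the two
#' parental haplotypes. Meiosis draws, per chromosome, a crossover count
#' from Poisson(length in Morgans) with crossover positions i.i.d. uniform
#' along the chromosome — no interference, i.e. Haldane's mapping — and
#' alternates parental origin between crossovers starting from a fair coin.
#'
#' @param hap_a,hap_b parental haplotypes (0/1 vectors over the map's markers).
#' @param map a `gsb_map`.
#' @return integer 0/1 gamete haplotype.
#' @export
simulate_gamete <- function(hap_a, hap_b, map) {
  gam <- hap_a
  for (idx in map_chrom_index(map)) {
    pos <- map$pos[idx]
    len <- max(pos)
    n_co <- stats::rpois(1, len / 100)           # cM -> Morgans
    start <- sample.int(2L, 1L) - 1L             # 0 = from a, 1 = from b
    if (n_co == 0L) {
      origin <- rep(start, length(idx))
    } else {
      bp <- sort(stats::runif(n_co, 0, len))
      # origin flips at each breakpoint; marker in [bp_i, bp_{i+1}) interval
      origin <- (start + findInterval(pos, bp)) %% 2L
    }
    from_b <- origin == 1L
    gam[idx[from_b]] <- hap_b[idx[from_b]]
  }
  gam
}

#' Produce doubled-haploid progeny of a biparental cross
#'
#' Each DH line is a single gamete of the virtual F1 between two homozygous
#' parents, doubled: the line is again fully homozygous, one meiosis away
#' from its parents.
#'
#' @param parent_a,parent_b haplotypes of the two (homozygous) parents.
#' @param n number of DH lines.
#' @param map a `gsb_map`.
#' @return integer matrix, `n` rows of DH haplotypes.
#' @export
make_dh <- function(parent_a, parent_b, n, map) {
  out <- matrix(0L, n, length(parent_a))
  diff_idx <- which(parent_a != parent_b)
  if (!length(diff_idx)) {           # identical parents: meiosis is invisible
    out[] <- rep(parent_a, each = n)
    return(out)
  }
  for (i in seq_len(n)) out[i, ] <- simulate_gamete(parent_a, parent_b, map)
  out
}

#' Execute a cross plan
#'
#' Runs every cross of the plan against a candidate pool and concatenates the
#' DH families into one population with complete pedigree and component tags.
#'
#' @param plan a [cross_plan()].
#' @param candidate_pool a `gsb_pop` containing every parent id of the plan.
#' @param map a `gsb_map`.
#' @param first_id id assigned to the first progeny (ids are consecutive).
#' @param generation birth generation recorded for the progeny (defaults to
#'   the plan's generation attribute).
#' @return a `gsb_pop` of all progeny (possibly empty).
#' @export
execute_cross_plan <- function(plan, candidate_pool, map, first_id = 1L,
                               generation = NULL) {
  if (is.null(generation)) generation <- attr(plan, "generation")
  k <- nrow(plan)
  if (k == 0L) {
    return(new_population(integer(0),
                          matrix(0L, 0, ncol(candidate_pool$haplo)),
                          generation = integer(0)))
  }
  rows_a <- match(plan$parent_a, candidate_pool$id)
  rows_b <- match(plan$parent_b, candidate_pool$id)
  if (anyNA(rows_a) || anyNA(rows_b)) {
    bad <- unique(c(plan$parent_a[is.na(rows_a)], plan$parent_b[is.na(rows_b)]))
    stop("unknown parent id(s): ", paste(bad, collapse = ", "))
  }
  fams <- vector("list", k)
  for (i in seq_len(k)) {
    fams[[i]] <- make_dh(candidate_pool$haplo[rows_a[i], ],
                         candidate_pool$haplo[rows_b[i], ],
                         plan$n_progeny[i], map)
  }
  n_tot <- sum(plan$n_progeny)
  new_population(
    id = first_id + seq_len(n_tot) - 1L,
    haplo = do.call(rbind, fams),
    parent1 = rep(plan$parent_a, plan$n_progeny),
    parent2 = rep(plan$parent_b, plan$n_progeny),
    component = rep(plan$component, plan$n_progeny),
    generation = as.integer(generation)
  )
}
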