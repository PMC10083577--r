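#' Inbred line populations
#'
#' A population holds fully homozygous (doubled-haploid or inbred) lines.
#' Because every line is homozygous at every site, a single binary haplotype
#' per line represents both gametes; the genotype dosage of a line at a marker
#' is `2 * haplotype allele`, i.e. dosages live in {0, 2}.
#'
#' @param id integer vector of individual ids (unique within the population).
#' @param haplo integer matrix, one row per individual, one column per marker,
#'   entries 0/1. Both chromosomes of a line carry this haplotype.
#' @param parent1,parent2 integer vectors of parent ids (`NA` for founders and
#'   donor-panel lines).
#' @param component character vector tagging each line's breeding component:
#'   `"founder"`, `"donor"`, `"bridging"` or `"elite"`.
#' @param generation integer vector of birth generations (founders are 0).
#'
#' @return An object of class `gsb_pop`.
#' @export
new_population <- function(id, haplo, parent1 = NA_integer_, parent2 = NA_integer_,
                           component = "founder", generation = 0L) {
  haplo <- as.matrix(haplo)
  dimnames(haplo) <- NULL
  storage.mode(haplo) <- "integer"
  n <- nrow(haplo)
  id <- as.integer(id)
  stopifnot(length(id) == n, !anyDuplicated(id))
  if (n > 0 && !all(haplo %in% c(0L, 1L))) {
    stop("haplotype alleles must be coded 0/1")
  }
  pop <- list(
    id         = id,
    haplo      = haplo,
    parent1    = rep_len(as.integer(parent1), n),
    parent2    = rep_len(as.integer(parent2), n),
    component  = rep_len(as.character(component), n),
    generation = rep_len(as.integer(generation), n)
  )
  class(pop) <- "gsb_pop"
  pop
}

#' @export
print.gsb_pop <- function(x, ...) {
  cat(sprintf(
    "<gsb_pop> %d lines x %d markers | components: %s | generations %s\n",
    n_ind(x), ncol(x$haplo),
    paste(sprintf("%s=%d", names(table(x$component)), table(x$component)),
          collapse = ", "),
    if (n_ind(x)) paste(range(x$generation), collapse = "..") else "-"
  ))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a `gsb_pop`.
#' @return integer count.
#' @export
n_ind <- function(pop) length(pop$id)

#' Subset a population by row index or id
#'
#' @param pop a `gsb_pop`.
#' @param i integer row indices (default) or, with `by_id = TRUE`, individual ids.
#' @param by_id interpret `i` as ids rather than positions.
#' @return a `gsb_pop` with the selected lines, marker set unchanged.
#' @export
pop_subset <- function(pop, i, by_id = FALSE) {
  if (by_id) {
    i <- match(i, pop$id)
    if (anyNA(i)) stop("unknown individual id(s) in subset")
  }
  new_population(pop$id[i], pop$haplo[i, , drop = FALSE],
                 pop$parent1[i], pop$parent2[i],
                 pop$component[i], pop$generation[i])
}

#' Concatenate populations sharing a marker set
#'
#' @param ... `gsb_pop` objects with identical marker counts.
#' @return a single `gsb_pop`.
#' @export
pop_bind <- function(...) {
  pops <- list(...)
  pops <- pops[vapply(pops, n_ind, 1L) > 0]
  if (!length(pops)) stop("nothing to bind")
  m <- unique(vapply(pops, function(p) ncol(p$haplo), 1L))
  if (length(m) != 1) stop("populations differ in marker count")
  new_population(
    id         = unlist(lapply(pops, `[[`, "id")),
    haplo      = do.call(rbind, lapply(pops, `[[`, "haplo")),
    parent1    = unlist(lapply(pops, `[[`, "parent1")),
    parent2    = unlist(lapply(pops, `[[`, "parent2")),
    component  = unlist(lapply(pops, `[[`, "component")),
    generation = unlist(lapply(pops, `[[`, "generation"))
  )
}

#' Genotype dosages of a population
#'
#' @param pop a `gsb_pop`.
#' @param markers optional marker column indices.
#' @return numeric matrix of dosages in {0, 2}, lines in rows.
#' @export
dosages <- function(pop, markers = NULL) {
  h <- if (is.null(markers)) pop$haplo else pop$haplo[, markers, drop = FALSE]
  2 * h
}

#' Allele frequencies in a population
#'
#' Frequency of the 1-coded allele at each marker (equal to the mean
#' haplotype allele since lines are homozygous).
#'
#' @param pop a `gsb_pop`.
#' @param markers optional marker column indices.
#' @return numeric vector of frequencies in `[0, 1]`.
#' @export
allele_freq <- function(pop, markers = NULL) {
  h <- if (is.null(markers)) pop$haplo else pop$haplo[, markers, drop = FALSE]
  colMeans(h)
}

#' Pedigree table of a population
#'
#' @param pop a `gsb_pop`.
#' @return data.frame with columns id, parent1, parent2, generation, component.
#' @export
pedigree_table <- function(pop) {
  data.frame(
    id = pop$id, parent1 = pop$parent1, parent2 = pop$parent2,
    generation = pop$generation, component = pop$component,
    stringsAsFactors = FALSE
  )
}

#' Hudson's Fst estimator between two groups of inbred lines
#'
#' Ratio-of-averages Hudson estimator computed on line haplotype frequencies
#' (each inbred line contributes one haplotype). Monomorphic markers across
#' both groups drop out of the ratio.
#'
#' @param pop a `gsb_pop`.
#' @param idx1,idx2 row indices of the two groups.
#' @return scalar Fst estimate.
#' @export
fst_hudson <- function(pop, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  stopifnot(n1 >= 2, n2 >= 2)
  p1 <- colMeans(pop$haplo[idx1, , drop = FALSE])
  p2 <- colMeans(pop$haplo[idx2, , drop = FALSE])
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}
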