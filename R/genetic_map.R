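#' Genetic maps
#'
#' A genetic map assigns every marker to a chromosome and a position in
#' centimorgans. It is the shared coordinate frame for recombination
#' simulation and for map-based progeny-variance prediction.
#'
#' @param chrom integer vector, chromosome of each marker.
#' @param pos numeric vector, position of each marker in cM; must be
#'   non-decreasing within a chromosome.
#' @param marker_id optional character ids (generated if missing).
#' @return an object of class `gsb_map`.
#' @export
new_genetic_map <- function(chrom, pos, marker_id = NULL) {
  stopifnot(length(chrom) == length(pos))
  chrom <- as.integer(chrom)
  pos <- as.numeric(pos)
  if (is.null(marker_id)) {
    marker_id <- sprintf("M%05d", seq_along(pos))
  }
  for (c_ in unique(chrom)) {
    p <- pos[chrom == c_]
    if (is.unsorted(p)) {
      stop("marker positions must be non-decreasing within chromosome ", c_)
    }
  }
  map <- list(chrom = chrom, pos = pos, marker_id = as.character(marker_id))
  class(map) <- "gsb_map"
  map
}

#' @export
print.gsb_map <- function(x, ...) {
  cat(sprintf("<gsb_map> %d markers on %d chromosome(s), %.1f cM total\n",
              n_markers(x), length(unique(x$chrom)),
              sum(tapply(x$pos, x$chrom, max))))
  invisible(x)
}

#' Number of markers on a map
#' @param map a `gsb_map`.
#' @return integer count.
#' @export
n_markers <- function(map) length(map$pos)

#' Marker indices per chromosome
#' @param map a `gsb_map`.
#' @return list of integer index vectors, one per chromosome (map order).
#' @export
map_chrom_index <- function(map) {
  split(seq_along(map$chrom), map$chrom)
}

#' Generate a uniform synthetic genetic map
#'
#' Markers are spread evenly over each chromosome: with k markers on a
#' chromosome of length L cM, positions are `seq(0, L, length.out = k)`.
#' The marker total is split as evenly as possible across chromosomes
#' (earlier chromosomes absorb the remainder).
#'
#' @param n_chromosomes number of chromosomes (default 10, maize-like).
#' @param chrom_length chromosome length in cM (default 160; recycled).
#' @param n_markers total marker count over the genome.
#' @return a `gsb_map`.
#' @export
#' @examples
#' map <- generate_genetic_map(n_chromosomes = 2, chrom_length = 100, n_markers = 11)
generate_genetic_map <- function(n_chromosomes = 10, chrom_length = 160,
                                 n_markers = 41495) {
  stopifnot(n_chromosomes >= 1, n_markers >= n_chromosomes,
            all(chrom_length >= 0))
  lens <- rep_len(chrom_length, n_chromosomes)
  per <- rep(n_markers %/% n_chromosomes, n_chromosomes)
  extra <- n_markers %% n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  if (any(per == 0)) stop("chromosome with zero markers; increase n_markers")
  chrom <- rep(seq_len(n_chromosomes), per)
  pos <- unlist(lapply(seq_len(n_chromosomes), function(c_) {
    k <- per[c_]
    if (k == 1) 0 else seq(0, lens[c_], length.out = k)
  }))
  new_genetic_map(chrom, pos)
}

#' Read / write a genetic map as CSV
#'
#' The CSV has columns `chrom, marker_id, pos_cM`.
#'
#' @param file path to a CSV file.
#' @return `read_genetic_map` returns a `gsb_map`; `write_genetic_map`
#'   returns `file` invisibly.
#' @export
read_genetic_map <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("chrom", "marker_id", "pos_cM")
  if (!all(need %in% names(df))) {
    stop("map CSV must have columns: ", paste(need, collapse = ", "))
  }
  new_genetic_map(df$chrom, df$pos_cM, df$marker_id)
}

#' @rdname read_genetic_map
#' @param map a `gsb_map`.
#' @export
write_genetic_map <- function(map, file) {
  utils::write.csv(
    data.frame(chrom = map$chrom, marker_id = map$marker_id, pos_cM = map$pos),
    file, row.names = FALSE, quote = FALSE
  )
  invisible(file)
}
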