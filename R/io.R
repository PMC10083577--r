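#' Write a homozygous population to VCF
#'
#' Lines are written as homozygous diploid genotypes (`0/0` / `1/1`).
#' Physical positions are synthesized from the genetic map
#' (`round(pos_cM * 1e4) + 1`) since the synthetic genome has no physical
#' coordinates; they are strictly for file validity.
#'
#' @param pop a `gsb_pop`.
#' @param map the matching `gsb_map`.
#' @param file output path (plain-text `.vcf`).
#' @return `file`, invisibly.
#' @export
write_population_vcf <- function(pop, map, file) {
  stopifnot(n_markers(map) == ncol(pop$haplo))
  gt <- ifelse(t(pop$haplo) == 1L, "1/1", "0/0")  # markers x lines
  pos <- as.integer(round(map$pos * 1e4)) + 1L
  # guarantee strictly increasing POS within a chromosome
  for (idx in map_chrom_index(map)) {
    p <- pos[idx]
    pos[idx] <- p + cumsum(c(0L, as.integer(diff(p) <= 0L)))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gsbridge",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("L", pop$id)), collapse = "\t")
  )
  body <- paste(map$chrom, pos, map$marker_id, "A", "T", ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), file)
  invisible(file)
}

#' Load a population of inbred lines from VCF or PLINK text files
#'
#' Reads homozygous line genotypes plus a genetic-map CSV
#' (columns `chrom, marker_id, pos_cM`). Markers are returned in map order.
#' Quality control mirrors routine inbred-panel filtering: a line whose
#' heterozygous-call rate exceeds `het_threshold` is dropped (with a
#' message); residual heterozygous calls in retained lines are resolved to a
#' random homozygote (seeded).
#'
#' @param genotype_file `.vcf` file, or a PLINK `.ped` file with its `.map`
#'   alongside.
#' @param map_file genetic-map CSV.
#' @param het_threshold per-line heterozygosity rate above which the line is
#'   rejected (default 0.1).
#' @param seed seed for the random resolution of residual heterozygous calls.
#' @return list with elements `population` (a `gsb_pop`), `map` (a `gsb_map`)
#'   and `n_dropped` (lines failing QC).
#' @export
load_population <- function(genotype_file, map_file, het_threshold = 0.1,
                            seed = 1L) {
  map <- read_genetic_map(map_file)
  g <- if (grepl("\\.vcf$", genotype_file, ignore.case = TRUE)) {
    read_vcf_genotypes(genotype_file)
  } else {
    read_plink_genotypes(genotype_file)
  }
  missing_in_map <- setdiff(g$marker_id, map$marker_id)
  if (length(missing_in_map)) {
    stop("markers absent from the map: ",
         paste(utils::head(missing_in_map, 10), collapse = ", "),
         if (length(missing_in_map) > 10) sprintf(" (and %d more)",
                                                  length(missing_in_map) - 10))
  }
  ord <- match(map$marker_id, g$marker_id)
  if (anyNA(ord)) stop("map markers missing from the genotype file")
  dos <- g$dosage[, ord, drop = FALSE]   # lines x markers, values 0/1/2, 1 = het

  het_rate <- rowMeans(dos == 1L)
  drop <- het_rate > het_threshold
  if (any(drop)) {
    message(sum(drop), " line(s) dropped for heterozygosity rate > ",
            het_threshold)
    dos <- dos[!drop, , drop = FALSE]
    g$line_id <- g$line_id[!drop]
  }
  set.seed(seed)
  het <- which(dos == 1L)
  if (length(het)) dos[het] <- 2L * (stats::runif(length(het)) < 0.5)
  pop <- new_population(seq_len(nrow(dos)), dos / 2L,
                        component = "founder", generation = 0L)
  attr(pop, "line_names") <- g$line_id
  list(population = pop, map = map, n_dropped = sum(drop))
}

# Parse a VCF of line genotypes into a dosage matrix (lines x markers).
read_vcf_genotypes <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("\\|", "/", gt)
  dos <- t(ifelse(gt == "0/0", 0L, ifelse(gt == "1/1", 2L, 1L)))
  list(dosage = dos, marker_id = rownames(gt), line_id = colnames(gt))
}

# Parse PLINK text .ped (+ sibling .map for marker ids).
read_plink_genotypes <- function(ped_file) {
  map_file <- sub("\\.ped$", ".map", ped_file, ignore.case = TRUE)
  if (!file.exists(map_file)) stop("PLINK .map file not found: ", map_file)
  pm <- utils::read.table(map_file, stringsAsFactors = FALSE)
  marker_id <- as.character(pm[[2]])
  ped <- utils::read.table(ped_file, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(ped) != 6 + 2 * length(marker_id)) {
    stop(".ped column count does not match .map marker count")
  }
  a1 <- as.matrix(ped[, 6 + 2 * seq_along(marker_id) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_along(marker_id), drop = FALSE])
  # allele "T" (or "2") is the counted allele, matching the VCF ALT
  cnt <- (a1 %in% c("T", "2")) + (a2 %in% c("T", "2"))
  dos <- matrix(as.integer(cnt), nrow = nrow(ped))
  list(dosage = dos, marker_id = marker_id, line_id = ped[[2]])
}
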