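#' Funnel cross design
#'
#' Topology and parameters of a three-level, eight-founder funnel cross.
#' Level 1 mates fixed founder pairs; levels 2 and 3 mate random pairs
#' drawn from pooled haploid progeny of the previous level. The pairings
#' must partition founders 1..8 into the four level-1 pairs and two
#' level-2 quartets.
#'
#' @param level1 List of four founder pairs
#'   (default `{1,2},{3,4},{5,6},{7,8}`).
#' @param level2 List of two founder quartets (default `{1..4},{5..8}`).
#' @param pool_size Haploid progeny kept per intermediate population and
#'   mating type (default 576).
#' @param n_final Number of final mapping strains to emit (default 2000).
#' @param c Crossover rate per meiosis, crossovers per Mb (default 3).
#' @param trisomy Optional trisomy event: a list with elements `chrom`
#'   (chromosome name), `g1_pop` (index of the level-1 population whose
#'   diploid carries the extra copy), `extra_hap` (founder code of the
#'   duplicated copy), `loh` (optional data.frame `start`, `end`, `hap`
#'   giving intervals of the extra copy overwritten by haplotype `hap`),
#'   and `disome_rate` (probability that a meiosis with 3 copies transmits
#'   2, default 0.5).
#' @param bottleneck Optional list `pop` (label such as "G1_1-2" or
#'   "G2_5-8") and `k` (effective ancestor count): that pool is collapsed
#'   to `k` distinct haploids resampled to full size.
#' @param lethal Optional two-locus viability rule, see
#'   [apply_viability_filter()].
#'
#' @return An object of class `cross_design`.
#' @export
cross_design <- function(level1 = list(c(1, 2), c(3, 4), c(5, 6), c(7, 8)),
                         level2 = list(1:4, 5:8),
                         pool_size = 576,
                         n_final = 2000,
                         c = 3,
                         trisomy = NULL,
                         bottleneck = NULL,
                         lethal = NULL) {
  if (length(level1) != 4 || !setequal(unlist(level1), 1:8) ||
      any(lengths(level1) != 2)) {
    stop("level1 must be four pairs partitioning founders 1..8")
  }
  if (length(level2) != 2 || !setequal(unlist(level2), 1:8) ||
      any(lengths(level2) != 4)) {
    stop("level2 must be two quartets partitioning founders 1..8")
  }
  # each level-2 quartet must be the union of two level-1 pairs
  for (q in level2) {
    inside <- vapply(level1, function(p) all(p %in% q), TRUE)
    if (sum(inside) != 2) stop("level2 quartets must nest the level1 pairs")
  }
  if (pool_size < 1) stop("pool_size must be >= 1")
  if (c < 0) stop("crossover rate c must be >= 0")
  if (!is.null(trisomy)) {
    need <- c("chrom", "g1_pop", "extra_hap")
    if (!all(need %in% names(trisomy))) {
      stop("trisomy spec needs elements: ", paste(need, collapse = ", "))
    }
    if (is.null(trisomy$disome_rate)) trisomy$disome_rate <- 0.5
    pair <- level1[[trisomy$g1_pop]]
    if (!(trisomy$extra_hap %in% pair)) {
      stop("trisomy extra_hap must belong to the designated level-1 pair")
    }
  }
  structure(list(level1 = level1, level2 = level2, pool_size = pool_size,
                 n_final = n_final, c = c, trisomy = trisomy,
                 bottleneck = bottleneck, lethal = lethal),
            class = "cross_design")
}

#' Founder sets of the intermediate populations
#'
#' @param design A `cross_design`.
#' @return Named list of founder-code sets, e.g. `G1_1-2` -> c(1,2),
#'   `G2_5-8` -> 5:8.
#' @export
population_sets <- function(design) {
  sets <- c(design$level1, design$level2)
  names(sets) <- c(
    vapply(design$level1, function(p)
      sprintf("G1_%d-%d", min(p), max(p)), ""),
    vapply(design$level2, function(q)
      sprintf("G2_%d-%d", min(q), max(q)), ""))
  sets
}

#' Simulation options for the synthetic funnel-cross generator
#'
#' Defaults emulate the study conditions of an 8-founder yeast funnel
#' cross panel: ~1 SNV per 44 bp, minor-allele sharing spectrum
#' 77.4% / 13.0% / 6.73% / 2.8% for 1..4 carrier founders, mean
#' sequencing depth 3.8x and 1% per-read error.
#'
#' @param bp_per_marker Mean bp per SNV (default 44).
#' @param sharing_spectrum Proportions of markers whose minor allele is
#'   carried by 1, 2, 3 or 4 founders; must sum to <= 1 (remainder is
#'   assigned to the 1-founder class).
#' @param mean_depth Mean per-marker sequencing depth (default 3.8).
#' @param error_rate Per-read sequencing error probability (default 0.01).
#'
#' @return An object of class `sim_options`.
#' @export
sim_options <- function(bp_per_marker = 44,
                        sharing_spectrum = c(0.774, 0.130, 0.0673, 0.028),
                        mean_depth = 3.8,
                        error_rate = 0.01) {
  if (bp_per_marker <= 0) stop("bp_per_marker must be > 0")
  if (length(sharing_spectrum) != 4 || any(sharing_spectrum < 0)) {
    stop("sharing_spectrum must be 4 non-negative proportions")
  }
  if (sum(sharing_spectrum) > 1 + 1e-9) {
    stop("sharing_spectrum must sum to <= 1")
  }
  sharing_spectrum[1] <- sharing_spectrum[1] + (1 - sum(sharing_spectrum))
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)")
  }
  structure(list(bp_per_marker = bp_per_marker,
                 sharing_spectrum = sharing_spectrum,
                 mean_depth = mean_depth, error_rate = error_rate),
            class = "sim_options")
}

#' Allele count matrices
#'
#' Per-marker x per-strain counts of reads supporting the reference and
#' alternative alleles of the founder marker table. Rows are markers
#' (aligned to a `marker_table`), columns strains.
#'
#' @param ref,alt Non-negative integer matrices of identical dimensions.
#' @param strains Strain labels (default column names of `ref`).
#' @return An object of class `allele_counts`.
#' @export
allele_counts <- function(ref, alt, strains = colnames(ref)) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
  if (!all(dim(ref) == dim(alt))) stop("ref/alt dimension mismatch")
  if (anyNA(ref) || anyNA(alt) || any(ref < 0) || any(alt < 0)) {
    stop("allele counts must be non-negative integers")
  }
  if (is.null(strains)) strains <- paste0("strain", seq_len(ncol(ref)))
  colnames(ref) <- strains; colnames(alt) <- strains
  structure(list(ref = ref, alt = alt, strains = strains),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("allele_counts:", nrow(x$ref), "markers x", ncol(x$ref), "strains,",
      "total reads", sum(x$ref) + sum(x$alt), "\n")
  invisible(x)
}

#' Read / write allele count matrices
#'
#' Each of the two count matrices is a TSV with a `marker` index column
#' followed by one column per strain; `read_allele_counts` takes the two
#' paths (reference-allele counts, alternative-allele counts).
#'
#' @param counts An `allele_counts` object.
#' @param ref_path,alt_path File paths for the two matrices.
#' @return `read_allele_counts` returns an `allele_counts`.
#' @export
write_allele_counts <- function(counts, ref_path, alt_path) {
  stopifnot(inherits(counts, "allele_counts"))
  wr <- function(m, path) {
    out <- data.frame(marker = seq_len(nrow(m)), m, check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(counts$ref, ref_path)
  wr(counts$alt, alt_path)
  invisible(NULL)
}

#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(ref_path, alt_path) {
  rd <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE)
    as.matrix(tab[-1])
  }
  ref <- rd(ref_path); alt <- rd(alt_path)
  allele_counts(ref, alt, strains = colnames(ref))
}
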