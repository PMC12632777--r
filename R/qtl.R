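# LOD-score QTL scans, empirical family-wise thresholds, and the
# power/resolution simulation study.

#' LOD score of a haplotype factor for one phenotype
#'
#' LOD = log10 P(B) - log10 P(A), where P(A) is the likelihood of the
#' phenotype under a single normal distribution with one mean and P(B)
#' the likelihood after fitting a separate mean for each observed
#' haplotype class (shared variance, maximum-likelihood estimates). With
#' ML variances this equals (n/2) log10(RSS0/RSS1). Strains with missing
#' haplotype are dropped; haplotype classes with no strains contribute no
#' parameter.
#'
#' @param phenotype Numeric phenotype vector.
#' @param hap Integer haplotype codes 1..8 (NA dropped), same length.
#' @return LOD score (>= 0).
#' @export
lod_score <- function(phenotype, hap) {
  stopifnot(length(phenotype) == length(hap))
  ok <- !is.na(hap) & !is.na(phenotype)
  y <- phenotype[ok]; g <- factor(hap[ok])
  n <- length(y)
  if (n < 2) return(NA_real_)
  rss0 <- sum((y - mean(y))^2)
  mu <- tapply(y, g, mean)
  rss1 <- sum((y - mu[g])^2)
  if (rss0 <= 0) return(0)
  max(0, n / 2 * (log10(rss0) - log10(rss1)))
}

#' Genome scan of one or more phenotypes over a marker set
#'
#' Vectorized over phenotypes via a compiled kernel; the per-marker LOD
#' equals [lod_score()]. The candidate marker is the argmax of the scan
#' (ties broken toward the smallest marker index).
#'
#' @param phenotypes Numeric vector (one phenotype) or matrix
#'   (strains x phenotypes).
#' @param haplotypes A [hap_matrix()] or code matrix (strains x markers).
#' @return List with `lod` (markers x phenotypes matrix) and `candidate`
#'   (argmax marker index per phenotype).
#' @export
genome_scan <- function(phenotypes, haplotypes) {
  H <- hap_codes(haplotypes)
  H[is.na(H)] <- 0L
  Y <- as.matrix(phenotypes)
  if (nrow(Y) != nrow(H)) stop("phenotype length must match strain count")
  lod <- lod_scan_cpp(H, Y)
  candidate <- apply(lod, 2, which.max)  # first max = smallest index
  list(lod = lod, candidate = as.integer(candidate))
}

#' Empirical family-wise LOD significance threshold
#'
#' Simulates `n_reps` null phenotypes (standard normal, independent of
#' genotype), records the maximum LOD across the scanned markers for each
#' replicate, and returns the 95th percentile (or `1 - alpha` quantile).
#'
#' @param haplotypes Scaffold haplotypes (strains x markers).
#' @param n_reps Null replicates (default 1000).
#' @param alpha Family-wise error rate (default 0.05).
#' @param seed Optional RNG seed.
#' @return The LOD threshold; per-replicate maxima in attribute
#'   `"max_lod"`.
#' @export
empirical_threshold <- function(haplotypes, n_reps = 1000, alpha = 0.05,
                                seed = NULL) {
  if (n_reps < 100) stop("n_reps must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  H <- hap_codes(haplotypes)
  n <- nrow(H)
  Y <- matrix(stats::rnorm(n * n_reps), n, n_reps)
  sc <- genome_scan(Y, H)
  mx <- apply(sc$lod, 2, max, na.rm = TRUE)
  structure(unname(stats::quantile(mx, 1 - alpha)), max_lod = mx)
}

#' Simulate a single-locus phenotype
#'
#' phenotype = beta (g - mean(g)) + eps with normal residuals
#' orthogonalized to the genotype and rescaled, so each phenotype has
#' mean 0, variance 1 and a fraction of variance explained by the
#' biallelic genotype that is exactly h2 (beta = sqrt(h2 / (f(1-f))) with
#' f the causative allele frequency). The exact decomposition, rather
#' than an in-expectation one, is what "a phenotype explaining h2 of the
#' variance" means here: the stated heritability is a property of each
#' simulated phenotype, not just of their ensemble. h2 = 0 gives a pure
#' standard normal.
#'
#' @param g 0/1 genotype vector at the causative marker.
#' @param h2 Heritability in [0, 1].
#' @param seed Optional RNG seed.
#' @return Numeric phenotype vector.
#' @export
simulate_phenotype <- function(g, h2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  n <- length(g)
  eps <- stats::rnorm(n)
  if (h2 == 0) return(eps)
  f <- mean(g)
  if (f <= 0 || f >= 1) stop("causative allele frequency must be in (0, 1)")
  gc <- g - f
  # remove the residuals' chance mean and genotype projection, then
  # rescale: the variance decomposition is exact, not just expected
  eps <- eps - mean(eps) - gc * sum(eps * gc) / sum(gc^2)
  eps <- if (h2 < 1) eps * sqrt(n * (1 - h2) / sum(eps^2)) else 0
  beta <- sqrt(h2 / mean(gc^2))
  beta * gc + eps
}

#' Scaffold marker most closely genetically linked to a position
#'
#' Smallest Haldane recombinant fraction, i.e. the nearest same-chromosome
#' scaffold marker by physical distance (ties toward the smaller
#' position); markers on other chromosomes are unlinked.
#'
#' @param chrom,pos Chromosome and position of the query locus.
#' @param scaffold_markers Data frame of the scaffold markers' `chrom`,
#'   `pos` (in scan column order).
#' @return Scaffold column index, or NA if no same-chromosome marker.
#' @export
nearest_scaffold_marker <- function(chrom, pos, scaffold_markers) {
  idx <- which(scaffold_markers$chrom == chrom)
  if (length(idx) == 0) return(NA_integer_)
  d <- abs(scaffold_markers$pos[idx] - pos)
  idx[which.min(d)]
}

#' QTL power and resolution simulation
#'
#' For each heritability, draws causative markers uniformly from the full
#' marker panel, simulates single-locus phenotypes on the true genotypes,
#' scans the scaffold markers, and summarizes: power (fraction of
#' candidate LODs at or above the threshold), the fraction of candidates
#' on the causative chromosome, and the mean candidate-to-causative
#' distance among same-chromosome cases.
#'
#' @param scaffold_hap Scaffold haplotype codes (strains x scaffold
#'   markers).
#' @param scaffold_markers Data frame `chrom`, `pos` for the scaffold
#'   columns.
#' @param full_hap_fun Function(marker_rows) returning the strains x
#'   length(marker_rows) haplotype codes at arbitrary full-panel markers
#'   (the causative candidates).
#' @param markers Full `marker_table` the causative markers are drawn
#'   from.
#' @param h2_grid Heritabilities to evaluate.
#' @param n_phen Phenotype replicates per heritability (default 150).
#' @param threshold LOD significance threshold (e.g. from
#'   [empirical_threshold()]).
#' @param seed Optional RNG seed.
#' @return Data frame: `h2`, `power`, `same_chrom_rate`, `mean_dist_bp`,
#'   `n`; per-replicate details in attribute `"details"`.
#' @export
power_resolution_experiment <- function(scaffold_hap, scaffold_markers,
                                        full_hap_fun, markers, h2_grid,
                                        n_phen = 150, threshold,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- hap_codes(scaffold_hap)
  n <- nrow(H)
  res <- vector("list", length(h2_grid))
  details <- vector("list", length(h2_grid))
  for (k in seq_along(h2_grid)) {
    h2 <- h2_grid[k]
    # draw causative markers; require a segregating allele when h2 > 0
    caus <- integer(n_phen)
    geno <- matrix(0L, n, n_phen)
    filled <- 0
    while (filled < n_phen) {
      cand <- sample.int(nrow(markers), n_phen - filled, replace = TRUE)
      gh <- full_hap_fun(cand)
      gg <- founder_genotype(gh, markers, cand)
      f <- colMeans(gg, na.rm = TRUE)
      keep <- if (h2 > 0) which(f > 0 & f < 1) else seq_along(cand)
      for (j in keep) {
        filled <- filled + 1
        caus[filled] <- cand[j]
        geno[, filled] <- gg[, j]
      }
    }
    Y <- sapply(seq_len(n_phen), function(j)
      simulate_phenotype(geno[, j], h2))
    sc <- genome_scan(Y, H)
    cand_lod <- sc$lod[cbind(sc$candidate, seq_len(n_phen))]
    cand_chrom <- scaffold_markers$chrom[sc$candidate]
    cand_pos <- scaffold_markers$pos[sc$candidate]
    same <- cand_chrom == markers$chrom[caus]
    dist <- ifelse(same, abs(cand_pos - markers$pos[caus]), NA)
    res[[k]] <- data.frame(
      h2 = h2,
      power = mean(cand_lod >= threshold),
      same_chrom_rate = mean(same),
      mean_dist_bp = mean(dist, na.rm = TRUE),
      n = n_phen)
    details[[k]] <- data.frame(h2 = h2, causative = caus,
                               candidate = sc$candidate,
                               lod = cand_lod, same_chrom = same,
                               dist_bp = dist)
  }
  out <- do.call(rbind, res)
  attr(out, "details") <- do.call(rbind, details)
  out
}
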