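# Single-marker and pairwise deviations from expected haplotype
# frequencies, with cross-structure variance calibration and Holm
# multiple-testing control.

#' Per-marker haplotype counts
#'
#' @param haplotypes A [hap_matrix()] or code matrix (strains x markers),
#'   euploid codes.
#' @return Integer matrix (markers x 8) of strain counts; markers with no
#'   called strains are listed in attribute `"empty"`.
#' @export
haplotype_counts <- function(haplotypes) {
  H <- hap_codes(haplotypes)
  counts <- t(apply(H, 2, function(col) tabulate(col, nbins = 8)))
  if (ncol(H) == 1) counts <- matrix(counts, 1, 8)
  colnames(counts) <- paste0("hap", 1:8)
  attr(counts, "empty") <- which(rowSums(counts) == 0)
  counts
}

#' Estimate the count-variance inflation divisor
#'
#' The chi-square goodness-of-fit null assumes Poisson dispersion of
#' haplotype counts around their expectation; cross structure inflates
#' the variance. Over an integer grid of divisors, the central fraction
#' (default 95%) of ordered counts is divided by each candidate and
#' regressed on the order statistics of a simulated Poisson sample with
#' the same mean (a Q-Q regression); the divisor whose slope is closest
#' to 1 is returned.
#'
#' @param counts Haplotype count observations pooled across markers (the
#'   flattened matrix from [haplotype_counts()] is typical).
#' @param central_fraction Central quantile mass to use (default 0.95,
#'   assuming sites under selection are rare).
#' @param divisor_grid Candidate integer divisors (default 1..100).
#' @param comparator_size Size multiplier for the simulated Poisson
#'   comparator sample (default 10x the observed count).
#' @param seed RNG seed for the comparator (default 1; fixed so the
#'   calibration is reproducible).
#' @return List of class `inflation_calibration`: `divisor`, `slope`
#'   (at the chosen divisor), and the grid profile.
#' @export
estimate_inflation_divisor <- function(counts, central_fraction = 0.95,
                                       divisor_grid = 1:100,
                                       comparator_size = 10, seed = 1) {
  counts <- as.vector(counts)
  counts <- counts[is.finite(counts)]
  if (length(counts) < 100) stop("need >= 100 count observations")
  if (stats::var(counts) == 0) stop("all counts equal; divisor undefined")
  n <- length(counts)
  drop <- (1 - central_fraction) / 2
  keep <- seq(floor(n * drop) + 1, ceiling(n * (1 - drop)))
  y_all <- sort(counts)
  probs <- (keep - 0.5) / n  # quantile ranks of the retained order stats
  oldseed <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = .GlobalEnv))
  set.seed(seed)
  slopes <- vapply(divisor_grid, function(D) {
    y <- y_all[keep] / D
    comp <- stats::rpois(comparator_size * n, mean(y_all / D))
    x <- stats::quantile(comp, probs, names = FALSE)
    if (stats::var(x) == 0) return(NA_real_)
    stats::cov(x, y) / stats::var(x)
  }, 0)
  k <- which.min(abs(slopes - 1))
  structure(list(divisor = divisor_grid[k], slope = slopes[k],
                 central_fraction = central_fraction,
                 grid = divisor_grid, slopes = slopes),
            class = "inflation_calibration")
}

#' Single-marker goodness-of-fit scan
#'
#' Chi-square goodness-of-fit of adjusted counts (counts / divisor)
#' against adjusted expected counts at every marker; haplotypes with
#' expected frequency 0 are excluded with the matching df reduction. The
#' Holm method sets the family-wise 0.05 nominal-p cutoff over all
#' markers.
#'
#' @param counts Matrix (markers x 8) from [haplotype_counts()].
#' @param expected_freqs Either a single 8-vector of expected frequencies
#'   or a markers x 8 matrix (for region-specific expectations such as a
#'   chromosome carrying an extra top-of-funnel copy).
#' @param divisor Variance-inflation divisor (e.g. from
#'   [estimate_inflation_divisor()]); default 1.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Data frame: `marker`, `statistic` (adjusted), `df`, `p`,
#'   `significant`; the Holm cutoff is attribute `"cutoff"`.
#' @export
single_marker_scan <- function(counts, expected_freqs = rep(1 / 8, 8),
                               divisor = 1, alpha = 0.05) {
  m <- nrow(counts)
  if (is.null(dim(expected_freqs))) {
    expected_freqs <- matrix(expected_freqs, m, 8, byrow = TRUE)
  }
  stopifnot(nrow(expected_freqs) == m, ncol(expected_freqs) == 8)
  stat <- numeric(m); df <- integer(m)
  for (i in seq_len(m)) {
    o <- counts[i, ]; f <- expected_freqs[i, ]
    use <- f > 0
    e <- sum(o) * f[use] / sum(f[use])
    # scaling both counts and expectations by the divisor restores
    # Poisson-like dispersion: sum((O/D - E/D)^2 / (E/D)) = X^2 / D
    stat[i] <- sum((o[use] - e)^2 / e) / divisor
    df[i] <- sum(use) - 1L
  }
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  cutoff <- holm_cutoff(p, alpha)
  data.frame(marker = seq_len(m), statistic = stat, df = df, p = p,
             significant = p < cutoff) |>
    structure(cutoff = cutoff)
}

#' Pearson chi-square independence statistic for two markers
#'
#' Standard statistic on the 8x8 joint haplotype count table, reported
#' with df = 49 (the (8-1)^2 of a full table); cells with zero expected
#' count contribute 0.
#'
#' @param hap_i,hap_j Monosomic haplotype code vectors over the same
#'   strains.
#' @return List: `statistic`, `df`, `table`.
#' @export
pairwise_chisq <- function(hap_i, hap_j) {
  ok <- !is.na(hap_i) & !is.na(hap_j)
  tab <- matrix(tabulate((hap_i[ok] - 1L) * 8L + hap_j[ok], nbins = 64),
                8, 8, byrow = TRUE)
  list(statistic = chisq_stat_8x8(tab), df = 49L, table = tab)
}

chisq_stat_8x8 <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  use <- e > 0
  sum((tab[use] - e[use])^2 / e[use])
}

#' Calibrate the pairwise-independence null
#'
#' The bottom fraction (default 95%) of observed inter-chromosomal
#' chi-square statistics is taken as the empirical null, and its ordered
#' values are regressed log-log on the matching theoretical
#' chi-square(49) quantiles. The inverse of the fitted log-linear map
#' transforms observed statistics back to the theoretical null scale.
#'
#' @param statistics Inter-chromosomal pair statistics (>= 1000).
#' @param bottom_fraction Fraction treated as null (default 0.95).
#' @param df Degrees of freedom of the theoretical null (default 49).
#' @return List of class `pairwise_calibration`: coefficients `a`
#'   (intercept) and `b` (slope) of log(observed) = a + b log(q), and
#'   `transform`, the function mapping a statistic to the null scale.
#' @export
calibrate_pairwise_null <- function(statistics, bottom_fraction = 0.95,
                                    df = 49) {
  statistics <- statistics[is.finite(statistics) & statistics > 0]
  m <- length(statistics)
  if (m < 1000) stop("need >= 1000 inter-chromosomal statistics")
  k <- floor(m * bottom_fraction)
  y <- sort(statistics)[seq_len(k)]
  q <- stats::qchisq(((seq_len(k)) - 0.5) / m, df)
  fit <- stats::lm.fit(cbind(1, log(q)), log(y))
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  if (b <= 0) stop("fitted log-linear transform is not increasing")
  structure(list(a = unname(a), b = unname(b), df = df,
                 transform = function(x) exp((log(x) - a) / b)),
            class = "pairwise_calibration")
}

#' Pairwise haplotype-independence scan
#'
#' Scores every marker pair with the chi-square independence statistic,
#' transforms inter-chromosomal statistics to the null scale with the
#' fitted calibration (a separate calibration may be supplied for pairs
#' involving a designated chromosome), and thresholds at the Holm
#' family-wise cutoff computed over the inter-chromosomal pairs.
#' Intra-chromosomal pairs are scored but flagged: linkage confounds
#' their null.
#'
#' @param haplotypes Scaffold haplotypes (strains x markers).
#' @param chrom Chromosome of each marker column.
#' @param calibration A `pairwise_calibration`, or NULL to fit one from
#'   this scan's inter-chromosomal statistics.
#' @param special_chrom Optional chromosome name whose pairs use
#'   `special_calibration` (e.g. a chromosome with a top-of-funnel extra
#'   copy).
#' @param special_calibration Calibration for pairs involving
#'   `special_chrom`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Data frame: `i`, `j`, `chrom_i`, `chrom_j`, `statistic`,
#'   `transformed`, `intra`, `p`, `significant`; the calibration and Holm
#'   cutoff are attached as attributes.
#' @export
pairwise_scan <- function(haplotypes, chrom, calibration = NULL,
                          special_chrom = NULL,
                          special_calibration = NULL, alpha = 0.05) {
  H <- hap_codes(haplotypes)
  m <- ncol(H)
  stopifnot(length(chrom) == m)
  pair <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  stat <- numeric(nrow(pair))
  for (k in seq_len(nrow(pair))) {
    stat[k] <- pairwise_chisq(H[, pair[k, 1]], H[, pair[k, 2]])$statistic
  }
  ci <- chrom[pair[, 1]]; cj <- chrom[pair[, 2]]
  intra <- ci == cj
  if (is.null(calibration)) {
    calibration <- calibrate_pairwise_null(stat[!intra])
  }
  special <- if (is.null(special_chrom)) rep(FALSE, length(stat))
             else (ci == special_chrom | cj == special_chrom)
  transformed <- rep(NA_real_, length(stat))
  std <- !intra & !special
  transformed[std] <- calibration$transform(stat[std])
  if (any(special & !intra)) {
    cal2 <- if (is.null(special_calibration)) calibration
            else special_calibration
    transformed[special & !intra] <- cal2$transform(stat[special & !intra])
  }
  p <- rep(NA_real_, length(stat))
  inter <- !intra
  p[inter] <- stats::pchisq(transformed[inter], calibration$df,
                            lower.tail = FALSE)
  cutoff <- holm_cutoff(p[inter], alpha)
  out <- data.frame(i = pair[, 1], j = pair[, 2],
                    chrom_i = ci, chrom_j = cj,
                    statistic = stat, transformed = transformed,
                    intra = intra, p = p,
                    significant = !is.na(p) & p < cutoff)
  structure(out, cutoff = cutoff, calibration = calibration)
}

#' Holm step-down nominal-p cutoff
#'
#' Sorts the p-values ascending and finds the largest k such that
#' p(i) <= alpha / (m - i + 1) for all i <= k; the returned cutoff is the
#' boundary alpha / (m - k) that the first accepted step failed (alpha if
#' everything is rejected, 0 if nothing is). Values strictly below the
#' cutoff are exactly the Holm rejections.
#'
#' @param p_values Nominal p-values in [0, 1] (NA dropped).
#' @param alpha Family-wise error rate (default 0.05).
#' @return The nominal-p cutoff.
#' @export
holm_cutoff <- function(p_values, alpha = 0.05) {
  p <- sort(p_values[!is.na(p_values)])
  m <- length(p)
  if (m == 0) stop("no p-values")
  thresh <- alpha / (m - seq_len(m) + 1)
  fail <- which(p > thresh)
  k <- if (length(fail) == 0) m else fail[1] - 1L
  if (k == 0) return(0)
  if (k == m) return(alpha)
  alpha / (m - k)
}
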