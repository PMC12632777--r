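# Identity decay with physical distance and the physical-to-genetic
# conversion coefficient.

#' Pairwise haplotype identity between markers
#'
#' Identity is the proportion of strains in which two markers carry the
#' same founder haplotype (1 - recombinant haplotype fraction); strains
#' missing at either marker are excluded pairwise. Two markers on the same
#' chromosome have expected identity (1 - R)^3 under the three-round
#' funnel; unlinked markers in a balanced population have identity 1/8.
#'
#' @param haplotypes A [hap_matrix()] or plain code matrix
#'   (strains x markers), monosomic codes.
#' @param pos Physical positions of the markers (same order as columns);
#'   used to report pair distances.
#' @return Data frame with columns `i`, `j` (column indices, i < j),
#'   `dist` (bp) and `identity`.
#' @export
pairwise_identity <- function(haplotypes, pos) {
  H <- hap_codes(haplotypes)
  m <- ncol(H)
  stopifnot(length(pos) == m)
  ok <- !is.na(H)
  denom <- crossprod(ok)                     # jointly called strains
  match <- matrix(0, m, m)
  for (h in 1:8) {
    ind <- (!is.na(H)) & (H == h)
    match <- match + crossprod(ind)
  }
  pair <- which(upper.tri(denom), arr.ind = TRUE)
  data.frame(i = pair[, 1], j = pair[, 2],
             dist = abs(pos[pair[, 2]] - pos[pair[, 1]]),
             identity = match[pair] / denom[pair])
}

#' Predicted identity from physical distance
#'
#' I(d; c) = (1 - 0.5 (1 - exp(-2 c d / 1e6)))^3: the probability of no
#' net haplotype change across three rounds of meiosis, with Haldane's
#' recombinant fraction per meiosis at genetic distance c d / 1e6 Morgans.
#'
#' @param d Physical distance in bp.
#' @param c Conversion coefficient, crossovers per Mb per meiosis.
#' @return Predicted identity in (1/8, 1].
#' @export
predicted_identity <- function(d, c) {
  (1 - haldane_r(c * d / 1e6))^3
}

#' Fit the physical-to-genetic conversion coefficient
#'
#' Grid search: for each candidate coefficient, observed identities are
#' regressed (OLS, with intercept) on the identities predicted from the
#' pair distances, and the coefficient minimizing the residual variance is
#' returned, together with the post-funnel rate 3c (three rounds of
#' meiosis).
#'
#' @param identity Observed identity per marker pair.
#' @param dist Physical distance per pair (bp).
#' @param grid Candidate per-meiosis coefficients (default 0.5..6 by
#'   0.01 crossovers/Mb).
#' @return List with `c_hat` (per meiosis), `rate3` (= 3 c_hat),
#'   `resid_var`, and the full grid profile.
#' @export
fit_conversion_coefficient <- function(identity, dist,
                                       grid = seq(0.5, 6, by = 0.01)) {
  ok <- is.finite(identity) & is.finite(dist)
  identity <- identity[ok]; dist <- dist[ok]
  if (length(unique(dist)) < 2) stop("need >= 2 distinct pair distances")
  n <- length(identity)
  sy <- sum(identity); syy <- sum(identity^2)
  rv <- vapply(grid, function(cc) {
    p <- predicted_identity(dist, cc)
    sp <- sum(p); spp <- sum(p^2); spy <- sum(p * identity)
    vp <- spp - sp^2 / n
    if (vp <= 0) return(Inf)  # degenerate constant prediction
    beta <- (spy - sp * sy / n) / vp
    (syy - sy^2 / n - beta^2 * vp) / n   # residual variance after OLS
  }, 0)
  if (all(!is.finite(rv))) stop("degenerate predictions on the whole grid")
  k <- which.min(rv)
  list(c_hat = grid[k], rate3 = 3 * grid[k], resid_var = rv[k],
       grid = grid, profile = rv)
}

#' Expected haplotype frequencies from copy weights
#'
#' With default unit weights every haplotype is expected at 1/8. A
#' chromosome carrying an extra copy of one haplotype at the top of the
#' funnel (e.g. weights 1,1,1,1,1,2,1,1) yields 1/9 for the single-copy
#' haplotypes and 2/9 for the duplicated one; LOH regions set a weight to
#' 0 or 3, giving 0 and 3/9.
#'
#' @param weights Non-negative per-haplotype copy weights (length 8,
#'   default all 1).
#' @return Numeric vector of 8 expected frequencies summing to 1.
#' @export
expected_haplotype_freqs <- function(weights = rep(1, 8)) {
  if (length(weights) != 8 || any(weights < 0)) {
    stop("weights must be 8 non-negative values")
  }
  if (sum(weights) == 0) stop("at least one weight must be positive")
  weights / sum(weights)
}
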