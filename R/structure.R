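# Shared intermediate-cross ancestry: haplotype-set masks, pairwise
# discordance distances, complete-linkage clustering.

#' Ancestry mask of a strain for an intermediate population
#'
#' Flags the markers whose haplotype code belongs to the founder set of an
#' intermediate population (e.g. \{1,2\} for the first two-founder
#' population, \{1,2,3,4\} for the first four-founder population): those
#' regions were inherited through that population.
#'
#' @param hap Integer vector of monosomic haplotype codes (NA allowed).
#' @param set Founder-code set of the population.
#' @return Logical vector (NA codes give FALSE).
#' @export
ancestry_mask <- function(hap, set) {
  !is.na(hap) & hap %in% set
}

#' Haplotype discordance between two strains within shared ancestry
#'
#' The proportion of non-matching haplotypes over the markers masked for
#' the population in both strains. 0 is expected when the strains share a
#' single ancestor in that intermediate population; otherwise 0.5
#' (two-founder populations) or 0.75 (four-founder populations).
#'
#' @param hap_a,hap_b Monosomic haplotype code vectors over the same
#'   markers.
#' @param set Founder-code set of the intermediate population.
#' @return List with `discordance` (NA when the joint mask is empty) and
#'   `n_joint` (jointly masked marker count).
#' @export
pairwise_discordance <- function(hap_a, hap_b, set) {
  joint <- ancestry_mask(hap_a, set) & ancestry_mask(hap_b, set)
  n <- sum(joint)
  if (n == 0) return(list(discordance = NA_real_, n_joint = 0L))
  list(discordance = mean(hap_a[joint] != hap_b[joint]), n_joint = n)
}

#' All-pairs discordance matrix for one intermediate population
#'
#' @param haplotypes A [hap_matrix()] or code matrix (strains x markers);
#'   aneuploid strains should be restricted to monosomic chromosomes
#'   before calling (disomic cells are treated as missing).
#' @param set Founder-code set of the population.
#' @param min_joint Pairs with fewer jointly masked markers than this are
#'   reported NA (default 50) to avoid noise-driven clusters.
#' @return List with `D` (symmetric strain x strain discordance, diagonal
#'   0) and `n_joint` (joint mask sizes).
#' @export
discordance_matrix <- function(haplotypes, set, min_joint = 50) {
  H <- hap_codes(haplotypes)
  mask <- !is.na(H) & matrix(H %in% set, nrow(H), ncol(H))
  joint <- tcrossprod(mask)
  match <- matrix(0, nrow(H), nrow(H))
  for (h in set) {
    ind <- !is.na(H) & (H == h)
    match <- match + tcrossprod(ind)
  }
  D <- 1 - match / joint
  D[joint < min_joint] <- NA
  diag(D) <- 0
  rn <- rownames(H)
  dimnames(D) <- list(rn, rn)
  list(D = D, n_joint = joint)
}

#' Cluster strains by shared intermediate ancestry
#'
#' Complete-linkage hierarchical clustering of the discordance distances,
#' cut at `cutoff`; clusters of two or more strains are reported as
#' shared-ancestor groups. Pairs flagged missing (NA) are set to the
#' maximal distance 1 before clustering.
#'
#' @param D Symmetric discordance matrix from [discordance_matrix()].
#' @param cutoff Tree cut height (default 0.25, far from both the
#'   shared-ancestor mode at 0 and the unrelated modes at 0.5/0.75).
#' @return List with `clusters` (list of strain index vectors, size >= 2)
#'   and `membership` (cluster id per strain).
#' @export
cluster_shared_ancestry <- function(D, cutoff = 0.25) {
  D2 <- D
  D2[is.na(D2)] <- 1
  hc <- stats::hclust(stats::as.dist(D2), method = "complete")
  memb <- stats::cutree(hc, h = cutoff)
  sizes <- table(memb)
  big <- as.integer(names(sizes)[sizes >= 2])
  clusters <- lapply(big, function(k) which(memb == k))
  list(clusters = clusters, membership = memb)
}
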