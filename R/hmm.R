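# Eight-state founder-haplotype HMM with funnel-cross transitions.

#' HMM parameters for haplotype inference
#'
#' @param error Per-read emission error probability (default 0.01; the
#'   expected allele is emitted with probability 1 - error).
#' @param c Physical-to-genetic conversion, crossovers per Mb per meiosis
#'   (default 3), used to turn inter-marker distances into recombinant
#'   fractions via Haldane's function.
#' @param read_cutoff Strains with total reads at or below this are
#'   dropped by [infer_haplotypes()] (default 12000).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(error = 0.01, c = 3, read_cutoff = 12000) {
  if (error <= 0 || error >= 0.5) stop("error must be in (0, 0.5)")
  if (c < 0) stop("c must be >= 0")
  structure(list(error = error, c = c, read_cutoff = read_cutoff),
            class = "hmm_params")
}

#' Haldane's mapping function
#'
#' Converts genetic distance m (Morgans) to the recombinant fraction
#' R = 0.5 (1 - exp(-2m)) under a no-interference Poisson crossover model.
#'
#' @param m Genetic distance in Morgans (>= 0).
#' @return Recombinant fraction in [0, 0.5).
#' @examples
#' haldane_r(0.03)       # 3 cM
#' haldane_r(3)          # 1 Mb at 3 crossovers/Mb, nearly unlinked
#' @export
haldane_r <- function(m) {
  if (any(m < 0)) stop("genetic distance must be >= 0")
  0.5 * (1 - exp(-2 * m))
}

# level-1 partner and level-2 quartet lookup for a design
funnel_topology <- function(design) {
  partner <- integer(8)
  for (p in design$level1) {
    partner[p[1]] <- p[2]; partner[p[2]] <- p[1]
  }
  quartet <- integer(8)
  for (k in 1:2) quartet[design$level2[[k]]] <- k
  list(partner = partner, quartet = quartet)
}

#' Funnel-cross transition matrix between founder haplotypes
#'
#' Probability that adjacent markers in a final mapping strain carry
#' haplotypes i and j, given per-meiosis recombinant fraction R and the
#' three-level funnel topology. From haplotype i: staying requires no net
#' crossover in any of the three meioses, (1-R)^3; moving to i's level-1
#' partner requires a crossover at level 1 only, R(1-R)^2; moving to
#' either haplotype of the other level-1 pair in i's quartet has
#' probability R(1-R)/2 each; moving to any of the four haplotypes of the
#' other quartet has probability R/4 each. Rows sum to 1.
#'
#' @param R Recombinant fraction per meiosis, in [0, 0.5].
#' @param design A [cross_design()] (topology only).
#' @return An 8x8 row-stochastic matrix.
#' @export
funnel_transition_matrix <- function(R, design = cross_design()) {
  if (R < 0 || R > 0.5) stop("R must be in [0, 0.5]")
  topo <- funnel_topology(design)
  T <- matrix(R / 4, 8, 8)
  for (i in 1:8) {
    same_quartet <- which(topo$quartet == topo$quartet[i])
    T[i, same_quartet] <- R * (1 - R) / 2
    T[i, topo$partner[i]] <- R * (1 - R)^2
    T[i, i] <- (1 - R)^3
  }
  T
}

#' Per-site emission log-likelihood of a founder haplotype
#'
#' Reads are treated as independent Bernoulli trials: each read matches
#' the founder's expected allele with probability 1 - error. A site with
#' zero coverage contributes 0 (uninformative) to every state.
#'
#' @param n_ref,n_alt Reads supporting the reference / alternative allele.
#' @param founder_allele 0 (founder carries reference) or 1 (alternative).
#' @param params An [hmm_params()].
#' @return Log-likelihood.
#' @export
emission_loglik <- function(n_ref, n_alt, founder_allele,
                            params = hmm_params()) {
  if (any(n_ref < 0) || any(n_alt < 0)) stop("counts must be >= 0")
  match <- ifelse(founder_allele == 1, n_alt, n_ref)
  mism <- ifelse(founder_allele == 1, n_ref, n_alt)
  match * log(1 - params$error) + mism * log(params$error)
}

# site x 8 emission log-likelihood matrix for one strain's chromosome
emission_matrix <- function(n_ref, n_alt, founders, error) {
  # founders: m x 8 0/1; match counts = n_alt where founder==1 else n_ref
  m_alt <- matrix(n_alt, length(n_alt), 8)
  m_ref <- matrix(n_ref, length(n_ref), 8)
  match <- ifelse(founders == 1, m_alt, m_ref)
  mism <- ifelse(founders == 1, m_ref, m_alt)
  match * log(1 - error) + mism * log(error)
}

# interval recombinant fractions from physical distances
interval_R <- function(pos, c_rate) {
  haldane_r(c_rate * diff(pos) / 1e6)
}

# 8x8 template classifying transitions: 1 = other quartet (R/4),
# 2 = other pair in quartet (R(1-R)/2), 3 = level-1 partner (R(1-R)^2),
# 4 = stay ((1-R)^3)
transition_classes <- function(design) {
  topo <- funnel_topology(design)
  cls <- matrix(1L, 8, 8)
  for (i in 1:8) {
    cls[i, topo$quartet == topo$quartet[i]] <- 2L
    cls[i, topo$partner[i]] <- 3L
    cls[i, i] <- 4L
  }
  cls
}

# per-interval 8x8 log-transition matrices, built once per chromosome
# (shared across strains) from the four distinct class probabilities
monosome_ltrans <- function(Rs, design) {
  cls <- transition_classes(design)
  lapply(Rs, function(R) {
    lv <- c(log(R / 4), log(R * (1 - R) / 2),
            log(R) + 2 * log1p(-R), 3 * log1p(-R))
    matrix(lv[cls], 8, 8)
  })
}

disome_ltrans <- function(Rs, design) {
  st <- disome_states()
  I1 <- st[, 1]; I2 <- st[, 2]
  dg <- which(I1 == I2)
  lapply(Rs, function(R) {
    T1 <- funnel_transition_matrix(R, design)
    T2 <- T1[I1, I1] * T1[I2, I2] + T1[I1, I2] * T1[I2, I1]
    T2[, dg] <- T2[, dg] / 2   # the two ordered terms coincide when k == l
    log(T2)
  })
}

# generic log-space Viterbi (compiled kernel); emis: m x S, ltrans: list
# of (m-1) S x S log matrices; uniform initial distribution; ties broken
# toward the smallest state index
viterbi_core <- function(emis, ltrans) {
  viterbi_cpp(emis, ltrans)
}

#' Viterbi haplotype decoding of one monosomic chromosome
#'
#' Decodes the most probable founder haplotype path from per-marker allele
#' counts under the eight-state funnel HMM: uniform initial distribution,
#' Bernoulli-read emissions, and per-interval funnel transition matrices
#' with R derived from the physical distance (Haldane, `c` crossovers per
#' Mb per meiosis).
#'
#' @param n_ref,n_alt Integer vectors of per-marker allele counts for one
#'   strain, restricted to one chromosome.
#' @param markers The matching rows of the `marker_table` (same order).
#' @param params An [hmm_params()].
#' @param design A [cross_design()] (topology).
#' @return Integer vector of haplotype codes 1..8, one per marker.
#' @export
viterbi_chromosome <- function(n_ref, n_alt, markers,
                               params = hmm_params(),
                               design = cross_design()) {
  m <- length(n_ref)
  if (m == 0) stop("empty marker set")
  stopifnot(length(n_alt) == m, nrow(markers) == m)
  if (length(unique(markers$chrom)) != 1) {
    stop("viterbi_chromosome expects markers from a single chromosome")
  }
  emis <- emission_matrix(n_ref, n_alt, founder_cols(markers),
                          params$error)
  ltr <- monosome_ltrans(interval_R(markers$pos, params$c), design)
  viterbi_core(emis, ltr)
}

# unordered founder pairs (i <= j), the 36 disome states
disome_states <- function() {
  st <- which(upper.tri(matrix(0, 8, 8), diag = TRUE), arr.ind = TRUE)
  st <- st[order(st[, "row"], st[, "col"]), , drop = FALSE]
  cbind(i = st[, "row"], j = st[, "col"])
}

# collapse the product of two independent monosome transitions onto
# unordered pairs
disome_transition_matrix <- function(R, design = cross_design()) {
  T1 <- funnel_transition_matrix(R, design)
  st <- disome_states()
  S <- nrow(st)
  T2 <- matrix(0, S, S)
  for (a in seq_len(S)) {
    i <- st[a, 1]; j <- st[a, 2]
    for (b in seq_len(S)) {
      k <- st[b, 1]; l <- st[b, 2]
      T2[a, b] <- if (k == l) T1[i, k] * T1[j, k]
                  else T1[i, k] * T1[j, l] + T1[i, l] * T1[j, k]
    }
  }
  T2
}

#' Viterbi haplotype decoding of one disomic chromosome
#'
#' Decodes over the 36 unordered founder-pair states. The emission for
#' pair \{i,j\} is the equal mixture of the two homolog allele models
#' (each read picks a homolog uniformly); the transition for ordered pairs
#' is the product of two independent monosome transitions, collapsed to
#' unordered pairs.
#'
#' @inheritParams viterbi_chromosome
#' @return Integer matrix with columns `hap1`, `hap2` (hap1 <= hap2), one
#'   row per marker.
#' @export
viterbi_disome <- function(n_ref, n_alt, markers,
                           params = hmm_params(),
                           design = cross_design()) {
  m <- length(n_ref)
  if (m == 0) stop("empty marker set")
  stopifnot(length(n_alt) == m, nrow(markers) == m)
  e <- params$error
  fo <- founder_cols(markers)
  p_alt_f <- ifelse(fo == 1, 1 - e, e)       # m x 8 per-homolog model
  st <- disome_states()
  S <- nrow(st)
  p_alt <- (p_alt_f[, st[, 1], drop = FALSE] +
              p_alt_f[, st[, 2], drop = FALSE]) / 2  # m x 36 mixture
  emis <- n_alt * log(p_alt) + n_ref * log(1 - p_alt)
  ltr <- disome_ltrans(interval_R(markers$pos, params$c), design)
  path <- viterbi_core(emis, ltr)
  cbind(hap1 = st[path, 1], hap2 = st[path, 2])
}

#' Infer founder haplotypes for a set of strains
#'
#' Applies [viterbi_chromosome()] (copy number 1) or [viterbi_disome()]
#' (copy number 2) per strain and chromosome. Strains whose total read
#' count is at or below `params$read_cutoff` are excluded and reported in
#' attribute `"dropped"`.
#'
#' @param counts An [allele_counts()] (markers x strains).
#' @param markers The matching `marker_table`.
#' @param ploidy Integer matrix (strains x chromosomes) of copy numbers
#'   1/2, as from [call_ploidy()]; NULL treats every chromosome as
#'   monosomic.
#' @param params An [hmm_params()].
#' @param design A [cross_design()].
#' @return A [hap_matrix()] for the retained strains.
#' @export
infer_haplotypes <- function(counts, markers, ploidy = NULL,
                             params = hmm_params(),
                             design = cross_design()) {
  stopifnot(inherits(counts, "allele_counts"))
  if (nrow(counts$ref) != nrow(markers)) {
    stop("dimension mismatch between counts and markers")
  }
  total <- colSums(counts$ref) + colSums(counts$alt)
  keep <- which(total > params$read_cutoff)
  dropped <- counts$strains[total <= params$read_cutoff]
  if (length(keep) == 0) {
    warning("all strains excluded by the read-count cutoff")
    hm <- hap_matrix(matrix(NA_integer_, 0, nrow(markers)),
                     strains = character(0))
    attr(hm, "dropped") <- dropped
    return(hm)
  }
  chroms <- unique(markers$chrom)
  n <- length(keep)
  hap1 <- matrix(NA_integer_, n, nrow(markers))
  hap2 <- matrix(NA_integer_, n, nrow(markers))
  any_dis <- FALSE
  st <- disome_states()
  e <- params$error
  for (ch in chroms) {
    idx <- which(markers$chrom == ch)
    fo <- founder_cols(markers)[idx, , drop = FALSE]
    Rs <- interval_R(markers$pos[idx], params$c)
    ltr_mono <- monosome_ltrans(Rs, design)
    ltr_dis <- NULL  # built lazily, only if a disomic strain needs it
    p_alt_f <- ifelse(fo == 1, 1 - e, e)
    for (s in seq_len(n)) {
      col <- keep[s]
      cn <- if (is.null(ploidy)) 1L else ploidy[col, ch]
      nr <- counts$ref[idx, col]; na <- counts$alt[idx, col]
      if (cn >= 2L) {
        if (is.null(ltr_dis)) ltr_dis <- disome_ltrans(Rs, design)
        p_alt <- (p_alt_f[, st[, 1], drop = FALSE] +
                    p_alt_f[, st[, 2], drop = FALSE]) / 2
        emis <- na * log(p_alt) + nr * log(1 - p_alt)
        path <- viterbi_core(emis, ltr_dis)
        hap1[s, idx] <- st[path, 1]; hap2[s, idx] <- st[path, 2]
        any_dis <- TRUE
      } else {
        emis <- emission_matrix(nr, na, fo, e)
        hap1[s, idx] <- viterbi_core(emis, ltr_mono)
      }
    }
  }
  hm <- hap_matrix(hap1, if (any_dis) hap2 else NULL,
                   strains = counts$strains[keep])
  attr(hm, "dropped") <- dropped
  hm
}
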