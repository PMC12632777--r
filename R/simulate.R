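# Synthetic funnel-cross generator.
#
# A haploid genome is stored as a per-chromosome list of "copies"; each
# copy is a mosaic list(ends, hap): segment i covers positions
# (ends[i-1], ends[i]] with founder code hap[i]. Euploid chromosomes have
# one copy, disomic chromosomes two.

new_mosaic <- function(ends, hap) list(ends = ends, hap = as.integer(hap))

#' Intact founder genome
#'
#' @param layout A `genome_layout`.
#' @param code Founder code 1..8.
#' @return A haploid genome: named per-chromosome list, each a list of one
#'   mosaic (`ends`, `hap`).
#' @export
founder_strain <- function(layout, code) {
  stopifnot(code %in% 1:8)
  out <- lapply(layout$length, function(L) list(new_mosaic(L, code)))
  names(out) <- layout$chrom
  out
}

# haplotype codes of one mosaic at sorted positions
mosaic_at <- function(m, pos) {
  m$hap[findInterval(pos - 0.5, m$ends) + 1L]
}

# recombine two single-copy mosaics: Poisson(c * L/1e6) crossovers,
# breakpoints uniform, template chosen by fair coin at the left end
meiose_chrom <- function(mA, mB, L, c_rate) {
  nx <- stats::rpois(1, c_rate * L / 1e6)
  first <- sample(2L, 1)
  if (nx == 0) return(if (first == 1L) mA else mB)
  bounds <- c(sort(stats::runif(nx, 0, L)), L)
  src <- rep_len(if (first == 1L) c(1L, 2L) else c(2L, 1L), length(bounds))
  ends <- numeric(0); hap <- integer(0)
  lo <- 0
  for (k in seq_along(bounds)) {
    hi <- bounds[k]
    m <- if (src[k] == 1L) mA else mB
    i1 <- findInterval(lo, m$ends) + 1L      # first segment with end > lo
    i2 <- findInterval(hi, m$ends, left.open = TRUE) + 1L  # first end >= hi
    ends <- c(ends, pmin(m$ends[i1:i2], hi))
    hap <- c(hap, m$hap[i1:i2])
    lo <- hi
  }
  n <- length(hap)
  keep <- c(hap[-1] != hap[-n], TRUE)  # merge adjacent same-code segments
  new_mosaic(ends[keep], hap[keep])
}

#' Simulate one meiosis between two haploid parents
#'
#' Crossover counts are Poisson with mean `c` per Mb per gamete (no
#' interference, no obligate crossover), breakpoints uniform; the gamete
#' alternates parental origin at breakpoints starting from a fair-coin
#' choice. With this convention Haldane's function with m = c d / 1e6
#' Morgans is exact for the recombinant fraction between two loci d bp
#' apart.
#'
#' @param parent_a,parent_b Haploid genomes as from [founder_strain()]
#'   (single-copy chromosomes).
#' @param layout A `genome_layout`.
#' @param c Crossovers per Mb per meiosis (default 3).
#' @param seed Optional RNG seed.
#' @return A haploid genome (gamete).
#' @export
simulate_meiosis <- function(parent_a, parent_b, layout, c = 3,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (c < 0) stop("crossover rate must be >= 0")
  out <- vector("list", nrow(layout))
  names(out) <- layout$chrom
  for (i in seq_len(nrow(layout))) {
    out[[i]] <- list(meiose_chrom(parent_a[[i]][[1]], parent_b[[i]][[1]],
                                  layout$length[i], c))
  }
  out
}

# gamete of a diploid whose chromosomes may carry 2 (normal) or >= 3
# (trisomic) copies; with k >= 3 copies, 2 intact copies transmit with
# probability disome_rate, else 1 (copies sampled uniformly without
# replacement; no crossover is modelled on such chromosomes)
diploid_gamete <- function(copiesA, copiesB, layout, c_rate, disome_rate) {
  out <- vector("list", nrow(layout))
  names(out) <- layout$chrom
  for (i in seq_len(nrow(layout))) {
    copies <- c(copiesA[[i]], copiesB[[i]])
    k <- length(copies)
    if (k == 2L) {
      out[[i]] <- list(meiose_chrom(copies[[1]], copies[[2]],
                                    layout$length[i], c_rate))
    } else {
      ntr <- if (stats::runif(1) < disome_rate) 2L else 1L
      out[[i]] <- copies[sample.int(k, ntr)]
    }
  }
  out
}

#' Simulate a founder marker panel
#'
#' Marker count per chromosome is Poisson with mean length /
#' `bp_per_marker` (at least 1), positions uniform (then sorted), and each
#' marker's minor-allele carrier count is drawn from the sharing spectrum,
#' with carriers chosen uniformly among the eight founders. Carriers get
#' the alternative allele.
#'
#' @param layout A `genome_layout`.
#' @param options A [sim_options()].
#' @param seed Optional RNG seed.
#' @return A [marker_table()].
#' @export
simulate_founder_markers <- function(layout, options = sim_options(),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- character(0); pos <- integer(0)
  for (i in seq_len(nrow(layout))) {
    L <- layout$length[i]
    n <- max(1L, stats::rpois(1, L / options$bp_per_marker))
    n <- min(n, L)  # positions are distinct integers in 1..L
    pos <- c(pos, sort(sample.int(L, n)))
    chrom <- c(chrom, rep(layout$chrom[i], n))
  }
  m <- length(pos)
  ncar <- sample(4L, m, replace = TRUE, prob = options$sharing_spectrum)
  fo <- matrix(0L, m, 8)
  for (k in 1:4) {
    idx <- which(ncar == k)
    for (j in idx) fo[j, sample.int(8, k)] <- 1L
  }
  marker_table(chrom, pos, ref = rep("A", m), alt = rep("C", m),
               founders = fo)
}

# build the 1-3 chromosome copies of the level-1 diploid affected by a
# scripted trisomy: the extra copy duplicates `extra_hap`, with optional
# LOH intervals overwritten by another haplotype
trisomy_copies <- function(trisomy, pair, L) {
  extra <- new_mosaic(L, trisomy$extra_hap)
  if (!is.null(trisomy$loh) && nrow(trisomy$loh) > 0) {
    loh <- trisomy$loh[order(trisomy$loh$start), , drop = FALSE]
    ends <- numeric(0); hap <- integer(0); lo <- 0
    for (r in seq_len(nrow(loh))) {
      s <- max(0, loh$start[r] - 1); e <- min(L, loh$end[r])
      if (s > lo) { ends <- c(ends, s); hap <- c(hap, trisomy$extra_hap) }
      ends <- c(ends, e); hap <- c(hap, loh$hap[r])
      lo <- e
    }
    if (lo < L) { ends <- c(ends, L); hap <- c(hap, trisomy$extra_hap) }
    keep <- c(hap[-1] != hap[-length(hap)], TRUE)
    extra <- new_mosaic(ends[keep], hap[keep])
  }
  list(new_mosaic(L, pair[1]), new_mosaic(L, pair[2]), extra)
}

#' Simulate a three-level funnel cross
#'
#' Level 1 mates the four fixed founder pairs; each level-1 diploid yields
#' a pool of `pool_size` haploid gametes per mating type. Levels 2 and 3
#' mate random pairs drawn with replacement from the opposite-mating-type
#' pools of the appropriate populations. Final strains are gametes of
#' level-3 diploids. If a trisomy event is configured, the designated
#' level-1 diploid carries an extra copy of the stated haplotype (with LOH
#' intervals applied) and transmission of that chromosome samples intact
#' copies, emitting disomic gametes at rate `disome_rate`.
#'
#' @param design A [cross_design()].
#' @param layout A `genome_layout` (default [sc_genome()]).
#' @param options A [sim_options()] (recorded; read-count parameters are
#'   consumed by [simulate_read_counts()]).
#' @param seed Optional RNG seed.
#' @param keep_pools Keep the intermediate haploid pools in the result
#'   (memory-heavy; used for lineage-conservation checks).
#' @return An object of class `funnel_pop`: list with `strains` (haploid
#'   genomes), `ploidy` (strains x chromosomes copy numbers), `lineage`
#'   (per-strain ancestor indices in each intermediate pool), `design`,
#'   `layout`, and (optionally) `pools`.
#' @export
simulate_funnel <- function(design, layout = sc_genome(),
                            options = sim_options(), seed = NULL,
                            keep_pools = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(design, "cross_design"))
  ps <- design$pool_size
  c_rate <- design$c
  tri <- design$trisomy
  dis_rate <- if (is.null(tri)) 0 else tri$disome_rate
  if (!is.null(tri) && !(tri$chrom %in% layout$chrom)) {
    stop("trisomy chromosome not in layout")
  }
  pop_names <- names(population_sets(design))  # 4 G1 then 2 G2 labels

  # --- level 1: four founder-pair diploids -> pools of gametes ---
  # anc vectors map pool slots to distinct ancestor ids (non-trivial only
  # under a bottleneck, where slots are resampled from k distinct strains)
  g1_pools <- vector("list", 4)
  g1_anc <- vector("list", 4)
  for (q in 1:4) {
    pair <- design$level1[[q]]
    da <- founder_strain(layout, pair[1])
    db <- founder_strain(layout, pair[2])
    if (!is.null(tri) && tri$g1_pop == q) {
      ic <- match(tri$chrom, layout$chrom)
      co <- trisomy_copies(tri, pair, layout$length[ic])
      da[[ic]] <- co[1]; db[[ic]] <- co[2:3]
    }
    n <- 2L * ps
    if (!is.null(design$bottleneck) &&
        design$bottleneck$pop == pop_names[q]) {
      k <- design$bottleneck$k
      distinct <- lapply(seq_len(k), function(j)
        diploid_gamete(da, db, layout, c_rate, dis_rate))
      pick <- sample.int(k, n, replace = TRUE)
      g1_pools[[q]] <- distinct[pick]
      g1_anc[[q]] <- pick
    } else {
      g1_pools[[q]] <- lapply(seq_len(n), function(j)
        diploid_gamete(da, db, layout, c_rate, dis_rate))
      g1_anc[[q]] <- seq_len(n)
    }
  }

  # --- level 2: two quartet populations ---
  # quartet r is the union of level-1 pools qa, qb
  g2_pools <- vector("list", 2)
  g2_lineage <- vector("list", 2)
  g2_anc <- vector("list", 2)
  for (r in 1:2) {
    quartet <- design$level2[[r]]
    qs <- which(vapply(design$level1, function(p) all(p %in% quartet), TRUE))
    n <- 2L * ps
    if (!is.null(design$bottleneck) &&
        design$bottleneck$pop == pop_names[4 + r]) {
      k <- design$bottleneck$k
      ia <- sample.int(2L * ps, k, replace = TRUE)
      ib <- sample.int(2L * ps, k, replace = TRUE)
      pick <- sample.int(k, n, replace = TRUE)
      gam <- lapply(seq_len(k), function(j)
        diploid_gamete(g1_pools[[qs[1]]][[ia[j]]],
                       g1_pools[[qs[2]]][[ib[j]]],
                       layout, c_rate, dis_rate))
      g2_pools[[r]] <- gam[pick]
      g2_lineage[[r]] <- cbind(pa = g1_anc[[qs[1]]][ia[pick]],
                               pb = g1_anc[[qs[2]]][ib[pick]])
      g2_anc[[r]] <- pick
    } else {
      ia <- sample.int(2L * ps, n, replace = TRUE)
      ib <- sample.int(2L * ps, n, replace = TRUE)
      g2_pools[[r]] <- lapply(seq_len(n), function(j)
        diploid_gamete(g1_pools[[qs[1]]][[ia[j]]],
                       g1_pools[[qs[2]]][[ib[j]]],
                       layout, c_rate, dis_rate))
      g2_lineage[[r]] <- cbind(pa = g1_anc[[qs[1]]][ia],
                               pb = g1_anc[[qs[2]]][ib])
      g2_anc[[r]] <- seq_len(n)
    }
  }

  # --- level 3: final mapping strains ---
  nf <- design$n_final
  i1 <- sample.int(2L * ps, nf, replace = TRUE)  # parent in G2 pool 1
  i2 <- sample.int(2L * ps, nf, replace = TRUE)  # parent in G2 pool 2
  strains <- vector("list", nf)
  ploidy <- matrix(1L, nf, nrow(layout),
                   dimnames = list(NULL, layout$chrom))
  for (s in seq_len(nf)) {
    g <- diploid_gamete(g2_pools[[1]][[i1[s]]], g2_pools[[2]][[i2[s]]],
                        layout, c_rate, dis_rate)
    strains[[s]] <- g
    ploidy[s, ] <- lengths(g)
  }
  lineage <- data.frame(
    strain = paste0("strain", seq_len(nf)),
    g1_a1 = g2_lineage[[1]][i1, "pa"], g1_a2 = g2_lineage[[1]][i1, "pb"],
    g1_b1 = g2_lineage[[2]][i2, "pa"], g1_b2 = g2_lineage[[2]][i2, "pb"],
    g2_a = g2_anc[[1]][i1], g2_b = g2_anc[[2]][i2])
  # label lineage columns by the intermediate populations they index
  q1 <- which(vapply(design$level1, function(p)
    all(p %in% design$level2[[1]]), TRUE))
  q2 <- which(vapply(design$level1, function(p)
    all(p %in% design$level2[[2]]), TRUE))
  names(lineage)[2:7] <- c(pop_names[q1], pop_names[q2],
                           pop_names[5], pop_names[6])

  pop <- structure(list(strains = strains, ploidy = ploidy,
                        lineage = lineage, design = design,
                        layout = layout, options = options),
                   class = "funnel_pop")
  if (keep_pools) pop$pools <- c(g1_pools, g2_pools)
  pop
}

#' @export
print.funnel_pop <- function(x, ...) {
  ndis <- sum(rowSums(x$ploidy > 1) > 0)
  cat("funnel_pop:", length(x$strains), "strains on",
      nrow(x$layout), "chromosomes;", ndis, "aneuploid\n")
  invisible(x)
}

#' True haplotypes of a simulated population at given markers
#'
#' @param pop A `funnel_pop`.
#' @param markers A `marker_table` (or data.frame with `chrom`, `pos`).
#' @param subset Optional marker row indices.
#' @return A [hap_matrix()] (with `hap2` filled on disomic chromosomes).
#' @export
true_haplotypes <- function(pop, markers, subset = NULL) {
  if (!is.null(subset)) markers <- markers[subset, , drop = FALSE]
  nf <- length(pop$strains)
  m <- nrow(markers)
  hap1 <- matrix(NA_integer_, nf, m)
  hap2 <- matrix(NA_integer_, nf, m)
  idx_by_chrom <- split(seq_len(m), markers$chrom)
  for (ch in names(idx_by_chrom)) {
    idx <- idx_by_chrom[[ch]]
    pos <- markers$pos[idx]
    for (s in seq_len(nf)) {
      copies <- pop$strains[[s]][[ch]]
      h1 <- mosaic_at(copies[[1]], pos)
      if (length(copies) > 1) {
        h2 <- mosaic_at(copies[[2]], pos)
        sw <- h2 < h1
        tmp <- h1[sw]; h1[sw] <- h2[sw]; h2[sw] <- tmp
        hap2[s, idx] <- h2
      }
      hap1[s, idx] <- h1
    }
  }
  if (all(is.na(hap2))) hap2 <- NULL
  hm <- hap_matrix(hap1, hap2, strains = pop$lineage$strain)
  colnames(hm$hap1) <- paste0(markers$chrom, "_", markers$pos)
  if (!is.null(hm$hap2)) colnames(hm$hap2) <- colnames(hm$hap1)
  hm
}

#' Remove strains violating a two-locus viability rule
#'
#' Emulates synthetic-lethal / synthetic-viable selection: a rule over the
#' haplotype pair at two loci decides survival; non-surviving strains are
#' removed from the population.
#'
#' @param pop A `funnel_pop`.
#' @param markers A `marker_table` used to locate the two loci.
#' @param lethal A list with `chrom_a`, `pos_a`, `chrom_b`, `pos_b` and
#'   `rule`, a vectorized function(h_a, h_b) returning TRUE for survivors.
#' @return The filtered `funnel_pop`; the number of removed strains is in
#'   attribute `"removed"`.
#' @export
apply_viability_filter <- function(pop, markers, lethal) {
  need <- c("chrom_a", "pos_a", "chrom_b", "pos_b", "rule")
  if (!all(need %in% names(lethal))) {
    stop("lethal spec needs elements: ", paste(need, collapse = ", "))
  }
  loc <- data.frame(chrom = c(lethal$chrom_a, lethal$chrom_b),
                    pos = c(lethal$pos_a, lethal$pos_b))
  h <- true_haplotypes(pop, loc)
  surv <- lethal$rule(h$hap1[, 1], h$hap1[, 2])
  if (anyNA(surv)) stop("viability rule returned NA")
  if (!any(surv)) stop("empty population: viability rule removed all strains")
  out <- pop
  out$strains <- pop$strains[surv]
  out$ploidy <- pop$ploidy[surv, , drop = FALSE]
  out$lineage <- pop$lineage[surv, , drop = FALSE]
  attr(out, "removed") <- sum(!surv)
  out
}

#' Simulate low-coverage allele counts
#'
#' Per strain x marker, sequencing depth is Poisson with the configured
#' mean times the chromosome copy number; each read reports the allele
#' implied by the strain's haplotype with probability 1 - error, else the
#' other allele. For disomic chromosomes each read first picks one
#' homolog uniformly.
#'
#' @param haplotypes A [hap_matrix()] (true or inferred).
#' @param markers The matching `marker_table`.
#' @param options A [sim_options()] (`mean_depth`, `error_rate`).
#' @param seed Optional RNG seed.
#' @return An [allele_counts()] (markers x strains).
#' @export
simulate_read_counts <- function(haplotypes, markers,
                                 options = sim_options(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(haplotypes, "hap_matrix"))
  if (ncol(haplotypes$hap1) != nrow(markers)) {
    stop("haplotype matrix and marker table dimensions disagree")
  }
  e <- options$error_rate
  fo <- founder_cols(markers)
  n <- nrow(haplotypes$hap1); m <- ncol(haplotypes$hap1)
  midx <- rep(seq_len(m), each = n)  # cells in strain-major order per marker
  a1 <- fo[cbind(midx, as.vector(haplotypes$hap1))]
  p_alt <- ifelse(a1 == 1, 1 - e, e)
  copies <- rep(1, n * m)
  if (!is.null(haplotypes$hap2)) {
    h2 <- as.vector(haplotypes$hap2)
    dis <- !is.na(h2)
    a2 <- fo[cbind(midx[dis], h2[dis])]
    p2 <- ifelse(a2 == 1, 1 - e, e)
    p_alt[dis] <- (p_alt[dis] + p2) / 2  # reads pick a homolog uniformly
    copies[dis] <- 2                     # depth scales with copy number
  }
  depth <- stats::rpois(n * m, options$mean_depth * copies)
  depth[is.na(p_alt)] <- 0L  # no call, no informative reads
  p_alt[is.na(p_alt)] <- 0
  alt <- stats::rbinom(n * m, depth, p_alt)
  ref <- depth - alt
  # reshape to markers x strains
  ref <- matrix(ref, nrow = n); alt <- matrix(alt, nrow = n)
  allele_counts(t(ref), t(alt), strains = haplotypes$strains)
}
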