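# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

fix_get <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# small two-chromosome genome for fast unit tests
tiny_layout <- function() genome_layout(c("c1", "c2"), c(4e5, 3e5))

tiny_markers <- function() {
  fix_get("tiny_markers", function()
    simulate_founder_markers(tiny_layout(), sim_options(), seed = 11))
}

tiny_pop <- function() {
  fix_get("tiny_pop", function()
    simulate_funnel(cross_design(pool_size = 100, n_final = 300),
                    tiny_layout(), sim_options(), seed = 12))
}

tiny_truth <- function() {
  fix_get("tiny_truth", function()
    true_haplotypes(tiny_pop(), tiny_markers()))
}

# medium population on the full genome layout, shared by the design-level
# acceptance checks (haplotype balance, discordance, conversion fit)
accept_pop <- function() {
  fix_get("accept_pop", function()
    simulate_funnel(cross_design(pool_size = 576, n_final = 2000),
                    sc_genome(), sim_options(), seed = 101))
}

accept_markers <- function() {
  fix_get("accept_markers", function()
    simulate_founder_markers(sc_genome(), sim_options(), seed = 102))
}

accept_scaffold <- function() {
  fix_get("accept_scaffold", function()
    select_scaffold(accept_markers(), 2000))
}

accept_scaffold_hap <- function() {
  fix_get("accept_scaffold_hap", function()
    true_haplotypes(accept_pop(), accept_markers(),
                    subset = as.integer(accept_scaffold())))
}

# score of one state path under the HMM, used by the brute-force oracle
path_score <- function(path, emis, ltrans) {
  s <- emis[1, path[1]] - log(ncol(emis))
  if (length(path) > 1) {
    for (t in 2:length(path)) {
      s <- s + ltrans[[t - 1]][path[t - 1], path[t]] + emis[t, path[t]]
    }
  }
  s
}

# exhaustive maximization over all S^L state sequences; returns the best
# score (enumeration grids are cached per (S, L))
brute_best_score <- function(emis, ltrans) {
  S <- ncol(emis); L <- nrow(emis)
  key <- paste0("grid_", S, "_", L)
  paths <- fix_get(key, function()
    as.matrix(expand.grid(rep(list(seq_len(S)), L))))
  score <- emis[cbind(1L, paths[, 1])] - log(S)
  if (L > 1) {
    for (t in 2:L) {
      score <- score + ltrans[[t - 1]][paths[, c(t - 1, t)]] +
        emis[cbind(t, paths[, t])]
    }
  }
  max(score)
}

# random founder table rows on one chromosome (for HMM instances)
random_chrom_markers <- function(L, chrom = "c1", spacing_max = 5e4) {
  pos <- sort(sample.int(spacing_max * L, L))
  fo <- matrix(0L, L, 8)
  for (i in seq_len(L)) fo[i, sample.int(8, sample(1:4, 1))] <- 1L
  marker_table(rep(chrom, L), pos, rep("A", L), rep("C", L), fo)
}

# direct two-likelihood LOD evaluation (normal ML fits), the algebraic
# oracle for the (n/2) log10(RSS0/RSS1) identity
lod_direct <- function(y, hap) {
  ok <- !is.na(hap)
  y <- y[ok]; g <- factor(hap[ok])
  n <- length(y)
  loglik <- function(res) {
    s2 <- mean(res^2)
    sum(stats::dnorm(res, 0, sqrt(s2), log = TRUE))
  }
  lA <- loglik(y - mean(y))
  mu <- tapply(y, g, mean)
  lB <- loglik(y - mu[g])
  (lB - lA) / log(10)
}

# design-sized population (11,392 strains) for the power/resolution study
xl_pop <- function() {
  fix_get("xl_pop", function()
    simulate_funnel(cross_design(pool_size = 576, n_final = 11392),
                    sc_genome(), sim_options(), seed = 201))
}

xl_scaffold_hap <- function() {
  fix_get("xl_scaffold_hap", function()
    true_haplotypes(xl_pop(), accept_markers(),
                    subset = as.integer(accept_scaffold())))
}
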