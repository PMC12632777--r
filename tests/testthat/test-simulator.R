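test_that("founder marker panels match the requested density and sharing spectrum", {
  lay <- genome_layout("c1", 2.2e6)
  mt <- simulate_founder_markers(lay, sim_options(), seed = 1)
  # marker count ~ Poisson(length / 44): within 4 sd
  expected <- 2.2e6 / 44
  expect_lt(abs(nrow(mt) - expected), 4 * sqrt(expected))
  expect_true(all(diff(mt$pos) > 0))

  # private spectrum: every marker has exactly one carrier
  mt1 <- simulate_founder_markers(lay, sim_options(
    sharing_spectrum = c(1, 0, 0, 0)), seed = 2)
  expect_true(all(rowSums(founder_cols(mt1)) == 1))

  # default spectrum: empirical carrier-class fractions near
  # 0.774/0.130/0.0673/0.028 (binomial 4 sd)
  carriers <- rowSums(founder_cols(mt))
  frac <- tabulate(carriers, 4) / nrow(mt)
  target <- c(0.774, 0.130, 0.0673, 0.028) / sum(c(0.774, 0.130, 0.0673, 0.028))
  for (k in 1:4) {
    se <- sqrt(target[k] * (1 - target[k]) / nrow(mt))
    expect_lt(abs(frac[k] - target[k]), 4 * se)
  }
})

test_that("a marker panel is produced even when the density exceeds a chromosome", {
  lay <- genome_layout(c("small", "big"), c(30, 1e5))
  mt <- simulate_founder_markers(lay, sim_options(bp_per_marker = 1e4),
                                 seed = 3)
  expect_gte(sum(mt$chrom == "small"), 1)
})

test_that("meiosis without crossovers returns an intact parental chromosome", {
  lay <- genome_layout("c1", 1e6)
  pa <- founder_strain(lay, 1)
  pb <- founder_strain(lay, 2)
  g <- simulate_meiosis(pa, pb, lay, c = 0, seed = 4)
  expect_length(g$c1[[1]]$hap, 1)
  expect_true(g$c1[[1]]$hap %in% c(1L, 2L))
})

test_that("crossover counts and recombinant fractions match the Poisson/Haldane model", {
  lay <- genome_layout("c1", 1e6)
  pa <- founder_strain(lay, 1)
  pb <- founder_strain(lay, 2)
  set.seed(5)
  n <- 4000
  nx <- numeric(n)
  rec <- logical(n)  # different founder at the two ends, 1 Mb apart
  for (i in seq_len(n)) {
    g <- simulate_meiosis(pa, pb, lay, c = 3)$c1[[1]]
    nx[i] <- length(g$hap) - 1
    rec[i] <- g$hap[1] != g$hap[length(g$hap)]
  }
  # mean crossovers ~ 3 per Mb (observed junction count underestimates
  # crossovers only by coincidental same-parent rejoins, which cannot
  # happen with two parents of distinct codes)
  expect_lt(abs(mean(nx) - 3), 3 * sd(nx) / sqrt(n))
  # Haldane closed form at m = 3: R = 0.5 (1 - e^-6) ~ 0.498761
  r_target <- 0.5 * (1 - exp(-6))
  se <- sqrt(r_target * (1 - r_target) / n)
  expect_lt(abs(mean(rec) - r_target), 3 * se)
})

test_that("funnel progeny are balanced mosaics of all eight founders", {
  hm <- tiny_truth()
  freq <- apply(hm$hap1, 2, tabulate, nbins = 8) / nrow(hm$hap1)
  genomewide <- rowMeans(freq)
  # per-strain genome fractions give the effective SE of each mean
  for (h in 1:8) {
    frac_h <- rowMeans(hm$hap1 == h)
    se <- sd(frac_h) / sqrt(length(frac_h))
    expect_lt(abs(genomewide[h] - 1 / 8), 4 * se)
  }
  expect_equal(sum(genomewide), 1)
})

test_that("every haplotype segment is traceable to the recorded lineage", {
  des <- cross_design(pool_size = 20, n_final = 40)
  lay <- tiny_layout()
  pop <- simulate_funnel(des, lay, sim_options(), seed = 13,
                         keep_pools = TRUE)
  mt <- tiny_markers()
  hm <- true_haplotypes(pop, mt)
  sets <- population_sets(des)
  # in regions with codes {1,2}, the strain must carry its recorded
  # G1_1-2 ancestor's haplotype exactly
  g1_pool <- pop$pools[[1]]
  for (s in c(1, 17, 40)) {
    anc <- g1_pool[[pop$lineage[s, "G1_1-2"]]]
    in12 <- which(hm$hap1[s, ] %in% sets[["G1_1-2"]])
    for (ch in unique(mt$chrom[in12])) {
      idx <- in12[mt$chrom[in12] == ch]
      anc_codes <- funnelcross:::mosaic_at(anc[[ch]][[1]], mt$pos[idx])
      expect_identical(unname(hm$hap1[s, idx]), anc_codes)
    }
  }
})

test_that("a pool bottleneck of size 1 forces a shared ancestor on all strains", {
  des <- cross_design(pool_size = 30, n_final = 25,
                      bottleneck = list(pop = "G1_1-2", k = 1))
  pop <- simulate_funnel(des, tiny_layout(), sim_options(), seed = 14)
  expect_true(all(pop$lineage[["G1_1-2"]] == pop$lineage[["G1_1-2"]][1]))
  # discordance in the shared region is exactly 0 for every pair
  hm <- true_haplotypes(pop, tiny_markers())
  dm <- discordance_matrix(hm, c(1, 2), min_joint = 20)
  off <- dm$D[upper.tri(dm$D)]
  expect_true(all(off[!is.na(off)] == 0))
})

test_that("seeded simulations are exactly reproducible", {
  des <- cross_design(pool_size = 15, n_final = 10)
  a <- simulate_funnel(des, tiny_layout(), sim_options(), seed = 99)
  b <- simulate_funnel(des, tiny_layout(), sim_options(), seed = 99)
  expect_identical(true_haplotypes(a, tiny_markers())$hap1,
                   true_haplotypes(b, tiny_markers())$hap1)
  mt1 <- simulate_founder_markers(tiny_layout(), sim_options(), seed = 7)
  mt2 <- simulate_founder_markers(tiny_layout(), sim_options(), seed = 7)
  expect_identical(mt1$pos, mt2$pos)
})

test_that("viability filtering removes rule violators and rejects empty results", {
  pop <- tiny_pop()
  mt <- tiny_markers()
  sc <- select_scaffold(mt)
  loci <- mt[c(sc[3], sc[length(sc) - 2]), ]
  lethal <- list(chrom_a = loci$chrom[1], pos_a = loci$pos[1],
                 chrom_b = loci$chrom[2], pos_b = loci$pos[2],
                 rule = function(h1, h2) (h1 == 8) == (h2 == 8))
  filt <- apply_viability_filter(pop, mt, lethal)
  h <- true_haplotypes(filt, loci)
  joint <- table(factor(h$hap1[, 1], levels = 1:8),
                 factor(h$hap1[, 2], levels = 1:8))
  expect_equal(sum(joint[8, 1:7]) + sum(joint[1:7, 8]), 0)
  expect_gt(joint[8, 8], 0)
  expect_equal(length(filt$strains) + attr(filt, "removed"),
               length(pop$strains))

  # always-true rule leaves the population unchanged
  ok <- apply_viability_filter(pop, mt, modifyList(lethal, list(
    rule = function(h1, h2) rep(TRUE, length(h1)))))
  expect_equal(length(ok$strains), length(pop$strains))
  # removing everything is an error
  expect_error(apply_viability_filter(pop, mt, modifyList(lethal, list(
    rule = function(h1, h2) rep(FALSE, length(h1))))), "empty population")
})

test_that("read-count sampling matches depth, error rate and disome mixing", {
  mt <- tiny_markers()[1:400, ]
  class(mt) <- c("marker_table", "data.frame")
  hm <- hap_matrix(matrix(rep(1:4, each = 400), 4, 400, byrow = TRUE))
  cts <- simulate_read_counts(hm, mt, sim_options(mean_depth = 3.8),
                              seed = 21)
  depth <- cts$ref + cts$alt
  expect_lt(abs(mean(depth) - 3.8), 4 * sqrt(3.8 / length(depth)))

  # error 0.01 at deep coverage: mismatch fraction ~ 0.01
  deep <- simulate_read_counts(hm, mt, sim_options(mean_depth = 60),
                               seed = 22)
  fo <- founder_cols(mt)
  mism <- 0; tot <- 0
  for (s in 1:4) {
    truth_alt <- fo[, s]  # strain s is founder s everywhere
    mism <- mism + sum(ifelse(truth_alt == 1, deep$ref[, s], deep$alt[, s]))
    tot <- tot + sum(deep$ref[, s] + deep$alt[, s])
  }
  expect_lt(abs(mism / tot - 0.01), 4 * sqrt(0.01 * 0.99 / tot))

  # disome {i,j} at a discriminating site: reads split evenly between
  # the two homolog alleles
  priv <- which(fo[, 5] == 1 & fo[, 6] == 0)[1]
  mt1 <- mt[priv, ]
  class(mt1) <- c("marker_table", "data.frame")
  hmd <- hap_matrix(matrix(5L, 1, 1), matrix(6L, 1, 1))
  cc <- simulate_read_counts(hmd, mt1,
                             sim_options(mean_depth = 4000,
                                         error_rate = 0.01), seed = 23)
  n <- cc$ref[1, 1] + cc$alt[1, 1]
  expect_lt(abs(cc$alt[1, 1] / n - 0.5), 4 * sqrt(0.25 / n))
})

test_that("a scripted top-of-funnel trisomy elevates the duplicated haplotype", {
  lay <- tiny_layout()
  # extra copy of haplotype 6 on c2 in the {5,6} level-1 diploid, with an
  # LOH interval where the extra copy reverts to haplotype 5
  tri <- list(chrom = "c2", g1_pop = 3, extra_hap = 6,
              loh = data.frame(start = 1, end = 6e4, hap = 5),
              disome_rate = 0.5)
  des <- cross_design(pool_size = 200, n_final = 1500, trisomy = tri)
  pop <- simulate_funnel(des, lay, sim_options(), seed = 31)
  expect_true(any(pop$ploidy[, "c2"] == 2L))
  expect_true(all(pop$ploidy[, "c1"] == 1L))

  mt <- tiny_markers()
  eu <- which(pop$ploidy[, "c2"] == 1L)
  on_c2 <- which(mt$chrom == "c2" & mt$pos > 1e5)  # outside the LOH region
  sub <- pop
  sub$strains <- pop$strains[eu]
  sub$ploidy <- pop$ploidy[eu, , drop = FALSE]
  sub$lineage <- pop$lineage[eu, , drop = FALSE]
  hm <- true_haplotypes(sub, mt, subset = on_c2)
  freq <- rowMeans(apply(hm$hap1, 2, tabulate, nbins = 8)) /
    length(eu)
  # copy pool is 9 founder chromosomes: single-copy haplotypes near 1/9,
  # the duplicated haplotype near 2/9 (euploid conditioning gives a small
  # bias; +/-0.02 absolute)
  expect_lt(abs(freq[1] - 1 / 9), 0.02)
  expect_lt(abs(freq[6] - 2 / 9), 0.035)
  # inside the LOH region the extra copy is haplotype 5: 5 and 6 swap
  in_loh <- which(mt$chrom == "c2" & mt$pos < 6e4)
  hm2 <- true_haplotypes(sub, mt, subset = in_loh)
  freq2 <- rowMeans(apply(hm2$hap1, 2, tabulate, nbins = 8)) /
    length(eu)
  expect_gt(freq2[5], freq2[6])
})
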