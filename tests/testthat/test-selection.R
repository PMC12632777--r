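test_that("haplotype counts tabulate strains per founder", {
  H <- matrix(1:8, 8, 2)
  counts <- haplotype_counts(H)
  expect_equal(unname(counts[1, ]), rep(1L, 8))
  H2 <- matrix(NA_integer_, 4, 1)
  c2 <- haplotype_counts(H2)
  expect_equal(sum(c2), 0)
  expect_equal(attr(c2, "empty"), 1L)
})

test_that("the inflation divisor is recovered for Poisson and 31x-overdispersed counts", {
  set.seed(92)
  mu <- 1400  # ~ n/8 for a design-sized population at a marker
  # pure Poisson: no inflation
  cal1 <- estimate_inflation_divisor(rpois(4000, mu))
  expect_lte(cal1$divisor, 2)
  # Poisson mixture with variance ~ 31x the mean: gamma-Poisson with
  # shape mu/30 has variance mu + 30 mu = 31 mu
  lam <- rgamma(4000, shape = mu / 30, rate = 1 / 30)
  over <- rpois(4000, lam)
  cal31 <- estimate_inflation_divisor(over)
  expect_lt(abs(cal31$divisor - 31), 0.1 * 31)
  expect_lt(abs(cal31$slope - 1), 0.1)
  expect_error(estimate_inflation_divisor(rep(5, 500)), "equal")
  expect_error(estimate_inflation_divisor(rpois(50, 5)), ">= 100")
})

test_that("single-marker goodness of fit is exact on matched counts", {
  counts <- matrix(125, 4, 8)  # exactly n/8 each
  res <- single_marker_scan(counts)
  expect_equal(res$statistic, rep(0, 4))
  expect_equal(res$p, rep(1, 4))
  expect_false(any(res$significant))
  # region-specific expectations with a zero class: statistic 0 when the
  # counts match 1/9..3/9 exactly, df reduced to 6
  w <- expected_haplotype_freqs(c(1, 1, 1, 1, 0, 3, 1, 1))
  cIX <- matrix(900 * w, 1, 8)
  res2 <- single_marker_scan(cIX, expected_freqs = w)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$df, 6L)
  # the divisor scales the statistic linearly
  off <- matrix(c(200, rep(100, 7)), 1, 8)
  s1 <- single_marker_scan(off)$statistic
  s31 <- single_marker_scan(off, divisor = 31)$statistic
  expect_equal(s31, s1 / 31)
})

test_that("a viability-selected locus is flagged by the calibrated single-marker scan", {
  pop <- accept_pop()
  mt <- accept_markers()
  sc <- as.integer(accept_scaffold())
  ia <- sc[mt$chrom[sc] == "chrIV"][20]
  ib <- sc[mt$chrom[sc] == "chrX"][20]
  lethal <- list(chrom_a = mt$chrom[ia], pos_a = mt$pos[ia],
                 chrom_b = mt$chrom[ib], pos_b = mt$pos[ib],
                 rule = function(h1, h2) (h1 == 8) == (h2 == 8))
  filt <- apply_viability_filter(pop, mt, lethal)
  hm <- true_haplotypes(filt, mt, subset = sc)
  counts <- haplotype_counts(hm)
  cal <- estimate_inflation_divisor(counts)
  res <- single_marker_scan(counts, divisor = cal$divisor)
  sa <- which(sc == ia); sb <- which(sc == ib)
  expect_true(res$significant[sa])
  expect_true(res$significant[sb])
  # after dividing out the cross-structure inflation, markers far from
  # the selected loci are overwhelmingly null
  near <- abs(mt$pos[sc] - mt$pos[ia]) < 1e5 & mt$chrom[sc] == "chrIV"
  near <- near | (abs(mt$pos[sc] - mt$pos[ib]) < 1e5 &
                    mt$chrom[sc] == "chrX")
  expect_lt(mean(res$significant[!near]), 0.01)
})

test_that("the pairwise statistic matches closed forms and is symmetric", {
  # perfectly associated diagonal table: statistic (k-1) n
  h <- rep(1:8, each = 25)
  ps <- pairwise_chisq(h, h)
  expect_equal(ps$statistic, 7 * 200)
  expect_equal(ps$df, 49L)
  # symmetry and relabeling invariance
  set.seed(93)
  a <- sample(1:8, 500, replace = TRUE)
  b <- sample(1:8, 500, replace = TRUE)
  expect_equal(pairwise_chisq(a, b)$statistic,
               pairwise_chisq(b, a)$statistic)
  perm <- sample(8)
  expect_equal(pairwise_chisq(perm[a], perm[b])$statistic,
               pairwise_chisq(a, b)$statistic, tolerance = 1e-12)
  # independent uniform haplotypes: mean ~ df = 49
  stats <- replicate(300, {
    x <- sample(1:8, 400, replace = TRUE)
    y <- sample(1:8, 400, replace = TRUE)
    pairwise_chisq(x, y)$statistic
  })
  expect_lt(abs(mean(stats) - 49), 3 * sd(stats) / sqrt(300))
  # agreement with the standard contingency-table implementation
  tab <- table(factor(a, levels = 1:8), factor(b, levels = 1:8))
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(pairwise_chisq(a, b)$statistic, unname(ref$statistic))
})

test_that("log-linear null calibration recovers an injected transform", {
  set.seed(94)
  base <- rchisq(5000, 49)
  # identity when the statistics are already chi-square(49)
  cal0 <- calibrate_pairwise_null(base)
  expect_lt(abs(cal0$b - 1), 0.05)
  expect_lt(abs(cal0$a), 0.1)
  # inflated a * x^b statistics are mapped back to the null scale
  a0 <- 2.5; b0 <- 1.3
  infl <- a0 * base^b0
  cal <- calibrate_pairwise_null(infl)
  expect_lt(abs(cal$b - b0), 0.05)
  expect_lt(abs(cal$a - log(a0)), 0.15)
  back <- cal$transform(infl)
  fit <- lm(sort(back)[1:4500] ~ qchisq((1:4500 - 0.5) / 5000, 49))
  expect_lt(abs(coef(fit)[2] - 1), 0.05)
  expect_error(calibrate_pairwise_null(rchisq(100, 49)), ">= 1000")
})

test_that("Holm cutoff follows the step-down rule", {
  expect_equal(holm_cutoff(0.01, alpha = 0.05), 0.05)  # single rejected test
  expect_equal(holm_cutoff(0.2, alpha = 0.05), 0)      # single accepted test
  # {0.001, 0.02, 0.9}: step 1 rejects (0.001 <= 0.05/3), step 2 rejects
  # (0.02 <= 0.05/2), step 3 accepts; cutoff is the failed boundary 0.05/1
  p <- c(0.001, 0.02, 0.9)
  cut <- holm_cutoff(p, alpha = 0.05)
  expect_equal(cut, 0.05)
  expect_equal(p < cut, c(TRUE, TRUE, FALSE))
  expect_equal(holm_cutoff(rep(1, 10)), 0)
  # agreement with p.adjust: rejections are identical
  set.seed(95)
  pv <- c(runif(50, 0, 1e-4), runif(50))
  cut2 <- holm_cutoff(pv, 0.05)
  expect_equal(pv < cut2, p.adjust(pv, "holm") < 0.05)
})

test_that("an injected lethal pair is detected by the pairwise scan", {
  lay <- genome_layout(paste0("c", 1:4), rep(3e5, 4))
  opts <- sim_options()
  mt <- simulate_founder_markers(lay, opts, seed = 96)
  sc <- as.integer(select_scaffold(mt, 20000))  # ~60 scan markers
  des <- cross_design(pool_size = 300, n_final = 1500)
  pop <- simulate_funnel(des, lay, opts, seed = 97)
  ia <- sc[8]; ib <- sc[40]
  stopifnot(mt$chrom[ia] != mt$chrom[ib])
  lethal <- list(chrom_a = mt$chrom[ia], pos_a = mt$pos[ia],
                 chrom_b = mt$chrom[ib], pos_b = mt$pos[ib],
                 rule = function(h1, h2) (h1 == 8) == (h2 == 8))
  filt <- apply_viability_filter(pop, mt, lethal)
  hm <- true_haplotypes(filt, mt, subset = sc)
  res <- pairwise_scan(hm, mt$chrom[sc])
  hit <- res[res$i == 8 & res$j == 40, ]
  expect_true(hit$significant)
  # the synthetic-viability pattern: off-diagonal haplotype-8 cells empty
  ps <- pairwise_chisq(hm$hap1[, 8], hm$hap1[, 40])
  expect_equal(sum(ps$table[8, 1:7]) + sum(ps$table[1:7, 8]), 0)
  # marginal haplotype-8 deficit is co-detected at both loci
  counts <- haplotype_counts(hm)
  sm <- single_marker_scan(counts)
  expect_true(sm$significant[8])
  expect_true(sm$significant[40])
})

test_that("the pairwise scan controls errors on null populations", {
  lay <- genome_layout(paste0("c", 1:4), rep(3e5, 4))
  opts <- sim_options()
  mt <- simulate_founder_markers(lay, opts, seed = 98)
  sc <- as.integer(select_scaffold(mt, 20000))
  nruns <- 12
  false_hits <- integer(nruns)
  for (r in seq_len(nruns)) {
    des <- cross_design(pool_size = 300, n_final = 400)
    pop <- simulate_funnel(des, lay, opts, seed = 1000 + r)
    hm <- true_haplotypes(pop, mt, subset = sc)
    res <- pairwise_scan(hm, mt$chrom[sc])
    false_hits[r] <- sum(res$significant, na.rm = TRUE)
  }
  # family-wise control at 5%: at most one of 12 runs with any hit
  expect_lte(sum(false_hits > 0), 1)
})
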