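---
title: "Models and methods for eight-founder funnel-cross mapping populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for eight-founder funnel-cross mapping populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

funnelcross simulates and analyses large multiparent mapping populations
built by a three-level "funnel" cross of eight haploid yeast founders:
four fixed founder pairs are mated, their pooled haploid progeny are
mated across pools to form two four-founder populations, and one final
round of pooled mating and sporulation yields haploid strains that are
recombinant mosaics of all eight founder genomes. This vignette explains
the models behind each stage, the tunable parameters, and the numerical
and design choices made where more than one convention was defensible.

## The synthetic funnel cross

`simulate_funnel()` is the package's ground-truth generator. Its defaults
are the study conditions the analyses are meant for:

* **Marker panel** (`simulate_founder_markers()`): one biallelic SNV per
  44 bp on average, with the minor allele carried by 1, 2, 3 or 4
  founders in proportions 0.774 / 0.130 / 0.0673 / 0.028 and carriers
  chosen uniformly. Positions are uniform within chromosomes. The
  default genome is the 16-chromosome S288c reference layout (~12.07
  Mb), so the default panel has ~270k markers.
* **Crossovers**: per meiosis and per gamete, crossover counts on a
  chromosome of length $d$ bp are Poisson with mean $c\,d/10^6$
  (default $c = 3$ crossovers/Mb), breakpoints uniform, no interference
  and no obligate crossover. The crossover process acts on the gamete,
  so the recombinant fraction between two loci at distance $d$ is
  exactly Haldane's $R = \tfrac12(1 - e^{-2m})$ with $m = c\,d/10^6$
  Morgans. This is the only convention under which the identity-decay
  model below is exact for the simulator, and it is the convention the
  analysis stages assume.
* **Pools**: each intermediate population keeps `pool_size` haploids per
  mating type (default 576); level-2 and level-3 matings draw random
  pairs with replacement from the opposite-mating-type pools. The
  pairing distribution within a pool is not part of the cross design
  proper; uniform random mating is assumed, and the `bottleneck`
  option exists precisely to perturb it (it collapses one pool to `k`
  distinct ancestors).
* **Read counts** (`simulate_read_counts()`): per strain and marker,
  depth is Poisson with mean 3.8 (times the chromosome copy number) and
  each read reports the true allele with probability 0.99. Reads on
  disomic chromosomes pick one homolog uniformly first.

Every stage takes an explicit seed; identical seeds reproduce identical
populations. The truth record (lineage of every final strain through the
intermediate pools, plus per-chromosome copy numbers) is what makes
parameter-recovery testing of the downstream stages possible.

What the generator deliberately does **not** emulate: sequence-level
artifacts (no reads, indels or structural variants), linkage
disequilibrium among founder alleles (carriers are drawn independently
per marker), chromosome-scale recombination-rate variation, mapping bias
near telomeres, and strain-to-strain depth variation beyond Poisson.
Passing recovery tests on synthetic data therefore demonstrates the
correctness of the algorithms under the stated model, not robustness to
every artifact of real sequencing data.

### The scripted trisomy

A known feature of the real cross this design emulates is an extra copy
of one chromosome in a level-1 diploid: the `trisomy` option places a
duplicated copy of one founder haplotype (with optional LOH intervals
overwritten by the homolog) in the designated level-1 diploid. Any
subsequent meiosis whose diploid carries three copies of that chromosome
transmits two intact copies with probability `disome_rate` (default 0.5)
and one otherwise, copies sampled uniformly; crossovers are not modelled
on the trisomic chromosome. With nine founder copies of the chromosome
in the top of the funnel, uniform copy sampling makes the expected
frequency of each copy 1/9 — hence 1/9 for the six unaffected
haplotypes, 2/9 for the duplicated one, and 0 or 3/9 inside LOH
intervals, which is exactly what `expected_haplotype_freqs()` returns
for the matching weight vectors. Conditioning on *euploid* final strains
biases these frequencies slightly (by about ±0.01, toward the
non-duplicated side), because euploidy is more likely for strains that
inherited the chromosome through a 2-copy diploid; the package treats
the weight-based expectations as the reference, as the analyses do.
Aneuploidy from any source other than the scripted trisomy is not
simulated; euploid recovery tests are therefore clean by construction.

## Haplotype inference

`infer_haplotypes()` decodes each strain's founder-of-origin mosaic from
sparse allele counts with an eight-state hidden Markov model, one state
per founder haplotype.

* **Emissions.** At a marker, a read matches the allele its founder
  state implies with probability $1 - \epsilon$ (default
  $\epsilon = 0.01$). Reads are treated as independent Bernoulli
  trials, so a site with $k$ matching and $j$ mismatching reads
  contributes $k\log(1-\epsilon) + j\log\epsilon$; the product form
  reduces to the single-read statement when depth is 1. Sites with no
  coverage contribute 0 to every state — they are carried, not imputed
  away.
* **Transitions.** For adjacent markers $d$ bp apart, $R$ is Haldane's
  function at $m = c\,d/10^6$. The funnel topology then fixes the
  transition law: staying on haplotype $i$ requires no net crossover in
  any of the three meioses, probability $(1-R)^3$; switching to $i$'s
  level-1 partner requires a crossover at level 1 only, $R(1-R)^2$;
  switching to either haplotype of the other level-1 pair inside $i$'s
  level-2 quartet has probability $R(1-R)/2$ each; and switching to any
  of the four haplotypes of the other quartet has probability $R/4$
  each. These are exact for the simulator because the founder sets of
  the three levels are disjoint (a "switch away and back" across levels
  cannot restore the same founder), and the row sums are identically 1.
  This law is the unique one consistent with the two pinned
  probabilities above and row normalization.
* **Decoding.** Viterbi in log space with a uniform initial
  distribution (the design's stationary distribution is uniform for all
  $R$). Ties are broken toward the smallest haplotype index so output
  is deterministic. Posterior (forward–backward) decoding is
  deliberately not offered: the mosaic, not per-site uncertainty, is
  the product.
* **Disomic chromosomes.** Chromosomes called at copy number 2 are
  decoded over the 36 unordered founder pairs: the emission for pair
  $\{i,j\}$ is the equal mixture of the two homolog models (reads pick
  a homolog uniformly), and the transition is the product of two
  independent monosome transitions collapsed onto unordered pairs.
  This treats the homologs as recombining independently, which matches
  the simulator's transmission model.
* **Quality gate.** Strains with total read count at or below
  `read_cutoff` (default 12,000) are dropped and reported rather than
  decoded.

The test suite checks the decoder against exhaustive enumeration of all
$8^L$ (monosome) and $36^L$ (disome) state sequences on short random
instances, and against simulation truth at 3.8x depth, where marker-level
accuracy exceeds 99%.

## Ploidy and the scaffold

Copy number is called per strain and chromosome from the mean total
allele count per marker, normalized by the strain's median chromosome
depth; a chromosome is disomic when its normalized depth is at or above
1.5, the midpoint of the expected euploid (1.0) and disomic (2.0)
values. Depth is computed from marker-site counts because counts are
this package's input; with ~1 marker per 44 bp this is a dense proxy for
full-read depth, and ploidy recovery on simulations is exact at 3.8x.
Copy numbers above 2 are not called.

The scaffolding subset (`select_scaffold()`) thins the panel for
statistical scans: per chromosome, start at the first marker and
repeatedly take the first marker at least `spacing` bp away (default
2000). "At least 2 kb apart" is interpreted as an inclusive position
difference (≥ 2000); the convention must be fixed one way for the
selection to be reproducible, and inclusive is the literal reading of
the rule. The selection is deterministic and idempotent, and
`scaffold_coverage()` reports the fraction of the genome (between each
chromosome's first and last marker) within a radius of a scaffold
marker — about 98% at 2 kb for a default-density panel.

## Identity decay and the genetic map

For two markers on the same chromosome, a final strain shows the same
haplotype at both exactly when no net haplotype change occurred in any
of the three meioses, so identity decays as $I(d) = (1-R(d))^3$, from 1
at $d = 0$ to $1/8$ for unlinked markers (which equals the matching
probability of two independent draws from eight equifrequent
haplotypes). `fit_conversion_coefficient()` estimates the
physical-to-genetic conversion $c$ by grid search (default 0.5–6
crossovers/Mb per meiosis in steps of 0.01): for each candidate, the
observed pair identities are regressed by OLS (with intercept — the
regression is of observed on predicted identity, and the intercept
absorbs any small calibration offset) on the predicted ones, and the
candidate minimizing residual variance wins. The post-funnel rate is
reported as $3\hat c$, three rounds of meiosis. Pairs are taken from the
scaffold subset, all same-chromosome pairs, subsampled to at most 200k
pairs for the grid search; the subsampling policy has no visible effect
on the fit at these scales. A derivative-free grid is used because the
profile is smooth but the residual variance is cheap to evaluate and the
grid makes the estimator trivially reproducible.

## Population structure

A haplotype code identifies the full inheritance path through the
funnel: codes in {1,2} passed through the first two-founder population,
codes in {1,2,3,4} through the first four-founder population, and so
on. For a pair of strains, `pairwise_discordance()` measures the
proportion of non-matching haplotypes over the markers masked for the
same intermediate population in both strains. Expected values are 0 when
the pair shares a single ancestor strain in that population, 0.5 for
unrelated pairs in two-founder (G1) populations and 0.75 in four-founder
(G2) populations.

`cluster_shared_ancestry()` applies complete-linkage hierarchical
clustering to the discordance distances and cuts at 0.25 — far from
both the shared-ancestor mode at 0 and the unrelated modes at 0.5/0.75.
The cutoff is a package decision (visual cutting is not reproducible),
and it is configurable. Two numerical guards matter: pairs whose joint
mask has fewer than `min_joint` markers (default 50) are reported
missing, and missing pairs enter clustering at the maximal distance 1.
Because the joint mask of an unrelated pair spans few independent
segments, single pairs can fall below the cutoff by chance; complete
linkage keeps such chance pairs from growing into sizeable clusters, so
shared-ancestor groups are read from clusters rather than from
individual pairs.

## QTL power and resolution

`lod_score()` compares a single-normal-mean model with a model fitting a
separate mean for each observed haplotype class at a marker, both with
maximum-likelihood (divide-by-$n$) variance estimates, giving
$\mathrm{LOD} = (n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$ — with ML
variances this identity is exact, whereas REML-style denominators would
change LOD slightly. Haplotype classes with no strains contribute no
parameter; strains missing at a marker are dropped there. The scan
kernel is compiled (`genome_scan()` vectorizes over phenotypes) and the
candidate marker is the scan argmax, ties toward the smaller index.

Phenotypes are simulated on the biallelic genotype of a causative SNV,
not on an eight-level haplotype effect:
$y = \beta(g - \bar g) + \varepsilon$ with
$\beta = \sqrt{h^2/(f(1-f))}$ and normal residuals orthogonalized to
the genotype and rescaled, so every phenotype has mean 0, variance 1
and exactly a fraction $h^2$ explained by the marker. The exact
decomposition (rather than residuals merely drawn with variance
$1-h^2$) treats the stated heritability as a property of each
phenotype; it is the convention under which power curves over an
$h^2$ grid are calibration curves rather than mixtures over realized
effect sizes. Placing the effect on the
SNV allele while scanning on the haplotype factor is intentional: causal
variants are SNVs, and the haplotype factor at the linked scaffold
marker is the instrument that detects them.

Family-wise significance is empirical: `empirical_threshold()` simulates
standard-normal null phenotypes (default 1000 replicates), takes each
replicate's maximum LOD over the scaffold, and returns the 95th
percentile. `power_resolution_experiment()` then draws causative markers
uniformly from the full panel, simulates phenotypes over a heritability
grid, and reports power (candidate LOD at or above the threshold), the
same-chromosome rate of the candidate, and the mean candidate-to-
causative distance among same-chromosome cases. At the design scale
(11,392 strains, ~6k scaffold markers) heritabilities of 0.36% are
detected with ≥95% power and kb-scale resolution. The packaged checks
run this study once at full population size with 200 null replicates and
150 phenotype replicates — sizes chosen to keep the whole suite
desk-scale while leaving the Monte-Carlo error on power near one
percentage point.

## Selection scans

**Single-marker scan.** Haplotype counts at a scaffold marker are
compared with their expectations (1/8 each, or region-specific weights
on a chromosome with a scripted extra copy) by chi-square goodness of
fit. The chi-square null assumes Poisson dispersion, but a mapping
population vastly larger than its intermediate pools has correlated
strains and therefore overdispersed counts.
`estimate_inflation_divisor()` quantifies this: over an integer grid of
divisors, the central 95% of ordered counts (selection being rare, the
bulk reflects the null) is divided by the candidate and regressed on the
order statistics of a simulated Poisson sample with the same mean; the
divisor with Q-Q slope closest to 1 wins. Q-Q regression is used because
the relationship between ordered counts and Poisson quantiles is linear
under pure scale inflation, with slope $\sqrt{k/D}$ for true inflation
$k$ — so the slope-1 divisor recovers $k$. Adjusted counts (counts and
expectations both divided by $D$) give the statistic
$\sum (O_i/D - E_i/D)^2/(E_i/D) = X^2/D$; categories with zero expected
frequency are excluded with the matching df reduction. The Holm
step-down method converts the nominal p-values into a family-wise 0.05
cutoff across markers.

**Pairwise scan.** Independence of haplotypes at two markers is tested
by the Pearson chi-square on the 8×8 joint count table (df 49). Cross
structure inflates these statistics too, and multiplicatively rather
than by a constant: the bottom 95% of inter-chromosomal statistics
(which should be null) are regressed log-log on the matching theoretical
chi-square(49) quantiles, and the inverse of the fitted log-linear map
transforms observed statistics back to the null scale, where Holm again
sets the cutoff. The log-linear form (log statistic linear in log
quantile, with intercept) recovers injected $a\,x^b$ inflation exactly
and reduces to the identity on well-calibrated data. Pairs involving a
chromosome with a scripted extra copy can be calibrated separately,
since their null differs. Intra-chromosomal pairs are scored but only
flagged: linkage, not selection, dominates their statistics.

## Known limitations

* The transition law is derived from the funnel topology; real crosses
  with deviations from the stated pairing scheme need a matching
  `cross_design`.
* No recombination interference and no obligate crossover; chromosomes
  short enough to demand an obligate crossover will show slightly more
  linkage in real data than the model assumes.
* Copy number is capped at 2, and the only scripted aneuploidy source
  is the level-1 trisomy; missegregation elsewhere is not simulated.
* The divisor calibration assumes a common inflation across markers;
  selection affecting many markers at once would bias the central-95%
  window.
* Discordance-based structure detection needs enough jointly masked
  markers per pair (the `min_joint` guard); very sparse scaffolds or
  short genomes make pair-level calls unreliable, as the clustering
  section explains.
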