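---
title: "Local-ancestry deviation scans against a drift null"
author: "AdmixScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-ancestry deviation scans against a drift null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AdmixScan)
```

## The problem

In a recently admixed population, every genomic position carries a *local
ancestry*: which ancestral population the surrounding haplotype segment
descends from. Averaged over a sample, local ancestry fluctuates around the
genome-wide admixture proportion. Two forces move it: genetic drift, which
perturbs every region a little, and post-admixture selection, which can
drag the ancestry of a selected haplotype far above (or below) the mean.
The scientific question this package answers is operational: *is an
observed local-ancestry peak larger than drift can plausibly produce?*

Three components cooperate: a per-SNP deviation test, an analytic model of
how much variance drift contributes (which doubles as an estimator of the
effective population size), and a forward simulator that generates whole
neutral genomes to calibrate the scan's extremes.

## The deviation test

Let $X_{ij} \in \{0,1,2\}$ be the number of target-ancestry alleles of
diploid individual $j$ at SNP $i$, modelled as
$X_{ij} \sim \mathrm{Binomial}(2, p_i)$. With $K$ sampled haplotypes the
MLE is $\hat p_i = \sum_j X_{ij} / K$, and the test of
$H_0\!: p_i = p_0$ against $H_1\!: p_i > p_0$ uses the score statistic

$$ z_i = \frac{\hat p_i - p_0}{\sqrt{p_0 (1-p_0) / K}} $$

with an upper-tail normal p-value. The null proportion $p_0$ is the
genome-wide ancestry mean of the same data (`p0 = "auto"`), which is how a
scan of real data is anchored; a fixed numeric $p_0$ is accepted for
controlled experiments. The default threshold is $P < 10^{-5}$, the
genome-wide cutoff conventionally used for admixture-mapping-style scans of
recently admixed populations; no further multiple-testing correction is
applied, because extremeness is instead judged against simulated neutral
genomes (below).

Three statistic variants are provided because MLE-asymptotics arguments are
agnostic between them: `score` (standard error under $H_0$; the default),
`wald` (standard error at $\hat p_i$; degenerate at $\hat p_i \in \{0,1\}$,
where the implementation falls back to the null SE with a warning), and
`t` (score statistic with a Student reference on $K-1$ df). At $K = 370$
they are nearly indistinguishable at moderate deviations; in the extreme
tail the score variant tracks the exact binomial tail within a factor of
two over $\hat p \in [0.55, 0.70]$, which the test suite asserts against
`pbinom()` directly.

P-values are clamped to the smallest positive double so that
$-\log_{10} P$ plots and JSON serialization stay finite.

## Drift variance and the Ne estimator

Over $T$ generations in a Wright–Fisher population of $N_e$ diploids, an
ancestry proportion starting at $p_0$ keeps expectation $p_0$ and acquires
variance (diffusion approximation)

$$ V_{\text{drift}} = p_0(1-p_0)\left(1 - e^{-T/2N_e}\right). $$

The continuous factor is used as printed in the population-genetic
literature; it differs from the discrete factor
$1-(1-1/2N_e)^T$ by about $1/2N_e$ relatively (a documented comparison
test), i.e. $\sim 10^{-4}$ at the scales of interest. Approximating the
drifted proportion by a Beta with these moments and compounding with
binomial sampling of $K$ haplotypes gives the observable across-SNP
variance of $\hat p_i$:

$$ \mathrm{Var}\!\left(\tfrac{k}{K}\right)
   = \frac{p_0(1-p_0)}{K}\bigl(1 + (K-1)\rho\bigr),
   \qquad \rho = 1 - e^{-T/2N_e}, $$

equivalently $V_{\text{drift}} + (p_0(1-p_0) - V_{\text{drift}})/K$. The
test suite verifies this closed form against numeric quadrature of the
compound distribution ($10^{-8}$ relative) and against $10^5$ Monte-Carlo
Beta-then-binomial draws.

`estimateNe()` solves the matching problem — find the $N_e$ whose model
variance equals the empirical across-SNP variance — in closed form:
$\rho = (K V_{\mathrm{emp}} / p_0(1-p_0) - 1)/(K-1)$,
$N_e = -T / (2\ln(1-\rho))$. A bisection oracle on $\ln N_e$ is kept in the
tests and agrees to $10^{-9}$ relative. Two boundaries are errors rather
than numbers: $V_{\mathrm{emp}} \le p_0(1-p_0)/K$ means no drift signal
above pure sampling noise ($N_e \to \infty$), and
$V_{\mathrm{emp}} \ge p_0(1-p_0)$ exceeds the maximal drift variance.

The empirical variance uses *all* SNPs, linked ones included, with a fixed
population denominator ($1/M$). Linkage does not bias the matching identity
but inflates the estimator's sampling variance: adjacent SNPs share drift,
so the effective number of observations is closer to the number of
independently segregating segments than to the SNP count. With 5,000
genuinely unlinked loci (`simulateDriftLoci()`) the estimator recovers the
true $N_e$ with a sampling SD near 7%; from one linked genome of 189
chromosomes the spread is several-fold larger. `T` is always supplied by
the user — admixture time and effective size are confounded in a single
variance, so joint inference is deliberately out of scope.

## The forward simulator

`simulatePopulation()` is a forward-time Wright–Fisher simulator that
tracks *ancestry tracts* (interval lists per chromosome), not per-SNP
states — this is what makes $N_e = 4500$ over 189 chromosomes and a
million-SNP projection a desk-scale computation (a few seconds per
replicate in compiled code). The model:

* **Founding.** Generation 0 has $2N_e$ haplotypes, each a whole-genome
  single-ancestry founder drawn i.i.d. from the configured proportions
  (defaults 0.521 EUR / 0.442 NAM / 0.037 AFR, a single pulse). Realized
  founder fractions therefore vary binomially between replicates, as they
  would in a finite founding population.
* **Reproduction.** Each offspring draws two parents uniformly with
  replacement (selfing allowed in the default hermaphrodite mode) and one
  recombinant gamete from each. The `two_sex` mode partitions each
  generation into equal female/male breeding pools and samples sex labels
  (e.g. 64 F / 121 M in a sample of 185); it exists for demographic
  fidelity and is ancestry-neutral on autosomes, which is why
  hermaphrodite is the default.
* **Meiosis.** Crossover counts per chromosome are Poisson(length in
  Morgans) with i.i.d. uniform breakpoints — no interference; an
  obligate-crossover model was rejected as an unsupported extra assumption
  at 0.2 M chromosome scale. Gametes are canonicalized (adjacent
  same-ancestry tracts merged), so the tract list is always the minimal
  junction representation.
* **Sampling.** After $T$ generations, `nSample` diploids are drawn
  without replacement. Same seed, same output, bit for bit.

The default genome is 189 chromosomes of 0.2 Morgans (total 37.8 M, close
to the human autosomal map) with a uniform 1 cM/Mb physical scale; SNP
positions are drawn uniformly in bp and mapped linearly to genetic
coordinates (`physicalToGenetic()`), preserving the spatial
autocorrelation of real local-ancestry data at the chosen marker density.
A literal 20-Morgans-per-chromosome genome can be configured
(`chromMorgans = 20`), but 3,780 M of genome is ~100× the human map and is
not the default. Projection of tracts onto SNPs uses half-open intervals
$[\mathrm{start}, \mathrm{end})$; a SNP exactly at a junction belongs to
the right-hand tract, and a SNP at the full chromosome length to the last
tract.

Checks tying the simulator to the analytic model (all in the test suite):
sampled ancestry fractions converge on the configured proportions within
Monte-Carlo error; junction counts match the $L\,T\,(1-\sum_a \alpha_a^2)$
density law for $T \ll N_e$ and are increasing in $T$; and for effectively
unlinked loci the across-replicate variance of sampled fractions matches
`modelObservedVariance()` within ~3 effective standard errors (tolerance
12%, set from an effective-sample-size calculation that accounts for
founder-induced correlation across chromosomes).

## Null calibration

`runNullReplicates()` repeats simulate → project → scan and records, per
replicate, the SNP maximizing $\hat p_i - p_0$ (the signed excess,
matching the upper-tailed test; an absolute-deviation option exists) and
its p-value. Each replicate uses its own realized genome-wide mean as
$p_0$, mirroring the treatment of real data. Replicate seeds derive from
the master seed by seeding R's RNG and drawing distinct integers
(`replicateSeeds()`), so batches are reproducible and order-invariant.
`compareToThreshold()` then renders the decision: a verdict of
"exceeds neutral null" requires the observed extreme to undercut every
neutral replicate's extreme while no neutral replicate breaches the
significance threshold.

Under negligible drift and independent markers the replicate minima follow
the order-statistic law $P(\min p < x) = 1-(1-x)^M$ (`expectedMinP()`);
with linkage and binomial discreteness the minima are stochastically
larger, and the tests assert exactly that one-sided behaviour.

### What the neutral extremes actually look like

A point worth stating plainly, because it bounds what null calibration can
promise: with $K = 370$, $T = 10$, $N_e = 4500$, the marginal SD of a
per-SNP ancestry fraction is $\approx 0.031$, and crossing $P < 10^{-5}$
requires a deviation of $\approx 3.6$ of those SDs. A 37.8 M genome at
$T = 10$ contains on the order of a thousand effectively independent
ancestry blocks, so the *expected number* of neutral threshold crossings
per genome is small but not negligible, and across many replicates some
neutral genomes do breach $10^{-5}$ — this is visible in the acceptance
suite, where the 20-replicate zero-breach check records breaches at the
rate extreme-value theory predicts (the tract simulator's extremes were
verified against an independent per-SNP Wright–Fisher implementation). The
practical consequence: a scan decision should weigh an observed peak
against the *distribution* of neutral extremes (as `compareToThreshold()`
reports), not treat the absence of neutral breaches as guaranteed; a
single fixed threshold is only as calibrated as the replicate count and
marker density behind it.

## Data model and formats

`AncestryCalls` couples a haplotype × SNP integer matrix to a SNP map
(snp_id, chrom, pos_bp strictly increasing per chromosome, optional
genetic position in Morgans — Morgans internally, always) and an ordered
label set (default EUR=0, NAM=1, AFR=2, the LAMP-LD digit convention). Two
dialects are read and written: a TSV with a sample_id column and one row
per haplotype, and a LAMP-LD-style format of two ancestry digits per SNP
per individual line. The digit format's exact layout is a documented
assumption (tools differ and the convention is not standardized), which is
why the reader takes an explicit dialect flag and never guesses. Missing
calls are an error by design: post-QC local-ancestry matrices are
complete, and silently imputing ancestry would corrupt the scan. Sample
sex is carried as metadata only.

## What the generator does and does not emulate

The simulator reproduces: a single admixture pulse, finite-founder
variance, Wright–Fisher drift of tracts, recombination at a uniform map,
and the marker-density-dependent autocorrelation of projected calls. It
does **not** emulate: local-ancestry inference error (calls are exact),
variable recombination maps or hotspots, non-autosomal inheritance,
continuous or multi-pulse migration, assortative mating, or selection.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated demographic model — not robustness to LAMP-LD
miscalls or to demographic misspecification in real data.

## Problem sizes and numerical choices

The shipped experiments use: 20 neutral replicates × 20,000 SNPs for the
null bound; 5,000 unlinked loci per $(T, N_e)$ recovery experiment; 10 full
forward replicates for ancestry conservation; $10^5$ draws for the
Monte-Carlo variance check; 1,000 null SNPs for type-I calibration (at
$K = 370$ the binomial support is discrete enough that the realized size
at $\alpha = 0.05$ is ≈ 0.041, which a 3-SE band at this width accommodates
honestly). Grids for the inversion identity span
$N_e \in [500, 20000]$, $T \in [5, 20]$ at $10^{-6}$ relative tolerance.

Tie-breaks and degenerate inputs: zero-SNP matrices cannot be written;
fewer than two SNPs have no empirical variance; `nSample` must not exceed
$N_e$; proportions are normalized and a proportion vector summing to
anything else is accepted only up to that normalization; the maximum of an
empty significant set is an empty region table, not an error.

## Known limitations

* $T$ must be supplied; it is confounded with $N_e$ in the drift variance.
* The Ne estimator's precision on linked genomes is limited by the number
  of independent segments, not the SNP count; report it with replicate
  spread.
* The zero-breach expectation for neutral replicates is a soft, scale-
  dependent property (see above), not a theorem.
* The uniform bp→Morgan map is a modelling convenience; supplying real
  genetic positions in the SNP map sidesteps it entirely.
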