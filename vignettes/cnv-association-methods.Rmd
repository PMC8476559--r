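---
title: "Copy-number genotyping and case-control association: methods and design"
author: "mrcCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number genotyping and case-control association: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcCNV)
```

# The problem

Multi-allelic copy-number variation (CNV) in immunity-related genes — the
complement genes *C4A*/*C4B*, the chemokine paralogs *CCL3L1*/*CCL3L3*,
*TLR7*, and others — has repeatedly been proposed as a risk factor for
systemic lupus erythematosus (SLE) and other autoimmune diseases. Testing
such associations needs a chain of methods that rarely live in one place:
a quantitative assay readout turned into integer copy-number genotypes, a
case-control test on the resulting categories (with the awkward zero-cell
case that arises when a genotype is absent from one group), a
Hardy-Weinberg equilibrium (HWE) check appropriate for *unphased* total
copy numbers, and an orthogonal confirmation assay. mrcCNV implements that
chain for competitive-PCR measurements with droplet digital PCR (ddPCR)
confirmation, together with a synthetic-cohort generator so that every
stage can be validated against known truth.

# Copy-number calling from competitive PCR

The measurement model: a target gene is co-amplified with a spiked
synthetic competitor that differs at engineered bases, alongside a diploid
control gene (e.g. *IGF1*) with its own competitor. After single-base
extension, peak heights `g_T`, `c_T` (target genomic/competitor) and
`g_I`, `c_I` (control) yield the raw relative copy number

$$ r = \frac{g_T / c_T}{\operatorname{mean}_j \left( g_{I_j} / c_{I_j} \right)}, $$

which is proportional to the true copy number; the spiked amounts cancel
later. When an assay uses two control-gene peak pairs, their ratios are
combined by an arithmetic mean — a symmetric choice that halves the
influence of one weak control peak (the combination rule is not dictated
by the chemistry).

**Standardization.** Raw ratios for a gene are divided by half their
cohort median (`standardizeCN()`), so the median individual scores sCN = 2
by construction. This carries two assumptions worth keeping explicit:

1. *The median individual is diploid for the gene.* If most of a cohort
   carries three copies, the calling grid is shifted and every call is
   wrong by design. The simulated-cohort tests in this package therefore
   use haplotype-class frequencies whose diploid self-convolution puts the
   median at 2 — the same assumption the method makes about real cohorts.
2. *The cohort median falls well inside its copy-number class.* The
   divisor is a sample quantile; when the median sits near the edge of its
   class, the multiplicative noise of the median individual biases the
   divisor by a few percent and erodes accuracy in the outermost bins
   first. This is a property of median standardization, not of the
   implementation.

By default the median pools cases and controls. A per-group option exists
(`callCopyNumbers(..., perGroup = TRUE)`), but pooling is the default
because separate medians would partially absorb a true case-control
copy-number shift into the standardization constants.

**Digitization.** sCN is binned with half-open intervals at x.5
(`digitizeCN()`), equivalent to `floor(sCN + 0.5)` below 6.5. Values at or
above 6.5 are clamped to 6 with a warning rather than rejected: display
tables pool the upper categories anyway, and a hard error on a legitimate
high-copy sample would be worse than a flagged clamp.

**Noise and recovery.** The simulator draws each of the four peaks with
independent multiplicative log-normal noise, $\sigma = \log(1 + CV)$.
Because the raw ratio multiplies four such terms, its coefficient of
variation is close to $2 \times CV$. By the delta method the probability
of a miscall at true copy number $c$ is governed by
$\Phi\!\left(\log\frac{c + 0.5}{c} / 2\sigma\right)$: bins narrow
*relatively* as $c$ grows, so accuracy always degrades first at high copy
number. At a per-peak CV of 2% the expected per-class accuracy for
classes 0-4 exceeds 99.5%, which is what the recovery tests assert; at a
per-peak CV of 5% (ratio CV about 10%) the class-4 accuracy drops to
roughly 80% — near-perfect recovery through class 4 is *not* attainable at
that noise level under this noise model, and the package does not claim
it. The per-peak CV of a real assay is not published for this chemistry;
the generator's default of 5% is a deliberately conservative stand-in and
is configurable everywhere it appears.

**QC.** `qcFilter()` applies the cohort accounting rules in a fixed
order — DNA-quantity exclusions first, then exclusion of any sample with a
failed assay among the required genes — and returns a ledger of counts per
reason, so the arithmetic (e.g. 368 − 5 − 36 = 327 retained cases) is
reproducible and auditable.

**X linkage.** For X-linked genes, males carry one haplotype. Sexes are
standardized as independent strata (`standardizeXLinked()`): females with
an expected median of 2, males with 1. HWE testing is skipped for X-linked
genes, since hemizygotes do not follow the diploid self-convolution model.

# Association testing

`buildContingency()` tabulates digitized copy numbers by group under named
schemes: one column per category with a pooled upper bin (`per_dcn`),
null-genotype status (`null_vs_rest`, 0 vs 1+), or low-copy status
(`low_vs_rest`, 1 vs 2+). Binary schemes keep empty cells — the zero cell
*is* the finding when a genotype is absent from one group.

**Fisher exact.** The two-sided p-value is the total null probability of
tables whose point probability does not exceed the observed one (the
Freeman-Halton definition, which reduces to the classical two-sided test
at k = 2). Three routes are provided: the network algorithm of
`stats::fisher.test`, a direct full enumeration (small tables; doubling as
the package's own exact oracle), and a Monte-Carlo route that samples
tables with fixed margins via `r2dtable` and reports an add-one estimator
with its standard error. All routes use the customary relative tolerance
of 1e-7 when comparing point probabilities, which makes them agree with
each other to numerical precision.

**Chi-squared.** Pearson's statistic with df = k − 1 and no continuity
correction by default; a note flags expected counts below 5, and the test
is never silently replaced by another. That explicitness matters here: in
the published table this package regresses against, the 2x2 p-values are
Fisher-exact values while the multi-category p-values are Pearson
chi-squared values, *regardless of the printed test markers*. The
regression entry point (`regressCountTables()`) therefore reports both
statistics for every table and leaves the choice visible.

**Odds ratios with zero cells.** For a binary table the odds ratio is
$(case_{exp} \cdot control_{unexp}) / (case_{unexp} \cdot control_{exp})$.
With a zero cell the estimate is infinite; the default policy substitutes
1 for the empty cell and flags the result as a *lower bound* (reproducing
the published ">" convention exactly: 17·338/(310·1) = 18.5355). The
Haldane-Anscombe +0.5 correction is available as an alternative; a strict
error policy is available for pipelines that must not see zero cells. The
95% CI is the Woolf log-normal interval and is suppressed after zero-cell
substitution, where it has no meaning.

**Multiple testing.** `bonferroni(p, m)` is exact `min(1, m*p)` arithmetic
with a *declared* family size — the family is a scientific statement, not
something to infer from a vector length. With the published raw value
0.0331 and the declared family of 11 tests, this gives 0.3641; the
published corrected value (0.3938) is not `m*p` for any integer m applied
to the printed raw values, so the package reports its own arithmetic and
documents the discrepancy rather than chasing it.

# Hardy-Weinberg testing for copy-number data

For unphased diploid totals the HWE null is that the total-CN distribution
is the self-convolution of unknown per-haplotype copy-class frequencies
$q_0, \dots, q_{A_{max}}$:
$$ P(k) = \sum_{a+b=k} q_a q_b. $$

`emFit()` estimates q by EM: the E-step assigns each individual with total
k the posterior over unordered class pairs $(a, k-a) \propto q_a q_{k-a}$;
the M-step averages the posterior haplotype counts over the 2n haplotypes.
The log-likelihood trace is stored and checked to be non-decreasing — an
EM identity that doubles as a regression test. Initialization spreads each
observed total over nearby haplotype classes (a smoothed moment start)
with a uniform fallback; for this model the likelihood surface is
well-behaved and the tests verify that the EM solution matches a dense
grid-search maximum over the simplex on all published histograms.

Design choices:

* **Haplotype space.** Default $A_{max} = \lceil k_{max}/2 \rceil$, the
  smallest space that can generate the observed totals. Larger spaces are
  configurable but approach saturation (as many parameters as
  categories), where the test degenerates.
* **Pooling.** Categories with expected counts below 1 are merged from the
  distribution's tails inward before the Pearson sum; pooled labels are
  reported. Display-style pooling ("4-6") is thus mirrored in the test
  when expectation demands it, and never otherwise.
* **Degrees of freedom.** Default (categories − 1) − $A_{max}$, clamped at
  1 with a saturation flag; a categories − 1 rule is available. Because
  df conventions for this family of tests genuinely vary between
  implementations, `hweBootstrap()` offers a parametric bootstrap that
  sidesteps the df question entirely: resample histograms from the fitted
  model, refit, and compare Pearson statistics. The bootstrap p is the
  plain fraction of resampled statistics at or above the observed one.
* **Groups.** Cases and controls are tested separately; a case-control
  design distorts the case genotype distribution whenever the gene is
  associated, so only the control group speaks to population HWE.

Under these conventions the strongly-departing published control
histogram (no null genotypes observed, yet a low-copy excess that forces a
nonzero fitted null-class frequency) rejects at p ≈ 2e-17 — the same
qualitative conclusion as the published 2.0e-13, but the printed HWE
p-values themselves are not reproduced: the cited method's df, pooling and
allele-space conventions are not recoverable from its description, and one
printed value is inconsistent with any self-convolution fit to the printed
counts. The package's conventions are stated here precisely so its numbers
are reproducible going forward.

# Droplet digital PCR quantification

ddPCR partitions a reaction into ~15,000 droplets; template molecules are
Poisson-distributed across them, so the concentration in copies per
droplet is $\hat\lambda = -\log(1 - k/n)$ from the positive count k. The
95% CI propagates the Wilson interval of k/n through the same transform —
the Wilson interval is used because it behaves at k near 0, exactly the
regime of null genotypes. Copy number is
$\mathrm{ploidy}_{ref} \cdot \hat\lambda_{target} / \hat\lambda_{ref}$
against a diploid reference gene, which cancels the droplet volume and
input amount.

The complication this package models explicitly is **probe
cross-reactivity between near-identical paralogs**: the target-channel
amplitude histogram has up to three clusters — negative, a weak
cross-reactive cluster from the homolog, and true positives. Gating
(`gateDroplets()`) finds histogram modes (256 bins by default; adjacent
maxima merge unless the valley between them dips below a fifth of the
lower peak — a prominence rule that ignores sampling wiggles within one
cluster) and thresholds at the minimum-density valley between the two
highest-amplitude modes. One case is undecidable from a single sample's
histogram alone: a null genotype whose only upper cluster is the
cross-reactive one looks bimodal. The gate therefore accepts an amplitude
floor — assay knowledge of the lowest amplitude a true positive can have —
and treats any valley below the floor as "positive cluster absent". The
vendor software this replaces resolves the same ambiguity with manually
placed thresholds; the floor is this package's explicit, recorded version
of that judgment.

Concordance between assays (`cnConcordance()`) is ordinary least squares
with $R^2$ as the squared Pearson correlation. The published concordance
values (R² = 0.9925/0.9912) belong to 16 specific physical samples and are
not reproducible without them; the package instead verifies on simulated
16-sample designs (three per copy-number class 0-4 plus one extra, at 3%
assay noise) that R² ≥ 0.98 in the large majority of runs.

# The synthetic cohort generator

The generator is first-class, tested code — it defines the conditions
under which everything else is validated.

* **Genotypes** are drawn i.i.d. from per-haplotype class frequencies, two
  per autosomal individual, one per X-linked male
  (`sampleGenotypes()`).
* **Case enrichment** is retrospective: the case total-CN distribution is
  the population distribution with the risk category's odds multiplied by
  the target odds ratio and renormalized (`tiltedTotalDistribution()`),
  i.e. weight OR on the risk category and 1 elsewhere. This guarantees the
  designed odds ratio exactly in expectation — the right construction for
  a case-control design, where sampling is conditional on outcome — and
  makes odds-ratio recovery a sharp test rather than an approximate one.
  Within a total-CN category the haplotype pair composition is left
  untouched.
* **Measurement** forward models are described above. Defaults: 90%
  female (matching the female predominance of SLE cohorts; the emulated
  study had 35 male cases among 327), per-assay failure 1% independent
  across sample-gene pairs (so ~7% of samples fail at least one of seven
  genes, matching the published exclusion fractions), per-peak CV 5%,
  competitor spikes at 1 arbitrary unit (they cancel in standardization).

What the generator does **not** emulate: plate and batch effects,
inter-assay drift, DNA-quality gradients, correlated failures, and any
deviation of real peak noise from log-normality. Passing the recovery and
calibration suites therefore demonstrates that the *statistics* behave as
designed under their own assumptions — not that a particular wet-lab assay
meets those assumptions.

# Problem sizes and numerical conventions

The validation suites run at the emulated study's scale where the claim
depends on it, and at reduced scale where only correctness of code paths
is at stake: genotype-frequency convergence at n = 10^5; HWE type-I error
from 2000 simulated histograms at n = 338 (asymptotic and parametric
bootstrap with B = 399 resamples, so the 5% decision threshold falls on an
exact resample rank); odds-ratio recovery at 338 controls / 327 cases over
500 replicates per design odds ratio (1, 2, 5); ddPCR recovery at 15,000
droplets; Monte-Carlo Fisher checks at B = 10^5. EM convergence is
max |Δq| < 1e-8 with a 1000-iteration cap (non-convergence warns and is
flagged, never silent); Fisher tie comparison uses relative tolerance
1e-7; even-length medians are the midpoint of the central order
statistics; missing measurements propagate as NA and are never coerced to
zero.

# Known limitations

* Median standardization fails structurally when the median individual is
  not diploid, and degrades near class-boundary medians (see above).
* The HWE asymptotic p-value depends on stated df and pooling conventions;
  use the bootstrap when comparing across software.
* Valley gating needs an amplitude floor to resolve null-with-homolog
  samples; a floor appropriate to one assay does not transfer to another.
* The odds-ratio lower bound from zero-cell substitution is a reporting
  convention, not an estimator with coverage guarantees; its CI is
  deliberately suppressed.
* Clinical-variable screening treats variables marginally (2x2 Fisher per
  variable); no covariate adjustment or matching machinery is provided.
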