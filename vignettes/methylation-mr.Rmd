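---
title: "Methods: summary-statistics MR for methylation-trait integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics MR for methylation-trait integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Epigenome-wide association studies correlate DNA methylation with a
phenotype in one set of individuals, which cannot separate causation
(methylation &rarr; phenotype), confounding (methylation &larr; environment
&rarr; phenotype) and reverse causation (phenotype &rarr; methylation).
`methmr` implements the SNP-based alternative: treat cis-mQTL alleles as
randomized instruments for methylation and combine cis-mQTL summary
statistics from one cohort with GWAS summary statistics for the phenotype
from a second, non-overlapping cohort (two-sample Mendelian randomization),
with an LD reference panel supplying the allelic correlation structure.

The analysis cascade mirrors the established tool chain
(SMR/HEIDI-style colocalization followed by GSMR-style multi-SNP MR):

1. **Colocalization.** At a probe's strongest cis-mQTL SNP, with
   $z_1 = b_{qtl}/se_{qtl}$ and $z_2 = b_{gwas}/se_{gwas}$,
   $T_{SMR} = z_1^2 z_2^2 / (z_1^2 + z_2^2)$ is referred to $\chi^2_1$.
   Small $p_{SMR}$ means the probe's QTL signal and the phenotype's GWAS
   signal are unlikely to be unrelated.
2. **Heterogeneity (HEIDI).** A single shared causal variant predicts one
   common Wald ratio $b_{gwas}/b_{qtl}$ across the cis region.  For each
   eligible SNP ($z_{qtl}^2 > 10$, $r^2$ with the top SNP in
   $[0.05, 0.9]$, at most 20 SNPs), $d_i = b_{smr}(i) - b_{smr}(top)$ is
   standardized by its delta-method variance (using panel LD for the
   covariances) and $Q = \sum_i (d_i/sd_i)^2$ is referred to a weighted sum
   of $\chi^2_1$ variables whose weights are the eigenvalues of the
   correlation matrix of the standardized $d$ (Imhof integration, with a
   Satterthwaite scaled-chi-square fallback).  Rejection indicates two
   linked variants rather than one shared one; an *undefined* HEIDI (fewer
   than 3 eligible SNPs) never passes the probe.
3. **Multi-SNP MR.** The instrument is built from the exposure dataset
   only: exposure-significant SNPs ($p < 5\times10^{-8}$), greedy
   p-ordered LD pruning at $r^2 < 0.05$, outcome effects looked up
   afterwards.  Per SNP, the Wald ratio $b_i = b_{zy,i}/b_{zx,i}$ carries
   delta-method variance
   $v_i = (se_{zy,i}^2 + b_i^2 se_{zx,i}^2)/b_{zx,i}^2$ and LD-induced
   covariance
   $cov(b_i,b_j) = r_{ij}(se_{zy,i}se_{zy,j} + b_i b_j se_{zx,i}se_{zx,j})
   /(b_{zx,i}b_{zx,j})$; the causal effect is the GLS mean
   $\hat b_{xy} = (1'V^{-1}b)/(1'V^{-1}1)$,
   $se = (1'V^{-1}1)^{-1/2}$.  SNPs whose ratio deviates from a
   provisional fit at $p < 0.01$ ($\chi^2_1$ on $(d_i/sd_i)^2$) are removed
   once, then the model is refit (single-pass outlier removal keeps the
   estimator deterministic and its runtime bounded).
4. **Reverse-causation filter.** The same machinery with exposure and
   outcome swapped (the phenotype's GWAS provides the instrument, the
   probe's methylation statistics are looked up).  A pair is retained iff
   forward $p < 5\times10^{-8}$ and reverse $p \ge 0.05$.
5. **Mediation.** For retained probes, the chain methylation &rarr;
   expression (instrument from mQTLs, outcome from the gene's eQTLs) and
   expression &rarr; phenotype (instrument from eQTLs) is compared in sign
   with the direct methylation &rarr; phenotype effect.  Mediation is
   assessed at the sign level only; no mediation-proportion model is fit.
6. **Rare-variant matching.** Rare variants are matched to mQTL SNP
   positions exactly or within a configurable window (default 1000 bp,
   exact matches ranked first).  The matching rule is a package decision;
   coordinate convention (1-based, one assembly) is the caller's
   responsibility.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `p_smr_max` | 5e-8 | colocalization pass threshold |
| `p_heidi_keep` | 0.05 | probes must *not* reject single-variant sharing |
| `p_instrument` | 5e-8 | exposure significance for instrument SNPs |
| `r2_prune` | 0.05 | LD ceiling between instrument SNPs |
| `p_outlier` | 0.01 | pleiotropic-outlier removal level |
| `p_forward` | 5e-8 | forward MR retention threshold |
| `p_reverse` | 0.05 | reverse MR exclusion threshold |
| `cis_window` | 1 Mb | half-width around the probe (not stated upstream; configurable) |
| HEIDI eligibility | $z^2>10$, $r^2\in[0.05,0.9]$, cap 20 | adopted from the tool chain's conventions |

All thresholds are plumbed through `pipeline_config()`; the classification
of per-probe statistics into final statuses is a pure function
(`classify_discovery()`), so threshold grids can be evaluated on cached
statistics.

## The synthetic world

`scenario_config()` + `simulate_study()` generate a two-sample study with
known truth.  Genotypes follow a latent-Gaussian AR(1) model: per
haplotype, a latent $N(0,1)$ vector with correlation $\rho^{|i-j|}$
(default $\rho = 0.8$) is thresholded at $\Phi^{-1}(maf)$ and two
haplotypes are summed, so each SNP is marginally Binomial(2, maf)
(maf ~ U(0.05, 0.5)) while neighbours are correlated.  This is enough to
exercise every LD-aware statistic; it does not attempt realistic human
haplotype structure, population stratification or relatedness, so a green
test establishes correct statistical behaviour of the pipeline, not
robustness to those confounders.

Defaults mirror the study design the package emulates: exposure cohort
n = 20,000 (mQTL/eQTL side; sized so cis-QTLs comfortably cross
$5\times10^{-8}$), outcome cohort n = 20,000 (GWAS side), LD panel
n = 503 (the size of the European reference panel used in the field),
200 SNPs per cis locus, three causal mQTL SNPs explaining 5/3/2% of
methylation variance.  Traits are scaled to unit variance; path
coefficients default to `theta_me` = 0.5 (methylation &rarr; expression)
and `theta_ey` = 0.1, i.e. a total causal effect of 0.05, the value used
for the parameter-recovery acceptance criterion.

A polygenic **background block** (10 unlinked SNPs carrying
`h2_background` = 0.2 of the outcome's variance) is part of every
scenario.  It gives the outcome trait its own genome-wide-significant
instrument, without which the reverse-causation filter would be vacuous:
the only reverse instruments would be the probe's own mediated cis SNPs,
and every truly causal probe would look reverse-causal.  With the block
present, the mediated SNPs enter the reverse instrument as pleiotropic
outliers and are removed by the same single-pass rule.

Scenarios: **causal** (M &rarr; E &rarr; Y), **pleiotropy** (one SNP
affects M and Y by separate paths; the HEIDI null), **linkage** (two
distinct SNPs in LD, one per trait; HEIDI's alternative), **reverse**
(Y has a cis genetic basis and M = `theta_ym`·Y + e) and **null**.
Reverse configs refuse a nonzero direct methylation effect.

### The 50-probe discovery fixture

`simulate_discovery_study()` plants 3 causal probes among decoys
(3 pleiotropy, 3 linkage, 3 reverse, 38 null; counts are package
decisions).  Effect sizes are chosen once, from power analysis, so that
each probe is handled by the stage that targets it:

* causal probes use `theta_ey` = 0.6 (total effect 0.3): the top-SNP GWAS
  z is then ~9.5 and $P_{SMR}$ clears $5\times10^{-8}$ with ~4 sigma of
  margin (at the module-default total of 0.05 the expected forward
  chi-square is ~5 and nothing could pass; at 0.2 a quarter of causal
  probes would miss the SMR threshold by chance);
* pleiotropy decoys use `theta_gy` = 0.008 (direct GWAS z ~ 12.6), so the
  planted SNP is removed as an outlier essentially surely and the probe
  falls at the forward-MR stage (the module default 0.002, GWAS z ~ 6.3,
  is kept for the outlier-removal power property, which at that size sits
  near its stated 70% bound by construction);
* reverse decoys use `theta_yx` = (0.05, 0.03) and `theta_ym` = 0.8 so
  their mQTLs are strong enough (top z ~ 25) to sail through SMR and
  HEIDI and be caught by the reverse filter — the stage that defines
  them.  With weaker settings the eligible HEIDI SNPs straddle the
  $z^2 > 10$ eligibility boundary, and selection on noisy denominators
  inflates the heterogeneity statistic, so the decoys would die at HEIDI
  instead (an interaction worth knowing about when interpreting real-data
  HEIDI p-values near the eligibility margin).

Loci are simulated independently and each locus's GWAS statistics use an
outcome realization in which the other loci's contributions are absorbed
into noise; with unlinked loci the joint distribution of the emitted
statistics is unchanged up to $O(1/n)$ cross-locus correlation, and memory
stays flat in the number of probes.

Even with well-sized effects, "exactly the planted probes pass" is a
stochastic event: each truly causal probe independently risks ~5% loss at
the reverse filter (a uniform null p compared against 0.05 — the price the
swap test exacts from true positives) and a few percent at HEIDI.  The
fixture seed is fixed a priori at 1 and the whole cascade is deterministic
given it.

## Numerical choices

* Weighted-chi-square tails by Imhof integration, starting at `rel.tol`
  1e-9 and relaxing the quadrature tolerance stepwise (to 1e-4) when the
  oscillatory integral does not converge — necessary for 2-3 components,
  where the integrand decays slowly; a single component is evaluated
  exactly as a scaled chi-square.  Satterthwaite moment matching is the
  last-resort fallback (also used when the tail is below ~1e-12, where the
  oscillatory integral is unreliable).
* Emitted p-values are two-sided normal (GWAS convention), floored at the
  smallest positive double; record validation checks p against |b/se| on
  the z scale (20% relative tolerance, only where implied z > 1, since
  relative agreement of extreme tail p-values is not meaningful across
  t/normal conventions).
* GLS solves use a Cholesky factorization with an escalating ridge
  (starting at 1e-10 of the mean diagonal) when the covariance is
  numerically singular; the ridge actually used is recorded.
* Outlier-removal variances are floored at 5% of the ratio variance to
  avoid negative values when `se_xy` exceeds a SNP's own variance.
* Greedy pruning breaks ties by exposure p-value order; the top SNP is the
  largest QTL z^2.
* Strand-ambiguous SNPs (A/T, C/G) are dropped by default; the optional
  frequency mode orients them only when both the record and the panel are
  more than 0.08 away from 50% frequency.
* The monotonicity property ("tightening never enlarges the passed set")
  holds for the four decision thresholds re-applied to cached statistics.
  It is *not* claimed for instrument-construction parameters
  (`p_instrument`, `r2_prune`): changing the instrument changes the
  estimate in either direction by nature.

## Known limitations

* cis-only: trans-QTL effects are out of scope.
* No MR-Egger / weighted-median sensitivity estimators; no winner's-curse
  or sample-overlap corrections.
* File-driven pipeline runs use the probe's cis records as the methylation
  side of the reverse test (matching what cis-only mQTL releases permit);
  the in-memory simulator supplies genome-wide methylation statistics and
  is the better-calibrated path.
* The LD panel file format annotates alleles in the column headers
  (`snp:A1:A2`); bare SNP-id headers are accepted but then harmonization
  falls back to the first dataset's allele frame.
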