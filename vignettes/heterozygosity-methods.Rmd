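---
title: "Multilocus heterozygosity and disease risk: models and methods"
author: "hetchd maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilocus heterozygosity and disease risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Heterozygote advantage — the idea that individuals carrying two different
alleles at a locus, or at many loci, enjoy a fitness benefit over
homozygotes — is well documented for a handful of single loci (the malaria
resistance of hemoglobin variants being the canonical case). Whether
*genome-wide* heterozygosity confers any advantage against common chronic
disease is a different and much weaker hypothesis. `hetchd` implements the
full analysis needed to test it in a nested case-control study: it
measures each individual's multilocus heterozygosity (MLH) — the count, or
the proportion, of genotyped biallelic SNPs at which the two alleles
differ — and relates it to incident disease and to continuous risk-factor
levels.

The population-genetic rationale is the inbreeding connection. If an
individual's two alleles are identical by descent with probability $F$
(the inbreeding coefficient), the expected heterozygosity at a locus with
allele frequency $p$ is

$$\mathbb{E}[\text{het}] = (1 - F)\, 2p(1-p).$$

MLH is an informative proxy for $F$ only when $F$ *varies* between
individuals; this variance induces a correlation of heterozygosity across
loci known as identity disequilibrium. The simulator makes this mechanism
explicit rather than assuming it away.

## The cohort generator

Because cohort genotype data of this kind are not publicly depositable,
every downstream stage is exercised against a synthetic cohort whose
defaults are chosen once to match the structure of a genotyped nested
case-control study of incident coronary heart disease (CHD):

* **Panel.** 692,794 autosomal SNPs (plus 3% X-chromosome SNPs for the
  sex-consistency check), ancestral allele frequencies uniform on
  $[0.001, 0.5]$, giving $\overline{2p(1-p)} \approx 0.334$.
* **Inbreeding.** $F_i \sim \mathrm{Beta}$ re-parameterized by mean
  0.005 and SD 0.009, truncated to $[0,1)$. At the full panel this yields
  per-individual heterozygous-locus counts near 229,000 with SD on the
  order of 2,000 — the observed scale in outbred cohorts of European
  ancestry, where the SD is dominated by the variance of $F$, not by
  binomial noise ($\sqrt{L \bar h (1-\bar h)} \approx 390$ at
  $L \approx 693$k).
* **Population structure.** $k$ subpopulations drift from the ancestral
  frequency under the Balding–Nichols model,
  $p_s \sim \mathrm{Beta}\big(p\tfrac{1-F_{st}}{F_{st}},
  (1-p)\tfrac{1-F_{st}}{F_{st}}\big)$, with variance $F_{st}\,p(1-p)$.
  Optionally each subpopulation has its own mean inbreeding
  (`subpopFMean`) and its own disease-risk shift (`subpopRiskLogOr`);
  together these plant genuine stratification confounding, which pure
  Balding–Nichols drift does not (drift leaves
  $\mathbb{E}[2p_s(1-p_s)]$ equal across subpopulations, so expected
  heterozygosity would not differ systematically).
* **Genotypes.** At each SNP an individual is autozygous with probability
  $F_i$ (homozygous, allele chosen with probability $p$) and
  Hardy–Weinberg otherwise ($\mathrm{Binomial}(2, p)$). SNPs are
  independent given $F$ and subpopulation: no linkage disequilibrium is
  simulated. Genotypes are masked missing completely at random
  (default 0.5%).
* **Annotation.** SNPs are laid on 22 chromosomes at ~4 kb spacing; gene
  regions are laid down so that gene bodies extended by 70 kb upstream and
  20 kb downstream flanks (strand-oriented) cover ~81.2% of SNPs, and
  ~0.69% of SNPs — always inside gene bodies — are flagged
  nonsynonymous. These fractions reproduce a 562,289-of-692,794 genic
  stratum and a 4,760-SNP nonsynonymous stratum at full panel size.
* **Outcomes.** Disease operates in discrete time (14 periods, one per
  follow-up year): the per-period event log-odds are
  $\mathrm{logit}(h_0) + \beta_{2000} (H_i - \bar H)/2000$, with baseline
  $h_0 = 0.0133$ so that a cohort of 2,500 yields roughly 435 cases — the
  per-cohort case count of the motivating design. A discrete-time logistic
  hazard is the simplest model with well-defined risk sets.
* **Matching.** Each case, in event-time order, is matched to 2 controls
  sampled from individuals still event-free at the case's event time in
  the same 2-year age band and smoking stratum (risk-set sampling). A
  control that later becomes a case is kept once, as a case, in its own
  matched set. Sets whose risk set is exhausted are dropped and counted.
  Band width is configuration, not inference: the design being emulated
  matches on "age and smoking" without stating calipers.
* **Biomarkers.** Thirteen risk-factor traits (lipids, inflammatory
  markers, adhesion molecules, homocysteine, adiponectin, BMI), each
  linear in $H_i/2000$ with Gaussian noise and age/smoking terms. The
  default heterozygosity effect is zero for every trait — the null that
  the analysis is designed to calibrate against — and several traits are
  measured only in a random half of the sampled individuals, mimicking
  assays run on an initial subset.

Identical configuration and seed give bit-identical cohorts.

**What the generator does not emulate:** linkage disequilibrium, a
realistic (U-shaped) allele-frequency spectrum, genotyping batch effects,
relatedness, and time-varying covariates. Passing calibration tests on
this generator therefore demonstrates the *statistical* correctness of the
pipeline under its stated model, not robustness to every artifact of real
array data.

## Quality control

Four rules, in fixed order, each exclusion carrying the first violated
rule as its primary reason:

1. **Sample call rate** strictly below 0.97 (an individual exactly at the
   threshold is retained).
2. **Sex consistency**: X-chromosome heterozygosity at or below 0.02
   infers male, at or above 0.20 infers female; a contradiction with
   reported sex excludes the individual, indeterminate rates are retained.
   The thresholds are explicit configuration with conservative defaults;
   with fewer than 50 X SNPs the check is skipped with a logged warning.
3. **Platform intersection**: analysis is restricted to SNPs shared by all
   genotyping platforms.
4. **Hardy–Weinberg in controls**: per SNP, genotype counts are tallied
   over control individuals only and tested with the exact conditional
   test; SNPs with $p < 10^{-4}$ are removed for everyone. Controls are
   pooled within the cohort; X SNPs are tested in female controls only,
   since hemizygous males cannot be heterozygous. Per-SNP call-rate
   filtering is deliberately *not* applied (the emulated design states
   only a sample-level rule).

The exact test conditions on the allele counts: the heterozygote count $k$
has probability proportional to $n!\,2^k / (n_{AA}!\,k!\,n_{aa}!)$, and
the two-sided p-value sums all attainable configurations no more probable
than the observed one (the standard convention; a mid-p variant is
available behind a flag, off by default). The implementation
self-normalizes log-weights for stability; the test suite checks it
against an independent enumeration using the closed-form normalization
$\binom{2n}{n_A}$ for every configuration with $n \le 50$.

## Heterozygosity strata and reporting units

Three strata: all autosomal SNPs; SNPs within gene bodies extended by
70 kb upstream / 20 kb downstream flanks (strand-aware, clamped at
position 1, overlapping regions merged so each SNP counts once); and
nonsynonymous SNPs. The flank asymmetry is read as upstream/downstream —
the only reading under which the asymmetry is meaningful — and both knobs
are explicit arguments. Counts use each individual's own non-missing
denominator; count and proportion are both first-class exposures (with
uniform missingness they give identical z-statistics, which the tests
verify).

Effects are reported per a fixed number of SNPs — 2,000 for the dense
strata, 25 for nonsynonymous SNPs — chosen to be roughly one SD of each
count at full panel size. Because the SD scales with panel size, the
`unit = "sd"` mode sets the unit to the observed SD; this is the
scale-invariant form of the same convention and is what the acceptance
script reports on scaled-down panels.

## Stratification adjustment

Principal components are computed from genotypes centered at twice the
observed allele frequency and scaled by the binomial SD, with missing
values mean-imputed, monomorphic SNPs dropped, and (by default) every 10th
autosomal SNP used — the stratification signal is dense and the subset
keeps the eigendecomposition light. The sign of each component is fixed by
making its largest-magnitude entry positive, so results are reproducible.
Three components are used as covariates by default. Ancestry outliers
beyond 6 SDs on any component are flagged, not auto-excluded;
reference-panel projection is out of scope. PCs are computed within the
cohort being analyzed.

## Association models

Incident disease is modeled by **unconditional logistic regression** of
case status on the standardized heterozygosity exposure, adjusting for the
matching factors (age continuous, smoking binary) and the eigenvectors.
Matching is handled by covariate adjustment rather than by conditional
likelihood; conditional logistic regression is deliberately out of scope
(the unconditional fit converges more reliably and gives similar
estimates in this design). Wald standard errors, 95% CIs and two-sided
p-values are reported; non-convergence or separation sets a flag rather
than failing silently. Subgroup analyses (e.g. baseline age < 65) keep
every individual passing the predicate regardless of matched-set
integrity, consistent with the unconditional model.

Biomarkers are modeled by linear regression of each trait on the
standardized exposure with age, smoking, eigenvectors and case-control
status as covariates — including both cases and controls is unbiased when
the genetic exposure is only weakly related to case status. A
per-matched-set random intercept (REML, via `lme4`) is available because
"mixed models" in this design is ambiguous between that structure and
fixed-only adjustment; with zero between-set variance both forms agree,
which the tests check. No multiple-testing correction is applied across
the strata-by-trait grid by default: the analysis tests one global
hypothesis at conventional significance levels, and the chance-expected
fraction of nominal hits is itself one of the calibration checks.

Report tables give, per stratum, case and control mean ± SD counts, a
two-sided Welch two-sample t-test for the mean difference (the test is a
package choice, logged in the output, since the emulated design does not
name one), and the adjusted OR per unit.

## Numerical and design choices

* Genotype codes count non-reference alleles; heterozygosity depends only
  on code 1, so allele polarity is irrelevant (tested by flipping).
* HWE tail ties are resolved with a $1+10^{-9}$ relative guard so that
  configurations equal to the observed probability up to rounding are
  included.
* The eigendecomposition uses the dense symmetric solver on the
  individual-by-individual covariance; `k` above the numerical rank is an
  error.
* Gene tables with `start > end` fail validation naming the gene; BED
  input should be converted to 1-based inclusive coordinates on read.
* Matching exhaustion drops the set and counts it; a converter whose own
  matching is exhausted remains a case with no set id.

## Problem sizes used in the checks

The calibration suite runs on scaled-down panels chosen as the smallest
sizes at which each property is informative: the full 692,794-SNP panel
for annotation fractions and (200 individuals) for the het-count scale;
50,000 SNPs × 2,500 individuals for null coverage, type-I error and
effect recovery (200, 200 and 100 outcome replicates over fixed
genotypes — coverage and rejection rates are properties of the outcome
model given genotypes, so genotypes are drawn once); 5,000 SNPs × 1,200
individuals × 150 replicates for the planted-confounding contrast; and
exhaustive enumeration up to totals of 50 for the exact HWE test.

## Known limitations

* No LD means the effective number of independent loci equals the panel
  size; real panels have fewer, widening real-data SDs relative to the
  binomial term.
* The discrete-time hazard approximates continuous-time risk-set sampling;
  with the default per-period risk (~1.3%) the odds ratio approximates the
  hazard ratio well, but this degrades for high-risk configurations.
* The sex-consistency thresholds assume array-like X heterozygosity; they
  are not calibrated for exome content.
* `g2`-type identity-disequilibrium estimators and runs-of-homozygosity
  are natural extensions, not implemented.
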