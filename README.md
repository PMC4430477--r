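# hetchd

Multilocus heterozygosity and disease risk in nested case-control cohorts.

## The problem this package addresses

Does genome-wide heterozygosity — the number (or proportion) of genotyped
biallelic SNPs at which an individual carries two different alleles —
protect against common chronic disease? Heterozygote advantage is well
established at single loci, and multilocus heterozygosity (MLH) proxies
the inbreeding coefficient *F* whenever *F* varies between individuals
(identity disequilibrium): at a locus with allele frequency *p*,

```
E[het] = (1 − F) · 2p(1 − p)
```

`hetchd` is for epidemiologists and statistical geneticists who want to
run (or calibrate) this analysis in a nested case-control design: cases of
incident disease matched to controls by risk-set sampling, genotyped on a
genome-wide array, analyzed by unconditional logistic regression of case
status on standardized MLH with adjustment for matching factors and
principal-component ancestry covariates, plus mixed/linear models of
continuous risk-factor levels. Because cohort genotype data of this kind
are not publicly depositable, the package includes a first-class
synthetic-cohort generator (Balding–Nichols population structure,
Beta-distributed per-individual inbreeding, discrete-time logistic
hazards, risk-set-sampled matched controls, biomarkers) so the entire
pipeline is testable end to end.

The pipeline stages:

* **Simulation** — `simConfig()`, `simulateCohort()` and the individual
  generator steps, with ground truth retained for parameter recovery.
* **IO** — `readGenotypes()` / `writeGenotypes()` (VCF and PLINK
  bed/bim/fam), covariate and annotation TSVs.
* **QC** — sample call rate (< 0.97 excluded), sex consistency from X
  heterozygosity, cross-platform SNP intersection, and an exact
  Hardy-Weinberg test in controls (p < 1e-4), via `runQc()` /
  `hweExactTest()`.
* **Heterozygosity** — per-individual counts and proportions over three
  strata (all autosomal; within gene bodies + 70 kb upstream / 20 kb
  downstream flanks; nonsynonymous), via `hetProfile()` /
  `defineGenicStratum()`; effects standardized per 2000 SNPs (25 for
  nonsynonymous), or per observed SD.
* **Stratification** — `computeEigenvectors()` (top-3 PCs of the scaled
  genotype covariance) and `flagAncestryOutliers()`.
* **Association** — `fitChdModel()` (logistic, Wald OR/CI/p),
  `fitBiomarkerModel()` (linear, optional per-matched-set random
  intercept), `subgroupFilter()`, `buildReports()`.

## Worked example

```r
library(hetchd)

cfg <- simConfig(nIndividuals = 1200, nSnps = 20000, seed = 2026)
sim <- simulateCohort(cfg)
qc  <- runQc(sim$geno)
hp  <- hetProfile(qc$geno)
print(hp)
#> HetProfile: 1200 individuals x 3 strata
#>   all_autosomal    mean n_het = 6630.7 (SD 89.3), unit = 2000
#>   genic            mean n_het = 5049.9 (SD 72.8), unit = 2000
#>   nonsynonymous    mean n_het = 45.0 (SD 5.2), unit = 25

ev  <- computeEigenvectors(qc$geno)
tab <- addEigenvectors(as.data.frame(sampleInfo(sim$geno)), ev)
fitChdModel(tab, hp, stratum = "all_autosomal", unit = "sd")
#> AssociationResult [all_autosomal, per 89.3121 SNPs, exposure=count]
#>   OR = 0.967 (95% CI 0.819-1.141), p = 0.69
#>   beta = -0.03368 (SE 0.08456); 210 cases / 384 controls
#>   adjusted for: age, smoking, EV1, EV2, EV3

fitBiomarkerModel(tab, hp, "hdl")
#>   trait       stratum unit     beta       se         p   n      model
#> 1   hdl all_autosomal 2000 -20.9336 12.22516 0.0868345 594 fixed-only
```

Reading the output: the generator planted no heterozygosity effect
(`betaPer2000 = 0`), and the fitted odds ratio per 1-SD unit (here 89
heterozygous loci on the scaled 20k-SNP panel) is 0.97 with a confidence
interval spanning 1 — the null is correctly retained. The mean het counts
scale with panel size: about one third of SNPs are heterozygous, and at
the default full-size panel (692,794 autosomal SNPs) the per-individual
count is ~229,000 with SD ~2,000. The HDL fit likewise shows no
significant association (p = 0.087 is one draw from a null grid; the
calibration suite verifies the nominal 5% hit rate across the full
trait-by-stratum grid).

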