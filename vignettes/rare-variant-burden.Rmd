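---
title: "Gene-based rare-variant burden testing with typed and imputed genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based rare-variant burden testing with typed and imputed genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The statistical model

`rvburden` tests whether a complex trait is associated with an
*accumulation of minor alleles* at the rare variants (minor allele
frequency, MAF, below 1%) of a gene or other functional unit.  Rare
variants are individually too infrequent for single-variant association
tests, so the package collapses them: with $N$ rare variants in the unit
and $G_{ij} \in \{0,1\}$ coding whether individual $i$ carries at least
one minor allele at variant $j$, the burden predictor is the carrier
proportion

$$x_i = \frac{1}{n_i} \sum_{j \,\in\, \text{observed}} G_{ij},$$

where $n_i \le N$ is the number of variants successfully assayed in
individual $i$.  The phenotype is modelled in a generalised linear model
$g\{E(y_i)\} = \alpha + \beta x_i + \boldsymbol\gamma^\top \mathbf{c}_i$
(identity link for quantitative traits, logit for binary ones), with
covariates $\mathbf{c}_i$ such as principal components of genetic
structure included in both the null and alternative models.  $\beta$ is
the expected phenotype difference between an individual carrying minor
alleles at every rare variant of the unit and one carrying none, so
$\beta/N$ is the per-minor-allele effect; for binary traits the package
reports $\mathrm{OR} = e^{\beta/N}$ with a Wald 95% interval.

To allow for differential call rates, each individual's log-likelihood
contribution is weighted by its call rate.  We normalise the weight to
$w_i = n_i/N \in [0,1]$: an unscaled weight of $n_i$ would multiply the
deviance roughly $N$-fold even with complete data, whereas $w_i = n_i/N$
makes the weighted likelihood-ratio test (LRT) reduce *exactly* to the
ordinary GLM analysis of deviance when every genotype is observed (a
property the test suite checks to 1e-8).  Individuals with $n_i = 0$
receive weight 0 and drop out of the likelihood; their $x_i$ is defined
as 0 so the design stays finite.  The test statistic is
$2(\ell_\text{alt} - \ell_\text{null})$, clipped at zero and referred to
$\chi^2_1$.

Imputed variants enter through their posterior genotype probabilities:
the genotype expectation is $E(G_{ij}) = 1 - h_{ij}$, where $h_{ij}$ is
the posterior probability of a *common-homozygote* call.  Files carry
probabilities on the A/B allele coding of the GEN format, which says
nothing about which allele is minor, so each variant is oriented by the
cohort's expected allele frequency: the allele with expected frequency
$\le 0.5$ is minor (ties resolve to allele B).  This per-variant,
data-driven orientation is a package convention; GEN files carry no
frequency metadata that could replace it.

### Fitting details

Fits use iteratively reweighted least squares (`stats::glm.fit`) with the
call-rate weights as prior weights.  The weighted log-likelihood
$\sum_i w_i \log L_i$ is computed explicitly: for the gaussian family the
residual variance is profiled at its weighted maximum-likelihood value
$\hat\sigma^2 = \sum w_i r_i^2 / \sum w_i$ (floored at the smallest
positive double so that a perfectly fitted, e.g. constant, response gives
an LRT of exactly zero rather than `NaN`); for the binomial family the
Bernoulli contributions are weighted directly, with fitted probabilities
clamped to $[10^{-12}, 1 - 10^{-12}]$.  IRLS stops at a relative
deviance change of 1e-8 or 100 iterations; non-convergence and complete
separation are flagged and yield a missing p-value.  Individuals with a
missing phenotype or covariate are excluded listwise.  Rank-deficient
designs (e.g. a conditioning covariate collinear with the burden) are
handled by the QR pivoting of the fitter: the aliased coefficient is
`NA` and the LRT collapses to zero, which is the correct collinearity
limit.  A constant conditioning dosage is dropped with a warning, so the
conditional analysis then equals the unadjusted one.

## The simulation framework

The power study emulates a quantitative-trait association study of a
50 kb gene embedded in a 1,050 kb region (500 kb of buffer either side,
which gives the imputation model long-range linkage information and
avoids edge effects).  Its defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_hap` | 40,000 | population haplotypes (coalescent with recombination) |
| `mu`, `rec` | 1e-8, 1e-8 | per-bp mutation rate; 1 cM/Mb recombination |
| `Ne` | 10,000 | effective population size |
| `n_individuals` | 2,000 | analysis cohort |
| `R` | 120 / 500 / 4,000 | reference-panel individuals |
| `delta` | 0.01 | maximum MAF of an individual causal variant |
| `Q` | 0.05 | total MAF of the causal set |
| `lambda` | 0.05 | causal share of trait variance |
| `n_gwas` | 240 | chip variants in the region (≈ 230 SNPs/Mb, the genome-wide density of a 660k chip) |
| `epsilon` | 0 (grid 0.001, 0.002) | per-allele base-call flip probability |
| `kappa` | 0 (grid 0.01) | per-genotype missingness probability |
| `replicates` | 500 | replicates per scenario |

Populations come from `msprime` (neutral coalescent with recombination);
the bridge is batched, deterministic under the master seed, and also
accepts user haplotypes in a plain-text format.  Causal variants are
drawn uniformly without replacement from the gene variants with
population MAF $q_j < \delta$ until the cumulative MAF first reaches
$Q$ — exact equality is generally unattainable, so the selection stops at
the *first crossing*, giving $Q \le Q_\text{achieved} < Q + \delta$.

Phenotypes follow a carrier-shift model: $y_i \sim N(\mu_i, \sigma)$
with $\mu_i = 1$ if the individual carries at least one causal minor
allele and $0$ otherwise.  Since the carrier indicator has variance
$p(1-p)$ at carrier probability $p$, fixing the causal variance share at
$\lambda$ requires

$$\sigma^2 = \frac{p(1-p)(1-\lambda)}{\lambda}.$$

$p$ is computed *empirically* from the haplotype matrix (the fraction of
the population's 20,000 disjoint haplotype pairs carrying a causal minor
allele) rather than from the linkage-free product
$1 - \prod_j (1-q_j)^2$: linkage disequilibrium among causal variants
makes the product formula only approximate (the two agree within ~20% on
simulated populations, a property the tests check).  The formula itself
is validated empirically: regressing simulated phenotypes on carrier
status at $n = 10^6$ recovers $R^2 \approx \lambda$ (this is also what
`scripts/acceptance.R` recomputes).

### The four assay strategies

Each replicate produces four observed-genotype datasets for the same
cohort and phenotypes:

1. **SEQ** — re-sequencing: hard calls at every gene variant with cohort
   MAF < 1% (strict; MAF is computed in the cohort, not the population).
2. **GEN** — panel genotyping: the SEQ set restricted to variants
   segregating among the reference panel's $2R$ haplotypes.
3. **GWAS** — chip only: the chip variants that fall inside the gene and
   are rare in the cohort (usually almost none).
4. **IMP** — chip + imputation: the cohort is typed at all chip variants
   region-wide, each haplotype is imputed up to the panel with a haploid
   Li–Stephens model, and the test runs on variants passing both the MAF
   filter and the info-score filter (info ≥ 0.4).

Chip ascertainment draws `n_gwas` variants without replacement with
weight proportional to $q_j$.  Under the neutral site-frequency spectrum
(density $\propto 1/q$) this yields the approximately uniform MAF
distribution characteristic of GWAS chips; the weight function is
pluggable (`uniform`, or a user vector).  The uniformity holds in the
regime where inclusion probabilities remain proportional to the weights
(small sampling fraction); at larger fractions sequential weighted
sampling saturates the common end of the spectrum, which is a property of
without-replacement sampling, not of the weight choice.

Base-call errors flip each allele call independently with probability
$\varepsilon$ — first in the reference panel, then in the cohort — giving
the documented genotype-call discordance of $1-(1-\varepsilon)^2$
(≈ 0.2% at $\varepsilon = 0.1\%$, ≈ 0.4% at $0.2\%$).  Missingness masks
each genotype independently with probability $\kappa$ in strategies 2–4
only (re-sequencing is treated as complete).  One genome-wide mask per
replicate is shared by strategies 2–4 so the strategies stay matched; the
mask removes a site from both haplotypes of an individual's imputation
scaffold.

A strategy with zero qualifying variants in a replicate counts as a
*non-rejection* when estimating power: the chip-only strategy routinely
assays no rare gene variant, and treating those replicates as missing
would bias its power upward.  Replicates whose gene cannot support the
requested causal MAF total (possible in small scaled-down populations)
are skipped with a warning before any assay is made, so all strategies
see the same replicates.

### The imputation stand-in

Cohort haplotypes are treated as pre-phased (they are known in the
simulation, mirroring the use of sample pre-phasing in practice), so
imputation is a *haploid* Li–Stephens hidden Markov model per haplotype:
the target is a mosaic of the $K = 2R$ panel haplotypes, with switch
probability $1 - \exp(-4 N_e r d / K)$ between typed sites at distance
$d$ and emission error
$\tilde\theta / \{2(\tilde\theta + K)\}$,
$\tilde\theta = 1/\sum_{k=1}^{K-1} k^{-1}$.  Forward–backward state
posteriors at the typed scaffold are computed with per-site rescaling
(in C++; the R-level oracle in the test suite is an independent
implementation).  At an untyped site the allele posterior is the
state-weighted panel allele, linearly interpolated in position between
the flanking typed sites — a deliberate simplification of propagating the
transition kernel to every untyped position.  The two haplotype
posteriors $a, b$ combine into genotype posteriors
$(1-a)(1-b),\; a(1-b)+b(1-a),\; ab$.  Directly typed, non-missing chip
genotypes inside the gene are kept as hard calls.

Imputation quality is screened by the IMPUTE-convention info score (the
ratio of observed to complete-data information about the allele
frequency): with dosage $e_i = p_{1i} + 2p_{2i}$,
$f_i = p_{1i} + 4p_{2i}$ and $\hat\theta = \sum e_i / 2N$,

$$\text{info} = 1 - \frac{\sum_i (f_i - e_i^2)}{2N\hat\theta(1-\hat\theta)},$$

clipped to $[0,1]$, with info $=0$ when $\hat\theta \in \{0,1\}$.  Hard
calls give info 1, so for directly typed data the imputation filter
reduces to the MAF filter.  The info boundary is *inclusive*
(info ≥ 0.4 retained) and configurable.  The MAF boundary is strict
(MAF < 1%).

## The genome-wide scan

`run_scan()` applies the burden test per gene from GEN/SAMPLE/gene-boundary
files: variants belong to a gene iff `start <= position <= stop` (1-based
inclusive, matching genome-browser display coordinates); genes are
processed in positional order, so results are invariant to the input
file's row order.  The scan reports the genomic-control inflation factor
$\lambda_\text{GC} = \text{median}(\Lambda)/0.4549$ (the $\chi^2_1$
median) as a structure diagnostic — it is *not* applied as a correction —
and a Bonferroni threshold of $\alpha$ over the number of genes tested
(or a fixed family size such as 30,000, giving $P < 1.7\times10^{-6}$ at
$\alpha = 0.05$).  Conditional analysis adds a lead SNP's expected
minor-allele dosage as a covariate to both models; samples missing the
dosage get weight zero for that gene.  `export_plots_data()` emits
Manhattan (gene transcript midpoints, $-\log_{10} P$) and QQ tables.

## What the simulations do and do not show

The generator reproduces the study conditions: neutral coalescent
variation, a single population for cohort and panel, all causal variants
acting in the same direction with equal carrier effects, an error-free
phased panel apart from the explicit $\varepsilon$ model.  It does *not*
model selection, demography, population stratification, gain- vs
loss-of-function mixtures, real chip manifests, or genotype-calling
intensity models — so passing tests demonstrate the statistical
machinery under the stated model, not robustness to these features of
real data.  The Li–Stephens stand-in shares the structure, but not the
code or every refinement, of production imputation software; numerical
agreement with IMPUTEv2's info score is not claimed, only the formula
above.

## Problem sizes used by the tests

The test suite exercises the full pipeline at reduced scale, chosen so
the whole suite stays well inside a half-hour on one CPU: null
calibration at cohorts of 300–400; the strategy power ordering at 200
replicates with 2,500-haplotype populations, 300-individual cohorts,
panels of $R = 30$ vs $250$ and $\lambda = 0.2$ (the causal share is
raised so that power sits in a measurable mid-range at the smaller cohort
size); error/missingness degradation at 100 matched replicates; and
imputation-accuracy monotonicity at 20 replicates with panels of 30, 100
and 300 individuals.  At these population sizes the gene's eligible rare
MAF occasionally cannot reach $Q = 0.05$; such replicates are skipped
symmetrically across strategies.  `scripts/acceptance.R` recomputes the
null rejection rate at 1,000 replicates and the $\lambda$ variance
decomposition at $n = 10^6$ at the sizes stated in its header.

## Known limitations

* The burden model assumes unidirectional effects; mixtures of
  protective and deleterious alleles dilute $\beta$ toward zero
  (dispersion-style tests are out of scope).
* MAF-dependent variant weighting and X-chromosome dosage models are not
  implemented.
* The GEN reader assumes a single chromosome per file (the format has no
  chromosome column); genome-wide scans run per chromosome.
* Multi-allelic variants and BGEN/VCF dosage input are not supported.
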