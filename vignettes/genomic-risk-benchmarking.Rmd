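---
title: "Benchmarking genomic risk prediction under the liability-threshold model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking genomic risk prediction under the liability-threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsbench)
```

## What this package does

`grsbench` is a benchmarking pipeline for whole-genome risk prediction in
case-control studies of complex disease. It implements four predictors that
span the methodological range used in the field —

* **GPRS** (genetic profile risk score): per-SNP effects from single-marker
  association (logistic on 0/1 status, linear on adjusted residuals),
  optionally thresholded on the association p-value;
* **GBLUP**: a linear mixed model with a genomic-relationship random effect,
  variance components by restricted maximum likelihood, out-of-sample
  genetic values through the mixed-model equations;
* **Elastic net**: penalized regression on the 8000 most associated SNPs
  (a pre-selection that keeps the design tractable), penalty weight chosen
  by inner 10-fold cross-validated deviance at fixed mixing parameter
  $\alpha = 0.5$;
* **BayesR-type mixture regression**: SNP effects drawn from a
  four-component normal mixture — a point mass at zero plus components with
  variances $\gamma_k \sigma_g^2$, $\gamma = (0, 10^{-4}, 10^{-3},
  10^{-2})$ — fitted by Gibbs sampling;

— together with the stages around them (SNP and sample quality control,
relatedness pruning, reference-panel PCA projection and phenotype
adjustment), a cross-validation harness scored by AUC, decile odds-ratio
risk stratification, and the liability-threshold conversion from an
observed AUC to the odds ratio expected between the top and bottom score
deciles.

All four predictors reduce to one currency, a `snp_effects` set (per-SNP
allele effects plus an intercept), consumed by one scorer
(`score_genotypes()`); GBLUP enters this pathway through its exact SNP-BLUP
equivalent. This guarantees that method comparisons differ only in how
effects are estimated, never in how they are applied.

## The generative model behind the synthetic data

Restricted case-control genotypes cannot ship with a package, so every
stage is exercised on synthetic cohorts drawn from the generative model the
analysis itself assumes:

1. Ancestral allele frequencies uniform on a configurable range; with two
   subpopulations, per-population frequencies from a Balding-Nichols Beta
   distribution with differentiation parameter $F_{st}$; independent
   binomial(2) dosages.
2. SNP effects on the standardized-genotype scale
   $z = (x - 2p)/\sqrt{2p(1-p)}$ from the four-component mixture; the
   effect vector is rescaled so the realized genetic variance equals the
   target $h^2$ *exactly*, which makes heritability-recovery tests sharp.
   (Standardized-scale effects are also what the GRM and the mixture
   regression assume, so the simulator and the estimators agree about
   units.)
3. Liability = genetic score + $N(0, 1 - h^2)$; disease when liability
   exceeds $t = \Phi^{-1}(1 - K)$ for prevalence $K$; cases and controls
   ascertained by sampling from a finite pool. Ascertainment by rejection
   is exact and simple; it requires a pool prevalence large enough to yield
   the requested cases, so simulator tests run at $K \ge 0.01$ while the
   clinical-utility mathematics (which has no such constraint) handles the
   low prevalences of Crohn's disease (0.005) and ulcerative colitis
   (0.002).
4. Optional machinery for the failure modes the QC stages exist to catch:
   palindromic allele labels, per-SNP imputation INFO scores, missing
   genotypes, case oversampling from one subpopulation
   (`confounding_delta`, confounding ancestry with status), and a second
   "batch" rendering of the same genotype matrix with symmetric per-genotype
   errors.

What the simulator does *not* emulate: linkage disequilibrium beyond
optional column duplication, realistic allele-frequency spectra,
imputation-error structure behind the INFO labels, or the X chromosome.
Passing tests therefore demonstrate correctness of the estimators under the
model they assume, not robustness to every pathology of real array data.

## The liability-threshold utility calculation

For prevalence $K$: threshold $t = \Phi^{-1}(1-K)$, density $z = \phi(t)$,
mean case liability $i = z/K$, mean control liability $i_2 = -z/(1-K)$. A
risk score explaining a fraction $v$ of liability variance has case/control
score means $vi$, $vi_2$ and within-class variances $v(1 - vi(i-t))$,
$v(1 - vi_2(i_2-t))$, giving

$$\mathrm{AUC} = \Phi\!\left(\frac{(i - i_2)\,v}
{\sqrt{v(1 - vi(i-t)) + v(1 - vi_2(i_2-t))}}\right).$$

`auc_to_liability_v()` inverts this monotone relation by bracketed
root-finding ($v \in [0, 1)$, tolerance $10^{-12}$). The expected risk in
score decile $d$ is then

$$P_d = 10 \int_{\Phi^{-1}((d-1)/10)}^{\Phi^{-1}(d/10)}
\Phi\!\left(\frac{\sqrt{v}\,z - t}{\sqrt{1-v}}\right)\phi(z)\,dz,$$

by adaptive quadrature (relative tolerance $10^{-10}$), and the expected
top-vs-bottom decile odds ratio is $[P_{10}/(1-P_{10})]/[P_1/(1-P_1)]$.
Integrating the risk *within* each decile matters: plugging in the decile
mean of the score instead materially overstates the tail odds ratios.

Two Monte-Carlo cross-checks ship with the function. `method = "mc"`
averages the same conditional risk over simulated scores — a
low-variance check of the quadrature that is reliable even at $K = 0.002$,
where the bottom decile's risk is of order $10^{-4}$. `method =
"liability_sim"` simulates the full bivariate score/liability pair and
thresholds it — fully generative, but it needs a prevalence large enough to
put cases into the bottom decile, so tests run it at $K = 0.05$.

```{r expected-or, eval = FALSE}
expected_decile_or(auc = 0.746, K = 0.005)   # ~32.8
expected_decile_or(auc = 0.696, K = 0.002)   # ~13.8
```

## Estimation choices

**REML.** With a single genomic variance component plus an intercept, the
restricted likelihood profiles exactly on the eigenbasis of the GRM: one
eigendecomposition, then a one-dimensional optimization over the variance
ratio $\delta = \sigma_e^2/\sigma_g^2$ (Brent, tolerance $10^{-8}$ on
$\log\delta$) with the total variance solved in closed form. This is exact
for the model fitted here, cannot diverge, and replaces iterative
average-information updates that would need convergence monitoring. The
boundary $\sigma_g^2 \to 0$ yields constant predictions and is flagged.

**The 0/1 scale.** GBLUP and the mixture regression treat disease status
(or its ancestry-adjusted residual) as a continuous trait. This mirrors
standard practice for large case-control panels: the ranking of individuals
— all that AUC and decile stratification use — is insensitive to the link,
while the linear model keeps the mixed-model machinery exact.

**Gibbs sampler.** Each sweep updates every SNP's component indicator from
the marginal likelihood of the four components (effect integrated out) and,
for non-null assignments, the effect from its conjugate normal conditional,
with running-residual bookkeeping; then the mixture proportions from a
Dirichlet posterior, and $\sigma_g^2$, $\sigma_e^2$ from scaled
inverse-chi-square conditionals. Desk-scale defaults are 10,000 iterations,
5,000 burn-in, thinning 10, one seeded chain; the per-draw log of
$(\sigma_g^2, \sigma_e^2, \pi, \text{model size})$ supports convergence
checks. Reported effects are posterior means.

**The mixture-proportion prior.** The Dirichlet prior defaults to sparse
pseudo-counts ($\approx 1\%$ non-null mass, 50 total pseudo-counts) rather
than the flat $(1,1,1,1)$. The reason is identifiability at moderate sample
size: components with variance $\gamma_k \sigma_g^2 \cdot n \ll \sigma_e^2$
are statistically indistinguishable from the point mass, so on
weak-signal data the posterior on $\pi$ simply echoes its prior — and a
flat Dirichlet implies a prior *expectation* of 75% non-null SNPs, which
misstates everything known about polygenic architecture. The sparse prior
keeps the reported model size honest on null data while real component
occupancy dominates it as soon as effects are identifiable (pseudo-counts
of 50 against thousands of SNP assignments). `dirichlet_alpha =
c(1, 1, 1, 1)` restores the flat prior.

**Ancestry adjustment.** PCA is computed on a reference panel standardized
by its own frequencies; reference scores are defined as $ZV$, so projecting
any dataset (standardized by *reference* frequencies) onto the loadings
reproduces the reference's own scores exactly — the testable
self-consistency contract. Phenotype adjustment is the OLS residual of
status on the top projected components (10 by default): the residual is
exactly orthogonal to the components and re-adjustment is a no-op.
Adjustment is linear, not logistic, because the residual is consumed
downstream as a continuous trait.

**Leakage discipline.** Inside cross-validation, every ingredient —
association scans for GPRS and the elastic-net candidate set, tuning folds,
GRM allele frequencies, training-fold frequencies used to impute missing
dosages at scoring time — is recomputed from the training folds only. The
guard test for this is behavioral: on signal-free data every method's
cross-validated AUC must sit at 0.5.

**Allele reconciliation.** The scorer matches effect SNPs by id and allele
pair; swapped A1/A2 labels contribute through the flipped dosage $2 - x$;
anything else is dropped and counted, and scoring aborts if fewer than half
the effect SNPs are usable. Palindromic SNPs are removed at QC rather than
strand-guessed.

**Quality control order.** Filters run INFO → MAF → Hardy-Weinberg →
palindromic, each on the survivors of the previous step, with MAF and HWE
recomputed on the current samples; the order is fixed and reported because
removal counts depend on it. The HWE test is the exact conditional test on
heterozygote counts (no mid-p correction). Relatedness pruning scans pairs
in ascending index order and removes one member uniformly at random,
seeded — deterministic and order-stable.

## Study conditions used by the shipped checks

The acceptance-style tests run at fixed, package-chosen sizes: heritability
recovery at $n = 2000$, $m = 1000$ over 20 replicates; null-data mixture
sparsity at $n = 1000$ training samples, $m = 2000$; the method-ranking
comparison on a $\pi_4$-dominated architecture ($h^2 = 0.5$, 2400 training
and 600 test samples, $m = 2000$, shortened chains of 1200 iterations) over
10 replicates; the confounding experiment with two subpopulations at
$F_{st} = 0.05$ (the scale of intra-European differentiation),
`confounding_delta = 0.5`, and study, external-validation and reference
sets carved from one shared pool so that all three share a SNP panel and
one true model. The reference slice is a synthetic stand-in for an external
reference panel. Prevalences in simulator tests are 0.1–0.3 so that finite
pools yield enough cases; the clinical-utility numbers use the real disease
prevalences analytically.

## Known limitations

* Independent SNPs: no LD-aware effect estimation is exercised, and the
  effective-marker-number statistic ($M_e = 1/\mathrm{Var}(G_{jk})$,
  $j<k$) is only validated in its independent-marker regime. It is
  documented as invalid for related or structured samples.
* The elastic net reports the penalized coefficients as-is; like the
  profile score it is not calibrated (regression slope of outcome on score
  far from 1), which the calibration diagnostic makes visible.
* Binary-trait heritability estimates are on the observed 0/1 scale of the
  ascertained sample; no transformation to the liability scale is applied,
  since the pipeline uses variance components only for prediction.
* The Gibbs sampler is single-chain; the chain log is provided for
  diagnostics, but no automatic convergence test is run.
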