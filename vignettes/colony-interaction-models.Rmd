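---
title: "Quantitative modeling of fetal hemoglobin regulation in edited colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative modeling of fetal hemoglobin regulation in edited colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbfedit)
```

## The scientific setting

Fetal hemoglobin (HbF, made from the γ-globin genes *HBG1*/*HBG2*) is
silenced in adult erythroid cells by trans-acting repressors — chiefly
BCL11A and ZBTB7A — acting on cis-regulatory elements of the β-globin
locus: a 13 bp BCL11A-binding element in the proximal *HBG1*/*2*
promoters, and distal elements near the adult genes, including a 3.5 kb
region upstream of *HBD* implicated in the phenotypic difference between
HPFH deletions (benign, high HbF) and δβ-thalassemia deletions.
Re-creating these naturally occurring mutations by CRISPR editing in
primary hematopoietic stem and progenitor cells, then genotyping and
phenotyping hundreds of single erythroid colonies (BFU-E), turns each
colony into one observation of a genotype–phenotype map: how many alleles
of each element are disrupted, and what fraction of β-like globin mRNA is
fetal.

This package implements the full quantitative side of such a study:
dosage genotyping, qPCR expression quantification, interaction linear
mixed models, chromatin-contact normalization, and a synthetic-study
generator that makes every stage testable without any external data.

## Genotype dosage coding

Each colony is coded on ordinal dosage scales:

* **HBG promoter dosage 0–4** — number of disrupted promoter alleles
  among the four (2 × *HBG1*, 2 × *HBG2*; the homologous promoters act
  semi-autonomously and are pooled). An allele is disruptive when **more
  than 2 bp** of its edit overlap the 13 bp element (positions −101 to
  −114 relative to the TSS). The rule is applied on the reference frame
  of the unedited amplicon with 0-based half-open intervals; a 2 bp
  substitution inside the window is *not* disruptive (the rule is
  strict), and substitutions count toward the edited-base total exactly
  like indels, since the underlying logic is occlusion of the
  BCL11A-binding site, which does not care how the bases were changed.
* **BCL11A allelic series 0–3** — 0 none, 1 heterozygous exon-2
  frameshift, 2 heterozygous exon-4 frameshift (exon-4 heterozygotes act
  beyond haploinsufficiency, hence the higher rank), 3 biallelic
  frameshift. Colonies heterozygous at both exons have no slot in this
  ordering and are excluded rather than forced into a rank. A plain
  exon-2 dosage (0–2) is available for designs that only perturb exon 2.
* **ZBTB7A dosage 0–2** — frameshift alleles. A frameshift is an indel
  whose length is not a multiple of 3.
* **Structural elements (HBB–HBD, HBD-3.5kb, HBB-3.5kb) 0–2** — called
  from three junction qPCR assays (internal amplicon, deletion junction,
  inversion junction). Presence is qualitative amplification below a Ct
  cutoff (default 35 cycles; the assay is used as a yes/no readout, so
  the exact cutoff only needs to separate amplification from
  no-amplification). Inversions are flagged; colonies with no
  amplification in any assay are uninterpretable and excluded; a
  positive whole-region scan (deletion spanning *HBG1*/*2* to *HBB*,
  an artifact of delivering promoter and structural guides together) is
  likewise an exclusion.

## Expression quantification

Globin transcripts are quantified by qPCR and the ΔCt method against the
α-globin (*HBA1*/*2*) endogenous control:
`rel = E^(Ct_ref − Ct_target)` with amplification efficiency `E = 2` by
default (configurable; the plate protocol does not fix an efficiency
model, and per-assay calibration curves can replace the default).
Technical replicates are averaged on the Ct scale before ΔCt. The
modeled response is the fetal fraction of β-like mRNA,
`HBG/(HBG + HBB)`; its complement is the HBB fraction, and the two
always sum to 1 (or 100 on the percent scale). The combined HBG signal
is split between *HBG1* and *HBG2* by the G:A peak ratio at the
discriminating position of the Sanger chromatogram, conserving the
total. A transcript undetected in a sample whose control amplified is
treated as absent (ratio 0), not missing.

## The interaction mixed model

The central estimator is the linear mixed model

$$y = X\beta + Z\mu + \varepsilon,$$

where $y$ is the per-colony expression measure, $X$ contains an
intercept, the dosage variables and their pairwise products, and $Z$
contains indicator columns for cell donor and for the guide set
delivered in each condition (independent random intercepts; the
unperturbed control condition can be made the reference level so that
its basal expression is carried by the intercept). The product terms are
the genetic-interaction parameters: on the fetal fraction, $\beta_{12} >
0$ means two perturbations reinforce each other (synergy), $\beta_{12} <
0$ means they act through overlapping pathways (antagonism), and
$\beta_{12} = 0$ gives parallel interaction-profile lines.

Three preset fixed-effect structures cover the study questions
(`model_formula()`): the two partial deletions with their interaction;
the HBB-3.5kb element and HBG promoter dosages crossed with the BCL11A
series; and the HBB-3.5kb element and ZBTB7A crossed with the BCL11A
series.

### Estimation

Variance components are estimated by REML, profiled over the ratios
$\lambda_k = \sigma_k^2/\sigma_e^2$. Each criterion evaluation works
through the $q \times q$ capacitance matrix $I + S Z'Z S$
($S = \mathrm{diag}\sqrt{\lambda}$), so the cost per iteration is
$O(q^3 + p^3)$ after one pass over the data — fits at a few hundred
colonies take milliseconds. The optimizer is Nelder–Mead (Brent for a
single component) on $\log\lambda$, from three fixed starting values
($\lambda = 1, 0.05, e^2$), followed by a high-precision L-BFGS-B
polish; everything is deterministic given the data, and permuting rows
leaves the estimates unchanged. Non-negativity is automatic on the log
scale; components that collapse below $10^{-6}$ are reported as boundary
estimates, not errors. In the zero-variance limit the generalized
least-squares solution coincides with ordinary least squares, and for a
balanced one-way layout the REML components equal the ANOVA
method-of-moments closed forms — both serve as exact oracles in the test
suite, alongside a head-to-head equivalence check against lme4/lmerTest
(which the package reproduces to ~1e-6 in coefficients and ~1e-2 in
denominator df, but does not call).

### Inference

Fixed-effect tests use the Satterthwaite approximation: for a contrast
$c$, the effective degrees of freedom are

$$\nu = \frac{2\,[\mathrm{Var}(c'\hat\beta)]^2}{g' A g},$$

with $g$ the gradient of $\mathrm{Var}(c'\hat\beta)$ with respect to the
variance components and $A$ their asymptotic covariance (twice the
inverse Hessian of the −2 REML log-likelihood, both obtained by central
finite differences with steps scaled to the component magnitudes).
Components at the zero boundary are held fixed during differentiation;
a singular information matrix falls back to the residual df with a
warning. With no random terms the df are exactly $n - p$. Calibration
was checked by simulation: under a null interaction the nominal 5% test
rejects at ~5% (the package's acceptance checks run 2000 replicates of
120 colonies), and 95% confidence intervals cover a non-zero generating
interaction at their nominal rate at 500 colonies. No multiplicity
correction is applied across the three preset models; p-values are
reported raw.

`interaction_profile()` and the `plot` method evaluate the fitted
surface over the observed dosage grid with t-based confidence bands —
the standard visualization in which non-parallel lines reveal an
interaction. Predictions outside the coded dosage range warn about
extrapolation.

### Response scale

The response scale behind such models is a genuine design choice: the
package defaults to the identity scale on the fetal fraction (effects
are additive percentage-point changes, the natural scale for a
proportion bounded well away from the extremes in this system), with a
log option (`transform = "log"`) when fold-change additivity is more
plausible. Interaction coefficients are scale-dependent, so fits on
different scales are not numerically comparable.

## Chromatin interaction quantification

Locus-specific contact profiles (from biotinylated dCas9 affinity
capture of a bait region) are reduced to a **relative interaction
frequency per kilobase**:

$$\mathrm{rif}_t = \frac{n_t \times 10^6}{\text{bait size (bp)} \times \sum_s n_s},$$

computed after discarding records with significance score BF < 20
(inclusive at exactly 20). Filtering precedes normalization — the
quantitative profile is defined over significant contacts only — so the
two operations do not commute and the pipeline fixes this order. The
rif values are invariant to uniform count scaling and conserve
$\sum_t \mathrm{rif}_t = 10^6/\text{bait size}$ exactly, which the tests
assert to 1e-9. For a multiplexed bait tiled by several sgRNA anchor
windows, the bait size defaults to the union interval of the anchors.
Two conditions (e.g. wild type vs BCL11A knockout) are compared per
(bait, target) pair as differences and ratios of rif.

3C ligation products are normalized per biological replicate to a
control interaction in the housekeeping *TUBA1A* locus by the same
ΔCt arithmetic, then summarized as mean ± SEM across replicates.

## The synthetic study generator

`simulate_colonies()` emulates the editing outcomes of the study design:
four independently edited HBG promoter alleles per colony (one guide
targets the homologous element in both promoters), two alleles per
trans-factor locus with indel lengths drawn from a configurable
spectrum, and per-allele deletion/inversion outcomes for paired-guide
structural elements, with junction-qPCR Ct values synthesized for the
genotyping module. `simulate_expression()` realizes the mixed model
exactly — dosage fixed effects, pairwise interactions, donor and
guide-set normal random intercepts, residual noise — and
`simulate_qpcr_plate()` inverts the ΔCt formula so plate quantification
round-trips the generated expression to numerical precision.

Default generator settings describe a study of 3 donors and 30 colonies
per condition across 15 arms (control, single perturbations, pairwise
combinations), per-allele editing probability 0.7, an indel spectrum
dominated by the recurrent 13 bp deletion (probability 0.5, plus −7,
−2, −1, +1), and per-allele deletion/inversion probabilities 0.35/0.10
for paired guides. The phenotype defaults put the unedited fetal
fraction at 0.20 (the ~20% baseline regime of erythroid colonies),
main effects of +0.08 to +0.15 per dosage unit, interactions of ±0.03
to ±0.07 mirroring the qualitative structure of interest (synergy
between the two partial deletions, antagonism of BCL11A with the cis
elements, additivity of BCL11A and ZBTB7A), and donor/guide/residual
standard deviations of 0.03/0.03/0.08 on the fraction scale. Where the
study design does not pin a value (per-condition colony counts most of
all), these are one-time choices of realistic magnitudes, not fitted
quantities.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: sequence-specific editing outcome biases
(microhomology), zygosity correlation between alleles of one cell,
clonal substructure within a colony, qPCR efficiency drift and plate
effects, chromatogram trace artifacts beyond a two-peak G:A ratio, and
any non-Gaussian donor effect. Identity-scale fractions are clipped to
[0, 1]; `clip = FALSE` yields the raw Gaussian response, which is what
the estimator-calibration experiments draw from, since they check the
estimator under its own assumptions.

Every simulation accepts a seed and is bit-reproducible; a replicate
study should draw all of its stages from one seeded stream
(`seed = NULL` continues the current stream) rather than reseeding each
stage with nearby integers, which measurably couples the streams.

## Numerical and degenerate-input policy

* Coordinates are 0-based half-open everywhere, in memory and on disk.
* Non-finite Cts propagate as missing; a zero denominator in a fraction
  (no β-like signal, both chromatogram peaks zero) is missing, not 0.
* A zero total interaction count for a bait is an error (the profile is
  undefined), as is a log transform of a non-positive response.
* Rank-deficient fixed-effect designs (e.g. an all-constant dosage) are
  rejected with the offending columns named; fewer observations than
  fixed-effect columns is an error.
* Colony exclusions (ambiguous BCL11A double-heterozygotes,
  uninterpretable junction assays, whole-region deletions) are dropped
  from designs and enumerated with reasons in the pipeline log.

## Problem sizes used in the checks

The packaged statistical checks use a balanced one-way layout of 6
groups × 10 for the closed-form REML oracle; 2000 replicates of 120
colonies (4 conditions × 30, 4 donors) for type-I calibration; 200
replicates of 500 colonies (4 conditions × 125, 3 donors) for bias and
coverage of a generating interaction of 0.05; 10,005 colonies for the
genotyping round trip; and 10,000 read pairs per bait for the chromatin
checks. These sizes put Monte-Carlo error comfortably inside the
assertion bands while keeping the default test run to a few minutes.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
sim <- simulate_colonies(sim_config())
geno <- call_genotypes(sim$alleles, sim$junctions,
                       colony_info = sim$colonies[1:3])
expr <- simulate_expression(sim, phenotype_model(), seed = 2)
plate <- simulate_qpcr_plate(expr, seed = 3)
d <- merge(geno, quantify_plate(plate), by = "colony_id")

fo <- model_formula("dd_interaction")
fit <- colony_lmm(fo, model_subset(d, fo),
                  ref_levels = c(guide_set_id = "AAVS1"))
summary(fit)
plot(fit)
```

Or end to end from one config:

```{r pipeline, eval = FALSE}
run_pipeline(list(seed = 1, outdir = "study_out"))
```

## Known limitations

The model family is deliberately small: independent random intercepts
only (no random slopes, no donor-by-guide interaction variance), no
Kenward–Roger correction, no generalized or Bayesian variants. The
Satterthwaite test is mildly anticonservative when a variance component
must be estimated from very few levels (three or four guide sets), the
same behavior the reference implementations show; with the default
study sizes the effect is within a half percentage point of the nominal
5% level. Chromatin significance scores are treated as opaque
per-record inputs — computing them from read-level data is outside the
package's scope, as are base-caller/aligner stages and protein-level
(HPLC, flow cytometry) phenotypes.
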