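---
title: "Linking epithelial-mesenchymal signatures to stemness and survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking epithelial-mesenchymal signatures to stemness and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emstate)
```

## The scientific problem

Carcinoma cells move between an epithelial (E) state -- cobblestone
morphology, tight junctions, CDH1/EPCAM/CD24 expression -- and a
mesenchymal (M) state -- fibroblast-like, motile, VIM/DCN/ZEB2 expression.
Which of the two marks cancer stem cells has been contested, because
luminal cell lines enrich stem-like behaviour with M markers while basal
lines do so with E markers. A resolution is the *hybrid E/M* hypothesis:
stem-like cells co-express both programs in the same cell, so a **mixed EM
signature** (top E genes plus top M genes together) should predict poor
outcome regardless of tumour subtype, and single-cell profiling should
find individual cells expressing both panels.

`emstate` implements the complete computational chain behind that
hypothesis as reusable, tested components:

1. **signatures** -- derive E/M/EM gene signatures from clone-labelled
   expression arrays;
2. **survival** -- score patient cohorts with a signature, classify
   subtypes from marker probes, dichotomize at the best cutoff, and
   estimate Kaplan-Meier/logrank/Cox summaries;
3. **resampling** -- random-gene-set permutation nulls and
   gene-subsampling robustness;
4. **singlecell** -- raw qPCR Cq processing into an E-M state space,
   co-expression counts, the exact cross-match test, Mann-Whitney U, PCA
   and correlation summaries;
5. **synthetic data** -- generators with known ground truth;
6. a thin orchestration layer, `run_pipeline()`.

## Signature derivation

Arrays are normalized by *central tendency* (each sample's median shifted
to zero) and optionally *relative normalization* (values expressed
against the per-gene mean of a reference group; the default reference in
`run_pipeline()` is the pooled E and M clones, i.e. the intermediate
expression between the two morphologies).

Differential expression between E and M clones uses a two-sample t
statistic with a simple empirical-Bayes variance moderation: per-gene
pooled variances $s_g^2$ (df $d = n_1 + n_2 - 2$) are shrunk towards
their mean $s_0^2$ with `prior_df` ($d_0$, default 4) pseudo-observations,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},\qquad
  t_g = \frac{\bar x_{E,g} - \bar x_{M,g}}
             {\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

referred to $t_{d_0 + d}$. This is deliberately a light-weight moderation:
the downstream contract is *ranking by effect size* (the difference of
group means on the log2 scale, positive = higher in E), and a test in the
suite confirms that effect sizes equal limma's log-fold-changes exactly
and that the moderated t ranks are concordant with limma's. Significance
is flagged at Benjamini-Hochberg adjusted $p < 0.01$ by default
(`adjust = FALSE` switches to raw p-values). Ties in $|$effect$|$ break by
smaller p, then gene id, for reproducibility.

`rank_signature()` takes the top `n` significant genes per direction
(shortage raises an error naming the direction unless `cap = TRUE`), and
`compose_em_signature()` interleaves the top `k` of each into a `2k`-gene
EM signature (typical sizes: 60 = 30 + 30, and 24 = 12 + 12). Probes are
treated as genes -- no collapsing is attempted unless the caller maps
probes to genes beforehand.

## Survival analysis

Patients are scored by the **unweighted mean log2 expression** of the
signature genes present in their profile (missing genes are dropped with
a warning; zero overlap is an error). Subtypes come from three marker
probes on the linear scale with strict-greater cutoffs (ESR 500,
MKI67 470, HER2 4800): luminal A (ESR+, HER2-, MKI67 low), luminal B
(ESR+, HER2-, MKI67 high; or ESR+, HER2+), basal (ESR-, HER2-), HER2
(ESR-, HER2+). The four labels partition every record with complete
probes; strictness at the cutoff value is a determinism choice, and both
the cutoffs and the direction are configurable.

`select_best_cutoff()` evaluates the logrank p at the five quantiles
implied by "median, quartile or tertile" splits
($\{0.25, 1/3, 0.5, 2/3, 0.75\}$), skipping candidates that leave fewer
than two patients on a side, and returns the smallest-p candidate, with
"high" meaning score strictly greater than the cutoff value. The selected
p is reported as-is, exactly as best-cutoff scanning tools report it;
this is an optimistic p (a multiple-testing caveat applies), and
`permutation_null()` provides the honest calibration against random gene
sets subjected to the *same* search. The logrank statistic is the
standard observed-minus-expected form over shared risk sets (validated
against `survival::survdiff` in the tests); the hazard ratio of high vs
low comes from a single-covariate Cox partial likelihood with Breslow tie
handling (`survival::coxph`) with a Wald 95% interval, and complete
separation is flagged rather than reported as a finite estimate.
OS and RFS are handled as separate endpoint labels; no competing risks.

## Permutation null and gene subsampling

`permutation_null()` draws random gene sets of the signature's size
uniformly (without replacement, from the full universe including the
signature's own genes -- no exclusion rule is applied) and re-runs the
*identical* pipeline per draw, including the best-cutoff search
(`fixed_cutoff` freezes the split instead; the default re-search is the
conservative choice). Extremeness is ordered by the signed logrank
statistic $z = \operatorname{sign}(\log \mathrm{HR})\sqrt{\chi^2}$, i.e.
larger $z$ is stronger evidence of *poor* outcome, and a null set counts
when $z_{\text{null}} \ge z_{\text{obs}}$ -- for an observed HR > 1 this
is identical to "null logrank p at most the observed one with the HR on
the same, poor-outcome side of 1". The tempting alternative rule "p at
most observed and HR on the same side *as observed*" is not a valid
p-value ordering: under the null it conditions on the random observed
direction and concentrates the permuted p on $(0, \tfrac12)$, whereas a
fixed ordering keeps it exactly uniform -- which the calibration test
verifies. `two_sided = TRUE` orders by $|z|$ instead. The reported p uses
the add-one estimator $(1 + \#\text{extreme})/(B + 1)$, so it is never
zero and is exactly uniform under the null. The historical
analysis ran $10^6$ draws; the calibration tests here run 199 draws per
replicate, which is sufficient to verify uniformity -- the estimator, not
the draw count, is the object under test.

`bootstrap_subsignatures()` draws `n_sets` subsets of `subsig_size`
distinct genes from a pool (e.g. 10 out of the 24 most EM-specific
genes), evaluates each, and summarizes the fraction with HR > 1 and the
fraction significantly associated with poor outcome.

## Single-cell qPCR processing

Raw Fluidigm-style plates carry Cq values per (well, assay) with empty
cells meaning no amplification. The chain is:

* **Background**: per-assay $C_{bg}$ = the *minimum* Cq over that assay's
  NTC wells -- the most conservative deterministic reading of
  "estimated background from NTC reactions" -- with a global fallback
  (default 24 cycles) for assays whose NTCs never amplify.
* **Expression**: $2^{C_{bg} - C_q}$ when $C_q < C_{bg}$; exactly 0 for
  $C_q \ge C_{bg}$ or no amplification.
* **Normalization**: per gene, division by the maximum over *single-cell*
  wells only; 100-cell pools are scaled by the same factor (and may
  exceed 1); a gene undetected in every single cell stays 0. The step is
  idempotent.
* **State space**: each cell maps to (mean over the 10 E-panel genes,
  mean over the 7 M-panel genes) of its normalized values; group means
  give the "crosses" of the state-space plots. The default panels are the
  published 10 E / 7 M marker genes (`em_panels()`), overridable.

Co-expression counting calls a cell *co-expressing* when at least one E
and one M gene are detected, *exclusive* when only one panel is, and
*silent* otherwise. PCA standardizes every gene to zero mean and unit
variance (zero-variance genes dropped with a warning) and fixes loading
signs so each component's largest-magnitude loading is positive.

## The cross-match test

To ask whether two groups of cells occupy different regions of the state
space without distributional assumptions, all cells are paired by an
**exact minimum-weight perfect matching** of the complete graph on their
pairwise Euclidean distances (a rank-based distance is available), and
the statistic $A_1$ counts pairs joining different groups: separated
groups pair within themselves, so small $A_1$ is evidence of separation.
Conditional on the matching, uniformly random labels give the closed-form
null

$$P(A_1 = a_1) = \frac{2^{a_1}\, I!}
 {\binom{N}{n_1}\, a_0!\, a_1!\, a_2!},\qquad
 a_0 = \tfrac{n_1 - a_1}{2},\; a_2 = \tfrac{n_2 - a_1}{2},\; I = N/2,$$

and the reported p is the lower tail $P(A_1 \le a_1)$. The test suite
verifies this closed form against exhaustive enumeration of all labelings
for every configuration up to 12 units.

The matching itself is computed by a blossom primal-dual algorithm
(O(n^3), in C++): distances are mapped affinely to positive integer
weights at $10^{12}$ relative resolution, under which the maximum-weight
matching on a complete even graph is perfect and minimizes the original
distance sum. The algorithm is deterministic for a fixed input, which is
what reproducibility requires; among exactly equal-weight matchings the
algorithmic order decides (a measure-zero event for continuous
coordinates). Odd group totals add a phantom unit farther from every real
unit than any observed distance; its matched partner is removed before
counting and the null uses the reduced even count.

Note the test is *exact but discrete*: with 8 cells per group the
achievable $A_1$ values are $0, 2, 4, 6, 8$ with null masses
$0.0054, 0.174, 0.522, 0.278, 0.020$, so the only rejection region inside
$\alpha = 0.05$ is $\{A_1 = 0\}$ and the realized size is 0.0054 -- far
below the nominal level. Calibration statements about small plates should
therefore be made against the exact null masses, not against the nominal
$\alpha$; the suite checks the realized rejection rate against
$P(A_1 = 0)$ directly.

Mann-Whitney U comparisons of one panel's aggregate at a time are
two-sided, exact for both samples at most 20 without ties, tie-corrected
normal approximation otherwise.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *structure* of the study's three data types
with known ground truth; defaults are chosen once to mirror the
described designs.

* `generate_clone_matrix()` -- 6 E-clone vs 4 M-clone arrays, baseline
  log2 intensities i.i.d. Normal(8, 1), 30 planted E-up and 30 M-up genes
  shifted +3, per-array offsets (sd 0.3) to exercise normalization.
  With the default noise sd of 1 the planted effect is 3 noise-sd units;
  at the 6-vs-4 design this gives an effect-size standard error of 0.65,
  so the extremes of ~940 null genes overlap the weakest planted genes
  and *exact* top-30 recovery is not statistically guaranteed -- the
  recovery property tests therefore also run at noise sd 0.5, where
  recovery is essentially certain. This is a property of the design (10
  arrays), not of the estimator.
* `generate_cohort()` -- a latent score per patient drives both the
  signature genes (loading 1, noise sd 1) and an exponential hazard
  $h_0 e^{\beta s}$ ($h_0 = 0.02$/month); censoring is uniform with the
  horizon calibrated by root-finding so the expected censoring fraction
  hits the target (default 20%); marker probes are drawn around the
  classification cutoffs to populate all four subtypes
  (35/25/20/20%). Exponential times keep closed-form sanity checks easy.
* `generate_cq_plate()` -- three latent states with log2 archetypes:
  E state expresses the E panel at log2 6 and the M panel at a low but
  detectable log2 1 (epithelial cells are promiscuous); the M state
  expresses the M panel at log2 6 and the E panel at log2 -3, far below
  detection (mesenchymal cells are exclusive); hybrids sit at half the
  pure linear level on both panels. Detection is Bernoulli with a
  logistic probability in latent log2 expression (slope 1.2, midpoint
  1.5), measured Cq is $C_{bg} - \log_2(\text{latent})$ plus noise
  (sd 0.5), NTCs amplify with probability 0.02 at or beyond background,
  and 100-cell pools sum 100 latent draws. Because the dropout curve has
  a midpoint, flattening it (smaller slope) increases dropout of
  *expressed* genes while slightly rescuing unexpressed ones; the
  monotonicity test therefore measures non-detection among
  panel-concordant reactions.

What passing tests on these generators do **not** show: real microarray
probe-level artefacts, scRNA-qPCR efficiency differences between assays,
batch structure, non-proportional hazards, or the covariate correlations
of a real clinical registry. The synthetic cohort results validate the
estimators, not the biological claim.

## Numerical and design choices

* Moderation prior df = 4: small enough to respect per-gene variance at
  10 arrays, large enough to stabilize it; the contract is ranking.
* Quantile type is R's default (type 7) everywhere a cutoff is taken.
* Matching weights are scaled to integers at $10^{12}$ relative
  resolution; below that, distances are treated as ties.
* All generators restore the caller's RNG state; every pipeline stage
  derives its own child seed from the configuration seed, so reruns are
  byte-identical (`report.json` carries the seed).
* Problem sizes in the calibration tests (200 replicates; 199
  permutation draws; cohorts of 60-300; 1000 cross-match replicates at
  8 + 8) were sized to estimate each rate to well inside its assertion
  band.

## Known limitations

* The best-cutoff logrank p is optimistic by construction; use the
  permutation null for calibrated claims.
* The cross-match p is conservative on small plates (discreteness, see
  above).
* `evaluate_signature_survival()` fits a single binary covariate; no
  multivariate adjustment.
* Published co-expression counts from the study's raw supplementary Cq
  tables can be recomputed with `read_cq_plate()` +
  `process_cq_plate()` + `count_coexpressing()` once the user supplies
  those tables; they are third-party data and not shipped.

## A worked run

```{r, eval = FALSE}
cfg <- list(seed = 1, out_dir = "run1",
            clone = list(n_genes = 1000, noise_sd = 0.5),
            signature = list(n_per_direction = 150, k_em = 30),
            cohort = list(n_patients = 300, beta = 0.5),
            permutation = list(n_perm = 999),
            plate = list(n_e = 24, n_m = 24),
            singlecell = list(compare = c("E", "M")))
report <- run_pipeline(cfg)
str(report)
```
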