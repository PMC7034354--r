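---
title: "Methods: longitudinal cytokine-microbiome analysis in pregnancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal cytokine-microbiome analysis in pregnancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregbiome)
```

# The study design this package serves

A pregnancy cohort is sampled longitudinally: women with inflammatory bowel
disease (Crohn's disease, ulcerative colitis, or unclassified IBD)
contribute faecal and serum samples at up to five timepoints — prepregnancy
(`pre`), the three trimesters (`T1`-`T3`) and postpartum (`post`) — while
healthy pregnant controls contribute samples at `T1`-`T3` only. The
microbiome arrives as a 16S feature table with taxonomy and a rooted
phylogeny; the immune state as a twelve-cytokine ELISA panel (IL-4, IL-5,
IL-6, IL-8, IL-9, IL-10, IL-12, IL-15, IL-17, IL-21, TNF-α, IFN-γ) in
pg/mL. Missingness is pervasive in such cohorts: subjects skip timepoints,
and a short serum aliquot means only a subset of cytokines was measured.
Every function in this package treats missingness as a first-class state
(empty cells, never sentinel values) and records the n actually used by
each test.

# Normalisation model

The microbiome normalisation chain is fixed in this order:

1. **Genus merge.** Each genus value is the *arithmetic mean* of the
   relative abundances of the features assigned to that genus. Averaging
   (rather than summing) makes the genus value an estimate of the typical
   member-feature abundance; the merged table is deliberately *not*
   renormalised to sum to one, because the downstream transform is
   per-genus and scale differences between genera are absorbed by the
   z-score. Features lacking a genus rank are pooled into
   `g__unclassified.<family>` buckets so nothing silently disappears.
2. **Pseudo-count log transform.** `x -> log10(x + 0.01)`. The pseudo-count
   0.01 is applied on the relative-abundance scale in `[0, 1]`, so an
   unobserved genus maps to exactly −2 on the log10 scale. The abundance
   scale for the offset is a genuine design choice (one could equally add
   0.01 on a percentage scale); it is fixed here, and configurable, because
   the zero-map value −2 keeps absences within ~2 log units of typical
   abundances rather than dominating the variance.
3. **Whitening.** Per genus: subtract the mean, divide by the standard
   deviation (sample SD, denominator n−1 — the conventional estimator;
   configurable in principle but fixed across the package for
   comparability). Genera with zero variance have no defined z-score and
   are dropped with a warning. The whitening statistics are kept on the
   returned object, so the transform fitted on one set of samples (a
   training fold, an analysis subset) can be applied frozen to new samples.
   Whitening scope is always *the subset passed in*: the package never
   silently fits statistics on a wider cohort than the analysis set.
4. **Detrending (optional).** For each genus and timepoint, subtract the
   mean of that genus over the samples at that timepoint. This removes the
   shared effect of gestational time, leaving between-subject variation.
   The operation is idempotent, and a timepoint observed in a single sample
   is mapped to exactly zero (its own mean) — logged, since such a sample
   carries no between-subject information afterwards.

Reordering whitening and detrending changes the result (detrended columns
no longer have unit variance), which is why the package exposes the chain
as `normalize_microbiome()` with a fixed order rather than as freely
composable pieces.

# Diversity

Alpha and beta diversity are computed on a rarefied table: samples with
fewer than `rarefaction_depth` reads (default 5928, the depth threshold the
study design uses) are removed, the rest subsampled without replacement to
exactly that depth. Depth filtering and rarefaction are conceptually
separate switches — the retained-sample rule and the equal-depth rule — and
both are applied by default.

* **Faith's PD** is the total branch length of the minimal subtree spanning
  the root and every observed leaf. Implemented by per-branch bookkeeping
  (a tips × edges incidence matrix built in postorder) and tested against
  an independent brute-force oracle that unions root paths per leaf.
* **Shannon** uses base-2 logarithms (bits), matching the common QIIME 2
  convention; **Pielou** divides by `log2(richness)`, so the base cancels.
  A single-taxon sample has Shannon 0 and undefined evenness (`NA`).
* **Unweighted UniFrac** is the fraction of observed branch length unique
  to one of the two samples (pure presence/absence, taken after
  rarefaction). **Weighted-normalised UniFrac** is
  `sum(b |p − q|) / sum(b (p + q))` over branches with subtree proportions
  p, q; the normalisation bounds it in `[0, 1]`. Both are checked against a
  branch-enumerating oracle to 1e−10 on random instances.
* **PERMANOVA** is the package's beta-diversity significance test: one-way
  pseudo-F from between/within sums of squared distances with a label
  permutation null, `p = (1 + #{F* ≥ F}) / (1 + n_perm)`, default 999
  permutations. The choice of PERMANOVA (rather than, say, ANOSIM) follows
  the dominant convention of the QIIME 2 toolchain; the permutation count
  is configuration, and printed p-values from any particular study are not
  expected to be reproduced by a different draw of permutations.

# Differential abundance

`lefse_like()` is a two-class, two-stage screen. Stage one tests each genus
with Kruskal-Wallis at `kw_alpha = 0.05`. Stage two computes, for survivors
only, an effect size on the LEfSe parts-per-million scale: over 30
bootstrap rounds a stratified two-thirds subsample is drawn and the
absolute class-mean difference along the one-dimensional Fisher
discriminant recorded; the effect size is the log10 of the bootstrap
average, signed by which class has the higher mean, thresholded at
`|score| ≥ 2`. Two deliberate simplifications relative to the canonical
multi-stage procedure: there is no subclass (within-class Wilcoxon) stage,
because the designs this package serves have no subclass structure; and
the discriminant is per-feature (with a unit-norm direction the projected
class difference reduces to the raw mean difference), because the screen is
already univariate. Bootstrap draws are made in sorted-label order so that
swapping the class labels flips every sign and changes nothing else — a
tested invariant.

# Classification

`loocv_linear_svm()` holds out one sample per fold, refits the
pseudo-count/log/whitening transform on the training fold, applies it
frozen to the held-out sample, trains a linear soft-margin SVM with box
constraint C = 1, and records the signed decision value. Per-fold
renormalisation is mandatory: fitting the z-score on all samples first
would leak the held-out sample's value into the transform. The AUC is the
midrank (Mann-Whitney) statistic over the n held-out decision values, so it
is invariant under monotone transforms and equals the brute-force
pairwise-comparison count (a tested invariant). No kernels and no
hyperparameter search are offered: with dozens of samples and tens of
genera, flexibility is overfitting. The realized support-vector count is
reported per fold rather than being a control: fixing the number of support
vectors is not a standard SVM parameter, so a stated count in a report
should be read as a post-hoc observation.

# Cytokine statistics

All panel tests are nonparametric by design. Shapiro-Wilk normality is
computed and logged per cytokine for transparency, but never switches a
test: serum cytokine panels are heavily skewed, and mixing test families by
per-cytokine normality outcomes would make the battery incoherent.

* **Prepregnancy versus trimester**: Wilcoxon matched-pairs signed-rank on
  complete pairs; zero differences are dropped (the classical convention;
  if every pair is tied the test reports p = 1 — no evidence of change).
  Exact null distribution for ≤ 25 pairs without ties, normal approximation
  with continuity correction otherwise.
* **Across trimesters**: Friedman on subjects with all three trimester
  values; when p < 0.05, Dunn's pairwise z-tests on the mean ranks with
  Bonferroni adjustment over the three pairs. Bonferroni is the
  conservative default where the multiplicity scheme is not otherwise
  pinned down; it is configurable.
* **Between groups per timepoint**: two-sided Mann-Whitney with midrank
  ties, skipping (with a flag) any cell with fewer than two measured
  subjects per group.
* **PCA**: cytokines are unit-variance scaled; missing entries are imputed
  by iterative low-rank SVD (rank = number of components, tolerance 1e−6,
  ≤ 100 iterations; on complete data the imputation is a no-op and the
  result is plain SVD PCA). Per group, a 95% prediction ellipse is drawn
  from the group mean and covariance of the first two scores with
  chi-squared(2) radius — the region in which a new observation from the
  group falls with probability 0.95 under a Gaussian model. One property
  worth knowing: after unit-variance scaling every cytokine contributes
  variance 1, so a group separation carried by a *single* cytokine can
  never dominate PC1 in a twelve-cytokine panel; visible PC1 separation
  implies a multi-cytokine signature.
* **Heatmap matrix**: per-cytokine medians by timepoint, min-max scaled
  within cytokine (0 = lowest median over the study, 1 = highest), plus
  average-linkage hierarchical clustering of complete samples on the scaled
  panel, verified against a brute-force agglomeration oracle.

# The dynamic network

The dynamic model asks a directional question correlation alone cannot:
does the *current* state predict the *next change*? For each subject, each
pair of consecutive *observed* timepoints (ordering
`pre < T1 < T2 < T3 < post`) forms a transition carrying bacteria z-scores
and cytokine pg/mL levels at the first timepoint and the deltas to the
second. Consecutive-observed (rather than calendar-adjacent) pairing is the
default because cohort missingness would otherwise discard most subjects; a
calendar-adjacent mode is available. Transitions are pooled across
subjects — with at most four transitions per subject, within-subject
correlation is not estimable.

Three correlation families are computed (Pearson r; two-sided p from the
exact t transform with df = n − 2, n the pairwise-complete transition
count): bacteria level → cytokine change, cytokine level → bacteria change,
and bacteria level → bacteria change (self-pairs allowed only here — a
taxon may predict its own regression). The fourth conceivable family,
cytokine level → cytokine change, is excluded by default (available by
flag): the model's purpose is the microbiome-immune interface plus
bacterial ecology, and adding within-panel autocorrelations would multiply
the test burden without serving it.

**The scrambled null.** Significance is calibrated by scrambling: bacterial
profiles are permuted across transitions while cytokines stay fixed, all
three families recomputed, and the minimal p per scramble recorded. Whole
profiles are permuted — not per-genus values — so the compositional
covariance between genera survives under the null; scrambling genera
independently would destroy it and understate the null. Two independent
non-identity permutations are drawn per scramble, one for the level
profiles and one for the delta profiles: a single shared permutation would
leave the bacteria → Δbacteria family intact (each profile would travel
with its own delta) and that family would never be nulled. The null summary
reports both the distribution of per-scramble minimal p and the per-test
pass rate, because "the smallest null p" can mean either. The default edge
threshold of p < 0.01 is the level this kind of scrambled null typically
motivates; it is configuration, reported alongside the observed null minima
rather than re-derived from them, with Benjamini-Hochberg as an alternative
mode (appropriate since the permutation null makes no normality claim).

**Hubs.** The hub of the bacterial subnetwork is the node of maximal total
degree (in + out) within the bacteria → Δbacteria family, with both degree
directions reported. Total degree is used because hub-ness in this model is
about connectivity, and the archetypal hub — a taxon whose *increase* many
other taxa predict — is a high *in*-degree node; an out-degree-only
definition would miss it.

# The synthetic cohort generator

`cohort_spec()` defaults encode the study conditions: 31 CD + 15 UC + 179
control subjects; IBD sampled at up to five timepoints with 20% per-visit
missingness, controls at `T1`-`T3`; per-sample sequencing depth uniform on
[3000, 20000] so a predictable fraction of samples falls below the 5928
filter. Genus counts are Dirichlet-multinomial: a log-scale base
composition, group/flare/parity offsets on designated genus sets, and a
concentration parameter that is lower in the IBD arm (15 versus 50), which
is what produces genuinely lower richness and evenness there. The UC/CD
offset shrinks to a quarter after `T1`, emulating disease-type differences
that attenuate in mid and late pregnancy. The genus tree is a random
coalescent with exponential branch lengths, so UniFrac is exercised on
non-trivial topologies. Cytokines are log-normal with a subject random
effect, an IBD prepregnancy elevation of the proinflammatory members
(IL-6, IL-8, IL-12, IL-17, TNF-α) that drops at conception, a control-only
trimester rise in IL-6 and IL-10, and IBD offsets (IL-8, IFN-γ up; IL-5,
IL-10 down). Where the emulated study does not state a magnitude, values
were chosen once at what practitioners would call moderate effect sizes
(log-scale offsets of 0.5-1) and not revisited.

What the generator does *not* emulate: realistic taxon names, sequencing
error, compositional zero-inflation structure beyond the
Dirichlet-multinomial, batch effects between cohorts, or correlated
missingness. Passing tests on synthetic cohorts therefore demonstrate that
the machinery is correct and calibrated — not that any particular biological
conclusion transfers to real data.

**Planted dynamic couplings.** `plant_dynamic_couplings()` rewrites target
trajectories as `target(t+1) = target(t) + β·source(t) + noise` on the
analysis scales, accumulating increments when several edges share a target,
and returns the planted edges as ground truth (which no analysis stage may
read). One subtlety drove the design of the recovery benchmarks: in a
multi-step system the target's level accumulates past source values, so
planted couplings *induce* genuine second-order correlations (for instance
a driven target correlating with its own subsequent change). The dynamic
correlation model rightly reports those, so a benchmark that counts them as
false discoveries mischaracterises the method. The false-discovery
benchmark therefore uses one transition per subject (60 single-step
subjects), where the planted edges are provably the only true couplings;
multi-step cohorts are used for the sensitivity and hub checks, where
induced edges do not distort the question.

# Numerical and reporting choices

* Cohort-table percentages are rounded half-up to one decimal (matching
  clinical-table convention; base R's half-even rounding would differ on
  ties) and always use an explicit denominator — the number of non-missing
  records for that attribute — because published tables routinely mix
  per-subject and per-pregnancy denominators and inferring them is how
  arithmetic errors propagate.
* Feature-table orientation on disk must be declared (`samples_rows` /
  `features_rows`); auto-detection is refused because a silently transposed
  abundance matrix is the classic microbiome bug.
* All randomised procedures (rarefaction, PERMANOVA, bootstraps, scrambles,
  the generator) take explicit integer seeds; the pipeline derives
  per-stage seeds deterministically from one master seed, so stages rerun
  independently yet bit-identically.
* Test problem sizes were chosen to make the suite informative at desk
  scale: calibration batteries use 500-1000 null replicates at n = 12-30,
  oracle comparisons use 100 random instances with ≤ 20 leaves and ≤ 10
  samples, and recovery checks use 50 seeds at 24-60 samples or 60
  transitions. These are the package's declared verification conditions,
  stated here so they can be scaled up by anyone with more patience.

# Known limitations

* The dynamic model is a first-order correlation screen, not causal
  inference: a common driver of two nodes produces edges between them.
* Pooling transitions across subjects assumes exchangeability of the
  subject trajectories after normalisation; strong per-subject dynamics
  would violate it.
* LEfSe-style scores from the per-feature discriminant are comparable
  within an analysis but not numerically identical to multi-feature LDA
  implementations.
* Prediction ellipses assume within-group Gaussian scores; with n < 10 per
  group they are descriptive at best.
* The generator's Dirichlet-multinomial cannot produce the extreme
  zero-inflation of real 16S data; depth filtering and pseudo-counts are
  exercised, but their behaviour at real-data sparsity should be checked on
  real data.
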