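---
title: "Methods: linking forager brain coexpression to colony traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking forager brain coexpression to colony traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific setting

`antcoex` analyses a hierarchical transcriptomic design that is common in
the study of social-insect collective behavior: gene expression is measured
in the brains of individual foragers (roughly ten per colony across about
nine colonies), while the phenotypes of interest are *colony-level* traits —
here, the sensitivity of colony foraging activity to humidity (fewer
foraging trips made per percent decrease in daily relative humidity) and the
mean forager brain dopamine-to-serotonin ratio (DA:5HT). The package
implements the full chain from raw expression tables to
evolutionary-constraint models, together with a synthetic-data generator
that plants every signal the analysis is designed to detect, so each stage
can be validated by parameter recovery and null calibration.

# Preprocessing

Raw counts are converted to transcripts per million
(TPM\(_g = 10^6 (c_g/l_g)/\sum_h (c_h/l_h)\)); genes with zero variance,
median TPM below 0.5 (strictly; exactly 0.5 is kept), or zero expression in
more than one-third of samples (exactly one-third is kept) are removed;
values are log2-transformed with pseudocount 1. Outliers are then handled
iteratively: expression values more than 3 SD from their gene's mean are
masked, and samples whose mean inter-sample Pearson correlation is more than
2 SD from the overall mean are removed, genes first, until a full pass
changes nothing. Masked cells are imputed by the gene's unmasked mean before
quantile normalization; batch structure is removed by per-gene
location-scale standardization across batches after regressing out protected
biological covariates (colony), whose fitted effects are restored afterward.
This adjuster deliberately omits empirical-Bayes shrinkage across genes: at
tens of samples per batch the gene-wise location/scale estimates are stable,
and the simpler estimator is transparent and exactly testable (batch means
provably equal after adjustment).

A practical note on quantile normalization: because it operates on ranks, a
coordinated expression swing in a large module shifts the ranks — and hence
the normalized values — of *all other* genes coherently. With realistic
module amplitudes (tenths of a log2 unit) the induced background correlation
is negligible, but at amplitudes of a full log2 unit spanning half the
transcriptome it becomes a visible artifact. The synthetic generator's
default amplitudes are set accordingly (see below).

# Expression–trait association

Each gene's association with a colony trait is estimated two ways: the
Pearson correlation of per-sample expression with the colony trait value
replicated to every nestmate (N = samples), and the correlation of
colony-mean expression with the trait (N = colonies). The two coincide
exactly when within-colony variance is zero and colonies are balanced, and
their genome-wide agreement (Pearson r, R² = r²) is reported. The
per-sample estimator is carried downstream as the summary coefficient
because its larger N stabilizes the estimate; its p-values are *descriptive*
under colony structure — replicating a colony value to nestmates
pseudoreplicates, so calibration holds only when within-colony correlation
is absent, which is exactly how the null-calibration fixtures are built
(colony effects off). Colony structure itself is described by PCA on
gene-centered log expression, linear discriminant analysis on the first 30
PCs (at most colonies − 1 axes), a k-nearest-neighbor sample network on
1 − Pearson distance (k = 3, undirected deduplication, nestmate-edge
fraction with a label-permutation p), and per-gene one-way ANOVA F across
colonies (∞ sentinel when within-colony variance vanishes).

# Omnibus gene-set enrichment

For a ranking of genes by trait correlation, the top 50%, 45%, …, 5% slices
(ties at a cut included) are each tested for term enrichment with the
one-sided hypergeometric (Fisher's exact) test, and the ten p-values are
combined as \(X^2 = -2\sum\ln p\) on 20 df. Terms with fewer than 10
annotated genes are skipped; Benjamini–Hochberg correction is applied across
terms within a direction. Because the nested slices are positively
dependent, the combined statistic is **anticonservative as a frequentist
p-value under the complete null** (simulation: ~15% of null terms below
0.05). It is retained as the primary ranking statistic for comparability
with practice, and an optional empirical omnibus p computed by permuting the
ranking (`n_null_perm`) is reported alongside; the permutation p is
calibrated and is the one to use when absolute error rates matter.

# Signed coexpression network

Gene pairs are scored by \(a_{ij} = ((1 + r_{ij})/2)^\beta\) (signed:
anticorrelated pairs are unconnected), with β = 12 by default or chosen as
the smallest candidate whose signed scale-free fit R² reaches 0.8.
Topological overlap
\(TO_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij})/(\min(k_i,k_j) + 1 - a_{ij})\)
feeds average-linkage clustering on 1 − TO. Modules are cut top-down from
the dendrogram root: a branch splits into its two children when both could
hold a module (≥ `min_module_size`, default 80) and the size-weighted mean
within-child TO density exceeds the parent's by at least `gap_depth`
(default 0.2, relative); undersized side branches are peeled off. Peeled
genes whose correlation with a module eigengene reaches `kme_reassign`
(default 0.5, the conventional module-membership cutoff) rejoin that module;
the rest are grey. This density-gain criterion was chosen over a
fixed-height quantile cut after direct comparison: a quantile cut leaves a
permanent trickle of grey stragglers (so the density-filter iteration below
cannot terminate) and a height-gap rule merges distinct modules of moderate
amplitude, while the density-gain rule recovers planted blocks exactly
(ARI = 1 on two-block fixtures, ARI ≥ 0.96 on six-module study-scale
fixtures).

Module density (mean within-module TO) is tested against 10,000
pseudo-modules of matched size drawn uniformly without replacement;
p = #{pseudo > observed}/n (strict inequality, no +1 correction, so p can be
exactly 0 — a deliberate fidelity choice). Genes in modules with p > 0.01
and grey genes are removed and the network rebuilt until every module passes
and no grey genes remain. Two behaviors of this published procedure are
worth knowing: it is a fixed point (re-running the filter on its own output
changes nothing), and the pseudo-module null mixes genes from *all* current
modules, so after background genes are gone the strongest module dominates
the null and genuinely coexpressed but weaker modules can be eliminated.
With many modules of comparable quality (the situation the procedure was
designed for) this is mild; with a few modules of very unequal density it is
pronounced.

Module eigengenes are the first principal component of the standardized
module submatrix (unit norm, sign-oriented so mean member kME ≥ 0); kME is a
gene's correlation with the eigengene. Module quality Z compares observed
density to label-permutation densities ((obs − mean)/SD; Z > 10 read as
strong evidence of a dense, distinct module); this single-statistic
permutation Z replaces a multi-statistic preservation summary whose exact
composition is not reproducible, keeping the threshold semantics. Eigengene–
trait correlations, within-module regressions of member |trait r| on kME,
eigengene ANOVA across colonies with Tukey HSD contrasts, and cross-module
regressions of mean trait correlation on mean dN/dS decile complete the
module-level analyses.

# Evolutionary constraint

Per-species dN/dS values are recoded as deciles (rank-based,
`ceiling(10·rank_min/n)`; ties share the lower decile; invariant under
strictly monotone transforms), averaged into a per-gene aggregate. The
constraint model is a Gaussian identity-link GLM of the decile on |trait
correlation| and kME with median TPM and expression SD as covariates — the
decile response is near-uniform on 1–10, so Gaussian least squares is
serviceable, with a proportional-odds logit available behind
`family = "ordinal"` for sensitivity analysis. Module-level tests compare
member deciles to the genomic mean decile (one-sample t; the empirical mean,
not 5.5, because ties and missingness shift it), module genes to unassigned
genes (two-sample t), and per-species regressions of decile on kME summarize
sign consistency across species.

# The synthetic-data generator

Log2 expression is built as gene baseline (N(5, 2)) + gene-specific colony
shifts (SD `colony_effect_sd`, default 0.3) + module loadings × module
factor + direct trait effects + batch shifts + N(0, `noise_sd`, default
0.4) noise, exponentiated and rescaled to TPM. Each module has one latent
factor: a colony-level part of SD `colony_loading_sd` (default 0.5) whose
correlation with the standardized trait is `link_strength`, plus a
per-sample part of SD 0.35; per-gene loadings are |N(1, 0.25)|. A fraction
`frac_trait_genes` of non-module genes get direct effects ~N(0,
`trait_effect_sd`) on one trait each. Colony traits are drawn uniformly in
configured ranges — only their ordering matters downstream. dN/dS is
log-normal: baseline − slopes × (centrality, |trait effect|) + shared gene
noise (`dispersion`) + per-species noise, so planted slopes are negative
relationships by construction. Annotations are uniform random terms plus
planted terms concentrated (at a configurable rate) in a target module or in
the positive-effect tail of a trait's gene set (positive tail because
enrichment is tested one-sided per direction). All draws derive from the
config seed plus fixed per-operation stream offsets, so any subset of the
generator replays identically.

Defaults represent the study design the package targets: 9 colonies × 10
foragers, 10⁴ genes, eleven modules spanning ~100–2,200 genes, two
sequencing runs 0.4 log2 units apart, six comparison species. Since
within-colony variance components are not independently known, the noise
defaults were chosen for testability: signals are recoverable but not
trivial. What the generator does *not* emulate: count overdispersion beyond
Poisson, correlated gene-gene noise within colonies, GO term hierarchy, or
phylogenetic covariance among species — so passing tests demonstrate the
statistical machinery, not robustness to those real-data features.

# Fixture scales and numerical choices

Validation fixtures are deliberately smaller than the study-scale defaults
so the whole suite runs comfortably on one CPU: module recovery uses 2,000
genes × 90 samples with six planted modules and n_pseudo = 2,000
(ARI ≥ 0.8 asserted; typical 0.96–0.99); ranking AUC uses 600 genes with
direct trait genes (positives defined by nonzero planted effect — module-
mediated positives are unstable at 9 colonies because the realized
factor–trait correlation itself varies); null calibrations use 200–500
replicates. Notable numerics: Pearson correlations throughout; eigengene via
SVD of the standardized submatrix; strict `>` in permutation p-values;
`Inf` sentinels for zero-within-variance F and zero permutation SD;
collinearity in the constraint GLM rejected at condition number 10⁶;
constant genes yield missing correlations that propagate with pairwise
deletion.

# Known limitations

The per-sample trait correlation's nominal p ignores nestmate
pseudoreplication; use it for ranking, not inference, when colony effects
are present. The Fisher omnibus p is anticonservative (see above). The
density filter inherits the strongest-module bias described above. The tree
cut is a simplified dynamic procedure: it recovers planted block structure
exactly but is not a byte-level reimplementation of any reference tool, and
peripheral members below the kME rescue threshold are lost (gene-level
recall ~0.75–0.87 at fixture noise levels even when every module is found).
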