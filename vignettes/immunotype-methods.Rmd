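---
title: "Methods: immune-context subtyping from bulk and single-cell transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-context subtyping from bulk and single-cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunotype)
```

`immunotype` stratifies tumor cohorts into hot, cold and immunosuppressed
immune contexts and follows the suppressive state into single-cell data, down
to candidate driver transcription factors and ligand–receptor signaling. This
vignette documents the models behind each stage, the tunable parameters and
their defaults, the numerical conventions, and what the synthetic-data
generators do and do not emulate.

## Expression data model

All stages consume a genes × observations matrix of log2-normalized
expression (`expr_matrix`). Missing values are a hard error: every downstream
statistic assumes complete data, and silently imputing would move results.
Raw UMI counts are accepted only where counts are semantically required (the
single-cell gene filter), behind an explicit `is_counts` flag. Gene
identifiers match by exact, case-sensitive string equality — alias resolution
is out of scope and silently lossy.

## NMF consensus subtyping

Genes are filtered by mean absolute deviation about the gene mean,
`(1/n) Σ_s |x_gs − mean_g| > 1` by default (a top-N mode is available for
cohorts on another dispersion scale). The filtered log2 matrix is shifted by
its global minimum when any entry is negative — shifting preserves
between-sample contrasts, which is all the factorization consumes.

Factorization minimizes the Frobenius loss with the classical multiplicative
updates (compiled; loss is provably non-increasing, which the tests verify
numerically). Entries of W and H initialize Uniform(0,1), scaled so the
product's expected magnitude matches `mean(V)`; iteration stops when the
relative loss change falls below `tol = 1e-5` or after `max_iter = 2000`
iterations.

For each candidate rank k, `n_runs = 30` seeded restarts each assign every
sample to its argmax component of H; the consensus matrix C(k) averages the
run-wise co-clustering indicators. Restarts that collapse to a single
component are excluded with a warning rather than re-run, keeping run counts
and seeds auditable. The cophenetic coefficient ρ(k) is the Pearson
correlation between the consensus dissimilarity 1 − C and the cophenetic
distances of its average-linkage tree; cluster labels are cuts of that tree.

**Rank selection.** The selected rank precedes the steepest *fall* of ρ. We
measure the fall on the scale of the consensus's departure from a perfectly
ultrametric structure: `fall(k) = (1 − ρ(k+1)) / (1 − ρ(k))`. The reason is
numerical: when subtype separation is strong, ρ sits within 0.01 of 1 at
*every* rank — between-subtype pairs are never confused, and spurious
sub-splits recur across restarts, so the consensus stays nearly ultrametric
and ρ decays convexly. An absolute difference ρ(k) − ρ(k+1) then drifts
toward the top of the candidate range (we verified the same flat, convex
profile with an independent NMF implementation). The relative fall instead
spikes at the true rank, where ρ is within numerical noise of 1 (departure
~5e−5) and one rank later the departure grows by one to two orders of
magnitude. On profiles with a genuine cliff (e.g. 0.99, 0.98, 0.80, 0.78)
both readings agree. If no coefficient decreases at all, a "no fall detected"
warning is raised and the smallest candidate returned by the tie rule.

## Signature scores

* `mean_signature_score()` — the average log2 expression of a marker set
  (liver, immunosuppressed, activated-T scores use published set sizes of
  24 / 35 / 28 genes). Log-scale averaging is used throughout; no internal
  re-normalization.
* `ssgsea_score()` — a single-sample, rank-based enrichment score: genes are
  ranked by descending expression (ties broken by ascending gene id, making
  the walk deterministic), in-set genes advance the in-set CDF by the rank
  weight `(G − position + 1)^α` normalized to unit mass, out-of-set genes by
  `1/(G − m)`, and the score sums `CDF_in − CDF_out` over all positions.
  `α = 0.25` by default; `α = 0` gives the unweighted Kolmogorov–Smirnov
  walk. Being rank-based, the score is invariant to any strictly monotone
  per-observation transform.
* `estimate_like_scores()` — immune and stromal scores are the enrichment
  score on user-supplied sets; purity is the affine-cosine transform
  `cos(a + b·combined)` with constants configurable (defaults are the ones
  published with the ESTIMATE method; on other score scales they matter only
  through monotonicity, which is all downstream use relies on).
* `quartile_positive_labels()` — positives at or above the 75th percentile,
  computed by linear interpolation between closest ranks (R's type-7
  quantile, the common scientific-computing default; the boundary sample is
  positive by the ≥ convention).
* `subtype_enrichment_score()` — the observed/expected ratio
  `[n(g,c)/n(g)] / [n(c)/N]` of sample group g in cell cluster c. For each
  group the cluster-frequency-weighted ratios sum to 1 (mass conservation),
  which the tests assert; this is the only reading of "frequency divided by
  cluster frequency" under which that normalization holds.

## Differential expression

`moderated_t()` computes per-gene pooled-variance two-group statistics with
empirical-Bayes variance shrinkage: a scaled inverse-chi-square prior
`(d0, s0²)` is fitted across genes by moment matching on `log s²` (mean and
variance of `e = log s² − digamma(d/2) + log(d/2)`; `d0/2` solves
`trigamma(d0/2) = var(e) − trigamma(d/2)` by Newton iteration). The posterior
variance `(d0·s0² + d·s²)/(d0 + d)` feeds a t statistic with `d + d0` degrees
of freedom. When the observed spread of log-variances does not exceed the
sampling expectation, the moment answer is `d0 = ∞` (all genes share s0²);
that is a valid fit, not a failure — the `d0 = 0` fallback (with warning) is
reserved for degenerate inputs. Forcing `d0 = 0` reproduces the ordinary
pooled t-test exactly; the tests also cross-check against the limma reference
implementation and verify type-I calibration on null data.

Subtype signatures follow the one-vs-both-others rule: a gene is "up" in a
subtype only if it passes log2FC > 1 and BH-FDR < 0.05 against *each* other
subtype, with BH adjustment within each pairwise contrast (per-contrast
adjustment keeps the two contrasts symmetric; the alternative global
adjustment is not exposed because the conjunction already dominates it). Up
genes are ranked by descending minimum pairwise log2FC — the ranking the
panel sweep consumes. The immune-candidate filter implements
`((up(S1) ∪ up(S3)) ∩ immune) \ up(S2)`, reading "immune genes in S2" as
S2-upregulated; a `strict` flag also removes S2-downregulated genes.

## The gene-panel classifier

Single-cell samples are pseudo-bulked (per-sample mean over cells). Reference
classes come from the three signature scores: upper-quartile positives map
liver → cold, immunosuppressed → suppressed, activated-T → hot; samples
positive for several families or none take the class of their maximal
z-scored score, and the basis of every assignment is recorded.

The sweep tests total panel sizes 30–126 in steps of 3, each panel the union
of the top ⌈n/3⌉ ranked signature genes per class — balanced selection is
consistent with a published final panel size divisible by three, and the
step of 3 keeps the per-class quota exact. Within the sweep, reference
samples are clustered by average-linkage hierarchical clustering on
correlation distance over the panel genes (correlation distance for scale
invariance), cut into three groups, and mapped to classes by the best
bijection against the reference labels; one-vs-rest FPR and TPR are recorded
per class. The selected size is the smallest with all FPR = 0 and TPR = 1;
if none is perfect the best-utility size is returned, explicitly flagged.
Applying the classifier to a cohort runs NMF consensus at k = 3 on the panel
genes (mirroring how the panel is used on large cohorts) and maps clusters to
classes by maximum-weight bijection over centroid correlations, which also
yields a per-sample confidence.

## Co-expression modules and hubs

Analyses run on pseudocells — means of 10 cells drawn at random within each
cell type — to damp dropout and outliers. The partition rule is declared
explicitly: full groups of 10; a remainder larger than half a group becomes
its own pseudocell, otherwise it merges into the last group; types with
fewer than 10 cells form a single pseudocell with a warning.

The network is unsigned: adjacency `|cor|^β`. The soft threshold β is the
smallest power whose connectivity distribution reaches a scale-free fit
R² ≥ 0.8 (log–log regression of bin frequency on mean connectivity over
bins equal-width in log connectivity). Strongly modular expression —
including the planted cohorts — has *bimodal* connectivity and is not
scale-free, so no power reaches the target; the fallback is then the
conventional unsigned-network default power 6 (the default of the reference
co-expression tool, and what "default parameters" means in the workflows
this package re-implements), never the argmax of noise-level fit values.

Topological overlap is
`TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`; modules are
branches of the average-linkage tree of 1 − TOM under a fixed cut at 0.8 of
the min–max-normalized merge-height range, with a minimum module size of 20
(smaller branches are unassigned, module 0). A fixed-height cut was chosen
over dynamic tree cutting for determinism and auditability; the cut sits
high because co-expressed modules assemble in the lower part of the tree
(TOM dissimilarities of 0.15–0.6 depending on module tightness) while the
uncorrelated background joins only in the top ~5% of the height range — a
cut at a small fraction of the range would keep only the very tightest
modules and discard real ones.

The module eigengene is the first principal component of the module's
standardized gene submatrix, unit-variance, sign-oriented to correlate
positively with the module's mean profile. Module–trait statistics are
Pearson correlations (two-sided p with n − 2 df) between eigengenes and
one-hot cell-type indicators; module membership (MM) and gene significance
(GS) are absolute gene-level correlations with the own-module eigengene and
each trait. Hub genes satisfy MM > 0.7 and GS > 0.6 for the module's
maximal-|r| trait — the published thresholds.

## Regulons

The raw-count gene filter keeps genes with total counts strictly greater
than `3 × 0.005 × n_cells` that are detected in at least 0.5% of cells (the
two conditions are conjoined; the strict inequality follows the source
formula).

Target inference is deliberately lightweight: genes whose Spearman
correlation with a TF reaches ρ ≥ 0.3 become its targets (weights = the
correlations; regulons with fewer than 10 targets are discarded with a
warning). The correlation of each pair is computed **over cells in which
both genes are detected**. This is a deliberate dropout correction: with a
30% multiplicative dropout, the all-cells rank correlation of even a
*perfectly* coupled TF–target pair is bounded near 0.19 by the independent
zero masks alone — below any useful threshold — while conditioning on joint
detection restores the biological signal (planted pairs score 0.5–0.7). The
flag `detected_only = FALSE` recovers the naive estimator. The backend is a
single pluggable function, so a tree-ensemble importance method can be
substituted where compute allows; motif-based pruning is out of scope.

Per-cell activity is the normalized area under the recovery curve: rank all
genes by descending expression (ties by ascending gene id), count regulon
genes among the top `k = ⌈0.05·G⌉` ranks cumulatively, and normalize by
`k·m`. The score is in [0, 1] and invariant to monotone transforms of a
cell's expression. Driver-TF prioritization tests each regulon's overlap
with the hub genes of the trait-relevant module against a
Hypergeometric(N, K, n) tail, BH-adjusted across TFs; the closed form is
verified against brute-force enumeration in the tests.

## Ligand–receptor screening

For ordered cell-type pair (A, B), a pair's score is the mean of the
ligand's average expression over A-cells and the receptor's over B-cells,
computed only when each gene is detected in ≥ 10% of its side's cells (the
published convention of the reference framework). Significance comes from
re-scoring after jointly permuting the cell-type label vector (type sizes
preserved), with the one-sided add-one estimate
`p = (1 + #{null ≥ obs}) / (n_perm + 1)` — the screen looks for enriched
interactions, and the minimum attainable p is `1/(n_perm + 1)` by
construction. Types with fewer than 3 cells are flagged low-power rather
than dropped.

## Survival

Kaplan–Meier curves and log-rank tests are delegated to the standard
survival machinery (product-limit estimator; hypergeometric-variance
log-rank with 1 df). The optimal expression cutoff re-expresses the familiar
two-group cutoff optimizer as an exhaustive scan: candidate cutoffs are the
observed marker values between the 10th and 90th percentiles, each split at
≥ cutoff subject to a 10% minimum group fraction, and the log-rank-maximizing
cutoff is returned. The reported p is the raw minimum-p and carries an
explicit selection-bias flag — the tests demonstrate the inflation on null
data — and a permutation-adjusted p (max-statistic null over marker
permutations) is available behind `adjust = TRUE`, defaulting off to mirror
common practice.

## Synthetic cohorts: what they emulate, and what they do not

`generate_bulk_cohort()` plants three disjoint 120-gene expression programs
over a 2000-gene, 118-sample cohort (40 hot / 48 cold / 30 suppressed,
mirroring published 120:144:89 proportions at reduced scale). Values are
Gaussian on the log2 scale — baseline 5, program shift +2, noise sd 1,
truncated at zero — because every in-scope statistic operates on normalized
log expression; a count-level simulator would add complexity without
exercising any additional computation. Survival times are exponential with a
2.5-fold hazard for the suppressed subtype (baseline rate 1/1000 per day —
median survival around two years, a realistic scale for an aggressive solid
tumor), administratively censored at 10 years, with observed failures
recorded as events with probability 0.7.

`generate_sc_cohort()` plants a ten-sample cohort (3 hot / 4 cold / 3
suppressed samples of 500 cells) over five cell types — hepatocyte,
activated T, suppressed T, macrophage, fibroblast — whose mixing proportions
differ by group (cold samples are 70% hepatocyte; hot samples 45% activated
T; suppressed samples 45% suppressed T). Each type has 30 disjoint marker
genes shifted by +4 — the order of magnitude of canonical lineage markers,
and large enough that per-sample pseudo-bulk contrasts clear the log2FC > 1
signature threshold given the mixing differences. Five TFs each drive a
20-gene regulon: the TF gene and its targets shift (+2 / +1.5) in cells
where the TF's latent activity is on (probability 0.9 in the TF's home type,
0.35 elsewhere), and the targets additionally carry a +1 shift in the home
type itself — regulon targets are part of the type's program, exactly as the
immunosuppression driver's targets are themselves repressed-T program genes.
That coupling is what makes targets legitimate hub-gene candidates while
keeping TF activity sufficiently decoupled from the type markers for
correlation-based inference to separate them. Gaussian noise (sd 0.75), a
Bernoulli 30% dropout mask, and truncation at zero complete the model. The
gene layout is aligned with the bulk generator's program blocks, so the two
cohorts share gene semantics and a classifier trained on one is meaningful
on the other. A planted ligand–receptor pair links a macrophage marker
(sender) to a suppressed-T marker (receiver), with signal-free decoy pairs.

What the generators do **not** emulate: realistic count distributions
(negative-binomial library-size effects), batch effects, doublets,
cell-state continua, correlated noise between genes, or gene-gene regulatory
cascades beyond one TF layer. Passing the recovery tests therefore
demonstrates that each algorithm recovers the structure it is designed to
detect under its stated assumptions — not that those assumptions hold in any
particular real dataset.

## Numerical conventions and problem sizes

All randomness flows through R's RNG via explicit seeds; per-stage and
per-run sub-seeds derive from the master seed by fixed offsets, so any stage
is independently re-runnable. Consensus runs, the permutation null and the
cutoff scan are deterministic given the seed. Ties are always broken
deterministically (ascending gene id in rank walks; smaller rank in rank
selection; first maximum in assignments). The test suite runs the full
planted recovery at the generators' default sizes (2000 × 118 bulk; 1000 ×
5000 single-cell; 20-seed replication for the subtype-recovery and survival
claims; 50 null cohorts for moderated-t calibration; 2000 combinations for
the permutation-null calibration) — sizes chosen so the planted effects are
comfortably identifiable while the whole suite stays desk-scale.

## Known limitations

- Rank selection assumes the candidate range brackets the true rank and
  that the consensus at the true rank is markedly crisper than beyond it;
  cohorts with genuinely hierarchical structure can legitimately prefer a
  larger k.
- The moment-matched variance prior assumes exchangeable gene variances; a
  strong mean–variance trend (counts) would call for trend-aware shrinkage,
  which is out of scope for log-normalized input.
- Correlation-based regulon inference cannot distinguish direct regulation
  from co-membership in a program; the hypergeometric integration with
  module hubs is a prioritization, not a causal claim.
- The optimal-cutoff raw p is biased by construction; any downstream use
  should either report the permutation-adjusted p or treat the cutoff as
  exploratory.
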