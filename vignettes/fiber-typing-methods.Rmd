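---
title: "Methods: estimating muscle fiber type composition from bulk RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating muscle fiber type composition from bulk RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A skeletal-muscle biopsy is a mixture of nuclei: mostly fiber nuclei of the
slow-twitch (type I) and fast-twitch (type II) programs, plus fibroblast-like,
endothelial and mural populations. Bulk total-RNA-seq therefore measures a
convex combination of per-population expression profiles. If a single-nuclei
reference with cluster labels is available, each cluster's profile can be
summarized as a *signature* — the mean linear-scale expression of its marker
genes — and the composition of any bulk sample recovered by solving

$$\min_{f}\; \lVert \hat{x} - \hat{S} f \rVert_2
\quad\text{s.t.}\quad f \ge 0,\; \textstyle\sum_k f_k = 1 .$$

The assumptions are the usual ones of linear deconvolution: expression mixes
additively on the linear scale in proportion to nuclei counts, marker genes
behave in bulk as they do in nuclei, and the signature matrix has full column
rank over the genes used. The model estimates *nuclei-type* proportions;
fiber-level proportions agree with these only insofar as nuclear density per
fiber is comparable across types. Type IIa and IIx share a fast program here
and are not distinguished.

## Fitting convention

Units are the first practical obstacle: references arrive as UMI counts,
cohorts as counts, CPM or TPM. Before solving, the bulk vector and every
signature column are scaled to unit total over the genes shared between
signature and sample. This makes the fit invariant to the unit and to any
positive rescaling of the sample (verified by a property test). The simplex
weights of the scaled problem are then mapped back through the signature
column totals, $f_k \propto g_k / \lVert S_{\cdot k}\rVert_1$, so the reported
fractions are mixing weights of the *original* signature columns: a noiseless
mixture $x = S f^{*}$ returns $f^{*}$ (the identifiability property is tested
to 1e-6, and typically holds to machine precision).

The constrained problem is solved by a primal active-set quadratic program
written for this package: start at the uniform feasible point, solve the
equality-constrained KKT system on the free coordinates, clip the step at the
first bound it violates, and release active bounds whose multipliers are
negative. With at most five clusters the system is tiny; the solver is exact,
deterministic (no randomness, no tolerance tuning beyond a 1e-10
feasibility/optimality epsilon) and validated against a multi-resolution
exhaustive grid search on the simplex with final step 0.001. A full 0.001
grid is enumerable only up to three clusters; for four and five the oracle
refines around the best coarse cells, which is sound because the objective is
convex. Degenerate inputs fail loudly: rank-deficient signatures, all-zero
bulk vectors and empty gene overlaps are errors, not warnings.

Two fitting modes exist because reference analyses differ in whether they
deconvolve against all clusters or only the two fiber signatures. The default
`fiber_only` restricts the signature to the type I/II columns and their own
markers (this is the mode used for the depth-robustness experiments);
`all_clusters` fits all five and renormalizes the two fiber fractions to give
the type I share. Both are exposed; on the synthetic cohorts they agree
closely when non-fiber contamination is absent.

Genes present in the signature but missing from a bulk table are dropped, not
zero-filled — absent quantification is not evidence of absence. Identifiers
are matched case-sensitively after stripping Ensembl `.version` suffixes. If
fewer than half of the signature genes are found, the cohort-level call
errors (downgradeable to a warning).

## Expression scaling

* **LogNormalize** (`log_normalize()`): $\ln(1 + c \cdot s/T)$ per entry with
  column total $T$ and scale factor $s = 10^4$, the standard single-cell
  convention (natural logarithm). Used only for marker *testing*.
* **CPM** (`cpm_normalize()`): columns scaled to $10^6$. Signatures are
  averaged on this linear scale, never on the log scale, because mixing is
  additive in linear expression.
* **TMM** (`tmm_factors()`): the classical trimmed mean of M-values with the
  published defaults — 30% two-tailed trim on M, 5% on A,
  inverse-asymptotic-variance weights, reference column chosen by the
  upper-quartile rule. The returned factors absorb library size (factor =
  compositional correction × library size, renormalized to geometric mean 1),
  so dividing columns by them puts libraries on one scale; two identical
  libraries get exactly 1. Numerically, M and A are computed on
  library-size-normalized counts and the library-size log-ratio is added to
  the trimmed weighted mean afterwards; the shift is constant per library, so
  the trim set is unchanged, but the floating-point tie structure of the
  ranks then matches the classical implementation bit for bit (agreement with
  edgeR to 1e-10 is a test).

## Quality control

Nuclei whose mitochondrial or ribosomal count fraction exceeds 0.20 are
removed, then genes with no UMI in any remaining nucleus. The 0.20 defaults
are the field's common practice for "high fraction" and are deliberately
explicit and configurable, because published analyses rarely state their
cut-offs; both gene families are recognized by symbol prefix (`MT-`,
`RPL`/`RPS`), overridable for non-symbol annotations. The filter is
idempotent and preserves ordering.

## Marker detection

Markers are found per cluster by a two-sided one-vs-rest Wilcoxon rank-sum
test on log-normalized expression, BH-adjusted within each cluster's family,
filtered at natural-log fold change ≥ 0.25 (computed on de-logged means with
pseudocount 1, which is stable for zero-heavy data), in-cluster detection
≥ 0.10 and adjusted p ≤ 0.05 — the de facto standard recipe, with every
threshold exposed. Ranking ties are broken lexicographically by gene id for
reproducibility.

P-values are exact whenever exactness is affordable: the full permutation
distribution of the midrank sum is enumerated when
$\binom{n}{n_\text{in}} \le 2\times10^5$ (this is the exact conditional
distribution under ties as well), otherwise the normal approximation with tie
and continuity correction is used. A fixed group-size cut-off would be the
more familiar rule, but enumeration cost is governed by the combination
count, not the group size — 25 vs 25 already has $\sim10^{14}$ assignments —
so the bound is placed on what is actually enumerated. Clusters with a single
nucleus are skipped with a warning: a rank test is undefined there.

The package also bundles the small literature panel of named human fiber-type
markers (`bundled_fiber_markers()`): ATP2A1/MYBPC2/MYH2 (type II),
XPO4/ATP2A2/TPM3/MYH7B (type I), LDB2/VWF/BTNL9/FLT1/LRRTM4 (endothelial) and
MECOM. It is a partial, text-citable panel — a convenience for demonstration
and sanity checks, not a substitute for reference-derived markers, and no
genes beyond the named ones are invented.

## Depth robustness by binomial thinning

Read-level subsampling of a library induces, per gene, a hypergeometric count
that is indistinguishable from Binomial($c$, $p$) at sequencing scale. The
package therefore thins count matrices directly: every count $c$ in a sample
with total $T$ is replaced by a Binomial($c$, $d/T$) draw for target depth
$d$. This is an *emulation* of FASTQ subsampling plus re-quantification — it
reproduces its distribution for per-gene counts but not mapping artifacts at
low coverage. `depth_robustness()` repeats thin → CPM → `fiber_only`
deconvolution over a depth grid (default: 7 logarithmic points from $10^4$ to
$10^7$, 10 replicates, seeded) and scores Spearman correlation and mean
square deviation against the truth (or against full-depth predictions when no
truth is supplied). Undefined correlations (constant vectors) are reported as
missing, never imputed.

## The synthetic generator

Every stage is testable without controlled-access data because the generator
emulates the *shape* of a real muscle snRNA-seq reference and bulk cohorts:

* five clusters — type II and type I fiber nuclei dominating, plus
  fibroblast-like, endothelial and pericyte-like — with 2699 nuclei
  (900/750/450/400/199) and 2000 genes;
* lognormal baseline gene abundance (sdlog 1.2), negative-binomial UMI counts
  (size 0.8; overdispersion is the rule for UMI data);
* 10 planted markers per cluster at fold change 8 in the home cluster, with
  baseline abundance at the 95th percentile of the gene-mean distribution —
  in muscle the sarcomeric transcripts are among the most abundant, and this
  abundance is precisely why shallow sequencing stays informative;
* per-nucleus library sizes lognormal around a value *calibrated by root
  finding* so the median number of detected genes per nucleus is ≈ 500;
* mitochondrial- and ribosomal-prefixed genes at modest abundance so the QC
  filters have something to act on;
* pseudo-bulk samples: type I fraction drawn from a Beta distribution
  parameterized by mode and concentration — default a single group with mode
  0.62 (the typical mean type I share of vastus lateralis in young men), and
  a two-group preset with modes 0.68 (women-like, n = 171) and 0.56
  (men-like, n = 398), concentrations 40 and 25 chosen so the central 95%
  mass roughly spans 0.53–0.81 and 0.36–0.75; the expected profile
  $f\,s_I + (1-f)\,s_{II}$ (plus optional non-fiber contamination) is sampled
  multinomially at 10^6 reads, which makes cohort generation consistent with
  binomial thinning.

What the generator does **not** emulate: gene-length and GC bias, ambient
RNA, doublets, batch effects, the correlation structure of real co-regulated
markers, or hybrid fibers. Passing tests therefore demonstrate that the
algorithms are correct and well-calibrated under the stated generative model
— not that field accuracy on any particular cohort is guaranteed.

## Validation statistics

Spearman correlation is computed as Pearson on midranks; its p-value uses the
t approximation with $n-2$ df and its confidence interval the Fisher z
transform with standard error $1/\sqrt{n-3}$. The CI convention for rank
correlations is not unique — alternatives differ in the second decimal — so
intervals are treated as descriptive, never as exact pass/fail quantities.
The Mann–Whitney test shares the rank-sum engine above (exact by enumeration
when affordable, otherwise corrected normal approximation); group medians in
`compare_groups()` carry seeded bootstrap percentile intervals (2000
resamples).

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` use: 1000 random QP instances
(2–5 clusters, 10–50 genes) against the 0.001 grid oracle; 100 noiseless
mixtures; the full-size default reference (2699 nuclei × 2000 genes) for
marker recovery, its fold-change-1 null, a 50-sample cohort at 10^6 reads,
and the 7-depth × 10-replicate robustness curve; and 100 repetitions of the
171-vs-398 group comparison. These sizes keep a complete run in the
single-digit minutes on one CPU while exercising every code path at the
study's scale. All random draws flow through explicit integer seeds
(`withr::with_seed`), and bit-level reproducibility of every stochastic path
under a fixed seed is itself an acceptance test.

## Known limitations

* Type IIa vs IIx cannot be separated; hybrid fibers are not modeled.
* Estimates are nuclei-type shares, not fiber cross-sectional-area shares —
  the quantity ATPase staining reports; perfect agreement with histochemistry
  is not expected even at infinite depth.
* `fiber_only` mode ignores non-fiber contamination; heavy endothelial or
  fibroblast content biases both fiber fractions (the `all_clusters` mode and
  the simulator's contamination knob exist to probe this).
* The mito/ribo QC thresholds are conventions, not estimates; references
  filtered with different cut-offs will yield slightly different signatures.
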