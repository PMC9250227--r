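# fibertype

Estimate the proportion of slow-twitch (type I) versus fast-twitch (type II)
muscle fiber nuclei in bulk skeletal-muscle RNA-seq samples.

Skeletal-muscle fiber type distribution matters for performance, metabolic
health and aging, but the reference assays (ATPase histochemistry, myosin
heavy chain gel electrophoresis) are labor-intensive and need well-preserved
tissue. Because slow- and fast-twitch fiber nuclei have distinct expression
programs (*ATP2A2*, *TPM3*, *MYH7B* versus *ATP2A1*, *MYBPC2*, *MYH2*), the
fiber composition of a bulk total-RNA-seq sample can instead be read off its
transcriptome: a bulk profile is modeled as a mixture of per-cluster
expression signatures derived from cluster-labeled single-nuclei RNA-seq of
muscle, and the mixture weights are the nuclei-type proportions.

## The model

Given a signature matrix **S** (marker genes × clusters, mean linear-scale
expression of each cluster's nuclei) and a bulk expression vector **x** over
the same genes, the package solves the constrained least-squares problem

    minimize  || x̂ − Ŝ f ||₂    subject to   f ≥ 0,  Σₖ fₖ = 1

where x̂ and the columns of Ŝ are scaled to unit total over the shared marker
genes (making the fit invariant to the expression unit — counts, CPM or TPM —
and to library size). The program is solved exactly with a deterministic
active-set quadratic program, and the simplex weights are mapped back through
the signature column totals so the reported fractions are mixing weights of
the original signatures; a noiseless mixture x = S f* returns f* to machine
precision. The type I fiber-nuclei fraction is f_I / (f_I + f_II).

Around this core the package provides the full desk-scale workflow:

* **I/O** — MatrixMarket triplets (10x-style) and dense TSV, gzip accepted
  (`read_count_matrix()`, `read_cluster_labels()`, `write_table()`).
* **QC & normalization** — mitochondrial/ribosomal nucleus filters,
  LogNormalize, CPM, and a trimmed-mean-of-M-values (TMM) implementation
  (`filter_nuclei_and_genes()`, `log_normalize()`, `cpm_normalize()`,
  `tmm_factors()`).
* **Markers & signatures** — one-vs-rest Wilcoxon rank-sum marker detection
  with BH adjustment, and cluster signatures as linear-scale mean CPM
  (`find_markers()`, `build_signature()`, `bundled_fiber_markers()`).
* **Deconvolution** — per-sample proportions for a whole cohort, in
  `fiber_only` (two fiber clusters) or `all_clusters` mode
  (`solve_proportions()`, `deconvolve_cohort()`).
* **Depth robustness** — binomial thinning of count matrices and
  accuracy-vs-depth curves (`thin_counts()`, `depth_robustness()`).
* **Simulation** — a synthetic 5-cluster muscle snRNA-seq reference and
  pseudo-bulk cohorts with known fiber fractions (`generate_reference()`,
  `generate_cohort()`).
* **Statistics** — Spearman correlation with Fisher-z CI, Mann-Whitney U,
  mean square deviation (`spearman_with_ci()`, `mann_whitney()`,
  `mean_square_deviation()`).

Results are tibbles with `tidy()`/`glance()` and `autoplot()` methods; a
command-line wrapper (`inst/cli/fibertype`, subcommands `qc`, `markers`,
`signature`, `predict`, `downsample-eval`, `simulate`, `eval`,
`compare-groups`) exposes the same functions to shell pipelines.

## Worked example

A fully synthetic run — reference with known markers, pseudo-bulk cohort with
known fractions, then recovery:

```r
library(fibertype)

ref     <- generate_reference(simulation_config(), seed = 7)
markers <- find_markers(log_normalize(ref$counts), ref$labels, top_n = 10)
head(markers, 3)
#>   gene           cluster log_fold_change pct_in pct_out   p_value adj_p_value
#> 1 MRK_type_II_01 type_II            2.09  0.92    0.588 1.27e-199   2.53e-196
#> 2 MRK_type_II_03 type_II            1.95  0.91    0.606 3.79e-190   3.79e-187
#> 3 MYH2           type_II            2.03  0.897   0.584 4.65e-187   3.10e-184

S <- build_signature(ref$counts, ref$labels, markers)
#> <signature_matrix> 50 marker genes x 5 clusters (type_II, type_I,
#>   fibroblast_like, endothelial, pericyte_like)

cohort <- generate_cohort(ref, simulation_config(), seed = 8)
est    <- deconvolve_cohort(S, cohort$bulk)
head(est[, c("sample_id", "type_I", "type_II", "type1_fraction")], 3)
#>   sample_id type_I type_II type1_fraction
#> 1 S001       0.613   0.387          0.613
#> 2 S002       0.490   0.510          0.490
#> 3 S003       0.659   0.341          0.659

spearman_with_ci(est$type1_fraction, cohort$truth$type1_fraction)
#>       r ci_low ci_high  p_value     n method
#>   1.000  0.999   1.000 2.04e-76    50 spearman_fisher_z
mean_square_deviation(est$type1_fraction, cohort$truth$type1_fraction)
#> [1] 4.347003e-05
```

Each marker row reports the natural-log fold change of de-logged mean
expression, the detection fractions inside and outside the cluster, and the
BH-adjusted rank-sum p-value. Each estimate row is one bulk sample's fitted
cluster composition; `type1_fraction` is the share of fiber nuclei that are
type I — here recovered from 1-million-read pseudo-bulk samples with a mean
square deviation of ~4e-5 against the simulated truth.

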