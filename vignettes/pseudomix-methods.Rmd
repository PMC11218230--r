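---
title: "Simulating heterogeneous pseudobulk mixtures for deconvolution benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating heterogeneous pseudobulk mixtures for deconvolution benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudomix)
```

## The problem

Computational deconvolution estimates the cell-type composition of a bulk
RNA-seq sample from its expression profile, usually through the linear mixing
model

$$ Y_{g \times s} \;=\; X_{g \times k} \, P_{k \times s} \;+\; E_{g \times s}, $$

where $Y$ is bulk expression over $g$ genes and $s$ samples, $X$ a reference
(signature) matrix of per-cell-type mean expression, $P$ the proportion
matrix, and $E$ residual noise. Methods are routinely benchmarked on
*pseudobulk*: mixtures assembled by pooling annotated single cells at known
proportions. The catch is *how* the cells are pooled. If every mixture draws
its cells at random from the whole cohort, every simulated sample carries the
cohort-average expression of each cell type, and the benchmark is far easier
than reality: real tumors differ from each other within every cell type
(malignant programs, stromal and immune activation states, patient-specific
expression shifts).

pseudomix implements pseudobulk simulation under controlled heterogeneity
regimes, quantifies whether the simulated cohort carries realistic
sample-to-sample variance, and closes the loop with reference construction,
a baseline NNLS deconvolver, and accuracy scoring.

## Simulation strategies

All strategies consume CPM-normalized single cells (every cell column sums
to $10^6$) and conserve that library size: each simulated bulk column sums
to $10^6$ exactly, because every component profile sums to $10^6$ and the
mixing weights sum to one.

* **Homogeneous** — the conventional construction. Per sample, $n$ cells are
  allocated over cell types by largest-remainder apportionment of the target
  fractions and drawn uniformly from *all* patients. The reported ground
  truth is the realized count fraction $n_k/n$, which removes integer
  rounding from the evaluation. $n$ defaults to the per-patient median cell
  count of the input, approximating a typical biological sample.
* **Heterogeneous** — each cell-type component of each sample comes
  exclusively from one randomly chosen patient's profile $C_k$, weighted by
  the simulated fraction: $y_i = \sum_k f_{ik} C_k^{(\text{patient})}$.
  Patient-level expression coherence survives into the mixtures.
* **Semi-heterogeneous** — only the malignant component is
  patient-restricted; non-malignant types are drawn at random as in the
  homogeneous scheme. This isolates malignant intra-tumor heterogeneity,
  usually the dominant axis.
* **Sample-ID-free heterogeneous** — as heterogeneous, but the random unit
  is a *sub-cluster* within the cell type rather than a patient, so the
  strategy works when sample annotations are unavailable or unreliable.

Two randomization details prevent simulated samples from reusing identical
cell sets: when a patient profile $C_k$ is built, a uniform 50–100% subset
of the available cells is averaged; and when a patient holds fewer than
`threshold` (default 10) cells of a type, cells of the same type from
additional randomly chosen patients are pooled (raw cells, i.e.
count-weighted) until the threshold is met. Whether non-malignant
semi-heterogeneous signal should be mixed as individual cells or per-type
mean profiles is ambiguous; we use per-type means over the drawn cells,
which keeps the library-size identity exact.

Sub-clusters are computed per cell type by log2(CPM/100 + 1) transform,
top-500 variable genes, PCA to at most 30 components and k-means with
$k = \lfloor m/50 \rfloor$, merging clusters below `min_size = 10` into
their nearest neighbor by centroid distance. This is a deliberate,
documented approximation of the graph-based quick-clustering used in
single-cell toolkits: it honors the same minimum-size contract while
remaining dependency-light and fully deterministic under seed.

## Fraction simulation

Ground-truth proportions mimic real inter-patient composition. The observed
per-patient cell-type fractions are fitted per cell type with a beta law by
method of moments: with sample mean $m$ and variance $v$,

$$ c = \frac{m(1-m)}{v} - 1, \qquad \alpha = m\,c, \qquad \beta = (1-m)\,c, $$

falling back to a point mass at $m$ when $v < 10^{-8}$ or $c \le 0$
(zero-variance types are kept, not dropped). Per simulated sample one value
is drawn per cell type and the vector is rescaled to the simplex. Rescaling
slightly distorts the marginal means; that distortion is accepted as part of
the procedure. Method of moments rather than maximum likelihood is chosen
because the goal is matching mean and variance, and the closed form is
transparent and testable.

The Dirichlet alternative uses concentrations $\alpha_k = p_k/d$ with base
frequencies $p$ and dispersion $d > 0$, so larger $d$ gives wider spread;
typical benchmark settings are $d \in \{0.001, 0.01, 0.05\}$. The original
tooling does not state its exact parameterization, so ours is documented
here rather than claimed equivalent.

## Variance diagnostics

Realism is judged against the *baseline pseudobulk* — one column per
patient, the mean CPM of that patient's cells. For each gene $i$ the
coefficient of variation is computed on log-transformed expression,

$$ CV_i = \sigma_i / \mu_i, $$

with $\mu_i, \sigma_i$ the mean and sample standard deviation (n−1) of
$\log_2(x+1)$ across samples; genes with $\mu_i = 0$ are flagged undefined
and excluded from averages rather than imputed. The log base and pseudocount
are configurable — the source procedure says only "log transformed", so
numerical equivalence with any particular figure is not claimed. Pathway
CVs average member genes (sets with fewer than three usable genes are
flagged). Sample-level structure is summarized by all pairwise Pearson
correlations between samples on the baseline's top-300 variable genes
(variance of log expression, ties broken by gene name).

On cohorts with nonzero patient effects the expected signature is: mean
gene CV ranks heterogeneous > semi-heterogeneous > homogeneous, and mean
pairwise sample correlation ranks the opposite way, with the heterogeneous
values sitting closest to the baseline.

## Reference construction

`celltype_mean_profile()` gives the all-gene signature (columns sum to
$10^6$). DE markers are found on $\log_2(\text{CPM}+1)$ with limma's
moderated t-statistics — one-vs-rest, or pairwise with the min-logFC rule —
keeping genes with logFC above the threshold (default 2) and BH-adjusted
p below 0.05; whether the original pipeline also applied a p cutoff is not
stated, so ours is switchable (`alpha = NULL`). Cell types with fewer than
`minimum_n = 5` passing genes are excluded. Signature↔marker
interconversion assigns each gene to its argmax cell type (exact ties drop
the gene — a tied gene is not specific), ranks within type by fold change
to the second-highest type (pseudocount 1 on both), and caps lists at
`maximum_n = 100`. Specificity scores are
$\max_k X_{gk} / \sum_{k'} X_{gk'}$ with the customary 0.5 / 0.3 selection
thresholds. External signature matrices (e.g. produced by web portals) are
accepted as plain gene × cell-type TSVs rather than re-deriving those
tools.

## Deconvolution and evaluation

The built-in baseline solves non-negative least squares per sample with a
hand-written Lawson–Hanson active-set solver (no NNLS package exists in the
target environment; the solver is cross-checked in the tests against
brute-force simplex search). Scale is unconstrained during the solve and
the solution is normalized to sum to one afterwards; an all-zero solution
falls back to uniform with a warning. Accuracy is scored per cell type by
Pearson r across samples (undefined correlations — constant vectors — are
flagged and excluded from averages, never zero-filled) and globally by
RMSE. Reference-free outputs are relabeled by best correlation against
truth, many-to-one allowed, ties broken by cell-type name order. The
influence of methodological choices is summarized by OLS:

$$ r \sim 1 + \text{regression\_choice} + \text{reference\_choice} +
   \text{dataset} \times \text{cell\_type}, $$

treatment-coded with `nnls` and `no_selection` baselines, fitted separately
per simulation strategy. External deconvolvers plug in as executables
mapping (bulk TSV, signature TSV) to a fraction TSV; malformed output is a
recorded failure, not a crash.

## The synthetic cohort generator

Because the real tumor cohorts behind the original benchmark require
downloads, every stage here is exercised on a generated multi-patient
cohort. Counts for a cell of patient $p$, type $k$ are

$$ \text{NB}\!\left(\mu = L_c \cdot \tilde p_g,\; \text{size} = \theta\right),
   \qquad \tilde p_g \propto b_g \cdot t_{gk} \cdot e_{gpk} \cdot s_{g}, $$

with log-normal base abundances $b_g$, planted marker blocks
$t_{gk} = 2^{\text{logFC}}$ (40 genes per type at log2FC 3 by default),
per-(gene, patient, type) log-normal effects $e_{gpk}$ with standard
deviation `patient_effect_sd` (default 0.8 — the heterogeneity dial), and
optional malignant subtype blocks $s_g$. Defaults: 1000 genes, 4 cell
types, 8 patients, 20–60 cells per patient and type (~160 cells/patient),
NB size 10, library sizes 2000–6000. These were fixed once as a plausible
desk-scale tumor cohort; the negative binomial (not Poisson) keeps
gene-level overdispersion present even with the patient dial at zero, and
patient effects are gene-wise independent (correlated gene modules are out
of scope).

What a green test does **not** establish: the generator has no gene–gene
co-expression network, no cell-type fraction covariances, no batch
structure, and its patients are exchangeable draws — so passing the suite
demonstrates the machinery is correct on a world with the stated structure,
not that any particular real cohort is reproduced.

## Numerical choices and degenerate inputs

* Library-size conservation is exact to float round-off; validators enforce
  $10^6$ column sums at $10^{-6}$ relative tolerance, fraction rows at
  $10^{-9}$.
* Largest-remainder ties break by cell-type name order; homogeneous cell
  draws are without replacement unless a type's request exceeds
  availability.
* Filtering on CPM input renormalizes the surviving columns, which makes
  filter-then-normalize and normalize-then-filter commute exactly.
* "Expressed in fewer than 5 cells" means strictly positive expression, not
  a count threshold; mitochondrial/ribosomal symbols are matched by
  anchored, case-insensitive prefixes (`^MT-`, `^RP[SL]\d`, `^MRP[SL]\d`),
  overridable for non-human data. Filtering is applied on counts before CPM
  normalization.
* Seeds fix every simulation bit-for-bit; the benchmark runner derives the
  repeat-`r` child seed as `master * 1000 + r` so single repeats reproduce
  in isolation.

## Known limitations

With only 8 patients and ~160 cells each, finite-cell sampling noise is
visible: homogeneous deconvolution accuracy hovers near (and at some seeds
below) the idealized 0.98 mark that large real cohorts reach, and with the
patient dial at zero the strategies still differ slightly in gene CV simply
because they average different numbers of cells per component. Both effects
shrink as cells per patient grow. Batch effects between reference and bulk
are not modeled, matching the simplified matched-reference scenario this
framework targets.

## A worked run

```{r example, eval = FALSE}
fx <- generate_benchmark_fixture(n_samples = 20, seed = 1)
variance_report(fx$bulk, fx$baseline)

sig <- celltype_mean_profile(fx$sc_cpm)
est <- deconvolve_nnls(fx$bulk$homogeneous, sig)$fractions
evaluate_deconvolution(est, fx$realized_fractions)$mean_r
```
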