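---
title: "Integrating unmatched expression studies by tensor decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating unmatched expression studies by tensor decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdfuse)
```

## The problem

Meta-analysis of gene expression usually assumes something is shared between
studies: matched samples (the same individuals measured twice) or at least
common labels (every study calls its samples "case" or "control" in a
comparable way). Many interesting comparisons offer neither. One study
contrasts induced pluripotent stem-cell lines carrying an APP duplication
with corrected lines; another knocks out CD33 in macrophages; a third
profiles patient-derived cell lines. The studies share nothing but the genes
they measure, yet a biologist may still want the genes whose expression
varies with *each* study's own class structure simultaneously.

tdfuse implements an unsupervised route to that question. Each study is
first compressed — by its own singular value decomposition (SVD) — to a
small genes-by-$L$ latent representation. These reduced profiles have a
shared axis (genes) and a comparable second axis (latent components ordered
by variance), so they can be stacked into a three-mode tensor even though no
sample of any study corresponds to a sample of another. A higher-order SVD
(HOSVD) of the stack then yields a single set of gene-side singular vectors
valid for all studies at once, and genes are selected from those vectors by
a chi-squared criterion.

## The procedure

For study $k$ with expression matrix $x_{ij_k} \in \mathbb{R}^{N \times M_k}$:

1. **Per-sample normalization.** Every sample profile is standardized over
   that study's native genes: $\sum_i x_{ij_k} = 0$ and
   $\sum_i x_{ij_k}^2 = N$ (division by the population standard deviation).
   Multi-condition studies (e.g. drug × dose × replicate tensors) normalize
   each condition cell the same way.
2. **Gene universe.** All studies are placed on a common ordered gene list,
   by default the gene list of the largest study; genes a study did not
   measure are filled with exact zeros. Padding happens *after*
   normalization, so padded rows carry no signal (they merely contribute
   zero loadings). We do not re-normalize after padding: the normalization
   identities are defined on native genes and could not survive padding
   anyway.
3. **Reduction.** SVD gives
   $x_{ij_k} = \sum_\ell u^{[k]}_{\ell i}\lambda^{[k]}_\ell v^{[k]}_{\ell j_k}$,
   and the reduced profile is
   $x_{i\ell k} = \sum_{j_k} x_{ij_k} v^{[k]}_{\ell j_k} = \lambda^{[k]}_\ell u^{[k]}_{\ell i}$
   for $\ell \le L$. Tensor studies use the HOSVD analogue: contraction with
   the leading factors of every condition mode, with per-mode ranks
   $L^{[s]}$ and columns enumerating the rank tuples in row-major order.
4. **Sign fixing.** Singular vectors are defined up to a joint sign flip of
   the gene- and sample-side factors. Before stacking, every column is put
   into a deterministic base convention (its largest-magnitude element is
   made positive) and then flipped, together with its paired sample factor,
   so that its correlation with the reference study's column is
   non-negative. The base convention makes the whole pipeline *bitwise*
   invariant to arbitrary sign flips applied upstream; components with
   essentially zero correlation to the reference (|r| < 1e-8) keep the base
   convention and raise a warning.
5. **Stacking and integration.** The sign-fixed profiles form
   $x_{i\ell k} \in \mathbb{R}^{N^* \times L \times K}$, decomposed by
   classical HOSVD (per-mode unfolding SVDs, no iterative refinement — the
   decomposition is deterministic and reproducible):
   $x_{i\ell k} = \sum G(\ell_1\ell_2\ell_3)\, u_{\ell_1 i} u_{\ell_2 \ell} u_{\ell_3 k}$.
   The gene mode is truncated at $L \cdot K$, which spans the entire
   nonzero spectrum of the gene-mode unfolding, so the truncation discards
   nothing.
6. **Factor choice ($\Omega$).** Gene-mode factors are ranked by their
   squared core mass $\sum_{\ell_2 \ell_3} G(\ell_1\ell_2\ell_3)^2$,
   optionally restricted to fixed values of the other modes. The automatic
   rule keeps factors whose weight exceeds twice the median weight (capped
   at five, never empty): in the integrated core, informative factors stand
   an order of magnitude above the noise floor while the null tops out near
   the median, so a fixed count would either dilute the statistic with
   noise factors or miss secondary structure. $\Omega$ can always be pinned
   explicitly.
7. **Gene selection.** Assuming the loadings of an uninformative gene are
   Gaussian, $P_i = P_{\chi^2}\!\left[> \sum_{\ell_1\in\Omega}
   (u_{\ell_1 i}/\sigma_{\ell_1})^2\right]$ with $|\Omega|$ degrees of
   freedom, where $\sigma_{\ell_1}$ is the standard deviation of
   $u_{\ell_1 i}$ over all genes in the universe (padded genes included by
   default; a subset can be supplied). P-values are Benjamini–Hochberg
   adjusted and genes with adjusted $P$ strictly below 0.01 are selected.
8. **Sample projection and association.** Samples are projected into the
   shared gene-factor space, $v_{\ell_1 j_k k} = \sum_i u_{\ell_1 i} x_{ij_k k}$,
   and each factor's coordinates are screened against that study's
   categorical labels by one-way ANOVA (the linear model on class
   indicators), BH-corrected across factors within each study's screen. A
   *consensus* operation reduces the per-study screens to the factors
   significant in every study — the integration's actual target, since a
   factor significant in a single study reflects study-specific structure
   or a lone screen's false positive. A global-BH option treats all
   factor-study tests as one family instead.

Two further workflows reuse the same machinery. **Drug ranking** projects a
drug × dose × replicate study onto the integrated gene factors and applies a
nested full-rank HOSVD to each gene factor's slice; drugs are scored by
$\sum_{\tilde\ell_1 \le T} \tilde u_{\tilde\ell_1 j}^2$, the squared mass of
the drug's row over the top $T$ drug-mode singular vectors. **scRNA-seq
compression** reduces each measurement (up to ~10^4 cells) to its top
$L = 10$ gene-side components before stacking, so memory scales with
$N \cdot L \cdot C$ regardless of cell counts; the measurement-mode factors
$u_{\ell_3 c}$ are screened against per-measurement group labels.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `L` | min(8, smallest $M_k$) | components kept per study; cannot exceed any study's sample count |
| `mode_ranks` | smallest ranks reaching `L` | per-mode ranks for tensor studies; replicate-like modes are best left at rank 1 since replicates share means |
| universe | reference (largest study) | union mode keeps every gene instead |
| `omega_gap` | 2 | weight-to-median ratio a gene factor must exceed to enter the automatic $\Omega$ |
| `omega_size` | 5 | cap on the automatic $\Omega$ |
| gene threshold | 0.01 | adjusted-P cutoff, strict inequality |
| factor threshold | 0.05 | adjusted-P cutoff of the association screen |
| `T` | 5 | drug-mode components scored; must stay small relative to the drug count (about 5% in the 94-drug setting it was designed for). For a ten-drug screen with a dose response of drug-mode rank one, the equivalent choice is `T = 1`; at `T = 5` of 10 the score saturates, since any drug's unit-norm row carries about T/10 of its mass in any five components. |
| scRNA `L` | 10 | components per measurement; the compression keeps no object with a cell-sized dimension |

## The synthetic generators

The generators produce the study designs the method targets, with planted
ground truth, so every stage is testable without downloads.

**Unmatched bulk studies** (`generate_unmatched_studies`): `K` studies over
a shared universe (defaults: 2000 genes; sample sizes 9, 23, 8 — the shape
of a typical three-study integration), i.i.d. Gaussian background, and a
planted program of 100 genes that shifts by ±2 noise-SD units between each
study's own classes (each gene with a fixed sign; class offsets centred,
spanning [−effect, effect]). Each study is multiplied by a random gain, so
measurement scales are not shared. Labels are study-specific and never
compared across studies.

**Drug tensors** (`generate_drug_tensor`): genes × drugs × doses ×
replicates (defaults 2000 × 10 × 4 × 3); effective drugs modulate the
planted program linearly and monotonically in dose, replicates share means.

**scRNA collections** (`generate_scrna_collection`): six measurements of
500 cells over 1000 genes, in four groups crossing two arms (case/control)
with two strata. Counts are Bernoulli-thinned Poisson on exponentiated
programs: a shared log-baseline `N(2, 1)`, a per-measurement random effect
(log-SD 0.1, the biological variability between samples), and a planted
arm program of 200 genes at ±1 log units. Three design choices deserve
explanation, all forced by the small collection (six measurements leave the
four-group ANOVA only two residual degrees of freedom):

* the program is *sign-balanced within baseline-matched gene pairs*, so
  both arms have identical marginal expression distributions — the program
  changes which genes are up or down, not the overall distribution, and the
  arm difference is exactly rank one;
* measurements *alternate arms*, keeping the arms balanced; an unbalanced
  contrast leaks into the leading (baseline) measurement factor;
* the measurement random effect provides the within-group variance that
  masks second-order systematic differences which would otherwise be
  declared significant against a near-zero error term.

What the generators do **not** emulate: library-size differences and
compositional effects, batch effects (out of scope by design — the setting
assumes labels are not even shared, so there is nothing to batch-correct
toward), dropout rates fitted to real data, gene–gene correlation beyond
the planted program, and the long-tailed expression distributions of real
scRNA-seq (real data is sparser than the default 55–65% zeros). Passing the
planted-recovery tests therefore demonstrates the machinery is correct and
well-calibrated under its stated model, not that any particular real
integration will behave as cleanly.

## Numerical choices

* HOSVD is the classical truncated algorithm (one SVD per mode unfolding);
  no HOOI iterations, so results are deterministic and orthonormality is
  inherited from LAPACK.
* Sign conventions: largest-magnitude element positive, first index on
  ties; all-zero columns are left untouched. An all-zero slice in the
  nested drug decomposition scores every drug zero rather than delegating
  to the SVD of a zero matrix.
* $\sigma_{\ell_1}$ uses the sample standard deviation over the full
  universe including padded genes (an option restricts the estimation set).
  Including strong planted loadings inflates $\sigma$ and makes the test
  conservative; this is the price of not knowing the signal genes in
  advance.
* scRNA compression never densifies: the cell-by-cell Gram matrix of the
  implicitly normalized data is assembled from sparse cross-products, its
  eigenvectors give the sample factors, and one sparse product yields the
  reduced profile. Eigenvalues are clamped at zero before taking roots.
* Zero-variance samples are an error (named); zero-variance genes are
  retained — they simply contribute zero loadings.
* BH adjustment delegates to `stats::p.adjust`; the chi-squared tail to
  `stats::pchisq`; the categorical regression to `stats::lm`/`anova`. The
  test suite checks each against an independent oracle (brute-force
  step-up, numerical integration of the density, hand-computed sums of
  squares).

## Scope of the validation suite

The tests and the acceptance script run at desk scale: universes of
300–2000 genes, the (9, 23, 8) three-study design, 10–20 seeds per
property, six 500-cell measurements, ten-drug screens. These sizes were
chosen so the full suite exercises every pipeline stage in well under a
minute per property while keeping the planted-signal geometry (signal
singular values a clear factor above the noise band) comparable to the
full-size setting.

## Known limitations

* Exact-string gene matching only; cross-annotation identifier mapping is
  the caller's job.
* The association screen needs more observations than classes; collections
  with as many groups as measurements cannot be screened.
* With `K = 1` the integration degenerates gracefully (it spans the study's
  own SVD subspace) but adds nothing over per-study analysis.
* CMF and group factor analysis, which the method is usually compared
  against, are external packages and are not re-implemented here; the
  built-in baselines are concatenation-SVD and per-study PCA overlap.
* The chi-squared null treats gene loadings as Gaussian; on real data this
  is an approximation whose main virtue is conservatism, not calibration.
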