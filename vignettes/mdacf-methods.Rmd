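---
title: "mdacf: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mdacf: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdacf)
```

## The prediction problem

Curated miRNA–disease catalogues are binary and very sparse: a few percent
of the disease × miRNA grid is experimentally validated, everything else is
unknown (not negative). `mdacf` treats prioritisation of the unknown
entries as a collaborative-filtering problem on the bipartite association
matrix `X`, resting on the standard assumption that functionally similar
miRNAs tend to associate with phenotypically similar diseases. The output
is a real-valued score per cell whose only meaningful use is *ranking*;
scores are not calibrated probabilities and are deliberately not clipped
to [0, 1].

## Similarity layer

Three sources feed an integrated disease similarity `ID` and an integrated
miRNA similarity `IM`:

**Disease semantic similarity (`semanticSimilarity`).** A disease in a
MeSH-style hierarchy is represented by its ancestor closure. An ancestor at
shortest downward distance $\ell$ contributes $\rho^\ell$; the pairwise
similarity is the shared-ancestor contribution mass normalised by the two
diseases' total semantic values. This is the classic DAG-overlap measure;
it equals 1 on the diagonal and 0 for diseases with disjoint ancestry.
The decay $\rho$ is not dictated by the data; we use the conventional
$\rho = 0.5$, under which each generation of ancestors matters half as
much as the previous one.

**miRNA functional similarity.** Consumed as a file
(`loadSimilarityMatrix`); the package does not re-derive it. Published
matrices are rarely bit-symmetric, so near-symmetric input is symmetrised
by averaging with a warning rather than rejected.

**Gaussian interaction-profile kernels (`gaussianKernel`).** The fallback
for pairs the primary measures do not cover:
$K(i,j) = \exp(-\delta \lVert BV_i - BV_j\rVert^2)$ over rows (diseases) or
columns (miRNAs) of `X`, with bandwidth
$\delta = \delta' / \overline{\lVert BV\rVert^2}$. Raw bandwidths
$\delta'_d = \delta'_m = 1$ follow the universal convention for this
kernel. When every profile is empty the mean norm vanishes; we fall back
to $\delta = \delta'$ with a warning rather than fail, since the kernel is
then constant anyway.

**Normalisation and integration.** The three matrices live on different
scales, so each is z-normalised before integration: subtract the mean and
divide by the *population* standard deviation of its defined entries
(diagonal included — nothing in the definition argues for excluding it,
and including it keeps the statistic a plain matrix summary).
`integrateSimilarity` then takes the semantic (resp. functional) value
wherever the **raw** measure is defined and strictly positive, and the
kernel elsewhere. The positivity gate is evaluated on the raw matrix, not
the z-scored one: z-scoring maps genuinely positive similarities below
zero, so a post-normalisation gate would misclassify roughly half of the
defined entries. This ordering (normalise values, gate on raw
availability) is the only one that preserves both the common scale and the
gate's semantics, which is why the package implements exactly one variant.

## Scoring layer

All three scorers consume a denoised evidence matrix $\tilde X$: the
truncated SVD reconstruction of the training `X` (`svdDenoise`). Rank is
chosen as the smallest `k` retaining 90% of squared singular-value energy
by default; an explicit integer rank or `svdEnabled = FALSE` (pure binary
evidence) are one flag away. Applying the truncation to `X` — rather than
to the similarity matrices or as a latent-factor model — keeps the three
pool definitions untouched while smoothing their 0/1 evidence, and
`svdEnabled = FALSE` recovers the pure neighbourhood model exactly.

With top-N neighbourhoods $T_d(d_i)$ and $T_m(m_j)$ (self always
excluded) on `ID`/`IM`:

- `sdaScore`: $\frac{1}{N}\sum_{d_u \in T_d(d_i)} s_d(d_i,d_u)\,\tilde X_{uj}$
- `smaScore`: $\frac{1}{N}\sum_{m_v \in T_m(m_j)} s_m(m_j,m_v)\,\tilde X_{iv}$
- `sdmaScore`: candidates are the cross product
  $T_d(d_i) \times T_m(m_j)$ (hence $u \neq i$, $v \neq j$); each pair is
  weighted by $s_{d,m} = (\,(1/s_d)^2 + (1/s_m)^2\,)^{-1/2}$, the top K
  contribute $\frac{1}{K}\sum s_{d,m}\tilde X_{uv}$.

Fusion: $\hat x = \alpha(1-\beta)\,\mathrm{SDA} +
(1-\alpha)(1-\beta)\,\mathrm{SMA} + \beta\,\mathrm{SDMA}$; the weights sum
to one for all $\alpha,\beta \in [0,1]$, and $\beta = 1$ reduces to the
pair pool alone.

Numerical conventions, chosen once for determinism:

- neighbour ties break by ascending index; pair-pool ties by ascending
  $(u, v)$;
- z-scored similarities may be negative. Negative-similarity neighbours
  stay in the top-N ranking (ranking is by value), but the pair similarity
  divides by its inputs, so pairs with a nonpositive side are undefined and
  drop out of the pool (`pairSimilarity` returns `NA`);
- under a candidate shortfall the divisor stays N (or K) — the score
  definitions fix the denominator, and shrinking it would inflate
  poorly-connected entities;
- empty neighbourhoods score 0.

## Defaults at a glance

| parameter | meaning | default | why |
|---|---|---|---|
| `alpha` | disease vs miRNA share of (1−β) | 0.3 | grid-search optimum on the curated catalogue |
| `beta` | pair-pool share | 0.1 | same |
| `nNeighbors` (N) | disease/miRNA neighbourhood | 20 | no canonical value exists; 20 is mid-range for catalogues of hundreds of entities, and the grid harness can sweep it |
| `kPairs` (K) | pair neighbourhood | 20 | same |
| `svdRank` | truncation rank / energy fraction | 0.9 | keeps the dominant structure, discards the noise tail |
| `rho` | semantic decay | 0.5 | the conventional value for DAG-overlap similarity |
| `deltaPrimeD/M` | raw kernel bandwidths | 1 | the universal interaction-profile convention |

## Evaluation harness

`loocv` holds out each known association in turn, zeroes the entry,
recomputes **everything** derived from `X` (both kernels and their
bandwidths, the integrated similarities, the SVD, all neighbourhoods) and
ranks the held-out miRNA among the disease's candidates (the held-out one
plus every miRNA not known for that disease; ties take mean rank). The
X-independent pieces — semantic similarity and the functional matrix — are
computed once and reused, which is an exact optimisation, not an
approximation. `fastLoocv = TRUE` additionally freezes the integrated
similarities at their full-data values; that *is* an approximation (common
in this literature) and is off by default.

Fold candidate sets differ in size, so pooling raw ranks would weight
folds unequally. Each candidate's rank r in a fold of n candidates maps to
the normalised score (n − r)/(n − 1); positives and negatives pool across
folds into one ROC. The stored AUC is the Mann–Whitney statistic with
half-credit ties, which matches the probability definition exactly and
yields the analytic endpoints: a scorer that always ranks the positive
first gives AUC 1, a constant scorer gives 0.5. Trapezoidal integration of
the threshold-swept curve (`trapezoidAuc`) agrees to machine precision,
and the test suite asserts that dual route.

`gridSearch` wraps `loocv` over an (α, β) grid; the default is the
one-dimensional sweep α ∈ {0.1, 0.3, 0.5, 0.7, 0.9} at β = 0.1, ties
towards smaller α then β. `caseStudyRank` exports ranked candidates, in
`"with-known"` mode (train on everything, rank the unknowns) or
`"isolated"` mode (zero the disease's row first — the stress test for
diseases with no known miRNA).

## Synthetic data: what it does and does not show

`makeAssociations` plants rank-`latentRank` structure: each disease and
miRNA gets a dominant latent cluster plus small nonnegative off-cluster
loadings; the factor product is thresholded to an exact count of ones
(`density`) and flipped entrywise with `noiseFlipProb`. `makeDag` builds a
tree whose subtrees follow the disease clusters (so semantic similarity
correlates with the planted structure), with 20% of diseases left out of
the DAG by default to exercise the kernel fallback; `makeFunctionalSim` is
a masked cosine of the miRNA factors, with 20% of pairs masked for the
same reason. A latent-factor generator (not an unstructured random graph)
is used precisely because collaborative filtering assumes such structure;
`permuteAssociations` provides the matching negative control by
redistributing the ones uniformly — permuting *entries*, not row/column
labels, because the kernels are computed from `X` itself and a label
permutation would leave its internal low-rank structure (and hence model
performance) intact.

The recovery study shipped in the tests and the acceptance script uses
60 × 80 matrices at density 0.05 with flip probability 0.02, rank 3, five
seeds — roughly the sparsity regime of real catalogues at a size where the
full rigorous cross-validation loop stays comfortable on one CPU. At these
settings the model's mean LOOCV AUC sits around 0.83 against ~0.50 for the
permuted control. About a quarter of the observed ones at these settings
are pure noise flips, which no method can rank well; that, not the model,
caps the attainable AUC.

What passing these checks shows: the pipeline recovers planted
low-rank structure far above chance under its stated protocol. What it
does not show: performance on real catalogues, whose similarity matrices
have block and hub structure, annotation biases and literature-driven
degree effects the generator does not emulate. Real-data AUC must be
measured on real data via the same `loocv` harness.

## Degenerate inputs and edge cases

- Empty DAG / diseases absent from the DAG: semantic rows are unavailable;
  the kernel silently takes over (that is the integration's purpose).
- Constant similarity matrix: z-normalisation fails loudly
  (`"constant similarity matrix"`) rather than dividing by zero.
- All-zero association matrix: kernel bandwidth falls back to
  $\delta'$ with a warning; all scores are 0.
- Asymmetric similarity input: averaged, warned.
- Cyclic hierarchy input: rejected at construction with one witness cycle
  in the message.
- A fold whose disease has every miRNA known: cannot occur in LOOCV
  (candidates always include the held-out miRNA); in case-study mode the
  candidate list is simply empty.

## Known limitations

- The rigorous LOOCV recomputes two kernels and an SVD per fold: fine at
  desk scale, a few hours at full catalogue scale (use `fastLoocv` or the
  `"bruteforce"`-vs-`"optimized"` equivalence to justify shortcuts).
- Disease-label matching between the association catalogue and the
  hierarchy is the caller's responsibility; unmatched labels silently get
  kernel-only similarity, which is correct but weaker.
- The pair pool drops pairs with nonpositive (z-scored) similarity; for
  very negative neighbourhoods SDMA can be exactly 0, making β the only
  route for those entries to differ from the SDA/SMA mixture.
- Scores across diseases are comparable only through ranks (the LOOCV
  pooling normalises for this; downstream consumers of `writeScores`
  output should rank within disease too).
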