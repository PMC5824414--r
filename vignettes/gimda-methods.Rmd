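---
title: "Graphlet-interaction scoring of miRNA-disease associations: model and methods"
author: "gimda package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graphlet-interaction scoring of miRNA-disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gimda)
```

## The prediction problem

Experimentally confirming a miRNA-disease association is slow and
expensive, so computational ranking of candidate pairs is used to
prioritize experiments. The premise, standard in this literature, is
that functionally related miRNAs tend to be associated with
phenotypically similar diseases. `gimda` implements GIMDA, a scoring
method that encodes this premise through *graphlet interactions*: the
relationship between two nodes of a weighted similarity graph is
summarized by how often the pair occupies each possible ordered pair of
positions inside every small connected subgraph pattern.

The inputs are

* a binary association matrix $A$ ($n$ diseases $\times$ $m$ miRNAs,
  $A_{ij} = 1$ for a known association),
* per-disease ancestor DAGs (MeSH-style), used for two semantic
  similarity models,
* a precomputed miRNA functional similarity matrix $FS$ (treated as an
  input, not recomputed), and
* Gaussian interaction-profile (GIP) kernels derived from $A$ itself.

## Similarity construction

**Semantic model 1.** A disease $D$ is a DAG of ancestor terms. Each
term $d$ contributes $D1_D(d) = \Delta^{\ell(d)}$ where $\ell$ is the
shortest directed distance down to $D$ (the disease itself contributes
1, and each term takes $\Delta$ times the largest contribution among
its children). The semantic value $DV1(D)$ sums the contributions, and
the similarity of two diseases is the contribution mass of their shared
terms divided by the sum of their semantic values. $\Delta$ defaults to
0.5, the convention of the semantic-similarity lineage this model comes
from; it is configurable (`gimdaConfig(delta = )`).

**Semantic model 2.** Identical in shape, but a term's contribution is
its corpus specificity $-\log(\text{DAGs containing } d / N)$, so terms
shared by every disease carry no weight. We take $N$ to be the number
of diseases owning a DAG in the corpus; "number of diseases" is
ambiguous in the source formulation and this is our reading. The
logarithm base cancels in the similarity ratio (asserted as a test).
When the denominator is zero (every term occurs in every DAG) the
similarity is 1 for identical DAGs and 0 otherwise; values above 1,
possible only under corpus pathologies, are clipped with a warning.

**GIP kernels.** The interaction profile of a disease is its row of
$A$; for a miRNA, its column. The kernel is
$K(i,j) = \exp(-\gamma \lVert IP(i) - IP(j)\rVert^2)$ with bandwidth
$\gamma = \gamma' / \overline{\lVert IP \rVert^2}$. The original
bandwidth $\gamma'$ defaults to 1 on both sides, the convention for
this kernel family; the all-zero-profile corner (undefined bandwidth)
is an error.

**Integration.** The disease similarity $SD$ is the average of the two
semantic models wherever both diseases own a DAG and the GIP kernel
value elsewhere; the miRNA similarity $SM$ is $FS$ wherever both
miRNAs appear in it and the kernel elsewhere. "Has semantic/functional
similarity" is interpreted as membership in the respective source —
the only membership information available.

## The graphlet-interaction catalog

All connected non-isomorphic undirected graphs on 2-4 nodes are
enumerated exhaustively: 9 graphlets. Node positions are reduced by
each graphlet's automorphism group into 15 orbits. An *interaction
isomer* is an orbit of ordered node pairs within one graphlet:
exchanging source and target gives a different isomer, and the catalog
has exactly 28. Because the enumeration is from first principles
(canonical codes over vertex permutations; the groups have at most 24
elements), the counts 9/15/28 are *computed*, not hard-wired, and the
tests cross-check non-isomorphism and orbit structure against igraph.

The printed labels $I_1..I_{28}$ follow the package's deterministic
canonical ordering (graphlet by node count, edge count, canonical code;
then source orbit, target orbit, template code). Published figures of
the same catalog order the isomers pictorially; only the cardinality is
comparable, and no result depends on the label order.

## Weighted isomer census

For isomer $k$ with template edge set $T_k$ and ordered pair $(i, j)$,

$$N_{ij}(I_k) = \frac{1}{\sigma_k}\sum_{\substack{l, m \text{ distinct}\\ l,m \notin \{i,j\}}}
  \prod_{(s,t) \in \text{slot pairs}} b_{st}, \qquad
  b_{st} = \begin{cases} a_{st} & (s,t) \in T_k\\ 1 - a_{st} & \text{otherwise,} \end{cases}$$

where $a$ is the similarity weight (an absent edge is weight 0).
Non-edges of the template contribute $1 - a$, i.e. templates match
*induced* weighted configurations — the only reading under which the
two branches of the $b$ definition are exhaustive. Sums over ordered
auxiliary tuples double-count templates symmetric in the auxiliaries,
so each count is divided by $\sigma_k$, the automorphism stabilizer of
the ordered (source, target) pair; unit-weight counts are then exactly
induced-occurrence counts and integral. Self pairs are stored as 0.

The fast path contracts the products with one matrix multiplication
per auxiliary node per template; `countIsomersOracle()` re-derives
every count by explicit tuple enumeration (and recomputes $\sigma_k$
independently by permutation search) and is used throughout the tests
as the independent verification route. Counts are multilinear in each
edge weight, which the tests exploit as an exactness property.

Edges exist wherever similarity is positive, weighted by the
similarity; no sparsification threshold is applied by default
(`minWeight = 0`), since none is part of the model.

## Scoring and regression

Counts are normalized per source over all other targets,
$\text{norm}(N_{pj}) = N_{pj} / \sum_{j' \neq p} N_{pj'}$ (all-zero
rows stay zero). The miRNA-graph feature of pair $(d(i), m(j))$ for
isomer $k$ sums $\text{norm}(N_{pj}(I_k))$ over the known partners
$p \in P(i)$; the disease graph mirrors this with $Q(j)$. One global
28-long weight vector per graph is fitted by the closed-form normal
equations $V = (X X^\top + \lambda I)^{-1} X s$ against the binary
labels from $A$ stacked over all pairs; fitting per disease would be
underdetermined (28 parameters against a handful of positives), and no
negative sampling is used — the closed form handles the full design
cheaply. $\lambda$ defaults to $10^{-6}$ because the unpenalized
system is frequently singular on small graphs; $\lambda = 0$
reproduces the textbook least-squares solution exactly when well
posed (asserted to $10^{-8}$ on synthetic full-rank designs). The
final score averages the two graph scores,
$S = (S_m + S_d)/2$, which keeps the method applicable when one side
has no known partners (new disease or new miRNA): that side contributes
zero and the within-entity ranking is carried entirely by the other
graph.

## Cross-validation protocol

`gimdaLoocv()` hides each known association in turn; `gimdaKfoldCv()`
partitions the positives uniformly into $k$ near-equal folds (exact
partition: union is all positives, pairwise disjoint), repeats the
partition `repeats` times (default 100, the reference protocol; scale
down for desk-size runs) and reports mean $\pm$ SD. Test pairs are
ranked against all unknown pairs (global) or the unknown miRNAs of the
same disease (local); the AUC is the mean percentile rank with midrank
tie handling, so an uninformative constant predictor scores exactly
0.5. `computeAuc()` is the Mann-Whitney statistic and equals the
trapezoidal area under `rocCurve()` (asserted, including heavy ties,
and cross-checked against pROC).

Leakage control: hidden associations are removed from $A$ *before* the
GIP kernels, partner sets and features are computed. The semantic
matrices are cached across folds (they do not depend on $A$). When
semantic and functional coverage is complete, $SM$ and $SD$ are
$A$-independent, so the census is computed once and reused — an exact
optimization, not an approximation. For partially covered inputs,
`fastApprox = TRUE` reuses the full-data similarities; this is an
explicit approximation of the strict protocol and is labelled as such.

Whether the weights should be refitted inside each fold is not
determined by the method's published description; we refit per fold,
which is the conservative (leak-free) choice.

## The synthetic benchmark

`generatePlantedWorld()` draws a latent block assignment shared by
diseases and miRNAs; similarities are Beta-distributed around
`withinBlockSim` (default 5/6, i.e. Beta(5,1)) inside blocks and
`betweenBlockSim` (1/6, Beta(1,5)) across; block-aligned pairs are
associated with probability `assocDensity` and a `hiddenFraction`
(default 20%) of positives is hidden as recoverable truth. Disease
DAGs attach same-block diseases under a shared ancestor chain (depth 3,
branching 2 by default) below a global root, so the semantic models see
the same block structure. `noise` interpolates to a null world:
at 1, similarities are i.i.d. uniform, DAG attachment is random, and
associations are uniform with matching expected count.

The default `assocDensity = 0.8` is deliberate. Hidden positives are
statistically exchangeable with aligned-block pairs that were simply
never drawn positive, so with two equal blocks *no* predictor can
exceed a held-out AUC of $1 - (1-\rho)/(2(2-\rho))$ at density
$\rho$ — about 0.79 at $\rho = 0.3$ and 0.92 at $\rho = 0.8$. The dense
regime keeps the ceiling near 1 so the measured AUC reflects method
quality rather than irreducible label ambiguity. On the defaults the
pipeline recovers hidden positives at mean AUC ≈ 0.91 over 10 seeds
and stays within 0.5 ± 0.1 on the null world, which is what passing
tests demonstrate: recovery of block-structured signal and absence of
self-delusion on noise. What they do not demonstrate is performance on
real association corpora, whose degree distributions are heavy-tailed
and whose similarity structure is far from block-constant; the
reference-scale corpora are external downloads and out of scope here.

## Numerical choices and degenerate inputs

* Similarity matrices must be symmetric within $10^{-9}$; file readers
  repair mild asymmetry by averaging (warning above $10^{-6}$) and
  clip values into $[0,1]$ with a warning.
* Entity labels are lower-cased and trimmed before matching across
  files; silent index misalignment between association and similarity
  sources is the dominant failure mode in practice.
* Census weights must have a zero diagonal; tiny negative round-off
  (above $-10^{-12}$) from BLAS contractions is clipped to zero.
* Normalization rows with zero total stay all-zero rather than NaN.
* Ranking ties break lexicographically by miRNA ID, making candidate
  lists deterministic across platforms.
* Cycles in a disease DAG, terms missing from the model-2 corpus,
  non-square similarity files and all-zero GIP profiles are hard
  errors naming the offending entity.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run entirely on generated
data: census equivalence on 50 random graphs of 4-12 nodes (binary and
uniform weights), planted and null worlds of 30 diseases × 30 miRNAs
over 10 seeds each, LOOCV/k-fold on worlds of 7-12 entities per side,
and 5-fold CV with 5 repeats on a 12 × 12 world. These sizes were
chosen so the whole battery completes in seconds while every code path
(including the strict leakage-controlled refit) is exercised; the
package itself handles reference-scale inputs (hundreds of entities,
thousands of associations) through the same functions.

## Known limitations

* Graphlets with five or more nodes are out of scope; similarity
  signal that only manifests across paths longer than three edges is
  invisible to the census.
* A pair that is new on *both* sides (new disease and new miRNA) has
  both partner sets empty and receives score 0; the method cannot rank
  such pairs.
* The regression treats every unknown pair as a 0-labelled training
  point; under extreme sparsity the fitted weights shrink toward
  scoring everything near zero, which ranking tolerates but calibrated
  probabilities would not.
* Model-2 semantic similarity depends on the corpus composition, so
  adding DAGs to the corpus changes existing pairwise values.
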