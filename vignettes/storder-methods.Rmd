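---
title: "Methods: joint trajectory inference from expression connectivity and spatial cell densities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint trajectory inference from expression connectivity and spatial cell densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Classical trajectory inference orders cell states purely by their proximity
in expression space. For processes in which differentiation is coupled to
physical migration through tissue — extravillous trophoblast invading the
decidua and myometrium is the motivating case, with a villous
cytotrophoblast origin, a single bifurcation, and endovascular and
giant-cell end states — expression similarity alone can under-determine the
tree: distinct states may be transcriptionally close without ever touching
in tissue, and vice versa. `storder` fuses two complementary pairwise
statistics over cell states:

* **P**, an expression connectivity matrix: for each pair of states, the
  number of inter-state edges in a cell-level k-NN graph divided by its
  expectation under random edge placement,
  $\hat e_{ij} = 2m\,n_i n_j / (n(n-1))$, clipped to $[0,1]$. This is the
  PAGA-style cluster connectivity statistic; a precomputed matrix from any
  PAGA variant can be supplied instead.
* **S**, a spatial correlation matrix: the normalised between-state
  cross-covariance of a pairwise Gaussian-process model fitted to per-spot
  cell-state densities (the output of a spot deconvolution tool).

and reconstructs the trajectory as a maximum spanning tree of

$$W = \beta\,(\alpha P + (1-\alpha) S) + (1-\beta)\, P \odot S,$$

screening each candidate tree against topology assumptions and summarising
the result over the whole $(\alpha,\beta)$ grid.

## The pairwise spatial covariance model

For states $i,j$ with centred density vectors $Y_i, Y_j$ over $n$ spots with
coordinates $X$,

$$\mathrm{vec}(Y_i, Y_j) \sim \mathcal N\!\left(0,\;
\Sigma^{(1)} \otimes K(X, l) + \mathrm{diag}(\sigma^2_i, \sigma^2_j)
\otimes I\right),
\qquad K(X,l)_{mn} = \exp\!\left(-\frac{\lVert x_m - x_n\rVert^2}{2l^2}\right).$$

The between-state covariance $\Sigma^{(1)}$ is kept symmetric positive
semidefinite by construction, $\Sigma^{(1)} = AA^\top$ with
$A = \begin{pmatrix} a_1 & 0 \\ a_2 & a_3\end{pmatrix}$, so every optimiser
iterate is admissible. The six free parameters are
$(a_1, a_2, a_3, \sigma^2_i, \sigma^2_j, l)$.

The reported score for the pair is the normalised cross-covariance

$$S_{ij} = \max\!\left(0,\; \Sigma^{(1)}_{12} \big/
\sqrt{\Sigma^{(1)}_{11}\,\Sigma^{(1)}_{22}}\right),$$

clipped below at zero so that S is commensurate with P on $[0,1]$: a
negative spatial cross-covariance (states avoiding each other) carries no
evidence for a differentiation link, so it is treated as zero rather than
penalised further.

### Likelihood evaluation

With $K = U \Lambda U^\top$ (one symmetric eigendecomposition per candidate
$l$, after adding a $10^{-6}$ jitter to the diagonal), rotating each field
by $U^\top$ decouples the $2n$-dimensional Gaussian into $n$ independent
bivariate Gaussians with covariance $\Sigma^{(1)} \lambda_m +
\mathrm{diag}(\sigma^2_i, \sigma^2_j)$. The log-likelihood is then a
vectorised sum of 2×2 determinants and quadratic forms — mathematically
identical to the dense $2n \times 2n$ Cholesky evaluation (the test suite
verifies agreement to relative error below $10^{-6}$ on random instances)
at a fraction of the cost.

### Optimisation

The length scale is *profiled*: an outer one-dimensional search over
$\log l$ wraps an inner BFGS over $(a_1, a_2, a_3, \log\sigma^2_i,
\log\sigma^2_j)$, for which the eigendecomposition is fixed and each
likelihood evaluation costs $O(n)$. The outer search first evaluates a
9-point grid spanning a factor of 8 either side of the initial $l$, then
refines by golden-section in the bracketing interval. Each inner solve is
attempted both from a data-driven default start (split the sample variance
evenly between spatial and noise components; initialise the cross term from
the empirical correlation) and from the best solution found so far — the
double start prevents a degenerate inner optimum at one $l$ (e.g. noise
collapsing to zero) from corrupting the rest of the profile, a failure mode
we observed with naive warm starting. This maximises exactly the same
six-parameter likelihood as a joint quasi-Newton run with automatic
differentiation would, and the wide outer bracket plays the role of
multiple length-scale restarts.

$l$ is initialised to the **median nearest-neighbour spot distance** — the
distance between neighbouring capture-spot centres on a regular array — and
users working on processes spanning many spots should widen
`length_scale_init` accordingly.

### Choices worth knowing about

* **Centering.** The model is zero-mean, so densities are mean-centred per
  state before fitting; no mean parameters are estimated. The score is
  invariant to rescaling both fields, so unit-variance scaling is
  unnecessary.
* **Degenerate pairs.** A state with constant (typically all-zero) density
  in the fitted region yields score 0 and a flag, never an error, so one
  empty state cannot abort a whole matrix.
* **Regions.** An optional spot mask (`region =`) restricts fitting to the
  anatomical regions that actually contain the states of interest;
  segmentation itself is out of scope and labels are consumed as given.
* **Multiple capture areas.** `offset_sample_coords()` shifts each sample's
  coordinates so areas never overlap; a joint fit then treats cross-sample
  spot pairs as uncorrelated through the kernel. Averaging per-sample S
  matrices is the alternative when areas differ strongly in quality.

## Tree reconstruction and the grid scan

The fused matrix W is turned into a tree by Kruskal's algorithm on
descending weights with a deterministic lexicographic tie-break — for
weights in $[0,1]$ this is equivalent to a minimum spanning tree on
$1 - W$, but deterministic and directly testable against exhaustive
enumeration of all labelled spanning trees (the suite checks 100 random
5-state instances against the $5^3 = 125$-tree brute force). Zero-weight
edges are admitted only when positive-weight edges leave the graph
disconnected, and the result is then flagged weakly connected.

Topology validity requires: a connected spanning tree; exactly one node of
degree $\ge 3$ (the branching point — degree exactly 3 is not required,
though the count of degree-3 nodes is reported separately); the root a
leaf; every required end state a leaf; and no other leaves. Interpreting
"start at" as *the root must itself be a leaf* matches a trajectory that
begins, rather than passes through, the origin population; it can be
relaxed with `root_must_be_leaf = FALSE`.

The grid scan enumerates $\alpha,\beta$ inclusively — at step 0.01 that is
$101^2 = 10{,}201$ pairs — and reports, per cell, validity and the branch
state, plus the modal branch state over valid cells (ties are reported, not
broken silently). When $S = P$ with distinct entries, every cell yields the
same tree, since $x \mapsto \beta x + (1-\beta)x^2$ is strictly increasing
on $[0,1]$ and cannot change the edge ranking; this identity is in the test
suite as a sanity anchor.

## Ambient-RNA gene filter

Droplets with fewer than 5 UMIs are discarded as likely artifacts; barcodes
present in the raw but not the filtered (cell-called) matrix are treated as
empty droplets; and per gene

$$P_g = \frac{E_g^{\text{empty}}}{E_g^{\text{empty}} + E_g^{\text{cells}}},$$

with totals summed over the pooled empty and cell droplets respectively.
Samples contribute only when their fraction-of-reads-in-cells metric is
strictly below 0.70 (`sample_noisiness_gate()`), the operating point at
which the metric indicates substantial ambient contamination. Genes are
labelled noisy when $P_g$ strictly exceeds the 50% quantile of the defined
$P_g$ distribution; the quantile uses linear interpolation between order
statistics (R's default type 7), a choice the source procedure leaves open,
and both the probability and the quantile are configurable. An explicit
`threshold =` supports labelling one droplet class with a cutoff derived
from another (e.g. nuclei-derived thresholds applied to cells, to avoid
over-filtering based on the cleaner modality). Genes with zero counts
everywhere are excluded rather than assigned $P = 0$.

## What the synthetic generators emulate

* `make_hex_lattice()` reproduces the triangular packing of spatial
  capture-spot centres; all nearest-neighbour distances equal the spacing.
* `simulate_pair_densities()` draws exactly from the pairwise GP model via
  a dense Cholesky factor of the full $2n \times 2n$ covariance —
  deliberately independent of the fast likelihood path, so simulation and
  inference cannot share a bug.
* `simulate_trajectory_landscape()` builds density fields as Gaussian bumps
  along a chain or Y path, *not* as GP draws: bump geometry makes the
  ground-truth adjacency unambiguous, so "recover the trajectory" tests are
  decoupled from "recover the model parameters" tests. Consecutive bump
  centres sit $2w(1-\text{overlap})$ apart for bump width $w$; additive
  noise is clipped at zero to honour density nonnegativity and the clipped
  fraction is reported.
* `simulate_droplet_matrix()` plants ambient structure by multiplying a
  designated gene subset's rate by `enrichment` in empty droplets. The
  default makes half the genes ambient-enriched, matching the operating
  point of the strict-median labelling rule (which by construction flags at
  most half of the genes); precision against the planted set is the
  recovery metric.

These generators emulate the *statistical* structure the method assumes —
smooth co-varying density fields, a tree-shaped state layout, an
ambient-enriched gene subset. They do not emulate real spatial
transcriptomics counts, deconvolution uncertainty (densities arrive
noise-free up to the planted noise term), histology, or segmentation error,
so passing tests demonstrate correctness of the algorithms under their own
model, not robustness to deconvolution artifacts.

## Problem sizes and numerical defaults

Parameter-recovery checks use a 20×20 hex lattice ($n = 400$ spots),
spatial-to-noise variance ratio 4:1 ($\sigma^{(1)}_{11} = \sigma^{(1)}_{33}
= 1$, noise $0.25$), true length scale twice the spot spacing, and 20
simulation seeds per correlation level — sizes at which the estimator's
sampling variability is small relative to the recovery tolerances while a
full run stays interactive. Kernel jitter is $10^{-6}$; the outer
length-scale search spans a factor of 8 either side of its initialisation
with tolerance $5\times10^{-3}$ on $\log l$; inner BFGS uses a relative
tolerance of $10^{-10}$.

## Limitations

The approach assumes gradual expression change accompanied by gradual
migration; states that jump spatially (or differentiate in place) violate
the model and S becomes uninformative or misleading — the fusion weights
$(\alpha, \beta)$ exist precisely to tune how much S is trusted. The
pairwise fits ignore other states (no joint multi-state GP), S inherits
whatever biases the upstream deconvolution has, and pseudotime along the
inferred tree is out of scope.
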