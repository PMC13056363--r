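---
title: "Separating mutation from selection in antibody somatic evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating mutation from selection in antibody somatic evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

During affinity maturation, B-cell receptor genes accumulate point
mutations through somatic hypermutation (SHM) and are then filtered by
selection on antigen binding and expression. A sequence model trained
naively on repertoire data conflates three signals: the strong k-mer
context biases of the SHM machinery, the structure of the codon table
(single-nucleotide codon changes are far more accessible than
multi-nucleotide ones), and the functional selection signal that is
actually of interest for antibody engineering.

`dasm` factors these apart. The observed data are parent-child pairs
(PCPs): aligned, gap-free, in-frame nucleotide sequences taken from the
edges of reconstructed B-cell lineage trees (clonal-family clustering,
tree inference and ancestral reconstruction happen upstream and are out
of scope here). For a parent codon sequence $X$ with translation
$\bar X$, child $Y$, and branch length $t$, the per-site likelihood of
observing codon $c$ at codon site $j$ is

$$
\ell_{j,c}(t, X) =
\begin{cases}
p_{j,c}(t, X)\, f_{j,\bar c}(\bar X) & c \text{ codes for an amino acid}\\
0 & c \text{ is a stop codon,}
\end{cases}
$$

with the wild-type codon receiving the residual
$1 - \sum_{c \ne x_j} \ell_{j,c}$. Here $p_{j,c}(t,X)$ is the *neutral*
probability of the codon change — a fixed, pre-estimated mutation model —
and $f_{j,a}(\bar X)$ is a *selection factor*: the multiplicative effect
of amino acid $a$ at site $j$ relative to neutral expectation ($>1$
beneficial, $<1$ deleterious). Selection factors for the wild-type amino
acid are fixed to exactly $1$. This gauge removes the scale
unidentifiability between mutation and selection and means synonymous
changes are treated as neutral, which anchors the branch-length scale.
The full-record likelihood is $\prod_j \ell_{j, y_j}(t, X)$.

## The neutral model

The neutral side is deliberately simple and fixed:

* **k-mer rates.** Each nucleotide site gets a relative mutability
  $\lambda_i$ and a 3-way substitution distribution looked up from its
  k-mer context (default $k = 5$, the classical S5F-style
  parameterization). Contexts that run off the sequence ends are N-padded
  and resolved by averaging over all matching k-mers.
* **Rates to probabilities.** $p_i = 1 - e^{-\lambda_i t}$, the standard
  competing-exponentials form, with a time-independent substitution
  distribution. Branch length $t$ is measured in expected neutral
  substitutions per site at unit rate; random tables generated by
  `randomKmerRateTable()` are normalized to mean rate 1 to keep this
  interpretation.
* **Codon products.** The 64-way codon probability is the product of the
  three per-position outcomes (`codonProbabilities()`), so each site's
  vector sums to 1 by construction.
* **Multihit correction.** SHM mutations cluster spatially, so codons
  with 2 or 3 nucleotide changes are observed more often than the
  independent-site product predicts. Hit-class multipliers
  $(m_1, m_2, m_3)$ scale each codon's probability by the multiplier of
  its nucleotide Hamming distance from the parent, followed by a
  full-vector renormalization. We renormalize the whole 64-vector (rather
  than preserving the site's total mutation probability) because it keeps
  every site's vector a probability distribution with no side conditions;
  the alternative reading would couple the correction to the branch
  length. `fitMultihit()` estimates the multipliers by maximum likelihood
  in log-coefficient space (BFGS with analytic gradients) on neutrally
  evolving data, fixing at 1 any hit class with no observed events.
* **Chain rates.** Light chains mutate more slowly than heavy chains;
  light-chain site rates are multiplied by a fixed factor, default 0.63
  (the median light/heavy relative rate from paired-chain phylogenetic
  estimates), while heavy-chain rates are untouched.

## The selection model

Selection factors come from a transformer encoder: an amino-acid
embedding (alphabetical token order, plus an `X` token for ambiguous
residues and a separator token), sinusoidal positional encodings, a
learned 2-way chain embedding for paired heavy-light inputs, a stack of
post-norm encoder layers (multi-head attention plus a ReLU feedforward
block), and a 20-way per-site linear head. One forward pass yields
factors for every amino acid at every site, independent of how many
variants are scored afterwards. The default architecture — 5 layers,
8 heads of 32 dimensions, feedforward width 1024, dropout 0.1 — has
about 3.96 million trainable parameters.

The head output passes through a bounded "wiggle" activation in
log-factor space:

$$
\mathrm{wiggle}(x) = \begin{cases}
\beta \log(1 + x/\beta) & x \ge 0\\
x & x < 0,
\end{cases}
\qquad f = e^{\mathrm{wiggle}(x)} .
$$

It fixes 0 (factor 1), is continuous and strictly increasing, grows
sub-linearly for beneficial outputs, and leaves the log factor unbounded
below so factors of strongly deleterious substitutions can approach 0.
The curvature scale $\beta$ (log-factor units, default 0.3) is exposed in
`DasmConfig` since the exact parameterization is a free design choice;
the qualitative properties above are what matter. Wild-type entries are
overwritten with exactly 1 after the forward pass.

Design choices that were genuinely open and how we resolved them:

* **Paired encoding.** Heavy chain, separator token, light chain, with
  the chain embedding added to token embeddings. Positional encodings run
  continuously through the light chain rather than restarting; the chain
  embedding already disambiguates the two segments.
* **Initialization.** The output head starts near zero, so an untrained
  model predicts factors $\approx 1$ everywhere — a neutral, stable
  starting point for the joint optimization.
* **Maximum length** 1024 positions, covering a paired Fv with margin.

The forward and backward passes are written in base R matrix operations;
the test suite verifies every parameter gradient against central finite
differences.

## Training

`trainDasm()` performs cyclic joint optimization (default 4 cycles).
Each cycle runs stochastic-gradient epochs (RMSprop; default 2 epochs,
batch 32, learning rate $2\times10^{-3}$) on the summed per-PCP negative
log-likelihood with branch lengths fixed, then re-optimizes every branch
length with the network fixed. Branch lengths are independent across
PCPs and are optimized by golden-section search over $\log t$ on
$[10^{-6}, 5]$ to a log-likelihood tolerance of $10^{-7}$, starting from
the observed nucleotide difference fraction (floored at $10^{-4}$).
Gradient steps use the full likelihood while branch-length steps use the
gauge-fixed factors, which under the wild-type gauge are the same
quantity — the gauge is enforced structurally, not as a penalty.

Numerical details worth knowing:

* Early in training $\sum_{c \neq x_j} p_{j,c} f_{j,\bar c}$ can exceed 1;
  the non-wild-type entries are then proportionally rescaled so their sum
  equals a ceiling just below 1 (default $1 - 10^{-6}$), and the wild
  type keeps the residual. Proportional rescaling preserves relative
  selection between alternatives.
* Codons containing ambiguous bases (N) are retained in the data but
  masked: they are excluded from likelihood sums and receive no gradient.
  Discarding whole sequences would waste data.
* PCPs that share an identical model input reuse a single
  forward/backward pass per batch with their output-layer gradients
  summed — mathematically identical for dropout-free configurations;
  with dropout the mask is shared across the group.
* The training seed governs initialization, data order and dropout, so a
  fixed seed reproduces the loss trace exactly.
* Whether branch lengths should be re-optimized before or after the
  network phase within a cycle is ambiguous; we optimize the network
  first, which combined with the divergence-based initialization means
  both orderings are effectively exercised.

## The simulator and what the tests show

`simulateDataset()` samples children *exactly* from the per-site codon
likelihood tables built by the same code path the likelihood evaluates,
given planted parameters: a k-mer table, multihit coefficients, a
selection landscape (mixture of neutral / deleterious / beneficial
entries; defaults 0.5 / 0.35 / 0.15 with factors log-uniform on
$[0.02, 0.5]$ and $[1.5, 4]$), and log-normal branch lengths (default
median 0.03, a plausible SHM divergence scale). This makes recovery
tests exact with respect to the fitted model — the simulator's recorded
sampling log-probability equals the model log-likelihood bit for bit —
and it is also the simulator's main limitation: it emulates the
*product* of upstream repertoire processing (clustered multi-nucleotide
codon changes via multihit, context-biased rates, per-site selection,
heterogeneous branch lengths) but not V(D)J recombination, indels,
shared tree structure within clonal families, or reconstruction error in
the parents. Passing recovery tests therefore demonstrate correctness
and identifiability of the estimation machinery under the model's own
assumptions, not robustness to real-data violations of them.

Problem sizes used by the test suite were chosen to give the recovery
statistics comfortable resolution at desk scale: multihit fitting uses
5,000 neutral PCPs of 100 codons (planted $m_2 = 5$, $m_3 = 25$
recovered within 20%); selection recovery trains a small configuration
(2 layers, 64-dim embedding, feedforward 256) for 4 cycles on 2,000
PCPs of 60 codons sharing a germline parent. Recovery of planted log
selection factors is assessed on (site, amino-acid) pairs with at least
5 simulated nonsynonymous events: substitutions that are never (or
almost never) simulated — chiefly multi-nucleotide-accessible amino
acids, whose neutral probability is second order in $t$ — carry no
training signal, and no estimator could recover them from the data; the
correlation is a statement about identifiable entries. Under an
all-neutral landscape the median absolute estimated log factor stays
below 0.25, confirming the model does not hallucinate selection from
mutation structure.

## Scoring statistics

For model evaluation the package implements the perplexity family:
ordinary perplexity (geometric-mean inverse probability of observed
tokens), pseudo-perplexity over mask-conditioned distributions,
masked-marginals pseudo-perplexity (variants scored with per-site
probabilities computed once in wild-type context, with its exact
additive-constant identity for single mutants), and conditional
perplexity, which scores only substituted sites under distributions
conditioned on a substitution occurring — for the DASM these come from
the amino-acid substitution probabilities renormalized over non-parent
residues. Variant scoring uses log selection factors directly: single
substitutions score $\log f_{j,a}$ (optionally stratified by whether the
amino acid is reachable by a single nucleotide change from the parent
codon), multi-mutants sum log factors over differences from a site-wise
consensus (ties broken alphabetically for determinism), and replicate
measurements are aggregated by geometric mean in linear scale with
variants above a linear-scale CV of 0.5 removed before scoring.

## Known limitations

* The neutral model is a pluggable k-mer table; wider-context
  convolutional neutral models are out of scope, as is per-site rate
  heterogeneity from tree inference.
* Training in base R is practical for the simulation scales above, not
  for millions of PCPs.
* The conserved-cysteine productivity filter takes its positions from
  configuration; antibody numbering schemes are not implemented.
* Branch lengths are optimized per PCP independently, ignoring shared
  internal branches of the clonal-family tree they came from.
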