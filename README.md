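# dasm: deep amino-acid selection models for antibody somatic evolution

`dasm` is an R package for codon-level mutation–selection modelling of
antibody affinity maturation. It is aimed at computational immunologists
and protein engineers who want per-site, per-amino-acid estimates of
natural selection that are *not* confounded by the nucleotide-level
processes shaping repertoire data — the k-mer context biases of somatic
hypermutation (SHM) and the accessibility structure of the codon table.

## The model

The training data are parent–child pairs (PCPs): aligned, in-frame
nucleotide sequences from the edges of reconstructed B-cell lineage
trees. For parent codon sequence *X* (translation *X̄*), branch length
*t*, and codon site *j*, the likelihood of observing codon *c* is

```
ℓ_{j,c}(t, X) = p_{j,c}(t, X) · f_{j,c̄}(X̄)   if c codes for an amino acid
ℓ_{j,c}(t, X) = 0                              if c is a stop codon
```

with the wild-type codon receiving the residual `1 − Σ ℓ` (clamped just
below 1 when selection pushes the sum past it). Here `p_{j,c}` is a
**fixed neutral model** — per-nucleotide-site rates and substitution
distributions from a 5-mer table, converted via `p = 1 − exp(−λt)`,
multiplied into per-codon products, with hit-class "multihit"
multipliers for clustered 2- and 3-nucleotide codon changes and a 0.63
rate factor for light-chain sites — and `f_{j,a}` is a **learned
selection factor** (>1 beneficial, <1 deleterious, wild type fixed at 1)
produced for all sites and amino acids in one forward pass of a
transformer encoder with a bounded "wiggle" output activation. The
per-PCP likelihood `Π_j ℓ_{j,y_j}` is optimized cyclically: RMSprop
epochs on the network with branch lengths fixed, then independent
golden-section branch-length optimization per PCP with the network
fixed.

The package provides the PCP data model and validators, the neutral
machinery (`siteRates`, `codonProbabilities`, `applyMultihit`,
`fitMultihit`), the selection model (`buildDasm`,
`predictSelectionFactors`), the likelihood and training stack
(`codonLikelihoods`, `pcpLogLikelihood`, `optimizeBranchLength`,
`trainDasm`), scoring statistics (perplexity family, DMS and
multi-mutant variant scoring, consensus building, replicate
aggregation), a generative simulator with planted parameters
(`simulateDataset`), and a CLI (`dasmMain`, with a wrapper script in
`inst/scripts/dasm`).

## Worked example

Simulate PCPs from a planted selection landscape, train a small model,
and compare estimated with planted log selection factors:

```r
library(dasm)

## 1. A planted world: germline, selection landscape, neutral SHM model
germ <- generateGermline(30, seed = 11)
landscape <- sampleSelectionLandscape(translateNt(germ), seed = 12)
neutral <- neutralModel(randomKmerRateTable(5, seed = 13),
                        MultihitCoefficients(1, 2.5, 6))

## 2. Simulate parent-child pairs from the mutation-selection model
sim <- simulateDataset(1000, germline = germ, neutral = neutral,
                       factors = landscape, tMedian = 0.05, seed = 14)
sim$pcps
#> PCPSet with 1000 parent-child pairs
#>   nt length range: 90 - 90
#>   paired records: 0
#>   branch lengths set: 1000

## 3. Joint training: network epochs, then branch lengths, 4 cycles
fit <- trainDasm(sim$pcps, neutral,
                 DasmConfig(layers = 2, heads = 4, headDim = 16,
                            ffDim = 256, dropout = 0),
                 TrainingConfig(cycles = 4, epochsPerCycle = 2, seed = 15))
tail(fit$trace, 3)
#>   cycle epoch     loss
#> 6     3     2 23.07099
#> 7     4     1 23.01663
#> 8     4     2 23.00585

## 4. One forward pass predicts factors for every substitution
est <- predictSelectionFactors(fit$model, translateNt(germ))
est
#> SelectionFactorMatrix: 30 sites x 20 amino acids
#>   log-factor range: [-3.13, 0.926]
```

The `loss` column is the mean per-PCP negative log-likelihood, which
decreases across cycles; the factor matrix has one row per site, wild
type exactly 1. Restricting to (site, amino-acid) substitutions actually
observed at least 5 times in the simulated data:

```r
#> r(planted, estimated log f) = 0.652 over 140 observed substitutions
```

a 90-second desk-scale run recovers the planted landscape well; the test
suite's larger recovery experiment (2,000 PCPs of 60 codons, 4 cycles)
reaches r > 0.7. The default architecture (5 layers, 8 heads × 32 dims,
feedforward 1024) counts ~3.96M trainable parameters.

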