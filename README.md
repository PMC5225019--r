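# hiMSA

Hierarchical multiple sequence alignment and subgroup pattern sampling
for protein superfamilies.

## The problem

A single profile hidden Markov model (HMM) describes a protein
superfamily poorly: subfamilies conserve residues — and sometimes whole
regions — that the family as a whole does not, and those
subfamily-specific positions are prime candidates for functional
specificity (substrate recognition, catalysis, interfaces).  hiMSA
aligns a superfamily, partitions it into hierarchically nested
subgroups, identifies the residue patterns that discriminate each
subgroup from its closest relatives, and selects the model's complexity
by the minimum description length (MDL) principle — all within one
Bayesian MCMC sampler, so alignment, partition and patterns inform each
other instead of being fixed upstream.

It is aimed at computational biologists studying large, functionally
diverse protein families who want statistically defensible
subfamily-defining ("specificity-determining") positions rather than
output from a tool chain whose steps optimize incompatible objectives.

## The model in brief

* **Alignment**: Gibbs sampling over the profile-HMM posterior
  π(R|X) ∝ Γ(h(R\_Xc)+β₀) · ∏ⱼ Γ(h(R\_Xⱼ)+βⱼ) with Dirichlet-mixture
  emission priors and position-specific gap penalties integrated out
  against Dirichlet priors (per position, three Dirichlet-multinomial
  blocks for transitions leaving match, insert and delete states).
  Single-sequence paths are redrawn by a C++ forward pass with
  stochastic traceback and a Metropolis-Hastings correction, so detailed
  balance holds exactly.
* **Partitioning (BPPS)**: every non-reject node of a rooted hierarchy
  defines a contrast alignment — foreground (its subtree) versus
  background (the rest of its parent's subtree; for the root, the
  standard amino-acid frequencies of random sequences).  Patterns are
  residue sets from a biochemical catalog, mixed with background
  contamination α; a reject node (prior 0.70) models unrelated
  sequences, and random input yields the null hierarchy with every
  sequence rejected.
* **MDL model selection**: the node count (geometric prior, factor
  0.99), the rooted tree (uniform over the Catalan number C\_n of
  shapes), each node's pattern, each sequence's assignment and each
  match state are priced in bits; nodes need ≥ 50 sequences per leaf and
  ≥ 7 net bits of pattern information, and match columns must beat their
  path cost in BILD (Bayesian Integral Log-odds) information.
* **Specificity statistics**: per column, the Δ-BILD score
  BILD(subgroup) + BILD(rest) − BILD(all), averaged over major
  subgroups, normalized to 0–100, flagged above mean + 2 SD; contrast
  alignments render in the standard text notation (consensus lines,
  frequency digits in integer tenths, pattern dots, semi-log divergence
  bars) and minimal RTF.

## Worked example

Plant a known three-subgroup family, emit sequences, and run the full
sampler:

```r
library(hiMSA)

pl  <- plantModel(syntheticSpec(), seed = 201)   # 3 leaves x 60 seqs, 120-column core
em  <- emitSequences(pl, seed = 301)
fit <- runHiMSA(em$seqs, SamplerConfig(), seed = 401)

fit@hierarchy
#> Hierarchy: 5 nodes (3 non-reject leaves), height 2, 180 sequences

scoreRecovery(em, fit)[c("ari", "patternRecall")]
#> $ari
#> [1] 1
#> $patternRecall
#> [1] 1
```

The fitted hierarchy recovers the three planted subgroups exactly
(adjusted Rand index 1 between true and inferred assignments) and every
planted specificity-determining column is selected by a node on its
lineage (pattern recall 1).  The Δ-BILD profile ranks the planted
columns on top:

```r
prof <- deltaBildProfile(fit@seqs, fit@alignment, fit@hierarchy)
head(prof[order(-prof$normalized), ], 3)
#>     column      raw normalized flag
#> 21      21 116.1176  100.00000 TRUE
#> 116    116 115.3206   99.47043 TRUE
#> 118    118 115.1252   99.34060 TRUE
```

Here `raw` is the average Δ-BILD in bits, `normalized` the 0–100
rescaling, and `flag` marks columns more than two standard deviations
above the mean — the candidate specificity-determining positions.

A thin command-line front end lives in `inst/scripts/himsa.R`
(`run`, `align`, `partition`, `weights`, `delta-bild`, `render`,
`simulate`, `mdl-selftest`).

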