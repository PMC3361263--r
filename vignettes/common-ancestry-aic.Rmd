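---
title: "Testing common ancestry of two gene families by AIC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing common ancestry of two gene families by AIC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancestryAIC)
```

## The question and the test

Given two gene families -- say the mitochondrial *cytb* and *nd2* genes
sampled from cow, deer and hippopotamus -- did they descend from one
common ancestral sequence, or do they have independent origins? The
package frames this as model selection between two fixed-topology
phylogenetic hypotheses:

* **Independent origins**: two disjoint unrooted 3-tip trees, one per
  family, with no branch connecting them (6 branch lengths in total).
* **Common origin**: a single unrooted 6-tip tree in which the two
  `((cow, deer), hippo)` subtrees are joined by one central branch
  (9 branch lengths).

Each hypothesis is fitted by maximum likelihood under a battery of
substitution models, and the hypotheses are compared by the Akaike
information criterion, `AIC = 2k - 2 lnL`, where `k` counts every free
parameter (branch lengths, substitution parameters, the gamma shape and,
by default, data-estimated frequencies). Lower AIC wins; ties are
resolved toward independent origins.

The scientific point of the package is *diagnostic*, not affirmative:
the machinery makes it easy to show how two demonstrably unrelated
families can nevertheless be assigned a common origin -- through
alignment (which by construction assumes homology) and through shared
composition bias.

## Likelihood machinery

Likelihoods are computed by Felsenstein's pruning algorithm over
compressed site patterns, with per-node rescaling of conditional
likelihoods. All models are time-reversible, so the likelihood is
invariant to the rooting used for the computation (the test suite checks
this, along with exact agreement with brute-force summation over
internal-node states on small trees).

Rate matrices are built as `Q[i,j] = s[i,j] * pi[j]` from a symmetric
exchangeability table `s` and stationary frequencies `pi`, normalised so
that branch lengths are expected substitutions per site. Nucleotide
families: JC, K80, HKY, GTR (GTR's `G<->T` exchangeability is fixed to 1,
leaving 5 free). Protein families: Poisson, JTT, mtmam; the JTT and mtmam
tables are the canonical published values (as distributed with phangorn,
in the standard PAML residue order). `+F` replaces an empirical model's
frequencies with observed proportions (erroring, rather than silently
pseudocounting, when a residue is absent); HKY/GTR always use observed
proportions. `+G` adds Yang's discrete gamma with 4 equal-probability
categories by default, each category rate being the mean of its slice.

Transition probabilities use the symmetric eigendecomposition of
`diag(sqrt(pi)) Q diag(1/sqrt(pi))`, cached per rate matrix.

### Optimisation

`maximizeLikelihood()` follows a PAML-like deterministic scheme: cyclic
coordinate ascent with a Brent line search per branch length (bounded in
`[0, 50]`) and a bounded quasi-Newton step over the log-transformed
substitution parameters (`alpha` bounded in `[0.005, 100]`), starting
from JC-corrected p-distance branch lengths, `kappa = 2`, `alpha = 0.5`.
Pure coordinate ascent converges quickly to within a fraction of a log
unit but then zigzags along the correlated branch-length/shape
directions, so after a few cycles the implementation inserts a joint
bounded quasi-Newton pass over *all* log-scale parameters and then
verifies convergence with further cycles (declared when a full cycle
gains less than `tol`, default `1e-6`). In cross-checks the optimum
matches or exceeds the one found by `phangorn::optim.pml` on the same
data. For AIC comparisons read at 0.1 resolution, `tol = 1e-4` is ample
and noticeably faster; the examples and tests use it.

### Parameter counting

Whether PAML-style empirical frequencies count toward `k` is genuinely
ambiguous in practice, so it is a switch (`countFreqs`, default `TRUE`:
3 for HKY/GTR, 19 for `+F`). The independent-origins fit uses separate
substitution parameters per family by default (two fits, summed), with
`sharedParams = TRUE` available to share them. This choice matters more
than it looks, as shown below.

## The aligner

`progressiveAlign()` is a Clustal-like progressive aligner: a UPGMA
guide tree from pairwise Gotoh-alignment p-distances, then
profile-profile Gotoh merges with sum-of-pairs column scores. Affine gap
runs cost `gop + (len - 1) * gep`; terminal gaps are penalised like
internal ones; traceback ties break deterministically
(diagonal > up > left). Default scores: match 1.9 / mismatch 0 for DNA
(with Clustal's default `(GOP, GEP) = (15, 6.66)`), BLOSUM62 for protein
(default `(10, 0.1)`). It deliberately does *not* reproduce Clustal W's
sequence weighting or position-specific penalties -- the analyses here
need the gap-penalty *trend*, not bit-identical output, and a true
Clustal alignment can be brought in through `importAlignment()`.

Before likelihood fitting, every column containing a gap is removed
(`stripGapColumns()`), mirroring complete-data (`cleandata`) analysis;
that is why aligned datasets shrink below the input length as penalties
fall.

## The homology statistic

`homologyStat()` reports `1 - mean p-distance` between the two families,
by default over all cross-family pairs (9 for two 3-taxon families);
`"sameTaxon"` restricts to the 3 same-taxon pairs. For unaligned
equal-length input the pairing is 1:1 by site. For two unrelated
sequences with compositions `f` and `g` its expectation is
`sum(f * g)` (`expectedRandomIdentity()`): 0.25 for uniform DNA, 0.05
for uniform protein. Values materially above that are what a finite
central branch can exploit.

## The simulator

`simulateCommon()` evolves one root (drawn from the model's stationary
frequencies) down a 6-tip tree; `simulateIndependent()` evolves two
roots independently down two 3-tip trees. A single seeded generator is
threaded through all draws in a documented order (root sites, then
edges in cladewise order; family A entirely before family B), so a seed
fully determines the output.

Defaults emulate the standard mitochondrial setting: 1,038 sites, taxa
`(cow, deer, hippo)` with topology `((cow, deer), hippo)`, tip branch
lengths 0.1/0.05/0.15 (a placeholder of realistic magnitude for these
taxa), cherry-internal branches 0.05, and a central branch of 0.5 for
the common-origin scenario. Composition bias follows the heavy-strand
pattern of mammalian mitochondrial protein genes: codon position 2
T-rich (`T = 0.45`), position 3 A-rich and G-poor (`A = 0.45`,
`G = 0.04`), position 1 uniform, implemented as three interleaved site
classes each evolving under an HKY-style generator (`kappa = 8`, a
realistic mitochondrial transition bias, chosen once) with the class
frequencies as target; the class frequencies also supply the root draws.
This captures a *mutational/compositional* correlation between
unrelated genes, which is the mechanism under study -- not selective
convergence.

What the simulator does not emulate: indels (the no-alignment analyses
have none), codon structure beyond position-wise composition (stop
codons can arise, so protein-level experiments should simulate amino
acids directly), selection, and lineage-specific composition drift.
Passing tests on these simulations therefore validate the machinery and
the compositional mechanism, not every property of real mitochondrial
data.

## What the simulations show about the test itself

Two structural effects are worth spelling out, because the test suite
asserts both:

* **Nesting direction.** For models with no free substitution
  parameters (JC, Poisson) the independent-origins fit is exactly the
  common-origin fit with the central branch pushed to infinity, so
  `lnL(common) >= lnL(independent)` always, and AIC hinges on whether
  the likelihood gain of the finite central branch repays 3 extra
  branch parameters.
* **Parameter-count asymmetry.** With separate per-family substitution
  parameters (the default), the independent hypothesis carries roughly
  twice the substitution parameters of the common one. For richly
  parameterised models such as GTR+G under `countFreqs = TRUE`, the
  expected chance improvement of those extra parameters (about half
  their number, by the usual chi-squared argument) is *smaller* than
  their AIC cost, so on truly unrelated, identically distributed
  families the comparison tilts toward "common origin" before any
  compositional signal enters. The false-preference experiments
  therefore also report the `sharedParams = TRUE` variant, where the
  two hypotheses differ by the 3 central-topology branches only and the
  compositional effect is isolated.

## Numerical choices and edge cases

* Ambiguity codes (N, X) are rejected on input rather than treated as
  missing data; the likelihood engine assumes complete data.
* Zero-width alignments (everything gapped) are refused downstream.
* Optimiser excursions into regions where some site pattern gets
  numerically zero probability are treated as very bad (-1e12), not
  fatal.
* AIC values are printed to 1 decimal as is conventional; comparisons
  use full precision. Exact AIC ties prefer independent origins and are
  conservative toward skepticism of common ancestry.
* Problem sizes used in the checks: parameter recovery at 1e5 sites
  (kappa within 5%, alpha within 20%), decision checks at 5,000 sites,
  false-preference batches of 20 replicates at 1,038 sites -- sizes at
  which the relevant effects are comfortably resolved.

## Limitations

The package does not search topologies, model indels or rate variation
across lineages, or implement statistical alignment (joint estimation
of alignment and phylogeny); it fixes the vertebrate mitochondrial
genetic code for translation. The aligner is Clustal-*like*, so column
counts at a given `(GOP, GEP)` need not match Clustal W's exactly.
Reproducing published AIC tables for the real cow/deer/hippo *cytb* and
*nd2* sequences requires those GenBank coding sequences as input
(`readFasta()` + `trim5Prime()` + `translateMito()`); they are not
distributed with the package.
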