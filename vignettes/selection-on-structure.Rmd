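---
title: "Testing for lineage-specific selection on RNA secondary structure"
author: "SSStest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for lineage-specific selection on RNA secondary structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most long non-coding RNAs show little sequence conservation, so classical
sequence-level selection tests have low power on them. When the molecule's
function depends on its secondary structure, however, the structure itself
can be treated as the phenotype: an excess of mutations with unexpectedly
*large* structural impact in one lineage is evidence of positive
(adaptive) selection on the structure, while an excess of mutations with
unexpectedly *small* impact indicates negative selection. This package
implements a test built on that idea, together with the synthetic
benchmark and the shuffle-based false discovery rate machinery needed to
exercise it without any external data.

There is no synonymous/non-synonymous dichotomy in non-coding RNA, so no
Ka/Ks-style ratio is available; the test instead quantifies the
*structural effect size* of each observed change against an empirical
null model.

## The test

The input is a multiple sequence alignment of orthologous RNA sequences,
one per species (at least three). Each species is tested in turn as the
**focal sequence** `x`:

1. **Background and consensus.** The focal row is removed; the remaining
   rows form the background alignment. Its per-column consensus (modal
   character, gaps counted as characters, ties broken `A < C < G < U`
   with the gap losing all ties) is the proxy for the ancestral state. A
   column is **well-conserved** when at least 60% (configurable) of the
   background agrees with the consensus; only well-conserved columns
   carry usable signal about lineage-specific change, so variants are
   called only there.
2. **Variant calling.** Differences between the focal row and the
   consensus are substitutions where both carry a base; runs of focal
   gaps under consensus bases are one merged **deletion** event, focal
   bases over consensus gaps one merged **insertion** event, independent
   of length — the thermodynamic cost of a loop changes only slowly with
   its size, so event count, not length, is what matters. An indel event
   is scored if at least one of its columns is well-conserved.
3. **Compensatory filtering.** A substitution that sits in a base pair
   present both in the focal MFE structure and in the background
   consensus MFE structure replaced one pair type by another without
   structural consequence (e.g. G–C to A–U); such sites carry no
   structural signal per se and are removed before scoring (both members
   of a doubly substituted pair).
4. **Substitution impact.** Each remaining substitution is applied to
   the ungapped background consensus and its base-pair probability
   matrix is compared with the wild type's over the **region of maximal
   structural discrepancy**: the contiguous interval (at least 20 nt by
   default) maximising the length-normalised Euclidean difference of the
   two matrices. The same exchange is applied at a uniformly chosen
   position carrying the same source base in `N` random sequences of the
   same length and GC content (`N = 200` by default), and the p-value is
   the add-one rank `(1 + k)/(N + 1)` of the observed discrepancy in
   that null sample — never exactly zero. Null sequences are uniform
   permutations of the wild type's own bases: random sequences matching
   length and GC content exactly (indeed the full base composition),
   hence exchangeable with the wild type given its composition, so the
   p-value is exactly uniform under the null — an i.i.d. null at the
   same expected GC would mix over compositions and squeeze the
   p-values away from both tails.
5. **Indel impact.** An indel of length `l` is slid over every position
   of the consensus (a placement ensemble of `L - l + 1` deletions or
   `L + 1` insertions). For each placement the unconstrained fold is
   compared, by unit-cost tree edit distance on the usual forest
   encoding of RNA structures, with the fold constrained to keep every
   consensus MFE pair not affected by the indel. The observed placement
   is ranked within the ensemble (`p_rank = r/n`, ties to the worst
   rank) and its relative impact scored as
   `p_struc = (4L - delta)/(4L)`, clamped below at `1/(4L)`; the
   complete p-value is `min(1, p_rank + p_struc)`.
6. **Correction and aggregation.** Substitution and indel p-values are
   corrected for multiple testing (Benjamini–Hochberg step-up by
   default, Bonferroni optionally) as two separate sets, mirroring the
   separate aggregation of the two scores; a joint correction is
   available behind a flag. The substitution score is
   `s = -sum(log p~)`, the indel score `s'` likewise, and the decision
   statistic is the **SSS-score** `2 s + s'` — the factor 2 is the
   empirically determined weighting of the substitution evidence.
7. **Decision.** A family is first screened by **family divergence**:
   for each species, its base-pair probability matrix (projected to
   alignment columns) is compared with the alignment's consensus matrix
   over the shared, species-unique and absent pair sets, scaled to
   `100/n_cols`; the family divergence `d` is the species median. With
   `d <= 10` (a structurally uniform family), an SSS-score `>= 10` is
   called **positive**, `<= 2` **conserved**, anything between
   **intermediate**; with `d > 10` no call is made. These cutoffs were
   calibrated on closely related species (primates) and are
   configurable — for more distant taxa they should be re-examined, and
   a relaxed positive cutoff of 4.5 is sometimes useful for candidate
   screening.

```r
library(SSStest)
fam <- readFamily("family.fa")
report <- runFamily(fam, runConfig(seed = 1), family_id = "family")
reportTable(report)
```

## Folding engine

All thermodynamic quantities (MFE and constrained MFE structures,
ensemble free energies, centroids, base-pair probability matrices,
alignment consensus structures, span-restricted local structures) are
delegated to the ViennaRNA programs `RNAfold`, `RNAalifold` and
`RNALfold`, invoked in batches and parsed from their documented output
(pair probabilities from the `i j sqrt(p) ubox` records of the dot-plot
files). Folding temperature defaults to the engine's 37 °C and is
recorded, along with the engine's version string and every configuration
value, in the metadata of each report, so a run is reproducible
bit-for-bit. Gapped alignment rows are never folded directly: each
species' ungapped sequence is folded and its matrix projected onto
alignment columns through the row's coordinate map (gap columns carry
zero probability). Pseudoknots are outside the model.

Coordinates are 1-based closed intervals internally — the R/Bioconductor
convention — and reports print 1-based inclusive positions; the only
0-based output is the BED-like block table of the command-line
front-end.

## Local structures of long RNAs

Base-pairing interactions in long RNAs occur mostly within a short span,
so selection is sought on local structural modules rather than global
folds: `localFold()` (maximum pair span 200 nt by default) proposes
locally stable structures per species, candidates with fewer than three
pairs are dropped as noise, the most stable mutually non-overlapping
ones are kept greedily, and structures from different species whose
start positions — projected to alignment columns — differ by at most 30%
of the shorter member's length are grouped into **blocks** by single
linkage (so membership does not depend on species order). Blocks with at
least three species are screened by family divergence and scored like
ordinary families. The 30% rule is applied in alignment columns, which
is what makes starts comparable across species.

## The synthetic benchmark

`generateFamilies()` evolves ortholog families *in silico* from a random
150-nt ancestor (length configurable) by proposing uniform single-base
substitutions and accepting them with a Metropolis rule (temperature 1)
on a regime-specific objective, until `n` proposals have been accepted
(`n` = 5 or 10 in the reference experiments; 100 families per
condition):

* **negative selection** — `1000 (Δ_centroid + ε)`: any base-pair
  distance between the ancestral and current centroid structures, or a
  loss of more than half the ancestral stability (the `ε` term), is
  penalised so hard that structure-breaking moves are effectively
  rejected;
* **random drift** — the objective is constant 0: every proposal is
  accepted, no folding needed;
* **positive selection** — `gibbs(m) + 50 Δ_shape5(target, m) + 1000 ε`:
  pressure towards a cloverleaf target shape `[[][][]]` (level-5
  abstract shape of the centroid) and towards a stable ensemble, from a
  Y-shaped ancestor (level-5 shape `[[][]]`).

Experiment 1 evolves one ancestor into five extant branches (a star
phylogeny) and probes family divergence; experiment 2 evolves a single
branch and keeps four ancestral copies, emulating lineage-specific
change, and probes the SSS-score. Y-shaped ancestors are plain random
sequences rejection-sampled on their centroid shape (several percent of
random 100-mers qualify); conditioning on the shape but not on
stability matters, because a template-designed Y with saturated stems
sits in so deep an energy well that the positive-selection walk can
only find structurally silent moves. The acceptance rule itself is a
design choice here — the objectives define the regimes, and Metropolis
at T = 1 realises the "hard penalty" intent — and both the rule and the
temperature are configurable.

The generator makes no claim of biological realism: no indel evolution,
no phylogenetic tree shapes beyond the star, substitutions only (the
families it returns are therefore already aligned). Tests passing on
these data show that the statistic separates the regimes it was designed
to separate, not that it is calibrated for any particular genome.

## False discovery rate

The shuffle null preserves per-column character multisets and every
row's gap pattern exactly (columns are permuted within groups of equal
gap pattern) while destroying the column covariation that carries
structural signal. With `F` positives on real families and `R` on their
shuffles, `FDR = R/F`; because shuffling does not always destroy the
signal, the fraction `f` of foreground positives whose shuffles stay
positive (20 independent randomisations by default) refines this to
`(1 - f) R/F`. The column-permutation shuffle preserves conservation but
not dinucleotide content; where a dinucleotide-preserving external
shuffler is available it can be substituted upstream, since the
estimators only consume counts.

## Numerical choices and degenerate inputs

* Natural logarithm in the score aggregation (configurable base).
* `p_rank + p_struc` can exceed 1 and is clamped to 1 before correction,
  keeping scores non-negative.
* Discrepancy-region ties go to the shortest, then leftmost interval;
  identical matrices return the full sequence with discrepancy 0.
* Consensus ties are broken deterministically (`A < C < G < U`, gap
  last); rank ties among indel placements take the worst rank
  (conservative).
* Constrained folds drop consensus pairs whose remapped span falls below
  the minimal hairpin span after a deletion — they count as affected by
  the indel; enforced pairs are validated (complementary, non-crossing,
  disjoint) before the engine is called.
* All-gap columns are kept everywhere (consensus folding leaves them
  unpaired), so column indices are stable across focal choices.
* A family of identical sequences has no variants and scores exactly
  zero with divergence numerically near zero.
* Seeds fan out to families and focal species by a stable string hash,
  so results are independent of processing order and any family can be
  reproduced in isolation.
* The `N` random null sequences of one focal sequence are shared across
  its substitutions (each mutated independently per substitution); the
  p-values remain marginally valid and the step-up correction does not
  require independence.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the method end to end
at reduced replicate counts chosen to keep a full run on a single CPU
comfortable: 100 sequences of 80 nt with 100 null samples for the null
calibration; 30 + 30 families (100 nt, 10 accepted substitutions) for
the divergence separation; 20 + 20 one-branch families with 40 null
samples for the score separation (the acceptance script uses 12 + 12
and 8 + 8); 50 random indel ensembles for the p-value bounds. The
separation experiments are statistical properties and are asserted
through one-sided Mann–Whitney tests at α = 0.05 rather than as point
values.

## Known limitations

* Secondary structure prediction is imperfect; false positives are
  unavoidable and candidates warrant experimental follow-up.
* The indel placement model is deliberately simple (rank plus relative
  impact); it is a heuristic, not a likelihood.
* The tree edit distance is a clean-room unit-cost implementation;
  per-family scores obtained with other structure-comparison tools are
  approximated, not reproduced bit-exactly.
* Paralogs inadvertently included in a family can mimic positive
  selection; alignments should be inspected.
* With fewer than three orthologs the test is undefined (a pairwise
  variant would not distinguish which lineage changed).
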