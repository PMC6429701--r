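# SSStest

Detection of lineage-specific selection on RNA secondary structure.

## The problem

Long non-coding RNAs (and many other ncRNAs) conserve their secondary
structure far better than their sequence, so sequence-level selection
tests have little power on them — and no Ka/Ks-style test exists because
non-coding RNA has no synonymous/non-synonymous dichotomy. When structure
is the phenotype, selection leaves a different footprint: a lineage under
**positive selection** accumulates substitutions and indels whose
structural impact is unexpectedly *large*, while **negative selection**
keeps the impact unexpectedly *small*. This package implements a
statistical test built on that idea, for anyone with a FASTA file of
orthologous RNA sequences (one per species, at least three) who wants
per-lineage selection calls: evolutionary genomicists screening lncRNA
catalogues, RNA biologists examining a locus of interest.

## The statistic

For a focal sequence *x* in an ortholog alignment, with background
consensus *z̄* (well-conserved columns only, 60% agreement by default):

* every non-compensatory substitution *z̄* → *x* gets an empirical
  p-value *pᵢ* for the discrepancy of base-pair probability matrices
  over the region of maximal structural change, against the same base
  exchange in *N* = 200 random sequences of the same length and GC
  content;
* every merged indel gets *p* = min(1, p_rank + p_struc), where p_rank =
  *r*/*n* ranks the observed placement's tree-edit impact δ(φ, ψ) among
  all *n* placements of the indel along *z̄*, and p_struc =
  (4ℓ − δ)/4ℓ (clamped at 1/4ℓ) scores its relative magnitude;
* after Benjamini–Hochberg correction (separately per set),
  *s*(x) = −Σ log p̃ᵢ over substitutions, *s′*(x) likewise over indels,
  and

  **SSS-score(x) = 2 s(x) + s′(x)**.

Families are screened by structural family divergence *d* (median over
species of a 100/L-scaled comparison of species vs consensus pair
probabilities); with *d* ≤ 10, SSS-score ≥ 10 flags positive selection
and ≤ 2 conservation. All thermodynamics come from the ViennaRNA
programs, which must be on the PATH.

## Worked example

Simulate a one-branch benchmark family — one lineage (`derived`) evolved
from a Y-shaped ancestor under selection towards a cloverleaf structure,
four lineages keeping the ancestral sequence — and test every species:

```r
library(SSStest)

fams <- generateFamilies("pos", n_families = 3, n_accepted = 10,
                         seq_length = 100, experiment = 2,
                         seed = 20240611)
rep <- runFamily(fams[["fam003"]],
                 runConfig(null_samples = 40, seed = 20240609),
                 family_id = "fam003")
reportTable(rep)
```

```
 family_id     species n_subst n_indel n_compensatory s_sub s_indel sss_score
    fam003     derived      10       0              0  4.48       0      8.97
    fam003 ancestral_1       0       0              0  0.00       0      0.00
    fam003 ancestral_2       0       0              0  0.00       0      0.00
    fam003 ancestral_3       0       0              0  0.00       0      0.00
    fam003 ancestral_4       0       0              0  0.00       0      0.00
   d_s family_d        label
 32.71     4.63 intermediate
  4.63     4.63    conserved
  4.63     4.63    conserved
  4.63     4.63    conserved
  4.63     4.63    conserved
```

Reading the output: the ten substitutions of `derived` have corrected
p-values small enough to aggregate to s = 4.48, hence SSS-score 8.97 —
just short of the strict positive cutoff of 10, and well above every
ancestral lineage (score exactly 0, labelled conserved); with the
relaxed screening cutoff of 4.5 (`runConfig(positive_cutoff = 4.5)`)
the derived lineage is called positive. The family divergence (4.63,
the median of the per-species d_s) is below 10, so selection calls are
made; the derived lineage's own d_s of 32.7 shows how far its structure
moved away from the family consensus.

Other entry points: `familyBlocks()`/`screenBlocks()` decompose long
RNAs into orthologous local-structure blocks before testing;
`generateFamilies()` simulates families under negative, neutral or
positive structural selection; `fdrAnalysis()` estimates the false
discovery rate by column-shuffling. A thin command-line front-end with
subcommands `score`, `blocks`, `simulate` and `fdr` is installed under
`exec/ssstest`. The methods vignette
(`vignettes/selection-on-structure.Rmd`) documents the model,
parameters and limitations.

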