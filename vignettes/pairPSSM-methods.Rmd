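---
title: "pairPSSM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pairPSSM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairPSSM)
```

## The problem

Interolog mapping infers that two proteins A' and B' interact because they
are homologous to the two chains of a dimer of known three-dimensional
structure. Plain sequence-level transfer fails in a characteristic way: a
protein can be globally similar to a template chain yet lack the particular
region that forms the interface, in which case the inferred interaction is
spurious. pairPSSM addresses this by scoring candidates *at the interface
contact positions of the template*, with position-specific score tables
learned from evolutionary profiles, instead of (or in addition to) a single
generic 20 x 20 contact potential.

## The model

**Contacts.** A contact residue pair of a two-chain template is a residue
from each chain with at least one pair of heavy (non-hydrogen) atoms within
4.5 Å (inclusive; the constant is `cutoff` in `extractContacts()`). The R
contact pairs, in order, are the *contact positions* of the template.

**Template quality control.** A template is usable when its resolution is
strictly below 3.0 Å, both chains are longer than 35 residues, it has more
than 25 contact pairs and each chain contributes more than 5 distinct
contact residues. All four comparisons are strict, following the usual
wording of such criteria ("smaller than", "more than"); `qcTemplate()`
reports each check. A missing resolution fails by default
(`missingResolutionPasses = FALSE`), since an unknown experimental quality
should not silently pass.

**Profiles and pairing.** Each chain carries a multiple sequence alignment
with the chain itself as template row. Rows more than 95% identical to the
template are purged; identity is computed over columns where both rows are
non-gap, divided by the shorter ungapped length (the denominator is not
dictated by the method's definition; this choice makes fragments count
against their own length). Because the observed quantity is a residue
*pair*, rows of the two alignments must be paired: we pair rows sharing a
source-organism key, keep the row with fewest gaps when a key is duplicated
within one alignment, and always pair the two template rows with each other
(the template's own contact pair is an observation). Any row pairing rule
satisfying "one joint observation per row pair" would do; organism pairing
is the natural default when profiles come from an organism-tagged database
search.

**Counting with a reduced alphabet.** At a contact position, the residue
pair of each paired row is tallied as a single symbol. By default the
symbol is the ordered pair of *groups* under a nine-group amino-acid
classification, so conservative substitutions (Leu for Ile, Asp for Glu)
accumulate in one symbol. Two classifications ship with the package: the
structure-environment scheme of Saha and colleagues, and a modified scheme
(Ala+Gly; Val+Met+Leu+Ile; Pro+Ser+Thr; Phe+Tyr+Trp; Cys; His+Arg; Lys;
Asp+Glu; Asn+Gln). The modification is justified empirically:
`groupSdTable()` computes the population standard deviation of the
empirical contact potential within each group pair, and the modified scheme
keeps every cell's spread below 0.4 for a potential with group-coherent
structure, whereas the original scheme does not (`compareSchemes()` shows
both tables side by side). Population (divide-by-N) SD is used because the
quantity is the descriptive spread of a small finite cluster, not an
estimate of a larger population's variance. A `scheme = "raw"` mode counts
residue-level pairs without pooling, for comparison.

**Scores.** For contact position r with observed-frequency table `f` over
symbols, the score of an ordered residue pair (x, y) (chain-A residue
first) is

    score_r(x, y) = ln( Q_xy / (P_x P_y) ),
    Q_xy = (alpha * f_xy + beta * g_xy) / (alpha + beta),
    g_xy = P_x P_y exp(S_xy),

where `S` is the empirical interfacial pair potential, `P` the interface
background composition, `alpha` = (number of distinct observed symbols in
the column) - 1, and `beta = 5`. This is the data-dependent pseudocount
construction: with a single observed symbol (`alpha = 0`) the score
reduces *exactly* to `S_xy`, so with no profile information the pairPSSM
degenerates to the general empirical matrix — the anchor identity tying
the two scoring systems together, asserted to 1e-12 in the tests. The
natural logarithm is the default (`logBase` is configurable); the base
rescales all energies uniformly and cancels from the normalized score.

Score tables are stored as full 20 x 20 matrices per position (R x 400
numbers). A partner-fixed 20-column slice — the table restricted to the
template's residue on one side — can be read off directly when a compact
R x 20 view is wanted.

**Energies and classification.** For a candidate pair with alignments to
the two template chains, the *specific interfacial energy* is the sum of
`score_r(x_r, y_r)` over the contact positions where both sides are
aligned; unaligned positions contribute zero. The *general interfacial
energy* is the same sum taken from `S`. The *normalized* specific energy
divides by the template's self-score (the template scored against itself),
which makes templates of different sizes comparable and, because unaligned
positions contribute nothing, penalizes candidates missing the interface —
the failure mode that motivates the method. A candidate is called a
homologous interaction when its normalized energy is at least 0.4
(inclusive; 0.5 is the stricter setting recommended for large
multi-organism screens). Summing only over aligned positions (rather than
imposing an explicit gap penalty) is a deliberate choice: the
normalization already converts missing coverage into a proportional score
reduction, and any additional penalty would be an uncited free parameter.

**Related dimers and pair coverage.** Whether two dimers realize the same
interaction type is quantified by pair coverage,
`PC = NCP_M^2 / (NCP_AB * NCP_A'B')`, the number of contact pairs matched
under per-chain residue correspondences, squared, over the product of the
two interface sizes. `PC >= 0.4` (inclusive — the boundary value appears
in both strict and non-strict phrasings in the literature, and we take the
inclusive reading) is the working definition of "same interaction type".
Representative selection within a structure cluster takes, among members
with more contact pairs than the cluster mean, the one with the best
resolution; when no member exceeds the mean the best-resolution member
overall is taken, with lexicographic id as final tie-break (the filter
rule is silent on this degenerate case).

**Evaluation.** Ranked screens are summarized by average precision
`AP = (1/A) sum_i i / T_i` and the false-positive mass
`FP = (1/A) sum_i (T_i - i)/(K - A)`, with `T_i` the rank of the i-th
positive among K candidates, averaged over templates (MAP, MFP). Ties in
the ranking place negatives first by default, so reported AP is a lower
bound (`tieRule = "optimistic"` flips this). Unannotated candidates can be
counted as negatives or dropped — both treatments are meaningful and both
are exposed. The balanced error rate at a threshold averages the
false-negative fraction of positives and the false-positive fraction of
negatives; the widely-quoted alternative phrasing that divides false
positives by the positive count is internally inconsistent and is kept
only behind `literal = TRUE`. The expression-profile check uses Pearson
correlation on pairwise-complete observations and a one-sided Welch
two-sample t-test ("standard two-sample t-test" leaves the
equal-variance question open; Welch is the safer default), excluding
self-pairs whose correlation is 1 by construction.

## The bundled potential

The 20 x 20 interfacial potential and interface composition under
`inst/extdata/` are **synthetic**, generated by `data-raw/make_potential.R`:
residue-pair energies are drawn around nine-group contact energies
(hydrophobic packing, aromatic stacking, salt bridges, like-charge
repulsion, disulfide pairing) with 0.08 within-group jitter, and the
composition is a realistic interface composition summing to one. The
synthetic matrix reproduces the *structural* property the grouping relies
on — small within-group spread under the modified scheme, large under the
unmodified one — but its absolute values are not a published potential.
For production use, supply a published interfacial statistical potential
and its matching composition as the two TSV inputs of `loadPotential()`;
every downstream computation is unchanged.

## The synthetic-data generators

`fixtureSpec()` fixes the study conditions for all generators:
40-residue chains with 30 engineered contacts (comfortably past the QC
thresholds), 50 paired profile rows, within-group substitution rate 0.3
and across-group rate 0.05 at contact columns (interfaces evolve mostly
conservatively), uniform substitution rate 0.3 at non-contact columns
(free drift; this also keeps simulated rows below the 95% purge), and a
screening benchmark of 20 positives and 20 negatives with 70% interface
ablation.

`makeToyDimer()` places residues (backbone + CB) on a lattice with
explicit separation margins: designed contact pairs sit at minimum atom
distances of about 3.4-3.7 Å, every other inter-chain atom pair beyond
5.5 Å, so extraction at 4.5 Å recovers exactly the designed set and the
oracle comparison is sharp. `makePairedMsas()` applies the substitution
model above with consistent organism keys across the two files.
`makeScreenBenchmark()` emits positives that conserve the interface up to
within-group substitution, and negatives with exactly
`round(0.7 * R)` contact positions ablated — each ablated position is,
with equal probability, left unaligned on one side (the
missing-interacting-domain pattern) or mutated across groups (a generic
but position-wise wrong interface, which the general potential tends to
tolerate and the pairPSSM does not). The expected normalized energy of a
negative is therefore near the unablated fraction (~0.3), below the 0.4
threshold, while positives stay near 1; the exact (rather than
binomial) ablation count is part of the stated conditions, not a tuning
knob. All generators are pure functions of their spec: identical seeds
give byte-identical files, and the caller's RNG stream is left untouched.

What the generators do *not* emulate: real folds, side-chain geometry,
phylogenetic correlation between profile rows (rows are i.i.d. given the
template), alignment errors, and the long-tailed homology structure of a
real proteome. Passing the synthetic screens therefore demonstrates that
the statistical machinery is implemented correctly and that the decision
boundary behaves as designed under the stated conservation model — not
that the same numbers would be obtained on PDB-scale data.

## Numerical choices and degenerate inputs

* Altloc atoms: the highest-occupancy conformer is used (ties: first
  altloc code alphabetically); multi-model files use the first model.
  These cases are not covered by the method's definition; both policies
  are conventional.
* Modified residues map to their parent amino acid when a standard
  mapping exists (MSE to M, SEP to S, ...); anything unmappable is
  skipped with a warning, as are waters and hydrogens.
* Contact-position indices are 1-based in R and 0-based in serialized
  JSON artifacts.
* PairPSSM JSON serialization writes doubles with 17 significant digits,
  which is lossless for IEEE doubles; round trips are bit-exact.
* An empty profile column falls back to `alpha = 0` with a warning; a
  template whose self-energy is not positive cannot normalize and is
  refused with a classed error rather than producing quiet nonsense.
* `pairCoverage()` on an empty interface returns `NA` with a warning
  (undefined, not zero).
* Thresholds at boundaries: the 0.4/0.5 energy threshold and the 0.4 PC
  threshold are inclusive; the 95% purge and the identity limit are
  strict (`>` removes).

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
templates of 40+40 residues with R = 30, profiles of 50 rows, benchmarks
of 20+20 candidates, and 10 replicate screens. These sizes keep the whole
suite under a minute while leaving the statistical checks (recovery rates,
substitution-rate calibration, p-value uniformity) well-powered.

## Known limitations

* Candidate alignments are consumed, not computed: the package does not
  run PSI-BLAST or structural alignment, and the quality of the scores is
  bounded by the quality of the supplied alignments.
* The row-pairing rule assumes a meaningful shared key between the two
  profiles; profiles without such keys degrade to the template-only
  (pure pseudocount) limit.
* Scores at a contact position treat the position independently;
  correlations between interface positions are not modelled.
* The bundled potential is synthetic (see above); headline numbers from
  PDB-era screens are not reproducible from this package alone.
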