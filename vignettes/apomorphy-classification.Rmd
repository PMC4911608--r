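---
title: "Hierarchical apomorphy-based classification: model, screening and identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical apomorphy-based classification: model, screening and identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoclass)
```

## The idea

Classical DNA barcoding assigns a specimen to a species by sequence
similarity at one locus; it gives a single level of resolution and no
information about relationships among barcodes. `apoclass` implements the
alternative: a *hierarchical, character-based* classification in which every
clade of a fixed reference phylogeny is described by one (or a few)
diagnostic amino-acid apomorphies — derived states inherited from the
clade's common ancestor — and every terminal category's full description is
the ordered concatenation of the codes along its root-to-leaf lineage. A
barcode is then a string such as

```
T_00_I_02_G_03_E_06_R_08_S_09_C_0B_
```

a sequence of `(state, ID)` pairs. The final pair is the clade's own
diagnostic code; everything before it is the *hierarchical prefix*, so an
ancestor's barcode is by construction a prefix of every descendant's, and
two terminals are sisters exactly when their prefixes agree and only the
last code differs. Identification of an unknown transcriptome is a walk
down this trie.

## Mining: parsimony with DELTRAN on a fixed topology

Apomorphies are mined per alignment column by unit-cost (Fitch) parsimony
on the fixed rooted tree. The engine computes, for each column:

* the **parsimony length** `s` — the minimum number of state changes;
* the exact **MPR set** of every node — the states it takes in at least one
  most-parsimonious reconstruction;
* a deterministic **DELTRAN** assignment — among all most-parsimonious
  reconstructions, changes are placed as close to the tips as possible.

Missing symbols are non-constraining: a leaf showing `X` (missing residue),
`-` (gap) or `?` (missing gene) accepts any state at zero cost and never
contributes to the length. The three symbols are kept distinct in storage
because the identification stage reports their provenance, but parsimony
treats them identically; this is our explicit policy for a step the
upstream tooling ecosystem leaves unspecified.

Implementation notes, where the design was genuinely open:

* **Exact dynamic programming rather than set-intersection Fitch.** The
  classical down-pass (iterated pairwise intersection/union) is not
  guaranteed minimal on multifurcating nodes. We instead run a unit-cost
  Sankoff recursion (`cost(v, s)` = minimal changes in the subtree of `v`
  given state `s`) plus an outside pass, which is exact on polytomies and
  yields the full MPR sets directly: `MPR(v) = {s : cost(v,s) +
  out(v,s) = s*}`. On binary trees the arg-min sets coincide with the
  Fitch down-pass sets, which serve as the "preliminary sets" in the
  tie-break below. Only observed states need be considered: with unit
  costs, a state absent from every leaf can never appear in a minimal
  reconstruction.
* **DELTRAN, concretely.** "Delay transformations" is made deterministic as
  a lexicographic objective: minimize the number of changes; among minima,
  maximize the summed root-to-edge depth of change edges (pushing changes
  tipward); remaining ties prefer the parent's state, at the root a state
  observed in the outgroup, then the alphabetically smallest state. The
  test suite verifies against exhaustive enumeration that this attains the
  true maximum depth sum, i.e. it is an extremal member of the MPR class,
  not merely a heuristic.
* **Ambiguity.** A change is *ambiguous* when either endpoint's MPR set has
  more than one state; ambiguous changes are dropped before any filtering,
  since a clade diagnosis that depends on an arbitrary optimization choice
  is no diagnosis. Changes into the outgroup (or into any node containing
  outgroup leaves) are never apomorphy candidates: polarity comes from the
  outgroup, codes describe the ingroup.

Each surviving change is annotated with its site's **consistency index**
`CI = (k − 1) / s`, where `k` is the number of distinct non-missing states
at the site — the Kluge–Farris minimum conceivable change count for an
unordered character. `CI = 1` means no homoplasy; a state that arises twice
independently gives `CI = 0.5`. The mining ladder filters at
`CI ≥ 1.0 / 0.9 / 0.8`; because the candidate predicate is monotone in the
threshold, the three candidate sets are always nested.

## Screening and code selection

Candidates are screened per clade, in this order:

1. **clade size** — clades sampled with fewer than `min_clade_taxa` leaves
   (default 2) are never coded: a character seen in one specimen is not
   known to be shared by the taxon;
2. **sister overlap** — the derived state must not occur in any non-missing
   leaf of the sister group (at a polytomy, the union of the other
   children), otherwise it may be a plesiomorphy;
3. **missing data** — rejected when the whole sister group, or the whole
   earliest-branching child lineage of the clade, is missing at the site
   (the comparison is then unknowable), or when more than
   `max_missing_fraction` (default 0.5) of the clade's leaves are missing;
4. **uniqueness class** — `unique` (the state occurs nowhere else in the
   matrix: highest priority), `clade_unique` (occurs elsewhere but not in
   the sister group, clade uniform), or `multistate_trend` (exactly two
   states, each uniform within one child subclade — the binary `|T/V|`
   pattern); anything else is rejected as inconsistent.

The screening thresholds deserve a note: the design brief behind this
system says missing taxa should be "limited" and very low-coverage clades
skipped, without numbers. Both are therefore explicit knobs with
conservative defaults, not claims about any particular published value.
Binary trend codes are admitted by the classifier but rarely survive
mining in practice, because a single parsimony change cannot create two
states inside its own clade without making the reconstruction ambiguous;
they matter mostly when candidates are supplied from an external apolist.

Within a clade, accepted candidates are ranked by class
(`unique > clade_unique > multistate_trend`), then fewer missing leaves,
then the breadth of the host gene (taxa with any data in that gene,
descending — broader genes make more checkable codes), then `(gene, site)`
for byte-for-byte determinism. Gene economy — preferring markers already
used by other clades — is applied only on exact rank ties, as a
preference, never a hard constraint. Each clade receives its top
`codes_per_clade` candidates (default 1; redundant multi-code databases
are supported end to end, a node then being judged matched when at least
half of its non-missing codes match).

## Encoding

Coded nodes are numbered in pre-order with consecutive two-character
base-36 IDs (`00 … 0Z, 10 …`), optionally behind a one-letter dataset
prefix (`S01 …` for a secondary, finer-scale database). We emit dense IDs;
sparse IDs are accepted on input because published tables may reserve IDs
for codes that are not shown. The database materializes the designed
barcode of every terminal category and exposes the two-dimensional
presentation (terminals × IDs) used for sequential descriptions. One
published barcode table that ships with the package contains a token whose
ID lost its leading `1` (`X_A_`); the parser normalizes single-character
IDs by restoring that digit, with a message, so the fixture loads
verbatim. Its idiosyncratic clade label "Coleopterodea" is likewise kept
as printed.

## Identification

A query is observed as one token per database code: an amino acid, `X`
(site missing inside a present gene) or `?` (gene absent). The matcher
walks the trie from the root:

* a child **matches** when the observed token is in its designed state set;
* an observed amino acid outside the set is a **mismatch** and excludes
  that branch permanently — no fuzzy matching, since rare variants and
  sequencing errors are exactly what the negative category is for;
* on a **missing** token the walk may descend past the code: a child stays
  viable while some deeper code matches with no non-missing mismatch on
  the way. Codes never observed at all (off-lineage codes of a published
  generated barcode) can veto nothing but also confirm nothing.

The walk descends while exactly one child is confirmable (or exactly one
matches directly); it stops at a terminal, when every child is excluded,
or when several children remain viable — in the last case we stop and
report `unresolved_missing` rather than guess a ranking among them. The
assigned clade is the deepest node whose own code matched non-missing.
Against a known truth the result is categorized as **positive** (right
terminal), **false positive** (wrong terminal), **false negative**
(stopped above the terminal because of missing states on the remaining
path), or **negative** (the truth lineage is contradicted by a mismatch).
A consequence worth stating: masking any strict subset of *internal* codes
of a designed barcode still identifies the terminal (the deeper matches
carry the walk), while masking the *terminal* code yields a false
negative — missing data degrades resolution, never correctness.

```{r fixture}
ev <- evaluate_table1()
glance(ev)
```

The embedded 51-transcriptome fixture reproduces the published outcome —
48 positive, 3 false-negative, no false positives, no negatives — and
every per-row assignment label. The package computes complete matches
itself and finds six generated barcodes identical to their designed
strings; the printed table stars five of them, a bookkeeping quirk we
preserve but do not propagate.

```{r diptera}
db <- db_from_table1()
compact_states(barcode_of(db, "Diptera"))
format_barcode(lineage_prefix(db, "Diptera"))
```

## The synthetic generator: what it emulates, and what not

`simulate_apomorphy_data()` builds the study conditions every stage is
tested under: a known tree (balanced, caterpillar or random ingroup of
`n_taxa` leaves, plus **two outgroup leaves in a basal trichotomy** — two
outgroup edges polarize the ingroup stem unambiguously, where a single
outgroup leaf would leave every stem change MPR-ambiguous); a
gene-partitioned alignment whose background columns are fully conserved,
so planted signal is analytically clean; one planted apomorphy column per
proper ingroup clade (the ingroup root is excluded: its convergent variant
cannot exist, since every leaf outside it is an outgroup leaf adjacent to
the root and the second change collapses); optional homoplasy — with
probability `homoplasy_rate` a planted column gives the derived state to
one extra ingroup leaf, chosen so the derived leaves do not form a clade,
which forces `CI = 0.5` exactly; and the two missing-data processes of
real transcriptomes, whole-gene absence (`?`) and per-residue dropout
(`X`), each with its own probability. Everything is deterministic under a
seed.

Default problem sizes used in the tests — 32 ingroup taxa, 10 genes of 60
columns, one apomorphy per clade — are the scale at which the planted
truth table, the threshold ladder and full-pipeline self-identification
are checked exhaustively. What the generator deliberately does *not*
emulate: realistic substitution processes (rate heterogeneity, codon
structure), alignment error, or orthology misassignment. Passing tests
therefore demonstrate the correctness of mining, screening, coding and
matching — not robustness to upstream inference error, which is outside
this package's scope (tree inference, alignment and orthology prediction
are inputs here).

## Numerical and degenerate-input choices

* Columns are 1-based; partition intervals closed on both ends.
* Invariant columns have undefined CI and carry no apomorphies; they are
  skipped, not errors.
* Polytomies are accepted as hard polytomies everywhere.
* Taxa present in the tree but absent from the matrix are pruned by
  default (`on_extra = "error"` to refuse instead); matrix taxa missing
  from the tree are always an error.
* All ties anywhere resolve alphabetically / lexicographically, making
  every pipeline stage reproducible byte for byte.

## Known limitations

* The DELTRAN realization is deterministic and extremal, but other
  parsimony software may break ties differently; apolists mined from the
  same data by other tools can differ at ambiguous sites, which is one
  reason ambiguous changes are discarded.
* With `codes_per_clade = 1` a single rare variant at a coded site turns a
  clade judgment into a mismatch; multi-code redundancy is the supported
  remedy.
* The matcher assumes queries are pre-aligned to the database gene
  alignments; no alignment is computed here.
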