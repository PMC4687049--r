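---
title: "Methods: screening and validating horizontal gene transfer into fishes"
author: "xenoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and validating horizontal gene transfer into fishes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A gene found in teleost fishes but in no other animal, with close homologs
in marine bacteria, is a candidate horizontal gene transfer (HGT). Turning
that observation into a defensible claim requires a chain of evidence, and
each link can fail independently: the phyletic pattern may be an artefact
of database composition, the tree may not actually nest the fish sequences
inside the donor group, the "gene" may be assembly contamination, and the
sequence signature may say nothing about how long the gene has resided in
the recipient genome. `xenoscreen` implements every link of that chain as
a separately testable component, plus a simulator that plants transfers
with known properties so the whole pipeline can be benchmarked offline.

# Screening cascade

Queries (the focal proteome) are compared against an **animal** database
and a **non-animal** database; hits arrive as 12-column tabular files.
A hit survives filtering iff its E-value is at most `e_max` (default
`1e-10`) and one aligned query segment covers at least `min_overlap` of
the query (default 0.33). We interpret *continuous overlap* as the single
longest HSP measured on the query, not the union of HSPs: merging HSPs
would let several short domain matches masquerade as full-length homology,
which is exactly what the overlap filter exists to prevent. Both knobs are
exposed because the per-HSP-versus-summed question is a genuine
free choice in this kind of screen.

Self-hits are removed by subject-identifier match and, when a taxonomy
index is available, by subject-taxon match, since a proteome searched
against a database containing itself always returns itself.

The phyletic profile of a query counts *distinct subject taxa* per
analysis group (`FISH_CORE`, `FISH_BASAL`, `NON_FISH_ANIMAL`, `FUNGI`,
`BACTERIA`, `OTHER_NON_ANIMAL`, and `DONOR_CANDIDATE` as a configurable
subgroup of bacteria, e.g. marine bacteria). A query becomes a candidate
iff it is **fish-restricted among animals** (zero passing non-fish-animal
hits, at least one fish hit — a categorical rule, not a ratio test) and
has at least one passing non-animal hit. The donor group is the non-animal
group holding the best hit, with deterministic tie-breaking (E-value, then
bit score, then lexicographic subject id).

Group membership uses the *most specific configured clade root* on the
path to the taxonomy root, which is what lets a marine-bacterial donor
clade nest inside bacteria. Taxa under no configured root default to
`OTHER_NON_ANIMAL` (configurable to be an error); taxa of genuinely
uncertain placement should be surfaced as errors rather than silently
grouped, so the index builder refuses unknown taxon ids outright.

# Tree-based validation

Validation asks whether the fish sequences *nest inside* the candidate
donor group with strong support. Distances are Poisson-corrected amino
acid distances, d = −ln(1 − p): the correction assumes equal substitution
rates across sites and no back-substitution structure beyond the Poisson
model, which is adequate for the moderate divergences the screen produces.
Gap handling is complete deletion by default (columns with any gap
dropped), with pairwise deletion as an option; p at or above 0.999 is
capped (−ln 0 is undefined) and flagged rather than silently truncated.

Trees are built by the Saitou–Nei neighbour-joining agglomeration.
Negative branch lengths are clamped to zero, and Q-criterion ties break on
the lexicographically smallest label pair so the result is invariant to
input order. Support comes from column bootstrap: resample columns with
replacement, rebuild the NJ tree per pseudoreplicate (1,000 in typical
use; tests use 100–200 for speed), count **unrooted bipartitions**, and
keep splits present in more than half the replicates (strict majority
rule). Supports are attached as internal node labels in percent.
Bipartitions rather than rooted clades are counted because distance trees
are unrooted objects; rooted wording in the literature mixes the two.

The nesting test searches the bipartitions for sides containing every
fish tip plus at least one other member with *all* other members in the
donor group; each such split certifies that the fish sequences nest
inside the donor radiation. The transfer is *validated* when the
best-supported certifying split reaches `support_min` (default 90, the
conventional strong bootstrap threshold). Judging the best-supported
rather than the smallest certifying split is deliberate: how the donor
clade resolves internally (e.g. which donor subclade the fish join first)
is irrelevant to the nesting claim, and a weakly supported split inside
the donor group should not veto a maximally supported enclosing one. Direction is `DONOR_TO_RECIPIENT` in that
configuration; if instead the donor tips are embedded inside a larger
clade of recipient-side eukaryotes, the call is `RECIPIENT_TO_DONOR` (the
signature of a transfer out of eukaryotes); anything else is
`UNRESOLVED`. Because the verdict consumes any tree with node supports,
externally inferred trees (e.g. Bayesian posteriors or ML bootstrap
trees) can be judged by the same rule; likelihood and Bayesian tree
inference are deliberately out of scope here.

The loss-versus-transfer argument is made explicit with Dollo parsimony:
under vertical inheritance the gene is present at the root and every
absence costs an independent loss branch; under transfer the gene is
gained once on the stem of the smallest clade containing the presence set,
plus any losses inside it. The hypothesis with fewer events is preferred;
ties are `UNRESOLVED`. Loss counts are verified in the tests against
exhaustive enumeration of Dollo-consistent labellings on trees of up to
ten tips.

# Contamination checks

Three rules, each independently switchable:

* **Introns** — bacterial DNA carries intronless genes, so at least one
  intron (exon count − 1 ≥ 1) in the recipient gene model argues against
  contamination. GFF3 coordinates are treated as 1-based inclusive.
  Splice-junction read support is accepted as a precomputed junction count
  table and reported alongside; read mapping itself is out of scope.
* **Physical linkage** — a real insertion sits among native genes. The
  check passes when at least one neighbour within `window` genes (default
  2 per side; the windows used in published screens are rarely stated, so
  this is configurable) is *animal-affiliated*: its phyletic profile has
  at least one animal taxon and animals outnumber donor-side bacteria. A
  candidate alone on its contig fails with reason "no context".
* **Recurrence** — independent genome assemblies are independent samples,
  so presence in at least `min_genomes` recipient genomes (default 2)
  makes shared contamination implausible.

`CLEAN` requires every enabled check to pass; anything else is `SUSPECT`.

# Amelioration metrics

A transferred gene gradually homogenizes ("ameliorates") toward the
recipient's base composition and codon usage. The package computes GC,
GC3s (G+C at third positions of synonymously variable codons; Met, Trp
and stops excluded), CAI, CBI, Fop and Wright's ENC.

Conventions that differ across published implementations are pinned down
as follows. CAI requires an explicit reference usage table (the host
coding set; the simulator provides one) — historical tools bundle ambiguous
default references, so none is bundled here — and unseen reference codons
receive a 0.5 pseudocount so relative adaptiveness stays positive.
Optimal codons are the most frequent codon per degenerate family in the
reference, making the Fop/CBI optimal set self-contained rather than
relying on curated lists. Six-fold families are treated as single
families, not split 2+4. ENC uses per-family homozygosity
F = (nΣp² − 1)/(n − 1) for families with n ≥ 2, class means over
degeneracy classes {2, 3, 4, 6}, ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆
clipped to [20, 61]; a missing 3-fold class is imputed as (F̄₂ + F̄₄)/2
following Wright, any other missing class by matching the mean
within-family spread of the observed classes, and imputation is flagged.

The host-versus-donor call computes, per metric, the gene's z-score
within each background gene set (at least 50 genes each by default);
the nearer background has the smaller |z|, the overall call is the
majority across metrics, ties are `INCONCLUSIVE`, and zero-variance
backgrounds fall back (flagged) to absolute differences.

# Expression

RPKM(g, s) = 10⁹ · C(g, s) / (N(s) · L(g)) with C the read count, N the
sample's mapped-read total and L the exon-model length (union of exon
intervals when a GFF3 is supplied). A stage is "expressed" at RPKM ≥ 1 by
default — published analyses of this kind rarely print their cutoff, so
the threshold is explicit and configurable — and the profile reports
whether expression is non-decreasing over a designated developmental
window. Read trimming, mapping and counting are consumed as a finished
count table, never recomputed.

# Selection

Pairwise Ka/Ks uses Nei–Gojobori (1986) counting: synonymous site
fractions per codon position (changes creating stops count as
nonsynonymous), sites averaged between the two sequences, equal-weight
averaging over substitution pathways for codons differing at more than
one position, and Jukes–Cantor correction d = −¾ ln(1 − 4p/3). Ks = 0
leaves ω undefined rather than infinite, and p ≥ 3/4 is reported as
saturation. The implementation is checked in the tests against values
frozen from an independent implementation (Biopython's NG86).

The one-ratio (M0) model is a Goldman–Yang-style 61-state codon chain:
single-nucleotide neighbours exchange at rate π_j · κ^[transition] ·
ω^[nonsynonymous], frequencies are F3x4 from the alignment (floored at
1e-8 and renormalized so the chain stays reversible when a nucleotide is
unseen at some position), the matrix is scaled to one expected
substitution per codon per unit branch length, and the likelihood is
computed by Felsenstein pruning over site patterns with per-pattern
rescaling. Gap- or stop-containing codon columns are dropped before
fitting. Optimization is L-BFGS-B over log branch lengths, log κ and
log ω from three fixed starting points (multi-start guards against local
optima while staying deterministic). The pruning likelihood is verified
against an independent matrix-exponential oracle on two-taxon alignments
to 1e-6. The likelihood-ratio harness (2Δ lnL against an upper-tail
chi-square) accepts any nested pair of fits, leaving room for site and
branch model extensions, which are not implemented here. Reproducing any
specific published ω for a real gene family requires that family's
accession-based alignment and is outside the desk-scale scope; the
package's claim is calibrated recovery on data of known ω.

# The simulator: what it emulates, and what it does not

`simulate_hgt_dataset()` generates, from a single seed, the full input
set: per-species proteomes for a fixed clade structure (three marine
donor bacteria, two other bacteria, two fungi, one other non-animal
eukaryote, two invertebrates, two tetrapods, two basal fishes, five core
fishes), surrogate hit tables for the animal and non-animal searches, a
taxonomy with the donor clade nested inside bacteria, GFF3 gene models in
which the transferred gene carries introns and sits between native genes
(plus an intronless contaminant contig carrying near-copies of bacterial
genes), per-genome presence of the transfer (absent from basal fishes),
an alignment of the transferred family, host and donor background coding
sets, and a stage-wise expression count table.

Background families fall into three presence classes (55% broad,
25% animal-only, 20% fish-restricted vertical) so that the screen's
rejection logic is exercised from both directions. Protein evolution uses
a 20-state equal-exchangeability model: the pipeline's logic is agnostic
to the exchangeability structure, and a self-contained model keeps the
generator free of external rate tables. Sequences within a family are
evolved without indels, so families are alignable by construction and the
surrogate hit generator can score identity positionally; its E-value
surrogate E = len² · 2^(−identities) is documented, monotone in identity,
and makes no Karlin–Altschul calibration claim — screening only needs
monotonicity. Coding sequences are back-translated with GC3-biased codon
profiles (host-rich, donor-poor), and the transferred gene draws each
codon from the mixture α · host + (1 − α) · donor, so the amelioration
sweep is monotone in α by construction. Expression counts are negative
binomial (size 10 by default) — the realistic overdispersed alternative
to Poisson — with the transfer's stage means zero in oocyte and 1-cell
stages, high in sperm and rising through the cleavage stages.

What the simulator does **not** emulate: indels and alignment error,
genome-scale family counts, database-composition biases, rate variation
across sites, GC heterogeneity along chromosomes, and read-level
sequencing noise. Passing the planted-truth benchmarks therefore shows
the pipeline's logic is correct under its stated assumptions, not that
real screens are free of the artefacts those missing features cause.

# Problem sizes and numerical choices

The packaged benchmarks use 20 seeded replicates of 200-gene proteomes
(amelioration α = 0.5) for screening recall and false positives, 100
random additive matrices of 4–8 taxa for neighbour joining (recovery is
certified by exact patristic-distance reproduction, which pins the unique
additive topology), 100 fuzzed coding sequences for the ENC oracle,
twenty 6-taxon 500-codon alignments simulated at ω = 0.08 for M0
recovery, and bootstrap consensus at 100–200 replicates (1,000 in typical
interactive use). These sizes were chosen as the smallest at which the
targeted properties are statistically unambiguous. With moderate-length
alignments (120–300 residues) the *finest* split joining the fish clade
to its nearest donor subclade sits on a short internal branch and can
fall below 90% support even when the enclosing fish-plus-all-donors clade
is maximally supported — the motivating observation for judging the
best-supported certifying split rather than the smallest one.

Other fixed numerical choices: NJ tie-breaking and bootstrap seeds make
every tree deterministic; the Poisson saturation cap is 0.999; consensus
splits need strictly more than 50% of replicates; M0 parameters are
bounded in [1e-6, 50] on the natural scale; degenerate fits (identical
sequences) drive branch lengths to the lower bound, recovering the
frequency-only likelihood.

# Limitations

The screen inherits every bias of its input hit tables; the package never
runs the homology search itself. The validation stage implements distance
phylogenetics only — externally computed likelihood or Bayesian trees are
consumed, not produced. NG86 and M0 assume no recombination and a single
ω across sites and branches; site/branch heterogeneity is expressly out
of scope. The amelioration call is a relative statement about two
supplied backgrounds, not an absolute clock: with small or unrepresentative
background sets it degrades gracefully to `INCONCLUSIVE` rather than
inventing precision.
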