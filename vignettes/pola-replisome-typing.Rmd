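---
title: "Typing viral DNA polymerase I and its replisome neighbourhood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing viral DNA polymerase I and its replisome neighbourhood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polatyper)
library(dplyr)
```

## The analysis in one paragraph

Family A DNA polymerase (PolA) is carried by roughly a quarter of known
dsDNA phage, and a single residue in its motif B region — position 762 in
*E. coli* numbering — correlates with polymerase biochemistry and, through
it, with phage lifestyle: phenylalanine (wild type) and tyrosine variants
occur in lytic phage, leucine variants predominantly in temperate phage.
`polatyper` implements an offline, fully testable pipeline around this
marker: it finds ORFs on assembled contigs, screens peptides for PolA,
anchors each PolA to a reference so the 762 residue can be read off,
inventories co-located replication genes (helicase families, ribonucleotide
reductase classes, primase, MazG), clusters markers at 75% amino-acid
identity, builds distance-based trees over anchored windows (including a
concatenated PolA+RNR alignment that resolves nine clades), and applies a
dichotomous "field guide" that predicts group and lifestyle from replisome
content. A seeded synthetic-community generator with a ground-truth table
makes every stage verifiable without any sequence download.

## Reference anchoring instead of multiple alignment

All coordinates in this analysis are *reference* coordinates. Each query is
aligned once to an anchor peptide by Needleman–Wunsch with BLOSUM62, affine
gaps (open 11, extend 1) and free terminal gaps on both sequences, and the
alignment is reduced to a map "reference position → query position or
deleted". Windows are then literal reference spans:

| window | anchor | span | length |
|---|---|---|---|
| `partial` | PolA | 675–799 | 125 aa |
| `full_domain` | PolA | 547–926 | 380 aa |
| `concat` | PolA | 784–926 | 143 aa |
| `rnr_region` | NrdA | 437–625 | 189 aa |

Ends-free alignment on both sides was a deliberate choice: the package's own
invariant — classification must not change when a query is padded with
unrelated flanking residues — requires reference-side terminal gaps to be
free as well, otherwise flanks would be forced into the anchor. Stacking
anchored rows (`stack_anchored_alignment()`) discards query insertions
relative to the anchor; this fixes column homology exactly, at the cost of
ignoring insertion-borne signal, which none of the downstream statistics
use. Rows covering less than 80% of a window are dropped from tree building;
the threshold is a package choice (the source analyses kept "as many
sequences as possible" without stating one).

The bundled anchors are **synthetic**: deterministically generated scaffolds
with the geometry of the real reference proteins (a 928-aa PolA-like
scaffold with Phe at 762; a 761-aa NrdA-like scaffold). Real anchor
peptides, where available, can be supplied via `read_anchor_panel()`. All
tests and bundled analyses are self-contained on the synthetic panel, which
also means that passing them demonstrates correct *mechanics* (anchoring,
typing, clustering, recovery), not performance on natural sequence families.

## Screening and family assignment

The PolA screen retains peptides with a Smith–Waterman hit to a PolA panel
entry at an estimated E-value at or below 1e-5 and length at least 200 aa.
E-values use the Karlin–Altschul form `E = K·m·n·exp(−λS)` with pinned
gapped-BLOSUM62 constants (λ = 0.267, K = 0.041) and the panel's residue
count as search space; the bundled panel is tiny compared to a real
database, so absolute E-values are conservative stand-ins and only the
decision rule's structure matters. An additional requirement — the local
alignment must cover at least 30% of the panel entry — stands in for the
independent domain-database confirmation used with online tools. Family
assignment takes the best family at or below the cutoff and labels a
peptide `ambiguous` when the top two families score within 5% of each
other; ambiguous calls are excluded from prevalence statistics.

## Clustering

Marker peptides are clustered at 75% amino-acid identity under the
furthest-neighbour (complete-linkage) criterion: a cluster may only form if
its maximum intra-cluster distance stays at or below 0.25. Identity is
counted over reference-anchored columns where at least one of the pair has
a residue, excluding columns inside either sequence's terminal gap runs —
the closest exactly-specifiable analogue of Mothur's one-gap counting;
exact replication of any particular Mothur version's distances is not
claimed. Representatives are the longest member (ties: smallest id). The
all-vs-all homology graph (edges at E ≤ 1e-20, clusters = connected
components) and the per-clade core rule (a cluster is core when present on
at least ⌈half the clade's contigs⌉) follow the published procedure.

## Trees, clades and their resolution

Tree building is distance-based: uncorrected p-distances over anchored
columns, Saitou–Nei neighbour joining (negative branch lengths clamped to
zero), and nonparametric bootstrap over columns (default 10 replicates,
matching the headline analyses) with supports as bipartition frequencies.
Neighbour joining replaces maximum-likelihood inference deliberately: the
clade structure rests on marker combinations, NJ recovers additive
distances exactly (a property the suite tests on random trees), and an ML
stack would add tool-replication without adding testable substance.

The concatenated analysis joins the PolA 784–926 window (143 columns,
PolA block first by convention) with the RNR 437–625 window (189 columns)
for contigs carrying both markers. Nine clades are delineated by RNR class
× 762 type. Two cells of that map are ambiguous by construction — (Class I
Other, Tyr762) → {2,3} and (Class II Other, ·) → {1,8,9} — and are resolved
by the nearest labelled leaf on the concatenated NJ tree (patristic
distance, restricted to labels consistent with the candidate set, ties by
label order). Without a tree or labelled references the candidate set is
reported unresolved rather than guessed.

## The field guide

Rules fire in a fixed order on contig-level gene presence (R1: Tyr762 →
lytic; R2: Phe762+DnaB → Phe762-I, lytic; R3: Phe762 with only non-ring
helicases → Phe762-II; R4: Leu762+RecB+SNF2 → Leu762-I, temperate; R5:
Leu762+UvrD+SNF2 → Leu762-II, temperate; R6: other Leu762 → unassigned).
Lifestyle is asserted only where the underlying meta-analyses support it:
Phe762-II and unassigned profiles stay `indeterminate`. Conflicts (an RNR
or a Gp4-like helicase on a Leu762 contig; no rule fired) are flagged but
never silently override a rule, so every prediction carries an explainable
trace. Adjacency (gene ranks) is recorded but advisory; the primary
statistic is same-contig presence — the percentage of contigs containing
each gene — which is also what the prevalence tables report.

## The synthetic community generator

`generate_community()` emulates the statistical structure the analysis
assumes; its defaults *are* the study conditions and are not tuned:

* Per-group contig counts (289 / 124 / 42 / 119 / 247 for Tyr762, Phe762-I,
  Phe762-II, Leu762-I, Leu762-II) and per-group gene-presence
  probabilities taken from the published percentages (e.g. Gp4-like 0.69
  and RNR 0.40 in the Tyr762 group). Genes are drawn independently, so
  pairwise co-occurrence equals the product of marginals; the published
  joint rates are sometimes higher (and in one case — Leu762-II, where
  UvrD was reported as always accompanied by SNF2 at marginals 68% vs 45%
  — mutually inconsistent), so only marginals are calibrated.
* Read-mass shares for the three dominant combinations (Tyr762+Gp4 28.4%,
  Leu762-II+SNF2+UvrD 16.4%, Phe762-I+DnaB 13.3%), with the remaining mass
  spread over all other contigs. Reads are error-free exact substrings
  (uniform position, random strand), pairing with the exact-substring
  recruiter; an error model would only blur a rule that is deterministic by
  construction.
* Sequence structure: each gene is its family template mutated by
  substitutions only (no indels) to a target identity, reverse-translated
  with uniformly drawn synonymous codons, ATG-initiated and TAA-terminated,
  laid out left to right with 20–100-nt random spacers. Within-group
  divergence defaults to 0.15 and templates sit at 0.45 divergence from
  their scaffolds; substitution-only mutation keeps anchored alignments
  gapless, which is why 762-recovery is exact up to high divergence —
  natural indel variation would erode that sooner.
* The clade-mode spec allocates the 140 PolA+RNR contigs as 11/1/1 (clade
  1, mixed types), 15/14/10 (clades 2–4), 14 (clade 5), 42/20 (clades
  6–7), 7/5 (clades 8–9) — a package choice satisfying the published
  constraints (clade-1 composition, 70/28/2 type split, 28/10/46/18 RNR
  class split), with per-clade sub-templates at 0.20 divergence and members
  at 0.10 so clades are separable both by combination and by tree
  proximity.

What passing recovery tests shows, therefore, is that the pipeline inverts
its own generative model at realistic parameter settings — not that it
matches tool-for-tool output on environmental data, where divergence is
larger, indels are real, and databases are incomparably bigger.

## Numerical choices and degenerate inputs

Alignment tie-breaking follows the alignment engine's deterministic
traceback, so outputs are bit-stable; optimal scores (which ties cannot
affect) are tested against a brute-force enumeration oracle. Pairs with an
empty identity denominator get distance 1 in clustering input; p-distance
(tree input) errors instead, since such a pair carries no signal.
Clustering at cutoff `h` merges while the complete-linkage height is ≤ h
(a 1e-12 tolerance absorbs floating-point ties at the boundary). ORF
calling is ATG-only under the standard code — the generator emits only such
ORFs — and `longest_only` collapses nested starts sharing a stop; the
pipeline's 150-aa ORF floor suppresses spurious random-frame ORFs while
every marker family template is ≥ 260 aa. Multi-contig reads are dropped
from the recruitment denominator (single-best-hit behaviour of real mappers
is not reproducible without the mapper). Bootstrap, read simulation and
mutation are the only stochastic elements; all are seeded, and runs with
identical inputs and seeds are byte-identical.

## Problem sizes used in the bundled analyses

The recovery analyses shipped with the package run at the sizes stated in
their descriptions: 200 peptides for 762 recovery, 1,000 contigs for
prevalence recovery, a 205-contig community with 20,000 reads for
combination-share recovery in the test suite (the acceptance script uses
the full 821-contig configuration with 100,000 reads), and the 140-contig
clade community. These sizes give binomial/multinomial standard errors
comfortably inside the stated tolerances (e.g. ±3 points for a 69%
prevalence at n = 1,000 is about two standard errors).

## Known limitations

* Synthetic templates are random scaffolds; no claim is made about
  sensitivity/specificity on natural protein families, and the pinned
  Karlin–Altschul constants are nominal for gapped BLOSUM62 rather than
  fitted to the panel.
* Identity counting approximates, but does not bit-match, Mothur's
  furthest-neighbour distances.
* The field guide encodes the published key verbatim; cases it leaves open
  (single-helicase Leu762 profiles) are surfaced as unassigned rather than
  forced.
* Clade 2-vs-3 style distinctions exist only through labelled references;
  unlabelled data gets candidate sets.

## A small worked run

```{r example, eval = FALSE}
spec <- serc_fig2_spec(
  groups = c("Tyr762", "Leu762-II"),
  n_contigs = c(Tyr762 = 20, "Leu762-II" = 15),
  n_reads = 2000
)
spec$abundance <- NULL # uniform read mass over contigs
comm <- generate_community(spec, seed = 1)
res <- run_pipeline(comm$contigs, reads = comm$reads)
glance(res)
tidy(res) |> count(group, lifestyle)
autoplot(res$prevalence)
```
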