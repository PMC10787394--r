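---
title: "Classifying RIP-degraded LTR retrotransposons with similarity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying RIP-degraded LTR retrotransposons with similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripnet)
```

## Why networks instead of consensus sequences

Repeat-induced point mutation (RIP) is a fungal pre-meiotic genome defense
that hypermutates C→T in duplicated regions, preferentially at CpA/TpG
dinucleotides. It acts on repeats roughly 400 bp and longer that share
about 80 % identity with another copy, and it degrades each copy
*independently*. Two consequences matter for TE classification. First,
copies of one subfamily drift apart along individual trajectories, so
conventional identity clustering (CD-HIT-style, consensus-based) shatters a
family into hundreds of clusters. Second, local alignments between two
RIPped copies come back fragmented and overlapping, so a "top hit"
identity underestimates how similar two copies really are.

`ripnet` addresses both. Pairwise similarity is recomputed over *all* HSPs
of a pair, and classification operates on the resulting similarity network
rather than on any consensus: communities of densely connected copies are
the subfamilies, and the best-connected member of each community (the
centroid) serves as its exemplar, e.g. for building masking libraries.

## The pair score

For each sequence pair the all-vs-all hit table is first cleaned:
self-hits are dropped and, of the two query/subject directions, only the
one with the larger total bitscore is kept (ties resolved by id order so
output is reproducible). The retained direction's HSPs are projected onto
the query and every covered base is assigned to exactly one HSP —
the one with the highest percent identity, then highest bitscore, then
lowest query start. With assigned lengths $\ell_i$ and HSP identities
$p_i$:

$$\mathrm{identity} = \frac{\sum_i p_i\,\ell_i}{\sum_i \ell_i},
\qquad
\mathrm{coverage} = 100\cdot\frac{\sum_i \ell_i}{L}.$$

The merged identity is therefore a convex combination of HSP identities,
and the per-base accounting is exact: the test suite checks
`merge_hsps()` against a literal per-base sweep on a thousand random HSP
configurations.

Two choices here were genuinely open:

* **The coverage denominator $L$.** Published descriptions of such
  pipelines rarely state whether coverage is relative to the query, the
  subject, or the shorter sequence. We use the query of the retained
  (higher-scoring) direction by default and expose
  `coverage_ref = "query" | "shorter" | "longer"`. With `"query"`, a short
  fragment aligning fully inside a longer copy reaches 100 % coverage —
  which is also how such fragments behave in the real data, where they
  connect into their subfamily through their intact region.
* **Overlap resolution.** "Excluding overlaps" does not say *which* HSP
  keeps an overlapped base. Assigning it to the higher-identity HSP is the
  optimistic choice consistent with recomputing identity from the best
  local evidence; the full tie-break chain makes the result deterministic.

## Network, communities, centroids

An edge connects two copies iff merged identity **>** 80 and merged
coverage **>** 80 (strict inequalities, following the published threshold
phrasing; `strict = FALSE` switches to ≥). Internal-region networks use
coverage > 70, reflecting the larger indel load of internal sequences.
Network construction is monotone in both thresholds, which the tests
assert.

Communities are found by unweighted greedy modularity maximization in the
Clauset–Newman–Moore style: start from singletons and repeatedly merge the
connected pair of communities with the largest gain

$$\Delta Q_{ij} = \frac{e_{ij}}{m} - 2\,\frac{d_i}{2m}\frac{d_j}{2m},$$

stopping when no merge increases $Q$. Three implementation decisions:

* **Unweighted.** Edge identities are deliberately not used as weights —
  the thresholds already encode "similar enough", and the reference
  algorithm is the unweighted one. Identities are kept only to break
  centroid ties.
* **Deterministic ties.** Equal $\Delta Q$ is resolved toward the
  lexicographically smallest community-pair label (a community is labelled
  by its smallest member id). Partitions are therefore bit-reproducible,
  which the determinism test exercises.
* **Hill-climb stop.** The agglomeration stops at the first non-positive
  gain rather than continuing to a full dendrogram. On disjoint clique
  unions and the barbell graph this recovers the exhaustive-search
  modularity optimum (verified against a Bell-number enumeration oracle up
  to $n = 10$); on general graphs it is the usual greedy approximation and
  is only guaranteed not to fall below the singleton partition.

Communities with fewer than five copies are left unclassified
(`min_size = 5`, keep if size ≥ 5). The source descriptions alternate
between "less than five are unclassified" and "kept communities contain
more than five copies"; both rules are implemented
(`keep_rule = "ge" | "gt"`) with `"ge"` as the default, and neither is
guessed to be canonical.

The centroid of a community is its member with the most edges **within the
community's induced subgraph** — inter-community edges are excluded so
that copies sitting between communities (a hallmark of heavily rearranged
elements) cannot become exemplars. Ties go to the largest summed identity
of incident edges, then the smallest id.

## Labels, comparison, rogues

Nested community pairs (highly similar centroids with minor structural
differences) can be merged into joint subfamilies through a merge map;
remaining communities are named `LTR1`, `LTR2`, … by decreasing size.
`compare_classifications()` restricts to copies classified by the first
classification, counts label differences (ids missing from the second
classification count as disagreements and are also reported separately)
and returns the rate as a percentage.

Rogue copies — classified copies falling outside their subfamily's main
clade in an ML phylogeny — are detected with an explicit rule, since
visual tree inspection is not reproducible. For subfamily $S$, candidate
clades are internal nodes (root included) in which $S$ members form a
**strict majority** of the classified leaves; the main clade is the
candidate containing the most $S$ members (ties: larger clade, then closer
to the root), and rogues are the members outside it. The threshold is
strict because at an exact 50–50 split an ancestral node carries no
evidence of being "the" subfamily clade; with a non-strict rule the root
would absorb any subfamily that happens to reach half of the tree.
Unclassified copies are ignored throughout — rogues are by definition
classified copies. The `purity` parameter generalizes the majority
fraction.

## Copy retrieval and RepeatMasker post-processing

`merge_hits_to_haplotypes()` reproduces the retrieval logic for full
copies: genome hits on the same contig and strand merge when their gap is
at most `merge_gap` (default 1000 bp — the source tool's value is not
published, so this is a documented parameter, not a constant), merged
haplotypes shorter than `min_size` are dropped and survivors extended by
`flank` on each side (defaults 4000/2000, the internal-region retrieval
settings), clipped at contig ends. Merging is idempotent.

A terminal-repeat occurrence is classified against the full-copy
annotation as `FULL_5P`/`FULL_3P` (overlaps an element end within
`end_tolerance`, default 10 bp — "overlaps the end" is not quantified in
the sources, so the tolerance is explicit), `NESTED` (overlaps only the
internal region) or `SOLO_FRAGMENT` (no overlap). A hit spanning both ends
of one element is an error flagged for curation.

RepeatMasker post-processing applies, in order: (1) drop hits with genomic
span ≤ 250 bp (strict >, so only hits reaching into the variable U3 region
are counted — subfamily LTRs are 339–443 bp); (2) copy-context
classification; (3) removal of putative solo-LTRs overlapping a curated
full-copy boundary repeat by ≥ 1 bp (no overlap fraction is published, so
any overlap counts and the choice is documented); (4) per-species,
per-subfamily counts split into full, solo/fragment and nested. Every
input hit is counted exactly once or dropped by exactly one rule, an
invariant the fixture tests assert by summation.

## The simulator

`simulate_family()` is a forward simulator of one LTR-retrotransposon
family, built so the classifier can be tested end to end with exact truth:

* **Element anatomy.** One ancestral LTR (default 400 bp: a variable U3
  half of 200 bp followed by a conserved half beginning with a fixed
  TATA-box motif) and one internal region (default 6.6 kb, giving a
  ~7.4 kb element). Subfamilies differ only in U3, each derived from the
  ancestral U3 by per-site substitution at rate `u3_divergence` — this is
  the empirically observed architecture in which subfamily variation is
  confined to the U3 region upstream of the TATA-box.
* **Insertion.** Copies transpose with *identical* paired LTRs (the 5' LTR
  is synthesized from the 3' template) and a 5 bp target-site duplication
  (TSD length is not reported for the emulated family; 5 bp is typical for
  LTR retrotransposons and configurable).
* **Per cycle**: neutral mutation (default 10⁻⁴/site), solo-LTR formation
  (a full copy collapses to a single LTR recombined from its two LTRs at a
  uniform breakpoint, TSD retained), fragmentation (uniform truncation
  from one end), optional nested insertion (a new copy splits a host into
  two fragments), then RIP.
* **RIP.** A copy is exposed iff it is ≥ `rip_min_len` (default 400 bp)
  long *and* shares ≥ `rip_min_id` (default 80 %) merged identity with at
  least one other copy — evaluated with the very same `merge_hsps()`
  machinery the classifier uses, so there is a single definition of
  similarity in the package. Exposed copies mutate C→T at rate `rip_p_cpa`
  when the next base is A, G→A at the same rate when the previous base is
  T (the reverse-strand CpA), and at `rip_p_other` elsewhere. RIP never
  creates C or G, so per-copy GC is monotone non-increasing — asserted as
  a property test.

Every copy carries a homology map: blocks of its sequence mapped to a
common ancestral axis (U3, conserved LTR half, internal; the 3' LTR maps
onto the LTR ranges again). `truth_hits()` derives an exact all-vs-all hit
table from block overlaps, with per-site identities computed directly from
the sequences; blocks under 30 bp or 50 % identity are suppressed to
emulate the sensitivity floor of a real local-alignment search (both
configurable). `local_align()` provides the search-based alternative —
iterated Smith–Waterman with affine gaps (match +1, mismatch −2, open 5,
extend 2), extracting secondary HSPs by N-masking the query interval of
each reported alignment — and agrees with `truth_hits()` within 2
percentage points on ungapped homologous pairs.

`extract_terminal_repeats()` emulates the curated copy set used for
classification: the 5' LTR per full copy, solo-LTRs whole, and for
fragments the LTR-derived run retaining the most U3. A copy enters the
curated set only if its terminal repeat keeps ≥ 30 bp of U3 — the
in-silico analogue of the curation rule that kept only sequences aligning
to another copy in the U3 region. This matters: a conserved-half-only
remnant is equally similar to every subfamily and carries no subfamily
signal, exactly the kind of sequence a curator discards.

### What the simulator does and does not show

The generator reproduces the features that make this classification
problem hard: multi-subfamily families with divergence confined to U3,
RIP-fragmented alignments, solo-LTRs, truncated fragments, nested
insertions and high-GC unRIPped solo copies. It does **not** model
selection, recombination hotspots, transposition-rate evolution, indel
accumulation inside alignments (homologous blocks stay ungapped), or the
deep subfamily-from-subfamily "ladder-like" histories of real families.
Passing the recovery tests therefore shows the pipeline is correct under
the generative assumptions it was designed for — not that any particular
biological dataset will classify as cleanly.

### Study conditions used in tests and the acceptance script

* Subfamily recovery: $K \in \{3, 5\}$ subfamilies × 20 copies,
  `u3_divergence` 0.5, `rip_p_cpa` 0.05, 3 cycles — moderate RIP on an
  otherwise default family; the pipeline (truth hits → pair scores →
  80/80 network → greedy communities → ≥ 5 filter) must recover exactly
  $K$ communities with adjusted Rand index ≥ 0.95 and centroids from the
  dominant truth subfamily.
* GC signature: `rip_min_len` 450 > `ltr_len` 400, so solo-LTRs escape
  RIP while full copies keep mutating; 3 × 40 = 120 copies, 6 cycles of
  strong RIP (`rip_p_cpa` 0.2, `rip_p_other` 0.05, `p_solo` 0.15). These
  rates reflect the efficiency of RIP over repeated sexual cycles in
  Podospora-like fungi, where heavily exposed copies lose tens of GC
  percentage points and solo-LTR formation is common; the expected
  outcome is the empirical pattern that solo/fragment copies retain
  mostly high GC while full copies are heavily RIPped, tested as
  one-sided stochastic dominance (Wilcoxon, α = 0.01).

Problem sizes throughout (tens of copies, kb-scale elements, $n \le 10$
for exhaustive modularity enumeration) were chosen as the smallest at
which each property is meaningfully exercised.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally with explicit strand;
  BLAST tabular and RepeatMasker input (1-based inclusive) are converted
  at the boundary, and conversion is an involution.
* Copy ids follow `contig_start-end`; the contig is everything left of the
  *rightmost* underscore because contig names themselves contain
  underscores. `start > end` encodes minus orientation; `start == end` is
  rejected.
* GC content excludes N and ambiguity codes from the denominator so RIP
  statistics are not diluted by assembly gaps; a sequence with no A/C/G/T
  yields `NA` with a warning.
* Modularity of an edgeless graph is undefined (`NA` with a warning);
  community detection on an edgeless graph returns singletons.
* An empty comparison set gives an undefined disagreement rate, signaled;
  empty hit tables flow through as empty results, not errors.

## Known limitations

* The greedy agglomeration is quadratic-ish in community count per merge;
  it is comfortable at the hundreds-to-low-thousands of copies this
  workflow targets, not for million-node graphs.
* Rogue detection depends on the provided tree being rooted sensibly; the
  majority-clade rule cannot rescue a tree rooted inside a subfamily.
* `local_align()` reports gapless-equivalent identity over aligned
  columns; heavily indel-ridden pairs will differ more from `truth_hits()`
  than the 2-point bound observed on ungapped homology.
* Species assignment in RepeatMasker post-processing comes from a per-file
  tag, never from contig names.
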