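---
title: "Inferring retrocopy translocation, intron loss and promoter carry-over"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring retrocopy translocation, intron loss and promoter carry-over}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrotrace)
```

## The problem

Hatching-enzyme genes (HEs) of teleost fish are a striking counterexample to
the rule that genes keep their genomic neighborhood: over teleost evolution
the clade I genes repeatedly moved to new chromosomal locations, and each
move coincided with the precise excision of several (or all) of their eight
ancestral introns, with no insertion or deletion in the exons.  That joint
signature — a new locus, fewer introns, exact exon boundaries — is the
fingerprint of retrocopy: a spliced (or partially spliced) mRNA is reverse
transcribed and reinserted, the new copy takes over, and the source copy
decays into a pseudogene vestige.  Unusually, the moved genes stayed active,
which implies the retrocopied transcript carried the promoter along.

`retrotrace` implements this inference as a reusable, testable pipeline over
annotated genomes (FASTA + GFF3) and a rooted species tree (Newick):

1. **In-silico cloning** (`infer_gene_structure()`, `cross_species_clone()`):
   locate every copy of the focal family in each genome and determine its
   exon–intron structure by splice-aware mapping of a seed coding sequence
   under the GT–AG rule; grade non-intact occupants as vestiges
   (`classify_vestige()`).
2. **Synteny slots** (`extract_context()`, `match_slots()`,
   `build_presence_matrix()`): describe each locus by its ordered flanking
   genes, match contexts across species into syntenic slots, and build the
   species × slot presence/vestige matrix.
3. **Event placement** (`irreversible_loss_parsimony()`,
   `dollo_presence_parsimony()`, `cotiming_report()`): date intron losses
   and slot gains on branches of the species tree and ask whether they are
   co-timed — the retrocopy signature.
4. **Promoter carry-over** (`extract_upstream()`, `scan_tf_sites()`,
   `conserved_block()`, `classify_carryover()`, `upstream_tree()`): test
   whether the ~200 bp promoter block (TATA box plus klf3/17 and foxa3
   binding sites) travelled with each daughter copy.
5. **A forward simulator** (`simulate_clade()`, `fixture_clade()`,
   `random_scenario()`): a miniature clade with planted events and a
   ground-truth log, so every stage of the inference is verifiable without
   downloading genomes.

## Splice-aware cloning

The exon–intron structure of a copy is the chain of ungapped exon segments
of the seed CDS whose gaps are introns beginning `GT` and ending `AG`
(minimum length 40 nt; minor `GC–AG` sites are deliberately not modeled).
The chain is found by dynamic programming (compiled code) minimising
`mismatches + 20 × introns`.  The weight of 20 mismatch-equivalents per
intron separates two regimes cleanly: *skipping* a true intron forces the
downstream CDS through ≥ 40 nt of intron sequence at ~75% mismatch (≥ 30
mismatches), while *inventing* a spurious intron can rescue at most a
handful of mismatches.  At the package's working divergences the result is
therefore the fewest-intron chain, which the test suite verifies against an
exhaustive chain enumerator on small regions.  Ties (e.g. two valid donors
4 nt apart) are broken toward the leftmost donor, making the output
deterministic.  A chain leaving more than 5% of CDS positions mismatched
raises `unmappable` — or `splice violation` when dropping the GT–AG
requirement would rescue it, which is how a non-canonical boundary shows up.

Vestiges are graded from a local alignment of the reference CDS against the
locus (Biostrings): *coverage* is the fraction of reference positions
matched, *disruption* counts frameshifting indels plus premature in-frame
stops.  Thresholds — full ≥ 0.9 coverage with no disruption; fragment
0.2–0.9; short fragment 0.05–0.2; absent < 0.05 — discretize the observed
continuum of decay (full-length gene → fragment → short fragment → nothing)
and are stated explicitly so tests are stable.  They sit far from the
simulator's planted retention fractions (0.4–0.6 and 0.1–0.2), so
classification is insensitive to small threshold changes.

## Synteny slots

A locus is identified across species by its flanking genes, not its
sequence: up to `k = 3` annotated neighbors per side (nearest first, in
genomic coordinate order), with a sentinel at chromosome ends that never
counts as an anchor.  Two contexts belong to one slot when they share at
least `min_anchors = 2` symbols in a consistent relative order; orientation
differences are tolerated, order reversals are not, and the closure is
taken by union–find so slot membership is transitive and
input-order-invariant.  The focal gene's own orientation never enters slot
identity (both orientations occur within conserved slots in real data).  A
copy inserted inside another gene's intron is reported with the host
symbol, the 1-based intron ordinal in the host's transcription direction,
and the relative orientation.

## Event placement

Two character types are placed on the tree:

* **Intron counts** are irreversible: counts never increase toward the
  tips (no intron gain).  Assigning each internal node the maximum of its
  children's counts yields the unique *latest* (closest-to-tips)
  reconstruction, and a loss of magnitude `parent − child` is emitted where
  the value drops.  This matches how "loss in the common ancestor of X" is
  normally phrased, and the test suite checks the total magnitude against
  exhaustive enumeration of all monotone labelings on trees of ≤ 6 leaves.
  Per-intron identity is not tracked — a loss of 3 is a count, not a set.
  Species without an intact copy contribute no constraint.
* **Slot presence** follows Dollo logic: a slot is gained once, on the stem
  of the clade of all species carrying the gene *or its vestige* (vestiges
  are evidence the copy was there), and may only be lost afterwards.
  Losses are the minimal branch set explaining absence; a loss branch is
  annotated `pseudogenization` when a descendant still shows a vestige and
  `copy_loss` when even the vestige is gone.

The slot whose gain sits closest to the root is the parent (ancestral)
locus; every other gain is a `translocation_gain`.  The co-timing report
intersects intron-loss branches with translocation branches; the verdict is
"co-timed" when every intron-loss branch also carries a gain.  Finer
within-branch ordering (did the copy lose introns just before or just after
moving?) is not inferable from genome comparison and is not claimed.

## Promoter carry-over

Offsets are negative coordinates relative to the TSS, modeled as the first
base of exon 1.  The TATA box is `TATA[AT]A[AT]`, searched at −50..−20 with
the 3′-most match winning (the figure-level evidence marks a TATA near the
TSS without giving a pattern; a standard consensus and window are fixed
here for testability).  Binding sites are the published consensus motifs:
klf3/17 `CACCC`/`CTCCC` (scanned as `CWCCC`) and foxa3 `TGTTT(A/G)C(T/A)
(T/C)(A/T)` (`TGTTTRCWYW`), sense strand only by default.  A daughter locus
carried its promoter when its upstream window shares a conserved block
(pairwise identity ≥ 0.7 over ≥ 100 bp) with the reference promoter and
that block contains a TATA box plus at least one klf and one foxa3 site
inside the indispensable −192..−91 subregion — the subregion whose deletion
abolishes reporter expression in the underlying experiments.  The
carry-over call is sequence-level only; it does not re-run any reporter
assay.

The upstream tree takes the 100 bp immediately 5′ of each TATA box,
computes Jukes–Cantor distances and builds a neighbor-joining tree.  This
deviates from the source study's maximum-likelihood GTR+Γ+I tree (an
external tool, out of scope); NJ+JC is adequate for the package's purpose
of checking that upstream regions cluster by history.  No multiple
alignment is performed because the simulator introduces no promoter indels;
on real data with indels the regions would need alignment first — a stated
limitation.

## What the simulator emulates, and what it does not

`simulate_clade()` evolves a small genome along the tree: spacers,
single-exon neighbor genes tracked by symbol, optional multi-exon host
genes, and the focal gene — nine exons, eight GT..AG introns (60–90 nt), a
780 nt CDS whose protein carries one `HExxHxxGFxHExxRxDR` and one `SxMHY`
active-site motif and exactly six cysteines, and a 200 bp promoter with the
TATA box at −31 and klf/foxa3 sites at −150/−120, inside −192..−91.  These
defaults are the stated anatomy of the gene family; the promoter motif
offsets are one concrete choice inside the documented subregion.

Substitution is uniform per site per branch, with no indels outside decay
events.  Functional copies keep their splice dinucleotides and promoter
motifs fixed — purifying selection in its crudest form.  This is a modeling
decision, not a convenience: the premise of the analysis is that these
elements are conserved across hundreds of millions of years, far beyond
neutral expectation, and a fully neutral simulator at 0.01/site/branch
would destroy a splice site or motif in most replicates and test nothing
but motif decay.  Decayed copies drift freely.

Planted events follow the retrocopy grammar: `translocation_gain` copies
the source with its 3′-most *k* introns precisely excised (no exonic edits)
into a new slot — intergenic after a named anchor, or inside a named host
intron — carrying the promoter iff the flag says so, and is logged together
with the implied `intron_loss` on the same branch; `pseudogenization`
replaces a copy with a contiguous 40–60% (fragment, 2 frameshifts) or
10–20% (short, 1 frameshift) of its spliced CDS; `copy_loss` replaces it
with random sequence of the same length, standing in for complete
obliteration by accumulated mutation (a stand-in, not a mechanistic claim).
Identical seeds give byte-identical output.

The random scenario generator samples only *identifiable* histories: a
witness lineage always retains the untouched ancestral gene, branches
carrying independent intron signals are clade-disjoint and pre-checked with
a count-level parsimony pass, at most one decay of the parent copy is
planted per scenario, and erasures never remove a root-child tip's record.
These constraints are facts about what any parsimony method can recover —
an event whose every trace is erased, or two equal losses whose witness
was destroyed, are not reconstructable from the tips — so a green recovery
test establishes correctness of the inference on recoverable histories,
not the recoverability of arbitrary ones.  What the simulator does *not*
emulate: realistic substitution models, indel noise in functional regions,
tandem duplication, orthology ambiguity between near-identical paralogs,
and genome-scale background gene content.

## A worked example

The deterministic fixture clade replays the qualitative teleost history in
miniature: 16 species, the ancestral gene between `tgfb2l` and `kcnk4`
(tail-to-tail), a five-intron copy inside the 14th intron of an
`aox5`-like host (opposite strand) in the otophysi-like subclade, an
intron-less copy near `glo1`/`slco3a1`/`mctp2b` in the euteleost-like
subclade, four further daughter insertions, and graded decay of the
euteleost parent-slot copy down to complete erasure in the cichlid-like
species.

```{r fixture, eval = FALSE}
fx <- fixture_clade()
run <- run_pipeline(fx)
glance(run)
run$cotiming
autoplot(run)
run$scorecard
```

The run reports intron losses of 3 and 8 co-timed with translocation gains
on the otophysi-like and euteleost-like stems, four independent euteleost
daughter slots, and promoter carry-over for every daughter locus.  The
scorecard against the planted log recovers every translocation and intron
loss branch-exactly; the two sibling decays of the euteleost parent-slot
copy (tilapia-like short fragment, cichlid-like erasure) are reconstructed
as one loss on their shared stem — the minimal-placement ambiguity
discussed above, and a useful illustration of what the scorecard can and
cannot establish.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; GFF3 I/O converts to/from
  1-based closed.  Genome sequences are uppercased on read; non-ACGTN
  symbols are rejected.
* Splice mapping: minimum intron 40 nt, mismatch tolerance 5%, intron
  weight 20, leftmost-donor tie-break; all configurable except the weight.
* Slot matching: `k = 3`, `min_anchors = 2`; two anchors in consistent
  order suffice to reject chance collisions at this genome scale.
* Vestige thresholds as above; conserved block: identity 0.7, length 100.
* Duplicate FASTA names, duplicate tree leaves, exons outside their gene,
  events on branches missing from the tree, and all-absent presence
  columns raise immediate errors.  A multifurcating root is accepted but
  flagged.  Chromosome-end truncation of upstream windows is flagged on
  the returned sequence.

## Known limitations

* Slot matching requires explicit anchor sharing; a locus whose neighbors
  are all unannotated or renamed lands in its own slot rather than being
  merged on "similar location".
* The intron-loss character is a count; per-intron presence matrices are
  out of scope.
* Carry-over is a sequence-pattern verdict, not a functional assay; the
  hypothesis that promoter-containing transcripts mediate the retrocopy is
  outside what genome comparison can test.
* `classify_vestige()` trusts local alignment; heavily shuffled vestiges
  below ~5% coverage are indistinguishable from background and are
  reported as absent.
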