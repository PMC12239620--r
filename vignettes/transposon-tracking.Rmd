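---
title: "Tracking transposable element movement by SNP fingerprints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking transposable element movement by SNP fingerprints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrack)
```

# The problem and the model

Transposable element (TE) families in a eukaryotic genome consist of
tens to thousands of copies that are nearly identical to one another.
When two assemblies of diverged lineages of the same species are
compared, a copy present in both cannot be paired up by similarity
search: every family member is an equally good hit.  `tetrack`
implements coordinate-free identification of individual copies by the
single-nucleotide polymorphisms (SNPs) that happen to fall inside them.
Each SNP-bearing copy has a private sequence variant in the query
lineage; applying the variant bases to the reference copy's sequence
yields the sequence that the same physical copy must have in the query
assembly, which can then be searched for by **exact** full-length string
equality among the query's TE annotations.  Coordinates enter only
afterwards, to decide whether the matched copy sits where whole-genome
alignment says it should.

The pipeline has four stages, each an exported function so that any
stage can be replaced or inspected:

1. **Variant retention** (`filter_variants`): SNPs with QUAL ≥ 30, at
   least 10 variant-supporting reads, at least 30 total high-quality
   reads, and a homozygous genotype.  Heterozygous calls — alleles still
   segregating in the sequenced populations — would make a copy's
   fingerprint unstable between preparations, so only homozygous sites
   feed fingerprints.
2. **Fingerprinting and projection** (`annotate_te_snps`,
   `apply_variants`, `uniquely_identifiable`): SNP offsets inside each
   overlapped copy; substitution-only projection of the alternate
   bases; and a census retaining only copies whose raw sequence occurs
   once among all reference copies *and* whose projected sequence occurs
   once among all projections.  Both censuses treat a sequence and its
   reverse complement as equal.
3. **Cross-reference** (`cross_reference`): exact equality of the
   projected sequence with a query TE annotation's sequence, in either
   orientation.  One hit is a tracked pair; two or more hits are a
   duplication ambiguity (it cannot be decided which copy is the
   original); zero hits means the copy is not recoverable in the query
   annotation set.
4. **Movement calling** (`build_anchor_map`/`blocks_from_paf`, `lift`,
   `call_movements`): coordinate comparison and artifact filters,
   described below.

## Indels and fingerprints

Fingerprints are substitution-only.  An insertion or deletion
overlapping a TE changes its length and makes exact cross-referencing
ill-defined, so copies touched by an indel's reference span are dropped
from tracking, with a reported count.  This mirrors the projection
step, which applies *variant bases* to the reference sequence.

# The synteny map and expected coordinates

The movement decision needs, for every reference position, the
coordinate where an unmoved sequence is expected in the query.  Two
interchangeable sources feed the same `synteny_map` container:

* **PAF import** (`blocks_from_paf`): each alignment row at least 1 kb
  long on the reference axis becomes a block; overlapping reference
  spans are resolved by keeping the longer row.  This is the route to
  use with an external whole-genome aligner.
* **Internal anchor aligner** (`build_anchor_map`): anchors are k-mers
  (default k = 21, odd so that a k-mer can never equal its reverse
  complement) occurring exactly once in each genome, counting both
  strands.  Matched anchors are chained into *exactly collinear* runs:
  a chain extends only while the diagonal (query offset) is unchanged
  and the anchor gap is at most `max_gap` (default 10 kb).  Chains of
  ≥ 5 anchors become blocks.  Because every block is a gap-free
  coordinate translation, a lift inside a block is exact — the design
  premise is a low-divergence strain pair, where substitutions merely
  thin the anchors and every indel simply starts a new chain.

For movement calling the TE annotations of both genomes should be
passed as anchor masks (`run_track` does this automatically).  Anchors
whose k-mer overlaps an annotated TE are discarded: a moved copy's
interior is unique sequence present in both genomes and would otherwise
form a small, displaced "block" at its destination, which would make
the moved copy look unmoved.  Masking is the in-package analogue of
the common practice of not letting repeats anchor a whole-genome
alignment.

`lift` translates a position inside a block exactly; between blocks of
a chromosome pair it extrapolates from the nearest flanking block edge
and flags the result `interpolated`; outside every pair's span it
returns `unplaced`.  Start coordinates of excised copies always fall in
a between-block gap, and their nearest edge is the excision junction
itself, so interpolated expectations at source loci are junction-exact
up to the small drift of any indel inside the gap.

A caveat inherent to any alignment: in the outer k−1 bp of a block —
the indel-junction window — the assignment of identical flanking bases
to one side of the indel or the other (left- versus right-aligned
indels) is arbitrary.  Coordinate checks in the package's validation
therefore probe block interiors.

# Movement verdicts

For each uniquely matched pair, with tolerance *t* (default 100 bp):

* different query chromosome than expected → **inter** candidate;
* same chromosome, |observed − expected| ≤ *t* → **unmoved**;
* same chromosome, displacement > *t* → **intra** candidate, with
  `distance = |observed − expected|` in query-frame bp.

Candidates then pass two filters:

* **Nested exclusion**: a candidate fully contained in a different TE
  of the same family (in either genome) is `excluded_nested` — whether
  the inner copy moved locally within its enveloping element cannot be
  inferred from coordinates.
* **Flank filter**: the 50-bp sequences flanking the copy at its
  reference locus and at its query locus are aligned (upstream vs
  upstream, downstream vs downstream; swapped and reverse-complemented
  when the match was in flipped orientation).  If either flank reaches
  90 % identity the candidate is `excluded_flank`: near-identical
  flanks at both loci mean the "movement" is better explained by an
  alignment artifact between two repeat-flanked loci.

Matches found at two or more query loci are classified
`ambiguous_duplication` directly, without coordinate analysis.
Verdicts partition the matched set: every match receives exactly one of
`unmoved`, `intra`, `inter`, `ambiguous_duplication`,
`excluded_nested`, `excluded_flank`, `unplaced`.

## Alignment scoring and the identity formula

`local_align` is Smith–Waterman local alignment with a single affine
gap class, scored to match the "asm5" preset used for aligning
low-divergence assemblies: match +1, mismatch penalty 19, gap open 39,
gap extend 3 (a gap of length L costs 39 + 3L).  The preset's second,
long-gap affine component is dropped: on 50-bp flanks a gap long enough
to reach the long-gap regime cannot occur.  The implementation wraps
`Biostrings::pairwiseAlignment`; its score convention was verified
against, and is continuously tested against, an independently written
three-matrix dynamic program.

Identity is defined as the number of identical aligned columns in the
optimal local alignment divided by the length of the **longer** input,
not by the alignment length.  With heavy mismatch penalties the optimal
local alignment of unrelated flanks is a short exact word; dividing by
the full flank length makes such spurious hits score near zero, while
genuinely homologous flanks approach 1.  An empty optimal alignment has
score 0 and identity 0.

## Choices where the procedure was open

Several details of the published strategy admit more than one reading;
the package fixes them as follows, each behind a parameter:

* **Orientation**: matches are accepted in either orientation
  (`orientation_flip` recorded); transposition can invert a copy and
  exactness is preserved either way.
* **Uniqueness scope**: a copy must be unique in *both* the raw
  reference census and the projected census (the stricter reading).
* **Flank rule**: the filter rejects when *either* flank reaches the
  identity ceiling (`flank_rule = "either"`); requiring both can be
  selected.  Lowering the ceiling can only shrink the movement set
  (tested as a monotonicity property).
* **Filter scope**: the flank filter is applied to interchromosomal
  candidates as well (`filter_inter = TRUE`); the artifact it guards
  against is not specific to same-chromosome displacement.  Setting
  `FALSE` restores an intra-only filter.
* **Distance frame**: movement distance is reported in query
  coordinates, where both the observed and the expected position live.

# The interval enrichment engine

`enrichment_test` asks whether a variant interval set overlaps an
annotation interval set more (or less) than uniform placement predicts,
*within a workspace* — a restricted territory such as one chromosome's
combined arm domains.  Arms default to the two terminal thirds of each
chromosome (`arm_fraction = 1/3` per end, boundaries rounded half-down)
and are mutually exclusive with the center workspace; any domain
structure can be supplied as a BED file instead.

The statistic is nucleotide overlap, summed per variant interval
against the annotation union.  For disjoint variants (SNP sets) this
equals plain nucleotide overlap of the two unions; for overlapping
variant sets it matches the null, in which every interval is re-placed
**independently**, uniformly over all start positions that keep it
inside a single workspace segment, with lengths preserved and mutual
overlap permitted.  Using the same functional for the observed and the
null statistic is what makes the permutation p-value exactly
calibrated.  The default iteration count is 20,000; the validation
suite scales it to 1,000 per test to keep runtimes in seconds.

Reported per test: observed overlap, null mean and SD,
`log2((obs+1)/(null_mean+1))` (the +1 bp pseudocount keeps the fold
finite at zero overlap), a two-sided empirical p-value
`min(1, 2*min(p_enrich, p_deplete))` with
`p_enrich = (1+#{null ≥ obs})/(n_iter+1)`, and a hypergeometric tail
probability of drawing the observed-or-more annotated bases when
`variant_bp` bases are drawn without replacement from the workspace.
The hypergeometric mapping treats bases as exchangeable draws — an
analytic approximation that ignores interval contiguity; the empirical
p-value is the primary statistic, the hypergeometric one is reported
for comparability with association-testing tools that quote it.
No multiple-testing correction is applied across cells; the per-cell
significance level is the caller's choice.

Degenerate inputs: an interval longer than every workspace segment is
kept at a uniformly chosen largest segment and clipped, with a warning;
an empty workspace is an error.

# The synthetic genome pair

`simulate_reference` + `derive_query` generate the study conditions the
pipeline is validated under.  Defaults
(`simulation_params()`): three 500-kb chromosomes; ten TE families
(Zator most abundant, consensus lengths 190–2,600 bp, ~200 copies
total, each copy mutated from its family consensus at 2–3 % so copies
are distinguishable) placed with four-fold higher per-bp density on the
arm domains; background SNPs at 3/kb (arms) and 2/kb (center) — the
modest bias that puts about three quarters of variants on the
two-thirds of the genome that is arm; small indels (1–10 bp) at 0.8/kb
with the same arm bias, never inside TE copies; fingerprint SNPs inside
TE copies at 4/kb, slightly above the arm background so TE sequences
come out mildly variant-enriched; five intrachromosomal movements
(planted distances 300 bp – 150 kb), five interchromosomal movements,
and three distractors of each class:

* **nested**: a same-family 200-bp fragment written inside a long host
  copy and shifted within it in the query — must come out
  `excluded_nested`;
* **identical-flank**: a second locus carrying an exact copy of a TE's
  50-bp flanks is planted in the reference, and the copy moves onto
  that landing pad in the query — a true movement that the flank filter
  must reject (`excluded_flank`), the deliberate false-negative the
  filter trades for artifact robustness;
* **duplication**: the copy stays put and an identical second copy
  appears elsewhere — must come out `ambiguous_duplication`.

Movements are clean cut-and-paste: excision leaves no scar and
insertion adds no target-site duplication, because the detector
operates on annotated intervals and start coordinates, not excision
footprints.  Every moved or duplicated copy is forced to carry at least
one fingerprint SNP (an unfingerprinted copy is invisible to the method
by construction).  All SNPs and background indels are emitted in a
reference-frame VCF with plausible QUAL/AD/DP fields; TE movements are
structural events and deliberately absent from it.  The generator also
returns the exact reference→query coordinate map of every unedited
segment (`truth_lift`), which doubles as the independent oracle for the
liftover machinery, and a truth table pairing each planted event with
its expected verdict and query TE id.

Everything is driven by one master seed through labeled sub-seeds, so
the reference, the query derivation, and every pipeline stage are
independently reproducible and all outputs are byte-identical across
re-runs.

## What the simulation does not emulate

The generator's genomes are uniform-random DNA: no GC structure, no
tandem or low-complexity repeats, no gene content.  TE consensi are
random sequences, not real family models (no terminal inverted repeats,
no ORFs); excision scars and target-site duplications are off by
default; background indels never fall inside TE copies, so the
indel-overlap exclusion path is exercised only by dedicated unit
fixtures; and there is no read-level error model — the VCF is exact.
Passing validation therefore demonstrates the correctness of the
bookkeeping, matching, liftover, verdict logic, and statistics under
the stated divergence structure; it does not demonstrate robustness to
annotation errors or assembly artifacts in real data, where the flank
filter and the duplication/nesting exclusions are exactly the
safeguards that matter.

# Validation problem sizes

The shipped validation (test suite plus `scripts/acceptance.R`) uses:
1,000 random pairs of ≤ 60-mers against the brute-force affine DP
(score-exact); the full default synthetic run (3 × 500 kb, 10 planted
movements, 9 distractors) with 100 % verdict-and-pairing recall, zero
false movements, and intra distances within the 100-bp tolerance of
truth; a 2 × 150 kb pair with 50 planted indels for exact in-block
liftover at 1,000 interior probes; 500 null-calibration replicates at
1,000 iterations each (Kolmogorov–Smirnov uniformity at α = 0.01) plus
the 20-bp exhaustive enumeration whose null mean is exactly 0.25 bp;
100 power replicates at a planted two-fold density; and byte-identity
of re-run outputs for every subcommand.
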