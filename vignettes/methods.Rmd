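---
title: "Methods: diffing near-identical genomes and censusing their transposons"
author: "twindiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffing near-identical genomes and censusing their transposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twindiff)
```

## The problem

Two bacterial strains can be phenotypically different while their genomes
are almost identical. The motivating case is a pair of filamentous
sulfur-oxidising *Beggiatoa leptomitoformis* strains in which one strain
has lost the ability to grow lithotrophically on reduced sulfur compounds:
the genomes differ only by a handful of point events and a set of
multi-hundred-bp insertions, most of which turn out to be insertion-sequence
(IS) transposons, one of them sitting inside the gene for the sulfur-globule
envelope protein. Resolving such a case requires four linked analyses:

1. **diff** two assemblies base-exactly and classify every discrepancy as a
   substitution, a one-letter indel, or a *long insert* (a contiguous
   inserted run of at least 2 bp);
2. **type** the differential long inserts into families by pairwise
   identity, with neighbor-joining trees and bootstrap support as the
   supporting evidence;
3. **census** each family genome-wide: decide whether it is a transposon by
   its terminal inverted repeats (TIR) and target-site duplications (TSD),
   and enumerate every additional copy by exact TIR match, full-length or
   truncated;
4. map every insertion and small variant onto the **gene annotation** to
   call disrupted genes, frameshifts and synonymous changes, and compare a
   configured panel of sulfur-metabolism genes across the pair.

Every stage is validated against a synthetic strain-pair generator that
implants events with a machine-readable truth table.

## Whole-genome diff

### Anchors and chaining

The two sequences are anchored on shared *unique* k-mers: a k-mer anchors
only if it occurs exactly once in each genome (k = 21 by default, minimum
15; k-mers containing N never anchor). Uniqueness makes the anchor set
immune to the dispersed transposon copies the genomes share — repeated
sequence simply cannot anchor — which is exactly the property a mobile-
element-rich genome pair needs. A maximum-cardinality collinear subset is
selected by patience-sorting longest-increasing-subsequence on the second
coordinate (O(n log n), compiled); at every chain length the smallest
feasible ending coordinate is kept, which makes the chain deterministic.
A drift-minimising tie-break among equal-cardinality chains would require
quadratic dynamic programming over hundreds of thousands of anchors and is
not implemented; ties essentially never arise on near-identical genomes,
where anchors are dense and collinear. Overlapping neighbours are trimmed
(starts moved forward in both genomes) and abutting same-diagonal anchors
merged, so the per-gap work scales with the number of discrepancies rather
than with genome length.

### Gap classification

Each inter-anchor gap is classified: an empty-versus-nonempty gap is an
inserted run directly (`long_insert` if at least 2 bp, else `indel_1bp`);
equal-length gaps with Hamming distance at most `substitution_ceiling`
(default 5) become that many substitutions; everything else is decomposed
by end-gap-penalised Needleman–Wunsch (match 1, mismatch −1, gap −2,
deterministic traceback preferring diagonal, then a gap in the second
sequence). The Hamming shortcut is provably score-optimal for d ≤ 2; for
3 ≤ d ≤ 5 a shifted-identity segment could in principle score better with
gaps, but such segments cannot occur between anchors of near-identical
genomes, and the shortcut is tested against a full-DP oracle on random
gaps.

### Canonical insertion coordinates

An insertion inside repeated sequence has no unique position, and TSDs
guarantee repeated sequence at element boundaries. All inserted runs —
called and simulated alike — are therefore left-normalised (while the base
before the run equals the run's last base, rotate the run one position
left). Exact-coordinate comparisons between calls and truth are defined on
this canonical form. The core self-consistency property, tested on every
synthetic pair and on random fuzz, is that applying the variant list to
genome A reconstructs genome B byte-exactly.

`aligned_identity` is matched columns over all aligned columns (inserted
runs count as columns), and `chain_coverage` below 0.5 in either genome
aborts with a "not near-identical" error. For circular replicons an
optional pre-rotation aligns the origins before diffing.

## Insert typing

Family assignment is single-linkage clustering at 90% pairwise identity.
The pipeline types the *elements*, not the raw inserted runs: each called
run is first canonicalised by the terminal-repeat detector (TSD stripped,
rotation resolved; see below), falling back to the run as called when no
terminal repeat exists. A left-normalised run drags a few bases of
site-specific target context along, and between opposite-orientation
copies that context sits at opposite ends and costs 1–3 percentage points
of spurious divergence; published within-family identities refer to the
element sequences, so that is what is compared. Identity for *typing* is
percent matched columns over the full global alignment, gap columns
counted as differences, and each pair is scored in both relative
orientations (copies insert on either strand; the better orientation
wins). Two further design points deserve justification:

* **Why not the gap-excluding p-distance here?** The p-distance excludes
  gap columns from both numerator and denominator, which is right inside an
  alignment of homologous sequences but pathological between unrelated
  sequences of very different lengths: the aligner concentrates the length
  difference into excluded gap columns and the remaining compared columns
  are mostly matches, rating a random 378 bp / 853 bp pair at 87–90%
  "identity". Under single linkage at 90% that occasionally chains separate
  families. The gap-inclusive measure rates the same pair below 50% and
  cannot chain them.
* **Threshold 90 vs reported >97.** The linkage threshold is deliberately
  permissive; the realised minimum within-type identity is computed and
  reported per type, so the much tighter observed figure (>97% under the
  default generator) is verified rather than assumed.

Types are numbered by decreasing member count. For trees, distances are
the canonical gap-excluding p-distance (mismatched over compared columns),
computed on pairwise alignments or on a star-anchored multiple alignment
(all members projected onto the longest member's columns; insertions
relative to the reference are discarded). The star MSA is crude but
deterministic and adequate for families above ~97% identity; it only feeds
the bootstrap.

Neighbor joining is the canonical agglomerative algorithm: join the pair
minimising the Q-criterion, pendant lengths from the two-point formulas,
negative branch lengths clamped to zero with the deficit moved to the
sister branch so path lengths are conserved, Q-ties broken on the
lexicographically smallest pair of representative leaf labels. On additive
matrices the generating tree is recovered exactly (tested for 4–10 leaves,
and against an independent implementation). Bootstrap support resamples
alignment columns with replacement (a multinomial reweighting of the
per-column mismatch counts, so replicates cost one matrix-vector product),
rebuilds the tree, and reports the percentage of replicates containing
each internal bipartition of the master tree; with all-zero distances the
topology carries no signal and supports are defined as 100.

## Transposon identification and census

### Terminal repeats

The TIR is the longest exact prefix of the element equal to the reverse
complement of its suffix (N never matches). Because insert calls are
left-normalised, the TSD travels *inside* the called run and the run may be
rotated relative to the element whenever the insertion context repeats.
The detector therefore searches left-rotations of the run (a rotation is a
valid alternative placement exactly while the run's prefix matches the
sequence following it) combined with a trailing TSD strip, and scores each
candidate as TIR length plus the length of a *validated* TSD — one whose
word also immediately precedes the element at that placement. The score
resolves the parse ambiguity created by self-complementary targets, where
two boundary choices both look structurally valid.

A single insertion site can still extend a member's terminal palindrome by
a base or two by chance, so the *type-level* TIR is fixed by cross-member
support: among all member-level candidates, the TIR found in the largest
number of members wins (rotations are handled by searching the doubled
run), ties broken by length. A type is a transposon iff a supported TIR of
at least `min_tir_len` (default 10 bp) exists; by default TSDs of at least
`min_dr_len = 3` bp are reported. Element-terminal direct repeats
(prefix = suffix) are detected and reported separately from TSDs, since
published descriptions of "direct repeats at element ends" can mean either.

### Copy census

The census finds every exact occurrence of the TIR and of its reverse
complement on the forward strand (an element and its reverse complement
present the same terminal pattern, so one scan covers both strands), pairs
each left occurrence with the nearest downstream right occurrence whose
span lies in the length window, and accepts candidates greedily shortest-
span-first so copies never overlap. Exact matching only — mismatch-tolerant
scanning is out of scope by design. With the default window unset, the scan
runs with a lower bound of 0.3× the consensus length and then keeps copies
within [0.3, 1.05]× the *longest copy found*: this is what lets the census
discover full-length elements (1731 and 1660 bp in the default conditions)
that are twice the length of the truncated differential inserts that
defined the family. Orientation is assigned by comparing the first stretch
of core against the consensus in both orientations (Hamming, window
100 bp). A copy is full-length iff its length is within 10 bp of the
longest copy of its type. Differential-insert loci are flagged so
"additional" copy tallies can exclude them.

### Excision scars

A transposon that leaves a site excises between the two copies of its TSD,
leaving a tandem duplication of the target; a site that never received an
element shows a single target copy. Differential long inserts that do not
carry a known family's TIR are tested for being an exact tandem duplication
of their own flank (insert length between `dr_len` and 25 bp); such sites
are reported as scars, all others as pre-insertion sites. The simulator can
implant scars to exercise this path; under the default conditions none are
implanted and none may be found.

## Annotation impact

Events are intersected with CDS features under closed-interval semantics
(touching a boundary counts as overlap). A long insert or element copy in a
CDS disrupts the gene; a 1-bp indel in a CDS is a frameshift; a CDS
substitution is translated in frame with the bacterial genetic code
(translation table 11) to call synonymous / missense / nonsense. Outside
CDS, a strand-aware window upstream of a CDS start (default 150 bp — the
notion of "promoter region" is not standardised, so the window is a
documented, configurable choice) is classified as promoter; everything else
is intergenic. The gene-panel comparison extracts each panel gene's CDS and
promoter window from both genomes, aligns them globally and reports percent
identities; a panel for the dissimilatory sulfur-metabolism genes of the
two *B. leptomitoformis* strains (locus tags for soxYZ/AX/B/F, sqr,
dsrEFHC, soeABC) ships with the package.

## The synthetic strain-pair generator

The generator is first-class, tested code, and its defaults *are* the
package's reference study conditions:

* 200 kb ancestor at 40% GC (typical for *Beggiatoa*) with 100
  non-overlapping ORFs of 300–1500 bp (start codon, sense codons at the
  background composition, stop codon);
* three element families: two TIR-bearing transposon types whose mobilised
  form is a truncated copy of a longer full element (853 of 1731 bp with a
  24 bp TIR; 782 of 1660 bp with a 26 bp TIR; both with 4 bp TSDs), and one
  378 bp family without terminal repeats;
* eight differential inserts per strain (A: 7 + 1; B: 3 + 4 + 1, so the
  second transposon family occurs only in strain B), one of the strain-B
  type-2 inserts placed inside a CDS and recorded as the disrupted locus;
* 42 shared dispersed copies (30/10/2 per family, one full-length copy per
  transposon family) implanted in the ancestor so both strains inherit them
  identically;
* four one-letter indels and one substitution, placed intergenically so
  every undisrupted ORF keeps translating (a liftover invariant the tests
  assert);
* 0.5% per-base core divergence per implanted copy (never in TIRs or
  TSDs), so realised within-type identities are high but not exactly 100%.

Scale is a deliberate choice: 200 kb keeps the full end-to-end run in
seconds while leaving anchor density, copy counts and event spacing in the
same regime as a megabase genome; the generator accepts any
`genome_length` for larger runs. Events are placed by rejection sampling
with a 50 bp exclusion margin (so each event falls in its own anchor gap),
genes are avoided except by the designated disruptor, and a master seed
spawns per-stage substreams, making every output bit-reproducible from
`(config, seed)`.

Two construction details prevent silent artifacts. Element cores are
resampled until the first core base does not complement the last used core
base of either the full or the truncated form — otherwise *every* copy of a
family would carry a one-base-longer terminal palindrome than the element's
true terminus. And truth coordinates for inserted runs are left-normalised
with the same rule the diff applies, so "exact coordinate recovery" is
well defined inside duplicated targets.

What the generator does **not** emulate: sequencing or assembly error
(inputs are finished assemblies by assumption), genome rearrangements,
phylogenetically realistic substitution processes, degenerate or nested
element copies, and mismatch-accumulating TIR decay. Passing tests
therefore demonstrate correctness of the algorithms under the stated event
model, not robustness to assembly artifacts.

## Numerical and degenerate-input choices

* Alignment scoring is integer (match 1 / mismatch −1 / gap −2) everywhere;
  traceback ties prefer diagonal, then consuming the first sequence.
* p-distance on zero compared columns is an error, not NaN; bootstrap
  replicate distances with zero compared columns are defined as 0.
* NJ Q-ties: lexicographically smallest representative label pair;
  negative branch lengths clamped with transfer to the sister branch.
* `chain_coverage < 0.5` in either genome is a hard error; genomes that
  dissimilar are outside the method's contract.
* Single census copies are full-length by definition; palindromic TIRs are
  excluded at generation and self-pairing is suppressed by requiring spans
  of at least twice the TIR length.
* Translation of a CDS whose length is not a multiple of 3 drops the
  trailing partial codon with a warning.

## Reproducing the analysis

```{r, eval = FALSE}
sim <- simulate_strain_pair(sim_config(), seed = 1)
res <- run_pipeline(sim$genomes$strainA, sim$genomes$strainB,
                    sim$features$strainA, sim$features$strainB)
score_against_truth(res, sim$truth)
write_report_tables(res, "twindiff_out")
```

`scripts/acceptance.R` wraps exactly this computation and writes the
headline numbers as JSON. To analyse a real pair of assemblies, convert
them to FASTA + GFF3 (GenBank flat files are not parsed natively; e.g.
Biopython's `SeqIO.convert` plus any GenBank-to-GFF3 converter) and call
`run_pipeline()` on the loaded genomes, or use the bundled command-line
front end in `inst/scripts/twindiff.R`.

## Known limitations

* Inversions and translocations are not called; the chain-coverage floor
  only detects that something large is wrong. The motivating genome pair
  has no large rearrangements.
* Exact-coordinate agreement with any particular external aligner is not
  guaranteed — alignment of insertions inside repeats is inherently
  ambiguous — only count-level agreement and the reconstruction property.
* The star MSA discards insertions relative to the reference member;
  bootstrap supports on families with long member-specific insertions
  would be approximate.
* The census is exact-match by design; decayed copies with mutated TIRs
  are invisible to it.
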