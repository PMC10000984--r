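---
title: "Consensus taxonomic assignment and benchmarking for meat metabarcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus taxonomic assignment and benchmarking for meat metabarcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabar)
```

## The problem

Amplicon metabarcoding of a short mitochondrial marker (here the ~75 bp 16S
rDNA fragment used for meat speciation) identifies all animal components of
a mixed food sample at once. After read preprocessing and clustering —
both outside the scope of this package — each read cluster is searched
against a large reference collection, and the computational core of the
analysis consists of:

1. deciding, from a noisy list of similarity-search hits, which taxon each
   cluster belongs to;
2. turning per-cluster assignments into a per-sample composition and
   deciding which components are real;
3. quantifying how well the whole chain performs against samples of known
   composition; and
4. predicting, before any sequencing happens, how well a primer pair can
   distinguish taxa at all.

`metabar` implements these four stages plus a synthetic data generator so
the entire chain can be exercised and validated without any external
database or sequencing run.

## Consensus assignment model

Hits are filtered in two stages. Hard filters keep a hit only if

* `evalue <= max_evalue` (default `1e-10`),
* `pident >= min_pident` (default 97%), and
* query coverage `100 * (qend - qstart + 1) / qlen >= min_qcov_percent`
  (default 100%).

Coverage is recomputed from the alignment coordinates rather than read
from a tool-specific coverage column, so any outfmt-6-style table works.
The e-value cut is applied as a post-filter even where the search tool
already accepts it as a search parameter; the retained hit set is the
same. A per-cluster *bitscore window* then keeps only hits within `delta`
bits (default 4) of the cluster's best bitscore. The bitscore depends only
on the alignment, not on database size, which makes this filter stable as
reference collections grow — unlike an e-value cut.

The surviving hits of a cluster vote for a taxon. The vote is taken over
the **unique** taxon set, not over raw hits, so a taxon with a thousand
reference entries does not outweigh one with a single entry. Given votes
and a consensus level $X \in (0.5, 1]$, the assignment is the deepest
taxonomy node whose subtree covers at least $X$ of the votes. Because
$X > 0.5$, at most one child can qualify at each depth, so the descent
from the root is unambiguous and no tie-breaking rule is needed; levels
at or below 0.5 are rejected outright. At $X = 1$ the consensus is
exactly the last common ancestor. The comparison is `>= X`, so a
fraction exactly at the level qualifies. The default level 0.51 is a
strict majority vote.

Duplicate entries in the vote list count multiply in `consensus_taxon()`
itself; dereplication to unique taxa is done by the caller
(`assign_cluster()`). This separates the voting mechanism from the
assignment policy and keeps both independently testable.

Taxonomy handling follows NCBI taxdump conventions: "no rank" nodes stay
in lineages but never answer rank queries; merged taxids remap silently
(with a `message()` as a log record); unknown taxids raise an error rather
than disappearing.

## Compositions and the detection threshold

A sample's composition maps each assigned taxid to its read count and its
proportion of **all assigned reads**. Clusters with no surviving hit are
reported as unassigned and never enter the denominator. A detection
threshold $T$ (default 0.001, the 0.1% operating point) removes entries
with `proportion < T`; an entry at exactly $T$ survives, so the published
operating point includes its own boundary. Proportions are **not**
renormalized after thresholding — they remain interpretable as fractions
of assigned reads, and the benchmark uses the same convention on both
sides of every comparison.

Evaluation at a fixed rank (typically genus) replaces every entry by its
lineage ancestor at that rank and merges counts. An entry assigned above
the rank (or whose lineage skips it) keeps its node and is flagged
`above_rank`; such entries can never match an expected component and are
counted as false positives. When matching against expectations the rollup
happens first and the threshold is applied to the rank-level proportions;
the two orders only differ when several sub-threshold congeners sum past
the threshold, and applying the threshold at the evaluation rank keeps
"what is reported at this rank" and "what is evaluated at this rank"
identical.

## Benchmark metrics

Matching observed to expected compositions at a rank is open-world (no
true negatives): TP are observed rank-level nodes equal to an expected
node, FP the remaining observed entries, FN the unmatched expected
entries. Aggregate counts over a sample set give

$$P = \frac{TP}{TP+FP}, \qquad R = \frac{TP}{TP+FN},$$

reported as exact fractions; an undefined ratio is absent, not zero. For
display the package rounds half away from zero to integer percent, the
raw fractions are always kept in machine output. Derived scores:

* $F_\beta = (1+\beta^2)PR / (\beta^2 P + R)$, default $\beta = 2$, which
  weights recall twice as heavily as precision — the right asymmetry for a
  screening method where a missed species is worse than a spurious one;
* the geometric mean $\sqrt{PR}$, a single qualitative accuracy number;
* the Euclidean (L2) distance between rank-level proportion vectors
  indexed by the union of taxa (absent components count 0);
* the signed relative error $(p_{pred} - p_{exp})/p_{exp}$ of each
  true-positive component;
* the yield, the fraction of input reads surviving to assignment, also
  reported per stage; and
* the splitting level $\log_{10}(\text{clusters}/\text{expected
  components})$ — 0 means one cluster per true sequence, 1 means each
  true sequence splits over ten clusters.

The detection-threshold sweep recomputes the aggregate confusion on a
regular grid (step 0.0001, i.e. 0.01% of total composition) from 0 to
just above the largest observed proportion, and reports the smallest
threshold attaining the maximal $F_2$. Recall is non-increasing in the
threshold; precision need not be monotone. The sweep should be fed
**pre-threshold** compositions (`composition_full` from
`run_assignment()`, or the `assign` CLI command with `--threshold 0`);
sweeping already-thresholded tables trivially returns the threshold that
produced them.

## Seeded down-sampling

Sequencing-depth experiments need reproducible random subsets.
`downsample_reads()` concatenates the decimal digits of the sample size
and the replicate index into the RNG seed (size 1000, replicate 2 → seed
10002), draws that many read pairs without replacement, applies the same
index set to both mates, and writes them in input order. The same
arguments therefore always produce byte-identical files, and mate pairing
is preserved by construction. The Mersenne-Twister generator with
rejection sampling is pinned explicitly so the index set does not depend
on the R session's RNG defaults.

## Barcode resolution analysis

`match_primer()` performs ungapped sliding-window matching with IUPAC
semantics: a degenerate primer position matches any base of its expansion
set, an N in the target matches nothing. Matching thresholds follow the
Primer-BLAST-style operating point: at least 80% of the primer aligned
and at least 65% identity over the aligned span. Coverage is anchored to
the primer 3' end — the 3'-proximal part of the primer must lie on the
target, and truncated alignments are only considered where the primer 5'
end would overhang a target boundary; interior placements are always
full length. For each 3'-end placement the longest qualifying span is
reported once.

`extract_barcodes()` emits the inter-primer sequence of every facing
primer placement within a maximal product length (default 2000 bp),
primers removed, minus-strand products reverse-complemented so all
barcodes share the forward orientation — which makes the whole extraction
invariant under reverse-complementing the reference, a property the test
suite checks. Barcodes are dereplicated taxon-wise: one representative
per (taxid, exact sequence), so identical sequences from different taxa
remain distinct.

Pairwise identities come from end-to-end Needleman–Wunsch alignment
(match +2, mismatch −4, gap open −20, gap extend −2, computed with
Biostrings). The hamming distance is the number of non-identical
alignment columns — mismatches plus gap columns — and identity is
$1 - \text{hamming}/\text{alignment length}$. Using the alignment length
as denominator keeps the formula well defined for unequal sequence
lengths; the scoring constants are common global-aligner defaults and are
documented rather than claimed to reproduce any particular aligner's
internals.

For each barcode and identity level, all set members within the level
(inclusive, always including the barcode itself — a sequence is trivially
within any identity level of itself) vote by unique taxon at the same
strict-majority level (0.51) used for read assignment. The summary
reports the share of barcodes resolved at species-or-below and
genus-or-below per identity level, where "at or below rank r" means the
consensus node's lineage contains a node of rank r. Shrinking the
neighborhood (raising the identity level) can only remove voters, so the
consensus depth is non-decreasing in the level — also property-tested.

## The synthetic data generator

`fixture_spec()` describes a miniature study: a taxonomy of species under
genera under families, one reference sequence per species embedding
`forward primer + 75 bp species-specific insert + revcomp(reverse
primer)`, and per-sample compositions realized as read clusters. It
emulates the structure of reference-material experiments:

* compositions enriched for components around 1%, the usual legal
  labeling limit, with a dominant background component;
* read depth 5000 per sample — the depth at which recall stops improving
  in down-sampling experiments, and small enough to keep tests fast;
* decoy hits around every true hit that the default filters must remove:
  one below the 97% identity floor, one 6 bits under the best hit
  (outside the Δ = 4 window), one with partial query coverage, one above
  the e-value ceiling;
* noise clusters assigned to off-plan genera, each below 0.05% of the
  sample — mirroring the trace contaminations observed in real
  proficiency-test material (unintentional goat or red deer traces)
  without simulating sequencing-error chemistry;
* sister-species barcode divergence controlled exactly (default 3
  substitutions on the 75-mer; 0 produces the shared-barcode corner
  case), genera separated by 8 substitutions.

Planted proportions are fractions of the *total* read depth, so the
realized proportion of a component differs from its design value only by
read-count rounding, at most `0.5/depth` per component; the end-to-end
recovery tests assert `<= 1/depth`. All randomness derives from the spec
seed with fixed offsets; two runs of any generator are byte-identical.

What the generator does **not** emulate: sequencing error profiles and
quality scores, chimera formation, cluster splitting noise (available
only through the explicit `clusters_per_component` knob), database
mislabeling, or taxa missing from the reference. A perfect
precision/recall result on these fixtures therefore validates the
*arithmetic and plumbing* of the chain — filters, votes, thresholds,
matching — not the field performance of any wet-lab protocol or of a
live reference database.

## Numerical and design choices

* Threshold comparisons are inclusive (`>= T` survives, identity
  `>= level` joins a neighborhood) so published operating points contain
  their boundaries.
* The sweep breaks F2 ties toward the smallest threshold, matching the
  convention of reporting a single optimal value.
* "Average precision" is implemented as the geometric mean of precision
  and recall (`gpr()`), the definition used in this validation context;
  the area-under-PR-curve quantity of the same name in some libraries is
  deliberately not implemented.
* Species-level evaluation counts clusters assigned above species as
  false positives at that rank; they are flagged `above_rank` so callers
  can report them separately.
* Expected compositions may sum to less than 1 (trace-contaminated
  reference material); they are never renormalized.
* Multi-taxid subject rows expand to one hit per taxid before unique-taxon
  dereplication, so a shared reference sequence contributes each of its
  taxa one vote.
* Merged taxids remap with a log message; deleted taxids raise. Silent
  loss of data is the one behavior always avoided.
* The per-cluster vote is unweighted; weighting by hit count or bitscore
  is not offered because no validated operating point exists for it.

## Problem sizes used by the test suite

Property tests run 1000 random taxonomies of up to 50 nodes against a
brute-force node-enumeration oracle for the consensus, 200 more for
lineage/permutation properties, and three random fixture specs
end-to-end; the complete suite runs in under two minutes on one core.
The acceptance script regenerates a three-sample, 15000-read fixture and
runs the entire assignment → benchmark → sweep → barcode chain in about
fifteen seconds.

## Limitations

* The consensus descent is linear in (votes × lineage depth) and the
  taxdump loader is linear in file size; both are meant for the
  desk-scale trees of validation work, not tuned for the full 2.5M-node
  NCBI tree (loading it works but takes minutes).
* `global_identity()` accepts plain ACGT sequences only; ambiguity codes
  in extracted barcodes are rare and should be cleaned upstream.
* The identity matrix is dense O(n²); for thousands of barcodes per
  taxon-neighborhood, compute it blockwise or pre-cluster.
* Conspecific probability — how often a barcode's nearest neighbor is a
  member of the same species — is out of scope here.
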