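# metabar

Consensus taxonomic assignment, validation metrics and barcode-resolution
analysis for DNA metabarcoding, aimed at meat and food authentication with
short mitochondrial markers (e.g. the ~75 bp 16S rDNA fragment used for
meat speciation).

Metabarcoding identifies every animal component of a mixed sample at
once, but between the similarity search and a defensible answer sit
several bespoke computations. `metabar` provides them as plain R
functions:

* **taxonomy** — an NCBI-taxdump loader (`nodes.dmp` / `names.dmp` /
  `merged.dmp`) with lineage, last-common-ancestor and
  fractional-consensus queries over the taxid tree;
* **assignment** — filtering of tabular (outfmt-6-style) hits and a
  majority-vote consensus assignment per read cluster. Hits survive
  `evalue ≤ 1e-10`, identity ≥ 97 %, query coverage ≥ 100 % and a
  per-cluster bitscore window of Δ = 4 bits; the retained hits'
  **unique** taxa then vote, and the cluster is assigned the deepest
  taxonomy node covered by at least X = 0.51 of the votes (X = 1 is the
  LCA). Compositions report each taxon's fraction of assigned reads,
  with a detection threshold T = 0.1 % and no renormalization;
* **benchmark** — open-world confusion counts at a chosen rank,
  precision P = TP/(TP+FP), recall R = TP/(TP+FN),
  F<sub>β</sub> = (1+β²)PR/(β²P+R) with β = 2, geometric-mean
  precision-recall √(PR), Euclidean distance between composition
  vectors, signed relative errors (p̂−p)/p, yields, splitting levels
  log₁₀(clusters/components), an F2-optimizing threshold sweep in 0.01 %
  increments, and seeded pairing-preserving FASTQ down-sampling;
* **barcode** — in-silico PCR: degenerate-primer matching (80 %
  coverage, 65 % identity, 3'-anchored), inter-primer barcode
  extraction, taxon-wise dereplication, global-alignment identity
  matrices and the consensus rank each barcode resolves at per identity
  level;
* **fixtures** — a seeded generator for synthetic taxonomies, reference
  sequences, hit tables with filterable decoys, sample compositions with
  sub-threshold noise, and paired FASTQ, so everything above is testable
  offline.

## Worked example

Generate a synthetic dataset, assign one sample, and benchmark all three
(the command-line wrapper in `inst/cli/metabar.R` drives the same
functions):

```r
library(metabar)

spec <- fixture_spec(seed = 5)           # 8 species, 3 samples, 5000 reads each
fx   <- make_fixture(spec, "fx")
tax  <- load_taxdump("fx/taxdump/nodes.dmp", "fx/taxdump/names.dmp")

hits <- parse_blast_tab("fx/hits_s1.tsv")
res  <- run_assignment(hits, fx$samples$s1$counts, tax, sample_id = "s1")
res$composition
#>   sample_id taxid reads proportion
#> 1        s1  1001  4495     0.8990
#> 2        s1  1002   250     0.0500
#> 3        s1  1003   150     0.0300
#> 4        s1  1005   102     0.0204
```

The two noise clusters planted in `s1` (3 reads in an off-plan genus,
0.06 % of assigned reads) were removed by the 0.1 % detection threshold;
the four planted components are recovered at exactly their design
proportions. Benchmarking the full set against the planted expectations
at the genus level:

```r
obs <- lapply(names(fx$samples), function(sid) {
  h <- parse_blast_tab(sprintf("fx/hits_%s.tsv", sid))
  run_assignment(h, fx$samples[[sid]]$counts, tax,
                 sample_id = sid)$composition_full
})
names(obs) <- names(fx$samples)
expd <- lapply(fx$samples, `[[`, "expected")

benchmark_compositions(expd, obs, tax, "genus", threshold = 0.001)
#> benchmark: TP 11 FP 0 FN 0 | precision 100% recall 100%

pr_threshold_sweep(expd, obs, tax, "genus")$optimal_threshold
#> [1] 7e-04
```

All 11 genus-level components are recovered with no false calls, and the
sweep places the optimal detection threshold at 0.07 % — above the
planted noise (≤ 0.06 %) and far below the smallest real component
(0.96 %), rounding to the 0.1 % operating point used in routine
analysis. Predicted resolution of the primer pair on the same reference
panel:

```r
bc <- dereplicate_taxonwise(extract_barcodes(
  fx$references$sequences, fx$references$taxid_map, fixture_primers()))
resolution_summary(bc, tax)$summary
#>   identity_level pct_species_or_below pct_genus_or_below
#> 1           0.97                  100                100
#> 2           1.00                  100                100
```

Every taxon's 75 bp barcode is distinct enough (sisters differ by 3
substitutions, genera by 8) that a strict-majority consensus resolves
all barcodes at species rank at both clustering identities.

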