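test_that("primer matching implements IUPAC semantics on both strands", {
  # exact full-length match
  m <- match_primer("ACGTACGT", paste0("TTTT", "ACGTACGT", "GGGG"))
  plus <- m[m$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(c(plus$start, plus$end, plus$mismatches), c(5, 12, 0))
  # degenerate positions match any base of their expansion set
  my <- match_primer("CAYR", "GGCATAGG")
  expect_true(any(my$strand == "+" & my$mismatches == 0))
  # N in the target matches nothing
  mn <- match_primer("ACGT", "ACNT")
  expect_false(any(mn$mismatches == 0))
  # reverse-complement occurrences are found on the minus strand
  target <- paste0("TT", revcomp("ACGTTGCA"), "AA")
  mm <- match_primer("ACGTTGCA", target)
  expect_true(any(mm$strand == "-" & mm$mismatches == 0))
  # primer longer than target: no result
  expect_equal(nrow(match_primer("ACGTACGTACGT", "ACG")), 0L)
})

test_that("identity and coverage thresholds gate reported matches", {
  primer <- strrep("A", 20)
  with_mm <- function(k) {    # k mismatches in a 20-bp window
    paste0(strrep("A", 20 - k), strrep("C", k))
  }
  # 6 mismatches: identity 0.70 >= 0.65, reported
  m6 <- match_primer(primer, with_mm(6))
  expect_true(any(m6$strand == "+" & m6$length == 20 & m6$mismatches == 6))
  # 8 mismatches: full-length identity 0.60 < 0.65, rejected (shorter
  # boundary-anchored spans are judged on their own identity)
  m8 <- match_primer(primer, with_mm(8))
  expect_false(any(m8$length == 20))
  # 3'-anchored partial coverage: primer 5' end may overhang the target
  part <- match_primer("GGGGACGTACGTACGTACGT", "ACGTACGTACGTACGTTTTT")
  expect_true(any(part$strand == "+" & part$start == 1 & part$length == 16))
})

test_that("barcode extraction requires facing primers and normalizes strand", {
  pair <- primer_pair("ACGGTCTAGCCTGACGTCAT", "TGCAGCACCTTGAGGACGTA")
  insert <- paste(rep(c("A", "C", "G", "T"), length.out = 75), collapse = "")
  amplicon <- paste0("TTTTT", pair$forward, insert, revcomp(pair$reverse),
                     "AAAAA")
  map <- data.frame(sequence_id = "r1", taxid = 9913L)
  bc <- extract_barcodes(c(r1 = amplicon), map, pair)
  expect_equal(nrow(bc), 1L)
  expect_equal(nchar(bc$sequence), 75L)
  expect_equal(bc$sequence, insert)
  expect_equal(bc$end - bc$start, 75L)          # 0-based half-open span
  # the reverse-complemented reference yields the same barcode sequence
  bc_rc <- extract_barcodes(c(r1 = revcomp(amplicon)), map, pair)
  expect_equal(bc_rc$sequence, insert)
  expect_equal(bc_rc$strand, "-")
  # outward-facing primers flank nothing
  outward <- paste0("TTTTT", revcomp(pair$reverse), insert, pair$forward,
                    "AAAAA")
  expect_equal(nrow(extract_barcodes(c(r1 = outward), map, pair)), 0L)
  # records without a taxid are skipped with a warning
  expect_warning(
    none <- extract_barcodes(c(r2 = amplicon),
                             data.frame(sequence_id = "r1", taxid = 1L),
                             pair),
    "skipped")
  expect_equal(nrow(none), 0L)
})

test_that("taxon-wise dereplication scopes uniqueness within each taxid", {
  bc <- data.frame(taxid = c(1L, 1L, 2L, 1L),
                   sequence = c("AA", "AA", "AA", "CC"),
                   source_id = sprintf("r%d", 1:4),
                   start = 0L, end = 2L, strand = "+",
                   stringsAsFactors = FALSE)
  dr <- dereplicate_taxonwise(bc)
  expect_equal(nrow(dr), 3L)                    # {1:AA, 2:AA, 1:CC}
  expect_equal(dr$count[dr$taxid == 1 & dr$sequence == "AA"], 2L)
  expect_equal(dr$count[dr$taxid == 2 & dr$sequence == "AA"], 1L)
})

test_that("global identity counts non-identical alignment columns", {
  expect_equal(global_identity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_equal(global_identity("ACGT", "ACGA"), 0.75)
  seq75 <- paste(rep(c("A", "C", "G"), length.out = 75), collapse = "")
  two_subs <- paste0("TT", substr(seq75, 3, 75))
  expect_equal(global_identity(seq75, two_subs), 1 - 2 / 75)
  three_subs <- paste0("TTT", substr(seq75, 4, 75))
  expect_lt(global_identity(seq75, three_subs), 0.97)
  # an indel counts against identity through the alignment length
  expect_lt(global_identity("ACGTACGT", "ACGTCGT"), 1.0)
  # symmetry and self-identity on random sequences
  set.seed(13)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 28, TRUE), collapse = "")
    expect_equal(global_identity(a, a), 1.0)
    expect_equal(global_identity(a, b), global_identity(b, a))
  }
})

test_that("identity matrices are symmetric with unit diagonal", {
  bc <- data.frame(taxid = 1:3,
                   sequence = c("ACGTACGTAC", "ACGTACGTCC", "TTGTACGTAC"),
                   stringsAsFactors = FALSE)
  m <- identity_matrix(bc)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(1, 3))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("resolution summary reports the consensus rank per identity level", {
  spec <- fixture_spec(seed = 2, divergence = 3)
  tax <- local({
    td <- make_taxonomy(spec)
    load_taxdump(td$nodes_path, td$names_path)
  })
  refs <- make_references(spec)
  bc <- dereplicate_taxonwise(
    extract_barcodes(refs$sequences, refs$taxid_map, fixture_primers()))
  # every taxon's barcode is > 3% away from other taxa: species everywhere
  rs <- resolution_summary(bc, tax)
  expect_equal(rs$summary$pct_species_or_below, c(100, 100))
  expect_equal(rs$n_taxids, 8L)
  expect_equal(rs$median_length, 75)

  # sister species sharing one barcode resolve at genus at identity 1.0
  spec0 <- fixture_spec(seed = 2, divergence = 0)
  refs0 <- make_references(spec0)
  bc0 <- dereplicate_taxonwise(
    extract_barcodes(refs0$sequences, refs0$taxid_map, fixture_primers()))
  rs0 <- resolution_summary(bc0, tax, identity_levels = 1.0)
  expect_equal(rs0$summary$pct_species_or_below, 0)
  expect_equal(rs0$summary$pct_genus_or_below, 100)
  expect_true(all(rs0$per_barcode$consensus_rank == "genus"))

  # a singleton taxon is its own consensus at species rank
  single <- bc[1, , drop = FALSE]
  rs1 <- resolution_summary(single, tax, identity_levels = 1.0)
  expect_equal(rs1$per_barcode$consensus_taxid, single$taxid)
  expect_equal(rs1$per_barcode$consensus_rank, "species")
})

test_that("raising the identity level never coarsens the consensus", {
  spec <- fixture_spec(seed = 6, divergence = 1)   # sisters at 1 - 1/75
  tax <- local({
    td <- make_taxonomy(spec)
    load_taxdump(td$nodes_path, td$names_path)
  })
  refs <- make_references(spec)
  bc <- dereplicate_taxonwise(
    extract_barcodes(refs$sequences, refs$taxid_map, fixture_primers()))
  idm <- identity_matrix(bc)
  levels <- c(0.9, 0.97, 0.99, 1.0)
  rs <- resolution_summary(bc, tax, identity_levels = levels, idm = idm)
  depth_of <- function(t) nrow(lineage(tax, t))
  per <- rs$per_barcode
  for (b in unique(per$barcode)) {
    depths <- vapply(levels, function(l)
      depth_of(per$consensus_taxid[per$barcode == b &
                                     per$identity_level == l]),
      integer(1L))
    expect_true(all(diff(depths) >= 0L))
  }
  # sisters at identity 1 - 1/75 cluster together at 0.97: genus consensus
  rs97 <- resolution_summary(bc, tax, identity_levels = 0.97, idm = idm)
  expect_equal(rs97$summary$pct_species_or_below, 0)
  expect_equal(rs97$summary$pct_genus_or_below, 100)
})

test_that("barcode presence flags taxa with at least one barcode", {
  tax <- bovid_taxonomy()
  bc <- data.frame(taxid = c(9913L, 9913L), sequence = c("AA", "CC"))
  pres <- barcode_presence(bc, tax, c(9913L, 9901L))
  expect_equal(pres$present, c(TRUE, FALSE))
  expect_equal(pres$scientific_name, c("Bos taurus", "Bison bison"))
})
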