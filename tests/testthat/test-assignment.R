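test_that("tabular hit parsing expands multi-taxid rows and flags empties", {
  h <- rbind(mk_hit("q1", 9913),
             mk_hit("q1", NA, staxids = "9913;72004"),
             mk_hit("q2", NA, staxids = ""))
  expect_warning(parsed <- hits_via_file(h), "1 row")
  expect_equal(nrow(parsed), 3L)              # 1 + 2 expanded, empty dropped
  expect_equal(parsed$taxid, c(9913L, 9913L, 72004L))
  two <- parsed[2:3, ]
  expect_equal(two$bitscore[1L], two$bitscore[2L])  # expansion shares fields

  empty <- tempfile(fileext = ".tsv")
  file.create(empty)
  expect_silent(p0 <- parse_blast_tab(empty))
  expect_equal(nrow(p0), 0L)

  expect_error(parse_blast_tab(empty, column_spec = c("qseqid", "sseqid")),
               "format error")
})

test_that("hard filters enforce e-value, identity and coverage jointly", {
  params <- filter_params()
  # boundary: identity just below the floor is dropped, at the floor kept
  h <- hits_via_file(rbind(mk_hit("q", 1001, pident = 96.9),
                           mk_hit("q", 1001, pident = 97)))
  expect_equal(apply_hard_filters(h, params)$pident, 97)
  # full-coverage hit is kept at the 100% coverage requirement
  h2 <- hits_via_file(mk_hit("q", 1001, qstart = 1, qend = 75))
  expect_equal(nrow(apply_hard_filters(h2, params)), 1L)
  # five hand-built hits: only the two passing all three predicates remain
  five <- hits_via_file(rbind(
    mk_hit("q", 1, pident = 100),                       # passes
    mk_hit("q", 2, pident = 96.5),                      # identity fails
    mk_hit("q", 3, qstart = 2),                         # coverage fails
    mk_hit("q", 4, evalue = 1e-8),                      # e-value fails
    mk_hit("q", 5, pident = 98.2)))                     # passes
  kept <- apply_hard_filters(five, params)
  oracle <- five[five$evalue <= 1e-10 & five$pident >= 97 &
                   100 * (five$qend - five$qstart + 1) / five$qlen >= 100, ]
  expect_equal(kept$taxid, oracle$taxid)
  expect_equal(kept$taxid, c(1L, 5L))
})

test_that("bitscore window keeps hits within delta of each cluster's best", {
  one <- hits_via_file(mk_hit("q", 1, bitscore = 50))
  expect_equal(nrow(apply_bitscore_filter(one, 0)), 1L)
  h <- hits_via_file(rbind(mk_hit("q", 1, bitscore = 130),
                           mk_hit("q", 2, bitscore = 127),
                           mk_hit("q", 3, bitscore = 125)))
  expect_equal(sort(apply_bitscore_filter(h, 4)$bitscore), c(127, 130))
  ties <- hits_via_file(rbind(mk_hit("q", 1, bitscore = 130),
                              mk_hit("q", 2, bitscore = 130),
                              mk_hit("q", 3, bitscore = 129)))
  expect_equal(nrow(apply_bitscore_filter(ties, 0)), 2L)
  # per-cluster maxima are independent
  multi <- hits_via_file(rbind(mk_hit("a", 1, bitscore = 130),
                               mk_hit("a", 2, bitscore = 120),
                               mk_hit("b", 3, bitscore = 60)))
  kept <- apply_bitscore_filter(multi, 4)
  expect_setequal(kept$taxid, c(1L, 3L))
})

test_that("cluster assignment votes over unique taxa", {
  tax <- bovid_taxonomy()
  all_same <- hits_via_file(rbind(mk_hit("q", 9913), mk_hit("q", 9913)))
  a <- assign_cluster(all_same, tax, 0.51)
  expect_equal(a$assigned_taxid, 9913L)
  expect_equal(a$assigned_rank, "species")
  # unique taxa {Bos taurus, Bison bison}: no majority below family
  pair <- hits_via_file(rbind(mk_hit("q", 9913), mk_hit("q", 9901)))
  expect_equal(assign_cluster(pair, tax, 0.51)$assigned_taxid,
               oracle_consensus(tax, c(9913, 9901), 0.51))
  # {Bos taurus, Bos mutus, Bison bison}: Bos carries 2/3 of unique taxa
  trio <- hits_via_file(rbind(mk_hit("q", 9913), mk_hit("q", 72004),
                              mk_hit("q", 9901)))
  expect_equal(assign_cluster(trio, tax, 0.51)$assigned_taxid, 9903L)
  # duplication of hits to one taxid cannot sway the vote
  stacked <- hits_via_file(rbind(mk_hit("q", 9913), mk_hit("q", 9913),
                                 mk_hit("q", 9913), mk_hit("q", 9901)))
  expect_equal(assign_cluster(stacked, tax, 0.51)$assigned_taxid,
               assign_cluster(pair, tax, 0.51)$assigned_taxid)
  # zero hits: unassigned marker, not an exception
  none <- assign_cluster(pair[0, ], tax, 0.51)
  expect_true(is.na(none$assigned_taxid))
  expect_equal(none$n_hits_retained, 0L)
})

test_that("compositions sum counts per taxid and normalize by assigned reads", {
  a1 <- data.frame(query_id = "A", assigned_taxid = 9913L,
                   assigned_rank = "species", n_hits_retained = 1L,
                   read_count = 100L)
  c1 <- build_composition(a1, "s")
  expect_equal(c1$proportion, 1.0)
  a2 <- rbind(a1, data.frame(query_id = "B", assigned_taxid = 9901L,
                             assigned_rank = "species",
                             n_hits_retained = 1L, read_count = 900L))
  c2 <- build_composition(a2, "s")
  expect_equal(c2$proportion[c2$taxid == 9901], 0.9)
  expect_equal(c2$proportion[c2$taxid == 9913], 0.1)
  expect_equal(sum(c2$proportion), 1.0)
  # same-taxid clusters merge into a single entry
  a3 <- rbind(a1, a1)
  a3$query_id <- c("A", "B")
  c3 <- build_composition(a3, "s")
  expect_equal(nrow(c3), 1L)
  expect_equal(c3$reads, 200L)
  expect_warning(
    c0 <- build_composition(a1[0, ], "s"), "no assigned")
  expect_equal(nrow(c0), 0L)
})

test_that("the detection threshold keeps the boundary and never renormalizes", {
  comp <- comp_df(c(1, 2, 3), c(0.989, 0.0105, 0.0005))
  thr <- apply_detection_threshold(comp, 0.001)
  expect_equal(thr$taxid, c(1, 2))
  expect_equal(sum(thr$proportion), 0.9995)   # no renormalization
  at_t <- apply_detection_threshold(comp_df(1, 0.001), 0.001)
  expect_equal(nrow(at_t), 1L)                # entry exactly at T survives
  expect_equal(apply_detection_threshold(comp, 0), comp)
})

test_that("rank rollup merges descendants and flags above-rank entries", {
  tax <- bovid_taxonomy()
  comp <- comp_df(c(9913, 72004, 9901), c(0.5, 0.3, 0.2),
                  reads = c(500, 300, 200))
  up <- rollup_to_rank(comp, tax, "genus")
  expect_equal(up$taxid[up$proportion == 0.8], 9903L)   # Bos merged
  expect_equal(up$taxid[up$proportion == 0.2], 9900L)
  expect_false(any(up$above_rank))
  # an entry already at genus is unchanged
  same <- rollup_to_rank(comp_df(9903, 1.0), tax, "genus")
  expect_equal(same$taxid, 9903L)
  # a family-level assignment has no genus ancestor: flagged, node kept
  fam <- rollup_to_rank(comp_df(9895, 1.0), tax, "genus")
  expect_true(fam$above_rank)
  expect_equal(fam$taxid, 9895L)
})

test_that("the full pipeline reports unassigned clusters outside the denominator", {
  tax <- bovid_taxonomy()
  hits <- hits_via_file(rbind(mk_hit("otu1", 9913),
                              mk_hit("otu2", 9901, pident = 90)))
  counts <- data.frame(query_id = c("otu1", "otu2"), reads = c(90L, 10L))
  res <- run_assignment(hits, counts, tax, sample_id = "s")
  expect_equal(res$reads_assigned, 90L)
  expect_equal(res$reads_total, 100L)
  expect_equal(res$composition$proportion, 1.0)   # denominator = assigned
  un <- res$assignments[is.na(res$assignments$assigned_taxid), ]
  expect_equal(un$query_id, "otu2")
})

test_that("read counts come from a TSV or from ;size= annotations", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("otu1\t90", "otu2\t10"), path)
  tab <- cluster_read_counts(path)
  expect_equal(tab$reads, c(90L, 10L))
  emb <- cluster_read_counts(query_ids = c("otu1;size=90", "otu2;size=10"))
  expect_equal(emb$reads, c(90L, 10L))
  expect_error(cluster_read_counts(query_ids = c("otu1;size=9", "otu2")),
               "format error")
})
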