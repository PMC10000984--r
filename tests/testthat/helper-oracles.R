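# Brute-force oracles and hand-built fixtures shared across test files.

# A small bovid/bison taxonomy written in the NCBI dmp dialect and loaded
# through the parser. Lineage of Bos taurus has 7 nodes.
bovid_taxdump <- function(dir = tempfile("bovid")) {
  dir.create(dir, showWarnings = FALSE)
  nodes <- c(
    "1\t|\t1\t|\tno rank\t|",
    "7742\t|\t1\t|\tclade\t|",          # Vertebrata
    "40674\t|\t7742\t|\tclass\t|",      # Mammalia
    "91561\t|\t40674\t|\torder\t|",     # Cetartiodactyla
    "9895\t|\t91561\t|\tfamily\t|",     # Bovidae
    "9903\t|\t9895\t|\tgenus\t|",       # Bos
    "9913\t|\t9903\t|\tspecies\t|",     # Bos taurus
    "72004\t|\t9903\t|\tspecies\t|",    # Bos mutus
    "9900\t|\t9895\t|\tgenus\t|",       # Bison
    "9901\t|\t9900\t|\tspecies\t|")     # Bison bison
  nm <- c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "7742\t|\tVertebrata\t|\t\t|\tscientific name\t|",
    "40674\t|\tMammalia\t|\t\t|\tscientific name\t|",
    "40674\t|\tmammals\t|\t\t|\tcommon name\t|",
    "91561\t|\tCetartiodactyla\t|\t\t|\tscientific name\t|",
    "9895\t|\tBovidae\t|\t\t|\tscientific name\t|",
    "9903\t|\tBos\t|\t\t|\tscientific name\t|",
    "9913\t|\tBos taurus\t|\t\t|\tscientific name\t|",
    "9913\t|\tcattle\t|\t\t|\tgenbank common name\t|",
    "72004\t|\tBos mutus\t|\t\t|\tscientific name\t|",
    "9900\t|\tBison\t|\t\t|\tscientific name\t|",
    "9901\t|\tBison bison\t|\t\t|\tscientific name\t|")
  merged <- "12345\t|\t9913\t|"
  writeLines(nodes, file.path(dir, "nodes.dmp"))
  writeLines(nm, file.path(dir, "names.dmp"))
  writeLines(merged, file.path(dir, "merged.dmp"))
  dir
}

bovid_taxonomy <- function() {
  dir <- bovid_taxdump()
  load_taxdump(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"),
               file.path(dir, "merged.dmp"))
}

# Construct a taxonomy object directly (taxids 1..n, node 1 the root);
# used by the randomized property tests where parsing is not the target.
fake_taxonomy <- function(parents, ranks = NULL) {
  n <- length(parents)
  stopifnot(parents[1L] == 1L, all(parents[-1L] < seq(2L, length.out = n - 1L)))
  if (is.null(ranks)) ranks <- rep("no rank", n)
  key <- as.character(seq_len(n))
  tax <- list(taxids = seq_len(n),
              parent = stats::setNames(as.integer(parents), key),
              rank = stats::setNames(ranks, key),
              name = stats::setNames(sprintf("node %d", seq_len(n)), key),
              merged = stats::setNames(integer(0L), character(0L)),
              root = 1L)
  class(tax) <- "taxonomy"
  tax
}

random_taxonomy <- function(max_nodes = 50L) {
  n <- sample(2:max_nodes, 1L)
  parents <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                          integer(1L)))
  fake_taxonomy(parents)
}

tax_depth <- function(tax, taxid) {
  nrow(lineage(tax, taxid))
}

# Independent LCA: intersect lineage node sets, take the deepest member.
oracle_lca <- function(tax, taxids) {
  common <- Reduce(intersect, lapply(taxids, function(t) lineage(tax, t)$taxid))
  depths <- vapply(common, tax_depth, integer(1L), tax = tax)
  common[which.max(depths)]
}

# Independent consensus: enumerate every node, count covering vote
# lineages, return the deepest node covered by >= level of the votes.
oracle_consensus <- function(tax, votes, level) {
  paths <- lapply(votes, function(t) lineage(tax, t)$taxid)
  n <- length(votes)
  cover <- vapply(tax$taxids, function(node)
    sum(vapply(paths, function(p) node %in% p, logical(1L))) / n,
    numeric(1L))
  qual <- tax$taxids[cover >= level]
  depths <- vapply(qual, tax_depth, integer(1L), tax = tax)
  qual[which.max(depths)]
}

# Write a hit table to a temp TSV and parse it back.
hits_via_file <- function(hits) {
  path <- tempfile(fileext = ".tsv")
  write_blast_tab(hits, path)
  parse_blast_tab(path)
}

# Hand-rollable hit row in the default column order.
mk_hit <- function(qseqid, taxid, pident = 100, qlen = 75, qstart = 1,
                   qend = qlen, evalue = 1e-30, bitscore = 139,
                   staxids = as.character(taxid)) {
  data.frame(qseqid = qseqid, sseqid = sprintf("ref_%s", staxids),
             pident = pident, length = qend - qstart + 1, qlen = qlen,
             qstart = qstart, qend = qend, evalue = evalue,
             bitscore = bitscore, staxids = staxids,
             stringsAsFactors = FALSE)
}

comp_df <- function(taxids, proportions, sample_id = "s",
                    reads = round(proportions * 1e6)) {
  data.frame(sample_id = sample_id, taxid = taxids,
             reads = as.integer(reads), proportion = proportions,
             stringsAsFactors = FALSE)
}
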