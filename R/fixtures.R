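# Synthetic input generation: mini taxonomies, reference sequences with
# planted primer sites, similarity-search hit tables with filterable
# decoys, paired FASTQ, and sample plans with sub-threshold noise.

#' Specification of a synthetic fixture
#'
#' Describes a complete synthetic dataset: a small taxonomy (species under
#' genera under families under one root branch), one reference sequence
#' per species embedding an amplifiable barcode, and per-sample
#' compositions realized as read clusters with decoy hits plus
#' sub-threshold noise clusters.
#'
#' @param seed Integer master seed; fixes every source of randomness.
#' @param n_genera,species_per_genus,genera_per_family Taxonomy shape
#'   (defaults 4, 2, 2).
#' @param barcode_length Length of the inter-primer barcode in bp
#'   (default 75, a short mitochondrial 16S fragment).
#' @param divergence Substitutions separating sister species' barcodes
#'   (default 3); 0 makes all species of a genus share one barcode.
#' @param genus_divergence Substitutions separating genera from the base
#'   barcode (default 8).
#' @param sample_plan Named list of data frames (`taxid`, `proportion`),
#'   one per sample; proportions sum to at most 1, the remainder becomes
#'   noise. `NULL` selects a default three-sample plan enriched for
#'   components around 1%, mirroring typical reference-material designs.
#' @param noise_floor Maximum proportion of any single noise cluster
#'   (default `0.0005`, i.e. 0.05%, below the 0.1% detection threshold).
#' @param depth Reads per sample (default 5000, the recommended minimum
#'   sequencing depth).
#' @param read_length Read length for generated FASTQ (default 150).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genera = 4L, species_per_genus = 2L,
                         genera_per_family = 2L, barcode_length = 75L,
                         divergence = 3L, genus_divergence = 8L,
                         sample_plan = NULL, noise_floor = 0.0005,
                         depth = 5000L, read_length = 150L) {
  stopifnot(n_genera >= 1L, species_per_genus >= 1L,
            genera_per_family >= 1L, barcode_length >= 20L,
            divergence >= 0L, depth >= 1L,
            noise_floor >= 0, noise_floor < 1)
  spec <- structure(list(seed = as.integer(seed), n_genera = n_genera,
                         species_per_genus = species_per_genus,
                         genera_per_family = genera_per_family,
                         barcode_length = barcode_length,
                         divergence = divergence,
                         genus_divergence = genus_divergence,
                         sample_plan = sample_plan,
                         noise_floor = noise_floor, depth = depth,
                         read_length = read_length),
                    class = "fixture_spec")
  if (is.null(spec$sample_plan)) spec$sample_plan <- default_sample_plan(spec)
  for (p in spec$sample_plan) stopifnot(sum(p$proportion) <= 1 + 1e-12)
  spec
}

#' Default primer pair of the synthetic references
#'
#' A 20-bp pair (one degenerate position each) planted around every
#' synthetic barcode.
#'
#' @return A [primer_pair()].
#' @export
fixture_primers <- function() {
  primer_pair(forward = "ACGGTCTRGCCTGACGTCAT",
              reverse = "TGCAGYACCTTGAGGACGTA")
}

# taxid layout: root 1; families 10+; genera 100+; species 1000+
fixture_species_table <- function(spec) {
  n_sp <- spec$n_genera * spec$species_per_genus
  genus_idx <- rep(seq_len(spec$n_genera), each = spec$species_per_genus)
  family_idx <- (genus_idx - 1L) %/% spec$genera_per_family + 1L
  data.frame(
    taxid = 1000L + seq_len(n_sp),
    name = sprintf("Genus%d species%d", genus_idx,
                   rep(seq_len(spec$species_per_genus), spec$n_genera)),
    genus_taxid = 100L + genus_idx,
    family_taxid = 10L + family_idx,
    stringsAsFactors = FALSE)
}

#' Write a synthetic taxonomy dump
#'
#' Builds the fixture tree (species under genera under families under a
#' single root) and writes `nodes.dmp`/`names.dmp` (plus an empty
#' `merged.dmp`) in the NCBI taxdump dialect.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return A list: `dir`, the file paths, and `species` (data frame with
#'   `taxid`, `name`, `genus_taxid`, `family_taxid`).
#' @export
make_taxonomy <- function(spec, dir = tempfile("taxdump")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- fixture_species_table(spec)
  genera <- unique(sp[, c("genus_taxid", "family_taxid")])
  families <- unique(sp$family_taxid)
  nodes <- rbind(
    data.frame(taxid = 1L, parent = 1L, rank = "no rank"),
    data.frame(taxid = families, parent = 1L, rank = "family"),
    data.frame(taxid = genera$genus_taxid, parent = genera$family_taxid,
               rank = "genus"),
    data.frame(taxid = sp$taxid, parent = sp$genus_taxid,
               rank = "species"))
  names_df <- rbind(
    data.frame(taxid = 1L, name = "root"),
    data.frame(taxid = families,
               name = sprintf("Family%d", seq_along(families))),
    data.frame(taxid = genera$genus_taxid,
               name = sprintf("Genus%d", genera$genus_taxid - 100L)),
    data.frame(taxid = sp$taxid, name = sp$name))
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  merged_path <- file.path(dir, "merged.dmp")
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", nodes$taxid, nodes$parent,
                     nodes$rank), nodes_path)
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                     names_df$taxid, names_df$name), names_path)
  writeLines(character(0L), merged_path)
  list(dir = dir, nodes_path = nodes_path, names_path = names_path,
       merged_path = merged_path, species = sp)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substitute_base <- function(chars, pos) {
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  chars[pos] <- rot[chars[pos]]
  chars
}

# Barcode insert per species: a seeded base sequence, genus-specific
# substitutions in one position block, species-specific substitutions in
# another, so sister species differ by exactly `divergence` substitutions
# and genera by >= `genus_divergence`.
fixture_inserts <- function(spec) {
  sp <- fixture_species_table(spec)
  base <- withr_seed(spec$seed * 97L + 11L,
                     strsplit(random_dna(spec$barcode_length), "")[[1L]])
  g_block <- spec$genus_divergence
  s_start <- spec$n_genera * g_block
  needed <- s_start +
    spec$n_genera * (spec$species_per_genus - 1L) * max(spec$divergence, 1L)
  if (needed > spec$barcode_length) {
    stop("argument error: barcode too short for the requested divergence")
  }
  inserts <- character(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    g <- sp$genus_taxid[i] - 100L
    k <- (i - 1L) %% spec$species_per_genus  # species index within genus
    chars <- base
    if (g_block > 0L) {
      chars <- substitute_base(chars, ((g - 1L) * g_block + 1L):(g * g_block))
    }
    if (spec$divergence > 0L && k > 0L) {
      slot <- (g - 1L) * (spec$species_per_genus - 1L) + (k - 1L)
      pos <- s_start + slot * spec$divergence + seq_len(spec$divergence)
      chars <- substitute_base(chars, pos)
    }
    inserts[i] <- paste(chars, collapse = "")
  }
  stats::setNames(inserts, as.character(sp$taxid))
}

#' Write synthetic reference sequences with planted primer sites
#'
#' One pseudo-mitochondrial record per species: random flanks around
#' `forward primer + species-specific insert + revcomp(reverse primer)`.
#' Inserts differ between sister species by exactly the spec's
#' `divergence` substitutions.
#'
#' @param spec A [fixture_spec()].
#' @param pair A [primer_pair()] (default [fixture_primers()]).
#' @param fasta_path,map_path Output FASTA and taxid-map TSV paths.
#' @param flank Flank length in bp on each side (default 40).
#' @return A list: `fasta_path`, `map_path`, `sequences` (named character
#'   vector), `taxid_map` (data frame `sequence_id`, `taxid`) and
#'   `inserts` (the planted barcodes, named by taxid).
#' @export
make_references <- function(spec, pair = fixture_primers(),
                            fasta_path = tempfile(fileext = ".fasta"),
                            map_path = tempfile(fileext = ".tsv"),
                            flank = 40L) {
  inserts <- fixture_inserts(spec)
  sp <- fixture_species_table(spec)
  # degenerate primer positions are planted as one concrete expansion
  fwd <- gsub("R", "A", gsub("Y", "C", pair$forward))
  rev <- gsub("R", "A", gsub("Y", "C", pair$reverse))
  seqs <- withr_seed(spec$seed * 97L + 23L, {
    vapply(seq_len(nrow(sp)), function(i) {
      paste0(random_dna(flank), fwd, inserts[[as.character(sp$taxid[i])]],
             revcomp(rev), random_dna(flank))
    }, character(1L))
  })
  ids <- sprintf("ref_%d", sp$taxid)
  names(seqs) <- ids
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, fasta_path)
  taxid_map <- data.frame(sequence_id = ids, taxid = sp$taxid,
                          stringsAsFactors = FALSE)
  utils::write.table(taxid_map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta_path = fasta_path, map_path = map_path, sequences = seqs,
       taxid_map = taxid_map, inserts = inserts)
}

default_sample_plan <- function(spec) {
  sp <- fixture_species_table(spec)$taxid
  pick <- function(i) sp[((i - 1L) %% length(sp)) + 1L]
  list(
    s1 = data.frame(taxid = pick(c(1, 2, 3, 5)),
                    proportion = c(0.899, 0.05, 0.03, 0.0204)),
    s2 = data.frame(taxid = pick(c(4, 6, 7, 2)),
                    proportion = c(0.6, 0.2, 0.1888, 0.01)),
    s3 = data.frame(taxid = pick(c(8, 1, 4, 6)),
                    proportion = c(0.97, 0.01, 0.01, 0.0096)))
}

#' Synthesize a hit table realizing a planted composition
#'
#' Emits one read cluster per planted component (or several, when
#' `clusters_per_component > 1`, to emulate cluster splitting), each with a
#' clean hit to its true taxon plus decoy hits that the default filters
#' must remove: one below the identity floor, one below the bitscore
#' window, one with partial query coverage and one above the e-value
#' ceiling. Reads left over after realizing the planted proportions become
#' noise clusters assigned to off-plan genera, each below the spec's noise
#' floor (and the per-taxon noise total below the 0.1% detection
#' threshold).
#'
#' @param spec A [fixture_spec()].
#' @param plan Data frame `taxid`, `proportion` for one sample (planted
#'   proportions of the total read depth; their sum may be below 1).
#' @param sample_id Sample identifier.
#' @param clusters_per_component Number of clusters each component is
#'   split over (default 1).
#' @return A list: `hits` (data frame in the default column order),
#'   `counts` (`query_id`, `reads`), `expected` (`sample_id`, `taxid`,
#'   `proportion` — the planted design values).
#' @export
make_blast_hits <- function(spec, plan, sample_id = "s1",
                            clusters_per_component = 1L) {
  sp <- fixture_species_table(spec)
  stopifnot(all(plan$taxid %in% sp$taxid))
  N <- spec$depth
  reads <- pmax(1L, as.integer(round(plan$proportion * N)))
  stopifnot(sum(reads) <= N)

  # noise goes to genera absent from the plan so rank-level rollups of the
  # planted components are not contaminated
  plan_genera <- sp$genus_taxid[match(plan$taxid, sp$taxid)]
  off <- sp$taxid[!sp$genus_taxid %in% plan_genera]
  if (!length(off)) off <- setdiff(sp$taxid, plan$taxid)
  noise_total <- N - sum(reads)
  chunk <- max(1L, as.integer(floor(spec$noise_floor * N)))
  noise_reads <- integer(0L)
  while (noise_total > 0L) {
    take <- min(chunk, noise_total)
    noise_reads <- c(noise_reads, take)
    noise_total <- noise_total - take
  }
  noise_taxa <- if (length(noise_reads))
    off[(seq_along(noise_reads) - 1L) %% length(off) + 1L] else integer(0L)
  if (length(noise_reads)) {
    per_taxon_noise <- tapply(noise_reads, noise_taxa, sum)
    stopifnot(all(per_taxon_noise < 0.001 * N))
    noise_genera <- sp$genus_taxid[match(noise_taxa, sp$taxid)]
    off_genus <- !noise_genera %in% plan_genera
    if (any(off_genus)) {
      per_genus <- tapply(noise_reads[off_genus], noise_genera[off_genus],
                          sum)
      stopifnot(all(per_genus < 0.001 * N))
    }
  }

  clusters <- list()
  for (i in seq_along(plan$taxid)) {
    split_reads <- balanced_split(reads[i], clusters_per_component)
    for (j in seq_along(split_reads)) {
      clusters[[length(clusters) + 1L]] <-
        list(taxid = plan$taxid[i], reads = split_reads[j])
    }
  }
  for (i in seq_along(noise_reads)) {
    clusters[[length(clusters) + 1L]] <-
      list(taxid = noise_taxa[i], reads = noise_reads[i])
  }

  qlen <- spec$barcode_length
  rows <- list()
  counts <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    qid <- sprintf("%s_otu%d", sample_id, ci)
    counts[[ci]] <- data.frame(query_id = qid, reads = cl$reads,
                               stringsAsFactors = FALSE)
    truth <- cl$taxid
    sib <- decoy_sibling(sp, truth)
    cousin <- decoy_cousin(sp, truth)
    hit <- function(taxid, pident, qstart, qend, evalue, bitscore) {
      data.frame(qseqid = qid, sseqid = sprintf("ref_%d", taxid),
                 pident = pident, length = qend - qstart + 1, qlen = qlen,
                 qstart = qstart, qend = qend, evalue = evalue,
                 bitscore = bitscore, staxids = as.character(taxid),
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- rbind(
      hit(truth, 100.0, 1, qlen, 1e-30, 139.0),          # clean best hit
      hit(truth, 98.7, 1, qlen, 1e-28, 136.0),           # survivor, same taxon
      hit(sib, 96.9, 1, qlen, 1e-28, 138.0),             # fails identity
      hit(cousin, 100.0, 1, qlen, 1e-30, 133.0),         # outside bitscore window
      hit(sib, 100.0, 3, qlen, 1e-29, 138.0),            # partial coverage
      hit(cousin, 100.0, 1, qlen, 1e-5, 139.0))          # fails e-value
  }
  hits <- do.call(rbind, rows)
  list(hits = hits, counts = do.call(rbind, counts),
       expected = data.frame(sample_id = sample_id, taxid = plan$taxid,
                             proportion = plan$proportion,
                             stringsAsFactors = FALSE))
}

balanced_split <- function(total, parts) {
  parts <- min(parts, total)
  base <- total %/% parts
  extra <- total %% parts
  c(rep(base + 1L, extra), rep(base, parts - extra))
}

decoy_sibling <- function(sp, taxid) {
  g <- sp$genus_taxid[match(taxid, sp$taxid)]
  cand <- sp$taxid[sp$genus_taxid == g & sp$taxid != taxid]
  if (length(cand)) cand[1L] else sp$taxid[sp$taxid != taxid][1L]
}

decoy_cousin <- function(sp, taxid) {
  g <- sp$genus_taxid[match(taxid, sp$taxid)]
  cand <- sp$taxid[sp$genus_taxid != g]
  if (length(cand)) cand[1L] else sp$taxid[sp$taxid != taxid][1L]
}

#' Write a hit table in the tabular search format
#' @param hits Hit data frame from [make_blast_hits()].
#' @param path Output TSV path (no header).
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate a synchronized pair of FASTQ files
#'
#' Random reads with matching identifiers in both mates; fully
#' deterministic under the spec seed.
#'
#' @param spec A [fixture_spec()].
#' @param r1_path,r2_path Output paths; `.gz` suffixes are honored.
#' @param n_pairs Number of read pairs (default `spec$depth`).
#' @return A list with the two paths and `n_pairs`.
#' @export
make_fastq <- function(spec,
                       r1_path = tempfile(fileext = "_R1.fastq.gz"),
                       r2_path = tempfile(fileext = "_R2.fastq.gz"),
                       n_pairs = spec$depth) {
  stopifnot(n_pairs >= 1L)
  qual <- strrep("I", spec$read_length)
  recs <- withr_seed(spec$seed * 97L + 41L, {
    lapply(seq_len(n_pairs), function(i) {
      list(id = sprintf("@pair_%06d", i),
           s1 = random_dna(spec$read_length),
           s2 = random_dna(spec$read_length))
    })
  })
  l1 <- unlist(lapply(recs, function(r) c(paste0(r$id, "/1"), r$s1, "+",
                                          qual)))
  l2 <- unlist(lapply(recs, function(r) c(paste0(r$id, "/2"), r$s2, "+",
                                          qual)))
  con1 <- open_out(r1_path); writeLines(l1, con1); close(con1)
  con2 <- open_out(r2_path); writeLines(l2, con2); close(con2)
  list(r1_path = r1_path, r2_path = r2_path, n_pairs = n_pairs)
}

#' Materialize a complete fixture directory
#'
#' Writes `taxdump/`, `reference.fasta`, `taxids.tsv`, per-sample
#' `hits_<sample>.tsv` / `counts_<sample>.tsv`, a combined
#' `expected.tsv`, and `r1.fastq.gz` / `r2.fastq.gz`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return A list with all paths, the loaded-back file names, and the
#'   in-memory `samples` (per-sample hit/count/expected data frames).
#' @export
make_fixture <- function(spec, dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  taxd <- make_taxonomy(spec, file.path(dir, "taxdump"))
  refs <- make_references(spec,
                          fasta_path = file.path(dir, "reference.fasta"),
                          map_path = file.path(dir, "taxids.tsv"))
  samples <- lapply(names(spec$sample_plan), function(sid) {
    s <- make_blast_hits(spec, spec$sample_plan[[sid]], sample_id = sid)
    write_blast_tab(s$hits, file.path(dir, sprintf("hits_%s.tsv", sid)))
    utils::write.table(s$counts, file.path(dir,
                                           sprintf("counts_%s.tsv", sid)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    s
  })
  names(samples) <- names(spec$sample_plan)
  expected <- do.call(rbind, lapply(samples, `[[`, "expected"))
  utils::write.table(expected, file.path(dir, "expected.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fq <- make_fastq(spec, file.path(dir, "r1.fastq.gz"),
                   file.path(dir, "r2.fastq.gz"))
  list(dir = dir, taxdump = taxd, references = refs, samples = samples,
       expected_path = file.path(dir, "expected.tsv"), fastq = fq)
}
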