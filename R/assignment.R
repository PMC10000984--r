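# Hit filtering and consensus taxonomic assignment of read clusters.

#' Default filter parameters for taxonomic assignment
#'
#' Bundles the assignment filter settings: hard filters on e-value, percent
#' identity and query coverage; the bitscore-difference window; the
#' consensus level of the majority vote; and the detection threshold applied
#' to sample compositions.
#'
#' @param max_evalue Maximum e-value of a retained hit (default `1e-10`).
#' @param min_pident Minimum percent identity, 0-100 (default `97`).
#' @param min_qcov_percent Minimum query coverage percent, computed as
#'   `100 * (qend - qstart + 1) / qlen` (default `100`).
#' @param bitscore_delta Width of the per-cluster bitscore window in bits:
#'   hits scoring below `max(bitscore) - bitscore_delta` are discarded
#'   (default `4`).
#' @param consensus_level Minimum fraction of voting taxa that must share a
#'   node for it to be the assignment, in `(0.5, 1]` (default `0.51`, a
#'   strict majority).
#' @param detection_threshold Minimum proportion of assigned reads for a
#'   composition entry to be reported, in `[0, 1)` (default `0.001`,
#'   i.e. 0.1%).
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(max_evalue = 1e-10, min_pident = 97,
                          min_qcov_percent = 100, bitscore_delta = 4,
                          consensus_level = 0.51,
                          detection_threshold = 0.001) {
  stopifnot(consensus_level > 0.5, consensus_level <= 1,
            bitscore_delta >= 0,
            detection_threshold >= 0, detection_threshold < 1)
  structure(list(max_evalue = max_evalue, min_pident = min_pident,
                 min_qcov_percent = min_qcov_percent,
                 bitscore_delta = bitscore_delta,
                 consensus_level = consensus_level,
                 detection_threshold = detection_threshold),
            class = "filter_params")
}

default_blast_columns <- c("qseqid", "sseqid", "pident", "length", "qlen",
                           "qstart", "qend", "evalue", "bitscore", "staxids")

#' Parse a tabular similarity-search hit file
#'
#' Reads a BLAST outfmt-6-style TSV. Rows whose subject-taxids column holds
#' several semicolon-separated taxids are expanded to one hit per taxid;
#' rows with an empty taxid field are dropped with a warning stating the
#' count.
#'
#' @param path Path to the TSV (no header).
#' @param column_spec Ordered column names; must include `qseqid`, `pident`,
#'   `qlen`, `qstart`, `qend`, `evalue`, `bitscore` and `staxids`.
#' @return A data frame of hits, one row per (input row x taxid), with an
#'   integer `staxids` column renamed to `taxid`.
#' @export
parse_blast_tab <- function(path, column_spec = default_blast_columns) {
  required <- c("qseqid", "pident", "qlen", "qstart", "qend", "evalue",
                "bitscore", "staxids")
  missing <- setdiff(required, column_spec)
  if (length(missing)) {
    stop(sprintf("format error: column spec lacks %s",
                 paste(missing, collapse = ", ")))
  }
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           col.names = column_spec,
                           colClasses = "character",
                           quote = "", comment.char = "")
  if (!nrow(raw)) return(empty_hits(column_spec))

  empty_tax <- is.na(raw$staxids) | !nzchar(trimws(raw$staxids))
  if (any(empty_tax)) {
    warning(sprintf("%d row(s) dropped: empty subject taxid", sum(empty_tax)))
    raw <- raw[!empty_tax, , drop = FALSE]
  }
  if (!nrow(raw)) return(empty_hits(column_spec))

  tax_lists <- strsplit(raw$staxids, ";", fixed = TRUE)
  idx <- rep.int(seq_len(nrow(raw)), lengths(tax_lists))
  hits <- raw[idx, setdiff(column_spec, "staxids"), drop = FALSE]
  hits$taxid <- as.integer(trimws(unlist(tax_lists)))
  for (col in intersect(c("pident", "qlen", "qstart", "qend", "evalue",
                          "bitscore", "length"), names(hits))) {
    hits[[col]] <- as.numeric(hits[[col]])
  }
  rownames(hits) <- NULL
  hits
}

empty_hits <- function(column_spec) {
  out <- stats::setNames(
    rep(list(character(0L)), length(column_spec) - 1L),
    setdiff(column_spec, "staxids"))
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  for (col in intersect(c("pident", "qlen", "qstart", "qend", "evalue",
                          "bitscore", "length"), names(out))) {
    out[[col]] <- numeric(0L)
  }
  out$taxid <- integer(0L)
  out
}

#' Query coverage of hits, in percent
#'
#' `100 * (qend - qstart + 1) / qlen` on 1-based inclusive query
#' coordinates, independent of any coverage column the search tool may
#' emit.
#'
#' @param hits Hit data frame with `qstart`, `qend`, `qlen`.
#' @return Numeric vector of coverage percentages.
#' @export
query_coverage <- function(hits) {
  100 * (hits$qend - hits$qstart + 1) / hits$qlen
}

#' Apply the hard e-value / identity / coverage filters
#'
#' Keeps hits with `evalue <= max_evalue`, `pident >= min_pident` and query
#' coverage at least `min_qcov_percent`.
#'
#' @param hits Hit data frame from [parse_blast_tab()].
#' @param params A [filter_params()] list.
#' @return The filtered hit data frame (possibly empty).
#' @export
apply_hard_filters <- function(hits, params = filter_params()) {
  if (!nrow(hits)) return(hits)
  keep <- hits$evalue <= params$max_evalue &
    hits$pident >= params$min_pident &
    query_coverage(hits) >= params$min_qcov_percent
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the per-cluster bitscore-difference filter
#'
#' Within each `qseqid`, keeps hits whose bitscore is within `delta` bits of
#' the cluster's best hit: `bitscore >= max(bitscore) - delta`. At
#' `delta = 0` only maximal-bitscore hits survive (ties all kept).
#'
#' @param hits Hit data frame (may span several clusters).
#' @param delta Non-negative bitscore window in bits.
#' @return The filtered hit data frame.
#' @export
apply_bitscore_filter <- function(hits, delta = 4) {
  stopifnot(delta >= 0)
  if (!nrow(hits)) return(hits)
  best <- stats::ave(hits$bitscore, hits$qseqid, FUN = max)
  out <- hits[hits$bitscore >= best - delta, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign one cluster a consensus taxon
#'
#' Dereplicates the retained hits of a single cluster to its unique taxon
#' set (so database over-representation of a taxon does not weight the
#' vote), then takes the fractional consensus at `consensus_level`.
#'
#' @param hits Hit data frame for one `qseqid`, already hard- and
#'   bitscore-filtered. Zero rows yield an unassigned ("no hit") record,
#'   not an error.
#' @param tax A `taxonomy` object.
#' @param consensus_level Fraction in `(0.5, 1]`.
#' @return A one-row data frame: `query_id`, `assigned_taxid`,
#'   `assigned_rank`, `n_hits_retained`. Unassigned clusters carry `NA`
#'   taxid/rank and zero retained hits.
#' @export
assign_cluster <- function(hits, tax, consensus_level = 0.51) {
  if (!nrow(hits)) {
    return(data.frame(query_id = NA_character_,
                      assigned_taxid = NA_integer_,
                      assigned_rank = NA_character_,
                      n_hits_retained = 0L, stringsAsFactors = FALSE))
  }
  qid <- unique(hits$qseqid)
  stopifnot(length(qid) == 1L)
  taxa <- unique(vapply(hits$taxid, function(t) resolve_taxid(tax, t),
                        integer(1L)))
  node <- consensus_taxon(tax, taxa, consensus_level)
  data.frame(query_id = qid, assigned_taxid = node,
             assigned_rank = tax_rank(tax, node),
             n_hits_retained = nrow(hits), stringsAsFactors = FALSE)
}

#' Assign every cluster in a filtered hit table
#'
#' @param hits Hit data frame, already filtered.
#' @param tax A `taxonomy` object.
#' @param consensus_level Fraction in `(0.5, 1]`.
#' @return Data frame with one row per cluster present in `hits`.
#' @export
assign_clusters <- function(hits, tax, consensus_level = 0.51) {
  if (!nrow(hits)) {
    return(data.frame(query_id = character(0L),
                      assigned_taxid = integer(0L),
                      assigned_rank = character(0L),
                      n_hits_retained = integer(0L),
                      stringsAsFactors = FALSE))
  }
  parts <- split(hits, hits$qseqid)
  out <- do.call(rbind, lapply(parts, assign_cluster, tax = tax,
                               consensus_level = consensus_level))
  rownames(out) <- NULL
  out
}

#' Read per-cluster read counts
#'
#' Two dialects are auto-detected: a 2-column TSV (`query_id`, `reads`), or
#' counts embedded in the cluster identifiers as `";size=N"` suffixes, in
#' which case `path` may be omitted and `query_ids` supplied instead.
#'
#' @param path Optional path to a 2-column TSV without header.
#' @param query_ids Optional character vector of cluster identifiers with
#'   embedded `";size=N"` annotations.
#' @return A data frame `query_id`, `reads` (integer). Embedded-size ids
#'   keep their full identifier (including the suffix) as `query_id`.
#' @export
cluster_read_counts <- function(path = NULL, query_ids = NULL) {
  if (!is.null(path)) {
    tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                             col.names = c("query_id", "reads"),
                             colClasses = c("character", "integer"))
    return(tab)
  }
  if (is.null(query_ids)) stop("argument error: need a path or query ids")
  m <- regmatches(query_ids, regexpr(";size=\\d+", query_ids))
  if (length(m) != length(query_ids)) {
    stop("format error: some query ids lack a ;size=N annotation")
  }
  data.frame(query_id = query_ids,
             reads = as.integer(sub(";size=", "", m, fixed = TRUE)),
             stringsAsFactors = FALSE)
}

#' Build a per-sample composition from cluster assignments
#'
#' Sums read counts per assigned taxid; the proportion of each entry is its
#' read count over the total reads of all assigned clusters. Unassigned
#' clusters never enter the denominator.
#'
#' @param assignments Data frame from [assign_clusters()] joined with a
#'   `read_count` column (reads per cluster).
#' @param sample_id Sample identifier attached to every entry.
#' @return A composition data frame: `sample_id`, `taxid`, `reads`,
#'   `proportion`. Empty (no assigned cluster) yields zero rows with a
#'   warning.
#' @export
build_composition <- function(assignments, sample_id) {
  ok <- !is.na(assignments$assigned_taxid)
  if (!any(ok)) {
    warning(sprintf("sample %s: no assigned clusters", sample_id))
    return(data.frame(sample_id = character(0L), taxid = integer(0L),
                      reads = integer(0L), proportion = numeric(0L),
                      stringsAsFactors = FALSE))
  }
  a <- assignments[ok, , drop = FALSE]
  stopifnot(all(a$read_count >= 1))
  reads <- tapply(a$read_count, a$assigned_taxid, sum)
  total <- sum(a$read_count)
  out <- data.frame(sample_id = sample_id,
                    taxid = as.integer(names(reads)),
                    reads = as.integer(reads),
                    proportion = as.numeric(reads) / total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$reads, out$taxid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the detection threshold to a composition
#'
#' Removes entries with `proportion < threshold`; an entry at exactly the
#' threshold is kept. Remaining proportions are deliberately NOT
#' renormalized, so they stay interpretable as fractions of all assigned
#' reads.
#'
#' @param comp Composition data frame.
#' @param threshold Fraction in `[0, 1)`.
#' @return The thresholded composition.
#' @export
apply_detection_threshold <- function(comp, threshold = 0.001) {
  stopifnot(threshold >= 0, threshold < 1)
  out <- comp[comp$proportion >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Roll a composition up to a fixed rank
#'
#' Replaces each entry by its lineage ancestor at `rank` and merges counts.
#' Entries whose lineage has no node at that rank (assignments above the
#' rank, or lineages skipping it) keep their original node and are flagged
#' `above_rank`.
#'
#' @param comp Composition data frame (columns `taxid`, `reads` and/or
#'   `proportion`).
#' @param tax A `taxonomy` object.
#' @param rank Rank label, e.g. `"genus"`.
#' @return A composition data frame with an additional logical
#'   `above_rank` column.
#' @export
rollup_to_rank <- function(comp, tax, rank) {
  if (!nrow(comp)) {
    out <- comp
    out$above_rank <- logical(0L)
    return(out)
  }
  anc <- vapply(comp$taxid, function(t) ancestor_at_rank(tax, t, rank),
                integer(1L))
  above <- is.na(anc)
  node <- ifelse(above, comp$taxid, anc)
  key <- paste(node, above)
  first <- !duplicated(key)
  out <- data.frame(sample_id = if ("sample_id" %in% names(comp))
                      comp$sample_id[first] else NULL,
                    taxid = as.integer(node[first]),
                    stringsAsFactors = FALSE)
  if ("reads" %in% names(comp)) {
    out$reads <- as.integer(tapply(comp$reads, key, sum)[key[first]])
  }
  if ("proportion" %in% names(comp)) {
    out$proportion <- as.numeric(tapply(comp$proportion, key, sum)[key[first]])
  }
  out$above_rank <- above[first]
  rownames(out) <- NULL
  out
}

#' Run the full per-sample assignment pipeline
#'
#' Hard filters, bitscore window, per-cluster consensus vote, composition
#' building and detection threshold, in that order.
#'
#' @param hits Hit data frame from [parse_blast_tab()] (unfiltered).
#' @param counts Data frame `query_id`, `reads` from
#'   [cluster_read_counts()]. Clusters in `counts` with no surviving hit
#'   are reported as unassigned.
#' @param tax A `taxonomy` object.
#' @param params A [filter_params()] list.
#' @param sample_id Sample identifier.
#' @return A list: `composition` (thresholded), `composition_full`
#'   (pre-threshold), `assignments` (per cluster, including unassigned
#'   ones with `NA` taxid), `reads_assigned`, `reads_total`.
#' @export
run_assignment <- function(hits, counts, tax, params = filter_params(),
                           sample_id = "sample") {
  filtered <- apply_bitscore_filter(apply_hard_filters(hits, params),
                                    params$bitscore_delta)
  assigned <- assign_clusters(filtered, tax, params$consensus_level)
  lost <- setdiff(counts$query_id, assigned$query_id)
  if (length(lost)) {
    assigned <- rbind(assigned,
                      data.frame(query_id = lost,
                                 assigned_taxid = NA_integer_,
                                 assigned_rank = NA_character_,
                                 n_hits_retained = 0L,
                                 stringsAsFactors = FALSE))
  }
  assigned$read_count <- counts$reads[match(assigned$query_id,
                                            counts$query_id)]
  comp_full <- build_composition(assigned, sample_id)
  list(composition = apply_detection_threshold(comp_full,
                                               params$detection_threshold),
       composition_full = comp_full,
       assignments = assigned,
       reads_assigned = sum(assigned$read_count[
         !is.na(assigned$assigned_taxid)]),
       reads_total = sum(counts$reads))
}

#' Write a composition table with names and ranks
#'
#' @param comp Composition data frame.
#' @param tax A `taxonomy` object.
#' @param path Output TSV path.
#' @return The annotated data frame, invisibly.
#' @export
write_composition <- function(comp, tax, path) {
  out <- data.frame(sample_id = comp$sample_id, taxid = comp$taxid,
                    scientific_name = vapply(comp$taxid, tax_name,
                                             character(1L), tax = tax),
                    rank = vapply(comp$taxid, tax_rank, character(1L),
                                  tax = tax),
                    reads = comp$reads, proportion = comp$proportion,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Read a composition table written by [write_composition()]
#'
#' @param path TSV path.
#' @return Composition data frame (`sample_id`, `taxid`, `reads`,
#'   `proportion`).
#' @export
read_composition <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tab[, intersect(c("sample_id", "taxid", "reads", "proportion"),
                  names(tab)), drop = FALSE]
}
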