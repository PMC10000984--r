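# NCBI-style taxonomy: loading, lineage, LCA and fractional consensus.

#' Load an NCBI-style taxonomy dump
#'
#' Parses `nodes.dmp`, `names.dmp` and optionally `merged.dmp` in the NCBI
#' taxdump dialect (fields separated by `"\t|\t"`, lines terminated by
#' `"\t|"`). Only `"scientific name"` entries of the names file are used;
#' other name classes are ignored.
#'
#' @param nodes_path Path to `nodes.dmp` (taxid, parent taxid, rank, ...).
#' @param names_path Path to `names.dmp` (taxid, name, unique name, class).
#' @param merged_path Optional path to `merged.dmp` (old taxid, new taxid).
#'
#' @return A `taxonomy` object: a list with integer vector `taxids`, named
#'   integer vector `parent`, named character vectors `rank` and `name`
#'   (keyed by taxid), a named integer vector `merged` (possibly empty) and
#'   the integer `root`.
#'
#' @details The root node is identified as the unique node that is its own
#'   parent. A node whose parent taxid does not resolve to a node, or a
#'   names/merged entry pointing outside the node table, raises an error.
#'
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines("1\t|\t1\t|\tno rank\t|", file.path(dir, "nodes.dmp"))
#' writeLines("1\t|\troot\t|\t\t|\tscientific name\t|",
#'            file.path(dir, "names.dmp"))
#' tax <- load_taxdump(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"))
#' tax_root(tax)
#' @export
load_taxdump <- function(nodes_path, names_path, merged_path = NULL) {
  nodes <- parse_dmp(nodes_path, min_fields = 3L)
  taxids <- suppressWarnings(as.integer(nodes[[1L]]))
  parents <- suppressWarnings(as.integer(nodes[[2L]]))
  bad <- which(is.na(taxids) | is.na(parents) | taxids <= 0L)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: non-numeric or non-positive taxid",
                 bad[1L], nodes_path))
  }
  if (anyDuplicated(taxids)) {
    stop(sprintf("duplicate taxid %d in %s", taxids[anyDuplicated(taxids)],
                 nodes_path))
  }
  key <- as.character(taxids)
  parent <- stats::setNames(parents, key)
  rank <- stats::setNames(nodes[[3L]], key)

  unresolved <- setdiff(parents, taxids)
  if (length(unresolved)) {
    stop(sprintf("integrity error in %s: parent taxid %d has no node",
                 nodes_path, unresolved[1L]))
  }
  root <- taxids[taxids == parents]
  if (length(root) != 1L) {
    stop(sprintf("integrity error in %s: expected exactly one root, found %d",
                 nodes_path, length(root)))
  }

  nm <- parse_dmp(names_path, min_fields = 4L)
  sci <- nm[[4L]] == "scientific name"
  nm_taxid <- suppressWarnings(as.integer(nm[[1L]][sci]))
  if (anyNA(nm_taxid)) {
    stop(sprintf("malformed line %d in %s: non-numeric taxid",
                 which(sci)[which(is.na(nm_taxid))[1L]], names_path))
  }
  outside <- setdiff(nm_taxid, taxids)
  if (length(outside)) {
    stop(sprintf("integrity error in %s: name entry for unknown taxid %d",
                 names_path, outside[1L]))
  }
  name <- stats::setNames(rep(NA_character_, length(taxids)), key)
  name[as.character(nm_taxid)] <- nm[[2L]][sci]

  merged <- stats::setNames(integer(0L), character(0L))
  if (!is.null(merged_path)) {
    mg <- parse_dmp(merged_path, min_fields = 2L, allow_empty = TRUE)
    if (nrow(mg)) {
      old <- suppressWarnings(as.integer(mg[[1L]]))
      new <- suppressWarnings(as.integer(mg[[2L]]))
      if (anyNA(old) || anyNA(new)) {
        stop(sprintf("malformed line %d in %s: non-numeric taxid",
                     which(is.na(old) | is.na(new))[1L], merged_path))
      }
      missing_new <- setdiff(new, taxids)
      if (length(missing_new)) {
        stop(sprintf("integrity error in %s: merged target %d has no node",
                     merged_path, missing_new[1L]))
      }
      merged <- stats::setNames(new, as.character(old))
    }
  }

  tax <- list(taxids = taxids, parent = parent, rank = rank, name = name,
              merged = merged, root = root)
  class(tax) <- "taxonomy"
  validate_taxonomy(tax)
  tax
}

# Split a dmp file into fields; NCBI dialect "\t|\t" separators, "\t|" EOL.
parse_dmp <- function(path, min_fields, allow_empty = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    if (allow_empty) {
      return(as.data.frame(matrix(character(0L), ncol = min_fields),
                           stringsAsFactors = FALSE))
    }
    stop(sprintf("malformed file %s: empty", path))
  }
  lines <- sub("\t\\|$", "", lines)
  parts <- strsplit(lines, "\t\\|\t", fixed = FALSE)
  nf <- lengths(parts)
  if (any(nf < min_fields)) {
    stop(sprintf("malformed line %d in %s: expected >= %d fields, found %d",
                 which(nf < min_fields)[1L], path, min_fields,
                 nf[which(nf < min_fields)[1L]]))
  }
  maxf <- max(nf)
  mat <- vapply(seq_len(maxf), function(i) {
    vapply(parts, function(p) if (length(p) >= i) p[[i]] else "", character(1L))
  }, character(length(parts)))
  as.data.frame(matrix(mat, nrow = length(parts)), stringsAsFactors = FALSE)
}

validate_taxonomy <- function(tax) {
  # parent walks must terminate at root without cycles
  n <- length(tax$taxids)
  for (t in tax$taxids) {
    steps <- 0L
    cur <- t
    while (cur != tax$root) {
      cur <- tax$parent[[as.character(cur)]]
      steps <- steps + 1L
      if (steps >= n) {
        stop(sprintf("integrity error: cycle detected at taxid %d", t))
      }
    }
  }
  invisible(tax)
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("taxonomy: %d nodes, root taxid %d, %d merged ids\n",
              length(x$taxids), x$root, length(x$merged)))
  invisible(x)
}

#' Number of nodes in a taxonomy
#' @param tax A `taxonomy` object.
#' @return Integer node count.
#' @export
tax_size <- function(tax) length(tax$taxids)

#' Root taxid of a taxonomy
#' @param tax A `taxonomy` object.
#' @return Integer taxid of the root node.
#' @export
tax_root <- function(tax) tax$root

#' Resolve a taxid, remapping merged identifiers
#'
#' Merged (old) taxids remap silently to their current node, with a `message`
#' as a log record; unknown taxids raise a lookup error.
#'
#' @param tax A `taxonomy` object.
#' @param taxid Integer taxid.
#' @return The resolved integer taxid.
#' @export
resolve_taxid <- function(tax, taxid) {
  key <- as.character(taxid)
  if (!is.na(tax$parent[key])) return(as.integer(taxid))
  if (key %in% names(tax$merged)) {
    new <- tax$merged[[key]]
    message(sprintf("taxid %s merged into %d", key, new))
    return(new)
  }
  stop(sprintf("lookup error: unknown taxid %s", key))
}

#' Scientific name of a node
#' @param tax A `taxonomy` object.
#' @param taxid Integer taxid (merged ids are remapped).
#' @return Character scientific name.
#' @export
tax_name <- function(tax, taxid) {
  unname(tax$name[as.character(resolve_taxid(tax, taxid))])
}

#' Rank label of a node
#' @param tax A `taxonomy` object.
#' @param taxid Integer taxid (merged ids are remapped).
#' @return Character rank label (e.g. `"species"`, `"no rank"`).
#' @export
tax_rank <- function(tax, taxid) {
  unname(tax$rank[as.character(resolve_taxid(tax, taxid))])
}

# Root-to-node vector of taxids; the workhorse behind lineage()/lca().
lineage_ids <- function(tax, taxid) {
  cur <- resolve_taxid(tax, taxid)
  path <- cur
  while (cur != tax$root) {
    cur <- tax$parent[[as.character(cur)]]
    path <- c(cur, path)
  }
  path
}

#' Lineage of a node
#'
#' Returns the root-to-node path as a data frame, one row per node.
#'
#' @param tax A `taxonomy` object.
#' @param taxid Integer taxid (merged ids are remapped).
#' @return A data frame with columns `taxid`, `rank`, `name`, ordered from
#'   the root (first row) to the query node (last row).
#' @export
lineage <- function(tax, taxid) {
  ids <- lineage_ids(tax, taxid)
  key <- as.character(ids)
  data.frame(taxid = ids, rank = unname(tax$rank[key]),
             name = unname(tax$name[key]), stringsAsFactors = FALSE)
}

#' Last common ancestor of a set of taxids
#'
#' The deepest node present in every input lineage; equivalent to consensus
#' at level 1.
#'
#' @param tax A `taxonomy` object.
#' @param taxids Non-empty integer vector of taxids.
#' @return The integer taxid of the LCA.
#' @export
lca <- function(tax, taxids) {
  if (!length(taxids)) stop("argument error: empty taxid list")
  paths <- lapply(taxids, function(t) lineage_ids(tax, t))
  prefix <- paths[[1L]]
  for (p in paths[-1L]) {
    k <- min(length(prefix), length(p))
    eq <- prefix[seq_len(k)] == p[seq_len(k)]
    depth <- if (all(eq)) k else which(!eq)[1L] - 1L
    prefix <- prefix[seq_len(depth)]
  }
  prefix[length(prefix)]
}

#' Fractional consensus taxon of a vote list
#'
#' Descends from the root, at each depth moving to the (necessarily unique,
#' since `level > 0.5`) child whose subtree covers at least `level` of the
#' votes; stops when no child qualifies. Duplicate taxids count multiply:
#' the vote list is taken as-is, and any dereplication to unique taxa is the
#' caller's responsibility. At `level = 1` the result equals [lca()].
#'
#' @param tax A `taxonomy` object.
#' @param taxids Non-empty integer vector of votes (duplicates allowed).
#' @param level Required fraction of votes, in `(0.5, 1]`. The comparison is
#'   `>= level`.
#' @return The integer taxid of the deepest node covered by at least `level`
#'   of the vote lineages.
#' @export
consensus_taxon <- function(tax, taxids, level) {
  if (!length(taxids)) stop("argument error: empty taxid list")
  if (!is.numeric(level) || length(level) != 1L || level <= 0.5 || level > 1) {
    stop("argument error: consensus level must be in (0.5, 1]")
  }
  paths <- lapply(taxids, function(t) lineage_ids(tax, t))
  n <- length(paths)
  depth <- 1L                       # all lineages start at the root
  repeat {
    nxt <- vapply(paths, function(p) {
      if (length(p) > depth) p[depth + 1L] else NA_integer_
    }, integer(1L))
    nxt <- nxt[!is.na(nxt)]
    if (!length(nxt)) break
    counts <- table(nxt)
    qual <- counts[counts / n >= level]
    if (!length(qual)) break
    child <- as.integer(names(qual)[1L])   # level > 0.5 ensures uniqueness
    paths <- paths[vapply(paths, function(p)
      length(p) > depth && p[depth + 1L] == child, logical(1L))]
    # keep only covering lineages for the next depth, but the vote total n
    # stays fixed: fractions are always of the full vote list
    depth <- depth + 1L
    node <- child
    if (!length(paths)) break
  }
  if (depth == 1L) tax$root else node
}

#' Ancestor of a node at a given rank
#'
#' @param tax A `taxonomy` object.
#' @param taxid Integer taxid (merged ids are remapped).
#' @param rank Rank label to look for (e.g. `"genus"`).
#' @return The integer taxid of the lineage node carrying `rank`, or `NA`
#'   if the lineage has no node at that rank (the node sits above it, or the
#'   lineage skips the rank).
#' @export
ancestor_at_rank <- function(tax, taxid, rank) {
  ids <- lineage_ids(tax, taxid)
  ranks <- unname(tax$rank[as.character(ids)])
  hit <- which(ranks == rank)
  if (length(hit)) ids[hit[length(hit)]] else NA_integer_
}

#' Is a node at or below a given rank?
#'
#' True when the node's lineage (including itself) contains a node carrying
#' the rank label. `"no rank"` nodes are kept in lineages but never match a
#' rank query.
#'
#' @param tax A `taxonomy` object.
#' @param taxid Integer taxid.
#' @param rank Rank label.
#' @return Logical.
#' @export
at_or_below_rank <- function(tax, taxid, rank) {
  !is.na(ancestor_at_rank(tax, taxid, rank))
}
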