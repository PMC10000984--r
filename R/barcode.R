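# In-silico PCR: degenerate primer matching, barcode extraction,
# pairwise-identity analysis and taxonomic resolution prediction.

IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

# Bitmask encoding of a sequence. Degenerate codes expand to their base
# sets; in `target` mode an N (or any non-ACGT letter) matches nothing.
seq_mask <- function(x, mode = c("primer", "target")) {
  mode <- match.arg(mode)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  m <- IUPAC_MASK[chars]
  if (mode == "primer") {
    if (anyNA(m)) {
      stop(sprintf("invalid IUPAC letter '%s' in primer",
                   chars[which(is.na(m))[1L]]))
    }
  } else {
    m[chars == "N"] <- 0L
    m[is.na(m)] <- 0L
  }
  unname(m)
}

#' Reverse complement of a (possibly degenerate) nucleotide string
#'
#' @param x Character sequence (IUPAC alphabet).
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' A PCR primer pair
#'
#' @param forward,reverse IUPAC nucleotide strings; the reverse primer is
#'   given 5'-to-3' on the opposite strand, as primers are ordered.
#' @return A list of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse) {
  stopifnot(nzchar(forward), nzchar(reverse))
  seq_mask(forward, "primer")  # validates the alphabet
  seq_mask(reverse, "primer")
  structure(list(forward = toupper(forward), reverse = toupper(reverse)),
            class = "primer_pair")
}

#' Find primer annealing sites on a target sequence
#'
#' Ungapped sliding-window matching with IUPAC semantics: a degenerate
#' primer position matches any base of its expansion set, while an N in the
#' target matches nothing. Partial matches are anchored to the primer 3'
#' end: up to `1 - min_coverage` of the primer may overhang the target
#' 5'-ward, but the 3'-proximal part must align contiguously. For every
#' 3'-end placement on either strand the longest aligned span with identity
#' at least `min_identity` is reported.
#'
#' @param primer IUPAC primer string (5' to 3').
#' @param target ACGTN target string.
#' @param min_coverage Minimum aligned fraction of the primer (default
#'   `0.8`).
#' @param min_identity Minimum identity over the aligned span (default
#'   `0.65`).
#' @return A data frame with 1-based inclusive `start`, `end` on the
#'   target, `strand` (`"+"` if the window itself matches the primer,
#'   `"-"` if its reverse complement does), `mismatches` and aligned
#'   `length`. Empty when the target is shorter than the minimum span.
#' @export
match_primer <- function(primer, target, min_coverage = 0.8,
                         min_identity = 0.65) {
  pm <- seq_mask(primer, "primer")
  tm <- seq_mask(target, "target")
  L <- length(pm)
  n <- length(tm)
  min_k <- as.integer(ceiling(min_coverage * L))
  out <- list()
  if (n >= min_k) {
    # plus strand: primer 3' end is the window's right edge; 5' truncation
    # shortens the window from the left
    out <- c(out, scan_windows(pm, tm, min_k, min_identity,
                               anchor = "right", strand = "+"))
    # minus strand: the reverse complement of the primer is matched against
    # the plus strand; the primer 3' end is then the window's LEFT edge
    rc <- rev(vapply(pm, comp_mask, integer(1L)))
    out <- c(out, scan_windows(rc, tm, min_k, min_identity,
                               anchor = "left", strand = "-"))
  }
  if (!length(out)) {
    return(data.frame(start = integer(0L), end = integer(0L),
                      strand = character(0L), mismatches = integer(0L),
                      length = integer(0L), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

comp_mask <- function(m) {
  # complement of a 4-bit base set: swap A<->T and C<->G bits
  a <- bitwAnd(m, 1L); c_ <- bitwAnd(m, 2L)
  g <- bitwAnd(m, 4L); t <- bitwAnd(m, 8L)
  bitwOr(bitwOr(if (a) 8L else 0L, if (c_) 4L else 0L),
         bitwOr(if (g) 2L else 0L, if (t) 1L else 0L))
}

# Slide spans of the (possibly truncated) primer mask over the target.
# anchor = "right": truncation removes the left end of the primer mask
# (plus-strand 5' truncation); anchor = "left": removes the right end
# (minus-strand representation). Truncated spans are only allowed where
# the primer 5' end would overhang the target boundary — the 3'-proximal
# part must lie on the target — so interior placements are always
# full-length. For each 3'-end placement keep the longest span meeting
# the identity threshold.
scan_windows <- function(pmask, tmask, min_k, min_identity, anchor, strand) {
  L <- length(pmask)
  n <- length(tmask)
  hits <- list()
  taken <- integer(0L)  # 3'-end positions already reported (longest first)
  for (k in seq(L, min_k)) {
    sub <- if (anchor == "right") pmask[(L - k + 1L):L] else pmask[1:k]
    if (k > n) next
    starts <- if (k == L) 1:(n - k + 1L)
              else if (anchor == "right") 1L else n - k + 1L
    for (s in starts) {
      window <- tmask[s:(s + k - 1L)]
      matches <- sum(bitwAnd(sub, window) > 0L)
      if (matches / k < min_identity) next
      end3 <- if (anchor == "right") s + k - 1L else s
      if (end3 %in% taken) next
      taken <- c(taken, end3)
      hits[[length(hits) + 1L]] <-
        data.frame(start = s, end = s + k - 1L, strand = strand,
                   mismatches = k - matches, length = k,
                   stringsAsFactors = FALSE)
    }
  }
  hits
}

#' Extract barcodes flanked by a facing primer pair
#'
#' For every facing placement of the two primers on a reference sequence
#' (forward on the plus strand upstream of the reverse-complemented
#' reverse primer, or the mirror arrangement on the minus strand) within
#' `max_product_len`, the inter-primer sequence is emitted with both
#' primer spans removed. Minus-strand products are reverse-complemented
#' so every barcode is reported in the forward orientation.
#'
#' @param references Named character vector of reference sequences, or a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file (plain or
#'   gzipped).
#' @param taxid_map Data frame `sequence_id`, `taxid` covering the used
#'   records; records without a taxid are skipped with a warning.
#' @param pair A [primer_pair()].
#' @param max_product_len Maximum amplicon length in bp including primers
#'   (default 2000).
#' @param min_coverage,min_identity Primer-matching thresholds, see
#'   [match_primer()].
#' @return A data frame of barcode records: `taxid`, `sequence`,
#'   `source_id`, `start`, `end` (0-based half-open on the source),
#'   `strand`.
#' @export
extract_barcodes <- function(references, taxid_map, pair,
                             max_product_len = 2000,
                             min_coverage = 0.8, min_identity = 0.65) {
  seqs <- as_named_sequences(references)
  out <- list()
  skipped <- 0L
  for (id in names(seqs)) {
    taxid <- taxid_map$taxid[match(id, taxid_map$sequence_id)]
    if (is.na(taxid)) {
      skipped <- skipped + 1L
      next
    }
    target <- toupper(seqs[[id]])
    fwd <- match_primer(pair$forward, target, min_coverage, min_identity)
    rev <- match_primer(pair$reverse, target, min_coverage, min_identity)
    # plus orientation: forward(+) ... revcomp(reverse) i.e. reverse(-)
    for (i in seq_len(nrow(fwd))) {
      if (fwd$strand[i] != "+") next
      for (j in seq_len(nrow(rev))) {
        if (rev$strand[j] != "-") next
        if (rev$start[j] <= fwd$end[i]) next
        if (rev$end[j] - fwd$start[i] + 1L > max_product_len) next
        bc <- substr(target, fwd$end[i] + 1L, rev$start[j] - 1L)
        if (!nzchar(bc)) next
        out[[length(out) + 1L]] <- data.frame(
          taxid = taxid, sequence = bc, source_id = id,
          start = fwd$end[i], end = rev$start[j] - 1L, strand = "+",
          stringsAsFactors = FALSE)
      }
    }
    # minus orientation: reverse(+) ... revcomp(forward) i.e. forward(-)
    for (i in seq_len(nrow(fwd))) {
      if (fwd$strand[i] != "-") next
      for (j in seq_len(nrow(rev))) {
        if (rev$strand[j] != "+") next
        if (fwd$start[i] <= rev$end[j]) next
        if (fwd$end[i] - rev$start[j] + 1L > max_product_len) next
        bc <- substr(target, rev$end[j] + 1L, fwd$start[i] - 1L)
        if (!nzchar(bc)) next
        out[[length(out) + 1L]] <- data.frame(
          taxid = taxid, sequence = revcomp(bc), source_id = id,
          start = rev$end[j], end = fwd$start[i] - 1L, strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (skipped) warning(sprintf("%d record(s) skipped: no taxid", skipped))
  if (!length(out)) {
    return(data.frame(taxid = integer(0L), sequence = character(0L),
                      source_id = character(0L), start = integer(0L),
                      end = integer(0L), strand = character(0L),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

as_named_sequences <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    return(stats::setNames(as.character(x), names(x)))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    names(ss) <- sub("\\s.*$", "", names(ss))
    return(stats::setNames(as.character(ss), names(ss)))
  }
  stopifnot(is.character(x), !is.null(names(x)))
  x
}

#' Dereplicate barcodes taxon-wise
#'
#' Collapses records to one representative per (taxid, exact sequence),
#' keeping the number of collapsed copies.
#'
#' @param barcodes Barcode data frame from [extract_barcodes()].
#' @return The dereplicated data frame with an integer `count` column.
#' @export
dereplicate_taxonwise <- function(barcodes) {
  if (!nrow(barcodes)) {
    out <- barcodes
    out$count <- integer(0L)
    return(out)
  }
  key <- paste(barcodes$taxid, barcodes$sequence, sep = "\r")
  first <- !duplicated(key)
  out <- barcodes[first, , drop = FALSE]
  out$count <- as.integer(table(key)[key[first]])
  rownames(out) <- NULL
  out
}

#' Global pairwise identity of two sequences
#'
#' End-to-end Needleman-Wunsch alignment (match +2, mismatch -4, gap open
#' -20, gap extend -2); the hamming distance is the number of non-identical
#' alignment columns (mismatches plus gap columns) and the identity is
#' `1 - hamming / alignment length`. The alignment-length denominator
#' keeps the formula well-defined for unequal sequence lengths.
#'
#' @param a,b Non-empty ACGT sequences.
#' @return Identity fraction in `[0, 1]`.
#' @export
global_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -4, baseOnly = TRUE),
    gapOpening = 20, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  sum(p == s & p != "-") / length(p)
}

#' Pairwise identity matrix over a barcode set
#'
#' @param barcodes Barcode data frame (dereplicated); row order is kept.
#' @return A symmetric numeric matrix with unit diagonal, one row/column
#'   per barcode.
#' @export
identity_matrix <- function(barcodes) {
  n <- nrow(barcodes)
  m <- diag(1, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <- global_identity(barcodes$sequence[i],
                                              barcodes$sequence[j])
      }
    }
  }
  m
}

#' Predicted taxonomic resolution of a barcode set
#'
#' For every barcode and identity level, collects all set members within
#' the identity level (inclusive, and always including the barcode
#' itself), dereplicates to unique taxa, and takes the strict-majority
#' consensus taxon. The summary reports, per level, the percentage of
#' barcodes whose consensus sits at species rank or below and at genus
#' rank or below, alongside the number of taxa retrieved, the median
#' number of unique barcodes per taxid and the median barcode length.
#'
#' @param barcodes Dereplicated barcode data frame.
#' @param tax A `taxonomy` object.
#' @param identity_levels Numeric identity levels (default
#'   `c(0.97, 1.0)`).
#' @param consensus_level Majority level for the neighborhood vote
#'   (default `0.51`).
#' @param idm Optional precomputed [identity_matrix()].
#' @return A list: `summary` (data frame `identity_level`,
#'   `pct_species_or_below`, `pct_genus_or_below`), `per_barcode` (data
#'   frame with the consensus taxid and rank flags per level),
#'   `n_taxids`, `median_barcodes_per_taxid`, `median_length`.
#' @export
resolution_summary <- function(barcodes, tax,
                               identity_levels = c(0.97, 1.0),
                               consensus_level = 0.51, idm = NULL) {
  stopifnot(nrow(barcodes) >= 1L)
  if (is.null(idm)) idm <- identity_matrix(barcodes)
  per <- list()
  summ <- list()
  for (lev in identity_levels) {
    cons <- vapply(seq_len(nrow(barcodes)), function(i) {
      members <- which(idm[i, ] >= lev)
      taxa <- unique(barcodes$taxid[members])
      consensus_taxon(tax, taxa, consensus_level)
    }, integer(1L))
    sp <- vapply(cons, at_or_below_rank, logical(1L), tax = tax,
                 rank = "species")
    ge <- vapply(cons, at_or_below_rank, logical(1L), tax = tax,
                 rank = "genus")
    per[[length(per) + 1L]] <- data.frame(
      identity_level = lev, barcode = seq_len(nrow(barcodes)),
      taxid = barcodes$taxid, consensus_taxid = cons,
      consensus_rank = vapply(cons, tax_rank, character(1L), tax = tax),
      species_or_below = sp, genus_or_below = ge,
      stringsAsFactors = FALSE)
    summ[[length(summ) + 1L]] <- data.frame(
      identity_level = lev,
      pct_species_or_below = 100 * mean(sp),
      pct_genus_or_below = 100 * mean(ge))
  }
  counts <- table(barcodes$taxid)
  list(summary = do.call(rbind, summ),
       per_barcode = do.call(rbind, per),
       n_taxids = length(counts),
       median_barcodes_per_taxid = stats::median(as.integer(counts)),
       median_length = stats::median(nchar(barcodes$sequence)))
}

#' Presence/absence of barcodes for a target species list
#'
#' @param barcodes Barcode data frame.
#' @param tax A `taxonomy` object.
#' @param taxids Integer vector of target taxids.
#' @return Data frame `taxid`, `scientific_name`, `present` (logical:
#'   at least one barcode retrieved for that taxid).
#' @export
barcode_presence <- function(barcodes, tax, taxids) {
  data.frame(taxid = taxids,
             scientific_name = vapply(taxids, tax_name, character(1L),
                                      tax = tax),
             present = taxids %in% barcodes$taxid,
             stringsAsFactors = FALSE)
}
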