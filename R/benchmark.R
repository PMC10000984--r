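# Validation metrics: confusion counts, precision/recall/F-beta, threshold
# sweep, composition distances, yield and splitting level.

#' Read an expected-composition table
#'
#' @param path TSV with header columns `sample_id`, `taxid`, `proportion`.
#' @return Data frame with those columns. Entries may sum to less than 1
#'   (trace-contaminated reference material); they are never renormalized.
#' @export
read_expected <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "taxid", "proportion")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop(sprintf("format error: expected-composition file lacks %s",
                 paste(missing, collapse = ", ")))
  }
  stopifnot(all(tab$proportion > 0), all(tab$proportion <= 1))
  tab[, need, drop = FALSE]
}

#' Confusion counts between expected and observed compositions
#'
#' Both compositions are rolled up to `rank`; the observed one is then
#' thresholded at `threshold`. Matching is open-world (no true negatives):
#' true positives are observed rank-level nodes that equal an expected
#' rank-level node, remaining observed entries (including entries flagged
#' `above_rank`, which cannot match) are false positives, and unmatched
#' expected entries are false negatives.
#'
#' @param expected Expected composition data frame (`taxid`, `proportion`).
#' @param observed Observed composition data frame (`taxid`, `proportion`).
#' @param tax A `taxonomy` object.
#' @param rank Evaluation rank, e.g. `"genus"`.
#' @param threshold Detection threshold applied to the observed
#'   composition (rank level), default `0.001`.
#' @return A list of class `confusion` with integer `tp`, `fp`, `fn`.
#' @export
match_compositions <- function(expected, observed, tax, rank,
                               threshold = 0.001) {
  exp_r <- rollup_to_rank(expected, tax, rank)
  obs_r <- apply_detection_threshold(rollup_to_rank(observed, tax, rank),
                                     threshold)
  confusion_at_rank(exp_r, obs_r)
}

# Confusion on already rank-rolled frames; observed already thresholded.
# Above-rank entries can never match: observed ones are FP, expected FN.
confusion_at_rank <- function(exp_r, obs_r) {
  exp_nodes <- exp_r$taxid[!exp_r$above_rank]
  obs_match <- !obs_r$above_rank & obs_r$taxid %in% exp_nodes
  tp <- sum(obs_match)
  fp <- nrow(obs_r) - tp
  fn <- sum(!exp_nodes %in% obs_r$taxid[obs_match]) + sum(exp_r$above_rank)
  confusion(tp, fp, fn)
}

#' Construct confusion counts
#' @param tp,fp,fn Non-negative integer counts.
#' @return A list of class `confusion`.
#' @export
confusion <- function(tp = 0L, fp = 0L, fn = 0L) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)), class = "confusion")
}

#' Sum confusion counts over samples
#' @param ... `confusion` objects or a list of them.
#' @return The aggregated `confusion`.
#' @export
aggregate_confusion <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "confusion")) xs <- xs[[1L]]
  confusion(sum(vapply(xs, `[[`, integer(1L), "tp")),
            sum(vapply(xs, `[[`, integer(1L), "fp")),
            sum(vapply(xs, `[[`, integer(1L), "fn")))
}

#' Precision and recall from confusion counts
#'
#' Exact ratios `tp/(tp+fp)` and `tp/(tp+fn)`. An undefined ratio (zero
#' denominator) is reported as `NA`, never as 0.
#'
#' @param conf A `confusion` object.
#' @return A list with `precision` and `recall` fractions (or `NA`).
#' @export
precision_recall <- function(conf) {
  list(precision = if (conf$tp + conf$fp > 0)
         conf$tp / (conf$tp + conf$fp) else NA_real_,
       recall = if (conf$tp + conf$fn > 0)
         conf$tp / (conf$tp + conf$fn) else NA_real_)
}

#' Round a fraction to integer percent, half away from zero
#'
#' Display convention for reports; machine outputs keep the raw fractions.
#'
#' @param x Numeric fraction(s) in `[-1, 1]`.
#' @return Integer percent(s).
#' @export
percent <- function(x) {
  sign(x) * floor(abs(x) * 100 + 0.5)
}

#' F-beta score
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`; 0 when both are 0. The
#' default `beta = 2` weights recall twice as heavily as precision, the
#' operating point used for detection-threshold optimization.
#'
#' @param precision,recall Fractions in `[0, 1]`.
#' @param beta Positive weight (default 2).
#' @return The F-beta score.
#' @export
fbeta <- function(precision, recall, beta = 2) {
  stopifnot(beta > 0)
  ifelse(precision == 0 & recall == 0, 0,
         (1 + beta^2) * precision * recall /
           (beta^2 * precision + recall))
}

#' Geometric-mean precision-recall
#'
#' `sqrt(P * R)`, the qualitative accuracy summary ("average precision" in
#' the geometric-mean sense).
#'
#' @param precision,recall Fractions in `[0, 1]`.
#' @return The geometric mean.
#' @export
gpr <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  sqrt(precision * recall)
}

#' Precision-recall sweep over detection thresholds
#'
#' Recomputes the aggregate confusion over all samples at every threshold
#' on a regular grid (default step 0.01% of total composition) and finds
#' the threshold maximizing the F-beta score. Ties are broken toward the
#' smallest threshold.
#'
#' @param expected_list Named list of expected compositions, one per
#'   sample.
#' @param observed_list Named list of observed compositions (pre-threshold)
#'   with matching names.
#' @param tax A `taxonomy` object.
#' @param rank Evaluation rank.
#' @param step Grid step as a fraction (default `1e-4`).
#' @param beta F-score weight (default 2).
#' @return A list: `curve` (data frame `threshold`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `fbeta`) and `optimal_threshold` (smallest
#'   grid threshold attaining the maximal F-beta).
#' @export
pr_threshold_sweep <- function(expected_list, observed_list, tax, rank,
                               step = 1e-4, beta = 2) {
  stopifnot(step > 0)
  if (!length(expected_list) || length(expected_list) != length(observed_list)) {
    stop("argument error: need matching non-empty expected/observed sets")
  }
  exp_rolled <- lapply(expected_list, rollup_to_rank, tax = tax, rank = rank)
  obs_rolled <- lapply(observed_list, rollup_to_rank, tax = tax, rank = rank)
  max_p <- max(vapply(obs_rolled, function(o)
    if (nrow(o)) max(o$proportion) else 0, numeric(1L)))
  thresholds <- seq(0, max_p + step, by = step)
  rows <- lapply(thresholds, function(T) {
    confs <- mapply(function(e, o)
      confusion_at_rank(e, apply_detection_threshold(o, T)),
      exp_rolled, obs_rolled, SIMPLIFY = FALSE)
    agg <- aggregate_confusion(confs)
    pr <- precision_recall(agg)
    p <- if (is.na(pr$precision)) 0 else pr$precision
    r <- if (is.na(pr$recall)) 0 else pr$recall
    data.frame(threshold = T, tp = agg$tp, fp = agg$fp, fn = agg$fn,
               precision = p, recall = r, fbeta = fbeta(p, r, beta))
  })
  curve <- do.call(rbind, rows)
  list(curve = curve,
       optimal_threshold = curve$threshold[which.max(curve$fbeta)])
}

#' Euclidean (L2) distance between compositions
#'
#' Both compositions are rolled up to `rank`; vectors are indexed by the
#' union of rank-level nodes, missing entries count as 0, and the L2 norm
#' of the difference is returned (proportions as fractions).
#'
#' @param expected Expected composition data frame.
#' @param observed Observed composition data frame.
#' @param tax A `taxonomy` object.
#' @param rank Evaluation rank.
#' @return Non-negative distance.
#' @export
euclidean_distance <- function(expected, observed, tax, rank) {
  exp_r <- rollup_to_rank(expected, tax, rank)
  obs_r <- rollup_to_rank(observed, tax, rank)
  nodes <- union(exp_r$taxid, obs_r$taxid)
  e <- exp_r$proportion[match(nodes, exp_r$taxid)]
  o <- obs_r$proportion[match(nodes, obs_r$taxid)]
  e[is.na(e)] <- 0
  o[is.na(o)] <- 0
  sqrt(sum((o - e)^2))
}

#' Relative quantification error of a true positive
#'
#' `(predicted - expected) / expected`, signed; defined only for
#' components with a positive expected proportion.
#'
#' @param expected_p Expected proportion(s), strictly positive.
#' @param predicted_p Predicted proportion(s).
#' @return Signed relative error(s).
#' @export
relative_error <- function(expected_p, predicted_p) {
  if (any(expected_p <= 0)) {
    stop("argument error: relative error undefined for expected <= 0")
  }
  (predicted_p - expected_p) / expected_p
}

#' Yield of the analysis
#'
#' Fraction of input reads retained through to taxonomic assignment.
#'
#' @param reads_in Reads entering the stage (positive).
#' @param reads_assigned Reads surviving it, `0 <= reads_assigned <=
#'   reads_in`.
#' @return Fraction in `[0, 1]`.
#' @export
yield_fraction <- function(reads_in, reads_assigned) {
  if (any(reads_in <= 0)) stop("argument error: reads_in must be positive")
  stopifnot(all(reads_assigned >= 0), all(reads_assigned <= reads_in))
  reads_assigned / reads_in
}

#' Per-stage yield report
#'
#' @param counts Named numeric vector of read counts per stage, the first
#'   element being the input (e.g. `c(input = 1000, merged = 980,
#'   clustered = 970, assigned = 960)`).
#' @return Named vector of fractions of the input for every later stage.
#' @export
yield_stages <- function(counts) {
  stopifnot(length(counts) >= 2L)
  yield_fraction(counts[[1L]], counts[-1L])
}

#' Splitting level of a sample
#'
#' `log10(n_clusters / n_expected_components)`: 0 means one cluster per
#' true sequence, 1 means each true sequence is split over ten clusters.
#'
#' @param n_clusters Number of read clusters (>= 1).
#' @param n_expected_components Number of expected components (>= 1).
#' @return The splitting level.
#' @export
splitting_level <- function(n_clusters, n_expected_components) {
  if (any(n_clusters < 1) || any(n_expected_components < 1)) {
    stop("argument error: counts must be >= 1")
  }
  log10(n_clusters / n_expected_components)
}

#' Benchmark a set of observed compositions against expectations
#'
#' Aggregates confusion counts over samples at the given rank and
#' threshold, and reports precision, recall, F-beta, geometric-mean
#' precision-recall, per-sample Euclidean distances and per-component
#' relative errors of true positives.
#'
#' @param expected_list Named list of expected compositions.
#' @param observed_list Named list of observed compositions
#'   (pre-threshold), names matching `expected_list`.
#' @param tax A `taxonomy` object.
#' @param rank Evaluation rank.
#' @param threshold Detection threshold (default `0.001`).
#' @param beta F-score weight (default 2).
#' @return A list of class `benchmark_report`: `confusion`, `precision`,
#'   `recall`, `fbeta`, `gpr`, `per_sample` (data frame with per-sample
#'   tp/fp/fn and Euclidean distance) and `relative_errors` (data frame
#'   per true-positive component).
#' @export
benchmark_compositions <- function(expected_list, observed_list, tax, rank,
                                   threshold = 0.001, beta = 2) {
  stopifnot(length(expected_list) == length(observed_list),
            length(expected_list) >= 1L)
  ids <- names(expected_list)
  if (is.null(ids)) ids <- as.character(seq_along(expected_list))
  per <- lapply(seq_along(ids), function(i) {
    e <- expected_list[[i]]
    o <- observed_list[[i]]
    conf <- match_compositions(e, o, tax, rank, threshold)
    o_thr <- apply_detection_threshold(rollup_to_rank(o, tax, rank),
                                       threshold)
    e_r <- rollup_to_rank(e, tax, rank)
    dist <- euclidean_distance(e, apply_detection_threshold(o, threshold),
                               tax, rank)
    shared <- intersect(e_r$taxid[!e_r$above_rank],
                        o_thr$taxid[!o_thr$above_rank])
    rel <- if (length(shared)) {
      data.frame(sample_id = ids[i], taxid = shared,
                 expected = e_r$proportion[match(shared, e_r$taxid)],
                 predicted = o_thr$proportion[match(shared, o_thr$taxid)],
                 stringsAsFactors = FALSE)
    } else NULL
    list(conf = conf, dist = dist, rel = rel)
  })
  agg <- aggregate_confusion(lapply(per, `[[`, "conf"))
  pr <- precision_recall(agg)
  rel <- do.call(rbind, Filter(Negate(is.null), lapply(per, `[[`, "rel")))
  if (!is.null(rel)) {
    rel$relative_error <- relative_error(rel$expected, rel$predicted)
  }
  structure(list(
    confusion = agg, precision = pr$precision, recall = pr$recall,
    fbeta = fbeta(pr$precision, pr$recall, beta),
    gpr = gpr(pr$precision, pr$recall),
    per_sample = data.frame(
      sample_id = ids,
      tp = vapply(per, function(x) x$conf$tp, integer(1L)),
      fp = vapply(per, function(x) x$conf$fp, integer(1L)),
      fn = vapply(per, function(x) x$conf$fn, integer(1L)),
      euclidean = vapply(per, `[[`, numeric(1L), "dist"),
      stringsAsFactors = FALSE),
    relative_errors = rel), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark: TP %d FP %d FN %d | precision %d%% recall %d%%\n",
              x$confusion$tp, x$confusion$fp, x$confusion$fn,
              percent(x$precision), percent(x$recall)))
  invisible(x)
}
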