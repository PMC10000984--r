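# Seeded, pairing-preserving down-sampling of paired FASTQ files.

read_fastq_records <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("format error: %s has %d lines, not a multiple of 4",
                 path, length(lines)))
  }
  lines
}

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}

#' Seed for a down-sampling run
#'
#' The sample size and replicate number are concatenated as decimal digit
#' strings and read back as one integer, e.g. size 1000 and replicate 2
#' give seed 10002.
#'
#' @param size Number of read pairs to draw.
#' @param replicate Replicate index.
#' @return Integer seed.
#' @export
downsample_seed <- function(size, replicate) {
  seed <- suppressWarnings(as.integer(paste0(size, replicate)))
  if (is.na(seed)) {
    stop("argument error: concatenated seed exceeds integer range")
  }
  seed
}

#' Down-sample a pair of FASTQ files
#'
#' Draws `size` read pairs without replacement using the concatenated
#' `size`/`replicate` seed; the same index set is applied to both mates so
#' pairing is preserved, and output order follows input order. Running
#' twice with the same arguments produces byte-identical outputs.
#'
#' @param fastq_r1,fastq_r2 Input FASTQ paths (plain or `.gz`), same
#'   number of records in the same order.
#' @param size Number of read pairs to keep; must not exceed the number
#'   available.
#' @param replicate Replicate index, combined with `size` into the seed.
#' @param out_r1,out_r2 Output paths; `.gz` suffixes are honored.
#' @return Invisibly, a list with the `seed` used, the selected (sorted)
#'   `indices`, and the output paths.
#' @export
downsample_reads <- function(fastq_r1, fastq_r2, size, replicate,
                             out_r1, out_r2) {
  r1 <- read_fastq_records(fastq_r1)
  r2 <- read_fastq_records(fastq_r2)
  n1 <- length(r1) %/% 4L
  n2 <- length(r2) %/% 4L
  if (n1 != n2) {
    stop(sprintf("format error: unequal record counts (%d vs %d)", n1, n2))
  }
  if (size > n1) {
    stop(sprintf("argument error: size %d exceeds available %d records",
                 size, n1))
  }
  seed <- downsample_seed(size, replicate)
  idx <- withr_seed(seed, sort(sample.int(n1, size)))
  keep <- as.vector(vapply(idx, function(i) (i - 1L) * 4L + 1:4,
                           integer(4L)))
  con1 <- open_out(out_r1); on.exit(close(con1), add = TRUE)
  con2 <- open_out(out_r2); on.exit(close(con2), add = TRUE)
  writeLines(r1[keep], con1)
  writeLines(r2[keep], con2)
  invisible(list(seed = seed, indices = idx, out_r1 = out_r1,
                 out_r2 = out_r2))
}

# Evaluate expr under a fixed RNG state, restoring the caller's state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}
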