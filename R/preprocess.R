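# Adapter trimming and per-protocol length selection.

LENGTH_WINDOWS <- list(bmn4_pirna = c(24L, 29L), bmn4_cp = c(30L, 70L),
                       mouse_pirna = c(25L, 33L), mouse_cp = c(34L, 70L))

# Hamming mismatches between two equal-length strings; N counts as mismatch.
hamming_mm <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(av != bv | av == "N" | bv == "N")
}

#' Trim the 3' adapter from a read
#'
#' cutadapt-style single-pass 3' trimming: the leftmost read suffix that
#' matches a prefix of the adapter with at most `max_err_frac` mismatches
#' over the overlap (and overlap >= `min_overlap`) is removed. N bases count
#' as mismatches. Untrimmed reads pass through unchanged and are flagged.
#'
#' @param sequence Read sequence(s), DNA, sequenced strand (vectorized).
#' @param adapter 3' adapter DNA sequence; must be at least `min_overlap`
#'   long.
#' @param min_overlap Minimum read/adapter overlap (default 6).
#' @param max_err_frac Maximum mismatch fraction over the overlap
#'   (default 0.1).
#' @return Data frame with columns `sequence` (trimmed) and `trimmed`
#'   (logical flag).
#' @examples
#' trim_adapter("ACGTACGTTGGAATTC", "TGGAATTCTCGG")
#' @export
trim_adapter <- function(sequence, adapter, min_overlap = 6L,
                         max_err_frac = 0.1) {
  stopifnot(nchar(adapter) >= min_overlap)
  alen <- nchar(adapter)
  out_seq <- sequence
  out_flag <- logical(length(sequence))
  for (r in seq_along(sequence)) {
    read <- sequence[r]
    rlen <- nchar(read)
    if (rlen < min_overlap) next
    for (p in 1:(rlen - min_overlap + 1L)) {
      ov <- min(alen, rlen - p + 1L)
      mm <- hamming_mm(substr(read, p, p + ov - 1L), substr(adapter, 1L, ov))
      if (mm <= floor(max_err_frac * ov)) {
        out_seq[r] <- substr(read, 1L, p - 1L)
        out_flag[r] <- TRUE
        break
      }
    }
  }
  data.frame(sequence = out_seq, trimmed = out_flag, stringsAsFactors = FALSE)
}

#' Trim a read table and report
#'
#' Applies [trim_adapter()] to a read data frame and attaches a JSON-able
#' trimming report.
#'
#' @param reads Data frame with `id` and `sequence`.
#' @param adapter 3' adapter sequence.
#' @param min_len Reads shorter than this after trimming are dropped
#'   (default 1, i.e. only empty reads are dropped).
#' @inheritParams trim_adapter
#' @return List with `reads` (trimmed data frame, dropped reads removed,
#'   `trimmed` flag retained) and `report` (counts trimmed / untrimmed /
#'   dropped).
#' @export
trim_reads <- function(reads, adapter, min_overlap = 6L, max_err_frac = 0.1,
                       min_len = 1L) {
  tr <- trim_adapter(reads$sequence, adapter, min_overlap, max_err_frac)
  out <- reads
  out$sequence <- tr$sequence
  out$trimmed <- tr$trimmed
  drop <- nchar(out$sequence) < min_len
  report <- list(n_input = nrow(reads), n_trimmed = sum(tr$trimmed),
                 n_untrimmed = sum(!tr$trimmed), n_dropped = sum(drop))
  list(reads = out[!drop, , drop = FALSE], report = report)
}

#' Select reads by library-specific length window
#'
#' Inclusive windows: 24-29 nt (`bmn4_pirna`), 30-70 nt (`bmn4_cp`),
#' 25-33 nt (`mouse_pirna`), 34-70 nt (`mouse_cp`).
#'
#' @param reads Data frame with a `sequence` column.
#' @param library_kind One of the four window names.
#' @return The rows of `reads` whose lengths fall in the window.
#' @export
length_filter <- function(reads, library_kind) {
  if (!library_kind %in% names(LENGTH_WINDOWS))
    stop("unknown library kind: ", library_kind, call. = FALSE)
  w <- LENGTH_WINDOWS[[library_kind]]
  len <- nchar(reads$sequence)
  reads[len >= w[1] & len <= w[2], , drop = FALSE]
}
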