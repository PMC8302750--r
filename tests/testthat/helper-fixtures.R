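# Shared fixtures and independent oracles for the test suite.

# All 8 physical initial end states (blocked/destroyed are not inputs).
all_end_states <- function() {
  expand.grid(five = c("phosphate", "hydroxyl"),
              three = c("cyclic_phosphate", "monophosphate", "hydroxyl",
                        "hydroxyl_2Ome"),
              stringsAsFactors = FALSE)
}

# Independent brute-force mapper: all placements of `read` on both strands
# of every reference within floor(max_mm_frac * len) mismatches, minimum
# mismatch count only. Pure base R, no Biostrings.
oracle_map_one <- function(read, refs, max_mm_frac = 0.05) {
  revcomp_dna <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  len <- nchar(read)
  mm_allow <- floor(max_mm_frac * len)
  hits <- list()
  for (fid in names(refs)) {
    ref <- refs[[fid]]
    L <- nchar(ref)
    if (L < len) next
    refv <- strsplit(ref, "")[[1]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else revcomp_dna(read)
      pv <- strsplit(pat, "")[[1]]
      for (s in 0:(L - len)) {
        mm <- sum(refv[(s + 1):(s + len)] != pv)
        if (mm <= mm_allow)
          hits[[length(hits) + 1L]] <- data.frame(
            feature_id = fid, strand = strand, start = s, end = s + len,
            n_mismatch = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(feature_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_mismatch = integer()))
  out <- do.call(rbind, hits)
  out[out$n_mismatch == min(out$n_mismatch), , drop = FALSE]
}

# Brute-force cutadapt oracle: leftmost trim position over all offsets.
oracle_trim <- function(read, adapter, min_overlap = 6L, max_err_frac = 0.1) {
  rlen <- nchar(read)
  alen <- nchar(adapter)
  if (rlen < min_overlap) return(read)
  for (p in 1:(rlen - min_overlap + 1L)) {
    ov <- min(alen, rlen - p + 1L)
    a <- strsplit(substr(read, p, p + ov - 1L), "")[[1]]
    b <- strsplit(substr(adapter, 1L, ov), "")[[1]]
    if (sum(a != b | a == "N") <= floor(max_err_frac * ov))
      return(substr(read, 1L, p - 1L))
  }
  read
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Small reference set for mapping tests.
tiny_refs <- function(seed = 42, n = 3, len = c(80, 160)) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) random_dna(sample(len[1]:len[2], 1)),
                 "")
  names(seqs) <- paste0("feat", seq_len(n))
  seqs
}

# Alignments reconstructed from a ground-truth library: one row per emitted
# read, at the molecule's true coordinates (the deterministic lineage join).
truth_alignments <- function(lib) {
  truth <- lib$truth
  idx <- match(lib$reads$record_id, truth$molecule_id)
  data.frame(read_id = lib$reads$id,
             feature_id = truth$feature_id[idx],
             strand = truth$strand[idx],
             start = truth$start[idx], end = truth$end[idx],
             n_mismatch = 0L, stringsAsFactors = FALSE)
}
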