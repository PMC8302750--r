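# Mismatch-tolerant read mapping (Hamming distance, no indels),
# hierarchical tier assignment, and tRNA-fragment classification.

# References as a named DNA character vector (U converted to T).
reference_dna <- function(references) {
  if (inherits(references, "ReferenceSet")) {
    out <- rna_to_dna(references$seqs)
  } else {
    if (length(references) == 0)
      stop("references must be non-empty", call. = FALSE)
    stopifnot(is.character(references), !is.null(names(references)))
    out <- rna_to_dna(references)
  }
  toupper(out)
}

empty_alignments <- function() {
  data.frame(read_id = character(), feature_id = character(),
             strand = character(), start = integer(), end = integer(),
             n_mismatch = integer(), stringsAsFactors = FALSE)
}

#' Map reads to references with proportional mismatch tolerance
#'
#' For each read, all placements on both strands of every reference with
#' Hamming distance at most `floor(max_mm_frac * read length)` are located
#' (no indels); only placements achieving the read's minimum mismatch count
#' are reported. Coordinates are 0-based half-open on the feature's +
#' sequence; a `-` strand alignment means the read matches the reverse
#' complement of that window.
#'
#' @param reads Data frame with `id` and `sequence` (DNA), or a named
#'   character vector.
#' @param references A [make_reference()] object or named character vector
#'   of reference sequences (RNA or DNA).
#' @param max_mm_frac Mismatch fraction tolerance (default 0.05).
#' @return Alignment data frame: `read_id`, `feature_id`, `strand`, `start`,
#'   `end`, `n_mismatch`.
#' @export
map_reads <- function(reads, references, max_mm_frac = 0.05) {
  if (is.character(reads))
    reads <- data.frame(id = if (is.null(names(reads)))
      paste0("read", seq_along(reads)) else names(reads),
      sequence = unname(reads), stringsAsFactors = FALSE)
  refs <- reference_dna(references)
  if (length(refs) == 0) stop("references must be non-empty", call. = FALSE)
  subject <- Biostrings::DNAStringSet(refs)
  ref_len <- nchar(refs)
  useqs <- unique(reads$sequence)
  per_seq <- lapply(useqs, function(s) {
    mm_allow <- floor(max_mm_frac * nchar(s))
    hits <- scan_one(s, subject, ref_len, mm_allow)
    if (nrow(hits) > 0) hits[hits$n_mismatch == min(hits$n_mismatch), ,
                             drop = FALSE]
    else hits
  })
  names(per_seq) <- useqs
  out <- lapply(seq_len(nrow(reads)), function(i) {
    h <- per_seq[[reads$sequence[i]]]
    if (nrow(h) == 0) return(NULL)
    h$read_id <- reads$id[i]
    h
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_alignments())
  rownames(out) <- NULL
  out[, c("read_id", "feature_id", "strand", "start", "end", "n_mismatch")]
}

# All hits of one sequence on both strands of a DNAStringSet, within
# mm_allow mismatches, with exact per-hit mismatch counts.
scan_one <- function(s, subject, ref_len, mm_allow) {
  res <- list()
  for (dir in c("+", "-")) {
    pat <- if (dir == "+") s else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    plen <- nchar(pat)
    ok <- which(ref_len >= plen)
    if (length(ok) == 0) next
    mi <- Biostrings::vmatchPattern(pat, subject[ok], max.mismatch = mm_allow,
                                    with.indels = FALSE, fixed = TRUE)
    pdna <- Biostrings::DNAString(pat)
    for (j in seq_along(ok)) {
      st <- BiocGenerics::start(mi[[j]])
      if (length(st) == 0) next
      # vmatchPattern can report out-of-bounds partial hits; drop them
      st <- st[st >= 1 & st + plen - 1L <= ref_len[ok[j]]]
      if (length(st) == 0) next
      nm <- Biostrings::neditStartingAt(pdna, subject[[ok[j]]],
                                        starting.at = st, fixed = TRUE)
      keep <- nm <= mm_allow
      if (!any(keep)) next
      res[[length(res) + 1L]] <- data.frame(
        feature_id = names(subject)[ok[j]], strand = dir,
        start = st[keep] - 1L, end = st[keep] - 1L + plen,
        n_mismatch = as.integer(nm[keep]), stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0)
    return(data.frame(feature_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_mismatch = integer(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Hierarchical mapping across reference tiers
#'
#' Reads are mapped tier by tier (default order: spike-ins when present,
#' then tRNA, rRNA, transposons); each read is assigned to the first tier
#' where it maps and removed from consideration for later tiers, so tier
#' assignment partitions the mapped reads. tRNA references get CCA appended
#' when their annotation says the acceptor end lacks it, matching
#' mature-tRNA mapping practice.
#'
#' @param reads Data frame with `id` and `sequence`.
#' @param references A [make_reference()] object, or a named list of named
#'   character vectors (one per tier, in order).
#' @param tiers Tier order when `references` is a `ReferenceSet`; classes
#'   absent from the reference set are skipped.
#' @param max_mm_frac Mismatch tolerance passed to [map_reads()].
#' @param multimap `"random-one"` keeps one alignment per read (uniformly,
#'   seeded) for counting; `"all"` keeps every best alignment.
#' @param seed Seed for random-one selection.
#' @return List with `alignments` (named list per tier) and `unmapped`
#'   (character vector of read ids).
#' @export
map_hierarchical <- function(reads, references,
                             tiers = c("spikein", "trna", "rrna", "transposon",
                                       "cluster"),
                             max_mm_frac = 0.05, multimap = "random-one",
                             seed = 1) {
  if (inherits(references, "ReferenceSet")) {
    tier_refs <- list()
    for (tier in tiers) {
      ids <- references$features$id[references$features$class == tier]
      if (length(ids) == 0) next
      seqs <- references$seqs[ids]
      if (tier == "trna")
        for (id in ids) {
          anno <- references$trna_annotations[[id]]
          if (!is.null(anno) && !isTRUE(anno$acceptor_has_CCA))
            seqs[[id]] <- paste0(seqs[[id]], "CCA")
        }
      tier_refs[[tier]] <- seqs
    }
  } else tier_refs <- references
  remaining <- reads
  out <- list()
  for (tier in names(tier_refs)) {
    if (nrow(remaining) == 0) {
      out[[tier]] <- empty_alignments()
      next
    }
    aln <- map_reads(remaining, tier_refs[[tier]], max_mm_frac)
    if (multimap == "random-one" && nrow(aln) > 0)
      aln <- choose_one_alignment(aln, seed = seed)
    out[[tier]] <- aln
    remaining <- remaining[!(remaining$id %in% aln$read_id), , drop = FALSE]
  }
  list(alignments = out, unmapped = remaining$id)
}

#' Resolve multimapping reads to one alignment each
#'
#' Chooses one alignment per read uniformly at random under a fixed seed
#' (default bowtie-like behavior).
#'
#' @param alignments Alignment data frame.
#' @param seed Integer seed.
#' @return Alignment data frame with one row per read.
#' @export
choose_one_alignment <- function(alignments, seed = 1) {
  if (nrow(alignments) == 0) return(alignments)
  with_seed(seed, {
    # deterministic order before sampling
    o <- order(alignments$read_id, alignments$feature_id, alignments$strand,
               alignments$start)
    a <- alignments[o, , drop = FALSE]
    picks <- unlist(lapply(split(seq_len(nrow(a)), a$read_id), function(ix) {
      if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
    }), use.names = FALSE)
    out <- a[sort(picks), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Classify a tRNA-mapped read
#'
#' Uses a +/- 4 nt window around the anticodon first position (1-based) as
#' the anticodon-loop boundary zone: a read anchored at the tRNA 5' end
#' (start <= 1, 0-based) whose 3' end falls inside the window is a 5' half;
#' a read reaching the 3' end (allowing the CCA tail) whose 5' end falls
#' inside the window is a 3' half; terminus-anchored reads ending elsewhere
#' are 5'/3' fragments; everything else (including - strand alignments,
#' with a warning) is `other`.
#'
#' @param aln Single-row alignment on a tRNA feature.
#' @param anno tRNA annotation list: `anticodon_start` (1-based),
#'   `acceptor_has_CCA`, `length` (nt, without CCA when
#'   `acceptor_has_CCA` is FALSE).
#' @return One of `"five_half"`, `"three_half"`, `"five_fragment"`,
#'   `"three_fragment"`, `"other"`.
#' @export
classify_trna_read <- function(aln, anno) {
  if (aln$strand != "+") {
    warning("minus-strand tRNA alignment classified as 'other'")
    return("other")
  }
  ac <- anno$anticodon_start
  window <- c(ac - 4L, ac + 4L)
  L <- anno$length + if (isTRUE(anno$acceptor_has_CCA)) 0L else 3L
  start1 <- aln$start + 1L   # 1-based first base
  end1 <- aln$end            # 1-based last base (half-open end)
  anchored5 <- aln$start <= 1L
  anchored3 <- end1 >= L - 1L
  end_in <- end1 >= window[1] && end1 <= window[2]
  start_in <- start1 >= window[1] && start1 <= window[2]
  if (anchored5 && end_in) return("five_half")
  if (anchored3 && start_in) return("three_half")
  if (anchored5) return("five_fragment")
  if (anchored3) return("three_fragment")
  "other"
}

#' Classify all tRNA-tier alignments and tabulate proportions
#'
#' @param alignments Alignment data frame on tRNA features.
#' @param refs A [make_reference()] object carrying tRNA annotations.
#' @return Named proportion vector over the five classes.
#' @export
trna_class_proportions <- function(alignments, refs) {
  classes <- c("five_half", "three_half", "five_fragment", "three_fragment",
               "other")
  if (nrow(alignments) == 0)
    return(stats::setNames(rep(NA_real_, 5), classes))
  cl <- vapply(seq_len(nrow(alignments)), function(i) {
    classify_trna_read(alignments[i, ],
                       refs$trna_annotations[[alignments$feature_id[i]]])
  }, "")
  tab <- table(factor(cl, levels = classes))
  stats::setNames(as.vector(tab / sum(tab)), classes)
}

#' Export alignments as BED6
#'
#' Features play the role of chromosomes; scores hold mismatch counts.
#'
#' @param alignments Alignment data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments_bed <- function(alignments, path) {
  bed <- data.frame(chrom = alignments$feature_id, start = alignments$start,
                    end = alignments$end, name = alignments$read_id,
                    score = alignments$n_mismatch, strand = alignments$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Export alignments as 1-based closed TSV
#'
#' @param alignments Alignment data frame (internal 0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(alignments, path) {
  out <- alignments
  out$start <- out$start + 1L  # 1-based closed for human consumption
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
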