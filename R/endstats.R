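# Cleavage-flank nucleotide composition, piRNA <-> cP-RNA cross-mapping
# ratios, and terminal-position match-rate profiles.

# Fetch reference bases at 1-based positions, "" outside bounds.
ref_base_at <- function(seq, pos) {
  b <- substring(seq, pos, pos)
  b[pos < 1 | pos > nchar(seq)] <- ""
  b
}

comp_base <- function(b) chartr("ACGU", "UGCA", b)

#' Nucleotide composition around read 5' and 3' ends
#'
#' For every alignment the window around each biological end is assembled
#' strand-aware: flank positions (-k..-1 for the 5' end, +1..+k for the 3'
#' end) are taken from the reference; read-covered positions from the
#' aligned read when `reads` is supplied, otherwise from the reference
#' window. Positions falling outside a feature contribute nothing
#' (per-position denominators). Position 0 does not exist: the dashed line
#' between -1 and +1 is the cleavage site.
#'
#' @param alignments Alignment data frame from [map_reads()].
#' @param references A [make_reference()] object or named character vector.
#' @param k Flank half-window in nt (default 3).
#' @param reads Optional read data frame (`id`, `sequence`) to source the
#'   covered positions from actual read bases.
#' @return List with elements `five` and `three`, each a positions x ACGU
#'   frequency matrix (rows sum to 1) with a `"n"` attribute of per-position
#'   denominators.
#' @export
end_composition <- function(alignments, references, k = 3L, reads = NULL) {
  refs <- if (inherits(references, "ReferenceSet"))
    dna_to_rna(references$seqs) else dna_to_rna(references)
  read_seq <- NULL
  if (!is.null(reads))
    read_seq <- stats::setNames(dna_to_rna(reads$sequence), reads$id)
  pos_labels <- c(paste0("-", k:1), paste0("+", 1:k))
  counts5 <- counts3 <- matrix(0L, nrow = 2L * k, ncol = 4L,
                               dimnames = list(pos_labels, RNA_BASES))
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    seq <- refs[[a$feature_id]]
    start1 <- a$start + 1L
    end1 <- a$end
    if (a$strand == "+") {
      up5 <- ref_base_at(seq, (start1 - k):(start1 - 1L))
      cov5 <- ref_base_at(seq, start1:(start1 + k - 1L))
      cov3 <- ref_base_at(seq, (end1 - k + 1L):end1)
      down3 <- ref_base_at(seq, (end1 + 1L):(end1 + k))
    } else {
      up5 <- comp_base(ref_base_at(seq, (end1 + k):(end1 + 1L)))
      cov5 <- comp_base(ref_base_at(seq, end1:(end1 - k + 1L)))
      cov3 <- comp_base(ref_base_at(seq, (start1 + k - 1L):start1))
      down3 <- comp_base(ref_base_at(seq, (start1 - 1L):(start1 - k)))
    }
    if (!is.null(read_seq) && a$read_id %in% names(read_seq)) {
      rs <- read_seq[[a$read_id]]
      L <- nchar(rs)
      cov5 <- ref_base_at(rs, 1:k)
      cov3 <- ref_base_at(rs, (L - k + 1L):L)
    }
    for (j in 1:k) {
      if (up5[j] %in% RNA_BASES) counts5[j, up5[j]] <- counts5[j, up5[j]] + 1L
      if (cov5[j] %in% RNA_BASES)
        counts5[k + j, cov5[j]] <- counts5[k + j, cov5[j]] + 1L
      if (cov3[j] %in% RNA_BASES)
        counts3[j, cov3[j]] <- counts3[j, cov3[j]] + 1L
      if (down3[j] %in% RNA_BASES)
        counts3[k + j, down3[j]] <- counts3[k + j, down3[j]] + 1L
    }
  }
  normalize <- function(m) {
    n <- rowSums(m)
    freq <- m / ifelse(n == 0, 1, n)
    attr(freq, "n") <- n
    freq
  }
  list(five = normalize(counts5), three = normalize(counts3))
}

#' Write composition matrices as TSV
#'
#' @param comp Output of [end_composition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(comp, path) {
  rows <- lapply(c("five", "three"), function(e) {
    m <- comp[[e]]
    data.frame(end = e, position = rownames(m), as.data.frame(unclass(m)),
               n = attr(m, "n"), row.names = NULL)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Map query reads onto a set of target sequences
#'
#' Cross-library mapping: each query (e.g. a piRNA read) must align fully
#' within a target (e.g. a distinct cP-RNA sequence) with at most
#' `floor(max_mm_frac * query length)` mismatches. Targets are deduplicated
#' by exact sequence first. Only sense-strand placements are considered:
#' the statistic asks whether the piRNA's own sequence lies inside the
#' cP-RNA's.
#'
#' @param query_reads Character vector of query read sequences (repeats
#'   allowed and counted as reads).
#' @param target_seqs Character vector of target sequences.
#' @param max_mm_frac Mismatch tolerance (default 0.05).
#' @return List: `read_mapping_ratio` (mapped query reads / total),
#'   `species_mapped_rate` (targets hit / total targets), `n_query_reads`,
#'   `n_target_species`, and `alignments` (query placements on targets,
#'   with a `weight` column of 1/m for queries hitting m targets).
#' @export
cross_mapping_stats <- function(query_reads, target_seqs,
                                max_mm_frac = 0.05) {
  if (length(target_seqs) == 0)
    stop("target set is empty", call. = FALSE)
  targets <- unique(toupper(rna_to_dna(target_seqs)))
  names(targets) <- sprintf("target%05d", seq_along(targets))
  queries <- toupper(rna_to_dna(query_reads))
  uq <- unique(queries)
  uq_reads <- data.frame(id = sprintf("q%06d", seq_along(uq)), sequence = uq,
                         stringsAsFactors = FALSE)
  aln <- map_reads(uq_reads, targets, max_mm_frac)
  aln <- aln[aln$strand == "+", , drop = FALSE]
  mult <- table(queries)[uq]                      # read multiplicity per seq
  mapped_seq <- uq_reads$id %in% aln$read_id
  read_ratio <- sum(mult[mapped_seq]) / length(queries)
  species_rate <- length(unique(aln$feature_id)) / length(targets)
  if (nrow(aln) > 0) {
    m <- table(aln$read_id)
    aln$weight <- as.numeric(unname(mult[match(
      aln$read_id, uq_reads$id) ])) / as.numeric(m[aln$read_id])
  } else aln$weight <- numeric(0)
  list(read_mapping_ratio = unname(read_ratio),
       species_mapped_rate = species_rate,
       n_query_reads = length(queries), n_target_species = length(targets),
       alignments = aln, targets = targets)
}

#' Terminal-position match profile of queries on their targets
#'
#' For query alignments inside target sequences, `matched_5prime[i]` is the
#' (weight-normalized) fraction of alignments whose 5' end sits at position
#' i of the target, counted 1-based from the target's 5' end;
#' `matched_3prime[i]` is symmetric from the target's 3' end. Each query
#' alignment contributes exactly one 5' and one 3' position; queries mapped
#' to several targets are down-weighted 1/m when the alignments carry a
#' `weight` column. The denominator is mapped queries only (recorded in the
#' `"denominator"` attribute).
#'
#' @param alignments Alignments of queries on targets (sense strand), e.g.
#'   from [cross_mapping_stats()].
#' @param targets Named character vector of target sequences.
#' @return Data frame `position`, `matched_5prime`, `matched_3prime` with
#'   attributes `n` (total weight) and `denominator`.
#' @export
terminal_match_rate <- function(alignments, targets) {
  L <- max(nchar(targets))
  w <- if ("weight" %in% names(alignments)) alignments$weight
       else rep(1, nrow(alignments))
  total <- sum(w)
  pos5 <- alignments$start + 1L
  pos3 <- nchar(targets)[match(alignments$feature_id, names(targets))] -
    alignments$end + 1L
  m5 <- vapply(1:L, function(i) sum(w[pos5 == i]), 0) / max(total, 1)
  m3 <- vapply(1:L, function(i) sum(w[pos3 == i]), 0) / max(total, 1)
  out <- data.frame(position = 1:L, matched_5prime = m5, matched_3prime = m3)
  attr(out, "n") <- total
  attr(out, "denominator") <- "mapped queries only"
  out
}
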