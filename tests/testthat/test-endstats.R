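# End composition, cross-mapping, terminal match profiles.

make_cp_world <- function(seed = 50, enzyme = enzyme_model(c(CA = 1)),
                          cut_rate = 1) {
  refs <- make_reference(list(n_transposons = 4,
                              transposon_length = c(300, 500)), seed = seed)
  pre <- make_precursors(refs)
  fr <- cleave_pool(pre, enzyme, cut_rate, seed = seed + 1)
  list(refs = refs, fragments = fr)
}

test_that("CA-only cleavage gives C at 3' -1 and A at 3' +1", {
  w <- make_cp_world()
  internal <- w$fragments[!is.na(w$fragments$cut3_dinuc), ]
  aln <- data.frame(read_id = internal$molecule_id,
                    feature_id = internal$feature_id, strand = "+",
                    start = internal$start, end = internal$end,
                    n_mismatch = 0L)
  comp <- end_composition(aln, w$refs, k = 3)
  expect_equal(unname(comp$three["-1", "C"]), 1.0)
  expect_equal(unname(comp$three["+1", "A"]), 1.0)
  # the 5' side of downstream fragments starts with A (after the CA cut)
  down <- w$fragments[!is.na(w$fragments$cut5_dinuc), ]
  aln5 <- data.frame(read_id = down$molecule_id,
                     feature_id = down$feature_id, strand = "+",
                     start = down$start, end = down$end, n_mismatch = 0L)
  comp5 <- end_composition(aln5, w$refs, k = 3)
  expect_equal(unname(comp5$five["+1", "A"]), 1.0)
  expect_equal(unname(comp5$five["-1", "C"]), 1.0)
})

test_that("forced-load piRNAs show U at the 5' +1 position", {
  w <- make_cp_world(seed = 60, enzyme = enzyme_model(), cut_rate = 0.3)
  mat <- mature_pirnas(w$fragments, w$refs,
                       list(p_load = 1, p_mature = 1, p_pingpong = 0,
                            background_antisense = 0), seed = 61)
  pir <- mat[mat$lineage == "mature_pirna", ]
  aln <- data.frame(read_id = pir$molecule_id, feature_id = pir$feature_id,
                    strand = pir$strand, start = pir$start, end = pir$end,
                    n_mismatch = 0L)
  comp <- end_composition(aln, w$refs, k = 3)
  expect_equal(unname(comp$five["+1", "U"]), 1.0)
})

test_that("rows sum to one and uniform input is near-uniform", {
  set.seed(70)
  refs <- list(f1 = paste(sample(c("A", "C", "G", "U"), 4000, replace = TRUE),
                          collapse = ""))
  names(refs) <- "f1"
  starts <- sample(10:3900, 400, replace = TRUE)
  aln <- data.frame(read_id = paste0("r", seq_along(starts)),
                    feature_id = "f1", strand = "+", start = starts,
                    end = starts + 30L, n_mismatch = 0L)
  comp <- end_composition(aln, unlist(refs), k = 3)
  for (m in comp) {
    expect_true(all(abs(rowSums(m) - 1) < 1e-9))
    # binomial 3-sigma around 0.25 at n = 400
    expect_true(all(abs(m - 0.25) < 3 * sqrt(0.25 * 0.75 / 400) + 0.02))
  }
})

test_that("composition is reproduced exactly on strand-reversed input", {
  w <- make_cp_world(seed = 80, enzyme = enzyme_model(), cut_rate = 0.4)
  fr <- w$fragments[!is.na(w$fragments$cut3_dinuc), ]
  aln <- data.frame(read_id = fr$molecule_id, feature_id = fr$feature_id,
                    strand = "+", start = fr$start, end = fr$end,
                    n_mismatch = 0L)
  comp_fwd <- end_composition(aln, w$refs, k = 3)
  # reverse-complement every feature; flip alignments accordingly
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(x)))
  refs_rc <- vapply(w$refs$seqs, rc, "")
  L <- nchar(w$refs$seqs)[aln$feature_id]
  aln_rc <- aln
  aln_rc$start <- L - aln$end
  aln_rc$end <- L - aln$start
  aln_rc$strand <- "-"
  comp_rev <- end_composition(aln_rc, refs_rc, k = 3)
  expect_equal(comp_fwd$five, comp_rev$five)
  expect_equal(comp_fwd$three, comp_rev$three)
})

test_that("composition is invariant to relabeling and unmapped reads", {
  w <- make_cp_world(seed = 90, enzyme = enzyme_model(), cut_rate = 0.4)
  fr <- w$fragments[!is.na(w$fragments$cut3_dinuc), ][1:20, ]
  aln <- data.frame(read_id = fr$molecule_id, feature_id = fr$feature_id,
                    strand = "+", start = fr$start, end = fr$end,
                    n_mismatch = 0L)
  base <- end_composition(aln, w$refs, k = 2)
  relabeled <- w$refs
  names(relabeled$seqs) <- paste0("X_", names(relabeled$seqs))
  aln2 <- aln
  aln2$feature_id <- paste0("X_", aln2$feature_id)
  expect_equal(end_composition(aln2, relabeled, k = 2), base)
})

test_that("cross-mapping ratios hit the trivial endpoints", {
  targets <- c("ACGUACGUACGUACGUACGUGGCAUGCAUAA",
               "UUGGCCAAUUGGCCAAUUGGAAUUCCGGAA")
  # queries that are exact substrings of targets
  q_in <- c(substr(targets[1], 3, 25), substr(targets[2], 1, 22))
  cm <- cross_mapping_stats(q_in, targets)
  expect_equal(cm$read_mapping_ratio, 1.0)
  expect_equal(cm$species_mapped_rate, 1.0)
  # alphabet-shuffled disjoint queries
  cm0 <- cross_mapping_stats(c("GGGGGGGGGGGGGGGGGGGGGG",
                               "CCCCCCCCCCCCCCCCCCCCCC"), targets)
  expect_equal(cm0$read_mapping_ratio, 0.0)
  expect_equal(cm0$species_mapped_rate, 0.0)
  expect_error(cross_mapping_stats(q_in, character(0)), "empty")
  # duplicate target sequences collapse to species
  cm2 <- cross_mapping_stats(q_in[1], c(targets, targets[1]))
  expect_equal(cm2$n_target_species, 2)
})

test_that("species_mapped_rate recovers a designed fraction by lineage", {
  w <- make_cp_world(seed = 95, enzyme = enzyme_model(), cut_rate = 0.3)
  mat <- mature_pirnas(w$fragments, w$refs,
                       list(p_load = 0.5, p_mature = 1, p_pingpong = 0,
                            background_antisense = 0), seed = 96)
  pir <- mat[mat$lineage == "mature_pirna" & mat$strand == "+", ]
  cps <- mat[mat$three_prime == "cyclic_phosphate" &
               nchar(mat$sequence) >= 30 & nchar(mat$sequence) <= 70, ]
  cm <- cross_mapping_stats(pir$sequence, cps$sequence, max_mm_frac = 0)
  # ground truth: a cP species is hit iff some piRNA is a substring of it
  truth_hits <- vapply(unique(cps$sequence), function(t)
    any(vapply(pir$sequence, function(q) grepl(q, t, fixed = TRUE), TRUE)),
    TRUE)
  expect_equal(cm$species_mapped_rate, mean(truth_hits))
})

test_that("terminal match profiles localize query ends on targets", {
  targets <- c(t1 = "ACGTACGTACGTACGTACGTACGTACGTACGT",
               t2 = "TTGGCCAATTGGCCAATTGGCCAATTGGCCAA")
  # prefixes -> matched_5prime[1] = 1; suffixes -> matched_3prime[1] = 1
  pref <- data.frame(read_id = c("a", "b"), feature_id = c("t1", "t2"),
                     strand = "+", start = 0L, end = c(20L, 24L),
                     n_mismatch = 0L)
  tmr <- terminal_match_rate(pref, targets)
  expect_equal(tmr$matched_5prime[1], 1.0)
  expect_equal(sum(tmr$matched_5prime), 1.0)
  suff <- data.frame(read_id = c("a", "b"), feature_id = c("t1", "t2"),
                     strand = "+", start = c(12L, 8L), end = 32L,
                     n_mismatch = 0L)
  tmr <- terminal_match_rate(suff, targets)
  expect_equal(tmr$matched_3prime[1], 1.0)
  # one 5' and one 3' position per query: sums bounded by 1
  expect_lte(sum(tmr$matched_5prime), 1.0)
})
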