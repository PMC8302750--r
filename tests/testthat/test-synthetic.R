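# Reference generation, cleavage simulation, maturation, library emission.

test_that("make_reference is reproducible and validates config", {
  cfg <- list(n_transposons = 3, transposon_length = c(100, 200))
  r1 <- make_reference(cfg, seed = 1)
  r2 <- make_reference(cfg, seed = 1)
  expect_identical(r1, r2)
  expect_false(identical(r1, make_reference(cfg, seed = 2)))
  # canonical spike-ins are present with their printed sequences
  expect_equal(unname(r1$seqs["spikein_1"]), "AUGUUGUGCCACAUAUUGAGCCAGUAGC")
  expect_equal(nchar(r1$seqs[["spikein_1"]]), 28)
  expect_equal(nchar(r1$seqs[["spikein_2"]]), 33)
  expect_error(make_reference(list(n_transposons = 0)), "transposon")
  expect_error(make_reference(list(transposon_length = c(500, 100))),
               "length range")
})

test_that("cleave_precursor cuts at weighted dinucleotides with cP/OH ends", {
  pre <- molecule_table("p", "GGGGG", "phosphate", "hydroxyl", "f", "+",
                        0, 5, "precursor")
  # no eligible site: precursor passes through unchanged
  out <- cleave_precursor(pre, enzyme_model(c(CA = 1)), cut_rate = 1)
  expect_equal(out$sequence, "GGGGG")
  expect_equal(out$lineage, "precursor")

  pre <- molecule_table("p", "UUCAUUCAUU", "phosphate", "hydroxyl", "f", "+",
                        0, 10, "precursor")
  fr <- cleave_precursor(pre, enzyme_model(c(CA = 1)), cut_rate = 1, seed = 1)
  expect_equal(fr$sequence, c("UUC", "AUUC", "AUU"))
  expect_equal(fr$three_prime,
               c("cyclic_phosphate", "cyclic_phosphate", "hydroxyl"))
  expect_equal(fr$five_prime, c("phosphate", "hydroxyl", "hydroxyl"))
  expect_equal(fr$cut3_dinuc, c("CA", "CA", NA))
  # outermost ends keep the precursor chemistry
  expect_equal(fr$five_prime[1], "phosphate")
  expect_equal(fr$three_prime[nrow(fr)], "hydroxyl")
  expect_error(cleave_precursor(pre, enzyme_model(), cut_rate = 1.2), "0, 1")
})

test_that("fragments reconstruct the precursor and flanks carry weight", {
  set.seed(11)
  refs <- make_reference(list(n_transposons = 4,
                              transposon_length = c(300, 500)), seed = 11)
  pre <- make_precursors(refs)
  enz <- enzyme_model()
  fr <- cleave_pool(pre, enz, cut_rate = 0.5, seed = 5)
  for (pid in unique(fr$feature_id)) {
    f <- fr[fr$feature_id == pid, ]
    f <- f[order(f$start), ]
    expect_equal(paste(f$sequence, collapse = ""), refs$seqs[[pid]])
    # contiguity of coordinates
    expect_equal(f$start[-1], f$end[-nrow(f)])
  }
  # every cP fragment's cut-site dinucleotide has weight > 0
  cp <- fr[fr$three_prime == "cyclic_phosphate", ]
  expect_true(all(enz[cp$cut3_dinuc] > 0))
  # and it equals terminal base + next reference base
  for (i in seq_len(nrow(cp))) {
    ref <- refs$seqs[[cp$feature_id[i]]]
    expect_equal(cp$cut3_dinuc[i], substr(ref, cp$end[i], cp$end[i] + 1))
  }
})

test_that("expected fragment count follows linearity of expectation", {
  set.seed(3)
  seq <- paste(sample(c("A", "C", "G", "U"), 1000, replace = TRUE),
               collapse = "")
  pre <- molecule_table("p", seq, "phosphate", "hydroxyl", "f", "+",
                        0, 1000, "precursor")
  enz <- enzyme_model()
  cut_rate <- 0.3
  bases <- strsplit(seq, "")[[1]]
  dn <- paste0(bases[-1000], bases[-1])
  expected <- 1 + cut_rate * sum(enz[dn]) / max(enz)
  counts <- vapply(1:400, function(s)
    nrow(cleave_precursor(pre, enz, cut_rate, seed = s)), 0)
  # Monte-Carlo mean within 4 binomial-ish sigma
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se + 1e-9)
})

test_that("maturation spawns anchored P-cP and piRNA derivatives", {
  refs <- make_reference(list(n_transposons = 2,
                              transposon_length = c(200, 300)), seed = 2)
  frag <- molecule_table("f1", "AUUCGGGACUUGGAUCCAGGUUACGGAAUCCGUAA",
                         "hydroxyl", "cyclic_phosphate", "TE001", "+",
                         10, 45, "cp_fragment")
  out <- mature_pirnas(frag, refs, list(p_load = 1, p_mature = 0,
                                        p_pingpong = 0,
                                        background_antisense = 0), seed = 1)
  # original fragment kept; P-cP derivative starts at the first downstream U
  expect_equal(nrow(out), 2)
  pcp <- out[is_pcp(out) & out$five_prime == "phosphate", ]
  expect_equal(substr(pcp$sequence, 1, 1), "U")
  expect_equal(pcp$start, 11)  # U at offset 2 of the fragment
  expect_equal(pcp$three_prime, "cyclic_phosphate")
  # p_load = 0 is the identity
  expect_identical(mature_pirnas(frag, refs, list(p_load = 0)), frag)
  expect_error(mature_pirnas(frag, refs, list(p_load = 2)), "0, 1")
})

test_that("ping-pong partners sit at exactly 10 nt 5'-5' overlap", {
  refs <- make_reference(list(n_transposons = 5,
                              transposon_length = c(400, 600)), seed = 7)
  pre <- make_precursors(refs)
  fr <- cleave_pool(pre, enzyme_model(), 0.3, seed = 8)
  mat <- mature_pirnas(fr, refs, list(p_load = 1, p_mature = 1,
                                      p_pingpong = 1,
                                      background_antisense = 0), seed = 9)
  partners <- mat[!is.na(mat$partner_id), ]
  expect_gt(nrow(partners), 10)
  guides <- mat[match(partners$partner_id, mat$molecule_id), ]
  expect_true(all(guides$strand == "+" & partners$strand == "-"))
  # 5' of - strand read (+ coords, 1-based) minus 5' of guide + 1 == 10
  d <- partners$end - (guides$start + 1) + 1
  expect_true(all(d == 10))
})

test_that("emit_library respects chemistry, is deterministic, errors on empty pool", {
  refs <- make_reference(list(n_transposons = 3,
                              transposon_length = c(200, 400)), seed = 4)
  pre <- make_precursors(refs)
  fr <- cleave_pool(pre, enzyme_model(), 0.3, seed = 4)
  mat <- mature_pirnas(fr, refs, list(), seed = 5)
  lib <- emit_library(mat, protocol_spec("CP_RNA_SEQ"), depth = 500, seed = 6)
  # all emitted reads trace to cP molecules within the window
  expect_true(all(lib$truth$three_prime %in%
                    c("cyclic_phosphate")))
  expect_true(all(nchar(lib$truth$sequence) >= 30 &
                    nchar(lib$truth$sequence) <= 70))
  expect_equal(sum(lib$truth$sampled_count), 500)
  # read ids encode the ground-truth record
  expect_true(all(lib$reads$record_id %in% lib$truth$molecule_id))
  # byte-identical FASTQ under the same seed
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  emit_library(mat, protocol_spec("CP_RNA_SEQ"), depth = 200, seed = 9,
               fastq = f1)
  emit_library(mat, protocol_spec("CP_RNA_SEQ"), depth = 200, seed = 9,
               fastq = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a pool with no 5'-P cP molecules cannot feed P-cP-RNA-seq
  only_oh <- mat[mat$five_prime == "hydroxyl" &
                   mat$three_prime == "cyclic_phosphate", ]
  expect_error(emit_library(only_oh, protocol_spec("P_CP_RNA_SEQ"), 100),
               "P_CP_RNA_SEQ")
})

test_that("tRNA halves carry the expected chemistry and coordinates", {
  refs <- make_reference(list(n_transposons = 1,
                              transposon_length = c(100, 100)), seed = 3)
  h <- make_trna_halves(refs)
  expect_equal(nrow(h), 2)
  anno <- refs$trna_annotations[[1]]
  five <- h[grepl("5half", h$molecule_id), ]
  three <- h[grepl("3half", h$molecule_id), ]
  expect_equal(five$three_prime, "cyclic_phosphate")
  expect_equal(five$end, anno$anticodon_start)
  expect_equal(three$five_prime, "hydroxyl")
  expect_equal(paste0(five$sequence, three$sequence),
               refs$seqs[[five$feature_id]])
})
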