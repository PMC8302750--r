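# Simulator: reference generation, dinucleotide-preferential cleavage,
# piRNA maturation, and sequencing-ready library emission with a full
# ground-truth lineage table.

RNA_BASES <- c("A", "C", "G", "U")

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

rna_to_dna <- function(x) chartr("Uu", "Tt", x)
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

# Vectorized reverse complement for RNA character vectors.
revcomp_rna <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

random_rna <- function(n) paste(sample(RNA_BASES, n, replace = TRUE),
                                collapse = "")

ALL_DINUCS <- as.vector(outer(RNA_BASES, RNA_BASES, paste0))

#' Dinucleotide-preferential endonuclease model
#'
#' Relative cleavage weights for the 16 RNA dinucleotides. The enzyme cleaves
#' the phosphodiester bond between the two bases of a dinucleotide, leaving a
#' 2',3'-cyclic phosphate on the upstream fragment and a 5'-hydroxyl on the
#' downstream fragment. The default ordering reflects an RNase kappa-like
#' enzyme: CA strongest, CC and AA equal and intermediate, GU weakest; the
#' numeric values are configuration defaults, not measured constants. UA
#' weight 0.25 represents the C/U-A cleavage bias seen in Bombyx libraries.
#'
#' @param weights Named non-negative numeric vector; names are RNA
#'   dinucleotides (e.g. `"CA"`). Unnamed dinucleotides get weight 0.
#' @return An `EnzymeModel`: a named numeric vector over all 16 dinucleotides.
#' @examples
#' enzyme_model()                      # RNase kappa-like defaults
#' enzyme_model(c(CA = 1))             # CA-only enzyme
#' @export
enzyme_model <- function(weights = c(CA = 1.0, CC = 0.35, AA = 0.35,
                                     GU = 0.05, UA = 0.25)) {
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            all(names(weights) %in% ALL_DINUCS))
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("enzyme weights must be finite and non-negative", call. = FALSE)
  w <- stats::setNames(numeric(16), ALL_DINUCS)
  w[names(weights)] <- weights
  if (all(w == 0)) stop("at least one enzyme weight must be > 0", call. = FALSE)
  structure(w, class = c("EnzymeModel", "numeric"))
}

#' Build a molecule/ground-truth table
#'
#' Molecules are rows of a data frame: sequence (RNA), terminal chemistry,
#' origin (`feature_id`, `strand`, 0-based half-open `start`/`end` on the
#' feature's + sequence), `lineage` (one of precursor, cp_fragment,
#' downstream_fragment, mature_pirna, spikein, trna_half), optional
#' `partner_id` linking ping-pong pairs, and the cleavage-site dinucleotides
#' that created each end (`cut5_dinuc`, `cut3_dinuc`; NA for ends inherited
#' from the precursor). This table doubles as the simulator's ground truth.
#'
#' @param molecule_id,sequence,five_prime,three_prime,feature_id,strand,start,end,lineage,partner_id,source_id,cut5_dinuc,cut3_dinuc
#'   Column vectors, recycled to common length. `source_id` records the
#'   molecule each row was derived from (its lineage parent).
#' @return A `data.frame` of molecules.
#' @export
molecule_table <- function(molecule_id, sequence, five_prime = "phosphate",
                           three_prime = "hydroxyl", feature_id, strand = "+",
                           start, end, lineage = "precursor",
                           partner_id = NA_character_,
                           source_id = NA_character_,
                           cut5_dinuc = NA_character_,
                           cut3_dinuc = NA_character_) {
  df <- data.frame(molecule_id = molecule_id, sequence = sequence,
                   five_prime = five_prime, three_prime = three_prime,
                   feature_id = feature_id, strand = strand,
                   start = as.integer(start), end = as.integer(end),
                   lineage = lineage, partner_id = partner_id,
                   source_id = source_id,
                   cut5_dinuc = cut5_dinuc, cut3_dinuc = cut3_dinuc,
                   stringsAsFactors = FALSE)
  stopifnot(all(df$end > df$start), all(nchar(df$sequence) == df$end - df$start))
  df
}

empty_molecule_table <- function() {
  molecule_table(character(), character(), character(), character(),
                 character(), character(), integer(), integer(), character(),
                 character(), character(), character(), character())[0, ]
}

#' Is a molecule a P-cP-RNA?
#'
#' A P-cP-RNA carries a 5'-monophosphate together with a 2',3'-cyclic
#' phosphate; it is the subset of cP-RNAs that 5'-adapter-first protocols
#' capture.
#'
#' @param molecules A [molecule_table()].
#' @return Logical vector.
#' @export
is_pcp <- function(molecules) {
  molecules$five_prime == "phosphate" &
    molecules$three_prime == "cyclic_phosphate"
}

#' Generate a synthetic reference set
#'
#' Builds a reproducible reference universe: random transposon consensus
#' sequences, one tRNA with an anticodon annotation, an rRNA decoy, and
#' spike-in RNAs whose default sequences are the two synthetic 28-nt and
#' 33-nt spike-ins used for piRNA-seq normalization.
#'
#' @param config List with elements `n_transposons` (default 50),
#'   `transposon_length` (`c(min, max)`, default `c(1000, 5000)`), `n_trna`
#'   (default 1), `trna_length` (default 76), `anticodon_start` (1-based,
#'   default 35), `n_rrna` (default 1), `rrna_length` (default 1500), and
#'   `spikein_seqs` (default the two canonical spike-in RNAs).
#' @param seed Integer seed; the same seed reproduces the same references.
#' @return A `ReferenceSet`: list with `features` (data frame: id, class,
#'   length), `seqs` (named RNA character vector), and `trna_annotations`
#'   (per-tRNA list with `anticodon_start`, `acceptor_has_CCA`, `length`).
#' @examples
#' refs <- make_reference(list(n_transposons = 3,
#'                             transposon_length = c(200, 400)), seed = 1)
#' @export
make_reference <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(list(
    n_transposons = 50L, transposon_length = c(1000L, 5000L),
    n_trna = 1L, trna_length = 76L, anticodon_start = 35L,
    n_rrna = 1L, rrna_length = 1500L,
    spikein_seqs = c(spikein_1 = "AUGUUGUGCCACAUAUUGAGCCAGUAGC",
                     spikein_2 = "UGCCACAUAUUGAGCCAGUAGCGCGGUGUAUUA")), config)
  if (cfg$n_transposons < 1)
    stop("invalid config: need at least one transposon", call. = FALSE)
  if (cfg$transposon_length[1] > cfg$transposon_length[2] ||
      cfg$transposon_length[1] < 1)
    stop("invalid config: bad transposon length range", call. = FALSE)
  if (cfg$anticodon_start < 1 || cfg$anticodon_start > cfg$trna_length - 2)
    stop("invalid config: anticodon_start out of range", call. = FALSE)
  with_seed(seed, {
    seqs <- character(0)
    feats <- list()
    for (i in seq_len(cfg$n_transposons)) {
      id <- sprintf("TE%03d", i)
      rng <- cfg$transposon_length
      len <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1) - 1L
      seqs[id] <- random_rna(len)
      feats[[id]] <- c(id, "transposon")
    }
    trna_annotations <- list()
    for (i in seq_len(cfg$n_trna)) {
      id <- sprintf("tRNA%02d", i)
      seqs[id] <- random_rna(cfg$trna_length)
      feats[[id]] <- c(id, "trna")
      trna_annotations[[id]] <- list(anticodon_start = cfg$anticodon_start,
                                     acceptor_has_CCA = FALSE,
                                     length = cfg$trna_length)
    }
    for (i in seq_len(cfg$n_rrna)) {
      id <- sprintf("rRNA%02d", i)
      seqs[id] <- random_rna(cfg$rrna_length)
      feats[[id]] <- c(id, "rrna")
    }
    for (i in seq_along(cfg$spikein_seqs)) {
      id <- names(cfg$spikein_seqs)[i]
      if (is.null(id) || id == "") id <- sprintf("spikein_%d", i)
      seqs[id] <- cfg$spikein_seqs[[i]]
      feats[[id]] <- c(id, "spikein")
    }
    features <- data.frame(id = vapply(feats, `[`, "", 1),
                           class = vapply(feats, `[`, "", 2),
                           length = nchar(seqs), row.names = NULL,
                           stringsAsFactors = FALSE)
    structure(list(features = features, seqs = seqs,
                   trna_annotations = trna_annotations),
              class = "ReferenceSet")
  })
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat("<ReferenceSet>\n")
  print(table(x$features$class))
  invisible(x)
}

#' Write a reference set as FASTA
#'
#' Sequences are written in DNA alphabet (U -> T), as mappers expect.
#'
#' @param refs A [make_reference()] object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  ss <- Biostrings::DNAStringSet(rna_to_dna(refs$seqs))
  names(ss) <- names(refs$seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Precursor molecules for a reference set
#'
#' One full-length + strand precursor per feature of the requested classes,
#' with the configured primary chemistry (default 5'-phosphate /
#' 3'-hydroxyl, a Pol II-like processed transcript).
#'
#' @param refs A [make_reference()] object.
#' @param classes Feature classes to instantiate (default `"transposon"`).
#' @param five_prime,three_prime Precursor end chemistry.
#' @return A [molecule_table()].
#' @export
make_precursors <- function(refs, classes = "transposon",
                            five_prime = "phosphate",
                            three_prime = "hydroxyl") {
  feats <- refs$features[refs$features$class %in% classes, ]
  if (nrow(feats) == 0) return(empty_molecule_table())
  molecule_table(molecule_id = paste0(feats$id, ":pre"),
                 sequence = unname(refs$seqs[feats$id]),
                 five_prime = five_prime, three_prime = three_prime,
                 feature_id = feats$id, strand = "+",
                 start = 0L, end = feats$length, lineage = "precursor")
}

#' Simulate endonucleolytic cleavage of one precursor
#'
#' Each internucleotide position i (between bases i and i+1) is cut
#' independently with probability `cut_rate * w[d_i] / max(w)`, where `d_i`
#' is the dinucleotide spanning the bond. Every cut leaves a 2',3'-cyclic
#' phosphate on the upstream fragment and a 5'-hydroxyl on the downstream
#' fragment; the outermost ends keep the precursor's chemistry. Fragment
#' coordinates and cut-site dinucleotides are recorded in the returned
#' ground-truth table.
#'
#' @param precursor A single-row [molecule_table()] with lineage
#'   `"precursor"`.
#' @param enzyme An [enzyme_model()].
#' @param cut_rate Probability scale in `[0, 1]` applied to the
#'   max-normalized weights.
#' @param seed Optional integer seed.
#' @return A [molecule_table()] of fragments (the unchanged precursor if no
#'   site was cut).
#' @examples
#' pre <- molecule_table("p", "UUCAUUCAUU", "phosphate", "hydroxyl",
#'                       "f1", "+", 0, 10, "precursor")
#' cleave_precursor(pre, enzyme_model(c(CA = 1)), cut_rate = 1)
#' @export
cleave_precursor <- function(precursor, enzyme, cut_rate, seed = NULL) {
  stopifnot(inherits(enzyme, "EnzymeModel"), nrow(precursor) == 1L)
  if (precursor$lineage != "precursor")
    stop("cleave_precursor expects a precursor molecule", call. = FALSE)
  if (cut_rate < 0 || cut_rate > 1)
    stop("cut_rate must lie in [0, 1]", call. = FALSE)
  seq <- precursor$sequence
  L <- nchar(seq)
  if (L < 2) return(precursor)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  dinucs <- paste0(bases[-L], bases[-1])
  p <- cut_rate * unname(enzyme[dinucs]) / max(enzyme)
  cuts <- with_seed(seed, which(stats::runif(L - 1L) < p))
  if (length(cuts) == 0) return(precursor)
  # fragment k spans (bounds[k], bounds[k+1]] in 1-based closed coordinates
  bounds <- c(0L, cuts, L)
  n <- length(bounds) - 1L
  frag_start <- precursor$start + bounds[-length(bounds)]  # 0-based
  frag_end <- precursor$start + bounds[-1]
  frag_seq <- substring(seq, bounds[-length(bounds)] + 1L, bounds[-1])
  five <- c(precursor$five_prime, rep("hydroxyl", n - 1L))
  three <- c(rep("cyclic_phosphate", n - 1L), precursor$three_prime)
  lineage <- c(rep("cp_fragment", n - 1L), "downstream_fragment")
  cut5 <- c(NA_character_, dinucs[cuts])
  cut3 <- c(dinucs[cuts], NA_character_)
  molecule_table(molecule_id = sprintf("%s:f%03d", precursor$molecule_id,
                                       seq_len(n)),
                 sequence = frag_seq, five_prime = five, three_prime = three,
                 feature_id = precursor$feature_id, strand = precursor$strand,
                 start = frag_start, end = frag_end, lineage = lineage,
                 source_id = precursor$molecule_id,
                 cut5_dinuc = cut5, cut3_dinuc = cut3)
}

#' Cleave a pool of precursors
#'
#' Applies [cleave_precursor()] to each row, with per-precursor seeds derived
#' from `seed` so the result is reproducible.
#'
#' @inheritParams cleave_precursor
#' @param precursors A [molecule_table()] of precursors.
#' @return A [molecule_table()] of all fragments.
#' @export
cleave_pool <- function(precursors, enzyme, cut_rate, seed = 1) {
  out <- lapply(seq_len(nrow(precursors)), function(i) {
    cleave_precursor(precursors[i, ], enzyme, cut_rate,
                     seed = (seed + 7919L * i) %% .Machine$integer.max)
  })
  do.call(rbind, out)
}

#' Mature cleavage fragments into piRNAs
#'
#' Models a molecular population: each cleavage fragment is a species of
#' which many copies exist, and maturation decides which downstream species
#' additionally exist. The input fragments are always kept; derivatives are
#' appended:
#' \enumerate{
#'   \item With probability `p_load` a fragment spawns a 5'-processed copy
#'     starting at the nearest downstream U within `scan_window` nt (no copy
#'     when no U is found), carrying a 5'-phosphate and the fragment's
#'     3'-cyclic phosphate — the P-cP-RNA stage (see [is_pcp()]).
#'   \item With probability `p_mature` a P-cP species at least
#'     `pirna_length[1]` nt long additionally spawns a mature piRNA: 3' end
#'     trimmed to a length drawn uniformly from `pirna_length` and set to
#'     2'-O-methylated hydroxyl. With probability `p_shift5` the mature 5'
#'     end is resected a further 1-3 nt (downstream 5' processing; the
#'     default 0 keeps piRNA 5' ends exactly anchored to their P-cP
#'     precursors).
#'   \item With probability `p_pingpong` a mature piRNA spawns an antisense
#'     partner on the same feature whose 5' end lies exactly 10 nt inside
#'     the guide's 5' end (5'-overlap of 10), linked via `partner_id`. With
#'     probability `background_antisense` an additional antisense molecule
#'     is emitted at a uniform non-10 overlap; the default 0.3 puts roughly
#'     70 percent of opposite-strand 5'-5' distances at 10 nt, the regime
#'     real piRNA libraries show.
#' }
#'
#' @param fragments A [molecule_table()] from [cleave_pool()].
#' @param refs The [make_reference()] the fragments came from (needed for
#'   antisense partner sequences).
#' @param config List overriding defaults: `p_load` (0.5), `p_mature` (0.8),
#'   `p_pingpong` (0.7), `p_shift5` (0), `background_antisense` (0.3),
#'   `scan_window` (10), `pirna_length` (`c(23, 30)`).
#' @param seed Integer seed.
#' @return A [molecule_table()]: the input fragments plus all spawned P-cP,
#'   mature-piRNA and antisense molecules. With `p_load = 0` the output
#'   equals the input.
#' @export
mature_pirnas <- function(fragments, refs, config = list(), seed = 1) {
  cfg <- utils::modifyList(list(p_load = 0.5, p_mature = 0.8, p_pingpong = 0.7,
                                p_shift5 = 0, background_antisense = 0.3,
                                scan_window = 10L, pirna_length = c(23L, 30L)),
                           config)
  for (p in c("p_load", "p_mature", "p_pingpong", "p_shift5",
              "background_antisense"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must lie in [0, 1]", call. = FALSE)
  if (nrow(fragments) == 0 || cfg$p_load == 0) return(fragments)
  with_seed(seed, {
    extras <- list()
    lens <- cfg$pirna_length[1]:cfg$pirna_length[2]
    for (i in seq_len(nrow(fragments))) {
      frag <- fragments[i, ]
      if (!(frag$lineage %in% c("cp_fragment", "downstream_fragment"))) next
      if (stats::runif(1) >= cfg$p_load) next
      win <- substr(frag$sequence, 1L, cfg$scan_window)
      o <- regexpr("U", win, fixed = TRUE)
      if (o < 0) next
      # 5'-processed P-cP species: starts at the downstream U, 5'-phosphate
      pcp <- frag
      pcp$molecule_id <- paste0(frag$molecule_id, ":pcp")
      pcp$sequence <- substr(frag$sequence, o, nchar(frag$sequence))
      pcp$start <- frag$start + o - 1L
      pcp$five_prime <- "phosphate"
      pcp$cut5_dinuc <- NA_character_
      pcp$source_id <- frag$molecule_id
      extras[[length(extras) + 1L]] <- pcp
      if (stats::runif(1) < cfg$p_mature && nchar(pcp$sequence) >= lens[1]) {
        pi <- pcp
        pi$molecule_id <- paste0(frag$molecule_id, ":pi")
        target <- min(sample(lens, 1), nchar(pcp$sequence))
        pi$sequence <- substr(pcp$sequence, 1L, target)
        pi$end <- pi$start + target
        pi$three_prime <- "hydroxyl_2Ome"
        pi$lineage <- "mature_pirna"
        pi$cut3_dinuc <- NA_character_
        pi$source_id <- pcp$molecule_id
        if (cfg$p_shift5 > 0 && stats::runif(1) < cfg$p_shift5 &&
            nchar(pi$sequence) > 4L) {
          sh <- sample(1:3, 1)
          pi$sequence <- substr(pi$sequence, sh + 1L, nchar(pi$sequence))
          pi$start <- pi$start + sh
        }
        extras[[length(extras) + 1L]] <- pi
        if (stats::runif(1) < cfg$p_pingpong) {
          pp <- antisense_partner(pi, refs, overlap = 10L,
                                  len = sample(lens, 1),
                                  partner_of = pi$molecule_id)
          if (!is.null(pp)) extras[[length(extras) + 1L]] <- pp
        }
        if (cfg$background_antisense > 0 &&
            stats::runif(1) < cfg$background_antisense) {
          d <- sample(setdiff(1:30, 10L), 1)
          bg <- antisense_partner(pi, refs, overlap = d,
                                  len = sample(lens, 1),
                                  partner_of = NA_character_)
          if (!is.null(bg)) extras[[length(extras) + 1L]] <- bg
        }
      }
    }
    out <- rbind(fragments, do.call(rbind, extras))
    rownames(out) <- NULL
    out
  })
}

# Antisense molecule on the same feature whose 5' end (in + coordinates)
# sits `overlap` - 1 nt downstream of the guide's 5' end, i.e. a 5'-5'
# overlap of `overlap` nt. Returns NULL when it would fall off the feature.
antisense_partner <- function(guide, refs, overlap, len, partner_of) {
  ref_seq <- refs$seqs[[guide$feature_id]]
  if (guide$strand != "+") return(NULL)
  p5 <- guide$start + overlap - 1L            # 0-based + coordinate of - 5' end
  start <- p5 - len + 1L
  end <- p5 + 1L
  if (start < 0L || end > nchar(ref_seq)) return(NULL)
  molecule_table(molecule_id = paste0(guide$molecule_id, ":as", overlap),
                 sequence = revcomp_rna(substr(ref_seq, start + 1L, end)),
                 five_prime = "phosphate", three_prime = "hydroxyl_2Ome",
                 feature_id = guide$feature_id, strand = "-",
                 start = start, end = end, lineage = "mature_pirna",
                 partner_id = partner_of, source_id = guide$molecule_id)
}

#' tRNA-half molecules from anticodon-loop cleavage
#'
#' Cleaves each annotated tRNA between the anticodon first and second
#' positions: the 5' half keeps the tRNA's 5'-phosphate and gains a
#' 2',3'-cyclic phosphate; the 3' half gets a 5'-hydroxyl and keeps a 3'
#' hydroxyl.
#'
#' @param refs A [make_reference()] object with tRNA annotations.
#' @return A [molecule_table()] with lineage `"trna_half"`.
#' @export
make_trna_halves <- function(refs) {
  out <- list()
  for (id in names(refs$trna_annotations)) {
    anno <- refs$trna_annotations[[id]]
    seq <- refs$seqs[[id]]
    cut <- anno$anticodon_start  # cut after anticodon position 1 (1-based)
    out[[length(out) + 1L]] <- molecule_table(
      molecule_id = paste0(id, c(":5half", ":3half")),
      sequence = c(substr(seq, 1L, cut), substr(seq, cut + 1L, nchar(seq))),
      five_prime = c("phosphate", "hydroxyl"),
      three_prime = c("cyclic_phosphate", "hydroxyl"),
      feature_id = id, strand = "+",
      start = c(0L, cut), end = c(cut, nchar(seq)),
      lineage = "trna_half")
  }
  if (length(out) == 0) return(empty_molecule_table())
  do.call(rbind, out)
}

#' Spike-in molecules
#'
#' Spike-ins are added after oxidation and before adapter ligation, so they
#' are modeled with a periodate-resistant ligatable 3' end
#' (`hydroxyl_2Ome`) and a 5'-phosphate.
#'
#' @param refs A [make_reference()] object.
#' @return A [molecule_table()] with lineage `"spikein"`.
#' @export
make_spikein_molecules <- function(refs) {
  feats <- refs$features[refs$features$class == "spikein", ]
  if (nrow(feats) == 0) return(empty_molecule_table())
  molecule_table(molecule_id = paste0(feats$id, ":mol"),
                 sequence = unname(refs$seqs[feats$id]),
                 five_prime = "phosphate", three_prime = "hydroxyl_2Ome",
                 feature_id = feats$id, strand = "+",
                 start = 0L, end = feats$length, lineage = "spikein")
}

#' Per-feature expression levels
#'
#' Log-normal(meanlog = 0, sdlog = 1) expression per feature, fixed by seed,
#' giving count tables a realistic dynamic range.
#'
#' @param refs A [make_reference()] object.
#' @param seed Integer seed.
#' @param sdlog Log-normal sd.
#' @return Named numeric vector of relative expression levels.
#' @export
make_abundance <- function(refs, seed = 1, sdlog = 1) {
  with_seed(seed, stats::setNames(
    stats::rlnorm(nrow(refs$features), meanlog = 0, sdlog = sdlog),
    refs$features$id))
}

#' Emit a sequencing library from a molecule pool
#'
#' Applies the protocol's retention logic ([protocol_retains()]) to the pool,
#' samples `depth` reads with replacement proportional to
#' `abundance[feature] * weight`, appends the 3' adapter, and returns the
#' reads together with the ground-truth records they were drawn from. Read
#' ids follow `<libname>:<record_id>:<serial>`.
#'
#' @param molecules A [molecule_table()].
#' @param protocol A [protocol_spec()].
#' @param depth Number of reads to emit (> 0).
#' @param adapter_3 3' adapter DNA sequence appended to every read.
#' @param seed Integer seed.
#' @param libname Library name used in read ids.
#' @param abundance Optional named per-feature weights (see
#'   [make_abundance()]); default all 1.
#' @param weight Optional per-molecule multiplicative weight.
#' @param fastq,truth_tsv Optional output paths; when given, a FASTQ file
#'   (uniform quality) and a TSV ground-truth sidecar are written.
#' @return List with `reads` (data frame: id, sequence (DNA, with adapter),
#'   insert, record_id) and `truth` (the retained [molecule_table()] with a
#'   `sampled_count` column).
#' @export
emit_library <- function(molecules, protocol, depth,
                         adapter_3 = "TGGAATTCTCGGGTGCCAAGG", seed = 1,
                         libname = tolower(protocol$name), abundance = NULL,
                         weight = NULL, fastq = NULL, truth_tsv = NULL) {
  stopifnot(depth > 0, nrow(molecules) > 0)
  keep <- vapply(seq_len(nrow(molecules)), function(i) {
    protocol_retains(end_chemistry(molecules$five_prime[i],
                                   molecules$three_prime[i]),
                     nchar(molecules$sequence[i]), protocol)
  }, TRUE)
  pool <- molecules[keep, , drop = FALSE]
  if (nrow(pool) == 0)
    stop("no molecules in the pool are retained by protocol ",
         protocol$name, " (", protocol$variant, ")", call. = FALSE)
  w <- if (is.null(weight)) rep(1, nrow(molecules)) else weight
  w <- w[keep]
  if (!is.null(abundance)) w <- w * unname(abundance[pool$feature_id])
  idx <- with_seed(seed, sample.int(nrow(pool), depth, replace = TRUE,
                                    prob = w))
  counts <- tabulate(idx, nbins = nrow(pool))
  reads <- data.frame(
    id = sprintf("%s:%s:%d", libname, pool$molecule_id[idx], seq_len(depth)),
    sequence = paste0(rna_to_dna(pool$sequence[idx]), adapter_3),
    insert = rna_to_dna(pool$sequence[idx]),
    record_id = pool$molecule_id[idx],
    stringsAsFactors = FALSE)
  truth <- pool
  truth$sampled_count <- counts
  if (!is.null(fastq)) write_fastq(reads$id, reads$sequence, fastq)
  if (!is.null(truth_tsv))
    utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(reads = reads, truth = truth)
}

#' Write reads as FASTQ with uniform quality
#'
#' @param ids Read identifiers.
#' @param seqs DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ (or FASTA) file into a read data frame
#'
#' @param path Input path.
#' @param format `"fastq"` or `"fasta"`.
#' @return Data frame with columns `id`, `sequence`.
#' @export
read_reads <- function(path, format = "fastq") {
  ss <- Biostrings::readDNAStringSet(path, format = format)
  data.frame(id = names(ss), sequence = as.character(ss),
             row.names = NULL, stringsAsFactors = FALSE)
}
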