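# End-to-end orchestration: simulate -> select-by-protocol -> trim ->
# filter -> map -> statistics, with seeded determinism and a
# machine-readable JSON run report.

#' Default pipeline configuration
#'
#' The demo configuration is a scaled-down germline small-RNA world: 20
#' transposon consensus sequences of 400-1200 nt, one tRNA, one rRNA decoy,
#' the two canonical spike-ins, an RNase kappa-like enzyme, and four
#' libraries (cP-RNA-seq, P-cP-RNA-seq, and control/knockdown piRNA-seq).
#' The knockdown library scales all biological abundances by `kd_factor`
#' while leaving spike-ins untouched.
#'
#' @param ... Named overrides merged into the defaults (nested lists are
#'   merged shallowly via [utils::modifyList()]).
#' @return A `RunConfig` list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = NULL,
    reference = list(n_transposons = 20L, transposon_length = c(400L, 1200L)),
    enzyme = c(CA = 1.0, CC = 0.35, AA = 0.35, GU = 0.05, UA = 0.25),
    cut_rate = 0.2,
    maturation = list(p_load = 0.5, p_mature = 0.8, p_pingpong = 0.7),
    depths = list(cp = 3000L, pcp = 2000L, pirna = 3000L, pirna_kd = 3000L),
    kd_factor = 0.25,
    adapter_3 = "TGGAATTCTCGGGTGCCAAGG",
    library_kinds = list(pirna = "bmn4_pirna", cp = "bmn4_cp"),
    max_mm_frac = 0.05,
    spikein_abundance = 20,
    spike_input = c(spikein_1 = 1, spikein_2 = 1),
    rpm_floor = 10)
  utils::modifyList(cfg, list(...))
}

#' Run the full simulation and analysis pipeline
#'
#' Stages: reference simulation, precursor cleavage, piRNA maturation,
#' tRNA-half and spike-in pool assembly, per-protocol library emission,
#' adapter trimming, length filtering, hierarchical mapping, and the full
#' statistics battery. Every figure-level statistic appears in the returned
#' report keyed by name; identical config + seed yields a byte-identical
#' report file.
#'
#' @param config A [default_run_config()] list (or overrides for it).
#' @param write_outputs Write FASTA/FASTQ/TSV per-stage outputs and the JSON
#'   report under `config$outdir` (default: only when `outdir` is set).
#' @return The run report, an R list mirroring the JSON.
#' @export
run_pipeline <- function(config = default_run_config(),
                         write_outputs = !is.null(config$outdir)) {
  cfg <- utils::modifyList(default_run_config(), config)
  seed <- as.integer(cfg$seed)
  outdir <- cfg$outdir
  if (write_outputs) {
    if (is.null(outdir)) outdir <- tempfile("cprnaseq_run_")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[cprnaseq] %-12s %6.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  refs <- stage("simulate", make_reference(cfg$reference, seed = seed))
  abundance <- make_abundance(refs, seed = seed + 1L)
  spike_ids <- refs$features$id[refs$features$class == "spikein"]
  abundance[spike_ids] <- cfg$spikein_abundance

  pool <- stage("cleave", {
    pre <- make_precursors(refs)
    frags <- cleave_pool(pre, enzyme_model(cfg$enzyme), cfg$cut_rate,
                         seed = seed + 2L)
    matured <- mature_pirnas(frags, refs, cfg$maturation, seed = seed + 3L)
    rbind(matured, make_trna_halves(refs), make_spikein_molecules(refs))
  })

  protocols <- list(
    cp = protocol_spec("CP_RNA_SEQ"),
    pcp = protocol_spec("P_CP_RNA_SEQ"),
    pirna = protocol_spec("PIRNA_SEQ"),
    pirna_kd = protocol_spec("PIRNA_SEQ"))
  kinds <- list(cp = cfg$library_kinds$cp, pcp = cfg$library_kinds$cp,
                pirna = cfg$library_kinds$pirna,
                pirna_kd = cfg$library_kinds$pirna)

  libs <- stage("select", {
    out <- list()
    for (lib in names(protocols)) {
      ab <- abundance
      if (lib == "pirna_kd")
        ab[setdiff(names(ab), spike_ids)] <-
          ab[setdiff(names(ab), spike_ids)] * cfg$kd_factor
      out[[lib]] <- emit_library(
        pool, protocols[[lib]], depth = cfg$depths[[lib]],
        adapter_3 = cfg$adapter_3, seed = seed + 10L + match(lib, names(protocols)),
        libname = lib, abundance = ab,
        fastq = if (write_outputs) file.path(outdir, paste0(lib, ".fastq"))
                else NULL,
        truth_tsv = if (write_outputs)
          file.path(outdir, paste0(lib, ".truth.tsv")) else NULL)
    }
    out
  })

  processed <- stage("trim", {
    lapply(stats::setNames(names(libs), names(libs)), function(lib) {
      tr <- trim_reads(libs[[lib]]$reads, cfg$adapter_3)
      filtered <- length_filter(tr$reads, kinds[[lib]])
      list(trimmed = tr$reads, filtered = filtered, report = tr$report)
    })
  })

  maps <- stage("map", {
    lapply(stats::setNames(names(libs), names(libs)), function(lib) {
      map_hierarchical(processed[[lib]]$filtered, refs,
                       max_mm_frac = cfg$max_mm_frac, seed = seed + 20L)
    })
  })

  report_stats <- stage("stats", {
    te_aln <- lapply(maps, function(m) m$alignments$transposon)
    # distinct cP/P-cP species = unique trimmed insert sequences that
    # mapped to the transposon tier
    species_of <- function(lib) {
      ids <- te_aln[[lib]]$read_id
      unique(processed[[lib]]$filtered$sequence[
        processed[[lib]]$filtered$id %in% ids])
    }
    cp_species <- species_of("cp")
    pcp_species <- species_of("pcp")
    pirna_seqs <- processed$pirna$filtered$sequence[
      processed$pirna$filtered$id %in% te_aln$pirna$read_id]

    comp <- end_composition(te_aln$cp, refs, k = 3L)
    trna_cls <- trna_class_proportions(maps$cp$alignments$trna, refs)

    xmap_cp <- cross_mapping_stats(pirna_seqs, cp_species,
                                   max_mm_frac = cfg$max_mm_frac)
    xmap_pcp <- cross_mapping_stats(pirna_seqs, pcp_species,
                                    max_mm_frac = cfg$max_mm_frac)
    tmr <- terminal_match_rate(xmap_pcp$alignments, xmap_pcp$targets)

    counts <- lapply(te_aln, count_and_rpm)
    r2_cp <- tryCatch(correlate_counts(counts$pirna, counts$cp,
                                       rpm_floor = cfg$rpm_floor),
                      error = function(e) list(r_squared = NA,
                                               n_features = 0))
    r2_pcp <- tryCatch(correlate_counts(counts$pirna, counts$pcp,
                                        rpm_floor = cfg$rpm_floor),
                       error = function(e) list(r_squared = NA,
                                                n_features = 0))

    pp <- pingpong_signal(te_aln$pirna)

    spike_counts <- function(lib) {
      sa <- maps[[lib]]$alignments$spikein
      if (nrow(sa) == 0) integer(0) else table(sa$feature_id)
    }
    full_table <- function(lib) {
      te <- table(te_aln[[lib]]$feature_id)
      sp <- spike_counts(lib)
      count_table(c(names(te), names(sp)), c(as.integer(te), as.integer(sp)),
                  library_id = lib)
    }
    spikes <- data.frame(id = names(cfg$spike_input),
                         input_amount = unname(cfg$spike_input))
    fold <- suppressWarnings(
      spikein_fold_change(full_table("pirna"), full_table("pirna_kd"),
                          spikes))

    list(
      nucleotide_composition = list(
        five = as.data.frame(unclass(comp$five)),
        three = as.data.frame(unclass(comp$three))),
      trna_classes = as.list(trna_cls),
      mapping_ratios = list(
        pirna_vs_cp = xmap_cp[c("read_mapping_ratio", "species_mapped_rate",
                                "n_query_reads", "n_target_species")],
        pirna_vs_pcp = xmap_pcp[c("read_mapping_ratio", "species_mapped_rate",
                                  "n_query_reads", "n_target_species")]),
      terminal_match = list(
        matched_5prime = tmr$matched_5prime[1:10],
        matched_3prime = tmr$matched_3prime[1:10],
        n = attr(tmr, "n"), denominator = attr(tmr, "denominator")),
      rpm_correlation = list(pirna_vs_cp = r2_cp[c("r_squared", "n_features")],
                             pirna_vs_pcp = r2_pcp[c("r_squared",
                                                     "n_features")]),
      pingpong = list(histogram = as.list(pp$histogram),
                      signal_fraction = pp$signal_fraction,
                      participant_fraction = pp$participant_fraction),
      spikein_fold_change = list(
        pirna_kd_vs_control = fold$fold_change,
        spikes_used = fold$spikes_used),
      length_histograms = lapply(processed, function(p)
        as.list(length_histogram(p$trimmed))))
  })

  report <- list(
    tool = "cprnaseq",
    seed = seed,
    config = config_echo(cfg),
    trimming = lapply(processed, `[[`, "report"),
    n_unmapped = lapply(maps, function(m) length(m$unmapped)),
    statistics = report_stats)

  if (write_outputs) {
    write_reference_fasta(refs, file.path(outdir, "references.fasta"))
    for (lib in names(maps)) {
      aln <- do.call(rbind, maps[[lib]]$alignments)
      write_alignments_tsv(aln, file.path(outdir,
                                          paste0(lib, ".alignments.tsv")))
    }
    yaml::write_yaml(config_echo(cfg), file.path(outdir, "config.yaml"))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$outdir <- outdir
  }
  report
}

# Config echo with non-serializable pieces normalized.
config_echo <- function(cfg) {
  cfg$outdir <- if (is.null(cfg$outdir)) NA_character_ else cfg$outdir
  cfg$enzyme <- as.list(cfg$enzyme)
  cfg$spike_input <- as.list(cfg$spike_input)
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' @param path Config file path; fields mirror [default_run_config()].
#' @return A `RunConfig` list (defaults merged under the file's values).
#' @export
load_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else stop("unsupported config format: ", ext, call. = FALSE)
  if (!is.null(cfg$enzyme)) cfg$enzyme <- unlist(cfg$enzyme)
  if (!is.null(cfg$spike_input)) cfg$spike_input <- unlist(cfg$spike_input)
  utils::modifyList(default_run_config(), cfg)
}
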