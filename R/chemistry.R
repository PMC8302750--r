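# Canonical tokens for terminal chemistry. 5' end: phosphate / hydroxyl /
# blocked_by_adapter; 3' end: cyclic_phosphate / monophosphate / hydroxyl /
# 2'-O-methylated hydroxyl / blocked_by_adapter.
FIVE_STATES  <- c("phosphate", "hydroxyl", "blocked_by_adapter")
THREE_STATES <- c("cyclic_phosphate", "monophosphate", "hydroxyl",
                  "hydroxyl_2Ome", "blocked_by_adapter")
TREATMENTS   <- c("CIP", "T4PNK", "PERIODATE", "LIGATE_3AD", "LIGATE_5AD")
PROTOCOL_NAMES <- c("PIRNA_SEQ", "CP_RNA_SEQ", "P_CP_RNA_SEQ", "OH_RNA_SEQ")
PROTOCOL_VARIANTS <- c("full", "no_pnk", "no_cip_no_pnk", "naio4_pretreated")

#' Terminal chemistry of an RNA molecule
#'
#' An `EndChemistry` records the 5' state (`phosphate`, `hydroxyl`, or
#' `blocked_by_adapter`), the 3' state (`cyclic_phosphate`, `monophosphate`,
#' `hydroxyl`, `hydroxyl_2Ome`, or `blocked_by_adapter`), and whether the
#' molecule has been destroyed (by periodate oxidation of an unprotected
#' 2',3'-cis-diol). This triple is the sole substrate of all protocol
#' selection logic: retention never depends on sequence.
#'
#' @param five_prime 5' state.
#' @param three_prime 3' state.
#' @param destroyed Logical; a destroyed molecule accepts no further
#'   treatment.
#' @return An object of class `EndChemistry`.
#' @examples
#' end_chemistry("hydroxyl", "cyclic_phosphate")
#' @export
end_chemistry <- function(five_prime = "phosphate", three_prime = "hydroxyl",
                          destroyed = FALSE) {
  five_prime  <- match.arg(five_prime, FIVE_STATES)
  three_prime <- match.arg(three_prime, THREE_STATES)
  stopifnot(is.logical(destroyed), length(destroyed) == 1L, !is.na(destroyed))
  structure(list(five_prime = five_prime, three_prime = three_prime,
                 destroyed = destroyed, ligation_failed = FALSE),
            class = "EndChemistry")
}

#' @export
print.EndChemistry <- function(x, ...) {
  cat(sprintf("<EndChemistry 5'=%s 3'=%s%s>\n", x$five_prime, x$three_prime,
              if (x$destroyed) " DESTROYED" else ""))
  invisible(x)
}

#' @export
format.EndChemistry <- function(x, ...) {
  if (x$destroyed) "destroyed" else paste0(x$five_prime, "/", x$three_prime)
}

#' Apply an enzymatic or chemical treatment to an end-chemistry state
#'
#' Deterministic single-step transition:
#' \describe{
#'   \item{CIP}{alkaline phosphatase: 3' monophosphate -> hydroxyl and 5'
#'     phosphate -> hydroxyl (unless adapter-blocked); cyclic phosphates are
#'     resistant.}
#'   \item{T4PNK}{polynucleotide kinase: opens the 2',3'-cyclic phosphate and
#'     removes 3' monophosphates (both -> hydroxyl); phosphorylates a 5'
#'     hydroxyl.}
#'   \item{PERIODATE}{NaIO4 oxidation destroys an unmethylated 3' hydroxyl
#'     (cis-diol); cyclic phosphate, monophosphate, 2'-O-methyl and blocked
#'     ends resist. An optional `leak` probability lets a cis-diol survive
#'     (robustness testing only; default 0 = complete oxidation).}
#'   \item{LIGATE_3AD}{3' adapter ligation: requires 3' hydroxyl (methylated
#'     or not); otherwise the molecule is left intact and the ligation is
#'     recorded as failed. `ome_efficiency` (default 1) optionally lowers the
#'     ligation efficiency of 2'-O-methylated ends.}
#'   \item{LIGATE_5AD}{5' adapter ligation: requires a 5' monophosphate.}
#' }
#' A `blocked_by_adapter` end is terminal for that end, and `destroyed` is
#' absorbing.
#'
#' @param state An [end_chemistry()] object with `destroyed = FALSE`.
#' @param treatment One of `"CIP"`, `"T4PNK"`, `"PERIODATE"`, `"LIGATE_3AD"`,
#'   `"LIGATE_5AD"`.
#' @param leak Probability that PERIODATE fails to destroy a cis-diol end.
#' @param ome_efficiency Probability that LIGATE_3AD succeeds on a
#'   2'-O-methylated 3' hydroxyl.
#' @return The transformed `EndChemistry`; the field `ligation_failed` is set
#'   when a ligation step could not attach its adapter.
#' @examples
#' apply_treatment(end_chemistry("phosphate", "cyclic_phosphate"), "CIP")
#' @export
apply_treatment <- function(state, treatment, leak = 0, ome_efficiency = 1) {
  stopifnot(inherits(state, "EndChemistry"))
  if (state$destroyed)
    stop("invalid state: cannot treat a destroyed molecule", call. = FALSE)
  treatment <- match.arg(treatment, TREATMENTS)
  s <- state
  s$ligation_failed <- FALSE
  switch(treatment,
    CIP = {
      if (s$three_prime == "monophosphate") s$three_prime <- "hydroxyl"
      if (s$five_prime == "phosphate") s$five_prime <- "hydroxyl"
    },
    T4PNK = {
      if (s$three_prime %in% c("cyclic_phosphate", "monophosphate"))
        s$three_prime <- "hydroxyl"
      if (s$five_prime == "hydroxyl") s$five_prime <- "phosphate"
    },
    PERIODATE = {
      if (s$three_prime == "hydroxyl") {
        survives <- leak > 0 && stats::runif(1) < leak
        if (!survives) s$destroyed <- TRUE
      }
    },
    LIGATE_3AD = {
      ok <- s$three_prime %in% c("hydroxyl", "hydroxyl_2Ome")
      if (ok && s$three_prime == "hydroxyl_2Ome" && ome_efficiency < 1)
        ok <- stats::runif(1) < ome_efficiency
      if (ok) s$three_prime <- "blocked_by_adapter" else s$ligation_failed <- TRUE
    },
    LIGATE_5AD = {
      if (s$five_prime == "phosphate") s$five_prime <- "blocked_by_adapter"
      else s$ligation_failed <- TRUE
    })
  s
}

#' Sequencing protocol definition
#'
#' Returns the ordered treatment list and read-length window of one of the
#' four library protocols, optionally modified by a control variant:
#' \describe{
#'   \item{PIRNA_SEQ}{PERIODATE, LIGATE_3AD, LIGATE_5AD — only
#'     oxidation-resistant, ligatable 3' ends (2'-O-methyl) with a 5'
#'     phosphate survive.}
#'   \item{CP_RNA_SEQ}{CIP, PERIODATE, T4PNK, LIGATE_3AD, LIGATE_5AD —
#'     cyclic-phosphate 3' ends resist both CIP and periodate, are opened by
#'     PNK and ligated; PNK also phosphorylates 5' hydroxyls, so both 5'-P
#'     and 5'-OH molecules are captured.}
#'   \item{P_CP_RNA_SEQ}{LIGATE_5AD first, then the cP-RNA-seq steps — only
#'     molecules that already carry a 5' monophosphate are captured.}
#'   \item{OH_RNA_SEQ}{LIGATE_3AD, LIGATE_5AD — direct ligation of 3'
#'     hydroxyl ends.}
#' }
#' Variants: `no_pnk` removes T4PNK; `no_cip_no_pnk` removes CIP and T4PNK;
#' `naio4_pretreated` prepends PERIODATE (meaningful for OH_RNA_SEQ).
#'
#' @param name Protocol name.
#' @param variant Protocol variant.
#' @param length_window Inclusive `[min, max]` insert-length window in nt;
#'   default depends on the protocol (24-29 for piRNA-seq, 30-70 otherwise,
#'   the BmN4 analysis windows).
#' @param leak,ome_efficiency Passed to [apply_treatment()].
#' @return A `ProtocolSpec` object.
#' @examples
#' protocol_spec("CP_RNA_SEQ")
#' protocol_spec("CP_RNA_SEQ", variant = "no_pnk")
#' @export
protocol_spec <- function(name, variant = "full", length_window = NULL,
                          leak = 0, ome_efficiency = 1) {
  name <- match.arg(name, PROTOCOL_NAMES)
  variant <- match.arg(variant, PROTOCOL_VARIANTS)
  steps <- switch(name,
    PIRNA_SEQ    = c("PERIODATE", "LIGATE_3AD", "LIGATE_5AD"),
    CP_RNA_SEQ   = c("CIP", "PERIODATE", "T4PNK", "LIGATE_3AD", "LIGATE_5AD"),
    P_CP_RNA_SEQ = c("LIGATE_5AD", "CIP", "PERIODATE", "T4PNK", "LIGATE_3AD"),
    OH_RNA_SEQ   = c("LIGATE_3AD", "LIGATE_5AD"))
  if (variant == "no_pnk") steps <- setdiff(steps, "T4PNK")
  if (variant == "no_cip_no_pnk") steps <- setdiff(steps, c("CIP", "T4PNK"))
  if (variant == "naio4_pretreated") steps <- c("PERIODATE", steps)
  if (is.null(length_window))
    length_window <- if (name == "PIRNA_SEQ") c(24L, 29L) else c(30L, 70L)
  stopifnot(length(length_window) == 2L,
            length_window[1] <= length_window[2], length_window[1] > 0)
  structure(list(name = name, variant = variant, steps = steps,
                 length_window = as.integer(length_window),
                 leak = leak, ome_efficiency = ome_efficiency),
            class = "ProtocolSpec")
}

#' @export
print.ProtocolSpec <- function(x, ...) {
  cat(sprintf("<ProtocolSpec %s (%s): %s; window %d-%d nt>\n", x$name,
              x$variant, paste(x$steps, collapse = " -> "),
              x$length_window[1], x$length_window[2]))
  invisible(x)
}

#' Load protocol definitions from a YAML or JSON config file
#'
#' The file holds a list of entries with fields `name` and optionally
#' `variant` and `length_window`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of `ProtocolSpec` objects.
#' @export
load_protocols <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("configuration error: unsupported config format: ", ext,
                   call. = FALSE)
  out <- lapply(cfg, function(e) {
    protocol_spec(e$name,
                  variant = if (is.null(e$variant)) "full" else e$variant,
                  length_window = if (is.null(e$length_window)) NULL
                                  else unlist(e$length_window))
  })
  names(out) <- vapply(out, function(p) paste0(p$name,
      if (p$variant == "full") "" else paste0(".", p$variant)), "")
  out
}

# Fold the protocol's treatment steps over a state; returns the final state
# (possibly destroyed). Stops early on destruction.
run_protocol_steps <- function(state, protocol) {
  for (t in protocol$steps) {
    if (state$destroyed) return(state)
    state <- apply_treatment(state, t, leak = protocol$leak,
                             ome_efficiency = protocol$ome_efficiency)
  }
  state
}

#' Does a protocol retain a molecule with a given end chemistry and length?
#'
#' A molecule is sequenced iff its length lies in the protocol's window and
#' folding the protocol's treatment steps over its end chemistry ends with
#' both adapters attached (both ends `blocked_by_adapter`) and the molecule
#' not destroyed. Retention depends only on (chemistry, length), never on
#' sequence.
#'
#' @param state An [end_chemistry()] object.
#' @param length_nt Molecule length in nt (> 0).
#' @param protocol A [protocol_spec()] object.
#' @return `TRUE` or `FALSE`.
#' @examples
#' protocol_retains(end_chemistry("hydroxyl", "cyclic_phosphate"), 45,
#'                  protocol_spec("CP_RNA_SEQ"))
#' @export
protocol_retains <- function(state, length_nt, protocol) {
  stopifnot(inherits(protocol, "ProtocolSpec"), length_nt > 0)
  if (length_nt < protocol$length_window[1] ||
      length_nt > protocol$length_window[2]) return(FALSE)
  final <- run_protocol_steps(state, protocol)
  !final$destroyed &&
    final$five_prime == "blocked_by_adapter" &&
    final$three_prime == "blocked_by_adapter"
}

#' Exhaustive retention truth table for a protocol
#'
#' Enumerates all 2 x 4 initial (5', 3') end states (`blocked_by_adapter`
#' initial states are not physical inputs) at an in-window length and reports
#' which are retained.
#'
#' @param protocol A [protocol_spec()] object.
#' @return A data frame with columns `five_prime`, `three_prime`, `retained`.
#' @examples
#' protocol_truth_table(protocol_spec("PIRNA_SEQ"))
#' @export
protocol_truth_table <- function(protocol) {
  stopifnot(inherits(protocol, "ProtocolSpec"))
  len <- protocol$length_window[1]
  grid <- expand.grid(five_prime = c("phosphate", "hydroxyl"),
                      three_prime = c("cyclic_phosphate", "monophosphate",
                                      "hydroxyl", "hydroxyl_2Ome"),
                      stringsAsFactors = FALSE)
  grid$retained <- mapply(function(f, t) {
    protocol_retains(end_chemistry(f, t), len, protocol)
  }, grid$five_prime, grid$three_prime, USE.NAMES = FALSE)
  grid
}

#' Write a protocol truth table as TSV
#'
#' @param table Output of [protocol_truth_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
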