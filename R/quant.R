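# Count tables, RPM, correlation, ping-pong signal, spike-in normalization,
# and read-length histograms.

#' Per-feature counts and RPM for one tier
#'
#' RPM is reads per million reads mapped to the counted tier:
#' `count * 1e6 / sum(counts)`.
#'
#' @param alignments Alignment data frame from one tier, one alignment per
#'   read (see [choose_one_alignment()]).
#' @param library_id Optional library label stored as an attribute.
#' @return `CountTable` data frame: `feature_id`, `count`, `rpm`.
#' @export
count_and_rpm <- function(alignments, library_id = NA_character_) {
  if (nrow(alignments) == 0)
    stop("zero mapped reads: RPM is undefined for an empty tier",
         call. = FALSE)
  tab <- table(alignments$feature_id)
  out <- data.frame(feature_id = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$rpm <- out$count * 1e6 / sum(out$count)
  attr(out, "library_id") <- library_id
  class(out) <- c("CountTable", "data.frame")
  out
}

#' Build a count table directly from counts
#'
#' @param feature_id Feature identifiers.
#' @param count Non-negative counts.
#' @param library_id Optional library label.
#' @return A `CountTable` (see [count_and_rpm()]).
#' @export
count_table <- function(feature_id, count, library_id = NA_character_) {
  stopifnot(all(count >= 0), length(feature_id) == length(count))
  if (sum(count) == 0)
    stop("zero mapped reads: RPM is undefined", call. = FALSE)
  out <- data.frame(feature_id = as.character(feature_id),
                    count = as.numeric(count), stringsAsFactors = FALSE)
  out$rpm <- out$count * 1e6 / sum(out$count)
  attr(out, "library_id") <- library_id
  class(out) <- c("CountTable", "data.frame")
  out
}

#' Correlate two count tables
#'
#' Features with RPM above `rpm_floor` in BOTH tables are kept;
#' `pearson_log10` returns the squared Pearson correlation of log10(RPM)
#' (the scatter-plot convention for RPM data), `spearman` the squared rank
#' correlation.
#'
#' @param table_a,table_b `CountTable` objects sharing a feature universe.
#' @param rpm_floor Keep features with RPM strictly above this in both
#'   tables (default 10).
#' @param method `"pearson_log10"` or `"spearman"`.
#' @return List: `r_squared`, `n_features`, `method`.
#' @export
correlate_counts <- function(table_a, table_b, rpm_floor = 10,
                             method = c("pearson_log10", "spearman")) {
  method <- match.arg(method)
  m <- merge(table_a[, c("feature_id", "rpm")],
             table_b[, c("feature_id", "rpm")], by = "feature_id")
  m <- m[m$rpm.x > rpm_floor & m$rpm.y > rpm_floor, ]
  if (nrow(m) < 3)
    stop("correlation undefined: fewer than 3 features pass the RPM floor",
         call. = FALSE)
  r <- if (method == "pearson_log10")
    stats::cor(log10(m$rpm.x), log10(m$rpm.y))
  else stats::cor(m$rpm.x, m$rpm.y, method = "spearman")
  list(r_squared = r^2, n_features = nrow(m), method = method)
}

#' Ping-pong profile of stranded alignments
#'
#' For each feature, every pair of reads on opposite strands contributes its
#' 5'-5' overlap distance d = (5' position of the minus-strand read in plus
#' coordinates) - (5' position of the plus-strand read) + 1, accumulated for
#' d in 1..30 and weighted by the product of the two 5'-position read
#' counts. The ping-pong signal is the fraction of that histogram at d = 10.
#' `participant_fraction` additionally reports the fraction of reads whose
#' 5' position takes part in at least one d = 10 pair.
#'
#' @param alignments Stranded alignment data frame (transposon tier).
#' @return List: `histogram` (named vector over d = 1..30),
#'   `signal_fraction`, `participant_fraction`, `n_pairs`.
#' @export
pingpong_signal <- function(alignments) {
  h <- stats::setNames(numeric(30), 1:30)
  part_reads <- 0
  total_reads <- nrow(alignments)
  for (fid in unique(alignments$feature_id)) {
    a <- alignments[alignments$feature_id == fid, ]
    plus <- a[a$strand == "+", ]
    minus <- a[a$strand == "-", ]
    if (nrow(plus) == 0 || nrow(minus) == 0) next
    p5 <- table(plus$start + 1L)    # 1-based 5' positions, with read counts
    m5 <- table(minus$end)          # half-open end == 1-based 5' of - read
    pp <- as.integer(names(p5)); pc <- as.numeric(p5)
    mp <- as.integer(names(m5)); mc <- as.numeric(m5)
    d <- outer(mp, pp, "-") + 1L
    wprod <- outer(mc, pc)
    ok <- d >= 1 & d <= 30
    if (any(ok)) {
      tt <- tapply(wprod[ok], d[ok], sum)
      h[names(tt)] <- h[names(tt)] + tt
    }
    ten <- d == 10
    if (any(ten)) {
      part_plus <- pp[apply(ten, 2, any)]
      part_minus <- mp[apply(ten, 1, any)]
      part_reads <- part_reads + sum(pc[pp %in% part_plus]) +
        sum(mc[mp %in% part_minus])
    }
  }
  tot <- sum(h)
  list(histogram = h,
       signal_fraction = if (tot > 0) unname(h["10"] / tot) else 0,
       participant_fraction = if (total_reads > 0) part_reads / total_reads
                              else 0,
       n_pairs = tot)
}

#' Spike-in normalized fold change between two libraries
#'
#' Per library, the scale factor is the mean over spike-ins of
#' `input_amount / observed count` (arithmetic mean by default, geometric
#' optional); the normalized abundance is the tier total (spike-ins
#' excluded) times the scale factor, and the returned fold change is
#' B over A. Spike-ins with zero observed counts in either library are
#' dropped with a warning; if none remain, this is an error.
#'
#' @param table_a,table_b `CountTable` objects that include spike-in
#'   features.
#' @param spikes Data frame with `id` and `input_amount` columns.
#' @param mean_type `"arithmetic"` or `"geometric"`.
#' @return List: `fold_change` (B/A), `scale_a`, `scale_b`,
#'   `normalized_total_a`, `normalized_total_b`, `per_feature` (data frame
#'   of per-feature normalized B/A ratios), `spikes_used`.
#' @export
spikein_fold_change <- function(table_a, table_b, spikes,
                                mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  obs <- function(tab, id) {
    i <- match(id, tab$feature_id)
    ifelse(is.na(i), 0, tab$count[i])
  }
  oa <- obs(table_a, spikes$id)
  ob <- obs(table_b, spikes$id)
  usable <- oa > 0 & ob > 0
  if (!all(usable))
    warning("dropping spike-ins with zero observed counts: ",
            paste(spikes$id[!usable], collapse = ", "))
  if (!any(usable))
    stop("no spike-in has nonzero counts in both libraries", call. = FALSE)
  ratios_a <- spikes$input_amount[usable] / oa[usable]
  ratios_b <- spikes$input_amount[usable] / ob[usable]
  mt <- function(x) if (mean_type == "arithmetic") mean(x)
                    else exp(mean(log(x)))
  scale_a <- mt(ratios_a)
  scale_b <- mt(ratios_b)
  bio_a <- table_a[!(table_a$feature_id %in% spikes$id), ]
  bio_b <- table_b[!(table_b$feature_id %in% spikes$id), ]
  norm_a <- sum(bio_a$count) * scale_a
  norm_b <- sum(bio_b$count) * scale_b
  pf <- merge(bio_a[, c("feature_id", "count")],
              bio_b[, c("feature_id", "count")], by = "feature_id",
              all = TRUE)
  pf[is.na(pf)] <- 0
  pf$ratio <- (pf$count.y * scale_b) / ifelse(pf$count.x > 0,
                                              pf$count.x * scale_a, NA)
  list(fold_change = norm_b / norm_a, scale_a = scale_a, scale_b = scale_b,
       normalized_total_a = norm_a, normalized_total_b = norm_b,
       per_feature = pf, spikes_used = spikes$id[usable])
}

#' Read length histogram
#'
#' @param reads Data frame with a `sequence` column, or a character vector.
#' @return Named integer vector: counts per length (empty for empty input).
#' @export
length_histogram <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  if (length(seqs) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(nchar(seqs))
  stats::setNames(as.integer(tab), names(tab))
}
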