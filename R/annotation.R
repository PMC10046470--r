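#' Replication-timing class from a signed Repli-seq score
#'
#' value < 0 -> "late"; 0 <= value < 1 -> "mid_early"; value >= 1 -> "early".
#' The two boundaries are included in the upper class (0 is mid_early, 1 is
#' early).
#'
#' @param value signed replication-timing score(s).
#' @return character vector of class labels.
#' @export
classify_timing <- function(value) {
  if (any(!is.finite(value))) input_error("replication-timing values must be finite")
  ifelse(value < 0, "late", ifelse(value < 1, "mid_early", "early"))
}

TIMING_CLASSES <- c("late", "mid_early", "early")
CHROMATIN_MARKS <- c("H3K27ac", "H3K36me3", "H3K9me3", "H3K27me3")

#' Read a 4-column BED track
#'
#' Coordinates are 0-based half-open. The 4th column is a chromatin-mark label
#' (`kind = "chromatin_mark"`) or a signed replication-timing value
#' (`kind = "replication_timing"`).
#'
#' @param path BED file path.
#' @param kind track kind.
#' @return data.frame with `chrom`, `start`, `end`, and `label` or `value`.
#' @export
read_track <- function(path, kind = c("chromatin_mark", "replication_timing")) {
  kind <- match.arg(kind)
  bed <- read_tsv(path, header = FALSE)
  if (ncol(bed) < 4) format_error(sprintf("%s: expected 4 BED columns", path))
  names(bed)[1:4] <- c("chrom", "start", "end", "V4")
  bad <- which(bed$start >= bed$end)
  if (length(bad)) {
    format_error(sprintf("%s: malformed interval (start >= end) at line %d", path, bad[1]))
  }
  out <- bed[, 1:4]
  if (kind == "chromatin_mark") {
    names(out)[4] <- "label"
  } else {
    out$V4 <- as.numeric(out$V4)
    if (any(is.na(out$V4))) format_error(sprintf("%s: non-numeric timing values", path))
    names(out)[4] <- "value"
  }
  attr(out, "kind") <- kind
  out
}

track_to_granges <- function(track) {
  # BED 0-based half-open [start, end) -> 1-based closed [start+1, end]
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(track$start + 1L, track$end))
}

#' Annotate CpG probes with chromatin marks and replication timing
#'
#' Each probe (a single-base position, BED 0-based) gains one boolean per
#' chromatin mark (TRUE when the position falls in any interval carrying that
#' mark), a replication-timing value (from the covering timing interval;
#' ties between overlapping intervals resolved by nearest interval midpoint),
#' and the corresponding timing class. Probes on chromosomes absent from a
#' track, or outside all its intervals, are uncovered (FALSE / NA), not
#' errors.
#'
#' @param manifest data.frame with `probe_id`, `chrom`, `pos` (0-based) and
#'   optionally `genomic_feature`.
#' @param mark_tracks named list of chromatin-mark tracks (see [read_track()]);
#'   a track may carry several labels in its 4th column.
#' @param timing_track replication-timing track, or NULL.
#' @return the manifest with one logical column per mark plus
#'   `timing_value` and `timing_class`.
#' @export
annotate_probes <- function(manifest, mark_tracks = list(), timing_track = NULL) {
  if (anyDuplicated(manifest[c("chrom", "pos")])) {
    input_error("duplicate (chrom, pos) in probe manifest")
  }
  probes <- GenomicRanges::GRanges(manifest$chrom,
                                   IRanges::IRanges(manifest$pos + 1L, manifest$pos + 1L))
  out <- manifest
  marks_seen <- character(0)
  for (track in mark_tracks) {
    if (any(track$start >= track$end)) format_error("malformed interval (start >= end) in mark track")
    gr <- track_to_granges(track)
    for (lab in unique(track$label)) {
      hits <- GenomicRanges::findOverlaps(probes, gr[track$label == lab])
      col <- rep(FALSE, nrow(manifest))
      col[unique(S4Vectors::queryHits(hits))] <- TRUE
      if (lab %in% marks_seen) {
        out[[lab]] <- out[[lab]] | col
      } else {
        out[[lab]] <- col
        marks_seen <- c(marks_seen, lab)
      }
    }
  }
  if (!is.null(timing_track)) {
    if (any(timing_track$start >= timing_track$end)) {
      format_error("malformed interval (start >= end) in timing track")
    }
    gr <- track_to_granges(timing_track)
    hits <- GenomicRanges::findOverlaps(probes, gr)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    tv <- rep(NA_real_, nrow(manifest))
    if (length(qh)) {
      # nearest-midpoint tie-break for probes covered by several intervals
      mid <- (timing_track$start + timing_track$end) / 2
      dist <- abs(manifest$pos[qh] - mid[sh])
      ord <- order(qh, dist)
      keep <- ord[!duplicated(qh[ord])]
      tv[qh[keep]] <- timing_track$value[sh[keep]]
    }
    out$timing_value <- tv
    out$timing_class <- ifelse(is.na(tv), NA_character_, classify_timing(ifelse(is.na(tv), 0, tv)))
  }
  out
}

#' Replication-timing profile of demethylated CpGs
#'
#' Reports (i) the fraction of a drug's DMCs falling in each timing class
#' (over DMCs with timing coverage; fractions sum to 1) and (ii) the Pearson
#' correlation between per-probe delta-beta and the timing value across all
#' tested probes with coverage.
#'
#' @param dmcs DMC table from [call_dmcs()].
#' @param annotated manifest from [annotate_probes()] with timing columns.
#' @param cutoff delta-beta cutoff selecting the DMC set (default 0).
#' @return list with `fractions` (named numeric over late/mid_early/early),
#'   `r`, `p_value`, `n_dmc_covered`.
#' @export
timing_demethylation_profile <- function(dmcs, annotated, cutoff = 0) {
  check_cutoff(cutoff)
  if (is.null(annotated$timing_value)) input_error("manifest lacks timing annotation")
  idx <- match(dmcs$probe_id, annotated$probe_id)
  tv <- annotated$timing_value[idx]
  covered <- is.finite(tv)
  if (sum(covered) < 3) input_error("fewer than 3 probes with timing coverage")
  flagged <- dmcs[[dmc_col(cutoff)]] & covered
  if (!any(flagged)) input_error("no covered DMCs at this cutoff")
  cls <- factor(classify_timing(tv[flagged]), levels = TIMING_CLASSES)
  fractions <- as.numeric(table(cls)) / sum(flagged)
  names(fractions) <- TIMING_CLASSES
  ct <- cor.test(dmcs$delta_beta[covered], tv[covered], method = "pearson")
  list(fractions = fractions, r = unname(ct$estimate), p_value = ct$p.value,
       n_dmc_covered = sum(flagged))
}
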