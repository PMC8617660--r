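# Interval calling from per-SNP significance masks, cross-method consensus,
# and the interval -> annotated-gene candidate funnel.

.interval_cols <- c("chrom", "start", "end", "method", "n_snps",
                    "peak_pos", "peak_value")

.empty_intervals <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             method = character(0), n_snps = integer(0),
             peak_pos = integer(0), peak_value = numeric(0))
}

#' Call QTL intervals from a significance mask
#'
#' Extracts maximal runs of at least `min_run` consecutive significant SNPs
#' per chromosome. Interval boundaries are the first and last significant
#' SNP positions of the run; the peak is the SNP maximizing the method's
#' statistic (|delta_smooth|, G', or the fitted ED^k). Runs are split where
#' adjacent significant SNPs lie more than `max_gap_bp` apart, so signals
#' separated by more than one smoothing window are reported separately.
#'
#' @param track a `stat_track` from [compute_stat_track()].
#' @param method one of `"gprime"`, `"delta"`, `"ed"`.
#' @param min_run minimum SNPs per interval (default 10).
#' @param max_gap_bp maximal distance between consecutive significant SNPs
#'   inside one interval; defaults to the track's smoothing window.
#' @return Data frame of intervals (`chrom`, `start`, `end`, `method`,
#'   `n_snps`, `peak_pos`, `peak_value`), ordered by chromosome and start.
#' @export
call_intervals <- function(track, method = c("gprime", "delta", "ed"),
                           min_run = 10, max_gap_bp = NULL) {
  method <- match.arg(method)
  cfg <- attr(track, "config")
  if (is.null(max_gap_bp))
    max_gap_bp <- if (!is.null(cfg)) cfg$window_bp else Inf
  mask <- switch(method, gprime = track$sig_gprime, delta = track$sig_delta,
                 ed = track$sig_ed)
  stat <- switch(method, gprime = track$Gprime,
                 delta = abs(track$delta_smooth), ed = track$ed_fit)
  mask[is.na(mask)] <- FALSE

  out <- .empty_intervals()
  for (ch in unique(track$chrom)) {
    i <- which(track$chrom == ch & mask)
    if (!length(i)) next
    pos <- track$pos[i]
    # split runs at non-consecutive SNP indices or large genomic gaps
    brk <- cumsum(c(0L, diff(i) != 1L | diff(pos) > max_gap_bp))
    for (g in split(seq_along(i), brk)) {
      if (length(g) < min_run) next
      ii <- i[g]
      pk <- ii[which.max(stat[ii])]
      out <- rbind(out, data.frame(
        chrom = ch, start = track$pos[ii[1L]], end = track$pos[ii[length(ii)]],
        method = method, n_snps = length(ii),
        peak_pos = track$pos[pk], peak_value = stat[pk]))
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.intervals_to_gr <- function(iv) {
  GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start, iv$end))
}

#' Consensus regions supported by multiple scan methods
#'
#' Returns the genomic regions covered by intervals from at least
#' `min_methods` distinct methods, computed as the coverage-function
#' intersection (per-method coverage is flattened first, so overlapping
#' intervals of the same method count once). With `min_methods = 1` this is
#' the union of all per-method coverage.
#'
#' @param intervals data frame of intervals from [call_intervals()]
#'   (possibly several methods row-bound together).
#' @param min_methods minimum number of supporting methods (default 2).
#' @param track optional `stat_track` used to fill `n_snps`, `peak_pos` and
#'   `peak_value` (peak = max |delta_smooth| within the region).
#' @return Data frame of consensus intervals (`method = "consensus"`).
#' @export
consensus <- function(intervals, min_methods = 2, track = NULL) {
  if (nrow(intervals) == 0L) return(.empty_intervals())
  per_method <- lapply(split(intervals, intervals$method), function(iv)
    GenomicRanges::reduce(.intervals_to_gr(iv)))
  # coverage vectors must share one length per chromosome before summing
  lens <- vapply(split(as.numeric(intervals$end), intervals$chrom), max, 0)
  cov <- Reduce(`+`, lapply(per_method, function(gr) {
    GenomeInfoDb::seqlevels(gr) <- names(lens)
    GenomeInfoDb::seqlengths(gr) <- lens
    GenomicRanges::coverage(gr)
  }))
  hits <- IRanges::slice(cov, lower = min_methods, rangesOnly = TRUE)
  gr <- GenomicRanges::GRanges(hits)
  if (length(gr) == 0L) return(.empty_intervals())
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    method = "consensus", n_snps = NA_integer_,
    peak_pos = NA_integer_, peak_value = NA_real_)
  if (!is.null(track)) {
    for (k in seq_len(nrow(out))) {
      in_iv <- track$chrom == out$chrom[k] &
        track$pos >= out$start[k] & track$pos <= out$end[k]
      out$n_snps[k] <- sum(in_iv)
      if (any(in_iv)) {
        s <- abs(track$delta_smooth)
        s[!in_iv | is.na(s)] <- -Inf
        out$peak_pos[k] <- track$pos[which.max(s)]
        out$peak_value[k] <- max(s)
      }
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.parse_flag <- function(x) {
  tolower(as.character(x)) %in% c("true", "1", "yes", "t")
}

#' Genes overlapping QTL intervals (the candidate funnel)
#'
#' Loads gene annotation (GFF3: `gene`-type features with `ID`; or BED with
#' >= 4 columns, optional extra flag columns), keeps genes overlapping any
#' interval by at least 1 bp, applies optional boolean flag filters (e.g.
#' `mito_targeted = TRUE`, `expressed = TRUE`, matching attribute tags of
#' the same name), and counts screened variants per gene.
#'
#' @param intervals interval data frame ([call_intervals()] /
#'   [consensus()]).
#' @param annotation path to a GFF3 or BED file, or a `GRanges`.
#' @param flag_filters named list of required boolean flag values.
#' @param snps optional screened-SNP data frame for per-gene variant counts.
#' @return Data frame with `gene_id`, `chrom`, `start`, `end`, one column
#'   per flag found, and `n_variants`.
#' @export
genes_in_intervals <- function(intervals, annotation, flag_filters = list(),
                               snps = NULL) {
  genes <- if (methods::is(annotation, "GRanges")) {
    annotation
  } else {
    gr <- rtracklayer::import(annotation)
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
    gr
  }
  mc <- S4Vectors::mcols(genes)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID)
         else if ("name" %in% names(mc)) as.character(mc$name)
         else paste0("gene", seq_along(genes))
  flags <- setdiff(names(mc),
                   c("ID", "name", "type", "source", "score", "phase",
                     "itemRgb", "thick", "blocks"))
  out <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes), end = GenomicRanges::end(genes),
    row.names = NULL)
  for (f in flags) out[[f]] <- .parse_flag(mc[[f]])

  if (nrow(intervals) == 0L) {
    out <- out[0, , drop = FALSE]
  } else {
    hit <- GenomicRanges::countOverlaps(genes, .intervals_to_gr(intervals)) > 0
    out <- out[hit, , drop = FALSE]
  }
  for (f in names(flag_filters)) {
    if (!f %in% names(out))
      stop2("flag '", f, "' not present in the annotation")
    out <- out[out[[f]] == flag_filters[[f]], , drop = FALSE]
  }
  out$n_variants <- rep(0L, nrow(out))
  if (!is.null(snps) && nrow(out) > 0L) {
    snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                     IRanges::IRanges(snps$pos, snps$pos))
    gene_gr <- GenomicRanges::GRanges(out$chrom,
                                      IRanges::IRanges(out$start, out$end))
    out$n_variants <- GenomicRanges::countOverlaps(gene_gr, snp_gr)
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write interval/gene reports
#'
#' Writes intervals and genes as TSV, a BED export of the intervals
#' (0-based half-open), and a plain-text summary. When a `sim_truth` is
#' given, each interval is flagged `covers_truth` if it contains the true
#' causal position.
#'
#' @param intervals interval data frame (any mix of methods).
#' @param genes gene data frame from [genes_in_intervals()] or NULL.
#' @param dir output directory (created if needed).
#' @param truth optional `sim_truth`.
#' @return Invisibly, the paths written.
#' @export
report_qtl <- function(intervals, genes = NULL, dir = ".", truth = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  iv <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  if (!is.null(truth))
    iv$covers_truth <- iv$chrom == truth$qtl_chrom &
      iv$start <= truth$qtl_pos & iv$end >= truth$qtl_pos

  paths <- c(intervals = file.path(dir, "intervals.tsv"),
             bed = file.path(dir, "intervals.bed"),
             summary = file.path(dir, "summary.txt"))
  write.table(iv, paths["intervals"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  bed <- data.frame(chrom = iv$chrom, start = iv$start - 1L, end = iv$end,
                    name = if (nrow(iv)) paste0(iv$method, "_", seq_len(nrow(iv)))
                           else character(0))
  write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(genes)) {
    paths["genes"] <- file.path(dir, "genes.tsv")
    write.table(genes, paths["genes"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  lines <- c("QTL interval report", "===================", "")
  for (m in unique(iv$method)) {
    sub <- iv[iv$method == m, , drop = FALSE]
    lines <- c(lines, sprintf("[%s] %d interval(s)", m, nrow(sub)),
               sprintf("  %s:%d-%d  n_snps=%d peak=%s@%d%s",
                       sub$chrom, sub$start, sub$end, sub$n_snps,
                       formatC(sub$peak_value, digits = 4, format = "g"),
                       sub$peak_pos,
                       if (!is.null(truth))
                         ifelse(sub$covers_truth, " covers_truth=true", "")
                       else ""))
  }
  if (!is.null(genes))
    lines <- c(lines, "", sprintf("genes in intervals: %d", nrow(genes)))
  lines <- c(lines,
             "", "note: the consensus rule (regions supported by >= min_methods",
             "scans) is a construction of this pipeline, not a published one.")
  writeLines(lines, paths["summary"])
  invisible(paths)
}
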