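# VCF ingestion, GATK-style hard filtering and the four genotype screening
# rules that produce the polarized per-SNP allele-depth table.

DROP_REASONS <- c("low_qual", "fs", "mq", "qd", "mqranksum", "readposranksum",
                  "parent_het", "parents_identical", "sbulk_mismatch",
                  "depth_out_of_range", "multiallelic", "missing_fields")

#' Default hard-filter thresholds
#'
#' GATK-style site rejection: a record fails when `QUAL < qual_min` or
#' `QD < qd_min` or `FS > fs_max` or `MQ < mq_min` or
#' `MQRankSum < mqranksum_min` or `ReadPosRankSum < readposranksum_min`.
#' A missing annotation passes its clause (GATK convention).
#'
#' @param qual_min,qd_min,fs_max,mq_min,mqranksum_min,readposranksum_min
#'   clause thresholds.
#' @return A named list of thresholds.
#' @export
filter_thresholds <- function(qual_min = 30, qd_min = 13, fs_max = 20,
                              mq_min = 20, mqranksum_min = -3,
                              readposranksum_min = -3) {
  list(qual_min = qual_min, qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
       mqranksum_min = mqranksum_min, readposranksum_min = readposranksum_min)
}

#' Read a multi-sample VCF into a flat record table
#'
#' Wraps `VariantAnnotation::readVcf()`. The four roles must each name a
#' sample present in the VCF header. Multi-allelic sites are kept but
#' flagged; allele depths are extracted for the first ALT allele only (such
#' sites are dropped later with reason `multiallelic`).
#'
#' @param path VCF file (plain text or gzip).
#' @param sample_roles named list/vector with entries `donor`, `recurrent`,
#'   `fbulk`, `sbulk` mapping role to sample name.
#' @return A data frame with one row per record: `chrom`, `pos`, `ref`,
#'   `alt`, `qual`, the INFO floats `FS`, `MQ`, `QD`, `MQRankSum`,
#'   `ReadPosRankSum` (NA when absent), `multiallelic`, per-role genotype
#'   strings `gt_*`, and bulk allele depths `fb_ref`, `fb_alt`, `sb_ref`,
#'   `sb_alt` (NA when AD is missing).
#' @export
read_vcf <- function(path, sample_roles = list(donor = "P596",
                                               recurrent = "P1318",
                                               fbulk = "F_bulk",
                                               sbulk = "S_bulk")) {
  if (!file.exists(path)) stop2("VCF not found: ", path)
  roles <- c("donor", "recurrent", "fbulk", "sbulk")
  if (!all(roles %in% names(sample_roles)))
    stop2("sample_roles must name all of: ", paste(roles, collapse = ", "))
  hdr <- VariantAnnotation::scanVcfHeader(path)
  have <- VariantAnnotation::samples(hdr)
  want <- unlist(sample_roles[roles], use.names = FALSE)
  if (!all(want %in% have))
    stop2("sample(s) not in VCF header: ",
          paste(setdiff(want, have), collapse = ", "))

  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  alt_flat <- as.character(unlist(alt))
  first_idx <- cumsum(n_alt) - n_alt + 1L
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt >= 1L] <- alt_flat[first_idx[n_alt >= 1L]]

  info <- VariantAnnotation::info(vcf)
  grab_info <- function(key) {
    if (key %in% colnames(info)) {
      v <- info[[key]]
      if (is.list(v) || methods::is(v, "List"))
        v <- vapply(v, function(x) if (length(x)) as.numeric(x[[1]]) else NA_real_,
                    0)
      as.numeric(v)
    } else rep(NA_real_, nrow(info))
  }

  gt <- VariantAnnotation::geno(vcf)$GT
  ad <- VariantAnnotation::geno(vcf)$AD
  # AD comes back as a 3-d array when every record has the same allele
  # count, otherwise as a matrix of per-record vectors
  ad_pair <- function(sample) {
    if (is.array(ad) && length(dim(ad)) == 3L) {
      r <- as.numeric(ad[, sample, 1L])
      a <- as.numeric(ad[, sample, 2L])
    } else {
      col <- ad[, sample]
      r <- vapply(col, function(x)
        if (length(x) >= 1L && !is.na(x[[1L]])) as.numeric(x[[1L]]) else NA_real_, 0)
      a <- vapply(col, function(x)
        if (length(x) >= 2L && !is.na(x[[2L]])) as.numeric(x[[2L]]) else NA_real_, 0)
    }
    list(ref = r, alt = a)
  }
  fb <- ad_pair(sample_roles$fbulk)
  sb <- ad_pair(sample_roles$sbulk)

  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt1,
    qual = as.numeric(rr$QUAL),
    FS = grab_info("FS"), MQ = grab_info("MQ"), QD = grab_info("QD"),
    MQRankSum = grab_info("MQRankSum"),
    ReadPosRankSum = grab_info("ReadPosRankSum"),
    multiallelic = n_alt > 1L,
    gt_donor = gt[, sample_roles$donor],
    gt_recurrent = gt[, sample_roles$recurrent],
    gt_fbulk = gt[, sample_roles$fbulk],
    gt_sbulk = gt[, sample_roles$sbulk],
    fb_ref = fb$ref, fb_alt = fb$alt, sb_ref = sb$ref, sb_alt = sb$alt,
    row.names = NULL)
}

#' Apply GATK-style hard filters to a record table
#'
#' @param records data frame from [read_vcf()].
#' @param th thresholds from [filter_thresholds()].
#' @return Character vector, one element per record: NA for pass, otherwise
#'   the first failing reason in the order `low_qual`, `qd`, `fs`, `mq`,
#'   `mqranksum`, `readposranksum`.
#' @export
hard_filter <- function(records, th = filter_thresholds()) {
  n <- nrow(records)
  fails <- function(x, bad) !is.na(x) & bad
  reason <- rep(NA_character_, n)
  clauses <- list(
    low_qual = fails(records$qual, records$qual < th$qual_min),
    qd = fails(records$QD, records$QD < th$qd_min),
    fs = fails(records$FS, records$FS > th$fs_max),
    mq = fails(records$MQ, records$MQ < th$mq_min),
    mqranksum = fails(records$MQRankSum, records$MQRankSum < th$mqranksum_min),
    readposranksum = fails(records$ReadPosRankSum,
                           records$ReadPosRankSum < th$readposranksum_min))
  for (nm in names(clauses))
    reason[is.na(reason) & clauses[[nm]]] <- nm
  reason
}

.is_hom <- function(gt) gt %in% c("0/0", "1/1", "0|0", "1|1")
.gt_norm <- function(gt) gsub("|", "/", gt, fixed = TRUE)

#' Screen hard-filter survivors with the four genotype rules
#'
#' A biallelic record is kept iff (1) both parents are homozygous, (2) the
#' parents' genotypes differ, (3) the S-bulk's called genotype equals the
#' recurrent parent's, and (4) both bulks' allele-depth totals fall in
#' `[min_depth, max_depth]`. Kept records are polarized onto the donor
#' allele: `donor_allele` is the allele carried homozygously by the donor
#' parent, `aF`/`rF` and `aS`/`rS` are the donor/other depths in the
#' F- and S-bulk.
#'
#' @param records data frame from [read_vcf()].
#' @param th hard-filter thresholds, see [filter_thresholds()].
#' @param min_depth,max_depth inclusive bulk depth bounds (defaults 10, 100).
#' @return A list of class `screen_result`: `snps` (data frame with columns
#'   `chrom`, `pos`, `donor_allele`, `aF`, `rF`, `aS`, `rS`, sorted by
#'   chromosome then position) and `report` (class `filter_report`, with the
#'   per-reason drop counts, `kept` and `total`).
#' @export
screen_table <- function(records, th = filter_thresholds(),
                         min_depth = 10, max_depth = 100) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  set <- function(mask, why) reason[is.na(reason) & mask] <<- why

  set(records$multiallelic, "multiallelic")
  gt_missing <- function(gt) is.na(gt) | gt %in% c(".", "./.", ".|.")
  missing_f <- gt_missing(records$gt_donor) | gt_missing(records$gt_recurrent) |
    gt_missing(records$gt_fbulk) | gt_missing(records$gt_sbulk) |
    is.na(records$fb_ref) | is.na(records$fb_alt) |
    is.na(records$sb_ref) | is.na(records$sb_alt)
  set(missing_f, "missing_fields")
  hf <- hard_filter(records, th)
  set(!is.na(hf) & hf == "low_qual", "low_qual")
  set(!is.na(hf) & hf == "qd", "qd")
  set(!is.na(hf) & hf == "fs", "fs")
  set(!is.na(hf) & hf == "mq", "mq")
  set(!is.na(hf) & hf == "mqranksum", "mqranksum")
  set(!is.na(hf) & hf == "readposranksum", "readposranksum")
  set(!(.is_hom(records$gt_donor) & .is_hom(records$gt_recurrent)),
      "parent_het")
  set(.gt_norm(records$gt_donor) == .gt_norm(records$gt_recurrent),
      "parents_identical")
  set(.gt_norm(records$gt_sbulk) != .gt_norm(records$gt_recurrent),
      "sbulk_mismatch")
  dp_f <- records$fb_ref + records$fb_alt
  dp_s <- records$sb_ref + records$sb_alt
  set(dp_f < min_depth | dp_f > max_depth |
        dp_s < min_depth | dp_s > max_depth, "depth_out_of_range")

  keep <- is.na(reason)
  kept <- records[keep, , drop = FALSE]
  donor_is_alt <- .gt_norm(kept$gt_donor) == "1/1"
  snps <- data.frame(
    chrom = kept$chrom, pos = kept$pos,
    donor_allele = ifelse(donor_is_alt, "ALT", "REF"),
    aF = ifelse(donor_is_alt, kept$fb_alt, kept$fb_ref),
    rF = ifelse(donor_is_alt, kept$fb_ref, kept$fb_alt),
    aS = ifelse(donor_is_alt, kept$sb_alt, kept$sb_ref),
    rS = ifelse(donor_is_alt, kept$sb_ref, kept$sb_alt),
    row.names = NULL)
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL

  counts <- vapply(DROP_REASONS, function(r) sum(reason == r, na.rm = TRUE), 0L)
  report <- structure(
    list(counts = counts, kept = sum(keep), total = n), class = "filter_report")
  stopifnot(report$kept + sum(report$counts) == report$total)
  structure(list(snps = snps, report = report), class = "screen_result")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("variant screening:", x$total, "records,", x$kept, "kept\n")
  nz <- x$counts[x$counts > 0]
  if (length(nz))
    cat(paste0("  ", format(names(nz)), " ", nz, collapse = "\n"), "\n")
  invisible(x)
}

#' Read VCF and screen in one step
#'
#' @inheritParams read_vcf
#' @inheritParams screen_table
#' @return A `screen_result`; fatal error when no SNP survives.
#' @export
screen_vcf <- function(path, sample_roles = list(donor = "P596",
                                                 recurrent = "P1318",
                                                 fbulk = "F_bulk",
                                                 sbulk = "S_bulk"),
                       th = filter_thresholds(),
                       min_depth = 10, max_depth = 100) {
  res <- screen_table(read_vcf(path, sample_roles), th, min_depth, max_depth)
  if (nrow(res$snps) == 0L) {
    print(res$report)
    stop2("no SNPs survived screening")
  }
  res
}

#' Write / read a screened-SNP table as TSV
#' @param snps,path the SNP data frame and file path.
#' @export
write_snps <- function(snps, path)
  write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' @rdname write_snps
#' @export
read_snps <- function(path)
  read.delim(path, colClasses = c(chrom = "character"))

#' Write a filter report as JSON
#' @param report a `filter_report`; `path` output file.
#' @param path output file.
#' @export
write_filter_report <- function(report, path)
  jsonlite::write_json(list(total = report$total, kept = report$kept,
                            dropped = as.list(report$counts)),
                       path, auto_unbox = TRUE, pretty = TRUE)
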