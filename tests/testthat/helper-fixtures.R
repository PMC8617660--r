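# Shared fixture builders: everything is generated in code at test time.

# A hand-assembled bc1_pop with known genotypes/grades, for bulk tests.
manual_pop <- function(genotype, grade) {
  structure(list(
    genotype = list(chr01 = genotype),
    qtl_genotype = genotype[, 1L],
    grade = grade, n = nrow(genotype)), class = "bc1_pop")
}

# Fully penetrant grade model: carriers always grade 3-4, non-carriers 0-1.
full_penetrance_qtl <- function(chrom, pos)
  restorer_qtl(chrom, pos,
               grade_dist_carrier = c(0, 0, 0, 0.5, 0.5),
               grade_dist_noncarrier = c(0.5, 0.5, 0, 0, 0))

# No-selection model: both genotype classes share one grade distribution,
# so bulk membership is independent of genotype (a true null).
null_qtl <- function(chrom, pos) {
  d <- c(0.3, 0.2, 0.0, 0.2, 0.3)
  restorer_qtl(chrom, pos, grade_dist_carrier = d, grade_dist_noncarrier = d)
}

# Simulate straight to a screened-SNP table (no VCF round trip): bulk read
# counts at every marker, polarized on the donor allele by construction.
simulate_snp_table <- function(map, qtl, pop_size = 200, bulk_size = 30,
                               depth_low = 10, depth_high = 100,
                               error_rate = 0.001, recomb_rate = 4e-8,
                               seed = 1) {
  pop <- simulate_bc1(map, qtl, pop_size, recomb_rate,
                      seed = derive_seed2(seed, 1))
  bulks <- select_bulks(pop, bulk_size, seed = derive_seed2(seed, 2))
  cf <- simulate_bulk_reads(bulks$F, depth_low, depth_high, error_rate,
                            seed = derive_seed2(seed, 3))
  cs <- simulate_bulk_reads(bulks$S, depth_low, depth_high, error_rate,
                            seed = derive_seed2(seed, 4))
  do.call(rbind, lapply(names(map$markers), function(ch) {
    data.frame(chrom = ch, pos = map$markers[[ch]],
               donor_allele = map$donor_allele[[ch]],
               aF = cf[[ch]]$donor_depth, rF = cf[[ch]]$other_depth,
               aS = cs[[ch]]$donor_depth, rS = cs[[ch]]$other_depth)
  }))
}

derive_seed2 <- function(seed, offset) (seed * 131L + offset) %% .Machine$integer.max

# O(n^2) brute-force tricube reference, written independently of the
# package's windowed implementation.
brute_tricube <- function(values, positions, window_bp) {
  n <- length(values)
  out <- numeric(n)
  for (f in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      D <- abs(positions[j] - positions[f])
      if (D <= window_bp / 2) {
        w <- (1 - (2 * D / window_bp)^3)^3
        num <- num + w * values[j]
        den <- den + w
      }
    }
    out[f] <- num / den
  }
  out
}

# Independent Benjamini-Hochberg oracle.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# The screening fixture: 15 records, 3 kept, each of the 12 drop reasons
# hit exactly once. Returns the VCF path.
write_screen_fixture <- function(path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr01,length=2000000>",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"x\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"x\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"x\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"x\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP596\tP1318\tF_bulk\tS_bulk")
  # rec(pos, overrides): one VCF line; defaults pass everything and get kept
  rec <- function(pos, qual = 50, fs = 1, mq = 60, qd = 20, mqrs = 0,
                  rprs = 0, alt = "T", p596 = "1/1:0,30:30",
                  p1318 = "0/0:30,0:30", fb = "0/1:20,20:40",
                  sb = "0/0:50,2:52") {
    sprintf("chr01\t%d\t.\tA\t%s\t%.1f\tPASS\tFS=%.1f;MQ=%.1f;QD=%.1f;MQRankSum=%.1f;ReadPosRankSum=%.1f\tGT:AD:DP\t%s\t%s\t%s\t%s",
            pos, alt, qual, fs, mq, qd, mqrs, rprs, p596, p1318, fb, sb)
  }
  body <- c(
    rec(1000),                                     # kept
    rec(2000, qual = 25),                          # low_qual
    rec(3000, fs = 25),                            # fs
    rec(4000, mq = 10),                            # mq
    rec(5000, qd = 5),                             # qd
    rec(6000, mqrs = -5),                          # mqranksum
    rec(7000, rprs = -5),                          # readposranksum
    rec(8000, p596 = "0/1:15,15:30"),              # parent_het
    rec(9000, p596 = "0/0:30,0:30",
        fb = "0/0:38,2:40"),                       # parents_identical
    rec(10000, sb = "0/1:30,22:52"),               # sbulk_mismatch
    rec(11000, fb = "0/1:4,3:7"),                  # depth_out_of_range
    rec(12000, alt = "T,G", fb = "0/1:20,15,5:40",
        sb = "0/0:45,4,3:52"),                     # multiallelic
    rec(13000, fb = "./.:.:."),                    # missing_fields
    rec(14000),                                    # kept
    rec(15000, p596 = "0/0:30,0:30", p1318 = "1/1:0,30:30",
        fb = "0/1:20,20:40", sb = "1/1:2,50:52"))  # kept (donor = REF)
  writeLines(c(hdr, body), path)
  path
}

# Small GFF3 gene annotation with boolean attribute flags.
write_gff_fixture <- function(path = tempfile(fileext = ".gff3")) {
  lines <- c(
    "##gff-version 3",
    "chr01\ttest\tgene\t1500\t1800\t.\t+\t.\tID=geneA;mito_targeted=true;expressed=true",
    "chr01\ttest\tgene\t2950\t3050\t.\t-\t.\tID=geneB;mito_targeted=false;expressed=true",
    "chr01\ttest\tgene\t9000\t9500\t.\t+\t.\tID=geneC;mito_targeted=true;expressed=false",
    "chr02\ttest\tgene\t100\t400\t.\t+\t.\tID=geneD;mito_targeted=true;expressed=true")
  writeLines(lines, path)
  path
}

# Minimal stat_track-shaped data frame for interval-calling tests.
manual_track <- function(chrom, pos, sig, stat = NULL) {
  n <- length(pos)
  stat <- stat %||% as.numeric(sig)
  df <- data.frame(
    chrom = chrom, pos = pos,
    delta_smooth = stat, Gprime = stat, ed_fit = stat,
    sig_gprime = sig, sig_delta = sig, sig_ed = sig)
  class(df) <- c("stat_track", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
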