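test_that("interval extraction follows the min-run rule", {
  tr <- manual_track("chr01", c(100, 200, 300, 400),
                     c(FALSE, TRUE, TRUE, FALSE))
  iv <- call_intervals(tr, "gprime", min_run = 2)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 200)
  expect_equal(iv$end, 300)
  expect_equal(iv$n_snps, 2)

  # isolated significant SNPs never reach min_run
  tr2 <- manual_track("chr01", (1:5) * 100, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(nrow(call_intervals(tr2, "gprime", min_run = 2)), 0)

  # everything significant: one interval per chromosome
  tr3 <- manual_track(rep(c("chr01", "chr02"), each = 4),
                      rep((1:4) * 100, 2), rep(TRUE, 8))
  iv3 <- call_intervals(tr3, "delta", min_run = 2)
  expect_equal(iv3$chrom, c("chr01", "chr02"))
  expect_equal(iv3$start, c(100, 100))
  expect_equal(iv3$end, c(400, 400))

  # peak sits at the maximal statistic and inside the interval
  tr4 <- manual_track("chr01", (1:6) * 100, rep(TRUE, 6),
                      stat = c(1, 2, 9, 3, 2, 1))
  iv4 <- call_intervals(tr4, "ed", min_run = 3)
  expect_equal(iv4$peak_pos, 300)
  expect_equal(iv4$peak_value, 9)

  # runs split across gaps wider than max_gap_bp
  tr5 <- manual_track("chr01", c(1e5, 2e5, 3e5, 5e6, 5.1e6, 5.2e6),
                      rep(TRUE, 6))
  expect_equal(nrow(call_intervals(tr5, "gprime", min_run = 3,
                                   max_gap_bp = 1e6)), 2)
  expect_equal(nrow(call_intervals(tr5, "gprime", min_run = 3,
                                   max_gap_bp = Inf)), 1)
})

test_that("interval calling is translation-equivariant", {
  set.seed(33)
  sig <- runif(50) < 0.4
  pos <- sort(sample.int(1e6, 50))
  tr <- manual_track("chr01", pos, sig)
  iv <- call_intervals(tr, "gprime", min_run = 3, max_gap_bp = Inf)
  shift <- manual_track("chr01", pos + 7777, sig)
  iv2 <- call_intervals(shift, "gprime", min_run = 3, max_gap_bp = Inf)
  expect_equal(iv2$start, iv$start + 7777)
  expect_equal(iv2$end, iv$end + 7777)
})

test_that("consensus is the coverage intersection across methods", {
  mk <- function(chrom, start, end, method)
    data.frame(chrom = chrom, start = start, end = end, method = method,
               n_snps = 10L, peak_pos = start, peak_value = 1)

  # idempotence: identical intervals from all three methods
  same <- rbind(mk("chr01", 100, 300, "gprime"), mk("chr01", 100, 300, "delta"),
                mk("chr01", 100, 300, "ed"))
  cs <- consensus(same, min_methods = 2)
  expect_equal(cs[, c("chrom", "start", "end")],
               data.frame(chrom = "chr01", start = 100, end = 300))

  # disjoint intervals: no consensus
  disj <- rbind(mk("chr01", 100, 200, "gprime"), mk("chr01", 300, 400, "ed"))
  expect_equal(nrow(consensus(disj, min_methods = 2)), 0)

  # partial overlap: the derived example [200, 300]
  part <- rbind(mk("chr01", 100, 300, "gprime"), mk("chr01", 200, 400, "ed"))
  cs2 <- consensus(part, min_methods = 2)
  expect_equal(cs2$start, 200)
  expect_equal(cs2$end, 300)

  # brute-force per-bp coverage oracle on random interval sets
  set.seed(44)
  rand <- do.call(rbind, lapply(c("gprime", "delta", "ed"), function(m) {
    s <- sort(sample.int(900, 4))
    mk("chr01", s, s + sample.int(120, 4), m)
  }))
  for (k in 1:3) {
    cov <- rep(0L, 1200)
    for (m in unique(rand$method)) {
      hit <- rep(FALSE, 1200)
      sub <- rand[rand$method == m, ]
      for (i in seq_len(nrow(sub))) hit[sub$start[i]:sub$end[i]] <- TRUE
      cov <- cov + hit
    }
    want <- which(cov >= k)
    cs3 <- consensus(rand, min_methods = k)
    got <- unlist(lapply(seq_len(nrow(cs3)),
                         function(i) cs3$start[i]:cs3$end[i]))
    expect_equal(sort(got), want)
  }

  # min_methods = 1 is the union of per-method coverage
  un <- consensus(rand, min_methods = 1)
  expect_true(all(un$end >= un$start))
  expect_equal(nrow(consensus(data.frame()[0, ], 2)), 0)
})

test_that("gene intersection applies the any-overlap rule and flags", {
  gff <- write_gff_fixture()
  iv <- data.frame(chrom = "chr01", start = 1000, end = 3000,
                   method = "consensus", n_snps = 5L, peak_pos = 2000,
                   peak_value = 1)
  genes <- genes_in_intervals(iv, gff)
  # geneA inside, geneB overlaps the boundary; geneC/geneD outside
  expect_equal(genes$gene_id, c("geneA", "geneB"))

  # 1 bp overlap is enough
  iv1 <- transform(iv, start = 1800, end = 1800)
  expect_equal(genes_in_intervals(iv1, gff)$gene_id, "geneA")

  # flag filters narrow the funnel
  flagged <- genes_in_intervals(iv, gff, flag_filters = list(mito_targeted = TRUE))
  expect_equal(flagged$gene_id, "geneA")
  expect_error(genes_in_intervals(iv, gff, flag_filters = list(nope = TRUE)),
               "nope")

  # screened variants are counted per gene
  snps <- data.frame(chrom = "chr01", pos = c(1500, 1600, 2970, 5000))
  counted <- genes_in_intervals(iv, gff, snps = snps)
  expect_equal(counted$n_variants, c(2L, 1L))

  expect_equal(nrow(genes_in_intervals(iv[0, ], gff)), 0)
})

test_that("reports are deterministic and truth-aware", {
  iv <- data.frame(chrom = "chr01", start = c(100, 5000), end = c(900, 9000),
                   method = c("gprime", "consensus"), n_snps = c(12L, 20L),
                   peak_pos = c(400, 7000), peak_value = c(3.2, 0.41))
  truth <- structure(list(qtl_chrom = "chr01", qtl_pos = 7000L),
                     class = "sim_truth")
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- report_qtl(iv, genes = NULL, dir = d1, truth = truth)
  p2 <- report_qtl(iv, genes = NULL, dir = d2, truth = truth)
  expect_identical(readLines(p1[["intervals"]]), readLines(p2[["intervals"]]))
  expect_identical(readLines(p1[["summary"]]), readLines(p2[["summary"]]))

  got <- read.delim(p1[["intervals"]])
  expect_equal(got$covers_truth, c(FALSE, TRUE))
  # BED export is 0-based half-open
  bed <- read.delim(p1[["bed"]], header = FALSE)
  expect_equal(bed$V2, iv$start - 1)
  expect_equal(bed$V3, iv$end)

  # empty interval set still yields valid files
  p0 <- report_qtl(iv[0, ], genes = NULL, dir = tempfile())
  expect_true(file.exists(p0[["intervals"]]))
  expect_equal(nrow(read.delim(p0[["intervals"]])), 0)
})
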