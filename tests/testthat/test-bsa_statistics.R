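test_that("SNP-index and delta have their closed forms", {
  expect_equal(snp_index(10, 10), 0.5)
  expect_equal(snp_index(0, 25), 0)
  expect_equal(snp_index(7, 3), 0.7)
  expect_error(snp_index(0, 0), "zero total depth")

  expect_equal(delta_snp_index(0.5, 0), 0.5)
  expect_equal(delta_snp_index(0.3, 0.3), 0)
  expect_equal(delta_snp_index(0, 0.5), -0.5)
  expect_error(delta_snp_index(1.2, 0), "\\[0, 1\\]")
})

test_that("tricube smoothing matches the brute-force reference", {
  # degenerate cases
  expect_equal(tricube_smooth(3.2, 100, 1e6), 3.2)
  expect_equal(tricube_smooth(rep(2, 50), seq(1e4, 5e5, 1e4), 1e6),
               rep(2, 50))

  # 1,000 random SNPs vs the O(n^2) double loop, within 1e-12
  set.seed(101)
  pos <- sort(sample.int(2e7, 1000))
  val <- rnorm(1000)
  expect_equal(tricube_smooth(val, pos, 1e6), brute_tricube(val, pos, 1e6),
               tolerance = 1e-12)

  # chromosomes are independent
  chrom <- rep(c("a", "b"), each = 500)
  two <- tricube_smooth(val, c(pos[1:500], pos[1:500]), 1e6, chrom)
  expect_equal(two[1:500], brute_tricube(val[1:500], pos[1:500], 1e6),
               tolerance = 1e-12)
  expect_equal(two[501:1000], brute_tricube(val[501:1000], pos[1:500], 1e6),
               tolerance = 1e-12)

  expect_error(tricube_smooth(1:3, c(5, 2, 9), 1e6), "sorted")
})

test_that("G statistic matches closed forms and the hand-computed oracle", {
  expect_equal(g_statistic(10, 10, 10, 10), 0)
  expect_equal(g_statistic(20, 0, 0, 20), 80 * log(2))
  # frozen from an independent evaluation of 2*sum(o*ln(o/e)),
  # e = row_total*col_total/n over the 2x2 table (12,8,6,14)
  expect_equal(g_statistic(12, 8, 6, 14), 3.6960663345, tolerance = 1e-9)

  # zero row/column convention
  expect_equal(g_statistic(0, 0, 5, 5), 0)
  expect_equal(g_statistic(0, 10, 0, 20), 0)

  # invariance under swapping bulks; vectorized evaluation
  set.seed(7)
  m <- matrix(rpois(400, 20), ncol = 4)
  expect_equal(g_statistic(m[, 1], m[, 2], m[, 3], m[, 4]),
               g_statistic(m[, 3], m[, 4], m[, 1], m[, 2]))
  expect_true(all(g_statistic(m[, 1], m[, 2], m[, 3], m[, 4]) >= 0))
})

test_that("G' equals smoothed G and matches the reference smoother", {
  set.seed(11)
  pos <- sort(sample.int(5e6, 300))
  G <- rexp(300)
  expect_equal(gprime(G, pos, 1e6), brute_tricube(G, pos, 1e6),
               tolerance = 1e-12)
  expect_equal(gprime(5, 1000, 1e6), 5)
  expect_equal(gprime(rep(1.3, 20), seq(1e4, 2e5, 1e4), 1e6), rep(1.3, 20))
})

test_that("log-normal null fit recovers parameters and controls the FDR", {
  # Monte-Carlo oracle: pure log-normal noise, no signal
  set.seed(2026)
  gp <- exp(rnorm(10000, mean = 1, sd = 0.5))
  fit <- gprime_pq(gp, fdr_q = 0.01)
  expect_lt(abs(fit$mu - 1), 0.05)
  expect_lt(abs(fit$sigma - 0.5), 0.05)
  expect_lte(mean(fit$sig), 0.02)

  # q-values equal an independently coded Benjamini-Hochberg adjustment
  expect_equal(fit$q, brute_bh(fit$p))
  # q monotone nondecreasing in p-rank
  expect_true(all(diff(fit$q[order(fit$p)]) >= -1e-15))

  # degenerate constant track: warning, no rejections
  expect_warning(cst <- gprime_pq(rep(2, 50)), "degenerate")
  expect_true(all(cst$p == 1))
  expect_false(any(cst$sig))
})

test_that("simulated delta confidence bands are nested, symmetric, narrowing", {
  cfg <- scan_config(ci_reps = 1e5, seed = 99)
  ci10 <- delta_ci(10, cfg)
  ci100 <- delta_ci(100, cfg)
  for (ci in list(ci10, ci100)) {
    # null symmetry: band contains 0, roughly centred on it
    expect_lt(ci[["ci95_lo"]], 0); expect_gt(ci[["ci95_hi"]], 0)
    expect_lt(abs(ci[["ci95_lo"]] + ci[["ci95_hi"]]), 0.05)
    expect_lt(abs(ci[["ci99_lo"]] + ci[["ci99_hi"]]), 0.05)
    # quantile nesting
    expect_lte(ci[["ci99_lo"]], ci[["ci95_lo"]])
    expect_gte(ci[["ci99_hi"]], ci[["ci95_hi"]])
  }
  # deeper sequencing narrows the band strictly
  expect_lt(ci100[["ci95_hi"]] - ci100[["ci95_lo"]],
            ci10[["ci95_hi"]] - ci10[["ci95_lo"]])
  # memoized per depth: identical on repeat call
  expect_identical(delta_ci(10, cfg), ci10)

  expect_error(delta_ci(10, scan_config(ci_reps = 50)), "ci_reps")
})

test_that("Euclidean distance has its closed form", {
  expect_equal(euclidean_distance(1, 0), sqrt(2))
  expect_equal(ed_power(euclidean_distance(1, 0)), 4 * sqrt(2))
  expect_equal(euclidean_distance(0.4, 0.4), 0)
  expect_equal(euclidean_distance(0.5, 0), 0.5 * sqrt(2))
  # ED = sqrt(2)|delta| for any biallelic pair
  set.seed(5)
  f <- runif(100); s <- runif(100)
  expect_equal(euclidean_distance(f, s), sqrt(2) * abs(f - s))
})

test_that("ED Loess fitting is locally exact with a stable threshold", {
  cfg <- scan_config()
  pos <- seq(1e4, 3e6, by = 1e4)

  # constant input: fitted constant, SD = 0, threshold = the constant
  const <- ed_loess_threshold(rep(0.25, length(pos)), pos, cfg = cfg)
  expect_equal(const$fitted, rep(0.25, length(pos)), tolerance = 1e-8)
  expect_equal(const$threshold, 0.25, tolerance = 1e-8)

  # noiseless quadratic is reproduced exactly by local quadratic fitting
  y <- 1e-3 * (2 + 3 * (pos / 1e6) - 0.5 * (pos / 1e6)^2)
  quad <- ed_loess_threshold(y, pos, cfg = cfg)
  expect_equal(quad$fitted, y, tolerance = 1e-6)

  # fitted values of a smooth input stay inside the data range
  set.seed(12)
  ysm <- 0.01 + 0.005 * sin(pos / 3e5)
  fit <- ed_loess_threshold(ysm, pos, cfg = cfg)
  expect_true(all(fit$fitted >= min(ysm) - 1e-6))
  expect_true(all(fit$fitted <= max(ysm) + 1e-6))

  # too few SNPs: tricube fallback with a warning
  expect_warning(fb <- ed_loess_threshold(rep(0.1, 5), (1:5) * 1e4, cfg = cfg),
                 "fewer than 10")
  expect_equal(fb$fitted, rep(0.1, 5))

  # per-chromosome threshold scope returns one value per chromosome
  cfg2 <- scan_config(ed_threshold_scope = "chromosome")
  two <- ed_loess_threshold(c(y, y * 2), c(pos, pos),
                            chrom = rep(c("a", "b"), each = length(pos)),
                            cfg = cfg2)
  expect_equal(length(two$threshold), 2)
})

test_that("the assembled track is internally consistent", {
  map <- build_marker_map(2, 3e6, 2e4, seed = 21)
  qtl <- full_penetrance_qtl("chr01", 1.5e6)
  snps <- simulate_snp_table(map, qtl, seed = 21)
  cfg <- scan_config(ci_reps = 1000, seed = 3)
  track <- compute_stat_track(snps, cfg)

  expect_s3_class(track, "stat_track")
  expect_equal(nrow(track), nrow(snps))
  expect_equal(track$delta, track$idxF - track$idxS, tolerance = 1e-12)
  expect_equal(track$ED, sqrt(2) * abs(track$delta), tolerance = 1e-12)
  expect_equal(track$ED5, track$ED^5, tolerance = 1e-12)
  expect_true(all(track$idxF >= 0 & track$idxF <= 1))
  expect_true(all(track$G >= 0))
  expect_true(all(track$q >= track$p - 1e-15, na.rm = TRUE))
  expect_true(all(track$ci99_lo <= track$ci95_lo + 1e-12))
  expect_true(all(track$ci99_hi >= track$ci95_hi - 1e-12))
  expect_length(attr(track, "ed_threshold"), 1)

  # swapping the bulks flips delta's sign, preserves G and ED5
  swapped <- snps
  names(swapped)[match(c("aF", "rF", "aS", "rS"), names(swapped))] <-
    c("aS", "rS", "aF", "rF")
  track2 <- compute_stat_track(swapped, cfg)
  expect_equal(track2$delta, -track$delta, tolerance = 1e-12)
  expect_equal(track2$G, track$G, tolerance = 1e-12)
  expect_equal(track2$ED5, track$ED5, tolerance = 1e-12)

  # TSV round trip preserves values and thresholds
  path <- tempfile(fileext = ".tsv")
  write_track(track, path)
  back <- read_track(path)
  expect_equal(back$delta_smooth, track$delta_smooth, tolerance = 1e-6)
  expect_equal(attr(back, "ed_threshold"), attr(track, "ed_threshold"),
               tolerance = 1e-9)
})
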