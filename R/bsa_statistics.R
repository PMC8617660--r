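# Genome-scan statistics on a screened SNP table: SNP-index / delta
# SNP-index with simulated confidence bands, the G statistic with tricube
# smoothing and an FDR-controlled log-normal null, and the fifth-power
# Euclidean distance with a Loess-derived threshold.

#' Genome-scan configuration
#'
#' Holds the tunable constants of the three scans. Defaults follow the
#' standard BSA-seq choices: a 1 Mb smoothing window, FDR 0.01 for the G'
#' scan, the fifth power for the Euclidean-distance scan, 95/99% simulated
#' confidence bands from 10,000 replicates with bulks of 30 under BC1
#' segregation, and per-chromosome Loess (degree 2, span 0.3) for the ED
#' threshold.
#'
#' @param window_bp full width of the tricube smoothing window, bp.
#' @param fdr_q false-discovery-rate threshold for the G' scan.
#' @param ed_exponent power applied to the Euclidean distance (>= 1).
#' @param ci_reps Monte-Carlo replicates per depth for the delta confidence
#'   bands (>= 100).
#' @param bulk_size plants per bulk in the null simulation.
#' @param pop_structure `"BC1"` (het vs hom-recurrent, 1:1) or `"F2"`
#'   (1:2:1).
#' @param ci_call_level band used for interval calling, 95 or 99.
#' @param loess_span,loess_degree per-chromosome Loess controls for the ED
#'   fit.
#' @param ed_threshold_scope `"genome"` (default) or `"chromosome"`: where
#'   the median + 3 SD threshold is computed.
#' @param ed_threshold_on `"fitted"` (default) or `"raw"` ED^k values.
#' @param hampel_k,mad_scale trimming and scale constants of the log-normal
#'   null fit for G'.
#' @param min_depth,max_depth bulk depth bounds used by screening.
#' @param seed integer seed for the confidence-band simulation.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(window_bp = 1e6, fdr_q = 0.01, ed_exponent = 5,
                        ci_reps = 10000, bulk_size = 30,
                        pop_structure = c("BC1", "F2"), ci_call_level = 99,
                        loess_span = 0.3, loess_degree = 2,
                        ed_threshold_scope = c("genome", "chromosome"),
                        ed_threshold_on = c("fitted", "raw"),
                        hampel_k = 5.2, mad_scale = 1.4826,
                        min_depth = 10, max_depth = 100, seed = NULL) {
  if (window_bp <= 0) stop2("window_bp must be > 0")
  if (fdr_q <= 0 || fdr_q >= 1) stop2("fdr_q must be in (0, 1)")
  if (ed_exponent < 1) stop2("ed_exponent must be >= 1")
  if (!is_count(bulk_size)) stop2("bulk_size must be a positive integer")
  if (!ci_call_level %in% c(95, 99)) stop2("ci_call_level must be 95 or 99")
  structure(list(
    window_bp = window_bp, fdr_q = fdr_q, ed_exponent = ed_exponent,
    ci_reps = ci_reps, bulk_size = as.integer(bulk_size),
    pop_structure = match.arg(pop_structure),
    ci_call_level = ci_call_level,
    loess_span = loess_span, loess_degree = loess_degree,
    ed_threshold_scope = match.arg(ed_threshold_scope),
    ed_threshold_on = match.arg(ed_threshold_on),
    hampel_k = hampel_k, mad_scale = mad_scale,
    min_depth = min_depth, max_depth = max_depth, seed = seed),
    class = "scan_config")
}

#' SNP-index and delta SNP-index
#'
#' The SNP-index of a bulk at a marker is the fraction of its reads carrying
#' the donor allele; the delta SNP-index is the fertile-bulk index minus the
#' sterile-bulk index. Near an unlinked locus the delta is ~0; at a locus
#' fully linked to the selected allele in a BC1 it approaches 0.5.
#'
#' @param donor_depth,other_depth donor- and other-allele read counts.
#' @return `snp_index`: fraction in `[0, 1]`.
#' @export
snp_index <- function(donor_depth, other_depth) {
  tot <- donor_depth + other_depth
  if (any(tot <= 0)) stop2("snp_index undefined at zero total depth")
  donor_depth / tot
}

#' @rdname snp_index
#' @param idxF,idxS SNP-index of the fertile and sterile bulk.
#' @return `delta_snp_index`: value in `[-1, 1]`.
#' @export
delta_snp_index <- function(idxF, idxS) {
  if (any(idxF < 0 | idxF > 1 | idxS < 0 | idxS > 1))
    stop2("SNP-index values must lie in [0, 1]")
  idxF - idxS
}

#' Tricube kernel smoothing along a chromosome
#'
#' Nadaraya-Watson weighted mean over all SNPs within half a window of the
#' focal SNP: for distance D <= window_bp/2 the weight is
#' `(1 - (2D/window_bp)^3)^3`, zero beyond. Chromosomes are smoothed
#' independently when `chrom` is given. NA values get zero weight; a focal
#' SNP whose window holds only NAs stays NA.
#'
#' @param values numeric track, one per SNP.
#' @param positions bp positions, sorted within chromosome.
#' @param window_bp full window width, bp.
#' @param chrom optional chromosome factor; NULL = single chromosome.
#' @return Smoothed numeric vector, same length as `values`.
#' @export
tricube_smooth <- function(values, positions, window_bp, chrom = NULL) {
  n <- length(values)
  stopifnot(length(positions) == n)
  if (n == 0L) return(numeric(0))
  if (is.null(chrom)) chrom <- rep("*", n)
  out <- rep(NA_real_, n)
  half <- window_bp / 2
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos <- positions[i]
    if (is.unsorted(pos)) stop2("positions must be sorted within chromosome")
    val <- values[i]
    lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + half, pos)
    sm <- numeric(length(i))
    for (j in seq_along(i)) {
      idx <- lo[j]:hi[j]
      d <- abs(pos[idx] - pos[j])
      w <- (1 - (d / half)^3)^3
      v <- val[idx]
      ok <- !is.na(v)
      sm[j] <- if (any(ok & w > 0)) sum(w[ok] * v[ok]) / sum(w[ok]) else NA_real_
    }
    out[i] <- sm
  }
  out
}

#' G statistic for a 2x2 table of bulk allele depths
#'
#' The likelihood-ratio statistic `G = 2 * sum(n_i * ln(n_i / e_i))` over the
#' four cells (donor/other x F-bulk/S-bulk), with expectations
#' `e_i = row_total * col_total / n` and the convention `0 * ln 0 = 0`. A
#' zero row or column total gives G = 0.
#'
#' @param aF,rF donor/other depths in the F-bulk.
#' @param aS,rS donor/other depths in the S-bulk.
#' @return Vector of G values (>= 0 up to rounding).
#' @export
g_statistic <- function(aF, rF, aS, rS) {
  if (any(c(aF, rF, aS, rS) < 0)) stop2("depths must be >= 0")
  o <- cbind(aF, rF, aS, rS)
  nF <- aF + rF; nS <- aS + rS
  na <- aF + aS; nr <- rF + rS
  n <- nF + nS
  if (any(n <= 0)) stop2("total depth must be > 0")
  e <- cbind(nF * na, nF * nr, nS * na, nS * nr) / n
  term <- o * log(o / e)
  term[o == 0] <- 0  # 0 * ln 0 = 0; also covers e = 0 cells
  g <- 2 * rowSums(term)
  g[nF == 0 | nS == 0 | na == 0 | nr == 0] <- 0
  pmax(unname(g), 0)
}

#' Smoothed G statistic (G')
#'
#' Tricube smoothing of per-SNP G values, see [tricube_smooth()].
#'
#' @param G per-SNP G values.
#' @inheritParams tricube_smooth
#' @return G' vector.
#' @export
gprime <- function(G, positions, window_bp, chrom = NULL)
  tricube_smooth(G, positions, window_bp, chrom)

#' P- and q-values for a G' scan
#'
#' The null distribution of G' is fitted as a log-normal: take `ln G'`, trim
#' probable signal by the Hampel rule (drop values above
#' `median + hampel_k * MAD`, raw MAD), then estimate the null mean as the
#' median and the null SD as `mad_scale * MAD` of the retained values.
#' P-values are upper-tail normal probabilities of `ln G'`; q-values are
#' Benjamini-Hochberg adjusted.
#'
#' @param Gprime_values G' vector (>= 0; zeros and NAs get p = 1 / NA).
#' @param fdr_q FDR threshold for the significance mask.
#' @param hampel_k,mad_scale trimming and MAD-to-SD constants.
#' @return List with `p`, `q`, `sig` (logical mask `q <= fdr_q`), and the
#'   fitted `mu`, `sigma`.
#' @export
gprime_pq <- function(Gprime_values, fdr_q = 0.01, hampel_k = 5.2,
                      mad_scale = 1.4826) {
  lng <- suppressWarnings(log(Gprime_values))
  usable <- is.finite(lng)
  fit <- lng[usable]
  med <- median(fit)
  raw_mad <- median(abs(fit - med))
  keep <- fit <= med + hampel_k * raw_mad
  mu <- median(fit[keep])
  sigma <- mad_scale * median(abs(fit[keep] - mu))
  n <- length(Gprime_values)
  p <- rep(NA_real_, n)
  if (!is.finite(sigma) || sigma <= 0) {
    warning("degenerate G' track (null SD = 0); all p-values set to 1")
    p[!is.na(Gprime_values)] <- 1
  } else {
    p[usable] <- pnorm((lng[usable] - mu) / sigma, lower.tail = FALSE)
    p[!usable & !is.na(Gprime_values)] <- 1  # G' = 0: certainly null
  }
  q <- p.adjust(p, method = "BH")
  list(p = p, q = q, sig = !is.na(q) & q <= fdr_q, mu = mu, sigma = sigma)
}

# Pooled donor-allele frequency of one simulated null bulk per replicate.
.null_bulk_freq <- function(reps, bulk_size, pop_structure) {
  if (pop_structure == "BC1") {
    0.5 * rbinom(reps, bulk_size, 0.5) / bulk_size
  } else {
    hom <- rbinom(reps, bulk_size, 0.25)
    het <- rbinom(reps, bulk_size - hom, 2 / 3)
    (2 * hom + het) / (2 * bulk_size)
  }
}

#' Simulated null confidence bands for the delta SNP-index
#'
#' Monte-Carlo null at a given read depth: each replicate draws the
#' genotypes of `bulk_size` plants per bulk under no-QTL segregation (BC1:
#' heterozygous with probability 1/2; F2: 1:2:1), forms the pooled
#' donor-allele frequency, draws binomial donor read counts at the given
#' depth for each bulk and takes the difference of the two read fractions.
#' The 95% and 99% bands are the empirical 2.5/97.5 and 0.5/99.5
#' percentiles. Results are memoized per depth within a session.
#'
#' @param depth total read depth (>= 1).
#' @param cfg a [scan_config()]; uses `ci_reps`, `bulk_size`,
#'   `pop_structure`, `seed`.
#' @return Named numeric: `ci95_lo`, `ci95_hi`, `ci99_lo`, `ci99_hi`.
#' @export
delta_ci <- function(depth, cfg = scan_config()) {
  if (!is_count(depth)) stop2("depth must be a positive integer")
  if (cfg$ci_reps < 100) stop2("ci_reps must be >= 100")
  # memoize only seeded configurations: unseeded calls draw from the
  # caller's RNG stream and must stay independent
  key <- if (is.null(cfg$seed)) NULL else
    paste(depth, cfg$ci_reps, cfg$bulk_size, cfg$pop_structure, cfg$seed,
          sep = "|")
  if (!is.null(key)) {
    hit <- .ci_cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  res <- with_seed(derive_seed(cfg$seed, depth), {
    fF <- .null_bulk_freq(cfg$ci_reps, cfg$bulk_size, cfg$pop_structure)
    fS <- .null_bulk_freq(cfg$ci_reps, cfg$bulk_size, cfg$pop_structure)
    delta <- rbinom(cfg$ci_reps, depth, fF) / depth -
      rbinom(cfg$ci_reps, depth, fS) / depth
    q <- quantile(delta, c(0.025, 0.975, 0.005, 0.995), names = FALSE)
    c(ci95_lo = q[1], ci95_hi = q[2], ci99_lo = q[3], ci99_hi = q[4])
  })
  if (!is.null(key)) .ci_cache[[key]] <- res
  res
}

.ci_cache <- new.env(parent = emptyenv())

#' Euclidean distance between bulk allele-frequency vectors
#'
#' For a biallelic SNP with donor-allele frequencies `idxF`, `idxS` in the
#' two bulks, `ED = sqrt((idxF-idxS)^2 + ((1-idxF)-(1-idxS))^2)`, i.e.
#' `sqrt(2) * |idxF - idxS|`. `ed_power` raises ED to the k-th power to
#' sharpen peaks before curve fitting.
#'
#' @param idxF,idxS SNP-index per bulk, in `[0, 1]`.
#' @return `euclidean_distance`: ED >= 0.
#' @export
euclidean_distance <- function(idxF, idxS) {
  if (any(idxF < 0 | idxF > 1 | idxS < 0 | idxS > 1))
    stop2("SNP-index values must lie in [0, 1]")
  sqrt(2) * abs(idxF - idxS)
}

#' @rdname euclidean_distance
#' @param ED Euclidean distances.
#' @param k exponent (default 5).
#' @return `ed_power`: ED^k.
#' @export
ed_power <- function(ED, k = 5) ED^k

#' Loess fit and significance threshold for the ED^k scan
#'
#' Fits ED^k against position per chromosome with local quadratic regression
#' (`stats::loess`, `surface = "direct"` for exact, deterministic fits) and
#' sets the threshold to `median(fitted) + 3 * SD(fitted)` where SD is the
#' population standard deviation; by default both are computed genome-wide
#' over the fitted values. Chromosomes with fewer than 10 usable SNPs (or
#' where Loess fails) fall back to tricube smoothing with `window_bp`, with
#' a warning. NA inputs are excluded from fitting and threshold computation
#' and remain NA in the output.
#'
#' @param ed5 ED^k values, one per SNP.
#' @param positions bp positions, sorted within chromosome.
#' @param chrom chromosome vector (NULL = single chromosome).
#' @param cfg a [scan_config()].
#' @return List with `fitted` (per-SNP values) and `threshold` (scalar for
#'   genome scope, named per-chromosome vector otherwise).
#' @export
ed_loess_threshold <- function(ed5, positions, chrom = NULL,
                               cfg = scan_config()) {
  n <- length(ed5)
  if (is.null(chrom)) chrom <- rep("*", n)
  fitted <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    ok <- i[!is.na(ed5[i])]
    if (length(ok) < 10) {
      warning("chromosome ", ch, ": fewer than 10 SNPs for Loess; ",
              "falling back to tricube smoothing")
      fitted[i] <- tricube_smooth(ed5[i], positions[i], cfg$window_bp)
      next
    }
    fit <- tryCatch(
      loess(y ~ x, data = data.frame(x = positions[ok], y = ed5[ok]),
            span = cfg$loess_span, degree = cfg$loess_degree,
            control = loess.control(surface = "direct")),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("chromosome ", ch, ": Loess failed; ",
              "falling back to tricube smoothing")
      fitted[i] <- tricube_smooth(ed5[i], positions[i], cfg$window_bp)
    } else {
      fitted[ok] <- fit$fitted
    }
  }
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  base <- if (cfg$ed_threshold_on == "fitted") fitted else ed5
  if (cfg$ed_threshold_scope == "genome") {
    v <- base[!is.na(base)]
    threshold <- median(v) + 3 * sd_pop(v)
  } else {
    threshold <- vapply(unique(chrom), function(ch) {
      v <- base[chrom == ch & !is.na(base)]
      median(v) + 3 * sd_pop(v)
    }, 0)
  }
  list(fitted = fitted, threshold = threshold)
}

#' Compute the full per-SNP genome-scan track
#'
#' Runs all three scans on a screened SNP table: SNP-indices and delta with
#' tricube-smoothed values and smoothed simulated confidence bands (the
#' per-SNP band depth is the smaller of the two bulk depths), G / G' with
#' log-normal-null p/q-values, and ED^k with its Loess fit and threshold.
#'
#' @param snps data frame with columns `chrom`, `pos`, `aF`, `rF`, `aS`,
#'   `rS` (from [screen_table()] or [read_snps()]).
#' @param cfg a [scan_config()].
#' @return A data frame of class `stat_track`, one row per SNP, with all
#'   statistic columns plus logical `sig_gprime`, `sig_delta`, `sig_ed`;
#'   attributes `ed_threshold`, `gprime_null` (mu, sigma) and `config`.
#' @export
compute_stat_track <- function(snps, cfg = scan_config()) {
  need <- c("chrom", "pos", "aF", "rF", "aS", "rS")
  if (!all(need %in% names(snps)))
    stop2("snps must have columns: ", paste(need, collapse = ", "))
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  n <- nrow(snps)
  if (n == 0L) stop2("empty SNP table")

  idxF <- snp_index(snps$aF, snps$rF)
  idxS <- snp_index(snps$aS, snps$rS)
  delta <- delta_snp_index(idxF, idxS)
  G <- g_statistic(snps$aF, snps$rF, snps$aS, snps$rS)
  ED <- euclidean_distance(idxF, idxS)
  ED5 <- ed_power(ED, cfg$ed_exponent)

  chrom <- snps$chrom
  pos <- snps$pos
  delta_smooth <- tricube_smooth(delta, pos, cfg$window_bp, chrom)
  Gp <- gprime(G, pos, cfg$window_bp, chrom)
  pq <- gprime_pq(Gp, cfg$fdr_q, cfg$hampel_k, cfg$mad_scale)

  depth <- pmin(snps$aF + snps$rF, snps$aS + snps$rS)
  ci <- t(vapply(unique(depth), function(d) delta_ci(d, cfg), numeric(4)))
  rownames(ci) <- unique(depth)
  ci <- ci[as.character(depth), , drop = FALSE]
  # smooth the bands alongside delta so band and curve are comparable
  ci_sm <- apply(ci, 2L, tricube_smooth, positions = pos,
                 window_bp = cfg$window_bp, chrom = chrom)

  edfit <- ed_loess_threshold(ED5, pos, chrom, cfg)
  ed_thr <- if (length(edfit$threshold) == 1L) {
    rep(edfit$threshold, n)
  } else {
    unname(edfit$threshold[chrom])
  }

  lo <- if (cfg$ci_call_level == 99) ci_sm[, "ci99_lo"] else ci_sm[, "ci95_lo"]
  hi <- if (cfg$ci_call_level == 99) ci_sm[, "ci99_hi"] else ci_sm[, "ci95_hi"]

  track <- data.frame(
    chrom = chrom, pos = pos,
    aF = snps$aF, rF = snps$rF, aS = snps$aS, rS = snps$rS,
    idxF = idxF, idxS = idxS, delta = delta, delta_smooth = delta_smooth,
    ci95_lo = ci_sm[, "ci95_lo"], ci95_hi = ci_sm[, "ci95_hi"],
    ci99_lo = ci_sm[, "ci99_lo"], ci99_hi = ci_sm[, "ci99_hi"],
    G = G, Gprime = Gp, p = pq$p, q = pq$q,
    ED = ED, ED5 = ED5, ed_fit = edfit$fitted,
    sig_gprime = pq$sig,
    sig_delta = !is.na(delta_smooth) & (delta_smooth < lo | delta_smooth > hi),
    sig_ed = !is.na(edfit$fitted) & edfit$fitted >= ed_thr,
    row.names = NULL)
  attr(track, "ed_threshold") <- edfit$threshold
  attr(track, "gprime_null") <- c(mu = pq$mu, sigma = pq$sigma)
  attr(track, "config") <- cfg
  class(track) <- c("stat_track", "data.frame")
  track
}

#' Write / read a stat track as TSV (thresholds in a JSON sidecar)
#' @param track a `stat_track`.
#' @param path TSV path; thresholds go to `<path>.thresholds.json`.
#' @export
write_track <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  thr <- attr(track, "ed_threshold")
  null <- attr(track, "gprime_null")
  cfg <- attr(track, "config")
  jsonlite::write_json(
    list(ed_threshold = thr, gprime_null = as.list(null),
         fdr_q = cfg$fdr_q, ci_call_level = cfg$ci_call_level,
         window_bp = cfg$window_bp, ed_exponent = cfg$ed_exponent),
    paste0(path, ".thresholds.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  track <- read.delim(path, colClasses = c(chrom = "character"))
  sidecar <- paste0(path, ".thresholds.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(track, "ed_threshold") <- meta$ed_threshold
    attr(track, "gprime_null") <- unlist(meta$gprime_null)
  }
  class(track) <- c("stat_track", "data.frame")
  track
}
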