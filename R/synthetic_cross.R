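# BC1 bulked-segregant simulator: marker maps, backcross populations,
# phenotype-selected bulks, pooled read counts, and VCF emission.

#' Build a synthetic marker map
#'
#' Places biallelic SNP markers at jittered regular spacing along one or more
#' chromosomes and assigns each marker REF/ALT bases plus the identity of the
#' donor-parent allele.
#'
#' Markers sit near the grid `spacing/2, 3*spacing/2, ...` with uniform jitter
#' of at most a quarter spacing, so positions are strictly increasing by
#' construction. If `marker_spacing_bp > chrom_len_bp` a single marker is
#' emitted at the chromosome midpoint.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_len_bp chromosome length in bp; scalar or vector of length
#'   `n_chrom`.
#' @param marker_spacing_bp mean distance between adjacent markers, bp.
#' @param seed integer seed; the same seed reproduces the same map.
#' @return An object of class `marker_map`: a list with `chrom_lengths`
#'   (named numeric), and per-chromosome lists `markers` (sorted 1-based
#'   positions), `ref`, `alt` (single bases), and `donor_allele`
#'   (`"REF"` or `"ALT"`, the allele carried homozygously by the donor
#'   parent).
#' @export
build_marker_map <- function(n_chrom, chrom_len_bp, marker_spacing_bp,
                             seed = NULL) {
  if (!is_count(n_chrom)) stop2("n_chrom must be a positive integer")
  if (!is_count(marker_spacing_bp)) stop2("marker_spacing_bp must be >= 1")
  len <- rep_len(as.numeric(chrom_len_bp), n_chrom)
  if (any(!is.finite(len)) || any(len < 1))
    stop2("chromosome length must be >= 1 bp")
  chroms <- sprintf("chr%02d", seq_len(n_chrom))
  names(len) <- chroms

  with_seed(seed, {
    markers <- ref <- alt <- donor <- vector("list", n_chrom)
    names(markers) <- names(ref) <- names(alt) <- names(donor) <- chroms
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n_chrom)) {
      s <- marker_spacing_bp
      if (s > len[i]) {
        pos <- max(1, floor(len[i] / 2))
      } else {
        k <- floor(len[i] / s)
        grid <- (seq_len(k) - 0.5) * s
        pos <- round(grid + runif(k, -0.25, 0.25) * s)
        pos <- pmin(pmax(pos, 1), len[i])
      }
      m <- length(pos)
      r <- sample(bases, m, replace = TRUE)
      a <- vapply(r, function(b) sample(setdiff(bases, b), 1L), "")
      markers[[i]] <- as.integer(pos)
      ref[[i]] <- r
      alt[[i]] <- unname(a)
      donor[[i]] <- sample(c("REF", "ALT"), m, replace = TRUE)
    }
    structure(
      list(chrom_lengths = len, markers = markers, ref = ref, alt = alt,
           donor_allele = donor),
      class = "marker_map")
  })
}

#' @export
print.marker_map <- function(x, ...) {
  cat("marker_map:", length(x$chrom_lengths), "chromosome(s),",
      sum(lengths(x$markers)), "markers\n")
  invisible(x)
}

n_markers <- function(map) sum(lengths(map$markers))

#' Define the restorer QTL and its penetrance model
#'
#' The restorer allele is dominant; penetrance is quantitative and is modeled
#' as a categorical distribution over fertility grades 0 (sterile) to 4
#' (fully fertile), one distribution per genotype class. The defaults give
#' carriers mostly grades 3-4 and non-carriers mostly grades 0-1, with a
#' small overlap emulating misclassification in field scoring.
#'
#' @param chrom chromosome name (must exist in the map used downstream).
#' @param pos_bp 1-based position of the causal locus.
#' @param grade_dist_carrier probability vector over grades 0-4 for
#'   heterozygous restorer carriers.
#' @param grade_dist_noncarrier probability vector over grades 0-4 for
#'   homozygous-recurrent plants.
#' @return An object of class `restorer_qtl`.
#' @export
restorer_qtl <- function(chrom, pos_bp,
                         grade_dist_carrier = c(0.02, 0.08, 0.20, 0.35, 0.35),
                         grade_dist_noncarrier = c(0.60, 0.30, 0.08, 0.02, 0)) {
  for (p in list(grade_dist_carrier, grade_dist_noncarrier)) {
    if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop2("grade distributions must be length-5 probability vectors summing to 1")
  }
  if (!is_count(pos_bp)) stop2("pos_bp must be a positive integer")
  structure(
    list(chrom = as.character(chrom), pos_bp = as.integer(pos_bp),
         grade_dist_carrier = grade_dist_carrier,
         grade_dist_noncarrier = grade_dist_noncarrier),
    class = "restorer_qtl")
}

# Haldane: recombination fraction from map distance d (Morgans).
haldane_r <- function(d) 0.5 * (1 - exp(-2 * d))

#' Simulate a BC1 population
#'
#' Each individual's gametic genotype along a chromosome is a two-state
#' Markov walk over the marker positions: at every locus the plant is either
#' heterozygous (carries the donor allele, state 1) or homozygous recurrent
#' (state 0), and switches state between adjacent loci with the Haldane
#' recombination fraction for the interval. The causal locus is walked as a
#' pseudo-marker so linkage between it and flanking markers is exact.
#' Fertility grades are drawn from the genotype class's grade distribution.
#'
#' @param map a `marker_map`.
#' @param qtl a `restorer_qtl`; its chromosome must exist in `map`.
#' @param n population size.
#' @param recomb_rate genetic map density in Morgans per bp
#'   (default 4e-8 = 4 cM/Mb).
#' @param seed integer seed.
#' @return An object of class `bc1_pop`: `genotype` is a per-chromosome list
#'   of n x m integer matrices (1 = heterozygous carrier, 0 = homozygous
#'   recurrent), `qtl_genotype` the length-n state at the causal locus,
#'   `grade` the length-n integer fertility grades.
#' @export
simulate_bc1 <- function(map, qtl, n, recomb_rate = 4e-8, seed = NULL) {
  stopifnot(inherits(map, "marker_map"), inherits(qtl, "restorer_qtl"))
  if (!is_count(n)) stop2("n must be a positive integer")
  if (!(qtl$chrom %in% names(map$chrom_lengths)))
    stop2("QTL chromosome '", qtl$chrom, "' not present in the marker map")
  if (recomb_rate < 0) stop2("recomb_rate must be >= 0")

  with_seed(seed, {
    geno <- vector("list", length(map$markers))
    names(geno) <- names(map$markers)
    qtl_geno <- NULL
    for (ch in names(map$markers)) {
      pos <- map$markers[[ch]]
      qtl_here <- identical(ch, qtl$chrom)
      walk_pos <- pos
      if (qtl_here) {
        walk_pos <- sort(unique(c(pos, qtl$pos_bp)))
        qtl_idx <- match(qtl$pos_bp, walk_pos)
      }
      m <- length(walk_pos)
      g <- matrix(0L, nrow = n, ncol = m)
      g[, 1L] <- rbinom(n, 1L, 0.5)
      if (m > 1L) {
        r <- haldane_r(recomb_rate * diff(walk_pos))
        # crossover indicators per interval; state = initial XOR parity
        x <- matrix(rbinom(n * (m - 1L), 1L, rep(r, each = n)), nrow = n)
        if (ncol(x) > 1L)
          for (j in 2:ncol(x)) x[, j] <- x[, j - 1L] + x[, j]
        g[, -1L] <- (g[, 1L] + x) %% 2L
      }
      if (qtl_here) {
        qtl_geno <- g[, qtl_idx]
        keep <- match(pos, walk_pos)
        g <- g[, keep, drop = FALSE]
      }
      geno[[ch]] <- g
    }
    grade <- integer(n)
    carrier <- qtl_geno == 1L
    if (any(carrier))
      grade[carrier] <- sample(0:4, sum(carrier), replace = TRUE,
                               prob = qtl$grade_dist_carrier)
    if (any(!carrier))
      grade[!carrier] <- sample(0:4, sum(!carrier), replace = TRUE,
                                prob = qtl$grade_dist_noncarrier)
    structure(list(genotype = geno, qtl_genotype = qtl_geno, grade = grade,
                   n = as.integer(n)),
              class = "bc1_pop")
  })
}

#' @export
print.bc1_pop <- function(x, ...) {
  cat("bc1_pop:", x$n, "individuals,",
      sum(vapply(x$genotype, ncol, 1L)), "markers; carrier fraction",
      round(mean(x$qtl_genotype), 3), "\n")
  invisible(x)
}

#' Select phenotypic-extreme bulks
#'
#' Samples `bulk_size` members uniformly without replacement from the
#' fertile-grade class (F-bulk) and the sterile-grade class (S-bulk). The
#' pooled donor-allele frequency at each marker is `0.5 * (fraction of
#' heterozygous members)`, since every BC1 plant contributes either 0 or 0.5.
#'
#' @param pop a `bc1_pop`.
#' @param bulk_size plants per bulk (default 30).
#' @param f_grades,s_grades fertility grades eligible for the fertile and
#'   sterile bulk (defaults 3-4 and 0-1).
#' @param seed integer seed.
#' @return A list with elements `F` and `S`, each of class `bulk`: `label`,
#'   `members` (individual indices), and `donor_freq` (per-chromosome list of
#'   pooled donor-allele frequencies).
#' @export
select_bulks <- function(pop, bulk_size = 30, f_grades = c(3, 4),
                         s_grades = c(0, 1), seed = NULL) {
  stopifnot(inherits(pop, "bc1_pop"))
  if (!is_count(bulk_size)) stop2("bulk_size must be a positive integer")
  elig_f <- which(pop$grade %in% f_grades)
  elig_s <- which(pop$grade %in% s_grades)
  for (side in list(list("F", elig_f, f_grades), list("S", elig_s, s_grades))) {
    if (length(side[[2]]) < bulk_size)
      stop2(sprintf(
        "%s-bulk needs %d plants with grade in {%s} but only %d are available (short by %d)",
        side[[1]], bulk_size, paste(side[[3]], collapse = ","),
        length(side[[2]]), bulk_size - length(side[[2]])))
  }
  with_seed(seed, {
    mk_bulk <- function(label, elig) {
      members <- sort(sample(elig, bulk_size))
      freq <- lapply(pop$genotype, function(g)
        colMeans(g[members, , drop = FALSE]) * 0.5)
      structure(list(label = label, members = members, donor_freq = freq,
                     bulk_size = as.integer(bulk_size)),
                class = "bulk")
    }
    list(F = mk_bulk("F", elig_f), S = mk_bulk("S", elig_s))
  })
}

#' Simulate pooled sequencing reads for a bulk
#'
#' Per marker the total depth is discrete uniform on
#' `[depth_low, depth_high]` and the donor-allele read count is binomial with
#' success probability `f*(1-e) + (1-f)*e`, where `f` is the pooled donor
#' frequency and `e` the per-read miscall probability.
#'
#' @param bulk a `bulk`.
#' @param depth_low,depth_high inclusive depth range (defaults 10 and 100).
#' @param error_rate per-read miscall probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @return Per-chromosome list of data frames with columns `donor_depth`,
#'   `other_depth`.
#' @export
simulate_bulk_reads <- function(bulk, depth_low = 10, depth_high = 100,
                                error_rate = 0.001, seed = NULL) {
  stopifnot(inherits(bulk, "bulk"))
  if (!(error_rate >= 0 && error_rate < 0.5))
    stop2("error_rate must be in [0, 0.5)")
  if (!is_count(depth_low) || !is_count(depth_high) || depth_low > depth_high)
    stop2("need 1 <= depth_low <= depth_high")
  with_seed(seed, {
    lapply(bulk$donor_freq, function(f) {
      m <- length(f)
      depth <- depth_low +
        if (depth_high > depth_low) sample.int(depth_high - depth_low + 1L, m,
                                               replace = TRUE) - 1L else 0L
      p <- f * (1 - error_rate) + (1 - f) * error_rate
      donor <- rbinom(m, depth, p)
      data.frame(donor_depth = donor, other_depth = depth - donor)
    })
  })
}

# --- VCF emission -----------------------------------------------------------

# INFO annotations drawn from clearly passing ranges; a contaminant site gets
# exactly one randomly chosen clause pushed past its default threshold.
.passing_info <- function(m) {
  data.frame(
    QUAL = runif(m, 60, 900),
    FS = runif(m, 0, 10), MQ = runif(m, 40, 60), QD = runif(m, 15, 35),
    MQRankSum = runif(m, -2, 2), ReadPosRankSum = runif(m, -2, 2))
}

.contaminate <- function(info, idx) {
  fields <- c("QUAL", "QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
  pick <- sample(fields, length(idx), replace = TRUE)
  lo <- c(QUAL = 1, QD = 0.5, FS = 20.5, MQ = 2, MQRankSum = -8,
          ReadPosRankSum = -8)
  hi <- c(QUAL = 29, QD = 12.5, FS = 60, MQ = 19, MQRankSum = -3.1,
          ReadPosRankSum = -3.1)
  for (f in fields) {
    j <- idx[pick == f]
    if (length(j)) info[[f]][j] <- runif(length(j), lo[[f]], hi[[f]])
  }
  info
}

#' Write a simulated 4-sample VCF and its ground-truth sidecar
#'
#' Emits a plain-text VCF 4.2 with samples donor parent, recurrent parent,
#' F-bulk and S-bulk (FORMAT `GT:AD:DP`). Parents are homozygous for opposite
#' alleles with fixed depth 30. Bulk genotypes are called from the observed
#' donor-read fraction: below 0.15 homozygous recurrent, above 0.85
#' homozygous donor, otherwise heterozygous (a simulator convention recorded
#' in the header so downstream genotype-based screening is exercisable).
#' Site QUAL and INFO annotations (FS, MQ, QD, MQRankSum, ReadPosRankSum) are
#' drawn from passing ranges; a `contaminant_fraction` of sites instead gets
#' one randomly chosen annotation pushed past its hard-filter threshold.
#'
#' A TSV sidecar (`<path>.truth.tsv`) records the seed, causal-locus
#' location, penetrance model, depth model and bulk membership. With a fixed
#' seed the VCF is byte-identical across runs except for the `##fileDate`
#' header line.
#'
#' @param map a `marker_map`.
#' @param counts_f,counts_s per-chromosome read counts from
#'   [simulate_bulk_reads()] for the F- and S-bulk.
#' @param truth a list describing the run (see [sim_truth()]).
#' @param path output VCF path.
#' @param sample_names the four sample names, in order donor parent,
#'   recurrent parent, F-bulk, S-bulk.
#' @param contaminant_fraction fraction of sites given one failing
#'   annotation.
#' @param seed integer seed for annotation draws.
#' @return Invisibly, a list with the VCF `path` and the `truth_path`.
#' @export
emit_vcf <- function(map, counts_f, counts_s, truth, path,
                     sample_names = c("P596", "P1318", "F_bulk", "S_bulk"),
                     contaminant_fraction = 0, seed = NULL) {
  stopifnot(inherits(map, "marker_map"), length(sample_names) == 4L)
  if (!identical(names(counts_f), names(map$markers)) ||
      !identical(names(counts_s), names(map$markers)))
    stop2("count tables and marker map cover different chromosomes")
  if (contaminant_fraction < 0 || contaminant_fraction > 1)
    stop2("contaminant_fraction must be in [0, 1]")

  body <- with_seed(seed, {
    rows <- character(0)
    for (ch in names(map$markers)) {
      pos <- map$markers[[ch]]
      m <- length(pos)
      if (!(nrow(counts_f[[ch]]) == m && nrow(counts_s[[ch]]) == m))
        stop2("count tables and marker map disagree on marker count for ", ch)
      info <- .passing_info(m)
      if (contaminant_fraction > 0) {
        bad <- which(runif(m) < contaminant_fraction)
        if (length(bad)) info <- .contaminate(info, bad)
      }
      donor_is_alt <- map$donor_allele[[ch]] == "ALT"
      gt_donor <- ifelse(donor_is_alt, "1/1", "0/0")
      gt_recur <- ifelse(donor_is_alt, "0/0", "1/1")
      # parents: fixed depth 30, all reads on their own allele
      par_ad <- function(gt) ifelse(gt == "1/1", "0,30", "30,0")
      bulk_field <- function(cnt) {
        dp <- cnt$donor_depth + cnt$other_depth
        frac <- ifelse(dp > 0, cnt$donor_depth / dp, NA_real_)
        gt_ds <- ifelse(is.na(frac), "./.",
                 ifelse(frac < 0.15, "REC", ifelse(frac > 0.85, "DON", "HET")))
        gt <- ifelse(gt_ds == "./.", "./.",
              ifelse(gt_ds == "HET", "0/1",
              ifelse((gt_ds == "DON") == donor_is_alt, "1/1", "0/0")))
        ref_d <- ifelse(donor_is_alt, cnt$other_depth, cnt$donor_depth)
        alt_d <- ifelse(donor_is_alt, cnt$donor_depth, cnt$other_depth)
        sprintf("%s:%d,%d:%d", gt, ref_d, alt_d, dp)
      }
      info_str <- sprintf(
        "FS=%.2f;MQ=%.2f;QD=%.2f;MQRankSum=%.2f;ReadPosRankSum=%.2f",
        info$FS, info$MQ, info$QD, info$MQRankSum, info$ReadPosRankSum)
      rows <- c(rows, sprintf(
        "%s\t%d\t.\t%s\t%s\t%.1f\tPASS\t%s\tGT:AD:DP\t%s:%s:30\t%s:%s:30\t%s\t%s",
        ch, pos, map$ref[[ch]], map$alt[[ch]], info$QUAL, info_str,
        gt_donor, par_ad(gt_donor), gt_recur, par_ad(gt_recur),
        bulk_field(counts_f[[ch]]), bulk_field(counts_s[[ch]])))
    }
    rows
  })

  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##fileDate=", format(Sys.Date(), "%Y%m%d")),
    "##source=bsaqtl-simulator",
    "##bulkGTconvention=donor-read fraction <0.15 hom-recurrent, >0.85 hom-donor, else het",
    sprintf("##contig=<ID=%s,length=%d>", names(map$chrom_lengths),
            as.integer(map$chrom_lengths)),
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
  writeLines(c(header, body), path)

  truth_path <- paste0(path, ".truth.tsv")
  write_truth(truth, truth_path)
  invisible(list(path = path, truth_path = truth_path))
}

#' Assemble the ground truth of a simulated run
#'
#' @param qtl a `restorer_qtl`.
#' @param seed the master seed of the run.
#' @param bulks the list returned by [select_bulks()].
#' @param depth_low,depth_high,error_rate the read model parameters.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(qtl, seed, bulks, depth_low = 10, depth_high = 100,
                      error_rate = 0.001) {
  structure(list(
    qtl_chrom = qtl$chrom, qtl_pos = qtl$pos_bp,
    grade_dist_carrier = qtl$grade_dist_carrier,
    grade_dist_noncarrier = qtl$grade_dist_noncarrier,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    f_members = bulks$F$members, s_members = bulks$S$members,
    depth_model = sprintf("uniform[%d,%d]", as.integer(depth_low),
                          as.integer(depth_high)),
    error_rate = error_rate), class = "sim_truth")
}

write_truth <- function(truth, path) {
  kv <- data.frame(
    key = c("seed", "qtl_chrom", "qtl_pos", "grade_dist_carrier",
            "grade_dist_noncarrier", "depth_model", "error_rate",
            "f_members", "s_members"),
    value = c(truth$seed, truth$qtl_chrom, truth$qtl_pos,
              paste(truth$grade_dist_carrier, collapse = ","),
              paste(truth$grade_dist_noncarrier, collapse = ","),
              truth$depth_model, truth$error_rate,
              paste(truth$f_members, collapse = ","),
              paste(truth$s_members, collapse = ",")))
  write.table(kv, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a ground-truth sidecar written by [emit_vcf()]
#' @param path path to a `.truth.tsv` file.
#' @return A list of class `sim_truth`.
#' @export
read_truth <- function(path) {
  kv <- read.delim(path, colClasses = "character")
  get <- function(k) kv$value[match(k, kv$key)]
  structure(list(
    qtl_chrom = get("qtl_chrom"), qtl_pos = as.integer(get("qtl_pos")),
    grade_dist_carrier = as.numeric(strsplit(get("grade_dist_carrier"), ",")[[1]]),
    grade_dist_noncarrier = as.numeric(strsplit(get("grade_dist_noncarrier"), ",")[[1]]),
    seed = as.integer(get("seed")),
    f_members = as.integer(strsplit(get("f_members"), ",")[[1]]),
    s_members = as.integer(strsplit(get("s_members"), ",")[[1]]),
    depth_model = get("depth_model"),
    error_rate = as.numeric(get("error_rate"))), class = "sim_truth")
}

#' Run the whole simulator: map, population, bulks, reads, VCF
#'
#' Convenience wrapper chaining [build_marker_map()], [simulate_bc1()],
#' [select_bulks()], [simulate_bulk_reads()] and [emit_vcf()] under one
#' master seed (stage seeds are fixed offsets of it).
#'
#' @param config a run configuration, see [default_config()]; the `sim`
#'   section holds all simulator parameters.
#' @param vcf_path output VCF path.
#' @param seed master seed; overrides `config$seed` when non-NULL.
#' @return Invisibly, list with `path`, `truth_path`, and the `map`, `pop`,
#'   `bulks` objects.
#' @export
simulate_dataset <- function(config = default_config(), vcf_path,
                             seed = NULL) {
  cfg <- config$sim
  seed <- seed %||% config$seed
  map <- build_marker_map(cfg$n_chrom, cfg$chrom_len_bp, cfg$marker_spacing_bp,
                          seed = derive_seed(seed, 101))
  qtl <- restorer_qtl(cfg$qtl_chrom %||% names(map$chrom_lengths)[1],
                      cfg$qtl_pos %||% floor(map$chrom_lengths[[1]] / 2),
                      cfg$grade_dist_carrier,
                      cfg$grade_dist_noncarrier)
  pop <- simulate_bc1(map, qtl, cfg$pop_size, cfg$recomb_rate,
                      seed = derive_seed(seed, 202))
  bulks <- select_bulks(pop, cfg$bulk_size, cfg$f_grades, cfg$s_grades,
                        seed = derive_seed(seed, 303))
  cf <- simulate_bulk_reads(bulks$F, cfg$depth_low, cfg$depth_high,
                            cfg$error_rate, seed = derive_seed(seed, 404))
  cs <- simulate_bulk_reads(bulks$S, cfg$depth_low, cfg$depth_high,
                            cfg$error_rate, seed = derive_seed(seed, 505))
  truth <- sim_truth(qtl, seed, bulks, cfg$depth_low, cfg$depth_high,
                     cfg$error_rate)
  out <- emit_vcf(map, cf, cs, truth, vcf_path,
                  contaminant_fraction = cfg$contaminant_fraction,
                  seed = derive_seed(seed, 606))
  invisible(c(out, list(map = map, pop = pop, bulks = bulks)))
}
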