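# Windowed population-genetic summary statistics.
#
# All window FST values are ratio-of-sums: per-site numerator and
# denominator components are accumulated over the SNPs of a window and
# divided once, which is less biased than averaging per-site ratios and
# makes the genome-wide value invariant to how sites are windowed.

#' Tile contigs into non-overlapping windows
#'
#' Windows are `[1, size]`, `[size + 1, 2 size]`, ... per contig, the
#' final window truncated at the contig end. Coordinates are 1-based
#' inclusive throughout.
#'
#' @param contig_lengths named integer vector of contig lengths (bp).
#' @param size window size in bp (default 10 kb).
#' @return data.frame with columns `contig`, `start`, `end`.
#' @export
make_windows <- function(contig_lengths, size = 10000L) {
  if (size < 1) stop("window size must be >= 1")
  stopifnot(all(contig_lengths >= 1), !is.null(names(contig_lengths)))
  out <- lapply(names(contig_lengths), function(ct) {
    len <- as.integer(contig_lengths[[ct]])
    starts <- seq.int(1L, len, by = as.integer(size))
    data.frame(contig = ct, start = starts,
               end = pmin(starts + as.integer(size) - 1L, len))
  })
  do.call(rbind, out)
}

# window index (row of `windows`) for each site; NA when outside
window_index <- function(sites, windows) {
  size <- max(windows$end - windows$start + 1L)
  wkey <- paste(windows$contig, (windows$start - 1L) %/% size)
  skey <- paste(sites$contig, (sites$pos - 1L) %/% size)
  match(skey, wkey)
}

#' Per-site nucleotide diversity
#'
#' Mean pairwise difference among the `n` sampled allele copies at a
#' biallelic site with `j` ALT alleles: `2 j (n - j) / (n (n - 1))`.
#'
#' @param j ALT allele count(s).
#' @param n total non-missing allele count(s), `n >= 2`.
#' @return numeric vector of per-site pi; `NA` where `n < 2`.
#' @export
site_pi <- function(j, n) {
  stopifnot(all(j >= 0 & j <= n, na.rm = TRUE))
  ifelse(n >= 2, 2 * j * (n - j) / (n * (n - 1)), NA_real_)
}

#' Windowed nucleotide diversity per bp
#'
#' Sum of [site_pi()] over the SNPs of each window divided by the window
#' span in bp; windows with no SNPs report 0. Sites with fewer than two
#' non-missing alleles are skipped (and counted).
#'
#' @param gm a [genotype_matrix()].
#' @param windows from [make_windows()].
#' @return `windows` with columns `n_snps`, `pi_sum` and `pi_bp` added.
#' @export
windowed_pi <- function(gm, windows) {
  fr <- site_freq(gm)
  j <- fr$p * fr$n
  pi <- site_pi(j, fr$n)
  wi <- window_index(gm$sites, windows)
  ok <- !is.na(pi) & !is.na(wi)
  windows$n_snps <- as.integer(tabulate(wi[ok], nbins = nrow(windows)))
  ps <- rep(0, nrow(windows))
  agg <- rowsum(pi[ok], wi[ok])
  ps[as.integer(rownames(agg))] <- agg[, 1]
  windows$pi_sum <- ps
  windows$pi_bp <- ps / (windows$end - windows$start + 1)
  windows
}

# per-population per-site genotype summaries: diploid sample count,
# ALT frequency and observed heterozygote frequency
pop_site_stats <- function(gm, sample_idx) {
  d <- gm$dosage[, sample_idx, drop = FALSE]
  n_ind <- rowSums(!is.na(d))
  p <- ifelse(n_ind > 0, rowSums(d, na.rm = TRUE) / (2 * n_ind), NA_real_)
  h <- ifelse(n_ind > 0, rowSums(d == 1L, na.rm = TRUE) / n_ind, NA_real_)
  list(n_ind = n_ind, p = p, h = h)
}

#' Hudson FST components at a site
#'
#' Moment estimator: `numerator = (p1 - p2)^2 - p1 (1 - p1) / (n1 - 1)
#' - p2 (1 - p2) / (n2 - 1)` and `denominator = p1 (1 - p2) +
#' p2 (1 - p1)`, with `n1`, `n2` haploid-equivalent allele counts. The
#' numerator may legitimately be negative; sites with `n <= 1` are
#' returned as `NA` (skipped downstream).
#'
#' @param p1,p2 ALT allele frequencies (vectorized).
#' @param n1,n2 non-missing allele counts.
#' @return list with `num` and `den` numeric vectors.
#' @export
hudson_fst_site <- function(p1, n1, p2, n2) {
  ok <- !is.na(p1) & !is.na(p2) & n1 > 1 & n2 > 1
  num <- den <- rep(NA_real_, length(p1))
  num[ok] <- (p1[ok] - p2[ok])^2 -
    p1[ok] * (1 - p1[ok]) / (n1[ok] - 1) -
    p2[ok] * (1 - p2[ok]) / (n2[ok] - 1)
  den[ok] <- p1[ok] * (1 - p2[ok]) + p2[ok] * (1 - p1[ok])
  list(num = num, den = den)
}

#' Weir-Cockerham FST variance components at a site (two populations)
#'
#' Computes the among-population component `a` and the total
#' `a + b + c` of Weir & Cockerham (1984) from per-population diploid
#' sample sizes, ALT frequencies and observed heterozygote frequencies.
#' `numerator = a`, `denominator = a + b + c`. Sites monomorphic across
#' both populations have a zero denominator and are skipped downstream.
#'
#' @param n1,n2 diploid sample counts with non-missing genotypes.
#' @param p1,p2 ALT allele frequencies.
#' @param h1,h2 observed heterozygote frequencies.
#' @return list with `num` and `den` numeric vectors.
#' @export
wc_fst_site <- function(n1, p1, h1, n2, p2, h2) {
  ok <- !is.na(p1) & !is.na(p2) & n1 >= 1 & n2 >= 1
  num <- den <- rep(NA_real_, length(p1))
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  # nbar == 1 (single sample in each pop) leaves a/b undefined
  ok <- ok & nbar > 1 & nc > 0
  num[ok] <- a[ok]
  den[ok] <- (a + b + cc)[ok]
  list(num = num, den = den)
}

# per-site FST components for a pair of sample index sets
pair_fst_components <- function(gm, idx1, idx2, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  s1 <- pop_site_stats(gm, idx1)
  s2 <- pop_site_stats(gm, idx2)
  if (estimator == "hudson")
    hudson_fst_site(s1$p, 2 * s1$n_ind, s2$p, 2 * s2$n_ind)
  else
    wc_fst_site(s1$n_ind, s1$p, s1$h, s2$n_ind, s2$p, s2$h)
}

pop_sample_idx <- function(gm, popmap, pop) {
  which(gm$samples %in% popmap$sample[popmap$region == pop |
                                        popmap$district == pop])
}

#' Windowed pairwise FST (ratio of sums)
#'
#' @param gm a [genotype_matrix()].
#' @param popmap data.frame as read by [read_popmap()]; `pair` entries
#'   are matched against region (or district) labels.
#' @param pair character vector of two population labels.
#' @param windows from [make_windows()].
#' @param estimator `"wc"` (Weir-Cockerham, default) or `"hudson"`.
#' @param min_snps windows with fewer usable SNPs are reported `NA` and
#'   excluded downstream.
#' @return `windows` with `n_snps`, `num`, `den` and `fst` columns.
#' @export
windowed_fst <- function(gm, popmap, pair, windows,
                         estimator = c("wc", "hudson"), min_snps = 3L) {
  estimator <- match.arg(estimator)
  idx1 <- pop_sample_idx(gm, popmap, pair[1])
  idx2 <- pop_sample_idx(gm, popmap, pair[2])
  if (!length(idx1) || !length(idx2))
    stop("empty population in pair: ", paste(pair, collapse = ":"))
  comp <- pair_fst_components(gm, idx1, idx2, estimator)
  wi <- window_index(gm$sites, windows)
  ok <- !is.na(comp$num) & !is.na(wi)
  nw <- nrow(windows)
  acc <- function(x) {
    out <- rep(0, nw)
    if (any(ok)) {
      agg <- rowsum(x[ok], wi[ok])
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  }
  windows$n_snps <- as.integer(tabulate(wi[ok], nbins = nw))
  windows$num <- acc(comp$num)
  windows$den <- acc(comp$den)
  windows$fst <- ifelse(windows$n_snps >= min_snps & windows$den > 0,
                        windows$num / windows$den, NA_real_)
  windows
}

#' Genome-wide mean pairwise FST (ratio of sums over all SNPs)
#'
#' @inheritParams windowed_fst
#' @param clamp_zero floor the estimate at 0 (off by default; estimator
#'   bias can make undifferentiated pairs slightly negative).
#' @return a single numeric value.
#' @export
mean_fst <- function(gm, popmap, pair, estimator = c("wc", "hudson"),
                     clamp_zero = FALSE) {
  estimator <- match.arg(estimator)
  idx1 <- pop_sample_idx(gm, popmap, pair[1])
  idx2 <- pop_sample_idx(gm, popmap, pair[2])
  if (!length(idx1) || !length(idx2))
    stop("empty population in pair: ", paste(pair, collapse = ":"))
  comp <- pair_fst_components(gm, idx1, idx2, estimator)
  ok <- !is.na(comp$num) & !is.na(comp$den)
  val <- sum(comp$num[ok]) / sum(comp$den[ok])
  if (clamp_zero) max(0, val) else val
}

#' Basic dataset summary
#'
#' Number of polymorphic sites, mean windowed nucleotide diversity per
#' 10 kb and mean pairwise FST for every pair of regions.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap population map.
#' @param windows from [make_windows()].
#' @param estimator FST estimator.
#' @return list with `polymorphic_sites`, `pi_per_10kb`, `mean_fst`
#'   (named per pair).
#' @export
summary_stats <- function(gm, popmap, windows, estimator = "wc") {
  fr <- site_freq(gm)
  poly <- sum(fr$maf > 0, na.rm = TRUE)
  wpi <- windowed_pi(gm, windows)
  regions <- intersect(c("Northern", "Central", "Southern"),
                       unique(popmap$region))
  pairs <- if (length(regions) >= 2) utils::combn(regions, 2, simplify = FALSE)
           else list()
  mf <- vapply(pairs, function(pr)
    mean_fst(gm, popmap, pr, estimator = estimator), 0)
  names(mf) <- vapply(pairs, paste, "", collapse = ":")
  list(polymorphic_sites = poly,
       pi_per_10kb = mean(wpi$pi_bp) * 10000,
       mean_fst = mf)
}
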