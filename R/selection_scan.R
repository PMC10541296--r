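# PBS / PBS_max selection scan with an intergenic empirical null.
#
# The population branch statistic converts the three pairwise FST values
# of a window into per-branch lengths T = -ln(1 - FST); the branch with
# the largest PBS is the putatively selected one (PBS_max). Outliers are
# the top 0.1% of the PBS_max distribution; their empirical p-values come
# from the PBS_max distribution of windows overlapping no gene.

#' Population branch statistic from three pairwise FST values
#'
#' FST values are clamped to `[0, cap]` before the log transform
#' (negative estimator output is floored at 0; the cap keeps fixed
#' differences finite while preserving ranking). For populations
#' (a, b, c): `pbs_a = (t_ab + t_ac - t_bc) / 2`, cyclically for b and
#' c, with `t_xy = -ln(1 - fst_xy)`. The identity
#' `pbs_a + pbs_b + pbs_c = (t_ab + t_ac + t_bc) / 2` holds exactly.
#' Ties in the argmax resolve in fixed label order a < b < c.
#'
#' @param fst_ab,fst_ac,fst_bc pairwise FST (vectorized); non-finite
#'   input marks that entry missing (`NA` throughout).
#' @param cap upper clamp, default `1 - 1e-6`.
#' @param labels branch names reported in `branch`.
#' @return data.frame with `t_ab`, `t_ac`, `t_bc`, `pbs_a`, `pbs_b`,
#'   `pbs_c`, `pbs_max`, `branch`.
#' @export
pbs_from_fst <- function(fst_ab, fst_ac, fst_bc, cap = 1 - 1e-6,
                         labels = c("A", "B", "C")) {
  ok <- is.finite(fst_ab) & is.finite(fst_ac) & is.finite(fst_bc)
  cl <- function(f) pmin(pmax(f, 0), cap)
  t_ab <- t_ac <- t_bc <- rep(NA_real_, length(fst_ab))
  t_ab[ok] <- -log(1 - cl(fst_ab[ok]))
  t_ac[ok] <- -log(1 - cl(fst_ac[ok]))
  t_bc[ok] <- -log(1 - cl(fst_bc[ok]))
  pbs_a <- (t_ab + t_ac - t_bc) / 2
  pbs_b <- (t_ab + t_bc - t_ac) / 2
  pbs_c <- (t_ac + t_bc - t_ab) / 2
  pbs <- cbind(pbs_a, pbs_b, pbs_c)
  arg <- apply(pbs, 1, function(x) if (anyNA(x)) NA_integer_
               else which.max(x))
  data.frame(t_ab = t_ab, t_ac = t_ac, t_bc = t_bc,
             pbs_a = pbs_a, pbs_b = pbs_b, pbs_c = pbs_c,
             pbs_max = apply(pbs, 1, function(x) if (anyNA(x)) NA_real_
                             else max(x)),
             branch = labels[arg])
}

#' Windowed PBS_max scan
#'
#' Computes windowed FST for the three region pairs
#' (Northern:Central, Northern:Southern, Central:Southern) and converts
#' each scored window into a PBS triple. Windows missing any pair's FST
#' (too few SNPs or a zero denominator) are excluded. Samples whose
#' region is not one of the three core regions (e.g. admixture-zone
#' populations) are ignored; putative non-natives must be excluded
#' beforehand.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param popmap population map.
#' @param windows from [make_windows()].
#' @param estimator `"wc"` or `"hudson"`.
#' @param min_snps minimum SNPs per window per pair.
#' @return `windows` with per-pair FST, `n_snps` (minimum over pairs),
#'   the PBS triple, `pbs_max` and `branch`; unscored windows carry
#'   `NA`.
#' @export
scan_pbs <- function(gm, popmap, windows, estimator = c("wc", "hudson"),
                     min_snps = 3L) {
  estimator <- match.arg(estimator)
  pops <- c("Northern", "Central", "Southern")
  n_by_pop <- vapply(pops, function(p)
    length(pop_sample_idx(gm, popmap, p)), 0L)
  if (any(n_by_pop < 2))
    stop("each region needs >= 2 samples; got ",
         paste(sprintf("%s=%d", pops, n_by_pop), collapse = ", "))
  f_nc <- windowed_fst(gm, popmap, c("Northern", "Central"), windows,
                       estimator, min_snps)
  f_ns <- windowed_fst(gm, popmap, c("Northern", "Southern"), windows,
                       estimator, min_snps)
  f_cs <- windowed_fst(gm, popmap, c("Central", "Southern"), windows,
                       estimator, min_snps)
  pbs <- pbs_from_fst(f_nc$fst, f_ns$fst, f_cs$fst, labels = pops)
  out <- windows
  out$fst_nc <- f_nc$fst
  out$fst_ns <- f_ns$fst
  out$fst_cs <- f_cs$fst
  out$n_snps <- pmin(f_nc$n_snps, f_ns$n_snps, f_cs$n_snps)
  out <- cbind(out, pbs[, c("pbs_a", "pbs_b", "pbs_c", "pbs_max", "branch")])
  names(out)[names(out) == "pbs_a"] <- "pbs_northern"
  names(out)[names(out) == "pbs_b"] <- "pbs_central"
  names(out)[names(out) == "pbs_c"] <- "pbs_southern"
  out
}

#' Flag windows as genic or intergenic
#'
#' A window is genic when it overlaps at least 1 bp of any gene span.
#'
#' @param windows data.frame with `contig`, `start`, `end`.
#' @param genes list of gene models ([read_gff()]) or a data.frame with
#'   `contig`, `start`, `end`.
#' @return logical vector, `TRUE` for genic windows.
#' @export
classify_windows_genic <- function(windows, genes) {
  gdf <- if (is.data.frame(genes)) genes else genes_as_df(genes)
  if (nrow(gdf) == 0) return(rep(FALSE, nrow(windows)))
  wr <- GenomicRanges::GRanges(windows$contig,
                               IRanges::IRanges(windows$start, windows$end))
  gr <- GenomicRanges::GRanges(gdf$contig,
                               IRanges::IRanges(gdf$start, gdf$end))
  IRanges::overlapsAny(wr, gr)
}

#' Empirical p-value against a null distribution
#'
#' `p = (1 + #\{null >= value\}) / (1 + N)`; ties count as exceeding.
#'
#' @param value observed statistic(s), vectorized.
#' @param null numeric vector of null draws (e.g. intergenic window
#'   PBS_max values); must be non-empty.
#' @return numeric vector of p-values in `(0, 1]`.
#' @export
empirical_p <- function(value, null) {
  null <- null[!is.na(null)]
  if (!length(null)) stop("empty null distribution")
  srt <- sort(null)
  n_ge <- length(srt) - findInterval(value, srt, left.open = TRUE)
  (1 + n_ge) / (1 + length(srt))
}

#' Call top-fraction outlier windows
#'
#' The threshold is the `(k + 1)`-th largest PBS_max with
#' `k = ceiling(top_frac * n)` over all scored windows; outliers are the
#' windows strictly above it, so `k` windows are called in the absence
#' of ties, every copy of a tied value above the threshold is included,
#' and a degenerate all-equal distribution yields no outliers.
#'
#' @param stats a [scan_pbs()] result (needs `pbs_max`).
#' @param top_frac outlier fraction (default 0.001, the top 0.1%).
#' @return `stats` rows that are outliers, with an `outlier` column set;
#'   the threshold is attached as attribute `threshold`.
#' @export
call_outliers <- function(stats, top_frac = 0.001) {
  scored <- which(!is.na(stats$pbs_max))
  n <- length(scored)
  if (n < 1 / top_frac)
    warning("fewer than 1/top_frac scored windows (", n, ")")
  k <- ceiling(top_frac * n)
  srt <- sort(stats$pbs_max[scored], decreasing = TRUE)
  thr <- if (k + 1 <= n) srt[k + 1] else -Inf
  out <- stats[scored, ][stats$pbs_max[scored] > thr, , drop = FALSE]
  out$outlier <- rep(TRUE, nrow(out))
  attr(out, "threshold") <- thr
  out
}

#' Merge outlier windows into candidate regions
#'
#' Outlier windows on the same contig separated by at most `gap_windows`
#' non-outlier windows merge into one region. Each region records its
#' maximal contiguous runs as spans, the number of member outlier
#' windows (`related_windows`), the peak PBS_max, the branch of the
#' peak window and (when a `p` column is present) the peak window's
#' empirical p.
#'
#' @param outliers a [call_outliers()] result.
#' @param window_size nominal window size in bp (used to count gap
#'   windows between non-adjacent members).
#' @param gap_windows maximum number of intervening non-outlier windows
#'   (default 1).
#' @return data.frame with one row per region: `contig`, `start`, `end`,
#'   `spans` (rendered, comma-separated), `related_windows`,
#'   `peak_pbs_max`, `branch`, `empirical_p`.
#' @export
merge_regions <- function(outliers, window_size = 10000L, gap_windows = 1L) {
  if (nrow(outliers) == 0)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), spans = character(),
                      related_windows = integer(),
                      peak_pbs_max = numeric(), branch = character(),
                      empirical_p = numeric()))
  o <- outliers[order(outliers$contig, outliers$start), , drop = FALSE]
  widx <- (o$start - 1) %/% window_size
  new_region <- c(TRUE, o$contig[-1] != o$contig[-nrow(o)] |
                    diff(widx) > gap_windows + 1)
  rid <- cumsum(new_region)
  regions <- lapply(split(seq_len(nrow(o)), rid), function(rows) {
    m <- o[rows, , drop = FALSE]
    run <- cumsum(c(TRUE, diff((m$start - 1) %/% window_size) > 1))
    spans <- vapply(split(seq_len(nrow(m)), run), function(rr)
      format_span(min(m$start[rr]), max(m$end[rr])), "")
    peak <- which.max(m$pbs_max)
    data.frame(contig = m$contig[1], start = min(m$start),
               end = max(m$end),
               spans = paste(spans, collapse = ", "),
               related_windows = nrow(m),
               peak_pbs_max = m$pbs_max[peak],
               branch = m$branch[peak],
               empirical_p = if ("p" %in% names(m)) m$p[peak] else NA_real_)
  })
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Full PBS_max outlier analysis
#'
#' [scan_pbs()], intergenic null, [call_outliers()] with empirical
#' p-values, and [merge_regions()].
#'
#' @inheritParams scan_pbs
#' @param genes gene models for the genic/intergenic split.
#' @param top_frac outlier fraction.
#' @param gap_windows region merge rule.
#' @param per_branch_null use a per-branch intergenic null (PBS of the
#'   window's own branch) instead of the branch-agnostic PBS_max null.
#' @return list with `windows` (scored scan table with `genic` flag),
#'   `outliers`, `regions`, `null` (sorted null draws) and `threshold`.
#' @export
pbs_outlier_analysis <- function(gm, popmap, windows, genes,
                                 estimator = "wc", min_snps = 3L,
                                 top_frac = 0.001, gap_windows = 1L,
                                 per_branch_null = FALSE) {
  stats <- scan_pbs(gm, popmap, windows, estimator, min_snps)
  stats$genic <- classify_windows_genic(stats, genes)
  scored <- !is.na(stats$pbs_max)
  null_pool <- stats[scored & !stats$genic, , drop = FALSE]
  outliers <- call_outliers(stats, top_frac)
  if (nrow(null_pool) >= 100) {
    if (per_branch_null) {
      cols <- c(Northern = "pbs_northern", Central = "pbs_central",
                Southern = "pbs_southern")
      outliers$p <- vapply(seq_len(nrow(outliers)), function(i)
        empirical_p(outliers$pbs_max[i],
                    null_pool[[cols[[outliers$branch[i]]]]]), 0)
    } else {
      outliers$p <- empirical_p(outliers$pbs_max, null_pool$pbs_max)
    }
  } else {
    warning("fewer than 100 intergenic windows; empirical p not reported")
    outliers$p <- NA_real_
  }
  size <- max(windows$end - windows$start + 1)
  regions <- merge_regions(outliers, window_size = size,
                           gap_windows = gap_windows)
  list(windows = stats, outliers = outliers, regions = regions,
       null = sort(null_pool$pbs_max),
       threshold = attr(outliers, "threshold"))
}
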