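test_that("PBS closed form, symmetry, and the half-sum identity", {
  z <- pbs_from_fst(0, 0, 0)
  expect_equal(unlist(z[, c("pbs_a", "pbs_b", "pbs_c", "pbs_max")]),
               c(pbs_a = 0, pbs_b = 0, pbs_c = 0, pbs_max = 0))
  r <- pbs_from_fst(0.3, 0.2, 0.1)
  expect_lt(abs(r$pbs_a - 0.237229), 1e-6)
  expect_lt(abs(r$pbs_b - 0.119446), 1e-6)
  expect_lt(abs(r$pbs_c - (-0.014085)), 1e-6)
  expect_equal(r$pbs_max, r$pbs_a)
  expect_equal(r$branch, "A")
  # symmetric input: all branches equal -ln(1 - f) / 2, tie -> A
  for (f in c(0.05, 0.3, 0.8)) {
    s <- pbs_from_fst(f, f, f)
    expect_equal(unlist(s[, c("pbs_a", "pbs_b", "pbs_c")]),
                 setNames(rep(-log(1 - f) / 2, 3),
                          c("pbs_a", "pbs_b", "pbs_c")),
                 tolerance = 1e-12)
    expect_equal(s$branch, "A")
  }
  # identity over random triples
  set.seed(20)
  fab <- runif(2000, -0.1, 0.999)
  fac <- runif(2000, -0.1, 0.999)
  fbc <- runif(2000, -0.1, 0.999)
  t3 <- pbs_from_fst(fab, fac, fbc)
  expect_lt(max(abs(t3$pbs_a + t3$pbs_b + t3$pbs_c -
                      (t3$t_ab + t3$t_ac + t3$t_bc) / 2)), 1e-12)
  expect_equal(t3$pbs_max, pmax(t3$pbs_a, t3$pbs_b, t3$pbs_c))
})

test_that("PBS clamping and missing-input handling", {
  # negative FST floored at zero
  expect_equal(pbs_from_fst(-0.5, -0.2, -0.9)$pbs_max, 0)
  # FST at/above 1 stays finite via the cap
  expect_true(is.finite(pbs_from_fst(1, 1, 1)$pbs_max))
  # non-finite input marks the window missing
  out <- pbs_from_fst(c(0.1, NA), c(0.1, 0.2), c(0.1, 0.2))
  expect_true(is.na(out$pbs_max[2]))
  expect_true(is.na(out$branch[2]))
  # each branch's PBS is monotone non-decreasing in its two adjacent FSTs
  set.seed(8)
  for (i in 1:50) {
    f <- runif(3, 0, 0.9)
    base <- pbs_from_fst(f[1], f[2], f[3])
    up <- runif(1, 0, 0.09)
    expect_gte(pbs_from_fst(f[1] + up, f[2], f[3])$pbs_a,
               base$pbs_a - 1e-12)
    expect_gte(pbs_from_fst(f[1], f[2] + up, f[3])$pbs_a,
               base$pbs_a - 1e-12)
    expect_gte(pbs_from_fst(f[1] + up, f[2], f[3])$pbs_b,
               base$pbs_b - 1e-12)
    expect_gte(pbs_from_fst(f[1], f[2], f[3] + up)$pbs_c,
               base$pbs_c - 1e-12)
  }
})

test_that("scan_pbs: a branch-private fixed-difference window tops the scan", {
  set.seed(33)
  m <- 60
  base <- runif(m, 0.3, 0.7)
  freq_n <- freq_c <- freq_s <- base
  # window 4 (30001-40000): fixed differences on the Northern branch only;
  # every other site in the window stays polymorphic so the Central
  # -Southern pair keeps a defined (non-degenerate) window FST
  pos <- sort(sample(seq(1, 59999), m))
  in_w4 <- which(pos >= 30001 & pos <= 40000)
  fix4 <- in_w4[seq(1, length(in_w4), by = 2)]
  freq_n[fix4] <- 1; freq_c[fix4] <- 0; freq_s[fix4] <- 0
  fx <- three_pop_gm(freq_n, freq_c, freq_s, n_per_pop = 8,
                     positions = pos)
  win <- make_windows(c(c1 = 60000L), 10000)
  st <- scan_pbs(fx$gm, fx$popmap, win, min_snps = 1)
  top <- which.max(st$pbs_max)
  expect_equal(st$start[top], 30001)
  expect_equal(st$branch[top], "Northern")
  # permuting samples leaves the scan unchanged
  perm <- sample(24)
  st2 <- scan_pbs(subset_gm(fx$gm, samples = perm),
                  fx$popmap[perm, ], win, min_snps = 1)
  expect_equal(st2$pbs_max, st$pbs_max, tolerance = 1e-12)
  # a region with < 2 samples errors
  pm_bad <- fx$popmap
  pm_bad$region[pm_bad$region == "Southern"] <- "Admixed"
  expect_error(scan_pbs(fx$gm, pm_bad, win), ">= 2 samples")
})

test_that("genic window classification overlaps by >= 1 bp", {
  genes <- list(structure(list(gene_id = "g1", name = NA_character_,
                               contig = "c1", strand = "+",
                               start = 9990L, end = 10200L,
                               cds = matrix(integer(), 0, 2)),
                          class = "gene_model"))
  win <- data.frame(contig = c("c1", "c1", "c2"),
                    start = c(1L, 10201L, 1L),
                    end = c(10000L, 20200L, 10000L))
  expect_equal(classify_windows_genic(win, genes), c(TRUE, FALSE, FALSE))
})

test_that("empirical p: counting rule, ties, monotonicity", {
  null99 <- sort(runif(99))
  expect_equal(empirical_p(2, null99), 0.01)
  expect_equal(empirical_p(-1, null99), 1)
  null3 <- c(0.1, 0.5, 0.9)
  expect_equal(empirical_p(0.9, null3), 0.5)   # tie counts as >=
  expect_equal(empirical_p(0.95, null3), 0.25)
  vals <- seq(-0.5, 1.5, length.out = 101)
  p <- empirical_p(vals, null99)
  expect_true(all(diff(p) <= 0))
  expect_error(empirical_p(1, numeric()), "empty null")
})

test_that("outlier calling matches the sort-and-slice oracle with ties", {
  mk <- function(x) data.frame(contig = "c1",
                               start = seq_along(x) * 10000L - 9999L,
                               end = seq_along(x) * 10000L,
                               pbs_max = x, branch = "Northern")
  # 2000 distinct values -> exactly 2 outliers
  set.seed(5)
  x <- rnorm(2000)
  out <- call_outliers(mk(x), 0.001)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$start, mk(x)$start[order(x, decreasing = TRUE)[1:2]])
  # all equal -> none
  expect_equal(nrow(suppressWarnings(call_outliers(mk(rep(1, 50)), 0.001))),
               0L)
  # randomized, with heavy ties, against the oracle
  for (seed in 1:10) {
    set.seed(seed)
    x <- sample(round(rnorm(300), 1), 500, replace = TRUE)
    got <- suppressWarnings(call_outliers(mk(x), 0.01))
    expect_setequal(got$start, mk(x)$start[outliers_brute(x, 0.01)])
  }
})

test_that("region merging: gap rule, contig boundaries, span rendering", {
  ow <- data.frame(
    contig = "contig2592",
    start = c(60001L, 70001L, 80001L, 90001L, 110001L),
    end = c(70000L, 80000L, 90000L, 100000L, 120000L),
    pbs_max = c(1.1, 1.35, 1.2, 1.0, 0.9),
    branch = "Central")
  r <- merge_regions(ow, window_size = 10000, gap_windows = 1)
  expect_equal(nrow(r), 1L)
  expect_equal(r$related_windows, 5L)
  expect_equal(r$spans, "60001–100000, 110001–120000")
  expect_equal(r$peak_pbs_max, 1.35)
  expect_equal(r$branch, "Central")
  # gap 0: adjacent-only merging -> two regions of 4 and 1 windows
  r0 <- merge_regions(ow, window_size = 10000, gap_windows = 0)
  expect_equal(nrow(r0), 2L)
  expect_equal(r0$related_windows, c(4L, 1L))
  # different contigs never merge
  ow2 <- ow; ow2$contig <- c(rep("cA", 3), rep("cB", 2))
  r2 <- merge_regions(ow2, 10000, 1)
  expect_equal(nrow(r2), 2L)
  # invariant to input ordering
  r3 <- merge_regions(ow[sample(5), ], 10000, 1)
  expect_equal(r3, r)
  # empty input
  expect_equal(nrow(merge_regions(ow[0, ], 10000, 1)), 0L)
})

test_that("full outlier analysis wires null, p-values and regions together", {
  cfg <- sim_small(seed = 41, n_contigs = 2L, contig_length_bp = 1000000L,
                   n_neutral_snps = 2000L, n_selected_loci = 20L,
                   n_selected_windows = 2L, n_env_loci = 0L,
                   admixed_pops = list(), n_hybrids = 0L)
  sim <- simulate_dataset(cfg)
  gm <- apply_site_filters(sim$gm)
  win <- make_windows(sim$contig_lengths, 10000)
  res <- pbs_outlier_analysis(gm, sim$popmap, win, sim$genes,
                              top_frac = 0.01)
  expect_true(all(!is.na(res$outliers$p)))
  expect_true(all(res$outliers$p <= 1 & res$outliers$p > 0))
  expect_gte(length(res$null), 100)
  # intergenic windows only in the null
  genic <- classify_windows_genic(res$windows, sim$genes)
  expect_equal(length(res$null),
               sum(!genic & !is.na(res$windows$pbs_max)))
  expect_true(nrow(res$regions) >= 1)
  # selected windows carry large PBS_max: mean above the intergenic 95th pct
  key <- paste(res$windows$contig, res$windows$start)
  sel <- match(paste(sim$selected_windows$contig,
                     sim$selected_windows$start), key)
  expect_gt(mean(res$windows$pbs_max[sel], na.rm = TRUE),
            quantile(res$null, 0.95))
})
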