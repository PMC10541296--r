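mk_gene <- function(gene_id, contig, strand, start, end, cds,
                    name = NA_character_) {
  structure(list(gene_id = gene_id, name = name, contig = contig,
                 strand = strand, start = as.integer(start),
                 end = as.integer(end),
                 cds = matrix(as.integer(cds), ncol = 2, byrow = TRUE,
                              dimnames = list(NULL, c("start", "end")))),
            class = "gene_model")
}

test_that("PBS candidate genes: 1-bp overlap rule and region bookkeeping", {
  genes <- list(
    mk_gene("g1", "c1", "+", 9990, 10200, integer()),
    mk_gene("g2", "c1", "+", 5000, 6000, integer()),   # nested in region
    mk_gene("g3", "c1", "+", 30000, 31000, integer()), # outside
    mk_gene("g4", "c2", "+", 1, 10000, integer()))
  regions <- data.frame(contig = "c1", start = 1L, end = 10000L,
                        spans = "1–10000", related_windows = 1L,
                        peak_pbs_max = 0.9, branch = "Central",
                        empirical_p = 0.01)
  cand <- candidate_genes_pbs(regions, genes)
  expect_setequal(cand$gene_id, c("g1", "g2"))
  expect_equal(unique(cand$evidence), "pbs:Central")
  expect_equal(unique(cand$related_count), 1L)
  expect_equal(nrow(candidate_genes_pbs(regions[0, ], genes)), 0L)
})

test_that("interval overlap agrees with the quadratic all-pairs oracle", {
  set.seed(14)
  rand_iv <- function(n) {
    st <- sample.int(5000, n, replace = TRUE)
    data.frame(contig = sample(c("c1", "c2", "c3"), n, replace = TRUE),
               start = st, end = st + sample.int(400, n, replace = TRUE))
  }
  a <- rand_iv(200); b <- rand_iv(200)
  got <- apiscan:::interval_overlaps(a, b)
  want <- overlap_brute(a, b)
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_equal(key(as.matrix(got)), key(want))
  # symmetric under swapping which list is indexed
  got_swap <- apiscan:::interval_overlaps(b, a)
  expect_equal(key(as.matrix(got_swap[, c(2, 1)])), key(want))
})

test_that("coding-effect classification: worked plus-strand examples", {
  # gene 11..19 with CDS ATG GCT TAA on the plus strand
  seqs <- list(c1 = paste0(strrep("T", 10), "ATGGCTTAA", strrep("G", 10)))
  seqs$c1 <- setNames(seqs$c1, NULL)
  ref <- c(c1 = seqs$c1)
  gene <- mk_gene("g1", "c1", "+", 11, 19, c(11, 19))
  # codon 2 GCT -> CCT: missense Ala -> Pro
  eff <- classify_coding_effect(
    list(contig = "c1", pos = 14, ref = "G", alt = "C"), gene, ref)
  expect_equal(eff$classification, "missense")
  expect_equal(c(eff$ref_codon, eff$alt_codon), c("GCT", "CCT"))
  expect_equal(c(eff$ref_aa, eff$alt_aa), c("A", "P"))
  # GCT -> GCC: synonymous
  eff2 <- classify_coding_effect(
    list(contig = "c1", pos = 16, ref = "T", alt = "C"), gene, ref)
  expect_equal(eff2$classification, "synonymous")
  # stop codon disrupted: stop_lost
  eff3 <- classify_coding_effect(
    list(contig = "c1", pos = 17, ref = "T", alt = "C"), gene, ref)
  expect_equal(eff3$classification, "stop_lost")
  # start codon disrupted: start_lost
  eff4 <- classify_coding_effect(
    list(contig = "c1", pos = 11, ref = "A", alt = "C"), gene, ref)
  expect_equal(eff4$classification, "start_lost")
  # reference mismatch errors
  expect_error(classify_coding_effect(
    list(contig = "c1", pos = 14, ref = "T", alt = "C"), gene, ref),
    "reference mismatch")
})

test_that("intron, intergenic and frame-violating genes are handled", {
  ref <- c(c1 = paste0(strrep("A", 5), "ATG", "CCCCC", "GCTTAA",
                       strrep("A", 10)))
  gene <- mk_gene("g1", "c1", "+", 6, 19, c(6, 8, 14, 19))
  # intronic site
  eff <- classify_coding_effect(
    list(contig = "c1", pos = 10, ref = "C", alt = "T"), gene, ref)
  expect_equal(eff$classification, "noncoding_in_gene")
  # outside the gene span
  eff2 <- classify_coding_effect(
    list(contig = "c1", pos = 25, ref = "A", alt = "T"), gene, ref)
  expect_equal(eff2$classification, "intergenic")
  # CDS not divisible by 3: warning, NA classification
  bad <- mk_gene("g2", "c1", "+", 6, 19, c(6, 9))
  expect_warning(
    effb <- classify_coding_effect(
      list(contig = "c1", pos = 7, ref = "T", alt = "C"), bad, ref),
    "divisible by 3")
  expect_true(is.na(effb$classification))
})

test_that("classification matches the brute-force oracle on random genes", {
  set.seed(25)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:120) {
    L <- 60
    contig_seq <- sample(bases, L, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    # one- or two-part CDS, total length divisible by 3
    if (runif(1) < 0.5) {
      l1 <- 3 * sample(2:5, 1)
      s1 <- sample(5:20, 1)
      cds <- c(s1, s1 + l1 - 1)
    } else {
      l1 <- sample(2:7, 1); l2 <- 3 * sample(2:4, 1) - l1 %% 3
      l2 <- l2 + (3 - (l1 + l2) %% 3) %% 3
      s1 <- sample(3:10, 1)
      s2 <- s1 + l1 + sample(2:6, 1)
      cds <- c(s1, s1 + l1 - 1, s2, s2 + l2 - 1)
    }
    gene <- mk_gene("g", "c1", strand, max(1, cds[1] - 2),
                    min(L, cds[length(cds)] + 2), cds)
    pos <- sample(gene$start:gene$end, 1)
    refb <- contig_seq[pos]
    altb <- sample(setdiff(bases, refb), 1)
    site <- list(contig = "c1", pos = pos, ref = refb, alt = altb)
    ref <- c(c1 = paste(contig_seq, collapse = ""))
    got <- classify_coding_effect(site, gene, ref)
    want <- classify_brute(site, gene, contig_seq)
    expect_equal(got$classification, want,
                 info = sprintf("rep %d strand %s pos %d", rep, strand, pos))
  }
})

test_that("minus-strand classification equals the reverse-complemented construct", {
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:25) {
    L <- 33
    contig_seq <- sample(bases, L, replace = TRUE)
    cds <- c(7, 7 + 11)  # 12 bp
    gene_minus <- mk_gene("g", "c1", "-", 5, 20, cds)
    pos <- sample(7:18, 1)
    refb <- contig_seq[pos]
    altb <- sample(setdiff(bases, refb), 1)
    got <- classify_coding_effect(
      list(contig = "c1", pos = pos, ref = refb, alt = altb),
      gene_minus, c(c1 = paste(contig_seq, collapse = "")))
    # build the reverse-complemented contig and the mirrored plus gene
    rc <- strsplit(revcomp_brute(paste(contig_seq, collapse = "")), "")[[1]]
    pos_rc <- L - pos + 1
    cds_rc <- c(L - cds[2] + 1, L - cds[1] + 1)
    gene_plus <- mk_gene("g", "c1", "+", L - 20 + 1, L - 5 + 1, cds_rc)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    got_rc <- classify_coding_effect(
      list(contig = "c1", pos = pos_rc, ref = comp[[refb]],
           alt = comp[[altb]]),
      gene_plus, c(c1 = paste(rc, collapse = "")))
    expect_equal(got$classification, got_rc$classification)
    expect_equal(got$ref_aa, got_rc$ref_aa)
    expect_equal(got$alt_aa, got_rc$alt_aa)
  }
})

test_that("env candidate genes count SNPs whose flanks overlap the gene", {
  genes <- list(mk_gene("g1", "c1", "+", 50000, 52000, integer(),
                        name = "sialin-like"),
                mk_gene("g2", "c1", "+", 90000, 91000, integer()))
  lens <- c(c1 = 200000L)
  # 17 significant SNPs within 5 kb of g1, 2 near g2
  pos1 <- seq(45100, 56900, length.out = 17)
  pos2 <- c(85500, 95500)
  assoc <- data.frame(contig = "c1", pos = as.integer(c(pos1, pos2)),
                      ref = "A", alt = "G", variable = "snowfall",
                      q = 0.01, significant = TRUE)
  cand <- candidate_genes_env(assoc, genes, lens, flank_bp = 5000)
  expect_equal(cand$related_count[cand$gene_id == "g1"], 17L)
  expect_equal(cand$related_count[cand$gene_id == "g2"], 2L)
  expect_equal(unique(cand$evidence), "env:snowfall")
})

test_that("report tables render spans and survive a parse round trip", {
  pbs_cand <- data.frame(
    gene_id = c("g10995", "g10996"), name = c("helicase", NA),
    contig = "contig2592", start = c(61000L, 75000L),
    end = c(62000L, 76000L), evidence = "pbs:Central",
    related_count = 5L, peak_score = 1.35, empirical_p = 0.0099,
    region_spans = "60001–100000, 110001–120000")
  env_cand <- data.frame(
    gene_id = "g4091", name = "Sialin isoform X2", contig = "c1",
    start = 50000L, end = 52000L, evidence = "env:snowfall",
    related_count = 17L, min_q = 0.003)
  out_dir <- tempfile("report_")
  paths <- report_tables(pbs_cand, env_cand, out_dir)
  tab <- read.delim(paths$pbs, check.names = FALSE)
  expect_equal(tab$genomic_position,
               rep("contig2592: 60001–100000, 110001–120000", 2))
  expect_equal(tab$related_windows, c(5L, 5L))
  expect_equal(tab$selection, c("Central", "Central"))
  # parse-back: spans and counts recovered exactly
  spans <- strsplit(sub("^[^:]+: ", "", tab$genomic_position[1]), ", ")[[1]]
  parsed <- parse_span(spans)
  expect_equal(parsed$start, c(60001L, 110001L))
  expect_equal(parsed$end, c(100000L, 120000L))
  etab <- read.delim(paths$env)
  expect_equal(etab$related_candidate_snp, 17L)
  expect_equal(etab$fdr, "<0.05")
  # empty candidate lists give header-only tables
  paths0 <- report_tables(pbs_cand[0, ], env_cand[0, ], tempfile("r0_"))
  expect_equal(nrow(read.delim(paths0$pbs)), 0L)
  expect_equal(nrow(read.delim(paths0$env)), 0L)
})
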