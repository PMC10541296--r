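# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and Biostrings/GenomicRanges where the implementation
# uses them).

# hand-coded standard nuclear genetic code
codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

revcomp_brute <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

translate_brute <- function(s) {
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  paste(codon_table[codons], collapse = "")
}

# brute-force coding-effect classification: rebuild the full CDS string,
# mutate, translate, compare
classify_brute <- function(site, gene, contig_seq) {
  in_span <- site$pos >= gene$start & site$pos <= gene$end
  if (!in_span) return("intergenic")
  cds_pos <- unlist(lapply(seq_len(nrow(gene$cds)), function(i)
    gene$cds[i, 1]:gene$cds[i, 2]))
  if (!site$pos %in% cds_pos) return("noncoding_in_gene")
  ref_str <- paste(contig_seq[cds_pos], collapse = "")
  alt_chars <- contig_seq
  alt_chars[site$pos] <- site$alt
  alt_str <- paste(alt_chars[cds_pos], collapse = "")
  if (gene$strand == "-") {
    ref_str <- revcomp_brute(ref_str)
    alt_str <- revcomp_brute(alt_str)
  }
  ref_aa <- translate_brute(ref_str)
  alt_aa <- translate_brute(alt_str)
  d <- which(strsplit(ref_aa, "")[[1]] != strsplit(alt_aa, "")[[1]])
  if (!length(d)) return("synonymous")
  ra <- substring(ref_aa, d[1], d[1]); aa <- substring(alt_aa, d[1], d[1])
  if (aa == "*") "stop_gained"
  else if (ra == "*") "stop_lost"
  else if (d[1] == 1 && ra == "M") "start_lost"
  else "missense"
}

# textbook Weir & Cockerham (1984) two-population estimator, scalar form
wc_brute <- function(n, p, h) {
  r <- 2
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, total = a + b + cc)
}

# step-up BH by explicit loop
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in m:1) {
    v <- m * p[o[i]] / i
    q_sorted[i] <- if (i == m) min(1, v) else min(q_sorted[i + 1], v, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# sort-and-slice outlier caller: strictly above the (k+1)-th largest
outliers_brute <- function(x, top_frac) {
  k <- ceiling(top_frac * length(x))
  srt <- sort(x, decreasing = TRUE)
  thr <- if (k + 1 <= length(x)) srt[k + 1] else -Inf
  which(x > thr)
}

# quadratic all-pairs interval overlap
overlap_brute <- function(a, b) {
  hits <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$contig[i] == b$contig[j] &&
        a$start[i] <= b$end[j] && b$start[j] <= a$end[i])
      hits <- rbind(hits, c(i, j))
  }
  hits
}

# all-pairs allele-copy nucleotide diversity at one site: expand the
# sampled allele copies and count differing pairs explicitly
site_pi_brute <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  alleles <- unlist(lapply(d, function(x) c(rep(1, x), rep(0, 2 - x))))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diff <- 0; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if (alleles[i] != alleles[j]) diff <- diff + 1
  }
  diff / tot
}
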