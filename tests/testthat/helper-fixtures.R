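# Programmatic fixtures shared across test files.

# random genotype matrix on one or more contigs
rand_gm <- function(n_sites = 50, n_samp = 20, seed = 1,
                    contigs = "c1", miss_rate = 0, pos_max = 1e6) {
  set.seed(seed)
  ct <- sort(sample(contigs, n_sites, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n_sites), ct), function(i)
    sort(sample.int(pos_max, length(i)))))
  p <- runif(n_sites, 0.1, 0.9)
  d <- matrix(rbinom(n_sites * n_samp, 2, p), n_sites, n_samp)
  if (miss_rate > 0)
    d[runif(length(d)) < miss_rate] <- NA_integer_
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  genotype_matrix(
    data.frame(contig = sort(ct), pos = pos, id = NA_character_,
               ref = ref, alt = unname(alt)),
    sprintf("S%02d", seq_len(n_samp)), d)
}

# three-population genotype matrix from explicit per-pop frequencies
three_pop_gm <- function(freq_n, freq_c, freq_s, n_per_pop = 6, seed = 1,
                         contig = "c1", positions = NULL) {
  set.seed(seed)
  m <- length(freq_n)
  draw <- function(p) matrix(rbinom(m * n_per_pop, 2, p), m, n_per_pop)
  d <- cbind(draw(freq_n), draw(freq_c), draw(freq_s))
  samples <- sprintf("%s%02d", rep(c("N", "C", "S"), each = n_per_pop),
                     seq_len(3 * n_per_pop))
  pos <- if (is.null(positions)) seq(100, by = 97, length.out = m)
         else positions
  gm <- genotype_matrix(
    data.frame(contig = contig, pos = pos, id = NA_character_,
               ref = "A", alt = "G"),
    samples, d)
  pm <- data.frame(sample = samples,
                   district = rep(c("Tohoku", "Chugoku", "Kyushu"),
                                  each = n_per_pop),
                   region = rep(c("Northern", "Central", "Southern"),
                                each = n_per_pop))
  list(gm = gm, popmap = pm)
}

# small, fast simulation configuration
sim_small <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_contigs = 2L,
                   contig_length_bp = 400000L,
                   n_neutral_snps = 800L, n_selected_loci = 20L,
                   n_selected_windows = 2L, n_env_loci = 20L,
                   admixed_pops = list(
                     Kinki = list(n = 3L, fractions = c(0.4, 0.6, 0)),
                     Shikoku = list(n = 3L, fractions = c(0.55, 0.3, 0.15))),
                   n_hybrids = 2L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

write_vcf_text <- function(lines) {
  tf <- tempfile(fileext = ".vcf")
  writeLines(lines, tf)
  tf
}

minimal_vcf_header <- function(samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
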