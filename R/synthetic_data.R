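# Balding-Nichols synthetic data generator.
#
# Emulates the sampling design the pipeline targets: three genetically
# diverged geographic regions (Northern, Central, Southern) drifted from a
# common ancestral pool, two admixture-zone populations, a few introduced
# ("hybrid") individuals placed in a pure district, a minority of strongly
# branch-differentiated windows, loci whose allele frequency follows a
# latitude-like environmental cline, and a genic/intergenic annotation.

#' Simulation configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' test-suite: 20 diploid samples per core region, a 5 x 10.01-Mb genome
#' tiled into 5005 10-kb windows, 50,000 neutral SNPs (about 10 per
#' window) drifted at F = 0.05, five windows of ten loci drifted at
#' F = 0.5 on a single branch each, 50 clinal loci whose per-locus
#' dosage R-squared with the driving variable is `env_r2`, two admixture
#' -zone populations and two introduced 60/40 hybrids.
#'
#' @param seed integer; fully determines the output.
#' @param n_per_pop named integer vector, samples per core region.
#' @param admixed_pops named list of admixture-zone populations, each
#'   `list(n =, fractions =)` with fractions over (Northern, Central,
#'   Southern).
#' @param n_hybrids number of introduced individuals placed in
#'   `hybrid_district`.
#' @param hybrid_fractions length-3 ancestry mixing proportions of the
#'   hybrids over (Northern, Central, Southern).
#' @param hybrid_district district the hybrids claim as home.
#' @param n_contigs,contig_length_bp genome shape.
#' @param window_size_bp scan window size (bp).
#' @param n_neutral_snps neutral biallelic SNPs placed uniformly outside
#'   selected windows.
#' @param f_neutral Balding-Nichols drift parameter of every branch at
#'   neutral loci.
#' @param n_selected_loci,n_selected_windows branch-selected loci,
#'   grouped evenly into that many windows.
#' @param f_selected drift parameter on the selected branch at selected
#'   loci.
#' @param selected_branch optional character vector of branch names per
#'   selected window; `NULL` draws them uniformly.
#' @param n_env_loci loci following the environmental cline.
#' @param env_beta logistic slope per clinal locus (scalar or vector);
#'   `NULL` derives per-locus slopes from `env_r2` via
#'   [env_beta_for_r2()].
#' @param env_r2 target per-locus dosage R-squared of clinal loci.
#' @param env_assoc_var which environmental variable drives the cline.
#' @param env_structured when `TRUE` (default) the driving variable is the
#'   latitude-derived gradient shared with population structure; when
#'   `FALSE` it is replaced by an independent standardized normal
#'   per-sample value, giving clinal loci with no structure confounding.
#' @param gene_fraction fraction of each contig covered by gene spans.
#' @param write_fasta also emit a reference FASTA (memory-heavy for
#'   large genomes; intended for small configurations).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_per_pop = c(Northern = 20L, Central = 20L,
                                     Southern = 20L),
                       admixed_pops = list(
                         Kinki = list(n = 5L, fractions = c(0.40, 0.60, 0)),
                         Shikoku = list(n = 5L, fractions = c(0.55, 0.30, 0.15))
                       ),
                       n_hybrids = 2L,
                       hybrid_fractions = c(0.6, 0, 0.4),
                       hybrid_district = "Tohoku",
                       n_contigs = 5L,
                       contig_length_bp = 10010000L,
                       window_size_bp = 10000L,
                       n_neutral_snps = 50000L,
                       f_neutral = 0.05,
                       n_selected_loci = 50L,
                       n_selected_windows = 5L,
                       f_selected = 0.5,
                       selected_branch = NULL,
                       n_env_loci = 50L,
                       env_beta = NULL,
                       env_r2 = 0.15,
                       env_assoc_var = "snowfall",
                       env_structured = TRUE,
                       gene_fraction = 0.4,
                       write_fasta = FALSE) {
  stopifnot(f_neutral > 0, f_neutral < 1, f_selected > 0, f_selected < 1,
            f_neutral < f_selected,
            all(names(n_per_pop) == c("Northern", "Central", "Southern")),
            abs(sum(hybrid_fractions) - 1) < 1e-9 || n_hybrids == 0,
            window_size_bp >= 1, gene_fraction >= 0, gene_fraction < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Logistic slope giving a target per-locus dosage R-squared
#'
#' For a locus with ancestral frequency `p0` and a standardized driving
#' variable z, the per-sample ALT frequency is
#' `plogis(qlogis(p0) + beta * z)`. To first order the dosage variance
#' explained by z is `(2 beta p0 q0)^2` against binomial noise
#' `2 p0 q0`, so `beta = sqrt(r2 / (1 - r2) / (2 p0 q0))` yields
#' R-squared approximately `r2`.
#'
#' @param r2 target R-squared in (0, 1).
#' @param p0 ancestral allele frequency (vectorized).
#' @return numeric slope(s).
#' @export
env_beta_for_r2 <- function(r2, p0) {
  stopifnot(r2 > 0, r2 < 1, all(p0 > 0), all(p0 < 1))
  sqrt(r2 / (1 - r2) / (2 * p0 * (1 - p0)))
}

# approximate district latitudes (degrees N) used for the
# environmental gradient
district_latitudes <- c(Tohoku = 39.5, Kanto = 36.0, Chugoku = 34.5,
                        Kyushu = 32.5, Kinki = 34.8, Shikoku = 33.8)

# sample frame: ids, district, claimed region, true ancestry, environment
build_samples <- function(cfg, env_structured = TRUE) {
  pops <- c("Northern", "Central", "Southern")
  dist_of <- list(Northern = c("Tohoku", "Kanto"), Central = "Chugoku",
                  Southern = "Kyushu")
  rows <- list()
  for (p in pops) {
    n <- cfg$n_per_pop[[p]]
    ds <- rep(dist_of[[p]], length.out = n)
    ds <- ds[order(ds)]
    rows[[p]] <- data.frame(district = ds, region = p, type = "pure",
                            qN = as.numeric(p == "Northern"),
                            qC = as.numeric(p == "Central"),
                            qS = as.numeric(p == "Southern"))
  }
  for (ap in names(cfg$admixed_pops)) {
    a <- cfg$admixed_pops[[ap]]
    if (a$n == 0) next
    rows[[ap]] <- data.frame(district = ap, region = "Admixed",
                             type = "admixed_pop",
                             qN = a$fractions[1], qC = a$fractions[2],
                             qS = a$fractions[3])[rep(1, a$n), ]
  }
  if (cfg$n_hybrids > 0) {
    hd <- cfg$hybrid_district
    hr <- names(Filter(function(d) hd %in% d,
                       list(Northern = c("Tohoku", "Kanto"),
                            Central = "Chugoku", Southern = "Kyushu")))
    rows[["hyb"]] <- data.frame(district = hd, region = hr[1],
                                type = "hybrid",
                                qN = cfg$hybrid_fractions[1],
                                qC = cfg$hybrid_fractions[2],
                                qS = cfg$hybrid_fractions[3])[
                                  rep(1, cfg$n_hybrids), ]
  }
  s <- do.call(rbind, rows)
  rownames(s) <- NULL
  idx <- stats::ave(seq_len(nrow(s)), s$district, s$type, FUN = seq_along)
  s$sample <- sprintf("%s_%s%02d", s$district,
                      ifelse(s$type == "hybrid", "h", "s"), idx)
  # environment: latitude with within-district spread, then four noisy
  # transforms standing in for temperature/snowfall/precipitation/sunlight
  lat <- district_latitudes[s$district] + rnorm(nrow(s), 0, 0.8)
  z <- as.numeric(scale(lat))
  mkvar <- function(sign) as.numeric(scale(sign * z + rnorm(nrow(s), 0, 0.5)))
  s$latitude <- lat
  env <- data.frame(sample = s$sample,
                    temperature = mkvar(-1),
                    snowfall = mkvar(+1),
                    precipitation = mkvar(-1),
                    sunlight = mkvar(-1))
  if (!env_structured)
    env[[cfg$env_assoc_var]] <- as.numeric(scale(rnorm(nrow(s))))
  list(samples = s, env = env)
}

#' Simulate per-population allele frequencies
#'
#' Under a star topology (no shared internal branch), each core
#' population's frequency at a neutral locus is drawn from the
#' Balding-Nichols Beta distribution around an ancestral frequency
#' `p0 ~ U(0.05, 0.95)` with drift `f_neutral`; selected loci use
#' `f_selected` on their assigned branch only; clinal loci take a
#' per-sample frequency `plogis(qlogis(p0) + beta * z)` from the driving
#' environmental variable.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_frequencies` list: `sites` (contig, pos, ref, alt,
#'   label), `p0`, `pop_freq` (sites x 3, `NA` rows for clinal loci),
#'   `env_p` (clinal loci x samples per-sample frequencies), the sample
#'   frame with true ancestry (`samples`), the environment table (`env`),
#'   and the selected-window truth table (`selected_windows`).
#' @export
simulate_frequencies <- function(cfg) {
  set.seed(cfg$seed)
  sf <- build_samples(cfg, env_structured = isTRUE(cfg$env_structured))
  contigs <- sprintf("contig%d", seq_len(cfg$n_contigs))
  clen <- setNames(rep(cfg$contig_length_bp, cfg$n_contigs), contigs)
  win <- make_windows(clen, cfg$window_size_bp)
  n_win <- nrow(win)
  stopifnot(cfg$n_selected_windows <= n_win)
  sel_w <- sort(sample.int(n_win, cfg$n_selected_windows))
  branches <- cfg$selected_branch
  if (is.null(branches) && cfg$n_selected_windows > 0)
    branches <- sample(c("Northern", "Central", "Southern"),
                       cfg$n_selected_windows, replace = TRUE)

  # selected loci: evenly split across their windows
  per_w <- if (cfg$n_selected_windows > 0)
    diff(round(seq(0, cfg$n_selected_loci,
                   length.out = cfg$n_selected_windows + 1))) else integer()
  sel_sites <- list()
  for (i in seq_along(sel_w)) {
    w <- win[sel_w[i], ]
    pos <- sort(sample.int(w$end - w$start + 1L, per_w[i]) + w$start - 1L)
    sel_sites[[i]] <- data.frame(contig = w$contig, pos = pos,
                                 label = paste0("selected:", branches[i]))
  }
  sel_sites <- if (length(sel_sites)) do.call(rbind, sel_sites) else NULL

  # neutral + clinal loci: balanced across the non-selected windows
  # (10 per 10-kb window under the defaults), uniform positions within
  # each window
  n_free <- cfg$n_neutral_snps + cfg$n_env_loci
  total_bp <- sum(as.numeric(clen))
  if (n_free + cfg$n_selected_loci > total_bp)
    stop("more SNPs requested than available positions")
  non_sel <- setdiff(seq_len(n_win), sel_w)
  counts <- rep(n_free %/% length(non_sel), length(non_sel))
  rem <- n_free %% length(non_sel)
  if (rem > 0) {
    bump <- sample.int(length(non_sel), rem)
    counts[bump] <- counts[bump] + 1L
  }
  free <- lapply(seq_along(non_sel), function(i) {
    if (counts[i] == 0) return(NULL)
    w <- win[non_sel[i], ]
    data.frame(contig = w$contig,
               pos = sort(sample.int(w$end - w$start + 1L, counts[i]) +
                            w$start - 1L))
  })
  free <- do.call(rbind, Filter(Negate(is.null), free))
  lab <- rep("neutral", n_free)
  if (cfg$n_env_loci > 0)
    lab[sample.int(n_free, cfg$n_env_loci)] <-
      paste0("env:", cfg$env_assoc_var)
  free$label <- lab
  sites <- rbind(free, sel_sites)
  ord <- order(match(sites$contig, contigs), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  n_sites <- nrow(sites)

  # alleles and ancestral frequency
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  sites$ref <- ref
  sites$alt <- unname(alt)
  p0 <- runif(n_sites, 0.05, 0.95)

  pops <- c("Northern", "Central", "Southern")
  pop_freq <- matrix(NA_real_, n_sites, 3, dimnames = list(NULL, pops))
  is_env <- startsWith(sites$label, "env:")
  drift <- !is_env
  for (k in seq_along(pops)) {
    f <- rep(cfg$f_neutral, sum(drift))
    sel_here <- sites$label[drift] == paste0("selected:", pops[k])
    f[sel_here] <- cfg$f_selected
    a <- p0[drift] * (1 - f) / f
    b <- (1 - p0[drift]) * (1 - f) / f
    if (any(a <= 0) || any(b <= 0))
      stop("Balding-Nichols Beta parameters <= 0 (p0 at the boundary?)")
    pop_freq[drift, k] <- rbeta(sum(drift), a, b)
  }

  env_p <- NULL
  if (cfg$n_env_loci > 0) {
    z <- sf$env[[cfg$env_assoc_var]]
    beta <- cfg$env_beta %||% env_beta_for_r2(cfg$env_r2, p0[is_env])
    beta <- rep_len(beta, sum(is_env))
    env_p <- plogis(outer(qlogis(p0[is_env]), rep(1, nrow(sf$samples))) +
                      beta %o% z)
    dimnames(env_p) <- list(NULL, sf$samples$sample)
  }
  selected_windows <- if (length(sel_w))
    cbind(win[sel_w, c("contig", "start", "end")],
          branch = branches) else NULL
  structure(list(sites = sites, p0 = p0, pop_freq = pop_freq,
                 env_p = env_p, samples = sf$samples, env = sf$env,
                 selected_windows = selected_windows,
                 contig_lengths = clen, cfg = cfg),
            class = "sim_frequencies")
}

#' Simulate genotypes (and optionally write the fixture files)
#'
#' Pure individuals draw dosage `Binomial(2, p_pop)`; admixture-zone and
#' hybrid individuals draw each allele's population of origin from their
#' ancestry fractions; clinal loci use the individual's own per-sample
#' frequency. When `out_dir` is given, writes `sim.vcf`, `sim.gff3`,
#' `popmap.tsv`, `env.tsv`, `true_Q.txt`, `truth_sites.tsv`,
#' `truth_samples.tsv` (and `sim.fa` when `cfg$write_fasta`).
#'
#' @param freqs a [simulate_frequencies()] result.
#' @param cfg the same [sim_config()].
#' @param out_dir optional output directory.
#' @return list with `gm` (a [genotype_matrix()]), `popmap`, `env`,
#'   `true_q`, `truth_sites`, `selected_windows`, `genes` (list of gene
#'   models), `contig_lengths` and, if written, `paths`.
#' @export
simulate_genotypes <- function(freqs, cfg = freqs$cfg, out_dir = NULL) {
  set.seed(derive_seed(cfg$seed, 1L))
  P <- freqs$pop_freq
  if (any(P < 0 | P > 1, na.rm = TRUE)) stop("frequencies outside [0, 1]")
  s <- freqs$samples
  n_sites <- nrow(freqs$sites)
  is_env <- startsWith(freqs$sites$label, "env:")
  dosage <- matrix(NA_integer_, n_sites, nrow(s))
  Q <- as.matrix(s[, c("qN", "qC", "qS")])
  for (j in seq_len(nrow(s))) {
    qj <- Q[j, ]
    if (max(qj) == 1) {
      k <- which.max(qj)
      d <- rbinom(n_sites, 2L, ifelse(is_env, 0, P[, k]))
    } else {
      o1 <- sample.int(3, n_sites, replace = TRUE, prob = qj)
      o2 <- sample.int(3, n_sites, replace = TRUE, prob = qj)
      pick <- function(o) ifelse(is_env, 0, P[cbind(seq_len(n_sites), o)])
      d <- rbinom(n_sites, 1L, pick(o1)) + rbinom(n_sites, 1L, pick(o2))
    }
    if (any(is_env))
      d[is_env] <- rbinom(sum(is_env), 2L, freqs$env_p[, j])
    dosage[, j] <- d
  }
  sites <- freqs$sites[, c("contig", "pos", "ref", "alt")]
  sites$id <- NA_character_
  gm <- genotype_matrix(sites, s$sample, dosage)
  popmap <- data.frame(sample = s$sample, district = s$district,
                       region = s$region)
  truth_sites <- freqs$sites
  truth_sites$p0 <- freqs$p0
  truth_sites <- cbind(truth_sites, freqs$pop_freq)
  genes <- synthetic_genes(freqs$contig_lengths, cfg$gene_fraction)
  out <- list(gm = gm, popmap = popmap, env = freqs$env,
              true_q = `dimnames<-`(Q, list(s$sample, c("N", "C", "S"))),
              truth_sites = truth_sites,
              truth_samples = s,
              selected_windows = freqs$selected_windows,
              genes = genes, contig_lengths = freqs$contig_lengths)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      vcf = file.path(out_dir, "sim.vcf"),
      gff = file.path(out_dir, "sim.gff3"),
      popmap = file.path(out_dir, "popmap.tsv"),
      env = file.path(out_dir, "env.tsv"),
      q = file.path(out_dir, "true_Q.txt"),
      truth_sites = file.path(out_dir, "truth_sites.tsv"),
      truth_samples = file.path(out_dir, "truth_samples.tsv")
    )
    write_vcf(gm, paths$vcf)
    write_gff(genes, freqs$contig_lengths, paths$gff)
    write.table(popmap, paths$popmap, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(freqs$env, paths$env, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(format(Q, digits = 6), paths$q, quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(truth_sites, paths$truth_sites, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(s, paths$truth_samples, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (isTRUE(cfg$write_fasta)) {
      set.seed(derive_seed(cfg$seed, 2L))
      paths$fasta <- file.path(out_dir, "sim.fa")
      write_synthetic_fasta(gm, freqs$contig_lengths, paths$fasta)
    }
    out$paths <- paths
  }
  out
}

#' Run the full generator
#'
#' Convenience wrapper: [simulate_frequencies()] then
#' [simulate_genotypes()].
#'
#' @inheritParams simulate_genotypes
#' @param cfg a [sim_config()].
#' @return see [simulate_genotypes()].
#' @export
simulate_dataset <- function(cfg = sim_config(), out_dir = NULL) {
  simulate_genotypes(simulate_frequencies(cfg), cfg, out_dir)
}

# deterministic gene tiling: one gene per `period` bp covering
# gene_fraction of it, alternating strand, with a two-part CDS.
# With the default 50-kb period and 10-kb windows the gene spans are
# window-aligned, so the genic fraction holds in bp and in windows.
synthetic_genes <- function(contig_lengths, gene_fraction,
                            period = 50000L) {
  if (gene_fraction <= 0) return(list())
  gl <- as.integer(round(period * gene_fraction))
  genes <- list()
  gid <- 0L
  for (ct in names(contig_lengths)) {
    n_genes <- as.integer(contig_lengths[[ct]] %/% period)
    for (i in seq_len(n_genes)) {
      gid <- gid + 1L
      start <- as.integer((i - 1L) * period + 1L)
      end <- start + gl - 1L
      pad <- max(10L, gl %/% 10L)
      intron <- max(10L, gl %/% 10L)
      usable <- gl - 2L * pad - intron
      l1 <- (usable %/% 2L) %/% 3L * 3L
      l2 <- (usable - l1) %/% 3L * 3L
      cds <- if (l1 >= 3 && l2 >= 3) {
        s1 <- start + pad
        s2 <- s1 + l1 + intron
        cbind(start = c(s1, s2), end = c(s1 + l1 - 1L, s2 + l2 - 1L))
      } else matrix(integer(), 0, 2,
                    dimnames = list(NULL, c("start", "end")))
      genes[[gid]] <- structure(
        list(gene_id = sprintf("g%05d", gid), name = NA_character_,
             contig = ct, strand = if (gid %% 2L) "+" else "-",
             start = start, end = end, cds = cds),
        class = "gene_model")
    }
  }
  genes
}

#' Write gene models as GFF3
#'
#' @param genes list of gene models (see [read_gff()]).
#' @param contig_lengths named vector for the sequence-region pragmas.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, contig_lengths, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(contig_lengths),
                     as.integer(contig_lengths)))
  for (g in genes) {
    attrs <- sprintf("ID=%s", g$gene_id)
    if (!is.na(g$name)) attrs <- paste0(attrs, ";Name=", g$name)
    lines <- c(lines,
               sprintf("%s\tapiscan\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       g$contig, g$start, g$end, g$strand, attrs))
    if (nrow(g$cds)) {
      phase <- cds_phases(g)
      ord <- seq_len(nrow(g$cds))
      lines <- c(lines,
                 sprintf("%s\tapiscan\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s",
                         g$contig, g$cds[ord, 1], g$cds[ord, 2], g$strand,
                         phase, g$gene_id, ord, g$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# GFF phase column for each CDS part, honouring strand order
cds_phases <- function(g) {
  n <- nrow(g$cds)
  lens <- g$cds[, 2] - g$cds[, 1] + 1L
  tx_order <- if (g$strand == "-") rev(seq_len(n)) else seq_len(n)
  ph <- integer(n)
  done <- 0L
  for (i in tx_order) {
    ph[i] <- (3L - done %% 3L) %% 3L
    done <- done + lens[i]
  }
  ph
}

# random reference consistent with the simulated REF alleles
write_synthetic_fasta <- function(gm, contig_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ct in names(contig_lengths)) {
    len <- as.integer(contig_lengths[[ct]])
    seq <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    here <- gm$sites$contig == ct
    seq[gm$sites$pos[here]] <- gm$sites$ref[here]
    writeLines(paste0(">", ct), con)
    idx <- seq(1, len, by = 70)
    writeLines(vapply(idx, function(i)
      paste(seq[i:min(i + 69, len)], collapse = ""), ""), con)
  }
  invisible(path)
}
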