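# Candidate-gene annotation: overlap outlier/flank regions with gene
# models, classify coding effects of SNPs, and emit report tables.

#' Candidate genes overlapping PBS outlier regions
#'
#' A gene is a candidate when its span overlaps at least 1 bp of any
#' region; each gene is counted once per region (the region's member
#' windows are reported through `related_windows`).
#'
#' @param regions a [merge_regions()] result.
#' @param genes list of gene models ([read_gff()]).
#' @return data.frame ordered by (contig, start): `gene_id`, `name`,
#'   `contig`, `start`, `end`, `evidence` (`"pbs:<branch>"`),
#'   `related_count`, `peak_score`, `empirical_p`, `region_spans`.
#' @export
candidate_genes_pbs <- function(regions, genes) {
  gdf <- genes_as_df(genes)
  empty <- data.frame(gene_id = character(), name = character(),
                      contig = character(), start = integer(),
                      end = integer(), evidence = character(),
                      related_count = integer(), peak_score = numeric(),
                      empirical_p = numeric(), region_spans = character())
  if (nrow(gdf) == 0 || nrow(regions) == 0) return(empty)
  hits <- interval_overlaps(regions, gdf)
  if (nrow(hits) == 0) return(empty)
  out <- data.frame(
    gene_id = gdf$gene_id[hits$subject],
    name = gdf$name[hits$subject],
    contig = gdf$contig[hits$subject],
    start = gdf$start[hits$subject],
    end = gdf$end[hits$subject],
    evidence = paste0("pbs:", regions$branch[hits$query]),
    related_count = regions$related_windows[hits$query],
    peak_score = regions$peak_pbs_max[hits$query],
    empirical_p = regions$empirical_p[hits$query],
    region_spans = regions$spans[hits$query]
  )
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Candidate genes overlapping significant-SNP flank regions
#'
#' `related_count` is the number of significant SNPs whose flank region
#' overlaps the gene (per environmental variable).
#'
#' @param assoc an [env_association_scan()] result (uses rows with
#'   `significant == TRUE`).
#' @param genes list of gene models.
#' @param contig_lengths named vector of contig lengths.
#' @param flank_bp flank on each side of a significant SNP.
#' @return data.frame: `gene_id`, `name`, `contig`, `start`, `end`,
#'   `evidence` (`"env:<variable>"`), `related_count`, `min_q`,
#'   `fdr_threshold`.
#' @export
candidate_genes_env <- function(assoc, genes, contig_lengths,
                                flank_bp = 5000L) {
  gdf <- genes_as_df(genes)
  empty <- data.frame(gene_id = character(), name = character(),
                      contig = character(), start = integer(),
                      end = integer(), evidence = character(),
                      related_count = integer(), min_q = numeric())
  sig <- assoc[assoc$significant, , drop = FALSE]
  if (nrow(gdf) == 0 || nrow(sig) == 0) return(empty)
  out <- lapply(split(sig, sig$variable), function(sv) {
    fl <- snp_flank_regions(sv, flank_bp, contig_lengths)$regions
    hits <- interval_overlaps(fl, gdf)
    if (nrow(hits) == 0) return(NULL)
    agg <- split(hits$query, hits$subject)
    gi <- as.integer(names(agg))
    data.frame(gene_id = gdf$gene_id[gi], name = gdf$name[gi],
               contig = gdf$contig[gi], start = gdf$start[gi],
               end = gdf$end[gi],
               evidence = paste0("env:", sv$variable[1]),
               related_count = lengths(agg),
               min_q = vapply(agg, function(r) min(sv$q[r]), 0))
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$evidence, -out$related_count, out$contig), , drop = FALSE]
}

# all overlapping (query, subject) index pairs between two interval
# tables with columns contig, start, end
interval_overlaps <- function(query, subject) {
  qr <- GenomicRanges::GRanges(query$contig,
                               IRanges::IRanges(query$start, query$end))
  sr <- GenomicRanges::GRanges(subject$contig,
                               IRanges::IRanges(subject$start, subject$end))
  h <- GenomicRanges::findOverlaps(qr, sr)
  data.frame(query = S4Vectors::queryHits(h),
             subject = S4Vectors::subjectHits(h))
}

#' Classify the coding effect of a SNP within one gene
#'
#' Locates the site within the gene's concatenated CDS (transcription
#' order; minus-strand genes use the reverse complement), substitutes
#' the ALT allele and translates the affected codon with the standard
#' nuclear code. Sites inside the gene span but outside the CDS are
#' `noncoding_in_gene`; sites outside the span are `intergenic`. Genes
#' whose declared CDS length is not divisible by 3 are skipped with a
#' warning (`NA` classification).
#'
#' @param site one-row data.frame (or list) with `contig`, `pos`,
#'   `ref`, `alt` (plus-strand alleles).
#' @param gene a gene model ([read_gff()]).
#' @param ref_seq reference sequence: named character vector or
#'   [Biostrings::DNAStringSet] keyed by contig.
#' @return data.frame: `contig`, `pos`, `gene_id`, `classification`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa` (codon fields `NA`
#'   outside CDS).
#' @export
classify_coding_effect <- function(site, gene, ref_seq) {
  res <- data.frame(contig = site$contig, pos = as.integer(site$pos),
                    gene_id = gene$gene_id,
                    classification = NA_character_,
                    ref_codon = NA_character_, alt_codon = NA_character_,
                    ref_aa = NA_character_, alt_aa = NA_character_)
  if (site$contig != gene$contig || site$pos < gene$start ||
      site$pos > gene$end) {
    res$classification <- "intergenic"
    res$gene_id <- NA_character_
    return(res)
  }
  in_cds <- nrow(gene$cds) > 0 &&
    any(site$pos >= gene$cds[, 1] & site$pos <= gene$cds[, 2])
  if (!in_cds) {
    res$classification <- "noncoding_in_gene"
    return(res)
  }
  cds_len <- sum(gene$cds[, 2] - gene$cds[, 1] + 1)
  if (cds_len %% 3 != 0) {
    warning("CDS length of ", gene$gene_id,
            " not divisible by 3; gene skipped")
    return(res)
  }
  contig_seq <- extract_contig_seq(ref_seq, site$contig)
  # coding sequence in transcription order
  plus_pos <- unlist(lapply(seq_len(nrow(gene$cds)), function(i)
    gene$cds[i, 1]:gene$cds[i, 2]))
  plus_bases <- contig_seq[plus_pos]
  ref_base_plus <- contig_seq[site$pos]
  if (ref_base_plus != site$ref)
    stop("reference mismatch at ", site$contig, ":", site$pos,
         " (reference has ", ref_base_plus, ", site says ", site$ref, ")")
  if (gene$strand == "-") {
    coding <- rev_complement(plus_bases)
    cds_idx <- length(plus_pos) - match(site$pos, plus_pos) + 1L
    alt_coding <- rev_complement(site$alt)
  } else {
    coding <- plus_bases
    cds_idx <- match(site$pos, plus_pos)
    alt_coding <- site$alt
  }
  codon_i <- (cds_idx - 1L) %/% 3L
  off <- (cds_idx - 1L) %% 3L + 1L
  codon <- coding[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
  alt_codon <- codon
  alt_codon[off] <- alt_coding
  ref_aa <- translate_codon(codon)
  alt_aa <- translate_codon(alt_codon)
  cls <- if (ref_aa == alt_aa) "synonymous"
         else if (alt_aa == "*") "stop_gained"
         else if (ref_aa == "*") "stop_lost"
         else if (codon_i == 0L && ref_aa == "M") "start_lost"
         else "missense"
  res$classification <- cls
  res$ref_codon <- paste(codon, collapse = "")
  res$alt_codon <- paste(alt_codon, collapse = "")
  res$ref_aa <- ref_aa
  res$alt_aa <- alt_aa
  res
}

# reference handling helpers (Biostrings does the translation work)
extract_contig_seq <- function(ref_seq, contig) {
  if (methods::is(ref_seq, "DNAStringSet")) {
    if (!contig %in% names(ref_seq)) stop("contig not in reference: ", contig)
    strsplit(as.character(ref_seq[[contig]]), "")[[1]]
  } else {
    if (!contig %in% names(ref_seq)) stop("contig not in reference: ", contig)
    strsplit(toupper(ref_seq[[contig]]), "")[[1]]
  }
}

rev_complement <- function(bases) {
  x <- Biostrings::reverseComplement(
    Biostrings::DNAString(paste(bases, collapse = "")))
  strsplit(as.character(x), "")[[1]]
}

translate_codon <- function(codon) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(paste(codon, collapse = "")),
    no.init.codon = TRUE))
}

#' Classify coding effects for many SNPs against a gene set
#'
#' Each SNP is classified against the gene whose span contains it (the
#' first by position when several overlap); SNPs outside all genes are
#' `intergenic`.
#'
#' @param sites data.frame with `contig`, `pos`, `ref`, `alt`.
#' @param genes list of gene models.
#' @param ref_seq reference sequence (see [classify_coding_effect()]).
#' @return data.frame, one row per SNP.
#' @export
classify_effects <- function(sites, genes, ref_seq) {
  gdf <- genes_as_df(genes)
  out <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, , drop = FALSE]
    gi <- which(gdf$contig == s$contig & gdf$start <= s$pos &
                  gdf$end >= s$pos)
    if (!length(gi)) {
      data.frame(contig = s$contig, pos = as.integer(s$pos),
                 gene_id = NA_character_, classification = "intergenic",
                 ref_codon = NA_character_, alt_codon = NA_character_,
                 ref_aa = NA_character_, alt_aa = NA_character_)
    } else {
      classify_coding_effect(s, genes[[gi[1]]], ref_seq)
    }
  })
  do.call(rbind, out)
}

#' Write candidate-gene report tables
#'
#' Emits `pbs_candidates.tsv` (genomic position rendered as
#' `"contig: start-end[, start-end]"` spans, related windows, highest
#' PBS_max score, selection branch, gene name, gene id),
#' `env_candidates.tsv` (environmental factor, related candidate SNP
#' count, contig, FDR threshold met, gene name, gene id) and, when
#' effects are supplied, `snp_effects.tsv`.
#'
#' @param pbs_candidates a [candidate_genes_pbs()] result.
#' @param env_candidates a [candidate_genes_env()] result.
#' @param out_dir output directory (created if needed).
#' @param effects optional [classify_effects()] result.
#' @param fdr_threshold named per-variable thresholds used for the
#'   `FDR` column of the env table.
#' @return named list of written paths, invisibly.
#' @export
report_tables <- function(pbs_candidates, env_candidates, out_dir,
                          effects = NULL,
                          fdr_threshold = c(temperature = 0.05,
                                            snowfall = 0.05,
                                            precipitation = 0.01,
                                            sunlight = 0.01)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(pbs = file.path(out_dir, "pbs_candidates.tsv"),
                env = file.path(out_dir, "env_candidates.tsv"))
  pbs_tab <- data.frame(
    genomic_position = if (nrow(pbs_candidates))
      paste0(pbs_candidates$contig, ": ", pbs_candidates$region_spans)
      else character(),
    related_windows = pbs_candidates$related_count,
    highest_pbs_max = pbs_candidates$peak_score,
    selection = sub("^pbs:", "", pbs_candidates$evidence),
    empirical_p = pbs_candidates$empirical_p,
    gene_name = pbs_candidates$name,
    gene_id = pbs_candidates$gene_id
  )
  write.table(pbs_tab, paths$pbs, sep = "\t", quote = FALSE,
              row.names = FALSE)
  vars <- sub("^env:", "", env_candidates$evidence)
  env_tab <- data.frame(
    environmental_factor = vars,
    related_candidate_snp = env_candidates$related_count,
    contig = env_candidates$contig,
    fdr = if (nrow(env_candidates))
      sprintf("<%g", unname(fdr_threshold[vars])) else character(),
    gene_name = env_candidates$name,
    gene_id = env_candidates$gene_id
  )
  write.table(env_tab, paths$env, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(effects)) {
    paths$effects <- file.path(out_dir, "snp_effects.tsv")
    write.table(effects, paths$effects, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
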