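# Genotype and annotation IO: VCF (GT only), GFF3 gene models, the
# sample->population map, environment table and ADMIXTURE-style Q matrix.

#' Construct a genotype matrix
#'
#' The central in-memory container of the pipeline: an ordered table of
#' sites and a sites x samples matrix of diploid ALT-allele dosages
#' (0, 1, 2, or `NA` for missing).
#'
#' @param sites data.frame with columns `contig`, `pos` (1-based), `id`,
#'   `ref`, `alt`. Extra columns are preserved.
#' @param samples character vector of sample ids.
#' @param dosage integer matrix, `nrow(sites)` x `length(samples)`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, samples, dosage) {
  stopifnot(is.data.frame(sites),
            all(c("contig", "pos", "ref", "alt") %in% names(sites)))
  if (is.null(sites$id)) sites$id <- NA_character_
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(sites) || ncol(dosage) != length(samples))
    stop("dosage dimensions do not match sites x samples")
  if (anyDuplicated(paste(sites$contig, sites$pos)))
    stop("duplicate (contig, pos) site records")
  if (any(sites$pos < 1)) stop("positions must be >= 1")
  bad <- !is.na(dosage) & (dosage < 0L | dosage > 2L)
  if (any(bad)) stop("dosage values must be in {0, 1, 2, NA}")
  rownames(dosage) <- NULL
  colnames(dosage) <- samples
  structure(list(sites = sites, samples = as.character(samples),
                 dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples on %d contig(s)\n",
              nrow(x$sites), length(x$samples),
              length(unique(x$sites$contig))))
  invisible(x)
}

#' Number of sites / samples of a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return integer count.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname n_sites
#' @export
n_samples <- function(gm) length(gm$samples)

#' Subset a genotype matrix by site and/or sample index
#' @param gm a [genotype_matrix()].
#' @param sites,samples integer or logical indices; `NULL` keeps all.
#' @return a [genotype_matrix()].
#' @export
subset_gm <- function(gm, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(gm)) else sites
  sa <- if (is.null(samples)) seq_len(n_samples(gm)) else samples
  genotype_matrix(gm$sites[si, , drop = FALSE],
                  gm$samples[sa],
                  gm$dosage[si, sa, drop = FALSE])
}

# TRUE for single-base biallelic SNP records (ref != alt, both A/C/G/T)
site_is_snp <- function(sites) {
  bases <- c("A", "C", "G", "T")
  sites$ref %in% bases & sites$alt %in% bases & sites$ref != sites$alt
}

#' Per-site allele-frequency summaries
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame with per-site ALT frequency `p` (over non-missing
#'   alleles), haploid-equivalent allele count `n` (2 x non-missing
#'   samples), minor allele frequency `maf` and `missing_fraction`.
#' @export
site_freq <- function(gm) {
  nm <- rowSums(!is.na(gm$dosage))
  p <- ifelse(nm > 0, rowSums(gm$dosage, na.rm = TRUE) / (2 * nm), NA_real_)
  data.frame(
    p = p,
    n = 2L * nm,
    maf = pmin(p, 1 - p),
    missing_fraction = 1 - nm / n_samples(gm)
  )
}

#' Read a VCF into a genotype matrix
#'
#' Only the GT field is consumed; phased and unphased genotypes are treated
#' identically and `./.` (or any genotype containing `.`) becomes missing.
#' Indel and multi-allelic records are retained but can be removed with
#' [apply_site_filters()].
#'
#' @param path path to a VCF 4.x file.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  check_vcf_body(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  samples <- colnames(v@gt)[-1]
  if (nrow(fix) == 0) {
    sites <- data.frame(contig = character(), pos = integer(),
                        id = character(), ref = character(),
                        alt = character())
    return(genotype_matrix(sites, samples,
                           matrix(integer(), 0, length(samples))))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  sites <- data.frame(
    contig = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = as.character(fix[, "ID"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"])
  )
  # decode the handful of distinct GT strings once
  vals <- unique(as.vector(gt))
  dec <- vapply(vals, function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) NA_integer_ else sum(a != "0")
  }, integer(1))
  dosage <- matrix(dec[match(as.vector(gt), vals)], nrow = nrow(gt))
  genotype_matrix(sites, samples, dosage)
}

# cheap structural check so malformed lines are reported with their number
check_vcf_body <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1)
    stop("VCF has no #CHROM header line: ", path)
  n_col <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  if (n_col < 10) stop("VCF header has no sample columns: ", path)
  body <- seq.int(hdr + 1L, length.out = length(lines) - hdr)
  if (length(body) == 0) return(invisible(TRUE))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf != n_col]
  if (length(bad))
    stop(sprintf("malformed VCF record at line %d (%d fields, expected %d)",
                 bad[1], nf[bad[1] - hdr], n_col))
  invisible(TRUE)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits a minimal header and unphased GT-only genotypes, sorted by
#' (contig, pos); missing dosage is serialized as `./.`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  key <- paste(gm$sites$contig, gm$sites$pos)
  if (anyDuplicated(key)) stop("duplicate (contig, pos) records; refusing to write")
  ord <- order(gm$sites$contig, gm$sites$pos)
  sites <- gm$sites[ord, , drop = FALSE]
  dos <- gm$dosage[ord, , drop = FALSE]
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_code[as.character(dos[ok])]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=apiscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  id <- ifelse(is.na(sites$id), ".", sites$id)
  body <- if (nrow(sites)) {
    paste(sites$contig, sites$pos, id, sites$ref, sites$alt,
          ".", ".", ".", "GT",
          apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Site-filter configuration
#'
#' @param maf_min minimum minor allele frequency; the boundary is
#'   inclusive (MAF = `maf_min` is retained), following common tool
#'   convention for "filtered with a MAF of 0.05".
#' @param max_missing_fraction maximum fraction of samples with missing
#'   genotype at a site.
#' @param biallelic_only drop records that are not single-base biallelic
#'   SNPs (indels, multi-allelic records).
#' @return a `filter_config` list.
#' @export
filter_config <- function(maf_min = 0.05, max_missing_fraction = 0.2,
                          biallelic_only = TRUE) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  structure(list(maf_min = maf_min,
                 max_missing_fraction = max_missing_fraction,
                 biallelic_only = biallelic_only),
            class = "filter_config")
}

#' Apply SNP site filters
#'
#' Retains sites that are single-base biallelic SNPs, have a missing
#' fraction at or below `max_missing_fraction`, and a minor allele
#' frequency (computed over non-missing alleles of the samples currently
#' in `gm`) at or above `maf_min`. Site order is preserved and surviving
#' records are not modified, so the operation is idempotent. Re-run the
#' filter after excluding samples (e.g. putative non-natives) so the MAF
#' reflects the scan dataset.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return the filtered [genotype_matrix()]; a warning (not an error) is
#'   issued when no site survives.
#' @export
apply_site_filters <- function(gm, cfg = filter_config()) {
  if (n_sites(gm) == 0) return(gm)
  fr <- site_freq(gm)
  keep <- rep(TRUE, n_sites(gm))
  if (cfg$biallelic_only) keep <- keep & site_is_snp(gm$sites)
  keep <- keep & fr$missing_fraction <= cfg$max_missing_fraction + 1e-12
  keep <- keep & !is.na(fr$maf) & fr$maf >= cfg$maf_min - 1e-12
  if (!any(keep)) warning("all sites removed by filters")
  subset_gm(gm, sites = which(keep))
}

#' Read GFF3 gene models
#'
#' Builds one gene model per `gene` feature; `CDS` children are linked by
#' `Parent`, either directly to the gene or through one intermediate
#' mRNA/transcript feature. Genes without CDS are allowed.
#'
#' @param path path to a GFF3 file.
#' @return list of `gene_model` objects (fields `gene_id`, `name`,
#'   `contig`, `strand`, `start`, `end` and `cds`, a 2-column matrix of
#'   1-based inclusive intervals sorted by position).
#' @export
read_gff <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g[, intersect(c("seqid", "type", "start", "end",
                                     "strand", "ID", "Parent", "Name"),
                                   names(g))])
  if (is.null(g$Name)) g$Name <- NA_character_
  if (any(g$end < g$start)) stop("GFF feature with end < start")
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, "")
  is_gene <- g$type == "gene"
  genes <- g[is_gene, , drop = FALSE]
  # map transcript-level features to their gene
  mid <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  to_gene <- setNames(genes$ID, genes$ID)
  if (nrow(mid)) to_gene <- c(to_gene, setNames(mid$Parent, mid$ID))
  cds <- g[g$type == "CDS", , drop = FALSE]
  if (nrow(cds)) {
    cds$gene <- to_gene[cds$Parent]
    if (any(is.na(cds$gene)))
      stop("CDS with unresolvable Parent: ",
           cds$Parent[is.na(cds$gene)][1])
  }
  out <- lapply(seq_len(nrow(genes)), function(i) {
    gi <- genes[i, ]
    parts <- if (nrow(cds)) cds[cds$gene == gi$ID, , drop = FALSE] else cds
    m <- if (nrow(parts)) {
      m0 <- cbind(start = parts$start, end = parts$end)
      m0[order(m0[, 1]), , drop = FALSE]
    } else matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end")))
    structure(list(gene_id = gi$ID,
                   name = if (is.na(gi$Name)) NA_character_ else gi$Name,
                   contig = as.character(gi$seqid),
                   strand = as.character(gi$strand),
                   start = as.integer(gi$start), end = as.integer(gi$end),
                   cds = m),
              class = "gene_model")
  })
  out
}

# genes as a plain table (one row per gene) for interval work
genes_as_df <- function(genes) {
  data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    name = vapply(genes, function(g) g$name %||% NA_character_, ""),
    contig = vapply(genes, `[[`, "", "contig"),
    strand = vapply(genes, `[[`, "", "strand"),
    start = vapply(genes, `[[`, 1L, "start"),
    end = vapply(genes, `[[`, 1L, "end")
  )
}

#' Read the sample-to-population map
#'
#' @param path TSV with columns `sample`, `district`, `region`; regions
#'   must be one of Northern, Central, Southern, Admixed.
#' @return data.frame with those columns.
#' @export
read_popmap <- function(path) {
  pm <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "district", "region") %in% names(pm)))
    stop("population map needs columns sample, district, region")
  bad <- setdiff(unique(pm$region),
                 c("Northern", "Central", "Southern", "Admixed"))
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(pm$sample)) stop("duplicate sample in population map")
  pm
}

#' Read a per-sample environment table
#'
#' @param path TSV with a `sample` column and one numeric column per
#'   environmental variable.
#' @return data.frame.
#' @export
read_env_table <- function(path) {
  env <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(env)) stop("environment table needs a sample column")
  env
}

#' Read an ADMIXTURE-style Q matrix
#'
#' Whitespace-delimited, one row per sample, K columns of ancestry
#' proportions. Row order must match the sample order supplied.
#'
#' @param path path to the Q file.
#' @param samples character vector of sample ids (row labels).
#' @return numeric matrix, samples x K, rows summing to 1.
#' @export
read_qmatrix <- function(path, samples) {
  q <- as.matrix(read.table(path, header = FALSE))
  if (nrow(q) != length(samples))
    stop("Q matrix rows (", nrow(q), ") != samples (", length(samples), ")")
  if (any(q < 0) || any(abs(rowSums(q) - 1) > 1e-4))
    stop("Q matrix rows must be non-negative and sum to 1")
  dimnames(q) <- list(samples, paste0("Q", seq_len(ncol(q))))
  q
}
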