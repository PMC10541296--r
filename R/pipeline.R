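# One-config orchestration of the full analysis:
# simulate/load -> filter -> structure QC -> sumstats -> PBS scan ->
# environmental association -> annotate -> report.

#' Build a pipeline configuration
#'
#' Either `simulate` (a list of [sim_config()] overrides) or
#' `paths$vcf` + `paths$popmap` must be supplied. All stage parameters
#' are validated before any stage runs.
#'
#' @param simulate `NULL`, or a (possibly empty) list of [sim_config()]
#'   overrides; the pipeline seed is injected.
#' @param paths named list of input paths (`vcf`, `popmap`, and
#'   optionally `gff`, `env`, `qmatrix`, `fasta`).
#' @param filter list of [filter_config()] overrides.
#' @param prune list of [prune_config()] overrides.
#' @param lfmm list of [lfmm_config()] overrides.
#' @param scan list: `window_size`, `top_frac`, `gap_windows`,
#'   `estimator`, `min_snps`.
#' @param n_components PCA components (capped at the data).
#' @param nonnative_threshold aberrant-ancestry flagging threshold.
#' @param seed global seed; stage seeds derive from it.
#' @param out_dir output directory.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, paths = list(),
                            filter = list(), prune = list(),
                            lfmm = list(), scan = list(),
                            n_components = 10L,
                            nonnative_threshold = 0.28,
                            seed = 1L, out_dir = tempfile("apiscan_run_")) {
  if (is.null(simulate)) {
    for (p in c("vcf", "popmap")) {
      if (is.null(paths[[p]])) stop("config needs paths$", p,
                                    " (or a simulate block)")
      if (!file.exists(paths[[p]])) stop("missing input file: ", paths[[p]])
    }
    for (p in intersect(names(paths), c("gff", "env", "qmatrix", "fasta")))
      if (!file.exists(paths[[p]])) stop("missing input file: ", paths[[p]])
  }
  scan <- utils::modifyList(list(window_size = 10000L, top_frac = 0.001,
                                 gap_windows = 1L, estimator = "wc",
                                 min_snps = 3L), scan)
  stopifnot(scan$top_frac > 0, scan$top_frac < 1, scan$window_size >= 1,
            scan$estimator %in% c("wc", "hudson"),
            nonnative_threshold > 0, nonnative_threshold <= 1)
  cfg <- list(simulate = simulate, paths = paths,
              filter = do.call(filter_config, filter),
              prune = do.call(prune_config, prune),
              lfmm = do.call(lfmm_config, lfmm),
              scan = scan, n_components = as.integer(n_components),
              nonnative_threshold = nonnative_threshold,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; top-level keys are
#'   [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full pipeline
#'
#' Stages run in a fixed order; each stage logs one line with its row
#' counts and records its parameters and output files in the manifest.
#' Re-running with an identical configuration and inputs reproduces
#' identical outputs.
#'
#' @param cfg a [pipeline_config()] (or a list of its arguments).
#' @param quiet suppress per-stage log lines.
#' @return the run manifest (stage parameters, counts, output files and
#'   their md5 hashes), invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (!inherits(cfg, "pipeline_config")) cfg <- do.call(pipeline_config, cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list())
  log_stage <- function(name, ...) {
    if (!quiet) message(sprintf("[%s] %s", name, sprintf(...)))
  }
  stage <- function(name, params, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- c(list(params = params), res$meta)
    res$value
  }

  ## inputs ----------------------------------------------------------------
  inputs <- stage("inputs", list(simulate = !is.null(cfg$simulate)),
                  function() {
    if (!is.null(cfg$simulate)) {
      sc <- do.call(sim_config,
                    utils::modifyList(cfg$simulate,
                                      list(seed = derive_seed(cfg$seed, 0L))))
      sim <- simulate_dataset(sc, out_dir = file.path(cfg$out_dir, "sim"))
      log_stage("inputs", "simulated %d sites x %d samples",
                n_sites(sim$gm), n_samples(sim$gm))
      list(value = list(gm = sim$gm, popmap = sim$popmap, env = sim$env,
                        qmat = sim$true_q, genes = sim$genes,
                        contig_lengths = sim$contig_lengths,
                        fasta = sim$paths$fasta, truth = sim),
           meta = list(counts = list(sites = n_sites(sim$gm),
                                     samples = n_samples(sim$gm))))
    } else {
      gm <- read_vcf(cfg$paths$vcf)
      popmap <- read_popmap(cfg$paths$popmap)
      genes <- if (!is.null(cfg$paths$gff)) read_gff(cfg$paths$gff)
               else list()
      env <- if (!is.null(cfg$paths$env)) read_env_table(cfg$paths$env)
             else NULL
      qmat <- if (!is.null(cfg$paths$qmatrix))
        read_qmatrix(cfg$paths$qmatrix, gm$samples) else NULL
      cl <- infer_contig_lengths(gm, genes, cfg$scan$window_size)
      log_stage("inputs", "read %d sites x %d samples", n_sites(gm),
                n_samples(gm))
      list(value = list(gm = gm, popmap = popmap, env = env, qmat = qmat,
                        genes = genes, contig_lengths = cl,
                        fasta = cfg$paths$fasta, truth = NULL),
           meta = list(counts = list(sites = n_sites(gm),
                                     samples = n_samples(gm))))
    }
  })
  pm <- inputs$popmap[match(inputs$gm$samples, inputs$popmap$sample), ]
  if (anyNA(pm$sample)) stop("population map does not cover all samples")

  ## structure QC on a pre-filtered, LD-pruned dataset ---------------------
  gm_f <- stage("filter", unclass(cfg$filter), function() {
    g <- apply_site_filters(inputs$gm, cfg$filter)
    log_stage("filter", "sites %d -> %d", n_sites(inputs$gm), n_sites(g))
    list(value = g, meta = list(counts = list(sites_in = n_sites(inputs$gm),
                                              sites_out = n_sites(g))))
  })
  structure_res <- stage("structure", c(unclass(cfg$prune),
                                        list(threshold = cfg$nonnative_threshold)),
                         function() {
    kept <- ld_prune(gm_f, cfg$prune)
    gm_p <- subset_gm(gm_f, sites = kept)
    npc <- min(cfg$n_components, n_samples(gm_p) - 1L, n_sites(gm_p))
    pca <- pca_genotypes(gm_p, npc)
    flags <- if (!is.null(inputs$qmat))
      flag_putative_nonnative(inputs$qmat, pm, cfg$nonnative_threshold)
      else NULL
    scores_path <- file.path(cfg$out_dir, "pca_scores.tsv")
    write.table(data.frame(sample = rownames(pca$scores), pca$scores),
                scores_path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(flags))
      write.table(flags, file.path(cfg$out_dir, "nonnative_flags.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("structure", "pruned to %d sites; flagged %d samples",
              length(kept), if (is.null(flags)) 0L else sum(flags$flagged))
    list(value = list(kept = kept, pca = pca, flags = flags),
         meta = list(counts = list(pruned_sites = length(kept),
                                   flagged = if (is.null(flags)) 0L
                                             else sum(flags$flagged))))
  })

  ## exclude flagged individuals, re-filter for the scans ------------------
  flags <- structure_res$flags
  scan_samples <- if (!is.null(flags))
    setdiff(inputs$gm$samples, flags$sample[flags$flagged])
    else inputs$gm$samples
  gm_scan <- apply_site_filters(
    subset_gm(inputs$gm, samples = match(scan_samples, inputs$gm$samples)),
    cfg$filter)
  pm_scan <- pm[match(gm_scan$samples, pm$sample), ]

  windows <- make_windows(inputs$contig_lengths, cfg$scan$window_size)

  ## summary statistics ----------------------------------------------------
  sums <- stage("sumstats", list(estimator = cfg$scan$estimator),
                function() {
    s <- summary_stats(gm_scan, pm_scan, windows, cfg$scan$estimator)
    log_stage("sumstats", "%d polymorphic sites; pi/10kb %.4g",
              s$polymorphic_sites, s$pi_per_10kb)
    list(value = s, meta = list(counts = s[c("polymorphic_sites")],
                                mean_fst = as.list(s$mean_fst)))
  })

  ## PBS scan --------------------------------------------------------------
  pbs <- stage("scan_pbs", cfg$scan, function() {
    res <- pbs_outlier_analysis(gm_scan, pm_scan, windows, inputs$genes,
                                estimator = cfg$scan$estimator,
                                min_snps = cfg$scan$min_snps,
                                top_frac = cfg$scan$top_frac,
                                gap_windows = cfg$scan$gap_windows)
    write.table(res$windows, file.path(cfg$out_dir, "pbs_windows.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$regions, file.path(cfg$out_dir, "pbs_regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("scan_pbs", "%d scored windows, %d outliers, %d regions",
              sum(!is.na(res$windows$pbs_max)), nrow(res$outliers),
              nrow(res$regions))
    list(value = res,
         meta = list(counts = list(scored = sum(!is.na(res$windows$pbs_max)),
                                   outliers = nrow(res$outliers),
                                   regions = nrow(res$regions))))
  })

  ## environmental association --------------------------------------------
  assoc <- NULL
  if (!is.null(inputs$env)) {
    assoc <- stage("scan_env", unclass(cfg$lfmm), function() {
      a <- env_association_scan(gm_scan, inputs$env, cfg$lfmm)
      write.table(a, file.path(cfg$out_dir, "env_association.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      log_stage("scan_env", "%d significant SNP-variable pairs",
                sum(a$significant))
      list(value = a,
           meta = list(counts = list(tests = nrow(a),
                                     significant = sum(a$significant))))
    })
  }

  ## candidate genes and reports -------------------------------------------
  reports <- stage("annotate", list(flank_bp = cfg$lfmm$flank_bp),
                   function() {
    pbs_cand <- candidate_genes_pbs(pbs$regions, inputs$genes)
    env_cand <- if (!is.null(assoc))
      candidate_genes_env(assoc, inputs$genes, inputs$contig_lengths,
                          cfg$lfmm$flank_bp)
      else candidate_genes_env(data.frame(significant = logical()),
                               inputs$genes, inputs$contig_lengths)
    effects <- NULL
    if (!is.null(inputs$fasta) && length(inputs$genes)) {
      ref <- Biostrings::readDNAStringSet(inputs$fasta)
      names(ref) <- sub("\\s.*$", "", names(ref))
      sig_sites <- unique(rbind(
        if (!is.null(assoc))
          assoc[assoc$significant, c("contig", "pos", "ref", "alt")]
          else NULL,
        gm_scan$sites[!is.na(window_index(gm_scan$sites, pbs$outliers)),
                      c("contig", "pos", "ref", "alt")]))
      if (!is.null(sig_sites) && nrow(sig_sites))
        effects <- classify_effects(sig_sites, inputs$genes, ref)
    }
    paths <- report_tables(pbs_cand, env_cand, cfg$out_dir, effects,
                           cfg$lfmm$fdr_threshold)
    log_stage("annotate", "%d PBS candidate genes, %d env candidate genes",
              nrow(pbs_cand), nrow(env_cand))
    list(value = list(pbs_candidates = pbs_cand, env_candidates = env_cand,
                      effects = effects, paths = paths),
         meta = list(counts = list(pbs_genes = nrow(pbs_cand),
                                   env_genes = nrow(env_cand))))
  })

  outputs <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest$outputs <- lapply(setNames(outputs,
                                      sub(paste0(cfg$out_dir, "/?"), "",
                                          outputs)),
                             function(f) unname(tools::md5sum(f)))
  manifest$results <- list(
    summary = sums,
    n_outlier_regions = nrow(pbs$regions),
    n_pbs_candidate_genes = nrow(reports$pbs_candidates),
    n_env_candidate_genes = nrow(reports$env_candidates),
    flagged_nonnative = if (!is.null(flags))
      flags$sample[flags$flagged] else character())
  jsonlite::write_json(manifest_for_json(manifest),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(manifest,
              list(gm_scan = gm_scan, pbs = pbs, assoc = assoc,
                   reports = reports, structure = structure_res,
                   inputs = inputs)))
}

# drop unserializable pieces before writing the manifest
manifest_for_json <- function(m) {
  m$stages <- lapply(m$stages, function(s) {
    s$params <- lapply(s$params, function(p)
      if (is.function(p) || is.environment(p)) NULL else p)
    s
  })
  m
}

# contig lengths from the data when no simulation truth is available:
# round the largest observed coordinate up to a whole window
infer_contig_lengths <- function(gm, genes, window_size) {
  tops <- tapply(gm$sites$pos, gm$sites$contig, max)
  if (length(genes)) {
    gdf <- genes_as_df(genes)
    gtop <- tapply(gdf$end, gdf$contig, max)
    all_ct <- union(names(tops), names(gtop))
    tops <- pmax(setNames(as.numeric(tops[all_ct]), all_ct),
                 setNames(as.numeric(gtop[all_ct]), all_ct), na.rm = TRUE)
  }
  ceiling(tops / window_size) * window_size
}
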