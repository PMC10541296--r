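# Latent-factor genotype-environment association.
#
# A deterministic least-squares variant of the latent factor mixed model:
# K latent factors are estimated as the top left singular vectors of the
# centered genotype matrix, each SNP's dosage is regressed on
# [intercept, environment, factors], and the env z-scores are calibrated
# with the genomic inflation factor before Benjamini-Hochberg FDR.

#' LFMM configuration
#'
#' @param k_factors number of latent factors (default 3, the number of
#'   core geographic clusters).
#' @param fdr_threshold named per-variable q-value thresholds; defaults
#'   follow the study design: 0.01 for precipitation and sunlight, 0.05
#'   for temperature and snowfall.
#' @param flank_bp flank added on each side of a significant SNP when
#'   building outlier regions (default 5 kb, 10 kb total).
#' @return an `lfmm_config` list.
#' @export
lfmm_config <- function(k_factors = 3L,
                        fdr_threshold = c(temperature = 0.05,
                                          snowfall = 0.05,
                                          precipitation = 0.01,
                                          sunlight = 0.01),
                        flank_bp = 5000L) {
  stopifnot(k_factors >= 0, all(fdr_threshold > 0 & fdr_threshold < 1),
            flank_bp >= 0)
  structure(list(k_factors = as.integer(k_factors),
                 fdr_threshold = fdr_threshold,
                 flank_bp = as.integer(flank_bp)),
            class = "lfmm_config")
}

#' Standardize environmental variables
#'
#' Per variable: subtract the mean, divide by the population standard
#' deviation (the root mean squared deviation, so `(1, 2, 3)` maps to
#' `(-1.2247, 0, 1.2247)`). Missing values and zero-variance variables
#' are errors (no imputation).
#'
#' @param env data.frame with a `sample` column and numeric variables.
#' @return `env` with every numeric variable standardized.
#' @export
standardize_env <- function(env) {
  vars <- setdiff(names(env), "sample")
  for (v in vars) {
    x <- env[[v]]
    if (!is.numeric(x)) stop("environment variable not numeric: ", v)
    if (anyNA(x)) stop("missing value in environment variable: ", v)
    s <- sqrt(mean((x - mean(x))^2))
    if (!is.finite(s) || s < 1e-12)
      stop("zero-variance environment variable: ", v)
    env[[v]] <- (x - mean(x)) / s
  }
  env
}

#' Latent-factor association for one environmental variable
#'
#' Genotype columns are mean-imputed and centered (and scaled); the top
#' `k_factors` left singular vectors of the centered genotype matrix are
#' the latent factors; each site's dosage is regressed by OLS on
#' [intercept, env, factors]. The genomic inflation factor
#' `lambda = median(z^2) / 0.4549` rescales the squared z-scores, and
#' calibrated p-values come from the chi-square(1) survival function.
#' Constant-dosage sites report `z = 0`, `p = 1`.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param env_values numeric vector, one standardized value per sample
#'   (order of `gm$samples`).
#' @param k_factors number of latent factors.
#' @param factors optional pre-computed factor matrix (samples x K),
#'   e.g. to share factors across variables.
#' @return data.frame per site: `effect`, `z`, `p_raw`, `p_calibrated`,
#'   `gif` (the shared lambda).
#' @export
fit_lfmm <- function(gm, env_values, k_factors = 3L, factors = NULL) {
  n <- n_samples(gm)
  stopifnot(length(env_values) == n)
  if (n < k_factors + 3) stop("need at least k_factors + 3 samples")
  X <- standardize_dosage(gm, scale_het = FALSE)
  sdv <- apply(X, 2, sd)
  keep <- sdv > 1e-12
  Xs <- sweep(X[, keep, drop = FALSE], 2, sdv[keep], "/")
  if (is.null(factors)) factors <- lfmm_factors(X, k_factors)
  D <- cbind(intercept = 1, env = env_values, factors)
  cn <- kappa(qr.R(qr(scale(D[, -1, drop = FALSE], scale = FALSE))),
              exact = TRUE)
  if (!is.finite(cn) || cn > 1e8)
    stop("collinear design (environment vs latent factors)")
  qrD <- qr(D)
  df <- n - ncol(D)
  if (df < 1) stop("no residual degrees of freedom")
  B <- qr.coef(qrD, Xs)
  res <- qr.resid(qrD, Xs)
  sigma2 <- colSums(res^2) / df
  DtDinv <- chol2inv(qr.R(qrD))
  se <- sqrt(pmax(sigma2 * DtDinv[2, 2], 1e-300))
  z_keep <- B[2, ] / se
  z <- rep(0, n_sites(gm))
  z[keep] <- z_keep
  lambda <- median(z_keep^2) / qchisq(0.5, 1)
  p_raw <- pchisq(z^2, 1, lower.tail = FALSE)
  p_cal <- pchisq(z^2 / lambda, 1, lower.tail = FALSE)
  p_raw[!keep] <- 1
  p_cal[!keep] <- 1
  eff <- rep(0, n_sites(gm))
  eff[keep] <- B[2, ]
  data.frame(effect = eff, z = z, p_raw = p_raw, p_calibrated = p_cal,
             gif = lambda)
}

#' Latent factors of a genotype matrix
#'
#' Top `k` left singular vectors of the centered (sample x site)
#' genotype matrix.
#'
#' @param X centered genotype matrix (samples x sites) from
#'   [standardize_dosage()], or a [genotype_matrix()].
#' @param k number of factors; `k = 0` gives a zero-column matrix.
#' @return samples x k matrix.
#' @export
lfmm_factors <- function(X, k) {
  if (inherits(X, "genotype_matrix")) X <- standardize_dosage(X, FALSE)
  if (k == 0) return(matrix(0, nrow(X), 0))
  sv <- svd(X, nu = k, nv = 0)
  sv$u[, seq_len(k), drop = FALSE]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up procedure: on ascending-sorted p-values,
#' `q_(i) = min_{j >= i} (m p_(j) / j)`, capped at 1 and mapped back to
#' the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric())
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Association scan over all environmental variables
#'
#' Standardizes the environment table, fits one latent-factor model per
#' variable (factors are shared across variables), and attaches
#' q-values and per-variable significance calls.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param env environment table (`sample` column plus variables), rows
#'   covering `gm$samples`.
#' @param cfg an [lfmm_config()].
#' @return data.frame with one row per (site, variable): site columns,
#'   `variable`, `effect`, `z`, `p_raw`, `p_calibrated`, `q`, `gif`,
#'   `significant`.
#' @export
env_association_scan <- function(gm, env, cfg = lfmm_config()) {
  ord <- match(gm$samples, env$sample)
  if (anyNA(ord)) stop("environment table does not cover all samples")
  env <- standardize_env(env[ord, , drop = FALSE])
  vars <- setdiff(names(env), "sample")
  factors <- lfmm_factors(gm, cfg$k_factors)
  out <- lapply(vars, function(v) {
    fit <- fit_lfmm(gm, env[[v]], cfg$k_factors, factors = factors)
    fit$q <- bh_fdr(fit$p_calibrated)
    thr <- if (v %in% names(cfg$fdr_threshold)) cfg$fdr_threshold[[v]]
           else 0.05
    fit$significant <- fit$q < thr
    cbind(gm$sites[, c("contig", "pos", "ref", "alt")],
          variable = v, fit, site_index = seq_len(n_sites(gm)))
  })
  do.call(rbind, out)
}

#' Flank regions around significant SNPs
#'
#' One region per SNP, `[max(1, pos - flank_bp), min(contig_end,
#' pos + flank_bp)]`. Overlapping per-SNP regions are deliberately not
#' merged for gene counting (each SNP contributes one region); a merged
#' track is also returned for reporting.
#'
#' @param snps data.frame with `contig`, `pos` (1-based).
#' @param flank_bp flank on each side (default 5000).
#' @param contig_lengths named vector of contig lengths.
#' @return list with `regions` (one row per SNP) and `merged`.
#' @export
snp_flank_regions <- function(snps, flank_bp = 5000L, contig_lengths) {
  if (nrow(snps) == 0) {
    empty <- data.frame(contig = character(), start = integer(),
                        end = integer())
    return(list(regions = empty, merged = empty))
  }
  len <- contig_lengths[snps$contig]
  if (anyNA(len)) stop("SNP on unknown contig")
  if (any(snps$pos > len)) stop("SNP position beyond contig end")
  regions <- data.frame(contig = snps$contig,
                        start = pmax(1L, snps$pos - as.integer(flank_bp)),
                        end = as.integer(pmin(len,
                                              snps$pos + as.integer(flank_bp))),
                        pos = snps$pos)
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(regions$contig,
                           IRanges::IRanges(regions$start, regions$end)))
  merged <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr),
                       end = GenomicRanges::end(gr))
  list(regions = regions, merged = merged)
}
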