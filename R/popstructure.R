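# Population-structure QC: sliding-window LD pruning, genotype PCA and
# the ancestry-based exclusion rule for putative non-native individuals.

#' LD-pruning configuration
#'
#' Defaults mirror the common `--indep-pairwise 50 10 0.1` convention:
#' windows of 50 sites advanced by 10 sites, pruning pairs with squared
#' dosage correlation above 0.1.
#'
#' @param window_sites sites per window.
#' @param step_sites window step (must be `<= window_sites`).
#' @param r2_max maximum allowed squared Pearson correlation.
#' @return a `prune_config` list.
#' @export
prune_config <- function(window_sites = 50L, step_sites = 10L,
                         r2_max = 0.1) {
  stopifnot(step_sites >= 1, step_sites <= window_sites,
            r2_max > 0, r2_max < 1)
  structure(list(window_sites = as.integer(window_sites),
                 step_sites = as.integer(step_sites), r2_max = r2_max),
            class = "prune_config")
}

#' Sliding-window LD pruning
#'
#' Within each window of `window_sites` sites (advanced by `step_sites`
#' within each contig, sites in position order), pairs of retained sites
#' with squared Pearson correlation of dosages above `r2_max` are broken
#' by removing the member with the smaller minor allele frequency (ties:
#' the later position). Pairs are visited in position order until no
#' offending pair remains; a zero-variance site has r2 defined as 0 and
#' is never removed on correlation grounds.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param cfg a [prune_config()].
#' @return integer vector of retained site indices (ascending).
#' @export
ld_prune <- function(gm, cfg = prune_config()) {
  maf <- site_freq(gm)$maf
  removed <- rep(FALSE, n_sites(gm))
  for (ct in unique(gm$sites$contig)) {
    idx <- which(gm$sites$contig == ct)
    idx <- idx[order(gm$sites$pos[idx])]
    n <- length(idx)
    starts <- if (n <= cfg$window_sites) 1L
              else unique(c(seq.int(1L, n - cfg$window_sites + 1L,
                                    by = cfg$step_sites),
                            n - cfg$window_sites + 1L))
    for (s in starts) {
      w <- idx[s:min(s + cfg$window_sites - 1L, n)]
      removed <- prune_window(gm$dosage, w, removed, maf, cfg$r2_max)
    }
  }
  which(!removed)
}

# greedy within-window pass; mutates and returns the removed mask
prune_window <- function(dosage, w, removed, maf, r2_max) {
  live <- w[!removed[w]]
  if (length(live) < 2) return(removed)
  x <- dosage[live, , drop = FALSE]
  storage.mode(x) <- "double"
  r <- suppressWarnings(cor(t(x), use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r2 <- r^2
  diag(r2) <- 0
  alive <- rep(TRUE, length(live))
  repeat {
    pair <- NULL
    for (i in seq_along(live)) {
      if (!alive[i]) next
      js <- which(alive & r2[i, ] > r2_max)
      js <- js[js > i]
      if (length(js)) { pair <- c(i, js[1]); break }
    }
    if (is.null(pair)) break
    mi <- maf[live[pair]]
    drop_local <- if (mi[1] < mi[2]) pair[1]
                  else if (mi[2] < mi[1]) pair[2]
                  else pair[2]  # tie: later position
    alive[drop_local] <- FALSE
  }
  removed[live[!alive]] <- TRUE
  removed
}

#' Genotype principal components analysis
#'
#' Missing dosages are mean-imputed per site, each site is centered and
#' scaled by `sqrt(2 p (1 - p))` (expected heterozygosity), and scores
#' are taken from a truncated singular-value decomposition. The sign of
#' each component is fixed by making its largest-magnitude site loading
#' positive.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param n_components number of components
#'   (`<= min(n_samples - 1, n_sites)`).
#' @param scale_het scale by expected heterozygosity (default); set
#'   `FALSE` for centered-only PCA.
#' @return list with `scores` (samples x components),
#'   `explained` (variance fractions) and `loadings` (sites x
#'   components).
#' @export
pca_genotypes <- function(gm, n_components = 10L, scale_het = TRUE) {
  n <- n_samples(gm)
  m <- n_sites(gm)
  if (n_components > min(n - 1L, m))
    stop("n_components exceeds min(n_samples - 1, n_sites)")
  X <- standardize_dosage(gm, scale_het)
  sv <- svd(X, nu = n_components, nv = n_components)
  # deterministic sign: largest-magnitude loading positive
  for (k in seq_len(n_components)) {
    v <- sv$v[, k]
    s <- sign(v[which.max(abs(v))])
    if (s < 0) { sv$v[, k] <- -v; sv$u[, k] <- -sv$u[, k] }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(gm$samples, paste0("PC", seq_len(n_components)))
  list(scores = scores,
       explained = sv$d[seq_len(n_components)]^2 / sum(sv$d^2),
       loadings = sv$v)
}

# samples x sites matrix: mean-imputed, centered, optionally scaled by
# sqrt(2 p q); zero-variance columns become 0
standardize_dosage <- function(gm, scale_het = TRUE) {
  X <- t(gm$dosage)
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  naX <- is.na(X)
  if (any(naX)) X[naX] <- mu[col(X)[naX]]
  X <- sweep(X, 2, mu)
  if (scale_het) {
    p <- mu / 2
    sc <- sqrt(2 * p * (1 - p))
    sc[sc < 1e-12] <- 1
    X <- sweep(X, 2, sc, "/")
  }
  X
}

#' Flag putative non-native individuals
#'
#' Within each district the dominant ancestry component is the one with
#' the largest per-district median of the Q matrix (the median is robust
#' to the very individuals being flagged). A sample's aberrant fraction
#' is `1 - Q[sample, dominant]`; samples with aberrant fraction at or
#' above `threshold` are flagged and should be excluded from the scans.
#'
#' @param q ancestry matrix, samples x K, rows summing to 1 (see
#'   [read_qmatrix()]).
#' @param popmap population map with a `district` column; rows align
#'   with `rownames(q)` via the `sample` column.
#' @param threshold flagging threshold on the aberrant fraction.
#' @return data.frame with `sample`, `district`, `dominant_component`,
#'   `aberrant_fraction`, `flagged`.
#' @export
flag_putative_nonnative <- function(q, popmap, threshold = 0.28) {
  stopifnot(nrow(q) == nrow(popmap))
  ord <- match(popmap$sample, rownames(q))
  if (any(is.na(ord))) stop("Q matrix rows do not cover the population map")
  q <- q[ord, , drop = FALSE]
  if (any(abs(rowSums(q) - 1) > 1e-6)) stop("Q rows must sum to 1")
  out <- data.frame(sample = popmap$sample, district = popmap$district,
                    dominant_component = NA_integer_,
                    aberrant_fraction = NA_real_, flagged = NA)
  for (d in unique(popmap$district)) {
    rows <- which(popmap$district == d)
    if (length(rows) < 2)
      warning("district ", d, " has < 2 samples; dominant component from ",
              "a single row")
    med <- apply(q[rows, , drop = FALSE], 2, median)
    dom <- which.max(med)
    ab <- 1 - q[rows, dom]
    out$dominant_component[rows] <- dom
    out$aberrant_fraction[rows] <- ab
    out$flagged[rows] <- ab >= threshold - 1e-12
  }
  out
}
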