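#' Pairwise r-squared between two sites
#'
#' Composite (genotype-correlation) LD for unphased diploids: the squared
#' Pearson correlation of ALT-dosage codes over jointly non-missing samples.
#' Symmetric in its arguments and invariant to allele relabelling.
#'
#' @param genotypes_a,genotypes_b dosage vectors (0/1/2, `NA` = missing).
#' @return r2 in `[0, 1]`; `NA` with attribute `reason` when either site is
#'   monomorphic after intersecting the missing data.
#' @export
pairwise_r2 <- function(genotypes_a, genotypes_b) {
  ok <- !is.na(genotypes_a) & !is.na(genotypes_b)
  a <- genotypes_a[ok]; b <- genotypes_b[ok]
  if (length(a) < 2L || stats::var(a) == 0 || stats::var(b) == 0)
    return(structure(NA_real_, reason = "monomorphic after missing-data intersection"))
  stats::cor(a, b)^2
}

#' Linkage-disequilibrium decay curve
#'
#' Aggregates r2 for all intra-chromosomal site pairs within `max_dist` into
#' half-open distance bins `[lo, hi)`. Site filters mirror the conventional
#' genotype-mode LD-decay settings: maximum missing-call fraction 0.5, minimum
#' MAF 0.05, maximum pair distance 100 kb.
#'
#' @param table a `variant_table`.
#' @param max_dist maximum pair distance in bp.
#' @param maf_min,miss_max per-site filters applied before pairing.
#' @param bin_width bin width in bp.
#' @return an `ld_decay_curve`: data.frame `bin_lo`, `bin_hi`, `mid`,
#'   `n_pairs`, `mean_r2` (mean undefined for empty bins), with the settings
#'   stored as attributes.
#' @export
ld_decay <- function(table, max_dist = 1e5, maf_min = 0.05, miss_max = 0.5,
                     bin_width = 100) {
  st <- compute_site_stats(table)
  keep <- st$defined & !is.na(st$maf) & st$maf >= maf_min &
    st$missing_rate <= miss_max & is_biallelic_snp(table)
  d <- dosage(table)
  breaks <- seq(0, max_dist + bin_width, by = bin_width)
  nb <- length(breaks) - 1L
  sums <- numeric(nb); counts <- integer(nb)
  for (ch in unique(table$sites$chrom)) {
    idx <- which(keep & table$sites$chrom == ch)
    if (length(idx) < 2L) next
    pos <- table$sites$pos[idx]
    r2 <- suppressWarnings(
      stats::cor(t(d[idx, , drop = FALSE]), use = "pairwise.complete.obs")^2)
    pd <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(pd)
    sel <- ut & pd <= max_dist & !is.na(r2)
    if (!any(sel)) next
    bin <- findInterval(pd[sel], breaks, rightmost.closed = FALSE,
                        left.open = FALSE)
    tb <- tapply(r2[sel], bin, sum)   # half-open [lo, hi) bins
    cb <- table(bin)
    ii <- as.integer(names(tb))
    sums[ii] <- sums[ii] + as.numeric(tb)
    counts[ii] <- counts[ii] + as.integer(cb)
  }
  curve <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                      mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                      n_pairs = counts,
                      mean_r2 = ifelse(counts > 0, sums / pmax(counts, 1),
                                       NA_real_))
  curve <- curve[curve$bin_lo < max_dist, , drop = FALSE]
  structure(curve, class = c("ld_decay_curve", "data.frame"),
            max_dist = max_dist, bin_width = bin_width)
}

#' Half-maximum LD decay distance
#'
#' The physical distance at which mean r2 drops to half its maximum: the
#' curve is scanned for the first crossing of half the maximum bin mean, with
#' linear interpolation between the flanking bin midpoints. `reference =
#' "first"` uses the shortest-distance bin instead of the global maximum (the
#' two coincide for monotone curves).
#'
#' @param curve an [ld_decay()] curve.
#' @param reference `"global"` (default) or `"first"`.
#' @return distance in bp; `Inf` with attribute `note = "> max_dist"` when the
#'   curve never drops below half-maximum within the curve's range.
#' @export
half_max_decay_distance <- function(curve, reference = c("global", "first")) {
  reference <- match.arg(reference)
  cc <- curve[!is.na(curve$mean_r2), , drop = FALSE]
  if (!nrow(cc)) stop("curve has no defined bins")
  maxr <- if (reference == "global") max(cc$mean_r2) else cc$mean_r2[1]
  half <- maxr / 2
  below <- which(cc$mean_r2 <= half)
  if (!length(below))
    return(structure(Inf, note = "> max_dist"))
  i <- below[1]
  if (i == 1L) return(cc$mid[1])
  # linear interpolation between the flanking bin midpoints
  x0 <- cc$mid[i - 1L]; y0 <- cc$mean_r2[i - 1L]
  x1 <- cc$mid[i]; y1 <- cc$mean_r2[i]
  if (y0 == y1) return(x1)
  x0 + (y0 - half) / (y0 - y1) * (x1 - x0)
}

#' Kinship matrix
#'
#' Sample-by-sample relatedness used as the random-effect covariance of the
#' mixed-model association scan. `"bn"` (default) is the Balding-Nichols-style
#' standardised relationship matrix: dosages centred by `2p` and scaled by
#' `sqrt(2 p (1-p))` per site, averaged with pairwise-complete denominators.
#' `"grm"` is the VanRaden centred relationship matrix; `"ibs"` is mean
#' identity-by-state.
#'
#' @param table a `variant_table`.
#' @param method `"bn"`, `"grm"` or `"ibs"`.
#' @return symmetric numeric matrix with sample dimnames and attribute
#'   `method`.
#' @export
kinship_matrix <- function(table, method = c("bn", "grm", "ibs")) {
  method <- match.arg(method)
  if (n_samples(table) < 2L) stop("need at least two samples")
  x <- t(dosage(table))                        # samples x sites
  all_miss <- rowSums(!is.na(x)) == 0L
  if (any(all_miss))
    stop("sample(s) with all calls missing: ",
         paste(table$samples[all_miss], collapse = ", "))
  p <- colMeans(x, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  x <- x[, poly, drop = FALSE]; p <- p[poly]
  if (!ncol(x)) stop("no polymorphic sites")
  ind <- (!is.na(x)) * 1
  npair <- ind %*% t(ind)
  K <- switch(method,
    bn = {
      z <- sweep(x, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = nrow(x))
      z[is.na(z)] <- 0
      (z %*% t(z)) / npair
    },
    grm = {
      z <- sweep(x, 2, 2 * p)
      z[is.na(z)] <- 0
      denom <- ind %*% (2 * p * (1 - p) * t(ind))
      (z %*% t(z)) / denom
    },
    ibs = {
      x0 <- x; x0[is.na(x0)] <- 0
      # mean of 1 - |xi - xj| / 2 over jointly typed sites
      sq <- (x0^2) %*% t(ind) + ind %*% t(x0^2) - 2 * x0 %*% t(x0)
      # |xi-xj| for dosages in {0,1,2}: |d| = d^2 when d in {-1,0,1}; split |2|
      both2 <- ((x0 == 2) * ind) %*% t((x0 == 0) * ind) +
        ((x0 == 0) * ind) %*% t((x0 == 2) * ind)
      absdiff <- sq - 2 * both2   # d^2 - 2 for |d| = 2 pairs
      1 - absdiff / (2 * npair)
    })
  dimnames(K) <- list(table$samples, table$samples)
  K <- (K + t(K)) / 2
  attr(K, "method") <- method
  K
}

# Shift the spectrum so the matrix is numerically PSD (floor at -tol).
psd_adjust <- function(K, tol = 1e-8) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lo <- min(ev)
  if (lo < -tol) K <- K + diag(-lo + tol, nrow(K))
  K
}

#' Principal components of the genotype matrix
#'
#' Eigendecomposition of the standardised genotype covariance (structure
#' covariates / diagnostic plumbing). Missing dosages are mean-imputed and
#' monomorphic sites dropped. Component signs are fixed by forcing the
#' largest-magnitude site loading positive, so results are deterministic.
#'
#' @param table a `variant_table` (ideally LD-pruned).
#' @param n_components components to return.
#' @return list with `scores` (samples x components), `variance_explained`,
#'   `values` (eigenvalues).
#' @export
pca_genotypes <- function(table, n_components = 10) {
  x <- t(dosage(table))
  p <- colMeans(x, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1 & !is.na(p)
  x <- x[, keep, drop = FALSE]; p <- p[keep]
  if (n_components > min(dim(x)))
    stop("n_components exceeds min(samples, sites)")
  z <- sweep(x, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = nrow(x))
  z[is.na(z)] <- 0
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  k <- n_components
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sign(rot[which.max(abs(rot[, j])), j])
    if (s < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
  }
  rownames(scores) <- table$samples
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, variance_explained = ve[seq_len(k)],
       values = pc$sdev[seq_len(k)]^2)
}
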