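#' Fit the single-random-effect null mixed model (REML)
#'
#' The association scan's variance components come from the null model
#' `y = X b + u + e` with `Var(u) = sg2 K`, `Var(e) = se2 I`, estimated once
#' by restricted maximum likelihood. One spectral decomposition of the
#' projected kinship reduces REML to a one-dimensional optimisation of the
#' variance ratio `delta = se2 / sg2`, the classical efficient mixed-model
#' formulation.
#'
#' @param phenotype named numeric vector (one value per sample).
#' @param kinship sample x sample matrix; PSD-adjusted internally.
#' @param covariates optional matrix of fixed covariates (intercept added
#'   automatically).
#' @return list with `sigma_g2`, `sigma_e2`, `delta`, `h2` (pseudo-
#'   heritability `sg2 / (sg2 + se2)`), `boundary` flag, and the spectral
#'   pieces reused by [association_scan()].
#' @export
fit_null_model <- function(phenotype, kinship, covariates = NULL) {
  y <- phenotype
  if (anyNA(y) || any(!is.finite(y))) stop("non-finite phenotype values")
  n <- length(y)
  if (!is.null(names(y)))
    kinship <- kinship[names(y), names(y), drop = FALSE]
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  q <- ncol(X)
  if (n < q + 2L) stop("too few samples for the covariate count")
  K <- psd_adjust(unclass(as.matrix(kinship)))

  # restricted likelihood: project out X, decompose the projected kinship
  qrX <- qr(X)
  Qc <- qr.Q(qrX, complete = TRUE)[, (q + 1L):n, drop = FALSE]  # n x (n-q)
  KP <- crossprod(Qc, K %*% Qc)
  ep <- eigen((KP + t(KP)) / 2, symmetric = TRUE)
  xi <- pmax(ep$values, 0)
  eta <- as.vector(crossprod(ep$vectors, crossprod(Qc, y)))
  nq <- n - q

  negll <- function(log_delta) {
    d <- exp(log_delta)
    denom <- xi + d
    0.5 * (nq * log(sum(eta^2 / denom)) + sum(log(denom)))
  }
  grid <- seq(-12, 12, length.out = 25)
  vals <- vapply(grid, negll, numeric(1))
  i0 <- which.min(vals)
  lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(negll, c(lo, hi))
  delta <- exp(opt$minimum)
  boundary <- opt$minimum <= grid[1] + 1e-6 || opt$minimum >= grid[length(grid)] - 1e-6

  sigma_g2 <- sum(eta^2 / (xi + delta)) / nq
  sigma_e2 <- sigma_g2 * delta
  list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
       h2 = 1 / (1 + delta), boundary = boundary,
       K = K, X = X, y = y)
}

#' Kinship-corrected association scan
#'
#' EMMAX-style approximation: variance components are fixed from the null
#' model, then every site is tested by generalised least squares after
#' whitening phenotype, covariates and genotypes with `V^(-1/2)`,
#' `V = sg2 K + se2 I`. Missing genotypes are mean-imputed per site for the
#' test only (never for LD or parentage). With an identity kinship the test
#' reduces exactly to ordinary least squares.
#'
#' @param table a `variant_table`.
#' @param phenotype named numeric vector over (a subset of) the samples.
#' @param kinship sample x sample matrix.
#' @param covariates optional fixed-covariate matrix.
#' @return an `association_result` data.frame ordered by position: `chrom`,
#'   `pos`, `id`, `beta`, `se`, `stat`, `p`, `note`; variance components and
#'   pseudo-heritability in attributes `vc`.
#' @export
association_scan <- function(table, phenotype, kinship, covariates = NULL) {
  samples <- names(phenotype) %||% table$samples
  tab <- if (identical(samples, table$samples)) table
         else subset_variants(table, samples = samples)
  null <- fit_null_model(phenotype, kinship, covariates)
  n <- length(phenotype); q <- ncol(null$X)

  V <- null$sigma_g2 * null$K + null$sigma_e2 * diag(n)
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
  W <- ev$vectors %*% (t(ev$vectors) / sqrt(pmax(ev$values, 1e-12)))  # V^(-1/2)
  ys <- as.vector(W %*% null$y)
  Xs <- W %*% null$X

  Gm <- dosage(tab)                      # sites x samples
  p_alt <- rowMeans(Gm, na.rm = TRUE) / 2
  mono <- is.na(p_alt) | p_alt == 0 | p_alt == 1
  mu <- rowMeans(Gm, na.rm = TRUE)
  miss <- is.na(Gm)
  Gm[miss] <- mu[row(Gm)[miss]]          # per-site mean imputation, scan only
  Gs <- Gm %*% t(W)                      # sites x samples, whitened

  # project out whitened covariates
  qrX <- qr(Xs)
  resid_y <- stats::resid(stats::lm.fit(Xs, ys))
  Gt <- Gs - t(qr.fitted(qrX, t(Gs)))
  gg <- rowSums(Gt^2)
  gy <- as.vector(Gt %*% resid_y)
  beta <- gy / gg
  df <- n - q - 1L
  rss <- sum(resid_y^2) - beta * gy
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gg)
  stat <- beta / se
  p <- 2 * stats::pt(-abs(stat), df)
  note <- rep(NA_character_, nrow(Gm))
  beta[mono] <- se[mono] <- stat[mono] <- p[mono] <- NA_real_
  note[mono] <- "monomorphic"
  out <- data.frame(chrom = tab$sites$chrom, pos = tab$sites$pos,
                    id = tab$sites$id, beta = beta, se = se, stat = stat,
                    p = p, note = note, stringsAsFactors = FALSE)
  structure(out, class = c("association_result", "data.frame"),
            vc = list(sigma_g2 = null$sigma_g2, sigma_e2 = null$sigma_e2,
                      h2 = null$h2, boundary = null$boundary))
}

#' Effective marker number and genome-wide threshold
#'
#' Estimates the number of independent tests from the LD structure by the
#' eigenvalue method: per chromosome, the effective number is
#' `sum(f(lambda))` with `f(x) = I(x >= 1) + (x - floor(x))` over the
#' eigenvalues of the dosage correlation matrix; chromosome contributions are
#' summed and the genome-wide significance threshold is `1 / Me`. The
#' `annotate_threshold` default (1.05e-5) is carried along for report
#' annotation only.
#'
#' @param table a `variant_table`.
#' @param annotate_threshold reference threshold echoed in the result.
#' @return list with `me`, `threshold` (= 1/me), `per_chromosome`,
#'   `annotate_threshold`.
#' @export
effective_marker_threshold <- function(table, annotate_threshold = 1.05e-5) {
  d <- dosage(table)
  per <- vapply(unique(table$sites$chrom), function(ch) {
    rows <- which(table$sites$chrom == ch)
    x <- d[rows, , drop = FALSE]
    v <- apply(x, 1, stats::var, na.rm = TRUE)
    x <- x[!is.na(v) & v > 0, , drop = FALSE]
    if (nrow(x) == 0L) return(0)
    if (nrow(x) == 1L) return(1)
    r <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
    r[is.na(r)] <- 0; diag(r) <- 1
    lam <- pmax(eigen((r + t(r)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values, 0)
    lam <- round(lam, 9)   # guard floor() against 4 - 1e-15 style noise
    sum((lam >= 1) + (lam - floor(lam)))
  }, numeric(1))
  me <- sum(per)
  list(me = me, threshold = 1 / me, per_chromosome = per,
       annotate_threshold = annotate_threshold)
}

#' LD-based QTL clumping of an association scan
#'
#' Implements the region-merging rule used for metabolite QTL reporting:
#' lead SNPs (p below `lead_p`) are processed in ascending p; supporting
#' variants with p below `support_p` (default 0.001), within `window` bp of
#' the lead (default 500 kb) and with r2 above `r2_min` (default 0.1) against
#' the lead are merged into an initial region, each support assigned to the
#' first eligible lead. Regions must harbour at least `min_snps` SNPs (lead
#' included; default 2). The initial span (min-max member positions) is then
#' extended by `extension` bp each side (default 100 kb), floored at
#' position 1, and overlapping extended regions for the same trait are merged.
#'
#' @param assoc an `association_result`.
#' @param table the `variant_table` the scan was run on (for LD with leads;
#'   missing genotypes are never imputed here).
#' @param lead_p lead significance threshold (e.g. `1 / Me`).
#' @param support_p,window,r2_min,min_snps,extension rule parameters.
#' @param trait trait label recorded on the regions.
#' @return a `qtl_regions` object: data.frame `trait`, `chrom`, `start`,
#'   `end`, `lead_id`, `lead_p`, `n_members`, with per-region member tables
#'   (id, p, r2 with lead) in attribute `members`.
#' @export
clump_qtl <- function(assoc, table, lead_p, support_p = 1e-3, window = 5e5,
                      r2_min = 0.1, min_snps = 2, extension = 1e5,
                      trait = "trait") {
  stopifnot(all(assoc$id %in% table$sites$id))
  d <- dosage(table)
  rownames(d) <- table$sites$id
  a <- assoc[!is.na(assoc$p), , drop = FALSE]
  leads <- a[a$p < lead_p, , drop = FALSE]
  leads <- leads[order(leads$p), , drop = FALSE]
  assigned <- character(0)
  regions <- list(); members <- list()
  for (i in seq_len(nrow(leads))) {
    lid <- leads$id[i]
    if (lid %in% assigned) next
    cand <- a[a$chrom == leads$chrom[i] & a$p < support_p &
                abs(a$pos - leads$pos[i]) <= window &
                !(a$id %in% assigned) & a$id != lid, , drop = FALSE]
    r2 <- vapply(cand$id, function(sid)
      as.numeric(pairwise_r2(d[lid, ], d[sid, ])), numeric(1))
    cand <- cand[!is.na(r2) & r2 > r2_min, , drop = FALSE]
    r2 <- r2[!is.na(r2) & r2 > r2_min]
    mem <- rbind(
      data.frame(id = lid, p = leads$p[i], r2 = 1, pos = leads$pos[i],
                 stringsAsFactors = FALSE),
      if (nrow(cand)) data.frame(id = cand$id, p = cand$p, r2 = r2,
                                 pos = cand$pos, stringsAsFactors = FALSE))
    if (nrow(mem) < min_snps) next     # lead stays available as a support
    assigned <- c(assigned, mem$id)
    regions[[length(regions) + 1L]] <- data.frame(
      trait = trait, chrom = leads$chrom[i],
      start = max(1, min(mem$pos) - extension),
      end = max(mem$pos) + extension,
      lead_id = lid, lead_p = leads$p[i], n_members = nrow(mem),
      stringsAsFactors = FALSE)
    members[[length(members) + 1L]] <- mem
  }
  if (!length(regions)) {
    out <- data.frame(trait = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      lead_id = character(), lead_p = numeric(),
                      n_members = integer(), stringsAsFactors = FALSE)
    return(structure(out, class = c("qtl_regions", "data.frame"),
                     members = list()))
  }
  reg <- do.call(rbind, regions)
  # merge overlapping extended regions of the same trait
  ord <- order(reg$chrom, reg$start)
  reg <- reg[ord, , drop = FALSE]; members <- members[ord]
  merged <- list(); mmem <- list()
  for (i in seq_len(nrow(reg))) {
    last <- length(merged)
    if (last > 0 && merged[[last]]$chrom == reg$chrom[i] &&
        reg$start[i] <= merged[[last]]$end) {
      merged[[last]]$end <- max(merged[[last]]$end, reg$end[i])
      if (reg$lead_p[i] < merged[[last]]$lead_p) {
        merged[[last]]$lead_id <- reg$lead_id[i]
        merged[[last]]$lead_p <- reg$lead_p[i]
      }
      mmem[[last]] <- rbind(mmem[[last]], members[[i]])
      merged[[last]]$n_members <- nrow(mmem[[last]])
    } else {
      merged[[last + 1L]] <- reg[i, , drop = FALSE]
      mmem[[last + 1L]] <- members[[i]]
    }
  }
  out <- do.call(rbind, lapply(merged, as.data.frame))
  rownames(out) <- NULL
  structure(out, class = c("qtl_regions", "data.frame"), members = mmem)
}
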