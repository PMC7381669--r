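# Structured two-subpop panel with a kinship-matched polygenic phenotype.
structured_panel <- function(n = 150, m = 400, h2 = 0.5, seed = 1) {
  cfg <- sim_config(n_founders = n, n_offspring = 0, n_subpops = 2,
                    fst = 0.25, admixture = 0, n_chromosomes = 2,
                    sites_per_chromosome = m / 2, chromosome_length = 5e6,
                    recombination_rate = 1e-3,   # near-independent sites
                    missing_rate = 0, genotyping_error = 0, seed = seed)
  fo <- simulate_founders(cfg)
  K <- kinship_matrix(fo$table, method = "bn")
  Ka <- teapop:::psd_adjust(K)
  ek <- eigen(Ka, symmetric = TRUE)
  set.seed(seed + 1)
  u <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * rnorm(n))
  y <- sqrt(h2) * as.vector(u) / stats::sd(u) + sqrt(1 - h2) * rnorm(n)
  names(y) <- fo$table$samples
  list(table = fo$table, K = K, y = y, truth = fo$truth)
}

test_that("with identity kinship the scan reduces to OLS", {
  pop <- small_population()
  tab <- pop$table
  y <- phenotype_vector(pop$phenotypes, "EGCG", "YL")[tab$samples]
  K <- diag(n_samples(tab))
  dimnames(K) <- list(tab$samples, tab$samples)
  scan <- association_scan(tab, y, K)
  d <- dosage(tab)
  mu <- rowMeans(d, na.rm = TRUE)
  idx <- which(!is.na(scan$p))[1:50]
  for (i in idx) {
    g <- d[i, ]; g[is.na(g)] <- mu[i]
    ols <- summary(stats::lm(y ~ g))$coefficients
    expect_equal(scan$p[i], ols["g", "Pr(>|t|)"], tolerance = 1e-8)
    expect_equal(scan$beta[i], ols["g", "Estimate"], tolerance = 1e-8)
  }
})

test_that("null heritability is estimated at the boundary", {
  set.seed(17)
  panel <- structured_panel(n = 120, m = 200, seed = 31)
  y <- rnorm(120)                      # no genetic signal at all
  names(y) <- panel$table$samples
  fit <- fit_null_model(y, panel$K)
  expect_lt(fit$h2, 0.15)
})

test_that("identity kinship collapses to a single-variance model", {
  set.seed(4)
  y <- rnorm(80)
  K <- diag(80); dimnames(K) <- list(paste0("s", 1:80), paste0("s", 1:80))
  names(y) <- rownames(K)
  fit <- fit_null_model(y, K)
  expect_equal(fit$sigma_g2 + fit$sigma_e2, stats::var(y), tolerance = 1e-6)
})

test_that("pseudo-heritability is recovered at h2 = 0.5", {
  h2s <- vapply(1:12, function(r) {
    panel <- structured_panel(n = 150, m = 200, h2 = 0.5, seed = 900 + r)
    fit_null_model(panel$y, panel$K)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2s) - 0.5), 0.1)
})

test_that("null scans are calibrated with the correct kinship, inflated without", {
  panel <- structured_panel(n = 150, m = 500, h2 = 0.5, seed = 61)
  scan_k <- association_scan(panel$table, panel$y, panel$K)
  p_k <- scan_k$p[!is.na(scan_k$p)]
  n_test <- length(p_k)
  hits <- sum(p_k < 0.05)
  ci <- stats::qbinom(c(0.025, 0.975), n_test, 0.05)
  expect_gte(hits, ci[1]); expect_lte(hits, ci[2])
  I <- diag(nrow(panel$K)); dimnames(I) <- dimnames(panel$K)
  scan_i <- association_scan(panel$table, panel$y, I)
  hits_i <- sum(scan_i$p[!is.na(scan_i$p)] < 0.05)
  expect_gt(hits_i, hits)
  expect_gt(hits_i, ci[2])
})

test_that("a planted QTL attains its chromosome's minimum p", {
  wins <- 0
  for (r in 1:10) {
    cfg <- sim_config(n_founders = 150, n_offspring = 0, n_subpops = 2,
                      fst = 0.15, n_chromosomes = 2,
                      sites_per_chromosome = 150, missing_rate = 0,
                      genotyping_error = 0, seed = 700 + r)
    fo <- simulate_founders(cfg)
    K <- kinship_matrix(fo$table, method = "bn")
    ph <- simulate_phenotypes(fo$table, fo$truth, kinship = K,
                              n_traits = 1, n_qtls_per_trait = 1,
                              effect_size = 1.3, polygenic_var = 0.3,
                              noise_sd = 1, seed = 800 + r)
    y <- phenotype_vector(ph$phenotypes, "EGCG", "YL")[fo$table$samples]
    scan <- association_scan(fo$table, y, K)
    qtl <- ph$truth$planted_qtls$site_id[1]
    chrom <- scan$chrom[scan$id == qtl]
    on_chr <- scan[scan$chrom == chrom & !is.na(scan$p), ]
    best <- on_chr$id[which.min(on_chr$p)]
    # count a win when the causal site is the top hit or in perfect LD with it
    r2 <- pairwise_r2(dosage(fo$table)[qtl, ], dosage(fo$table)[best, ])
    wins <- wins + (best == qtl || (!is.na(r2) && r2 > 0.8))
  }
  expect_gte(wins, 9)
})

test_that("scan p-values are invariant under affine phenotype transforms", {
  panel <- structured_panel(n = 100, m = 150, seed = 5)
  s1 <- association_scan(panel$table, panel$y, panel$K)
  s2 <- association_scan(panel$table, 3 * panel$y + 5, panel$K)
  expect_equal(s1$p, s2$p, tolerance = 1e-10)
})

test_that("effective marker number: redundancy, independence and threshold", {
  g <- c(0, 1, 2, 0, 1, 2, 1, 0, 2, 1)
  tab <- toy_table(rbind(g, g, g, g))
  me <- effective_marker_threshold(tab)
  expect_equal(me$me, 1)
  expect_equal(me$threshold, 1)
  set.seed(8)
  ind <- toy_table(matrix(rbinom(100 * 1500, 2, 0.5), nrow = 100))
  me2 <- effective_marker_threshold(ind)
  expect_lt(abs(me2$me - 100) / 100, 0.05)
  expect_equal(me2$threshold, 1 / me2$me)
  expect_equal(me$annotate_threshold, 1.05e-5)
})

test_that("QTL clumping matches hand enumeration on the 8-site toy", {
  # two independent haplotype blocks 100 kb apart plus isolated sites
  set.seed(2)
  n <- 60
  block1 <- rbinom(n, 2, 0.5)
  block2 <- rbinom(n, 2, 0.5)
  noise <- function() rbinom(n, 2, 0.5)
  dos <- rbind(block1,                       # s1 lead, p tiny
               block1,                       # s2 support (r2 = 1)
               noise(),                      # s3 low p but r2 ~ 0 with s1
               block1,                       # s4 support
               noise(),                      # s5 p too large
               block2,                       # s6 second lead
               block2,                       # s7 support of s6
               noise())                      # s8 far beyond the window
  pos <- c(1e5, 1.5e5, 2e5, 2.5e5, 3e5, 9e5, 9.5e5, 2.0e6)
  tab <- toy_table(dos, pos = pos)
  assoc <- data.frame(chrom = "chr01", pos = pos,
                      id = sprintf("s%03d", 1:8),
                      beta = 1, se = 1, stat = 1,
                      p = c(1e-8, 5e-4, 8e-4, 9e-4, 0.02,
                            1e-6, 4e-4, 1e-7),
                      note = NA, stringsAsFactors = FALSE)
  regions <- clump_qtl(assoc, tab, lead_p = 1e-5, support_p = 1e-3,
                       window = 5e5, r2_min = 0.1, min_snps = 2,
                       extension = 1e5)
  # manual application: lead s1 (p 1e-8) takes s2 and s4 (r2 = 1, within
  # 500 kb, p < 1e-3); s3 fails the r2 rule; span 100-250 kb -> 0-350 kb
  # after extension. Lead s8 (p 1e-7) has no eligible support -> dropped.
  # Lead s6 takes s7: span 900-950 kb -> 800 kb-1.05 Mb.
  expect_equal(nrow(regions), 2L)
  r1 <- regions[regions$lead_id == "s001", ]
  expect_equal(r1$start, 1)            # 1e5 - 1e5 floored at 1
  expect_equal(r1$end, 3.5e5)
  expect_equal(r1$n_members, 3L)
  r2_ <- regions[regions$lead_id == "s006", ]
  expect_equal(r2_$start, 8e5)
  expect_equal(r2_$end, 1.05e6)
  expect_equal(r2_$n_members, 2L)
  mem <- attr(regions, "members")
  for (k in seq_along(mem)) {
    m <- mem[[k]]
    expect_true(all(m$p < 1e-3))
    expect_true(all(m$r2 > 0.1))
    expect_true(all(abs(m$pos - m$pos[1]) <= 5e5))
  }
})

test_that("a zero-width region is handled with extension 0", {
  n <- 40
  set.seed(6)
  g <- rbinom(n, 2, 0.5)
  dos <- rbind(g, g)
  tab <- toy_table(dos, pos = c(5000, 5001))   # adjacent records, ~one locus
  assoc <- data.frame(chrom = "chr01", pos = tab$sites$pos,
                      id = tab$sites$id, beta = 1, se = 1, stat = 1,
                      p = c(1e-8, 5e-4), note = NA)
  reg <- clump_qtl(assoc, tab, lead_p = 1e-5, extension = 0)
  expect_equal(reg$start, 5000)
  expect_equal(reg$end, 5001)
})

test_that("a lead without eligible support emits no region", {
  n <- 40
  set.seed(7)
  dos <- rbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.5))
  tab <- toy_table(dos, pos = c(1000, 2000))
  assoc <- data.frame(chrom = "chr01", pos = c(1000, 2000),
                      id = tab$sites$id, beta = 1, se = 1, stat = 1,
                      p = c(1e-9, 0.5), note = NA)
  reg <- clump_qtl(assoc, tab, lead_p = 1e-5)
  expect_equal(nrow(reg), 0L)
})
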