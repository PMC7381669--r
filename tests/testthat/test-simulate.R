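test_that("configuration validation rejects bad counts and fractions", {
  expect_error(sim_config(n_founders = 0), "positive count")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(missing_rate = 1.2), "fraction")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("the same seed reproduces byte-identical simulations", {
  cfg <- sim_config(n_founders = 30, n_offspring = 5, n_chromosomes = 2,
                    sites_per_chromosome = 80, seed = 99)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("fst = 0 leaves subpopulations undifferentiated", {
  cfg <- sim_config(n_founders = 120, n_offspring = 0, n_subpops = 2,
                    fst = 0, admixture = 0, inbreeding = 0,
                    n_chromosomes = 2, sites_per_chromosome = 400, seed = 5)
  fo <- simulate_founders(cfg)
  d <- dosage(fo$table)
  sp <- fo$truth$subpop_labels
  f1 <- rowMeans(d[, sp == 1], na.rm = TRUE) / 2
  f2 <- rowMeans(d[, sp == 2], na.rm = TRUE) / 2
  expect_lt(mean(abs(f1 - f2)), 0.08)    # pure sampling noise at n = 60/subpop
  expect_lt(abs(hudson_fst(d[, sp == 1], d[, sp == 2])), 0.02)
})

test_that("simulated differentiation matches the Hudson estimator", {
  cfg <- sim_config(n_founders = 200, n_offspring = 0, n_subpops = 2,
                    fst = 0.2, admixture = 0, inbreeding = 0,
                    n_chromosomes = 5, sites_per_chromosome = 2000,
                    recombination_rate = 1e-3,   # near-independent sites
                    seed = 8)
  fo <- simulate_founders(cfg)
  d <- dosage(fo$table)
  sp <- fo$truth$subpop_labels
  fst_hat <- hudson_fst(d[, sp == 1], d[, sp == 2])
  expect_lt(abs(fst_hat - 0.2), 0.05)
})

test_that("default-scale population hits the target heterozygosity", {
  pop <- small_population()
  st <- compute_site_stats(pop$table)
  expect_gt(mean(st$het_rate, na.rm = TRUE), 0.18)
  expect_lt(mean(st$het_rate, na.rm = TRUE), 0.34)
})

test_that("founder allele frequencies fit their generating distribution", {
  # 50 replicate batches, no inbreeding/structure: allele counts binomial
  z2 <- 0; n_tests <- 0
  for (r in 1:50) {
    cfg <- sim_config(n_founders = 40, n_offspring = 0, n_subpops = 1,
                      fst = 0, admixture = 0, inbreeding = 0,
                      n_chromosomes = 1, sites_per_chromosome = 60,
                      recombination_rate = 1e-2, seed = 1000 + r)
    fo <- simulate_founders(cfg)
    p <- fo$truth$p_anc
    cnt <- rowSums(dosage(fo$table))
    z <- (cnt - 80 * p) / sqrt(80 * p * (1 - p))
    z2 <- z2 + sum(z^2); n_tests <- n_tests + length(z)
  }
  gof_p <- stats::pchisq(z2, df = n_tests)
  expect_gt(gof_p, 0.005)
  expect_lt(gof_p, 0.995)
})

test_that("error-free transmission is Mendelian-consistent", {
  cfg <- sim_config(n_founders = 40, n_offspring = 15,
                    genotyping_error = 0, missing_rate = 0,
                    n_chromosomes = 2, sites_per_chromosome = 150, seed = 3)
  fo <- simulate_founders(cfg)
  pe <- simulate_pedigree(fo$table, fo$truth, cfg)
  d <- dosage(pe$table)
  for (i in seq_len(nrow(pe$truth$pedigree_edges))) {
    gp <- d[, pe$truth$pedigree_edges$parent[i]]
    go <- d[, pe$truth$pedigree_edges$offspring[i]]
    expect_equal(sum(abs(gp - go) == 2, na.rm = TRUE), 0L)
  }
})

test_that("unknown parent ids are rejected", {
  cfg <- sim_config(n_founders = 10, seed = 2, n_chromosomes = 1,
                    sites_per_chromosome = 50)
  fo <- simulate_founders(cfg)
  expect_error(
    simulate_pedigree(fo$table, fo$truth, cfg,
                      crosses = data.frame(parent1 = "NOPE", parent2 = NA)),
    "parent id not found")
})

test_that("a large cohort from one cross reproduces the parental mean", {
  cfg <- sim_config(n_founders = 10, genotyping_error = 0, missing_rate = 0,
                    n_chromosomes = 1, sites_per_chromosome = 300, seed = 21)
  fo <- simulate_founders(cfg)
  crosses <- data.frame(parent1 = "ACC001", parent2 = "ACC002")
  crosses <- crosses[rep(1, 200), ]
  pe <- simulate_pedigree(fo$table, fo$truth, cfg, crosses)
  d <- dosage(pe$table)
  off <- grep("^OFF", colnames(d))
  tA <- d[, "ACC001"] / 2; tB <- d[, "ACC002"] / 2
  expected <- (tA + tB) / 2
  se <- sqrt(tA * (1 - tA) + tB * (1 - tB)) / (2 * sqrt(length(off)))
  obs <- rowMeans(d[, off]) / 2
  dev <- abs(obs - expected)
  expect_true(all(dev <= pmax(5 * se, 1e-12)))
})

test_that("opposite-homozygote rate under mistyping matches the closed form", {
  e <- 0.02
  cfg <- sim_config(n_founders = 60, n_offspring = 40,
                    genotyping_error = e, missing_rate = 0,
                    n_chromosomes = 2, sites_per_chromosome = 400, seed = 13)
  fo <- simulate_founders(cfg)
  pe <- simulate_pedigree(fo$table, fo$truth, cfg)
  # per-call dosage transition under "flip one random allele w.p. e"
  M <- rbind(c(1 - e, e, 0),
             c(e / 2, 1 - e, e / 2),
             c(0, e, 1 - e))
  tg <- pe$truth$true_a1 + pe$truth$true_a2
  d <- dosage(pe$table)
  edges <- pe$truth$pedigree_edges
  expected <- 0; observed <- 0; n_calls <- 0
  for (i in seq_len(nrow(edges))) {
    tp <- tg[, edges$parent[i]]; to <- tg[, edges$offspring[i]]
    pr <- M[cbind(tp + 1, 1)] * M[cbind(to + 1, 3)] +
          M[cbind(tp + 1, 3)] * M[cbind(to + 1, 1)]
    expected <- expected + sum(pr)
    op <- d[, edges$parent[i]]; oo <- d[, edges$offspring[i]]
    observed <- observed + sum(abs(op - oo) == 2, na.rm = TRUE)
    n_calls <- n_calls + sum(!is.na(op) & !is.na(oo))
  }
  # observed count within a generous binomial window of the expectation
  expect_lt(abs(observed - expected), 4 * sqrt(expected) + 3)
})

test_that("null phenotypes are pure noise and QTL effects order dosage groups", {
  pop <- small_population()
  blank <- pop$truth
  blank$planted_qtls <- blank$planted_qtls[0, , drop = FALSE]
  null <- simulate_phenotypes(pop$table, blank, kinship = NULL,
                              n_traits = 1, n_qtls_per_trait = 0,
                              polygenic_var = 0, seed = 4)
  y <- phenotype_vector(null$phenotypes, "EGCG", "YL")
  expect_equal(length(y), n_samples(pop$table))
  expect_lt(abs(stats::sd(y) - 1), 0.25)

  one <- simulate_phenotypes(pop$table, blank, kinship = NULL,
                             n_traits = 1, n_qtls_per_trait = 1,
                             effect_size = 1, polygenic_var = 0, seed = 6)
  q <- one$truth$planted_qtls
  g <- dosage(pop$table)[q$site_id[1], ]
  y <- phenotype_vector(one$phenotypes, "EGCG", "YL")[names(g)]
  mg <- tapply(y, g, mean)
  if (q$effect[1] < 0) mg <- rev(mg)
  expect_true(all(diff(mg) > 0))
})

test_that("traits sharing planted QTLs are positively correlated", {
  pop <- small_population()
  ph <- simulate_phenotypes(pop$table, pop$truth, kinship = pop$kinship,
                            n_traits = 4, n_qtls_per_trait = 3,
                            effect_size = 1, polygenic_var = 0.6, seed = 9)
  cm <- compound_correlations(ph$phenotypes)
  off_diag <- cm$YL[upper.tri(cm$YL)]
  expect_gt(mean(off_diag, na.rm = TRUE), 0.1)
})

test_that("fixtures round-trip losslessly and the VCF is well-formed", {
  cfg <- sim_config(n_founders = 12, n_offspring = 3, n_chromosomes = 2,
                    sites_per_chromosome = 40, seed = 17)
  pop <- simulate_population(cfg)
  dir <- withr::local_tempdir()
  files <- write_fixture(pop$table, pop$phenotypes, pop$truth, dir)
  back <- read_vcf(files[["vcf"]])
  expect_identical(dosage(back), dosage(pop$table))
  expect_identical(back$sites$pos, pop$table$sites$pos)
  expect_identical(back$dp, pop$table$dp)
  expect_identical(back$ad_ref, pop$table$ad_ref)
  ped <- utils::read.table(files[["pedigree"]], header = TRUE,
                           stringsAsFactors = FALSE)
  expect_identical(ped$offspring, pop$truth$pedigree_edges$offspring)
  # format conformance via an external VCF-aware validator when available
  bcf <- Sys.which("bcftools")
  if (nzchar(bcf)) {
    status <- system2(bcf, c("view", files[["vcf"]]), stdout = FALSE,
                      stderr = FALSE)
    expect_identical(status, 0L)
  } else {
    header <- readLines(files[["vcf"]], n = 1)
    expect_identical(header, "##fileformat=VCFv4.2")
  }
})
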