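#' Simulation configuration
#'
#' Parameters of the synthetic tea-like population generator. Defaults emulate
#' the scale of a clonally propagated breeding collection: ~220 accessions in 5
#' admixed subpopulations, RNA-seq-derived SNPs whose mean per-site
#' heterozygosity sits near 26%, kilobase-scale LD decay, and a few dozen
#' parent-offspring pairs hidden in the sample.
#'
#' @param n_founders founder accessions placed in the sample.
#' @param n_offspring offspring accessions appended by [simulate_pedigree()];
#'   by default each has one in-sample parent and one unsampled parent, so the
#'   number of true parent-offspring pairs equals `n_offspring`.
#' @param n_subpops number of subpopulations.
#' @param fst Wright's differentiation among subpopulations, in `[0, 1)`;
#'   subpopulation allele frequencies follow the Balding-Nichols beta model
#'   `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency `p`.
#' @param admixture probability that a founder haplotype-chromosome descends
#'   from a random other subpopulation rather than the founder's own.
#' @param n_chromosomes,sites_per_chromosome,chromosome_length genome layout;
#'   site positions are drawn uniformly per chromosome and sorted.
#' @param recombination_rate per-bp rate; controls both the exponential decay of
#'   founder haplotype LD and meiotic recombination in pedigree transmission.
#'   The default puts the half-maximum r2 decay distance in the 5-9 kb range.
#' @param freq_beta_shape shape of the symmetric Beta ancestral site-frequency
#'   distribution (truncated to `[maf_floor, 1-maf_floor]`).
#' @param inbreeding within-subpopulation inbreeding coefficient F_IS:
#'   probability that a founder chromosome pair is autozygous (the second
#'   haplotype copies the first), scaling mean heterozygosity by `1 - F_IS`.
#'   Together with `freq_beta_shape` the default puts mean per-site
#'   heterozygosity near 26%.
#' @param genotyping_error probability a called genotype has one randomly
#'   chosen allele flipped.
#' @param missing_rate probability a call is masked to missing.
#' @param maf_floor truncation bound of the ancestral frequency distribution.
#' @param seed integer; the same seed reproduces byte-identical output.
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_founders = 190, n_offspring = 30, n_subpops = 5,
                       fst = 0.1, admixture = 0.1,
                       n_chromosomes = 5, sites_per_chromosome = 1000,
                       chromosome_length = 2e6, recombination_rate = 5e-5,
                       freq_beta_shape = 0.55, inbreeding = 0.23,
                       genotyping_error = 0.01, missing_rate = 0.02,
                       maf_floor = 0.05, seed = 1L) {
  cfg <- list(n_founders = n_founders, n_offspring = n_offspring,
              n_subpops = n_subpops, fst = fst, admixture = admixture,
              n_chromosomes = n_chromosomes,
              sites_per_chromosome = sites_per_chromosome,
              chromosome_length = chromosome_length,
              recombination_rate = recombination_rate,
              freq_beta_shape = freq_beta_shape, inbreeding = inbreeding,
              genotyping_error = genotyping_error,
              missing_rate = missing_rate, maf_floor = maf_floor,
              seed = as.integer(seed))
  counts <- c("n_founders", "n_subpops", "n_chromosomes",
              "sites_per_chromosome", "chromosome_length")
  for (nm in counts)
    if (length(cfg[[nm]]) != 1L || !is.finite(cfg[[nm]]) || cfg[[nm]] < 1)
      stop("configuration error: ", nm, " must be a positive count")
  if (cfg$n_offspring < 0) stop("configuration error: n_offspring must be >= 0")
  fracs <- c("fst", "admixture", "inbreeding", "genotyping_error",
             "missing_rate", "maf_floor")
  for (nm in fracs)
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("configuration error: ", nm, " must be a fraction in [0, 1]")
  if (cfg$fst >= 1) stop("configuration error: fst must be < 1")
  if (cfg$recombination_rate < 0)
    stop("configuration error: recombination_rate must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# Truncated symmetric Beta(s, s) sampler on [lo, 1-lo] via inverse CDF.
rtruncbeta <- function(n, shape, lo) {
  a <- stats::pbeta(lo, shape, shape)
  b <- stats::pbeta(1 - lo, shape, shape)
  stats::qbeta(stats::runif(n, a, b), shape, shape)
}

# Haplotypes for one chromosome under the first-order Markov latent-Gaussian
# model: a standard-normal AR(1) chain along sites with step correlation
# exp(-rate * gap_bp), thresholded at qnorm(f) so marginal ALT frequencies are
# exact while adjacent-site LD decays exponentially with distance.
sim_haplotypes <- function(pos, thresholds, rate) {
  n_hap <- ncol(thresholds)
  s <- length(pos)
  z <- matrix(0, s, n_hap)
  z[1L, ] <- stats::rnorm(n_hap)
  if (s > 1L) {
    a <- exp(-rate * diff(pos))
    for (i in 2L:s)
      z[i, ] <- a[i - 1L] * z[i - 1L, ] +
        sqrt(1 - a[i - 1L]^2) * stats::rnorm(n_hap)
  }
  (z < thresholds) * 1L
}

#' Simulate founder accessions
#'
#' Draws ancestral allele frequencies from a truncated symmetric Beta
#' distribution, perturbs them per subpopulation under the Balding-Nichols
#' model with variance `fst * p * (1 - p)`, and builds founder haplotypes with
#' a first-order Markov process along each chromosome so that r2 between sites
#' decays exponentially with physical distance. Founders are diploid; each
#' haplotype-chromosome may descend from a non-primary subpopulation with
#' probability `admixture`.
#'
#' @param config a [sim_config()].
#' @return list with elements `table` (a clean [variant_table()], no
#'   genotyping error, missingness or depth fields yet) and `truth` (a
#'   `population_truth` carrying subpopulation labels, haplotypes, and the
#'   generating frequencies).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_founders
    K <- config$n_subpops
    spc <- config$sites_per_chromosome
    m <- config$n_chromosomes * spc

    p_anc <- rtruncbeta(m, config$freq_beta_shape, config$maf_floor)
    fmat <- matrix(0, m, K)  # subpop ALT frequencies
    if (config$fst == 0) {
      fmat[] <- p_anc
    } else {
      ratio <- (1 - config$fst) / config$fst
      for (k in seq_len(K))
        fmat[, k] <- stats::rbeta(m, p_anc * ratio, (1 - p_anc) * ratio)
      # keep sites informative: avoid exactly fixed subpop frequencies
      fmat <- pmin(pmax(fmat, 1e-4), 1 - 1e-4)
    }

    subpop <- sort(rep_len(seq_len(K), n))
    chrom <- rep(sprintf("chr%02d", seq_len(config$n_chromosomes)), each = spc)
    pos <- unlist(lapply(seq_len(config$n_chromosomes), function(cc)
      sort(sample.int(config$chromosome_length, spc))))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    sites <- data.frame(chrom = chrom, pos = pos,
                        id = sprintf("%s_%d", chrom, pos),
                        ref = ref, alt = alt, is_indel = FALSE,
                        stringsAsFactors = FALSE)

    h1 <- matrix(0L, m, n); h2 <- matrix(0L, m, n)
    for (cc in seq_len(config$n_chromosomes)) {
      rows <- ((cc - 1L) * spc + 1L):(cc * spc)
      for (hap in 1:2) {
        src <- subpop
        adm <- stats::runif(n) < config$admixture
        if (any(adm) && K > 1L)
          src[adm] <- vapply(src[adm], function(s)
            sample(setdiff(seq_len(K), s), 1L), integer(1))
        thr <- stats::qnorm(fmat[rows, src, drop = FALSE])
        hh <- sim_haplotypes(pos[rows], thr, config$recombination_rate)
        if (hap == 1) h1[rows, ] <- hh else h2[rows, ] <- hh
      }
      # autozygous chromosome pairs at rate F_IS
      auto <- which(stats::runif(n) < config$inbreeding)
      if (length(auto)) h2[rows, auto] <- h1[rows, auto]
    }

    ids <- sprintf("ACC%03d", seq_len(n))
    colnames(h1) <- colnames(h2) <- ids
    tab <- variant_table(sites, h1, h2, ids)
    truth <- structure(list(
      pedigree_edges = data.frame(parent = character(), offspring = character(),
                                  stringsAsFactors = FALSE),
      subpop_labels = stats::setNames(subpop, ids),
      planted_qtls = data.frame(site_id = character(), trait = character(),
                                effect = numeric(), stringsAsFactors = FALSE),
      heritability = numeric(0),
      h1 = h1, h2 = h2, p_anc = p_anc, subpop_freqs = fmat,
      true_a1 = h1, true_a2 = h2), class = "population_truth")
    list(table = tab, truth = truth)
  })
}

#' Append pedigreed offspring and apply the observation model
#'
#' Each offspring receives one recombinant gamete from each parent (Mendelian
#' transmission; crossovers placed with Haldane switch probabilities derived
#' from `recombination_rate`). By default every offspring has one parent drawn
#' from the sampled founders and one hidden, unsampled parent simulated fresh
#' from the same subpopulation, so the number of recoverable parent-offspring
#' pairs equals the number of offspring. After transmission the observation
#' model is applied to the whole matrix: with probability `genotyping_error`
#' one randomly chosen allele of a call is flipped, and calls are masked at
#' `missing_rate`; plausible depth (`AD`/`DP`) and site annotation fields are
#' then synthesised for the observed calls.
#'
#' @param founders,truth output of [simulate_founders()].
#' @param config the [sim_config()] used for the founders.
#' @param crosses optional data.frame with columns `parent1`, `parent2` (sample
#'   ids; `parent2 = NA` means an unsampled parent), one row per offspring.
#'   Defaults to `n_offspring` rows with `parent1` sampled with replacement.
#' @return list with `table` (observed `variant_table`, depth fields attached)
#'   and the extended `truth` (pedigree edges, clean true genotypes).
#' @export
simulate_pedigree <- function(founders, truth, config, crosses = NULL) {
  stopifnot(inherits(founders, "variant_table"),
            inherits(truth, "population_truth"))
  if (n_sites(founders) == 0L) stop("input error: founders table is empty")
  with_seed(derive_seed(config$seed, 1L), {
    if (is.null(crosses)) {
      crosses <- data.frame(
        parent1 = sample(founders$samples, config$n_offspring, replace = TRUE),
        parent2 = NA_character_, stringsAsFactors = FALSE)
    }
    bad <- setdiff(stats::na.omit(c(crosses$parent1, crosses$parent2)),
                   founders$samples)
    if (length(bad))
      stop("input error: parent id not found: ", paste(bad, collapse = ", "))

    sites <- founders$sites
    spc_rows <- split(seq_len(nrow(sites)), sites$chrom)
    n_off <- nrow(crosses)
    off_ids <- sprintf("OFF%03d", seq_len(n_off))

    gamete <- function(hA, hB) {
      g <- integer(nrow(sites))
      for (rows in spc_rows) {
        d <- diff(sites$pos[rows])
        sw <- 0.5 * (1 - exp(-2 * config$recombination_rate * d))
        state <- integer(length(rows))
        state[1L] <- sample(0:1, 1L)
        if (length(rows) > 1L) {
          flip <- stats::runif(length(d)) < sw
          state <- cumsum(c(state[1L], flip)) %% 2L
        }
        g[rows] <- ifelse(state == 0L, hA[rows], hB[rows])
      }
      g
    }

    oh1 <- matrix(0L, nrow(sites), n_off)
    oh2 <- matrix(0L, nrow(sites), n_off)
    for (i in seq_len(n_off)) {
      p1 <- crosses$parent1[i]
      oh1[, i] <- gamete(truth$h1[, p1], truth$h2[, p1])
      p2 <- crosses$parent2[i]
      if (is.na(p2)) {
        # hidden parent: fresh haplotypes from parent1's subpopulation
        sp <- truth$subpop_labels[[p1]]
        hh <- lapply(1:2, function(h) {
          out <- integer(nrow(sites))
          for (rows in spc_rows) {
            thr <- matrix(stats::qnorm(truth$subpop_freqs[rows, sp]), ncol = 1)
            out[rows] <- sim_haplotypes(sites$pos[rows], thr,
                                        config$recombination_rate)
          }
          out
        })
        oh2[, i] <- gamete(hh[[1]], hh[[2]])
      } else {
        oh2[, i] <- gamete(truth$h1[, p2], truth$h2[, p2])
      }
    }
    colnames(oh1) <- colnames(oh2) <- off_ids

    a1 <- cbind(truth$h1, oh1); a2 <- cbind(truth$h2, oh2)
    ids <- colnames(a1)
    truth$true_a1 <- a1; truth$true_a2 <- a2
    truth$h1 <- cbind(truth$h1, oh1); truth$h2 <- cbind(truth$h2, oh2)
    off_sub <- stats::setNames(truth$subpop_labels[crosses$parent1], off_ids)
    truth$subpop_labels <- c(truth$subpop_labels, off_sub)
    edges <- data.frame(parent = crosses$parent1, offspring = off_ids,
                        stringsAsFactors = FALSE)
    p2in <- !is.na(crosses$parent2)
    if (any(p2in))
      edges <- rbind(edges, data.frame(parent = crosses$parent2[p2in],
                                       offspring = off_ids[p2in]))
    truth$pedigree_edges <- rbind(truth$pedigree_edges, edges)

    # observation model: allele flips, then missingness
    nc <- length(a1) # total calls
    if (config$genotyping_error > 0) {
      hit <- which(stats::runif(nc) < config$genotyping_error)
      which_allele <- stats::runif(length(hit)) < 0.5
      i1 <- hit[which_allele]; i2 <- hit[!which_allele]
      a1[i1] <- 1L - a1[i1]; a2[i2] <- 1L - a2[i2]
    }
    if (config$missing_rate > 0) {
      miss <- stats::runif(nc) < config$missing_rate
      a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    }

    tab <- variant_table(sites, a1, a2, ids)
    tab <- synthesize_support(tab, seed = derive_seed(config$seed, 2L))
    list(table = tab, truth = truth)
  })
}

# Attach plausible per-call depths and per-site GATK-style annotations to a
# simulated table (all values drawn from comfortably passing ranges).
synthesize_support <- function(tab, mean_depth = 40, seed = 1L) {
  with_seed(seed, {
    m <- n_sites(tab); n <- n_samples(tab)
    dp <- matrix(stats::rpois(m * n, mean_depth), m, n)
    het <- !is.na(tab$a1) & tab$a1 != tab$a2
    hom_alt <- !is.na(tab$a1) & tab$a1 == 1L & tab$a2 == 1L
    ad_ref <- dp; ad_ref[hom_alt] <- 0L
    ad_ref[het] <- stats::rbinom(sum(het), dp[het], 0.5)
    ad_alt <- dp - ad_ref
    miss <- is.na(tab$a1)
    dp[miss] <- ad_ref[miss] <- ad_alt[miss] <- NA_integer_
    tab$dp <- dp; tab$ad_ref <- ad_ref; tab$ad_alt <- ad_alt
    tab$sites$qd <- round(stats::runif(m, 10, 35), 2)
    tab$sites$fs <- round(stats::runif(m, 0, 20), 3)
    tab$sites$mq <- round(stats::runif(m, 50, 60), 2)
    tab$sites$mq_rank_sum <- round(stats::rnorm(m, 0, 2), 3)
    tab$sites$read_pos_rank_sum <- round(stats::rnorm(m, 0, 2), 3)
    tab
  })
}

#' Simulate metabolite phenotypes with planted QTLs
#'
#' Phenotypes follow an additive model: a small number of planted QTLs with
#' effects expressed in phenotype-SD units on the standardised ALT dosage, a
#' polygenic term drawn multivariate-normal with covariance proportional to the
#' kinship matrix, a tissue shift, and independent noise. Traits drawn from a
#' shared QTL pool become positively correlated, emulating the strong
#' inter-correlations of catechin compounds. True genotypes (pre-error) are
#' used when available in `truth`.
#'
#' @param genotypes a `variant_table`.
#' @param truth a `population_truth`; if `truth$planted_qtls` is empty, QTLs
#'   are planted here and recorded.
#' @param kinship optional sample x sample matrix for the polygenic term.
#' @param n_traits number of compounds (up to 9, named after the catechins
#'   C, EC, ECG, EGC, EGCG, GC, CG, GCG and gallic acid GA).
#' @param noise_sd independent noise SD per tissue replicate.
#' @param n_qtls_per_trait,effect_size planted-QTL design (effects in SD units).
#' @param polygenic_var variance of the kinship-structured polygenic term.
#' @param tissues,tissue_shift tissue labels and additive shifts (young leaf
#'   highest by default, matching the decline of catechins with leaf age).
#' @param baseline grand mean, mg per g dry weight.
#' @param seed integer.
#' @return list with `phenotypes` (a `phenotype_table` data.frame with columns
#'   accession, tissue, compound, value) and the updated `truth` whose
#'   `heritability` records per-trait realised genetic variance fractions.
#' @export
simulate_phenotypes <- function(genotypes, truth, kinship = NULL,
                                n_traits = 9, noise_sd = 1,
                                n_qtls_per_trait = 2, effect_size = 1,
                                polygenic_var = 0.5,
                                tissues = c("YL", "TL", "ML"),
                                tissue_shift = c(YL = 2, TL = 1, ML = 0),
                                baseline = 10, seed = 1L) {
  stopifnot(inherits(genotypes, "variant_table"))
  compounds <- c("EGCG", "EGC", "ECG", "EC", "C", "GC", "CG", "GCG", "GA")
  if (n_traits > length(compounds)) stop("at most 9 traits supported")
  traits <- compounds[seq_len(n_traits)]
  with_seed(seed, {
    n <- n_samples(genotypes)
    x <- if (!is.null(truth$true_a1))
      truth$true_a1 + truth$true_a2 else dosage(genotypes)
    storage.mode(x) <- "double"

    if (nrow(truth$planted_qtls) == 0L && n_qtls_per_trait > 0) {
      f <- rowMeans(x, na.rm = TRUE) / 2
      maf <- pmin(f, 1 - f)
      pool_ids <- genotypes$sites$id[maf >= 0.1 & is_biallelic_snp(genotypes)]
      # tight shared pool + same-sign effects: traits drawing overlapping
      # QTLs become positively correlated, as the catechins are
      pool <- sample(pool_ids, min(length(pool_ids), 2 * n_qtls_per_trait))
      qtl <- do.call(rbind, lapply(traits, function(tr)
        data.frame(site_id = sample(pool, n_qtls_per_trait), trait = tr,
                   effect = effect_size, stringsAsFactors = FALSE)))
      truth$planted_qtls <- qtl
    }
    qtl <- truth$planted_qtls

    if (nrow(qtl)) {
      idx <- match(qtl$site_id, genotypes$sites$id)
      if (anyNA(idx)) stop("planted QTL site absent from the genotype matrix")
      xs <- x[idx, , drop = FALSE]
      sds <- apply(xs, 1, stats::sd, na.rm = TRUE)
      if (any(!is.finite(sds) | sds == 0))
        stop("planted sites must be polymorphic")
      xs <- (xs - rowMeans(xs, na.rm = TRUE)) / sds
      xs[is.na(xs)] <- 0
    }

    u <- matrix(0, n, n_traits)
    if (!is.null(kinship) && polygenic_var > 0) {
      K <- psd_adjust(as.matrix(kinship))
      ek <- eigen(K, symmetric = TRUE)
      if (all(ek$values < 1e-10))
        stop("numerical error: singular kinship with nonzero polygenic variance")
      L <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0)), n)
      u <- sqrt(polygenic_var) * (L %*% matrix(stats::rnorm(n * n_traits), n))
    }

    recs <- list(); h2 <- stats::setNames(numeric(n_traits), traits)
    for (ti in seq_along(traits)) {
      tr <- traits[ti]
      g <- rep(0, n)
      qt <- qtl[qtl$trait == tr, , drop = FALSE]
      if (nrow(qt)) {
        sel <- which(qtl$trait == tr)  # xs rows align with qtl rows
        g <- as.vector(crossprod(xs[sel, , drop = FALSE], qtl$effect[sel]))
      }
      gen <- g + u[, ti]
      for (ts in tissues) {
        e <- stats::rnorm(n, 0, noise_sd)
        val <- baseline + unname(tissue_shift[ts]) + gen + e
        recs[[length(recs) + 1L]] <- data.frame(
          accession = genotypes$samples, tissue = ts, compound = tr,
          value = val, stringsAsFactors = FALSE)
      }
      h2[tr] <- stats::var(gen) / (stats::var(gen) + noise_sd^2)
    }
    pheno <- do.call(rbind, recs)
    class(pheno) <- c("phenotype_table", "data.frame")
    truth$heritability <- h2
    list(phenotypes = pheno, truth = truth)
  })
}

#' Extract one compound x tissue phenotype vector
#'
#' @param phenotypes a `phenotype_table`.
#' @param compound,tissue labels to select.
#' @return named numeric vector (accession -> value), replicates averaged.
#' @export
phenotype_vector <- function(phenotypes, compound, tissue) {
  sel <- phenotypes$compound == compound & phenotypes$tissue == tissue
  if (!any(sel)) stop("no records for ", compound, " in ", tissue)
  tapply(phenotypes$value[sel], phenotypes$accession[sel], mean)
}

#' Simulate a complete study population
#'
#' Convenience wrapper: founders, pedigree + observation model, kinship and
#' phenotypes in one call.
#'
#' @param config a [sim_config()].
#' @param ... passed to [simulate_phenotypes()].
#' @return list with `table`, `truth`, `kinship`, `phenotypes`.
#' @export
simulate_population <- function(config, ...) {
  fo <- simulate_founders(config)
  pe <- simulate_pedigree(fo$table, fo$truth, config)
  K <- kinship_matrix(pe$table, method = "bn")
  ph <- simulate_phenotypes(pe$table, pe$truth, kinship = K,
                            seed = derive_seed(config$seed, 3L), ...)
  list(table = pe$table, truth = ph$truth, kinship = K,
       phenotypes = ph$phenotypes)
}

#' Write a simulated data set to disk as plain-text fixtures
#'
#' Emits a VCF 4.2 file (FORMAT `GT:AD:DP`, INFO `QD,FS,MQ,MQRankSum,
#' ReadPosRankSum`), a phenotype CSV (`accession,tissue,compound,value`) and
#' truth TSVs (pedigree edges, subpopulation labels, planted QTLs). The VCF
#' round-trips losslessly through [read_vcf()].
#'
#' @param genotypes a `variant_table`.
#' @param phenotypes a `phenotype_table` or `NULL`.
#' @param truth a `population_truth` or `NULL`.
#' @param directory output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_fixture <- function(genotypes, phenotypes, truth, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  out <- c(vcf = file.path(directory, "genotypes.vcf"))
  write_vcf(genotypes, out[["vcf"]])
  if (!is.null(phenotypes)) {
    out[["phenotypes"]] <- file.path(directory, "phenotypes.csv")
    utils::write.csv(as.data.frame(phenotypes), out[["phenotypes"]],
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(truth)) {
    out[["pedigree"]] <- file.path(directory, "pedigree.tsv")
    utils::write.table(truth$pedigree_edges, out[["pedigree"]], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    out[["subpops"]] <- file.path(directory, "subpops.tsv")
    utils::write.table(
      data.frame(sample = names(truth$subpop_labels),
                 subpop = unname(truth$subpop_labels)),
      out[["subpops"]], sep = "\t", row.names = FALSE, quote = FALSE)
    out[["qtls"]] <- file.path(directory, "qtls.tsv")
    utils::write.table(truth$planted_qtls, out[["qtls"]], sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  out
}
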