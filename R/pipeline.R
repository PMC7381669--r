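#' Pipeline configuration
#'
#' Stage toggles, thresholds (defaulting to the conventional values used
#' throughout the package), paths and the master seed for a [run_pipeline()]
#' invocation. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed below.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # inputs: either a VCF path or a simulation config
    vcf = NULL, phenotypes = NULL, sim = sim_config(),
    out_dir = NULL, seed = 1L,
    # stage toggles
    run_parentage = TRUE, run_popgen = TRUE, run_gwas = TRUE,
    run_alleles = TRUE,
    # QC
    hom_min_depth = 10, het_min_allele_depth = 4, indel_window = 10,
    max_missing = 0.8, min_maf = 0.05,
    # parentage
    n_marker_sets = 10, marker_set_size = 500, min_support = 9,
    mistyping = 0.01, sim_offspring = 2000, pic_min = 0.35,
    # popgen
    prune_window = 50, prune_step = 10, prune_r2 = 0.1,
    ld_max_dist = 1e5, ld_bin_width = 100,
    # gwas / clumping
    gwas_compound = "EGCG", gwas_tissue = "YL",
    support_p = 1e-3, clump_window = 5e5, clump_r2 = 0.1,
    clump_min_snps = 2, clump_extension = 1e5,
    # alleles
    class_min_size = 3)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the end-to-end analysis pipeline
#'
#' Stage order: input (read or simulate) -> QC cascade -> site statistics ->
#' parentage consensus -> population genetics (pruning, PCA, kinship, LD
#' decay) -> mixed-model association + QTL clumping -> genotype-class
#' analysis. Writes per-stage TSV outputs plus a JSON summary (stage counts,
#' assignments, regions, classes, truth comparison when simulated truth is
#' available, and the effective configuration echo); the summary is
#' byte-identical across reruns with the same config and seed.
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly; files under `config$out_dir` when set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  summary <- list(config = config[setdiff(names(config), c("sim", "out_dir"))])
  summary$config$sim <- unclass(config$sim)

  log_stage <- function(...) message("[teapop] ", sprintf(...))

  # --- input ------------------------------------------------------------
  truth <- NULL; pheno <- NULL
  if (!is.null(config$vcf)) {
    log_stage("reading VCF %s", config$vcf)
    tab <- read_vcf(config$vcf)
    if (!is.null(config$phenotypes)) pheno <- read_phenotypes(config$phenotypes)
  } else {
    sim <- config$sim
    sim$seed <- derive_seed(seed, 17L)
    sim <- do.call(sim_config, unclass(sim)[setdiff(names(sim), NULL)])
    log_stage("simulating population (%d founders + %d offspring)",
              sim$n_founders, sim$n_offspring)
    pop <- simulate_population(sim)
    tab <- pop$table; truth <- pop$truth; pheno <- pop$phenotypes
  }
  summary$input <- list(n_sites = n_sites(tab), n_samples = n_samples(tab))

  # --- qc ---------------------------------------------------------------
  log_stage("QC cascade on %d sites", n_sites(tab))
  qc <- qc_cascade(tab, hom_min_depth = config$hom_min_depth,
                   het_min_allele_depth = config$het_min_allele_depth,
                   indel_window = config$indel_window,
                   max_missing = config$max_missing, min_maf = config$min_maf)
  tab <- qc$table
  summary$qc <- list(counts = as.list(qc$counts),
                     removed = nrow(qc$log))
  st <- compute_site_stats(tab)
  summary$site_stats <- list(
    mean_het_pct = round(100 * mean(st$het_rate, na.rm = TRUE), 2),
    mean_maf = round(mean(st$maf, na.rm = TRUE), 4),
    n_pic_gt_0.35 = sum(st$pic > 0.35, na.rm = TRUE))

  # --- parentage --------------------------------------------------------
  if (config$run_parentage) {
    log_stage("parentage: %d sets of %d markers", config$n_marker_sets,
              config$marker_set_size)
    par <- parentage_analysis(
      tab, n_sets = config$n_marker_sets, set_size = config$marker_set_size,
      min_support = config$min_support,
      model = parentage_model(error = config$mistyping),
      sim_offspring = config$sim_offspring,
      seed = derive_seed(seed, 23L), pic_min = config$pic_min)
    summary$parentage <- list(
      n_pairs = nrow(par$pairs),
      n_groups = max(c(0L, par$groups$group)),
      pairs = par$pairs[, c("id1", "id2", "support")])
    if (!is.null(truth) && nrow(truth$pedigree_edges)) {
      tp <- truth_pair_overlap(par$pairs, truth$pedigree_edges)
      summary$parentage$recall <- round(tp$recall, 4)
      summary$parentage$false_pairs <- tp$false_pairs
    }
  } else par <- NULL

  # --- popgen -----------------------------------------------------------
  if (config$run_popgen) {
    log_stage("popgen: pruning, PCA, kinship, LD decay")
    kept <- ld_prune(tab, config$prune_window, config$prune_step,
                     config$prune_r2)
    pruned <- subset_variants(tab, sites = kept)
    pca <- pca_genotypes(pruned, n_components = min(5L, n_samples(tab) - 1L))
    K <- kinship_matrix(tab, method = "bn")
    curve <- ld_decay(tab, max_dist = config$ld_max_dist,
                      bin_width = config$ld_bin_width)
    halfmax <- half_max_decay_distance(curve)
    summary$popgen <- list(
      n_pruned = length(kept),
      pc1_var_pct = round(100 * pca$variance_explained[1], 2),
      ld_halfmax_kb = if (is.finite(halfmax)) round(halfmax / 1000, 3)
                      else paste0("> ", config$ld_max_dist / 1000))
  } else K <- kinship_matrix(tab, method = "bn")

  # --- gwas -------------------------------------------------------------
  if (config$run_gwas && !is.null(pheno)) {
    y <- phenotype_vector(pheno, config$gwas_compound, config$gwas_tissue)
    y <- y[intersect(tab$samples, names(y))]
    log_stage("mixed-model scan: %s in %s (n = %d)", config$gwas_compound,
              config$gwas_tissue, length(y))
    scan <- association_scan(tab, y, K)
    me <- effective_marker_threshold(tab)
    regions <- clump_qtl(scan, tab, lead_p = me$threshold,
                         support_p = config$support_p,
                         window = config$clump_window,
                         r2_min = config$clump_r2,
                         min_snps = config$clump_min_snps,
                         extension = config$clump_extension,
                         trait = config$gwas_compound)
    summary$gwas <- list(
      h2 = round(attr(scan, "vc")$h2, 4),
      me = round(me$me, 1), threshold = signif(me$threshold, 4),
      n_regions = nrow(regions),
      regions = as.data.frame(regions))
    if (!is.null(truth) && nrow(truth$planted_qtls)) {
      planted <- truth$planted_qtls[truth$planted_qtls$trait ==
                                      config$gwas_compound, , drop = FALSE]
      hit <- qtl_truth_overlap(regions, planted, tab)
      summary$gwas$planted_recovered <- hit
    }
  } else scan <- NULL

  # --- alleles ----------------------------------------------------------
  if (config$run_alleles && !is.null(scan) && !is.null(truth) &&
      nrow(truth$planted_qtls)) {
    planted <- truth$planted_qtls[truth$planted_qtls$trait ==
                                    config$gwas_compound, , drop = FALSE]
    ids <- intersect(planted$site_id, tab$sites$id)
    if (length(ids) >= 2L) {
      cls <- genotype_class_strings(tab, ids)
      cls <- filter_classes(cls, min_size = config$class_min_size)
      if (length(unique(cls)) >= 2L) {
        y <- phenotype_vector(pheno, config$gwas_compound, config$gwas_tissue)
        tk <- tukey_posthoc(cls, y)
        enr <- subpop_enrichment(cls, truth$subpop_labels)
        summary$alleles <- list(
          n_classes = nrow(attr(cls, "summary")),
          classes = tk[, c("class", "n", "mean", "letter")],
          top_enrichment = utils::head(
            enr[, c("class", "subpop", "odds_ratio", "p")], 3))
      }
    }
  }

  # --- outputs ----------------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(qc$log, file.path(config$out_dir, "qc_removals.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(st, file.path(config$out_dir, "site_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(par))
      utils::write.table(par$pairs,
                         file.path(config$out_dir, "parentage_pairs.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(scan)) {
      out_scan <- as.data.frame(scan)
      utils::write.table(out_scan,
                         file.path(config$out_dir, "association.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    # config echo for provenance
    writeLines(yaml::as.yaml(summary$config),
               file.path(config$out_dir, "config_echo.yaml"))
    writeLines(summary_json(summary),
               file.path(config$out_dir, "summary.json"))
  }
  invisible(summary)
}

# Canonical JSON rendering of the run summary (stable digits => reruns with
# one seed are byte-identical).
summary_json <- function(summary) {
  as.character(jsonlite::toJSON(summary, digits = I(10), auto_unbox = TRUE,
                                dataframe = "rows", null = "null",
                                pretty = TRUE))
}

# Recall / false-pair count of consensus pairs against true pedigree edges.
truth_pair_overlap <- function(pairs, edges) {
  true_keys <- unique(ifelse(edges$parent < edges$offspring,
                             paste(edges$parent, edges$offspring),
                             paste(edges$offspring, edges$parent)))
  got_keys <- if (nrow(pairs))
    paste(pmin(pairs$id1, pairs$id2), pmax(pairs$id1, pairs$id2)) else character(0)
  list(recall = mean(true_keys %in% got_keys),
       false_pairs = sum(!(got_keys %in% true_keys)),
       n_true = length(true_keys), n_found = length(got_keys))
}

# How many planted QTL sites fall inside a reported region for their trait.
qtl_truth_overlap <- function(regions, planted, table) {
  if (!nrow(planted)) return(0L)
  pos <- table$sites$pos[match(planted$site_id, table$sites$id)]
  chr <- table$sites$chrom[match(planted$site_id, table$sites$id)]
  sum(vapply(seq_len(nrow(planted)), function(i) {
    if (is.na(pos[i])) return(FALSE)
    any(regions$chrom == chr[i] & regions$start <= pos[i] &
          regions$end >= pos[i])
  }, logical(1)))
}
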