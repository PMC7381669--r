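#' Default hard-filter thresholds
#'
#' The standard GATK-style site annotation cutoffs used for RNA-seq derived
#' SNP calls: a site is removed when `QD < 2`, `FS > 60`, `MQ < 40`,
#' `MQRankSum < -12.5` or `ReadPosRankSum < -8`. An absent annotation never
#' fails its rule.
#'
#' @return named list of thresholds.
#' @export
hard_filter_thresholds <- function() {
  list(qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
       mq_rank_sum_min = -12.5, read_pos_rank_sum_min = -8.0)
}

#' Apply site-annotation hard filters
#'
#' Step 1 of the QC cascade. Sites failing any annotation predicate are
#' removed; the removal log records every failing rule for each removed site
#' (semicolon-joined). Retained plus removed always equals the input count.
#'
#' @param table a `variant_table`.
#' @param thresholds list as returned by [hard_filter_thresholds()].
#' @return list with `table` (filtered) and `log` (data.frame `id`, `rule`).
#' @export
apply_hard_filters <- function(table, thresholds = hard_filter_thresholds()) {
  s <- table$sites
  fails <- cbind(
    QD = !is.na(s$qd) & s$qd < thresholds$qd_min,
    FS = !is.na(s$fs) & s$fs > thresholds$fs_max,
    MQ = !is.na(s$mq) & s$mq < thresholds$mq_min,
    MQRankSum = !is.na(s$mq_rank_sum) &
      s$mq_rank_sum < thresholds$mq_rank_sum_min,
    ReadPosRankSum = !is.na(s$read_pos_rank_sum) &
      s$read_pos_rank_sum < thresholds$read_pos_rank_sum_min)
  bad <- rowSums(fails) > 0
  log <- data.frame(
    id = s$id[bad],
    rule = apply(fails[bad, , drop = FALSE], 1, function(f)
      paste(colnames(fails)[f], collapse = ";")),
    stringsAsFactors = FALSE)
  list(table = subset_variants(table, !bad), log = log)
}

#' Apply per-genotype depth filters
#'
#' Steps 3-4 of the cascade: homozygous calls need total supporting depth
#' strictly greater than `hom_min_depth` (default 10) and heterozygous calls
#' need each allele's depth strictly greater than `het_min_allele_depth`
#' (default 4). Failing calls are set to missing; sites are retained. Calls
#' without depth information pass unchanged. `hom_depth = "allele"` switches
#' the homozygous rule to the called allele's depth instead of total depth.
#'
#' @param table a `variant_table` with depth fields.
#' @param hom_min_depth,het_min_allele_depth strict lower bounds.
#' @param hom_depth `"total"` (default) or `"allele"`.
#' @return the `variant_table` with failing calls masked.
#' @export
apply_genotype_filters <- function(table, hom_min_depth = 10,
                                   het_min_allele_depth = 4,
                                   hom_depth = c("total", "allele")) {
  hom_depth <- match.arg(hom_depth)
  if (is.null(table$dp)) return(table)
  het <- !is.na(table$a1) & table$a1 != table$a2
  hom <- !is.na(table$a1) & table$a1 == table$a2
  hd <- if (hom_depth == "total") table$dp else {
    d <- table$dp
    d[table$a1 == 0L] <- table$ad_ref[table$a1 == 0L]
    d[table$a1 == 1L] <- table$ad_alt[table$a1 == 1L]
    d
  }
  bad_hom <- hom & !is.na(hd) & hd <= hom_min_depth
  min_ad <- pmin(table$ad_ref, table$ad_alt)
  bad_het <- het & !is.na(min_ad) & min_ad <= het_min_allele_depth
  bad <- bad_hom | bad_het
  table$a1[bad] <- NA_integer_; table$a2[bad] <- NA_integer_
  table$dp[bad] <- NA_integer_
  table$ad_ref[bad] <- NA_integer_; table$ad_alt[bad] <- NA_integer_
  table
}

#' Apply site-level filters
#'
#' Steps 2, 5 and 6 of the cascade, run after the genotype-level filters:
#' multi-allelic sites removed, indel records and SNPs within `indel_window`
#' bp of an indel removed (boundary inclusive: exactly 10 bp away is removed),
#' then sites with missing rate above `max_missing` or minor allele frequency
#' below `min_maf` removed.
#'
#' @param table a `variant_table`.
#' @param biallelic_only drop sites with more than two alleles.
#' @param indel_window bp; 0 disables indel-proximity filtering.
#' @param max_missing maximum tolerated missing-call fraction.
#' @param min_maf minimum minor allele frequency.
#' @return list with `table` and removal `log` (data.frame `id`, `rule`).
#' @export
apply_site_filters <- function(table, biallelic_only = TRUE, indel_window = 10,
                               max_missing = 0.8, min_maf = 0.05) {
  s <- table$sites
  rules <- character(nrow(s))
  add_rule <- function(mask, name)
    ifelse(mask, ifelse(rules == "", name, paste(rules, name, sep = ";")), rules)

  multi <- grepl(",", s$alt, fixed = TRUE)
  if (biallelic_only) rules <- add_rule(multi, "multiallelic")
  rules <- add_rule(s$is_indel, "indel")
  if (indel_window > 0 && any(s$is_indel)) {
    near <- rep(FALSE, nrow(s))
    for (ch in unique(s$chrom[s$is_indel])) {
      on_ch <- s$chrom == ch
      ip <- s$pos[on_ch & s$is_indel]
      d <- vapply(s$pos[on_ch], function(p) min(abs(p - ip)), numeric(1))
      near[on_ch] <- d <= indel_window & !s$is_indel[on_ch]
    }
    rules <- add_rule(near, "near_indel")
  }
  st <- compute_site_stats(table)
  rules <- add_rule(!is.na(st$missing_rate) & st$missing_rate > max_missing,
                    "missing_rate")
  rules <- add_rule(is.na(st$maf) | st$maf < min_maf, "maf")
  bad <- rules != ""
  list(table = subset_variants(table, !bad),
       log = data.frame(id = s$id[bad], rule = rules[bad],
                        stringsAsFactors = FALSE))
}

#' Run the full six-step QC cascade
#'
#' Hard annotation filters, genotype depth filters (failing calls set to
#' missing), then site-level filters, in that fixed order. Site counts are
#' conserved: every input site appears exactly once as retained or as a
#' removal-log entry.
#'
#' @param table a `variant_table`.
#' @param thresholds hard-filter thresholds.
#' @param hom_min_depth,het_min_allele_depth,biallelic_only,indel_window,max_missing,min_maf
#'   see the individual filter functions.
#' @return list with `table`, `log` (combined removal log with a `stage`
#'   column) and `counts` (sites entering/retained per stage).
#' @export
qc_cascade <- function(table, thresholds = hard_filter_thresholds(),
                       hom_min_depth = 10, het_min_allele_depth = 4,
                       biallelic_only = TRUE, indel_window = 10,
                       max_missing = 0.8, min_maf = 0.05) {
  n0 <- n_sites(table)
  hf <- apply_hard_filters(table, thresholds)
  gt <- apply_genotype_filters(hf$table, hom_min_depth, het_min_allele_depth)
  sf <- apply_site_filters(gt, biallelic_only, indel_window,
                           max_missing, min_maf)
  log <- rbind(
    if (nrow(hf$log)) cbind(hf$log, stage = "hard_filter"),
    if (nrow(sf$log)) cbind(sf$log, stage = "site_filter"))
  if (is.null(log)) log <- data.frame(id = character(), rule = character(),
                                      stage = character())
  list(table = sf$table, log = log,
       counts = c(input = n0, after_hard = n_sites(hf$table),
                  retained = n_sites(sf$table)))
}

#' Per-site summary statistics
#'
#' Minor allele frequency, missing rate, heterozygosity rate (fraction of
#' non-missing calls that are heterozygous) and polymorphic information
#' content. PIC follows the Botstein closed form; for a biallelic site
#' `PIC = 1 - p^2 - q^2 - 2 p^2 q^2`, maximal at 0.375 when p = 0.5. Sites
#' with every call missing get `NA` statistics and `defined = FALSE`.
#'
#' @param table a `variant_table`.
#' @return data.frame with one row per site: `id`, `chrom`, `pos`, `n_called`,
#'   `missing_rate`, `maf`, `het_rate`, `pic`, `defined`.
#' @export
compute_site_stats <- function(table) {
  if (n_sites(table) == 0L) stop("table is empty")
  a1 <- table$a1; a2 <- table$a2
  called <- !is.na(a1)
  n_called <- rowSums(called)
  n <- n_samples(table)
  # allele frequency of the first ALT among called alleles (dosage basis);
  # calls touching a further ALT allele are excluded from the frequency
  simple <- called & a1 <= 1L & a2 <= 1L
  cnt <- rowSums(simple)
  alt <- rowSums((a1 == 1L) * simple, na.rm = TRUE) +
    rowSums((a2 == 1L) * simple, na.rm = TRUE)
  p_alt <- ifelse(cnt > 0, alt / (2 * cnt), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  het <- ifelse(n_called > 0,
                rowSums(called & a1 != a2) / n_called, NA_real_)
  q <- 1 - p_alt
  pic <- 1 - p_alt^2 - q^2 - 2 * p_alt^2 * q^2
  out <- data.frame(id = table$sites$id, chrom = table$sites$chrom,
                    pos = table$sites$pos, n_called = n_called,
                    missing_rate = 1 - n_called / n,
                    maf = maf, het_rate = het, pic = pic,
                    defined = n_called > 0, stringsAsFactors = FALSE)
  out$maf[!out$defined] <- NA_real_
  out$pic[!out$defined] <- NA_real_
  out
}

#' Select random marker sets of high-PIC sites
#'
#' Reproduces the marker-eligibility rule used for parentage: biallelic sites
#' with missing rate at most `miss_max`, MAF above `maf_min` and PIC above
#' `pic_min` form the pool, from which `n_sets` uniform random subsets of
#' `set_size` sites are drawn without replacement (sets may overlap across
#' draws).
#'
#' @param stats output of [compute_site_stats()].
#' @param n_sets,set_size number and size of the sets (defaults: ten sets of
#'   500 markers).
#' @param seed integer; draws are seed-reproducible.
#' @param pic_min,miss_max,maf_min eligibility thresholds.
#' @return list of character vectors of site ids.
#' @export
select_marker_sets <- function(stats, n_sets = 10, set_size = 500, seed = 1L,
                               pic_min = 0.35, miss_max = 0.10,
                               maf_min = 0.05) {
  ok <- stats$defined & !is.na(stats$pic) & stats$pic > pic_min &
    stats$missing_rate <= miss_max & !is.na(stats$maf) & stats$maf > maf_min
  pool <- stats$id[ok]
  if (length(pool) < set_size)
    stop(sprintf("eligible sites (%d) fewer than set_size (%d)",
                 length(pool), set_size))
  with_seed(seed, lapply(seq_len(n_sets), function(i)
    sample(pool, set_size)))
}

#' LD pruning (windowed pairwise)
#'
#' Greedy windowed r2 pruning in the style of PLINK `--indep-pairwise`:
#' within each scanning window of `window` sites (advanced by `step`), pairs
#' of retained sites with dosage-correlation r2 above `r2_max` are resolved by
#' removing the later site of the pair. Defaults mirror
#' `--indep-pairwise 50 10 0.1`.
#'
#' @param table a `variant_table`.
#' @param window,step window size and step, in sites.
#' @param r2_max maximum tolerated pairwise r2.
#' @return character vector of retained site ids; monomorphic sites are
#'   skipped (always retained) and listed in attribute `"skipped"`.
#' @export
ld_prune <- function(table, window = 50, step = 10, r2_max = 0.1) {
  d <- dosage(table)
  keep <- rep(TRUE, n_sites(table))
  mono <- apply(d, 1, function(v) {
    v <- v[!is.na(v)]; length(v) == 0L || stats::var(v) == 0
  })
  for (ch in unique(table$sites$chrom)) {
    idx <- which(table$sites$chrom == ch & !mono)
    if (length(idx) < 2L) next
    start <- 1L
    repeat {
      win <- idx[start:min(start + window - 1L, length(idx))]
      win <- win[keep[win]]
      if (length(win) > 1L) {
        r2 <- suppressWarnings(
          stats::cor(t(d[win, , drop = FALSE]),
                     use = "pairwise.complete.obs")^2)
        for (i in seq_len(length(win) - 1L)) {
          if (!keep[win[i]]) next
          for (j in (i + 1L):length(win)) {
            if (!keep[win[j]]) next
            if (!is.na(r2[i, j]) && r2[i, j] > r2_max) keep[win[j]] <- FALSE
          }
        }
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  out <- table$sites$id[keep]
  attr(out, "skipped") <- table$sites$id[mono]
  out
}
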