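#' Multi-SNP genotype class strings
#'
#' Renders, per sample, the concatenated genotype over a set of candidate-gene
#' SNPs ordered by genomic position: a homozygous site contributes its allele
#' base once, a heterozygous site contributes `"X/Y"` with the reference
#' allele first. A sample missing any of the sites is excluded (listed in
#' attribute `excluded`). With the default empty separator a heterozygous
#' first site followed by homozygous G, T, T renders as `"T/CGTT"`.
#'
#' @param table a `variant_table`.
#' @param snp_ids site ids (re-ordered by position); all must be biallelic
#'   SNPs.
#' @param sep separator between sites.
#' @return named character vector sample -> class string.
#' @export
genotype_class_strings <- function(table, snp_ids, sep = "") {
  idx <- match(snp_ids, table$sites$id)
  if (anyNA(idx)) stop("unknown snp id(s)")
  idx <- idx[order(table$sites$pos[idx])]
  if (!all(is_biallelic_snp(table)[idx]))
    stop("genotype classes require biallelic SNP sites")
  ref <- table$sites$ref[idx]; alt <- table$sites$alt[idx]
  a1 <- table$a1[idx, , drop = FALSE]; a2 <- table$a2[idx, , drop = FALSE]
  complete <- colSums(is.na(a1)) == 0L
  per_site <- function(i) {
    b1 <- ifelse(a1[i, ] == 0L, ref[i], alt[i])
    hom <- a1[i, ] == a2[i, ]
    # heterozygote rendered reference-allele first
    ifelse(hom, b1, paste(ref[i], alt[i], sep = "/"))
  }
  parts <- matrix(vapply(seq_along(idx), per_site,
                         character(n_samples(table))),
                  nrow = n_samples(table))
  cls <- apply(parts, 1, paste, collapse = sep)
  names(cls) <- table$samples
  out <- cls[complete]
  attr(out, "excluded") <- table$samples[!complete]
  out
}

#' Filter genotype classes by sample size and SNP frequency
#'
#' Drops classes observed in fewer than `min_size` samples (default 3). When
#' the source table and SNP list are supplied, each contributing SNP must
#' individually exceed `maf_min` or an error is raised.
#'
#' @param classes named vector from [genotype_class_strings()].
#' @param min_size minimum class sample size.
#' @param table,snp_ids optional: enforce the per-SNP MAF requirement.
#' @param maf_min minimum per-SNP minor allele frequency.
#' @return filtered class vector; class summary (class, n, frequency among
#'   classed samples) in attribute `summary`. Warns when nothing survives.
#' @export
filter_classes <- function(classes, min_size = 3, table = NULL,
                           snp_ids = NULL, maf_min = 0.05) {
  if (!is.null(table) && !is.null(snp_ids)) {
    st <- compute_site_stats(table)
    maf <- st$maf[match(snp_ids, st$id)]
    if (any(is.na(maf) | maf <= maf_min))
      stop("contributing SNP(s) below the MAF threshold: ",
           paste(snp_ids[is.na(maf) | maf <= maf_min], collapse = ", "))
  }
  tab <- table(classes)
  keep_cls <- names(tab)[tab >= min_size]
  out <- classes[classes %in% keep_cls]
  if (!length(out)) warning("no genotype class reaches the minimum size")
  tab2 <- sort(table(out), decreasing = TRUE)
  attr(out, "summary") <- data.frame(
    class = names(tab2), n = as.integer(tab2),
    freq = as.numeric(tab2) / max(length(out), 1L),
    stringsAsFactors = FALSE)
  out
}

#' One-way ANOVA of a phenotype across single-SNP genotype groups
#'
#' @param table a `variant_table`.
#' @param snp_id site id.
#' @param phenotype named numeric vector over samples.
#' @return p-value; `NA` with attribute `reason` when fewer than two genotype
#'   groups have two or more phenotyped samples.
#' @export
snp_anova <- function(table, snp_id, phenotype) {
  g <- dosage(subset_variants(table, sites = snp_id))[1, ]
  common <- intersect(names(phenotype), names(g)[!is.na(g)])
  y <- phenotype[common]; gg <- factor(g[common])
  sizes <- table(gg)
  if (sum(sizes >= 2) < 2)
    return(structure(NA_real_, reason = "fewer than two usable genotype groups"))
  stats::anova(stats::lm(y ~ gg))[["Pr(>F)"]][1]
}

# Compact letter display from a "not significantly different" pairwise
# indicator matrix: groups share a letter iff they lie in a common maximal
# clique of the non-difference graph.
compact_letters <- function(nsd, order_by = NULL) {
  k <- nrow(nsd)
  labs <- rownames(nsd)
  if (k == 1L) return(stats::setNames("a", labs))
  g <- igraph::graph_from_adjacency_matrix(nsd, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  cl <- lapply(cliques, function(cc) labs[as.integer(cc)])
  # order cliques by their best-ranked member so letter 'a' goes to the top
  rank_of <- if (is.null(order_by)) stats::setNames(seq_len(k), labs)
             else stats::setNames(rank(-order_by), labs)
  cl <- cl[order(vapply(cl, function(m) min(rank_of[m]), numeric(1)))]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- stats::setNames(rep("", k), labs)
  for (i in seq_along(cl))
    out[cl[[i]]] <- paste0(out[cl[[i]]], letters_pool[i])
  out
}

#' Tukey HSD post-hoc letters over genotype classes
#'
#' All-pairs Tukey honest significant difference on the class means, followed
#' by a compact letter display: two classes share a letter exactly when their
#' Tukey-adjusted p-value is at or above `alpha`.
#'
#' @param classes named vector sample -> class (post-filter).
#' @param phenotype named numeric vector over samples.
#' @param alpha adjusted-p significance level.
#' @return data.frame `class`, `n`, `mean`, `sd`, `letter` (descending mean);
#'   the pairwise adjusted-p matrix is in attribute `p_adj`.
#' @export
tukey_posthoc <- function(classes, phenotype, alpha = 0.05) {
  common <- intersect(names(classes), names(phenotype))
  cls <- factor(classes[common]); y <- phenotype[common]
  if (nlevels(cls) < 2L) stop("need at least two surviving classes")
  if (all(tapply(y, cls, stats::sd) == 0, na.rm = TRUE))
    return(structure(class_summary(cls, y, rep("a", nlevels(cls))),
                     degenerate = "zero within-class variance"))
  fit <- stats::aov(y ~ cls)
  tk <- stats::TukeyHSD(fit)$cls
  lev <- levels(cls)
  p_adj <- matrix(1, nlevels(cls), nlevels(cls), dimnames = list(lev, lev))
  pr <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pr)) {
    p_adj[pr[[i]][1], pr[[i]][2]] <- tk[i, "p adj"]
    p_adj[pr[[i]][2], pr[[i]][1]] <- tk[i, "p adj"]
  }
  nsd <- p_adj >= alpha
  means <- tapply(y, cls, mean)
  letters <- compact_letters(nsd, order_by = means)
  structure(class_summary(cls, y, letters[lev]), p_adj = p_adj)
}

class_summary <- function(cls, y, letters) {
  lev <- levels(cls)
  out <- data.frame(class = lev,
                    n = as.integer(table(cls)[lev]),
                    mean = as.numeric(tapply(y, cls, mean)[lev]),
                    sd = as.numeric(tapply(y, cls, stats::sd)[lev]),
                    letter = letters, stringsAsFactors = FALSE)
  out[order(-out$mean), , drop = FALSE]
}

#' Genotype-class enrichment across subpopulations
#'
#' For every class x subpopulation combination, a two-sided Fisher exact test
#' on the 2x2 table (in class / not in class) x (in subpopulation / not).
#' Raw p-values are reported (as is conventional for these enrichment stars);
#' a Benjamini-Hochberg adjusted column is emitted alongside for transparency.
#'
#' @param classes named vector sample -> class.
#' @param subpop_labels named vector sample -> subpopulation.
#' @return data.frame `class`, `subpop`, `n_class_in`, `n_class_out`,
#'   `odds_ratio`, `p`, `p_bh`, `note`.
#' @export
subpop_enrichment <- function(classes, subpop_labels) {
  common <- intersect(names(classes), names(subpop_labels))
  if (!length(common)) stop("subpopulation labels do not cover the classed samples")
  cls <- classes[common]; sp <- subpop_labels[common]
  combos <- expand.grid(class = unique(cls), subpop = unique(sp),
                        stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    inc <- cls == combos$class[i]; ins <- sp == combos$subpop[i]
    m <- matrix(c(sum(inc & ins), sum(inc & !ins),
                  sum(!inc & ins), sum(!inc & !ins)), 2, byrow = TRUE)
    if (any(rowSums(m) == 0L) || any(colSums(m) == 0L))
      return(data.frame(class = combos$class[i], subpop = combos$subpop[i],
                        n_class_in = m[1, 1], n_class_out = m[1, 2],
                        odds_ratio = NA_real_, p = 1,
                        note = "empty margin", stringsAsFactors = FALSE))
    ft <- stats::fisher.test(m, alternative = "two.sided")
    data.frame(class = combos$class[i], subpop = combos$subpop[i],
               n_class_in = m[1, 1], n_class_out = m[1, 2],
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               note = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), c("class", "subpop", "n_class_in", "n_class_out",
                      "odds_ratio", "p", "p_bh", "note")]
}

#' Tissue-wise phenotype comparison with Tukey letters
#'
#' Per compound, Tukey HSD across the tissue classes (young leaf, third leaf,
#' mature leaf) with a compact letter display at `alpha` (default 0.01).
#' Compounds observed in fewer than two tissues are excluded with a note.
#'
#' @param phenotypes a `phenotype_table`.
#' @param alpha adjusted-p significance level.
#' @return data.frame `compound`, `tissue`, `n`, `mean`, `sd`, `letter`;
#'   excluded compounds in attribute `excluded`.
#' @export
tissue_compare <- function(phenotypes, alpha = 0.01) {
  out <- list(); excluded <- character(0)
  for (cp in unique(phenotypes$compound)) {
    d <- phenotypes[phenotypes$compound == cp, , drop = FALSE]
    if (length(unique(d$tissue)) < 2L) { excluded <- c(excluded, cp); next }
    fake <- stats::setNames(d$value, paste0(seq_len(nrow(d))))
    cls <- stats::setNames(d$tissue, names(fake))
    tp <- tukey_posthoc(cls, fake, alpha = alpha)
    tp <- data.frame(compound = cp, tissue = tp$class, n = tp$n,
                     mean = tp$mean, sd = tp$sd, letter = tp$letter,
                     stringsAsFactors = FALSE)
    out[[cp]] <- tp
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, excluded = excluded)
}

#' Compound-by-compound correlation matrices per tissue
#'
#' Pearson correlations between compound abundances over accessions with both
#' values, computed separately per tissue. Matrices are symmetric with unit
#' diagonal; entries with fewer than 3 complete pairs or a constant compound
#' are `NA` and listed in attribute `flagged`.
#'
#' @param phenotypes a `phenotype_table`.
#' @return named list (tissue -> correlation matrix).
#' @export
compound_correlations <- function(phenotypes) {
  out <- list(); flagged <- character(0)
  for (ts in unique(phenotypes$tissue)) {
    d <- phenotypes[phenotypes$tissue == ts, , drop = FALSE]
    wide <- stats::reshape(d[, c("accession", "compound", "value")],
                           idvar = "accession", timevar = "compound",
                           direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    colnames(m) <- sub("^value\\.", "", colnames(m))
    cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
    n_ok <- crossprod((!is.na(m)) * 1)
    cm[n_ok < 3] <- NA_real_
    const <- apply(m, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
    if (any(const, na.rm = TRUE)) {
      cm[const, ] <- NA_real_; cm[, const] <- NA_real_
      flagged <- c(flagged, paste(ts, colnames(m)[which(const)], sep = ":"))
    }
    diag(cm) <- 1
    out[[ts]] <- cm
  }
  structure(out, flagged = flagged)
}
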