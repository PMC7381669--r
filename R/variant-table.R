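#' Construct a variant table
#'
#' The central genotype container used by every stage of the pipeline: an
#' ordered site table plus per-sample allele calls, optional allele depths and
#' optional GATK-style site annotations. Genotypes are stored as two allele
#' index matrices (`a1`, `a2`; 0 = REF, 1 = first ALT, ...) so that
#' multi-allelic records survive until the biallelic filter and so that
#' genotype-class strings can be rendered from the actual bases.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `id`, `ref`,
#'   `alt` (comma-separated for multi-allelic records). Optional columns:
#'   `qd`, `fs`, `mq`, `mq_rank_sum`, `read_pos_rank_sum` (site annotations;
#'   `NA` = annotation absent) and `is_indel`.
#' @param a1,a2 integer matrices (sites x samples) of allele indices; `NA`
#'   in either marks a missing call. Unphased: the pair is unordered.
#' @param samples character vector of sample names (matrix columns).
#' @param ad_ref,ad_alt,dp optional integer matrices (sites x samples) with
#'   the REF-allele depth, summed ALT-allele depth and total depth.
#'
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, a1, a2, samples,
                          ad_ref = NULL, ad_alt = NULL, dp = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(sites)))
  n_sites <- nrow(sites)
  n_samples <- length(samples)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!all(dim(a1) == c(n_sites, n_samples)) ||
      !all(dim(a2) == c(n_sites, n_samples)))
    stop("genotype matrices must be n_sites x n_samples")
  # missingness must be consistent between the two allele slots
  if (!identical(is.na(a1), is.na(a2)))
    stop("a1/a2 must be NA at exactly the same calls")
  for (nm in c("qd", "fs", "mq", "mq_rank_sum", "read_pos_rank_sum"))
    if (is.null(sites[[nm]])) sites[[nm]] <- NA_real_
  if (is.null(sites$is_indel))
    sites$is_indel <- nchar(sites$ref) > 1L |
      vapply(strsplit(sites$alt, ",", fixed = TRUE),
             function(a) any(nchar(a) != nchar(sites$ref[1])), logical(1))
  # positions strictly increasing within each chromosome
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(n_sites))) {
    sites <- sites[ord, , drop = FALSE]
    a1 <- a1[ord, , drop = FALSE]; a2 <- a2[ord, , drop = FALSE]
    if (!is.null(ad_ref)) ad_ref <- ad_ref[ord, , drop = FALSE]
    if (!is.null(ad_alt)) ad_alt <- ad_alt[ord, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[ord, , drop = FALSE]
  }
  dup <- unlist(tapply(sites$pos, sites$chrom, function(p) c(FALSE, diff(p) <= 0)))
  if (any(dup)) stop("positions must be strictly increasing within a chromosome")
  rownames(a1) <- rownames(a2) <- sites$id
  colnames(a1) <- colnames(a2) <- samples
  structure(list(sites = sites, a1 = a1, a2 = a2, samples = samples,
                 ad_ref = ad_ref, ad_alt = ad_alt, dp = dp),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples on %d chromosome(s)\n",
              n_sites(x), n_samples(x), length(unique(x$sites$chrom))))
  cat(sprintf("  biallelic SNPs: %d; indels: %d; depth fields: %s\n",
              sum(is_biallelic_snp(x)), sum(x$sites$is_indel),
              if (is.null(x$dp)) "absent" else "present"))
  invisible(x)
}

#' Number of sites / samples in a variant table
#' @param x a `variant_table`
#' @return integer count.
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_samples <- function(x) length(x$samples)

#' Logical mask of biallelic SNP sites
#' @param x a `variant_table`
#' @return logical vector over sites: single ALT allele, both alleles length 1,
#'   not flagged as indel.
#' @export
is_biallelic_snp <- function(x) {
  alt <- x$sites$alt
  !grepl(",", alt, fixed = TRUE) & nchar(x$sites$ref) == 1L &
    nchar(alt) == 1L & !x$sites$is_indel
}

#' ALT-allele dosage matrix
#'
#' Codes each biallelic call as the count of the (first) ALT allele: 0, 1 or 2.
#' Calls that are missing or involve an allele beyond the first ALT are `NA`.
#'
#' @param x a `variant_table`
#' @return numeric matrix, sites x samples.
#' @export
dosage <- function(x) {
  d <- x$a1 + x$a2
  d[x$a1 > 1L | x$a2 > 1L] <- NA_real_
  storage.mode(d) <- "double"
  d
}

#' Subset a variant table
#'
#' @param x a `variant_table`
#' @param sites site ids, logical mask or integer indices (default: all)
#' @param samples sample names, logical mask or integer indices (default: all)
#' @return the subsetted `variant_table`.
#' @export
subset_variants <- function(x, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(x))
        else if (is.character(sites)) match(sites, x$sites$id)
        else if (is.logical(sites)) which(sites) else sites
  if (anyNA(si)) stop("unknown site id(s): ",
                      paste(sites[is.na(match(sites, x$sites$id))][1:3], collapse = ", "))
  sj <- if (is.null(samples)) seq_len(n_samples(x))
        else if (is.character(samples)) match(samples, x$samples)
        else if (is.logical(samples)) which(samples) else samples
  if (anyNA(sj)) stop("unknown sample name(s)")
  pick <- function(m) if (is.null(m)) NULL else m[si, sj, drop = FALSE]
  variant_table(x$sites[si, , drop = FALSE],
                x$a1[si, sj, drop = FALSE], x$a2[si, sj, drop = FALSE],
                x$samples[sj], pick(x$ad_ref), pick(x$ad_alt), pick(x$dp))
}

# ---- internal helpers --------------------------------------------------------

# Run code under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
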