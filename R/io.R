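#' Write a variant table as VCF 4.2
#'
#' Plain-text VCF with FORMAT `GT:AD:DP` (AD/DP omitted when the table has no
#' depth fields) and the site annotations `QD`, `FS`, `MQ`, `MQRankSum`,
#' `ReadPosRankSum` in INFO when present.
#'
#' @param table a `variant_table`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_vcf <- function(table, path) {
  s <- table$sites
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=teapop",
    sprintf("##contig=<ID=%s>", unique(s$chrom)),
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples), collapse = "\t")), con)
  info_field <- function(i) {
    kv <- c(QD = s$qd[i], FS = s$fs[i], MQ = s$mq[i],
            MQRankSum = s$mq_rank_sum[i], ReadPosRankSum = s$read_pos_rank_sum[i])
    kv <- kv[!is.na(kv)]
    if (!length(kv)) "." else paste(names(kv), kv, sep = "=", collapse = ";")
  }
  has_depth <- !is.null(table$dp)
  fmt <- if (has_depth) "GT:AD:DP" else "GT"
  lines <- vapply(seq_len(n_sites(table)), function(i) {
    a1 <- table$a1[i, ]; a2 <- table$a2[i, ]
    # write the smaller allele index first (unphased, unordered)
    lo <- pmin(a1, a2); hi <- pmax(a1, a2)
    gt <- ifelse(is.na(a1), "./.", paste(lo, hi, sep = "/"))
    if (has_depth) {
      ad <- ifelse(is.na(table$ad_ref[i, ]), ".",
                   paste(table$ad_ref[i, ], table$ad_alt[i, ], sep = ","))
      dp <- ifelse(is.na(table$dp[i, ]), ".", table$dp[i, ])
      gt <- paste(gt, ad, dp, sep = ":")
    }
    paste(c(s$chrom[i], s$pos[i], s$id[i], s$ref[i], s$alt[i], ".", "PASS",
            info_field(i), fmt, gt), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Parses a VCF 4.2 file (via the vcfR reader): 1-based positions are
#' preserved, `./.` maps to missing, multi-allelic records are retained (the
#' biallelic site filter removes them later), `GT`/`AD`/`DP` and the standard
#' GATK INFO annotations are extracted when present.
#'
#' @param path VCF file.
#' @return a `variant_table`.
#' @export
read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info_num <- function(tag) {
    x <- suppressWarnings(vcfR::extract.info(v, element = tag, as.numeric = TRUE))
    if (is.null(x)) rep(NA_real_, nrow(fix)) else x
  }
  sites <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    qd = info_num("QD"), fs = info_num("FS"), mq = info_num("MQ"),
    mq_rank_sum = info_num("MQRankSum"),
    read_pos_rank_sum = info_num("ReadPosRankSum"),
    stringsAsFactors = FALSE)
  alt1 <- vapply(strsplit(sites$alt, ",", fixed = TRUE), `[`, "", 1)
  sites$is_indel <- nchar(sites$ref) > 1L | nchar(alt1) > 1L

  gt <- vcfR::extract.gt(v, element = "GT")
  split_allele <- function(k) {
    a <- sub(if (k == 1) "^([0-9.]+)[/|].*$" else "^.*[/|]([0-9.]+)$", "\\1", gt)
    a[a == "."] <- NA
    suppressWarnings(matrix(as.integer(a), nrow(gt), ncol(gt)))
  }
  a1 <- split_allele(1); a2 <- split_allele(2)
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_

  ad_ref <- ad_alt <- dp <- NULL
  fmt_tags <- strsplit(v@gt[1, "FORMAT"], ":", fixed = TRUE)[[1]]
  if ("AD" %in% fmt_tags) {
    ad <- vcfR::extract.gt(v, element = "AD")
    ad_ref <- suppressWarnings(matrix(as.integer(
      sub(",.*$", "", ad)), nrow(ad), ncol(ad)))
    # summed depth over all ALT alleles
    ad_alt <- suppressWarnings(matrix(vapply(strsplit(ad, ",", fixed = TRUE),
      function(x) if (length(x) < 2L || anyNA(x)) NA_integer_
                  else sum(as.integer(x[-1])), integer(1)),
      nrow(ad), ncol(ad)))
  }
  if ("DP" %in% fmt_tags) {
    dpx <- vcfR::extract.gt(v, element = "DP")
    dp <- suppressWarnings(matrix(as.integer(dpx), nrow(dpx), ncol(dpx)))
  }
  variant_table(sites, a1, a2, colnames(gt), ad_ref, ad_alt, dp)
}

#' Read a metabolite phenotype table
#'
#' CSV with header `accession,tissue,compound,value`. Tissue labels must come
#' from the young/third/mature-leaf vocabulary (`YL`, `TL`, `ML`) and
#' compounds from the catechin + gallic acid vocabulary. Replicates
#' (duplicated accession x tissue x compound rows) are averaged, with the
#' replicate count recorded in attribute `replicates`.
#'
#' @param path CSV file.
#' @return a `phenotype_table` data.frame.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession", "tissue", "compound", "value")
  if (!all(need %in% names(d)))
    stop("phenotype file must have columns ", paste(need, collapse = ","))
  tissues <- c("YL", "TL", "ML")
  compounds <- c("C", "EC", "CG", "ECG", "GC", "EGC", "GCG", "EGCG", "GA")
  bad_t <- setdiff(unique(d$tissue), tissues)
  if (length(bad_t)) stop("unknown tissue label(s): ", paste(bad_t, collapse = ", "))
  bad_c <- setdiff(unique(d$compound), compounds)
  if (length(bad_c)) stop("unknown compound label(s): ", paste(bad_c, collapse = ", "))
  if (!is.numeric(d$value)) {
    bad_row <- which(is.na(suppressWarnings(as.numeric(d$value))))[1]
    stop("non-numeric phenotype value at data row ", bad_row)
  }
  if (anyNA(d$value)) stop("non-numeric phenotype value at data row ",
                           which(is.na(d$value))[1])
  agg <- stats::aggregate(value ~ accession + tissue + compound, d, mean)
  reps <- stats::aggregate(value ~ accession + tissue + compound, d, length)
  names(reps)[4] <- "n"
  class(agg) <- c("phenotype_table", "data.frame")
  attr(agg, "replicates") <- reps
  agg
}
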