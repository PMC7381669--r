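# Builders for small in-code fixtures used across the suite.

# Variant table from a dosage matrix (sites x samples; NA = missing).
# All sites biallelic A>G SNPs 1 kb apart unless positions given.
toy_table <- function(dos, chrom = "chr01", pos = NULL, ref = "A", alt = "G",
                      samples = NULL, ...) {
  dos <- as.matrix(dos)
  m <- nrow(dos); n <- ncol(dos)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(n))
  sites <- data.frame(chrom = rep_len(chrom, m), pos = pos,
                      id = sprintf("s%03d", seq_len(m)),
                      ref = rep_len(ref, m), alt = rep_len(alt, m),
                      is_indel = FALSE, stringsAsFactors = FALSE, ...)
  a1 <- pmin(dos, 1L); a2 <- pmax(dos - 1L, 0L)
  a1[is.na(dos)] <- NA_integer_; a2[is.na(dos)] <- NA_integer_
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  variant_table(sites, a1, a2, samples)
}

# Small default population reused by several tests (cached per session).
small_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_founders = 60, n_offspring = 10, n_subpops = 3,
                        n_chromosomes = 2, sites_per_chromosome = 300,
                        chromosome_length = 1e6, seed = 42)
      cache <<- simulate_population(cfg)
    }
    cache
  }
})
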