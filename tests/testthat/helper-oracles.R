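# Independent oracles, deliberately written with different machinery than the
# implementation they check.

# Hudson's FST estimator (ratio of averages) from two subpop dosage matrices.
hudson_fst <- function(d1, d2) {
  p1 <- rowMeans(d1, na.rm = TRUE) / 2
  p2 <- rowMeans(d2, na.rm = TRUE) / 2
  n1 <- ncol(d1); n2 <- ncol(d2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- is.finite(num) & is.finite(den) & den > 0
  sum(num[ok]) / sum(den[ok])
}

# Plain union-find over an edge list; returns membership keyed by node name.
union_find_groups <- function(edges) {
  parent <- new.env(parent = emptyenv())
  find <- function(x) {
    p <- parent[[x]] %||% x
    if (p != x) { p <- find(p); parent[[x]] <- p }
    p
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges[i, 1]); rb <- find(edges[i, 2])
    if (ra != rb) parent[[rb]] <- ra
  }
  nodes <- unique(c(edges[, 1], edges[, 2]))
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# Two-sided Fisher p by full hypergeometric enumeration over all tables with
# the observed margins: sum of probabilities <= that of the observed table.
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1), numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Single-marker parentage LOD by brute-force enumeration of true genotypes
# under the replace-with-HWE mistyping model.
brute_lod <- function(op, oo, q, e) {
  hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  trans <- function(tp, to) {   # P(offspring dosage | parent dosage)
    p <- 1 - q
    m <- rbind(c(p, q, 0), c(p / 2, 1 / 2, q / 2), c(0, p, q))
    m[tp + 1, to + 1]
  }
  obs_given_true <- function(obs, true) (1 - e) * (obs == true) + e * hw[obs + 1]
  num <- 0; den_p <- 0; den_o <- 0
  for (tp in 0:2) for (to in 0:2)
    num <- num + hw[tp + 1] * trans(tp, to) *
      obs_given_true(op, tp) * obs_given_true(oo, to)
  for (t in 0:2) {
    den_p <- den_p + hw[t + 1] * obs_given_true(op, t)
    den_o <- den_o + hw[t + 1] * obs_given_true(oo, t)
  }
  log(num) - log(den_p * den_o)
}

# Mean silhouette width of a 1-d embedding against integer labels.
silhouette_1d <- function(x, labels) {
  n <- length(x)
  dmat <- abs(outer(x, x, "-"))
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(dmat[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(dmat[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Genomic inflation factor of a p-value vector.
inflation_factor <- function(p) {
  stats::median(stats::qchisq(1 - p, df = 1)) / stats::qchisq(0.5, df = 1)
}
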