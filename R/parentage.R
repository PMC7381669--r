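#' Parentage model parameters
#'
#' Parameters of the likelihood model and of the confidence-calibration
#' simulation: the mistyping rate (a genotype is replaced by a random
#' Hardy-Weinberg draw with this probability), the proportion of candidate
#' parents assumed sampled, the proportion of loci typed, and the two
#' assignment confidence levels. Defaults follow the conventional single-parent
#' analysis settings for a ~220-accession collection: mistyping 0.01,
#' proportion sampled 0.5, proportion typed 0.8, confidence 95% (strict) and
#' 80% (relaxed).
#'
#' @param error mistyping rate in `[0, 1)`.
#' @param prop_sampled proportion of true parents present among candidates.
#' @param prop_typed proportion of loci typed per individual.
#' @param conf_strict,conf_relaxed assignment confidence levels.
#' @return a `parentage_model` list.
#' @export
parentage_model <- function(error = 0.01, prop_sampled = 0.5,
                            prop_typed = 0.8,
                            conf_strict = 0.95, conf_relaxed = 0.80) {
  stopifnot(error >= 0, error < 1, prop_sampled > 0, prop_sampled <= 1,
            prop_typed > 0, prop_typed <= 1)
  structure(list(error = error, prop_sampled = prop_sampled,
                 prop_typed = prop_typed, conf_strict = conf_strict,
                 conf_relaxed = conf_relaxed), class = "parentage_model")
}

#' Mendelian transmission probability
#'
#' Probability of an offspring genotype given one known parent, the other
#' parental allele drawn from population frequencies. Genotypes are ALT-allele
#' dosages (0, 1, 2) at a biallelic marker.
#'
#' @param parent_genotype,offspring_genotype dosages in `{0, 1, 2}`.
#' @param allele_frequencies numeric length-2 vector `c(ref, alt)`; must sum
#'   to 1.
#' @return probability in `[0, 1]`; for a fixed parent genotype the values sum
#'   to 1 over the three offspring genotypes.
#' @export
transmission_probability <- function(parent_genotype, offspring_genotype,
                                     allele_frequencies) {
  if (abs(sum(allele_frequencies) - 1) > 1e-8)
    stop("allele frequencies must sum to 1")
  if (anyNA(c(parent_genotype, offspring_genotype)))
    stop("genotypes must be non-missing")
  transmission_matrix(allele_frequencies[2])[parent_genotype + 1L,
                                             offspring_genotype + 1L]
}

# 3x3 matrix T[gp+1, go+1] = P(offspring dosage go | parent dosage gp),
# untransmitted allele from the population (ALT frequency q).
transmission_matrix <- function(q) {
  p <- 1 - q
  matrix(c(p,     q,      0,
           p / 2, 1 / 2,  q / 2,
           0,     p,      q),
         nrow = 3, byrow = TRUE)
}

# Hardy-Weinberg genotype frequencies for ALT frequency q.
hwe_freqs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

# Per-marker 3x3 LOD contribution tables under the mistyping model: with
# probability e an observed genotype is a fresh Hardy-Weinberg draw, so
# P(obs | true) = (1-e) [obs == true] + e HWE(obs) and the marginal of an
# observed genotype stays HWE. Returns a 3 x 3 x n_markers array indexed
# [parent_obs + 1, offspring_obs + 1, marker]; exclusions are -Inf when e = 0.
lod_tables <- function(alt_freqs, error) {
  n <- length(alt_freqs)
  out <- array(NA_real_, c(3, 3, n))
  for (l in seq_len(n)) {
    q <- alt_freqs[l]
    hw <- hwe_freqs(q)
    tm <- transmission_matrix(q)
    # joint distribution of observed pair under H1 (candidate is parent)
    joint <- matrix(0, 3, 3)
    for (op in 0:2) for (oo in 0:2) {
      s <- 0
      for (tp in 0:2) for (to in 0:2) {
        e_p <- (1 - error) * (op == tp) + error * hw[op + 1L]
        e_o <- (1 - error) * (oo == to) + error * hw[oo + 1L]
        s <- s + hw[tp + 1L] * tm[tp + 1L, to + 1L] * e_p * e_o
      }
      joint[op + 1L, oo + 1L] <- s
    }
    denom <- outer(hw, hw)  # H2: unrelated
    out[, , l] <- log(joint) - log(denom)
  }
  out
}

#' Parent-offspring LOD score for one candidate
#'
#' Natural-log likelihood ratio that the candidate is a parent of the
#' offspring versus unrelated, summed over markers typed in both individuals.
#' The mistyping model folds the error rate into the genotype likelihoods, so
#' the score is finite whenever `error > 0`; with `error = 0` an
#' opposite-homozygote marker yields `-Inf` (exclusion).
#'
#' @param offspring,candidate dosage vectors over the markers (`NA` = untyped).
#' @param alt_freqs ALT allele frequency per marker.
#' @param model a [parentage_model()].
#' @return the LOD score; `NA` with attribute `reason` when no marker is typed
#'   in both.
#' @export
pair_lod <- function(offspring, candidate, alt_freqs, model = parentage_model()) {
  ok <- !is.na(offspring) & !is.na(candidate)
  if (!any(ok))
    return(structure(NA_real_, reason = "no jointly typed markers"))
  tabs <- lod_tables(alt_freqs[ok], model$error)
  idx <- cbind(candidate[ok] + 1L, offspring[ok] + 1L, seq_len(sum(ok)))
  sum(tabs[idx])
}

#' Simulate Delta critical values for assignment confidence
#'
#' Monte-Carlo calibration of the Delta statistic (gap between the best and
#' second-best candidates' LOD). Simulated offspring are bred from a true
#' mother drawn from the marker allele frequencies; with probability
#' `prop_sampled` the mother is added to a fixed panel of unrelated candidate
#' genotypes. Typing (`prop_typed`), and mistyping (`error`) are applied to
#' everyone. The critical Delta at a confidence level is the smallest value
#' such that, among most-likely assignments whose Delta exceeds it, the
#' proportion of correct assignments reaches that level.
#'
#' @param model a [parentage_model()].
#' @param alt_freqs ALT allele frequency per marker in the active set.
#' @param n_offspring number of simulated offspring (the conventional full-
#'   scale run uses 10,000; tests use fewer).
#' @param n_candidates number of candidate parents.
#' @param seed integer.
#' @return list with `strict` and `relaxed` critical Delta values, the
#'   simulated success rates, and the Delta samples.
#' @export
simulate_critical_values <- function(model, alt_freqs, n_offspring = 10000,
                                     n_candidates = 221, seed = 1L) {
  q <- alt_freqs
  if (all(q <= 0 | q >= 1))
    stop("degenerate frequency spectrum: all markers monomorphic")
  m <- length(q)
  with_seed(seed, {
    draw_geno <- function(n) # n individuals x m markers, HWE dosages
      matrix(stats::rbinom(n * m, 2L, rep(q, each = n)), n, m)
    mistype <- function(g) {
      hit <- matrix(stats::runif(length(g)) < model$error, nrow(g))
      if (any(hit)) {
        qs <- rep(q, each = nrow(g))
        g[hit] <- stats::rbinom(sum(hit), 2L, qs[hit])
      }
      g
    }
    untype <- function(g) {
      g[matrix(stats::runif(length(g)) >= model$prop_typed, nrow(g))] <- NA_integer_
      g
    }

    cand <- untype(mistype(draw_geno(n_candidates)))
    mothers <- draw_geno(n_offspring)
    # offspring: one allele from the mother, one from the population
    from_mother <- matrix(stats::rbinom(n_offspring * m, 1L,
                                        mothers / 2), n_offspring, m)
    pop_allele <- matrix(stats::rbinom(n_offspring * m, 1L,
                                       rep(q, each = n_offspring)),
                         n_offspring, m)
    off <- untype(mistype(from_mother + pop_allele))
    mothers_obs <- untype(mistype(mothers))
    sampled <- stats::runif(n_offspring) < model$prop_sampled

    lods <- lod_matrix(cand, off, q, model$error)        # cand x offspring
    mother_lod <- pair_lod_rows(mothers_obs, off, q, model$error)
    mother_lod[is.na(mother_lod)] <- -Inf

    top2 <- apply(lods, 2, function(v) {
      v <- sort(v, decreasing = TRUE); c(v[1], v[2])
    })
    best_cand <- top2[1, ]; second_cand <- top2[2, ]
    # when the mother is sampled she joins the candidate list
    best <- ifelse(sampled & mother_lod > best_cand, mother_lod, best_cand)
    second <- ifelse(sampled & mother_lod > best_cand, best_cand,
                     pmax(second_cand, ifelse(sampled, mother_lod, -Inf)))
    correct <- sampled & mother_lod > best_cand
    delta <- best - second
    # keep cases with a usable best score; delta may be +Inf when every
    # other candidate is excluded outright (error = 0)
    ok <- is.finite(best) & !is.na(delta)
    delta <- delta[ok]; correct <- correct[ok]

    crit_at <- function(conf) {
      o <- order(delta, decreasing = TRUE)
      frac <- cumsum(correct[o]) / seq_along(o)
      pass <- which(frac >= conf)
      if (!length(pass)) return(Inf)
      delta[o][max(pass)]
    }
    list(strict = crit_at(model$conf_strict),
         relaxed = crit_at(model$conf_relaxed),
         success_rate = mean(correct), delta = delta, correct = correct)
  })
}

# LOD of every candidate row against every offspring row (matrices of dosages,
# NA = untyped), vectorised through indicator-matrix products. Exclusion
# (-Inf) is encoded as a large negative score so that BLAS products stay
# finite; anything below -1e8 is reported as -Inf.
lod_matrix <- function(cand, off, alt_freqs, error) {
  tabs <- lod_tables(alt_freqs, error)
  tabs[!is.finite(tabs)] <- -1e9
  m <- ncol(cand)
  acc <- matrix(0, nrow(cand), nrow(off))
  for (gp in 0:2) {
    cp <- (!is.na(cand) & cand == gp) * 1          # cand x markers
    w <- matrix(0, m, nrow(off))                   # markers x offspring
    for (go in 0:2) {
      oo <- t(!is.na(off) & off == go) * 1         # markers x offspring
      w <- w + tabs[gp + 1L, go + 1L, ] * oo
    }
    acc <- acc + cp %*% w
  }
  acc[acc < -1e8] <- -Inf
  acc
}

# Row-wise LOD between paired parent/offspring observation matrices.
pair_lod_rows <- function(parents, off, alt_freqs, error) {
  tabs <- lod_tables(alt_freqs, error)
  tabs[!is.finite(tabs)] <- -1e9
  n <- nrow(off); m <- ncol(off)
  out <- numeric(n)
  for (gp in 0:2) for (go in 0:2) {
    hit <- !is.na(parents) & parents == gp & !is.na(off) & off == go
    out <- out + hit %*% tabs[gp + 1L, go + 1L, ]
  }
  out <- as.vector(out)
  out[out < -1e8] <- -Inf
  out
}

#' Assign a most-likely parent to every sample for one marker set
#'
#' Every sample is treated in turn as the offspring and every other sample as
#' a candidate parent (self excluded). The best candidate receives the
#' confidence label implied by its Delta against the simulated critical
#' values.
#'
#' @param table a `variant_table`.
#' @param marker_set character vector of site ids (must be in `table`).
#' @param model a [parentage_model()].
#' @param critical list with `strict`/`relaxed` Delta critical values from
#'   [simulate_critical_values()]; `NULL` labels every assignment `"none"`.
#' @return data.frame with one row per offspring: `offspring`, `parent`,
#'   `lod`, `delta`, `confidence` (`"strict"`, `"relaxed"` or `"none"`).
#'   Unassignable offspring (no finite candidate score) keep `NA` parent with
#'   a `reason`.
#' @export
assign_parents <- function(table, marker_set, model = parentage_model(),
                           critical = NULL) {
  sub <- subset_variants(table, sites = marker_set)
  d <- t(dosage(sub))                    # samples x markers
  f <- colMeans(d, na.rm = TRUE) / 2
  poly <- f > 0 & f < 1
  d <- d[, poly, drop = FALSE]; f <- f[poly]
  lods <- lod_matrix(d, d, f, model$error)  # candidates x offspring
  diag(lods) <- -Inf                        # self-exclusion
  n <- nrow(d)
  res <- data.frame(offspring = sub$samples, parent = NA_character_,
                    lod = NA_real_, delta = NA_real_,
                    confidence = "none", reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    v <- lods[, j]
    best <- which.max(v)
    if (!is.finite(v[best])) { res$reason[j] <- "no finite candidate"; next }
    second <- max(v[-best])
    res$parent[j] <- sub$samples[best]
    res$lod[j] <- v[best]
    res$delta[j] <- v[best] - second
    if (!is.null(critical)) {
      res$confidence[j] <-
        if (res$delta[j] >= critical$strict) "strict"
        else if (res$delta[j] >= critical$relaxed) "relaxed" else "none"
    }
  }
  res
}

#' Consensus parent-offspring pairs over marker sets
#'
#' A pair is reliable when the same (unordered) parent-offspring pair is
#' assigned at the required confidence in at least `min_support` of the marker
#' sets — the "at least nine of ten sets" rule by default.
#'
#' @param per_set_assignments list of data.frames from [assign_parents()].
#' @param min_support minimum number of supporting sets.
#' @param confidence minimum confidence label counted as support
#'   (`"strict"` default, or `"relaxed"` to accept both levels).
#' @return data.frame `id1`, `id2` (unordered pair, `id1 < id2`), `support`,
#'   `mean_lod`.
#' @export
consensus_pairs <- function(per_set_assignments, min_support = 9,
                            confidence = c("strict", "relaxed")) {
  confidence <- match.arg(confidence)
  n_sets <- length(per_set_assignments)
  if (min_support > n_sets)
    stop(sprintf("min_support (%d) exceeds number of sets (%d)",
                 min_support, n_sets))
  lev <- if (confidence == "strict") "strict" else c("strict", "relaxed")
  tallies <- new.env(parent = emptyenv())
  for (a in per_set_assignments) {
    a <- a[!is.na(a$parent) & a$confidence %in% lev, , drop = FALSE]
    if (!nrow(a)) next
    key <- ifelse(a$offspring < a$parent,
                  paste(a$offspring, a$parent, sep = "\r"),
                  paste(a$parent, a$offspring, sep = "\r"))
    # a pair assigned from both directions still counts once per set
    best <- tapply(a$lod, key, max)
    for (i in seq_along(best)) {
      k <- names(best)[i]
      cur <- tallies[[k]] %||% c(0, 0)
      tallies[[k]] <- cur + c(1, best[[i]])
    }
  }
  keys <- ls(tallies)
  if (!length(keys))
    return(data.frame(id1 = character(), id2 = character(),
                      support = integer(), mean_lod = numeric()))
  sup <- t(vapply(keys, function(k) tallies[[k]], numeric(2)))
  keep <- sup[, 1] >= min_support
  parts <- strsplit(keys[keep], "\r", fixed = TRUE)
  out <- data.frame(id1 = vapply(parts, `[`, "", 1),
                    id2 = vapply(parts, `[`, "", 2),
                    support = as.integer(sup[keep, 1]),
                    mean_lod = sup[keep, 2] / sup[keep, 1],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$id1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge reliable pairs into family groups
#'
#' Connected components of the undirected pair graph: accessions linked by any
#' chain of reliable parent-offspring pairs form one family group.
#'
#' @param pairs data.frame from [consensus_pairs()] (columns `id1`, `id2`).
#' @return data.frame `group`, `member`; groups numbered by decreasing size
#'   then lexicographic first member.
#' @export
merge_groups <- function(pairs) {
  if (!nrow(pairs))
    return(data.frame(group = integer(), member = character()))
  g <- igraph::graph_from_data_frame(pairs[, c("id1", "id2")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  mem <- split(names(comp$membership), comp$membership)
  mem <- mem[order(-vapply(mem, length, 1L),
                   vapply(mem, function(m) sort(m)[1], ""))]
  data.frame(group = rep(seq_along(mem), vapply(mem, length, 1L)),
             member = unlist(lapply(mem, sort), use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Full consensus parentage analysis
#'
#' Ties the pieces together: marker-set selection, per-set confidence
#' calibration, per-set assignment, and the cross-set consensus rule.
#'
#' @param table a QC'd `variant_table`.
#' @param n_sets,set_size,min_support marker-set design (ten sets of 500,
#'   support in at least nine).
#' @param model a [parentage_model()].
#' @param sim_offspring simulated offspring per calibration run.
#' @param seed integer.
#' @param pic_min PIC eligibility threshold for markers.
#' @return list with `pairs` (consensus), `groups`, `per_set` assignments and
#'   `critical` values per set.
#' @export
parentage_analysis <- function(table, n_sets = 10, set_size = 500,
                               min_support = 9, model = parentage_model(),
                               sim_offspring = 2000, seed = 1L,
                               pic_min = 0.35) {
  stats <- compute_site_stats(table)
  sets <- select_marker_sets(stats, n_sets, set_size,
                             seed = derive_seed(seed, 11L), pic_min = pic_min)
  per_set <- vector("list", n_sets)
  critical <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    sub <- subset_variants(table, sites = sets[[i]])
    f <- rowMeans(dosage(sub), na.rm = TRUE) / 2
    critical[[i]] <- simulate_critical_values(
      model, f[f > 0 & f < 1], n_offspring = sim_offspring,
      n_candidates = n_samples(table),
      seed = derive_seed(seed, 100L + i))
    per_set[[i]] <- assign_parents(table, sets[[i]], model, critical[[i]])
  }
  pairs <- consensus_pairs(per_set, min_support)
  list(pairs = pairs, groups = merge_groups(pairs),
       per_set = per_set, critical = critical, marker_sets = sets)
}
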