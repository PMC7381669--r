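test_that("transmission probabilities match hand Mendelian calculations", {
  # parent AA (dosage 0), offspring AA, freq(A) = 0.5: transmit A, draw A
  expect_equal(transmission_probability(0, 0, c(0.5, 0.5)), 0.5)
  expect_equal(transmission_probability(0, 2, c(0.5, 0.5)), 0)   # exclusion
  expect_equal(transmission_probability(1, 1, c(0.3, 0.7)), 0.5)
  expect_equal(transmission_probability(2, 1, c(0.3, 0.7)), 0.3)
  for (gp in 0:2) {
    tot <- sum(vapply(0:2, function(go)
      transmission_probability(gp, go, c(0.3, 0.7)), numeric(1)))
    expect_equal(tot, 1)
  }
  expect_error(transmission_probability(0, 0, c(0.5, 0.4)), "sum to 1")
})

test_that("single-marker LOD reproduces the ln 2 worked example", {
  model <- parentage_model(error = 0)
  # parent AA, offspring AA, freq 0.5: ln(0.5 / 0.25) = ln 2
  expect_equal(pair_lod(0, 0, 0.5, model), log(2))
  # opposite homozygotes exclude the candidate outright
  expect_identical(pair_lod(2, 0, 0.5, model), -Inf)
  # no jointly typed markers is flagged, not silently zero
  r <- pair_lod(c(NA, 1), c(1, NA), c(0.5, 0.5), model)
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "jointly typed")
})

test_that("LOD with mistyping matches brute-force enumeration", {
  model <- parentage_model(error = 0.01)
  q <- c(0.3, 0.5, 0.8)
  for (op in 0:2) for (oo in 0:2) {
    got <- pair_lod(rep(oo, 3), rep(op, 3), q, model)
    want <- sum(vapply(seq_along(q), function(l)
      brute_lod(op, oo, q[l], 0.01), numeric(1)))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("LOD is additive over disjoint marker subsets", {
  model <- parentage_model(error = 0.01)
  set.seed(5)
  q <- runif(20, 0.1, 0.9)
  off <- rbinom(20, 2, q); cand <- rbinom(20, 2, q)
  whole <- pair_lod(off, cand, q, model)
  parts <- pair_lod(off[1:7], cand[1:7], q[1:7], model) +
    pair_lod(off[8:20], cand[8:20], q[8:20], model)
  expect_equal(whole, parts, tolerance = 1e-12)
})

test_that("confidence simulation is calibrated and accepts the stated design", {
  model <- parentage_model(error = 0, prop_sampled = 1, prop_typed = 1)
  q <- rep(0.5, 60)                        # highly informative markers
  cv <- simulate_critical_values(model, q, n_offspring = 400,
                                 n_candidates = 50, seed = 2)
  # with every parent sampled and no error, assignments above the strict
  # critical value are >= 95% correct by construction
  keep <- cv$delta >= cv$strict
  expect_gte(mean(cv$correct[keep]), 0.95)
  expect_error(simulate_critical_values(model, rep(0, 10)), "monomorphic")
})

test_that("assignment success is monotone in marker informativeness", {
  model <- parentage_model(error = 0.01)
  wins_mid <- 0; wins_lo <- 0
  for (r in 1:10) {
    rates <- vapply(c(0.5, 0.15, 0.03), function(q)
      simulate_critical_values(model, rep(q, 40), n_offspring = 500,
                               n_candidates = 40,
                               seed = 300 + r)$success_rate, numeric(1))
    wins_mid <- wins_mid + (rates[1] >= rates[2])
    wins_lo <- wins_lo + (rates[2] >= rates[3])
  }
  expect_gte(wins_mid, 8)
  expect_gte(wins_lo, 8)
})

test_that("trio data with no error recovers every true parent", {
  cfg <- sim_config(n_founders = 40, n_offspring = 12,
                    genotyping_error = 0, missing_rate = 0,
                    n_chromosomes = 2, sites_per_chromosome = 250, seed = 77)
  fo <- simulate_founders(cfg)
  pe <- simulate_pedigree(fo$table, fo$truth, cfg)
  st <- compute_site_stats(pe$table)
  markers <- st$id[order(-st$pic)][1:120]
  res <- assign_parents(pe$table, markers, parentage_model(error = 1e-4))
  expect_true(all(res$parent != res$offspring, na.rm = TRUE))  # self-exclusion
  edges <- pe$truth$pedigree_edges
  for (i in seq_len(nrow(edges))) {
    got <- res$parent[res$offspring == edges$offspring[i]]
    expect_identical(got, edges$parent[i])
  }
})

test_that("with error = 0 an opposite-homozygote candidate is never assigned", {
  cfg <- sim_config(n_founders = 30, n_offspring = 8,
                    genotyping_error = 0, missing_rate = 0,
                    n_chromosomes = 1, sites_per_chromosome = 200, seed = 55)
  fo <- simulate_founders(cfg)
  pe <- simulate_pedigree(fo$table, fo$truth, cfg)
  st <- compute_site_stats(pe$table)
  markers <- st$id[st$maf > 0.1]
  model <- parentage_model(error = 0)
  sub <- subset_variants(pe$table, sites = markers)
  d <- dosage(sub)
  res <- assign_parents(pe$table, markers, model)
  for (j in seq_len(nrow(res))) {
    if (is.na(res$parent[j])) next
    opp <- sum(abs(d[, res$offspring[j]] - d[, res$parent[j]]) == 2,
               na.rm = TRUE)
    expect_equal(opp, 0L)
  }
})

test_that("the consensus rule honors the support threshold exactly", {
  mk <- function(off, par, conf = "strict")
    data.frame(offspring = off, parent = par, lod = 1, delta = 1,
               confidence = conf, reason = NA, stringsAsFactors = FALSE)
  nine <- c(replicate(9, mk("B", "A"), simplify = FALSE),
            list(mk("B", "C")))
  out <- consensus_pairs(nine, min_support = 9)
  expect_identical(out$id1, "A"); expect_identical(out$id2, "B")
  expect_identical(out$support, 9L)
  eight <- c(replicate(8, mk("B", "A"), simplify = FALSE),
             replicate(2, mk("B", "C"), simplify = FALSE))
  expect_equal(nrow(consensus_pairs(eight, min_support = 9)), 0L)
  # direction-agnostic: offspring/parent swapped across sets still counts
  flip <- c(replicate(5, mk("B", "A"), simplify = FALSE),
            replicate(4, mk("A", "B"), simplify = FALSE),
            list(mk("B", "C")))
  out <- consensus_pairs(flip, min_support = 9)
  expect_identical(out$support, 9L)
  expect_error(consensus_pairs(nine, min_support = 11), "exceeds")
})

test_that("crafted per-set assignments match a counting oracle", {
  set.seed(9)
  samples <- LETTERS[1:8]
  sets <- lapply(1:10, function(s) {
    off <- sample(samples, 5)
    par <- vapply(off, function(o) sample(setdiff(samples, o), 1), "")
    data.frame(offspring = off, parent = par, lod = rnorm(5), delta = 1,
               confidence = sample(c("strict", "none"), 5, replace = TRUE),
               reason = NA, stringsAsFactors = FALSE)
  })
  got <- consensus_pairs(sets, min_support = 3)
  # oracle: flat count of unordered strict pairs
  keys <- unlist(lapply(sets, function(a) {
    a <- a[a$confidence == "strict", ]
    unique(paste(pmin(a$offspring, a$parent), pmax(a$offspring, a$parent)))
  }))
  tab <- table(keys)
  want <- sort(names(tab)[tab >= 3])
  expect_identical(sort(paste(got$id1, got$id2)), want)
})

test_that("family groups equal connected components (union-find oracle)", {
  pairs <- data.frame(id1 = c("A", "B"), id2 = c("B", "C"))
  g <- merge_groups(pairs)
  expect_identical(sort(g$member[g$group == 1]), c("A", "B", "C"))
  two <- merge_groups(data.frame(id1 = c("A", "C"), id2 = c("B", "D")))
  expect_equal(max(two$group), 2L)
  set.seed(11)
  for (r in 1:5) {
    nodes <- sprintf("N%02d", 1:15)
    e <- data.frame(id1 = sample(nodes, 12, TRUE),
                    id2 = sample(nodes, 12, TRUE))
    e <- e[e$id1 != e$id2, ]
    got <- merge_groups(e)
    want <- union_find_groups(as.matrix(e))
    got_sets <- lapply(split(got$member, got$group), sort)
    want_sets <- lapply(want, sort)
    expect_setequal(unname(vapply(got_sets, paste, "", collapse = ",")),
                    unname(vapply(want_sets, paste, "", collapse = ",")))
  }
})

test_that("consensus recall degrades gracefully as mistyping rises", {
  recalls <- vapply(c(0, 0.05), function(err) {
    cfg <- sim_config(n_founders = 50, n_offspring = 10,
                      genotyping_error = err, missing_rate = 0,
                      n_chromosomes = 2, sites_per_chromosome = 250,
                      seed = 19)
    fo <- simulate_founders(cfg)
    pe <- simulate_pedigree(fo$table, fo$truth, cfg)
    st <- compute_site_stats(pe$table)
    markers <- st$id[order(-st$pic)][1:100]
    res <- assign_parents(pe$table, markers,
                          parentage_model(error = max(err, 1e-3)))
    edges <- pe$truth$pedigree_edges
    mean(vapply(seq_len(nrow(edges)), function(i)
      identical(res$parent[res$offspring == edges$offspring[i]],
                edges$parent[i]), logical(1)))
  }, numeric(1))
  expect_gte(recalls[1], recalls[2])
  expect_gte(recalls[1], 0.9)
})
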