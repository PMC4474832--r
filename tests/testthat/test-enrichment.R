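test_that("SumStat sums weighted gene statistics over mapped members", {
  sc <- make_scores(c(2, 3, 5), c("g1", "g2", "g3"))
  off <- weightScheme(enabled = FALSE)
  expect_equal(sumstatScore(sc, c("g1", "g3"), off, minMapped = 1), 7)
  on <- weightScheme(igeneWeight = 2)
  expect_equal(sumstatScore(sc, c("g1", "g3"), on, igenes = "g3",
                            minMapped = 1), 12)
  expect_message(
    skipped <- sumstatScore(sc, "absent", on, minMapped = 1), "skipped")
  expect_true(is.na(skipped))
})

test_that("the enrichment score walks the ranking to its signed extremum", {
  sc <- make_scores(c(4, 3, 2, 1), c("a", "b", "c", "d"))
  expect_equal(gseaEs(sc, "a"), 1)
  expect_equal(gseaEs(sc, "d"), -1)
  expect_equal(gseaEs(sc, c("a", "b", "c", "d")), 1)
  expect_error(gseaEs(make_scores(c(0, 0), c("a", "b")), "a"), "zero")
})

test_that("the enrichment score matches direct enumeration for small gene lists", {
  set.seed(501)
  for (rep in 1:200) {
    n <- sample(2:6, 1)
    stats_ <- sort(stats::rexp(n) + 0.01, decreasing = TRUE)
    ids <- paste0("g", 1:n)
    k <- sample(1:(n - 1), 1)
    members <- sample(ids, k)
    sc <- make_scores(stats_, ids)
    es <- gseaEs(sc, members)
    expect_equal(es, oracle_es(stats_, ids %in% members), tolerance = 1e-12)
    expect_true(es >= -1 - 1e-12 && es <= 1 + 1e-12)
  }
})

test_that("permutation nulls are reproducible and collapse when stats are constant", {
  sc <- make_scores(rep(2.5, 40))
  n1 <- permutationNull(sc, 8, B = 10, seed = 99)
  n2 <- permutationNull(sc, 8, B = 10, seed = 99)
  expect_identical(n1, n2)
  expect_true(all(n1 == 2.5 * 8))
  expect_error(permutationNull(sc, 100, B = 5, seed = 1), "exceeds")
  expect_equal(formals(permutationNull)$B, 15000)
})

test_that("empirical p-values use the +1/(B+1) convention with >= counting", {
  expect_equal(empiricalP(10, 1:9), 1 / 10)
  expect_equal(empiricalP(5, c(1:4, 5)), (1 + 1) / 6)   # tie counts
  expect_equal(empiricalP(0, 1:9), 1)
  expect_equal(empiricalP(-0.9, c(0.95, -0.2, 0.1), "gsea"), 2 / 4)
  expect_error(empiricalP(1, numeric()), "empty")
})

test_that("BH adjustment matches an independent step-up implementation", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.2), 0.2)
  set.seed(77)
  for (r in 1:1000) {
    p <- stats::runif(sample(1:40, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("pathway analysis is seed-reproducible and weight-coherent", {
  spec <- simulationSpec(nGenes = 300, snpsPerGeneMean = 4, nIgenes = 40,
                         seed = 21)
  sim <- simulateStudy(spec, nSets = 25, sizeRange = c(10, 30))
  scores <- scoreGenes(sim$assoc, sim$annotation)
  cc <- filterBySize(newCuratedCatalog(sim$catalog, sim$truth$igenes))

  r1 <- runPathwayAnalysis(scores, cc, sim$truth$igenes, B = 100, seed = 5)
  r2 <- runPathwayAnalysis(scores, cc, sim$truth$igenes, B = 100, seed = 5)
  expect_identical(resultTable(r1), resultTable(r2))

  tab <- resultTable(r1)
  info <- curationInfo(cc)
  zero_ig <- info$set_id[info$n_igenes == 0]
  for (id in zero_ig) {
    rows <- tab[tab$set_id == id, ]
    expect_equal(rows$p_perm[rows$weighted], rows$p_perm[!rows$weighted])
  }
  # doubling I-Gene weight strictly increases the observed score when a
  # pathway holds an I-Gene with positive statistic
  with_ig <- info$set_id[info$n_igenes > 0]
  rows <- tab[tab$set_id %in% with_ig, ]
  expect_true(all(rows$score[rows$weighted] >
                  rows$score[!rows$weighted]))
  # BH within each weighting column
  for (w in c(FALSE, TRUE)) {
    sel <- tab$weighted == w
    expect_equal(tab$p_adj[sel], oracle_bh(tab$p_perm[sel]))
  }
})

test_that("GSEA-mode pathway analysis returns bounded scores and valid p-values", {
  spec <- simulationSpec(nGenes = 120, snpsPerGeneMean = 3, nIgenes = 20,
                         seed = 31)
  sim <- simulateStudy(spec, nSets = 6, sizeRange = c(8, 15))
  scores <- scoreGenes(sim$assoc, sim$annotation)
  cc <- filterBySize(newCuratedCatalog(sim$catalog, sim$truth$igenes),
                     minSize = 5)
  res <- runPathwayAnalysis(scores, cc, sim$truth$igenes, B = 50, seed = 2,
                            method = "gsea")
  tab <- resultTable(res)
  expect_true(all(tab$es >= -1 & tab$es <= 1))
  expect_true(all(tab$p_perm > 0 & tab$p_perm <= 1))
})
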