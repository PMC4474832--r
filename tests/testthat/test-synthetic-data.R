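test_that("gene annotation generation is deterministic with disjoint intervals", {
  spec <- simulationSpec(nGenes = 10, seed = 1)
  a1 <- generateGeneAnnotation(spec)
  a2 <- generateGeneAnnotation(spec)
  expect_identical(a1, a2)
  expect_equal(length(a1), 10L)
  ovl <- GenomicRanges::findOverlaps(a1, drop.self = TRUE)
  expect_equal(length(ovl), 0L)
  expect_true(all(a1$n_snps >= 1L))

  single <- generateGeneAnnotation(simulationSpec(nGenes = 1, seed = 3))
  expect_equal(length(single), 1L)
})

test_that("null summary statistics are uniform and reproducible", {
  spec <- simulationSpec(nGenes = 2000, snpsPerGeneMean = 5, seed = 1)
  ann <- generateGeneAnnotation(spec)
  assoc <- generateNullAssoc(ann, spec)
  expect_gt(nrow(assoc), 8000)
  expect_true(all(assoc$pvalue >= 0 & assoc$pvalue <= 1))
  ks <- stats::ks.test(assoc$pvalue, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_identical(assoc, generateNullAssoc(ann, spec))
})

test_that("planting with delta = 0 leaves the p-value distribution uniform", {
  spec <- simulationSpec(nGenes = 400, snpsPerGeneMean = 3, seed = 11)
  ann <- generateGeneAnnotation(spec)
  assoc <- generateNullAssoc(ann, spec)
  genes <- ann$gene_id[1:200]
  planted <- plantAssociation(assoc, ann, genes, delta = 0, spec)
  changed <- planted$pvalue[planted$pvalue != assoc$pvalue]
  expect_gt(length(changed), 100)  # one replacement per gene, mostly new draws
  ks <- stats::ks.test(planted$pvalue, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("planting a positive effect depresses affected genes' minimum p", {
  affected_means <- numeric(20)
  unaffected_means <- numeric(20)
  for (r in 1:20) {
    spec <- simulationSpec(nGenes = 60, snpsPerGeneMean = 4, seed = 100 + r)
    ann <- generateGeneAnnotation(spec)
    assoc <- generateNullAssoc(ann, spec)
    genes <- ann$gene_id[1:20]
    assoc <- plantAssociation(assoc, ann, genes, delta = 4, spec)
    scores <- scoreGenes(assoc, ann, windowKb = 0)
    aff <- scores$gene_id %in% genes
    affected_means[r] <- mean(scores$p_min[aff])
    unaffected_means[r] <- mean(scores$p_min[!aff])
  }
  expect_lt(mean(affected_means), mean(unaffected_means))

  spec <- simulationSpec(nGenes = 5, seed = 1)
  ann <- generateGeneAnnotation(spec)
  assoc <- generateNullAssoc(ann, spec)
  expect_error(plantAssociation(assoc, ann, "NOPE", 1, spec), "NOPE")
})

test_that("synthetic interaction tables recover the planted I-Genes by strict filtering", {
  spec <- simulationSpec(nGenes = 100, nIgenes = 25, seed = 5)
  ann <- generateGeneAnnotation(spec)
  ppi <- generatePpi(ann, ann$gene_id[1], spec)
  expect_equal(nrow(partners(ppi)), 50L)
  expect_length(iGenes(ppi), 25L)
  expect_false(ann$gene_id[1] %in% partners(ppi)$gene_id)
  expect_identical(partners(generatePpi(ann, ann$gene_id[1], spec)),
                   partners(ppi))
  expect_error(generatePpi(ann, "NOPE", spec), "absent")
  bad <- simulationSpec(nGenes = 10, nIgenes = 10, seed = 1)
  annb <- generateGeneAnnotation(bad)
  expect_error(generatePpi(annb, annb$gene_id[1], bad), "smaller")
})

test_that("catalogue generation realizes requested sizes and I-Gene fractions", {
  spec <- simulationSpec(nGenes = 200, nIgenes = 40, seed = 9)
  ann <- generateGeneAnnotation(spec)
  ppi <- generatePpi(ann, ann$gene_id[1], spec)
  ig <- iGenes(ppi)
  cat <- generateCatalog(ann, ig, nSets = 30, sizeRange = c(20, 20),
                         igeneFracs = c(0.7, 0, 0.25), spec)
  sz <- setSizes(cat)
  expect_true(all(sz == 20L))
  nIg <- vapply(geneSets(cat), function(g) length(intersect(g, ig)),
                integer(1))
  expect_equal(unname(nIg[1]), 14L)          # 70% of 20
  expect_equal(unname(nIg[2]), 0L)           # fraction zero
  expect_equal(unname(nIg[3]), 5L)           # 25% of 20
  expect_true(all(nIg == rep(c(14L, 0L, 5L), 10)))

  varied <- generateCatalog(ann, ig, nSets = 50, sizeRange = c(10, 60),
                            igeneFracs = 0.1, spec)
  expect_true(all(setSizes(varied) >= 10 & setSizes(varied) <= 60))

  expect_error(
    generateCatalog(ann, ig, nSets = 1, sizeRange = c(150, 150),
                    igeneFracs = 0.9, spec),
    "I-Genes")
})
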