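write_tmp <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("GMT reader parses sets, deduplicates with a warning, rejects short lines", {
  f <- write_tmp(c("PW1\tdesc\tG1\tG2", "PW2\tKEGG\tG3\tG4\tG5"), ".gmt")
  cat <- readGmt(f)
  expect_s4_class(cat, "GeneSetCatalog")
  expect_equal(length(cat), 2L)
  expect_equal(unname(setSizes(cat)), c(2L, 3L))
  expect_equal(geneSets(cat)$PW1, c("G1", "G2"))
  expect_equal(unname(setSource(cat)["PW2"]), "KEGG")

  fd <- write_tmp("PW1\td\tG1\tG1\tG2", ".gmt")
  expect_warning(cat2 <- readGmt(fd), "duplicate")
  expect_equal(unname(setSizes(cat2)), 2L)

  fb <- write_tmp(c("PW1\tdesc\tG1", "PW2\tdesc"), ".gmt")
  expect_error(readGmt(fb), "line 2")
})

test_that("GMT writing round-trips", {
  cat <- GeneSetCatalog(list(A = c("G1", "G2"), B = c("G2", "G3", "G4")),
                        c("src1", "src2"))
  f <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(cat, f)
  back <- readGmt(f)
  expect_equal(geneSets(back), geneSets(cat))
  expect_equal(setSource(back), setSource(cat))
})

test_that("interaction reader keeps evidence strictly above the threshold", {
  f <- write_tmp(c("gene_id\tevidence", "G1\t0.41", "G2\t0.40", "G3\t0.95"))
  ppi <- readInteractionTable(f, seedGene = "SEED", minEvidence = 0.4)
  expect_setequal(partners(ppi)$gene_id, c("G1", "G3"))
  expect_false("G2" %in% partners(ppi)$gene_id)  # equality is exclusion
  expect_setequal(iGenes(ppi), c("G1", "G3"))

  fb <- write_tmp(c("G1\t0.5", "G3\t1.2"))
  expect_error(readInteractionTable(fb, "SEED"), "out of \\[0, 1\\]")
})

test_that("interaction reader rescales the 0-1000 evidence dialect", {
  f <- write_tmp(c("G1\t410", "G2\t400", "G3\t950"))
  ppi <- readInteractionTable(f, seedGene = "SEED", minEvidence = 0.4)
  expect_setequal(partners(ppi)$gene_id, c("G1", "G3"))
  expect_equal(sort(partners(ppi)$evidence), c(0.41, 0.95))
})

test_that("association reader validates rows and uniqueness", {
  f <- write_tmp(c("snp\tchr\tpos\tp", "rs1\tchr1\t100\t0.5",
                   "rs2\tchr1\t200\t0.01", "rs3\tchr2\t50\t1.0"))
  assoc <- readAssocTable(f)
  expect_equal(nrow(assoc), 3L)
  expect_type(assoc$pos, "integer")
  expect_named(assoc, c("snp_id", "chrom", "pos", "pvalue"))

  fb <- write_tmp(c("snp\tchr\tpos\tp", "rs1\tchr1\t100\t1.5"))
  expect_error(readAssocTable(fb), "row 1")

  fd <- write_tmp(c("snp\tchr\tpos\tp", "rs1\tchr1\t100\t0.5",
                    "rs1\tchr1\t200\t0.2"))
  expect_error(readAssocTable(fd), "rs1")
})

test_that("FASTA reader returns ordered, uppercased records and rejects malformed files", {
  f <- write_tmp(c(">a", "acgt"), ".fa")
  seqs <- readFasta(f, "nucleotide")
  expect_equal(length(seqs), 1L)
  expect_equal(as.character(seqs[[1]]), "ACGT")

  f2 <- write_tmp(c(">first", "ACGT", ">second", "GGCC"), ".fa")
  two <- readFasta(f2, "nucleotide")
  expect_equal(names(two), c("first", "second"))

  fe <- write_tmp(c(">a", ""), ".fa")
  expect_error(readFasta(fe, "nucleotide"), "empty sequence|no records")

  fh <- write_tmp(c("ACGT", ">a", "ACGT"), ".fa")
  expect_error(readFasta(fh, "nucleotide"), "before header")

  f0 <- withr::local_tempfile(fileext = ".fa")
  file.create(f0)
  expect_error(readFasta(f0, "nucleotide"), "empty")
})

test_that("BED annotation round-trips through 0-based half-open coordinates", {
  ann <- make_annotation(c("GA", "GB"), "chr1", c(1001, 5001), c(2000, 6000))
  f <- withr::local_tempfile(fileext = ".bed")
  writeGeneBed(ann, f)
  # on disk: BED start is 0-based
  fields <- strsplit(readLines(f)[1], "\t")[[1]]
  expect_equal(as.integer(fields[2]), 1000L)
  back <- readGeneBed(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(ann))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(ann))
  expect_equal(back$gene_id, ann$gene_id)
})

test_that("Newick serialisation covers 2-taxon and star trees and round-trips", {
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(writeNewick(njTree(d2)), "(A:0.5,B:0.5);")

  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  txt <- writeNewick(njTree(d3))
  reread <- ape::read.tree(text = txt)
  expect_equal(sort(reread$tip.label), c("A", "B", "C"))
  lens <- reread$edge.length[match(1:3, reread$edge[, 2])]
  expect_equal(sort(lens), c(0.5, 1.5, 2.5))

  # round-trip on a larger random tree
  set.seed(42)
  tr <- ape::rtree(6)
  back <- ape::read.tree(text = writeNewick(tr))
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)

  bad <- ape::rtree(3)
  bad$tip.label[2] <- ""
  expect_error(writeNewick(bad), "unnamed")
})

test_that("report writer emits the fixed column layout with 2-decimal percentages", {
  tab <- data.frame(
    set_id = rep("PW1", 2), source = "KEGG", n_genes = 20L, n_mapped = 20L,
    pct_igenes = 70, method = "sumstat", weighted = c(FALSE, TRUE),
    score = c(10, 15), es = NA_real_, p_perm = c(0.02, 0.03),
    p_adj = c(0.02, 0.03), n_permutations = 100L,
    stringsAsFactors = FALSE)
  res <- new("EnrichmentResult", table = tab, params = list(B = 100L))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeReport(res, f)
  lines <- readLines(f)
  expect_length(lines, 2L)
  expect_equal(strsplit(lines[1], "\t")[[1]],
               c("pathway", "source", "n_genes", "n_mapped", "pct_igenes",
                 "p_unweighted", "p_weighted", "p_adj_unweighted",
                 "p_adj_weighted"))
  expect_equal(strsplit(lines[2], "\t")[[1]][5], "70.00")

  empty <- new("EnrichmentResult", table = tab[0, ], params = list())
  expect_error(writeReport(empty, f), "empty")
})
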