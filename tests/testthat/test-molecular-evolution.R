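library(Biostrings)

aa <- function(...) {
  x <- c(...)
  AAStringSet(setNames(x, names(x)))
}
dna <- function(...) {
  x <- c(...)
  DNAStringSet(setNames(x, names(x)))
}

test_that("global alignment handles identity, gaps, and input errors", {
  self <- globalAlign(dna(s1 = "ACGT"), dna(s2 = "ACGT"))
  expect_equal(self$row_a, "ACGT")
  expect_equal(self$row_b, "ACGT")

  gapped <- globalAlign(dna(s1 = "ACGT"), dna(s2 = "AGT"))
  expect_equal(nchar(gapped$row_a), 4L)
  expect_equal(sum(strsplit(gapped$row_b, "")[[1]] == "-"), 1L)
  expect_equal(gsub("-", "", gapped$row_b), "AGT")

  expect_error(globalAlign(dna(s1 = "ACGT"), aa(p = "MKV")), "align")
  expect_error(globalAlign(dna(s1 = ""), dna(s2 = "ACGT")), "empty")
})

test_that("percent identity is symmetric and distinguishes trimmed from global", {
  expect_equal(percentIdentity(globalAlign(dna(a = "ACGT"), dna(b = "ACGA"))),
               75)
  expect_equal(percentIdentity(globalAlign(aa(a = "MKVLT"), aa(b = "MKVLT"))),
               100)
  set.seed(12)
  for (r in 1:20) {
    x <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
    pid_xy <- percentIdentity(globalAlign(dna(a = x), dna(b = y)))
    pid_yx <- percentIdentity(globalAlign(dna(b = y), dna(a = x)))
    expect_equal(pid_xy, pid_yx, tolerance = 1e-9)
  }
  # terminal overhang ignored in trimmed mode, counted in global mode
  overhang <- globalAlign(dna(a = "AAAACGTACGT"), dna(b = "CGTACGT"))
  expect_equal(percentIdentity(overhang, "trimmed"), 100)
  expect_lt(percentIdentity(overhang, "global"), 100)
})

test_that("back-translation maps protein columns to codons and checks coding", {
  protA <- aa(a = "MKF")
  protB <- aa(b = "MF")
  aln <- globalAlign(protA, protB)
  caln <- backtranslate(aln, dna(a = "ATGAAATTTTAA"), dna(b = "ATGTTT"))
  expect_length(caln$codons_a, 3L)
  expect_equal(caln$codons_a, c("ATG", "AAA", "TTT"))  # trailing stop stripped
  expect_equal(sum(caln$codons_b == "---"), 1L)

  gapless <- backtranslate(globalAlign(aa(a = "MK"), aa(b = "MK")),
                           dna(a = "ATGAAA"), dna(b = "ATGAAG"))
  expect_equal(gapless$codons_b, c("ATG", "AAG"))

  expect_error(
    backtranslate(globalAlign(aa(a = "MK"), aa(b = "MK")),
                  dna(a = "ATGCCC"), dna(b = "ATGAAA")),
    "residue 2")
})

test_that("NG86 counts sites and differences as the codon table dictates", {
  mk <- function(a, b) structure(list(codons_a = a, codons_b = b),
                                 class = "CodonAln")
  same <- ng86(mk(c("ATG", "AAA"), c("ATG", "AAA")))
  expect_equal(same$Sd, 0)
  expect_equal(same$Nd, 0)
  expect_equal(same$dS, 0)
  expect_equal(same$dN, 0)
  expect_true(is.na(same$omega))

  # TTT: only the TTC mutant preserves Phe among the 9 single-base mutants
  expect_equal(ng86(mk("TTT", "TTT"))$S_sites, 1 / 3, tolerance = 1e-12)

  two <- ng86(mk(c("AAA", "AAA"), c("AAG", "AAC")))
  expect_equal(two$Sd, 1)   # AAA->AAG, Lys->Lys
  expect_equal(two$Nd, 1)   # AAA->AAC, Lys->Asn
  expect_equal(two$S_sites + two$N_sites, 3 * two$n_codons)

  gappy <- ng86(mk(c("ATG", "---", "AAA"), c("ATG", "CCC", "AAA")))
  expect_equal(gappy$n_codons, 2L)  # pairwise deletion of the gapped pair
  expect_error(ng86(mk("---", "ATG")), "no comparable")
})

test_that("NG86 agrees with explicit pathway enumeration on random codon pairs", {
  set.seed(86)
  for (r in 1:300) {
    n <- sample(1:3, 1)
    a <- random_codons(n)
    b <- random_codons(n)
    got <- ng86(structure(list(codons_a = a, codons_b = b),
                          class = "CodonAln"))
    want <- oracle_ng86(a, b)
    expect_equal(got$S_sites, want$S, tolerance = 1e-9)
    expect_equal(got$N_sites, want$N, tolerance = 1e-9)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
    expect_equal(got$S_sites + got$N_sites, 3 * n, tolerance = 1e-9)
  }
})

test_that("p-distance matrices are symmetric with zero diagonal", {
  seqs <- dna(a = "ACGTACGT", b = "ACGTACGA", c = "ACGTACGT")
  d <- pdistanceMatrix(seqs)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["a", "c"], 0)
  expect_equal(pdistanceMatrix(dna(x = "ACGT", y = "ACGA"))["x", "y"], 0.25)
})

test_that("neighbor-joining reproduces closed forms and additive topologies", {
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr <- njTree(d3)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens[["A"]], 0.5)
  expect_equal(lens[["B"]], 1.5)
  expect_equal(lens[["C"]], 2.5)

  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- njTree(d2)
  expect_equal(t2$edge.length, c(0.5, 0.5))

  set.seed(4321)
  for (r in 1:20) {
    case <- random_additive_case(sample(4:8, 1))
    rec <- njTree(case$d)
    expect_equal(phangorn::RF.dist(rec, case$tree), 0)
  }

  bad <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(njTree(bad), "symmetric")
})

test_that("pairwise dN/dS over diverged synthetic orthologs stays below one under purifying acceptance", {
  # simulate a codon ancestor and two descendants where nonsynonymous
  # substitutions are accepted with low probability
  set.seed(99)
  evolve <- function(codons, n_events, accept_nonsyn = 0.1) {
    bases <- c("A", "C", "G", "T")
    i <- 0
    while (i < n_events) {
      at <- sample(length(codons), 1)
      ch <- strsplit(codons[at], "")[[1]]
      pos <- sample(3, 1)
      ch[pos] <- sample(setdiff(bases, ch[pos]), 1)
      mut <- paste(ch, collapse = "")
      aa_old <- seqinr::translate(strsplit(codons[at], "")[[1]])
      aa_new <- seqinr::translate(strsplit(mut, "")[[1]])
      if (aa_new == "*") next
      if (aa_new != aa_old && stats::runif(1) > accept_nonsyn) next
      codons[at] <- mut
      i <- i + 1
    }
    codons
  }
  anc <- random_codons(200)
  cds <- Biostrings::DNAStringSet(c(
    sp1 = paste(evolve(anc, 25), collapse = ""),
    sp2 = paste(evolve(anc, 25), collapse = ""),
    sp3 = paste(evolve(anc, 40), collapse = "")))
  tab <- ng86Pairwise(cds)
  expect_equal(nrow(tab), 3L)
  expect_true(all(is.finite(tab$omega)))
  expect_true(all(tab$omega < 1))
})
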