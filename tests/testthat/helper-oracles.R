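# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package:
# translation goes through seqinr, permutations and running sums are
# enumerated with plain loops.

# --- Benjamini-Hochberg step-up, written out longhand ----------------------
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in seq(m, 1)) {
    val <- min(1, m * p[ord[i]] / i)
    prev <- min(prev, val)
    adj[ord[i]] <- prev
  }
  adj
}

# --- GSEA running sum by direct enumeration --------------------------------
oracle_es <- function(stat_desc, is_hit) {
  hit_sum <- sum(stat_desc[is_hit])
  n_miss <- sum(!is_hit)
  running <- 0
  best <- 0
  best_abs <- -1
  for (i in seq_along(stat_desc)) {
    running <- running +
      if (is_hit[i]) stat_desc[i] / hit_sum else -1 / n_miss
    if (abs(running) > best_abs) {
      best_abs <- abs(running)
      best <- running
    }
  }
  best
}

# --- Nei-Gojobori counting with explicit pathway enumeration ---------------
oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

oracle_syn_sites <- function(codon) {
  aa <- oracle_translate(codon)
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (b in bases) {
      ch <- strsplit(codon, "")[[1]]
      if (b == ch[pos]) next
      ch[pos] <- b
      if (oracle_translate(paste(ch, collapse = "")) == aa) s <- s + 1 / 3
    }
  }
  s
}

oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

oracle_pathway_counts <- function(ca, cb, allow_stops = FALSE) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0) return(c(0, 0))
  acc <- list()
  for (ord in oracle_permutations(pos)) {
    cur <- a
    sd <- nd <- 0
    blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b[p]
      if (!allow_stops && oracle_translate(paste(nxt, collapse = "")) == "*") {
        blocked <- TRUE
        break
      }
      if (oracle_translate(paste(cur, collapse = "")) ==
          oracle_translate(paste(nxt, collapse = "")))
        sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (!blocked) acc[[length(acc) + 1]] <- c(sd, nd)
  }
  if (length(acc) == 0) return(oracle_pathway_counts(ca, cb, allow_stops = TRUE))
  Reduce(`+`, acc) / length(acc)
}

oracle_ng86 <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, oracle_syn_sites, numeric(1))) +
        sum(vapply(codons_b, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(codons_a) - S
  sd <- nd <- 0
  for (i in seq_along(codons_a)) {
    cnt <- oracle_pathway_counts(codons_a[i], codons_b[i])
    sd <- sd + cnt[1]
    nd <- nd + cnt[2]
  }
  list(S = S, N = N, Sd = sd, Nd = nd)
}

# random sense codons (no stops)
random_codons <- function(n) {
  stops <- c("TAA", "TAG", "TGA")
  all64 <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                           c("A","C","G","T"), paste0))
  sample(setdiff(all64, stops), n, replace = TRUE)
}

# --- small fixtures --------------------------------------------------------
make_scores <- function(stats, ids = sprintf("g%02d", seq_along(stats))) {
  data.frame(gene_id = ids, m_snps = 1L, p_min = NA_real_,
             p_fosco = NA_real_, stat = stats, stringsAsFactors = FALSE)
}

# a tiny annotation with explicit coordinates, for assignment tests
make_annotation <- function(gene_id, chrom, start, end) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    gene_id = gene_id)
  names(gr) <- gene_id
  gr
}

make_assoc <- function(snp_id, chrom, pos, pvalue) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
             pvalue = pvalue, stringsAsFactors = FALSE)
}

# random additive tree distances for neighbor-joining recovery checks
random_additive_case <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, br = stats::runif(2 * n_taxa - 2, 0.1, 1))
  list(tree = ape::unroot(tree), d = ape::cophenetic.phylo(tree))
}
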