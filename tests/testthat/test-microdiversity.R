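test_that("nucleotide_diversity: closed forms and invariances", {
  empty <- snv_profile("g", data.frame(contig = character(),
                                       position = integer(),
                                       ref = character(), A = integer(),
                                       C = integer(), G = integer(),
                                       T = integer()))
  expect_equal(nucleotide_diversity(empty, 100), 0)
  # one biallelic site at 0.5/0.5 in a 100-bp genome
  pr <- snv_profile("g", data.frame(contig = "c1", position = 10L,
                                    ref = "A", A = 25L, C = 25L,
                                    G = 0L, T = 0L))
  expect_equal(nucleotide_diversity(pr, 100), 0.005)
  # frequencies only: scaling all counts leaves pi unchanged
  pr3 <- snv_profile("g", data.frame(contig = "c1", position = 10L,
                                     ref = "A", A = 75L, C = 75L,
                                     G = 0L, T = 0L))
  expect_equal(nucleotide_diversity(pr3, 100),
               nucleotide_diversity(pr, 100))
  # sites failing filters count as monomorphic
  low <- snv_profile("g", data.frame(contig = "c1", position = 10L,
                                     ref = "A", A = 2L, C = 2L,
                                     G = 0L, T = 0L))
  expect_equal(nucleotide_diversity(low, 100, min_total = 5), 0)
  # zero-total site is an error (constructed around the class validator)
  broken <- structure(list(genome_id = "g",
                           sites = data.frame(contig = "c1", position = 1L,
                                              ref = "A", A = 0L, C = 0L,
                                              G = 0L, T = 0L)),
                      class = "snv_profile")
  expect_error(nucleotide_diversity(broken, 100), "zero total")
})

test_that("site pi is maximised at equal allele frequencies", {
  set.seed(14)
  for (i in 1:20) {
    f <- stats::rgamma(4, 1); f <- f / sum(f)
    expect_lte(1 - sum(f^2), 1 - sum(rep(0.25, 4)^2) + 1e-12)
  }
})

# independent NG86 oracle: enumerate the 9 single-nucleotide mutations of
# each codon against the genetic code
oracle_sites <- function(seq) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  starts <- seq(1, nchar(seq), 3)
  syn <- 0; tot_codons <- 0
  for (s in starts) {
    cod <- substr(seq, s, s + 2)
    if (grepl("N", cod)) next
    tot_codons <- tot_codons + 1
    for (pos in 1:3) for (b in setdiff(bases, substr(cod, pos, pos))) {
      mut <- cod; substr(mut, pos, pos) <- b
      if (code[[mut]] == code[[cod]]) syn <- syn + 1 / 3
    }
  }
  c(nonsyn = 3 * tot_codons - syn, syn = syn)
}

test_that("count_sites matches the genetic-code enumeration oracle", {
  expect_equal(unname(count_sites("TTT")), c(8 / 3, 1 / 3))
  expect_equal(unname(count_sites("ATG")), c(3, 0))
  expect_error(count_sites("ACGT"), "divisible by 3")
  set.seed(15)
  for (i in 1:10) {
    g <- rand_seq(30)
    got <- count_sites(g)
    ref <- oracle_sites(g)
    expect_equal(unname(got), unname(ref), tolerance = 1e-12)
    # conservation: syn + nonsyn = 3 per counted codon
    expect_equal(sum(got), 30, tolerance = 1e-12)
  }
  # codons containing N are skipped
  expect_equal(sum(count_sites("TTTNNNATG")), 6)
})

test_that("pnps classifies synonymous and nonsynonymous changes", {
  # gene = contig = ATG AAA TTT CCC (12 bp, plus strand)
  contig <- c(c1 = "ATGAAATTTCCC")
  genes <- data.frame(gene_id = "g1", contig = "c1", start = 1L, end = 12L,
                      strand = "+")
  mk_prof <- function(sites) snv_profile("gen", sites)
  # TTT -> TTC at position 9 is synonymous
  syn_site <- data.frame(contig = "c1", position = 9L, ref = "T",
                         A = 0L, C = 10L, G = 0L, T = 40L)
  res <- pnps(mk_prof(syn_site), genes, contig)
  expect_equal(res$s_changes, 1)
  expect_equal(res$n_changes, 0)
  expect_equal(res$pnps, 0)
  expect_equal(res$classification, "purifying")
  # AAA -> GAA at position 4 is nonsynonymous; no syn change -> undefined
  non_site <- data.frame(contig = "c1", position = 4L, ref = "A",
                         A = 40L, C = 0L, G = 10L, T = 0L)
  res2 <- pnps(mk_prof(non_site), genes, contig)
  expect_equal(res2$n_changes, 1)
  expect_true(is.na(res2$pnps))
  expect_equal(res2$classification, "undefined")
  # multi-allelic site contributes each minor allele separately
  multi <- data.frame(contig = "c1", position = 4L, ref = "A",
                      A = 30L, C = 10L, G = 10L, T = 0L)
  res3 <- pnps(mk_prof(multi), genes, contig)
  expect_equal(res3$n_changes + res3$s_changes, 2)
  # SNVs outside any gene are counted, not fatal
  out_site <- data.frame(contig = "c1", position = 9L, ref = "T",
                         A = 0L, C = 10L, G = 0L, T = 40L)
  genes_short <- data.frame(gene_id = "g1", contig = "c1", start = 1L,
                            end = 6L, strand = "+")
  res4 <- pnps(mk_prof(out_site), genes_short, contig)
  expect_equal(attr(res4, "n_unassigned"), 1)
})

test_that("pnps handles minus-strand genes via reverse complement", {
  # genomic AAACAT read on '-' is ATGTTT (Met-Phe)
  contig <- c(c1 = "AAACAT")
  genes <- data.frame(gene_id = "gneg", contig = "c1", start = 1L,
                      end = 6L, strand = "-")
  # genome position 1 ref A -> G means coding TTT -> TTC: synonymous
  prof <- snv_profile("g", data.frame(contig = "c1", position = 1L,
                                      ref = "A", A = 40L, C = 0L,
                                      G = 10L, T = 0L))
  res <- pnps(prof, genes, contig)
  expect_equal(res$s_changes, 1)
  expect_equal(res$n_changes, 0)
  # genome position 6 ref T -> C means coding ATG -> GTG: nonsynonymous
  prof2 <- snv_profile("g", data.frame(contig = "c1", position = 6L,
                                       ref = "T", A = 0L, C = 10L,
                                       G = 0L, T = 40L))
  res2 <- pnps(prof2, genes, contig)
  expect_equal(res2$n_changes, 1)
})

test_that("uniform random mutations give pooled pN/pS near 1 (small run)", {
  set.seed(16)
  n_genes <- 60; gene_len <- 300
  contig_seq <- character(n_genes)
  for (i in seq_len(n_genes)) contig_seq[i] <- rand_seq(gene_len)
  contig <- c(c1 = paste(contig_seq, collapse = ""))
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
                      contig = "c1",
                      start = (seq_len(n_genes) - 1L) * gene_len + 1L,
                      end = seq_len(n_genes) * gene_len,
                      strand = rep(c("+", "-"), length.out = n_genes))
  L <- nchar(contig)
  pos <- sample.int(L, 600)
  refs <- strsplit(contig[[1]], "")[[1]][pos]
  alts <- vapply(refs, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  counts <- matrix(0L, length(pos), 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[cbind(seq_along(pos), match(refs, colnames(counts)))] <- 25L
  counts[cbind(seq_along(pos), match(alts, colnames(counts)))] <- 25L
  prof <- snv_profile("g", data.frame(contig = "c1", position = pos,
                                      ref = refs, counts))
  sel <- pnps(prof, genes, contig)
  pooled <- pooled_pnps(sel)
  N <- sum(sel$n_changes); S <- sum(sel$s_changes)
  sigma <- pooled * sqrt(1 / N + 1 / S)
  expect_lt(abs(pooled - 1), 3 * sigma)
})

test_that("rank_selection orders by ratio, excludes undefined, breaks ties", {
  sel <- data.frame(gene_id = c("gB", "gA", "gC", "gD", "gE"),
                    n_changes = 1, s_changes = c(1, 1, 1, 0, 1),
                    nonsyn_sites = 10, syn_sites = 5,
                    pn = 0.1, ps = 0.2,
                    pnps = c(1.5, 0.2, 0.7, NA, 1.5),
                    classification = c("positive", "purifying", "purifying",
                                       "undefined", "positive"))
  ann <- data.frame(gene_id = c("gB", "gA"), annotation_type = "KO",
                    label = c("K00001", "K00002"))
  r <- rank_selection(sel, ann, top_n = 1)
  expect_equal(r$top$gene_id, "gB")          # 1.5 tie broken by id
  expect_equal(r$bottom$gene_id, "gA")
  expect_equal(r$top$annotation, "KO:K00001")
  r3 <- rank_selection(sel, ann, top_n = 10)
  expect_false("gD" %in% c(r3$top$gene_id, r3$bottom$gene_id))
  expect_equal(r3$top$gene_id[1:2], c("gB", "gE"))
  expect_error(rank_selection(sel[4, ], ann), "defined")
})
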