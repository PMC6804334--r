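ref <- synthetic_reference()
ann <- mito_genes()

toy_ann <- function(len, strand = "+") {
  structure(data.frame(gene = "toy", start = 1L, end = as.integer(len),
                       strand = strand, stringsAsFactors = FALSE),
            class = c("gene_annotation", "data.frame"))
}

test_that("classification reproduces the documented example sites", {
  cls <- classify_mutations(c(3424L, 14804L, 16117L), c("G", "G", "T"),
                            c("A", "A", "C"), ann, ref)
  expect_equal(cls$category, c("NS", "NS", "NC"))
  expect_equal(cls$gene[1:2], c("ND1", "CYB"))
  expect_true(is.na(cls$gene[3]))  # D-loop, no coding gene
})

test_that("synonymous third positions and toy genes classify correctly", {
  toy <- mito_reference("ATGGCTGCA")
  # third base of codon 2: GCT -> GCC, both Ala
  expect_equal(classify_mutations(6L, "T", "C", toy_ann(9), toy)$category, "S")
  # first base of codon 2: GCT -> CCT, Ala -> Pro
  expect_equal(classify_mutations(4L, "G", "C", toy_ann(9), toy)$category, "NS")
  # beyond the annotated gene: noncoding
  toy2 <- mito_reference("ATGGCTGCAAAA")
  expect_equal(classify_mutations(12L, "A", "G", toy_ann(9), toy2)$category,
               "NC")
  # input validation
  expect_error(classify_mutations(99L, "A", "G", toy_ann(9), toy), "outside")
  expect_error(classify_mutations(6L, "A", "G", toy_ann(9), toy), "mismatch")
  expect_error(classify_mutations(6L, "T", "T", toy_ann(9), toy), "differ")
})

test_that("light-strand genes are classified on the reverse complement", {
  # reference GGCCAT read on '-' strand is CDS ATGGCC (Met-Ala)
  toy <- mito_reference("GGCCAT")
  a <- toy_ann(6, strand = "-")
  # ref pos 1 G->A is CDS third base of codon 2: GCC -> GCT, synonymous
  expect_equal(classify_mutations(1L, "G", "A", a, toy)$category, "S")
  # ref pos 3 C->T is CDS first base of codon 2: GCC -> ACC, Ala -> Thr
  expect_equal(classify_mutations(3L, "C", "T", a, toy)$category, "NS")
})

test_that("classification agrees with brute-force full-gene translation", {
  set.seed(12)
  cc <- coding_changes(ann, ref)
  pick <- cc[sample(nrow(cc), 80L), ]
  cls <- classify_mutations(pick$position, pick$ref, pick$alt, ann, ref)
  for (i in seq_len(nrow(pick))) {
    genes <- strsplit(cls$gene[i], ",")[[1L]]
    mutref <- mutate_reference(ref, pick$position[i], pick$alt[i])
    changed <- vapply(genes, function(g) {
      gene <- ann[ann$gene == g, ]
      !identical(translate_gene(ref, gene), translate_gene(mutref, gene))
    }, logical(1L))
    expect_equal(cls$category[i], if (any(changed)) "NS" else "S",
                 info = sprintf("pos %d %s>%s", pick$position[i],
                                pick$ref[i], pick$alt[i]))
  }
})

test_that("degenerate codon positions classify exhaustively as expected", {
  # gene of 4-fold degenerate codons: every third-position change is S,
  # every first-position change is NS
  toy <- mito_reference("GCTGTCCGG")  # Ala Val Arg
  a <- toy_ann(9)
  for (codon_i in 0:2) {
    p3 <- 3L * codon_i + 3L
    p1 <- 3L * codon_i + 1L
    for (alt in setdiff(c("A", "C", "G", "T"), toy$bases[p3]))
      expect_equal(classify_mutations(p3, toy$bases[p3], alt, a, toy)$category,
                   "S")
    for (alt in setdiff(c("A", "C", "G", "T"), toy$bases[p1]))
      expect_equal(classify_mutations(p1, toy$bases[p1], alt, a, toy)$category,
                   "NS")
  }
})

test_that("shared heteroplasmies deduplicate by position and alleles", {
  calls <- data.frame(sample = c("s1", "s2", "s3", "s1"),
                      position = c(14804L, 14804L, 14804L, 100L),
                      ref = "G", alt = "A", stringsAsFactors = FALSE)
  dd <- dedup_mutations(calls)
  expect_equal(nrow(dd), 2L)
  expect_equal(dd$n_samples[dd$position == 14804L], 3L)
  expect_equal(dd$samples[dd$position == 14804L], "s1,s2,s3")
  # disjoint sets concatenate; empty input stays empty
  expect_equal(nrow(dedup_mutations(calls[0L, ])), 0L)
})

test_that("Ka/Ks matches a hand-computed NG86 toy", {
  # codons TTT GCT ATG CGA under the vertebrate mito code:
  # S sites = 1/3 + 1 + 1/3 + 1 = 8/3, N sites = 12 - 8/3 = 28/3
  toy <- mito_reference("TTTGCTATGCGA")
  a <- toy_ann(12)
  sites <- mitohet:::ng86_sites(a, toy)
  expect_equal(unname(sites["s_sites"]), 8 / 3)
  expect_equal(unname(sites["n_sites"]), 28 / 3)
  # one NS (pos 1 T>C: Phe->Leu), one S (pos 6 T>A: Ala->Ala)
  muts <- data.frame(position = c(1L, 6L), ref = c("T", "T"),
                     alt = c("C", "A"), stringsAsFactors = FALSE)
  res <- ka_ks(muts, a, toy, n_resamples = 100L, seed = 1L)
  expect_equal(res$ka, (1 / (28 / 3)))
  expect_equal(res$ks, (1 / (8 / 3)))
  expect_equal(res$ratio, 2 / 7)
})

test_that("an all-synonymous mutation set gives ratio 0 and Ks-less sets flag", {
  toy <- mito_reference("TTTGCTATGCGA")
  a <- toy_ann(12)
  s_only <- data.frame(position = 6L, ref = "T", alt = "A")
  expect_equal(ka_ks(s_only, a, toy, n_resamples = 50L, seed = 1L)$ratio, 0)
  ns_only <- data.frame(position = 1L, ref = "T", alt = "C")
  res <- ka_ks(ns_only, a, toy, n_resamples = 50L, seed = 1L)
  expect_true(res$degenerate)
  expect_true(is.na(res$ratio))
})

test_that("bootstrap CIs are reproducible and bracket the point estimate", {
  set.seed(3)
  cc <- coding_changes(ann, ref)
  muts <- cc[sample(nrow(cc), 60L), ]
  a <- ka_ks(muts, ann, ref, n_resamples = 300L, seed = 7L)
  b <- ka_ks(muts, ann, ref, n_resamples = 300L, seed = 7L)
  expect_equal(a$ci_low, b$ci_low)
  expect_equal(a$ci_high, b$ci_high)
  expect_gte(a$ratio, a$ci_low - 1e-9)
  expect_lte(a$ratio, a$ci_high + 1e-9)
})

test_that("rank-sum comparisons behave at the extremes", {
  expect_equal(maf_compare(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # completely separated groups of 5: exact minimal two-sided p
  p <- maf_compare(1:5 / 100, 6:10 / 100)$p_value
  expect_equal(p, 2 / choose(10, 5))
  # rank-based: invariant to monotone transforms
  a <- runif(8); b <- runif(8) + 0.2
  expect_equal(maf_compare(a, b)$p_value,
               maf_compare(log(a), log(b))$p_value)
})

test_that("gene-set composition test agrees with hypergeometric enumeration", {
  v <- data.frame(gene = c(rep("m", 12), rep("o", 243)),
                  frequency = seq_len(255) / 255,
                  category = c(rep("NS", 9), rep("S", 3),
                               rep("NS", 199), rep("S", 44)),
                  stringsAsFactors = FALSE)
  gs <- geneset_compare(v, "m")
  expect_equal(gs$table["in_set", ], c(NS = 9L, S = 3L))
  expect_equal(gs$table["background", ], c(NS = 199L, S = 44L))
  expect_gt(gs$ns_s_p, 0.05)
  # brute-force two-sided Fisher p: sum of hypergeometric point masses
  # not exceeding the observed one
  m <- gs$table
  k <- sum(m["in_set", ]); K <- sum(m[, "NS"]); N <- sum(m)
  probs <- dhyper(0:k, K, N - K, k)
  obs <- dhyper(m["in_set", "NS"], K, N - K, k)
  expect_equal(gs$ns_s_p, sum(probs[probs <= obs * (1 + 1e-7)]),
               tolerance = 1e-9)
  # identical composition: p = 1
  v2 <- data.frame(gene = rep(c("m", "o"), each = 4),
                   frequency = runif(8),
                   category = rep(c("NS", "S"), 4))
  expect_equal(geneset_compare(v2, "m")$ns_s_p, 1)
})
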