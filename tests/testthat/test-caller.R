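cfg <- caller_config()

test_that("a strand-concordant non-reference major allele is a substitution", {
  s <- make_site(16117L, "T", C_fwd = 40L, C_rev = 38L)
  res <- call_site(s, "T", cfg)
  expect_equal(res$substitution$alt, "C")
  expect_equal(res$substitution$fwd, 40L)
  expect_null(res$heteroplasmy)  # no minor allele support

  # reference-matching major: nothing called
  s <- make_site(100L, "T", T_fwd = 500L, T_rev = 480L)
  res <- call_site(s, "T", cfg)
  expect_null(res$substitution)
  expect_null(res$heteroplasmy)
})

test_that("a significant strand-concordant minor allele is a heteroplasmy", {
  s <- make_site(2000L, "G", G_fwd = 425L, A_fwd = 75L,
                 G_rev = 426L, A_rev = 74L)
  res <- call_site(s, "G", cfg)
  h <- res$heteroplasmy
  expect_equal(h$major, "G")
  expect_equal(h$minor, "A")
  expect_equal(h$maf, 149 / 1000)
  # exact one-sided binomial tail oracle
  expect_equal(h$p_value,
               sum(dbinom(149:1000, 1000, 0.01)), tolerance = 1e-12)
  expect_null(res$substitution)  # major equals reference
})

test_that("per-strand support must strictly exceed the threshold", {
  # minor with fwd = 3 (not > 3) rejected regardless of p-value
  s <- make_site(2000L, "G", G_fwd = 500L, A_fwd = 3L,
                 G_rev = 200L, A_rev = 50L)
  expect_null(call_site(s, "G", cfg)$heteroplasmy)
  # fwd = 4 passes
  s$A_fwd <- 4L
  expect_false(is.null(call_site(s, "G", cfg)$heteroplasmy))
})

test_that("masked positions and reference N are never heteroplasmy calls", {
  s <- make_site(310L, "A", A_fwd = 400L, C_fwd = 60L,
                 A_rev = 410L, C_rev = 55L)
  expect_null(call_site(s, "A", cfg)$heteroplasmy)
  # same counts outside the mask are called
  s$position <- 1000L
  expect_false(is.null(call_site(s, "A", cfg)$heteroplasmy))
  # reference N: skipped entirely
  expect_null(call_site(s, "N", cfg)$heteroplasmy)
  expect_null(call_site(s, "N", cfg)$substitution)
})

test_that("strand-discordant alleles are rejected", {
  s <- make_site(1000L, "G", G_fwd = 400L, A_fwd = 30L,
                 G_rev = 400L, C_rev = 30L)
  expect_null(call_site(s, "G", cfg)$heteroplasmy)
})

test_that("binomial decision matches tail-probability enumeration", {
  for (n in c(120L, 604L, 2000L)) {
    for (minor in c(4L, 6L, 8L, 10L, 12L, 16L, 24L, 40L)) {
      major <- n - minor
      s <- make_site(1000L, "A",
                     A_fwd = major %/% 2L, A_rev = major - major %/% 2L,
                     C_fwd = minor %/% 2L, C_rev = minor - minor %/% 2L)
      strand_ok <- minor %/% 2L > cfg$min_strand_reads
      tail_p <- sum(dbinom(minor:n, n, cfg$noise_floor))
      called <- !is.null(call_site(s, "A", cfg)$heteroplasmy)
      expect_equal(called, strand_ok && tail_p < cfg$alpha,
                   info = sprintf("n=%d minor=%d", n, minor))
    }
  }
})

test_that("raising alpha never removes and raising the threshold never adds calls", {
  set.seed(8)
  for (i in 1:60) {
    n2 <- rpois(1L, 300)
    s <- make_site(1000L, "A",
                   A_fwd = n2, A_rev = rpois(1L, 300),
                   C_fwd = rpois(1L, 5), C_rev = rpois(1L, 5))
    low <- !is.null(call_site(s, "A", caller_config(alpha = 0.01))$heteroplasmy)
    high <- !is.null(call_site(s, "A", caller_config(alpha = 0.10))$heteroplasmy)
    if (low) expect_true(high)
    strict <- !is.null(call_site(s, "A",
                                 caller_config(min_strand_reads = 6L))$heteroplasmy)
    lax <- !is.null(call_site(s, "A",
                              caller_config(min_strand_reads = 2L))$heteroplasmy)
    if (strict) expect_true(lax)
  }
})

test_that("tie-breaks are alphabetical and deterministic", {
  s <- make_site(1000L, "G", A_fwd = 50L, T_fwd = 50L,
                 A_rev = 50L, T_rev = 50L)
  res <- call_site(s, "G", cfg)
  expect_equal(res$substitution$alt, "A")
  h <- res$heteroplasmy
  expect_equal(h$major, "A")
  expect_equal(h$minor, "T")
})

test_that("emitted MAFs never exceed 0.5 and are reproducible from counts", {
  set.seed(21)
  for (i in 1:40) {
    s <- make_site(1000L, "A",
                   A_fwd = rpois(1L, 200), A_rev = rpois(1L, 200),
                   G_fwd = rpois(1L, 40), G_rev = rpois(1L, 40),
                   T_fwd = rpois(1L, 3), T_rev = rpois(1L, 3))
    h <- call_site(s, "A", cfg)$heteroplasmy
    if (!is.null(h)) {
      expect_lte(h$maf, 0.5)
      expect_equal(h$maf, (h$minor_fwd + h$minor_rev) / site_depth(s))
    }
  }
})

test_that("major+minor denominator convention is honoured", {
  # A is residual background; the minor allele is T (100 per strand)
  s <- make_site(1000L, "G", G_fwd = 400L, A_fwd = 50L,
                 G_rev = 400L, A_rev = 50L, T_fwd = 100L, T_rev = 100L)
  h_tot <- call_site(s, "G", cfg)$heteroplasmy
  h_mm <- call_site(s, "G",
                    caller_config(denominator = "major_minor"))$heteroplasmy
  expect_equal(h_tot$minor, "T")
  expect_equal(h_tot$maf, 200 / 1100)
  expect_equal(h_mm$maf, 200 / 1000)
})

test_that("call_sample sorts, deduplicates and matches per-site calls", {
  ref <- synthetic_reference()
  truth <- sample_truth(ref, 8L, 0.2, seed = 31L)
  counts <- simulate_counts(ref, truth, sim_config(n_reads = 50000L),
                            seed = 31L)
  calls <- call_sample(counts, ref, cfg)
  expect_false(is.unsorted(calls$heteroplasmies$position))
  # site-wise agreement on every called position
  for (p in calls$heteroplasmies$position) {
    one <- call_site(counts[counts$position == p, ], ref$bases[p], cfg)
    expect_equal(one$heteroplasmy$maf,
                 calls$heteroplasmies$maf[calls$heteroplasmies$position == p])
  }
  dup <- rbind(counts[1:3, ], counts[2, ])
  expect_error(call_sample(dup, ref, cfg), "duplicate")
})

test_that("calls from folded pseudo-coordinate counts equal direct calls", {
  ref <- synthetic_reference()
  L <- length(ref$bases); E <- 500L
  truth <- sample_truth(ref, 6L, 0.15, seed = 13L)
  counts <- simulate_counts(ref, truth, sim_config(n_reads = 50000L),
                            seed = 13L)
  # split the counts of the first E positions between the canonical row and
  # its extension copy, as an aligner against the pseudo-reference would
  pseudo <- rbind(counts, counts[1:E, ])
  pseudo$position[(L + 1L):(L + E)] <- L + 1:E
  for (cc in mitohet:::count_columns()) {
    first <- counts[[cc]][1:E]
    keep <- first %/% 2L
    pseudo[[cc]][1:E] <- keep
    pseudo[[cc]][(L + 1L):(L + E)] <- first - keep
  }
  folded <- fold_counts(pseudo, L, E)
  direct <- call_sample(counts, ref, cfg)
  via_fold <- call_sample(folded, ref, cfg)
  expect_equal(via_fold$heteroplasmies, direct$heteroplasmies)
  expect_equal(via_fold$substitutions, direct$substitutions)
})

test_that("call outputs serialize to TSV and VCF", {
  s <- make_site(2000L, "G", G_fwd = 425L, A_fwd = 75L,
                 G_rev = 426L, A_rev = 74L)
  s2 <- make_site(16117L, "T", C_fwd = 40L, C_rev = 38L)
  calls <- call_sample(rbind(s, s2), cfg = cfg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_calls_tsv(calls, tsv)
  tab <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$maf[tab$type == "heteroplasmy"], 0.149)
  write_calls_vcf(calls, vcf)
  lines <- readLines(vcf)
  expect_true(any(grepl("^##fileformat=VCF", lines)))
  expect_equal(sum(!startsWith(lines, "#")), 2L)
})
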