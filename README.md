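# mitohet

Detection of mitochondrial DNA substitutions and low-frequency
heteroplasmies from strand-resolved base counts, with the downstream
intratumor analyses that such calls feed: simulation-based precision/recall
evaluation of the caller, purity/ploidy-corrected relative mtDNA copy
number, weighted Robinson–Foulds comparison of sample dendrograms with
permutation significance, and Ka/Ks selection statistics under the
vertebrate mitochondrial genetic code.

The package is aimed at analyses of multi-region sequencing of a single
tumor (or any collection of related samples), where the questions are: which
mtDNA sites are heteroplasmic in which samples, does the heteroplasmy
profile track the physical sampling geometry, and do the observed mutations
show any departure from neutral evolution.

## The calling model

The caller consumes per-site, strand-resolved read counts
(A/C/G/T × forward/reverse), built either from `samtools mpileup` text
(`parse_pileup()`, Phred ≥ 30 by default) or from the built-in simulator.
Because mtDNA is circular, reads spanning the origin are rescued by aligning
to a *pseudo-reference* — the circle with its first *E* bases (default 500)
copied to its end — and folding the extended coordinates back with
`fold_counts()`, which conserves counts exactly.

At each site the major and minor allele are determined independently on each
strand. With `M` the minor-allele count summed over strands and `N` the
total site depth:

* **substitution** — the strand-wise major alleles agree, differ from the
  reference allele, and each strand's major count exceeds 3 reads;
* **heteroplasmy** — the strand-wise major *and* minor alleles agree, each
  of the four allele×strand counts exceeds 3 reads, a one-sided exact
  binomial test rejects H₀: p = 0.01 in favour of p > 0.01 at α = 0.05
  (`P(X ≥ M | N, 0.01) < α`), and the site lies outside the masked
  low-complexity regions (302–316, 513–526, 566–573, 3106–3107,
  16181–16194). The reported minor-allele fraction is `MAF = M / N`.

All thresholds are configurable via `caller_config()`. The two call types
are independent: a site with a non-reference major allele and a significant
minor allele yields both.

Downstream, sample dendrograms are built (neighbor-joining by default,
UPGMA optional) from min–max-normalized distance matrices over coordinates,
heteroplasmy MAF profiles, copy numbers, or nuclear variants, and compared
by the weighted Robinson–Foulds distance
`wRFD(T₁,T₂) = Σ_s |w₁(s) − w₂(s)|` over the union of nontrivial
bipartitions, with significance from a leaf-label permutation test.
Selection is summarized by a Nei–Gojobori-style Ka/Ks on the deduplicated
mutation list with bootstrap-percentile confidence intervals.

## Worked example

Simulate ~1,200× coverage with five planted 10% heteroplasmies, call, and
score (the bundled reference is synthetic; load a real one with
`read_reference_fasta()`):

```r
library(mitohet)
ref    <- synthetic_reference()
truth  <- sample_truth(ref, n_sites = 5, maf = 0.10, seed = 42)
counts <- simulate_counts(ref, truth, sim_config(n_reads = 200000), seed = 42)
calls  <- call_sample(counts, ref)
calls$heteroplasmies[, c("position", "major", "minor", "maf", "p_value")]
#>   position major minor    maf  p_value
#> 1     1289     G     T 0.1056 2.30e-83
#> 2     8865     G     T 0.0946 3.11e-72
#> 3     9329     G     A 0.1061 1.33e-85
#> 4    10328     A     C 0.1059 7.22e-83
#> 5    15545     T     C 0.0911 2.79e-66
evaluate_calls(calls$heteroplasmies, truth)
#>   tp fp fn precision recall
#> 1  5  0  0         1      1
```

All five planted sites are recovered at their target fraction with no false
positives; the p-values are the exact binomial tails against the 1% noise
floor.

Copy number with the purity/ploidy correction
(`R_tumor = purity × ploidy + (1 − purity) × 2`):

```r
compute_mtcn(data.frame(sample_id = "T1", mt_depth = 2100, cds_depth = 70,
                        purity = 0.72, ploidy = 3.1))
#>   sample_id r_tumor  mtcn convention
#> 1        T1   2.792 83.76     ploidy
```

Spatial structure of heteroplasmy on a synthetic clonal tumor: the
coordinate and heteroplasmy dendrograms are far closer than label-scrambled
trees would be:

```r
g  <- generate_synthetic_tumor(seed = 11)
tc <- build_tree(normalize_distances(coordinate_matrix(g$coords)))
th <- build_tree(normalize_distances(het_matrix(g$maf)))
permutation_test(tc, th, n_permutations = 1000, seed = 11)
#> wRFD = 1.673, permutation p = 0.000999 (1000 permutations)
```

Classification of the two heteroplasmies shared by all (or nearly all)
tumor samples in the packaged summary table — both are first-codon-position
G→A changes and hence nonsynonymous:

```r
tab  <- load_table1()
classify_mutations(c(3424, 14804), c("G", "G"), c("A", "A"),
                   mito_genes(), ref)
#>   position ref alt category gene
#> 1     3424   G   A       NS  ND1
#> 2    14804   G   A       NS  CYB
```

A command-line wrapper with `call`, `simulate`, `evaluate`, `mtcn`,
`spatial` and `fixtures` subcommands is installed under `exec/mitohet`.

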