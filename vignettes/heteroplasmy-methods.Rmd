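---
title: "Calling mitochondrial heteroplasmy and testing its spatial and selective structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling mitochondrial heteroplasmy and testing its spatial and selective structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohet)
```

This vignette is the package's account of its methods: the models and
criteria it implements, the parameters that matter and their defaults, the
choices made where the design was genuinely open, and what the test suite
does and does not establish about real data.

## The data model

Everything downstream of alignment consumes one evidence unit: per-site,
strand-resolved counts of the four bases (`A_fwd … T_rev`), 1-based
coordinates throughout. Counts come either from `parse_pileup()` — a
single-sample `samtools mpileup` decoder that skips indel blocks,
read-start/end markers and sub-threshold bases (Phred ≥ 30 by default) — or
from the built-in simulator. Mapping-quality filtering (secondary and
supplementary alignments) is assumed done upstream, when the pileup is
produced; the parser does not re-filter. Only the four canonical bases are
tallied: `N`, deletions (`*`) and reference skips are ignored, because every
calling criterion operates on A/C/G/T counts.

## Circularity: the pseudo-reference

mtDNA is circular but references are stored linearly, so reads spanning the
origin fail to map and depth collapses at both ends — exactly where the
control region lies. `build_pseudo_reference()` appends the first
`extension_length` bases (default 500, capped at the genome length) to the
end; after alignment, `fold_counts()` adds the counts observed at extension
position `L + p` back into position `p`. Folding is a pure coordinate sum
and conserves the total base count exactly — a property the tests assert on
random tables. We assume the upstream aligner reports one alignment per
read, so no read is double-counted across the junction.

## Calling criteria

At each site the major and minor alleles are ranked per strand (ties broken
alphabetically, so results are deterministic). With defaults from
`caller_config()`:

* a **substitution** requires strand-concordant major alleles that differ
  from the reference, each supported by strictly more than
  `min_strand_reads = 3` reads per strand;
* a **heteroplasmy** requires strand-concordant major *and* minor alleles,
  all four allele × strand counts strictly above the threshold, a one-sided
  exact binomial rejection of H₀: p = `noise_floor` (1%) at
  `alpha = 0.05`, and an unmasked position.

Strand concordance is the package's main guard against sequencing and
alignment artifacts, which are typically strand-biased; the binomial test
guards against the residual error floor; the mask removes the homopolymer
and repeat tracts (302–316, 513–526, 566–573, 3106–3107, 16181–16194) where
alignment is unreliable. Reference-`N` positions (position 3107 is a
placeholder in the standard human reference) are never called.

Three choices here were genuinely open and are all configurable:

* **Significance level.** No standard value attaches to the binomial
  criterion; we use a conventional one-sided α = 0.05 with no
  multiple-testing correction, since the strand and support filters already
  dominate the operating characteristics (see below).
* **Denominator.** The binomial trial count and the reported MAF use the
  total of all eight counts at the site (`denominator = "total"`), the most
  direct reading of "frequency of the minor allele"; `"major_minor"`
  restricts both to the two ranked alleles.
* **Interaction of the two call types.** They are independent: a site with
  a non-reference major allele *and* a significant minor allele emits both
  calls; a site passing the substitution criteria whose residual minor
  counts fail the heteroplasmy criteria emits the substitution only.

Two monotonicity properties follow from the definitions and are asserted in
the tests: raising `alpha` never removes a heteroplasmy call, and raising
`min_strand_reads` never adds one.

## The simulator and the caller's operating characteristics

`simulate_counts()` works at the count level: uniform fixed-length reads on
the circle, planted minor fractions at chosen sites, independent per-base
miscalls at `error_rate`, and a fair coin for strand. It deliberately skips
FASTQ and alignment so that the evaluation isolates the calling criteria
and runs at desk scale; consequently it does not emulate alignment
artifacts, nuclear-insert (NUMT) contamination, quality-score structure,
overlapping mate pairs, or indels — a caller that is perfect here can still
be defeated by those upstream effects.

Defaults mirror the evaluation protocol: 100 bp reads, 3‰ error, read
counts 100,000–1,000,000 (mean depths ≈ 604–6,035×), planted minor
fractions 1.5–20.5%, 100 replicates per grid cell. The number of planted
heteroplasmies per replicate is not fixed by the protocol; we use 30,
matching the tens of distinct heteroplasmic positions typical of
multi-region tumor data, and enough to estimate per-replicate recall
stably.

The grid results (`run_grid()`, `summarize_grid()`) show precision
indistinguishable from 1 across the grid: an error-driven false call needs
four or more reads of the *same* wrong base on *each* strand plus a
significant binomial tail, and at 3‰ error the expected count per strand
and alternative base is ≈ 0.6 even at ~600×, so false positives are
essentially impossible. Recall, in contrast, is support-limited at the
lowest cell (1.5% at ~604×): the expected minor reads per strand are
604 × 0.016 / 2 ≈ 4.8, so the probability that *both* strands clear the
>3-read rule is only ≈ 0.5, and the exact binomial test against the 1%
floor needs ≥ 11 minor reads where ≈ 9.7 are expected (power ≈ 0.37). The
joint pass probability is ≈ 0.3, which is what `scripts/acceptance.R`
measures (mean recall ≈ 0.29 over 100 replicates). No reading of the
stated criteria — any α between 0.01 and 0.5, either denominator, ≥3
instead of >3 — lifts recall above ~0.5 at this depth; the strand rule
alone caps it. Recall climbs quickly with either axis: ≈ 0.87 at 2.5%/604×
and ≈ 1 from 5.5% upward or at double the depth. Users who need
sensitivity at 1–2% minor fraction should sequence deeper rather than relax
the strand rule, which is what protects precision.

## Relative mtDNA copy number

`compute_mtcn()` multiplies the depth ratio `mt_depth / CDS_depth` by the
effective nuclear ploidy `R_tumor = purity × ploidy + (1 − purity) × 2`, a
convex combination of the tumor ploidy and the diploid stroma. Some
formulations divide `R_tumor` by 2, reporting copies per *diploid* genome
rather than per effective genome; both conventions are supported
(`convention = "half"` halves every value) and the choice is recorded in
the output. Purity and ploidy are taken as given — estimating them is out
of scope.

## Distance matrices, dendrograms, and the weighted RF distance

Four per-sample characteristics become distance matrices: Euclidean
distance between sampling coordinates; the Euclidean (default) or Manhattan
norm between per-sample MAF profiles with absent sites as 0 (absence means
no detectable minor allele, which is informative); absolute differences of
scalar values (copy number), whose tree is necessarily a caterpillar; and
any externally supplied matrix (e.g. nuclear variant distances). Matrices
are min–max normalized over off-diagonal entries so the four
characteristics are comparable — the literal reading of scaling between 0
and 1; divide-by-max is available where preserving ratios matters. A
constant matrix normalizes to zeros. Normalization precedes tree building.

Trees are built with neighbor-joining by default — the canonical use of the
underlying phylogenetics library for arbitrary (non-ultrametric) distance
matrices — with UPGMA as the option; negative NJ branch lengths are clamped
to 0, three samples are solved exactly as the unique additive tree, and a
designated sample (the non-tumor outgroup in the motivating design, which
has no spatial coordinate and appears only in the heteroplasmy matrix) can
root the tree on its pendant edge.

`wrfd()` implements the weighted Robinson–Foulds distance as the sum of
absolute branch-weight differences over the union of *nontrivial*
bipartitions, with unrooted semantics (trees are unrooted first, so pendant
edges never contribute). Note that some implementations include the trivial
per-leaf splits, adding pendant-length differences; the tests pin the exact
relationship between the two conventions. Significance comes from
`permutation_test()`: the null is the wRFD to the second tree with its leaf
labels uniformly permuted, and `p = (1 + #{null ≤ observed}) / (1 + n)` —
the add-one convention, so p is never 0, and ties count against rejection,
making the test conservative when many permutations share no splits with
the first tree. Permutations are seeded and the null draws are returned.

## The synthetic tumor generator

`generate_synthetic_tumor()` provides data with the structure the spatial
analysis assumes: microsections on a ~35 mm disc (default 23 samples,
matching a dense multi-region design), mutations partitioned among spatial
clones (default 30 sites in 6 clones), and per-sample MAFs decaying
exponentially with distance from the clone center (length scale 8 mm —
about a quarter of the sampled region, so clones are local but span several
sections) plus Gaussian measurement noise (sd 0.01) and a 1% detection
floor below which a site is absent. `shuffled = TRUE` permutes the
coordinates after the MAFs are drawn: all marginals are preserved but the
spatial signal is destroyed, giving the null configuration.

On these defaults the coordinate–heteroplasmy permutation test rejects at
α = 0.05 with power > 0.9, and on shuffled data its empirical type-I error
sits at or slightly below α (slightly below, because of the tie
conservatism described above). Passing these calibrations shows the test
machinery is sound under the generator's model — clonal, spatially local,
additively noisy MAFs. It does not show that real tumors satisfy that
model: real heteroplasmy profiles can mix clonal structure with convergent
mutation, contamination gradients, and depth-dependent censoring that the
generator does not produce.

## Ka/Ks on a sparse mutation list

The observed data are a handful of single-base heteroplasmies, not a
diverged alignment, so a maximum-likelihood codon model is not fittable;
the package instead uses the Nei–Gojobori counting approach.
`ng86_sites()` counts synonymous/nonsynonymous *sites* over the
concatenated coding sequence (each codon position contributes the fraction
of its three possible changes that preserve the amino acid, under the
vertebrate mitochondrial code), `classify_mutations()` assigns each
observed mutation S/NS/NC, and `ka_ks()` reports
`(NS_obs / NS_sites) / (S_obs / S_sites)`. With mutations sampled uniformly
from all possible coding changes this ratio converges to 1 by
construction — the neutral calibration the tests exercise at n = 2,000.

Choices worth recording:

* **Shared events are counted once.** The same heteroplasmy in many
  samples almost surely traces to one mutation event;
  `dedup_mutations()` collapses on (position, ref, alt) and keeps the
  occurrence list.
* **Overlapping genes** (the ATP8/ATP6 and ND4L/ND4 overlaps): a mutation
  is NS if it is nonsynonymous in *any* covering gene — the conservative
  functional-impact reading; `mode = "all"` requires change in every gene.
  Site totals likewise count overlap positions once per covering gene, so
  observed and expected counts use the same convention.
* **Stop codons** are treated as a 21st amino acid: changes into, out of,
  or between stops are synonymous only if the translation is unchanged.
  This keeps site counting and mutation classification consistent on
  arbitrary sequences.
* **Incomplete trailing codons** (mitochondrial stops completed by
  polyadenylation) are excluded from translation and site counting;
  positions covered only by such a partial codon classify as noncoding.
* **Confidence intervals** are bootstrap percentiles from resampling the
  mutation list with replacement 1,000 times (seeded); resamples with no
  synonymous draw have an undefined ratio and are dropped from the
  percentile computation, and a `ks = 0` point estimate is flagged rather
  than reported as a number.
* Group comparisons use the two-sided Wilcoxon rank-sum test for MAF or
  frequency differences and Fisher's exact test for NS:S composition.

## Reference sequence and annotation

The package ships the standard coordinates of the 13 human mitochondrial
protein-coding genes (`mito_genes()`; ND6 on the light strand, translated
from the reverse complement). It does not ship the human reference
sequence; `synthetic_reference()` generates a reproducible random sequence
with realistic base composition, an `N` at position 3107, and the canonical
reference alleles pinned at the few positions used in the documentation's
worked examples. Classification results at other positions on the synthetic
sequence are internally consistent but not biologically meaningful — load
the real sequence with `read_reference_fasta()` for real analyses. (The
worked examples at 3424 and 14804 are robust to this substitution: both
are first-codon-position G→A changes, which are nonsynonymous under the
vertebrate mitochondrial code for every codon with G in that position.)

## Numerical conventions and degenerate inputs

Alphabetical tie-breaks for equal allele counts; strict inequalities at
every threshold (`> 3` reads means ≥ 4, `p < α` for rejection); folding
requires positions within `1..L+E` and errors otherwise; duplicate pileup
positions are a structural error; fewer than 3 samples cannot form a tree;
trees compared by `wrfd()` must share their leaf set exactly; undefined
precision (no calls) and recall (no truth) are reported as `NA`, never 0.
Every stochastic routine accepts an explicit seed and is bit-reproducible
from it.

## Problem sizes in the test suite

The suite exercises the full-size genome where it matters (the acceptance
checks simulate 100 replicates of 100,000 reads at the noise-floor cell and
spot-check three higher cells at 5 replicates) and scales the rest to keep
a run a few minutes long: property checks use 200 random tree pairs of ≤ 6
leaves against brute-force split enumeration, 200 shuffled tumor
generations for type-I calibration (200 permutations each), 25 structured
generations for power, and 2,000 sampled mutations for the neutral Ka/Ks
calibration.

## Known limitations

No indel calling; no NUMT-aware filtering (the caller trusts its input
pileup); no contamination or quality-score modelling in the simulator;
copy-number purity/ploidy are inputs, not estimates; the Ka/Ks counting
method makes no multiple-hit correction (appropriate only in the
low-divergence regime it targets); and the spatial analysis assumes the
sample set is common to all characteristics being compared.
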