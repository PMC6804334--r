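# Mutation classification and Ka/Ks under the vertebrate mitochondrial code ---

#' Read a protein-coding gene annotation table
#'
#' Tab-separated with header \code{gene start end strand}; coordinates
#' 1-based inclusive, strand \code{+} for heavy-strand (reference-sense)
#' genes and \code{-} for light-strand genes (reverse-complemented before
#' translation). Trailing bases that do not complete a codon (mitochondrial
#' stop codons completed by polyadenylation) are ignored for translation.
#'
#' @param path File path.
#' @return A data.frame of class \code{gene_annotation}.
#' @export
read_gene_annotation <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene", "start", "end", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$end < tab$start)) stop("gene end before start")
  if (!all(tab$strand %in% c("+", "-"))) stop("strand must be + or -")
  structure(tab, class = c("gene_annotation", "data.frame"))
}

#' The 13 human mitochondrial protein-coding genes
#'
#' Standard rCRS coordinates of the protein-coding genes (ND6 on the light
#' strand), shipped as a packaged table; substitute your own with
#' \code{\link{read_gene_annotation}}.
#'
#' @return A \code{gene_annotation} data.frame.
#' @export
mito_genes <- function() {
  read_gene_annotation(system.file("extdata", "mt_genes.tsv",
                                   package = "mitohet", mustWork = TRUE))
}

# Vertebrate mitochondrial genetic code as a named vector codon -> aa.
mito_code <- function() {
  Biostrings::getGeneticCode("2")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Codon (3 bases, coding orientation) and within-codon offset (1..3) for a
# reference position inside one gene; NULL when the position falls in an
# incomplete trailing codon.
codon_context <- function(position, gene, ref_bases) {
  if (gene$strand == "+") {
    off <- position - gene$start
    idx <- off %/% 3L
    first <- gene$start + 3L * idx
    if (first + 2L > gene$end) return(NULL)
    list(codon = ref_bases[first + 0:2], within = off %% 3L + 1L,
         forward = TRUE)
  } else {
    off <- gene$end - position
    idx <- off %/% 3L
    first <- gene$end - 3L * idx
    if (first - 2L < gene$start) return(NULL)
    codon <- unname(COMPLEMENT[ref_bases[c(first, first - 1L, first - 2L)]])
    list(codon = codon, within = off %% 3L + 1L, forward = FALSE)
  }
}

translate_codon <- function(codon, code = mito_code()) {
  key <- paste(codon, collapse = "")
  if (grepl("N", key, fixed = TRUE)) return(NA_character_)
  unname(code[key])
}

#' Classify mutations as noncoding, synonymous, or nonsynonymous
#'
#' A mutation is NC when no protein-coding gene covers its position.
#' Otherwise the affected codon is translated with and without the
#' alternative allele under the vertebrate mitochondrial code
#' (light-strand genes via the reverse complement). With
#' \code{mode = "any"} (default) a mutation is NS if it changes the amino
#' acid in any covering gene (the conservative functional-impact reading
#' for overlapping genes); \code{mode = "all"} requires a change in every
#' covering gene. Positions falling only in incomplete trailing codons are
#' classified NC.
#'
#' @param position,ref,alt Parallel vectors describing the mutations;
#'   \code{ref} must match the reference at each position.
#' @param annotations A \code{gene_annotation} table.
#' @param reference A \code{\link{mito_reference}}.
#' @param mode \code{"any"} or \code{"all"} (overlapping-gene rule).
#' @return A data.frame: position, ref, alt, category (NC/S/NS), gene
#'   (comma-joined covering genes, NA for NC).
#' @export
classify_mutations <- function(position, ref, alt, annotations = mito_genes(),
                               reference, mode = c("any", "all")) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "mito_reference"))
  position <- as.integer(position)
  ref <- toupper(ref); alt <- toupper(alt)
  L <- length(reference$bases)
  if (any(position < 1L | position > L))
    stop("position outside the reference")
  mism <- ref != reference$bases[position]
  if (any(mism))
    stop("ref allele mismatch at position(s): ",
         paste(position[mism], collapse = ", "))
  if (any(ref == alt)) stop("ref and alt must differ")
  code <- mito_code()
  out <- data.frame(position = position, ref = ref, alt = alt,
                    category = NA_character_, gene = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(position)) {
    cov <- which(annotations$start <= position[i] &
                 annotations$end >= position[i])
    verdicts <- character(0L); genes <- character(0L)
    for (g in cov) {
      ctx <- codon_context(position[i], annotations[g, ], reference$bases)
      if (is.null(ctx)) next
      before <- translate_codon(ctx$codon, code)
      mut <- ctx$codon
      mut[ctx$within] <- if (ctx$forward) alt[i] else
        unname(COMPLEMENT[alt[i]])
      after <- translate_codon(mut, code)
      if (is.na(before) || is.na(after)) next
      verdicts <- c(verdicts, if (identical(before, after)) "S" else "NS")
      genes <- c(genes, annotations$gene[g])
    }
    if (!length(verdicts)) {
      out$category[i] <- "NC"
    } else {
      ns <- verdicts == "NS"
      out$category[i] <- if (mode == "any") {
        if (any(ns)) "NS" else "S"
      } else {
        if (all(ns)) "NS" else "S"
      }
      out$gene[i] <- paste(genes, collapse = ",")
    }
  }
  out
}

#' Deduplicate heteroplasmies shared across samples
#'
#' The same heteroplasmy observed in multiple samples most likely traces
#' back to a single mutation event and is counted once for selection
#' statistics; the occurrence list is retained.
#'
#' @param calls A data.frame with columns \code{sample}, \code{position},
#'   \code{ref}, \code{alt} (one row per sample-level call).
#' @return A data.frame with one row per unique (position, ref, alt):
#'   n_samples and a comma-joined \code{samples} column.
#' @export
dedup_mutations <- function(calls) {
  need <- c("sample", "position", "ref", "alt")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("calls missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(calls))
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), n_samples = integer(),
                      samples = character(), stringsAsFactors = FALSE))
  key <- paste(calls$position, calls$ref, calls$alt)
  sp <- split(calls, key)
  out <- do.call(rbind, lapply(sp, function(g)
    data.frame(position = g$position[1L], ref = g$ref[1L], alt = g$alt[1L],
               n_samples = length(unique(g$sample)),
               samples = paste(unique(g$sample), collapse = ","),
               stringsAsFactors = FALSE)))
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-gene counts of synonymous and nonsynonymous sites (NG86): each codon
# position contributes the fraction of its 3 possible substitutions that
# leave the amino acid unchanged. Changes creating or destroying a stop are
# counted like any amino-acid change (nonsynonymous unless aa identical).
ng86_sites <- function(annotations, reference) {
  code <- mito_code()
  bases <- c("A", "C", "G", "T")
  s_sites <- 0; total <- 0
  for (g in seq_len(nrow(annotations))) {
    gene <- annotations[g, ]
    len <- gene$end - gene$start + 1L
    ncod <- len %/% 3L
    if (!ncod) next
    seq_fwd <- reference$bases[gene$start:gene$end]
    cds <- if (gene$strand == "+") seq_fwd else
      unname(COMPLEMENT[rev(seq_fwd)])
    cds <- cds[seq_len(3L * ncod)]
    for (ci in seq_len(ncod)) {
      codon <- cds[(3L * ci - 2L):(3L * ci)]
      if (any(!codon %in% bases)) next
      aa <- translate_codon(codon, code)
      for (pos in 1:3) {
        syn <- 0L
        for (b in setdiff(bases, codon[pos])) {
          mut <- codon; mut[pos] <- b
          if (identical(translate_codon(mut, code), aa)) syn <- syn + 1L
        }
        s_sites <- s_sites + syn / 3
        total <- total + 1
      }
    }
  }
  c(s_sites = s_sites, n_sites = total - s_sites)
}

#' Nei-Gojobori style Ka/Ks from a sparse mutation list
#'
#' Counts synonymous and nonsynonymous sites over the concatenated coding
#' sequence (per-site fractions of synonymous change under the vertebrate
#' mitochondrial code) and synonymous/nonsynonymous observed mutations, so
#' that \code{ka = NS_obs / NS_sites}, \code{ks = S_obs / S_sites}. Suited
#' to the sparse within-individual setting where the observed mutations are
#' a handful of single-base heteroplasmies rather than a diverged
#' alignment (no multiple-hit correction is attempted). Confidence
#' intervals come from case resampling: the mutation list is resampled with
#' replacement \code{n_resamples} times and the 2.5/97.5 empirical
#' percentiles of the ratio are reported. Positions covered by two
#' overlapping genes contribute sites to both, matching how their
#' mutations are classified.
#'
#' @param mutations A data.frame with columns \code{position}, \code{ref},
#'   \code{alt} (deduplicated; see \code{\link{dedup_mutations}}).
#'   Noncoding mutations are dropped.
#' @param annotations A \code{gene_annotation} table.
#' @param reference A \code{\link{mito_reference}}.
#' @param n_resamples Resamples for the CI; default 1000.
#' @param seed Optional integer seed for the resampling.
#' @param mode Overlapping-gene rule passed to
#'   \code{\link{classify_mutations}}.
#' @return A list of class \code{selection_result}: ka, ks, ratio (NA and
#'   flagged degenerate when \code{ks} is 0), ci_low, ci_high, counts, and
#'   n_resamples.
#' @export
ka_ks <- function(mutations, annotations = mito_genes(), reference,
                  n_resamples = 1000L, seed = NULL, mode = "any") {
  if (!is.null(seed)) set.seed(seed)
  cls <- classify_mutations(mutations$position, mutations$ref, mutations$alt,
                            annotations, reference, mode = mode)
  coding <- cls[cls$category %in% c("S", "NS"), , drop = FALSE]
  sites <- ng86_sites(annotations, reference)
  if (!nrow(coding)) {
    res <- list(ka = NA_real_, ks = NA_real_, ratio = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_,
                counts = c(ns_obs = 0L, s_obs = 0L, sites),
                n_resamples = 0L, degenerate = TRUE)
    return(structure(res, class = "selection_result"))
  }
  ratio_of <- function(cats) {
    ka <- sum(cats == "NS") / sites[["n_sites"]]
    ks <- sum(cats == "S") / sites[["s_sites"]]
    c(ka = ka, ks = ks, ratio = if (ks > 0) ka / ks else NA_real_)
  }
  pt <- ratio_of(coding$category)
  boot <- replicate(n_resamples, {
    ratio_of(sample(coding$category, nrow(coding), replace = TRUE))[["ratio"]]
  })
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(ka = pt[["ka"]], ks = pt[["ks"]], ratio = pt[["ratio"]],
                 ci_low = ci[1L], ci_high = ci[2L],
                 counts = c(ns_obs = sum(coding$category == "NS"),
                            s_obs = sum(coding$category == "S"), sites),
                 n_resamples = as.integer(n_resamples),
                 degenerate = is.na(pt[["ratio"]])),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Ka/Ks = %s (Ka = %.4g, Ks = %.4g; 95%% CI %.3g-%.3g, %d resamples)\n",
              if (is.na(x$ratio)) "undefined (Ks = 0)" else
                sprintf("%.4g", x$ratio),
              x$ka, x$ks, x$ci_low, x$ci_high, x$n_resamples))
  invisible(x)
}

#' Enumerate all possible single-base coding changes
#'
#' Every position covered by at least one complete codon of a coding gene,
#' with each of its three alternative bases; useful for neutral-calibration
#' checks of \code{\link{ka_ks}}.
#'
#' @param annotations A \code{gene_annotation} table.
#' @param reference A \code{\link{mito_reference}}.
#' @return A data.frame: position, ref, alt.
#' @export
coding_changes <- function(annotations, reference) {
  bases <- c("A", "C", "G", "T")
  pos <- unique(unlist(lapply(seq_len(nrow(annotations)), function(g) {
    gene <- annotations[g, ]
    ncod <- (gene$end - gene$start + 1L) %/% 3L
    if (!ncod) return(integer(0L))
    if (gene$strand == "+")
      gene$start:(gene$start + 3L * ncod - 1L)
    else
      (gene$end - 3L * ncod + 1L):gene$end
  })))
  pos <- sort(pos[reference$bases[pos] %in% bases])
  refb <- reference$bases[pos]
  do.call(rbind, lapply(seq_along(pos), function(i)
    data.frame(position = pos[i], ref = refb[i],
               alt = setdiff(bases, refb[i]), stringsAsFactors = FALSE)))
}

#' Compare minor-allele fractions between two groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test: exact for small
#' tie-free samples, normal approximation with tie correction otherwise.
#'
#' @param group_a,group_b Numeric vectors of MAFs.
#' @return A list: p_value, statistic (U for group_a), method.
#' @export
maf_compare <- function(group_a, group_b) {
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = "two.sided"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       method = wt$method)
}

#' Compare a gene set's variants against the background
#'
#' For variants annotated with a gene, a per-variant frequency and an
#' S/NS category, splits them into the gene set (e.g. nuclear-encoded
#' mitochondrial genes) versus the rest and tests (a) the frequency
#' difference by a two-sided rank-sum test and (b) the NS:S composition by
#' Fisher's exact test on the 2x2 count table.
#'
#' @param variants A data.frame with columns \code{gene},
#'   \code{frequency}, \code{category} (\code{"NS"} or \code{"S"}).
#' @param geneset Character vector of gene names defining the set.
#' @return A list: frequency_p, ns_s_p, table (2x2 counts, rows = in/out of
#'   set, cols = NS/S), n_in, n_out.
#' @export
geneset_compare <- function(variants, geneset) {
  need <- c("gene", "frequency", "category")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variants missing column(s): ", paste(miss, collapse = ", "))
  inset <- variants$gene %in% geneset
  tab <- matrix(c(sum(inset & variants$category == "NS"),
                  sum(inset & variants$category == "S"),
                  sum(!inset & variants$category == "NS"),
                  sum(!inset & variants$category == "S")),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("in_set", "background"), c("NS", "S")))
  freq_p <- if (any(inset) && any(!inset))
    maf_compare(variants$frequency[inset], variants$frequency[!inset])$p_value
  else NA_real_
  list(frequency_p = freq_p,
       ns_s_p = stats::fisher.test(tab)$p.value,
       table = tab, n_in = sum(inset), n_out = sum(!inset))
}
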