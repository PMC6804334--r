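# Substitution and heteroplasmy calling ---------------------------------------
#
# A site is examined on each strand separately: the major allele is the base
# with the highest count, the minor allele the second highest (ties broken
# alphabetically, deterministically). A SUBSTITUTION requires the two
# strand-wise major alleles to agree, to differ from the reference allele,
# and to each exceed the per-strand read threshold. A HETEROPLASMY requires
# strand-concordant major AND minor alleles, all four (allele x strand)
# counts above the threshold, a one-sided exact binomial rejection of the
# hypothesis that the minor fraction equals the noise floor, and the
# position to lie outside the region mask. The two calls are independent: a
# site with a non-reference major allele and a significant minor allele
# yields both.

#' Caller configuration
#'
#' @param min_strand_reads An allele must be supported by strictly more than
#'   this many reads on each strand (default 3, i.e. at least 4).
#' @param noise_floor Null minor-allele fraction for the exact binomial
#'   test; default 0.01 (1 percent).
#' @param alpha One-sided significance level of the binomial test; default
#'   0.05. A heteroplasmy is emitted when the tail probability is strictly
#'   below \code{alpha}.
#' @param mask A \code{\link{region_mask}} of positions excluded from
#'   heteroplasmy calling; default \code{\link{default_region_mask}}.
#' @param denominator Either \code{"total"} (default): the binomial trial
#'   count and the reported minor-allele fraction both use the total of all
#'   eight strand/base counts at the site; or \code{"major_minor"}: both use
#'   major + minor support only.
#' @return A list of class \code{caller_config}.
#' @export
caller_config <- function(min_strand_reads = 3L, noise_floor = 0.01,
                          alpha = 0.05, mask = default_region_mask(),
                          denominator = c("total", "major_minor")) {
  denominator <- match.arg(denominator)
  if (!(noise_floor > 0 && noise_floor < 0.5))
    stop("noise_floor must lie in (0, 0.5)")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (min_strand_reads < 0) stop("min_strand_reads must be >= 0")
  stopifnot(inherits(mask, "region_mask"))
  structure(list(min_strand_reads = as.integer(min_strand_reads),
                 noise_floor = noise_floor, alpha = alpha, mask = mask,
                 denominator = denominator),
            class = "caller_config")
}

# Vectorized calling core over a validated site-count table. ref_allele is a
# character vector aligned with rows. Returns list(substitutions, heteroplasmies).
call_core <- function(counts, ref_allele, cfg) {
  bases <- c("A", "C", "G", "T")
  n <- nrow(counts)
  empty_sub <- data.frame(position = integer(), ref = character(),
                          alt = character(), fwd = integer(),
                          rev = integer(), stringsAsFactors = FALSE)
  empty_het <- data.frame(position = integer(), ref = character(),
                          major = character(), minor = character(),
                          maf = numeric(), p_value = numeric(),
                          major_fwd = integer(), major_rev = integer(),
                          minor_fwd = integer(), minor_rev = integer(),
                          stringsAsFactors = FALSE)
  if (n == 0L) return(list(substitutions = empty_sub, heteroplasmies = empty_het))

  fwd <- as.matrix(counts[, paste0(bases, "_fwd")])
  rev <- as.matrix(counts[, paste0(bases, "_rev")])
  top2 <- function(m) {
    # major/minor column per row; ties broken alphabetically (first column)
    maj <- max.col(m, ties.method = "first")
    m2 <- m
    m2[cbind(seq_len(nrow(m)), maj)] <- -1L
    min_ <- max.col(m2, ties.method = "first")
    list(maj = maj, maj_n = m[cbind(seq_len(nrow(m)), maj)],
         min = min_, min_n = m[cbind(seq_len(nrow(m)), min_)])
  }
  f <- top2(fwd); r <- top2(rev)
  msr <- cfg$min_strand_reads
  callable <- ref_allele %in% bases

  # substitutions
  sub_ok <- callable & f$maj == r$maj & bases[f$maj] != ref_allele &
    f$maj_n > msr & r$maj_n > msr
  subs <- data.frame(position = counts$position[sub_ok],
                     ref = ref_allele[sub_ok],
                     alt = bases[f$maj[sub_ok]],
                     fwd = as.integer(f$maj_n[sub_ok]),
                     rev = as.integer(r$maj_n[sub_ok]),
                     stringsAsFactors = FALSE)

  # heteroplasmies
  het_ok <- callable & f$maj == r$maj & f$min == r$min &
    f$maj_n > msr & r$maj_n > msr & f$min_n > msr & r$min_n > msr &
    !in_mask(counts$position, cfg$mask)
  if (any(het_ok)) {
    i <- which(het_ok)
    minor_tot <- as.integer(f$min_n[i] + r$min_n[i])
    major_tot <- as.integer(f$maj_n[i] + r$maj_n[i])
    depth_tot <- as.integer(rowSums(fwd[i, , drop = FALSE]) +
                            rowSums(rev[i, , drop = FALSE]))
    trials <- if (cfg$denominator == "total") depth_tot else
      major_tot + minor_tot
    p <- stats::pbinom(minor_tot - 1L, trials, cfg$noise_floor,
                       lower.tail = FALSE)
    keep <- p < cfg$alpha
    i <- i[keep]
    hets <- data.frame(position = counts$position[i],
                       ref = ref_allele[i],
                       major = bases[f$maj[i]],
                       minor = bases[f$min[i]],
                       maf = (f$min_n[i] + r$min_n[i]) / trials[keep],
                       p_value = p[keep],
                       major_fwd = as.integer(f$maj_n[i]),
                       major_rev = as.integer(r$maj_n[i]),
                       minor_fwd = as.integer(f$min_n[i]),
                       minor_rev = as.integer(r$min_n[i]),
                       stringsAsFactors = FALSE)
  } else hets <- empty_het
  list(substitutions = subs, heteroplasmies = hets)
}

#' Call a single site
#'
#' @param site A one-row site-count table (see \code{\link{parse_pileup}}).
#' @param ref_allele Reference base at the site; \code{"N"} yields no call.
#' @param cfg A \code{\link{caller_config}}.
#' @return A list with elements \code{substitution} and \code{heteroplasmy},
#'   each a one-row data.frame or \code{NULL} when not called.
#' @examples
#' s <- empty_site_counts(1)
#' s$ref <- "T"; s$C_fwd <- 40L; s$C_rev <- 38L
#' call_site(s, "T", caller_config())$substitution
#' @export
call_site <- function(site, ref_allele, cfg = caller_config()) {
  validate_site_counts(site)
  if (nrow(site) != 1L) stop("call_site expects exactly one row")
  res <- call_core(site, toupper(ref_allele), cfg)
  list(substitution = if (nrow(res$substitutions)) res$substitutions else NULL,
       heteroplasmy = if (nrow(res$heteroplasmies)) res$heteroplasmies else NULL)
}

#' Call substitutions and heteroplasmies across a genome
#'
#' @param sites A site-count table covering a subset of 1..L; duplicate
#'   positions are an error.
#' @param ref Optional \code{\link{mito_reference}}; when supplied its base
#'   at each position overrides the table's \code{ref} column. Positions
#'   with reference \code{N} are skipped.
#' @param cfg A \code{\link{caller_config}}.
#' @return A list with data.frames \code{substitutions} (position, ref, alt,
#'   per-strand support) and \code{heteroplasmies} (position, ref, major,
#'   minor, maf, p_value, per-strand support), both sorted by position.
#' @export
call_sample <- function(sites, ref = NULL, cfg = caller_config()) {
  validate_site_counts(sites)
  if (anyDuplicated(sites$position))
    stop("duplicate positions in site-count table")
  ref_allele <- toupper(sites$ref)
  if (!is.null(ref)) {
    stopifnot(inherits(ref, "mito_reference"))
    if (nrow(sites) && max(sites$position) > length(ref$bases))
      stop("site positions exceed reference length")
    ref_allele <- ref$bases[sites$position]
  }
  res <- call_core(sites, ref_allele, cfg)
  res$substitutions <- res$substitutions[order(res$substitutions$position), ,
                                         drop = FALSE]
  res$heteroplasmies <-
    res$heteroplasmies[order(res$heteroplasmies$position), , drop = FALSE]
  rownames(res$substitutions) <- rownames(res$heteroplasmies) <- NULL
  res
}

#' Write calls as a flat TSV
#'
#' One row per call; heteroplasmies carry \code{major/minor: maf} semantics
#' (e.g. \code{G/A 0.0542}), substitutions carry \code{ref/alt}.
#'
#' @param calls Result of \code{\link{call_sample}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  h <- calls$heteroplasmies
  s <- calls$substitutions
  rows <- rbind(
    if (nrow(s)) data.frame(position = s$position, type = "substitution",
                            major = s$alt, minor = s$ref, maf = NA_real_,
                            p_value = NA_real_, stringsAsFactors = FALSE),
    if (nrow(h)) data.frame(position = h$position, type = "heteroplasmy",
                            major = h$major, minor = h$minor, maf = h$maf,
                            p_value = h$p_value, stringsAsFactors = FALSE))
  if (is.null(rows)) rows <- data.frame(position = integer(), type = character(),
                                        major = character(), minor = character(),
                                        maf = numeric(), p_value = numeric())
  rows <- rows[order(rows$position), , drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write calls as a minimal VCF
#'
#' Heteroplasmies are emitted with the minor allele as ALT and INFO fields
#' \code{AF} (minor-allele fraction), \code{TYPE}, and strand support
#' \code{FWD}/\code{REV}; substitutions with the major allele as ALT.
#'
#' @param calls Result of \code{\link{call_sample}}.
#' @param path Output path.
#' @param contig Contig name written in the VCF records.
#' @return \code{path}, invisibly.
#' @export
write_calls_vcf <- function(calls, path, contig = "MT") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", contig),
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Minor allele fraction\">",
           "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"substitution or heteroplasmy\">",
           "##INFO=<ID=FWD,Number=1,Type=Integer,Description=\"Forward-strand ALT support\">",
           "##INFO=<ID=REV,Number=1,Type=Integer,Description=\"Reverse-strand ALT support\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  s <- calls$substitutions
  h <- calls$heteroplasmies
  rec <- character(0L)
  if (nrow(s))
    rec <- c(rec, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tTYPE=substitution;FWD=%d;REV=%d",
                          contig, s$position, s$ref, s$alt, s$fwd, s$rev))
  if (nrow(h))
    rec <- c(rec, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tTYPE=heteroplasmy;AF=%.6g;FWD=%d;REV=%d",
                          contig, h$position, h$major, h$minor, h$maf,
                          h$minor_fwd, h$minor_rev))
  ord <- order(as.integer(sub("^\\S+\t(\\d+)\t.*$", "\\1", rec)))
  writeLines(c(hdr, rec[ord]), path)
  invisible(path)
}
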