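# Site-count tables -----------------------------------------------------------
#
# The evidence unit consumed by the caller is a data.frame with one row per
# reference position and the columns
#   position : 1-based integer
#   ref      : reference base (A/C/G/T/N)
#   A_fwd, C_fwd, G_fwd, T_fwd : read-base counts on the forward strand
#   A_rev, C_rev, G_rev, T_rev : read-base counts on the reverse strand
# This is also the on-disk TSV dialect used between modules.

count_columns <- function() {
  c(paste0(c("A", "C", "G", "T"), "_fwd"),
    paste0(c("A", "C", "G", "T"), "_rev"))
}

validate_site_counts <- function(x) {
  need <- c("position", "ref", count_columns())
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("site-count table missing column(s): ", paste(miss, collapse = ", "))
  cnt <- as.matrix(x[, count_columns()])
  if (nrow(x) && (any(is.na(cnt)) || any(cnt < 0)))
    stop("site counts must be non-negative and non-missing")
  invisible(x)
}

empty_site_counts <- function(L, ref = NULL) {
  out <- data.frame(position = seq_len(L),
                    ref = if (is.null(ref)) rep("N", L) else ref,
                    stringsAsFactors = FALSE)
  for (cc in count_columns()) out[[cc]] <- 0L
  out
}

#' Total read depth per site
#'
#' @param counts A site-count table.
#' @return Integer vector: sum of all eight strand/base counts per row.
#' @export
site_depth <- function(counts) {
  validate_site_counts(counts)
  as.integer(rowSums(counts[, count_columns()]))
}

#' Parse samtools mpileup text into strand-resolved base counts
#'
#' Decodes the single-sample, 6-column mpileup dialect (chrom, pos, ref,
#' depth, read bases, base qualities). Uppercase base symbols and \code{.}
#' count toward the forward strand; lowercase and \code{,} toward the
#' reverse. Indel blocks (\code{+}/\code{-} followed by a length and that
#' many bases), read-start markers (\code{^} plus the mapping-quality
#' character) and read-end markers (\code{$}) are skipped and never counted.
#' \code{N}, \code{n}, \code{*}, \code{<} and \code{>} consume a quality
#' character but are not tallied: only the four canonical bases enter the
#' counts. Bases whose Phred+33 quality is below \code{min_base_quality}
#' are excluded.
#'
#' Mapping-quality filtering (e.g. of secondary/supplementary alignments) is
#' assumed to have been done upstream when the pileup was produced.
#'
#' @param lines Character vector of mpileup lines (or see
#'   \code{\link{parse_pileup_file}}).
#' @param min_base_quality Minimum Phred base quality; default 30.
#' @return A site-count table (one row per input line), ordered as input.
#' @examples
#' parse_pileup("MT\t5\tT\t6\t.,.,Tt\tIIIIII")
#' @export
parse_pileup <- function(lines, min_base_quality = 30L) {
  rows <- lapply(seq_along(lines), function(i) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) return(NULL)
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 6L) {
      if (length(f) >= 4L && as.integer(f[4L]) == 0L)
        f <- c(f[1:4], "", "")[1:6]
      else
        stop(sprintf("pileup line %d: expected 6 columns, found %d",
                     i, length(f)))
    }
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos)) stop(sprintf("pileup line %d: bad position '%s'", i, f[2L]))
    ref <- toupper(f[3L])
    counts <- decode_pileup_bases(f[5L], f[6L], ref, min_base_quality, i)
    c(list(position = pos, ref = ref), as.list(counts))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty_site_counts(0L)[0L, ])
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  validate_site_counts(out)
  out
}

# Character-by-character decoder for one mpileup base string. Returns a
# named integer vector over count_columns().
decode_pileup_bases <- function(bases, quals, ref, min_q, line_no = NA) {
  cnt <- stats::setNames(integer(8L), count_columns())
  ch <- strsplit(bases, "", fixed = TRUE)[[1L]]
  qv <- if (nzchar(quals)) utf8ToInt(quals) - 33L else integer(0L)
  i <- 1L; qi <- 1L
  n <- length(ch)
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "^") {            # read start: next char is mapping quality
      i <- i + 2L
    } else if (c0 == "$") {     # read end marker
      i <- i + 1L
    } else if (c0 == "+" || c0 == "-") {  # indel: [+-](\d+)(bases)
      j <- i + 1L
      while (j <= n && ch[j] >= "0" && ch[j] <= "9") j <- j + 1L
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
    } else {
      # a read base, consuming one quality character
      if (qi > length(qv))
        stop(sprintf("pileup line %s: base string longer than quality string",
                     line_no))
      q <- qv[qi]; qi <- qi + 1L
      if (q >= min_q) {
        b <- switch(c0, "." = ref, "," = tolower(ref), c0)
        up <- toupper(b)
        if (up %in% c("A", "C", "G", "T")) {
          strand <- if (b %in% c("A", "C", "G", "T")) "_fwd" else "_rev"
          key <- paste0(up, strand)
          cnt[key] <- cnt[key] + 1L
        }
      }
      i <- i + 1L
    }
  }
  if (qi != length(qv) + 1L)
    stop(sprintf("pileup line %s: base/quality length mismatch", line_no))
  cnt
}

#' @rdname parse_pileup
#' @param path Path to an mpileup text file.
#' @export
parse_pileup_file <- function(path, min_base_quality = 30L) {
  parse_pileup(readLines(path), min_base_quality = min_base_quality)
}

#' Read / write the site-count TSV dialect
#'
#' Tab-separated, with the documented header
#' \code{position ref A_fwd C_fwd G_fwd T_fwd A_rev C_rev G_rev T_rev}.
#' Round-trips bit-exactly.
#'
#' @param counts A site-count table.
#' @param path File path.
#' @return \code{write_site_counts}: \code{path} invisibly;
#'   \code{read_site_counts}: the table.
#' @export
write_site_counts <- function(counts, path) {
  validate_site_counts(counts)
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_counts
#' @export
read_site_counts <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c("integer", "character",
                                          rep("integer", 8L)))
  validate_site_counts(out)
  out
}
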