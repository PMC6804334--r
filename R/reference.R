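#' Mitochondrial reference sequence
#'
#' Container for a circular mitochondrial reference. The sequence is stored
#' as a vector of single uppercase bases so that per-position lookups during
#' calling and annotation are O(1). All coordinates throughout the package
#' are 1-based inclusive, matching the conventions of mutation names such as
#' T16117C.
#'
#' @param sequence A single string or a character vector of single bases.
#'   Alphabet restricted to A, C, G, T, N (case-insensitive).
#' @param name Sequence identifier.
#' @return An object of class \code{mito_reference} with elements
#'   \code{bases} (character vector) and \code{name}.
#' @examples
#' ref <- mito_reference("ACGTACGTAA", name = "toy")
#' length(ref$bases)
#' @export
mito_reference <- function(sequence, name = "MT") {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bases <- toupper(as.character(sequence))
  if (length(bases) == 0L)
    stop("reference sequence must be non-empty")
  bad <- setdiff(unique(bases), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("reference contains invalid symbols: ", paste(bad, collapse = ", "))
  structure(list(bases = bases, name = as.character(name)[1L]),
            class = "mito_reference")
}

#' @export
print.mito_reference <- function(x, ...) {
  cat(sprintf("<mito_reference> %s: %d bp (%d N)\n",
              x$name, length(x$bases), sum(x$bases == "N")))
  invisible(x)
}

#' @export
length.mito_reference <- function(x) length(x$bases)

#' Read a single-record reference FASTA
#'
#' @param path Path to a FASTA file holding exactly one sequence.
#' @return A \code{\link{mito_reference}}.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected a single-record FASTA, found ", length(ss), " records")
  mito_reference(as.character(ss[[1L]]),
                 name = sub("\\s.*$", "", names(ss)[1L]))
}

#' Write a reference (or pseudo-reference) to FASTA
#'
#' @param ref A \code{mito_reference} or \code{pseudo_reference}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  bases <- if (inherits(ref, "pseudo_reference")) ref$bases else ref$bases
  nm <- if (inherits(ref, "pseudo_reference"))
    paste0(ref$base$name, "_pseudo") else ref$name
  ss <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Build a circular pseudo-reference
#'
#' Appends the first \code{extension_length} bases of a circular reference to
#' its end, so that reads spanning the origin (for human mtDNA, the D-loop)
#' map contiguously. After alignment, per-site counts over the extended
#' coordinates are folded back with \code{\link{fold_counts}}.
#'
#' @param ref A \code{\link{mito_reference}} of length L.
#' @param extension_length Number of bases copied from the head to the tail;
#'   must lie in [0, L]. Default 500.
#' @return An object of class \code{pseudo_reference} with elements
#'   \code{base} (the input), \code{extension_length}, and \code{bases}
#'   (character vector of length L + extension_length).
#' @examples
#' ref <- mito_reference("ACGTACGTAA")
#' pseudo <- build_pseudo_reference(ref, 3)
#' paste(pseudo$bases, collapse = "")  # "ACGTACGTAAACG"
#' @export
build_pseudo_reference <- function(ref, extension_length = 500L) {
  stopifnot(inherits(ref, "mito_reference"))
  e <- as.integer(extension_length)
  L <- length(ref$bases)
  if (is.na(e) || e < 0L || e > L)
    stop("extension_length must be an integer in [0, reference length]")
  structure(list(base = ref, extension_length = e,
                 bases = c(ref$bases, ref$bases[seq_len(e)])),
            class = "pseudo_reference")
}

#' @export
print.pseudo_reference <- function(x, ...) {
  cat(sprintf("<pseudo_reference> %s: %d bp = %d + %d extension\n",
              x$base$name, length(x$bases), length(x$base$bases),
              x$extension_length))
  invisible(x)
}

#' Fold extended-coordinate counts back to the canonical circle
#'
#' Reads aligned to a pseudo-reference of length L + E yield per-site counts
#' over positions 1..L+E. Folding adds the counts at extension position L + p
#' (p in 1..E) into canonical position p, conserving the total base count
#' exactly.
#'
#' @param pseudo_counts A site-count table (see \code{\link{parse_pileup}}
#'   for the column contract) over positions 1..L+E. Positions may be a
#'   subset; absent positions count as zero.
#' @param L Canonical circle length.
#' @param E Extension length.
#' @return A site-count table over positions 1..L (rows for every position,
#'   zero-filled where no reads were observed). Reference alleles for
#'   extension positions are taken from the canonical row when present.
#' @export
fold_counts <- function(pseudo_counts, L, E) {
  L <- as.integer(L); E <- as.integer(E)
  validate_site_counts(pseudo_counts)
  if (nrow(pseudo_counts) && (min(pseudo_counts$position) < 1L ||
                              max(pseudo_counts$position) > L + E))
    stop("pseudo_counts positions out of range 1..L+E")
  out <- empty_site_counts(L)
  idx <- pseudo_counts$position
  canon <- ifelse(idx > L, idx - L, idx)
  cols <- count_columns()
  for (cc in cols) {
    v <- numeric(L)
    tt <- tapply(pseudo_counts[[cc]], canon, sum)
    v[as.integer(names(tt))] <- tt
    out[[cc]] <- as.integer(v)
  }
  ref <- rep(NA_character_, L)
  ref[canon] <- pseudo_counts$ref
  # canonical rows win over folded extension rows for the ref allele
  primary <- idx <= L
  ref[idx[primary]] <- pseudo_counts$ref[primary]
  out$ref <- ifelse(is.na(ref), "N", ref)
  out
}

#' Region mask of excluded positions
#'
#' Low-complexity and ambiguous stretches of the mitochondrial genome where
#' heteroplasmy calls are unreliable (alignment artifacts around homopolymer
#' and repeat tracts). Intervals are 1-based inclusive, sorted,
#' non-overlapping.
#'
#' @param start,end Integer vectors of equal length.
#' @return An object of class \code{region_mask}: a data.frame with columns
#'   \code{start}, \code{end}.
#' @seealso \code{\link{default_region_mask}}, \code{\link{in_mask}}
#' @export
region_mask <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end)) stop("start and end lengths differ")
  if (any(is.na(start)) || any(is.na(end)) || any(end < start))
    stop("invalid interval(s)")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) > 1L && any(start[-1L] <= end[-length(end)]))
    stop("mask intervals must be non-overlapping")
  structure(data.frame(start = start, end = end),
            class = c("region_mask", "data.frame"))
}

#' Default mask for the human mitochondrial genome
#'
#' The low-complexity and ambiguous regions excluded from heteroplasmy
#' calling: 302-316, 513-526, 566-573, 3106-3107, 16181-16194.
#'
#' @return A \code{\link{region_mask}}.
#' @export
default_region_mask <- function() {
  region_mask(start = c(302L, 513L, 566L, 3106L, 16181L),
              end   = c(316L, 526L, 573L, 3107L, 16194L))
}

#' Read a mask from a BED-like TSV
#'
#' Accepts either a 3-column BED (0-based half-open; converted) or a
#' 2-column 1-based inclusive table with header \code{start\tend}.
#'
#' @param path File path.
#' @param bed If \code{TRUE} (default when the file has 3+ columns and no
#'   header), interpret as BED 0-based half-open.
#' @return A \code{\link{region_mask}}.
#' @export
read_region_mask <- function(path, bed = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("start", first, ignore.case = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE)
  if (is.null(bed)) bed <- !has_header && ncol(tab) >= 3L
  if (bed) {
    if (ncol(tab) < 3L) stop("BED mask needs chrom/start/end columns")
    region_mask(as.integer(tab[[2L]]) + 1L, as.integer(tab[[3L]]))
  } else {
    cols <- if (has_header) c("start", "end") else c(1L, 2L)
    region_mask(tab[[cols[[1L]]]], tab[[cols[[2L]]]])
  }
}

#' Test positions for mask membership
#'
#' @param position Integer vector of 1-based positions.
#' @param mask A \code{\link{region_mask}}.
#' @return Logical vector: \code{TRUE} where the position lies inside any
#'   mask interval (inclusive).
#' @examples
#' in_mask(c(303, 317), default_region_mask())  # TRUE FALSE
#' @export
in_mask <- function(position, mask) {
  stopifnot(inherits(mask, "region_mask"))
  position <- as.integer(position)
  if (nrow(mask) == 0L) return(rep(FALSE, length(position)))
  vapply(position,
         function(p) any(p >= mask$start & p <= mask$end),
         logical(1L))
}
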