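# Independent oracles and fixture builders used across the test files.

# Reference mpileup decoder built on regex surgery rather than the package's
# character-by-character scan: strip read-start/end markers and indel blocks,
# then pair the remaining symbols 1:1 with quality characters.
ref_decode_pileup <- function(bases, quals, ref, min_q = 30L) {
  bases <- gsub("\\^.", "", bases)
  bases <- gsub("$", "", bases, fixed = TRUE)
  repeat {
    m <- regexpr("[+-][0-9]+", bases)
    if (m == -1L) break
    len <- as.integer(substr(bases, m + 1L, m + attr(m, "match.length") - 1L))
    bases <- paste0(substr(bases, 1L, m - 1L),
                    substr(bases, m + attr(m, "match.length") + len,
                           nchar(bases)))
  }
  ch <- strsplit(bases, "")[[1L]]
  qv <- utf8ToInt(quals) - 33L
  stopifnot(length(ch) == length(qv))
  cnt <- stats::setNames(integer(8L),
                         c(paste0(c("A", "C", "G", "T"), "_fwd"),
                           paste0(c("A", "C", "G", "T"), "_rev")))
  for (i in seq_along(ch)) {
    if (qv[i] < min_q) next
    b <- switch(ch[i], "." = ref, "," = tolower(ref), ch[i])
    if (toupper(b) %in% c("A", "C", "G", "T")) {
      key <- paste0(toupper(b), if (b %in% c("A", "C", "G", "T")) "_fwd"
                    else "_rev")
      cnt[key] <- cnt[key] + 1L
    }
  }
  cnt
}

# Random synthetic mpileup line exercising markers, indels and the quality
# floor. Returns list(line, ref).
random_pileup_line <- function(pos, n_reads = 20L) {
  bases4 <- c("A", "C", "G", "T")
  ref <- sample(bases4, 1L)
  syms <- character(0L); quals <- character(0L)
  for (i in seq_len(n_reads)) {
    s <- character(0L)
    if (runif(1) < 0.2)
      s <- c(s, "^", sample(strsplit("!5AIZ~", "")[[1L]], 1L))
    sym <- sample(c(".", ",", bases4, tolower(bases4), "*", "N", "n"), 1L,
                  prob = c(8, 8, rep(1, 8), 0.5, 0.3, 0.3))
    s <- c(s, sym)
    if (runif(1) < 0.15) {
      len <- sample(1:3, 1L)
      ins <- sample(c(bases4, tolower(bases4)), len, replace = TRUE)
      s <- c(s, sample(c("+", "-"), 1L), len, ins)
    }
    if (runif(1) < 0.2) s <- c(s, "$")
    syms <- c(syms, paste(s, collapse = ""))
    quals <- c(quals, intToUtf8(sample(33:74, 1L)))
  }
  list(line = paste("MT", pos, ref, n_reads, paste(syms, collapse = ""),
                    paste(quals, collapse = ""), sep = "\t"),
       ref = ref)
}

# One-row site-count table.
make_site <- function(position = 1000L, ref = "A", ...) {
  s <- mitohet:::empty_site_counts(1L)
  s$position <- as.integer(position)
  s$ref <- ref
  extra <- list(...)
  for (nm in names(extra)) s[[nm]] <- as.integer(extra[[nm]])
  s
}

# Brute-force weighted RF: enumerate every candidate leaf subset, test
# whether it is a split of each tree via ape's monophyly machinery (rooted
# at a leaf outside the subset), and read the stem-edge length.
brute_wrfd <- function(t1, t2) {
  leaves <- sort(t1$tip.label)
  n <- length(leaves)
  anchor <- leaves[1L]
  others <- setdiff(leaves, anchor)
  subsets <- unlist(lapply(2:(n - 2L), function(k)
    utils::combn(others, k, simplify = FALSE)), recursive = FALSE)
  r1 <- ape::root(t1, outgroup = anchor, resolve.root = TRUE)
  r2 <- ape::root(t2, outgroup = anchor, resolve.root = TRUE)
  weight_in <- function(rt, S) {
    if (!ape::is.monophyletic(rt, S)) return(0)
    node <- ape::getMRCA(rt, S)
    rt$edge.length[which(rt$edge[, 2L] == node)]
  }
  tot <- 0
  for (S in subsets)
    tot <- tot + abs(weight_in(r1, S) - weight_in(r2, S))
  tot
}

# Translate a gene's CDS (complete codons only) from a mito_reference under
# the vertebrate mitochondrial code using Biostrings end to end.
translate_gene <- function(reference, gene) {
  seq_fwd <- paste(reference$bases[gene$start:gene$end], collapse = "")
  dna <- Biostrings::DNAString(seq_fwd)
  if (gene$strand == "-") dna <- Biostrings::reverseComplement(dna)
  ncod <- length(dna) %/% 3L
  dna <- Biostrings::subseq(dna, 1L, 3L * ncod)
  as.character(Biostrings::translate(
    dna, genetic.code = Biostrings::getGeneticCode("2")))
}

# Apply a point mutation to a mito_reference, returning a new reference.
mutate_reference <- function(reference, position, alt) {
  b <- reference$bases
  b[position] <- alt
  mito_reference(b, name = reference$name)
}
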