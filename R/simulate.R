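# Count-level read simulator and precision/recall evaluation ------------------
#
# Uniform fixed-length reads are placed on the circular genome; a read
# covering a planted heteroplasmic site carries the alternative allele with
# probability equal to the target minor fraction; every emitted base is
# independently miscalled to a uniformly chosen different base with the
# per-base error rate; each read is assigned a strand with probability 1/2.
# The simulator emits per-site strand-resolved counts directly, bypassing
# FASTQ and alignment, so the evaluation exercises the calling criteria
# themselves and is independent of any external aligner.

#' Simulation configuration
#'
#' Defaults follow the evaluation protocol: 100 bp reads, per-base error
#' 3 per mille, read counts 100,000 to 1,000,000 over a 16,569 bp circle
#' (mean depths ~600x to ~6,000x), planted minor fractions from 1.5% to
#' 20.5%, 100 replicates per condition.
#'
#' @param error_rate Per-base miscall probability; default 0.003.
#' @param read_length Read length in bp; default 100.
#' @param n_reads Reads per replicate; default 100,000.
#' @param maf_grid Planted minor-allele fractions for grid runs.
#' @param depth_reads Read counts defining the depth axis of grid runs.
#' @param n_heteroplasmies Heteroplasmies planted per replicate; default 30.
#' @param replicates Replicates per grid cell; default 100.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(error_rate = 0.003, read_length = 100L,
                       n_reads = 100000L,
                       maf_grid = c(0.015, 0.025, 0.035, 0.045, 0.055, 0.065,
                                    0.075, 0.085, 0.095, 0.105, 0.205),
                       depth_reads = c(1e5, 2e5, 4e5, 6e5, 8e5, 1e6),
                       n_heteroplasmies = 30L, replicates = 100L) {
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (any(maf_grid <= 0) || any(maf_grid > 0.5))
    stop("maf_grid values must lie in (0, 0.5]")
  structure(list(error_rate = error_rate,
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads),
                 maf_grid = maf_grid,
                 depth_reads = as.integer(depth_reads),
                 n_heteroplasmies = as.integer(n_heteroplasmies),
                 replicates = as.integer(replicates)),
            class = "sim_config")
}

#' Draw a set of planted heteroplasmies
#'
#' Positions are sampled uniformly from unmasked, non-N positions; the
#' alternative allele uniformly from the three non-reference bases.
#'
#' @param ref A \code{\link{mito_reference}}.
#' @param n_sites Number of planted sites.
#' @param maf Target minor-allele fraction, recycled over sites.
#' @param mask A \code{\link{region_mask}} of excluded positions.
#' @param seed Optional integer seed; \code{NULL} uses the current RNG
#'   stream.
#' @return A data.frame (position, ref, alt, target_maf) sorted by position.
#' @export
sample_truth <- function(ref, n_sites, maf, mask = default_region_mask(),
                         seed = NULL) {
  stopifnot(inherits(ref, "mito_reference"))
  if (!is.null(seed)) set.seed(seed)
  L <- length(ref$bases)
  eligible <- which(ref$bases %in% c("A", "C", "G", "T") &
                    !in_mask(seq_len(L), mask))
  if (n_sites > length(eligible)) stop("too many sites requested")
  pos <- sort(sample(eligible, n_sites))
  refb <- ref$bases[pos]
  alt <- vapply(refb, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
  data.frame(position = pos, ref = refb, alt = unname(alt),
             target_maf = rep_len(maf, n_sites), stringsAsFactors = FALSE)
}

# Multinomial draws over A/C/G/T for a vector of trial counts sharing one
# probability vector, by cascading conditional binomials (vectorized).
rmultinom4 <- function(n_vec, p) {
  k <- length(n_vec)
  out <- matrix(0L, k, 4L)
  rem <- as.integer(n_vec)
  ptot <- 1
  for (j in 1:3) {
    pj <- if (ptot > 0) min(1, p[j] / ptot) else 0
    out[, j] <- stats::rbinom(k, rem, pj)
    rem <- rem - out[, j]
    ptot <- ptot - p[j]
  }
  out[, 4L] <- rem
  out
}

#' Simulate per-site strand-resolved counts
#'
#' @param ref A \code{\link{mito_reference}}.
#' @param truth A truth table from \code{\link{sample_truth}} (may have zero
#'   rows for a clean genome).
#' @param cfg A \code{\link{sim_config}}.
#' @param seed Optional integer seed; \code{NULL} uses the current stream.
#' @return A site-count table over all positions 1..L. Positions with
#'   reference \code{N} receive no counted bases.
#' @export
simulate_counts <- function(ref, truth = NULL, cfg = sim_config(),
                            seed = NULL) {
  stopifnot(inherits(ref, "mito_reference"))
  if (!is.null(seed)) set.seed(seed)
  L <- length(ref$bases)
  rl <- cfg$read_length
  if (rl > L) stop("read length exceeds reference length")
  if (!is.null(truth) && nrow(truth)) {
    if (max(truth$position) > L) stop("truth position exceeds reference length")
    if (any(truth$ref != ref$bases[truth$position]))
      stop("truth ref alleles do not match the reference")
  }
  bases <- c("A", "C", "G", "T")
  e <- cfg$error_rate

  starts <- sample.int(L, cfg$n_reads, replace = TRUE)
  tab <- tabulate(starts, nbins = L)
  # circular window sum: depth at p = number of starts in (p - rl + 1 .. p)
  ext <- if (rl > 1L) c(tab[(L - rl + 2L):L], tab) else tab
  cs <- c(0, cumsum(ext))
  depth <- as.integer(cs[seq_len(L) + rl] - cs[seq_len(L)])

  fwd_depth <- stats::rbinom(L, depth, 0.5)
  rev_depth <- depth - fwd_depth

  fwd <- matrix(0L, L, 4L, dimnames = list(NULL, bases))
  rev <- matrix(0L, L, 4L, dimnames = list(NULL, bases))
  planted <- if (is.null(truth)) integer(0L) else truth$position

  for (b in seq_along(bases)) {
    idx <- which(ref$bases == bases[b] & !(seq_len(L) %in% planted))
    if (!length(idx)) next
    p <- rep(e / 3, 4L); p[b] <- 1 - e
    fwd[idx, ] <- rmultinom4(fwd_depth[idx], p)
    rev[idx, ] <- rmultinom4(rev_depth[idx], p)
  }
  if (length(planted)) for (i in seq_len(nrow(truth))) {
    pos <- truth$position[i]
    m <- truth$target_maf[i]
    bi <- match(truth$ref[i], bases)
    ai <- match(truth$alt[i], bases)
    p <- rep(e / 3, 4L)
    p[bi] <- (1 - m) * (1 - e) + m * e / 3
    p[ai] <- m * (1 - e) + (1 - m) * e / 3
    fwd[pos, ] <- as.integer(stats::rmultinom(1L, fwd_depth[pos], p))
    rev[pos, ] <- as.integer(stats::rmultinom(1L, rev_depth[pos], p))
  }

  out <- data.frame(position = seq_len(L), ref = ref$bases,
                    stringsAsFactors = FALSE)
  for (b in seq_along(bases)) out[[paste0(bases[b], "_fwd")]] <- fwd[, b]
  for (b in seq_along(bases)) out[[paste0(bases[b], "_rev")]] <- rev[, b]
  out
}

#' Score heteroplasmy calls against planted truth
#'
#' @param calls Heteroplasmy data.frame from \code{\link{call_sample}}.
#' @param truth Truth table from \code{\link{sample_truth}}.
#' @param allele_aware If \code{TRUE} (default) a true positive must match
#'   both the position and the minor allele; otherwise position only.
#' @return A one-row data.frame: tp, fp, fn, precision, recall. Precision is
#'   \code{NA} when no calls were made; recall is \code{NA} when the truth
#'   set is empty (undefined, never reported as zero).
#' @export
evaluate_calls <- function(calls, truth, allele_aware = TRUE) {
  key <- function(pos, allele)
    if (allele_aware) paste(pos, allele) else as.character(pos)
  call_keys <- if (nrow(calls)) key(calls$position, calls$minor) else character(0L)
  truth_keys <- if (nrow(truth)) key(truth$position, truth$alt) else character(0L)
  tp <- sum(truth_keys %in% call_keys)
  fp <- sum(!(call_keys %in% truth_keys))
  fn <- length(truth_keys) - tp
  data.frame(tp = tp, fp = fp, fn = fn,
             precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             recall = if (length(truth_keys)) tp / (tp + fn) else NA_real_)
}

#' Run the precision/recall simulation grid
#'
#' For every combination of planted minor fraction and read count, repeats
#' the simulate/call/evaluate cycle and collects per-replicate counts.
#'
#' @param ref A \code{\link{mito_reference}}.
#' @param cfg A \code{\link{sim_config}}; \code{maf_grid}, \code{depth_reads}
#'   and \code{replicates} define the grid.
#' @param caller_cfg A \code{\link{caller_config}}.
#' @param seed Integer seed; the whole grid is reproducible from it.
#' @param allele_aware Passed to \code{\link{evaluate_calls}}.
#' @return A long data.frame with columns maf, n_reads, mean_depth,
#'   replicate, tp, fp, fn, precision, recall.
#' @export
run_grid <- function(ref, cfg = sim_config(), caller_cfg = caller_config(),
                     seed = 1L, allele_aware = TRUE) {
  set.seed(seed)
  L <- length(ref$bases)
  res <- list()
  for (m in cfg$maf_grid) for (nr in cfg$depth_reads) {
    cell_cfg <- cfg
    cell_cfg$n_reads <- as.integer(nr)
    for (rep_i in seq_len(cfg$replicates)) {
      truth <- sample_truth(ref, cfg$n_heteroplasmies, m,
                            mask = caller_cfg$mask)
      counts <- simulate_counts(ref, truth, cell_cfg)
      calls <- call_sample(counts, ref, caller_cfg)
      ev <- evaluate_calls(calls$heteroplasmies, truth,
                           allele_aware = allele_aware)
      res[[length(res) + 1L]] <-
        cbind(data.frame(maf = m, n_reads = as.integer(nr),
                         mean_depth = nr * cfg$read_length / L,
                         replicate = rep_i), ev)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Aggregate grid results per cell
#'
#' @param grid Output of \code{\link{run_grid}}.
#' @return One row per (maf, n_reads): replicate means of precision and
#'   recall (undefined replicates dropped from the mean) and summed counts.
#' @export
summarize_grid <- function(grid) {
  sp <- split(grid, list(grid$maf, grid$n_reads), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g)
    data.frame(maf = g$maf[1L], n_reads = g$n_reads[1L],
               mean_depth = g$mean_depth[1L],
               replicates = nrow(g),
               tp = sum(g$tp), fp = sum(g$fp), fn = sum(g$fn),
               mean_precision = mean(g$precision, na.rm = TRUE),
               mean_recall = mean(g$recall, na.rm = TRUE))))
  out <- out[order(out$maf, out$n_reads), , drop = FALSE]
  rownames(out) <- NULL
  out
}
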