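# Packaged data and synthetic input generators --------------------------------

#' Shared heteroplasmic sites across the 23 tumor samples
#'
#' The packaged summary of the three heteroplasmic sites (3424, 14804,
#' 16117) shared across tumor samples: major/minor allele and minor-allele
#' fraction per sample (4 decimal places as published), plus the total
#' number of heteroplasmies per sample. Samples A61, B45, D16 and Z1 carry
#' no heteroplasmy at 3424 (empty allele fields, MAF \code{NA}). Sites
#' 14804 and 16117 are present in all 23 samples.
#'
#' @return A 23-row data.frame: sample, major/minor/maf for each of the
#'   three positions, heter_num.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "shared_heteroplasmies.tsv",
                      package = "mitohet", mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "character", "numeric",
                                          "character", "character", "numeric",
                                          "character", "character", "numeric",
                                          "integer"))
  stopifnot(nrow(tab) == 23L)
  tab
}

#' Synthetic mitochondrial reference sequence
#'
#' A reproducible 16,569 bp random sequence with the base composition of
#' human mtDNA, standing in for the real reference when it is not
#' available. It is synthetic: only a handful of positions are pinned to
#' the canonical reference alleles so that the worked examples are
#' meaningful (N at 3107 -- the canonical placeholder -- plus G at 3424,
#' G at 14804 and T at 16117, the sites discussed throughout the package
#' documentation). Any analysis needing the true sequence should load it
#' with \code{\link{read_reference_fasta}} instead.
#'
#' @param L Sequence length; default 16,569.
#' @param seed Seed for the random sequence; fixed default so every call
#'   returns the same reference.
#' @return A \code{\link{mito_reference}} named \code{"MT_synthetic"}.
#' @export
synthetic_reference <- function(L = 16569L, seed = 20191010L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # approximate human mtDNA base composition (heavy strand reference)
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c(0.309, 0.313, 0.131, 0.247))
  if (L >= 3107L) bases[3107L] <- "N"
  if (L >= 3424L) bases[3424L] <- "G"
  if (L >= 14804L) bases[14804L] <- "G"
  if (L >= 16117L) bases[16117L] <- "T"
  mito_reference(bases, name = "MT_synthetic")
}

#' Generate a synthetic spatially-clustered tumor
#'
#' Emulates the statistical structure the spatial analysis assumes: tumor
#' microsections sampled across a ~35 mm disc, heteroplasmic mutations
#' arising in spatial clones so that nearby samples share mutations with
#' correlated minor-allele fractions, and per-sample relative mtDNA copy
#' numbers. Each clone has a center on the disc and a set of private
#' sites; a sample's MAF at a clone site decays exponentially with its
#' distance from the clone center (length scale
#' \code{correlation_length} mm), plus Gaussian measurement noise, clipped
#' to [0, 0.5], with values below the detection floor set to 0 (site not
#' called). \code{shuffled = TRUE} permutes the coordinate assignment after
#' the MAFs are drawn, destroying the spatial signal while preserving all
#' marginals -- the null configuration for calibration.
#'
#' @param n_samples Number of tumor microsections; default 23.
#' @param n_sites Number of heteroplasmic sites; default 30.
#' @param n_clones Number of spatial clones the sites are partitioned
#'   into; default 6.
#' @param diameter Sampled region diameter in mm; default 35.
#' @param correlation_length Spatial decay length of clone MAFs in mm;
#'   default 8.
#' @param maf_noise SD of additive measurement noise on each MAF; default
#'   0.01.
#' @param detection_floor MAFs below this are zeroed (site absent);
#'   default 0.01.
#' @param shuffled Break the coordinate-heteroplasmy association (null
#'   configuration); default \code{FALSE}.
#' @param seed Optional integer seed.
#' @return A list: \code{coords} (data.frame sample_id, x, y), \code{maf}
#'   (samples x sites matrix), \code{mtcn} (named vector), \code{clones}
#'   (data.frame site, clone, base_maf, cx, cy), and the parameters.
#' @export
generate_synthetic_tumor <- function(n_samples = 23L, n_sites = 30L,
                                     n_clones = 6L, diameter = 35,
                                     correlation_length = 8,
                                     maf_noise = 0.01,
                                     detection_floor = 0.01,
                                     shuffled = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_samples < 3L || n_sites < 1L || n_clones < 1L || diameter <= 0 ||
      correlation_length < 0 || maf_noise < 0)
    stop("invalid generator parameters")
  r <- diameter / 2
  disc <- function(n) {
    rad <- r * sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
    cbind(x = rad * cos(th), y = rad * sin(th))
  }
  xy <- disc(n_samples)
  coords <- data.frame(sample_id = sprintf("S%02d", seq_len(n_samples)),
                       x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
  centers <- disc(n_clones)
  clone_of <- rep_len(seq_len(n_clones), n_sites)
  base_maf <- stats::runif(n_sites, 0.05, 0.4)
  clones <- data.frame(site = sprintf("site%02d", seq_len(n_sites)),
                       clone = clone_of, base_maf = base_maf,
                       cx = centers[clone_of, 1], cy = centers[clone_of, 2])
  d <- sqrt(outer(coords$x, clones$cx, "-")^2 +
            outer(coords$y, clones$cy, "-")^2)
  decay <- if (correlation_length > 0) exp(-d / correlation_length) else
    (d == 0) * 1
  maf <- sweep(decay, 2L, base_maf, "*") +
    matrix(stats::rnorm(n_samples * n_sites, 0, maf_noise),
           n_samples, n_sites)
  maf <- pmin(pmax(maf, 0), 0.5)
  maf[maf < detection_floor] <- 0
  dimnames(maf) <- list(coords$sample_id, clones$site)
  if (shuffled) {
    perm <- sample(n_samples)
    coords$x <- coords$x[perm]
    coords$y <- coords$y[perm]
  }
  mtcn <- stats::setNames(stats::rlnorm(n_samples, log(200), 0.4),
                          coords$sample_id)
  list(coords = coords, maf = maf, mtcn = mtcn, clones = clones,
       params = list(n_samples = n_samples, n_sites = n_sites,
                     n_clones = n_clones, diameter = diameter,
                     correlation_length = correlation_length,
                     maf_noise = maf_noise,
                     detection_floor = detection_floor,
                     shuffled = shuffled))
}
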