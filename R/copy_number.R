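#' Relative mtDNA copy number with purity/ploidy correction
#'
#' The raw depth ratio mt_depth / CDS_depth estimates mtDNA copies per
#' haploid nuclear genome equivalent of sequencing. In a tumor sample the
#' effective nuclear ploidy is not 2: a fraction \code{purity} of cells
#' carries the tumor ploidy and the remainder is diploid stroma, so
#' \deqn{R_{tumor} = purity \times ploidy + (1 - purity) \times 2}
#' and \deqn{mtCN = mt\_depth / CDS\_depth \times R_{tumor}.}
#'
#' Some renderings of the correction divide \eqn{R_{tumor}} by 2 (copies per
#' diploid genome rather than per effective genome); that convention is
#' available via \code{convention = "half"} and halves every value.
#'
#' @param records A data.frame with columns \code{sample_id},
#'   \code{mt_depth}, \code{cds_depth}, \code{purity}, \code{ploidy}.
#' @param convention \code{"ploidy"} (default; multiply the depth ratio by
#'   \eqn{R_{tumor}}) or \code{"half"} (multiply by \eqn{R_{tumor}/2}).
#' @return A data.frame: sample_id, r_tumor, mtcn, convention.
#' @examples
#' compute_mtcn(data.frame(sample_id = "A1", mt_depth = 300,
#'                         cds_depth = 3, purity = 0.8, ploidy = 3))
#' @export
compute_mtcn <- function(records, convention = c("ploidy", "half")) {
  convention <- match.arg(convention)
  need <- c("sample_id", "mt_depth", "cds_depth", "purity", "ploidy")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (any(records$cds_depth <= 0)) stop("cds_depth must be positive")
  if (any(records$mt_depth <= 0)) stop("mt_depth must be positive")
  if (any(records$purity < 0 | records$purity > 1))
    stop("purity must lie in [0, 1]")
  if (any(records$ploidy <= 0)) stop("ploidy must be positive")
  r_tumor <- records$purity * records$ploidy + (1 - records$purity) * 2
  scale <- if (convention == "half") r_tumor / 2 else r_tumor
  data.frame(sample_id = records$sample_id,
             r_tumor = r_tumor,
             mtcn = records$mt_depth / records$cds_depth * scale,
             convention = convention,
             stringsAsFactors = FALSE)
}
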