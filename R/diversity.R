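#' Order-2 Hill-number diversity
#'
#' Effective number of equally frequent variants, `D = 1 / sum(p_i^2)`,
#' where `p_i` are the variant proportions. This is the reciprocal of the
#' probability that two copies drawn at random (with replacement) are the
#' same variant, so `D` ranges from 1 (monomorphic) to the number of
#' variants (all equally frequent). Zero-count variants are dropped before
#' computing proportions.
#'
#' @param counts Non-negative counts (or proportions) per variant; at least
#'   one must be positive.
#' @return The order-2 Hill number (scalar, >= 1).
#' @examples
#' hill2(c(10, 10, 10))          # 3 equally frequent variants
#' hill2(c(0.5, 0.25, 0.25))     # 8/3
#' @export
hill2 <- function(counts) {
  if (length(counts) == 0 || any(counts < 0) || any(!is.finite(counts)))
    stop("`counts` must be non-negative and finite")
  counts <- counts[counts > 0]
  if (length(counts) == 0)
    stop("at least one variant must have a positive count")
  p <- counts / sum(counts)
  1 / sum(p^2)
}

#' Diversity ratio
#'
#' `DR = D_bg / D_f`: order-2 diversity of the (non-transferable) background
#' genome divided by that of the (transferable) focal locus. `DR` near 1
#' indicates a vertical sweep or no sweep; `DR >> 1` indicates a horizontal,
#' gene-specific sweep that homogenised the focal locus while leaving the
#' background genomes diverse.
#'
#' @param D_bg Background-genome diversity (> 0).
#' @param D_f Focal-locus diversity (> 0).
#' @return The diversity ratio (scalar).
#' @export
diversity_ratio <- function(D_bg, D_f) {
  stopifnot(is.finite(D_bg), is.finite(D_f), D_f > 0, D_bg > 0)
  D_bg / D_f
}
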