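# MCAR masking of the tooth-site block.

#' Induce missing-completely-at-random holes
#'
#' Masks each of the 32 tooth-site cells independently with probability `rate`
#' (an independent Bernoulli trial per patient and variable). Demographic
#' columns are never masked: they are assumed recorded in every clinical
#' setting. The returned mask is the ground-truth record of which cells were
#' hidden and is carried separately so evaluation never has to re-infer it.
#'
#' @param cohort A complete cohort `data.frame` from [generate_cohort()] (or
#'   any table with the same schema).
#' @param rate Masking probability in \[0, 1\] (default 0.15).
#' @param seed RNG seed for the Bernoulli trials.
#' @return A list with components `masked` (the cohort with masked tooth-site
#'   cells set to `NA`) and `mask` (logical matrix, patients x 32 features,
#'   `TRUE` = hidden).
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 10, seed = 1))
#' mc <- apply_mcar(cohort, rate = 0.15, seed = 2)
#' sum(mc$mask)
apply_mcar <- function(cohort, rate = 0.15, seed = 1L) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) ||
      rate < 0 || rate > 1) {
    stop("invalid configuration: rate must be a probability in [0, 1]")
  }
  feats <- site_features()
  X <- site_matrix(cohort)  # validates schema
  n <- nrow(X)
  set.seed(seed)
  mask <- matrix(stats::runif(n * length(feats)) < rate, nrow = n,
                 dimnames = list(NULL, feats))
  masked <- cohort
  for (f in feats) masked[[f]][mask[, f]] <- NA_real_
  list(masked = masked, mask = mask)
}

#' Count masked cells per feature
#'
#' @param mask Logical mask matrix from [apply_mcar()] (or read from a mask
#'   CSV).
#' @return List with `per_feature` (named integer vector) and `total`.
#' @export
missing_counts <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    stop("mask must be a logical matrix")
  }
  per <- colSums(mask)
  list(per_feature = per, total = sum(per))
}
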