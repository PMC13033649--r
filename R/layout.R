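# Feature layout of the periodontal chart and seeded substreams.

.perio_sites <- c("UR1", "UR6", "UL1", "UL6", "LR1", "LR6", "LL1", "LL6")
.perio_measures <- c("ProbingDepth", "AttachmentLoss", "Furcation",
                     "BleedingOnProbing")

#' Tooth-site feature names
#'
#' The 32 tooth-site features of the cohort schema: for each site, in chart
#' order, probing depth (mm), attachment loss (mm), furcation grade (0-3) and
#' bleeding on probing (0/1).
#'
#' @param sites Character vector of site labels (default: the eight standard
#'   sites UR1, UR6, UL1, UL6, LR1, LR6, LL1, LL6).
#' @return Character vector of `4 * length(sites)` feature names such as
#'   `"UR1_ProbingDepth"`.
#' @export
#' @examples
#' site_features()[1:4]
site_features <- function(sites = .perio_sites) {
  as.vector(vapply(sites, function(s) paste(s, .perio_measures, sep = "_"),
                   character(length(.perio_measures))))
}

#' Demographic feature names
#'
#' @return `c("Age", "Gender", "Smoking", "Diabetes")`, the four always-observed
#'   patient-level covariates.
#' @export
demographic_features <- function() c("Age", "Gender", "Smoking", "Diabetes")

#' Clinical category of each tooth-site feature
#'
#' Strips the site prefix: `"UR1_Furcation"` maps to `"Furcation"`.
#'
#' @param features Character vector of tooth-site feature names.
#' @return Character vector of categories, each one of `"ProbingDepth"`,
#'   `"AttachmentLoss"`, `"Furcation"`, `"BleedingOnProbing"`.
#' @export
feature_category <- function(features) {
  cat <- sub("^[^_]+_", "", features)
  bad <- !cat %in% .perio_measures
  if (any(bad)) {
    stop("unmapped feature(s): ", paste(features[bad], collapse = ", "))
  }
  cat
}

# Features whose imputations are treated as categorical (vote / discretise).
.is_categorical <- function(features) {
  feature_category(features) %in% c("Furcation", "BleedingOnProbing")
}

#' Derive a named substream seed from a master seed
#'
#' One master seed spawns independent named substreams (e.g. one per tooth
#' site), so adding a stream never perturbs draws in another. The derivation is
#' a polynomial string hash folded into the master seed modulo 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param name Substream label.
#' @return An integer seed in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(42, "demographics")
substream_seed <- function(seed, name) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% m
  as.integer((abs(as.numeric(seed)) %% m * 69069 + h) %% m)
}

# Extract the n x 32 tooth-site block of a cohort data.frame as a matrix.
site_matrix <- function(cohort, sites = .perio_sites) {
  feats <- site_features(sites)
  missing_cols <- setdiff(feats, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing tooth-site column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  as.matrix(cohort[feats])
}
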