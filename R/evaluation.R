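# Imputation-quality metrics: per-feature, category-weighted and overall
# MAE/RMSE, multiple-imputation averaging, ordinal agreement, distributions.

#' Per-feature imputation errors at masked cells
#'
#' For each tooth-site feature, the mean absolute error and the root mean
#' squared error between imputed and true values, restricted to the masked
#' cells of that feature. Features with no masked cells are reported with
#' `NA` metrics.
#'
#' @param truth Complete cohort `data.frame` (the ground truth).
#' @param imputed Imputed cohort `data.frame` (same schema).
#' @param mask Logical mask matrix.
#' @return `data.frame` with columns `feature`, `category`, `n_missing`,
#'   `mae`, `rmse`.
#' @export
feature_errors <- function(truth, imputed, mask) {
  Xt <- site_matrix(truth)
  Xi <- site_matrix(imputed)
  if (!all(dim(Xt) == dim(Xi)) || nrow(mask) != nrow(Xt) ||
      ncol(mask) != ncol(Xt)) {
    stop("schema mismatch between truth, imputed and mask")
  }
  if (anyNA(Xi[mask])) stop("imputed cohort still has missing masked cells")
  feats <- colnames(Xt)
  res <- lapply(feats, function(f) {
    sel <- mask[, f]
    n <- sum(sel)
    if (n == 0) return(data.frame(feature = f, n_missing = 0L,
                                  mae = NA_real_, rmse = NA_real_))
    err <- Xi[sel, f] - Xt[sel, f]
    data.frame(feature = f, n_missing = n,
               mae = mean(abs(err)), rmse = sqrt(mean(err^2)))
  })
  out <- do.call(rbind, res)
  out$category <- feature_category(out$feature)
  out[c("feature", "category", "n_missing", "mae", "rmse")]
}

# Pool a set of per-feature rows by missing-count weighting:
# MAE is the weighted mean, RMSE the root of the weighted mean square —
# identical to computing both directly on the concatenated masked residuals.
.pool_rows <- function(rows) {
  rows <- rows[rows$n_missing > 0, , drop = FALSE]
  n <- sum(rows$n_missing)
  if (n == 0) return(list(n_missing = 0L, mae = NA_real_, rmse = NA_real_))
  list(n_missing = n,
       mae = sum(rows$n_missing * rows$mae) / n,
       rmse = sqrt(sum(rows$n_missing * rows$rmse^2) / n))
}

#' Category-weighted imputation errors
#'
#' Pools per-feature errors within each clinical category (probing depth,
#' attachment loss, furcation, bleeding on probing), weighting by the number
#' of masked cells per feature. RMSE is pooled on the squared-error scale
#' (root of the weighted mean square), so the category value equals the RMSE
#' computed directly on all masked residuals of the category. Categories with
#' no masked cells get `NA` metrics.
#'
#' @param feat_errors Output of [feature_errors()].
#' @return `data.frame` with columns `category`, `n_missing`, `mae`, `rmse`.
#' @export
category_errors <- function(feat_errors) {
  cats <- unique(feature_category(site_features()))
  out <- lapply(cats, function(ct) {
    rows <- feat_errors[feat_errors$category == ct, , drop = FALSE]
    p <- .pool_rows(rows)
    data.frame(category = ct, n_missing = p$n_missing, mae = p$mae,
               rmse = p$rmse)
  })
  do.call(rbind, out)
}

#' Overall imputation errors
#'
#' The same missing-count-weighted pooling as [category_errors()], over all
#' tooth-site features jointly — equivalent to MAE/RMSE computed on every
#' masked residual in the table.
#'
#' @param feat_errors Output of [feature_errors()].
#' @return List with `n_missing`, `mae`, `rmse`. Zero masked cells gives `NA`
#'   metrics with a warning.
#' @export
overall_errors <- function(feat_errors) {
  p <- .pool_rows(feat_errors)
  if (p$n_missing == 0) warning("no masked cells; overall metrics undefined")
  p
}

#' Quadratic weighted kappa
#'
#' Chance-corrected agreement for ordinal labels:
#' `1 - sum(w * O) / sum(w * E)` with quadratic penalty
#' `w_ij = ((i - j) / (K - 1))^2`, `O` the observed contingency table and `E`
#' the outer product of its marginals scaled to the same total. 1 at perfect
#' agreement, about 0 at chance, negative for systematic disagreement.
#'
#' @param truth Vector of true ordinal labels.
#' @param pred Vector of predicted ordinal labels.
#' @param levels Ordered category levels (default: sorted union of values).
#' @return Scalar in `[-1, 1]`, or `NA` with a warning when both marginals
#'   are concentrated on a single level (the chance-agreement denominator
#'   vanishes).
#' @export
#' @examples
#' quadratic_weighted_kappa(c(0, 1, 2, 2), c(0, 1, 2, 2), levels = 0:3)
quadratic_weighted_kappa <- function(truth, pred,
                                     levels = sort(unique(c(truth, pred)))) {
  if (length(truth) != length(pred) || length(truth) < 1) {
    stop("truth and pred must be equal-length, nonempty vectors")
  }
  if (!all(truth %in% levels) || !all(pred %in% levels)) {
    stop("values outside the supplied levels")
  }
  K <- length(levels)
  if (K == 1) {
    warning("degenerate agreement: a single level")
    return(NA_real_)
  }
  O <- table(factor(truth, levels = levels), factor(pred, levels = levels))
  idx <- seq_len(K)
  W <- outer(idx, idx, function(i, j) ((i - j) / (K - 1))^2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  den <- sum(W * E)
  if (den == 0) {
    warning("degenerate agreement: marginals concentrated on one level")
    return(NA_real_)
  }
  1 - sum(W * O) / den
}

#' Compare distributions of observed and imputed values
#'
#' Histogram counts for the observed (unmasked) values of a feature and the
#' imputed values at its masked cells, on shared equal-width bin edges
#' spanning the union range, plus mean and sd deltas. Used as a plausibility
#' check that imputations land in the clinically expected range.
#'
#' @param observed Observed values of the feature.
#' @param imputed Imputed values at the feature's masked cells.
#' @param n_bins Number of equal-width bins (default 15).
#' @return List with `edges`, `observed_counts`, `imputed_counts`,
#'   `delta_mean`, `delta_sd`. An empty imputed set yields observed-only
#'   counts with a warning.
#' @export
distribution_summary <- function(observed, imputed, n_bins = 15L) {
  if (!length(observed)) stop("observed values must be nonempty")
  if (!length(imputed)) {
    warning("no imputed values; observed-only summary")
    imputed <- numeric(0)
  }
  rng <- range(c(observed, imputed))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  count_in <- function(x) {
    if (!length(x)) return(integer(n_bins))
    graphics::hist(x, breaks = edges, plot = FALSE,
                   include.lowest = TRUE, right = TRUE)$counts
  }
  list(edges = edges,
       observed_counts = count_in(observed),
       imputed_counts = count_in(imputed),
       delta_mean = if (length(imputed)) mean(imputed) - mean(observed)
                    else NA_real_,
       delta_sd = if (length(imputed) > 1) stats::sd(imputed) - stats::sd(observed)
                  else NA_real_)
}

#' Full evaluation report for one imputed cohort
#'
#' Assembles per-feature, per-category and overall MAE/RMSE, quadratic
#' weighted kappa for each furcation feature (computed on values discretised
#' into grades, since agreement is defined on categories), and optional
#' distribution summaries for every feature with masked cells.
#'
#' @param truth Complete cohort `data.frame`.
#' @param imputed Imputed cohort `data.frame`.
#' @param mask Logical mask matrix.
#' @param qwk Compute per-furcation-feature quadratic weighted kappa?
#' @param distributions Compute per-feature histogram summaries?
#' @param n_bins Histogram bins for the distribution summaries.
#' @return List of class `perio_eval` with elements `per_feature`,
#'   `per_category`, `overall`, `qwk`, `distributions`.
#' @export
evaluate_imputation <- function(truth, imputed, mask, qwk = TRUE,
                                distributions = FALSE, n_bins = 15L) {
  fe <- feature_errors(truth, imputed, mask)
  report <- list(per_feature = fe,
                 per_category = category_errors(fe),
                 overall = overall_errors(fe))
  if (qwk) {
    Xt <- site_matrix(truth)
    Xi <- site_matrix(imputed)
    furc <- colnames(Xt)[feature_category(colnames(Xt)) == "Furcation"]
    report$qwk <- vapply(furc, function(f) {
      sel <- mask[, f]
      if (sum(sel) < 2) return(NA_real_)
      grades <- pmin(3, pmax(0, round(Xi[sel, f])))
      suppressWarnings(quadratic_weighted_kappa(Xt[sel, f], grades,
                                                levels = 0:3))
    }, numeric(1))
  }
  if (distributions) {
    Xt <- site_matrix(truth)
    Xi <- site_matrix(imputed)
    with_missing <- colnames(Xt)[colSums(mask) > 0]
    report$distributions <- lapply(stats::setNames(nm = with_missing),
      function(f) distribution_summary(Xt[!mask[, f], f], Xi[mask[, f], f],
                                       n_bins = n_bins))
  }
  structure(report, class = "perio_eval")
}

#' @export
print.perio_eval <- function(x, ...) {
  cat("Imputation evaluation over", x$overall$n_missing, "masked cells\n")
  cat(sprintf("  overall MAE %.4f  RMSE %.4f\n", x$overall$mae,
              x$overall$rmse))
  pc <- x$per_category
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-18s MAE %.4f  RMSE %.4f  (n = %d)\n", pc$category[i],
                pc$mae[i], pc$rmse[i], pc$n_missing[i]))
  }
  invisible(x)
}

#' Average evaluation reports across multiple imputations
#'
#' For multiple imputation (e.g. the chained-equations baseline with `m`
#' completions) the final MAE and RMSE are the arithmetic means of the
#' per-imputation metrics, preserving between-imputation variability in the
#' inputs while yielding a single comparable number.
#'
#' @param reports List of `perio_eval` reports with identical schema.
#' @return A single averaged `perio_eval`.
#' @export
pool_imputations <- function(reports) {
  if (!length(reports)) stop("no reports to pool")
  first <- reports[[1]]
  if (length(reports) == 1) return(first)
  same_feats <- vapply(reports, function(r) {
    identical(r$per_feature$feature, first$per_feature$feature)
  }, logical(1))
  if (!all(same_feats)) stop("schema mismatch across reports")
  avg <- function(get) {
    vals <- vapply(reports, get, numeric(length(get(first))))
    if (is.null(dim(vals))) mean(vals) else rowMeans(vals)
  }
  out <- first
  out$per_feature$mae <- avg(function(r) r$per_feature$mae)
  out$per_feature$rmse <- avg(function(r) r$per_feature$rmse)
  out$per_category$mae <- avg(function(r) r$per_category$mae)
  out$per_category$rmse <- avg(function(r) r$per_category$rmse)
  out$overall$mae <- avg(function(r) r$overall$mae)
  out$overall$rmse <- avg(function(r) r$overall$rmse)
  if (!is.null(first$qwk)) out$qwk <- avg(function(r) r$qwk)
  out$distributions <- NULL
  out
}
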