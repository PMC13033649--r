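# Classical comparison imputers: column mean, k-nearest neighbours, and
# chained equations with type-appropriate conditional models.

#' Mean imputation
#'
#' Each masked cell is replaced by the mean of the observed values in its
#' column. The simplest baseline; it destroys between-variable structure but
#' is unbiased for the marginal mean under MCAR.
#'
#' @param masked Masked cohort `data.frame`.
#' @param mask Logical mask matrix consistent with `masked`.
#' @return Imputed cohort `data.frame` with attribute `"imputed_mask"`.
#' @export
impute_mean <- function(masked, mask) {
  X <- site_matrix(masked)
  check_mask_consistency(X, mask)
  mf <- mean_fill(X)
  out <- masked
  for (f in colnames(mask)) out[[f]][mask[, f]] <- mf$fill_values[f]
  attr(out, "imputed_mask") <- mask
  out
}

#' KNN imputation configuration
#'
#' @param k Number of donor neighbours (default 5).
#' @param distance Distance metric; only `"euclidean"` (on standardised
#'   tooth-site features, missing-aware) is implemented.
#' @return List of class `perio_knn_config`.
#' @export
knn_config <- function(k = 5L, distance = "euclidean") {
  if (k < 1 || k != round(k)) stop("invalid configuration: k must be >= 1")
  distance <- match.arg(distance, "euclidean")
  structure(list(k = as.integer(k), distance = distance),
            class = "perio_knn_config")
}

#' K-nearest-neighbour imputation
#'
#' Distances are Euclidean on the standardised tooth-site block, computed over
#' the coordinates observed in *both* patients and rescaled by
#' `n_features / n_shared` so patients with fewer shared coordinates are not
#' spuriously close. For each masked cell the `k` nearest donors that observe
#' the target feature supply the value: their mean for continuous features
#' (probing depth, attachment loss) and a majority vote for categorical ones
#' (furcation, bleeding). Distance ties break toward the lower patient index
#' and vote ties toward the lower category, so the result is deterministic.
#' A cell with no eligible donor falls back to the column mean with a warning.
#'
#' @param masked Masked cohort `data.frame`.
#' @param mask Logical mask matrix consistent with `masked`.
#' @param config A [knn_config()].
#' @return Imputed cohort `data.frame` with attribute `"imputed_mask"`.
#' @export
impute_knn <- function(masked, mask, config = knn_config()) {
  X <- site_matrix(masked)
  check_mask_consistency(X, mask)
  n <- nrow(X)
  if (n <= config$k) stop("need more than k = ", config$k, " patients")
  p <- ncol(X)
  categorical <- .is_categorical(colnames(X))

  # standardise on observed cells (population sd, constant guard at 1)
  mu <- colMeans(X, na.rm = TRUE)
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2, na.rm = TRUE))
  sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  obs <- !is.na(Z)
  Z0 <- Z
  Z0[!obs] <- 0

  out <- masked
  mean_fallback <- character(0)
  for (i in which(rowSums(mask) > 0)) {
    diff2 <- sweep(Z0, 2, Z0[i, ])^2
    shared <- obs & matrix(obs[i, ], n, p, byrow = TRUE)
    diff2[!shared] <- 0
    n_shared <- rowSums(shared)
    d <- ifelse(n_shared > 0, sqrt(rowSums(diff2) * p / n_shared), Inf)
    d[i] <- Inf
    ord <- order(d, seq_len(n))
    for (f in colnames(mask)[mask[i, ]]) {
      eligible <- ord[!is.na(X[ord, f]) & is.finite(d[ord])]
      if (!length(eligible)) {
        out[[f]][i] <- mu[f]
        mean_fallback <- c(mean_fallback, f)
        next
      }
      donors <- utils::head(eligible, config$k)
      vals <- X[donors, f]
      out[[f]][i] <- if (categorical[colnames(X) == f]) {
        tab <- table(vals)
        winners <- as.numeric(names(tab)[tab == max(tab)])
        min(winners)
      } else {
        mean(vals)
      }
    }
  }
  if (length(mean_fallback)) {
    warning("no eligible donors for ", length(mean_fallback),
            " cell(s); column mean used")
  }
  attr(out, "imputed_mask") <- mask
  out
}

#' Chained-equations configuration
#'
#' Defaults follow common multiple-imputation practice: 5 stochastic
#' imputations, 10 cycles each, predictive-mean-matching donor pools of 5.
#' Conditional models are assigned by clinical category — predictive mean
#' matching for probing depth and attachment loss, logistic regression for
#' bleeding on probing, proportional-odds logistic regression for furcation —
#' and imputed values are clipped to plausible clinical ranges.
#'
#' @param m Number of imputations (>= 1).
#' @param cycles Gibbs-style cycles per imputation (>= 1).
#' @param pmm_donors Donor-pool size for predictive mean matching (>= 1).
#' @param variable_models Named list mapping feature name to one of `"pmm"`,
#'   `"logistic"`, `"proportional_odds"`; defaults derive from the category.
#' @param constraints Named list mapping feature name to `c(lo, hi)`;
#'   defaults: probing depth `[1, Inf)`, attachment loss `[0, Inf)`,
#'   furcation `[0, 3]`, bleeding `[0, 1]`.
#' @param seed RNG seed.
#' @return List of class `perio_chained_config`.
#' @export
chained_config <- function(m = 5L, cycles = 10L, pmm_donors = 5L,
                           variable_models = NULL, constraints = NULL,
                           seed = 1L) {
  if (m < 1 || cycles < 1 || pmm_donors < 1) {
    stop("invalid configuration: m, cycles and pmm_donors must all be >= 1")
  }
  structure(list(m = as.integer(m), cycles = as.integer(cycles),
                 pmm_donors = as.integer(pmm_donors),
                 variable_models = variable_models, constraints = constraints,
                 seed = as.integer(seed)),
            class = "perio_chained_config")
}

.default_model_for <- function(feature) {
  switch(feature_category(feature),
         ProbingDepth = "pmm", AttachmentLoss = "pmm",
         BleedingOnProbing = "logistic", Furcation = "proportional_odds")
}

.default_constraint_for <- function(feature) {
  switch(feature_category(feature),
         ProbingDepth = c(1, Inf), AttachmentLoss = c(0, Inf),
         Furcation = c(0, 3), BleedingOnProbing = c(0, 1))
}

# Least-squares coefficients with a ridge fallback for singular designs.
.lm_coef <- function(D, y) {
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("singular design matrix; ridge fallback used")
    XtX <- crossprod(D) + diag(1e-6, ncol(D))
    drop(solve(XtX, crossprod(D, y)))
  } else {
    drop(qr.coef(qrD, y))
  }
}

# One PMM draw set: nearest predicted-value donors, random pick per cell.
.pmm_draw <- function(D, y, obs, mis, donors) {
  beta <- .lm_coef(D[obs, , drop = FALSE], y[obs])
  pred <- drop(D %*% beta)
  y_obs <- y[obs]
  pred_obs <- pred[obs]
  vapply(which(mis), function(row) {
    pool <- order(abs(pred_obs - pred[row]))[seq_len(min(donors,
                                                         length(pred_obs)))]
    y_obs[pool[sample.int(length(pool), 1)]]
  }, numeric(1))
}

.logistic_draw <- function(D, y, obs, mis) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(D[obs, , drop = FALSE], y[obs],
                                    family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    p <- rep(mean(y[obs]), sum(mis))
  } else {
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    p <- stats::plogis(drop(D[mis, , drop = FALSE] %*% beta))
  }
  stats::rbinom(sum(mis), 1, p)
}

.polr_draw <- function(D, y, obs, mis) {
  lev <- sort(unique(y[obs]))
  if (length(lev) < 2) return(rep(lev, sum(mis)))
  df <- as.data.frame(D[, -1, drop = FALSE])  # polr adds its own intercept
  df$.y <- factor(y, levels = lev, ordered = TRUE)
  probs <- tryCatch({
    fit <- suppressWarnings(MASS::polr(.y ~ ., data = df[obs, , drop = FALSE],
                                       Hess = FALSE))
    stats::predict(fit, newdata = df[mis, , drop = FALSE], type = "probs")
  }, error = function(e) NULL)
  if (is.null(probs)) {
    # marginal draw when the proportional-odds fit or prediction fails
    # (e.g. a rank-deficient design on a small cohort)
    return(sample(y[obs], sum(mis), replace = TRUE))
  }
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  apply(probs, 1, function(p) lev[sample.int(length(lev), 1, prob = p)])
}

#' Chained-equations multiple imputation
#'
#' Generates `m` stochastic completions of the masked cohort. Each imputation
#' starts by filling masked cells with random draws from their feature's
#' observed values, then runs `cycles` passes over the incomplete features in
#' column order; at each visit the feature is regressed on all other features
#' (the four demographics plus the 31 remaining tooth-site variables, current
#' imputations included) over the rows where it was observed, and its masked
#' cells are redrawn from the fitted conditional — predictive mean matching
#' for continuous features, a Bernoulli draw from logistic regression for
#' binary ones, a categorical draw from proportional-odds regression for
#' ordinal ones. Draws are clipped to the plausibility constraints.
#'
#' @param masked Masked cohort `data.frame`.
#' @param mask Logical mask matrix consistent with `masked`.
#' @param config A [chained_config()].
#' @return List of `m` imputed cohort `data.frame`s, each with attribute
#'   `"imputed_mask"`.
#' @export
impute_chained <- function(masked, mask, config = chained_config()) {
  X <- site_matrix(masked)
  check_mask_consistency(X, mask)
  feats <- colnames(mask)
  demo <- demographic_features()
  missing_demo <- setdiff(demo, names(masked))
  if (length(missing_demo)) {
    stop("cohort is missing demographic column(s): ",
         paste(missing_demo, collapse = ", "))
  }
  incomplete <- feats[colSums(mask) > 0]
  set.seed(config$seed)
  results <- vector("list", config$m)
  for (imp in seq_len(config$m)) {
    cur <- masked
    for (f in incomplete) {
      obs_vals <- cur[[f]][!mask[, f]]
      if (!length(obs_vals)) stop("column with no observed values: ", f)
      cur[[f]][mask[, f]] <- sample(obs_vals, sum(mask[, f]), replace = TRUE)
    }
    for (cycle in seq_len(config$cycles)) {
      for (f in incomplete) {
        obs <- !mask[, f]
        mis <- mask[, f]
        model <- config$variable_models[[f]]
        if (is.null(model)) model <- .default_model_for(f)
        con <- config$constraints[[f]]
        if (is.null(con)) con <- .default_constraint_for(f)
        predictors <- c(demo, setdiff(feats, f))
        D <- cbind(1, as.matrix(cur[predictors]))
        y <- cur[[f]]
        drawn <- switch(model,
          pmm = .pmm_draw(D, y, obs, mis, config$pmm_donors),
          logistic = .logistic_draw(D, y, obs, mis),
          proportional_odds = .polr_draw(D, y, obs, mis),
          stop("unknown conditional model: ", model))
        cur[[f]][mis] <- pmin(con[2], pmax(con[1], drawn))
      }
    }
    attr(cur, "imputed_mask") <- mask
    results[[imp]] <- cur
  }
  results
}
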