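# Denoising autoencoder: mean-fill corruption, standardisation, a 32-18-32
# tanh/linear network trained by full-batch gradient descent, and imputation.

#' Training configuration for the denoising autoencoder
#'
#' Defaults are the reference settings: 100 epochs of full-batch gradient
#' descent at learning rate 0.01 on a single hidden layer of 18 tanh units.
#' Weights are initialised Glorot-uniform (bound `sqrt(6 / (fan_in +
#' fan_out))`), biases at zero; `init_scale` overrides the bound if set.
#'
#' @param epochs Number of full-batch epochs (>= 0).
#' @param learning_rate Gradient-descent step size (>= 0).
#' @param hidden_units Hidden-layer width (>= 1).
#' @param init_scale Optional uniform initialisation half-width; `NULL` means
#'   the Glorot bound per weight matrix.
#' @param seed RNG seed for weight initialisation.
#' @return List of class `perio_train_config`.
#' @export
train_config <- function(epochs = 100L, learning_rate = 0.01,
                         hidden_units = 18L, init_scale = NULL, seed = 1L) {
  if (epochs < 0 || epochs != round(epochs)) {
    stop("invalid configuration: epochs must be a nonnegative integer")
  }
  if (learning_rate < 0) {
    stop("invalid configuration: learning_rate must be >= 0")
  }
  if (hidden_units < 1 || hidden_units != round(hidden_units)) {
    stop("invalid configuration: hidden_units must be a positive integer")
  }
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 hidden_units = as.integer(hidden_units),
                 init_scale = init_scale, seed = as.integer(seed)),
            class = "perio_train_config")
}

#' Fill missing cells with observed column means
#'
#' The corruption step of the denoising autoencoder: each `NA` is replaced by
#' the mean of the observed values in its column. Observed cells are untouched.
#'
#' @param X Numeric matrix with `NA`s at missing cells.
#' @return List with `filled` (the completed matrix) and `fill_values` (the
#'   per-column observed means used).
#' @export
mean_fill <- function(X) {
  if (!is.matrix(X)) stop("X must be a matrix")
  fills <- colMeans(X, na.rm = TRUE)
  bad <- !is.finite(fills)
  if (any(bad)) {
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- which(bad)
    stop("column(s) with no observed values: ", paste(nm, collapse = ", "))
  }
  idx <- which(is.na(X), arr.ind = TRUE)
  filled <- X
  if (nrow(idx)) filled[idx] <- fills[idx[, 2]]
  list(filled = filled, fill_values = fills)
}

#' Fit per-column standardisation parameters
#'
#' Computes per-column mean and population standard deviation (divide by `n`)
#' on the fitting matrix — conventionally the mean-filled training matrix, so
#' imputation at deployment reuses training statistics and introduces no new
#' information. Columns with standard deviation below `sd_floor` degenerate to
#' pure centering: their stored sd is set to 1 with a warning.
#'
#' @param X Numeric matrix (no `NA`s).
#' @param sd_floor Threshold below which a column counts as constant.
#' @return List of class `perio_scaler` with `center` and `scale` vectors.
#' @export
fit_scaler <- function(X, sd_floor = 1e-8) {
  if (anyNA(X)) stop("X must not contain missing values; mean-fill first")
  center <- colMeans(X)
  scale <- sqrt(colMeans(sweep(X, 2, center)^2))
  degenerate <- scale < sd_floor
  if (any(degenerate)) {
    nm <- colnames(X)[degenerate]
    if (is.null(nm)) nm <- which(degenerate)
    warning("constant column(s) standardised by centering only: ",
            paste(nm, collapse = ", "))
    scale[degenerate] <- 1
  }
  structure(list(center = center, scale = scale), class = "perio_scaler")
}

#' @rdname fit_scaler
#' @param scaler A `perio_scaler`.
#' @export
scaler_transform <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

#' @rdname fit_scaler
#' @export
scaler_inverse <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$scale, "*"), 2, scaler$center, "+")
}

#' Initialise autoencoder parameters
#'
#' Weights are drawn uniformly on `[-b, b]` with `b` the Glorot bound
#' `sqrt(6 / (fan_in + fan_out))` per matrix (or `init_scale` if given);
#' biases start at zero. Deterministic given the config seed.
#'
#' @param config A [train_config()].
#' @param n_features Input/output width (default 32, the tooth-site block).
#' @return List of class `perio_dae_params` with `W1` (features x hidden),
#'   `b1`, `W2` (hidden x features), `b2`.
#' @export
init_dae <- function(config = train_config(), n_features = 32L) {
  set.seed(substream_seed(config$seed, "init"))
  h <- config$hidden_units
  bound <- function(fan_in, fan_out) {
    if (is.null(config$init_scale)) sqrt(6 / (fan_in + fan_out))
    else config$init_scale
  }
  b1v <- bound(n_features, h)
  b2v <- bound(h, n_features)
  structure(list(
    W1 = matrix(stats::runif(n_features * h, -b1v, b1v), n_features, h),
    b1 = numeric(h),
    W2 = matrix(stats::runif(h * n_features, -b2v, b2v), h, n_features),
    b2 = numeric(n_features)
  ), class = "perio_dae_params")
}

#' Forward pass
#'
#' `H = tanh(X W1 + b1)` row-wise, then the linear decoder
#' `Xhat = H W2 + b2`.
#'
#' @param params `perio_dae_params`.
#' @param X Standardised input matrix, rows = patients.
#' @return List with hidden activations `H` and reconstruction `Xhat`.
#' @export
dae_forward <- function(params, X) {
  if (ncol(X) != nrow(params$W1)) {
    stop("dimension mismatch: X has ", ncol(X), " columns but W1 expects ",
         nrow(params$W1))
  }
  H <- tanh(sweep(X %*% params$W1, 2, params$b1, "+"))
  Xhat <- sweep(H %*% params$W2, 2, params$b2, "+")
  list(H = H, Xhat = Xhat)
}

#' Reconstruction loss
#'
#' Mean over patients of the squared Euclidean norm of the row residual:
#' `L = (1/n) sum_i || xhat_i - x_i ||^2`. Note the per-row norm sums over all
#' features, so a perfect reconstruction gives 0 and the loss scale grows with
#' the feature count; a per-entry variant (`L / n_features`) is logged in the
#' training trace for comparability across widths.
#'
#' @param Xhat Reconstruction matrix.
#' @param X_target Target matrix of the same shape.
#' @return Scalar loss (>= 0).
#' @export
dae_loss <- function(Xhat, X_target) {
  if (!all(dim(Xhat) == dim(X_target))) {
    stop("dimension mismatch between reconstruction and target")
  }
  mean(rowSums((Xhat - X_target)^2))
}

#' Analytic gradients of the reconstruction loss
#'
#' Backpropagation through the linear decoder and tanh encoder. Exact
#' derivatives of [dae_loss()] with respect to all four parameter blocks.
#'
#' @param params `perio_dae_params`.
#' @param X_in Input matrix (standardised, mean-filled).
#' @param X_target Target matrix.
#' @return List with `W1`, `b1`, `W2`, `b2` gradient blocks (same shapes as
#'   the parameters).
#' @export
dae_gradients <- function(params, X_in, X_target) {
  fw <- dae_forward(params, X_in)
  n <- nrow(X_in)
  dXhat <- 2 * (fw$Xhat - X_target) / n
  dH <- dXhat %*% t(params$W2)
  dZ <- dH * (1 - fw$H^2)  # tanh'(z) = 1 - tanh(z)^2
  list(W1 = t(X_in) %*% dZ,
       b1 = colSums(dZ),
       W2 = t(fw$H) %*% dXhat,
       b2 = colSums(dXhat))
}

#' Train the denoising autoencoder on a masked cohort
#'
#' Pipeline: mean-fill the tooth-site block, standardise it (statistics from
#' the filled matrix), initialise the network, then run `epochs` full-batch
#' gradient steps. By default the network is trained to reconstruct the
#' standardised mean-filled matrix itself — the only matrix available when the
#' ground truth is genuinely unknown; `target = "truth"` trains against the
#' standardised complete cohort instead, for controlled experiments where it
#' exists.
#'
#' @param masked Masked cohort `data.frame` (tooth-site `NA`s at hidden cells).
#' @param config A [train_config()].
#' @param target `"filled"` (default) or `"truth"`.
#' @param truth Complete cohort `data.frame`; required when
#'   `target = "truth"`.
#' @return List of class `perio_dae` with `params`, `scaler`, `fill_values`,
#'   `trace` (data.frame: epoch, loss, loss_per_entry) and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 40, seed = 1))
#' mc <- apply_mcar(cohort, seed = 2)
#' fit <- train_dae(mc$masked, train_config(epochs = 10, seed = 3))
#' tail(fit$trace, 1)
train_dae <- function(masked, config = train_config(),
                      target = c("filled", "truth"), truth = NULL) {
  target <- match.arg(target)
  X <- site_matrix(masked)
  mf <- mean_fill(X)
  scaler <- fit_scaler(mf$filled)
  Z_in <- scaler_transform(scaler, mf$filled)
  Z_target <- if (target == "truth") {
    if (is.null(truth)) stop("target = \"truth\" requires the complete cohort")
    scaler_transform(scaler, site_matrix(truth))
  } else {
    Z_in
  }
  params <- init_dae(config, n_features = ncol(X))
  n_epochs <- config$epochs
  loss_trace <- numeric(n_epochs)
  for (epoch in seq_len(n_epochs)) {
    fw <- dae_forward(params, Z_in)
    loss_trace[epoch] <- dae_loss(fw$Xhat, Z_target)
    if (!is.finite(loss_trace[epoch])) {
      stop("training diverged (non-finite loss) at epoch ", epoch)
    }
    g <- dae_gradients(params, Z_in, Z_target)
    lr <- config$learning_rate
    params$W1 <- params$W1 - lr * g$W1
    params$b1 <- params$b1 - lr * g$b1
    params$W2 <- params$W2 - lr * g$W2
    params$b2 <- params$b2 - lr * g$b2
  }
  # parameters are positional; drop dimnames picked up from the data
  dimnames(params$W1) <- dimnames(params$W2) <- NULL
  names(params$b1) <- names(params$b2) <- NULL
  structure(list(
    params = params, scaler = scaler, fill_values = mf$fill_values,
    trace = data.frame(epoch = seq_len(n_epochs), loss = loss_trace,
                       loss_per_entry = loss_trace / ncol(X)),
    config = config
  ), class = "perio_dae")
}

#' @export
print.perio_dae <- function(x, ...) {
  cat("Denoising autoencoder fit:", nrow(x$params$W1), "-",
      ncol(x$params$W1), "-", ncol(x$params$W2), "architecture\n")
  cat("  epochs:", x$config$epochs, " lr:", x$config$learning_rate, "\n")
  if (nrow(x$trace)) {
    cat("  loss: first", format(x$trace$loss[1], digits = 4),
        "-> final", format(x$trace$loss[nrow(x$trace)], digits = 4), "\n")
  }
  invisible(x)
}

# Clinical post-processing of imputed values, by category:
# BoP thresholded at 0.5, furcation rounded and clipped to 0..3,
# PD clipped to >= pd_floor, AL clipped to >= 0.
clinical_postprocess <- function(values, categories, pd_floor = 1.0) {
  out <- values
  pd <- categories == "ProbingDepth"
  al <- categories == "AttachmentLoss"
  fu <- categories == "Furcation"
  bp <- categories == "BleedingOnProbing"
  out[pd] <- pmax(pd_floor, out[pd])
  out[al] <- pmax(0, out[al])
  out[fu] <- pmin(3, pmax(0, round(out[fu])))
  out[bp] <- as.numeric(out[bp] >= 0.5)
  out
}

#' Impute masked cells with a trained autoencoder
#'
#' Replays the training preprocessing — fill masked cells with the training
#' column means, standardise with the training scaler — runs the encoder and
#' decoder, inverse-transforms the reconstruction to clinical units, and
#' substitutes it at masked cells only. Observed cells are preserved
#' bit-identically.
#'
#' `post_process = "raw"` (the default) leaves all reconstructions continuous,
#' which is the form used for the error metrics; `"clinical"` produces
#' chart-ready values (bleeding thresholded at 0.5, furcation rounded into
#' grades 0-3, probing depth floored at `pd_floor`, attachment loss at 0).
#'
#' @param fit A `perio_dae` from [train_dae()].
#' @param masked Masked cohort `data.frame`.
#' @param mask Logical mask matrix consistent with `masked`.
#' @param post_process `"raw"` or `"clinical"`.
#' @param pd_floor Probing-depth floor for clinical mode, mm.
#' @return The imputed cohort `data.frame`, with the mask attached as
#'   attribute `"imputed_mask"` (cell provenance: `TRUE` = imputed).
#' @export
impute_dae <- function(fit, masked, mask, post_process = c("raw", "clinical"),
                       pd_floor = 1.0) {
  post_process <- match.arg(post_process)
  X <- site_matrix(masked)
  check_mask_consistency(X, mask)
  filled <- X
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) filled[idx] <- fit$fill_values[idx[, 2]]
  Z <- scaler_transform(fit$scaler, filled)
  recon <- scaler_inverse(fit$scaler, dae_forward(fit$params, Z)$Xhat)
  dimnames(recon) <- dimnames(X)
  if (post_process == "clinical") {
    cats <- feature_category(colnames(recon))
    for (j in seq_len(ncol(recon))) {
      recon[, j] <- clinical_postprocess(recon[, j], rep(cats[j], nrow(recon)),
                                         pd_floor = pd_floor)
    }
  }
  out <- masked
  for (f in colnames(mask)) out[[f]][mask[, f]] <- recon[mask[, f], f]
  attr(out, "imputed_mask") <- mask
  attr(out, "post_process") <- post_process
  out
}

# Shared validation: the mask must cover exactly the NA cells of the block.
check_mask_consistency <- function(X, mask) {
  if (!is.matrix(mask) || !is.logical(mask) ||
      nrow(mask) != nrow(X) || ncol(mask) != ncol(X)) {
    stop("dimension mismatch between mask and tooth-site block")
  }
  if (is.null(colnames(mask)) || !identical(colnames(mask), colnames(X))) {
    stop("mask columns must match the tooth-site features in order")
  }
  na_cells <- is.na(X)
  if (!identical(unname(na_cells), unname(mask))) {
    stop("mask is inconsistent with the missing cells of the cohort")
  }
  invisible(TRUE)
}
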