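# CSV / JSON / YAML interfaces: wide cohort tables, 0/1 masks, model
# checkpoints, evaluation reports, run configuration.

.cohort_header <- function() {
  c("patient_id", demographic_features(), site_features())
}

# Field-count validation shared by the CSV readers: every row must have the
# header's width; violations are reported with their line number.
.check_row_widths <- function(path, expected) {
  widths <- utils::count.fields(path, sep = ",", quote = "\"",
                                blank.lines.skip = FALSE)
  bad <- which(widths != expected)
  if (length(bad)) {
    stop("parse error in ", path, ": line ", bad[1], " has ",
         widths[bad[1]], " fields, expected ", expected)
  }
}

#' Read / write cohort CSV files
#'
#' The wide cohort format: header `patient_id,Age,Gender,Smoking,Diabetes`
#' followed by the 32 tooth-site columns in site order. Missing tooth-site
#' values are empty cells; continuous values are written in full precision so
#' a write/read round trip reproduces the table to float-text accuracy and
#' the missingness pattern exactly.
#'
#' @param path File path.
#' @return `read_cohort_csv`: the cohort `data.frame` (`NA` at empty cells).
#' @export
read_cohort_csv <- function(path) {
  header <- .cohort_header()
  .check_row_widths(path, length(header))
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "numeric", na.strings = "")
  if (!identical(names(df), header)) {
    stop("parse error in ", path, ": header does not match the cohort schema")
  }
  if (anyNA(df[c("patient_id", demographic_features())])) {
    stop("parse error in ", path,
         ": demographic columns must not have empty cells")
  }
  df
}

#' @rdname read_cohort_csv
#' @param cohort Cohort `data.frame` matching the schema.
#' @export
write_cohort_csv <- function(cohort, path) {
  header <- .cohort_header()
  if (!all(header %in% names(cohort))) {
    stop("cohort is missing column(s): ",
         paste(setdiff(header, names(cohort)), collapse = ", "))
  }
  utils::write.csv(cohort[header], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write mask CSV files
#'
#' Same row order as the cohort, header `patient_id` plus the 32 tooth-site
#' columns; entries are 0 (observed) or 1 (masked).
#'
#' @param path File path.
#' @return `read_mask_csv`: a logical mask matrix.
#' @export
read_mask_csv <- function(path) {
  feats <- site_features()
  .check_row_widths(path, length(feats) + 1)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), c("patient_id", feats))) {
    stop("parse error in ", path, ": header does not match the mask schema")
  }
  M <- as.matrix(df[feats])
  if (anyNA(M) || !all(M %in% c(0, 1))) {
    stop("parse error in ", path, ": mask entries must be 0 or 1")
  }
  matrix(M == 1, nrow = nrow(M), dimnames = list(NULL, feats))
}

#' @rdname read_mask_csv
#' @param mask Logical mask matrix.
#' @param patient_id Patient identifiers (default 0-based row index).
#' @export
write_mask_csv <- function(mask, path, patient_id = seq_len(nrow(mask)) - 1L) {
  df <- data.frame(patient_id = patient_id)
  df[colnames(mask)] <- as.data.frame(mask * 1L)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained autoencoder checkpoint
#'
#' Flat JSON: parameter shapes, row-major weight arrays, scaler statistics,
#' fill values and the training configuration, so a fit can be re-used
#' without retraining.
#'
#' @param fit A `perio_dae` from [train_dae()].
#' @param path File path.
#' @export
save_checkpoint <- function(fit, path) {
  p <- fit$params
  obj <- list(
    shapes = list(W1 = dim(p$W1), W2 = dim(p$W2)),
    W1 = as.vector(t(p$W1)), b1 = p$b1,
    W2 = as.vector(t(p$W2)), b2 = p$b2,
    scaler_center = fit$scaler$center, scaler_scale = fit$scaler$scale,
    fill_values = fit$fill_values,
    config = unclass(fit$config)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: a `perio_dae` (without a training trace).
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d1 <- obj$shapes$W1
  d2 <- obj$shapes$W2
  params <- structure(list(
    W1 = matrix(obj$W1, d1[1], d1[2], byrow = TRUE),
    b1 = as.numeric(obj$b1),
    W2 = matrix(obj$W2, d2[1], d2[2], byrow = TRUE),
    b2 = as.numeric(obj$b2)
  ), class = "perio_dae_params")
  cfg <- obj$config
  config <- train_config(epochs = cfg$epochs, learning_rate = cfg$learning_rate,
                         hidden_units = cfg$hidden_units,
                         init_scale = cfg$init_scale, seed = cfg$seed)
  scaler <- structure(list(center = obj$scaler_center,
                           scale = obj$scaler_scale), class = "perio_scaler")
  names(scaler$center) <- names(scaler$scale) <- site_features()
  fills <- as.numeric(obj$fill_values)
  names(fills) <- site_features()
  structure(list(params = params, scaler = scaler, fill_values = fills,
                 trace = data.frame(epoch = integer(0), loss = numeric(0),
                                    loss_per_entry = numeric(0)),
                 config = config),
            class = "perio_dae")
}

#' Write an evaluation report
#'
#' JSON with keys `per_feature`, `per_category`, `overall`, `qwk` and any
#' run metadata supplied; optionally also a flat CSV of the per-feature rows.
#'
#' @param report A `perio_eval`.
#' @param path JSON output path.
#' @param csv_path Optional per-feature CSV path.
#' @param metadata Optional named list merged into the JSON (seeds, config).
#' @export
write_report <- function(report, path, csv_path = NULL, metadata = NULL) {
  obj <- list(per_feature = report$per_feature,
              per_category = report$per_category,
              overall = report$overall,
              qwk = as.list(report$qwk))
  if (!is.null(metadata)) obj$metadata <- metadata
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", dataframe = "rows")
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_feature, csv_path, row.names = FALSE)
  }
  invisible(path)
}
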