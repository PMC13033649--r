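# End-to-end orchestration: cohort -> mask -> imputation -> evaluation,
# per seed and aggregated across seeds.

#' Workflow configuration
#'
#' Bundles the stage configurations of the end-to-end run. Each seed in
#' `seeds` drives one complete replicate — cohort generation, masking, model
#' fitting and imputation all derive their substream seeds from it — so the
#' per-seed outputs are independent of the order and number of seeds.
#'
#' @param sim A [sim_config()] (its own seed is ignored; the run seed is
#'   used).
#' @param rate MCAR masking rate over the tooth-site block.
#' @param train A [train_config()] for the autoencoder.
#' @param methods Character subset of `c("dae", "mean", "knn", "mice")`.
#' @param knn A [knn_config()].
#' @param chained A [chained_config()].
#' @param seeds Integer vector of replicate seeds (>= 1 of them).
#' @param post_process Autoencoder output mode passed to [impute_dae()].
#' @param out_dir Optional directory for artifacts (CSVs, traces,
#'   checkpoints, reports); `NULL` keeps everything in memory.
#' @return List of class `perio_run_config`.
#' @export
run_config <- function(sim = sim_config(), rate = 0.15,
                       train = train_config(),
                       methods = "dae", knn = knn_config(),
                       chained = chained_config(), seeds = 1L,
                       post_process = "raw", out_dir = NULL) {
  methods <- match.arg(methods, c("dae", "mean", "knn", "mice"),
                       several.ok = TRUE)
  if (!length(seeds)) stop("invalid configuration: need at least one seed")
  structure(list(sim = sim, rate = rate, train = train, methods = methods,
                 knn = knn, chained = chained, seeds = as.integer(seeds),
                 post_process = post_process, out_dir = out_dir),
            class = "perio_run_config")
}

.stage_log <- function(stage, seed, started, ...) {
  extras <- paste(c(...), collapse = " ")
  message(sprintf("[%s] seed=%d %.2fs %s", stage, seed,
                  as.numeric(Sys.time()) - started, extras))
}

# One replicate: returns a named list of perio_eval reports, one per method.
.run_one_seed <- function(config, seed, verbose = FALSE) {
  out_dir <- config$out_dir
  artifact <- function(name) file.path(out_dir, sprintf("seed%d_%s", seed,
                                                        name))
  t0 <- as.numeric(Sys.time())
  sim <- config$sim
  sim$seed <- substream_seed(seed, "cohort")
  cohort <- generate_cohort(sim)
  .stage_log("simulate", seed, t0, paste0("n=", nrow(cohort)))

  t0 <- as.numeric(Sys.time())
  mc <- apply_mcar(cohort, rate = config$rate,
                   seed = substream_seed(seed, "mask"))
  .stage_log("mask", seed, t0, paste0("masked=", sum(mc$mask)))
  if (!is.null(out_dir)) {
    write_cohort_csv(cohort, artifact("cohort.csv"))
    write_cohort_csv(mc$masked, artifact("masked.csv"))
    write_mask_csv(mc$mask, artifact("mask.csv"),
                   patient_id = cohort$patient_id)
  }

  reports <- list()
  for (method in config$methods) {
    t0 <- as.numeric(Sys.time())
    if (method == "dae") {
      tc <- config$train
      tc$seed <- substream_seed(seed, "train")
      fit <- train_dae(mc$masked, tc)
      if (verbose) {
        for (i in seq_len(nrow(fit$trace))) {
          message(sprintf("  epoch %d loss %.6f", fit$trace$epoch[i],
                          fit$trace$loss[i]))
        }
      }
      imputed <- impute_dae(fit, mc$masked, mc$mask,
                            post_process = config$post_process,
                            pd_floor = config$sim$pd_floor)
      report <- evaluate_imputation(cohort, imputed, mc$mask)
      if (!is.null(out_dir)) {
        utils::write.csv(fit$trace, artifact("dae_trace.csv"),
                         row.names = FALSE)
        save_checkpoint(fit, artifact("dae_checkpoint.json"))
        write_cohort_csv(imputed, artifact("dae_imputed.csv"))
      }
    } else if (method == "mean") {
      imputed <- impute_mean(mc$masked, mc$mask)
      report <- evaluate_imputation(cohort, imputed, mc$mask)
      if (!is.null(out_dir)) write_cohort_csv(imputed,
                                              artifact("mean_imputed.csv"))
    } else if (method == "knn") {
      imputed <- impute_knn(mc$masked, mc$mask, config$knn)
      report <- evaluate_imputation(cohort, imputed, mc$mask)
      if (!is.null(out_dir)) write_cohort_csv(imputed,
                                              artifact("knn_imputed.csv"))
    } else {  # mice
      cc <- config$chained
      cc$seed <- substream_seed(seed, "chained")
      imps <- impute_chained(mc$masked, mc$mask, cc)
      if (!is.null(out_dir)) {
        for (i in seq_along(imps)) {
          write_cohort_csv(imps[[i]], artifact(sprintf("mice_imp%d.csv", i)))
        }
      }
      report <- pool_imputations(lapply(imps, function(im) {
        evaluate_imputation(cohort, im, mc$mask)
      }))
    }
    ov <- report$overall
    .stage_log(method, seed, t0,
               sprintf("MAE=%.4f RMSE=%.4f", ov$mae, ov$rmse))
    if (!is.null(out_dir)) {
      write_report(report, artifact(paste0(method, "_report.json")),
                   metadata = list(seed = seed, method = method,
                                   rate = config$rate))
    }
    reports[[method]] <- report
  }
  reports
}

# mean and sd of a metric across per-seed reports
.aggregate_metric <- function(reports, get) {
  vals <- vapply(reports, get, numeric(1))
  list(mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals)
                               else NA_real_)
}

#' Run the end-to-end workflow
#'
#' For each seed: generate the cohort, induce MCAR missingness, impute with
#' every requested method and evaluate against the ground truth. Per-seed
#' reports are aggregated (mean and sd of each overall and per-category
#' metric across seeds) into one summary per method.
#'
#' @param config A [run_config()].
#' @param verbose Log per-epoch autoencoder loss?
#' @return List with `per_seed` (nested: seed -> method -> `perio_eval`) and
#'   `aggregate` (method -> list of metric summaries), invisibly written to
#'   `out_dir` when set.
#' @export
#' @examples
#' res <- run_workflow(run_config(sim = sim_config(n_patients = 40),
#'                                train = train_config(epochs = 20),
#'                                seeds = c(1, 2)))
#' res$aggregate$dae$overall_mae
run_workflow <- function(config = run_config(), verbose = FALSE) {
  if (!is.null(config$out_dir) && !dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  per_seed <- lapply(config$seeds, function(s) {
    .run_one_seed(config, s, verbose = verbose)
  })
  names(per_seed) <- paste0("seed", config$seeds)

  aggregate <- lapply(stats::setNames(nm = config$methods), function(method) {
    reps <- lapply(per_seed, `[[`, method)
    agg <- list(
      overall_mae = .aggregate_metric(reps, function(r) r$overall$mae),
      overall_rmse = .aggregate_metric(reps, function(r) r$overall$rmse))
    for (ct in unique(feature_category(site_features()))) {
      agg[[paste0(ct, "_mae")]] <- .aggregate_metric(reps, function(r) {
        r$per_category$mae[r$per_category$category == ct]
      })
      agg[[paste0(ct, "_rmse")]] <- .aggregate_metric(reps, function(r) {
        r$per_category$rmse[r$per_category$category == ct]
      })
    }
    agg
  })
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(
      list(aggregate = aggregate,
           config = list(n_patients = config$sim$n_patients,
                         rate = config$rate, methods = config$methods,
                         seeds = config$seeds,
                         epochs = config$train$epochs,
                         learning_rate = config$train$learning_rate,
                         hidden_units = config$train$hidden_units)),
      file.path(config$out_dir, "aggregate_report.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(list(per_seed = per_seed, aggregate = aggregate))
}

#' Read a workflow configuration from YAML
#'
#' The YAML mirrors the [run_config()] structure: top-level keys `sim`,
#' `rate`, `train`, `methods`, `knn`, `chained`, `seeds`, `post_process`,
#' `out_dir`, each (where structured) holding the corresponding constructor's
#' field names.
#'
#' @param path YAML file path.
#' @return A `perio_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$age_range)) y$sim$age_range <- unlist(y$sim$age_range)
    if (!is.null(y$sim$furcation_probs)) {
      y$sim$furcation_probs <- unlist(y$sim$furcation_probs)
    }
    args$sim <- do.call(sim_config, y$sim)
  }
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  if (!is.null(y$knn)) args$knn <- do.call(knn_config, y$knn)
  if (!is.null(y$chained)) args$chained <- do.call(chained_config, y$chained)
  for (field in c("rate", "methods", "post_process", "out_dir")) {
    if (!is.null(y[[field]])) args[[field]] <- unlist(y[[field]])
  }
  if (!is.null(y$seeds)) args$seeds <- unlist(y$seeds)
  do.call(run_config, args)
}
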