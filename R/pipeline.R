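#' Default end-to-end run configuration
#'
#' The shipped defaults follow the study protocol wherever one is stated:
#' 500 Hz records of 20-25 s, 5 s windows slid by 1 s, 500-point model
#' inputs, one-day-forward labels, the 184-feature layout, RF feature
#' subsampling of 12 (184 features) or 20 (500 raw points), and the PSO
#' settings (20 particles, 200 iterations, tolerance 1e-3, c1 = 1.5,
#' c2 = 1.7, box \[0.1, 100\]). Cohort size, EEMD ensemble size, and RCMSE
#' (m, r) are the package's own documented choices.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    synthetic = list(n_subjects = 6L, days_per_subject = 10L, fs = 500,
                     duration_range_s = c(20, 25), class_effect = 1.5,
                     hi_rho = 0.6, snr_db = 20),
    preprocess = list(window_s = 5, step_s = 1, target_len = 500L,
                      lag = 1L),
    features = list(drop_dc = FALSE, wavelet_name = "db4",
                    wavelet_level = 3L,
                    eemd = list(trials = 100L, noise_ratio = 0.2,
                                n_imfs_out = 10L, max_siftings = 10L,
                                sift_tolerance = 0.2),
                    rcmse = list(m = 2L, r = 0.15, tau_max = 20L)),
    model = list(type = "rf",
                 rf = list(n_trees = 500L, mtry = NULL),
                 pso = list(n_particles = 20L, max_iters = 200L,
                            tol = 1e-3, c1 = 1.5, c2 = 1.7,
                            bounds = c(0.1, 100)),
                 svm_cv_folds = 5L),
    evaluation = list(train_frac = 0.70, positive = 1L,
                      cv_rounds = 0L, cv_train_frac = 0.67)
  )
}

# recursive merge of user values over defaults, collecting unknown keys
merge_config <- function(defaults, user, path = "", errors) {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      errors$msgs <- c(errors$msgs, sprintf("unknown key '%s'", full))
      next
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        errors$msgs <- c(errors$msgs,
                         sprintf("'%s' must be a block", full))
      } else {
        defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full,
                                        errors)
      }
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate and complete a run configuration
#'
#' Merges a partial configuration (a nested list, or a path to a YAML file)
#' over [default_config()], rejects unknown keys, and range-checks every
#' value, accumulating all problems into a single error rather than failing
#' on the first.
#'
#' @param config Partial configuration list, a YAML file path, or
#'   \code{NULL} for pure defaults.
#' @return The completed configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  errors <- new.env()
  errors$msgs <- character(0)
  cfg <- merge_config(default_config(), config, "", errors)
  chk <- function(ok, msg) if (!isTRUE(ok)) errors$msgs <<- c(errors$msgs, msg)

  chk(cfg$synthetic$n_subjects >= 1, "synthetic.n_subjects must be >= 1")
  chk(cfg$synthetic$days_per_subject >= 1,
      "synthetic.days_per_subject must be >= 1")
  chk(cfg$synthetic$fs > 0, "synthetic.fs must be > 0")
  chk(length(cfg$synthetic$duration_range_s) == 2L &&
        cfg$synthetic$duration_range_s[1L] > 0 &&
        cfg$synthetic$duration_range_s[2L] >=
          cfg$synthetic$duration_range_s[1L],
      "synthetic.duration_range_s must be a valid (min, max) pair")
  chk(cfg$synthetic$class_effect >= 0,
      "synthetic.class_effect must be >= 0")
  chk(cfg$preprocess$window_s > 0, "preprocess.window_s must be > 0")
  chk(cfg$preprocess$step_s > 0, "preprocess.step_s must be > 0")
  chk(cfg$preprocess$target_len >= 8, "preprocess.target_len must be >= 8")
  chk(cfg$preprocess$lag >= 0, "preprocess.lag must be >= 0")
  chk(cfg$features$eemd$trials >= 1, "features.eemd.trials must be >= 1")
  chk(cfg$features$eemd$noise_ratio >= 0,
      "features.eemd.noise_ratio must be >= 0")
  chk(cfg$features$rcmse$m >= 1, "features.rcmse.m must be >= 1")
  chk(cfg$features$rcmse$r > 0, "features.rcmse.r must be > 0")
  chk(cfg$features$rcmse$tau_max >= 1, "features.rcmse.tau_max must be >= 1")
  chk(cfg$model$type %in% c("rf", "pso-svm"),
      "model.type must be 'rf' or 'pso-svm'")
  chk(cfg$model$pso$bounds[1L] < cfg$model$pso$bounds[2L],
      "model.pso.bounds must satisfy min < max")
  chk(cfg$evaluation$train_frac > 0 && cfg$evaluation$train_frac < 1,
      "evaluation.train_frac must be in (0, 1)")

  if (length(errors$msgs))
    stop(paste(c("invalid configuration:", errors$msgs), collapse = "\n  "),
         call. = FALSE)
  cfg
}

#' Run the full wellness-prediction pipeline
#'
#' Executes the three stages end to end on a synthetic cohort: feature
#' construction (segmentation, resampling, 184-feature extraction), data
#' preparation (min-max normalization fitted on the training split,
#' Fisher-Yates labels), and predictive-model development (stratified 70/30
#' hold-out; RF or PSO-SVM). Artifacts (cohort manifest, segments, feature
#' matrix, metrics, run manifest with MD5 checksums) are written to
#' \code{out_dir}. Re-running with the same configuration reproduces the
#' feature matrix bit for bit.
#'
#' @param config A configuration as accepted by [validate_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_segments Also write the (large) segments CSV (default
#'   \code{FALSE}).
#' @return Invisibly, a list with the test-set \code{metrics_report}, the
#'   trained \code{model}, the \code{features} matrix, \code{labels}, the
#'   completed \code{config}, and the artifact \code{paths}.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("wellness_run_"),
                         write_segments = FALSE) {
  cfg <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seeds <- spawn_seeds(cfg$seed, 4L)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  cohort <- stage("simulate", {
    sp <- cfg$synthetic
    generate_cohort(cohort_spec(
      n_subjects = sp$n_subjects, days_per_subject = sp$days_per_subject,
      fs = sp$fs, duration_range_s = sp$duration_range_s,
      class_effect = sp$class_effect, hi_rho = sp$hi_rho,
      snr_db = sp$snr_db, seed = seeds[1L]))
  })
  cohort_dir <- file.path(out_dir, "cohort")
  stage("write-cohort", write_cohort_csv(cohort, cohort_dir))

  dataset <- stage("segment-label", {
    pp <- cfg$preprocess
    make_segment_dataset(cohort, pp$window_s, pp$step_s, pp$target_len,
                         pp$lag)
  })
  if (write_segments) {
    seg_path <- file.path(out_dir, "segments.csv")
    data.table::fwrite(
      cbind(data.table::as.data.table(dataset$meta),
            label = dataset$labels,
            data.table::as.data.table(dataset$segments)),
      seg_path)
  }

  fs_eff <- cfg$preprocess$target_len / cfg$preprocess$window_s
  fcfg <- feature_configs(
    drop_dc = cfg$features$drop_dc,
    wavelet_name = cfg$features$wavelet_name,
    wavelet_level = cfg$features$wavelet_level,
    eemd = eemd_config(trials = cfg$features$eemd$trials,
                       noise_ratio = cfg$features$eemd$noise_ratio,
                       n_imfs_out = cfg$features$eemd$n_imfs_out,
                       max_siftings = cfg$features$eemd$max_siftings,
                       sift_tolerance = cfg$features$eemd$sift_tolerance,
                       seed = seeds[2L]),
    rcmse = rcmse_params(m = cfg$features$rcmse$m, r = cfg$features$rcmse$r,
                         tau_max = cfg$features$rcmse$tau_max))
  features <- stage("extract",
                    extract_matrix(dataset, fs_eff, fcfg,
                                   progress_every = 200L))
  feat_path <- file.path(out_dir, "features.csv")
  write_feature_csv(features, dataset$labels, feat_path,
                    meta = dataset$meta)

  result <- stage("model", {
    idx <- split_holdout(dataset$labels, cfg$evaluation$train_frac,
                         seeds[3L])
    norm <- fit_minmax(features[idx$train, , drop = FALSE])
    x_tr <- apply_minmax(norm, features[idx$train, , drop = FALSE])
    x_te <- apply_minmax(norm, features[idx$test, , drop = FALSE])
    y_tr <- dataset$labels[idx$train]
    y_te <- dataset$labels[idx$test]
    model <- if (cfg$model$type == "rf") {
      train_rf(x_tr, y_tr, rf_config(n_trees = cfg$model$rf$n_trees,
                                     mtry = cfg$model$rf$mtry,
                                     seed = seeds[4L]))
    } else {
      pc <- cfg$model$pso
      train_pso_svm(x_tr, y_tr,
                    pso_config(n_particles = pc$n_particles,
                               max_iters = pc$max_iters, tol = pc$tol,
                               c1 = pc$c1, c2 = pc$c2, bounds = pc$bounds,
                               seed = seeds[4L]),
                    cv_folds = cfg$model$svm_cv_folds)
    }
    report <- evaluate(predict(model, x_te), y_te,
                       positive = cfg$evaluation$positive)
    list(model = model, report = report, norm = norm, split = idx)
  })

  metrics_path <- file.path(out_dir, "metrics.yaml")
  yaml::write_yaml(
    list(confusion = as.list(result$report$confusion),
         metrics = as.list(result$report$metrics)),
    metrics_path)

  artifacts <- c(file.path(cohort_dir, "manifest.csv"), feat_path,
                 metrics_path)
  manifest <- list(
    seed = cfg$seed,
    config = cfg,
    n_records = length(cohort),
    n_segments = nrow(dataset$segments),
    r_version = as.character(getRversion()),
    checksums = as.list(tools::md5sum(artifacts))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))

  invisible(list(metrics = result$report, model = result$model,
                 features = features, labels = dataset$labels,
                 config = cfg,
                 paths = list(out_dir = out_dir, features = feat_path,
                              metrics = metrics_path)))
}
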