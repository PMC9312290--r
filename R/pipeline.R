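# End-to-end orchestration: simulate -> detect -> extract -> select ->
# train -> evaluate, with reproducible multi-label stratified splits and a
# strict fit-on-train contract: feature standardization, attribute
# selection, window z-scoring and imputation parameters are all computed on
# training indices only.

#' Pipeline run configuration
#'
#' @param n_records Number of synthetic records (ignored when `records`
#'   given).
#' @param records Optional pre-built list of `ecg_record`s.
#' @param prevalence Label prevalences for the synthetic generator.
#' @param duration_s,noise_sd Synthetic record duration and noise level.
#' @param lead Lead used for fiducials and features.
#' @param window_length_s,stride_s Window geometry.
#' @param selection_enabled Run the attribute selector (`TRUE`) or keep the
#'   full 118-attribute catalog (`FALSE`, ablation mode).
#' @param k_select Number of attributes retained (default 20).
#' @param alpha,beta,gamma1,gamma2 Selector hyperparameters.
#' @param split_policy `"cv"` (default; stratified k-fold) or `"holdout"`.
#' @param train_frac Training fraction for holdout (default 0.6).
#' @param cv_folds Folds for `"cv"` (default 5).
#' @param epochs,batch_size,learning_rate Training knobs. The pipeline
#'   defaults (120 epochs, batch 16, step 0.05) are sized for datasets of a
#'   few hundred records, where they give the optimiser a number of SGD
#'   updates comparable to large-cohort training; [train_config()] itself
#'   defaults to the large-cohort protocol (batch 150, step 0.001).
#' @param threshold Probability cut-off for label binarisation.
#' @param seed Master seed; every stochastic stage derives from it.
#' @return A `run_config` list.
#' @export
run_config <- function(n_records = 300, records = NULL,
                       prevalence = c(Normal = 0.18, AF = 0.24, PVC = 0.14,
                                      PAC = 0.12, LBBB = 0.05, RBBB = 0.36),
                       duration_s = 10, noise_sd = 0.02, lead = "II",
                       window_length_s = 2, stride_s = 1,
                       selection_enabled = TRUE, k_select = 20,
                       alpha = 0.1, beta = 0.1, gamma1 = 0.1, gamma2 = 0.1,
                       split_policy = c("cv", "holdout"), train_frac = 0.6,
                       cv_folds = 5, epochs = 120, batch_size = 16,
                       learning_rate = 0.05, threshold = 0.5, seed = 1) {
  split_policy <- match.arg(split_policy)
  if (train_frac <= 0 || train_frac >= 1) stopf("`train_frac` must be in (0, 1)")
  if (cv_folds < 2) stopf("`cv_folds` must be >= 2")
  structure(as.list(environment()), class = "run_config")
}

#' Multi-label stratified dataset split
#'
#' `"holdout"` returns one train/test pair; `"cv"` returns `cv_folds`
#' pairs whose test sets partition the indices. Fold assignment uses
#' iterative stratification: labels are processed from rarest to most
#' common and each positive instance goes to the fold with the largest
#' remaining demand for that label, which keeps per-label prevalence
#' approximately equal across folds.
#'
#' @param Y n x m binary label matrix (or list of `ecg_record`s).
#' @param policy `"holdout"` or `"cv"`.
#' @param train_frac Training fraction for holdout.
#' @param cv_folds Number of folds.
#' @param seed Integer seed.
#' @return List of lists with `train` and `test` integer index vectors.
#' @export
split_dataset <- function(Y, policy = c("cv", "holdout"), train_frac = 0.6,
                          cv_folds = 5, seed = 1) {
  policy <- match.arg(policy)
  if (is.list(Y) && !is.matrix(Y)) Y <- label_matrix(Y)
  n <- nrow(Y)
  k <- if (policy == "cv") cv_folds else {
    if (n < 2) stopf("need at least 2 records to split")
    2L
  }
  if (n < k) stopf("need at least %d records for %d folds", k, k)
  # integer fold capacities: equal (plus remainder spread) for cv;
  # (1 - train_frac, train_frac) rounded for holdout
  cap <- if (policy == "cv") {
    base <- rep(n %/% k, k)
    extra <- n - sum(base)
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  } else {
    n_test <- round(n * (1 - train_frac))
    c(n_test, n - n_test)
  }
  fold <- rep(NA_integer_, n)
  with_seed(seed, {
    remaining_cap <- cap
    # per-fold desired positives per label, proportional to capacity
    lbl_counts <- colSums(Y)
    desire <- outer(cap / n, lbl_counts)
    unassigned <- rep(TRUE, n)
    ord_labels <- order(lbl_counts) # rarest label first
    pick <- function(score) {
      score[remaining_cap <= 0] <- -Inf
      which.max(score + stats::runif(k) * 1e-9)
    }
    for (j in ord_labels) {
      idx <- which(unassigned & Y[, j] == 1)
      for (i in idx[sample.int(length(idx))]) {
        f <- pick(desire[, j])
        fold[i] <- f
        unassigned[i] <- FALSE
        desire[f, ] <- desire[f, ] - Y[i, ]
        remaining_cap[f] <- remaining_cap[f] - 1
      }
    }
    rest <- which(unassigned)
    for (i in rest[sample.int(length(rest))]) {
      f <- pick(remaining_cap / max(cap, 1))
      fold[i] <- f
      remaining_cap[f] <- remaining_cap[f] - 1
    }
  })
  if (policy == "cv") {
    lapply(seq_len(k), function(f) {
      list(train = which(fold != f), test = which(fold == f))
    })
  } else {
    list(list(train = which(fold == 2L), test = which(fold == 1L)))
  }
}

# Majority baseline: per label, predict the training-majority bit.
.majority_predict <- function(Y_train, n_test) {
  bits <- as.integer(colMeans(Y_train) > 0.5)
  matrix(bits, n_test, length(bits), byrow = TRUE,
         dimnames = list(NULL, colnames(Y_train)))
}

#' Run the full multi-label classification pipeline
#'
#' Generates (or accepts) a dataset, detects fiducials, extracts the
#' 118-attribute catalog, selects the top-k attributes on training data,
#' builds z-scored window matrices, trains the CNN-GRU classifier and
#' evaluates on held-out records. With `split_policy = "cv"` every fold is
#' processed independently and the report carries per-fold metrics plus
#' their mean and SD; a per-label-majority baseline is evaluated alongside.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return An `experiment_report`: list with `metrics` (per-fold tibble,
#'   baseline metrics included), `summary` (mean and SD across folds),
#'   `selected_features` (per fold), `models`, `config` and provenance
#'   (`seed`, `config_hash`, `catalog_version`).
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", what, conditionMessage(e))
    })
  }

  records <- stage("simulate", {
    config$records %||% generate_dataset(
      config$n_records, prevalence = config$prevalence, seed = config$seed,
      duration_s = config$duration_s, noise_sd = config$noise_sd
    )
  })
  n <- length(records)
  say("dataset: %d records", n)

  Y_all <- label_matrix(records)
  keep_lbl <- colSums(Y_all) > 0
  Y_all <- Y_all[, keep_lbl, drop = FALSE]

  fids <- stage("detect", purrr::map(records, find_fiducials,
                                     lead = config$lead))
  feats <- stage("extract", {
    purrr::map_dfr(seq_along(records), function(i) {
      v <- extract_all(records[[i]], lead = config$lead,
                       fiducials = fids[[i]])
      tibble::as_tibble_row(c(list(record_id = records[[i]]$record_id),
                              as.list(v)))
    })
  })
  say("features: %d x %d", nrow(feats), ncol(feats) - 1)

  raw_mats <- NULL # built lazily per fold on the selected attributes
  splits <- split_dataset(Y_all, policy = config$split_policy,
                          train_frac = config$train_frac,
                          cv_folds = config$cv_folds, seed = config$seed)

  fold_metrics <- list()
  fold_selected <- list()
  models <- list()
  for (f in seq_along(splits)) {
    tr <- splits[[f]]$train
    te <- splits[[f]]$test
    say("fold %d: %d train / %d test", f, length(tr), length(te))

    Xtbl <- dplyr::select(feats, -"record_id")
    Xtr_raw <- as.matrix(impute_features(Xtbl[tr, ], reference = Xtbl[tr, ]))
    std <- standardize_columns(Xtr_raw)

    selected <- if (config$selection_enabled) {
      fit <- stage("select", mlfs_fit(
        std$X, Y_all[tr, , drop = FALSE],
        alpha = config$alpha, beta = config$beta,
        gamma1 = config$gamma1, gamma2 = config$gamma2,
        max_iter = 300, tol = 1e-6, seed = config$seed
      ))
      select_top_k(fit, min(config$k_select, ncol(std$X)))
    } else {
      feature_catalog()$name
    }
    fold_selected[[f]] <- selected

    feat_mat <- as.matrix(dplyr::select(feats, -"record_id"))
    mats <- stage("window", purrr::map(seq_along(records), function(i) {
      build_window_matrix(records[[i]], selected,
                          window_length_s = config$window_length_s,
                          stride_s = config$stride_s,
                          lead = config$lead, fiducials = fids[[i]],
                          record_features = feat_mat[i, ])
    }))
    zp <- fit_zparams(mats[tr])
    mats <- purrr::map(mats, apply_zparams, zparams = zp)

    net <- network_config(ncol(Y_all), input_channels = 1L + length(selected))
    tc <- train_config(learning_rate = config$learning_rate,
                       batch_size = config$batch_size,
                       epochs = config$epochs, seed = config$seed + f)
    model <- stage("train", cnn_gru_train(mats[tr], Y_all[tr, , drop = FALSE],
                                          config = net, tc = tc))
    models[[f]] <- model

    Y_pred <- stats::predict(model, mats[te], threshold = config$threshold)
    rep_f <- evaluate_multilabel(Y_all[te, , drop = FALSE], Y_pred)
    base_pred <- .majority_predict(Y_all[tr, , drop = FALSE], length(te))
    rep_b <- evaluate_multilabel(Y_all[te, , drop = FALSE], base_pred)
    fold_metrics[[f]] <- dplyr::bind_rows(
      dplyr::mutate(tibble::as_tibble(rep_f), fold = f, model = "cnn_gru",
                    .before = 1),
      dplyr::mutate(tibble::as_tibble(rep_b), fold = f, model = "majority",
                    .before = 1)
    )
  }

  metrics <- dplyr::bind_rows(fold_metrics)
  summary_tbl <- metrics |>
    tidyr::pivot_longer(-c("fold", "model"), names_to = "metric") |>
    dplyr::group_by(.data$model, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")

  structure(
    list(metrics = metrics, summary = summary_tbl,
         selected_features = fold_selected, models = models,
         features = feats, config = config,
         provenance = list(
           seed = config$seed,
           config_hash = rlang::hash(config[setdiff(names(config), "records")]),
           catalog_version = rlang::hash(feature_catalog()),
           n_records = n
         )),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d records, %d fold(s), seed %d\n",
              x$provenance$n_records, length(x$models), x$provenance$seed))
  s <- dplyr::filter(x$summary, .data$model == "cnn_gru",
                     .data$metric %in% c("accuracy", "hamming_loss",
                                         "jaccard", "f1"))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s %.3f +/- %.3f\n", s$metric[i], s$mean[i],
                ifelse(is.na(s$sd[i]), 0, s$sd[i])))
  }
  invisible(x)
}

#' Tidy an experiment report
#'
#' @param x An `experiment_report`.
#' @param ... Unused.
#' @return The per-fold metric tibble (models and baseline).
#' @method tidy experiment_report
#' @export
tidy.experiment_report <- function(x, ...) x$metrics

#' Glance at an experiment report
#'
#' @param x An `experiment_report`.
#' @param ... Unused.
#' @return One-row tibble of fold-averaged classifier metrics.
#' @method glance experiment_report
#' @export
glance.experiment_report <- function(x, ...) {
  x$metrics |>
    dplyr::filter(.data$model == "cnn_gru") |>
    dplyr::select(-"fold", -"model") |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean))
}

#' Plot fold metrics of an experiment
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot object comparing classifier and baseline across folds.
#' @method autoplot experiment_report
#' @export
autoplot.experiment_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$metrics, -c("fold", "model"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~fold) +
    ggplot2::coord_flip() +
    ggplot2::labs(title = "Multi-label metrics per fold", x = NULL) +
    ggplot2::theme_minimal()
}
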