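# Training, cross-validation, metrics and the optimizer grid.

#' Training configuration
#'
#' @param optimizer one of `"adagrad"`, `"adam"`, `"nag"`, `"rmsprop"`,
#'   `"sgd"`. NAG is SGD with Nesterov momentum 0.9.
#' @param learning_rate initial learning rate (> 0).
#' @param decay per-update inverse-time learning-rate decay.
#' @param batch_size minibatch size (default 16).
#' @param epochs training epochs (default 30; 0 returns an untrained model).
#' @param k_folds folds for [crossvalidate()] (default 10).
#' @param augment an [augment_config()] applied during training only, or
#'   `NULL` for none.
#' @param seed integer seed governing initialization, shuffling, dropout and
#'   augmentation draws.
#' @param standardize_targets z-score ages on the training set internally
#'   (inverted at prediction); keeps the regression head well-scaled at small
#'   learning rates.
#' @param normalize_input apply foreground z-scoring to every input volume.
#' @return an object of class `train_config`.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 0.001,
                         decay = 0.0003, batch_size = 16L, epochs = 30L,
                         k_folds = 10L, augment = NULL, seed = 1L,
                         standardize_targets = TRUE, normalize_input = TRUE) {
  optimizer <- match.arg(optimizer, OPTIMIZERS)
  if (!is.numeric(learning_rate) || learning_rate <= 0) stopf("learning_rate must be > 0")
  if (!is_count(batch_size) || batch_size < 1) stopf("batch_size must be >= 1")
  if (!is_count(epochs) || epochs < 0) stopf("epochs must be >= 0")
  if (!is_count(k_folds) || k_folds < 2) stopf("k_folds must be >= 2")
  if (!is.null(augment) && !inherits(augment, "augment_config")) {
    stopf("augment must be NULL or an augment_config")
  }
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 decay = decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), k_folds = as.integer(k_folds),
                 augment = augment, seed = as.integer(seed),
                 standardize_targets = isTRUE(standardize_targets),
                 normalize_input = isTRUE(normalize_input)),
            class = "train_config")
}

#' Regression performance metrics
#'
#' MAE, RMSE and the coefficient of determination, with R^2 computed as
#' `1 - SS_res / SS_tot` about the mean of `y_true`. A zero-variance
#' `y_true` leaves R^2 undefined (`NA`) with a warning.
#'
#' @param y_true true ages (years).
#' @param y_pred predicted ages (years), same length.
#' @return an object of class `metrics`: list with `mae`, `rmse`, `r2`.
#' @examples
#' compute_metrics(c(2, 4, 6), c(3, 4, 5))  # mae 2/3, rmse sqrt(2/3), r2 0.75
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stopf("length mismatch: %d true vs %d predicted", length(y_true), length(y_pred))
  }
  if (length(y_true) == 0L) stopf("empty input")
  e <- y_pred - y_true
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero-variance y_true: R^2 undefined", call. = FALSE)
    NA_real_
  } else {
    1 - sum(e^2) / ss_tot
  }
  structure(list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)), r2 = r2),
            class = "metrics")
}

#' @export
print.metrics <- function(x, ...) {
  cat(sprintf("MAE %.3f years | RMSE %.3f years | R^2 %s\n",
              x$mae, x$rmse,
              if (is.na(x$r2)) "NA" else sprintf("%.3f", x$r2)))
  invisible(x)
}

age_bins <- function(ages, width) floor((ages - min(ages)) / width)

#' Age-stratified train/test split
#'
#' Within each age bin, `round(test_fraction * n_bin)` members go to the
#' test set, giving both sets an (approximately) identical age distribution.
#'
#' @param records a `subject_cohort` or list of [subject_record]s.
#' @param test_fraction fraction per bin assigned to test.
#' @param age_bin_width stratification bin width in years (default 5).
#' @param seed integer seed for the within-bin draw.
#' @return list with `train` and `test` record lists and the index vectors
#'   `train_idx`, `test_idx` (a disjoint, exhaustive partition).
#' @export
stratified_split <- function(records, test_fraction, age_bin_width = 5,
                             seed = 1L) {
  records <- as_records(records)
  if (!length(records)) stopf("empty cohort")
  if (test_fraction < 0 || test_fraction > 1) stopf("test_fraction must lie in [0, 1]")
  ages <- record_ages(records)
  bins <- age_bins(ages, age_bin_width)
  test_idx <- integer(0)
  with_seed_(seed, {
    for (b in unique(bins)) {
      members <- which(bins == b)
      k <- round(test_fraction * length(members))
      if (k > 0) test_idx <- c(test_idx, sample(members, k))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(records), test_idx)
  list(train = records[train_idx], test = records[test_idx],
       train_idx = train_idx, test_idx = test_idx)
}

#' Train a predictor
#'
#' Minibatch gradient descent on mean-squared error with the configured
#' optimizer. Deterministic for a fixed seed. Augmentation (when configured)
#' is applied per sample per epoch during training only; evaluation always
#' sees unaugmented volumes. Aborts with diagnostics if the loss turns
#' non-finite.
#'
#' @param spec a [model_spec].
#' @param train_records training records with attached volumes.
#' @param config a [train_config].
#' @return a trained predictor; `$history` holds the per-epoch mean loss
#'   (length = epochs).
#' @export
train <- function(spec, train_records, config = train_config()) {
  train_records <- as_records(train_records)
  if (!length(train_records)) stopf("no training records")
  if (!inherits(config, "train_config")) stopf("config must be a train_config")

  vols <- lapply(train_records, function(r) r$volume)
  ages <- record_ages(train_records)
  sexes <- record_sexes(train_records)
  n <- length(train_records)

  tmean <- if (config$standardize_targets) mean(ages) else 0
  tsd <- if (config$standardize_targets) max(stats::sd(ages), 1e-8) else 1
  if (!is.finite(tsd)) tsd <- 1     # single-subject training set
  targets <- (ages - tmean) / tsd

  pred <- build_model(spec, init_seed = derive_seed(config$seed, 1L))
  pred$target_norm <- c(mean = tmean, sd = tsd)
  pred$normalize_input <- config$normalize_input
  pred$fingerprint$train_seed <- config$seed
  pred$fingerprint$config_hash <- paste(config$optimizer, config$learning_rate,
                                        config$decay, config$batch_size,
                                        config$epochs, sep = "|")

  # plain forward inputs, normalized once (augmented samples re-normalized)
  xfull <- stack_volumes(lapply(vols, `[[`, "data"), spec,
                         config$normalize_input)
  sexmat <- sex_onehot(sexes)

  if (config$epochs == 0L) {
    pred$history <- numeric(0)
    return(pred)
  }

  opt <- make_optimizer(config$optimizer, config$learning_rate, config$decay)
  state <- list()
  history <- numeric(config$epochs)

  with_seed_(derive_seed(config$seed, 2L), {
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- order_idx[start:min(start + config$batch_size - 1L, n)]
        b <- length(idx)
        x <- xfull[, idx, drop = FALSE]
        if (!is.null(config$augment)) {
          for (j in seq_len(b)) {
            ds <- sample.int(2147483647L, 1L)
            av <- augment(vols[[idx[j]]], config$augment, draw_seed = ds)
            if (!identical(av, vols[[idx[j]]])) {
              a <- av$data
              if (config$normalize_input) a <- normalize_array(a)
              x[, j] <- as.numeric(a)
            }
          }
        }
        fp <- forward_pass(pred, x, sexmat[idx, , drop = FALSE], b,
                           training = TRUE)
        pred <- fp$pred
        err <- fp$y - targets[idx]
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          stopf("training diverged: non-finite loss at epoch %d (optimizer %s, lr %g, decay %g)",
                epoch, config$optimizer, config$learning_rate, config$decay)
        }
        losses <- c(losses, loss)
        bp <- backward_pass(pred, fp$caches, 2 * err / b, b)
        st <- optim_step(opt, pred, bp$grads, state)
        opt <- st$opt; pred <- st$pred; state <- st$state
      }
      history[epoch] <- mean(losses)
    }
  })
  pred$history <- history
  pred
}

make_folds <- function(records, k, age_bin_width, seed) {
  ages <- record_ages(records)
  n <- length(records)
  if (k > n) stopf("k_folds (%d) exceeds number of records (%d)", k, n)
  bins <- age_bins(ages, age_bin_width)
  fold <- integer(n)
  with_seed_(seed, {
    counter <- 0L
    for (b in sort(unique(bins))) {
      members <- sample(which(bins == b))
      for (m in members) {
        fold[m] <- (counter %% k) + 1L
        counter <- counter + 1L
      }
    }
  })
  fold
}

#' k-fold cross-validation
#'
#' Folds are a disjoint, exhaustive partition stratified by 5-year age bins.
#' Each fold's model trains on the other k-1 folds (with a fold-derived
#' seed) and is evaluated on the held-out fold.
#'
#' @param spec a [model_spec].
#' @param records cohort with attached volumes.
#' @param config a [train_config]; `config$k_folds` sets k.
#' @param age_bin_width stratification width in years.
#' @return an object of class `cv_report`: per-fold `metrics` list, a
#'   `summary` data frame (mean and sd of each metric) and the fold
#'   assignment vector.
#' @export
crossvalidate <- function(spec, records, config = train_config(),
                          age_bin_width = 5) {
  records <- as_records(records)
  k <- config$k_folds
  fold <- make_folds(records, k, age_bin_width, derive_seed(config$seed, 3L))
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    cfg_f <- config
    cfg_f$seed <- derive_seed(config$seed, 100L + f)
    model <- train(spec, records[fold != f], cfg_f)
    heldout <- records[fold == f]
    pred_ages <- predict(model, heldout)
    folds[[f]] <- compute_metrics(record_ages(heldout), pred_ages)
  }
  mets <- c("mae", "rmse", "r2")
  vals <- sapply(mets, function(m) vapply(folds, `[[`, numeric(1), m))
  summary <- data.frame(
    metric = mets,
    mean = colMeans(vals),
    sd = apply(vals, 2, stats::sd),
    row.names = NULL
  )
  structure(list(folds = folds, summary = summary, fold_assignment = fold),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds\n", length(x$folds)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Optimizer / learning-rate grid search
#'
#' Runs [crossvalidate()] for every combination of the five optimizers and
#' the two (learning rate, decay) pairs of the tuning protocol — ten cells —
#' and selects the best row by mean cross-validated MAE.
#'
#' @param spec a [model_spec].
#' @param records cohort with attached volumes.
#' @param base_config a [train_config]; its optimizer/lr/decay are
#'   overridden cell by cell.
#' @param optimizers optimizers to sweep (default all five).
#' @param lr_decay list of `c(learning_rate, decay)` pairs (default the two
#'   protocol pairs).
#' @return an object of class `grid_report`: `table` (one row per cell with
#'   metric summaries), `reports` (the cv_report per cell) and `best`
#'   (row index of the argmin mean MAE).
#' @export
optimizer_grid <- function(spec, records, base_config = train_config(),
                           optimizers = OPTIMIZERS,
                           lr_decay = list(c(0.01, 0.003), c(0.001, 0.0003))) {
  rows <- list(); reports <- list()
  for (opt in optimizers) {
    for (ld in lr_decay) {
      cfg <- base_config
      cfg$optimizer <- opt
      cfg$learning_rate <- ld[1]
      cfg$decay <- ld[2]
      rep_ <- tryCatch(crossvalidate(spec, records, cfg),
                       error = function(e) {
                         stopf("grid cell (%s, lr=%g, decay=%g) failed: %s",
                               opt, ld[1], ld[2], conditionMessage(e))
                       })
      s <- rep_$summary
      rows[[length(rows) + 1L]] <- data.frame(
        optimizer = opt, learning_rate = ld[1], decay = ld[2],
        mae_mean = s$mean[s$metric == "mae"], mae_sd = s$sd[s$metric == "mae"],
        rmse_mean = s$mean[s$metric == "rmse"], rmse_sd = s$sd[s$metric == "rmse"],
        r2_mean = s$mean[s$metric == "r2"], r2_sd = s$sd[s$metric == "r2"]
      )
      reports[[length(reports) + 1L]] <- rep_
    }
  }
  table <- do.call(rbind, rows)
  structure(list(table = table, reports = reports,
                 best = which.min(table$mae_mean)),
            class = "grid_report")
}

#' @export
print.grid_report <- function(x, ...) {
  print(x$table, digits = 4)
  cat(sprintf("best: row %d (%s, lr=%g) by mean MAE\n", x$best,
              x$table$optimizer[x$best], x$table$learning_rate[x$best]))
  invisible(x)
}
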