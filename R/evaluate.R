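# Stratified repeated k-fold evaluation with in-fold band selection, and
# the paired one-sided test used to compare decoders.

#' Stratified fold assignment
#'
#' Assigns each trial to one of `k` folds, preserving the class
#' proportions of `labels` in every fold to within one trial. Uses the
#' current RNG stream.
#'
#' @param labels Class label per trial.
#' @param k Number of folds; every class must have at least `k` members.
#' @return Integer fold id (1..k) per trial.
#' @export
stratified_folds <- function(labels, k) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  tab <- table(labels)
  if (any(tab < k))
    stop("class smaller than k: ", names(tab)[which.min(tab)],
         " has ", min(tab), " trial(s)")
  folds <- integer(length(labels))
  for (cls in names(tab)) {
    idx <- which(labels == as.integer(cls))
    idx <- sample(idx)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Repeated stratified k-fold evaluation
#'
#' The evaluation protocol of the pipeline: per repeat, a fresh stratified
#' `k`-fold partition; each fold serves once as the test set, the next
#' fold as the validation set, and the remaining `k - 2` folds as the
#' training set (for `k = 2` the model factory receives no explicit
#' validation set and holds out its own). The model factory is called
#' inside every fold with training data only, so any data-driven band
#' selection it performs never sees the test trials. The reported accuracy
#' is the mean over folds, then over repeats.
#'
#' @param model_factory A function `(train, val)` of [trial_set()]s
#'   returning a list with at least `predict`, a function mapping a
#'   `trial_set` to predicted labels. See [pacnet_factory()],
#'   [baseline_factory()], [majority_factory()], [oracle_factory()].
#' @param trials A [trial_set()].
#' @param k Folds (default 10).
#' @param repeats Repeats with fresh shuffling (default 5).
#' @param seed Base seed.
#' @return An object of class `cv_result`: a data frame of per-repeat,
#'   per-fold test accuracies plus `mean` and `sd` summaries.
#' @export
evaluate_repeated_kfold <- function(model_factory, trials, k = 10L,
                                    repeats = 5L, seed = 1L) {
  stopifnot(inherits(trials, "trial_set"), is.function(model_factory))
  set.seed(seed)
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    folds <- stratified_folds(trials$labels, k)
    for (fold_i in seq_len(k)) {
      test_idx <- which(folds == fold_i)
      if (k > 2L) {
        val_fold <- (fold_i %% k) + 1L
        val_idx <- which(folds == val_fold)
        train_idx <- which(folds != fold_i & folds != val_fold)
        val_ts <- trials[val_idx]
      } else {
        val_ts <- NULL
        train_idx <- which(folds != fold_i)
      }
      fit <- model_factory(trials[train_idx], val_ts)
      pred <- fit$predict(trials[test_idx])
      acc <- mean(as.integer(pred) == trials$labels[test_idx])
      rows[[length(rows) + 1L]] <-
        data.frame(rep = rep_i, fold = fold_i, accuracy = acc)
    }
  }
  df <- do.call(rbind, rows)
  structure(list(accuracies = df,
                 mean = mean(df$accuracy),
                 sd = stats::sd(df$accuracy),
                 k = k, repeats = repeats, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d repeat(s) x %d folds, accuracy %.4f +/- %.4f>\n",
              x$repeats, x$k, x$mean, x$sd))
  invisible(x)
}

#' Paired one-sided t-test on matched accuracies
#'
#' Tests whether the mean of `a - b` is greater than zero (the hypothesis
#' that decoder `a` outperforms its competitor `b`), pairing by fold.
#'
#' @param a,b Matched per-fold accuracy vectors of equal length (>= 2).
#' @return The one-sided p-value.
#' @export
paired_onesided_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch between paired samples")
  if (length(a) < 2L) stop("need at least 2 paired values")
  d <- a - b
  if (stats::sd(d) == 0) stop("zero-variance differences")
  stats::t.test(a, b, paired = TRUE, alternative = "greater")$p.value
}

#' Compare two cross-validation results
#'
#' Pairs the per-(repeat, fold) accuracies of two [cv_result()]s obtained
#' on the same partitions (same `seed`, `k`, `repeats`) and applies
#' [paired_onesided_ttest()] for the hypothesis that the first outperforms
#' the second.
#'
#' @param a,b `cv_result` objects.
#' @return A list with `mean_diff` and `p_value`.
#' @export
compare_cv <- function(a, b) {
  stopifnot(inherits(a, "cv_result"), inherits(b, "cv_result"))
  key_a <- paste(a$accuracies$rep, a$accuracies$fold)
  key_b <- paste(b$accuracies$rep, b$accuracies$fold)
  if (!identical(key_a, key_b)) stop("results are not matched fold-by-fold")
  list(mean_diff = a$mean - b$mean,
       p_value = paired_onesided_ttest(a$accuracies$accuracy,
                                       b$accuracies$accuracy))
}

#' Model factories for the evaluation harness
#'
#' Each factory returns a function `(train, val)` suitable for
#' [evaluate_repeated_kfold()]:
#'
#' * `pacnet_factory`: fits the ERPAC band selection on the training
#'   trials, synthesizes the mixed filter bank, and trains a split-branch
#'   PACNet; the stored selection is applied to the test trials at predict
#'   time (no test leakage).
#' * `baseline_factory`: the no-PAC ablation control — a single-branch
#'   decoder on the broadband 70-200 Hz bandpass.
#' * `majority_factory`: predicts the most frequent training label
#'   (ties toward the smaller label).
#' * `oracle_factory`: returns the true test labels (harness check only).
#'
#' @param config A [default_config()]-style configuration.
#' @return A factory function.
#' @export
pacnet_factory <- function(config = default_config()) {
  config <- validate_config(config)
  function(train, val = NULL) {
    sel <- erpac_fbs(train, config)
    fb <- build_mixed_signals(train, sel)
    d <- dim(fb$data)
    dc <- config$decoder
    dc$n_classes <- length(unique(train$labels))
    model <- build_pacnet(dc, d[2:4], seed = config$seed)
    if (!is.null(val)) {
      fbv <- build_mixed_signals(val, sel)
      model <- train_model(model, fb, x_val = fbv)
    } else {
      model <- train_model(model, fb)
    }
    list(predict = function(test)
           predict(model, build_mixed_signals(test, sel), type = "class"),
         model = model, selection = sel)
  }
}

#' @rdname pacnet_factory
#' @export
baseline_factory <- function(config = default_config()) {
  config <- validate_config(config)
  hg <- high_gamma_band()
  filt <- function(ts) {
    d <- dim(ts$data)
    X <- matrix(aperm(ts$data, c(3L, 2L, 1L)), nrow = d[3])
    Y <- bandpass(X, ts$fs, hg, config$filter$order)
    arr <- aperm(array(Y, c(d[3], d[2], d[1])), c(3L, 2L, 1L))
    dim(arr) <- c(d[1], 1L, d[2], d[3])
    arr
  }
  function(train, val = NULL) {
    dc <- config$decoder
    dc$n_classes <- length(unique(train$labels))
    d <- dim(train$data)
    model <- build_baseline(dc, d[2:3], seed = config$seed)
    xtr <- filt(train)
    if (!is.null(val)) {
      model <- train_model(model, xtr, y = train$labels,
                           x_val = filt(val), y_val = val$labels)
    } else {
      model <- train_model(model, xtr, y = train$labels)
    }
    list(predict = function(test)
           predict(model, filt(test), type = "class"),
         model = model)
  }
}

#' @rdname pacnet_factory
#' @export
majority_factory <- function() {
  function(train, val = NULL) {
    tab <- table(train$labels)
    lab <- as.integer(names(tab)[which.max(tab)])
    list(predict = function(test) rep(lab, n_trials(test)))
  }
}

#' @rdname pacnet_factory
#' @export
oracle_factory <- function() {
  function(train, val = NULL) {
    list(predict = function(test) test$labels)
  }
}
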