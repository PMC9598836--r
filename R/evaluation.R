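#' Concordance index for uncensored survival data
#'
#' Over every unordered pair of samples with strictly different survival
#' times, a pair is concordant when the longer-lived sample has the
#' higher score (1), tied when the scores are equal (0.5), discordant
#' otherwise (0); the C-index is the total over the number of comparable
#' pairs.  0.5 is random ordering, 1.0 perfect.
#'
#' @param pred Numeric vector of survival scores (higher = longer
#'   predicted survival).
#' @param time Positive observed survival times (uncensored).
#' @return Scalar in `[0, 1]`.
#' @export
concordance_index <- function(pred, time) {
  if (length(pred) < 2L) stop("concordance index needs at least 2 samples")
  stopifnot(length(pred) == length(time), all(time > 0))
  comp <- outer(time, time, "<")  # [i, j]: time_i < time_j, each pair once
  n_comp <- sum(comp)
  if (n_comp == 0L) stop("no comparable pairs: all survival times are equal")
  dpred <- outer(pred, pred, "-") # [i, j]: pred_i - pred_j
  score <- sum(comp & (dpred < 0)) + 0.5 * sum(comp & (dpred == 0))
  score / n_comp
}

#' Repeated K-fold cross-validation splits
#'
#' For each of `repeats` independent repetitions, the samples are
#' randomly partitioned into `k` folds of near-equal size (differing by
#' at most one); each fold in turn is the test set.  With the reference
#' protocol (n = 125, k = 5, 20 repeats) this gives 100 experiments with
#' 100 training and 25 test samples each.
#'
#' @param sample_ids Character vector of unique sample IDs.
#' @param k Folds per repeat (>= 2).
#' @param repeats Number of repetitions.
#' @param seed Integer seed; the full split list is reproducible.
#' @return List of `repeats * k` splits, each a list with `repeat_idx`,
#'   `fold`, `train`, `test` (ID vectors).
#' @export
make_cv_splits <- function(sample_ids, k = 5L, repeats = 20L, seed = 1L) {
  n <- length(sample_ids)
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("fewer samples (", n, ") than folds (", k, ")")
  if (anyDuplicated(sample_ids)) stop("sample IDs must be unique")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  splits <- vector("list", repeats * k)
  s <- 0L
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, 404L, r))
    fold_of <- sample(rep(seq_len(k), length.out = n))
    for (f in seq_len(k)) {
      s <- s + 1L
      splits[[s]] <- list(repeat_idx = r, fold = f,
                          train = sample_ids[fold_of != f],
                          test = sample_ids[fold_of == f])
    }
  }
  splits
}

#' Run the full repeated cross-validation experiment
#'
#' For every split: fit the preprocessing pipeline on the training
#' partition only, transform both partitions with it, train a freshly
#' initialized network (per-split seed derived from `seed`, repeat and
#' fold), score the held-out samples and compute the concordance index.
#' Raw (unpreprocessed) inputs are required so that the leakage-free
#' contract is exercised on every split.
#'
#' An external learner can be evaluated under the identical protocol by
#' supplying `predict_fun`, which then replaces the network.
#'
#' @param mrna,mirna Raw-scale expression matrices (genes x samples).
#' @param clinical Clinical data.frame with `sample_id`, or `NULL`.
#' @param survival data.frame with `sample_id`, `time`, `event`; only
#'   `event == 1` samples enter the cohort.
#' @param config A [multipen_config()].
#' @param k,repeats Cross-validation geometry (default 5 x 20).
#' @param seed Master seed for splits and per-split model seeds.
#' @param predict_fun Optional `function(train_data, train_time,
#'   test_data)` returning test scores, evaluated in place of the
#'   network (`train_data`/`test_data` are preprocessed modality lists).
#' @param standardize Z-score kept genes with training statistics inside
#'   each split's preprocessor (see [fit_preprocessor()]).
#' @param collect_attention Also average per-gene attention over the
#'   split models (evaluated on each split's full preprocessed cohort).
#' @param keep_preprocessors Store each split's fitted preprocessor,
#'   serialized to its JSON form, in the result (used to verify the
#'   leakage-free contract by hashing).
#' @return An object of class `"multipen_experiment"`: per-split
#'   C-indices, their mean and sd, and provenance.
#' @export
run_experiment <- function(mrna, mirna, clinical = NULL, survival,
                           config = multipen_config(), k = 5L,
                           repeats = 20L, seed = 1L, predict_fun = NULL,
                           standardize = FALSE, collect_attention = FALSE,
                           keep_preprocessors = FALSE) {
  keep <- survival$event == 1
  survival <- survival[keep, , drop = FALSE]
  ids <- survival$sample_id
  stopifnot(all(ids %in% colnames(mrna)), all(ids %in% colnames(mirna)))
  mrna <- mrna[, ids, drop = FALSE]
  mirna <- mirna[, ids, drop = FALSE]
  if (!is.null(clinical)) {
    clinical <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  }
  time <- stats::setNames(survival$time, ids)
  splits <- make_cv_splits(ids, k = k, repeats = repeats, seed = seed)
  results <- data.frame(repeat_idx = integer(0), fold = integer(0),
                        n_train = integer(0), n_test = integer(0),
                        cindex = numeric(0))
  att_sum <- list(); att_cnt <- list()
  preps <- if (keep_preprocessors) vector("list", length(splits))
  sp_i <- 0L
  for (sp in splits) {
    sp_i <- sp_i + 1L
    if (length(sp$test) < 2L) stop("split with fewer than 2 test samples")
    tr_cl <- if (!is.null(clinical))
      clinical[match(sp$train, clinical$sample_id), , drop = FALSE]
    te_cl <- if (!is.null(clinical))
      clinical[match(sp$test, clinical$sample_id), , drop = FALSE]
    prep <- fit_preprocessor(mrna[, sp$train, drop = FALSE],
                             mirna[, sp$train, drop = FALSE],
                             tr_cl, log_base = config$log_base,
                             standardize = standardize)
    if (keep_preprocessors) {
      tf <- tempfile(fileext = ".json")
      write_preprocessor(prep, tf)
      preps[[sp_i]] <- paste(readLines(tf), collapse = "\n")
      unlink(tf)
    }
    tr_data <- predict(prep, mrna[, sp$train, drop = FALSE],
                       mirna[, sp$train, drop = FALSE], tr_cl)
    te_data <- predict(prep, mrna[, sp$test, drop = FALSE],
                       mirna[, sp$test, drop = FALSE], te_cl)
    if (is.null(predict_fun)) {
      split_seed <- derive_seed(seed, 505L, sp$repeat_idx, sp$fold)
      cfg <- config
      cfg$seed <- split_seed
      fit <- multipen(tr_data$mrna, tr_data$mirna, tr_data$clinical,
                      time = time[sp$train], config = cfg)
      scores <- predict(fit, te_data$mrna, te_data$mirna, te_data$clinical)
      if (collect_attention) {
        full_data <- predict(prep, mrna, mirna, clinical)
        reports <- compute_gene_attention(fit, full_data)
        for (layer in names(reports)) {
          rp <- reports[[layer]]
          if (is.null(att_sum[[layer]])) {
            att_sum[[layer]] <- stats::setNames(numeric(0), character(0))
            att_cnt[[layer]] <- stats::setNames(numeric(0), character(0))
          }
          new_ids <- setdiff(rp$feature_id, names(att_sum[[layer]]))
          att_sum[[layer]][new_ids] <- 0
          att_cnt[[layer]][new_ids] <- 0
          att_sum[[layer]][rp$feature_id] <-
            att_sum[[layer]][rp$feature_id] + rp$mean_attention
          att_cnt[[layer]][rp$feature_id] <-
            att_cnt[[layer]][rp$feature_id] + 1
        }
      }
    } else {
      scores <- predict_fun(tr_data, time[sp$train], te_data)
    }
    results <- rbind(results, data.frame(
      repeat_idx = sp$repeat_idx, fold = sp$fold,
      n_train = length(sp$train), n_test = length(sp$test),
      cindex = concordance_index(scores, time[sp$test])))
  }
  attention <- NULL
  if (collect_attention && length(att_sum)) {
    attention <- lapply(names(att_sum), function(layer) {
      mean_att <- att_sum[[layer]] / att_cnt[[layer]]
      make_attention_report(layer, names(mean_att), unname(mean_att))
    })
    names(attention) <- names(att_sum)
  }
  structure(list(results = results, mean_cindex = mean(results$cindex),
                 sd_cindex = stats::sd(results$cindex),
                 k = k, repeats = repeats, seed = seed, config = config,
                 attention = attention, preprocessors = preps),
            class = "multipen_experiment")
}

#' @export
print.multipen_experiment <- function(x, ...) {
  cat(sprintf("Repeated cross-validation: %d folds x %d repeats = %d experiments\n",
              x$k, x$repeats, nrow(x$results)))
  cat(sprintf("C-index: mean %.4f, sd %.4f (seed %d)\n",
              x$mean_cindex, x$sd_cindex, x$seed))
  invisible(x)
}

#' @export
summary.multipen_experiment <- function(object, ...) {
  c(mean = object$mean_cindex, sd = object$sd_cindex,
    stats::quantile(object$results$cindex, c(0.025, 0.25, 0.5, 0.75, 0.975)))
}

#' Histogram of split-level C-indices
#' @param x A `"multipen_experiment"`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.multipen_experiment <- function(x, ...) {
  graphics::hist(x$results$cindex, xlab = "C-index",
                 main = sprintf("%d experiments (mean %.3f)",
                                nrow(x$results), x$mean_cindex), ...)
  graphics::abline(v = x$mean_cindex, col = "red3", lwd = 2)
  invisible(x)
}
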