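#' Pairwise hinge ranking loss on survival times
#'
#' Over every ordered pair (i, j) whose times satisfy `time_i < time_j`
#' (strictly; tied times carry no order information and are skipped) the
#' loss contributes `max(0, margin + pred_i - pred_j)`: the
#' shorter-lived sample must score lower by at least the margin.  The
#' result is the mean over comparable pairs, 0 if there are none.
#'
#' @param pred Numeric vector of survival scores.
#' @param time Positive survival times, same length (all uncensored).
#' @param margin Non-negative margin.
#' @return Non-negative scalar.
#' @export
ranking_loss <- function(pred, time, margin = 0.1) {
  if (length(pred) < 2L) stop("ranking loss needs at least 2 samples")
  stopifnot(length(pred) == length(time), margin >= 0, all(time > 0))
  comp <- outer(time, time, "<")          # [i, j]: time_i < time_j
  if (!any(comp)) return(0)
  viol <- pmax(0, margin + outer(pred, pred, "-"))
  sum(viol[comp]) / sum(comp)
}

# d(ranking_loss)/d(pred): +1/P at the short-lived side of each active
# pair, -1/P at the long-lived side (subgradient 0 on the hinge boundary).
ranking_loss_grad <- function(pred, time, margin = 0.1) {
  comp <- outer(time, time, "<")
  P <- sum(comp)
  if (P == 0L) return(numeric(length(pred)))
  active <- comp & (margin + outer(pred, pred, "-") > 0)
  (rowSums(active) - colSums(active)) / P
}

#' Partition sample indices into random mini-batches
#'
#' Random partition of `1..n` into `k` disjoint sets whose sizes differ
#' by at most one, drawn from the current RNG stream.
#'
#' @param n Number of samples.
#' @param k Number of mini-batches.
#' @return List of `k` integer index vectors covering `1..n`.
#' @export
make_minibatches <- function(n, k) {
  if (k > n) stop("cannot form ", k, " mini-batches from ", n, " samples")
  stopifnot(k >= 1)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(k), times = sizes))
}

zeros_like <- function(tr) {
  if (is.list(tr)) lapply(tr, zeros_like) else tr * 0
}

tree_mapn <- function(trees, f) {
  if (is.list(trees[[1L]])) {
    out <- vector("list", length(trees[[1L]]))
    names(out) <- names(trees[[1L]])
    for (k in seq_along(trees[[1L]])) {
      out[[k]] <- tree_mapn(lapply(trees, `[[`, k), f)
    }
    out
  } else {
    do.call(f, trees)
  }
}

# freeze linear-map biases when config$use_bias is FALSE (layer-norm
# shifts stay trainable; they are normalization parameters, not biases)
zero_bias_grads <- function(tr) {
  if (!is.list(tr)) return(tr)
  keys <- names(tr)
  for (k in seq_along(tr)) {
    key <- if (is.null(keys)) "" else keys[k]
    if (key %in% c("b1", "b2", "bs", "b") && !is.list(tr[[k]])) {
      tr[[k]][] <- 0
    } else {
      tr[[k]] <- zero_bias_grads(tr[[k]])
    }
  }
  tr
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_mapn(list(state$m, grad),
                       function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_mapn(list(state$v, grad),
                       function(v, g) beta2 * v + (1 - beta2) * g^2)
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  par <- tree_mapn(list(par, state$m, state$v), function(p, m, v) {
    p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
  })
  list(par = par, state = state)
}

#' Train a prognosis network with the ranking objective
#'
#' Runs `epochs x minibatches` Adam steps.  Within each mini-batch the
#' pairwise ranking loss is applied to the ensemble-mean score and, with
#' equal weight, to each sub-model's own score:
#' `L = (RL(mean) + sum_i RL(pred_i)) / (n + 1)`.  Sub-models train
#' jointly through the shared attention layers.  Mini-batch order and
#' dropout are drawn from a stream seeded by `config$seed`, so identical
#' seed, config and data give identical final weights.
#'
#' @param model A `"multipen_model"` from [init_model()].
#' @param data List of preprocessed matrices `mrna`, `mirna`, optionally
#'   `clinical` (features x samples, shared sample order).
#' @param time Positive survival times aligned with the sample columns
#'   (uncensored cohort).
#' @param config A [multipen_config()]; defaults to the model's own.
#' @return List with `model` (trained, in eval mode) and `history`, an
#'   epochs x minibatches matrix of batch losses.
#' @export
train <- function(model, data, time, config = model$config) {
  check_data_dims(model, data)
  n <- ncol(data$mrna)
  stopifnot(length(time) == n, all(time > 0))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(derive_seed(config$seed, 303L))
  params <- model[c("attention", "submodels")]
  state <- list(t = 0L, m = zeros_like(params), v = zeros_like(params))
  history <- matrix(NA_real_, config$epochs, config$minibatches,
                    dimnames = list(paste0("epoch", seq_len(config$epochs)),
                                    paste0("batch", seq_len(config$minibatches))))
  n_sub <- length(model$submodels)
  for (epoch in seq_len(config$epochs)) {
    batches <- make_minibatches(n, config$minibatches)
    for (b in seq_along(batches)) {
      idx <- batches[[b]]
      bdata <- list(mrna = data$mrna[, idx, drop = FALSE],
                    mirna = data$mirna[, idx, drop = FALSE],
                    clinical = if (!is.null(data$clinical))
                      data$clinical[, idx, drop = FALSE])
      btime <- time[idx]
      model$attention <- params$attention
      model$submodels <- params$submodels
      fw <- model_forward(model, bdata, mode = "train",
                          dropout = config$dropout)
      loss_ens <- ranking_loss(fw$pred, btime, config$margin)
      loss_sub <- apply(fw$sub_preds, 1L, ranking_loss, time = btime,
                        margin = config$margin)
      loss <- (loss_ens + sum(loss_sub)) / (n_sub + 1)
      if (!is.finite(loss)) {
        stop("non-finite loss at epoch ", epoch, ", batch ", b)
      }
      history[epoch, b] <- loss
      g_ens <- ranking_loss_grad(fw$pred, btime, config$margin)
      dsub <- matrix(rep(g_ens / n_sub, each = n_sub), n_sub)
      for (i in seq_len(n_sub)) {
        dsub[i, ] <- dsub[i, ] +
          ranking_loss_grad(fw$sub_preds[i, ], btime, config$margin)
      }
      dsub <- dsub / (n_sub + 1)
      grads <- model_backward(model, fw, dsub)
      if (!config$use_bias) grads <- zero_bias_grads(grads)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$par
      state <- upd$state
    }
  }
  model$attention <- params$attention
  model$submodels <- params$submodels
  list(model = model, history = history)
}

#' Fit a multi-omics prognosis estimation network
#'
#' The central fitting function: initializes a network over the given
#' (already preprocessed) mRNA, miRNA and clinical blocks and trains it
#' to rank uncensored survival times.  The returned object supports
#' `print`, `summary`, `predict`, `coef` and `plot`.
#'
#' @param mrna,mirna Preprocessed (log-scale) expression matrices,
#'   features x samples, with rownames and a shared sample column order.
#' @param clinical Encoded clinical feature matrix (features x samples)
#'   or `NULL`.
#' @param time Positive survival times, one per sample column.
#' @param config A [multipen_config()].
#' @param seed Seed for initialization and training; defaults to
#'   `config$seed`.
#' @return An object of class `"multipen"`.
#' @examples
#' set.seed(1)
#' co <- generate_cohort(cohort_spec(n_samples = 40, p_mrna = 30,
#'                                   p_mirna = 10, seed = 1))
#' prep <- fit_preprocessor(co$mrna, co$mirna, co$clinical)
#' dat <- predict(prep, co$mrna, co$mirna, co$clinical)
#' cfg <- multipen_config(n_submodels = 2, epochs = 2, seed = 1)
#' fit <- multipen(dat$mrna, dat$mirna, dat$clinical,
#'                 time = co$survival$time, config = cfg)
#' fit
#' @export
multipen <- function(mrna, mirna, clinical = NULL, time,
                     config = multipen_config(), seed = config$seed) {
  stopifnot(is.matrix(mrna), is.matrix(mirna))
  config$seed <- as.integer(seed)
  model <- init_model(config, nrow(mrna), nrow(mirna),
                      if (is.null(clinical)) 0L else nrow(clinical),
                      seed = seed)
  data <- list(mrna = mrna, mirna = mirna, clinical = clinical)
  tr <- train(model, data, time, config)
  structure(list(model = tr$model, history = tr$history, config = config,
                 feature_ids = list(mrna = rownames(mrna),
                                    mirna = rownames(mirna),
                                    clinical = rownames(clinical)),
                 n_samples = ncol(mrna), seed = as.integer(seed),
                 call = match.call()),
            class = "multipen")
}

#' @export
print.multipen <- function(x, ...) {
  cat("Multi-omics prognosis estimation network\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  p <- x$model$p
  cat(sprintf("Features: %d mRNA + %d miRNA + %d clinical (fused %d)\n",
              p["mrna"], p["mirna"], p["clinical"], x$model$d_fused))
  cat(sprintf("Ensemble of %d sub-models; trained on %d samples, final loss %.4f\n",
              length(x$model$submodels), x$n_samples,
              x$history[nrow(x$history), ncol(x$history)]))
  invisible(x)
}

#' @export
summary.multipen <- function(object, ...) {
  per_epoch <- rowMeans(object$history)
  n_par <- sum(rapply(object$model$attention, length, how = "unlist")) +
    sum(rapply(object$model$submodels, length, how = "unlist"))
  out <- list(config = object$config,
              p = object$model$p,
              n_parameters = n_par,
              loss_first_epoch = per_epoch[1L],
              loss_last_epoch = per_epoch[length(per_epoch)],
              per_epoch_loss = per_epoch)
  class(out) <- "summary.multipen"
  out
}

#' @export
print.summary.multipen <- function(x, ...) {
  print(x$config)
  cat(sprintf("Trainable parameters: %d\n", x$n_parameters))
  cat(sprintf("Mean batch loss: %.4f (first epoch) -> %.4f (last epoch)\n",
              x$loss_first_epoch, x$loss_last_epoch))
  invisible(x)
}

#' Predict survival scores from a fitted network
#'
#' @param object A fitted `"multipen"`.
#' @param mrna,mirna,clinical New data, preprocessed identically to the
#'   training data (features x samples).
#' @param type `"ensemble"` for the averaged score (default) or
#'   `"submodels"` for the n_submodels x n matrix.
#' @param ... Unused.
#' @return Named numeric vector of scores in (-1, 1), or a matrix for
#'   `type = "submodels"`.
#' @export
predict.multipen <- function(object, mrna, mirna, clinical = NULL,
                             type = c("ensemble", "submodels"), ...) {
  type <- match.arg(type)
  check_feature_ids(object$feature_ids$mrna, rownames(mrna), "mRNA")
  check_feature_ids(object$feature_ids$mirna, rownames(mirna), "miRNA")
  out <- ensemble_predict(object$model,
                          list(mrna = mrna, mirna = mirna,
                               clinical = clinical))
  if (type == "ensemble") stats::setNames(out$pred, colnames(mrna))
  else out$sub_preds
}

check_feature_ids <- function(fitted, given, layer) {
  if (!is.null(fitted) && !is.null(given) && !identical(fitted, given)) {
    stop(layer, " feature IDs do not match the fitted model ",
         "(same genes, same order, required)")
  }
  invisible(TRUE)
}

#' @export
coef.multipen <- function(object, ...) {
  object$model[c("attention", "submodels")]
}

#' Plot the training loss trajectory
#' @param x A fitted `"multipen"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.multipen <- function(x, ...) {
  losses <- as.vector(t(x$history))
  graphics::plot(seq_along(losses), losses, type = "l",
                 xlab = "gradient step", ylab = "ranking loss",
                 main = "Training loss", ...)
  graphics::abline(v = seq(0, length(losses), by = ncol(x$history)),
                   col = "grey85", lty = 3)
  invisible(x)
}
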