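#' Model and training configuration
#'
#' Collects every tunable hyperparameter of the prognosis network.  The
#' defaults are the reference settings: ten sub-models, attention
#' bottleneck of 10 nodes, residual-block widths 16 and 8, Adam with
#' learning rate 1e-4, 20 epochs of 5 mini-batches.  The dropout rate
#' and ranking margin are this package's documented choices (the source
#' architecture leaves them open).
#'
#' @param n_submodels Ensemble size (default 10).
#' @param q Attention bottleneck width (default 10).
#' @param widths Integer pair: nodes in the two fully connected layers of
#'   each residual block (default `c(16, 8)`).
#' @param dropout Dropout rate in `[0, 1)` applied inside residual blocks
#'   during training (default 0.5).
#' @param learning_rate Adam step size (default 1e-4).
#' @param epochs Training epochs (default 20).
#' @param minibatches Mini-batches per epoch (default 5).
#' @param margin Ranking-loss margin (default 0.1).
#' @param use_bias Include bias terms in all linear maps (default TRUE).
#' @param log_base Log base used by the preprocessing pipeline.
#' @param seed Integer seed governing initialization, mini-batch order
#'   and dropout.
#' @return An object of class `"multipen_config"`.
#' @export
multipen_config <- function(n_submodels = 10L, q = 10L, widths = c(16L, 8L),
                            dropout = 0.5, learning_rate = 1e-4,
                            epochs = 20L, minibatches = 5L, margin = 0.1,
                            use_bias = TRUE,
                            log_base = c("log2", "ln", "log10"),
                            seed = 1L) {
  log_base <- match.arg(log_base)
  stopifnot(n_submodels >= 1, q >= 1, length(widths) == 2L, all(widths >= 1),
            dropout >= 0, dropout < 1, learning_rate > 0,
            epochs >= 1, minibatches >= 1, margin >= 0)
  structure(list(n_submodels = as.integer(n_submodels), q = as.integer(q),
                 widths = as.integer(widths), dropout = dropout,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 minibatches = as.integer(minibatches), margin = margin,
                 use_bias = use_bias, log_base = log_base,
                 seed = as.integer(seed)),
            class = "multipen_config")
}

#' @export
print.multipen_config <- function(x, ...) {
  cat("multipen configuration\n")
  cat(sprintf("  sub-models %d | attention q %d | widths %d/%d | dropout %.2f\n",
              x$n_submodels, x$q, x$widths[1], x$widths[2], x$dropout))
  cat(sprintf("  Adam lr %g | %d epochs x %d mini-batches | margin %g | seed %d\n",
              x$learning_rate, x$epochs, x$minibatches, x$margin, x$seed))
  invisible(x)
}

# Deterministic seed mixing (splitmix-style), kept inside 0..2^31-2 so the
# result is always a valid set.seed() argument.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(h)
}

he_uniform <- function(n_out, n_in) {
  lim <- sqrt(6 / n_in)
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

init_attention <- function(p, q) {
  list(W1 = he_uniform(q, p), b1 = numeric(q),
       W2 = he_uniform(p, q), b2 = numeric(p))
}

init_block <- function(d_in, widths) {
  d1 <- widths[1]; d2 <- widths[2]
  block <- list(W1 = he_uniform(d1, d_in), b1 = numeric(d1),
                g1 = rep(1, d1), be1 = numeric(d1),
                W2 = he_uniform(d2, d1), b2 = numeric(d2),
                g2 = rep(1, d2), be2 = numeric(d2))
  if (d_in != d2) {
    block$Ws <- he_uniform(d2, d_in)
    block$bs <- numeric(d2)
  }
  block
}

init_submodel <- function(d_in, widths) {
  d2 <- widths[2]
  list(block1 = init_block(d_in, widths),
       block2 = init_block(d2, widths),
       head = list(w = he_uniform(1, d2), b = 0))
}

#' Initialize a prognosis estimation network
#'
#' Builds one gene-attention layer per datatype (mRNA, miRNA, clinical)
#' and `n_submodels` residual sub-models over the fused attended vector.
#' All weights are drawn with He-style fan-in uniform scaling from a
#' deterministic stream: the same seed yields a bitwise-identical model,
#' different sub-models get distinct sub-streams.
#'
#' @param config A [multipen_config()].
#' @param p_mrna,p_mirna Gene counts per omics layer (> 0).
#' @param p_clinical Clinical feature count (0 drops the clinical
#'   modality and its attention layer).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `"multipen_model"` owning all weight
#'   tensors.
#' @export
init_model <- function(config = multipen_config(), p_mrna, p_mirna,
                       p_clinical = 0L, seed = config$seed) {
  stopifnot(p_mrna > 0, p_mirna > 0, p_clinical >= 0)
  if (config$n_submodels < 1) stop("ensemble size must be positive")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(derive_seed(seed, 101L))
  attention <- list(mrna = init_attention(p_mrna, config$q),
                    mirna = init_attention(p_mirna, config$q))
  if (p_clinical > 0) {
    attention$clinical <- init_attention(p_clinical, config$q)
  }
  d_fused <- p_mrna + p_mirna + p_clinical
  submodels <- vector("list", config$n_submodels)
  for (i in seq_len(config$n_submodels)) {
    set.seed(derive_seed(seed, 202L, i))
    submodels[[i]] <- init_submodel(d_fused, config$widths)
  }
  structure(list(attention = attention, submodels = submodels,
                 p = c(mrna = p_mrna, mirna = p_mirna, clinical = p_clinical),
                 d_fused = d_fused, config = config, seed = as.integer(seed)),
            class = "multipen_model")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

sigmoid <- function(x) stats::plogis(x)
relu <- function(x) pmax(x, 0)

#' Gene-attention (squeeze-and-excitation) forward pass
#'
#' Computes `a = sigmoid(W2 . relu(W1 x + b1) + b2)` and the attended
#' input `a * x`.  Attention is input-dependent: each sample gets its own
#' gating vector, every component strictly in (0, 1).
#'
#' @param layer Attention weight list (`W1`, `b1`, `W2`, `b2`), e.g. one
#'   element of `model$attention`.
#' @param x Numeric vector of length p, or a p x n matrix of samples in
#'   columns.
#' @return List with `attended` and `a`, shaped like `x`.
#' @export
attention_forward <- function(layer, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else x
  p <- nrow(layer$W2)
  if (nrow(X) != p) {
    stop("attention layer expects ", p, " features, got ", nrow(X))
  }
  H <- relu(layer$W1 %*% X + layer$b1)
  A <- sigmoid(layer$W2 %*% H + layer$b2)
  att <- A * X
  if (vec) list(attended = drop(att), a = drop(A))
  else list(attended = att, a = A)
}

#' Fuse attended modalities by concatenation
#'
#' Fixed order mRNA, miRNA, clinical; a `NULL` or zero-length modality is
#' skipped.
#'
#' @param xm,xmi,xc Attended vectors/matrices (samples in columns).
#' @return The row-concatenated fused vector/matrix.
#' @export
fuse_modalities <- function(xm, xmi, xc = NULL) {
  parts <- list(xm, xmi, xc)
  parts <- Filter(function(z) !is.null(z) && NROW(z) > 0, parts)
  if (all(vapply(parts, function(z) is.null(dim(z)), logical(1)))) {
    unlist(parts, use.names = FALSE)
  } else {
    do.call(rbind, lapply(parts, function(z) {
      if (is.null(dim(z))) matrix(z, ncol = 1L) else z
    }))
  }
}

layernorm_forward <- function(Z, g, be, eps = 1e-5) {
  mu <- colMeans(Z)
  Zc <- sweep(Z, 2L, mu)
  v <- colMeans(Zc^2)
  sdv <- sqrt(v + eps)
  Zn <- sweep(Zc, 2L, sdv, "/")
  list(out = g * Zn + be, zn = Zn, sdv = sdv)
}

layernorm_backward <- function(dOut, ln, g) {
  dg <- rowSums(dOut * ln$zn)
  dbe <- rowSums(dOut)
  dzn <- g * dOut
  m1 <- colMeans(dzn)
  m2 <- colMeans(dzn * ln$zn)
  dZ <- sweep(dzn, 2L, m1) - sweep(ln$zn, 2L, m2, "*")
  dZ <- sweep(dZ, 2L, ln$sdv, "/")
  list(dZ = dZ, dg = dg, dbe = dbe)
}

block_forward <- function(block, X, mode = "eval", dropout = 0) {
  Z1 <- block$W1 %*% X + block$b1
  ln1 <- layernorm_forward(Z1, block$g1, block$be1)
  A1 <- relu(ln1$out)
  if (mode == "train" && dropout > 0) {
    M <- matrix(stats::runif(length(A1)) >= dropout, nrow(A1), ncol(A1)) /
      (1 - dropout)
    D1 <- A1 * M
  } else {
    M <- NULL
    D1 <- A1
  }
  Z2 <- block$W2 %*% D1 + block$b2
  ln2 <- layernorm_forward(Z2, block$g2, block$be2)
  F2 <- relu(ln2$out)
  S <- if (is.null(block$Ws)) X else block$Ws %*% X + block$bs
  out <- S + F2
  if (anyNA(out)) stop("non-finite values in residual block forward pass")
  list(out = out, cache = list(X = X, ln1 = ln1, ln1out = ln1$out, M = M,
                               D1 = D1, ln2 = ln2, ln2out = ln2$out))
}

block_backward <- function(block, cache, dOut) {
  if (is.null(block$Ws)) {
    dX <- dOut
    dWs <- NULL; dbs <- NULL
  } else {
    dWs <- dOut %*% t(cache$X)
    dbs <- rowSums(dOut)
    dX <- t(block$Ws) %*% dOut
  }
  dLn2 <- dOut * (cache$ln2out > 0)
  bw2 <- layernorm_backward(dLn2, cache$ln2, block$g2)
  dW2 <- bw2$dZ %*% t(cache$D1)
  db2 <- rowSums(bw2$dZ)
  dD1 <- t(block$W2) %*% bw2$dZ
  dA1 <- if (is.null(cache$M)) dD1 else dD1 * cache$M
  dLn1 <- dA1 * (cache$ln1out > 0)
  bw1 <- layernorm_backward(dLn1, cache$ln1, block$g1)
  dW1 <- bw1$dZ %*% t(cache$X)
  db1 <- rowSums(bw1$dZ)
  dX <- dX + t(block$W1) %*% bw1$dZ
  grads <- list(W1 = dW1, b1 = db1, g1 = bw1$dg, be1 = bw1$dbe,
                W2 = dW2, b2 = db2, g2 = bw2$dg, be2 = bw2$dbe)
  if (!is.null(dWs)) { grads$Ws <- dWs; grads$bs <- dbs }
  list(grads = grads, dX = dX)
}

#' Forward pass of one residual block
#'
#' Inner path: linear (width 16) -> layer norm -> ReLU -> dropout ->
#' linear (width 8) -> layer norm -> ReLU; output is `skip(x)` plus the
#' inner path, where the skip is the identity when the input already has
#' width 8 and a learned linear projection otherwise.  Dropout is active
#' only in `"train"` mode; `"eval"` mode is deterministic.
#'
#' @param block Block weight list (one element of a sub-model).
#' @param x Input vector of length `d_in`, or `d_in` x n matrix.
#' @param mode `"eval"` (default) or `"train"`.
#' @param dropout Dropout rate used in train mode.
#' @return Output vector/matrix of width 8.
#' @export
residual_block_forward <- function(block, x, mode = c("eval", "train"),
                                   dropout = 0) {
  mode <- match.arg(mode)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else x
  if (nrow(X) != ncol(block$W1)) {
    stop("residual block expects ", ncol(block$W1), " inputs, got ", nrow(X))
  }
  out <- block_forward(block, X, mode, dropout)$out
  if (vec) drop(out) else out
}

submodel_forward_cached <- function(sm, fused, mode, dropout) {
  b1 <- block_forward(sm$block1, fused, mode, dropout)
  b2 <- block_forward(sm$block2, b1$out, mode, dropout)
  U <- drop(sm$head$w %*% b2$out) + sm$head$b
  pred <- tanh(U)
  list(pred = pred, cache = list(b1 = b1$cache, h1 = b1$out,
                                 b2 = b2$cache, h2 = b2$out, pred = pred))
}

#' Forward pass of one sub-model
#'
#' Two residual blocks in series followed by a linear output head and a
#' hyperbolic tangent, so the survival score is strictly in (-1, 1);
#' higher scores mean higher likelihood of survival.
#'
#' @param sm Sub-model weight list (one element of `model$submodels`).
#' @param fused Fused input vector, or matrix with samples in columns.
#' @param mode `"eval"` or `"train"`.
#' @param dropout Dropout rate used in train mode.
#' @return Scalar score per sample.
#' @export
submodel_forward <- function(sm, fused, mode = c("eval", "train"),
                             dropout = 0) {
  mode <- match.arg(mode)
  vec <- is.null(dim(fused))
  X <- if (vec) matrix(fused, ncol = 1L) else fused
  submodel_forward_cached(sm, X, mode, dropout)$pred
}

model_forward <- function(model, data, mode = "eval", dropout = 0) {
  att_m <- attention_forward(model$attention$mrna, data$mrna)
  att_mi <- attention_forward(model$attention$mirna, data$mirna)
  att_c <- if (!is.null(model$attention$clinical)) {
    attention_forward(model$attention$clinical, data$clinical)
  }
  fused <- fuse_modalities(att_m$attended, att_mi$attended,
                           if (!is.null(att_c)) att_c$attended)
  n_sub <- length(model$submodels)
  sub_out <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    sub_out[[i]] <- submodel_forward_cached(model$submodels[[i]], fused,
                                            mode, dropout)
  }
  sub_preds <- do.call(rbind, lapply(sub_out, `[[`, "pred"))
  list(pred = colMeans(sub_preds), sub_preds = sub_preds,
       cache = list(att = list(mrna = att_m, mirna = att_mi, clinical = att_c),
                    fused = fused, sub = lapply(sub_out, `[[`, "cache"),
                    data = data))
}

attention_backward <- function(layer, X, att, dAtt) {
  dA <- dAtt * X
  dS <- dA * att$a * (1 - att$a)
  H <- relu(layer$W1 %*% X + layer$b1)  # recompute; cheap relative to storage
  dW2 <- dS %*% t(H)
  db2 <- rowSums(dS)
  dH <- t(layer$W2) %*% dS
  dZh <- dH * (H > 0)
  dW1 <- dZh %*% t(X)
  db1 <- rowSums(dZh)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

# Backpropagate d(loss)/d(sub_pred) [n_sub x n matrix] through the whole
# model; returns gradients mirroring the model's weight structure.
model_backward <- function(model, fw, dsub_preds) {
  cache <- fw$cache
  n_sub <- length(model$submodels)
  dFused <- matrix(0, nrow(cache$fused), ncol(cache$fused))
  sub_grads <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    sm <- model$submodels[[i]]
    sc <- cache$sub[[i]]
    dU <- dsub_preds[i, ] * (1 - sc$pred^2)
    dH2 <- t(sm$head$w) %*% matrix(dU, nrow = 1L)
    gw <- matrix(dU, nrow = 1L) %*% t(sc$h2)
    gb <- sum(dU)
    bw2 <- block_backward(sm$block2, sc$b2, dH2)
    bw1 <- block_backward(sm$block1, sc$b1, bw2$dX)
    dFused <- dFused + bw1$dX
    sub_grads[[i]] <- list(block1 = bw1$grads, block2 = bw2$grads,
                           head = list(w = gw, b = gb))
  }
  p <- model$p
  idx_m <- seq_len(p["mrna"])
  idx_mi <- p["mrna"] + seq_len(p["mirna"])
  att_grads <- list(
    mrna = attention_backward(model$attention$mrna, cache$data$mrna,
                              cache$att$mrna, dFused[idx_m, , drop = FALSE]),
    mirna = attention_backward(model$attention$mirna, cache$data$mirna,
                               cache$att$mirna, dFused[idx_mi, , drop = FALSE])
  )
  if (!is.null(model$attention$clinical)) {
    idx_c <- p["mrna"] + p["mirna"] + seq_len(p["clinical"])
    att_grads$clinical <- attention_backward(
      model$attention$clinical, cache$data$clinical,
      cache$att$clinical, dFused[idx_c, , drop = FALSE])
  }
  list(attention = att_grads, submodels = sub_grads)
}

#' Ensemble prediction
#'
#' Runs the shared attention layers and every sub-model in evaluation
#' mode and averages the sub-model scores arithmetically.
#'
#' @param model A `"multipen_model"`.
#' @param data List with matrices `mrna`, `mirna` and optionally
#'   `clinical` (features x samples, shared sample order).
#' @return List with `pred` (length-n ensemble score) and `sub_preds`
#'   (n_submodels x n matrix of per-sub-model scores).
#' @export
ensemble_predict <- function(model, data) {
  check_data_dims(model, data)
  fw <- model_forward(model, data, mode = "eval")
  list(pred = fw$pred, sub_preds = fw$sub_preds)
}

check_data_dims <- function(model, data) {
  if (nrow(data$mrna) != model$p["mrna"]) {
    stop("mRNA feature count ", nrow(data$mrna), " != model's ", model$p["mrna"])
  }
  if (nrow(data$mirna) != model$p["mirna"]) {
    stop("miRNA feature count ", nrow(data$mirna), " != model's ", model$p["mirna"])
  }
  if (model$p["clinical"] > 0) {
    if (is.null(data$clinical) || nrow(data$clinical) != model$p["clinical"]) {
      stop("clinical feature count mismatch with model (expected ",
           model$p["clinical"], ")")
    }
  }
  ns <- c(ncol(data$mrna), ncol(data$mirna),
          if (!is.null(data$clinical)) ncol(data$clinical))
  if (length(unique(ns)) != 1L) stop("modalities disagree on sample count")
  invisible(TRUE)
}
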