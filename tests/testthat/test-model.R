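test_that("attention with zero weights gates every gene at exactly 0.5", {
  layer <- list(W1 = matrix(0, 3, 5), b1 = numeric(3),
                W2 = matrix(0, 5, 3), b2 = numeric(5))
  x <- c(-2, -1, 0, 1, 2)
  out <- attention_forward(layer, x)
  expect_equal(out$a, rep(0.5, 5))
  expect_equal(out$attended, 0.5 * x)
})

test_that("attention matches the hand-computed two-gene fixture", {
  layer <- list(W1 = matrix(c(1, 0), 1, 2), b1 = 0,
                W2 = matrix(c(1, -1), 2, 1), b2 = c(0, 0))
  out <- attention_forward(layer, c(1, 0))
  expect_equal(out$a, c(0.7310585786, 0.2689414214), tolerance = 1e-9)
  expect_equal(out$attended, c(0.7310585786, 0), tolerance = 1e-9)
  expect_error(attention_forward(layer, c(1, 0, 2)), "2 features")
})

test_that("attention values are strictly inside (0,1) for random inputs", {
  set.seed(11)
  cfg <- multipen_config(q = 4, seed = 1)
  model <- init_model(cfg, 20, 6, 3, seed = 1)
  for (rep in 1:20) {
    x <- rnorm(20, sd = 5)
    a <- attention_forward(model$attention$mrna, x)$a
    expect_true(all(a > 0 & a < 1))
    expect_true(all(abs(attention_forward(model$attention$mrna, x)$attended)
                    <= abs(x)))
  }
})

test_that("modality fusion concatenates in fixed mRNA/miRNA/clinical order", {
  xm <- 1:5; xmi <- 6:8; xc <- 9:10
  fused <- fuse_modalities(xm, xmi, xc)
  expect_length(fused, 10)
  expect_equal(fused[1:5], xm)
  expect_equal(fused[6:8], xmi)
  expect_equal(fuse_modalities(xm, xmi, NULL), c(xm, xmi))
  expect_equal(fuse_modalities(xm, xmi, numeric(0)), c(xm, xmi))
  M <- fuse_modalities(matrix(1:6, 3), matrix(7:10, 2), NULL)
  expect_equal(dim(M), c(5L, 2L))
})

test_that("residual block with zero inner weights is the identity for d_in = 8", {
  block <- list(W1 = matrix(0, 16, 8), b1 = numeric(16),
                g1 = rep(1, 16), be1 = numeric(16),
                W2 = matrix(0, 8, 16), b2 = numeric(8),
                g2 = rep(1, 8), be2 = numeric(8))
  x <- rnorm(8)
  expect_identical(residual_block_forward(block, x), x)
})

test_that("residual block matches the scalar oracle on the integer toy", {
  block <- toy_block()
  out <- residual_block_forward(block, c(1, 2))
  expect_equal(out, c(1.9999977778, 2.0000000000), tolerance = 1e-9)
  expect_equal(out, oracle_block(block, c(1, 2)), tolerance = 1e-12)
  # random small blocks against the loop oracle, vector and batch paths
  set.seed(5)
  for (rep in 1:10) {
    b <- init_model(multipen_config(seed = rep), 4, 2, 0, seed = rep)$submodels[[1]]$block1
    x <- rnorm(6)
    expect_equal(residual_block_forward(b, x), oracle_block(b, x),
                 tolerance = 1e-12)
  }
  expect_error(residual_block_forward(block, c(1, 2, 3)), "2 inputs")
})

test_that("evaluation-mode forward passes are bitwise reproducible", {
  set.seed(9)
  model <- init_model(multipen_config(n_submodels = 3, seed = 2), 10, 4, 3,
                      seed = 2)
  data <- list(mrna = matrix(rnorm(50), 10), mirna = matrix(rnorm(20), 4),
               clinical = matrix(rnorm(15), 3))
  p1 <- ensemble_predict(model, data)
  p2 <- ensemble_predict(model, data)
  expect_identical(p1, p2)
})

test_that("sub-model output is tanh-bounded and matches the scalar oracle", {
  blk <- toy_block()
  sm <- list(block1 = blk, block2 = blk,
             head = list(w = matrix(c(1, -2), 1, 2), b = 0.5))
  expect_equal(submodel_forward(sm, c(1, 2)), -0.4621206526, tolerance = 1e-9)
  expect_equal(submodel_forward(sm, c(1, 2)), oracle_submodel(sm, c(1, 2)),
               tolerance = 1e-12)
  # zero head -> tanh(0) = 0
  sm0 <- sm; sm0$head <- list(w = matrix(0, 1, 2), b = 0)
  expect_equal(submodel_forward(sm0, c(1, 2)), 0)
  set.seed(21)
  model <- init_model(multipen_config(seed = 3), 12, 5, 0, seed = 3)
  for (rep in 1:20) {
    x <- rnorm(17, sd = 3)
    out <- submodel_forward(model$submodels[[1]], x)
    expect_true(abs(out) < 1)
  }
})

test_that("ensemble prediction is the arithmetic mean of sub-model scores", {
  set.seed(13)
  model <- init_model(multipen_config(n_submodels = 10, seed = 4), 8, 4, 2,
                      seed = 4)
  data <- list(mrna = matrix(rnorm(8 * 6), 8), mirna = matrix(rnorm(24), 4),
               clinical = matrix(rnorm(12), 2))
  out <- ensemble_predict(model, data)
  indep <- colMeans(do.call(rbind, lapply(model$submodels, function(sm) {
    vapply(seq_len(6), function(j) {
      fused <- c(attention_forward(model$attention$mrna, data$mrna[, j])$attended,
                 attention_forward(model$attention$mirna, data$mirna[, j])$attended,
                 attention_forward(model$attention$clinical, data$clinical[, j])$attended)
      oracle_submodel(sm, fused)
    }, numeric(1))
  })))
  expect_equal(out$pred, indep, tolerance = 1e-6)
  expect_equal(dim(out$sub_preds), c(10L, 6L))

  # identical sub-models collapse the mean onto any single one
  model$submodels <- rep(model$submodels[1], 10)
  same <- ensemble_predict(model, data)
  expect_equal(same$pred, same$sub_preds[1, ])

  # symmetric heads cancel
  model2 <- init_model(multipen_config(n_submodels = 2, seed = 5), 8, 4, 2,
                       seed = 5)
  model2$submodels[[2]] <- model2$submodels[[1]]
  model2$submodels[[1]]$head <- list(w = matrix(0, 1, 8), b = 1)
  model2$submodels[[2]]$head <- list(w = matrix(0, 1, 8), b = -1)
  expect_equal(ensemble_predict(model2, data)$pred, rep(0, 6))
})

test_that("initialization honours the reference architecture defaults", {
  model <- init_model(multipen_config(), 30, 12, 5, seed = 7)
  expect_length(model$submodels, 10)
  expect_equal(nrow(model$attention$mrna$W1), 10)   # q = 10 bottleneck
  expect_equal(dim(model$submodels[[1]]$block1$W1), c(16L, 47L))
  expect_equal(dim(model$submodels[[1]]$block1$W2), c(8L, 16L))
  expect_equal(dim(model$submodels[[1]]$block2$W1), c(16L, 8L))
  expect_null(model$submodels[[1]]$block2$Ws)       # identity skip at width 8
  expect_false(is.null(model$submodels[[1]]$block1$Ws))
})

test_that("initialization is seed-deterministic and seed-sensitive", {
  a <- init_model(multipen_config(), 10, 5, 2, seed = 7)
  b <- init_model(multipen_config(), 10, 5, 2, seed = 7)
  c <- init_model(multipen_config(), 10, 5, 2, seed = 8)
  expect_identical(a[c("attention", "submodels")],
                   b[c("attention", "submodels")])
  expect_false(identical(a$attention$mrna$W1, c$attention$mrna$W1))
  # distinct sub-model initializations within one model
  expect_false(identical(a$submodels[[1]]$block1$W1,
                         a$submodels[[2]]$block1$W1))
  expect_error(multipen_config(n_submodels = 0))
  cfg0 <- multipen_config()
  cfg0$n_submodels <- 0L
  expect_error(init_model(cfg0, 5, 5, 0), "positive")
})

test_that("backpropagation matches central finite differences", {
  set.seed(42)
  cfg <- multipen_config(n_submodels = 2, q = 2, dropout = 0, seed = 3)
  model <- init_model(cfg, 4, 3, 2, seed = 3)
  n <- 6
  data <- list(mrna = matrix(rnorm(4 * n), 4), mirna = matrix(rnorm(3 * n), 3),
               clinical = matrix(rnorm(2 * n), 2))
  time <- rexp(n) + 0.1
  loss_fn <- function(m) {
    fw <- multipen:::model_forward(m, data, mode = "eval")
    (ranking_loss(fw$pred, time, 0.1) +
       sum(apply(fw$sub_preds, 1, ranking_loss, time = time,
                 margin = 0.1))) / 3
  }
  fw <- multipen:::model_forward(model, data, mode = "eval")
  g_ens <- multipen:::ranking_loss_grad(fw$pred, time, 0.1)
  dsub <- matrix(rep(g_ens / 2, each = 2), 2)
  for (i in 1:2) {
    dsub[i, ] <- dsub[i, ] +
      multipen:::ranking_loss_grad(fw$sub_preds[i, ], time, 0.1)
  }
  grads <- multipen:::model_backward(model, fw, dsub / 3)
  paths <- list(list("attention", "mrna", "W1"),
                list("attention", "clinical", "W2"),
                list("submodels", 1, "block1", "Ws"),
                list("submodels", 1, "block1", "g1"),
                list("submodels", 2, "block2", "W2"),
                list("submodels", 2, "block2", "be1"),
                list("submodels", 2, "head", "w"))
  get_leaf <- function(tr, path) { for (k in path) tr <- tr[[k]]; tr }
  set_leaf <- function(tr, path, v) {
    if (length(path) == 1) { tr[[path[[1]]]] <- v; return(tr) }
    tr[[path[[1]]]] <- set_leaf(tr[[path[[1]]]], path[-1], v)
    tr
  }
  eps <- 1e-6
  for (path in paths) {
    leaf <- get_leaf(model, path)
    gleaf <- get_leaf(grads, path)
    for (i in sample(length(leaf), min(2, length(leaf)))) {
      up <- leaf; up[i] <- up[i] + eps
      dn <- leaf; dn[i] <- dn[i] - eps
      num <- (loss_fn(set_leaf(model, path, up)) -
                loss_fn(set_leaf(model, path, dn))) / (2 * eps)
      expect_equal(gleaf[i], num, tolerance = 1e-5)
    }
  }
})

test_that("forcing a gene's attention to zero removes its influence", {
  set.seed(31)
  model <- init_model(multipen_config(n_submodels = 2, seed = 6), 6, 3, 0,
                      seed = 6)
  data <- list(mrna = matrix(rnorm(6 * 4), 6), mirna = matrix(rnorm(12), 3))
  # probe: force gene 1's gate to 0 and detach it from the squeeze layer
  # (attention is input-dependent, so the gene must also stop influencing
  # the other genes' gates for its sensitivity to vanish)
  model$attention$mrna$b2[1] <- -1e9
  model$attention$mrna$W1[, 1] <- 0
  base <- ensemble_predict(model, data)$pred
  bumped <- data
  bumped$mrna[1, ] <- bumped$mrna[1, ] + 5
  expect_equal(ensemble_predict(model, bumped)$pred, base, tolerance = 1e-6)
})
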