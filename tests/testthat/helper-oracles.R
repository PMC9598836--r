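# Independent oracles: deliberately naive scalar/loop implementations,
# kept free of any package internals so they can arbitrate correctness.

# O(n^2) pair-by-pair concordance counter
brute_cindex <- function(pred, time) {
  num <- 0; den <- 0
  n <- length(pred)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      den <- den + 1
      lo <- if (time[i] < time[j]) i else j  # shorter-lived sample
      hi <- if (time[i] < time[j]) j else i
      if (pred[hi] > pred[lo]) num <- num + 1
      else if (pred[hi] == pred[lo]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# pair-enumeration ranking loss
brute_ranking_loss <- function(pred, time, margin) {
  tot <- 0; den <- 0
  n <- length(pred)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (time[i] < time[j]) {
        den <- den + 1
        tot <- tot + max(0, margin + pred[i] - pred[j])
      }
    }
  }
  if (den == 0) return(0)
  tot / den
}

# scalar layer-norm + two-layer residual block, one sample at a time
oracle_layernorm <- function(z, g, be, eps = 1e-5) {
  mu <- mean(z)
  v <- mean((z - mu)^2)
  g * (z - mu) / sqrt(v + eps) + be
}

oracle_block <- function(block, x) {
  z1 <- as.vector(block$W1 %*% x) + block$b1
  a1 <- pmax(oracle_layernorm(z1, block$g1, block$be1), 0)
  z2 <- as.vector(block$W2 %*% a1) + block$b2
  f2 <- pmax(oracle_layernorm(z2, block$g2, block$be2), 0)
  skip <- if (is.null(block$Ws)) x else as.vector(block$Ws %*% x) + block$bs
  skip + f2
}

oracle_submodel <- function(sm, x) {
  h2 <- oracle_block(sm$block2, oracle_block(sm$block1, x))
  tanh(sum(sm$head$w * h2) + sm$head$b)
}

# small toy residual block with integer weights and identity skip
toy_block <- function() {
  list(W1 = rbind(c(1, 0), c(0, -1)), b1 = c(0, 1),
       g1 = c(1, 2), be1 = c(0.5, -0.5),
       W2 = rbind(c(1, 1), c(-1, 2)), b2 = c(0, 0),
       g2 = c(1, 1), be2 = c(0, 0))
}

tiny_cohort <- function(n = 40, p_mrna = 30, p_mirna = 10, beta = 1.5,
                        seed = 1, ...) {
  generate_cohort(cohort_spec(n_samples = n, p_mrna = p_mrna,
                              p_mirna = p_mirna, n_prognostic_mrna = 5,
                              n_prognostic_mirna = 3, beta = beta,
                              zero_rate = 0, seed = seed, ...))
}

preprocess_cohort <- function(co, standardize = FALSE) {
  prep <- fit_preprocessor(co$mrna, co$mirna, co$clinical,
                           standardize = standardize)
  predict(prep, co$mrna, co$mirna, co$clinical)
}
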