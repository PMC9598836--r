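test_that("ranking loss reproduces the worked pair enumerations", {
  # fully separated by more than the margin
  expect_equal(ranking_loss(c(-0.9, 0, 0.9), c(1, 2, 3), 0.1), 0)
  # all-tied predictions cost exactly the margin on every pair
  expect_equal(ranking_loss(rep(0.3, 4), c(1, 2, 3, 4), 0.25), 0.25)
  # single inverted pair
  expect_equal(ranking_loss(c(0.5, -0.5), c(1, 2), 0.1), 1.1)
  # tied survival times carry no order information
  expect_equal(ranking_loss(c(1, -1), c(2, 2), 0.1), 0)
  expect_error(ranking_loss(0.5, 1, 0.1), "2 samples")
})

test_that("ranking loss agrees with the brute-force enumerator", {
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(2:12, 1)
    pred <- round(rnorm(n), 2)
    time <- sample(1:6, n, replace = TRUE)  # deliberate time ties
    m <- runif(1, 0, 0.5)
    expect_equal(ranking_loss(pred, time, m),
                 brute_ranking_loss(pred, time, m), tolerance = 1e-12)
  }
})

test_that("ranking loss is non-negative and zero iff margin-separated", {
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    pred <- rnorm(n); time <- rexp(n) + 0.01
    l <- ranking_loss(pred, time, 0.1)
    expect_gte(l, 0)
    sep <- all(outer(pred, pred, function(a, b) b - a)[outer(time, time, "<")]
               >= 0.1)
    expect_identical(l == 0, sep)
  }
})

test_that("analytic ranking-loss gradient matches central differences", {
  set.seed(29)
  for (rep in 1:20) {
    pred <- rnorm(2)
    time <- c(1, 2)
    m <- 0.1
    # only check where the hinge is strictly active or inactive
    if (abs(m + pred[1] - pred[2]) < 1e-3) next
    g <- multipen:::ranking_loss_grad(pred, time, m)
    eps <- 1e-6
    for (i in 1:2) {
      up <- pred; up[i] <- up[i] + eps
      dn <- pred; dn[i] <- dn[i] - eps
      num <- (ranking_loss(up, time, m) - ranking_loss(dn, time, m)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
})

test_that("mini-batches form a near-equal random partition", {
  set.seed(1)
  b <- make_minibatches(100, 5)
  expect_length(b, 5)
  expect_equal(unname(lengths(b)), rep(20L, 5))
  expect_setequal(unlist(b), 1:100)
  b2 <- make_minibatches(7, 3)
  expect_equal(sort(unname(lengths(b2)), decreasing = TRUE), c(3L, 2L, 2L))
  expect_setequal(unlist(b2), 1:7)
  set.seed(99); p1 <- make_minibatches(20, 4)
  set.seed(99); p2 <- make_minibatches(20, 4)
  expect_identical(p1, p2)
  expect_error(make_minibatches(3, 5), "cannot form")
})

test_that("training records epochs x minibatches losses and ends deterministic", {
  co <- tiny_cohort(seed = 2)
  dat <- preprocess_cohort(co, standardize = TRUE)
  cfg <- multipen_config(n_submodels = 2, epochs = 3, minibatches = 4,
                         learning_rate = 1e-3, seed = 8)
  fit1 <- multipen(dat$mrna, dat$mirna, dat$clinical,
                   time = co$survival$time, config = cfg)
  expect_equal(dim(fit1$history), c(3L, 4L))
  expect_true(all(is.finite(fit1$history)))
  fit2 <- multipen(dat$mrna, dat$mirna, dat$clinical,
                   time = co$survival$time, config = cfg)
  expect_identical(fit1$model[c("attention", "submodels")],
                   fit2$model[c("attention", "submodels")])
  expect_identical(predict(fit1, dat$mrna, dat$mirna, dat$clinical),
                   predict(fit2, dat$mrna, dat$mirna, dat$clinical))
})

test_that("loss decreases over training on a strong-signal cohort", {
  co <- tiny_cohort(n = 60, p_mrna = 40, p_mirna = 15, beta = 5, seed = 3,
                    sd_noise = 0.3)
  dat <- preprocess_cohort(co, standardize = TRUE)
  cfg <- multipen_config(n_submodels = 3, epochs = 10, learning_rate = 0.01,
                         dropout = 0.2, seed = 5)
  fit <- multipen(dat$mrna, dat$mirna, dat$clinical,
                  time = co$survival$time, config = cfg)
  expect_lt(mean(fit$history[nrow(fit$history), ]),
            mean(fit$history[1, ]))
})

test_that("training on a null cohort stays at chance-level concordance", {
  cs <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_spec(
      n_samples = 50, p_mrna = 30, p_mirna = 10, n_prognostic_mrna = 5,
      n_prognostic_mirna = 3, beta = 0, zero_rate = 0,
      clinical_effects = c(age = 0, grade = 0, idh = 0), seed = s))
    dat <- preprocess_cohort(co, standardize = TRUE)
    tr <- 1:35; te <- 36:50
    cfg <- multipen_config(n_submodels = 2, epochs = 3, learning_rate = 0.01,
                           dropout = 0.2, seed = s)
    fit <- multipen(dat$mrna[, tr], dat$mirna[, tr], dat$clinical[, tr],
                    time = co$survival$time[tr], config = cfg)
    sc <- predict(fit, dat$mrna[, te], dat$mirna[, te], dat$clinical[, te])
    concordance_index(sc, co$survival$time[te])
  }, numeric(1))
  ci <- mean(cs) + c(-1, 1) * 1.96 * sd(cs) / sqrt(length(cs))
  expect_gte(0.5, ci[1])
  expect_lte(0.5, ci[2])
})

test_that("non-finite training inputs abort with the failing step", {
  co <- tiny_cohort(seed = 4, n = 20)
  dat <- preprocess_cohort(co)
  dat$mrna[1, 1] <- Inf
  cfg <- multipen_config(n_submodels = 1, epochs = 1, minibatches = 1,
                         seed = 1)
  expect_error(multipen(dat$mrna, dat$mirna, dat$clinical,
                        time = co$survival$time, config = cfg),
               "non-finite|NaN")
})
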