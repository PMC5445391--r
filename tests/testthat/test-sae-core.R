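toy_data <- function(n = 40, d = 4, seed = 7) {
  set.seed(seed)
  X <- matrix(runif(n * d), n, d)
  y <- as.integer(X[, 1] + X[, 2] > 1)
  list(X = X, y = y)
}

test_that("initialization is deterministic and shape-correct", {
  m1 <- sae_init(c(420, 400, 2), seed = 1)
  m2 <- sae_init(c(420, 400, 2), seed = 1)
  expect_identical(m1$layers, m2$layers)
  m3 <- sae_init(c(420, 400, 2), seed = 2)
  expect_false(identical(m1$layers, m3$layers))
  expect_identical(dim(m1$layers[[1]]$W_enc), c(400L, 420L))
  expect_identical(dim(m1$layers[[1]]$W_dec), c(420L, 400L))
  expect_identical(dim(m1$head$W), c(2L, 400L))
  # encoder + head parameter count: 420*400+400 + 400*2+2
  n_par <- length(m1$layers[[1]]$W_enc) + length(m1$layers[[1]]$b_enc) +
    length(m1$head$W) + length(m1$head$b)
  expect_identical(n_par, 420L * 400L + 400L + 400L * 2L + 2L)
  expect_equal(summary(m1)$n_parameters, n_par)
  expect_error(sae_init(c(4)), "at least")
  expect_error(sae_init(c(4, 0, 2)), "positive")
  expect_error(sae_init(c(4, 3, 3)), "size 2")
})

test_that("forward pass yields normalized probabilities", {
  m <- sae_init(c(4, 3, 2), seed = 5)
  set.seed(6)
  X <- matrix(rnorm(40), 10, 4)
  fw <- sae_forward(m, X)
  expect_equal(unname(rowSums(fw$prob)), rep(1, 10), tolerance = 1e-12)
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  # zero parameters give exactly (0.5, 0.5) by symmetry
  m0 <- m
  m0$layers[[1]]$W_enc[] <- 0; m0$layers[[1]]$b_enc[] <- 0
  fw0 <- sae_forward(m0, X)
  expect_identical(unname(fw0$prob), matrix(0.5, 10, 2))
  expect_error(sae_forward(m, X[, 1:3]), "expects")
})

test_that("forward pass matches a hand-computed toy network", {
  m <- sae_init(c(2, 2, 2), seed = 1)
  m$layers[[1]]$W_enc <- matrix(c(1, -1, 0.5, 2), 2, 2)
  m$layers[[1]]$b_enc <- c(0.1, -0.2)
  m$head$W <- matrix(c(0.3, -0.3, 1, 0), 2, 2)
  m$head$b <- c(0.05, -0.05)
  x <- c(0.4, 0.7)
  # scalar arithmetic, independent of the matrix implementation
  z1 <- 1 * 0.4 + 0.5 * 0.7 + 0.1
  z2 <- -1 * 0.4 + 2 * 0.7 - 0.2
  a1 <- 1 / (1 + exp(-z1)); a2 <- 1 / (1 + exp(-z2))
  l1 <- 0.3 * a1 + 1 * a2 + 0.05
  l2 <- -0.3 * a1 + 0 * a2 - 0.05
  p1 <- exp(l1) / (exp(l1) + exp(l2))
  fw <- sae_forward(m, matrix(x, 1, 2))
  expect_equal(unname(fw$activations[[2]][1, ]), c(a1, a2), tolerance = 1e-12)
  expect_equal(unname(fw$prob[1, ]), c(p1, 1 - p1), tolerance = 1e-12)
})

test_that("pretraining reduces reconstruction loss", {
  td <- toy_data(n = 50, d = 6)
  m <- sae_init(c(6, 4, 2), seed = 3)
  ctl <- sae_control(batch_size = 10, pretrain_epochs = 15)
  m <- sae_pretrain_layer(m, 1, td$X, ctl)
  tr <- m$pretrain_trace[[1]]
  expect_length(tr, 15L)
  expect_lt(tail(tr, 1), tr[1])
  expect_error(sae_pretrain_layer(m, 1, td$X[, 1:3], ctl), "input width")
})

test_that("an overcomplete autoencoder memorizes a tiny sample", {
  set.seed(9)
  X <- matrix(runif(10 * 3), 10, 3)
  m <- sae_init(c(3, 8, 2), seed = 4)
  ctl <- sae_control(batch_size = 10, pretrain_epochs = 400,
                     lr_pretrain = 1)
  m <- sae_pretrain_layer(m, 1, X, ctl)
  expect_lt(tail(m$pretrain_trace[[1]], 1), 0.01)
})

test_that("fine-tuning solves a linearly separable toy problem", {
  set.seed(10)
  X <- matrix(runif(120 * 2), 120, 2)
  y <- as.integer(X[, 1] > X[, 2])
  m <- sae_init(c(2, 4, 2), seed = 2)
  ctl <- sae_control(batch_size = 20, finetune_epochs = 200,
                     lr_finetune = 0.5)
  m <- sae_finetune(m, X, y, ctl)
  expect_identical(mean(predict(m, X) == y), 1)
})

test_that("a zero learning rate leaves parameters untouched", {
  td <- toy_data()
  m <- sae_init(c(4, 3, 2), seed = 2)
  ctl <- sae_control(lr_finetune = 0, finetune_epochs = 3, batch_size = 10)
  m2 <- sae_finetune(m, td$X, td$y, ctl)
  expect_identical(m$layers, m2$layers)
  expect_identical(m$head, m2$head)
})

test_that("training is bitwise reproducible under a fixed seed", {
  td <- toy_data()
  ctl <- sae_control(batch_size = 10, pretrain_epochs = 3,
                     finetune_epochs = 5)
  f1 <- sae(td$X, td$y, hidden = 3, control = ctl, seed = 42)
  f2 <- sae(td$X, td$y, hidden = 3, control = ctl, seed = 42)
  expect_identical(f1$layers, f2$layers)
  expect_identical(f1$finetune_trace, f2$finetune_trace)
  expect_identical(f1$fitted.values, f2$fitted.values)
})

test_that("labels outside {0,1} are rejected", {
  td <- toy_data()
  m <- sae_init(c(4, 3, 2), seed = 1)
  expect_error(sae_finetune(m, td$X, td$y + 1L), "0 or 1")
})

test_that("analytic gradients match finite differences on toy models", {
  set.seed(11)
  m <- sae_init(c(4, 3, 2), seed = 8)
  X <- matrix(runif(5 * 4), 5, 4)
  y <- c(0L, 1L, 1L, 0L, 1L)
  # exercise non-zero head weights too
  m <- sae_finetune(m, X, y, sae_control(batch_size = 5,
                                         finetune_epochs = 2))
  expect_lt(sae_gradient_check(m, X, y, "finetune"), 1e-6)
  expect_lt(sae_gradient_check(m, X, objective = "pretrain"), 1e-6)
  # degenerate batch: all-zero inputs and labels stay finite
  X0 <- matrix(0, 4, 4)
  d0 <- sae_gradient_check(m, X0, rep(0L, 4), "finetune")
  expect_true(is.finite(d0))
  # deterministic: same inputs, same discrepancy
  expect_identical(sae_gradient_check(m, X, y, "finetune"),
                   sae_gradient_check(m, X, y, "finetune"))
})

test_that("prediction uses argmax with ties resolved to non-interaction", {
  m <- sae_init(c(4, 3, 2), seed = 1)
  m$layers[[1]]$W_enc[] <- 0; m$layers[[1]]$b_enc[] <- 0
  X <- matrix(runif(12), 3, 4)
  # zero model: probabilities exactly 0.5 -> negative class
  expect_identical(predict(m, X), c(0L, 0L, 0L))
  td <- toy_data()
  fit <- sae(td$X, td$y, hidden = 3, seed = 1,
             control = sae_control(batch_size = 10, pretrain_epochs = 2,
                                   finetune_epochs = 10))
  batch <- predict(fit, td$X)
  single <- vapply(seq_len(nrow(td$X)), function(i)
    predict(fit, td$X[i, , drop = FALSE]), integer(1))
  expect_identical(batch, single)
})

test_that("model JSON serialization round-trips predictions bitwise", {
  td <- toy_data()
  fit <- sae(td$X, td$y, hidden = 3, seed = 5,
             control = sae_control(batch_size = 10, pretrain_epochs = 2,
                                   finetune_epochs = 5))
  scaler <- fit_scaler(td$X)
  path <- withr::local_tempfile(fileext = ".json")
  save_sae(fit, path, scaler = scaler, scheme = "AC", lag_max = 30)
  back <- load_sae(path)
  expect_identical(unname(predict(fit, td$X, type = "prob")),
                   unname(predict(back, td$X, type = "prob")))
  expect_equal(back$scaler$min, unname(as.numeric(scaler$min)))
  expect_identical(back$scheme, "AC")
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), bad)
  expect_error(load_sae(bad), "not a ppisae model")
})

test_that("model print and summary report architecture and accuracy", {
  td <- toy_data()
  fit <- sae(td$X, td$y, hidden = 3, seed = 5,
             control = sae_control(batch_size = 10, pretrain_epochs = 2,
                                   finetune_epochs = 5))
  expect_output(print(fit), "architecture: \\[4, 3, 2\\]")
  expect_output(print(summary(fit)), "trainable parameters")
  expect_length(coef(fit), 2L)  # one hidden layer + head
  expect_length(residuals(fit), nrow(td$X))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(nrow(td$X), 3L))
  expect_true(all(unlist(sims) %in% 0:1))
})
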