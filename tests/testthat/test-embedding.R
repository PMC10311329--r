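test_that("contrastive loss evaluates the documented cases", {
  e <- matrix(1:6, 2, 3)
  expect_equal(contrastive_loss(e, e, c(1, 1)), 0)
  # cannot-link at distance 2 with margin 1: hinge saturated
  e1 <- matrix(c(0, 0), 1); e2 <- matrix(c(2, 0), 1)
  expect_equal(contrastive_loss(e1, e2, 0), 0)
  # d = 0.5: both labels give 0.25
  e2 <- matrix(c(0.5, 0), 1)
  expect_equal(contrastive_loss(e1, e2, 0), 0.25)
  expect_equal(contrastive_loss(e1, e2, 1), 0.25)
  # batch value is the mean over pairs
  E1 <- rbind(c(0, 0), c(0, 0)); E2 <- rbind(c(0.5, 0), c(2, 0))
  expect_equal(contrastive_loss(E1, E2, c(0, 0)), 0.125)
})

test_that("loss is zero iff must-links coincide and cannot-links clear the margin", {
  set.seed(1)
  e1 <- matrix(rnorm(10), 2)
  expect_gt(contrastive_loss(e1, e1 + 0.01, c(1, 1)), 0)
  far <- e1 + matrix(c(10, 0, 0, 0, 0, 10, 0, 0, 0, 0), 2)
  expect_equal(contrastive_loss(e1, far, c(0, 0)), 0)
  expect_gt(contrastive_loss(e1, e1 + 0.1, c(0, 0)), 0)
})

test_that("analytic loss gradient matches central finite differences", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:5, 1); d <- sample(2:8, 1)
    e1 <- matrix(rnorm(n * d, sd = 0.5), n, d)
    e2 <- matrix(rnorm(n * d, sd = 0.5), n, d)
    y <- sample(0:1, n, replace = TRUE)
    g <- contrastive_loss_grad(e1, e2, y)
    h <- 1e-6
    for (k in sample(seq_len(n * d), min(6, n * d))) {
      ep <- e1; em <- e1
      ep[k] <- ep[k] + h; em[k] <- em[k] - h
      num <- (contrastive_loss(ep, e2, y) - contrastive_loss(em, e2, y)) / (2 * h)
      denom <- max(abs(num), abs(g$g1[k]), 1e-8)
      expect_lt(abs(num - g$g1[k]) / denom, 1e-4)
    }
  }
})

test_that("full network backward pass matches finite differences on a tiny model", {
  set.seed(8)
  m <- new_siamese_model(6, hidden = c(5L, 4L), out_dim = 3, dropout = 0,
                         seed = 3)
  X <- matrix(rnorm(8 * 6), 8, 6)
  y <- c(1, 0, 1, 0)
  loss_at <- function(model) {
    fw <- forward_at(model)
    contrastive_loss(fw$out[1:4, ], fw$out[5:8, ], y)
  }
  forward_at <- function(model) contrabin:::forward_pass(model, X, training = TRUE)
  fw <- forward_at(m)
  gr <- contrastive_loss_grad(fw$out[1:4, ], fw$out[5:8, ], y)
  grads <- contrabin:::backward_pass(m, fw$cache, rbind(gr$g1, gr$g2))
  h <- 1e-5
  for (nm in names(m$params)) {
    k <- sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))
    for (idx in k) {
      mp <- m; mp$params[[nm]][idx] <- mp$params[[nm]][idx] + h
      mm <- m; mm$params[[nm]][idx] <- mm$params[[nm]][idx] - h
      num <- (loss_at(mp) - loss_at(mm)) / (2 * h)
      denom <- max(abs(num), abs(grads[[nm]][idx]), 1e-6)
      expect_lt(abs(num - grads[[nm]][idx]) / denom, 1e-3)
    }
  }
})

test_that("inference is deterministic and batch-size independent", {
  set.seed(5)
  m <- new_siamese_model(10, hidden = c(16L, 16L), out_dim = 7, seed = 1)
  X <- matrix(rnorm(32 * 10), 32, 10)
  out1 <- model_forward(m, X)
  out2 <- model_forward(m, X)
  expect_identical(out1, out2)
  expect_equal(dim(out1), c(32L, 7L))
  single <- model_forward(m, X[5, , drop = FALSE])
  expect_equal(single[1, ], out1[5, ], tolerance = 1e-5)
  # zeroed output head forces all-zero embeddings
  m0 <- m; m0$params$W3[] <- 0; m0$params$b3[] <- 0
  expect_true(all(model_forward(m0, X) == 0))
  expect_error(model_forward(m, X[, 1:3]), "expects")
})

test_that("zero epochs leave the model untouched with an empty trace", {
  task <- fixture_embedding_task(n_genomes = 2, contigs_per_genome = 8)
  cs <- constraint_set(task$must, task$cannot)
  m <- new_siamese_model(ncol(task$features), hidden = c(8L, 8L), seed = 2)
  tr <- train_siamese(m, task$features, cs, training_config(epochs = 0))
  expect_identical(tr$model$params, m$params)
  expect_length(tr$loss_trace, 0L)
  bad <- constraint_set(data.frame(a = "ghost_1", b = "ghost_2"),
                        task$cannot[1, ])
  expect_error(train_siamese(m, task$features, bad, training_config()),
               "no feature row")
})

test_that("training reduces the loss and separates held-out pairs", {
  task <- fixture_embedding_task(n_genomes = 3, contigs_per_genome = 25,
                                 seed = 21)
  # hold out every 5th pair of each label
  hold_m <- seq(1, nrow(task$must), by = 5)
  hold_c <- seq(1, nrow(task$cannot), by = 5)
  cs <- constraint_set(task$must[-hold_m, ], task$cannot[-hold_c, ])
  m <- new_siamese_model(ncol(task$features), hidden = c(64L, 64L), seed = 4)
  tr <- train_siamese(m, task$features, cs,
                      training_config(epochs = 25, batch_size = 128, seed = 4))
  expect_lt(tr$loss_trace[length(tr$loss_trace)], tr$loss_trace[1])
  expect_true(tr$model$trained)
  emb <- model_forward(tr$model, task$features)
  pair_dist <- function(pairs) {
    rowSums((emb[pairs$a, , drop = FALSE] - emb[pairs$b, , drop = FALSE])^2)^0.5
  }
  d_must <- mean(pair_dist(task$must[hold_m, ]))
  d_cannot <- mean(pair_dist(task$cannot[hold_c, ]))
  expect_lt(d_must, d_cannot)
})

test_that("training is reproducible bit-for-loss given a seed", {
  task <- fixture_embedding_task(n_genomes = 2, contigs_per_genome = 10,
                                 seed = 33)
  cs <- constraint_set(task$must, task$cannot)
  m <- new_siamese_model(ncol(task$features), hidden = c(16L, 16L), seed = 9)
  cfg <- training_config(epochs = 5, batch_size = 16, seed = 77)
  t1 <- train_siamese(m, task$features, cs, cfg)
  t2 <- train_siamese(m, task$features, cs, cfg)
  expect_identical(t1$loss_trace, t2$loss_trace)
  expect_identical(t1$model$params, t2$model$params)
})

test_that("model checkpoints round-trip and reject bad files", {
  m <- new_siamese_model(12, hidden = c(8L, 8L), out_dim = 5, seed = 6)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  X <- matrix(rnorm(20 * 12), 20, 12)
  expect_identical(model_forward(m, X), model_forward(m2, X))
  # truncated checkpoint
  trunc <- tempfile()
  raw <- readBin(path, "raw", file.info(path)$size)
  writeBin(raw[1:10], trunc)
  expect_error(load_model(trunc), "truncated|failed to read")
  # format version mismatch
  m$format_version <- 999L
  saveRDS(m, path)
  expect_error(load_model(path), "version")
})
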