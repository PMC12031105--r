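test_that("model configuration validates its invariants", {
  expect_error(sgatcn_config(epochs = 0), "epochs")
  expect_error(sgatcn_config(n_classes = 1), "n_classes")
  expect_error(sgatcn_config(learning_rate = 0), "learning_rate")
  cfg <- sgatcn_config()
  expect_equal(cfg$epochs, 800L)
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$batch_size, 30L)
})

test_that("attention coefficients form neighbourhood distributions", {
  # single node: self-loop only, a_ii = 1
  W <- matrix(rnorm(6), 2, 3)
  a <- rnorm(6)
  al1 <- attention_coefficients(matrix(c(1, 2), 1, 2), matrix(0, 1, 1), W, a)
  expect_equal(al1[1, 1], 1)

  # two identical nodes, mutual edge: all coefficients 1/2
  X2 <- matrix(c(1, 1, 2, 2), 2, 2)
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  al2 <- attention_coefficients(X2, A2, W, a)
  expect_equal(as.vector(al2), rep(0.5, 4))

  # 3-node path with fixed weights: matches the step-by-step oracle
  set.seed(1)
  X3 <- matrix(rnorm(6), 3, 2)
  A3 <- matrix(0, 3, 3)
  A3[1, 2] <- A3[2, 1] <- A3[2, 3] <- A3[3, 2] <- 1
  ref <- oracle_gat(X3, A3, W, a)
  al3 <- attention_coefficients(X3, A3, W, a)
  expect_equal(al3, ref$alpha, tolerance = 1e-12)
  # rows sum to 1 on the closed neighbourhood; zero outside
  expect_equal(rowSums(al3), rep(1, 3), tolerance = 1e-6)
  expect_equal(al3[1, 3], 0)
  expect_equal(al3[3, 1], 0)
})

test_that("the GAT update equals the dense aggregation oracle", {
  set.seed(2)
  n <- 7
  X <- matrix(rnorm(n * 2), n, 2)
  A <- random_sym_adj(n, 0.4, seed = 3)
  W <- matrix(rnorm(8), 2, 4)
  a <- rnorm(8)
  ref <- oracle_gat(X, A, W, a)
  H <- gat_update(X, A, W, a)
  expect_equal(H, ref$H, tolerance = 1e-12)

  # identity-like W, isolated node: output = ELU of own transform
  Wi <- diag(2)
  ai <- rep(0, 4)
  h1 <- gat_update(matrix(c(-1, 2), 1, 2), matrix(0, 1, 1), Wi, ai)
  expect_equal(as.vector(h1), c(exp(-1) - 1, 2))

  # uniform attention over identical neighbours equals the
  # single-neighbour case
  Xs <- matrix(rep(c(0.3, -0.7), each = 3), 3, 2)
  As <- matrix(1, 3, 3) - diag(3)
  hs <- gat_update(Xs, As, W, a)
  h1n <- gat_update(Xs[1, , drop = FALSE], matrix(0, 1, 1), W, a)
  for (i in 1:3) expect_equal(hs[i, ], h1n[1, ], tolerance = 1e-12)
})

test_that("the stacked GAT stage is permutation-equivariant", {
  cfg <- tiny_config()
  dg <- toy_graph(seed = 4, class_id = 0, n_nodes = 8)
  model <- sgatcn_init(cfg)
  model <- workloadnet:::ensure_fc(model, dg)
  emb <- sgat_embed(model, dg, scaling = NULL)

  set.seed(5)
  perm <- sample(8)
  dgp <- dg
  for (b in seq_along(dgp$snapshots)) {
    dgp$snapshots[[b]]$adjacency <- dg$snapshots[[b]]$adjacency[perm, perm]
    dgp$snapshots[[b]]$features <- dg$snapshots[[b]]$features[perm, ]
  }
  embp <- sgat_embed(model, dgp, scaling = NULL)
  for (b in seq_along(emb)) {
    expect_equal(embp[[b]], emb[[b]][perm, ], tolerance = 1e-12)
  }

  # zero adjacency: embeddings depend on own features only
  dgz <- dg
  for (b in seq_along(dgz$snapshots)) dgz$snapshots[[b]]$adjacency[] <- 0
  embz <- sgat_embed(model, dgz, scaling = NULL)
  dgz2 <- dgz
  dgz2$snapshots[[1]]$features[2, ] <- dgz2$snapshots[[1]]$features[2, ] + 5
  embz2 <- sgat_embed(model, dgz2, scaling = NULL)
  expect_equal(embz2[[1]][-2, ], embz[[1]][-2, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(embz2[[1]][2, ], embz[[1]][2, ])))

  # masked snapshot embeds to the image of zero input
  dgm <- mask_band(dg, "theta")
  embm <- sgat_embed(model, dgm, scaling = NULL)
  expect_equal(embm[[2]], matrix(0, 8, cfg$gat_out), tolerance = 1e-12)
})

test_that("the convolution stage matches the quadruple-loop oracle", {
  # 1x1 kernel, unit weight: ReLU of the input channel
  X <- matrix(rnorm(12), 3, 4)
  out <- conv_forward(list(X), matrix(1, 1, 1), 0, c(1L, 1L))
  expect_equal(out[[1]], pmax(X, 0))

  # all-ones 2x2 kernel on all-ones 4x4 input: interior values 4
  out2 <- conv_forward(list(matrix(1, 4, 4)), matrix(1, 1, 4), 0, c(2L, 2L))
  expect_equal(out2[[1]], matrix(4, 3, 3))

  # random multi-channel kernels vs the direct summation oracle
  set.seed(6)
  channels <- lapply(1:4, function(b) matrix(rnorm(40), 8, 5))
  K <- matrix(rnorm(3 * 4 * 2 * 2), 3, 16)
  bconv <- rnorm(3)
  expect_equal(conv_forward(channels, K, bconv, c(2L, 2L)),
    oracle_conv(channels, K, bconv, c(2L, 2L)), tolerance = 1e-12)

  expect_error(conv_forward(list(matrix(1, 2, 2)), matrix(1, 1, 9), 0,
    c(3L, 3L)), "kernel larger")
})

test_that("classification head produces calibrated probabilities", {
  cfg <- tiny_config()
  dg <- toy_graph(seed = 7, class_id = 1)
  model <- sgatcn_init(cfg)
  p <- sgatcn_predict(model, dg, scaling = NULL)
  expect_length(p, 3L)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))

  # zeroed final layer: exactly uniform probabilities
  model0 <- workloadnet:::ensure_fc(model, dg)
  model0$params$Wfc[] <- 0
  model0$params$bfc[] <- 0
  expect_equal(sgatcn_predict(model0, dg, scaling = NULL), rep(1 / 3, 3),
    tolerance = 1e-12)

  # shifting all logits by a constant leaves probabilities unchanged
  modelc <- model0
  modelc$params$bfc[] <- 7.5
  expect_equal(sgatcn_predict(modelc, dg, scaling = NULL), rep(1 / 3, 3),
    tolerance = 1e-12)
})

test_that("backpropagation matches central finite differences", {
  cfg <- tiny_config(seed = 3)
  dg <- toy_graph(seed = 11, class_id = 0)
  model <- workloadnet:::ensure_fc(sgatcn_init(cfg), dg)
  params <- model$params
  adjl <- list(workloadnet:::dg_to_adj(dg))
  featl <- list(workloadnet:::dg_to_feats(dg))
  g <- workloadnet:::sgatcn_batch_grad_cpp(params, adjl, featl, 0L)
  lossfn <- function(p) {
    workloadnet:::sgatcn_batch_grad_cpp(p, adjl, featl, 0L)$loss
  }
  set.seed(9)
  h <- 1e-5
  checked <- 0L
  for (nm in c("W1", "a1s", "a1d", "W2", "a2s", "a2d", "K", "bconv",
    "Wfc", "bfc")) {
    for (ii in sample(length(params[[nm]]), min(2, length(params[[nm]])))) {
      pp <- params
      pp[[nm]][ii] <- pp[[nm]][ii] + h
      pm <- params
      pm[[nm]][ii] <- pm[[nm]][ii] - h
      fd <- (lossfn(pp) - lossfn(pm)) / (2 * h)
      an <- g$grads[[nm]][ii]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 10L)
})

test_that("training descends, separates separable classes, and is deterministic", {
  dgs <- toy_dataset(60)
  cfg <- tiny_config(epochs = 200L)

  # one Adam step on a fixed batch reduces that batch's loss
  # (averaged over 5 seeds)
  deltas <- vapply(1:5, function(s) {
    cfg1 <- tiny_config(epochs = 1L, batch_size = 60L, seed = s)
    m0 <- workloadnet:::ensure_fc(sgatcn_init(cfg1), dgs[[1]])
    adjs <- lapply(dgs, workloadnet:::dg_to_adj)
    feats <- lapply(dgs, workloadnet:::dg_to_feats, scaling = NULL)
    y <- match(vapply(dgs, `[[`, character(1), "label"),
      c("low", "medium", "high")) - 1L
    before <- workloadnet:::sgatcn_batch_grad_cpp(m0$params, adjs, feats, y)
    m1 <- sgatcn_train(dgs, cfg1, scale_features = FALSE)
    after <- workloadnet:::sgatcn_batch_grad_cpp(m1$params, adjs, feats, y)
    before$loss - after$loss
  }, numeric(1))
  expect_gt(mean(deltas), 0)

  # strongly separable 3-class toy data: high training accuracy
  model <- sgatcn_train(dgs, cfg)
  expect_gte(utils::tail(model$history$train_acc, 1), 0.95)
  expect_equal(mean(sgatcn_classify(model, dgs) ==
    vapply(dgs, `[[`, character(1), "label")), 1, tolerance = 0.05)

  # bit-identical loss curves under the same seed
  model2 <- sgatcn_train(dgs, cfg)
  expect_identical(model$history$loss, model2$history$loss)

  expect_error(sgatcn_train(list(), cfg), "empty")
})

test_that("model checkpoints round-trip through the JSON archive", {
  dgs <- toy_dataset(12)
  cfg <- tiny_config(epochs = 3L)
  model <- sgatcn_train(dgs, cfg)
  path <- file.path(tempdir(), "ckpt.json")
  save_sgatcn(model, path)
  back <- load_sgatcn(path)
  expect_equal(back$params$W1, model$params$W1, tolerance = 1e-12)
  expect_equal(back$params$Wfc, model$params$Wfc, tolerance = 1e-12)
  expect_equal(back$scaling$center, model$scaling$center,
    tolerance = 1e-12)
  expect_equal(back$config$seed, cfg$seed)
  expect_equal(back$history$loss, model$history$loss, tolerance = 1e-10)
  # identical predictions after reload
  p1 <- sgatcn_predict(model, dgs[[1]])
  p2 <- sgatcn_predict(back, dgs[[1]])
  expect_equal(p1, p2, tolerance = 1e-12)
  unlink(c(path, paste0(path, ".history.csv")))
})
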