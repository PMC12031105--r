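#' SGATCN model configuration
#'
#' Hyperparameters of the stacked graph-attention + convolution
#' network. Defaults follow the reference training recipe (800
#' epochs, learning rate 0.001, batch size 30) with a single
#' attention head, GAT hidden size 16 and output size 8, and an
#' 8-filter 3x3 valid convolution over the band-stacked embedding
#' plane.
#'
#' @param in_features Node feature length per snapshot (2: PSD, DE).
#' @param gat_hidden First GAT layer output size.
#' @param gat_out Second GAT layer output size.
#' @param n_heads Attention heads (single-head supported).
#' @param leaky_slope LeakyReLU negative slope in the attention.
#' @param conv_filters Convolution output channels.
#' @param conv_kernel Kernel size `c(rows, cols)`.
#' @param n_classes Number of workload classes.
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param clip_norm Gradient-norm clipping threshold.
#' @param seed Integer seed for initialization and shuffling.
#' @return An object of class `sgatcn_config`.
#' @export
sgatcn_config <- function(in_features = 2L, gat_hidden = 16L, gat_out = 8L,
                          n_heads = 1L, leaky_slope = 0.2,
                          conv_filters = 8L, conv_kernel = c(3L, 3L),
                          n_classes = 3L, epochs = 800L,
                          learning_rate = 0.001, batch_size = 30L,
                          clip_norm = 5, seed = 1L) {
  stopifnot(epochs >= 1L, n_classes >= 2L, learning_rate > 0,
    n_heads == 1L, batch_size >= 1L)
  structure(
    list(
      in_features = as.integer(in_features),
      gat_hidden = as.integer(gat_hidden),
      gat_out = as.integer(gat_out),
      n_heads = as.integer(n_heads),
      leaky_slope = leaky_slope,
      conv_filters = as.integer(conv_filters),
      conv_kernel = as.integer(conv_kernel),
      n_classes = as.integer(n_classes),
      epochs = as.integer(epochs),
      learning_rate = learning_rate,
      batch_size = as.integer(batch_size),
      clip_norm = clip_norm,
      seed = as.integer(seed)
    ),
    class = "sgatcn_config"
  )
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize SGATCN parameters
#'
#' Glorot-uniform weight matrices, zero biases; fully reproducible
#' from `config$seed`.
#'
#' @param config A [sgatcn_config()].
#' @param n_bands Number of discrete-graph snapshots (4).
#' @return Named parameter list (class `sgatcn_model`).
#' @export
sgatcn_init <- function(config, n_bands = 4L) {
  set.seed(config$seed)
  kr <- config$conv_kernel[1]
  kc <- config$conv_kernel[2]
  params <- list(
    W1 = glorot(config$in_features, config$gat_hidden),
    a1s = stats::runif(config$gat_hidden, -0.1, 0.1),
    a1d = stats::runif(config$gat_hidden, -0.1, 0.1),
    W2 = glorot(config$gat_hidden, config$gat_out),
    a2s = stats::runif(config$gat_out, -0.1, 0.1),
    a2d = stats::runif(config$gat_out, -0.1, 0.1),
    K = glorot(config$conv_filters, n_bands * kr * kc),
    bconv = numeric(config$conv_filters),
    conv_kernel = config$conv_kernel,
    leaky_slope = config$leaky_slope
  )
  # FC dimensions depend on the node count; deferred until first use
  structure(
    list(params = params, config = config, n_bands = as.integer(n_bands),
      fc_ready = FALSE),
    class = "sgatcn_model"
  )
}

dg_to_adj <- function(dg) lapply(dg$snapshots, function(s) {
  m <- s$adjacency
  storage.mode(m) <- "double"
  m
})

dg_to_feats <- function(dg, scaling = NULL) {
  lapply(seq_along(dg$snapshots), function(b) {
    v <- dg$snapshots[[b]]$features
    if (!is.null(scaling)) {
      v <- sweep(sweep(v, 2L, scaling$center[b, ]), 2L, scaling$scale[b, ],
        "/")
      # masked (all-zero) snapshots stay exactly zero
      if (all(dg$snapshots[[b]]$adjacency == 0) &&
            all(dg$snapshots[[b]]$features == 0)) {
        v[] <- 0
      }
    }
    v
  })
}

ensure_fc <- function(model, dg) {
  if (model$fc_ready) {
    return(model)
  }
  cfg <- model$config
  n_nodes <- nrow(dg$snapshots[[1]]$adjacency)
  orr <- n_nodes - cfg$conv_kernel[1] + 1L
  occ <- cfg$gat_out - cfg$conv_kernel[2] + 1L
  if (orr < 1L || occ < 1L) stop("convolution kernel larger than input")
  flat <- cfg$conv_filters * orr * occ
  set.seed(cfg$seed + 1L)
  model$params$Wfc <- glorot(cfg$n_classes, flat)
  model$params$bfc <- numeric(cfg$n_classes)
  model$fc_ready <- TRUE
  model
}

#' Class probabilities for one discrete graph
#'
#' Full forward pass: shared two-layer GAT per band snapshot,
#' band-stacked convolution, flatten, fully connected, softmax.
#'
#' @param model A `sgatcn_model` (trained or freshly initialized).
#' @param dg A `discrete_graph`.
#' @param scaling Optional feature-scaling statistics from training.
#' @return Probability vector over classes (sums to 1).
#' @export
sgatcn_predict <- function(model, dg, scaling = model$scaling) {
  model <- ensure_fc(model, dg)
  if (length(dg$snapshots) != model$n_bands) {
    stop("discrete graph must have ", model$n_bands, " snapshots")
  }
  out <- sgatcn_forward_cpp(model$params, dg_to_adj(dg),
    dg_to_feats(dg, scaling))
  as.numeric(out$probs)
}

#' Band-stacked GAT embeddings
#'
#' Runs only the stacked graph-attention stage and returns the
#' per-band node embeddings (list of `nodes x gat_out` matrices in
#' band order).
#'
#' @inheritParams sgatcn_predict
#' @export
sgat_embed <- function(model, dg, scaling = model$scaling) {
  model <- ensure_fc(model, dg)
  sgat_embed_cpp(model$params, dg_to_adj(dg), dg_to_feats(dg, scaling))
}

#' Attention coefficients of a single GAT layer
#'
#' Exposes the normalized attention matrix `a_ij` (rows sum to 1 over
#' each node's closed neighbourhood; zero outside it) for a given
#' adjacency, feature matrix and layer parameters.
#'
#' @param features `nodes x in_features` matrix.
#' @param adjacency Binary symmetric adjacency (self-loops added
#'   internally).
#' @param W Weight matrix `in_features x out_features`.
#' @param a Attention vector of length `2 * out_features`
#'   (concatenation `[a_src; a_dst]`).
#' @param leaky_slope LeakyReLU negative slope.
#' @return `nodes x nodes` attention matrix.
#' @export
attention_coefficients <- function(features, adjacency, W, a,
                                   leaky_slope = 0.2) {
  fp <- ncol(W)
  stopifnot(length(a) == 2L * fp)
  gat_attention_cpp(features, adjacency, W, a[seq_len(fp)],
    a[fp + seq_len(fp)], leaky_slope)
}

#' One GAT layer update
#'
#' Attention-weighted aggregation of transformed neighbour features
#' followed by the ELU nonlinearity.
#'
#' @inheritParams attention_coefficients
#' @return `nodes x out_features` updated feature matrix.
#' @export
gat_update <- function(features, adjacency, W, a, leaky_slope = 0.2) {
  fp <- ncol(W)
  stopifnot(length(a) == 2L * fp)
  gat_layer_cpp(features, adjacency, W, a[seq_len(fp)],
    a[fp + seq_len(fp)], leaky_slope)
}

#' Convolution stage of the classifier
#'
#' Valid 2-D convolution (cross-correlation indexing, the deep-
#' learning convention) of the band-stacked embedding plane:
#' `channels` are treated as input channels, each row of `K` holds
#' one filter's weights in channel-major, row-major patch order, and
#' ReLU is applied.
#'
#' @param channels List of equally-sized numeric matrices (one per
#'   band).
#' @param K Filter matrix `filters x (channels * kr * kc)`.
#' @param bconv Per-filter bias.
#' @param kernel `c(kr, kc)` kernel size.
#' @return List of `filters` feature-map matrices of size
#'   `(rows - kr + 1) x (cols - kc + 1)`.
#' @export
conv_forward <- function(channels, K, bconv = numeric(nrow(K)),
                         kernel = c(3L, 3L)) {
  conv_forward_cpp(channels, K, bconv, as.integer(kernel))
}

label_codes <- function(labels, class_levels) {
  codes <- match(labels, class_levels) - 1L
  if (anyNA(codes)) stop("label outside the model's class set")
  codes
}

#' Feature-scaling statistics over a training set
#'
#' Per-band, per-feature mean and SD of the node features, computed
#' on the training graphs only.
#' @keywords internal
fit_scaling <- function(dataset) {
  n_bands <- length(dataset[[1]]$snapshots)
  n_feat <- ncol(dataset[[1]]$snapshots[[1]]$features)
  center <- matrix(0, n_bands, n_feat)
  scale <- matrix(1, n_bands, n_feat)
  for (b in seq_len(n_bands)) {
    vals <- do.call(rbind, lapply(dataset, function(dg) {
      dg$snapshots[[b]]$features
    }))
    center[b, ] <- colMeans(vals)
    s <- apply(vals, 2L, stats::sd)
    s[s == 0 | !is.finite(s)] <- 1
    scale[b, ] <- s
  }
  list(center = center, scale = scale)
}

#' Train the SGATCN classifier
#'
#' Minimizes cross-entropy with Adam over minibatches; weight
#' initialization and epoch shuffling are derived from
#' `config$seed`, so identical inputs and seed give identical loss
#' curves. Node features are z-scored with statistics fitted on the
#' training set (reused at prediction time).
#'
#' @param dataset List of labelled `discrete_graph`s.
#' @param config A [sgatcn_config()].
#' @param class_levels Class label order; defaults to
#'   low/medium/high.
#' @param scale_features Fit and apply per-band feature z-scoring.
#' @param verbose Print progress every 50 epochs.
#' @return A trained `sgatcn_model` with `history` (per-epoch mean
#'   loss and training accuracy) and `scaling`.
#' @export
sgatcn_train <- function(dataset, config = sgatcn_config(),
                         class_levels = c("low", "medium", "high"),
                         scale_features = TRUE, verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty training set")
  labels <- vapply(dataset, `[[`, character(1), "label")
  y <- label_codes(labels, class_levels)
  model <- sgatcn_init(config, n_bands = length(dataset[[1]]$snapshots))
  model <- ensure_fc(model, dataset[[1]])
  model$class_levels <- class_levels
  scaling <- if (scale_features) fit_scaling(dataset) else NULL
  model$scaling <- scaling
  # neighbourhood lists are static across epochs: precompute once
  adjs <- lapply(dataset, function(dg) adj_to_csr_cpp(dg_to_adj(dg)))
  feats <- lapply(dataset, dg_to_feats, scaling = scaling)

  trainable <- setdiff(names(model$params), c("conv_kernel", "leaky_slope"))
  m1 <- lapply(model$params[trainable], function(p) p * 0)
  m2 <- m1
  beta1 <- 0.9
  beta2 <- 0.999
  eps <- 1e-8
  t_step <- 0L
  n <- length(dataset)
  history <- data.frame(epoch = integer(), loss = numeric(),
    train_acc = numeric())
  set.seed(config$seed + 2L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    correct <- 0L
    for (batch in batches) {
      out <- sgatcn_batch_grad_cpp(model$params, adjs[batch], feats[batch],
        y[batch])
      if (!is.finite(out$loss)) {
        stop("non-finite training loss at epoch ", ep)
      }
      ep_loss <- ep_loss + out$loss * length(batch)
      pred <- max.col(out$probs) - 1L
      correct <- correct + sum(pred == y[batch])
      g <- out$grads[trainable]
      gnorm <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
      if (is.finite(config$clip_norm) && gnorm > config$clip_norm) {
        g <- lapply(g, function(x) x * (config$clip_norm / gnorm))
      }
      t_step <- t_step + 1L
      for (nm in trainable) {
        m1[[nm]] <- beta1 * m1[[nm]] + (1 - beta1) * g[[nm]]
        m2[[nm]] <- beta2 * m2[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- m1[[nm]] / (1 - beta1^t_step)
        vhat <- m2[[nm]] / (1 - beta2^t_step)
        model$params[[nm]] <- model$params[[nm]] -
          config$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    history[ep, ] <- list(ep, ep_loss / n, correct / n)
    if (verbose && ep %% 50L == 0L) {
      message(sprintf("epoch %d: loss %.4f acc %.3f", ep, ep_loss / n,
        correct / n))
    }
  }
  model$history <- history
  model
}

#' Predicted class labels for a list of discrete graphs
#'
#' @param model Trained `sgatcn_model`.
#' @param dataset List of `discrete_graph`s.
#' @return Character vector of predicted class labels.
#' @export
sgatcn_classify <- function(model, dataset) {
  model <- ensure_fc(model, dataset[[1]])
  adjs <- lapply(dataset, function(dg) adj_to_csr_cpp(dg_to_adj(dg)))
  feats <- lapply(dataset, dg_to_feats, scaling = model$scaling)
  probs <- sgatcn_predict_batch_cpp(model$params, adjs, feats)
  model$class_levels[max.col(probs)]
}

#' Save / load an SGATCN model checkpoint
#'
#' The checkpoint is a single JSON archive holding the
#' configuration (including the seed), all weight matrices, the
#' feature-scaling statistics and the class levels; the training
#' history is written alongside as CSV (`<path>.history.csv`) when
#' present.
#'
#' @param model A `sgatcn_model`.
#' @param path Checkpoint file path (JSON).
#' @export
save_sgatcn <- function(model, path) {
  ckpt <- list(
    config = model$config[setdiff(names(model$config), character())],
    n_bands = model$n_bands,
    fc_ready = model$fc_ready,
    class_levels = model$class_levels,
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p)) else p
    }),
    scaling = if (!is.null(model$scaling)) {
      lapply(model$scaling, function(m) list(dim = dim(m),
        data = as.vector(m)))
    }
  )
  jsonlite::write_json(ckpt, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(model$history)) {
    utils::write.csv(model$history, paste0(path, ".history.csv"),
      row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_sgatcn
#' @export
load_sgatcn <- function(path) {
  ckpt <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(sgatcn_config, ckpt$config[names(ckpt$config) %in%
    names(formals(sgatcn_config))])
  restore <- function(p) {
    if (is.list(p) && !is.null(p$dim)) {
      matrix(p$data, p$dim[1], p$dim[2])
    } else if (is.numeric(p)) {
      as.numeric(p)
    } else {
      p
    }
  }
  params <- lapply(ckpt$params, restore)
  params$conv_kernel <- as.integer(params$conv_kernel)
  model <- structure(
    list(params = params, config = cfg,
      n_bands = as.integer(ckpt$n_bands), fc_ready = ckpt$fc_ready),
    class = "sgatcn_model"
  )
  model$class_levels <- ckpt$class_levels
  if (!is.null(ckpt$scaling)) {
    model$scaling <- lapply(ckpt$scaling, restore)
  }
  hist_path <- paste0(path, ".history.csv")
  if (file.exists(hist_path)) {
    model$history <- utils::read.csv(hist_path)
  }
  model
}
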