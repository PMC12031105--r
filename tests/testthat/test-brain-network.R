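test_that("proportional thresholding keeps the contracted edge count", {
  set.seed(1)
  n <- 59
  M <- matrix(runif(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  adj <- sparsify(M, 0.3)
  expect_equal(sum(adj) / 2, 513) # floor(0.3 * 1711)
  expect_identical(adj, t(adj))
  expect_true(all(diag(adj) == 0))

  # edge-count formula across the sparsity grid on random matrices
  for (sp in seq(0.1, 0.9, by = 0.1)) {
    expect_equal(sum(sparsify(M, sp)) / 2, floor(sp * n * (n - 1) / 2))
  }

  # near-1 sparsity with distinct weights keeps every pair
  small <- matrix(0, 5, 5)
  small[upper.tri(small)] <- (1:10) / 10
  small <- small + t(small)
  expect_equal(sum(sparsify(small, 0.999)) / 2, 9) # floor(.999*10)

  # all-equal weights: deterministic lexicographic tie-break
  ties <- matrix(1, 8, 8)
  diag(ties) <- 0
  a1 <- sparsify(ties, 0.1)
  a2 <- sparsify(ties, 0.1)
  expect_identical(a1, a2)
  ut <- which(upper.tri(ties), arr.ind = TRUE)
  expected_first <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE][
    seq_len(floor(0.1 * 28)), , drop = FALSE]
  expect_true(all(a1[expected_first] == 1))

  expect_error(sparsify(M, 0), "sparsity")
  expect_error(sparsify(M, 1), "sparsity")
})

test_that("graph metrics take exact values on canonical graphs", {
  k3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(clustering_coefficient(k3)$ci, rep(1, 3))

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- 1
  star <- star + t(star)
  expect_equal(clustering_coefficient(star)$ci, rep(0, 5))
  expect_equal(local_efficiency(star), rep(0, 5))

  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(path_lengths(k5)$L, 1)
  expect_equal(global_efficiency(k5), 1)

  # path 1-2-3: L = 4/3, E_glob = 5/6
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 3] <- 1
  p3 <- p3 + t(p3)
  expect_equal(path_lengths(p3)$L, 4 / 3)
  expect_equal(global_efficiency(p3), 5 / 6)

  # K4: every neighbour subgraph is K3, all four metrics are 1
  k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(clustering_coefficient(k4)$cc, 1)
  expect_equal(path_lengths(k4)$L, 1)
  expect_equal(global_efficiency(k4), 1)
  expect_equal(local_efficiency(k4), rep(1, 4))

  # edgeless graph: efficiency zero by the stated rule, L undefined
  z <- matrix(0, 4, 4)
  expect_equal(global_efficiency(z), 0)
  expect_error(path_lengths(z), "undefined")
})

test_that("metrics equal brute-force oracles on 50 random graphs", {
  for (s in 1:50) {
    n <- sample(4:15, 1)
    adj <- random_sym_adj(n, runif(1, 0.2, 0.7), seed = s)
    if (sum(adj) == 0) { # guarantee one connected pair
      adj[1, 2] <- adj[2, 1] <- 1L
    }
    expect_equal(clustering_coefficient(adj)$ci, oracle_clustering(adj),
      tolerance = 1e-12)
    D <- path_lengths(adj)$lengths
    expect_equal(unname(D), oracle_distances(adj), tolerance = 1e-12,
      ignore_attr = TRUE)
    expect_equal(global_efficiency(adj), oracle_global_efficiency(adj),
      tolerance = 1e-12)
    expect_equal(local_efficiency(adj), oracle_local_efficiency(adj),
      tolerance = 1e-12)
  }
})

test_that("global efficiency is monotone under edge addition", {
  set.seed(6)
  adj <- random_sym_adj(12, 0.15, seed = 6)
  e <- global_efficiency(adj)
  missing <- which(upper.tri(adj) & adj == 0, arr.ind = TRUE)
  for (k in sample(nrow(missing), 10)) {
    adj2 <- adj
    adj2[missing[k, 1], missing[k, 2]] <- 1
    adj2[missing[k, 2], missing[k, 1]] <- 1
    expect_gte(global_efficiency(adj2), e)
  }
})

test_that("small-world sigma separates lattice-like from random graphs", {
  # Erdos-Renyi: sigma ~ 1
  set.seed(7)
  er <- random_sym_adj(50, 0.2, seed = 7)
  sw <- small_world_sigma(er, n_surrogates = 20, seed = 1)
  expect_equal(sw$sigma, 1, tolerance = 0.2)

  # Watts-Strogatz ring: sigma > 1
  set.seed(8)
  ws_g <- igraph::sample_smallworld(1, 50, 3, 0.1)
  ws <- as.matrix(igraph::as_adjacency_matrix(ws_g, sparse = FALSE))
  ws[ws > 1] <- 1
  sw2 <- small_world_sigma(ws, n_surrogates = 20, seed = 2)
  expect_gt(sw2$sigma, 1)

  # surrogate randomization preserves the degree sequence exactly
  g <- igraph::graph_from_adjacency_matrix(er != 0, mode = "undirected")
  set.seed(3)
  gs <- igraph::rewire(g, igraph::keeping_degseq(niter = 1000))
  expect_identical(igraph::degree(gs), igraph::degree(g))

  # same seed, same sigma
  expect_identical(
    small_world_sigma(er, n_surrogates = 5, seed = 9)$sigma,
    small_world_sigma(er, n_surrogates = 5, seed = 9)$sigma
  )
})

test_that("one-way level ANOVA matches closed-form and aov", {
  identical_groups <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(anova_levels(identical_groups)$f, 0)

  equal_means <- list(c(-1, 1), c(-2, 2), c(-3, 3))
  expect_lt(anova_levels(equal_means)$f, 1e-12)

  # textbook case vs stats::aov
  g <- list(c(6, 8, 4, 5, 3, 4), c(8, 12, 9, 11, 6, 8), c(13, 9, 11, 8, 7, 12))
  res <- anova_levels(g)
  y <- unlist(g)
  f <- factor(rep(1:3, each = 6))
  ref <- summary(stats::aov(y ~ f))[[1]]
  expect_equal(res$f, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(res$p, ref[1, "Pr(>F)"], tolerance = 1e-10)

  expect_error(anova_levels(list(1:3)), "2 groups")
  expect_error(anova_levels(list(1, 2, 3)), "2 samples")
})

test_that("significant-node counting recovers the planted fraction", {
  set.seed(10)
  n_nodes <- 59L
  n_per <- 40L
  shifted <- seq_len(30L)
  mk <- function(shift) {
    m <- matrix(rnorm(n_per * n_nodes, sd = 0.1), n_per, n_nodes)
    m[, shifted] <- m[, shifted] + shift
    m
  }
  samples <- list(mk(0), mk(1), mk(2)) # shift >> noise on 30 nodes
  res <- significant_node_fraction(samples, alpha = 0.05)
  expect_equal(res$fraction, 30 / 59, tolerance = 0.02)

  # identical samples across levels: between-group variance is zero,
  # so F = 0 and nothing is significant
  base <- matrix(rnorm(4 * 59), 4, 59)
  flat <- list(base, base, base)
  expect_equal(significant_node_fraction(flat)$fraction, 0)
  expect_equal(significant_node_fraction(samples, alpha = 1)$fraction, 1)
})

test_that("feature ranking scores level-separating features first", {
  expect_equal(floor(0.05 * 6844), 342)
  set.seed(11)
  n <- 90
  labels <- rep(c("low", "medium", "high"), each = 30)
  feats <- matrix(rnorm(n * 40), n, 40)
  feats[, 7] <- feats[, 7] + (as.integer(factor(labels,
    c("low", "medium", "high"))) - 1) * 5
  res <- rank_connection_features(feats, labels, top_percent = 5)
  expect_equal(res$ranking[1], 7L)
  expect_equal(res$n_top, 2L) # floor(0.05 * 40)
  expect_true(res$mask[7])

  # closed-form F agrees with aov on sampled columns
  for (j in c(1, 7, 20)) {
    ref <- summary(stats::aov(feats[, j] ~ factor(labels)))[[1]][1, "F value"]
    expect_equal(res$scores[j], ref, tolerance = 1e-8)
  }

  # constant features score zero and rank last
  feats[, 3] <- 1
  res2 <- rank_connection_features(feats, labels)
  expect_equal(res2$scores[3], 0)
  expect_equal(res2$ranking[40], 3L)

  # top 100% keeps everything
  res3 <- rank_connection_features(feats, labels, top_percent = 100)
  expect_true(all(res3$mask))
})

test_that("discrete-graph assembly enforces band order and masking", {
  bands <- c("delta", "theta", "alpha", "beta")
  adj <- stats::setNames(lapply(bands, function(b) {
    random_sym_adj(5, 0.5, seed = match(b, bands))
  }), bands)
  nf <- stats::setNames(lapply(bands, function(b) matrix(1, 5, 2)), bands)
  dg <- assemble_discrete_graph(adj, nf, label = "low", task = "t",
    band_order = rev(bands))
  expect_equal(vapply(dg$snapshots, `[[`, character(1), "band"),
    rev(bands))
  dg2 <- assemble_discrete_graph(adj, nf, label = "low", task = "t")
  expect_equal(vapply(dg2$snapshots, `[[`, character(1), "band"), bands)

  masked <- mask_band(dg2, "theta")
  expect_true(all(masked$snapshots[[2]]$adjacency == 0))
  expect_true(all(masked$snapshots[[2]]$features == 0))
  expect_false(all(masked$snapshots[[1]]$adjacency == 0))
  expect_error(mask_band(dg2, "gamma"), "unknown band")

  expect_error(assemble_discrete_graph(adj[1:3], nf, "low", "t"),
    "missing band")
  nf_bad <- nf
  nf_bad$beta <- matrix(1, 4, 2)
  expect_error(assemble_discrete_graph(adj, nf_bad, "low", "t"),
    "inconsistent channel count")
})

test_that("per-epoch graph metric reports feed level ANOVA", {
  set.seed(12)
  mats <- lapply(1:18, function(e) {
    lv <- (e - 1) %/% 6 # denser connectivity at higher levels
    M <- matrix(runif(15 * 15, 0, 1), 15, 15) + lv * 0.3 * random_sym_adj(15, 0.5, e)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    M
  })
  labels <- rep(c("low", "medium", "high"), each = 6)
  rep_out <- graph_metrics_report(mats, labels, sparsity = 0.5,
    n_surrogates = 5, seed = 3)
  expect_length(rep_out$sigma, 18L)
  expect_true(all(rep_out$global_efficiency >= 0 &
    rep_out$global_efficiency <= 1))
  expect_true(all(rep_out$clustering >= 0 & rep_out$clustering <= 1))
  expect_true(is.finite(rep_out$anova$sigma$f))
  expect_true(rep_out$node_fractions$clustering$fraction >= 0)
})
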