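#' Proportional thresholding of a connectivity matrix
#'
#' Keeps the `floor(sparsity * n * (n - 1) / 2)` strongest
#' upper-triangle weights, binarizes them to 1 and mirrors to a
#' symmetric adjacency with zero diagonal. Ties are broken by
#' (row, column) lexicographic order, so the result is deterministic.
#'
#' @param m Symmetric numeric matrix (connectivity weights).
#' @param sparsity Fraction of possible edges to keep, in (0, 1).
#' @return Binary symmetric adjacency matrix.
#' @export
sparsify <- function(m, sparsity) {
  if (sparsity <= 0 || sparsity >= 1) stop("sparsity must lie in (0, 1)")
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[ut]
  k <- floor(sparsity * n * (n - 1) / 2)
  adj <- matrix(0L, n, n)
  if (k > 0L) {
    ord <- order(-w, ut[, 1L], ut[, 2L])
    keep <- ord[seq_len(min(k, length(ord)))]
    adj[ut[keep, , drop = FALSE]] <- 1L
    adj <- adj + t(adj)
  }
  adj
}

adj_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
    diag = FALSE)
}

#' Node clustering coefficients
#'
#' `C_i = 2 t_i / (k_i (k_i - 1))` with `t_i` the number of triangles
#' through node `i` and `k_i` its degree; `C_i = 0` for degree < 2.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return List with per-node `ci` and their mean `cc`.
#' @export
clustering_coefficient <- function(adj) {
  A <- (adj != 0) * 1
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ci <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  list(ci = as.numeric(ci), cc = mean(ci))
}

#' Shortest path lengths and characteristic path length
#'
#' Unweighted shortest-path distances between all node pairs and
#' their average `L` over connected ordered pairs only; disconnected
#' pairs are `Inf` in the matrix and flagged.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return List with `lengths` (matrix, `Inf` where disconnected),
#'   characteristic path length `L`, and `disconnected` flag.
#' @export
path_lengths <- function(adj) {
  g <- adj_graph(adj)
  D <- igraph::distances(g)
  off <- D[upper.tri(D)]
  finite <- is.finite(off)
  if (!any(finite)) stop("graph has no connected pair: L undefined")
  list(
    lengths = D,
    L = mean(off[finite]),
    disconnected = any(!finite)
  )
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the reciprocal shortest-path
#' length, with `1/Inf = 0` for disconnected pairs. 1 for a complete
#' graph, 0 for an edgeless one.
#'
#' @param adj Binary symmetric adjacency matrix (>= 2 nodes).
#' @return Efficiency in \[0, 1\].
#' @export
global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2L) {
    return(0)
  }
  D <- igraph::distances(adj_graph(adj))
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency per node
#'
#' Global efficiency of the subgraph induced by each node's
#' neighbours (the node itself excluded); 0 for nodes of degree < 2.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return Numeric vector of per-node local efficiencies in \[0, 1\].
#' @export
local_efficiency <- function(adj) {
  A <- (adj != 0) * 1
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    if (length(nb) < 2L) {
      return(0)
    }
    global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
}

#' Small-world coefficient against degree-preserving surrogates
#'
#' `sigma = (CC / CC_r) / (L / L_r)`, where `CC_r` and `L_r` are the
#' mean clustering coefficient and characteristic path length of
#' degree-preserving randomized surrogates (double-edge swaps).
#' `sigma > 1` indicates small-world topology. If the graph is
#' disconnected, the largest connected component is used, with a
#' warning.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @param n_surrogates Number of randomized surrogates.
#' @param seed Integer seed for the surrogate randomization.
#' @param swaps_per_edge Double-edge-swap attempts per edge.
#' @return List with `sigma`, `cc`, `l`, `cc_random`, `l_random`.
#' @export
small_world_sigma <- function(adj, n_surrogates = 100L, seed = 1L,
                              swaps_per_edge = 10) {
  g <- adj_graph(adj)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning("graph disconnected: using largest connected component")
    keep <- which(comp$membership == which.max(comp$csize))
    adj <- adj[keep, keep, drop = FALSE]
    g <- adj_graph(adj)
  }
  cc <- clustering_coefficient(adj)$cc
  l <- path_lengths(adj)$L
  n_edges <- igraph::ecount(g)
  if (n_edges < 2L) stop("too few edges for surrogate randomization")
  set.seed(seed)
  cc_r <- numeric(n_surrogates)
  l_r <- numeric(n_surrogates)
  for (s in seq_len(n_surrogates)) {
    gs <- igraph::rewire(
      g, igraph::keeping_degseq(niter = ceiling(swaps_per_edge * n_edges))
    )
    As <- as.matrix(igraph::as_adjacency_matrix(gs, sparse = FALSE))
    cc_r[s] <- clustering_coefficient(As)$cc
    Ds <- igraph::distances(gs)
    off <- Ds[upper.tri(Ds)]
    l_r[s] <- mean(off[is.finite(off)])
  }
  cc_random <- mean(cc_r)
  l_random <- mean(l_r)
  if (cc_random <= 0) stop("surrogate clustering is zero: sigma undefined")
  list(
    sigma = (cc / cc_random) / (l / l_random),
    cc = cc, l = l, cc_random = cc_random, l_random = l_random
  )
}

#' One-way ANOVA across workload levels
#'
#' Single-factor analysis of variance of a metric across level
#' groups.
#'
#' @param groups List (one element per level) of numeric samples,
#'   each of length >= 2.
#' @return List with `f` and `p`.
#' @export
anova_levels <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("need >= 2 samples per group")
  }
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (stats::var(y) == 0) {
    return(list(f = 0, p = 1))
  }
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  f <- unname(fit$statistic)
  if (!is.finite(f)) stop("undefined F: zero within-group variance")
  list(f = f, p = unname(fit$p.value))
}

#' Fraction of nodes with significant level differences
#'
#' Runs a per-node one-way ANOVA of a local metric across workload
#' levels and reports the fraction of nodes with `p < alpha`. No
#' multiplicity correction by default; Benjamini-Hochberg is
#' available via `adjust`.
#'
#' @param node_samples List (one element per level) of matrices
#'   `samples x nodes` holding the per-node metric for each
#'   observation at that level.
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List with `fraction`, per-node `p`, and the node count.
#' @export
significant_node_fraction <- function(node_samples, alpha = 0.05,
                                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  n_nodes <- ncol(node_samples[[1]])
  p <- vapply(seq_len(n_nodes), function(i) {
    groups <- lapply(node_samples, function(m) m[, i])
    out <- tryCatch(anova_levels(groups), error = function(e) NULL)
    if (is.null(out)) NA_real_ else out$p
  }, numeric(1))
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  ok <- !is.na(p)
  if (!any(ok)) stop("no node yielded a defined ANOVA")
  list(fraction = mean(p[ok] < alpha), p = p, n_nodes = n_nodes)
}

#' Graph metrics report across epochs and levels
#'
#' Computes per-epoch global metrics (small-world sigma, global
#' efficiency) and per-node local metrics (clustering, local
#' efficiency) for binarized per-epoch networks, then tests each
#' metric across workload levels by one-way ANOVA.
#'
#' @param mats List of connectivity matrices (one per epoch).
#' @param labels Workload level per epoch.
#' @param sparsity Proportional threshold for binarization.
#' @param n_surrogates Surrogates for sigma (per epoch).
#' @param seed Base seed for surrogate randomization.
#' @param alpha Significance level for node counting.
#' @return List with per-epoch metric tables, per-metric ANOVA
#'   results, and significant-node fractions.
#' @export
graph_metrics_report <- function(mats, labels, sparsity = 0.3,
                                 n_surrogates = 20L, seed = 1L,
                                 alpha = 0.05) {
  n_ep <- length(mats)
  stopifnot(length(labels) == n_ep)
  n_ch <- nrow(mats[[1]])
  sigma <- numeric(n_ep)
  eglob <- numeric(n_ep)
  ci <- matrix(0, n_ep, n_ch)
  eloc <- matrix(0, n_ep, n_ch)
  for (e in seq_len(n_ep)) {
    adj <- sparsify(unclass(mats[[e]]), sparsity)
    sw <- small_world_sigma(adj, n_surrogates = n_surrogates,
      seed = seed + e)
    sigma[e] <- sw$sigma
    eglob[e] <- global_efficiency(adj)
    ci[e, ] <- clustering_coefficient(adj)$ci
    eloc[e, ] <- local_efficiency(adj)
  }
  lv <- unique(labels)
  by_level <- function(x) lapply(lv, function(l) x[labels == l])
  by_level_m <- function(m) lapply(lv, function(l) m[labels == l, , drop = FALSE])
  list(
    sigma = sigma, global_efficiency = eglob,
    clustering = ci, local_efficiency = eloc,
    anova = list(
      sigma = anova_levels(by_level(sigma)),
      global_efficiency = anova_levels(by_level(eglob))
    ),
    node_fractions = list(
      clustering = significant_node_fraction(by_level_m(ci), alpha),
      local_efficiency = significant_node_fraction(by_level_m(eloc), alpha)
    ),
    levels = lv
  )
}

#' Rank pairwise connectivity features by level discriminability
#'
#' Scores every pairwise connectivity feature (channel pair x band)
#' by its one-way ANOVA F statistic across workload levels and
#' returns the descending ranking plus a top-`k` percent mask.
#' Constant features score 0 and rank last.
#'
#' @param features Numeric matrix `epochs x features` (e.g. the 6844
#'   upper-triangle PLV values over four bands).
#' @param labels Workload level per epoch (>= 2 distinct).
#' @param top_percent Percentage of features to retain.
#' @return List with `scores`, `ranking` (feature indices, best
#'   first), `mask` (logical top-k% indicator) and `n_top`.
#' @export
rank_connection_features <- function(features, labels, top_percent = 5) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 classes to rank features")
  n <- nrow(features)
  groups <- split(seq_len(n), labels)
  k <- length(groups)
  grand <- colMeans(features)
  ssb <- numeric(ncol(features))
  ssw <- numeric(ncol(features))
  for (g in groups) {
    gm <- colMeans(features[g, , drop = FALSE])
    ssb <- ssb + length(g) * (gm - grand)^2
    ssw <- ssw + colSums(
      sweep(features[g, , drop = FALSE], 2L, gm)^2
    )
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[!is.finite(f)] <- 0
  ranking <- order(-f, seq_along(f))
  n_top <- floor(top_percent / 100 * ncol(features))
  mask <- logical(ncol(features))
  mask[ranking[seq_len(n_top)]] <- TRUE
  list(scores = f, ranking = ranking, mask = mask, n_top = n_top)
}

#' Assemble a four-band discrete graph
#'
#' Bundles one binary adjacency and one node-feature matrix per band
#' into the ordered snapshot list (delta, theta, alpha, beta) that
#' the classifier consumes.
#'
#' @param adjacency Named list of binary adjacency matrices, one per
#'   band.
#' @param node_features Named list of `channels x features` matrices,
#'   one per band.
#' @param label Workload level.
#' @param task Task tag.
#' @param band_order Canonical snapshot order.
#' @return A `discrete_graph`: list of 4 snapshots (each with
#'   `adjacency`, `features`, `band`), plus `label` and `task`.
#' @export
assemble_discrete_graph <- function(adjacency, node_features, label, task,
                                    band_order = c("delta", "theta",
                                                   "alpha", "beta")) {
  missing <- setdiff(band_order, intersect(names(adjacency),
    names(node_features)))
  if (length(missing)) {
    stop("missing band snapshot(s): ", paste(missing, collapse = ", "))
  }
  n_ch <- nrow(adjacency[[band_order[1]]])
  snaps <- lapply(band_order, function(b) {
    a <- adjacency[[b]]
    v <- node_features[[b]]
    if (nrow(a) != n_ch || nrow(v) != n_ch) {
      stop("inconsistent channel count across band snapshots")
    }
    list(adjacency = a, features = v, band = b)
  })
  structure(
    list(snapshots = snaps, label = label, task = task),
    class = "discrete_graph"
  )
}

#' Zero out one band snapshot of a discrete graph
#'
#' Masking ("shielding") a band replaces its adjacency and node
#' features by zeros, leaving shapes unchanged.
#'
#' @param dg A `discrete_graph`.
#' @param band Band name to mask.
#' @return The masked `discrete_graph`.
#' @export
mask_band <- function(dg, band) {
  idx <- which(vapply(dg$snapshots, `[[`, character(1), "band") == band)
  if (!length(idx)) stop("unknown band: ", band)
  for (i in idx) {
    dg$snapshots[[i]]$adjacency[] <- 0
    dg$snapshots[[i]]$features[] <- 0
  }
  dg
}
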