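# Shared fixtures. The end-to-end dataset (one synthetic subject,
# 24-s blocks -> 216 labelled discrete graphs) is expensive to build,
# so it is memoised across test files.

fixture_env <- new.env(parent = emptyenv())

e2e_protocol <- function() session_protocol(block_duration = 24, seed = 42)

e2e_recordings <- function() {
  if (is.null(fixture_env$recs)) {
    fixture_env$recs <- generate_session(e2e_protocol(), subject = 1,
      fs = 200)
  }
  fixture_env$recs
}

e2e_graphs <- function() {
  if (is.null(fixture_env$graphs)) {
    fixture_env$graphs <- build_discrete_graphs(e2e_recordings(),
      method = "plv", sparsity = 0.3, notch = NULL)
  }
  fixture_env$graphs
}

# small fully synthetic discrete graphs with class-dependent feature
# means, for fast classifier tests without the signal pipeline
toy_graph <- function(seed, class_id, n_nodes = 6L,
                      label = c("low", "medium", "high")[class_id + 1L],
                      task = "t1") {
  set.seed(seed)
  bands <- c("delta", "theta", "alpha", "beta")
  adj <- lapply(bands, function(b) {
    A <- matrix(rbinom(n_nodes^2, 1, 0.4), n_nodes, n_nodes)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 0
    A
  })
  names(adj) <- bands
  nf <- lapply(bands, function(b) {
    matrix(rnorm(n_nodes * 2, mean = class_id * 2), n_nodes, 2)
  })
  names(nf) <- bands
  assemble_discrete_graph(adj, nf, label = label, task = task)
}

toy_dataset <- function(n = 60L, tasks = c("t1", "t2", "t3")) {
  # class cycles within each task block so task and class stay
  # unconfounded
  lapply(seq_len(n), function(k) {
    toy_graph(seed = 1000 + k, class_id = (k - 1L) %% 3L,
      task = tasks[1L + (((k - 1L) %/% 3L) %% length(tasks))])
  })
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(in_features = 2L, gat_hidden = 4L, gat_out = 3L,
      conv_filters = 2L, conv_kernel = c(2L, 2L), epochs = 40L,
      batch_size = 10L, seed = 7L),
    list(...)
  )
  do.call(sgatcn_config, args)
}
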