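#' Build labelled discrete graphs from raw recordings
#'
#' Full pipeline from a list of recordings to classifier-ready
#' four-band discrete graphs: preprocessing (resample, broadband +
#' notch, common-average reference, band decomposition, 3-s
#' segmentation), per-epoch per-band connectivity, proportional
#' thresholding, and (PSD, DE) node features.
#'
#' @param recordings List of [recording()]s with task/level metadata.
#' @param method Connectivity estimator (`"plv"`, `"pli"`, `"pcc"`,
#'   `"mi"`).
#' @param sparsity Proportional threshold for binarization.
#' @param target_fs Analysis sampling rate (Hz).
#' @param window_seconds Epoch length (s).
#' @param bands Band definitions.
#' @param n_bins Histogram bins for MI.
#' @param notch Notch band, or `NULL` to skip (synthetic data carries
#'   no mains interference; the default keeps the standard chain).
#' @param node_features_mode `"band"` (default): each snapshot carries
#'   its own band's (PSD, DE) 2-vector per node; `"all-bands"`: every
#'   snapshot carries the concatenated features of all four bands
#'   (feature length `2 * n_bands`).
#' @return List of `discrete_graph`s, one per epoch.
#' @export
build_discrete_graphs <- function(recordings, method = "plv",
                                  sparsity = 0.3, target_fs = 200,
                                  window_seconds = 3,
                                  bands = default_bands(), n_bins = 16L,
                                  notch = c(49, 51),
                                  node_features_mode = c("band", "all-bands")) {
  node_features_mode <- match.arg(node_features_mode)
  graphs <- list()
  for (rec in recordings) {
    band_epochs <- preprocess_recording(rec, target_fs = target_fs,
      window_seconds = window_seconds, bands = bands, notch = notch)
    feats <- build_node_features(band_epochs, bands)
    conn <- lapply(band_epochs, connectivity_matrix, method = method,
      n_bins = n_bins)
    n_ep <- dim(feats)[1]
    for (e in seq_len(n_ep)) {
      adjacency <- lapply(conn, function(mats) {
        sparsify(unclass(mats[[e]]), sparsity)
      })
      node_features <- lapply(names(bands), function(b) {
        if (node_features_mode == "band") {
          feats[e, b, , ]
        } else {
          do.call(cbind, lapply(names(bands), function(b2) feats[e, b2, , ]))
        }
      })
      names(node_features) <- names(bands)
      graphs[[length(graphs) + 1L]] <- assemble_discrete_graph(
        adjacency, node_features,
        label = rec$meta$level, task = rec$meta$task,
        band_order = names(bands)
      )
    }
  }
  graphs
}

#' Pairwise connectivity feature matrix across bands
#'
#' Per-epoch vector of all upper-triangle connectivity values over
#' the four bands (59 channels x 4 bands = 6844 features), used by
#' [rank_connection_features()].
#'
#' @param recordings List of [recording()]s.
#' @param method Connectivity estimator.
#' @inheritParams build_discrete_graphs
#' @return List with `features` (epochs x features matrix), `labels`,
#'   `task_tags`, and `feature_info` (band, channel pair per column).
#' @export
connectivity_feature_matrix <- function(recordings, method = "plv",
                                        target_fs = 200,
                                        window_seconds = 3,
                                        bands = default_bands(),
                                        n_bins = 16L, notch = c(49, 51)) {
  rows <- list()
  labels <- character()
  tasks <- character()
  info <- NULL
  for (rec in recordings) {
    band_epochs <- preprocess_recording(rec, target_fs = target_fs,
      window_seconds = window_seconds, bands = bands, notch = notch)
    conn <- lapply(band_epochs, connectivity_matrix, method = method,
      n_bins = n_bins)
    n_ep <- length(conn[[1]])
    n_ch <- nrow(conn[[1]][[1]])
    if (is.null(info)) {
      ut <- which(upper.tri(diag(n_ch)), arr.ind = TRUE)
      info <- do.call(rbind, lapply(names(bands), function(b) {
        data.frame(band = b, i = ut[, 1], j = ut[, 2])
      }))
    }
    for (e in seq_len(n_ep)) {
      v <- unlist(lapply(names(bands), function(b) {
        m <- unclass(conn[[b]][[e]])
        m[upper.tri(m)]
      }))
      rows[[length(rows) + 1L]] <- v
      labels <- c(labels, rec$meta$level)
      tasks <- c(tasks, rec$meta$task)
    }
  }
  list(
    features = do.call(rbind, rows), labels = labels, task_tags = tasks,
    feature_info = info
  )
}

#' Cached discrete-graph builder over a recording set
#'
#' Precomputes the expensive, sparsity-independent pipeline stages
#' (preprocessing, per-epoch per-band connectivity, node features)
#' once and returns a closure that assembles discrete graphs at any
#' requested sparsity — the natural input for [sparsity_sweep()].
#'
#' @inheritParams build_discrete_graphs
#' @return Function `(sparsity) -> list of discrete_graph`.
#' @export
discrete_graph_builder <- function(recordings, method = "plv",
                                   target_fs = 200, window_seconds = 3,
                                   bands = default_bands(), n_bins = 16L,
                                   notch = c(49, 51)) {
  cache <- list()
  for (rec in recordings) {
    band_epochs <- preprocess_recording(rec, target_fs = target_fs,
      window_seconds = window_seconds, bands = bands, notch = notch)
    feats <- build_node_features(band_epochs, bands)
    conn <- lapply(band_epochs, connectivity_matrix, method = method,
      n_bins = n_bins)
    cache[[length(cache) + 1L]] <- list(
      feats = feats, conn = conn,
      level = rec$meta$level, task = rec$meta$task
    )
  }
  band_names <- names(bands)
  function(sparsity) {
    graphs <- list()
    for (entry in cache) {
      n_ep <- dim(entry$feats)[1]
      for (e in seq_len(n_ep)) {
        adjacency <- lapply(entry$conn, function(mats) {
          sparsify(unclass(mats[[e]]), sparsity)
        })
        node_features <- stats::setNames(
          lapply(band_names, function(b) entry$feats[e, b, , ]),
          band_names
        )
        graphs[[length(graphs) + 1L]] <- assemble_discrete_graph(
          adjacency, node_features,
          label = entry$level, task = entry$task, band_order = band_names
        )
      }
    }
    graphs
  }
}
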