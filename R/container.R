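#' Multichannel EEG recording
#'
#' Lightweight container for one continuous recording block: a
#' channels x samples matrix plus sampling rate, montage labels and
#' subject/task/level/round metadata.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one label per channel.
#' @param meta Named list of metadata (subject, task, level, round).
#'
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, channel_labels = NULL, meta = list()) {
  data <- as.matrix(data)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("CH%02d", seq_len(nrow(data)))
  }
  if (nrow(data) != length(channel_labels)) {
    stop("data row count must equal the number of channel labels")
  }
  if (fs <= 0) stop("fs must be positive")
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels, meta = meta),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta),
      sep = "=", collapse = ", "
    ), "\n")
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A [recording()].
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Write a recording to the chunked array container
#'
#' The container is a directory holding the sample matrix as one or
#' more plain CSV chunks (`data_0001.csv`, ... — channels as columns,
#' samples as rows, split along time) and a `meta.json` sidecar with
#' the sampling rate, montage, metadata and chunk layout.
#'
#' @param rec A [recording()].
#' @param path Directory to create.
#' @param chunk_samples Samples per CSV chunk.
#' @export
write_recording <- function(rec, path, chunk_samples = 60000L) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- ncol(rec$data)
  starts <- seq(1L, n, by = chunk_samples)
  chunks <- character(length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:min(starts[k] + chunk_samples - 1L, n)
    chunk <- t(rec$data[, idx, drop = FALSE])
    colnames(chunk) <- rec$channel_labels
    chunks[k] <- sprintf("data_%04d.csv", k)
    utils::write.csv(chunk, file.path(path, chunks[k]), row.names = FALSE)
  }
  sidecar <- list(
    fs = rec$fs,
    channel_labels = rec$channel_labels,
    n_samples = n,
    chunk_samples = chunk_samples,
    chunks = chunks,
    meta = rec$meta
  )
  jsonlite::write_json(sidecar, file.path(path, "meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a recording from the chunked array container
#'
#' @param path Directory written by [write_recording()].
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  sidecar <- jsonlite::read_json(file.path(path, "meta.json"),
    simplifyVector = TRUE
  )
  parts <- lapply(sidecar$chunks, function(f) {
    as.matrix(utils::read.csv(file.path(path, f), check.names = FALSE))
  })
  data <- t(do.call(rbind, parts))
  recording(
    data = data, fs = sidecar$fs,
    channel_labels = sidecar$channel_labels,
    meta = as.list(sidecar$meta)
  )
}

#' Export a connectivity matrix to CSV
#'
#' Writes the matrix with channel labels as row and column names;
#' the file round-trips through [read_connectivity_csv()] (estimator
#' and band tags are not serialized).
#'
#' @param mat A `connectivity_matrix` (or plain symmetric matrix).
#' @param path Output CSV file.
#' @param channel_labels Optional channel labels.
#' @export
write_connectivity_csv <- function(mat, path, channel_labels = NULL) {
  m <- unclass(mat)
  for (a in c("method", "band", "epoch", "signed")) attr(m, a) <- NULL
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("CH%02d", seq_len(nrow(m)))
  }
  dimnames(m) <- list(channel_labels, channel_labels)
  utils::write.csv(m, path)
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @export
read_connectivity_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  m
}

#' Export a brain-graph adjacency to GraphML
#'
#' @param adjacency Binary symmetric adjacency matrix.
#' @param path Output `.graphml` file.
#' @param channel_labels Optional node name attribute.
#' @export
export_graphml <- function(adjacency, path, channel_labels = NULL) {
  g <- igraph::graph_from_adjacency_matrix(adjacency != 0,
    mode = "undirected", diag = FALSE)
  if (!is.null(channel_labels)) {
    igraph::V(g)$name <- channel_labels
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
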