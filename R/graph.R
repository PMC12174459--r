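#' Cosine similarity between samples
#'
#' `S_ij = <x_i, x_j> / (||x_i|| ||x_j||)` over the feature vectors of a
#' view. Zero-length sample vectors get similarity 0 to everything by
#' convention; for all other samples the diagonal is exactly 1.
#'
#' @param x An [omics_view()] or a numeric sample-by-feature matrix.
#' @return A symmetric n-by-n similarity matrix.
#' @export
cosine_similarity_matrix <- function(x) {
  m <- if (inherits(x, "omics_view")) view_matrix(x) else as.matrix(x)
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  mn <- m
  mn[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  mn[!nz, ] <- 0
  s <- tcrossprod(mn)
  s <- (s + t(s)) / 2
  diag(s)[nz] <- 1
  s
}

# Threshold-by-count sparsification: keep the k strongest sample pairs where
# k targets a mean off-diagonal degree, then restore unit self-loops.
sparsify_similarity <- function(s, avg_degree) {
  n <- nrow(s)
  if (n < 2) abort("need at least 2 samples to build a graph")
  npairs <- n * (n - 1) / 2
  k <- max(1, min(round(avg_degree * n / 2), npairs))
  up <- s[upper.tri(s)]
  tau <- sort(up, decreasing = TRUE)[k]
  a <- ifelse(s >= tau, s, 0)
  a[a < 0] <- 0   # a negative similarity is no affinity at all
  diag(a) <- 1
  dimnames(a) <- dimnames(s)
  a
}

#' Build the weighted patient-similarity graph for one view
#'
#' Nodes are samples, edge weights are cosine similarities, and the graph is
#' sparsified by keeping the `k = round(avg_degree * n / 2)` strongest pairs
#' (ties at the threshold are all kept), so the mean off-diagonal degree is
#' about `avg_degree` regardless of the similarity scale. Self-loops with
#' weight 1 are always present so every node attends at least to itself.
#'
#' @param view An [omics_view()] (normalized features recommended).
#' @param avg_degree Target mean off-diagonal degree.
#' @return An object of class `patient_graph` with fields `sample_ids`,
#'   `adjacency` (dense symmetric matrix) and `view_name`.
#' @export
build_patient_graph <- function(view, avg_degree = 10) {
  s <- cosine_similarity_matrix(view)
  a <- sparsify_similarity(s, avg_degree)
  ids <- if (inherits(view, "omics_view")) view$sample_id else rownames(a)
  structure(list(sample_ids = ids, adjacency = a,
                 view_name = if (inherits(view, "omics_view"))
                   view_name(view) else "view"),
            class = "patient_graph")
}

#' @export
print.patient_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  deg <- (sum(x$adjacency > 0) - n) / n
  cat(sprintf("<patient_graph '%s': %d nodes, mean degree %.2f>\n",
              x$view_name, n, deg))
  invisible(x)
}

#' Edge list of a patient graph
#'
#' Three-column tidy dump (one row per unordered off-diagonal pair) for
#' inspection or export.
#'
#' @param graph A `patient_graph`.
#' @return Tibble with columns `i`, `j` (sample ids) and `weight`.
#' @export
edge_list <- function(graph) {
  a <- graph$adjacency
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  tibble::tibble(i = graph$sample_ids[idx[, 1]],
                 j = graph$sample_ids[idx[, 2]],
                 weight = a[idx])
}

# CSR edge representation consumed by the C++ core: directed edges including
# self-loops, sorted by source node, 0-based.
graph_csr <- function(adjacency) {
  a <- adjacency
  diag(a) <- pmax(diag(a), 1)
  n <- nrow(a)
  ei <- integer(0); ej <- integer(0)
  nb <- lapply(seq_len(n), function(i) which(a[i, ] > 0))
  counts <- vapply(nb, length, integer(1))
  ei <- rep.int(seq_len(n), counts) - 1L
  ej <- unlist(nb, use.names = FALSE) - 1L
  ptr <- c(0L, cumsum(counts))
  list(ei = as.integer(ei), ej = as.integer(ej), ptr = as.integer(ptr))
}

# Inductive attachment: new samples link to their `round(avg_degree)` most
# similar TRAINING samples (plus a self-loop); the training block keeps the
# training graph's edges. Rows of `new_m` follow the training rows.
attach_to_graph <- function(train_adj, train_m, new_m, avg_degree) {
  nt <- nrow(train_m); nn <- nrow(new_m)
  r <- max(1, min(round(avg_degree), nt))
  a <- matrix(0, nt + nn, nt + nn)
  a[seq_len(nt), seq_len(nt)] <- train_adj
  tn <- sqrt(rowSums(train_m^2)); tn[tn == 0] <- Inf
  nn2 <- sqrt(rowSums(new_m^2)); nn2[nn2 == 0] <- Inf
  sims <- (new_m / nn2) %*% t(train_m / tn)
  for (i in seq_len(nn)) {
    top <- order(-sims[i, ])[seq_len(r)]
    a[nt + i, top] <- pmax(sims[i, top], 0)
    a[top, nt + i] <- a[nt + i, top]
  }
  diag(a) <- 1
  a
}
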