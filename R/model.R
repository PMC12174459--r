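#' Xavier (Glorot) uniform initialization
#'
#' Entries drawn uniformly on `+- sqrt(6 / (fan_in + fan_out))`, giving the
#' variance `2 / (fan_in + fan_out)` that keeps activations on a stable scale
#' through deep stacks. Uses R's RNG, so `set.seed()` makes it reproducible.
#'
#' @param fan_in,fan_out Input and output dimension of the layer.
#' @param nrow,ncol Matrix shape (defaults to `fan_in` x `fan_out`).
#' @return A `nrow` x `ncol` matrix.
#' @export
xavier_uniform <- function(fan_in, fan_out, nrow = fan_in, ncol = fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# One branch's parameter set. Layout (all plain matrices; biases 1 x d):
#   W1..b3  three FC reduction layers D -> h -> h -> h
#   G1W/G1a1/G1a2  first attention layer, `heads` heads of width dh (concat)
#   G2W/G2a1/G2a2  second attention layer, single head
#   OW/Ob   linear head to C classes
init_view_params <- function(D, C, config) {
  h <- config$hidden_dims
  dh <- config$hidden_dims
  heads <- config$num_heads
  zb <- function(d) matrix(0, 1, d)
  # per-head fan for the shared projection, standard for attention layers
  g1w <- matrix(0, h, heads * dh)
  for (k in seq_len(heads)) {
    g1w[, ((k - 1) * dh + 1):(k * dh)] <- xavier_uniform(h, dh)
  }
  list(
    W1 = xavier_uniform(D, h), b1 = zb(h),
    W2 = xavier_uniform(h, h), b2 = zb(h),
    W3 = xavier_uniform(h, h), b3 = zb(h),
    G1W = g1w,
    G1a1 = xavier_uniform(2 * dh, 1, nrow = dh, ncol = heads),
    G1a2 = xavier_uniform(2 * dh, 1, nrow = dh, ncol = heads),
    G2W = xavier_uniform(heads * dh, dh),
    G2a1 = xavier_uniform(2 * dh, 1, nrow = dh, ncol = 1),
    G2a2 = xavier_uniform(2 * dh, 1, nrow = dh, ncol = 1),
    OW = xavier_uniform(dh, C), Ob = zb(C))
}

init_fusion_params <- function(C, m, config) {
  K <- C^m
  f <- config$vcdn_features
  list(W1 = xavier_uniform(K, f), b1 = matrix(0, 1, f),
       W2 = xavier_uniform(f, C), b2 = matrix(0, 1, C))
}

init_model_params <- function(dims, C, config, use_fusion) {
  m <- length(dims)
  list(views = lapply(dims, function(D) init_view_params(D, C, config)),
       fusion = if (use_fusion && m >= 2) init_fusion_params(C, m, config))
}

#' Forward pass of one omics-specific branch
#'
#' Runs the fully connected reduction, the two graph-attention layers over
#' the patient graph, and the softmax class head for a single view, in
#' evaluation mode (no dropout). Mostly useful for inspection and testing;
#' training happens jointly in [mogat_fit()].
#'
#' @param view An [omics_view()] (or numeric matrix) of normalized features.
#' @param graph A [build_patient_graph()] result over the same samples, in
#'   the same order.
#' @param params A branch parameter list (see [mogat_fit()]'s `params$views`).
#' @param config A [mogat_config()].
#' @return Tibble of per-sample class probabilities (`sample_id` plus one
#'   column per class index); rows lie on the probability simplex.
#' @export
branch_forward <- function(view, graph, params, config = mogat_config()) {
  m <- if (inherits(view, "omics_view")) view_matrix(view) else as.matrix(view)
  if (!identical(rownames(m), graph$sample_ids)) {
    abort("view and graph sample order differ")
  }
  csr <- graph_csr(graph$adjacency)
  out <- cpp_branch_forward(m, csr$ei, csr$ej, csr$ptr, params,
                            config$num_heads, config$hidden_dims,
                            config$leaky_slope, config$use_layernorm)
  probs <- out$probs
  colnames(probs) <- paste0("p", seq_len(ncol(probs)) - 1L)
  tibble::as_tibble(cbind(tibble::tibble(sample_id = graph$sample_ids),
                          tibble::as_tibble(probs)))
}

#' Cross-omics discovery tensor for one sample
#'
#' The outer product of the per-view class-probability rows: for views
#' 1..m and C classes, entry `(a, b, ..., z)` equals
#' `p1[a] * p2[b] * ... * pm[z]`, an order-m array of shape C x ... x C.
#' When every row is a probability vector the entries are nonnegative and
#' sum to 1, and marginalizing over all axes but v recovers view v's row
#' exactly.
#'
#' @param probs List of m numeric probability vectors, all of length C
#'   (2 <= m; a single view bypasses fusion upstream).
#' @return An array with `m` dimensions of extent C.
#' @export
cross_tensor <- function(probs) {
  stopifnot(is.list(probs), length(probs) >= 2)
  C <- length(probs[[1]])
  for (p in probs) {
    if (length(p) != C) abort("probability rows have differing lengths")
  }
  t <- Reduce(function(acc, p) outer(acc, p), probs[-1], probs[[1]])
  array(t, dim = rep(C, length(probs)))
}

#' Flatten a cross-omics tensor to the fusion input vector
#'
#' Row-major order with view 1 as the slowest axis: flat index
#' `t = a * C^(m-1) + b * C^(m-2) + ... + z` (0-based). This layout is fixed
#' so serialized fusion weights stay portable.
#'
#' @param tensor An array from [cross_tensor()].
#' @return Numeric vector of length `C^m`.
#' @export
flatten_tensor <- function(tensor) {
  m <- length(dim(tensor))
  as.vector(aperm(tensor, m:1))
}

#' Fusion head forward pass
#'
#' `softmax(W2 %*% LeakyReLU(W1 %*% flatten(tensor) + b1) + b2)`: the
#' two-layer fully connected network mapping the flattened cross-omics
#' tensor to the final class distribution.
#'
#' @param tensor Array from [cross_tensor()] (or an already-flat vector).
#' @param head List with `W1` (`C^m` x f), `b1`, `W2` (f x C), `b2`.
#' @param leaky_slope Negative slope of the LeakyReLU.
#' @return Probability vector of length C.
#' @export
fusion_forward <- function(tensor, head, leaky_slope = 0.2) {
  v <- if (is.array(tensor) && !is.null(dim(tensor))) flatten_tensor(tensor)
       else as.numeric(tensor)
  if (length(v) != nrow(head$W1)) {
    abort(sprintf("fusion head expects input of length %d, got %d",
                  nrow(head$W1), length(v)))
  }
  z1 <- drop(v %*% head$W1) + drop(head$b1)
  a1 <- ifelse(z1 > 0, z1, leaky_slope * z1)
  z2 <- drop(a1 %*% head$W2) + drop(head$b2)
  e <- exp(z2 - max(z2))
  e / sum(e)
}
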