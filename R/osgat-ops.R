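# Reference implementations of the omics-specific branch primitives in plain
# R. They define the semantics of the fast C++ training path and are handy
# for inspection; mogat_fit() never calls them.

#' Fully connected dimensionality reduction (reference implementation)
#'
#' Three affine layers, each followed by ReLU and (optionally) per-sample
#' feature normalization, mapping a high-dimensional omics profile to the
#' hidden width used by the attention layers. Evaluation mode: no dropout.
#'
#' @param X Numeric n x D matrix.
#' @param fc List with `W1`, `b1`, `W2`, `b2`, `W3`, `b3` (biases 1 x d).
#' @param use_layernorm Apply the normalization after each ReLU.
#' @return n x d matrix of reduced features.
#' @export
fc_reduce <- function(X, fc, use_layernorm = TRUE) {
  ln <- function(m) {
    if (!use_layernorm) return(m)
    t(apply(m, 1, function(r) {
      mu <- mean(r)
      (r - mu) / sqrt(mean((r - mu)^2) + 1e-5)
    }))
  }
  h <- X
  for (l in 1:3) {
    W <- fc[[paste0("W", l)]]
    b <- fc[[paste0("b", l)]]
    if (ncol(h) != nrow(W)) abort("fc_reduce: dimension mismatch")
    h <- sweep(h %*% W, 2, -as.numeric(b))
    h <- pmax(h, 0)
    h <- ln(h)
  }
  h
}

#' Raw graph attention scores (reference implementation)
#'
#' For each directed edge (i, j) of the patient graph, the unnormalized
#' score `e_ij = LeakyReLU(a^T [W h_i || W h_j])`, where `W` is the shared
#' projection and `a` the learnable probe over the concatenated pair.
#'
#' @param H Node feature matrix (n x d).
#' @param W Projection matrix (d x dh).
#' @param a Probe vector of length `2 * dh` (first half scores the self
#'   embedding, second half the neighbor embedding).
#' @param edges Two-column integer matrix of directed edges (1-based,
#'   self-loops included).
#' @param slope LeakyReLU negative slope.
#' @return Numeric vector of scores, one per edge row.
#' @export
attention_scores <- function(H, W, a, edges, slope = 0.2) {
  dh <- ncol(W)
  if (length(a) != 2 * dh) {
    abort(sprintf("attention probe must have length %d (= 2 x %d)", 2 * dh, dh))
  }
  HW <- H %*% W
  s1 <- drop(HW %*% a[seq_len(dh)])
  s2 <- drop(HW %*% a[dh + seq_len(dh)])
  e <- s1[edges[, 1]] + s2[edges[, 2]]
  ifelse(e > 0, e, slope * e)
}

#' Softmax-normalized attention coefficients (reference implementation)
#'
#' `a_ij = exp(e_ij) / sum_k exp(e_ik)` over each source node's
#' neighborhood, computed with max subtraction for overflow safety. Every
#' node's coefficients sum to 1.
#'
#' @param e Raw scores from [attention_scores()].
#' @param edges The same edge matrix.
#' @return Numeric vector of coefficients, one per edge row.
#' @export
attention_normalize <- function(e, edges) {
  out <- numeric(length(e))
  for (i in unique(edges[, 1])) {
    idx <- which(edges[, 1] == i)
    if (length(idx) == 0) abort("node with empty neighborhood")
    ex <- exp(e[idx] - max(e[idx]))
    out[idx] <- ex / sum(ex)
  }
  out
}

#' Attention-weighted neighborhood aggregation (reference implementation)
#'
#' `out_i = act( sum_{j in N(i)} a_ij * (W h_j) )`: each node's new feature
#' is the coefficient-weighted sum of its neighbors' projected features
#' (neighbor-indexed, so the layer genuinely mixes the neighborhood).
#'
#' @param H Node feature matrix (n x d).
#' @param W Projection matrix (d x dh).
#' @param coef Normalized coefficients from [attention_normalize()].
#' @param edges The same edge matrix.
#' @param activation `"elu"` for hidden layers, `"identity"` before the
#'   class head.
#' @return n x dh matrix of aggregated features.
#' @export
gat_aggregate <- function(H, W, coef, edges, activation = c("elu", "identity")) {
  activation <- match.arg(activation)
  HW <- H %*% W
  out <- matrix(0, nrow(H), ncol(W))
  for (k in seq_len(nrow(edges))) {
    out[edges[k, 1], ] <- out[edges[k, 1], ] + coef[k] * HW[edges[k, 2], ]
  }
  if (activation == "elu") out <- ifelse(out > 0, out, expm1(out))
  out
}
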