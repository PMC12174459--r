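test_that("Xavier initialization has the prescribed variance and bounds", {
  set.seed(1)
  w <- xavier_uniform(512, 512)
  lim <- sqrt(6 / 1024)
  expect_true(all(abs(w) <= lim))
  expect_lt(abs(var(as.numeric(w)) - 2 / 1024) / (2 / 1024), 0.1)
})

test_that("attention scores and coefficients follow the stated formulas", {
  set.seed(2)
  H <- matrix(rnorm(6), 3, 2)
  W <- matrix(rnorm(4), 2, 2)
  edges <- cbind(c(1, 1, 2, 2, 3), c(1, 2, 1, 2, 3))

  # zero probe: every raw score is 0
  expect_equal(attention_scores(H, W, rep(0, 4), edges), rep(0, 5))

  # LeakyReLU definition: a pre-activation of -1 with slope 0.2 gives -0.2
  H1 <- matrix(1, 1, 1); W1 <- matrix(1, 1, 1)
  e1 <- attention_scores(H1, W1, c(-0.5, -0.5), cbind(1, 1), slope = 0.2)
  expect_equal(e1, -0.2)

  # hand evaluation on a 2-node toy with integer weights
  Hh <- rbind(c(1, 0), c(0, 1))
  Wh <- rbind(c(1, 2), c(3, 4))
  a <- c(1, -1, 2, 0.5)
  eh <- attention_scores(Hh, Wh, a, cbind(c(1, 1), c(1, 2)), slope = 0.2)
  # Wh_1 = (1,2), Wh_2 = (3,4); e_11 = lr(1*1 + (-1)*2 + 2*1 + 0.5*2) = 2
  # e_12 = lr(1 - 2 + 2*3 + 0.5*4) = 7
  expect_equal(eh, c(2, 7))

  # softmax normalization: degenerate, symmetric and hand-computed cases
  expect_equal(attention_normalize(0.3, cbind(1, 1)), 1.0)
  expect_equal(attention_normalize(c(2, 2), cbind(c(1, 1), c(1, 2))),
               c(0.5, 0.5))
  co <- attention_normalize(c(1, 2), cbind(c(1, 1), c(1, 2)))
  expect_equal(co, c(0.268941, 0.731059), tolerance = 1e-6)

  # shift invariance of the per-node softmax
  e <- rnorm(5)
  co1 <- attention_normalize(e, edges)
  co2 <- attention_normalize(e + c(7, 7, -3, -3, 11), edges)
  expect_equal(co1, co2, tolerance = 1e-12)
})

test_that("aggregation is the coefficient-weighted neighbor sum", {
  W <- rbind(c(1, 0), c(0, 2))
  H <- rbind(c(1, 1), c(2, 0.5), c(0.3, 0.3))
  # self-loop-only node: sigma(W h_i)
  out <- gat_aggregate(H, W, 1, cbind(1, 1), activation = "identity")
  expect_equal(out[1, ], c(1, 2))
  # identical neighbors with uniform coefficients: unchanged by degree
  Hc <- rbind(c(1, 1), c(1, 1), c(1, 1))
  out2 <- gat_aggregate(Hc, W, rep(1 / 3, 3), cbind(c(1, 1, 1), c(1, 2, 3)),
                        activation = "identity")
  expect_equal(out2[1, ], c(1, 2))
  # 3-node toy against a hand-computed weighted sum (ELU on negatives)
  co <- c(0.5, 0.3, 0.2)
  out3 <- gat_aggregate(H, -W, co, cbind(c(1, 1, 1), c(1, 2, 3)),
                        activation = "elu")
  hand <- -(0.5 * c(1, 2) + 0.3 * c(2, 1) + 0.2 * c(0.3, 0.6))
  expect_equal(out3[1, ], exp(hand) - 1, tolerance = 1e-12)
})

test_that("fc_reduce matches hand-multiplied affine + ReLU chains", {
  fc0 <- list(W1 = matrix(0, 2, 2), b1 = matrix(0, 1, 2),
              W2 = matrix(0, 2, 2), b2 = matrix(0, 1, 2),
              W3 = matrix(0, 2, 2), b3 = matrix(0, 1, 2))
  expect_equal(fc_reduce(matrix(rnorm(4), 2, 2), fc0, use_layernorm = FALSE),
               matrix(0, 2, 2))
  # identity weights on nonnegative input reproduce the input
  fci <- list(W1 = diag(2), b1 = matrix(0, 1, 2),
              W2 = diag(2), b2 = matrix(0, 1, 2),
              W3 = diag(2), b3 = matrix(0, 1, 2))
  X <- matrix(c(0.5, 2, 0, 1), 2, 2)
  expect_equal(fc_reduce(X, fci, use_layernorm = FALSE), X)
  # fixed 2x2 weights on a 1x2 input
  fc <- list(W1 = rbind(c(1, -1), c(2, 0.5)), b1 = matrix(c(0.1, -0.2), 1),
             W2 = diag(2), b2 = matrix(0, 1, 2),
             W3 = diag(2), b3 = matrix(0, 1, 2))
  x <- matrix(c(1, 2), 1, 2)
  a1 <- pmax(c(1 * 1 + 2 * 2 + 0.1, 1 * (-1) + 2 * 0.5 - 0.2), 0)
  expect_equal(fc_reduce(x, fc, use_layernorm = FALSE)[1, ], a1)
})

test_that("branch forward output rows are simplex points, deterministically", {
  s <- fit_small()
  out <- branch_forward(mogat:::view_from_matrix(s$fit$X$mRNA, "mRNA"),
                        s$fit$graphs$mRNA, s$fit$params$views[[1]],
                        s$fit$config)
  probs <- as.matrix(out[, -1])
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-6)
  out2 <- branch_forward(mogat:::view_from_matrix(s$fit$X$mRNA, "mRNA"),
                         s$fit$graphs$mRNA, s$fit$params$views[[1]],
                         s$fit$config)
  expect_identical(out, out2)
})

test_that("branch forward is equivariant under node permutation", {
  set.seed(6)
  n <- 12
  X <- matrix(runif(n * 5), n, 5,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:5)))
  cfg <- mogat_config(num_heads = 3, hidden_dims = 4, dropout = 0, seed = 1)
  params <- mogat:::init_view_params(5L, 2L, cfg)
  g <- build_patient_graph(mogat:::view_from_matrix(X, "v"), avg_degree = 4)
  p1 <- branch_forward(mogat:::view_from_matrix(X, "v"), g, params, cfg)

  perm <- sample(n)
  Xp <- X[perm, , drop = FALSE]
  gp <- build_patient_graph(mogat:::view_from_matrix(Xp, "v"), avg_degree = 4)
  p2 <- branch_forward(mogat:::view_from_matrix(Xp, "v"), gp, params, cfg)
  m1 <- as.matrix(p1[, -1]); m2 <- as.matrix(p2[order(perm), -1])
  expect_equal(m2, m1, tolerance = 1e-9)
})

test_that("the C++ branch matches the straight-line R oracle", {
  set.seed(7)
  n <- 5
  X <- matrix(runif(n * 4), n, 4,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:4)))
  cfg <- mogat_config(num_heads = 2, hidden_dims = 3, dropout = 0, seed = 2)
  params <- mogat:::init_view_params(4L, 3L, cfg)
  for (nm in c("b1", "b2", "b3", "Ob")) {
    params[[nm]][] <- rnorm(length(params[[nm]]), 0, 0.2)
  }
  g <- build_patient_graph(mogat:::view_from_matrix(X, "v"), avg_degree = 2)
  got <- as.matrix(branch_forward(mogat:::view_from_matrix(X, "v"),
                                  g, params, cfg)[, -1])
  want <- oracle_branch(X, graph_edges_1based(g), params,
                        heads = 2, dh = 3, slope = 0.2, use_ln = TRUE)
  expect_equal(unname(got), want, tolerance = 1e-9)
})
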