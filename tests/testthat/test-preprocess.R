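mk_view <- function(m, nm = "v") mogat:::view_from_matrix(m, nm)

test_that("low-quality features are dropped by zero/missing fraction", {
  m <- cbind(allzero = rep(0, 10), fine = rnorm(10) + 5)
  rownames(m) <- sprintf("s%02d", 1:10)
  suppressMessages(out <- filter_low_quality(mk_view(m), max_zero_fraction = 0.5))
  expect_equal(feature_names(out), "fine")

  # no zeros, no missing: identity
  m2 <- matrix(rnorm(20) + 10, 5, 4,
               dimnames = list(paste0("s", 1:5), paste0("f", 1:4)))
  expect_equal(view_matrix(filter_low_quality(mk_view(m2))), m2)

  # brute-force count: 3 of 10 features exceed a 0.2 zero-fraction cut
  set.seed(1)
  m3 <- matrix(abs(rnorm(200)) + 1, 20, 10,
               dimnames = list(sprintf("s%02d", 1:20), sprintf("f%02d", 1:10)))
  m3[1:10, 1] <- 0; m3[1:6, 2] <- 0; m3[1:5, 3] <- 0  # fractions .5 .3 .25
  frac <- colMeans(m3 == 0)
  expect_equal(sum(frac > 0.2), 3)
  suppressMessages(out3 <- filter_low_quality(mk_view(m3), max_zero_fraction = 0.2))
  expect_equal(ncol(view_matrix(out3)), 7)

  allz <- matrix(0, 4, 2, dimnames = list(paste0("s", 1:4), c("f1", "f2")))
  expect_error(
    suppressMessages(filter_low_quality(mk_view(allz), max_zero_fraction = 0.5)),
    "all features dropped")
})

test_that("missing entries are imputed with the training-sample median", {
  m <- matrix(c(1, 2, 3, 4, NA, 10), 6, 1,
              dimnames = list(paste0("s", 1:6), "f1"))
  out <- filter_low_quality(mk_view(m), max_missing_fraction = 0.5,
                            stats_ids = paste0("s", 1:4))
  expect_equal(unname(view_matrix(out)["s5", "f1"]), median(c(1, 2, 3, 4)))
})

test_that("min-max normalization follows training statistics and clips", {
  m <- matrix(c(2, 4, 6), 3, 1, dimnames = list(paste0("s", 1:3), "f1"))
  v <- normalize_minmax(mk_view(m))
  expect_equal(unname(view_matrix(v)[, 1]), c(0, 0.5, 1))

  const <- matrix(5, 3, 1, dimnames = list(paste0("s", 1:3), "f1"))
  expect_equal(unname(view_matrix(normalize_minmax(mk_view(const)))[, 1]),
               c(0, 0, 0))

  train <- mk_view(matrix(c(0, 10), 2, 1,
                          dimnames = list(c("a", "b"), "f1")))
  test <- mk_view(matrix(12, 1, 1, dimnames = list("c", "f1")))
  expect_equal(unname(view_matrix(normalize_minmax(test, train = train))[1, 1]), 1)

  # idempotence on the training view
  sim <- small_sim(n = 20)
  v1 <- normalize_minmax(sim$views$mRNA)
  v2 <- normalize_minmax(v1)
  expect_equal(view_matrix(v2), view_matrix(v1))

  bad <- mk_view(matrix(1, 2, 1, dimnames = list(c("a", "b"), "other")))
  expect_error(normalize_minmax(bad, train = train), "mismatch")
})

test_that("correlation selection scores, caps and ordering match the rules", {
  set.seed(2)
  n <- 40
  codes <- rep(0:1, each = n / 2)
  ids <- sprintf("s%02d", 1:n)
  labels <- tibble::tibble(sample_id = ids, label = c("I", "II")[codes + 1])
  m <- cbind(perfect = as.numeric(codes == 0),
             constant = rep(1, n),
             matrix(rnorm(4 * n), n, 4, dimnames = list(NULL, paste0("noise", 1:4))))
  rownames(m) <- ids
  sel <- cfs_select(mk_view(m), labels, feature_fraction = 1)
  expect_equal(sel$feature[1], "perfect")
  expect_equal(sel$score[1], 1.0)
  expect_equal(sel$score[sel$feature == "constant"], 0)

  # brute-force oracle over a 6-feature fixture
  brute <- apply(m, 2, function(x) {
    max(vapply(0:1, function(cc) {
      r <- suppressWarnings(cor(x, as.numeric(codes == cc)))
      if (is.na(r)) 0 else abs(r)
    }, numeric(1)))
  })
  ord <- order(-brute, names(brute))
  expect_equal(sel$feature, names(brute)[ord])
  expect_equal(sel$score, unname(brute[ord]))

  # k = min(ceiling(fraction * p), cap)
  expect_equal(attr(cfs_select(mk_view(m), labels, 0.25, 5000), "k"),
               as.integer(ceiling(0.25 * 6)))
  expect_equal(attr(cfs_select(mk_view(m), labels, 0.9, 3), "k"), 3L)

  tiny <- mk_view(m[1:2, , drop = FALSE])
  expect_error(cfs_select(tiny, labels[1:2, ]), "3 samples")
})

test_that("the 5,000-feature cap binds at omics scale", {
  set.seed(3)
  n <- 12; p <- 20000
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%05d", 1:p)))
  labels <- tibble::tibble(sample_id = rownames(m),
                           label = rep(c("I", "II"), length.out = n))
  sel <- cfs_select(mk_view(m), labels, feature_fraction = 0.25,
                    feature_cap = 5000)
  expect_equal(attr(sel, "k"), 5000L)
  expect_equal(sum(sel$kept), 5000L)
})

test_that("selection is fitted on training samples only (no test leakage)", {
  sim <- small_sim(n = 40, effect = 2)
  labels <- sim$labels
  train <- labels$sample_id[1:28]
  sel1 <- cfs_select(sim$views$mRNA, labels, train_ids = train)
  # permute the held-out labels: selection must not change
  labels2 <- labels
  test_rows <- !(labels2$sample_id %in% train)
  set.seed(4)
  labels2$label[test_rows] <- sample(labels2$label[test_rows])
  sel2 <- cfs_select(sim$views$mRNA, labels2, train_ids = train)
  expect_identical(sel1$feature, sel2$feature)
  expect_identical(sel1$score, sel2$score)
})

test_that("selection recovers planted informative features", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_multiomics(
      n = 120, C = 3,
      view_specs = list(v = list(p = 60L, s = 8L, kind = "expression")),
      effect = 2, noise_sd = 1, seed = 100 + s)
    sel <- cfs_select(sim$views$v, sim$labels)
    top_s <- sel$feature[seq_len(8)]
    mean(sim$truth$v$informative %in% top_s)
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("methylation features are renamed via the mapping, collisions by variance", {
  set.seed(5)
  m <- cbind(cg0001 = rnorm(10, sd = 1), cg0002 = rnorm(10, sd = 3),
             cg0003 = rnorm(10), cg0004 = rnorm(10))
  rownames(m) <- sprintf("s%02d", 1:10)
  mapping <- tibble::tibble(feature = c("cg0001", "cg0002", "cg0003"),
                            gene = c("HMGN5", "HMGN5", "TP63"))
  suppressMessages(out <- rename_methylation_features(mk_view(m), mapping))
  expect_setequal(feature_names(out), c("HMGN5", "TP63"))
  # cg0002 has higher variance, so HMGN5 keeps its values
  expect_equal(unname(view_matrix(out)[, "HMGN5"]), unname(m[, "cg0002"]))
  # cg0004 was unmapped, hence dropped
  expect_false("cg0004" %in% feature_names(out))
  expect_error(rename_methylation_features(mk_view(m), mapping[0, ]), "empty")
})
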