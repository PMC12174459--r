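# shared fixture builders (all data generated in code)

tiny_config <- function(...) {
  base <- list(num_epochs = 25, num_heads = 4, hidden_dims = 8,
               vcdn_features = 16, avg_degree = 5, dropout = 0, seed = 11)
  do.call(mogat_config, utils::modifyList(base, list(...)))
}

small_sim <- function(n = 60, C = 3, p = c(20L, 15L, 18L), s = c(5L, 5L, 5L),
                      effect = 3, seed = 7, ...) {
  simulate_multiomics(n = n, C = C,
                      view_specs = default_view_specs(p = p, s = s),
                      effect = effect, seed = seed, ...)
}

# edges (1-based, incl self loops, sorted by source) of a patient graph
graph_edges_1based <- function(graph) {
  a <- graph$adjacency
  diag(a) <- pmax(diag(a), 1)
  do.call(rbind, lapply(seq_len(nrow(a)), function(i) {
    cbind(i, which(a[i, ] > 0))
  }))
}

fit_small <- function(sim = small_sim(), config = tiny_config(),
                      split_seed = 3) {
  sp <- split_stratified(sim$labels, config$train_fraction, seed = split_seed)
  pp <- preprocess_views(sim$views, sim$labels, train_ids = sp$train_ids,
                         config = config)
  fit <- mogat_fit(pp$views, sim$labels, train_ids = sp$train_ids,
                   config = config, feature_universe = pp$universe)
  list(fit = fit, split = sp, pp = pp, sim = sim)
}

test_accuracy <- function(fit, labels) {
  pr <- predict(fit)
  keep <- pr$sample_id %in% fit$test_ids
  mean(as.character(pr$.pred_class[keep]) ==
         labels$label[match(pr$sample_id[keep], labels$sample_id)])
}
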