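# Shared trained models for the end-to-end structure-recovery tests.
# Training the benchmark (3 contexts x 200 proteins, 100 epochs, 3 seeds,
# plus the metagraph-off ablation) takes a few minutes, so the runs are
# computed once per session and reused across test files.

.bench_env <- new.env(parent = emptyenv())

benchmark_runs <- function() {
  if (!is.null(.bench_env$runs)) return(.bench_env$runs)
  gs <- graph_spec(n_tissues = 20, seed = 1)
  g <- synth_multiscale_graph(gs)
  msg <- multiscale_graph(g$contexts, g$metagraph)
  full <- lapply(1:3, function(s) {
    contextppi(msg, config = synthetic_train_config(seed = s))
  })
  ablated <- lapply(1:3, function(s) {
    contextppi(msg, config = synthetic_train_config(seed = s,
                                                    use_metagraph = FALSE,
                                                    use_bridge = FALSE))
  })
  .bench_env$runs <- list(g = g, graph = msg, full = full, ablated = ablated)
  .bench_env$runs
}

# Hierarchy-retrieval benchmark: more contexts, so the metagraph's
# ancestor-closed tissue set is large enough (>= 12 tissues) for stable
# ontology-distance statistics.
hierarchy_runs <- function() {
  if (!is.null(.bench_env$hier)) return(.bench_env$hier)
  gs <- graph_spec(n_contexts = 8, proteins_per_context = 80, n_tissues = 24,
                   tissue_tree_depth = 3, seed = 1)
  g <- synth_multiscale_graph(gs)
  msg <- multiscale_graph(g$contexts, g$metagraph)
  full <- lapply(1:3, function(s) {
    contextppi(msg, config = synthetic_train_config(seed = s))
  })
  .bench_env$hier <- list(g = g, graph = msg, full = full)
  .bench_env$hier
}
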