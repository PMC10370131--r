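# Brute-force oracle for APR@K used to validate the closed-form version.
apr_brute <- function(rel, K) {
  r <- sum(rel[1:K])
  if (r == 0) return(0)
  acc <- 0
  for (k in 1:K) {
    if (rel[k] == 1) acc <- acc + sum(rel[1:k]) / k
  }
  acc / r
}

test_that("APR@K matches hand enumeration and a brute-force oracle", {
  expect_equal(apr_at_k(c(1, 1, 1), 3), 1)
  expect_equal(apr_at_k(c(1, 0, 1), 3), (1 + 2 / 3) / 2)
  expect_equal(apr_at_k(c(0, 0, 0), 3), 0)
  expect_error(apr_at_k(c(1, 0), 3), "out of range")
  set.seed(70)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    rel <- rbinom(n, 1, 0.4)
    K <- sample(n, 1)
    expect_equal(apr_at_k(rel, K), apr_brute(rel, K))
  }
})

test_that("similarity gap separates constructed within/cross structures", {
  # within-context pairs colinear, cross-context pairs orthogonal
  emb <- rbind(c(1, 0), c(2, 0), c(0, 1), c(0, 3))
  ctx <- c("a", "a", "b", "b")
  gap <- similarity_gap(emb, ctx)
  expect_equal(gap$median_within, 1)
  expect_equal(gap$median_cross, 0)
  expect_equal(gap$ks_stat, 1)
  expect_gte(gap$ks_stat, 0); expect_lte(gap$ks_stat, 1)
  # identical embeddings: both medians 1, zero gap
  same <- matrix(1, 4, 3)
  gap2 <- similarity_gap(same, ctx)
  expect_equal(gap2$median_within, 1)
  expect_equal(gap2$median_cross, 1)
  expect_equal(gap2$gap, 0)
  # same-protein pairs excluded from the cross set when identities given
  prot <- c("P1", "P2", "P1", "P2")
  gap3 <- similarity_gap(emb, ctx, prot)
  expect_equal(length(gap3$cross), 2)  # only the P1-P2 cross pairs remain
})

test_that("multiplicity correlation matches an explicit rank computation", {
  # constructed monotone-decreasing table: more contexts, lower self-similarity
  emb <- rbind(
    c(1, 0), c(1, 0),                      # P1: 2 contexts, identical
    c(1, 0), c(0.9, 0.1), c(0.8, 0.3),     # P2: 3 contexts, spread a bit
    c(1, 0), c(0, 1), c(-1, 0), c(0, -1))  # P3: 4 contexts, orthogonal
  prot <- c("P1", "P1", "P2", "P2", "P2", "P3", "P3", "P3", "P3")
  mc <- multiplicity_correlation(emb, prot)
  expect_equal(mc$rho, -1)
  set.seed(71)
  emb2 <- matrix(rnorm(30), 15, 2)
  prot2 <- rep(c("A", "B", "C", "D", "E"), times = c(2, 2, 3, 4, 4))
  mc2 <- multiplicity_correlation(emb2, prot2)
  # independent Spearman: explicit average ranks
  sp <- function(x, y) stats::cor(rank(x), rank(y))
  expect_equal(mc2$rho, sp(mc2$table$n_contexts, mc2$table$mean_self_similarity),
               tolerance = 1e-12)
  # degenerate ranks reported as 0 with the tie flag
  emb3 <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1), c(1, 1), c(1, 1))
  mc3 <- multiplicity_correlation(emb3, rep(c("A", "B", "C"), each = 2))
  expect_equal(mc3$rho, 0)
  expect_true(mc3$tied)
})

test_that("tissue ontology distance equals a BFS oracle", {
  onto <- data.frame(child = c("a", "b", "c", "d", "e"),
                     parent = c("root", "root", "a", "a", "b"))
  tree <- ontology_tree(onto)
  expect_equal(tissue_ontology_distance("c", "c", tree), 0)
  expect_equal(tissue_ontology_distance("c", "a", tree), 1)
  expect_equal(tissue_ontology_distance("c", "d", tree), 2)  # siblings
  expect_equal(tissue_ontology_distance("c", "e", tree), 4)  # via root
  expect_error(tissue_ontology_distance("c", "zz", tree), "unknown")
  # BFS oracle on the undirected tree via igraph
  g <- igraph::graph_from_data_frame(onto, directed = FALSE)
  for (t1 in tree$nodes) for (t2 in tree$nodes) {
    expect_equal(tissue_ontology_distance(t1, t2, tree),
                 as.numeric(igraph::distances(g, t1, t2)))
  }
})

test_that("hierarchy retrieval gives rho 1 on monotone constructions and a centered null", {
  set.seed(72)
  # place tissues on a line so embedding distance increases with tree distance
  onto <- data.frame(child = sprintf("t%02d", 2:20),
                     parent = sprintf("t%02d", 1:19))
  tree <- ontology_tree(onto)
  # equally spaced angles on the unit circle: cosine distance is a strictly
  # increasing function of |i - j|, which is exactly the path-tree distance
  theta <- seq(0, 1, length.out = 20)
  emb <- cbind(cos(theta), sin(theta))
  rownames(emb) <- sprintf("t%02d", 1:20)
  hr <- hierarchy_retrieval(emb, tree, n_shuffles = 10, seed = 1)
  expect_gt(hr$rho, 0.99)
  expect_equal(length(hr$null_rho), 10)
  expect_lt(abs(mean(hr$null_rho)), 0.1)
})

test_that("permutation test matches exhaustive enumeration on tiny inputs", {
  # binding = {1}, nonbinding = {0}: two equally likely assignments
  r <- score_gap_permutation_test(1, 0, n_iter = 1e5, seed = 1)
  expect_equal(r$gap, 1)
  se <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(r$p - 0.5), 3 * se)
  # all binding below nonbinding: permuted gap always >= observed
  r2 <- score_gap_permutation_test(c(0.1, 0.2), c(0.8, 0.9), n_iter = 2000, seed = 1)
  expect_gt(r2$p, 0.95)
  # exhaustive oracle for all inputs with <= 8 scores
  set.seed(73)
  for (trial in 1:5) {
    n <- sample(2:4, 1); m <- sample(2:4, 1)
    b <- round(runif(n), 3); nb <- round(runif(m), 3)
    pool <- c(b, nb)
    gap <- mean(b) - mean(nb)
    combs <- utils::combn(n + m, n)
    exact <- mean(apply(combs, 2, function(ii) {
      mean(pool[ii]) - mean(pool[-ii]) >= gap - 1e-12
    }))
    mc <- score_gap_permutation_test(b, nb, n_iter = 20000, seed = trial)
    se <- sqrt(max(exact * (1 - exact), 1e-6) / 20000)
    expect_lt(abs(mc$p - exact), max(3 * se, 0.02))
  }
})

test_that("spatial enrichment flags a planted labeled cluster and only that", {
  set.seed(74)
  tight <- matrix(rnorm(20 * 4, sd = 0.05), 20, 4)
  tight <- sweep(tight, 2, c(5, 0, 0, 0), "+")
  rest <- matrix(rnorm(60 * 4), 60, 4)
  emb <- rbind(tight, rest)
  labels <- c(rep(1, 20), rep(0, 60))
  er <- spatial_enrichment(emb, labels, sim_threshold = 0.3, radius = 0.15)
  expect_s3_class(er, "enrichment_result")
  expect_gt(er$n_enriched, 0)
  # the planted cluster's neighborhoods are detected essentially in full
  in_cluster <- er$table$node <= 20
  expect_gt(mean(er$table$significant[in_cluster]), 0.9)
  # per-neighborhood p-values match a direct hypergeometric tail computation
  i <- which.max(er$table$n_labeled)
  N <- nrow(er$table); K <- sum(labels[er$kept] == 1)
  expect_equal(er$table$p[i],
               stats::phyper(er$table$n_labeled[i] - 1, K, N - K,
                             er$table$neighborhood_size[i], lower.tail = FALSE))
  # BH correction against an independent step-up implementation
  bh <- function(p) {
    n <- length(p); o <- order(p)
    adj <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
    out <- numeric(n); out[o] <- adj; out
  }
  expect_equal(er$table$p_adj, bh(er$table$p), tolerance = 1e-12)
  # uniform labels can never be over-represented
  er_all <- spatial_enrichment(emb, rep(1, 80), sim_threshold = 0.3)
  expect_equal(er_all$n_enriched, 0)
})

test_that("shuffled labels keep the enriched fraction near the nominal level", {
  set.seed(75)
  emb <- matrix(rnorm(60 * 5), 60, 5)
  fracs <- replicate(20, {
    labels <- sample(c(rep(1, 15), rep(0, 45)))
    er <- spatial_enrichment(emb, labels, sim_threshold = 0, radius = 0.25,
                             alpha = 0.05)
    er$n_enriched / nrow(er$table)
  })
  # BH at alpha = 0.05 under the null: mean significant fraction well below
  # alpha plus two binomial standard errors
  expect_lt(mean(fracs), 0.05 + 2 * sqrt(0.05 * 0.95 / (20 * 60)))
})

test_that("external vectors are contextualized by concatenation", {
  gs <- graph_spec(n_contexts = 2, proteins_per_context = 20,
                   shared_fraction = 0.5, seed = 76)
  g <- synth_multiscale_graph(gs)
  msg <- multiscale_graph(g$contexts, g$metagraph)
  msg <- init_protein_features(msg, 4, seed = 1)
  emb <- list(protein = msg$features[match(
    msg$node_index$protein[order(msg$node_index$node_id)],
    rownames(msg$features)), , drop = FALSE],
    index = msg$node_index)
  shared <- names(which(table(msg$node_index$protein) == 2))[1]
  ext <- rnorm(6)
  cz <- contextualize_external(ext, emb, shared)
  expect_equal(length(cz$per_context), 2)
  expect_equal(length(cz$per_context[[1]]), 6 + 4)   # dims add
  rows <- emb$index[emb$index$protein == shared, ]
  expect_equal(cz$context_free,
               c(ext, colMeans(emb$protein[rows$node_id, ])))
  # cosine of combined vectors matches a direct scalar computation
  a <- cz$per_context[[1]]; b <- cz$per_context[[2]]
  expect_equal(cosine_similarity(a, b),
               sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  expect_error(contextualize_external(ext, emb, "nope"), "unknown protein")
})

test_that("median pooling keeps top-scored patches and takes row medians", {
  m <- matrix(1:12, 3, 4, byrow = TRUE)
  sc <- c(0.1, 0.9, 0.5)
  out <- median_pool_patches(m, sc, k_select = 3)
  # rows ordered by score: row2, row3, row1; row medians via explicit sort
  expect_equal(out, c(median(m[2, ]), median(m[3, ]), median(m[1, ])))
  const <- matrix(7, 5, 4)
  expect_equal(median_pool_patches(const, 1:5, 5), rep(7, 5))
  expect_error(median_pool_patches(m, sc, k_select = 4), "fewer patch rows")
  # selecting k of many keeps exactly the top k rows
  set.seed(77)
  big <- matrix(rnorm(40), 10, 4)
  scores <- rnorm(10)
  out2 <- median_pool_patches(big, scores, 4)
  keep <- order(-scores)[1:4]
  expect_equal(out2, apply(big[keep, ], 1, median))
})
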