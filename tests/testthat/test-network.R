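test_that("edge test handles perfect monotone and antitone agreement", {
  up <- spearman_edge_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(up$rs, 1)
  expect_lt(up$p, 1e-3)
  down <- spearman_edge_test(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(down$rs, -1)
  expect_error(spearman_edge_test(1:3, 3:1), class = "lncnet_validation_error")
  expect_error(spearman_edge_test(1:5, rep(2, 5)),
               class = "lncnet_constant_error")
})

test_that("edge test matches rank-Pearson and the exact permutation null", {
  x <- 1:5
  y <- c(2, 1, 4, 3, 5)
  res <- spearman_edge_test(x, y)
  expect_equal(res$rs, 0.8)
  expect_equal(res$rs, cor(x, y, method = "spearman"))
  p_perm <- perm_spearman_p(x, y)
  expect_lt(abs(res$p - p_perm), 0.05)
})

test_that("edge test is symmetric and rank-invariant", {
  withr::local_seed(21)
  for (i in 1:10) {
    x <- runif(12)
    y <- runif(12)
    expect_equal(spearman_edge_test(x, y), spearman_edge_test(y, x))
    # strictly increasing transforms leave all outputs unchanged
    expect_equal(spearman_edge_test(exp(3 * x), y), spearman_edge_test(x, y))
    expect_equal(spearman_edge_test(x, y^3 + 2 * y), spearman_edge_test(x, y))
  }
})

test_that("build_network reproduces a brute-force run on a 3-gene toy", {
  withr::local_seed(8)
  n <- 20
  base <- rnorm(n)
  m <- rbind(g1 = exp(base),
             g2 = exp(base + rnorm(n, sd = 0.1)),
             g3 = exp(rnorm(n)))
  expr <- dplyr::bind_cols(
    tibble::tibble(gene_id = c("g1", "g2", "g3"),
                   biotype = c("coding", "coding", "lncRNA")),
    tibble::as_tibble(m, .name_repair = ~ sprintf("s%02d", 1:n))
  )
  net <- build_network(expr, rho_cutoff = 0.5, alpha = 0.01)
  # oracle: test each pair directly and apply the per-gene Bonferroni rule
  pairs <- t(combn(c("g1", "g2", "g3"), 2))
  expected <- character()
  for (r in seq_len(nrow(pairs))) {
    res <- spearman_edge_test(m[pairs[r, 1], ], m[pairs[r, 2], ])
    p_adj <- min(1, res$p * 2)   # each gene participates in 2 tests
    if (res$rs >= 0.5 && p_adj <= 0.01) {
      expected <- c(expected, paste(pairs[r, 1], pairs[r, 2]))
    }
  }
  expect_setequal(paste(net$edges$gene_a, net$edges$gene_b), expected)
  expect_true("g1 g2" %in% expected)  # planted correlated pair found
  # Bonferroni invariants
  expect_true(all(net$edges$p_adj >= net$edges$p))
  expect_true(all(net$edges$p_adj <= 1))
})

test_that("an impossible cutoff empties the edge set and constants are dropped", {
  withr::local_seed(9)
  m <- matrix(rexp(48), nrow = 4)
  m[4, ] <- 1  # constant gene
  expr <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%d", 1:4), biotype = "coding"),
    tibble::as_tibble(m, .name_repair = ~ sprintf("s%02d", 1:12))
  )
  expect_warning(net <- build_network(expr, rho_cutoff = 1.01), "constant")
  expect_equal(nrow(net$edges), 0)
  expect_false("g4" %in% net$nodes$gene_id)
})

test_that("edge categories follow node biotypes and fractions sum to one", {
  net <- make_net(c("a-b", "a-c", "b-c", "c-d"),
                  tibble::tibble(gene_id = c("a", "b", "c", "d"),
                                 biotype = c("coding", "lncRNA", "lncRNA",
                                             "coding")))
  tab <- classify_edges(net)
  expect_equal(sum(tab$n), 4)
  expect_equal(sum(tab$fraction), 1)
  expect_equal(tab$n[tab$category == "lnc-lnc"], 1)      # b-c
  expect_equal(tab$n[tab$category == "coding-lnc"], 3)
  # all-lncRNA network is 100% lnc-lnc
  lnc_net <- make_net(c("x-y"), tibble::tibble(gene_id = c("x", "y"),
                                               biotype = "lncRNA"))
  lnc_tab <- classify_edges(lnc_net)
  expect_equal(lnc_tab$pct[lnc_tab$category == "lnc-lnc"], 100)
  # empty network: zero counts, undefined fractions
  empty <- classify_edges(make_net(character(),
                                   tibble::tibble(gene_id = "z",
                                                  biotype = "coding")))
  expect_equal(sum(empty$n), 0)
  expect_true(all(is.na(empty$fraction)))
})

test_that("clustering and transitivity match closed forms on canonical graphs", {
  tri <- make_net(c("a-b", "b-c", "a-c"))
  cc <- clustering_coefficient(tri)
  expect_equal(attr(cc, "C"), 1)
  expect_equal(transitivity(tri), 1)
  path <- make_net(c("a-b", "b-c"))
  expect_equal(attr(clustering_coefficient(path), "C"), 0)
  star <- make_net(c("h-a", "h-b", "h-c", "h-d"))
  expect_equal(transitivity(star), 0)
  expect_equal(transitivity(make_net("a-b")), 0)  # no connected triples
})

test_that("graph statistics agree with brute-force enumeration", {
  withr::local_seed(31)
  for (rep in 1:20) {
    g <- random_network(sample(4:30, 1), runif(1, 0.1, 0.6))
    oracle <- brute_graph_stats(g$adj)
    cc <- clustering_coefficient(g$net)
    expect_equal(attr(cc, "C"), oracle$C)
    expect_equal(cc$c_i, oracle$c_i, ignore_attr = TRUE)
    expect_equal(transitivity(g$net), oracle$T)
  }
})

test_that("sweep is monotone in the cutoff and consistent with build_network", {
  expr <- generate_expression(
    synthetic_config(n_coding = 12, n_lnc = 6, n_modules = 3,
                     n_samples = 16, n_tissues = 4, noise_sd = 0.8, seed = 2))
  sw <- suppressWarnings(network_sweep(expr, c(0.3, 0.5, 0.7)))
  expect_equal(nrow(sw), 3)
  expect_true(all(diff(sw$edges) <= 0))
  expect_true(all(diff(sw$nodes) <= 0))
  one <- suppressWarnings(network_sweep(expr, 0.5))
  net <- suppressWarnings(build_network(expr, rho_cutoff = 0.5))
  s <- network_stats(net)
  expect_equal(one$edges, s$n_edges)
  expect_equal(one$nodes, s$n_connected)
  expect_equal(one$clustering, s$clustering)
  expect_equal(one$transitivity, s$transitivity)
  expect_error(network_sweep(expr, numeric()),
               class = "lncnet_validation_error")
})

test_that("noise-free modules are cliques at every cutoff", {
  expr <- generate_expression(
    synthetic_config(n_coding = 9, n_lnc = 3, n_modules = 3, n_samples = 12,
                     n_tissues = 3, noise_sd = 0, seed = 6))
  sw <- network_sweep(expr, c(0.3, 0.6, 0.9))
  expect_equal(sw$clustering, rep(1, 3))
})

test_that("ego subnetworks are induced and respect neighbor filters", {
  nodes <- tibble::tibble(
    gene_id = c("hub", "c1", "c2", "l1", "iso"),
    biotype = c("lncRNA", "coding", "coding", "lncRNA", "coding"))
  net <- make_net(c("hub-c1", "hub-c2", "hub-l1", "c1-c2"), nodes)
  ego <- ego_subnetwork(net, "hub")
  expect_setequal(ego$nodes$gene_id, c("hub", "c1", "c2", "l1"))
  expect_equal(nrow(ego$edges), 4)  # induced: includes c1-c2
  # coding-only neighborhood drops the lncRNA neighbor
  cod <- ego_subnetwork(net, "hub", neighbor_filter = "coding")
  expect_setequal(cod$nodes$gene_id, c("hub", "c1", "c2"))
  # isolated focal gene
  iso <- ego_subnetwork(net, "iso")
  expect_equal(iso$nodes$gene_id, "iso")
  expect_equal(nrow(iso$edges), 0)
  # star hub returns the whole star
  star <- make_net(c("h-a", "h-b", "h-c"))
  expect_equal(nrow(ego_subnetwork(star, "h")$nodes), 4)
  expect_error(ego_subnetwork(net, "nope"), class = "lncnet_validation_error")
})

test_that("network constructor enforces simple undirected structure", {
  expect_error(make_net("a-a"), class = "lncnet_validation_error")
  dup <- as_coexpression_network(
    tibble::tibble(gene_a = c("b", "a"), gene_b = c("a", "b")))
  expect_equal(nrow(dup$edges), 1)
  expect_equal(dup$edges$gene_a, "a")
})
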