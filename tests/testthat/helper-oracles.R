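# Independent brute-force oracles used across the suite.

# All permutations of a vector (n <= 7 in practice).
permn <- function(v) {
  n <- length(v)
  if (n == 1) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permn(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# Exact two-sided permutation p for the Spearman statistic: fraction of
# permutations of y with |rs| at least the observed |rs|.
perm_spearman_p <- function(x, y) {
  rs_obs <- cor(rank(x), rank(y))
  all_rs <- vapply(permn(y), function(yy) cor(rank(x), rank(yy)), numeric(1))
  mean(abs(all_rs) >= abs(rs_obs) - 1e-12)
}

# O(n^3) clustering / transitivity by direct enumeration on an adjacency
# matrix (0/1, symmetric, zero diagonal).
brute_graph_stats <- function(adj) {
  n <- nrow(adj)
  tri <- numeric(n)
  triples <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    d <- length(nb)
    triples[i] <- d * (d - 1) / 2
    if (d >= 2) {
      cnt <- 0
      for (a in seq_along(nb)) {
        for (b in seq_along(nb)) {
          if (a < b && adj[nb[a], nb[b]] == 1) cnt <- cnt + 1
        }
      }
      tri[i] <- cnt
    }
  }
  c_i <- ifelse(triples > 0, tri / triples, 0)
  list(
    C = if (n == 0) NA_real_ else mean(c_i),
    c_i = c_i,
    T = if (sum(triples) == 0) 0 else sum(tri) / sum(triples)
  )
}

# Random simple graph as a network object plus its adjacency matrix.
random_network <- function(n_nodes, p_edge) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  adj <- matrix(0, n_nodes, n_nodes)
  edges <- list()
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (runif(1) < p_edge) {
        adj[i, j] <- adj[j, i] <- 1
        edges[[length(edges) + 1]] <- c(ids[i], ids[j])
      }
    }
  }
  edges <- if (length(edges)) {
    tibble::tibble(gene_a = vapply(edges, `[`, "", 1),
                   gene_b = vapply(edges, `[`, "", 2))
  } else {
    tibble::tibble(gene_a = character(), gene_b = character())
  }
  net <- as_coexpression_network(
    edges, tibble::tibble(gene_id = ids, biotype = "coding")
  )
  list(net = net, adj = adj)
}

# Complete graph on n labelled nodes.
complete_network <- function(n) {
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  as_coexpression_network(
    tibble::tibble(gene_a = pairs[, 1], gene_b = pairs[, 2]),
    tibble::tibble(gene_id = ids, biotype = "coding")
  )
}

# Hypergeometric upper tail by the direct finite sum with exact choose().
# All binomials for N <= 25 are exact integers in double precision, so the
# complement is taken by integer subtraction in the numerator (one rounding
# at the final division) rather than as 1 - (lower sum), which cancels.
enum_hypergeom_upper <- function(N, M, n, k) {
  if (k == 0) return(1)
  i <- 0:(k - 1)
  lower_num <- sum(choose(M, i) * choose(N - M, n - i))
  (choose(N, n) - lower_num) / choose(N, n)
}

# Build a network from a compact "a-b" edge specification.
make_net <- function(edge_spec, nodes = NULL) {
  if (length(edge_spec) == 0) {
    edges <- tibble::tibble(gene_a = character(), gene_b = character())
  } else {
    parts <- strsplit(edge_spec, "-", fixed = TRUE)
    edges <- tibble::tibble(gene_a = vapply(parts, `[`, "", 1),
                            gene_b = vapply(parts, `[`, "", 2))
  }
  as_coexpression_network(edges, nodes)
}
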