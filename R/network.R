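#' Spearman rank correlation edge test with Fisher-transform z-score
#'
#' Computes the Spearman coefficient as the Pearson correlation of average
#' (mid) ranks, then
#' \deqn{F(R_s) = \tfrac{1}{2}\log\frac{1+R_s}{1-R_s}, \qquad
#'       Z = \sqrt{\frac{n-3}{1.06}}\,F(R_s),}
#' with a two-sided p-value from the standard-normal tail of \eqn{Z}. The
#' 1.06 factor is the classical variance correction for the Fisher
#' transform of a rank correlation. \eqn{|R_s| = 1} is clamped to
#' \eqn{\pm(1 - 10^{-15})} before transforming.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`; neither constant.
#' @return One-row tibble with columns `rs`, `z`, `p`, `n`.
#' @export
spearman_edge_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) {
    stop_lncnet("`x` and `y` must have equal length", class = "lncnet_validation_error")
  }
  if (n < 4) {
    stop_lncnet("need at least 4 paired observations", class = "lncnet_validation_error")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_lncnet("missing values not allowed", class = "lncnet_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_lncnet("correlation undefined for a constant vector",
                class = "lncnet_constant_error")
  }
  rs <- stats::cor(rank(x), rank(y))
  zp <- fisher_z_p(rs, n)
  tibble(rs = rs, z = zp$z, p = zp$p, n = n)
}

# Vectorized Fisher-transform z and two-sided p for rank correlations.
fisher_z_p <- function(rs, n) {
  rc <- pmin(pmax(rs, -(1 - 1e-15)), 1 - 1e-15)
  f <- 0.5 * log((1 + rc) / (1 - rc))
  z <- sqrt((n - 3) / 1.06) * f
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# All-pairs edge statistics for the testable (non-constant) genes of an
# expression tibble. Returns list(pairs = tibble, nodes = tibble, n_samples).
all_pair_edge_stats <- function(expr) {
  validate_expression(expr)
  m <- expr_matrix(expr)
  n <- ncol(m)
  if (n < 4) {
    stop_lncnet("need at least 4 samples to test edges",
                class = "lncnet_validation_error")
  }
  constant <- apply(m, 1, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    warn(paste0("excluding ", sum(constant),
                " constant-expression gene(s) from network construction"))
  }
  keep <- expr[!constant, , drop = FALSE]
  m <- m[!constant, , drop = FALSE]
  g <- nrow(m)
  if (g < 2) {
    stop_lncnet("fewer than 2 testable genes", class = "lncnet_validation_error")
  }
  ranks <- t(apply(m, 1, rank))
  rs_mat <- stats::cor(t(ranks))
  idx <- which(upper.tri(rs_mat), arr.ind = TRUE)
  ga <- keep$gene_id[idx[, 1]]
  gb <- keep$gene_id[idx[, 2]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  rs <- rs_mat[idx]
  zp <- fisher_z_p(rs, n)
  # per-gene Bonferroni: every gene is in g - 1 tests; an edge must pass
  # alpha under both endpoints' adjusted values (identical families here)
  p_adj <- pmin(1, zp$p * (g - 1))
  bio <- setNames(keep$biotype, keep$gene_id)
  category <- edge_category(bio[ga], bio[gb])
  pairs <- tibble(gene_a = ga, gene_b = gb, rs = rs, z = zp$z,
                  p = zp$p, p_adj = p_adj, category = category) |>
    arrange(.data$gene_a, .data$gene_b)
  list(pairs = pairs,
       nodes = select(keep, "gene_id", "biotype"),
       n_samples = n)
}

edge_category <- function(bio_a, bio_b) {
  dplyr::case_when(
    bio_a == "coding" & bio_b == "coding" ~ "coding-coding",
    bio_a == "lncRNA" & bio_b == "lncRNA" ~ "lnc-lnc",
    TRUE ~ "coding-lnc"
  )
}

#' Assemble a co-expression network from an edge and node table
#'
#' Low-level constructor used by [build_network()] and handy for building
#' toy networks in analyses and tests. The graph is undirected and simple:
#' self-loops are rejected and duplicate pairs collapsed.
#'
#' @param edges Data frame with at least `gene_a`, `gene_b`; optional
#'   statistic columns (`rs`, `z`, `p`, `p_adj`) are kept.
#' @param nodes Data frame with `gene_id`, `biotype`; defaults to the genes
#'   appearing in `edges` with biotype `"coding"`.
#' @param params Named list of construction parameters to record.
#' @return An object of class `"coexpression_network"`: a list with tibbles
#'   `nodes`, `edges` and the `params` list.
#' @export
as_coexpression_network <- function(edges, nodes = NULL, params = list()) {
  edges <- as_tibble(edges)
  if (nrow(edges) > 0) {
    if (any(edges$gene_a == edges$gene_b)) {
      stop_lncnet("self-loops are not allowed", class = "lncnet_validation_error")
    }
    swap <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
    edges <- distinct(edges, .data$gene_a, .data$gene_b, .keep_all = TRUE) |>
      arrange(.data$gene_a, .data$gene_b)
  }
  if (is.null(nodes)) {
    nodes <- tibble(gene_id = sort(unique(c(edges$gene_a, edges$gene_b))),
                    biotype = "coding")
  }
  nodes <- as_tibble(nodes)
  if (anyDuplicated(nodes$gene_id)) {
    stop_lncnet("duplicate node ids", class = "lncnet_validation_error")
  }
  stray <- setdiff(c(edges$gene_a, edges$gene_b), nodes$gene_id)
  if (length(stray) > 0) {
    stop_lncnet(paste0("edge endpoint(s) missing from nodes: ",
                       paste(head(stray, 5), collapse = ", ")),
                class = "lncnet_validation_error")
  }
  if (!"category" %in% names(edges)) {
    bio <- setNames(nodes$biotype, nodes$gene_id)
    edges$category <- edge_category(bio[edges$gene_a], bio[edges$gene_b])
  }
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "coexpression_network")
}

#' Build a coding-lncRNA co-expression network
#'
#' Tests every unordered gene pair with [spearman_edge_test()]; each
#' p-value is Bonferroni-adjusted by the number of tests its endpoint genes
#' participate in, and an edge is kept iff `rs >= rho_cutoff` (or
#' `|rs| >= rho_cutoff` with `absolute = TRUE`) and the adjusted p-value is
#' at most `alpha` under both endpoints. Constant-expression genes are
#' excluded with a warning. All testable genes remain nodes, including ones
#' that end up isolated.
#'
#' @param expr Expression tibble with >= 4 samples.
#' @param rho_cutoff Minimum Spearman coefficient, default 0.5.
#' @param alpha Adjusted p-value threshold, default 0.01.
#' @param absolute If `TRUE`, threshold `|rs|`; by default only positive
#'   correlations form edges.
#' @return A `"coexpression_network"` (see [as_coexpression_network()]);
#'   edge tibble columns: `gene_a`, `gene_b`, `rs`, `z`, `p`, `p_adj`,
#'   `category`.
#' @export
build_network <- function(expr, rho_cutoff = 0.5, alpha = 0.01,
                          absolute = FALSE) {
  stats <- all_pair_edge_stats(expr)
  keep <- if (absolute) abs(stats$pairs$rs) >= rho_cutoff else
    stats$pairs$rs >= rho_cutoff
  edges <- stats$pairs[keep & stats$pairs$p_adj <= alpha, , drop = FALSE]
  as_coexpression_network(
    edges, stats$nodes,
    params = list(rho_cutoff = rho_cutoff, alpha = alpha,
                  absolute = absolute, n_samples = stats$n_samples)
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  bc <- table(factor(x$nodes$biotype, levels = c("coding", "lncRNA")))
  cat("<coexpression_network> ", nrow(x$nodes), " nodes (",
      bc[["coding"]], " coding, ", bc[["lncRNA"]], " lncRNA), ",
      nrow(x$edges), " edges\n", sep = "")
  if (length(x$params)) {
    cat("  params: ",
        paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.coexpression_network <- function(x, ...) {
  x$edges
}

#' @export
glance.coexpression_network <- function(x, ...) {
  network_stats(x)
}

#' Per-node degrees of a co-expression network
#'
#' @param net A `"coexpression_network"`.
#' @return Tibble `gene_id`, `biotype`, `degree` (0 for isolated nodes).
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  d <- table(factor(c(net$edges$gene_a, net$edges$gene_b),
                    levels = net$nodes$gene_id))
  mutate(net$nodes, degree = as.integer(d[.data$gene_id]))
}

# Sparse adjacency matrix over all nodes, in node-table order.
adjacency_matrix <- function(net) {
  ids <- net$nodes$gene_id
  n <- length(ids)
  i <- match(net$edges$gene_a, ids)
  j <- match(net$edges$gene_b, ids)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                       dims = c(n, n), dimnames = list(ids, ids))
}

# Per-node triangle and centered-triple counts.
triangle_triple_counts <- function(net) {
  a <- adjacency_matrix(net)
  deg <- Matrix::rowSums(a)
  tri <- if (nrow(a) == 0) numeric(0) else Matrix::diag(a %*% a %*% a) / 2
  tibble(gene_id = net$nodes$gene_id,
         degree = as.integer(deg),
         triangles = as.numeric(tri),
         triples = choose(as.integer(deg), 2))
}

#' Local and average clustering coefficients
#'
#' The local coefficient of node \eqn{i} is the number of triangles through
#' \eqn{i} divided by the number of triples centered on \eqn{i}
#' (\eqn{\binom{d_i}{2}}); nodes of degree < 2 score 0. The network
#' coefficient \eqn{C} is the mean of the local values over all nodes.
#'
#' @param net A `"coexpression_network"`.
#' @return Tibble `gene_id`, `degree`, `triangles`, `triples`, `c_i`, with
#'   the average \eqn{C} as attribute `"C"`.
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  tt <- triangle_triple_counts(net)
  out <- mutate(tt, c_i = if_else(.data$triples > 0,
                                  .data$triangles / .data$triples, 0))
  attr(out, "C") <- if (nrow(out) == 0) NA_real_ else mean(out$c_i)
  out
}

#' Network transitivity (global triangle density)
#'
#' \eqn{T = 3 \times (\mathrm{number\ of\ triangles}) /
#' (\mathrm{number\ of\ connected\ triples})}; the factor 3 accounts for a
#' triangle contributing one centered triple at each of its nodes, so
#' \eqn{T \in [0, 1]} with \eqn{T = 1} for a complete graph. Returns 0 when
#' the graph has no connected triples.
#'
#' @param net A `"coexpression_network"`.
#' @return A single number in \[0, 1\].
#' @export
transitivity <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  tt <- triangle_triple_counts(net)
  total_triples <- sum(tt$triples)
  if (total_triples == 0) return(0)
  total_triangles <- sum(tt$triangles) / 3
  3 * total_triangles / total_triples
}

#' Summary statistics of a co-expression network
#'
#' @param net A `"coexpression_network"`.
#' @return One-row tibble: node counts by biotype, connected (degree >= 1)
#'   node count, edge counts by category, average clustering coefficient
#'   `clustering` and `transitivity`.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  deg <- node_degrees(net)
  cats <- table(factor(net$edges$category,
                       levels = c("coding-coding", "coding-lnc", "lnc-lnc")))
  cc <- clustering_coefficient(net)
  tibble(
    n_nodes = nrow(net$nodes),
    n_coding = sum(net$nodes$biotype == "coding"),
    n_lncRNA = sum(net$nodes$biotype == "lncRNA"),
    n_connected = sum(deg$degree > 0),
    n_edges = nrow(net$edges),
    n_coding_coding = as.integer(cats[["coding-coding"]]),
    n_coding_lnc = as.integer(cats[["coding-lnc"]]),
    n_lnc_lnc = as.integer(cats[["lnc-lnc"]]),
    clustering = attr(cc, "C"),
    transitivity = transitivity(net)
  )
}

#' Tabulate edge counts and fractions by biotype category
#'
#' @param net A `"coexpression_network"`, or a named vector/list of counts
#'   for the three categories (`coding-coding`, `coding-lnc`, `lnc-lnc`).
#' @return Tibble `category`, `n`, `fraction` (proportion) and `pct`
#'   (percentage rounded to 2 decimals for display). With zero edges the
#'   fractions are `NA`.
#' @export
classify_edges <- function(net) {
  if (inherits(net, "coexpression_network")) {
    counts <- table(factor(net$edges$category,
                           levels = c("coding-coding", "coding-lnc", "lnc-lnc")))
    counts <- setNames(as.numeric(counts), names(counts))
  } else {
    counts <- unlist(net)
    missing <- setdiff(c("coding-coding", "coding-lnc", "lnc-lnc"), names(counts))
    counts[missing] <- 0
    counts <- counts[c("coding-coding", "coding-lnc", "lnc-lnc")]
  }
  total <- sum(counts)
  frac <- if (total > 0) counts / total else rep(NA_real_, 3)
  tibble(category = names(counts), n = as.numeric(counts),
         fraction = as.numeric(frac), pct = percent(as.numeric(frac)))
}

#' Network statistics across a grid of correlation cutoffs
#'
#' Edge statistics are computed once for all gene pairs, then thresholded
#' at each cutoff; each thresholded network is identical to what
#' [build_network()] would produce with that cutoff.
#'
#' @param expr Expression tibble.
#' @param cutoffs Numeric vector of Spearman-coefficient thresholds.
#' @param alpha Adjusted p-value threshold (default 0.01).
#' @param absolute Threshold `|rs|` instead of `rs`.
#' @return Tibble with one row per cutoff: `cutoff`, `nodes` (connected,
#'   degree >= 1), `edges`, `clustering`, `transitivity`.
#' @export
network_sweep <- function(expr, cutoffs, alpha = 0.01, absolute = FALSE) {
  if (length(cutoffs) == 0) {
    stop_lncnet("`cutoffs` must not be empty", class = "lncnet_validation_error")
  }
  stats <- all_pair_edge_stats(expr)
  purrr::map_dfr(cutoffs, function(cut) {
    keep <- if (absolute) abs(stats$pairs$rs) >= cut else stats$pairs$rs >= cut
    net <- as_coexpression_network(
      stats$pairs[keep & stats$pairs$p_adj <= alpha, , drop = FALSE],
      stats$nodes,
      params = list(rho_cutoff = cut, alpha = alpha, absolute = absolute)
    )
    s <- network_stats(net)
    tibble(cutoff = cut, nodes = s$n_connected, edges = s$n_edges,
           clustering = s$clustering, transitivity = s$transitivity)
  })
}

#' Ego subnetwork of a focal gene
#'
#' Induced subgraph on a gene and its immediate neighbors, optionally
#' restricted to neighbors of one biotype or passing a predicate.
#'
#' @param net A `"coexpression_network"`.
#' @param gene Focal gene id (must be a node).
#' @param neighbor_filter Either `NULL` (keep all neighbors), a biotype
#'   string (`"coding"` or `"lncRNA"`), or a predicate taking the neighbor
#'   node tibble and returning a logical vector.
#' @return A `"coexpression_network"` on the focal gene plus kept neighbors.
#' @export
ego_subnetwork <- function(net, gene, neighbor_filter = NULL) {
  stopifnot(inherits(net, "coexpression_network"))
  if (!gene %in% net$nodes$gene_id) {
    stop_lncnet(paste0("gene not in network: ", gene),
                class = "lncnet_validation_error")
  }
  nb <- neighbors_of(net, gene)
  nb_nodes <- filter(net$nodes, .data$gene_id %in% nb)
  if (!is.null(neighbor_filter)) {
    keep <- if (is.function(neighbor_filter)) {
      neighbor_filter(nb_nodes)
    } else {
      nb_nodes$biotype %in% neighbor_filter
    }
    nb_nodes <- nb_nodes[keep, , drop = FALSE]
  }
  members <- c(gene, nb_nodes$gene_id)
  as_coexpression_network(
    filter(net$edges, .data$gene_a %in% members & .data$gene_b %in% members),
    filter(net$nodes, .data$gene_id %in% members),
    params = c(net$params, list(ego = gene))
  )
}

# Immediate neighbors of a gene.
neighbors_of <- function(net, gene) {
  unique(c(net$edges$gene_b[net$edges$gene_a == gene],
           net$edges$gene_a[net$edges$gene_b == gene]))
}

#' Export the degree histogram of a network
#'
#' @param net A `"coexpression_network"`.
#' @return Tibble `degree`, `n_nodes` (only degrees >= 1 are listed).
#' @export
degree_histogram <- function(net) {
  node_degrees(net) |>
    filter(.data$degree > 0) |>
    count(.data$degree, name = "n_nodes")
}
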